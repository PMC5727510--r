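#' Mean time series of a seed region
#'
#' Unweighted average over the region's voxels at each timepoint.
#'
#' @param ts a [subject_ts()].
#' @param roi integer vector of mask ordinals (non-empty, inside the mask).
#' @return numeric vector of length T.
#' @export
seed_timeseries <- function(ts, roi) {
  stopifnot(inherits(ts, "subject_ts"))
  roi <- as.integer(roi)
  if (!length(roi)) stop("seed region is empty")
  if (any(roi < 1L | roi > ncol(ts$data)))
    stop("seed region falls outside the group mask")
  rowMeans(ts$data[, roi, drop = FALSE])
}

fisher_z <- function(r, clamp = 1 - 1e-7) {
  atanh(pmin(pmax(r, -clamp), clamp))
}

#' Seed-based correlation map (Fisher Z)
#'
#' Pearson correlation of the seed time series with every in-mask voxel,
#' clamped to +/- (1 - 1e-7) and transformed with `atanh` (Fisher Z).
#'
#' @param ts a [subject_ts()].
#' @param seed_series numeric seed time series (length T, nonconstant), e.g.
#'   from [seed_timeseries()].
#' @return a [stat_map()] of kind `"fisherz"`.
#' @export
sca_map <- function(ts, seed_series) {
  stopifnot(inherits(ts, "subject_ts"))
  if (stats::sd(seed_series) == 0) stop("constant seed time series")
  r <- as.numeric(stats::cor(seed_series, ts$data))
  stat_map(fisher_z(r), ts$mask, "fisherz")
}

#' Group-level GLM over subject connectivity maps
#'
#' Per voxel, ordinary least-squares regression of the subjects' Fisher-Z
#' connectivity values on the same design used for MDMR. Emits the t
#' statistic of the variable of interest and its signed Z equivalent
#' (through the t CDF then the inverse normal), so the positive and negative
#' contrasts are `z` and `-z`.
#'
#' @param z_maps list of per-subject [stat_map()]s (or an n x V matrix).
#' @param design an [mdmr_design()].
#' @return Object of class `cwas_glm`: `t`, `z` ([stat_map()]s), `beta`
#'   (interest coefficients), `df`, `design`.
#' @export
group_glm <- function(z_maps, design) {
  stopifnot(inherits(design, "mdmr_design"))
  y <- if (is.list(z_maps)) {
    mask <- z_maps[[1]]$mask
    do.call(rbind, lapply(z_maps, function(m) m$values))
  } else {
    mask <- NULL
    as.matrix(z_maps)
  }
  x <- design$x_full
  n <- nrow(x); p <- ncol(x)
  if (nrow(y) != n) stop("number of maps must match design rows")
  if (n < p + 2L) stop("need at least p + 2 subjects")
  qrx <- qr(x)
  if (qrx$rank < p) stop("rank-deficient design")
  coefs <- qr.coef(qrx, y)
  res <- y - x %*% coefs
  df <- n - p
  sigma2 <- colSums(res^2) / df
  xtxinv <- chol2inv(qr.R(qrx))
  se <- sqrt(sigma2 * xtxinv[p, p])
  tval <- coefs[p, ] / se
  z <- stats::qnorm(stats::pt(tval, df))
  z <- pmin(pmax(z, -8.2), 8.2)
  if (is.null(mask)) {
    tmap <- tval; zmap <- z
  } else {
    tmap <- stat_map(tval, mask, "t"); zmap <- stat_map(z, mask, "z")
  }
  structure(list(t = tmap, z = zmap, beta = coefs[p, ], df = df,
                 design = design, residuals = res),
            class = "cwas_glm")
}

#' @export
print.cwas_glm <- function(x, ...) {
  tv <- if (inherits(x$t, "stat_map")) x$t$values else x$t
  cat("Group-level GLM (", utils::tail(colnames(x$design$x_full), 1),
      "), df = ", x$df, ", t range [", signif(min(tv), 4), ", ",
      signif(max(tv), 4), "]\n", sep = "")
  invisible(x)
}

#' Per-subject connection strength for a cluster ROI
#'
#' Mean Fisher-Z connectivity over the cluster's voxels, per subject.
#'
#' @param z_maps list of per-subject [stat_map()]s (kind `"fisherz"`).
#' @param cluster_roi integer mask ordinals of the cluster (non-empty).
#' @return numeric vector, one value per subject.
#' @export
extract_connection <- function(z_maps, cluster_roi) {
  cluster_roi <- as.integer(cluster_roi)
  if (!length(cluster_roi)) stop("empty cluster")
  vapply(z_maps, function(m) {
    v <- if (inherits(m, "stat_map")) m$values else as.numeric(m)
    mean(v[cluster_roi])
  }, numeric(1))
}

#' Difference between two dependent correlations sharing one variable
#'
#' Steiger-type Z test for H0: cor(ifc, a) = cor(ifc, b) when the two
#' correlations share the connectivity variable. With Fisher transforms
#' z_jk, z_jh, back-transformed mean correlation
#' `rbar = tanh((z_jk + z_jh)/2)`, and
#' `psi = r_kh (1 - 2 rbar^2) - rbar^2 (1 - 2 rbar^2 - r_kh^2) / 2`,
#' the statistic is
#' `Z = (z_jk - z_jh) sqrt((n - 3) / (2 - 2 psi / (1 - rbar^2)^2))`,
#' referred to the standard normal (two-sided).
#'
#' @param ifc per-subject connectivity strengths (the shared variable).
#' @param pheno_a,pheno_b the two phenotypes.
#' @return object of class `htest` with the Z statistic, two-sided p and
#'   the three pairwise correlations.
#' @export
corr_diff_test <- function(ifc, pheno_a, pheno_b) {
  n <- length(ifc)
  if (length(pheno_a) != n || length(pheno_b) != n)
    stop("inputs must have equal length")
  if (n < 4L) stop("need n >= 4")
  r_jk <- stats::cor(ifc, pheno_a)
  r_jh <- stats::cor(ifc, pheno_b)
  r_kh <- stats::cor(pheno_a, pheno_b)
  if (abs(r_jk) >= 1 - 1e-12 || abs(r_jh) >= 1 - 1e-12)
    stop("a connectivity-behaviour correlation is exactly +/- 1; ",
         "test undefined")
  z_jk <- atanh(r_jk); z_jh <- atanh(r_jh)
  if (z_jk == z_jh) {
    zstat <- 0          # identical correlations (e.g. pheno_a == pheno_b)
  } else {
    if (abs(r_kh) >= 1 - 1e-12)
      stop("the two phenotypes are perfectly correlated but give unequal ",
           "correlations; test undefined")
    rbar <- tanh((z_jk + z_jh) / 2)
    psi <- r_kh * (1 - 2 * rbar^2) - 0.5 * rbar^2 * (1 - 2 * rbar^2 - r_kh^2)
    cov_z <- psi / (1 - rbar^2)^2
    zstat <- (z_jk - z_jh) * sqrt((n - 3) / (2 - 2 * cov_z))
  }
  p <- 2 * stats::pnorm(abs(zstat), lower.tail = FALSE)
  structure(list(statistic = c(Z = zstat), p.value = p,
                 estimate = c(r_jk = r_jk, r_jh = r_jh, r_kh = r_kh),
                 parameter = c(n = n),
                 method = paste("Steiger Z test for two dependent",
                                "correlations with one variable in common"),
                 alternative = "two.sided",
                 data.name = "ifc vs pheno_a and pheno_b"),
            class = "htest")
}

#' D'Agostino omnibus normality test
#'
#' The K-squared omnibus statistic combining the transformed skewness
#' (D'Agostino 1970) and kurtosis (Anscombe-Glynn 1983) Z scores,
#' `K2 = Z1^2 + Z2^2`, referred to chi-squared with 2 df.
#'
#' @param x numeric vector, n >= 8.
#' @return object of class `htest` with K2, skewness/kurtosis Z's and p.
#' @export
dagostino_test <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 8L) stop("need n >= 8")
  if (stats::sd(x) == 0) stop("zero-variance input")
  m <- mean(x)
  m2 <- mean((x - m)^2); m3 <- mean((x - m)^3); m4 <- mean((x - m)^4)
  b1 <- m3 / m2^1.5
  b2 <- m4 / m2^2
  # skewness: D'Agostino's Johnson SU transform
  y <- b1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  z1 <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))
  # kurtosis: Anscombe-Glynn
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - eb2) / sqrt(vb2)
  sqb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sqb1 * (2 / sqb1 + sqrt(1 + 4 / sqb1^2))
  z2 <- ((1 - 2 / (9 * a)) -
         ((1 - 2 / a) / (1 + xk * sqrt(2 / (a - 4))))^(1 / 3)) /
    sqrt(2 / (9 * a))
  k2 <- z1^2 + z2^2
  p <- stats::pchisq(k2, df = 2, lower.tail = FALSE)
  structure(list(statistic = c(K2 = k2), p.value = p,
                 parameter = c(df = 2),
                 estimate = c(skew_z = z1, kurt_z = z2),
                 method = "D'Agostino K-squared omnibus normality test",
                 data.name = deparse(substitute(x))),
            class = "htest")
}

#' Numeracy-literacy discrepancy analysis
#'
#' The per-subject discrepancy is `numeracy_ss - literacy_ss` (positive =
#' "Superior Numerical"). The discrepancies are tested for normality with
#' the D'Agostino omnibus test, and Pearson-correlated with each named
#' connection (raw and Bonferroni-adjusted p-values are both reported).
#'
#' @param pheno phenotype table with `literacy_ss` and `numeracy_ss`.
#' @param connections named list (or data.frame) of per-subject connection
#'   strength vectors.
#' @return list: `discrepancy` (vector), `normality` (htest), `table`
#'   (data.frame connection, r, p, p_bonferroni).
#' @export
discrepancy_analysis <- function(pheno, connections) {
  if (!all(c("literacy_ss", "numeracy_ss") %in% names(pheno)))
    stop("phenotype table must contain literacy_ss and numeracy_ss")
  d <- pheno$numeracy_ss - pheno$literacy_ss
  if (stats::sd(d) == 0) stop("zero-variance discrepancy scores")
  connections <- as.list(connections)
  norm <- dagostino_test(d)
  rows <- lapply(names(connections), function(nm) {
    ct <- stats::cor.test(d, connections[[nm]])
    data.frame(connection = nm, r = unname(ct$estimate),
               p = ct$p.value, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$p_bonferroni <- pmin(tab$p * nrow(tab), 1)
  list(discrepancy = d, normality = norm, table = tab)
}

#' Cross-correlation matrix of named connections
#'
#' Pairwise Pearson correlations (and two-sided p-values) of connection
#' strength vectors across subjects.
#'
#' @param connections named list (or data.frame) of equal-length vectors
#'   (>= 2 connections).
#' @return list with `r` (symmetric, unit-diagonal matrix) and `p`.
#' @export
connection_matrix <- function(connections) {
  connections <- as.list(connections)
  k <- length(connections)
  if (k < 2L) stop("need at least 2 connections")
  len <- vapply(connections, length, 0L)
  if (length(unique(len)) != 1L) stop("connection vectors differ in length")
  nms <- names(connections)
  r <- diag(k); p <- matrix(NA_real_, k, k)
  dimnames(r) <- dimnames(p) <- list(nms, nms)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    ct <- stats::cor.test(connections[[i]], connections[[j]])
    r[i, j] <- r[j, i] <- unname(ct$estimate)
    p[i, j] <- p[j, i] <- ct$p.value
  }
  list(r = r, p = p)
}
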