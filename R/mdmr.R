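#' Whole-brain connectivity profile of one target voxel
#'
#' Pearson correlations between the target voxel's time series and every
#' other in-mask voxel (self entry excluded).
#'
#' @param ts a [subject_ts()].
#' @param voxel target voxel mask ordinal.
#' @return numeric vector of length V - 1 (entries in mask-ordinal order with
#'   the target removed).
#' @export
ifc_profile <- function(ts, voxel) {
  stopifnot(inherits(ts, "subject_ts"))
  V <- ncol(ts$data)
  if (voxel < 1L || voxel > V) stop("voxel ordinal out of range")
  sds <- apply(ts$data, 2, stats::sd)
  if (sds[voxel] == 0) stop("zero-variance target voxel ", voxel)
  zero <- which(sds == 0)
  if (length(zero))
    stop("zero-variance partner voxel(s), first at ordinal ", zero[1],
         "; rebuild the mask to exclude them")
  r <- as.numeric(stats::cor(ts$data[, voxel], ts$data))
  r[-voxel]
}

#' Between-subject connectivity-profile distance matrix
#'
#' For one target voxel, the distance between two subjects is
#' `sqrt(2 * (1 - r))`, where r is the spatial (across-voxel) Pearson
#' correlation of their connectivity profiles. The diagonal is exactly 0 and
#' entries lie in \[0, 2\].
#'
#' @param profiles n x (V-1) matrix, one subject's profile per row, or a list
#'   of equal-length profile vectors.
#' @return n x n symmetric distance matrix of class `dist_matrix`.
#' @export
distance_matrix <- function(profiles) {
  if (is.list(profiles)) profiles <- do.call(rbind, profiles)
  profiles <- as.matrix(profiles)
  sds <- apply(profiles, 1, stats::sd)
  zero <- which(sds == 0)
  if (length(zero))
    stop("zero-variance profile for subject ", zero[1],
         " (spatial correlation undefined)")
  r <- stats::cor(t(profiles))
  r[r > 1] <- 1; r[r < -1] <- -1
  d <- sqrt(2 * (1 - r))
  diag(d) <- 0
  structure(d, class = c("dist_matrix", "matrix"))
}

#' Gower-centered inner-product matrix
#'
#' `G = C A C` with `A = -d^2 / 2` and `C = I - 11'/n`. Every row of G sums
#' to zero; for distances realisable in Euclidean space G is positive
#' semi-definite (classical multidimensional scaling).
#'
#' @param d n x n distance matrix.
#' @return n x n symmetric matrix G.
#' @export
gower_center <- function(d) {
  d <- unclass(as.matrix(d))
  a <- -0.5 * d^2
  n <- nrow(a)
  rm_ <- rowMeans(a); gm <- mean(a)
  g <- a - outer(rm_, rep(1, n)) - outer(rep(1, n), rm_) + gm
  (g + t(g)) / 2
}

#' Design for a covariate-adjusted MDMR model
#'
#' Full design = intercept + nuisance covariates + one variable of interest;
#' reduced design drops the variable of interest. The default nuisance set is
#' age, sex, handedness, mean FD, and global connectivity.
#'
#' @param pheno phenotype data.frame.
#' @param interest name of the variable-of-interest column.
#' @param nuisance character vector of nuisance column names.
#' @return Object of class `mdmr_design`: `x_full`, `x_reduced`, `interest`
#'   (the raw interest vector), `names`.
#' @export
mdmr_design <- function(pheno, interest,
                        nuisance = c("age", "sex", "handedness",
                                     "mean_fd", "gcor")) {
  miss <- setdiff(c(interest, nuisance), names(pheno))
  if (length(miss)) stop("missing phenotype columns: ",
                         paste(miss, collapse = ", "))
  if (interest %in% nuisance)
    stop("variable of interest also appears in the nuisance set")
  xr <- cbind(intercept = 1,
              as.matrix(pheno[, nuisance, drop = FALSE]))
  xi <- as.numeric(pheno[[interest]])
  xf <- cbind(xr, xi)
  colnames(xf) <- c(colnames(xr), interest)
  n <- nrow(xf)
  if (qr(xf)$rank < ncol(xf)) stop("full design is rank deficient")
  if (n <= ncol(xf) + 1L) stop("need n > p + 1 subjects")
  structure(list(x_full = xf, x_reduced = xr, interest = xi,
                 names = c(nuisance, interest)),
            class = "mdmr_design")
}

hat_matrix <- function(x) {
  q <- qr.Q(qr(x))
  tcrossprod(q)
}

#' PERMANOVA-style pseudo-F statistic
#'
#' With H and H0 the hat (projection) matrices of the full and reduced
#' designs and m = 1 variable of interest:
#' `F = [tr(H G H) - tr(H0 G H0)] / [tr((I-H) G (I-H)) / (n - rank(H))]`.
#' For profiles of length 1 (univariate Euclidean responses) this reduces to
#' the classical partial F of ordinary regression.
#'
#' @param g Gower-centered matrix from [gower_center()].
#' @param design an [mdmr_design()].
#' @return scalar pseudo-F.
#' @export
pseudo_f <- function(g, design) {
  stopifnot(inherits(design, "mdmr_design"))
  n <- nrow(g)
  h <- hat_matrix(design$x_full)
  h0 <- hat_matrix(design$x_reduced)
  p <- ncol(design$x_full)
  num <- sum(h * g) - sum(h0 * g)          # tr(HGH) = tr(HG) for idempotent H
  den <- sum(diag(g)) - sum(h * g)
  if (den <= n * 1e-12 * max(1, abs(sum(diag(g)))))
    stop("residual trace <= 0: degenerate distance matrix ",
         "(e.g. identical profiles for all subjects)")
  num / (den / (n - p))
}

#' Permutation p-value for one distance matrix
#'
#' Under the Freedman-Lane scheme (default) the nuisance-residualized
#' variable of interest is permuted while the nuisance columns are held
#' fixed; `scheme = "raw"` permutes the raw variable instead. The p-value
#' uses the "at least as extreme, including the observed" convention,
#' `p = (1 + #\{F_perm >= F_obs\}) / (1 + n_perm)`, with floor
#' `1/(n_perm + 1)`.
#'
#' @param g Gower-centered matrix.
#' @param design an [mdmr_design()].
#' @param n_perm number of permutations (full-scale default 10,000).
#' @param seed integer seed used when `perms` is not supplied.
#' @param perms optional explicit n x n_perm matrix of permutation indices
#'   (one permutation per column), for oracle comparisons.
#' @param scheme `"freedman_lane"` or `"raw"`.
#' @return list with `p`, `f_obs`, `f_perm`, `n_perm`.
#' @export
permutation_test <- function(g, design, n_perm = 10000, seed = 1L,
                             perms = NULL,
                             scheme = c("freedman_lane", "raw")) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(design, "mdmr_design"))
  n <- nrow(g)
  if (is.null(perms)) {
    if (n_perm < 1L) stop("'n_perm' must be >= 1")
    set.seed(seed)
    perms <- replicate(n_perm, sample.int(n))
  }
  perms <- as.matrix(perms)
  qmat <- perm_q_matrix(design, perms, scheme)
  stats <- f_from_q(g, design, qmat)
  f_obs <- stats$f[1]
  f_perm <- stats$f[-1]
  p <- (1 + sum(f_perm >= f_obs)) / (1 + ncol(perms))
  list(p = p, f_obs = f_obs, f_perm = f_perm, n_perm = ncol(perms))
}

# Unit-norm residual directions of the (possibly permuted) interest variable
# after projecting out the reduced design. Column 1 is the observed one.
perm_q_matrix <- function(design, perms, scheme) {
  qz <- qr.Q(qr(design$x_reduced))
  x <- design$interest
  e <- x - qz %*% crossprod(qz, x)
  base <- if (scheme == "freedman_lane") as.numeric(e) else x
  em <- cbind(as.numeric(e),
              matrix(base[perms], nrow = length(x)))
  em <- em - qz %*% crossprod(qz, em)
  nrm <- sqrt(colSums(em^2))
  if (any(nrm < 1e-10))
    stop("variable of interest is collinear with the nuisance design")
  sweep(em, 2, nrm, "/")
}

# Pseudo-F for observed + permuted interest directions from precomputed
# quantities: numerator q'Gq, denominator tr(G) - tr(H0 G) - q'Gq.
f_from_q <- function(g, design, qmat) {
  n <- nrow(g)
  qz <- qr.Q(qr(design$x_reduced))
  tr_g <- sum(diag(g))
  tr_h0g <- sum((g %*% qz) * qz)
  s <- colSums((g %*% qmat) * qmat)
  p_full <- ncol(design$x_reduced) + 1L
  den <- (tr_g - tr_h0g - s) / (n - p_full)
  list(f = s / den, num = s, den = den)
}

#' One-tailed p-to-Z conversion
#'
#' `z = qnorm(1 - p)`; `p = 1` maps to the documented floor `-z_max`
#' (default 8.2, roughly the double-precision limit of the normal quantile).
#'
#' @param p p-values in (0, 1].
#' @param z_max cap for |z|.
#' @return z values.
#' @export
p_to_z <- function(p, z_max = 8.2) {
  if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  z <- stats::qnorm(1 - p)
  pmin(pmax(z, -z_max), z_max)
}

#' Fit a voxel-wise MDMR connectome-wide association model
#'
#' For every mask voxel: (1) each subject's whole-brain connectivity profile
#' (Pearson r of the target voxel with all other voxels); (2) the
#' between-subject distance matrix `sqrt(2 (1 - r))` on those profiles;
#' (3) Gower centering, covariate-adjusted pseudo-F, and a permutation
#' p-value converted to a one-tailed Z. One shared permutation sequence
#' (from `seed`) is reused across voxels, enabling permutation-based
#' cluster correction.
#'
#' If the nuisance set contains `"gcor"` and the phenotype column is absent
#' or NA, per-subject global connectivity is computed from the data.
#'
#' @param ts_list list of [subject_ts()] sharing one mask, in phenotype row
#'   order.
#' @param pheno phenotype data.frame (one row per subject).
#' @param interest variable-of-interest column (`"literacy_ss"` or
#'   `"numeracy_ss"` for the two preset models).
#' @param nuisance nuisance column names.
#' @param n_perm permutations (full-scale default 10,000).
#' @param seed integer seed for the shared permutation sequence.
#' @param scheme permutation scheme, see [permutation_test()].
#' @param batch_size voxels per profile batch (memory/speed trade-off).
#' @param engine `"cpp"` (compiled batch kernel, default) or `"r"` (reference
#'   implementation); both produce identical results.
#' @param keep_perm_f keep the V x (n_perm + 1) matrix of pseudo-F values
#'   (observed first), needed for permutation cluster correction.
#' @return Object of class `cwas_mdmr` with elements `f`, `p`, `z`
#'   ([stat_map()]s), `design`, `interest`, `n_perm`, `seed`, `scheme`,
#'   `n_missing`, and optionally `perm_f`.
#' @export
run_mdmr <- function(ts_list, pheno, interest = "numeracy_ss",
                     nuisance = c("age", "sex", "handedness",
                                  "mean_fd", "gcor"),
                     n_perm = 10000, seed = 1L,
                     scheme = c("freedman_lane", "raw"),
                     batch_size = 64, engine = c("cpp", "r"),
                     keep_perm_f = FALSE) {
  scheme <- match.arg(scheme)
  engine <- match.arg(engine)
  n <- length(ts_list)
  if (n < 4L) stop("need at least 4 subjects")
  if (nrow(pheno) != n) stop("phenotype rows must match subjects")
  mask <- ts_list[[1]]$mask
  V <- mask$n_voxels
  for (ts in ts_list)
    if (!identical(dim(ts$data)[2], V) ||
        !identical(ts$mask$ijk, mask$ijk))
      stop("subjects must share one group mask")

  if ("gcor" %in% nuisance &&
      (!"gcor" %in% names(pheno) || anyNA(pheno$gcor)))
    pheno$gcor <- vapply(ts_list, gcor, numeric(1))

  design <- mdmr_design(pheno, interest, nuisance)

  # column-standardized data (zero mean, unit norm) per subject
  zs <- vector("list", n)
  for (s in seq_len(n)) {
    u <- ts_list[[s]]$data
    u <- sweep(u, 2, colMeans(u))
    nrm <- sqrt(colSums(u^2))
    zero <- which(nrm == 0)
    if (length(zero))
      stop("preflight: zero-variance voxel ordinal ", zero[1],
           " for subject ", ts_list[[s]]$subject_id,
           "; rebuild the mask to exclude degenerate voxels")
    zs[[s]] <- sweep(u, 2, nrm, "/")
  }

  set.seed(seed)
  perms <- replicate(n_perm, sample.int(n))
  qmat <- perm_q_matrix(design, perms, scheme)
  qz <- qr.Q(qr(design$x_reduced))
  p_full <- ncol(design$x_reduced) + 1L
  cmat <- diag(n) - matrix(1 / n, n, n)

  f_obs <- p_perm <- rep(NA_real_, V)
  perm_f <- if (keep_perm_f) matrix(NA_real_, V, n_perm + 1L) else NULL
  n_missing <- 0L
  batches <- split(seq_len(V), ceiling(seq_len(V) / batch_size))
  for (b in batches) {
    nb <- length(b)
    if (engine == "cpp") {
      # per-subject profiles, voxel-contiguous: V x nb per subject
      prof_t <- lapply(zs, function(z)
        crossprod(z, z[, b, drop = FALSE]))
      res <- .mdmr_batch_cpp(prof_t, as.integer(b - 1L), qz, qmat,
                             as.integer(n - p_full))
      for (k in seq_len(nb)) {
        v <- b[k]
        if (!res$ok[k]) { n_missing <- n_missing + 1L; next }
        fs <- res$f[k, ]
        f_obs[v] <- fs[1]
        p_perm[v] <- (1 + sum(fs[-1] >= fs[1])) / (1 + n_perm)
        if (keep_perm_f) perm_f[v, ] <- fs
      }
      next
    }
    # per-subject correlation profiles for this voxel batch: nb x V each
    prof <- array(NA_real_, dim = c(nb, V, n))
    for (s in seq_len(n))
      prof[, , s] <- crossprod(zs[[s]][, b, drop = FALSE], zs[[s]])
    for (k in seq_len(nb)) {
      v <- b[k]
      m <- t(prof[k, -v, , drop = TRUE])        # n x (V-1) profiles
      m <- m - rowMeans(m)
      nrm <- sqrt(rowSums(m^2))
      if (any(nrm == 0)) { n_missing <- n_missing + 1L; next }
      m <- m / nrm
      r <- tcrossprod(m)
      r[r > 1] <- 1; r[r < -1] <- -1
      g <- cmat %*% r %*% cmat    # Gower centering of d = sqrt(2(1-r))
      g <- (g + t(g)) / 2
      tr_g <- sum(diag(g))
      tr_h0g <- sum((g %*% qz) * qz)
      s_q <- colSums((g %*% qmat) * qmat)
      den <- (tr_g - tr_h0g - s_q) / (n - p_full)
      if (!is.finite(den[1]) || den[1] <= 1e-12) {
        n_missing <- n_missing + 1L; next
      }
      fs <- s_q / den
      f_obs[v] <- fs[1]
      p_perm[v] <- (1 + sum(fs[-1] >= fs[1])) / (1 + n_perm)
      if (keep_perm_f) perm_f[v, ] <- fs
    }
  }
  ok <- !is.na(p_perm)
  z <- rep(NA_real_, V)
  z[ok] <- p_to_z(p_perm[ok])
  structure(list(
    f = stat_map(f_obs, mask, "pseudoF"),
    p = stat_map(p_perm, mask, "p"),
    z = stat_map(z, mask, "z"),
    design = design, interest = interest, nuisance = nuisance,
    n_perm = n_perm, seed = seed, scheme = scheme,
    n_missing = n_missing, n_subjects = n,
    perm_f = perm_f, mask = mask),
    class = "cwas_mdmr")
}

#' Peak voxel of an MDMR fit
#'
#' The maximum-Z voxel of the fit. Because permutation p-values (and hence
#' Z) saturate at the floor `1/(n_perm + 1)`, ties on Z are broken by the
#' underlying pseudo-F, then by the lowest mask ordinal.
#'
#' @param fit a `cwas_mdmr` object.
#' @return the peak voxel's mask ordinal.
#' @export
mdmr_peak <- function(fit) {
  stopifnot(inherits(fit, "cwas_mdmr"))
  order(-fit$z$values, -fit$f$values, na.last = TRUE)[1]
}

#' @export
print.cwas_mdmr <- function(x, ...) {
  cat("Connectome-wide MDMR fit\n")
  cat("  variable of interest:", x$interest, "\n")
  cat("  nuisance:", paste(x$nuisance, collapse = ", "), "\n")
  cat("  subjects:", x$n_subjects, "  voxels:", x$mask$n_voxels,
      "  permutations:", x$n_perm, "(", x$scheme, ")\n")
  cat("  min permutation p:", signif(min(x$p$values, na.rm = TRUE), 4),
      "  max Z:", signif(max(x$z$values, na.rm = TRUE), 4), "\n")
  if (x$n_missing) cat("  flagged-missing voxels:", x$n_missing, "\n")
  invisible(x)
}

#' @export
summary.cwas_mdmr <- function(object, z_thresh = 3.1, ...) {
  z <- object$z$values
  top <- order(z, decreasing = TRUE)[seq_len(min(5, length(z)))]
  ijk <- mask_ordinal_to_ijk(object$mask, top)
  out <- list(interest = object$interest,
              n_suprathreshold = sum(z > z_thresh, na.rm = TRUE),
              z_thresh = z_thresh,
              peak = data.frame(ordinal = top, z = z[top],
                                i = ijk[, 1], j = ijk[, 2], k = ijk[, 3]),
              n_missing = object$n_missing)
  class(out) <- "summary.cwas_mdmr"
  out
}

#' @export
print.summary.cwas_mdmr <- function(x, ...) {
  cat("MDMR summary (", x$interest, "): ", x$n_suprathreshold,
      " voxels with Z > ", x$z_thresh, "\n", sep = "")
  print(x$peak, row.names = FALSE)
  invisible(x)
}

#' @export
plot.cwas_mdmr <- function(x, ...) {
  z <- x$z$values
  graphics::hist(z[is.finite(z)], breaks = 30, main = paste(
    "MDMR Z map:", x$interest), xlab = "Z")
  graphics::abline(v = 3.1, lty = 2)
  invisible(x)
}
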