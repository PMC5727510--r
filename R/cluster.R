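neighbor_offsets <- function(connectivity) {
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  if (connectivity == 6) off <- off[rowSums(abs(off)) == 1, , drop = FALSE]
  else if (connectivity == 18) off <- off[rowSums(abs(off)) <= 2, , drop = FALSE]
  else if (connectivity != 26) stop("connectivity must be 6, 18 or 26")
  off
}

# Label connected components of the in-mask voxel set `active` (ordinals).
# Returns an integer vector over mask voxels (0 = not active).
label_components <- function(mask, active, connectivity = 26) {
  labels <- integer(mask$n_voxels)
  if (!length(active)) return(labels)
  off <- neighbor_offsets(connectivity)
  shp <- mask$grid$shape
  act <- logical(mask$n_voxels); act[active] <- TRUE
  cur <- 0L
  for (v in active) {
    if (labels[v]) next
    cur <- cur + 1L
    queue <- v; labels[v] <- cur
    while (length(queue)) {
      u <- queue[[1]]; queue <- queue[-1]
      nb <- sweep(off, 2, mask$ijk[u, ], "+")
      keep <- nb[, 1] >= 1 & nb[, 1] <= shp[1] &
              nb[, 2] >= 1 & nb[, 2] <= shp[2] &
              nb[, 3] >= 1 & nb[, 3] <= shp[3]
      ords <- mask$ordinal[nb[keep, , drop = FALSE]]
      ords <- ords[ords > 0L]
      ords <- ords[act[ords] & labels[ords] == 0L]
      if (length(ords)) { labels[ords] <- cur; queue <- c(queue, ords) }
    }
  }
  labels
}

#' Suprathreshold cluster formation
#'
#' Connected components of the strictly suprathreshold set `{z > z_thresh}`
#' under 6-, 18- or 26-neighbour connectivity (default 26: faces, edges and
#' corners). The peak of each cluster is its maximum-Z voxel; ties are broken
#' by the lowest mask ordinal.
#'
#' @param zmap a [stat_map()] of kind `"z"` (or any statistic to threshold).
#' @param z_thresh cluster-forming height threshold (default 3.1).
#' @param connectivity 6, 18 or 26.
#' @return Object of class `cluster_table`: data.frame `table` with columns
#'   label, size, peak_z, peak ordinal, peak i/j/k, peak world mm x/y/z,
#'   p_corrected (NA until a correction is applied); plus `labels` (integer
#'   vector over mask voxels) and the call parameters. The table is empty
#'   when no voxel exceeds the threshold.
#' @export
form_clusters <- function(zmap, z_thresh = 3.1, connectivity = 26) {
  stopifnot(inherits(zmap, "stat_map"))
  mask <- zmap$mask
  z <- zmap$values
  active <- which(is.finite(z) & z > z_thresh)
  labels <- label_components(mask, active, connectivity)
  nlab <- max(labels)
  if (nlab == 0L) {
    tab <- data.frame(label = integer(), size = integer(),
                      peak_z = numeric(), peak_ordinal = integer(),
                      peak_i = integer(), peak_j = integer(),
                      peak_k = integer(), peak_x = numeric(),
                      peak_y = numeric(), peak_z_mm = numeric(),
                      p_corrected = numeric())
  } else {
    rows <- lapply(seq_len(nlab), function(l) {
      vox <- which(labels == l)
      pk <- vox[which.max(z[vox])]   # which.max -> first (lowest ordinal) tie
      ijk <- mask_ordinal_to_ijk(mask, pk)
      xyz <- voxel_to_world(mask$grid, ijk)
      data.frame(label = l, size = length(vox), peak_z = z[pk],
                 peak_ordinal = pk, peak_i = ijk[1], peak_j = ijk[2],
                 peak_k = ijk[3], peak_x = xyz[1], peak_y = xyz[2],
                 peak_z_mm = xyz[3], p_corrected = NA_real_)
    })
    tab <- do.call(rbind, rows)
    tab <- tab[order(-tab$size), , drop = FALSE]
    rownames(tab) <- NULL
  }
  structure(list(table = tab, labels = labels, z_thresh = z_thresh,
                 connectivity = connectivity, mask = mask),
            class = "cluster_table")
}

#' @export
print.cluster_table <- function(x, ...) {
  cat("<cluster_table> ", nrow(x$table), " cluster(s) at z > ",
      x$z_thresh, " (", x$connectivity, "-connectivity)\n", sep = "")
  if (nrow(x$table)) print(x$table, row.names = FALSE)
  invisible(x)
}

#' Estimate field smoothness from residual maps
#'
#' Per-axis FWHM from the lag-1 spatial autocorrelation of standardized
#' residual maps, assuming a Gaussian autocorrelation function:
#' `FWHM_vox = sqrt(-2 log(2) / log(rho1))` (exact for Gaussian-smoothed
#' white noise). The autocorrelation is pooled over all in-mask neighbour
#' pairs and all maps; it is floored at `exp(-8 log 2)` (i.e. FWHM >= 0.5
#' voxels) so unsmoothed noise yields a finite sub-voxel estimate. Resels are
#' the mask volume divided by the product of the FWHMs.
#'
#' @param resid_maps list (length >= 2) of [stat_map()]s or numeric vectors
#'   over mask voxels (e.g. per-subject standardized residuals of the group
#'   model).
#' @param mask a [group_mask()] (taken from the first `stat_map`).
#' @return Object of class `smoothness_estimate`: `fwhm_mm` (3-vector),
#'   `fwhm_vox`, `resels`, `n_maps`.
#' @export
estimate_smoothness <- function(resid_maps, mask = NULL) {
  if (length(resid_maps) < 2L) stop("need at least 2 residual maps")
  vals <- lapply(resid_maps, function(m) {
    if (inherits(m, "stat_map")) { if (is.null(mask)) mask <<- m$mask; m$values }
    else as.numeric(m)
  })
  stopifnot(inherits(mask, "group_mask"))
  pairs <- lapply(1:3, function(ax) {
    nb <- mask$ijk
    nb[, ax] <- nb[, ax] + 1L
    ok <- nb[, ax] <= mask$grid$shape[ax]
    j <- mask$ordinal[nb[ok, , drop = FALSE]]
    keep <- j > 0L
    cbind(which(ok)[keep], j[keep])
  })
  rho <- numeric(3)
  for (ax in 1:3) {
    pr <- pairs[[ax]]
    if (nrow(pr) < 2L) stop("mask too thin along axis ", ax)
    num <- den1 <- den2 <- 0
    for (v in vals) {
      x <- (v - mean(v)) / stats::sd(v)
      if (!all(is.finite(x))) stop("flat residual map (zero variance)")
      num <- num + sum(x[pr[, 1]] * x[pr[, 2]])
      den1 <- den1 + sum(x[pr[, 1]]^2)
      den2 <- den2 + sum(x[pr[, 2]]^2)
    }
    rho[ax] <- num / sqrt(den1 * den2)
  }
  rho <- pmin(pmax(rho, exp(-8 * log(2))), 1 - 1e-12)
  fwhm_vox <- sqrt(-2 * log(2) / log(rho))
  fwhm_mm <- fwhm_vox * mask$grid$voxel_size
  resels <- mask$n_voxels * prod(mask$grid$voxel_size) / prod(fwhm_mm)
  structure(list(fwhm_mm = fwhm_mm, fwhm_vox = fwhm_vox,
                 resels = resels, n_maps = length(vals)),
            class = "smoothness_estimate")
}

#' @export
print.smoothness_estimate <- function(x, ...) {
  cat("<smoothness_estimate> FWHM =",
      paste(signif(x$fwhm_mm, 4), collapse = " x "),
      "mm, resels =", signif(x$resels, 4), "\n")
  invisible(x)
}

#' Gaussian-random-field corrected cluster p-value
#'
#' Family-wise-error corrected p for a cluster of `cluster_size` voxels at
#' cluster-forming height `u`, from the canonical 3D Gaussian-field
#' approximations: expected cluster count from the Euler-characteristic
#' density, `E_m = R (4 log 2)^{3/2} (2 pi)^{-2} (u^2 - 1) exp(-u^2/2)`
#' with R the resel count; expected suprathreshold volume
#' `E_N = V (1 - Phi(u))`; cluster-size tail
#' `P(n >= k) = exp(-beta k^{2/3})` with
#' `beta = (Gamma(5/2) E_m / E_N)^{2/3}`; and
#' `p_FWER = 1 - exp(-E_m P(n >= k))`. Monotone decreasing in k and
#' increasing in FWHM.
#'
#' @param cluster_size cluster extent in voxels (>= 1); vectorised.
#' @param z_thresh cluster-forming threshold u.
#' @param smoothness a [estimate_smoothness()] result.
#' @param mask the search-volume [group_mask()].
#' @return corrected p-value(s) in (0, 1].
#' @export
grf_cluster_p <- function(cluster_size, z_thresh, smoothness, mask) {
  stopifnot(inherits(smoothness, "smoothness_estimate"),
            inherits(mask, "group_mask"))
  if (any(cluster_size < 1)) stop("cluster_size must be >= 1")
  if (!is.finite(smoothness$resels) || smoothness$resels <= 0)
    stop("invalid smoothness estimate")
  u <- z_thresh
  em <- smoothness$resels * (4 * log(2))^1.5 * (2 * pi)^(-2) *
    (u^2 - 1) * exp(-u^2 / 2)
  en <- mask$n_voxels * stats::pnorm(u, lower.tail = FALSE)
  nbar <- en / em
  beta <- (gamma(5 / 2) / nbar)^(2 / 3)
  p_tail <- exp(-beta * cluster_size^(2 / 3))
  p <- 1 - exp(-em * p_tail)
  pmin(pmax(p, .Machine$double.xmin), 1)
}

#' Permutation-based cluster-extent correction
#'
#' Corrected p of an observed cluster of size k against the permutation
#' distribution of the maximum cluster size:
#' `p = (1 + #\{max_size_perm >= k\}) / (1 + n_perm)`.
#'
#' @param max_sizes integer vector of maximum suprathreshold cluster sizes,
#'   one per permutation (a warning is recorded below 100).
#' @param clusters a [form_clusters()] result (or integer sizes).
#' @return the `cluster_table` with `p_corrected` filled in (or a numeric
#'   vector when `clusters` is a plain size vector).
#' @export
permutation_cluster_correction <- function(max_sizes, clusters) {
  max_sizes <- as.numeric(max_sizes)
  if (length(max_sizes) < 100L)
    warning("fewer than 100 permutation max sizes; corrected p is coarse")
  pc <- function(k) (1 + sum(max_sizes >= k)) / (1 + length(max_sizes))
  if (inherits(clusters, "cluster_table")) {
    if (nrow(clusters$table))
      clusters$table$p_corrected <- vapply(clusters$table$size, pc, 0)
    clusters
  } else vapply(as.numeric(clusters), pc, 0)
}

#' Permutation cluster correction for an MDMR fit
#'
#' Uses the shared permutation sequence of a [run_mdmr()] fit (run with
#' `keep_perm_f = TRUE`): each permutation's pseudo-F map is converted to a
#' Z map through the pooled per-voxel permutation ranks, thresholded and
#' clustered exactly like the observed map, and the resulting maximum
#' cluster sizes form the null for the extent correction.
#'
#' @param fit a `cwas_mdmr` object with `perm_f`.
#' @param z_thresh cluster-forming threshold.
#' @param connectivity neighbourhood (6, 18, 26).
#' @return list: `clusters` (corrected [form_clusters()] table for the
#'   observed map), `max_sizes` (null distribution), `z_thresh`.
#' @export
mdmr_cluster_perm <- function(fit, z_thresh = 3.1, connectivity = 26) {
  stopifnot(inherits(fit, "cwas_mdmr"))
  if (is.null(fit$perm_f))
    stop("fit was run without keep_perm_f = TRUE")
  fmat <- fit$perm_f
  ok <- rowSums(is.na(fmat)) == 0L
  np1 <- ncol(fmat)                      # n_perm + 1 (observed first)
  # per-voxel p of every column against the pooled permutation distribution
  pmat <- matrix(NA_real_, nrow(fmat), np1)
  pmat[ok, ] <- t(apply(fmat[ok, , drop = FALSE], 1, function(f)
    (np1 + 1 - rank(f, ties.method = "min")) / np1))
  p_thresh <- stats::pnorm(z_thresh, lower.tail = FALSE)
  max_sizes <- integer(np1 - 1L)
  for (j in 2:np1) {
    active <- which(ok & pmat[, j] < p_thresh)
    lab <- label_components(fit$mask, active, connectivity)
    max_sizes[j - 1L] <- if (max(lab) == 0L) 0L else max(tabulate(lab))
  }
  zobs <- rep(NA_real_, nrow(fmat))
  zobs[ok] <- p_to_z(pmat[ok, 1])
  clusters <- form_clusters(stat_map(zobs, fit$mask, "z"),
                            z_thresh = z_thresh, connectivity = connectivity)
  clusters <- permutation_cluster_correction(max_sizes, clusters)
  list(clusters = clusters, max_sizes = max_sizes, z_thresh = z_thresh)
}
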