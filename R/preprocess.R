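#' Grand-mean intensity normalization
#'
#' Rescales all volumes so the grand mean (mean over all in-mask voxels and
#' timepoints) equals 10,000.
#'
#' @param ts a [subject_ts()].
#' @param target target grand mean.
#' @return a rescaled [subject_ts()].
#' @export
intensity_normalize <- function(ts, target = 10000) {
  stopifnot(inherits(ts, "subject_ts"))
  gm <- mean(ts$data)
  if (!is.finite(gm) || gm <= 0)
    stop("grand mean must be > 0 (got ", signif(gm, 4), ")")
  subject_ts(ts$subject_id, ts$data * (target / gm), ts$tr, ts$mask)
}

#' Frame-wise displacement
#'
#' Power-style FD: for each frame t >= 2,
#' `FD(t) = sum |delta translation| + radius * sum |delta rotation|`,
#' with rotations (radians) converted to arc length on a sphere of
#' `radius_mm` (default 50 mm). `FD(1) = 0`.
#'
#' @param motion T x 6 matrix: 3 translations (mm), 3 rotations (radians).
#' @param radius_mm head-radius for the rotation arc length.
#' @return list with `fd` (length-T vector) and `mean_fd`.
#' @export
compute_fd <- function(motion, radius_mm = 50) {
  motion <- as.matrix(motion)
  if (nrow(motion) < 2L || ncol(motion) != 6L)
    stop("motion must be a T x 6 matrix with T >= 2")
  if (any(!is.finite(motion)) || !is.finite(radius_mm))
    stop("non-finite motion parameters")
  d <- abs(diff(motion))
  fd <- c(0, rowSums(d[, 1:3, drop = FALSE]) +
               radius_mm * rowSums(d[, 4:6, drop = FALSE]))
  list(fd = fd, mean_fd = mean(fd))
}

#' Friston-24 motion regressors
#'
#' The 6 rigid-body parameters, their one-volume-lagged values, and the 12
#' corresponding squared terms; the lag row 1 is zero-filled.
#'
#' @param motion T x 6 motion matrix.
#' @return T x 24 matrix, columns `[m, m_lag1, m^2, m_lag1^2]`.
#' @export
friston24 <- function(motion) {
  motion <- as.matrix(motion)
  if (nrow(motion) < 2L || ncol(motion) != 6L)
    stop("motion must be a T x 6 matrix with T >= 2")
  lag1 <- rbind(0, motion[-nrow(motion), , drop = FALSE])
  out <- cbind(motion, lag1, motion^2, lag1^2)
  colnames(out) <- c(paste0("m", 1:6), paste0("m", 1:6, "_lag1"),
                     paste0("m", 1:6, "_sq"), paste0("m", 1:6, "_lag1_sq"))
  out
}

#' CompCor noise components
#'
#' Top-k principal-component time series of the column-demeaned noise-region
#' matrix, unit-normalized and mutually orthogonal (left singular vectors).
#'
#' @param noise_ts T x M matrix of time series from noise regions of interest
#'   (e.g. a designated region outside the analysis mask in synthetic data).
#' @param k number of components (default 5).
#' @return T x k matrix of orthonormal component time series.
#' @export
compcor <- function(noise_ts, k = 5) {
  noise_ts <- as.matrix(noise_ts)
  T_len <- nrow(noise_ts)
  if (ncol(noise_ts) < k) stop("need at least k = ", k, " noise columns")
  if (T_len <= k) stop("need more timepoints than components")
  x <- sweep(noise_ts, 2, colMeans(noise_ts))
  sv <- svd(x, nu = k, nv = 0)
  achieved <- sum(sv$d > sv$d[1] * 1e-10)
  if (achieved < k)
    stop("noise matrix rank ", achieved, " < requested k = ", k)
  comp <- sv$u
  colnames(comp) <- paste0("compcor", seq_len(k))
  comp
}

#' Nuisance regressor design
#'
#' Assembles the temporal nuisance design: orthogonal polynomial trend
#' columns (linear and quadratic), Friston-24 motion block, and CompCor
#' components, plus an intercept.
#'
#' @param T_len number of timepoints.
#' @param motion optional T x 6 motion matrix (expanded via [friston24()]).
#' @param compcor_comp optional T x k CompCor block.
#' @param trends polynomial trend order (default 2: linear + quadratic).
#' @return T x K numeric matrix whose first column is the intercept.
#' @export
nuisance_design <- function(T_len, motion = NULL, compcor_comp = NULL,
                            trends = 2) {
  x <- matrix(1, T_len, 1, dimnames = list(NULL, "intercept"))
  if (trends > 0) {
    tp <- stats::poly(seq_len(T_len), degree = trends)
    colnames(tp) <- paste0("trend", seq_len(trends))
    x <- cbind(x, tp)
  }
  if (!is.null(motion)) x <- cbind(x, friston24(motion))
  if (!is.null(compcor_comp)) x <- cbind(x, as.matrix(compcor_comp))
  if (ncol(x) >= T_len) stop("design has K >= T columns")
  x
}

#' Ordinary least-squares nuisance regression
#'
#' Projects each voxel's time series onto the orthogonal complement of the
#' design (which must include an intercept) and returns the residuals.
#' Idempotent: regressing the residuals on the same design changes nothing.
#'
#' @param ts a [subject_ts()] or T x V matrix.
#' @param design T x K full-column-rank design matrix.
#' @return residual object of the same type as `ts`.
#' @export
nuisance_regress <- function(ts, design) {
  dat <- if (inherits(ts, "subject_ts")) ts$data else as.matrix(ts)
  design <- as.matrix(design)
  if (nrow(design) != nrow(dat)) stop("design rows must match timepoints")
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) stop("rank-deficient nuisance design")
  res <- dat - qr.fitted(qrd, dat)
  if (inherits(ts, "subject_ts"))
    structure(list(subject_id = ts$subject_id, data = res, tr = ts$tr,
                   mask = ts$mask), class = "subject_ts")
  else res
}

#' Frequency-domain band-pass filter
#'
#' Zero-phase band-pass by discrete-Fourier-transform masking: Fourier
#' coefficients with |frequency| inside `[low, high]` Hz are kept, all others
#' (including DC) are zeroed. Exactly preserves passband sinusoids that fall
#' on DFT bins and introduces no temporal shift.
#'
#' @param ts a [subject_ts()] or T x V matrix.
#' @param tr repetition time in seconds (taken from `ts` when available).
#' @param low,high passband edges in Hz; requires
#'   `0 <= low < high < 1/(2*tr)`.
#' @return filtered object of the same type as `ts`.
#' @export
bandpass <- function(ts, tr = NULL, low = 0.01, high = 0.1) {
  dat <- if (inherits(ts, "subject_ts")) ts$data else as.matrix(ts)
  if (is.null(tr)) {
    if (!inherits(ts, "subject_ts")) stop("'tr' required for matrix input")
    tr <- ts$tr
  }
  nyq <- 1 / (2 * tr)
  if (low < 0 || low >= high) stop("need 0 <= low < high")
  if (high >= nyq)
    stop("'high' (", high, " Hz) must be below Nyquist = ",
         signif(nyq, 4), " Hz for TR = ", tr, " s")
  T_len <- nrow(dat)
  freq <- seq_len(T_len) - 1
  freq <- pmin(freq, T_len - freq) / (T_len * tr)
  keep <- freq >= low & freq <= high
  co <- stats::mvfft(dat)
  co[!keep, ] <- 0
  out <- Re(stats::mvfft(co, inverse = TRUE)) / T_len
  if (inherits(ts, "subject_ts"))
    structure(list(subject_id = ts$subject_id, data = out, tr = ts$tr,
                   mask = ts$mask), class = "subject_ts")
  else out
}

gaussian_kernel_matrix <- function(n, sigma_vox) {
  if (sigma_vox <= 0) return(diag(n))
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  k <- exp(-d^2 / (2 * sigma_vox^2))
  k[d > ceiling(4 * sigma_vox)] <- 0
  k  # unnormalized; the mask-mass division in smooth_volume cancels the scale
}

smooth_axis <- function(vol, axis, kmat) {
  d <- dim(vol)
  perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  v <- aperm(vol, perm)
  dp <- dim(v)
  v <- kmat %*% matrix(v, dp[1], dp[2] * dp[3])
  v <- array(v, dp)
  aperm(v, order(perm))
}

#' Gaussian spatial smoothing inside a mask
#'
#' Separable Gaussian convolution with `sigma = fwhm / (2 sqrt(2 ln 2))` per
#' axis in mm. The result is renormalized by the smoothed mask (in-mask
#' kernel mass), so constant fields are unchanged and there is no edge
#' attenuation at the mask boundary.
#'
#' @param x a [stat_map()], a 3D array, or a numeric vector over mask voxels.
#' @param mask a [group_mask()] (taken from `x` when it is a `stat_map`).
#' @param fwhm_mm full width at half maximum in mm (default 6); 0 is the
#'   identity.
#' @return same type as `x`.
#' @export
smooth_volume <- function(x, mask = NULL, fwhm_mm = 6) {
  was_map <- inherits(x, "stat_map")
  if (was_map) { mask <- x$mask; kind <- x$kind; x <- x$values }
  stopifnot(inherits(mask, "group_mask"))
  if (fwhm_mm < 0) stop("'fwhm_mm' must be >= 0")
  was_vec <- is.null(dim(x))
  vol <- if (was_vec) map_to_volume(x, mask) else
    array(as.numeric(x), dim = mask$grid$shape)
  if (fwhm_mm == 0) {
    out_vals <- vol[mask$ijk]
  } else {
    sigma_mm <- fwhm_mm / (2 * sqrt(2 * log(2)))
    m <- array(as.numeric(mask$inside), dim = mask$grid$shape)
    num <- vol * m
    den <- m
    for (ax in 1:3) {
      kmat <- gaussian_kernel_matrix(mask$grid$shape[ax],
                                     sigma_mm / mask$grid$voxel_size[ax])
      num <- smooth_axis(num, ax, kmat)
      den <- smooth_axis(den, ax, kmat)
    }
    sm <- num / pmax(den, .Machine$double.eps)
    out_vals <- sm[mask$ijk]
  }
  if (was_map) return(stat_map(out_vals, mask, kind))
  if (was_vec) return(out_vals)
  map_to_volume(out_vals, mask)
}

#' Global connectivity (GCOR)
#'
#' Mean of the full V x V Pearson correlation matrix (diagonal included),
#' computed in O(T V) memory from the column-standardized data: with unit
#' vectors u_v, `sum_ij r_ij = ||sum_v u_v||^2`.
#'
#' @param ts a [subject_ts()] or T x V matrix.
#' @return scalar GCOR.
#' @export
gcor <- function(ts) {
  dat <- if (inherits(ts, "subject_ts")) ts$data else as.matrix(ts)
  u <- sweep(dat, 2, colMeans(dat))
  nrm <- sqrt(colSums(u^2))
  zero <- which(nrm == 0)
  if (length(zero))
    stop("zero-variance voxel(s), first at ordinal ", zero[1])
  u <- sweep(u, 2, nrm, "/")
  s <- rowSums(u)
  sum(s^2) / ncol(dat)^2
}

#' Default temporal preprocessing pipeline
#'
#' Applies, in order: grand-mean intensity normalization, nuisance
#' regression (trends + Friston-24 + CompCor as available), band-pass
#' filtering, and optional spatial smoothing of each volume. Re-running with
#' the same inputs is bit-identical (no randomness).
#'
#' @param ts a [subject_ts()].
#' @param motion optional T x 6 motion matrix.
#' @param noise_ts optional T x M noise-region matrix for CompCor.
#' @param low,high band-pass edges in Hz.
#' @param fwhm_mm smoothing kernel (0 disables smoothing).
#' @param normalize apply intensity normalization first (requires positive
#'   data; disable for zero-mean synthetic series).
#' @return preprocessed [subject_ts()].
#' @export
preprocess_bold <- function(ts, motion = NULL, noise_ts = NULL,
                            low = 0.01, high = 0.1, fwhm_mm = 0,
                            normalize = TRUE) {
  stopifnot(inherits(ts, "subject_ts"))
  if (normalize) ts <- intensity_normalize(ts)
  cc <- if (!is.null(noise_ts)) compcor(noise_ts) else NULL
  des <- nuisance_design(nrow(ts$data), motion = motion, compcor_comp = cc)
  ts <- nuisance_regress(ts, des)
  ts <- bandpass(ts, low = low, high = high)
  if (fwhm_mm > 0) {
    sm <- apply(ts$data, 1, smooth_volume, mask = ts$mask, fwhm_mm = fwhm_mm)
    ts <- subject_ts(ts$subject_id, t(sm), ts$tr, ts$mask)
  }
  ts
}
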