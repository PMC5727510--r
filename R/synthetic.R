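#' Cohort specification for the synthetic phenotype generator
#'
#' Defaults emulate a community-ascertained adult cohort assessed with
#' WIAT-style achievement tests: literacy and numeracy standard scores drawn
#' from a bivariate normal (means 101.20 / 99.10, SDs 11.19 / 15.90,
#' inter-score correlation 0.44), age 20-49 years, sex coded 0 = male /
#' 1 = female with P(female) = 44/70, Edinburgh-style handedness 50-100, and
#' low head motion (mean FD around 0.06 mm).
#'
#' @param n_subjects number of subjects (>= 4).
#' @param literacy_mean,literacy_sd,numeracy_mean,numeracy_sd score moments.
#' @param target_correlation literacy-numeracy correlation, |rho| < 1.
#' @param age_mean,age_sd,age_range age distribution (normal, clamped).
#' @param p_female Bernoulli probability for sex = 1.
#' @param hand_mean,hand_sd,hand_range handedness distribution (normal, clamped).
#' @param fd_mean,fd_sd,fd_range mean-FD distribution (normal, clamped).
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 70,
                        literacy_mean = 101.20, literacy_sd = 11.19,
                        numeracy_mean = 99.10, numeracy_sd = 15.90,
                        target_correlation = 0.44,
                        age_mean = 30.76, age_sd = 10.03,
                        age_range = c(20, 49),
                        p_female = 44 / 70,
                        hand_mean = 77.36, hand_sd = 19.14,
                        hand_range = c(50, 100),
                        fd_mean = 0.06, fd_sd = 0.02,
                        fd_range = c(0.03, 0.17)) {
  if (n_subjects < 4L) stop("'n_subjects' must be >= 4")
  if (literacy_sd <= 0 || numeracy_sd <= 0 || age_sd <= 0 ||
      hand_sd <= 0 || fd_sd <= 0) stop("SDs must be > 0")
  if (abs(target_correlation) >= 1) stop("|target_correlation| must be < 1")
  if (p_female < 0 || p_female > 1) stop("'p_female' must be in [0, 1]")
  structure(as.list(environment()), class = "cohort_spec")
}

#' Generate a synthetic phenotype table
#'
#' Literacy and numeracy standard scores are drawn from the bivariate normal
#' given by the spec and rounded to integers (standard-score convention);
#' nuisance covariates follow the spec's clamped-normal / Bernoulli
#' distributions. The `gcor` column is initialised to `NA` and is filled from
#' image data by the analysis stage. Deterministic given `seed`.
#'
#' @param spec a [cohort_spec()].
#' @param seed integer RNG seed.
#' @return data.frame with columns `subject_id`, `literacy_ss`, `numeracy_ss`,
#'   `age`, `sex`, `handedness`, `mean_fd`, `gcor`.
#' @export
generate_cohort <- function(spec = cohort_spec(), seed = 1L) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(seed)
  n <- spec$n_subjects
  z1 <- stats::rnorm(n)
  z2 <- spec$target_correlation * z1 +
    sqrt(1 - spec$target_correlation^2) * stats::rnorm(n)
  lit <- round(spec$literacy_mean + spec$literacy_sd * z1)
  num <- round(spec$numeracy_mean + spec$numeracy_sd * z2)
  clamp <- function(x, r) pmin(pmax(x, r[1]), r[2])
  age <- clamp(round(stats::rnorm(n, spec$age_mean, spec$age_sd)),
               spec$age_range)
  sex <- stats::rbinom(n, 1L, spec$p_female)
  hand <- clamp(round(stats::rnorm(n, spec$hand_mean, spec$hand_sd)),
                spec$hand_range)
  fd <- clamp(stats::rnorm(n, spec$fd_mean, spec$fd_sd), spec$fd_range)
  data.frame(subject_id = sprintf("sub-%03d", seq_len(n)),
             literacy_ss = lit, numeracy_ss = num,
             age = age, sex = sex, handedness = hand,
             mean_fd = fd, gcor = NA_real_,
             stringsAsFactors = FALSE)
}

#' Planted connectivity-phenotype effect
#'
#' Describes the effect planted in synthetic time series: the correlation
#' between a target region and a partner region varies linearly with the
#' (standardised) phenotype, so the target voxels' whole-brain connectivity
#' profiles differ across subjects as a function of behaviour.
#'
#' @param target_region integer mask ordinals of the seed-like region whose
#'   connectivity profile carries the effect.
#' @param partner_region integer mask ordinals of the partner region; must be
#'   disjoint from `target_region`.
#' @param phenotype_name phenotype column driving the effect.
#' @param slope change in inter-region correlation per 1 SD of phenotype.
#' @param baseline_r inter-region correlation at the phenotype mean.
#' @param within_r within-region voxel correlation (constant across subjects).
#' @param background_r pairwise correlation of background voxels (shared
#'   low-variance latent keeping connectivity profiles non-degenerate).
#' @return Object of class `effect_spec`.
#' @export
effect_spec <- function(target_region, partner_region,
                        phenotype_name = "numeracy_ss",
                        slope = 0.2, baseline_r = 0.2,
                        within_r = 0.8, background_r = 0.1) {
  target_region <- as.integer(target_region)
  partner_region <- as.integer(partner_region)
  if (!length(target_region) || !length(partner_region))
    stop("regions must be non-empty")
  if (length(intersect(target_region, partner_region)))
    stop("target and partner regions must be disjoint")
  extreme <- abs(baseline_r) + 2 * abs(slope)
  if (extreme >= 0.95)
    stop("baseline_r +/- 2*slope must stay inside (-0.95, 0.95)")
  if (within_r <= 0 || within_r >= 1) stop("'within_r' must be in (0, 1)")
  if (background_r < 0 || background_r >= 1)
    stop("'background_r' must be in [0, 1)")
  structure(list(target_region = target_region,
                 partner_region = partner_region,
                 phenotype_name = phenotype_name,
                 slope = slope, baseline_r = baseline_r,
                 within_r = within_r, background_r = background_r),
            class = "effect_spec")
}

#' Default desk-scale simulation geometry
#'
#' A 17 x 17 x 9 grid of 3 mm isotropic voxels whose mask drops the one-voxel
#' border (V = 1575 analysed voxels), with a 3 x 3 x 3 target block and a
#' 5 x 5 x 4 partner block. A synthetic gray-matter probability volume
#' (0.6 inside the interior box, 0.1 on the border) reproduces the mask via
#' [make_group_mask()] at the default 0.25 threshold.
#'
#' @param shape grid dimensions.
#' @param voxel_mm isotropic voxel size in mm.
#' @return list with `grid`, `mask`, `gm_prob`, `target_region`,
#'   `partner_region` (mask ordinals).
#' @export
default_sim_grid <- function(shape = c(17, 17, 9), voxel_mm = 3) {
  if (any(shape < c(13, 13, 7)))
    stop("'shape' must be at least 13 x 13 x 7 to hold the default regions; ",
         "build smaller geometries with make_group_mask() and effect_spec()")
  grid <- volume_grid(shape, voxel_mm = voxel_mm)
  gm <- array(0.1, dim = shape)
  gm[2:(shape[1] - 1), 2:(shape[2] - 1), 2:(shape[3] - 1)] <- 0.6
  mask <- make_group_mask(list(array(TRUE, shape)), gm_prob = gm, grid = grid)
  block <- function(xr, yr, zr) {
    idx <- as.matrix(expand.grid(xr, yr, zr))
    ord <- mask$ordinal[idx]
    sort(ord[ord > 0L])
  }
  list(grid = grid, mask = mask, gm_prob = gm,
       target_region = block(3:5, 3:5, 3:5),
       partner_region = block(8:12, 8:12, 3:6))
}

#' Generate multi-subject voxel time series with a planted effect
#'
#' Each subject's data are sampled from a zero-mean Gaussian process with
#' block covariance. Target and partner voxels load on region latent signals
#' (loading `sqrt(within_r)`), so within-region correlations equal
#' `within_r`; the two latents are correlated such that the inter-region
#' voxel correlation equals `baseline_r + slope * z(phenotype)`, with the
#' subject's standardised phenotype clamped to +/- 2.5 SD. Background voxels
#' share a weak global latent (pairwise correlation `background_r`).
#' Deterministic given `seed`.
#'
#' @param cohort phenotype table from [generate_cohort()].
#' @param mask a [group_mask()].
#' @param effect an [effect_spec()]; regions must lie inside the mask.
#' @param T_len number of timepoints (>= 20).
#' @param tr repetition time in seconds (default 0.645).
#' @param noise_sd overall amplitude scale.
#' @param seed integer RNG seed.
#' @return list of [subject_ts()], one per cohort row.
#' @export
generate_timeseries <- function(cohort, mask, effect, T_len = 300,
                                tr = 0.645, noise_sd = 1, seed = 1L) {
  stopifnot(inherits(mask, "group_mask"), inherits(effect, "effect_spec"))
  if (T_len < 20L) stop("'T_len' must be >= 20")
  V <- mask$n_voxels
  if (max(effect$target_region, effect$partner_region) > V)
    stop("effect regions must lie inside the mask")
  ph <- cohort[[effect$phenotype_name]]
  if (is.null(ph)) stop("phenotype column '", effect$phenotype_name,
                        "' not found in cohort")
  z <- if (stats::sd(ph) > 0) as.numeric(scale(ph)) else rep(0, length(ph))
  z <- pmin(pmax(z, -2.5), 2.5)
  w <- effect$within_r
  bg <- setdiff(seq_len(V), c(effect$target_region, effect$partner_region))
  a_bg <- effect$background_r
  set.seed(seed)
  out <- vector("list", nrow(cohort))
  for (s in seq_len(nrow(cohort))) {
    r_sub <- effect$baseline_r + effect$slope * z[s]
    c_lat <- r_sub / w
    if (abs(c_lat) > 0.97)
      stop("requested inter-region correlation ", signif(r_sub, 3),
           " for subject ", cohort$subject_id[s],
           " exceeds the feasible range (|r| <= 0.97 * within_r); ",
           "covariance not positive definite")
    f_t <- stats::rnorm(T_len)
    f_p <- c_lat * f_t + sqrt(1 - c_lat^2) * stats::rnorm(T_len)
    g <- stats::rnorm(T_len)
    dat <- matrix(stats::rnorm(T_len * V), T_len, V)
    if (length(bg))
      dat[, bg] <- sqrt(a_bg) * g + sqrt(1 - a_bg) * dat[, bg]
    dat[, effect$target_region] <-
      sqrt(w) * f_t + sqrt(1 - w) * dat[, effect$target_region]
    dat[, effect$partner_region] <-
      sqrt(w) * f_p + sqrt(1 - w) * dat[, effect$partner_region]
    out[[s]] <- subject_ts(cohort$subject_id[s], noise_sd * dat, tr, mask)
  }
  out
}

#' Generate a synthetic rigid-body motion trace
#'
#' Random-walk translations (mm) and rotations (radians) with optional
#' motion spikes. Deterministic given `seed`.
#'
#' @param T_len number of frames (>= 2).
#' @param drift_scale SD of the per-frame random-walk increments
#'   (mm for translations; the rotation increments use `drift_scale / 50`
#'   radians so both contribute comparably to FD at the default 50 mm radius).
#' @param spike_prob per-frame probability of a transient spike.
#' @param spike_amp spike amplitude in mm.
#' @param seed integer RNG seed.
#' @return T x 6 matrix, columns tx, ty, tz (mm), rx, ry, rz (radians).
#' @export
generate_motion <- function(T_len, drift_scale = 0.02, spike_prob = 0.01,
                            spike_amp = 0.5, seed = 1L) {
  if (T_len < 2L) stop("'T_len' must be >= 2")
  set.seed(seed)
  m <- cbind(
    matrix(stats::rnorm(T_len * 3, sd = drift_scale), T_len, 3),
    matrix(stats::rnorm(T_len * 3, sd = drift_scale / 50), T_len, 3))
  m <- apply(m, 2, cumsum)
  if (spike_prob > 0) {
    hit <- which(stats::runif(T_len) < spike_prob)
    hit <- hit[hit > 1L]
    for (t in hit) {
      axis <- sample.int(3L, 1L)
      m[t, axis] <- m[t, axis] + spike_amp * sample(c(-1, 1), 1L)
    }
  }
  dimnames(m) <- list(NULL, c("tx", "ty", "tz", "rx", "ry", "rz"))
  m
}

#' One-call synthetic study
#'
#' Convenience wrapper generating a cohort and its time series under the
#' default desk-scale geometry. Used by tests and examples.
#'
#' @param n_subjects,T_len,slope,baseline_r,phenotype_name,seed forwarded to
#'   the component generators.
#' @param sim geometry from [default_sim_grid()].
#' @return list with `cohort`, `ts` (list of [subject_ts()]), `mask`,
#'   `effect`, `sim`.
#' @export
simulate_study <- function(n_subjects = 60, T_len = 300, slope = 0.2,
                           baseline_r = 0.2,
                           phenotype_name = "numeracy_ss", seed = 1L,
                           sim = default_sim_grid()) {
  cohort <- generate_cohort(cohort_spec(n_subjects = n_subjects), seed = seed)
  eff <- effect_spec(sim$target_region, sim$partner_region,
                     phenotype_name = phenotype_name,
                     slope = slope, baseline_r = baseline_r)
  ts <- generate_timeseries(cohort, sim$mask, eff, T_len = T_len,
                            seed = seed + 1000L)
  list(cohort = cohort, ts = ts, mask = sim$mask, effect = eff, sim = sim)
}
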