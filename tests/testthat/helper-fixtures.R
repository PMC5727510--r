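# Shared fixtures: tiny grids, tiny planted-effect studies, and memoized
# simulation batches reused across test files.

# a minimal 4x4x4 grid with an 8-voxel cubic mask
tiny_mask <- function() {
  grid <- volume_grid(c(4, 4, 4), voxel_mm = 3)
  inside <- array(FALSE, dim = c(4, 4, 4))
  inside[2:3, 2:3, 2:3] <- TRUE
  group_mask(grid, inside)
}

# 6x6x4 grid, 32-voxel interior mask, with small planted regions
tiny_sim_grid <- function() {
  grid <- volume_grid(c(6, 6, 4), voxel_mm = 3)
  gm <- array(0.1, dim = c(6, 6, 4))
  gm[2:5, 2:5, 2:3] <- 0.6
  mask <- make_group_mask(list(array(TRUE, c(6, 6, 4))), gm_prob = gm,
                          grid = grid)
  block <- function(xr, yr, zr) {
    ord <- mask$ordinal[as.matrix(expand.grid(xr, yr, zr))]
    sort(ord[ord > 0L])
  }
  list(grid = grid, mask = mask,
       target_region = block(2:3, 2:3, 2:3),     # 8 voxels
       partner_region = block(4:5, 4:5, 2:3))    # 8 voxels
}

tiny_study <- function(n_subjects = 30, T_len = 150, slope = 0.2,
                       phenotype_name = "numeracy_ss", seed = 1L) {
  sg <- tiny_sim_grid()
  cohort <- generate_cohort(cohort_spec(n_subjects = n_subjects), seed = seed)
  eff <- effect_spec(sg$target_region, sg$partner_region,
                     phenotype_name = phenotype_name, slope = slope)
  ts <- generate_timeseries(cohort, sg$mask, eff, T_len = T_len,
                            seed = seed + 500L)
  list(cohort = cohort, ts = ts, mask = sg$mask, effect = eff, sim = sg)
}

# random subject time series without planted structure
random_ts <- function(mask, n, T_len, seed) {
  set.seed(seed)
  lapply(seq_len(n), function(s)
    subject_ts(sprintf("s%02d", s),
               matrix(rnorm(T_len * mask$n_voxels), T_len), tr = 0.645,
               mask = mask))
}

random_pheno <- function(n, seed) {
  set.seed(seed)
  data.frame(subject_id = sprintf("s%02d", seq_len(n)),
             literacy_ss = round(rnorm(n, 101, 11)),
             numeracy_ss = round(rnorm(n, 99, 16)),
             age = round(runif(n, 20, 49)), sex = rbinom(n, 1, 0.6),
             handedness = round(runif(n, 50, 100)),
             mean_fd = runif(n, 0.03, 0.17), gcor = rnorm(n, 0.1, 0.02))
}

# --- memoized simulation batches (shared by recovery/specificity tests) ----

.sim_cache <- new.env(parent = emptyenv())

memoize <- function(key, expr) {
  if (!exists(key, envir = .sim_cache))
    assign(key, force(expr), envir = .sim_cache)
  get(key, envir = .sim_cache)
}

# 20 repetitions of the strong-effect study (n=60, T=300, slope=0.2, effect
# planted for numeracy): per repetition, MDMR under both preset models with
# permutation cluster correction, and post-hoc SCA from the planted seed.
recovery_batch <- function(n_reps = 20) {
  memoize("recovery", {
    lapply(seq_len(n_reps), function(rep) {
      st <- simulate_study(n_subjects = 60, T_len = 300, slope = 0.2,
                           phenotype_name = "numeracy_ss", seed = 9000 + rep)
      fit_num <- run_mdmr(st$ts, st$cohort, interest = "numeracy_ss",
                          n_perm = 1999, seed = 100 + rep,
                          keep_perm_f = TRUE)
      cl_num <- mdmr_cluster_perm(fit_num)
      fit_lit <- run_mdmr(st$ts, st$cohort, interest = "literacy_ss",
                          n_perm = 1999, seed = 100 + rep,
                          keep_perm_f = TRUE)
      cl_lit <- mdmr_cluster_perm(fit_lit)
      # post-hoc SCA: planted target region as seed, same group model
      zmaps <- lapply(st$ts, function(ts)
        sca_map(ts, seed_timeseries(ts, st$effect$target_region)))
      pheno <- st$cohort
      pheno$gcor <- vapply(st$ts, gcor, numeric(1))
      des <- mdmr_design(pheno, "numeracy_ss")
      glm_fit <- group_glm(zmaps, des)
      sca_vals <- glm_fit$z$values
      sca_vals[st$effect$target_region] <- -Inf  # seed region is trivial
      list(peak_num = mdmr_peak(fit_num),
           sig_num = any(cl_num$clusters$table$p_corrected < 0.05),
           sig_lit = if (nrow(cl_lit$clusters$table))
             any(cl_lit$clusters$table$p_corrected < 0.05) else FALSE,
           sca_peak = which.max(sca_vals),
           target = st$effect$target_region,
           partner = st$effect$partner_region)
    })
  })
}

# null (slope = 0) MDMR voxel tests: 500 independent datasets, one voxel
# each (independence across tests is what the binomial calibration check
# assumes; voxels within one dataset share subjects and permutations)
null_pvals <- function() {
  memoize("null_pvals", {
    vapply(1:500, function(rep) {
      st <- tiny_study(n_subjects = 30, T_len = 150, slope = 0,
                       seed = 3000 + rep)
      fit <- run_mdmr(st$ts, st$cohort, interest = "numeracy_ss",
                      n_perm = 199, seed = 700 + rep)
      fit$p$values[1 + (rep %% fit$mask$n_voxels)]
    }, numeric(1))
  })
}

# smooth Gaussian null fields: white noise smoothed with a 6 mm kernel on a
# padded grid, cropped to a 24 x 24 x 14 box (stationary), standardized.
smooth_null_fields <- function(n_fields, seed, shape = c(36, 36, 20),
                               pad = 5, fwhm = 6) {
  padded <- shape + 2 * pad
  grid_p <- volume_grid(padded, voxel_mm = 3)
  mask_p <- group_mask(grid_p, array(TRUE, padded))
  grid <- volume_grid(shape, voxel_mm = 3)
  mask <- group_mask(grid, array(TRUE, shape))
  core <- sweep(mask$ijk, 2, pad, "+")   # crop in mask-ordinal order
  set.seed(seed)
  fields <- lapply(seq_len(n_fields), function(i) {
    x <- array(rnorm(prod(padded)), dim = padded)
    s <- smooth_volume(x, mask_p, fwhm_mm = fwhm)
    v <- s[core]
    (v - mean(v)) / sd(v)
  })
  list(fields = fields, mask = mask)
}
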