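test_that("connectivity profiles match a brute-force voxel loop", {
  mask <- tiny_sim_grid()$mask
  set.seed(41)
  ts <- random_ts(mask, 1, 40, seed = 41)[[1]]
  v <- 7L
  prof <- ifc_profile(ts, v)
  expect_length(prof, mask$n_voxels - 1L)
  brute <- sapply(seq_len(mask$n_voxels)[-v],
                  function(w) cor(ts$data[, v], ts$data[, w]))
  expect_equal(prof, brute, tolerance = 1e-12)
  # duplicated and negated targets hit the +/-1 bounds
  ts$data[, 9] <- ts$data[, v]
  ts$data[, 10] <- -ts$data[, v]
  prof2 <- ifc_profile(ts, v)
  expect_equal(prof2[8], 1)                  # ordinal 9 is entry 8 after drop
  expect_equal(prof2[9], -1)
  ts$data[, 3] <- 5
  expect_error(ifc_profile(ts, v), "zero-variance partner")
})

test_that("profile distances follow sqrt(2(1-r)) with its analytic values", {
  base <- rnorm(50)
  profs <- rbind(base, base, -base, rnorm(50))
  d <- distance_matrix(profs)
  expect_equal(unname(d[1, 2]), 0)                     # r = 1
  expect_equal(unname(d[1, 3]), 2)                     # r = -1
  p1 <- rep(c(1, -1), 24)                              # exactly r = 0
  p2 <- rep(c(1, 1, -1, -1), 12)
  d0 <- distance_matrix(rbind(p1, p2))
  expect_equal(unname(d0[1, 2]), sqrt(2), tolerance = 1e-12)
  # symmetry, zero diagonal, range
  expect_equal(unclass(d), t(unclass(d)), ignore_attr = TRUE)
  expect_true(all(diag(d) == 0))
  expect_true(all(d >= 0 & d <= 2))
  expect_error(distance_matrix(rbind(rep(1, 50), base)), "zero-variance")
})

test_that("Gower centering has zero row sums and the classical MDS form", {
  d2 <- matrix(c(0, sqrt(2), sqrt(2), 0), 2, 2)
  expect_equal(gower_center(d2),
               matrix(c(0.5, -0.5, -0.5, 0.5), 2, 2), tolerance = 1e-12)
  # any distance matrix: rows sum to zero
  set.seed(42)
  pts <- matrix(rnorm(8 * 3), 8, 3)
  d <- as.matrix(dist(pts))
  g <- gower_center(d)
  expect_lt(max(abs(rowSums(g))), 1e-10)
  # Euclidean points: positive semi-definite (classical MDS)
  expect_gt(min(eigen(g, symmetric = TRUE)$values), -1e-8)
  # and G recovers the centred inner products
  pc <- scale(pts, scale = FALSE)
  expect_equal(g, tcrossprod(pc), tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("pseudo-F reduces to the classical partial F for scalars", {
  set.seed(43)
  n <- 12
  pheno <- data.frame(subject_id = as.character(1:n),
                      age = rnorm(n, 30, 8), sex = rbinom(n, 1, 0.5),
                      x = rnorm(n))
  y <- 0.5 * pheno$x + rnorm(n)
  d <- abs(outer(y, y, "-"))                # Euclidean distance on scalars
  g <- gower_center(d)
  des <- mdmr_design(pheno, "x", nuisance = c("age", "sex"))
  f_pkg <- pseudo_f(g, des)
  f_lm <- anova(lm(y ~ age + sex + x, data = pheno))["x", "F value"]
  expect_equal(f_pkg, f_lm, tolerance = 1e-8)
  # degenerate: identical profiles for everyone
  expect_error(pseudo_f(gower_center(matrix(0, n, n)), des), "degenerate")
})

test_that("pseudo-F is invariant to affine rescaling of nuisance columns", {
  set.seed(44)
  n <- 20
  pheno <- random_pheno(n, 44)
  pts <- matrix(rnorm(n * 6), n, 6)
  g <- gower_center(as.matrix(dist(pts)))
  des1 <- mdmr_design(pheno, "numeracy_ss")
  pheno2 <- pheno
  pheno2$age <- pheno2$age * 100 - 17
  pheno2$mean_fd <- pheno2$mean_fd / 3 + 2
  des2 <- mdmr_design(pheno2, "numeracy_ss")
  expect_lt(abs(pseudo_f(g, des1) - pseudo_f(g, des2)), 1e-8)
})

test_that("pseudo-F agrees with vegan's marginal PERMANOVA F", {
  skip_if_not_installed("vegan")
  set.seed(45)
  n <- 16
  pheno <- random_pheno(n, 45)
  pts <- matrix(rnorm(n * 10), n, 10)
  d <- dist(pts)
  g <- gower_center(as.matrix(d))
  des <- mdmr_design(pheno, "numeracy_ss", nuisance = c("age", "sex"))
  f_pkg <- pseudo_f(g, des)
  res <- vegan::adonis2(d ~ age + sex + numeracy_ss, data = pheno,
                        by = "margin", permutations = 2)
  expect_equal(f_pkg, res["numeracy_ss", "F"], tolerance = 1e-8)
})

test_that("permutation p matches the brute-force oracle exactly (n=8, V=30)", {
  n <- 8; V <- 30; T_len <- 25
  grid <- volume_grid(c(V, 1, 1), voxel_mm = 3)
  mask <- group_mask(grid, array(TRUE, c(V, 1, 1)))
  ts_list <- random_ts(mask, n, T_len, seed = 46)
  set.seed(47)
  pheno <- data.frame(subject_id = sprintf("s%02d", 1:n),
                      numeracy_ss = round(rnorm(n, 99, 16)),
                      age = round(runif(n, 20, 49)), sex = rbinom(n, 1, 0.5))
  n_perm <- 99; seed <- 48
  fit <- run_mdmr(ts_list, pheno, interest = "numeracy_ss",
                  nuisance = c("age", "sex"), n_perm = n_perm, seed = seed,
                  batch_size = 7)
  # regenerate the fit's shared permutation list for the oracle
  set.seed(seed)
  perms <- replicate(n_perm, sample.int(n))
  x_red <- cbind(1, pheno$age, pheno$sex)
  dat_list <- lapply(ts_list, `[[`, "data")
  for (v in c(1L, 8L, 17L, 30L)) {
    oracle <- brute_mdmr_voxel(dat_list, v, x_red, pheno$numeracy_ss, perms)
    expect_equal(fit$f$values[v], oracle$f, tolerance = 1e-8)
    expect_equal(fit$p$values[v], oracle$p)
  }
  # explicit-permutation single-voxel interface agrees too
  des <- mdmr_design(pheno, "numeracy_ss", nuisance = c("age", "sex"))
  prof <- t(vapply(ts_list, ifc_profile, numeric(V - 1L), voxel = 17L))
  g <- gower_center(distance_matrix(prof))
  pt <- permutation_test(g, des, perms = perms)
  expect_equal(pt$p, fit$p$values[17])
  expect_equal(pt$f_obs, fit$f$values[17], tolerance = 1e-10)
})

test_that("p-to-Z conversion is the inverse-normal with a documented floor", {
  expect_equal(p_to_z(0.5), 0)
  expect_equal(p_to_z(0.001), 3.0902, tolerance = 1e-4)
  expect_equal(p_to_z(1), -8.2)          # floor policy for p = 1
  expect_equal(p_to_z(pnorm(3.1, lower.tail = FALSE)), 3.1, tolerance = 1e-10)
  expect_error(p_to_z(0), "\\(0, 1\\]")
  expect_error(p_to_z(1.2), "\\(0, 1\\]")
})

test_that("permutation conventions: floor, determinism, counting rule", {
  set.seed(49)
  n <- 10
  pheno <- random_pheno(n, 49)
  des <- mdmr_design(pheno, "numeracy_ss", nuisance = c("age", "sex"))
  # plant a perfect alignment so F_obs dominates all permutations
  y <- des$interest + rnorm(n, sd = 1e-3)
  g <- gower_center(abs(outer(y, y, "-")))
  pt <- permutation_test(g, des, n_perm = 199, seed = 50)
  expect_equal(pt$p, 1 / 200)
  pt2 <- permutation_test(g, des, n_perm = 199, seed = 50)
  expect_identical(pt$p, pt2$p)
  expect_identical(pt$f_perm, pt2$f_perm)
  # raw-variable scheme is available and gives a valid p
  pt3 <- permutation_test(g, des, n_perm = 199, seed = 50, scheme = "raw")
  expect_true(pt3$p >= 1 / 200 && pt3$p <= 1)
})

test_that("whole-brain MDMR runs are reproducible and flag degeneracies", {
  st <- tiny_study(n_subjects = 12, T_len = 60, slope = 0.1, seed = 51)
  fit1 <- run_mdmr(st$ts, st$cohort, interest = "numeracy_ss",
                   nuisance = c("age", "sex"), n_perm = 99, seed = 52)
  fit2 <- run_mdmr(st$ts, st$cohort, interest = "numeracy_ss",
                   nuisance = c("age", "sex"), n_perm = 99, seed = 52,
                   batch_size = 5)
  expect_equal(fit1$p$values, fit2$p$values)
  expect_equal(fit1$f$values, fit2$f$values, tolerance = 1e-10)
  expect_true(all(fit1$p$values >= 1 / 100 & fit1$p$values <= 1))
  expect_equal(fit1$z$values, p_to_z(fit1$p$values))
  # a constant voxel aborts with a preflight report
  st$ts[[3]]$data[, 5] <- 42
  expect_error(run_mdmr(st$ts, st$cohort, interest = "numeracy_ss",
                        nuisance = c("age", "sex"), n_perm = 9, seed = 1),
               "preflight")
})
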