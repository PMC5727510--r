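test_that("seed time series averaging behaves on degenerate regions", {
  st <- tiny_study(n_subjects = 4, T_len = 40, slope = 0.1, seed = 71)
  ts <- st$ts[[1]]
  expect_equal(seed_timeseries(ts, 5L), ts$data[, 5])
  ts$data[, 6] <- ts$data[, 5]
  expect_equal(seed_timeseries(ts, c(5L, 6L)), ts$data[, 5])
  t_axis <- seq_len(40)
  ts$data[, 7] <- sin(2 * pi * t_axis / 10)
  ts$data[, 8] <- -sin(2 * pi * t_axis / 10)
  expect_lt(max(abs(seed_timeseries(ts, c(7L, 8L)))), 1e-12)
  expect_error(seed_timeseries(ts, integer(0)), "empty")
  expect_error(seed_timeseries(ts, 999L), "outside")
})

test_that("seed correlation maps are clamped Fisher-Z of brute-force r", {
  V <- 30
  mask <- group_mask(volume_grid(c(V, 1, 1), voxel_mm = 3),
                     array(TRUE, c(V, 1, 1)))
  ts <- random_ts(mask, 1, 50, seed = 72)[[1]]
  seed_series <- ts$data[, 4]
  zm <- sca_map(ts, seed_series)
  brute <- atanh(pmin(pmax(sapply(seq_len(V), function(v)
    cor(seed_series, ts$data[, v])), -(1 - 1e-7)), 1 - 1e-7))
  expect_equal(zm$values, brute, tolerance = 1e-12)
  expect_equal(zm$values[4], atanh(1 - 1e-7))    # self voxel at the clamp
  expect_equal(zm$kind, "fisherz")
  expect_error(sca_map(ts, rep(1, 50)), "constant")
  # monotone in r after clamping
  r <- seq(-0.99, 0.99, by = 0.01)
  expect_true(all(diff(atanh(pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7))) > 0))
})

test_that("group GLM recovers planted voxel effects and rejects bad designs", {
  set.seed(73)
  n <- 40; V <- 120
  pheno <- random_pheno(n, 73)
  des <- mdmr_design(pheno, "numeracy_ss", nuisance = c("age", "sex"))
  y <- matrix(rnorm(n * V, sd = 0.5), n, V)
  y[, 7] <- y[, 7] + 0.04 * pheno$numeracy_ss          # planted slope
  fitg <- group_glm(y, des)
  expect_gt(fitg$t[7], 0)
  expect_lt(2 * pt(abs(fitg$t[7]), fitg$df, lower.tail = FALSE), 0.01)
  # t and z agree through the t CDF
  expect_equal(fitg$z, qnorm(pt(fitg$t, fitg$df)), tolerance = 1e-6)
  # oracle: per-voxel lm t statistic
  lm_t <- summary(lm(y[, 7] ~ age + sex + numeracy_ss,
                     data = pheno))$coefficients["numeracy_ss", "t value"]
  expect_equal(unname(fitg$t[7]), lm_t, tolerance = 1e-8)
  # null calibration: permuted phenotype gives uniform p over voxels
  pheno_perm <- pheno
  pheno_perm$numeracy_ss <- sample(pheno$numeracy_ss)
  des_p <- mdmr_design(pheno_perm, "numeracy_ss", nuisance = c("age", "sex"))
  y0 <- matrix(rnorm(n * 1000), n, 1000)
  fit0 <- group_glm(y0, des_p)
  pvals <- 2 * pt(abs(fit0$t), fit0$df, lower.tail = FALSE)
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
  # interest duplicated in nuisance is a rank error
  pheno_dup <- pheno; pheno_dup$age <- pheno_dup$numeracy_ss
  expect_error(mdmr_design(pheno_dup, "numeracy_ss",
                           nuisance = c("age", "sex")), "rank")
})

test_that("connection extraction averages Fisher-Z over cluster voxels", {
  mask <- tiny_mask()
  maps <- lapply(1:5, function(s)
    stat_map(rnorm(mask$n_voxels), mask, "fisherz"))
  roi <- c(2L, 4L, 5L, 7L, 8L)
  got <- extract_connection(maps, roi)
  brute <- sapply(maps, function(m) mean(m$values[roi]))
  expect_equal(got, brute, tolerance = 1e-12)
  expect_equal(extract_connection(maps, 3L),
               sapply(maps, function(m) m$values[3]))
  const <- lapply(1:5, function(s) stat_map(rep(0.7, 8), mask, "fisherz"))
  expect_equal(extract_connection(const, roi), rep(0.7, 5))
  expect_error(extract_connection(maps, integer(0)), "empty")
})

test_that("dependent-correlation test matches the oracle and edge cases", {
  set.seed(74)
  n <- 20
  j <- rnorm(n); k <- 0.5 * j + rnorm(n); h <- 0.3 * j + rnorm(n)
  got <- corr_diff_test(j, k, h)
  want <- steiger_oracle(j, k, h)
  expect_equal(unname(got$statistic), want$z, tolerance = 1e-8)
  expect_equal(got$p.value, want$p, tolerance = 1e-8)
  # identical phenotypes: Z = 0, p = 1
  same <- corr_diff_test(j, k, k)
  expect_equal(unname(same$statistic), 0)
  expect_equal(same$p.value, 1)
  expect_error(corr_diff_test(j, j, h), "1")
  expect_error(corr_diff_test(j[1:3], k[1:3], h[1:3]), "n >= 4")
})

test_that("D'Agostino omnibus matches reference values on fixed data", {
  # reference statistics computed with an independent implementation of the
  # K-squared omnibus (skew + kurtosis) on this frozen fixture
  x <- c(7.058, 8.284, 7.293, 3.054, 2.214, 5.134, 6.723, 6.018, 8.621,
         6.502, 6.28, 3.537, 2.785, 7.969, 5.098, 6.623, 2.247, 4.127,
         2.418, 3.449, 6.806, 2.039, 3.932, 5.328)
  h <- dagostino_test(x)
  expect_equal(unname(h$statistic), 5.6156868475, tolerance = 1e-9)
  expect_equal(h$p.value, 0.0603349692, tolerance = 1e-9)
  expect_equal(unname(h$estimate), c(-0.0683704784, -2.3687575488),
               tolerance = 1e-9)
  y <- c(0.586, 0.817, 0.837, 1.397, 0.708, 1.243, 1.047, 1.404, 1.197,
         3.767, 0.588, 2.61, 0.725, 0.465, 2.635, 0.704, 0.733, 0.329,
         0.187, 1.661, 0.394, 1.864, 4.387, 0.912, 0.406, 1.371, 1.839,
         0.811, 1.014, 2.91)
  hy <- dagostino_test(y)
  expect_equal(unname(hy$statistic), 14.5139852032, tolerance = 1e-9)
  expect_lt(hy$p.value, 0.001)            # clearly non-normal (lognormal)
})

test_that("discrepancy analysis uses numeracy minus literacy", {
  set.seed(75)
  n <- 30
  pheno <- data.frame(subject_id = as.character(1:n),
                      literacy_ss = round(rnorm(n, 101, 11)),
                      numeracy_ss = round(rnorm(n, 99, 16)))
  pheno$numeracy_ss[1] <- 110; pheno$literacy_ss[1] <- 100
  conns <- list(a = rnorm(n), b = rnorm(n))
  res <- discrepancy_analysis(pheno, conns)
  expect_equal(res$discrepancy[1], 10)    # Superior Numerical is positive
  expect_equal(res$discrepancy, pheno$numeracy_ss - pheno$literacy_ss)
  expect_equal(nrow(res$table), 2L)
  expect_equal(res$table$p_bonferroni, pmin(res$table$p * 2, 1))
  oracle <- cor.test(res$discrepancy, conns$a)
  expect_equal(res$table$r[1], unname(oracle$estimate), tolerance = 1e-12)
  pheno$numeracy_ss <- pheno$literacy_ss
  expect_error(discrepancy_analysis(pheno, conns), "zero-variance")
})

test_that("connection cross-correlation matrix matches a pairwise loop", {
  set.seed(76)
  conns <- list(w = rnorm(25), x = rnorm(25), y = rnorm(25), z = rnorm(25))
  cm <- connection_matrix(conns)
  expect_equal(diag(cm$r), rep(1, 4), ignore_attr = TRUE)
  expect_equal(cm$r, t(cm$r))
  for (i in 1:3) for (j in (i + 1):4) {
    ct <- cor.test(conns[[i]], conns[[j]])
    expect_equal(cm$r[i, j], unname(ct$estimate), tolerance = 1e-12)
    expect_equal(cm$p[i, j], ct$p.value, tolerance = 1e-12)
  }
  expect_error(connection_matrix(conns[1]), "at least 2")
  expect_error(connection_matrix(list(a = rnorm(5), b = rnorm(6))),
               "length")
})
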