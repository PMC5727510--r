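# Independent brute-force oracles, written as literal transcriptions of the
# underlying constructions (full hat matrices, explicit voxel loops). They
# share nothing with the package's batched implementations beyond base R.

brute_hat <- function(x) x %*% solve(crossprod(x)) %*% t(x)

# PERMANOVA-style distance regression for one target voxel, with
# Freedman-Lane permutation of the nuisance-residualized interest variable.
brute_mdmr_voxel <- function(dat_list, voxel, x_red, x_int, perms) {
  n <- length(dat_list)
  profs <- t(vapply(dat_list, function(d) {
    v <- d[, voxel]
    sapply(seq_len(ncol(d))[-voxel], function(w) cor(v, d[, w]))
  }, numeric(ncol(dat_list[[1]]) - 1L)))
  d <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n)
    if (i != j) d[i, j] <- sqrt(2 * (1 - cor(profs[i, ], profs[j, ])))
  a <- -0.5 * d^2
  cmat <- diag(n) - matrix(1 / n, n, n)
  g <- cmat %*% a %*% cmat
  h0 <- brute_hat(x_red)
  e <- (diag(n) - h0) %*% x_int
  f_of <- function(xi) {
    h <- brute_hat(cbind(x_red, xi))
    p <- ncol(x_red) + 1L
    num <- sum(diag(h %*% g %*% h)) - sum(diag(h0 %*% g %*% h0))
    den <- sum(diag((diag(n) - h) %*% g %*% (diag(n) - h))) / (n - p)
    num / den
  }
  f_obs <- f_of(e)
  f_perm <- apply(perms, 2, function(pp) f_of(e[pp]))
  list(f = f_obs, p = (1 + sum(f_perm >= f_obs)) / (1 + ncol(perms)))
}

# dependent-correlation Z test (two correlations sharing one variable),
# coded from the published formula with its own Fisher transform
steiger_oracle <- function(j, k, h) {
  n <- length(j)
  rjk <- cor(j, k); rjh <- cor(j, h); rkh <- cor(k, h)
  zjk <- 0.5 * log((1 + rjk) / (1 - rjk))
  zjh <- 0.5 * log((1 + rjh) / (1 - rjh))
  zbar <- (zjk + zjh) / 2
  rbar <- (exp(2 * zbar) - 1) / (exp(2 * zbar) + 1)
  psi <- rkh * (1 - rbar^2 - rbar^2) -
    0.5 * rbar^2 * (1 - rbar^2 - rbar^2 - rkh^2)
  s <- psi / ((1 - rbar^2) * (1 - rbar^2))
  z <- (zjk - zjh) * sqrt((n - 3) / (2 - 2 * s))
  list(z = z, p = 2 * pnorm(-abs(z)))
}
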