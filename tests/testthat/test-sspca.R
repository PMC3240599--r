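# principal angles between the column spaces of two matrices
principal_angles <- function(A, B) {
  qa <- qr.Q(qr(A))
  qb <- qr.Q(qr(B))
  s <- svd(crossprod(qa, qb))$d
  acos(pmin(pmax(s, -1), 1))
}

# a complete matrix that is exactly low-rank after column standardization
make_lowrank <- function(N, M, d, seed = 1) {
  set.seed(seed)
  A0 <- scale(matrix(rnorm(N * d), N, d), center = TRUE, scale = FALSE)
  S0 <- matrix(rnorm(M * d), M, d)
  X <- tcrossprod(A0, S0)
  sweep(X, 2, apply(X, 2, sd), "/")
}

test_that("complete rank-d data are recovered exactly", {
  X <- make_lowrank(25, 60, 2, seed = 51)
  fit <- fit_sspca(X, d = 2, seed = 3)
  expect_lt(fit$R, 1e-8 * sum(X^2))
  expect_lt(max(abs(tcrossprod(fit$A, fit$S) - X)), 1e-5)
  # constraints: orthonormal scores, orthogonal loadings
  expect_lt(max(abs(crossprod(fit$A) - diag(2))), 1e-10)
  ss <- crossprod(fit$S)
  expect_lt(abs(ss[1, 2]) / sqrt(ss[1, 1] * ss[2, 2]), 1e-10)
})

test_that("complete-data subspace equals the covariance eigen-decomposition", {
  set.seed(52)
  X <- matrix(rnorm(40 * 120), 40, 120) +
    tcrossprod(matrix(rnorm(40 * 3), 40, 3), matrix(rnorm(120 * 3), 120, 3))
  st <- standardize_columns(X)
  Xs <- st$x[, st$keep]
  fit <- fit_sspca(Xs, d = 3, seed = 4, max_iter = 2000, tol = 1e-14)
  ev <- eigen(tcrossprod(Xs), symmetric = TRUE)$vectors[, 1:3]
  expect_lt(max(principal_angles(fit$A, ev)), 1e-6)
  # PC1 scores match covariance PCA up to sign
  pcs <- pcs_from_factors(fit)
  pr <- prcomp(Xs, center = FALSE, scale. = FALSE)
  expect_gt(abs(cor(pcs$scores[, 1], pr$x[, 1])), 1 - 1e-8)
})

test_that("achieved reconstruction error matches a direct optimizer", {
  set.seed(53)
  G <- matrix(rnorm(6 * 8), 6, 8) +
    tcrossprod(matrix(rnorm(12), 6, 2), matrix(rnorm(16), 8, 2))
  G[sample(48, 14)] <- NA              # ~30% missing
  st <- standardize_columns(G)
  Xs <- st$x[, st$keep]
  W <- !is.na(Xs)
  X0 <- ifelse(W, Xs, 0)
  n <- nrow(Xs); m <- ncol(Xs); d <- 2
  obj <- function(par) {
    A <- matrix(par[1:(n * d)], n, d)
    S <- matrix(par[-(1:(n * d))], m, d)
    sum(((X0 - tcrossprod(A, S)) * W)^2)
  }
  best <- Inf
  for (s in 1:5) {
    set.seed(s)
    o <- optim(rnorm(n * d + m * d, sd = 0.5), obj, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-14))
    best <- min(best, o$value)
  }
  # small masked factorizations can have local minima: both solvers get the
  # same number of independent starts
  fit <- fit_sspca(G, d = 2, seed = 5, n_starts = 5, max_iter = 2000,
                   tol = 1e-14)
  expect_lt(abs(fit$R - best), 1e-6 * max(best, 1))
})

test_that("ALS half-steps never increase the reconstruction error", {
  sim <- tiny_admixture(n_ind = 20, M = 800, n_source = 40, seed = 54)
  mp <- mask_to_virtual(sim$panel, sim$track, 1)
  fit <- fit_sspca(mp, d = 2, seed = 6, track_objective = TRUE)
  o <- fit$objective
  expect_true(all(diff(o) <= 1e-9 * pmax(o[-length(o)], 1)))
})

test_that("the gradient solver decreases R toward the ALS optimum", {
  set.seed(55)
  G <- matrix(rnorm(15 * 30), 15, 30) +
    tcrossprod(matrix(rnorm(30), 15, 2), matrix(rnorm(60), 30, 2)) * 2
  G[sample(450, 90)] <- NA
  als <- fit_sspca(G, d = 2, seed = 7)
  grad <- fit_sspca(G, d = 2, seed = 7, solver = "gradient",
                    lambda = 1e-3, max_iter = 3000, tol = 1e-12,
                    track_objective = TRUE)
  expect_true(all(diff(grad$objective) <= 1e-9))
  expect_lt(grad$R, als$R * 1.05)
})

test_that("principal components are ordered, signed, and equivariant", {
  X <- make_lowrank(30, 70, 2, seed = 56) +
    0.01 * matrix(rnorm(30 * 70), 30, 70)
  fit <- fit_sspca(X, d = 2, seed = 8)
  pcs <- pcs_from_factors(fit)
  expect_true(pcs$sv[1] >= pcs$sv[2])
  # sign convention: largest-magnitude loading positive
  for (j in 1:2) expect_gt(pcs$loadings[which.max(abs(pcs$loadings[, j])), j], 0)
  # d = 1: scores are the normalized factor times its singular value
  fit1 <- fit_sspca(X, d = 1, seed = 8)
  expect_equal(pcs_from_factors(fit1)$scores[, 1],
               fit1$A[, 1] * fit1$sv[1], ignore_attr = TRUE)
  # permuting individuals permutes the scores identically
  perm <- sample(30)
  fitp <- fit_sspca(X[perm, ], d = 2, seed = 8)
  sp <- pcs_from_factors(fitp)$scores
  s0 <- pcs_from_factors(fit)$scores[perm, ]
  for (j in 1:2)
    expect_lt(min(max(abs(sp[, j] - s0[, j])),
                  max(abs(sp[, j] + s0[, j]))), 1e-4)
})

test_that("projection reproduces and extends the fitted scores", {
  sim <- tiny_admixture(n_ind = 25, M = 1200, n_source = 60, seed = 57)
  mp <- mask_to_virtual(sim$panel, sim$track, 1)
  # complete rows: projecting the complete diploid dosage reproduces scores
  X <- make_lowrank(25, 80, 2, seed = 58) +
    0.05 * matrix(rnorm(25 * 80), 25, 80)
  fit <- fit_sspca(X, d = 2, seed = 9)
  proj <- project_onto_pcs(X, fit)
  expect_lt(max(abs(proj - pcs_from_factors(fit)$scores)), 1e-6)
  # a duplicated row with 50% masking projects near its complete-row score
  set.seed(59)
  Xm <- X
  Xm[cbind(1:25, 1)] <- X[, 1]
  mask <- matrix(runif(25 * 80) < 0.5, 25, 80)
  Xm[mask] <- NA
  projm <- project_onto_pcs(Xm, fit)
  expect_gt(cor(proj[, 1], projm[, 1]), 0.9)
  # all-missing rows are flagged
  Xa <- X; Xa[3, ] <- NA
  pa <- project_onto_pcs(Xa, fit)
  expect_true(3 %in% attr(pa, "flagged"))
  expect_true(all(is.na(pa[3, ])))
})

test_that("confusion fraction enumerates the best threshold", {
  expect_equal(confusion_fraction(c(0.1, 0.2, 0.9, 1.0),
                                  c("a", "a", "b", "b"))$xi, 0)
  expect_equal(confusion_fraction(c(0.1, 0.9, 0.2, 1.0),
                                  c("a", "a", "b", "b"))$xi, 0.25)
  set.seed(60)
  xi_same <- confusion_fraction(rnorm(200), rep(c("a", "b"), 100))$xi
  expect_lte(xi_same, 0.5)
  expect_gt(xi_same, 0.3)
  expect_error(confusion_fraction(1:4, rep("a", 4)), "two levels")
})

test_that("subspace PCA resists observed-fraction leakage", {
  # two groups, per-individual observed fractions varying 0.3-1.0
  set.seed(61)
  grid <- simulate_marker_grid(2500)
  fr <- draw_population_freqs(grid$p_anc, 0.05, K = 2)
  pans <- simulate_source_haplotypes(fr, 60, grid$markers, founder_frac = 1)
  dose <- function(p) p$alleles[seq(1, 59, 2), ] + p$alleles[seq(2, 60, 2), ]
  G <- rbind(dose(pans[[1]]), dose(pans[[2]])) / 2
  grp <- rep(c("a", "b"), each = 30)
  obs_frac <- runif(60, 0.3, 1.0)
  Gm <- G
  for (i in 1:60)
    Gm[i, runif(2500) > obs_frac[i]] <- NA
  fit <- fit_sspca(Gm, d = 2, seed = 10)
  sc <- pcs_from_factors(fit)$scores
  expect_lt(confusion_fraction(sc[, 1], grp)$xi, 0.05)
  # mean-imputed covariance PCA baseline: impute standardized NA as 0
  st <- standardize_columns(Gm)
  Xs <- st$x[, st$keep]
  Xs[is.na(Xs)] <- 0
  pr <- prcomp(Xs, center = FALSE, scale. = FALSE)
  leak_base <- max(abs(cor(pr$x[, 1], obs_frac)),
                   abs(cor(pr$x[, 2], obs_frac)))
  leak_ss <- max(abs(cor(sc[, 1], obs_frac)), abs(cor(sc[, 2], obs_frac)))
  expect_gt(leak_base, leak_ss)
})

test_that("errors are raised for degenerate fits", {
  X <- make_lowrank(6, 20, 2, seed = 62)
  expect_error(fit_sspca(X, d = 6), "d < N")
  Xa <- X; Xa[2, ] <- NA
  expect_error(fit_sspca(Xa, d = 2), "no observed entries")
})
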