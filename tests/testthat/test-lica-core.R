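# Linked ICA core: standardization, exact small cases, planted-structure
# recovery, ARD shrinkage, contribution fractions, reconstruction, and the
# factorization invariants.

test_that("standardization centers features, hits unit mean-square, and inverts", {
  set.seed(41)
  raw <- list(matrix(rnorm(30 * 8, mean = 5), 30, 8),
              matrix(rnorm(12 * 8, sd = 40), 12, 8))
  raw[[1]][3, ] <- 2.5  # constant feature row
  inp <- standardize_modalities(raw)
  for (k in 1:2) {
    expect_lt(max(abs(rowMeans(inp$modalities[[k]]))), 1e-12)
    expect_equal(mean(inp$modalities[[k]]^2), 1, tolerance = 1e-12)
  }
  expect_true(all(inp$modalities[[1]][3, ] == 0))
  for (k in 1:2) {
    expect_equal(destandardize_modality(inp, k), raw[[k]], tolerance = 1e-10)
  }
  expect_error(standardize_modalities(list(matrix(1, 5, 4))), "zero variance")
  expect_error(standardize_modalities(list(matrix(rnorm(20), 5, 4),
                                           matrix(rnorm(15), 5, 3))),
               "subject counts differ")
  na_mod <- matrix(rnorm(20), 5, 4); na_mod[2, 2] <- NA
  expect_error(standardize_modalities(list(na_mod)), "missing")
})

test_that("a noiseless rank-1 problem is solved exactly", {
  set.seed(42)
  s <- rnorm(50); s <- s / sqrt(sum(s^2))
  h <- rnorm(20); h <- h / sqrt(sum(h^2))
  X <- 4.2 * s %*% t(h)
  inp <- standardize_modalities(list(X), center = FALSE, scale = FALSE)
  fit <- fit_lica(inp, n_components = 1, max_iter = 200, seed = 1)
  expect_lt(abs(fit$lambda[1, 1] - 4.2), 1e-6)
  expect_lt(max(abs(reconstruct(fit, 1) - X)), 1e-6)
  P <- contribution_fractions(fit)
  expect_equal(unname(P[1, 1]), 1)
  # sign convention: largest-|.| loading entry is positive
  expect_gt(fit$H[1, which.max(abs(fit$H[1, ]))], 0)
})

test_that("planted multi-modality structure is recovered and ARD silences absent modalities", {
  lam <- gblica:::default_lambda_matrix(2, 3)
  lam[2, ] <- 0  # middle modality carries no signal
  co <- make_joint_dataset(n_subjects = 40, n_genera = 30, n_networks = 2,
                           n_components = 3, sparsity = 0.1, noise_sd = 0.1,
                           lambda_matrix = lam, seed = 5)
  fit <- fit_lica(co$modalities, n_components = 3, seed = 1)
  m <- greedy_match(fit$H, co$truth$H_true)
  expect_true(all(m$r >= 0.9))
  # ARD shrinkage: estimated weights for the silent modality are tiny
  ratios <- fit$lambda[2, ] / apply(fit$lambda, 2, max)
  expect_true(all(ratios <= 0.05))
})

test_that("the objective trace is monotone non-increasing", {
  co <- make_joint_dataset(n_subjects = 25, n_networks = 1, n_genera = 20,
                           grid_shape = c(5, 5, 5), seed = 19)
  fit <- fit_lica(co$modalities, n_components = 3, seed = 1)
  tr <- fit$objective_trace
  expect_true(all(diff(tr) <= 1e-8 * pmax(1, abs(tr[-length(tr)]))))
  expect_true(fit$converged)
})

test_that("contribution fractions follow their closed form and sum to one", {
  # K = 1: everything attributed to the single modality
  m1 <- toy_model(lambda = matrix(c(3, 1.2), 1, 2))
  expect_true(all(contribution_fractions(m1) == 1))
  # closed forms over two modalities
  m2 <- toy_model(lambda = cbind(c(2, 0), c(1, 1)))
  P <- contribution_fractions(m2)
  expect_equal(unname(P[, 1]), c(1, 0))
  expect_equal(unname(P[, 2]), c(0.5, 0.5))
  expect_lt(max(abs(colSums(P) - 1)), 1e-9)
  # degenerate all-zero column -> uniform, flagged
  m3 <- toy_model(lambda = cbind(c(1, 1), c(0, 0)))
  P3 <- contribution_fractions(m3)
  expect_equal(unname(P3[, 2]), c(0.5, 0.5))
  expect_true(attr(P3, "degenerate")[2])
})

test_that("recovered contribution fractions track the planted variance split", {
  lam <- rbind(c(8, 8, 8), c(4, 4, 4)) # 0.8 / 0.2 variance split per component
  co <- make_joint_dataset(n_subjects = 40, n_genera = 30, n_networks = 2,
                           n_components = 3, lambda_matrix = rbind(lam, c(0.01, 0.01, 0.01)),
                           sparsity = 0.1, noise_sd = 0.1, seed = 23)
  fit <- fit_lica(co$modalities[1:2], n_components = 3, seed = 1)
  inp <- standardize_modalities(co$modalities[1:2])
  lam_std <- lam * inp$scales
  P_true <- sweep(lam_std^2, 2, colSums(lam_std^2), "/")
  m <- greedy_match(fit$H, co$truth$H_true)
  P_est <- contribution_fractions(fit)[, m$perm, drop = FALSE]
  expect_lt(max(abs(P_est - P_true)), 0.1)
})

test_that("reconstruction accounts for all variance and the noise precision", {
  co <- make_joint_dataset(n_subjects = 30, n_networks = 1, n_genera = 20,
                           grid_shape = c(5, 5, 5), noise_sd = 0.2, seed = 29)
  inp <- standardize_modalities(co$modalities)
  fit <- fit_lica(inp, n_components = 3, seed = 1)
  # empty subset -> zero matrix
  expect_true(all(reconstruct(fit, 1, integer(0)) == 0))
  # residual variance matches the beta_k-implied noise variance within 10%
  for (k in 1:2) {
    resid <- inp$modalities[[k]] - reconstruct(fit, k)
    expect_lt(abs(mean(resid^2) * fit$beta[k] - 1), 0.1)
  }
  # full-subset reconstruction on noiseless data reproduces the input
  co0 <- make_joint_dataset(n_subjects = 20, n_networks = 1, n_genera = 15,
                            grid_shape = c(4, 4, 4), noise_sd = 0, seed = 30)
  inp0 <- standardize_modalities(co0$modalities)
  fit0 <- fit_lica(inp0, n_components = 3, seed = 1)
  for (k in 1:2) {
    expect_lt(max(abs(reconstruct(fit0, k) - inp0$modalities[[k]])), 1e-6)
  }
})

test_that("modality relabeling permutes fractions; raw rescaling changes nothing", {
  co <- make_joint_dataset(n_subjects = 25, n_networks = 1, n_genera = 20,
                           grid_shape = c(4, 4, 4), seed = 37)
  f1 <- fit_lica(co$modalities, n_components = 2, seed = 1)
  f2 <- fit_lica(co$modalities[c(2, 1)], n_components = 2, seed = 1)
  P1 <- unclass(contribution_fractions(f1))
  P2 <- unclass(contribution_fractions(f2))
  expect_equal(unname(P2), unname(P1[c(2, 1), ]), tolerance = 1e-6,
               ignore_attr = TRUE)
  # scale invariance: multiplying a raw modality by 10 is absorbed upstream
  scaled <- co$modalities
  scaled[[1]] <- scaled[[1]] * 10
  f3 <- fit_lica(scaled, n_components = 2, seed = 1)
  expect_equal(f3$H, f1$H, tolerance = 1e-8)
  expect_equal(unclass(contribution_fractions(f3)), P1, tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("noiseless factorization spans the SVD-oracle subspace", {
  co <- make_joint_dataset(n_subjects = 20, n_networks = 1, n_genera = 15,
                           grid_shape = c(4, 4, 4), n_components = 2,
                           noise_sd = 0, seed = 43)
  fit <- fit_lica(co$modalities, n_components = 2, seed = 1)
  inp <- standardize_modalities(co$modalities)
  sv <- svd(do.call(rbind, inp$modalities), nu = 0, nv = 2)
  # principal angle between row space of fitted H and the oracle subspace
  q1 <- qr.Q(qr(t(fit$H)))
  q2 <- qr.Q(qr(sv$v))
  angle <- acos(min(svd(crossprod(q1, q2))$d, 1))
  expect_lt(angle, 1e-3)
})

test_that("loading recovery degrades monotonically with noise on average", {
  noise_levels <- c(0, 0.1, 0.3, 1.0)
  mean_r <- vapply(noise_levels, function(ns) {
    rs <- vapply(1:20, function(s) {
      co <- make_joint_dataset(n_subjects = 20, n_networks = 1, n_genera = 15,
                               grid_shape = c(4, 4, 4), n_components = 2,
                               sparsity = 0.15, noise_sd = ns, seed = 100 + s)
      fit <- fit_lica(co$modalities, n_components = 2, max_iter = 200,
                      tol = 1e-5, seed = 1)
      mean(greedy_match(fit$H, co$truth$H_true)$r)
    }, numeric(1))
    mean(rs)
  }, numeric(1))
  expect_true(all(diff(mean_r) < 0))
})

test_that("fit rejects impossible configurations", {
  co <- make_joint_dataset(n_subjects = 10, n_networks = 1, n_genera = 8,
                           grid_shape = c(3, 3, 3), n_components = 2, seed = 3)
  expect_error(fit_lica(co$modalities, n_components = 11), "n_components")
  expect_error(fit_lica(co$modalities, n_components = 2, max_iter = 0), "max_iter")
})
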