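# Dual regression: exact inversion on noiseless inputs, null z calibration,
# conditioning on the full template set, NIfTI round trips.

test_that("stage 1 inverts a noiseless spatial mixture exactly", {
  set.seed(21)
  maps <- qr.Q(qr(matrix(rnorm(200 * 4), 200, 4)))
  tmpl <- template_set(maps, grid = c(10, 5, 4))
  tc <- matrix(rnorm(50 * 4), 50, 4)
  fmri <- maps %*% t(tc)
  expect_lt(max(abs(stage1_spatial_regression(tmpl, fmri) - tc)), 1e-8)
  # zero data -> zero timecourses
  expect_true(all(stage1_spatial_regression(tmpl, fmri * 0) == 0))
})

test_that("stage 1 joint regression matches the normal-equations oracle for correlated templates", {
  set.seed(22)
  base <- matrix(rnorm(150 * 3), 150, 3)
  maps <- cbind(base[, 1], base[, 1] * 0.6 + base[, 2], base[, 3])  # correlated
  tmpl <- template_set(maps, grid = c(15, 5, 2))
  tc <- matrix(rnorm(40 * 3), 40, 3)
  fmri <- maps %*% t(tc)
  rec <- stage1_spatial_regression(tmpl, fmri)
  expect_lt(max(abs(rec - tc)) / max(abs(tc)), 1e-6)
  # independent oracle: explicit normal-equations solve on demeaned design
  A <- sweep(maps, 2, colMeans(maps))
  Y <- sweep(fmri, 2, colMeans(fmri))
  oracle <- t(solve(crossprod(A), crossprod(A, Y)))
  expect_equal(unname(rec), unname(oracle), tolerance = 1e-10)
})

test_that("stage 1 rejects rank-deficient templates, naming the collinear pair", {
  maps <- matrix(rnorm(100 * 2), 100, 2)
  maps <- cbind(maps, maps[, 1] * 2)  # exact duplicate direction
  tmpl <- template_set(maps, grid = c(10, 5, 2),
                       network_names = c("DMN", "ECN", "DMNcopy"))
  fmri <- matrix(rnorm(100 * 30), 100, 30)
  expect_error(stage1_spatial_regression(tmpl, fmri), "DMN ~ DMNcopy")
  expect_error(stage1_spatial_regression(tmpl, fmri[, 1:3]), "timepoints")
})

test_that("stage 2 recovers generating maps up to per-network scale when noiseless", {
  set.seed(23)
  maps <- matrix(rnorm(180 * 3), 180, 3)
  tc <- matrix(rnorm(60 * 3), 60, 3)
  fmri <- maps %*% t(tc)
  B <- stage2_temporal_regression(tc, fmri, output = "beta")
  # regression on variance-normalized demeaned timecourses: betas = maps * sd(tc_k)
  for (k in 1:3) {
    expect_lt(max(abs(B[, k] / sd(tc[, k]) - maps[, k])) / max(abs(maps[, k])), 1e-6)
  }
})

test_that("stage 2 z-scores are null-calibrated on pure-noise data", {
  set.seed(24)
  fmri <- matrix(rnorm(500 * 80), 500, 80)
  tc <- matrix(rnorm(80 * 3), 80, 3)
  z <- stage2_temporal_regression(tc, fmri, output = "z")
  expect_lt(abs(mean(z)), 0.1)
  expect_gt(sd(z), 0.9)
  expect_lt(sd(z), 1.1)
})

test_that("stage 2 rejects degenerate designs", {
  tc <- cbind(rnorm(30), 0)  # constant-zero timecourse appended
  fmri <- matrix(rnorm(50 * 30), 50, 30)
  expect_error(stage2_temporal_regression(tc, fmri), "collinear|rank")
  expect_error(stage2_temporal_regression(matrix(rnorm(4 * 3), 4, 3),
                                          matrix(rnorm(20 * 4), 20, 4)),
               "degrees of freedom")
})

test_that("full dual regression recovers subject maps and keeps bookkeeping straight", {
  co <- make_joint_dataset(n_subjects = 5, n_networks = 2, seed = 7,
                           noise_sd = 0, timepoints = 60, fmri_noise_sd = 0)
  maps <- run_dual_regression(co$templates, co$fmri, output = "beta")
  expect_length(maps, 2)
  nv <- prod(co$grid_shape)
  for (k in 1:2) {
    expect_equal(nrow(maps[[k]]$maps), 5)
    block <- (k - 1) * nv + seq_len(nv)
    for (r in 1:5) {
      gen <- co$templates$maps[block, k] + co$modalities[[k]][, r]
      expect_gt(abs(cor(gen, maps[[k]]$maps[r, block])), 0.999)
    }
  }
  # selection: 1 of 2 networks -> list length 1, named network, 5 rows
  sel <- run_dual_regression(co$templates, co$fmri, select = "NET02")
  expect_length(sel, 1)
  expect_identical(sel[[1]]$network_name, "NET02")
  expect_error(run_dual_regression(co$templates, co$fmri, select = "NET09"),
               "unknown network")
  # grid mismatch reported with shapes
  bad <- lapply(co$fmri, function(f) f[-1, ])
  expect_error(run_dual_regression(co$templates, bad), "voxels")
})

test_that("template permutation permutes outputs; an orthogonal distractor changes nothing", {
  set.seed(26)
  maps <- qr.Q(qr(matrix(rnorm(120 * 4), 120, 4)))
  tc <- matrix(rnorm(50 * 3), 50, 3)
  fmri <- maps[, 1:3] %*% t(tc)  # data spanned by first three templates only
  tmpl3 <- template_set(maps[, 1:3], grid = c(6, 5, 4),
                        network_names = c("A", "B", "C"))
  tmpl3_perm <- template_set(maps[, c(2, 3, 1)], grid = c(6, 5, 4),
                             network_names = c("B", "C", "A"))
  out1 <- run_dual_regression(tmpl3, list(fmri), output = "beta")
  out2 <- run_dual_regression(tmpl3_perm, list(fmri), select = c("A", "B", "C"),
                              output = "beta")
  for (k in 1:3) {
    expect_equal(out2[[k]]$maps, out1[[k]]$maps, tolerance = 1e-10)
  }
  # conditioning on all templates: adding an orthogonal distractor leaves
  # the selected networks' maps unchanged (noiseless case)
  tmpl4 <- template_set(maps, grid = c(6, 5, 4),
                        network_names = c("A", "B", "C", "D"))
  out3 <- run_dual_regression(tmpl4, list(fmri), select = c("A", "B", "C"),
                              output = "beta")
  for (k in 1:3) {
    expect_equal(out3[[k]]$maps, out1[[k]]$maps, tolerance = 1e-6)
  }
})

test_that("map recovery stays high at moderate noise", {
  co <- make_joint_dataset(n_subjects = 6, n_networks = 2, seed = 31,
                           noise_sd = 0, timepoints = 150, fmri_noise_sd = 0.5)
  maps <- run_dual_regression(co$templates, co$fmri, output = "beta")
  nv <- prod(co$grid_shape)
  cors <- c()
  for (k in 1:2) {
    block <- (k - 1) * nv + seq_len(nv)
    for (r in 1:6) {
      gen <- co$templates$maps[block, k] + co$modalities[[k]][, r]
      cors <- c(cors, cor(gen, maps[[k]]$maps[r, block]))
    }
  }
  expect_gt(mean(cors), 0.9)
})

test_that("zero-variance voxels are masked out of every subject's maps", {
  co <- make_joint_dataset(n_subjects = 3, n_networks = 2, seed = 33,
                           noise_sd = 0, timepoints = 50, fmri_noise_sd = 0)
  fmri <- co$fmri
  fmri[[2]][5, ] <- 7  # constant time series in one subject
  maps <- run_dual_regression(co$templates, fmri)
  for (m in maps) {
    expect_false(m$mask[5])
    expect_true(all(m$maps[, 5] == 0))
  }
})

test_that("NIfTI template and map stacks round-trip through disk", {
  co <- make_joint_dataset(n_subjects = 4, n_networks = 2, seed = 12,
                           timepoints = 40)
  tf <- tempfile(fileext = ".nii.gz")
  write_templates(co$templates, tf)
  back <- read_templates(tf, network_names = co$templates$network_names)
  expect_equal(back$maps, co$templates$maps, tolerance = 1e-6)
  expect_identical(back$grid, co$templates$grid)
  mf <- tempfile(fileext = ".nii.gz")
  write_network_maps(co$network_maps[[1]], mf)
  arr <- as.array(RNifti::readNifti(mf))
  expect_equal(matrix(arr, prod(dim(arr)[1:3]), dim(arr)[4]),
               t(co$network_maps[[1]]$maps), tolerance = 1e-6,
               ignore_attr = TRUE)
  ff <- tempfile(fileext = ".nii.gz")
  arr4 <- array(co$fmri[[1]], dim = c(co$templates$grid, 40))
  RNifti::writeNifti(RNifti::asNifti(arr4), ff)
  expect_equal(unname(read_fmri(ff)), unname(co$fmri[[1]]), tolerance = 1e-6,
               ignore_attr = TRUE)
})
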