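gt <- default_gradient_scheme()

test_that("isotropic signal fits to d * identity at every voxel", {
  d <- 0.7e-3
  S <- 900 * exp(-gt$bvals * d) # identical in all directions
  dwi <- array(rep(S, each = 8), dim = c(2, 2, 2, length(S)))
  fit <- fit_tensor(dwi, gt)
  for (v in seq_len(8)) {
    idx <- arrayInd(v, c(2, 2, 2))
    expect_equal(
      fit$D[idx[1], idx[2], idx[3], ],
      c(d, d, d, 0, 0, 0),
      tolerance = 1e-10
    )
  }
})

test_that("noise-free forward simulation is recovered to high precision", {
  D <- diag(c(1.4, 0.4, 0.3)) * 1e-3
  S <- simulate_dwi_signal(D, gt)
  dwi <- array(S, dim = c(1, 1, 1, length(S)))
  fit <- fit_tensor(dwi, gt)
  got <- fit$D[1, 1, 1, ]
  want <- c(1.4e-3, 0.4e-3, 0.3e-3, 0, 0, 0)
  expect_lt(max(abs(got - want)) / max(abs(want)), 1e-8)
})

test_that("round-trip recovery holds across random SPD tensors and is scale-equivariant", {
  set.seed(11)
  for (i in 1:30) {
    D <- random_spd_tensor()
    S <- simulate_dwi_signal(D, gt, s0 = 800)
    dwi <- array(S, dim = c(1, 1, 1, length(S)))
    got <- fit_tensor(dwi, gt)$D[1, 1, 1, ]
    want <- c(D[1, 1], D[2, 2], D[3, 3], D[1, 2], D[1, 3], D[2, 3])
    expect_lt(max(abs(got - want)) / max(abs(want)), 1e-8)
    # multiplying all signals by a constant leaves the tensor unchanged
    got2 <- fit_tensor(dwi * 3.7, gt)$D[1, 1, 1, ]
    expect_equal(got2, got, tolerance = 1e-10)
  }
})

test_that("degenerate gradient designs and bad inputs raise errors", {
  S <- rep(1000, 63)
  dwi <- array(S, dim = c(1, 1, 1, 63))
  expect_error(
    fit_tensor(array(S, c(1, 1, 1, 62)), gt),
    "62 volumes"
  )
  allb0 <- gradient_table(rep(0, 5), matrix(0, 3, 5), require_fit_design = FALSE)
  expect_error(
    fit_tensor(array(1000, c(1, 1, 1, 5)), allb0),
    "b = 0|6 unique"
  )
  few <- gradient_table(
    c(0, rep(1000, 3)),
    cbind(0, diag(3)),
    require_fit_design = FALSE
  )
  expect_error(
    fit_tensor(array(1000, c(1, 1, 1, 4)), few),
    "Rank-deficient"
  )
})

test_that("nonpositive signals are masked and reported, not fitted", {
  D <- diag(3) * 0.7e-3
  S <- simulate_dwi_signal(D, gt)
  dwi <- array(rep(S, each = 2), dim = c(2, 1, 1, length(S)))
  dwi[2, 1, 1, 5] <- -1
  expect_message(fit <- fit_tensor(dwi, gt), "1 voxel")
  expect_identical(attr(fit, "n_masked"), 1L)
  expect_false(fit$fit_mask[2, 1, 1])
  expect_true(all(is.na(fit$D[2, 1, 1, ])))
  expect_true(all(is.finite(fit$D[1, 1, 1, ])))
})

test_that("eigendecomposition sorts descending and reconstructs the tensor", {
  tv <- tensor_volume(array(c(3, 1, 2, 0, 0, 0), c(1, 1, 1, 6)))
  e <- tensor_eigen(tv)
  expect_equal(e$values[1, 1, 1, ], c(3, 2, 1))

  iso <- tensor_volume(array(c(rep(0.7e-3, 3), 0, 0, 0), c(1, 1, 1, 6)))
  expect_equal(tensor_eigen(iso)$values[1, 1, 1, ], rep(0.7e-3, 3))

  set.seed(21)
  for (i in 1:20) {
    D <- random_spd_tensor()
    v6 <- c(D[1, 1], D[2, 2], D[3, 3], D[1, 2], D[1, 3], D[2, 3])
    e <- tensor_eigen(tensor_volume(array(v6, c(1, 1, 1, 6))))
    V <- matrix(e$vectors[1, 1, 1, , ], 3, 3)
    lam <- e$values[1, 1, 1, ]
    expect_lt(max(abs(V %*% diag(lam) %*% t(V) - D)), 1e-10)
    expect_lt(max(abs(crossprod(V) - diag(3))), 1e-8)
    expect_true(all(diff(lam) <= 0))
  }
})

test_that("non-finite tensors propagate as NA with a reported count; negative eigenvalues are flagged", {
  D <- array(0, c(2, 1, 1, 6))
  D[1, 1, 1, ] <- c(NA, 1, 1, 0, 0, 0)
  D[2, 1, 1, ] <- c(-1e-4, 1e-3, 1e-3, 0, 0, 0)
  expect_message(e <- tensor_eigen(tensor_volume(D)), "1 voxel")
  expect_true(all(is.na(e$values[1, 1, 1, ])))
  expect_true(e$negative_eigenvalue[2, 1, 1])
  expect_false(e$negative_eigenvalue[1, 1, 1])
})

test_that("scalar maps match their defining formulas and limits", {
  # isotropic: FA 0, MD = AD = RD = d
  sm <- scalar_maps(array(rep(0.7e-3, 3), c(1, 1, 1, 3)))
  expect_equal(sm$fa[1, 1, 1], 0)
  expect_equal(sm$md[1, 1, 1], 0.7e-3)
  expect_equal(sm$ad[1, 1, 1], 0.7e-3)
  expect_equal(sm$rd[1, 1, 1], 0.7e-3)

  # maximal anisotropy limit
  expect_equal(scalar_maps(array(c(1, 0, 0), c(1, 1, 1, 3)))$fa[1, 1, 1], 1)
  # all-zero voxel: FA defined as 0
  expect_equal(scalar_maps(array(0, c(1, 1, 1, 3)))$fa[1, 1, 1], 0)

  # prolate case against an independent algebraic form of FA
  lam <- c(1.4e-3, 0.4e-3, 0.3e-3)
  sm <- scalar_maps(array(lam, c(1, 1, 1, 3)))
  fa_alt <- sqrt(0.5) * sqrt(
    ((lam[1] - lam[2])^2 + (lam[2] - lam[3])^2 + (lam[3] - lam[1])^2) /
      sum(lam^2)
  )
  expect_equal(sm$fa[1, 1, 1], fa_alt, tolerance = 1e-12)
  expect_equal(sm$fa[1, 1, 1], 0.7087048, tolerance = 1e-7)
  expect_equal(sm$md[1, 1, 1], 0.7e-3)
  expect_equal(sm$ad[1, 1, 1], 1.4e-3)
  expect_equal(sm$rd[1, 1, 1], 0.35e-3)
})

test_that("ordering and scaling properties of scalar maps hold on random eigenvalues", {
  set.seed(31)
  lam <- matrix(sort(runif(300, 0, 2e-3), decreasing = TRUE), ncol = 3)
  lam <- t(apply(lam, 1, sort, decreasing = TRUE))
  sm <- scalar_maps(array(lam, c(nrow(lam), 1, 1, 3)))
  expect_true(all(sm$ad >= sm$md - 1e-15 & sm$md >= sm$rd - 1e-15))
  # FA invariant under uniform scaling; MD/AD/RD scale linearly
  sm5 <- scalar_maps(array(lam * 5, c(nrow(lam), 1, 1, 3)))
  expect_equal(sm5$fa, sm$fa, tolerance = 1e-12)
  expect_equal(sm5$md, sm$md * 5, tolerance = 1e-12)
  expect_equal(sm5$ad, sm$ad * 5, tolerance = 1e-12)
  expect_equal(sm5$rd, sm$rd * 5, tolerance = 1e-12)
})

test_that("tensor volumes survive a NIfTI round trip", {
  set.seed(41)
  D <- array(rnorm(2 * 2 * 2 * 6, 7e-4, 1e-4), c(2, 2, 2, 6))
  tv <- tensor_volume(D, voxel_size_mm = c(2, 2, 4.2))
  path <- withr::local_tempfile(fileext = ".nii.gz")
  write_tensor_nifti(tv, path)
  tv2 <- read_tensor_nifti(path)
  expect_equal(tv2$D, tv$D, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(tv2$voxel_size_mm, tv$voxel_size_mm, tolerance = 1e-6,
    ignore_attr = TRUE)
})
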