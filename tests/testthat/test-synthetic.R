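test_that("phantom configuration rejects overlapping or out-of-grid regions", {
  expect_error(
    phantom_config(regions = list(
      proj_left = c(6, 12, 6, 12, 13, 19),
      proj_right = c(10, 16, 6, 12, 13, 19), # overlaps proj_left
      assoc_left = c(6, 12, 21, 27, 13, 19),
      assoc_right = c(21, 27, 21, 27, 13, 19)
    )),
    "overlap"
  )
  expect_error(
    phantom_config(regions = list(
      proj_left = c(6, 40, 6, 12, 13, 19),
      proj_right = c(21, 27, 6, 12, 13, 19),
      assoc_left = c(6, 12, 21, 27, 13, 19),
      assoc_right = c(21, 27, 21, 27, 13, 19)
    )),
    "invalid|outside"
  )
})

test_that("phantom generation is a pure function of (g, config, seed)", {
  cfg <- phantom_config()
  a <- generate_phantom_dwi(1.4, cfg, seed = 5)
  b <- generate_phantom_dwi(1.4, cfg, seed = 5)
  expect_identical(a$dwi, b$dwi)
  c <- generate_phantom_dwi(1.4, cfg, seed = 6)
  expect_false(identical(a$dwi, c$dwi))
})

test_that("noise-free pipeline reproduces the analytic index; isotropic gives 1", {
  # fully isotropic regions: lambda_axial = lambda_perp and g = 1
  iso <- phantom_config(
    lambda_axial = 0.4e-3, lambda_perp = 0.4e-3,
    background_d = 0.4e-3, noise_model = "none"
  )
  ph <- generate_phantom_dwi(1, iso)
  fit <- fit_tensor(ph$dwi, ph$gtab, iso$voxel_size_mm)
  res <- alps_from_tensors(fit, ph$rois)
  expect_equal(res$alps, 1, tolerance = 1e-10)

  # anisotropic fibers at several glymphatic levels
  cfg <- phantom_config(noise_model = "none")
  for (g in c(0.9, 1.2, 1.6)) {
    ph <- generate_phantom_dwi(g, cfg)
    expect_equal(ph$alps_analytic, g, tolerance = 1e-12)
    fit <- fit_tensor(ph$dwi, ph$gtab, cfg$voxel_size_mm)
    res <- alps_from_tensors(fit, ph$rois)
    expect_equal(res$alps, ph$alps_analytic, tolerance = 1e-10)
    expect_equal(res$alps_left, res$alps_right, tolerance = 1e-10)
  }
})

test_that("the analytic index increases strictly with the glymphatic level", {
  cfg <- phantom_config()
  g <- seq(0.5, 2, by = 0.25)
  expect_true(all(diff(phantom_analytic_alps(cfg, g)) > 0))
  # HC-style aging contrast: lower g at older age maps to lower index
  expect_lt(phantom_analytic_alps(cfg, 1.2), phantom_analytic_alps(cfg, 1.5))
})

test_that("noisy pipeline estimates fall within the delta-method error band", {
  cfg <- phantom_config() # gaussian noise, sd 15
  g <- 1.4
  se <- predict_alps_se(cfg, g)
  expect_gt(se, 0)
  devs <- vapply(1:12, function(s) {
    ph <- generate_phantom_dwi(g, cfg, seed = 100 + s)
    fit <- fit_tensor(ph$dwi, ph$gtab, cfg$voxel_size_mm)
    alps_from_tensors(fit, ph$rois)$alps - g
  }, numeric(1))
  # individually within 3 SE for at least 11/12; empirical SD near prediction
  expect_gte(sum(abs(devs) <= 3 * se), 11L)
  expect_lt(sd(devs) / se, 2.5)
  expect_gt(sd(devs) / se, 0.4)
})

test_that("cohort generation is seeded, sized, and carries the configured structure", {
  cfg <- cohort_config()
  a <- generate_cohort(cfg, seed = 4)
  b <- generate_cohort(cfg, seed = 4)
  expect_identical(a, b)
  expect_identical(nrow(a), 145L)
  expect_identical(sum(a$group == "hc"), 45L)
  expect_identical(sum(a$group == "hiv"), 100L)
  expect_true(all(a$age >= 20 & a$age <= 70))
  expect_true(all(a$alps > 0))
  expect_true(all(cognitive_domains() %in% names(a)))
  # blood markers only meaningful in the HIV group
  expect_true(all(is.na(a$viral_load[a$group == "hc"])))
  expect_true(all(a$viral_load[a$group == "hiv"] > 0))
})

test_that("null configurations generate null effects", {
  # zero PAD offsets: group PAD difference consistent with zero
  cfg0 <- cohort_config(
    n_hc = 300, n_hiv = 300,
    pad_offsets = setNames(
      rep(0, 6),
      cohort_config()$structures
    )
  )
  co <- generate_cohort(cfg0, seed = 12)
  pads <- compute_brain_pad(co)
  d <- mean(pads$pad_left_central_operculum[co$group == "hiv"]) -
    mean(pads$pad_left_central_operculum[co$group == "hc"])
  expect_lt(abs(d), 3 * cfg0$pad_sd * sqrt(2 / 300))

  # zero T-score coupling: PAD-motor correlation centered on zero
  cfgg <- cohort_config(n_hc = 300, n_hiv = 300, tscore_coupling = 0)
  cog <- generate_cohort(cfgg, seed = 13)
  pad <- cog$pred_age_left_central_operculum - cog$age
  r <- cor(pad, cog$motor)
  expect_lt(abs(r), 3 / sqrt(600))
})

test_that("generated trajectories carry the configured group slopes", {
  cfg <- cohort_config()
  co <- generate_cohort(cfg, seed = 21)
  hc <- co[co$group == "hc", ]
  hiv <- co[co$group == "hiv", ]
  pad_hc <- hc$pred_age_left_central_operculum - hc$age
  pad_hiv <- hiv$pred_age_left_central_operculum - hiv$age
  f_hc <- fit_trajectory(pad_hc, hc$alps, kind = "brain_pad", group = "hc")
  f_hiv <- fit_trajectory(pad_hiv, hiv$alps, kind = "brain_pad", group = "hiv")
  expect_lt(abs(f_hc$slope - cfg$alps_pad_slope_hc), 3 * f_hc$slope_se)
  expect_lt(abs(f_hiv$slope - cfg$alps_pad_slope_hiv), 3 * f_hiv$slope_se)
  expect_lt(f_hc$slope, 0)
})
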