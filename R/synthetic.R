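#' Configuration of the synthetic DWI phantom
#'
#' The phantom is a small template-frame volume holding two fiber regions per
#' hemisphere at the ALPS reference slice: a projection-fiber region (axial
#' eigenvector along z, inferior-superior) and an association-fiber region
#' (axial eigenvector along y, anterior-posterior), embedded in an isotropic
#' background. A subject's glymphatic level `g` scales the x-axis (medullary
#' vein direction) diffusivity of both fiber regions, `Dxx = g * lambda_perp`,
#' so the analytic ALPS index of the phantom equals `g` exactly and increases
#' strictly with it.
#'
#' @param grid_shape Grid dimensions (default `c(32, 32, 32)`).
#' @param voxel_size_mm Voxel size in mm (default 1 mm isotropic).
#' @param regions Named list of four integer bounding boxes
#'   (`proj_left`, `proj_right`, `assoc_left`, `assoc_right`), each
#'   `c(x1, x2, y1, y2, z1, z2)` in 1-based voxel indices. Regions must be
#'   pairwise disjoint.
#' @param lambda_axial,lambda_perp Fiber-region eigenvalues along / across
#'   the fiber axis, mm^2/s (defaults 1.4e-3 and 0.4e-3, typical white-matter
#'   values).
#' @param background_d Isotropic background diffusivity (default 0.7e-3).
#' @param roi_diameter_mm ALPS ROI diameter (default 5).
#' @param noise_model `"gaussian"` (default), `"rician"` or `"none"`; noise is
#'   applied to the simulated signals.
#' @param noise_sd Signal noise SD (default 15, i.e. SNR ~ 67 on the b = 0
#'   reference).
#' @param s0 Non-diffusion-weighted signal level (default 1000).
#' @param gtab Gradient scheme; defaults to the 60-direction b = 1000 shell
#'   with 3 b = 0 references of [default_gradient_scheme()].
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(grid_shape = c(32, 32, 32),
                           voxel_size_mm = c(1, 1, 1),
                           regions = list(
                             proj_left = c(6, 12, 6, 12, 13, 19),
                             proj_right = c(21, 27, 6, 12, 13, 19),
                             assoc_left = c(6, 12, 21, 27, 13, 19),
                             assoc_right = c(21, 27, 21, 27, 13, 19)
                           ),
                           lambda_axial = 1.4e-3, lambda_perp = 0.4e-3,
                           background_d = 0.7e-3,
                           roi_diameter_mm = 5,
                           noise_model = c("gaussian", "rician", "none"),
                           noise_sd = 15, s0 = 1000,
                           gtab = default_gradient_scheme()) {
  noise_model <- match.arg(noise_model)
  grid_shape <- as.integer(grid_shape)
  stopifnot(
    length(grid_shape) == 3L, all(grid_shape >= 8L),
    length(voxel_size_mm) == 3L, all(voxel_size_mm > 0),
    lambda_axial > 0, lambda_perp > 0, background_d > 0,
    roi_diameter_mm > 0, noise_sd >= 0, s0 > 0,
    inherits(gtab, "gradient_table")
  )
  need <- c("proj_left", "proj_right", "assoc_left", "assoc_right")
  if (!setequal(names(regions), need)) {
    abort(sprintf("`regions` must be named: %s.", paste(need, collapse = ", ")))
  }
  for (nm in need) {
    b <- regions[[nm]]
    if (length(b) != 6L || any(b < 1) ||
      any(b[c(2, 4, 6)] > grid_shape) || any(b[c(1, 3, 5)] > b[c(2, 4, 6)])) {
      abort(sprintf("Region '%s' box is invalid or outside the grid.", nm))
    }
  }
  overlap1d <- function(a, b) a[1] <= b[2] && b[1] <= a[2]
  boxes <- regions[need]
  for (i in 1:3) {
    for (j in (i + 1):4) {
      a <- boxes[[i]]
      b <- boxes[[j]]
      if (overlap1d(a[1:2], b[1:2]) && overlap1d(a[3:4], b[3:4]) &&
        overlap1d(a[5:6], b[5:6])) {
        abort(sprintf(
          "Phantom regions '%s' and '%s' overlap.", need[i], need[j]
        ))
      }
    }
  }
  structure(
    list(
      grid_shape = grid_shape, voxel_size_mm = as.numeric(voxel_size_mm),
      regions = boxes, lambda_axial = lambda_axial, lambda_perp = lambda_perp,
      background_d = background_d, roi_diameter_mm = roi_diameter_mm,
      noise_model = noise_model, noise_sd = noise_sd, s0 = s0, gtab = gtab
    ),
    class = "phantom_config"
  )
}

# ROI specs at the region box centers
phantom_rois <- function(cfg) {
  ctr <- function(b) as.integer(round((b[c(1, 3, 5)] + b[c(2, 4, 6)]) / 2))
  list(
    roi_spec("proj_left", ctr(cfg$regions$proj_left), cfg$roi_diameter_mm,
      "projection", "left"),
    roi_spec("proj_right", ctr(cfg$regions$proj_right), cfg$roi_diameter_mm,
      "projection", "right"),
    roi_spec("assoc_left", ctr(cfg$regions$assoc_left), cfg$roi_diameter_mm,
      "association", "left"),
    roi_spec("assoc_right", ctr(cfg$regions$assoc_right), cfg$roi_diameter_mm,
      "association", "right")
  )
}

# the three distinct phantom tensors as 6-vectors (Dxx, Dyy, Dzz, 0, 0, 0)
phantom_tensors6 <- function(cfg, g) {
  list(
    background = c(rep(cfg$background_d, 3), 0, 0, 0),
    projection = c(g * cfg$lambda_perp, cfg$lambda_perp, cfg$lambda_axial, 0, 0, 0),
    association = c(g * cfg$lambda_perp, cfg$lambda_axial, cfg$lambda_perp, 0, 0, 0)
  )
}

#' Analytic ALPS index of a phantom
#'
#' The noise-free ALPS index implied by the phantom's region tensors for a
#' subject at glymphatic level `g`. With the default parameterization
#' (`Dxx = g * lambda_perp` in both fiber regions) this equals `g`.
#'
#' @param cfg A [phantom_config].
#' @param g Glymphatic level(s), > 0.
#' @return Numeric, same length as `g`.
#' @export
phantom_analytic_alps <- function(cfg, g) {
  stopifnot(inherits(cfg, "phantom_config"), all(g > 0))
  vapply(g, function(gi) {
    tn <- phantom_tensors6(cfg, gi)
    compute_alps(
      dx_proj = tn$projection[1], dx_assoc = tn$association[1],
      dy_proj = tn$projection[2], dz_assoc = tn$association[3]
    )
  }, numeric(1))
}

#' Generate a synthetic DWI phantom for one subject
#'
#' Builds the true tensor field, forward-simulates the DWI signals with the
#' configured gradient scheme and noise model, and returns everything a
#' downstream ALPS analysis needs, plus the analytic (noise-free) index the
#' generator implies.
#'
#' @param g Subject glymphatic level (> 0); the analytic ALPS index.
#' @param cfg A [phantom_config].
#' @param seed Integer seed for the noise draws; the output is a pure
#'   function of `(g, cfg, seed)`.
#' @return List with `dwi` (4-D signal array), `gtab`, `rois` (list of four
#'   [roi_spec]), `tensors_true` ([tensor_volume]), `alps_analytic`, `seed`
#'   and `config`.
#' @export
generate_phantom_dwi <- function(g, cfg = phantom_config(), seed = 1L) {
  stopifnot(inherits(cfg, "phantom_config"), is.numeric(g), length(g) == 1L, g > 0)
  tn <- phantom_tensors6(cfg, g)
  gs <- cfg$grid_shape
  type <- array("background", dim = gs)
  for (nm in names(cfg$regions)) {
    b <- cfg$regions[[nm]]
    cls <- if (startsWith(nm, "proj")) "projection" else "association"
    type[b[1]:b[2], b[3]:b[4], b[5]:b[6]] <- cls
  }
  D <- array(0, dim = c(gs, 6L))
  Dm <- matrix(D, ncol = 6L)
  for (cls in names(tn)) {
    Dm[type == cls, ] <- matrix(tn[[cls]], nrow = sum(type == cls), ncol = 6L,
      byrow = TRUE)
  }
  tensors_true <- tensor_volume(array(Dm, c(gs, 6L)), cfg$voxel_size_mm)

  sig <- lapply(tn, function(v) {
    simulate_dwi_signal(tensor6_to_mat(v), cfg$gtab, s0 = cfg$s0)
  })
  K <- length(cfg$gtab$bvals)
  S <- matrix(0, nrow = prod(gs), ncol = K)
  for (cls in names(sig)) {
    S[type == cls, ] <- matrix(sig[[cls]], nrow = sum(type == cls), ncol = K,
      byrow = TRUE)
  }
  if (cfg$noise_model != "none" && cfg$noise_sd > 0) {
    S <- withr::with_seed(seed, {
      if (cfg$noise_model == "gaussian") {
        S + matrix(rnorm(length(S), 0, cfg$noise_sd), nrow = nrow(S))
      } else {
        # Rician: magnitude of complex signal with iid Gaussian noise per channel
        n1 <- matrix(rnorm(length(S), 0, cfg$noise_sd), nrow = nrow(S))
        n2 <- matrix(rnorm(length(S), 0, cfg$noise_sd), nrow = nrow(S))
        sqrt((S + n1)^2 + n2^2)
      }
    })
  }
  list(
    dwi = array(S, dim = c(gs, K)),
    gtab = cfg$gtab,
    rois = phantom_rois(cfg),
    tensors_true = tensors_true,
    alps_analytic = phantom_analytic_alps(cfg, g),
    seed = as.integer(seed),
    config = cfg
  )
}

#' Predicted standard error of the phantom-pipeline ALPS index
#'
#' First-order (delta-method) propagation of Gaussian signal noise through
#' the log-linear tensor fit, the ROI averages and the ALPS ratio, for a
#' phantom at glymphatic level `g`. Valid for the `"gaussian"` noise model at
#' reasonable SNR (noise SD well below the diffusion-weighted signal).
#'
#' @param cfg A [phantom_config].
#' @param g Glymphatic level.
#' @return Predicted SE of the bilateral-mean ALPS index (0 when noise is
#'   off).
#' @export
predict_alps_se <- function(cfg, g) {
  stopifnot(inherits(cfg, "phantom_config"), g > 0)
  if (cfg$noise_model == "none" || cfg$noise_sd == 0) {
    return(0)
  }
  X <- tensor_design_matrix(cfg$gtab)
  A <- solve(crossprod(X), t(X)) # 7 x K
  tn <- phantom_tensors6(cfg, g)
  covD <- lapply(tn[c("projection", "association")], function(v) {
    S <- simulate_dwi_signal(tensor6_to_mat(v), cfg$gtab, s0 = cfg$s0)
    # var(log S) ~ sd^2 / S^2 per volume
    A %*% (t(A) * (cfg$noise_sd^2 / S^2))
  })
  n_roi <- sum(make_spherical_roi(
    roi_spec("tmp", pmax(2L, cfg$grid_shape %/% 2L), cfg$roi_diameter_mm),
    cfg$voxel_size_mm, cfg$grid_shape
  ))
  # component indices in the 7-row coefficient vector: 1 logS0, 2 Dxx, 3 Dyy, 4 Dzz
  Cp <- covD$projection / n_roi
  Ca <- covD$association / n_roi
  num <- (tn$projection[1] + tn$association[1]) / 2
  den <- (tn$projection[2] + tn$association[3]) / 2
  v_num <- (Cp[2, 2] + Ca[2, 2]) / 4
  v_den <- (Cp[3, 3] + Ca[4, 4]) / 4
  cov_nd <- (Cp[2, 3] + Ca[2, 4]) / 4
  var_one_hemi <- (1 / den^2) * v_num + (num^2 / den^4) * v_den -
    2 * (num / den^3) * cov_nd
  # the two hemispheres are independent ROI sets; the bilateral mean halves the variance
  sqrt(var_one_hemi / 2)
}

#' Configuration of the synthetic cohort generator
#'
#' Emulates the statistical structure the trajectory analysis assumes: a
#' healthy-control group whose ALPS index declines with age and with the
#' brain-PAD of a coupling structure, and an HIV group with a lower, flat
#' ALPS level, positive per-structure PAD offsets, and negative PAD-to-motor
#' (and executive) T-score coupling.
#'
#' @param n_hc,n_hiv Group sizes (defaults 45 and 100, the study design).
#' @param age_range Chronological-age range in years, sampled uniformly
#'   (default 20-70).
#' @param structures Character vector of structure labels (snake-case; they
#'   become `pred_age_<structure>` columns).
#' @param pad_offsets Named numeric, per-structure predicted-age offset
#'   (years) applied to the HIV group; defaults to +3 on the four
#'   operculum/inferior-frontal structures and 0 elsewhere.
#' @param pad_sd Between-subject SD of the predicted-age error (years,
#'   default 6.5).
#' @param coupling_structure The structure whose PAD drives the ALPS index
#'   and the motor/executive T-scores.
#' @param alps_intercept_hc,alps_intercept_hiv ALPS level at the reference
#'   age (45 y) and PAD 0.
#' @param alps_age_slope_hc,alps_age_slope_hiv ALPS change per year of
#'   chronological age (defaults -0.004 and 0).
#' @param alps_pad_slope_hc,alps_pad_slope_hiv ALPS change per year of
#'   coupling-structure PAD (defaults -0.04 and 0).
#' @param alps_noise_sd Residual ALPS SD (default 0.12).
#' @param tscore_coupling T-score points lost per year of coupling-structure
#'   PAD in the motor and abstract/executive domains (default 0.45).
#' @param tscore_sd Residual T-score SD (default 10).
#' @param functional_impaired_prob Named probabilities (hc, hiv) that
#'   everyday functioning is self-reported impaired.
#' @param seed Default seed used by [generate_cohort()].
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_hc = 45, n_hiv = 100,
                          age_range = c(20, 70),
                          structures = c(
                            "left_central_operculum",
                            "left_frontal_operculum",
                            "left_opercular_inf_frontal_gyrus",
                            "left_triangular_inf_frontal_gyrus",
                            "left_thalamus",
                            "right_frontal_pole"
                          ),
                          pad_offsets = NULL,
                          pad_sd = 6.5,
                          coupling_structure = "left_central_operculum",
                          alps_intercept_hc = 1.45,
                          alps_intercept_hiv = 1.38,
                          alps_age_slope_hc = -0.004,
                          alps_age_slope_hiv = 0,
                          alps_pad_slope_hc = -0.04,
                          alps_pad_slope_hiv = 0,
                          alps_noise_sd = 0.12,
                          tscore_coupling = 0.45,
                          tscore_sd = 10,
                          functional_impaired_prob = c(hc = 0.02, hiv = 0.10),
                          seed = 1L) {
  if (is.null(pad_offsets)) {
    pad_offsets <- setNames(
      ifelse(grepl("operculum|frontal_gyrus", structures), 3, 0), structures
    )
  }
  if (!setequal(names(pad_offsets), structures)) {
    abort("`pad_offsets` must be named by the structure labels.")
  }
  stopifnot(
    n_hc >= 3, n_hiv >= 3, length(age_range) == 2L, age_range[1] < age_range[2],
    pad_sd >= 0, alps_noise_sd >= 0, tscore_sd >= 0, tscore_coupling >= 0,
    coupling_structure %in% structures,
    all(functional_impaired_prob >= 0 & functional_impaired_prob <= 1)
  )
  structure(
    list(
      n_hc = as.integer(n_hc), n_hiv = as.integer(n_hiv),
      age_range = as.numeric(age_range), structures = structures,
      pad_offsets = pad_offsets[structures], pad_sd = pad_sd,
      coupling_structure = coupling_structure,
      alps_intercept_hc = alps_intercept_hc,
      alps_intercept_hiv = alps_intercept_hiv,
      alps_age_slope_hc = alps_age_slope_hc,
      alps_age_slope_hiv = alps_age_slope_hiv,
      alps_pad_slope_hc = alps_pad_slope_hc,
      alps_pad_slope_hiv = alps_pad_slope_hiv,
      alps_noise_sd = alps_noise_sd,
      tscore_coupling = tscore_coupling, tscore_sd = tscore_sd,
      functional_impaired_prob = functional_impaired_prob,
      age_ref = 45,
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

#' Generate a synthetic subject cohort
#'
#' Draws a full subject table from the seeded generator: demographics,
#' per-structure predicted ages, the ALPS glymphatic index, six cognitive
#' domain T-scores, functional status and clinical markers (viral load in
#' copies/ml, CD4 count, CD4/CD8 ratio; blood markers are HIV-group only).
#' All draws are a pure function of `(cfg, seed)`.
#'
#' @param cfg A [cohort_config].
#' @param seed Integer seed (defaults to `cfg$seed`).
#' @return A tibble with one row per subject; the generating config is
#'   attached as attribute `"config"`.
#' @export
generate_cohort <- function(cfg = cohort_config(), seed = cfg$seed) {
  stopifnot(inherits(cfg, "cohort_config"))
  n <- cfg$n_hc + cfg$n_hiv
  group <- rep(c("hc", "hiv"), c(cfg$n_hc, cfg$n_hiv))
  withr::with_seed(seed, {
    age <- runif(n, cfg$age_range[1], cfg$age_range[2])
    sex <- ifelse(rbinom(n, 1, 0.5) == 1, "male", "female")
    hiv <- group == "hiv"

    pred <- lapply(cfg$structures, function(s) {
      age + cfg$pad_offsets[[s]] * hiv + rnorm(n, 0, cfg$pad_sd)
    })
    names(pred) <- paste0("pred_age_", cfg$structures)
    pred_age_global <- age + mean(cfg$pad_offsets) * hiv + rnorm(n, 0, 2)

    pad_cpl <- pred[[paste0("pred_age_", cfg$coupling_structure)]] - age
    alps <- ifelse(hiv,
      cfg$alps_intercept_hiv + cfg$alps_age_slope_hiv * (age - cfg$age_ref) +
        cfg$alps_pad_slope_hiv * pad_cpl,
      cfg$alps_intercept_hc + cfg$alps_age_slope_hc * (age - cfg$age_ref) +
        cfg$alps_pad_slope_hc * pad_cpl
    ) + rnorm(n, 0, cfg$alps_noise_sd)
    if (any(alps <= 0)) {
      abort("Cohort config produced nonpositive ALPS values; check effect sizes.")
    }

    doms <- cognitive_domains()
    tsc <- lapply(doms, function(d) {
      base <- 50 + rnorm(n, 0, cfg$tscore_sd)
      if (d %in% c("motor", "abstract_executive")) {
        base - cfg$tscore_coupling * pad_cpl
      } else {
        base
      }
    })
    names(tsc) <- doms
    functional_status <- ifelse(
      runif(n) < cfg$functional_impaired_prob[ifelse(hiv, "hiv", "hc")],
      "impaired", "intact"
    )

    viral_load <- ifelse(hiv, rlnorm(n, log(1000), 1.5), NA_real_)
    cd4 <- pmax(50, rnorm(n, ifelse(hiv, 550, 900), ifelse(hiv, 200, 250)))
    cd4_cd8_ratio <- rlnorm(n, ifelse(hiv, log(0.8), log(1.5)),
      ifelse(hiv, 0.4, 0.3))

    out <- dplyr::bind_cols(
      tibble::tibble(
        subject_id = sprintf("S%03d", seq_len(n)),
        group = group, age = age, sex = sex
      ),
      tibble::as_tibble(pred),
      tibble::tibble(pred_age_global = pred_age_global, alps = alps),
      tibble::as_tibble(tsc),
      tibble::tibble(
        functional_status = functional_status,
        viral_load = viral_load, cd4 = cd4, cd4_cd8_ratio = cd4_cd8_ratio
      )
    )
    attr(out, "config") <- cfg
    out
  })
}
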