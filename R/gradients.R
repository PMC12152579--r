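#' Diffusion gradient table
#'
#' Bundles the b-values and unit gradient directions of a diffusion-weighted
#' acquisition, one entry per volume. Directions of nonzero-b volumes must be
#' unit vectors; at least one b = 0 reference volume and at least six unique
#' nonzero-b directions are required so that a full tensor is identifiable.
#'
#' @param bvals Numeric vector of b-values in s/mm^2 (one per volume).
#' @param bvecs 3 x N numeric matrix of gradient directions (columns are
#'   volumes, FSL convention). Directions for b = 0 volumes may be zero.
#' @param require_fit_design If `TRUE` (default) enforce >= 6 unique nonzero-b
#'   directions and >= 1 reference volume, the preconditions for tensor
#'   fitting. Set to `FALSE` to hold partial schemes while assembling one.
#' @return An object of class `gradient_table` with elements `bvals` and
#'   `bvecs` (3 x N matrix).
#' @examples
#' gt <- default_gradient_scheme()
#' gt
#' @export
gradient_table <- function(bvals, bvecs, require_fit_design = TRUE) {
  bvals <- as.numeric(bvals)
  bvecs <- as.matrix(bvecs)
  if (nrow(bvecs) != 3L) {
    abort("`bvecs` must be a 3 x N matrix (directions in columns).")
  }
  if (length(bvals) != ncol(bvecs)) {
    abort(sprintf(
      "Length mismatch: %d b-values but %d direction columns.",
      length(bvals), ncol(bvecs)
    ))
  }
  if (any(!is.finite(bvals)) || any(bvals < 0)) {
    abort("All b-values must be finite and nonnegative.")
  }
  nz <- bvals > 0
  if (any(nz)) {
    norms <- sqrt(colSums(bvecs[, nz, drop = FALSE]^2))
    if (any(abs(norms - 1) > 1e-6)) {
      abort("Every nonzero-b direction must be a unit vector (|norm - 1| <= 1e-6).")
    }
  }
  if (require_fit_design) {
    if (!any(!nz)) {
      abort("Gradient table has no b = 0 reference volume.")
    }
    if (n_unique_directions(bvals, bvecs) < 6L) {
      abort("Tensor fitting needs at least 6 unique nonzero-b gradient directions.")
    }
  }
  structure(list(bvals = bvals, bvecs = bvecs), class = "gradient_table")
}

# Unique nonzero-b directions, identifying v with -v (they give the same
# b-matrix row).
n_unique_directions <- function(bvals, bvecs) {
  nz <- which(bvals > 0)
  if (!length(nz)) {
    return(0L)
  }
  v <- round(bvecs[, nz, drop = FALSE], 6)
  # canonical sign: first nonzero component positive
  for (j in seq_len(ncol(v))) {
    k <- which(v[, j] != 0)[1]
    if (!is.na(k) && v[k, j] < 0) v[, j] <- -v[, j]
  }
  nrow(unique(t(v)))
}

#' @export
print.gradient_table <- function(x, ...) {
  nb0 <- sum(x$bvals == 0)
  cat(sprintf(
    "<gradient_table> %d volumes: %d b=0 reference(s), %d diffusion-weighted (b in [%g, %g] s/mm^2)\n",
    length(x$bvals), nb0, length(x$bvals) - nb0,
    if (any(x$bvals > 0)) min(x$bvals[x$bvals > 0]) else NA,
    suppressWarnings(max(x$bvals))
  ))
  invisible(x)
}

#' Default diffusion-encoding scheme
#'
#' A deterministic 60-direction single-shell scheme at b = 1000 s/mm^2 plus
#' three b = 0 reference volumes, mirroring a common clinical DTI protocol.
#' Directions are spread on the sphere with a golden-angle (Fibonacci) spiral,
#' so the scheme is reproducible without a random seed.
#'
#' @param n_directions Number of diffusion-weighted directions (default 60).
#' @param bval Shell b-value in s/mm^2 (default 1000).
#' @param n_b0 Number of b = 0 reference volumes (default 3), placed first.
#' @return A [gradient_table].
#' @export
default_gradient_scheme <- function(n_directions = 60, bval = 1000, n_b0 = 3) {
  stopifnot(n_directions >= 6, n_b0 >= 1, bval > 0)
  i <- seq_len(n_directions) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n_directions
  r <- sqrt(pmax(0, 1 - z^2))
  dirs <- rbind(r * cos(phi), r * sin(phi), z)
  dirs <- sweep(dirs, 2, sqrt(colSums(dirs^2)), "/")
  gradient_table(
    bvals = c(rep(0, n_b0), rep(bval, n_directions)),
    bvecs = cbind(matrix(0, 3, n_b0), dirs)
  )
}

#' Read an FSL-style bval/bvec pair
#'
#' Reads whitespace-delimited `.bval` (one row of b-values) and `.bvec`
#' (three rows of direction components) text files.
#'
#' @param bval_path,bvec_path Paths to the text files.
#' @param require_fit_design Passed to [gradient_table()].
#' @return A [gradient_table].
#' @export
read_bvals_bvecs <- function(bval_path, bvec_path, require_fit_design = TRUE) {
  bvals <- scan(bval_path, quiet = TRUE)
  bv <- scan(bvec_path, quiet = TRUE)
  if (length(bv) != 3L * length(bvals)) {
    abort(sprintf(
      "bvec file holds %d numbers; expected 3 x %d to match the bval file.",
      length(bv), length(bvals)
    ))
  }
  gradient_table(bvals, matrix(bv, nrow = 3, byrow = TRUE),
    require_fit_design = require_fit_design
  )
}

#' Write an FSL-style bval/bvec pair
#'
#' @param gtab A [gradient_table].
#' @param bval_path,bvec_path Output paths.
#' @return Invisibly, `c(bval_path, bvec_path)`.
#' @export
write_bvals_bvecs <- function(gtab, bval_path, bvec_path) {
  stopifnot(inherits(gtab, "gradient_table"))
  writeLines(paste(format(gtab$bvals, trim = TRUE, scientific = FALSE),
    collapse = " "
  ), bval_path)
  writeLines(apply(gtab$bvecs, 1, function(row) {
    paste(format(row, trim = TRUE, digits = 10), collapse = " ")
  }), bvec_path)
  invisible(c(bval_path, bvec_path))
}
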