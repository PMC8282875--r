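#' Phantom specification
#'
#' Describes a synthetic TPEF slice: bright speckled cytoplasm of deformed
#' elliptic cells, dark near-circular nuclei fully or partially enclosed by
#' cytoplasm, a dark granular intercellular matrix, radial shading toward
#' the image edges, and optional additive Gaussian noise. Defaults emulate a
#' stratum-spinosum-like slice at 0.39 um/px: cell radii 25-40 px
#' (~20-31 um diameter), nuclei 35-55% of the cell radius, and a
#' nucleus/cytoplasm contrast of ~105 grey levels.
#'
#' @param shape_px image size (rows, cols), default 512 x 512.
#' @param n_cells number of cells, default 12.
#' @param cell_radius_px range of base cell radii in pixels.
#' @param nucleus_radius_fraction range of nucleus radius as a fraction of
#'   the cell radius.
#' @param matrix_mean,cytoplasm_mean,nucleus_mean class mean intensities;
#'   nuclei and matrix must be darker than cytoplasm.
#' @param speckle_strength relative sd of the multiplicative granularity
#'   field (smoothed at ~2 px) applied to cytoplasm and matrix.
#' @param shading_strength maximal relative signal drop at the image
#'   corners (cosine-squared radial falloff).
#' @param noise list with `mu`, `sigma` (additive Gaussian noise) and
#'   optional `seed`.
#' @param open_boundary_fraction fraction of cells rendered with a broken
#'   cytoplasm wedge so the nucleus touches the matrix; those objects are
#'   flagged uncertain.
#' @param seed RNG seed controlling everything.
#' @return an `msm_phantom_spec` list.
#' @export
phantom_spec <- function(shape_px = c(512L, 512L),
                         n_cells = 12L,
                         cell_radius_px = c(25, 40),
                         nucleus_radius_fraction = c(0.35, 0.55),
                         matrix_mean = 70,
                         cytoplasm_mean = 150,
                         nucleus_mean = 45,
                         speckle_strength = 0.12,
                         shading_strength = 0.2,
                         noise = list(mu = 0, sigma = 0),
                         open_boundary_fraction = 0.2,
                         seed = 1L) {
  spec <- list(shape_px = as.integer(shape_px), n_cells = as.integer(n_cells),
               cell_radius_px = as.numeric(cell_radius_px),
               nucleus_radius_fraction = as.numeric(nucleus_radius_fraction),
               matrix_mean = matrix_mean, cytoplasm_mean = cytoplasm_mean,
               nucleus_mean = nucleus_mean,
               speckle_strength = speckle_strength,
               shading_strength = shading_strength,
               noise = noise,
               open_boundary_fraction = open_boundary_fraction,
               seed = as.integer(seed))
  validate_phantom_spec(spec)
  structure(spec, class = "msm_phantom_spec")
}

validate_phantom_spec <- function(s) {
  lv <- c(s$matrix_mean, s$cytoplasm_mean, s$nucleus_mean)
  if (any(lv < 0 | lv > 255)) stop("class intensities must lie in [0, 255]")
  if (!(s$nucleus_mean < s$cytoplasm_mean))
    stop("nucleus_mean must be below cytoplasm_mean")
  if (!(s$matrix_mean < s$cytoplasm_mean))
    stop("matrix_mean must be below cytoplasm_mean")
  if (any(s$nucleus_radius_fraction >= 1))
    stop("nucleus_radius_fraction must be < 1")
  if (s$open_boundary_fraction < 0 || s$open_boundary_fraction > 1)
    stop("open_boundary_fraction must lie in [0, 1]")
  invisible(s)
}

# Smoothed unit-variance Gaussian random field.
smooth_field <- function(nr, nc, sigma = 2) {
  f <- gaussian_smooth(matrix(stats::rnorm(nr * nc), nr, nc), sigma)
  f / stats::sd(f)
}

#' Generate a synthetic phantom slice with ground truth
#'
#' Fully determined by `spec$seed`: identical spec and seed give a
#' bit-identical image and ground truth.
#'
#' @param spec an `msm_phantom_spec` (or arguments for [phantom_spec()]).
#' @return list with `image` ([slice()]), and `gt`: list with
#'   `nucleus_labels`, `cell_labels` (integer label maps, 0 = none; cell
#'   labels include the nucleus pixels) and `certainty` (named
#'   `"certain"`/`"uncertain"` per object).
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  if (!inherits(spec, "msm_phantom_spec")) spec <- do.call(phantom_spec, spec)
  nr <- spec$shape_px[1L]; nc <- spec$shape_px[2L]
  with_seed(spec$seed, {
    n <- spec$n_cells
    rads <- stats::runif(n, spec$cell_radius_px[1L], spec$cell_radius_px[2L])
    # non-overlapping placement by rejection sampling
    centers <- matrix(NA_real_, n, 2L)
    for (i in seq_len(n)) {
      margin <- rads[i] + 8
      if (2 * margin >= min(nr, nc))
        stop("infeasible packing: cells too large for the image")
      ok <- FALSE
      for (try in seq_len(400L)) {
        cy <- stats::runif(1, margin, nr - margin)
        cx <- stats::runif(1, margin, nc - margin)
        if (i == 1L) { ok <- TRUE }
        else {
          dd <- sqrt((centers[seq_len(i - 1L), 1L] - cy)^2 +
                     (centers[seq_len(i - 1L), 2L] - cx)^2)
          ok <- all(dd > rads[seq_len(i - 1L)] + rads[i] + 6)
        }
        if (ok) break
      }
      if (!ok) stop("infeasible packing: could not place all cells")
      centers[i, ] <- c(cy, cx)
    }

    nuc_lab <- matrix(0L, nr, nc)
    cell_lab <- matrix(0L, nr, nc)
    n_open <- round(spec$open_boundary_fraction * n)
    open_cells <- if (n_open > 0) sample.int(n, n_open) else integer(0)

    for (i in seq_len(n)) {
      r0 <- rads[i]
      a1 <- stats::runif(1, 0, 0.15); p1 <- stats::runif(1, 0, 2 * pi)
      a2 <- stats::runif(1, 0, 0.08); p2 <- stats::runif(1, 0, 2 * pi)
      fn <- stats::runif(1, spec$nucleus_radius_fraction[1L],
                         spec$nucleus_radius_fraction[2L])
      rn <- fn * r0
      odir <- stats::runif(1, 0, 2 * pi)
      omag <- stats::runif(1, 0, 0.25 * (r0 * 0.77 - rn))
      omag <- max(omag, 0)
      ny <- centers[i, 1L] + omag * sin(odir)
      nx <- centers[i, 2L] + omag * cos(odir)
      wedge <- i %in% open_cells
      wpsi <- stats::runif(1, 0, 2 * pi)
      wwid <- stats::runif(1, 40, 80) * pi / 180

      rmax <- ceiling(r0 * 1.25)
      ys <- max(1L, floor(centers[i, 1L] - rmax)):min(nr, ceiling(centers[i, 1L] + rmax))
      xs <- max(1L, floor(centers[i, 2L] - rmax)):min(nc, ceiling(centers[i, 2L] + rmax))
      dy <- outer(ys - centers[i, 1L], rep(1, length(xs)))
      dx <- outer(rep(1, length(ys)), xs - centers[i, 2L])
      th <- atan2(dy, dx)
      rr <- sqrt(dy^2 + dx^2)
      rcell <- r0 * (1 + a1 * cos(2 * th + p1) + a2 * cos(3 * th + p2))
      inside <- rr <= rcell
      dn <- sqrt((outer(ys - ny, rep(1, length(xs))))^2 +
                 (outer(rep(1, length(ys)), xs - nx))^2)
      in_nuc <- dn <= rn
      if (wedge) {
        adiff <- atan2(sin(th - wpsi), cos(th - wpsi))
        cut <- abs(adiff) < wwid / 2 & !in_nuc
        inside <- inside & !cut
      }
      sub_cell <- cell_lab[ys, xs]
      sub_cell[inside] <- i
      cell_lab[ys, xs] <- sub_cell
      sub_nuc <- nuc_lab[ys, xs]
      sub_nuc[in_nuc & inside | in_nuc] <- i
      nuc_lab[ys, xs] <- sub_nuc
      # the nucleus always belongs to its cell
      sub_cell <- cell_lab[ys, xs]
      sub_cell[in_nuc] <- i
      cell_lab[ys, xs] <- sub_cell
    }

    cyto <- cell_lab > 0L & nuc_lab == 0L
    nucm <- nuc_lab > 0L

    img <- spec$matrix_mean * (1 + spec$speckle_strength * smooth_field(nr, nc))
    fcy <- spec$cytoplasm_mean *
      (1 + spec$speckle_strength * smooth_field(nr, nc))
    img[cyto] <- fcy[cyto]
    img[nucm] <- spec$nucleus_mean

    # radial shading: cosine-squared falloff, strongest at the corners
    yy <- (seq_len(nr) - (nr + 1) / 2) / (nr / 2)
    xx <- (seq_len(nc) - (nc + 1) / 2) / (nc / 2)
    rho <- sqrt(outer(yy^2, rep(1, nc)) + outer(rep(1, nr), xx^2)) / sqrt(2)
    img <- img * (1 - spec$shading_strength * sin(pmin(rho, 1) * pi / 2)^2)
    img <- clip255(round(img))

    if ((spec$noise$sigma %||% 0) > 0 || (spec$noise$mu %||% 0) != 0) {
      nz <- add_noise_and_psnr(img, spec$noise$sigma %||% 0,
                               spec$noise$mu %||% 0,
                               seed = spec$noise$seed %||% spec$seed)
      img <- nz$noisy
    }

    certainty <- stats::setNames(rep("certain", n), seq_len(n))
    certainty[as.character(open_cells)] <- "uncertain"
    list(image = slice(img),
         gt = list(nucleus_labels = nuc_lab, cell_labels = cell_lab,
                   certainty = certainty),
         spec = spec)
  })
}

#' Depth series of phantoms
#'
#' Emulates the depth-dependent data characteristics: cell radii shrink by
#' `size_decay` per slice and the class contrast against the matrix is
#' reduced linearly by `contrast_decay` per slice.
#'
#' @param base_spec `msm_phantom_spec` of the first slice.
#' @param n_slices number of slices.
#' @param size_decay multiplicative radius decay per slice in (0, 1\].
#' @param contrast_decay linear contrast reduction per slice (default 0.1).
#' @return list of `generate_phantom()` results.
#' @export
depth_series <- function(base_spec = phantom_spec(), n_slices = 3L,
                         size_decay = 0.85, contrast_decay = 0.1) {
  if (!(size_decay > 0 && size_decay <= 1))
    stop("size_decay must lie in (0, 1]")
  out <- vector("list", n_slices)
  for (k in seq_len(n_slices)) {
    sc <- size_decay^(k - 1)
    cs <- max(1 - (k - 1) * contrast_decay, 0.05)
    radii <- base_spec$cell_radius_px * sc
    if (min(radii * min(base_spec$nucleus_radius_fraction)) < 3)
      stop(sprintf("slice %d: nucleus radii fall below 3 px", k))
    s <- base_spec
    s$cell_radius_px <- radii
    s$cytoplasm_mean <- base_spec$matrix_mean +
      (base_spec$cytoplasm_mean - base_spec$matrix_mean) * cs
    s$nucleus_mean <- base_spec$matrix_mean +
      (base_spec$nucleus_mean - base_spec$matrix_mean) * cs
    s$seed <- base_spec$seed + k - 1L
    class(s) <- "msm_phantom_spec"
    validate_phantom_spec(s)
    out[[k]] <- generate_phantom(s)
    attr(out[[k]]$image, "depth_um") <- k
  }
  out
}
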