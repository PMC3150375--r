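#' Synthetic colony scenes with exact ground truth
#'
#' Generates phase-contrast-like and fluorescence-like image pairs of
#' adherent stem-cell colonies in a perfusion chamber, with exact pixel
#' masks. Colonies are rotated ellipses with a low-order Fourier wobble on
#' the boundary, which reproduces the lobed outline of mESC colonies without
#' any cell-level growth model. The generator is a pure function of
#' (seed, parameters): the same seed gives bit-identical output.
#'
#' @name synthetic-imaging
NULL

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Render specification for synthetic micrographs
#'
#' Intensity model for the phase channel: mid-grey background, slightly
#' brighter textured colony interior, and a bright rim (the phase halo) that
#' the downstream bright-feature segmentation keys on.
#'
#' @param background_level,interior_level,rim_level normalized intensities in
#'   [0, 1]; the rim must be brighter than the background.
#' @param rim_width halo width (px).
#' @param noise_sigma additive Gaussian noise sd (normalized units).
#' @param bit_depth 8 or 16; images are quantized to this depth so that
#'   write/read round-trips are exact.
#' @return an object of class `render_spec`.
#' @export
render_spec <- function(background_level = 0.45, interior_level = 0.52,
                        rim_level = 0.8, rim_width = 3, noise_sigma = 0.02,
                        bit_depth = 16) {
  lv <- c(background_level, interior_level, rim_level)
  if (any(lv < 0 | lv > 1)) stop_invalid("intensity levels must lie in [0, 1]")
  if (rim_level <= background_level) {
    stop_invalid("rim must be brighter than background (phase halo)")
  }
  if (!bit_depth %in% c(8, 16)) stop_invalid("bit_depth must be 8 or 16")
  structure(list(background_level = background_level,
                 interior_level = interior_level, rim_level = rim_level,
                 rim_width = rim_width, noise_sigma = noise_sigma,
                 bit_depth = bit_depth), class = "render_spec")
}

# Signed radial geometry of one colony: for every pixel, distance from the
# colony centre and the boundary radius along that direction (ellipse with
# Fourier wobble). Returns masks restricted to the colony's bounding box.
colony_masks <- function(colony, shape, rim_width = 0) {
  a <- colony$a; b <- colony$b
  rmax <- max(a, b) * (1 + sum(abs(colony$wobble_amp))) + 1
  r0 <- max(1, floor(colony$center[1] - rmax)); r1 <- min(shape[1], ceiling(colony$center[1] + rmax))
  c0 <- max(1, floor(colony$center[2] - rmax)); c1 <- min(shape[2], ceiling(colony$center[2] + rmax))
  if (r0 > r1 || c0 > c1) {
    return(list(rows = integer(0), cols = integer(0),
                inside = matrix(FALSE, 0, 0), rim = matrix(FALSE, 0, 0)))
  }
  ri <- r0:r1; ci <- c0:c1
  dy <- matrix(ri - colony$center[1], nrow = length(ri), ncol = length(ci))
  dx <- matrix(ci - colony$center[2], nrow = length(ri), ncol = length(ci), byrow = TRUE)
  ct <- cos(colony$theta); st <- sin(colony$theta)
  xr <- dx * ct + dy * st
  yr <- -dx * st + dy * ct
  d <- sqrt(xr^2 + yr^2)
  phi <- atan2(yr, xr)
  r_ell <- a * b / sqrt((b * cos(phi))^2 + (a * sin(phi))^2)
  wob <- 0
  if (length(colony$wobble_amp)) {
    for (k in seq_along(colony$wobble_amp)) {
      wob <- wob + colony$wobble_amp[k] *
        cos((k + 1) * phi + colony$wobble_phase[k])
    }
  }
  r_eff <- r_ell * (1 + wob)
  inside <- d <= r_eff
  rim <- if (rim_width > 0) inside & (d > pmax(r_eff - rim_width, 0)) else
    matrix(FALSE, length(ri), length(ci))
  list(rows = ri, cols = ci, inside = inside, rim = rim)
}

scene_masks <- function(scene, rim_width = 0) {
  cell <- matrix(FALSE, scene$shape[1], scene$shape[2])
  rim <- matrix(FALSE, scene$shape[1], scene$shape[2])
  owner <- matrix(0L, scene$shape[1], scene$shape[2])
  for (k in seq_along(scene$colonies)) {
    cm <- colony_masks(scene$colonies[[k]], scene$shape, rim_width)
    if (!length(cm$rows)) next
    sub_new <- cm$inside & owner[cm$rows, cm$cols] == 0L
    owner[cm$rows, cm$cols][sub_new] <- k
    cell[cm$rows, cm$cols] <- cell[cm$rows, cm$cols] | cm$inside
    rim[cm$rows, cm$cols] <- rim[cm$rows, cm$cols] | cm$rim
  }
  list(cell = cell, rim = rim & cell, owner = owner)
}

scale_colonies <- function(colonies, s) {
  lapply(colonies, function(col) { col$a <- col$a * s; col$b <- col$b * s; col })
}

# Pull colony centres inward so each colony stays fully inside the frame
# (colonies spread where there is room); a colony larger than the frame is
# centred and inevitably clipped.
clamp_colonies <- function(colonies, shape) {
  lapply(colonies, function(col) {
    rmax <- max(col$a, col$b) * (1 + sum(abs(col$wobble_amp))) + 2
    for (d in 1:2) {
      lo <- rmax + 1; hi <- shape[d] - rmax
      col$center[d] <- if (lo > hi) shape[d] / 2 else min(max(col$center[d], lo), hi)
    }
    col
  })
}

apply_scale <- function(scene, s) {
  scene$colonies <- clamp_colonies(scale_colonies(scene$colonies, s), scene$shape)
  scene
}

scene_area_fraction <- function(scene) {
  mean(scene_masks(scene)$cell)
}

# Bisect a global radial scale so the union mask hits a target area fraction.
# When the target exceeds what in-frame colonies can cover, either error
# (sampling) or saturate at the largest reachable coverage (growth).
fit_scale_to_target <- function(scene, target, s_lo = 0.05, s_hi = 20,
                                rel_tol = 0.02, iters = 40,
                                on_unreachable = c("error", "saturate")) {
  on_unreachable <- match.arg(on_unreachable)
  area_at <- function(s) scene_area_fraction(apply_scale(scene, s))
  if (area_at(s_hi) < target * (1 - rel_tol)) {
    if (on_unreachable == "error") {
      stop_invalid("target area fraction %.3f unreachable with these colonies", target)
    }
    return(s_hi)
  }
  lo <- s_lo; hi <- s_hi
  for (it in seq_len(iters)) {
    mid <- sqrt(lo * hi)
    a <- area_at(mid)
    if (abs(a - target) / target <= rel_tol * 0.5) { lo <- hi <- mid; break }
    if (a < target) lo <- mid else hi <- mid
  }
  sqrt(lo * hi)
}

#' Sample a colony scene at a target coverage
#'
#' Places `n_colonies` wobbled ellipses at random positions (fully inside the
#' frame) with lognormal size variation, then rescales all colony radii by a
#' single bisected factor so the realized union coverage lands within 10%
#' (relative) of `target_area_fraction`. The default target, 7.5% of chamber
#' area, matches typical attachment coverage ~24 h after seeding.
#'
#' @param seed integer seed; the scene is a pure function of it.
#' @param n_colonies number of colonies (default 12).
#' @param target_area_fraction target coverage in (0, 0.95).
#' @param shape image dimensions (rows, cols), default 512 x 512.
#' @param mean_radius_px,radius_sdlog lognormal size distribution of the
#'   colony equivalent radius before rescaling.
#' @param reporter_fraction fraction of colony area carrying the
#'   fluorescence reporter, in [0, 1] (see [ground_truth()]).
#' @return list with elements `scene` (class `colony_scene`) and `truth`
#'   (class `ground_truth`).
#' @export
sample_scene <- function(seed, n_colonies = 12, target_area_fraction = 0.075,
                         shape = c(512, 512), mean_radius_px = 28,
                         radius_sdlog = 0.3, reporter_fraction = 0) {
  if (target_area_fraction <= 0 || target_area_fraction >= 0.95) {
    stop_invalid("target_area_fraction must lie in (0, 0.95)")
  }
  scene <- with_seed(seed, {
    colonies <- vector("list", n_colonies)
    if (n_colonies > 0) {
      for (k in seq_len(n_colonies)) {
        r <- stats::rlnorm(1, log(mean_radius_px), radius_sdlog)
        aspect <- stats::runif(1, 0.6, 1)
        a <- r / sqrt(aspect); b <- r * sqrt(aspect)
        margin <- max(a, b) * 1.15 + 2
        margin_r <- min(margin, shape[1] / 2 - 1)
        margin_c <- min(margin, shape[2] / 2 - 1)
        colonies[[k]] <- list(
          center = c(stats::runif(1, margin_r, shape[1] - margin_r),
                     stats::runif(1, margin_c, shape[2] - margin_c)),
          a = a, b = b, theta = stats::runif(1, 0, pi),
          wobble_amp = stats::runif(3, 0, 0.05),
          wobble_phase = stats::runif(3, 0, 2 * pi)
        )
      }
    }
    structure(list(shape = shape, colonies = colonies, seed = seed,
                   capped = FALSE), class = "colony_scene")
  })
  if (n_colonies > 0) {
    s <- fit_scale_to_target(scene, target_area_fraction)
    scene <- apply_scale(scene, s)
    realized <- scene_area_fraction(scene)
    if (abs(realized - target_area_fraction) / target_area_fraction > 0.10) {
      stop_invalid("could not realize target coverage %.3f (got %.3f)",
                   target_area_fraction, realized)
    }
  }
  list(scene = scene, truth = ground_truth(scene, reporter_fraction))
}

#' Exact ground truth of a scene
#'
#' Computes the union cell mask and its area fraction exactly from the scene
#' parameters, and carves a reporter mask covering `reporter_fraction` of the
#' cell area. Reporter status is assigned colony-by-colony (whole colonies
#' first, then a partial cut through the colony that crosses the budget), so
#' reporter regions are spatially coherent as in a mixed-fate culture.
#'
#' @param scene a `colony_scene`.
#' @param reporter_fraction fraction of cell area reporter-positive, in [0, 1].
#' @return an object of class `ground_truth`: `cell_mask`, `area_fraction`,
#'   `reporter_mask`, `reporter_fraction` (realized), `capped`.
#' @export
ground_truth <- function(scene, reporter_fraction = 0) {
  if (reporter_fraction < 0 || reporter_fraction > 1) {
    stop_invalid("reporter_fraction must lie in [0, 1]")
  }
  m <- scene_masks(scene)
  cell <- m$cell
  n_cell <- sum(cell)
  reporter <- matrix(FALSE, nrow(cell), ncol(cell))
  if (n_cell > 0 && reporter_fraction > 0) {
    budget <- round(reporter_fraction * n_cell)
    for (k in seq_along(scene$colonies)) {
      if (budget <= 0) break
      pix <- which(m$owner == k)
      if (!length(pix)) next
      take <- min(length(pix), budget)
      reporter[pix[seq_len(take)]] <- TRUE
      budget <- budget - take
    }
    # pixels claimed by no colony owner (overlap edge cases) top up if short
    if (budget > 0) {
      rest <- which(cell & !reporter)
      reporter[rest[seq_len(min(budget, length(rest)))]] <- TRUE
    }
  }
  structure(list(
    cell_mask = cell,
    area_fraction = n_cell / length(cell),
    reporter_mask = reporter,
    reporter_fraction = if (n_cell > 0) sum(reporter) / n_cell else NA_real_,
    capped = isTRUE(scene$capped)
  ), class = "ground_truth")
}

#' Grow a scene by a target area fold
#'
#' Rescales all colony radii by a single bisected factor so the union
#' coverage becomes `fold` times the current coverage (within 10% relative),
#' emulating colony spreading between imaging days. Colony centres are
#' pulled inward as needed so colonies stay inside the frame. Coverage is
#' capped at 0.95 (confluency), and growth saturates earlier when in-frame
#' colonies cannot cover the target; either limit sets the `capped` flag.
#'
#' @param scene a `colony_scene`.
#' @param fold target area fold >= 1.
#' @return the grown `colony_scene`.
#' @export
grow_scene <- function(scene, fold) {
  if (fold < 1) stop_invalid("growth fold must be >= 1 (got %g)", fold)
  if (fold == 1 || length(scene$colonies) == 0) return(scene)
  base <- scene_area_fraction(scene)
  target <- fold * base
  capped <- FALSE
  if (target > 0.95) { target <- 0.95; capped <- TRUE }
  s <- fit_scale_to_target(scene, target, s_lo = 1, s_hi = 50,
                           on_unreachable = "saturate")
  scene <- apply_scale(scene, s)
  realized <- scene_area_fraction(scene)
  if (realized < target * 0.9) capped <- TRUE   # geometric saturation
  scene$capped <- capped
  scene
}

quantize <- function(img, bit_depth) {
  levels <- 2^bit_depth - 1
  round(pmin(pmax(img, 0), 1) * levels) / levels
}

#' Render the phase-contrast channel
#'
#' Draws each colony with a bright rim (phase halo) of `rim_width` px and a
#' textured interior over a mid-grey background, adds Gaussian noise, and
#' quantizes to the spec's bit depth. Deterministic given the scene seed.
#'
#' @param scene a `colony_scene`.
#' @param spec a [render_spec()].
#' @return numeric matrix in [0, 1].
#' @export
render_phase <- function(scene, spec = render_spec()) {
  m <- scene_masks(scene, rim_width = spec$rim_width)
  img <- matrix(spec$background_level, scene$shape[1], scene$shape[2])
  interior <- m$cell & !m$rim
  with_seed(scene$seed + 1000003L, {
    img[interior] <- spec$interior_level +
      stats::rnorm(sum(interior), 0, 0.02)        # interior texture
    img[m$rim] <- spec$rim_level
    if (spec$noise_sigma > 0) {
      img <- img + stats::rnorm(length(img), 0, spec$noise_sigma)
    }
  })
  quantize(img, spec$bit_depth)
}

#' Render the fluorescence channel
#'
#' Reporter-positive pixels are bright over a dim background; everything
#' else, including reporter-negative cells, stays at background (the reporter
#' is the only fluorophore). Deterministic given the scene seed.
#'
#' @param scene a `colony_scene`.
#' @param truth the matching [ground_truth()].
#' @param spec a [render_spec()].
#' @param reporter_level,background_level normalized intensities.
#' @return numeric matrix in [0, 1].
#' @export
render_fluorescence <- function(scene, truth, spec = render_spec(),
                                reporter_level = 0.6, background_level = 0.05) {
  if (!all(dim(truth$reporter_mask) == scene$shape)) {
    stop_invalid("reporter mask shape does not match scene")
  }
  if (any(truth$reporter_mask & !truth$cell_mask)) {
    stop_invalid("reporter mask must be a subset of the cell mask")
  }
  img <- matrix(background_level, scene$shape[1], scene$shape[2])
  img[truth$reporter_mask] <- reporter_level
  with_seed(scene$seed + 2000003L, {
    if (spec$noise_sigma > 0) {
      img <- img + stats::rnorm(length(img), 0, spec$noise_sigma)
    }
  })
  quantize(img, spec$bit_depth)
}

#' Read or write a grayscale image
#'
#' Thin wrappers over the TIFF and PNG readers; format chosen by file
#' extension. Images are numeric matrices in [0, 1]; 16-bit TIFF is the
#' default interchange format and round-trips quantized images exactly.
#'
#' @param img numeric matrix in [0, 1].
#' @param path file path ending in .tif/.tiff or .png.
#' @param bit_depth bits per sample (8 or 16).
#' @return `read_image` returns a numeric matrix; `write_image` the path,
#'   invisibly.
#' @export
write_image <- function(img, path, bit_depth = 16) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(img, path, bits.per.sample = bit_depth)
  } else if (ext == "png") {
    png::writePNG(img, path)
  } else stop_invalid("unsupported image extension: .%s", ext)
  invisible(path)
}

#' @rdname write_image
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext %in% c("tif", "tiff")) tiff::readTIFF(path)
  else if (ext == "png") png::readPNG(path)
  else stop_invalid("unsupported image extension: .%s", ext)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img
}
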