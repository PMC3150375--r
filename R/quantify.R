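#' Segmentation parameters
#'
#' Parameters of the phase-image pipeline: bright-feature extraction (white
#' top-hat), percentile contrast stretch, threshold, small-object removal and
#' hole filling. The defaults were chosen for 512 px fields of colonies with
#' a few-pixel phase halo; the pipeline is judged by ground-truth recovery,
#' not by any particular parameter set.
#'
#' @param tophat_radius structuring-element radius for the white top-hat (px).
#' @param stretch_percentiles low/high percentiles for the contrast stretch.
#' @param threshold_method `"otsu"` (default) or `"fixed"`.
#' @param fixed_threshold normalized threshold used when `threshold_method`
#'   is `"fixed"`.
#' @param min_object_px objects smaller than this are discarded before hole
#'   filling.
#' @return an object of class `segmentation_params`.
#' @export
segmentation_params <- function(tophat_radius = 15,
                                stretch_percentiles = c(1, 99.5),
                                threshold_method = c("otsu", "fixed"),
                                fixed_threshold = 0.5,
                                min_object_px = 50) {
  threshold_method <- match.arg(threshold_method)
  lo <- stretch_percentiles[1]; hi <- stretch_percentiles[2]
  if (!(lo >= 0 && lo < hi && hi <= 100)) {
    stop_invalid("stretch percentiles must satisfy 0 <= low < high <= 100")
  }
  if (tophat_radius <= 0) stop_invalid("tophat_radius must be positive")
  structure(list(tophat_radius = tophat_radius,
                 stretch_percentiles = stretch_percentiles,
                 threshold_method = threshold_method,
                 fixed_threshold = fixed_threshold,
                 min_object_px = min_object_px),
            class = "segmentation_params")
}

stretch_contrast <- function(img, percentiles) {
  qs <- stats::quantile(img, percentiles / 100, names = FALSE)
  if (qs[2] <= qs[1]) return(NULL)  # degenerate histogram
  pmin(pmax((img - qs[1]) / (qs[2] - qs[1]), 0), 1)
}

threshold_image <- function(img, method, fixed_threshold) {
  if (method == "fixed") return(img > fixed_threshold)
  thr <- tryCatch(EBImage::otsu(EBImage::Image(img), range = c(0, 1)),
                  error = function(e) NA_real_)
  if (is.na(thr)) return(NULL)
  img > thr
}

remove_small_objects <- function(mask, min_px) {
  if (!any(mask) || min_px <= 1) return(mask)
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  sizes <- tabulate(as.integer(EBImage::imageData(lab)))
  keep <- which(sizes >= min_px)
  matrix(as.integer(EBImage::imageData(lab)) %in% keep, nrow(mask), ncol(mask))
}

fill_holes <- function(mask) {
  out <- EBImage::fillHull(EBImage::Image(mask * 1))
  EBImage::imageData(out) > 0
}

#' Segment the cell area of a phase-contrast image
#'
#' Fixed pipeline order: white top-hat (extract bright morphological
#' features such as the colony halo) -> percentile contrast stretch ->
#' threshold (Otsu by default) -> binarize -> remove objects below
#' `min_object_px` -> fill holes, so that halo rings become solid colony
#' masks. A constant (degenerate-histogram) image yields an empty mask with
#' a warning.
#'
#' @param img numeric matrix in [0, 1].
#' @param params a [segmentation_params()].
#' @return logical cell mask of the same shape.
#' @export
segment_phase <- function(img, params = segmentation_params()) {
  if (length(dim(img)) != 2) stop_invalid("segment_phase needs a 2D grayscale image")
  brush <- EBImage::makeBrush(2 * params$tophat_radius + 1, shape = "disc")
  th <- EBImage::imageData(EBImage::whiteTopHat(EBImage::Image(img), brush))
  stretched <- stretch_contrast(th, params$stretch_percentiles)
  if (is.null(stretched)) {
    warning("degenerate intensity histogram; returning empty mask", call. = FALSE)
    return(matrix(FALSE, nrow(img), ncol(img)))
  }
  mask <- threshold_image(stretched, params$threshold_method, params$fixed_threshold)
  if (is.null(mask)) {
    warning("threshold selection failed; returning empty mask", call. = FALSE)
    return(matrix(FALSE, nrow(img), ncol(img)))
  }
  mask <- remove_small_objects(mask, params$min_object_px)
  fill_holes(mask)
}

#' Cell-covered area fraction of a mask
#'
#' @param mask logical matrix.
#' @return foreground pixels / total pixels.
#' @export
cell_area <- function(mask) {
  if (!is.logical(mask)) stop_invalid("cell_area needs a logical mask")
  mean(mask)
}

#' Fold increase in cell area
#'
#' Cell-covered area at a time point over the initial attached-cell area
#' (~24 h after seeding).
#'
#' @param area_t area (fraction) at the time point.
#' @param area_0 initial area (fraction), > 0.
#' @return dimensionless fold.
#' @export
fold_increase <- function(area_t, area_0) {
  if (area_0 <= 0) stop_invalid("fold increase undefined: initial area is zero")
  area_t / area_0
}

#' Reporter-positive fraction of the cell area
#'
#' Segments the fluorescence channel (contrast stretch then threshold; no
#' top-hat, reporter regions are filled, not ringed) and reports the area of
#' reporter-positive pixels inside the phase mask over the phase-mask area.
#' Intersecting with the phase mask keeps the ratio in [0, 1].
#'
#' Because a contrast stretch maps even a signal-free field onto the full
#' intensity range, candidate pixels must additionally clear a signal floor
#' of median + 6 MAD of the background, estimated from pixels outside the
#' phase mask (the non-cell region carries no reporter, playing the role of
#' the reporter-negative exposure reference). A reporter-free image therefore
#' yields fraction 0 rather than thresholded noise.
#'
#' @param phase_mask logical cell mask from [segment_phase()].
#' @param fluor_img fluorescence channel, numeric matrix in [0, 1].
#' @param params a [segmentation_params()] (stretch/threshold settings used).
#' @return list with `fraction` (NA with `undefined = TRUE` when the phase
#'   mask is empty) and the fluorescence mask.
#' @export
sox1_fraction <- function(phase_mask, fluor_img, params = segmentation_params()) {
  if (!all(dim(phase_mask) == dim(fluor_img))) {
    stop_invalid("phase mask and fluorescence image shapes differ")
  }
  if (!any(phase_mask)) {
    warning("empty phase mask: reporter fraction undefined", call. = FALSE)
    return(list(fraction = NA_real_, undefined = TRUE,
                fluor_mask = matrix(FALSE, nrow(fluor_img), ncol(fluor_img))))
  }
  stretched <- stretch_contrast(fluor_img, params$stretch_percentiles)
  if (is.null(stretched)) {
    return(list(fraction = 0, undefined = FALSE,
                fluor_mask = matrix(FALSE, nrow(fluor_img), ncol(fluor_img))))
  }
  fmask <- threshold_image(stretched, params$threshold_method, params$fixed_threshold)
  if (is.null(fmask)) fmask <- matrix(FALSE, nrow(fluor_img), ncol(fluor_img))
  bg <- fluor_img[!phase_mask]
  if (length(bg) > 10) {
    floor_level <- stats::median(bg) + 6 * stats::mad(bg)
    fmask <- fmask & fluor_img > floor_level
  }
  fmask <- remove_small_objects(fmask, params$min_object_px)
  list(fraction = sum(fmask & phase_mask) / sum(phase_mask),
       undefined = FALSE, fluor_mask = fmask)
}

#' Aggregate per-image measurements to a condition summary
#'
#' Follows the experimental hierarchy: images average to chamber means,
#' chambers to a per-experiment condition mean, and experiments to the
#' reported mean +/- sample sd (n - 1 denominator), as in figures reporting
#' "average +/- s.d. of N independent experiments".
#'
#' @param measurements data.frame with columns `experiment`, `chamber`,
#'   `value` (one row per image).
#' @param condition label for the summary.
#' @return an object of class `condition_summary`: per-chamber and
#'   per-experiment tables plus `mean`, `sd`, `n` (experiments).
#' @export
aggregate_condition <- function(measurements, condition = "condition") {
  need <- c("experiment", "chamber", "value")
  if (!all(need %in% names(measurements))) {
    stop_invalid("measurements must have columns %s", paste(need, collapse = ", "))
  }
  if (nrow(measurements) == 0) stop_invalid("no measurements to aggregate")
  per_chamber <- stats::aggregate(value ~ experiment + chamber,
                                  data = measurements, FUN = mean)
  per_experiment <- stats::aggregate(value ~ experiment, data = per_chamber,
                                     FUN = mean)
  structure(list(
    condition = condition,
    per_chamber = per_chamber,
    per_experiment = per_experiment,
    mean = mean(per_experiment$value),
    sd = if (nrow(per_experiment) > 1) stats::sd(per_experiment$value) else 0,
    n = nrow(per_experiment)
  ), class = "condition_summary")
}

#' Unpaired two-tailed pooled-variance t-test
#'
#' Student's t-test assuming equal variances, written out from the pooled
#' variance formula: s_p^2 = ((n_a - 1) s_a^2 + (n_b - 1) s_b^2) /
#' (n_a + n_b - 2), t = (mean_a - mean_b) / (s_p sqrt(1/n_a + 1/n_b)),
#' two-tailed p from the t distribution with n_a + n_b - 2 df.
#'
#' @param group_a,group_b numeric vectors, each of length >= 2.
#' @return list with `t`, `p`, `df`, and `degenerate` (TRUE when the pooled
#'   variance is zero).
#' @export
ttest_unpaired_equal_var <- function(group_a, group_b) {
  na <- length(group_a); nb <- length(group_b)
  if (na < 2 || nb < 2) stop_invalid("each group needs n >= 2")
  df <- na + nb - 2
  sp2 <- ((na - 1) * stats::var(group_a) + (nb - 1) * stats::var(group_b)) / df
  delta <- mean(group_a) - mean(group_b)
  if (sp2 == 0) {
    if (delta == 0) return(list(t = 0, p = 1, df = df, degenerate = TRUE))
    warning("zero pooled variance with unequal means: p -> 0", call. = FALSE)
    return(list(t = sign(delta) * Inf, p = 0, df = df, degenerate = TRUE))
  }
  tstat <- delta / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = tstat, p = 2 * stats::pt(-abs(tstat), df), df = df, degenerate = FALSE)
}
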