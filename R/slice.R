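#' @title Grayscale slice container
#'
#' @description A `grayscale_slice` holds one 2-D image on the common 8-bit
#' analysis scale (integer intensities 0--255). All downstream quantification
#' (region histograms, Otsu thresholding, the SD >= 35 equalization gate)
#' is defined on this scale, so every reader normalizes into it.
#'
#' @param pixels integer or numeric matrix; values must lie in `[0, 255]`
#'   (they are rounded to integers).
#' @param source_id opaque identifier string for the slice.
#' @param laterality one of `"left"`, `"right"`, `"unknown"`.
#' @param meta optional named list of provenance metadata (original bit
#'   depth, file path, normalization policy, ...).
#'
#' @return An object of class `grayscale_slice` with elements `pixels`
#'   (integer matrix), `height`, `width`, `source_id`, `laterality`, `meta`.
#' @export
grayscale_slice <- function(pixels, source_id = "slice",
                            laterality = c("unknown", "left", "right"),
                            meta = list()) {
  laterality <- match.arg(laterality)
  if (!is.matrix(pixels)) {
    stop("`pixels` must be a matrix", call. = FALSE)
  }
  px <- round(pixels)
  if (anyNA(px) || min(px) < 0 || max(px) > 255) {
    stop("slice intensities must be finite and in [0, 255]", call. = FALSE)
  }
  if (nrow(px) < 32 || ncol(px) < 32) {
    stop("slice must be at least 32 x 32 pixels", call. = FALSE)
  }
  storage.mode(px) <- "integer"
  structure(
    list(
      pixels = px,
      height = nrow(px),
      width = ncol(px),
      source_id = as.character(source_id),
      laterality = laterality,
      meta = meta
    ),
    class = "grayscale_slice"
  )
}

#' @export
print.grayscale_slice <- function(x, ...) {
  cat(sprintf(
    "<grayscale_slice '%s'> %d x %d, intensities %d..%d, laterality %s\n",
    x$source_id, x$height, x$width, min(x$pixels), max(x$pixels), x$laterality
  ))
  invisible(x)
}

#' Normalize raw intensities to the 8-bit analysis scale
#'
#' Maps an arbitrary-depth intensity array onto integers 0--255. Two
#' policies are provided: `"minmax"` linearly rescales the observed range,
#' and `"percentile"` clips at the `p_lo`/`p_hi` intensity percentiles
#' before the same linear rescale (robust to isolated hot pixels). The
#' mapping is monotone non-decreasing in the raw intensities; rounding is
#' half-away-from-zero so, e.g., raw `{0, 50, 100}` under minmax maps to
#' `{0, 128, 255}`.
#'
#' A constant image carries no contrast and is mapped, by convention, to
#' all zeros.
#'
#' @param raw numeric matrix of raw scanner intensities.
#' @param policy `"minmax"` (default) or `"percentile"`.
#' @param p_lo,p_hi percentile bounds in `[0, 100]` for the percentile
#'   policy; must satisfy `p_lo < p_hi`.
#' @param source_id,laterality passed to [grayscale_slice()].
#' @return A [grayscale_slice()] with pixels in `[0, 255]`.
#' @export
normalize_to_8bit <- function(raw, policy = c("minmax", "percentile"),
                              p_lo = 0.5, p_hi = 99.5,
                              source_id = "slice", laterality = "unknown") {
  policy <- match.arg(policy)
  if (!is.matrix(raw) || !is.numeric(raw)) {
    stop("`raw` must be a numeric matrix", call. = FALSE)
  }
  if (anyNA(raw)) stop("`raw` contains missing values", call. = FALSE)
  v <- raw
  if (policy == "percentile") {
    if (p_lo >= p_hi) {
      stop("percentile bounds must satisfy p_lo < p_hi", call. = FALSE)
    }
    q <- stats::quantile(v, c(p_lo, p_hi) / 100, names = FALSE, type = 7)
    v <- pmin(pmax(v, q[1L]), q[2L])
  }
  lo <- min(v)
  hi <- max(v)
  if (hi > lo) {
    px <- round_half_up((v - lo) * 255 / (hi - lo))
  } else {
    px <- array(0, dim(v)) # constant image: no contrast, all zeros
  }
  dim(px) <- dim(raw)
  grayscale_slice(px,
    source_id = source_id, laterality = laterality,
    meta = list(
      normalization = policy, raw_min = min(raw), raw_max = max(raw),
      clip = if (policy == "percentile") c(p_lo, p_hi) else NULL
    )
  )
}

# round half away from zero (base round() is banker's rounding)
round_half_up <- function(x) trunc(x + 0.5 * sign(x))

#' Paired fossa and muscle masks for one slice
#'
#' The supraspinatus fossa and muscle regions are exchanged as binary masks
#' aligned to the slice they annotate. For ground-truth annotations the
#' muscle is drawn inside the fossa, so muscle pixels outside the fossa are
#' an annotation error; for predicted masks the containment can be violated
#' and the violation count is carried for reporting.
#'
#' @param fossa,muscle logical (or 0/1) matrices of identical shape.
#' @param ground_truth if `TRUE` (default), any muscle pixel outside the
#'   fossa beyond `violation_tolerance` raises an error; if `FALSE`
#'   violations are counted but tolerated.
#' @param violation_tolerance maximum tolerated muscle-outside-fossa pixel
#'   count for ground truth (default 0).
#' @return An object of class `region_masks` with elements `fossa`,
#'   `muscle` (logical matrices), and `containment_violations` (integer
#'   count of muscle pixels outside the fossa).
#' @export
region_masks <- function(fossa, muscle, ground_truth = TRUE,
                         violation_tolerance = 0L) {
  fossa <- as_binary_mask(fossa, "fossa")
  muscle <- as_binary_mask(muscle, "muscle")
  if (!identical(dim(fossa), dim(muscle))) {
    stop("fossa and muscle masks must have identical shape", call. = FALSE)
  }
  if (!any(fossa)) stop("fossa mask is empty", call. = FALSE)
  if (!any(muscle)) stop("muscle mask is empty", call. = FALSE)
  viol <- sum(muscle & !fossa)
  if (ground_truth && viol > violation_tolerance) {
    stop(sprintf(
      "ground-truth muscle mask has %d pixel(s) outside the fossa", viol
    ), call. = FALSE)
  }
  structure(
    list(fossa = fossa, muscle = muscle,
         containment_violations = as.integer(viol)),
    class = "region_masks"
  )
}

#' @export
print.region_masks <- function(x, ...) {
  cat(sprintf(
    "<region_masks> %d x %d, fossa %d px, muscle %d px, %d containment violation(s)\n",
    nrow(x$fossa), ncol(x$fossa), sum(x$fossa), sum(x$muscle),
    x$containment_violations
  ))
  invisible(x)
}

as_binary_mask <- function(m, what = "mask") {
  if (is.null(dim(m)) || length(dim(m)) != 2L) {
    stop(sprintf("`%s` must be a 2-D matrix", what), call. = FALSE)
  }
  if (is.logical(m)) return(m)
  if (!all(m %in% c(0, 1))) {
    stop(sprintf("`%s` must be strictly binary (0/1)", what), call. = FALSE)
  }
  array(m == 1, dim(m))
}

check_mask_shapes <- function(a, b) {
  if (!identical(dim(a), dim(b))) {
    stop("masks have mismatching shapes", call. = FALSE)
  }
}
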