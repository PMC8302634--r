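#' Horizontal flip of a slice and its masks
#'
#' Mirrors the image about the vertical axis (left/right exchange), the
#' standard trick for balancing left and right shoulders in training data.
#' All masks follow the image, laterality metadata is toggled, and the
#' operation is an involution: flipping twice restores the input
#' bit-exactly.
#'
#' @param case either a [grayscale_slice()], a `phantom_case`, or a list
#'   with elements `slice` and optionally `masks` / `fat_mask_true`.
#' @return An object of the same shape with all planes mirrored.
#' @export
flip_lr <- function(case) {
  if (inherits(case, "grayscale_slice")) {
    out <- case
    out$pixels <- flip_cols(case$pixels)
    out$laterality <- switch(case$laterality,
      left = "right", right = "left", "unknown"
    )
    return(out)
  }
  if (is.list(case) && !is.null(case$slice)) {
    out <- case
    out$slice <- flip_lr(case$slice)
    if (!is.null(case$masks)) {
      out$masks <- region_masks(
        flip_cols(case$masks$fossa), flip_cols(case$masks$muscle),
        ground_truth = FALSE
      )
    }
    if (!is.null(case$fat_mask_true)) {
      out$fat_mask_true <- flip_cols(case$fat_mask_true)
    }
    return(out)
  }
  stop("cannot flip this object", call. = FALSE)
}

flip_cols <- function(m) m[, rev(seq_len(ncol(m))), drop = FALSE]

#' Whole-image 256-bin histogram of a slice
#'
#' @param slice a [grayscale_slice()].
#' @return integer vector of 256 counts.
#' @export
slice_histogram <- function(slice) {
  tabulate(slice$pixels + 1L, nbins = 256L)
}

#' Classify a corpus into brightness stages
#'
#' Ranks slices by whole-image mean intensity and splits them into
#' `n_stages` quantile groups of near-equal size (sizes differ by at most
#' one; ties in mean intensity break stably by corpus order). Each stage
#' carries the per-bin mean of its members' 256-bin histograms as the
#' reference distribution for histogram-matching augmentation.
#'
#' @param corpus list of [grayscale_slice()] objects.
#' @param n_stages number of brightness stages (default 5).
#' @return list of `n_stages` lists, each with `stage_index`,
#'   `member_ids`, `mean_intensities`, `reference_histogram`.
#' @export
assign_brightness_stages <- function(corpus, n_stages = 5L) {
  if (length(corpus) < n_stages) {
    stop("corpus smaller than the number of brightness stages",
         call. = FALSE)
  }
  ids <- vapply(corpus, function(s) s$source_id, character(1))
  means <- vapply(corpus, function(s) mean(s$pixels), numeric(1))
  ord <- order(means, seq_along(means)) # stable on ties
  bounds <- floor(seq(0, length(corpus), length.out = n_stages + 1))
  lapply(seq_len(n_stages), function(k) {
    members <- ord[(bounds[k] + 1L):bounds[k + 1L]]
    hists <- vapply(corpus[members], slice_histogram, numeric(256))
    list(
      stage_index = k,
      member_ids = ids[members],
      mean_intensities = means[members],
      reference_histogram = rowMeans(hists)
    )
  })
}

#' Histogram matching to a reference distribution
#'
#' Standard CDF-to-CDF matching: each gray level `v` with source CDF
#' `F(v)` maps to the smallest level `g` whose reference CDF `G(g)` reaches
#' `F(v)`. The mapping is monotone non-decreasing, so the intensity order
#' of any two pixels is preserved; matching a slice to its own histogram
#' is the identity up to quantization.
#'
#' @param slice a [grayscale_slice()].
#' @param reference_histogram 256-bin vector of non-negative weights with
#'   positive total (counts or averaged counts).
#' @return A new [grayscale_slice()] whose histogram approximates the
#'   reference.
#' @export
histogram_match <- function(slice, reference_histogram) {
  if (length(reference_histogram) != 256L ||
      any(reference_histogram < 0) || sum(reference_histogram) <= 0) {
    stop("reference histogram must be 256 non-negative weights, not all zero",
         call. = FALSE)
  }
  src_cdf <- cumsum(slice_histogram(slice)) / (slice$height * slice$width)
  ref_cdf <- cumsum(reference_histogram) / sum(reference_histogram)
  # level v -> smallest g with ref_cdf[g] >= src_cdf[v]
  mapping <- findInterval(src_cdf, ref_cdf, left.open = TRUE)
  mapping <- pmin(mapping, 255L)
  out <- slice
  out$pixels <- array(as.integer(mapping)[slice$pixels + 1L],
                      dim(slice$pixels))
  out$meta$histogram_matched <- TRUE
  out
}

#' Augment one training fold tenfold
#'
#' The augmentation scheme for training folds: each case is taken in its
#' original and left/right-flipped orientation (x2), and each orientation
#' is histogram-matched to each of the 5 brightness-stage reference
#' distributions (x5), for exactly 10 derived cases per input. Masks pass
#' through brightness operations bit-exactly and are mirrored with the
#' flip. Stage references must be computed on the training corpus only —
#' validation images stay original — and every derived case records its
#' provenance so the leakage guard is auditable.
#'
#' @param fold_cases list of cases (each a list with `slice` and
#'   optionally `masks`).
#' @param stages brightness stages from [assign_brightness_stages()],
#'   computed on the training fold only.
#' @return list of `length(fold_cases) * 2 * length(stages)` cases; each
#'   gains a `provenance` list (`derived_id`, `parent_id`, `flipped`,
#'   `stage_index`).
#' @export
augment_training_fold <- function(fold_cases, stages) {
  out <- vector("list", length(fold_cases) * 2L * length(stages))
  pos <- 0L
  for (case in fold_cases) {
    parent_id <- case$slice$source_id
    for (flipped in c(FALSE, TRUE)) {
      base <- if (flipped) flip_lr(case) else case
      for (st in stages) {
        derived <- base
        derived$slice <- histogram_match(base$slice, st$reference_histogram)
        derived$slice$source_id <- sprintf(
          "%s_f%d_s%d", parent_id, as.integer(flipped), st$stage_index
        )
        derived$provenance <- list(
          derived_id = derived$slice$source_id,
          parent_id = parent_id,
          flipped = flipped,
          stage_index = st$stage_index
        )
        pos <- pos + 1L
        out[[pos]] <- derived
      }
    }
  }
  out
}

#' Manifest of an augmented fold
#'
#' @param augmented list returned by [augment_training_fold()].
#' @return data frame with columns derived_id, parent_id, flip,
#'   stage_index.
#' @export
augmentation_manifest <- function(augmented) {
  do.call(rbind, lapply(augmented, function(a) {
    data.frame(
      derived_id = a$provenance$derived_id,
      parent_id = a$provenance$parent_id,
      flip = a$provenance$flipped,
      stage_index = a$provenance$stage_index,
      stringsAsFactors = FALSE
    )
  }))
}
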