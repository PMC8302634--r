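#' Read a 2-D grayscale slice from PNG, NIfTI or DICOM
#'
#' Loads one slice and brings it onto the common 8-bit analysis scale.
#' Sources that are already 8-bit (grayscale PNG, integer data in
#' `[0, 255]`) pass through unchanged; deeper sources are rescaled with
#' [normalize_to_8bit()] under `policy`.
#'
#' @param path file path.
#' @param format `"png"`, `"nifti"` or `"dicom"`; default guesses from the
#'   file extension.
#' @param slice_index for NIfTI volumes with more than one slice, the
#'   index (third dimension) of the slice to extract; mandatory in that
#'   case.
#' @param policy normalization policy for non-8-bit sources; see
#'   [normalize_to_8bit()].
#' @param source_id identifier; defaults to the file name.
#' @return A [grayscale_slice()]; `meta$bit_depth` records the source
#'   depth and `meta$path` the origin.
#' @export
read_slice <- function(path, format = c("auto", "png", "nifti", "dicom"),
                       slice_index = NULL, policy = "minmax",
                       source_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop(sprintf("cannot read slice: no such file '%s'", path), call. = FALSE)
  }
  if (format == "auto") format <- guess_format(path)
  if (is.null(source_id)) source_id <- basename(path)

  if (format == "png") {
    arr <- png::readPNG(path)
    if (length(dim(arr)) == 3L) arr <- arr[, , 1L] # drop colour/alpha planes
    # readPNG returns intensities scaled to [0,1]; 8-bit files are v/255
    raw <- round_half_up(arr * 255)
    return(grayscale_slice(raw, source_id = source_id,
                           meta = list(path = path, bit_depth = 8L)))
  }

  if (format == "nifti") {
    vol <- tryCatch(RNifti::readNifti(path), error = function(e) {
      stop(sprintf("cannot read NIfTI '%s': %s", path, conditionMessage(e)),
           call. = FALSE)
    })
    raw <- extract_slice(unclass(vol)[seq_along(vol)], dim(vol), slice_index,
                         path)
    return(finish_raw_slice(raw, policy, source_id, path))
  }

  hdr <- read_dicom_gray(path)
  finish_raw_slice(hdr$pixels, policy, source_id, path,
                   bit_depth = hdr$bits_stored)
}

guess_format <- function(path) {
  lower <- tolower(path)
  if (grepl("\\.png$", lower)) return("png")
  if (grepl("\\.nii(\\.gz)?$", lower)) return("nifti")
  if (grepl("\\.dcm$", lower)) return("dicom")
  stop(sprintf("cannot guess format of '%s'; pass `format`", path),
       call. = FALSE)
}

extract_slice <- function(values, dims, slice_index, path) {
  arr <- array(values, dims)
  if (length(dims) == 2L) return(arr)
  extra <- dims[-(1:2)]
  if (prod(extra) == 1L) return(array(arr, dims[1:2]))
  if (is.null(slice_index)) {
    stop(sprintf(
      "'%s' holds %d slices; supply `slice_index`", path, prod(extra)
    ), call. = FALSE)
  }
  if (slice_index < 1L || slice_index > dims[3L]) {
    stop("`slice_index` out of range", call. = FALSE)
  }
  array(arr[, , slice_index], dims[1:2])
}

finish_raw_slice <- function(raw, policy, source_id, path, bit_depth = NULL) {
  storage_is_8bit <- all(raw == round(raw)) && min(raw) >= 0 && max(raw) <= 255
  if (storage_is_8bit) {
    grayscale_slice(raw, source_id = source_id,
                    meta = list(path = path,
                                bit_depth = bit_depth %||% 8L))
  } else {
    out <- normalize_to_8bit(raw, policy = policy, source_id = source_id)
    out$meta$path <- path
    out$meta$bit_depth <- bit_depth %||% guess_bit_depth(raw)
    out
  }
}

guess_bit_depth <- function(raw) {
  mx <- max(raw)
  if (mx <= 255) 8L else if (mx <= 4095) 12L else 16L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a grayscale slice as 8-bit PNG
#'
#' @param slice a [grayscale_slice()] or an integer matrix in `[0, 255]`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_slice_png <- function(slice, path) {
  px <- if (inherits(slice, "grayscale_slice")) slice$pixels else slice
  png::writePNG(px / 255, target = path)
  invisible(path)
}

#' Read fossa/muscle masks from an ITK-SNAP-style integer label map
#'
#' The label map is a NIfTI volume of integer labels in the nested
#' convention produced by brush annotation: muscle pixels carry
#' `muscle_label`, fossa pixels not covered by muscle carry `fossa_label`,
#' everything else 0. The fossa mask is therefore the union of the two
#' labels. Predicted masks, which need not respect the containment, travel
#' as per-region masks instead (see [write_region_masks()]).
#'
#' @param path NIfTI file of integer labels.
#' @param fossa_label,muscle_label label values (defaults 1 and 2).
#' @param slice_index slice to extract when the volume has several.
#' @param ground_truth passed to [region_masks()].
#' @return A [region_masks()] object.
#' @export
read_label_map <- function(path, fossa_label = 1L, muscle_label = 2L,
                           slice_index = NULL, ground_truth = TRUE) {
  vol <- tryCatch(RNifti::readNifti(path), error = function(e) {
    stop(sprintf("cannot read label map '%s': %s", path,
                 conditionMessage(e)), call. = FALSE)
  })
  lab <- extract_slice(unclass(vol)[seq_along(vol)], dim(vol), slice_index,
                       path)
  lab <- round(lab)
  for (lv in c(fossa = fossa_label, muscle = muscle_label)) {
    if (!any(lab == lv)) {
      stop(sprintf("label %d absent from '%s'", lv, path), call. = FALSE)
    }
  }
  muscle <- lab == muscle_label
  fossa <- muscle | lab == fossa_label
  region_masks(fossa, muscle, ground_truth = ground_truth)
}

#' Write fossa/muscle masks as an ITK-SNAP-style integer label map
#'
#' Inverse of [read_label_map()]: muscle pixels get `muscle_label`,
#' fossa-only pixels `fossa_label`, background 0. Muscle pixels outside the
#' fossa (possible for predictions) are written with `muscle_label`, so the
#' flattening is lossless for ground truth and muscle-priority for
#' violating predictions.
#'
#' @param masks a [region_masks()] object.
#' @param path output `.nii`/`.nii.gz` path.
#' @param fossa_label,muscle_label label values to emit.
#' @return `path`, invisibly.
#' @export
write_label_map <- function(masks, path, fossa_label = 1L,
                            muscle_label = 2L) {
  lab <- array(0L, dim(masks$fossa))
  lab[masks$fossa] <- fossa_label
  lab[masks$muscle] <- muscle_label
  RNifti::writeNifti(lab, path, datatype = "int16")
  invisible(path)
}

#' Write/read per-region binary masks (prediction exchange format)
#'
#' Predictions from the segmentation network are two independent per-pixel
#' masks that may violate the muscle-in-fossa containment, so they are
#' stored as a two-volume NIfTI (fossa first, muscle second) rather than a
#' flattened label map.
#'
#' @param masks a [region_masks()] object.
#' @param path output path.
#' @return `path` (write) or a [region_masks()] with `ground_truth = FALSE`
#'   (read).
#' @export
write_region_masks <- function(masks, path) {
  arr <- array(0L, c(dim(masks$fossa), 2L))
  arr[, , 1L] <- masks$fossa * 1L
  arr[, , 2L] <- masks$muscle * 1L
  RNifti::writeNifti(arr, path, datatype = "int16")
  invisible(path)
}

#' @rdname write_region_masks
#' @export
read_region_masks <- function(path) {
  vol <- RNifti::readNifti(path)
  d <- dim(vol)
  if (length(d) < 3L || d[3L] != 2L) {
    stop(sprintf("'%s' is not a two-volume region-mask file", path),
         call. = FALSE)
  }
  arr <- array(unclass(vol)[seq_along(vol)], d)
  region_masks(arr[, , 1L] == 1, arr[, , 2L] == 1, ground_truth = FALSE)
}

#' Read or write Goutallier grade annotations
#'
#' Grades travel in a CSV sidecar with columns `source_id` and `grade`.
#' Grade semantics: 0 normal muscle, 1 fatty streaking, 2 more muscle than
#' fat, 3 equal fat and muscle, 4 more fat than muscle.
#'
#' @param path CSV path.
#' @return `read_grades`: data frame with character `source_id` and
#'   integer `grade`.
#' @export
read_grades <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("source_id", "grade") %in% names(df))) {
    stop("grade CSV must have columns source_id, grade", call. = FALSE)
  }
  df$grade <- as.integer(df$grade)
  if (anyNA(df$grade) || any(df$grade < 0L | df$grade > 4L)) {
    stop("grades must be integers in 0..4", call. = FALSE)
  }
  df[, c("source_id", "grade")]
}

#' @rdname read_grades
#' @param grades data frame with columns `source_id`, `grade`.
#' @export
write_grades <- function(grades, path) {
  stopifnot(all(c("source_id", "grade") %in% names(grades)))
  utils::write.csv(grades[, c("source_id", "grade")], path,
                   row.names = FALSE)
  invisible(path)
}
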