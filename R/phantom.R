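#' Specification of a synthetic scapular-Y-view phantom
#'
#' A phantom emulates the analysis-relevant content of a T1 scapular
#' Y-view slice: a smooth convex-ish supraspinatus-fossa region, a muscle
#' region nested inside it whose area is a controllable fraction of the
#' fossa (the occupation ratio), spatially clustered bright specks inside
#' the muscle standing in for intramuscular fat (fat is bright on T1), a
#' few fat-intensity distractor blobs just outside the muscle emulating
#' neurovascular structures of similar signal, and additive truncated
#' Gaussian noise. It is deliberately not an anatomical rendering: its role
#' is to provide images with exactly known occupation ratio and fat
#' fraction.
#'
#' @param image_size side length in pixels (square slice), default 512.
#' @param occupation_ratio_true target muscle/fossa area ratio in `(0, 1]`.
#' @param fat_fraction_true target fat/muscle area fraction in `[0, 1)`.
#' @param muscle_intensity_mean,fat_intensity_mean mean gray levels of
#'   muscle and fat tissue; fat must be brighter than muscle.
#' @param fat_intensity_levels optional vector of gray levels; when given,
#'   fat clusters cycle through these levels (multi-stage fat, emulating
#'   internally degenerated tissue whose intensity is expressed in several
#'   stages) instead of the single `fat_intensity_mean`.
#' @param fossa_intensity_mean gray level of fossa tissue outside the
#'   muscle.
#' @param background_intensity gray level outside the fossa.
#' @param intensity_sd standard deviation of the additive Gaussian noise
#'   (gray levels); 0 gives a noiseless phantom.
#' @param n_distractors number of fat-intensity blobs placed outside (but
#'   near) the muscle.
#' @param cluster_scale radius scale (pixels) of the fat specks.
#' @param seed integer seed; every random choice in the phantom flows from
#'   it.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_size = 512L,
                         occupation_ratio_true = 0.6,
                         fat_fraction_true = 0.2,
                         muscle_intensity_mean = 60,
                         fat_intensity_mean = 180,
                         fat_intensity_levels = NULL,
                         fossa_intensity_mean = 110,
                         background_intensity = 20,
                         intensity_sd = 8,
                         n_distractors = 3L,
                         cluster_scale = 3L,
                         seed = 1L) {
  if (image_size < 32L) stop("image_size must be >= 32", call. = FALSE)
  if (occupation_ratio_true <= 0 || occupation_ratio_true > 1) {
    stop("occupation_ratio_true must be in (0, 1]", call. = FALSE)
  }
  if (fat_fraction_true < 0 || fat_fraction_true >= 1) {
    stop("fat_fraction_true must be in [0, 1)", call. = FALSE)
  }
  fat_levels <- fat_intensity_levels %||% fat_intensity_mean
  if (min(fat_levels) <= muscle_intensity_mean) {
    stop("fat intensity must exceed muscle intensity (fat is bright on T1)",
         call. = FALSE)
  }
  structure(
    list(
      image_size = as.integer(image_size),
      occupation_ratio_true = occupation_ratio_true,
      fat_fraction_true = fat_fraction_true,
      muscle_intensity_mean = muscle_intensity_mean,
      fat_intensity_mean = fat_intensity_mean,
      fat_intensity_levels = fat_intensity_levels,
      fossa_intensity_mean = fossa_intensity_mean,
      background_intensity = background_intensity,
      intensity_sd = intensity_sd,
      n_distractors = as.integer(n_distractors),
      cluster_scale = as.integer(cluster_scale),
      seed = as.integer(seed)
    ),
    class = "phantom_spec"
  )
}

# Evaluate code with a local, seeded RNG stream; the global .Random.seed is
# restored afterwards so phantom generation never perturbs user randomness.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate one phantom case
#'
#' Deterministic given `spec$seed`. The fossa is a smooth star-convex
#' region (low-order harmonic perturbation of an ellipse); the muscle is a
#' radially scaled copy nested inside it, with the scale solved by
#' bisection on pixel counts so the realized occupation ratio matches
#' `occupation_ratio_true` within 1% relative; exactly
#' `round(fat_fraction_true * muscle_area)` muscle pixels are reassigned to
#' fat intensity in clustered specks, so the realized fat fraction matches
#' the target up to integer rounding.
#'
#' @param spec a [phantom_spec()].
#' @return An object of class `phantom_case`: list with `slice`
#'   ([grayscale_slice()]), `masks` ([region_masks()]), `fat_mask_true`
#'   (logical matrix, subset of the muscle mask), and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, generate_phantom_impl(spec))
}

generate_phantom_impl <- function(spec) {
  n <- spec$image_size
  cx <- n / 2 + stats::runif(1, -0.03, 0.03) * n
  cy <- n / 2 + stats::runif(1, -0.03, 0.03) * n
  xs <- matrix(rep(seq_len(n), each = n), n) # column index
  ys <- matrix(rep(seq_len(n), times = n), n) # row index
  dx <- (xs - cx) / n
  dy <- (ys - cy) / n
  theta <- atan2(dy, dx)
  rr <- sqrt(dx^2 + dy^2)

  # smooth star-convex fossa: perturbed ellipse radius profile
  ax <- stats::runif(1, 0.30, 0.38)
  ay <- stats::runif(1, 0.22, 0.30)
  a2 <- stats::runif(1, -0.06, 0.06)
  a3 <- stats::runif(1, -0.04, 0.04)
  p2 <- stats::runif(1, 0, 2 * pi)
  p3 <- stats::runif(1, 0, 2 * pi)
  r_fossa <- ellipse_radius(theta, ax, ay) *
    (1 + a2 * cos(2 * theta + p2) + a3 * cos(3 * theta + p3))
  fossa <- rr < r_fossa
  fossa_area <- sum(fossa)
  if (fossa_area < 64L) stop("degenerate fossa geometry", call. = FALSE)

  # muscle: radially scaled copy of the fossa profile; bisection on the
  # scale so the pixel-count occupation ratio hits the target
  target <- spec$occupation_ratio_true * fossa_area
  lo <- 0
  hi <- 1
  for (i in 1:48) {
    mid <- (lo + hi) / 2
    area <- sum(rr < mid * r_fossa)
    if (area < target) lo <- mid else hi <- mid
  }
  s_lo <- sum(rr < lo * r_fossa)
  s_hi <- sum(rr < hi * r_fossa)
  s <- if (abs(s_lo - target) < abs(s_hi - target)) lo else hi
  muscle <- rr < s * r_fossa
  muscle_area <- sum(muscle)
  if (muscle_area < 16L ||
      abs(muscle_area - target) / target > 0.01) {
    stop("cannot realize the requested occupation ratio on this grid",
         call. = FALSE)
  }

  # clustered fat specks inside the muscle, exact pixel budget
  n_fat <- round(spec$fat_fraction_true * muscle_area)
  fat_levels <- spec$fat_intensity_levels %||% spec$fat_intensity_mean
  fat_assign <- place_fat_clusters(muscle, n_fat, spec$cluster_scale,
                                   length(fat_levels))
  fat_mask <- fat_assign > 0L

  img <- matrix(spec$background_intensity, n, n)
  img[fossa] <- spec$fossa_intensity_mean
  img[muscle] <- spec$muscle_intensity_mean
  if (n_fat > 0L) img[fat_mask] <- fat_levels[fat_assign[fat_mask]]

  # distractors: fat-bright blobs outside the muscle (never touching it)
  if (spec$n_distractors > 0L) {
    forbidden <- dilate_mask(muscle, 2L)
    for (d in seq_len(spec$n_distractors)) {
      ang <- stats::runif(1, 0, 2 * pi)
      rad <- ellipse_radius(ang, ax, ay) *
        (1 + a2 * cos(2 * ang + p2) + a3 * cos(3 * ang + p3))
      rho <- rad * s * stats::runif(1, 1.15, 1.45)
      bx <- cx + rho * n * cos(ang)
      by <- cy + rho * n * sin(ang)
      br <- stats::runif(1, 0.008, 0.02) * n + 1
      blob <- (xs - bx)^2 + (ys - by)^2 < br^2
      blob <- blob & !forbidden
      img[blob] <- fat_levels[1L]
    }
  }

  if (spec$intensity_sd > 0) {
    img <- img + stats::rnorm(n * n, 0, spec$intensity_sd)
  }
  img <- pmin(pmax(round_half_up(img), 0), 255)
  dim(img) <- c(n, n)

  structure(
    list(
      slice = grayscale_slice(img,
        source_id = sprintf("phantom-%d", spec$seed),
        meta = list(synthetic = TRUE)
      ),
      masks = region_masks(fossa, muscle, ground_truth = TRUE),
      fat_mask_true = fat_mask,
      spec = spec
    ),
    class = "phantom_case"
  )
}

ellipse_radius <- function(theta, ax, ay) {
  1 / sqrt((cos(theta) / ax)^2 + (sin(theta) / ay)^2)
}

# Grow clustered specks until exactly n_fat muscle pixels are fat.
# Returns an integer matrix: 0 = not fat, k >= 1 = fat at level index k.
place_fat_clusters <- function(muscle, n_fat, cluster_scale, n_levels) {
  out <- array(0L, dim(muscle))
  if (n_fat <= 0L) return(out)
  idx <- which(muscle)
  nr <- nrow(muscle)
  placed <- 0L
  level <- 0L
  guard <- 0L
  while (placed < n_fat) {
    guard <- guard + 1L
    if (guard > 100L * n_fat + 1000L) {
      stop("fat placement failed to converge", call. = FALSE)
    }
    centre <- idx[sample.int(length(idx), 1L)]
    ci <- (centre - 1L) %% nr + 1L
    cj <- (centre - 1L) %/% nr + 1L
    rad <- sample.int(cluster_scale, 1L) + stats::runif(1, 0, 1)
    ii <- max(1L, ci - ceiling(rad)):min(nr, ci + ceiling(rad))
    jj <- max(1L, cj - ceiling(rad)):min(ncol(muscle), cj + ceiling(rad))
    sub <- expand.grid(i = ii, j = jj)
    d2 <- (sub$i - ci)^2 + (sub$j - cj)^2
    sub <- sub[d2 < rad^2, , drop = FALSE]
    d2 <- d2[d2 < rad^2]
    lin <- sub$i + (sub$j - 1L) * nr
    keep <- muscle[lin] & out[lin] == 0L
    lin <- lin[keep]
    d2 <- d2[keep]
    if (length(lin) == 0L) next
    if (placed + length(lin) > n_fat) {
      # trim the blob from the rim inward to land exactly on the budget
      need <- n_fat - placed
      lin <- lin[order(d2)][seq_len(need)]
    }
    level <- level %% n_levels + 1L
    out[lin] <- level
    placed <- placed + length(lin)
  }
  out
}

# binary dilation by a (2k+1)x(2k+1) square structuring element, via shifts
dilate_mask <- function(mask, k) {
  out <- mask
  nr <- nrow(mask)
  nc <- ncol(mask)
  for (di in -k:k) {
    for (dj in -k:k) {
      if (di == 0L && dj == 0L) next
      src_i <- max(1L, 1L - di):min(nr, nr - di)
      src_j <- max(1L, 1L - dj):min(nc, nc - dj)
      out[src_i + di, src_j + dj] <-
        out[src_i + di, src_j + dj] | mask[src_i, src_j]
    }
  }
  out
}

#' @export
print.phantom_case <- function(x, ...) {
  cat(sprintf(
    "<phantom_case seed %d> %dx%d, OR true %.3f, FF true %.3f, fat px %d\n",
    x$spec$seed, x$spec$image_size, x$spec$image_size,
    x$spec$occupation_ratio_true, x$spec$fat_fraction_true,
    sum(x$fat_mask_true)
  ))
  invisible(x)
}

#' Generate a cohort of phantoms
#'
#' Draws per-case occupation ratios and fat fractions and generates one
#' phantom per draw. In `"negative"` coupling mode the two parameters
#' follow a linear negative trend with Gaussian jitter — emulating the
#' clinical pattern that atrophied (low occupation ratio) muscles carry
#' more fat — plus a configurable fraction of discordant outlier cases
#' (high occupation ratio with high fat, and the reverse). In
#' `"independent"` mode both are drawn independently and uniformly.
#'
#' The functional form in negative mode: OR ~ U(0.30, 0.95);
#' FF = 0.62 * (0.95 - OR) / 0.65 + N(0, 0.06), clipped to [0, 0.65];
#' outlier cases replace FF with 0.62 - FF (reflection across the trend).
#'
#' @param n number of cases (>= 2).
#' @param coupling `"negative"` (default) or `"independent"`.
#' @param seed integer master seed; per-case seeds are derived from it.
#' @param outlier_fraction fraction of discordant cases in negative mode.
#' @param image_size,intensity_sd,n_distractors passed to each
#'   [phantom_spec()].
#' @param ... further arguments passed to [phantom_spec()].
#' @return list of `phantom_case` objects; attribute `"truth"` carries a
#'   data frame of the drawn parameters (case_id, or_true, ff_true,
#'   grade_bin).
#' @export
generate_cohort <- function(n, coupling = c("negative", "independent"),
                            seed = 1L, outlier_fraction = 0.06,
                            image_size = 512L, intensity_sd = 8,
                            n_distractors = 3L, ...) {
  coupling <- match.arg(coupling)
  if (n < 2L) stop("a cohort needs at least 2 cases", call. = FALSE)
  params <- with_seed(seed, {
    or_true <- stats::runif(n, 0.30, 0.95)
    if (coupling == "negative") {
      ff <- 0.62 * (0.95 - or_true) / 0.65 + stats::rnorm(n, 0, 0.06)
      ff <- pmin(pmax(ff, 0), 0.65)
      n_out <- round(outlier_fraction * n)
      if (n_out > 0L) {
        out_idx <- sample.int(n, n_out)
        ff[out_idx] <- pmin(pmax(0.62 - ff[out_idx], 0), 0.65)
      }
    } else {
      ff <- stats::runif(n, 0, 0.65)
    }
    list(or_true = or_true, ff_true = ff,
         case_seeds = sample.int(2^30, n))
  })
  cases <- vector("list", n)
  for (i in seq_len(n)) {
    spec <- phantom_spec(
      image_size = image_size,
      occupation_ratio_true = params$or_true[i],
      fat_fraction_true = params$ff_true[i],
      intensity_sd = intensity_sd,
      n_distractors = n_distractors,
      seed = params$case_seeds[i],
      ...
    )
    cases[[i]] <- generate_phantom(spec)
    cases[[i]]$slice$source_id <- sprintf("case-%03d", i)
  }
  truth <- data.frame(
    case_id = sprintf("case-%03d", seq_len(n)),
    or_true = params$or_true,
    ff_true = params$ff_true,
    grade_bin = grade_from_fat_fraction(params$ff_true),
    stringsAsFactors = FALSE
  )
  attr(cases, "truth") <- truth
  cases
}

#' Map a fat fraction to a Goutallier-like ordinal bin
#'
#' Coarse binning used only to give phantom cohorts grade-like labels for
#' the statistics layer: 0 below 2% fat, 1 below 10%, 2 below 30%, 3 below
#' 50% (roughly equal fat and muscle), 4 at or above 50%.
#'
#' @param ff numeric vector of fat fractions in `[0, 1]`.
#' @return integer vector of bins in 0..4.
#' @export
grade_from_fat_fraction <- function(ff) {
  findInterval(ff, c(0.02, 0.10, 0.30, 0.50))
}

#' Write a phantom case to disk
#'
#' Emits the slice as 8-bit PNG, the ground-truth masks as an integer
#' NIfTI label map (1 = fossa, 2 = muscle), and a JSON truth sidecar with
#' the generative parameters and the realized areas.
#'
#' @param case a `phantom_case`.
#' @param dir output directory (created if needed).
#' @param stem file-name stem; default the slice's source id.
#' @return named character vector of the written paths, invisibly.
#' @export
write_phantom_case <- function(case, dir, stem = NULL) {
  stopifnot(inherits(case, "phantom_case"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  stem <- stem %||% case$slice$source_id
  p_img <- file.path(dir, paste0(stem, ".png"))
  p_lab <- file.path(dir, paste0(stem, "_labels.nii.gz"))
  p_json <- file.path(dir, paste0(stem, "_truth.json"))
  write_slice_png(case$slice, p_img)
  write_label_map(case$masks, p_lab)
  truth <- list(
    source_id = case$slice$source_id,
    synthetic = TRUE,
    occupation_ratio_true = case$spec$occupation_ratio_true,
    fat_fraction_true = case$spec$fat_fraction_true,
    fossa_area_px = sum(case$masks$fossa),
    muscle_area_px = sum(case$masks$muscle),
    fat_area_px = sum(case$fat_mask_true),
    seed = case$spec$seed
  )
  jsonlite::write_json(truth, p_json, auto_unbox = TRUE, digits = NA)
  invisible(c(image = p_img, labels = p_lab, truth = p_json))
}
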