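# Independent oracles and small fixture builders shared across tests.

# Exhaustive Otsu oracle: recompute class weights and means from first
# principles at every candidate threshold, without the cumulative-sum
# shortcut used by the implementation. Same contract: class 0 is <= t,
# ties to the lowest maximizer, single-occupied-level histogram returns
# that level.
oracle_otsu <- function(hist) {
  levels <- 0:255
  occupied <- which(hist > 0)
  if (length(occupied) == 1L) return(occupied - 1L)
  n <- sum(hist)
  v <- numeric(256)
  for (t in 0:255) {
    in0 <- levels <= t
    n0 <- sum(hist[in0])
    n1 <- n - n0
    if (n0 > 0 && n1 > 0) {
      mu0 <- sum(hist[in0] * levels[in0]) / n0
      mu1 <- sum(hist[!in0] * levels[!in0]) / n1
      v[t + 1L] <- (n0 / n) * (n1 / n) * (mu0 - mu1)^2
    }
  }
  # lowest maximizer, exact ties identified up to round-off
  which(v >= max(v) - max(v) * 1e-9)[1L] - 1L
}

# Brute-force confusion matrix by explicit pixel enumeration.
oracle_confusion <- function(gt, pred) {
  tp <- 0L; fp <- 0L; tn <- 0L; fn <- 0L
  for (i in seq_along(gt)) {
    if (gt[i] && pred[i]) tp <- tp + 1L
    else if (!gt[i] && pred[i]) fp <- fp + 1L
    else if (gt[i] && !pred[i]) fn <- fn + 1L
    else tn <- tn + 1L
  }
  c(tp = tp, fp = fp, tn = tn, fn = fn)
}

# Build a slice from a pixel matrix, padding to the 32x32 minimum.
make_slice <- function(px, id = "fix") {
  if (nrow(px) < 32L || ncol(px) < 32L) {
    m <- matrix(0L, max(32L, nrow(px)), max(32L, ncol(px)))
    m[seq_len(nrow(px)), seq_len(ncol(px))] <- px
    px <- m
  }
  grayscale_slice(px, source_id = id)
}

# Slice + rectangular ROI mask holding the given intensity values (in
# order); the rest of the image is zero.
roi_fixture <- function(values, ncol_roi = length(values)) {
  stopifnot(length(values) %% ncol_roi == 0)
  nr <- length(values) / ncol_roi
  px <- matrix(0L, max(32L, nr), max(32L, ncol_roi))
  mask <- matrix(FALSE, nrow(px), ncol(px))
  px[seq_len(nr), seq_len(ncol_roi)] <- matrix(values, nr, ncol_roi)
  mask[seq_len(nr), seq_len(ncol_roi)] <- TRUE
  list(slice = grayscale_slice(px, source_id = "roi-fix"), mask = mask)
}

random_mask <- function(h, w, p = 0.3) {
  matrix(stats::runif(h * w) < p, h, w)
}

tiny_phantom <- function(seed = 1L, ...) {
  generate_phantom(phantom_spec(image_size = 128L, seed = seed, ...))
}
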