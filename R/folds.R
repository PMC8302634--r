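#' Balanced k-fold splits
#'
#' Randomly partitions the ids into `k` disjoint folds covering the corpus,
#' with sizes differing by at most one (240 ids and `k = 10` give ten folds
#' of 24). Deterministic given `seed`; validation ids are never duplicated
#' across folds.
#'
#' @param ids character or integer vector of case ids (no duplicates).
#' @param k number of folds (default 10).
#' @param seed integer seed.
#' @return An object of class `fold_split`: list with `k` and `folds`, a
#'   list of `k` id vectors.
#' @export
make_fold_splits <- function(ids, k = 10L, seed = 1L) {
  if (anyDuplicated(ids)) stop("ids must be unique", call. = FALSE)
  n <- length(ids)
  if (k > n) stop("k cannot exceed the number of ids", call. = FALSE)
  if (k < 2L) stop("k must be at least 2", call. = FALSE)
  perm <- with_seed(seed, sample.int(n))
  sizes <- diff(floor(seq(0, n, length.out = k + 1)))
  folds <- split(ids[perm], rep(seq_len(k), times = sizes))
  names(folds) <- sprintf("fold%02d", seq_len(k))
  structure(list(k = as.integer(k), folds = folds), class = "fold_split")
}

#' @export
print.fold_split <- function(x, ...) {
  cat(sprintf("<fold_split> k = %d, sizes: %s\n", x$k,
              paste(lengths(x$folds), collapse = ", ")))
  invisible(x)
}
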