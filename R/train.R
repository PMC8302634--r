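# Training loop (Adam) and the k-fold cross-validation harness.

adam_init <- function(params) {
  lapply(params, function(l) {
    zW <- if (is.list(l$W)) lapply(l$W, function(w) w * 0) else l$W * 0
    list(mW = zW, vW = zW, mb = l$b * 0, vb = l$b * 0)
  })
}

adam_step <- function(params, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  upd <- function(theta, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    theta <- theta - lr * (m / bc1) / (sqrt(v / bc2) + eps)
    list(theta = theta, m = m, v = v)
  }
  for (nm in names(grads)) {
    l <- params[[nm]]
    g <- grads[[nm]]
    s <- state[[nm]]
    if (is.list(l$W)) {
      for (k in seq_along(l$W)) {
        u <- upd(l$W[[k]], g$dW[[k]], s$mW[[k]], s$vW[[k]])
        l$W[[k]] <- u$theta
        s$mW[[k]] <- u$m
        s$vW[[k]] <- u$v
      }
    } else {
      u <- upd(l$W, g$dW, s$mW, s$vW)
      l$W <- u$theta
      s$mW <- u$m
      s$vW <- u$v
    }
    u <- upd(l$b, g$db, s$mb, s$vb)
    l$b <- u$theta
    s$mb <- u$m
    s$vb <- u$v
    params[[nm]] <- l
    state[[nm]] <- s
  }
  list(params = params, state = state)
}

case_target <- function(case) {
  cbind(as.numeric(case$masks$fossa), as.numeric(case$masks$muscle))
}

#' Train the network on a set of cases
#'
#' Per-image Adam on a per-pixel, per-channel binary cross-entropy loss.
#' The two output channels (fossa, muscle) are non-exclusive sigmoid
#' channels: the muscle lies inside the fossa, so exclusive softmax labels
#' would be ill-posed. Fully deterministic given `seed`.
#'
#' @param model an `fcn_model` from [build_fcn()].
#' @param cases list of cases, each with `slice` and `masks`.
#' @param epochs number of passes over the cases.
#' @param lr Adam learning rate.
#' @param seed seed for the epoch shuffling.
#' @param verbose print the running loss every few epochs.
#' @return The trained `fcn_model`, with a `history` element (mean loss
#'   per epoch) and `trained_on` (the source ids seen during training).
#' @export
fcn_train <- function(model, cases, epochs = 100L, lr = 3e-3, seed = 1L,
                      verbose = FALSE) {
  state <- adam_init(model$params)
  targets <- lapply(cases, case_target)
  history <- numeric(epochs)
  t_step <- 0L
  order_seeds <- with_seed(seed, sample.int(2^30, epochs))
  for (ep in seq_len(epochs)) {
    ord <- with_seed(order_seeds[ep], sample.int(length(cases)))
    losses <- numeric(length(ord))
    for (ii in seq_along(ord)) {
      i <- ord[ii]
      fwd <- fcn_forward(model, cases[[i]]$slice, keep_cache = TRUE)
      y <- targets[[i]]
      pr <- pmin(pmax(fwd$prob, 1e-12), 1 - 1e-12)
      losses[ii] <- -mean(y * log(pr) + (1 - y) * log(1 - pr))
      grads <- fcn_backward(model, fwd, y)
      t_step <- t_step + 1L
      st <- adam_step(model$params, grads, state, lr, t_step)
      model$params <- st$params
      state <- st$state
    }
    history[ep] <- mean(losses)
    if (verbose && (ep %% 10L == 0L || ep == 1L)) {
      message(sprintf("epoch %d/%d  loss %.5f", ep, epochs, history[ep]))
    }
  }
  model$history <- history
  model$trained_on <- vapply(cases, function(c) c$slice$source_id,
                             character(1))
  model
}

#' Predict fossa/muscle masks for a slice
#'
#' Runs the forward pass and binarizes the two sigmoid score channels at
#' `threshold` (default 0.5). Predictions are independent per channel and
#' may violate the muscle-in-fossa containment; the violation count is
#' carried in the returned masks.
#'
#' @param model a trained `fcn_model`.
#' @param slice a [grayscale_slice()].
#' @param threshold score threshold in `(0, 1)`.
#' @return A [region_masks()] object (with `ground_truth = FALSE`), or
#'   `NULL` masks replaced by all-false when a channel predicts nothing
#'   (returned as a plain list with `empty = TRUE` in that case).
#' @export
fcn_predict <- function(model, slice, threshold = 0.5) {
  fwd <- fcn_forward(model, slice)
  fossa <- matrix(fwd$prob[, 1L] >= threshold, fwd$H, fwd$W)
  muscle <- matrix(fwd$prob[, 2L] >= threshold, fwd$H, fwd$W)
  if (!any(fossa) || !any(muscle)) {
    return(list(fossa = fossa, muscle = muscle, empty = TRUE,
                containment_violations = sum(muscle & !fossa)))
  }
  region_masks(fossa, muscle, ground_truth = FALSE)
}

#' k-fold cross-validated training and evaluation
#'
#' The evaluation harness: for each fold, a fresh network is trained on
#' the remaining folds (optionally tenfold-augmented; brightness stages
#' are computed on the training fold only) and evaluated on the held-out
#' originals with the segmentation metrics. Validation images are never
#' augmented and never contribute a gradient; each fold's provenance is
#' recorded so the leakage guard can be audited.
#'
#' @param cases named-by-id list of cases (each with `slice`, `masks`).
#' @param splits a `fold_split` over the case ids.
#' @param config an [fcn_config()] for the per-fold models.
#' @param epochs,lr training schedule per fold.
#' @param seed master seed; per-fold seeds derive from it.
#' @param augment apply [augment_training_fold()] to each training fold.
#' @param threshold prediction binarization threshold.
#' @return list with `per_case` (data frame: fold, case_id, region, dsc,
#'   accuracy, sensitivity, specificity, rad_pct), `summary` (mean and SD
#'   per region across cases), `fold_provenance` (per fold: validation
#'   ids, training parent ids), and `mean_dsc`.
#' @export
train_and_validate <- function(cases, splits, config, epochs = 60L,
                               lr = 3e-3, seed = 1L, augment = FALSE,
                               threshold = 0.5) {
  stopifnot(inherits(splits, "fold_split"))
  ids <- vapply(cases, function(c) c$slice$source_id, character(1))
  names(cases) <- ids
  all_ids <- unlist(splits$folds, use.names = FALSE)
  if (!setequal(all_ids, ids)) {
    stop("fold split does not cover the case ids", call. = FALSE)
  }
  fold_seeds <- with_seed(seed, sample.int(2^30, splits$k))
  rows <- list()
  prov <- list()
  for (f in seq_len(splits$k)) {
    val_ids <- splits$folds[[f]]
    if (length(val_ids) == 0L) stop("empty fold", call. = FALSE)
    train_ids <- setdiff(ids, val_ids)
    train_cases <- cases[train_ids]
    if (augment) {
      stages <- assign_brightness_stages(
        lapply(train_cases, function(c) c$slice),
        n_stages = min(5L, length(train_cases))
      )
      train_cases <- augment_training_fold(train_cases, stages)
    }
    model <- build_fcn(config, seed = fold_seeds[f])
    model <- fcn_train(model, train_cases, epochs = epochs, lr = lr,
                       seed = fold_seeds[f])
    parents <- if (augment) {
      unique(vapply(train_cases, function(c) c$provenance$parent_id,
                    character(1)))
    } else train_ids
    prov[[f]] <- list(fold = f, validation_ids = val_ids,
                      training_parent_ids = parents)
    for (id in val_ids) {
      pred <- fcn_predict(model, cases[[id]]$slice, threshold = threshold)
      for (region in c("fossa", "muscle")) {
        rep_ <- seg_metric_report(cases[[id]]$masks[[region]],
                                  pred[[region]], region = region)
        rows[[length(rows) + 1L]] <- data.frame(
          fold = f, case_id = id, region = region, dsc = rep_$dsc,
          accuracy = rep_$accuracy, sensitivity = rep_$sensitivity,
          specificity = rep_$specificity, rad_pct = rep_$rad_pct,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  per_case <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(per_case, per_case$region),
                                function(d) {
    data.frame(
      region = d$region[1L],
      dsc_mean = mean(d$dsc), dsc_sd = stats::sd(d$dsc),
      accuracy_mean = mean(d$accuracy), accuracy_sd = stats::sd(d$accuracy),
      sensitivity_mean = mean(d$sensitivity),
      sensitivity_sd = stats::sd(d$sensitivity),
      specificity_mean = mean(d$specificity),
      specificity_sd = stats::sd(d$specificity),
      rad_mean = mean(d$rad_pct), rad_sd = stats::sd(d$rad_pct),
      stringsAsFactors = FALSE
    )
  }))
  rownames(summ) <- NULL
  list(per_case = per_case, summary = summ, fold_provenance = prov,
       mean_dsc = mean(per_case$dsc))
}
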