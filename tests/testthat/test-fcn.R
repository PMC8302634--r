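test_that("network configs expose the stated layer counts and shapes", {
  full <- fcn_config("full", 512L)
  expect_identical(full$conv_layers, 15L)
  expect_identical(full$pool_layers, 5L)
  expect_identical(full$head_layers, 3L)
  expect_identical(full$skip_sources, c("pool3", "pool4"))
  expect_identical(fcn_output_shape(full), c(512L, 512L, 2L))
  # the untruncated VGG19 encoder variant has 16 convolutions
  expect_identical(fcn_config("full", vgg19_full = TRUE)$conv_layers, 16L)
  expect_error(fcn_config("small", in_size = 100L), "divisible by 32")
  expect_error(fcn_output_shape(full, 100L), "divisible by 32")
})

test_that("parameter count is deterministic and matches layer arithmetic", {
  cfg <- fcn_config("small", 64L)
  m1 <- build_fcn(cfg, seed = 4L)
  m2 <- build_fcn(cfg, seed = 4L)
  expect_identical(m1$params, m2$params)

  # recompute the expected count from the architecture
  conv3 <- function(cin, cout) 9 * cin * cout + cout
  conv1 <- function(cin, cout) cin * cout + cout
  ch <- cfg$channels
  hc <- cfg$head_channels
  expected <- conv3(1, ch[1]) + conv3(ch[1], ch[2]) + conv3(ch[2], ch[3]) +
    conv3(ch[3], ch[4]) + conv3(ch[4], ch[5]) +
    conv3(ch[5], hc) + conv1(hc, hc) + conv1(hc, 2) +
    conv1(ch[4], 2) + conv1(ch[3], 2) +
    3 * conv3(2, 2)
  expect_identical(fcn_parameter_count(m1), expected)
})

test_that("forward pass honors the shape contract and stays finite", {
  m <- build_fcn(fcn_config("small", 64L), seed = 1L)
  fwd <- fcn_forward(m, matrix(0, 64, 64))
  expect_identical(dim(fwd$logits), c(64L * 64L, 2L))
  expect_true(all(is.finite(fwd$logits)))
  expect_true(all(fwd$prob >= 0 & fwd$prob <= 1))
  expect_error(fcn_forward(m, matrix(0, 50, 50)), "divisible by 32")
})

test_that("analytic gradients match numerical differentiation", {
  set.seed(23)
  m <- build_fcn(fcn_config("small", 64L), seed = 5L)
  img <- matrix(runif(64 * 64), 64, 64)
  y <- cbind(as.numeric(runif(64 * 64) > 0.5),
             as.numeric(runif(64 * 64) > 0.5))
  loss_of <- function(model) {
    fwd <- fcn_forward(model, img)
    pr <- pmin(pmax(fwd$prob, 1e-12), 1 - 1e-12)
    -mean(y * log(pr) + (1 - y) * log(1 - pr))
  }
  fwd <- fcn_forward(m, img, keep_cache = TRUE)
  gr <- fcn_backward(m, fwd, y)
  base <- loss_of(m)
  eps <- 1e-6
  probes <- list(
    list("enc1_1", 5L, 2L), list("enc4_1", 7L, 11L),
    list("head1", 4L, 3L), list("up_final", 2L, 1L)
  )
  for (p in probes) {
    m2 <- m
    m2$params[[p[[1]]]]$W[[p[[2]]]][p[[3]]] <-
      m2$params[[p[[1]]]]$W[[p[[2]]]][p[[3]]] + eps
    num <- (loss_of(m2) - base) / eps
    ana <- gr[[p[[1]]]]$dW[[p[[2]]]][p[[3]]]
    expect_lt(abs(ana - num), 1e-4 * max(1, abs(num)))
  }
  for (nm in c("score", "score_pool3")) {
    m2 <- m
    m2$params[[nm]]$W[2L] <- m2$params[[nm]]$W[2L] + eps
    num <- (loss_of(m2) - base) / eps
    expect_lt(abs(gr[[nm]]$dW[2L] - num), 1e-4 * max(1, abs(num)))
  }
})

test_that("training a single phantom overfits it and feeds the pipeline", {
  pc <- generate_phantom(phantom_spec(image_size = 64L, intensity_sd = 0,
                                      n_distractors = 0L, seed = 500L))
  case <- list(slice = pc$slice, masks = pc$masks)
  m <- build_fcn(fcn_config("small", 64L), seed = 2L)
  m <- fcn_train(m, list(case), epochs = 40L, lr = 5e-3, seed = 2L)
  expect_true(tail(m$history, 1) < m$history[1])
  pred <- fcn_predict(m, pc$slice)
  expect_s3_class(pred, "region_masks")
  expect_gt(dice(pc$masks$muscle, pred$muscle), 0.85)
  # predicted masks post-process without shape adaptation
  expect_gt(occupation_ratio(pred), 0)
  fi <- quantify_fat(pc$slice, pred$muscle)
  expect_true(fi$fatty_infiltration_pct >= 0 &&
                fi$fatty_infiltration_pct <= 100)
})

test_that("training is deterministic under fixed seeds", {
  pc <- generate_phantom(phantom_spec(image_size = 64L, intensity_sd = 0,
                                      n_distractors = 0L, seed = 501L))
  case <- list(slice = pc$slice, masks = pc$masks)
  run <- function() {
    m <- build_fcn(fcn_config("small", 64L), seed = 3L)
    m <- fcn_train(m, list(case), epochs = 5L, lr = 5e-3, seed = 3L)
    fcn_forward(m, pc$slice)$logits
  }
  expect_identical(run(), run())
})

test_that("cross-validation audits provenance and reports per fold", {
  cases <- lapply(1:4, function(i) {
    pc <- generate_phantom(phantom_spec(image_size = 64L, intensity_sd = 0,
                                        n_distractors = 0L,
                                        seed = 600L + i))
    pc$slice$source_id <- sprintf("cv-%d", i)
    list(slice = pc$slice, masks = pc$masks)
  })
  ids <- vapply(cases, function(c) c$slice$source_id, character(1))
  splits <- make_fold_splits(ids, k = 2L, seed = 9L)
  cv <- train_and_validate(cases, splits, fcn_config("small", 64L),
                           epochs = 8L, lr = 5e-3, seed = 9L,
                           augment = TRUE)
  expect_identical(nrow(cv$per_case), 8L) # 4 cases x 2 regions
  expect_identical(sort(unique(cv$per_case$region)), c("fossa", "muscle"))
  # leakage guard: no validation id among the training parents
  for (pr in cv$fold_provenance) {
    expect_length(intersect(pr$validation_ids, pr$training_parent_ids), 0L)
  }
  expect_identical(nrow(cv$summary), 2L)
})
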