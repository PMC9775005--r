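test_that("build_model partitions the backbone into the three-part scheme", {
  m <- build_model("dan", "smallnet", input_shape = c(64L, 64L, 1L), seed = 1)
  stages <- vapply(m$layers, `[[`, "", "stage")
  # frozen prefix, then finetune, then adapt: no interleaving
  expect_equal(rle(stages)$values, c("frozen", "finetune", "adapt"))
  # three adaptation hooks: both hidden fc activations and the logits
  hooked <- vapply(m$layers, function(l) isTRUE(l$hook), TRUE)
  expect_equal(sum(hooked), 3)
  expect_true(all(stages[hooked] == "adapt"))
  # logits layer matches the class count
  expect_equal(m$layers[[length(m$layers)]]$out_shape, 2L)
  # discriminator exists only for dann
  expect_null(m$discriminator)
  expect_false(is.null(build_model("dann", seed = 1)$discriminator))
  # weight init is seed-deterministic
  m2 <- build_model("dan", "smallnet", input_shape = c(64L, 64L, 1L), seed = 1)
  expect_identical(stage_param_vector(m, "finetune"),
                   stage_param_vector(m2, "finetune"))
  expect_error(build_model("dan", input_shape = c(60L, 64L, 1L)),
               class = "eegdan_invalid_argument")
})

test_that("2x2 max pooling picks maxima and routes gradients to them", {
  lay <- eegdan:::layer_pool(2L, 2L, 1L, "frozen")
  X <- matrix(c(1, 4, 2, 3), ncol = 1)  # column-major 2x2 block
  fw <- eegdan:::layer_forward(lay, X)
  expect_equal(as.numeric(fw$out), 4)
  bk <- eegdan:::layer_backward(lay, matrix(5, 1, 1), fw$cache)
  expect_equal(as.numeric(bk$dX), c(0, 5, 0, 0))
})

test_that("gain-2 average pooling averages and spreads gradients evenly", {
  lay <- eegdan:::layer_pool(2L, 2L, 1L, "frozen", op = "avg")
  X <- matrix(c(1, 4, 2, 3), ncol = 1)
  fw <- eegdan:::layer_forward(lay, X)
  expect_equal(as.numeric(fw$out), 2 * mean(X))
  bk <- eegdan:::layer_backward(lay, matrix(4, 1, 1), fw$cache)
  expect_equal(as.numeric(bk$dX), rep(2, 4))
})

test_that("weight decay shrinks weights and leaves biases alone", {
  imgs <- toy_images(4)
  m0 <- build_model("source_only", input_shape = c(64L, 64L, 1L), seed = 12)
  cfg0 <- train_config(epochs = 5, seed = 2, weight_decay = 0)
  cfgw <- train_config(epochs = 5, seed = 2, weight_decay = 0.05)
  m_plain <- train(m0, imgs, imgs, cfg0)
  m_decay <- train(m0, imgs, imgs, cfgw)
  w_plain <- sum(stage_param_vector(m_plain, "adapt")^2)
  w_decay <- sum(stage_param_vector(m_decay, "adapt")^2)
  expect_lt(w_decay, w_plain)
  expect_error(train_config(weight_decay = -1),
               class = "eegdan_invalid_argument")
})

test_that("network gradients agree with finite differences", {
  set.seed(6)
  m <- build_model("source_only", "smallnet", input_shape = c(32L, 32L, 1L),
                   seed = 2)
  X <- matrix(runif(32 * 32 * 2), ncol = 2)
  y <- c(1L, 2L)
  loss_of <- function(model) {
    P <- eegdan:::softmax_cols(eegdan:::run_layers(model$layers, X)$out)
    -mean(log(P[cbind(y, 1:2)]))
  }
  fw <- eegdan:::run_layers(m$layers, X, keep_cache = TRUE)
  P <- eegdan:::softmax_cols(fw$out)
  G <- P; G[cbind(y, 1:2)] <- G[cbind(y, 1:2)] - 1; G <- G / 2
  grads <- vector("list", length(m$layers))
  dOut <- G
  for (j in rev(seq_along(m$layers))) {
    r <- eegdan:::layer_backward(m$layers[[j]], dOut, fw$caches[[j]],
                                 need_dx = j > 1)
    grads[[j]] <- r$grads
    dOut <- r$dX
  }
  eps <- 1e-5
  for (j in seq_along(m$layers)) {
    for (pn in names(m$layers[[j]]$params)) {
      i <- sample(length(m$layers[[j]]$params[[pn]]), 1)
      mp <- m; mp$layers[[j]]$params[[pn]][i] <-
        mp$layers[[j]]$params[[pn]][i] + eps
      mm <- m; mm$layers[[j]]$params[[pn]][i] <-
        mm$layers[[j]]$params[[pn]][i] - eps
      num <- (loss_of(mp) - loss_of(mm)) / (2 * eps)
      expect_equal(grads[[j]][[pn]][i], num, tolerance = 1e-4,
                   label = sprintf("layer %d param %s", j, pn))
    }
  }
})

test_that("frozen parameters are bit-identical after training", {
  imgs <- toy_images(4)
  m <- build_model("dan", input_shape = c(64L, 64L, 1L), seed = 3)
  before_frozen <- stage_param_vector(m, "frozen")
  before_ft <- stage_param_vector(m, "finetune")
  tr <- train(m, imgs, imgs, train_config(epochs = 3, seed = 1, lambda = 0.1))
  expect_identical(stage_param_vector(tr, "frozen"), before_frozen)
  # while the trainable stages actually moved
  expect_false(identical(stage_param_vector(tr, "finetune"), before_ft))
})

test_that("lambda_warmup disables adaptation for the warm-up fraction", {
  imgs <- toy_images(4)
  tgt <- toy_images(4, seed = 8)  # distinct target set so MK-MMD > 0
  cfg <- train_config(epochs = 4, seed = 13, lambda = 0.5,
                      lambda_schedule = "constant", lambda_warmup = 0.5)
  m <- train(build_model("dan", input_shape = c(64L, 64L, 1L), seed = 14),
             imgs, tgt, cfg)
  # epochs 1-2 are within the warm-up (p <= 0.5): no adaptation loss
  expect_equal(m$log$adapt_loss[1:2], c(0, 0))
  expect_true(all(m$log$adapt_loss[3:4] > 0))
  # and they coincide with the source_only trajectory
  ms <- train(build_model("source_only", input_shape = c(64L, 64L, 1L),
                          seed = 14),
              imgs, tgt, cfg)
  expect_identical(m$log$cls_loss[1:2], ms$log$cls_loss[1:2])
  expect_error(train_config(lambda_warmup = 1),
               class = "eegdan_invalid_argument")
})

test_that("dan with lambda 0 reproduces the source_only trajectory exactly", {
  imgs <- toy_images(4)
  cfg <- train_config(epochs = 4, seed = 7, lambda = 0)
  m1 <- train(build_model("dan", input_shape = c(64L, 64L, 1L), seed = 5),
              imgs, imgs, cfg)
  m2 <- train(build_model("source_only", input_shape = c(64L, 64L, 1L), seed = 5),
              imgs, imgs, cfg)
  expect_identical(m1$log$cls_loss, m2$log$cls_loss)
  expect_identical(stage_param_vector(m1, "adapt"),
                   stage_param_vector(m2, "adapt"))
})

test_that("the model can overfit a small separable image set", {
  imgs <- toy_images(8)
  m <- train(build_model("source_only", input_shape = c(64L, 64L, 1L), seed = 4),
             imgs, imgs, train_config(epochs = 30, seed = 2))
  pr <- predict(m, imgs)
  truth <- vapply(imgs, function(i) as.character(i$label), "")
  expect_equal(mean(as.character(pr$pred) == truth), 1.0)
  expect_true(all(abs(pr$score_healthy + pr$score_depressed - 1) < 1e-12))
  # training losses decreased
  expect_lt(tail(m$log$cls_loss, 1), m$log$cls_loss[1])
})

test_that("every method runs one epoch and logs both loss terms", {
  imgs <- toy_images(4)
  for (meth in c("dan", "dann", "deepcoral", "source_only")) {
    m <- train(build_model(meth, input_shape = c(64L, 64L, 1L), seed = 6),
               imgs, imgs,
               train_config(epochs = 1, seed = 3, lambda = 0.5,
                            lambda_schedule = "constant"))
    expect_true(is.finite(m$log$cls_loss))
    expect_true(is.finite(m$log$adapt_loss))
    if (meth == "source_only") expect_equal(m$log$adapt_loss, 0)
    expect_length(m$curve, 1)
  }
})

test_that("resnet_mini backbone trains end to end", {
  imgs <- toy_images(3)
  m <- train(build_model("deepcoral", "resnet_mini",
                         input_shape = c(64L, 64L, 1L), seed = 8),
             imgs, imgs, train_config(epochs = 2, seed = 4, lambda = 0.5))
  expect_true(m$trained)
  pr <- predict(m, imgs)
  expect_equal(nrow(pr), length(imgs))
})

test_that("training is deterministic given the config seed", {
  imgs <- toy_images(3)
  mk <- function() {
    train(build_model("dan", input_shape = c(64L, 64L, 1L), seed = 9),
          imgs, imgs, train_config(epochs = 2, seed = 11, lambda = 0.3))
  }
  a <- mk(); b <- mk()
  expect_identical(a$log, b$log)
  expect_identical(stage_param_vector(a, "adapt"), stage_param_vector(b, "adapt"))
})

test_that("prediction ties break toward the lower class index", {
  m <- build_model("source_only", input_shape = c(64L, 64L, 1L), seed = 10)
  # zero out the logits layer so both classes score exactly 0.5
  nl <- length(m$layers)
  m$layers[[nl]]$params$W[] <- 0
  m$layers[[nl]]$params$b[] <- 0
  img <- toy_images(1)[[1]]
  pr <- predict(m, list(img))
  expect_equal(as.character(pr$pred), "healthy")
  expect_equal(pr$score_healthy, 0.5)
})

test_that("train rejects unlabeled sources and empty sets", {
  imgs <- toy_images(2)
  bad <- imgs
  bad[[1]]$label <- NULL
  m <- build_model("source_only", input_shape = c(64L, 64L, 1L), seed = 1)
  expect_error(train(m, bad, imgs, train_config(epochs = 1)),
               class = "eegdan_invalid_argument")
  expect_error(train(m, list(), imgs, train_config(epochs = 1)),
               class = "eegdan_invalid_argument")
})
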