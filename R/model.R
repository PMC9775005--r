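# Adaptation models: a small CNN partitioned into frozen / fine-tuned /
# adapted stages, mirroring the three-part deep-adaptation-network scheme
# (early convolutions extract generic features and stay frozen; middle
# convolutions are fine-tuned; the final fully connected layers are the
# least transferable and carry the adaptation loss).

#' Training configuration
#'
#' @param epochs Training epochs (default 500, the full-protocol setting;
#'   desk-scale runs use far fewer).
#' @param batch_size Per-domain minibatch size (default 16; kept small so
#'   each step sees a varied slice of the data).
#' @param lambda Adaptation-loss weight (default 1).
#' @param lr,momentum SGD settings (default 0.01, 0.9).
#' @param lr_decay_at Fractions of training at which the learning rate is
#'   multiplied by 0.1 (default `c(0.6, 0.8)`).
#' @param lambda_schedule `"constant"` (default) or `"progressive"` (ramps
#'   lambda from 0 to its value via `2 / (1 + exp(-10 p)) - 1`).
#' @param lambda_warmup Fraction of training during which the adaptation
#'   loss is disabled entirely (default 0); the schedule then runs over the
#'   remaining epochs. Lets the classifier establish non-degenerate features
#'   before the alignment penalty is applied.
#' @param target_batch_size Number of target examples forwarded per step for
#'   the adaptation losses. Default `NULL` pairs the source batch size;
#'   `Inf` uses the whole target set every step, which removes the
#'   minibatch noise from the MK-MMD/CORAL estimates at extra compute cost.
#' @param weight_decay L2 penalty coefficient applied to the weight matrices
#'   (not biases) of the trainable stages (default 0).
#' @param seed Seed for all randomness in the training run.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 500L, batch_size = 16L, lambda = 1,
                         lr = 0.01, momentum = 0.9,
                         lr_decay_at = c(0.6, 0.8),
                         lambda_schedule = c("constant", "progressive"),
                         lambda_warmup = 0, target_batch_size = NULL,
                         weight_decay = 0, seed = 1L) {
  if (epochs < 1) stop_invalid("`epochs` must be >= 1")
  check_scalar(lambda, "lambda", nonneg = TRUE)
  check_scalar(lambda_warmup, "lambda_warmup", nonneg = TRUE)
  if (lambda_warmup >= 1) stop_invalid("`lambda_warmup` must be < 1")
  if (!is.null(target_batch_size) &&
      (!is.numeric(target_batch_size) || length(target_batch_size) != 1L ||
       is.na(target_batch_size) || target_batch_size < 1)) {
    stop_invalid("`target_batch_size` must be NULL or a number >= 1")
  }
  check_scalar(weight_decay, "weight_decay", nonneg = TRUE)
  structure(
    list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
         lambda = lambda, lr = lr, momentum = momentum,
         lr_decay_at = lr_decay_at,
         lambda_schedule = match.arg(lambda_schedule),
         lambda_warmup = lambda_warmup,
         target_batch_size = target_batch_size,
         weight_decay = weight_decay,
         seed = as.integer(seed)),
    class = "train_config"
  )
}

.build_smallnet <- function(input_shape, n_classes, pooling = "max") {
  H <- input_shape[1]; W <- input_shape[2]; C <- input_shape[3]
  if (H %% 32L != 0L || W %% 32L != 0L) {
    stop_invalid("smallnet needs height and width divisible by 32")
  }
  ls <- list()
  add <- function(l) ls[[length(ls) + 1L]] <<- l
  add(layer_conv(H, W, C, 8L, "frozen"))
  add(layer_relu(c(H, W, 8L), "frozen")); add(layer_pool(H, W, 8L, "frozen", pooling))
  H <- H %/% 2L; W <- W %/% 2L
  add(layer_conv(H, W, 8L, 8L, "frozen"))
  add(layer_relu(c(H, W, 8L), "frozen")); add(layer_pool(H, W, 8L, "frozen", pooling))
  H <- H %/% 2L; W <- W %/% 2L
  add(layer_conv(H, W, 8L, 16L, "frozen"))
  add(layer_relu(c(H, W, 16L), "frozen")); add(layer_pool(H, W, 16L, "frozen", pooling))
  H <- H %/% 2L; W <- W %/% 2L
  add(layer_conv(H, W, 16L, 16L, "finetune"))
  add(layer_relu(c(H, W, 16L), "finetune")); add(layer_pool(H, W, 16L, "finetune", pooling))
  H <- H %/% 2L; W <- W %/% 2L
  add(layer_conv(H, W, 16L, 32L, "finetune"))
  add(layer_relu(c(H, W, 32L), "finetune")); add(layer_pool(H, W, 32L, "finetune", pooling))
  H <- H %/% 2L; W <- W %/% 2L
  d <- H * W * 32L
  add(layer_fc(d, 64L, "adapt"))
  add(layer_relu(64L, "adapt", hook = TRUE))
  add(layer_fc(64L, 32L, "adapt"))
  add(layer_relu(32L, "adapt", hook = TRUE))
  add(layer_fc(32L, n_classes, "adapt", hook = TRUE))
  ls
}

.build_resnet_mini <- function(input_shape, n_classes, pooling = "max") {
  H <- input_shape[1]; W <- input_shape[2]; C <- input_shape[3]
  if (H %% 32L != 0L || W %% 32L != 0L) {
    stop_invalid("resnet_mini needs height and width divisible by 32")
  }
  ls <- list()
  add <- function(l) ls[[length(ls) + 1L]] <<- l
  add(layer_conv(H, W, C, 8L, "frozen"))
  add(layer_relu(c(H, W, 8L), "frozen")); add(layer_pool(H, W, 8L, "frozen", pooling))
  H <- H %/% 2L; W <- W %/% 2L
  add(layer_conv(H, W, 8L, 16L, "frozen"))
  add(layer_relu(c(H, W, 16L), "frozen")); add(layer_pool(H, W, 16L, "frozen", pooling))
  H <- H %/% 2L; W <- W %/% 2L
  add(layer_residual(H, W, 16L, "finetune")); add(layer_pool(H, W, 16L, "finetune", pooling))
  H <- H %/% 2L; W <- W %/% 2L
  add(layer_residual(H, W, 16L, "finetune")); add(layer_pool(H, W, 16L, "finetune", pooling))
  H <- H %/% 2L; W <- W %/% 2L
  add(layer_conv(H, W, 16L, 32L, "finetune"))
  add(layer_relu(c(H, W, 32L), "finetune")); add(layer_pool(H, W, 32L, "finetune", pooling))
  H <- H %/% 2L; W <- W %/% 2L
  d <- H * W * 32L
  add(layer_fc(d, 64L, "adapt"))
  add(layer_relu(64L, "adapt", hook = TRUE))
  add(layer_fc(64L, 32L, "adapt"))
  add(layer_relu(32L, "adapt", hook = TRUE))
  add(layer_fc(32L, n_classes, "adapt", hook = TRUE))
  ls
}

#' Build an adaptation model
#'
#' Constructs the backbone and partitions it into a frozen stage (early
#' convolutions), a fine-tuned stage (middle convolutions) and an adapted
#' stage (the three final fully connected layers, whose activations carry
#' the method's alignment loss: one MK-MMD term per adapt layer for `dan`, a
#' domain discriminator behind gradient reversal for `dann`, covariance
#' alignment on the final features for `deepcoral`, nothing for
#' `source_only`).
#'
#' @param method One of `"dan"`, `"dann"`, `"deepcoral"`, `"source_only"`.
#' @param backbone `"smallnet"` (5 conv + 3 fc) or `"resnet_mini"` (residual
#'   middle stages); both follow the same three-part partition.
#' @param n_classes Number of classes (default 2).
#' @param input_shape `c(height, width, planes)`; planes 1 for merged-chart
#'   images, 3 for RGB synthesis. Height and width must be multiples of 32.
#' @param lambda Adaptation-loss weight stored as the model default.
#' @param mmd_m,mmd_spacing Gaussian kernel count and bandwidth spacing for
#'   the MK-MMD family (defaults 5 and 2).
#' @param pooling `"max"` (default) or `"avg"` (gain-2 average pooling) for
#'   all 2x2 pooling layers.
#' @param seed Seed for weight initialization.
#' @return An object of class `adaptation_model`.
#' @export
build_model <- function(method = c("dan", "dann", "deepcoral", "source_only"),
                        backbone = c("smallnet", "resnet_mini"),
                        n_classes = 2L, input_shape = c(64L, 64L, 1L),
                        lambda = 1, mmd_m = 5L, mmd_spacing = 2,
                        pooling = c("max", "avg"), seed = 1L) {
  method <- match.arg(method)
  backbone <- match.arg(backbone)
  pooling <- match.arg(pooling)
  if (length(input_shape) != 3L) stop_invalid("`input_shape` must be c(H, W, C)")
  with_seed(seed, {
    layers <- switch(backbone,
      smallnet = .build_smallnet(input_shape, n_classes, pooling),
      resnet_mini = .build_resnet_mini(input_shape, n_classes, pooling)
    )
    disc <- NULL
    if (method == "dann") {
      disc <- list(W1 = .he_init(16L, 32L), b1 = numeric(16L),
                   W2 = .he_init(1L, 16L), b2 = numeric(1L))
    }
    structure(
      list(layers = layers, method = method, backbone = backbone,
           n_classes = as.integer(n_classes),
           input_shape = as.integer(input_shape),
           lambda = lambda, mmd_m = as.integer(mmd_m),
           mmd_spacing = mmd_spacing, classes = CLASS_LEVELS,
           discriminator = disc, trained = FALSE),
      class = "adaptation_model"
    )
  })
}

#' @export
print.adaptation_model <- function(x, ...) {
  cat(sprintf("<adaptation_model> method=%s backbone=%s input=%s %s\n",
              x$method, x$backbone, paste(x$input_shape, collapse = "x"),
              if (x$trained) "(trained)" else "(untrained)"))
  invisible(x)
}

# Stack encoded images (or raw pixel matrices/arrays) into a D x N matrix.
# Pixel intensities are mapped to [0, 1] with the trace at 1 and the
# background at 0, so the signal is sparse-positive for the ReLU net.
images_to_matrix <- function(images, input_shape) {
  n <- length(images)
  if (n == 0L) stop_invalid("empty image set")
  D <- prod(input_shape)
  X <- matrix(0, D, n)
  for (i in seq_len(n)) {
    px <- if (inherits(images[[i]], "encoded_image")) images[[i]]$pixels
          else images[[i]]
    d <- dim(px)
    planes <- if (length(d) == 3L) d[3] else 1L
    if (d[1] != input_shape[1] || d[2] != input_shape[2] ||
        planes != input_shape[3]) {
      stop_invalid("image ", i, " has shape ", paste(c(d[1], d[2], planes),
                   collapse = "x"), ", model expects ",
                   paste(input_shape, collapse = "x"))
    }
    X[, i] <- 1 - as.numeric(px) / 255
  }
  X
}

image_labels <- function(images) {
  labs <- vapply(images, function(im) {
    if (inherits(im, "encoded_image") && length(im$label) == 1L) {
      as.character(im$label)
    } else {
      NA_character_
    }
  }, "")
  match(labs, CLASS_LEVELS)
}

# Split layer list into the frozen prefix and the trainable remainder.
.stage_split <- function(layers) {
  stages <- vapply(layers, `[[`, "", "stage")
  frozen <- stages == "frozen"
  if (any(frozen) && any(diff(frozen) > 0)) {
    stop_invalid("frozen layers must form a prefix of the network")
  }
  list(frozen = which(frozen), trainable = which(!frozen))
}

# Forward a large batch through the given layers in memory-bounded chunks.
.forward_chunked <- function(layers, X, chunk = 64L) {
  n <- ncol(X)
  if (n <= chunk) return(run_layers(layers, X)$out)
  parts <- split(seq_len(n), ceiling(seq_len(n) / chunk))
  do.call(cbind, lapply(parts, function(ix) {
    run_layers(layers, X[, ix, drop = FALSE])$out
  }))
}

# One discriminator pass for DANN: forward + gradients. Domain labels:
# source 1, target 0. Returns the BCE, parameter grads, and the feature
# gradient already passed through the gradient-reversal node.
.dann_step <- function(disc, feats, n_src, lambda_eff) {
  n_all <- ncol(feats)
  dom <- c(rep(1, n_src), rep(0, n_all - n_src))
  gr <- grad_reverse(feats, lambda_eff)
  h1 <- disc$W1 %*% gr$value + disc$b1
  r1 <- h1 * (h1 > 0)
  z <- as.numeric(disc$W2 %*% r1 + disc$b2)
  p <- 1 / (1 + exp(-z))
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  bce <- -mean(dom * log(p) + (1 - dom) * log(1 - p))
  dz <- matrix((p - dom) / n_all, nrow = 1)
  dW2 <- tcrossprod(dz, r1); db2 <- rowSums(dz)
  dr1 <- crossprod(disc$W2, dz) * (h1 > 0)
  dW1 <- tcrossprod(dr1, gr$value); db1 <- rowSums(dr1)
  dfeat <- gr$backward(crossprod(disc$W1, dr1))
  list(loss = bce, grads = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2),
       dfeat = dfeat)
}

#' Train an adaptation model
#'
#' Minimizes source cross-entropy plus `lambda` times the method's
#' adaptation loss over paired source/target minibatches. Target labels are
#' used only to report the per-epoch target accuracy curve, never for
#' gradients. The frozen stage is evaluated once per dataset and cached;
#' its parameters are untouched by construction.
#'
#' @param model An [build_model()] object.
#' @param source_images Labelled `encoded_image` list (the source subjects).
#' @param target_images `encoded_image` list for the target subjects;
#'   labels, if present, feed the accuracy curve only.
#' @param cfg A [train_config()].
#' @return The trained model, with `$curve` (per-epoch target accuracy, NA
#'   when target labels are absent) and `$log` (per-epoch losses) attached.
#' @export
train <- function(model, source_images, target_images, cfg = train_config()) {
  if (!inherits(model, "adaptation_model")) stop_invalid("`model` must be an adaptation_model")
  if (length(source_images) == 0L || length(target_images) == 0L) {
    stop_invalid("source and target image sets must be nonempty")
  }
  Xs <- images_to_matrix(source_images, model$input_shape)
  Xt <- images_to_matrix(target_images, model$input_shape)
  ys <- image_labels(source_images)
  if (anyNA(ys)) stop_invalid("all source images must carry a class label")
  yt <- image_labels(target_images)
  have_curve <- !anyNA(yt)

  sp <- .stage_split(model$layers)
  frozen_layers <- model$layers[sp$frozen]
  Fs <- .forward_chunked(frozen_layers, Xs)
  Ft <- .forward_chunked(frozen_layers, Xt)
  tr_idx <- sp$trainable
  n_src <- ncol(Fs); n_tgt <- ncol(Ft)
  bs <- min(cfg$batch_size, n_src)

  # momentum buffers mirroring each trainable layer's params
  vel <- lapply(model$layers[tr_idx], function(l) lapply(l$params, function(p) p * 0))
  vel_disc <- if (!is.null(model$discriminator)) {
    lapply(model$discriminator, function(p) p * 0)
  } else NULL

  n_classes <- model$n_classes
  log_rows <- vector("list", cfg$epochs)
  curve <- rep(NA_real_, cfg$epochs)
  decay_epochs <- ceiling(cfg$lr_decay_at * cfg$epochs)

  with_seed(cfg$seed, {
    tpos <- 0L
    for (epoch in seq_len(cfg$epochs)) {
      lr <- cfg$lr * 0.1^sum(epoch > decay_epochs)
      p <- epoch / cfg$epochs
      lambda_eff <- if (p <= cfg$lambda_warmup) {
        0
      } else if (cfg$lambda_schedule == "progressive") {
        pr <- (p - cfg$lambda_warmup) / (1 - cfg$lambda_warmup)
        cfg$lambda * (2 / (1 + exp(-10 * pr)) - 1)
      } else cfg$lambda
      use_adapt <- model$method != "source_only" && lambda_eff > 0
      order_s <- sample.int(n_src)
      cls_losses <- c(); ad_losses <- c()
      for (start in seq(1L, n_src, by = bs)) {
        idx_s <- order_s[start:min(start + bs - 1L, n_src)]
        b <- length(idx_s)
        # target columns are forwarded only when an adaptation loss is
        # active this epoch; target batch size defaults to the source's
        nt <- if (is.null(cfg$target_batch_size)) b
              else as.integer(min(cfg$target_batch_size, n_tgt))
        Fb <- if (use_adapt) {
          idx_t <- ((tpos + seq_len(nt) - 1L) %% n_tgt) + 1L
          tpos <- tpos + nt
          cbind(Fs[, idx_s, drop = FALSE], Ft[, idx_t, drop = FALSE])
        } else Fs[, idx_s, drop = FALSE]
        fw <- run_layers(model$layers[tr_idx], Fb, keep_cache = TRUE,
                         collect_hooks = TRUE)
        logits <- fw$out
        P <- softmax_cols(logits)
        src_cols <- seq_len(b)
        ce <- -mean(log(pmax(P[cbind(ys[idx_s], src_cols)], 1e-12)))
        dLogits <- matrix(0, n_classes, ncol(logits))
        dP <- P[, src_cols, drop = FALSE]
        dP[cbind(ys[idx_s], src_cols)] <- dP[cbind(ys[idx_s], src_cols)] - 1
        dLogits[, src_cols] <- dP / b

        # gradient injections at hook layers (position within tr_idx)
        inject <- vector("list", length(tr_idx))
        adapt_loss <- 0
        if (use_adapt) {
          hooks <- fw$hooks
          if (model$method == "dan") {
            for (hk in hooks) {
              act <- hk$act
              Zs <- t(act[, src_cols, drop = FALSE])
              Zt <- t(act[, -src_cols, drop = FALSE])
              fam <- suppressWarnings(
                make_kernel_family(rbind(Zs, Zt), model$mmd_m, model$mmd_spacing))
              g <- mk_mmd2_grad(Zs, Zt, fam)
              adapt_loss <- adapt_loss + g$value
              gi <- lambda_eff * cbind(t(g$grad_source), t(g$grad_target))
              inject[[hk$index]] <- if (is.null(inject[[hk$index]])) gi
                                    else inject[[hk$index]] + gi
            }
          } else if (model$method == "deepcoral") {
            hk <- hooks[[length(hooks)]]   # final adapt features (logits)
            Zs <- t(hk$act[, src_cols, drop = FALSE])
            Zt <- t(hk$act[, -src_cols, drop = FALSE])
            g <- coral_loss_grad(Zs, Zt)
            adapt_loss <- g$value
            inject[[hk$index]] <- lambda_eff *
              cbind(t(g$grad_source), t(g$grad_target))
          } else if (model$method == "dann") {
            hk <- hooks[[length(hooks) - 1L]]  # last hidden adapt feature
            ds <- .dann_step(model$discriminator, hk$act, b, lambda_eff)
            adapt_loss <- ds$loss
            inject[[hk$index]] <- ds$dfeat
            for (nm in names(ds$grads)) {
              vel_disc[[nm]] <- cfg$momentum * vel_disc[[nm]] -
                lr * ds$grads[[nm]]
              model$discriminator[[nm]] <- model$discriminator[[nm]] +
                vel_disc[[nm]]
            }
          }
        }

        # hook on the logits layer injects directly into dLogits
        last_pos <- length(tr_idx)
        if (!is.null(inject[[last_pos]])) {
          dLogits <- dLogits + inject[[last_pos]]
          inject[last_pos] <- list(NULL)
        }

        dX <- dLogits
        for (j in rev(seq_along(tr_idx))) {
          l <- model$layers[[tr_idx[j]]]
          bk <- layer_backward(l, dX, fw$caches[[j]], need_dx = j > 1L)
          if (length(bk$grads)) {
            for (nm in names(bk$grads)) {
              g_nm <- bk$grads[[nm]]
              if (cfg$weight_decay > 0 && startsWith(nm, "W")) {
                g_nm <- g_nm + cfg$weight_decay *
                  model$layers[[tr_idx[j]]]$params[[nm]]
              }
              vel[[j]][[nm]] <- cfg$momentum * vel[[j]][[nm]] - lr * g_nm
              model$layers[[tr_idx[j]]]$params[[nm]] <-
                model$layers[[tr_idx[j]]]$params[[nm]] + vel[[j]][[nm]]
            }
          }
          if (j > 1L) {
            dX <- bk$dX
            if (!is.null(inject[[j - 1L]])) dX <- dX + inject[[j - 1L]]
          }
        }
        cls_losses <- c(cls_losses, ce)
        ad_losses <- c(ad_losses, adapt_loss)
      }

      acc <- NA_real_
      if (have_curve) {
        logits_t <- .forward_chunked(model$layers[tr_idx], Ft)
        pred <- apply(logits_t, 2, which.max)
        acc <- mean(pred == yt)
      }
      curve[epoch] <- acc
      log_rows[[epoch]] <- data.frame(
        epoch = epoch, cls_loss = mean(cls_losses),
        adapt_loss = mean(ad_losses), target_accuracy = acc
      )
    }
  })

  model$trained <- TRUE
  model$curve <- curve
  model$log <- do.call(rbind, log_rows)
  model
}

#' Predict class labels and scores for encoded images
#'
#' Softmax scores from the full network; the predicted label is the argmax,
#' with ties broken toward the lower class index.
#'
#' @param object A trained (or initialized) [build_model()] object.
#' @param images List of `encoded_image` objects (or pixel arrays) matching
#'   the model's input shape.
#' @param ... Unused.
#' @return A data frame with columns `pred` (factor), and per-class score
#'   columns.
#' @export
predict.adaptation_model <- function(object, images, ...) {
  X <- images_to_matrix(images, object$input_shape)
  logits <- .forward_chunked(object$layers, X)
  P <- softmax_cols(logits)
  pred_idx <- apply(P, 2, which.max)   # ties resolve to the first (lower) index
  out <- data.frame(
    pred = factor(object$classes[pred_idx], levels = object$classes)
  )
  for (k in seq_len(object$n_classes)) {
    out[[paste0("score_", object$classes[k])]] <- P[k, ]
  }
  out
}
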