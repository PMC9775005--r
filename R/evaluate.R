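# Subject-level source/target allocation and the group-accuracy protocol:
# each group draws 8 healthy + 8 depressed subjects and partitions them
# either 7:1 (7+7 source, 1+1 target) or 4:4 per class; groups are drawn
# independently, and per-method accuracies are averaged across groups.

#' Subject-level source/target splits
#'
#' Each group samples 8 healthy and 8 depressed subjects without replacement
#' and partitions them per the ratio: `"7:1"` keeps 7 of each class as
#' source and 1 of each as target; `"4:4"` splits each class equally.
#' Groups are sampled independently of one another.
#'
#' @param cohort List of [recording()] objects (>= 8 per class).
#' @param ratio `"7:1"` (default) or `"4:4"`.
#' @param n_groups Number of independent groups (default 11).
#' @param seed Integer seed.
#' @return List of `domain_split` objects with fields `group_id`,
#'   `source_subjects`, `target_subjects`, `ratio`.
#' @export
make_splits <- function(cohort, ratio = c("7:1", "4:4"), n_groups = 11L,
                        seed = 1L) {
  ratio <- match.arg(ratio)
  labels <- vapply(cohort, `[[`, "", "label")
  ids <- vapply(cohort, `[[`, "", "subject_id")
  hc <- ids[labels == "healthy"]
  dep <- ids[labels == "depressed"]
  if (length(hc) < 8L || length(dep) < 8L) {
    stop_invalid("need at least 8 subjects per class, got ",
                 length(hc), " healthy / ", length(dep), " depressed")
  }
  n_src <- if (ratio == "7:1") 7L else 4L
  with_seed(seed, {
    lapply(seq_len(n_groups), function(g) {
      hc_g <- sample(hc, 8L)
      dep_g <- sample(dep, 8L)
      structure(
        list(group_id = sprintf("G%02d", g),
             source_subjects = c(hc_g[seq_len(n_src)], dep_g[seq_len(n_src)]),
             target_subjects = c(hc_g[(n_src + 1L):8L], dep_g[(n_src + 1L):8L]),
             ratio = ratio),
        class = "domain_split"
      )
    })
  })
}

#' @export
print.domain_split <- function(x, ...) {
  cat(sprintf("<domain_split> %s (%s): %d source, %d target subjects\n",
              x$group_id, x$ratio, length(x$source_subjects),
              length(x$target_subjects)))
  invisible(x)
}

# Preprocess + encode one subject's recording, memoised in `cache` (an
# environment) so subjects shared across groups are only processed once.
.subject_images <- function(rec, encoding, pre, spec, channel_map, cache) {
  key <- paste(rec$subject_id, encoding, sep = "|")
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  ws <- preprocess_recording(rec, pre)
  imgs <- encode_window_set(ws, encoding, spec, channel_map)
  if (!is.null(cache)) cache[[key]] <- imgs
  imgs
}

#' Run one source-to-target group end to end
#'
#' Preprocesses and encodes every subject in the split, trains the requested
#' adaptation method on the labelled source windows plus unlabelled target
#' windows, and reports the final per-window target accuracy (each encoded
#' one-second image is one prediction) along with a per-subject
#' majority-vote accuracy and the per-epoch accuracy curve.
#'
#' @param split A `domain_split`.
#' @param cohort The full cohort the split indexes into.
#' @param method `"dan"`, `"dann"`, `"deepcoral"` or `"source_only"`.
#' @param encoding `"merged"` or `"rgb"`.
#' @param cfg A [train_config()].
#' @param pre A [preprocess_config()].
#' @param spec A [raster_spec()]; its size fixes the model input shape.
#' @param backbone Backbone identifier for [build_model()].
#' @param channel_map Channel-to-color map for RGB encoding.
#' @param cache Optional environment memoising per-subject encoded images
#'   across groups.
#' @return A `group_result` with `final_accuracy`, `subject_accuracy`,
#'   `accuracy_curve`, `method`, `encoding`, `group_id`, `seed`.
#' @export
run_group <- function(split, cohort, method = "dan",
                      encoding = c("merged", "rgb"), cfg = train_config(),
                      pre = preprocess_config(), spec = raster_spec(64L, 64L),
                      backbone = "smallnet", channel_map = c(1L, 2L, 3L),
                      cache = NULL) {
  encoding <- match.arg(encoding)
  ids <- vapply(cohort, `[[`, "", "subject_id")
  get_rec <- function(sid) {
    i <- match(sid, ids)
    if (is.na(i)) stop_invalid("subject ", sid, " not found in cohort")
    cohort[[i]]
  }
  src_imgs <- unlist(lapply(split$source_subjects, function(sid) {
    .subject_images(get_rec(sid), encoding, pre, spec, channel_map, cache)
  }), recursive = FALSE)
  tgt_imgs <- unlist(lapply(split$target_subjects, function(sid) {
    .subject_images(get_rec(sid), encoding, pre, spec, channel_map, cache)
  }), recursive = FALSE)

  planes <- if (encoding == "merged") 1L else 3L
  model <- build_model(method, backbone = backbone,
                       n_classes = 2L,
                       input_shape = c(spec$height, spec$width, planes),
                       lambda = cfg$lambda, seed = cfg$seed)
  model <- train(model, src_imgs, tgt_imgs, cfg)

  preds <- predict(model, tgt_imgs)
  truth <- vapply(tgt_imgs, function(im) as.character(im$label), "")
  subj <- vapply(tgt_imgs, function(im) as.character(im$subject_id), "")
  final_acc <- mean(as.character(preds$pred) == truth)
  # secondary metric: majority vote over each target subject's windows
  vote <- tapply(as.character(preds$pred), subj, function(p) {
    names(sort(table(factor(p, levels = CLASS_LEVELS)), decreasing = TRUE))[1]
  })
  subj_truth <- tapply(truth, subj, `[`, 1)
  subj_acc <- mean(vote == subj_truth)

  structure(
    list(group_id = split$group_id, method = method, encoding = encoding,
         final_accuracy = final_acc, subject_accuracy = subj_acc,
         accuracy_curve = model$curve, seed = cfg$seed,
         n_target_windows = length(tgt_imgs)),
    class = "group_result"
  )
}

#' @export
print.group_result <- function(x, ...) {
  cat(sprintf("<group_result> %s %s/%s: accuracy %.3f (subject vote %.3f)\n",
              x$group_id, x$method, x$encoding, x$final_accuracy,
              x$subject_accuracy))
  invisible(x)
}

#' Summarize group results into the groups-by-methods accuracy grid
#'
#' Per-method mean and sample (n-1) standard deviation of the final
#' accuracies across groups, plus the full grid.
#'
#' @param results Nonempty list of `group_result` objects.
#' @return List with `grid` (data frame, one row per group, one column per
#'   method) and `summary` (data frame: method, mean_accuracy, sd_accuracy,
#'   n_groups).
#' @export
summarize_groups <- function(results) {
  if (length(results) == 0L) stop_invalid("`results` must be nonempty")
  df <- data.frame(
    group_id = vapply(results, `[[`, "", "group_id"),
    method = vapply(results, `[[`, "", "method"),
    accuracy = vapply(results, `[[`, 0, "final_accuracy"),
    stringsAsFactors = FALSE
  )
  methods <- unique(df$method)
  groups <- unique(df$group_id)
  grid <- data.frame(group_id = groups, stringsAsFactors = FALSE)
  for (m in methods) {
    sub <- df[df$method == m, ]
    grid[[m]] <- sub$accuracy[match(groups, sub$group_id)]
  }
  summary <- do.call(rbind, lapply(methods, function(m) {
    a <- df$accuracy[df$method == m]
    data.frame(method = m, mean_accuracy = mean(a),
               sd_accuracy = if (length(a) > 1L) stats::sd(a) else 0,
               n_groups = length(a), stringsAsFactors = FALSE)
  }))
  list(grid = grid, summary = summary)
}
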