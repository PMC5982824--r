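#' Predict sweep classes for feature vectors
#'
#' Works for both the convolutional model and the Extra-Trees baseline.
#' Each region receives the five class-membership probabilities, the argmax
#' label, and the scalar sweep score `P(hard) + P(soft)` used for the binary
#' sweep-versus-unselected task.
#'
#' @param model a trained `sweep_cnn` or `sweep_etc`.
#' @param data tibble with `<stat>_win<i>` feature columns (other columns
#'   are ignored), or a numeric feature matrix. See [prediction_records()]
#'   for attaching genomic coordinates to the result.
#' @return Tibble with columns `pred` (factor), `sweep_prob`, and one
#'   probability column per class.
#' @export
predict_sweeps <- function(model, data) {
  X <- as_feature_matrix(data)
  probs <- predict_probs(model, X)
  colnames(probs) <- class_levels()
  pred <- factor(class_levels()[max.col(probs, ties.method = "first")],
                 levels = class_levels())
  dplyr::bind_cols(
    tibble::tibble(pred = pred,
                   sweep_prob = probs[, "hard"] + probs[, "soft"]),
    tibble::as_tibble(probs))
}

predict_probs <- function(model, X) UseMethod("predict_probs")

#' @export
predict_probs.sweep_cnn <- function(model, X) {
  out <- matrix(0, nrow(X), model$spec$n_classes)
  for (b0 in seq(1, nrow(X), by = 256)) {
    bi <- b0:min(b0 + 255, nrow(X))
    out[bi, ] <- cnn_forward(model, X[bi, , drop = FALSE])$probs
  }
  out
}

#' @export
predict_probs.sweep_etc <- function(model, X) {
  colnames(X) <- model$feature_names
  pr <- stats::predict(model$fit, data = as.data.frame(X))$predictions
  out <- matrix(0, nrow(pr), 5, dimnames = list(NULL, class_levels()))
  out[, colnames(pr)] <- pr  # classes absent from training keep probability 0
  out
}

#' Extra-Trees baseline classifier
#'
#' An ensemble of extremely randomized trees over the flattened 132-element
#' feature vectors, the reference learner against which the convolutional
#' classifier is compared (fit with `ranger`: random split points, no
#' bootstrap resampling).
#'
#' @param data tibble with `label` and feature columns; rows with
#'   `set == "test"` are excluded.
#' @param num_trees ensemble size.
#' @param seed optional seed for the forest.
#' @return Object of class `sweep_etc`.
#' @export
train_extratrees <- function(data, num_trees = 500L, seed = NULL) {
  if ("set" %in% names(data)) data <- data[data$set == "train", , drop = FALSE]
  if (!nrow(data)) stop("empty training set")
  labs <- factor(as.character(data$label), levels = class_levels())
  if (length(unique(labs)) < 2) stop("training set must contain at least 2 classes")
  X <- as_feature_matrix(data)
  df <- as.data.frame(X)
  df$..label.. <- droplevels(labs)
  fit <- ranger::ranger(
    dependent.variable.name = "..label..", data = df,
    probability = TRUE, num.trees = num_trees,
    splitrule = "extratrees", num.random.splits = 1L,
    replace = FALSE, sample.fraction = 1,
    seed = if (is.null(seed)) sample.int(.Machine$integer.max, 1) else seed)
  structure(list(fit = fit, feature_names = colnames(X)), class = "sweep_etc")
}

#' @exportS3Method base::print
print.sweep_etc <- function(x, ...) {
  cat("<sweep_etc> Extra-Trees baseline, ", x$fit$num.trees, " trees\n", sep = "")
  invisible(x)
}

#' Rank-based ROC AUC
#'
#' Mann-Whitney form of the area under the ROC curve (average ranks under
#' ties), for the binary sweep-versus-unselected task.
#'
#' @param score numeric scores, larger = more sweep-like.
#' @param is_pos logical truth.
#' @return AUC in \[0, 1\].
#' @export
auc_rank <- function(score, is_pos) {
  is_pos <- as.logical(is_pos)
  n1 <- sum(is_pos)
  n0 <- sum(!is_pos)
  if (n1 == 0 || n0 == 0) stop("need both positive and negative examples for AUC")
  r <- rank(score)
  (sum(r[is_pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

roc_points <- function(score, is_pos) {
  ord <- order(score, decreasing = TRUE)
  tp <- cumsum(is_pos[ord])
  fp <- cumsum(!is_pos[ord])
  tibble::tibble(threshold = score[ord],
                 tpr = tp / sum(is_pos), fpr = fp / sum(!is_pos)) |>
    dplyr::bind_rows(tibble::tibble(threshold = Inf, tpr = 0, fpr = 0)) |>
    dplyr::arrange(.data$fpr, .data$tpr)
}

#' Evaluate a trained classifier on a labeled test set
#'
#' Computes the multiclass accuracy, the 5 x 5 confusion matrix (counts and
#' row-normalized), the binary sweep-versus-unselected ROC and AUC using the
#' summed sweep-class probability, the sweep false-positive rate (unselected
#' examples predicted hard or soft), the sweep recall (hard/soft examples
#' predicted hard or soft), and — when the test set carries `sweep_win`
#' metadata — the positional confusion of predicted classes by true sweep
#' offset.
#'
#' @param model trained `sweep_cnn` or `sweep_etc`.
#' @param data labeled tibble; rows with `set == "test"` are used when a
#'   `set` column is present, otherwise all rows.
#' @return Object of class `sweep_eval`.
#' @export
evaluate_classifier <- function(model, data) {
  if ("set" %in% names(data)) data <- data[data$set == "test", , drop = FALSE]
  if (!nrow(data)) stop("empty test set")
  truth <- factor(as.character(data$label), levels = class_levels())
  if (anyNA(truth)) stop("test labels outside the known classes")
  pr <- predict_sweeps(model, data)
  cm <- table(truth = truth, pred = pr$pred)
  cm <- unclass(cm)[class_levels(), class_levels()]
  acc <- sum(diag(cm)) / sum(cm)
  cm_prop <- cm / pmax(rowSums(cm), 1)
  is_sweep <- truth %in% c("hard", "soft")
  auc <- auc_rank(pr$sweep_prob, is_sweep)
  pred_sweep <- pr$pred %in% c("hard", "soft")
  fpr <- mean(pred_sweep[!is_sweep])
  recall <- mean(pred_sweep[is_sweep])
  positional <- NULL
  if ("sweep_win" %in% names(data)) {
    central <- 6L
    positional <- tibble::tibble(truth = truth, pred = pr$pred,
                                 offset = data$sweep_win - central) |>
      dplyr::filter(!is.na(.data$offset)) |>
      dplyr::count(.data$truth, .data$offset, .data$pred) |>
      dplyr::group_by(.data$truth, .data$offset) |>
      dplyr::mutate(fraction = .data$n / sum(.data$n)) |>
      dplyr::ungroup()
  }
  structure(list(accuracy = acc, confusion = cm, confusion_prop = cm_prop,
                 auc = auc, sweep_fpr = fpr, sweep_recall = recall,
                 roc = roc_points(pr$sweep_prob, is_sweep),
                 positional = positional, n_test = nrow(data)),
            class = "sweep_eval")
}

#' @exportS3Method base::print
print.sweep_eval <- function(x, ...) {
  cat("<sweep_eval> n = ", x$n_test,
      sprintf(" | accuracy %.3f | sweep AUC %.3f | recall %.3f | FPR %.3f\n",
              x$accuracy, x$auc, x$sweep_recall, x$sweep_fpr), sep = "")
  cat("confusion (row-normalized):\n")
  print(round(x$confusion_prop, 3))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a classifier evaluation into a long confusion tibble
#'
#' @param x a `sweep_eval`.
#' @param ... unused.
#' @return Tibble with `truth`, `pred`, `n`, `fraction`.
#' @export
tidy.sweep_eval <- function(x, ...) {
  out <- tibble::as_tibble(as.table(x$confusion))
  names(out) <- c("truth", "pred", "n")
  out |>
    dplyr::group_by(.data$truth) |>
    dplyr::mutate(fraction = .data$n / pmax(sum(.data$n), 1)) |>
    dplyr::ungroup()
}

#' @export
glance.sweep_eval <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, auc = x$auc,
                 sweep_recall = x$sweep_recall, sweep_fpr = x$sweep_fpr,
                 n_test = x$n_test)
}

#' Tidy training history of the convolutional classifier
#' @param x a `sweep_cnn`.
#' @param ... unused.
#' @return Per-epoch tibble with `epoch`, `train_loss`, `val_accuracy`.
#' @export
tidy.sweep_cnn <- function(x, ...) {
  if (is.null(x$history)) tibble::tibble(epoch = integer(), train_loss = numeric(),
                                         val_accuracy = numeric()) else x$history
}

#' @export
glance.sweep_cnn <- function(x, ...) {
  tibble::tibble(
    n_parameters = sum(vapply(x$params, length, numeric(1))),
    n_branches = length(x$spec$branches),
    epochs_trained = if (is.null(x$history)) 0L else nrow(x$history),
    best_val_accuracy = if (is.null(x$history)) NA_real_ else max(x$history$val_accuracy))
}
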