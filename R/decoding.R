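# Linear-SVM decoding of schedule condition with repeated balanced
# undersampling and stratified k-fold cross-validation.

#' Build a per-trial feature table from two peri-event tables
#'
#' One row per event of the requested class, with the default features being
#' the mean dF/F over the pre-event and post-event halves of `input_range`
#' (seconds relative to the event; the event frame belongs to the post
#' half). Labels come from the source condition of each table.
#'
#' @param pem_rr,pem_ri `perievent_tbl`s for the RR and RI conditions.
#' @param event_class One of the six peri-event class labels.
#' @param input_range Length-2 numeric `(a, b)` with `a < 0 < b`, within the
#'   extraction window.
#' @return A `feature_table` tibble: `label` (factor RR/RI), `event_class`,
#'   `pre_mean`, `post_mean`.
#' @export
build_features <- function(pem_rr, pem_ri, event_class,
                           input_range = c(-2, 2)) {
  stopifnot(length(input_range) == 2, input_range[1] < 0, input_range[2] > 0)
  mats <- list(RR = pem_matrix(pem_rr, event_class), RI = pem_matrix(pem_ri, event_class))
  fps <- attr(pem_rr, "fps")
  n_pre <- round(attr(pem_rr, "pre_s") * fps)
  tt <- (seq_len(attr(pem_rr, "n_frames")) - 1 - n_pre) / fps
  pre_idx <- which(tt >= input_range[1] & tt < 0)
  post_idx <- which(tt >= 0 & tt < input_range[2])
  if (!length(pre_idx) || !length(post_idx)) {
    stop("`input_range` covers no frames", call. = FALSE)
  }
  out <- purrr::imap_dfr(mats, function(m, lab) {
    tibble(
      label = lab,
      event_class = event_class,
      pre_mean = rowMeans(m[, pre_idx, drop = FALSE]),
      post_mean = rowMeans(m[, post_idx, drop = FALSE])
    )
  })
  if (anyNA(out$pre_mean) || anyNA(out$post_mean)) {
    stop("features contain NA", call. = FALSE)
  }
  out$label <- factor(out$label, levels = c("RR", "RI"))
  class(out) <- c("feature_table", class(out))
  out
}

# Mann-Whitney AUC of `scores` for separating positive from negative trials.
auc_rank <- function(scores, positive) {
  n1 <- sum(positive)
  n0 <- sum(!positive)
  r <- rank(scores)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Empirical ROC points (fpr, tpr), collapsing tied scores.
roc_points <- function(scores, positive) {
  o <- order(scores, decreasing = TRUE)
  t <- positive[o]
  s <- scores[o]
  tp <- cumsum(t)
  fp <- cumsum(!t)
  keep <- c(s[-1] != s[-length(s)], TRUE)
  list(
    fpr = c(0, fp[keep] / sum(!positive)),
    tpr = c(0, tp[keep] / sum(positive))
  )
}

# TPR of the step ROC evaluated on a fixed FPR grid.
roc_interp <- function(scores, positive, grid) {
  p <- roc_points(scores, positive)
  stats::approx(p$fpr, p$tpr,
    xout = grid, method = "constant", f = 0,
    ties = max, rule = 2
  )$y
}

#' Classification metrics from a confusion matrix
#'
#' Evaluates accuracy `(tn + tp) / (tn + tp + fn + fp)`, sensitivity
#' `tp / (tp + fn)` and specificity `tn / (tn + fp)`. A zero denominator
#' yields `NaN` with a warning rather than an error.
#'
#' @param tp,tn,fp,fn Non-negative integer counts.
#' @return A one-row tibble: `accuracy`, `sensitivity`, `specificity`.
#' @examples
#' metrics_from_confusion(tp = 3, tn = 4, fp = 1, fn = 2)
#' @export
metrics_from_confusion <- function(tp, tn, fp, fn) {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("confusion counts must be non-negative integers", call. = FALSE)
  }
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined: zero denominator", call. = FALSE)
      return(NaN)
    }
    num / den
  }
  tibble(
    accuracy = safe_div(tn + tp, tn + tp + fn + fp, "accuracy"),
    sensitivity = safe_div(tp, tp + fn, "sensitivity"),
    specificity = safe_div(tn, tn + fp, "specificity")
  )
}

one_svm_resample <- function(X, lab, k, cost, n_min, pos, fpr_grid,
                             permute = FALSE) {
  if (permute) lab <- sample(lab)
  lev <- levels(lab)
  idx <- unlist(lapply(lev, function(cl) {
    ii <- which(lab == cl)
    if (length(ii) > n_min) sample(ii, n_min) else ii
  }))
  y <- factor(lab[idx], levels = lev)
  Xs <- X[idx, , drop = FALSE]
  fold <- integer(length(idx))
  for (cl in lev) {
    ii <- which(y == cl)
    fold[ii] <- sample(rep_len(seq_len(k), length(ii)))
  }
  scores <- numeric(length(idx))
  predlab <- character(length(idx))
  for (f in seq_len(k)) {
    tr <- fold != f
    mu <- colMeans(Xs[tr, , drop = FALSE])
    sdv <- apply(Xs[tr, , drop = FALSE], 2, stats::sd)
    sdv[!is.finite(sdv) | sdv == 0] <- 1
    Xtr <- scale(Xs[tr, , drop = FALSE], mu, sdv)
    Xte <- scale(Xs[!tr, , drop = FALSE], mu, sdv)
    fit <- e1071::svm(Xtr, y[tr], kernel = "linear", cost = cost, scale = FALSE)
    pr <- stats::predict(fit, Xte, decision.values = TRUE)
    dv <- attr(pr, "decision.values")
    first <- strsplit(colnames(dv), "/", fixed = TRUE)[[1]][1]
    s <- if (identical(first, pos)) drop(dv) else -drop(dv)
    scores[!tr] <- s
    predlab[!tr] <- as.character(pr)
  }
  truth <- y == pos
  predpos <- predlab == pos
  list(
    auc = auc_rank(scores, truth),
    tp = sum(predpos & truth), tn = sum(!predpos & !truth),
    fp = sum(predpos & !truth), fn = sum(!predpos & truth),
    tpr = roc_interp(scores, truth, fpr_grid)
  )
}

#' Run the undersampled SVM decoding protocol
#'
#' For each of `n_resamples` repeats: undersample the majority class without
#' replacement to the minority count; assign stratified `k`-fold splits;
#' per fold, standardise features using training-fold statistics only, fit a
#' linear maximum-margin classifier (fixed regularisation `cost`), and score
#' the held-out fold; pool the held-out decision values into one ROC/AUC and
#' one confusion matrix at the zero-decision threshold. Per-resample metrics
#' are averaged; ROC curves are vertically averaged on a fixed
#' false-positive-rate grid.
#'
#' @param features A `feature_table` (or any data frame with a two-level
#'   `label` column; every other numeric column is used as a feature).
#' @param k Number of cross-validation folds (default 4).
#' @param n_resamples Number of undersampling repeats (default 400).
#' @param cost SVM regularisation constant (default 1).
#' @param seed Optional seed; identical seeds give identical results.
#' @param fpr_grid False-positive-rate grid for ROC averaging (default 101
#'   points).
#' @param permute_labels If `TRUE`, class labels are freshly permuted at the
#'   start of every resample: a permutation-null control whose averaged
#'   metrics estimate the protocol's empirical chance level.
#' @return A `decoding_result`: list with `metrics` (tibble of per-resample
#'   `auc`, `accuracy`, `sensitivity`, `specificity`), `roc` (tibble `fpr`,
#'   `tpr`), `summary` (mean and SD per metric), and protocol metadata.
#'   The positive class is `"RI"` when present.
#' @export
run_svm_protocol <- function(features, k = 4, n_resamples = 400, cost = 1,
                             seed = NULL, fpr_grid = seq(0, 1, by = 0.01),
                             permute_labels = FALSE) {
  lab <- droplevels(as.factor(features$label))
  if (nlevels(lab) != 2) stop("`label` must have exactly two classes", call. = FALSE)
  featcols <- names(features)[vapply(features, is.numeric, TRUE)]
  featcols <- setdiff(featcols, c("label"))
  if (!length(featcols)) stop("no numeric feature columns", call. = FALSE)
  X <- as.matrix(features[featcols])
  if (anyNA(X)) stop("features contain NA", call. = FALSE)
  n_min <- min(table(lab))
  if (n_min < k) {
    stop("insufficient trials: each class needs at least k = ", k, call. = FALSE)
  }
  pos <- if ("RI" %in% levels(lab)) "RI" else levels(lab)[2]

  with_seed_(seed, {
    res <- purrr::map(seq_len(n_resamples), function(r) {
      one_svm_resample(X, lab, k, cost, n_min, pos, fpr_grid,
        permute = permute_labels
      )
    })
    metrics <- purrr::imap_dfr(res, function(x, r) {
      m <- suppressWarnings(metrics_from_confusion(x$tp, x$tn, x$fp, x$fn))
      tibble(
        resample = r, auc = x$auc,
        accuracy = m$accuracy, sensitivity = m$sensitivity,
        specificity = m$specificity
      )
    })
    tprs <- do.call(rbind, purrr::map(res, "tpr"))
    structure(
      list(
        metrics = metrics,
        roc = tibble(
          fpr = fpr_grid,
          tpr = colMeans(tprs),
          tpr_sd = apply(tprs, 2, stats::sd)
        ),
        summary = tibble(
          metric = c("auc", "accuracy", "sensitivity", "specificity"),
          mean = c(
            mean(metrics$auc), mean(metrics$accuracy),
            mean(metrics$sensitivity), mean(metrics$specificity)
          ),
          sd = c(
            stats::sd(metrics$auc), stats::sd(metrics$accuracy),
            stats::sd(metrics$sensitivity), stats::sd(metrics$specificity)
          )
        ),
        n_resamples = n_resamples, k = k, cost = cost,
        n_per_class = n_min, positive = pos,
        event_class = if ("event_class" %in% names(features)) {
          as.character(features$event_class[1])
        } else {
          NA_character_
        }
      ),
      class = "decoding_result"
    )
  })
}

#' @export
print.decoding_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<decoding_result> %s | %d resamples, %d-fold CV, %d/class\n",
    ifelse(is.na(x$event_class), "features", x$event_class),
    x$n_resamples, x$k, x$n_per_class
  ))
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-11s %.3f (SD %.3f)\n", s$metric[i], s$mean[i], s$sd[i]))
  }
  invisible(x)
}

#' One-sample t test of per-resample metrics against chance
#'
#' @param values Numeric vector of per-resample metric values.
#' @param chance Chance level (default 0.5).
#' @return A one-row tibble: `estimate` (mean), `t`, `df`, `p_value`
#'   (two-tailed).
#' @export
compare_to_chance <- function(values, chance = 0.5) {
  if (length(values) < 2) stop("need at least 2 values", call. = FALSE)
  if (stats::sd(values) == 0) stop("zero variance in `values`", call. = FALSE)
  ht <- stats::t.test(values, mu = chance)
  tibble(
    estimate = unname(ht$estimate),
    t = unname(ht$statistic),
    df = unname(ht$parameter),
    p_value = ht$p.value
  )
}
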