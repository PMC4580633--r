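# Model evaluation: rank-based AUC, the balanced sensitivity/specificity
# cut-off, and k-fold cross-validated AUC.

check_two_classes <- function(labels) {
  labels <- as.logical(labels)
  if (anyNA(labels)) stop_kc("labels contain NA")
  if (all(labels) || !any(labels)) {
    stop_kc("both classes must be present")
  }
  labels
}

#' Area under the ROC curve
#'
#' The Mann-Whitney probability P(score+ > score-) + 0.5 P(tie),
#' computed from rank statistics (midranks handle ties).
#'
#' @param scores numeric scores (higher = more likely positive).
#' @param labels binary labels (logical or 0/1); both classes required.
#' @return AUC in \[0, 1\].
#' @examples
#' auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
#' @export
auc <- function(scores, labels) {
  labels <- check_two_classes(labels)
  if (length(scores) != length(labels)) stop_kc("length mismatch")
  n1 <- sum(labels)
  n0 <- sum(!labels)
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Balanced-classification cut-off
#'
#' Scans candidate thresholds (midpoints between adjacent distinct
#' scores plus the extremes) and returns the one minimizing
#' |sensitivity - specificity| for the rule "predict positive when
#' score >= cutoff"; ties break toward the smaller cutoff.
#'
#' @inheritParams auc
#' @return list with `cutoff`, `sensitivity`, `specificity`.
#' @export
choose_cutoff <- function(scores, labels) {
  labels <- check_two_classes(labels)
  us <- sort(unique(scores))
  cands <- us[1]
  if (length(us) > 1) {
    cands <- c(us[1], (us[-1] + us[-length(us)]) / 2, us[length(us)])
  }
  n1 <- sum(labels)
  n0 <- sum(!labels)
  best <- NULL
  for (cut in cands) {
    pos <- scores >= cut
    sens <- sum(pos & labels) / n1
    spec <- sum(!pos & !labels) / n0
    gap <- abs(sens - spec)
    if (is.null(best) || gap < best$gap - 1e-12) {
      best <- list(cutoff = cut, sensitivity = sens, specificity = spec,
                   gap = gap)
    }
  }
  best$gap <- NULL
  best
}

#' k-fold cross-validated AUC
#'
#' Random stratified partition (each class shuffled separately under the
#' seed, then dealt round-robin into k folds). For each fold the spec is
#' refitted on the remainder, the held-out fold is scored, and a fold
#' AUC computed; the unweighted mean is returned. Reproducible given the
#' seed; errors if any fold would lack a class.
#'
#' @param data covariate data.frame with the response column.
#' @param spec a [model_spec()].
#' @param k number of folds (default 20).
#' @param seed integer seed for the fold assignment.
#' @param response response column name.
#' @return mean held-out AUC.
#' @export
kfold_auc <- function(data, spec, k = 20, seed = 1,
                      response = "FEEDING") {
  dm <- build_design_matrix(data, spec, response = response)
  X <- dm$X
  y <- dm$y
  n <- length(y)
  if (k < 2 || k > n) stop_kc("k must be in [2, n]")
  fold <- integer(n)
  with_seed(seed, {
    for (cls in c(0L, 1L)) {
      idx <- sample(which(y == cls))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  for (f in seq_len(k)) {
    if (length(unique(y[fold == f])) < 2 ||
        length(unique(y[fold != f])) < 2) {
      stop_kc("fold ", f, " would lack a class; use fewer folds")
    }
  }
  fold_auc <- vapply(seq_len(k), function(f) {
    test <- fold == f
    fit <- fit_logistic(y[!test], X[!test, , drop = FALSE], spec = spec)
    p <- invlogit(drop(X[test, , drop = FALSE] %*% fit$beta))
    auc(p, y[test])
  }, 0)
  mean(fold_auc)
}

#' Full evaluation of one model
#'
#' Apparent AUC, balanced cut-off with its sensitivity/specificity, and
#' (optionally) the k-fold cross-validated AUC, from one refit of `spec`
#' on `data`.
#'
#' @inheritParams kfold_auc
#' @param cv compute the cross-validated AUC (default TRUE).
#' @return list with `cutoff`, `sensitivity`, `specificity`, `auc`,
#'   `cv_auc` (or `NA`), `k_folds`, `seed`, and the fitted `model`.
#' @export
evaluate_model <- function(data, spec, k = 20, seed = 1, cv = TRUE,
                           response = "FEEDING") {
  fit <- fit_model(data, spec, response = response)
  dm <- build_design_matrix(data, spec, response = response)
  scores <- invlogit(drop(dm$X %*% fit$beta))
  cut <- choose_cutoff(scores, dm$y)
  list(
    cutoff = cut$cutoff, sensitivity = cut$sensitivity,
    specificity = cut$specificity,
    auc = auc(scores, dm$y),
    cv_auc = if (cv) {
      kfold_auc(data, spec, k = k, seed = seed, response = response)
    } else {
      NA_real_
    },
    k_folds = k, seed = seed, model = fit
  )
}
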