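## Correlation-filtered stepwise forward feature selection, ranked by
## cross-validated accuracy contribution of each added feature.

#' Select the most predictive, mutually non-redundant features
#'
#' Greedy forward selection: at every step the candidate pool is the set
#' of unselected features whose absolute Pearson correlation with every
#' already-selected feature is below `threshold` (redundancy filter).
#' Each candidate is scored by the cross-validated accuracy of the
#' classifier trained on the selected set plus that candidate; the best
#' candidate is appended. The contribution of a feature is the accuracy
#' gain over the previous step; for the first feature it is the gain over
#' the majority-class baseline. Selection stops after `k` features or
#' when no admissible candidate remains (shorter result, with a warning).
#'
#' @param features Labelled feature tibble (columns from
#'   [feature_names()] plus `behaviour`).
#' @param k Number of features to select; default 5.
#' @param threshold Pairwise absolute-correlation threshold; default 0.9.
#' @param hp Hyperparameters used for the scoring classifier, the same
#'   as the final model's for coherence.
#' @param folds Cross-validation folds used for scoring, default 5.
#' @param seed Integer seed; scoring is reproducible given the seed.
#' @return An object of class `"selection_result"`: a tibble with columns
#'   `feature`, `step`, `accuracy` (cumulative CV accuracy) and
#'   `contribution`, with attributes `baseline` (majority-class accuracy)
#'   and `threshold`.
#' @export
select_features <- function(features, k = 5L, threshold = 0.9,
                            hp = default_hyperparams(), folds = 5L,
                            seed = 1L) {
  stopifnot(k >= 1L, threshold > 0, threshold <= 1)
  if (!"behaviour" %in% names(features)) abort("features must carry `behaviour`")
  if (length(unique(features$behaviour)) < 2L) {
    abort("feature selection needs >= 2 behaviour classes")
  }
  pool <- intersect(feature_names(), names(features))
  cors <- abs(stats::cor(as.matrix(features[, pool, drop = FALSE])))
  cors[!is.finite(cors)] <- 0  # constant columns carry no redundancy signal
  baseline <- max(table(features$behaviour)) / nrow(features)

  selected <- character()
  acc_prev <- baseline
  rows <- list()
  for (step in seq_len(k)) {
    admissible <- setdiff(pool, selected)
    if (length(selected) > 0L) {
      ok <- vapply(admissible, function(f) {
        all(cors[f, selected] < threshold)
      }, logical(1))
      admissible <- admissible[ok]
    }
    if (length(admissible) == 0L) {
      warn(sprintf("only %d admissible feature(s) under |r| < %g; stopping early",
                   length(selected), threshold))
      break
    }
    scores <- vapply(admissible, function(f) {
      cross_validate(features, c(selected, f), hp = hp,
                     folds = folds, seed = seed)$accuracy
    }, numeric(1))
    best <- admissible[which.max(scores)]
    selected <- c(selected, best)
    rows[[step]] <- tibble::tibble(
      feature = best, step = step,
      accuracy = max(scores), contribution = max(scores) - acc_prev
    )
    acc_prev <- max(scores)
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "baseline") <- baseline
  attr(out, "threshold") <- threshold
  class(out) <- c("selection_result", class(out))
  out
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("Forward feature selection (baseline accuracy %.3f, |r| < %g)\n",
              attr(x, "baseline"), attr(x, "threshold")))
  NextMethod()
  invisible(x)
}

#' Write a selection result as delimited text
#'
#' @param result A `"selection_result"` from [select_features()].
#' @param path Output path (columns feature, step, accuracy, contribution).
#' @return `path`, invisibly.
#' @export
write_selection <- function(result, path) {
  write.csv(as.data.frame(result), path, row.names = FALSE)
  invisible(path)
}
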