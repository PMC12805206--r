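# ROC curves and AUC for difference-recovery scores against ground truth.

#' ROC curve and AUC
#'
#' Scores (typically posterior inclusion probabilities) are evaluated against
#' binary ground-truth labels. The ROC staircase is built over the distinct
#' score thresholds; the AUC is computed through the Mann-Whitney identity
#' with midrank tie handling, which equals the trapezoidal area under the
#' staircase.
#'
#' @param scores numeric vector.
#' @param labels binary (0/1 or logical) vector of the same length.
#' @return list of class `roc_result` with `thresholds`, `fpr`, `tpr`
#'   (staircase from (0,0) to (1,1)) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  stopifnot(length(scores) == length(labels))
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("roc_auc: need at least one positive and one negative label; ",
         "AUC is undefined for a single class", call. = FALSE)
  }
  # Mann-Whitney with midranks
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  # staircase over decreasing distinct thresholds
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  last_of_tie <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(l)[last_of_tie]
  fp <- cumsum(1L - l)[last_of_tie]
  structure(list(
    thresholds = s[last_of_tie],
    fpr = c(0, fp / n_neg),
    tpr = c(0, tp / n_pos),
    auc = auc), class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat("<roc_result> AUC =", format(x$auc, digits = 4), "over",
      length(x$thresholds), "thresholds\n")
  invisible(x)
}

#' Summarize AUC over a harness table
#'
#' Computes per-replicate AUCs of `pip` against `true_diff` from a table
#' produced by [run_simulation_cell()] and returns the mean and its standard
#' error over replicates.
#'
#' @param cell data.frame with columns `replicate`, `true_diff`, `pip`.
#' @return data.frame with one row: `replicates`, `mean_auc`, `se_auc`.
#' @export
auc_summary <- function(cell) {
  stopifnot(all(c("replicate", "true_diff", "pip") %in% names(cell)))
  aucs <- vapply(split(cell, cell$replicate),
                 function(d) roc_auc(d$pip, d$true_diff)$auc, 1.0)
  data.frame(replicates = length(aucs), mean_auc = mean(aucs),
             se_auc = sd(aucs) / sqrt(length(aucs)))
}
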