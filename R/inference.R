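# Posterior summaries: inclusion probabilities, inclusion Bayes factors, and
# parameter tables from stored draws.

#' Posterior inclusion probability
#'
#' The posterior mean of a binary inclusion indicator, estimated as the
#' proportion of MCMC draws in which it equals one.
#'
#' @param indicator_draws binary vector of stored indicator values.
#' @return probability in `[0, 1]`.
#' @export
posterior_inclusion_probability <- function(indicator_draws) {
  if (length(indicator_draws) < 1L) {
    stop("posterior_inclusion_probability: empty chain", call. = FALSE)
  }
  mean(indicator_draws)
}

#' Inclusion Bayes factor
#'
#' `bf_10 = (pip / (1 - pip)) / prior_odds`: the posterior odds of including
#' a difference divided by its prior odds. Values above 1 support a group
#' difference, values below 1 support equivalence, and `bf_01 = 1 / bf_10`.
#' A pip of exactly 0 or 1 is beyond the resolution of `T` draws; it is
#' clamped to `1/(2T)` or `1 - 1/(2T)` and the result flagged as a bound.
#'
#' @param pip posterior inclusion probability.
#' @param prior_odds prior inclusion odds, from
#'   [single_indicator_prior_odds()].
#' @param T number of posterior draws behind `pip`.
#' @return list with `bf_10`, `bf_01`, `pip` (possibly clamped), and
#'   `is_bound`.
#' @export
inclusion_bayes_factor <- function(pip, prior_odds, T) {
  stopifnot(pip >= 0, pip <= 1, prior_odds > 0, T >= 1)
  is_bound <- pip %in% c(0, 1)
  if (pip == 0) pip <- 1 / (2 * T)
  if (pip == 1) pip <- 1 - 1 / (2 * T)
  bf <- (pip / (1 - pip)) / prior_odds
  list(bf_10 = bf, bf_01 = 1 / bf, pip = pip, is_bound = is_bound)
}

chain_summary <- function(x) {
  c(mean = mean(x), sd = sd(x),
    lower = unname(quantile(x, 0.025, type = 7)),
    upper = unname(quantile(x, 0.975, type = 7)))
}

# summaries of difference draws: model-averaged over all draws, conditional
# over draws with the indicator on (absent when included < min_count times)
effect_table <- function(par_draws, ind_draws, prior_odds, min_count = 10L) {
  T <- nrow(par_draws)
  out <- data.frame(effect = colnames(par_draws), pip = NA_real_,
                    bf_10 = NA_real_, bf_01 = NA_real_, bf_bound = NA,
                    mean = NA_real_, sd = NA_real_,
                    lower = NA_real_, upper = NA_real_,
                    cond_mean = NA_real_, cond_sd = NA_real_,
                    cond_lower = NA_real_, cond_upper = NA_real_,
                    stringsAsFactors = FALSE)
  for (k in seq_len(ncol(par_draws))) {
    ind <- ind_draws[, k]
    pip <- posterior_inclusion_probability(ind)
    bf <- inclusion_bayes_factor(pip, prior_odds, T)
    out$pip[k] <- pip
    out$bf_10[k] <- bf$bf_10; out$bf_01[k] <- bf$bf_01
    out$bf_bound[k] <- bf$is_bound
    out[k, c("mean", "sd", "lower", "upper")] <- chain_summary(par_draws[, k])
    on <- ind == 1L
    if (sum(on) >= min_count) {
      out[k, c("cond_mean", "cond_sd", "cond_lower", "cond_upper")] <-
        chain_summary(par_draws[on, k])
    }
  }
  out
}

plain_table <- function(par_draws) {
  s <- t(apply(par_draws, 2L, chain_summary))
  data.frame(effect = colnames(par_draws), s, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Summarize posterior draws
#'
#' Turns an `omrf_draws` object into per-effect tables: posterior inclusion
#' probabilities and inclusion Bayes factors for every tested difference,
#' plus model-averaged and inclusion-conditional posterior mean / sd /
#' central 95% intervals (type-7 quantiles). Conditional summaries are
#' reported as `NA` when an effect was included in fewer than `min_count`
#' draws.
#'
#' @param draws an `omrf_draws` object from [run_estimation()] or
#'   [run_selection()].
#' @param min_count minimum number of inclusion draws for conditional
#'   summaries (default 10).
#' @return list of class `omrf_summary`: `interaction_diff_tests`,
#'   `threshold_diff_tests` (Collapse mode only), `overall_interactions`,
#'   overall/group threshold tables, and run metadata.
#' @export
summarize_draws <- function(draws, min_count = 10L) {
  stopifnot(inherits(draws, "omrf_draws"))
  pri <- draws$priors
  out <- list(
    mode = draws$mode,
    selection = draws$selection,
    n_per_group = draws$n_per_group,
    seed = draws$config$seed,
    alignment_plan = draws$alignment_plan,
    priors = pri,
    overall_interactions = plain_table(draws$overall_interactions),
    interaction_diff_tests = effect_table(
      draws$interaction_diffs, draws$interaction_indicators,
      single_indicator_prior_odds(pri$interaction_indicator_prior),
      min_count)
  )
  if (draws$mode == "Collapse") {
    out$overall_thresholds <- plain_table(draws$overall_thresholds)
    # one indicator per variable governs that variable's whole diff vector:
    # expand to per-threshold rows for the parameter table, but test at the
    # variable level
    vn <- draws$variable_names
    var_of_col <- sub("\\(.*$", "", colnames(draws$threshold_diffs))
    ind_expanded <- draws$threshold_indicators[, match(var_of_col, vn),
                                               drop = FALSE]
    colnames(ind_expanded) <- colnames(draws$threshold_diffs)
    out$threshold_diff_params <- effect_table(
      draws$threshold_diffs, ind_expanded,
      single_indicator_prior_odds(pri$threshold_indicator_prior), min_count)
    T <- nrow(draws$threshold_indicators)
    po <- single_indicator_prior_odds(pri$threshold_indicator_prior)
    tests <- lapply(seq_along(vn), function(i) {
      pip <- posterior_inclusion_probability(draws$threshold_indicators[, i])
      bf <- inclusion_bayes_factor(pip, po, T)
      data.frame(effect = vn[i], pip = pip, bf_10 = bf$bf_10,
                 bf_01 = bf$bf_01, bf_bound = bf$is_bound,
                 stringsAsFactors = FALSE)
    })
    out$threshold_diff_tests <- do.call(rbind, tests)
  } else {
    out$thresholds_group1 <- plain_table(draws$thresholds_group1)
    out$thresholds_group2 <- plain_table(draws$thresholds_group2)
  }
  class(out) <- "omrf_summary"
  out
}

#' @export
print.omrf_summary <- function(x, ...) {
  cat("<omrf_summary> mode=", x$mode, ", n = ",
      paste(x$n_per_group, collapse = "/"), " per group\n", sep = "")
  cat("\nInteraction difference tests:\n")
  print(x$interaction_diff_tests[, c("effect", "pip", "bf_10", "bf_01",
                                     "mean", "sd")], digits = 3)
  if (!is.null(x$threshold_diff_tests)) {
    cat("\nThreshold difference tests:\n")
    print(x$threshold_diff_tests, digits = 3)
  }
  invisible(x)
}
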