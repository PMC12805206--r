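# Adaptive Metropolis-within-Gibbs over the pseudoposterior: configuration,
# the estimation-mode and selection-mode drivers (C++ core), and the scalar
# random-walk / adaptation primitives used throughout.

#' Sampler configuration
#'
#' @param main_iterations posterior draws to store (default 10000).
#' @param burnin_iterations total burn-in, split into two equal parts (odd
#'   totals put the extra iteration in part one). Part one adapts proposal
#'   sds without indicator updates; part two adds indicator updates
#'   (selection mode only). Default 5000.
#' @param seed integer seed; every source of randomness in a run derives
#'   from it.
#' @param target_accept target acceptance rate of the Robbins-Monro
#'   adaptation (default 0.44, the scalar random-walk optimum).
#' @param decay adaptation decay exponent (default 0.6).
#' @param sd_bounds length-2 positive bounds on all proposal sds.
#' @return list of class `sampler_config`.
#' @export
sampler_config <- function(main_iterations = 10000,
                           burnin_iterations = 5000,
                           seed = 1L,
                           target_accept = 0.44,
                           decay = 0.6,
                           sd_bounds = c(1e-3, 10)) {
  stopifnot(main_iterations >= 1, burnin_iterations >= 1,
            target_accept > 0, target_accept < 1, decay > 0,
            length(sd_bounds) == 2, all(sd_bounds > 0),
            sd_bounds[1] < sd_bounds[2])
  structure(list(
    main_iterations = as.integer(main_iterations),
    burnin_iterations = as.integer(burnin_iterations),
    burnin_phase1 = as.integer(ceiling(burnin_iterations / 2)),
    burnin_phase2 = as.integer(floor(burnin_iterations / 2)),
    seed = as.integer(seed),
    target_accept = target_accept, decay = decay,
    sd_bounds = sd_bounds), class = "sampler_config")
}

#' One scalar/vector random-walk Metropolis step
#'
#' Symmetric Gaussian proposal; the move is accepted with probability
#' `min(1, exp(log_target(proposal) - log_target(current)))`. A proposal with
#' non-finite log-target is treated as a rejection.
#'
#' @param current numeric vector, current state.
#' @param log_target function returning the log target density.
#' @param proposal_sd positive proposal sd(s), recycled over components.
#' @return list with `value` (new state) and `accepted` (logical).
#' @export
rw_metropolis_step <- function(current, log_target, proposal_sd) {
  stopifnot(all(proposal_sd > 0))
  lt0 <- log_target(current)
  if (!is.finite(lt0)) {
    stop("rw_metropolis_step: log_target not finite at the current state",
         call. = FALSE)
  }
  prop <- current + rnorm(length(current), sd = proposal_sd)
  lt1 <- log_target(prop)
  if (is.finite(lt1) && log(runif(1)) < lt1 - lt0) {
    list(value = prop, accepted = TRUE)
  } else {
    list(value = current, accepted = FALSE)
  }
}

#' Robbins-Monro proposal-sd adaptation
#'
#' `log sd <- log sd + step^(-decay) * (accepted - target)`, clipped to the
#' configured bounds. Applied only during burn-in by the samplers.
#'
#' @param sd current proposal sd.
#' @param accepted logical, last proposal accepted?
#' @param step iteration number (>= 1).
#' @param cfg a [sampler_config()].
#' @return updated sd within `cfg$sd_bounds`.
#' @export
adapt_proposal_sd <- function(sd, accepted, step, cfg = sampler_config()) {
  stopifnot(step >= 1, sd > 0)
  ls <- log(sd) + step^(-cfg$decay) * (as.numeric(accepted) - cfg$target_accept)
  min(max(exp(ls), cfg$sd_bounds[1]), cfg$sd_bounds[2])
}

dedup_rows <- function(x) {
  if (nrow(x) == 0L) {
    return(list(u = x, w = integer(0)))
  }
  key <- apply(x, 1L, paste, collapse = ",")
  idx <- !duplicated(key)
  u <- x[idx, , drop = FALSE]
  w <- as.integer(table(factor(key, levels = key[idx])))
  list(u = u, w = w)
}

ind_prior_code <- function(prior) {
  if (prior$type == "bernoulli") c(0, prior$pi, 0)
  else c(1, prior$alpha, prior$beta)
}

run_sampler_internal <- function(data1, data2, priors, cfg, mode, selection,
                                 init = list(), update = list()) {
  stopifnot(inherits(priors, "prior_config"), inherits(cfg, "sampler_config"))
  al <- align_categories(data1, data2, mode = mode)
  d1 <- al$data1; d2 <- al$data2
  p <- ncol(d1$responses)
  collapse <- al$plan$mode == "Collapse"
  ncat1 <- d1$n_categories; ncat2 <- d2$n_categories
  maxm <- max(c(ncat1, ncat2)) - 1L
  npairs <- p * (p - 1L) / 2L

  upd <- modifyList(list(thresholds = TRUE, interactions = TRUE,
                         threshold_diffs = TRUE, interaction_diffs = TRUE),
                    update)

  zero_mat <- function(x) if (is.null(x)) matrix(0, p, max(maxm, 1L)) else x
  init_thrA <- zero_mat(init$thrA)
  init_thrB <- zero_mat(init$thrB)
  init_sigma <- init$sigma %||% matrix(0, p, p)
  init_sigdiff <- init$sigdiff %||% matrix(0, p, p)
  init_thr_ind <- init$thr_ind %||% rep(1L, p)
  init_sig_ind <- init$sig_ind %||% rep(1L, npairs)

  du1 <- dedup_rows(d1$responses)
  du2 <- dedup_rows(d2$responses)

  tp <- ind_prior_code(priors$threshold_indicator_prior)
  sp <- ind_prior_code(priors$interaction_indicator_prior)

  set.seed(cfg$seed)
  res <- cpp_run_sampler(
    du1$u, du1$w, du2$u, du2$w, ncat1, ncat2,
    if (collapse) 0L else 1L, selection,
    priors$threshold_shape_a, priors$threshold_shape_b,
    priors$overall_interaction_scale,
    priors$threshold_difference_scale, priors$interaction_difference_scale,
    tp[1], tp[2], tp[3], sp[1], sp[2], sp[3],
    cfg$main_iterations, cfg$burnin_phase1, cfg$burnin_phase2,
    cfg$target_accept, cfg$decay, cfg$sd_bounds[1], cfg$sd_bounds[2],
    upd$thresholds, upd$interactions,
    upd$threshold_diffs, upd$interaction_diffs,
    init_thrA, init_thrB, init_sigma, init_sigdiff,
    as.integer(init_thr_ind), as.integer(init_sig_ind))

  vn <- d1$variable_names
  pair_names <- character(npairs)
  k <- 1L
  for (i in seq_len(p - 1L)) {
    for (j in (i + 1L):p) {
      pair_names[k] <- paste0(vn[i], "--", vn[j]); k <- k + 1L
    }
  }
  # select and name the valid (ragged) threshold columns, variable-major
  thr_cols <- function(mi) {
    cols <- integer(0); nm <- character(0)
    for (i in seq_len(p)) {
      for (c in seq_len(mi[i])) {
        cols <- c(cols, (c - 1L) * p + i)
        nm <- c(nm, paste0(vn[i], "(", c, ")"))
      }
    }
    list(cols = cols, names = nm)
  }
  miA <- ncat1 - 1L
  miB <- if (collapse) ncat1 - 1L else ncat2 - 1L
  ca <- thr_cols(miA); cb <- thr_cols(miB)
  thrA <- res$thrA[, ca$cols, drop = FALSE]; colnames(thrA) <- ca$names
  thrB <- res$thrB[, cb$cols, drop = FALSE]; colnames(thrB) <- cb$names
  colnames(res$sigma) <- colnames(res$sigdiff) <-
    colnames(res$sig_ind) <- pair_names
  colnames(res$thr_ind) <- vn

  out <- list(
    mode = al$plan$mode,
    selection = selection,
    alignment_plan = al$plan,
    priors = priors,
    config = cfg,
    variable_names = vn,
    pair_names = pair_names,
    n_per_group = c(nrow(d1$responses), nrow(d2$responses)),
    acceptance_rates = setNames(
      res$acceptance_rates,
      c("threshold", "threshold_diff", "interaction", "interaction_diff",
        "threshold_flip", "interaction_flip")),
    final_proposal_sd = res$final_sd
  )
  if (collapse) {
    out$overall_thresholds <- thrA
    out$threshold_diffs <- thrB
    out$threshold_indicators <- res$thr_ind
  } else {
    out$thresholds_group1 <- thrA
    out$thresholds_group2 <- thrB
  }
  out$overall_interactions <- res$sigma
  out$interaction_diffs <- res$sigdiff
  out$interaction_indicators <- res$sig_ind
  class(out) <- "omrf_draws"
  out
}

#' Estimation-mode sampler (all difference parameters free)
#'
#' Cycles through the four parameter blocks (overall thresholds, overall
#' interactions, threshold differences, interaction differences) with
#' adaptive scalar/vector random-walk Metropolis updates; no indicator
#' (selection) moves. Parameters start at zero and proposal sds at one;
#' adaptation runs during burn-in only. Runs are deterministic given
#' `cfg$seed`.
#'
#' @param data1,data2 [ordinal_dataset()] objects on a common pooled coding
#'   (Group 1 is `data1`; all difference contrasts are Group 2 minus Group 1).
#' @param priors a [prior_config()].
#' @param cfg a [sampler_config()].
#' @param mode category alignment, `"Collapse"` (default) or `"Free"`.
#' @param init,update optional named lists for advanced use: initial values
#'   (`thrA`, `thrB`, `sigma`, `sigdiff`) and logical switches turning
#'   parameter-block updates off (`thresholds`, `interactions`,
#'   `threshold_diffs`, `interaction_diffs`), e.g. to hold the overall model
#'   fixed in oracle checks.
#' @return An `omrf_draws` object: per-iteration parameter records, indicator
#'   records, acceptance rates, final proposal sds, and metadata.
#' @export
run_estimation <- function(data1, data2, priors = prior_config(),
                           cfg = sampler_config(), mode = "Collapse",
                           init = list(), update = list()) {
  run_sampler_internal(data1, data2, priors, cfg, mode, selection = FALSE,
                       init = init, update = update)
}

#' Selection-mode sampler (spike-and-slab difference testing)
#'
#' Extends the estimation sampler with pairwise Metropolis moves that jointly
#' flip each difference-inclusion indicator and its parameter (vector):
#' an exclusion proposal sets the parameter to exact zero, an inclusion
#' proposal draws it from the tuned Gaussian proposal and accepts with the
#' pseudoposterior-times-slab over proposal-density ratio times the
#' indicator prior odds. Burn-in part one runs without indicator moves.
#' Threshold differences are tested only under `"Collapse"` alignment; in
#' `"Free"` mode group thresholds are estimated separately and only
#' interaction differences are tested.
#'
#' @inheritParams run_estimation
#' @return An `omrf_draws` object; in every stored draw an indicator of zero
#'   coincides with an exactly-zero difference parameter.
#' @export
run_selection <- function(data1, data2, priors = prior_config(),
                          cfg = sampler_config(), mode = "Collapse",
                          init = list(), update = list()) {
  run_sampler_internal(data1, data2, priors, cfg, mode, selection = TRUE,
                       init = init, update = update)
}

#' @export
print.omrf_draws <- function(x, ...) {
  cat("<omrf_draws> ", x$config$main_iterations, " draws, ",
      length(x$variable_names), " variables, mode=", x$mode,
      if (x$selection) ", selection" else ", estimation", "\n", sep = "")
  cat("  groups n = ", paste(x$n_per_group, collapse = " / "), "\n", sep = "")
  invisible(x)
}
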