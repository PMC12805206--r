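# Synthetic data generation: sampling from an OMRF (exact or Gibbs),
# two-group truth construction, the marginal-category safeguard, and the
# simulation harness.

#' Truth-model configuration for simulations
#'
#' Describes the data-generating two-group OMRF. Nonzero overall interactions
#' are drawn from `interaction_pool` if supplied, otherwise from a shifted
#' gamma surrogate (`pool_shift + Gamma(pool_shape, rate = pool_rate)`),
#' a right-skewed positive distribution standing in for interaction values
#' estimated from large empirical Likert datasets. Standalone ("target")
#' thresholds are drawn from `threshold_pool` if supplied, otherwise i.i.d.
#' normal with sd `threshold_sd`; a deterministic mean-field recentering pass
#' then offsets the thresholds for the realized interaction structure so
#' marginal category frequencies stay comparable across density conditions.
#'
#' @param p number of variables (>= 2).
#' @param n_categories categories per variable (scalar recycled or vector;
#'   default 4, a 4-point Likert format).
#' @param density probability that each overall interaction is nonzero.
#' @param prop_diff fraction of all variable pairs receiving a nonzero
#'   interaction difference (rounded to the nearest count).
#' @param diff_low,diff_high bounds of the uniform magnitude mixture for
#'   difference values; signs are positive or negative with probability 1/2
#'   each (defaults 0.1 and 0.5).
#' @param interaction_pool optional numeric vector of plausible interaction
#'   values, sampled with replacement.
#' @param pool_shape,pool_rate,pool_shift gamma-surrogate parameters
#'   (defaults 1.5, 10, 0.05: mean 0.2, right-skewed, strictly positive).
#' @param threshold_pool optional numeric vector of standalone threshold
#'   values.
#' @param threshold_sd sd of the normal threshold surrogate (default 0.75).
#' @param min_second_category_count marginal-category safeguard: minimum
#'   count required in the second-most frequent observed category of every
#'   variable in every group (default 10).
#' @param seed integer seed used by the harness.
#' @return list of class `truth_config`.
#' @export
truth_config <- function(p, n_categories = 4L, density = 0.15,
                         prop_diff = 0.2, diff_low = 0.1, diff_high = 0.5,
                         interaction_pool = NULL,
                         pool_shape = 1.5, pool_rate = 10, pool_shift = 0.05,
                         threshold_pool = NULL, threshold_sd = 0.75,
                         min_second_category_count = 10L, seed = 1L) {
  stopifnot(p >= 2, density >= 0, density <= 1,
            prop_diff >= 0, prop_diff <= 1,
            diff_low > 0, diff_low < diff_high,
            min_second_category_count >= 1)
  n_categories <- rep_len(as.integer(n_categories), p)
  stopifnot(all(n_categories >= 2))
  structure(list(
    p = as.integer(p), n_categories = n_categories,
    density = density, prop_diff = prop_diff,
    diff_low = diff_low, diff_high = diff_high,
    interaction_pool = interaction_pool,
    pool_shape = pool_shape, pool_rate = pool_rate, pool_shift = pool_shift,
    threshold_pool = threshold_pool, threshold_sd = threshold_sd,
    min_second_category_count = as.integer(min_second_category_count),
    seed = as.integer(seed)), class = "truth_config")
}

# standalone marginal mean of one variable with thresholds mu (categories
# 1..m, baseline 0) and no neighbors
standalone_mean <- function(mu) {
  w <- exp(c(0, mu) - max(c(0, mu)))
  p <- w / sum(w)
  sum((seq_along(p) - 1) * p)
}

#' Generate a two-group truth model
#'
#' Retains each of the `p(p-1)/2` overall interactions independently with
#' probability `density` and fills retained edges from the interaction pool.
#' Thresholds are the drawn standalone targets offset by a mean-field
#' recentering term `-c * sum_j sigma[i,j] * ebar_j` (with `ebar_j` the
#' standalone marginal mean of variable `j`), so that the realized marginal
#' category frequencies track the targets regardless of network density.
#' A fraction `prop_diff` of all pairs, chosen uniformly at random, receives
#' an interaction difference with magnitude `Uniform(diff_low, diff_high)`
#' and random sign; threshold differences are zero.
#'
#' Uses the current RNG state (seed management belongs to the caller or the
#' harness).
#'
#' @param cfg a [truth_config()].
#' @return A [two_group_model()].
#' @export
generate_truth <- function(cfg) {
  stopifnot(inherits(cfg, "truth_config"))
  p <- cfg$p
  npairs <- p * (p - 1L) / 2L
  if (cfg$prop_diff > 0 && npairs == 0L) {
    stop("generate_truth: prop_diff > 0 but there are no variable pairs",
         call. = FALSE)
  }
  draw_pool <- function(n) {
    if (!is.null(cfg$interaction_pool)) {
      sample(cfg$interaction_pool, n, replace = TRUE)
    } else {
      cfg$pool_shift + rgamma(n, shape = cfg$pool_shape, rate = cfg$pool_rate)
    }
  }
  sigma <- matrix(0, p, p)
  keep <- runif(npairs) < cfg$density
  vals <- numeric(npairs)
  vals[keep] <- draw_pool(sum(keep))
  k <- 1L
  for (i in seq_len(p - 1L)) {
    for (j in (i + 1L):p) {
      sigma[i, j] <- sigma[j, i] <- vals[k]
      k <- k + 1L
    }
  }
  m <- cfg$n_categories - 1L
  mu0 <- lapply(seq_len(p), function(i) {
    if (!is.null(cfg$threshold_pool)) {
      sample(cfg$threshold_pool, m[i], replace = TRUE)
    } else {
      rnorm(m[i], sd = cfg$threshold_sd)
    }
  })
  ebar <- vapply(mu0, standalone_mean, 1.0)
  thresholds <- lapply(seq_len(p), function(i) {
    field <- sum(sigma[i, -i] * ebar[-i])
    mu0[[i]] - seq_len(m[i]) * field
  })
  n_diff <- round(cfg$prop_diff * npairs)
  dvals <- numeric(npairs)
  if (n_diff > 0) {
    which_diff <- sample.int(npairs, n_diff)
    mag <- runif(n_diff, cfg$diff_low, cfg$diff_high)
    sgn <- ifelse(runif(n_diff) < 0.5, -1, 1)
    dvals[which_diff] <- sgn * mag
  }
  sigdiff <- matrix(0, p, p)
  k <- 1L
  for (i in seq_len(p - 1L)) {
    for (j in (i + 1L):p) {
      sigdiff[i, j] <- sigdiff[j, i] <- dvals[k]
      k <- k + 1L
    }
  }
  two_group_model(
    group_model(thresholds, sigma),
    difference_model(lapply(m, numeric), sigdiff))
}

#' Sample observations from a one-group OMRF
#'
#' `method = "exact"` draws rows by inverse-CDF sampling from the enumerated
#' joint pmf (subject to the state-count guard); `method = "gibbs"` runs `n`
#' parallel single-site Gibbs chains from uniform random starts for
#' `gibbs_burnin` full sweeps and returns the final states.
#'
#' @param model a [group_model()].
#' @param n number of rows.
#' @param method `"exact"` or `"gibbs"`.
#' @param gibbs_burnin sweeps per chain in Gibbs mode (default 1000).
#' @param max_states enumeration guard for exact mode.
#' @return An [ordinal_dataset()].
#' @export
sample_dataset <- function(model, n, method = c("exact", "gibbs"),
                           gibbs_burnin = 1000L, max_states = 1e7) {
  method <- match.arg(method)
  ncat <- model_n_categories(model)
  p <- length(ncat)
  if (method == "exact") {
    pmf <- tryCatch(enumerate_joint_pmf(model, max_states = max_states),
                    error = function(e) {
                      stop(conditionMessage(e),
                           " (use method = \"gibbs\" instead)", call. = FALSE)
                    })
    cdf <- cumsum(pmf$probabilities)
    idx <- findInterval(runif(n), cdf) + 1L
    x <- pmf$states[idx, , drop = FALSE]
  } else {
    x <- vapply(seq_len(p),
                function(i) sample.int(ncat[i], n, replace = TRUE) - 1L,
                integer(n))
    x <- matrix(as.integer(x), nrow = n)
    sigma <- model$interactions
    for (sweep in seq_len(gibbs_burnin)) {
      for (i in seq_len(p)) {
        mu <- c(0, model$thresholds[[i]])
        cats <- seq_along(mu) - 1
        rest <- x %*% sigma[, i]
        logw <- outer(as.numeric(rest), cats) + rep(mu, each = n)
        mx <- apply(logw, 1L, max)
        w <- exp(logw - mx)
        cdf <- w / rowSums(w)
        for (c in 2:ncol(cdf)) cdf[, c] <- cdf[, c] + cdf[, c - 1L]
        x[, i] <- as.integer(rowSums(runif(n) > cdf[, -ncol(cdf), drop = FALSE]))
      }
    }
  }
  ordinal_dataset(x, n_categories = ncat)
}

#' Generate truth and data under the marginal-category safeguard
#'
#' Regenerates the whole process -- truth model and both groups' data --
#' until, for every variable in every group, the second-most frequent
#' observed category holds at least `cfg$min_second_category_count`
#' observations. Near-constant variables carry almost no information about
#' thresholds or interactions, so draws violating the constraint are
#' discarded wholesale rather than patched.
#'
#' @param cfg a [truth_config()].
#' @param n observations per group.
#' @param generator function `cfg -> two_group_model` (default
#'   [generate_truth()]).
#' @param method sampling method passed to [sample_dataset()].
#' @param max_resample cap on regeneration rounds (default 100).
#' @return list with `truth`, `data1`, `data2`, `resample_count`.
#' @export
apply_marginal_safeguard <- function(cfg, n, generator = generate_truth,
                                     method = "exact", max_resample = 100L) {
  stopifnot(cfg$min_second_category_count < n)
  ok <- function(data) {
    for (i in seq_len(ncol(data$responses))) {
      counts <- sort(tabulate(data$responses[, i] + 1L,
                              nbins = data$n_categories[i]),
                     decreasing = TRUE)
      if (counts[2] < cfg$min_second_category_count) return(FALSE)
    }
    TRUE
  }
  for (attempt in 0:max_resample) {
    truth <- generator(cfg)
    d1 <- sample_dataset(derive_group_model(truth, 1), n, method = method)
    d2 <- sample_dataset(derive_group_model(truth, 2), n, method = method)
    if (ok(d1) && ok(d2)) {
      return(list(truth = truth, data1 = d1, data2 = d2,
                  resample_count = attempt))
    }
  }
  stop("apply_marginal_safeguard: constraint not met after ", max_resample,
       " resampling rounds; thresholds or sample size are too extreme",
       call. = FALSE)
}

#' Run one simulation condition cell
#'
#' For each replicate: generate a truth model and safeguarded data, run the
#' selection sampler, and record every pair's posterior inclusion probability
#' next to its ground-truth difference flag.
#'
#' @param cfg a [truth_config()].
#' @param n_per_group observations per group.
#' @param priors a [prior_config()].
#' @param sampler_cfg a [sampler_config()] (its seed is re-derived per
#'   replicate from `cfg$seed`).
#' @param replicates number of replicates (>= 1).
#' @param method data sampling method.
#' @return data.frame with columns `replicate`, `edge`, `true_diff`
#'   (logical), `delta` (true difference value), `pip`.
#' @export
run_simulation_cell <- function(cfg, n_per_group, priors = prior_config(),
                                sampler_cfg = sampler_config(),
                                replicates = 10L, method = "exact") {
  stopifnot(replicates >= 1)
  rows <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    data_seed <- cfg$seed + 2L * (r - 1L)
    fit_seed <- cfg$seed + 2L * (r - 1L) + 1L
    set.seed(data_seed)
    gen <- apply_marginal_safeguard(cfg, n_per_group, method = method)
    scfg <- sampler_cfg
    scfg$seed <- fit_seed
    draws <- run_selection(gen$data1, gen$data2, priors, scfg,
                           mode = "Collapse")
    pip <- colMeans(draws$interaction_indicators)
    delta <- gen$truth$diffs$interaction_diffs
    delta_vec <- delta[pair_index_matrix(cfg$p)]
    rows[[r]] <- data.frame(
      replicate = r, edge = draws$pair_names,
      true_diff = delta_vec != 0, delta = delta_vec, pip = unname(pip),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# (i, j) pairs with i < j in the sampler's row-major order
pair_index_matrix <- function(p) {
  i <- rep(seq_len(p - 1L), times = (p - 1L):1L)
  j <- unlist(lapply(seq_len(p - 1L), function(a) (a + 1L):p))
  cbind(i, j)
}
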