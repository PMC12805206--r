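# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths: direct formulas, enumeration, and
# quadrature at tiny problem sizes.

# Ising pmf over x in {0,1}^p with fields h and couplings J, computed by a
# direct loop over states (independent of enumerate_joint_pmf).
ising_pmf_direct <- function(h, J) {
  p <- length(h)
  states <- as.matrix(expand.grid(rep(list(0:1), p)))
  w <- apply(states, 1L, function(x) {
    e <- sum(h * x)
    for (i in seq_len(p - 1L)) {
      for (j in (i + 1L):p) e <- e + J[i, j] * x[i] * x[j]
    }
    exp(e)
  })
  list(states = states, probabilities = w / sum(w))
}

# Full conditional of variable i computed from a joint pmf table.
conditional_from_pmf <- function(pmf, row, i) {
  rest <- pmf$states[, -i, drop = FALSE]
  match_rows <- apply(rest, 1L, function(r) all(r == row[-i]))
  pr <- pmf$probabilities[match_rows]
  ord <- order(pmf$states[match_rows, i])
  pr <- pr[ord]
  pr / sum(pr)
}

# Direct (scalar, formula-level) evaluation of the log full conditional of
# one observation, written independently of category_probabilities.
log_conditional_direct <- function(thresholds, sigma, row, i) {
  m <- length(thresholds[[i]])
  rest <- 0
  for (j in seq_along(row)) if (j != i) rest <- rest + sigma[i, j] * row[j]
  logw <- vapply(0:m, function(c) {
    mu_c <- if (c == 0) 0 else thresholds[[i]][c]
    mu_c + c * rest
  }, 1.0)
  logw[row[i] + 1L] - log(sum(exp(logw)))
}

# 1-D quadrature oracle for the posterior inclusion probability of a single
# interaction difference with a Cauchy slab and fixed overall parameters.
quadrature_pip <- function(overall, d1, d2, slab_scale = 1, prior_pi = 0.5,
                           pair = c(1L, 2L)) {
  p <- length(overall$thresholds)
  mk_diff <- function(delta) {
    dm <- matrix(0, p, p)
    dm[pair[1], pair[2]] <- dm[pair[2], pair[1]] <- delta
    difference_model(lapply(overall$thresholds, function(t) numeric(length(t))),
                     dm)
  }
  lpl <- function(delta) {
    two_group_log_pseudolikelihood(two_group_model(overall, mk_diff(delta)),
                                   d1, d2)
  }
  l0 <- lpl(0)
  f <- Vectorize(function(d) exp(lpl(d) - l0) * dcauchy(d, scale = slab_scale))
  m1_rel <- integrate(f, -Inf, Inf, rel.tol = 1e-10)$value
  (prior_pi * m1_rel) / (prior_pi * m1_rel + (1 - prior_pi))
}

# Monte-Carlo standard error of the mean of a (possibly autocorrelated)
# chain, by non-overlapping batch means.
batch_se <- function(x, n_batch = 50L) {
  n <- length(x)
  b <- floor(n / n_batch)
  means <- vapply(seq_len(n_batch),
                  function(k) mean(x[((k - 1L) * b + 1L):(k * b)]), 1.0)
  sd(means) / sqrt(n_batch)
}

# small two-variable three-category test model
toy_model_2x3 <- function(sigma12 = 0.5) {
  group_model(list(c(0.3, -0.2), c(-0.1, 0.4)),
              matrix(c(0, sigma12, sigma12, 0), 2))
}

# deterministic small dataset on p variables with the given category counts
toy_data <- function(n, ncat, seed = 1) {
  set.seed(seed)
  x <- vapply(ncat, function(m) sample.int(m, n, replace = TRUE) - 1L,
              integer(n))
  ordinal_dataset(matrix(as.integer(x), nrow = n), n_categories = ncat)
}

# empty dataset helper for prior-only runs
empty_data <- function(ncat) {
  ordinal_dataset(matrix(integer(0), 0, length(ncat)), n_categories = ncat)
}

row_major_pairs <- function(p) {
  cbind(rep(seq_len(p - 1L), times = (p - 1L):1L),
        unlist(lapply(seq_len(p - 1L), function(a) (a + 1L):p)))
}
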