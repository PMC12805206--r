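# Metropolis primitives, adaptation, and the estimation/selection drivers.

test_that("random-walk Metropolis accepts uphill moves and targets correctly", {
  # a flat target makes every move uphill-or-equal: always accepted
  set.seed(1)
  for (rep in 1:20) {
    st <- rw_metropolis_step(rnorm(1), function(x) 0, proposal_sd = 1)
    expect_true(st$accepted)
  }
  # a non-finite proposal target is treated as a rejection
  st <- rw_metropolis_step(0, function(x) if (x == 0) 0 else -Inf, 1)
  expect_false(st$accepted)
  expect_identical(st$value, 0)
  # long run on a standard normal target
  set.seed(2)
  x <- numeric(50000)
  cur <- 0
  for (t in seq_along(x)) {
    st <- rw_metropolis_step(cur, function(z) -z^2 / 2, 2.4)
    cur <- st$value
    x[t] <- cur
  }
  expect_lt(abs(mean(x)), 0.05)
  expect_lt(abs(var(x) - 1), 0.1)
})

test_that("a fixed downhill step is accepted at its Metropolis rate", {
  # log target drop of log 2 => acceptance probability 1/2
  set.seed(3)
  acc <- replicate(4000, {
    st <- rw_metropolis_step(0, function(z) ifelse(z == 0, 0, -log(2)), 1)
    st$accepted
  })
  expect_lt(abs(mean(acc) - 0.5), 3 * sqrt(0.25 / 4000))
})

test_that("proposal-sd adaptation drifts with acceptance and respects bounds", {
  cfg <- sampler_config()
  expect_gt(adapt_proposal_sd(1, TRUE, 10, cfg), 1)
  expect_lt(adapt_proposal_sd(1, FALSE, 10, cfg), 1)
  # any sequence stays inside the configured bounds
  sd <- 1
  for (t in 1:200) sd <- adapt_proposal_sd(sd, TRUE, t, cfg)
  expect_lte(sd, cfg$sd_bounds[2])
  sd <- 1
  for (t in 1:200) sd <- adapt_proposal_sd(sd, FALSE, t, cfg)
  expect_gte(sd, cfg$sd_bounds[1])
  # balanced acceptance at the target rate leaves sd essentially in place
  sd <- 1
  set.seed(4)
  for (t in 1:5000) sd <- adapt_proposal_sd(sd, runif(1) < cfg$target_accept,
                                            t, cfg)
  expect_lt(abs(log(sd)), 1)
})

test_that("adaptive sampling of a normal target lands near the target rate", {
  cfg <- sampler_config(target_accept = 0.44, decay = 0.6)
  set.seed(5)
  sd <- 8
  cur <- 0
  for (t in 1:3000) {  # burn-in with adaptation
    st <- rw_metropolis_step(cur, function(z) -z^2 / 2, sd)
    cur <- st$value
    sd <- adapt_proposal_sd(sd, st$accepted, t, cfg)
  }
  acc <- logical(3000)
  for (t in seq_along(acc)) {  # frozen sd
    st <- rw_metropolis_step(cur, function(z) -z^2 / 2, sd)
    cur <- st$value
    acc[t] <- st$accepted
  }
  expect_gt(mean(acc), 0.3)
  expect_lt(mean(acc), 0.6)
})

test_that("samplers are deterministic given the seed", {
  d1 <- toy_data(60, c(3L, 3L, 2L), seed = 31)
  d2 <- toy_data(60, c(3L, 3L, 2L), seed = 32)
  cfg <- sampler_config(main_iterations = 300, burnin_iterations = 200,
                        seed = 99)
  a <- run_selection(d1, d2, prior_config(), cfg)
  b <- run_selection(d1, d2, prior_config(), cfg)
  expect_identical(a$interaction_diffs, b$interaction_diffs)
  expect_identical(a$overall_thresholds, b$overall_thresholds)
  expect_identical(a$interaction_indicators, b$interaction_indicators)
  c2 <- run_estimation(d1, d2, prior_config(), cfg)
  d2r <- run_estimation(d1, d2, prior_config(), cfg)
  expect_identical(c2$overall_interactions, d2r$overall_interactions)
})

test_that("excluded difference parameters are exactly zero in every draw", {
  d1 <- toy_data(80, c(2L, 2L, 2L), seed = 41)
  d2 <- toy_data(80, c(2L, 2L, 2L), seed = 42)
  dr <- run_selection(d1, d2, prior_config(),
                      sampler_config(main_iterations = 500,
                                     burnin_iterations = 300, seed = 7))
  expect_true(all((dr$interaction_indicators == 0) ==
                  (dr$interaction_diffs == 0)))
  for (i in seq_along(dr$variable_names)) {
    off <- dr$threshold_indicators[, i] == 0
    expect_true(all(dr$threshold_diffs[off, i] == 0))
  }
})

test_that("prior-only selection roughly recovers Bernoulli(0.5) inclusion", {
  e <- empty_data(c(2L, 2L, 2L))
  dr <- run_selection(e, e, prior_config(),
                      sampler_config(main_iterations = 4000,
                                     burnin_iterations = 500, seed = 8))
  pips <- colMeans(dr$interaction_indicators)
  expect_true(all(abs(pips - 0.5) < 0.08))
})

test_that("estimation recovers overall interactions and null differences", {
  set.seed(51)
  p <- 4
  J <- matrix(0, p, p)
  J[upper.tri(J)] <- c(0.6, 0, 0.4, 0, 0.5, 0)
  J <- J + t(J)
  truth <- group_model(as.list(rnorm(p, sd = 0.3)), J)
  d1 <- sample_dataset(truth, 1500)
  d2 <- sample_dataset(truth, 1500)
  dr <- run_estimation(d1, d2, prior_config(),
                       sampler_config(main_iterations = 1200,
                                      burnin_iterations = 600, seed = 9))
  post_mean <- colMeans(dr$overall_interactions)
  post_sd <- apply(dr$overall_interactions, 2, sd)
  truth_vec <- J[row_major_pairs(p)]
  expect_true(all(abs(post_mean - truth_vec) < 3.5 * post_sd))
  # identical generating model in both groups: differences near zero
  dmean <- colMeans(dr$interaction_diffs)
  dsd <- apply(dr$interaction_diffs, 2, sd)
  expect_true(all(abs(dmean) < 3.5 * dsd))
})

test_that("initial values can be held fixed for oracle checks", {
  d1 <- toy_data(50, c(2L, 2L), seed = 61)
  d2 <- toy_data(50, c(2L, 2L), seed = 62)
  sig0 <- matrix(c(0, 0.3, 0.3, 0), 2)
  dr <- run_selection(d1, d2, prior_config(),
                      sampler_config(main_iterations = 200,
                                     burnin_iterations = 100, seed = 10),
                      init = list(thrA = matrix(0.1, 2, 1), sigma = sig0),
                      update = list(thresholds = FALSE, interactions = FALSE,
                                    threshold_diffs = FALSE))
  expect_true(all(dr$overall_thresholds == 0.1))
  expect_true(all(dr$overall_interactions == 0.3))
})

test_that("Free alignment estimates group thresholds separately", {
  # category 2 of variable 1 unobserved in group 1
  set.seed(71)
  x1 <- cbind(sample(0:1, 120, TRUE), sample(0:2, 120, TRUE))
  x2 <- cbind(sample(0:2, 120, TRUE), sample(0:2, 120, TRUE))
  d1 <- ordinal_dataset(x1, n_categories = c(3L, 3L))
  d2 <- ordinal_dataset(x2, n_categories = c(3L, 3L))
  dr <- run_selection(d1, d2, prior_config(),
                      sampler_config(main_iterations = 300,
                                     burnin_iterations = 200, seed = 11),
                      mode = "Free")
  expect_equal(ncol(dr$thresholds_group1), 1 + 2)  # 1 threshold + 2
  expect_equal(ncol(dr$thresholds_group2), 2 + 2)
  expect_null(dr$threshold_diffs)
  summ <- summarize_draws(dr)
  expect_null(summ$threshold_diff_tests)
  expect_s3_class(summ$interaction_diff_tests, "data.frame")
})
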