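# Two-group reparameterization, category alignment, and the two-group
# pseudolikelihood.

mk_two_group <- function(p = 3, seed = 1, ncat = rep(3L, 3)) {
  set.seed(seed)
  overall <- group_model(lapply(ncat - 1, rnorm),
                         matrix(rnorm(p * p, sd = 0.4), p, p))
  diffs <- difference_model(lapply(ncat - 1, function(k) rnorm(k, sd = 0.3)),
                            matrix(rnorm(p * p, sd = 0.3), p, p))
  two_group_model(overall, diffs)
}

test_that("group models distribute the difference evenly around the overall", {
  m <- mk_two_group()
  g1 <- derive_group_model(m, 1)
  g2 <- derive_group_model(m, 2)
  # reconstruction: contrast and average identities hold exactly
  expect_equal(g2$interactions - g1$interactions,
               m$diffs$interaction_diffs, tolerance = 1e-14)
  expect_equal((g1$interactions + g2$interactions) / 2,
               m$overall$interactions, tolerance = 1e-15)
  for (i in 1:3) {
    expect_equal(g2$thresholds[[i]] - g1$thresholds[[i]],
                 m$diffs$threshold_diffs[[i]], tolerance = 1e-14)
  }
  # zero difference: both groups carry the overall value
  m0 <- two_group_model(m$overall,
                        difference_model(lapply(c(2, 2, 2), numeric),
                                         matrix(0, 3, 3)))
  expect_identical(derive_group_model(m0, 1)$interactions,
                   derive_group_model(m0, 2)$interactions)
  # zero overall with nonzero difference: groups sit at minus/plus half
  ov0 <- group_model(lapply(c(2, 2, 2), numeric), matrix(0, 3, 3))
  md <- two_group_model(ov0, m$diffs)
  expect_equal(derive_group_model(md, 1)$interactions,
               -m$diffs$interaction_diffs / 2, tolerance = 1e-15)
  expect_equal(derive_group_model(md, 2)$interactions,
               m$diffs$interaction_diffs / 2, tolerance = 1e-15)
})

test_that("Free alignment squeezes only the group with the unobserved category", {
  # category 1 of variable 1 unobserved in group 1 only
  d1 <- ordinal_dataset(matrix(c(0L, 2L, 2L, 0L,  0L, 1L, 2L, 1L), ncol = 2),
                        n_categories = c(3L, 3L))
  d2 <- ordinal_dataset(matrix(c(0L, 1L, 2L, 1L,  0L, 1L, 2L, 2L), ncol = 2),
                        n_categories = c(3L, 3L))
  al <- align_categories(d1, d2, mode = "Free")
  expect_identical(al$plan$n_categories$group1, c(2L, 3L))
  expect_identical(al$plan$n_categories$group2, c(3L, 3L))
  expect_identical(al$data1$responses[, 1], c(0L, 1L, 1L, 0L))  # 2 -> 1
  # group 2 untouched
  expect_identical(al$data2$responses, d2$responses)
})

test_that("Collapse alignment merges symmetrically in both groups", {
  d1 <- ordinal_dataset(matrix(c(0L, 2L, 2L, 0L), ncol = 1),
                        n_categories = 3L)
  d2 <- ordinal_dataset(matrix(c(0L, 1L, 2L, 1L), ncol = 1),
                        n_categories = 3L)
  al <- align_categories(d1, d2, mode = "Collapse")
  expect_identical(al$plan$n_categories$group1, 2L)
  expect_identical(al$plan$n_categories$group2, 2L)
  # the kept categories {0, 2} become {0, 1}; the unobserved category 1
  # merges downward into 0 wherever group 2 observed it
  expect_identical(al$data1$responses[, 1], c(0L, 1L, 1L, 0L))
  expect_identical(al$data2$responses[, 1], c(0L, 0L, 1L, 0L))
})

test_that("missing lowest category collapses upward; both-missing drops out", {
  # category 0 unobserved in group 1: with Collapse it merges into 1
  d1 <- ordinal_dataset(matrix(c(1L, 2L, 1L, 2L), ncol = 1), n_categories = 3L)
  d2 <- ordinal_dataset(matrix(c(0L, 1L, 2L, 0L), ncol = 1), n_categories = 3L)
  al <- align_categories(d1, d2, mode = "Collapse")
  expect_identical(al$data1$responses[, 1], c(0L, 1L, 0L, 1L))
  expect_identical(al$data2$responses[, 1], c(0L, 0L, 1L, 0L))
  # a category observed in neither group disappears under Free too
  d3 <- ordinal_dataset(matrix(c(0L, 2L, 0L, 2L), ncol = 1), n_categories = 3L)
  d4 <- ordinal_dataset(matrix(c(0L, 2L, 2L, 0L), ncol = 1), n_categories = 3L)
  alf <- align_categories(d3, d4, mode = "Free")
  expect_identical(alf$plan$n_categories$group1, 2L)
  expect_identical(alf$plan$n_categories$group2, 2L)
})

test_that("alignment is the identity when every category is observed", {
  d1 <- toy_data(30, c(3L, 2L), seed = 3)
  d2 <- toy_data(30, c(3L, 2L), seed = 4)
  for (mode in c("Free", "Collapse")) {
    al <- align_categories(d1, d2, mode = mode)
    expect_identical(al$data1$responses, d1$responses)
    expect_identical(al$data2$responses, d2$responses)
  }
})

test_that("alignment rejects a variable left with a single category", {
  d1 <- ordinal_dataset(matrix(c(1L, 1L, 1L), ncol = 1), n_categories = 2L)
  d2 <- ordinal_dataset(matrix(c(0L, 1L, 0L), ncol = 1), n_categories = 2L)
  expect_error(align_categories(d1, d2, mode = "Free"), "fewer than 2")
})

test_that("two-group pseudolikelihood composes from per-group evaluations", {
  m <- mk_two_group(seed = 13)
  d1 <- toy_data(25, c(3L, 3L, 3L), seed = 5)
  d2 <- toy_data(35, c(3L, 3L, 3L), seed = 6)
  expect_equal(two_group_log_pseudolikelihood(m, d1, d2),
               log_pseudolikelihood(derive_group_model(m, 1), d1) +
                 log_pseudolikelihood(derive_group_model(m, 2), d2),
               tolerance = 1e-12)
  # both groups empty
  e <- empty_data(c(3L, 3L, 3L))
  expect_identical(two_group_log_pseudolikelihood(m, e, e), 0)
})

test_that("zero contrasts reduce to the pooled one-group pseudolikelihood", {
  m <- mk_two_group(seed = 17)
  m0 <- two_group_model(m$overall,
                        difference_model(lapply(c(2, 2, 2), numeric),
                                         matrix(0, 3, 3)))
  d1 <- toy_data(20, c(3L, 3L, 3L), seed = 7)
  d2 <- toy_data(30, c(3L, 3L, 3L), seed = 8)
  pooled <- ordinal_dataset(rbind(d1$responses, d2$responses),
                            n_categories = c(3L, 3L, 3L))
  expect_identical(two_group_log_pseudolikelihood(m0, d1, d2),
                   log_pseudolikelihood(m$overall, pooled))
})

test_that("swapping groups while negating contrasts leaves the value unchanged", {
  m <- mk_two_group(seed = 19)
  d1 <- toy_data(20, c(3L, 3L, 3L), seed = 9)
  d2 <- toy_data(25, c(3L, 3L, 3L), seed = 10)
  m_neg <- two_group_model(
    m$overall,
    difference_model(lapply(m$diffs$threshold_diffs, function(x) -x),
                     -m$diffs$interaction_diffs))
  expect_equal(two_group_log_pseudolikelihood(m, d1, d2),
               two_group_log_pseudolikelihood(m_neg, d2, d1),
               tolerance = 1e-12)
})

test_that("binary two-group models are identified by their group pmf pair", {
  # closed-form inversion of the Ising log-pmf recovers (overall, diffs)
  set.seed(23)
  p <- 3
  mk <- function() {
    ov <- group_model(as.list(rnorm(p)),
                      {J <- matrix(0, p, p)
                       J[upper.tri(J)] <- rnorm(3, sd = 0.6); J + t(J)})
    df <- difference_model(as.list(rep(0, p)),
                           {D <- matrix(0, p, p)
                            D[upper.tri(D)] <- rnorm(3, sd = 0.4); D + t(D)})
    two_group_model(ov, df)
  }
  invert <- function(pmf) {
    # h_i = log P(e_i)/P(0); J_ij = log P(e_i + e_j) P(0) / (P(e_i) P(e_j))
    s <- pmf$states
    pr <- pmf$probabilities
    at <- function(x) pr[apply(s, 1, function(r) all(r == x))]
    p0 <- at(c(0, 0, 0))
    h <- vapply(1:p, function(i) {
      e <- rep(0, p); e[i] <- 1; log(at(e) / p0)
    }, 1.0)
    J <- matrix(0, p, p)
    for (i in 1:(p - 1)) for (j in (i + 1):p) {
      ei <- rep(0, p); ei[i] <- 1
      ej <- rep(0, p); ej[j] <- 1
      J[i, j] <- J[j, i] <- log(at(ei + ej) * p0 / (at(ei) * at(ej)))
    }
    list(h = h, J = J)
  }
  m <- mk()
  f1 <- invert(enumerate_joint_pmf(derive_group_model(m, 1)))
  f2 <- invert(enumerate_joint_pmf(derive_group_model(m, 2)))
  expect_equal((f1$J + f2$J) / 2, m$overall$interactions, tolerance = 1e-8)
  expect_equal(f2$J - f1$J, m$diffs$interaction_diffs, tolerance = 1e-8)
  expect_equal((f1$h + f2$h) / 2, unlist(m$overall$thresholds),
               tolerance = 1e-8)
  # and a genuinely different model produces different group pmfs
  m2 <- mk()
  tv <- sum(abs(enumerate_joint_pmf(derive_group_model(m, 1))$probabilities -
                enumerate_joint_pmf(derive_group_model(m2, 1))$probabilities)) / 2
  expect_gt(tv, 0)
})
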