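# Two-group reparameterization: overall effects plus group-difference
# contrasts, category alignment across groups, and the two-group
# pseudolikelihood.

#' Construct a difference-parameter set
#'
#' Holds the group contrasts: per-variable threshold-difference vectors and a
#' symmetric matrix of pairwise interaction differences. Each contrast is
#' Group 2 minus Group 1; each group carries plus or minus half of it.
#'
#' @param threshold_diffs list of numeric vectors shaped like the (aligned)
#'   thresholds.
#' @param interaction_diffs numeric `p x p` matrix; upper triangle
#'   authoritative, diagonal zero.
#' @return Object of class `difference_model`.
#' @export
difference_model <- function(threshold_diffs, interaction_diffs) {
  if (!is.list(threshold_diffs)) threshold_diffs <- as.list(threshold_diffs)
  p <- length(threshold_diffs)
  interaction_diffs <- as.matrix(interaction_diffs)
  if (!all(dim(interaction_diffs) == c(p, p))) {
    stop("difference_model: interaction_diffs must be ", p, " x ", p,
         call. = FALSE)
  }
  interaction_diffs[lower.tri(interaction_diffs)] <-
    t(interaction_diffs)[lower.tri(interaction_diffs)]
  diag(interaction_diffs) <- 0
  structure(
    list(threshold_diffs = lapply(threshold_diffs, as.numeric),
         interaction_diffs = interaction_diffs),
    class = "difference_model"
  )
}

#' Construct a two-group OMRF
#'
#' Combines overall parameters (the values shared across groups; averages of
#' the group-specific values) with a [difference_model()] of group contrasts.
#'
#' @param overall a [group_model()] of overall thresholds and interactions.
#' @param diffs a [difference_model()] with matching shapes.
#' @return Object of class `two_group_model`.
#' @export
two_group_model <- function(overall, diffs) {
  stopifnot(inherits(overall, "group_model"),
            inherits(diffs, "difference_model"))
  sh_o <- vapply(overall$thresholds, length, 1L)
  sh_d <- vapply(diffs$threshold_diffs, length, 1L)
  if (length(sh_o) != length(sh_d) || any(sh_o != sh_d)) {
    stop("two_group_model: overall and diffs threshold shapes differ",
         call. = FALSE)
  }
  structure(list(overall = overall, diffs = diffs),
            class = "two_group_model")
}

#' Derive one group's parameters from a two-group model
#'
#' Each group difference is distributed evenly around the overall value:
#' Group 1 carries `overall - diffs / 2`, Group 2 carries
#' `overall + diffs / 2`, for both thresholds and interactions. Consequently
#' group 2 minus group 1 reproduces the contrasts and their average the
#' overall parameters.
#'
#' @param m a [two_group_model()].
#' @param group 1 or 2.
#' @return A [group_model()] for the requested group.
#' @export
derive_group_model <- function(m, group) {
  stopifnot(inherits(m, "two_group_model"))
  if (!group %in% c(1, 2)) stop("group must be 1 or 2", call. = FALSE)
  sign <- if (group == 1) -0.5 else 0.5
  thr <- mapply(function(mu, d) mu + sign * d,
                m$overall$thresholds, m$diffs$threshold_diffs,
                SIMPLIFY = FALSE)
  group_model(thr, m$overall$interactions + sign * m$diffs$interaction_diffs)
}

#' Align response categories across two groups
#'
#' Thresholds attach to specific response categories, so a category observed
#' in only one group has no identifiable threshold (or threshold difference)
#' in the other. Two strategies are offered:
#'
#' * `"Free"` — each group's unobserved categories are squeezed out of that
#'   group's coding only; the groups may end with different category counts,
#'   thresholds are then estimated separately per group, and the
#'   threshold-difference test is unavailable.
#' * `"Collapse"` — a category unobserved in *either* group is merged into the
#'   next lower category (or the next higher one when the lowest category is
#'   missing) in *both* groups, keeping one shared category structure.
#'
#' Categories unobserved in both groups are always removed. Output codings are
#' consecutive integers from 0.
#'
#' @param data1,data2 [ordinal_dataset()] objects with identical variable
#'   order; codes refer to a common pooled coding.
#' @param mode `"Collapse"` (default) or `"Free"`.
#' @return list with `plan` (class `alignment_plan`: `mode`, per-group
#'   `mapping` lists of old-code -> new-code vectors, per-group
#'   `n_categories`), and the recoded datasets `data1`, `data2`.
#' @export
align_categories <- function(data1, data2, mode = c("Collapse", "Free")) {
  mode <- match.arg(mode)
  stopifnot(inherits(data1, "ordinal_dataset"),
            inherits(data2, "ordinal_dataset"))
  p <- ncol(data1$responses)
  if (ncol(data2$responses) != p) {
    stop("align_categories: groups have different variable counts",
         call. = FALSE)
  }
  ncat_pool <- pmax(data1$n_categories, data2$n_categories)
  map1 <- map2 <- vector("list", p)
  for (i in seq_len(p)) {
    codes <- 0:(ncat_pool[i] - 1L)
    obs1 <- codes %in% data1$responses[, i]
    obs2 <- codes %in% data2$responses[, i]
    if (nrow(data1$responses) == 0L) obs1 <- rep(TRUE, length(codes))
    if (nrow(data2$responses) == 0L) obs2 <- rep(TRUE, length(codes))
    if (mode == "Free") {
      map1[[i]] <- squeeze_map(obs1)
      map2[[i]] <- squeeze_map(obs2)
    } else {
      keep <- obs1 & obs2     # categories identifiable in both groups
      map1[[i]] <- map2[[i]] <- collapse_map(keep)
    }
    for (m_ in list(map1[[i]], map2[[i]])) {
      if (max(m_, na.rm = TRUE) < 1L) {
        stop("align_categories: variable ", i, " has fewer than 2 observed ",
             "categories after alignment; no identifiable threshold",
             call. = FALSE)
      }
    }
  }
  plan <- structure(
    list(mode = mode, mapping = list(group1 = map1, group2 = map2),
         n_categories = list(
           group1 = vapply(map1, function(m_) max(m_, na.rm = TRUE) + 1L, 1L),
           group2 = vapply(map2, function(m_) max(m_, na.rm = TRUE) + 1L, 1L))),
    class = "alignment_plan"
  )
  list(plan = plan,
       data1 = recode_dataset(data1, map1, plan$n_categories$group1),
       data2 = recode_dataset(data2, map2, plan$n_categories$group2))
}

# Free mode: drop unobserved categories from this group's coding only.
# Unobserved codes get NA (they never occur in this group's data).
squeeze_map <- function(obs) {
  map <- rep(NA_integer_, length(obs))
  map[obs] <- seq_len(sum(obs)) - 1L
  map
}

# Collapse mode: merge a dropped category into the next lower kept category,
# or the next higher one when no lower category is kept (lowest missing).
collapse_map <- function(keep) {
  if (!any(keep)) stop("no observed categories", call. = FALSE)
  k <- length(keep)
  map <- integer(k)
  kept_codes <- which(keep) - 1L
  new_of_kept <- setNames(seq_along(kept_codes) - 1L, kept_codes)
  for (code in 0:(k - 1L)) {
    if (keep[code + 1L]) {
      map[code + 1L] <- new_of_kept[[as.character(code)]]
    } else {
      lower <- kept_codes[kept_codes < code]
      target <- if (length(lower)) max(lower) else min(kept_codes[kept_codes > code])
      map[code + 1L] <- new_of_kept[[as.character(target)]]
    }
  }
  map
}

recode_dataset <- function(data, map, new_ncat) {
  x <- data$responses
  for (i in seq_len(ncol(x))) {
    if (nrow(x) > 0) x[, i] <- map[[i]][x[, i] + 1L]
  }
  ordinal_dataset(x, n_categories = new_ncat,
                  variable_names = data$variable_names)
}

#' Two-group log-pseudolikelihood
#'
#' Individuals are independent within and between groups, so the two-group
#' log-pseudolikelihood is the sum of the per-group values under each group's
#' derived parameters.
#'
#' @param m a [two_group_model()].
#' @param data1,data2 aligned [ordinal_dataset()] objects.
#' @return scalar log-pseudolikelihood.
#' @export
two_group_log_pseudolikelihood <- function(m, data1, data2) {
  n1 <- nrow(data1$responses)
  n2 <- nrow(data2$responses)
  if (n1 == 0L && n2 == 0L) return(0)
  # with all contrasts zero both groups share the overall model, so the
  # two-group value reduces (exactly) to the pooled one-group evaluation
  no_diff <- all(unlist(m$diffs$threshold_diffs) == 0) &&
    all(m$diffs$interaction_diffs == 0) &&
    all(data1$n_categories == data2$n_categories)
  if (no_diff) {
    pooled <- ordinal_dataset(rbind(data1$responses, data2$responses),
                              n_categories = data1$n_categories,
                              variable_names = data1$variable_names)
    return(log_pseudolikelihood(m$overall, pooled))
  }
  out <- 0
  if (n1 > 0L) out <- out + log_pseudolikelihood(derive_group_model(m, 1), data1)
  if (n2 > 0L) out <- out + log_pseudolikelihood(derive_group_model(m, 2), data2)
  out
}
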