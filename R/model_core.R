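# One-group ordinal Markov random field: containers, full conditionals,
# log-pseudolikelihood, and the exact enumeration oracle for small networks.

#' Construct an ordinal dataset
#'
#' Wraps an integer-coded response matrix (rows are individuals, columns are
#' variables). Category codes must be consecutive integers starting at 0;
#' variable `i` takes values in `0:(n_categories[i] - 1)`. Missing values are
#' not supported and raise an error at construction.
#'
#' @param responses integer matrix (or coercible), `n x p`; `n = 0` is allowed
#'   for prior-only analyses provided `n_categories` is given.
#' @param n_categories integer vector of length `p`: number of observed
#'   categories per variable (at least 2). Defaults to `max(column) + 1`.
#' @param variable_names character vector of length `p`.
#' @return An object of class `ordinal_dataset` with fields `responses`,
#'   `n_categories`, `variable_names`.
#' @examples
#' x <- matrix(c(0L, 1L, 2L, 1L, 0L, 2L), nrow = 3)
#' ordinal_dataset(x)
#' @export
ordinal_dataset <- function(responses, n_categories = NULL,
                            variable_names = NULL) {
  responses <- as.matrix(responses)
  if (anyNA(responses)) {
    stop("ordinal_dataset: missing entries are not supported; ",
         "remove or impute rows before construction", call. = FALSE)
  }
  if (nrow(responses) > 0 && any(responses != round(responses))) {
    stop("ordinal_dataset: responses must be integer category codes",
         call. = FALSE)
  }
  storage.mode(responses) <- "integer"
  p <- ncol(responses)
  if (p < 1L) stop("ordinal_dataset: need at least one variable", call. = FALSE)
  if (is.null(n_categories)) {
    if (nrow(responses) == 0L) {
      stop("ordinal_dataset: n_categories is required for empty data",
           call. = FALSE)
    }
    n_categories <- apply(responses, 2L, max) + 1L
  }
  n_categories <- as.integer(n_categories)
  if (length(n_categories) != p || any(n_categories < 2L)) {
    stop("ordinal_dataset: n_categories must give >= 2 categories for each ",
         "of the ", p, " variables", call. = FALSE)
  }
  if (nrow(responses) > 0) {
    bad <- which(apply(responses, 2L, min) < 0L |
                 apply(responses, 2L, max) > n_categories - 1L)
    if (length(bad)) {
      stop("ordinal_dataset: entries of variable(s) ",
           paste(bad, collapse = ", "),
           " fall outside {0, ..., n_categories - 1}", call. = FALSE)
    }
  }
  if (is.null(variable_names)) {
    variable_names <- colnames(responses)
    if (is.null(variable_names)) variable_names <- paste0("V", seq_len(p))
  }
  colnames(responses) <- variable_names
  structure(
    list(responses = responses, n_categories = n_categories,
         variable_names = variable_names),
    class = "ordinal_dataset"
  )
}

#' @export
print.ordinal_dataset <- function(x, ...) {
  cat("<ordinal_dataset> ", nrow(x$responses), " rows x ",
      ncol(x$responses), " variables; categories per variable: ",
      paste(x$n_categories, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Construct a one-group OMRF parameter set
#'
#' Thresholds are in log-odds units relative to the baseline category 0
#' (`mu[i][c]` for category `c`; the baseline threshold is fixed at zero and
#' not stored). Interactions are linear-by-linear partial-association weights
#' on products of category indices; the upper triangle is authoritative and
#' mirrored onto the lower triangle.
#'
#' @param thresholds list of numeric vectors; element `i` has length
#'   `n_categories[i] - 1`.
#' @param interactions numeric `p x p` matrix; diagonal forced to zero.
#' @return Object of class `group_model`.
#' @examples
#' group_model(list(c(0, 0), c(0, 0)), matrix(c(0, 1, 1, 0), 2))
#' @export
group_model <- function(thresholds, interactions) {
  if (!is.list(thresholds)) thresholds <- as.list(thresholds)
  p <- length(thresholds)
  interactions <- as.matrix(interactions)
  if (!all(dim(interactions) == c(p, p))) {
    stop("group_model: interactions must be ", p, " x ", p, call. = FALSE)
  }
  if (any(!is.finite(unlist(thresholds))) || any(!is.finite(interactions))) {
    stop("group_model: parameters must be finite", call. = FALSE)
  }
  # upper triangle is authoritative; mirror down, zero the diagonal
  interactions[lower.tri(interactions)] <- t(interactions)[lower.tri(interactions)]
  diag(interactions) <- 0
  structure(
    list(thresholds = lapply(thresholds, as.numeric),
         interactions = interactions),
    class = "group_model"
  )
}

n_vars <- function(model) length(model$thresholds)

model_n_categories <- function(model) {
  vapply(model$thresholds, length, 1L) + 1L
}

check_model_data <- function(model, data) {
  if (n_vars(model) != ncol(data$responses)) {
    stop("model has ", n_vars(model), " variables but data has ",
         ncol(data$responses), call. = FALSE)
  }
  mm <- model_n_categories(model)
  if (any(mm != data$n_categories)) {
    stop("model and data disagree on the number of categories: model ",
         paste(mm, collapse = "/"), " vs data ",
         paste(data$n_categories, collapse = "/"), call. = FALSE)
  }
  invisible(TRUE)
}

#' Full-conditional category probabilities
#'
#' Probability of each category of variable `i` given the remaining entries of
#' `row`, under the adjacent-category form of the OMRF:
#' `P(X_i = c | rest)` is proportional to
#' `exp(mu[i][c] + c * sum_j sigma[i, j] * x_j)` with `mu[i][0] = 0`.
#'
#' @param model a [group_model()].
#' @param row integer vector of length `p` with valid category codes.
#' @param i variable index (1-based).
#' @return numeric probability vector of length `n_categories[i]`, summing to 1.
#' @examples
#' m <- group_model(list(c(0, 0), c(0, 0)), diag(0, 2))
#' category_probabilities(m, c(0L, 1L), 1L)  # uniform under the null model
#' @export
category_probabilities <- function(model, row, i) {
  p <- n_vars(model)
  if (length(row) != p) {
    stop("row has length ", length(row), " but model has ", p, " variables",
         call. = FALSE)
  }
  ncat <- model_n_categories(model)
  if (any(row < 0L) || any(row > ncat - 1L)) {
    stop("row contains invalid category codes", call. = FALSE)
  }
  mu <- c(0, model$thresholds[[i]])
  rest <- sum(model$interactions[i, -i] * row[-i])
  logw <- mu + (seq_along(mu) - 1) * rest
  w <- exp(logw - max(logw))
  w / sum(w)
}

#' Log-pseudolikelihood of one group
#'
#' Sum over rows and variables of the logged full conditional of the observed
#' category, the tractable surrogate for the full likelihood whose
#' normalization constant requires summing over every category configuration.
#'
#' @param model a [group_model()].
#' @param data an [ordinal_dataset()] with matching shapes.
#' @return scalar log-pseudolikelihood (`<= 0`); 0 with a warning for empty
#'   data.
#' @export
log_pseudolikelihood <- function(model, data) {
  check_model_data(model, data)
  x <- data$responses
  n <- nrow(x)
  if (n == 0L) {
    warning("log_pseudolikelihood: empty dataset, returning 0")
    return(0)
  }
  p <- ncol(x)
  sigma <- model$interactions
  rest <- x %*% sigma           # rest[r, i] = sum_j sigma[i,j] x[r,j]
  total <- 0
  for (i in seq_len(p)) {
    mu <- c(0, model$thresholds[[i]])
    cats <- seq_along(mu) - 1
    # n x (m+1) matrix of unnormalized log-weights
    logw <- outer(rest[, i], cats) + rep(mu, each = n)
    mx <- apply(logw, 1L, max)
    logz <- mx + log(rowSums(exp(logw - mx)))
    picked <- logw[cbind(seq_len(n), x[, i] + 1L)]
    total <- total + sum(picked - logz)
  }
  total
}

#' Exact joint probability table by enumeration
#'
#' Enumerates all `prod(n_categories)` category-index vectors and normalizes
#' the exponential-family weights
#' `exp(sum_i mu[i][x_i] + sum_{i<j} sigma[i,j] x_i x_j)`. Only feasible for
#' small networks; guarded by `max_states`.
#'
#' @param model a [group_model()].
#' @param max_states capacity guard on the number of joint states
#'   (default `1e7`).
#' @return list of class `joint_pmf` with `states` (integer matrix, one row
#'   per state) and `probabilities` (summing to 1).
#' @examples
#' m <- group_model(list(0, 0), matrix(c(0, 1, 1, 0), 2))
#' pmf <- enumerate_joint_pmf(m)
#' pmf$probabilities[4]  # P(1,1) = e / (3 + e)
#' @export
enumerate_joint_pmf <- function(model, max_states = 1e7) {
  ncat <- model_n_categories(model)
  n_states <- prod(as.numeric(ncat))
  if (n_states > max_states) {
    stop("enumerate_joint_pmf: ", format(n_states, big.mark = ","),
         " joint states exceed the guard of ",
         format(max_states, big.mark = ","),
         "; the normalization constant is intractable at this size",
         call. = FALSE)
  }
  p <- length(ncat)
  states <- as.matrix(expand.grid(lapply(ncat, function(m) 0:(m - 1L)),
                                  KEEP.OUT.ATTRS = FALSE))
  storage.mode(states) <- "integer"
  colnames(states) <- NULL
  logw <- numeric(nrow(states))
  for (i in seq_len(p)) {
    mu <- c(0, model$thresholds[[i]])
    logw <- logw + mu[states[, i] + 1L]
  }
  sigma <- model$interactions
  for (i in seq_len(p - 1L)) {
    for (j in (i + 1L):p) {
      if (sigma[i, j] != 0) {
        logw <- logw + sigma[i, j] * states[, i] * states[, j]
      }
    }
  }
  w <- exp(logw - max(logw))
  structure(list(states = states, probabilities = w / sum(w)),
            class = "joint_pmf")
}
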