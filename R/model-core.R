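# Core probability models for DOMC item responses: the 2PL subprocess
# logistic, the logistic positive exponent (LPE), and the five competing
# parameterizations that let item functioning depend on the scheduled
# number of response options k.

PROB_EPS <- 1e-12

#' Admissible scheduled-option counts for an item design
#'
#' Under DOMC administration the options are shown one at a time in random
#' order until the last keyed option appears, so the scheduled number of
#' response options k ranges from `n_keys` (all keys first) to `n_options`
#' (last key shown last).
#'
#' @param n_keys Number of keyed (correct) options, an integer in 1..3.
#' @param n_options Total number of response options (> `n_keys`).
#' @return Integer vector `n_keys:n_options`.
#' @export
admissible_k <- function(n_keys, n_options) {
  if (n_keys >= n_options) {
    stop("invalid design: n_keys (", n_keys, ") must be < n_options (",
         n_options, ")", call. = FALSE)
  }
  seq.int(n_keys, n_options)
}

#' Construct an item-design table
#'
#' @param item_id Character or integer item identifiers (unique).
#' @param n_keys Integer vector of key counts in `{1, 2, 3}`.
#' @param n_options Total option counts; defaults to 5 for triple-keyed items
#'   and 4 otherwise.
#' @return A `data.frame` with columns `item_id`, `n_keys`, `n_options`.
#' @export
item_designs <- function(item_id, n_keys,
                         n_options = ifelse(n_keys == 3L, 5L, 4L)) {
  item_id <- as.character(item_id)
  n_keys <- as.integer(n_keys)
  n_options <- as.integer(rep_len(n_options, length(item_id)))
  if (anyDuplicated(item_id)) {
    stop("duplicate item_id in design table", call. = FALSE)
  }
  if (any(n_keys < 1L) || any(n_keys >= n_options)) {
    stop("invalid design: need 1 <= n_keys < n_options", call. = FALSE)
  }
  data.frame(item_id = item_id, n_keys = n_keys, n_options = n_options,
             stringsAsFactors = FALSE)
}

#' Name an item-by-k parameter cell
#'
#' Parameters that vary with the scheduled option count are keyed by
#' `"item_id:k"`; this helper builds those names consistently.
#'
#' @param item_id Item identifier(s).
#' @param k Scheduled option count(s).
#' @return Character vector of cell keys.
#' @export
cell_key <- function(item_id, k) paste(item_id, k, sep = ":")

#' Subprocess success probability (2PL logistic)
#'
#' Probability that a single component subprocess -- here, the response to one
#' administered DOMC option -- is executed successfully:
#' \eqn{\Psi(\theta) = \exp[a(\theta - b)] / (1 + \exp[a(\theta - b)])}.
#'
#' @param theta Ability value(s).
#' @param a Discrimination, `> 0`.
#' @param b Difficulty on the theta scale.
#' @param log.p If `TRUE` return the log probability.
#' @return Probabilities (or log probabilities) of the same length as the
#'   longest argument.
#' @export
subprocess_prob <- function(theta, a, b, log.p = FALSE) {
  if (any(a <= 0)) stop("invalid parameter: a must be > 0", call. = FALSE)
  stats::plogis(a * (theta - b), log.p = log.p)
}

#' Logistic positive exponent (LPE) response probability
#'
#' Raises the subprocess probability to an exponent `xi > 0`:
#' \eqn{P(U = 1 | \theta) = \Psi(\theta)^{\xi}}. `xi` acts as an item
#' complexity parameter: `xi > 1` corresponds to conjunctively interacting
#' subprocesses (positively asymmetric, harder, more discriminating items),
#' `xi < 1` to disjunctive ones, and `xi = 1` recovers the symmetric 2PL.
#'
#' @inheritParams subprocess_prob
#' @param xi Positive exponent (complexity) parameter.
#' @export
lpe_prob <- function(theta, a, b, xi, log.p = FALSE) {
  if (any(xi <= 0)) stop("invalid parameter: xi must be > 0", call. = FALSE)
  lp <- xi * subprocess_prob(theta, a, b, log.p = TRUE)
  if (log.p) lp else exp(lp)
}

MODEL_IDS <- c("model1", "model2", "model3", "model4", "model5")

#' Construct a model parameter set
#'
#' Bundles the item parameters of one of the five DOMC response models with
#' examinee abilities. Layouts by model:
#' \describe{
#'   \item{model1}{2PL per item, no effect of k: `a`, `b` named by item.}
#'   \item{model2}{2PL per item-by-k cell: `a`, `b` named by `"item:k"`.}
#'   \item{model3}{2PL, common slope: `a` named by item, `b` named by cell.}
#'   \item{model4}{LPE: `a`, `b` named by item, `xi` named by cell.}
#'   \item{model5}{LPE with linear exponent `xi_ik = c_i * k`: `a`, `b`, `c`
#'     named by item.}
#' }
#' Cell names use the convention `paste(item_id, k, sep = ":")`.
#'
#' @param model One of `"model1"` .. `"model5"`.
#' @param a,b,xi,c Named numeric vectors per the layout above (unused blocks
#'   may be omitted).
#' @param theta Named numeric vector of abilities, one per examinee.
#' @return An object of class `parameter_set`.
#' @export
parameter_set <- function(model, a = NULL, b = NULL, xi = NULL, c = NULL,
                          theta = numeric()) {
  model <- match.arg(model, MODEL_IDS)
  need <- switch(model,
    model1 = c("a", "b"), model2 = c("a", "b"), model3 = c("a", "b"),
    model4 = c("a", "b", "xi"), model5 = c("a", "b", "c"))
  blocks <- list(a = a, b = b, xi = xi, c = c)
  for (nm in need) {
    v <- blocks[[nm]]
    if (is.null(v) || is.null(names(v)) || any(!nzchar(names(v)))) {
      stop("parameter set for ", model, " requires a fully named '", nm,
           "' block", call. = FALSE)
    }
  }
  if (any(a <= 0)) stop("invalid parameter: a must be > 0", call. = FALSE)
  if (model == "model4" && any(xi <= 0)) {
    stop("invalid parameter: xi must be > 0", call. = FALSE)
  }
  if (model == "model5" && any(c <= 0)) {
    stop("invalid parameter: c must be > 0", call. = FALSE)
  }
  structure(list(model = model, a = a, b = b, xi = xi, c = c, theta = theta),
            class = "parameter_set")
}

#' @export
print.parameter_set <- function(x, ...) {
  cat("<parameter_set>", x$model, "\n")
  for (nm in c("a", "b", "xi", "c")) {
    if (!is.null(x[[nm]])) cat("  ", nm, ": ", length(x[[nm]]), " values\n",
                               sep = "")
  }
  cat("  theta: ", length(x$theta), " examinees\n", sep = "")
  invisible(x)
}

# Look up a parameter block by key, failing loudly with the offending cell.
lookup_param <- function(vec, keys, block, model) {
  idx <- match(keys, names(vec))
  if (anyNA(idx)) {
    miss <- unique(keys[is.na(idx)])
    stop("missing ", block, " parameter cell(s) for ", model, ": ",
         paste(utils::head(miss, 5L), collapse = ", "), call. = FALSE)
  }
  unname(vec[idx])
}

#' Model-implied probability of a correct DOMC item score
#'
#' Evaluates the probability of a correct item score under the parameter
#' set's model, for administrations of item `item_id` scheduled with `k`
#' response options. Vectorized over `theta`, `item_id` and `k` (recycled to
#' a common length).
#'
#' @param pset A [parameter_set()].
#' @param item_id Item identifier(s).
#' @param k Scheduled number of response options.
#' @param theta Ability value(s).
#' @param log.p If `TRUE` return log probabilities.
#' @return Numeric vector of probabilities.
#' @export
response_prob <- function(pset, item_id, k, theta, log.p = FALSE) {
  stopifnot(inherits(pset, "parameter_set"))
  n <- max(length(theta), length(item_id), length(k))
  item_id <- rep_len(as.character(item_id), n)
  k <- rep_len(as.integer(k), n)
  theta <- rep_len(theta, n)
  ck <- cell_key(item_id, k)
  m <- pset$model
  lp <- switch(m,
    model1 = subprocess_prob(theta, lookup_param(pset$a, item_id, "a", m),
                             lookup_param(pset$b, item_id, "b", m),
                             log.p = TRUE),
    model2 = subprocess_prob(theta, lookup_param(pset$a, ck, "a", m),
                             lookup_param(pset$b, ck, "b", m), log.p = TRUE),
    model3 = subprocess_prob(theta, lookup_param(pset$a, item_id, "a", m),
                             lookup_param(pset$b, ck, "b", m), log.p = TRUE),
    model4 = lpe_prob(theta, lookup_param(pset$a, item_id, "a", m),
                      lookup_param(pset$b, item_id, "b", m),
                      lookup_param(pset$xi, ck, "xi", m), log.p = TRUE),
    model5 = lpe_prob(theta, lookup_param(pset$a, item_id, "a", m),
                      lookup_param(pset$b, item_id, "b", m),
                      lookup_param(pset$c, item_id, "c", m) * k, log.p = TRUE))
  if (log.p) lp else exp(lp)
}

#' Bernoulli deviance of a response table under a parameter set
#'
#' Computes \eqn{D = -2 \sum_j \log P(U_j = u_j)} over the records of a
#' long-format response table. Probabilities are clamped to
#' `[1e-12, 1 - 1e-12]` before taking logs so that extreme parameter values
#' yield a large finite deviance rather than an infinite one.
#'
#' @param pset A [parameter_set()] whose `theta` block covers every examinee
#'   in `data`.
#' @param data Response table with columns `examinee_id`, `item_id`,
#'   `k_scheduled`, `score` (see [read_responses()]).
#' @return The deviance, a non-negative scalar.
#' @export
domc_deviance <- function(pset, data) {
  if (nrow(data) == 0L) return(0)
  theta <- lookup_param(pset$theta, as.character(data$examinee_id),
                        "theta", pset$model)
  p <- response_prob(pset, data$item_id, data$k_scheduled, theta)
  p <- pmin(pmax(p, PROB_EPS), 1 - PROB_EPS)
  y <- data$score
  -2 * sum(y * log(p) + (1 - y) * log1p(-p))
}

#' Item characteristic curve on a theta grid
#'
#' @inheritParams response_prob
#' @param theta_grid Grid of ability values; the default `-4..4` in steps of
#'   0.05 covers the support of the N(0, 1) ability prior used for metric
#'   identification.
#' @return Numeric vector of response probabilities, one per grid point.
#' @export
icc_curve <- function(pset, item_id, k, theta_grid = seq(-4, 4, by = 0.05)) {
  if (any(!is.finite(theta_grid))) {
    stop("theta_grid must be finite", call. = FALSE)
  }
  response_prob(pset, item_id, k, theta_grid)
}
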