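# DOMC administration simulator: random option order determines the key
# location (hence the scheduled number of response options k), and scoring is
# conjunctive -- an item is correct only if every keyed option is endorsed and
# every administered distractor rejected.

# Evaluate code under a temporary RNG seed, restoring global RNG state after.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Draw scheduled option counts by randomizing key locations
#'
#' Uniformly permutes the option positions of an item and returns the
#' position of the last keyed option, which equals the scheduled number of
#' response options k for that administration. k always falls in
#' `[n_keys, n_options]`.
#'
#' @param n_keys Number of keyed options (`1 <= n_keys < n_options`).
#' @param n_options Total number of options.
#' @param n Number of independent administrations to draw.
#' @return Integer vector of length `n`.
#' @export
draw_key_location <- function(n_keys, n_options, n = 1L) {
  if (n_keys >= n_options || n_keys < 1L) {
    stop("invalid design: need 1 <= n_keys < n_options", call. = FALSE)
  }
  vapply(seq_len(n), function(i) max(sample.int(n_options, n_keys)), 1L)
}

#' Score a DOMC administration at the option level
#'
#' Draws the k scheduled option responses as independent subprocess
#' Bernoullis with success probability [subprocess_prob()] and scores the
#' item correct only if all k succeed -- the conjunctive mechanism that makes
#' the LPE with `xi = k` the exact item-level model. Vectorized over
#' administrations (the draw is a single binomial of size `k` per record,
#' which is distributionally identical to k separate option draws).
#'
#' @inheritParams subprocess_prob
#' @param k Scheduled number of response options per administration.
#' @return Integer 0/1 scores, one per administration.
#' @export
conjunctive_score <- function(theta, a, b, k) {
  psi <- subprocess_prob(theta, a, b)
  as.integer(stats::rbinom(length(psi), size = k, prob = psi) == k)
}

#' Construct a DOMC item bank
#'
#' @param designs An [item_designs()] table.
#' @param forms Named list mapping form id to a character vector of item ids;
#'   every item must belong to at least one form.
#' @param true_params A [parameter_set()] holding the generating item
#'   parameters (used by [simulate_responses()]).
#' @return An object of class `domc_bank`.
#' @export
domc_bank <- function(designs, forms, true_params = NULL) {
  stopifnot(is.data.frame(designs), is.list(forms), length(forms) >= 1L)
  all_form_items <- unique(unlist(forms, use.names = FALSE))
  orphan <- setdiff(designs$item_id, all_form_items)
  if (length(orphan)) {
    stop("items belong to no form: ", paste(utils::head(orphan, 5L),
         collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(all_form_items, designs$item_id)
  if (length(unknown)) {
    stop("form references unknown items: ", paste(utils::head(unknown, 5L),
         collapse = ", "), call. = FALSE)
  }
  structure(list(designs = designs, forms = forms, true_params = true_params),
            class = "domc_bank")
}

#' @export
print.domc_bank <- function(x, ...) {
  cat("<domc_bank> ", nrow(x$designs), " items (",
      paste(table(x$designs$n_keys), "with", names(table(x$designs$n_keys)),
            "key(s)", collapse = ", "), "), ",
      length(x$forms), " form(s)\n", sep = "")
  invisible(x)
}

# Group mean targets for generated complexity exponents, by key count and k.
# Anchored to observed DOMC calibrations: roughly 0.6 at k = 1 rising in
# near-equal steps to about 1.8 (single-keyed, k = 4) and 2.5 (triple-keyed,
# k = 5).
XI_TARGETS <- list(
  `1` = c(`1` = 0.619, `2` = 1.000, `3` = 1.487, `4` = 1.819),
  `2` = c(`2` = 1.013, `3` = 1.629, `4` = 2.246),
  `3` = c(`3` = 1.468, `4` = 1.832, `5` = 2.534))

#' Draw generating (true) item parameters
#'
#' Discriminations are lognormal(0, 0.5) and difficulties standard normal,
#' matching the calibration priors. For `model4`, complexity exponents are
#' built per item as a first-cell draw (multiplicative lognormal noise around
#' the k-specific group target) plus strictly positive gamma increments whose
#' means follow the target gaps, so `xi` is strictly increasing in k within
#' every item while group means track the targets. For `model5`, a single
#' positive slope `c` per item is drawn with mean 0.5.
#'
#' @param designs An [item_designs()] table.
#' @param seed Integer seed; draws are reproducible.
#' @param model Generating model, `"model4"` (default) or `"model5"`.
#' @return A [parameter_set()] with an empty `theta` block.
#' @export
draw_true_params <- function(designs, seed, model = c("model4", "model5")) {
  model <- match.arg(model)
  n <- nrow(designs)
  with_seed(seed, {
    a <- stats::rlnorm(n, 0, 0.5)
    b <- stats::rnorm(n, 0, 1)
    names(a) <- names(b) <- designs$item_id
    if (model == "model5") {
      cc <- stats::rgamma(n, shape = 4, rate = 8)
      names(cc) <- designs$item_id
      parameter_set("model5", a = a, b = b, c = cc)
    } else {
      sdlog <- 0.594  # cv ~0.65 for the first cell, mean exactly on target
      xi <- numeric(0)
      for (i in seq_len(n)) {
        tg <- XI_TARGETS[[as.character(designs$n_keys[i])]]
        ks <- admissible_k(designs$n_keys[i], designs$n_options[i])
        first <- tg[1] * stats::rlnorm(1, -sdlog^2 / 2, sdlog)
        gaps <- diff(tg)
        incr <- if (length(gaps)) stats::rgamma(length(gaps), shape = 4,
                                                rate = 4 / gaps) else numeric(0)
        v <- cumsum(c(first, incr))
        names(v) <- cell_key(designs$item_id[i], ks)
        xi <- c(xi, v)
      }
      parameter_set("model4", a = a, b = b, xi = xi)
    }
  })
}

#' Reference two-form certification-style item bank
#'
#' Builds an item bank emulating the structure of a two-form IT certification
#' test scored under DOMC: 83 distinct items (54 single-keyed, 24
#' double-keyed, 5 triple-keyed; triple-keyed items carry 5 response options,
#' all others 4), arranged in two 59-item forms sharing exactly 35 items so
#' that concurrent calibration links the forms on one latent metric.
#'
#' @param seed Integer seed governing form assignment and true parameters.
#' @param model Generating model for the true parameters.
#' @return A `domc_bank` with `true_params` attached.
#' @export
reference_bank <- function(seed, model = c("model4", "model5")) {
  model <- match.arg(model)
  n_keys <- rep(c(1L, 2L, 3L), c(54L, 24L, 5L))
  ids <- sprintf("it%02d", seq_along(n_keys))
  designs <- item_designs(ids, n_keys)
  forms <- with_seed(seed, {
    shuffled <- sample(ids)
    shared <- shuffled[1:35]
    only_a <- shuffled[36:59]
    only_b <- shuffled[60:83]
    list(A = sort(c(shared, only_a)), B = sort(c(shared, only_b)))
  })
  tp <- draw_true_params(designs, seed = seed + 1L, model = model)
  domc_bank(designs, forms, tp)
}

#' Simulation configuration
#'
#' @param n_examinees Number of examinees (> 0); abilities are drawn from the
#'   standard normal, mirroring the N(0, 1) prior that fixes the latent
#'   metric.
#' @param seed Integer seed; a fixed seed gives identical output.
#' @param mode `"item_level"` scores each administration in one Bernoulli
#'   draw with the model-implied item probability; `"option_level"` draws the
#'   k scheduled option responses as independent subprocess Bernoullis and
#'   scores the item correct only if all succeed.
#' @param form_assignment `"even"` alternates examinees across forms.
#' @param mask_extra_option If `TRUE`, flags administrations where an extra
#'   masking option would be shown after the final key (probability 0.5, no
#'   effect on the score or on `k_scheduled`).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_examinees, seed,
                       mode = c("item_level", "option_level"),
                       form_assignment = "even", mask_extra_option = FALSE) {
  stopifnot(n_examinees > 0)
  structure(list(n_examinees = as.integer(n_examinees),
                 seed = as.integer(seed), mode = match.arg(mode),
                 form_assignment = form_assignment,
                 mask_extra_option = isTRUE(mask_extra_option)),
            class = "sim_config")
}

#' Simulate DOMC administrations from an item bank
#'
#' For every examinee and every item on the examinee's form, a key location
#' is drawn by uniform permutation of the option order
#' ([draw_key_location()]), fixing the scheduled option count k, and the
#' administration is then scored. In `item_level` mode the score is Bernoulli
#' with the generating model's response probability; in `option_level` mode
#' the k scheduled options are answered as independent subprocess Bernoullis
#' (the conjunctive mechanism that motivates the LPE) and the item is correct
#' only if all k succeed.
#'
#' Draw order under the single seeded generator: abilities (examinee order),
#' then per record (examinee-major, form item order) key locations, then
#' scores; this order is part of the reproducibility contract.
#'
#' @param bank A [domc_bank()] with `true_params` (model4 or model5 for
#'   `item_level` mode; the subprocess `a`, `b` blocks are used directly in
#'   `option_level` mode).
#' @param config A [sim_config()].
#' @return A list of class `domc_sim` with elements `responses` (long-format
#'   data frame: `examinee_id`, `form_id`, `item_id`, `n_keys`,
#'   `k_scheduled`, `score`), `theta` (named vector of generating abilities)
#'   and `bank`.
#' @export
simulate_responses <- function(bank, config) {
  stopifnot(inherits(bank, "domc_bank"), inherits(config, "sim_config"))
  tp <- bank$true_params
  if (is.null(tp)) stop("bank has no true_params", call. = FALSE)
  n <- config$n_examinees
  ex_ids <- sprintf("ex%04d", seq_len(n))
  form_ids <- names(bank$forms)
  if (!identical(config$form_assignment, "even")) {
    stop("unknown form_assignment rule: ", config$form_assignment,
         call. = FALSE)
  }
  ex_form <- form_ids[((seq_len(n) - 1L) %% length(form_ids)) + 1L]

  des <- bank$designs
  items_of <- lapply(bank$forms, function(it) match(it, des$item_id))
  with_seed(config$seed, {
    theta <- stats::rnorm(n)
    names(theta) <- ex_ids
    ex_idx <- rep(seq_len(n), times = lengths(bank$forms)[ex_form])
    item_idx <- unlist(items_of[ex_form], use.names = FALSE)
    nk <- des$n_keys[item_idx]
    no <- des$n_options[item_idx]
    k <- vapply(seq_along(item_idx),
                function(r) max(sample.int(no[r], nk[r])), 1L)
    th <- theta[ex_idx]
    if (config$mode == "item_level") {
      p <- response_prob(tp, des$item_id[item_idx], k, th)
      score <- as.integer(stats::runif(length(p)) < p)
    } else {
      score <- conjunctive_score(th, unname(tp$a[des$item_id[item_idx]]),
                                 unname(tp$b[des$item_id[item_idx]]), k)
    }
    responses <- data.frame(
      examinee_id = ex_ids[ex_idx], form_id = ex_form[ex_idx],
      item_id = des$item_id[item_idx], n_keys = nk, k_scheduled = k,
      score = score, stringsAsFactors = FALSE)
    if (config$mask_extra_option) {
      responses$extra_shown <- k < no & stats::runif(nrow(responses)) < 0.5
    }
    structure(list(responses = responses, theta = theta, bank = bank,
                   config = config), class = "domc_sim")
  })
}
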