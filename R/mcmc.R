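# Metropolis-within-Gibbs calibration of the five DOMC response models.
#
# Each sweep updates four parameter blocks (abilities; discriminations;
# difficulties; exponents or slopes, where the model has them) by
# random-walk Metropolis. Components within a block are conditionally
# independent given the other blocks -- abilities across examinees, item
# parameters across items, exponent cells across (item, k) cells -- so every
# block proposes and accepts all of its components in one vectorized pass.
# Positivity-constrained parameters (a, xi, c) are proposed on the log scale
# with the Jacobian term included in the acceptance ratio.

#' Prior specification for Bayesian calibration
#'
#' Defaults: `xi ~ Gamma(0.25, 0.25)` (shape, rate; mean 1),
#' `b ~ Normal(0, 1)`, `a ~ Lognormal(0, 0.5)` (meanlog, sdlog),
#' `theta ~ Normal(0, 1)` (which alone fixes the latent metric under
#' concurrent calibration), and for the linear-exponent model
#' `c ~ Gamma(1, 2)` (mean 0.5).
#'
#' @param xi_shape,xi_rate Gamma prior for LPE exponents.
#' @param b_mean,b_sd Normal prior for difficulties.
#' @param a_logmean,a_logsd Lognormal prior for discriminations.
#' @param theta_mean,theta_sd Normal prior for abilities.
#' @param c_shape,c_rate Gamma prior for the linear exponent slope.
#' @return A list of class `prior_spec`.
#' @export
prior_spec <- function(xi_shape = 0.25, xi_rate = 0.25, b_mean = 0, b_sd = 1,
                       a_logmean = 0, a_logsd = 0.5,
                       theta_mean = 0, theta_sd = 1,
                       c_shape = 1, c_rate = 2) {
  stopifnot(xi_shape > 0, xi_rate > 0, b_sd > 0, a_logsd > 0, theta_sd > 0,
            c_shape > 0, c_rate > 0)
  structure(list(xi_shape = xi_shape, xi_rate = xi_rate, b_mean = b_mean,
                 b_sd = b_sd, a_logmean = a_logmean, a_logsd = a_logsd,
                 theta_mean = theta_mean, theta_sd = theta_sd,
                 c_shape = c_shape, c_rate = c_rate), class = "prior_spec")
}

# Index a long-format response table against the designs for fast
# vectorized likelihood evaluation. Validates k admissibility up front.
index_response_data <- function(data, designs, model, examinees = NULL) {
  di <- match(as.character(data$item_id), designs$item_id)
  if (anyNA(di)) {
    stop("responses reference items absent from the designs: ",
         paste(utils::head(unique(data$item_id[is.na(di)]), 5L),
               collapse = ", "), call. = FALSE)
  }
  k <- as.integer(data$k_scheduled)
  bad <- which(k < designs$n_keys[di] | k > designs$n_options[di])
  if (length(bad)) {
    stop("k_scheduled outside the admissible range [n_keys, n_options] ",
         "for record(s) ", paste(utils::head(bad, 5L), collapse = ", "),
         call. = FALSE)
  }
  if (length(data$score) && !all(data$score %in% c(0L, 1L))) {
    stop("scores must be binary 0/1", call. = FALSE)
  }
  if (is.null(examinees)) {
    examinees <- sort(unique(as.character(data$examinee_id)))
  }
  # Parameter cells are instantiated for observed (item, k) combinations;
  # with no data (prior-only runs) every admissible cell is instantiated.
  if (nrow(data)) {
    cells <- unique(data.frame(item_id = as.character(data$item_id), k = k,
                               stringsAsFactors = FALSE))
    cells <- cells[order(match(cells$item_id, designs$item_id), cells$k), ]
  } else {
    cells <- do.call(rbind, lapply(seq_len(nrow(designs)), function(i) {
      data.frame(item_id = designs$item_id[i],
                 k = admissible_k(designs$n_keys[i], designs$n_options[i]),
                 stringsAsFactors = FALSE)
    }))
  }
  rownames(cells) <- NULL
  ckeys <- cell_key(cells$item_id, cells$k)
  list(
    examinees = examinees, items = designs$item_id, cells = cells,
    cell_keys = ckeys,
    ex = match(as.character(data$examinee_id), examinees),
    it = di,
    cell = match(cell_key(as.character(data$item_id), k), ckeys),
    k = as.numeric(k), y = as.numeric(data$score))
}

# Per-record log-likelihood given explicit parameter vectors, with the
# probability clamped away from 0 and 1 so wandering proposals give a large
# finite deviance.
record_loglik <- function(model, rec, theta, a, b, x3) {
  if (!length(rec$y)) return(numeric(0))
  th <- theta[rec$ex]
  if (model %in% c("model1", "model4", "model5")) {
    ar <- a[rec$it]; br <- b[rec$it]
  } else if (model == "model2") {
    ar <- a[rec$cell]; br <- b[rec$cell]
  } else {
    ar <- a[rec$it]; br <- b[rec$cell]
  }
  lp <- stats::plogis(ar * (th - br), log.p = TRUE)
  if (model == "model4") lp <- lp * x3[rec$cell]
  if (model == "model5") lp <- lp * (x3[rec$it] * rec$k)
  p <- pmin(pmax(exp(lp), PROB_EPS), 1 - PROB_EPS)
  rec$y * log(p) + (1 - rec$y) * log1p(-p)
}

# Block layout per model: which state slot each block updates, how records
# group onto its components, and its prior log-density.
model_blocks <- function(model, rec, priors) {
  n_ex <- length(rec$examinees)
  n_it <- length(rec$items)
  n_cell <- nrow(rec$cells)
  blk <- function(slot, len, group, positive, logprior, init, scale, names) {
    list(slot = slot, len = len, group = group, positive = positive,
         logprior = logprior, init = init, scale = scale, names = names)
  }
  theta_blk <- blk("theta", n_ex, rec$ex, FALSE,
                   function(x) stats::dnorm(x, priors$theta_mean,
                                            priors$theta_sd, log = TRUE),
                   0, 0.6, rec$examinees)
  a_it <- blk("a", n_it, rec$it, TRUE,
              function(x) stats::dlnorm(x, priors$a_logmean, priors$a_logsd,
                                        log = TRUE),
              1, 0.3, rec$items)
  b_it <- blk("b", n_it, rec$it, FALSE,
              function(x) stats::dnorm(x, priors$b_mean, priors$b_sd,
                                       log = TRUE),
              0, 0.4, rec$items)
  a_cell <- blk("a", n_cell, rec$cell, TRUE, a_it$logprior, 1, 0.3,
                rec$cell_keys)
  b_cell <- blk("b", n_cell, rec$cell, FALSE, b_it$logprior, 0, 0.4,
                rec$cell_keys)
  xi_cell <- blk("x3", n_cell, rec$cell, TRUE,
                 function(x) stats::dgamma(x, priors$xi_shape, priors$xi_rate,
                                           log = TRUE),
                 1, 0.5, rec$cell_keys)
  c_it <- blk("x3", n_it, rec$it, TRUE,
              function(x) stats::dgamma(x, priors$c_shape, priors$c_rate,
                                        log = TRUE),
              0.5, 0.4, rec$items)
  switch(model,
    model1 = list(theta = theta_blk, a = a_it, b = b_it),
    model2 = list(theta = theta_blk, a = a_cell, b = b_cell),
    model3 = list(theta = theta_blk, a = a_it, b = b_cell),
    model4 = list(theta = theta_blk, a = a_it, b = b_it, xi = xi_cell),
    model5 = list(theta = theta_blk, a = a_it, b = b_it, c = c_it))
}

# Sum a per-record vector over a block's components, returning a
# full-length vector (zero for components with no records).
group_sum <- function(x, group, len) {
  out <- numeric(len)
  if (length(x)) {
    s <- rowsum(x, group)
    out[as.integer(rownames(s))] <- s[, 1L]
  }
  out
}

#' Run one Metropolis-within-Gibbs chain
#'
#' Calibrates one of the five DOMC response models. Every sweep updates each
#' parameter block componentwise by random-walk Metropolis (log-scale
#' proposals for positive parameters); proposal scales adapt toward an
#' acceptance rate of roughly 0.44 during the first `adapt` iterations and
#' are frozen afterwards. The deviance `-2 log L` is recorded at every
#' iteration.
#'
#' @param model One of `"model1"` .. `"model5"`.
#' @param data Long-format response table (may have zero rows, in which case
#'   the chain samples the priors).
#' @param designs An [item_designs()] table covering every item in `data`.
#' @param priors A [prior_spec()].
#' @param n_iter Number of iterations (>= 100); all draws are stored, and
#'   burn-in is discarded downstream.
#' @param seed Integer seed.
#' @param init `"default"` starts at a = 1, b = 0, xi = 1, c = 0.5,
#'   theta = 0; `"prior"` starts from a prior draw (used for the auxiliary
#'   chains of a convergence run).
#' @param adapt Number of initial adaptation iterations (default half).
#' @param examinees Optional character vector forcing the examinee roster;
#'   defaults to the ids present in `data`. Useful with a zero-row `data`
#'   to sample ability priors.
#' @return An object of class `domc_chain`: draw matrices per block
#'   (iterations in rows, named components in columns), the per-iteration
#'   `deviance`, acceptance rates, and the cell table.
#' @export
run_chain <- function(model, data, designs, priors = prior_spec(),
                      n_iter = 2000L, seed = 1L,
                      init = c("default", "prior"),
                      adapt = floor(n_iter / 2), examinees = NULL) {
  model <- match.arg(model, MODEL_IDS)
  init <- match.arg(init)
  if (n_iter < 100L) stop("n_iter must be >= 100", call. = FALSE)
  rec <- index_response_data(data, designs, model, examinees)
  blocks <- model_blocks(model, rec, priors)

  with_seed(seed, {
    state <- list(theta = NULL, a = NULL, b = NULL, x3 = NULL)
    for (bn in names(blocks)) {
      bl <- blocks[[bn]]
      state[[bl$slot]] <- rep(bl$init, bl$len)
    }
    if (init == "prior") {
      for (bn in names(blocks)) {
        bl <- blocks[[bn]]
        state[[bl$slot]] <- switch(bn,
          theta = stats::rnorm(bl$len, priors$theta_mean, priors$theta_sd),
          a = stats::rlnorm(bl$len, priors$a_logmean, priors$a_logsd),
          b = stats::rnorm(bl$len, priors$b_mean, priors$b_sd),
          xi = stats::rgamma(bl$len, priors$xi_shape, priors$xi_rate),
          c = stats::rgamma(bl$len, priors$c_shape, priors$c_rate))
      }
    }
    scales <- lapply(blocks, function(bl) rep(bl$scale, bl$len))
    acc_n <- lapply(blocks, function(bl) numeric(bl$len))
    acc_total <- lapply(blocks, function(bl) numeric(bl$len))
    draws <- lapply(blocks, function(bl)
      matrix(NA_real_, n_iter, bl$len, dimnames = list(NULL, bl$names)))
    deviance <- numeric(n_iter)
    ll <- record_loglik(model, rec, state$theta, state$a, state$b, state$x3)
    batch <- 50L

    for (iter in seq_len(n_iter)) {
      for (bn in names(blocks)) {
        bl <- blocks[[bn]]
        if (bl$len == 0L) next
        cur <- state[[bl$slot]]
        eps <- stats::rnorm(bl$len, 0, scales[[bn]])
        prop <- if (bl$positive) cur * exp(eps) else cur + eps
        st2 <- state
        st2[[bl$slot]] <- prop
        ll_prop <- record_loglik(model, rec, st2$theta, st2$a, st2$b, st2$x3)
        dll <- group_sum(ll_prop - ll, bl$group, bl$len)
        lr <- dll + bl$logprior(prop) - bl$logprior(cur)
        if (bl$positive) lr <- lr + eps  # Jacobian of the log-scale walk
        accept <- log(stats::runif(bl$len)) < lr
        accept[is.na(accept)] <- FALSE
        if (any(accept)) {
          cur[accept] <- prop[accept]
          state[[bl$slot]] <- cur
          if (length(ll)) {
            upd <- accept[bl$group]
            ll[upd] <- ll_prop[upd]
          }
        }
        acc_n[[bn]] <- acc_n[[bn]] + accept
        acc_total[[bn]] <- acc_total[[bn]] + accept
        if (iter <= adapt && iter %% batch == 0L) {
          delta <- min(0.1, 1 / sqrt(iter / batch))
          rate <- acc_n[[bn]] / batch
          scales[[bn]] <- scales[[bn]] * exp(ifelse(rate > 0.44, delta,
                                                    -delta))
          acc_n[[bn]][] <- 0
        }
        draws[[bn]][iter, ] <- state[[bl$slot]]
      }
      deviance[iter] <- -2 * sum(ll)
    }
    acc_rate <- vapply(acc_total, function(n) mean(n) / n_iter, 1)
    structure(list(model = model, draws = draws, deviance = deviance,
                   n_iter = n_iter, seed = seed, cells = rec$cells,
                   examinees = rec$examinees, items = rec$items,
                   acceptance = acc_rate),
              class = "domc_chain")
  })
}

#' @export
print.domc_chain <- function(x, ...) {
  cat("<domc_chain>", x$model, "-", x$n_iter, "iterations,",
      length(x$examinees), "examinees,", length(x$items), "items\n")
  invisible(x)
}

#' Fit a DOMC response model by MCMC
#'
#' Runs `n_chains` Metropolis-within-Gibbs chains ([run_chain()]). The first
#' chain starts from the conventional fixed values (a = 1, b = 0, xi = 1,
#' c = 0.5, theta = 0); additional chains start from prior draws so that the
#' Gelman-Rubin diagnostic compares genuinely dispersed trajectories.
#'
#' @inheritParams run_chain
#' @param n_chains Number of chains.
#' @param burn_in Iterations discarded before summarizing (default half).
#' @return An object of class `domc_fit` holding the chains, the data and
#'   designs (for deviance-based summaries), and the run settings.
#' @export
fit_domc <- function(data, designs, model, priors = prior_spec(),
                     n_iter = 2000L, n_chains = 2L,
                     burn_in = floor(n_iter / 2), seed = 1L) {
  model <- match.arg(model, MODEL_IDS)
  if (burn_in >= n_iter) stop("burn_in must be < n_iter", call. = FALSE)
  chains <- lapply(seq_len(n_chains), function(ch) {
    run_chain(model, data, designs, priors = priors, n_iter = n_iter,
              seed = seed + ch - 1L,
              init = if (ch == 1L) "default" else "prior",
              adapt = burn_in)
  })
  structure(list(model = model, chains = chains, data = data,
                 designs = designs, priors = priors, n_iter = n_iter,
                 burn_in = burn_in, seed = seed),
            class = "domc_fit")
}

#' @export
print.domc_fit <- function(x, ...) {
  cat("<domc_fit>", x$model, "-", length(x$chains), "chain(s) x", x$n_iter,
      "iterations (burn-in", x$burn_in, ")\n")
  invisible(x)
}

# Pool retained draws for one block across chains into a single matrix.
pooled_draws <- function(fit, block, burn_in) {
  keep <- seq.int(burn_in + 1L, fit$n_iter)
  do.call(rbind, lapply(fit$chains, function(ch) ch$draws[[block]][keep, ,
                                                                   drop = FALSE]))
}

#' Posterior means (and SDs) of every sampled parameter
#'
#' Elementwise means over the retained draws of all chains; the posterior
#' mean abilities are the examinee scoring output. Posterior SDs are
#' attached as the `"sd"` attribute (a list of named vectors per block).
#'
#' @param fit A [fit_domc()] result (or a single [run_chain()] result).
#' @param burn_in Iterations to discard (defaults to the fit's setting).
#' @return A [parameter_set()] of posterior means.
#' @export
posterior_summaries <- function(fit, burn_in = NULL) {
  if (inherits(fit, "domc_chain")) {
    fit <- structure(list(model = fit$model, chains = list(fit),
                          n_iter = fit$n_iter,
                          burn_in = floor(fit$n_iter / 2)),
                     class = "domc_fit")
  }
  if (is.null(burn_in)) burn_in <- fit$burn_in
  if (burn_in >= fit$n_iter) {
    stop("burn_in must be smaller than the number of draws", call. = FALSE)
  }
  blocks <- names(fit$chains[[1L]]$draws)
  means <- sds <- list()
  for (bn in blocks) {
    d <- pooled_draws(fit, bn, burn_in)
    means[[bn]] <- colMeans(d)
    sds[[bn]] <- apply(d, 2L, stats::sd)
  }
  pset <- parameter_set(fit$model, a = means$a, b = means$b,
                        xi = means$xi, c = means$c,
                        theta = if (is.null(means$theta)) numeric()
                                else means$theta)
  attr(pset, "sd") <- sds
  pset
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Computes the PSRF from between- and within-chain variances:
#' \eqn{\hat R = \sqrt{((n-1)/n \, W + B/n) / W}} for `m` chains of length
#' `n`. Values near 1 indicate convergence.
#'
#' @param chains A list of two or more equal-length numeric vectors (one
#'   scalar parameter's draws per chain).
#' @return The PSRF, a scalar.
#' @export
gelman_rubin <- function(chains) {
  if (!is.list(chains) || length(chains) < 2L) {
    stop("need at least 2 chains", call. = FALSE)
  }
  n <- unique(lengths(chains))
  if (length(n) != 1L) stop("chains must have equal lengths", call. = FALSE)
  if (n < 10L) stop("chains too short for the diagnostic", call. = FALSE)
  w <- mean(vapply(chains, stats::var, 1))
  b_over_n <- stats::var(vapply(chains, mean, 1))
  if (w == 0) return(if (b_over_n == 0) 1 else Inf)
  sqrt(((n - 1) / n * w + b_over_n) / w)
}

#' Per-parameter convergence diagnostics for a multi-chain fit
#'
#' @param fit A [fit_domc()] result with at least two chains.
#' @param burn_in Iterations to discard.
#' @param threshold Pass/fail cutoff on the PSRF (default 1.1).
#' @return A data frame with `block`, `parameter`, `r_hat`, `pass`.
#' @export
convergence_diagnostics <- function(fit, burn_in = NULL, threshold = 1.1) {
  stopifnot(inherits(fit, "domc_fit"))
  if (length(fit$chains) < 2L) {
    stop("convergence diagnostics need >= 2 chains", call. = FALSE)
  }
  if (is.null(burn_in)) burn_in <- fit$burn_in
  keep <- seq.int(burn_in + 1L, fit$n_iter)
  out <- list()
  for (bn in names(fit$chains[[1L]]$draws)) {
    nms <- colnames(fit$chains[[1L]]$draws[[bn]])
    if (!length(nms)) next
    rh <- vapply(seq_along(nms), function(j) {
      gelman_rubin(lapply(fit$chains, function(ch) ch$draws[[bn]][keep, j]))
    }, 1)
    out[[bn]] <- data.frame(block = bn, parameter = nms, r_hat = rh,
                            pass = rh < threshold, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Deviance information criterion of a fitted model
#'
#' The conditional-deviance DIC: `d_bar` is the posterior mean of the
#' deviance over retained draws, `d_hat` the deviance at the posterior means
#' of all parameters (including abilities) on their natural scales,
#' `p_d = d_bar - d_hat` the effective number of parameters, and
#' `dic = d_bar + p_d`. Lower DIC is preferred.
#'
#' @param fit A [fit_domc()] result.
#' @param burn_in Iterations to discard (defaults to the fit's setting).
#' @return An object of class `dic_result` with `d_bar`, `d_hat`, `p_d`,
#'   `dic`.
#' @export
dic <- function(fit, burn_in = NULL) {
  stopifnot(inherits(fit, "domc_fit"))
  if (is.null(burn_in)) burn_in <- fit$burn_in
  keep <- seq.int(burn_in + 1L, fit$n_iter)
  if (length(keep) < 2L) stop("need >= 2 retained draws", call. = FALSE)
  devs <- unlist(lapply(fit$chains, function(ch) ch$deviance[keep]))
  pm <- posterior_summaries(fit, burn_in)
  dic_result(d_bar = mean(devs), d_hat = domc_deviance(pm, fit$data))
}

#' Assemble a DIC result from its components
#'
#' Encodes the DIC identities `p_d = d_bar - d_hat` and
#' `dic = d_bar + p_d = d_hat + 2 p_d`; supply any two of the printed
#' components and the rest follow.
#'
#' @param d_bar Posterior mean deviance.
#' @param d_hat Deviance at the posterior means (plug-in deviance).
#' @param p_d Effective number of parameters (needed if `d_hat` is missing).
#' @return An object of class `dic_result`.
#' @export
dic_result <- function(d_bar, d_hat = NULL, p_d = NULL) {
  if (is.null(d_hat) && is.null(p_d)) {
    stop("supply d_hat or p_d alongside d_bar", call. = FALSE)
  }
  if (is.null(d_hat)) d_hat <- d_bar - p_d
  p_d <- d_bar - d_hat
  structure(list(d_bar = d_bar, d_hat = d_hat, p_d = p_d, dic = d_bar + p_d),
            class = "dic_result")
}

#' @export
print.dic_result <- function(x, ...) {
  cat(sprintf("DIC %.1f  (D-bar %.1f, D-hat %.1f, pD %.1f)\n",
              x$dic, x$d_bar, x$d_hat, x$p_d))
  invisible(x)
}
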