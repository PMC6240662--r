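# Independent oracles and small fixtures shared across the suite.

# Exact key-location pmf by brute-force enumeration of all C(n_options,
# n_keys) equally likely key-position sets; k is the maximum key position.
key_pmf_oracle <- function(n_keys, n_options) {
  sets <- utils::combn(n_options, n_keys)
  tabulate(apply(sets, 2L, max), nbins = n_options) / ncol(sets)
}

tv_dist <- function(p, q) 0.5 * sum(abs(p - q))

# Monte-Carlo standard error of the mean of a (possibly autocorrelated)
# draw sequence, by non-overlapping batch means.
mcse_batch <- function(x, n_batch = 50L) {
  n <- length(x) %/% n_batch * n_batch
  bm <- colMeans(matrix(x[seq_len(n)], ncol = n_batch))
  stats::sd(bm) / sqrt(n_batch)
}

# A small single-form bank for fast calibration tests.
tiny_bank <- function(seed = 1L, n_single = 6L, n_double = 3L,
                      n_triple = 1L, model = "model4") {
  n_keys <- rep(c(1L, 2L, 3L), c(n_single, n_double, n_triple))
  designs <- item_designs(sprintf("q%02d", seq_along(n_keys)), n_keys)
  tp <- draw_true_params(designs, seed = seed, model = model)
  domc_bank(designs, forms = list(F1 = designs$item_id), tp)
}

# Hand-buildable parameter sets for the probability-model tests.
pset_model4 <- function(items, a, b, xi_cells, theta = numeric()) {
  names(a) <- names(b) <- items
  parameter_set("model4", a = a, b = b, xi = xi_cells, theta = theta)
}

# Construct a synthetic single-chain object (for summary/DIC unit tests
# that need full control over the stored draws).
fake_chain <- function(draws, deviance, model = "model4") {
  structure(list(model = model, draws = draws, deviance = deviance,
                 n_iter = length(deviance), seed = 0L,
                 cells = NULL, examinees = colnames(draws$theta),
                 items = colnames(draws$a)),
            class = "domc_chain")
}

fake_fit <- function(chains, data = NULL, model = "model4",
                     burn_in = 0L) {
  structure(list(model = model, chains = chains, data = data,
                 designs = NULL, n_iter = chains[[1L]]$n_iter,
                 burn_in = burn_in, seed = 0L),
            class = "domc_fit")
}
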