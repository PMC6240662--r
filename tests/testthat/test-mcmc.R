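# Sampler mechanics: convergence diagnostic, posterior summaries, DIC, and
# internal consistency of the recorded deviance.

test_that("gelman_rubin matches its closed form on constructed chains", {
  x <- rnorm(1000)
  # identical chains: no between-chain variance
  expect_equal(gelman_rubin(list(x, x)), sqrt(999 / 1000))
  # stationary chains from one distribution stay near 1
  set.seed(31)
  expect_lt(gelman_rubin(list(rnorm(1000), rnorm(1000))), 1.05)
  # well-separated chains: closed-form B and W plugged into the PSRF
  lo <- x - 10; hi <- x + 10
  w <- (var(lo) + var(hi)) / 2
  b_over_n <- var(c(mean(lo), mean(hi)))
  expect_equal(gelman_rubin(list(lo, hi)),
               sqrt((999 / 1000 * w + b_over_n) / w))
  expect_gt(gelman_rubin(list(lo, hi)), 3)
  expect_error(gelman_rubin(list(x)), "at least 2")
  expect_error(gelman_rubin(list(x, rnorm(999))), "equal lengths")
})

test_that("posterior summaries are elementwise means over retained draws", {
  dr <- list(theta = cbind(e1 = rep(2, 100), e2 = c(rep(0, 50), rep(1, 50))),
             a = cbind(i1 = rep(1.5, 100)), b = cbind(i1 = rep(-0.5, 100)),
             xi = cbind(`i1:1` = seq(0.5, 1.5, length.out = 100)))
  fit <- fake_fit(list(fake_chain(dr, numeric(100))))
  pm <- posterior_summaries(fit, burn_in = 0)
  expect_equal(unname(pm$theta["e1"]), 2)
  expect_equal(unname(attr(pm, "sd")$theta["e1"]), 0)
  expect_equal(unname(pm$xi[1]), mean(seq(0.5, 1.5, length.out = 100)))
  # burn-in drops the first half
  pm2 <- posterior_summaries(fit, burn_in = 50)
  expect_equal(unname(pm2$theta["e2"]), 1)
  expect_error(posterior_summaries(fit, burn_in = 100), "burn_in")

  # streaming-mean oracle on a 500-draw block
  set.seed(8)
  m <- matrix(rnorm(500 * 3), 500, 3,
              dimnames = list(NULL, c("e1", "e2", "e3")))
  dr2 <- list(theta = m, a = cbind(i1 = rep(1, 500)),
              b = cbind(i1 = rep(0, 500)), xi = cbind(`i1:1` = rep(1, 500)))
  fit2 <- fake_fit(list(fake_chain(dr2, numeric(500))))
  pm <- posterior_summaries(fit2, burn_in = 0)
  stream <- numeric(3)
  for (r in seq_len(500)) stream <- stream + (m[r, ] - stream) / r
  expect_equal(unname(pm$theta), unname(stream))
})

test_that("DIC identities hold, including the point-mass degenerate case", {
  d <- data.frame(examinee_id = "e1", item_id = "i1", k_scheduled = 1,
                  score = 1)
  dr <- list(theta = cbind(e1 = rep(0, 100)), a = cbind(i1 = rep(1, 100)),
             b = cbind(i1 = rep(0, 100)), xi = cbind(`i1:1` = rep(1, 100)))
  dev <- rep(-2 * log(0.5), 100)
  fit <- fake_fit(list(fake_chain(dr, dev)), data = d)
  res <- dic(fit, burn_in = 0)
  expect_equal(res$p_d, 0)
  expect_equal(res$dic, res$d_bar)
  expect_equal(res$d_hat, res$d_bar)

  r2 <- dic_result(d_bar = 100, d_hat = 90)
  expect_equal(r2$p_d, 10)
  expect_equal(r2$dic, 110)
  expect_equal(r2$dic, r2$d_hat + 2 * r2$p_d)
  expect_error(dic_result(d_bar = 100), "d_hat or p_d")
})

test_that("the recorded deviance matches the sampled parameters", {
  b <- tiny_bank(6)
  s <- simulate_responses(b, sim_config(25, seed = 2))
  ch <- run_chain("model4", s$responses, b$designs, n_iter = 120, seed = 4)
  for (iter in c(37L, 120L)) {
    pset <- parameter_set("model4",
                          a = ch$draws$a[iter, ], b = ch$draws$b[iter, ],
                          xi = ch$draws$xi[iter, ],
                          theta = ch$draws$theta[iter, ])
    expect_equal(ch$deviance[iter], domc_deviance(pset, s$responses))
  }
})

test_that("chains are reproducible and validate their inputs", {
  b <- tiny_bank(6)
  s <- simulate_responses(b, sim_config(15, seed = 2))
  c1 <- run_chain("model2", s$responses, b$designs, n_iter = 100, seed = 9)
  c2 <- run_chain("model2", s$responses, b$designs, n_iter = 100, seed = 9)
  expect_identical(c1$draws, c2$draws)
  bad <- s$responses
  bad$k_scheduled[1] <- 6L
  expect_error(run_chain("model1", bad, b$designs, n_iter = 100),
               "admissible")
  expect_error(run_chain("model1", s$responses, b$designs, n_iter = 50),
               ">= 100")
})

test_that("with no data the chain reproduces its priors", {
  empty <- data.frame(examinee_id = character(), form_id = character(),
                      item_id = character(), n_keys = integer(),
                      k_scheduled = integer(), score = integer())
  d <- item_designs(c("i1", "i2"), c(1L, 2L))
  ch <- run_chain("model4", empty, d, n_iter = 4000, seed = 12,
                  examinees = c("e1", "e2"))
  keep <- 2001:4000
  xi_draws <- as.vector(ch$draws$xi[keep, ])
  # Gamma(0.25, 0.25): mean 1
  expect_lt(abs(mean(xi_draws) - 1),
            3 * mcse_batch(rowMeans(ch$draws$xi[keep, ])))
  th <- ch$draws$theta[keep, 1]
  expect_lt(abs(mean(th) - 0), 3 * mcse_batch(th) + 1e-9)
  ch5 <- run_chain("model5", empty, d, n_iter = 4000, seed = 13)
  cdraws <- ch5$draws$c[2001:4000, ]
  # Gamma(1, 2): mean 0.5
  expect_lt(abs(mean(cdraws) - 0.5), 3 * mcse_batch(rowMeans(cdraws)))
})

test_that("a short calibration recovers a strong simulated signal", {
  # small but informative: 10 items, 60 examinees, model1 on model1-style
  # data (xi = 1 for all cells)
  d <- item_designs(sprintf("m%02d", 1:10), rep(1L, 10))
  set.seed(77)
  a <- stats::setNames(rlnorm(10, 0, 0.3), d$item_id)
  b <- stats::setNames(seq(-1.5, 1.5, length.out = 10), d$item_id)
  bank <- domc_bank(d, list(F1 = d$item_id),
                    parameter_set("model5", a = a, b = b,
                                  c = stats::setNames(rep(1, 10), d$item_id)))
  sim <- simulate_responses(bank, sim_config(120, 5, mode = "option_level"))
  # fit the plain 2PL; b ordering should be recovered
  fit <- fit_domc(sim$responses, d, "model1", n_iter = 600, n_chains = 1,
                  seed = 3)
  pm <- posterior_summaries(fit)
  expect_gt(cor(pm$b, b), 0.8)
  expect_gt(cor(pm$theta[names(sim$theta)], sim$theta), 0.6)
})

test_that("convergence diagnostics cover every sampled parameter", {
  b <- tiny_bank(6)
  s <- simulate_responses(b, sim_config(20, seed = 2))
  fit <- fit_domc(s$responses, b$designs, "model1", n_iter = 200,
                  n_chains = 2, seed = 5)
  cd <- convergence_diagnostics(fit)
  n_par <- 20 + 2 * nrow(b$designs)
  expect_identical(nrow(cd), as.integer(n_par))
  expect_true(all(is.finite(cd$r_hat)))
  expect_error(convergence_diagnostics(
    fake_fit(list(fit$chains[[1]]))), ">= 2 chains")
})
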