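# Evaluation surfaces: classical statistics by key location, exponent
# summaries, DIC ranking, metric spread, recovery reporting.

hand_data <- function() {
  # 6 examinees, 2 items; item q1 observed at k = 1 and k = 2
  data.frame(
    examinee_id = rep(sprintf("e%d", 1:6), each = 2),
    item_id = rep(c("q1", "q2"), 6),
    n_keys = 1L,
    k_scheduled = c(1, 1, 1, 1, 2, 1, 2, 1, 2, 1, 1, 1),
    score = c(1, 1, 0, 1, 1, 0, 0, 0, 1, 1, 1, 0))
}

test_that("classical statistics match a hand calculation", {
  st <- classical_item_stats(hand_data())
  q1k1 <- st$by_cell[st$by_cell$item_id == "q1" & st$by_cell$k == 1, ]
  # q1 at k=1: examinees e1 (1), e2 (0), e6 (1) -> p = 2/3
  expect_equal(q1k1$p_value, 2 / 3)
  # totals: e1=2, e2=1, e6=1; cor(c(1,0,1), c(2,1,1))
  expect_equal(q1k1$item_total_r, cor(c(1, 0, 1), c(2, 1, 1)))
  q1k2 <- st$by_cell[st$by_cell$item_id == "q1" & st$by_cell$k == 2, ]
  expect_equal(q1k2$p_value, 2 / 3)
  expect_true(all(st$by_cell$p_value >= 0 & st$by_cell$p_value <= 1))
})

test_that("classical statistics ignore record order and flag degenerate cells", {
  d <- hand_data()
  st1 <- classical_item_stats(d)
  st2 <- classical_item_stats(d[sample(nrow(d)), ])
  expect_equal(st1$by_cell, st2$by_cell)
  expect_equal(st1$by_group, st2$by_group)

  allc <- d
  allc$score[allc$item_id == "q2"] <- 1L
  expect_warning(st3 <- classical_item_stats(allc), "undefined")
  q2 <- st3$by_cell[st3$by_cell$item_id == "q2", ]
  expect_equal(q2$p_value, 1)
  expect_true(is.na(q2$item_total_r))
  expect_error(classical_item_stats(hand_data()[0, ]), "nonempty")
})

test_that("the corrected item-total variant subtracts the item", {
  st <- classical_item_stats(hand_data(), corrected = TRUE)
  q1k1 <- st$by_cell[st$by_cell$item_id == "q1" & st$by_cell$k == 1, ]
  expect_equal(q1k1$item_total_r, cor(c(1, 0, 1), c(2, 1, 1) - c(1, 0, 1)))
})

test_that("simulated difficulty falls and discrimination rises with k", {
  # the key-location trend: later keys mean more scheduled options, larger
  # generating exponents, lower p and higher item-total correlation
  b <- reference_bank(17)
  s <- simulate_responses(b, sim_config(500, 18))
  st <- classical_item_stats(s$responses)
  g1 <- st$by_group[st$by_group$n_keys == 1, ]
  expect_identical(g1$k, 1:4)
  expect_true(all(diff(g1$mean_p) < 0))
  expect_gt(g1$mean_item_total_r[4], g1$mean_item_total_r[1])
})

test_that("xi_summary groups cell estimates by key count and k", {
  d <- item_designs(c("q1", "q2", "q3"), c(1L, 1L, 2L))
  xi <- c("q1:1" = 0.4, "q1:2" = 0.9, "q2:1" = 0.6, "q2:2" = 1.1,
          "q3:2" = 1.0)
  p <- parameter_set("model4", a = c(q1 = 1, q2 = 1, q3 = 1),
                     b = c(q1 = 0, q2 = 0, q3 = 0), xi = xi)
  tab <- xi_summary(p, d)
  r11 <- tab[tab$n_keys == 1 & tab$k == 1, ]
  expect_equal(r11$mean_xi, 0.5)
  expect_equal(r11$sd_xi, sd(c(0.4, 0.6)))
  r32 <- tab[tab$n_keys == 2 & tab$k == 2, ]
  expect_equal(r32$mean_xi, 1.0)
  expect_equal(r32$sd_xi, 0)       # single value
  expect_identical(r32$n_items, 1L)
  p1 <- parameter_set("model1", a = c(q1 = 1), b = c(q1 = 0))
  expect_error(xi_summary(p1, d), "model4")
})

test_that("group means agree between streaming and batch computation", {
  set.seed(9)
  d <- item_designs(sprintf("q%02d", 1:30), rep(1L, 30))
  tp <- draw_true_params(d, seed = 2)
  p <- parameter_set("model4", a = tp$a, b = tp$b, xi = tp$xi)
  tab <- xi_summary(p, d)
  for (k in 1:4) {
    idx <- paste(d$item_id, k, sep = ":")
    stream <- 0
    vals <- tp$xi[idx]
    for (j in seq_along(vals)) stream <- stream + (vals[j] - stream) / j
    expect_lt(abs(tab$mean_xi[tab$k == k] - stream), 1e-12)
  }
})

test_that("compare_models ranks by DIC with stable tie handling", {
  f <- list(model1 = dic_result(120, p_d = 80), model4 = dic_result(80, 60))
  tab <- compare_models(f)
  expect_identical(tab$model, c("model4", "model1"))
  expect_true(tab$winner[1] && !tab$winner[2])
  expect_false(any(tab$tie))
  ft <- list(m_a = dic_result(100, 50), m_b = dic_result(100, 50))
  tt <- compare_models(ft)
  expect_identical(tt$model[1], "m_a")  # tie broken by input order
  expect_true(all(tt$tie))
  expect_error(compare_models(list(m = dic_result(1, 0))), "at least 2")
  expect_error(compare_models(stats::setNames(list(dic_result(1, 0),
                                                   dic_result(2, 0)),
                                              c("m", "m"))), "duplicate")
})

test_that("metric_spread computes paired spread statistics", {
  set.seed(12)
  th <- stats::setNames(rnorm(200), sprintf("e%03d", 1:200))
  same <- metric_spread(th, th)
  expect_equal(same$overall_sd_ratio, 1)
  expect_equal(same$upper_decile_sd_ratio, 1)
  expect_true(all(abs(same$quantile_diff) < 1e-12))
  half <- metric_spread(th, 2 * th)
  expect_equal(half$overall_sd_ratio, 0.5)
  expect_equal(half$upper_decile_sd_ratio, 0.5)
  expect_error(metric_spread(th, th[-1]), "same examinee ids")
  shuffled <- th[sample(200)]
  expect_equal(metric_spread(th, shuffled * 1)$overall_sd_ratio,
               sd(th) / sd(shuffled))
})

test_that("theta histograms share bin edges and conserve counts", {
  set.seed(3)
  th_a <- stats::setNames(rnorm(150), sprintf("e%03d", 1:150))
  th_b <- th_a * 0.8
  h <- theta_histogram_data(th_a, th_b, bin_width = 0.5)
  expect_equal(sum(h$count_a), 150)
  expect_equal(sum(h$count_b), 150)
  expect_equal(h$upper - h$lower, rep(0.5, nrow(h)))
  same <- theta_histogram_data(th_a, th_a)
  expect_identical(same$count_a, same$count_b)
  expect_error(theta_histogram_data(th_a, th_b[-1]), "same examinee ids")
})

test_that("recovery_report measures bias, RMSE and correlation per block", {
  d <- item_designs(sprintf("q%d", 1:10), rep(1L, 10))
  tp <- draw_true_params(d, seed = 4)
  truth <- parameter_set("model4", a = tp$a, b = tp$b, xi = tp$xi,
                         theta = stats::setNames(rnorm(5), sprintf("e%d", 1:5)))
  same <- recovery_report(truth, truth)
  expect_true(all(same$bias == 0))
  expect_true(all(same$rmse == 0))
  expect_true(all(same$cor == 1))
  shifted <- truth
  shifted$b <- truth$b + 0.1
  rep2 <- recovery_report(truth, shifted)
  expect_equal(rep2$bias[rep2$block == "b"], 0.1)
  expect_equal(rep2$rmse[rep2$block == "b"], 0.1)
  # brute-force elementwise oracle on the 20-cell xi block
  jit <- truth
  set.seed(5)
  jit$xi <- truth$xi * exp(rnorm(length(truth$xi), 0, 0.2))
  rep3 <- recovery_report(truth, jit)
  err <- jit$xi - truth$xi
  expect_equal(rep3$bias[rep3$block == "xi"], sum(err) / length(err))
  expect_equal(rep3$rmse[rep3$block == "xi"], sqrt(sum(err^2) / length(err)))
  expect_equal(rep3$cor[rep3$block == "xi"], cor(truth$xi, jit$xi))
  bad <- truth
  names(bad$b)[1] <- "zzz"
  expect_error(recovery_report(truth, bad), "layout mismatch")
})
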