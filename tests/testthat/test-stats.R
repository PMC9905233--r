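make_counts <- function(n_runs = 100, slope = 0, base = 1, seed = 1,
                        schemes = c("none", "additive")) {
  set.seed(seed)
  do.call(rbind, lapply(schemes, function(s) {
    re <- rnorm(n_runs, 0, 0.2)
    expand.grid(run = 1:n_runs, iteration = 1:30) |>
      transform(bonus = s) |>
      (\(d) {d$count <- rpois(nrow(d),
                              exp(base + slope * d$iteration + re[d$run]));
             d})()
  }))
}

test_that("count model recovers a flat round effect for trendless data", {
  cnt <- make_counts(slope = 0, seed = 2)
  res <- fit_profitable_count_model(cnt)
  it <- res$coefficients[res$coefficients$term == "iteration", ]
  expect_lt(abs(it$estimate), 2 * it$se)
  expect_true(all(c("r2_marginal", "r2_conditional") %in%
                    names(res$fit_stats)))
  bad <- cnt; bad$count <- bad$count + 0.5
  expect_error(fit_profitable_count_model(bad), "integers")
})

test_that("deviation-coded scheme coefficients cover all schemes and sum to zero", {
  cnt <- make_counts(slope = 0.02, seed = 3,
                     schemes = c("none", "additive", "multiplicative"))
  res <- fit_profitable_count_model(cnt)
  co <- res$coefficients
  main <- co$estimate[co$term %in% paste0("bonus_",
                                          c("none", "additive",
                                            "multiplicative"))]
  expect_length(main, 3L)
  expect_lt(abs(sum(main)), 1e-8)
  inter <- co$estimate[grepl(":iteration$", co$term)]
  expect_length(inter, 3L)
  expect_lt(abs(sum(inter)), 1e-8)
})

test_that("learning-curve model guards separation and rejects shuffled rounds", {
  grid <- expand.grid(player = 1:30, round = 1:30)
  grid$group <- (grid$player - 1) %/% 6 + 1
  always <- transform(grid, profitable = 1)
  res <- fit_learning_curve(always)
  expect_true(all(res$fitted_by_round$fitted >= 0.99))
  expect_match(res$note, "separation")
  # genuine learning signal: positive slope
  set.seed(11)
  grid$profitable <- rbinom(nrow(grid), 1, plogis(-2 + 0.08 * grid$round))
  res2 <- fit_learning_curve(grid)
  slope <- res2$coefficients[res2$coefficients$term == "round", ]
  expect_gt(slope$estimate, 0)
  expect_lt(slope$p_value, 0.05)
  # permutation null: shuffling round labels kills the slope
  shuf <- grid
  shuf$round <- sample(shuf$round)
  res3 <- fit_learning_curve(shuf)
  s3 <- res3$coefficients[res3$coefficients$term == "round", ]
  expect_lt(abs(s3$estimate), 2 * s3$se)
  expect_error(fit_learning_curve(transform(grid, profitable = 2)), "binary")
})

test_that("exploration-quality fit returns both models and a likelihood ratio", {
  set.seed(5)
  d <- data.frame(player = 1:96, group = rep(1:16, each = 6),
                  half_change_round = sample(1:30, 96, replace = TRUE))
  # pure linear generator: quadratic term n.s.
  d$choice_score <- 60 - 0.8 * d$half_change_round + rnorm(96, 0, 4)
  res <- fit_exploration_quality(d)
  quad <- res$quadratic$coefficients
  qterm <- quad[grepl("\\^2", quad$term), ]
  expect_gt(qterm$p_value, 0.05)
  lin <- res$linear$coefficients
  expect_lt(lin$estimate[lin$term == "half_change_round"], 0)
  expect_gte(res$lrt_chisq, 0)
  # U-shaped generator: quadratic term positive and significant
  d$choice_score <- 60 - 3 * d$half_change_round +
    0.1 * d$half_change_round^2 + rnorm(96, 0, 3)
  res_u <- fit_exploration_quality(d)
  qu <- res_u$quadratic$coefficients
  expect_gt(qu$estimate[grepl("\\^2", qu$term)], 0)
  expect_lt(res_u$lrt_p, 0.05)
  # constant outcome: slopes collapse to zero
  d$choice_score <- 70
  res_c <- fit_exploration_quality(d)
  cc <- res_c$quadratic$coefficients
  expect_lt(max(abs(cc$estimate[cc$term != "(Intercept)"])), 1e-6)
  expect_warning(fit_exploration_quality(transform(d, group = 1)),
                 "fewer than 2 groups")
})

test_that("mediation decomposes total into direct plus indirect", {
  set.seed(8)
  n <- 120
  x <- rep(0:1, each = n / 2)
  m <- 2 * x + rnorm(n)
  y <- 1.5 * x + 3 * m + rnorm(n)
  res <- mediate(x, m, y, n_boot = 500, seed = 1)
  expect_lt(abs(res$total$estimate -
                  (res$direct$estimate + res$indirect$estimate)), 1e-8)
  expect_gt(res$indirect$ci[1], 0)
  expect_gt(res$proportion_mediated, 0.5)
  # mediator independent of condition: proportion mediated is 0
  m0 <- rnorm(n)
  y0 <- 2 * x + rnorm(n)
  res0 <- mediate(x, m0, y0, n_boot = 500, seed = 1)
  expect_identical(res0$proportion_mediated, 0)
  # constant outcome: all effects 0
  resc <- mediate(x, m, rep(3, n), n_boot = 200, seed = 1)
  expect_equal(resc$total$estimate, 0)
  expect_equal(resc$indirect$estimate, 0)
  expect_error(mediate(x, m, y, n_boot = 50), "at least 100")
})

test_that("group comparisons report statistic, p and effect size", {
  x <- c(1, 2, 3, 4, 5)
  same <- compare_groups(x, x, "welch_t")
  expect_equal(same$p_value, 1)
  expect_equal(same$effect_size, 0)
  set.seed(13)
  a <- rnorm(50); b <- rnorm(50, 1)
  wt <- compare_groups(a, b, "welch_t")
  expect_lt(wt$p_value, 0.05)
  expect_lt(wt$effect_size, 0)
  wx <- compare_groups(a, b, "wilcoxon", alternative = "less")
  expect_lt(wx$p_value, 0.05)
  tab <- matrix(c(30, 30, 30, 30), 2)
  cs <- compare_groups(tab, test = "chi_square")
  expect_gt(cs$p_value, 0.05)
  expect_error(compare_groups(1, c(1, 2), "welch_t"), "at least 2")
})
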