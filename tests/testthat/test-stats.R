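# Comparison statistics, multinomial model, design effect and power.

test_that("chi-square matches the 2x2 closed form and handles degenerate input", {
  tab <- rbind(c(10, 20), c(20, 10))
  res <- chi_square_table(tab)
  expect_equal(res$statistic, chisq_2x2_closed_form(10, 20, 20, 10),
               tolerance = 1e-10)
  expect_equal(res$df, 1)
  # cross-check against the standard implementation (no continuity correction)
  expect_equal(res$statistic,
               unname(chisq.test(tab, correct = FALSE)$statistic))
  same <- rbind(c(5, 10, 15), c(5, 10, 15))
  res0 <- chi_square_table(same)
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_value, 1)
  expect_error(chi_square_table(rbind(c(0, 0), c(1, 2))),
               class = "nutrinet_validation_error")
  expect_error(chi_square_table(matrix(1:3, 1)))
})

test_that("two-group Kruskal-Wallis agrees with the Mann-Whitney relation", {
  set.seed(2)
  y <- c(rnorm(20), rnorm(20, 1))
  g <- rep(c("a", "b"), each = 20)
  res <- kruskal_wallis_dunn(data.frame(y, g), y, g)
  mw <- wilcox.test(y ~ g, exact = FALSE, correct = FALSE)
  expect_equal(res$p_value, mw$p.value, tolerance = 1e-10)
  # the single Dunn z squared equals the KW statistic for two groups
  expect_equal(res$pairwise$z^2, res$statistic, tolerance = 1e-10)
})

test_that("Dunn pairs flag only the shifted group and Holm never lowers p", {
  set.seed(9)
  y <- c(rnorm(40), rnorm(40), rnorm(40, 3))
  g <- rep(c("a", "b", "c"), each = 40)
  res <- kruskal_wallis_dunn(data.frame(y, g), y, g)
  pw <- res$pairwise
  expect_true(all(pw$p_adjusted >= pw$p_value - 1e-15))
  expect_true(all(pw$p_adjusted <= 1))
  hit_c <- pw$group1 == "c" | pw$group2 == "c"
  expect_true(all(pw$p_adjusted[hit_c] < 0.05))
  expect_true(all(pw$p_adjusted[!hit_c] > 0.05))
  # all-identical values take the p = 1 path without dividing by zero
  flat <- kruskal_wallis_dunn(values = rep(5, 30), groups = rep(1:3, 10))
  expect_equal(flat$p_value, 1)
  expect_true(all(is.finite(flat$pairwise$z)))
})

test_that("multinomial fit reduces to binary logistic with two outcomes", {
  set.seed(4)
  n <- 400
  d <- tibble::tibble(
    pattern = sample(1:2, n, TRUE),
    dmpw = sample(dmpw_levels(), n, TRUE)
  )
  fit <- fit_multinomial(d, baseline = "1", predictors = "dmpw")
  ref <- glm(I(pattern == 2) ~ factor(dmpw, levels = dmpw_levels()),
             data = d, family = binomial)
  ours <- fit$or_table
  expect_equal(sort(unname(ours$log_or)), sort(unname(coef(ref))),
               tolerance = 1e-4)
  expect_true(all(ours$conf_low <= ours$odds_ratio + 1e-12))
  expect_true(all(ours$odds_ratio <= ours$conf_high + 1e-12))
})

test_that("a planted odds ratio is recovered within its CI half-width", {
  set.seed(14)
  n <- 1500
  dmpw <- sample(dmpw_levels(), n, TRUE, prob = c(0.68, 0.2, 0.12))
  # outcome 2 is baseline; Overestimated doubles the odds of pattern 1
  lin <- ifelse(dmpw == "Overestimated", log(2), 0)
  p1 <- exp(lin) / (exp(lin) + 1 + 1 + 1)
  pattern <- vapply(seq_len(n), function(i) {
    sample(1:4, 1, prob = c(p1[i], (1 - p1[i]) / 3, (1 - p1[i]) / 3,
                            (1 - p1[i]) / 3))
  }, integer(1))
  fit <- fit_multinomial(tibble::tibble(pattern = pattern, dmpw = dmpw),
                         baseline = "2", predictors = "dmpw")
  row <- dplyr::filter(fit$or_table, outcome == "1",
                       grepl("Overestimated", term))
  half_width <- (log(row$conf_high) - log(row$conf_low)) / 2
  expect_lt(abs(row$log_or - log(2)), half_width)
})

test_that("design effect follows 1 + (m - 1) icc and its edge cases", {
  # iid data: icc clamps at 0, Deff ~ 1
  set.seed(6)
  iid <- tibble::tibble(y = rnorm(1000), cl = rep(1:25, each = 40))
  de <- design_effect(iid, "y", "cl")
  expect_equal(de$deff, 1, tolerance = 0.25)
  expect_equal(de$mean_cluster_size, 40)
  expect_false(de$sampling_influenced)
  # strong cluster effects: hand-check Deff against the formula with the
  # ANOVA icc computed independently
  cl <- rep(1:21, each = 21)
  y <- rnorm(21)[cl] + rnorm(length(cl), 0, 1)
  d2 <- design_effect(tibble::tibble(y = y, cl = cl), "y", "cl")
  s <- summary(aov(y ~ factor(cl)))[[1]]
  icc_hand <- max(0, (s$`Mean Sq`[1] - s$`Mean Sq`[2]) /
                    (s$`Mean Sq`[1] + (21 - 1) * s$`Mean Sq`[2]))
  expect_equal(d2$deff, 1 + (21 - 1) * icc_hand, tolerance = 1e-10)
  # m = 21 at icc = 0.1 would flag once Deff crosses 3
  expect_equal(1 + (21 - 1) * 0.1, 3)
  expect_error(design_effect(tibble::tibble(y = 1:5, cl = rep(1, 5)), "y", "cl"),
               class = "nutrinet_validation_error")
})

test_that("power is alpha at null, monotone, and saturates for huge effects", {
  null <- power_simulation(n_per_group = 30, fold_change = 1, alpha = 0.05,
                           reps = 400, seed = 2)
  expect_lt(abs(null$power - 0.05), 0.05)
  lo <- power_simulation(n_per_group = 15, fold_change = 2, alpha = 0.01,
                         reps = 300, seed = 3)
  hi <- power_simulation(n_per_group = 60, fold_change = 2, alpha = 0.01,
                         reps = 300, seed = 3)
  expect_gte(hi$power, lo$power)
  big <- power_simulation(n_per_group = 30, fold_change = 50, alpha = 0.01,
                          reps = 200, seed = 4)
  expect_gt(big$power, 0.99)
  expect_warning(power_simulation(reps = 50, seed = 1), "100")
})

test_that("the planted study size reaches the planned power", {
  # 50 per group, 2-fold shift, alpha 1%: planned to exceed 90% power
  ps <- power_simulation(n_per_group = 50, fold_change = 2, alpha = 0.01,
                         cv = 0.8, reps = 400, seed = 11)
  expect_gt(ps$power, 0.9)
})
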