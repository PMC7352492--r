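# Synthetic-cohort generator: determinism, marginal recovery, copula
# fidelity, truth-table consistency and the FFQ round trip.

test_that("generation is deterministic given config and seed", {
  cfg <- generator_config(n_subjects = 150, seed = 99)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$cohort, b$cohort)
  expect_identical(a$truth$labels, b$truth$labels)
  ia <- generate_ffq_intakes(a, cfg)
  ib <- generate_ffq_intakes(b, cfg)
  expect_identical(ia, ib)
  ra <- generate_ffq_responses(ia, default_group_map(), cfg)
  expect_identical(ra, generate_ffq_responses(ib, default_group_map(), cfg))
})

test_that("configured marginals are recovered at cohort scale", {
  cfg <- generator_config(n_subjects = 1496, seed = 5)
  b <- generate_cohort(cfg)
  props <- prop.table(table(b$cohort$dmpw))
  expect_equal(unname(props["Agreed"]), 0.683, tolerance = 0.02 / 0.683)
  expect_equal(unname(props["Underestimated"]), 0.197, tolerance = 0.02 / 0.197)
  expect_equal(unname(props["Overestimated"]), 0.120, tolerance = 0.02 / 0.120)
  expect_equal(mean(b$cohort$sex == "female"), 0.571, tolerance = 0.05)
  all_female <- generate_cohort(generator_config(
    n_subjects = 50, sex_proportion_female = 1, seed = 1))
  expect_true(all(all_female$cohort$sex == "female"))
})

test_that("planted DMPW labels re-classify identically through the rule", {
  cfg <- generator_config(n_subjects = 800, seed = 12)
  b <- generate_cohort(cfg)
  reclass <- classify_dmpw(b$cohort$status, b$cohort$perceived_level)
  expect_identical(as.character(reclass), as.character(b$truth$labels$dmpw))
  # percentile lies inside the band of the assigned status
  expect_identical(as.character(classify_status(b$cohort$bmi_for_age_percentile)),
                   as.character(b$cohort$status))
})

test_that("infeasible DMPW/status combinations are rejected at config time", {
  expect_error(
    generator_config(
      status_proportions = c(underweight = 0, normal = 0,
                             overweight = 0.5, obese = 0.5)),
    class = "nutrinet_config_error"
  )
  expect_error(generator_config(dmpw_proportions = c(0.9, 0.2, -0.1)))
  expect_error(generator_config(dmpw_proportions = c(0.5, 0.4, 0.2)))
})

test_that("copula reproduces planted rank correlations on a fixed marginal", {
  # single mixture component: the pooled group Spearman equals the target
  cfg <- network_recovery_config(n_subjects = 6000, seed = 3)
  b <- generate_cohort(cfg)
  intake <- generate_ffq_intakes(b, cfg)
  spec <- default_correlation_spec()
  for (d in dmpw_levels()) {
    sub <- intake[b$cohort$dmpw == d, ]
    sm <- spearman_matrix(sub)
    expect_lt(max(abs(sm$rho - spec[[d]])), 0.1)
  }
  # planted +0.8 edge shows up strongly at n ~ 500
  g <- food_groups()
  eye <- diag(14); dimnames(eye) <- list(g, g)
  R <- eye
  R["sugar_sweets", "sweetened_beverages"] <-
    R["sweetened_beverages", "sugar_sweets"] <- 0.8
  cfg2 <- network_recovery_config(
    n_subjects = 1500, seed = 8,
    correlation_spec = list(Agreed = R, Underestimated = eye,
                            Overestimated = eye)
  )
  b2 <- generate_cohort(cfg2)
  i2 <- generate_ffq_intakes(b2, cfg2)
  agreed <- i2[b2$cohort$dmpw == "Agreed", ]
  sm <- spearman_matrix(agreed)
  expect_gt(sm$rho["sugar_sweets", "sweetened_beverages"], 0.6)
  # identity structure stays near zero off-diagonal
  over <- i2[b2$cohort$dmpw == "Overestimated", ]
  sm0 <- spearman_matrix(over)
  expect_lt(max(abs(sm0$rho - diag(14))), 0.15)
})

test_that("planted negative correlation between roots and oils is inverse", {
  cfg <- network_recovery_config(n_subjects = 900, seed = 21)
  b <- generate_cohort(cfg)
  intake <- generate_ffq_intakes(b, cfg)
  over <- intake[b$cohort$dmpw == "Overestimated", ]
  sm <- spearman_matrix(over)
  expect_lt(sm$rho["roots", "oils"], -0.5)
})

test_that("FFQ responses round-trip through the ffq module within grid error", {
  cfg <- generator_config(n_subjects = 120, seed = 31)
  b <- generate_cohort(cfg)
  intake <- generate_ffq_intakes(b, cfg)
  map <- default_group_map()
  resp <- generate_ffq_responses(intake, map, cfg)
  rec <- aggregate_food_groups(resp, map)
  rec <- rec[match(intake$subject_id, rec$subject_id), names(intake)]
  # loss only from quantization to never/rare: below half the monthly rate
  # of the reference portion, per item
  items_per_group <- 2
  bound <- items_per_group * cfg$reference_portion_g * (2 / 30.44) / 2 + 1e-9
  err <- abs(as.matrix(rec[, -1]) - as.matrix(intake[, -1]))
  expect_true(all(err <= bound))
  # zero-intake subject maps to all never/rare
  zero <- intake[1, ]
  zero[, -1] <- 0
  rz <- generate_ffq_responses(zero, map, cfg)
  expect_true(all(rz$frequency == "never/rare"))
  # a single-item group at one weekly 70 g portion is 10 g/day
  one <- tibble::tibble(subject_id = 1, snacks = 10)
  m1 <- tibble::tibble(item_id = "snack_item", group = "snacks")
  cfg70 <- generator_config(n_subjects = 10, reference_portion_g = 70, seed = 1)
  r1 <- generate_ffq_responses(one, m1, cfg70)
  expect_equal(r1$frequency, "1/week")
  expect_equal(r1$portion_g, 70)
  expect_error(generate_ffq_responses(one, tibble::tibble(item_id = "x", group = "other"),
                                      cfg70),
               class = "nutrinet_validation_error")
})

test_that("cluster structure yields a design effect near its target", {
  cfg <- generator_config(n_subjects = 1496, seed = 17)
  b <- generate_cohort(cfg)
  de <- design_effect(b$truth$labels, "pattern", "cluster")
  # 1 + (1496/50 - 1) * 0.004 = 1.116; ANOVA estimate is noisy around it
  expect_gt(de$deff, 0.95)
  expect_lt(de$deff, 1.6)
})
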