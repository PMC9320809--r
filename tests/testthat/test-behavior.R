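trial_of <- function(states, id = "T1", male = "A", female = "B") {
  ethogram_trial(id, states, male_strain = male, female_strain = female)
}

test_that("the two initiation rules fire where enumeration says they should", {
  tr <- trial_of(c("separate", "separate", "engaging", "separate",
                   "singing", "singing", "singing"))
  expect_identical(detect_initiation(tr, "first"), 3L)
  expect_identical(detect_initiation(tr, "consecutive3"), 5L)

  expect_true(is.na(detect_initiation(trial_of(rep("separate", 4)), "first")))
  expect_true(is.na(detect_initiation(trial_of(rep("separate", 4)), "consecutive3")))

  immediate <- trial_of(c("engaging", "engaging", "engaging", "singing"))
  expect_identical(detect_initiation(immediate, "first"), 1L)
  expect_identical(detect_initiation(immediate, "consecutive3"), 1L)

  # two isolated contacts never satisfy the three-consecutive rule
  broken <- trial_of(c("separate", "engaging", "separate", "engaging", "separate"))
  expect_identical(detect_initiation(broken, "first"), 2L)
  expect_true(is.na(detect_initiation(broken, "consecutive3")))
})

test_that("the consecutive3 rule never fires before the first rule", {
  set.seed(42)
  for (i in 1:200) {
    states <- sample(c("separate", "engaging", "singing"), 12, replace = TRUE,
                     prob = c(.5, .3, .2))
    tr <- trial_of(states)
    a <- detect_initiation(tr, "first")
    b <- detect_initiation(tr, "consecutive3")
    if (!is.na(a) && !is.na(b)) expect_gte(b, a)
    if (is.na(a)) expect_true(is.na(b))
  }
})

test_that("trial summaries count latency and budgets by hand-derived values", {
  s <- summarize_trial(trial_of(c("engaging", "singing", "singing", "singing",
                                  "copulating")))
  expect_identical(s$initiation_index, 1L)
  expect_equal(s$copulation_latency_s, 40)
  expect_equal(s$budget_engaging, 0.25)
  expect_equal(s$budget_singing, 0.75)
  expect_equal(s$separate_fraction, 0)

  # too short for the three-consecutive rule, so use the first-contact rule
  s2 <- summarize_trial(trial_of(c("singing", "copulating")), "first")
  expect_equal(s2$copulation_latency_s, 10)
  expect_equal(s2$budget_singing, 1.0)

  s3 <- summarize_trial(trial_of(rep("separate", 5)))
  expect_true(s3$censored)
  expect_true(is.na(s3$initiation_index))
  expect_identical(s3$n_timepoints, 0L)
})

test_that("budget fractions sum to one over the scoring window", {
  cfg <- default_config(seed = 77, n_male_strains = 4, trials_per_pair = 3)
  panel <- simulate_panel(cfg)
  s <- summarize_trials(panel$trials, quiet = TRUE)
  courting <- s[!is.na(s$initiation_index), ]
  sums <- rowSums(courting[paste0("budget_", active_states())]) +
    courting$separate_fraction
  expect_equal(unname(sums), rep(1, nrow(courting)))
})

test_that("summaries ignore trailing separate padding beyond the imputed window", {
  states <- c("separate", "engaging", "singing", "singing", "singing")
  a <- summarize_trial(trial_of(states), censored_window_s = 30)
  b <- summarize_trial(trial_of(c(states, rep("separate", 20))),
                       censored_window_s = 30)
  for (col in c(paste0("budget_", active_states()), "separate_fraction",
                "n_timepoints")) {
    expect_equal(a[[col]], b[[col]])
  }
})

test_that("censored scoring windows equal the group's mean successful latency", {
  trials <- list(
    trial_of(c("engaging", rep("singing", 9), "copulating"), "s1"),   # 100 s
    trial_of(c("engaging", rep("singing", 19), "copulating"), "s2"),  # 200 s
    trial_of(rep("separate", 10), "c1")
  )
  expect_equal(impute_censored_window(trials, "A", "B"), 150)
  one <- list(trial_of(c("engaging", rep("singing", 8), "copulating"), "s1"))
  expect_equal(impute_censored_window(one, "A", "B"), 90)
  expect_error(
    impute_censored_window(list(trial_of(rep("separate", 5))), "A", "B"),
    "no reference latency"
  )
})

test_that("mating index fills censored latencies and weights by success rate", {
  expect_equal(mating_index(c(100, 200), 2, 2, max_observed = 200)$index, 150)
  expect_equal(mating_index(c(100, NA), 1, 2, max_observed = 600)$index, 700)
  zero <- mating_index(c(NA, NA, NA, NA, NA), 0, 5, max_observed = 600)
  expect_true(is.infinite(zero$index))
  expect_true(zero$all_failed)
  expect_error(mating_index(c(-5, 10), 1, 2, 10), "negative latency")
})

test_that("progeny latency log-rank matches the hand-computed one-event table", {
  # identical event times: no evidence of a difference
  same <- data.frame(male_strain = rep(c("ref", "tst"), each = 4),
                     days = rep(c(2, 5, 9, 16), 2),
                     censored = rep(c(FALSE, FALSE, FALSE, TRUE), 2))
  res <- progeny_latency_test(same, "ref")
  expect_equal(res$chisq, 0, tolerance = 1e-12)
  expect_equal(res$p, 1, tolerance = 1e-12)

  # all reference events on day 1, test group fully censored at 16:
  # single event time, O - E = 5 - 2.5, V = 5 * 25 * 5 / (100 * 9) -> chisq 9
  split <- data.frame(male_strain = rep(c("ref", "tst"), each = 5),
                      days = c(rep(1, 5), rep(16, 5)),
                      censored = rep(c(FALSE, TRUE), each = 5))
  res2 <- progeny_latency_test(split, "ref")
  expect_equal(res2$chisq, 9, tolerance = 1e-8)

  expect_error(
    progeny_latency_test(split[c(1:5, 6), ], "ref"),
    "fewer than 2 trials"
  )
  allcens <- data.frame(male_strain = rep(c("ref", "tst"), each = 3),
                        days = 16, censored = TRUE)
  expect_error(progeny_latency_test(allcens, "ref"), "degenerate comparison")
})

test_that("initiation-method discrepancy diagnostic reports seconds", {
  trials <- list(
    trial_of(c("separate", "engaging", "separate", "singing", "singing",
               "singing"), "a"),
    trial_of(c("engaging", "engaging", "engaging"), "b")
  )
  d <- compare_initiation_methods(trials)
  expect_identical(d$n, 2L)
  expect_equal(sort(d$discrepancy_s), c(0, 20))
  expect_equal(d$mean_s, 10)
  expect_equal(d$max_s, 20)
})
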