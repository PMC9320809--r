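mk_trial <- function(states, id = "T1", male = "A", female = "Z") {
  ethogram_trial(id, states, male_strain = male, female_strain = female)
}

test_that("transition counting matches hand counts and is additive", {
  tr <- mk_trial(c("engaging", "singing", "singing", "copulating"))
  cnt <- count_transitions(list(tr))
  expect_identical(cnt["engaging", "singing"], 1L)
  expect_identical(cnt["singing", "singing"], 1L)
  expect_identical(cnt["singing", "copulating"], 1L)
  expect_identical(sum(cnt), 3L)
  expect_true(all(cnt["copulating", ] == 0L))

  two <- count_transitions(list(tr, mk_trial(tr$states, "T2")))
  expect_equal(unclass(two), unclass(cnt) * 2L, ignore_attr = TRUE)

  lone <- count_transitions(list(mk_trial("separate")))
  expect_identical(sum(lone), 0L)
  expect_error(count_transitions(list()), "empty trial set")
  expect_error(
    count_transitions(list(tr, mk_trial("separate", male = "other"))),
    "several strain pairs"
  )
})

test_that("matrix estimation normalizes rows with and without smoothing", {
  cnt <- count_transitions(list(
    mk_trial(c(rep(c("singing", "singing"), 3), "copulating"))
  ))
  # singing row: 5 self-transitions, 1 into copulating
  p <- estimate_matrix(cnt)
  expect_equal(p["singing", "singing"], 5 / 6)
  expect_equal(p["singing", "copulating"], 1 / 6)
  expect_equal(unname(rowSums(p)), rep(1, 8), tolerance = 1e-12)
  expect_equal(p["copulating", "copulating"], 1)

  # smoothing example: row total 2, all mass into copulating, alpha = 1, k = 8
  cnt2 <- matrix(0L, 8, 8, dimnames = list(behavior_states(), behavior_states()))
  cnt2["singing", "copulating"] <- 2L
  p2 <- estimate_matrix(cnt2, smoothing = 1)
  expect_equal(p2["singing", "copulating"], 3 / 10)

  # unsmoothed all-zero row: uniform fallback, flagged
  p3 <- estimate_matrix(cnt2)
  expect_true("scissoring" %in% attr(p3, "flagged_rows"))
  expect_equal(unname(p3["scissoring", ]), rep(1 / 8, 8))
})

test_that("homogeneity statistic equals the multinomial likelihood-ratio oracle", {
  g1 <- matrix(0L, 8, 8, dimnames = list(behavior_states(), behavior_states()))
  g2 <- g1
  g1["separate", c("separate", "engaging")] <- c(30L, 10L)
  g1["engaging", c("separate", "engaging")] <- c(5L, 5L)
  g2["separate", c("separate", "engaging")] <- c(10L, 30L)
  g2["engaging", c("separate", "engaging")] <- c(5L, 5L)
  ht <- homogeneity_test(g1, g2, correct = FALSE)
  expect_equal(ht$statistic, oracle_g2(list(g1, g2)), tolerance = 1e-10)
  expect_identical(ht$df, 2L)
  # random sparse matrices, several group counts
  set.seed(99)
  for (rep in 1:20) {
    ng <- sample(2:4, 1)
    mats <- lapply(seq_len(ng), function(i) {
      m <- matrix(rpois(64, 1.2), 8, 8,
                  dimnames = list(behavior_states(), behavior_states()))
      m[8, ] <- 0L
      m
    })
    ht <- homogeneity_test(mats, correct = FALSE)
    expect_equal(ht$statistic, oracle_g2(mats), tolerance = 1e-8)
  }
})

test_that("identical groups give statistic 0 and p = 1", {
  m <- matrix(rpois(64, 3), 8, 8,
              dimnames = list(behavior_states(), behavior_states()))
  m[8, ] <- 0L
  ht <- homogeneity_test(m, m)
  expect_equal(ht$statistic, 0, tolerance = 1e-12)
  expect_equal(ht$p.value, 1)
})

test_that("homogeneity test is symmetric under group relabeling", {
  set.seed(13)
  m1 <- matrix(rpois(64, 2), 8, 8,
               dimnames = list(behavior_states(), behavior_states()))
  m2 <- matrix(rpois(64, 2), 8, 8,
               dimnames = list(behavior_states(), behavior_states()))
  m1[8, ] <- m2[8, ] <- 0L
  a <- homogeneity_test(m1, m2)
  b <- homogeneity_test(m2, m1)
  expect_equal(a$statistic, b$statistic)
  expect_identical(a$df, b$df)
})

test_that("degenerate homogeneity inputs raise errors", {
  m <- matrix(0L, 8, 8, dimnames = list(behavior_states(), behavior_states()))
  expect_error(homogeneity_test(m), "at least 2 groups")
  expect_error(homogeneity_test(m, m), "degenerate test")
  m1 <- m
  m1["singing", "singing"] <- 5L   # single supported column per group
  expect_error(homogeneity_test(m1, m1), "degenerate test")
})

test_that("per-trial transition frequencies normalize to one", {
  f <- per_trial_transition_freq(mk_trial(c("engaging", "singing", "copulating")))
  expect_equal(f[["engaging->singing"]], 0.5)
  expect_equal(f[["singing->copulating"]], 0.5)
  f2 <- per_trial_transition_freq(mk_trial(rep("singing", 3)))
  expect_equal(unname(f2), 1)
  expect_error(per_trial_transition_freq(mk_trial("singing")), ">= 2 states")

  set.seed(7)
  m <- null_dynamics()
  for (i in 1:25) {
    tr <- sample_chain_trial(m, sample(5:40, 1))
    expect_equal(sum(per_trial_transition_freq(tr)), 1, tolerance = 1e-12)
  }
})

test_that("transition-frequency tables align trials on shared pair columns", {
  trials <- list(mk_trial(c("engaging", "singing", "copulating"), "a"),
                 mk_trial(c("singing", "singing", "singing"), "b"))
  tab <- transition_freq_table(trials)
  expect_identical(nrow(tab), 2L)
  expect_equal(tab[tab$trial_id == "b", "singing->singing"], 1)
  expect_equal(tab[tab$trial_id == "b", "engaging->singing"], 0)
  expect_equal(unname(rowSums(tab[, -(1:3)])), c(1, 1))
})
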