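test_that("default configs satisfy the transition-matrix invariants", {
  cfg <- default_config(seed = 3)
  expect_length(cfg$male_strains, 12L)
  expect_identical(cfg$female_strains, c("Zlike", "Mlike"))
  for (s in cfg$male_strains) {
    for (f in cfg$female_strains) {
      m <- cfg$matrices[[s]][[f]]
      expect_equal(unname(rowSums(m)), rep(1, 8), tolerance = 1e-12)
      expect_true(all(m >= 0))
      expect_equal(m["copulating", "copulating"], 1)
    }
  }
  # exactly one divergently selected trait in the ground truth
  g <- cfg$truth$gamma
  divergent <- rownames(g)[g[, "Zlike"] * g[, "Mlike"] < 0]
  expect_identical(divergent, "cVA")
  expect_identical(cfg$truth$divergent_trait, "cVA")
})

test_that("simulated panels are byte-identical under the same seed", {
  cfg <- default_config(seed = 9, n_male_strains = 4, trials_per_pair = 2)
  p1 <- simulate_panel(cfg)
  p2 <- simulate_panel(cfg)
  expect_identical(p1$trials, p2$trials)
  expect_identical(p1$chc_peaks, p2$chc_peaks)
  p3 <- simulate_panel(default_config(seed = 10, n_male_strains = 4,
                                      trials_per_pair = 2))
  expect_false(identical(p1$trials, p3$trials))
})

test_that("copulating is absorbing in every simulated trial", {
  cfg <- default_config(seed = 21, n_male_strains = 6, trials_per_pair = 4)
  panel <- simulate_panel(cfg)
  for (tr in panel$trials) {
    cop <- which(tr$states == "copulating")
    expect_lte(length(cop), 1L)
    if (length(cop) == 1L) {
      expect_identical(cop, length(tr$states))
      expect_true(tr$copulated)
    } else {
      expect_false(tr$copulated)
    }
    expect_lte(length(tr$states), cfg$max_timepoints)
  }
})

test_that("degenerate dynamics behave as configured", {
  cfg <- default_config(seed = 2, n_male_strains = 2, trials_per_pair = 1)
  cfg$success_intercept <- 50  # force the mating branch
  instant <- matrix(0, 8, 8, dimnames = list(behavior_states(), behavior_states()))
  instant["separate", "copulating"] <- 1
  for (s in behavior_states()[-1]) instant[s, "copulating"] <- 1
  cfg$matrices[["L01"]][["Zlike"]] <- instant
  tr <- simulate_trial(cfg, "L01", "Zlike", seed = 5)
  expect_identical(tr$states, c("separate", "copulating"))
  expect_true(tr$copulated)

  # all-self-loop dynamics never absorb: censored at the recording limit
  stuck <- diag(8)
  dimnames(stuck) <- list(behavior_states(), behavior_states())
  cfg$matrices[["L02"]][["Zlike"]] <- stuck
  tr2 <- simulate_trial(cfg, "L02", "Zlike", seed = 6)
  expect_false(tr2$copulated)
  expect_equal(length(tr2$states), cfg$max_timepoints)
  expect_true(all(tr2$states == "separate"))

  bad <- instant
  bad["singing", ] <- 2 * bad["singing", ]
  cfg$matrices[["L01"]][["Zlike"]] <- bad
  expect_error(simulate_trial(cfg, "L01", "Zlike", seed = 1), "sum to 1")
})

test_that("plastic strains sing more with M-like females", {
  cfg <- default_config(seed = 31, n_male_strains = 12, trials_per_pair = 1)
  strain <- cfg$plastic_strains[1]
  set.seed(1)
  budgets <- sapply(cfg$female_strains, function(f) {
    reps <- lapply(1:40, function(i) {
      simulate_trial(cfg, strain, f, seed = 5000 + 13 * i)
    })
    s <- summarize_trials(reps, quiet = TRUE)
    mean(s$budget_singing, na.rm = TRUE)
  })
  expect_gt(budgets[["Mlike"]], budgets[["Zlike"]])

  # with the context shift switched off, every strain shares one matrix
  flat <- default_config(seed = 31, n_male_strains = 6, singing_shift = 0)
  expect_length(flat$plastic_strains, 0L)
  for (s in flat$male_strains) {
    expect_identical(flat$matrices[[s]][["Zlike"]],
                     flat$matrices[[s]][["Mlike"]])
  }
})

test_that("never-mate pairs fail and reluctant males often never initiate", {
  cfg <- default_config(seed = 41, trials_per_pair = 6)
  panel <- simulate_panel(cfg)
  nm <- cfg$never_mate
  for (i in seq_len(nrow(nm))) {
    hits <- Filter(function(tr) {
      tr$male_strain == nm$male_strain[i] && tr$female_strain == nm$female_strain[i]
    }, panel$trials)
    expect_true(all(!vapply(hits, function(tr) tr$copulated, logical(1))))
  }
  rel <- Filter(function(tr) {
    tr$male_strain == cfg$reluctant$male_strain[1] &&
      tr$female_strain == cfg$reluctant$female_strain[1]
  }, panel$trials)
  inits <- vapply(rel, function(tr) detect_initiation(tr), integer(1))
  expect_gt(sum(is.na(inits)) + sum(inits > 30, na.rm = TRUE), 0L)
})

test_that("simulated files parse cleanly through the io layer", {
  cfg <- default_config(seed = 51, n_male_strains = 3, trials_per_pair = 2)
  panel <- simulate_panel(cfg)
  dir <- tempfile("simdir_")
  expect_no_warning(panel_to_files(panel, dir))
  expect_no_warning({
    back <- read_event_log(file.path(dir, "events.csv"))
    chc <- normalize_chc(as.data.frame(
      readr::read_csv(file.path(dir, "chc.csv"), show_col_types = FALSE,
                      progress = FALSE)
    ))
  })
  expect_length(back, length(panel$trials))
  expect_true(all(chc$amount >= 0))
  truth <- jsonlite::fromJSON(file.path(dir, "truth.json"))
  expect_identical(truth$divergent_trait, "cVA")
})

test_that("latency matching hits the requested expected absorption time", {
  cfg <- default_config(seed = 61, n_male_strains = 2, trials_per_pair = 1)
  m <- cfg$matrices[["L01"]][["Zlike"]]
  for (target in c(12, 30, 90)) {
    scaled <- courtshipSelect:::.match_absorption(m, target)
    expect_equal(courtshipSelect:::.expected_absorption(scaled), target,
                 tolerance = 1e-2)
  }
})
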