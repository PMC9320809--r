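# Base one-step dynamics of a courting male, rows in behavior_states() order.
# Non-`separate` rows carry a baseline copulation hazard of 0.03 that the
# latency-matching step rescales per trial; `separate` cannot lead directly
# to copulation. The `singing` and `attempted_copulation` rows share their
# exit profile toward the other states so that reallocating occupancy
# between those two behaviors (the plasticity shift) leaves the remaining
# budgets nearly untouched.
.base_dynamics <- function() {
  m <- rbind(
    separate             = c(.52, .38, .04, .02, .02, .01, .01, .00),
    engaging             = c(.10, .35, .30, .06, .06, .05, .05, .03),
    singing              = c(.05, .15, .45, .05, .05, .05, .17, .03),
    singing2             = c(.05, .15, .15, .40, .05, .05, .12, .03),
    scissoring           = c(.05, .15, .10, .05, .45, .07, .10, .03),
    circling             = c(.05, .15, .10, .05, .07, .45, .10, .03),
    attempted_copulation = c(.05, .15, .25, .05, .05, .05, .37, .03),
    copulating           = c(0, 0, 0, 0, 0, 0, 0, 1)
  )
  colnames(m) <- behavior_states()
  m
}

.validate_matrix <- function(m) {
  k <- length(behavior_states())
  if (!is.matrix(m) || nrow(m) != k || ncol(m) != k) {
    stop("config error: transition matrix must be 8 x 8", call. = FALSE)
  }
  if (any(m < 0) || any(abs(rowSums(m) - 1) > 1e-12)) {
    stop("config error: transition-matrix rows must be non-negative and sum to 1",
         call. = FALSE)
  }
  cop <- match("copulating", behavior_states())
  if (m[cop, cop] != 1 || any(m[cop, -cop] != 0)) {
    stop("config error: 'copulating' row must be absorbing", call. = FALSE)
  }
  invisible(m)
}

# Multiply each strain's non-copulation transition mass by a seeded jitter
# so male strains differ (male-strain main effects), keeping per-row
# copulation hazard fixed.
.jitter_dynamics <- function(m, jitter_sd) {
  k <- nrow(m)
  cop <- k
  for (i in seq_len(k - 1L)) {
    w <- m[i, -cop] * exp(stats::rnorm(k - 1L, 0, jitter_sd))
    m[i, -cop] <- w / sum(w) * (1 - m[i, cop])
  }
  m
}

# Context shift for plastic strains in the M-like context: move a fraction of
# each row's attempted-copulation mass to singing, then inflate the remaining
# singing transition mass by (1 + frac), renormalizing the rest of the row
# against the fixed copulation hazard. Males sing markedly more and attempt
# less with M-like females; the reverse pattern appears with Z-like ones.
.apply_singing_shift <- function(m, frac) {
  sing <- match("singing", behavior_states())
  att <- match("attempted_copulation", behavior_states())
  cop <- match("copulating", behavior_states())
  for (i in seq_len(nrow(m) - 1L)) {
    if (i == cop) next
    delta <- frac * m[i, att]
    m[i, att] <- m[i, att] - delta
    m[i, sing] <- (m[i, sing] + delta) * (1 + frac)
    w <- m[i, -cop]
    m[i, -cop] <- w / sum(w) * (1 - m[i, cop])
  }
  m
}

#' Default simulation scenario
#'
#' A documented scenario mirroring the structure the analysis pipeline
#' assumes: `n_male_strains` male strains (default 12) crossed with two
#' female contexts (`"Zlike"`, a Southern-African-type female, and `"Mlike"`,
#' a cosmopolitan-type female), eight-state courtship chains sampled every
#' 10 s for at most 30 min with `copulating` absorbing. Ground truth built
#' in:
#' * a singing/attempted-copulation plasticity shift -- a fixed fraction of
#'   every row's attempted-copulation transition mass is reallocated to
#'   singing in the M-like context -- applied to the first 7/12 of strains;
#' * the CHC `cVA` under divergent selection (log-latency and mating-success
#'   effects of opposite sign in the two contexts) and `7-C25` beneficial
#'   only in the Z-like context; `n-C21` and `7-C23` are measured but
#'   selectively neutral;
#' * two strains that never mate with one female context each (asymmetric
#'   isolation), and one strain reluctant to initiate courtship with Z-like
#'   females (near-unbroken `separate` self-loop) to exercise the
#'   non-courting exclusion rules.
#'
#' Copulation latency is trait-linked and log-normal
#' (`log t = mu0 - sum(gamma * z) + N(0, sigma)`), mating success follows
#' `logit(p) = a + sum(b * z)`, and CHC profiles are log-normal around
#' seeded per-strain means with a 7-C23 reduction after exposure to
#' opposite-type females.
#'
#' @param seed Integer master seed; strain-level quantities (dynamics
#'   jitter, CHC strain means) are drawn here so the config is fully
#'   deterministic.
#' @param n_male_strains Number of male strains (default 12).
#' @param trials_per_pair Courtship trials per male-strain by female-context
#'   pair (default 5, the per-combination target of the study design).
#' @param singing_shift Fraction of attempted-copulation mass reallocated to
#'   singing in the M-like context for plastic strains (default 0.5).
#' @param gamma_divergent Magnitude of the divergent selection gradient on
#'   `cVA` in log-latency units per trait SD (default 0.3).
#' @return Object of class `sim_config`. Fields include `male_strains`,
#'   `female_strains`, `interval_s`, `max_timepoints`, `matrices` (per
#'   strain, per context), `gamma`, `b`, `success_intercept`, `mu0_log_s`,
#'   `sigma_log`, `chc` (compound-level parameters), `z_true`, and the truth
#'   record under `truth`.
#' @export
default_config <- function(seed = 1, n_male_strains = 12, trials_per_pair = 5,
                           singing_shift = 0.5, gamma_divergent = 0.3) {
  if (trials_per_pair < 1L) stop("config error: trials >= 1 required", call. = FALSE)
  set.seed(seed)
  males <- sprintf("L%02d", seq_len(n_male_strains))
  females <- c("Zlike", "Mlike")
  compounds <- c("cVA", "7-C25", "n-C21", "7-C23")
  # plasticity is consistent across male genotypes (parallel reaction norms);
  # a context-independent panel for negative controls is obtained by setting
  # singing_shift = 0
  plastic <- if (singing_shift > 0) males else character(0)
  # asymmetric-isolation pairs and the non-courting strain need a panel large
  # enough to spare them; small test panels simply omit those features
  never_mate <- if (n_male_strains >= 5L) {
    data.frame(
      male_strain = males[c(n_male_strains - 1L, n_male_strains)],
      female_strain = c("Mlike", "Zlike"),
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(male_strain = character(0), female_strain = character(0),
               stringsAsFactors = FALSE)
  }
  reluctant <- if (n_male_strains >= 5L) {
    data.frame(male_strain = males[n_male_strains - 2L],
               female_strain = "Zlike", stringsAsFactors = FALSE)
  } else {
    data.frame(male_strain = character(0), female_strain = character(0),
               stringsAsFactors = FALSE)
  }

  base <- .base_dynamics()
  matrices <- lapply(males, function(s) {
    m_z <- .jitter_dynamics(base, jitter_sd = 0.15)
    m_m <- if (s %in% plastic) .apply_singing_shift(m_z, singing_shift) else m_z
    list(Zlike = .validate_matrix(m_z), Mlike = .validate_matrix(m_m))
  })
  names(matrices) <- males

  # strain-level CHC log-means; measured abundances are log-normal around
  # them, and the selection models act on the standardized strain means
  chc_base_log <- c("cVA" = log(1.2), "7-C25" = log(0.8),
                    "n-C21" = log(0.5), "7-C23" = log(2.0))
  chc_strain_log <- sapply(compounds, function(cmp) {
    stats::rnorm(n_male_strains, chc_base_log[cmp], 0.5)
  })
  rownames(chc_strain_log) <- males
  z_true <- apply(chc_strain_log, 2L, standardize)
  rownames(z_true) <- males

  gamma <- cbind(
    Zlike = c(cVA = -gamma_divergent, `7-C25` = gamma_divergent,
              `n-C21` = 0, `7-C23` = 0),
    Mlike = c(cVA = gamma_divergent, `7-C25` = 0, `n-C21` = 0, `7-C23` = 0)
  )
  b <- cbind(
    Zlike = c(cVA = -0.8, `7-C25` = 0.8, `n-C21` = 0, `7-C23` = 0),
    Mlike = c(cVA = 0.8, `7-C25` = 0, `n-C21` = 0, `7-C23` = 0)
  )

  cfg <- structure(list(
    seed = seed,
    male_strains = males, female_strains = females,
    interval_s = 10, max_timepoints = 180,
    trials_per_pair = trials_per_pair,
    matrices = matrices,
    gamma = gamma, b = b, success_intercept = 1.5,
    mu0_log_s = log(300), sigma_log = 0.35,
    never_mate = never_mate, reluctant = reluctant,
    reluctant_escape = 0.005,
    plastic_strains = plastic, singing_shift = singing_shift,
    chc = list(compounds = compounds, strain_log = chc_strain_log,
               noise_sd = 0.2, exposure_shift = c("7-C23" = -0.3),
               is_compound = "n-C26", is_area_log = log(1000),
               is_area_sd = 0.1, individuals_per_cell = 3),
    z_true = z_true
  ), class = "sim_config")
  cfg$truth <- list(
    gamma = gamma, b = b, divergent_trait = "cVA",
    plastic_traits = c("singing", "attempted_copulation"),
    plastic_strains = plastic, never_mate = never_mate,
    reluctant = reluctant, z_true = z_true
  )
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> %d male strains x %s female contexts, %d trials/pair, seed %d\n",
    length(x$male_strains), paste(x$female_strains, collapse = "/"),
    x$trials_per_pair, x$seed
  ))
  invisible(x)
}

# Expected number of steps to absorption starting from `separate` when each
# row's copulation hazard is multiplied by `scale` (capped at 0.95) and the
# remaining mass of the row is renormalized.
.scaled_matrix <- function(m, scale) {
  k <- nrow(m)
  cop <- k
  for (i in seq_len(k - 1L)) {
    h0 <- m[i, cop]
    if (h0 == 0 || h0 >= 1) next  # no hazard, or already a sure transition
    h <- min(0.95, scale * h0)
    m[i, -cop] <- m[i, -cop] * (1 - h) / (1 - h0)
    m[i, cop] <- h
  }
  m
}

.expected_absorption <- function(m) {
  k <- nrow(m)
  q <- m[-k, -k, drop = FALSE]
  t <- tryCatch(solve(diag(k - 1L) - q, rep(1, k - 1L)),
                error = function(e) rep(Inf, k - 1L))
  unname(t[1])
}

# Choose the hazard scale whose expected absorption time (in steps) matches
# the trial's target latency; monotone in the scale, solved on the log scale.
.match_absorption <- function(m, target_steps) {
  f <- function(lc) .expected_absorption(.scaled_matrix(m, exp(lc))) - target_steps
  lo <- -8; hi <- log(0.95 / max(m[-nrow(m), ncol(m)]))
  if (f(hi) >= 0) return(.scaled_matrix(m, exp(hi)))
  if (f(lo) <= 0) return(.scaled_matrix(m, exp(lo)))
  r <- stats::uniroot(f, c(lo, hi), tol = 1e-4)
  .scaled_matrix(m, exp(r$root))
}

.pair_matrix <- function(config, male, female) {
  m <- config$matrices[[male]][[female]]
  rel <- config$reluctant
  if (!is.null(rel) &&
      any(rel$male_strain == male & rel$female_strain == female)) {
    esc <- config$reluctant_escape
    sep <- match("separate", behavior_states())
    row <- m[sep, ]
    row[-sep] <- row[-sep] / sum(row[-sep]) * esc
    row[sep] <- 1 - esc
    m[sep, ] <- row
  }
  m
}

.run_chain <- function(m, max_steps) {
  k <- nrow(m)
  cop <- k
  states <- integer(max_steps)
  cur <- match("separate", behavior_states())
  states[1L] <- cur
  for (t in 2:max_steps) {
    cur <- sample.int(k, 1L, prob = m[cur, ])
    states[t] <- cur
    if (cur == cop) return(states[1:t])
  }
  states
}

#' Simulate one courtship trial
#'
#' Draws mating success from the configured logistic model, then -- for
#' mating trials -- draws a trait-linked log-normal target latency and
#' rescales the pair's transition-matrix copulation hazards so the chain's
#' expected absorption time matches it (sequence structure and fitness
#' structure stay independently controllable). The chain starts in
#' `separate`, steps once per grid interval, and ends at absorption
#' (`copulating`) or at the recording limit; `copulated` is true iff the
#' chain absorbed.
#'
#' @param config A `sim_config` from [default_config()].
#' @param male,female Strain/context labels from the config.
#' @param trial_id Identifier for the resulting trial.
#' @param seed Optional integer seed for this trial's substream.
#' @return An [ethogram_trial()].
#' @export
simulate_trial <- function(config, male, female, trial_id = "T1", seed = NULL) {
  if (!male %in% config$male_strains || !female %in% config$female_strains) {
    stop("config error: unknown strain pair ", male, " x ", female, call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  m <- .validate_matrix(.pair_matrix(config, male, female))
  z <- config$z_true[male, ]
  p_mate <- stats::plogis(config$success_intercept +
                            sum(config$b[names(z), female] * z))
  nm <- config$never_mate
  if (!is.null(nm) && any(nm$male_strain == male & nm$female_strain == female)) {
    p_mate <- 0
  }
  mate <- stats::runif(1) < p_mate
  if (mate) {
    target_s <- exp(config$mu0_log_s - sum(config$gamma[names(z), female] * z) +
                      stats::rnorm(1, 0, config$sigma_log))
    target_steps <- min(max(target_s / config$interval_s, 4),
                        0.8 * config$max_timepoints)
    m_run <- .match_absorption(m, target_steps)
  } else {
    cop <- ncol(m)
    m_run <- m
    for (i in seq_len(nrow(m) - 1L)) {
      if (m_run[i, cop] > 0) {
        m_run[i, -cop] <- m_run[i, -cop] / (1 - m_run[i, cop])
        m_run[i, cop] <- 0
      }
    }
  }
  idx <- .run_chain(m_run, config$max_timepoints)
  ethogram_trial(
    trial_id = trial_id,
    states = behavior_states()[idx],
    male_strain = male, female_strain = female,
    interval_s = config$interval_s,
    max_span_s = config$max_timepoints * config$interval_s
  )
}

#' Simulate a full factorial courtship and CHC panel
#'
#' Runs [simulate_trial()] for every male-strain by female-context pair with
#' the configured number of trials, generates per-individual CHC peak tables
#' (areas plus the hexacosane internal standard, ready for
#' [normalize_chc()]), and returns the ground-truth record alongside the
#' data. Fully reproducible: per-trial seeds are derived deterministically
#' from the master seed by a counter, so the same config yields identical
#' panels.
#'
#' @param config A `sim_config` from [default_config()].
#' @return List with `trials` (an `ethogram_set`), `chc_peaks` (long peak
#'   table with `individual`, `strain`, `sex`, `treatment`, `compound`,
#'   `area`) and `truth` (the config's ground-truth record).
#' @export
simulate_panel <- function(config) {
  n_trials <- length(config$male_strains) * length(config$female_strains) *
    config$trials_per_pair
  # per-trial substreams: seeds drawn once from the master stream, indexed by
  # trial counter (arithmetically spaced seeds would give correlated chains)
  set.seed(config$seed)
  trial_seeds <- sample.int(.Machine$integer.max - 1L, n_trials)
  counter <- 0L
  trials <- list()
  for (male in config$male_strains) {
    for (female in config$female_strains) {
      for (r in seq_len(config$trials_per_pair)) {
        counter <- counter + 1L
        trials[[counter]] <- simulate_trial(
          config, male, female,
          trial_id = sprintf("%s_%s_%03d", male, female, r),
          seed = trial_seeds[counter]
        )
      }
    }
  }
  set.seed((config$seed %% 100000L) * 20011L + 1000003L)
  chc <- config$chc
  rows <- list()
  for (male in config$male_strains) {
    for (treat in c("virgin", "exposed_same", "exposed_opposite")) {
      for (ind in seq_len(chc$individuals_per_cell)) {
        id <- sprintf("%s_%s_%d", male, treat, ind)
        is_area <- exp(stats::rnorm(1, chc$is_area_log, chc$is_area_sd))
        amounts <- exp(chc$strain_log[male, ] +
                         stats::rnorm(length(chc$compounds), 0, chc$noise_sd))
        if (treat == "exposed_opposite") {
          shift <- chc$exposure_shift
          amounts[names(shift)] <- amounts[names(shift)] * exp(shift)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          individual = id, strain = male, sex = "M", treatment = treat,
          compound = c(chc$compounds, chc$is_compound),
          area = c(amounts * is_area, is_area),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  chc_peaks <- do.call(rbind, rows)
  rownames(chc_peaks) <- NULL
  list(trials = as_ethogram_set(trials), chc_peaks = chc_peaks,
       truth = config$truth)
}

#' Write a simulated panel to plain-text files
#'
#' Emits `events.csv` (gridded event log), `chc.csv` (peak table) and
#' `truth.json` (ground-truth record) into a directory, in the formats the
#' `io` functions read back.
#'
#' @param panel Output of [simulate_panel()].
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
panel_to_files <- function(panel, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_event_log(panel$trials, file.path(dir, "events.csv"))
  readr::write_csv(panel$chc_peaks, file.path(dir, "chc.csv"), progress = FALSE)
  truth <- panel$truth
  truth$never_mate <- as.list(truth$never_mate)
  truth$reluctant <- as.list(truth$reluctant)
  jsonlite::write_json(truth, file.path(dir, "truth.json"), digits = NA,
                       auto_unbox = TRUE, matrix = "rowmajor")
  invisible(dir)
}
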