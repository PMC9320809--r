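#' Detect courtship initiation in a trial
#'
#' Two operational rules are supported: `"first"`, the first timepoint scored
#' as any non-`separate` behavior; and `"consecutive3"` (the default used
#' throughout the package), the first element of the earliest run of at least
#' three consecutive non-`separate` states. The stricter rule guards against
#' brief early contacts that are broken off long before courtship proper; for
#' most trials the two rules agree closely and [compare_initiation_methods()]
#' reports the discrepancy distribution.
#'
#' @param trial An [ethogram_trial()].
#' @param method `"consecutive3"` (default) or `"first"`.
#' @return 1-based grid index of initiation, or `NA_integer_` if the trial
#'   never qualifies (absence of initiation is a legal result, not an error).
#' @export
#' @examples
#' tr <- ethogram_trial("T1", c("separate", "separate", "engaging", "separate",
#'                              "singing", "singing", "singing"))
#' detect_initiation(tr, "first")        # 3
#' detect_initiation(tr, "consecutive3") # 5
detect_initiation <- function(trial, method = c("consecutive3", "first")) {
  method <- match.arg(method)
  non_sep <- trial$states != "separate"
  if (method == "first") {
    idx <- which(non_sep)[1]
    return(if (is.na(idx)) NA_integer_ else as.integer(idx))
  }
  r <- rle(non_sep)
  starts <- cumsum(c(1L, r$lengths))[seq_along(r$lengths)]
  hit <- which(r$values & r$lengths >= 3L)[1]
  if (is.na(hit)) NA_integer_ else as.integer(starts[hit])
}

.empty_budget <- function() {
  setNames(rep(NA_real_, length(active_states())), active_states())
}

#' Summarize one courtship trial
#'
#' Computes initiation, copulation latency and the time budget of a single
#' trial. Latency is `(copulation index - initiation index) * interval_s`.
#' The budget window runs from initiation up to but excluding `copulating`;
#' for censored (non-copulating) trials it runs to the end of the recording
#' unless `censored_window_s` (typically from [impute_censored_window()])
#' caps it. Budget fractions are counts of timepoints per behavior divided by
#' the total number of timepoints in the window, so the six active-state
#' fractions plus the post-initiation `separate` fraction sum to 1.
#'
#' @param trial An [ethogram_trial()].
#' @param initiation_method Passed to [detect_initiation()].
#' @param censored_window_s Optional scoring window (seconds) for censored
#'   trials, e.g. the group's mean successful latency.
#' @return A one-row data frame with columns `trial_id`, `male_strain`,
#'   `female_strain`, `copulated`, `censored`, `initiation_index`,
#'   `initiation_time_s`, `copulation_latency_s`, `latency_imputed`,
#'   `n_timepoints`, `separate_fraction` and one `budget_<state>` column per
#'   active state.
#' @export
summarize_trial <- function(trial, initiation_method = c("consecutive3", "first"),
                            censored_window_s = NULL) {
  initiation_method <- match.arg(initiation_method)
  if (trial$copulated && trial$states[length(trial$states)] != "copulating") {
    stop("validation error: copulated trial without terminal 'copulating' state",
         call. = FALSE)
  }
  init <- detect_initiation(trial, initiation_method)
  base <- data.frame(
    trial_id = trial$trial_id,
    male_strain = trial$male_strain,
    female_strain = trial$female_strain,
    copulated = trial$copulated,
    censored = !trial$copulated,
    initiation_index = init,
    initiation_time_s = (init - 1L) * trial$interval_s,
    copulation_latency_s = NA_real_,
    latency_imputed = FALSE,
    n_timepoints = 0L,
    separate_fraction = NA_real_,
    stringsAsFactors = FALSE
  )
  budget <- .empty_budget()
  if (!is.na(init)) {
    if (trial$copulated) {
      cop_idx <- length(trial$states)
      base$copulation_latency_s <- (cop_idx - init) * trial$interval_s
      window <- trial$states[init:(cop_idx - 1L)]
    } else {
      end <- length(trial$states)
      if (!is.null(censored_window_s)) {
        w_tp <- max(1L, round(censored_window_s / trial$interval_s))
        end <- min(end, init + w_tp - 1L)
        base$copulation_latency_s <- censored_window_s
        base$latency_imputed <- TRUE
      }
      window <- trial$states[init:end]
    }
    n <- length(window)
    base$n_timepoints <- n
    counts <- table(factor(window, levels = behavior_states()))
    budget <- as.numeric(counts[active_states()]) / n
    names(budget) <- active_states()
    base$separate_fraction <- as.numeric(counts[["separate"]]) / n
  }
  budget_df <- as.data.frame(as.list(budget))
  names(budget_df) <- paste0("budget_", active_states())
  cbind(base, budget_df)
}

#' Compute the censored-trial scoring window for one genotype pair
#'
#' Unsuccessful trials are quantified for a time equal to the average
#' copulation latency of the successful trials for the same male-strain by
#' female-strain combination, rounded to the grid.
#'
#' @param trials List of [ethogram_trial()] objects (any strains; filtered).
#' @param male_strain,female_strain The genotype combination.
#' @param initiation_method Passed to [detect_initiation()].
#' @return Window length in seconds (a multiple of the grid interval).
#'   Errors with "no reference latency" if the group has no successful trial;
#'   callers must then fall back to the full recording.
#' @export
impute_censored_window <- function(trials, male_strain, female_strain,
                                   initiation_method = c("consecutive3", "first")) {
  initiation_method <- match.arg(initiation_method)
  grp <- Filter(function(tr) {
    tr$male_strain == male_strain && tr$female_strain == female_strain && tr$copulated
  }, trials)
  if (length(grp) == 0L) {
    stop(sprintf("no reference latency: zero successful trials for %s x %s",
                 male_strain, female_strain), call. = FALSE)
  }
  lat <- vapply(grp, function(tr) {
    init <- detect_initiation(tr, initiation_method)
    if (is.na(init)) return(NA_real_)
    (length(tr$states) - init) * tr$interval_s
  }, numeric(1))
  lat <- lat[!is.na(lat)]
  if (length(lat) == 0L) {
    stop(sprintf("no reference latency: successful trials for %s x %s never initiated",
                 male_strain, female_strain), call. = FALSE)
  }
  interval <- grp[[1]]$interval_s
  round(mean(lat) / interval) * interval
}

#' Summarize a set of trials
#'
#' Applies [summarize_trial()] to every trial. With `impute = TRUE` (default)
#' each censored trial's scoring window is set to the mean successful latency
#' of its genotype combination via [impute_censored_window()]; combinations
#' with no successful trial fall back to the full recording (with a warning
#' unless `quiet = TRUE`).
#'
#' @param trials An `ethogram_set` or list of [ethogram_trial()] objects.
#' @param initiation_method Passed to [detect_initiation()].
#' @param impute Whether to impute censored scoring windows.
#' @param quiet Suppress fallback warnings.
#' @return Data frame with one row per trial (see [summarize_trial()]).
#' @export
summarize_trials <- function(trials, initiation_method = c("consecutive3", "first"),
                             impute = TRUE, quiet = FALSE) {
  initiation_method <- match.arg(initiation_method)
  if (length(trials) == 0L) stop("validation error: empty trial set", call. = FALSE)
  windows <- new.env(parent = emptyenv())
  get_window <- function(tr) {
    key <- paste(tr$male_strain, tr$female_strain, sep = "\r")
    if (!is.null(windows[[key]])) return(windows[[key]])
    w <- tryCatch(
      impute_censored_window(trials, tr$male_strain, tr$female_strain,
                             initiation_method),
      error = function(e) {
        if (!quiet) {
          warning(sprintf("%s x %s: %s; scoring censored trials over the full recording",
                          tr$male_strain, tr$female_strain, conditionMessage(e)),
                  call. = FALSE)
        }
        NA_real_
      }
    )
    windows[[key]] <- w
    w
  }
  rows <- lapply(trials, function(tr) {
    w <- if (impute && !tr$copulated) get_window(tr) else NA_real_
    summarize_trial(tr, initiation_method,
                    censored_window_s = if (is.na(w)) NULL else w)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare the two courtship-initiation rules
#'
#' Diagnostic for the choice of initiation rule: per-trial absolute
#' discrepancy, in seconds, between the `"first"` and `"consecutive3"`
#' initiation times, over trials where both rules fire. The stricter rule can
#' never fire earlier, so the mean and maximum discrepancy quantify how often
#' an early isolated contact would have been mistaken for initiation.
#'
#' @param trials List of [ethogram_trial()] objects.
#' @return List with `n`, `mean_s`, `max_s` and the per-trial `discrepancy_s`.
#' @export
compare_initiation_methods <- function(trials) {
  d <- vapply(trials, function(tr) {
    a <- detect_initiation(tr, "first")
    b <- detect_initiation(tr, "consecutive3")
    if (is.na(a) || is.na(b)) return(NA_real_)
    (b - a) * tr$interval_s
  }, numeric(1))
  d <- d[!is.na(d)]
  list(n = length(d), mean_s = mean(d), max_s = max(d), discrepancy_s = d)
}

#' Mating index combining latency and mating success
#'
#' A fitness proxy usable when some genotype combinations never mate within
#' the recording window: censored latencies are set to the maximum observed
#' time (an underestimate of the true latency) and the mean latency is then
#' weighted by the proportion of trials that mated, i.e.
#' `index = mean(latencies with censored -> max_observed) / (successes/trials)`.
#' Larger values indicate worse mating performance. With zero successes the
#' index is infinite and flagged.
#'
#' @param latencies Numeric vector of per-trial latencies in seconds;
#'   `NA` marks censored trials.
#' @param successes,trials Counts of successful and total trials.
#' @param max_observed Maximum latency observed (seconds) used to fill
#'   censored trials.
#' @return List with `index`, `prop_mated` and `all_failed` flag.
#' @export
#' @examples
#' mating_index(c(100, NA), successes = 1, trials = 2, max_observed = 600)$index # 700
mating_index <- function(latencies, successes, trials, max_observed) {
  if (trials < 1L) stop("validation error: trials must be >= 1", call. = FALSE)
  if (any(latencies < 0, na.rm = TRUE)) {
    stop("validation error: negative latency", call. = FALSE)
  }
  filled <- ifelse(is.na(latencies), max_observed, latencies)
  prop <- successes / trials
  if (prop == 0) {
    return(list(index = Inf, prop_mated = 0, all_failed = TRUE))
  }
  list(index = mean(filled) / prop, prop_mated = prop, all_failed = FALSE)
}

#' Progeny-latency isolation assay: survival comparison vs a reference male
#'
#' For genotype combinations that fail to copulate on video, long-term
#' isolation is assayed as the number of days until progeny first appear over
#' a 16-day window, right-censored at day 16. Each test male strain's
#' Kaplan-Meier curve is compared with the reference strain's by a log-rank
#' test ([survival::survdiff()]).
#'
#' @param progeny Data frame with columns `male_strain`, `days` (days to
#'   first progeny) and `censored` (logical; `TRUE` if no progeny were seen
#'   by `horizon`). Days must lie in `[1, horizon]`.
#' @param reference_male Strain used as the comparison baseline.
#' @param test_males Strains to compare (default: all non-reference strains).
#' @param horizon Censoring horizon in days (default 16).
#' @return Data frame with one row per test strain: `male_strain`, `n_ref`,
#'   `n_test`, `chisq`, `df`, `p`.
#' @export
progeny_latency_test <- function(progeny, reference_male, test_males = NULL,
                                 horizon = 16) {
  for (col in c("male_strain", "days", "censored")) .find_column(progeny, col)
  if (any(progeny$days < 1 | progeny$days > horizon)) {
    stop(sprintf("validation error: days must lie in [1, %g]", horizon), call. = FALSE)
  }
  if (is.null(test_males)) {
    test_males <- setdiff(unique(progeny$male_strain), reference_male)
  }
  ref <- progeny[progeny$male_strain == reference_male, , drop = FALSE]
  if (nrow(ref) < 2L) {
    stop(sprintf("validation error: reference strain '%s' has fewer than 2 trials",
                 reference_male), call. = FALSE)
  }
  rows <- lapply(test_males, function(s) {
    tst <- progeny[progeny$male_strain == s, , drop = FALSE]
    if (nrow(tst) < 2L) {
      stop(sprintf("validation error: strain '%s' has fewer than 2 trials", s),
           call. = FALSE)
    }
    both <- rbind(ref, tst)
    if (all(both$censored)) {
      stop(sprintf("degenerate comparison: all observations censored for %s vs %s",
                   reference_male, s), call. = FALSE)
    }
    grp <- factor(both$male_strain, levels = c(reference_male, s))
    fit <- survival::survdiff(
      survival::Surv(both$days, !both$censored) ~ grp
    )
    data.frame(
      male_strain = s, n_ref = nrow(ref), n_test = nrow(tst),
      chisq = unname(fit$chisq), df = 1L,
      p = stats::pchisq(fit$chisq, df = 1, lower.tail = FALSE),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
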