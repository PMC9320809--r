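#' Build a per-male-strain trait table for one female context
#'
#' Assembles the unit-of-analysis table for selection-gradient estimation:
#' one row per male strain courting the given female strain, with strain
#' means of the behavioral time-budget traits (over trials where the male
#' initiated courtship), strain means of CHC abundances (virgin males by
#' default), mating successes and trials, and the mean copulation latency of
#' successful trials. Strain means are used because CHCs are measured on
#' separate individuals from the courtship trials and because successful-
#' trial counts differ between combinations. Trials where the male never
#' initiated courtship (no run of three consecutive non-`separate` states)
#' carry no behavioral trait information and are excluded from the budget
#' means but still count as failed trials for mating success.
#'
#' @param summaries Per-trial summary data frame from [summarize_trials()].
#' @param female_strain Which female context to extract.
#' @param chc Optional long-form CHC profiles from [normalize_chc()]; male
#'   (`sex == "M"`) rows with `treatment == chc_treatment` are averaged per
#'   strain and compound.
#' @param chc_treatment CHC treatment to use (default `"virgin"`).
#' @return Data frame with one row per male strain: `male_strain`,
#'   `successes`, `trials`, `mean_latency_s` (NA when no successes),
#'   `n_courting`, one column per active behavior (budget means) and one per
#'   CHC compound.
#' @export
build_trait_table <- function(summaries, female_strain, chc = NULL,
                              chc_treatment = "virgin") {
  s <- summaries[summaries$female_strain == female_strain, , drop = FALSE]
  if (nrow(s) == 0L) {
    stop("validation error: no trials for female strain ", female_strain,
         call. = FALSE)
  }
  budget_cols <- paste0("budget_", active_states())
  rows <- lapply(split(s, s$male_strain), function(d) {
    courting <- d[!is.na(d$initiation_index), , drop = FALSE]
    succ <- d[d$copulated, , drop = FALSE]
    out <- data.frame(
      male_strain = d$male_strain[1],
      female_strain = female_strain,
      successes = nrow(succ),
      trials = nrow(d),
      mean_latency_s = if (any(!is.na(succ$copulation_latency_s))) {
        # copulated trials that never met the initiation rule carry no latency
        mean(succ$copulation_latency_s, na.rm = TRUE)
      } else {
        NA_real_
      },
      n_courting = nrow(courting),
      stringsAsFactors = FALSE
    )
    budgets <- if (nrow(courting) > 0) {
      colMeans(courting[budget_cols])
    } else {
      setNames(rep(NA_real_, length(budget_cols)), budget_cols)
    }
    cbind(out, as.data.frame(as.list(budgets)))
  })
  tt <- do.call(rbind, rows)
  rownames(tt) <- NULL
  names(tt) <- sub("^budget_", "", names(tt))
  if (!is.null(chc)) {
    males <- chc[chc$sex == "M" & chc$treatment == chc_treatment, , drop = FALSE]
    if (nrow(males) == 0L) {
      stop("validation error: no male CHC profiles with treatment ",
           chc_treatment, call. = FALSE)
    }
    agg <- aggregate(amount ~ strain + compound, data = males, FUN = mean)
    for (cmp in unique(agg$compound)) {
      sub <- agg[agg$compound == cmp, , drop = FALSE]
      tt[[cmp]] <- sub$amount[match(tt$male_strain, sub$strain)]
    }
  }
  tt
}

#' Estimate selection gradients and success regressions for one female strain
#'
#' For each requested trait: standardizes the per-strain trait means, builds
#' relative fitness from successful-trial latencies under the chosen
#' convention, fits the median-regression selection gradient with a bootstrap
#' CI, and fits the binomial regression of mating success. Strains with zero
#' successful matings carry no latency and are excluded from the gradient
#' regression (they remain in the binomial regression, and under the
#' `"mating_index"` convention they re-enter the gradient path with the
#' maximum observed latency weighted by success proportion).
#'
#' @param trait_table Output of [build_trait_table()].
#' @param traits Character vector of trait columns to analyse.
#' @param fitness `"inverse_latency"` (default), `"latency"` or
#'   `"mating_index"`.
#' @param bootstrap,seed,level Passed to [median_regression()].
#' @return Data frame of class `selection_result`: one row per trait with
#'   `trait`, `female_strain` (if unique in input), `n`, `gradient`,
#'   `ci_low`, `ci_high`, `gradient_sig` (CI excludes zero), `binom_coef`,
#'   `binom_low`, `binom_high`, `binom_sig`, `separated`.
#' @export
selection_analysis <- function(trait_table, traits,
                               fitness = c("inverse_latency", "latency",
                                           "mating_index"),
                               bootstrap = 2000, seed = 1, level = 0.95) {
  fitness <- match.arg(fitness)
  missing_traits <- setdiff(traits, names(trait_table))
  if (length(missing_traits) > 0L) {
    stop("format error: trait table lacks column(s) ",
         paste(missing_traits, collapse = ", "), call. = FALSE)
  }
  if (fitness == "mating_index") {
    keep <- trait_table
    max_obs <- max(keep$mean_latency_s, na.rm = TRUE)
    fit_in <- vapply(seq_len(nrow(keep)), function(i) {
      mating_index(
        latencies = if (is.na(keep$mean_latency_s[i])) NA_real_
                    else keep$mean_latency_s[i],
        successes = keep$successes[i], trials = keep$trials[i],
        max_observed = max_obs
      )$index
    }, numeric(1))
    w_all <- relative_fitness(fit_in, "mating_index")
  } else {
    keep <- trait_table[trait_table$successes > 0 &
                          !is.na(trait_table$mean_latency_s), , drop = FALSE]
    if (nrow(keep) < 3L) {
      stop("validation error: fewer than 3 strains with successful matings",
           call. = FALSE)
    }
    w_all <- relative_fitness(keep$mean_latency_s, fitness)
  }
  rows <- lapply(seq_along(traits), function(ti) {
    tr <- traits[ti]
    ok <- !is.na(keep[[tr]])
    z <- standardize(keep[[tr]][ok], trait = tr)
    w <- w_all[ok]
    grad <- median_regression(z, w, bootstrap = bootstrap,
                              seed = seed + ti, level = level)
    ok_all <- !is.na(trait_table[[tr]])
    zb <- standardize(trait_table[[tr]][ok_all], trait = tr)
    bin <- binomial_success_regression(zb, trait_table$successes[ok_all],
                                       trait_table$trials[ok_all], level = level)
    data.frame(
      trait = tr, n = grad$n,
      gradient = grad$gradient, ci_low = grad$ci[1], ci_high = grad$ci[2],
      gradient_sig = grad$ci[1] > 0 || grad$ci[2] < 0,
      binom_coef = bin$coefficient, binom_low = bin$ci[1],
      binom_high = bin$ci[2],
      binom_sig = !bin$separated && (bin$ci[1] > 0 || bin$ci[2] < 0),
      separated = bin$separated,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  fem <- unique(trait_table$female_strain)
  if (length(fem) == 0L) fem <- NA_character_
  out <- cbind(female_strain = if (length(fem) == 1L) fem else NA_character_,
               out, stringsAsFactors = FALSE)
  class(out) <- c("selection_result", "data.frame")
  out
}
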