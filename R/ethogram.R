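#' Courtship behavior states
#'
#' The eight admissible state labels of the courtship ethogram, in canonical
#' order: `separate`, `engaging`, `singing`, `singing2`, `scissoring`,
#' `circling`, `attempted_copulation` and `copulating`. `copulating` is
#' absorbing: within a trial no state may follow it. All ethogram-facing
#' functions validate against this set.
#'
#' @return Character vector of the eight state labels.
#' @export
#' @examples
#' behavior_states()
behavior_states <- function() {
  c("separate", "engaging", "singing", "singing2", "scissoring",
    "circling", "attempted_copulation", "copulating")
}

#' Active (courting, non-terminal) behavior states
#'
#' All states except `separate` and `copulating`; these are the behaviors
#' whose time-budget fractions are analysed as male courtship traits.
#'
#' @return Character vector of six state labels.
#' @export
active_states <- function() {
  setdiff(behavior_states(), c("separate", "copulating"))
}

.check_state_labels <- function(labels, where = "input") {
  bad <- which(!labels %in% behavior_states())
  if (length(bad) > 0L) {
    stop(sprintf(
      "validation error: unknown behavior label(s) in %s: %s (rows %s)",
      where,
      paste(unique(labels[bad]), collapse = ", "),
      paste(utils::head(bad, 10L), collapse = ", ")
    ), call. = FALSE)
  }
  invisible(labels)
}

#' Construct a single courtship trial (ethogram on a fixed grid)
#'
#' One courtship bout: an ordered sequence of behavior states sampled on a
#' fixed grid (default every 10 s, 30 min maximum span), plus trial metadata.
#' The trial is validated on construction: states must be drawn from
#' [behavior_states()], `copulating` may occur only once and only as the final
#' element, and the sequence must fit in the recording span.
#'
#' @param trial_id Character scalar identifying the trial.
#' @param states Character vector of states, one per grid point.
#' @param male_strain,female_strain Strain labels (metadata).
#' @param interval_s Grid interval in seconds (default 10).
#' @param block_id Optional recording-block label.
#' @param max_span_s Maximum recording span in seconds (default 1800 = 30 min).
#' @return An object of class `ethogram_trial`.
#' @export
#' @examples
#' ethogram_trial("T1", c("separate", "singing", "copulating"), "Z53", "DGRP-882")
ethogram_trial <- function(trial_id, states, male_strain = NA_character_,
                           female_strain = NA_character_, interval_s = 10,
                           block_id = NULL, max_span_s = 1800) {
  states <- as.character(states)
  if (length(states) == 0L) {
    stop("validation error: trial '", trial_id, "' has no states", call. = FALSE)
  }
  .check_state_labels(states, where = paste0("trial '", trial_id, "'"))
  if (length(states) * interval_s > max_span_s + interval_s) {
    stop(sprintf(
      "validation error: trial '%s' spans %d x %g s, exceeding the %g s recording span",
      trial_id, length(states), interval_s, max_span_s
    ), call. = FALSE)
  }
  cop <- which(states == "copulating")
  if (length(cop) > 1L || (length(cop) == 1L && cop != length(states))) {
    stop(sprintf(
      "validation error: trial '%s' has states after 'copulating' (copulating is terminal)",
      trial_id
    ), call. = FALSE)
  }
  structure(
    list(
      trial_id = as.character(trial_id),
      male_strain = as.character(male_strain),
      female_strain = as.character(female_strain),
      interval_s = interval_s,
      states = states,
      copulated = length(cop) == 1L,
      block_id = if (is.null(block_id)) NA_character_ else as.character(block_id)
    ),
    class = "ethogram_trial"
  )
}

#' @export
print.ethogram_trial <- function(x, ...) {
  cat(sprintf(
    "<ethogram_trial> %s  [%s male x %s female]  %d timepoints @ %gs, %s\n",
    x$trial_id, x$male_strain, x$female_strain, length(x$states),
    x$interval_s, if (x$copulated) "copulated" else "censored"
  ))
  invisible(x)
}

#' @export
print.ethogram_set <- function(x, ...) {
  n_cop <- sum(vapply(x, function(t) t$copulated, logical(1)))
  cat(sprintf("<ethogram_set> %d trials (%d copulated)\n", length(x), n_cop))
  invisible(x)
}

as_ethogram_set <- function(trials) {
  structure(trials, class = "ethogram_set")
}
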