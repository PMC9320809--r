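#' Count one-step behavioral transitions, pooled over trials
#'
#' Builds the k-by-k transition count matrix for a group of trials (normally
#' one male-strain by female-strain combination): `counts[i, j]` is the number
#' of adjacent state pairs `(s_t = i, s_{t+1} = j)` summed over trials.
#' Transitions never cross trial boundaries, and the `copulating` row is all
#' zeros by construction (absorbing). Counting is additive over disjoint
#' trial sets.
#'
#' @param trials Non-empty list of [ethogram_trial()] objects.
#' @param check_group Require all trials to share one male-strain by
#'   female-strain pair (default TRUE).
#' @return Integer matrix of class `transition_counts` with state dimnames
#'   and attributes `male_strain`, `female_strain`, `n_trials`.
#' @export
count_transitions <- function(trials, check_group = TRUE) {
  if (length(trials) == 0L) {
    stop("validation error: empty trial set", call. = FALSE)
  }
  if (check_group) {
    ms <- unique(vapply(trials, function(tr) tr$male_strain, character(1)))
    fs <- unique(vapply(trials, function(tr) tr$female_strain, character(1)))
    if (length(ms) > 1L || length(fs) > 1L) {
      stop("validation error: trials span several strain pairs; pass one group ",
           "or set check_group = FALSE", call. = FALSE)
    }
  } else {
    ms <- fs <- NA_character_
  }
  k <- length(behavior_states())
  counts <- matrix(0L, k, k, dimnames = list(behavior_states(), behavior_states()))
  for (tr in trials) {
    n <- length(tr$states)
    if (n < 2L) next
    from <- match(tr$states[-n], behavior_states())
    to <- match(tr$states[-1L], behavior_states())
    for (i in seq_along(from)) {
      counts[from[i], to[i]] <- counts[from[i], to[i]] + 1L
    }
  }
  structure(counts, class = c("transition_counts", "matrix"),
            male_strain = ms[1], female_strain = fs[1],
            n_trials = length(trials))
}

#' Estimate a row-stochastic transition matrix from counts
#'
#' Maximum-likelihood row normalization with optional additive (pseudo-count)
#' smoothing: `p[i, j] = (counts[i, j] + alpha) / (rowsum_i + k * alpha)`.
#' The absorbing `copulating` row is the identity on `copulating`. An
#' unsmoothed all-zero row has no MLE; it falls back to the uniform
#' distribution over k states and is flagged in the `"flagged_rows"`
#' attribute. Every estimated row sums to 1 within 1e-12.
#'
#' @param counts A `transition_counts` matrix (or plain k-by-k count matrix).
#' @param smoothing Pseudo-count alpha >= 0 (default 0: raw MLE, the form
#'   used for inference; 0.5 is recommended for reporting or simulation
#'   matrices).
#' @return Row-stochastic numeric matrix with attribute `flagged_rows`.
#' @export
estimate_matrix <- function(counts, smoothing = 0) {
  counts <- unclass(counts)
  k <- nrow(counts)
  states <- rownames(counts)
  if (is.null(states)) states <- as.character(seq_len(k))
  p <- matrix(0, k, k, dimnames = list(states, states))
  flagged <- character(0)
  absorbing <- states == "copulating"
  for (i in seq_len(k)) {
    if (absorbing[i]) {
      p[i, i] <- 1
      next
    }
    tot <- sum(counts[i, ]) + k * smoothing
    if (tot > 0) {
      p[i, ] <- (counts[i, ] + smoothing) / tot
    } else {
      p[i, ] <- 1 / k
      flagged <- c(flagged, states[i])
    }
  }
  structure(p, flagged_rows = flagged)
}

#' Test homogeneity of transition matrices across groups
#'
#' Likelihood-ratio (G-squared) test of whether two or more groups of
#' courtship sequences share a single transition matrix, the Markov-chain
#' analogue of a chi-square homogeneity test: conditional on row (source
#' state) totals, each source state contributes an independent groups-by-
#' destinations contingency comparison of the per-group transition
#' distributions against the pooled one.
#'
#' The statistic is
#' `G2 = 2 * sum_g sum_ij n_gij * log((n_gij / n_gi.) / (n_+ij / n_+i.))`
#' over cells with `n_gij > 0`. Degrees of freedom account for sparse
#' support: each source row i contributes `(G_i - 1) * (k_i - 1)` where `G_i`
#' counts groups with nonzero row-i total and `k_i` counts destination states
#' with nonzero pooled row-i count. Rows or columns with zero pooled support
#' (e.g. the absorbing `copulating` row) drop out.
#'
#' Eight-state ethograms at realistic trial counts leave many destination
#' cells with tiny expected counts, where the plain G2 statistic is markedly
#' anti-conservative. By default each source-state table's contribution is
#' therefore divided by its Williams (1976) small-sample factor
#' `q = 1 + (N * sum(1/n_g.) - 1)(N * sum(1/n_.j) - 1) / (6 N (G_i - 1)(k_i - 1))`,
#' which restores near-nominal type-I error at a few hundred transitions per
#' group; `correct = FALSE` gives the uncorrected statistic, and
#' `method = "pearson"` the Pearson chi-square variant (never corrected).
#'
#' @param ... Two or more `transition_counts` matrices over the same state
#'   set, or a single list of them.
#' @param method `"lr"` (likelihood ratio, default) or `"pearson"`.
#' @param correct Apply the Williams correction to the likelihood-ratio
#'   statistic (default TRUE; ignored for Pearson).
#' @return Object of class `homogeneity_test`: list with `statistic`, `df`,
#'   `p.value`, `method`, `corrected` and `groups`.
#' @export
homogeneity_test <- function(..., method = c("lr", "pearson"), correct = TRUE) {
  method <- match.arg(method)
  groups <- list(...)
  if (length(groups) == 1L && is.list(groups[[1]]) && !is.matrix(groups[[1]])) {
    groups <- groups[[1]]
  }
  if (length(groups) < 2L) {
    stop("validation error: homogeneity test needs at least 2 groups", call. = FALSE)
  }
  mats <- lapply(groups, function(g) {
    m <- unclass(g)
    storage.mode(m) <- "double"
    m
  })
  k <- nrow(mats[[1]])
  if (!all(vapply(mats, function(m) nrow(m) == k && ncol(m) == k, logical(1)))) {
    stop("validation error: groups must share one state set", call. = FALSE)
  }
  pooled <- Reduce(`+`, mats)
  if (sum(pooled) == 0) {
    stop("degenerate test: no transitions in any group", call. = FALSE)
  }
  stat <- 0
  df <- 0L
  for (i in seq_len(k)) {
    rows <- do.call(rbind, lapply(mats, function(m) m[i, ]))
    rows <- rows[rowSums(rows) > 0, , drop = FALSE]
    if (nrow(rows) < 2L) next
    cols <- colSums(rows) > 0
    tab <- rows[, cols, drop = FALSE]
    if (ncol(tab) < 2L) next
    N <- sum(tab)
    rs <- rowSums(tab)
    cs <- colSums(tab)
    e <- outer(rs, cs) / N
    df_i <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
    df <- df + df_i
    if (method == "lr") {
      nz <- tab > 0
      g <- 2 * sum(tab[nz] * log(tab[nz] / e[nz]))
      if (correct) {
        q <- 1 + ((N * sum(1 / rs) - 1) * (N * sum(1 / cs) - 1)) / (6 * N * df_i)
        g <- g / q
      }
      stat <- stat + g
    } else {
      stat <- stat + sum((tab - e)^2 / e)
    }
  }
  if (df == 0L) {
    stop("degenerate test: no source state has multi-group, multi-destination support",
         call. = FALSE)
  }
  labels <- vapply(seq_along(groups), function(j) {
    lb <- attr(groups[[j]], "female_strain")
    if (is.null(lb) || is.na(lb)) paste0("group", j) else lb
  }, character(1))
  structure(
    list(statistic = stat, df = df,
         p.value = stats::pchisq(stat, df, lower.tail = FALSE),
         method = method, corrected = method == "lr" && correct,
         groups = labels),
    class = "homogeneity_test"
  )
}

#' @export
print.homogeneity_test <- function(x, ...) {
  cat(sprintf(
    "Transition-matrix homogeneity test (%s)\ngroups: %s\nstatistic = %.4g, df = %d, p = %.4g\n",
    if (x$method == "lr") "likelihood ratio G2" else "Pearson chi-square",
    paste(x$groups, collapse = ", "), x$statistic, x$df, x$p.value
  ))
  invisible(x)
}

#' Per-trial transition frequencies
#'
#' Fraction of a trial's one-step transitions falling on each observed
#' state pair; fractions sum to 1 per trial. These per-trial frequencies are
#' the response variables for transition-level plasticity tests (e.g.
#' singing to attempted-copulation) via [art_anova()].
#'
#' @param trial An [ethogram_trial()] with at least 2 states.
#' @return Named numeric vector, names `"from->to"`.
#' @export
per_trial_transition_freq <- function(trial) {
  n <- length(trial$states)
  if (n < 2L) {
    stop("validation error: transition frequencies need a trial with >= 2 states",
         call. = FALSE)
  }
  pair <- paste(trial$states[-n], trial$states[-1L], sep = "->")
  tab <- table(pair)
  setNames(as.numeric(tab) / (n - 1L), names(tab))
}

#' Per-trial transition-frequency table for a set of trials
#'
#' @param trials List of [ethogram_trial()] objects (trials with fewer than
#'   2 states are dropped).
#' @param pairs Optional character vector of `"from->to"` pairs to report;
#'   default is every pair observed in any trial. Unobserved pairs are 0.
#' @return Data frame with `trial_id`, `male_strain`, `female_strain` and one
#'   column per transition pair (names `"from->to"`).
#' @export
transition_freq_table <- function(trials, pairs = NULL) {
  trials <- Filter(function(tr) length(tr$states) >= 2L, trials)
  if (length(trials) == 0L) {
    stop("validation error: no trial has >= 2 states", call. = FALSE)
  }
  freqs <- lapply(trials, per_trial_transition_freq)
  if (is.null(pairs)) pairs <- sort(unique(unlist(lapply(freqs, names))))
  mat <- matrix(0, length(trials), length(pairs),
                dimnames = list(NULL, pairs))
  for (i in seq_along(freqs)) {
    shared <- intersect(names(freqs[[i]]), pairs)
    mat[i, shared] <- freqs[[i]][shared]
  }
  meta <- data.frame(
    trial_id = vapply(trials, function(tr) tr$trial_id, character(1)),
    male_strain = vapply(trials, function(tr) tr$male_strain, character(1)),
    female_strain = vapply(trials, function(tr) tr$female_strain, character(1)),
    stringsAsFactors = FALSE
  )
  cbind(meta, as.data.frame(mat, check.names = FALSE))
}
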