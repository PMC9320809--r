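.art_check_data <- function(data, response) {
  for (col in c(response, "male_strain", "female_strain")) {
    if (!col %in% names(data)) {
      stop("format error: missing required column '", col, "'", call. = FALSE)
    }
  }
  data <- data[!is.na(data[[response]]), , drop = FALSE]
  if (nrow(data) == 0L) stop("validation error: no non-missing responses", call. = FALSE)
  data$male_strain <- factor(data$male_strain)
  data$female_strain <- factor(data$female_strain)
  data
}

# Cell means of the saturated two-factor model and the unweighted marginal
# means derived from them (the estimates used for alignment; with unbalanced
# cells this matches sum-to-zero / Type-III conventions rather than raw
# marginal averages).
.art_means <- function(data, response) {
  cell <- tapply(data[[response]], list(data$male_strain, data$female_strain),
                 mean)
  mu_a <- rowMeans(cell)
  mu_b <- colMeans(cell)
  grand <- mean(cell)
  list(cell = cell, mu_a = mu_a, mu_b = mu_b, grand = grand)
}

#' Align responses for one effect of a two-factor design
#'
#' The alignment step of the aligned-rank-transform (ART) procedure. Each
#' observation is stripped to its residual from its male-by-female cell mean
#' and the estimated target effect is added back: for a main effect the
#' corresponding unweighted marginal mean of cell means, for the interaction
#' the cell mean minus both marginal means plus the grand mean. In a balanced
#' design all estimated effects other than the target are thereby removed
#' exactly -- e.g. after aligning for `male`, the female-strain marginal means
#' of the aligned responses are all equal.
#'
#' @param data Data frame with columns `male_strain`, `female_strain` and the
#'   response.
#' @param effect `"male"`, `"female"` or `"interaction"`.
#' @param response Name of the response column (default `"response"`).
#' @return Numeric vector of aligned responses, same length/order as `data`
#'   rows with non-missing response.
#' @export
art_align <- function(data, effect = c("male", "female", "interaction"),
                      response = "response") {
  effect <- match.arg(effect)
  data <- .art_check_data(data, response)
  m <- .art_means(data, response)
  if (any(is.na(m$cell))) {
    empty <- which(is.na(m$cell), arr.ind = TRUE)
    cells <- apply(empty, 1L, function(ij) {
      paste(rownames(m$cell)[ij[1]], colnames(m$cell)[ij[2]], sep = " x ")
    })
    stop("validation error: alignment undefined with empty cell(s): ",
         paste(cells, collapse = "; "), call. = FALSE)
  }
  ai <- as.integer(data$male_strain)
  bi <- as.integer(data$female_strain)
  resid <- data[[response]] - m$cell[cbind(ai, bi)]
  est <- switch(effect,
    male = m$mu_a[ai],
    female = m$mu_b[bi],
    interaction = m$cell[cbind(ai, bi)] - m$mu_a[ai] - m$mu_b[bi] + 2 * m$grand
  )
  unname(resid + est)
}

# Sum-to-zero model matrix blocks for the full two-factor model; returns the
# full matrix and the column index sets of each effect.
.art_model_matrix <- function(data) {
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old), add = TRUE)
  X <- stats::model.matrix(~ male_strain * female_strain, data = data)
  asg <- attr(X, "assign")
  list(X = X, cols = list(male = which(asg == 1L), female = which(asg == 2L),
                          interaction = which(asg == 3L)))
}

.type3_f <- function(X, cols_drop, y) {
  fit_full <- stats::lm.fit(X, y)
  rss_full <- sum(fit_full$residuals^2)
  df_res <- length(y) - fit_full$rank
  fit_red <- stats::lm.fit(X[, -cols_drop, drop = FALSE], y)
  ss_eff <- sum(fit_red$residuals^2) - rss_full
  df_eff <- length(cols_drop)
  if (df_res <= 0L) stop("validation error: zero residual df", call. = FALSE)
  # exact-fit and no-effect corners: define F = 0 when the effect SS is zero,
  # F = Inf when residual variation is zero but the effect SS is not
  if (ss_eff <= 1e-10 * max(1, rss_full)) {
    f <- 0
  } else if (rss_full <= 1e-10 * ss_eff) {
    f <- Inf
  } else {
    f <- (ss_eff / df_eff) / (rss_full / df_res)
  }
  list(F = f, df1 = df_eff, df2 = df_res,
       p = stats::pf(f, df_eff, df_res, lower.tail = FALSE))
}

#' Aligned-rank-transform two-factor ANOVA
#'
#' Nonparametric factorial ANOVA for male-strain, female-strain and
#' interaction effects on a trait (behavioral budget, CHC abundance or
#' transition frequency). For each effect the responses are aligned with
#' [art_align()], ranked (average ranks for ties), and the full two-factor
#' linear ANOVA is fitted to the ranks with sum-to-zero factor coding; only
#' the target effect's Type-III F and p are reported from each fit. A
#' significant female-strain effect indicates plasticity (males shift the
#' trait depending on the female genotype they court); a significant
#' interaction indicates the shift is not parallel across male strains.
#'
#' @param data Data frame with columns `male_strain`, `female_strain` and the
#'   response. Both factors need at least 2 levels and the design must leave
#'   residual degrees of freedom (some cell with >= 2 replicates).
#' @param effects Which effects to test (default all three).
#' @param response Name of the response column.
#' @return Data frame of class `plasticity_result`: one row per effect with
#'   `effect`, `F`, `df1`, `df2`, `p`.
#' @export
art_anova <- function(data, effects = c("male", "female", "interaction"),
                      response = "response") {
  effects <- match.arg(effects, several.ok = TRUE)
  data <- .art_check_data(data, response)
  if (nlevels(data$male_strain) < 2L || nlevels(data$female_strain) < 2L) {
    stop("validation error: both factors need >= 2 levels", call. = FALSE)
  }
  mm <- .art_model_matrix(data)
  if (nrow(data) - ncol(mm$X) <= 0L) {
    stop("validation error: zero residual df (need replicated cells)", call. = FALSE)
  }
  rows <- lapply(effects, function(eff) {
    aligned <- art_align(data, eff, response)
    r <- rank(aligned)
    res <- .type3_f(mm$X, mm$cols[[eff]], r)
    data.frame(effect = eff, F = res$F, df1 = res$df1, df2 = res$df2, p = res$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("plasticity_result", "data.frame")
  out
}

#' Reaction norms: per-strain trait means in each female context
#'
#' Summarizes plasticity graphically-shaped data: the mean trait value of
#' each male strain in each female context, the per-strain context
#' difference, and the sign pattern of those differences (parallel reaction
#' norms show a consistent sign, e.g. "12/12 negative"). Strains observed in
#' only one context get a mean but no difference.
#'
#' @param data Data frame with columns `male_strain`, `female_strain` and the
#'   response.
#' @param response Name of the response column.
#' @param contexts Optional length-2 character vector ordering the female
#'   contexts; the difference is `mean(contexts[2]) - mean(contexts[1])`.
#' @return List with `norms` (male_strain, female_strain, mean, n),
#'   `differences` (male_strain, difference; `NA` when a strain lacks one
#'   context) and `sign_pattern` (counts of positive/negative/zero/missing).
#' @export
reaction_norms <- function(data, response = "response", contexts = NULL) {
  data <- .art_check_data(data, response)
  norms <- aggregate(data[[response]],
                     by = list(male_strain = as.character(data$male_strain),
                               female_strain = as.character(data$female_strain)),
                     FUN = mean)
  names(norms)[3] <- "mean"
  nn <- aggregate(data[[response]],
                  by = list(male_strain = as.character(data$male_strain),
                            female_strain = as.character(data$female_strain)),
                  FUN = length)
  norms$n <- nn$x
  if (is.null(contexts)) contexts <- levels(data$female_strain)
  if (length(contexts) != 2L) {
    return(list(norms = norms, differences = NULL, sign_pattern = NULL))
  }
  strains <- sort(unique(norms$male_strain))
  diffs <- vapply(strains, function(s) {
    m1 <- norms$mean[norms$male_strain == s & norms$female_strain == contexts[1]]
    m2 <- norms$mean[norms$male_strain == s & norms$female_strain == contexts[2]]
    if (length(m1) == 0L || length(m2) == 0L) NA_real_ else m2 - m1
  }, numeric(1))
  differences <- data.frame(male_strain = strains, difference = unname(diffs),
                            stringsAsFactors = FALSE)
  sign_pattern <- list(
    contexts = contexts,
    n_positive = sum(diffs > 0, na.rm = TRUE),
    n_negative = sum(diffs < 0, na.rm = TRUE),
    n_zero = sum(diffs == 0, na.rm = TRUE),
    n_single_context = sum(is.na(diffs))
  )
  list(norms = norms, differences = differences, sign_pattern = sign_pattern)
}
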