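#' @useDynLib courtshipSelect, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Standardize a trait to mean 0, SD 1
#'
#' Variance-standardization used before selection-gradient estimation:
#' `z = (x - mean(x)) / sd(x)` with the sample (n-1) SD, so standardized
#' gradients are comparable across traits and female strains. Idempotent.
#'
#' @param x Numeric vector, length >= 2, non-constant.
#' @param trait Optional trait name used in error messages.
#' @return Standardized numeric vector.
#' @export
#' @examples
#' standardize(c(1, 2, 3)) # -1 0 1
standardize <- function(x, trait = deparse(substitute(x))) {
  if (length(x) < 2L) {
    stop("validation error: standardize needs >= 2 values (trait ", trait, ")",
         call. = FALSE)
  }
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    stop("validation error: zero variance in trait ", trait, call. = FALSE)
  }
  (x - mean(x)) / s
}

#' Relative fitness from copulation latencies
#'
#' Scales a fitness proxy to mean 1 across the compared male strains. Under
#' the default `"inverse_latency"` convention, `w = (1/t) / mean(1/t)`, so a
#' trait that shortens latency gets a positive selection gradient and
#' positive regression coefficients represent positive selection. The
#' `"latency"` convention (`w = t / mean(t)`) is the literal mean-scaled
#' latency, under which larger values mark slower, less fit males and
#' gradient signs invert. `"mating_index"` treats the input as mating-index
#' values (see [mating_index()]; larger = worse) and uses their mean-scaled
#' reciprocals, which accommodates strains whose only information is failure
#' (infinite index gives w = 0).
#'
#' @param x Positive latencies in seconds (or mating-index values under
#'   `"mating_index"`; `Inf` allowed there).
#' @param convention `"inverse_latency"` (default), `"latency"` or
#'   `"mating_index"`.
#' @return Numeric vector with mean 1.
#' @export
#' @examples
#' relative_fitness(c(100, 200), "inverse_latency") # 4/3 2/3
#' relative_fitness(c(100, 200, 300), "latency")    # 0.5 1.0 1.5
relative_fitness <- function(x, convention = c("inverse_latency", "latency",
                                               "mating_index")) {
  convention <- match.arg(convention)
  if (convention != "mating_index" && any(!is.finite(x))) {
    stop("validation error: latencies must be finite", call. = FALSE)
  }
  if (any(x <= 0)) {
    stop("validation error: latencies must be strictly positive", call. = FALSE)
  }
  w <- switch(convention,
    latency = x / mean(x),
    inverse_latency = (1 / x) / mean(1 / x),
    mating_index = (1 / x) / mean(1 / x)
  )
  unname(w)
}

#' Selection gradient by exact median (L1) regression with bootstrap CI
#'
#' Fits relative fitness `w` on a standardized trait `z` at the median
#' (tau = 0.5): the coefficients minimize `sum |w - a - b z|`, solved exactly
#' by enumerating the candidate lines through point pairs (feasible because
#' strain-level analyses are small-n). The slope `b` is the standardized
#' linear selection gradient; conditioning on the median makes it robust to
#' the long-tailed latency distributions and outlier strains typical of
#' mating data. The 95% confidence interval is a seeded case-resampling
#' (paired z, w) percentile bootstrap.
#'
#' @param z Standardized trait values (length >= 3, non-constant).
#' @param w Relative fitness values.
#' @param bootstrap Number of bootstrap replicates (default 2000).
#' @param seed Integer seed for the bootstrap resampling.
#' @param level Confidence level (default 0.95).
#' @return Object of class `selection_gradient`: list with `gradient`,
#'   `intercept`, `loss`, `ci` (length 2), `level`, `bootstrap`, `seed`,
#'   `n` and `method`.
#' @export
median_regression <- function(z, w, bootstrap = 2000, seed = 1, level = 0.95) {
  n <- length(z)
  if (n < 3L || length(w) != n) {
    stop("validation error: median regression needs matched z, w with n >= 3",
         call. = FALSE)
  }
  if (length(unique(z)) < 2L) {
    stop("validation error: all trait values identical", call. = FALSE)
  }
  fit <- .l1_line_fit(as.numeric(z), as.numeric(w))
  boots <- rep(NA_real_, bootstrap)
  if (bootstrap > 0) {
    set.seed(seed)
    for (b in seq_len(bootstrap)) {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(z[idx])) < 2L) next  # degenerate resample carries no slope
      boots[b] <- .l1_line_fit(z[idx], w[idx])[["slope"]]
    }
  }
  alpha <- (1 - level) / 2
  ci <- if (all(is.na(boots))) {
    c(fit[["slope"]], fit[["slope"]])
  } else {
    unname(stats::quantile(boots, c(alpha, 1 - alpha), na.rm = TRUE, type = 7))
  }
  structure(
    list(gradient = fit[["slope"]], intercept = fit[["intercept"]],
         loss = fit[["loss"]], ci = ci, level = level, bootstrap = bootstrap,
         seed = seed, n = n,
         method = "exact L1 (pair enumeration), percentile bootstrap CI"),
    class = "selection_gradient"
  )
}

#' @export
print.selection_gradient <- function(x, ...) {
  cat(sprintf(
    "Median-regression selection gradient: beta = %.4g  [%.4g, %.4g] (%d%% CI, B = %d, n = %d)\n",
    x$gradient, x$ci[1], x$ci[2], round(100 * x$level), x$bootstrap, x$n
  ))
  invisible(x)
}

#' Binomial regression of mating success on a standardized trait
#'
#' Logistic model `logit(p_i) = a + b z_i` for per-strain mating proportions
#' (successes out of trials), fitted by iteratively reweighted least squares
#' ([stats::glm()] with binomial family), with a Wald confidence interval on
#' the trait coefficient. Complete separation (the trait perfectly orders
#' all-success vs all-failure strains) is detected and reported as a flag
#' rather than a spuriously huge finite estimate.
#'
#' @param z Standardized trait values, one per strain (length >= 2).
#' @param successes,trials Integer vectors of successful and total trials per
#'   strain; every strain needs `trials >= 1`.
#' @param level Confidence level (default 0.95).
#' @return List with `coefficient`, `se`, `ci`, `intercept`, `separated`,
#'   `n`.
#' @export
binomial_success_regression <- function(z, successes, trials, level = 0.95) {
  n <- length(z)
  if (n < 2L || length(successes) != n || length(trials) != n) {
    stop("validation error: need matched z, successes, trials (n >= 2)",
         call. = FALSE)
  }
  if (any(trials < 1L)) {
    stop("validation error: every strain needs trials >= 1", call. = FALSE)
  }
  if (any(successes < 0L | successes > trials)) {
    stop("validation error: successes must lie in [0, trials]", call. = FALSE)
  }
  fit <- suppressWarnings(
    stats::glm(cbind(successes, trials - successes) ~ z, family = stats::binomial())
  )
  co <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  separated <- !fit$converged || abs(co[2]) > 15 || se[2] > 100
  zq <- stats::qnorm(1 - (1 - level) / 2)
  list(
    coefficient = if (separated) sign(co[2]) * Inf else unname(co[2]),
    se = if (separated) NA_real_ else unname(se[2]),
    ci = if (separated) c(NA_real_, NA_real_)
         else unname(co[2] + c(-1, 1) * zq * se[2]),
    intercept = unname(co[1]),
    separated = separated,
    n = n
  )
}

#' Two-stage random-forest variable reduction
#'
#' Reduces the full set of candidate male traits (behavioral budgets, CHC
#' abundances, transition frequencies) to the subset worth estimating
#' selection gradients for, using permutation importance from an ensemble of
#' randomized regression forests. Stage 1 (thresholding): each trait's
#' permutation importance is averaged over `R` forest fits and must exceed
#' both (a) the typical importance standard deviation of the lowest-ranked
#' (presumed-null) half of traits and (b) a permutation-null bar -- the 90th
#' percentile of the maximum trait importance obtained when the response is
#' randomly permuted -- which calibrates away traits that are merely the best
#' of p spurious correlates at this sample size. Stage 2 (interpretation):
#' surviving traits are added one at a time in importance order, and a trait
#' is kept only if it lowers the mean out-of-bag error by more than one
#' standard deviation of that error estimate. Deterministic given `seed`.
#'
#' @param traits Numeric matrix or data frame (rows = strains or trials,
#'   columns = traits), >= 2 traits and >= 4 rows.
#' @param response Numeric response (relative fitness or success proportion).
#' @param seed Integer seed.
#' @param R Number of forest fits used for importance averaging (default 50).
#' @param stage2_reps Forest fits per candidate model in stage 2 (default 10).
#' @param ntree Trees per forest (default 300).
#' @return Character vector of selected trait names in importance order, with
#'   attributes `importance` (mean and SD per trait) and `threshold`.
#' @export
variable_select <- function(traits, response, seed = 1, R = 50,
                            stage2_reps = 10, ntree = 300) {
  traits <- as.data.frame(traits)
  p <- ncol(traits)
  if (p < 2L || nrow(traits) < 4L) {
    stop("validation error: variable selection needs >= 2 traits and >= 4 rows",
         call. = FALSE)
  }
  if (length(unique(response)) < 2L) {
    stop("validation error: constant response", call. = FALSE)
  }
  set.seed(seed)
  imp <- matrix(NA_real_, R, p, dimnames = list(NULL, names(traits)))
  for (r in seq_len(R)) {
    rf <- suppressWarnings(
      randomForest::randomForest(x = traits, y = response, ntree = ntree,
                                 importance = TRUE)
    )
    imp[r, ] <- randomForest::importance(rf, type = 1, scale = FALSE)[, 1]
  }
  # a trait the forest never uses gets NaN permutation importance: that is
  # zero evidence of signal
  imp[!is.finite(imp)] <- 0
  mean_imp <- colMeans(imp)
  sd_imp <- apply(imp, 2L, stats::sd)
  ord <- order(mean_imp, decreasing = TRUE)
  lower <- ord[seq.int(floor(p / 2) + 1L, p)]
  n_null <- max(10L, ceiling(R / 2))
  null_max <- vapply(seq_len(n_null), function(i) {
    rf <- suppressWarnings(
      randomForest::randomForest(x = traits, y = sample(response),
                                 ntree = ntree, importance = TRUE)
    )
    ni <- randomForest::importance(rf, type = 1, scale = FALSE)[, 1]
    max(ni[is.finite(ni)], 0)
  }, numeric(1))
  threshold <- max(mean(sd_imp[lower]),
                   stats::quantile(null_max, 0.9, names = FALSE))
  kept <- ord[mean_imp[ord] > threshold]
  imp_tab <- data.frame(trait = names(traits)[ord],
                        mean_importance = mean_imp[ord],
                        sd_importance = sd_imp[ord],
                        row.names = NULL, stringsAsFactors = FALSE)
  if (length(kept) == 0L) {
    return(structure(character(0), importance = imp_tab, threshold = threshold))
  }
  oob_error <- function(cols) {
    errs <- vapply(seq_len(stage2_reps), function(i) {
      rf <- suppressWarnings(
        randomForest::randomForest(x = traits[, cols, drop = FALSE],
                                   y = response, ntree = ntree)
      )
      rf$mse[ntree]
    }, numeric(1))
    c(mean = mean(errs), sd = stats::sd(errs))
  }
  selected <- kept[1]
  cur <- oob_error(selected)
  for (v in kept[-1]) {
    cand <- oob_error(c(selected, v))
    if (cur[["mean"]] - cand[["mean"]] > cand[["sd"]]) {
      selected <- c(selected, v)
      cur <- cand
    }
  }
  structure(names(traits)[selected], importance = imp_tab, threshold = threshold)
}

#' Principal component analysis of male courtship and CHC trait means
#'
#' Eigendecomposition of the trait correlation matrix (PCA on standardized
#' columns) of per-strain trait means, used to examine how courtship
#' behaviors and cuticular hydrocarbons covary across male genotypes. Signs
#' follow a fixed convention -- within each component the loading of largest
#' magnitude is positive -- so repeated runs are identical.
#'
#' @param x Numeric matrix or data frame of per-strain trait means (>= 3
#'   strains, >= 2 traits, no constant column).
#' @return List with `scores` (strains x components), `loadings` (traits x
#'   components) and `var_explained` (fractions summing to 1).
#' @export
pca_traits <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 3L) {
    stop("validation error: PCA needs >= 3 strains", call. = FALSE)
  }
  if (ncol(x) < 2L) {
    stop("validation error: PCA needs >= 2 traits", call. = FALSE)
  }
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("validation error: zero variance in trait ",
         paste(colnames(x)[sds == 0], collapse = ", "), call. = FALSE)
  }
  fit <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  for (j in seq_len(ncol(fit$rotation))) {
    lead <- which.max(abs(fit$rotation[, j]))
    if (fit$rotation[lead, j] < 0) {
      fit$rotation[, j] <- -fit$rotation[, j]
      fit$x[, j] <- -fit$x[, j]
    }
  }
  list(scores = fit$x, loadings = fit$rotation,
       var_explained = fit$sdev^2 / sum(fit$sdev^2))
}
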