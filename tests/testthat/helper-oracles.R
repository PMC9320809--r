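# Independent brute-force oracles and small fixture builders. These are kept
# deliberately separate from the package implementations they check.

# Exhaustive L1 line fit: try every line through a pair of points (plus the
# horizontal line through each point's median), score the absolute loss
# directly, break ties toward the smallest |slope| then smallest slope.
oracle_l1 <- function(x, y) {
  n <- length(x)
  slopes <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (x[i] != x[j]) slopes <- c(slopes, (y[j] - y[i]) / (x[j] - x[i]))
    }
  }
  slopes <- unique(slopes)
  best <- NULL
  for (b in slopes) {
    a <- median(y - b * x)
    loss <- sum(abs(y - a - b * x))
    if (is.null(best) || loss < best$loss - 1e-9 * (1 + best$loss) ||
        (abs(loss - best$loss) <= 1e-9 * (1 + best$loss) &&
         (abs(b) < abs(best$b) - 1e-12 ||
          (abs(abs(b) - abs(best$b)) <= 1e-12 && b < best$b)))) {
      best <- list(a = a, b = b, loss = loss)
    }
  }
  best
}

# Binomial-likelihood grid search, refined in two stages around the coarse
# optimum; independent of glm/IRLS.
oracle_binom <- function(z, successes, trials, span = 6, coarse = 121) {
  loglik <- function(a, b) {
    p <- plogis(a + b * z)
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    sum(successes * log(p) + (trials - successes) * log(1 - p))
  }
  grid_opt <- function(ac, bc, half, k) {
    as <- seq(ac - half, ac + half, length.out = k)
    bs <- seq(bc - half, bc + half, length.out = k)
    ll <- outer(as, bs, Vectorize(loglik))
    ij <- which(ll == max(ll), arr.ind = TRUE)[1, ]
    c(a = as[ij[1]], b = bs[ij[2]])
  }
  est <- c(a = 0, b = 0)
  half <- span
  for (step in 1:4) {
    est <- grid_opt(est["a"], est["b"], half, coarse)
    half <- half * 2.5 / coarse * 2
  }
  est
}

# Independent multinomial log-likelihood-ratio homogeneity statistic:
# 2 * (sum of per-group multinomial log-likelihoods at the group MLEs minus
# the log-likelihood at the pooled MLE), row by row.
oracle_g2 <- function(mats) {
  k <- nrow(mats[[1]])
  ll <- function(counts, p) {
    nz <- counts > 0
    sum(counts[nz] * log(p[nz]))
  }
  stat <- 0
  for (i in seq_len(k)) {
    pooled <- Reduce(`+`, lapply(mats, function(m) m[i, ]))
    if (sum(pooled) == 0) next
    p_pool <- pooled / sum(pooled)
    for (m in mats) {
      row <- m[i, ]
      if (sum(row) == 0) next
      stat <- stat + 2 * (ll(row, row / sum(row)) - ll(row, p_pool))
    }
  }
  stat
}

# Aligned-rank ANOVA oracle for balanced designs: raw-mean alignment (valid
# because balanced), rank, then stats::aov sequential sums of squares (equal
# to Type III in balanced designs).
oracle_art_f <- function(data, effect) {
  y <- data$response
  A <- factor(data$male_strain)
  B <- factor(data$female_strain)
  cell <- ave(y, A, B)
  mu_a <- ave(y, A)
  mu_b <- ave(y, B)
  mu <- mean(y)
  aligned <- switch(effect,
    male = y - cell + mu_a,
    female = y - cell + mu_b,
    interaction = y - mu_a - mu_b + mu
  )
  r <- rank(aligned)
  tab <- summary(stats::aov(r ~ A * B))[[1]]
  row <- switch(effect, male = "A", female = "B", interaction = "A:B")
  tab[trimws(rownames(tab)) == row, "F value"]
}

# Chain sampler independent of the package simulator: length-`len` state
# sequence from a row-stochastic matrix, started in `separate`.
sample_chain_trial <- function(m, len, id = "t1", male = NA, female = NA) {
  s <- integer(len)
  s[1] <- 1L
  for (t in 2:len) s[t] <- sample.int(nrow(m), 1L, prob = m[s[t - 1L], ])
  ethogram_trial(id, behavior_states()[s], male_strain = male,
                 female_strain = female)
}

# Non-absorbing 8-state matrix used for homogeneity calibration checks.
null_dynamics <- function() {
  m <- rbind(
    c(.52, .38, .04, .02, .02, .01, .01, 0),
    c(.10, .36, .31, .06, .06, .05, .06, 0),
    c(.05, .16, .46, .05, .05, .05, .18, 0),
    c(.05, .16, .15, .41, .05, .05, .13, 0),
    c(.05, .16, .10, .05, .46, .07, .11, 0),
    c(.05, .16, .10, .05, .07, .46, .11, 0),
    c(.05, .16, .26, .05, .05, .05, .38, 0),
    c(0, 0, 0, 0, 0, 0, 0, 1)
  )
  m <- m / rowSums(m)
  dimnames(m) <- list(behavior_states(), behavior_states())
  m
}

balanced_factorial <- function(n_male, n_female, n_per_cell) {
  d <- expand.grid(male_strain = sprintf("m%02d", seq_len(n_male)),
                   female_strain = sprintf("f%d", seq_len(n_female)),
                   stringsAsFactors = FALSE)
  d[rep(seq_len(nrow(d)), each = n_per_cell), , drop = FALSE]
}
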