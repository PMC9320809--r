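test_that("standardization centers, scales, idempotent, and guards degeneracy", {
  expect_equal(standardize(c(1, 2, 3)), c(-1, 0, 1))
  z <- standardize(rlnorm(20))
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_equal(standardize(z), z)
  expect_error(standardize(rep(2, 5), trait = "cVA"), "zero variance.*cVA")
  expect_error(standardize(3), ">= 2 values")
})

test_that("relative fitness conventions scale to mean one with the right shape", {
  expect_equal(relative_fitness(c(100, 200, 300), "latency"), c(0.5, 1.0, 1.5))
  expect_equal(relative_fitness(c(100, 200), "inverse_latency"), c(4 / 3, 2 / 3))
  for (conv in c("latency", "inverse_latency")) {
    expect_equal(relative_fitness(rep(123, 4), conv), rep(1, 4))
    expect_equal(mean(relative_fitness(rlnorm(9, 5), conv)), 1, tolerance = 1e-12)
  }
  expect_error(relative_fitness(c(10, 0), "latency"), "strictly positive")
  # infinite mating index (never mated) maps to zero fitness
  w <- relative_fitness(c(100, 200, Inf), "mating_index")
  expect_equal(w[3], 0)
  expect_equal(mean(w), 1, tolerance = 1e-12)
})

test_that("median regression is exact on collinear points", {
  z <- c(-1, 0, 2)
  w <- 1 + 0.5 * z
  fit <- median_regression(z, w, bootstrap = 200, seed = 3)
  expect_equal(fit$gradient, 0.5, tolerance = 1e-12)
  expect_equal(fit$intercept, 1, tolerance = 1e-12)
  expect_equal(fit$loss, 0, tolerance = 1e-12)
  expect_equal(unname(fit$ci), c(0.5, 0.5), tolerance = 1e-12)
})

test_that("a single outlier does not drag the median fit", {
  z <- c(-1, 0, 1, 2)
  w <- c(1, 1, 1, 5)
  fit <- median_regression(z, w, bootstrap = 0)
  orc <- oracle_l1(z, w)
  expect_equal(fit$loss, orc$loss, tolerance = 1e-9)
  expect_equal(fit$gradient, orc$b, tolerance = 1e-9)
  # flat fit through the three inliers ties the interpolating alternative;
  # the deterministic tie-break picks the flat line
  expect_equal(fit$gradient, 0)
  expect_equal(fit$loss, 4)
})

test_that("median regression matches the pair-enumeration oracle on random data", {
  set.seed(606)
  for (i in 1:60) {
    n <- sample(4:12, 1)
    z <- rnorm(n)
    w <- 1 + rnorm(1) * z + rt(n, df = 3) * 0.5
    fit <- median_regression(z, w, bootstrap = 0)
    orc <- oracle_l1(z, w)
    expect_equal(fit$loss, orc$loss, tolerance = 1e-9)
    expect_equal(fit$gradient, orc$b, tolerance = 1e-9)
  }
})

test_that("median regression validates its inputs", {
  expect_error(median_regression(c(1, 1, 1), c(1, 2, 3), bootstrap = 0),
               "identical")
  expect_error(median_regression(c(1, 2), c(1, 2), bootstrap = 0), "n >= 3")
})

test_that("gradient recovery: simulated linear selection is re-estimated", {
  set.seed(99)
  hits <- 0
  for (r in 1:40) {
    n <- 200
    z <- rnorm(n)
    noise <- stats::rexp(n, 1 / 0.1) * sample(c(-1, 1), n, replace = TRUE) / 2
    w <- 1 + 0.4 * z + noise
    fit <- median_regression(z, w, bootstrap = 0)
    if (abs(fit$gradient - 0.4) < 0.05) hits <- hits + 1
  }
  expect_gte(hits / 40, 0.95)
})

test_that("binomial success regression reproduces closed-form two-point fits", {
  flat <- binomial_success_regression(c(-1, 0, 1), c(5, 5, 5), c(10, 10, 10))
  expect_equal(flat$coefficient, 0, tolerance = 1e-9)
  expect_equal(flat$intercept, 0, tolerance = 1e-9)

  two <- binomial_success_regression(c(-1, 1), c(2, 8), c(10, 10))
  expect_equal(two$intercept, 0, tolerance = 1e-7)
  expect_equal(two$coefficient, log(4), tolerance = 1e-7)

  sep <- binomial_success_regression(c(-1, -0.5, 0.5, 1), c(0, 0, 10, 10),
                                     rep(10, 4))
  expect_true(sep$separated)
  expect_true(is.infinite(sep$coefficient))

  expect_error(binomial_success_regression(c(0, 1), c(0, 1), c(0, 2)),
               "trials >= 1")
})

test_that("IRLS estimates agree with the likelihood grid-search oracle", {
  set.seed(31)
  for (i in 1:10) {
    n <- sample(4:8, 1)
    z <- rnorm(n)
    tr <- sample(5:15, n, replace = TRUE)
    p <- plogis(0.3 + 0.8 * z)
    s <- rbinom(n, tr, p)
    if (all(s == 0) || all(s == tr)) next
    fit <- binomial_success_regression(z, s, tr)
    if (fit$separated) next
    orc <- oracle_binom(z, s, tr)
    expect_equal(fit$coefficient, unname(orc["b"]), tolerance = 1e-3)
    expect_equal(fit$intercept, unname(orc["a"]), tolerance = 1e-3)
  }
})

test_that("variable selection finds a planted signal and is seed-deterministic", {
  set.seed(808)
  n <- 60
  traits <- as.data.frame(matrix(rnorm(n * 6), n, 6))
  names(traits) <- c("signal", paste0("noise", 1:5))
  resp <- 1 + 1.5 * traits$signal + rnorm(n, 0, 0.5)
  sel <- variable_select(traits, resp, seed = 5, R = 15, stage2_reps = 5,
                         ntree = 200)
  expect_true("signal" %in% sel)
  expect_lte(length(sel), 2L)
  sel2 <- variable_select(traits, resp, seed = 5, R = 15, stage2_reps = 5,
                          ntree = 200)
  expect_identical(as.character(sel), as.character(sel2))
  expect_error(variable_select(traits, rep(1, n), seed = 1), "constant response")
})

test_that("all-noise traits yield an empty or near-empty selection", {
  set.seed(809)
  ok <- 0
  for (r in 1:5) {
    n <- 60
    traits <- as.data.frame(matrix(rnorm(n * 6), n, 6))
    resp <- rnorm(n)
    sel <- variable_select(traits, resp, seed = r, R = 10, stage2_reps = 8,
                           ntree = 150)
    if (length(sel) <= 1L) ok <- ok + 1
  }
  expect_gte(ok, 4)
})

test_that("PCA of traits matches an eigendecomposition oracle", {
  set.seed(19)
  # two perfectly correlated traits: one axis carries everything
  x <- rnorm(10)
  p1 <- pca_traits(cbind(a = x, b = 2 * x + 3))
  expect_equal(p1$var_explained[1], 1, tolerance = 1e-12)

  # two independent blocks: leading axes match the correlation eigensolve
  n <- 40
  b1 <- rnorm(n); b2 <- rnorm(n)
  X <- cbind(t1 = b1, t2 = b1 + rnorm(n, 0, .05),
             t3 = b2, t4 = b2 + rnorm(n, 0, .05))
  p <- pca_traits(X)
  ev <- eigen(cor(X))
  expect_equal(p$var_explained, ev$values / sum(ev$values), tolerance = 1e-10)
  for (j in 1:2) {
    expect_equal(abs(p$loadings[, j]), abs(ev$vectors[, j]), tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
  expect_equal(sum(p$var_explained), 1, tolerance = 1e-12)

  # deterministic sign convention: leading loading positive, runs identical
  p2 <- pca_traits(X)
  expect_identical(p$loadings, p2$loadings)
  for (j in seq_len(ncol(p$loadings))) {
    expect_gt(p$loadings[which.max(abs(p$loadings[, j])), j], 0)
  }
  expect_error(pca_traits(X[1:2, ]), ">= 3 strains")
})
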