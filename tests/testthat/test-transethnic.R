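test_that("partition enumeration matches Bell numbers and covers labels disjointly", {
  expect_length(enumerate_partitions("a"), 1)
  expect_length(enumerate_partitions(c("a", "b", "c", "d")), 15)
  # Bell-number recurrence oracle: B(n+1) = sum C(n,k) B(k)
  bell <- c(1, 1)
  for (n in 1:6) {
    bell <- c(bell, sum(choose(n, 0:n) * bell[1:(n + 1)]))
  }
  for (k in 2:6) {
    expect_length(enumerate_partitions(letters[1:k]), bell[k + 1])
  }
  parts3 <- enumerate_partitions(c("x", "y", "z"))
  expect_length(parts3, 5)
  for (p in parts3) {
    expect_setequal(unlist(p), c("x", "y", "z"))
    expect_equal(length(unlist(p)), 3)  # disjoint cover
  }
  expect_error(enumerate_partitions(letters[1:11]), "10 populations")
  expect_error(enumerate_partitions(c("a", "a")), "unique")
})

test_that("cluster marginal matches the Wakefield single-study closed form", {
  for (case in list(c(0.35, 0.1, 0.2), c(-1.2, 0.4, 0.5), c(0, 0.2, 1))) {
    b <- case[1]; s <- case[2]; sg <- case[3]
    log_bf <- cluster_log_marginal(b, s, sg) - dnorm(b, 0, s, log = TRUE)
    z <- b / s
    wakefield <- 0.5 * log(s^2 / (s^2 + sg^2)) +
      0.5 * z^2 * sg^2 / (s^2 + sg^2)
    expect_equal(log_bf, wakefield, tolerance = 1e-10)
  }
})

test_that("sigma = 0 collapses the cluster marginal to the null likelihood", {
  b <- c(0.2, -0.1, 0.4); s <- c(0.1, 0.2, 0.15)
  expect_equal(cluster_log_marginal(b, s, 0),
               sum(dnorm(b, 0, s, log = TRUE)), tolerance = 1e-12)
})

test_that("cluster marginal agrees with adaptive quadrature over the shared effect", {
  set.seed(71)
  for (i in 1:5) {
    b <- rnorm(3, 0, 0.3); s <- runif(3, 0.05, 0.4); sg <- runif(1, 0.1, 0.5)
    closed <- cluster_log_marginal(b, s, sg)
    integrand <- function(mu) {
      vapply(mu, function(m) {
        exp(sum(dnorm(b, m, s, log = TRUE)) + dnorm(m, 0, sg, log = TRUE))
      }, numeric(1))
    }
    quad <- integrate(integrand, -5, 5, rel.tol = 1e-12)$value
    expect_equal(closed, log(quad), tolerance = 1e-8)
  }
})

test_that("full Bayes factor matches a quadrature-based enumeration oracle", {
  set.seed(72)
  est <- tibble::tibble(label = c("p1", "p2", "p3"),
                        beta = c(0.25, 0.3, -0.05),
                        se = c(0.08, 0.1, 0.12))
  sg <- 0.2
  fit <- transethnic_bf(est, sigma = sg)
  # oracle: same model, but every cluster marginal from numeric integration
  quad_cluster <- function(b, s) {
    integrand <- function(mu) {
      vapply(mu, function(m) {
        exp(sum(dnorm(b, m, s, log = TRUE)) + dnorm(m, 0, sg, log = TRUE))
      }, numeric(1))
    }
    log(integrate(integrand, -6, 6, rel.tol = 1e-13)$value)
  }
  parts <- enumerate_partitions(est$label)
  log_ml <- vapply(parts, function(p) {
    sum(vapply(p, function(cl) {
      idx <- match(cl, est$label)
      quad_cluster(est$beta[idx], est$se[idx])
    }, numeric(1)))
  }, numeric(1))
  log_model <- log(mean(exp(log_ml)))  # uniform prior over partitions
  log_null <- sum(dnorm(est$beta, 0, est$se, log = TRUE))
  expect_equal(fit$log10_bf, (log_model - log_null) / log(10),
               tolerance = 1e-6)
})

test_that("null inputs never favour association; strong shared signal does", {
  null_fit <- transethnic_bf(
    tibble::tibble(beta = rep(0, 4), se = rep(0.1, 4)), sigma = 0.2)
  expect_lte(null_fit$log10_bf, 0)

  strong <- tibble::tibble(label = c("a", "b", "c", "d"),
                           beta = rep(0.5, 4), se = rep(0.1, 4))  # all z = 5
  strong_fit <- transethnic_bf(strong, sigma = 0.2)
  expect_gt(strong_fit$log10_bf, 1.5)
  top <- tidy(strong_fit)
  expect_equal(top$partition[1], "{a,b,c,d}")  # one shared cluster wins
})

test_that("Bayes factor is monotone in signal scale and allele-flip invariant", {
  base <- tibble::tibble(beta = c(0.1, 0.15, 0.08, 0.2),
                         se = rep(0.1, 4))
  bfs <- vapply(seq(0.5, 4, by = 0.5), function(scale) {
    scaled <- base
    scaled$beta <- scaled$beta * scale
    transethnic_bf(scaled, sigma = 0.2)$log10_bf
  }, numeric(1))
  expect_true(all(diff(bfs) >= -1e-12))

  flipped <- base
  flipped$beta <- -flipped$beta
  expect_equal(transethnic_bf(flipped, sigma = 0.2)$log10_bf,
               transethnic_bf(base, sigma = 0.2)$log10_bf,
               tolerance = 1e-12)
})

test_that("posterior partition weights form a probability distribution", {
  set.seed(73)
  for (i in 1:5) {
    k <- sample(2:5, 1)
    est <- tibble::tibble(beta = rnorm(k, 0, 0.3), se = runif(k, 0.05, 0.3))
    fit <- transethnic_bf(est, sigma = 0.25)
    expect_equal(sum(fit$posterior), 1, tolerance = 1e-12)
    expect_true(all(fit$posterior >= 0))
  }
})

test_that("results are bit-reproducible and the distance prior reweights partitions", {
  est <- tibble::tibble(label = c("a", "b", "c"),
                        beta = c(0.3, 0.28, -0.1), se = rep(0.1, 3))
  f1 <- transethnic_bf(est, sigma = 0.2)
  f2 <- transethnic_bf(est, sigma = 0.2)
  expect_identical(f1$log10_bf, f2$log10_bf)

  D <- matrix(1, 3, 3, dimnames = list(est$label, est$label))
  diag(D) <- 0
  D["a", "b"] <- D["b", "a"] <- 0.01  # a,b nearly identical populations
  fd <- transethnic_bf(est, sigma = 0.2, distance_matrix = D,
                       concentration = 5)
  # the {a,b}|{c} partition gains prior mass relative to uniform
  idx <- match("{a,b}|{c}", fd$partitions)
  expect_gt(exp(fd$log_prior[idx]), 1 / length(fd$partitions))
})
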