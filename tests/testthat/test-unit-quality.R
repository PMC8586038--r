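make_two_clusters <- function(n = 60, d = 2, sep = 20, seed = 1) {
  set.seed(seed)
  target <- matrix(rnorm(n * d), n, d)
  noise <- matrix(rnorm(n * d), n, d)
  noise[, 1] <- noise[, 1] + sep
  feature_matrix(rbind(target, noise),
                 c(rep("t", n), rep("n", n)))
}

test_that("ISI violation fraction handles the forced-arithmetic cases", {
  expect_equal(isi_violation_fraction(cumsum(rep(0.010, 50))), 0)
  # 1 violating ISI among 99: 1/99, which fails the <1% gate
  t <- cumsum(c(0.01, 0.001, rep(0.01, 98)))  # 100 spikes, 99 ISIs
  f <- isi_violation_fraction(t)
  expect_equal(f, 1 / 99)
  expect_false(f < 0.01)
  expect_error(isi_violation_fraction(c(1)), ">= 2 spikes")
})

test_that("Poisson trains match the exponential-ISI closed form", {
  # fraction of ISIs < 2 ms ~ 1 - exp(-r * 0.002)
  set.seed(8)
  for (r in c(5, 20)) {
    t <- cumsum(rexp(20000, r))
    expect_lt(abs(isi_violation_fraction(t) - (1 - exp(-r * 0.002))),
              0.005)
  }
})

test_that("isolation distance equals the brute-force Mahalanobis oracle", {
  for (d in 2:4) {
    fm <- make_two_clusters(n = 50, d = d, seed = d)
    X <- fm$features[fm$labels == "t", ]
    noise <- fm$features[fm$labels == "n", ]
    expect_equal(isolation_distance(fm, "t"),
                 sort(oracle_mahal(X, noise))[nrow(X)],
                 tolerance = 1e-9)
  }
})

test_that("L-ratio equals the direct-summation oracle", {
  for (d in 2:4) {
    fm <- make_two_clusters(n = 40, d = d, sep = 5, seed = 10 + d)
    X <- fm$features[fm$labels == "t", ]
    noise <- fm$features[fm$labels == "n", ]
    want <- sum(1 - pchisq(oracle_mahal(X, noise), df = d)) / nrow(X)
    expect_equal(l_ratio(fm, "t"), want, tolerance = 1e-12)
  }
})

test_that("degenerate feature inputs are rejected", {
  # noise coincident with the cluster mean: distance 0, L-ratio m/n
  set.seed(3)
  X <- matrix(rnorm(40), 20, 2)
  mu <- colMeans(X)
  fm <- feature_matrix(rbind(X, matrix(mu, 5, 2, byrow = TRUE)),
                       c(rep("t", 20), rep("n", 5)))
  expect_equal(l_ratio(fm, "t"), 5 / 20, tolerance = 1e-12)
  # fewer noise than target spikes
  expect_error(isolation_distance(fm, "t"), "fewer noise")
  # singular covariance
  Xs <- cbind(1:20, 2 * (1:20))
  fms <- feature_matrix(rbind(Xs, matrix(rnorm(10), 5, 2)),
                        c(rep("t", 20), rep("n", 5)))
  expect_error(l_ratio(fms, "t"), "singular|degenerate")
})

test_that("Mahalanobis metrics are affine invariant", {
  fm <- make_two_clusters(n = 50, d = 3, sep = 8, seed = 20)
  iso0 <- isolation_distance(fm, "t")
  lr0 <- l_ratio(fm, "t")
  set.seed(21)
  for (k in 1:3) {
    A <- matrix(rnorm(9), 3, 3)
    while (abs(det(A)) < 0.1) A <- matrix(rnorm(9), 3, 3)
    b <- rnorm(3)
    fmT <- feature_matrix(sweep(fm$features %*% A, 2, -b), fm$labels)
    expect_equal(isolation_distance(fmT, "t"), iso0, tolerance = 1e-6)
    expect_equal(l_ratio(fmT, "t"), lr0, tolerance = 1e-6)
  }
})

test_that("duplicate detection is symmetric and matches closed forms", {
  t <- sort(runif(200, 0, 100))
  tr <- spike_train("a", t, span = c(0, 100))
  # identical trains -> fraction 1, duplicate
  r <- duplicate_pair(tr, tr)
  expect_equal(r$coincidence_fraction, 1)
  expect_true(r$is_duplicate)
  # jitter within the window keeps full coincidence
  r2 <- duplicate_pair(t, t + 0.0005)
  expect_equal(r2$coincidence_fraction, 1)
  # symmetry
  set.seed(30)
  a <- cumsum(rexp(300, 5)); b <- cumsum(rexp(400, 5))
  expect_equal(duplicate_pair(a, b)$coincidence_fraction,
               duplicate_pair(b, a)$coincidence_fraction)
  # independent Poisson trains: coincidence ~ 1 - exp(-2 * r * w), tiny
  set.seed(31)
  fr <- replicate(30, {
    a <- cumsum(rexp(500, 5)); b <- cumsum(rexp(500, 5))
    duplicate_pair(a, b)$coincidence_fraction
  })
  expect_lt(mean(fr), 0.05)
  expect_false(any(fr > 0.5))
  expect_error(duplicate_pair(numeric(0), a), "empty")
})

test_that("qc_report applies the gates and drops the lower-count duplicate", {
  eth <- toy_ethogram(1)
  span <- c(0, 120)
  t <- seq(0.1, 119, by = 0.3)
  good <- spike_train("good", t, span = span)
  # a partial re-detection of the same unit: fewer spikes, sub-ms offsets
  dup <- spike_train("dup", t[seq(1, length(t), by = 2)] + 0.0004,
                     span = span)
  # a contaminated unit (150 ms away from "good", so not its duplicate)
  # with a refractory violation at every spike
  violator <- spike_train("violator", sort(c(t + 0.15, t + 0.1508)),
                          span = span)
  s <- session(list(good, dup, violator), eth)
  rep <- qc_report(s)
  expect_true(rep$kept[rep$unit_id == "good"])
  expect_false(rep$kept[rep$unit_id == "dup"])
  expect_equal(rep$duplicate_of[rep$unit_id == "dup"], "good")
  expect_false(rep$kept[rep$unit_id == "violator"])
  expect_gt(rep$isi_violation_fraction[rep$unit_id == "violator"], 0.01)
})
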