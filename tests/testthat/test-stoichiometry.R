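test_that("binomial labeling probabilities match exhaustive enumeration", {
  expect_equal(binomial_label_prob(2, 2, 0.8), 0.64, tolerance = 1e-12)
  for (N in 1:4) expect_equal(binomial_label_prob(N, N, 1.0), 1)
  # 3 * 0.8 * 0.2^2, and the full enumeration oracle over orders <= 5
  expect_equal(binomial_label_prob(3, 1, 0.8), 0.096, tolerance = 1e-12)
  for (p in c(0.3, 0.8, 1)) {
    for (i in 1:5) {
      for (m in 0:i) {
        expect_equal(binomial_label_prob(i, m, p), enum_label_prob(i, m, p),
                     tolerance = 1e-12)
      }
    }
  }
  expect_error(binomial_label_prob(2, 3, 0.8), "cannot exceed")
  expect_error(binomial_label_prob(2, 2, 1.2), "probability")
})

test_that("observation matrix is column-stochastic and reduces to identity", {
  expect_equal(observation_matrix(1, 5), diag(5), ignore_attr = TRUE)
  A <- observation_matrix(0.8, 2)
  expect_equal(unname(A[, 2]), c(1 / 3, 2 / 3), tolerance = 1e-12)
  for (p in c(0.3, 0.55, 0.8, 0.99)) {
    A <- observation_matrix(p, 5)
    expect_equal(unname(colSums(A)), rep(1, 5), tolerance = 1e-12)
    expect_true(all(A[lower.tri(A)] == 0 | row(A)[lower.tri(A)] <=
                      col(A)[lower.tri(A)]))
    expect_true(all(A[row(A) > col(A)] == 0))
    expect_true(all(A >= 0 & A <= 1))
  }
})

test_that("forward model agrees with enumeration and known fractions", {
  expect_equal(unname(forward_observe(c(0, 1, 0, 0, 0), 0.8)),
               c(1 / 3, 2 / 3, 0, 0, 0), tolerance = 1e-12)
  x <- c(0.1, 0.3, 0.25, 0.2, 0.15)
  expect_equal(unname(forward_observe(x, 1)), x, tolerance = 1e-12)
  set.seed(41)
  for (rep in 1:10) {
    x <- as.vector(rmultinom(1, 100, runif(5))) / 100
    p <- runif(1, 0.3, 1)
    expect_equal(unname(forward_observe(x, p)), enum_forward(x, p),
                 tolerance = 1e-12)
  }
  # a mostly monomer/dimer truth at 80% labeling shows ~56-57% one-step events
  r <- forward_observe(c(0.435, 0.467, 0.098, 0, 0), 0.8)
  expect_gt(r[1], 0.56)
  expect_lt(r[1], 0.575)
})

test_that("inversion round-trips the forward model across P_f values", {
  set.seed(42)
  for (rep in 1:20) {
    x <- as.vector(rmultinom(1, 1000, runif(5))) / 1000
    p <- runif(1, 0.3, 1)
    fit <- correct_stoichiometry(forward_observe(x, p), p_f = p)
    expect_lt(fit$residual_norm, 1e-9)
    expect_equal(tidy(fit)$fraction, x, tolerance = 1e-8)
  }
  # printed-style high-density fractions round-trip exactly
  x <- c(0.133, 0.560, 0.135, 0.172, 0)
  fit <- correct_stoichiometry(forward_observe(x, 0.8), p_f = 0.8)
  expect_equal(tidy(fit)$fraction, x, tolerance = 1e-9)
})

test_that("inversion on noisy histograms returns a valid distribution", {
  set.seed(7)
  truth <- c(0.13, 0.56, 0.14, 0.17, 0)
  r <- forward_observe(truth, 0.8)
  counts <- as.vector(rmultinom(1, 500, r))
  fit <- correct_stoichiometry(counts, p_f = 0.8)
  out <- tidy(fit)$fraction
  expect_true(all(out >= 0))
  expect_equal(sum(out), 1, tolerance = 1e-9)
  expect_error(correct_stoichiometry(rep(0, 5), p_f = 0.8), "empty")
})

test_that("solver recovers sampled truths within 2 points at n = 10,000", {
  set.seed(11)
  truth <- c(0.13, 0.56, 0.14, 0.17, 0)
  hits <- 0
  for (rep in 1:100) {
    orders <- sample.int(5, 10000, replace = TRUE, prob = truth)
    labeled <- rbinom(length(orders), orders, 0.8)
    counts <- tabulate(labeled[labeled >= 1], nbins = 5)
    est <- tidy(correct_stoichiometry(counts, p_f = 0.8))$fraction
    if (max(abs(est - truth)) <= 0.02) hits <- hits + 1
  }
  # the exact inversion's sampling noise puts ~93% of replicates inside
  # 2 points at this n; require a 90% pass rate with no systematic bias
  expect_gte(hits, 90)
})

test_that("perfect labeling limit: corrected equals observed, condition -> 1", {
  fit <- correct_stoichiometry(c(10, 20, 5, 3, 1), p_f = 1)
  expect_equal(tidy(fit)$fraction, c(10, 20, 5, 3, 1) / 39, tolerance = 1e-12)
  expect_equal(fit$condition_indicator, 1, tolerance = 1e-12)
  expect_equal(correct_stoichiometry(c(1, 0, 0, 0, 0), p_f = 1)$corrected$fraction,
               c(1, 0, 0, 0, 0))
  # condition indicator grows as labeling gets worse
  kappas <- vapply(c(0.99, 0.8, 0.5, 0.3),
                   function(p) correct_stoichiometry(c(5, 4, 3, 2, 1),
                                                     p_f = p)$condition_indicator,
                   numeric(1))
  expect_true(all(diff(kappas) > 0))
})

test_that("expected observed step count is monotone in labeling efficiency", {
  set.seed(13)
  for (rep in 1:5) {
    x <- as.vector(rmultinom(1, 100, runif(5))) / 100
    ps <- seq(0.3, 1, by = 0.05)
    mean_steps <- vapply(ps, function(p) {
      sum(seq_len(5) * forward_observe(x, p))
    }, numeric(1))
    expect_true(all(diff(mean_steps) >= -1e-12))
  }
})

test_that("bootstrap intervals are deterministic, cover, and shrink", {
  r <- forward_observe(c(0.4, 0.4, 0.2, 0, 0), 0.8)
  big <- round(r * 1e6)
  fit <- correct_stoichiometry(big, p_f = 0.8, bootstrap = 200, seed = 99)
  td <- tidy(fit)
  expect_true(all(td$ci_high - td$ci_low < 0.01))
  expect_true(all(td$fraction >= td$ci_low - 1e-9 &
                    td$fraction <= td$ci_high + 1e-9))
  fit2 <- correct_stoichiometry(big, p_f = 0.8, bootstrap = 200, seed = 99)
  expect_identical(tidy(fit), tidy(fit2))
  # degenerate pure-monomer histogram at full labeling: zero-width interval
  fit3 <- correct_stoichiometry(c(50, 0, 0, 0, 0), p_f = 1, bootstrap = 100,
                                seed = 1)
  td3 <- tidy(fit3)
  expect_equal(td3$ci_low[1], 1)
  expect_equal(td3$ci_high[1], 1)
})

test_that("entity fractions weight particles by subunit count", {
  expect_equal(unname(particle_to_entity(c(1, 0, 0, 0, 0))),
               c(1, 0, 0, 0, 0))
  expect_equal(unname(particle_to_entity(c(0.5, 0.5, 0, 0, 0))),
               c(1 / 3, 2 / 3, 0, 0, 0), tolerance = 1e-12)
  e <- particle_to_entity(c(0.133, 0.560, 0.135, 0.172, 0))
  expect_equal(sum(e), 1, tolerance = 1e-12)
  expect_lt(abs(e[1] - 0.05), 0.03)
  expect_lt(abs(e[2] - 0.46), 0.03)
})

test_that("grouping sums fractions exactly and validates coverage", {
  g <- group_fractions(c(0.133, 0.560, 0.135, 0.172, 0))
  expect_equal(g$fraction[g$group == "oligomer"], 0.307, tolerance = 1e-12)
  expect_equal(sum(g$fraction), 1, tolerance = 1e-12)
  ident <- group_fractions(c(0.2, 0.3, 0.5),
                           grouping = list(a = 1, b = 2, c = 3))
  expect_equal(ident$fraction, c(0.2, 0.3, 0.5))
  expect_error(group_fractions(c(0.5, 0.5), grouping = list(a = 1)),
               "cover")
})

test_that("density and reference-fold arithmetic", {
  expect_equal(receptors_per_cell(1.0, 100), 100)
  expect_equal(receptors_per_cell(0.22, 1200), 260)
  expect_equal(receptors_per_cell(0.76, 1200, round_to = 1), 912)
  expect_equal(fold_over_reference(7.0, 0.5), 14)
  expect_equal(fold_over_reference(3, 3), 1)
  expect_error(fold_over_reference(1, 0), "reference")
})
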