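test_that("enumeration produces the full allocation set with identity included once", {
  tr6 <- simulate_crt(crt_scenario(1, clusters_per_arm = 3), seed = 2)
  S6 <- generate_allocations(tr6, permutation_plan(enumerate = TRUE))
  expect_equal(nrow(S6), choose(6, 3))
  expect_true(attr(S6, "exact"))
  expect_equal(nrow(unique(S6)), nrow(S6))

  tr4 <- simulate_crt(crt_scenario(1, clusters_per_arm = 2), seed = 2)
  S4 <- generate_allocations(tr4, permutation_plan(enumerate = TRUE))
  expect_equal(nrow(S4), choose(4, 2))
  obs <- permcrt:::observed_allocation(tr4)
  expect_equal(sum(apply(S4, 1, function(s) all(s == obs[colnames(S4)]))), 1L)
})

test_that("allocation sampling is seeded and arm-size preserving", {
  trial <- simulate_crt(crt_scenario(2), seed = 3)
  S1 <- generate_allocations(trial, permutation_plan(M = 100, seed = 42))
  S2 <- generate_allocations(trial, permutation_plan(M = 100, seed = 42))
  expect_identical(S1, S2)
  expect_true(all(rowSums(S1) == 7))
  expect_error(generate_allocations(trial, permutation_plan(enumerate = TRUE, cap = 100)),
               class = "permcrt_argument_error")
  expect_error(generate_allocations(trial,
                                    permutation_plan(allocations = list(c("1", "2")))),
               class = "permcrt_argument_error")
})

test_that("the identity allocation reproduces the observed statistics", {
  trial <- simulate_crt(crt_scenario(2, clusters_per_arm = 3), seed = 7)
  fits <- suppressMessages(lapply(outcome_specs(trial), fit_nuisance,
                                  data = trial))
  pr <- permutation_matrix(trial, fits, plan = permutation_plan(enumerate = TRUE))
  obs <- permcrt:::observed_allocation(trial)
  S <- generate_allocations(trial, permutation_plan(enumerate = TRUE))
  idrow <- which(apply(S, 1, function(s) all(s == obs[colnames(S)])))
  expect_equal(unname(pr$permuted[idrow, ]), unname(pr$observed))
})

test_that("permuted statistics pair antisymmetrically in parallel designs", {
  trial <- simulate_crt(crt_scenario(1, clusters_per_arm = 3), seed = 9)
  fit <- suppressMessages(fit_nuisance(trial, outcome_specs(trial)$y1))
  pr <- permutation_matrix(trial, list(fit), plan = permutation_plan(enumerate = TRUE))
  S <- generate_allocations(trial, permutation_plan(enumerate = TRUE))
  compl <- apply(S, 1, function(s)
    which(apply(S, 1, function(z) all(z == !s))))
  expect_equal(pr$permuted[compl, 1], -pr$permuted[, 1], tolerance = 1e-12)
  expect_equal(mean(pr$permuted[, 1]), 0, tolerance = 1e-12)
})

test_that("Monte-Carlo p-values agree with exact enumeration", {
  trial <- simulate_crt(crt_scenario(1, clusters_per_arm = 3,
                                     delta = c(0.4, 0)), seed = 21)
  fits <- suppressMessages(lapply(outcome_specs(trial), fit_nuisance,
                                  data = trial))
  exact <- permutation_matrix(trial, fits, plan = permutation_plan(enumerate = TRUE))
  M <- 10000
  mc <- permutation_matrix(trial, fits, plan = permutation_plan(M = M, seed = 5))
  for (j in 1:2) {
    se <- sqrt(exact$p_raw[j] * (1 - exact$p_raw[j]) / M)
    expect_lt(abs(mc$p_raw[j] - exact$p_raw[j]), 3 * se + 2 / (M + 1))
  }
})

test_that("mc_pvalue matches the add-one estimator and its bounds", {
  expect_equal(mc_pvalue(5, rnorm(19)), 1 / 20)
  expect_equal(mc_pvalue(0.1, rep(3, 50)), 1)
  expect_equal(mc_pvalue(0, rnorm(99)), 1)
  expect_equal(mc_pvalue(2, c(rep(0.5, 8), 2.5), sidedness = "greater"), 2 / 10)
  expect_equal(mc_pvalue(-2, c(rep(0.5, 8), -2.5), sidedness = "less"), 2 / 10)
  expect_error(mc_pvalue(NaN, rnorm(5)), class = "permcrt_argument_error")
  p <- replicate(20, mc_pvalue(rnorm(1), rnorm(30)))
  expect_true(all(p >= 1 / 31 & p <= 1))
})

test_that("null p-values are uniform on the enumeration grid", {
  # known nuisance (no fitting): the test is an exact randomization test,
  # so ranks of the observed statistic are uniform over replicates
  n_reps <- 400
  p <- numeric(n_reps)
  sc <- crt_scenario(1, clusters_per_arm = 4, n_per_cluster = 5)
  for (i in seq_len(n_reps)) {
    trial <- simulate_crt(sc, seed = 5000 + i)
    fit <- make_fit(trial, name = "y1", mu0 = 1)
    pr <- permutation_matrix(trial, list(fit),
                             plan = permutation_plan(enumerate = TRUE))
    p[i] <- pr$p_raw[[1]]
  }
  grid_means <- c(mean(p <= 0.25), mean(p <= 0.5), mean(p <= 0.75))
  se <- sqrt(c(0.25, 0.5, 0.75) * c(0.75, 0.5, 0.25) / n_reps)
  expect_true(all(abs(grid_means - c(0.25, 0.5, 0.75)) < 3 * se + 2 / choose(8, 4)))
})
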