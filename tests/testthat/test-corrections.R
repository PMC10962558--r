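test_that("Bonferroni and Holm follow their closed forms", {
  perm <- fake_perm(c(y1 = 2.5, y2 = 2.0),
                    matrix(rnorm(200), 100))
  perm$p_raw <- c(y1 = 0.01, y2 = 0.04)  # fixed raw p for the formula check
  bf <- adjust_pvalues(perm, "bonferroni")
  hm <- adjust_pvalues(perm, "holm")
  expect_equal(bf$results$p_adj, c(0.02, 0.08))
  expect_equal(hm$results$p_adj, c(0.02, 0.04))

  perm$p_raw <- c(y1 = 0.6, y2 = 0.7)
  expect_equal(adjust_pvalues(perm, "bonferroni")$results$p_adj, c(1, 1))

  none <- adjust_pvalues(perm, "none")
  expect_equal(none$results$p_adj, unname(perm$p_raw))
})

test_that("all corrections reduce to the raw test for a single hypothesis", {
  set.seed(31)
  perm <- fake_perm(c(y = 1.9), matrix(rnorm(499), ncol = 1))
  for (m in c("romano_wolf", "holm", "bonferroni", "none")) {
    res <- adjust_pvalues(perm, m)
    expect_equal(res$results$p_adj, unname(perm$p_raw), info = m)
  }
})

test_that("Romano-Wolf equals the brute-force subset-max stepdown", {
  # enumerated toy design
  trial <- simulate_crt(crt_scenario(1, clusters_per_arm = 3,
                                     delta = c(0.5, 0)), seed = 17)
  fits <- suppressMessages(lapply(outcome_specs(trial), fit_nuisance,
                                  data = trial))
  pr <- permutation_matrix(trial, fits, plan = permutation_plan(enumerate = TRUE))
  rw <- romano_wolf_stepdown(pr, 0.05)
  expect_equal(rw$results$p_adj,
               rw_bruteforce(pr$observed, pr$permuted, exact = TRUE))

  # Monte-Carlo matrices with more hypotheses, several seeds
  for (s in 1:5) {
    set.seed(100 + s)
    J <- 4; M <- 200
    obs <- rnorm(J, sd = 1.5)
    permuted <- matrix(rnorm(M * J), M)
    perm <- fake_perm(obs, permuted)
    rw <- romano_wolf_stepdown(perm, 0.05)
    expect_equal(rw$results$p_adj, rw_bruteforce(obs, permuted))
  }
})

test_that("perfectly dependent outcomes share the single-outcome p-value", {
  set.seed(23)
  M <- 400
  col <- rnorm(M)
  perm <- fake_perm(c(y1 = 1.7, y2 = 1.7), cbind(col, col))
  rw <- romano_wolf_stepdown(perm, 0.05)
  single <- mc_pvalue(1.7, col)
  expect_equal(rw$results$p_adj, rep(single, 2))
})

test_that("stepdown p-values are monotone and decisions match the level", {
  set.seed(29)
  for (s in 1:10) {
    J <- sample(2:5, 1)
    perm <- fake_perm(rnorm(J, sd = 2), matrix(rnorm(300 * J), 300))
    rw <- romano_wolf_stepdown(perm, 0.05)
    res <- rw$results[order(rw$results$step), ]
    expect_true(all(diff(res$p_adj) >= -1e-12))
    expect_equal(res$rejected, res$p_adj <= 0.05)
    expect_true(all(res$p_adj >= 1 / 301 & res$p_adj <= 1))
    # a rejection further down the order implies all earlier rejected
    if (any(res$rejected)) expect_true(all(res$rejected[seq_len(max(which(res$rejected)))]))
  }
})

test_that("adjusted p-values order romano_wolf <= holm <= bonferroni under dependence", {
  # strict ordering is a population statement; with Monte-Carlo matrices it
  # holds up to resampling noise, tightly so under positive dependence
  set.seed(37)
  M <- 2000
  for (s in 1:10) {
    J <- 3
    z <- rnorm(M)
    permuted <- sqrt(0.8) * matrix(z, M, J) + sqrt(0.2) * matrix(rnorm(M * J), M)
    shared <- rnorm(1)
    obs <- sqrt(0.8) * shared + sqrt(0.2) * rnorm(J)
    perm <- fake_perm(obs, permuted)
    p_rw <- romano_wolf_stepdown(perm, 0.05)$results$p_adj
    p_holm <- adjust_pvalues(perm, "holm")$results$p_adj
    p_bonf <- adjust_pvalues(perm, "bonferroni")$results$p_adj
    expect_true(all(p_rw <= p_holm + 3 / (M + 1)))
    expect_true(all(p_holm <= p_bonf + 1e-12))
  }
})
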