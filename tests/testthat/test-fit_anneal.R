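test_that("propose perturbs one coordinate and reflects at the bounds", {
  state <- c(0.5, 0.5, 0.5)
  lo <- rep(0, 3); hi <- rep(1, 3)
  set.seed(1)
  expect_identical(propose(state, lo, hi, step_sigma = 0), state)
  # a huge positive kick from the upper bound reflects back inside
  set.seed(7)
  for (k in 1:50) {
    cand <- propose(c(0.999, 0.5), c(0, 0), c(1, 1), step_sigma = 0.3)
    expect_true(all(cand >= 0 & cand <= 1))
    expect_equal(sum(cand != c(0.999, 0.5)), 1)
  }
})

test_that("Metropolis rule accepts everything at very high temperature", {
  set.seed(3)
  deltas <- -rexp(2000)
  acc <- vapply(deltas, anneal_accept, logical(1), temperature = 1e12)
  expect_true(all(acc))
  # and rejects large drops when cold
  acc_cold <- vapply(-10 - deltas, anneal_accept, logical(1),
                     temperature = 1e-6)
  expect_false(any(acc_cold))
})

test_that("fit drives a specialist onto its prey", {
  f <- fit(web_specialist(), "pnm", quick_cfg(seed = 2))
  expect_lt(abs(f$lnL - log(niche_constants()$a)), 1e-6)
  expect_equal(unname(f$params$c[1]), unname(f$params$n[2]))
})

test_that("fit is deterministic given the seed and records a sane result", {
  w <- generate_niche_web(8, 0.2, seed = 31)$web
  f1 <- fit(w, "pnm", quick_cfg(seed = 11))
  f2 <- fit(w, "pnm", quick_cfg(seed = 11))
  expect_identical(f1$params, f2$params)
  expect_identical(f1$lnL, f2$lnL)
  expect_identical(f1$trace, f2$trace)
  # reported lnL is re-evaluated from the returned parameters
  expect_equal(f1$lnL,
               log_likelihood(probability_matrix(f1$params, f1$mask), w))
  expect_equal(f1$aic, 2 * f1$k - 2 * f1$lnL)
  # best-so-far trace never decreases
  expect_true(all(diff(f1$trace) >= 0))
})

test_that("fit rejects webs without consumers and the random spec", {
  w <- food_web(matrix(0, 3, 3))
  expect_error(fit(w, "pnm"), "no consumers")
  expect_error(fit(web_specialist(), "random"), "closed form")
})

test_that("grid oracle finds the specialist optimum and refines monotonically", {
  w <- web_specialist()
  g <- grid_search_oracle(w, "pnm", resolution = 0.02)
  expect_lt(abs(g$lnL - log(niche_constants()$a)), 1e-6)
  expect_equal(unname(g$params$c[1]), unname(g$params$n[2]))
  expect_equal(unname(g$params$r[1]), niche_constants()$r_floor)
  g_coarse <- grid_search_oracle(w, "pnm", resolution = 0.04)
  expect_gte(g$lnL, g_coarse$lnL)
  expect_error(grid_search_oracle(w, "pnm", resolution = 1e-4), "limit")
})

test_that("annealer reaches the grid-search optimum on a 3-species web", {
  w <- web_generalist3()
  g <- grid_search_oracle(w, "pnm", resolution = 0.05)
  f <- fit(w, "pnm", anneal_config(stages = 80, restarts = 3, seed = 2))
  expect_gte(f$lnL, g$lnL - 1e-2)
})

test_that("fitting recovers the niche axis of a simulated web", {
  sw <- generate_niche_web(20, 0.2, seed = 11)
  pw <- generate_pnm_web(sw$true_params, seed = 12)
  mask <- constraint_mask(pw$web)
  lnl_true <- log_likelihood(probability_matrix(sw$true_params, mask), pw$web)
  f <- fit(pw$web, "pnm", anneal_config(restarts = 5, seed = 42))
  expect_gte(f$lnL, lnl_true - 1e-6)
  cons <- !mask$producer
  rho <- cor(f$params$n[cons], sw$true_params$n[cons], method = "spearman")
  expect_gte(abs(rho), 0.9)
})
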