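test_that("allometric_niche normalizes log mass onto [0, 1]", {
  expect_equal(unname(allometric_niche(c(1, 10, 100))), c(0, 0.5, 1))
  expect_equal(unname(allometric_niche(c(2, 8, 32))), c(0, 0.5, 1))
  m <- c(0.003, 12, 7, 950, 0.4)
  n <- allometric_niche(m)
  expect_equal(n[which.min(m)], 0)
  expect_equal(n[which.max(m)], 1)
  expect_identical(order(n), order(m))
  # invariant to a global rescaling of mass
  expect_equal(allometric_niche(m * 1e6), n)
  expect_error(allometric_niche(c(5, 5, 5)), "degenerate")
  expect_error(allometric_niche(c(1, -1)), "positive")
})

test_that("model_spec validates names and coefficients", {
  expect_s3_class(model_spec("pnm"), "model_spec")
  expect_error(model_spec("cascade"))
  expect_error(model_spec("pnm", coefficients = c(r0 = 1)), "no coupling")
  expect_error(model_spec("r_of_c", coefficients = c(c0 = 1)), "needs")
})

test_that("expand_params applies couplings and constraints", {
  # exponential coupling at c = 0 gives r = r0
  sp <- model_spec("r_of_c", coefficients = c(r0 = 0.1, r1 = 2))
  ex <- expand_params(sp, c(0.5, 0.2, 0, 0.7), S = 2)  # n1 n2 c1 c2
  expect_equal(unname(ex$params$r), c(0.1, 0.1 * exp(2 * 0.7)))

  # linear diet-position coupling
  sp2 <- model_spec("c_of_n", coefficients = c(c0 = 0, c1 = 0.5))
  rf <- niche_constants()$r_floor
  ex2 <- expand_params(sp2, c(0.2, 0.8, 0.3, 0.4), S = 2)  # n1 n2 r1 r2
  expect_equal(unname(ex2$params$c), c(0.1, 0.4))

  # linear range coupling, hand arithmetic
  sp3 <- model_spec("r_of_n", coefficients = c(r0 = 0.05, r1 = 0.5))
  ex3 <- expand_params(sp3, c(0.9, 0.1, 0.2, 0.3), S = 2)  # n1 n2 c1 c2
  expect_equal(unname(ex3$params$r[1]), 0.5)

  # producer/specialist fixing through the mask
  w <- web_specialist()
  mask <- constraint_mask(w)
  ex4 <- expand_params("pnm", c(0.7, 0.2, 0.2), S = 2, mask = mask)
  expect_equal(unname(ex4$params$c[2]), 0)   # producer
  expect_equal(unname(ex4$params$r), c(rf, rf))  # specialist + producer

  expect_error(expand_params("pnm", c(0.5, 0.5), S = 2), "length")
})

test_that("random_model reproduces the closed form", {
  r <- random_model(29, 203)
  expect_equal(r$p, 203 / 841)
  expect_equal(round(r$aic), 932)
  expect_equal(r$aic, 931.6, tolerance = 1e-4)
  expect_equal(r$k, 1L)

  r2 <- random_model(2, 2)
  expect_equal(r2$p, 0.5)
  expect_equal(r2$lnL, 4 * log(0.5))

  expect_error(random_model(3, 0), "degenerate")
  expect_error(random_model(3, 9), "degenerate")
})

test_that("random_model lnL equals log_likelihood on the constant matrix", {
  for (seed in 1:3) {
    w <- random_web(11, 30, seed = seed)
    r <- random_model(11, 30)
    expect_equal(r$lnL, log_likelihood(matrix(r$p, 11, 11), w))
  }
})

test_that("variant fits never beat the full model on the same web", {
  sw <- generate_niche_web(12, 0.22, seed = 21)
  pw <- generate_pnm_web(sw$true_params, seed = 22)
  web <- food_web(pw$web$A,
                  body_mass = generate_body_masses(sw$true_params$n, seed = 23))
  cfg <- quick_cfg(seed = 5, stages = 100, restarts = 3)
  full <- fit(web, "pnm", cfg)
  st <- web_stats(web)
  expect_gte(full$lnL, random_model(st$S, st$L)$lnL)
  for (m in c("anm", "r_of_c", "c_of_n", "c_and_r_of_n")) {
    reduced <- fit(web, m, cfg)
    expect_lte(reduced$lnL, full$lnL + 1e-6)
  }
})
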