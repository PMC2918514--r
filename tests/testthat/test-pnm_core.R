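test_that("link_probability follows the Gaussian kernel", {
  a <- niche_constants()$a
  # resource exactly on the feeding optimum
  expect_equal(link_probability(0.5, 0.5, 0.3), a)
  # half a range away: a / e
  expect_equal(link_probability(0.5 + 0.1, 0.5, 0.2), a * exp(-1))
  # hand evaluation: ((0.6 - 0.3) / 0.1)^2 = 9
  expect_equal(link_probability(0.6, 0.3, 0.2), a * exp(-9))
  # floor clamp far away
  expect_equal(link_probability(1, 0, 1e-3), niche_constants()$p_floor)
  # strictly decreasing in |n - c|
  d <- seq(0, 0.5, by = 0.05)
  p <- link_probability(0.5 + d, 0.5, 0.4)
  expect_true(all(diff(p) < 0))
  expect_error(link_probability(0.5, 0.5, 0), "positive")
  expect_error(link_probability(0.5, 0.5, -1), "positive")
})

test_that("probability_matrix matches element-wise link_probability", {
  p <- random_params(4, seed = 8)
  P <- probability_matrix(p)
  for (i in 1:4) for (j in 1:4) {
    expect_equal(P[i, j], link_probability(p$n[j], p$c[i], p$r[i]))
  }
})

test_that("probability_matrix applies producer and specialist constraints", {
  pf <- niche_constants()$p_floor
  # all-producer web: every entry floored
  w <- food_web(matrix(0, 3, 3))
  mask <- constraint_mask(w)
  p <- random_params(3, seed = 1)
  expect_true(all(probability_matrix(p, mask) == pf))

  # specialist centred on its prey: near-a entry, rest floored
  ws <- web_specialist()
  m2 <- constraint_mask(ws)
  p2 <- param_set(n = c(0.9, 0.3), c = c(0.3, 0), r = c(0.5, 1e-6))
  P2 <- probability_matrix(p2, m2)
  expect_equal(P2[1, 2], niche_constants()$a)
  expect_equal(P2[1, 1], pf)  # own column is far away at r_floor
  expect_true(all(P2[2, ] == pf))

  expect_error(probability_matrix(p2, constraint_mask(web_generalist3())),
               "does not match")
})

test_that("constraint_mask identifies producers, specialists and their prey", {
  w <- web_generalist3()
  m <- constraint_mask(w)
  expect_identical(m$producer, c(FALSE, TRUE, TRUE))
  expect_identical(m$specialist, c(FALSE, FALSE, FALSE))
  ms <- constraint_mask(web_specialist())
  expect_identical(ms$specialist, c(TRUE, FALSE))
  expect_identical(ms$specialist_prey, c(2L, NA_integer_))
})

test_that("log_likelihood matches hand-computed sums", {
  pf <- niche_constants()$p_floor
  a <- niche_constants()$a
  # empty web, all probabilities floored: essentially 0
  A0 <- matrix(0L, 5, 5)
  P0 <- matrix(pf, 5, 5)
  expect_equal(log_likelihood(P0, A0), 25 * log1p(-pf))

  # four-term hand sum on a 2x2 web
  A <- rbind(c(0L, 1L), c(0L, 0L))
  P <- rbind(c(pf, a), c(pf, pf))
  expect_equal(log_likelihood(P, A), log(a) + 3 * log1p(-pf))

  # uniform p = L / S^2 closed form at S = 29, L = 203
  w <- random_web(29, 203, seed = 6)
  C <- 203 / 841
  lnl <- log_likelihood(matrix(C, 29, 29), w)
  expect_equal(lnl, 841 * (C * log(C) + (1 - C) * log(1 - C)))
  expect_equal(lnl, -464.79, tolerance = 1e-4)

  expect_error(log_likelihood(matrix(1, 2, 2), A), "strictly inside")
  expect_error(log_likelihood(matrix(0.5, 3, 3), A), "same shape")
})

test_that("log_likelihood is non-positive and improves toward the data", {
  for (seed in 1:4) {
    w <- random_web(8, 14, seed = seed)
    p <- random_params(8, seed = seed + 10)
    P <- probability_matrix(p, constraint_mask(w))
    lnl <- log_likelihood(P, w)
    expect_lte(lnl, 0)
    # moving one entry toward the observation strictly increases lnL
    ij <- which(w$A == 1L, arr.ind = TRUE)[1, ]
    P2 <- P
    P2[ij[1], ij[2]] <- (P[ij[1], ij[2]] + 0.9999) / 2
    expect_gt(log_likelihood(P2, w), lnl)
  }
})

test_that("lnL is invariant under reflection of the niche axis", {
  for (seed in 1:6) {
    w <- random_web(10, 22, seed = seed)
    mask <- constraint_mask(w)
    p <- random_params(10, seed = seed + 50)
    refl <- param_set(1 - p$n, 1 - p$c, p$r)
    l1 <- log_likelihood(probability_matrix(p, mask), w)
    l2 <- log_likelihood(probability_matrix(refl, mask), w)
    expect_equal(l1, l2)
  }
})

test_that("a perfectly centred all-specialist web reaches L * log(a)", {
  S <- 6
  n <- seq(0.05, 0.95, length.out = S)
  A <- matrix(0L, S, S)
  prey <- c(2:S, 1)  # ring of specialists
  A[cbind(1:S, prey)] <- 1L
  w <- food_web(A)
  p <- param_set(n, c = n[prey], r = rep(niche_constants()$r_floor, S))
  lnl <- log_likelihood(probability_matrix(p, constraint_mask(w)), w)
  expect_lt(abs(lnl - S * log(niche_constants()$a)), 1e-6)
})

test_that("aic is 2k - 2 lnL", {
  expect_equal(aic(0, 0), 0)
  expect_equal(aic(-10, 2), 24)
  expect_equal(round(aic(random_model(29, 203)$lnL, 1)), 932)
  expect_error(aic(-1, -1), ">= 0")
})

test_that("nominal parameter counts match the model family", {
  expect_equal(count_parameters("pnm", 29), 87)
  expect_equal(count_parameters("anm", 29), 58)
  expect_equal(count_parameters("c_and_r_of_n", 29), 33)
  expect_equal(count_parameters("r_of_c", 29), 60)
  expect_equal(count_parameters("r_of_n", 29), 60)
  expect_equal(count_parameters("c_of_n", 29), 60)
  expect_equal(count_parameters("random", 29), 1)
  expect_error(count_parameters("cascade", 29), "unknown")
})
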