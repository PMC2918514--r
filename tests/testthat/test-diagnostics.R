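test_that("derived_ratios computes x = r/n and c' = c/n with guards", {
  p <- param_set(n = c(0.5, 0, 1), c = c(0.4, 0.2, 1), r = c(0.25, 0.1, 0.3))
  rt <- derived_ratios(p)
  expect_equal(rt$x[1], 0.5)
  expect_equal(rt$c_prime[1], 0.8)
  expect_true(is.na(rt$x[2]) && is.na(rt$c_prime[2]))  # n = 0
  expect_equal(rt$c_prime[3], 1)  # c = n: hierarchical boundary
})

test_that("correlation_table recovers monotone relationships", {
  set.seed(4)
  n <- sort(runif(20))
  p <- param_set(n, c = clamp_unit(n * 0.8), r = 1 - 0.9 * n)
  tab <- correlation_table(p, body_mass = 10^(2 * n))
  expect_s3_class(tab, "data.frame")
  expect_equal(nrow(tab), 10)
  get <- function(pair) tab[tab$pair == pair, ]
  expect_equal(get("n, c")$rho, 1)
  expect_equal(get("n, r")$rho, -1)
  expect_equal(get("n, body mass")$rho, 1)
  expect_true(get("n, c")$significant)
  # mass pairs dropped without masses
  tab2 <- correlation_table(p)
  expect_equal(nrow(tab2), 5)
  expect_error(correlation_table(param_set(1:3 / 4, 1:3 / 4, rep(0.1, 3))),
               "fewer than 4")
})

test_that("Spearman rho matches a brute-force rank computation", {
  set.seed(9)
  a <- runif(5); b <- runif(5)
  p <- param_set(n = a, c = b, r = runif(5, 0.1, 1))
  tab <- correlation_table(p)
  ra <- rank(a); rb <- rank(b)
  rho_hand <- sum((ra - mean(ra)) * (rb - mean(rb))) /
    sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
  expect_equal(tab$rho[tab$pair == "n, c"], rho_hand)
})

test_that("Spearman rho is invariant under monotone transforms", {
  set.seed(12)
  n <- runif(15)
  mass <- 10^(3 * n + rnorm(15, 0, 0.2))
  p <- param_set(n, clamp_unit(0.7 * n), pmax(0.05, 0.5 * n + 0.01))
  t_raw <- correlation_table(p, body_mass = mass)
  t_cube <- correlation_table(p, body_mass = mass^3)
  expect_equal(t_raw$rho, t_cube$rho)
})

test_that("BH control rejects a superset of Bonferroni and none at p = 1", {
  p <- c(1e-6, 2e-4, 0.01, 0.04, 0.2, 0.6, 1, 1, 1, 1)
  bh <- p.adjust(p, "BH") <= 0.05
  bonf <- p.adjust(p, "bonferroni") <= 0.05
  expect_true(all(bh[bonf]))
  expect_true(sum(bh) >= sum(bonf))
  expect_false(any(p.adjust(rep(1, 10), "BH") <= 0.05))
})

test_that("distribution_tests behave under their generating models", {
  set.seed(30)
  m <- 1000
  n <- runif(m)
  r <- pmax(rexp(m, rate = 1 / 0.7), niche_constants()$r_floor)
  p <- param_set(n, c = clamp_unit(0.8 * n), r = r)
  dt <- distribution_tests(p)
  expect_gt(dt$n_uniform$p, 0.05)           # uniform null holds
  expect_equal(dt$r_exponential$beta, 0.7, tolerance = 0.1)
  expect_gt(dt$r_exponential$p, 0.01)
  expect_lte(dt$cprime_uniform$p, 1)
  # c' > 1 values are excluded, and exclusion can empty the sample
  p_bad <- param_set(n = rep(0.1, 6), c = rep(0.9, 6), r = rep(0.1, 6))
  expect_error(distribution_tests(p_bad), "excluding")
})

test_that("pca_variance finds collinearity and normalizes to 1", {
  n <- seq(0.1, 0.9, length.out = 10)
  collinear <- param_set(n, n, pmax(n, 0.05))
  v <- pca_variance(collinear)
  expect_equal(v[1], 1)
  expect_equal(sum(v), 1)
  set.seed(2)
  iso <- param_set(runif(600), runif(600), runif(600, 0.05, 1))
  vi <- pca_variance(iso)
  expect_equal(sum(vi), 1)
  expect_true(all(abs(vi - 1 / 3) < 0.08))
  expect_error(pca_variance(param_set(rep(0.5, 5), runif(5), runif(5, 0.1, 1))),
               "degenerate")
})
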