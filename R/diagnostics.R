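# Post-fit analysis of MLE parameters: derived ratios, distribution
# tests, rank correlations with body mass, multiple-testing control.
#
# Producers are dropped from the correlation and distribution analyses
# when a constraint mask is supplied: their diet position and range are
# fixed by convention, not estimated, so they carry no information about
# the fitted parameter distributions.

#' Range-to-position and relative diet-position ratios
#'
#' `x = r / n` and `c' = c / n`, per species. `c' = 1` marks the boundary
#' of hierarchical ordering (diet centred exactly on the species' own
#' niche position); `c' < 1` is a diet below the species. Ratios are
#' undefined (`NA`) for species with `n <= n_eps`.
#'
#' @param params A [param_set()].
#' @param n_eps Threshold below which a niche position counts as zero.
#' @return List of class `ratio_set` with numeric vectors `x` and
#'   `c_prime`.
#' @export
derived_ratios <- function(params, n_eps = .nf$n_eps) {
  ok <- params$n > n_eps
  x <- ifelse(ok, params$r / params$n, NA_real_)
  cp <- ifelse(ok, params$c / params$n, NA_real_)
  structure(list(x = x, c_prime = cp), class = "ratio_set")
}

.pair_defs <- function(params, ratios, body_mass) {
  lm_ <- if (is.null(body_mass)) NULL else log10(body_mass)
  list(
    "n, c"          = list(params$n, params$c),
    "n, r"          = list(params$n, params$r),
    "c, r"          = list(params$c, params$r),
    "n, body mass"  = list(params$n, lm_),
    "c, body mass"  = list(params$c, lm_),
    "r, body mass"  = list(params$r, lm_),
    "n, x"          = list(params$n, ratios$x),
    "x, body mass"  = list(ratios$x, lm_),
    "n, c'"         = list(params$n, ratios$c_prime),
    "c', body mass" = list(ratios$c_prime, lm_)
  )
}

#' Spearman correlations among parameters, ratios and body mass
#'
#' The ten canonical pairs: (n,c), (n,r), (c,r), (n,mass), (c,mass),
#' (r,mass), (n,x), (x,mass), (n,c'), (c',mass). Body mass enters on the
#' log scale, which is irrelevant for a rank correlation but matches how
#' the masses are plotted. Missing entries are dropped pairwise;
#' significance is flagged by Benjamini-Hochberg false-discovery-rate
#' control across the table.
#'
#' @param params A [param_set()].
#' @param ratios A [derived_ratios()] result; computed if `NULL`.
#' @param body_mass Optional positive masses; mass pairs are omitted when
#'   absent.
#' @param alpha FDR level (default 0.05).
#' @param mask Optional [constraint_mask()]; producers are excluded.
#' @return A data.frame of class `correlation_table` with columns `pair`,
#'   `rho`, `p`, `p_bh`, `significant`, `n_obs`.
#' @export
correlation_table <- function(params, ratios = NULL, body_mass = NULL,
                              alpha = 0.05, mask = NULL) {
  if (is.null(ratios)) ratios <- derived_ratios(params)
  keep <- if (is.null(mask)) rep(TRUE, length(params$n)) else !mask$producer
  sub <- function(v) if (is.null(v)) NULL else v[keep]
  p2 <- list(n = sub(params$n), c = sub(params$c), r = sub(params$r),
             a = params$a)
  r2 <- list(x = sub(ratios$x), c_prime = sub(ratios$c_prime))
  pairs <- .pair_defs(p2, r2, sub(body_mass))
  pairs <- Filter(function(p) !is.null(p[[2]]) && !is.null(p[[1]]), pairs)
  rows <- lapply(names(pairs), function(nm) {
    a <- pairs[[nm]][[1]]; b <- pairs[[nm]][[2]]
    ok <- is.finite(a) & is.finite(b)
    if (sum(ok) < 4) {
      stop("fewer than 4 complete observations for pair ", nm)
    }
    ct <- suppressWarnings(cor.test(a[ok], b[ok], method = "spearman"))
    data.frame(pair = nm, rho = unname(ct$estimate), p = ct$p.value,
               n_obs = sum(ok))
  })
  tab <- do.call(rbind, rows)
  tab$p_bh <- p.adjust(tab$p, method = "BH")
  tab$significant <- tab$p_bh <= alpha
  class(tab) <- c("correlation_table", "data.frame")
  tab
}

#' Distribution tests of the fitted parameters
#'
#' Tests the distributional assumptions of the classic niche model
#' against the fitted values: niche positions `n` against Uniform(0, 1)
#' (one-sample Kolmogorov-Smirnov); feeding ranges `r` against an
#' exponential whose scale `beta` is the sample mean (asymptotic K-S, no
#' small-sample correction); and the relative diet position `c'` against
#' Uniform(0, 1) after excluding species with `c' > 1` (the
#' non-hierarchical ones).
#'
#' @param params A [param_set()].
#' @param ratios A [derived_ratios()] result; computed if `NULL`.
#' @param mask Optional [constraint_mask()]; producers are excluded.
#' @param min_n Minimum sample size per test (default 5).
#' @return List of class `distribution_tests` with elements `n_uniform`
#'   (`statistic`, `p`), `r_exponential` (`beta`, `statistic`, `p`) and
#'   `cprime_uniform` (`statistic`, `p`, `n_excluded`).
#' @export
distribution_tests <- function(params, ratios = NULL, mask = NULL,
                               min_n = 5) {
  if (is.null(ratios)) ratios <- derived_ratios(params)
  keep <- if (is.null(mask)) rep(TRUE, length(params$n)) else !mask$producer
  n <- params$n[keep]
  r <- params$r[keep]
  cp <- ratios$c_prime[keep]
  if (length(n) < min_n) stop("fewer than ", min_n, " species for the n test")
  ks_n <- suppressWarnings(ks.test(n, "punif"))
  r <- r[is.finite(r)]
  if (length(r) < min_n) stop("fewer than ", min_n, " ranges for the r test")
  beta <- mean(r)
  ks_r <- suppressWarnings(ks.test(r, "pexp", rate = 1 / beta))
  cp <- cp[is.finite(cp)]
  n_exc <- sum(cp > 1)
  cp <- cp[cp <= 1]
  if (length(cp) < min_n) {
    stop("fewer than ", min_n, " relative diet positions after excluding c' > 1")
  }
  ks_c <- suppressWarnings(ks.test(cp, "punif"))
  structure(list(
    n_uniform = list(statistic = unname(ks_n$statistic), p = ks_n$p.value),
    r_exponential = list(beta = beta, statistic = unname(ks_r$statistic),
                         p = ks_r$p.value),
    cprime_uniform = list(statistic = unname(ks_c$statistic),
                          p = ks_c$p.value, n_excluded = n_exc)
  ), class = "distribution_tests")
}

#' @export
print.distribution_tests <- function(x, ...) {
  cat(sprintf("n ~ U(0,1):      D = %.3f, p = %.3g\n",
              x$n_uniform$statistic, x$n_uniform$p))
  cat(sprintf("r ~ Exp(beta):   beta = %.3f, D = %.3f, p = %.3g\n",
              x$r_exponential$beta, x$r_exponential$statistic,
              x$r_exponential$p))
  cat(sprintf("c' ~ U(0,1):     D = %.3f, p = %.3g (%d excluded with c' > 1)\n",
              x$cprime_uniform$statistic, x$cprime_uniform$p,
              x$cprime_uniform$n_excluded))
  invisible(x)
}

#' Variance explained by the principal axes of (n, c, r)
#'
#' Standardized PCA of the complete (n, c, r) triples; returns the
#' fractions of variance on each principal axis, descending and summing
#' to 1.
#'
#' @param params A [param_set()].
#' @param mask Optional [constraint_mask()]; producers are excluded.
#' @return Numeric vector of length 3.
#' @export
pca_variance <- function(params, mask = NULL) {
  keep <- if (is.null(mask)) rep(TRUE, length(params$n)) else !mask$producer
  M <- cbind(n = params$n, c = params$c, r = params$r)[keep, , drop = FALSE]
  M <- M[stats::complete.cases(M), , drop = FALSE]
  if (nrow(M) < 3) stop("need at least 3 species with complete (n, c, r)")
  sds <- apply(M, 2, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance parameter column; standardized PCA is degenerate")
  }
  pc <- prcomp(M, center = TRUE, scale. = TRUE)
  v <- pc$sdev^2
  v / sum(v)
}
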