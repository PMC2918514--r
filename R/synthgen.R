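# Synthetic food-web generators: classic niche-model webs (interval
# diets, known construction), Bernoulli webs realized from a parameter
# set, and allometrically consistent body masses. These provide ground
# truth for parameter-recovery studies and test fixtures.

#' Generate a web from the classic niche model
#'
#' The classic construction: niche positions `n_i ~ U(0, 1)`; relative
#' range `x_i ~ Beta(1, 1/(2C) - 1)` so that `E[x] = 2C`; feeding range
#' `r_i = x_i * n_i`; diet position `c_i ~ U(r_i / 2, n_i)` (hierarchical
#' ordering, slightly relaxed by half a range); a link `i -> j` exists iff
#' `|n_j - c_i| <= r_i / 2`, so every diet is an exact interval in niche
#' order. The species with the smallest niche position is forced basal
#' (`r = 0`), guaranteeing at least one producer.
#'
#' @param S Species count (>= 2).
#' @param C Target directed connectance, in (0, 0.5).
#' @param seed Integer RNG seed.
#' @return An object of class `synthetic_web`: list with `web`
#'   ([food_web()]), `true_params` ([param_set()]; the basal species gets
#'   `c = 0`, `r = r_floor`), `generator = "niche"` and `seed`.
#' @export
generate_niche_web <- function(S, C, seed = 1L) {
  stopifnot(S >= 2)
  if (C <= 0 || C >= 0.5) {
    stop("target connectance must lie in (0, 0.5) for the beta construction")
  }
  set.seed(seed)
  n <- runif(S)
  beta_shape2 <- 1 / (2 * C) - 1
  x <- rbeta(S, 1, beta_shape2)
  r <- x * n
  basal <- which.min(n)
  r[basal] <- 0
  c_ <- runif(S, r / 2, n)
  c_[basal] <- 0
  A <- matrix(0L, S, S)
  for (i in seq_len(S)) {
    if (r[i] > 0) A[i, ] <- as.integer(abs(n - c_[i]) <= r[i] / 2)
  }
  species <- paste0("sp", seq_len(S))
  dimnames(A) <- list(species, species)
  web <- food_web(A, species = species)
  params <- param_set(n, clamp(c_, 0, 1), pmax(r, .nf$r_floor),
                      species = species)
  structure(list(web = web, true_params = params, generator = "niche",
                 seed = as.integer(seed)),
            class = "synthetic_web")
}

#' Realize a Bernoulli web from a parameter set
#'
#' Draws `A_ij ~ Bernoulli(P_ij)` independently with `P` from
#' [probability_matrix()]. With the default `mask = NULL` the floors in
#' the kernel alone determine the row probabilities.
#'
#' @param params A [param_set()].
#' @param seed Integer RNG seed.
#' @param mask Optional [constraint_mask()] applied when forming `P`.
#' @return An object of class `synthetic_web` with `generator = "pnm"`.
#' @export
generate_pnm_web <- function(params, seed = 1L, mask = NULL) {
  set.seed(seed)
  P <- probability_matrix(params, mask)
  S <- nrow(P)
  A <- matrix(rbinom(S * S, 1L, as.vector(P)), S, S)
  species <- params$species %||% paste0("sp", seq_len(S))
  dimnames(A) <- list(species, species)
  structure(list(web = food_web(A, species = species), true_params = params,
                 generator = "pnm", seed = as.integer(seed)),
            class = "synthetic_web")
}

#' @export
print.synthetic_web <- function(x, ...) {
  st <- web_stats(x$web)
  cat(sprintf("synthetic_web (%s, seed %d): S = %d, L = %d, C = %.3f\n",
              x$generator, x$seed, st$S, st$L, st$C))
  invisible(x)
}

#' Generate body masses consistent with a niche axis
#'
#' Power-law (log-linear) masses:
#' `log10 m_i = intercept + slope * n_i + Normal(0, noise_sd)`. The
#' defaults span roughly bacteria (`1e-13` g) at the bottom of the axis to
#' large pelagic fish (`1e5` g) at the top, the magnitude range of a
#' pelagic marine web, with half a decade of lognormal scatter.
#'
#' @param n Niche positions in `[0, 1]`.
#' @param intercept log10 mass (grams) at `n = 0`.
#' @param slope log10 mass range across the axis.
#' @param noise_sd Lognormal scatter (decades), `>= 0`.
#' @param seed Integer RNG seed.
#' @return Positive masses (grams), named like `n`.
#' @export
#' @examples
#' generate_body_masses(c(0, 0.5, 1), intercept = 0, slope = 2, noise_sd = 0)
generate_body_masses <- function(n, intercept = -13, slope = 18,
                                 noise_sd = 0.5, seed = 1L) {
  stopifnot(noise_sd >= 0)
  set.seed(seed)
  lg <- intercept + slope * n + rnorm(length(n), 0, noise_sd)
  m <- 10^lg
  names(m) <- names(n)
  m
}
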