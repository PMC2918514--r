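# Probabilistic niche model kernel: link probabilities, constraint
# handling, Bernoulli log-likelihood, AIC, nominal parameter counts.

#' Construct a niche-model parameter set
#'
#' Per-species niche position `n`, diet position `c` and feeding range
#' `r`, plus the global peak link probability `a`. The feeding range is a
#' full width: the link probability falls to `a/e` where the resource sits
#' half a range away from the consumer's diet position.
#'
#' @param n,c Numeric vectors in `[0, 1]`, one entry per species.
#' @param r Numeric vector of feeding ranges, `>= r_floor` (see
#'   [niche_constants()]).
#' @param a Global peak probability, in (0, 1); default 0.9999.
#' @param species Optional species names.
#' @return An object of class `param_set`.
#' @export
param_set <- function(n, c, r, a = .nf$a, species = NULL) {
  S <- length(n)
  if (length(c) != S || length(r) != S) {
    stop("n, c and r must have the same length")
  }
  n <- as.numeric(n); c <- as.numeric(c); r <- as.numeric(r)
  if (anyNA(n) || any(n < 0 | n > 1)) stop("niche positions n must lie in [0, 1]")
  if (anyNA(c) || any(c < 0 | c > 1)) stop("diet positions c must lie in [0, 1]")
  if (anyNA(r) || any(r < .nf$r_floor)) {
    stop("feeding ranges r must be >= r_floor = ", .nf$r_floor)
  }
  if (!is.numeric(a) || length(a) != 1L || a <= 0 || a >= 1) {
    stop("peak probability a must lie strictly between 0 and 1")
  }
  if (!is.null(species)) {
    species <- as.character(species)
    if (length(species) != S) stop("species names must have length ", S)
    names(n) <- names(c) <- names(r) <- species
  }
  structure(list(n = n, c = c, r = r, a = a, species = species),
            class = "param_set")
}

#' @export
print.param_set <- function(x, ...) {
  cat(sprintf("param_set: S = %d, a = %g\n", length(x$n), x$a))
  print(utils::head(data.frame(n = x$n, c = x$c, r = x$r), 10))
  if (length(x$n) > 10) cat("...\n")
  invisible(x)
}

#' Producer and specialist constraints of a web
#'
#' Producers (no prey) have their diet position fixed at 0 and feeding
#' range at the floor, which forces all their outgoing link probabilities
#' to the probability floor. Specialists (exactly one prey) have their
#' range pinned at the floor while their diet position stays free, so the
#' fitted diet position converges onto the sole prey's niche position.
#'
#' @param web A [food_web()].
#' @return An object of class `constraint_mask`: list with logical vectors
#'   `producer`, `specialist` and integer vector `specialist_prey` (index
#'   of the sole prey, `NA` for non-specialists).
#' @export
constraint_mask <- function(web) {
  A <- as_adjacency(web)
  R <- unname(rowSums(A))
  producer <- R == 0
  specialist <- R == 1
  prey <- rep(NA_integer_, nrow(A))
  prey[specialist] <- apply(A[specialist, , drop = FALSE], 1, which.max)
  structure(list(producer = producer, specialist = specialist,
                 specialist_prey = prey),
            class = "constraint_mask")
}

empty_mask <- function(S) {
  structure(list(producer = rep(FALSE, S), specialist = rep(FALSE, S),
                 specialist_prey = rep(NA_integer_, S)),
            class = "constraint_mask")
}

#' Gaussian link probability
#'
#' Probability that a consumer with diet position `c_i` and feeding range
#' `r_i` eats a resource at niche position `n_j`:
#' `p = a * exp(-((n_j - c_i) / (r_i / 2))^2)`, floored at `p_floor` so the
#' Bernoulli log-likelihood stays finite. The probability equals `a`
#' exactly when the resource sits on the consumer's feeding optimum and
#' decreases strictly with niche distance.
#'
#' @param n_j Resource niche position(s).
#' @param c_i Consumer diet position(s).
#' @param r_i Consumer feeding range(s), strictly positive.
#' @param a Peak probability; default 0.9999.
#' @param p_floor Lower clamp; default `1e-10`.
#' @return Probabilities in `[p_floor, a]`, vectorized over the inputs.
#' @export
#' @examples
#' link_probability(0.6, 0.3, 0.2)  # 0.9999 * exp(-9)
link_probability <- function(n_j, c_i, r_i, a = .nf$a, p_floor = .nf$p_floor) {
  if (any(r_i <= 0)) stop("feeding range r must be strictly positive")
  pmax(a * exp(-((n_j - c_i) / (r_i / 2))^2), p_floor)
}

#' Link-probability matrix of a parameter set
#'
#' Applies [link_probability()] entry-wise: `P[i, j]` is the probability
#' that consumer `i` eats resource `j`. When a [constraint_mask()] is
#' supplied, producer rows are set to the probability floor everywhere and
#' specialist rows are evaluated with the feeding range pinned at the
#' range floor.
#'
#' @param params A [param_set()].
#' @param mask Optional [constraint_mask()] of matching length.
#' @return An S x S matrix with entries in `[p_floor, a]`.
#' @export
probability_matrix <- function(params, mask = NULL) {
  S <- length(params$n)
  if (!is.null(mask) && length(mask$producer) != S) {
    stop("constraint mask length ", length(mask$producer),
         " does not match S = ", S)
  }
  c_eff <- params$c
  r_eff <- pmax(params$r, .nf$r_floor)
  if (!is.null(mask)) {
    c_eff[mask$producer] <- 0
    r_eff[mask$producer | mask$specialist] <- .nf$r_floor
  }
  d <- outer(c_eff, params$n, function(ci, nj) nj - ci)  # d[i, j] = n_j - c_i
  P <- pmax(params$a * exp(-(d / (r_eff / 2))^2), .nf$p_floor)
  if (!is.null(mask)) P[mask$producer, ] <- .nf$p_floor
  dimnames(P) <- list(params$species, params$species)
  P
}

#' Bernoulli log-likelihood of a web under a probability matrix
#'
#' `sum over all S^2 entries (diagonal included) of
#' A_ij * log(P_ij) + (1 - A_ij) * log(1 - P_ij)`. Always `<= 0`.
#'
#' @param P Probability matrix with entries strictly inside (0, 1).
#' @param web A [food_web()] or 0/1 matrix of the same shape.
#' @return The log-likelihood (scalar).
#' @export
log_likelihood <- function(P, web) {
  A <- as_adjacency(web)
  if (!identical(dim(P), dim(A))) {
    stop("P and the connection matrix must have the same shape")
  }
  if (any(P <= 0) || any(P >= 1)) {
    stop("all link probabilities must lie strictly inside (0, 1)")
  }
  sum(ifelse(A == 1L, log(P), log1p(-P)))
}

#' Akaike information criterion
#'
#' @param lnL Maximized log-likelihood.
#' @param k Number of model parameters, `>= 0`.
#' @return `2 * k - 2 * lnL`.
#' @export
aic <- function(lnL, k) {
  if (k < 0) stop("parameter count k must be >= 0")
  2 * k - 2 * lnL
}

#' Nominal parameter count of a model variant
#'
#' The counting is nominal, per-variant: the full model has 3 free
#' parameters per species (3S), the allometric model 2S (niche positions
#' come from body mass), and each per-species parameter replaced by a
#' global coupling contributes its 2 coefficients instead of S values.
#' Producer/specialist fixing is not subtracted.
#'
#' @param spec A [model_spec()] or variant name.
#' @param S Number of species.
#' @return Integer parameter count `k`.
#' @export
#' @examples
#' count_parameters("pnm", 29)  # 87
count_parameters <- function(spec, S) {
  name <- if (inherits(spec, "model_spec")) spec$name else as.character(spec)
  switch(name,
    pnm           = 3L * S,
    anm           = 2L * S,
    r_of_c        = 2L * S + 2L,
    r_of_n        = 2L * S + 2L,
    c_of_n        = 2L * S + 2L,
    c_and_r_of_n  = S + 4L,
    random        = 1L,
    stop("unknown model variant: ", name)
  )
}
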