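# The model family: full model, allometric model, reduced-parameter
# couplings, and the closed-form random baseline.
#
# Variant names and couplings:
#   pnm          n, c, r free per species
#   anm          n = normalized log10 body mass; c, r free
#   r_of_c       n, c free; r = r0 * exp(r1 * c)   (global r0, r1)
#   r_of_n       n, c free; r = r0 + r1 * n        (global r0, r1)
#   c_of_n       n, r free; c = c0 + c1 * n        (global c0, c1)
#   c_and_r_of_n n free;    c = c0 + c1 * n, r = r0 + r1 * n
#   random       single uniform link probability p = L / S^2

.variant_names <- c("pnm", "anm", "r_of_c", "r_of_n", "c_of_n",
                    "c_and_r_of_n", "random")

#' Specify a model variant
#'
#' @param name One of `"pnm"`, `"anm"`, `"r_of_c"`, `"r_of_n"`,
#'   `"c_of_n"`, `"c_and_r_of_n"`, `"random"`.
#' @param coefficients Optional named numeric vector fixing the global
#'   coupling coefficients (`c0`, `c1` for linear diet position; `r0`,
#'   `r1` for the range coupling). When omitted, the coefficients are free
#'   and estimated by [fit()].
#' @return An object of class `model_spec`.
#' @export
#' @examples
#' model_spec("r_of_c", coefficients = c(r0 = 0.1, r1 = 2))
model_spec <- function(name, coefficients = NULL) {
  name <- match.arg(name, .variant_names)
  need <- switch(name,
    c_of_n = c("c0", "c1"),
    r_of_c = , r_of_n = c("r0", "r1"),
    c_and_r_of_n = c("c0", "c1", "r0", "r1"),
    character(0))
  if (!is.null(coefficients)) {
    if (!length(need)) {
      stop("variant '", name, "' has no coupling coefficients")
    }
    if (!all(need %in% names(coefficients))) {
      stop("variant '", name, "' needs coefficients: ",
           paste(need, collapse = ", "))
    }
    coefficients <- coefficients[need]
  }
  structure(list(name = name, coefficients = coefficients,
                 coupled = need),
            class = "model_spec")
}

as_model_spec <- function(spec) {
  if (inherits(spec, "model_spec")) spec else model_spec(spec)
}

#' @export
print.model_spec <- function(x, ...) {
  cat("model_spec:", x$name)
  if (!is.null(x$coefficients)) {
    cat(" (", paste(names(x$coefficients), "=",
                    signif(x$coefficients, 4), collapse = ", "), ")")
  }
  cat("\n")
  invisible(x)
}

#' Allometric niche positions from body masses
#'
#' Maps body masses onto the unit niche axis through the log-mass range:
#' `n_i = (log10 m_i - log10 m_min) / (log10 m_max - log10 m_min)`. The
#' lightest species lands at 0, the heaviest at 1, and the map is
#' order-preserving and invariant to rescaling all masses by a constant.
#'
#' @param body_mass Positive body masses, at least two distinct values.
#' @return Niche positions in `[0, 1]`, named like the input.
#' @export
#' @examples
#' allometric_niche(c(1, 10, 100))  # 0, 0.5, 1
allometric_niche <- function(body_mass) {
  if (any(!is.finite(body_mass)) || any(body_mass <= 0)) {
    stop("body masses must all be positive and finite")
  }
  lg <- log10(body_mass)
  rng <- range(lg)
  if (diff(rng) == 0) {
    stop("all body masses are equal; the allometric axis is degenerate")
  }
  (lg - rng[1]) / diff(rng)
}

# Free-parameter layout of a variant: one row per optimized coordinate.
# type codes: 0 = n_i, 1 = c_i, 2 = r_i, 3 = c0, 4 = c1, 5 = r0, 6 = r1.
# Packing order: all free n, then free c, then free r, then globals.
free_param_layout <- function(spec, mask, S) {
  spec <- as_model_spec(spec)
  name <- spec$name
  if (name == "random") stop("the random model has no free layout")
  type <- integer(0); index <- integer(0); lo <- numeric(0); hi <- numeric(0)
  add <- function(t, i, l, h) {
    type <<- c(type, t); index <<- c(index, i); lo <<- c(lo, l); hi <<- c(hi, h)
  }
  n_free <- name %in% c("pnm", "r_of_c", "r_of_n", "c_of_n", "c_and_r_of_n")
  c_free <- name %in% c("pnm", "anm", "r_of_c", "r_of_n")
  r_free <- name %in% c("pnm", "anm", "c_of_n")
  if (n_free) for (i in seq_len(S)) add(0L, i, 0, 1)
  if (c_free) for (i in seq_len(S)) if (!mask$producer[i]) add(1L, i, 0, 1)
  if (r_free) {
    for (i in seq_len(S)) {
      if (!mask$producer[i] && !mask$specialist[i]) {
        add(2L, i, .nf$r_floor, .nf$r_max)
      }
    }
  }
  if (is.null(spec$coefficients)) {
    if (name %in% c("c_of_n", "c_and_r_of_n")) {
      add(3L, NA_integer_, -2, 2)   # c0
      add(4L, NA_integer_, -4, 4)   # c1
    }
    if (name == "r_of_c") {
      add(5L, NA_integer_, 1e-4, 2) # r0 (exponential prefactor, > 0)
      add(6L, NA_integer_, -6, 6)   # r1 (exponent slope)
    }
    if (name %in% c("r_of_n", "c_and_r_of_n")) {
      add(5L, NA_integer_, -2, 2)   # r0
      add(6L, NA_integer_, -4, 4)   # r1
    }
  }
  data.frame(type = type, index = index, lo = lo, hi = hi)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Expand packed free parameters into a full parameter set
#'
#' Inverse of the packing used by the optimizer: per-species free values
#' are unpacked, coupled parameters are computed from their source
#' parameter and the global coefficients (then clamped into the model
#' bounds), and producer/specialist constraints from `mask` are applied
#' (producers: `c = 0`, `r = r_floor`; specialists: `r = r_floor`).
#'
#' Packing order: all free niche positions `n`, then free diet positions
#' `c`, then free ranges `r`, then any free global coefficients in the
#' order `c0, c1, r0, r1`.
#'
#' @param spec A [model_spec()]; fixed coefficients, if any, are taken
#'   from it.
#' @param free Numeric vector of packed free parameters.
#' @param S Number of species.
#' @param mask Optional [constraint_mask()]; default no constraints.
#' @param n_fixed Fixed niche positions (required for `"anm"`).
#' @return A list with elements `params` (a [param_set()]) and
#'   `coefficients` (named numeric or `NULL`).
#' @export
expand_params <- function(spec, free, S, mask = NULL, n_fixed = NULL) {
  spec <- as_model_spec(spec)
  if (is.null(mask)) mask <- empty_mask(S)
  layout <- free_param_layout(spec, mask, S)
  if (length(free) != nrow(layout)) {
    stop("packed parameter vector has length ", length(free),
         " but the '", spec$name, "' layout needs ", nrow(layout))
  }
  n <- if (spec$name == "anm") {
    if (is.null(n_fixed)) stop("the allometric model needs fixed niche positions")
    as.numeric(n_fixed)
  } else rep(0.5, S)
  c_ <- rep(0, S)
  r <- rep(.nf$r_floor, S)
  g <- c(c0 = NA_real_, c1 = NA_real_, r0 = NA_real_, r1 = NA_real_)
  if (!is.null(spec$coefficients)) g[names(spec$coefficients)] <- spec$coefficients
  for (k in seq_len(nrow(layout))) {
    v <- free[k]
    switch(layout$type[k] + 1L,
      n[layout$index[k]] <- v,          # 0
      c_[layout$index[k]] <- v,         # 1
      r[layout$index[k]] <- v,          # 2
      g["c0"] <- v, g["c1"] <- v,       # 3, 4
      g["r0"] <- v, g["r1"] <- v)       # 5, 6
  }
  if (spec$name %in% c("c_of_n", "c_and_r_of_n")) {
    c_ <- clamp(g["c0"] + g["c1"] * n, 0, 1)
  }
  if (spec$name == "r_of_c") {
    r <- clamp(g["r0"] * exp(g["r1"] * c_), .nf$r_floor, .nf$r_max)
  }
  if (spec$name %in% c("r_of_n", "c_and_r_of_n")) {
    r <- clamp(g["r0"] + g["r1"] * n, .nf$r_floor, .nf$r_max)
  }
  c_[mask$producer] <- 0
  r[mask$producer | mask$specialist] <- .nf$r_floor
  gout <- g[!is.na(g)]
  list(params = param_set(n, c_, r),
       coefficients = if (length(gout)) gout else NULL)
}

#' Closed-form random-graph baseline
#'
#' The maximum-likelihood random model assigns every possible link the
#' same probability `p = L / S^2`; its maximized log-likelihood has the
#' closed form `S^2 * (C * log(C) + (1 - C) * log(1 - C))` with `C = p`,
#' and it spends a single parameter, so `AIC = 2 - 2 * lnL`.
#'
#' @param S Species count.
#' @param L Link count, with `0 < L < S^2`.
#' @return List with elements `p`, `lnL`, `k` (= 1) and `aic`.
#' @export
#' @examples
#' round(random_model(29, 203)$aic)  # 932
random_model <- function(S, L) {
  if (L <= 0 || L >= S^2) {
    stop("the random model is degenerate unless 0 < L < S^2")
  }
  p <- L / S^2
  lnL <- S^2 * (p * log(p) + (1 - p) * log1p(-p))
  list(p = p, lnL = lnL, k = 1L, aic = aic(lnL, 1L))
}
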