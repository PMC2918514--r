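# Maximum-likelihood estimation by simulated annealing, with restarts,
# a deterministic coordinate polish, and a brute-force grid oracle.

#' Annealing configuration
#'
#' Geometric cooling `T_k = T0 * cooling^k` with Metropolis acceptance
#' `exp(delta_lnL / T)`. `steps_per_stage = NULL` scales the stage length
#' to 50 proposals per free parameter. A small fraction `snap_prob` of
#' proposals are data-informed: a consumer's diet position is set onto an
#' observed prey's niche position (or a resource's niche position onto a
#' consumer's diet position), which lets specialists — whose range is
#' pinned at the floor — reach their needle-shaped optimum exactly.
#'
#' @param T0 Initial temperature (> 0).
#' @param cooling Geometric cooling factor in (0, 1).
#' @param stages Number of temperature stages.
#' @param steps_per_stage Proposals per stage, or `NULL` for
#'   `50 * n_free`.
#' @param restarts Independent annealing runs; the first uses a
#'   trophic-rank warm start, the rest random initial states.
#' @param step_sigma Gaussian proposal scale.
#' @param snap_prob Probability of a data-informed snap proposal.
#' @param polish_cycles Deterministic coordinate-scan polish passes after
#'   annealing.
#' @param seed RNG seed (integer).
#' @return An object of class `anneal_config`.
#' @export
anneal_config <- function(T0 = 1, cooling = 0.95, stages = 200,
                          steps_per_stage = NULL, restarts = 5,
                          step_sigma = 0.1, snap_prob = 0.1,
                          polish_cycles = 2, seed = 1L) {
  stopifnot(T0 > 0, cooling > 0, cooling < 1, stages >= 1, restarts >= 1,
            step_sigma >= 0, snap_prob >= 0, snap_prob < 1,
            polish_cycles >= 0)
  if (!is.null(steps_per_stage)) stopifnot(steps_per_stage >= 1)
  structure(list(T0 = T0, cooling = cooling, stages = as.integer(stages),
                 steps_per_stage = steps_per_stage,
                 restarts = as.integer(restarts), step_sigma = step_sigma,
                 snap_prob = snap_prob,
                 polish_cycles = as.integer(polish_cycles),
                 seed = as.integer(seed)),
            class = "anneal_config")
}

#' Single-coordinate Gaussian proposal with reflecting bounds
#'
#' Perturbs one uniformly chosen coordinate of `state` by a normal draw of
#' scale `step_sigma`, reflecting at the box bounds; all other coordinates
#' are unchanged. This is the basic random-walk move of the annealer,
#' exposed for inspection and testing.
#'
#' @param state Numeric vector within `[lo, hi]`.
#' @param lo,hi Bound vectors of the same length.
#' @param step_sigma Proposal scale; 0 returns `state` unchanged.
#' @return The candidate state vector.
#' @export
propose <- function(state, lo, hi, step_sigma) {
  stopifnot(length(lo) == length(state), length(hi) == length(state))
  k <- sample.int(length(state), 1L)
  x <- state[k] + rnorm(1L, 0, step_sigma)
  w <- hi[k] - lo[k]
  if (w > 0) {
    y <- (x - lo[k]) %% (2 * w)
    x <- lo[k] + if (y <= w) y else 2 * w - y
  } else {
    x <- lo[k]
  }
  state[k] <- x
  state
}

#' Metropolis acceptance rule
#'
#' Accepts an uphill move always and a downhill move with probability
#' `exp(delta / temperature)`.
#'
#' @param delta Change in log-likelihood of the proposed move.
#' @param temperature Current annealing temperature (> 0).
#' @return Logical: accept the move?
#' @export
anneal_accept <- function(delta, temperature) {
  delta >= 0 || runif(1L) < exp(delta / temperature)
}

variant_code <- function(name) {
  match(name, c("pnm", "anm", "r_of_c", "r_of_n", "c_of_n",
                "c_and_r_of_n")) - 1L
}

# Prey-averaged trophic height, damped so cycles stay solvable, used only
# to order species for the warm start.
trophic_rank <- function(web) {
  A <- as_adjacency(web)
  S <- nrow(A)
  R <- rowSums(A)
  W <- A / pmax(R, 1)
  tl <- tryCatch(solve(diag(S) - 0.95 * W, rep(1, S)),
                 error = function(e) 1 + R / max(R, 1))
  order_key <- rank(tl, ties.method = "first")
  (order_key - 1) / max(S - 1, 1)
}

warm_start <- function(web, spec, mask, layout, n_fixed = NULL) {
  A <- as_adjacency(web)
  S <- nrow(A)
  n0 <- if (spec$name == "anm") n_fixed else trophic_rank(web)
  c0 <- vapply(seq_len(S), function(i) {
    prey <- which(A[i, ] == 1L)
    if (length(prey)) mean(n0[prey]) else n0[i] / 2
  }, numeric(1))
  r0 <- rep(0.2, S)
  init <- numeric(nrow(layout))
  for (k in seq_len(nrow(layout))) {
    init[k] <- switch(layout$type[k] + 1L,
      n0[layout$index[k]], c0[layout$index[k]], r0[layout$index[k]],
      0,    # c0: through the origin
      0.8,  # c1: diets slightly below the consumer
      if (spec$name == "r_of_c") 0.1 else 0.05,  # r0
      if (spec$name == "r_of_c") 1 else 0.5)     # r1
  }
  clamp(init, layout$lo, layout$hi)
}

observed_links <- function(web, mask) {
  idx <- which(as_adjacency(web) == 1L, arr.ind = TRUE)
  idx <- idx[!mask$producer[idx[, 1]], , drop = FALSE]
  matrix(as.integer(idx - 1L), ncol = 2)  # 0-based for the C++ side
}

#' Fit a niche-model variant by simulated annealing
#'
#' Maximizes the Bernoulli log-likelihood of the web under the chosen
#' variant over the free parameters, subject to the producer/specialist
#' constraints derived from the data. Runs `config$restarts` independent
#' annealing chains (warm-started from trophic ordering, then random) and
#' keeps the best, then applies a deterministic coordinate polish. The
#' reported log-likelihood is re-evaluated in R from the returned
#' parameter set. For the full model the fitted axis is re-oriented (the
#' likelihood is invariant to reflecting the axis) so that niche position
#' correlates non-negatively with prey count.
#'
#' @param web A [food_web()]; must have at least one consumer, and body
#'   masses for `"anm"`.
#' @param spec A [model_spec()] or variant name; `"random"` has a closed
#'   form, use [random_model()].
#' @param config An [anneal_config()].
#' @return An object of class `niche_fit`: list with `params`
#'   ([param_set()] at the optimum), `coefficients` (global coupling
#'   coefficients or `NULL`), `lnL`, `k` (nominal parameter count), `aic`,
#'   `trace` (best lnL per stage of the winning restart), `restart`
#'   (index of the winning restart), `seed_used`, `spec`, `config`,
#'   `mask`.
#' @export
fit <- function(web, spec, config = anneal_config()) {
  spec <- as_model_spec(spec)
  if (spec$name == "random") {
    stop("the random model has a closed form; use random_model()")
  }
  A <- as_adjacency(web)
  S <- nrow(A)
  mask <- constraint_mask(web)
  if (all(mask$producer)) stop("web has no consumers; nothing to fit")
  n_fixed <- NULL
  if (spec$name == "anm") {
    if (is.null(web$body_mass)) {
      stop("the allometric model needs body masses on the web")
    }
    n_fixed <- unname(allometric_niche(web$body_mass))
  }
  layout <- free_param_layout(spec, mask, S)
  nfree <- nrow(layout)
  sps <- config$steps_per_stage %||% (50L * nfree)
  links <- observed_links(web, mask)

  # fixed (non-free) baseline values fed to the optimizer
  n0 <- n_fixed %||% rep(0.5, S)
  c0 <- rep(0, S)
  r0 <- rep(.nf$r_floor, S)
  g0 <- c(0, 0, 0.1, 0)

  set.seed(config$seed)
  best <- NULL
  warm <- warm_start(web, spec, mask, layout, n_fixed)
  for (k in seq_len(config$restarts)) {
    init <- if (k == 1L) warm else runif(nfree, layout$lo, layout$hi)
    res <- .anneal_cpp(A, mask$producer, mask$specialist,
                       variant_code(spec$name),
                       n0, c0, r0, g0,
                       layout$type, layout$index - 1L, layout$lo, layout$hi,
                       init, links,
                       config$T0, config$cooling, config$stages,
                       as.integer(sps), config$step_sigma, config$snap_prob,
                       config$polish_cycles,
                       .nf$a, .nf$p_floor, .nf$r_floor, .nf$r_max)
    if (is.null(best) || res$lnl > best$lnl) {
      best <- res
      best$restart <- k
    }
  }

  ex <- expand_params(spec, best$state, S, mask, n_fixed)
  params <- ex$params
  params$species <- web$species
  names(params$n) <- names(params$c) <- names(params$r) <- web$species

  if (spec$name == "pnm") {
    R <- rowSums(A)
    rho <- suppressWarnings(cor(params$n, R, method = "spearman"))
    if (is.finite(rho) && rho < 0) {
      params$n <- 1 - params$n
      params$c[!mask$producer] <- 1 - params$c[!mask$producer]
    }
  }

  lnL <- log_likelihood(probability_matrix(params, mask), web)
  k_nom <- count_parameters(spec, S)
  structure(list(params = params, coefficients = ex$coefficients,
                 lnL = lnL, k = k_nom, aic = aic(lnL, k_nom),
                 trace = best$trace, restart = best$restart,
                 seed_used = config$seed, spec = spec, config = config,
                 mask = mask),
            class = "niche_fit")
}

#' @export
print.niche_fit <- function(x, ...) {
  cat(sprintf("niche_fit: %s, S = %d, lnL = %.3f, k = %d, AIC = %.1f (restart %d)\n",
              x$spec$name, length(x$params$n), x$lnL, x$k, x$aic, x$restart))
  invisible(x)
}

#' Exhaustive grid-search oracle
#'
#' Maximizes the log-likelihood over a regular lattice of the free
#' parameters. Intended as an independent reference for testing the
#' annealer on very small problems; the total lattice size must not
#' exceed `limit` points.
#'
#' @param web A [food_web()].
#' @param spec A [model_spec()] or variant name.
#' @param resolution Grid step on the unit axis (ranges use the same
#'   step over `[r_floor, r_max]`).
#' @param limit Maximum number of lattice points (default `1e7`).
#' @return List with `lnL` (lattice maximum), `state` (packed free
#'   parameters at the maximum), `params` (expanded [param_set()]) and
#'   `n_points`.
#' @export
grid_search_oracle <- function(web, spec, resolution, limit = 1e7) {
  spec <- as_model_spec(spec)
  A <- as_adjacency(web)
  S <- nrow(A)
  mask <- constraint_mask(web)
  layout <- free_param_layout(spec, mask, S)
  grids <- lapply(seq_len(nrow(layout)), function(k) {
    if (layout$type[k] %in% c(0L, 1L)) seq(0, 1, by = resolution)
    else seq(layout$lo[k], layout$hi[k], by = resolution)
  })
  sizes <- vapply(grids, length, integer(1))
  N <- prod(sizes)
  if (N > limit) {
    stop("grid has ", format(N, big.mark = ","), " points, above the limit of ",
         format(limit, big.mark = ","))
  }
  div <- cumprod(c(1, sizes[-length(sizes)]))
  producer <- mask$producer
  prod_row_ll <- S * log1p(-.nf$p_floor)

  best_ll <- -Inf
  best_state <- NULL
  chunk <- 65536L
  for (start in seq(0, N - 1, by = chunk)) {
    idx <- start:min(start + chunk - 1, N - 1)
    V <- vapply(seq_along(grids), function(s) {
      grids[[s]][(idx %/% div[s]) %% sizes[s] + 1L]
    }, numeric(length(idx)))
    V <- matrix(V, nrow = length(idx))
    ll <- chunk_loglik(V, layout, spec, mask, A, prod_row_ll)
    w <- which.max(ll)
    if (ll[w] > best_ll) {
      best_ll <- ll[w]
      best_state <- V[w, ]
    }
  }
  ex <- expand_params(spec, best_state, S, mask)
  list(lnL = best_ll, state = best_state, params = ex$params,
       n_points = N)
}

# Vectorized log-likelihood of many packed states (rows of V).
chunk_loglik <- function(V, layout, spec, mask, A, prod_row_ll) {
  S <- nrow(A)
  npts <- nrow(V)
  n <- matrix(0.5, npts, S)
  c_ <- matrix(0, npts, S)
  r <- matrix(.nf$r_floor, npts, S)
  g <- list(c0 = NA_real_, c1 = NA_real_, r0 = NA_real_, r1 = NA_real_)
  if (!is.null(spec$coefficients)) {
    for (nm in names(spec$coefficients)) g[[nm]] <- spec$coefficients[[nm]]
  }
  for (k in seq_len(nrow(layout))) {
    v <- V[, k]
    t <- layout$type[k]; i <- layout$index[k]
    if (t == 0L) n[, i] <- v
    else if (t == 1L) c_[, i] <- v
    else if (t == 2L) r[, i] <- v
    else g[[t - 2L]] <- v
  }
  if (spec$name %in% c("c_of_n", "c_and_r_of_n")) {
    c_ <- clamp(g$c0 + g$c1 * n, 0, 1)
  }
  if (spec$name == "r_of_c") {
    r <- clamp(g$r0 * exp(g$r1 * c_), .nf$r_floor, .nf$r_max)
  }
  if (spec$name %in% c("r_of_n", "c_and_r_of_n")) {
    r <- clamp(g$r0 + g$r1 * n, .nf$r_floor, .nf$r_max)
  }
  c_[, mask$producer] <- 0
  r[, mask$producer | mask$specialist] <- .nf$r_floor
  ll <- numeric(npts)
  for (i in seq_len(S)) {
    if (mask$producer[i]) {
      ll <- ll + prod_row_ll
      next
    }
    for (j in seq_len(S)) {
      d <- (n[, j] - c_[, i]) / (r[, i] / 2)
      p <- pmax(.nf$a * exp(-d^2), .nf$p_floor)
      ll <- ll + if (A[i, j] == 1L) log(p) else log1p(-p)
    }
  }
  ll
}
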