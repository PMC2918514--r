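# Goodness-of-fit statistics comparing a link-probability matrix with an
# observed web.

#' Goodness-of-fit report
#'
#' Expected-value summaries of how well a probability matrix reproduces
#' the observed web: the expected number of links `sum(P)`; the expected
#' number of observed links predicted correctly
#' `N1 = sum over observed links of P_ij` and the fraction `f_L = N1 / L`;
#' the expected fraction of all `S^2` connection-matrix entries (diagonal
#' included) reproduced correctly
#' `sum(A * P + (1 - A) * (1 - P)) / S^2`; and the per-species prey-side
#' (`n_Ri`, `f_Ri = n_Ri / R_i`) and predator-side (`n_Ci`,
#' `f_Ci = n_Ci / C_i`) decompositions. Fractions with a zero denominator
#' (basal species on the prey side, top predators on the predator side)
#' are reported as `NA`.
#'
#' @param P Probability matrix with entries strictly inside (0, 1).
#' @param web A [food_web()] or 0/1 matrix of the same shape.
#' @return An object of class `gof_report`: list with scalars
#'   `expected_links`, `N1`, `f_L`, `entries_correct` and a data.frame
#'   `species` with columns `species`, `R`, `C`, `n_R`, `f_R`, `n_C`,
#'   `f_C`.
#' @export
gof_report <- function(P, web) {
  A <- as_adjacency(web)
  if (!identical(dim(P), dim(A))) {
    stop("P and the connection matrix must have the same shape")
  }
  if (any(P <= 0) || any(P >= 1)) {
    stop("all link probabilities must lie strictly inside (0, 1)")
  }
  S <- nrow(A)
  L <- sum(A)
  PA <- P * A
  n_R <- rowSums(PA)
  n_C <- colSums(PA)
  R <- rowSums(A)
  Cn <- colSums(A)
  species <- rownames(A) %||% paste0("sp", seq_len(S))
  structure(list(
    expected_links = sum(P),
    N1 = sum(PA),
    f_L = sum(PA) / L,
    entries_correct = sum(A * P + (1 - A) * (1 - P)) / S^2,
    species = data.frame(
      species = species, R = R, C = Cn,
      n_R = n_R, f_R = ifelse(R > 0, n_R / R, NA_real_),
      n_C = n_C, f_C = ifelse(Cn > 0, n_C / Cn, NA_real_),
      row.names = NULL)
  ), class = "gof_report")
}

#' @export
print.gof_report <- function(x, ...) {
  cat(sprintf(
    "gof_report: expected links = %.1f, N1 = %.1f, f_L = %.3f, entries correct = %.3f\n",
    x$expected_links, x$N1, x$f_L, x$entries_correct))
  invisible(x)
}

#' Flag species with poorly predicted links
#'
#' @param report A [gof_report()].
#' @param threshold Flag species whose defined `f_R` (prey side) or `f_C`
#'   (predator side) is `<= threshold`; undefined fractions are never
#'   flagged.
#' @return List with character vectors `prey_side` and `predator_side`.
#' @export
flag_poorly_predicted <- function(report, threshold = 0.65) {
  stopifnot(threshold > 0, threshold <= 1)
  d <- report$species
  list(
    prey_side = d$species[!is.na(d$f_R) & d$f_R <= threshold],
    predator_side = d$species[!is.na(d$f_C) & d$f_C <= threshold]
  )
}
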