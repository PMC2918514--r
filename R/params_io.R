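# Serialization of parameter sets: a species CSV (species, n, c, r) plus
# a one-line JSON sidecar carrying the peak probability and model name.

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

#' Write a parameter set to CSV (+ JSON sidecar)
#'
#' @param params A [param_set()].
#' @param path CSV output path; a sidecar `<path-minus-ext>.json` records
#'   `a`, the model name and any global coefficients.
#' @param model Model variant name recorded in the sidecar.
#' @param coefficients Optional named global coefficients for the sidecar.
#' @return `path`, invisibly.
#' @export
write_params <- function(params, path, model = "pnm", coefficients = NULL) {
  species <- params$species %||% paste0("sp", seq_along(params$n))
  d <- data.frame(species = species, n = params$n, c = params$c,
                  r = params$r, row.names = NULL)
  write.csv(d, path, row.names = FALSE, quote = FALSE)
  side <- list(a = params$a, model = model)
  if (!is.null(coefficients)) side$coefficients <- as.list(coefficients)
  jsonlite::write_json(side, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a parameter set written by [write_params()]
#'
#' @param path CSV path; the JSON sidecar is read when present.
#' @return A [param_set()]; the sidecar model name is attached as
#'   attribute `"model"`.
#' @export
read_params <- function(path) {
  d <- read.csv(path, check.names = FALSE)
  a <- .nf$a
  model <- "pnm"
  sp <- sidecar_path(path)
  if (file.exists(sp)) {
    side <- jsonlite::read_json(sp, simplifyVector = TRUE)
    a <- side$a %||% a
    model <- side$model %||% model
  }
  p <- param_set(d$n, d$c, d$r, a = a, species = d$species)
  attr(p, "model") <- model
  p
}
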