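# Data model and I/O for binary food webs.
#
# A food web is an S x S binary connection matrix A with rows = consumers:
# A[i, j] = 1 means species i eats species j. Diagonal entries
# (cannibalism) are legal data and retained.

#' Construct a binary food web
#'
#' @param A Square matrix of 0/1 entries; `A[i, j] = 1` means consumer `i`
#'   eats resource `j`. Row/column names, if present, must agree and are
#'   used as species names.
#' @param species Character vector of unique species names; defaults to
#'   the dimnames of `A` or `sp1 ... spS`.
#' @param body_mass Optional numeric vector of average body masses
#'   (grams), one per species, all positive and finite. May be named by
#'   species.
#' @return An object of class `food_web`: a list with elements `species`,
#'   `A` (integer matrix with species dimnames) and `body_mass` (or
#'   `NULL`).
#' @export
#' @examples
#' w <- food_web(rbind(c(0, 1), c(0, 0)), species = c("fox", "hare"))
#' web_stats(w)$L
food_web <- function(A, species = NULL, body_mass = NULL) {
  A <- as.matrix(A)
  if (nrow(A) != ncol(A)) {
    stop("connection matrix must be square, got ", nrow(A), "x", ncol(A))
  }
  S <- nrow(A)
  if (S < 2) stop("a food web needs at least 2 species")
  if (is.null(species)) {
    species <- rownames(A)
    if (is.null(species)) species <- paste0("sp", seq_len(S))
  }
  species <- as.character(species)
  if (length(species) != S) stop("species names must have length S = ", S)
  if (anyDuplicated(species)) {
    stop("duplicate species name: ", species[duplicated(species)][1L])
  }
  av <- suppressWarnings(as.numeric(A))
  if (anyNA(av) || !all(av %in% c(0, 1))) {
    stop("connection matrix entries must all be 0 or 1")
  }
  A <- matrix(as.integer(av), S, S, dimnames = list(species, species))
  if (!is.null(body_mass)) {
    if (!is.null(names(body_mass))) {
      if (!setequal(names(body_mass), species)) {
        stop("body_mass names do not match the species list")
      }
      body_mass <- body_mass[species]
    }
    body_mass <- as.numeric(body_mass)
    if (length(body_mass) != S) stop("body_mass must have one value per species")
    if (anyNA(body_mass) || any(!is.finite(body_mass)) || any(body_mass <= 0)) {
      stop("body masses must all be positive and finite")
    }
    names(body_mass) <- species
  }
  structure(list(species = species, A = A, body_mass = body_mass),
            class = "food_web")
}

#' @export
print.food_web <- function(x, ...) {
  st <- web_stats(x)
  cat(sprintf("food_web: S = %d species, L = %d links, C = %.4f%s\n",
              st$S, st$L, st$C,
              if (is.null(x$body_mass)) "" else ", with body masses"))
  invisible(x)
}

as_adjacency <- function(web) {
  if (inherits(web, "food_web")) return(web$A)
  A <- as.matrix(web)
  storage.mode(A) <- "integer"
  A
}

#' Summary statistics of a food web
#'
#' Counts species `S`, links `L`, directed connectance `C = L / S^2`,
#' links per species, the per-species prey counts `R` (row sums) and
#' predator counts `Cn` (column sums), and the basal (no prey) and
#' specialist (single prey) species.
#'
#' @param web A [food_web()].
#' @return An object of class `web_stats`: list with elements `S`, `L`,
#'   `C`, `links_per_species`, `R`, `Cn`, `basal`, `specialists`.
#' @export
web_stats <- function(web) {
  A <- as_adjacency(web)
  S <- nrow(A)
  R <- rowSums(A)
  Cn <- colSums(A)
  L <- sum(A)
  structure(list(
    S = S, L = L, C = L / S^2, links_per_species = L / S,
    R = R, Cn = Cn,
    basal = names(R)[R == 0] %||% which(R == 0),
    specialists = names(R)[R == 1] %||% which(R == 1)
  ), class = "web_stats")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.web_stats <- function(x, ...) {
  cat(sprintf("S = %d, L = %d, C = %.4f, L/S = %.2f, %d basal, %d specialists\n",
              x$S, x$L, x$C, x$links_per_species,
              length(x$basal), length(x$specialists)))
  invisible(x)
}

#' Read a food web from disk
#'
#' Two plain-text dialects are supported. `"adjacency"`: a CSV whose first
#' row and first column hold species names and whose cells are 0/1, rows =
#' consumers. `"edgelist"`: a two-column TSV of consumer, resource pairs;
#' the species universe is the union of the names plus any
#' `extra_species` (isolated species do not appear in an edge list).
#'
#' @param path File to read.
#' @param format `"adjacency"` or `"edgelist"`.
#' @param extra_species Optional character vector of additional (isolated)
#'   species for the edge-list dialect.
#' @param body_mass Optional path to a species-attribute CSV with columns
#'   `name`, `body_mass_g`.
#' @return A [food_web()].
#' @export
read_web <- function(path, format = c("adjacency", "edgelist"),
                     extra_species = NULL, body_mass = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "adjacency") {
    d <- read.csv(path, check.names = FALSE, row.names = 1)
    A <- as.matrix(d)
    if (nrow(A) != ncol(A)) {
      stop("adjacency file is not square: ", nrow(A), " rows x ",
           ncol(A), " columns")
    }
    if (!identical(rownames(A), colnames(A))) {
      stop("adjacency row and column species names differ")
    }
    web <- food_web(A)
  } else {
    d <- read.delim(path, header = TRUE, colClasses = "character")
    if (ncol(d) < 2) stop("edge list must have columns consumer, resource")
    consumer <- d[[1]]; resource <- d[[2]]
    species <- unique(c(consumer, resource, extra_species))
    A <- matrix(0L, length(species), length(species),
                dimnames = list(species, species))
    A[cbind(match(consumer, species), match(resource, species))] <- 1L
    web <- food_web(A, species = species)
  }
  if (!is.null(body_mass)) {
    tab <- read_species_table(body_mass)
    m <- setNames(tab$body_mass_g, tab$name)
    missing <- setdiff(web$species, names(m))
    if (length(missing)) {
      stop("body mass missing for species: ", paste(missing, collapse = ", "))
    }
    web <- food_web(web$A, body_mass = m[web$species])
  }
  web
}

#' Read a species-attribute table
#'
#' @param path CSV with columns `name` and `body_mass_g`.
#' @return A data.frame with columns `name` (character) and
#'   `body_mass_g` (numeric).
#' @export
read_species_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- read.csv(path, check.names = FALSE)
  need <- c("name", "body_mass_g")
  if (!all(need %in% names(d))) {
    stop("species table must have columns: ", paste(need, collapse = ", "))
  }
  data.frame(name = as.character(d$name),
             body_mass_g = as.numeric(d$body_mass_g))
}

#' Write a food web to disk
#'
#' Inverse of [read_web()]; round-trips exactly for both dialects (an edge
#' list loses isolated species unless they are re-supplied on read).
#'
#' @param web A [food_web()].
#' @param path Output file.
#' @param format `"adjacency"` or `"edgelist"`.
#' @return `path`, invisibly.
#' @export
write_web <- function(web, path, format = c("adjacency", "edgelist")) {
  format <- match.arg(format)
  if (format == "adjacency") {
    d <- as.data.frame(web$A)
    write.csv(d, path, row.names = TRUE, quote = FALSE)
  } else {
    idx <- which(web$A == 1L, arr.ind = TRUE)
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    d <- data.frame(consumer = web$species[idx[, 1]],
                    resource = web$species[idx[, 2]])
    write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
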