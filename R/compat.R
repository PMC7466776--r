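#' Y-site compatibility matrices
#'
#' A compatibility matrix records, for every pair of drugs it knows, whether
#' the two solutions may share tubing (and hence an infusion packet or a
#' lumen) without precipitation or inactivation. It is a symmetric logical
#' relation; a drug is compatible with itself by convention, and any pair
#' involving a drug the matrix does not know is reported incompatible —
#' fluids absent from the compatibility database must never be mixed.
#'
#' The bundled chart (`default_compat()`) is a deterministic synthetic
#' illustration (see [synthetic_compat_chart()]); it carries no clinical
#' authority and exists so that the package runs end-to-end without external
#' data.
#'
#' @name compat_matrix
NULL

#' Construct a compatibility matrix
#'
#' @param drugs character vector of drug names.
#' @param compat logical matrix (`length(drugs)` square) of pairwise
#'   compatibilities; it is symmetrized with `&` and the diagonal forced to
#'   `TRUE`.
#' @return a `compat_matrix`.
#' @export
compat_matrix <- function(drugs, compat) {
  drugs <- as.character(drugs)
  if (anyDuplicated(drugs)) mux_validation_error("duplicate drug names in compatibility matrix")
  m <- matrix(as.logical(compat), length(drugs), length(drugs),
              dimnames = list(drugs, drugs))
  m <- m & t(m)                      # enforce symmetry conservatively
  diag(m) <- TRUE
  class(m) <- c("compat_matrix", class(m))
  m
}

#' Pairwise compatibility lookup
#'
#' Total function: querying unknown drug names returns `FALSE` (unknown
#' fluids are considered incompatible with everything); `a == b` returns
#' `TRUE`.
#'
#' @param matrix a `compat_matrix`.
#' @param a,b drug names.
#' @return logical scalar.
#' @export
is_compatible <- function(matrix, a, b) {
  if (identical(a, b)) return(TRUE)
  drugs <- rownames(matrix)
  if (!(a %in% drugs) || !(b %in% drugs)) return(FALSE)
  isTRUE(matrix[a, b])
}

#' Are all drugs in a set mutually compatible?
#'
#' `TRUE` iff every unordered pair in `drugs` is compatible; the empty set
#' and singletons are vacuously compatible.
#'
#' @param matrix a `compat_matrix`.
#' @param drugs character vector of drug names (duplicates ignored).
#' @return logical scalar.
#' @export
all_pairwise_compatible <- function(matrix, drugs) {
  drugs <- unique(as.character(drugs))
  if (length(drugs) < 2) return(TRUE)
  for (i in seq_len(length(drugs) - 1)) {
    for (j in seq.int(i + 1, length(drugs))) {
      if (!is_compatible(matrix, drugs[i], drugs[j])) return(FALSE)
    }
  }
  TRUE
}

#' Generate a random compatibility matrix
#'
#' Each unordered off-diagonal pair is compatible independently with
#' probability `density`; reproducible under a fixed seed. Used for
#' property testing and for synthetic cohorts when no chart is supplied.
#'
#' @param drugs character vector of drug names.
#' @param density probability in \[0, 1\] that a pair is compatible.
#' @param seed integer seed.
#' @return a `compat_matrix`.
#' @export
generate_random_matrix <- function(drugs, density, seed) {
  if (!is.numeric(density) || length(density) != 1 || is.na(density) ||
      density < 0 || density > 1) {
    mux_validation_error("density must be a probability in [0, 1]")
  }
  n <- length(drugs)
  m <- matrix(TRUE, n, n)
  if (n > 1) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(as.integer(seed))
    for (i in seq_len(n - 1)) {
      for (j in seq.int(i + 1, n)) {
        m[i, j] <- m[j, i] <- stats::runif(1) < density
      }
    }
  }
  compat_matrix(drugs, m)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Read / write compatibility matrices
#'
#' Two plain-text representations are supported: a full square matrix
#' (`format = "matrix"`: first column `drug`, one 0/1 column per drug) and an
#' edge list of compatible pairs (`format = "pairs"`: columns `a`, `b`, with
#' a header row; every listed drug is a matrix member, pairs not listed are
#' incompatible). Writing then reading either format reproduces the matrix.
#'
#' @param path file path.
#' @param format `"matrix"` or `"pairs"`.
#' @param drugs for `format = "pairs"` reading: optional full drug universe
#'   (drugs with no compatible partner would otherwise be lost from an edge
#'   list).
#' @return a `compat_matrix` (for `load_compat`).
#' @export
load_compat <- function(path, format = c("matrix", "pairs"), drugs = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) mux_validation_error(sprintf("compatibility file not found: %s", path))
  if (format == "matrix") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
    if (!"drug" %in% names(df)) mux_schema_error("matrix file is missing the 'drug' column")
    nm <- as.character(df$drug)
    m <- as.matrix(df[, setdiff(names(df), "drug"), drop = FALSE]) == 1
    if (!identical(colnames(m), nm)) mux_schema_error("matrix rows and columns disagree")
    rownames(m) <- nm
    compat_matrix(nm, m)
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("a", "b") %in% names(df))) mux_schema_error("pair file needs columns 'a' and 'b'")
    nm <- unique(c(drugs, df$a, df$b))
    m <- matrix(FALSE, length(nm), length(nm), dimnames = list(nm, nm))
    for (k in seq_len(nrow(df))) m[df$a[k], df$b[k]] <- m[df$b[k], df$a[k]] <- TRUE
    compat_matrix(nm, m)
  }
}

#' @rdname load_compat
#' @param matrix a `compat_matrix` to write.
#' @export
save_compat <- function(matrix, path, format = c("matrix", "pairs")) {
  format <- match.arg(format)
  drugs <- rownames(matrix)
  if (format == "matrix") {
    df <- data.frame(drug = drugs, check.names = FALSE)
    body <- matrix(as.integer(unclass(matrix)), nrow(matrix),
                   dimnames = dimnames(matrix))
    df <- cbind(df, as.data.frame(body, check.names = FALSE))
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    pairs <- which(upper.tri(matrix) & matrix, arr.ind = TRUE)
    df <- data.frame(a = drugs[pairs[, 1]], b = drugs[pairs[, 2]])
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Deterministic synthetic compatibility chart
#'
#' Builds an illustrative chart over the catalog's drugs: vasoactive drugs
#' are mutually compatible (they conventionally share the designated
#' vasoactive lumen), analgesics/sedatives are mutually compatible,
#' antibiotics are pairwise incompatible with each other, and every other
#' pair is decided by a seeded coin flip at the given density. Entirely
#' synthetic — a stand-in for a curated Y-site chart, with no clinical
#' validity.
#'
#' @param catalog a `drug_catalog`.
#' @param density probability for the random cross-pairs.
#' @param seed integer seed.
#' @return a `compat_matrix`.
#' @export
synthetic_compat_chart <- function(catalog, density = 0.5, seed = 2020L) {
  antibiotics <- c("amoxicilin", "ceftazidime", "clindamycin", "flucloxacillin",
                   "gentamycin", "tobramycin", "vancomycin")
  m <- generate_random_matrix(catalog$drug, density, seed)
  cls <- unclass(m)
  vaso <- catalog$drug[catalog$category == "vasoactive"]
  seda <- catalog$drug[catalog$category == "analgesic_sedative"]
  cls[vaso, vaso] <- TRUE
  cls[seda, seda] <- TRUE
  abx <- intersect(antibiotics, catalog$drug)
  cls[abx, abx] <- FALSE
  compat_matrix(catalog$drug, cls)
}

#' The bundled synthetic compatibility chart
#'
#' Loads the chart shipped with the package (the output of
#' [synthetic_compat_chart()] on the default catalog, pinned to a file so
#' round-trip serialization is exercised). Synthetic and illustrative only.
#'
#' @return a `compat_matrix`.
#' @export
default_compat <- function() {
  load_compat(system.file("extdata", "compat_chart_synthetic.csv", package = "ivmux"))
}

#' @export
print.compat_matrix <- function(x, ...) {
  n <- nrow(x)
  off <- unclass(x)[upper.tri(x)]
  cat(sprintf("<compat_matrix> %d drugs, %.0f%% of pairs compatible\n",
              n, if (length(off)) 100 * mean(off) else 100))
  invisible(x)
}
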