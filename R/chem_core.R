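# Exact monoisotopic mass arithmetic: elemental formulas, residue tables and
# the canonical constants (proton, water, methylene) used everywhere else.

.lipoladder_cache <- new.env(parent = emptyenv())

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "lipoladder")
  if (!nzchar(path)) stop("bundled data file not found: ", file, call. = FALSE)
  path
}

#' Monoisotopic atomic masses
#'
#' Returns the monoisotopic atomic mass table used for all mass bookkeeping
#' in the package. The element set is fixed to C, H, N, O, S, which covers
#' peptides and beta-hydroxy fatty acids; the values are read from the
#' versioned table shipped in `extdata/atomic_masses.tsv`.
#'
#' @return Named numeric vector of monoisotopic masses in Da.
#' @export
atomic_masses <- function() {
  if (is.null(.lipoladder_cache$atomic)) {
    tab <- utils::read.delim(.extdata("atomic_masses.tsv"), stringsAsFactors = FALSE)
    .lipoladder_cache$atomic <- stats::setNames(tab$mass, tab$symbol)
  }
  .lipoladder_cache$atomic
}

#' Canonical mass constants
#'
#' Fixed monoisotopic constants: the proton (charge carrier of \eqn{[M+H]^+}
#' ions), water (the mass separating a lactone-closed cyclic lipopeptide from
#' its ring-opened linear form), methylene (the CH2 spacing of a fatty-acid
#' homolog ladder) and the electron.
#'
#' @return List with elements `proton`, `water`, `methylene`, `electron` (Da).
#' @export
mass_constants <- function() {
  am <- atomic_masses()
  list(
    proton    = 1.00727646,
    water     = 2 * am[["H"]] + am[["O"]],
    methylene = am[["C"]] + 2 * am[["H"]],
    electron  = 0.00054857990907
  )
}

#' Construct an elemental formula
#'
#' @param counts Named integer vector or list, element symbol -> count.
#'   Counts must be non-negative; elements must be in the supported set
#'   (C, H, N, O, S). Zero counts are dropped.
#' @return An `elemental_formula`: a named integer vector in Hill order
#'   (C first, then H, then remaining elements alphabetically).
#' @export
elemental_formula <- function(counts = integer()) {
  counts <- unlist(counts)
  if (length(counts) == 0) {
    out <- integer(0)
    class(out) <- "elemental_formula"
    return(out)
  }
  if (is.null(names(counts)) || any(!nzchar(names(counts))))
    stop("formula counts must be named by element symbol", call. = FALSE)
  known <- names(atomic_masses())
  bad <- setdiff(names(counts), known)
  if (length(bad))
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "), call. = FALSE)
  if (any(counts != round(counts)) || any(counts < 0))
    stop("element counts must be non-negative integers", call. = FALSE)
  counts <- tapply(as.integer(counts), names(counts), sum)
  counts <- counts[counts > 0]
  out <- as.integer(counts)
  names(out) <- names(counts)
  out <- out[.hill_order(names(out))]
  class(out) <- "elemental_formula"
  out
}

.hill_order <- function(symbols) {
  rest <- sort(setdiff(symbols, c("C", "H")))
  match(intersect(c("C", "H", rest), symbols), symbols)
}

#' Parse an elemental formula string
#'
#' Parses compact formula strings such as `"C12H22O4"` into element counts.
#' Each token is an element symbol optionally followed by a positive integer.
#'
#' @param text Formula string, e.g. `"C12H24O3"`.
#' @return An [elemental_formula()].
#' @examples
#' parse_formula("C12H22O4")
#' parse_formula("H2O")
#' @export
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1 || is.na(text) || !nzchar(text))
    stop("formula string must be a single non-empty character value", call. = FALSE)
  if (!grepl("^([A-Z][a-z]?[0-9]*)+$", text))
    stop("malformed formula string: '", text, "'", call. = FALSE)
  toks <- regmatches(text, gregexpr("[A-Z][a-z]?[0-9]*", text))[[1]]
  els <- gsub("[0-9]", "", toks)
  ns <- sub("^[A-Za-z]+", "", toks)
  if (any(ns == "0"))
    stop("malformed count in formula string: '", text, "'", call. = FALSE)
  counts <- ifelse(nzchar(ns), suppressWarnings(as.integer(ns)), 1L)
  elemental_formula(stats::setNames(counts, els))
}

#' Format an elemental formula as a string
#'
#' Inverse of [parse_formula()]: Hill-ordered compact notation, count 1
#' implicit.
#'
#' @param f An [elemental_formula()].
#' @return Character scalar.
#' @export
format_formula <- function(f) {
  stopifnot(inherits(f, "elemental_formula"))
  if (length(f) == 0) return("")
  paste0(names(f), ifelse(unclass(f) == 1L, "", unclass(f)), collapse = "")
}

#' @export
print.elemental_formula <- function(x, ...) {
  cat("<elemental_formula> ", format_formula(x), "\n", sep = "")
  invisible(x)
}

#' @export
`+.elemental_formula` <- function(e1, e2) {
  stopifnot(inherits(e1, "elemental_formula"), inherits(e2, "elemental_formula"))
  all_el <- union(names(e1), names(e2))
  a <- stats::setNames(rep(0L, length(all_el)), all_el)
  a[names(e1)] <- a[names(e1)] + unclass(e1)
  a[names(e2)] <- a[names(e2)] + unclass(e2)
  elemental_formula(a)
}

#' @export
`-.elemental_formula` <- function(e1, e2) {
  stopifnot(inherits(e1, "elemental_formula"), inherits(e2, "elemental_formula"))
  all_el <- union(names(e1), names(e2))
  a <- stats::setNames(rep(0L, length(all_el)), all_el)
  a[names(e1)] <- a[names(e1)] + unclass(e1)
  a[names(e2)] <- a[names(e2)] - unclass(e2)
  if (any(a < 0))
    stop("formula subtraction would give a negative count for: ",
         paste(names(a)[a < 0], collapse = ", "), call. = FALSE)
  elemental_formula(a)
}

#' Monoisotopic mass of an elemental formula
#'
#' @param f An [elemental_formula()] or a formula string.
#' @return Monoisotopic mass in Da; 0 for the empty formula. Additive:
#'   `mono_mass(a + b) == mono_mass(a) + mono_mass(b)`.
#' @examples
#' mono_mass("H2O")       # 18.0105646
#' mono_mass("C12H24O3")  # beta-hydroxy C12 fatty acid
#' @export
mono_mass <- function(f) {
  if (is.character(f)) f <- parse_formula(f)
  stopifnot(inherits(f, "elemental_formula"))
  if (length(f) == 0) return(0)
  am <- atomic_masses()
  sum(am[names(f)] * unclass(f))
}

#' Amino-acid residue mass table
#'
#' The monoisotopic residue (i.e. dehydrated amino acid) masses used for
#' peptide mass computation, read from the versioned table shipped in
#' `extdata/residue_masses.tsv`. Leucine and isoleucine are isobaric and
#' share one mass; collision-induced dissociation cannot distinguish them,
#' so sequences here conventionally use "L".
#'
#' @return Data frame with columns `symbol`, `formula`, `mass` (Da).
#' @export
residue_table <- function() {
  if (is.null(.lipoladder_cache$residues)) {
    tab <- utils::read.delim(.extdata("residue_masses.tsv"), stringsAsFactors = FALSE)
    .lipoladder_cache$residues <- tab
  }
  .lipoladder_cache$residues
}

#' Sum of residue masses of a peptide sequence
#'
#' Plain sum of residue masses: no termini, no water. The neutral mass of a
#' free linear peptide would be this sum plus one water.
#'
#' @param sequence Residue-letter string (one-letter code); may be empty.
#' @param table Residue table as returned by [residue_table()].
#' @return Mass in Da.
#' @examples
#' residue_sum("LLLVDLL")
#' @export
residue_sum <- function(sequence, table = residue_table()) {
  stopifnot(is.character(sequence), length(sequence) == 1, !is.na(sequence))
  if (!nzchar(sequence)) return(0)
  letters1 <- strsplit(sequence, "")[[1]]
  idx <- match(letters1, table$symbol)
  if (anyNA(idx))
    stop("unknown residue letter(s): ",
         paste(unique(letters1[is.na(idx)]), collapse = ", "), call. = FALSE)
  sum(table$mass[idx])
}
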