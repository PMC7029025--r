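# Theoretical b/y fragment ladders for (ring-opened) lipopeptides, spectrum
# matching, and the +18 Da ring-opening daughter-ion topology test.

#' Ring-opened parent m/z
#'
#' Collision-induced dissociation of a lactone-cyclised depsipeptide first
#' opens the ring hydrolytically, producing a daughter ion 18.0105646 Da
#' above the parent. Observing that daughter is diagnostic of cyclic
#' topology.
#'
#' @param parent_mz Parent \eqn{[M+H]^+} (Da, > 0 for a real ion; 0 allowed
#'   for the degenerate identity).
#' @return `parent_mz + 18.0105646`.
#' @export
ring_open <- function(parent_mz) {
  stopifnot(is.numeric(parent_mz), all(parent_mz >= 0))
  parent_mz + mass_constants()$water
}

#' Theoretical MS2 fragment table of a lipopeptide hypothesis
#'
#' Emits the singly protonated b and y ion series of the linear (or
#' ring-opened cyclic) form: for an n-residue sequence, b_i carries the
#' N-terminal beta-hydroxy-acyl modification
#' (\eqn{b_i = \sum res_{1..i} + (tail - H_2O) + H^+}) and y_j the free
#' C-terminus (\eqn{y_j = \sum res_{n-j+1..n} + H_2O + H^+}), i, j in
#' 1..n-1, giving 2(n-1) ions. A cyclic spec is ring-opened at the ester
#' before series generation and additionally contributes the
#' `ring_opened_parent` ion at parent + 18.0105646.
#'
#' @param spec A [lipopeptide_spec()] with at least 2 residues.
#' @param table Residue table.
#' @return Data frame with columns `series` (`"b"`, `"y"`,
#'   `"ring_opened_parent"`), `index` (1..n-1; 0 for the ring-opened
#'   parent), `mz`, `composition_note`.
#' @export
fragment_table <- function(spec, table = residue_table()) {
  stopifnot(inherits(spec, "lipopeptide_spec"))
  res <- strsplit(spec$sequence, "")[[1]]
  n <- length(res)
  if (n < 2) stop("fragmentation needs at least 2 residues", call. = FALSE)
  k <- mass_constants()
  masses <- vapply(res, function(r) residue_sum(r, table), 0)
  acyl_mod <- mono_mass(tail_formula(spec)) - k$water
  idx <- seq_len(n - 1)
  b_mz <- cumsum(masses)[idx] + acyl_mod + k$proton
  # y_j covers residues n-j+1..n
  y_mz <- vapply(idx, function(j) sum(masses[(n - j + 1):n]), 0) + k$water + k$proton
  out <- rbind(
    data.frame(series = "b", index = idx, mz = b_mz,
               composition_note = sprintf("b%d (%s + C%d beta-OH acyl)", idx,
                                          substring(spec$sequence, 1, idx),
                                          spec$tail_carbons),
               stringsAsFactors = FALSE),
    data.frame(series = "y", index = idx, mz = y_mz,
               composition_note = sprintf("y%d (%s + H2O)", idx,
                                          substring(spec$sequence, n - idx + 1)),
               stringsAsFactors = FALSE)
  )
  if (spec$topology == "cyclic") {
    parent <- spec_mz(spec, table)
    out <- rbind(out, data.frame(
      series = "ring_opened_parent", index = 0L, mz = ring_open(parent),
      composition_note = "parent + H2O (lactone ring opening)",
      stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Match an observed MS2 spectrum against a lipopeptide hypothesis
#'
#' Greedy nearest-peak matching of the theoretical b/y ions to the observed
#' fragments: theoretical ions are visited in increasing m/z and each
#' observed peak is consumed at most once. Coverage is the fraction of the
#' 2(n-1) theoretical b/y positions matched within `frag_tol`. The topology
#' call applies [topology_test()] to the same spectrum.
#'
#' @param parent_mz Precursor \eqn{[M+H]^+} (Da).
#' @param peaks Data frame with columns `mz` and `intensity` (may be empty).
#' @param spec A [lipopeptide_spec()].
#' @param frag_tol Fragment match tolerance in Da (default 0.05).
#' @param daughter_tol Tolerance for the ring-opened daughter (default 0.2).
#' @param table Residue table.
#' @return A `spectrum_match`: list with `parent_mz`, `matched` (data frame
#'   of series, index, theoretical and observed m/z, delta), `coverage`,
#'   `topology_call`.
#' @export
match_spectrum <- function(parent_mz, peaks, spec, frag_tol = 0.05,
                           daughter_tol = 0.2, table = residue_table()) {
  stopifnot(inherits(spec, "lipopeptide_spec"))
  if (frag_tol <= 0) stop("frag_tol must be positive", call. = FALSE)
  peaks <- .as_spectrum(peaks)
  theo <- fragment_table(spec, table)
  theo <- theo[theo$series %in% c("b", "y"), , drop = FALSE]
  theo <- theo[order(theo$mz, theo$series, theo$index), , drop = FALSE]
  used <- logical(nrow(peaks))
  hits <- vector("list", nrow(theo))
  for (k in seq_len(nrow(theo))) {
    if (!nrow(peaks)) break
    d <- abs(peaks$mz - theo$mz[k])
    d[used] <- Inf
    j <- which.min(d)
    if (length(j) && is.finite(d[j]) && d[j] <= frag_tol) {
      used[j] <- TRUE
      hits[[k]] <- data.frame(series = theo$series[k], index = theo$index[k],
                              theoretical_mz = theo$mz[k],
                              observed_mz = peaks$mz[j],
                              intensity = peaks$intensity[j],
                              delta = peaks$mz[j] - theo$mz[k],
                              stringsAsFactors = FALSE)
    }
  }
  matched <- do.call(rbind, hits[!vapply(hits, is.null, TRUE)])
  if (is.null(matched))
    matched <- data.frame(series = character(), index = integer(),
                          theoretical_mz = numeric(), observed_mz = numeric(),
                          intensity = numeric(), delta = numeric(),
                          stringsAsFactors = FALSE)
  structure(
    list(parent_mz = parent_mz, matched = matched,
         coverage = nrow(matched) / nrow(theo),
         topology_call = topology_test(parent_mz, peaks, daughter_tol)),
    class = "spectrum_match")
}

#' @export
print.spectrum_match <- function(x, ...) {
  cat(sprintf("<spectrum_match> parent %.4f | coverage %.2f | topology %s\n",
              x$parent_mz, x$coverage, x$topology_call))
  if (nrow(x$matched)) print(x$matched, row.names = FALSE)
  invisible(x)
}

.as_spectrum <- function(peaks) {
  if (is.null(peaks) || (is.data.frame(peaks) && nrow(peaks) == 0))
    return(data.frame(mz = numeric(), intensity = numeric()))
  stopifnot(is.data.frame(peaks), "mz" %in% names(peaks))
  if (!("intensity" %in% names(peaks))) peaks$intensity <- 1
  peaks[, c("mz", "intensity"), drop = FALSE]
}

#' Ring-opening daughter-ion topology test
#'
#' Calls a precursor cyclic if its MS2 spectrum contains an ion within
#' `daughter_tol` of parent + 18.0105646 (the hydrolytically ring-opened
#' parent); linear if fragments are present but no such daughter is;
#' inconclusive on an empty spectrum.
#'
#' @inheritParams match_spectrum
#' @param daughter_tol Tolerance in Da (default 0.2, wide enough for the
#'   mass accuracy typically seen on daughter ions near the precursor).
#' @return `"cyclic"`, `"linear"` or `"inconclusive"`.
#' @export
topology_test <- function(parent_mz, peaks, daughter_tol = 0.2) {
  if (daughter_tol <= 0) stop("daughter_tol must be positive", call. = FALSE)
  peaks <- .as_spectrum(peaks)
  if (nrow(peaks) == 0) return("inconclusive")
  if (any(abs(peaks$mz - ring_open(parent_mz)) <= daughter_tol)) "cyclic"
  else "linear"
}

#' Reconcile MS1 and MS2 topology evidence
#'
#' MS2 evidence (the ring-opening daughter test) overrides the MS1 water-
#' partner call when they conflict; an inconclusive MS2 defers to MS1.
#'
#' @param ms1_call MS1 topology call (`"cyclic"`, `"linear"`, `"unknown"`).
#' @param ms2_call MS2 topology call (`"cyclic"`, `"linear"`,
#'   `"inconclusive"`).
#' @return List with `topology` and `note` (character; records conflicts).
#' @export
reconcile_topology <- function(ms1_call, ms2_call) {
  if (is.na(ms2_call) || ms2_call == "inconclusive") {
    return(list(topology = ms1_call,
                note = "MS2 inconclusive; MS1 call retained"))
  }
  if (is.na(ms1_call) || ms1_call == "unknown" || identical(ms1_call, ms2_call)) {
    return(list(topology = ms2_call, note = "MS1 and MS2 evidence agree"))
  }
  list(topology = ms2_call,
       note = sprintf("conflict: MS1 called %s but MS2 called %s; MS2 takes precedence",
                      ms1_call, ms2_call))
}

#' Fold MS2 spectra into an annotated family
#'
#' Associates each spectrum with the family member nearest its precursor
#' m/z (within `precursor_tol`), runs the ring-opening topology test and
#' reconciles it with the MS1 call; conflicts are recorded in the family
#' warnings and the topology updated.
#'
#' @param family An annotated `isoform_family`.
#' @param spectra List of spectra as returned by [read_mgf()] or
#'   [simulate_ms2()] wrapped with a `precursor_mz`: each element a list
#'   with `precursor_mz` and `peaks`.
#' @param daughter_tol Daughter-ion tolerance (Da).
#' @param precursor_tol Precursor association tolerance (Da, default 0.03).
#' @return The family with MS2-reconciled topology calls.
#' @export
apply_ms2_evidence <- function(family, spectra, daughter_tol = 0.2,
                               precursor_tol = 0.03) {
  stopifnot(inherits(family, "isoform_family"))
  for (sp in spectra) {
    d <- abs(family$members$mz - sp$precursor_mz)
    if (!length(d) || min(d) > precursor_tol) next
    i <- which.min(d)
    ms2 <- topology_test(family$members$mz[i], sp$peaks, daughter_tol)
    rec <- reconcile_topology(family$members$topology[i], ms2)
    if (!identical(rec$topology, family$members$topology[i]))
      family$warnings <- c(family$warnings,
        sprintf("peak %s: %s", family$members$id[i], rec$note))
    family$members$topology[i] <- rec$topology
  }
  family
}
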