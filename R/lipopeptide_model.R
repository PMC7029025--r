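# Theoretical neutral / protonated masses for cyclic and linear lipopeptide
# hypotheses, and ranking of candidate compositions against an observed m/z.
#
# Mass bookkeeping convention: the fatty-acid tail is represented as the free
# saturated beta-hydroxy acid CnH2nO3 (minus 2 H per double bond). Acylation
# of the N-terminus and lactone closure are explicit water losses, so
#   linear  M = sum(residues) + tail        (the amide condensation consumes
#                                            the water the free termini add)
#   cyclic  M = linear - H2O                (ester closure of the lactone)
# which forces assemble_neutral(linear) - assemble_neutral(cyclic) = 18.0105646
# for every spec.

#' Construct a lipopeptide hypothesis
#'
#' A lipopeptide hypothesis is a peptide sequence N-acylated with a
#' beta-hydroxy fatty acid of a given carbon count, in cyclic (lactone,
#' ester between the beta-hydroxyl and the C-terminal carboxyl) or linear
#' (free beta-OH and free C-terminal carboxyl) topology.
#'
#' @param sequence Residue-letter peptide sequence, e.g. `"LLLVDLL"`.
#' @param tail_carbons Integer >= 3: carbon count of the beta-hydroxy
#'   fatty-acid tail.
#' @param topology `"cyclic"` or `"linear"`.
#' @param double_bonds Number of C=C double bonds in the tail (default 0,
#'   i.e. saturated; each double bond removes 2 H). Branching is not
#'   represented because it is mass-identical.
#' @return A `lipopeptide_spec` object.
#' @examples
#' lipopeptide_spec("LLLVDLL", 12, "cyclic")
#' @export
lipopeptide_spec <- function(sequence, tail_carbons,
                             topology = c("cyclic", "linear"),
                             double_bonds = 0L) {
  topology <- match.arg(topology)
  stopifnot(is.character(sequence), length(sequence) == 1, nzchar(sequence))
  if (length(tail_carbons) != 1 || is.na(tail_carbons) ||
      tail_carbons != round(tail_carbons) || tail_carbons < 3)
    stop("tail_carbons must be a single integer >= 3", call. = FALSE)
  if (double_bonds < 0 || double_bonds != round(double_bonds))
    stop("double_bonds must be a non-negative integer", call. = FALSE)
  # validates residue letters eagerly
  residue_sum(sequence)
  structure(
    list(sequence = sequence, tail_carbons = as.integer(tail_carbons),
         topology = topology, double_bonds = as.integer(double_bonds)),
    class = "lipopeptide_spec"
  )
}

#' @export
print.lipopeptide_spec <- function(x, ...) {
  cat(sprintf("<lipopeptide_spec> %s | C%d beta-OH tail%s | %s\n",
              x$sequence, x$tail_carbons,
              if (x$double_bonds > 0) sprintf(" (%d C=C)", x$double_bonds) else "",
              x$topology))
  invisible(x)
}

#' Elemental formula of the free beta-hydroxy fatty-acid tail
#'
#' Saturated tails follow CnH2nO3; each double bond removes two hydrogens.
#'
#' @param spec A [lipopeptide_spec()].
#' @return An [elemental_formula()].
#' @export
tail_formula <- function(spec) {
  stopifnot(inherits(spec, "lipopeptide_spec"))
  n <- spec$tail_carbons
  h <- 2L * n - 2L * spec$double_bonds
  if (h <= 0) stop("too many double bonds for tail length", call. = FALSE)
  elemental_formula(c(C = n, H = h, O = 3L))
}

#' Theoretical neutral monoisotopic mass of a lipopeptide hypothesis
#'
#' @param spec A [lipopeptide_spec()].
#' @param table Residue table, see [residue_table()].
#' @return Neutral monoisotopic mass in Da.
#' @examples
#' assemble_neutral(lipopeptide_spec("LLLVDLL", 12, "cyclic"))  # 977.6776
#' @export
assemble_neutral <- function(spec, table = residue_table()) {
  stopifnot(inherits(spec, "lipopeptide_spec"))
  m <- residue_sum(spec$sequence, table) + mono_mass(tail_formula(spec))
  if (spec$topology == "cyclic") m <- m - mass_constants()$water
  m
}

#' Singly protonated m/z of a neutral mass
#'
#' All observed ions are treated as \eqn{[M+H]^+} (positive-mode
#' electrospray, charge 1).
#'
#' @param neutral Neutral mass in Da (must be >= 0).
#' @return m/z of the singly protonated species.
#' @export
protonated_mz <- function(neutral) {
  stopifnot(is.numeric(neutral), all(neutral >= 0))
  neutral + mass_constants()$proton
}

#' Theoretical [M+H]+ of a lipopeptide hypothesis
#'
#' @inheritParams assemble_neutral
#' @return m/z in Da.
#' @export
spec_mz <- function(spec, table = residue_table()) {
  protonated_mz(assemble_neutral(spec, table))
}

#' Build a grid of candidate lipopeptide hypotheses
#'
#' Cartesian product of sequences, tail carbon counts and topologies, as a
#' list of [lipopeptide_spec()] objects.
#'
#' @param sequences Character vector of residue sequences.
#' @param tail_carbons Integer vector of tail carbon counts.
#' @param topologies Character vector, subset of `c("cyclic", "linear")`.
#' @return List of `lipopeptide_spec`.
#' @export
candidate_specs <- function(sequences, tail_carbons,
                            topologies = c("cyclic", "linear")) {
  grid <- expand.grid(sequence = sequences, tail_carbons = tail_carbons,
                      topology = topologies, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(grid)), function(i)
    lipopeptide_spec(grid$sequence[i], grid$tail_carbons[i], grid$topology[i]))
}

#' Rank candidate compositions against an observed m/z
#'
#' Computes, for every candidate hypothesis, the theoretical \eqn{[M+H]^+},
#' the mass error (observed - theoretical) and the relative error in ppm,
#' and returns the candidates sorted by absolute ppm error (ties broken by
#' tail carbons, then topology, then sequence, so the order is deterministic
#' and invariant under permutation of the input).
#'
#' @param observed_mz Observed m/z (Da).
#' @param candidates Non-empty list of [lipopeptide_spec()] objects.
#' @param table Residue table.
#' @param ppm_window Candidates within this |ppm| are flagged as matches in
#'   the `within_window` column (default 30 ppm).
#' @return Data frame with columns `sequence`, `tail_carbons`, `topology`,
#'   `theoretical_mz`, `delta`, `ppm`, `within_window`.
#' @export
composition_fit <- function(observed_mz, candidates, table = residue_table(),
                            ppm_window = 30) {
  stopifnot(is.numeric(observed_mz), length(observed_mz) == 1)
  if (!is.list(candidates) || length(candidates) == 0)
    stop("candidate set must be a non-empty list of lipopeptide_spec", call. = FALSE)
  rows <- lapply(candidates, function(sp) {
    stopifnot(inherits(sp, "lipopeptide_spec"))
    theo <- spec_mz(sp, table)
    delta <- observed_mz - theo
    data.frame(sequence = sp$sequence, tail_carbons = sp$tail_carbons,
               topology = sp$topology, theoretical_mz = theo,
               delta = delta, ppm = delta / theo * 1e6,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$within_window <- abs(out$ppm) <= ppm_window
  ord <- order(abs(out$ppm), out$tail_carbons, out$topology, out$sequence)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Convert a printed lipid-tail formula label to tail parameters
#'
#' Vendor peptide-sequencing software expresses the fatty-acid tail as a
#' "modification formula" whose water bookkeeping differs from the free-acid
#' convention used internally. The shipped conversion table maps those
#' printed labels to tail carbon count and topology context.
#'
#' @param label Printed tail formula label, e.g. `"C12H22O4"`.
#' @return List with `tail_carbons` and `topology`.
#' @export
tail_label_to_carbons <- function(label) {
  tab <- utils::read.delim(.extdata("tail_formula_labels.tsv"),
                           stringsAsFactors = FALSE)
  i <- match(label, tab$label)
  if (is.na(i))
    stop("unknown tail formula label: '", label, "'", call. = FALSE)
  list(tail_carbons = tab$tail_carbons[i], topology = tab$topology[i])
}
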