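# Structure-activity analysis: monotone trends of antimicrobial potency
# (inhibition zone, MIC) with fatty-acid tail length, and the
# bacteria/fungi selectivity crossover.

#' Bundled antimicrobial activity table
#'
#' Mean +/- SD inhibition-zone and MIC measurements (independent
#' triplicates) of the four cyclic isoforms A-D against a Gram-positive
#' bacterial model (*Staphylococcus* spp) and a fungal model (*Trichoderma*
#' spp), keyed by designation with tail carbon counts joined from the
#' annotation module. Note the `zone_measure` column: the fungal zones were
#' published labelled as a radius while the bacterial zones are diameters;
#' the numbers are stored verbatim as printed.
#'
#' @return Data frame with columns `designation`, `tail_carbons`,
#'   `organism_class`, `zone_mm_mean`, `zone_mm_sd`, `mic_ugml_mean`,
#'   `mic_ugml_sd`, `zone_measure`.
#' @export
activity_table <- function() {
  read_activity(.extdata("activity_table.csv"))
}

#' Read an antimicrobial activity CSV
#'
#' @param path CSV with the columns of [activity_table()] (the
#'   `zone_measure` column is optional).
#' @return Validated data frame of activity records.
#' @export
read_activity <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("designation", "tail_carbons", "organism_class",
            "zone_mm_mean", "zone_mm_sd", "mic_ugml_mean", "mic_ugml_sd")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("activity table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!all(df$organism_class %in% c("bacteria", "fungi")))
    stop("organism_class must be 'bacteria' or 'fungi'", call. = FALSE)
  if (any(df$mic_ugml_mean <= 0)) stop("MIC means must be positive", call. = FALSE)
  if (any(df$mic_ugml_sd < 0) || any(df$zone_mm_sd < 0))
    stop("SDs must be non-negative", call. = FALSE)
  df
}

.sar_select <- function(records, organism_class, response) {
  organism_class <- match.arg(organism_class, c("bacteria", "fungi"))
  response <- match.arg(response, c("mic", "zone"))
  r <- records[records$organism_class == organism_class, , drop = FALSE]
  y <- if (response == "mic") r$mic_ugml_mean else r$zone_mm_mean
  ysd <- if (response == "mic") r$mic_ugml_sd else r$zone_mm_sd
  if (length(unique(r$tail_carbons)) < 3)
    stop("need at least 3 records with distinct tail_carbons for class '",
         organism_class, "'", call. = FALSE)
  list(x = r$tail_carbons, y = y, ysd = ysd)
}

#' Tail-length vs activity trend (Spearman)
#'
#' Spearman rank correlation between fatty-acid tail carbon count and the
#' mean response (MIC or inhibition zone) within one organism class. Rank
#' correlation is used because the claim under test is ordinal (longer
#' tails are more/less potent), with only four tail lengths and no
#' linearity assumption.
#'
#' @param records Activity records, see [activity_table()].
#' @param organism_class `"bacteria"` or `"fungi"`.
#' @param response `"mic"` or `"zone"`.
#' @return List with `rho` and `direction` (`"increasing"`, `"decreasing"`
#'   or `"flat"` when |rho| < 0.5).
#' @examples
#' sar_trend(activity_table(), "bacteria", "mic")   # rho = +1
#' sar_trend(activity_table(), "fungi", "mic")      # rho = -1
#' @export
sar_trend <- function(records, organism_class, response = c("mic", "zone")) {
  s <- .sar_select(records, organism_class, match.arg(response))
  if (stats::sd(s$y) == 0)
    stop("constant response: rank correlation is undefined", call. = FALSE)
  rho <- stats::cor(s$x, s$y, method = "spearman")
  direction <- if (abs(rho) < 0.5) "flat"
               else if (rho > 0) "increasing" else "decreasing"
  list(rho = rho, direction = direction)
}

#' Per-isoform selectivity index and crossover
#'
#' The selectivity index of an isoform is MIC(fungi) / MIC(bacteria):
#' values above 1 mean the compound is more potent against bacteria
#' (bacteria-selective), below 1 more potent against fungi. The crossover
#' is the adjacent pair of isoforms (ordered by tail carbons) whose ratios
#' bracket 1 - the tail length at which selectivity flips.
#'
#' @param records Activity records with both organism classes present for
#'   every isoform.
#' @return Data frame (one row per isoform, ordered by tail carbons) with
#'   `designation`, `tail_carbons`, `mic_bacteria`, `mic_fungi`, `ratio`,
#'   `selectivity`; the crossover pair is attached as
#'   `attr(, "crossover")`, a character vector of the two designations (or
#'   NULL if the ratios never cross 1).
#' @examples
#' si <- selectivity_index(activity_table())
#' attr(si, "crossover")  # "B" "C"
#' @export
selectivity_index <- function(records) {
  bact <- records[records$organism_class == "bacteria", , drop = FALSE]
  fung <- records[records$organism_class == "fungi", , drop = FALSE]
  iso <- unique(records$designation)
  miss <- iso[!(iso %in% bact$designation) | !(iso %in% fung$designation)]
  if (length(miss))
    stop("isoform(s) missing one organism class: ", paste(miss, collapse = ", "),
         call. = FALSE)
  out <- data.frame(
    designation = bact$designation,
    tail_carbons = bact$tail_carbons,
    mic_bacteria = bact$mic_ugml_mean,
    mic_fungi = fung$mic_ugml_mean[match(bact$designation, fung$designation)],
    stringsAsFactors = FALSE)
  out$ratio <- out$mic_fungi / out$mic_bacteria
  out$selectivity <- ifelse(out$ratio > 1, "bacteria", "fungi")
  out <- out[order(out$tail_carbons), , drop = FALSE]
  rownames(out) <- NULL
  crossover <- NULL
  if (nrow(out) >= 2) {
    s <- sign(out$ratio - 1)
    flip <- which(s[-length(s)] * s[-1] < 0)
    if (length(flip))
      crossover <- c(out$designation[flip[1]], out$designation[flip[1] + 1])
  }
  attr(out, "crossover") <- crossover
  out
}

#' Bootstrap stability of the tail-length trend
#'
#' The published activity values are triplicate means with SDs; this
#' propagates that uncertainty by resampling each mean from a normal
#' distribution with its printed SD, recomputing the Spearman trend, and
#' reporting the fraction of resamples that preserve the sign of the
#' point-estimate rho.
#'
#' @inheritParams sar_trend
#' @param n_boot Number of resamples (>= 100).
#' @param seed Integer seed; the result is deterministic given the seed.
#' @return Fraction in [0, 1] of resamples whose rho has the same sign as
#'   the point estimate.
#' @export
bootstrap_trend <- function(records, organism_class, response = c("mic", "zone"),
                            n_boot = 1000, seed = 1L) {
  if (n_boot < 100) stop("n_boot must be at least 100", call. = FALSE)
  response <- match.arg(response)
  s <- .sar_select(records, organism_class, response)
  if (anyNA(s$ysd)) stop("SDs are required for the bootstrap", call. = FALSE)
  base_sign <- sign(sar_trend(records, organism_class, response)$rho)
  local_seed(seed, {
    same <- vapply(seq_len(n_boot), function(b) {
      yb <- stats::rnorm(length(s$y), mean = s$y, sd = s$ysd)
      if (stats::sd(yb) == 0) return(NA)
      sign(stats::cor(s$x, yb, method = "spearman")) == base_sign
    }, NA)
    mean(same, na.rm = TRUE)
  })
}
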