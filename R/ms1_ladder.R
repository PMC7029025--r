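# CH2 homolog-ladder and water-partner detection in MS1 peak lists:
# families, topology calls, tail-length propagation and designations.

CH2_DA   <- 14.0156500
WATER_DA <- 18.0105646

#' Construct and validate an MS1 peak list
#'
#' @param rt Retention times in minutes (>= 0), or a data frame with columns
#'   `rt_min`, `mz`, `intensity` and optionally `id`.
#' @param mz m/z values (> 0).
#' @param intensity Intensities (>= 0); defaults to 1.
#' @param id Optional character ids; defaults to the row index.
#' @return A `peak_list`: data frame with columns `id`, `rt_min`, `mz`,
#'   `intensity`.
#' @export
peak_list <- function(rt, mz = NULL, intensity = NULL, id = NULL) {
  if (is.data.frame(rt)) {
    df <- rt
    need <- c("rt_min", "mz")
    miss <- setdiff(need, names(df))
    if (length(miss))
      stop("peak list is missing column(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    rt <- df$rt_min
    mz <- df$mz
    intensity <- if ("intensity" %in% names(df)) df$intensity else NULL
    id <- if ("id" %in% names(df)) as.character(df$id) else NULL
  }
  n <- length(rt)
  if (is.null(intensity)) intensity <- rep(1, n)
  if (is.null(id)) id <- as.character(seq_len(n))
  stopifnot(length(mz) == n, length(intensity) == n, length(id) == n)
  if (anyDuplicated(id)) stop("peak ids must be unique", call. = FALSE)
  if (n > 0) {
    if (any(!is.finite(rt)) || any(rt < 0)) stop("rt must be finite and >= 0", call. = FALSE)
    if (any(!is.finite(mz)) || any(mz <= 0)) stop("mz must be finite and > 0", call. = FALSE)
    if (any(!is.finite(intensity)) || any(intensity < 0))
      stop("intensity must be finite and >= 0", call. = FALSE)
  }
  out <- data.frame(id = id, rt_min = as.numeric(rt), mz = as.numeric(mz),
                    intensity = as.numeric(intensity), stringsAsFactors = FALSE)
  class(out) <- c("peak_list", "data.frame")
  out
}

.new_family <- function(members, edges, warnings = character()) {
  members <- members[order(members$mz, members$rt_min, members$id), , drop = FALSE]
  rownames(members) <- NULL
  structure(list(members = members, edges = edges, anchor = NULL,
                 warnings = warnings),
            class = "isoform_family")
}

.empty_edges <- function() {
  data.frame(from = character(), to = character(), kind = character(),
             observed_delta = numeric(), residual = numeric(),
             stringsAsFactors = FALSE)
}

#' Detect CH2 homolog ladders and water partners in a peak list
#'
#' Builds edges between peak pairs whose m/z difference matches the
#' methylene spacing (14.01565 Da, homologs differing by one tail CH2) or
#' the water spacing (18.01056 Da, linear vs cyclic topology partners)
#' within the given tolerances, resolves conflicting edges (each peak takes
#' at most one partner per edge kind and direction, preferring the smaller
#' mass residual, then the smaller retention-time gap), and groups the
#' connected components into isoform families. Peaks connected to nothing
#' become singleton families. The result is deterministic and invariant
#' under permutation of the input rows.
#'
#' @param peaks A [peak_list()].
#' @param ch2_tol Tolerance (Da) for the CH2 spacing; default 0.03.
#' @param water_tol Tolerance (Da) for the water spacing; default 0.03.
#' @return List of `isoform_family` objects, sorted by decreasing size then
#'   by lightest member m/z. Members carry `topology`, `tail_carbons`,
#'   `designation`, `nominal_offset` columns initialised to NA.
#' @export
detect_ladders <- function(peaks, ch2_tol = 0.03, water_tol = 0.03) {
  peaks <- peak_list(peaks)
  if (nrow(peaks) < 1) stop("need at least one peak", call. = FALSE)
  if (ch2_tol <= 0 || water_tol <= 0)
    stop("tolerances must be positive", call. = FALSE)
  p <- peaks[order(peaks$mz, peaks$rt_min, peaks$id), , drop = FALSE]
  n <- nrow(p)

  cand <- list()
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in seq((i + 1), n)) {
        d <- p$mz[j] - p$mz[i]
        if (d > WATER_DA + water_tol) break
        kind <- NA_character_; resid <- NA_real_
        if (abs(d - CH2_DA) <= ch2_tol) {
          kind <- "CH2"; resid <- abs(d - CH2_DA)
        } else if (abs(d - WATER_DA) <= water_tol) {
          kind <- "WATER"; resid <- abs(d - WATER_DA)
        }
        if (!is.na(kind))
          cand[[length(cand) + 1L]] <- data.frame(
            from = p$id[i], to = p$id[j], kind = kind, observed_delta = d,
            residual = resid, rt_gap = abs(p$rt_min[j] - p$rt_min[i]),
            stringsAsFactors = FALSE)
      }
    }
  }
  edges <- .empty_edges()
  if (length(cand)) {
    cand <- do.call(rbind, cand)
    # greedy conflict resolution: one partner per (peak, kind, direction)
    cand <- cand[order(cand$residual, cand$rt_gap, cand$from, cand$to), , drop = FALSE]
    used_from <- character(); used_to <- character()
    keep <- logical(nrow(cand))
    for (k in seq_len(nrow(cand))) {
      kf <- paste(cand$from[k], cand$kind[k])
      kt <- paste(cand$to[k], cand$kind[k])
      if (!(kf %in% used_from) && !(kt %in% used_to)) {
        keep[k] <- TRUE
        used_from <- c(used_from, kf)
        used_to <- c(used_to, kt)
      }
    }
    edges <- cand[keep, c("from", "to", "kind", "observed_delta", "residual"),
                  drop = FALSE]
    edges <- edges[order(edges$from, edges$to, edges$kind), , drop = FALSE]
    rownames(edges) <- NULL
  }

  # connected components (union-find over peak ids)
  parent <- stats::setNames(seq_len(n), p$id)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (k in seq_len(nrow(edges))) {
    a <- find(match(edges$from[k], p$id))
    b <- find(match(edges$to[k], p$id))
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  comp <- vapply(seq_len(n), find, 0L)

  members_cols <- function(df) {
    df$topology <- NA_character_
    df$tail_carbons <- NA_integer_
    df$designation <- NA_character_
    df$nominal_offset <- NA_integer_
    df
  }
  fams <- lapply(unique(comp), function(ci) {
    sel <- comp == ci
    ids <- p$id[sel]
    .new_family(members_cols(as.data.frame(p[sel, , drop = FALSE])),
                edges[edges$from %in% ids & edges$to %in% ids, , drop = FALSE])
  })
  sizes <- vapply(fams, function(f) nrow(f$members), 0L)
  lightest <- vapply(fams, function(f) min(f$members$mz), 0)
  fams <- fams[order(-sizes, lightest)]
  class(fams) <- "isoform_family_list"
  fams
}

#' Classify cyclic vs linear topology from MS1 evidence
#'
#' For every water edge the heavier member is called linear (the hydrated,
#' ring-opened form) and the lighter member cyclic. Peaks without a water
#' edge but connected to the family by CH2 edges are cyclic candidates;
#' isolated peaks stay `"unknown"`. A warning is appended whenever a linear
#' member does not elute earlier than its cyclic partner (on reverse phase
#' the free acid / free hydroxyl linear form is less retained); retention
#' time is corroboration, never a filter.
#'
#' @param family An `isoform_family` from [detect_ladders()].
#' @return The family with the `topology` member column filled in.
#' @export
classify_topology_ms1 <- function(family) {
  stopifnot(inherits(family, "isoform_family"))
  m <- family$members
  topo <- stats::setNames(rep(NA_character_, nrow(m)), m$id)
  we <- family$edges[family$edges$kind == "WATER", , drop = FALSE]
  for (k in seq_len(nrow(we))) {
    lighter <- we$from[k]; heavier <- we$to[k]
    if (identical(topo[[heavier]], "cyclic")) {
      family$warnings <- c(family$warnings, sprintf(
        "peak %s participates in chained water edges; linear call retained",
        heavier))
    }
    topo[heavier] <- "linear"
    if (!identical(topo[[lighter]], "linear")) topo[lighter] <- "cyclic"
    else {
      topo[lighter] <- "linear"
      family$warnings <- c(family$warnings, sprintf(
        "peak %s participates in chained water edges; linear call retained",
        lighter))
    }
    # RT corroboration: linear partners eluted ~3 min earlier in practice
    rt_lin <- m$rt_min[m$id == heavier]
    rt_cyc <- m$rt_min[m$id == lighter]
    if (rt_lin >= rt_cyc)
      family$warnings <- c(family$warnings, sprintf(
        "linear member %s (rt %.2f min) does not elute earlier than its cyclic partner %s (rt %.2f min)",
        heavier, rt_lin, lighter, rt_cyc))
  }
  has_edge <- m$id %in% c(family$edges$from, family$edges$to)
  topo[is.na(topo) & has_edge] <- "cyclic"
  topo[is.na(topo)] <- "unknown"
  family$members$topology <- unname(topo[m$id])
  family
}

#' Propagate fatty-acid tail carbon counts from an anchored member
#'
#' Starting from one member of known tail length (the anchor), carbon
#' counts propagate along CH2 edges (+1 toward the heavier member, -1
#' toward the lighter) and across water edges unchanged (hydration does not
#' alter the carbon count). Also computes each member's nominal integer mass
#' offset from the lightest cyclic member.
#'
#' @param family An `isoform_family`, topology already classified.
#' @param anchor List with `id` (a member peak id) and `carbons`
#'   (its known tail carbon count).
#' @return The family with `tail_carbons` and `nominal_offset` filled in and
#'   `anchor` recorded.
#' @export
infer_tail_lengths <- function(family, anchor) {
  stopifnot(inherits(family, "isoform_family"))
  if (!is.list(anchor) || is.null(anchor$id) || is.null(anchor$carbons))
    stop("anchor must be a list with elements 'id' and 'carbons'", call. = FALSE)
  m <- family$members
  if (!(anchor$id %in% m$id))
    stop("anchor peak '", anchor$id, "' is not a member of this family", call. = FALSE)

  carb <- stats::setNames(rep(NA_integer_, nrow(m)), m$id)
  carb[anchor$id] <- as.integer(anchor$carbons)
  e <- family$edges
  queue <- anchor$id
  while (length(queue)) {
    cur <- queue[1]; queue <- queue[-1]
    touching <- which(e$from == cur | e$to == cur)
    for (k in touching) {
      other <- if (e$from[k] == cur) e$to[k] else e$from[k]
      step <- if (e$kind[k] == "WATER") 0L else 1L
      # +1 carbon toward the heavier member of a CH2 edge
      val <- carb[[cur]] + if (e$to[k] == other) step else -step
      if (is.na(carb[[other]])) {
        carb[other] <- val
        queue <- c(queue, other)
      } else if (carb[[other]] != val) {
        stop(sprintf(
          "inconsistent tail-carbon propagation: peak %s reached with %d and %d carbons (edge %s-%s)",
          other, carb[[other]], val, e$from[k], e$to[k]), call. = FALSE)
      }
    }
  }
  family$members$tail_carbons <- unname(carb[m$id])

  cyc_mz <- m$mz[m$topology %in% "cyclic"]
  if (length(cyc_mz)) {
    base <- min(cyc_mz)
  } else {
    base <- min(m$mz)
    family$warnings <- c(family$warnings,
      "no cyclic member; nominal offsets are relative to the lightest member")
  }
  family$members$nominal_offset <- as.integer(round(family$members$mz - base))
  family$anchor <- list(id = anchor$id, carbons = as.integer(anchor$carbons))
  family
}

.letter_designation <- function(i) {
  # A, B, ..., Z, AA, AB, ... (spreadsheet-style)
  out <- ""
  while (i > 0) {
    r <- (i - 1) %% 26
    out <- paste0(LETTERS[r + 1], out)
    i <- (i - 1) %/% 26
  }
  out
}

#' Assign alphabetical isoform designations
#'
#' Cyclic members (plus members of unknown topology) receive letters A, B,
#' C, ... in order of increasing protonated mass. Each linear member takes
#' the letter of its cyclic water partner with an `_L` subscript; a linear
#' member without a water partner gets the letter its tail carbon count
#' would imply (with a warning).
#'
#' @param family An `isoform_family`, topology already classified.
#' @return The family with the `designation` column filled in.
#' @export
assign_designations <- function(family) {
  stopifnot(inherits(family, "isoform_family"))
  m <- family$members
  if (all(is.na(m$topology)))
    stop("classify topology before assigning designations", call. = FALSE)
  desig <- stats::setNames(rep(NA_character_, nrow(m)), m$id)

  pool <- which(m$topology %in% c("cyclic", "unknown"))
  pool <- pool[order(m$mz[pool])]
  for (i in seq_along(pool)) desig[m$id[pool[i]]] <- .letter_designation(i)

  cyc <- m[m$topology %in% "cyclic", , drop = FALSE]
  lin <- which(m$topology %in% "linear")
  lin <- lin[order(m$mz[lin])]
  we <- family$edges[family$edges$kind == "WATER", , drop = FALSE]
  for (i in lin) {
    id <- m$id[i]
    partner <- we$from[we$to == id]
    partner <- partner[partner %in% cyc$id]
    if (length(partner) == 1) {
      desig[id] <- paste0(desig[[partner]], "_L")
    } else {
      # no cyclic water partner: use the letter the tail count (or the
      # dehydrated mass position) would imply among the cyclic members
      if (!is.na(m$tail_carbons[i]) && !all(is.na(cyc$tail_carbons))) {
        j <- which(cyc$tail_carbons == m$tail_carbons[i])
        if (length(j)) {
          desig[id] <- paste0(desig[[cyc$id[j[1]]]], "_L")
        } else {
          idx <- 1L + sum(cyc$tail_carbons < m$tail_carbons[i], na.rm = TRUE)
          desig[id] <- paste0(.letter_designation(idx), "_L")
        }
      } else {
        idx <- 1L + sum(cyc$mz < (m$mz[i] - WATER_DA + 1))
        desig[id] <- paste0(.letter_designation(idx), "_L")
      }
      family$warnings <- c(family$warnings, sprintf(
        "linear member %s has no cyclic water partner; designation %s inferred",
        id, desig[[id]]))
    }
  }
  # enforce uniqueness in pathological inputs
  dup <- duplicated(desig)
  if (any(dup))
    desig[dup] <- paste0(desig[dup], ".", cumsum(dup)[dup] + 1L)
  family$members$designation <- unname(desig[m$id])
  family
}

#' Annotate a peak list end to end
#'
#' Runs the full MS1 pipeline: ladder detection, topology classification,
#' tail-length propagation from an anchor (if one is supplied and resolves
#' to a peak) and designation assignment.
#'
#' @param peaks A [peak_list()] or data frame coercible to one.
#' @param anchor Optional list with `carbons` and either `id` (peak id) or
#'   `mz` (resolved to the nearest peak within `ch2_tol`).
#' @inheritParams detect_ladders
#' @return List of annotated `isoform_family` objects.
#' @examples
#' peaks <- read_peaklist(system.file("extdata", "table1_peaks.csv",
#'                                    package = "lipoladder"))
#' fams <- annotate_peaks(peaks, anchor = list(mz = 1008.6832, carbons = 13))
#' fams[[1]]
#' @export
annotate_peaks <- function(peaks, anchor = NULL, ch2_tol = 0.03, water_tol = 0.03) {
  peaks <- peak_list(peaks)
  fams <- detect_ladders(peaks, ch2_tol, water_tol)
  anchor_id <- NULL
  if (!is.null(anchor)) {
    if (is.null(anchor$carbons))
      stop("anchor must include 'carbons'", call. = FALSE)
    if (!is.null(anchor$id)) {
      anchor_id <- as.character(anchor$id)
    } else if (!is.null(anchor$mz)) {
      d <- abs(peaks$mz - anchor$mz)
      if (min(d) > ch2_tol)
        stop(sprintf("no peak within %.3f Da of anchor m/z %.4f", ch2_tol,
                     anchor$mz), call. = FALSE)
      anchor_id <- peaks$id[which.min(d)]
    } else stop("anchor must include 'id' or 'mz'", call. = FALSE)
  }
  fams <- lapply(fams, function(f) {
    f <- classify_topology_ms1(f)
    if (!is.null(anchor_id) && anchor_id %in% f$members$id)
      f <- infer_tail_lengths(f, list(id = anchor_id, carbons = anchor$carbons))
    assign_designations(f)
  })
  class(fams) <- "isoform_family_list"
  fams
}

#' Tabular report of an annotated family
#'
#' One row per member with the designation, retention time, protonated
#' mass, topology call, tail carbon count and nominal mass offset from the
#' lightest cyclic member.
#'
#' @param family An `isoform_family`.
#' @return Data frame sorted by m/z.
#' @export
family_report <- function(family) {
  stopifnot(inherits(family, "isoform_family"))
  m <- family$members
  out <- data.frame(designation = m$designation, rt_min = m$rt_min, mz = m$mz,
                    type = m$topology, tail_carbons = m$tail_carbons,
                    nominal_offset = m$nominal_offset, stringsAsFactors = FALSE)
  out[order(out$mz), , drop = FALSE]
}

#' @export
print.isoform_family <- function(x, ...) {
  cat(sprintf("<isoform_family> %d member(s), %d edge(s)\n",
              nrow(x$members), nrow(x$edges)))
  print(family_report(x), row.names = FALSE)
  if (length(x$warnings))
    cat("warnings:\n", paste0("  - ", x$warnings, collapse = "\n"), "\n", sep = "")
  invisible(x)
}

#' @export
print.isoform_family_list <- function(x, ...) {
  cat(sprintf("List of %d isoform family/families\n", length(x)))
  for (i in seq_along(x)) {
    cat(sprintf("-- family %d --\n", i))
    print(x[[i]])
  }
  invisible(x)
}
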