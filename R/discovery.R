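# Resolve conflicting hits within a protein, keeping the lower
# i-E-value hit of any pair overlapping by more than max_overlap
# residues. A small tolerance (default 15, under half a repeat) lets
# fixed-length profile windows over tandem repeats of shorter length
# coexist while still collapsing rescored duplicates.
resolve_overlaps <- function(hits, max_overlap = 15L) {
  if (nrow(hits) < 2L) return(hits)
  out <- list()
  for (pid in unique(hits$protein_id)) {
    h <- hits[hits$protein_id == pid, , drop = FALSE]
    h <- h[order(h$i_evalue, h$env_start), , drop = FALSE]
    kept <- h[0, ]
    for (i in seq_len(nrow(h))) {
      ov <- if (nrow(kept) == 0L) integer(0) else
        pmax(0L, pmin(h$env_end[i], kept$env_end) -
                 pmax(h$env_start[i], kept$env_start) + 1L)
      if (all(ov <= max_overlap)) kept <- rbind(kept, h[i, ])
    }
    out[[pid]] <- kept[order(kept$env_start), , drop = FALSE]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Iterative PPR-motif discovery
#'
#' Runs the two-iteration motif discovery procedure on a proteome:
#'
#' 1. **Iteration 1** — generic (plant-style) profile hits are
#'    filtered at an i-E-value threshold, either calibrated against
#'    the curated motif reference ([select_threshold()]) or supplied
#'    directly (the study's applied value was 8.6).
#' 2. **Gap rescue** — 30–40-residue gaps between assigned motifs are
#'    extended by 10 residues on both sides and searched for
#'    structure-valid motif windows ([validate_structure()]); requires
#'    secondary-structure tracks and is skipped (with a flag) without
#'    them.
#' 3. **Profile rebuild** — iteration-1 motifs with in-range lengths
#'    plus rescued motifs are combined into a lineage-specific profile
#'    ([build_profile()]).
#' 4. **Iteration 2** — the proteome is searched with the new profile:
#'    externally supplied domain hits (`hits2`) when available,
#'    otherwise the internal scanner ([scan_with_profile()]); hits are
#'    filtered at the second threshold (calibrated, or the study's
#'    applied 11).
#'
#' A protein is called PPR-containing when it retains at least one
#' final motif (iteration-2 hit or rescued motif). Every motif carries
#' its provenance (`source`, `iteration`).
#'
#' @param proteins Protein table from [read_fasta()].
#' @param hits1 Iteration-1 domain hits (e.g. from
#'   [read_domtblout()]).
#' @param reference Optional motif reference (list with `positive`,
#'   `negative` span tables) for threshold calibration.
#' @param tracks Optional structure tracks from
#'   [read_structure_table()].
#' @param thresholds Optional numeric vector `c(t1, t2)`; when given,
#'   calibration is skipped and these thresholds are honored. Both
#'   are applied as strict `i_evalue < t`.
#' @param hits2 Optional externally produced iteration-2 domain hits;
#'   when `NULL` the internal profile scanner is used.
#' @param min_gap,max_gap,flank Gap-rescue geometry (defaults 30, 40,
#'   10).
#' @param null_decoys,seed,score_floor Passed to
#'   [scan_with_profile()] when the internal scanner runs. The
#'   default here (50 decoys, e-value resolution 0.02) is coarser
#'   than the standalone scanner's: the pipeline only needs e-values
#'   at threshold-decision resolution, where the true and decoy score
#'   populations differ by orders of magnitude.
#' @return An object of class `ppr_discovery`: `motifs` (final motif
#'   table with provenance and structure validation), `proteins_called`
#'   (ids with >= 1 final motif), `thresholds` (applied t1/t2),
#'   `calibration1`, `calibration2` (when run), `profile`,
#'   `gap_rescue_skipped`, `iteration1_motifs`.
#' @export
iterate_discovery <- function(proteins, hits1, reference = NULL,
                              tracks = NULL, thresholds = NULL,
                              hits2 = NULL, min_gap = 30L,
                              max_gap = 40L, flank = 10L,
                              null_decoys = 50L, seed = 42L,
                              score_floor = 0) {
  if (is.null(reference) && is.null(thresholds))
    stop("supply either a motif reference for calibration or ",
         "explicit thresholds c(t1, t2)")
  calibration1 <- calibration2 <- NULL

  # -- iteration 1 threshold
  if (!is.null(thresholds)) {
    stopifnot(length(thresholds) == 2L, all(thresholds > 0))
    t1 <- thresholds[1L]
  } else {
    labeled1 <- match_hits_to_reference(hits1, reference)
    calibration1 <- select_threshold(labeled1, reference)
    t1 <- calibration1$selected_threshold
  }
  iter1 <- hits1[hits1$i_evalue < t1, , drop = FALSE]
  iter1 <- resolve_overlaps(iter1)

  # -- gap rescue
  track_of <- if (!is.null(tracks))
    stats::setNames(tracks$labels, tracks$protein_id) else NULL
  gap_rescue_skipped <- is.null(track_of)
  rescued <- data.frame(protein_id = character(), start = integer(),
                        end = integer(), stringsAsFactors = FALSE)
  if (!gap_rescue_skipped && nrow(iter1) > 0L) {
    plen <- stats::setNames(proteins$length, proteins$id)
    strict <- resolve_overlaps(iter1, max_overlap = 0L)
    spans <- data.frame(protein_id = strict$protein_id,
                        start = strict$env_start,
                        end = strict$env_end,
                        stringsAsFactors = FALSE)
    regions <- find_gap_candidates(spans, plen, min_gap = min_gap,
                                   max_gap = max_gap, flank = flank)
    if (nrow(regions) > 0L) {
      found <- list()
      for (i in seq_len(nrow(regions))) {
        tr <- track_of[[regions$protein_id[i]]]
        if (is.null(tr)) next
        w <- best_valid_window(tr, regions$start[i], regions$end[i])
        if (!is.null(w))
          found[[length(found) + 1L]] <- data.frame(
            protein_id = regions$protein_id[i],
            start = w$start, end = w$start + w$length - 1L,
            stringsAsFactors = FALSE)
      }
      if (length(found) > 0L) {
        rescued <- unique(do.call(rbind, found))
        rownames(rescued) <- NULL
      }
    }
  }

  # -- profile rebuild from iteration-1 + rescued motif sequences
  seq_of <- stats::setNames(proteins$sequence, proteins$id)
  motif_seq <- function(pid, s, e) substr(seq_of[[pid]], s, e)
  iter1_len <- iter1$env_end - iter1$env_start + 1L
  in_range <- iter1_len >= 31L & iter1_len <= 40L
  pool <- c(
    if (nrow(iter1) > 0L)
      mapply(motif_seq, iter1$protein_id[in_range],
             iter1$env_start[in_range], iter1$env_end[in_range]),
    if (nrow(rescued) > 0L)
      mapply(motif_seq, rescued$protein_id, rescued$start,
             rescued$end))
  pool <- unname(pool[!is.na(pool) & nzchar(pool)])
  profile <- if (length(pool) >= 2L) build_profile(pool) else NULL

  # -- iteration 2
  if (is.null(hits2)) {
    if (is.null(profile))
      stop("fewer than two motifs survive iteration 1; cannot build ",
           "the second-iteration profile (supply hits2 instead)")
    hits2 <- scan_with_profile(profile, proteins,
                               null_decoys = null_decoys, seed = seed,
                               score_floor = score_floor)
  }
  if (!is.null(thresholds)) {
    t2 <- thresholds[2L]
  } else {
    labeled2 <- match_hits_to_reference(hits2, reference)
    calibration2 <- select_threshold(labeled2, reference)
    t2 <- calibration2$selected_threshold
  }
  iter2 <- hits2[hits2$i_evalue < t2, , drop = FALSE]
  iter2 <- resolve_overlaps(iter2)

  # -- assemble final motif set with provenance
  mk <- function(pid, s, e, src, it, iev) {
    data.frame(protein_id = pid, start = s, end = e,
               length = e - s + 1L, source = src, iteration = it,
               i_evalue = iev, stringsAsFactors = FALSE)
  }
  # rescued motifs re-found by the second search are credited to it
  n_rescued_validated <- nrow(rescued)
  if (nrow(rescued) > 0L && nrow(iter2) > 0L) {
    dup <- vapply(seq_len(nrow(rescued)), function(i) {
      cand <- iter2[iter2$protein_id == rescued$protein_id[i], ,
                    drop = FALSE]
      if (nrow(cand) == 0L) return(FALSE)
      any(overlap_frac_shorter(cand$env_start, cand$env_end,
                               rescued$start[i],
                               rescued$end[i]) >= 0.5)
    }, logical(1))
    rescued <- rescued[!dup, , drop = FALSE]
  }
  final <- rbind(
    if (nrow(iter2) > 0L)
      mk(iter2$protein_id, iter2$env_start, iter2$env_end,
         "hmm_hit", 2L, iter2$i_evalue),
    if (nrow(rescued) > 0L)
      mk(rescued$protein_id, rescued$start, rescued$end,
         "gap_rescue", 1L, NA_real_))
  if (is.null(final))
    final <- mk(character(0), integer(0), integer(0), character(0),
                integer(0), numeric(0))
  # structure validation verdict on every final motif where a track
  # exists and the length is in the canonical range
  final$structure_valid <- NA
  if (!is.null(track_of) && nrow(final) > 0L) {
    for (i in seq_len(nrow(final))) {
      tr <- track_of[[final$protein_id[i]]]
      if (is.null(tr) || final$length[i] < 31L ||
          final$length[i] > 40L ||
          final$end[i] > nchar(tr)) next
      final$structure_valid[i] <-
        validate_structure(tr, final$start[i],
                           final$length[i])$structure_valid
    }
  }
  final <- final[order(final$protein_id, final$start), , drop = FALSE]
  rownames(final) <- NULL

  structure(list(motifs = final,
                 proteins_called = sort(unique(final$protein_id)),
                 thresholds = c(t1 = t1, t2 = t2),
                 calibration1 = calibration1,
                 calibration2 = calibration2,
                 profile = profile,
                 gap_rescue_skipped = gap_rescue_skipped,
                 n_rescued = n_rescued_validated,
                 iteration1_motifs = iter1),
            class = "ppr_discovery")
}

#' @export
print.ppr_discovery <- function(x, ...) {
  cat("PPR-motif discovery\n")
  cat("  thresholds: t1 =", format(x$thresholds[["t1"]]),
      ", t2 =", format(x$thresholds[["t2"]]), "\n")
  cat("  iteration-1 motifs:", nrow(x$iteration1_motifs), "\n")
  cat("  gap-rescued motifs:", x$n_rescued,
      if (x$gap_rescue_skipped) "(rescue skipped: no tracks)" else "",
      "\n")
  cat("  final motifs:", nrow(x$motifs), "on",
      length(x$proteins_called), "protein(s)\n")
  invisible(x)
}

#' @export
summary.ppr_discovery <- function(object, ...) {
  m <- object$motifs
  data.frame(
    n_motifs = nrow(m),
    n_proteins = length(object$proteins_called),
    n_gap_rescued = sum(m$source == "gap_rescue"),
    n_structure_valid = sum(m$structure_valid %in% TRUE),
    t1 = object$thresholds[["t1"]],
    t2 = object$thresholds[["t2"]])
}
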