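# Overlap fraction of two 1-based inclusive intervals, relative to the
# shorter of the two. Vectorized over the first interval set.
overlap_frac_shorter <- function(s1, e1, s2, e2) {
  ov <- pmin(e1, e2) - pmax(s1, s2) + 1L
  ov <- pmax(ov, 0L)
  shorter <- pmin(e1 - s1 + 1L, e2 - s2 + 1L)
  ov / shorter
}

#' Label domain hits against a curated motif reference
#'
#' Matches each hit to the positive and negative motif reference by
#' interval overlap: a hit is a TP candidate when it overlaps a
#' positive reference span by at least `min_overlap` of the shorter of
#' the two intervals, an FP candidate when it similarly overlaps a
#' negative span, and unlabeled otherwise (ignored in precision/recall
#' accounting). When a hit overlaps both lists, the better-overlapped
#' span wins, ties going to the positive list.
#'
#' @param hits Domain hits (`protein_id`, `env_start`, `env_end`,
#'   `i_evalue`, ...).
#' @param reference A list with elements `positive` and `negative`,
#'   each a span table from [read_motif_spans()].
#' @param min_overlap Minimum overlap fraction of the shorter interval.
#' @return `hits` with added columns `label` (`"TP"`, `"FP"` or `NA`)
#'   and `ref_index` (row of the matched reference span within its
#'   list).
#' @export
match_hits_to_reference <- function(hits, reference,
                                    min_overlap = 0.5) {
  stopifnot(is.list(reference),
            all(c("positive", "negative") %in% names(reference)))
  best_against <- function(hit_row, spans) {
    cand <- which(spans$protein_id == hits$protein_id[hit_row])
    if (length(cand) == 0L) return(c(0, NA_integer_))
    fr <- overlap_frac_shorter(spans$start[cand], spans$end[cand],
                               hits$env_start[hit_row],
                               hits$env_end[hit_row])
    j <- which.max(fr)
    c(fr[j], cand[j])
  }
  n <- nrow(hits)
  label <- rep(NA_character_, n)
  ref_index <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    bp <- best_against(i, reference$positive)
    bn <- best_against(i, reference$negative)
    if (bp[1L] >= min_overlap && bp[1L] >= bn[1L]) {
      label[i] <- "TP"; ref_index[i] <- bp[2L]
    } else if (bn[1L] >= min_overlap) {
      label[i] <- "FP"; ref_index[i] <- bn[2L]
    }
  }
  hits$label <- label
  hits$ref_index <- ref_index
  hits
}

#' Precision, recall and F1 from confusion counts
#'
#' `P = TP/(TP + FP)`, `R = TP/(TP + FN)`,
#' `F1 = TP/(TP + 0.5 (FP + FN))`. A zero denominator yields `NA`
#' (undefined), never 0.
#'
#' @param tp,fp,fn Non-negative counts (vectorized).
#' @return A `data.frame` with columns `precision`, `recall`, `f1`.
#' @export
precision_recall_f1 <- function(tp, fp, fn) {
  if (any(c(tp, fp, fn) < 0)) stop("counts must be non-negative")
  p <- ifelse(tp + fp > 0, tp / (tp + fp), NA_real_)
  r <- ifelse(tp + fn > 0, tp / (tp + fn), NA_real_)
  f1 <- ifelse(tp + 0.5 * (fp + fn) > 0,
               tp / (tp + 0.5 * (fp + fn)), NA_real_)
  data.frame(precision = p, recall = r, f1 = f1)
}

confusion_at_threshold <- function(labeled, n_pos, n_neg, t) {
  retained <- labeled$i_evalue < t
  tp <- length(unique(labeled$ref_index[retained &
                                        labeled$label %in% "TP"]))
  fp <- length(unique(labeled$ref_index[retained &
                                        labeled$label %in% "FP"]))
  c(TP = tp, FP = fp, FN = n_pos - tp, TN = n_neg - fp)
}

#' F1-calibrated selection of the motif E-value threshold
#'
#' Sweeps candidate i-E-value thresholds over labeled hits (retaining
#' hits with `i_evalue < t`), counting at each threshold how many
#' distinct positive reference motifs are retrieved (TP), how many
#' distinct negative reference motifs are retrieved (FP), and the
#' resulting precision, recall and F1. The selected threshold is the
#' largest one retrieving all positive reference motifs and none of the
#' negative ones; when no threshold achieves that perfect separation,
#' the F1-maximizing threshold is chosen, ties broken toward the larger
#' threshold. The full threshold-vs-F1 table is retained for plotting.
#'
#' @param labeled Hits labeled by [match_hits_to_reference()].
#' @param reference The reference list used for labeling (sizes give
#'   the FN/TN complements).
#' @param thresholds Optional candidate thresholds; defaults to the
#'   geometric midpoints between consecutive distinct observed
#'   i-E-values, plus one candidate below the minimum and one above
#'   the maximum, so the selected threshold falls strictly between
#'   score populations rather than on an observed value.
#' @return An object of class `ppr_calibration`: `table` (per-threshold
#'   counts and scores), `selected_threshold`, `perfect_separation`,
#'   `n_pos`, `n_neg`.
#' @export
select_threshold <- function(labeled, reference, thresholds = NULL) {
  n_pos <- nrow(reference$positive)
  n_neg <- nrow(reference$negative)
  if (n_pos == 0L || n_neg == 0L)
    stop("both reference lists must be non-empty for calibration")
  if (is.null(thresholds)) {
    ev <- sort(unique(labeled$i_evalue))
    if (length(ev) == 0L) stop("no hits to calibrate on")
    mids <- if (length(ev) > 1L) sqrt(ev[-length(ev)] * ev[-1L])
            else numeric(0)
    thresholds <- sort(unique(c(min(ev) / 2, mids, max(ev) * 2)))
  }
  stopifnot(all(thresholds > 0), all(is.finite(thresholds)))
  thresholds <- sort(unique(thresholds))
  cc <- t(vapply(thresholds, function(t)
    confusion_at_threshold(labeled, n_pos, n_neg, t),
    numeric(4)))
  prf <- precision_recall_f1(cc[, "TP"], cc[, "FP"], cc[, "FN"])
  tab <- data.frame(threshold = thresholds, cc, prf)
  perfect <- tab$FP == 0L & tab$FN == 0L
  if (any(perfect)) {
    sel <- max(tab$threshold[perfect])
    perfect_sep <- TRUE
  } else {
    f1 <- ifelse(is.na(tab$f1), -Inf, tab$f1)
    best <- which(f1 == max(f1))
    sel <- max(tab$threshold[best])
    perfect_sep <- FALSE
  }
  structure(list(table = tab, selected_threshold = sel,
                 perfect_separation = perfect_sep,
                 n_pos = n_pos, n_neg = n_neg),
            class = "ppr_calibration")
}

#' @export
print.ppr_calibration <- function(x, ...) {
  cat("Motif i-E-value threshold calibration\n")
  cat("  reference: ", x$n_pos, " positive / ", x$n_neg,
      " negative motifs\n", sep = "")
  cat("  thresholds evaluated: ", nrow(x$table), "\n", sep = "")
  cat("  selected threshold: ", format(x$selected_threshold),
      if (x$perfect_separation) "  (perfect separation)"
      else "  (max F1 fallback)", "\n", sep = "")
  i <- match(x$selected_threshold, x$table$threshold)
  cat(sprintf("  at selection: TP=%d FP=%d FN=%d  P=%.3f R=%.3f F1=%.3f\n",
              x$table$TP[i], x$table$FP[i], x$table$FN[i],
              x$table$precision[i], x$table$recall[i], x$table$f1[i]))
  invisible(x)
}

#' @export
plot.ppr_calibration <- function(x, ...) {
  tab <- x$table
  plot(log10(tab$threshold), tab$f1, type = "b", pch = 16,
       xlab = "log10 i-E-value threshold", ylab = "F1",
       ylim = c(0, 1), ...)
  abline(v = log10(x$selected_threshold), lty = 2)
  invisible(x)
}

#' Find inter-motif gaps that may hide missed motifs
#'
#' Screens each protein's assigned motifs for 30–40-residue gaps
#' between adjacent motifs — the length range of one repeat unit — and
#' emits each such gap extended by `flank` residues up- and downstream
#' (clipped to the protein), the candidate region for structure-based
#' motif rescue. Gaps require an assigned motif on both sides.
#'
#' @param motifs `data.frame` with columns `protein_id`, `start`,
#'   `end` (1-based inclusive), non-overlapping within each protein.
#' @param protein_lengths Named integer vector of protein lengths.
#' @param min_gap,max_gap Inclusive bounds on the inter-motif residue
#'   count (defaults 30 and 40).
#' @param flank Extension on both sides (default 10).
#' @return A `data.frame` of candidate regions: `protein_id`, `start`,
#'   `end`, `gap_start`, `gap_end`, `gap_length`.
#' @examples
#' m <- data.frame(protein_id = "p", start = c(66, 136),
#'                 end = c(100, 170))
#' find_gap_candidates(m, c(p = 200))  # region 91..145 around gap 101..135
#' @export
find_gap_candidates <- function(motifs, protein_lengths,
                                min_gap = 30L, max_gap = 40L,
                                flank = 10L) {
  empty <- data.frame(protein_id = character(), start = integer(),
                      end = integer(), gap_start = integer(),
                      gap_end = integer(), gap_length = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(motifs) == 0L) return(empty)
  out <- list()
  for (pid in unique(motifs$protein_id)) {
    m <- motifs[motifs$protein_id == pid, , drop = FALSE]
    m <- m[order(m$start), , drop = FALSE]
    if (nrow(m) > 1L &&
        any(m$start[-1L] <= m$end[-nrow(m)]))
      stop("overlapping input motifs in protein '", pid, "'")
    if (nrow(m) < 2L) next
    plen <- protein_lengths[[pid]]
    if (is.null(plen) || is.na(plen))
      stop("no length for protein '", pid, "'")
    gap_len <- m$start[-1L] - m$end[-nrow(m)] - 1L
    sel <- which(gap_len >= min_gap & gap_len <= max_gap)
    if (length(sel) == 0L) next
    gs <- m$end[sel] + 1L
    ge <- m$start[sel + 1L] - 1L
    out[[pid]] <- data.frame(
      protein_id = pid,
      start = pmax(1L, gs - flank),
      end = pmin(as.integer(plen), ge + flank),
      gap_start = gs, gap_end = ge, gap_length = gap_len[sel],
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Validate a candidate motif span against secondary structure
#'
#' Applies the helix-turn-helix criteria that define a PPR repeat
#' unit: helix A (motif positions 1–10) and helix B (positions 14 to
#' the motif end) must each contain at least seven helix-forming
#' residues (8-state labels `H`, `G`, `I`; non-helical residues are
#' permitted within the helices), and positions 11–13 must all carry
#' the turn label `T`.
#'
#' @param track Per-residue 8-state label string for the protein.
#' @param start 1-based start of the candidate motif within the
#'   protein.
#' @param motif_length Motif length, between 31 and 40.
#' @return A list: `structure_valid`, `helixA_count`, `helixB_count`,
#'   `turn_ok`.
#' @export
validate_structure <- function(track, start, motif_length) {
  stopifnot(is.character(track), length(track) == 1L,
            motif_length >= 31L, motif_length <= 40L)
  end <- start + motif_length - 1L
  if (start < 1L || end > nchar(track))
    stop("candidate span ", start, "..", end,
         " exceeds the structure track (length ", nchar(track), ")")
  lab <- strsplit(substr(track, start, end), "")[[1L]]
  helix <- c("H", "G", "I")
  helixA <- sum(lab[1:10] %in% helix)
  helixB <- sum(lab[14:motif_length] %in% helix)
  turn_ok <- all(lab[11:13] == "T")
  list(structure_valid = helixA >= 7L && helixB >= 7L && turn_ok,
       helixA_count = helixA, helixB_count = helixB,
       turn_ok = turn_ok)
}

# Best structure-valid window of length 31..40 inside a candidate
# region: among valid windows, maximize helixA+helixB helix-forming
# residues; ties to earliest start, then shorter length.
best_valid_window <- function(track, region_start, region_end,
                              lengths = 31:40) {
  best <- NULL
  best_key <- c(-Inf, Inf, Inf)
  for (len in lengths) {
    if (region_end - region_start + 1L < len) next
    for (s in region_start:(region_end - len + 1L)) {
      v <- validate_structure(track, s, len)
      if (!v$structure_valid) next
      key <- c(v$helixA_count + v$helixB_count, s, len)
      if (key[1L] > best_key[1L] ||
          (key[1L] == best_key[1L] &&
           (key[2L] < best_key[2L] ||
            (key[2L] == best_key[2L] && key[3L] < best_key[3L])))) {
        best_key <- key
        best <- list(start = s, length = len, validation = v)
      }
    }
  }
  best
}
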