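#' Scan a protein for twin-Cx9C motifs
#'
#' Finds C-x9-C motifs (and C-x10-C when `allow_cx10c`) by a greedy
#' left-to-right scan, then keeps only motifs chained to at least one
#' neighbouring motif with an inter-motif spacer inside
#' `[min_spacer, max_spacer]` — the twin arrangement characteristic of
#' CHCH-fold intermembrane-space proteins. The spacer is the number of
#' residues strictly between the closing cysteine of one motif and the
#' opening cysteine of the next. By default a motif's interior may not
#' contain a cysteine.
#'
#' @param sequence Amino-acid string.
#' @param protein_id Optional id attached to the result.
#' @param allow_cx10c Also accept C-x10-C motifs (Cox12-style variant).
#' @param min_spacer,max_spacer Chaining bounds on the inter-motif
#'   spacer (defaults 3 and 50, bracketing observed spacers of 5–38).
#' @param allow_internal_c Permit cysteines inside the x9/x10 interior.
#' @return A list of class `twin_cx_call`: `protein_id`, `motifs`
#'   (`data.frame` with `start`, `inner_length`, `motif_string`;
#'   1-based `start` of the opening cysteine) and `spacers` (integer
#'   vector of length `nrow(motifs) - 1`).
#' @examples
#' s <- paste0("MA", "CHMFKRSFNLC", "AGEWLDKPNQSTV", "CAIEKEDWYNC", "TT")
#' scan_cx9c(s)$spacers  # 13
#' @export
scan_cx9c <- function(sequence, protein_id = NA_character_,
                      allow_cx10c = FALSE, min_spacer = 3L,
                      max_spacer = 50L, allow_internal_c = FALSE) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  chars <- strsplit(sequence, "")[[1L]]
  n <- length(chars)
  inner_opts <- if (allow_cx10c) c(9L, 10L) else 9L
  starts <- integer(0); inners <- integer(0)
  i <- 1L
  while (i <= n) {
    matched <- FALSE
    if (chars[i] == "C") {
      for (k in inner_opts) {
        close_pos <- i + k + 1L
        if (close_pos <= n && chars[close_pos] == "C" &&
            (allow_internal_c ||
             !any(chars[(i + 1L):(close_pos - 1L)] == "C"))) {
          starts <- c(starts, i); inners <- c(inners, k)
          i <- close_pos + 1L  # greedy: resume after the closing C
          matched <- TRUE
          break
        }
      }
    }
    if (!matched) i <- i + 1L
  }
  empty <- list(protein_id = protein_id,
                motifs = data.frame(start = integer(0),
                                    inner_length = integer(0),
                                    motif_string = character(0),
                                    stringsAsFactors = FALSE),
                spacers = integer(0))
  class(empty) <- "twin_cx_call"
  if (length(starts) < 2L) return(empty)
  ends <- starts + inners + 1L
  spacer_next <- starts[-1L] - ends[-length(ends)] - 1L
  in_range <- spacer_next >= min_spacer & spacer_next <= max_spacer
  keep <- logical(length(starts))
  keep[-length(keep)] <- keep[-length(keep)] | in_range
  keep[-1L] <- keep[-1L] | in_range
  if (sum(keep) < 2L) return(empty)
  starts <- starts[keep]; inners <- inners[keep]
  ends <- starts + inners + 1L
  motifs <- data.frame(
    start = starts,
    inner_length = inners,
    motif_string = vapply(seq_along(starts), function(j)
      substr(sequence, starts[j], ends[j]), character(1)),
    stringsAsFactors = FALSE)
  out <- list(protein_id = protein_id, motifs = motifs,
              spacers = starts[-1L] - ends[-length(ends)] - 1L)
  class(out) <- "twin_cx_call"
  out
}

#' @export
print.twin_cx_call <- function(x, ...) {
  n <- nrow(x$motifs)
  cat("Twin-Cx9C call", if (!is.na(x$protein_id))
    paste0(" for ", x$protein_id), ": ", n, " motif(s)\n", sep = "")
  if (n > 0L) {
    parts <- x$motifs$motif_string
    if (n > 1L)
      parts <- paste(parts,
                     c(sprintf("- [%d] -", x$spacers), ""),
                     collapse = " ")
    else parts <- paste(parts, collapse = " ")
    cat(" ", trimws(parts), "\n")
  }
  invisible(x)
}

#' Alanine/lysine composition screen
#'
#' Flags proteins in which alanine plus lysine make up strictly more
#' than `threshold_pct` percent of all residues — the signature of the
#' AK-rich, HMG-box-bearing protein family implicated in mitochondrial
#' DNA metabolism. The C-terminal window (default 80 residues, the
#' approximate length of the family's shared C-terminal motif) is
#' reported for downstream profile matching.
#'
#' @param sequence Amino-acid string.
#' @param protein_id Optional id attached to the result.
#' @param threshold_pct Strict percentage cutoff (default 60).
#' @param tail_window Length of the reported C-terminal window.
#' @return A list: `protein_id`, `flagged`, `pct_ak`, `n_ala`, `n_lys`,
#'   `tail` (the C-terminal subsequence).
#' @export
ak_composition_screen <- function(sequence, protein_id = NA_character_,
                                  threshold_pct = 60,
                                  tail_window = 80L) {
  stopifnot(is.character(sequence), length(sequence) == 1L,
            nchar(sequence) > 0L)
  chars <- strsplit(sequence, "")[[1L]]
  n_ala <- sum(chars == "A")
  n_lys <- sum(chars == "K")
  pct <- 100 * (n_ala + n_lys) / length(chars)
  tail_start <- max(1L, length(chars) - tail_window + 1L)
  list(protein_id = protein_id,
       flagged = pct > threshold_pct,
       pct_ak = pct, n_ala = n_ala, n_lys = n_lys,
       tail = substr(sequence, tail_start, length(chars)))
}

#' Filter domain hits by independent E-value and tabulate
#'
#' Retains hits with `i_evalue <= max_evalue` (the generic Pfam-style
#' domain screen, default cutoff 0.05) and tabulates per-protein domain
#' counts per profile, plus the per-profile census of proteins carrying
#' at least one retained domain.
#'
#' @param hits Domain-hit `data.frame` from [read_domtblout()].
#' @param max_evalue Positive E-value cutoff.
#' @return A list: `hits` (retained rows), `motif_counts`
#'   (`protein_id`, `profile_name`, `n_domains`), `protein_counts`
#'   (`profile_name`, `n_proteins`).
#' @export
filter_domain_hits <- function(hits, max_evalue = 0.05) {
  if (!is.numeric(max_evalue) || max_evalue <= 0)
    stop("max_evalue must be positive")
  keep <- hits[hits$i_evalue <= max_evalue, , drop = FALSE]
  rownames(keep) <- NULL
  if (nrow(keep) == 0L) {
    return(list(hits = keep,
                motif_counts = data.frame(protein_id = character(),
                                          profile_name = character(),
                                          n_domains = integer()),
                protein_counts = data.frame(profile_name = character(),
                                            n_proteins = integer())))
  }
  mc <- as.data.frame(table(protein_id = keep$protein_id,
                            profile_name = keep$profile_name),
                      stringsAsFactors = FALSE)
  names(mc)[3L] <- "n_domains"
  mc <- mc[mc$n_domains > 0L, , drop = FALSE]
  mc <- mc[order(mc$protein_id, mc$profile_name), , drop = FALSE]
  rownames(mc) <- NULL
  pc_tab <- tapply(mc$protein_id, mc$profile_name,
                   function(x) length(unique(x)))
  pc <- data.frame(profile_name = names(pc_tab),
                   n_proteins = as.integer(pc_tab),
                   stringsAsFactors = FALSE)
  rownames(pc) <- NULL
  list(hits = keep, motif_counts = mc, protein_counts = pc)
}
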