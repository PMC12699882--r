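#' Build a lineage-specific motif profile from validated motifs
#'
#' Combines validated motif sequences into an ungapped positional
#' profile. Motifs are grouped by length class; within a class columns
#' align positionally, and classes are merged onto the longest class's
#' coordinates by padding shorter motifs at the C-terminus. Each
#' column's amino-acid probabilities use a Laplace pseudocount
#' (`alpha`, default 0.5) over the 20 standard residues:
#' `p(a) = (n_a + alpha) / (n + 20 alpha)` with `n` the non-gap count
#' in the column. Log-odds are taken against a background distribution
#' (uniform by default). The underlying alignment is kept so it can be
#' exported (aligned FASTA or Stockholm) for an external `hmmbuild`.
#'
#' @param motif_seqs Character vector of at least two motif sequences,
#'   each 31–40 residues.
#' @param name Profile name.
#' @param alpha Laplace pseudocount.
#' @param background Named numeric vector of background frequencies
#'   over the 20 standard residues; uniform when `NULL`.
#' @return An object of class `motif_profile`: `name`, `length`,
#'   `prob` and `log_odds` (20 x length matrices), `background`,
#'   `alignment` (padded motif strings), `consensus`.
#' @export
build_profile <- function(motif_seqs, name = "dipPPR", alpha = 0.5,
                          background = NULL) {
  if (length(motif_seqs) < 2L)
    stop("at least two motifs are required to build a profile")
  lens <- nchar(motif_seqs)
  if (any(lens < 31L | lens > 40L))
    stop("motif lengths must be within 31..40 (got ",
         paste(range(lens), collapse = ".."), ")")
  if (is.null(background)) {
    background <- stats::setNames(rep(1 / 20, 20), AA_STANDARD)
  } else {
    stopifnot(all(AA_STANDARD %in% names(background)),
              abs(sum(background) - 1) < 1e-6)
    background <- background[AA_STANDARD]
  }
  L <- max(lens)
  aligned <- vapply(motif_seqs, function(s)
    paste0(s, strrep("-", L - nchar(s))), character(1),
    USE.NAMES = FALSE)
  mat <- do.call(rbind, strsplit(aligned, ""))
  prob <- matrix(0, nrow = 20L, ncol = L,
                 dimnames = list(AA_STANDARD, NULL))
  for (j in seq_len(L)) {
    col <- mat[, j]
    col <- col[col != "-" & col != "X"]
    counts <- table(factor(col, levels = AA_STANDARD))
    prob[, j] <- (as.numeric(counts) + alpha) /
      (length(col) + 20 * alpha)
  }
  log_odds <- log2(prob / background)
  consensus <- paste(AA_STANDARD[apply(prob, 2L, which.max)],
                     collapse = "")
  structure(list(name = name, length = L, prob = prob,
                 log_odds = log_odds, background = background,
                 alignment = aligned, alpha = alpha,
                 consensus = consensus),
            class = "motif_profile")
}

#' @export
print.motif_profile <- function(x, ...) {
  cat("Motif profile '", x$name, "': length ", x$length, ", ",
      length(x$alignment), " aligned motifs\n", sep = "")
  cat("  consensus: ", x$consensus, "\n", sep = "")
  invisible(x)
}

#' Export a profile's alignment
#'
#' Writes the motif alignment underlying a [build_profile()] result in
#' aligned FASTA or Stockholm 1.0, the input formats an external
#' `hmmbuild` accepts.
#'
#' @param profile A `motif_profile`.
#' @param path Output path.
#' @param format `"fasta"` or `"stockholm"`.
#' @return `path`, invisibly.
#' @export
write_profile_alignment <- function(profile, path,
                                    format = c("stockholm", "fasta")) {
  format <- match.arg(format)
  ids <- sprintf("%s_motif%03d", profile$name,
                 seq_along(profile$alignment))
  if (format == "fasta") {
    writeLines(as.vector(rbind(paste0(">", ids), profile$alignment)),
               path)
  } else {
    pad <- max(nchar(ids)) + 2L
    writeLines(c("# STOCKHOLM 1.0",
                 paste0("#=GF ID ", profile$name),
                 sprintf(paste0("%-", pad, "s%s"), ids,
                         gsub("-", ".", profile$alignment)),
                 "//"), path)
  }
  invisible(path)
}

# Window log-odds scores along an integer-encoded sequence.
# Encoding: 1..20 standard residues, 21 = X (scores 0, background),
# 22 = protein-boundary sentinel (score -Inf-like, so windows spanning
# two proteins are never reported). lod: 20 x L matrix.
window_scores <- function(idx, lod) {
  L <- ncol(lod)
  n <- length(idx)
  if (n < L) return(numeric(0))
  nw <- n - L + 1L
  sc <- numeric(nw)
  for (j in seq_len(L)) {
    lut <- c(lod[, j], 0, -1e9)
    sc <- sc + lut[idx[j:(j + nw - 1L)]]
  }
  sc
}

encode_seq <- function(sequence) {
  i <- match(strsplit(sequence, "")[[1L]], AA_STANDARD)
  i[is.na(i)] <- 21L
  i
}

# Concatenate encoded proteins with L-1 boundary sentinels between
# them; returns the vector and each protein's offset.
concat_encoded <- function(idx_list, L) {
  sep <- rep(22L, L - 1L)
  n <- length(idx_list)
  pieces <- vector("list", 2L * n - 1L)
  offsets <- integer(n)
  pos <- 0L
  for (i in seq_len(n)) {
    offsets[i] <- pos
    pieces[[2L * i - 1L]] <- idx_list[[i]]
    pos <- pos + length(idx_list[[i]])
    if (i < n) {
      pieces[[2L * i]] <- sep
      pos <- pos + length(sep)
    }
  }
  list(idx = unlist(pieces, use.names = FALSE), offsets = offsets)
}

# Greedy selection of windows by descending score whose starts are at
# least min_sep apart (tandem repeats shorter than the profile may
# legitimately start closer than one profile length).
pick_nonoverlapping <- function(starts, scores, min_sep) {
  ord <- order(scores, decreasing = TRUE)
  taken_start <- integer(0)
  keep <- integer(0)
  for (i in ord) {
    s <- starts[i]
    if (all(abs(s - taken_start) >= min_sep)) {
      keep <- c(keep, i)
      taken_start <- c(taken_start, s)
    }
  }
  sort(keep)
}

#' Scan a proteome with a motif profile
#'
#' Slides the profile over every window of profile length in every
#' protein, scoring windows by summed log-odds, and reports
#' non-overlapping hits above a score floor. Statistical calibration is
#' empirical: the null score distribution is obtained from
#' `null_decoys` within-protein residue-shuffled copies of the
#' proteome, and a hit's e-value is the expected number of null windows
#' scoring at least as high, scaled to one proteome. Zero null
#' exceedances are reported as half a count (0.5 / `null_decoys`) so
#' e-values stay positive. Proteins shorter than the profile are
#' skipped. When real `hmmsearch` output is available it should be
#' preferred; this scanner exists so the second search iteration runs
#' self-contained.
#'
#' @param profile A `motif_profile`.
#' @param proteins Protein table from [read_fasta()].
#' @param null_decoys Number of shuffled proteome copies (default 200).
#' @param seed RNG seed for the decoy shuffles (default 42).
#' @param score_floor Minimum window score reported.
#' @param min_separation Minimum distance between reported hit starts
#'   within a protein; defaults to the shortest repeat length (31) so
#'   tandem repeats shorter than the profile are not suppressed.
#' @return A domain-hit `data.frame` (`protein_id`, `profile_name`,
#'   `env_start`, `env_end`, `i_evalue`, `bit_score`) with empirical
#'   e-values.
#' @export
scan_with_profile <- function(profile, proteins, null_decoys = 200L,
                              seed = 42L, score_floor = 0,
                              min_separation = 31L) {
  stopifnot(inherits(profile, "motif_profile"))
  empty <- data.frame(protein_id = character(),
                      profile_name = character(),
                      env_start = integer(), env_end = integer(),
                      i_evalue = numeric(), bit_score = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(proteins) == 0L) return(empty)
  L <- profile$length
  lod <- profile$log_odds
  idx_list <- lapply(proteins$sequence, encode_seq)
  names(idx_list) <- proteins$id
  cc <- concat_encoded(idx_list, L)
  all_sc <- window_scores(cc$idx, lod)

  hits <- list()
  for (i in seq_along(idx_list)) {
    plen <- length(idx_list[[i]])
    if (plen < L) next
    sc <- all_sc[(cc$offsets[i] + 1L):(cc$offsets[i] + plen - L + 1L)]
    above <- which(sc > score_floor)
    if (length(above) == 0L) next
    sel <- pick_nonoverlapping(above, sc[above],
                               min(min_separation, L))
    s <- above[sel]
    hits[[length(hits) + 1L]] <- data.frame(
      protein_id = proteins$id[i], profile_name = profile$name,
      env_start = s, env_end = s + L - 1L, bit_score = sc[s],
      stringsAsFactors = FALSE)
  }
  if (length(hits) == 0L) return(empty)
  hits <- do.call(rbind, hits)
  rownames(hits) <- NULL

  # empirical null: within-protein residue shuffles of the whole
  # proteome; only exceedance counts at the observed hit scores are
  # accumulated, never the raw null score vectors
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv())
         else NULL
  set.seed(seed)
  seg <- lapply(seq_along(idx_list), function(i)
    (cc$offsets[i] + 1L):(cc$offsets[i] + length(idx_list[[i]])))
  exceed <- numeric(nrow(hits))
  dec_idx <- cc$idx
  for (d in seq_len(null_decoys)) {
    for (s in seg) dec_idx[s] <- cc$idx[s][sample.int(length(s))]
    ns <- sort(window_scores(dec_idx, lod))
    exceed <- exceed + (length(ns) -
      findInterval(hits$bit_score, ns, left.open = TRUE))
  }
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  hits$i_evalue <- pmax(exceed, 0.5) / null_decoys
  hits[, c("protein_id", "profile_name", "env_start", "env_end",
           "i_evalue", "bit_score")]
}
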