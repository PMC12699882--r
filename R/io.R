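# Amino-acid alphabet used throughout: the 20 standard residues plus X.
# Ambiguity/rare codes (B, Z, U, O, J) are mapped to X on read; X counts
# toward length and toward composition denominators.
AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
AA_VALID    <- c(AA_STANDARD, "X")

BAND_LEVELS <- c("non_mitochondrial", "low_probability", "likely",
                 "very_likely", "almost_certainly")

SS8_ALPHABET <- c("H", "G", "I", "E", "B", "T", "S", "C")

#' Read a protein FASTA file
#'
#' Reads protein sequences, normalising them to the 20 standard amino
#' acids plus `X`: rare/ambiguity codes (`B`, `Z`, `U`, `O`, `J`) are
#' mapped to `X` and a trailing stop (`*`) is stripped. Record ids are
#' the header text up to the first whitespace and must be unique.
#'
#' @param path Path to a FASTA file.
#' @return A `data.frame` with columns `id`, `sequence`, `length`, in
#'   file order.
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1", "MKR"), tf)
#' read_fasta(tf)
#' @export
read_fasta <- function(path) {
  stopifnot(is.character(path), length(path) == 1L)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  header_lines <- grep("^>", lines)
  if (length(header_lines) == 0L)
    stop("empty FASTA file (no records): ", path)
  aa <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(aa))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    first_dup <- dup[[1L]]
    ln <- header_lines[which(ids == first_dup)[2L]]
    stop("duplicate sequence id '", first_dup, "' (line ", ln, ")")
  }
  seqs <- toupper(as.character(aa))
  seqs <- sub("\\*+$", "", seqs)
  seqs <- chartr("BZUOJ", "XXXXX", seqs)
  bad <- grepl(paste0("[^", paste(AA_VALID, collapse = ""), "]"), seqs)
  if (any(bad)) {
    i <- which(bad)[[1L]]
    stop("non-amino-acid characters in record '", ids[i],
         "' (record starting at line ", header_lines[i], ")")
  }
  if (any(nchar(seqs) == 0L)) {
    i <- which(nchar(seqs) == 0L)[[1L]]
    stop("empty sequence for record '", ids[i],
         "' (line ", header_lines[i], ")")
  }
  data.frame(id = ids, sequence = seqs, length = nchar(seqs),
             stringsAsFactors = FALSE)
}

#' Write a protein set to FASTA
#'
#' @param proteins A `data.frame` with columns `id` and `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path) {
  stopifnot(all(c("id", "sequence") %in% names(proteins)))
  aa <- Biostrings::AAStringSet(proteins$sequence)
  names(aa) <- proteins$id
  Biostrings::writeXStringSet(aa, filepath = path, width = 70L)
  invisible(path)
}

#' Read an HMMER3 per-domain table (domtblout)
#'
#' Parses the whitespace-separated per-domain table written by
#' `hmmsearch --domtblout`. Envelope coordinates (`env from`/`env to`)
#' define each hit's span; the independent E-value (i-E-value) column is
#' the hit's score for downstream calibration. Coordinates are 1-based
#' inclusive, as in the file.
#'
#' @param path Path to a domtblout file.
#' @return A `data.frame` of domain hits with columns `protein_id`,
#'   `profile_name`, `env_start`, `env_end`, `i_evalue`, `bit_score`.
#' @export
read_domtblout <- function(path) {
  if (!file.exists(path)) stop("domtblout file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  rows <- which(keep)
  if (length(rows) == 0L)
    return(data.frame(protein_id = character(), profile_name = character(),
                      env_start = integer(), env_end = integer(),
                      i_evalue = numeric(), bit_score = numeric(),
                      stringsAsFactors = FALSE))
  parse_row <- function(ln) {
    f <- strsplit(trimws(lines[ln]), "\\s+")[[1L]]
    if (length(f) < 22L)
      stop("malformed domtblout row at line ", ln,
           " (", length(f), " fields, expected >= 22)")
    iev <- suppressWarnings(as.numeric(f[13L]))
    es  <- suppressWarnings(as.integer(f[20L]))
    ee  <- suppressWarnings(as.integer(f[21L]))
    bs  <- suppressWarnings(as.numeric(f[14L]))
    if (anyNA(c(iev, es, ee, bs)))
      stop("non-numeric field in domtblout row at line ", ln)
    if (iev <= 0)
      stop("non-positive i-Evalue at line ", ln)
    if (es < 1L || es > ee)
      stop("invalid envelope coordinates (", es, "..", ee,
           ") at line ", ln)
    list(protein_id = f[1L], profile_name = f[4L],
         env_start = es, env_end = ee, i_evalue = iev, bit_score = bs)
  }
  parsed <- lapply(rows, parse_row)
  data.frame(
    protein_id   = vapply(parsed, `[[`, character(1), "protein_id"),
    profile_name = vapply(parsed, `[[`, character(1), "profile_name"),
    env_start    = vapply(parsed, `[[`, integer(1), "env_start"),
    env_end      = vapply(parsed, `[[`, integer(1), "env_end"),
    i_evalue     = vapply(parsed, `[[`, numeric(1), "i_evalue"),
    bit_score    = vapply(parsed, `[[`, numeric(1), "bit_score"),
    stringsAsFactors = FALSE)
}

#' Write domain hits in the HMMER3 domtblout dialect
#'
#' Emits the 23-column whitespace-separated per-domain table so that
#' internally generated hits round-trip through [read_domtblout()].
#' Columns not represented in the hit table (alignment coordinates,
#' biases, full-sequence statistics) are filled with placeholders.
#'
#' @param hits A domain-hit `data.frame` as returned by
#'   [read_domtblout()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_domtblout <- function(hits, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# target name        accession   tlen query name           accession   qlen   E-value  score  bias   #  of  c-Evalue  i-Evalue  score  bias  from    to  from    to  from    to  acc description of target",
    "#------------------- ---------- ----- -------------------- ---------- ----- --------- ------ ----- --- --- --------- --------- ------ ----- ----- ----- ----- ----- ----- ----- ---- ---------------------"),
    con)
  if (nrow(hits) > 0L) {
    tlen <- if ("target_len" %in% names(hits)) hits$target_len else hits$env_end
    n_by <- stats::ave(seq_len(nrow(hits)), hits$protein_id,
                       FUN = seq_along)
    tot  <- stats::ave(seq_len(nrow(hits)), hits$protein_id,
                       FUN = length)
    rows <- sprintf(
      "%-20s -          %5d %-20s -          %5d %9.2g %6.1f   0.0 %3d %3d %9.2g %9.3g %6.1f   0.0 %5d %5d %5d %5d %5d %5d 0.90 -",
      hits$protein_id, tlen, hits$profile_name,
      hits$env_end - hits$env_start + 1L,
      hits$i_evalue, hits$bit_score, n_by, tot,
      hits$i_evalue, hits$i_evalue, hits$bit_score,
      1L, hits$env_end - hits$env_start + 1L,
      hits$env_start, hits$env_end, hits$env_start, hits$env_end)
    writeLines(rows, con)
  }
  invisible(path)
}

#' Read a localization-predictor score table
#'
#' Reads a tab-separated table of per-protein scores from the three
#' localization predictors feeding the ensemble: a primary
#' (DeepLoc2-style) mitochondrion probability, a secondary
#' (MULocDeep-style) probability, and a tertiary (WoLF PSORT-style)
#' unnormalized score. Each probability-scale score must lie in
#' \[0, 1\]; the tertiary raw score is divided by `norm_constant_tertiary`
#' and clamped at 1. The tools' own "assigned to mitochondrion" flags
#' are required columns, not inferred from the scores, because each
#' tool's internal assignment rule is its own.
#'
#' @param path Path to a tab-separated file with header columns
#'   `protein_id`, `score_primary`, `assigned_primary`,
#'   `score_secondary`, `assigned_secondary`, `score_tertiary_raw`.
#' @param norm_constant_tertiary Positive constant mapping the raw
#'   tertiary score into \[0, 1\]. No published value exists for the
#'   normalization used upstream, so it is a required argument.
#' @return The validated table with an added `score_tertiary` column
#'   (normalized, clamped to \[0, 1\]).
#' @export
read_predictor_table <- function(path, norm_constant_tertiary) {
  stopifnot(is.numeric(norm_constant_tertiary),
            length(norm_constant_tertiary) == 1L,
            norm_constant_tertiary > 0)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("protein_id", "score_primary", "assigned_primary",
                "score_secondary", "assigned_secondary",
                "score_tertiary_raw")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0L)
    stop("predictor table is missing column(s): ",
         paste(missing, collapse = ", "))
  validate_predictor_table(tab)
  tab$assigned_primary <- as.logical(tab$assigned_primary)
  tab$assigned_secondary <- as.logical(tab$assigned_secondary)
  tab$score_tertiary <- pmin(1, tab$score_tertiary_raw /
                                 norm_constant_tertiary)
  tab
}

validate_predictor_table <- function(tab) {
  bad <- function(x) is.na(x) | x < 0 | x > 1
  if (any(bad(tab$score_primary)))
    stop("score_primary outside [0, 1] for protein '",
         tab$protein_id[which(bad(tab$score_primary))[1L]], "'")
  if (any(bad(tab$score_secondary)))
    stop("score_secondary outside [0, 1] for protein '",
         tab$protein_id[which(bad(tab$score_secondary))[1L]], "'")
  if (any(is.na(tab$score_tertiary_raw) | tab$score_tertiary_raw < 0))
    stop("score_tertiary_raw must be non-negative")
  if (anyDuplicated(tab$protein_id))
    stop("duplicate protein_id in predictor table: '",
         tab$protein_id[duplicated(tab$protein_id)][1L], "'")
  invisible(tab)
}

#' Read an MS quantification table
#'
#' One row per protein with spectral counts and ion intensities across
#' the three subcellular fractions (whole cell, cytosol, mitochondria),
#' plus a flag marking detection in protein-complex pull-down datasets
#' (respirasome / mitoribosome style).
#'
#' @param path Tab-separated file with header columns `protein_id`,
#'   `sc_whole_cell`, `sc_cytosol`, `sc_mitochondria`,
#'   `int_whole_cell`, `int_cytosol`, `int_mitochondria`,
#'   `in_complex_datasets`.
#' @return The validated `data.frame`.
#' @export
read_quant_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("protein_id", "sc_whole_cell", "sc_cytosol",
                "sc_mitochondria", "int_whole_cell", "int_cytosol",
                "int_mitochondria", "in_complex_datasets")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0L)
    stop("quant table is missing column(s): ",
         paste(missing, collapse = ", "))
  num <- setdiff(required, c("protein_id", "in_complex_datasets"))
  for (cn in num) {
    if (any(is.na(tab[[cn]]) | tab[[cn]] < 0))
      stop("negative or missing values in column '", cn, "'")
  }
  sc <- c("sc_whole_cell", "sc_cytosol", "sc_mitochondria")
  if (any(tab[sc] != round(tab[sc])))
    stop("spectral counts must be integers")
  tab$in_complex_datasets <- as.logical(tab$in_complex_datasets)
  if (anyDuplicated(tab$protein_id))
    stop("duplicate protein_id in quant table")
  tab
}

#' Read per-residue secondary-structure tracks
#'
#' Reads 8-state secondary-structure label strings (NetSurfP-style
#' alphabet `H G I E B T S C`), one row per protein.
#'
#' @param path Tab-separated file with header columns `protein_id`,
#'   `labels`.
#' @param proteins Optional protein table from [read_fasta()]; when
#'   given, each track's length is checked against the sequence length.
#' @return A `data.frame` with columns `protein_id`, `labels`.
#' @export
read_structure_table <- function(path, proteins = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("protein_id", "labels") %in% names(tab)))
    stop("structure table must have columns 'protein_id' and 'labels'")
  bad <- grepl(paste0("[^", paste(SS8_ALPHABET, collapse = ""), "]"),
               tab$labels)
  if (any(bad))
    stop("structure labels outside the 8-state alphabet for protein '",
         tab$protein_id[which(bad)[1L]], "'")
  if (!is.null(proteins)) {
    m <- match(tab$protein_id, proteins$id)
    if (anyNA(m))
      stop("structure track for unknown protein '",
           tab$protein_id[which(is.na(m))[1L]], "'")
    mism <- nchar(tab$labels) != proteins$length[m]
    if (any(mism))
      stop("structure track length mismatch for protein '",
           tab$protein_id[which(mism)[1L]], "'")
  }
  tab
}

#' Read a motif span reference table
#'
#' Three tab-separated columns (`protein_id`, `start`, `end`) with
#' 1-based inclusive coordinates; used for the curated positive and
#' negative motif references that calibrate the motif E-value threshold.
#'
#' @param path Path to the table.
#' @return A `data.frame` with columns `protein_id`, `start`, `end`.
#' @export
read_motif_spans <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("protein_id", "start", "end") %in% names(tab)))
    stop("motif span table must have columns protein_id, start, end")
  if (any(tab$start < 1L | tab$start > tab$end))
    stop("invalid motif span (need 1 <= start <= end)")
  tab
}

#' Write the per-protein annotation table
#'
#' Joins localization calls, enrichment verdicts and motif counts into
#' one tab-separated row per protein, the pipeline's principal output.
#' All coordinates in span fields are 1-based inclusive; column order
#' is fixed so identical inputs yield byte-identical files.
#'
#' @param calls Localization calls from [wa_score()] (columns
#'   `protein_id`, `wa_score`, `penalized`, `band`, optionally
#'   `band_odds`).
#' @param motifs Optional motif table with columns `protein_id` and
#'   `source` (PPR motifs) used to derive per-protein counts; `NULL`
#'   for none.
#' @param enrichment Optional enrichment calls from
#'   [enrichment_calls()]; `NULL` for none.
#' @param path Output path.
#' @return The assembled `data.frame`, invisibly.
#' @export
write_annotation_table <- function(calls, motifs = NULL,
                                   enrichment = NULL, path) {
  if (anyDuplicated(calls$protein_id)) {
    d <- calls$protein_id[duplicated(calls$protein_id)][1L]
    dup_rows <- calls[calls$protein_id == d, , drop = FALSE]
    if (nrow(unique(dup_rows)) > 1L)
      stop("conflicting duplicate rows for protein '", d, "'")
    calls <- calls[!duplicated(calls$protein_id), , drop = FALSE]
  }
  out <- data.frame(protein_id = calls$protein_id,
                    wa_score = calls$wa_score,
                    penalized = calls$penalized,
                    band = as.character(calls$band),
                    stringsAsFactors = FALSE)
  out$band_odds <- if ("band_odds" %in% names(calls))
    calls$band_odds else rep(NA_real_, nrow(out))
  if (!is.null(enrichment)) {
    m <- match(out$protein_id, enrichment$protein_id)
    out$detected_mito <- enrichment$detected[m]
    out$via_complex <- enrichment$via_complex[m]
  } else {
    out$detected_mito <- rep(NA, nrow(out))
    out$via_complex <- rep(NA, nrow(out))
  }
  out$n_ppr_motifs <- rep(0L, nrow(out))
  if (!is.null(motifs) && nrow(motifs) > 0L) {
    cnt <- table(motifs$protein_id)
    m <- match(out$protein_id, names(cnt))
    out$n_ppr_motifs <- ifelse(is.na(m), 0L, as.integer(cnt[m]))
  }
  utils::write.table(out, file = path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(out)
}

#' Read back an annotation table written by [write_annotation_table()]
#' @param path Path to the table.
#' @return A `data.frame`.
#' @export
read_annotation_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
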