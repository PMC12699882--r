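# Shared fixtures, built in code.

# One-row predictor table with the normalized tertiary column already
# computed (as read_predictor_table would do with the given norm).
predictor_row <- function(id = "p1", s1 = 0.9, a1 = TRUE, s2 = 0.8,
                          a2 = TRUE, raw3 = 14, norm3 = 28) {
  data.frame(protein_id = id, score_primary = s1,
             assigned_primary = a1, score_secondary = s2,
             assigned_secondary = a2, score_tertiary_raw = raw3,
             score_tertiary = pmin(1, raw3 / norm3),
             stringsAsFactors = FALSE)
}

write_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# A valid 23-column domtblout data row.
domtbl_row <- function(target = "p1", query = "prof", iev = 3.1,
                       env_from = 12, env_to = 46, score = 25.0) {
  paste(target, "-", 500, query, "-", 35, "1e-5", 30.1, 0.0, 1, 1,
        iev, iev, score, 0.0, 1, 35, env_from, env_to, env_from,
        env_to, 0.9, "-")
}

# Fraction of spans in `a` overlapped >= 50% (of the shorter span) by
# some span in `b`; used for planted-truth recovery measurements.
span_recovery <- function(a, b) {
  if (nrow(a) == 0L) return(NA_real_)
  hit <- logical(nrow(a))
  for (i in seq_len(nrow(a))) {
    cand <- b[b$protein_id == a$protein_id[i], , drop = FALSE]
    if (nrow(cand) == 0L) next
    ov <- pmin(cand$end, a$end[i]) - pmax(cand$start, a$start[i]) + 1L
    shorter <- pmin(cand$end - cand$start, a$end[i] - a$start[i]) + 1L
    hit[i] <- any(ov / shorter >= 0.5)
  }
  mean(hit)
}

# Structure track with the canonical repeat pattern planted at spans.
track_with_motifs <- function(len, starts, motif_len = 35L,
                              background = "C") {
  lab <- rep(background, len)
  for (s in starts) {
    pat <- c(rep("H", 10L), rep("T", 3L), rep("H", motif_len - 13L))
    lab[s:(s + motif_len - 1L)] <- pat
  }
  paste(lab, collapse = "")
}
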