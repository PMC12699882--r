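quant_cols <- function(metric) {
  switch(metric,
         spectral_counts = c(whole = "sc_whole_cell",
                             cyto = "sc_cytosol",
                             mito = "sc_mitochondria"),
         ion_intensity = c(whole = "int_whole_cell",
                           cyto = "int_cytosol",
                           mito = "int_mitochondria"),
         stop("unknown metric: ", metric))
}

#' Dataset floor for zero-divisor substitution
#'
#' The enrichment ratios divide by the whole-cell quantity; when a
#' protein was not detected in the whole-cell lysate the divisor is
#' substituted by the minimal non-zero value of that metric observed
#' anywhere in the dataset (all proteins, all fractions). In the
#' original study this floor was 1 for spectral counts and 35,000 for
#' ion intensities; here it is recomputed from the data at hand.
#'
#' @param quants Quant table from [read_quant_table()].
#' @param metric `"spectral_counts"` or `"ion_intensity"`.
#' @return The floor (a single positive number).
#' @export
compute_floors <- function(quants,
                           metric = c("spectral_counts",
                                      "ion_intensity")) {
  metric <- match.arg(metric)
  cols <- quant_cols(metric)
  v <- unlist(quants[, cols], use.names = FALSE)
  v <- v[!is.na(v) & v > 0]
  if (length(v) == 0L)
    stop("cannot compute a floor: all ", metric, " values are zero")
  min(v)
}

enrichment_one_metric <- function(quants, metric, floor) {
  cols <- quant_cols(metric)
  whole <- quants[[cols["whole"]]]
  cyto  <- quants[[cols["cyto"]]]
  mito  <- quants[[cols["mito"]]]
  if (any(whole < 0 | cyto < 0 | mito < 0))
    stop("negative quantities in metric ", metric)
  substituted <- whole == 0
  divisor <- ifelse(substituted, floor, whole)
  ratio_mito <- mito / divisor
  ratio_cyto <- cyto / divisor
  detected <- ratio_mito > ratio_cyto & ratio_mito > 1.5
  data.frame(ratio_mito = ratio_mito, ratio_cyto = ratio_cyto,
             divisor_substituted = substituted, detected = detected)
}

#' Classify proteins as detected in mitochondria
#'
#' Applies the fraction-ratio rule: for each protein the mitochondrial
#' and cytosolic quantities are each divided by the whole-cell quantity
#' (or, when the protein is absent from the whole-cell lysate, by the
#' dataset floor from [compute_floors()]); the protein is 'detected in
#' mitochondria' when the mitochondrion:whole-cell ratio exceeds the
#' cytosol:whole-cell ratio and is strictly greater than 1.5.
#' Proteins flagged as present in mitochondrial protein-complex
#' datasets are classified as detected by association, regardless of
#' the ratios. With `metric = "both"` the rule is applied per metric
#' and a protein is detected when either metric passes; both
#' metric-level verdicts are retained in the output.
#'
#' @param quants Quant table from [read_quant_table()].
#' @param metric `"spectral_counts"`, `"ion_intensity"` or `"both"`.
#' @param floors Optional named list of floors per metric; computed
#'   from the data when `NULL`.
#' @return A `data.frame` with per-metric ratios and verdicts plus the
#'   combined `detected` and `via_complex` columns.
#' @examples
#' q <- data.frame(protein_id = "p", sc_whole_cell = 10L,
#'                 sc_cytosol = 2L, sc_mitochondria = 20L,
#'                 int_whole_cell = 0, int_cytosol = 0,
#'                 int_mitochondria = 0, in_complex_datasets = FALSE)
#' enrichment_calls(q, metric = "spectral_counts")  # ratios 2.0 / 0.2
#' @export
enrichment_calls <- function(quants,
                             metric = c("both", "spectral_counts",
                                        "ion_intensity"),
                             floors = NULL) {
  metric <- match.arg(metric)
  metrics <- if (metric == "both")
    c("spectral_counts", "ion_intensity") else metric
  out <- data.frame(protein_id = quants$protein_id,
                    stringsAsFactors = FALSE)
  any_detected <- rep(FALSE, nrow(quants))
  for (m in metrics) {
    fl <- if (!is.null(floors) && !is.null(floors[[m]])) floors[[m]]
          else compute_floors(quants, m)
    res <- enrichment_one_metric(quants, m, fl)
    tag <- if (m == "spectral_counts") "sc" else "int"
    names(res) <- paste(tag, names(res), sep = "_")
    out <- cbind(out, res)
    any_detected <- any_detected | res[[paste0(tag, "_detected")]]
  }
  out$via_complex <- as.logical(quants$in_complex_datasets)
  out$detected <- any_detected | out$via_complex
  out
}

#' Count theoretically observable tryptic peptides
#'
#' Enumerates the fully tryptic peptides of a sequence — cleavage after
#' every K or R not followed by P, zero missed cleavages — and counts
#' those of length 7 to 30 residues, the standard iBAQ divisor.
#'
#' @param sequence Amino-acid string.
#' @param min_len,max_len Observable peptide length bounds.
#' @return Integer count.
#' @export
count_tryptic_peptides <- function(sequence, min_len = 7L,
                                   max_len = 30L) {
  stopifnot(is.character(sequence), length(sequence) == 1L,
            nchar(sequence) > 0L)
  chars <- strsplit(sequence, "")[[1L]]
  n <- length(chars)
  cut_after <- which(chars %in% c("K", "R"))
  cut_after <- cut_after[cut_after < n & chars[cut_after + 1L] != "P"]
  bounds <- c(0L, cut_after, n)
  lens <- diff(bounds)
  sum(lens >= min_len & lens <= max_len)
}

#' iBAQ quantification
#'
#' Intensity-based absolute quantification: the summed precursor
#' intensity divided by the number of theoretically observable tryptic
#' peptides (7–30 residues, zero missed cleavages) of the protein.
#' Returns `NA` when the protein yields no observable peptide — the
#' quantity is undefined, not zero.
#'
#' @param intensity_sum Non-negative summed intensity.
#' @param sequence Protein sequence.
#' @return The iBAQ value, or `NA` if no observable peptide exists.
#' @export
ibaq <- function(intensity_sum, sequence) {
  stopifnot(is.numeric(intensity_sum), length(intensity_sum) == 1L)
  if (is.na(intensity_sum) || intensity_sum < 0)
    stop("intensity must be non-negative")
  k <- count_tryptic_peptides(sequence)
  if (k == 0L) return(NA_real_)
  intensity_sum / k
}

#' Per-category detection summary
#'
#' Summarises, per functional category (labels `A` through `J`), how
#' many proteins there are and how many were detected in mitochondria,
#' mirroring the per-category detection percentages of a mitoproteome
#' survey figure.
#'
#' @param calls `data.frame` with columns `protein_id`, `detected`
#'   (logical).
#' @param categories `data.frame` with columns `protein_id`,
#'   `category` (single letters A–J).
#' @return A `data.frame` with one row per category plus a `Total`
#'   row: `n`, `n_detected`, `pct_detected`.
#' @export
category_summary <- function(calls, categories) {
  stopifnot(all(c("protein_id", "category") %in% names(categories)))
  valid <- LETTERS[1:10]
  bad <- !categories$category %in% valid
  if (any(bad))
    stop("unknown category label '",
         categories$category[which(bad)[1L]],
         "' (expected A through J)")
  m <- match(categories$protein_id, calls$protein_id)
  det <- calls$detected[m]
  det[is.na(det)] <- FALSE
  cat_f <- factor(categories$category, levels = valid)
  n <- as.integer(table(cat_f))
  nd <- as.integer(tapply(det, cat_f, sum, default = 0L))
  pct <- ifelse(n > 0L, 100 * nd / n, NA_real_)
  out <- data.frame(category = valid, n = n, n_detected = nd,
                    pct_detected = pct, stringsAsFactors = FALSE)
  total <- data.frame(category = "Total", n = sum(n),
                      n_detected = sum(nd),
                      pct_detected = if (sum(n) > 0L)
                        100 * sum(nd) / sum(n) else NA_real_)
  rbind(out, total)
}
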