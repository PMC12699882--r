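stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
}

#' Load a pipeline configuration from YAML
#'
#' Reads a YAML file naming the pipeline inputs and options and loads
#' every referenced file through the package readers. Recognised keys:
#' `fasta`, `predictors` (+ `norm_constant_tertiary`), `domtblout`,
#' `structures`, `quant`, `reference_pos`/`reference_neg` (protein-id
#' lists), `motif_reference_pos`/`motif_reference_neg` (span tables),
#' `ppr_thresholds` (two numbers; when absent, thresholds are
#' calibrated from the motif reference), `min_band`, `overrides`
#' (list of `protein_id`/`reason` pairs), `categories` (TSV with
#' `protein_id`, `category`), `seed`, `outdir`.
#'
#' @param path Path to the YAML file. Relative input paths are
#'   resolved against the YAML file's directory.
#' @return A configuration list ready for [run_pipeline()].
#' @export
load_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  rel <- function(f) if (is.null(f) || file.exists(f)) f
                     else file.path(base, f)
  need <- function(key) {
    f <- rel(raw[[key]])
    if (!is.null(f) && !file.exists(f))
      stop("configured file for '", key, "' not found: ", f)
    f
  }
  cfg <- list(seed = raw$seed %||% 42L,
              min_band = raw$min_band %||% "very_likely",
              ppr_thresholds = raw$ppr_thresholds,
              outdir = raw$outdir)
  fasta <- need("fasta")
  if (is.null(fasta)) stop("config must name a 'fasta' input")
  cfg$proteins <- read_fasta(fasta)
  if (!is.null(raw$predictors)) {
    nc <- raw$norm_constant_tertiary
    if (is.null(nc))
      stop("'norm_constant_tertiary' is required with 'predictors'")
    cfg$predictors <- read_predictor_table(need("predictors"), nc)
  }
  if (!is.null(raw$domtblout))
    cfg$hits <- read_domtblout(need("domtblout"))
  if (!is.null(raw$structures))
    cfg$tracks <- read_structure_table(need("structures"),
                                       cfg$proteins)
  if (!is.null(raw$quant))
    cfg$quants <- read_quant_table(need("quant"))
  if (!is.null(raw$reference_pos))
    cfg$reference_pos <- readLines(need("reference_pos"))
  if (!is.null(raw$reference_neg))
    cfg$reference_neg <- readLines(need("reference_neg"))
  if (!is.null(raw$motif_reference_pos))
    cfg$motif_reference <- list(
      positive = read_motif_spans(need("motif_reference_pos")),
      negative = read_motif_spans(need("motif_reference_neg")))
  if (!is.null(raw$overrides))
    cfg$overrides <- do.call(rbind, lapply(raw$overrides, function(o) {
      if (is.null(o$reason) || !nzchar(o$reason))
        stop("every override needs a free-text 'reason'")
      data.frame(protein_id = o$protein_id, reason = o$reason,
                 stringsAsFactors = FALSE)
    }))
  if (!is.null(raw$categories))
    cfg$categories <- utils::read.delim(need("categories"),
                                        stringsAsFactors = FALSE)
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full mitoproteome inference pipeline
#'
#' Executes every stage on the supplied inputs: ensemble localization
#' scoring with band assignment (and band-odds calibration when
#' protein-level references are given), MS enrichment classification,
#' the twin-Cx9C and AK-composition sequence screens, and iterative
#' PPR-motif discovery. Produces the joined per-protein annotation
#' table and a summary block (per-band counts, candidate count, the
#' percentage of candidates with WA > 0.5, detection and motif
#' counts). Any stage failure aborts with a stage-named error.
#' Identical inputs and configuration reproduce identical outputs.
#'
#' @param config A list as produced by [load_pipeline_config()], or
#'   assembled in code: must contain `proteins`; optional elements
#'   `predictors`, `hits`, `tracks`, `quants`, `reference_pos`,
#'   `reference_neg`, `motif_reference`, `ppr_thresholds`,
#'   `overrides`, `categories`, `min_band`, `seed`, `outdir`.
#' @return An object of class `mito_pipeline`: `annotation` (the
#'   per-protein table), `calls`, `band_odds`, `candidates`,
#'   `enrichment`, `ppr`, `cx9c`, `ak`, `category_table`, `summary`.
#' @export
run_pipeline <- function(config) {
  stopifnot(is.list(config), !is.null(config$proteins))
  proteins <- config$proteins
  seed <- config$seed %||% 42L
  min_band <- config$min_band %||% "very_likely"

  calls <- NULL; band_odds <- NULL; candidates <- NULL
  if (!is.null(config$predictors)) {
    calls <- stage("localization",
                   wa_score(config$predictors))
    if (!is.null(config$reference_pos) &&
        !is.null(config$reference_neg)) {
      band_odds <- stage("band_calibration",
                         calibrate_band_odds(calls,
                                             config$reference_pos,
                                             config$reference_neg))
      calls$band_odds <-
        band_odds$odds[match(as.character(calls$band),
                             as.character(band_odds$band))]
    }
    candidates <- stage("candidate_selection",
                        select_candidates(calls, min_band = min_band,
                                          overrides =
                                            config$overrides))
  }

  enrichment <- NULL
  if (!is.null(config$quants))
    enrichment <- stage("enrichment",
                        enrichment_calls(config$quants))

  cx9c <- stage("cx9c_screen", {
    res <- lapply(seq_len(nrow(proteins)), function(i)
      scan_cx9c(proteins$sequence[i], proteins$id[i]))
    res[vapply(res, function(r) nrow(r$motifs) > 0L, logical(1))]
  })
  ak <- stage("ak_screen", {
    res <- lapply(seq_len(nrow(proteins)), function(i)
      ak_composition_screen(proteins$sequence[i], proteins$id[i]))
    flags <- vapply(res, `[[`, logical(1), "flagged")
    data.frame(protein_id = proteins$id,
               pct_ak = vapply(res, `[[`, numeric(1), "pct_ak"),
               flagged = flags, stringsAsFactors = FALSE)
  })

  ppr <- NULL
  if (!is.null(config$hits))
    ppr <- stage("ppr_discovery",
                 iterate_discovery(proteins, config$hits,
                                   reference = config$motif_reference,
                                   tracks = config$tracks,
                                   thresholds = config$ppr_thresholds,
                                   null_decoys =
                                     config$null_decoys %||% 50L,
                                   seed = seed))

  if (is.null(calls))
    calls <- data.frame(protein_id = proteins$id,
                        wa_score = rep(NA_real_, nrow(proteins)),
                        penalized = rep(NA, nrow(proteins)),
                        band = rep(NA_character_, nrow(proteins)),
                        stringsAsFactors = FALSE)
  annotation <- stage("annotation", {
    path <- if (!is.null(config$outdir)) {
      dir.create(config$outdir, showWarnings = FALSE,
                 recursive = TRUE)
      file.path(config$outdir, "annotation.tsv")
    } else tempfile(fileext = ".tsv")
    write_annotation_table(calls, motifs = if (!is.null(ppr))
      ppr$motifs, enrichment = enrichment, path = path)
  })

  category_table <- NULL
  if (!is.null(config$categories) && !is.null(enrichment))
    category_table <- stage("category_summary",
                            category_summary(enrichment,
                                             config$categories))

  band_counts <- if (any(!is.na(calls$wa_score)))
    table(factor(as.character(calls$band), levels = BAND_LEVELS))
  else NULL
  n_cand <- if (!is.null(candidates)) nrow(candidates) else NA_integer_
  pct_above_half <- if (!is.null(candidates) && nrow(candidates) > 0L)
    100 * mean(candidates$wa_score > 0.5) else NA_real_

  summary_block <- list(
    n_proteins = nrow(proteins),
    band_counts = band_counts,
    n_candidates = n_cand,
    pct_candidates_wa_above_0.5 = pct_above_half,
    n_detected_mito = if (!is.null(enrichment))
      sum(enrichment$detected) else NA_integer_,
    n_ppr_proteins = if (!is.null(ppr))
      length(ppr$proteins_called) else NA_integer_,
    n_cx9c_proteins = length(cx9c),
    n_ak_flagged = sum(ak$flagged))

  res <- structure(list(annotation = annotation, calls = calls,
                        band_odds = band_odds,
                        candidates = candidates,
                        enrichment = enrichment, ppr = ppr,
                        cx9c = cx9c, ak = ak,
                        category_table = category_table,
                        summary = summary_block),
                   class = "mito_pipeline")
  if (!is.null(config$outdir))
    stage("report", write_pipeline_summary(res,
      file.path(config$outdir, "summary.txt")))
  res
}

write_pipeline_summary <- function(res, path) {
  s <- res$summary
  lines <- c(
    "mitoscope pipeline summary",
    sprintf("proteins analysed: %d", s$n_proteins),
    if (!is.null(s$band_counts))
      sprintf("  band %-18s %d", names(s$band_counts),
              as.integer(s$band_counts)),
    sprintf("candidate mitoproteins: %s", format(s$n_candidates)),
    sprintf("candidates with WA > 0.5: %s%%",
            format(round(s$pct_candidates_wa_above_0.5, 1))),
    sprintf("detected in mitochondria (MS): %s",
            format(s$n_detected_mito)),
    sprintf("PPR-containing proteins: %s", format(s$n_ppr_proteins)),
    sprintf("twin-Cx9C proteins: %d", s$n_cx9c_proteins),
    sprintf("AK-rich proteins: %d", s$n_ak_flagged))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.mito_pipeline <- function(x, ...) {
  s <- x$summary
  cat("Mitoproteome inference run\n")
  cat("  proteins:", s$n_proteins, "\n")
  if (!is.null(s$band_counts)) {
    cat("  localization bands:\n")
    for (b in names(s$band_counts))
      cat(sprintf("    %-18s %d\n", b, s$band_counts[[b]]))
    cat("  candidates (>= selection band):", s$n_candidates, "\n")
    cat(sprintf("  candidates with WA > 0.5: %.1f%%\n",
                s$pct_candidates_wa_above_0.5))
  }
  if (!is.na(s$n_detected_mito))
    cat("  detected in mitochondria (MS):", s$n_detected_mito, "\n")
  if (!is.na(s$n_ppr_proteins))
    cat("  PPR-containing proteins:", s$n_ppr_proteins, "\n")
  cat("  twin-Cx9C proteins:", s$n_cx9c_proteins,
      "| AK-rich proteins:", s$n_ak_flagged, "\n")
  invisible(x)
}
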