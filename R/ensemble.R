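#' Ensemble configuration for the weighted-average localization score
#'
#' The ensemble combines three predictors' mitochondrion scores into a
#' weighted average (WA):
#' \deqn{WA = (w_2 s_{sec} + w_3 s_{ter} + w_1 s_{pri}) / d}
#' with default weights 2.5 (secondary, MULocDeep-style), 1.5 (tertiary,
#' normalized WoLF PSORT-style) and 6 (primary, DeepLoc2-style), and
#' divisor 10. Proteins the primary predictor does not assign to the
#' mitochondrion but the secondary does are downgraded by
#' `penalty_factor`; proteins neither assigns default to WA = 0.
#'
#' @param weight_primary,weight_secondary,weight_tertiary Positive
#'   weights; must sum to `divisor` so that WA stays in \[0, 1\].
#' @param divisor Normalizing divisor (default 10).
#' @param penalty_factor Multiplicative downgrade in (0, 1) applied when
#'   only the secondary predictor assigns the protein to the
#'   mitochondrion (default 0.25).
#' @param band_edges Strictly increasing cut points in (0, 1) between
#'   the `low_probability`/`likely`, `likely`/`very_likely` and
#'   `very_likely`/`almost_certainly` bands (default 0.25, 0.5, 0.75).
#' @return An object of class `ensemble_config`.
#' @export
ensemble_config <- function(weight_primary = 6, weight_secondary = 2.5,
                            weight_tertiary = 1.5, divisor = 10,
                            penalty_factor = 0.25,
                            band_edges = c(0.25, 0.5, 0.75)) {
  w <- c(weight_primary, weight_secondary, weight_tertiary)
  stopifnot(all(w > 0), divisor > 0,
            penalty_factor > 0, penalty_factor < 1,
            length(band_edges) == 3L,
            all(diff(band_edges) > 0),
            band_edges[1L] > 0, band_edges[3L] < 1)
  if (abs(sum(w) - divisor) > 1e-9)
    stop("predictor weights must sum to the divisor (got ",
         sum(w), " vs ", divisor, ")")
  structure(list(weight_primary = weight_primary,
                 weight_secondary = weight_secondary,
                 weight_tertiary = weight_tertiary,
                 divisor = divisor,
                 penalty_factor = penalty_factor,
                 band_edges = band_edges),
            class = "ensemble_config")
}

#' Weighted-average mitochondrial localization score
#'
#' Computes the ensemble WA score and confidence band for each protein
#' in a predictor table. The raw weighted average is
#' `(2.5 * secondary + 1.5 * tertiary + 6 * primary) / 10` under the
#' default configuration. If the primary predictor assigned the protein
#' to the mitochondrion the raw value is kept; if only the secondary did,
#' it is multiplied by the penalty factor (0.25), placing penalized
#' scores in \[0, 0.25); if neither did, the WA score defaults to 0 and
#' the protein is called non-mitochondrial regardless of the numeric
#' scores.
#'
#' @param predictors A predictor table as returned by
#'   [read_predictor_table()] (must contain `score_tertiary`; pass
#'   `norm_constant_tertiary` there).
#' @param cfg An [ensemble_config()].
#' @return A `data.frame` of localization calls: `protein_id`,
#'   `wa_score`, `penalized`, `band`.
#' @examples
#' tab <- data.frame(protein_id = "p1",
#'                   score_primary = 0.9, assigned_primary = TRUE,
#'                   score_secondary = 0.8, assigned_secondary = TRUE,
#'                   score_tertiary_raw = 16.8, score_tertiary = 0.6)
#' wa_score(tab)  # (2.5*0.8 + 1.5*0.6 + 6*0.9)/10 = 0.83
#' @export
wa_score <- function(predictors, cfg = ensemble_config()) {
  stopifnot(inherits(cfg, "ensemble_config"))
  required <- c("protein_id", "score_primary", "assigned_primary",
                "score_secondary", "assigned_secondary", "score_tertiary")
  missing <- setdiff(required, names(predictors))
  if (length(missing) > 0L)
    stop("predictor table is missing column(s): ",
         paste(missing, collapse = ", "))
  validate_predictor_table(predictors)
  raw <- (cfg$weight_secondary * predictors$score_secondary +
          cfg$weight_tertiary  * predictors$score_tertiary +
          cfg$weight_primary   * predictors$score_primary) / cfg$divisor
  wa <- ifelse(predictors$assigned_primary, raw,
        ifelse(predictors$assigned_secondary, cfg$penalty_factor * raw, 0))
  penalized <- !predictors$assigned_primary & predictors$assigned_secondary
  data.frame(protein_id = predictors$protein_id,
             wa_score = wa,
             penalized = penalized,
             band = assign_band(wa, cfg),
             stringsAsFactors = FALSE)
}

#' Assign a WA score to a confidence band
#'
#' Bands partition \[0, 1\]: `non_mitochondrial` exactly at 0,
#' `low_probability` on (0, 0.25), `likely` on \[0.25, 0.5),
#' `very_likely` on \[0.5, 0.75) and `almost_certainly` on \[0.75, 1\].
#' Intervals are half-open below their upper edge except the top band,
#' which is closed at 1, so 0.75 is `almost_certainly`.
#'
#' @param wa Numeric vector of WA scores in \[0, 1\].
#' @param cfg An [ensemble_config()] supplying the band edges.
#' @return A factor with levels `non_mitochondrial < low_probability <
#'   likely < very_likely < almost_certainly`.
#' @export
assign_band <- function(wa, cfg = ensemble_config()) {
  if (any(is.na(wa) | wa < 0 | wa > 1))
    stop("WA scores must lie in [0, 1]")
  e <- cfg$band_edges
  band <- ifelse(wa == 0, "non_mitochondrial",
          ifelse(wa < e[1L], "low_probability",
          ifelse(wa < e[2L], "likely",
          ifelse(wa < e[3L], "very_likely", "almost_certainly"))))
  factor(band, levels = BAND_LEVELS, ordered = TRUE)
}

#' Calibrate per-band likelihood ratios from reference sets
#'
#' For each confidence band, estimates the odds of a protein in that
#' band being mitochondrial as the ratio of the fraction of reference
#' positives landing in the band to the fraction of reference negatives
#' doing so. Raw counts are reported alongside. No smoothing is
#' applied: a band holding positives but no negatives has infinite
#' odds, and a band holding no reference protein at all has undefined
#' odds (`NA`, flagged in `undefined`).
#'
#' @param calls Localization calls from [wa_score()].
#' @param positives,negatives Character vectors of reference protein
#'   ids, disjoint and both non-empty; every id must have a call.
#' @return A `data.frame` with one row per band: counts, fractions,
#'   `odds` and `undefined`.
#' @export
calibrate_band_odds <- function(calls, positives, negatives) {
  stopifnot(length(positives) > 0L, length(negatives) > 0L)
  if (length(intersect(positives, negatives)) > 0L)
    stop("reference positives and negatives must be disjoint")
  missing <- setdiff(c(positives, negatives), calls$protein_id)
  if (length(missing) > 0L)
    stop("reference id(s) without a localization call: ",
         paste(utils::head(missing, 3L), collapse = ", "))
  band_of <- stats::setNames(as.character(calls$band), calls$protein_id)
  pos_band <- factor(band_of[positives], levels = BAND_LEVELS)
  neg_band <- factor(band_of[negatives], levels = BAND_LEVELS)
  n_pos <- as.integer(table(pos_band))
  n_neg <- as.integer(table(neg_band))
  frac_pos <- n_pos / length(positives)
  frac_neg <- n_neg / length(negatives)
  odds <- ifelse(n_pos == 0L & n_neg == 0L, NA_real_,
          ifelse(n_neg == 0L, Inf, frac_pos / frac_neg))
  data.frame(band = factor(BAND_LEVELS, levels = BAND_LEVELS,
                           ordered = TRUE),
             n_pos = n_pos, n_neg = n_neg,
             frac_pos = frac_pos, frac_neg = frac_neg,
             odds = odds,
             undefined = n_pos == 0L & n_neg == 0L)
}

#' Select candidate mitoproteins from localization calls
#'
#' Retains proteins whose band is at or above `min_band` (default
#' `very_likely`, i.e. WA >= 0.5), plus explicitly listed overrides —
#' proteins admitted on external evidence (for example direct isolation
#' from purified mitochondria) despite a lower score. Each override
#' carries a free-text reason that is propagated to the output.
#'
#' @param calls Localization calls from [wa_score()].
#' @param min_band Lowest band admitted without an override.
#' @param overrides Optional `data.frame` with columns `protein_id`,
#'   `reason`; every id must have a call.
#' @return A `data.frame` of selected proteins with columns of `calls`
#'   plus `override` (logical) and `override_reason`.
#' @export
select_candidates <- function(calls, min_band = "very_likely",
                              overrides = NULL) {
  min_band <- match.arg(min_band, BAND_LEVELS)
  band <- factor(as.character(calls$band), levels = BAND_LEVELS,
                 ordered = TRUE)
  keep <- band >= min_band
  out <- calls[keep, , drop = FALSE]
  out$override <- rep(FALSE, nrow(out))
  out$override_reason <- rep(NA_character_, nrow(out))
  if (!is.null(overrides) && nrow(overrides) > 0L) {
    stopifnot(all(c("protein_id", "reason") %in% names(overrides)))
    missing <- setdiff(overrides$protein_id, calls$protein_id)
    if (length(missing) > 0L)
      stop("override id(s) absent from calls: ",
           paste(missing, collapse = ", "))
    extra_ids <- setdiff(overrides$protein_id, out$protein_id)
    extra <- calls[match(extra_ids, calls$protein_id), , drop = FALSE]
    if (nrow(extra) > 0L) {
      extra$override <- TRUE
      extra$override_reason <-
        overrides$reason[match(extra_ids, overrides$protein_id)]
      out <- rbind(out, extra)
    }
  }
  rownames(out) <- NULL
  out
}
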