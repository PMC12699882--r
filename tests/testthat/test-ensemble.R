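test_that("WA score follows the weighted-average formula", {
  # weights sum to the divisor: all-ones scores give exactly 1
  row <- predictor_row(s1 = 1, s2 = 1, raw3 = 28)
  expect_equal(wa_score(row)$wa_score, 1.0)
  # hand arithmetic: (2.5*0.8 + 1.5*0.6 + 6*0.9)/10
  row <- predictor_row(s1 = 0.9, s2 = 0.8, raw3 = 0.6 * 28)
  expect_equal(wa_score(row)$wa_score, 0.83)
})

test_that("default-zero rule: both tools unassigned forces WA to 0", {
  row <- predictor_row(s1 = 0.9, a1 = FALSE, s2 = 0.9, a2 = FALSE,
                       raw3 = 20)
  call <- wa_score(row)
  expect_equal(call$wa_score, 0)
  expect_equal(as.character(call$band), "non_mitochondrial")
  expect_false(call$penalized)
})

test_that("secondary-only assignment downgrades WA by the penalty factor", {
  row <- predictor_row(s1 = 0.8, a1 = FALSE, s2 = 0.6, a2 = TRUE,
                       raw3 = 14)
  call <- wa_score(row)
  raw <- (2.5 * 0.6 + 1.5 * 0.5 + 6 * 0.8) / 10
  expect_equal(call$wa_score, 0.25 * raw)
  expect_equal(call$wa_score / raw, 0.25)
  expect_true(call$penalized)
  expect_lt(call$wa_score, 0.25)
})

test_that("band assignment respects the published interval edges", {
  cfg <- ensemble_config()
  expect_equal(as.character(assign_band(0.75, cfg)), "almost_certainly")
  expect_equal(as.character(assign_band(0.4999, cfg)), "likely")
  expect_equal(as.character(assign_band(0, cfg)), "non_mitochondrial")
  expect_equal(as.character(assign_band(0.25, cfg)), "likely")
  expect_equal(as.character(assign_band(0.5, cfg)), "very_likely")
  expect_equal(as.character(assign_band(1, cfg)), "almost_certainly")
  expect_equal(as.character(assign_band(1e-6, cfg)), "low_probability")
  expect_error(assign_band(1.2, cfg), "0, 1")
})

test_that("bands partition [0,1] and WA is monotone in each score", {
  set.seed(11)
  wa <- c(0, 1, runif(200))
  bands <- assign_band(wa)
  expect_false(anyNA(bands))              # every score lands in a band
  expect_equal(length(bands), length(wa)) # exactly one band each

  for (i in 1:30) {
    base <- predictor_row(s1 = runif(1), a1 = sample(c(TRUE, FALSE), 1),
                          s2 = runif(1), a2 = sample(c(TRUE, FALSE), 1),
                          raw3 = runif(1, 0, 28))
    bumped <- base
    field <- sample(c("score_primary", "score_secondary",
                      "score_tertiary"), 1)
    bumped[[field]] <- min(1, bumped[[field]] + runif(1, 0, 0.3))
    expect_gte(wa_score(bumped)$wa_score, wa_score(base)$wa_score)
    expect_true(wa_score(base)$wa_score >= 0 &&
                  wa_score(base)$wa_score <= 1)
  }
})

test_that("ensemble_config validates weight/divisor consistency", {
  expect_error(ensemble_config(weight_primary = 7), "divisor")
  expect_error(ensemble_config(penalty_factor = 1.5))
  expect_error(ensemble_config(band_edges = c(0.5, 0.25, 0.75)))
})

test_that("band odds match a brute-force count and the direct ratio", {
  # 27 positives and 1 negative in a band from equal-size references
  n <- 50
  calls <- data.frame(
    protein_id = c(sprintf("pos%02d", 1:n), sprintf("neg%02d", 1:n)),
    wa_score = c(rep(0.6, 27), rep(0.9, n - 27),
                 rep(0.6, 1), rep(0.1, n - 1)),
    penalized = FALSE, stringsAsFactors = FALSE)
  calls$band <- assign_band(calls$wa_score)
  odds <- calibrate_band_odds(calls, sprintf("pos%02d", 1:n),
                              sprintf("neg%02d", 1:n))
  vl <- odds[odds$band == "very_likely", ]
  expect_equal(vl$odds, 27)
  expect_equal(vl$n_pos, 27L)

  # perfect separation: positives-only band has infinite odds
  ac <- odds[odds$band == "almost_certainly", ]
  expect_equal(ac$odds, Inf)
  # band containing no reference protein is undefined, not fabricated
  lk <- odds[odds$band == "likely", ]
  expect_true(lk$undefined)
  expect_true(is.na(lk$odds))

  # brute-force oracle on random calls
  set.seed(3)
  calls2 <- data.frame(protein_id = sprintf("x%03d", 1:200),
                       wa_score = sample(c(0, runif(199))),
                       penalized = FALSE, stringsAsFactors = FALSE)
  calls2$band <- assign_band(calls2$wa_score)
  pos <- sample(calls2$protein_id, 80)
  neg <- setdiff(calls2$protein_id, pos)[1:80]
  odds2 <- calibrate_band_odds(calls2, pos, neg)
  for (b in levels(calls2$band)) {
    in_band <- calls2$protein_id[as.character(calls2$band) == b]
    fp <- sum(pos %in% in_band) / length(pos)
    fn <- sum(neg %in% in_band) / length(neg)
    expected <- if (fp == 0 && fn == 0) NA_real_
                else if (fn == 0) Inf else fp / fn
    expect_equal(odds2$odds[odds2$band == b], expected)
  }
})

test_that("calibration rejects overlapping or uncovered references", {
  calls <- data.frame(protein_id = c("a", "b"), wa_score = c(0.9, 0.1),
                      penalized = FALSE)
  calls$band <- assign_band(calls$wa_score)
  expect_error(calibrate_band_odds(calls, "a", "a"), "disjoint")
  expect_error(calibrate_band_odds(calls, "a", "zzz"), "without")
})

test_that("candidate selection honors the band floor and overrides", {
  calls <- data.frame(protein_id = c("A", "B", "C"),
                      wa_score = c(0.8, 0.6, 0.3), penalized = FALSE,
                      stringsAsFactors = FALSE)
  calls$band <- assign_band(calls$wa_score)
  sel <- select_candidates(calls)
  expect_setequal(sel$protein_id, c("A", "B"))

  ov <- data.frame(protein_id = "C", reason = "complex pull-down")
  sel2 <- select_candidates(calls, overrides = ov)
  expect_setequal(sel2$protein_id, c("A", "B", "C"))
  expect_true(sel2$override[sel2$protein_id == "C"])
  expect_equal(sel2$override_reason[sel2$protein_id == "C"],
               "complex pull-down")

  expect_equal(nrow(select_candidates(calls[0, ])), 0L)
  expect_error(select_candidates(calls, overrides =
    data.frame(protein_id = "Z", reason = "x")), "absent")
})

test_that("band odds increase with band on class-conditional scores", {
  set.seed(42)
  n_pos <- 469L; n_neg <- 482L
  ids <- c(sprintf("m%04d", 1:n_pos), sprintf("n%04d", 1:n_neg))
  mito <- c(rep(TRUE, n_pos), rep(FALSE, n_neg))
  clamp01 <- function(x) pmin(1, pmax(0, x))
  theta <- ifelse(mito, rbeta(length(mito), 8, 2),
                  rbeta(length(mito), 2, 8))
  s1 <- theta
  s2 <- clamp01(theta + rnorm(length(theta), 0, 0.12))
  s3 <- clamp01(theta + rnorm(length(theta), 0, 0.12))
  tab <- data.frame(protein_id = ids, score_primary = s1,
                    assigned_primary = s1 > 0.5,
                    score_secondary = s2,
                    assigned_secondary = s2 > 0.5,
                    score_tertiary_raw = s3 * 28,
                    score_tertiary = s3, stringsAsFactors = FALSE)
  calls <- wa_score(tab)
  odds <- calibrate_band_odds(calls, ids[mito], ids[!mito])
  o <- odds$odds[match(c("low_probability", "likely", "very_likely",
                         "almost_certainly"),
                       as.character(odds$band))]
  o <- o[!is.na(o)]
  expect_true(all(diff(o) > 0))
})
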