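small_cfg <- function(...) {
  defaults <- list(n_proteins = 120L, n_ppr_proteins = 15L,
                   n_decoy_proteins = 10L, n_cx9c_proteins = 5L,
                   n_ak_proteins = 3L, n_ref_pos = 30L,
                   n_ref_neg = 30L, n_ref_motif_pos = 40L,
                   n_ref_motif_neg = 40L)
  do.call(synth_config, utils::modifyList(defaults, list(...)))
}

test_that("generation is deterministic under a fixed seed", {
  cfg <- small_cfg(seed = 7L)
  d1 <- make_proteome(cfg)
  d2 <- make_proteome(cfg)
  expect_identical(d1$proteins$sequence, d2$proteins$sequence)
  expect_identical(d1$truth$motifs, d2$truth$motifs)

  f1 <- tempfile(); f2 <- tempfile()
  write_fasta(d1$proteins, f1)
  write_fasta(d2$proteins, f2)
  expect_identical(readLines(f1), readLines(f2))

  p1 <- make_predictor_table(cfg, d1$truth, d1$proteins)
  p2 <- make_predictor_table(cfg, d2$truth, d2$proteins)
  expect_identical(p1, p2)

  d3 <- make_proteome(small_cfg(seed = 8L))
  expect_false(identical(d1$proteins$sequence,
                         d3$proteins$sequence))
})

test_that("planted arrays are recorded as ordered disjoint spans", {
  cfg <- small_cfg(motifs_per_array = c(5L, 5L))
  d <- make_proteome(cfg)
  m <- d$truth$motifs[d$truth$motifs$class == "ppr", ]
  for (pid in unique(m$protein_id)) {
    sp <- m[m$protein_id == pid, ]
    expect_equal(nrow(sp), 5L)
    expect_true(all(diff(sp$start) > 0))
    expect_true(all(sp$start[-1] > sp$end[-nrow(sp)]))
    plen <- d$proteins$length[d$proteins$id == pid]
    expect_true(all(sp$end <= plen))
    # planted sequence matches the truth span length
    expect_true(all(sp$end - sp$start + 1L == sp$length))
  }

  none <- make_proteome(small_cfg(n_ppr_proteins = 0L,
                                  n_decoy_proteins = 0L))
  expect_equal(nrow(none$truth$motifs), 0L)
})

test_that("emitted files pass the package validators", {
  dir <- tempfile()
  d <- synth_dataset(small_cfg(), dir)
  pro <- read_fasta(file.path(dir, "proteome.fasta"))
  expect_equal(pro$id, d$proteins$id)
  expect_equal(pro$sequence, d$proteins$sequence)

  pred <- read_predictor_table(file.path(dir, "predictors.tsv"),
                               d$cfg$norm_constant_tertiary)
  expect_equal(pred$protein_id, d$predictors$protein_id)
  expect_equal(pred$score_tertiary, d$predictors$score_tertiary,
               tolerance = 1e-6)

  hits <- read_domtblout(file.path(dir, "hits.domtblout"))
  expect_equal(nrow(hits), nrow(d$hits))
  expect_equal(hits$env_start, d$hits$env_start)

  q <- read_quant_table(file.path(dir, "quant.tsv"))
  expect_equal(nrow(q), nrow(d$quants))
  tr <- read_structure_table(file.path(dir, "structures.tsv"), pro)
  expect_equal(nrow(tr), nrow(pro))
})

test_that("hit omission bookkeeping matches the planted truth", {
  cfg <- small_cfg(hit_omission_rate = 0.2,
                   motifs_per_array = c(10L, 10L))
  d <- synth_dataset(cfg)
  n_true <- sum(d$truth$motifs$class == "ppr")
  n_decoy <- sum(d$truth$motifs$class == "decoy")
  expect_equal(nrow(d$hits) + nrow(d$omitted), n_true + n_decoy)
  # omitted motifs are interior: never the first or last of an array
  for (i in seq_len(nrow(d$omitted))) {
    arr <- d$truth$motifs[
      d$truth$motifs$protein_id == d$omitted$protein_id[i], ]
    expect_gt(d$omitted$start[i], min(arr$start))
    expect_lt(d$omitted$start[i], max(arr$start))
  }
})

test_that("structure labels obey the noise dial", {
  cfg0 <- small_cfg(structure_noise = 0)
  d0 <- synth_dataset(cfg0)
  tr <- setNames(d0$tracks$labels, d0$tracks$protein_id)
  m <- d0$truth$motifs[d0$truth$motifs$class == "ppr", ]
  ok <- vapply(seq_len(nrow(m)), function(i)
    validate_structure(tr[[m$protein_id[i]]], m$start[i],
                       m$length[i])$structure_valid, logical(1))
  expect_true(all(ok))  # noise-free labels all validate

  # decoy repeats never validate (helix without the 11-13 turn)
  md <- d0$truth$motifs[d0$truth$motifs$class == "decoy", ]
  okd <- vapply(seq_len(nrow(md)), function(i)
    validate_structure(tr[[md$protein_id[i]]], md$start[i],
                       md$length[i])$structure_valid, logical(1))
  expect_false(any(okd))

  cfg1 <- small_cfg(structure_noise = 1)
  d1 <- synth_dataset(cfg1)
  tr1 <- setNames(d1$tracks$labels, d1$tracks$protein_id)
  ok1 <- vapply(seq_len(nrow(m)), function(i)
    validate_structure(tr1[[m$protein_id[i]]], m$start[i],
                       m$length[i])$structure_valid, logical(1))
  # fully randomized labels almost never satisfy the criteria
  expect_lt(mean(ok1), 0.05)
})

test_that("an all-non-mitochondrial proteome concentrates WA at 0", {
  cfg <- synth_config(n_proteins = 1000L, fraction_mito = 0,
                      n_ppr_proteins = 0L, n_decoy_proteins = 0L,
                      n_cx9c_proteins = 0L, n_ak_proteins = 0L,
                      seed = 11L)
  d <- make_proteome(cfg)
  pred <- make_predictor_table(cfg, d$truth, d$proteins)
  calls <- wa_score(pred)
  expect_gt(mean(calls$wa_score == 0), 0.9)
  expect_lt(mean(calls$wa_score), 0.02)
})

test_that("planted MS enrichment follows its dials", {
  # unit enrichment factors: nothing is detected
  cfg_flat <- small_cfg(enrich_factor_mito = 1, enrich_factor_cyto = 1,
                        enriched_fraction = 0, quant_noise = 0)
  d <- synth_dataset(cfg_flat)
  calls <- enrichment_calls(d$quants)
  expect_false(any(calls$detected))

  # noise-free defaults: detection recovers the planted labels exactly
  cfg0 <- small_cfg(quant_noise = 0)
  d0 <- synth_dataset(cfg0)
  calls0 <- enrichment_calls(d0$quants)
  det <- calls0$protein_id[calls0$detected]
  expect_true(all(d0$enriched_ids %in% det))
  expect_true(all(det %in% d0$enriched_ids))
})

test_that("planted Cx9C and AK-rich proteins are recovered by screens", {
  d <- make_proteome(small_cfg())
  cx_found <- vapply(seq_len(nrow(d$proteins)), function(i)
    nrow(scan_cx9c(d$proteins$sequence[i])$motifs) >= 2L, logical(1))
  expect_true(all(d$truth$cx9c_ids %in% d$proteins$id[cx_found]))
  ak_found <- vapply(seq_len(nrow(d$proteins)), function(i)
    ak_composition_screen(d$proteins$sequence[i])$flagged, logical(1))
  expect_setequal(d$proteins$id[ak_found], d$truth$ak_ids)
})
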