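make_ref <- function(pos, neg) list(positive = pos, negative = neg)

span_df <- function(id, start, end)
  data.frame(protein_id = id, start = start, end = end,
             stringsAsFactors = FALSE)

hit_df <- function(id, s, e, iev)
  data.frame(protein_id = id, profile_name = "prof", env_start = s,
             env_end = e, i_evalue = iev, bit_score = 1,
             stringsAsFactors = FALSE)

test_that("hits are labeled by overlap with the motif reference", {
  ref <- make_ref(span_df("p", 12L, 46L), span_df("p", 200L, 234L))
  # overlap 33 of the shorter 35-mer: TP candidate
  lab <- match_hits_to_reference(hit_df("p", 10L, 44L, 1), ref)
  expect_equal(lab$label, "TP")
  # no overlap with either list: unlabeled
  lab <- match_hits_to_reference(hit_df("p", 100L, 134L, 1), ref)
  expect_true(is.na(lab$label))
  # exact match to a negative span: FP candidate
  lab <- match_hits_to_reference(hit_df("p", 200L, 234L, 1), ref)
  expect_equal(lab$label, "FP")
  # below the overlap floor: unlabeled
  lab <- match_hits_to_reference(hit_df("p", 30L, 64L, 1), ref)
  expect_true(is.na(lab$label))
})

test_that("precision/recall/F1 follow the printed formulas", {
  expect_equal(unlist(precision_recall_f1(79, 0, 0)),
               c(precision = 1, recall = 1, f1 = 1))
  res <- precision_recall_f1(60, 20, 20)
  expect_equal(res$f1, 0.75)      # 60 / (60 + 0.5*40)
  expect_equal(res$precision, 0.75)
  res0 <- precision_recall_f1(0, 0, 0)
  expect_true(all(is.na(unlist(res0))))   # undefined, not zero
  expect_error(precision_recall_f1(-1, 0, 0), "non-negative")

  # harmonic-mean identity F1 = 2PR/(P+R)
  set.seed(13)
  for (i in 1:50) {
    tp <- sample(1:100, 1); fp <- sample(0:50, 1); fn <- sample(0:50, 1)
    r <- precision_recall_f1(tp, fp, fn)
    expect_equal(r$f1, 2 * r$precision * r$recall /
                         (r$precision + r$recall))
  }
})

test_that("threshold selection picks the largest separating value", {
  pos <- span_df(sprintf("p%02d", 1:5), 1L, 35L)
  neg <- span_df(sprintf("n%02d", 1:5), 1L, 35L)
  ref <- make_ref(pos, neg)
  hits <- rbind(hit_df(pos$protein_id, 1L, 35L, c(0.5, 1, 2, 3, 4.9)),
                hit_df(neg$protein_id, 1L, 35L, c(110, 200, 3e3, 1e4,
                                                  1e5)))
  lab <- match_hits_to_reference(hits, ref)
  cal <- select_threshold(lab, ref,
                          thresholds = c(1, 5, 8.6, 50, 200))
  expect_equal(cal$selected_threshold, 50)
  expect_true(cal$perfect_separation)
  i <- match(50, cal$table$threshold)
  expect_equal(cal$table$TP[i], 5L)
  expect_equal(cal$table$FP[i], 0L)

  # default grid: a single positive below a single negative selects a
  # threshold strictly between them
  ref1 <- make_ref(span_df("a", 1L, 35L), span_df("b", 1L, 35L))
  lab1 <- match_hits_to_reference(
    rbind(hit_df("a", 1L, 35L, 1), hit_df("b", 1L, 35L, 10)), ref1)
  cal1 <- select_threshold(lab1, ref1)
  expect_gt(cal1$selected_threshold, 1)
  expect_lt(cal1$selected_threshold, 10)
})

test_that("inseparable scores fall back to the max-F1 threshold", {
  set.seed(31)
  n <- 40
  pos <- span_df(sprintf("p%02d", 1:n), 1L, 35L)
  neg <- span_df(sprintf("n%02d", 1:n), 1L, 35L)
  ref <- make_ref(pos, neg)
  hits <- rbind(hit_df(pos$protein_id, 1L, 35L, 10^runif(n, -6, 1)),
                hit_df(neg$protein_id, 1L, 35L, 10^runif(n, -2, 4)))
  lab <- match_hits_to_reference(hits, ref)
  cal <- select_threshold(lab, ref)
  expect_false(cal$perfect_separation)

  # exhaustive-sweep oracle over the same candidate set
  oracle_best <- -Inf; oracle_t <- NA
  for (t in cal$table$threshold) {
    tp <- sum(lab$label %in% "TP" & lab$i_evalue < t)
    fp <- sum(lab$label %in% "FP" & lab$i_evalue < t)
    fn <- n - tp
    f1 <- if (tp + 0.5 * (fp + fn) > 0) tp / (tp + 0.5 * (fp + fn))
          else NA
    if (!is.na(f1) && (f1 > oracle_best ||
                       (f1 == oracle_best && t > oracle_t))) {
      oracle_best <- f1; oracle_t <- t
    }
  }
  expect_equal(cal$selected_threshold, oracle_t)
  i <- match(cal$selected_threshold, cal$table$threshold)
  expect_equal(cal$table$f1[i], oracle_best)
})

test_that("TP and FP counts are monotone in the threshold", {
  set.seed(17)
  n <- 30
  pos <- span_df(sprintf("p%02d", 1:n), 1L, 35L)
  neg <- span_df(sprintf("n%02d", 1:n), 1L, 35L)
  ref <- make_ref(pos, neg)
  hits <- rbind(hit_df(pos$protein_id, 1L, 35L, 10^runif(n, -8, 2)),
                hit_df(neg$protein_id, 1L, 35L, 10^runif(n, -1, 5)))
  lab <- match_hits_to_reference(hits, ref)
  cal <- select_threshold(lab, ref)
  expect_true(all(diff(cal$table$TP) >= 0))
  expect_true(all(diff(cal$table$FP) >= 0))
})

test_that("gap candidates are emitted with flanks and clipped", {
  # motifs ending at 100 and starting at 136: gap 35, region 91..145
  m <- span_df("p", c(66L, 136L), c(100L, 170L))
  res <- find_gap_candidates(m, c(p = 200L))
  expect_equal(res$start, 91L)
  expect_equal(res$end, 145L)
  expect_equal(res$gap_length, 35L)

  # gap of 29 is below the window
  m29 <- span_df("p", c(66L, 130L), c(100L, 164L))
  expect_equal(nrow(find_gap_candidates(m29, c(p = 200L))), 0L)
  # a single motif has no flanked gap
  expect_equal(nrow(find_gap_candidates(span_df("p", 50L, 84L),
                                        c(p = 200L))), 0L)
  # flanked region around a gap at the start of a short protein
  m_edge <- span_df("p", c(2L, 68L), c(32L, 100L))
  res_edge <- find_gap_candidates(m_edge, c(p = 105L))
  expect_equal(res_edge$start, 23L)
  expect_equal(res_edge$end, 77L)
  expect_error(find_gap_candidates(span_df("p", c(10L, 30L),
                                           c(44L, 64L)),
                                   c(p = 100L)), "overlap")
})

test_that("gap regions stay in bounds and near their gap", {
  set.seed(19)
  for (i in 1:20) {
    k <- sample(2:6, 1)
    lens <- sample(31:40, k, replace = TRUE)
    gaps <- sample(20:50, k - 1, replace = TRUE)
    starts <- integer(k)
    starts[1] <- sample(1:30, 1)
    for (j in seq_len(k - 1))
      starts[j + 1] <- starts[j] + lens[j] + gaps[j]
    ends <- starts + lens - 1L
    plen <- max(ends) + sample(0:30, 1)
    m <- span_df("p", as.integer(starts), as.integer(ends))
    res <- find_gap_candidates(m, c(p = as.integer(plen)))
    if (nrow(res) == 0L) next
    expect_true(all(res$start >= 1L & res$end <= plen))
    expect_true(all(res$start >= res$gap_start - 10L))
    expect_true(all(res$end <= res$gap_end + 10L))
    expect_true(all(res$gap_length >= 30L & res$gap_length <= 40L))
  }
})

test_that("structure validation enforces helix-turn-helix criteria", {
  # 10 helix, 3 turn, 18 helix: valid 31-mer
  tr <- paste0(strrep("H", 10), "TTT", strrep("H", 18))
  v <- validate_structure(tr, 1L, 31L)
  expect_true(v$structure_valid)
  expect_equal(v$helixA_count, 10L)
  expect_equal(v$helixB_count, 18L)

  # helix A with only 6 helix-forming residues fails
  tr2 <- paste0(strrep("H", 6), strrep("C", 4), "TTT", strrep("H", 18))
  expect_false(validate_structure(tr2, 1L, 31L)$structure_valid)

  # turn at positions 12-14 instead of 11-13 fails
  tr3 <- paste0(strrep("H", 11), "TTT", strrep("H", 17))
  expect_false(validate_structure(tr3, 1L, 31L)$turn_ok)

  # G and I count as helix-forming; non-helical residues permitted
  tr4 <- paste0("GGGIIHHHCC", "TTT", strrep("G", 10), strrep("C", 8))
  expect_true(validate_structure(tr4, 1L, 31L)$structure_valid)

  expect_error(validate_structure(tr, 5L, 31L), "exceeds")
  expect_error(validate_structure(tr, 1L, 30L))
})

test_that("validation ignores labels outside the candidate span", {
  core <- paste0(strrep("H", 10), "TTT", strrep("H", 22))
  for (pad in c("CCCC", "EEEE", "TTTT")) {
    tr <- paste0(pad, core, pad)
    expect_true(validate_structure(tr, 5L, 35L)$structure_valid)
  }
})

test_that("profiles use Laplace pseudocounts and length merging", {
  m <- strrep("A", 35)
  prof <- build_profile(c(m, m))
  expect_equal(prof$length, 35L)
  expect_equal(prof$consensus, m)
  # (n + alpha) / (n + 20 alpha) with n = 2
  expect_equal(unname(prof$prob["A", 1]), 2.5 / 12)
  expect_equal(unname(prof$prob["W", 1]), 0.5 / 12)
  expect_equal(colSums(prof$prob), rep(1, 35), ignore_attr = TRUE)

  # 31- and 35-residue classes merge on the longer coordinates
  prof2 <- build_profile(c(strrep("L", 31), strrep("L", 35)))
  expect_equal(prof2$length, 35L)
  # padded tail columns have a single observation
  expect_equal(unname(prof2$prob["L", 35]), 1.5 / 11)

  expect_error(build_profile(strrep("A", 35)), "two")
  expect_error(build_profile(c(strrep("A", 30), strrep("A", 35))),
               "31")
})

test_that("profile alignments export to FASTA and Stockholm", {
  prof <- build_profile(c(strrep("A", 35), strrep("C", 31)))
  fa <- tempfile(); st <- tempfile()
  write_profile_alignment(prof, fa, "fasta")
  lines <- readLines(fa)
  expect_equal(sum(grepl("^>", lines)), 2L)
  expect_true(any(grepl("----$", lines)))
  write_profile_alignment(prof, st, "stockholm")
  sl <- readLines(st)
  expect_equal(sl[1], "# STOCKHOLM 1.0")
  expect_equal(sl[length(sl)], "//")
})

test_that("the profile scanner ranks the consensus window highest", {
  set.seed(3)
  motifs <- vapply(1:6, function(i) {
    ch <- strsplit(mitoscope:::PPR_CONSENSUS_35, "")[[1]]
    mut <- sample(35, 3)
    ch[mut] <- sample(c("A", "G", "S"), 3, replace = TRUE)
    paste(ch, collapse = "")
  }, character(1))
  prof <- build_profile(motifs)
  bg <- paste(sample(mitoscope:::AA_STANDARD, 150, replace = TRUE),
              collapse = "")
  target <- paste0(substr(bg, 1, 60), prof$consensus,
                   substr(bg, 61, 150))
  pro <- data.frame(id = "t1", sequence = target,
                    length = nchar(target))
  hits <- scan_with_profile(prof, pro, null_decoys = 20, seed = 1)
  expect_gte(nrow(hits), 1L)
  best <- hits[which.max(hits$bit_score), ]
  expect_equal(best$env_start, 61L)
  expect_equal(best$i_evalue, min(hits$i_evalue))

  # empty proteome gives an empty hit table
  expect_equal(nrow(scan_with_profile(prof, pro[0, ],
                                      null_decoys = 5)), 0L)
  # a protein shorter than the profile is skipped, not an error
  short <- data.frame(id = "s", sequence = "MKR", length = 3L)
  expect_equal(nrow(scan_with_profile(prof, short,
                                      null_decoys = 5)), 0L)
})
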