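# Fixed motif consensus sequences used by the generator. The 35-mer is
# a canonical P-type-repeat-like helix-turn-helix consensus (cysteine
# avoided so the Cx9C screen stays independent); the 31-mer is its
# short length class.
PPR_CONSENSUS_35 <- "VTYNTLISGLAKAGKLDEALELFREMKEKGIEPDV"
PPR_CONSENSUS_31 <- substr(PPR_CONSENSUS_35, 1L, 31L)

#' Configuration for the synthetic-data generator
#'
#' Defines the statistical structure of every generated input: the
#' class-conditional predictor score distributions (Beta(8, 2) for
#' mitochondrial, Beta(2, 8) for non-mitochondrial proteins), planted
#' PPR arrays of 2–11 tandem repeats per protein, separable i-E-value
#' supports for true motifs (log-uniform on \[1e-30, 1e-3\]) versus
#' decoy repeats (log-uniform on \[1e2, 1e6\]), twin-Cx9C proteins with
#' spacers drawn from the observed 5–38 range, AK-rich proteins,
#' noisy 8-state structure labels, and fraction-wise MS quantities with
#' 5x mitochondrial / 0.2x cytosolic enrichment factors. Reference-set
#' sizes default to the curated sets' sizes (469/482 proteins,
#' 79/1457 motifs). All randomness flows from `seed`.
#'
#' @param n_proteins Total proteome size.
#' @param fraction_mito Fraction of proteins labeled mitochondrial.
#' @param n_ppr_proteins,n_decoy_proteins,n_cx9c_proteins,n_ak_proteins
#'   Planted protein counts per class.
#' @param motifs_per_array Inclusive range of repeats per planted
#'   array.
#' @param mutation_rate Per-position probability of mutating the motif
#'   consensus in a planted repeat.
#' @param assignment_cutoff Predictor score above which a tool
#'   "assigns" the protein to the mitochondrion.
#' @param norm_constant_tertiary Scale of the raw tertiary score.
#' @param true_log10_evalue,decoy_log10_evalue Log10 supports of the
#'   i-E-value distributions.
#' @param hit_omission_rate Fraction of interior true motifs omitted
#'   from the hit table (gap-rescue targets).
#' @param structure_noise Per-residue probability of randomizing a
#'   structure label.
#' @param enrich_factor_mito,enrich_factor_cyto MS enrichment factors
#'   relative to the whole-cell quantity.
#' @param enriched_fraction Fraction of mitochondrial proteins planted
#'   as enriched.
#' @param absent_whole_fraction Fraction of proteins zeroed in the
#'   whole-cell fraction (exercises the floor rule).
#' @param quant_noise Relative noise on MS quantities.
#' @param n_ref_pos,n_ref_neg Protein-level reference sizes.
#' @param n_ref_motif_pos,n_ref_motif_neg Motif-level reference sizes
#'   (clamped to the number of planted motifs available).
#' @param seed Integer seed.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_proteins = 1200L, fraction_mito = 0.45,
                         n_ppr_proteins = 50L, n_decoy_proteins = 30L,
                         n_cx9c_proteins = 10L, n_ak_proteins = 5L,
                         motifs_per_array = c(2L, 11L),
                         mutation_rate = 0.1,
                         assignment_cutoff = 0.5,
                         norm_constant_tertiary = 28,
                         true_log10_evalue = c(-30, -3),
                         decoy_log10_evalue = c(2, 6),
                         hit_omission_rate = 0.15,
                         structure_noise = 0.05,
                         enrich_factor_mito = 5,
                         enrich_factor_cyto = 0.2,
                         enriched_fraction = 0.7,
                         absent_whole_fraction = 0.1,
                         quant_noise = 0.05,
                         n_ref_pos = 469L, n_ref_neg = 482L,
                         n_ref_motif_pos = 79L,
                         n_ref_motif_neg = 1457L,
                         seed = 42L) {
  cfg <- as.list(environment())
  stopifnot(n_proteins >= n_ppr_proteins + n_decoy_proteins +
              n_cx9c_proteins + n_ak_proteins,
            fraction_mito >= 0, fraction_mito <= 1,
            mutation_rate >= 0, mutation_rate < 1,
            structure_noise >= 0, structure_noise <= 1,
            hit_omission_rate >= 0, hit_omission_rate < 1,
            motifs_per_array[1L] >= 1L,
            diff(motifs_per_array) >= 0,
            seed == as.integer(seed))
  class(cfg) <- "synth_config"
  cfg
}

# sample() treats a length-1 numeric as 1:x; this helper never does
pick1 <- function(x) if (length(x) == 1L) x else sample(x, 1L)

random_residues <- function(n, exclude = NULL) {
  pool <- setdiff(AA_STANDARD, exclude)
  paste(sample(pool, n, replace = TRUE), collapse = "")
}

mutate_motif <- function(consensus, rate) {
  chars <- strsplit(consensus, "")[[1L]]
  hit <- runif(length(chars)) < rate
  chars[hit] <- sample(AA_STANDARD, sum(hit), replace = TRUE)
  paste(chars, collapse = "")
}

# Column-shuffled decoy consensus: same composition per column set,
# scrambled order, so decoys resemble the true repeat in composition
# but not position.
decoy_consensus <- function() {
  chars <- strsplit(PPR_CONSENSUS_35, "")[[1L]]
  perm <- c(18L, 3L, 29L, 11L, 25L, 7L, 33L, 1L, 21L, 14L, 30L, 5L,
            26L, 9L, 35L, 2L, 19L, 12L, 31L, 6L, 27L, 10L, 22L, 15L,
            34L, 4L, 20L, 13L, 32L, 8L, 28L, 16L, 23L, 17L, 24L)
  paste(chars[perm], collapse = "")
}

#' Generate a synthetic proteome with planted ground truth
#'
#' Builds a proteome of random-background proteins into which are
#' planted: tandem PPR arrays (mutated copies of a 35- or 31-residue
#' consensus), decoy repeat arrays (column-shuffled consensus, the
#' TPR/Ankyrin stand-ins), twin-Cx9C proteins with spacers in the
#' observed 5–38 range, and AK-rich proteins with > 60% Ala+Lys.
#' Mitochondrial labels cover all planted PPR/Cx9C/AK proteins and a
#' random complement reaching `fraction_mito`.
#'
#' @param cfg A [synth_config()].
#' @return A list: `proteins` (`data.frame` as from [read_fasta()]),
#'   `truth` (list with `mito_ids`, `motifs` — per-motif spans and
#'   class —, `ppr_protein_ids`, `decoy_protein_ids`, `cx9c_ids`,
#'   `ak_ids`).
#' @export
make_proteome <- function(cfg = synth_config()) {
  set.seed(cfg$seed)
  n <- cfg$n_proteins
  ids <- sprintf("SYNP_%05d", seq_len(n))
  classes <- rep("background", n)
  i <- 1L
  assign_class <- function(classes, label, k) {
    if (k > 0L) classes[i:(i + k - 1L)] <- label
    classes
  }
  classes <- assign_class(classes, "ppr", cfg$n_ppr_proteins)
  i <- i + cfg$n_ppr_proteins
  classes <- assign_class(classes, "decoy", cfg$n_decoy_proteins)
  i <- i + cfg$n_decoy_proteins
  classes <- assign_class(classes, "cx9c", cfg$n_cx9c_proteins)
  i <- i + cfg$n_cx9c_proteins
  classes <- assign_class(classes, "ak", cfg$n_ak_proteins)

  dec_cons <- decoy_consensus()
  seqs <- character(n)
  motif_rows <- list()
  cx_spans <- list()
  for (j in seq_len(n)) {
    cls <- classes[j]
    if (cls %in% c("ppr", "decoy")) {
      k <- pick1(seq(cfg$motifs_per_array[1L],
                     cfg$motifs_per_array[2L]))
      n_flank <- sample(30:80, 2L, replace = TRUE)
      lens <- sample(c(35L, 31L), k, replace = TRUE,
                     prob = c(0.8, 0.2))
      motifs <- vapply(lens, function(L) {
        cons <- if (cls == "ppr") {
          if (L == 35L) PPR_CONSENSUS_35 else PPR_CONSENSUS_31
        } else {
          if (L == 35L) dec_cons else substr(dec_cons, 1L, 31L)
        }
        mutate_motif(cons, cfg$mutation_rate)
      }, character(1))
      seqs[j] <- paste0(random_residues(n_flank[1L]),
                        paste(motifs, collapse = ""),
                        random_residues(n_flank[2L]))
      starts <- n_flank[1L] + cumsum(c(0L, lens[-k])) + 1L
      motif_rows[[j]] <- data.frame(
        protein_id = ids[j], start = starts,
        end = starts + lens - 1L, length = lens, class = cls,
        stringsAsFactors = FALSE)
    } else if (cls == "cx9c") {
      k <- sample(2:4, 1L)
      spacers <- sample(5:38, k - 1L, replace = TRUE)
      parts <- character(0)
      for (m in seq_len(k)) {
        parts <- c(parts,
                   paste0("C", random_residues(9L, exclude = "C"),
                          "C"))
        if (m < k)
          parts <- c(parts,
                     random_residues(spacers[m], exclude = "C"))
      }
      seqs[j] <- paste0(random_residues(sample(20:60, 1L),
                                        exclude = "C"),
                        paste(parts, collapse = ""),
                        random_residues(sample(20:60, 1L),
                                        exclude = "C"))
      cx_spans[[j]] <- ids[j]
    } else if (cls == "ak") {
      L <- sample(120:250, 1L)
      res <- sample(AA_STANDARD, L, replace = TRUE,
                    prob = ifelse(AA_STANDARD == "A", 10,
                           ifelse(AA_STANDARD == "K", 7, 0.4)))
      seqs[j] <- paste(res, collapse = "")
    } else {
      L <- round(rlnorm(1L, meanlog = log(300), sdlog = 0.35))
      L <- min(max(L, 80L), 900L)
      seqs[j] <- random_residues(L)
    }
  }

  planted_mito <- classes %in% c("ppr", "cx9c", "ak")
  target <- round(cfg$fraction_mito * n)
  extra_needed <- max(0L, target - sum(planted_mito))
  candidates <- which(!planted_mito)
  mito <- planted_mito
  if (extra_needed > 0L && length(candidates) > 0L)
    mito[sample(candidates, min(extra_needed,
                                length(candidates)))] <- TRUE

  motifs <- if (length(motif_rows) > 0L)
    do.call(rbind, motif_rows[!vapply(motif_rows, is.null,
                                      logical(1))])
  else data.frame(protein_id = character(), start = integer(),
                  end = integer(), length = integer(),
                  class = character(), stringsAsFactors = FALSE)
  rownames(motifs) <- NULL

  list(proteins = data.frame(id = ids, sequence = seqs,
                             length = nchar(seqs),
                             stringsAsFactors = FALSE),
       truth = list(mito_ids = ids[mito],
                    motifs = motifs,
                    ppr_protein_ids = ids[classes == "ppr"],
                    decoy_protein_ids = ids[classes == "decoy"],
                    cx9c_ids = unlist(cx_spans),
                    ak_ids = ids[classes == "ak"]))
}

#' Generate a class-conditional predictor score table
#'
#' Each protein receives a latent mitochondrial propensity drawn from
#' the class-conditional distribution — Beta(8, 2) for mitochondrial
#' proteins, Beta(2, 8) otherwise. The primary predictor reports the
#' propensity itself; the secondary and tertiary report noisy copies
#' (the tertiary scaled by the norm constant), so the three tools
#' agree on a protein up to observation noise, as real predictors do.
#' Each tool's assignment flag follows the `assignment_cutoff` rule
#' (score > cutoff).
#'
#' @param cfg A [synth_config()].
#' @param truth Ground truth from [make_proteome()].
#' @param proteins Protein table from [make_proteome()].
#' @return A predictor `data.frame` including the normalized
#'   `score_tertiary` column (as [read_predictor_table()] would add).
#' @export
make_predictor_table <- function(cfg, truth, proteins) {
  set.seed(cfg$seed + 1L)
  n <- nrow(proteins)
  is_mito <- proteins$id %in% truth$mito_ids
  clamp01 <- function(x) pmin(1, pmax(0, x))
  theta <- numeric(n)
  theta[is_mito] <- rbeta(sum(is_mito), 8, 2)
  theta[!is_mito] <- rbeta(sum(!is_mito), 2, 8)
  s1 <- theta
  s2 <- clamp01(theta + rnorm(n, 0, 0.12))
  s3 <- clamp01(theta + rnorm(n, 0, 0.12))
  raw3 <- pmax(0, s3 * cfg$norm_constant_tertiary +
                 rnorm(n, 0, 0.02 * cfg$norm_constant_tertiary))
  data.frame(protein_id = proteins$id,
             score_primary = s1,
             assigned_primary = s1 > cfg$assignment_cutoff,
             score_secondary = s2,
             assigned_secondary = s2 > cfg$assignment_cutoff,
             score_tertiary_raw = raw3,
             score_tertiary = pmin(1, raw3 /
                                     cfg$norm_constant_tertiary),
             stringsAsFactors = FALSE)
}

ppr_structure_pattern <- function(len) {
  paste0(strrep("H", 10L), "TTT", strrep("H", len - 13L))
}

#' Generate domain hits and structure tracks for planted motifs
#'
#' True planted motifs receive hits with i-E-values drawn log-uniform
#' from the true-class support; decoy repeats receive decoy-class
#' values — the separable two-population structure the threshold
#' calibration assumes. A configurable fraction of interior true
#' motifs is omitted from the hit table but keeps valid structure
#' labels: these are the gap-rescue targets. Structure tracks label
#' true motifs with the canonical helix–turn–helix pattern (10 helix,
#' 3 turn, helix to the end), decoy motifs with an uninterrupted helix
#' (no turn, so they fail validation), and the background with
#' coil-biased labels; per-residue noise then randomizes labels at the
#' configured rate.
#'
#' @param cfg A [synth_config()].
#' @param truth,proteins From [make_proteome()].
#' @return A list: `hits` (domain-hit `data.frame`), `tracks`
#'   (structure `data.frame`), `omitted` (truth motifs left out of the
#'   hit table).
#' @export
make_hits_and_structs <- function(cfg, truth, proteins) {
  set.seed(cfg$seed + 2L)
  motifs <- truth$motifs

  # omit interior true motifs (those with a neighbour on both sides)
  omit <- rep(FALSE, nrow(motifs))
  if (nrow(motifs) > 0L) {
    for (pid in unique(motifs$protein_id[motifs$class == "ppr"])) {
      rows <- which(motifs$protein_id == pid)
      if (length(rows) >= 3L) {
        interior <- rows[-c(1L, length(rows))]
        omit[interior] <- runif(length(interior)) <
          cfg$hit_omission_rate
      }
    }
  }
  hit_rows <- motifs[!omit, , drop = FALSE]
  n_hit <- nrow(hit_rows)
  is_true <- hit_rows$class == "ppr"
  lg <- numeric(n_hit)
  lg[is_true] <- runif(sum(is_true), cfg$true_log10_evalue[1L],
                       cfg$true_log10_evalue[2L])
  lg[!is_true] <- runif(sum(!is_true), cfg$decoy_log10_evalue[1L],
                        cfg$decoy_log10_evalue[2L])
  hits <- data.frame(protein_id = hit_rows$protein_id,
                     profile_name = "plantPPR_P",
                     env_start = hit_rows$start,
                     env_end = hit_rows$end,
                     i_evalue = 10^lg,
                     bit_score = -lg * 2 + rnorm(n_hit, 0, 0.5),
                     stringsAsFactors = FALSE)
  hits <- hits[order(hits$protein_id, hits$env_start), , drop = FALSE]
  rownames(hits) <- NULL

  # structure tracks
  bg_states <- c("C", "S", "E", "T", "B")
  bg_probs <- c(0.5, 0.2, 0.15, 0.1, 0.05)
  tracks <- vapply(seq_len(nrow(proteins)), function(j) {
    L <- proteins$length[j]
    lab <- sample(bg_states, L, replace = TRUE, prob = bg_probs)
    m <- motifs[motifs$protein_id == proteins$id[j], , drop = FALSE]
    if (nrow(m) > 0L) {
      for (r in seq_len(nrow(m))) {
        pat <- if (m$class[r] == "ppr")
          ppr_structure_pattern(m$length[r])
        else strrep("H", m$length[r])
        lab[m$start[r]:m$end[r]] <- strsplit(pat, "")[[1L]]
      }
    }
    noisy <- runif(L) < cfg$structure_noise
    lab[noisy] <- sample(SS8_ALPHABET, sum(noisy), replace = TRUE)
    paste(lab, collapse = "")
  }, character(1))

  list(hits = hits,
       tracks = data.frame(protein_id = proteins$id, labels = tracks,
                           stringsAsFactors = FALSE),
       omitted = motifs[omit, , drop = FALSE])
}

#' Generate an MS quantification table with planted enrichment
#'
#' Enriched proteins (a configurable fraction of the mitochondrial
#' ones) receive mitochondrial quantities `enrich_factor_mito` times
#' and cytosolic quantities `enrich_factor_cyto` times their
#' whole-cell level; all other proteins are flat across fractions up
#' to multiplicative noise. A configurable fraction of the enriched
#' proteins is zeroed in the whole-cell fraction (proteins detectable
#' only after organellar enrichment), exercising the floor rule; a few
#' enriched proteins are flagged as complex-dataset members.
#'
#' @param cfg A [synth_config()].
#' @param truth,proteins From [make_proteome()].
#' @return A list: `quants` (table as from [read_quant_table()]),
#'   `enriched_ids` (planted truth).
#' @export
make_quant_table <- function(cfg, truth, proteins) {
  set.seed(cfg$seed + 3L)
  n <- nrow(proteins)
  mito <- proteins$id %in% truth$mito_ids
  enriched <- mito & runif(n) < cfg$enriched_fraction
  noise <- function(k) exp(rnorm(k, 0, cfg$quant_noise))

  base_sc <- rpois(n, 20) + 1L
  base_int <- rlnorm(n, meanlog = log(1e6), sdlog = 0.8)
  base_int <- pmax(base_int, 4e4)

  f_mito <- ifelse(enriched, cfg$enrich_factor_mito, 1)
  f_cyto <- ifelse(enriched, cfg$enrich_factor_cyto, 1)
  sc_mito <- round(base_sc * f_mito * noise(n))
  sc_cyto <- round(base_sc * f_cyto * noise(n))
  int_mito <- base_int * f_mito * noise(n)
  int_cyto <- base_int * f_cyto * noise(n)

  # proteins below detection in the whole-cell lysate are the ones
  # only visible after organellar enrichment
  absent <- enriched & runif(n) < cfg$absent_whole_fraction
  sc_whole <- ifelse(absent, 0L, base_sc)
  int_whole <- ifelse(absent, 0, base_int)

  in_complex <- rep(FALSE, n)
  pool <- which(enriched)
  if (length(pool) > 0L)
    in_complex[sample(pool, max(1L, round(0.05 * length(pool))))] <-
      TRUE

  list(quants = data.frame(protein_id = proteins$id,
                           sc_whole_cell = as.integer(sc_whole),
                           sc_cytosol = as.integer(sc_cyto),
                           sc_mitochondria = as.integer(sc_mito),
                           int_whole_cell = int_whole,
                           int_cytosol = int_cyto,
                           int_mitochondria = int_mito,
                           in_complex_datasets = in_complex,
                           stringsAsFactors = FALSE),
       enriched_ids = proteins$id[enriched])
}

#' Sample protein- and motif-level reference sets from the truth
#'
#' Protein-level positives/negatives are sampled from the planted
#' mitochondrial labels (default sizes 469/482); motif-level
#' positives/negatives from the planted true/decoy repeat spans
#' (default sizes 79/1457, clamped to availability). When the hit
#' table is supplied, positive motifs are sampled only from motifs
#' present in it — matching how a curated motif reference is built
#' from motifs a profile search can actually retrieve; motifs omitted
#' from the hit table are gap-rescue targets, not reference material.
#'
#' @param cfg A [synth_config()].
#' @param truth,proteins From [make_proteome()].
#' @param hits Optional hit table from [make_hits_and_structs()].
#' @return A list: `protein` (list `positives`, `negatives` of ids),
#'   `motif` (list `positive`, `negative` span tables).
#' @export
make_reference <- function(cfg, truth, proteins, hits = NULL) {
  set.seed(cfg$seed + 4L)
  mito <- proteins$id[proteins$id %in% truth$mito_ids]
  non <- setdiff(proteins$id, mito)
  pos <- sample(mito, min(cfg$n_ref_pos, length(mito)))
  neg <- sample(non, min(cfg$n_ref_neg, length(non)))
  m <- truth$motifs
  tru <- which(m$class == "ppr")
  if (!is.null(hits)) {
    key <- paste(m$protein_id, m$start, m$end)
    hit_key <- paste(hits$protein_id, hits$env_start, hits$env_end)
    tru <- tru[key[tru] %in% hit_key]
  }
  dec <- which(m$class == "decoy")
  mp <- m[sample(tru, min(cfg$n_ref_motif_pos, length(tru))),
          c("protein_id", "start", "end"), drop = FALSE]
  mn <- m[sample(dec, min(cfg$n_ref_motif_neg, length(dec))),
          c("protein_id", "start", "end"), drop = FALSE]
  rownames(mp) <- rownames(mn) <- NULL
  list(protein = list(positives = pos, negatives = neg),
       motif = list(positive = mp, negative = mn))
}

#' Generate a complete synthetic dataset
#'
#' Runs every generator with a shared configuration and, when `dir` is
#' given, writes all pipeline input files: `proteome.fasta`,
#' `predictors.tsv` (raw scores), `hits.domtblout`, `structures.tsv`,
#' `quant.tsv`, reference lists and per-motif truth tables.
#'
#' @param cfg A [synth_config()].
#' @param dir Optional output directory (created if needed).
#' @return A list with elements `proteins`, `truth`, `predictors`,
#'   `hits`, `tracks`, `omitted`, `quants`, `enriched_ids`,
#'   `reference`, `cfg`.
#' @export
synth_dataset <- function(cfg = synth_config(), dir = NULL) {
  pro <- make_proteome(cfg)
  pred <- make_predictor_table(cfg, pro$truth, pro$proteins)
  hs <- make_hits_and_structs(cfg, pro$truth, pro$proteins)
  qt <- make_quant_table(cfg, pro$truth, pro$proteins)
  ref <- make_reference(cfg, pro$truth, pro$proteins, hs$hits)
  out <- list(proteins = pro$proteins, truth = pro$truth,
              predictors = pred, hits = hs$hits, tracks = hs$tracks,
              omitted = hs$omitted, quants = qt$quants,
              enriched_ids = qt$enriched_ids, reference = ref,
              cfg = cfg)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(dir, f)
    write_fasta(pro$proteins, p("proteome.fasta"))
    utils::write.table(
      pred[, c("protein_id", "score_primary", "assigned_primary",
               "score_secondary", "assigned_secondary",
               "score_tertiary_raw")],
      p("predictors.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    write_domtblout(hs$hits, p("hits.domtblout"))
    utils::write.table(hs$tracks, p("structures.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(qt$quants, p("quant.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    writeLines(ref$protein$positives, p("reference_positive.txt"))
    writeLines(ref$protein$negatives, p("reference_negative.txt"))
    utils::write.table(ref$motif$positive, p("motif_reference_pos.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(ref$motif$negative, p("motif_reference_neg.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(pro$truth$motifs, p("truth_motifs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(pro$truth$mito_ids, p("truth_mito_ids.txt"))
    writeLines(qt$enriched_ids, p("truth_enriched_ids.txt"))
  }
  out
}
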