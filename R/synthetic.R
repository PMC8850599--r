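# Synthetic-data generators with planted ground truth for every input the
# pipeline consumes: knowledge bases with planted triads and per-stage
# decoys, Ct datasets at the study's group design, dual-luciferase plates,
# and wild-type/mutant sequence pairs with implanted seed sites. Every
# generator is a pure function of (config, seed); the returned manifest
# fully determines the expected output of the matching recovery test.

decoy_modes_all <- c("lncbase_score", "tissue", "degree", "known_pd",
                     "gene_link", "specificity", "cis_gap")

#' Synthetic-data configuration
#'
#' Defaults encode the emulated study design: 20 controls and 38 patients
#' split by clinical stage into 27 early (stage I n=10, stage II n=17) and
#' 11 late (stage III n=10, stage IV n=1); marker panel of two lncRNAs, two
#' miRNAs and two mRNAs with the observed effect directions (linc01128,
#' miR-24-3p, miR-30c-5p down-regulated; linc00938, LRRK2, ATP13A2
#' up-regulated in patients). Effect sizes are parameterized as
#' delta-delta-Ct shifts in cycles (positive shift = higher Ct = lower
#' expression), defaulting to +/- 0.5 cycles.
#'
#' @param n_planted_triads Number of planted triads in the knowledge base
#'   (default 2).
#' @param decoy_modes Which single-violation decoy lncRNAs to plant; one per
#'   elimination mode (default all seven).
#' @param n_background_mirnas Extra miRNA records that fail the
#'   strong-validation stage (default 10).
#' @param group_sizes Named vector `control`, `stage1`..`stage4`.
#' @param marker_shifts Named numeric vector of per-marker delta-delta-Ct
#'   shifts (cycles) applied to patient samples.
#' @param biological_sd Per-sample biological SD of the target-gene Ct,
#'   cycles (default 0.5).
#' @param technical_sd Per-replicate technical SD, cycles (default 0.15).
#' @param ref_biological_sd Per-sample SD of reference-gene Ct (housekeeping
#'   genes modelled as stable; default 0.1 cycles).
#' @param n_replicates Technical replicates per (sample, gene) (default 3).
#' @param inhibition Named vector of true inhibition fractions per reporter
#'   condition (default `c(WT = 0.70, MT = 0)`); each must lie in \[0, 1).
#' @param reporter_cv Lognormal coefficient of variation of well noise
#'   (default 0.05).
#' @param reporter_replicates Wells per condition (default 6).
#' @param seq_length Length (nt) of generated target constructs
#'   (default 140).
#' @param site_class Implanted seed-site class (default `"8mer"`).
#' @param mirna_sequence miRNA used for sequence generation (default the
#'   mature hsa-miR-30c-5p sequence).
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(n_planted_triads = 2,
                         decoy_modes = decoy_modes_all,
                         n_background_mirnas = 10,
                         group_sizes = c(control = 20, stage1 = 10, stage2 = 17,
                                         stage3 = 10, stage4 = 1),
                         marker_shifts = c("linc01128" = 0.5,
                                           "hsa-miR-24-3p" = 0.5,
                                           "hsa-miR-30c-5p" = 0.5,
                                           "linc00938" = -0.5,
                                           "LRRK2" = -0.5,
                                           "ATP13A2" = -0.5),
                         biological_sd = 0.5,
                         technical_sd = 0.15,
                         ref_biological_sd = 0.1,
                         n_replicates = 3,
                         inhibition = c(WT = 0.70, MT = 0),
                         reporter_cv = 0.05,
                         reporter_replicates = 6,
                         seq_length = 140,
                         site_class = "8mer",
                         mirna_sequence = "UGUAAACAUCCUACACUCUCAGC") {
  cfg <- list(n_planted_triads = as.integer(n_planted_triads),
              decoy_modes = as.character(decoy_modes),
              n_background_mirnas = as.integer(n_background_mirnas),
              group_sizes = group_sizes,
              marker_shifts = marker_shifts,
              biological_sd = biological_sd,
              technical_sd = technical_sd,
              ref_biological_sd = ref_biological_sd,
              n_replicates = as.integer(n_replicates),
              inhibition = inhibition,
              reporter_cv = reporter_cv,
              reporter_replicates = as.integer(reporter_replicates),
              seq_length = as.integer(seq_length),
              site_class = site_class,
              mirna_sequence = mirna_sequence)
  assert_that(cfg$n_planted_triads >= 0, "n_planted_triads must be >= 0")
  assert_that(all(cfg$decoy_modes %in% decoy_modes_all),
              sprintf("unknown decoy mode(s): %s",
                      paste(setdiff(cfg$decoy_modes, decoy_modes_all), collapse = ", ")))
  assert_that(all(c("control", "stage1", "stage2", "stage3", "stage4") %in%
                    names(cfg$group_sizes)), "group_sizes must name control, stage1..stage4")
  assert_that(all(cfg$group_sizes >= 0), "group sizes must be >= 0")
  assert_that(cfg$biological_sd >= 0 && cfg$technical_sd >= 0 &&
                cfg$ref_biological_sd >= 0, "noise SDs must be >= 0")
  assert_that(all(cfg$inhibition >= 0 & cfg$inhibition < 1),
              "inhibition fractions must lie in [0, 1)")
  assert_that(cfg$reporter_cv >= 0, "reporter_cv must be >= 0")
  assert_that(cfg$site_class %in% site_class_levels,
              sprintf("site_class must be one of %s",
                      paste(site_class_levels, collapse = ", ")))
  assert_that(cfg$seq_length >= 10, "seq_length must be >= site length + 2")
  structure(cfg, class = "synth_config")
}

#' Generate a knowledge base with planted triads and per-stage decoys
#'
#' Each planted triad (lncRNA, miRNA, gene) satisfies every cascade
#' predicate: its two miRNAs pass strong validation, interaction scores
#' exceed the lncBase gate, the lncRNA is expressed in blood and brain with
#' degree >= 2, one miRNA hits a disease gene above the prediction gate,
#' there is no excluded-disease association, and the lncRNA/gene loci lie
#' within the cis gap. Each decoy lncRNA violates exactly its designated
#' predicate and satisfies all others. Background miRNAs fail the
#' strong-validation stage. Deterministic given `seed`.
#'
#' @param config A [synth_config()].
#' @param seed Integer seed (mandatory).
#' @return List: `kb` (a [knowledge_base()]), `screen_config` (the matching
#'   [screen_config()]), `manifest` (list of class `ground_truth_manifest`
#'   with `triads`, `decoys`, `seed`).
#' @export
generate_knowledge_base <- function(config = synth_config(), seed) {
  assert_that(!missing(seed) && is.finite(seed), "seed is mandatory")
  set.seed(as.integer(seed))
  np <- config$n_planted_triads
  modes <- config$decoy_modes

  scfg <- screen_config(pd_gene_set = character())
  chrom_pool <- paste0("chr", 1:22)

  mirnas <- list(); m_lnc <- list(); m_gene <- list(); l_gene <- list()
  loci <- list(); tissues <- list(); diseases <- list()
  pd_genes <- character()

  add_locus <- function(name, chrom, start, end) {
    loci[[length(loci) + 1L]] <<- data.frame(
      chrom = chrom, start = start, end = end, name = name, score = "0",
      strand = sample(c("+", "-"), 1), stringsAsFactors = FALSE)
  }
  strong <- join_tokens(c("reporter-assay", "qPCR"))

  # unit: one lncRNA with two strong miRNAs, one target gene; `mode` breaks
  # exactly one predicate for decoys (NULL = planted triad).
  build_unit <- function(idx, mode = NULL) {
    tag <- if (is.null(mode)) sprintf("P%02d", idx) else sprintf("D_%s", mode)
    L <- sprintf("LNC-%s", tag)
    m1 <- sprintf("mir-%s-a", tag); m2 <- sprintf("mir-%s-b", tag)
    G <- sprintf("GENE-%s", tag)
    chrom <- sample(chrom_pool, 1)

    mirnas[[length(mirnas) + 1L]] <<- data.frame(
      mirna_id = c(m1, m2), evidence_methods = strong,
      pd_related = TRUE, stringsAsFactors = FALSE)

    sc1 <- round(stats::runif(1, 0.75, 0.95), 3)
    sc2 <- round(stats::runif(1, 0.72, 0.95), 3)
    if (!is.null(mode) && mode == "lncbase_score") {
      sc1 <- round(stats::runif(1, 0.30, 0.65), 3)
      sc2 <- round(stats::runif(1, 0.30, 0.65), 3)
    }
    keep_m2 <- is.null(mode) || mode != "degree"
    inter <- data.frame(mirna_id = m1, lncrna_id = L, score = sc1,
                        assay = "immunoprecipitation", stringsAsFactors = FALSE)
    if (keep_m2) {
      inter <- rbind(inter, data.frame(mirna_id = m2, lncrna_id = L, score = sc2,
                                       assay = "immunoprecipitation",
                                       stringsAsFactors = FALSE))
    }
    m_lnc[[length(m_lnc) + 1L]] <<- inter

    gene_score <- round(stats::runif(1, 85, 99), 1)
    if (!is.null(mode) && mode == "gene_link") gene_score <- round(stats::runif(1, 40, 75), 1)
    m_gene[[length(m_gene) + 1L]] <<- data.frame(
      mirna_id = m1, gene_id = G, prediction_score = gene_score,
      stringsAsFactors = FALSE)
    pd_genes <<- c(pd_genes, G)
    l_gene[[length(l_gene) + 1L]] <<- data.frame(
      lncrna_id = L, gene_id = G,
      n_predicted_interactions = sample(0:3, 1), stringsAsFactors = FALSE)

    tis <- c("blood", "brain")
    if (!is.null(mode) && mode == "tissue") tis <- "blood"
    tissues[[length(tissues) + 1L]] <<- data.frame(
      entity_id = L, tissues = join_tokens(tis), stringsAsFactors = FALSE)

    if (!is.null(mode) && mode == "known_pd") {
      diseases[[length(diseases) + 1L]] <<- data.frame(
        entity_id = L, disease = scfg$pd_disease_label, source = "literature",
        stringsAsFactors = FALSE)
    }
    if (!is.null(mode) && mode == "specificity") {
      diseases[[length(diseases) + 1L]] <<- data.frame(
        entity_id = L, disease = scfg$excluded_disease_labels[1],
        source = "database", stringsAsFactors = FALSE)
    }

    l_start <- floor(stats::runif(1, 1e5, 2e6))
    l_end <- l_start + floor(stats::runif(1, 5e3, 3e4))
    gap <- if (!is.null(mode) && mode == "cis_gap") {
      floor(stats::runif(1, 60000, 500000))
    } else {
      floor(stats::runif(1, 2000, 45000))
    }
    g_start <- l_end + gap
    add_locus(L, chrom, l_start, l_end)
    add_locus(G, chrom, g_start, g_start + floor(stats::runif(1, 1e4, 5e4)))

    data.frame(lncrna_id = L, mirna_id = m1, gene_id = G,
               lncbase_score = sc1, gene_prediction_score = gene_score,
               cis_gap_bp = gap, mode = if (is.null(mode)) "planted" else mode,
               stringsAsFactors = FALSE)
  }

  planted <- lapply(seq_len(np), build_unit)
  decoys <- lapply(modes, function(md) build_unit(0L, md))

  # background miRNAs that fail strong validation
  if (config$n_background_mirnas > 0) {
    ids <- sprintf("mir-bg-%02d", seq_len(config$n_background_mirnas))
    pdrel <- stats::runif(length(ids)) < 0.5
    # either disease-related with only weak evidence, or strongly validated
    # but not disease-related: both fail stage A
    mirnas[[length(mirnas) + 1L]] <- data.frame(
      mirna_id = ids,
      evidence_methods = ifelse(pdrel, "microarray", strong),
      pd_related = pdrel,
      stringsAsFactors = FALSE)
  }

  bind <- function(lst, proto) if (length(lst)) do.call(rbind, lst) else proto
  kb <- knowledge_base(
    mirnas = bind(mirnas, data.frame(mirna_id = character(),
                                     evidence_methods = character(),
                                     pd_related = logical())),
    mirna_lncrna = bind(m_lnc, data.frame(mirna_id = character(),
                                          lncrna_id = character(),
                                          score = numeric(), assay = character())),
    mirna_gene = bind(m_gene, data.frame(mirna_id = character(),
                                         gene_id = character(),
                                         prediction_score = numeric())),
    lncrna_gene = bind(l_gene, data.frame(lncrna_id = character(),
                                          gene_id = character(),
                                          n_predicted_interactions = integer())),
    loci = bind(loci, data.frame(chrom = character(), start = numeric(),
                                 end = numeric(), name = character(),
                                 score = character(), strand = character())),
    tissues = bind(tissues, data.frame(entity_id = character(),
                                       tissues = character())),
    diseases = bind(diseases, data.frame(entity_id = character(),
                                         disease = character(),
                                         source = character()))
  )
  scfg$pd_gene_set <- pd_genes

  triads_df <- bind(planted, data.frame())
  decoys_df <- bind(decoys, data.frame())
  stage_of_mode <- c(lncbase_score = "lncbase_score", tissue = "tissue",
                     degree = "known_and_degree", known_pd = "known_and_degree",
                     gene_link = "pd_gene_link", specificity = "specificity",
                     cis_gap = "cis_pairing")
  if (nrow(decoys_df)) decoys_df$designed_stage <- stage_of_mode[decoys_df$mode]

  manifest <- structure(list(triads = triads_df, decoys = decoys_df,
                             seed = as.integer(seed)),
                        class = "ground_truth_manifest")
  list(kb = kb, screen_config = scfg, manifest = manifest)
}

rtrunc_norm <- function(n, mean, sd, lower, upper) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lower | x > upper)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(x < lower | x > upper)
  }
  x
}

rlnorm_meansd <- function(n, mean, sd) {
  sdlog <- sqrt(log(1 + (sd / mean)^2))
  meanlog <- log(mean) - sdlog^2 / 2
  stats::rlnorm(n, meanlog, sdlog)
}

#' Generate a qRT-PCR Ct dataset at the study design
#'
#' Samples follow the emulated design: controls plus patients in clinical
#' stages I-IV (stage class early = I-II, late = III-IV), with demographic
#' metadata drawn from distributions matching the study's reported subgroup
#' means/SDs (see [demo_demographics()]); disease duration is lognormal
#' (its reported SD is of the order of its mean, indicating right skew);
#' MoCA scores are always >= 26 (lower scores were an exclusion criterion).
#' Reference genes (U6, GAPDH, 18S) are generated shift-free; each target
#' marker's Ct adds its group shift (patients only) plus per-sample
#' biological and per-replicate technical noise.
#'
#' @param config A [synth_config()].
#' @param seed Integer seed (mandatory).
#' @return List: `ct` (long data.frame `sample_id`, `gene_id`, `replicate`,
#'   `ct`), `samples` (metadata frame), `manifest` (class
#'   `ground_truth_manifest` with the planted shifts and noise levels).
#' @export
generate_ct_dataset <- function(config = synth_config(), seed) {
  assert_that(!missing(seed) && is.finite(seed), "seed is mandatory")
  set.seed(as.integer(seed))
  gs <- config$group_sizes
  n_ctrl <- gs[["control"]]
  stage_n <- c(I = gs[["stage1"]], II = gs[["stage2"]],
               III = gs[["stage3"]], IV = gs[["stage4"]])
  n_pd <- sum(stage_n)
  n <- n_ctrl + n_pd
  assert_that(n > 0, "empty design")

  stage <- c(rep("none", n_ctrl),
             rep(names(stage_n), times = stage_n))
  stage_class <- ifelse(stage %in% c("I", "II"), "early",
                        ifelse(stage %in% c("III", "IV"), "late", "none"))
  group <- ifelse(stage == "none", "control", "PD")
  sample_id <- sprintf("S%03d", seq_len(n))

  demo <- demo_demographics()
  par_of <- function(grp, col) demo[[col]][demo$group == grp]
  age <- numeric(n); bmi <- numeric(n); duration <- rep(NA_real_, n)
  is_e <- stage_class == "early"; is_l <- stage_class == "late"; is_c <- group == "control"
  age[is_c] <- rtrunc_norm(sum(is_c), par_of("control", "age_mean"),
                           par_of("control", "age_sd"), 35, 95)
  age[is_e] <- rtrunc_norm(sum(is_e), par_of("early", "age_mean"),
                           par_of("early", "age_sd"), 35, 95)
  age[is_l] <- rtrunc_norm(sum(is_l), par_of("late", "age_mean"),
                           par_of("late", "age_sd"), 35, 95)
  bmi[is_c] <- rtrunc_norm(sum(is_c), par_of("control", "bmi_mean"),
                           par_of("control", "bmi_sd"), 15, 45)
  bmi[is_e] <- rtrunc_norm(sum(is_e), par_of("early", "bmi_mean"),
                           par_of("early", "bmi_sd"), 15, 45)
  bmi[is_l] <- rtrunc_norm(sum(is_l), par_of("late", "bmi_mean"),
                           par_of("late", "bmi_sd"), 15, 45)
  if (any(is_e)) duration[is_e] <- rlnorm_meansd(sum(is_e),
                                                 par_of("early", "duration_mean"),
                                                 par_of("early", "duration_sd"))
  if (any(is_l)) duration[is_l] <- rlnorm_meansd(sum(is_l),
                                                 par_of("late", "duration_mean"),
                                                 par_of("late", "duration_sd"))
  sex <- character(n)
  sex[is_c] <- sample(rep(c("male", "female"), length.out = sum(is_c)))
  sex[!is_c] <- sample(c(rep("male", 21), rep("female", 17)),
                       size = sum(!is_c), replace = sum(!is_c) > 38)
  moca <- sample(26:30, n, replace = TRUE)
  updrs <- rep(NA_real_, n)
  is_pd <- group == "PD"
  updrs_lo <- c(I = 0, II = 25, III = 51, IV = 76)[stage[is_pd]]
  updrs_hi <- c(I = 24, II = 50, III = 75, IV = 100)[stage[is_pd]]
  updrs[is_pd] <- stats::runif(sum(is_pd), updrs_lo, updrs_hi)

  samples <- data.frame(sample_id = sample_id, group = group, stage = stage,
                        stage_class = stage_class, age = round(age, 1),
                        sex = sex, disease_duration = round(duration, 1),
                        bmi = round(bmi, 1), moca_score = moca,
                        updrs_percent = round(updrs, 1), stringsAsFactors = FALSE)

  markers <- names(config$marker_shifts)
  base_ct <- vapply(markers, function(m) {
    if (grepl("^(hsa-)?mir", m, ignore.case = TRUE)) 28 else if (grepl("^linc", m, ignore.case = TRUE)) 30 else 26
  }, numeric(1))
  ref_ct <- c(U6 = 22, GAPDH = 20, `18S` = 12)

  ct_rows <- list()
  emit <- function(gene, per_sample_ct) {
    for (r in seq_len(config$n_replicates)) {
      ct_rows[[length(ct_rows) + 1L]] <<- data.frame(
        sample_id = sample_id, gene_id = gene, replicate = r,
        ct = per_sample_ct + stats::rnorm(n, 0, config$technical_sd),
        stringsAsFactors = FALSE)
    }
  }
  for (g in names(ref_ct)) {
    emit(g, ref_ct[[g]] + stats::rnorm(n, 0, config$ref_biological_sd))
  }
  for (m in markers) {
    shift <- ifelse(group == "PD", config$marker_shifts[[m]], 0)
    emit(m, base_ct[[m]] + shift + stats::rnorm(n, 0, config$biological_sd))
  }
  ct <- do.call(rbind, ct_rows)
  ct$ct <- pmin(pmax(ct$ct, 1), 45)
  rownames(ct) <- NULL

  manifest <- structure(list(
    marker_shifts = config$marker_shifts,
    directions = ifelse(config$marker_shifts > 0, "down",
                        ifelse(config$marker_shifts < 0, "up", "none")),
    biological_sd = config$biological_sd,
    technical_sd = config$technical_sd,
    ref_biological_sd = config$ref_biological_sd,
    group_sizes = gs, reference_genes = names(ref_ct),
    seed = as.integer(seed)), class = "ground_truth_manifest")

  list(ct = ct, samples = samples, manifest = manifest)
}

#' Generate a dual-luciferase reporter plate
#'
#' Four conditions (NC, WT, MT, blank). The normalized ratio of each test
#' condition equals the NC ratio times `(1 - inhibition)`, with lognormal
#' well noise at the configured CV on both channels. Blank wells carry
#' near-zero background counts. Deterministic per seed.
#'
#' @param config A [synth_config()] (`inhibition`, `reporter_cv`,
#'   `reporter_replicates`).
#' @param seed Integer seed (mandatory).
#' @return List: `plate` (data.frame `condition`, `replicate`, `renilla`,
#'   `firefly`), `manifest` (true inhibition fractions, CV, base ratio).
#' @export
generate_reporter_plate <- function(config = synth_config(), seed) {
  assert_that(!missing(seed) && is.finite(seed), "seed is mandatory")
  set.seed(as.integer(seed))
  nrep <- config$reporter_replicates
  cv <- config$reporter_cv
  sdlog <- sqrt(log(1 + cv^2))
  base_ratio <- 1.2          # renilla/firefly ratio of the uninhibited reporter
  base_firefly <- 1e5

  conditions <- c("NC", names(config$inhibition))
  inhib <- c(NC = 0, config$inhibition)
  rows <- list()
  for (cn in conditions) {
    firefly <- base_firefly * stats::rlnorm(nrep, -sdlog^2 / 2, sdlog)
    ratio <- base_ratio * (1 - inhib[[cn]]) *
      stats::rlnorm(nrep, -sdlog^2 / 2, sdlog)
    rows[[cn]] <- data.frame(condition = cn, replicate = seq_len(nrep),
                             renilla = firefly * ratio, firefly = firefly,
                             stringsAsFactors = FALSE)
  }
  rows[["blank"]] <- data.frame(condition = "blank", replicate = seq_len(nrep),
                                renilla = stats::runif(nrep, 10, 80),
                                firefly = stats::runif(nrep, 10, 80),
                                stringsAsFactors = FALSE)
  plate <- do.call(rbind, rows)
  rownames(plate) <- NULL

  manifest <- structure(list(inhibition = inhib, cv = cv,
                             base_ratio = base_ratio, n_replicates = nrep,
                             signal = "renilla", seed = as.integer(seed)),
                        class = "ground_truth_manifest")
  list(plate = plate, manifest = manifest)
}

random_rna <- function(len) {
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
}

#' Generate a wild-type / mutant target-sequence pair
#'
#' Draws a random background sequence free of any seed site (class >= 6mer)
#' for the configured miRNA, implants one site of the configured class at a
#' recorded position, and derives the mutant by shuffling the site window
#' until no site of class >= 6mer remains anywhere in the mutant. Both the
#' implant and the disruption are re-verified by [find_seed_sites()] before
#' returning; generation retries a bounded number of times.
#'
#' @param config A [synth_config()] (`seq_length`, `site_class`,
#'   `mirna_sequence`).
#' @param seed Integer seed (mandatory).
#' @param max_tries Bounded retries for background/mutant rejection sampling
#'   (default 200).
#' @return List: `wt`, `mt`, `mirna` (character sequences), `manifest`
#'   (implanted `start`, `end`, `site_class`, seed).
#' @export
generate_sequences <- function(config = synth_config(), seed, max_tries = 200) {
  assert_that(!missing(seed) && is.finite(seed), "seed is mandatory")
  set.seed(as.integer(seed))
  m <- norm_rna(config$mirna_sequence, "miRNA sequence")
  len <- config$seq_length
  cls <- config$site_class

  core <- rna_revcomp(substr(m, 2, 7))
  m8 <- rna_complement(substr(m, 8, 8))
  site_seq <- switch(cls,
                     "6mer" = core,
                     "7mer-A1" = paste0(core, "A"),
                     "7mer-m8" = paste0(m8, core),
                     "8mer" = paste0(m8, core, "A"))
  site_len <- nchar(site_seq)
  assert_that(len >= site_len + 2, "seq_length must be >= site length + 2")

  for (try in seq_len(max_tries)) {
    bg <- random_rna(len)
    if (nrow(find_seed_sites(m, bg))) next
    # 1-based insert position, keeping one flanking base each side
    pos <- sample(2:(len - site_len), 1)
    wt <- paste0(substr(bg, 1, pos - 1), site_seq,
                 substr(bg, pos + site_len, len))
    sites <- find_seed_sites(m, wt)
    if (nrow(sites) != 1 || sites$site_class != cls ||
        sites$start != pos - 1 || sites$end != pos - 1 + site_len) next

    mt <- NULL
    for (mt_try in seq_len(max_tries)) {
      shuffled <- paste(sample(strsplit(site_seq, "")[[1]]), collapse = "")
      cand <- paste0(substr(wt, 1, pos - 1), shuffled,
                     substr(wt, pos + site_len, len))
      if (!nrow(find_seed_sites(m, cand))) { mt <- cand; break }
    }
    if (is.null(mt)) next

    manifest <- structure(list(start = sites$start, end = sites$end,
                               site_class = cls, mirna = m,
                               seed = as.integer(seed)),
                          class = "ground_truth_manifest")
    return(list(wt = wt, mt = mt, mirna = m, manifest = manifest))
  }
  stop("could not generate a clean wild-type/mutant pair after bounded retries; ",
       "try a longer sequence", call. = FALSE)
}
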