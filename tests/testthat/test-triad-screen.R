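cfg0 <- screen_config(pd_gene_set = "G1")

test_that("strong-validation stage keeps only disease miRNAs with whitelist evidence", {
  recs <- data.frame(
    mirna_id = c("m1", "m2", "m3"),
    evidence_methods = c("reporter-assay", "microarray", "reporter-assay,qPCR"),
    pd_related = c(TRUE, TRUE, FALSE), stringsAsFactors = FALSE)
  expect_identical(filter_strong_validation(recs, cfg0), "m1")
  expect_error(filter_strong_validation(recs, screen_config(
    strong_evidence_methods = character(), pd_gene_set = "G1")),
    "configuration error")
})

test_that("interaction mapping applies the strict score gate and inverts to lncRNA keys", {
  inter <- data.frame(mirna_id = c("m1", "m1", "m2"),
                      lncrna_id = c("L1", "L2", "L1"),
                      score = c(0.79, 0.69, 0.70),
                      assay = "ip", stringsAsFactors = FALSE)
  map <- mirna_to_lncrna(c("m1", "m2"), inter, cfg0)
  expect_identical(names(map), "L1")
  expect_identical(map$L1, "m1")   # 0.70 fails the strict "above 0.7" gate
  expect_length(mirna_to_lncrna(character(), inter, cfg0), 0)
})

test_that("score gate at threshold zero retains every interaction of known miRNAs", {
  set.seed(21)
  inter <- data.frame(mirna_id = sample(c("m1", "m2"), 10, TRUE),
                      lncrna_id = sample(paste0("L", 1:4), 10, TRUE),
                      score = runif(10), assay = "ip", stringsAsFactors = FALSE)
  inter <- inter[!duplicated(inter[1:2]), ]
  cfg <- screen_config(min_lncbase_score = 0, pd_gene_set = "G1")
  map <- mirna_to_lncrna(c("m1", "m2"), inter, cfg)
  kept <- inter[inter$score > 0, ]
  for (L in unique(kept$lncrna_id)) {
    expect_setequal(map[[L]], kept$mirna_id[kept$lncrna_id == L])
  }
})

test_that("tissue filter is a superset test over required tissues", {
  tr <- data.frame(entity_id = c("L1", "L2", "L3"),
                   tissues = c("blood,brain", "blood", "brain,liver"),
                   stringsAsFactors = FALSE)
  expect_identical(filter_tissue(c("L1", "L2", "L3", "L4"), tr, cfg0), "L1")
  expect_identical(filter_tissue(character(), tr, cfg0), character())
})

test_that("known-disease and degree exclusions behave and the identity case holds", {
  map <- list(L1 = "m1", L2 = c("m1", "m2"), L3 = c("m1", "m2", "m3"))
  out <- exclude_known_and_low_degree(map, "L3", cfg0)
  expect_identical(names(out), "L2")
  id_cfg <- screen_config(min_mirna_degree = 0, pd_gene_set = "G1")
  expect_identical(exclude_known_and_low_degree(map, character(), id_cfg), map)
})

test_that("key-gene linkage requires a strict score above the gate", {
  map <- list(L1 = "m1", L2 = "m2")
  mg <- data.frame(mirna_id = c("m1", "m2"),
                   gene_id = c("LRRK2", "OTHER"),
                   prediction_score = c(93, 99), stringsAsFactors = FALSE)
  cfg <- screen_config(pd_gene_set = "LRRK2")
  expect_identical(names(filter_pd_gene_link(map, mg, cfg)), "L1")
  expect_error(filter_pd_gene_link(map, mg, screen_config()), "pd_gene_set is empty")
  # boundary: a score equal to the gate fails
  mg80 <- data.frame(mirna_id = "m1", gene_id = "LRRK2", prediction_score = 80,
                     stringsAsFactors = FALSE)
  expect_length(filter_pd_gene_link(list(L1 = "m1"), mg80, cfg), 0)
})

test_that("specificity filter removes excluded-disease lncRNAs only", {
  map <- list(L1 = "m1", L2 = "m2")
  da <- data.frame(entity_id = "L1", disease = "Alzheimer disease",
                   source = "database", stringsAsFactors = FALSE)
  expect_identical(names(filter_specificity(map, da, cfg0)), "L2")
  none <- screen_config(excluded_disease_labels = character(), pd_gene_set = "G1")
  expect_identical(filter_specificity(map, da, none), map)
})

test_that("cis pairing is strict at the gap threshold and audits missing loci", {
  mg <- data.frame(mirna_id = "m1", gene_id = "G1", prediction_score = 95,
                   stringsAsFactors = FALSE)
  mk_loci <- function(gap) data.frame(
    chrom = "chr1", start = c(0, 1000 + gap), end = c(1000, 2000 + gap),
    name = c("L1", "G1"), score = "0", strand = "+", stringsAsFactors = FALSE)
  t1 <- pair_cis(list(L1 = "m1"), mk_loci(49999), cfg0, mg)
  expect_identical(nrow(t1), 1L)
  expect_identical(t1$cis_gap_bp, 49999)
  t2 <- pair_cis(list(L1 = "m1"), mk_loci(50000), cfg0, mg)
  expect_identical(nrow(t2), 0L)
  # lncRNA without locus cannot pair
  no_l <- mk_loci(1000)[2, , drop = FALSE]
  expect_identical(nrow(pair_cis(list(L1 = "m1"), no_l, cfg0, mg)), 0L)
})

test_that("the demonstration fixture reproduces the two published triads", {
  res <- run_cascade(demo_knowledge_base(), demo_screen_config())
  expect_identical(res$stage_counts$n, c(2L, 2L, 2L, 2L, 2L, 2L, 2L))
  expect_identical(res$triads$lncrna_id, c("linc00938", "linc01128"))
  expect_identical(res$triads$mirna_id, c("hsa-miR-30c-5p", "hsa-miR-24-3p"))
  expect_identical(res$triads$gene_id, c("LRRK2", "ATP13A2"))
  expect_identical(res$triads$lncbase_score[res$triads$lncrna_id == "linc00938"], 0.79)
  expect_identical(res$triads$gene_prediction_score, c(93, 88))
})

test_that("an empty knowledge base yields zero counts and no triads", {
  empty <- knowledge_base(
    data.frame(mirna_id = character(), evidence_methods = character(),
               pd_related = logical()),
    data.frame(mirna_id = character(), lncrna_id = character(),
               score = numeric(), assay = character()),
    data.frame(mirna_id = character(), gene_id = character(),
               prediction_score = numeric()),
    data.frame(lncrna_id = character(), gene_id = character(),
               n_predicted_interactions = integer()),
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               name = character(), score = character(), strand = character()),
    data.frame(entity_id = character(), tissues = character()),
    data.frame(entity_id = character(), disease = character(),
               source = character()))
  res <- run_cascade(empty, cfg0)
  expect_true(all(res$stage_counts$n == 0))
  expect_identical(nrow(res$triads), 0L)
})

test_that("cascade equals the brute-force conjunction on random knowledge bases", {
  for (seed in 1:25) {
    rk <- random_kb(seed)
    got <- run_cascade(rk$kb, rk$cfg)$triads
    want <- brute_force_triads(rk$kb, rk$cfg)
    expect_same_triads(got, want)
  }
})

test_that("audit trail is complete at every stage", {
  for (seed in c(5, 17)) {
    rk <- random_kb(seed)
    res <- run_cascade(rk$kb, rk$cfg)
    audit <- res$audit
    # every miRNA is survivor or eliminated at stage A, exactly once
    elim_m <- audit$entity_id[audit$entity_type == "miRNA"]
    expect_identical(sort(c(res$survivors$strong_validation, elim_m)),
                     sort(rk$kb$mirnas$mirna_id))
    # every candidate lncRNA is final survivor (paired) or eliminated once
    all_lnc <- unique(rk$kb$mirna_lncrna$lncrna_id)
    elim_l <- audit$entity_id[audit$entity_type == "lncRNA"]
    expect_identical(anyDuplicated(elim_l), 0L)
    paired <- unique(res$triads$lncrna_id)
    expect_setequal(c(paired, elim_l), all_lnc)
  }
})

test_that("relaxing any single threshold never shrinks the surviving set", {
  key <- function(d) paste(d$lncrna_id, d$mirna_id, d$gene_id)
  for (seed in c(3, 9, 14)) {
    rk <- random_kb(seed)
    base <- key(run_cascade(rk$kb, rk$cfg)$triads)
    relaxed <- list(
      modifyList(rk$cfg, list(min_lncbase_score = rk$cfg$min_lncbase_score - 0.2)),
      modifyList(rk$cfg, list(min_gene_prediction_score = rk$cfg$min_gene_prediction_score - 20)),
      modifyList(rk$cfg, list(min_mirna_degree = 0L)),
      modifyList(rk$cfg, list(max_cis_gap_bp = rk$cfg$max_cis_gap_bp * 10)))
    for (cfg in relaxed) {
      class(cfg) <- "screen_config"
      expect_true(all(base %in% key(run_cascade(rk$kb, cfg)$triads)))
    }
  }
})

test_that("tissue, specificity and known-disease filters commute", {
  for (seed in c(2, 8)) {
    rk <- random_kb(seed)
    cfg <- rk$cfg
    mirnas_a <- filter_strong_validation(rk$kb$mirnas, cfg)
    map <- mirna_to_lncrna(mirnas_a, rk$kb$mirna_lncrna, cfg)
    known <- unique(rk$kb$diseases$entity_id[
      rk$kb$diseases$disease == cfg$pd_disease_label &
        rk$kb$diseases$source == "literature"])
    f_tissue <- function(m) m[filter_tissue(names(m), rk$kb$tissues, cfg)]
    f_spec <- function(m) filter_specificity(m, rk$kb$diseases, cfg)
    f_known <- function(m) m[setdiff(names(m), known)]
    perms <- list(c(1, 2, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
    fns <- list(f_tissue, f_spec, f_known)
    results <- lapply(perms, function(p) {
      out <- map
      for (i in p) out <- fns[[i]](out)
      sort(names(out))
    })
    for (r in results[-1]) expect_identical(r, results[[1]])
  }
})

test_that("cascade outputs serialize to the three TSV artefacts", {
  res <- run_cascade(demo_knowledge_base(), demo_screen_config())
  dir <- file.path(tempdir(), "cascade_out")
  write_cascade_result(res, dir)
  expect_true(all(file.exists(file.path(dir, c("triads.tsv", "stage_counts.tsv",
                                               "audit.tsv")))))
  tri <- read.delim(file.path(dir, "triads.tsv"))
  expect_identical(nrow(tri), 2L)
  unlink(dir, recursive = TRUE)
})
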