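test_that("generators are pure functions of (config, seed)", {
  cfg <- synth_config()
  a <- generate_knowledge_base(cfg, seed = 91)
  b <- generate_knowledge_base(cfg, seed = 91)
  expect_identical(a$kb$mirna_lncrna, b$kb$mirna_lncrna)
  expect_identical(a$manifest$triads, b$manifest$triads)
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  write_knowledge_base(a$kb, d1); write_knowledge_base(b$kb, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  unlink(c(d1, d2), recursive = TRUE)

  c1 <- generate_ct_dataset(cfg, seed = 92)
  c2 <- generate_ct_dataset(cfg, seed = 92)
  expect_identical(c1$ct, c2$ct)
  expect_identical(c1$samples, c2$samples)
  expect_false(identical(c1$ct, generate_ct_dataset(cfg, seed = 93)$ct))

  s1 <- generate_sequences(cfg, seed = 94)
  s2 <- generate_sequences(cfg, seed = 94)
  expect_identical(s1$wt, s2$wt)
  expect_identical(s1$mt, s2$mt)

  p1 <- generate_reporter_plate(cfg, seed = 95)
  p2 <- generate_reporter_plate(cfg, seed = 95)
  expect_identical(p1$plate, p2$plate)
})

test_that("planted triads and only they survive the cascade", {
  for (seed in c(96, 97, 98)) {
    g <- generate_knowledge_base(synth_config(), seed = seed)
    res <- run_cascade(g$kb, g$screen_config)
    expect_same_triads(res$triads, g$manifest$triads)
    # and the result matches brute force on the same inputs
    expect_same_triads(res$triads, brute_force_triads(g$kb, g$screen_config))
  }
})

test_that("each decoy class is eliminated at its designed stage", {
  g <- generate_knowledge_base(synth_config(), seed = 99)
  res <- run_cascade(g$kb, g$screen_config)
  audit <- res$audit
  for (i in seq_len(nrow(g$manifest$decoys))) {
    d <- g$manifest$decoys[i, ]
    row <- audit[audit$entity_id == d$lncrna_id, ]
    expect_identical(nrow(row), 1L, info = d$mode)
    expect_identical(row$stage, d$designed_stage, info = d$mode)
  }
})

test_that("a zero-plant zero-decoy config yields an empty cascade", {
  g <- generate_knowledge_base(synth_config(n_planted_triads = 0,
                                            decoy_modes = character(),
                                            n_background_mirnas = 5), seed = 100)
  g$screen_config$pd_gene_set <- "G-NONE"   # stage E needs a non-empty set
  res <- run_cascade(g$kb, g$screen_config)
  expect_identical(nrow(res$triads), 0L)
})

test_that("the Ct study design matches the emulated cohort", {
  d <- generate_ct_dataset(synth_config(), seed = 111)
  s <- d$samples
  expect_identical(sum(s$group == "control"), 20L)
  expect_identical(sum(s$group == "PD"), 38L)
  expect_identical(unname(table(s$stage)[c("I", "II", "III", "IV")]),
                   table(factor(c(rep("I", 10), rep("II", 17), rep("III", 10),
                                  "IV")))[c("I", "II", "III", "IV")],
                   ignore_attr = TRUE)
  expect_identical(sum(s$stage_class == "early"), 27L)
  expect_identical(sum(s$stage_class == "late"), 11L)
  expect_true(all(s$stage[s$group == "control"] == "none"))
  expect_true(all(s$moca_score >= 26))
  expect_true(all(is.na(s$updrs_percent[s$group == "control"])))
  expect_true(all(s$updrs_percent[s$stage == "I"] < 25, na.rm = TRUE))
  expect_true(all(s$updrs_percent[s$stage == "III"] > 50, na.rm = TRUE))
  # three replicates per (sample, gene); Ct in range
  tab <- table(d$ct$sample_id, d$ct$gene_id)
  expect_true(all(tab == 3))
  expect_true(all(d$ct$ct > 0 & d$ct$ct <= 45))
})

test_that("metadata distributions center near the reported subgroup summaries", {
  set.seed(1)
  ages <- replicate(40, {
    d <- generate_ct_dataset(synth_config(), seed = sample.int(1e6, 1))
    mean(d$samples$age[d$samples$group == "PD"])
  })
  demo <- demo_demographics()
  expect_lt(abs(mean(ages) - demo$age_mean[demo$group == "PD"]), 2)
})

test_that("generated wild-type carries exactly the manifest site and the mutant none", {
  for (seed in c(112, 113)) {
    sq <- generate_sequences(synth_config(), seed = seed)
    s <- find_seed_sites(sq$mirna, sq$wt)
    expect_identical(nrow(s), 1L)
    expect_identical(s$start, sq$manifest$start)
    expect_identical(s$end, sq$manifest$end)
    expect_identical(s$site_class, sq$manifest$site_class)
    expect_identical(nrow(find_seed_sites(sq$mirna, sq$mt)), 0L)
    expect_true(verify_mutant_disruption(sq$wt, sq$mt, sq$mirna)$verdict)
    expect_identical(nchar(sq$wt), 140L)
  }
})

test_that("invalid configurations are rejected", {
  expect_error(synth_config(inhibition = c(WT = 1.0)), "\\[0, 1\\)")
  expect_error(synth_config(biological_sd = -1), "SDs")
  expect_error(synth_config(site_class = "9mer"), "site_class")
  expect_error(generate_ct_dataset(synth_config(
    group_sizes = c(control = 0, stage1 = 0, stage2 = 0, stage3 = 0, stage4 = 0)),
    seed = 1), "empty design")
  expect_error(generate_knowledge_base(synth_config(), ), "seed is mandatory")
})
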