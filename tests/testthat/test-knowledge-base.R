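test_that("write/load round-trips every table of a generated knowledge base", {
  g <- generate_knowledge_base(synth_config(), seed = 101)
  dir <- file.path(tempdir(), "kb_roundtrip")
  write_knowledge_base(g$kb, dir)
  kb2 <- load_knowledge_base(dir)
  for (tb in c("mirnas", "mirna_lncrna", "mirna_gene", "lncrna_gene",
               "loci", "tissues", "diseases")) {
    a <- g$kb[[tb]]; b <- kb2[[tb]]
    b <- b[names(a)]
    for (cn in names(a)) {
      if (is.numeric(a[[cn]])) {
        expect_equal(as.numeric(b[[cn]]), as.numeric(a[[cn]]),
                     tolerance = 1e-12, info = paste(tb, cn))
      } else {
        expect_identical(as.character(b[[cn]]), as.character(a[[cn]]),
                         info = paste(tb, cn))
      }
    }
  }
  expect_equal(kb2$provenance$n_rows,
               vapply(c("mirnas", "mirna_lncrna", "mirna_gene", "lncrna_gene",
                        "loci", "tissues", "diseases"),
                      function(tb) nrow(g$kb[[tb]]), integer(1)),
               ignore_attr = TRUE)
  unlink(dir, recursive = TRUE)
})

test_that("loading an empty directory fails naming the missing tables", {
  dir <- file.path(tempdir(), "kb_empty")
  dir.create(dir, showWarnings = FALSE)
  expect_error(load_knowledge_base(dir), "missing table")
  unlink(dir, recursive = TRUE)
})

test_that("out-of-range scores are rejected naming the offending row", {
  g <- generate_knowledge_base(synth_config(), seed = 102)
  kb <- g$kb
  bad <- kb$mirna_lncrna
  bad$score[1] <- 1.3
  expect_error(
    knowledge_base(kb$mirnas, bad, kb$mirna_gene, kb$lncrna_gene,
                   kb$loci, kb$tissues, kb$diseases),
    "score out of \\[0,1\\].*row")
  bad2 <- kb$mirna_gene
  bad2$prediction_score[1] <- -5
  expect_error(
    knowledge_base(kb$mirnas, kb$mirna_lncrna, bad2, kb$lncrna_gene,
                   kb$loci, kb$tissues, kb$diseases),
    "prediction_score out of \\[0,100\\]")
})

test_that("malformed numeric fields are reported with file, line and column", {
  g <- generate_knowledge_base(synth_config(), seed = 103)
  dir <- file.path(tempdir(), "kb_malformed")
  write_knowledge_base(g$kb, dir)
  lines <- readLines(file.path(dir, "mirna_lncrna.tsv"))
  parts <- strsplit(lines[3], "\t")[[1]]
  parts[3] <- "not-a-number"
  lines[3] <- paste(parts, collapse = "\t")
  writeLines(lines, file.path(dir, "mirna_lncrna.tsv"))
  expect_error(load_knowledge_base(dir),
               "mirna_lncrna\\.tsv.*line 3.*column 'score'")
  unlink(dir, recursive = TRUE)
})

test_that("duplicate primary keys are fatal and list the offenders", {
  g <- generate_knowledge_base(synth_config(), seed = 104)
  kb <- g$kb
  dup <- rbind(kb$mirnas, kb$mirnas[1, ])
  expect_error(
    knowledge_base(dup, kb$mirna_lncrna, kb$mirna_gene, kb$lncrna_gene,
                   kb$loci, kb$tissues, kb$diseases),
    paste0("duplicate primary key.*", kb$mirnas$mirna_id[1]))
})

test_that("validation reports referential gaps without raising", {
  expect_identical(nrow(validate_knowledge_base(demo_knowledge_base())), 0L)

  kb <- demo_knowledge_base()
  kb$mirna_lncrna <- rbind(kb$mirna_lncrna, data.frame(
    mirna_id = "hsa-miR-24-3p", lncrna_id = "LNC-ORPHAN", score = 0.9,
    assay = "immunoprecipitation", stringsAsFactors = FALSE))
  rep1 <- validate_knowledge_base(kb)
  expect_true(any(rep1$category == "missing_locus" & rep1$entity_id == "LNC-ORPHAN"))

  kb2 <- demo_knowledge_base()
  kb2$diseases <- rbind(kb2$diseases, kb2$diseases[1, ])
  rep2 <- validate_knowledge_base(kb2)
  expect_identical(sum(rep2$category == "duplicate_association"), 1L)

  kb3 <- demo_knowledge_base()
  kb3$mirna_gene$mirna_id[1] <- "mir-unknown"
  rep3 <- validate_knowledge_base(kb3)
  expect_true(any(rep3$category == "dangling_reference" &
                    rep3$entity_id == "mir-unknown"))
})

test_that("genomic gap follows the half-open convention", {
  l <- function(chrom, s, e) list(chrom = chrom, start = s, end = e)
  expect_identical(genomic_gap(l("chr1", 100, 200), l("chr1", 150, 300)), 0)
  expect_identical(genomic_gap(l("chr1", 0, 5), l("chr1", 5, 9)), 0)
  expect_identical(genomic_gap(l("chr1", 1000, 2000), l("chr1", 51999, 60000)), 49999)
  expect_identical(genomic_gap(l("chr1", 0, 10), l("chr2", 0, 10)), Inf)
  expect_error(genomic_gap(l("chr1", 10, 10), l("chr1", 0, 5)), "invalid interval")
})

test_that("genomic gap is symmetric and zero iff intervals touch", {
  set.seed(11)
  for (i in 1:50) {
    s1 <- sample(0:1000, 1); e1 <- s1 + sample(1:500, 1)
    s2 <- sample(0:1000, 1); e2 <- s2 + sample(1:500, 1)
    a <- list(chrom = "chrX", start = s1, end = e1)
    b <- list(chrom = "chrX", start = s2, end = e2)
    gap <- genomic_gap(a, b)
    expect_identical(gap, genomic_gap(b, a))
    touching <- (s1 <= e2) && (s2 <= e1)
    expect_identical(gap == 0, touching)
  }
})
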