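# Independent oracles and fixture builders, deliberately structured as
# single-pass brute-force evaluations so they share no code path with the
# staged implementations they check.

# Brute-force cascade: evaluate the conjunction of all stage predicates over
# every (lncRNA, miRNA, gene) combination in one pass.
brute_force_triads <- function(kb, cfg) {
  splitset <- function(x) if (is.na(x) || !nzchar(x)) character() else
    trimws(strsplit(x, ",", fixed = TRUE)[[1]])

  strong_mirnas <- kb$mirnas$mirna_id[vapply(seq_len(nrow(kb$mirnas)), function(i) {
    isTRUE(kb$mirnas$pd_related[i]) &&
      length(intersect(splitset(kb$mirnas$evidence_methods[i]),
                       cfg$strong_evidence_methods)) > 0
  }, logical(1))]

  il <- kb$mirna_lncrna
  pass_score <- if (cfg$apply_lncbase_gate) il$score > cfg$min_lncbase_score else
    rep(TRUE, nrow(il))
  good_edge <- il$mirna_id %in% strong_mirnas & pass_score

  tissue_ok <- function(L) {
    i <- match(L, kb$tissues$entity_id)
    !is.na(i) && all(cfg$required_tissues %in% splitset(kb$tissues$tissues[i]))
  }
  known_pd <- unique(kb$diseases$entity_id[
    kb$diseases$disease == cfg$pd_disease_label & kb$diseases$source == "literature"])
  excluded <- unique(kb$diseases$entity_id[
    kb$diseases$disease %in% cfg$excluded_disease_labels])
  degree_of <- function(L) length(unique(il$mirna_id[good_edge & il$lncrna_id == L]))
  locus_of <- function(id) {
    i <- match(id, kb$loci$name)
    if (is.na(i)) NULL else list(chrom = kb$loci$chrom[i],
                                 start = kb$loci$start[i], end = kb$loci$end[i])
  }
  gap_of <- function(a, b) {
    if (is.null(a) || is.null(b)) return(Inf)
    if (a$chrom != b$chrom) return(Inf)
    max(0, max(a$start, b$start) - min(a$end, b$end))
  }
  mg <- kb$mirna_gene
  gene_pass <- if (cfg$apply_gene_score_gate)
    mg$prediction_score > cfg$min_gene_prediction_score else rep(TRUE, nrow(mg))

  out <- list()
  for (L in unique(il$lncrna_id)) {
    if (!tissue_ok(L)) next
    if (L %in% known_pd || L %in% excluded) next
    if (degree_of(L) < cfg$min_mirna_degree) next
    mirnas_L <- unique(il$mirna_id[good_edge & il$lncrna_id == L])
    if (!length(mirnas_L)) next
    # the lncRNA must also be linked (via any of its miRNAs) to a key gene
    linked <- any(mg$mirna_id %in% mirnas_L & gene_pass & mg$gene_id %in% cfg$pd_gene_set)
    if (!linked) next
    for (m in mirnas_L) {
      rows <- which(mg$mirna_id == m & gene_pass & mg$gene_id %in% cfg$pd_gene_set)
      for (j in rows) {
        G <- mg$gene_id[j]
        if (gap_of(locus_of(L), locus_of(G)) < cfg$max_cis_gap_bp) {
          out[[length(out) + 1L]] <- data.frame(
            lncrna_id = L, mirna_id = m, gene_id = G, stringsAsFactors = FALSE)
        }
      }
    }
  }
  res <- if (length(out)) unique(do.call(rbind, out)) else
    data.frame(lncrna_id = character(), mirna_id = character(),
               gene_id = character(), stringsAsFactors = FALSE)
  res <- res[order(res$lncrna_id, res$mirna_id, res$gene_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Small random knowledge base (no planting): random entities, interactions,
# annotations; used for the cascade-equals-brute-force property.
random_kb <- function(seed, n_mirna = 8, n_lnc = 8, n_gene = 6) {
  set.seed(seed)
  methods_pool <- c("reporter-assay", "western-blot", "qPCR", "microarray",
                    "sequencing")
  mirnas <- data.frame(
    mirna_id = sprintf("m%02d", seq_len(n_mirna)),
    evidence_methods = vapply(seq_len(n_mirna), function(i)
      paste(sample(methods_pool, sample(0:3, 1)), collapse = ","), character(1)),
    pd_related = runif(n_mirna) < 0.7, stringsAsFactors = FALSE)
  lnc <- sprintf("L%02d", seq_len(n_lnc))
  genes <- sprintf("G%02d", seq_len(n_gene))
  n_il <- sample(5:(n_mirna * n_lnc / 2), 1)
  il <- unique(data.frame(
    mirna_id = sample(mirnas$mirna_id, n_il, replace = TRUE),
    lncrna_id = sample(lnc, n_il, replace = TRUE), stringsAsFactors = FALSE))
  il$score <- round(runif(nrow(il), 0.4, 1.0), 3)
  il$assay <- "immunoprecipitation"
  n_mg <- sample(4:(n_mirna * n_gene / 2), 1)
  mg <- unique(data.frame(
    mirna_id = sample(mirnas$mirna_id, n_mg, replace = TRUE),
    gene_id = sample(genes, n_mg, replace = TRUE), stringsAsFactors = FALSE))
  mg$prediction_score <- round(runif(nrow(mg), 50, 100), 1)
  lg <- data.frame(lncrna_id = character(), gene_id = character(),
                   n_predicted_interactions = integer(), stringsAsFactors = FALSE)
  ids <- c(lnc, genes)
  with_locus <- sample(ids, ceiling(length(ids) * 0.85))
  loci <- data.frame(
    chrom = sample(c("chr1", "chr2", "chr3"), length(with_locus), replace = TRUE),
    start = floor(runif(length(with_locus), 0, 3e5)), stringsAsFactors = FALSE)
  loci$end <- loci$start + floor(runif(length(with_locus), 1e3, 6e4))
  loci$name <- with_locus
  loci$score <- "0"
  loci$strand <- sample(c("+", "-", "."), length(with_locus), replace = TRUE)
  loci <- loci[c("chrom", "start", "end", "name", "score", "strand")]
  tissue_pool <- c("blood", "brain", "liver", "muscle")
  tis_ids <- sample(lnc, ceiling(n_lnc * 0.8))
  tissues <- data.frame(
    entity_id = tis_ids,
    tissues = vapply(tis_ids, function(i)
      paste(sample(tissue_pool, sample(1:3, 1)), collapse = ","), character(1)),
    stringsAsFactors = FALSE)
  disease_pool <- c("Parkinson disease", "Alzheimer disease", "epilepsy")
  n_d <- sample(0:4, 1)
  diseases <- data.frame(
    entity_id = sample(lnc, n_d, replace = TRUE),
    disease = sample(disease_pool, n_d, replace = TRUE),
    source = sample(c("literature", "database"), n_d, replace = TRUE),
    stringsAsFactors = FALSE)
  diseases <- unique(diseases)

  kb <- knowledge_base(mirnas, il, mg, lg, loci, tissues, diseases)
  cfg <- screen_config(pd_gene_set = sample(genes, max(2, n_gene %/% 2)),
                       min_mirna_degree = sample(1:2, 1))
  list(kb = kb, cfg = cfg)
}

# Window-by-window seed-site oracle: checks each candidate window by
# re-deriving Watson-Crick pairing base by base from the miRNA.
seed_scan_oracle <- function(mirna, target) {
  norm <- function(s) chartr("T", "U", toupper(s))
  m <- strsplit(norm(mirna), "")[[1]]
  t <- strsplit(norm(target), "")[[1]]
  wc <- c(A = "U", C = "G", G = "C", U = "A")
  n <- length(t)
  hits <- list()
  for (s in seq_len(max(0, n - 5))) {            # 1-based core start
    # core: target[s + k] must pair miRNA position 7 - k, k = 0..5
    core_ok <- all(vapply(0:5, function(k) t[s + k] == wc[[m[7 - k]]], logical(1)))
    if (!core_ok) next
    m8 <- s > 1 && t[s - 1] == wc[[m[8]]]
    a1 <- (s + 6) <= n && t[s + 6] == "A"
    cls <- if (m8 && a1) "8mer" else if (m8) "7mer-m8" else if (a1) "7mer-A1" else "6mer"
    st <- if (m8) s - 2L else s - 1L
    en <- if (a1) s + 6L else s + 5L
    hits[[length(hits) + 1L]] <- data.frame(start = st, end = en,
                                            site_class = cls,
                                            stringsAsFactors = FALSE)
  }
  if (!length(hits)) return(data.frame(start = integer(), end = integer(),
                                       site_class = character(),
                                       stringsAsFactors = FALSE))
  do.call(rbind, hits)
}

random_rna_str <- function(len) {
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
}

expect_same_triads <- function(a, b) {
  key <- function(d) sort(paste(d$lncrna_id, d$mirna_id, d$gene_id))
  expect_identical(key(a), key(b))
}
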