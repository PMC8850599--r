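# Packaged demonstration fixture: a hand-written reconstruction of the named
# entities and printed interaction scores of the Parkinson-disease ceRNA
# study this pipeline emulates, so the two headline triads are reproduced
# end-to-end without any database download.
#
# This is a RECONSTRUCTION, not a database snapshot: only the entity names
# and the printed scores (lncBase 0.79; target-prediction 88 and 93; the
# LncRRIsearch "two predicted interactions") are encoded. Genomic
# coordinates are synthetic illustrative values chosen to satisfy the cis
# criterion; the real loci of these genes are megabases apart and the
# fixture makes no claim about them.

#' Demonstration knowledge base (reconstruction)
#'
#' Encodes the two Parkinson-disease ceRNA triads
#' (linc01128, hsa-miR-24-3p, ATP13A2) and (linc00938, hsa-miR-30c-5p,
#' LRRK2): both miRNAs strongly validated and disease-related, interaction
#' scores above the 0.7 gate (0.79 for miR-30c-5p/linc00938, the published
#' immunoprecipitation score), target-prediction scores 88
#' (miR-24-3p/ATP13A2) and 93 (miR-30c-5p/LRRK2), both lncRNAs expressed in
#' blood and brain, and synthetic cis-proximal loci (gaps of 30 kb and
#' 45 kb). Running [run_cascade()] with [demo_screen_config()] yields
#' exactly the two triads.
#'
#' @return A [knowledge_base()].
#' @examples
#' run_cascade(demo_knowledge_base(), demo_screen_config())
#' @export
demo_knowledge_base <- function() {
  strong <- join_tokens(c("reporter-assay", "western-blot", "qPCR"))
  knowledge_base(
    mirnas = data.frame(
      mirna_id = c("hsa-miR-24-3p", "hsa-miR-30c-5p", "hsa-miR-1-3p"),
      evidence_methods = c(strong, strong, "microarray"),
      pd_related = c(TRUE, TRUE, TRUE),
      stringsAsFactors = FALSE),
    mirna_lncrna = data.frame(
      mirna_id = c("hsa-miR-24-3p", "hsa-miR-30c-5p",
                   "hsa-miR-30c-5p", "hsa-miR-24-3p"),
      lncrna_id = c("linc01128", "linc01128", "linc00938", "linc00938"),
      score = c(0.75, 0.72, 0.79, 0.71),
      assay = "immunoprecipitation",
      stringsAsFactors = FALSE),
    mirna_gene = data.frame(
      mirna_id = c("hsa-miR-24-3p", "hsa-miR-30c-5p"),
      gene_id = c("ATP13A2", "LRRK2"),
      prediction_score = c(88, 93),
      stringsAsFactors = FALSE),
    lncrna_gene = data.frame(
      lncrna_id = c("linc01128", "linc00938"),
      gene_id = c("ATP13A2", "LRRK2"),
      n_predicted_interactions = c(2L, 0L),
      stringsAsFactors = FALSE),
    loci = data.frame(
      chrom = c("chr1", "chr1", "chr12", "chr12"),
      start = c(100000, 160000, 500000, 565000),
      end = c(130000, 200000, 520000, 600000),
      name = c("linc01128", "ATP13A2", "linc00938", "LRRK2"),
      score = "0", strand = c("+", "-", "+", "+"),
      stringsAsFactors = FALSE),
    tissues = data.frame(
      entity_id = c("linc01128", "linc00938"),
      tissues = join_tokens(c("blood", "brain")),
      stringsAsFactors = FALSE),
    diseases = data.frame(
      entity_id = c("ATP13A2", "LRRK2"),
      disease = "Parkinson disease", source = "database",
      stringsAsFactors = FALSE)
  )
}

#' Screening configuration matching the demonstration fixture
#'
#' Default thresholds with the disease gene set holding the two key
#' Parkinson genes of the fixture.
#'
#' @return A [screen_config()].
#' @export
demo_screen_config <- function() {
  screen_config(pd_gene_set = c("ATP13A2", "LRRK2"))
}

#' Reported demographic summaries of the emulated study (reconstruction)
#'
#' Subgroup sizes and demographic summary statistics of the emulated
#' case-control design: 20 controls, 38 patients split 27 early-stage /
#' 11 late-stage, with subgroup means and SDs for age (years), disease
#' duration (months) and BMI, plus male/female counts. These values
#' parameterize the metadata model of [generate_ct_dataset()] and feed the
#' internal-consistency checks (the pooled patient mean must equal the
#' n-weighted subgroup means via [pooled_mean()]).
#'
#' @return data.frame with one row per group (`control`, `PD`, `early`,
#'   `late`).
#' @export
demo_demographics <- function() {
  data.frame(
    group = c("control", "PD", "early", "late"),
    n = c(20L, 38L, 27L, 11L),
    n_male = c(10L, 21L, 15L, 6L),
    n_female = c(10L, 17L, 12L, 5L),
    age_mean = c(59.45, 64.45, 65.11, 62.82),
    age_sd = c(8.15, 10.96, 10.40, 12.59),
    duration_mean = c(NA, 59.90, 43.85, 99.27),
    duration_sd = c(NA, 54.39, 31.69, 77.04),
    bmi_mean = c(27.57, 25.86, 26.05, 25.38),
    bmi_sd = c(5.55, 4.22, 4.60, 3.24),
    stringsAsFactors = FALSE)
}

#' Two-miRNA target table reproducing the published network arithmetic
#'
#' Builds a miRNA-target interaction table in which one miRNA targets 131
#' genes, the other 34, with exactly 5 shared targets named as in the
#' published network (IL1A, LHFPL2, EPHB2, NEFM, C9orf79); the remaining
#' target identifiers are synthetic. [build_network()] over this table
#' yields 162 nodes (2 miRNAs + 160 distinct genes) and 165 edges.
#'
#' @param n_targets_1,n_targets_2 Per-miRNA target counts (defaults 131
#'   and 34).
#' @param common Shared target gene ids (default the five published names).
#' @return data.frame `mirna_id`, `gene_id`.
#' @export
demo_mirna_target_table <- function(n_targets_1 = 131, n_targets_2 = 34,
                                    common = c("IL1A", "LHFPL2", "EPHB2",
                                               "NEFM", "C9orf79")) {
  k <- length(common)
  assert_that(n_targets_1 >= k && n_targets_2 >= k,
              "target counts must be >= number of common genes")
  own1 <- sprintf("G30C-%03d", seq_len(n_targets_1 - k))
  own2 <- sprintf("G24-%03d", seq_len(n_targets_2 - k))
  data.frame(
    mirna_id = c(rep("hsa-miR-30c-5p", n_targets_1), rep("hsa-miR-24-3p", n_targets_2)),
    gene_id = c(own1, common, own2, common),
    stringsAsFactors = FALSE)
}
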