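#' Screening-cascade configuration
#'
#' Bundles every numeric threshold and label set the triad-screening cascade
#' consumes. No stage of the cascade carries a numeric literal of its own:
#' all gates are read from this object, so a screen is fully described by
#' its knowledge base plus one `screen_config`.
#'
#' @param min_lncbase_score Minimum miRNA-lncRNA interaction score
#'   (scale 0-1); the gate is strict, a candidate passes only with
#'   `score > min_lncbase_score`. Default 0.7.
#' @param required_tissues Tissue labels an lncRNA must all carry to pass the
#'   tissue filter. Default `c("blood", "brain")`.
#' @param min_mirna_degree Minimum number of cascade-surviving miRNAs an
#'   lncRNA must interact with (candidates below are removed). Default 2.
#' @param min_gene_prediction_score Minimum miRNA-mRNA prediction score
#'   (scale 0-100), strict gate. Default 80.
#' @param max_cis_gap_bp Maximum genomic gap (bp) between the lncRNA gene and
#'   the protein-coding gene for a cis-proximal pair; strict
#'   (`gap < max_cis_gap_bp`). Default 50000.
#' @param strong_evidence_methods Evidence-method whitelist defining "strong
#'   experimental validation" of a miRNA record. Default
#'   `c("reporter-assay", "western-blot", "qPCR")`.
#' @param excluded_disease_labels Disease labels whose association disqualifies
#'   an lncRNA in the specificity filter (other neurodegenerative diseases).
#' @param pd_gene_set Gene identifiers regarded as key disease genes; the gene
#'   vertex of every triad must belong to this set.
#' @param pd_disease_label Disease label whose literature-sourced associations
#'   define "already known disease lncRNAs" removed by the cascade.
#'   Default "Parkinson disease".
#' @param apply_lncbase_gate,apply_gene_score_gate Switches to disable the
#'   interaction-score gates (the screen then keeps all interactions of the
#'   corresponding table) while leaving the stage structure intact.
#' @return An object of class `screen_config` (a validated named list).
#' @seealso [read_screen_config()], [run_cascade()]
#' @export
screen_config <- function(min_lncbase_score = 0.7,
                          required_tissues = c("blood", "brain"),
                          min_mirna_degree = 2L,
                          min_gene_prediction_score = 80,
                          max_cis_gap_bp = 50000L,
                          strong_evidence_methods = c("reporter-assay", "western-blot", "qPCR"),
                          excluded_disease_labels = c("Alzheimer disease",
                                                      "Amyotrophic lateral sclerosis",
                                                      "Huntington disease"),
                          pd_gene_set = character(),
                          pd_disease_label = "Parkinson disease",
                          apply_lncbase_gate = TRUE,
                          apply_gene_score_gate = TRUE) {
  cfg <- list(
    min_lncbase_score = as.numeric(min_lncbase_score),
    required_tissues = as.character(required_tissues),
    min_mirna_degree = as.integer(min_mirna_degree),
    min_gene_prediction_score = as.numeric(min_gene_prediction_score),
    max_cis_gap_bp = as.numeric(max_cis_gap_bp),
    strong_evidence_methods = as.character(strong_evidence_methods),
    excluded_disease_labels = as.character(excluded_disease_labels),
    pd_gene_set = as.character(pd_gene_set),
    pd_disease_label = as.character(pd_disease_label)[1],
    apply_lncbase_gate = isTRUE(apply_lncbase_gate),
    apply_gene_score_gate = isTRUE(apply_gene_score_gate)
  )
  assert_that(cfg$min_lncbase_score >= 0 && cfg$min_lncbase_score <= 1,
              "min_lncbase_score must lie in [0, 1]")
  assert_that(cfg$min_gene_prediction_score >= 0 && cfg$min_gene_prediction_score <= 100,
              "min_gene_prediction_score must lie in [0, 100]")
  assert_that(cfg$max_cis_gap_bp > 0, "max_cis_gap_bp must be > 0")
  assert_that(cfg$min_mirna_degree >= 0, "min_mirna_degree must be >= 0")
  structure(cfg, class = "screen_config")
}

#' Read a screening configuration from a YAML file
#'
#' The YAML keys mirror the arguments of [screen_config()]; absent keys take
#' the defaults.
#'
#' @param path Path to a YAML file.
#' @return A `screen_config`.
#' @export
read_screen_config <- function(path) {
  assert_that(file.exists(path), sprintf("config file not found: %s", path))
  raw <- yaml::read_yaml(path)
  known <- names(formals(screen_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  do.call(screen_config, raw)
}

#' Write a screening configuration to YAML
#'
#' Inverse of [read_screen_config()].
#'
#' @param config A `screen_config`.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_screen_config <- function(config, path) {
  assert_that(inherits(config, "screen_config"), "not a screen_config")
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @export
print.screen_config <- function(x, ...) {
  cat("Triad screening configuration\n")
  cat(sprintf("  lncBase score gate        : > %.3g%s\n", x$min_lncbase_score,
              if (x$apply_lncbase_gate) "" else "  [disabled]"))
  cat(sprintf("  required tissues          : %s\n", join_tokens(x$required_tissues)))
  cat(sprintf("  min miRNA degree          : %d\n", x$min_mirna_degree))
  cat(sprintf("  gene prediction gate      : > %.3g%s\n", x$min_gene_prediction_score,
              if (x$apply_gene_score_gate) "" else "  [disabled]"))
  cat(sprintf("  max cis gap               : < %s bp\n",
              format(x$max_cis_gap_bp, big.mark = ",")))
  cat(sprintf("  strong evidence methods   : %s\n", join_tokens(x$strong_evidence_methods)))
  cat(sprintf("  excluded disease labels   : %s\n", join_tokens(x$excluded_disease_labels)))
  cat(sprintf("  disease gene set          : %d gene(s)\n", length(x$pd_gene_set)))
  invisible(x)
}
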