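# Seven-stage candidate-selection cascade producing lncRNA-miRNA-mRNA ceRNA
# triads with a per-stage audit trail.
#
# Stage order (fixed; it mirrors the screening narrative):
#   A strong_validation : disease-related miRNAs with strong experimental evidence
#   B lncbase_score     : miRNA -> lncRNA interactions above the score gate
#   C tissue            : lncRNAs expressed in every required tissue
#   D known_and_degree  : drop literature-known disease lncRNAs and low-degree ones
#   E pd_gene_link      : lncRNAs whose miRNAs hit a key disease gene above the gate
#   F specificity       : drop lncRNAs linked to other excluded diseases
#   G cis_pairing       : emit triads whose lncRNA/gene loci lie within the cis gap

cascade_stages <- c("strong_validation", "lncbase_score", "tissue",
                    "known_and_degree", "pd_gene_link", "specificity",
                    "cis_pairing")

#' Stage A: miRNAs with strong experimental validation
#'
#' Keeps miRNA records that are flagged disease-related and whose evidence
#' methods intersect the configured strong-evidence whitelist.
#'
#' @param mirna_records The `mirnas` table of a [knowledge_base()].
#' @param config A [screen_config()]; an empty `strong_evidence_methods`
#'   whitelist is a configuration error.
#' @return Character vector of surviving `mirna_id`s (input order).
#' @export
filter_strong_validation <- function(mirna_records, config) {
  assert_that(length(config$strong_evidence_methods) > 0,
              "configuration error: strong_evidence_methods whitelist is empty")
  if (!nrow(mirna_records)) return(character())
  keep <- vapply(seq_len(nrow(mirna_records)), function(i) {
    isTRUE(mirna_records$pd_related[i]) &&
      length(intersect(split_tokens(mirna_records$evidence_methods[i]),
                       config$strong_evidence_methods)) > 0
  }, logical(1))
  mirna_records$mirna_id[keep]
}

#' Stage B: map surviving miRNAs to candidate lncRNAs
#'
#' Retains interaction (m, l) iff `m` survived stage A and the interaction
#' score exceeds the lncBase gate (strict), then inverts to an lncRNA-keyed
#' mapping.
#'
#' @param mirna_ids Character vector of stage-A survivors.
#' @param interactions The `mirna_lncrna` table.
#' @param config A [screen_config()].
#' @return Named list: `lncrna_id` -> character vector of interacting
#'   `mirna_id`s.
#' @export
mirna_to_lncrna <- function(mirna_ids, interactions, config) {
  if (!length(mirna_ids) || !nrow(interactions)) return(structure(list(), names = character()))
  keep <- interactions$mirna_id %in% mirna_ids
  if (config$apply_lncbase_gate) {
    keep <- keep & interactions$score > config$min_lncbase_score
  }
  hits <- interactions[keep, , drop = FALSE]
  if (!nrow(hits)) return(structure(list(), names = character()))
  split(hits$mirna_id, hits$lncrna_id)
}

#' Stage C: tissue-expression filter
#'
#' Keeps entities whose recorded tissue set is a superset of the required
#' tissues. An entity with no tissue record fails (the filter is a positive
#' selection).
#'
#' @param lncrna_ids Character vector of candidate entity ids.
#' @param tissue_records The `tissues` table.
#' @param config A [screen_config()].
#' @return Surviving subset of `lncrna_ids`.
#' @export
filter_tissue <- function(lncrna_ids, tissue_records, config) {
  if (!length(lncrna_ids)) return(character())
  recorded <- stats::setNames(tissue_records$tissues, tissue_records$entity_id)
  keep <- vapply(lncrna_ids, function(id) {
    if (!id %in% names(recorded)) return(FALSE)
    all(config$required_tissues %in% split_tokens(recorded[[id]]))
  }, logical(1))
  lncrna_ids[keep]
}

#' Stage D: drop known disease lncRNAs and low-degree candidates
#'
#' Removes lncRNAs already reported as disease-related (the `pd_lncrna_set`)
#' and lncRNAs interacting with fewer than `min_mirna_degree` surviving
#' miRNAs. Degree is counted over the stage-A survivors carried in the
#' mapping, not over the whole interaction table.
#'
#' @param mapping lncRNA-keyed mapping from [mirna_to_lncrna()] (already
#'   tissue-filtered).
#' @param pd_lncrna_set Character vector of lncRNAs to exclude as already
#'   known.
#' @param config A [screen_config()].
#' @return The filtered mapping; survivors keep their full miRNA sets.
#' @export
exclude_known_and_low_degree <- function(mapping, pd_lncrna_set, config) {
  if (!length(mapping)) return(mapping)
  keep <- !(names(mapping) %in% pd_lncrna_set) &
    lengths(mapping) >= config$min_mirna_degree
  mapping[keep]
}

#' Stage E: require a strong link to a key disease gene
#'
#' Keeps lncRNA `L` iff some miRNA in `L`'s set has a target-prediction record
#' to a gene in `pd_gene_set` with score above the gate (strict).
#'
#' @param mapping lncRNA-keyed mapping of surviving candidates.
#' @param mirna_gene_table The `mirna_gene` table.
#' @param config A [screen_config()]; an empty `pd_gene_set` is a
#'   configuration error.
#' @return The filtered mapping.
#' @export
filter_pd_gene_link <- function(mapping, mirna_gene_table, config) {
  assert_that(length(config$pd_gene_set) > 0,
              "configuration error: pd_gene_set is empty")
  if (!length(mapping)) return(mapping)
  hits <- mirna_gene_table[mirna_gene_table$gene_id %in% config$pd_gene_set, ,
                           drop = FALSE]
  if (config$apply_gene_score_gate) {
    hits <- hits[hits$prediction_score > config$min_gene_prediction_score, ,
                 drop = FALSE]
  }
  linked_mirnas <- unique(hits$mirna_id)
  keep <- vapply(mapping, function(ms) any(ms %in% linked_mirnas), logical(1))
  mapping[keep]
}

#' Stage F: disease-specificity filter
#'
#' Removes any lncRNA carrying a disease association whose label belongs to
#' the excluded set (associations with other neurodegenerative diseases);
#' the survivors can be considered specific to the disease of interest.
#'
#' @param mapping lncRNA-keyed mapping of surviving candidates.
#' @param disease_associations The `diseases` table.
#' @param config A [screen_config()].
#' @return The filtered mapping.
#' @export
filter_specificity <- function(mapping, disease_associations, config) {
  if (!length(mapping) || !length(config$excluded_disease_labels)) return(mapping)
  flagged <- unique(disease_associations$entity_id[
    disease_associations$disease %in% config$excluded_disease_labels])
  mapping[!(names(mapping) %in% flagged)]
}

#' Stage G: cis-proximal triad pairing
#'
#' Emits a triad (L, m, G) iff `L` survived the prior stages, `m` belongs to
#' `L`'s miRNA set, the (m, G) prediction passes the gene-score gate with `G`
#' in the disease gene set, and the genomic gap between the loci of `L` and
#' `G` is strictly below `max_cis_gap_bp`. An entity without a locus cannot
#' pair (recorded in the audit trail by [run_cascade()], not an error).
#'
#' @param mapping lncRNA-keyed mapping of stage-F survivors.
#' @param loci The `loci` table.
#' @param config A [screen_config()].
#' @param mirna_gene_table The `mirna_gene` table.
#' @param mirna_lncrna_table Optional `mirna_lncrna` table used to attach the
#'   supporting interaction score to each triad.
#' @return data.frame of class `candidate_triads` with columns `lncrna_id`,
#'   `mirna_id`, `gene_id`, `lncbase_score`, `gene_prediction_score`,
#'   `cis_gap_bp`.
#' @export
pair_cis <- function(mapping, loci, config, mirna_gene_table,
                     mirna_lncrna_table = NULL) {
  assert_that(length(config$pd_gene_set) > 0,
              "configuration error: pd_gene_set is empty")
  out <- list()
  locus_of <- function(id) {
    i <- match(id, loci$name)
    if (is.na(i)) NULL else list(chrom = loci$chrom[i], start = loci$start[i],
                                 end = loci$end[i])
  }
  gene_hits <- mirna_gene_table[mirna_gene_table$gene_id %in% config$pd_gene_set, ,
                                drop = FALSE]
  if (config$apply_gene_score_gate) {
    gene_hits <- gene_hits[gene_hits$prediction_score > config$min_gene_prediction_score, ,
                           drop = FALSE]
  }
  for (L in names(mapping)) {
    locus_L <- locus_of(L)
    if (is.null(locus_L)) next
    for (m in mapping[[L]]) {
      rows <- gene_hits[gene_hits$mirna_id == m, , drop = FALSE]
      if (!nrow(rows)) next
      for (j in seq_len(nrow(rows))) {
        G <- rows$gene_id[j]
        locus_G <- locus_of(G)
        if (is.null(locus_G)) next
        gap <- genomic_gap(locus_L, locus_G)
        if (gap < config$max_cis_gap_bp) {
          sc <- NA_real_
          if (!is.null(mirna_lncrna_table)) {
            k <- which(mirna_lncrna_table$mirna_id == m &
                         mirna_lncrna_table$lncrna_id == L)
            if (length(k)) sc <- mirna_lncrna_table$score[k[1]]
          }
          out[[length(out) + 1L]] <- data.frame(
            lncrna_id = L, mirna_id = m, gene_id = G,
            lncbase_score = sc, gene_prediction_score = rows$prediction_score[j],
            cis_gap_bp = gap, stringsAsFactors = FALSE)
        }
      }
    }
  }
  triads <- if (length(out)) do.call(rbind, out) else
    data.frame(lncrna_id = character(), mirna_id = character(),
               gene_id = character(), lncbase_score = numeric(),
               gene_prediction_score = numeric(), cis_gap_bp = numeric(),
               stringsAsFactors = FALSE)
  triads <- triads[order(triads$lncrna_id, triads$mirna_id, triads$gene_id), ,
                   drop = FALSE]
  rownames(triads) <- NULL
  class(triads) <- c("candidate_triads", "data.frame")
  triads
}

#' Run the full seven-stage screening cascade
#'
#' Applies the six filters and the cis pairing in their fixed order, recording
#' per-stage survivor sets, per-stage counts, and an audit trail attributing
#' every eliminated entity to the first stage that removed it. Deterministic
#' given `(kb, config)`.
#'
#' The "already known disease lncRNA" removal set of stage D is derived from
#' the knowledge base itself: entities carrying a literature-sourced
#' association with `config$pd_disease_label`.
#'
#' @param kb A [knowledge_base()] (referential gaps permitted; entities
#'   lacking annotations fail the corresponding filter rather than erroring).
#' @param config A [screen_config()].
#' @return An object of class `cascade_result`: list with elements
#'   `stage_counts` (data.frame stage/entity_type/n), `survivors` (per-stage
#'   sets), `triads` (a `candidate_triads` frame), `audit` (data.frame
#'   entity_id/entity_type/stage/reason) and `config`.
#' @export
run_cascade <- function(kb, config = screen_config()) {
  assert_that(inherits(kb, "knowledge_base"), "kb must be a knowledge_base")
  audit <- list()
  note <- function(entity_id, entity_type, stage, reason) {
    if (!length(entity_id)) return(invisible(NULL))
    audit[[length(audit) + 1L]] <<- data.frame(
      entity_id = entity_id, entity_type = entity_type, stage = stage,
      reason = reason, stringsAsFactors = FALSE)
  }

  # A: strong validation
  mirnas_a <- filter_strong_validation(kb$mirnas, config)
  note(setdiff(kb$mirnas$mirna_id, mirnas_a), "miRNA", "strong_validation",
       "not disease-related with strong evidence")

  # B: score-gated interactions, inverted to lncRNA-keyed mapping
  map_b <- mirna_to_lncrna(mirnas_a, kb$mirna_lncrna, config)
  all_lnc <- unique(kb$mirna_lncrna$lncrna_id)
  note(setdiff(all_lnc, names(map_b)), "lncRNA", "lncbase_score",
       "no surviving interaction above score gate")

  # C: tissue filter
  keep_c <- filter_tissue(names(map_b), kb$tissues, config)
  note(setdiff(names(map_b), keep_c), "lncRNA", "tissue",
       "not expressed in all required tissues")
  map_c <- map_b[keep_c]

  # D: known disease lncRNAs + degree
  pd_lnc <- unique(kb$diseases$entity_id[
    kb$diseases$disease == config$pd_disease_label &
      kb$diseases$source == "literature"])
  map_d <- exclude_known_and_low_degree(map_c, pd_lnc, config)
  gone_d <- setdiff(names(map_c), names(map_d))
  known <- gone_d[gone_d %in% pd_lnc]
  note(known, "lncRNA", "known_and_degree", "already known disease lncRNA")
  note(setdiff(gone_d, known), "lncRNA", "known_and_degree",
       sprintf("fewer than %d interacting miRNAs", config$min_mirna_degree))

  # E: link to key disease gene
  map_e <- filter_pd_gene_link(map_d, kb$mirna_gene, config)
  note(setdiff(names(map_d), names(map_e)), "lncRNA", "pd_gene_link",
       "no miRNA link to a key disease gene above score gate")

  # F: specificity
  map_f <- filter_specificity(map_e, kb$diseases, config)
  note(setdiff(names(map_e), names(map_f)), "lncRNA", "specificity",
       "associated with an excluded disease")

  # G: cis pairing
  triads <- pair_cis(map_f, kb$loci, config, kb$mirna_gene, kb$mirna_lncrna)
  paired <- unique(triads$lncrna_id)
  for (L in setdiff(names(map_f), paired)) {
    reason <- if (!L %in% kb$loci$name) "no locus" else
      "no cis-proximal key gene within gap threshold"
    note(L, "lncRNA", "cis_pairing", reason)
  }

  audit_df <- if (length(audit)) do.call(rbind, audit) else
    data.frame(entity_id = character(), entity_type = character(),
               stage = character(), reason = character(), stringsAsFactors = FALSE)

  stage_counts <- data.frame(
    stage = cascade_stages,
    entity_type = c("miRNA", rep("lncRNA", 5), "triad"),
    n = c(length(mirnas_a), length(map_b), length(map_c), length(map_d),
          length(map_e), length(map_f), nrow(triads)),
    stringsAsFactors = FALSE
  )

  structure(list(
    stage_counts = stage_counts,
    survivors = list(strong_validation = mirnas_a,
                     lncbase_score = map_b, tissue = map_c,
                     known_and_degree = map_d, pd_gene_link = map_e,
                     specificity = map_f),
    triads = triads,
    audit = audit_df,
    config = config
  ), class = "cascade_result")
}

#' @export
print.cascade_result <- function(x, ...) {
  cat("ceRNA triad screening cascade\n")
  for (i in seq_len(nrow(x$stage_counts))) {
    cat(sprintf("  %s %-18s %4d %s\n", LETTERS[i], x$stage_counts$stage[i],
                x$stage_counts$n[i], x$stage_counts$entity_type[i]))
  }
  if (nrow(x$triads)) {
    cat("Final triads:\n")
    print.data.frame(x$triads, row.names = FALSE)
  } else {
    cat("No triads survived.\n")
  }
  invisible(x)
}

#' Write cascade outputs as TSV
#'
#' Writes `triads.tsv`, `stage_counts.tsv` and `audit.tsv` to a directory.
#'
#' @param result A `cascade_result`.
#' @param directory_path Output directory (created if absent).
#' @return The directory, invisibly.
#' @export
write_cascade_result <- function(result, directory_path) {
  assert_that(inherits(result, "cascade_result"), "not a cascade_result")
  if (!dir.exists(directory_path)) dir.create(directory_path, recursive = TRUE)
  write_tsv_plain(as.data.frame(result$triads), file.path(directory_path, "triads.tsv"))
  write_tsv_plain(result$stage_counts, file.path(directory_path, "stage_counts.tsv"))
  write_tsv_plain(result$audit, file.path(directory_path, "audit.tsv"))
  invisible(directory_path)
}
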