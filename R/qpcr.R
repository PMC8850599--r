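# Comparative-CT (delta-delta-Ct) relative quantification.
#
# Ct input is a long table: one row per (sample, gene, replicate) with the
# raw cycle-threshold value. Replicates are collapsed to an arithmetic mean
# with an SD-based QC flag, then each target marker is normalized to its
# reference gene(s) and to the baseline-group mean delta-Ct:
#   dCt  = Ct_target - mean(Ct_references)
#   ddCt = dCt_sample - mean(dCt over baseline group)
#   rq   = 2^(-ddCt)

#' Collapse technical qPCR replicates
#'
#' Arithmetic mean of the replicate Ct values per (sample, gene); entries
#' whose replicate standard deviation exceeds `max_replicate_sd` are flagged
#' for quality control but never dropped. A single replicate has undefined
#' SD and is left unflagged.
#'
#' @param measurements data.frame with columns `sample_id`, `gene_id`, `ct`
#'   (cycles; each Ct must lie in (0, 45\]) and optionally `replicate`,
#'   `plate_id`.
#' @param max_replicate_sd QC threshold on the replicate SD, in cycles
#'   (default 0.5).
#' @return data.frame `sample_id`, `gene_id`, `ct_mean`, `ct_sd`,
#'   `n_replicates`, `qc_flag`.
#' @export
collapse_replicates <- function(measurements, max_replicate_sd = 0.5) {
  need <- c("sample_id", "gene_id", "ct")
  missing <- setdiff(need, names(measurements))
  assert_that(length(missing) == 0,
              sprintf("measurements lack column(s): %s", paste(missing, collapse = ", ")))
  assert_that(nrow(measurements) > 0, "no replicate measurements supplied")
  ct <- as.numeric(measurements$ct)
  assert_that(all(is.finite(ct)) && all(ct > 0 & ct <= 45),
              "Ct values must lie in (0, 45] cycles")

  key <- interaction(measurements$sample_id, measurements$gene_id, drop = TRUE,
                     lex.order = TRUE)
  # tapply orders by factor level; align the id columns to that order
  idx_first <- match(levels(key), as.character(key))
  out <- data.frame(
    sample_id = measurements$sample_id[idx_first],
    gene_id = measurements$gene_id[idx_first],
    ct_mean = as.vector(tapply(ct, key, mean)),
    ct_sd = as.vector(tapply(ct, key, function(v) if (length(v) > 1) stats::sd(v) else NA_real_)),
    n_replicates = as.vector(tapply(ct, key, length)),
    stringsAsFactors = FALSE
  )
  out$qc_flag <- !is.na(out$ct_sd) & out$ct_sd > max_replicate_sd
  rownames(out) <- NULL
  out
}

#' Default marker-to-reference mapping
#'
#' Standard practice for mixed panels: miRNA markers normalize to the small
#' nuclear RNA U6; mRNA and lncRNA markers normalize to the mean of GAPDH
#' and 18S.
#'
#' @param markers Character vector of marker gene ids.
#' @return Named list mapping each marker to its reference gene id(s).
#' @export
default_reference_map <- function(markers) {
  stats::setNames(lapply(markers, function(m) {
    if (grepl("^(hsa-)?mir", m, ignore.case = TRUE)) "U6" else c("GAPDH", "18S")
  }), markers)
}

#' Comparative-CT relative expression
#'
#' Computes delta-Ct against the (arithmetic) mean of each marker's reference
#' genes, delta-delta-Ct against the baseline-group mean delta-Ct, and the
#' fold change `rq = 2^(-ddCt)`. By construction the geometric mean of `rq`
#' over the baseline group is exactly 1.
#'
#' @param ct_table Collapsed Ct table from [collapse_replicates()] (columns
#'   `sample_id`, `gene_id`, `ct_mean`).
#' @param samples data.frame of sample metadata with columns `sample_id`,
#'   `group`.
#' @param reference_map Named list mapping each marker to its reference gene
#'   id(s); defaults to [default_reference_map()] over the non-reference
#'   genes present.
#' @param baseline_group Group label whose mean delta-Ct anchors
#'   delta-delta-Ct (default `"control"`).
#' @return data.frame of class `relative_expression`: `sample_id`, `gene_id`,
#'   `delta_ct`, `delta_delta_ct`, `rq`, `reference_genes`.
#' @export
relative_expression <- function(ct_table, samples, reference_map = NULL,
                                baseline_group = "control") {
  need <- c("sample_id", "gene_id", "ct_mean")
  assert_that(all(need %in% names(ct_table)),
              "ct_table needs columns sample_id, gene_id, ct_mean")
  assert_that(all(c("sample_id", "group") %in% names(samples)),
              "samples needs columns sample_id, group")
  baseline_ids <- samples$sample_id[samples$group == baseline_group]
  assert_that(length(baseline_ids) > 0,
              sprintf("no samples in baseline group '%s'", baseline_group))

  genes <- unique(ct_table$gene_id)
  if (is.null(reference_map)) {
    refs_present <- intersect(c("U6", "GAPDH", "18S"), genes)
    reference_map <- default_reference_map(setdiff(genes, refs_present))
  }

  ct_of <- function(sample, gene) {
    i <- which(ct_table$sample_id == sample & ct_table$gene_id == gene)
    if (length(i)) ct_table$ct_mean[i[1]] else NA_real_
  }

  rows <- list()
  for (marker in names(reference_map)) {
    refs <- reference_map[[marker]]
    sample_ids <- unique(ct_table$sample_id[ct_table$gene_id == marker])
    dct <- vapply(sample_ids, function(s) {
      ref_ct <- vapply(refs, function(g) ct_of(s, g), numeric(1))
      ref_ct <- ref_ct[is.finite(ref_ct)]
      if (!length(ref_ct)) {
        stop(sprintf("sample '%s' lacks every reference gene (%s) for marker '%s'",
                     s, join_tokens(refs), marker), call. = FALSE)
      }
      ct_of(s, marker) - mean(ref_ct)
    }, numeric(1))
    base <- dct[sample_ids %in% baseline_ids]
    assert_that(length(base) > 0 && all(is.finite(base)),
                sprintf("marker '%s': no baseline-group delta-Ct available", marker))
    ddct <- dct - mean(base)
    rows[[marker]] <- data.frame(
      sample_id = sample_ids, gene_id = marker,
      delta_ct = unname(dct), delta_delta_ct = unname(ddct),
      rq = 2^(-unname(ddct)),
      reference_genes = join_tokens(refs), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("relative_expression", "data.frame")
  out
}
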