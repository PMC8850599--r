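# Per-marker statistical report: group summaries (mean +/- SEM), the four
# standard comparisons of a two-stage case-control design (control vs all
# patients; control / early / late omnibus plus pairwise post hoc), ROC
# biomarker evaluation and an up/down direction call.

#' Assemble the per-marker expression report
#'
#' For every marker present in the relative-expression table: group
#' summaries (n, mean, SEM of `rq`), the adaptive two-group comparison
#' control vs patients, the three-group (control / early / late) omnibus and
#' pairwise post hoc comparisons, the ROC result for control vs patients,
#' and a direction call (`"up"`/`"down"` in patients by median fold change).
#' Samples whose `stage_class` is `none` (the controls) form the control arm
#' of the staged comparison.
#'
#' @param rel_expr A [relative_expression()] table.
#' @param sample_meta data.frame with `sample_id`, `group`
#'   (`control`/`PD`), `stage_class` (`early`/`late`/`none`).
#' @param config A [qpcr_config()]; with `p_adjust = "BH"` the
#'   control-vs-patient p-values are Benjamini-Hochberg corrected across
#'   markers.
#' @param control_group,case_group Group labels (defaults `control`, `PD`).
#' @return Object of class `marker_report`: list with `summaries`,
#'   `comparisons` (both data.frames over all markers), `roc` (named list of
#'   [roc_curve()] results), `directions` (named character vector).
#' @export
marker_report <- function(rel_expr, sample_meta, config = qpcr_config(),
                          control_group = "control", case_group = "PD") {
  assert_that(all(c("sample_id", "group", "stage_class") %in% names(sample_meta)),
              "sample_meta needs sample_id, group, stage_class")
  markers <- unique(rel_expr$gene_id)
  if (!length(markers)) {
    return(structure(list(
      summaries = data.frame(marker_id = character(), group = character(),
                             n = integer(), mean_rq = numeric(), sem_rq = numeric()),
      comparisons = data.frame(marker_id = character(), comparison = character(),
                               test_name = character(), statistic = numeric(),
                               p_value = numeric(), effect = numeric(),
                               ci_low = numeric(), ci_high = numeric(),
                               significant = logical()),
      roc = list(), directions = character()), class = "marker_report"))
  }
  summaries <- list(); comparisons <- list(); rocs <- list(); directions <- character()

  grp_of <- stats::setNames(sample_meta$group, sample_meta$sample_id)
  stage_of <- stats::setNames(sample_meta$stage_class, sample_meta$sample_id)

  for (marker in markers) {
    sub <- rel_expr[rel_expr$gene_id == marker, , drop = FALSE]
    rq <- stats::setNames(sub$rq, sub$sample_id)
    g <- grp_of[names(rq)]
    sc <- stage_of[names(rq)]

    two <- list(rq[g == control_group], rq[g == case_group])
    names(two) <- c("Controls", "PD")
    three <- list(rq[g == control_group], rq[sc == "early"], rq[sc == "late"])
    names(three) <- c("Controls", "Early stage", "Late stage")

    for (lab in names(three)) {
      v <- three[[lab]]
      summaries[[paste(marker, lab)]] <- data.frame(
        marker_id = marker, group = lab, n = length(v), mean_rq = mean(v),
        sem_rq = stats::sd(v) / sqrt(length(v)), stringsAsFactors = FALSE)
    }

    cmp2 <- compare_groups(two, config)
    cmp2$comparison <- "Controls vs. PD"
    cmp3 <- compare_groups(three, config)
    cmp <- rbind(cmp2, cmp3)
    cmp <- cbind(marker_id = marker, cmp, stringsAsFactors = FALSE)
    comparisons[[marker]] <- cmp

    rocs[[marker]] <- roc_curve(rq, g == case_group)
    directions[[marker]] <-
      if (stats::median(two$PD) >= stats::median(two$Controls)) "up" else "down"
  }

  comparisons <- do.call(rbind, comparisons)
  rownames(comparisons) <- NULL
  if (config$p_adjust == "BH") {
    main <- comparisons$comparison == "Controls vs. PD"
    comparisons$p_value[main] <- stats::p.adjust(comparisons$p_value[main], "BH")
    comparisons$significant[main] <- comparisons$p_value[main] < config$alpha
  }
  summaries <- do.call(rbind, summaries)
  rownames(summaries) <- NULL

  structure(list(summaries = summaries, comparisons = comparisons,
                 roc = rocs, directions = directions),
            class = "marker_report")
}

#' @export
print.marker_report <- function(x, ...) {
  cat("Marker expression report\n\nGroup summaries (mean rq +/- SEM):\n")
  print.data.frame(x$summaries, row.names = FALSE, digits = 4)
  cat("\nComparisons:\n")
  print.data.frame(x$comparisons, row.names = FALSE, digits = 4)
  cat("\nROC AUC:\n")
  for (m in names(x$roc)) {
    cat(sprintf("  %-16s AUC %.4f  direction in cases: %s\n", m, x$roc[[m]]$auc,
                x$directions[[m]]))
  }
  invisible(x)
}

#' Serialize a marker report
#'
#' Writes `summaries.tsv`, `comparisons.tsv`, `roc.tsv` (marker, AUC,
#' orientation, n) and a combined `report.json`.
#'
#' @param report A `marker_report`.
#' @param directory_path Output directory (created if absent).
#' @return The directory, invisibly.
#' @export
write_marker_report <- function(report, directory_path) {
  assert_that(inherits(report, "marker_report"), "not a marker_report")
  if (!dir.exists(directory_path)) dir.create(directory_path, recursive = TRUE)
  write_tsv_plain(report$summaries, file.path(directory_path, "summaries.tsv"))
  write_tsv_plain(report$comparisons, file.path(directory_path, "comparisons.tsv"))
  roc_df <- do.call(rbind, lapply(names(report$roc), function(m) {
    r <- report$roc[[m]]
    data.frame(marker_id = m, auc = r$auc, flipped = r$flipped,
               n_case = r$n_case, n_control = r$n_control,
               direction = report$directions[[m]], stringsAsFactors = FALSE)
  }))
  if (is.null(roc_df)) roc_df <- data.frame()
  write_tsv_plain(roc_df, file.path(directory_path, "roc.tsv"))
  jsonlite::write_json(
    list(summaries = report$summaries, comparisons = report$comparisons,
         roc = roc_df, directions = as.list(report$directions)),
    file.path(directory_path, "report.json"),
    dataframe = "rows", auto_unbox = TRUE, pretty = TRUE, na = "null")
  invisible(directory_path)
}
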