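# In-memory model and TSV I/O for the seven annotation/interaction tables the
# screening cascade consumes, plus genomic-interval gap arithmetic.
#
# Table dialect: UTF-8, tab-separated, header row, no quoting; set-valued
# fields (evidence methods, tissue labels) are comma-joined tokens. Loci use
# BED-compatible columns (chrom/start/end/name/score/strand) with 0-based
# half-open coordinates.

kb_table_files <- c(
  mirnas       = "mirnas.tsv",
  mirna_lncrna = "mirna_lncrna.tsv",
  mirna_gene   = "mirna_gene.tsv",
  lncrna_gene  = "lncrna_gene.tsv",
  loci         = "loci.tsv",
  tissues      = "tissues.tsv",
  diseases     = "diseases.tsv"
)

#' Construct a knowledge base from its seven tables
#'
#' Validates the row-level invariants of each table (score ranges, interval
#' sanity, primary-key uniqueness) and assembles the typed bundle consumed by
#' [run_cascade()]. Cross-table referential integrity is deliberately *not*
#' enforced here: gaps between tables are reported by
#' [validate_knowledge_base()], never fatal.
#'
#' @param mirnas data.frame with columns `mirna_id`, `evidence_methods`
#'   (comma-joined method labels, may be empty), `pd_related` (logical).
#' @param mirna_lncrna data.frame `mirna_id`, `lncrna_id`, `score` in
#'   \[0, 1\], `assay`.
#' @param mirna_gene data.frame `mirna_id`, `gene_id`, `prediction_score`
#'   in \[0, 100\].
#' @param lncrna_gene data.frame `lncrna_id`, `gene_id`,
#'   `n_predicted_interactions` (non-negative integer).
#' @param loci data.frame in BED column order `chrom`, `start`, `end`,
#'   `name` (entity id), `score`, `strand` (`+`, `-` or `.` for unknown);
#'   coordinates 0-based half-open, `start < end`.
#' @param tissues data.frame `entity_id`, `tissues` (comma-joined labels).
#' @param diseases data.frame `entity_id`, `disease`, `source`
#'   (`literature` or `database`).
#' @param provenance Optional data.frame recording file paths, checksums and
#'   row counts (filled in by [load_knowledge_base()]).
#' @return An object of class `knowledge_base`.
#' @export
knowledge_base <- function(mirnas, mirna_lncrna, mirna_gene, lncrna_gene,
                           loci, tissues, diseases, provenance = NULL) {
  kb <- list(mirnas = as.data.frame(mirnas),
             mirna_lncrna = as.data.frame(mirna_lncrna),
             mirna_gene = as.data.frame(mirna_gene),
             lncrna_gene = as.data.frame(lncrna_gene),
             loci = as.data.frame(loci),
             tissues = as.data.frame(tissues),
             diseases = as.data.frame(diseases),
             provenance = provenance)

  need <- list(
    mirnas = c("mirna_id", "evidence_methods", "pd_related"),
    mirna_lncrna = c("mirna_id", "lncrna_id", "score", "assay"),
    mirna_gene = c("mirna_id", "gene_id", "prediction_score"),
    lncrna_gene = c("lncrna_id", "gene_id", "n_predicted_interactions"),
    loci = c("chrom", "start", "end", "name", "score", "strand"),
    tissues = c("entity_id", "tissues"),
    diseases = c("entity_id", "disease", "source")
  )
  for (tb in names(need)) {
    missing <- setdiff(need[[tb]], names(kb[[tb]]))
    if (length(missing)) {
      stop(sprintf("table '%s' lacks column(s): %s", tb,
                   paste(missing, collapse = ", ")), call. = FALSE)
    }
  }

  assert_that(all(nzchar(kb$mirnas$mirna_id)), "mirna_id must be non-empty")
  check_primary_key(kb$mirnas, "mirna_id", "mirnas")
  check_primary_key(kb$mirna_lncrna, c("mirna_id", "lncrna_id"), "mirna_lncrna")
  check_primary_key(kb$mirna_gene, c("mirna_id", "gene_id"), "mirna_gene")
  check_primary_key(kb$lncrna_gene, c("lncrna_id", "gene_id"), "lncrna_gene")
  check_primary_key(kb$loci, "name", "loci")
  check_primary_key(kb$tissues, "entity_id", "tissues")
  # duplicate disease associations are reported by validate_knowledge_base()

  bad <- which(kb$mirna_lncrna$score < 0 | kb$mirna_lncrna$score > 1)
  if (length(bad)) {
    stop(sprintf(
      "mirna_lncrna: score out of [0,1] for row(s) %s (e.g. %s-%s score=%g)",
      paste(bad, collapse = ","), kb$mirna_lncrna$mirna_id[bad[1]],
      kb$mirna_lncrna$lncrna_id[bad[1]], kb$mirna_lncrna$score[bad[1]]),
      call. = FALSE)
  }
  bad <- which(kb$mirna_gene$prediction_score < 0 | kb$mirna_gene$prediction_score > 100)
  if (length(bad)) {
    stop(sprintf(
      "mirna_gene: prediction_score out of [0,100] for row(s) %s (e.g. %s-%s score=%g)",
      paste(bad, collapse = ","), kb$mirna_gene$mirna_id[bad[1]],
      kb$mirna_gene$gene_id[bad[1]], kb$mirna_gene$prediction_score[bad[1]]),
      call. = FALSE)
  }
  bad <- which(kb$lncrna_gene$n_predicted_interactions < 0)
  if (length(bad)) {
    stop(sprintf("lncrna_gene: negative n_predicted_interactions in row(s) %s",
                 paste(bad, collapse = ",")), call. = FALSE)
  }
  bad <- which(!(kb$loci$start >= 0 & kb$loci$start < kb$loci$end))
  if (length(bad)) {
    stop(sprintf("loci: invalid interval (need 0 <= start < end) for '%s'",
                 kb$loci$name[bad[1]]), call. = FALSE)
  }
  bad <- which(!kb$loci$strand %in% c("+", "-", "."))
  if (length(bad)) {
    stop(sprintf("loci: strand must be one of +, -, . (row %d)", bad[1]),
         call. = FALSE)
  }
  assert_that(all(nzchar(kb$diseases$disease)), "disease labels must be non-empty")
  bad <- which(!kb$diseases$source %in% c("literature", "database"))
  if (length(bad)) {
    stop(sprintf("diseases: source must be 'literature' or 'database' (row %d)",
                 bad[1]), call. = FALSE)
  }

  structure(kb, class = "knowledge_base")
}

#' Load a knowledge base from a directory of TSV tables
#'
#' Expects the seven files `mirnas.tsv`, `mirna_lncrna.tsv`, `mirna_gene.tsv`,
#' `lncrna_gene.tsv`, `loci.tsv`, `tissues.tsv`, `diseases.tsv`. A missing
#' file raises an error naming the table; a malformed numeric field raises an
#' error naming file, line and column; duplicated primary keys raise an error
#' listing the offenders. Row counts and MD5 checksums are recorded in the
#' provenance block.
#'
#' @param directory_path Directory holding the TSV tables.
#' @param config A [screen_config()] (kept for interface symmetry; thresholds
#'   are applied by the cascade, not at load time).
#' @return A `knowledge_base`.
#' @export
load_knowledge_base <- function(directory_path, config = screen_config()) {
  assert_that(dir.exists(directory_path),
              sprintf("knowledge-base directory not found: %s", directory_path))
  paths <- file.path(directory_path, kb_table_files)
  names(paths) <- names(kb_table_files)
  absent <- !file.exists(paths)
  if (any(absent)) {
    stop(sprintf("missing table(s): %s (expected file %s)",
                 paste(names(paths)[absent], collapse = ", "),
                 paste(kb_table_files[absent], collapse = ", ")), call. = FALSE)
  }

  mirnas <- read_tsv_strict(paths["mirnas"],
                            c("mirna_id", "evidence_methods", "pd_related"),
                            logical_cols = "pd_related")
  mirna_lncrna <- read_tsv_strict(paths["mirna_lncrna"],
                                  c("mirna_id", "lncrna_id", "score", "assay"),
                                  numeric_cols = "score")
  mirna_gene <- read_tsv_strict(paths["mirna_gene"],
                                c("mirna_id", "gene_id", "prediction_score"),
                                numeric_cols = "prediction_score")
  lncrna_gene <- read_tsv_strict(paths["lncrna_gene"],
                                 c("lncrna_id", "gene_id", "n_predicted_interactions"),
                                 integer_cols = "n_predicted_interactions")
  loci <- read_tsv_strict(paths["loci"],
                          c("chrom", "start", "end", "name", "score", "strand"),
                          numeric_cols = c("start", "end"))
  tissues <- read_tsv_strict(paths["tissues"], c("entity_id", "tissues"))
  diseases <- read_tsv_strict(paths["diseases"], c("entity_id", "disease", "source"))

  tables <- list(mirnas, mirna_lncrna, mirna_gene, lncrna_gene, loci, tissues, diseases)
  provenance <- data.frame(
    table = names(kb_table_files),
    path = unname(paths),
    n_rows = vapply(tables, nrow, integer(1)),
    md5 = unname(tools::md5sum(paths)),
    stringsAsFactors = FALSE
  )
  knowledge_base(mirnas, mirna_lncrna, mirna_gene, lncrna_gene,
                 loci, tissues, diseases, provenance = provenance)
}

#' Write a knowledge base as TSV tables
#'
#' Inverse of [load_knowledge_base()]: `load(write(kb))` reproduces every
#' table verbatim.
#'
#' @param kb A `knowledge_base`.
#' @param directory_path Output directory (created if absent).
#' @return The directory path, invisibly.
#' @export
write_knowledge_base <- function(kb, directory_path) {
  assert_that(inherits(kb, "knowledge_base"), "kb must be a knowledge_base")
  if (!dir.exists(directory_path)) dir.create(directory_path, recursive = TRUE)
  for (tb in names(kb_table_files)) {
    write_tsv_plain(kb[[tb]], file.path(directory_path, kb_table_files[[tb]]))
  }
  invisible(directory_path)
}

#' Referential-integrity report for a knowledge base
#'
#' Reports (never raises on) cross-table gaps: interactions naming a miRNA
#' absent from the miRNA table, interaction partners without a genomic locus,
#' and duplicated disease associations. An empty report means the bundle is
#' fully consistent.
#'
#' @param kb A `knowledge_base`.
#' @return A data.frame of class `kb_validation_report` with columns
#'   `category`, `table`, `entity_id`, `message`; zero rows when consistent.
#' @export
validate_knowledge_base <- function(kb) {
  assert_that(inherits(kb, "knowledge_base"), "kb must be a knowledge_base")
  entries <- list()
  add <- function(category, table, entity_id, message) {
    entries[[length(entries) + 1L]] <<- data.frame(
      category = category, table = table, entity_id = entity_id,
      message = message, stringsAsFactors = FALSE)
  }

  known_mirnas <- kb$mirnas$mirna_id
  for (tb in c("mirna_lncrna", "mirna_gene")) {
    dangling <- setdiff(unique(kb[[tb]]$mirna_id), known_mirnas)
    for (id in dangling) {
      add("dangling_reference", tb, id,
          sprintf("miRNA '%s' referenced in %s but absent from mirnas", id, tb))
    }
  }

  with_locus <- kb$loci$name
  lnc_ids <- unique(c(kb$mirna_lncrna$lncrna_id, kb$lncrna_gene$lncrna_id))
  gene_ids <- unique(c(kb$mirna_gene$gene_id, kb$lncrna_gene$gene_id))
  for (id in setdiff(lnc_ids, with_locus)) {
    add("missing_locus", "loci", id, sprintf("lncRNA '%s' has no locus", id))
  }
  for (id in setdiff(gene_ids, with_locus)) {
    add("missing_locus", "loci", id, sprintf("gene '%s' has no locus", id))
  }

  if (nrow(kb$diseases)) {
    key <- paste(kb$diseases$entity_id, kb$diseases$disease, kb$diseases$source,
                 sep = "\r")
    for (k in unique(key[duplicated(key)])) {
      parts <- strsplit(k, "\r", fixed = TRUE)[[1]]
      add("duplicate_association", "diseases", parts[1],
          sprintf("duplicated association %s - %s (%s)", parts[1], parts[2], parts[3]))
    }
  }

  report <- if (length(entries)) do.call(rbind, entries) else
    data.frame(category = character(), table = character(),
               entity_id = character(), message = character(),
               stringsAsFactors = FALSE)
  class(report) <- c("kb_validation_report", "data.frame")
  report
}

#' @export
print.kb_validation_report <- function(x, ...) {
  if (!nrow(x)) {
    cat("Knowledge base consistent: no referential gaps found.\n")
  } else {
    cat(sprintf("Knowledge-base validation: %d issue(s)\n", nrow(x)))
    tab <- table(x$category)
    for (nm in names(tab)) cat(sprintf("  %-22s %d\n", nm, tab[[nm]]))
    cat("\n")
    print.data.frame(x, row.names = FALSE)
  }
  invisible(x)
}

#' Serialize a validation report
#'
#' @param report A report from [validate_knowledge_base()].
#' @param path Output path; format chosen by extension (`.json` for
#'   machine-readable JSON, anything else plain text).
#' @return `path`, invisibly.
#' @export
write_validation_report <- function(report, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(as.data.frame(unclass(report)), path,
                         dataframe = "rows", auto_unbox = TRUE, pretty = TRUE)
  } else {
    txt <- utils::capture.output(print(report))
    writeLines(txt, path)
  }
  invisible(path)
}

#' @export
print.knowledge_base <- function(x, ...) {
  cat("Knowledge base\n")
  for (tb in names(kb_table_files)) {
    cat(sprintf("  %-13s %5d row(s)\n", tb, nrow(x[[tb]])))
  }
  invisible(x)
}

#' Genomic gap between two loci
#'
#' Distance between two genomic intervals under the 0-based half-open
#' convention: `Inf` on different chromosomes, 0 for overlapping or abutting
#' intervals, otherwise the number of bases strictly between the nearer ends.
#' Strand-agnostic and symmetric in its arguments.
#'
#' @param locus_a,locus_b Lists or one-row data.frames with fields `chrom`,
#'   `start`, `end` (0-based half-open, `start < end`).
#' @return Non-negative number of bases, or `Inf`.
#' @examples
#' genomic_gap(list(chrom = "chr1", start = 1000, end = 2000),
#'             list(chrom = "chr1", start = 51999, end = 60000))  # 49999
#' @export
genomic_gap <- function(locus_a, locus_b) {
  a <- as.list(locus_a); b <- as.list(locus_b)
  for (loc in list(a, b)) {
    assert_that(!is.null(loc$chrom) && !is.null(loc$start) && !is.null(loc$end),
                "locus needs fields chrom, start, end")
    assert_that(is.finite(loc$start) && is.finite(loc$end) && loc$start < loc$end,
                sprintf("invalid interval [%s, %s): need start < end",
                        format(loc$start), format(loc$end)))
  }
  if (as.character(a$chrom) != as.character(b$chrom)) return(Inf)
  max(0, max(a$start, b$start) - min(a$end, b$end))
}
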