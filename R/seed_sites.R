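# Canonical miRNA seed-site scanning (TargetScan-style site classes) and
# wild-type / mutant construct verification.
#
# A canonical site is defined on the target written 5'->3': the target
# carries the reverse complement of miRNA seed positions 2-7 (6mer core),
# optionally extended by a match to miRNA position 8 on the 5' side of the
# core (m8) and/or an adenosine opposite miRNA position 1 on the 3' side
# (A1). Classes, weakest to strongest: 6mer < 7mer-A1 < 7mer-m8 < 8mer.
# Each core window is reported once, at its maximal class. U and T are
# equivalent; case carries no meaning.

site_class_levels <- c("6mer", "7mer-A1", "7mer-m8", "8mer")

# normalize a nucleotide string to uppercase RNA; error on anything else
norm_rna <- function(seq, what = "sequence") {
  s <- toupper(as.character(seq)[1])
  s <- chartr("T", "U", s)
  if (grepl("[^ACGU]", s)) {
    bad <- regmatches(s, regexpr("[^ACGU]", s))
    stop(sprintf("%s contains non-nucleotide character '%s'", what, bad),
         call. = FALSE)
  }
  s
}

rna_complement <- function(s) chartr("ACGU", "UGCA", s)

rna_revcomp <- function(s) {
  paste(rev(strsplit(rna_complement(s), "")[[1]]), collapse = "")
}

#' Rank of a seed-site class
#'
#' @param site_class Character vector of classes
#'   (`6mer`, `7mer-A1`, `7mer-m8`, `8mer`).
#' @return Integer rank (1 weakest ... 4 strongest).
#' @export
site_class_rank <- function(site_class) {
  r <- match(site_class, site_class_levels)
  assert_that(!anyNA(r), sprintf("unknown site class: %s",
                                 paste(site_class[is.na(r)], collapse = ", ")))
  r
}

#' Scan a target sequence for canonical miRNA seed sites
#'
#' Finds every window whose target sequence is the reverse complement of
#' miRNA positions 2-7, upgrades each match by the m8 and A1 criteria, and
#' reports the window once at its maximal class. Overlapping sites are all
#' reported. Coordinates are 0-based half-open on the target and span the
#' full site (including the m8 and A1 positions where present), so
#' `end - start` is 6, 7 or 8 according to the class.
#'
#' @param mirna_sequence miRNA sequence, 5'->3' (RNA or DNA alphabet, case
#'   insensitive), length >= 8.
#' @param target_sequence Target sequence, 5'->3'.
#' @param mirna_id Optional identifier copied into the result.
#' @return data.frame with columns `start`, `end`, `site_class`,
#'   `site_seq`, `mirna_id`; zero rows when no site is present.
#' @examples
#' find_seed_sites("UGAGGUAGUAGGUUGUAUAGUU", "GGGCUACCUCAGGG")  # one 8mer at [3,11)
#' @export
find_seed_sites <- function(mirna_sequence, target_sequence, mirna_id = NA_character_) {
  m <- norm_rna(mirna_sequence, "miRNA sequence")
  t <- norm_rna(target_sequence, "target sequence")
  assert_that(nchar(m) >= 8, "miRNA sequence must be at least 8 nt")

  empty <- data.frame(start = integer(), end = integer(),
                      site_class = character(), site_seq = character(),
                      mirna_id = character(), stringsAsFactors = FALSE)
  if (nchar(t) < 6) return(empty)

  core <- rna_revcomp(substr(m, 2, 7))          # target-sense 6mer core
  m8_target <- rna_complement(substr(m, 8, 8))  # target base pairing position 8
  tlen <- nchar(t)

  rows <- list()
  for (s in seq_len(tlen - 5)) {                # 1-based core start
    if (substr(t, s, s + 5) != core) next
    has_m8 <- s > 1 && substr(t, s - 1, s - 1) == m8_target
    has_a1 <- (s + 6) <= tlen && substr(t, s + 6, s + 6) == "A"
    if (has_m8 && has_a1) {
      cls <- "8mer";    start0 <- s - 2L; end0 <- s + 6L
    } else if (has_m8) {
      cls <- "7mer-m8"; start0 <- s - 2L; end0 <- s + 5L
    } else if (has_a1) {
      cls <- "7mer-A1"; start0 <- s - 1L; end0 <- s + 6L
    } else {
      cls <- "6mer";    start0 <- s - 1L; end0 <- s + 5L
    }
    rows[[length(rows) + 1L]] <- data.frame(
      start = start0, end = end0, site_class = cls,
      site_seq = substr(t, start0 + 1L, end0), mirna_id = mirna_id,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

intervals_overlap <- function(s1, e1, s2, e2) s1 < e2 & s2 < e1

#' Verify that a mutant construct disrupts the wild-type seed site
#'
#' The verdict is `TRUE` iff the wild-type sequence carries at least one
#' site of class at least `min_class` and the mutant carries no site of
#' class at least `min_class` overlapping any wild-type site's coordinates.
#' Indel mutants (different lengths) are allowed; coordinates are compared
#' as given.
#'
#' @param wt_sequence,mt_sequence Wild-type and mutant target sequences.
#' @param mirna_sequence The miRNA, 5'->3'.
#' @param min_class Weakest site class that counts (default `"7mer-m8"`).
#' @return List with `verdict` (logical), `wt_sites`, `mt_sites` (site
#'   frames at class >= `min_class`) and `surviving_sites` (mutant sites
#'   overlapping wild-type site coordinates; non-empty only when the
#'   disruption failed).
#' @export
verify_mutant_disruption <- function(wt_sequence, mt_sequence, mirna_sequence,
                                     min_class = "7mer-m8") {
  min_rank <- site_class_rank(min_class)
  keep_strong <- function(sites) {
    sites[site_class_rank(sites$site_class) >= min_rank, , drop = FALSE]
  }
  wt_sites <- keep_strong(find_seed_sites(mirna_sequence, wt_sequence))
  mt_sites <- keep_strong(find_seed_sites(mirna_sequence, mt_sequence))

  surviving <- mt_sites[0, , drop = FALSE]
  if (nrow(wt_sites) && nrow(mt_sites)) {
    hit <- vapply(seq_len(nrow(mt_sites)), function(i) {
      any(intervals_overlap(mt_sites$start[i], mt_sites$end[i],
                            wt_sites$start, wt_sites$end))
    }, logical(1))
    surviving <- mt_sites[hit, , drop = FALSE]
  }
  list(verdict = nrow(wt_sites) > 0 && nrow(surviving) == 0,
       wt_sites = wt_sites, mt_sites = mt_sites, surviving_sites = surviving)
}

#' Read sequences from a FASTA file
#'
#' Thin wrapper over `Biostrings::readBStringSet` returning a plain named
#' character vector (any nucleotide alphabet, RNA or DNA).
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  assert_that(requireNamespace("Biostrings", quietly = TRUE),
              "Biostrings is required for FASTA I/O")
  set <- Biostrings::readBStringSet(path)
  stats::setNames(as.character(set), names(set))
}

#' Write sequences to a FASTA file
#'
#' @param sequences Named character vector of sequences.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  assert_that(requireNamespace("Biostrings", quietly = TRUE),
              "Biostrings is required for FASTA I/O")
  assert_that(!is.null(names(sequences)) && all(nzchar(names(sequences))),
              "sequences must be named")
  Biostrings::writeXStringSet(Biostrings::BStringSet(sequences), path)
  invisible(path)
}
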