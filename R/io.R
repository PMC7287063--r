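OUTFMT6_COLS <- c(
  "qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
  "qstart", "qend", "sstart", "send", "evalue", "bitscore"
)

#' Read a 12-column tabular hit file
#'
#' Parses the standard 12-column tabular similarity-search format (query,
#' subject, percent identity, alignment length, mismatches, gap opens,
#' query start/end, subject start/end, e-value, bitscore; no header) into
#' the tidy hit layout used throughout the package. The subject's taxonomic
#' category is either taken from the subject id prefix (`category|seqid`)
#' or joined from an explicit `subject_categories` table.
#'
#' @param path Path to the tabular file.
#' @param subject_categories Optional tibble (`subject_id`, `category`);
#'   when `NULL`, the category is the part of `sseqid` before the first
#'   `|`.
#' @return Tidy hit tibble: `query_id`, `subject_id`, `category`, `evalue`,
#'   `bitscore`, `qstart`, `qend`.
#' @export
read_hits <- function(path, subject_categories = NULL) {
  raw <- readr::read_tsv(path,
    col_names = OUTFMT6_COLS,
    col_types = "ccdiiiiiiidd", progress = FALSE
  )
  out <- tibble::tibble(
    query_id = raw$qseqid,
    subject_id = raw$sseqid,
    evalue = raw$evalue,
    bitscore = raw$bitscore,
    qstart = raw$qstart,
    qend = raw$qend
  )
  if (is.null(subject_categories)) {
    out$category <- sub("\\|.*$", "", raw$sseqid)
  } else {
    sc <- tibble::as_tibble(subject_categories)
    out$category <- sc$category[match(raw$sseqid, sc$subject_id)]
    if (anyNA(out$category)) {
      stop("subject id without category mapping: ",
        out$subject_id[which(is.na(out$category))[1]])
    }
  }
  dplyr::relocate(out, "category", .after = "subject_id")
}

#' Write hits in 12-column tabular format
#'
#' @param hits Tidy hit tibble (see [read_hits()]).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_hits <- function(hits, path) {
  hits <- tibble::as_tibble(hits)
  len <- hits$qend - hits$qstart + 1L
  out <- tibble::tibble(
    qseqid = hits$query_id,
    sseqid = hits$subject_id,
    pident = 50,
    length = len,
    mismatch = 0L,
    gapopen = 0L,
    qstart = hits$qstart,
    qend = hits$qend,
    sstart = 1L,
    send = len,
    evalue = hits$evalue,
    bitscore = hits$bitscore
  )
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' Read a gene-to-contig map
#'
#' @param path TSV with columns `gene_id`, `contig_id`, `start`, `end`,
#'   `strand` (1-based inclusive coordinates).
#' @return Tibble.
#' @export
read_gene_map <- function(path) {
  readr::read_tsv(path, col_types = "cciic", progress = FALSE)
}

#' Read a long-format marker status matrix
#'
#' @param path TSV with columns `taxon`, `marker`, `status`, `copy_number`.
#' @return Tibble.
#' @export
read_marker_matrix <- function(path) {
  readr::read_tsv(path, col_types = "cccd", progress = FALSE)
}

#' Read per-genome domain-count profiles
#'
#' @param path TSV with columns `genome_id`, `domain`, `count`.
#' @return Tibble.
#' @export
read_domain_profiles <- function(path) {
  readr::read_tsv(path, col_types = "ccd", progress = FALSE)
}
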