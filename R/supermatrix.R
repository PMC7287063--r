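GAP_CHARS <- c("-", ".")

as_alignment <- function(x) {
  if (is.matrix(x)) {
    return(x)
  }
  if (inherits(x, "XStringSet") || is.character(x)) {
    seqs <- as.character(x)
    lens <- nchar(seqs)
    if (length(unique(lens)) > 1) stop("alignment rows differ in length")
    m <- do.call(rbind, strsplit(seqs, ""))
    rownames(m) <- names(seqs)
    return(m)
  }
  stop("cannot interpret object as an alignment")
}

#' Read / write a FASTA alignment
#'
#' Alignments are represented as character matrices (rows = taxa, columns =
#' positions, `"-"` for gaps).
#'
#' @param path FASTA file path.
#' @return `read_alignment()`: a character matrix. `write_alignment()`:
#'   invisibly, `path`.
#' @export
read_alignment <- function(path) {
  as_alignment(Biostrings::readBStringSet(path))
}

#' @rdname read_alignment
#' @param aln Character matrix alignment.
#' @export
write_alignment <- function(aln, path) {
  seqs <- apply(aln, 1, paste, collapse = "")
  Biostrings::writeXStringSet(
    Biostrings::BStringSet(stats::setNames(seqs, rownames(aln))), path
  )
  invisible(path)
}

#' Select conserved markers from a status matrix
#'
#' A marker is selected when it is present (status `complete` or
#' `fragmented`; `duplicated` counts via `count_duplicated`) in strictly
#' more than `min_presence` of the sampled taxa AND its mean copy number,
#' averaged over all taxa (missing taxa contribute 0; set
#' `copy_over_present_only = TRUE` for the present-only alternative), is
#' strictly below `max_mean_copy`.
#'
#' @param matrix Long tibble with columns `taxon`, `marker`, `status`
#'   (`complete`/`fragmented`/`duplicated`/`missing`), `copy_number`.
#' @param min_presence Presence fraction threshold, strict (default 0.60).
#' @param max_mean_copy Mean copy threshold, strict (default 1.5).
#' @param count_duplicated Whether `duplicated` status counts as present
#'   (default `FALSE`: presence follows the complete-or-fragmented rule).
#' @param copy_over_present_only Average copy number over present taxa only
#'   (default `FALSE`).
#' @return Tibble: `marker`, `presence`, `mean_copy`, `selected`.
#' @export
select_markers <- function(matrix, min_presence = 0.60, max_mean_copy = 1.5,
                           count_duplicated = FALSE,
                           copy_over_present_only = FALSE) {
  matrix <- tibble::as_tibble(matrix)
  if (nrow(matrix) == 0) stop("empty marker matrix")
  present_status <- c("complete", "fragmented", if (count_duplicated) "duplicated")
  matrix |>
    dplyr::group_by(.data$marker) |>
    dplyr::summarise(
      presence = mean(.data$status %in% present_status),
      mean_copy = if (copy_over_present_only) {
        mean(.data$copy_number[.data$status != "missing"])
      } else {
        mean(.data$copy_number)
      },
      .groups = "drop"
    ) |>
    dplyr::mutate(
      selected = .data$presence > min_presence & .data$mean_copy < max_mean_copy
    )
}

column_identity <- function(aln) {
  apply(aln, 2, function(col) {
    res <- col[!col %in% GAP_CHARS]
    if (length(res) < 2) {
      return(NA_real_)
    }
    max(table(res)) / length(res)
  })
}

#' Trim alignment termini by column identity
#'
#' Drops the regions upstream of the first and downstream of the last
#' column whose identity exceeds the threshold. Column identity is the
#' frequency of the most common non-gap residue among non-gap residues;
#' columns with fewer than two non-gap residues never qualify.
#'
#' @param aln Character matrix alignment.
#' @param identity_threshold Strict identity cutoff (default 0.70).
#' @return List: `alignment` (possibly zero-column matrix), `kept_range`
#'   (`c(start, end)` or `NULL` with a warning when no column qualifies).
#' @export
trim_termini_identity <- function(aln, identity_threshold = 0.70) {
  aln <- as_alignment(aln)
  if (ncol(aln) == 0) stop("empty alignment")
  idn <- column_identity(aln)
  ok <- which(!is.na(idn) & idn > identity_threshold)
  if (length(ok) == 0) {
    warning("no column exceeds the identity threshold; empty alignment returned")
    return(list(alignment = aln[, 0, drop = FALSE], kept_range = NULL))
  }
  rng <- c(min(ok), max(ok))
  list(
    alignment = aln[, rng[1]:rng[2], drop = FALSE],
    kept_range = rng
  )
}

#' Trim alignment columns by gap fraction
#'
#' Keeps a column iff its fraction of non-gap residues is at least `gt`
#' (boundary kept, mirroring the "minimum fraction without gaps" semantics
#' of standard gap trimming). Column order is preserved.
#'
#' @param aln Character matrix alignment.
#' @param gt Minimum non-gap fraction (default 0.5).
#' @return List: `alignment`, `kept_columns` (integer indices).
#' @export
trim_gap_fraction <- function(aln, gt = 0.5) {
  aln <- as_alignment(aln)
  if (ncol(aln) == 0) stop("empty alignment")
  nongap <- apply(aln, 2, function(col) mean(!col %in% GAP_CHARS))
  keep <- which(nongap >= gt)
  list(alignment = aln[, keep, drop = FALSE], kept_columns = keep)
}

#' Concatenate per-marker alignments into a partitioned supermatrix
#'
#' Takes the union of taxa across markers; a taxon absent from a marker is
#' filled with gap characters across that marker's columns, keeping the
#' matrix rectangular. Partition bounds are recorded 1-based inclusive in
#' input order.
#'
#' @param alignments Named list of character matrix alignments.
#' @return Object of class `supermatrix`: `alignment` (character matrix over
#'   the taxon union) and `partitions` (tibble `name`, `start`, `end`,
#'   `length`).
#' @examples
#' a <- matrix("A", 2, 3, dimnames = list(c("t1", "t2"), NULL))
#' b <- matrix("C", 2, 2, dimnames = list(c("t1", "t3"), NULL))
#' sm <- concatenate_alignments(list(SSU = a, rbcL = b))
#' sm$partitions
#' @export
concatenate_alignments <- function(alignments) {
  if (length(alignments) == 0) stop("zero alignments")
  if (is.null(names(alignments)) || any(names(alignments) == "")) {
    names(alignments) <- paste0("part", seq_along(alignments))
  }
  alignments <- purrr::map(alignments, as_alignment)
  for (nm in names(alignments)) {
    taxa <- rownames(alignments[[nm]])
    if (is.null(taxa)) stop("alignment '", nm, "' lacks taxon names")
    if (anyDuplicated(taxa) > 0) stop("duplicate taxon within alignment '", nm, "'")
  }
  taxa <- unique(unlist(purrr::map(alignments, rownames)))
  lens <- purrr::map_int(alignments, ncol)
  total <- sum(lens)
  out <- matrix("-", length(taxa), total, dimnames = list(taxa, NULL))
  end <- cumsum(lens)
  start <- end - lens + 1L
  for (i in seq_along(alignments)) {
    a <- alignments[[i]]
    out[rownames(a), start[i]:end[i]] <- a
  }
  structure(
    list(
      alignment = out,
      partitions = tibble::tibble(
        name = names(alignments),
        start = as.integer(start),
        end = as.integer(end),
        length = as.integer(lens)
      )
    ),
    class = "supermatrix"
  )
}

#' @export
print.supermatrix <- function(x, ...) {
  cat(
    "<supermatrix>", nrow(x$alignment), "taxa x", ncol(x$alignment),
    "positions in", nrow(x$partitions), "partition(s)\n"
  )
  print(x$partitions)
  invisible(x)
}

#' Write a partition definition file
#'
#' One line per partition in `NAME = start-end` format.
#'
#' @param sm A `supermatrix`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_partitions <- function(sm, path) {
  lines <- sprintf("%s = %d-%d", sm$partitions$name, sm$partitions$start, sm$partitions$end)
  writeLines(lines, path)
  invisible(path)
}
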