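#' Presence/absence region report for domain repertoires
#'
#' Partitions the focal genome's domain set by the presence/absence pattern
#' of each domain across the reference genomes (the regions of a Venn
#' diagram over the references, from the focal genome's point of view). The
#' `"unique"` region collects focal domains absent from every reference;
#' the complementary `core_missing` set collects domains present in all
#' references but absent from the focal genome.
#'
#' @param focal Tibble (`domain`, `count`) for the focal genome, or a
#'   character vector of domain accessions.
#' @param references Named list of reference profiles (same forms).
#' @return Object of class `region_report`: `regions` (tibble `domain`,
#'   `pattern` — `+`/`-` per reference in order — and `region`, a
#'   human-readable label), `summary` (tibble `region`, `n`),
#'   `core_missing` (character), `reference_names`.
#' @examples
#' rr <- region_report(
#'   c("A", "B", "C"),
#'   list(R1 = "A", R2 = c("A", "B"))
#' )
#' rr$summary
#' @export
region_report <- function(focal, references) {
  as_domains <- function(x) {
    if (is.character(x)) {
      return(unique(x))
    }
    unique(tibble::as_tibble(x)$domain)
  }
  if (length(references) == 0) stop("at least one reference profile required")
  if (is.null(names(references)) || anyDuplicated(names(references)) > 0 ||
    any(names(references) == "")) {
    stop("references must have unique non-empty genome ids")
  }
  f <- as_domains(focal)
  refs <- purrr::map(references, as_domains)
  k <- length(refs)
  pattern_mat <- purrr::map(refs, ~ f %in% .x) |>
    purrr::reduce(cbind)
  pattern_mat <- matrix(pattern_mat, nrow = length(f), ncol = k)
  pattern <- apply(pattern_mat, 1, function(p) {
    paste(ifelse(p, "+", "-"), collapse = "")
  })
  region_label <- apply(pattern_mat, 1, function(p) {
    if (!any(p)) "unique" else paste(names(refs)[p], collapse = "&")
  })
  if (length(f) == 0) {
    pattern <- character(0)
    region_label <- character(0)
  }
  regions <- tibble::tibble(domain = f, pattern = pattern, region = region_label)
  core <- setdiff(purrr::reduce(refs, intersect), f)
  structure(
    list(
      regions = regions,
      summary = regions |> dplyr::count(.data$region, name = "n"),
      core_missing = sort(core),
      reference_names = names(refs)
    ),
    class = "region_report"
  )
}

#' @export
print.region_report <- function(x, ...) {
  cat(
    "<region_report>", nrow(x$regions), "focal domains vs",
    length(x$reference_names), "references;",
    length(x$core_missing), "core-missing\n"
  )
  print(x$summary)
  invisible(x)
}

#' @exportS3Method ggplot2::autoplot
autoplot.region_report <- function(object, ...) {
  df <- object$summary |>
    dplyr::arrange(dplyr::desc(.data$n))
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$region, .data$n), y = .data$n
  )) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(
      x = "presence/absence region", y = "focal domains",
      title = "Domain repertoire regions"
    )
}

#' High-copy, focal-specific domains
#'
#' Lists domains whose copy number in the focal genome strictly exceeds
#' `min_copies` and which (optionally) are absent from every other profile,
#' sorted by descending focal count.
#'
#' @param profiles Long tibble (`genome_id`, `domain`, `count`) covering
#'   all genomes, or a named list of (`domain`, `count`) tibbles.
#' @param focal Focal genome id.
#' @param min_copies Strict copy cutoff (default 5).
#' @param require_absent_in_others Require count 0 in every other genome
#'   (default `TRUE`).
#' @return Tibble: `domain`, `count`.
#' @export
copy_threshold_report <- function(profiles, focal, min_copies = 5,
                                  require_absent_in_others = TRUE) {
  if (is.list(profiles) && !is.data.frame(profiles)) {
    profiles <- purrr::imap(profiles, function(p, id) {
      dplyr::mutate(tibble::as_tibble(p), genome_id = id)
    }) |> purrr::list_rbind()
  }
  profiles <- tibble::as_tibble(profiles)
  if (!focal %in% profiles$genome_id) stop("focal genome '", focal, "' missing")
  fp <- profiles |> dplyr::filter(.data$genome_id == focal, .data$count > min_copies)
  if (require_absent_in_others) {
    elsewhere <- profiles |>
      dplyr::filter(.data$genome_id != focal, .data$count > 0) |>
      dplyr::pull("domain")
    fp <- fp |> dplyr::filter(!.data$domain %in% elsewhere)
  }
  fp |>
    dplyr::arrange(dplyr::desc(.data$count), .data$domain) |>
    dplyr::select("domain", "count")
}

#' Functional-term over-representation of a domain set
#'
#' One-sided hypergeometric test per term: the probability of drawing at
#' least the observed number of term-annotated domains when sampling
#' `|foreground|` domains from the background without replacement, adjusted
#' across terms by Benjamini-Hochberg. Domains without any term annotation
#' simply never contribute; terms absent from the foreground get p = 1.
#'
#' @param term_map Tibble (`domain`, `term`); a domain may map to several
#'   terms.
#' @param foreground Character vector of domains (subset of `background`).
#' @param background Character vector of domains.
#' @return Tibble: `term`, `count`, `background_count`, `expected`, `p`,
#'   `p_adjusted`, sorted by `p`.
#' @export
term_enrichment <- function(term_map, foreground, background) {
  foreground <- unique(foreground)
  background <- unique(background)
  if (!all(foreground %in% background)) {
    stop("foreground must be a subset of background")
  }
  term_map <- tibble::as_tibble(term_map) |>
    dplyr::filter(.data$domain %in% background) |>
    dplyr::distinct(.data$domain, .data$term)
  n_bg <- length(background)
  n_fg <- length(foreground)
  term_map |>
    dplyr::group_by(.data$term) |>
    dplyr::summarise(
      count = sum(.data$domain %in% foreground),
      background_count = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      expected = n_fg * .data$background_count / n_bg,
      p = stats::phyper(
        .data$count - 1, .data$background_count,
        n_bg - .data$background_count, n_fg,
        lower.tail = FALSE
      ),
      p_adjusted = stats::p.adjust(.data$p, method = "BH")
    ) |>
    dplyr::arrange(.data$p, .data$term)
}
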