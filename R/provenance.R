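#' Rank a gene's homology hits into a non-redundant list
#'
#' Keeps the single best hit per category ("non-redundant": lowest e-value,
#' ties broken by highest bitscore, then lexicographic subject id) and sorts
#' the retained hits by ascending e-value with the same tie-breaks. The
#' result is a pure function of the hit set: permuting the input rows never
#' changes the output.
#'
#' @param hits Tibble of hits for a single gene, with columns `query_id`,
#'   `subject_id`, `category`, `evalue`, `bitscore` (additional columns such
#'   as `qstart`/`qend` are carried through).
#' @return The ranked, deduplicated hit tibble (possibly empty).
#' @export
rank_hits <- function(hits) {
  hits <- tibble::as_tibble(hits)
  if (nrow(hits) == 0) {
    return(hits)
  }
  if (length(unique(hits$query_id)) > 1) {
    stop("rank_hits expects hits for a single gene")
  }
  ord <- order(hits$evalue, -hits$bitscore, hits$subject_id)
  hits <- hits[ord, , drop = FALSE]
  hits[!duplicated(hits$category), , drop = FALSE]
}

#' Classify a gene's evolutionary origin from its ranked hits
#'
#' Applies the first-two-hit rule: the categories of the two best
#' non-redundant hits determine the call. Two sub-categories of one lineage
#' give that lineage (level `"lineage"` for eukaryotic lineages,
#' `"prokaryote-lineage"` for prokaryotic ones, or `"sub-category"` when the
#' two categories coalesce strictly below the lineage node); a pair crossing
#' lineages escalates to the smallest shared level — `"stramenopile"` when
#' both are stramenopiles, `"eukaryote"` when both are eukaryotes — and
#' otherwise (host + prokaryote, or two prokaryote lineages) the call is
#' `"unresolved"` at the shared ancestor. A same-lineage pair outside the
#' host (diatom) clade marks the gene as a horizontal-transfer candidate.
#'
#' @param ranked Output of [rank_hits()] for one gene.
#' @param tax A `taxonomy` whose categories cover all hit categories.
#' @return One-row tibble: `gene_id`, `level`, `label`, `top1`, `top2`,
#'   `hgt_candidate`, `n_hits`.
#' @export
classify_origin <- function(ranked, tax) {
  ranked <- tibble::as_tibble(ranked)
  gene_id <- if (nrow(ranked) > 0) ranked$query_id[1] else NA_character_
  unresolved <- function() {
    tibble::tibble(
      gene_id = gene_id, level = "unresolved", label = NA_character_,
      top1 = if (nrow(ranked) >= 1) ranked$category[1] else NA_character_,
      top2 = NA_character_, hgt_candidate = FALSE, n_hits = nrow(ranked)
    )
  }
  if (nrow(ranked) < 2) {
    return(unresolved())
  }
  cats <- tax$categories
  c1 <- ranked$category[1]
  c2 <- ranked$category[2]
  i1 <- match(c1, cats$category_id)
  i2 <- match(c2, cats$category_id)
  if (is.na(i1) || is.na(i2)) {
    stop("category '", if (is.na(i1)) c1 else c2, "' absent from taxonomy")
  }
  shared <- lca(tax, c(c1, c2))
  if (cats$lineage[i1] == cats$lineage[i2]) {
    lin <- cats$lineage[i1]
    below_lineage <- shared != lin && lin %in% node_path(tax, shared)
    level <- if (below_lineage) {
      "sub-category"
    } else if (cats$is_prokaryote[i1]) {
      "prokaryote-lineage"
    } else {
      "lineage"
    }
    label <- if (below_lineage) shared else lin
    hgt <- !cats$is_diatom[i1]
  } else if (cats$is_stramenopile[i1] && cats$is_stramenopile[i2]) {
    level <- "stramenopile"
    label <- shared
    hgt <- FALSE
  } else if (cats$is_eukaryote[i1] && cats$is_eukaryote[i2]) {
    level <- "eukaryote"
    label <- shared
    hgt <- FALSE
  } else {
    # host + prokaryote, or prokaryote pair crossing lineages: the deeper
    # origin is left unresolved at the shared ancestor rather than called
    # a transfer.
    level <- "unresolved"
    label <- shared
    hgt <- FALSE
  }
  tibble::tibble(
    gene_id = gene_id, level = level, label = label,
    top1 = c1, top2 = c2, hgt_candidate = hgt, n_hits = nrow(ranked)
  )
}

#' Classify every gene in a hit table
#'
#' Convenience wrapper: splits a multi-gene hit table by `query_id`, ranks
#' each gene's hits and classifies its origin.
#'
#' @param hits Tidy hit tibble (see [rank_hits()]) covering many genes.
#' @param tax A `taxonomy`.
#' @return Tibble with one [classify_origin()] row per gene.
#' @export
classify_origins <- function(hits, tax) {
  hits <- tibble::as_tibble(hits)
  split(hits, hits$query_id) |>
    purrr::map(~ classify_origin(rank_hits(.x), tax)) |>
    purrr::list_rbind()
}

#' Detect a lineage-specific gene
#'
#' A gene is lineage-specific when its only similarity hits below the
#' e-value threshold (strict `<`) lie inside the focal set of categories
#' (e.g. the other araphid pennate libraries), and at least one such hit
#' exists. Hits at or above the threshold are ignored entirely. Lowering the
#' threshold can therefore only remove non-focal evidence, never create it.
#'
#' @param hits Hit tibble for one gene (self-library hits already excluded).
#' @param focal_categories Character vector of category ids forming the focal
#'   clade.
#' @param evalue_max Significance threshold; hits with `evalue < evalue_max`
#'   count as real homology evidence. Default `1e-5`.
#' @return `TRUE` or `FALSE`.
#' @export
detect_lineage_specific <- function(hits, focal_categories, evalue_max = 1e-5) {
  hits <- tibble::as_tibble(hits)
  sig <- hits[hits$evalue < evalue_max, , drop = FALSE]
  nrow(sig) > 0 && all(sig$category %in% focal_categories)
}

#' Detect a chimeric ("S-") gene from positioned hits
#'
#' Clusters a gene's hits into segments along the query by reciprocal
#' overlap: two hits belong together when their query ranges overlap by more
#' than half the shorter range. Adjacent clusters separated by at most
#' `gap_merge_tol` residues are merged when their origin calls agree.
#' Each retained segment (spanning at least `min_segment_len` residues) is
#' classified from its own hits; the gene is called chimeric when at least
#' two segments have confident origins belonging to different supergroups
#' (their labels coalesce only at the root or a domain node), e.g. a
#' bacterial N-terminus joined to a diatom C-terminus.
#'
#' @param hits Hit tibble for one gene with `qstart`/`qend` columns (1-based
#'   inclusive).
#' @param tax A `taxonomy`.
#' @param min_segment_len Minimum segment span in residues (default 50).
#' @param gap_merge_tol Maximum gap between same-origin clusters that is
#'   bridged (default 10).
#' @return List of class `chimera_call`: `gene_id`, `segments` (tibble:
#'   `qstart`, `qend`, `level`, `label`, `n_hits`), `is_chimera`.
#' @export
detect_chimera <- function(hits, tax, min_segment_len = 50, gap_merge_tol = 10) {
  hits <- tibble::as_tibble(hits)
  if (!all(c("qstart", "qend") %in% names(hits)) ||
    nrow(hits) == 0 || all(is.na(hits$qstart))) {
    stop("ranges required")
  }
  hits <- hits[!is.na(hits$qstart) & !is.na(hits$qend), , drop = FALSE]
  if (any(hits$qstart > hits$qend)) stop("invalid query range (start > end)")
  n <- nrow(hits)

  # Single-linkage clustering on >50% reciprocal overlap of query ranges.
  comp <- seq_len(n)
  find <- function(i) {
    while (comp[i] != i) i <- comp[i]
    i
  }
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      ov <- min(hits$qend[i], hits$qend[j]) - max(hits$qstart[i], hits$qstart[j]) + 1
      shorter <- min(
        hits$qend[i] - hits$qstart[i] + 1,
        hits$qend[j] - hits$qstart[j] + 1
      )
      if (ov > 0.5 * shorter) comp[find(i)] <- find(j)
    }
  }
  cl <- vapply(seq_len(n), find, integer(1))

  seg <- split(hits, cl) |>
    purrr::map(function(h) {
      call <- classify_origin(rank_hits(h), tax)
      tibble::tibble(
        qstart = min(h$qstart), qend = max(h$qend),
        level = call$level, label = call$label, n_hits = nrow(h)
      )
    }) |>
    purrr::list_rbind() |>
    dplyr::arrange(.data$qstart)

  # Bridge small gaps between consecutive segments with identical calls.
  if (nrow(seg) > 1) {
    keep <- rep(TRUE, nrow(seg))
    for (i in 2:nrow(seg)) {
      prev <- max(which(keep[1:(i - 1)]))
      same <- identical(seg$label[prev], seg$label[i]) &&
        identical(seg$level[prev], seg$level[i])
      if (same && seg$qstart[i] - seg$qend[prev] - 1 <= gap_merge_tol) {
        seg$qend[prev] <- max(seg$qend[prev], seg$qend[i])
        seg$n_hits[prev] <- seg$n_hits[prev] + seg$n_hits[i]
        keep[i] <- FALSE
      }
    }
    seg <- seg[keep, , drop = FALSE]
  }
  seg <- seg[seg$qend - seg$qstart + 1 >= min_segment_len, , drop = FALSE]

  confident <- seg$level != "unresolved" & !is.na(seg$label)
  lab <- unique(seg$label[confident])
  diff_supergroup <- FALSE
  if (length(lab) >= 2) {
    pairs <- utils::combn(lab, 2, simplify = FALSE)
    diff_supergroup <- any(purrr::map_lgl(pairs, function(p) {
      tax_depth_vec(tax)[[lca(tax, p)]] <= 1
    }))
  }
  structure(
    list(
      gene_id = hits$query_id[1],
      segments = seg,
      is_chimera = diff_supergroup
    ),
    class = "chimera_call"
  )
}

#' @export
print.chimera_call <- function(x, ...) {
  cat(
    "<chimera_call>", x$gene_id, "-",
    nrow(x$segments), "segment(s), is_chimera =", x$is_chimera, "\n"
  )
  print(x$segments)
  invisible(x)
}

#' Contig-context filter for HGT candidates
#'
#' A horizontally acquired gene that sits on a contig carrying at least one
#' other gene of confident host (diatom) origin is unlikely to be a
#' contaminant; a candidate alone on its contig, or surrounded only by
#' non-host genes, is flagged. Confident host origin means a call at
#' `"lineage"` or `"sub-category"` level whose label lies within the host
#' clade.
#'
#' @param candidates Character vector of candidate gene ids.
#' @param origin_calls Tibble of [classify_origin()] rows for all genes.
#' @param gene_map Tibble with `gene_id`, `contig_id`.
#' @param tax A `taxonomy`.
#' @param host_clade Node id of the host clade (default `"diatoms"`).
#' @return Tibble: `gene_id`, `contig_id`, `n_host_genes`, `status`
#'   (`"retained"` or `"flagged_contaminant"`).
#' @export
contig_context_filter <- function(candidates, origin_calls, gene_map, tax,
                                  host_clade = "diatoms") {
  gene_map <- tibble::as_tibble(gene_map)
  missing <- setdiff(candidates, gene_map$gene_id)
  if (length(missing) > 0) {
    stop("gene '", missing[1], "' missing from the gene map")
  }
  host_confident <- origin_calls |>
    dplyr::filter(
      .data$level %in% c("lineage", "sub-category"),
      !is.na(.data$label),
      purrr::map_lgl(.data$label, ~ is_ancestor(tax, host_clade, .x))
    ) |>
    dplyr::pull("gene_id")

  purrr::map(candidates, function(g) {
    contig <- gene_map$contig_id[match(g, gene_map$gene_id)]
    neighbours <- setdiff(gene_map$gene_id[gene_map$contig_id == contig], g)
    n_host <- sum(neighbours %in% host_confident)
    tibble::tibble(
      gene_id = g, contig_id = contig, n_host_genes = n_host,
      status = if (n_host >= 1) "retained" else "flagged_contaminant"
    )
  }) |>
    purrr::list_rbind()
}
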