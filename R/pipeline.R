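#' Run the full provenance pipeline on a simulated co-assembly
#'
#' One command that exercises every stage on synthetic data with planted
#' truth. The generator side simulates a host + symbiont metagenome and
#' plants per-gene origins: host background genes of diatom origin,
#' symbiont background genes with cross-lineage prokaryote affinities
#' (top hits scattered across prokaryote lineages, as expected for
#' bacterial genes once self-library hits are excluded), `n_hgt`
#' horizontally transferred genes — all but one on host contigs that also
#' carry verified diatom genes, one alone on a contig without diatom
#' context — and `n_chimera` chimeric genes (bacterial N-terminus, diatom
#' C-terminus). The analysis side then bins contigs by GC + LCA consensus,
#' classifies gene origins on the non-symbiont fraction (host and
#' ambiguous contigs), confirms every HGT candidate against a simulated
#' gene tree via the sister-group rule, applies the contig-context
#' contaminant filter, and screens the analysed genes for chimeras.
#'
#' @param seed Integer master seed.
#' @param config A [sim_config()] (default: `sim_config(seed)`).
#' @param tax A `taxonomy` (default [toy_taxonomy()]).
#' @param n_hgt Number of planted transfers (default 8; one of them is
#'   planted without diatom contig context).
#' @param n_chimera Number of planted chimeric genes (default 2).
#' @param hit_noise Passed to [simulate_hit_table()] (default 0).
#' @return List: `bins`, `fit` (the `gc_mixture`), `origin_calls` (analysed
#'   fraction), `hgt` (per-candidate tibble: donor, confirmation, context
#'   status), `chimeras` (per-gene `is_chimera` tibble), `truth`, and
#'   `counts` — a one-row tibble with `n_hgt_candidates`, `n_confirmed`,
#'   `n_retained`, `n_flagged`, `n_chimeras`, `binning_accuracy`.
#' @export
run_synthetic_pipeline <- function(seed = 1, config = sim_config(seed),
                                   tax = toy_taxonomy(), n_hgt = 8,
                                   n_chimera = 2, hit_noise = 0) {
  sim <- simulate_metagenome(config)
  gene_map <- sim$gene_map
  contig_truth <- sim$truth

  # ---- plant per-gene origins ------------------------------------------
  genes <- gene_map |>
    dplyr::left_join(
      contig_truth |> dplyr::select("contig_id", "true_bin", "gc"),
      by = "contig_id"
    ) |>
    dplyr::mutate(
      scenario = ifelse(.data$true_bin == "host", "lineage", "cross_prokaryote"),
      origin = ifelse(.data$true_bin == "host", "diatoms", NA_character_),
      origin2 = NA_character_,
      planted = "background"
    )

  # Scenario genes go on host contigs whose GC sits near the host median,
  # so the planted contigs bin unambiguously under the study conditions.
  host_counts <- genes |>
    dplyr::filter(.data$true_bin == "host") |>
    dplyr::group_by(.data$contig_id) |>
    dplyr::summarise(n = dplyr::n(), gc = .data$gc[1], .groups = "drop") |>
    dplyr::filter(abs(.data$gc - config$host_gc_median) < 0.03)
  multi <- host_counts |> dplyr::filter(.data$n >= 2)
  single <- host_counts |> dplyr::filter(.data$n == 1)
  if (nrow(multi) < n_hgt - 1 + n_chimera || nrow(single) < 1) {
    stop("simulated metagenome too small to plant the requested scenarios")
  }

  with_seed(derive_seed(seed, 7), {
    prok_donors <- c("chlorobi", "alphaproteobacteria", "verrucomicrobia")
    donors <- c(
      rep_len(prok_donors, max(0, n_hgt - 2)),
      if (n_hgt >= 2) "haptophytes",
      sample(prok_donors, 1) # the candidate without diatom context
    )[seq_len(n_hgt)]
    hgt_contigs <- c(sample(multi$contig_id, n_hgt - 1), sample(single$contig_id, 1))
    chimera_contigs <- sample(setdiff(multi$contig_id, hgt_contigs), n_chimera)
  })

  plant_first_gene <- function(genes, contig, scenario, origin,
                               origin2 = NA_character_, planted = scenario) {
    idx <- which(genes$contig_id == contig)[1]
    genes$scenario[idx] <- scenario
    genes$origin[idx] <- origin
    genes$origin2[idx] <- origin2
    genes$planted[idx] <- planted
    genes
  }
  for (i in seq_len(n_hgt)) {
    genes <- plant_first_gene(
      genes, hgt_contigs[i], "lineage", donors[i],
      planted = if (i < n_hgt) "hgt" else "hgt_no_context"
    )
  }
  for (ctg in chimera_contigs) {
    genes <- plant_first_gene(genes, ctg, "chimera", "verrucomicrobia", "diatoms")
  }

  ht <- simulate_hit_table(
    genes |> dplyr::select("gene_id", "scenario", "origin", "origin2"),
    tax,
    hit_noise = hit_noise, seed = derive_seed(seed, 8)
  )
  hits <- ht$hits

  # ---- binning ---------------------------------------------------------
  binned <- bin_contigs(sim$contigs, gene_map, hits, tax)
  bins <- binned$bins
  accuracy <- bins |>
    dplyr::left_join(contig_truth |> dplyr::select("contig_id", "true_bin"),
      by = "contig_id"
    ) |>
    dplyr::summarise(
      acc = mean((.data$gc_bin == "low_gc") == (.data$true_bin == "host"))
    ) |>
    dplyr::pull("acc")

  # ---- provenance on the non-symbiont fraction -------------------------
  analysed_contigs <- bins$contig_id[bins$consensus != "symbiont"]
  analysed_genes <- gene_map$gene_id[gene_map$contig_id %in% analysed_contigs]
  host_hits <- hits |> dplyr::filter(.data$query_id %in% analysed_genes)
  origin_calls <- classify_origins(host_hits, tax)

  # Chimera screen first: a gene with segments of conflicting origin gets
  # per-segment treatment, not a whole-gene transfer call.
  chimeras <- split(host_hits, host_hits$query_id) |>
    purrr::imap(function(h, g) {
      cc <- detect_chimera(h, tax)
      tibble::tibble(
        gene_id = g, is_chimera = cc$is_chimera, n_segments = nrow(cc$segments)
      )
    }) |>
    purrr::list_rbind()
  chimeric <- chimeras$gene_id[chimeras$is_chimera]

  candidates <- setdiff(
    origin_calls$gene_id[origin_calls$hgt_candidate], chimeric
  )

  # ---- tree confirmation of each candidate -----------------------------
  hgt <- purrr::map(seq_along(candidates), function(i) {
    g <- candidates[i]
    call <- origin_calls[origin_calls$gene_id == g, ]
    support <- with_seed(derive_seed(seed, 100 + i), sample(55:99, 1))
    gt <- simulate_gene_tree(
      donor = call$top1, support = support, tax = tax,
      seed = derive_seed(seed, 200 + i)
    )
    dplyr::bind_cols(
      tibble::tibble(gene_id = g),
      confirm_hgt(gt$tree, "QUERY", gt$leaf_categories, call$top1) |>
        dplyr::select(-"query")
    )
  }) |>
    purrr::list_rbind()

  confirmed <- if (nrow(hgt) > 0) hgt$gene_id[hgt$confirmed] else character(0)
  context <- contig_context_filter(confirmed, origin_calls, gene_map, tax)
  if (nrow(hgt) > 0) {
    hgt <- hgt |> dplyr::left_join(
      context |> dplyr::select("gene_id", "status", "n_host_genes"),
      by = "gene_id"
    )
  }

  counts <- tibble::tibble(
    n_hgt_candidates = length(candidates),
    n_confirmed = length(confirmed),
    n_retained = sum(hgt$status == "retained", na.rm = TRUE),
    n_flagged = sum(hgt$status == "flagged_contaminant", na.rm = TRUE),
    n_chimeras = sum(chimeras$is_chimera),
    binning_accuracy = accuracy
  )
  list(
    bins = bins, fit = binned$fit, origin_calls = origin_calls,
    hgt = hgt, chimeras = chimeras,
    truth = list(genes = genes, contigs = contig_truth, hits = ht$truth),
    counts = counts
  )
}
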