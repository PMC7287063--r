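tax <- toy_taxonomy()

test_that("simulated metagenome hits the configured GC medians and is deterministic", {
  cfg <- sim_config(seed = 1)
  sim <- simulate_metagenome(cfg)
  med <- sim$truth |>
    dplyr::group_by(.data$true_bin) |>
    dplyr::summarise(m = stats::median(.data$gc))
  expect_equal(med$m[med$true_bin == "host"], 0.51, tolerance = 0.01)
  expect_equal(med$m[med$true_bin == "symbiont"], 0.64, tolerance = 0.01)

  # genes tile contigs without overlap and stay inside the contig
  by_contig <- split(sim$gene_map, sim$gene_map$contig_id)
  lens <- stats::setNames(sim$truth$length, sim$truth$contig_id)
  for (g in by_contig[1:20]) {
    g <- g[order(g$start), ]
    expect_true(all(g$end <= lens[[g$contig_id[1]]]))
    if (nrow(g) > 1) expect_true(all(g$start[-1] > g$end[-nrow(g)]))
  }

  # byte-identical FASTA under the same seed
  f1 <- tempfile(fileext = ".fa")
  f2 <- tempfile(fileext = ".fa")
  Biostrings::writeXStringSet(sim$contigs, f1)
  Biostrings::writeXStringSet(simulate_metagenome(cfg)$contigs, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)), readBin(f2, "raw", file.size(f2)))
})

test_that("zero GC dispersion puts every contig at the configured median", {
  cfg <- sim_config(seed = 3, gc_sd = c(1e-12, 1e-12), n_contigs = c(30, 30))
  sim <- simulate_metagenome(cfg)
  host <- sim$truth[sim$truth$true_bin == "host", ]
  # exact up to integer base-composition rounding
  expect_true(all(abs(host$gc - 0.51) <= 0.5 / host$length + 1e-9))
  expect_error(sim_config(gc_sd = c(0, 0.01)), "gc_sd")
  expect_error(sim_config(n_contigs = c(0, 10)), "n_contigs")
})

test_that("noise-free hit tables round-trip through the origin classifier", {
  genes <- tibble::tibble(
    gene_id = sprintf("g%02d", 1:40),
    scenario = rep(c("lineage", "lineage", "lineage", "cross_prokaryote"), 10),
    origin = rep(c("diatoms", "alphaproteobacteria", "chlorobi", NA), 10),
    origin2 = NA_character_
  )
  ht <- simulate_hit_table(genes, tax, hit_noise = 0, seed = 5)
  calls <- classify_origins(ht$hits, tax)
  merged <- dplyr::left_join(genes, calls, by = "gene_id")
  planted <- merged[merged$scenario == "lineage", ]
  expect_equal(planted$label, planted$origin)
  expect_true(all(planted$hgt_candidate == (planted$origin != "diatoms")))
  expect_true(all(merged$level[merged$scenario == "cross_prokaryote"] == "unresolved"))
  # e-values strictly ordered within each gene
  ord <- ht$hits |>
    dplyr::group_by(.data$query_id) |>
    dplyr::summarise(strict = !anyDuplicated(.data$evalue))
  expect_true(all(ord$strict))
})

test_that("planted lineage-specific genes pass the focal filter", {
  genes <- tibble::tibble(
    gene_id = "ls1", scenario = "lineage_specific",
    origin = "diatoms", origin2 = NA_character_
  )
  ht <- simulate_hit_table(genes, tax, seed = 9)
  focal <- tax$categories$category_id[tax$categories$lineage == "diatoms"]
  expect_true(detect_lineage_specific(ht$hits, focal))
  # the generated non-focal hit sits at or above the threshold
  nonfocal <- ht$hits[!ht$hits$category %in% focal, ]
  expect_true(all(nonfocal$evalue >= 1e-5))
})

test_that("a single-category taxonomy leaves every gene unresolved", {
  tax1 <- load_taxonomy(tibble::tibble(
    category_id = "only", path = "root;only", flags = "eukaryote"
  ))
  genes <- tibble::tibble(
    gene_id = c("a", "b"), scenario = "single",
    origin = "root", origin2 = NA_character_
  )
  ht <- simulate_hit_table(genes, tax1, hit_noise = 1, seed = 2)
  calls <- classify_origins(ht$hits, tax1)
  expect_true(all(calls$level == "unresolved"))
})

test_that("planted gene-tree scenarios round-trip through confirm_hgt", {
  gt <- simulate_gene_tree("chlorobi-a", support = 90, tax = tax, seed = 4)
  v <- confirm_hgt(gt$tree, "QUERY", gt$leaf_categories, "chlorobi-a")
  expect_true(v$confirmed)

  gt <- simulate_gene_tree("chlorobi-a", support = 40, tax = tax, seed = 4)
  v <- confirm_hgt(gt$tree, "QUERY", gt$leaf_categories, "chlorobi-a")
  expect_false(v$confirmed)
  expect_equal(v$reason, "low_support")

  gt <- simulate_gene_tree("chlorobi-a",
    support = 95, tax = tax, seed = 4,
    mixed_sister = TRUE
  )
  v <- confirm_hgt(gt$tree, "QUERY", gt$leaf_categories, "chlorobi-a")
  expect_equal(v$reason, "mixed_sister")

  expect_error(simulate_gene_tree("chlorobi-a", support = 140, tax = tax), "support")
})

test_that("planted paraphyly scenarios round-trip through alpha_origin_test", {
  for (planted in c(TRUE, FALSE)) {
    at <- simulate_alpha_tree(planted, tax, seed = 6)
    res <- alpha_origin_test(at$tree, "QUERY", at$leaf_categories, tax)
    expect_equal(res$verdict, planted)
  }
})

test_that("marker matrices reproduce their planted pass set exactly", {
  mm <- simulate_marker_matrix(n_taxa = 25, n_markers = 12, seed = 8)
  sel <- select_markers(mm$matrix)
  expect_equal(
    sort(sel$marker[sel$selected]),
    sort(mm$truth$marker[mm$truth$planted_pass])
  )
  expect_error(simulate_marker_matrix(n_taxa = 0), "positive")
  # all markers failing gives an empty selection
  mm0 <- simulate_marker_matrix(n_taxa = 20, n_markers = 5,
    planted_pass = character(0), seed = 3)
  expect_equal(sum(select_markers(mm0$matrix)$selected), 0)
})

test_that("simulated alignments realize conserved blocks and gap fractions", {
  aln <- simulate_alignment(
    n_taxa = 12, length = 30, conserved_blocks = list(c(5, 20)), seed = 10
  )
  tr <- trim_termini_identity(aln)
  expect_equal(tr$kept_range, c(5, 20))

  gp <- c(rep(0, 10), 0.6, rep(0, 9))
  aln2 <- simulate_alignment(n_taxa = 10, length = 20, gap_fraction = gp, seed = 2)
  frac <- colMeans(aln2 == "-")
  expect_true(all(abs(frac - gp) <= 1 / 10 + 1e-9))
  expect_equal(trim_gap_fraction(aln2)$kept_columns, setdiff(1:20, 11))

  # zero gaps everywhere: gap trimming is the identity
  aln3 <- simulate_alignment(n_taxa = 8, length = 15, seed = 3)
  expect_equal(trim_gap_fraction(aln3)$kept_columns, 1:15)
  expect_error(simulate_alignment(length = 0), "length")
  expect_error(
    simulate_alignment(length = 10, conserved_blocks = list(c(5, 12))),
    "block"
  )
})
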