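# Deterministic child-seed derivation: one global seed fans out to
# per-generator streams so stages can be re-run independently.
derive_seed <- function(seed, stream) {
  x <- ((as.numeric(seed) %% 2147483647) * 48271 + stream * 7919) %% 2147483647
  as.integer(x)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Simulation configuration for the synthetic metagenome
#'
#' Captures the study conditions emulated by the generator: a two-component
#' contig GC mixture (host diatom median 0.51, bacterial symbiont median
#' 0.64), contig lengths, and gene density. All downstream generators derive
#' their random streams from the single `seed`.
#'
#' @param seed Integer master seed.
#' @param host_gc_median,symbiont_gc_median Component GC medians (defaults
#'   0.51 and 0.64).
#' @param gc_sd Length-2 numeric, GC standard deviation per component
#'   (host, symbiont); defaults `c(0.02, 0.03)`.
#' @param n_contigs Length-2 integer, contigs per component (host,
#'   symbiont); defaults `c(500, 500)`.
#' @param contig_length_meanlog,contig_length_sdlog Log-normal contig length
#'   parameters (defaults `log(4000)`, 0.35); lengths are floored at
#'   `min_contig_length`.
#' @param min_contig_length Minimum contig length in bp (default 1000).
#' @param genes_per_contig_lambda Poisson mean number of genes tiled on each
#'   contig (default 2).
#' @param gene_length,gene_spacing Gene tiling parameters in bp (defaults
#'   600 and 100).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1,
                       host_gc_median = 0.51,
                       symbiont_gc_median = 0.64,
                       gc_sd = c(0.02, 0.03),
                       n_contigs = c(500, 500),
                       contig_length_meanlog = log(4000),
                       contig_length_sdlog = 0.35,
                       min_contig_length = 1000,
                       genes_per_contig_lambda = 2,
                       gene_length = 600,
                       gene_spacing = 100) {
  stopifnot(
    host_gc_median > 0, host_gc_median < 1,
    symbiont_gc_median > 0, symbiont_gc_median < 1,
    length(gc_sd) == 2, length(n_contigs) == 2
  )
  if (any(gc_sd <= 0)) stop("gc_sd must be positive")
  if (any(n_contigs <= 0)) stop("n_contigs must be positive")
  structure(
    list(
      seed = as.integer(seed),
      host_gc_median = host_gc_median,
      symbiont_gc_median = symbiont_gc_median,
      gc_sd = gc_sd,
      n_contigs = n_contigs,
      contig_length_meanlog = contig_length_meanlog,
      contig_length_sdlog = contig_length_sdlog,
      min_contig_length = min_contig_length,
      genes_per_contig_lambda = genes_per_contig_lambda,
      gene_length = gene_length,
      gene_spacing = gene_spacing
    ),
    class = "sim_config"
  )
}

#' Simulate a host + symbiont metagenome co-assembly
#'
#' Generates contigs for both components with GC realized by constructive
#' base composition: each contig's G+C count is fixed at
#' `round(gc * length)` and the bases are shuffled, so the empirical GC is
#' exact up to integer rounding (with `gc_sd = 0` every contig sits at the
#' configured median). Genes are tiled left-to-right on each contig without
#' overlap. Output is byte-deterministic under a fixed seed.
#'
#' @param config A [sim_config()].
#' @return List: `contigs` ([Biostrings::DNAStringSet]), `gene_map` (tibble
#'   `gene_id`, `contig_id`, `start`, `end`, `strand`), `truth` (tibble
#'   `contig_id`, `true_bin`, `target_gc`, `gc`, `length`), `config`.
#' @export
simulate_metagenome <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(derive_seed(config$seed, 1), {
    comp <- tibble::tibble(
      true_bin = rep(c("host", "symbiont"), config$n_contigs),
      gc_median = rep(
        c(config$host_gc_median, config$symbiont_gc_median),
        config$n_contigs
      ),
      gc_sd = rep(config$gc_sd, config$n_contigs)
    )
    n <- nrow(comp)
    comp$contig_id <- sprintf("contig_%04d", seq_len(n))
    comp$length <- pmax(
      config$min_contig_length,
      round(stats::rlnorm(n, config$contig_length_meanlog, config$contig_length_sdlog))
    )
    comp$target_gc <- pmin(0.95, pmax(
      0.05,
      stats::rnorm(n, comp$gc_median, comp$gc_sd)
    ))

    seqs <- vapply(seq_len(n), function(i) {
      len <- comp$length[i]
      n_gc <- round(comp$target_gc[i] * len)
      bases <- c(
        sample(c("G", "C"), n_gc, replace = TRUE),
        sample(c("A", "T"), len - n_gc, replace = TRUE)
      )
      paste(sample(bases), collapse = "")
    }, character(1))
    contigs <- Biostrings::DNAStringSet(stats::setNames(seqs, comp$contig_id))

    n_genes <- stats::rpois(n, config$genes_per_contig_lambda)
    slot <- config$gene_length + config$gene_spacing
    n_genes <- pmin(n_genes, comp$length %/% slot)
    gene_map <- purrr::map(seq_len(n), function(i) {
      k <- n_genes[i]
      if (k == 0) {
        return(NULL)
      }
      start <- (seq_len(k) - 1L) * slot + 1L
      tibble::tibble(
        contig_id = comp$contig_id[i],
        start = start,
        end = start + config$gene_length - 1L,
        strand = sample(c("+", "-"), k, replace = TRUE)
      )
    }) |>
      purrr::list_rbind() |>
      dplyr::mutate(
        gene_id = sprintf("g%05d", dplyr::row_number()),
        .before = 1
      )

    freq <- Biostrings::alphabetFrequency(contigs, baseOnly = TRUE)
    comp$gc <- unname((freq[, "C"] + freq[, "G"]) / rowSums(freq[, c("A", "C", "G", "T")]))

    list(
      contigs = contigs,
      gene_map = gene_map,
      truth = comp[, c("contig_id", "true_bin", "target_gc", "gc", "length")],
      config = config
    )
  })
}

#' Write simulated metagenome files
#'
#' @param sim Output of [simulate_metagenome()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written (`contigs.fasta`, `gene_map.tsv`,
#'   `contig_truth.tsv`).
#' @export
write_metagenome <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "contigs.fasta")
  Biostrings::writeXStringSet(sim$contigs, fa)
  gm <- file.path(dir, "gene_map.tsv")
  readr::write_tsv(sim$gene_map, gm)
  tr <- file.path(dir, "contig_truth.tsv")
  readr::write_tsv(sim$truth, tr)
  invisible(c(fa, gm, tr))
}

# Pick k distinct leaf categories belonging to one lineage node.
lineage_categories <- function(tax, lineage_node, k = 2) {
  cats <- tax$categories$category_id[tax$categories$lineage == lineage_node]
  if (length(cats) < k) {
    stop(
      "lineage '", lineage_node, "' has fewer than ", k,
      " sub-categories in the taxonomy"
    )
  }
  sample(cats, k)
}

#' Simulate a hit table conditioned on planted per-gene origins
#'
#' Generates ranked homology hits per gene so that the origin classifier
#' recovers every planted origin exactly when `hit_noise = 0`. E-value
#' exponents are sampled on the log scale with strictly decreasing
#' significance, so the ranking is unambiguous, and noise hits (spurious
#' off-origin hits added with probability `hit_noise` per gene) are always
#' strictly worse than planted hits.
#'
#' Planted scenarios, one per row of `genes`:
#' \describe{
#'   \item{`lineage`}{two best hits in two distinct sub-categories of the
#'     lineage node in `origin` (an HGT candidate when the lineage is not
#'     the host clade).}
#'   \item{`lineage_specific`}{significant hits (e-value < 1e-5) only in
#'     sub-categories of the focal lineage `origin`, plus one non-focal hit
#'     at or above the threshold.}
#'   \item{`chimera`}{positioned hits: an N-terminal segment from `origin`
#'     and a C-terminal segment from `origin2`, each backed by two
#'     sub-categories.}
#'   \item{`cross_prokaryote`}{two best hits in sub-categories of two
#'     different prokaryote lineages (classifier: unresolved at the shared
#'     prokaryote ancestor), emulating bacterial genes whose top hits
#'     scatter across lineages once self-library hits are excluded;
#'     `origin` is ignored.}
#'   \item{`single`}{one hit only (classifier returns unresolved).}
#' }
#'
#' @param genes Tibble with columns `gene_id`, `scenario`, `origin`
#'   (lineage node id) and optionally `origin2` (chimera only).
#' @param tax A `taxonomy`.
#' @param hit_noise Per-gene probability of adding one spurious off-origin
#'   hit (default 0, the planted-truth condition).
#' @param seed Integer seed.
#' @param gene_length Query length in residues used for hit coordinates
#'   (default 250).
#' @return List: `hits` (tidy hit tibble with `query_id`, `subject_id`,
#'   `category`, `evalue`, `bitscore`, `qstart`, `qend`), `truth` (the
#'   input `genes` tibble).
#' @export
simulate_hit_table <- function(genes, tax, hit_noise = 0, seed = 1,
                               gene_length = 250) {
  genes <- tibble::as_tibble(genes)
  all_lineages <- unique(tax$categories$lineage)
  uses_origin <- genes$scenario != "cross_prokaryote"
  origins <- c(genes$origin[uses_origin], genes$origin2[uses_origin])
  bad <- setdiff(unique(origins), c(all_lineages, NA))
  if (length(bad) > 0) stop("unknown category or lineage '", bad[1], "'")

  with_seed(derive_seed(seed, 2), {
    serial <- 0L
    mk_hits <- function(gene_id, cats, exponents, qstart, qend) {
      serial <<- serial + length(cats)
      tibble::tibble(
        query_id = gene_id,
        subject_id = sprintf("%s|s%05d", cats, serial - rev(seq_along(cats)) + 1L),
        category = cats,
        evalue = 10^(-exponents),
        bitscore = 30 + 2 * exponents,
        qstart = as.integer(qstart),
        qend = as.integer(qend)
      )
    }
    dec_exponents <- function(k, hi = 60, lo = 8) {
      # strictly decreasing significance, first the strongest
      start <- stats::runif(1, lo + 5 * k, hi)
      start - cumsum(c(0, stats::runif(k - 1, 1, 4)))
    }

    rows <- purrr::pmap(genes, function(gene_id, scenario, origin,
                                        origin2 = NA, ...) {
      half <- gene_length %/% 2
      out <- switch(scenario,
        lineage = {
          cats <- lineage_categories(tax, origin, 2)
          mk_hits(gene_id, cats, dec_exponents(2), 1, gene_length)
        },
        lineage_specific = {
          cats <- lineage_categories(tax, origin, 2)
          focal <- mk_hits(gene_id, cats, dec_exponents(2, lo = 10), 1, gene_length)
          nonfocal_cat <- sample(
            tax$categories$category_id[tax$categories$lineage != origin], 1
          )
          weak <- mk_hits(gene_id, nonfocal_cat, stats::runif(1, 1, 4), 1, gene_length)
          dplyr::bind_rows(focal, weak)
        },
        chimera = {
          cats_n <- lineage_categories(tax, origin, 2)
          cats_c <- lineage_categories(tax, origin2, 2)
          dplyr::bind_rows(
            mk_hits(gene_id, cats_n, dec_exponents(2), 1, half),
            mk_hits(gene_id, cats_c, dec_exponents(2), half + 11, gene_length)
          )
        },
        cross_prokaryote = {
          prok <- tax$categories[tax$categories$is_prokaryote, ]
          lins <- sample(unique(prok$lineage), 2)
          cats <- purrr::map_chr(lins, function(l) {
            sample(prok$category_id[prok$lineage == l], 1)
          })
          mk_hits(gene_id, cats, dec_exponents(2), 1, gene_length)
        },
        single = {
          cats <- lineage_categories(tax, origin, 1)
          mk_hits(gene_id, cats, dec_exponents(1), 1, gene_length)
        },
        stop("unknown scenario '", scenario, "'")
      )
      if (hit_noise > 0 && stats::runif(1) < hit_noise) {
        noise_cat <- sample(tax$categories$category_id, 1)
        worst <- min(-log10(out$evalue))
        noise <- mk_hits(
          gene_id, noise_cat, max(worst - stats::runif(1, 2, 6), 0.5),
          1, gene_length
        )
        out <- dplyr::bind_rows(out, noise)
      }
      out
    })
    list(hits = purrr::list_rbind(rows), truth = genes)
  })
}

#' Simulate a gene tree with a planted sister-group scenario
#'
#' Builds a rooted gene tree by grafting the query onto a random scaffold so
#' that the planted topology is guaranteed: the query's sister clade
#' consists of leaves of the donor category (`n_donor` of them), and the
#' split subtending query + sister carries the configured bootstrap
#' support. With `mixed_sister = TRUE` one sister leaf is drawn from a
#' different category, so confirmation must fail regardless of support.
#'
#' @param donor Leaf category id of the planted donor.
#' @param support Integer bootstrap support in `[0, 100]` on the query
#'   split.
#' @param tax A `taxonomy`.
#' @param seed Integer seed.
#' @param n_donor Number of donor leaves in the sister clade (default 2).
#' @param n_background Number of scaffold leaves (default 8).
#' @param mixed_sister Plant a contaminating non-donor leaf inside the
#'   sister clade (default `FALSE`).
#' @param query Query leaf label (default `"QUERY"`).
#' @return List: `tree` (rooted `phylo` with integer node supports),
#'   `leaf_categories` (tibble `leaf`, `category`), `truth` (tibble with
#'   the planted expectation for [confirm_hgt()] at the default cutoff).
#' @export
simulate_gene_tree <- function(donor, support, tax, seed = 1, n_donor = 2,
                               n_background = 8, mixed_sister = FALSE,
                               query = "QUERY") {
  if (support < 0 || support > 100) stop("support outside [0,100]")
  if (!donor %in% tax$categories$category_id) {
    stop("unknown category '", donor, "'")
  }
  with_seed(derive_seed(seed, 3), {
    other <- setdiff(tax$categories$category_id, donor)
    bg_cats <- sample(other, n_background, replace = TRUE)
    bg_leaves <- sprintf("bg%02d", seq_len(n_background))
    scaffold <- ape::rtree(n_background, tip.label = bg_leaves)
    scaffold_nwk <- sub(";$", "", ape::write.tree(scaffold))

    donor_cats <- rep(donor, n_donor)
    if (mixed_sister) donor_cats[n_donor] <- sample(other, 1)
    donor_leaves <- sprintf("don%02d", seq_len(n_donor))
    inner_support <- sample(60:99, 1)
    donor_nwk <- paste0(
      "(", paste0(donor_leaves, ":0.1", collapse = ","), ")",
      inner_support, ":0.1"
    )
    nwk <- paste0(
      "((", query, ":0.2,", donor_nwk, ")", support, ":0.1,",
      scaffold_nwk, ":0.1);"
    )
    tree <- ape::read.tree(text = nwk)
    leaf_categories <- tibble::tibble(
      leaf = c(query, donor_leaves, bg_leaves),
      category = c(NA_character_, donor_cats, bg_cats)
    )
    expected <- !mixed_sister && support > 50
    list(
      tree = tree,
      leaf_categories = leaf_categories,
      truth = tibble::tibble(
        query = query, donor = donor, support = support,
        mixed_sister = mixed_sister, expected_confirmed = expected
      )
    )
  })
}

#' Simulate a gene tree for the alpha-proteobacterial paraphyly rule
#'
#' Plants a tree in which the query either nests inside a paraphyletic
#' assemblage of alpha-proteobacteria and eukaryotes to the exclusion of all
#' non-alpha prokaryotes (`planted = TRUE`: the query's sister is an alpha
#' leaf) or does not (`planted = FALSE`: the query's sister is a non-alpha
#' prokaryote, so every split containing the query and an alpha leaf also
#' contains that prokaryote).
#'
#' @param planted Logical planted verdict.
#' @param tax A `taxonomy`.
#' @param seed Integer seed.
#' @param n_alpha,n_euk,n_other_prok Numbers of alpha-proteobacterial,
#'   eukaryote and non-alpha prokaryote reference leaves (defaults 4, 3, 5,
#'   mirroring the five best non-alpha prokaryotes retained per marker).
#' @param query Query leaf label (default `"QUERY"`).
#' @return List: `tree`, `leaf_categories`, `truth` (tibble `query`,
#'   `planted`).
#' @export
simulate_alpha_tree <- function(planted, tax, seed = 1, n_alpha = 4,
                                n_euk = 3, n_other_prok = 5,
                                query = "QUERY") {
  cats <- tax$categories
  alpha_cats <- cats$category_id[cats$is_alphaproteobacterium]
  euk_cats <- cats$category_id[cats$is_eukaryote]
  oprok_cats <- cats$category_id[cats$is_prokaryote & !cats$is_alphaproteobacterium]
  with_seed(derive_seed(seed, 4), {
    a <- sprintf("alp%02d", seq_len(n_alpha))
    e <- sprintf("euk%02d", seq_len(n_euk))
    p <- sprintf("prk%02d", seq_len(n_other_prok))
    sup <- function() sample(50:100, 1)
    clade <- function(leaves) {
      # random ladder over the leaves, each internal node supported
      leaves <- sample(leaves)
      out <- paste0(leaves[1], ":0.1")
      for (x in leaves[-1]) {
        out <- paste0("(", out, ",", x, ":0.1)", sup(), ":0.1")
      }
      out
    }
    sister <- if (planted) {
      first_alpha <- paste0(a[1], ":0.1")
      rest <- clade(c(a[-1], e))
      core <- paste0("((", query, ":0.2,", first_alpha, ")", sup(), ":0.1,", rest, ")")
      paste0(core, sup(), ":0.1")
    } else {
      first_prok <- paste0(p[1], ":0.1")
      rest <- clade(c(a, e))
      core <- paste0("((", query, ":0.2,", first_prok, ")", sup(), ":0.1,", rest, ")")
      paste0(core, sup(), ":0.1")
    }
    out_leaves <- if (planted) p else p[-1]
    nwk <- paste0("(", sister, ",", clade(out_leaves), ");")
    tree <- ape::read.tree(text = nwk)
    leaf_categories <- tibble::tibble(
      leaf = c(query, a, e, p),
      category = c(
        NA_character_,
        sample(alpha_cats, n_alpha, replace = TRUE),
        sample(euk_cats, n_euk, replace = TRUE),
        sample(oprok_cats, n_other_prok, replace = TRUE)
      )
    )
    list(
      tree = tree,
      leaf_categories = leaf_categories,
      truth = tibble::tibble(query = query, planted = planted)
    )
  })
}

#' Simulate a marker status matrix with planted pass/fail structure
#'
#' Builds a per-taxon marker status matrix (complete / fragmented /
#' duplicated / missing plus copy numbers) such that
#' [select_markers()] at the default thresholds (presence > 0.60, mean copy
#' < 1.5) returns exactly the planted pass set. Failing markers violate
#' exactly one rule: either presence at or below 0.60 (including the exact
#' boundary) or mean copy number at or above 1.5.
#'
#' @param n_taxa Number of taxa (default 20).
#' @param n_markers Number of markers (default 10).
#' @param planted_pass Character vector of marker ids (subset of
#'   `m01..`) planted to pass; default the first half.
#' @param seed Integer seed.
#' @return List: `matrix` (long tibble `taxon`, `marker`, `status`,
#'   `copy_number`), `truth` (tibble `marker`, `planted_pass`).
#' @export
simulate_marker_matrix <- function(n_taxa = 20, n_markers = 10,
                                   planted_pass = NULL, seed = 1) {
  if (n_taxa == 0) stop("n_taxa must be positive")
  markers <- sprintf("m%02d", seq_len(n_markers))
  if (is.null(planted_pass)) planted_pass <- markers[seq_len(n_markers %/% 2)]
  if (!all(planted_pass %in% markers)) stop("planted_pass must be a subset of markers")
  taxa <- sprintf("t%02d", seq_len(n_taxa))
  with_seed(derive_seed(seed, 5), {
    rows <- purrr::map(markers, function(m) {
      pass <- m %in% planted_pass
      status <- rep("missing", n_taxa)
      copy <- rep(0, n_taxa)
      if (pass) {
        k <- sample(seq(floor(0.6 * n_taxa) + 1, n_taxa), 1)
        present <- sample(n_taxa, k)
        status[present] <- sample(c("complete", "fragmented"), k,
          replace = TRUE, prob = c(0.8, 0.2)
        )
        copy[present] <- 1
        # a little duplication, but only as long as the complete-or-
        # fragmented presence fraction stays strictly above the cutoff
        # and the mean copy number stays safely below its cutoff
        n_dup <- min(
          max(0, k - (floor(0.6 * n_taxa) + 1L)),
          max(0, floor(0.2 * n_taxa))
        )
        if (n_dup > 0) {
          dup <- sample(present, n_dup)
          status[dup] <- "duplicated"
          copy[dup] <- 2
        }
      } else if (stats::runif(1) < 0.5) {
        # fail on presence: exactly at or below the 0.60 boundary
        k <- sample(seq(0, floor(0.6 * n_taxa)), 1)
        if (k > 0) {
          present <- sample(n_taxa, k)
          status[present] <- "complete"
          copy[present] <- 1
        }
      } else {
        # fail on copy number: everyone duplicated, mean >= 1.5
        status <- rep("duplicated", n_taxa)
        copy <- sample(2:3, n_taxa, replace = TRUE)
      }
      tibble::tibble(
        taxon = taxa, marker = m, status = status, copy_number = copy
      )
    })
    list(
      matrix = purrr::list_rbind(rows),
      truth = tibble::tibble(marker = markers, planted_pass = markers %in% planted_pass)
    )
  })
}

#' Simulate an alignment with planted conserved blocks and gap structure
#'
#' Columns inside `conserved_blocks` have a modal residue shared by strictly
#' more than 70% of non-gap rows; columns outside the blocks have balanced
#' residue usage so no residue exceeds half the rows. Per-column gap
#' fractions are realized exactly as `round(gap_fraction * n_taxa)` gaps.
#'
#' @param n_taxa Number of rows (default 10).
#' @param length Number of columns.
#' @param conserved_blocks List of `c(start, end)` ranges (1-based
#'   inclusive) or `NULL`.
#' @param gap_fraction Scalar or length-`length` vector of per-column gap
#'   fractions (default 0).
#' @param seed Integer seed.
#' @return Character matrix (rows taxa, columns positions) over the amino
#'   acid alphabet plus `"-"`.
#' @export
simulate_alignment <- function(n_taxa = 10, length = 60,
                               conserved_blocks = list(), gap_fraction = 0,
                               seed = 1) {
  if (length == 0) stop("length must be positive")
  blocks <- conserved_blocks
  if (!is.null(blocks) && !is.list(blocks)) blocks <- list(blocks)
  for (b in blocks) {
    if (b[1] < 1 || b[2] > length || b[1] > b[2]) {
      stop("conserved block outside [1, length]")
    }
  }
  gap_fraction <- rep_len(gap_fraction, length)
  aa <- c(
    "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
  )
  with_seed(derive_seed(seed, 6), {
    conserved <- rep(FALSE, length)
    for (b in blocks) conserved[b[1]:b[2]] <- TRUE
    aln <- matrix("-", n_taxa, length,
      dimnames = list(sprintf("t%02d", seq_len(n_taxa)), NULL)
    )
    for (j in seq_len(length)) {
      n_gap <- round(gap_fraction[j] * n_taxa)
      n_res <- n_taxa - n_gap
      col <- rep("-", n_taxa)
      if (n_res > 0) {
        residues <- if (conserved[j]) {
          modal <- sample(aa, 1)
          k <- min(n_res, floor(0.7 * n_res) + 1L)
          c(rep(modal, k), sample(setdiff(aa, modal), n_res - k, replace = TRUE))
        } else {
          rep_len(sample(aa, 4), n_res)
        }
        col[sample(n_taxa, n_res)] <- sample(residues)
      }
      aln[, j] <- col
    }
    aln
  })
}
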