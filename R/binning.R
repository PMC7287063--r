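#' Per-contig GC content
#'
#' Computes the GC fraction of every contig as (G+C)/(A+C+G+T), ignoring
#' ambiguous IUPAC symbols (N, R, Y, ...) in both numerator and denominator.
#' Contigs with zero unambiguous bases get `gc = NA` and are flagged.
#'
#' @param contigs A FASTA file path, a [Biostrings::DNAStringSet], or a named
#'   character vector of sequences.
#' @return Tibble: `contig_id`, `length`, `gc`, `n_unambiguous`, `flagged`.
#' @examples
#' gc_profile(c(c1 = "ACGT", c2 = "AAAA", c3 = "ACGN"))
#' @export
gc_profile <- function(contigs) {
  if (is.character(contigs) && length(contigs) == 1 && file.exists(contigs)) {
    contigs <- Biostrings::readDNAStringSet(contigs)
  }
  if (is.character(contigs)) {
    contigs <- Biostrings::DNAStringSet(contigs)
  }
  if (length(contigs) == 0) stop("empty contig set")
  if (any(Biostrings::width(contigs) == 0)) stop("empty sequence record")
  freq <- Biostrings::alphabetFrequency(contigs, baseOnly = TRUE)
  acgt <- freq[, c("A", "C", "G", "T"), drop = FALSE]
  denom <- rowSums(acgt)
  gc <- ifelse(denom > 0, (acgt[, "C"] + acgt[, "G"]) / denom, NA_real_)
  tibble::tibble(
    contig_id = names(contigs),
    length = Biostrings::width(contigs),
    gc = unname(gc),
    n_unambiguous = unname(denom),
    flagged = denom == 0
  )
}

#' Fit a two-component GC mixture
#'
#' Separates per-contig GC values into a low-GC and a high-GC component with
#' a two-component univariate normal mixture fitted by expectation-
#' maximization, initialized at the 25th and 75th percentiles of the data.
#' Components are reported in ascending mean order, so labels are stable
#' across runs. Each contig receives the posterior probability of the
#' high-GC component; contigs with posterior within `margin` of 0.5 are
#' flagged low-confidence.
#'
#' @param gc Numeric vector of GC fractions (at least two distinct values).
#' @param max_iter Maximum EM iterations (default 500).
#' @param tol Convergence tolerance on the log-likelihood (default 1e-8).
#' @param margin Posterior half-width around 0.5 flagged as low confidence
#'   (default 0.1).
#' @param unimodal_tol Warn "unimodal" when the fitted means differ by less
#'   than this (default 0.02).
#' @return Object of class `gc_mixture`: component parameters, per-value
#'   posteriors for the high-GC component, hard assignments
#'   (`"low_gc"`/`"high_gc"`), low-confidence flags and the log-likelihood
#'   trace. Supports [generics::tidy()], [generics::glance()] and
#'   [ggplot2::autoplot()].
#' @export
fit_gc_mixture <- function(gc, max_iter = 500, tol = 1e-8, margin = 0.1,
                           unimodal_tol = 0.02) {
  gc <- as.numeric(gc)
  gc <- gc[!is.na(gc)]
  if (length(unique(gc)) < 2) {
    stop("degenerate input: need at least two distinct GC values")
  }
  mu <- unname(stats::quantile(gc, c(0.25, 0.75)))
  if (mu[1] == mu[2]) mu <- range(gc)
  sd0 <- max(stats::sd(gc) / 2, 1e-4)
  sigma <- c(sd0, sd0)
  w <- c(0.5, 0.5)
  loglik <- numeric(0)
  n <- length(gc)
  post <- matrix(0.5, n, 2)
  for (iter in seq_len(max_iter)) {
    dens <- cbind(
      w[1] * stats::dnorm(gc, mu[1], sigma[1]),
      w[2] * stats::dnorm(gc, mu[2], sigma[2])
    )
    rowsum_ <- pmax(rowSums(dens), .Machine$double.xmin)
    post <- dens / rowsum_
    ll <- sum(log(rowsum_))
    loglik <- c(loglik, ll)
    nk <- colSums(post)
    w <- nk / n
    mu <- colSums(post * gc) / nk
    sigma <- sqrt(colSums(post * (outer(gc, mu, "-")^2)) / nk)
    sigma <- pmax(sigma, 1e-6)
    if (iter > 1 && abs(loglik[iter] - loglik[iter - 1]) < tol) break
  }
  ord <- order(mu)
  mu <- mu[ord]
  sigma <- sigma[ord]
  w <- w[ord]
  post <- post[, ord, drop = FALSE]
  if (diff(mu) < unimodal_tol) {
    warning("unimodal: fitted component means are within ", unimodal_tol)
  }
  posterior_high <- post[, 2]
  structure(
    list(
      mean = mu, sd = sigma, weight = w,
      posterior_high = posterior_high,
      assignment = ifelse(posterior_high >= 0.5, "high_gc", "low_gc"),
      low_confidence = abs(posterior_high - 0.5) < margin,
      margin = margin,
      loglik = loglik,
      iterations = length(loglik),
      converged = length(loglik) < max_iter,
      data = gc
    ),
    class = "gc_mixture"
  )
}

#' @export
print.gc_mixture <- function(x, ...) {
  cat("<gc_mixture> 2-component normal mixture, n =", length(x$data), "\n")
  cat(sprintf(
    "  low_gc : mean %.4f sd %.4f weight %.3f\n", x$mean[1], x$sd[1], x$weight[1]
  ))
  cat(sprintf(
    "  high_gc: mean %.4f sd %.4f weight %.3f\n", x$mean[2], x$sd[2], x$weight[2]
  ))
  cat(
    "  logLik", round(dplyr::last(x$loglik), 3), "after", x$iterations,
    "iterations (converged:", x$converged, ")\n"
  )
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @exportS3Method generics::tidy
tidy.gc_mixture <- function(x, ...) {
  tibble::tibble(
    component = c("low_gc", "high_gc"),
    mean = x$mean, sd = x$sd, weight = x$weight
  )
}

#' @exportS3Method generics::glance
glance.gc_mixture <- function(x, ...) {
  tibble::tibble(
    logLik = dplyr::last(x$loglik),
    iterations = x$iterations,
    converged = x$converged,
    n = length(x$data),
    n_low_confidence = sum(x$low_confidence)
  )
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @exportS3Method ggplot2::autoplot
autoplot.gc_mixture <- function(object, bins = 60, ...) {
  df <- tibble::tibble(gc = object$data, assignment = object$assignment)
  grid <- seq(min(object$data), max(object$data), length.out = 400)
  dens <- purrr::map(1:2, function(k) {
    tibble::tibble(
      gc = grid,
      density = object$weight[k] * stats::dnorm(grid, object$mean[k], object$sd[k]),
      component = c("low_gc", "high_gc")[k]
    )
  }) |> purrr::list_rbind()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gc)) +
    ggplot2::geom_histogram(
      ggplot2::aes(y = ggplot2::after_stat(density), fill = .data$assignment),
      bins = bins, alpha = 0.6, position = "identity"
    ) +
    ggplot2::geom_line(
      data = dens,
      ggplot2::aes(y = .data$density, colour = .data$component),
      linewidth = 0.8
    ) +
    ggplot2::labs(
      x = "GC fraction", y = "density",
      title = "Two-component GC mixture"
    )
}

#' LCA taxonomic annotation of contigs
#'
#' Labels each contig with the last common ancestor of the best-hit
#' categories of its resident genes, using each gene's single best hit and
#' only genes whose best hit is at least as significant as `evalue_max`.
#' Contigs with no qualifying gene are `"unclassified"`.
#'
#' @param hits Tidy hit tibble (`query_id`, `category`, `evalue`,
#'   `bitscore`, ...).
#' @param gene_map Tibble with `gene_id`, `contig_id`.
#' @param tax A `taxonomy`.
#' @param evalue_max Best-hit significance cutoff (default 1e-5).
#' @return Tibble: `contig_id`, `lca_label` (node id or `"unclassified"`),
#'   `n_genes_used`.
#' @export
lca_annotate_contigs <- function(hits, gene_map, tax, evalue_max = 1e-5) {
  hits <- tibble::as_tibble(hits)
  gene_map <- tibble::as_tibble(gene_map)
  unknown <- setdiff(unique(hits$category), tax$categories$category_id)
  if (length(unknown) > 0) stop("unknown category '", unknown[1], "'")
  best <- hits |>
    dplyr::group_by(.data$query_id) |>
    dplyr::arrange(.data$evalue, dplyr::desc(.data$bitscore), .data$subject_id,
      .by_group = TRUE
    ) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$evalue <= evalue_max)
  annotated <- gene_map |>
    dplyr::left_join(
      best |> dplyr::select(gene_id = "query_id", "category"),
      by = "gene_id"
    )
  annotated |>
    dplyr::group_by(.data$contig_id) |>
    dplyr::summarise(
      lca_label = {
        cats <- .data$category[!is.na(.data$category)]
        if (length(cats) == 0) "unclassified" else lca(tax, cats)
      },
      n_genes_used = sum(!is.na(.data$category)),
      .groups = "drop"
    )
}

#' Consensus host/symbiont bin assignment
#'
#' Combines the GC-mixture channel with the LCA channel into one verdict per
#' contig. The GC channel votes host for the low-GC component and symbiont
#' for the high-GC component (host diatom genomes here are AT-richer than
#' the bacterial symbiont; flip with `host_bin`). The LCA channel votes at
#' domain level: a label wholly within the eukaryote side is host, wholly
#' prokaryote is symbiont, anything else (root-level label or
#' `"unclassified"`) abstains.
#'
#' Rules: agreement gives the shared verdict; a domain-confident LCA
#' overrides a low-confidence GC call; a confident GC call wins over an
#' abstaining LCA; a confident conflict — and a low-confidence GC call with
#' no LCA evidence — is `"ambiguous"`.
#'
#' @param gc_bins Tibble with `contig_id`, `gc_bin` (`"low_gc"`/`"high_gc"`),
#'   `posterior` (high-GC posterior), `low_confidence`.
#' @param lca_labels Tibble from [lca_annotate_contigs()].
#' @param tax A `taxonomy`.
#' @param host_bin Which GC bin is the host (default `"low_gc"`).
#' @return Tibble: `contig_id`, `gc_bin`, `posterior`, `lca_label`,
#'   `lca_vote`, `consensus` (`"host"`/`"symbiont"`/`"ambiguous"`).
#' @export
consensus_bin <- function(gc_bins, lca_labels, tax, host_bin = "low_gc") {
  gc_bins <- tibble::as_tibble(gc_bins)
  merged <- gc_bins |>
    dplyr::left_join(lca_labels, by = "contig_id") |>
    dplyr::mutate(lca_label = dplyr::coalesce(.data$lca_label, "unclassified"))

  lca_vote_of <- function(label) {
    if (label == "unclassified") {
      return("none")
    }
    euk <- node_flag(tax, label, "is_eukaryote")
    prok <- node_flag(tax, label, "is_prokaryote")
    if (isTRUE(euk)) "host" else if (isTRUE(prok)) "symbiont" else "none"
  }
  merged |>
    dplyr::mutate(
      gc_vote = ifelse(.data$gc_bin == host_bin, "host", "symbiont"),
      lca_vote = purrr::map_chr(.data$lca_label, lca_vote_of),
      consensus = dplyr::case_when(
        lca_vote != "none" & gc_vote == lca_vote ~ gc_vote,
        lca_vote != "none" & low_confidence ~ lca_vote,
        lca_vote == "none" & !low_confidence ~ gc_vote,
        lca_vote == "none" & low_confidence ~ "ambiguous",
        TRUE ~ "ambiguous" # confident conflict
      )
    ) |>
    dplyr::select(
      "contig_id", "gc_bin", "posterior", "lca_label", "lca_vote", "consensus"
    )
}

#' Bin contigs by GC and LCA evidence
#'
#' End-to-end binning: computes per-contig GC, fits the two-component
#' mixture, annotates contigs by gene-level LCA, and forms the consensus
#' verdict.
#'
#' @param contigs FASTA path, `DNAStringSet` or named character vector.
#' @param gene_map Tibble with `gene_id`, `contig_id`.
#' @param hits Tidy hit tibble for the resident genes.
#' @param tax A `taxonomy`.
#' @param evalue_max LCA best-hit cutoff (default 1e-5).
#' @param ... Passed to [fit_gc_mixture()].
#' @return List with `bins` (one row per contig: `contig_id`, `gc`,
#'   `gc_bin`, `posterior`, `lca_label`, `consensus`) and `fit` (the
#'   `gc_mixture`).
#' @export
bin_contigs <- function(contigs, gene_map, hits, tax, evalue_max = 1e-5, ...) {
  prof <- gc_profile(contigs)
  fit <- fit_gc_mixture(prof$gc, ...)
  gc_bins <- prof |>
    dplyr::mutate(
      gc_bin = fit$assignment,
      posterior = fit$posterior_high,
      low_confidence = fit$low_confidence
    )
  lca_labels <- lca_annotate_contigs(hits, gene_map, tax, evalue_max)
  bins <- consensus_bin(gc_bins, lca_labels, tax) |>
    dplyr::left_join(prof |> dplyr::select("contig_id", "gc"), by = "contig_id") |>
    dplyr::relocate("gc", .after = "contig_id")
  list(bins = bins, fit = fit)
}
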