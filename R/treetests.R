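tip_index <- function(tree, leaf) {
  i <- match(leaf, tree$tip.label)
  if (is.na(i)) stop("leaf '", leaf, "' absent from tree")
  i
}

node_support <- function(tree, node) {
  ntip <- length(tree$tip.label)
  lab <- tree$node.label
  if (is.null(lab)) {
    return(NA_real_)
  }
  s <- lab[node - ntip]
  if (is.na(s) || s == "") {
    return(NA_real_)
  }
  suppressWarnings(as.numeric(s))
}

clade_tips <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) {
    return(tree$tip.label[node])
  }
  tree$tip.label[phangorn::Descendants(tree, node, "tips")[[1]]]
}

#' Root a gene tree on an outgroup
#'
#' Roots on the edge subtending the smallest bipartition side containing all
#' outgroup leaves, provided that side excludes the query; otherwise
#' (outgroup paraphyletic around the query) falls back to midpoint rooting
#' with a warning. Support labels stay attached to the edges they describe.
#'
#' @param tree An unrooted or rooted `phylo`.
#' @param outgroup_leaves Character vector of leaf labels forming the
#'   outgroup (e.g. all leaves of the outgroup categories).
#' @param query Query leaf label (must not be inside the outgroup clade for
#'   outgroup rooting to apply).
#' @return A rooted `phylo`; attribute `rooting` is `"outgroup"` or
#'   `"midpoint"`.
#' @export
root_tree <- function(tree, outgroup_leaves, query) {
  missing <- setdiff(outgroup_leaves, tree$tip.label)
  if (length(missing) > 0 || length(outgroup_leaves) == 0) {
    stop("outgroup leaves absent from tree")
  }
  if (setequal(outgroup_leaves, tree$tip.label)) {
    stop("outgroup cannot contain all leaves")
  }
  tip_index(tree, query)
  unrooted <- ape::unroot(tree)
  ntip <- length(unrooted$tip.label)
  internal <- unique(unrooted$edge[, 2])
  sides <- purrr::map(internal, function(v) clade_tips(unrooted, v))
  best <- NULL
  best_size <- Inf
  for (i in seq_along(sides)) {
    for (side in list(sides[[i]], setdiff(unrooted$tip.label, sides[[i]]))) {
      # skip the degenerate side complementary to the query's own pendant
      # edge: rooting there would place the query at the root
      if (length(side) == ntip - 1 && !query %in% side) next
      if (all(outgroup_leaves %in% side) && length(side) < best_size &&
        length(side) < ntip) {
        best <- side
        best_size <- length(side)
      }
    }
  }
  if (!is.null(best) && !query %in% best) {
    rooted <- ape::root(unrooted,
      outgroup = best, resolve.root = TRUE,
      edgelabel = TRUE
    )
    attr(rooted, "rooting") <- "outgroup"
    rooted
  } else {
    warning("outgroup is paraphyletic around the query; midpoint rooting used")
    rooted <- phangorn::midpoint(unrooted, node.labels = "support")
    attr(rooted, "rooting") <- "midpoint"
    rooted
  }
}

#' Sister group of a query leaf
#'
#' In a rooted tree the sister of the query is the union of the leaf sets of
#' the other child subtrees of the query's parent (a polytomous parent
#' contributes all of its non-query children). The reported support is the
#' bootstrap label on the query's parent node, i.e. the split joining the
#' query with its sister.
#'
#' @param tree A rooted `phylo`.
#' @param query Query leaf label.
#' @param leaf_categories Optional tibble (`leaf`, `category`) used to
#'   report sister categories.
#' @return List of class `sister_result`: `query`, `sister` (leaf labels),
#'   `categories`, `support` (numeric or `NA`).
#' @export
sister_group <- function(tree, query, leaf_categories = NULL) {
  if (!ape::is.rooted(tree)) stop("sister_group requires a rooted tree")
  q <- tip_index(tree, query)
  ntip <- length(tree$tip.label)
  parent <- tree$edge[tree$edge[, 2] == q, 1]
  if (parent == ntip + 1) stop("query attaches at the root")
  siblings <- setdiff(tree$edge[tree$edge[, 1] == parent, 2], q)
  sister <- unlist(purrr::map(siblings, ~ clade_tips(tree, .x)))
  cats <- NULL
  if (!is.null(leaf_categories)) {
    cats <- leaf_categories$category[match(sister, leaf_categories$leaf)]
  }
  structure(
    list(
      query = query, sister = sister, categories = cats,
      support = node_support(tree, parent)
    ),
    class = "sister_result"
  )
}

#' @export
print.sister_result <- function(x, ...) {
  cat(
    "<sister_result>", x$query, "~ {", paste(x$sister, collapse = ", "),
    "} support", x$support, "\n"
  )
  invisible(x)
}

#' Confirm a horizontal gene transfer candidate from its gene tree
#'
#' Confirmed when every sister leaf of the query maps to the donor category
#' predicted by the top similarity hit AND the split's bootstrap support
#' strictly exceeds `min_support`. A mixed sister rejects regardless of
#' support; a missing support annotation is treated conservatively as
#' unsupported.
#'
#' @param tree A rooted `phylo`.
#' @param query Query leaf label.
#' @param leaf_categories Tibble (`leaf`, `category`).
#' @param donor Donor category id.
#' @param min_support Strict support cutoff (default 50).
#' @return One-row tibble: `query`, `donor`, `confirmed`, `reason`
#'   (`"confirmed"`, `"mixed_sister"`, `"low_support"`, `"no_support"`),
#'   `support`, `n_sister`.
#' @export
confirm_hgt <- function(tree, query, leaf_categories, donor, min_support = 50) {
  sr <- sister_group(tree, query, leaf_categories)
  cats <- sr$categories
  reason <- if (any(is.na(cats)) || any(cats != donor)) {
    "mixed_sister"
  } else if (is.na(sr$support)) {
    "no_support"
  } else if (sr$support > min_support) {
    "confirmed"
  } else {
    "low_support"
  }
  tibble::tibble(
    query = query, donor = donor,
    confirmed = reason == "confirmed", reason = reason,
    support = sr$support, n_sister = length(sr$sister)
  )
}

#' Alpha-proteobacterial paraphyly test
#'
#' Tests whether the query resolves within a paraphyletic group of
#' alpha-proteobacteria and eukaryotes to the exclusion of all non-alpha
#' prokaryote leaves: the verdict is true iff some edge of the unrooted tree
#' separates the query, at least one alpha-proteobacterial leaf, and any
#' eukaryote leaves from every non-alpha prokaryote leaf (no non-alpha
#' prokaryote on the query side). The maximal qualifying split is reported.
#'
#' @param tree A `phylo` (treated as unrooted).
#' @param query Query leaf label.
#' @param leaf_categories Tibble (`leaf`, `category`); the query may have
#'   `NA` category.
#' @param tax A `taxonomy` supplying the alpha-proteobacterium and
#'   prokaryote flags.
#' @return List of class `paraphyly_result`: `query`, `verdict`,
#'   `query_side` (leaves of the maximal qualifying split, or `NULL`),
#'   `excluded_prokaryotes` (the non-alpha prokaryote leaves).
#' @export
alpha_origin_test <- function(tree, query, leaf_categories, tax) {
  cats <- tax$categories
  lc <- tibble::as_tibble(leaf_categories)
  lc <- lc[lc$leaf != query, , drop = FALSE]
  flag <- function(leaf, col) {
    cat <- lc$category[match(leaf, lc$leaf)]
    i <- match(cat, cats$category_id)
    !is.na(i) && cats[[col]][i]
  }
  leaves <- setdiff(tree$tip.label, query)
  alpha <- leaves[purrr::map_lgl(leaves, ~ flag(.x, "is_alphaproteobacterium"))]
  oprok <- leaves[purrr::map_lgl(leaves, function(l) {
    flag(l, "is_prokaryote") && !flag(l, "is_alphaproteobacterium")
  })]
  if (length(alpha) == 0 || length(oprok) == 0) stop("underdetermined")

  unrooted <- ape::unroot(tree)
  tip_index(unrooted, query)
  ntip <- length(unrooted$tip.label)
  nodes <- unrooted$edge[, 2]
  best <- NULL
  for (v in nodes) {
    side <- clade_tips(unrooted, v)
    qside <- if (query %in% side) side else setdiff(unrooted$tip.label, side)
    if (!any(oprok %in% qside) && any(alpha %in% qside)) {
      if (is.null(best) || length(qside) > length(best)) best <- qside
    }
  }
  structure(
    list(
      query = query, verdict = !is.null(best),
      query_side = best, excluded_prokaryotes = oprok
    ),
    class = "paraphyly_result"
  )
}

#' @export
print.paraphyly_result <- function(x, ...) {
  cat("<paraphyly_result>", x$query, "verdict:", x$verdict, "\n")
  invisible(x)
}

#' Screen one library for an alpha-proteobacterial commensal
#'
#' A library (genome or transcriptome) is called positive when at least
#' `min_markers` of the single-copy alpha-proteobacterial marker genes have
#' a true paraphyly verdict (default: at least 2 of a panel of 27).
#'
#' @param verdicts Tibble (`marker`, `verdict`) or named logical vector of
#'   per-marker [alpha_origin_test()] verdicts for one library.
#' @param min_markers Minimum positive markers (default 2).
#' @param marker_panel_size Maximum panel size (default 27).
#' @return One-row tibble: `n_markers_positive`, `positive`,
#'   `markers_positive` (comma-separated).
#' @export
screen_library <- function(verdicts, min_markers = 2, marker_panel_size = 27) {
  if (is.logical(verdicts)) {
    verdicts <- tibble::tibble(marker = names(verdicts), verdict = unname(verdicts))
  }
  verdicts <- tibble::as_tibble(verdicts)
  if (anyDuplicated(verdicts$marker) > 0) stop("duplicate marker id")
  if (nrow(verdicts) > marker_panel_size) {
    stop("more verdicts than the marker panel size (", marker_panel_size, ")")
  }
  pos <- verdicts$marker[verdicts$verdict]
  tibble::tibble(
    n_markers_positive = length(pos),
    positive = length(pos) >= min_markers,
    markers_positive = paste(sort(pos), collapse = ",")
  )
}

#' Screen many libraries for commensals
#'
#' @param verdicts Tibble with columns `library`, `marker`, `verdict`.
#' @param ... Passed to [screen_library()].
#' @return Tibble with one [screen_library()] row per library.
#' @export
screen_libraries <- function(verdicts, ...) {
  verdicts <- tibble::as_tibble(verdicts)
  split(verdicts, verdicts$library) |>
    purrr::imap(function(v, lib) {
      dplyr::bind_cols(tibble::tibble(library = lib), screen_library(v, ...))
    }) |>
    purrr::list_rbind()
}
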