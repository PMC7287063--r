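#' Load a hierarchical taxonomic category system
#'
#' Reads a category table describing the leaf categories used for homology-hit
#' classification (the analysis "sub-categories") together with their full
#' lineage paths, and builds a validated taxonomy: a rooted tree of named
#' nodes plus a category map carrying per-category membership flags.
#'
#' The table must have three columns:
#' \describe{
#'   \item{category_id}{unique leaf category identifier; must equal the last
#'     element of `path`.}
#'   \item{path}{semicolon-delimited lineage from the root to the category
#'     leaf, e.g. `cellular;eukaryota;stramenopiles;diatoms;araphid-pennate`.}
#'   \item{flags}{comma-delimited tokens among `diatom`, `stramenopile`,
#'     `eukaryote`, `prokaryote`, `alphaproteobacterium`, plus an optional
#'     `lineage=<node>` token naming the category's major lineage node (a node
#'     on its own path; defaults to the leaf's parent).}
#' }
#'
#' Node identifiers are case-sensitive exact strings; a node name appearing in
#' two paths must have the same parent and depth everywhere (otherwise the
#' table is rejected, since that would imply an orphan or a cycle).
#'
#' Flags must be internally consistent: `diatom` implies `stramenopile`
#' implies `eukaryote`; `alphaproteobacterium` implies `prokaryote`;
#' `eukaryote` and `prokaryote` are mutually exclusive. For diatom categories
#' a `diatom_subgroup` label is derived as the path node immediately below the
#' lineage node (the leaf itself when the category sits directly under the
#' lineage).
#'
#' @param table Path to a TSV file, or a data frame with the three columns
#'   above.
#' @return An object of class `taxonomy`: a list with `nodes` (tibble:
#'   `node_id`, `parent_id`, `depth`) and `categories` (tibble of per-category
#'   flags, lineage and subgroup labels).
#' @examples
#' tax <- load_taxonomy(system.file("extdata", "toy_taxonomy.tsv",
#'   package = "symbiophylo"
#' ))
#' tax$categories
#' lca(tax, c("araphid-pennate", "raphid-pennate"))
#' @export
load_taxonomy <- function(table) {
  if (is.character(table) && length(table) == 1) {
    table <- readr::read_tsv(table,
      col_types = readr::cols(.default = readr::col_character()),
      progress = FALSE
    )
  }
  table <- tibble::as_tibble(table)
  required <- c("category_id", "path", "flags")
  missing_cols <- setdiff(required, names(table))
  if (length(missing_cols) > 0) {
    stop("category table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(table) == 0) stop("no categories")
  dup <- which(duplicated(table$category_id))
  if (length(dup) > 0) {
    stop("duplicate category '", table$category_id[dup[1]], "' at row ", dup[1])
  }

  paths <- stringr::str_split(table$path, ";")
  paths <- purrr::map(paths, stringr::str_trim)
  bad <- which(purrr::map_lgl(paths, ~ any(.x == "") || length(.x) < 1))
  if (length(bad) > 0) stop("empty lineage path at row ", bad[1])
  leaf_mismatch <- which(purrr::map_chr(paths, dplyr::last) != table$category_id)
  if (length(leaf_mismatch) > 0) {
    stop(
      "path leaf does not match category_id at row ", leaf_mismatch[1],
      " ('", table$category_id[leaf_mismatch[1]], "')"
    )
  }

  # Build the node set; reject any node observed with two different parents
  # or depths (orphan / cycle in disguise).
  parent <- character(0)
  depth <- integer(0)
  for (i in seq_along(paths)) {
    p <- paths[[i]]
    for (j in seq_along(p)) {
      node <- p[j]
      par <- if (j == 1) NA_character_ else p[j - 1]
      if (node %in% names(parent)) {
        if (!identical(parent[[node]], par) || depth[[node]] != j - 1L) {
          stop(
            "inconsistent placement of node '", node, "' at row ", i,
            " (conflicting parent or depth)"
          )
        }
      } else {
        parent[[node]] <- par
        depth[[node]] <- j - 1L
      }
    }
  }
  roots <- names(parent)[is.na(parent)]
  if (length(roots) != 1) {
    stop("taxonomy must have exactly one root, found: ", paste(roots, collapse = ", "))
  }

  flag_tokens <- stringr::str_split(table$flags, ",")
  flag_tokens <- purrr::map(flag_tokens, ~ stringr::str_trim(.x[.x != ""]))
  known <- c("diatom", "stramenopile", "eukaryote", "prokaryote", "alphaproteobacterium")
  lineage <- character(nrow(table))
  flags <- matrix(FALSE, nrow(table), length(known), dimnames = list(NULL, known))
  for (i in seq_len(nrow(table))) {
    toks <- flag_tokens[[i]]
    lin_tok <- toks[stringr::str_starts(toks, "lineage=")]
    plain <- setdiff(toks, lin_tok)
    unknown <- setdiff(plain, known)
    if (length(unknown) > 0) {
      stop("unknown flag '", unknown[1], "' at row ", i)
    }
    flags[i, plain] <- TRUE
    p <- paths[[i]]
    lin <- if (length(lin_tok) > 0) {
      sub("^lineage=", "", lin_tok[1])
    } else if (length(p) >= 2) {
      p[length(p) - 1]
    } else {
      p[1]
    }
    if (!lin %in% p) {
      stop("lineage node '", lin, "' not on the path of row ", i)
    }
    lineage[i] <- lin
  }
  fl <- tibble::as_tibble(flags)
  names(fl) <- paste0("is_", known)
  if (any(fl$is_diatom & !fl$is_stramenopile) ||
    any(fl$is_stramenopile & !fl$is_eukaryote)) {
    stop("flag inconsistency: diatom implies stramenopile implies eukaryote")
  }
  if (any(fl$is_alphaproteobacterium & !fl$is_prokaryote)) {
    stop("flag inconsistency: alphaproteobacterium implies prokaryote")
  }
  if (any(fl$is_eukaryote & fl$is_prokaryote)) {
    stop("flag inconsistency: eukaryote and prokaryote are mutually exclusive")
  }

  subgroup <- purrr::map2_chr(paths, lineage, function(p, lin) {
    i <- match(lin, p)
    if (is.na(i) || i >= length(p)) p[length(p)] else p[i + 1]
  })
  subgroup[!fl$is_diatom] <- NA_character_

  categories <- dplyr::bind_cols(
    tibble::tibble(category_id = table$category_id, lineage = lineage),
    fl,
    tibble::tibble(diatom_subgroup = subgroup, path = paths)
  )

  nodes <- tibble::tibble(
    node_id = names(parent),
    parent_id = unname(parent),
    depth = unname(depth)
  )
  structure(
    list(nodes = nodes, categories = categories, root = roots),
    class = "taxonomy"
  )
}

#' @export
print.taxonomy <- function(x, ...) {
  cat(
    "<taxonomy>", nrow(x$nodes), "nodes,",
    nrow(x$categories), "leaf categories, root:", x$root, "\n"
  )
  invisible(x)
}

#' Bundled toy taxonomy
#'
#' A small category system spanning four diatom subgroups, other
#' stramenopiles, other eukaryotes (haptophytes, chlorophytes) and four
#' prokaryote lineages (two alpha-proteobacterial sub-categories,
#' gamma-proteobacteria, chlorobi, verrucomicrobia). Each plantable
#' horizontal-transfer donor lineage carries at least two sub-categories so
#' that the first-two-hit origin rule can resolve it. Intended for tests and
#' examples; real analyses supply their own category table.
#'
#' @return A `taxonomy` object.
#' @export
toy_taxonomy <- function() {
  load_taxonomy(system.file("extdata", "toy_taxonomy.tsv",
    package = "symbiophylo", mustWork = TRUE
  ))
}

tax_parent_vec <- function(tax) {
  stats::setNames(tax$nodes$parent_id, tax$nodes$node_id)
}

tax_depth_vec <- function(tax) {
  stats::setNames(tax$nodes$depth, tax$nodes$node_id)
}

#' Root-to-node path of a taxonomy node
#'
#' @param tax A `taxonomy`.
#' @param node A node id.
#' @return Character vector of node ids from the root down to `node`.
#' @export
node_path <- function(tax, node) {
  parent <- tax_parent_vec(tax)
  if (!node %in% names(parent)) stop("unknown node '", node, "'")
  out <- node
  while (!is.na(parent[[node]])) {
    node <- parent[[node]]
    out <- c(node, out)
  }
  out
}

#' Last common ancestor of a set of taxonomy nodes
#'
#' Returns the deepest node whose subtree contains every input node. The
#' result is invariant to the order and multiplicity of the inputs, and
#' `lca(tax, c(S, lca(tax, S)))` equals `lca(tax, S)`.
#'
#' @param tax A `taxonomy`.
#' @param nodes Non-empty character vector of node ids (categories are nodes).
#' @return A single node id.
#' @export
lca <- function(tax, nodes) {
  nodes <- unique(nodes)
  if (length(nodes) == 0) stop("empty node set")
  parent <- tax_parent_vec(tax)
  depth <- tax_depth_vec(tax)
  unknown <- setdiff(nodes, names(parent))
  if (length(unknown) > 0) stop("unknown node '", unknown[1], "'")
  lca2 <- function(a, b) {
    while (depth[[a]] > depth[[b]]) a <- parent[[a]]
    while (depth[[b]] > depth[[a]]) b <- parent[[b]]
    while (a != b) {
      a <- parent[[a]]
      b <- parent[[b]]
    }
    a
  }
  Reduce(lca2, nodes)
}

#' Test ancestry between taxonomy nodes
#'
#' @param tax A `taxonomy`.
#' @param ancestor,node Node ids.
#' @return `TRUE` if `ancestor` lies on the root path of `node`
#'   (ancestor-or-self).
#' @export
is_ancestor <- function(tax, ancestor, node) {
  ancestor %in% node_path(tax, node)
}

# Aggregate a category flag up to an arbitrary node: TRUE iff every leaf
# category descending from (or equal to) the node carries the flag. Used to
# decide whether an LCA label is host-side or symbiont-side at domain level.
node_flag <- function(tax, node, flag) {
  cats <- tax$categories
  under <- purrr::map_lgl(cats$path, ~ node %in% .x)
  if (!any(under)) {
    return(NA)
  }
  all(cats[[flag]][under])
}
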