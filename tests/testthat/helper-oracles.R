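# Independent oracles used by the unit and acceptance tests. These
# deliberately re-derive results by brute force (path intersection, edge
# deletion + component labelling, exhaustive enumeration) so they share no
# code path with the implementation they check.

# ---- taxonomy ----------------------------------------------------------

# Random rooted taxonomy: node i (i >= 2) attaches to a uniform earlier
# node; leaf nodes become the categories.
random_taxonomy_table <- function(n_nodes) {
  stopifnot(n_nodes >= 3)
  parent <- c(NA, vapply(2:n_nodes, function(i) sample.int(i - 1, 1), 1L))
  name <- paste0("n", seq_len(n_nodes))
  is_leaf <- !(seq_len(n_nodes) %in% parent)
  path_of <- function(i) {
    p <- i
    while (!is.na(parent[p[1]])) p <- c(parent[p[1]], p)
    name[p]
  }
  leaves <- which(is_leaf)
  tibble::tibble(
    category_id = name[leaves],
    path = vapply(leaves, function(i) paste(path_of(i), collapse = ";"), ""),
    flags = "eukaryote"
  )
}

# Brute-force LCA: intersect the root paths, return the deepest shared node.
oracle_lca <- function(tax, nodes) {
  paths <- lapply(nodes, function(n) node_path(tax, n))
  shared <- Reduce(intersect, paths)
  shared[length(shared)]
}

# ---- origin classification --------------------------------------------

toy_diatom_cats <- c(
  "araphid-pennate", "raphid-pennate", "polar-centric", "radial-centric"
)
toy_stram_cats <- c(toy_diatom_cats, "pelagophytes", "eustigmatophytes")
toy_euk_cats <- c(
  toy_stram_cats, "haptophyte-prymnesiales", "haptophyte-coccolithales",
  "chlorophytes"
)
toy_proteo_cats <- c(
  "alpha-rhodobacterales", "alpha-rhizobiales", "gammaproteobacteria"
)
toy_lineage_of <- c(
  "araphid-pennate" = "diatoms", "raphid-pennate" = "diatoms",
  "polar-centric" = "diatoms", "radial-centric" = "diatoms",
  "pelagophytes" = "pelagophytes", "eustigmatophytes" = "eustigmatophytes",
  "haptophyte-prymnesiales" = "haptophytes",
  "haptophyte-coccolithales" = "haptophytes",
  "chlorophytes" = "chlorophytes",
  "alpha-rhodobacterales" = "alphaproteobacteria",
  "alpha-rhizobiales" = "alphaproteobacteria",
  "gammaproteobacteria" = "gammaproteobacteria",
  "chlorobi-a" = "chlorobi", "chlorobi-b" = "chlorobi",
  "verrucomicrobia-a" = "verrucomicrobia", "verrucomicrobia-b" = "verrucomicrobia"
)

# Hand-written rule table for the first-two-hit classifier on the toy
# taxonomy (independent of the tree machinery).
oracle_classify <- function(c1, c2) {
  lin1 <- toy_lineage_of[[c1]]
  lin2 <- toy_lineage_of[[c2]]
  euk1 <- c1 %in% toy_euk_cats
  euk2 <- c2 %in% toy_euk_cats
  if (lin1 == lin2) {
    list(
      level = if (euk1) "lineage" else "prokaryote-lineage",
      label = lin1,
      hgt = !(c1 %in% toy_diatom_cats)
    )
  } else if (c1 %in% toy_stram_cats && c2 %in% toy_stram_cats) {
    list(level = "stramenopile", label = "stramenopiles", hgt = FALSE)
  } else if (euk1 && euk2) {
    list(level = "eukaryote", label = "eukaryota", hgt = FALSE)
  } else if (!euk1 && !euk2) {
    lab <- if (all(c(c1, c2) %in% toy_proteo_cats)) "proteobacteria" else "bacteria"
    list(level = "unresolved", label = lab, hgt = FALSE)
  } else {
    list(level = "unresolved", label = "cellular", hgt = FALSE)
  }
}

make_hits <- function(gene, cats, exponents, qstart = NA_integer_,
                      qend = NA_integer_, bitscore = NULL) {
  if (is.null(bitscore)) bitscore <- 30 + 2 * exponents
  tibble::tibble(
    query_id = gene,
    subject_id = paste0(cats, "|x", seq_along(cats)),
    category = cats,
    evalue = 10^(-exponents),
    bitscore = bitscore,
    qstart = rep_len(as.integer(qstart), length(cats)),
    qend = rep_len(as.integer(qend), length(cats))
  )
}

# ---- trees -------------------------------------------------------------

# Tip labels of the component containing `from_node` after deleting edge
# `drop` (row index into tree$edge), by breadth-first search on the
# undirected adjacency.
component_tips <- function(tree, drop, from_node) {
  edges <- tree$edge[-drop, , drop = FALSE]
  adj <- split(
    c(edges[, 2], edges[, 1]),
    c(edges[, 1], edges[, 2])
  )
  seen <- from_node
  frontier <- from_node
  while (length(frontier) > 0) {
    nxt <- unique(unlist(adj[as.character(frontier)]))
    frontier <- setdiff(nxt, seen)
    seen <- c(seen, frontier)
  }
  tree$tip.label[seen[seen <= length(tree$tip.label)]]
}

# Brute-force paraphyly rule: try every edge bipartition.
oracle_alpha_origin <- function(tree, query, alpha_leaves, oprok_leaves) {
  q <- match(query, tree$tip.label)
  for (i in seq_len(nrow(tree$edge))) {
    qside <- component_tips(tree, i, q)
    if (!any(oprok_leaves %in% qside) && any(alpha_leaves %in% qside)) {
      return(TRUE)
    }
  }
  FALSE
}

# Brute-force sister set on a rooted tree: enumerate every clade (the
# component hanging below each edge), take the smallest one strictly
# containing the query, minus the query.
oracle_sister <- function(tree, query) {
  best <- NULL
  for (i in seq_len(nrow(tree$edge))) {
    side <- component_tips(tree, i, tree$edge[i, 2])
    if (query %in% side && length(side) > 1 &&
      (is.null(best) || length(side) < length(best))) {
      best <- side
    }
  }
  setdiff(best, query)
}

# ---- alignments --------------------------------------------------------

oracle_trim_termini <- function(aln, threshold = 0.70) {
  qualifies <- logical(ncol(aln))
  for (j in seq_len(ncol(aln))) {
    res <- aln[, j]
    res <- res[res != "-" & res != "."]
    if (length(res) >= 2) {
      qualifies[j] <- (max(table(res)) / length(res)) > threshold
    }
  }
  if (!any(qualifies)) {
    return(NULL)
  }
  c(min(which(qualifies)), max(which(qualifies)))
}

oracle_trim_gaps <- function(aln, gt = 0.5) {
  keep <- logical(ncol(aln))
  for (j in seq_len(ncol(aln))) {
    keep[j] <- sum(aln[, j] != "-" & aln[, j] != ".") / nrow(aln) >= gt
  }
  which(keep)
}

random_alignment <- function(n_taxa, len, gap_prob = 0.3) {
  m <- matrix(
    sample(c("A", "R", "N", "D", "-"), n_taxa * len,
      replace = TRUE,
      prob = c(rep((1 - gap_prob) / 4, 4), gap_prob)
    ),
    n_taxa, len,
    dimnames = list(paste0("t", seq_len(n_taxa)), NULL)
  )
  m
}

# ---- enrichment --------------------------------------------------------

# Exhaustive tail probability: enumerate every |fg|-subset of the
# background and count those with at least `observed` term members.
oracle_hyper_tail <- function(term_domains, background, n_fg, observed) {
  draws <- utils::combn(background, n_fg, simplify = FALSE)
  mean(vapply(draws, function(d) sum(d %in% term_domains) >= observed, TRUE))
}
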