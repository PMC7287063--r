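tax <- toy_taxonomy()

test_that("sister_group reads the sibling subtree and the parent split support", {
  tr <- ape::read.tree(text = "((q:1,(a1:1,a2:1)90:1)75:1,out:1);")
  sr <- sister_group(tr, "q")
  expect_setequal(sr$sister, c("a1", "a2"))
  expect_equal(sr$support, 75)

  tr2 <- ape::read.tree(text = "((q:1,a1:1)40:1,out:1);")
  sr2 <- sister_group(tr2, "q")
  expect_equal(sr2$sister, "a1")
  expect_equal(sr2$support, 40)

  # polytomous parent: union of the non-query siblings
  tr3 <- ape::read.tree(text = "((q:1,a1:1,(b1:1,b2:1)80:1)66:1,out:1);")
  expect_setequal(sister_group(tr3, "q")$sister, c("a1", "b1", "b2"))

  expect_error(sister_group(tr, "nope"), "absent")
  expect_error(
    sister_group(ape::read.tree(text = "(q:1,(a:1,b:1)50:1);"), "q"),
    "root"
  )
})

test_that("sister_group matches the minimal-bipartition oracle on random trees", {
  set.seed(21)
  for (rep in 1:40) {
    n <- sample(6:25, 1)
    tr <- ape::rtree(n)
    tr$node.label <- as.character(sample(0:100, tr$Nnode, replace = TRUE))
    q <- sample(tr$tip.label[tr$tip.label != tr$tip.label[1]], 1)
    parent <- tr$edge[tr$edge[, 2] == match(q, tr$tip.label), 1]
    if (parent == n + 1) next # query at root: error case tested above
    expect_setequal(sister_group(tr, q)$sister, oracle_sister(tr, q))
  }
})

test_that("sister evaluation is invariant under ladderization", {
  set.seed(3)
  gt <- simulate_gene_tree("chlorobi-a", support = 88, tax = tax, seed = 12)
  v1 <- confirm_hgt(gt$tree, "QUERY", gt$leaf_categories, "chlorobi-a")
  v2 <- confirm_hgt(
    ape::ladderize(gt$tree), "QUERY", gt$leaf_categories, "chlorobi-a"
  )
  v3 <- confirm_hgt(
    ape::ladderize(gt$tree, right = FALSE), "QUERY", gt$leaf_categories,
    "chlorobi-a"
  )
  expect_equal(v1$confirmed, v2$confirmed)
  expect_equal(v1$support, v2$support)
  expect_equal(v1, v3)
})

test_that("confirm_hgt applies the strict support cutoff and sister purity", {
  lc <- tibble::tibble(
    leaf = c("q", "a1", "a2", "h1", "out"),
    category = c(NA, "chlorobi-a", "chlorobi-a", "haptophyte-prymnesiales", "chlorophytes")
  )
  mk <- function(s) {
    ape::read.tree(text = sprintf("((q:1,(a1:1,a2:1)90:1)%s:1,out:1);", s))
  }
  expect_true(confirm_hgt(mk(75), "q", lc, "chlorobi-a")$confirmed)
  v50 <- confirm_hgt(mk(50), "q", lc, "chlorobi-a")
  expect_false(v50$confirmed)
  expect_equal(v50$reason, "low_support")
  expect_true(confirm_hgt(mk(51), "q", lc, "chlorobi-a")$confirmed)

  mixed <- ape::read.tree(text = "((q:1,(a1:1,h1:1)90:1)90:1,out:1);")
  vm <- confirm_hgt(mixed, "q", lc, "chlorobi-a")
  expect_equal(vm$reason, "mixed_sister")

  nosup <- ape::read.tree(text = "((q:1,(a1:1,a2:1)90:1):1,out:1);")
  expect_equal(confirm_hgt(nosup, "q", lc, "chlorobi-a")$reason, "no_support")
})

test_that("root_tree roots on a monophyletic outgroup and falls back to midpoint", {
  tr <- ape::read.tree(text = "(((q:1,a:1)80:1,b:1)60:1,(o1:1,o2:2)90:1);")
  rooted <- root_tree(tr, c("o1", "o2"), "q")
  expect_equal(attr(rooted, "rooting"), "outgroup")
  expect_setequal(sister_group(rooted, "q")$sister, "a")

  expect_error(root_tree(tr, tr$tip.label, "q"), "all leaves")
  expect_error(root_tree(tr, c("zz"), "q"), "absent")

  # outgroup paraphyletic around the query: midpoint fallback with warning
  tr2 <- ape::read.tree(text = "((o1:1,(q:3,o2:1)70:1)50:1,(a:1,b:1)40:1);")
  expect_warning(rooted2 <- root_tree(tr2, c("o1", "o2"), "q"), "midpoint")
  expect_equal(attr(rooted2, "rooting"), "midpoint")
  expect_true(ape::is.rooted(rooted2))
})

test_that("alpha_origin_test follows the paraphyly rule on hand-built trees", {
  lc <- tibble::tibble(
    leaf = c("q", "a1", "a2", "e1", "p1", "p2", "p3", "p4", "p5"),
    category = c(
      NA, "alpha-rhodobacterales", "alpha-rhizobiales",
      "haptophyte-prymnesiales",
      "gammaproteobacteria", "chlorobi-a", "chlorobi-b",
      "verrucomicrobia-a", "verrucomicrobia-b"
    )
  )
  good <- ape::read.tree(
    text = "(((q:1,a1:1)90:1,(a2:1,e1:1)80:1)70:1,(((p1:1,p2:1)50:1,(p3:1,p4:1)60:1)40:1,p5:1)90:1);"
  )
  res <- alpha_origin_test(good, "q", lc, tax)
  expect_true(res$verdict)
  expect_setequal(res$query_side, c("q", "a1", "a2", "e1"))
  expect_setequal(res$excluded_prokaryotes, paste0("p", 1:5))

  # one gamma-proteobacterium inside the query-side split breaks the rule
  bad <- ape::read.tree(
    text = "(((q:1,p1:1)90:1,(a1:1,a2:1)80:1)70:1,(((e1:1,p2:1)50:1,(p3:1,p4:1)60:1)40:1,p5:1)90:1);"
  )
  expect_false(alpha_origin_test(bad, "q", lc, tax)$verdict)

  only_alpha <- ape::read.tree(text = "((q:1,a1:1)90:1,a2:1);")
  expect_error(alpha_origin_test(only_alpha, "q", lc, tax), "underdetermined")
})

test_that("alpha_origin_test equals the edge-deletion oracle on random trees", {
  set.seed(31)
  cats <- tax$categories
  alpha_cats <- cats$category_id[cats$is_alphaproteobacterium]
  oprok_cats <- cats$category_id[cats$is_prokaryote & !cats$is_alphaproteobacterium]
  euk_cats <- cats$category_id[cats$is_eukaryote]
  for (rep in 1:60) {
    n <- sample(8:30, 1)
    tr <- ape::rtree(n)
    pool <- c(alpha_cats, oprok_cats, euk_cats)
    lc <- tibble::tibble(
      leaf = tr$tip.label,
      category = sample(pool, n, replace = TRUE)
    )
    q <- sample(tr$tip.label, 1)
    lc$category[lc$leaf == q] <- NA
    alpha <- lc$leaf[!is.na(lc$category) & lc$category %in% alpha_cats]
    oprok <- lc$leaf[!is.na(lc$category) & lc$category %in% oprok_cats]
    if (length(alpha) == 0 || length(oprok) == 0) next
    got <- alpha_origin_test(tr, q, lc, tax)$verdict
    expect_equal(got, oracle_alpha_origin(tr, q, alpha, oprok))
  }
})

test_that("library screening implements the at-least-two-marker rule", {
  v <- function(k, n = 27) {
    tibble::tibble(
      marker = sprintf("m%02d", seq_len(n)),
      verdict = seq_len(n) <= k
    )
  }
  expect_true(screen_library(v(3))$positive)
  expect_false(screen_library(v(1))$positive)
  expect_false(screen_library(v(0))$positive)
  expect_error(
    screen_library(tibble::tibble(marker = c("m1", "m1"), verdict = TRUE)),
    "duplicate marker"
  )
  expect_error(screen_library(v(2, n = 30)), "panel")
  # monotone: adding a positive marker never flips positive -> negative
  for (k in 0:26) {
    expect_gte(
      screen_library(v(k + 1))$positive,
      screen_library(v(k))$positive
    )
  }
})
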