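tax <- toy_taxonomy()

test_that("rank_hits keeps one best hit per category with stated tie-breaks", {
  # duplicate category: keep the stronger hit
  h <- make_hits("g", c("chlorobi-a", "chlorobi-a"), c(50, 40))
  r <- rank_hits(h)
  expect_equal(nrow(r), 1)
  expect_equal(r$evalue, 1e-50)

  # A(1e-30), B(1e-20), A(1e-10) -> [A(1e-30), B(1e-20)]
  h <- make_hits("g", c("chlorobi-a", "chlorobi-b", "chlorobi-a"), c(30, 20, 10))
  r <- rank_hits(h)
  expect_equal(r$category, c("chlorobi-a", "chlorobi-b"))
  expect_equal(r$evalue, c(1e-30, 1e-20))

  # equal e-values: higher bitscore wins
  h <- make_hits("g", c("chlorobi-a", "chlorobi-b"), c(20, 20),
    bitscore = c(180, 200)
  )
  expect_equal(rank_hits(h)$bitscore, c(200, 180))

  # full tie: lexicographic subject id
  h <- make_hits("g", c("chlorobi-a", "chlorobi-b"), c(20, 20),
    bitscore = c(200, 200)
  )
  h$subject_id <- c("zzz", "aaa")
  expect_equal(rank_hits(h)$subject_id, c("aaa", "zzz"))

  expect_equal(nrow(rank_hits(make_hits("g", character(), numeric()))), 0)
  expect_error(
    rank_hits(dplyr::bind_rows(
      make_hits("g1", "chlorobi-a", 10), make_hits("g2", "chlorobi-a", 10)
    )),
    "single gene"
  )
})

test_that("classify_origin reproduces the documented escalation rules", {
  cl <- function(cats) {
    classify_origin(rank_hits(make_hits("g", cats, c(30, 20))), tax)
  }
  x <- cl(c("araphid-pennate", "raphid-pennate"))
  expect_equal(x$level, "lineage")
  expect_equal(x$label, "diatoms")
  expect_false(x$hgt_candidate)

  x <- cl(c("araphid-pennate", "pelagophytes"))
  expect_equal(x$level, "stramenopile")

  x <- cl(c("araphid-pennate", "haptophyte-prymnesiales"))
  expect_equal(x$level, "eukaryote")

  x <- cl(c("alpha-rhodobacterales", "alpha-rhizobiales"))
  expect_equal(x$level, "prokaryote-lineage")
  expect_equal(x$label, "alphaproteobacteria")
  expect_true(x$hgt_candidate)

  # host + prokaryote stays unresolved, never a transfer call
  x <- cl(c("araphid-pennate", "chlorobi-a"))
  expect_equal(x$level, "unresolved")
  expect_false(x$hgt_candidate)

  x <- classify_origin(rank_hits(make_hits("g", "chlorobi-a", 30)), tax)
  expect_equal(x$level, "unresolved")
  expect_equal(x$n_hits, 1)

  expect_error(
    classify_origin(make_hits("g", c("x", "y"), c(30, 20)), tax),
    "absent from taxonomy"
  )
})

test_that("classify_origin matches the hand-written rule table exhaustively", {
  cats <- tax$categories$category_id
  for (c1 in cats) {
    for (c2 in setdiff(cats, c1)) {
      got <- classify_origin(rank_hits(make_hits("g", c(c1, c2), c(30, 20))), tax)
      want <- oracle_classify(c1, c2)
      expect_equal(got$level, want$level, info = paste(c1, c2))
      expect_equal(got$label, want$label, info = paste(c1, c2))
      expect_equal(got$hgt_candidate, want$hgt, info = paste(c1, c2))
    }
  }
})

test_that("classification is invariant to raw hit order", {
  set.seed(5)
  for (rep in 1:20) {
    cats <- sample(tax$categories$category_id, 5, replace = TRUE)
    h <- make_hits("g", cats, sample(seq(10, 60, by = 2), 5))
    ref <- classify_origin(rank_hits(h), tax)
    for (p in 1:10) {
      perm <- h[sample(nrow(h)), ]
      expect_equal(classify_origin(rank_hits(perm), tax), ref)
    }
  }
})

test_that("a deeper taxonomy yields sub-category level calls", {
  deep <- load_taxonomy(tibble::tibble(
    category_id = c("stauro-a", "stauro-b", "raphid-x"),
    path = c(
      "root;diatoms;araphid;stauro-a",
      "root;diatoms;araphid;stauro-b",
      "root;diatoms;raphid;raphid-x"
    ),
    flags = "diatom,stramenopile,eukaryote,lineage=diatoms"
  ))
  x <- classify_origin(
    rank_hits(make_hits("g", c("stauro-a", "stauro-b"), c(30, 20))), deep
  )
  expect_equal(x$level, "sub-category")
  expect_equal(x$label, "araphid")
})

test_that("lineage-specific detection applies the strict e-value threshold", {
  focal <- c("araphid-pennate")
  h <- dplyr::bind_rows(
    make_hits("g", "araphid-pennate", 30),
    make_hits("g", "araphid-pennate", 12),
    make_hits("g", "haptophyte-prymnesiales", 3) # 1e-3 >= 1e-5: ignored
  )
  expect_true(detect_lineage_specific(h, focal))

  h2 <- dplyr::bind_rows(
    make_hits("g", "araphid-pennate", 30),
    make_hits("g", "chlorophytes", 8)
  )
  expect_false(detect_lineage_specific(h2, focal))

  expect_false(detect_lineage_specific(make_hits("g", "araphid-pennate", 3), focal))
  # exact boundary: evalue == threshold is not significant
  expect_false(detect_lineage_specific(
    make_hits("g", "araphid-pennate", 5), focal
  ))
})

test_that("lowering the threshold never creates a lineage-specific call", {
  set.seed(9)
  focal <- tax$categories$category_id[tax$categories$lineage == "diatoms"]
  for (rep in 1:30) {
    h <- make_hits("g",
      sample(tax$categories$category_id, 6, replace = TRUE),
      stats::runif(6, 1, 40)
    )
    thresholds <- 10^-c(3, 5, 8, 12)
    calls <- vapply(
      thresholds,
      function(t) detect_lineage_specific(h, focal, evalue_max = t), TRUE
    )
    # once FALSE because a non-focal hit is significant, tightening the
    # threshold may flip to TRUE only by silencing that hit - but never
    # the reverse via non-focal additions
    sig_nonfocal <- function(t) {
      s <- h[h$evalue < t, ]
      nrow(s) > 0 && !all(s$category %in% focal)
    }
    expect_equal(calls, vapply(
      thresholds,
      function(t) {
        s <- h[h$evalue < t, ]
        nrow(s) > 0 && all(s$category %in% focal)
      }, TRUE
    ))
  }
})

test_that("chimera detection requires two confident conflicting segments", {
  # bacterial N-terminus + diatom C-terminus
  h <- dplyr::bind_rows(
    make_hits("g", c("verrucomicrobia-a", "verrucomicrobia-b"), c(40, 35), 1, 120),
    make_hits("g", c("araphid-pennate", "raphid-pennate"), c(38, 30), 131, 250)
  )
  cc <- detect_chimera(h, tax)
  expect_true(cc$is_chimera)
  expect_equal(nrow(cc$segments), 2)
  expect_equal(cc$segments$label, c("verrucomicrobia", "diatoms"))

  # full-length single origin: one segment, not chimeric
  h1 <- make_hits("g", c("araphid-pennate", "raphid-pennate"), c(40, 30), 1, 250)
  cc1 <- detect_chimera(h1, tax)
  expect_false(cc1$is_chimera)
  expect_equal(nrow(cc1$segments), 1)

  # one segment unresolved: not chimeric
  h2 <- dplyr::bind_rows(
    make_hits("g", c("verrucomicrobia-a", "verrucomicrobia-b"), c(40, 35), 1, 120),
    make_hits("g", "araphid-pennate", 30, 131, 250)
  )
  expect_false(detect_chimera(h2, tax)$is_chimera)

  # conflicting segments within one domain are not a chimera
  h3 <- dplyr::bind_rows(
    make_hits("g", c("araphid-pennate", "raphid-pennate"), c(40, 35), 1, 120),
    make_hits("g", c("polar-centric", "radial-centric"), c(38, 30), 131, 250)
  )
  expect_false(detect_chimera(h3, tax)$is_chimera)

  expect_error(
    detect_chimera(make_hits("g", "chlorobi-a", 30), tax),
    "ranges required"
  )
})

test_that("the contig-context filter retains candidates with diatom neighbours", {
  gene_map <- tibble::tibble(
    gene_id = c("h1", "d1", "d2", "d3", "h2", "h3", "b1", "b2"),
    contig_id = c("c1", "c1", "c1", "c1", "c2", "c3", "c3", "c3")
  )
  calls <- dplyr::bind_rows(
    classify_origins(dplyr::bind_rows(
      make_hits("h1", c("chlorobi-a", "chlorobi-b"), c(40, 30)),
      make_hits("d1", c("araphid-pennate", "raphid-pennate"), c(40, 30)),
      make_hits("d2", c("araphid-pennate", "polar-centric"), c(40, 30)),
      make_hits("d3", c("raphid-pennate", "radial-centric"), c(40, 30)),
      make_hits("h2", c("chlorobi-a", "chlorobi-b"), c(40, 30)),
      make_hits("h3", c("alpha-rhodobacterales", "alpha-rhizobiales"), c(40, 30)),
      make_hits("b1", c("alpha-rhodobacterales", "alpha-rhizobiales"), c(40, 30)),
      make_hits("b2", c("gammaproteobacteria", "chlorobi-a"), c(40, 30))
    ), tax)
  )
  out <- contig_context_filter(c("h1", "h2", "h3"), calls, gene_map, tax)
  st <- stats::setNames(out$status, out$gene_id)
  expect_equal(st[["h1"]], "retained") # 3 diatom neighbours
  expect_equal(st[["h2"]], "flagged_contaminant") # alone on contig
  expect_equal(st[["h3"]], "flagged_contaminant") # bacterial neighbours only
  expect_error(
    contig_context_filter("nope", calls, gene_map, tax),
    "missing from the gene map"
  )
})
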