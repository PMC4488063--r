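test_that("newick parsing mirrors nesting and strips annotations", {
  tr <- parse_newick("(A,(B,C));")
  expect_s3_class(tr, "phylo")
  expect_setequal(tr$tip.label, c("A", "B", "C"))
  expect_equal(tr$Nnode, 2L)
  # lengths and support values are discarded: same split/clade structure
  annotated <- parse_newick("((A:1,B:2)90:0.1,C);")
  plain <- parse_newick("((A,B),C);")
  taxa <- build_taxon_index(list(annotated, plain))
  expect_identical(extract_clades(annotated, taxa)$keys,
                   extract_clades(plain, taxa)$keys)
  expect_null(annotated$edge.length)
})

test_that("malformed newick input fails with positional diagnostics", {
  expect_error(parse_newick("((A,B),(A,C));"), "duplicate leaf label")
  expect_error(parse_newick(""), "empty")
  expect_error(parse_newick("((A,B),C;"), "unbalanced '\\('")
  expect_error(parse_newick("(A,B)),C;"), "position 6")
  expect_error(parse_newick("(A,B)"), "not terminated")
})

test_that("TNT parenthetical dialect resolves indices and separators", {
  ref <- parse_newick("(A,(B,C));")
  taxa <- build_taxon_index(list(ref))
  by_index <- parse_tnt_trees("(0 (1 2));", c("A", "B", "C"))[[1L]]
  by_name <- parse_tnt_trees("(A (B C));")[[1L]]
  expect_identical(extract_clades(by_index, taxa)$keys,
                   extract_clades(ref, taxa)$keys)
  expect_identical(extract_clades(by_name, taxa)$keys,
                   extract_clades(ref, taxa)$keys)
  # multiple trees, '*' separator, tread header
  two <- parse_tnt_trees("tread 'two trees' (A (B C)) * (B (A C));")
  expect_length(two, 2L)
  expect_error(parse_tnt_trees("(0 (1 5));", c("A", "B", "C")),
               "out of range")
  expect_error(parse_tnt_trees("(A (B C)) extra;"), "trailing")
})

test_that("newick writer quotes awkward labels and round-trips", {
  tr <- parse_newick("(('one two',B),C);")
  out <- write_newick(tr)
  expect_match(out, "'one two'", fixed = TRUE)
  back <- parse_newick(out)
  expect_setequal(back$tip.label, c("one two", "B", "C"))
  # embedded quote
  tr2 <- parse_newick("(('don''t',B),C);")
  expect_true("don't" %in% tr2$tip.label)
  expect_true("don't" %in% parse_newick(write_newick(tr2))$tip.label)
})

test_that("parse-write-parse preserves the split set on random trees", {
  for (i in 1:40) {
    n <- 8L + (17L * i) %% 121L
    tr <- random_tree(n, seed = 1000 + i)
    taxa <- build_taxon_index(list(tr))
    back <- parse_newick(write_newick(tr))
    expect_identical(sort(extract_splits(back, taxa)$keys),
                     sort(extract_splits(tr, taxa)$keys))
  }
})

test_that("rerooting preserves the unrooted split set", {
  for (i in 1:10) {
    tr <- random_tree(20, seed = 50 + i)
    taxa <- build_taxon_index(list(tr))
    before <- sort(extract_splits(tr, taxa)$keys)
    out <- tr$tip.label[(3L * i) %% length(tr$tip.label) + 1L]
    rr <- reroot_outgroup(tr, out)
    expect_true(ape::is.rooted(rr))
    expect_identical(sort(extract_splits(rr, taxa)$keys), before)
  }
  tr <- parse_newick("(A,(B,C));")
  expect_error(reroot_outgroup(tr, c("A", "B", "C")), "proper subset")
  expect_error(reroot_outgroup(tr, "Z"), "absent")
  # non-displayable outgroup
  t4 <- parse_newick("((A,B),(C,D));")
  expect_error(reroot_outgroup(t4, c("A", "C")), "not displayable")
})

test_that("nexus matrices parse with verified dimensions and missing-data expansion", {
  nex <- paste(
    "#NEXUS", "BEGIN DATA;",
    "DIMENSIONS NTAX=4 NCHAR=3;",
    "FORMAT SYMBOLS=\"01\" MISSING=? GAP=-;",
    "MATRIX", "A 010", "B 01?", "C 110", "D -10", ";", "END;",
    sep = "\n")
  m <- parse_nexus_data(nex)
  expect_identical(m$taxa, c("A", "B", "C", "D"))
  expect_equal(m$n_char, 3L)
  # '?' and '-' expand to the observed alphabet of the column
  expect_identical(m$cells[[3L]][["B"]], c("0"))
  expect_identical(m$cells[[1L]][["D"]], c("0", "1"))
  # gap-as-state keeps '-' as a symbol
  m2 <- parse_nexus_data(nex, gap_as_state = TRUE)
  expect_identical(m2$cells[[1L]][["D"]], "-")
  expect_true("-" %in% m2$alphabet[[1L]])
  # per-character alphabets are the observed states of the column
  dna <- paste("#NEXUS", "BEGIN DATA;",
               "DIMENSIONS NTAX=3 NCHAR=2;",
               "FORMAT DATATYPE=STANDARD SYMBOLS=\"ACGT\" MISSING=?;",
               "MATRIX", "x AC", "y AG", "z TC", ";", "END;", sep = "\n")
  md <- parse_nexus_data(dna)
  expect_identical(md$alphabet[[1L]], c("A", "T"))
  expect_identical(md$alphabet[[2L]], c("C", "G"))
})

test_that("nexus dimension or block violations are rejected", {
  bad_dim <- paste("#NEXUS", "BEGIN DATA;",
                   "DIMENSIONS NTAX=2 NCHAR=5;",
                   "MATRIX", "A 0101", "B 1010", ";", "END;", sep = "\n")
  expect_error(parse_nexus_data(bad_dim), "nchar|NCHAR")
  expect_error(parse_nexus_data("#NEXUS\nBEGIN TREES;\nEND;"),
               "no DATA block")
  two <- paste("#NEXUS", "BEGIN DATA;", "END;", "BEGIN DATA;", "END;",
               sep = "\n")
  expect_error(parse_nexus_data(two), "multiple DATA blocks")
})

test_that("nexus write/read round-trips a character matrix", {
  tr <- random_tree(6, 3)
  m <- random_matrix(NULL, 5, c("0", "1", "2"), 11, tree = tr)
  f <- withr::local_tempfile(fileext = ".nex")
  write_nexus_matrix(m, f)
  back <- read_nexus_matrix(f)
  expect_identical(back$raw[m$taxa, ], m$raw[m$taxa, ])
})
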