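quartet <- function() parse_newick("((A,B),(C,D));")

test_that("parsimony length matches hand-enumerated quartets", {
  m <- char_mat(c("A", "B", "C", "D"),
                c("0", "0", "0", "0"),   # constant
                c("0", "0", "1", "1"),   # one clean gain
                c("0", "1", "0", "1"))   # two parallel gains
  tr <- quartet()
  expect_equal(fitch_length(tr, m, 1), 0L)
  expect_equal(fitch_length(tr, m, 2), 1L)
  expect_equal(fitch_length(tr, m, 3), 2L)
  # leaf absent from the matrix
  m2 <- char_mat(c("A", "B", "C"), c("0", "0", "1"))
  expect_error(fitch_length(tr, m2, 1), "absent from the character matrix")
})

test_that("parsimony length equals the exhaustive assignment minimum", {
  for (i in 1:40) {
    n <- 5L + i %% 4L            # 5..8 leaves
    s <- 2L + i %% 2L            # 2..3 states
    tr <- random_tree(n, 5000 + i)
    m <- random_matrix(NULL, 2, as.character(seq_len(s) - 1L),
                       5100 + i, tree = tr, change_prob = 0.3)
    for (j in 1:2) {
      cells <- topocomp:::char_cells(tr, m, j)
      alpha <- m$alphabet[[j]]
      if (length(alpha) <= 1L) next
      expect_equal(fitch_length(tr, m, j),
                   oracle_fitch(tr, cells, length(alpha)))
    }
  }
})

test_that("parsimony length agrees with an independent implementation", {
  skip_if_not_installed("phangorn")
  for (i in 1:10) {
    tr <- random_tree(10, 5500 + i)
    m <- random_matrix(NULL, 6, c("0", "1", "2"), 5600 + i, tree = tr,
                       change_prob = 0.25)
    dat <- phangorn::phyDat(m$raw, type = "USER",
                            levels = c("0", "1", "2"))
    expect_equal(sum(vapply(seq_len(m$n_char), function(j)
                   fitch_length(tr, m, j), integer(1))),
                 as.integer(phangorn::parsimony(tr, dat,
                                                method = "sankoff")))
  }
})

test_that("ACCTRAN and DELTRAN are most-parsimonious and extreme", {
  # constant character: both variants constant everywhere
  m0 <- char_mat(c("A", "B", "C", "D"), c("1", "1", "1", "1"))
  tr <- quartet()
  ra <- reconstruct(tr, m0, 1, "ACCTRAN")
  expect_equal(ra$length, 0L)
  expect_true(all(ra$states == "1"))
  # reversal-vs-parallelism ambiguity: ACCTRAN gains early and reverses,
  # DELTRAN gains twice in parallel; both realize the fitch length, and
  # they agree on the unambiguous gain of state 2
  tr6 <- parse_newick("((A,(B,C)),(D,(E,F)));")
  m6 <- char_mat(c("A", "B", "C", "D", "E", "F"),
                 c("1", "1", "0", "0", "0", "2"))
  acc <- reconstruct(tr6, m6, 1, "ACCTRAN")
  del <- reconstruct(tr6, m6, 1, "DELTRAN")
  L <- fitch_length(tr6, m6, 1)
  expect_equal(acc$length, L)
  expect_equal(del$length, L)
  expect_false(identical(acc$changes, del$changes))
  f_id <- which(tr6$tip.label == "F")
  expect_true(any(acc$changes$child == f_id & acc$changes$to == "2"))
  expect_true(any(del$changes$child == f_id & del$changes$to == "2"))
  # both variants' assignments are in the exhaustive MP set
  cells <- topocomp:::char_cells(tr6, m6, 1)
  mp <- oracle_mp_assignments(tr6, cells, 3L)
  alpha <- m6$alphabet[[1L]]
  expect_true(any(vapply(mp, function(a)
    identical(alpha[a], acc$states), logical(1))))
  expect_true(any(vapply(mp, function(a)
    identical(alpha[a], del$states), logical(1))))
})

test_that("reconstruction change counts equal the parsimony length", {
  for (i in 1:15) {
    tr <- random_tree(7, 6000 + i)
    m <- random_matrix(NULL, 3, c("0", "1", "2"), 6100 + i, tree = tr,
                       change_prob = 0.3)
    for (j in seq_len(m$n_char)) {
      L <- fitch_length(tr, m, j)
      expect_equal(reconstruct(tr, m, j, "ACCTRAN")$length, L)
      expect_equal(reconstruct(tr, m, j, "DELTRAN")$length, L)
    }
  }
})

test_that("missing data never creates a change on its own terminal branch", {
  tr <- parse_newick("((A,B),(C,D));")
  m <- char_mat(c("A", "B", "C", "D"), c("?", "0", "1", "1"))
  for (v in c("ACCTRAN", "DELTRAN")) {
    rec <- reconstruct(tr, m, 1, v)
    a_id <- which(tr$tip.label == "A")
    expect_false(a_id %in% rec$changes$child)
  }
})

test_that("synapomorphy categories follow the three-way scheme", {
  tr <- quartet()
  # single gain, consistency index 1: unique and non-homoplastic
  m1 <- char_mat(c("A", "B", "C", "D"), c("0", "0", "1", "1"))
  r1 <- classify_transformations(tr, m1)
  expect_equal(nrow(r1), 1L)
  expect_identical(r1$ambiguity, "unambiguous")
  expect_identical(r1$category, "unique-nonhomoplastic")
  # two independent gains: non-unique and homoplastic
  m2 <- char_mat(c("A", "B", "C", "D"), c("0", "1", "0", "1"))
  r2 <- classify_transformations(tr, m2)
  expect_equal(nrow(r2), 2L)
  expect_identical(unique(r2$category), "nonunique-homoplastic")
  expect_setequal(r2$child_label, c("B", "D"))
  # single-origin state inside an otherwise homoplastic character:
  # unique and homoplastic
  tr6 <- parse_newick("((A,B),((C,D),(E,F)));")
  m3 <- char_mat(c("A", "B", "C", "D", "E", "F"),
                 c("1", "0", "1", "0", "2", "2"))
  r3 <- classify_transformations(tr6, m3)
  rec2 <- r3[r3$to == "2", ]
  expect_equal(nrow(rec2), 1L)
  expect_identical(rec2$category, "unique-homoplastic")
  expect_identical(rec2$ambiguity, "unambiguous")
  expect_identical(sort(r3$category[r3$to == "1"]),
                   rep("nonunique-homoplastic", 2L))
  # ambiguous optimization yields not-applicable records
  tr4 <- parse_newick("((A,(B,C)),D);")
  m4 <- char_mat(c("A", "B", "C", "D"), c("1", "1", "0", "0"))
  r4 <- classify_transformations(tr4, m4)
  expect_true(all(r4$ambiguity == "ambiguous"))
  expect_true(all(r4$category == "not-applicable"))
  expect_gt(nrow(r4), 0L)
})

test_that("minimum-length characters never yield homoplastic records", {
  count <- 0L
  for (i in 1:25) {
    tr <- random_tree(8, 7000 + i)
    m <- random_matrix(NULL, 4, c("0", "1"), 7100 + i, tree = tr,
                       change_prob = 0.25)
    recs <- classify_transformations(tr, m)
    for (j in seq_len(m$n_char)) {
      L <- fitch_length(tr, m, j)
      sub <- recs[recs$character == j - 1L, ]
      if (L == length(m$alphabet[[j]]) - 1L && nrow(sub)) {
        count <- count + 1L
        expect_false(any(grepl("homoplastic",
                               sub$category[sub$ambiguity ==
                                            "unambiguous"]) &
                         sub$category[sub$ambiguity == "unambiguous"] !=
                         "unique-nonhomoplastic"))
        expect_true(all(sub$category[sub$ambiguity == "unambiguous"] ==
                        "unique-nonhomoplastic"))
      }
    }
  }
  expect_gt(count, 5L)  # the sweep actually exercised the property
})

test_that("diagnosis CSV and SVG artifacts reflect the records", {
  tr <- parse_newick("((A,B),(C,D));")
  m <- char_mat(c("A", "B", "C", "D"),
                c("0", "0", "1", "1"), c("0", "1", "0", "1"))
  recs <- classify_transformations(tr, m)
  dir <- withr::local_tempdir()
  csv <- file.path(dir, "diag.csv")
  svg <- file.path(dir, "diag.svg")
  write_diagnosis(recs, tr, csv = csv, svg = svg)
  back <- utils::read.csv(csv, comment.char = "#",
                          stringsAsFactors = FALSE)
  expect_equal(nrow(back), nrow(recs))
  expect_identical(names(back),
                   c("character", "child_node", "child_label", "from",
                     "to", "ambiguity", "category"))
  # footer carries the total tree length
  footer <- grep("total_tree_length", readLines(csv), value = TRUE)
  expect_match(footer, paste0(attr(recs, "total_length"), "$"))
  # SVG has one glyph circle per record and node-number labels
  skip_if_not_installed("xml2")
  doc <- xml2::read_xml(svg)
  circles <- xml2::xml_find_all(doc, ".//*[local-name()='circle']")
  expect_length(circles, nrow(recs))
  texts <- xml2::xml_text(
    xml2::xml_find_all(doc, ".//*[local-name()='text']"))
  expect_true(all(c("A", "B", "C", "D") %in% texts))
  expect_true(any(grepl("^n[0-9]+$", texts)))
  # empty diagnosis: header-only CSV and a bare tree SVG
  m0 <- char_mat(c("A", "B", "C", "D"), c("0", "0", "0", "0"))
  recs0 <- classify_transformations(tr, m0)
  write_diagnosis(recs0, tr, csv = csv, svg = svg)
  expect_equal(nrow(utils::read.csv(csv, comment.char = "#")), 0L)
  doc0 <- xml2::read_xml(svg)
  expect_length(xml2::xml_find_all(doc0,
                                   ".//*[local-name()='circle']"), 0L)
})
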