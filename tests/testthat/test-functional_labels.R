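test_that("canonicalize sorts, deduplicates, and passes empty sets through", {
  expect_identical(canonicalize(c("Transmembrane", "Membrane", "Membrane")),
                   c("Membrane", "Transmembrane"))
  expect_identical(canonicalize(character(0)), character(0))
  expect_identical(canonicalize("Kinase"), "Kinase")
})

test_that("catalogue assigns one FL per distinct keyword combination in lexicographic order", {
  ds <- build_catalogue(organism_dataset(
    c("p1", "p2", "p3"), c("t1", "t2", "t3"),
    list(c("A", "B"), "A", c("B", "A")), "o"), scope = "x")
  tab <- ds$catalogue$table
  expect_equal(tab$fl_id, c("FLx1", "FLx2"))
  expect_identical(tab$keywords[[1L]], "A")            # ("A") < ("A","B")
  expect_identical(tab$keywords[[2L]], c("A", "B"))
  # identical combinations map to the same FL
  expect_equal(ds$proteins$fl_id[c(1L, 3L)], c("FLx2", "FLx2"))
  expect_equal(tab$n_proteins, c(1L, 2L))
  expect_error(build_catalogue(ds, scope = ""), "scope")
})

test_that("catalogue build is deterministic under protein permutation and bijective", {
  set.seed(5)
  ds <- random_small_dataset(6L)
  p <- ds$proteins
  perm <- sample(nrow(p))
  ds2 <- build_catalogue(organism_dataset(
    p$protein_id[perm], p$tu_id[perm], p$keywords[perm], "rand"),
    scope = "r")
  expect_identical(ds2$catalogue$table, ds$catalogue$table)
  expect_identical(
    ds2$proteins$fl_id[order(ds2$proteins$protein_id)],
    ds$proteins$fl_id[order(ds$proteins$protein_id)])
  # bijection: #FLs equals #distinct nonempty canonical keys
  keys <- vapply(p$keywords, function(k) paste(canonicalize(k), collapse = ";"), "")
  expect_equal(nrow(ds$catalogue$table), length(unique(keys[nzchar(keys)])))
  expect_false(anyDuplicated(ds$catalogue$table$fl_id) > 0)
  expect_false(anyDuplicated(ds$catalogue$table$key) > 0)
})

test_that("TU classes follow the FL-count invariants", {
  ds <- build_catalogue(organism_dataset(
    paste0("p", 1:5), c("t1", "t1", "t2", "t3", "t3"),
    list("A", "B", "A", character(0), character(0)), "o"), "x")
  cls <- setNames(ds$tus$class, ds$tus$tu_id)
  expect_equal(unname(cls[c("t1", "t2", "t3")]),
               c("polyform", "monoform", "unannotated"))
  nfl <- setNames(lengths(ds$tus$fls), ds$tus$tu_id)
  expect_true(all((cls == "unannotated") == (nfl == 0L)))
  expect_true(all((cls == "monoform") == (nfl == 1L)))
  expect_true(all((cls == "polyform") == (nfl >= 2L)))
})

test_that("catalogue intersection finds shared combinations and tallies keywords", {
  mk <- function(sets, org, scope) build_catalogue(organism_dataset(
    paste0(org, seq_along(sets)), paste0(org, "t", seq_along(sets)),
    sets, org), scope)$catalogue
  c1 <- mk(list(c("A", "B")), "u", "u")
  c2 <- mk(list(c("A", "B"), "C"), "v", "v")
  rep12 <- intersect_catalogues(list(c1, c2))
  expect_equal(rep12$common_count, 1L)
  expect_equal(rep12$common_labels$fl_id, "FLc1")

  disj <- intersect_catalogues(list(mk(list("A"), "u", "u"),
                                    mk(list("B"), "v", "v")))
  expect_equal(disj$common_count, 0L)
  expect_length(disj$keyword_frequency, 0L)

  c3 <- mk(list("A", c("A", "B")), "w", "w")
  c4 <- mk(list("A", c("A", "B")), "z", "z")
  both <- intersect_catalogues(list(c3, c4))
  expect_equal(unname(both$keyword_frequency["A"]), 2L)
  expect_equal(unname(both$keyword_frequency["B"]), 1L)
  # order invariance
  expect_equal(intersect_catalogues(list(c4, c3))$keyword_frequency,
               both$keyword_frequency)
  expect_error(intersect_catalogues(list(c1)), "at least 2")
})

test_that("top keywords rank by count with lexicographic tie-break", {
  rep_ <- structure(list(common_count = 2L, common_labels = NULL,
                         keyword_frequency = c(B = 2L, A = 2L, C = 1L)),
                    class = "shared_fl_report")
  expect_equal(top_keywords(rep_, 2L)$keyword, c("A", "B"))
  expect_equal(top_keywords(rep_, 1L),
               data.frame(keyword = "A", count = 2L))
  expect_equal(nrow(top_keywords(rep_, 99L)), 3L)
})
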