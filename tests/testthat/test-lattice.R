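demo_lat <- concept_lattice(crc_demo_context())

test_that("the demo context yields 7 concepts, 5 proper, 9 cover edges", {
  expect_equal(length(demo_lat$concepts), 7)
  expect_equal(proper_concept_count(demo_lat), 5)
  expect_equal(nrow(demo_lat$cover_edges), 9)
  # unique top (maximal extent) and bottom (minimal extent)
  sizes <- vapply(demo_lat$concepts, function(co) length(co$extent), 0L)
  expect_equal(sum(sizes == max(sizes)), 1)
  expect_equal(sum(sizes == min(sizes)), 1)
  expect_equal(demo_lat$concepts[[1]]$id, "C1")
  expect_equal(length(demo_lat$concepts[[1]]$extent), 3)  # top first
  # every concept is a Galois fixed point
  for (co in demo_lat$concepts) {
    expect_true(is_concept(demo_lat$context, co$extent, co$intent))
  }
})

test_that("degenerate contexts enumerate correctly", {
  one_full <- formal_context(matrix(1, 1, 1), "g1", "m1")
  lat <- concept_lattice(one_full)
  expect_equal(length(lat$concepts), 1)
  expect_equal(lat$concepts[[1]]$extent, "g1")
  expect_equal(lat$concepts[[1]]$intent, "m1")
  expect_equal(nrow(lat$cover_edges), 0)
  expect_equal(proper_concept_count(lat), 1)

  one_empty <- formal_context(matrix(0, 1, 1), "g1", "m1")
  lat2 <- concept_lattice(one_empty)
  expect_equal(length(lat2$concepts), 2)
  expect_equal(proper_concept_count(lat2), 0)

  all_ones <- formal_context(matrix(1, 4, 4))
  expect_equal(length(concept_lattice(all_ones)$concepts), 1)
  expect_equal(length(brute_force_concepts(all_ones)), 1)
})

test_that("a chain context produces a chain of c-1 cover edges", {
  # nested rows: g_i has attributes m_1..m_i
  I <- outer(1:4, 1:4, ">=")
  lat <- concept_lattice(formal_context(I))
  expect_equal(nrow(lat$cover_edges), length(lat$concepts) - 1)
})

test_that("NextClosure equals the powerset brute-force oracle on random contexts", {
  for (seed in 1:30) {
    rc <- random_context(sample(2:8, 1), sample(2:8, 1), seed,
                         p = sample(c(0.25, 0.5, 0.75), 1))
    lat <- concept_lattice(rc)
    expect_identical(concept_keys(lat$concepts), concept_keys(brute_force_concepts(rc)))
  }
})

test_that("lectic enumeration emits each closed intent once, in increasing order", {
  for (seed in c(3, 14, 27)) {
    rc <- random_context(6, 7, seed, p = 0.5)
    enum <- fcakb:::next_closure_intents(rc)
    keys <- vapply(enum$intents, function(b) paste(as.integer(b), collapse = ""), "")
    expect_false(anyDuplicated(keys) > 0)
    for (i in seq_len(length(enum$intents) - 1)) {
      expect_true(lectic_lt(enum$intents[[i]], enum$intents[[i + 1]]))
    }
  }
})

test_that("concept ids and order are reproducible across runs", {
  lat2 <- concept_lattice(crc_demo_context())
  expect_identical(vapply(demo_lat$concepts, `[[`, "", "id"),
                   vapply(lat2$concepts, `[[`, "", "id"))
  expect_identical(demo_lat$cover_edges, lat2$cover_edges)
})

test_that("subconcept order follows extent inclusion", {
  ids <- vapply(demo_lat$concepts, `[[`, "", "id")
  by_extent <- function(ext) {
    demo_lat$concepts[[which(vapply(demo_lat$concepts, function(co) {
      setequal(co$extent, ext)
    }, logical(1)))]]
  }
  p3 <- by_extent("P3"); p23 <- by_extent(c("P2", "P3")); p13 <- by_extent(c("P1", "P3"))
  top <- demo_lat$concepts[[1]]
  expect_true(subconcept_of(p3, p23))
  expect_false(subconcept_of(p13, p23))
  for (co in demo_lat$concepts) expect_true(subconcept_of(co, top))
})

test_that("brute force is guarded against large attribute sets", {
  big <- formal_context(matrix(1, 2, 21))
  expect_error(brute_force_concepts(big), class = "fcakb_size_error")
})

test_that("covering_edges validates duplicate extents and works on bare lists", {
  cs <- list(formal_concept(c("a", "b"), "x", id = "K1"),
             formal_concept("a", c("x", "y"), id = "K2"),
             formal_concept(c("b", "a"), "x", id = "K3"))
  expect_error(covering_edges(cs), class = "fcakb_validation_error")
  e <- covering_edges(brute_force_concepts(crc_demo_context()))
  expect_equal(nrow(e), 9)
})

test_that("lattice exports: concepts CSV shape and DOT node/edge counts", {
  csv <- tempfile(fileext = ".csv")
  export_lattice(demo_lat, csv, "concepts_csv")
  df <- read.csv(csv, stringsAsFactors = FALSE)
  expect_equal(names(df), c("concept_id", "attributes", "n_objects", "objects"))
  expect_equal(nrow(df), 7)
  # object ids listed only when count <= 2
  expect_true(all(df$objects[df$n_objects > 2] == "" | is.na(df$objects[df$n_objects > 2])))
  expect_true(all(nchar(df$objects[df$n_objects == 1]) > 0))

  dot <- tempfile(fileext = ".dot")
  export_lattice(demo_lat, dot, "dot")
  lines <- readLines(dot)
  expect_equal(sum(grepl("label=", lines)), 7)
  expect_equal(sum(grepl("->", lines)), 9)
})

test_that("lattice JSON round-trips concepts, edges and context", {
  f <- tempfile(fileext = ".json")
  write_lattice_json(demo_lat, f)
  back <- read_lattice_json(f)
  expect_identical(concept_keys(back$concepts), concept_keys(demo_lat$concepts))
  expect_identical(back$context$incidence, demo_lat$context$incidence)
  expect_equal(back$cover_edges$upper, demo_lat$cover_edges$upper)
  expect_equal(back$cover_edges$lower, demo_lat$cover_edges$lower)
})

test_that("plot method draws without error", {
  pdf(NULL)
  on.exit(dev.off())
  expect_invisible(plot(demo_lat))
})
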