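mkIa <- function(c, g, src = "CTD")
  data.frame(compound_id = c, gene_symbol = g,
             source = rep(src, length.out = length(c)),
             evidence = rep(NA_character_, length(c)),
             stringsAsFactors = FALSE)

proteinMap <- function(symbols, dir = withr::local_tempdir()) {
  parseDiseaseMap(writeSbml(file.path(dir, "map.xml"),
                            speciesDf(symbols, class = "PROTEIN")))
}

test_that("build intersects interactions with the map universe", {
  idx <- proteinMap(c("CFTR", "HSP90AA1"))
  link <- buildIndex(mkIa(c("C1", "C1"), c("CFTR", "XYZ")), idx,
                     timestamp = "t0")
  expect_equal(forwardMap(link), list(C1 = "CFTR"))
  expect_equal(droppedInteractions(link), 1L)
  # reverse has a key for every map gene-like symbol, empty when untargeted
  expect_equal(names(reverseMap(link)), c("CFTR", "HSP90AA1"))
  expect_equal(reverseMap(link)$HSP90AA1, character(0))
  # two compounds on the same gene transpose into one sorted reverse list
  l2 <- buildIndex(mkIa(c("C2", "C1"), c("CFTR", "CFTR")), idx,
                   timestamp = "t0")
  expect_equal(reverseMap(l2)$CFTR, c("C1", "C2"))
  # no interactions at all: empty forward, all-empty reverse
  l0 <- buildIndex(mkIa(character(0), character(0)), idx, timestamp = "t0")
  expect_equal(length(forwardMap(l0)), 0L)
  expect_true(all(lengths(reverseMap(l0)) == 0L))
  # an empty symbol universe cannot be indexed
  onlyOther <- parseDiseaseMap(writeSbml(
    file.path(withr::local_tempdir(), "o.xml"), speciesDf(c("ATP", "X"))))
  expect_error(buildIndex(mkIa("C1", "ATP"), onlyOther),
               class = "cmap_validation_error")
})

test_that("build is invariant under permutation of the interaction list", {
  set.seed(77)
  idx <- proteinMap(sprintf("G%02d", 1:20))
  ia <- mkIa(sprintf("C%d", sample(10, 60, replace = TRUE)),
             sprintf("G%02d", sample(25, 60, replace = TRUE)))
  l1 <- buildIndex(ia, idx, timestamp = "t0")
  l2 <- buildIndex(ia[sample(nrow(ia)), ], idx, timestamp = "t0")
  expect_identical(forwardMap(l1), forwardMap(l2))
  expect_identical(reverseMap(l1), reverseMap(l2))
  expect_identical(droppedInteractions(l1), droppedInteractions(l2))
})

test_that("transpose consistency holds on synthetic indices (pair oracle)", {
  set.seed(99)
  for (rep in 1:10) {
    nc <- sample(1:40, 1); ng <- sample(1:40, 1); n <- sample(0:300, 1)
    idx <- proteinMap(sprintf("G%03d", seq_len(ng)))
    ia <- mkIa(sprintf("C%02d", sample(nc, n, replace = TRUE)),
               sprintf("G%03d", sample(ng + 5L, n, replace = TRUE)))
    link <- buildIndex(ia, idx, timestamp = "t0")
    # brute-force enumeration of pairs from both sides
    expect_setequal(forwardPairs(link), reversePairs(link))
    # conservation: distinct on-map pairs = sum of forward = sum of reverse
    onMap <- unique(ia[ia$gene_symbol %in% sprintf("G%03d", seq_len(ng)), ])
    expect_equal(sum(lengths(forwardMap(link))), nrow(onMap))
    expect_equal(sum(lengths(reverseMap(link))), nrow(onMap))
  }
})

test_that("write/read round-trips and is byte-deterministic", {
  idx <- proteinMap(c("A", "B", "C"))
  link <- buildIndex(mkIa(c("C1", "C1", "C2"), c("A", "B", "A")), idx,
                     timestamp = "2026-01-01T00:00:00Z")
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- writeIndex(link, d1)
  p2 <- writeIndex(link, d2)
  expect_identical(readLines(p1[[1]]), readLines(p2[[1]]))
  expect_identical(readLines(p1[[2]]), readLines(p2[[2]]))
  back <- readIndex(d1)
  expect_identical(forwardMap(back), forwardMap(link))
  expect_identical(reverseMap(back), reverseMap(link))
  # the transpose is materialized: C1 appears under both A and B
  g2c <- jsonlite::fromJSON(p1[["gene2compounds"]])
  expect_true(all(c("A", "B") %in% names(g2c$genes)))
  expect_true(all(vapply(g2c$genes[c("A", "B")],
                         function(v) "C1" %in% v, logical(1))))
})

test_that("read rejects schema violations and planted transpose corruption", {
  idx <- proteinMap(c("A", "B"))
  link <- buildIndex(mkIa(c("C1", "C1"), c("A", "B")), idx,
                     timestamp = "t0")
  d <- withr::local_tempdir()
  writeIndex(link, d)
  g2cPath <- file.path(d, "gene2compounds.json")
  g2c <- jsonlite::fromJSON(g2cPath, simplifyVector = FALSE)
  # drop C1 under gene A: the loader must name the witness pair
  g2c$genes$A <- list()
  writeLines(jsonlite::toJSON(g2c, auto_unbox = TRUE), g2cPath)
  expect_error(readIndex(d), "C1.*A|A.*C1",
               class = "cmap_integrity_error")
  # a file missing its top-level key is a format error naming the key
  writeLines('{"header":{}}', g2cPath)
  expect_error(readIndex(d), "genes", class = "cmap_format_error")
})

test_that("unsorted forward lists are normalized on read with a warning", {
  idx <- proteinMap(c("A", "B"))
  link <- buildIndex(mkIa(c("C1", "C1"), c("A", "B")), idx,
                     timestamp = "t0")
  d <- withr::local_tempdir()
  paths <- writeIndex(link, d)
  fwd <- jsonlite::fromJSON(paths[[1]], simplifyVector = FALSE)
  fwd$compounds$C1 <- list("B", "A")
  writeLines(jsonlite::toJSON(fwd, auto_unbox = TRUE), paths[[1]])
  expect_warning(back <- readIndex(d), "normalized")
  expect_equal(forwardMap(back)$C1, c("A", "B"))
  # re-serialization restores the canonical byte form
  d2 <- withr::local_tempdir(); d3 <- withr::local_tempdir()
  back@header <- link@header
  writeIndex(back, d2)
  writeIndex(link, d3)
  expect_identical(readLines(file.path(d2, "compound2genes.json")),
                   readLines(file.path(d3, "compound2genes.json")))
})
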