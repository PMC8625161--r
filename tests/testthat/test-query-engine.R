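mkIa <- function(c, g, src = "CTD")
  data.frame(compound_id = c, gene_symbol = g,
             source = rep(src, length.out = length(c)),
             evidence = rep(NA_character_, length(c)),
             stringsAsFactors = FALSE)

# Map where symbol B lives in two compartments: A -> e1, B -> e2 + e3.
fanoutFixture <- function() {
  d <- withr::local_tempdir()
  sp <- data.frame(id = c("e1", "e2", "e3"),
                   name = c("A", "B", "B"),
                   class = "PROTEIN",
                   compartment = c("c1", "c1", "c2"),
                   stringsAsFactors = FALSE)
  idx <- parseDiseaseMap(writeSbml(file.path(d, "m.xml"), sp))
  link <- buildIndex(mkIa(c("C1", "C1", "C2", "C2"),
                          c("A", "B", "B", "C")), idx, timestamp = "t0")
  list(idx = idx, link = link)
}

test_that("targetsOf fans symbols out to every realizing entity", {
  fx <- fanoutFixture()
  hs <- targetsOf("C1", fx$link, fx$idx)
  expect_equal(highlightSymbols(hs), c("A", "B"))
  expect_equal(highlightEntities(hs), c("e1", "e2", "e3"))
  expect_equal(nTargets(hs), 3L)
  # one symbol, one entity
  hs2 <- targetsOf("C2", fx$link, fx$idx)
  expect_equal(nTargets(hs2), 2L)  # B fans out to e2 + e3
  # unknown compound is a soft empty result with a notice
  expect_message(hs0 <- targetsOf("NOPE", fx$link, fx$idx), "NOPE")
  expect_equal(nTargets(hs0), 0L)
  expect_equal(highlightSymbols(hs0), character(0))
})

test_that("commonTargets is the symbol-level intersection and symmetric", {
  fx <- fanoutFixture()
  both <- commonTargets("C1", "C2", fx$link, fx$idx)
  expect_equal(highlightSymbols(both), "B")
  expect_equal(highlightEntities(both), c("e2", "e3"))
  # symmetry and self-intersection
  expect_identical(highlightSymbols(commonTargets("C2", "C1", fx$link,
                                                  fx$idx)),
                   highlightSymbols(both))
  expect_identical(highlightSymbols(commonTargets("C1", "C1", fx$link,
                                                  fx$idx)),
                   highlightSymbols(targetsOf("C1", fx$link, fx$idx)))
  # disjoint sets intersect to nothing
  d <- withr::local_tempdir()
  idx <- parseDiseaseMap(writeSbml(file.path(d, "m.xml"),
                                   speciesDf(c("X", "Y"),
                                             class = "PROTEIN")))
  link <- buildIndex(mkIa(c("C1", "C2"), c("X", "Y")), idx,
                     timestamp = "t0")
  expect_equal(nTargets(commonTargets("C1", "C2", link, idx)), 0L)
})

test_that("compoundsFor resolves entity ids and symbols to the reverse list", {
  fx <- fanoutFixture()
  expect_equal(compoundsFor("e1", fx$link, fx$idx), "C1")
  expect_equal(compoundsFor("e3", fx$link, fx$idx), c("C1", "C2"))
  expect_equal(compoundsFor("B", fx$link, fx$idx), c("C1", "C2"))
  expect_error(compoundsFor("does_not_exist", fx$link, fx$idx),
               "does_not_exist", class = "cmap_input_error")
  # known entity with no interactions: empty list, not an error
  d <- withr::local_tempdir()
  idx <- parseDiseaseMap(writeSbml(file.path(d, "m.xml"),
                                   speciesDf(c("X", "Y"),
                                             class = "PROTEIN")))
  link <- buildIndex(mkIa("C1", "X"), idx, timestamp = "t0")
  expect_equal(compoundsFor("Y", link, idx), character(0))
  # a non-gene-like entity follows the build flag: outside the reverse
  # index it yields an empty result with a notice
  sp <- rbind(speciesDf("X", class = "PROTEIN"),
              data.frame(id = "spm", name = "ATP", class = NA,
                         compartment = "c1"))
  idx2 <- parseDiseaseMap(writeSbml(file.path(d, "m2.xml"), sp))
  link2 <- buildIndex(mkIa("C1", "X"), idx2, timestamp = "t0")
  expect_message(out <- compoundsFor("spm", link2, idx2), "ATP")
  expect_equal(out, character(0))
})

test_that("coverage counts covered symbols and mapped compounds", {
  d <- withr::local_tempdir()
  idx <- parseDiseaseMap(writeSbml(file.path(d, "m.xml"),
                                   speciesDf(c("A", "B", "C"),
                                             class = "PROTEIN")))
  link <- buildIndex(mkIa(c("C1", "C2"), c("A", "C")), idx,
                     timestamp = "t0")
  cov <- mapCoverage(link, idx)
  expect_equal(cov@nCovered, 2L)
  expect_equal(cov@nGeneEntities, 3L)
  expect_equal(coverageFraction(cov), 2 / 3)
  expect_equal(cov@nCompoundsMapped, 2L)
  expect_equal(highlightSymbols(cov@highlight), c("A", "C"))
  # zero case
  l0 <- buildIndex(mkIa(character(0), character(0)), idx,
                   timestamp = "t0")
  expect_equal(coverageFraction(mapCoverage(l0, idx)), 0)
  # saturation
  l1 <- buildIndex(mkIa(rep("C1", 3), c("A", "B", "C")), idx,
                   timestamp = "t0")
  expect_equal(coverageFraction(mapCoverage(l1, idx)), 1)
})

test_that("queries agree exhaustively with brute-force set oracles", {
  fx <- quietFixture(fixtureSpec(40, 25, 0.25, 0.15, 0.2, seed = 13),
                     withr::local_tempdir())
  pl <- quietPipeline(fx$files, timestamp = "t0")
  pairs <- fx$truth[fx$truth$on_map, c("compound_id", "gene_symbol")]
  allC <- sort(unique(fx$truth$compound_id))
  allG <- symbolsInMap(pl$entityIndex)

  for (cpd in allC) {
    expect_equal(
      suppressMessages(
        highlightSymbols(targetsOf(cpd, pl$link, pl$entityIndex))),
      oracleTargets(pairs, cpd))
  }
  for (g in allG) {
    expect_equal(suppressMessages(
      compoundsFor(g, pl$link, pl$entityIndex)),
      oracleCompounds(pairs, g))
  }
  # transpose duality on every (compound, gene) combination
  for (cpd in allC) {
    tg <- oracleTargets(pairs, cpd)
    for (g in allG) {
      expect_equal(cpd %in% oracleCompounds(pairs, g), g %in% tg)
    }
  }
  cov <- mapCoverage(pl$link, pl$entityIndex)
  expect_equal(cov@nCovered, length(unique(pairs$gene_symbol)))

  # pairwise comparisons on a subset, plus the subset/equality property
  some <- allC[seq(1, length(allC), by = 4)]
  for (a in some) for (b in some) {
    got <- highlightSymbols(commonTargets(a, b, pl$link, pl$entityIndex))
    expect_equal(got, oracleCommon(pairs, a, b))
    expect_true(all(got %in% oracleTargets(pairs, a)))
  }
})
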