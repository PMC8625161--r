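# Shared fixture builders and independent brute-force oracles. The oracles
# operate on raw pair tables with plain set operations so they stay
# independent of the index/query implementations they check.

`%||%` <- function(a, b) if (is.null(a)) b else a

demoFiles <- function() {
  d <- system.file("extdata", "demo", package = "cmaplink")
  c(compounds = file.path(d, "compounds.csv"),
    ctd = file.path(d, "ctd_interactions.tsv"),
    chembl = file.path(d, "chembl_interactions.tsv"),
    map = file.path(d, "cftr_map.xml"))
}

writeLinesTo <- function(lines, dir = withr::local_tempdir(),
                         name = "table.tsv") {
  path <- file.path(dir, name)
  writeLines(lines, path)
  path
}

# Minimal compound CSV from parallel vectors; NA fields become blanks.
writeCompoundCsv <- function(path, compound_id, inchikey = NA, smiles = NA,
                             cas_number = NA, pubchem_cid = NA,
                             names = compound_id) {
  n <- length(compound_id)
  blank <- function(x) ifelse(is.na(rep(x, length.out = n)), "",
                              rep(x, length.out = n))
  writeLines(c(
    "compound_id,inchikey,smiles,cas_number,pubchem_cid,names",
    sprintf("%s,%s,%s,%s,%s,%s", compound_id, blank(inchikey),
            blank(smiles), blank(cas_number), blank(pubchem_cid),
            blank(names))
  ), path)
  path
}

# Hand-rolled SBML writer for tests: species given as a data.frame with
# name, optional class (NA = no CellDesigner annotation), compartment.
writeSbml <- function(path, species) {
  spLines <- vapply(seq_len(nrow(species)), function(i) {
    cls <- species$class[i]
    open <- sprintf('<species id="%s" name="%s" compartment="%s"',
                    species$id[i], species$name[i],
                    species$compartment[i])
    if (is.na(cls)) return(paste0(open, "/>"))
    paste0(open, "><annotation><celldesigner:extension>",
           "<celldesigner:speciesIdentity><celldesigner:class>", cls,
           "</celldesigner:class></celldesigner:speciesIdentity>",
           "</celldesigner:extension></annotation></species>")
  }, character(1))
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    paste0('<sbml xmlns="http://www.sbml.org/sbml/level2/version4" ',
           'xmlns:celldesigner="http://www.sbml.org/2001/ns/celldesigner" ',
           'level="2" version="4">'),
    '<model id="m"><listOfCompartments>',
    '<compartment id="c1"/><compartment id="c2"/>',
    "</listOfCompartments><listOfSpecies>",
    spLines,
    "</listOfSpecies></model></sbml>"
  ), path)
  path
}

speciesDf <- function(name, class = NA_character_,
                      compartment = "c1", id = NULL) {
  data.frame(
    id = if (is.null(id)) sprintf("sp%03d", seq_along(name)) else id,
    name = name,
    class = rep(class, length.out = length(name)),
    compartment = rep(compartment, length.out = length(name)),
    stringsAsFactors = FALSE
  )
}

# ---- oracles ----------------------------------------------------------------

pairKey <- function(c, g) paste(c, g, sep = "\034")

# Forward/reverse of a LinkIndex flattened into a pair-key character set.
forwardPairs <- function(link) {
  fwd <- forwardMap(link)
  pairKey(rep(names(fwd), lengths(fwd)), unlist(fwd, use.names = FALSE))
}

reversePairs <- function(link) {
  rev <- reverseMap(link)
  pairKey(unlist(rev, use.names = FALSE), rep(names(rev), lengths(rev)))
}

# Brute-force expectation from a planted truth table: the distinct on-map
# (compound, gene) pairs.
truthPairs <- function(truth) {
  on <- truth[truth$on_map, , drop = FALSE]
  unique(pairKey(on$compound_id, on$gene_symbol))
}

# Independent set-operation oracles over a raw pair table.
oracleTargets <- function(pairs, compound) {
  sort(unique(pairs$gene_symbol[pairs$compound_id == compound]))
}

oracleCompounds <- function(pairs, gene) {
  sort(unique(pairs$compound_id[pairs$gene_symbol == gene]))
}

oracleCommon <- function(pairs, a, b) {
  sort(intersect(oracleTargets(pairs, a), oracleTargets(pairs, b)))
}

expectLinkEqualsTruth <- function(link, truth) {
  expect_setequal(forwardPairs(link), truthPairs(truth))
  expect_identical(droppedInteractions(link),
                   length(unique(pairKey(
                     truth$compound_id[!truth$on_map],
                     truth$gene_symbol[!truth$on_map]))))
}

quietPipeline <- function(files, ...) {
  suppressMessages(suppressWarnings(runPipeline(files, ...)))
}

quietFixture <- function(spec, dir) {
  suppressMessages(generateFixture(spec, dir))
}
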