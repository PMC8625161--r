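## fixtures module: synthetic compound collections, interaction tables and
## SBML maps with planted ground truth, so the whole pipeline is testable
## without downloads.

#' Construct a fixture specification
#'
#' @param nCompounds,nGenes sizes of the synthetic collection and map.
#' @param interactionDensity probability each (compound, gene) pair
#'   carries an interaction.
#' @param offmapGeneFraction probability an interaction is redirected to a
#'   gene absent from the map (these must be dropped at index build).
#' @param duplicateSourceFraction probability an interaction is emitted in
#'   both source dialects (these must collapse to one record on merge).
#' @param seed RNG seed; identical spec + seed reproduces byte-identical
#'   files.
#' @return a validated [FixtureSpec-class].
#' @export
fixtureSpec <- function(nCompounds, nGenes, interactionDensity = 0.2,
                        offmapGeneFraction = 0.1,
                        duplicateSourceFraction = 0.1, seed = 1L) {
  spec <- tryCatch(
    new("FixtureSpec",
        nCompounds = as.integer(nCompounds),
        nGenes = as.integer(nGenes),
        interactionDensity = as.numeric(interactionDensity),
        offmapGeneFraction = as.numeric(offmapGeneFraction),
        duplicateSourceFraction = as.numeric(duplicateSourceFraction),
        seed = as.integer(seed)),
    error = function(e) .validationError("invalid fixture spec: %s",
                                         conditionMessage(e)))
  spec
}

.syntheticInchikeys <- function(n) {
  gen <- function(k) {
    block <- function(len) vapply(seq_len(k), function(i)
      paste(sample(LETTERS, len, replace = TRUE), collapse = ""),
      character(1))
    paste0(block(14L), "-", block(10L), "-", block(1L))
  }
  keys <- gen(n)
  while (anyDuplicated(keys)) {
    dup <- duplicated(keys)
    keys[dup] <- gen(sum(dup))
  }
  keys
}

.sbmlSpecies <- function(id, name, cdClass = NULL) {
  if (is.null(cdClass)) {
    sprintf('      <species id="%s" name="%s" compartment="default"/>',
            id, name)
  } else {
    paste0(
      sprintf('      <species id="%s" name="%s" compartment="default">\n',
              id, name),
      "        <annotation>\n",
      "          <celldesigner:extension>\n",
      "            <celldesigner:speciesIdentity>\n",
      sprintf("              <celldesigner:class>%s</celldesigner:class>\n",
              cdClass),
      "            </celldesigner:speciesIdentity>\n",
      "          </celldesigner:extension>\n",
      "        </annotation>\n",
      "      </species>")
  }
}

.writeSyntheticMap <- function(path, geneSymbols) {
  n <- length(geneSymbols)
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    paste0('<sbml xmlns="http://www.sbml.org/sbml/level2/version4" ',
           'xmlns:celldesigner="http://www.sbml.org/2001/ns/celldesigner" ',
           'level="2" version="4">'),
    '  <model id="synthetic_map" name="Synthetic disease map">',
    "    <listOfCompartments>",
    '      <compartment id="default" name="default"/>',
    "    </listOfCompartments>",
    "    <listOfSpecies>",
    vapply(seq_len(n), function(i)
      .sbmlSpecies(sprintf("s%d", i), geneSymbols[i], "PROTEIN"),
      character(1)),
    .sbmlSpecies(sprintf("s%d", n + 1L), "SYNTH_ATP", "SIMPLE_MOLECULE"),
    .sbmlSpecies(sprintf("s%d", n + 2L), "SYNTH_METABOLITE"),
    "    </listOfSpecies>",
    "  </model>",
    "</sbml>"
  )
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, useBytes = TRUE)
}

#' Generate a synthetic pipeline fixture with planted truth
#'
#' Writes four files to \code{outDir}: a compound-collection CSV
#' (\code{compounds.csv}, ids \code{C000...} with well-formed synthetic
#' InChIKeys and CAS numbers), a CTD-style TSV (\code{ctd.tsv}, keyed by
#' CAS), a ChEMBL-style TSV (\code{chembl.tsv}, keyed alternately by
#' InChIKey and PubChem CID), and an SBML map (\code{map.xml}) with
#' \code{nGenes} PROTEIN species plus two OTHER species. Off-map
#' interactions target unique synthetic symbols (\code{OFF...}) absent
#' from the map. The returned planted-truth table lists the exact
#' (compound, gene) pair set and which pairs are off-map; identical spec
#' and seed reproduce byte-identical files.
#'
#' The synthetic InChIKeys are format-valid random strings, not derived
#' from structures: no pipeline step interprets InChIKey chemistry.
#'
#' @param spec a [FixtureSpec-class] from [fixtureSpec()].
#' @param outDir writable output directory (created if missing).
#' @return list with \code{files} (named paths), \code{truth} (data.frame
#'   \code{compound_id}, \code{gene_symbol}, \code{on_map}) and the
#'   \code{spec}.
#' @export
generateFixture <- function(spec, outDir) {
  if (!is(spec, "FixtureSpec"))
    .validationError("spec must be a FixtureSpec")
  validObject(spec)
  if (!dir.exists(outDir) &&
      !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
    .ioError("cannot create fixture directory %s", outDir)

  nC <- spec@nCompounds
  nG <- spec@nGenes
  cw <- max(3L, nchar(as.character(nC - 1L)))
  compoundIds <- sprintf(paste0("C%0", cw, "d"), seq_len(nC) - 1L)
  geneSymbols <- sprintf("G%04d", seq_len(nG))

  .withSeed(spec@seed, {
    inchikeys <- .syntheticInchikeys(nC)
    cas <- sprintf("%d-%02d-%d", 100L + seq_len(nC),
                   (seq_len(nC) * 7L) %% 100L, seq_len(nC) %% 10L)
    cids <- 100000L + seq_len(nC)
    smiles <- paste0("O=C(", strrep("C", seq_len(nC) %% 12L + 1L), ")N",
                     seq_len(nC))
    names1 <- sprintf("Compound %d", seq_len(nC))
    names2 <- sprintf("CMP-%04d", seq_len(nC))

    # interaction lattice: one Bernoulli draw per (compound, gene) slot,
    # then per-interaction redirection off-map and source assignment
    ci <- rep(seq_len(nC), each = nG)
    gi <- rep(seq_len(nG), times = nC)
    exists <- stats::runif(nC * nG) < spec@interactionDensity
    offmap <- stats::runif(nC * nG) < spec@offmapGeneFraction
    dup <- stats::runif(nC * nG) < spec@duplicateSourceFraction
    toCtd <- stats::runif(nC * nG) < 0.5

    ci <- ci[exists]; gi <- gi[exists]
    offmap <- offmap[exists]; dup <- dup[exists]; toCtd <- toCtd[exists]
    gene <- ifelse(offmap, sprintf("OFF%dX%d", ci, gi), geneSymbols[gi])

    truth <- data.frame(
      compound_id = compoundIds[ci],
      gene_symbol = gene,
      on_map = !offmap,
      stringsAsFactors = FALSE
    )

    inCtd <- toCtd | dup
    inChembl <- !toCtd | dup

    dbLines <- c(
      "compound_id,inchikey,smiles,cas_number,pubchem_cid,names",
      sprintf("%s,%s,%s,%s,%d,%s|%s", compoundIds, inchikeys, smiles, cas,
              cids, names1, names2)
    )
    ctdLines <- c(
      "ChemicalName\tCasRN\tGeneSymbol\tInteractionActions",
      if (any(inCtd)) sprintf("%s\t%s\t%s\taffects^activity",
                              names1[ci[inCtd]], cas[ci[inCtd]],
                              gene[inCtd])
    )
    # alternate compound key kind by compound parity
    key <- ifelse(ci %% 2L == 0L, inchikeys[ci], as.character(cids[ci]))
    chemblLines <- c(
      "compound_key\tgene_symbol\ttarget_name",
      if (any(inChembl)) sprintf("%s\t%s\t%s protein", key[inChembl],
                                 gene[inChembl], gene[inChembl])
    )

    files <- c(
      compounds = file.path(outDir, "compounds.csv"),
      ctd = file.path(outDir, "ctd.tsv"),
      chembl = file.path(outDir, "chembl.tsv"),
      map = file.path(outDir, "map.xml")
    )
    for (nm in c("compounds", "ctd", "chembl")) {
      lines <- switch(nm, compounds = dbLines, ctd = ctdLines,
                      chembl = chemblLines)
      con <- file(files[[nm]], open = "wb")
      writeLines(lines, con, useBytes = TRUE)
      close(con)
    }
    .writeSyntheticMap(files[["map"]], geneSymbols)

    list(files = files, truth = truth, spec = spec)
  })
}

#' Run the full pipeline over a generated fixture
#'
#' Convenience wrapper chaining load, parse, resolve, merge and build over
#' the file layout emitted by [generateFixture()] (or any directory with
#' the same file names). Used by tests and the CLI demo path.
#'
#' @param files named paths as returned in a fixture manifest
#'   (\code{compounds}, \code{ctd}, \code{chembl}, \code{map}).
#' @param geneLikeOnly passed to [buildIndex()].
#' @param timestamp passed to [buildIndex()].
#' @return list with \code{collection}, \code{entityIndex}, \code{link},
#'   \code{merged} interactions and the two \code{unresolved} reports.
#' @export
runPipeline <- function(files, geneLikeOnly = TRUE,
                        timestamp = format(Sys.time(),
                                           "%Y-%m-%dT%H:%M:%SZ",
                                           tz = "UTC")) {
  collection <- loadCompoundDb(files[["compounds"]], "csv")
  ctdRaw <- parseCtdTable(files[["ctd"]])
  chemblRaw <- parseChemblTable(files[["chembl"]])
  ctd <- resolveInteractions(ctdRaw, collection, "CTD")
  chembl <- resolveInteractions(chemblRaw, collection, "CHEMBL")
  merged <- mergeInteractions(ctd$interactions, chembl$interactions)
  entityIndex <- parseDiseaseMap(files[["map"]])
  link <- buildIndex(merged, entityIndex, geneLikeOnly = geneLikeOnly,
                     sources = basename(unname(files[c("ctd", "chembl")])),
                     timestamp = timestamp)
  list(collection = collection, entityIndex = entityIndex, link = link,
       merged = merged,
       unresolved = list(ctd = ctd$unresolved, chembl = chembl$unresolved))
}
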