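#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importFrom IRanges CharacterList
NULL

## ---- CompoundCollection -----------------------------------------------------

#' Compound collection with synonym and identifier indices
#'
#' Container for an application-specific compound collection (the custom
#' candidate-therapeutics database role). Each record carries an opaque
#' \code{compound_id}, the optional structure identifiers InChIKey, SMILES,
#' CAS registry number and PubChem CID, and an ordered synonym list whose
#' first element is the preferred display name.
#'
#' @slot records \code{DataFrame} with columns \code{compound_id},
#'   \code{inchikey}, \code{smiles}, \code{cas_number}, \code{pubchem_cid}
#'   and a \code{CharacterList} column \code{names}.
#' @slot synonymIndex named list: case-folded, trimmed name to character
#'   vector of compound ids carrying that name.
#' @slot idIndex named character vector: identifier-kind-qualified key
#'   (\code{"inchikey:..."}, \code{"cas:..."}, \code{"cid:..."},
#'   \code{"smiles:..."}, \code{"compound_id:..."}) to compound id.
#'
#' @seealso [loadCompoundDb()], [findCompounds()]
#' @export
setClass("CompoundCollection",
  representation(
    records = "DataFrame",
    synonymIndex = "list",
    idIndex = "character"
  )
)

setValidity("CompoundCollection", function(object) {
  rec <- object@records
  need <- c("compound_id", "inchikey", "smiles", "cas_number",
            "pubchem_cid", "names")
  if (!all(need %in% colnames(rec)))
    return(paste("records must have columns:", paste(need, collapse = ", ")))
  ids <- rec$compound_id
  if (any(is.na(ids)) || any(!nzchar(ids)))
    return("compound_id must be non-empty")
  if (anyDuplicated(ids))
    return(sprintf("duplicate compound_id: %s", ids[duplicated(ids)][1L]))
  ik <- rec$inchikey
  bad <- !is.na(ik) & !grepl(.INCHIKEY_RE, ik)
  if (any(bad))
    return(sprintf("malformed inchikey for %s", ids[bad][1L]))
  cas <- rec$cas_number
  bad <- !is.na(cas) & !grepl(.CAS_RE, cas)
  if (any(bad))
    return(sprintf("malformed cas_number for %s", ids[bad][1L]))
  if (any(lengths(rec$names) == 0L))
    return("every record must have at least one name")
  referenced <- unique(c(unlist(object@synonymIndex, use.names = FALSE),
                         unname(object@idIndex)))
  if (length(referenced) && !all(referenced %in% ids))
    return("index entries reference unknown compound ids")
  TRUE
})

## ---- EntityIndex ------------------------------------------------------------

#' Named-entity index of an SBML disease map
#'
#' One entity per SBML species, with the entity class read from a
#' CellDesigner extension annotation where present (\code{PROTEIN},
#' \code{GENE}, \code{RNA}; everything else is \code{OTHER}), plus a
#' name-normalized lookup from uppercased display name/alias to entity ids.
#'
#' @slot entities \code{DataFrame} with columns \code{entity_id},
#'   \code{display_name}, \code{entity_class}, \code{compartment} and a
#'   \code{CharacterList} column \code{aliases}.
#' @slot bySymbol named list: uppercased name to character vector of
#'   entity ids realizing it (a symbol may live in several compartments).
#' @slot geneLikeIds entity ids whose class is GENE, PROTEIN or RNA.
#' @slot provenance list with the source path and md5 checksum of the map
#'   file, carried into the index header for staleness detection.
#'
#' @seealso [parseDiseaseMap()], [symbolsInMap()]
#' @export
setClass("EntityIndex",
  representation(
    entities = "DataFrame",
    bySymbol = "list",
    geneLikeIds = "character",
    provenance = "list"
  )
)

setValidity("EntityIndex", function(object) {
  ent <- object@entities
  need <- c("entity_id", "display_name", "entity_class", "compartment",
            "aliases")
  if (!all(need %in% colnames(ent)))
    return(paste("entities must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(ent$entity_id))
    return("entity_id must be unique within a map")
  if (any(is.na(ent$display_name)) || any(!nzchar(ent$display_name)))
    return("display_name must be non-empty")
  if (!all(ent$entity_class %in% c("GENE", "PROTEIN", "RNA", "OTHER")))
    return("entity_class must be GENE, PROTEIN, RNA or OTHER")
  known <- ent$entity_id
  idx <- unique(unlist(object@bySymbol, use.names = FALSE))
  if (length(idx) && !all(idx %in% known))
    return("bySymbol references unknown entity ids")
  if (length(object@geneLikeIds) && !all(object@geneLikeIds %in% known))
    return("geneLikeIds references unknown entity ids")
  TRUE
})

## ---- LinkIndex --------------------------------------------------------------

#' Paired forward/reverse compound-gene link index
#'
#' The materialized product of intersecting merged interaction records with
#' a disease map's symbol universe: \code{forward} maps each compound id to
#' its map-covered target symbols (compounds with none are omitted);
#' \code{reverse} has one key per map gene-like symbol, possibly with an
#' empty compound list. The two mappings are mutual transposes.
#'
#' @slot forward named list: compound id to sorted character vector of gene
#'   symbols present in the map.
#' @slot reverse named list: map gene symbol to sorted character vector of
#'   compound ids targeting it.
#' @slot header provenance list (map checksum, source table names, build
#'   timestamp, tool version).
#' @slot dropped number of interactions excluded because their gene symbol
#'   is absent from the map (NA when the index was read from disk).
#'
#' @seealso [buildIndex()], [writeIndex()], [readIndex()]
#' @export
setClass("LinkIndex",
  representation(
    forward = "list",
    reverse = "list",
    header = "list",
    dropped = "integer"
  )
)

.checkSortedLists <- function(lst, what) {
  for (k in names(lst)) {
    v <- lst[[k]]
    if (!is.character(v))
      return(sprintf("%s[%s] is not a character vector", what, k))
    if (anyDuplicated(v))
      return(sprintf("%s[%s] has duplicates", what, k))
    if (is.unsorted(v, strictly = TRUE) && length(v) > 1L)
      return(sprintf("%s[%s] is not sorted", what, k))
  }
  NULL
}

setValidity("LinkIndex", function(object) {
  fwd <- object@forward
  rev <- object@reverse
  if (length(fwd) && is.null(names(fwd))) return("forward must be named")
  if (length(rev) && is.null(names(rev))) return("reverse must be named")
  msg <- .checkSortedLists(fwd, "forward")
  if (!is.null(msg)) return(msg)
  msg <- .checkSortedLists(rev, "reverse")
  if (!is.null(msg)) return(msg)
  wit <- .transposeWitness(fwd, rev)
  if (!is.null(wit))
    return(sprintf("transpose inconsistency at (%s, %s)", wit[1L], wit[2L]))
  if (any(lengths(fwd) == 0L))
    return("forward must omit compounds with no map-covered targets")
  TRUE
})

# First (compound, gene) pair present in one mapping but not its transpose,
# or NULL when the two agree. Used by validity and by readIndex.
.transposeWitness <- function(fwd, rev) {
  fp <- if (length(fwd)) {
    data.frame(c = rep(names(fwd), lengths(fwd)),
               g = unlist(fwd, use.names = FALSE))
  } else data.frame(c = character(0), g = character(0))
  rp <- if (length(rev)) {
    data.frame(g = rep(names(rev), lengths(rev)),
               c = unlist(rev, use.names = FALSE))
  } else data.frame(g = character(0), c = character(0))
  fk <- paste(fp$c, fp$g, sep = "\r")
  rk <- paste(rp$c, rp$g, sep = "\r")
  onlyF <- setdiff(fk, rk)
  if (length(onlyF)) return(strsplit(onlyF[1L], "\r", fixed = TRUE)[[1L]])
  onlyR <- setdiff(rk, fk)
  if (length(onlyR)) return(strsplit(onlyR[1L], "\r", fixed = TRUE)[[1L]])
  NULL
}

## ---- TargetHighlightSet -----------------------------------------------------

#' Set of map entities answering a target query
#'
#' The result shape of the compound-side queries: the gene symbols involved
#' and every map entity realizing one of them (a symbol present in several
#' compartments fans out to all matching entities, so counts are
#' per-entity, not per-symbol).
#'
#' @slot queryDescription human-readable echo of the query.
#' @slot symbols sorted gene symbols.
#' @slot entityIds sorted map entity ids realizing those symbols.
#' @slot nTargets number of entity ids.
#' @export
setClass("TargetHighlightSet",
  representation(
    queryDescription = "character",
    symbols = "character",
    entityIds = "character",
    nTargets = "integer"
  )
)

setValidity("TargetHighlightSet", function(object) {
  if (object@nTargets != length(object@entityIds))
    return("nTargets must equal the number of entity ids")
  if (is.unsorted(object@symbols, strictly = TRUE) &&
      length(object@symbols) > 1L)
    return("symbols must be sorted")
  TRUE
})

## ---- CoverageReport ---------------------------------------------------------

#' Database-map coverage summary
#'
#' Counts and fraction of the map's gene-like symbol universe hit by at
#' least one compound, plus the highlight set of covered symbols.
#'
#' @slot nGeneEntities number of gene-like symbols in the map.
#' @slot nCovered symbols with at least one targeting compound.
#' @slot fraction \code{nCovered / nGeneEntities}.
#' @slot nCompoundsMapped compounds with at least one map target.
#' @slot highlight \code{TargetHighlightSet} of all covered symbols.
#' @export
setClass("CoverageReport",
  representation(
    nGeneEntities = "integer",
    nCovered = "integer",
    fraction = "numeric",
    nCompoundsMapped = "integer",
    highlight = "TargetHighlightSet"
  )
)

setValidity("CoverageReport", function(object) {
  if (object@fraction < 0 || object@fraction > 1)
    return("fraction must be in [0, 1]")
  if (object@nGeneEntities > 0L &&
      !isTRUE(all.equal(object@fraction,
                        object@nCovered / object@nGeneEntities)))
    return("fraction must equal nCovered / nGeneEntities")
  TRUE
})

## ---- FixtureSpec ------------------------------------------------------------

#' Specification of a synthetic pipeline fixture
#'
#' Parameters of the fixture generator: collection size, map gene count,
#' interaction density, the fraction of interactions pointing at genes
#' absent from the map, the fraction duplicated across both source
#' dialects, and the RNG seed. See [fixtureSpec()].
#'
#' @slot nCompounds number of compounds in the synthetic collection.
#' @slot nGenes number of gene (PROTEIN) species in the synthetic map.
#' @slot interactionDensity per-pair probability an interaction exists.
#' @slot offmapGeneFraction probability an interaction is redirected to a
#'   gene absent from the map.
#' @slot duplicateSourceFraction probability an interaction is emitted in
#'   both the CTD-style and the ChEMBL-style table.
#' @slot seed integer RNG seed; identical spec + seed reproduces
#'   byte-identical files.
#' @export
setClass("FixtureSpec",
  representation(
    nCompounds = "integer",
    nGenes = "integer",
    interactionDensity = "numeric",
    offmapGeneFraction = "numeric",
    duplicateSourceFraction = "numeric",
    seed = "integer"
  )
)

setValidity("FixtureSpec", function(object) {
  if (object@nCompounds < 1L || object@nGenes < 1L)
    return("nCompounds and nGenes must be >= 1")
  p <- c(object@interactionDensity, object@offmapGeneFraction,
         object@duplicateSourceFraction)
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    return("all probabilities must lie in [0, 1]")
  TRUE
})
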