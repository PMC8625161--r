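## query_engine module: coverage, compound target search with pairwise
## comparison, and reverse target search over a LinkIndex + EntityIndex.

# Fan a set of symbols out to the map entities realizing them. A symbol
# present in several compartments highlights all matching entities, so
# target counts are per-entity.
.fanOut <- function(symbols, index, geneLikeOnly = TRUE) {
  ids <- unlist(index@bySymbol[symbols], use.names = FALSE)
  ids <- ids[!is.na(ids)]
  if (geneLikeOnly) ids <- ids[ids %in% index@geneLikeIds]
  .sortAsc(ids)
}

.highlightSet <- function(description, symbols, index, geneLikeOnly = TRUE) {
  symbols <- .sortAsc(symbols)
  ids <- .fanOut(symbols, index, geneLikeOnly)
  new("TargetHighlightSet",
      queryDescription = description,
      symbols = symbols,
      entityIds = ids,
      nTargets = length(ids))
}

#' Targets of one compound, highlighted on the map
#'
#' Looks the compound up in the forward index and fans its target symbols
#' out to every map entity realizing them. An unknown compound yields an
#' empty set with a notice, mirroring a search UI returning nothing.
#'
#' @param compoundId compound id to query.
#' @param link a [LinkIndex-class].
#' @param index the [EntityIndex-class] of the same map.
#' @param geneLikeOnly restrict entity fan-out to gene-like entities.
#' @return a [TargetHighlightSet-class].
#' @export
targetsOf <- function(compoundId, link, index, geneLikeOnly = TRUE) {
  stopifnot(is(link, "LinkIndex"), is(index, "EntityIndex"))
  syms <- link@forward[[compoundId]]
  if (is.null(syms)) {
    message(sprintf("compound '%s' has no map-covered targets", compoundId))
    syms <- character(0)
  }
  .highlightSet(sprintf("targets of %s", compoundId), syms, index,
                geneLikeOnly)
}

#' Common targets of two compounds
#'
#' Symbol-level set intersection of the two compounds' map-covered target
#' sets, fanned out to entities as in [targetsOf()]. Symmetric in its
#' arguments; \code{commonTargets(c, c)} equals \code{targetsOf(c)}.
#' More than two compounds may be supplied via \code{...} and are folded
#' in by iterated intersection.
#'
#' @param compoundA,compoundB compound ids to compare.
#' @param link a [LinkIndex-class].
#' @param index the matching [EntityIndex-class].
#' @param ... further compound ids for an n-way comparison.
#' @param geneLikeOnly restrict entity fan-out to gene-like entities.
#' @return a [TargetHighlightSet-class].
#' @export
commonTargets <- function(compoundA, compoundB, link, index, ...,
                          geneLikeOnly = TRUE) {
  stopifnot(is(link, "LinkIndex"), is(index, "EntityIndex"))
  ids <- c(compoundA, compoundB, ...)
  sets <- lapply(ids, function(id) link@forward[[id]] %||% character(0))
  syms <- Reduce(intersect, sets)
  .highlightSet(sprintf("common targets of %s", paste(ids, collapse = " & ")),
                syms, index, geneLikeOnly)
}

#' Compounds interacting with a selected map entity
#'
#' The reverse target search: the selection may be a map entity id (as
#' picked on the map) or a gene symbol; an entity id is translated to its
#' display symbol. Returns the sorted compound ids of the reverse index
#' for that symbol. A selection resolving to nothing in the map is an
#' input error; a known entity with no interactions gives an empty list.
#' Whether non-gene-like entities are searchable follows the
#' \code{geneLikeOnly} flag the index was built with (their symbols are
#' simply absent from the reverse mapping).
#'
#' @param selection entity id or gene symbol.
#' @param link a [LinkIndex-class].
#' @param index the matching [EntityIndex-class].
#' @return sorted character vector of compound ids.
#' @export
compoundsFor <- function(selection, link, index) {
  stopifnot(is(link, "LinkIndex"), is(index, "EntityIndex"))
  sel <- trimws(selection)
  if (!nzchar(sel)) .inputError("empty selection")
  ent <- index@entities
  pos <- match(sel, ent$entity_id)
  if (!is.na(pos)) {
    symbol <- toupper(ent$display_name[pos])
  } else {
    symbol <- toupper(sel)
    if (!symbol %in% names(index@bySymbol))
      .inputError("unknown map entity or symbol: '%s'", selection)
  }
  hits <- link@reverse[[symbol]]
  if (is.null(hits)) {
    message(sprintf(
      "symbol '%s' is outside the reverse index (built gene-like only?)",
      symbol))
    return(character(0))
  }
  .sortAsc(hits)
}

#' Database-to-map coverage summary
#'
#' How much of the map's gene-like symbol universe is hit by at least one
#' compound of the collection, together with the full highlight set of
#' covered symbols for the show-all overlay.
#'
#' @param link a [LinkIndex-class].
#' @param index the matching [EntityIndex-class].
#' @param geneLikeOnly restrict entity fan-out to gene-like entities.
#' @return a [CoverageReport-class].
#' @export
mapCoverage <- function(link, index, geneLikeOnly = TRUE) {
  stopifnot(is(link, "LinkIndex"), is(index, "EntityIndex"))
  rev <- link@reverse
  nGenes <- length(rev)
  covered <- names(rev)[lengths(rev) > 0L]
  hl <- .highlightSet("all targets of all compounds", covered, index,
                      geneLikeOnly)
  new("CoverageReport",
      nGeneEntities = nGenes,
      nCovered = length(covered),
      fraction = if (nGenes > 0L) length(covered) / nGenes else 0,
      nCompoundsMapped = length(link@forward),
      highlight = hl)
}
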