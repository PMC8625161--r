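## Accessor generics and show methods for the core containers.

#' @describeIn CompoundCollection-class number of compound records
#' @param x,object a container object
#' @export
setGeneric("nCompounds", function(x) standardGeneric("nCompounds"))

#' @export
setMethod("nCompounds", "CompoundCollection",
          function(x) nrow(x@records))

#' @describeIn CompoundCollection-class all compound ids, ascending
#' @export
setGeneric("compoundIds", function(x) standardGeneric("compoundIds"))

#' @export
setMethod("compoundIds", "CompoundCollection",
          function(x) .sortAsc(x@records$compound_id))

#' @describeIn CompoundCollection-class the record table (`DataFrame`)
#' @export
setGeneric("compoundRecords", function(x) standardGeneric("compoundRecords"))

#' @export
setMethod("compoundRecords", "CompoundCollection", function(x) x@records)

#' @describeIn EntityIndex-class the entity table (`DataFrame`)
#' @export
setGeneric("mapEntities", function(x) standardGeneric("mapEntities"))

#' @export
setMethod("mapEntities", "EntityIndex", function(x) x@entities)

#' @describeIn EntityIndex-class entity ids with class GENE/PROTEIN/RNA
#' @export
setGeneric("geneLikeIds", function(x) standardGeneric("geneLikeIds"))

#' @export
setMethod("geneLikeIds", "EntityIndex", function(x) x@geneLikeIds)

#' @describeIn LinkIndex-class compound id to map-covered gene symbols
#' @export
setGeneric("forwardMap", function(x) standardGeneric("forwardMap"))

#' @export
setMethod("forwardMap", "LinkIndex", function(x) x@forward)

#' @describeIn LinkIndex-class map gene symbol to targeting compound ids
#' @export
setGeneric("reverseMap", function(x) standardGeneric("reverseMap"))

#' @export
setMethod("reverseMap", "LinkIndex", function(x) x@reverse)

#' @describeIn LinkIndex-class provenance header of the index
#' @export
setGeneric("indexHeader", function(x) standardGeneric("indexHeader"))

#' @export
setMethod("indexHeader", "LinkIndex", function(x) x@header)

#' @describeIn LinkIndex-class interactions dropped as off-map at build
#' @export
setGeneric("droppedInteractions",
           function(x) standardGeneric("droppedInteractions"))

#' @export
setMethod("droppedInteractions", "LinkIndex", function(x) x@dropped)

#' @describeIn TargetHighlightSet-class gene symbols of a highlight set
#' @export
setGeneric("highlightSymbols", function(x) standardGeneric("highlightSymbols"))

#' @export
setMethod("highlightSymbols", "TargetHighlightSet", function(x) x@symbols)

#' @describeIn TargetHighlightSet-class map entity ids of a highlight set
#' @export
setGeneric("highlightEntities",
           function(x) standardGeneric("highlightEntities"))

#' @export
setMethod("highlightEntities", "TargetHighlightSet", function(x) x@entityIds)

#' @describeIn TargetHighlightSet-class number of highlighted entities
#' @export
setGeneric("nTargets", function(x) standardGeneric("nTargets"))

#' @export
setMethod("nTargets", "TargetHighlightSet", function(x) x@nTargets)

#' @describeIn CoverageReport-class covered fraction of the gene universe
#' @export
setGeneric("coverageFraction",
           function(x) standardGeneric("coverageFraction"))

#' @export
setMethod("coverageFraction", "CoverageReport", function(x) x@fraction)

## ---- show methods -----------------------------------------------------------

#' @export
setMethod("show", "CompoundCollection", function(object) {
  cat(sprintf("CompoundCollection with %d records\n", nrow(object@records)))
  cat(sprintf("  synonym keys: %d | identifier keys: %d\n",
              length(object@synonymIndex), length(object@idIndex)))
  ids <- utils::head(object@records$compound_id, 5L)
  cat("  ids:", paste(ids, collapse = ", "),
      if (nrow(object@records) > 5L) "..." else "", "\n")
})

#' @export
setMethod("show", "EntityIndex", function(object) {
  cls <- table(object@entities$entity_class)
  cat(sprintf("EntityIndex with %d entities (%d gene-like)\n",
              nrow(object@entities), length(object@geneLikeIds)))
  cat("  classes:",
      paste(sprintf("%s=%d", names(cls), as.integer(cls)), collapse = " "),
      "\n")
})

#' @export
setMethod("show", "LinkIndex", function(object) {
  cat(sprintf(
    "LinkIndex: %d compounds -> %d map genes (%d covered), %s dropped\n",
    length(object@forward), length(object@reverse),
    sum(lengths(object@reverse) > 0L),
    ifelse(is.na(object@dropped), "?", as.character(object@dropped))))
  if (length(object@header))
    cat("  built:", object@header$timestamp %||% "?",
        "| tool:", object@header$tool_version %||% "?", "\n")
})

#' @export
setMethod("show", "TargetHighlightSet", function(object) {
  cat(sprintf("TargetHighlightSet: %s\n", object@queryDescription))
  cat(sprintf("  %d symbols, %d entities highlighted\n",
              length(object@symbols), object@nTargets))
})

#' @export
setMethod("show", "CoverageReport", function(object) {
  cat(sprintf(
    "CoverageReport: %d / %d gene entities covered (%.1f%%), %d compounds mapped\n",
    object@nCovered, object@nGeneEntities, 100 * object@fraction,
    object@nCompoundsMapped))
})

#' @export
setMethod("show", "FixtureSpec", function(object) {
  cat(sprintf(
    "FixtureSpec: %d compounds x %d genes, density %.2f, offmap %.2f, dup %.2f, seed %d\n",
    object@nCompounds, object@nGenes, object@interactionDensity,
    object@offmapGeneFraction, object@duplicateSourceFraction, object@seed))
})
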