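## disease_map module: extract named species from an SBML disease map and
## build a name-normalized entity index.

# CellDesigner species classes mapped into the coarse entity classes used
# for the gene-like universe; anything unlisted is OTHER.
.CD_CLASS_MAP <- c(
  PROTEIN = "PROTEIN", GENE = "GENE", RNA = "RNA", ANTISENSE_RNA = "RNA",
  RECEPTOR = "PROTEIN", ION_CHANNEL = "PROTEIN", TRUNCATED_PROTEIN = "PROTEIN"
)

#' Parse an SBML disease map into an entity index
#'
#' Reads one \code{MapEntity} per SBML species (levels 2-3). The entity
#' class is taken from a CellDesigner extension \code{class} annotation
#' when one is present, matched on local element names so that mixed
#' celldesigner namespace versions are tolerated; species without one are
#' \code{OTHER}. Complex species are kept as single OTHER entities. The
#' uppercased-name lookup covers the display name and every alias.
#'
#' @param path path to the SBML \code{.xml} file.
#' @return an [EntityIndex-class] object.
#' @examples
#' map <- system.file("extdata", "demo", "cftr_map.xml",
#'                    package = "cmaplink")
#' idx <- parseDiseaseMap(map)
#' symbolsInMap(idx)
#' @export
parseDiseaseMap <- function(path) {
  if (!file.exists(path))
    .inputError("disease map file not found: %s", path)
  doc <- tryCatch(
    xml2::read_xml(path),
    error = function(e) .formatError("cannot parse SBML %s: %s", path,
                                     conditionMessage(e)))

  # Only top-level model species; CellDesigner annotations nest their own
  # <celldesigner:species> under listOfIncludedSpecies, which must not be
  # double-counted.
  species <- xml2::xml_find_all(
    doc,
    "/*[local-name()='sbml']/*[local-name()='model']/*[local-name()='listOfSpecies']/*[local-name()='species']"
  )
  if (length(species) == 0L)
    .validationError("disease map %s contains no species", path)

  entity_id <- xml2::xml_attr(species, "id")
  rawName <- xml2::xml_attr(species, "name")
  compartment <- xml2::xml_attr(species, "compartment")
  display <- trimws(ifelse(is.na(rawName) | !nzchar(trimws(rawName)),
                           entity_id, rawName))

  cdClass <- vapply(species, function(sp) {
    node <- xml2::xml_find_first(sp, ".//*[local-name()='class']")
    if (inherits(node, "xml_missing")) NA_character_
    else toupper(trimws(xml2::xml_text(node)))
  }, character(1))
  entity_class <- unname(.CD_CLASS_MAP[cdClass])
  entity_class[is.na(entity_class)] <- "OTHER"

  ent <- DataFrame(
    entity_id = entity_id,
    display_name = display,
    entity_class = entity_class,
    compartment = ifelse(is.na(compartment), NA_character_, compartment),
    aliases = CharacterList(vector("list", length(entity_id)))
  )
  if (anyDuplicated(ent$entity_id))
    .validationError("duplicate species id in %s: %s", path,
                     ent$entity_id[duplicated(ent$entity_id)][1L])

  nameTbl <- data.frame(
    sym = toupper(c(display, unlist(ent$aliases, use.names = FALSE))),
    id = c(entity_id, rep(entity_id, lengths(ent$aliases))),
    stringsAsFactors = FALSE
  )
  bySymbol <- split(nameTbl$id, nameTbl$sym)
  bySymbol <- lapply(bySymbol, function(v) .sortAsc(v))

  idx <- new("EntityIndex",
    entities = ent,
    bySymbol = bySymbol,
    geneLikeIds = entity_id[entity_class %in% c("GENE", "PROTEIN", "RNA")],
    provenance = list(path = path,
                      md5 = unname(tools::md5sum(path)))
  )
  validObject(idx)
  idx
}

#' Symbol universe of a disease map
#'
#' The deduplicated, sorted, uppercased names (display names and aliases)
#' of the map's entities, optionally restricted to gene-like entities
#' (class GENE, PROTEIN or RNA) -- the universe against which interactions
#' are filtered.
#'
#' @param index an [EntityIndex-class].
#' @param geneLikeOnly restrict to gene-like entities (default) or return
#'   every named species, metabolites included.
#' @return sorted character vector of uppercase symbols.
#' @export
symbolsInMap <- function(index, geneLikeOnly = TRUE) {
  stopifnot(is(index, "EntityIndex"))
  if (!geneLikeOnly)
    return(.sortAsc(names(index@bySymbol)))
  keep <- vapply(index@bySymbol,
                 function(ids) any(ids %in% index@geneLikeIds),
                 logical(1))
  .sortAsc(names(index@bySymbol)[keep])
}
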