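## index_builder module: intersect interactions with the map universe and
## materialize / reload the paired JSON index files.

#' Build the bidirectional link index
#'
#' Intersects merged interaction records with the map's symbol universe.
#' The forward mapping keeps only compounds with at least one map-covered
#' target; interactions whose gene symbol is absent from the map are
#' excluded and counted in the dropped-interactions statistic. The reverse
#' mapping has one key per map gene-like symbol, with an empty list when no
#' compound targets it. The result is invariant under permutation of the
#' input interaction list.
#'
#' @param interactions merged interaction data.frame (see
#'   [mergeInteractions()]).
#' @param index an [EntityIndex-class] for the disease map.
#' @param geneLikeOnly restrict the symbol universe to gene-like entities
#'   (default), matching the reverse-search scope of the built index.
#' @param sources character vector naming the source tables, recorded in
#'   the header.
#' @param timestamp build timestamp recorded in the header; pin it to get
#'   byte-identical [writeIndex()] output across runs.
#' @return a [LinkIndex-class] object.
#' @export
buildIndex <- function(interactions, index, geneLikeOnly = TRUE,
                       sources = character(0),
                       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ",
                                          tz = "UTC")) {
  stopifnot(is(index, "EntityIndex"))
  universe <- symbolsInMap(index, geneLikeOnly = geneLikeOnly)
  if (length(universe) == 0L)
    .validationError("disease map has an empty symbol universe")

  ia <- unique(interactions[, c("compound_id", "gene_symbol")])
  onMap <- ia$gene_symbol %in% universe
  dropped <- sum(!onMap)
  kept <- ia[onMap, , drop = FALSE]

  forward <- lapply(split(kept$gene_symbol, kept$compound_id), .sortAsc)
  forward <- forward[.sortAsc(names(forward))]
  if (!length(forward)) forward <- setNames(list(), character(0))

  reverse <- setNames(rep(list(character(0)), length(universe)), universe)
  if (nrow(kept)) {
    byGene <- lapply(split(kept$compound_id, kept$gene_symbol), .sortAsc)
    reverse[names(byGene)] <- byGene
  }

  link <- new("LinkIndex",
    forward = forward,
    reverse = reverse,
    header = list(
      map_checksum = index@provenance$md5 %||% NA_character_,
      map_path = basename(index@provenance$path %||% NA_character_),
      sources = as.character(sources),
      gene_like_only = geneLikeOnly,
      timestamp = timestamp,
      tool_version = .toolVersion()
    ),
    dropped = as.integer(dropped)
  )
  validObject(link)
  link
}

.headerJSON <- function(header) {
  h <- header
  scal <- function(x) if (length(x) == 1L) jsonlite::unbox(x) else x
  lapply(h, scal)
}

.writeIndexFile <- function(payload, path) {
  txt <- jsonlite::toJSON(payload, pretty = 2, auto_unbox = FALSE,
                          digits = NA, null = "null", na = "null")
  con <- tryCatch(file(path, open = "wb"),
                  error = function(e) .ioError("cannot write %s: %s", path,
                                               conditionMessage(e)))
  on.exit(close(con))
  writeLines(txt, con, useBytes = TRUE)
  path
}

#' Write the two JSON index files
#'
#' Materializes \code{compound2genes.json} (\code{header} + a
#' \code{compounds} object mapping compound id to target symbols) and
#' \code{gene2compounds.json} (\code{header} + a \code{genes} object
#' mapping each map gene symbol to its targeting compound ids). Output is
#' UTF-8, keys sorted, 2-space indent; identical index content with a
#' pinned header timestamp serializes byte-identically. JSON Schemas for
#' both files ship under \code{inst/schemas/}.
#'
#' @param link a [LinkIndex-class].
#' @param outDir output directory (created if missing).
#' @return named character vector with the two file paths.
#' @export
writeIndex <- function(link, outDir) {
  stopifnot(is(link, "LinkIndex"))
  if (!dir.exists(outDir) &&
      !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
    .ioError("cannot create output directory %s", outDir)

  fwd <- link@forward[.sortAsc(names(link@forward))]
  if (!length(fwd)) fwd <- setNames(list(), character(0))
  rev <- link@reverse[.sortAsc(names(link@reverse))]
  if (!length(rev)) rev <- setNames(list(), character(0))

  c2g <- file.path(outDir, "compound2genes.json")
  g2c <- file.path(outDir, "gene2compounds.json")
  .writeIndexFile(list(header = .headerJSON(link@header), compounds = fwd),
                  c2g)
  .writeIndexFile(list(header = .headerJSON(link@header), genes = rev), g2c)
  c(compound2genes = c2g, gene2compounds = g2c)
}

.readIndexFile <- function(path, key) {
  if (!file.exists(path))
    .inputError("index file not found: %s", path)
  obj <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) .formatError("cannot parse %s: %s", path,
                                     conditionMessage(e)))
  if (!is.list(obj) || is.null(obj[[key]]))
    .formatError("index file %s lacks required key '%s'", path, key)
  m <- obj[[key]]
  if (length(m) && is.null(names(m)))
    .formatError("'%s' in %s must be a JSON object", key, path)
  norm <- vector("list", length(m))
  names(norm) <- names(m)
  normalized <- FALSE
  for (k in names(m)) {
    v <- m[[k]]
    if (!all(vapply(v, is.character, logical(1))) && length(v))
      .formatError("'%s' entry '%s' in %s is not an array of strings",
                   key, k, path)
    v <- as.character(unlist(v, use.names = FALSE))
    s <- .sortAsc(v)
    if (!identical(s, v)) normalized <- TRUE
    norm[[k]] <- s
  }
  if (normalized)
    warning(sprintf("unsorted or duplicated list(s) in %s normalized on read",
                    path), call. = FALSE)
  list(map = norm, header = obj$header)
}

#' Read a link index back from its JSON files
#'
#' Loads and schema-checks the two files written by [writeIndex()],
#' normalizing unsorted lists with a warning. Transpose consistency between
#' forward and reverse is re-verified on load; a violation is an integrity
#' error naming one witness (compound, gene) pair.
#'
#' @param dir directory containing \code{compound2genes.json} and
#'   \code{gene2compounds.json}, or the path of the forward file when
#'   \code{reversePath} is given.
#' @param reversePath optional explicit path of the reverse file.
#' @return a [LinkIndex-class]; its \code{dropped} statistic is \code{NA}
#'   (not stored in the files).
#' @export
readIndex <- function(dir, reversePath = NULL) {
  if (is.null(reversePath)) {
    fwdPath <- file.path(dir, "compound2genes.json")
    revPath <- file.path(dir, "gene2compounds.json")
  } else {
    fwdPath <- dir
    revPath <- reversePath
  }
  f <- .readIndexFile(fwdPath, "compounds")
  r <- .readIndexFile(revPath, "genes")

  # drop compounds that lost all targets (e.g. hand-edited files) so the
  # no-empty-forward invariant holds; the transpose check still sees them
  # through the reverse side if the edit was inconsistent.
  fwd <- f$map[lengths(f$map) > 0L]
  if (!length(fwd)) fwd <- setNames(list(), character(0))

  wit <- .transposeWitness(fwd, r$map)
  if (!is.null(wit))
    .integrityError(
      "forward/reverse files disagree: pair (%s, %s) present on one side only",
      wit[1L], wit[2L])

  header <- lapply(f$header %||% list(), function(x)
    if (is.list(x)) as.character(unlist(x)) else x)
  new("LinkIndex", forward = fwd, reverse = r$map, header = header,
      dropped = NA_integer_)
}
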