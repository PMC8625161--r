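## compound_db module: read, validate and search the compound collection.

# Build synonym and identifier indices for a validated record table.
.buildCollection <- function(rec) {
  ids <- rec$compound_id

  nm <- rec$names
  syn <- data.frame(
    key = .normName(unlist(nm, use.names = FALSE)),
    id = rep(ids, lengths(nm)),
    stringsAsFactors = FALSE
  )
  syn <- unique(syn)
  synonymIndex <- split(syn$id, syn$key)

  idKey <- character(0)
  idVal <- character(0)
  addKeys <- function(kind, values) {
    keep <- which(!is.na(values) & nzchar(values))
    if (!length(keep)) return(invisible())
    idKey <<- c(idKey, paste0(kind, ":", values[keep]))
    idVal <<- c(idVal, ids[keep])
  }
  addKeys("compound_id", ids)
  addKeys("inchikey", rec$inchikey)
  addKeys("cas", rec$cas_number)
  addKeys("cid", ifelse(is.na(rec$pubchem_cid), NA_character_,
                        as.character(rec$pubchem_cid)))
  addKeys("smiles", rec$smiles)
  if (anyDuplicated(idKey)) {
    dups <- unique(idKey[duplicated(idKey)])
    warning(sprintf(
      "identifier value(s) shared by several compounds, first wins: %s",
      paste(utils::head(dups, 3L), collapse = ", ")), call. = FALSE)
    keep <- !duplicated(idKey)
    idKey <- idKey[keep]
    idVal <- idVal[keep]
  }
  idIndex <- stats::setNames(idVal, idKey)

  new("CompoundCollection", records = rec, synonymIndex = synonymIndex,
      idIndex = idIndex)
}

# Drop malformed optional identifiers (keep the record), warning per field.
.sanitizeIdentifiers <- function(rec) {
  dropField <- function(col, ok, label) {
    v <- rec[[col]]
    bad <- !is.na(v) & !ok(v)
    if (any(bad)) {
      warning(sprintf(
        "%d record(s) with malformed %s; field dropped (e.g. %s = \"%s\")",
        sum(bad), label, rec$compound_id[bad][1L], v[bad][1L]),
        call. = FALSE)
      v[bad] <- NA
    }
    rec[[col]] <<- v
  }
  dropField("inchikey", .isInChIKey, "InChIKey")
  dropField("cas_number", .isCAS, "CAS number")
  cid <- rec$pubchem_cid
  bad <- !is.na(cid) & !(.isCID(as.character(cid)))
  if (any(bad)) {
    warning(sprintf("%d record(s) with malformed PubChem CID; field dropped",
                    sum(bad)), call. = FALSE)
    cid[bad] <- NA
  }
  rec$pubchem_cid <- suppressWarnings(as.integer(cid))
  rec
}

#' Load a compound collection from CSV or JSON
#'
#' Reads the compound-database file, validates identifiers and builds both
#' lookup indices. Records with malformed optional identifiers (InChIKey,
#' CAS number, PubChem CID) are kept with the offending field dropped and a
#' warning; a missing, duplicated or absent \code{compound_id} is an error.
#'
#' The CSV dialect is UTF-8 with a header row and columns
#' \code{compound_id,inchikey,smiles,cas_number,pubchem_cid,names}; the
#' \code{names} cell is a pipe-separated synonym list whose first entry is
#' the preferred display name. The JSON dialect is an array of objects with
#' the same keys and \code{names} as an array.
#'
#' @param path path to the collection file.
#' @param format \code{"csv"} or \code{"json"}.
#' @return a [CompoundCollection-class] object.
#' @examples
#' demo <- system.file("extdata", "demo", "compounds.csv",
#'                     package = "cmaplink")
#' db <- loadCompoundDb(demo, "csv")
#' nCompounds(db)
#' @export
loadCompoundDb <- function(path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (!file.exists(path))
    .inputError("compound database file not found: %s", path)

  if (format == "csv") {
    df <- tryCatch(
      utils::read.csv(path, colClasses = "character",
                      stringsAsFactors = FALSE, encoding = "UTF-8"),
      error = function(e) .formatError("cannot parse CSV %s: %s", path,
                                       conditionMessage(e)))
    if (!"compound_id" %in% colnames(df))
      .formatError("required column 'compound_id' missing in %s", path)
    for (col in c("inchikey", "smiles", "cas_number", "pubchem_cid", "names"))
      if (!col %in% colnames(df)) df[[col]] <- rep(NA_character_, nrow(df))
    nameList <- lapply(df$names, function(x) {
      if (is.na(x) || !nzchar(trimws(x))) character(0)
      else trimws(strsplit(x, "|", fixed = TRUE)[[1L]])
    })
  } else {
    objs <- tryCatch(
      jsonlite::fromJSON(path, simplifyVector = FALSE),
      error = function(e) .formatError("cannot parse JSON %s: %s", path,
                                       conditionMessage(e)))
    if (!is.list(objs))
      .formatError("JSON compound db must be an array of objects: %s", path)
    pick <- function(o, k) {
      v <- o[[k]]
      if (is.null(v) || !length(v)) NA_character_ else as.character(v[[1L]])
    }
    df <- data.frame(
      compound_id = vapply(objs, pick, character(1), "compound_id"),
      inchikey = vapply(objs, pick, character(1), "inchikey"),
      smiles = vapply(objs, pick, character(1), "smiles"),
      cas_number = vapply(objs, pick, character(1), "cas_number"),
      pubchem_cid = vapply(objs, pick, character(1), "pubchem_cid"),
      stringsAsFactors = FALSE
    )
    if (any(is.na(df$compound_id)))
      .formatError("required field 'compound_id' missing in %s", path)
    nameList <- lapply(objs, function(o)
      trimws(as.character(unlist(o$names, use.names = FALSE))))
  }

  if (nrow(df) == 0L)
    .validationError("empty compound collection: %s", path)
  df$compound_id <- trimws(df$compound_id)
  if (any(!nzchar(df$compound_id)))
    .validationError("empty compound_id in row %d",
                     which(!nzchar(df$compound_id))[1L])
  if (anyDuplicated(df$compound_id))
    .validationError("duplicate compound_id: %s",
                     df$compound_id[duplicated(df$compound_id)][1L])

  blank2na <- function(x) {
    x <- trimws(x)
    x[!nzchar(x)] <- NA
    x
  }
  rec <- DataFrame(
    compound_id = df$compound_id,
    inchikey = blank2na(df$inchikey),
    smiles = blank2na(df$smiles),
    cas_number = blank2na(df$cas_number),
    pubchem_cid = blank2na(df$pubchem_cid),
    names = CharacterList(nameList)
  )
  rec <- .sanitizeIdentifiers(rec)

  # Tolerate rows without names: fall back to the id as display name so
  # partial records survive (synthesized compounds often lack synonyms).
  empty <- lengths(rec$names) == 0L
  if (any(empty)) {
    warning(sprintf("%d record(s) without names; using compound_id",
                    sum(empty)), call. = FALSE)
    rec$names[empty] <- as.list(rec$compound_id[empty])
  }

  coll <- .buildCollection(rec)
  validObject(coll)
  coll
}

#' Serialize a compound collection to JSON
#'
#' Inverse of \code{loadCompoundDb(..., format = "json")}: writing and
#' re-loading yields a collection with an identical record set.
#'
#' @param collection a [CompoundCollection-class].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeCompoundDb <- function(collection, path) {
  stopifnot(is(collection, "CompoundCollection"))
  rec <- collection@records
  objs <- lapply(seq_len(nrow(rec)), function(i) {
    o <- list(compound_id = jsonlite::unbox(rec$compound_id[i]))
    addOpt <- function(k, v) {
      if (!is.na(v)) o[[k]] <<- jsonlite::unbox(v)
    }
    addOpt("inchikey", rec$inchikey[i])
    addOpt("smiles", rec$smiles[i])
    addOpt("cas_number", rec$cas_number[i])
    addOpt("pubchem_cid", rec$pubchem_cid[i])
    o$names <- as.character(rec$names[[i]])
    o
  })
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(jsonlite::toJSON(objs, pretty = 2, auto_unbox = FALSE,
                              digits = NA),
             con, useBytes = TRUE)
  invisible(path)
}

#' Search the compound collection
#'
#' Synonym mode matches the case-folded, trimmed query against every name
#' of every record (exact token match by default; \code{contains = TRUE}
#' switches to substring search). Identifier mode matches the query
#' verbatim against compound id, InChIKey, CAS number, SMILES, and the
#' PubChem CID compared as a string. No match is an empty result, not an
#' error.
#'
#' @param query search string, non-empty after trimming.
#' @param collection a [CompoundCollection-class].
#' @param mode \code{"synonym"} or \code{"exact_id"}.
#' @param contains in synonym mode, match as substring instead of whole
#'   name.
#' @return a \code{DataFrame} of matching records, ascending
#'   \code{compound_id}.
#' @examples
#' db <- loadCompoundDb(system.file("extdata", "demo", "compounds.csv",
#'                                  package = "cmaplink"), "csv")
#' findCompounds("curcumin", db)
#' @export
findCompounds <- function(query, collection,
                          mode = c("synonym", "exact_id"),
                          contains = FALSE) {
  stopifnot(is(collection, "CompoundCollection"))
  mode <- match.arg(mode)
  q <- trimws(query)
  if (!nzchar(q)) .inputError("empty search query")

  if (mode == "synonym") {
    qn <- .normName(q)
    if (contains) {
      keys <- names(collection@synonymIndex)
      hit <- keys[grepl(qn, keys, fixed = TRUE)]
      ids <- unique(unlist(collection@synonymIndex[hit], use.names = FALSE))
    } else {
      ids <- unique(collection@synonymIndex[[qn]])
    }
  } else {
    kinds <- c("compound_id", "inchikey", "cas", "smiles")
    keys <- paste0(kinds, ":", q)
    if (grepl("^[0-9]+$", q)) keys <- c(keys, paste0("cid:", q))
    ids <- unique(unname(collection@idIndex[keys]))
    ids <- ids[!is.na(ids)]
  }
  if (is.null(ids) || !length(ids))
    return(collection@records[0L, ])
  rec <- collection@records
  rec[rec$compound_id %in% ids, ][order(rec$compound_id[rec$compound_id %in% ids]), ]
}
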