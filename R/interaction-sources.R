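## interaction_sources module: parse CTD-style and ChEMBL-style exports,
## resolve their compound keys against the collection, and merge.

#' @importFrom stats setNames
NULL

.readTsv <- function(path, required, label) {
  if (!file.exists(path))
    .inputError("%s table not found: %s", label, path)
  df <- tryCatch(
    utils::read.delim(path, colClasses = "character", comment.char = "#",
                      stringsAsFactors = FALSE, encoding = "UTF-8",
                      check.names = FALSE),
    error = function(e) .formatError("cannot parse %s table %s: %s", label,
                                     path, conditionMessage(e)))
  missing <- setdiff(required, colnames(df))
  if (length(missing))
    .formatError("%s table %s lacks required column(s): %s", label, path,
                 paste(missing, collapse = ", "))
  df
}

.rawRows <- function(df, keep, key, keyType, gene, evidence, nInput) {
  out <- data.frame(
    key = key[keep],
    key_type = keyType[keep],
    gene_symbol = gene[keep],
    evidence = evidence[keep],
    stringsAsFactors = FALSE
  )
  attr(out, "nInput") <- nInput
  attr(out, "nSkipped") <- nInput - nrow(out)
  out
}

#' Parse a CTD-style chemical-gene interaction table
#'
#' Tab-separated export keyed by CAS registry number, with columns
#' \code{CasRN} and \code{GeneSymbol} (required), \code{ChemicalName} and
#' \code{InteractionActions} (optional); lines starting with \code{#} are
#' ignored. Rows with an empty CAS or gene symbol are counted and logged,
#' not returned. Values are preserved verbatim; case normalization of gene
#' symbols is deferred to [resolveInteractions()].
#'
#' @param path path to the TSV file.
#' @return a data.frame of raw rows with columns \code{key} (CAS),
#'   \code{key_type} (\code{"cas"}), \code{gene_symbol}, \code{evidence},
#'   plus attributes \code{nInput} and \code{nSkipped}.
#' @export
parseCtdTable <- function(path) {
  df <- .readTsv(path, c("CasRN", "GeneSymbol"), "CTD-style")
  n <- nrow(df)
  cas <- trimws(df$CasRN)
  gene <- df$GeneSymbol
  keep <- nzchar(cas) & nzchar(trimws(gene))
  if (any(!keep))
    message(sprintf("parseCtdTable: skipped %d row(s) with empty CasRN/GeneSymbol",
                    sum(!keep)))
  ev <- if ("InteractionActions" %in% colnames(df))
    df$InteractionActions else rep(NA_character_, n)
  .rawRows(df, keep, cas, rep("cas", n), gene, ev, n)
}

#' Parse a ChEMBL-style compound-target table
#'
#' Tab-separated export with columns \code{compound_key} and
#' \code{gene_symbol} (required) and \code{target_name} (optional). The
#' compound key is classified by shape: all digits is a PubChem CID, the
#' 14-10-1 uppercase pattern is an InChIKey; anything else is skipped and
#' logged. The \code{gene_symbol} column carries the end product of the
#' target-name-to-gene lookup already performed by the exporter.
#'
#' @param path path to the TSV file.
#' @return a data.frame of raw rows (columns as in [parseCtdTable()], with
#'   \code{key_type} \code{"cid"} or \code{"inchikey"}).
#' @export
parseChemblTable <- function(path) {
  df <- .readTsv(path, c("compound_key", "gene_symbol"), "ChEMBL-style")
  n <- nrow(df)
  key <- trimws(df$compound_key)
  gene <- df$gene_symbol
  keyType <- rep(NA_character_, n)
  keyType[grepl("^[0-9]+$", key)] <- "cid"
  keyType[.isInChIKey(key)] <- "inchikey"
  keep <- !is.na(keyType) & nzchar(key) & nzchar(trimws(gene))
  if (any(!keep))
    message(sprintf(
      "parseChemblTable: skipped %d row(s) (unclassifiable key or empty field)",
      sum(!keep)))
  ev <- if ("target_name" %in% colnames(df))
    df$target_name else rep(NA_character_, n)
  .rawRows(df, keep, key, keyType, gene, ev, n)
}

#' Resolve raw interaction rows against a compound collection
#'
#' Looks each row's compound key (CAS for CTD rows, InChIKey or CID for
#' ChEMBL rows) up in the collection's identifier index. Resolved rows
#' become normalized interaction records with the gene symbol trimmed and
#' uppercased; unresolved rows are returned in a report and never silently
#' dropped.
#'
#' @param rows raw rows from [parseCtdTable()] or [parseChemblTable()].
#' @param collection a [CompoundCollection-class].
#' @param source source tag: \code{"CTD"}, \code{"CHEMBL"} or
#'   \code{"CUSTOM"}.
#' @return list with \code{interactions} (data.frame \code{compound_id},
#'   \code{gene_symbol}, \code{source}, \code{evidence}) and
#'   \code{unresolved} (data.frame \code{key}, \code{reason}).
#' @export
resolveInteractions <- function(rows, collection,
                                source = c("CTD", "CHEMBL", "CUSTOM")) {
  stopifnot(is(collection, "CompoundCollection"))
  source <- match.arg(source)
  n <- nrow(rows)
  if (n == 0L) {
    return(list(
      interactions = data.frame(compound_id = character(0),
                                gene_symbol = character(0),
                                source = character(0),
                                evidence = character(0),
                                stringsAsFactors = FALSE),
      unresolved = data.frame(key = character(0), reason = character(0),
                              stringsAsFactors = FALSE)))
  }
  lookup <- unname(collection@idIndex[paste0(rows$key_type, ":", rows$key)])
  hit <- !is.na(lookup)
  interactions <- data.frame(
    compound_id = lookup[hit],
    gene_symbol = .normSymbol(rows$gene_symbol[hit]),
    source = rep(source, sum(hit)),
    evidence = rows$evidence[hit],
    stringsAsFactors = FALSE
  )
  unresolved <- data.frame(
    key = rows$key[!hit],
    reason = sprintf("no compound with %s '%s' in collection",
                     rows$key_type[!hit], rows$key[!hit]),
    stringsAsFactors = FALSE
  )
  list(interactions = interactions, unresolved = unresolved)
}

#' Merge interaction record lists across sources
#'
#' Concatenates any number of interaction record data.frames and
#' deduplicates on the (compound id, gene symbol) pair. When duplicates
#' span sources, the source tag of the first occurrence wins and all
#' contributing source names are concatenated into the evidence field.
#' Output is sorted by (compound id, gene symbol); merging a list with
#' itself is a no-op.
#'
#' @param ... interaction data.frames (or a single list of them).
#' @return one deduplicated, sorted interaction data.frame.
#' @export
mergeInteractions <- function(...) {
  lists <- list(...)
  if (length(lists) == 1L && is.list(lists[[1L]]) &&
      !is.data.frame(lists[[1L]]))
    lists <- lists[[1L]]
  all <- do.call(rbind, lists)
  if (is.null(all) || nrow(all) == 0L) {
    return(data.frame(compound_id = character(0), gene_symbol = character(0),
                      source = character(0), evidence = character(0),
                      stringsAsFactors = FALSE))
  }
  pair <- paste(all$compound_id, all$gene_symbol, sep = "\r")
  groups <- split(seq_len(nrow(all)), pair)
  rows <- lapply(groups, function(ix) {
    srcs <- unique(all$source[ix])
    ev <- unique(all$evidence[ix])
    ev <- ev[!is.na(ev) & nzchar(ev)]
    if (length(srcs) > 1L)
      ev <- c(ev, paste0("sources:", paste(srcs, collapse = "+")))
    data.frame(
      compound_id = all$compound_id[ix[1L]],
      gene_symbol = all$gene_symbol[ix[1L]],
      source = all$source[ix[1L]],
      evidence = if (length(ev)) paste(ev, collapse = "; ")
                 else NA_character_,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$compound_id, out$gene_symbol, method = "radix"), ]
  rownames(out) <- NULL
  out
}
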