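## Internal helpers: typed conditions, identifier validation, normalization.

#' @importFrom methods new validObject is slot
#' @importFrom utils read.csv read.delim head
NULL

# Typed abort so callers (and the CLI exit-code mapping) can distinguish
# user/input problems from data-format, validation, I/O and integrity faults.
.cmapStop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "cmap_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

.inputError      <- function(msg, ...) .cmapStop("cmap_input_error", msg, ...)
.formatError     <- function(msg, ...) .cmapStop("cmap_format_error", msg, ...)
.validationError <- function(msg, ...) .cmapStop("cmap_validation_error", msg, ...)
.ioError         <- function(msg, ...) .cmapStop("cmap_io_error", msg, ...)
.integrityError  <- function(msg, ...) .cmapStop("cmap_integrity_error", msg, ...)

# Standard InChIKey shape: 14 uppercase letters, hyphen, 10, hyphen, 1.
.INCHIKEY_RE <- "^[A-Z]{14}-[A-Z]{10}-[A-Z]$"
# CAS registry number: 2-7 digits, hyphen, 2 digits, hyphen, 1 check digit.
.CAS_RE <- "^[0-9]{2,7}-[0-9]{2}-[0-9]$"

.isInChIKey <- function(x) !is.na(x) & grepl(.INCHIKEY_RE, x)
.isCAS      <- function(x) !is.na(x) & grepl(.CAS_RE, x)
.isCID      <- function(x) !is.na(x) & grepl("^[0-9]+$", x) & x != "0"

# Case-folded, whitespace-trimmed form used for all synonym keys.
.normName <- function(x) tolower(trimws(x))

# Official-gene-symbol normalization: trim then uppercase.
.normSymbol <- function(x) toupper(trimws(x))

.sortAsc <- function(x) sort(unique(as.character(x)), method = "radix")

# Run expr with a locally seeded RNG, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.toolVersion <- function() {
  as.character(utils::packageVersion("cmaplink"))
}
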