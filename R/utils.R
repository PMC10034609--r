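#' @keywords internal
"_PACKAGE"

#' @importFrom stats aggregate ave rpois runif setNames
#' @importFrom utils read.csv head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

nz_string <- function(x) is_string(x) && nzchar(x)

abort2 <- function(msg, class) {
  stop(structure(class = c(class, "ehr2omop_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' Path to a packaged fixture file
#'
#' Convenience wrapper around [system.file()] for the data shipped with the
#' package (archetype definitions, toy terminology, mapping configurations).
#'
#' @param ... path components below `inst/extdata`.
#' @return Absolute path to the file (empty string if it does not exist).
#' @export
ehr2omop_extdata <- function(...) {
  system.file("extdata", ..., package = "ehr2omop")
}

## Timestamps in source systems are local wall-clock; everything emitted by
## the package is ISO-8601 with an explicit UTC offset (Europe/Madrid by
## default, matching the synthetic source fixtures).
iso_datetime <- function(x, tz = "Europe/Madrid") {
  t <- tryCatch({
    if (inherits(x, "POSIXt")) as.POSIXct(x, tz = tz)
    else as.POSIXct(x, tz = tz,
                    tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                                   "%Y-%m-%d %H:%M", "%Y-%m-%d"))
  }, error = function(e) NA)
  if (any(is.na(t))) abort2("unparseable datetime value", "ehr2omop_parse_error")
  off <- format(t, "%z")
  paste0(format(t, "%Y-%m-%dT%H:%M:%S"),
         substr(off, 1, 3), ":", substr(off, 4, 5))
}

iso_date <- function(iso_dt) substr(iso_dt, 1, 10)

## Keyed 48-bit hash used for pseudonyms and deterministic instance IRIs:
## SHA-256 HMAC truncated to 12 hex digits, returned as an exact integer
## (< 2^48 so it is representable without loss in a double).
keyed_hash48 <- function(x, key) {
  hx <- vapply(x, function(v)
    digest::hmac(key = key, object = v, algo = "sha256"), character(1),
    USE.NAMES = FALSE)
  strtoi_hex48(substr(hx, 1, 12))
}

strtoi_hex48 <- function(h) {
  hi <- strtoi(substr(h, 1, 6), base = 16L)
  lo <- strtoi(substr(h, 7, 12), base = 16L)
  hi * 16777216 + lo
}

read_csv_chr <- function(path) {
  read.csv(path, colClasses = "character", check.names = FALSE,
           na.strings = character(0))
}

write_csv_rfc <- function(df, path) {
  ## RFC 4180: CRLF line endings, header row, quote only where needed.
  con <- file(path, open = "wb")
  on.exit(close(con))
  esc <- function(v) {
    v[is.na(v)] <- ""
    need <- grepl('[",\r\n]', v)
    v[need] <- paste0('"', gsub('"', '""', v[need]), '"')
    v
  }
  lines <- paste(esc(names(df)), collapse = ",")
  if (nrow(df)) {
    cells <- vapply(df, function(col) esc(as.character(col)), character(nrow(df)))
    if (nrow(df) == 1L) cells <- matrix(cells, nrow = 1L)
    lines <- c(lines, apply(cells, 1L, paste, collapse = ","))
  }
  writeLines(lines, con, sep = "\r\n")
  invisible(path)
}
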