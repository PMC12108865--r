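# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Normalize gene symbols
#'
#' Trims surrounding whitespace and (by default) upper-cases symbols so
#' that human-style (TP63) and mouse-style (Tp63) spellings collapse to a
#' single key. No alias or orthology expansion is attempted.
#'
#' @param x character vector of gene symbols.
#' @param case_fold upper-case the symbols? Default `TRUE`.
#' @return normalized character vector.
#' @export
normalize_symbols <- function(x, case_fold = TRUE) {
  x <- trimws(as.character(x))
  if (isTRUE(case_fold)) x <- toupper(x)
  x
}

gcd2 <- function(a, b) {
  while (b != 0) {
    t <- b
    b <- a %% b
    a <- t
  }
  a
}

# votes/total as a reduced fraction string ("4/21", "1/7"); keeps the
# dictionary file reproduction bit-exact where the counts are integers.
format_fraction <- function(num, den) {
  stopifnot(length(num) == length(den))
  if (length(num) == 0) return(character(0))
  mapply(function(n, d) {
    if (is.na(n) || is.na(d) || d <= 0) return(NA_character_)
    if (n == 0) return("0")
    g <- gcd2(n, d)
    n <- n %/% g
    d <- d %/% g
    if (d == 1) as.character(n) else paste0(n, "/", d)
  }, num, den, USE.NAMES = FALSE)
}

# accepts "4/21" fraction strings or plain decimals
parse_percent <- function(x) {
  x <- trimws(as.character(x))
  vapply(x, function(s) {
    if (is.na(s) || !nzchar(s)) return(NA_real_)
    if (grepl("/", s, fixed = TRUE)) {
      parts <- strsplit(s, "/", fixed = TRUE)[[1]]
      as.numeric(parts[1]) / as.numeric(parts[2])
    } else {
      as.numeric(s)
    }
  }, numeric(1), USE.NAMES = FALSE)
}

canon_name <- function(x) gsub("[^a-z0-9]+", "", tolower(x))

# Map logical column names onto a header via case/punctuation-insensitive
# aliases. Returns a named integer vector of column indices (NA when an
# optional column is absent).
match_header <- function(header, aliases, required = names(aliases),
                         context = "input") {
  hc <- canon_name(header)
  idx <- vapply(names(aliases), function(nm) {
    hit <- which(hc %in% canon_name(aliases[[nm]]))
    if (length(hit)) hit[1] else NA_integer_
  }, integer(1))
  missing <- names(idx)[is.na(idx) & names(idx) %in% required]
  if (length(missing)) {
    stop(sprintf(
      "%s: missing required column '%s' (accepted names: %s)",
      context, missing[1],
      paste(aliases[[missing[1]]], collapse = ", ")
    ), call. = FALSE)
  }
  idx
}

# Delimiter from extension unless given: .csv -> comma, otherwise tab.
read_table_auto <- function(path, delim = NULL) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  if (is.null(delim)) {
    delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  utils::read.table(path,
    header = TRUE, sep = delim, quote = "\"",
    check.names = FALSE, stringsAsFactors = FALSE,
    comment.char = "", colClasses = "character"
  )
}

write_tsv_plain <- function(df, path) {
  utils::write.table(df, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = TRUE, na = ""
  )
}
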