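#' Marker-gene voting dictionary
#'
#' A marker dictionary records, for each cell type, which marker genes the
#' curated literature sources voted for and how often. Each record carries
#' a vote count; the per-type weight of a gene is its votes divided by the
#' total votes received by all retained genes of that type, so the weights
#' of every cell type sum to one. Genes with more votes therefore
#' contribute more to the similarity score of their cell type.
#'
#' @param records a data.frame with columns `cell_type`, `gene`, `votes`
#'   and optionally `total_votes` and `percent`. Duplicate
#'   (cell_type, gene) pairs (e.g. created by case-folding) have their
#'   votes summed, with a warning.
#' @param case_fold upper-case gene symbols? Default `TRUE`.
#' @return an object of class `marker_dictionary`: a list with elements
#'   `records` (validated data.frame with recomputed `total_votes` and
#'   `percent`), `cell_types`, `genes` (ordered unique, first appearance)
#'   and `weights` (gene x cell-type matrix; per-type columns sum to 1).
#' @examples
#' d <- marker_dictionary(data.frame(
#'   cell_type = "T cell", gene = c("CD3D", "CD3E"), votes = c(3, 1)
#' ))
#' d$weights
#' @export
marker_dictionary <- function(records, case_fold = TRUE) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  needed <- c("cell_type", "gene", "votes")
  if (!all(needed %in% names(records))) {
    stop("records must have columns cell_type, gene, votes", call. = FALSE)
  }
  records$cell_type <- trimws(as.character(records$cell_type))
  records$gene <- normalize_symbols(records$gene, case_fold = case_fold)
  records$votes <- as.numeric(records$votes)
  if (nrow(records) > 0 && any(records$votes < 0 | records$votes != round(records$votes))) {
    bad <- which(records$votes < 0 | records$votes != round(records$votes))[1]
    stop(sprintf("votes must be nonnegative integers (row %d)", bad),
      call. = FALSE
    )
  }
  records$votes <- as.integer(round(records$votes))

  if (nrow(records) > 0) {
    key <- paste(records$cell_type, records$gene, sep = "\r")
    if (anyDuplicated(key)) {
      warning(sprintf(
        "%d duplicate (cell_type, gene) pairs merged by summing votes",
        sum(duplicated(key))
      ), call. = FALSE)
      votes <- tapply(records$votes, key, sum)
      first <- !duplicated(key)
      records <- records[first, c("cell_type", "gene"), drop = FALSE]
      records$votes <- as.integer(votes[paste(records$cell_type,
        records$gene,
        sep = "\r"
      )])
    } else {
      records <- records[, c("cell_type", "gene", "votes")]
    }
  } else {
    records <- data.frame(
      cell_type = character(), gene = character(),
      votes = integer(), stringsAsFactors = FALSE
    )
  }
  rownames(records) <- NULL

  out <- structure(
    list(
      records = records,
      cell_types = unique(records$cell_type),
      genes = unique(records$gene),
      weights = NULL,
      case_fold = isTRUE(case_fold)
    ),
    class = "marker_dictionary"
  )
  compute_weights(out)
}

#' Recompute per-type marker weights
#'
#' The weight of gene g for cell type m is votes(m, g) divided by the sum
#' of votes over all genes retained for m; weights of each type sum to 1.
#' `total_votes` and `percent` in the records are reconciled with the
#' recomputed per-type totals.
#'
#' @param dictionary a `marker_dictionary`.
#' @return the dictionary with `records$total_votes`, `records$percent`
#'   and the `weights` matrix populated.
#' @export
compute_weights <- function(dictionary) {
  stopifnot(inherits(dictionary, "marker_dictionary"))
  rec <- dictionary$records
  if (nrow(rec) == 0) {
    dictionary$records <- data.frame(
      cell_type = character(), gene = character(), votes = integer(),
      total_votes = integer(), percent = numeric(),
      stringsAsFactors = FALSE
    )
    dictionary$weights <- matrix(numeric(0),
      nrow = 0, ncol = 0,
      dimnames = list(character(), character())
    )
    return(dictionary)
  }
  totals <- tapply(rec$votes, rec$cell_type, sum)
  if (any(totals == 0)) {
    stop(sprintf(
      "cell type with zero total votes: %s",
      paste(names(totals)[totals == 0], collapse = ", ")
    ), call. = FALSE)
  }
  rec$total_votes <- as.integer(totals[rec$cell_type])
  rec$percent <- rec$votes / rec$total_votes
  dictionary$records <- rec

  genes <- unique(rec$gene)
  types <- unique(rec$cell_type)
  w <- matrix(0,
    nrow = length(genes), ncol = length(types),
    dimnames = list(genes, types)
  )
  w[cbind(match(rec$gene, genes), match(rec$cell_type, types))] <- rec$percent
  dictionary$genes <- genes
  dictionary$cell_types <- types
  dictionary$weights <- w
  dictionary
}

# column aliases for the five-column dictionary schema
.dict_aliases <- list(
  cell_type = c("cell_cluster", "Cell Cluster", "cell_type", "cell type"),
  gene = c("marker_gene", "Marker Gene", "gene"),
  votes = c("n_votes", "Number of Votes Received", "votes_received"),
  total_votes = c("votes_total", "Votes", "total_votes"),
  percent = c("percent", "Percent")
)

#' Read a marker dictionary from a five-column TSV
#'
#' The expected schema has columns `cell_cluster`, `marker_gene`,
#' `n_votes`, `votes_total` and `percent` (header matching is
#' case/punctuation-insensitive and order-insensitive; the human-readable
#' spellings "Cell Cluster", "Marker Gene", "Number of Votes Received",
#' "Votes", "Percent" are accepted as aliases). The percent column may
#' hold fraction strings ("4/21") or decimals and is re-derived from the
#' vote counts after loading.
#'
#' @param path path to a tab-delimited dictionary file.
#' @param case_fold upper-case gene symbols? Default `TRUE`.
#' @param delim field delimiter; default tab.
#' @return a [marker_dictionary()].
#' @export
read_dictionary <- function(path, case_fold = TRUE, delim = "\t") {
  df <- read_table_auto(path, delim = delim)
  idx <- match_header(names(df), .dict_aliases,
    required = c("cell_type", "gene", "votes", "total_votes", "percent"),
    context = basename(path)
  )
  votes_raw <- suppressWarnings(as.numeric(df[[idx["votes"]]]))
  totals_raw <- suppressWarnings(as.numeric(df[[idx["total_votes"]]]))
  if (nrow(df) > 0) {
    bad <- which(is.na(votes_raw) | votes_raw != round(votes_raw))
    if (length(bad)) {
      stop(sprintf(
        "%s: non-integer vote count '%s' at data row %d",
        basename(path), df[[idx["votes"]]][bad[1]], bad[1]
      ), call. = FALSE)
    }
    over <- which(!is.na(totals_raw) & votes_raw > totals_raw)
    if (length(over)) {
      stop(sprintf(
        "%s: votes (%s) exceed total votes (%s) at data row %d",
        basename(path), votes_raw[over[1]], totals_raw[over[1]], over[1]
      ), call. = FALSE)
    }
  }
  marker_dictionary(
    data.frame(
      cell_type = df[[idx["cell_type"]]],
      gene = df[[idx["gene"]]],
      votes = votes_raw,
      stringsAsFactors = FALSE
    ),
    case_fold = case_fold
  )
}

#' Write a marker dictionary to the five-column TSV schema
#'
#' Percent is written as a reduced fraction string (e.g. "1/7") with a
#' `percent_decimal` convenience column appended; re-reading the file with
#' [read_dictionary()] reproduces the dictionary exactly.
#'
#' @param dictionary a `marker_dictionary`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dictionary <- function(dictionary, path) {
  stopifnot(inherits(dictionary, "marker_dictionary"))
  rec <- dictionary$records
  out <- data.frame(
    cell_cluster = rec$cell_type,
    marker_gene = rec$gene,
    n_votes = rec$votes,
    votes_total = rec$total_votes,
    percent = format_fraction(rec$votes, rec$total_votes),
    percent_decimal = rec$percent,
    stringsAsFactors = FALSE
  )
  write_tsv_plain(out, path)
  invisible(path)
}

#' Build a voting dictionary from per-study marker tables
#'
#' Each source study contributes one vote per (cell type, gene) pair it
#' lists. Per cell type, the ten most-voted genes are retained (ties
#' broken by the best rank the gene attained in any source, then by gene
#' symbol); the type's total votes are the sum over retained genes and
#' weights are recomputed.
#'
#' @param sources either a single long-format data.frame with columns
#'   `source_id`, `cell_type`, `gene` and optionally `rank`, or a list of
#'   per-study data.frames (columns `cell_type`, `gene`, optional `rank`)
#'   whose names are used as source ids.
#' @param top_n number of genes retained per cell type (default 10).
#' @param case_fold upper-case gene symbols? Default `TRUE`.
#' @return a [marker_dictionary()].
#' @export
build_votes_from_sources <- function(sources, top_n = 10, case_fold = TRUE) {
  if (is.data.frame(sources)) {
    long <- sources
    if (!"source_id" %in% names(long)) {
      stop("long-format sources need a source_id column", call. = FALSE)
    }
  } else {
    if (!is.list(sources) || length(sources) == 0) {
      stop("sources must be a non-empty list of tables or a long data.frame",
        call. = FALSE
      )
    }
    ids <- names(sources) %||% as.character(seq_along(sources))
    if (is.null(names(sources))) names(sources) <- ids
    long <- do.call(rbind, lapply(names(sources), function(id) {
      s <- as.data.frame(sources[[id]], stringsAsFactors = FALSE)
      s$source_id <- id
      s
    }))
  }
  if (nrow(long) == 0) stop("sources contain no marker rows", call. = FALSE)
  if (!"cell_type" %in% names(long)) {
    stop("sources: no recognizable cell_type column", call. = FALSE)
  }
  if (!"gene" %in% names(long)) {
    stop("sources: no recognizable gene column", call. = FALSE)
  }
  if (!"rank" %in% names(long)) {
    # per-source listing order stands in for an explicit rank
    long$rank <- stats::ave(seq_len(nrow(long)),
      paste(long$source_id, long$cell_type, sep = "\r"),
      FUN = seq_along
    )
  }
  long$gene <- normalize_symbols(long$gene, case_fold = case_fold)
  long$cell_type <- trimws(as.character(long$cell_type))
  long$rank <- as.numeric(long$rank)

  # one vote per source per (type, gene); keep each source's best rank
  skey <- paste(long$source_id, long$cell_type, long$gene, sep = "\r")
  long <- long[order(skey, long$rank), ]
  long <- long[!duplicated(paste(long$source_id, long$cell_type, long$gene,
    sep = "\r"
  )), ]

  key <- paste(long$cell_type, long$gene, sep = "\r")
  votes <- tapply(rep(1L, nrow(long)), key, sum)
  best_rank <- tapply(long$rank, key, min)
  first <- !duplicated(key)
  tally <- data.frame(
    cell_type = long$cell_type[first],
    gene = long$gene[first],
    stringsAsFactors = FALSE
  )
  k <- paste(tally$cell_type, tally$gene, sep = "\r")
  tally$votes <- as.integer(votes[k])
  tally$best_rank <- as.numeric(best_rank[k])

  kept <- do.call(rbind, lapply(split(tally, tally$cell_type), function(d) {
    d <- d[order(-d$votes, d$best_rank, d$gene), ]
    utils::head(d, top_n)
  }))
  rownames(kept) <- NULL
  marker_dictionary(kept[, c("cell_type", "gene", "votes")],
    case_fold = case_fold
  )
}

#' Summarize a marker dictionary
#'
#' @param dictionary a `marker_dictionary`.
#' @return a list with `n_genes` (unique genes across all types),
#'   `n_cell_types`, `n_records` and `genes_per_type` (named integer
#'   vector).
#' @export
dictionary_stats <- function(dictionary) {
  stopifnot(inherits(dictionary, "marker_dictionary"))
  rec <- dictionary$records
  gpt <- if (nrow(rec)) {
    tbl <- table(rec$cell_type)
    stats::setNames(as.integer(tbl), names(tbl))
  } else {
    stats::setNames(integer(0), character(0))
  }
  list(
    n_genes = length(dictionary$genes),
    n_cell_types = length(dictionary$cell_types),
    n_records = nrow(rec),
    genes_per_type = gpt
  )
}

#' @export
print.marker_dictionary <- function(x, ...) {
  s <- dictionary_stats(x)
  cat(sprintf(
    "marker_dictionary: %d cell types, %d unique genes, %d records\n",
    s$n_cell_types, s$n_genes, s$n_records
  ))
  invisible(x)
}
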