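#' Read one annotator's per-cluster label table
#'
#' TSV with columns `cluster`, `label` and optionally `label2` (a
#' secondary label). The annotator name defaults to the file name.
#'
#' @param path path to the TSV.
#' @param name annotator name; default the file's base name without
#'   extension.
#' @return a data.frame of class `label_table` with columns `cluster`,
#'   `label`, `label2` and an `annotator` attribute.
#' @export
read_label_table <- function(path, name = NULL) {
  df <- read_table_auto(path, delim = "\t")
  idx <- match_header(names(df),
    list(cluster = "cluster", label = "label", label2 = "label2"),
    required = c("cluster", "label"), context = basename(path)
  )
  label_table(
    cluster = df[[idx["cluster"]]],
    label = df[[idx["label"]]],
    label2 = if (!is.na(idx["label2"])) df[[idx["label2"]]] else NA_character_,
    name = name %||% tools::file_path_sans_ext(basename(path))
  )
}

#' Construct a label table in memory
#'
#' @param cluster cluster labels.
#' @param label primary cell-type labels.
#' @param label2 optional secondary labels (`NA` when absent).
#' @param name annotator name.
#' @return a `label_table` data.frame.
#' @export
label_table <- function(cluster, label, label2 = NA_character_, name = "annotator") {
  cluster <- trimws(as.character(cluster))
  if (anyDuplicated(cluster)) {
    stop(sprintf(
      "annotator '%s': duplicated cluster '%s'",
      name, cluster[duplicated(cluster)][1]
    ), call. = FALSE)
  }
  label2 <- as.character(label2)
  label2[!is.na(label2) & !nzchar(trimws(label2))] <- NA_character_
  structure(
    data.frame(
      cluster = cluster,
      label = as.character(label),
      label2 = rep_len(label2, length(cluster)),
      stringsAsFactors = FALSE
    ),
    class = c("label_table", "data.frame"),
    annotator = name
  )
}

#' Write a label table as TSV
#'
#' @param table a `label_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_label_table <- function(table, path) {
  write_tsv_plain(as.data.frame(table)[, c("cluster", "label", "label2")], path)
  invisible(path)
}

norm_label <- function(x) toupper(trimws(as.character(x)))

# Boyer-Moore majority vote: single candidate/counter pass. Returns the
# surviving candidate, which is the majority element IF one exists; the
# caller must verify with a count.
boyer_moore_candidate <- function(votes) {
  candidate <- NULL
  count <- 0L
  for (v in votes) {
    if (count == 0L) {
      candidate <- v
      count <- 1L
    } else if (identical(v, candidate)) {
      count <- count + 1L
    } else {
      count <- count - 1L
    }
  }
  candidate
}

#' Majority-vote pseudo-reference over several annotators
#'
#' For every cluster appearing in any table, the annotators' primary
#' labels (taken in the order the tables are supplied; annotators missing
#' the cluster abstain) are combined with the Boyer-Moore majority-vote
#' algorithm followed by a verification count. If the surviving candidate
#' holds a strict majority it becomes the reference label; otherwise the
#' plurality label wins, with lexicographic tie-breaking (such clusters
#' are recorded in the `no_strict_majority` attribute and reported via a
#' message).
#'
#' @param tables list of `label_table`s (one per annotator).
#' @return named character vector mapping cluster to reference label,
#'   with attribute `no_strict_majority` listing fallback clusters.
#' @export
majority_reference <- function(tables) {
  if (!is.list(tables) || length(tables) == 0) {
    stop("need at least one label table", call. = FALSE)
  }
  clusters <- unique(unlist(lapply(tables, function(t) t$cluster)))
  fallback <- character(0)
  ref <- vapply(clusters, function(cl) {
    votes <- unlist(lapply(tables, function(t) {
      i <- match(cl, t$cluster)
      if (is.na(i)) NULL else t$label[i]
    }))
    cand <- boyer_moore_candidate(votes)
    n_cand <- sum(votes == cand)
    if (n_cand > length(votes) / 2) {
      cand
    } else {
      counts <- table(votes)
      top <- names(counts)[counts == max(counts)]
      fallback <<- c(fallback, cl)
      sort(top)[1]
    }
  }, character(1))
  names(ref) <- clusters
  if (length(fallback)) {
    message(sprintf(
      "NO_STRICT_MAJORITY: plurality fallback used for %d cluster(s): %s",
      length(fallback), paste(fallback, collapse = ", ")
    ))
  }
  structure(ref, no_strict_majority = fallback)
}

#' Score one annotator against a reference labelling
#'
#' A cluster scores one point when the annotator's label matches the
#' reference label (string equality after trimming and case-folding).
#' With `match_mode = "either"` the secondary label may also claim the
#' point; `"primary"` scores the primary label only. The denominator is
#' the number of reference clusters, so reference clusters the annotator
#' did not label (and clusters left "Unannotated") count as misses.
#'
#' @param predicted a `label_table`.
#' @param reference named character vector (cluster -> label), e.g. from
#'   [majority_reference()].
#' @param match_mode `"either"` (default) or `"primary"`.
#' @return list with `matches`, `total` and `accuracy` = matches/total.
#' @export
accuracy <- function(predicted, reference, match_mode = c("either", "primary")) {
  match_mode <- match.arg(match_mode)
  if (length(reference) == 0) stop("reference is empty", call. = FALSE)
  ref_lab <- norm_label(reference)
  cl <- names(reference)
  i <- match(cl, predicted$cluster)
  hit <- !is.na(i) & norm_label(predicted$label[i]) == ref_lab
  if (match_mode == "either") {
    hit2 <- !is.na(i) & !is.na(predicted$label2[i]) &
      norm_label(predicted$label2[i]) == ref_lab
    hit <- hit | hit2
  }
  matches <- sum(hit)
  list(
    matches = matches, total = length(reference),
    accuracy = matches / length(reference)
  )
}

#' Range of a model's accuracy across two reference files
#'
#' The absolute difference between the accuracies a model attains under
#' two different reference annotation files; a small range indicates the
#' model is stable with respect to the choice of reference.
#'
#' @param acc1,acc2 accuracies in \[0, 1\].
#' @return `|acc1 - acc2|`.
#' @export
range_stat <- function(acc1, acc2) {
  stopifnot(
    is.numeric(acc1), is.numeric(acc2),
    acc1 >= 0, acc1 <= 1, acc2 >= 0, acc2 <= 1
  )
  abs(acc1 - acc2)
}

#' Evaluate annotators against a majority-vote pseudo-reference
#'
#' Builds the pseudo-reference from the supplied tables (unless an
#' explicit `reference` is given), scores every annotator, and computes
#' the range statistic for each declared model-family pair.
#'
#' @param tables list of `label_table`s.
#' @param pairing optional named list mapping a model family to a
#'   character pair of annotator names whose accuracies define its range.
#' @param match_mode passed to [accuracy()].
#' @param reference optional explicit reference labelling (named
#'   character vector); default: majority vote over `tables`.
#' @return list of class `evaluation_report` with `reference`,
#'   `per_annotator` (data.frame: annotator, matches, total, accuracy,
#'   unannotated, subtype) and `ranges` (named numeric vector).
#' @export
evaluate_models <- function(tables, pairing = NULL,
                            match_mode = c("either", "primary"),
                            reference = NULL) {
  match_mode <- match.arg(match_mode)
  if (!is.list(tables) || length(tables) == 0) {
    stop("need at least one label table", call. = FALSE)
  }
  nm <- vapply(
    tables,
    function(t) attr(t, "annotator") %||% "annotator", character(1)
  )
  if (anyDuplicated(nm)) {
    stop(sprintf(
      "annotator name collision: %s", nm[duplicated(nm)][1]
    ), call. = FALSE)
  }
  names(tables) <- nm
  if (is.null(reference)) reference <- majority_reference(tables)

  per <- do.call(rbind, lapply(nm, function(a) {
    t <- tables[[a]]
    acc <- accuracy(t, reference, match_mode)
    data.frame(
      annotator = a,
      matches = acc$matches,
      total = acc$total,
      accuracy = acc$accuracy,
      unannotated = any(norm_label(t$label) == "UNANNOTATED"),
      subtype = any(!is.na(t$label2)),
      stringsAsFactors = FALSE
    )
  }))

  ranges <- numeric(0)
  if (!is.null(pairing)) {
    for (fam in names(pairing)) {
      pair <- pairing[[fam]]
      if (length(pair) != 2 || !all(pair %in% nm)) {
        stop(sprintf(
          "pairing '%s' must name two known annotators (have: %s)",
          fam, paste(nm, collapse = ", ")
        ), call. = FALSE)
      }
      a1 <- per$accuracy[per$annotator == pair[1]]
      a2 <- per$accuracy[per$annotator == pair[2]]
      ranges[fam] <- range_stat(a1, a2)
    }
  }
  structure(
    list(reference = reference, per_annotator = per, ranges = ranges),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(
    "evaluation_report: %d annotators over %d clusters\n",
    nrow(x$per_annotator), length(x$reference)
  ))
  print(x$per_annotator, row.names = FALSE)
  if (length(x$ranges)) {
    cat("ranges:\n")
    for (f in names(x$ranges)) cat(sprintf("  %s: %.3f\n", f, x$ranges[f]))
  }
  invisible(x)
}

#' Write an evaluation report (TSV table + range footnotes)
#'
#' @param report an `evaluation_report`.
#' @param path output path for the per-annotator TSV; a `.ranges.tsv`
#'   sibling file is written when ranges are present.
#' @return `path`, invisibly.
#' @export
write_evaluation_report <- function(report, path) {
  write_tsv_plain(report$per_annotator, path)
  if (length(report$ranges)) {
    write_tsv_plain(
      data.frame(
        family = names(report$ranges), range = unname(report$ranges),
        stringsAsFactors = FALSE
      ),
      sub("(\\.[^.]*)?$", ".ranges.tsv", path)
    )
  }
  invisible(path)
}
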