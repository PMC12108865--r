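make_em <- function(values) {
  # values: named list gene -> named cluster vector
  tab <- do.call(rbind, lapply(names(values), function(g) {
    data.frame(
      gene = g, cluster = names(values[[g]]),
      value = unname(values[[g]]), stringsAsFactors = FALSE
    )
  }))
  normalize_expression(build_expression_matrix(tab))
}

test_that("similarity is the weighted sum over shared genes", {
  # single shared gene: E = 0.5, weight = 0.2 -> score 0.1
  em <- make_em(list(GA = c(c1 = 1, c2 = 1), GB = c(c1 = 2)))
  dict <- marker_dictionary(data.frame(
    cell_type = "T", gene = c("GA", "GX", "GY", "GZ", "GW"),
    votes = c(1L, 1L, 1L, 1L, 1L)
  ))
  s <- compute_similarity(em, dict)
  expect_equal(s["c1", "T"], 0.5 * 0.2)
  expect_equal(s["c2", "T"], 0.5 * 0.2)
})

test_that("disjoint gene sets give zero scores with a warning", {
  em <- make_em(list(GA = c(c1 = 1)))
  dict <- marker_dictionary(data.frame(
    cell_type = "T", gene = "OTHER", votes = 1L
  ))
  expect_warning(s <- compute_similarity(em, dict), "no gene symbols shared")
  expect_true(all(s == 0))
  expect_equal(dim(s), c(1, 1))
})

test_that("similarity agrees with the exhaustive double-loop oracle", {
  set.seed(11)
  for (i in 1:20) {
    fx <- random_fixture(
      n_genes = sample(5:30, 1),
      n_clusters = sample(2:6, 1),
      n_types = sample(2:6, 1)
    )
    s <- compute_similarity(fx$em, fx$dict)
    expect_equal(s, brute_similarity(fx$em, fx$dict), tolerance = 1e-12)
  }
})

test_that("scaling one type's weights scales only its similarity column", {
  set.seed(12)
  fx <- random_fixture(20, 4, 3)
  s <- compute_similarity(fx$em, fx$dict)
  d2 <- fx$dict
  d2$weights[, "T2"] <- d2$weights[, "T2"] * 3
  s2 <- compute_similarity(fx$em, d2)
  expect_equal(s2[, "T2"], s[, "T2"] * 3)
  expect_equal(s2[, c("T1", "T3")], s[, c("T1", "T3")])
})

test_that("threshold statistics follow the max/second-max/median rule", {
  th <- derive_thresholds(c(0.5, 0.4, 0.2, 0.1))
  expect_equal(th$s_median, 0.3)
  expect_equal(th$lambda1, 0.2)
  expect_true(th$has_lambda2) # gap 0.1 > 1e-5
  expect_equal(th$lambda2, 0.1)

  # all-equal row: max equals median
  th2 <- derive_thresholds(c(0.3, 0.3, 0.3))
  expect_equal(th2$lambda1, 0)
  expect_false(th2$has_lambda2) # tied max, gap 0

  # tied maximum: multiset second max equals the max, no trigger; in a
  # 3-entry row the tied max is also the median, so lambda1 collapses to 0
  th3 <- derive_thresholds(c(0.5, 0.5, 0.1))
  expect_equal(th3$lambda1, 0)
  expect_equal(th3$s_secmax, 0.5)
  expect_false(th3$has_lambda2)

  # single-entry row: median is the value itself
  th4 <- derive_thresholds(0.7)
  expect_equal(th4$lambda1, 0)
  expect_false(th4$has_lambda2)

  expect_error(derive_thresholds(numeric(0)), "empty")
  expect_error(derive_thresholds(c(1, 2), epsilon = 0))
})

test_that("median-variant trigger fires on the max-median gap", {
  # gap to secmax is tiny but gap to median is large
  row <- c(0.5, 0.5 - 1e-7, 0.1, 0.05)
  expect_false(derive_thresholds(row)$has_lambda2)
  expect_true(derive_thresholds(row, lambda2_trigger = "median")$has_lambda2)
})

test_that("labels follow the argmax with the lambda1 > 0 gate", {
  s <- rbind(
    c0 = c(t1 = 0, t2 = 0, t3 = 0, t4 = 0),
    c1 = c(0.5, 0.4, 0.2, 0.1),
    c2 = c(0.3, 0.3, 0.3, 0.3)
  )
  ann <- assign_labels(s)
  expect_equal(ann$primary_type, c("Unannotated", "t1", "Unannotated"))
  expect_equal(ann$secondary_type, c(NA, "t2", NA))
  expect_equal(ann$lambda1[2], 0.5 - 0.3)
  # unannotated exactly when max equals median
  expect_equal(
    ann$primary_type == "Unannotated",
    ann$s_max == ann$s_median
  )
})

test_that("tied maxima break lexicographically and suppress the secondary", {
  s <- rbind(c1 = c(tb = 0.5, ta = 0.5, tc = 0.1, td = 0.05))
  ann <- assign_labels(s)
  expect_equal(ann$primary_type, "ta")
  expect_true(is.na(ann$secondary_type))
  expect_equal(attr(ann, "n_ties"), 1L)
  expect_error(assign_labels(matrix(numeric(0), 0, 0)), "empty")
})

test_that("secondary label requires a positive lambda2", {
  # secmax equals the median -> lambda2 = 0 -> no secondary
  s <- rbind(c1 = c(ta = 0.6, tb = 0.2, tc = 0.2))
  ann <- assign_labels(s)
  expect_equal(ann$primary_type, "ta")
  expect_true(is.na(ann$secondary_type))
  # secmax above the median -> secondary attaches
  s2 <- rbind(c1 = c(ta = 0.6, tb = 0.4, tc = 0.1, td = 0.05))
  ann2 <- assign_labels(s2)
  expect_equal(ann2$secondary_type, "tb")
})

test_that("pipeline recovers planted labels and is order-invariant", {
  spec <- synthetic_spec(
    n_cell_types = 5, n_clusters = 7, marker_overlap = 0,
    noise_sd = 0, dropout = 0, seed = 31
  )
  out <- tempfile()
  res <- simulate_benchmark(spec, out)
  ann <- annotate(res$markers, res$dictionary)
  expect_equal(
    ann$annotation$primary_type,
    unname(res$assignment[ann$annotation$cluster])
  )
  # permuting dictionary rows leaves the output unchanged
  d <- read.delim(res$dictionary, check.names = FALSE)
  set.seed(1)
  perm_path <- tempfile(fileext = ".tsv")
  write.table(d[sample(nrow(d)), ], perm_path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  ann2 <- annotate(res$markers, perm_path)
  expect_equal(
    ann2$annotation[order(ann2$annotation$cluster), c("cluster", "primary_type")],
    ann$annotation[order(ann$annotation$cluster), c("cluster", "primary_type")],
    ignore_attr = TRUE
  )
})

test_that("zero dictionary overlap leaves every cluster unannotated", {
  spec <- synthetic_spec(
    n_cell_types = 4, n_clusters = 4, noise_sd = 0, dropout = 0, seed = 5
  )
  out <- tempfile()
  res <- simulate_benchmark(spec, out)
  other <- marker_dictionary(data.frame(
    cell_type = "X", gene = c("FOO1", "FOO2"), votes = c(1L, 1L)
  ))
  alt <- tempfile(fileext = ".tsv")
  write_dictionary(other, alt)
  expect_warning(ann <- annotate(res$markers, alt), "shared")
  expect_true(all(ann$annotation$primary_type == "Unannotated"))
})

test_that("epsilon influences only secondary labels", {
  set.seed(21)
  for (i in 1:10) {
    fx <- random_fixture(25, 5, 6)
    s <- compute_similarity(fx$em, fx$dict)
    a1 <- assign_labels(s, epsilon = 1e-5)
    a2 <- assign_labels(s, epsilon = 0.01)
    expect_equal(a1$primary_type, a2$primary_type)
    expect_equal(a1$lambda1, a2$lambda1)
  }
})

test_that("stage failures name the failing stage", {
  expect_error(
    annotate(tempfile(), basal_resting_path()),
    "\\[marker_table\\]"
  )
  p <- write_tmp(c("p_val,avg_log2FC,cluster,gene", "1e-5,1,0,CD3D"),
    ext = ".csv"
  )
  expect_error(annotate(p, tempfile()), "\\[dictionary\\]")
  expect_error(
    annotate(p, basal_resting_path(), config = list(bogus = 1)),
    "unknown config keys"
  )
})

test_that("annotation and similarity tables export in the documented layout", {
  s <- rbind(c1 = c(ta = 0.6, tb = 0.4, tc = 0.1))
  ann <- assign_labels(s)
  p1 <- tempfile(fileext = ".tsv")
  write_annotation(ann, p1)
  df <- read.delim(p1, check.names = FALSE)
  expect_equal(
    names(df),
    c(
      "cluster", "primary_type", "secondary_type", "lambda1", "lambda2",
      "s_max", "s_secmax", "s_median"
    )
  )
  p2 <- tempfile(fileext = ".tsv")
  write_similarity(s, p2)
  sim <- read.delim(p2, check.names = FALSE)
  expect_equal(sim$cell_type, c("ta", "tb", "tc")) # types as rows
  expect_equal(sim$c1, c(0.6, 0.4, 0.1))
})
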