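# Small helper: matrix + annotations for a 2-group design.
toy_matrix <- function(values, n_treated = 3, n_untreated = 3,
                       proteins = NULL) {
  m <- matrix(values, ncol = n_treated + n_untreated, byrow = TRUE)
  rownames(m) <- proteins %||% sprintf("P%02d", seq_len(nrow(m)))
  colnames(m) <- c(sprintf("t%d", seq_len(n_treated)),
                   sprintf("u%d", seq_len(n_untreated)))
  ann <- data.frame(
    run_id = colnames(m),
    group = rep(c("treated", "untreated"), c(n_treated, n_untreated)),
    bio_rep = c(seq_len(n_treated), seq_len(n_untreated)),
    tech_rep = 1L
  )
  list(m = m, ann = ann)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("preprocessing is pure log2 when normalization and imputation are off", {
  tm <- toy_matrix(c(4, 4, 4, 8, 8, 8,
                     2, 2, 2, 2, 2, 2))
  cfg <- de_config(normalization = "none", imputation = "none")
  x <- preprocess_intensities(tm$m, tm$ann, cfg)
  expect_equal(as.vector(x), as.vector(log2(tm$m)))
  expect_equal(dim(x), dim(tm$m))
  expect_equal(attr(x, "scale"), "log2")
})

test_that("non-positive intensities are rejected naming the cell", {
  tm <- toy_matrix(rep(1, 12))
  tm$m["P02", "u1"] <- 0
  expect_error(preprocess_intensities(tm$m, tm$ann),
               "protein 'P02', run 'u1'")
})

test_that("a protein observed at a constant level imputes to that level", {
  tm <- toy_matrix(c(4, 4, NA, 4, 4, 4))
  cfg <- de_config(normalization = "none")
  x <- preprocess_intensities(tm$m, tm$ann, cfg)
  expect_equal(unname(x["P01", "t3"]), log2(4))
  expect_length(attr(x, "flagged_proteins"), 0)
})

test_that("a protein absent from a whole group is flagged, not imputed", {
  tm <- toy_matrix(c(NA, NA, NA, 4, 4, 4,
                     3, 3, 3, 3, 3, 3))
  x <- preprocess_intensities(tm$m, tm$ann, de_config(normalization = "none"))
  expect_equal(attr(x, "flagged_proteins"), "P01")
  expect_true(all(is.na(x["P01", 1:3])))
  # fully missing protein likewise
  tm2 <- toy_matrix(c(rep(NA, 6), rep(2, 6)))
  x2 <- preprocess_intensities(tm2$m, tm2$ann, de_config(normalization = "none"))
  expect_equal(attr(x2, "flagged_proteins"), "P01")
})

test_that("median centering cancels a global per-run scale factor", {
  set.seed(6)
  base <- matrix(2^rnorm(60, 10, 1), nrow = 10)
  m <- cbind(base[, 1:3], base[, 1:3] * 2)  # runs 4-6 are a 2x copy of 1-3
  rownames(m) <- sprintf("P%02d", 1:10)
  colnames(m) <- c("t1", "t2", "t3", "u1", "u2", "u3")
  ann <- data.frame(run_id = colnames(m),
                    group = rep(c("treated", "untreated"), each = 3),
                    bio_rep = rep(1:3, 2), tech_rep = 1L)
  x <- preprocess_intensities(m, ann, de_config())
  expect_equal(unname(x[, 1:3]), unname(x[, 4:6]), tolerance = 1e-12)
  # glog surrogate also removes the shift (approximately, large intensities)
  xg <- preprocess_intensities(m, ann, de_config(normalization = "glog_vsn_surrogate"))
  expect_equal(unname(xg[, 1:3]), unname(xg[, 4:6]), tolerance = 1e-6)
})

test_that("identical groups give fold-change 1 and planted 2x effects are recovered", {
  tm <- toy_matrix(c(4, 4, 4, 4, 4, 4,
                     6, 6.1, 5.9, 6, 6.1, 5.9))
  x <- preprocess_intensities(tm$m, tm$ann, de_config(normalization = "none"))
  r <- differential_expression(x, tm$ann)
  expect_equal(r$log2fc, c(0, 0))
  expect_equal(r$fold_change, c(1, 1))

  # treated exactly 2x untreated with small jitter
  set.seed(3)
  u <- 2^rnorm(18, 10, 0.05)
  m <- matrix(NA_real_, 3, 6,
              dimnames = list(sprintf("P%02d", 1:3),
                              c("t1", "t2", "t3", "u1", "u2", "u3")))
  m[, 4:6] <- u[1:9]
  m[, 1:3] <- 2 * u[10:18]
  ann <- toy_matrix(rep(1, 6))$ann
  x2 <- preprocess_intensities(m, ann, de_config(normalization = "none"))
  r2 <- differential_expression(x2, ann)
  expect_equal(r2$fold_change, rep(2, 3), tolerance = 0.15)
})

test_that("a protein with fewer than two observations per group is flagged ns", {
  tm <- toy_matrix(c(4, NA, NA, 5, 5, 5))
  x <- preprocess_intensities(tm$m, tm$ann,
                              de_config(normalization = "none", imputation = "none"))
  r <- differential_expression(x, tm$ann)
  expect_true(is.na(r$p_value))
  expect_true(r$flagged)
  expect_equal(filter_de(r)$status, "ns")
})

test_that("collapse_mean averages technical replicates into biological samples", {
  # 2 bio x 2 tech per group; tech reps are exact copies
  m <- matrix(rep(2^c(10, 11, 12, 13), each = 2), nrow = 1)
  m <- rbind(m, m * 4)
  rownames(m) <- c("P01", "P02")
  colnames(m) <- c("t_b1_t1", "t_b1_t2", "t_b2_t1", "t_b2_t2",
                   "u_b1_t1", "u_b1_t2", "u_b2_t1", "u_b2_t2")
  ann <- data.frame(run_id = colnames(m),
                    group = rep(c("treated", "untreated"), each = 4),
                    bio_rep = rep(c(1, 1, 2, 2), 2),
                    tech_rep = rep(1:2, 4))
  x <- preprocess_intensities(m, ann, de_config(normalization = "none"))
  r <- differential_expression(x, ann, de_config(normalization = "none",
                                                 tech_rep_policy = "collapse_mean"))
  # group means: treated (10+11)/2? no: bio means 10, 11 vs 12, 13 -> diff -2
  expect_equal(r$log2fc, c(-2, -2))
  expect_equal(r$n_treated, c(2L, 2L))  # collapsed to bio-rep count
})

test_that("the fold-change/p gate uses inclusive fold and strict p boundaries", {
  r <- data.frame(protein_id = sprintf("P%d", 1:5),
                  log2fc = log2(c(1.0, 2.0, 0.5, 3.0, 2.5)),
                  fold_change = c(1.0, 2.0, 0.5, 3.0, 2.5),
                  p_value = c(0.5, 0.01, 0.049, 0.05, NA))
  out <- filter_de(r)
  expect_equal(out$status, c("ns", "up", "down", "ns", "ns"))
  s <- summarize_de(out)
  expect_equal(c(s$n_up, s$n_down, s$n_total_de), c(1L, 1L, 2L))
  # status coherence with log2fc at default thresholds
  expect_true(all(out$log2fc[out$status == "up"] >= 1))
  expect_true(all(out$log2fc[out$status == "down"] <= -1))
})

test_that("volcano export drops unscored proteins and heatmap rows are z-scored", {
  r <- data.frame(protein_id = c("A", "B", "C"),
                  log2fc = c(1, -1, 0.5),
                  fold_change = 2^c(1, -1, 0.5),
                  p_value = c(0.01, NA, 0.2))
  out <- filter_de(r)
  expect_message(v <- export_volcano(out), "1 protein")
  expect_equal(v$protein_id, c("A", "C"))
  expect_equal(v$neg_log10_p, -log10(c(0.01, 0.2)))

  tm <- toy_matrix(c(4, 4, 4, 4, 4, 4,
                     1, 2, 3, 4, 5, 6))
  x <- preprocess_intensities(tm$m, tm$ann, de_config(normalization = "none"))
  hm <- export_heatmap_matrix(x, c("P01", "P02"))
  expect_equal(unname(hm["P01", ]), rep(0, 6))     # constant row -> zeros
  expect_equal(mean(hm["P02", ]), 0, tolerance = 1e-12)
  expect_equal(sd(hm["P02", ]), 1, tolerance = 1e-12)
  expect_error(export_heatmap_matrix(x, "nope"), "not in matrix")
})
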