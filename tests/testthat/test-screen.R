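# Build a small annotated candidate set for screen tests.
screen_inputs <- function(seqs, charges = NULL, labels = "helix",
                          consensus = NULL) {
  lib <- toy_library(seqs)
  ch <- if (is.null(charges)) annotate_charges(lib) else
    data.frame(peptide_id = lib$peptide_id, net_charge = charges)
  st <- data.frame(peptide_id = lib$peptide_id,
                   structure_label = rep_len(labels, nrow(lib)))
  co <- data.frame(peptide_id = lib$peptide_id,
                   consensus = if (is.null(consensus))
                     seq(0.9, 0.6, length.out = nrow(lib)) else consensus)
  list(lib = lib, ch = ch, st = st, co = co)
}

test_that("filters name the failing rule and rank survivors by consensus", {
  x <- screen_inputs(c("KKKAA", "KKKCC", "AAAAA", "KKKGG"),
                     labels = c("helix", "coil", "helix", "helix-coil"),
                     consensus = c(0.7, 0.9, 0.95, 0.8))
  out <- apply_filters(x$lib, x$ch, x$st, x$co)
  expect_equal(out$status_detail[out$peptide_id == "pep02"], "require_helix")
  expect_equal(out$status_detail[out$peptide_id == "pep03"], "min_charge")
  kept <- out[out$status == "kept", ]
  expect_equal(kept$peptide_id, c("pep04", "pep01"))  # 0.8 then 0.7
  expect_equal(kept$rank, 1:2)
})

test_that("all-zero charges are fully filtered at min_charge 3", {
  x <- screen_inputs(c("AAAAA", "GGGGG", "SSSSS"))
  out <- apply_filters(x$lib, x$ch, x$st, x$co)
  expect_true(all(out$status == "filtered_out"))
  expect_true(all(out$status_detail == "min_charge"))
})

test_that("consensus below threshold is filtered and sub-threshold calls are non-ACP", {
  x <- screen_inputs(c("KKKAA", "KKKSS"), consensus = c(0.9, 0.3))
  out <- apply_filters(x$lib, x$ch, x$st, x$co)
  expect_equal(out$status_detail[out$peptide_id == "pep02"], "consensus_threshold")
  expect_equal(out$call[out$peptide_id == "pep02"], "non-ACP")
})

test_that("equal-consensus ties break deterministically and reproducibly", {
  x <- screen_inputs(c("KKKKAA", "RRRAA", "KKKAA"),
                     consensus = c(0.8, 0.8, 0.8))
  out1 <- apply_filters(x$lib, x$ch, x$st, x$co)
  out2 <- apply_filters(x$lib, x$ch, x$st, x$co)
  expect_identical(out1, out2)
  kept <- out1[out1$status == "kept", ]
  # higher charge first (pep01: +4), then shorter length (pep02 vs pep03: 5 both)
  expect_equal(kept$peptide_id[1], "pep01")
  # pep02 (RRRAA) vs pep03 (KKKAA): same charge, same length -> lexicographic
  expect_equal(kept$peptide_id[2:3], c("pep03", "pep02"))
})

test_that("apply_filters is idempotent on its own survivors", {
  x <- screen_inputs(c("KKKAA", "KKKCC", "AAAAA", "KKKGG"),
                     labels = c("helix", "coil", "helix", "helix"),
                     consensus = c(0.7, 0.9, 0.95, 0.8))
  out <- apply_filters(x$lib, x$ch, x$st, x$co)
  surv <- out[out$status == "kept", c("peptide_id", "sequence", "length")]
  again <- apply_filters(surv, x$ch, x$st, x$co)
  expect_equal(again$peptide_id, surv$peptide_id)
  expect_true(all(again$status == "kept"))
  expect_equal(again$rank, seq_len(nrow(again)))
})

test_that("structure annotations may cover only charge-passing peptides", {
  x <- screen_inputs(c("KKKAA", "AAAAA"), consensus = c(0.9, 0.8))
  st_partial <- x$st[1, , drop = FALSE]  # only the charge-passer annotated
  out <- apply_filters(x$lib, x$ch, st_partial, x$co)
  expect_equal(out$status[out$peptide_id == "pep01"], "kept")
  # but a charge-passing peptide without structure errors in strict mode
  x2 <- screen_inputs(c("KKKAA", "RRRGG"), consensus = c(0.9, 0.8))
  expect_error(apply_filters(x2$lib, x2$ch, x2$st[1, , drop = FALSE], x2$co,
                             strict = TRUE), "missing structure")
  expect_warning(out2 <- apply_filters(x2$lib, x2$ch, x2$st[1, , drop = FALSE],
                                       x2$co), "missing structure")
  expect_equal(out2$status_detail[out2$peptide_id == "pep02"],
               "missing_annotation")
})

test_that("substring redundancy collapses onto the higher-ranked candidate", {
  # shorter candidate contained in a longer, lower-ranked one, and vice versa
  x <- screen_inputs(c("KLWCKSSQVPQSRKK", "AAKLWCKSSQVPQSRKKAA", "KKKFFFAA"),
                     consensus = c(0.9, 0.85, 0.8))
  out <- collapse_redundant(apply_filters(x$lib, x$ch, x$st, x$co))
  expect_equal(out$status[out$peptide_id == "pep02"], "redundant")
  expect_equal(out$status_detail[out$peptide_id == "pep02"], "pep01")
  expect_equal(out$status[out$peptide_id == "pep03"], "kept")
  # surviving ranks are gapless
  expect_equal(sort(out$rank[out$status == "kept"]), 1:2)
})

test_that("no kept pair is in substring relation (brute-force scan)", {
  prot <- gen_protein(60, composition = c(K = 3, A = 5, L = 5, R = 2), seed = 9)
  lib <- enumerate_windows(prot, 5, 12)
  ch <- annotate_charges(lib)
  st <- data.frame(peptide_id = lib$peptide_id, structure_label = "helix")
  set.seed(1)
  co <- data.frame(peptide_id = lib$peptide_id, consensus = runif(nrow(lib)))
  out <- collapse_redundant(
    apply_filters(lib, ch, st, co, screen_config(min_charge = 1)))
  kept <- out$sequence[out$status == "kept"]
  for (i in seq_along(kept)) for (j in seq_along(kept)) {
    if (i != j) expect_false(grepl(kept[i], kept[j], fixed = TRUE))
  }
})

test_that("overlap-fraction redundancy uses source coordinates", {
  prot <- c(src = "KKKAAAAKKKAAAA")
  lib <- enumerate_windows(prot, 8, 10)
  ch <- annotate_charges(lib)
  st <- data.frame(peptide_id = lib$peptide_id, structure_label = "helix")
  set.seed(2)
  co <- data.frame(peptide_id = lib$peptide_id,
                   consensus = runif(nrow(lib), 0.6, 1))
  cfg <- screen_config(min_charge = 0, redundancy_mode = "overlap_fraction",
                       overlap_fraction_cutoff = 0.8)
  out <- collapse_redundant(apply_filters(lib, ch, st, co, cfg), cfg)
  kept <- out[out$status == "kept", ]
  for (i in seq_len(nrow(kept))) for (j in seq_len(nrow(kept))) {
    if (i == j) next
    ov <- min(kept$end[i], kept$end[j]) - max(kept$start[i], kept$start[j]) + 1
    expect_lt(ov, 0.8 * min(kept$length[i], kept$length[j]))
  }
})

test_that("select_top returns the shortlist and warns when short", {
  x <- screen_inputs(c("KKKAA", "RRRGG", "KKRAA"),
                     consensus = c(0.9, 0.8, 0.7))
  out <- collapse_redundant(apply_filters(x$lib, x$ch, x$st, x$co))
  top <- select_top(out, top_k = 2)
  expect_equal(top$peptide_id, c("pep01", "pep02"))
  expect_true(all(top$status == "selected"))
  expect_warning(all3 <- select_top(out, top_k = 5), "only 3 candidate")
  expect_equal(nrow(all3), 3L)
  empty <- out[0, ]
  expect_warning(none <- select_top(empty, top_k = 1), "only 0")
  expect_equal(nrow(none), 0L)
})

test_that("controls bypass filters but never enter the shortlist", {
  x <- screen_inputs(c("KKKAA", "RRRGG"), consensus = c(0.9, 0.8))
  ctl <- data.frame(peptide_id = "CTRL", sequence = "FKCRR",
                    net_charge = 3, structure_label = "coil",
                    consensus = 0.99, stringsAsFactors = FALSE)
  res <- screen_candidates(x$lib, x$ch, x$st, x$co, controls = ctl)
  expect_false("CTRL" %in% res$shortlist$peptide_id)
  crow <- res$candidates[res$candidates$peptide_id == "CTRL", ]
  expect_equal(crow$status, "control")  # kept despite coil structure
})

test_that("top-of-list precision beats the planted base rate on synthetic scores", {
  prot <- gen_protein(142, seed = 500)
  lib <- enumerate_windows(prot)
  base_rate <- 0.1
  gs <- gen_score_table(lib, base_rate = base_rate, seed = 500)
  co <- score_consensus(gs$scores)
  ch <- annotate_charges(lib)
  st <- gen_structure_annotations(lib, helix_fraction = 0.8, seed = 500)
  cfg <- screen_config(min_charge = 0, top_k = 20)
  res <- screen_candidates(lib, ch, st, co, cfg)
  truth <- gs$truth$is_acp[match(res$shortlist$peptide_id, gs$truth$peptide_id)]
  precision <- mean(truth)
  expect_gt(precision, base_rate)
})
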