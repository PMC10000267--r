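# Label-free (SWATH/DIA) differential expression from an extracted
# protein-by-run intensity matrix: log2 transform, per-run normalization,
# per-protein median imputation, two-sample t-tests, and fold-change /
# p-value gating with volcano and heatmap exports.

#' Differential-expression configuration
#'
#' @param fc_threshold Linear fold-change gate (default 2; inclusive on the
#'   fold-change side).
#' @param p_threshold p-value gate (default 0.05; strict).
#' @param normalization `"median_center"` (default): subtract each run's
#'   median log2 intensity and restore the global median — a documented
#'   stand-in for variance-stabilizing normalization; `"glog_vsn_surrogate"`:
#'   a generalized-log (arsinh-type) transform with a robust per-run scale,
#'   then median centering; or `"none"`.
#' @param imputation `"protein_median"` (default): impute a missing cell with
#'   the protein's median over observed runs, but only when the protein is
#'   observed in at least one run of each group — a protein absent from an
#'   entire group is flagged, not imputed; or `"none"`.
#' @param tech_rep_policy `"as_samples"` (default): technical replicates enter
#'   the test as samples (n = bio x tech per group); `"collapse_mean"`:
#'   average technical replicates within each biological replicate first (the
#'   statistically conservative alternative — see the vignette on
#'   pseudo-replication).
#' @param test `"welch_t"` (default, unequal variances) or `"student_t"`.
#' @return A list of class `"de_config"`.
#' @export
de_config <- function(fc_threshold = 2, p_threshold = 0.05,
                      normalization = c("median_center", "glog_vsn_surrogate", "none"),
                      imputation = c("protein_median", "none"),
                      tech_rep_policy = c("as_samples", "collapse_mean"),
                      test = c("welch_t", "student_t")) {
  stopifnot(fc_threshold > 0, p_threshold > 0)
  structure(list(
    fc_threshold = fc_threshold, p_threshold = p_threshold,
    normalization = match.arg(normalization),
    imputation = match.arg(imputation),
    tech_rep_policy = match.arg(tech_rep_policy),
    test = match.arg(test)
  ), class = "de_config")
}

.check_annotations <- function(intensities, annotations) {
  stopifnot(is.matrix(intensities), is.data.frame(annotations),
            all(c("run_id", "group") %in% names(annotations)))
  if (is.null(colnames(intensities)) || is.null(rownames(intensities)))
    stop("intensity matrix needs protein rownames and run colnames", call. = FALSE)
  miss <- setdiff(colnames(intensities), annotations$run_id)
  if (length(miss)) stop(sprintf("run '%s' has no annotation", miss[1L]), call. = FALSE)
  groups <- unique(annotations$group)
  if (length(groups) != 2L)
    stop(sprintf("need exactly 2 groups, got: %s", paste(groups, collapse = ", ")),
         call. = FALSE)
  invisible(annotations[match(colnames(intensities), annotations$run_id), ,
                        drop = FALSE])
}

#' Read an intensity matrix and its run annotations
#'
#' @param matrix_path Wide TSV/CSV: first column protein ids, one column per
#'   run (empty cells / NA are missing values).
#' @param annotation_path TSV with columns `run_id`, `group`, and optionally
#'   `bio_rep`, `tech_rep`.
#' @return A list with `intensities` (numeric matrix, proteins x runs) and
#'   `annotations` (data frame, one row per run in column order).
#' @export
read_intensity_matrix <- function(matrix_path, annotation_path) {
  sep <- if (grepl("\\.csv$", matrix_path, ignore.case = TRUE)) "," else "\t"
  tab <- read.delim(matrix_path, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE, comment.char = "#")
  mat <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- tab[[1L]]
  ann <- read.delim(annotation_path, stringsAsFactors = FALSE, comment.char = "#")
  ann <- .check_annotations(mat, ann)
  list(intensities = mat, annotations = ann)
}

.glog2 <- function(y, a) log2((y + sqrt(y^2 + a^2)) / 2)

#' Preprocess an intensity matrix
#'
#' Transforms linear intensities to the log2 scale, normalizes runs, and
#' imputes missing values, in that order (normalize before impute, so imputed
#' values inherit the normalized scale). Proteins that cannot be imputed
#' (absent from every run of a group, or from all runs) are flagged in
#' `attr(, "flagged_proteins")` and left `NA`.
#'
#' @param intensities Numeric matrix, proteins x runs, positive where
#'   observed (`NA` = missing). A non-positive observed value raises an error
#'   naming the cell.
#' @param annotations Run annotation data frame (`run_id`, `group`, ...);
#'   required for group-aware imputation flagging.
#' @param config A [de_config()].
#' @return The transformed matrix (log2 scale) with attributes
#'   `flagged_proteins` and `scale = "log2"`.
#' @export
preprocess_intensities <- function(intensities, annotations,
                                   config = de_config()) {
  ann <- .check_annotations(intensities, annotations)
  bad <- which(!is.na(intensities) & intensities <= 0, arr.ind = TRUE)
  if (nrow(bad)) stop(sprintf(
    "non-positive intensity at protein '%s', run '%s'",
    rownames(intensities)[bad[1L, 1L]], colnames(intensities)[bad[1L, 2L]]),
    call. = FALSE)

  x <- switch(config$normalization,
    none = ,
    median_center = log2(intensities),
    glog_vsn_surrogate = {
      apply(intensities, 2L, function(y) {
        a <- stats::mad(y, na.rm = TRUE)
        if (!is.finite(a) || a == 0) a <- 1
        .glog2(y, a)
      })
    }
  )
  if (config$normalization != "none") {
    run_med <- apply(x, 2L, median, na.rm = TRUE)
    x <- sweep(x, 2L, run_med) + median(run_med)
  }

  flagged <- character(0)
  if (config$imputation == "protein_median") {
    groups <- split(seq_len(ncol(x)), ann$group)
    for (i in seq_len(nrow(x))) {
      if (!anyNA(x[i, ])) next
      seen_per_group <- vapply(groups, function(j) any(!is.na(x[i, j])), logical(1L))
      if (all(seen_per_group)) {
        x[i, is.na(x[i, ])] <- median(x[i, ], na.rm = TRUE)
      } else {
        flagged <- c(flagged, rownames(x)[i])
      }
    }
  }
  attr(x, "flagged_proteins") <- flagged
  attr(x, "scale") <- "log2"
  x
}

# Average technical replicates within each (group, bio_rep).
.collapse_tech <- function(x, ann) {
  if (!"bio_rep" %in% names(ann))
    stop("collapse_mean needs a bio_rep annotation column", call. = FALSE)
  key <- paste(ann$group, ann$bio_rep, sep = "_")
  cols <- split(seq_len(ncol(x)), key)
  xm <- vapply(cols, function(j) rowMeans(x[, j, drop = FALSE], na.rm = TRUE),
               numeric(nrow(x)))
  xm[is.nan(xm)] <- NA_real_
  ann2 <- data.frame(run_id = names(cols),
                     group = vapply(cols, function(j) ann$group[j[1L]], character(1L)),
                     stringsAsFactors = FALSE)
  list(x = xm, ann = ann2)
}

#' Per-protein differential expression
#'
#' For each protein, the log2 fold-change is the difference of group means on
#' the log2 scale (`fold_change = 2^log2fc`, treated/untreated), and the
#' p-value comes from a two-sided two-sample t-test on the log2 values
#' (Welch by default). Proteins with fewer than two observations in either
#' group get `p_value = NA`, are flagged, and will be called `ns`.
#' A Benjamini-Hochberg `q_value` column is included for transparency, but
#' the default significance gate (matching common practice in SWATH reports)
#' does not use it.
#'
#' @param x Preprocessed log2 matrix from [preprocess_intensities()].
#' @param annotations Run annotations (`run_id`, `group`, `bio_rep`,
#'   `tech_rep`).
#' @param config A [de_config()].
#' @param group_treated,group_control Which annotation group is the
#'   fold-change numerator / denominator (defaults `"treated"`,
#'   `"untreated"`).
#' @return A data frame `(protein_id, log2fc, fold_change, p_value, q_value,
#'   n_treated, n_untreated, flagged)` sorted by `protein_id`.
#' @export
differential_expression <- function(x, annotations, config = de_config(),
                                    group_treated = "treated",
                                    group_control = "untreated") {
  ann <- .check_annotations(x, annotations)
  if (!all(c(group_treated, group_control) %in% ann$group))
    stop(sprintf("groups '%s'/'%s' not found in annotations",
                 group_treated, group_control), call. = FALSE)
  if (config$tech_rep_policy == "collapse_mean") {
    cc <- .collapse_tech(x, ann)
    x <- cc$x; ann <- cc$ann
  }
  jt <- which(ann$group == group_treated)
  ju <- which(ann$group == group_control)
  if (length(jt) < 2L || length(ju) < 2L)
    stop("need >= 2 runs per group after the technical-replicate policy",
         call. = FALSE)

  n <- nrow(x)
  log2fc <- p <- rep(NA_real_, n)
  nt <- nu <- integer(n)
  for (i in seq_len(n)) {
    a <- x[i, jt]; a <- a[!is.na(a)]
    b <- x[i, ju]; b <- b[!is.na(b)]
    nt[i] <- length(a); nu[i] <- length(b)
    if (length(a) >= 1L && length(b) >= 1L) log2fc[i] <- mean(a) - mean(b)
    if (length(a) >= 2L && length(b) >= 2L) {
      p[i] <- tryCatch(
        t.test(a, b, var.equal = config$test == "student_t")$p.value,
        error = function(e) NA_real_)  # zero-variance degenerate case
    }
  }
  out <- data.frame(
    protein_id = rownames(x), log2fc = log2fc, fold_change = 2^log2fc,
    p_value = p, q_value = p.adjust(p, method = "BH"),
    n_treated = nt, n_untreated = nu, flagged = is.na(p),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$protein_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Gate results at fold-change and p-value thresholds
#'
#' `up` iff `fold_change >= fc_threshold` and `p < p_threshold`; `down` iff
#' `fold_change <= 1/fc_threshold` and `p < p_threshold`; otherwise `ns`.
#' The fold-change boundary is inclusive, the p boundary strict. Proteins
#' with missing p are `ns`.
#'
#' @param results Data frame with `fold_change` and `p_value` (e.g. from
#'   [differential_expression()], or a table of published pairs).
#' @param config A [de_config()] carrying the thresholds.
#' @return `results` with a `status` column added.
#' @seealso [summarize_de()] for the up/down/total counts.
#' @export
filter_de <- function(results, config = de_config()) {
  stopifnot(is.data.frame(results),
            all(c("fold_change", "p_value") %in% names(results)))
  fc <- results$fold_change
  p <- results$p_value
  sig <- !is.na(p) & p < config$p_threshold & !is.na(fc)
  status <- rep("ns", nrow(results))
  status[sig & fc >= config$fc_threshold] <- "up"
  status[sig & fc <= 1 / config$fc_threshold] <- "down"
  results$status <- status
  results
}

#' Count differentially expressed proteins
#'
#' @param results Output of [filter_de()].
#' @return A data frame with `n_up`, `n_down`, `n_total_de`, `n_tested`.
#' @export
summarize_de <- function(results) {
  stopifnot("status" %in% names(results))
  data.frame(
    n_up = sum(results$status == "up"),
    n_down = sum(results$status == "down"),
    n_total_de = sum(results$status %in% c("up", "down")),
    n_tested = nrow(results)
  )
}

#' Export a volcano table
#'
#' @param results Output of [filter_de()].
#' @return A data frame `(protein_id, log2fc, neg_log10_p, status)` for all
#'   proteins with a p-value; proteins with missing p are excluded with a
#'   message.
#' @export
export_volcano <- function(results) {
  stopifnot(all(c("protein_id", "log2fc", "p_value", "status") %in% names(results)))
  drop <- is.na(results$p_value)
  if (any(drop)) message(sprintf("excluding %d protein(s) without a p-value",
                                 sum(drop)))
  r <- results[!drop, , drop = FALSE]
  data.frame(protein_id = r$protein_id, log2fc = r$log2fc,
             neg_log10_p = -log10(r$p_value), status = r$status,
             stringsAsFactors = FALSE)
}

#' Export a z-scored heatmap matrix
#'
#' Rows (proteins) are centered and scaled over runs; a constant row maps to
#' zeros rather than NaN.
#'
#' @param x Preprocessed log2 matrix.
#' @param protein_ids Which proteins to include (e.g. the DE set).
#' @return The z-scored submatrix (proteins x runs).
#' @export
export_heatmap_matrix <- function(x, protein_ids) {
  miss <- setdiff(protein_ids, rownames(x))
  if (length(miss)) stop(sprintf("protein '%s' not in matrix", miss[1L]),
                         call. = FALSE)
  sub <- x[protein_ids, , drop = FALSE]
  t(apply(sub, 1L, function(r) {
    s <- sd(r, na.rm = TRUE)
    if (!is.finite(s) || s == 0) return(rep(0, length(r)))
    (r - mean(r, na.rm = TRUE)) / s
  }))
}
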