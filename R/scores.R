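# Consensus scoring: aggregate per-predictor ACP probabilities into the
# geometric mean and call ACP / non-ACP at a configurable threshold.

#' Read per-predictor probability tables into one score table
#'
#' Accepts either one two-column TSV per predictor (`peptide_id`,
#' `probability`) or a single wide TSV (`peptide_id` plus one numeric column
#' per predictor). Per-predictor files are inner-joined on `peptide_id`;
#' peptides missing from any predictor are excluded with a warning
#' (`policy = "strict"` errors instead). A geometric mean over fewer
#' predictors would not be comparable across peptides, so no k-reduction is
#' ever performed.
#'
#' @param paths Character vector of file paths.
#' @param predictor_names Optional names for the probability columns
#'   (defaults to file base names, or the wide file's own column names).
#' @param policy `"inner"` (default) or `"strict"`.
#' @return A wide data frame: `peptide_id` plus one probability column per
#'   predictor, all values validated to lie in \[0, 1\]. Duplicate
#'   `peptide_id`s within one file, or out-of-range probabilities, raise
#'   errors naming the offender.
#' @export
read_score_tables <- function(paths, predictor_names = NULL,
                              policy = c("inner", "strict")) {
  policy <- match.arg(policy)
  stopifnot(length(paths) >= 1L)

  check_probs <- function(p, label) {
    bad <- which(!is.na(p) & (p < 0 | p > 1))
    if (length(bad)) stop(sprintf(
      "probability %.4g out of [0,1] at row %d of %s", p[bad[1L]], bad[1L], label),
      call. = FALSE)
  }

  if (length(paths) == 1L) {
    tab <- read.delim(paths[1L], stringsAsFactors = FALSE, comment.char = "#")
    if (!"peptide_id" %in% names(tab))
      stop("score table needs a peptide_id column", call. = FALSE)
    if (ncol(tab) > 2L) {  # wide format
      dup <- tab$peptide_id[duplicated(tab$peptide_id)]
      if (length(dup)) stop(sprintf("duplicate peptide_id '%s' in %s",
                                    dup[1L], paths[1L]), call. = FALSE)
      pcols <- setdiff(names(tab), "peptide_id")
      for (pc in pcols) check_probs(tab[[pc]], sprintf("%s (column %s)", paths[1L], pc))
      if (!is.null(predictor_names)) {
        stopifnot(length(predictor_names) == length(pcols))
        names(tab)[match(pcols, names(tab))] <- predictor_names
      }
      return(tab)
    }
  }

  if (is.null(predictor_names))
    predictor_names <- make.unique(sub("\\.[^.]*$", "", basename(paths)))
  stopifnot(length(predictor_names) == length(paths))

  tabs <- lapply(seq_along(paths), function(i) {
    tab <- read.delim(paths[i], stringsAsFactors = FALSE, comment.char = "#")
    if (!"peptide_id" %in% names(tab))
      stop(sprintf("%s needs a peptide_id column", paths[i]), call. = FALSE)
    prob_col <- setdiff(names(tab), "peptide_id")[1L]
    dup <- tab$peptide_id[duplicated(tab$peptide_id)]
    if (length(dup)) stop(sprintf("duplicate peptide_id '%s' in %s",
                                  dup[1L], paths[i]), call. = FALSE)
    check_probs(tab[[prob_col]], paths[i])
    setNames(tab[c("peptide_id", prob_col)], c("peptide_id", predictor_names[i]))
  })

  ids <- lapply(tabs, `[[`, "peptide_id")
  common <- Reduce(intersect, ids)
  dropped <- setdiff(unique(unlist(ids)), common)
  if (length(dropped)) {
    msg <- sprintf("%d peptide(s) missing from at least one predictor: %s",
                   length(dropped),
                   paste(head(dropped, 5L), collapse = ", "))
    if (policy == "strict") stop(msg, call. = FALSE)
    warning(paste(msg, "- excluded"), call. = FALSE)
  }
  out <- Reduce(function(a, b) merge(a, b, by = "peptide_id", sort = FALSE), tabs)
  out <- out[match(intersect(ids[[1L]], common), out$peptide_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Geometric-mean consensus of classifier probabilities
#'
#' The consensus score of k probabilities is `(p1 * ... * pk)^(1/k)`. It is
#' bounded by the smallest and largest input, equals the arithmetic mean only
#' when all inputs agree, and is annihilated by any zero (no epsilon
#' flooring). Values are stored at full precision; rounding to the 3-decimal
#' report convention is left to [round_half_up()] at the report layer.
#'
#' @param probabilities Numeric vector of k >= 1 probabilities in \[0, 1\].
#' @return The geometric mean, in \[0, 1\].
#' @examples
#' consensus_score(c(0.992, 0.480, 0.798))  # 0.724 at 3 dp
#' @export
consensus_score <- function(probabilities) {
  if (!is.numeric(probabilities) || length(probabilities) < 1L)
    stop("need at least one probability", call. = FALSE)
  if (anyNA(probabilities)) stop("probabilities contain NA", call. = FALSE)
  if (any(probabilities < 0 | probabilities > 1))
    stop(sprintf("probability out of [0,1]: %.4g",
                 probabilities[which(probabilities < 0 | probabilities > 1)[1L]]),
         call. = FALSE)
  prod(probabilities)^(1 / length(probabilities))
}

#' Call ACP / non-ACP from a consensus score
#'
#' The call is `ACP` iff the consensus reaches the threshold (inclusive).
#' The default 0.5 is the natural probability midpoint; it is configurable.
#'
#' @param consensus Numeric vector of consensus scores in \[0, 1\].
#' @param threshold Decision threshold in \[0, 1\] (default 0.5).
#' @return Character vector, `"ACP"` or `"non-ACP"`.
#' @export
classify_acp <- function(consensus, threshold = 0.5) {
  stopifnot(is.numeric(consensus), is.numeric(threshold), length(threshold) == 1L,
            threshold >= 0, threshold <= 1)
  if (any(!is.na(consensus) & (consensus < 0 | consensus > 1)))
    stop("consensus out of [0,1]", call. = FALSE)
  ifelse(consensus >= threshold, "ACP", "non-ACP")
}

#' Add consensus score and call columns to a score table
#'
#' @param scores A wide score table (`peptide_id` plus one numeric
#'   probability column per predictor), as from [read_score_tables()].
#' @param threshold Passed to [classify_acp()].
#' @return `scores` with appended `consensus` (full precision) and `call`
#'   columns and an `n_predictors` attribute.
#' @export
score_consensus <- function(scores, threshold = 0.5) {
  stopifnot(is.data.frame(scores), "peptide_id" %in% names(scores))
  pcols <- setdiff(names(scores), "peptide_id")
  pcols <- pcols[vapply(scores[pcols], is.numeric, logical(1L))]
  if (!length(pcols)) stop("no predictor columns found", call. = FALSE)
  cons <- apply(as.matrix(scores[pcols]), 1L, consensus_score)
  scores$consensus <- cons
  scores$call <- classify_acp(cons, threshold)
  attr(scores, "n_predictors") <- length(pcols)
  scores
}

#' Round half away from zero
#'
#' Report-layer rounding matching the 3-decimal display convention of
#' screening tables (`round()` in R rounds half to even, which would turn
#' e.g. 0.8365 into 0.836 or 0.8375 into 0.838 inconsistently).
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 3).
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 3L) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}
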