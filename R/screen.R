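# Candidate screening: combine charge, structure, and consensus annotations;
# filter, rank, collapse redundant sequences, and emit a shortlist.
#
# Filters are evaluated charge -> structure -> consensus, so the expensive
# external structure annotation may legitimately cover only the
# charge-passing subset of the library.

#' Screening configuration
#'
#' @param min_charge Minimum net charge to keep a candidate (default +3, the
#'   usual cationicity requirement for ACPs).
#' @param require_helix Keep only candidates whose structure annotation
#'   contains at least one helix segment (default `TRUE`).
#' @param consensus_threshold ACP-call threshold on the consensus score
#'   (default 0.5, inclusive).
#' @param redundancy_mode `"substring"` (default): two candidates are
#'   redundant when either sequence contains the other; or
#'   `"overlap_fraction"`: redundant when they come from the same source and
#'   their coordinate overlap covers at least `overlap_fraction_cutoff` of
#'   the shorter peptide.
#' @param overlap_fraction_cutoff Overlap fraction in (0, 1\] for
#'   `"overlap_fraction"` mode (default 0.8).
#' @param top_k Shortlist size (default 2).
#' @return A list of class `"screen_config"`.
#' @export
screen_config <- function(min_charge = 3, require_helix = TRUE,
                          consensus_threshold = 0.5,
                          redundancy_mode = c("substring", "overlap_fraction"),
                          overlap_fraction_cutoff = 0.8, top_k = 2L) {
  redundancy_mode <- match.arg(redundancy_mode)
  stopifnot(top_k >= 1L, overlap_fraction_cutoff > 0, overlap_fraction_cutoff <= 1,
            consensus_threshold >= 0, consensus_threshold <= 1)
  structure(list(
    min_charge = min_charge, require_helix = isTRUE(require_helix),
    consensus_threshold = consensus_threshold,
    redundancy_mode = redundancy_mode,
    overlap_fraction_cutoff = overlap_fraction_cutoff,
    top_k = as.integer(top_k)
  ), class = "screen_config")
}

# Deterministic candidate ordering: consensus desc, then net charge desc,
# then length asc, then sequence lexicographic.
.rank_order <- function(df) {
  order(-df$consensus, -df$net_charge, df$length,
        df$sequence, method = "radix")
}

.rerank <- function(candidates) {
  candidates$rank <- NA_integer_
  keep <- which(candidates$status %in% c("kept", "selected"))
  keep <- keep[order(candidates$consensus[keep], decreasing = TRUE)]
  keep <- keep[.rank_order(candidates[keep, , drop = FALSE])]
  candidates$rank[keep] <- seq_along(keep)
  candidates
}

#' Filter and rank screening candidates
#'
#' Joins the library with its charge, structure and consensus annotations,
#' marks candidates failing a rule as `filtered_out` (naming the rule in
#' `status_detail`), and ranks survivors by consensus score descending. Ties
#' break deterministically: higher net charge, then shorter length, then
#' lexicographic sequence.
#'
#' @param library Peptide library data frame (`peptide_id`, `sequence`,
#'   optionally `source_id`, `start`, `end`, `length`).
#' @param charges Data frame `(peptide_id, net_charge)` covering the library.
#' @param structures Data frame `(peptide_id, structure_label)`; may cover
#'   only the charge-passing subset (the filter order makes that legitimate).
#' @param consensus Data frame with `peptide_id` and `consensus` (e.g. from
#'   [score_consensus()]).
#' @param config A [screen_config()].
#' @param strict If `TRUE`, a peptide that passes the charge filter but lacks
#'   a structure or consensus annotation raises an error naming it; default
#'   marks it `filtered_out (missing_annotation)` with a warning.
#' @return A candidate data frame with annotation columns plus `rank`
#'   (1..n over survivors, `NA` otherwise), `status` (`"kept"` or
#'   `"filtered_out"`), and `status_detail`. Survivors come first in rank
#'   order. Re-running on its own survivors is a no-op (idempotence).
#' @export
apply_filters <- function(library, charges, structures, consensus,
                          config = screen_config(), strict = FALSE) {
  stopifnot(inherits(config, "screen_config"),
            is.data.frame(library), "peptide_id" %in% names(library))
  df <- library[intersect(c("peptide_id", "source_id", "start", "end",
                            "length", "sequence"), names(library))]
  if (!"length" %in% names(df)) df$length <- nchar(df$sequence)

  miss_charge <- setdiff(df$peptide_id, charges$peptide_id)
  if (length(miss_charge)) stop(sprintf(
    "no charge annotation for peptide '%s'", miss_charge[1L]), call. = FALSE)
  df$net_charge <- charges$net_charge[match(df$peptide_id, charges$peptide_id)]
  df$structure_label <-
    structures$structure_label[match(df$peptide_id, structures$peptide_id)]
  df$has_helix <- ifelse(is.na(df$structure_label), NA,
                         has_helix(ifelse(is.na(df$structure_label), "coil",
                                          df$structure_label)))
  df$consensus <- consensus$consensus[match(df$peptide_id, consensus$peptide_id)]

  df$status <- "kept"
  df$status_detail <- ""
  fail <- function(rows, reason) {
    rows <- rows & df$status == "kept"
    df$status[rows] <<- "filtered_out"
    df$status_detail[rows] <<- reason
  }

  # 1) charge
  fail(df$net_charge < config$min_charge, "min_charge")
  # 2) structure (only charge-passing peptides need an annotation)
  need_struct <- df$status == "kept"
  if (config$require_helix) {
    missing_struct <- need_struct & is.na(df$structure_label)
    if (any(missing_struct)) {
      msg <- sprintf("missing structure annotation for %d charge-passing peptide(s), e.g. '%s'",
                     sum(missing_struct), df$peptide_id[which(missing_struct)[1L]])
      if (strict) stop(msg, call. = FALSE)
      warning(paste(msg, "- filtered out"), call. = FALSE)
      fail(missing_struct, "missing_annotation")
    }
    fail(!is.na(df$has_helix) & !df$has_helix, "require_helix")
  }
  # 3) consensus
  need_cons <- df$status == "kept"
  missing_cons <- need_cons & is.na(df$consensus)
  if (any(missing_cons)) {
    msg <- sprintf("missing consensus score for %d peptide(s), e.g. '%s'",
                   sum(missing_cons), df$peptide_id[which(missing_cons)[1L]])
    if (strict) stop(msg, call. = FALSE)
    warning(paste(msg, "- filtered out"), call. = FALSE)
    fail(missing_cons, "missing_annotation")
  }
  fail(!is.na(df$consensus) & df$consensus < config$consensus_threshold,
       "consensus_threshold")

  df$call <- ifelse(is.na(df$consensus), NA_character_,
                    classify_acp(pmin(pmax(df$consensus, 0), 1),
                                 config$consensus_threshold))
  df <- .rerank(df)
  df <- df[order(is.na(df$rank), df$rank), , drop = FALSE]
  rownames(df) <- NULL
  df
}

.redundant_pair <- function(a, b, config) {
  if (config$redundancy_mode == "substring") {
    grepl(a$sequence, b$sequence, fixed = TRUE) ||
      grepl(b$sequence, a$sequence, fixed = TRUE)
  } else {
    if (is.null(a$source_id) || is.na(a$source_id) || is.na(b$source_id) ||
        a$source_id != b$source_id) return(FALSE)
    ov <- min(a$end, b$end) - max(a$start, b$start) + 1L
    ov >= config$overlap_fraction_cutoff * min(a$length, b$length)
  }
}

#' Collapse redundant candidates
#'
#' Greedy scan from the best rank: a candidate redundant with any
#' already-kept candidate is marked `redundant` with the representative's id
#' in `status_detail`. The kept set is pairwise non-redundant; survivors are
#' re-ranked 1..n without gaps.
#'
#' @param candidates Output of [apply_filters()].
#' @param config A [screen_config()]; see `redundancy_mode` there.
#' @return The candidate data frame with redundant rows marked.
#' @export
collapse_redundant <- function(candidates, config = screen_config()) {
  stopifnot(inherits(config, "screen_config"), is.data.frame(candidates))
  idx <- which(candidates$status == "kept")
  idx <- idx[order(candidates$rank[idx])]
  kept <- integer(0)
  for (i in idx) {
    rep_of <- NA_integer_
    for (j in kept) {
      if (.redundant_pair(as.list(candidates[i, ]), as.list(candidates[j, ]),
                          config)) { rep_of <- j; break }
    }
    if (is.na(rep_of)) {
      kept <- c(kept, i)
    } else {
      candidates$status[i] <- "redundant"
      candidates$status_detail[i] <- candidates$peptide_id[rep_of]
    }
  }
  .rerank(candidates)
}

#' Select the top-k shortlist
#'
#' @param candidates A filtered, collapsed candidate table.
#' @param top_k Shortlist size; defaults to `config$top_k`.
#' @param config A [screen_config()].
#' @return The first `top_k` kept candidates in rank order, with status
#'   `"selected"`. If fewer survive, all are returned with a warning.
#' @export
select_top <- function(candidates, top_k = NULL, config = screen_config()) {
  if (is.null(top_k)) top_k <- config$top_k
  idx <- which(candidates$status == "kept")
  idx <- idx[order(candidates$rank[idx])]
  if (length(idx) < top_k) {
    warning(sprintf("only %d candidate(s) survive screening (top_k = %d)",
                    length(idx), top_k), call. = FALSE)
  }
  sel <- head(idx, top_k)
  out <- candidates[sel, , drop = FALSE]
  if (nrow(out)) out$status <- "selected"
  rownames(out) <- NULL
  out
}

#' Run the full screen: filter, rank, collapse, shortlist
#'
#' Convenience wrapper over [apply_filters()], [collapse_redundant()] and
#' [select_top()]. Control peptides (e.g. a known ACP run alongside the
#' library) bypass all filters and are excluded from the shortlist; they are
#' returned with status `"control"` for side-by-side reporting.
#'
#' @inheritParams apply_filters
#' @param controls Optional data frame of control peptides with the same
#'   annotation columns (`peptide_id`, `sequence`, `net_charge`,
#'   `structure_label`, `consensus`).
#' @return A list with `candidates` (full annotated table, controls appended)
#'   and `shortlist`.
#' @export
screen_candidates <- function(library, charges, structures, consensus,
                              config = screen_config(), strict = FALSE,
                              controls = NULL) {
  cand <- apply_filters(library, charges, structures, consensus, config, strict)
  cand <- collapse_redundant(cand, config)
  shortlist <- select_top(cand, config = config)
  cand$status[cand$peptide_id %in% shortlist$peptide_id] <- "selected"
  if (!is.null(controls) && nrow(controls)) {
    ctl <- controls
    ctl$length <- nchar(ctl$sequence)
    ctl$has_helix <- has_helix(ctl$structure_label)
    ctl$call <- classify_acp(ctl$consensus, config$consensus_threshold)
    ctl$rank <- NA_integer_
    ctl$status <- "control"
    ctl$status_detail <- ""
    common <- intersect(names(cand), names(ctl))
    for (nm in setdiff(names(cand), names(ctl))) ctl[[nm]] <- NA
    cand <- rbind(cand, ctl[names(cand)])
    rownames(cand) <- NULL
  }
  list(candidates = cand, shortlist = shortlist)
}
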