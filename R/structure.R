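# Secondary-structure annotations. Real annotations come from an external
# structure predictor and enter as a TSV of dash-joined segment labels
# (e.g. "coil-helix-coil-helix"); the screening filter only asks whether a
# peptide contains at least one helix segment. A deterministic Chou-Fasman
# style propensity annotator is provided so synthetic pipelines can run
# end-to-end without a structure server -- it is a surrogate, not a
# re-implementation of any de novo predictor.

.STRUCTURE_TOKENS <- c("helix", "coil", "sheet")

#' Parse a dash-joined secondary-structure label
#'
#' Splits on hyphen, en dash or em dash and normalizes tokens
#' case-insensitively to `helix`, `coil`, `sheet`.
#'
#' @param label Character vector of raw labels (e.g. `"coil-helix"`,
#'   en dashes accepted).
#' @return A list of character vectors of segment tokens (one per label). An
#'   unknown token raises an error naming it.
#' @examples
#' structure_segments("coil–helix")
#' @export
structure_segments <- function(label) {
  stopifnot(is.character(label))
  lapply(label, function(x) {
    toks <- tolower(trimws(strsplit(x, "[-–—]+")[[1L]]))
    toks <- toks[nzchar(toks)]
    if (!length(toks)) stop("empty structure label", call. = FALSE)
    bad <- setdiff(toks, .STRUCTURE_TOKENS)
    if (length(bad)) stop(sprintf(
      "unknown structure token '%s' (expected %s)", bad[1L],
      paste(.STRUCTURE_TOKENS, collapse = "/")), call. = FALSE)
    toks
  })
}

#' Format segment tokens back into a label
#'
#' @param segments Character vector of segment tokens.
#' @return A single dash-joined label; `format_structure_label` inverts
#'   [structure_segments()] for valid labels (hyphen canonical form).
#' @export
format_structure_label <- function(segments) {
  stopifnot(is.character(segments), length(segments) >= 1L)
  paste(segments, collapse = "-")
}

#' Read a per-peptide structure annotation table
#'
#' @param path TSV with columns `peptide_id`, `structure_label`.
#' @return A data frame `(peptide_id, structure_label)` with every label
#'   validated; an unknown token raises an error naming the token and row.
#' @export
parse_structure_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("peptide_id", "structure_label")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop(sprintf("structure table lacks columns: %s",
                                 paste(miss, collapse = ", ")), call. = FALSE)
  for (i in seq_len(nrow(tab))) {
    ok <- tryCatch({ structure_segments(tab$structure_label[i]); TRUE },
                   error = function(e) e)
    if (!isTRUE(ok)) stop(sprintf("row %d (peptide '%s'): %s", i,
                                  tab$peptide_id[i], conditionMessage(ok)),
                          call. = FALSE)
  }
  tab[need]
}

#' Does an annotation contain a helix segment?
#'
#' The screening filter is "contains at least one helix segment", not "fully
#' helical": selected candidates routinely carry mixed labels such as
#' `helix-coil`.
#'
#' @param x A character vector of raw labels, or a list of segment vectors as
#'   returned by [structure_segments()].
#' @return Logical vector.
#' @examples
#' has_helix(c("coil–helix–coil–helix", "coil"))  # TRUE, FALSE
#' @export
has_helix <- function(x) {
  segs <- if (is.character(x)) structure_segments(x) else x
  vapply(segs, function(s) "helix" %in% s, logical(1L))
}

#' Helix propensity table
#'
#' Chou-Fasman style per-residue alpha-helix propensities, shipped as a plain
#' CSV data file (`extdata/helix_propensity.csv`). Values above 1 mark helix
#' formers (A, E, L, M), values well below 1 mark breakers (G, P).
#'
#' @return Named numeric vector over the 20 standard residues.
#' @export
helix_propensity <- function() {
  if (is.null(.acpforge_env$helix_propensity)) {
    path <- system.file("extdata", "helix_propensity.csv", package = "acpforge")
    tab <- read.csv(path, stringsAsFactors = FALSE)
    .acpforge_env$helix_propensity <- setNames(tab$propensity, tab$residue)
  }
  .acpforge_env$helix_propensity
}

#' Propensity-based surrogate helix annotator
#'
#' Deterministic stand-in for an external secondary-structure predictor, used
#' so synthetic pipelines run without a web server. Every window of
#' `min_window` consecutive residues whose mean helix propensity reaches
#' `cutoff` marks its residues as helix; remaining residues are coil, and
#' adjacent identical labels merge into segments.
#'
#' This is explicitly not a re-implementation of any de novo structure
#' predictor and carries no claim of accuracy on real peptides.
#'
#' @param sequence Character vector of peptide sequences.
#' @param cutoff Mean-propensity threshold (default 1.0, the former/breaker
#'   boundary of the propensity scale).
#' @param min_window Window width in residues (default 4, the shortest
#'   helical turn worth labelling).
#' @return Character vector of dash-joined structure labels.
#' @examples
#' surrogate_helix_annotator(c("AAAAAAAAAA", "GGGGGGGGGG"))  # "helix", "coil"
#' @export
surrogate_helix_annotator <- function(sequence, cutoff = 1.0, min_window = 4L) {
  prop <- helix_propensity()
  min_window <- as.integer(min_window)
  stopifnot(min_window >= 1L)
  vapply(sequence, function(s) {
    .validate_sequence(s)
    chars <- strsplit(s, "", fixed = TRUE)[[1L]]
    n <- length(chars)
    p <- unname(prop[chars])
    helix <- logical(n)
    if (n >= min_window) {
      for (i in seq_len(n - min_window + 1L)) {
        idx <- i:(i + min_window - 1L)
        if (mean(p[idx]) >= cutoff) helix[idx] <- TRUE
      }
    }
    r <- rle(ifelse(helix, "helix", "coil"))
    format_structure_label(r$values)
  }, character(1L), USE.NAMES = FALSE)
}

#' Annotate a peptide library with surrogate structure labels
#'
#' @param library A peptide library (data frame with `peptide_id`,
#'   `sequence`).
#' @param ... Passed to [surrogate_helix_annotator()].
#' @return A data frame `(peptide_id, structure_label)`.
#' @export
annotate_structures <- function(library, ...) {
  stopifnot(is.data.frame(library), all(c("peptide_id", "sequence") %in% names(library)))
  data.frame(
    peptide_id = library$peptide_id,
    structure_label = surrogate_helix_annotator(library$sequence, ...),
    stringsAsFactors = FALSE
  )
}
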