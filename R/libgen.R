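# Peptide library generation: read a source protein and enumerate every
# contiguous window in a length range, stepping one residue at a time.

#' Read protein records from a FASTA file
#'
#' Reads one or more protein records, uppercases the sequences, and validates
#' them against the 20 standard amino-acid letters. Records are returned in
#' input order.
#'
#' @param path Path to a FASTA file (single- or multi-record).
#' @param skip_invalid If `TRUE`, records containing non-standard residues
#'   (B, J, O, U, X, Z, ...) are dropped with a warning instead of raising an
#'   error. Default `FALSE`: the first offending character and its position
#'   are named in the error.
#' @return A data frame with columns `id`, `description`, `sequence`,
#'   `length` (one row per record).
#' @examples
#' fa <- system.file("extdata", "P00709.fasta", package = "acpforge")
#' read_fasta(fa)$length
#' @export
read_fasta <- function(path, skip_invalid = FALSE) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L) stop("no records in FASTA file", call. = FALSE)
  headers <- names(aa)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seqs <- toupper(as.character(aa))
  keep <- rep(TRUE, length(seqs))
  for (i in seq_along(seqs)) {
    ok <- tryCatch({ .validate_sequence(seqs[i], context = ids[i]); TRUE },
                   error = function(e) e)
    if (!isTRUE(ok)) {
      if (skip_invalid) {
        warning(sprintf("dropping record '%s': %s", ids[i], conditionMessage(ok)),
                call. = FALSE)
        keep[i] <- FALSE
      } else {
        stop(conditionMessage(ok), call. = FALSE)
      }
    }
  }
  out <- data.frame(
    id = ids[keep], description = desc[keep], sequence = seqs[keep],
    length = nchar(seqs[keep]), stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Enumerate all contiguous peptide windows of a protein
#'
#' Generates every subsequence of each length in `[lmin, min(lmax, N)]`,
#' advancing the start position by `step` residues (default 1, N- to
#' C-terminal). Coordinates are 1-based and inclusive at both ends. For a
#' protein of length N and step 1 the window count is the closed form
#' sum over L of (N - L + 1); a 142-residue protein with the default 5-25
#' range yields 2688 windows.
#'
#' Duplicate sequences arising from internal repeats are kept as separate
#' windows; use [distinct_sequences()] to inspect them.
#'
#' @param protein A data frame as returned by [read_fasta()] (one or more
#'   rows; each record is processed independently), or a single character
#'   sequence (optionally named with its id).
#' @param lmin,lmax Inclusive window-length bounds in residues (defaults 5
#'   and 25, the usual ACP length range).
#' @param step Start-position increment in residues (default 1).
#' @return A peptide library: a data frame with columns `peptide_id`
#'   (`"source|start-end"`), `source_id`, `start`, `end`, `length`,
#'   `sequence`, carrying the generation parameters in
#'   `attr(, "params")`.
#' @examples
#' lib <- enumerate_windows(c(toy = "MKWVTFISLLLF"), lmin = 5, lmax = 6)
#' nrow(lib)
#' @export
enumerate_windows <- function(protein, lmin = 5L, lmax = 25L, step = 1L) {
  if (is.character(protein)) {
    id <- if (!is.null(names(protein)) && nzchar(names(protein)[1L]))
      names(protein)[1L] else "protein"
    protein <- data.frame(id = id, sequence = unname(protein[1L]),
                          stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(protein), all(c("id", "sequence") %in% names(protein)))
  lmin <- as.integer(lmin); lmax <- as.integer(lmax); step <- as.integer(step)
  if (lmin < 1L || lmax < lmin) stop("need 1 <= lmin <= lmax", call. = FALSE)
  if (step < 1L) stop("step must be >= 1", call. = FALSE)

  one <- function(id, seqstr) {
    .validate_sequence(seqstr, context = id)
    n <- nchar(seqstr)
    if (lmin > n) {
      warning(sprintf("lmin (%d) exceeds protein length (%d) for '%s'; empty library",
                      lmin, n, id), call. = FALSE)
      return(NULL)
    }
    parts <- lapply(lmin:min(lmax, n), function(L) {
      starts <- seq.int(1L, n - L + 1L, by = step)
      data.frame(
        source_id = id, start = starts, end = starts + L - 1L, length = L,
        sequence = substring(seqstr, starts, starts + L - 1L),
        stringsAsFactors = FALSE
      )
    })
    do.call(rbind, parts)
  }

  pieces <- mapply(one, protein$id, protein$sequence, SIMPLIFY = FALSE)
  pieces <- pieces[!vapply(pieces, is.null, logical(1L))]
  if (!length(pieces)) {
    lib <- data.frame(peptide_id = character(), source_id = character(),
                      start = integer(), end = integer(), length = integer(),
                      sequence = character(), stringsAsFactors = FALSE)
  } else {
    lib <- do.call(rbind, pieces)
    # sort within each source by (start, length)
    lib <- lib[order(match(lib$source_id, protein$id), lib$start, lib$length), ]
    lib <- cbind(
      peptide_id = sprintf("%s|%d-%d", lib$source_id, lib$start, lib$end),
      lib, stringsAsFactors = FALSE
    )
    rownames(lib) <- NULL
  }
  attr(lib, "params") <- list(lmin = lmin, lmax = lmax, step = step)
  lib
}

#' Count distinct peptide sequences in a library
#'
#' The library keeps duplicate sequences (internal repeats of the source
#' protein) as separate windows; this reports how many unique sequence
#' strings the library contains and which windows carry each.
#'
#' @param library A peptide library from [enumerate_windows()].
#' @return A list with `n_windows`, `n_distinct`, and `windows`: a named list
#'   mapping each unique sequence to the `peptide_id`s that carry it.
#' @export
distinct_sequences <- function(library) {
  stopifnot(is.data.frame(library), all(c("peptide_id", "sequence") %in% names(library)))
  groups <- split(library$peptide_id, library$sequence)
  list(n_windows = nrow(library), n_distinct = length(groups), windows = groups)
}

#' Tabulate window counts by peptide length
#'
#' @param library A peptide library from [enumerate_windows()].
#' @return A data frame `(length, count)` sorted by length; counts sum to the
#'   window count. For step-1 libraries `count(L) = N - L + 1`.
#' @export
length_distribution <- function(library) {
  stopifnot(is.data.frame(library), "length" %in% names(library))
  if (nrow(library) == 0L) {
    return(data.frame(length = integer(), count = integer()))
  }
  tab <- table(library$length)
  data.frame(length = as.integer(names(tab)), count = as.integer(tab))
}

#' Write a peptide library to TSV or FASTA
#'
#' TSV output carries a `#` header line stating that coordinates are 1-based
#' and inclusive; FASTA records are named `"source|start-end"`.
#'
#' @param library A peptide library from [enumerate_windows()].
#' @param path Output file path.
#' @param format `"tsv"` (default) or `"fasta"`.
#' @return `path`, invisibly.
#' @export
write_library <- function(library, path, format = c("tsv", "fasta")) {
  format <- match.arg(format)
  if (format == "tsv") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("# peptide library; start/end are 1-based, inclusive", con)
    write.table(library, con, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    aa <- Biostrings::AAStringSet(setNames(library$sequence, library$peptide_id))
    Biostrings::writeXStringSet(aa, path)
  }
  invisible(path)
}

#' Read a peptide library written by [write_library()]
#'
#' @param path A TSV written by `write_library(format = "tsv")`.
#' @return The library data frame.
#' @export
read_library <- function(path) {
  lib <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("peptide_id", "source_id", "start", "end", "length", "sequence")
  miss <- setdiff(need, names(lib))
  if (length(miss)) stop(sprintf("library file lacks columns: %s",
                                 paste(miss, collapse = ", ")), call. = FALSE)
  lib
}
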