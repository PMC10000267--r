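# Amino-acid alphabet and reference composition.

# The 20 standard one-letter codes; everything downstream (charge model,
# generators, validation) is defined over this alphabet only.
.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Average residue composition of well-annotated vertebrate/SwissProt proteins
# (percent, normalized at use). Used as the default composition for random
# protein generation so synthetic libraries have realistic charge spectra.
.AA_COMPOSITION <- c(
  A = 8.25, C = 1.38, D = 5.46, E = 6.72, F = 3.86, G = 7.07, H = 2.27,
  I = 5.91, K = 5.80, L = 9.65, M = 2.41, N = 4.06, P = 4.74, Q = 3.93,
  R = 5.53, S = 6.64, T = 5.35, V = 6.86, W = 1.10, Y = 2.92
)

#' Validate a peptide or protein sequence
#'
#' Checks that a sequence is a non-empty string over the 20 standard
#' amino-acid letters, naming the first offending character and its position
#' otherwise.
#'
#' @param sequence Character scalar, the residue string (upper case).
#' @param context Optional label (record id, peptide id) used in error
#'   messages.
#' @return The validated sequence, invisibly.
#' @keywords internal
.validate_sequence <- function(sequence, context = NULL) {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence) ||
      !nzchar(sequence)) {
    stop("sequence must be a non-empty string", call. = FALSE)
  }
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% .AA20)
  if (length(bad)) {
    where <- if (is.null(context)) "" else sprintf(" in '%s'", context)
    stop(sprintf(
      "non-standard residue '%s' at position %d%s (allowed: %s)",
      chars[bad[1L]], bad[1L], where, paste(.AA20, collapse = "")
    ), call. = FALSE)
  }
  invisible(sequence)
}
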