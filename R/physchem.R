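# Net-charge physicochemistry. The default model counts K/R as +1 and D/E as
# -1 with histidine and the termini neutral -- the integer convention used
# throughout ACP screening reports. A pH-dependent Henderson-Hasselbalch mode
# is available for probing convention sensitivity.

# Side-chain pKa values (plus termini) for the optional pH mode.
.PKA <- list(
  positive = c(K = 10.54, R = 12.48, H = 6.04),
  negative = c(D = 3.90, E = 4.07, C = 8.33, Y = 10.46),
  n_term = 9.00, c_term = 2.35
)

#' Construct a residue charge model
#'
#' By default lysine and arginine contribute +1, aspartate and glutamate -1,
#' histidine and all other residues 0, and the termini are ignored; this
#' integer convention reproduces the charges reported for synthesized ACP
#' candidates. Individual contributions can be overridden (e.g. `H = 0.1`),
#' terminal charges can be switched on (+1 at the free N-terminus, -1 at the
#' C-terminus), or a pH can be supplied to use Henderson-Hasselbalch partial
#' charges instead.
#'
#' @param overrides Named numeric vector of per-residue contributions to
#'   override, e.g. `c(H = 0.5)`.
#' @param termini If `TRUE`, add +1 for the N-terminus and -1 for the
#'   C-terminus (net zero for an unmodified peptide, but relevant with
#'   fractional pH-mode charges).
#' @param pH If non-`NULL`, ignore the integer defaults and compute
#'   fractional side-chain charges at this pH from standard pKa values
#'   (K, R, H positive; D, E, C, Y negative).
#' @return A named numeric vector over the 20 standard residues with
#'   attributes `termini`, `n_term`, `c_term`, of class `"charge_model"`.
#' @examples
#' net_charge("KLWCKSSQVPQSR")                      # +3
#' net_charge("KLWCKSSQVPQSR", charge_model(pH = 7))
#' @export
charge_model <- function(overrides = NULL, termini = FALSE, pH = NULL) {
  contrib <- setNames(numeric(length(.AA20)), .AA20)
  if (is.null(pH)) {
    contrib[c("K", "R")] <- 1
    contrib[c("D", "E")] <- -1
  } else {
    stopifnot(is.numeric(pH), length(pH) == 1L)
    for (r in names(.PKA$positive))
      contrib[r] <- 1 / (1 + 10^(pH - .PKA$positive[[r]]))
    for (r in names(.PKA$negative))
      contrib[r] <- -1 / (1 + 10^(.PKA$negative[[r]] - pH))
  }
  if (!is.null(overrides)) {
    stopifnot(is.numeric(overrides), !is.null(names(overrides)))
    bad <- setdiff(names(overrides), .AA20)
    if (length(bad)) stop(sprintf("unknown residue(s) in overrides: %s",
                                  paste(bad, collapse = ", ")), call. = FALSE)
    contrib[names(overrides)] <- overrides
  }
  n_term <- if (is.null(pH)) 1 else 1 / (1 + 10^(pH - .PKA$n_term))
  c_term <- if (is.null(pH)) -1 else -1 / (1 + 10^(.PKA$c_term - pH))
  structure(contrib, termini = isTRUE(termini), n_term = n_term,
            c_term = c_term, class = "charge_model")
}

#' Net charge of peptide sequences
#'
#' Sums the model's per-residue contributions over each sequence. With the
#' default model this is `(#K + #R) - (#D + #E)`, an integer in elementary
#' charge units.
#'
#' @param sequence Character vector of peptide sequences (standard letters
#'   only; a non-standard letter raises an error naming it).
#' @param model A [charge_model()].
#' @return Numeric vector of net charges (integer-valued under the default
#'   model).
#' @examples
#' net_charge(c("KLWCKSSQVPQSR", "DDEEK"))  # +3, -3
#' @export
net_charge <- function(sequence, model = charge_model()) {
  stopifnot(is.character(sequence), inherits(model, "charge_model"))
  vapply(sequence, function(s) {
    .validate_sequence(s)
    chars <- strsplit(s, "", fixed = TRUE)[[1L]]
    z <- sum(unclass(model)[chars])
    if (isTRUE(attr(model, "termini")))
      z <- z + attr(model, "n_term") + attr(model, "c_term")
    z
  }, numeric(1L), USE.NAMES = FALSE)
}

#' Annotate a peptide library with net charges
#'
#' @param library A peptide library from [enumerate_windows()] (or any data
#'   frame with `peptide_id` and `sequence`).
#' @param model A [charge_model()].
#' @return A data frame `(peptide_id, sequence, length, net_charge)`, one row
#'   per window, input order preserved. Errors from [net_charge()] are
#'   re-raised naming the offending `peptide_id`.
#' @export
annotate_charges <- function(library, model = charge_model()) {
  stopifnot(is.data.frame(library), all(c("peptide_id", "sequence") %in% names(library)))
  z <- tryCatch(
    net_charge(library$sequence, model),
    error = function(e) {
      # re-run one by one to name the failing peptide
      for (i in seq_len(nrow(library))) {
        ok <- tryCatch({ net_charge(library$sequence[i], model); TRUE },
                       error = function(e2) e2)
        if (!isTRUE(ok)) stop(sprintf("peptide '%s': %s", library$peptide_id[i],
                                      conditionMessage(ok)), call. = FALSE)
      }
      stop(e)
    }
  )
  data.frame(
    peptide_id = library$peptide_id, sequence = library$sequence,
    length = nchar(library$sequence), net_charge = z, stringsAsFactors = FALSE
  )
}

#' Tabulate a library's net-charge distribution
#'
#' @param charges A data frame with a `net_charge` column (as from
#'   [annotate_charges()]) or a numeric vector of charges.
#' @return A data frame `(charge, count)` sorted by charge ascending; counts
#'   sum to the number of inputs. Empty input yields an empty table.
#' @export
charge_distribution <- function(charges) {
  z <- if (is.data.frame(charges)) charges$net_charge else charges
  if (length(z) == 0L) return(data.frame(charge = numeric(), count = integer()))
  tab <- table(z)
  out <- data.frame(charge = as.numeric(names(tab)), count = as.integer(tab))
  out[order(out$charge), , drop = FALSE]
}
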