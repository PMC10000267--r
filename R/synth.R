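# Seeded synthetic-data generators: every input the pipeline consumes can be
# produced locally, so all stages are testable without external predictors,
# plate readers or mass spectrometers. All generators are deterministic given
# (parameters, seed); one global seed fans out to independent per-generator
# substreams, so adding a generator never perturbs existing fixtures.

# Derive a generator-specific sub-seed from a global seed and a tag, keeping
# the result inside the 32-bit integer range.
.derive_seed <- function(seed, tag) {
  if (is.null(seed)) return(NULL)
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 48271 + h * 7919) %% 2147483562 + 1)
}

.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(seed, code)
}

#' Generate a random protein record
#'
#' Residues are drawn i.i.d. from `composition` (default: average vertebrate
#' residue frequencies, so synthetic libraries have realistic charge
#' spectra).
#'
#' @param length Protein length in residues (>= 1).
#' @param composition Optional named numeric over the 20 standard letters
#'   (relative weights; normalized internally). All-zero weights error.
#' @param seed Integer seed (generator substream); `NULL` for the current RNG
#'   state.
#' @param id Record id for the output.
#' @return A one-row data frame matching [read_fasta()] output.
#' @export
gen_protein <- function(length, composition = NULL, seed = NULL,
                        id = "synthetic_protein") {
  stopifnot(length >= 1L)
  if (is.null(composition)) composition <- .AA_COMPOSITION
  stopifnot(is.numeric(composition), !is.null(names(composition)))
  bad <- setdiff(names(composition), .AA20)
  if (length(bad)) stop(sprintf("unknown residue '%s' in composition", bad[1L]),
                        call. = FALSE)
  w <- setNames(numeric(20L), .AA20)
  w[names(composition)] <- composition
  if (any(w < 0) || sum(w) <= 0) stop("degenerate composition", call. = FALSE)
  seqstr <- .with_seed(.derive_seed(seed, "gen_protein"),
                       paste(sample(.AA20, length, replace = TRUE, prob = w / sum(w)),
                             collapse = ""))
  data.frame(id = id, description = "synthetic random protein",
             sequence = seqstr, length = nchar(seqstr), stringsAsFactors = FALSE)
}

#' Generate a predictor score table with planted truth
#'
#' A hidden "true ACP" label is planted for each peptide at `base_rate`; true
#' ACPs draw a latent probability from `Beta(acp_shape)` (default Beta(8, 2),
#' concentrated high) and the rest from `Beta(non_shape)` (default Beta(2, 8),
#' concentrated low), mimicking the bimodal probability spread real ACP
#' classifiers produce. Each predictor observes the latent probability through
#' independent logit-scale Gaussian noise. Truth labels are returned
#' separately for evaluation.
#'
#' @param library Peptide library data frame (`peptide_id` required).
#' @param base_rate Fraction of peptides planted as true ACPs (default 0.1).
#' @param acp_shape,non_shape Length-2 Beta shape parameters for the two
#'   label classes.
#' @param noise_sd Per-predictor noise SD on the logit scale (default 0.5).
#' @param predictors Predictor (column) names; length >= 1.
#' @param acp_point,non_point Optional constants replacing the Beta draws
#'   (degenerate point-mass distributions for noiseless checks).
#' @param seed Integer seed; `NULL` for the current RNG state.
#' @return A list with `scores` (wide data frame: `peptide_id` + one column
#'   per predictor) and `truth` (`peptide_id`, `is_acp`).
#' @export
gen_score_table <- function(library, base_rate = 0.1, acp_shape = c(8, 2),
                            non_shape = c(2, 8), noise_sd = 0.5,
                            predictors = c("predA", "predB", "predC"),
                            acp_point = NULL, non_point = NULL, seed = NULL) {
  stopifnot(is.data.frame(library), "peptide_id" %in% names(library),
            nrow(library) >= 1L, base_rate >= 0, base_rate <= 1,
            all(acp_shape > 0), all(non_shape > 0), noise_sd >= 0,
            length(predictors) >= 1L)
  n <- nrow(library)
  .with_seed(.derive_seed(seed, "gen_score_table"), {
    is_acp <- runif(n) < base_rate
    latent <- numeric(n)
    latent[is_acp] <- if (is.null(acp_point))
      rbeta(sum(is_acp), acp_shape[1L], acp_shape[2L]) else acp_point
    latent[!is_acp] <- if (is.null(non_point))
      rbeta(sum(!is_acp), non_shape[1L], non_shape[2L]) else non_point
    scores <- data.frame(peptide_id = library$peptide_id, stringsAsFactors = FALSE)
    for (pr in predictors) {
      if (noise_sd == 0) {
        p <- latent
      } else {
        lat <- pmin(pmax(latent, 1e-12), 1 - 1e-12)  # keep logit finite
        p <- plogis(qlogis(lat) + rnorm(n, sd = noise_sd))
      }
      scores[[pr]] <- pmin(pmax(p, 0), 1)
    }
    list(scores = scores,
         truth = data.frame(peptide_id = library$peptide_id, is_acp = is_acp,
                            stringsAsFactors = FALSE))
  })
}

#' Generate random structure annotations
#'
#' Each peptide receives a helix-containing label with probability
#' `helix_fraction` and a coil/sheet label otherwise, in the dash-joined
#' format [parse_structure_table()] reads.
#'
#' @param library Peptide library data frame (`peptide_id`).
#' @param helix_fraction Fraction of helix-containing annotations, in
#'   \[0, 1\].
#' @param seed Integer seed.
#' @return A data frame `(peptide_id, structure_label)`.
#' @export
gen_structure_annotations <- function(library, helix_fraction = 0.8, seed = NULL) {
  stopifnot(is.data.frame(library), "peptide_id" %in% names(library),
            helix_fraction >= 0, helix_fraction <= 1)
  helixy <- c("helix", "helix-coil", "coil-helix", "coil-helix-coil")
  coily <- c("coil", "sheet", "coil-sheet", "sheet-coil")
  n <- nrow(library)
  .with_seed(.derive_seed(seed, "gen_structure_annotations"), {
    lab <- ifelse(runif(n) < helix_fraction,
                  sample(helixy, n, replace = TRUE),
                  sample(coily, n, replace = TRUE))
    data.frame(peptide_id = library$peptide_id, structure_label = lab,
               stringsAsFactors = FALSE)
  })
}

#' Generate a synthetic absorbance plate
#'
#' Builds a long-format plate (`well`, `condition`, `absorbance`) from
#' specified true percent values plus Gaussian read noise, so the viability
#' and hemolysis formulas can be round-trip tested. Viability plates carry
#' `media` and `untreated` reference conditions (true absorbances 0.05 and
#' 1.05); hemolysis plates carry `blank` (0.10) and `positive` (2.10).
#'
#' @param type `"viability"` or `"hemolysis"`.
#' @param true_percent Named numeric: true percent viability / hemolysis per
#'   sample condition, e.g. `c(treated = 60)`.
#' @param n_replicates Wells per condition (default 3).
#' @param noise_sd Absorbance read-noise SD (default 0.01; 0 gives an exact
#'   round trip).
#' @param seed Integer seed.
#' @return A long data frame `(well, condition, absorbance)`.
#' @export
gen_assay_plate <- function(type = c("viability", "hemolysis"),
                            true_percent = c(treated = 60), n_replicates = 3L,
                            noise_sd = 0.01, seed = NULL) {
  type <- match.arg(type)
  stopifnot(is.numeric(true_percent), !is.null(names(true_percent)),
            n_replicates >= 1L, noise_sd >= 0)
  refs <- if (type == "viability") c(media = 0.05, untreated = 1.05)
          else c(blank = 0.10, positive = 2.10)
  lo <- refs[[1L]]
  hi <- refs[[2L]]
  truth <- c(refs, lo + true_percent / 100 * (hi - lo))
  names(truth) <- c(names(refs), names(true_percent))
  .with_seed(.derive_seed(seed, "gen_assay_plate"), {
    cond <- rep(names(truth), each = n_replicates)
    abs_true <- rep(unname(truth), each = n_replicates)
    data.frame(
      well = sprintf("%s%02d", LETTERS[(seq_along(cond) - 1L) %/% 12L + 1L],
                     (seq_along(cond) - 1L) %% 12L + 1L),
      condition = cond,
      absorbance = abs_true + rnorm(length(cond), sd = noise_sd),
      stringsAsFactors = FALSE
    )
  })
}

#' Generate a synthetic proteomics intensity matrix
#'
#' Emulates the statistical shape of a two-group SWATH/DIA design with
#' biological and technical replication: on the log2 scale each cell is
#' `protein baseline + group effect (DE proteins only) + biological-replicate
#' effect + technical noise`, exponentiated to the linear intensity scale,
#' with cells masked missing completely at random. The planted per-protein
#' log2 effect (sign randomized) is returned as a truth table.
#'
#' @param n_proteins Number of proteins (default 200).
#' @param de_fraction Fraction of proteins with a planted effect (default
#'   0.1).
#' @param log2_effect Magnitude of the planted |log2 fold-change| (default 1).
#' @param bio_sd Between-biological-replicate SD on the log2 scale (default
#'   0.3).
#' @param tech_sd Technical (within-bio) SD on the log2 scale (default 0.2).
#' @param missing_rate Fraction of cells masked missing (default 0.05).
#' @param n_bio Biological replicates per group (default 3).
#' @param n_tech Technical replicates per biological sample (default 3).
#' @param baseline_mean,baseline_sd Per-protein baseline log2 abundance
#'   distribution (defaults 20 and 2, typical DIA peak-area scale).
#' @param seed Integer seed.
#' @return A list with `intensities` (linear-scale matrix with NAs),
#'   `annotations` (`run_id`, `group`, `bio_rep`, `tech_rep`), and `truth`
#'   (`protein_id`, `log2fc_true`).
#' @export
gen_proteome <- function(n_proteins = 200L, de_fraction = 0.1, log2_effect = 1,
                         bio_sd = 0.3, tech_sd = 0.2, missing_rate = 0.05,
                         n_bio = 3L, n_tech = 3L, baseline_mean = 20,
                         baseline_sd = 2, seed = NULL) {
  stopifnot(n_proteins >= 1L, de_fraction >= 0, de_fraction <= 1,
            bio_sd >= 0, tech_sd >= 0, missing_rate >= 0, missing_rate <= 1,
            n_bio >= 1L, n_tech >= 1L)
  groups <- c("treated", "untreated")
  ann <- expand.grid(tech_rep = seq_len(n_tech), bio_rep = seq_len(n_bio),
                     group = groups, stringsAsFactors = FALSE)
  ann <- ann[c("group", "bio_rep", "tech_rep")]
  ann$run_id <- sprintf("%s_b%d_t%d", ann$group, ann$bio_rep, ann$tech_rep)
  ann <- ann[c("run_id", "group", "bio_rep", "tech_rep")]
  n_runs <- nrow(ann)

  .with_seed(.derive_seed(seed, "gen_proteome"), {
    protein_id <- sprintf("PROT%04d", seq_len(n_proteins))
    n_de <- round(n_proteins * de_fraction)
    delta <- numeric(n_proteins)
    if (n_de > 0) {
      idx <- sample.int(n_proteins, n_de)
      delta[idx] <- log2_effect * sample(c(-1, 1), n_de, replace = TRUE)
    }
    baseline <- rnorm(n_proteins, baseline_mean, baseline_sd)
    # biological-replicate effects: one per (protein, group, bio)
    x <- matrix(NA_real_, n_proteins, n_runs,
                dimnames = list(protein_id, ann$run_id))
    for (g in groups) {
      for (b in seq_len(n_bio)) {
        bio_eff <- rnorm(n_proteins, 0, bio_sd)
        cols <- which(ann$group == g & ann$bio_rep == b)
        for (j in cols) {
          x[, j] <- baseline + (g == "treated") * delta + bio_eff +
            rnorm(n_proteins, 0, tech_sd)
        }
      }
    }
    intensities <- 2^x
    if (missing_rate > 0) {
      mask <- matrix(runif(length(intensities)) < missing_rate,
                     nrow(intensities))
      intensities[mask] <- NA_real_
    }
    list(intensities = intensities, annotations = ann,
         truth = data.frame(protein_id = protein_id, log2fc_true = delta,
                            stringsAsFactors = FALSE))
  })
}
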