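---
title: "In silico anticancer peptide screening with acpforge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{In silico anticancer peptide screening with acpforge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acpforge)
```

## The problem and the pipeline

Anticancer peptides (ACPs) are short (roughly 5–25 residue) sequences with
cytotoxic activity against cancer cells. Screening them experimentally is slow
and expensive, so a common strategy is to enumerate every candidate a source
protein can yield, score the candidates cheaply in silico, and synthesize only
a handful. `acpforge` implements that strategy as a chain of small, testable
stages:

1. **Library generation** — every contiguous window of the source protein in a
   length range (default 5–25), stepping one residue from the N- to the
   C-terminus. For a protein of length $N$ and step 1 the library holds
   $\sum_{L=L_{\min}}^{\min(L_{\max},N)} (N - L + 1)$ windows; a 142-residue
   protein gives 2688 at the defaults. Coordinates are 1-based and inclusive,
   matching how protein residues are conventionally numbered, and duplicate
   sequences arising from internal repeats are *kept* (the library is a window
   list; `distinct_sequences()` exposes any collisions rather than silently
   removing them).
2. **Physicochemistry** — the net charge of each window. The default model
   counts K/R as $+1$, D/E as $-1$, histidine and the termini as neutral:
   the unique simple convention consistent with the published charges of the
   worked-example peptides (four +3 candidates and a +7 control). Because
   external predictors use unpublished, sometimes pH-aware conventions, the
   model is configurable: per-residue overrides, terminal charges, or a full
   Henderson–Hasselbalch mode (`charge_model(pH = 7)`).
3. **Structure** — per-peptide secondary-structure labels
   (`"coil-helix-coil"`-style strings from an external predictor). The filter
   is *contains at least one helix segment*, not *fully helical*: selected
   real candidates routinely carry mixed labels. For synthetic runs a
   deterministic Chou–Fasman-style surrogate annotator is included; it is a
   stand-in so pipelines run without a web server, carries no accuracy claim,
   and is deliberately excluded from every check against published values.
4. **Consensus scoring** — the geometric mean of $k \ge 1$ classifier
   probabilities, $(\prod_i p_i)^{1/k}$. The geometric mean penalizes
   disagreement (one sceptical predictor drags the score down harder than an
   arithmetic mean would) and any zero annihilates it — both desirable for a
   "synthesize only what everyone likes" shortlist. The ACP call threshold is
   0.5, inclusive; no published value pins it tighter (the printed table jumps
   from 0.319 → non-ACP to 0.724 → ACP), so it is a configurable default, not
   an estimate. Peptides missing any predictor are excluded rather than
   averaged over fewer predictors: a $k{-}1$-mean is not comparable to a
   $k$-mean.
5. **Screening** — filters are applied charge → structure → consensus (so the
   expensive external structure annotation may legitimately cover only the
   charge-passing subset), survivors are ranked by consensus descending, and
   redundant sequences are collapsed greedily from the top: a candidate whose
   sequence contains (or is contained in) an already-kept candidate is marked
   `redundant` with its representative. An alternative coordinate-overlap rule
   (`overlap_fraction`) is available for libraries where near-duplicates are
   shifted rather than nested. Ties in consensus break deterministically —
   higher charge, then shorter length, then lexicographic sequence — so
   reports are reproducible.
6. **Assays** — the downstream quantification formulas:
   $\%\text{viability} = 100\,(A_{570}^{treated} - A_{570}^{media}) /
   (A_{570}^{untreated} - A_{570}^{media})$,
   $\%\text{hemolysis} = 100\,(A_{415}^{sample} - A_{415}^{blank}) /
   (A_{415}^{positive} - A_{415}^{blank})$, autophagy activity as the
   treated/untreated ratio of nucleus-normalized fluorescence, and an IC50
   read from the mean dose–response curve by piecewise-linear interpolation.
7. **Differential expression** — a label-free SWATH/DIA comparison starting
   from an extracted protein × run intensity matrix: log2 transform, per-run
   normalization, per-protein median imputation, per-protein two-sample
   t-tests, and an up/down/ns gate at fold-change ≥ 2 (inclusive) with
   p < 0.05 (strict).

A seeded generator family (`gen_protein()`, `gen_score_table()`,
`gen_structure_annotations()`, `gen_assay_plate()`, `gen_proteome()`) produces
synthetic inputs for every stage.

## A worked example

The package ships a five-peptide candidate table (four alpha-lactalbumin
windows plus a bovine milk-derived positive-control ACP) with probabilities
from three external classifiers:

```{r example}
tab <- read.delim(system.file("extdata", "ala_candidates.tsv",
                              package = "acpforge"), comment.char = "#")
sc <- score_consensus(tab[c("peptide_id", "acpred_fl", "anticp2", "macppred")])
data.frame(id = sc$peptide_id, charge = net_charge(tab$sequence),
           consensus = round_half_up(sc$consensus, 3), call = sc$call)
```

```{r screen}
cand <- tab[tab$role == "candidate", ]
lib <- data.frame(peptide_id = cand$peptide_id, sequence = cand$sequence,
                  length = nchar(cand$sequence))
res <- screen_candidates(lib, annotate_charges(lib),
                         cand[c("peptide_id", "structure_label")],
                         score_consensus(cand[c("peptide_id", "acpred_fl",
                                                "anticp2", "macppred")]))
res$candidates[c("peptide_id", "rank", "net_charge", "consensus",
                 "status", "status_detail")]
```

ALA-A3 (ALA-A1 plus one residue) collapses onto ALA-A1 and ALA-A4 (a
superstring of ALA-A2) is removed by the structure filter before redundancy is
even assessed; the shortlist is ALA-A1 and ALA-A2.

### Precision of the consensus worked examples

The shipped classifier probabilities are printed to 3 decimals. Rounding each
input by up to $5\times10^{-4}$ propagates an error of up to about $10^{-3}$
into the geometric mean, so recomputed consensus values can differ from
published ones by one unit in the third decimal; the tests therefore assert
agreement to within 0.001 rather than exact 3-dp equality (three of the five
worked examples do reproduce exactly).

## Numerical and design choices

* **IC50 by interpolation, not 4PL.** Replicates are averaged per dose, the
  first crossing of 50% is interpolated linearly between the bracketing
  doses, and an exact 50% reading returns its dose. Curves that never cross
  are *censored* at the tested range ("greater than the maximum dose") —
  never extrapolated. This is assumption-free and monotone: uniformly
  lowering viability never raises the estimate.
* **Out-of-range assay values are preserved.** Viability above 100% or below
  0% is reported as-is with a warning, keeping QC problems visible.
* **Normalization surrogate.** The DE stage's default normalization subtracts
  each run's median log2 intensity and restores the global median; a
  generalized-log (arsinh-type, robust per-run scale) option is available.
  Both are documented surrogates for variance-stabilizing normalization,
  isolated behind `de_config()` so an external VSN fit can be swapped in.
* **Order: normalize, then impute.** Imputed values then inherit the
  normalized scale. Imputation is the protein's median over observed runs and
  is *refused* (protein flagged, cells left `NA`) when a protein is absent
  from an entire group — a median drawn wholly from the other group would
  manufacture a fold-change.
* **Technical replicates.** The default `as_samples` policy matches designs
  that report n = bio × tech per group; `collapse_mean` averages technical
  replicates first. Treating technical replicates as samples pseudo-replicates
  the biological unit and makes t-tests anticonservative whenever biological
  variance is non-zero — the package exposes both policies precisely so that
  sensitivity can be checked.
* **No multiple-testing gate by default.** The up/down gate is the plain
  fold-change ≥ 2 / p < 0.05 rule used in the comparative reports this stage
  mirrors; a Benjamini–Hochberg `q_value` column is always exported alongside
  for transparency.
* **Fold-change as `2^Δmean(log2)`**, consistent with the log-scale pipeline,
  not a ratio of raw means.
* **Degenerate inputs.** Zero probabilities are legal (consensus 0, no epsilon
  flooring); a zero t-test variance yields `p = NA` and status `ns`; constant
  heatmap rows z-score to zeros, not `NaN`.

## What the generators emulate — and what they do not

* `gen_protein()` draws residues i.i.d. from an average vertebrate
  composition: realistic *marginal* charge spectra, but no domain structure,
  repeats, or local hydrophobic patterning.
* `gen_score_table()` plants a hidden ACP label at a configurable base rate
  (default 0.1) and draws latent probabilities from Beta(8, 2) for true ACPs
  and Beta(2, 8) otherwise, observed through logit-normal predictor noise
  (SD 0.5). This mimics the bimodal spread real classifier panels produce,
  but the three synthetic predictors are conditionally independent —
  real classifiers share training data and features, so real consensus
  scores are more correlated and the synthetic screening-precision results
  are optimistic.
* `gen_proteome()` follows a 2-group × 3-biological × 3-technical design on
  the log2 scale: protein baseline ~ N(20, 2), biological-replicate effects
  (SD 0.3), technical noise (SD 0.2), sign-randomized planted effects, and
  missing-completely-at-random dropouts. Real DIA missingness is
  intensity-dependent (left-censored), so imputation behaves better here than
  it would on real data; passing tests demonstrate the machinery, not
  field performance.
* `gen_assay_plate()` adds Gaussian read noise to true absorbances implied by
  specified percent values, with fixed reference levels (media 0.05 /
  untreated 1.05; blank 0.10 / positive 2.10). No edge effects, drift, or
  pipetting error.

All generators are bit-reproducible given a seed; one global seed fans out to
independent per-generator substreams, so adding a generator never perturbs
existing fixtures.

## Problem sizes used in the test suite

The statistical property tests run at sizes chosen to make their Monte-Carlo
error small relative to the asserted bands: type-I control of the DE stage on
a 2000-protein null matrix of independent runs (technical noise only, so the
nominal 5% level is actually the correct reference — see the
pseudo-replication note above); log2-fold-change recovery on 200 proteins
with 100 carrying a planted effect of 1 (Monte-Carlo SE of the mean recovered
effect ≈ 0.026 against a ±0.1 band); and screening precision on a full
2688-window synthetic library.

## Known limitations

* The charge census of a real protein library depends on the (often
  unpublished) convention of the external predictors; with the default model
  the alpha-lactalbumin precursor's library spans charges −6..+3, but the
  exact count of +3 windows is convention-sensitive and the package makes no
  attempt to reverse-engineer any particular server.
* The surrogate structure annotator is a propensity heuristic for plumbing
  tests only.
* The DE stage starts from an extracted intensity matrix; peptide-to-protein
  rollup, FDR at identification level, and acquisition-side processing are
  upstream of this package.
* No pathway enrichment: the DE stage ends at the ranked protein list.
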