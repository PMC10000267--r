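# acpforge

In silico screening of anticancer peptide (ACP) candidates from a source
protein, in R.

Experimental ACP discovery means synthesizing and assaying peptides one at a
time; `acpforge` implements the computational front end that makes that
affordable, plus the quantification used to validate the survivors. It is
aimed at peptide/drug-discovery groups who run external ACP classifiers and
structure predictors and need the surrounding pipeline to be reproducible:

* **Library generation** — every contiguous window of a protein in a length
  range (default 5–25 aa, step 1). For a protein of length *N* the library
  holds Σ<sub>L</sub> (N − L + 1) windows; 142 residues → 2688 peptides.
* **Net charge** — per-window charge under a configurable residue model
  (default: K/R +1, D/E −1, H and termini neutral; Henderson–Hasselbalch pH
  mode available) and library-wide charge distributions.
* **Structure** — dash-joined secondary-structure labels from an external
  predictor (`"coil-helix-coil"`), a *contains-helix* filter, and a
  deterministic propensity-based surrogate annotator for synthetic runs.
* **Consensus scoring** — the geometric mean of k classifier probabilities,
  consensus = (p₁ ⋯ p<sub>k</sub>)<sup>1/k</sup>, with an inclusive 0.5
  ACP-call threshold.
* **Screening** — filter (charge ≥ 3, helix-containing, consensus ≥ 0.5),
  rank by consensus, collapse substring-redundant candidates greedily from
  the top, and emit a top-k shortlist; controls bypass filters but never
  enter the shortlist.
* **Assays** — % viability and % hemolysis from plate absorbances, autophagy
  activity fold-change, and IC50 by linear interpolation with censoring at
  the tested dose range.
* **Differential expression** — label-free SWATH/DIA comparison from a
  protein × run intensity matrix: log2, per-run median normalization,
  per-protein median imputation, Welch t-tests, and an up/down gate at
  fold-change ≥ 2 with p < 0.05, plus volcano/heatmap exports.
* **Synthetic data** — seeded generators for proteins, planted-truth score
  tables, structure annotations, assay plates, and proteomics matrices, so
  every stage is testable offline.

## Worked example

The package ships a five-peptide candidate table (four alpha-lactalbumin
windows plus the bovine milk-derived control ACP BMP-S6) with probabilities
from three external classifiers (ACPred-FL, AntiCP2.0, mACPpred):

```r
library(acpforge)

fa  <- read_fasta(system.file("extdata", "P00709.fasta", package = "acpforge"))
lib <- enumerate_windows(fa)          # 5-25-mers of the 142-aa precursor
nrow(lib)
#> [1] 2688

tab <- read.delim(system.file("extdata", "ala_candidates.tsv",
                              package = "acpforge"), comment.char = "#")
sc <- score_consensus(tab[c("peptide_id", "acpred_fl", "anticp2", "macppred")])
data.frame(id = sc$peptide_id, charge = net_charge(tab$sequence),
           consensus = round_half_up(sc$consensus, 3), call = sc$call)
#>       id charge consensus    call
#> 1 ALA-A1      3     0.837     ACP
#> 2 ALA-A2      3     0.724     ACP
#> 3 ALA-A3      3     0.827     ACP
#> 4 ALA-A4      3     0.319 non-ACP
#> 5 BMP-S6      7     0.842     ACP

cand <- tab[tab$role == "candidate", ]
libx <- data.frame(peptide_id = cand$peptide_id, sequence = cand$sequence,
                   length = nchar(cand$sequence))
res <- screen_candidates(libx, annotate_charges(libx),
                         cand[c("peptide_id", "structure_label")],
                         score_consensus(cand[c("peptide_id", "acpred_fl",
                                                "anticp2", "macppred")]))
res$candidates[c("peptide_id", "rank", "status", "status_detail")]
#>   peptide_id rank       status status_detail
#> 1     ALA-A1    1     selected
#> 2     ALA-A3   NA    redundant        ALA-A1
#> 3     ALA-A2    2     selected
#> 4     ALA-A4   NA filtered_out require_helix
res$shortlist$peptide_id
#> [1] "ALA-A1" "ALA-A2"
```

Reading the output: all four candidates carry the required +3 charge; ALA-A4
(label `coil`) fails the helix filter; ALA-A3 — ALA-A1 plus one C-terminal
residue — is collapsed onto ALA-A1 as sequence-redundant; the shortlist of
non-redundant, helix-containing, high-consensus peptides is ALA-A1 and
ALA-A2. A consensus of 0.837 means the three classifiers jointly place the
peptide well above the 0.5 ACP midpoint (the geometric mean punishes any
single sceptical predictor).

The differential-expression stage on the shipped SWATH example summary:

```r
de <- read.delim(system.file("extdata", "a549_swath_de.tsv",
                             package = "acpforge"), comment.char = "#")
summarize_de(filter_de(de))
#>   n_up n_down n_total_de n_tested
#> 1   12     26         38       38
```

A thin command-line wrapper over the same functions lives at
`inst/cli/acp-forge.R` (subcommands `libgen`, `charges`, `consensus`,
`screen`, `de`, `synth`).

See `vignettes/acp-screening.Rmd` for the model assumptions, numerical
choices, and what the synthetic generators do and do not emulate.

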