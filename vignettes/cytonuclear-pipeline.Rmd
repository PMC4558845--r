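---
title: "Methods: profiling, placement, rates and reassignment scans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: profiling, placement, rates and reassignment scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytonuc)
```

This vignette is the package's own account of its models and the choices
behind them: what each stage assumes, which tunable parameters matter, what
the synthetic generators do and do not emulate, and where the design was
genuinely open.

## The scientific setting

Mitochondrial translation depends on two genomes. The tRNAs are (mostly)
mitochondrially encoded; the aminoacyl-tRNA synthetases (aaRS) that charge
them are nuclear-encoded and imported. When a lineage loses an mt-tRNA, the
cell must import a cytosolic tRNA, and the dedicated mitochondrial aaRS
becomes dispensable; conversely, changes in a fast-evolving mt-tRNA might
drag its aaRS along through compensatory substitutions. Distinguishing those
scenarios requires (i) reliable presence/absence calls for aaRS families in
often-fragmentary assemblies, (ii) comparable substitution-rate estimates
for aaRS and mt-tRNAs, (iii) an explicit statistical model relating them,
and (iv) a way to detect the codon-reassignment events that accompany
rewiring of mitochondrial decoding.

## Profile search

`build_profile()` turns a curated alignment into a position-specific model:
match columns are those with gap fraction below `gap_threshold` (default
0.5); emissions are Henikoff position-based weighted counts plus
background-proportional pseudocounts with total mass 1 per column;
transitions come from weighted state-path counts with Laplace smoothing.
The search model is a *lean* local profile HMM — match/insert/delete core,
uniform local entry and exit, background-emitting flanks — deliberately not
a byte-compatible reimplementation of any published search tool. The
procedure needs a calibrated profile search, not a particular tool's exact
scores. Insert→delete and delete→insert transitions are dropped (the usual
Plan7 simplification); an insert run that re-enters on a delete state is
counted as insert→match and absorbed by smoothing.

Scores are log2 odds against the background; the forward algorithm (all
local alignments) gives the reported bit score, the Viterbi traceback gives
the residue-to-column map used to project hits into reference coordinates.
By construction forward ≥ Viterbi, which the tests assert.

**E-values.** Analytic extreme-value parameters are not available for
arbitrary profile parameters, so `calibrate_evalues()` scores `n_decoys`
(default 200) i.i.d. background-sampled decoys and fits a Gumbel law by
maximum likelihood; `E(S) = N_db · (1 − GumbelCDF(S))`. Calibration is
seeded, making every presence/absence call reproducible. The default search
gate is `e_cutoff = 1e-5`, the pipeline's canonical threshold. Within a
search, one best-scoring hit is kept per target id (how overlapping
fragmentary hits of one locus were deduplicated historically is unstated;
best-per-target is our rule). Ordering is deterministic everywhere:
ascending E-value, then descending bit score, then lexicographic id.

## Placement

`place_query()` attaches a query row (reference coordinates, gaps = missing
data) to every edge of the reference tree at the **edge midpoint**, with a
new pendant branch as the only free parameter (bounded Brent search on
[1e-8, 5], tolerance 1e-6), under WAG with discrete-Γ rates (default shape
α = 1, 4 categories; α is configuration, not estimated, since tree
inference — where α would normally be fitted — is outside this package's
scope). Likelihoods use the standard pruning recursion with the reference
partials precomputed once per family from both sides of every edge, so a
pendant evaluation costs one 20×20 matrix exponential per category. The
reported `like_weight_ratio` is the normalized likelihood weight of the best
edge across all edges.

Restricting the attachment point to the midpoint keeps the optimization
one-dimensional and oracle-checkable; `naive_attach_loglik()` re-grafts the
query with `ape::bind.tree` and recomputes the full-tree likelihood by an
independent plain recursion, and the tests require agreement of the best
edge and reproduction of its log-likelihood to 1e-6.

**Classification.** "Placed inside a eukaryotic lineage" is made precise as:
the edge's subtended tip set is purely eukaryote-annotated, checked from
both sides of the edge so that unrooted semantics are respected. The stem
edge of a maximal eukaryote-only clade — including the branch separating the
domains — counts as inside, but is flagged low-confidence: the phrase is
genuinely ambiguous there, and the inclusive rule preserves information
while marking it. Mixed subtrees on both sides are classified prokaryote and
not retained. The same rule over mitochondrial/cytosolic labels of the
subtended eukaryote tips yields the lineage call; mixtures give
"ambiguous". An earlier external homology double-check (BLAST against a
reference protein database) is deliberately replaced by the placement
classification itself, removing a network dependency.

**Two rounds.** Round 2 rebuilds the profile from the eukaryote-only
subalignment *in the same column coordinate system* (rows dropped, columns
kept), so placements from both rounds live on the same reference. The same
E-value cutoff is used in both rounds (whether the original procedure varied
it is unstated). Placements serialize to jplace v3 with 0-based edge numbers
in curly braces.

## Distances

`k80_distance()` implements the closed-form ML estimate from transition and
transversion proportions; a non-positive logarithm argument sets a
saturation flag (infinite distance) rather than raising an error.
`wag_ml_distance()` maximizes the reversible pairwise likelihood
Σ ln(π_a P(t)_ab) by bounded scalar search on [1e-8, 50], tolerance 1e-6.
Both are **rate-homogeneous**: pairwise "WAG distances" and "K80 distances"
mean the plain models; Γ heterogeneity is used only in placement
likelihoods. P(t) comes from the symmetric eigendecomposition of
π^{1/2}Qπ^{−1/2}, exact for a reversible generator and cheap to re-evaluate.

Columns with a gap or ambiguity in *either* sequence of a pair are excluded
pairwise, not listwise — it maximizes usable sites per pair and matches
common pairwise-deletion practice. `mean_outgroup_distance()` averages
outgroup→ingroup pairwise distances into a per-family rate; saturated pairs
are excluded with a warning (not truncated to a cap, which would bias the
downstream regression), and averaging is over sequences (a species
contributing several copies contributes each; averaging over species first
is a documented alternative). The WAG constants ship as a plain-text
PAML-layout file (`inst/extdata/wag.dat`).

## The compensatory-substitution model

`fit_compensatory_model()` fits, by ordinary least squares,

$$Y_i = \beta_0 + \beta_1 \delta_{mt} + \beta_2 X_i + \beta_3 X_i \delta_{mt} + \epsilon_i$$

and its two nested cases (β₃ = 0; β₃ = β₂ = 0), with homoskedastic
two-sided t tests and no multiple-testing correction — mirroring the source
analysis, which used none. Note that a cytosolic aaRS row still carries the
mt-tRNA rate of its specificity as X: that is literally the comparison being
made (cy-aaRS do not bind mt-tRNAs; the cy line is the control for shared
specificity constraints). "Most parsimonious model" is operationalized as
backward selection by nested F-tests at α = 0.05 from the full model
(`select_parsimonious_model()`), reported alongside all three fits.
`mt_cy_rate_correlation()` gives the Pearson correlation between mt- and
cy-aaRS rates across specificities having both.

## Codon-reassignment scan

The focal CDS is translated with the scanned codon masked to `X` (mirroring
a genome whose code is unknown at that codon, and avoiding biasing the
alignment), and mapped through the gaps of its row in the reference
alignment. A column is *conserved* when its reference-residue Shannon
entropy is below `entropy_max` and its gap fraction below `gap_max`;
defaults 1.0 and 0.20. Entropy is computed in **nats** — threshold 1.0
matching the conventional filter literally — with a base option because the
convention's base is not universally stated. Gaps are excluded from entropy
and counted only in the gap fraction. "Corresponds to amino acid *a*" is
operationalized per column as the plurality reference residue (ties split
fractionally), aggregated as the fraction of retained columns; the reported
call is the argmax with its fraction. The default genetic code is NCBI
table 4, appropriate for non-bilaterian animal mtDNA, configurable per run.

## The synthetic world

The generators state one fixed world; their defaults are not tuned to tests:

* Reference families: 8 eukaryote + 6 prokaryote taxa as sister clades,
  coalescent shapes, branch lengths ~ Exponential(mean 0.15 subst/site),
  200 WAG-evolved columns; eukaryote tips split between mitochondrial and
  cytosolic paralog lineages.
* Databases: orthologs/contaminants evolved from random eukaryote/prokaryote
  tips with pendant 0.1; fragment lengths truncated-geometric with floor
  30 aa and mean 100 aa, emulating transcriptome fragments.
* Rate tables: X ~ Uniform(0.1, 0.6) (the range of realistic mt-tRNA K80
  rates), Gaussian noise σ = 0.05, paired mt/cy rows per specificity. The
  noise is *not* truncated at zero: a negative simulated Y is tolerated so
  OLS recovery of the generating coefficients stays unbiased; measured rate
  tables are validated as non-negative.
* Reassigned genomes: per-column conservation 0.95 controls entropy; 15% of
  positions carry the target codon, the planted fraction (default 0.8) of
  them with the planted residue as reference plurality; 5% reference gaps.
* One global seed expands into per-component child seeds through a fixed
  polynomial hash (`child_seed()`), so stages re-run independently.

What the generators do **not** emulate: indels within alignments (fragments
create terminal gaps only), alignment error, compositional heterogeneity
across lineages, rate variation across families, non-homologous
contaminants (simulated contaminants are homologous prokaryotic family
members — the *hard* case for the E-value gate, which is why the placement
filter carries the discrimination), or sequencing error. A green profiling
benchmark therefore establishes that the pipeline separates homologous
eukaryote fragments from homologous prokaryote fragments under the stated
fragment-length regime; short fragments near the information floor can
still place ambiguously, and occasionally a contaminant fragment lands
inside the eukaryote clade — the benchmark bounds that leakage at 5%, it
does not eliminate it.

## Numerical choices

* Matrix exponentials by symmetric eigendecomposition (real spectrum
  guaranteed by reversibility); no partial-likelihood rescaling, which is
  safe for the curated families this targets (tens of tips) but would
  underflow on trees orders of magnitude larger.
* Bounded Brent searches: pendant [1e-8, 5] tol 1e-6; pairwise distance
  [1e-8, 50] tol 1e-6. Identical sequences short-circuit to distance 0
  exactly, satisfying "zero iff identical".
* Ambiguity codes translate to `X` and enter likelihoods as missing data
  (partial vectors of one); `-` and `.` both read as gaps, `-` canonical on
  output; intervals are 0-based half-open; frames are {+1,+2,+3,−1,−2,−3}.
* Ties: search ordering as above; plurality ties split fractionally;
  likelihood-tied placement edges (the two rooted halves of one unrooted
  branch) are interchangeable and treated as agreement in validation.
* Six-frame ORF extraction is stop-to-stop with a 30-residue floor — how
  nucleotide data were originally translated for profile search is unstated,
  and explicit ORFs are the transparent stand-in.

## Limitations

Attachment-point optimization along an edge, multi-placement uncertainty
beyond the likelihood weight ratio, tree re-estimation, Γ-shape estimation,
other empirical matrices (LG, JTT), codon substitution models,
phylogenetically independent contrasts for the regression, and full
per-codon expected/observed tables for all 64 codons are all out of scope.
Applying the chain to published accessions requires network retrieval of
those sequences and curated alignments; every function in that path is the
same one exercised on the synthetic world here.
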