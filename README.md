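# cytonuc

Tools for studying **cytonuclear coevolution of mitochondrial tRNA
metabolism**: how nuclear-encoded aminoacyl-tRNA synthetases (aaRS) evolve
alongside the mitochondrially encoded tRNAs (mt-tRNAs) they service, and what
happens to the mitochondrial genetic code when pieces of that machinery are
lost or replaced.

The package is aimed at molecular evolutionists working with fragmentary
transcriptome or genome data from non-model eukaryotes, where homology search
alone cannot distinguish a genuine nuclear-encoded mitochondrial enzyme from
a bacterial contaminant. It implements four connected analyses:

1. **Two-round phylogenetic profiling.** Position-specific profile models
   (lean local profile HMMs with match/insert/delete states) are built from
   curated eukaryote+prokaryote alignments and used to search each species'
   proteome or six-frame-translated transcriptome with an E-value gate
   (default `1e-5`, seeded Gumbel calibration on background decoys). Passing
   fragments are aligned into reference coordinates and **placed by maximum
   likelihood** on a fixed annotated reference tree (WAG+Γ, pendant-branch
   optimization at each edge midpoint); only fragments placed inside a
   eukaryotic lineage are retained. Profiles are then rebuilt from the
   eukaryote-only subalignment and the search repeated, yielding
   presence/absence calls with mitochondrial/cytosolic lineage labels.
2. **Substitution-rate estimation.** Pairwise maximum-likelihood distances
   under WAG (amino acid, numerically maximized likelihood) and the Kimura
   two-parameter model (nucleotide, closed form
   `d = -1/2 ln(1-2P-Q) - 1/4 ln(1-2Q)`), averaged from an outgroup to a set
   of ingroup sequences to give per-family rates.
3. **The compensatory-substitution linear model.** With `Y_i` the aaRS rate
   of specificity *i*, `X_i` the mt-tRNA rate of the same specificity and
   `δ_mt` an indicator for mitochondrial aaRS,

   ```
   Y_i = β0 + β1·δ_mt + β2·X_i + β3·X_i·δ_mt + ε_i
   ```

   fitted by OLS, with nested F-tests of `β3 = 0` and `β3 = β2 = 0`
   (`β1`: rate elevation under relaxed selection; `β2`: shared-specificity
   coupling; `β3`: the compensatory-evolution interaction), plus the Pearson
   correlation between mt- and cy-aaRS rates of shared specificity.
4. **Codon-reassignment scanning.** A focal mitochondrial coding sequence is
   translated with the scanned codon masked, mapped through a reference
   amino-acid alignment, and each occurrence of the target codon at a
   *conserved position* (Shannon entropy < 1.0 nats, gap fraction < 20%) is
   asked which amino acid the reference plurality supports — e.g. a TGA→Ser
   or AUA→Ile reassignment call.

Everything is exercised against **seeded synthetic-data generators**
(sequence evolution along annotated trees, contaminated fragmentary
databases, rate tables drawn from the linear model, genomes with planted
reassignments) so the full chain is testable offline with known ground truth.

## Worked example

```r
library(cytonuc)

fam <- simulate_family(seed = 42)            # 8 eukaryote + 6 prokaryote taxa
eng <- placement_engine(fam$atree, fam$msa)  # WAG+Gamma placement likelihoods
prof <- calibrate_evalues(build_profile(fam$msa), seed = 7)

db <- simulate_profiling_db(fam, n_orthologs = 2, n_contaminants = 1, seed = 7)
hits <- search_database(prof, db$db, e_cutoff = 1e-5)
hits[, c("target_id", "bit_score", "e_value")]
#>   target_id bit_score e_value
#> 1   orth002 234.06957       0
#> 2   cont001 104.85064       0
#> 3   orth001  75.86006       0

hit <- hits[1, , drop = FALSE]; attr(hit, "profile_id") <- attr(hits, "profile_id")
place_query(eng, align_hit_to_reference(hit, prof, db$db), hit$target_id)
#> placement of 'orth002': edge 7 (pendant 0.0933, logL -4014.300, LWR 1.000)
#>   -> eukaryote/mitochondrial
```

The fragment places on edge 7 — inside the eukaryote clade, on its
mitochondrial-paralog side — with all of the likelihood weight, so it is
retained as a genuine mt-lineage homolog. (Homologous bacterial contaminants
also score well in the profile search, which is exactly why the placement
filter exists.)

```r
tab <- simulate_rate_table(c(0.10, 0.39, 0.38, 0.07), 20, sigma = 0.05, seed = 11)
fit_compensatory_model(tab, "full")
#> compensatory-substitution model (full), n = 40
#>       estimate      se       t       p
#> beta0  0.12928 0.03375 3.83033 0.00049
#> beta1  0.35418 0.04773 7.42054 0.00000
#> beta2  0.26443 0.09355 2.82671 0.00763
#> beta3  0.19342 0.13229 1.46202 0.15241
#> SSE 0.14055, R^2 0.930, residual df 36
```

`beta1` is sharply positive (mt-aaRS evolve faster), `beta2` positive (aaRS
rates track their tRNAs' rates), and the interaction `beta3` is not
distinguishable from zero at this sample size — the pattern expected when
rate elevation reflects relaxed selection rather than compensatory coupling.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the whole chain from scratch under one seed — reference-family
simulation, two-round profiling with recall/leakage scoring against the
generator's truth labels, WAG/K80 rate estimation, the compensatory-model
fits with nested F-tests and the mt/cy correlation, and the codon
reassignment scan — and writes the JSON report to `--out`.

Analyses of published sequence data (the coefficient estimates and the
TGA→Ser / AUA→Ile column fractions reported for real mitochondrial genomes)
require retrieving the public accessions and curated family alignments;
the same function path shown above (`read_sequences` / `read_alignment` /
`read_ref_tree` → `run_two_round_profiling` → `mean_outgroup_distance` →
`assemble_rate_table` → `fit_compensatory_model`, and
`map_codons_to_columns` → `scan_codon_reassignment`) applies unchanged to
those inputs.
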