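---
title: "Detecting duplicated-gene incompatibilities: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting duplicated-gene incompatibilities: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dupincompat)
```

## The problem

When a gene is duplicated, either copy can degenerate — by a loss-of-function
(LoF) mutation, by promoter hypermethylation that silences expression, or by
outright deletion — as long as the other copy still works.  Two lineages that
pseudofunctionalize *different* copies are each healthy, but their hybrids can
stack the two dead alleles: a genotype carrying zero functional copies of an
essential gene dies.  This is the classic Bateson–Dobzhansky–Muller (BDM)
incompatibility, produced here by reciprocal pseudofunctionalization rather
than by novel alleles.

`dupincompat` implements the full detection pipeline for this signal:

1. a forward simulator of multiparent recombinant inbred line (RIL)
   subpopulations under a diallel crossing design, with embryo-lethal
   incompatibilities and rescuing modifier copies;
2. founder-haplotype reconstruction (identity-by-descent mosaics) from noisy
   biallelic markers with a hidden Markov model (HMM);
3. a segregation-distortion scan over unlinked duplicated gene pairs
   (chi-square tests per subpopulation, in merged same-founder subpopulations,
   and population-wide), followed by a founder-LoF confirmation filter;
4. functional-allele calling in accession panels from LoF variant effects,
   promoter-methylation clustering, pseudoheterozygous variant assignment and
   coverage-based deletion calls;
5. kinship-corrected mixed-model genome-wide association (GWA) mapping of
   modifier loci from the binary functional-copy phenotype;
6. read-depth copy-number estimation and carrier calling.

## The RIL simulator

A subpopulation follows the four-founder design: two F1 hybrids (founder 1 x 2
and founder 3 x 4) are crossed, and the four-way F1 is selfed by single-seed
descent to the configured generation (F4 or F6; `cross_design()`).

*Meiosis.*  Crossover counts per chromosome are Poisson with mean equal to the
genetic length in Morgans, without interference; crossover positions are
uniform in genetic distance and mapped to bp by linear interpolation
(`sample_gamete()`).  The default genome (`default_genome_map()`) has five
chromosomes of 18.6–30.4 Mb and 0.9–1.2 Morgans, an Arabidopsis-scale layout.

*Lethality.*  Selection acts at zygote formation in every generation: an
individual whose total functional-copy count over an essential family
(`dup_gene_spec()`) is zero dies with probability equal to the family's
penetrance and is redrawn from the same parents (rejection resampling within
the line, bounded retries).  Partial penetrance models incompatibilities that
reduce rather than eliminate a class.  Residual heterozygosity arises
naturally from the finite number of selfing generations; nothing is forced.

*Observed markers.*  Founder alleles are biallelic, redrawn until polymorphic
within the founder quadruple.  Observed dosages flip each allele independently
with probability `error_rate` (default 0.5%) and drop calls uniformly at
`missing_rate` (default 10%).  These two rates are not estimated from any real
panel; they are plausible RAD-seq-like values and are exposed in the
configuration precisely because they are conventions, not data.

*Accession panels* (`simulate_accession_panel()`) emulate a natural diversity
panel: discrete subpopulations whose marker frequencies drift apart under a
Balding–Nichols beta model (`fst`, default 0.1, 3 groups), fully homozygous
dosages (selfing species), per-copy haplotype classes drawn from configured
frequencies, bimodal promoter-methylation classes (Beta-distributed window
fractions with means 0.80 vs 0.05 and concentration 100), DNA/RNA
variant-evidence flags with small flip errors, and Poisson coverage whose
regional mean scales with carried copy number.  Accessions with zero
functional reference copies are made modifier carriers — in nature they would
not otherwise exist — and the modifier is tagged by a ten-marker window so
that the GWA stage has a recoverable target.  What the generator does *not*
emulate: linkage disequilibrium beyond block structure, realistic site
frequency spectra, sequence-level reads, or shared ancestry between the
methylation and marker processes.  Passing tests therefore demonstrate that
the statistical machinery is correct under its stated model, not that real
panels satisfy that model.

## Founder-haplotype HMM

States are unordered founder pairs: 4 homozygous + 6 heterozygous for a
four-founder subpopulation (`enumerate_states()`).

* **Emissions.**  The observed dosage given a state flips each of the two
  alleles independently with rate epsilon — the same error process the
  simulator uses.  Missing calls contribute likelihood 1 in every state.
* **Transitions.**  Over an inter-marker interval of `d` Morgans the chain
  leaves its state with probability `1 - exp(-k d)`, spread uniformly over the
  other states; `k` (default 1) scales the expected number of state switches.
  A uniform kernel ignores that switches into states sharing a founder are
  more likely, but it keeps the model honest about what one meiosis can do and
  decodes F6 mosaics essentially perfectly at realistic marker density.
* **Prior.**  Heterozygous states share weight `h` with the homozygous states
  sharing `1 - h`; the default `h = 2^-5` is the expected residual
  heterozygosity after five rounds of selfing (halving per round).
* **Decoding.**  Scaled forward–backward (per-marker normalization constants,
  not log space), which keeps the recursion directly comparable to an
  exhaustive path-sum oracle; the forward and backward likelihoods agree to
  1e-9 relative as an internal invariant.
* **Blocks.**  Maximum-a-posteriori states (ties to the lowest canonical
  index) are merged into runs; runs shorter than `min_markers` are absorbed
  into the flanking run with the higher mean posterior, and boundaries sit at
  the midpoint between the flanking markers of a switch.

*Breakpoint resolution.*  A biallelic marker separates two diplotype states
only when their expected dosages differ; for a switch between two homozygous
states roughly half the markers are uninformative.  A crossover is therefore
localizable only to its stretch of pair-informative observed markers, and the
accuracy tests measure breakpoint recall within one interval *of that grid*
(97% in the shipped test, with 99%+ per-marker state accuracy).  Recall
within one physical marker interval is information-theoretically capped well
below that (about 0.8 under the default conditions), which is a property of
biallelic panels, not of the decoder.

## The distortion scan

At each unlinked duplicated gene pair every individual contributes two counts
to the founder allele-pair table: a double homozygote "aabb" adds 2 to
`o_ab`, and a genotype with heterozygosity is split positionally after
sorting each locus's allele pair, so "abbc" adds 1 to `o_ab` and 1 to
`o_bc` (`count_allele_pairs()`).  True phase across unlinked loci is
unknowable, so positional pairing after canonical sorting is a convention —
but a fixed, reproducible one.

Expected counts (`expected_pairs()`) default to the classical marginal
(independence) construction, which is robust to single-locus segregation
distortion — essential, since the scan's target is two-locus epistasis, not
single-locus transmission bias.  The uniform design expectation
(`total / 16`) is available for comparison; the tests show it inflates the
statistic under pure single-locus distortion.  Degrees of freedom follow the
construction: `(r-1)(c-1)` over the nonzero marginal classes for marginal
expectations, cells minus one for design expectations.

*Calibration.*  Because each individual contributes two (usually identical)
counts, the raw Pearson statistic on the table is inflated: if a fraction `q`
of individuals place both counts in the same cell, the null statistic is
`(1 + q)` times a chi-square variable (exactly 2x in a fully inbred
population).  The scan therefore divides the statistic by `1 + q` by default
(`scale = "individual"`), which makes neutral-pair p-values uniform; the raw
statistic is available as `scale = "pair"` for comparison with published
tables computed without the correction.  `chisq_distortion()` itself applies
no correction unless asked — the printed toy example
(`o = [[10, 0], [0, 10]]` giving chi-square 20, df 1) is the raw statistic.

The population-wide test (`chisq_whole_population()`) sums observed and
expected tables over subpopulations on the union founder set — expectations
computed within each subpopulation first, which absorbs population structure
— and reduces to the single-population test when one table is supplied.

Screening (`screen_gene_pairs()`) runs every pair in every subpopulation, in
configured merged same-founder subpopulation groups (tables summed), and
population-wide; Benjamini–Hochberg FDR is applied within each population's
scan family and a pair is retained when any q-value clears `alpha`.  The
second step (`confirm_lof_in_founders()`) keeps a retained pair only if some
founder is nonfunctional at copy 1 *and* some founder is nonfunctional at
copy 2 — otherwise no cross can produce a zero-functional genotype, and the
distortion (e.g. hitchhiking on a linked true incompatibility) is not the
pair's own doing.

## Functional-allele calling

*Variant effects* (`classify_variant_effect()`) use a deliberately minimal
classifier over synthetic gene models: `cds_loss` (deletion removing a full
CDS segment; checked first so a whole-exon deletion is not reported as its
frameshift/splice side effects), `start_lost` / `stop_lost` (first/last codon
hit), `stop_gained` (SNV creating an in-frame stop, verified on the actual
CDS sequence), `splice_damage` (within 2 bp of an intron boundary — the
canonical donor/acceptor dinucleotides), `frameshift` (CDS length change not
divisible by 3), else `none`.  Multi-transcript models, NMD rules and
alternative-splicing rescue are out of scope; a rescue can be injected as an
override on the LoF evidence table.

*Methylation* (`profile_methylation()`): percent methylated cytosines per
context (CG/CHG/CHH) in 100-bp non-overlapping windows running in
transcription direction from 500 bp upstream of the TSS to 300 bp downstream
of the TES.  Windows without covered cytosines are missing and imputed with
the accession-wise context mean before clustering.  Two-group Ward clustering
(`cluster_methylation_profiles()`) uses Euclidean distances and `hclust`
`ward.D2`; the group with the higher mean promoter-region CG methylation is
labelled hypermethylated (an automatic version of labelling by inspection).
Cohorts processed by different pipelines are clustered separately, because a
global pipeline shift would otherwise dominate the first split.

*Pseudoheterozygous variants* — apparent het calls created by reads from two
near-identical copies collapsing onto one locus — are assigned by expression
contrast (`assign_pseudohet_variant()`): present in DNA but absent in RNA
with exactly one copy silenced, the variant belongs to the silenced copy;
present in both with one copy silenced, to the expressed copy; otherwise it
stays unassigned.  The default notion of "absent in RNA" in the panel
generator is zero supporting reads where coverage exists; the threshold is a
configuration, not an inference.

*Composition* (`build_functional_matrix()`) uses fixed precedence per
accession x copy cell: `absent` (coverage) over `lof` (assigned effect) over
`silenced` (hypermethylated) over `functional`; accessions without
methylation data are assumed expressed; a coverage-absent copy with
RNA-expressed variant evidence is contradictory and becomes `unknown`.
Phenotypes (`phenotype_from_matrix()`) are binary: `any_copy` scores 1 when
at least one copy is functional (families with both copies in the reference),
`reference_copy` scores the designated reference copy alone (families whose
reference carries one copy).

## Mixed-model GWA

The binary phenotype is fitted with a *linear* mixed model — a documented
simplification that matches standard practice for this phenotype type:
`y = mu + g + e` with `g ~ N(0, sg2 K)`, `e ~ N(0, se2 I)`.

* Markers are filtered to minor allele frequency > 0.05 and missing rate
  < 0.1, then mean-imputed (`filter_and_impute()`) — a deliberate,
  transparent replacement for model-based imputation.
* Kinship is the VanRaden centered cross-product
  `Z Z' / sum(2 p (1-p))` (`compute_kinship()`).
* Variance components come from spectral REML on the null model
  (`fit_null_mlm()`): the ratio `delta = se2/sg2` is profiled on the
  eigendecomposition of `K`, located on a log10 grid over `[1e-5, 1e5]` and
  refined by bounded scalar optimization (tolerance 1e-8).
* The scan (`association_scan()`) is a single-fit approximation: variance
  components stay fixed from the null while each marker is tested by
  generalized least squares in the rotated eigenspace.  The residual scale is
  re-estimated per marker and significance uses a t reference on `n - 2`
  degrees of freedom, so with identity kinship the scan collapses *exactly*
  onto ordinary least squares — which is also the test oracle.
* The genome-wide threshold is Bonferroni: `-log10(alpha / markers)`,
  reported to two decimals.

Constant markers after imputation get `p = 1` and are flagged rather than
dropped silently.

## Copy number

The normalized ratio is mean regional depth over genome-wide mean depth
(`normalized_coverage()`); integer copies are `round(ratio x baseline)` with
ties to even (`estimate_copies()`), where the baseline is the copy count of
the measured region in the reference (2 for a two-copy family union, so a
ratio of 1.5 means three copies somewhere in the family).  Carrier calls on a
non-reference assembly use an inclusive mean-depth threshold of 5
(`call_presence()`).  No GC or mappability correction is applied.

## Numerical and design notes

* All randomness flows through R's global RNG; simulator entry points accept
  a `seed`, and identical seed + configuration reproduce byte-identical
  pipeline artifacts (checksummed in the `run_pipeline()` manifest).
* Anchors falling exactly on a block boundary belong to the left
  (lower-coordinate) block; coordinates are BED-like 0-based half-open for
  blocks and coverage, 1-based inclusive for gene models and VCF.
* Degenerate inputs fail loudly: empty maps, all-missing marker vectors,
  zero-total count tables, non-PSD kinship (reported with its smallest
  eigenvalues), monomorphic-only panels, empty coverage regions.
* Test problem sizes are chosen to exercise study-scale behaviour while
  keeping the suite quick: 90-line F6 subpopulations (1,000 neutral pairs for
  calibration; 100 replicates for detection power), 300-accession panels with
  5,000 markers (100 replicates for locus recovery), 2,000 markers per
  chromosome for decoder accuracy, 500-bp regions at 10–30x for copy number.

## Limitations

The linear model on a binary phenotype, the uniform HMM transition kernel,
mean-dosage imputation, the positional het-pairing convention and the absence
of LD in the panel generator are all deliberate simplifications, each noted
above where it is made.  Headline counts from any particular real population
(numbers of distorted pairs, accession tallies, breakpoint totals) depend on
that population's private structure and are not reproduced by the synthetic
study; the test suite instead verifies the properties that make such counts
trustworthy — calibration under the null, power under planted truth, and
exact agreement with independent oracles on small instances.
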