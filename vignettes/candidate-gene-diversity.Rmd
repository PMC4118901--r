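---
title: "Candidate-gene diversity, haplotype and association analysis: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Candidate-gene diversity, haplotype and association analysis: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genediv)
```

## Scope and data model

genediv analyses a single resequenced gene amplicon across a panel of
inbred lines. Inbreds are treated as haploid haplotypes: every sequence is
one allele, there are no heterozygous calls, and no phasing is ever needed.
Three inputs drive everything:

* an **aligned panel** — a gapped multiple sequence alignment (FASTA) of N
  lines over L columns, alphabet `A,C,G,T,N,-`, with an optional
  annotation-only reference row (a B73-style allele used to anchor
  coordinates but excluded from all statistics unless explicitly kept as a
  sample);
* a **gene model** — ordered, non-overlapping named regions (promoter,
  exons, introns, UTRs) in 1-based inclusive alignment coordinates, plus
  the exon list whose concatenation forms the CDS;
* per-line **phenotypes** (with optional replicates) and a
  **STRUCTURE-style Q matrix** of admixture proportions, both consumed,
  never estimated.

All coordinates everywhere are 1-based inclusive alignment columns. The
gene model is authoritative: nothing in the package assumes a particular
amplicon length, and per-region statistics are driven entirely by the
annotation file.

## Variant model

A column containing any gap character belongs to an indel event; all other
polymorphic columns are SNPs. An **indel event** is a maximal contiguous
run of gap-containing columns; distinct gap patterns over the same run are
alleles of one multi-allelic event, so nested deletions (no deletion / −3 /
−6 over the same six columns) are a single tri-allelic event. This
convention makes the distinction between "number of indels" (events) and
"number of indel sites" (columns) exact, and it is the convention under
which the usual per-region summary table bookkeeping (events, sites, mean
indel length = sites/events) is reproduced.

`N` is missing data: excluded from allele counts, never the seed of a
variant. A variant is a **singleton** when exactly one line carries a
non-major allele, otherwise parsimony-informative. Major alleles are the
most frequent; ties break toward the reference allele when one is attached,
else lexicographically, so calling is deterministic and
permutation-invariant in sample order.

Coding SNPs are classified synonymous/nonsynonymous by substituting each
minor allele into the majority-allele codon and translating with the
standard genetic code (minus-strand models are reverse-complemented first).
Coding indels are in-frame when every allele's length change is a multiple
of 3, else frameshift. An internal stop introduced by a substitution is a
warning, not an error — real panels contain pseudogenized alleles.

## Diversity and neutrality statistics

Gap handling is *complete deletion of indel columns*: for every scope
(region, union of regions, entire locus) the net length is
`L_net = L_gross − indel sites`, and all statistics are computed over the
net column set. This choice is not cosmetic — it is the convention under
which Watterson's theta computed from a scope's segregating-site count and
net length reproduces DnaSP-style published values, and it keeps pi and
theta on the same denominator.

* **pi** is computed from sequences (pairwise Hamming differences over the
  net columns, pairs with missing bases compared over their shared called
  sites, denominator fixed at `choose(N,2) * L_net`). A reconstruction of
  pi from variant-table allele counts is kept as a cross-check oracle in
  the tests, never as the implementation, so the two routes stay
  independent.
* **Watterson's theta** is `S/(a1 * L_net)` with `a1` the (n−1)-th harmonic
  number.
* **Tajima's D** uses the classical constants through `e1`, `e2`;
  significance comes from the moment-matched beta distribution over the
  statistic's theoretical range — the same approximation behind the
  published confidence tables.
* **Fu and Li's D\* and F\*** are the no-outgroup forms contrasting the
  singleton count `eta_s` with `S` and with pi respectively. Two variants
  of the corrected F\* variance coefficients circulate in the literature,
  differing in whether the last numerator term is `8*a1/n` or `8*a2/n`;
  genediv uses the `a2` form, which is the one consistent with published
  candidate-gene values we verified against. `eta_s` counts singleton
  *SNPs* only — indels never enter the four test statistics. Significance
  stars for D\*/F\* use a two-sided normal approximation, documented as
  such; the exact percentage points are tabulated in the original sources
  and not closed-form. For all four tests `S = 0` yields `NaN`, printed as
  `NAN` in the wide table.

Scopes are composable: `summarize_regions()` evaluates every annotated
region, any requested union (all exons pooled, by default), and the entire
locus, pooling net columns before computing — so a union's S is additive
over disjoint parts but its D is computed on the pooled data, not averaged.

## Haplotypes and proteins

Haplotypes are exact sequence classes over a column set (gaps significant),
numbered by descending count with ties to the first-occurring line.
Missing-base handling follows the closest-complete-match rule: a line whose
`N` pattern is its only difference joins the otherwise-identical haplotype
(ties to the larger one); this mirrors how the standard desktop tools
behave and is documented here because published methods are silent on it.
Haplotype diversity is `Hd = (n/(n−1))(1 − Σ p²)`.

The CDS partition provably refines the full-length partition (two lines
identical over all columns are identical over CDS columns);
`haplotype_mapping()` asserts this rather than assuming it. CDS haplotypes
are translated after per-haplotype gap removal; haplotypes that differ only
by synonymous substitutions collapse to one protein, so the number of
distinct proteins can be smaller than the number of CDS haplotypes —
with one nonsynonymous SNP and two in-frame deletions, four distinct
non-reference protein changes is the arithmetic maximum, whatever the
haplotype count. Residue coordinates for reported protein variants
(substitutions, residue deletions) are anchored on the longest
(no-deletion) protein, and domain overlap uses closed residue intervals, so
a variant at a domain boundary overlaps it.

## Linkage disequilibrium and recombination

r² between two biallelic SNPs is computed from haplotype frequencies over
the pairwise-complete lines; the significance test is a two-sided Fisher
exact test on the 2×2 haplotype table (chosen for small-count robustness;
raw p at 0.05 by default, Bonferroni available). Multi-allelic variants and
indels are excluded — LD is a SNP statistic here.

Five decay families are fitted to r² against distance: linear `a+bd`,
loglinear `a+b ln d`, exponential `a e^{bd}`, power `a d^b`, and the
Hill–Weir drift-recombination expectation ("Remington" curve) with the
recombination scale `C = rho*d` fitted nonlinearly (log-spaced grid over
`rho` from 1e−5 to 1e−1 per bp seeds the optimizer). The coefficient of
determination is evaluated on the original r² scale for *all* families —
fitting exponential/power on the log scale and reporting log-scale R²
would bias model selection — and the family with the highest R² among
converged fits is selected. Each family also reports the distance at which
its curve crosses a target r² (0.1 by default), taking the smallest
positive root and reporting `NA` when the curve never reaches it.

The minimum recombination count applies the four-gamete test to every SNP
pair, keeps incompatible intervals that contain no smaller incompatible
interval, and counts disjoint intervals greedily left-to-right by right
endpoint. Because a minimum point set piercing a family of intervals has
the same size as a maximum disjoint subfamily, this greedy count is the
exact minimum; the tests verify it against an exhaustive point-placement
oracle on all small panels.

## Association under population structure

Association runs on per-line trait means (replicates are for the
across-line ANOVA, not the GLM). The MAF filter removes alleles with
frequency strictly below the threshold (an allele at exactly 0.05 in 80
lines — 4 carriers — is retained); lines carrying a removed allele become
missing for that variant, so a tri-allelic indel cleanly reduces to its
common biallelic contrast. The model is

  trait ~ intercept + Q[, 1..K−1] + marker

with the last admixture column dropped to avoid intercept collinearity.
The marker test is the partial F of the full model against the Q-only
model, and **marker R²** is `(SSE_reduced − SSE_full)/SS_total` — the
share of total phenotypic variance explained by the marker *after*
structure. The marginal (structure-ignoring) definition differs whenever
marker and structure are correlated; the partial one is the default
because it is what a structured-GLM run reports. Rank-deficient designs
(marker collinear with Q) are flagged with `p = NA` rather than silently
dropped. Allele-class comparisons use Welch's t by default
(pooled-variance by flag); multiple testing is reported as raw p plus a
Bonferroni column, with no correction applied by default.

## The synthetic study panel

`zmbt1_sim_config()` fixes the study conditions the package is tested
under: 80 inbred lines over a 2,436 bp amplicon with seven regions
(promoter 520, exon1 624, intron1 131, exon2 162, intron2 128, exon3 534,
3'-UTR 337 bp; CDS 1,320 bp = 440 codons). The published description of
this panel states a 2,442 bp amplicon but prints region lengths totalling
2,436; the annotation is taken as authoritative and nothing hard-codes
either number.

Planted structure, all recovered exactly by the pipeline:

* 22 SNPs (7/5/0/0/0/4/6 across the regions) and 8 indel events over 37
  columns (1/3/19/0/7/6/1 sites; mean length 4.625), including one
  tri-allelic in-frame coding deletion with no-deletion/−3/−6 alleles
  (27 and 3 carriers) — the causal variant;
* exactly one singleton SNP and two singleton indels;
* 11 full-length haplotypes with counts 29/16/18/9/1/1/2/1/1/1/1
  (Hd 0.7734) collapsing to 6 CDS haplotypes 32/16/18/9/2/3 (Hd 0.7440),
  every CDS haplotype holding at least 2 lines;
* 4 distinct proteins carrying the four amino-acid variants (E deletion,
  ED deletion, one residue deletion, one substitution), none inside the
  three configured carrier-domain intervals;
* one recombinant haplotype spliced from two backgrounds at column 700,
  which is the panel's only four-gamete signal (Rm = 1).

Coding consequences are guaranteed by construction, not by luck: the
reference CDS is drawn from stop-free codons, synonymous SNPs sit at
third positions of forced `GCA` codons, the nonsynonymous SNP at a first
position, and the deleted codons are forced to `GAA GAT` (E, D) with a
fixed downstream codon so deletion coordinates are unambiguous.

Two design questions were genuinely open and are worth recording. First,
the LD relationship between the causal indel and the other markers:
carrier sets are laminar (nested or disjoint — i.e. tree-compatible)
except for the single recombinant, and no marker tags the causal indel
closely (strongest proxy |r| ≈ 0.5). This mirrors the emulated study's own
outcome — only the causal variant associated with the trait — and makes
the planted effect identifiable; a design in which a shared-branch marker
is in near-perfect LD with the causal indel would contradict that outcome.
Second, population structure: lines are assigned to three subpopulations
by a soft haplotype tilt (each haplotype has a home subpopulation drawn
with probability 0.6) and admixture rows are Dirichlet draws concentrated
on the membership. A hard haplotype-to-subpopulation partition would make
the causal indel collinear with Q and its partial R² unestimable; the
soft tilt keeps structure real (omitting Q inflates null rejections when a
subpopulation effect is planted) without absorbing the causal signal.

Phenotypes use the published panel means and standard deviations for the
seven RVA pasting traits and four DSC gelatinization traits; the enthalpy
trait carries the causal effect with target marker R² 9.26% (negative
direction: deletion carriers pasting lower), with `beta` solved from the
realized allele frequency and residual variance shrunk so the total stays
at the nominal sd. Three replicates per line add within-line noise at 0.3
of the trait sd — large enough for a finite ANOVA F, small enough that
line effects dominate, as in the emulated panel. The four gelatinization
columns are named To/Tp/Tc/dH with the temperatures in physical order;
analysis code carries traits by name and never relies on that mapping.

What the generator does *not* emulate: sequencing error, alignment
ambiguity, heterozygous residual sites, missing genotype patterns
correlated with structure, multi-locus background, and trait correlations
beyond the single planted effect (traits are conditionally independent
given the causal variant and structure). Passing tests therefore
demonstrate the correctness of the statistics and the internal consistency
of the pipeline on clean inbred-panel data, not robustness to noisy real
alignments.

The `"neutral"` mode places a fixed number of infinite-sites mutations on
a random coalescent genealogy (branch-length weighted) — adequate for
sanity bands on the neutrality tests (mean D over replicates close to 0)
and for recombination-free (`Rm = 0`) property tests, and documented as an
approximation, not a full coalescent simulator.

## Numerical choices and degenerate inputs

* `S = 0` scopes: pi = theta = 0, all tests `NaN` (`NAN` in exports).
* Tajima's D requires n ≥ 4; Hd requires n ≥ 2.
* Pairs monomorphic in their shared called subset are skipped in LD with a
  log entry; a nearly-fixed site gives Fisher p = 1, not an error.
* Nonlinear decay fits that fail to converge are excluded from model
  selection, not fatal.
* A zero-variance trait yields sd 0, undefined correlations (`NA`), and a
  warning with `F = Inf` when replicates are degenerate.
* All simulation is a deterministic function of the seed (offset-derived
  streams for panel/Q/phenotypes), and written studies are byte-identical
  across runs.

## Problem sizes used in the test suite

Property tests run at deliberately modest sizes chosen to make the
statistics' behaviour visible without waste: brute-force pi oracles on
8×50 panels, exhaustive recombination minima on ≤8 SNPs × 8 lines, 500
neutral replicates for the D sanity band, 1,000 null replicates for the
GLM type-I rate, 200 replicates for causal-variant recovery, and 100
replicates for Remington-curve parameter recovery. The full suite runs in
about three minutes on one CPU.

## Known limitations

* Significance for D\*/F\* is a normal approximation; users needing exact
  percentage points should consult the original tables.
* The LD significance test is Fisher's exact on haplotype counts; it does
  not model multiple testing beyond the optional Bonferroni column.
* `coding_effect` evaluates single-variant consequences against the
  majority background; compound effects of co-occurring variants on one
  haplotype are visible through protein translation, not through the
  per-variant labels.
* The association model is a fixed-effects GLM with Q covariates only; no
  kinship/mixed-model correction is provided, by design.
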