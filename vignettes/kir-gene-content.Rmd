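---
title: "Gene-content population genetics for KIR and their MHC ligands"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-content population genetics for KIR and their MHC ligands}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kircontent)
```

## The problem

Killer-cell immunoglobulin-like receptor (KIR) haplotypes differ between
individuals not only in allele sequence but in which genes they carry at
all. A typing panel therefore yields, per individual, a presence/absence
vector over a registry of loci — the *gene-content genotype*, the
locus-wise OR of the individual's two haplotypes. `kircontent`
implements the statistics that make such data comparable across
individuals, populations and species: genotype-diversity resampling,
gene-content linkage disequilibrium (LD), haplotype-frequency estimation
from unphased presence/absence genotypes, epitope classification of the
MHC class I ligands, parsimony counting of the residue changes that
create or destroy those epitopes, and a population-level receptor–ligand
interaction statistic (ANDI).

Everything operates on five small containers: a `locus_registry` (locus
names plus centromeric/telomeric/framework region tags), a
`genotype_panel`, a `haplotype_table` (presence vectors with frequencies
summing to 1), a `frequency_table` of per-population phenotype
frequencies, and a `tip_state_tree`. Missing genotype cells are rejected
at load rather than imputed: every downstream statistic assumes complete
typing, and silently imputing presence/absence would bias counts of
distinct genotypes. Copy number is deliberately not modelled — a locus is
"present" if at least one copy exists on either chromosome.

## Genotype diversity

`count_distinct_genotypes()` uses exact vector equality over the
registry. To compare panels of different sizes,
`resample_genotype_count()` rarefies: it draws `n` individuals *without*
replacement (default `n = 26`, matching an unrelated chimpanzee panel
against which human populations are standardized) and summarizes the
distinct-genotype counts of 5,000 such draws by mean, SD and a
percentile 95% CI (2.5th–97.5th percentiles). Rarefaction rather than a
with-replacement bootstrap was a genuine design choice: the aim is "the
count a panel of size 26 would show", for which sampling without
replacement is the standard (ecological rarefaction) estimator; a
with-replacement mode remains available behind `replace = TRUE`. The
percentile CI was chosen because the replicate counts are small
discrete numbers for which normal approximations are poor.

`bootstrap_pairwise_difference()` treats each locus column as one
polymorphic site: the point estimate is the mean Hamming distance over
all unordered pairs of individuals (loci equally weighted, no
self-pairs), and the bootstrap resamples *columns* with replacement
(default 10,000 replicates), with the SE taken as the SD of replicate
means. Degenerate columns (identical in everyone) contribute no
variance, so the SE shrinks to 0 as columns become uniform.

## Gene-content LD and association ratios

On a haplotype table, the *pairing frequency* of two genes is the total
frequency of haplotypes carrying both or neither; its expectation under
independence is `pA*pB + (1-pA)*(1-pB)`. Significance uses a two-tailed
Fisher exact test on a 2×2 table of haplotype counts. Exact tests need
integers, so frequencies are scaled to a user-supplied chromosome count
(2N) with largest-remainder rounding, which guarantees the cells total
2N exactly. The two-tailed rule is the common one — sum the
probabilities of all tables (margins fixed) whose point probability does
not exceed the observed table's. A zero margin means one gene is fixed;
every margin-compatible table is then equally extreme and the p-value is
defined as 1, with a warning. The default significance threshold is
0.001, and no multiple-testing correction is applied by default because
per-pair significance at a fixed threshold is the reporting convention
for these panels; both are arguments.

`association_ratios()` summarizes haplotype structure relative to a
reference gene (classically *KIR2DL5*): for each gene the ratio
`P(g | ref+) / P(g | ref-)`. Conditioning on the reference background is
what normalizes for the difference in frequency between ref-positive and
ref-negative haplotypes; the ratio is invariant under any uniform
rescaling of haplotype frequencies. A gene never seen off the reference
background gets the `AL` (absolute linkage) sentinel rather than a
division by zero; a gene absent everywhere is `undefined`. Known
absolute-linkage constraints (e.g. a gene occupying two genomic
locations that always travels with the reference) can be declared; the
pair is forced to co-segregate before computation and the affected rows
are flagged so reports can parenthesize them.

## EM haplotype frequencies from presence/absence genotypes

Haplotype frequencies are estimated by maximum likelihood under
Hardy–Weinberg random pairing:

$$ P(g \mid f) \;=\; \sum_{\substack{h_1 \le h_2 \\ h_1 \vee h_2 = g}}
   f_{h_1} f_{h_2}\,(2 - \delta_{h_1 h_2}). $$

The E-step distributes each individual over its compatible unordered
pairs; the M-step sets each haplotype's frequency to half its expected
dosage. Initialization is uniform over candidates, so the fit is
deterministic and needs no seed. Candidates default to every sub-vector
of an observed genotype (the empty, framework-only haplotype is always
legal — minimal haplotypes carrying no variable gene are real), bounded
by a `cap` because the sub-vector space is exponential in the number of
present loci; beyond the cap the user restricts loci or supplies
candidates explicitly.

Two caveats are surfaced rather than hidden. First, EM guarantees a
non-decreasing log-likelihood (asserted in the tests at every
iteration) but not a global optimum; convergence to boundary optima can
be slow, so `converged = FALSE` with the iteration count is reported
honestly instead of stopping early. Second, OR-genotypes can leave
frequency combinations non-identifiable; candidates whose frequency can
be perturbed with a log-likelihood change below 1e-6 are listed in
`flat` (a curvature heuristic, documented as such). Convergence is
declared when the largest frequency change falls below `tol = 1e-8` —
tight enough that reported frequencies are stable to far more digits
than the data support. Simulation shows pools of up to 6 haplotypes are
recovered from 500 genotypes to a mean total-variation distance below
0.05 over 20 seeds; that bound is a property of this panel size and
pool complexity, not a general guarantee (a 39-individual panel cannot
identify a 128-haplotype pool, and the end-to-end test instead checks
the fit reproduces the panel's carrier frequencies).

## Epitope logic and the co-occurrence test

The C1 and C2 epitopes recognized by lineage III KIR are determined by
MHC class I residues 76 and 80: V76+N80 gives C1, V76+K80 gives C2, and
I80 or T80 marks Bw4 allotypes. The classifier implements exactly this
rule table (an exhaustive 400-pair truth-table test pins it down); V76
arising on an I80/T80 background is still reported as Bw4 but flagged,
because that combination perturbs Bw4 recognition without creating C1
or C2 and is the configuration selection appears to eliminate. Residues
beyond 76/80 (the fuller Bw4 motif spans 77–83) are deliberately out of
scope: the operational rule used here is the 76/80 one. Positions are
1-based in the mature protein; any leader-peptide offset must be
applied upstream.

`binomial_cooccurrence_test()` asks how likely it is that all (or at
least k) of n independent epitope-creating substitutions landed on a
given background by chance: `P(X >= k)`, `X ~ Binomial(n, p)`. The test
is one-sided because the hypothesis is directional. With the observed 8
independent V76-creating substitutions all on N80 allotypes and an N80
background of 67% (I80/T80 being 33%), the tail is `0.67^8 ≈ 0.041`.
The background fraction can be computed from a supplied allotype list
(`n80_background_fraction()`) or given numerically; both the rounded
0.67 and an unrounded fraction are accepted since the sourcing
convention is ambiguous.

## Parsimony change counting

`parsimony_changes()` is unit-cost Sankoff parsimony: Fitch would need
special-casing for polytomies and larger alphabets, Sankoff does not.
The minimum change count is the parsimony score; because directional
attribution (was an edge E→V or V→E?) differs between equally
parsimonious reconstructions, per-transition counts are reported as
[min, max] ranges over *all* most-parsimonious reconstructions (MPRs).
"At least k events" claims correspond to the range minimum.

The ranges are computed exactly at any tree size by a second dynamic
program rather than by enumerating MPRs: the Sankoff recursion makes
the MPR set decompose into independent local argmin choices, and
transition counts are additive over edges, so their extremes satisfy
the same recursion. (An earlier design enumerated MPRs for small trees
and fell back to ACCTRAN/DELTRAN bounds; the exact DP supersedes both,
and the test suite keeps an exhaustive-enumeration oracle to prove it.)
A supplied `root_state` that is compatible with some MPR restricts the
root; an incompatible one is *reported* (warning, `root_state_ok =
FALSE`) and not forced, since forcing it would change the score and
silently contradict the data. This counter is a deliberate lower-bound
surrogate for likelihood-based ancestral reconstruction: it uses no
branch lengths and no substitution model, and its minimum counts
understate the true number of events when changes are dense — which is
exactly the conservative direction for "at least k events" statements.

## ANDI

The average number of distinct KIR2DL–HLA interactions in a population
is a sum of products of *phenotype* (carrier) frequencies:

$$ \mathrm{ANDI} = \mathrm{2DL1}\cdot\mathrm{C2}
 + \mathrm{2DL2}\cdot\mathrm{C2} + \mathrm{2DL2}\cdot\mathrm{C1}
 + \mathrm{2DL3}\cdot\mathrm{C1}, $$

extended by `2DL2*B46 + 2DL3*B46` for populations carrying HLA-B\*46
(a KIR2DL2/3 ligand), and with an alternative model that omits the
weaker `2DL2*C2` interaction. Whether the B\*46 terms apply is a
per-population flag in the frequency table, not a hard-coded region
list. Carrier frequencies — not allele frequencies — enter throughout;
`pf_from_allele_freq()` converts under HWE (`PF = 1-(1-af)^2`) for
sources that publish allele frequencies. Summaries report min, max,
median and the 25–75 percentile band both over populations and over
group labels, plus the median of group medians, because "median over
population groups" has two defensible readings and reporting both costs
nothing.

`hwe_max_andi()` treats C1/C2 as a biallelic epitope system at HLA-C
(every HLA-C allele carries exactly one of the two epitopes, the
standard framing): with C1-allele frequency `c`, carrier frequencies
are `C1 = 1-(1-c)^2`, `C2 = 1-c^2`, and the HLA-C terms are maximized
over `c` by bounded scalar optimization (tolerance 1e-9, boundary
values checked; the objective is a smooth quadratic, and the result
matches a 1e-4 grid search within 1e-6). B\*46 is not an HLA-C allele,
so its term is held constant during the maximization. At unit KIR
frequencies the base-model maximum is 3.0, at `c = 0.5`.

## What the synthetic generators emulate — and what they do not

The generators make every analysis testable without access to any
typing panel:

* `chimp_pool_spec()` builds a 14-marker registry whose variable
  diversity comes from seven independently present centromeric
  recombination units, three of them two-gene blocks in absolute or
  near-absolute linkage — the documented structure of the chimpanzee
  centromeric interval. Unit presence probabilities (0.15–0.85) were
  fixed once to reproduce the qualitative frequency gradient
  (intermediate, high, low) of the five variable pairs.
* `human_pool_spec()` crosses centromeric with telomeric gene-content
  motifs (A- and B-style), the recombination structure that dominates
  human haplotype diversity; motif frequencies multiply.
* `simulate_genotypes()` pairs haplotypes i.i.d. from the pool
  (Hardy–Weinberg), since nothing indicates deviation from random
  pairing in such panels; per-locus carrier frequency converges to
  `1-(1-p)^2`, which the suite checks at n = 10,000 within 3 SE.
* `simulate_frequency_table()` draws 33 populations in 8 geographic
  groups with carrier-frequency ranges a population immunogeneticist
  would call realistic (KIR2DL1 0.85–1, KIR2DL2 0.25–0.9, KIR2DL3
  0.7–1, C1 0.45–1, C2 0.25–0.8) and B\*46 at 0.087–0.275 confined to
  the East Asian group, the published carrier range for that allele.
* `simulate_tip_states()` places substitution events on edges
  identified by the child clade's tip set (Newick has no canonical edge
  labels, and tip-set signatures survive re-reading) and propagates
  from the root; events on disjoint edges are independently recoverable
  by the parsimony counter.

Pool generation is exact (enumeration with product probabilities)
rather than sampled, so stated frequencies are reproduced without Monte
Carlo noise; a sampling mode (`n_draws`) exists when noisy pools are
wanted. All stochastic functions take one explicit seed and restore the
caller's RNG state — there is no hidden global state.

What passing tests on these generators do *not* show: real panels
contain relatives (the unrelated mask is honoured but relatedness is
not simulated), genotyping error and partial typing (missingness is
rejected by design), copy-number variation, allele-level diversity
beneath presence/absence, and linkage patterns produced by actual
recombination breakpoints rather than by unit/motif mixing. Conclusions
about real data rest on the correctness of the statistics, not on the
realism of the simulator.

## Problem sizes and numerical choices

The default test-suite and script workloads — 5,000 rarefaction
replicates, 10,000 column bootstraps, 20-seed EM recovery at 500
genotypes per pool, exhaustive Fisher enumeration to table totals of
30, 100 random trees to 20 tips — were sized to exercise every claimed
property at full stated strength while completing in well under a
minute each on a single core. Frequencies are validated to sum to 1
within 1e-6; EM convergence is 1e-8 on frequencies; the HWE maximizer
is checked against a 1e-4 grid within 1e-6. Ties in the parsimony
reconstruction prefer the parent's state (a DELTRAN-like choice), which
affects only the single illustrative reconstruction, never the score or
the reported ranges.

## Known limitations

* EM offers no pedigree-aware phasing; use the unrelated mask.
* The candidate cap makes full-registry EM on gene-rich genotypes
  infeasible without candidate restriction — intentional, since the
  unrestricted candidate space is exponential and mostly junk.
* Parsimony counts are lower bounds relative to model-based ancestral
  reconstruction and use no branch-length information.
* The registry keeps duplicate markers of one fused-gene region
  distinct by default; collapse them upstream if a gene-level (rather
  than marker-level) diversity statistic is wanted.
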