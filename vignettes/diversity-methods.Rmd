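---
title: "Measuring genome diversity in closed dog breeds: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring genome diversity in closed dog breeds: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`canidiv` quantifies genetic diversity in a closed breed population from two
complementary sources: the registry pedigree and genome-wide SNP genotypes.
Pedigree statistics capture recent, recorded breeding events; molecular
statistics integrate the whole (partly unrecorded) history of the gene pool.
This vignette explains each method, the tunable parameters and the reasoning
behind the design decisions, and what the synthetic-data validation does and
does not demonstrate.

## Pedigree model

A pedigree is a set of animal records (`id`, `sire`, `dam`, `sex`,
`birth_year`) with unknown parents modelled as absent links, not as dummy
animals. A founder is an animal with both parents unknown. Records are
re-ordered so every parent precedes its offspring (a cycle is a hard error),
parents referenced without a record of their own are auto-registered as
founders with a warning, and sex is used only for sire/dam consistency
warnings — never in any computation. Imported animals with truncated foreign
ancestry simply carry unknown parents; the per-record unknown-parent counts
are visible through `summary()`.

## Inbreeding and its rate

`inbreeding()` computes Wright's F for every animal with the Meuwissen–Luo
tabular algorithm: a single pass in pedigree order, accumulating each
animal's ancestor coefficients against precomputed Mendelian sampling
variances. The algorithm is exact for arbitrary pedigree depth and loop
structure; the test suite checks it against an independent common-ancestor
path-counting oracle over hundreds of random topologies (all such F values
are dyadic rationals, so the comparison is exact, with no floating-point
tolerance).

The per-generation inbreeding rate uses the regression formulation
$$\Delta F = \frac{F_n - F_{n-1}}{1 - F_{n-1}}, \qquad F_n - F_{n-1} = l\,b,$$
where $b$ is the ordinary least-squares slope of yearly mean F on birth year,
$l$ the generation interval (mean parent–offspring birth-year difference) and
$F_n$ the reference-population mean F. The realized effective population size
is $N_e = 1/(2\Delta F)$. Two modes are provided: regression on birth year
(default, matching the formulation above) and regression of individual F on
complete equivalent generations, whose slope is per-generation directly. The
yearly regression is unweighted: weighting by yearly cohort size is defensible
but changes little on registry-scale data, and the unweighted fit is what the
formulation states. A slope indistinguishable from zero (|ΔF| < 1e-12) yields
an explicitly undefined Ne rather than an arbitrarily large one.

Pedigree completeness is summarised by complete equivalent generations,
$\mathrm{EqG}_i = \sum_{\text{known ancestor paths}} (1/2)^{\mathrm{depth}}$,
computed by dynamic programming over the ordered pedigree.

## Probabilities of gene origin: f, fe, fa

Founder contributions $q_k$ (the expected fraction of the reference gene pool
contributed by origin $k$) are computed by propagating each reference
animal's gene mass up the pedigree, halving at each parent link. The
effective number of founders is $f_e = 1/\sum q_k^2$.

Every gene lineage terminates at an unknown-parent slot. An animal with one
known and one unknown parent therefore contributes half its genome as its own
origin (a "half founder"), which keeps $\sum q_k = 1$ on any pedigree; when
unknown parents come in pairs this reduces to the classic founder definition.

The effective number of ancestors $f_a = 1/\sum p_j^2$ uses the iterative
marginal-contribution procedure: each round selects the ancestor explaining
the largest share of the reference gene pool *not yet explained* by the
previously selected ancestors. The marginal contribution of a candidate is
the product of (i) the gene mass reaching it from the reference set along
paths avoiding already-selected ancestors and (ii) the fraction of its own
genome not descending from selected ancestors. Ties are broken by earliest
birth year, then lexicographic id, so output is deterministic. Selection
stops when the best marginal contribution falls below 1e-9 or all ancestry is
explained.

One caveat worth stating plainly: the greedy selection is not prefix-optimal,
so on unusual topologies the marginal distribution $p$ can end up slightly
*flatter* than $q$, making $f_a$ marginally exceed $f_e$. On
breeding-structured pedigrees (discrete generations, repeated sire use) we
observe $f_a \le f_e$ throughout, occasionally with sub-percent excursions;
no clamping is applied because the quantity reported is the procedure's
definition, not an inequality-constrained estimate.

## SNP quality control

The QC cascade removes samples with more than 10% missing genotypes, then
drops non-autosomal markers (dog autosomes 1–38), then keeps markers with
call rate strictly above 90%, then keeps markers with minor allele frequency
at least 0.05 computed on the surviving samples. The MAF boundary is the
exclusion rule "remove MAF < 0.05" (so a marker at exactly 0.05 is retained);
the comparison operator is exposed (`maf_op`) because conventions differ
between tools. The filters are idempotent and the QC report counts reconcile
exactly with matrix dimensions, both enforced by tests.

PLINK text (ped/map) and binary (bed/bim/fam, SNP-major) filesets are read
and written natively; calls count copies of the A1 allele declared in the
`.bim` file.

## Heterozygosity and excess-homozygosity inbreeding

MLH is each sample's fraction of non-missing genotyped loci that are
heterozygous. The molecular inbreeding coefficient follows the
observed-versus-expected homozygosity convention:
$F = (O_{\mathrm{hom}} - E_{\mathrm{hom}})/(L - E_{\mathrm{hom}})$ with
$E_{\mathrm{hom}} = \sum_m \left(1 - 2p_m(1-p_m)\tfrac{n_m}{n_m-1}\right)$
over the sample's non-missing markers — the $n/(n-1)$ factor is the
small-sample correction on expected heterozygosity, matching the `--het`
convention of standard tooling. Markers observed in fewer than two samples
are skipped.

## Runs of homozygosity

`detect_roh()` implements the sliding-window scan with the canine-chip
defaults frozen in `roh_params()`: 50-SNP windows allowing 1 heterozygote
(tolerating a ~1% genotyping error rate) and 5 missing calls; a SNP is
run-eligible when at least 5% of its covering windows are homozygous; runs
split at inter-SNP gaps over 100 kb; emitted runs need at least 50 SNPs,
1000 kb, one SNP per 50 kb on average (the kb-per-SNP density convention)
and at most one heterozygous call. Candidate runs are trimmed so both
endpoints are homozygous non-missing calls before the final filters: because
a window containing one heterozygote still counts as homozygous, flanking
heterozygotes would otherwise be dragged into every run and the one-het run
budget would be consumed at the boundaries, contradicting the intent of the
window tolerance. Segment length is `end − start` of the bounding SNP
positions; the ±1 bp convention is immaterial at Mb scale but fixed for
determinism. Published `--homozyg` implementations have undocumented corner
behaviours; this package freezes the contract above as its definition and
verifies it against an independent straight-loop re-implementation in the
test suite rather than bit-matching any binary.

$F_{\mathrm{ROH}}$ divides each sample's total ROH length (per minimum-length
class: >1, >2, >4, >8 Mb, reflecting progressively more recent common
ancestors) by the SNP-covered autosomal genome length — the sum over
autosomes of last-minus-first marker position, computed on the post-QC map
(the map the runs were actually called on). The class profile is monotone
non-increasing by construction and tested as such.

`min_roh_snps()` gives the minimum run length (in SNPs) that keeps the
expected number of chance runs below a tolerance:
$\lceil \ln(\alpha/(n_{\mathrm{snps}} n_{\mathrm{samples}})) / \ln(1-\bar h) \rceil$.

## LD-based effective population size

Markers are first thinned: the concatenated autosomal genome is cut into
10,000 equal-bp segments and the highest-MAF SNP per segment is kept
(ties → lowest position; MAF < 0.05 never selected). Thinning caps the pair
count and biases selection toward informative markers.

For every marker pair the squared correlation of genotype scores is computed
from Burrows' composite disequilibrium: half the sample covariance of the
0/1/2 scores (the (S−1) denominator carries the usual small-sample factor),
squared, divided by $p(1-p)q(1-q)$. The mean $\bar r^2$ (weighted by pair
sample size when data are missing) minus the finite-sample expectation
$1/S + 3.19/S^2$ (the S ≥ 30 form) gives the drift signal $r^{2\prime}$, and
$$\hat N_e = \frac{1/3 + \sqrt{1/9 - 2.76\, r^{2\prime}}}{2 r^{2\prime}},$$
with $r^{2\prime} \le 0$ reported as an infinite estimate rather than a
number. A parametric confidence interval treats $J \bar r^2 / r^2$ as
chi-square with $J$ (number of pairs) degrees of freedom. All pairs are used,
including same-chromosome pairs, per the convention of the standard
estimator; physically linked pairs bias the estimate slightly downward, which
is why validation uses a karyotype with many chromosomes (38) where linked
pairs are ~2.6% of the total. The mating model is fixed to random.

## Population structure

The IBS distance between two samples is one minus the mean shared-allele
fraction over markers non-missing in both. The population network is a
mutual k-nearest-neighbour graph (default k = 10): an edge survives only if
each endpoint is in the other's neighbour set, with neighbour sets
tie-inclusive (every sample at the k-th-nearest distance belongs), making the
construction deterministic and purely rank-based — adding a constant to all
distances changes nothing. Edge weights (1 − distance) are carried for
visualisation only. Cluster labels come from connected components refined by
fast-greedy modularity on the unweighted graph; a partition is only accepted
when its modularity is positive (a clique is never split), and clusters below
the minimum size (default 2) are flagged unclustered rather than forced into
a group. This deterministic construction replaces the super-paramagnetic
Monte-Carlo clustering used in some network pipelines, whose temperature
schedule and seeds are rarely reported; the mutual-kNN formulation is the
construction adopted by later versions of the same pipeline family and keeps
the published parameters (k = 10, minimum cluster size 2).

Between-population relationships use neighbour joining on the same
1 − IBS distances (via `ape::nj`), which is exact on additive tree metrics —
a property the tests verify by regenerating random 8-leaf trees from their
path-length matrices. Negative branch lengths are clamped to zero with the
deficit recorded. Trees serialise to Newick; networks to GraphML plus plain
edge/node tables.

## Synthetic data: what it emulates and what it does not

Three simulators provide ground truth:

* `simulate_pedigree()` builds discrete-generation pedigrees with
  Dirichlet-skewed sire usage (low concentration = popular-sire breeding),
  optional unknown-parent masking, and fixed birth-year spacing. Defaults
  (100 founders, 10 generations of 150, concentration 1, 3-year gap from
  1980) sketch a mid-size national breed registry.
* `gene_drop()` drops uniquely labelled founder haplotypes through a pedigree
  with Poisson recombination (no crossover interference), recording realized
  autozygous tracts (both haplotypes carrying the same founder label) next to
  the observed genotypes. Founder haplotype alleles follow a first-order
  copy chain along each chromosome (`ld_rho`), the simplest model giving
  realistic local redundancy for the thinning step. The default genome is
  deliberately scaled down — 38 chromosomes × 60 Mb, 20,000 markers — so
  whole-pipeline validation runs in minutes; ROH-focused checks use denser
  maps (~55–60 SNPs/Mb) matching the marker density of a 170k canine array,
  since run detection is density-limited.
* `wright_fisher()` evolves a constant-size random-mating population
  (selfing allowed, so census size equals inbreeding-effective size) and
  genotypes a final-generation sample. LD-Ne validation runs 40 generations
  of burn-in at Ne = 50 — ample for drift LD to equilibrate at unlinked and
  moderately linked distances — then estimates Ne from 30 samples and at most
  2,000 thinned SNPs.

The simulations validate internal consistency: estimator code paths, known
expectations (full-sib autozygosity 0.25, half-sib 0.125, slope ≈ 1 of
realized autozygosity on pedigree F), planted-tract recovery and Ne
recovery. They do not emulate ascertainment bias of commercial SNP panels,
non-uniform recombination maps, genotyping batch effects, or real breed
demography; agreement here shows the methods are implemented correctly, not
that any particular real population satisfies their assumptions.

## Numerical and degenerate-input choices

* Inbreeding is computed in double precision in production; exactness is
  established by the dyadic-rational oracle at test scale.
* Ancestor-selection ties: earliest birth year, then lexicographic id.
* `delta_f_ne()` treats |ΔF| < 1e-12 as zero (Ne undefined, flagged).
* Monomorphic markers are excluded from r² computation; pairs with fewer
  than two joint observations are dropped.
* A sample pair with no overlapping markers makes `ibs_distance()` fail
  loudly (naming the pair) rather than imputing.
* All simulators are bit-reproducible under a fixed seed; pipeline reruns
  write byte-identical reports.

## Known limitations

* The LD-Ne point estimate inherits the standard estimator's downward bias
  from physically linked pairs and its large sampling variance at small S;
  the parametric CI does not account for linkage.
* fa can marginally exceed fe on adversarial topologies (greedy
  prefix-suboptimality), as discussed above.
* The ROH scan is a frozen contract, not a bit-level reproduction of any
  specific tool version.
* Gene-drop founder LD is a first-order chain; long-range LD structure of
  real populations is not reproduced.
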