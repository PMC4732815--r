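# canidiv

Genealogical and molecular genome-diversity analysis for closed dog-breed
populations.

Breed clubs and population geneticists monitor diversity in pedigree dogs
from two sides: the registry pedigree (what breeding was recorded) and
genome-wide SNP genotypes (what the genome actually retained). `canidiv`
implements both halves of that analysis in one tested R package, together
with pedigree/genotype simulators that provide exact ground truth for
validating every stage.

**Pedigree statistics** (for a reference population within a registry):

* Wright's inbreeding coefficient *F* for every animal, by the
  Meuwissen–Luo tabular algorithm (exact at any pedigree depth);
* complete equivalent generations EqG = Σ (1/2)^depth over known ancestors;
* generation interval *l* (mean parent–offspring birth-year gap);
* founder statistics from probabilities of gene origin: founder count *f*,
  effective founders *f*<sub>e</sub> = 1/Σq², effective ancestors
  *f*<sub>a</sub> = 1/Σp² via iterative marginal contributions;
* inbreeding rate ΔF = (F<sub>n</sub> − F<sub>n−1</sub>)/(1 − F<sub>n−1</sub>)
  with F<sub>n</sub> − F<sub>n−1</sub> = *l·b* from the regression of yearly
  mean F on birth year, and realized effective population size
  N<sub>e</sub> = 1/(2ΔF);
* the additive relationship matrix (a<sub>ii</sub> = 1 + F<sub>i</sub>).

**Molecular statistics** (PLINK text/binary input, dog autosomes 1–38):

* QC cascade (sample missingness > 10%, marker call rate ≤ 90%, MAF < 0.05);
* multilocus heterozygosity and excess-homozygosity inbreeding
  (*F* = (O<sub>hom</sub> − E<sub>hom</sub>)/(L − E<sub>hom</sub>), `--het`
  convention);
* runs of homozygosity by the 50-SNP sliding-window scan (1 het / 5 missing
  per window, 5% window threshold, ≥ 50 SNPs, ≥ 1000 kb, ≤ 50 kb/SNP,
  ≤ 100 kb gaps, ≤ 1 het per run) and
  F<sub>ROH</sub> = L<sub>ROH</sub>/L<sub>AUTOSOME</sub> by length class
  (> 1/2/4/8 Mb);
* LD-based N<sub>e</sub>: top-MAF thinning to 10,000 genome segments,
  Burrows composite r², bias correction 1/S + 3.19/S², and
  N̂<sub>e</sub> = (1/3 + √(1/9 − 2.76 r²′))/(2 r²′);
* identity-by-state distances, mutual k-NN population networks with
  deterministic community detection, and neighbour-joining trees with
  Newick/GraphML output.

**Simulators**: skewed-sire-usage pedigrees, gene dropping with
recombination and labelled founder haplotypes (realized autozygosity and IBD
tracts as ground truth), and a Wright–Fisher population with known true
N<sub>e</sub>.

## Worked example

```r
library(canidiv)

# a synthetic breed: 16 founders, five generations with popular-sire skew,
# gene-dropped onto a chip-density genome
ped <- simulate_pedigree(n_founders = 16, n_generations = 5, n_per_gen = 30,
                         sire_skew = 0.3, seed = 71)
cfg <- genome_config(n_chromosomes = 6, chrom_length_bp = 3e7,
                     n_markers = 10000, missing_rate = 0.002)
gd  <- gene_drop(ped, cfg, seed = 72)

genotyped <- ped$records$id[(ped$n - 29):ped$n]     # the last generation
g <- gd$genotypes
keep <- match(genotyped, g$samples$iid)
g <- genotype_matrix(g$calls[keep, ], g$map, g$samples[keep, ])

report <- full_run(ped, g, ne_bins = 500, network_k = 6,
                   autosomes = as.character(1:6))
report
```

```
Genealogical diversity report
  reference population: 110 animals, mean F = 0.0992
  EqG = 3.01 +/- 1.70
  generation interval l = 3.00 years
  f = 10, fe = 5.6, fa = 5.6
  delta F = 0.0398 (3.98%/generation), Ne = 12.6
Molecular diversity report
  post-QC: 30 samples x 8394 markers
  mean MLH = 0.3682, mean F(het) = -0.0201
  ROH: 248 segments; % genome >1Mb = 17.15
  LD Ne = 3.1
  network: 4 cluster(s)
Pedigree-molecular inbreeding correlation:
   estimator  n         r      p_value
       F_het 30 0.6434229 0.0001253179
 F_ROH_gt1Mb 30 0.6157062 0.0002925610
```

Reading the output: heavily skewed sire usage in a tiny founder base has
pushed the effective founder number (5.6) well below the founder count (10,
the founders actually contributing to this reference population) and driven
an inbreeding rate near 4% per generation, a realized N<sub>e</sub> of about
13. The final generation's genotypes carry the matching molecular signal —
about 17% of the genome in runs of homozygosity over 1 Mb — and
per-individual molecular inbreeding correlates strongly with pedigree F, as
expected when the pedigree is fully recorded. (The LD-N<sub>e</sub> on one
small sibling-rich cohort is a noisy, downward-biased point estimate; the
Wright–Fisher validation in the acceptance script measures the estimator
under its own assumptions.) `write_report(report, "out/")` emits the per-animal and
summary TSVs, the network (GraphML + edge/node tables), the Newick tree and
a JSON summary.

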