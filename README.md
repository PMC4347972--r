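# broadHMM

Differential analysis of histone modifications with broad genomic
footprints.

Repressive chromatin marks such as H3K27me3 and H3K9me3 form diffuse
domains spanning many kilobases at low read density, where peak callers
built for sharp point-source signals produce unreliable calls. broadHMM is
for epigenomics researchers who need to segment such broad-mark ChIP-seq
signal into modified/unmodified domains in one sample, or to compare two
samples (strains, sexes, cell lines) and obtain probabilistic calls of
regions that are *modified in both*, *unmodified in both*, or
*differentially modified*.

## The model

Reads are reduced to their start positions and counted in 1000 bp bins;
each sample's counts are truncated at the genome-wide 0.999 quantile. The
per-bin counts of one sample follow a two-component mixture

&nbsp;&nbsp;&nbsp;&nbsp;*P(x | θ) = α f(x, θ₀) + (1 − α) f(x, θ₁)*,

with zero-inflated negative binomial components

&nbsp;&nbsp;&nbsp;&nbsp;*f(x, (r, p, β)) = β·I(x = 0) + (1 − β)·Γ(r + x)/(Γ(r)·x!) · pʳ(1 − p)ˣ*,

fitted by EM (median-split initialization, one training chromosome). The
two component densities become the fixed emissions of a 2-state HMM;
Baum–Welch estimates transitions, the forward–backward algorithm gives
per-bin posteriors, and bins with P(modified) > λ = 0.5 are called
modified.

For two samples, the hidden state is the pair (a, b) of per-sample
modification indicators — a 4-state HMM. Each state's bivariate count
emission couples the corresponding ZINB margins through a Gaussian copula:
counts map to normal scores *z = Φ⁻¹(F(x))*, the state covariance
Σ<sub>a,b</sub> is the sample covariance of these scores over bins with
high-confidence (> 0.9) univariate calls in both samples, and

&nbsp;&nbsp;&nbsp;&nbsp;*P(X = x, Y = y)* = ∫∫ φ<sub>Σ</sub>(z_x, z_y) dz_x dz_y

over the rectangle between consecutive transformed CDF values, evaluated
with the Genz bivariate-normal algorithm. Bins are classified by maximal
posterior state; differential regions are the A-only and B-only states.

See the methods vignette
(`vignettes/broad-domain-differential-calling.Rmd`) for assumptions,
parameter rationale and numerical details.

## Worked example

Simulate a two-sample pair with planted four-state truth under the demo
conditions (2 chromosomes × 5000 bins, domain self-transition 0.95,
component means ≈ 2.7 and 25, copula correlation 0.5 in concordant
states), then run the differential caller:

```r
library(broadHMM)
spec <- simulationSpec(seed = 42)
sim  <- simulateBivariate(spec)
res  <- callDifferential(sim$trackA, sim$trackB)

res$singleA$mixture
#> UnivariateMixture for sample 'simA'
#>   alpha (unmodified weight): 0.5229
#>   theta0 (unmodified): r=1.861 p=0.363 beta=0.1135 mean=2.896
#>   theta1 (modified):   r=5.102 p=0.1656 beta=0 mean=25.712
#>   EM: 49 iterations, final loglik -17842.70

res$bivariate
#> BivariateMixture with components (a,b):
#>   00: rho=0.450 weight=0.249 support=2426
#>   11: rho=0.475 weight=0.210 support=2042
#>   10: rho=0.007 weight=0.287 support=2789
#>   01: rho=-0.018 weight=0.254 support=2477
```

The univariate fit recovers the generating mixture (means 2.9 and 25.7
against true ≈ 2.7 and 25), and the copula correlations of the concordant
states land near the simulated 0.5. The estimated 4-state transition
matrix has ≈ 0.95 self-transitions, matching the planted domain
persistence. Region calls are a `GRanges` partition of the genome:

```r
head(res$regions, 3)
#> GRanges object with 3 ranges and 4 metadata columns:
#>       seqnames      ranges strand |      state     nBins meanPosterior maxPosterior
#>   [1]     chr1     1-16000      * | unmod-both        16      0.999849     1.000000
#>   [2]     chr1 16001-22000      * | mod-B-only         6      0.999955     0.999998
#>   [3]     chr1 22001-42000      * | unmod-both        20      0.995198     1.000000

tapply(width(res$regions), mcols(res$regions)$state, sum) / 1e6
#> unmod-both   mod-both mod-A-only mod-B-only
#>       2.48       2.11       2.87       2.54

mean(res$labels == sim$states)
#> [1] 0.995
```

99.5% of bins are classified into the correct planted state. Exporters
write per-state BED files (score = 1000 × mean posterior), a combined
GFF3 and per-state posterior bedGraph tracks
(`exportRegions()`, `exportPosteriorBedGraph()`).

A thin command-line front end covers the same workflows for BAM/BED input
or count tables:

```sh
exec/broadhmm call-regions      --bam sample.bam --chrom-sizes genome.txt --out out/
exec/broadhmm call-differential --sample-a a.bam --sample-b b.bam \
                                --chrom-sizes genome.txt --confidence 0.9 --out out/
exec/broadhmm simulate          --out sim/ --seed 1
```

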