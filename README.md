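# mdfa

Single- and multichannel **detrended fluctuation analysis** (DFA / mDFA)
for uniformly sampled biomedical time series, built for the kind of
multichannel electrophysiology where the question is not only *"does each
channel carry long-range temporal correlations?"* but *"how correlated is
the ensemble as a whole, and what happens to it when the channels are
decoupled?"* — e.g. spontaneous cord dorsum potentials recorded over
several spinal segments before and after a partial lesion of the
connecting pathways.

## The statistics

**DFA.** Integrate the mean-removed series into a profile
`y(k) = Σ_{i≤k} (x(i) − ⟨x⟩)`, cut it into `⌊N/n⌋` boxes of size `n`,
remove a per-box least-squares polynomial of degree `m` (m = 1 classical,
general m = "DFAm"), and pool the residuals:

    F(n) = sqrt( (1/N') Σ [y(k) − y_n(k)]² ),   N' = n⌊N/n⌋.

The scaling exponent `α` is the OLS slope of `log10 F(n)` vs `log10 n`:
α = 0.5 uncorrelated, α > 0.5 persistent long-range correlation,
α ≈ 1 for 1/f noise.

**mDFA.** For d aligned channels: integrate and detrend each channel
separately on one shared box partition and pool squared residuals across
channels,

    F(n) = sqrt( (1/(N'·d)) Σ_c Σ_k [y_c(k) − y_{c,n}(k)]² ),

giving a single ensemble exponent. The 1/(N'·d) normalization makes d = 1
reduce exactly to DFA, makes channel duplication/permutation a no-op, and
gives the pooling identity `F(n)² = mean_c F_c(n)²`.

Around the core sit shuffle surrogates (randomization control → α ≈ 0.5),
Welch magnitude-squared coherence (the pairwise cross-check), paired
comparison of fluctuation curves across conditions, and a seeded synthetic
generator: white noise, exact fractional Gaussian noise (circulant
embedding), 1/f noise, and coupled CDP-like multichannel ensembles whose
ground-truth coupling matrix can be "lesioned"
(`apply_lesion()` attenuates chosen edges). See the methods vignette
(`vignettes/mdfa-methods.Rmd`) for assumptions, parameter defaults, and
limitations.

## Worked example

```r
library(mdfa)

# 1. A known-H validation: DFA on fractional Gaussian noise, H = 0.9
dfa(gen_fgn(0.9, 2^17, seed = 42))
#> <dfa result> alpha = 0.8925, R^2 = 0.9990 over n in [6, 29226] (m = 1)

# 2. A coupled 4-channel CDP-like ensemble and its ensemble exponent
cs <- coupling_spec(4, 0.9, labels = c("L5L", "L5R", "L6L", "L6R"))
mc <- gen_coupled_multichannel(cs, "one_over_f", n = 2^16, seed = 42)
mdfa(mc)
#> <mdfa result> alpha = 0.9850, R^2 = 0.9991 over n in [6, 14613] (m = 1)

# 3. Randomization control: shuffling destroys the correlations
mdfa(shuffle_multichannel(mc, seed = 43))
#> <mdfa result> alpha = 0.5102, R^2 = 0.9997 over n in [6, 14613] (m = 1)

# 4. Simulated sequential lesions decouple the segments
run_lesion_demo(n = 2^16, seed = 42)
#> <lesion_demo_report>
#>   baseline     pooled mDFA alpha = 0.9817 (R^2 = 0.9990)
#>   lesion_left  pooled mDFA alpha = 0.9497 (R^2 = 0.9981)
#>   lesion_right pooled mDFA alpha = 0.8949 (R^2 = 0.9955)
#>   lesion_left vs baseline: t = -3.40, reduction p = 0.000707
#>   lesion_right vs baseline: t = -5.77, reduction p = 3.4e-07
```

Reading the numbers: the fGn run recovers its prescribed Hurst exponent
(0.89 vs 0.9) with an essentially straight log–log fluctuation curve
(R² = 0.999). The strongly coupled ensemble inherits the 1/f character of
its shared source (α ≈ 0.98); shuffling collapses it to the randomness
point (α ≈ 0.51). Each simulated lesion attenuates coupling edges across
the L5/L6 boundary, whitening the affected channels, so the pooled
ensemble exponent falls stage by stage and the reduction-tail comparison
of the fluctuation curves flags both lesions.

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "mdfa-cli.R", package = "mdfa"))')
Rscript $CLI simulate --source coupled --n 65536 --k 4 --coupling 0.9 --seed 1 --out rec.tsv
Rscript $CLI mdfa --input rec.tsv --out result.json
Rscript $CLI coherence --input rec.tsv --channels ch1,ch2 --band 0.3,10 --out coh.json
Rscript $CLI lesion-demo --seed 1 --out demo.json
```

Recordings are delimited text (header row = channel labels) with the
sampling rate in a JSON sidecar or a `# sampling_rate: <Hz>` first line;
results are JSON at full double precision, with every reported exponent
carrying its R² and fit range.

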