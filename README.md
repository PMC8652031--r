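# cycletope

Topology-based detection of cycling transcripts in circadian time-series
transcriptomics.

## What it does, and for whom

Circadian experiments profile gene expression every 1–4 h over 36–96 h and
ask which of ~10⁴ transcripts oscillate with a ~24 h period. cycletope is
for analysts of such bulk (or pseudobulked single-cell) time courses who
want a *template-free* rhythmicity test: no cosinor shape assumptions, a
biologically constrained permutation null, and support for replicates,
uneven sampling and missing data.

## The statistic at its core

A rhythmic signal traces a closed loop in state space. For each gene
\(x_t\) (replicate-averaged, imputed, standardized), cycletope:

1. embeds the series in \(\mathbb{R}^3\) as points
   \((x_t,\, x_{t-\tau},\, x_{t-2\tau})\) (Takens' delay embedding);
2. projects to \(\mathbb{R}^2\) with Laplacian Eigenmaps (symmetric kNN
   graph, heat-kernel weights, eigenvectors of the 2nd/3rd smallest
   eigenvalues of the symmetric normalized Laplacian), which keeps the
   loop and discards drift;
3. scores circularity as the maximum H1 persistence of the Vietoris–Rips
   filtration, \(\mathrm{pers} = \epsilon_{death} - \epsilon_{birth}\)
   (radius scale), averaged over a sweep of lags \(\tau \in \{2,3,4,5\}\);
4. compares the score to a shared null built by permuting each series'
   finite differences (preserving the marginal distribution of expression
   changes, i.e. attainable transcription/degradation rates):
   \(p = (1 + \#\{s_{null} \ge s_{obs}\}) / (1 + n_{resamples})\),
   followed by Benjamini–Hochberg FDR.

Period, phase and amplitude are estimated separately from a joint
least-squares fit of a line plus the three dominant DFT harmonics of the
*unscaled* series (see the methods vignette).

## Worked example

```r
library(cycletope)

# a benchmark dataset: 2-h/48-h sampling, one replicate, 10% noise,
# 100 genes per waveform family (7 cyclic + 4 non-cyclic families)
ds  <- simulate_dataset(sampling_spec(2, 48, 1, 0.1),
                        n_per_shape = 100, seed = 11)
res <- cycletope(ds$data, cycle_config(resamples = 1000, seed = 5))
head(res[order(res$pVal), ], 3)
#>        gene persistence     pVal     qVal period  phase amplitude
#> 1 sine_0001      0.1679 0.000999 0.003829     24  5.885     1.533
#> 3 sine_0003      0.1495 0.000999 0.003829     24 10.645     2.755
#> 4 sine_0004      0.1589 0.000999 0.003829     24  6.265     3.271

rc <- roc_auc(-log10(res$pVal), ds$labels$is_cyclic)
rc$auc
#> [1] 0.9015946
```

`persistence` is the lag-averaged maximum H1 persistence of the gene's
embedding — larger means more circular, i.e. more rhythmic. `pVal` is its
tail probability under the finite-difference permutation null (here
bounded below by 1/1001), `qVal` the BH-adjusted value; `period`/`phase`
(hours) and `amplitude` (expression units) come from the harmonic fit. The
AUC of 0.90 is the probability that a random cyclic gene outranks a random
non-cyclic one at this sampling scheme and noise level, matching the
published benchmark level for 2-h/48-h sampling.

Command line:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "cycletope", package = "cycletope"))')
Rscript $CLI simulate --interval 2 --length 48 --replicates 1 --noise 0.1 \
                      --n-per-shape 100 --seed 11 --out sim.tsv
Rscript $CLI run      --input sim.tsv --output results.tsv --resamples 1000 --seed 5
Rscript $CLI evaluate --results results.tsv --labels sim.tsv.labels.tsv --out eval.tsv
```

## Layout

- `R/`, `src/` — pipeline (preprocessing, embedding, eigenmaps, Rips H1,
  permutation inference, rhythm parameters), synthetic benchmark, ROC
  evaluation, CLI; the numerical kernels are C++.
- `tests/testthat/` — unit + property tests, a brute-force persistence
  oracle, and `test-acceptance.R` with the acceptance criteria.
- `vignettes/cycletope-methods.Rmd` — model, assumptions, parameter
  choices, generator details, limitations.
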