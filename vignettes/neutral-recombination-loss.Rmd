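---
title: "Neutral loss of recombination around a sex-determining locus: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neutral loss of recombination around a sex-determining locus: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nrrsim)
```

## The model

`nrrsim` simulates a single stretch of DNA of length $L$ (default 100 kb) in
a dioecious Wright--Fisher population of $N$ diploids with non-overlapping
generations and an XY sex-determination system: a single nucleotide midway
along the sequence (the SD locus, position $L/2$) is heterozygous (X/Y) in
every male and homozygous (X/X) in every female.  There is no selection of
any kind.  Neutral point mutations arise at per-site rate $\mu$ per gamete
per generation; crossovers occur with per-site baseline probability $r$ per
meiosis.

The single mechanistic ingredient beyond the standard neutral model is that
sequence divergence suppresses recombination locally, as it does in real
meioses through homology search and mismatch repair.  In each meiosis the
per-position crossover probability is

$$ r_i = r_{0i}\,\Bigl(1 - \frac{E\,h}{W}\Bigr), $$

clamped at zero, where $r_{0i}$ is the ancestral (baseline) probability at
position $i$, $h$ is the number of sites at which the individual's two
haplotypes differ inside the window of width $W$ centred on $i$, and $E$ is
the suppression strength: each heterozygous site removes a fraction $E/W$
of the local baseline.  With the defaults $E = 30$, $W = 1000$ a single
heterozygous site lowers the local rate by exactly 3%, and recombination
stops completely once divergence inside the window reaches $1/E \approx
3.3\%$.  Because the SD locus itself is permanently heterozygous in males,
its neighbourhood starts every male meiosis with $h \ge 1$: divergence
accumulated in linkage with the SD feeds back into less recombination,
which permits more divergence — the engine of the process.

The **non-recombining region (NRR)** is the maximal contiguous interval
containing the SD position in which $r_i = 0$ for every in-scope meiosis.
The key emergent quantities are the NRR size over time, the
within-individual divergences $d_{XX}$ (females) and $d_{XY}$ (males), and
the per-position male--female $F_{ST}$.

## Parameters and defaults

| Parameter | Meaning | Default | Units |
|---|---|---|---|
| `N` | diploid population size | 100 | individuals |
| `L` | sequence length | 100 000 | bp |
| `mu` | sex-averaged mutation rate | 7.5e-6 | /site/gamete/generation |
| `r` | baseline recombination probability | 1e-7 | /site/meiosis |
| `E` | suppression per heterozygous site | 30 | — |
| `W` | suppression window | 1000 | bp |
| `mmb` | male/female mutation-rate ratio | 1 | — |
| `generations` | run length | 20 000 | generations |
| `record_interval` | statistic cadence | 100 | generations |
| `n_replicates` | replicate runs averaged | 25 | — |

The defaults are the reference condition of the published sweeps: they give
the population-scaled rates $\theta = 4N\mu = 3\times10^{-3}$ and $\rho =
4Nr = 4\times10^{-5}$, typical eukaryotic values, and a 1 cM linkage map
($r \cdot L = 0.01$ expected crossovers per meiosis).  `r` is a *per-site*
probability; the printed map lengths only come out right under that
reading, so the package treats the genome-wide crossover rate as $\sum_i
r_{0i}$.

Male mutation bias is applied with the sex-averaged rate held fixed:
$\mu_m = 2\,\mathrm{mmb}\,\mu/(1+\mathrm{mmb})$ and $\mu_f =
2\mu/(1+\mathrm{mmb})$, so changing `mmb` redistributes mutation input
between the sexes without changing its total.

## Ancestral recombination landscapes

Three spatial patterns of $r_{0i}$ are available; all conserve the global
mean over sexes and positions exactly, so they redistribute recombination
without changing its amount:

* **uniform** — both sexes constant at $r$;
* **heterochiasmatic** — female uniform; male follows a raised cosine
  $r\,(1 + a\cos(2\pi i/L))$, highest at the sequence ends and lowest at
  the centre, where the SD sits.  The published description fixes only the
  qualitative shape (male rate high at the ends, low at the centre); the
  raised cosine is the simplest smooth symmetric profile with an exactly
  preserved mean, with the amplitude $a$ (default 0.9) configurable;
* **hotspot/coldspot** — both sexes follow $r\,(1 + a\sin(2\pi k i/L))$
  with $k$ full periods (default $k = 10$, i.e. alternating 5 kb hot and
  cold bands at the default $L$), again with configurable amplitude.

## Mutation placement and collision policies

Mutation counts per gamete are Poisson with mean $\mu_{\text{sex}} L$
(exactly the thinned-process limit at $\mu \ll 1$, and $O$(#mutations)
cost); positions are uniform.  Under the default `reallocate` policy a
draw landing on a currently polymorphic position — including the SD — is
redrawn until it hits a monomorphic one; under `discard` it is dropped.
Both keep every site biallelic.  "Polymorphic" means segregating in the
parental population; sites that reach fixation in all $2N$ haplotypes are
flipped to the ancestral state and freed for future mutation.  The two
policies produce statistically indistinguishable NRR trajectories at the
simulated scales (the test suite checks this), because the polymorphic
fraction of the sequence stays small.

Mutations are applied to each transmitted gamete *after* crossover
sampling: a new mutation is heritable but cannot influence the meiosis
that created it.  Each transmitted gamete mutates independently.

## The generation loop

Each of the $N$ offspring draws a mother and a father uniformly with
replacement; each parent contributes one gamete from its own
heterozygosity-modified meiosis; the offspring's sex is whatever its
paternal gamete carries at the SD.  Under the default `fixed_equal` mode
the paternal meiosis is resampled until the SD allele required for an
exactly equal sex ratio is transmitted — this conditions only the
transmitted SD allele and leaves the within-class gamete distribution
untouched, while preventing the stochastic loss of a sex in the small
populations simulated.  A `binomial` mode with unconditioned sexes is
available; it errors out if a sex goes extinct.

Crossover placement treats every position as an independent Bernoulli
trial with probability $r_i$ (no interference; with $\sum_i r_i \approx
0.01$ double crossovers are already rare).  Suppression therefore lowers
the total crossover rate rather than moving crossovers elsewhere — an NRR
is only meaningful if events cannot occur inside it.  The alternative
semantics (constant total rate, positions redistributed in proportion to
the suppressed profile) is kept behind
`suppression_semantics = "redistribute"` for sensitivity analysis.

### Numerical implementation

The engine (C++ via Rcpp) stores haplotypes sparsely as sorted
derived-allele positions.  The window count $h(i)$ is piecewise constant
between the window edges of the heterozygous sites, so each meiosis works
on $O(k)$ segments rather than $L$ positions.  Breakpoints are sampled
exactly: one homogeneous Binomial$(L, r_{\max})$ candidate draw per
meiosis, thinned by $f(i)\,r_{0i}/r_{\max}$ — an exact per-position
Bernoulli field that costs essentially one RNG call when no candidate
occurs.  The window-segment decomposition, the dense R reference
implementations, and a naive $O(LW)$ literal oracle are cross-checked
against each other in the test suite.  All randomness flows through R's
RNG; a run is bit-for-bit reproducible from its seed, and replicate seeds
are `base_seed + 0:(k-1)`.

## Statistics

* `nrr_size`: length of the maximal interval around the SD with $r_i = 0$
  for all in-scope meioses, each evaluated against its sex's own baseline
  vector.  A position with zero baseline counts as non-recombining.
* `divergence_means`: $d_{XY}$ ($d_{XX}$) is the mean across males
  (females) of the fraction of the $L$ positions at which the individual's
  haplotypes differ.
* `fst_profile`: Hudson-style estimator from haplotype allele frequencies,
  $F_{ST} = (H_b - H_w)/H_b$ with $H_b = p_m(1-p_f) + p_f(1-p_m)$ and
  $H_w = p_m(1-p_m) + p_f(1-p_f)$, defined as 0 where $H_b = 0$.  It was
  chosen for its insensitivity to sample-size corrections at $N = 100$; at
  the SD it equals $0.5$ identically.
* `pairwise_diversity`: mean pairwise differences per site within the X
  pool (female haplotypes plus male X), the Y pool, or all haplotypes.

### Scope of the NRR criterion

The published definition reads "recombination probabilities ... reached
zero in the entire population".  Taken literally over all meioses it can
never be satisfied: female X--X heterozygosity near the SD stays at the
neutral background $\pi \approx 3N\mu$ (2--3 heterozygous sites per kb
window at the default rates), far below the $W/E \ge 34$ sites needed to
zero a female meiosis, so an all-meioses NRR is identically 0 at every
parameter combination explored — while the published NRR grows to many kb.
The dynamics are those of the male (X--Y) meioses, so `nrrsim` defaults to
`nrr_scope = "males_only"` and keeps `"all_individuals"` as an option; the
suite verifies that the males-only NRR always bounds the all-individuals
one from above.

## Window-edge conventions

Windows are the half-open integer interval $[i - \lfloor W/2 \rfloor,\,
i + W - \lfloor W/2 \rfloor)$, clipped to the sequence, but the
denominator in $E h/W$ is always $W$: one heterozygous site reduces $r_i$
by exactly $E/W$ (the 3% anchor) even at the sequence ends.  A crossover
"at position $i$" separates positions $i-1$ and $i$; coordinates are
0-based throughout.

## What the simulations emulate — and what they do not

The generator reproduces the study conditions: small populations
($N = 50$--$200$), a 100 kb neutral sequence, rates tuned so that
$\theta$ and $\rho$ are eukaryote-typical, and 25-replicate averaging.
Real sex chromosomes differ in ways the model deliberately ignores:
structural variants and inversions (which suppress recombination far more
strongly than point mutations), motif-dependent hotspot loss,
transposable-element silencing, crossover interference, gene conversion,
the L-shaped (rather than linear) divergence--recombination relationship
at high divergence, demography and selection of any kind.  Passing tests
therefore show that the *neutral feedback mechanism* behaves as described,
not that it is the mechanism operating in any particular natural system.

## Desk-scale experiment design

The full published sweeps (100 kb, 10--30 thousand generations, 25
replicates) are reproduced in direction rather than magnitude by
desk-scale runs chosen once as $L = 10$ kb, 2000 generations, 20
replicates, with per-site rates and $W$ unchanged so the local dynamics
around the SD are preserved (`scale_params()` implements this
convention).  The trend experiments in the test suite use mutation and
recombination rates at the ends of the published grids
($\mu \in \{10^{-6}, 10^{-5}\}$, $r \in \{10^{-7}, 10^{-6}\}$) so that the
contrasts are resolvable within 2000 generations; the population-size
contrast holds $\theta = 3\times10^{-3}$, $\rho = 4\times10^{-5}$ fixed at
$N = 50$ vs $N = 100$.  For the heterochiasmy comparison a mean rate of
$r = 5\times10^{-7}$ is used: at $r = 10^{-7}$ recombination near the SD
is already too rare for the landscape to matter over 2000 generations at
this $L$.  For the strata experiment the sinusoid is given $k = 2$ periods
at $L = 10$ kb (2.5 kb bands) so that the band width stays well above the
1 kb suppression window, preserving the full-scale geometry (5 kb bands vs
a 1 kb window); with $k = 10$ at desk scale the 500 bp bands would be
below the resolution of the suppression process itself.  The male--female
$F_{ST}$ is then compared between the coldspot band flanking the SD on one
side and the hotspot band flanking it on the other (each excluding the
SD's own window).

The effective-size check runs paired sex-linked and autosomal populations
with no recombination and no mutation bias ($N = 50$, $L = 2$ kb,
$\mu = 10^{-4}$), discards a burn-in of $20N$ generations (several
coalescent timescales) and averages diversity over the following 2000
generations; with 100 replicate pairs the X/autosome and Y/autosome
diversity ratios come out near their census expectations of 3/4 and 1/4.
The autosomal control allows selfing (classic Wright--Fisher), so its
expected diversity is exactly $\theta = 4N\mu$.

## A worked example

```{r example, eval = FALSE}
p <- sim_params(N = 100, L = 10000, mu = 1e-5, r = 1e-7,
                generations = 2000, seed = 11)
res <- run(p)
tail(res$records, 3)
reps <- run_replicates(p, n_replicates = 10)
plot_nrr_timeseries(reps)
```

With these settings a males-only NRR of roughly a kilobase typically
emerges within 2000 generations, while $d_{XY}$ climbs far above $d_{XX}$
— the signature of gametolog divergence without any selection.

## Known limitations

* The linear suppression rule is a first-order stand-in for the empirical
  divergence--recombination curve; rare crossovers at high divergence
  (which would slow NRR expansion) are not modelled.
* Populations above a few hundred individuals are slow to equilibrate at
  the simulated rates; extrapolation to natural effective sizes is a
  matter of scaling arguments, not simulation output.
* The infinite-sites approximation degrades once a noticeable fraction of
  positions segregates (reallocation then concentrates input on
  monomorphic sites); at the default rates the segregating fraction stays
  below ~1%.
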