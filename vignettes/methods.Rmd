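---
title: "Model and methods behind phescan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods behind phescan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

A phenome-wide association study (PheWAS) asks whether one genetic variant —
here called the *query variant*, a SNP whose causal effect on some *primary
trait* is already established by fine-mapping or functional evidence — is
associated with each of hundreds or thousands of *query traits*. Conventional
PheWAS thresholds the query variant's p-value after multiplicity correction.
That test cannot distinguish a genuine causal effect of the query variant from
*LD confounding*: a small p-value produced by correlation with a nearby causal
variant. phescan replaces the marginal test with a regional Bayesian
comparison of three hypotheses for each (query variant, query trait) pair:

* **Hn** — no variant in the region is causal for the query trait;
* **Ha** — some variant other than the query variant is causal;
* **Hc** — the query variant itself is causal.

Under a single-causal-variant assumption a region of $Q$ SNPs admits $Q+1$
*configurations* (no causal variant, or causal at SNP $j$), partitioning into
the three hypotheses: one configuration for Hn, $Q-1$ for Ha, one for Hc.

# Evidence: per-SNP Bayes factors

For SNP $j$ with effect estimate $\hat\beta_j$, sampling variance $V_j$
(so $z_j = \hat\beta_j/\sqrt{V_j}$) and a $N(0, W)$ prior on the true
effect, the Wakefield approximate Bayes factor against the null is

$$\log \mathrm{ABF}_j \;=\; \tfrac12\left[\log\frac{V_j}{V_j+W}
  + z_j^2\,\frac{W}{V_j+W}\right],$$

the log ratio of the marginal likelihoods $N(\hat\beta_j; 0, V_j+W)$ and
$N(\hat\beta_j; 0, V_j)$. Defaults $W = 0.2^2$ (case-control, log odds-ratio
scale) and $W = 0.15^2$ (quantitative, standardized scale) are the
conventional values in the colocalisation literature; they are assumptions,
not estimates, and are exposed through `effect_prior()`. When `se` is absent,
$V_j$ falls back to the design approximation
$1/(2f_j(1-f_j)\,n\,s(1-s))$ (case-control) or $1/(2f_j(1-f_j)\,n)$
(quantitative), with $f_j$ the MAF, $n$ the sample size and $s$ the case
fraction. All Bayes factor arithmetic is kept on the natural-log scale with
log-sum-exp reductions; posteriors stay finite for $|z|$ well beyond 40.

When several causal variants are plausible, `susie_rss()` replaces the single
ABF row by a minimal sum-of-single-effects decomposition on the RSS
likelihood $z \sim \mathrm{MVN}(R\lambda, R)$: iterative Bayesian stepwise
selection fits up to `L_max` single effects, each a Wakefield single-SNP
regression on residualized z-scores with its prior variance chosen by
maximum marginal likelihood over a fixed grid that includes 0 (so an effect
can switch itself off). An effect is retained only if its credible set
(smallest SNP set reaching `coverage` posterior mass, default 0.95) has
purity — minimum absolute pairwise LD among members — of at least
`min_purity` (default 0.5; singletons count as pure). Each retained signal
contributes its own row of per-SNP log Bayes factors, scored independently
downstream. These defaults follow fine-mapping ecosystem conventions; the
source publications for this class of scan do not print theirs.

**Fallback.** When no credible set survives, the scan falls back to the
single ABF row rather than dropping the region. We apply the fallback
unconditionally (no extra p-value screen): a region with no detectable
signal scores essentially identically under both Bayes factor modes and
lands on Hn, so the only effect of the unconditional rule is that every
testable region remains scorable. This was a genuinely open design point.

# Priors and posteriors

With prior mass $p_n$ on Hn, $p_a$ on each non-query configuration and
$p_c$ on the query configuration, $p_n + (Q-1)p_a + p_c = 1$, the
per-signal posterior masses are

$$m_n = p_n,\qquad
  m_a = p_a \sum_{j \ne q} \mathrm{BF}_j,\qquad
  m_c = p_c\, \mathrm{BF}_q,$$

normalized to give $(\mathrm{ppHn}, \mathrm{ppHa}, \mathrm{ppHc})$. Traits
are called **Hc** when $\mathrm{ppHc} > 0.6$ for at least one signal, else
**Hn** when $\mathrm{ppHn} > 0.2$ for some signal (deliberately conservative
about ruling out pleiotropy), else **Ha**, reporting the signal with minimum
ppHa. Among several Hc signals the maximal-ppHc one is reported. The 0.6 and
0.2 thresholds are the published operating point at which the internal FDR
estimate stays below 0.05 in large simulations; both are arguments
everywhere they appear.

The internal FDR estimate at threshold $t$ is
$1 - \mathrm{mean}(\mathrm{ppHc} \mid \mathrm{ppHc} > t)$ — the expected
fraction of false Hc calls if the posteriors are calibrated. It is an
*internal* diagnostic; the simulation benchmark also reports the external
(true-label) FDR, which counts calls whose simulated truth is Hn/Ha/Ha2.

# Hierarchical priors

Fixed priors require the analyst to guess how enriched the query variant set
is for real effects. phescan instead learns the priors from all tested
regions jointly. The parametrization is a softmax over the $Q+1$
configurations with the null as reference:

$$p_a = e^\alpha / D_x,\qquad
  p_c = e^{\alpha+\beta+\gamma x} / D_x,\qquad
  p_n = 1 / D_x,$$

with $D_x = 1 + (Q-1)e^\alpha + e^{\alpha+\beta+\gamma x}$ and $x$ an
optional per-trait covariate (we use the genetic correlation $r_g$ between
the query and primary traits, signed and untransformed — the covariate's
effect is expected to be directional). The constraint holds by construction
and $p_c/p_a = e^{\beta+\gamma x}$, making $\beta$ a direct log-enrichment
of the query variant. The marginal likelihood of the dataset is the product
over (region, signal) of $p_n + p_a\sum_{j\ne q}\mathrm{BF}_j +
p_c\,\mathrm{BF}_q$; multiple SuSiE signals from one region enter as
independent factors (an open point in the source method; parameter-recovery
tests back this reading at the scales we simulate).

Sampling is random-walk Metropolis on $(\alpha, \beta, \gamma)$ with
Gaussian proposals and weakly informative hyper-priors
$\alpha \sim N(-10, 5^2)$, $\beta \sim N(0, 5^2)$,
$\gamma \sim N(0, 2^2)$ — centred on plausible per-SNP scales
($e^{-10} \approx 5\times10^{-5}$ per SNP) but diffuse enough to move
several orders of magnitude. A single global proposal scale is adapted
towards 30% acceptance *only during the burn-in window* and frozen before
any retained-and-averaged sample is drawn, preserving detailed balance where
it matters. The default schedule (30000 iterations, thin 30, discard the
first 50% of the retained chain) is a 1/10 scaling of the production
schedule used at phenome scale (3e5 iterations without a covariate, 1e6
with); region priors and hypothesis posteriors are averaged over the
post-burn-in samples. Acceptance rates outside $[0.05, 0.8]$ set a mixing
warning on the result, mirroring diagnostics needed for weakly enriched
variant sets in practice. The proposal stream always draws three increments
per iteration, so pinning $\gamma = 0$ reproduces the no-covariate model
bit-for-bit on the same seed.

Averaged $(p_a, p_c)$ can be exported and reused as fixed priors for small
follow-up datasets, where a hierarchical fit would be under-informed.

# The simulation benchmark

`build_benchmark_dataset()` emulates the published evaluation design without
external downloads. Five trait classes — Hn (no causal variant), Ha/Ha2
(one/two causal non-query variants), Hc (query causal), Hc2 (query plus one
other causal) — are simulated as regional case-control summary statistics of
10000 cases and 10000 controls via the multivariate-normal z-score model:
$\lambda_m = \gamma_m\sqrt{2f_m(1-f_m)\,n\,s(1-s)}$ at causal SNPs,
$z \sim \mathrm{MVN}(R\lambda, R)$. Reference-panel haplotypes are replaced
by parametric LD: the default template is block-diagonal AR1 (blocks of 25
SNPs, $\rho = 0.95$), so a randomly placed non-query causal variant has a
realistic chance of being a strong LD proxy of the query variant — the
mechanism that makes conventional PheWAS fail. MAFs are uniform on
$(0.01, 0.5]$; causal $|\gamma| \sim U(0.08, 0.25)$ with random sign (the
publication does not print its effect-size distribution; this range gives
non-centralities roughly 1–11 at the default design, i.e. a realistic mix
of underpowered and well-powered traits). Two-causal scenarios resample
until the causal pair has $|r| < 0.95$. The covariate generator draws
$r_g$ from truncated normals on $[-1,1]$ (sd 0.25) centred at 0.5 for
Hc/Hc2 and at 0 otherwise. The desk-scale default is $Q = 200$ with class
counts 8805/470/470/628/628 — 1/10 of the production design with
proportions preserved.

What a green benchmark does **not** establish: real LD is not block-AR1
(long-range and irregular LD change the proxy-rate geometry); effect sizes,
MAF spectra and case fractions vary across real phenotypes; summary
statistics from biobank regressions carry rare-event bias the simulator
does not model; and out-of-sample LD panels degrade the SuSiE decomposition
in ways the in-sample simulation cannot show.

One scale interaction is worth recording. The irreducible false positives
of this scan are Ha traits whose causal SNP is a near-perfect LD proxy
($|r| > 0.9$) of the query variant; their rate per Ha trait scales as
$1/Q$ for randomly placed causals. Robustness experiments that vary the
fraction of Hc traits therefore keep the production region size
$Q = 1000$: shrinking regions to desk scale would inflate exactly the
false-positive rate under study. The headline FDR benchmark, whose
acceptance contract fixes $Q = 200$, is unaffected because its internal
estimate is calibrated against its own world.

# Numerical choices and edge cases

* All hypothesis-mass arithmetic in log space; `lse3`/`logsumexp` guard
  overflow (tested to $|z| = 40$ and parameters at $\pm 300$).
* LD matrices are shrunk $(1-\varepsilon)R + \varepsilon I$ with
  $\varepsilon = 10^{-4}$ before factorization when they come from finite
  panels or composite construction; exact closed-form AR1 templates are
  left untouched so closed-form tests stay exact.
* `prior_set()` accepts $p_n$ rounding to exactly 1 (degenerate no-signal
  limit of the hierarchical map); everything else in $(0,1)$ strictly.
* The case allele count filter uses $2ns f$ as an approximation when the
  true count is absent from a summary dialect; pairs at or below 25 are
  flagged non-testable rather than silently dropped. Variants on chr6
  inside 20–40 Mb (HLA) are removed.
* Allele harmonization: ids are `chrom_pos_ref_alt` with alt as effect
  allele; a region variant matching the LD panel only under ref/alt swap
  has `z` and `beta` negated and adopts the panel id. Losing the query
  variant in alignment is a hard error.
* Empty credible-set SuSiE fits fall back to the ABF row (see above);
  duplicate credible sets from redundant effects are dropped.
* `estimate_fdr()` returns `NA` when nothing exceeds the threshold.
* Text round-trips write doubles as `%.17g`, so written datasets re-read
  bit-exactly.

# Known limitations

* Single ancestry; no cross-population LD handling.
* The covariate enters linearly on the log-odds of Hc; categorical
  covariates work via coding, but multivariate priors across correlated
  query traits are out of scope.
* The hierarchical model treats regions as exchangeable given $(Q, x)$;
  systematic per-trait power differences are absorbed into the Bayes
  factors, not the priors.
* Sensitivity degrades when the assumed maximum number of causal variants
  is exceeded, and misspecified query variants in strong LD with the true
  causal variant can still be called Hc — the proxy problem above — so
  variant sets should be fine-mapped, not merely clumped.
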