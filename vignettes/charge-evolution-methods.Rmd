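---
title: "Modelling myoglobin net surface charge evolution with mbcharge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling myoglobin net surface charge evolution with mbcharge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mbcharge)
```

## The problem

Semi-aquatic mammals carry myoglobins with an elevated net surface charge
(Z~Mb~): the extra positive charge is thought to permit higher muscle
myoglobin concentrations — and so larger oxygen stores — without
aggregation. Because Z~Mb~ is computable from primary structure alone, it
can serve as a molecular fossil: reconstruct ancestral myoglobin sequences
on a species tree, compute the charge at every node, and read off where
lineages became (or stopped being) divers. `mbcharge` implements that full
inference chain for eulipotyphlan-scale problems (shrews, moles, desmans,
solenodons), together with the discrete-trait analyses used to corroborate
it: parsimony origin counting, Bayesian threshold-model ancestral
lifestyles, a liability-correlation model linking Z~Mb~ to lifestyle, and a
PGLS calibration of electrophoretic mobility against computed charge.

## The charge model

Each ionizable group contributes a Henderson–Hasselbalch fractional charge
at pH $p$:

$$q_\text{acid} = \frac{-1}{1 + 10^{pK_a - p}}, \qquad
  q_\text{base} = \frac{+1}{1 + 10^{p - pK_a}},$$

and Z~Mb~ is the sum over Asp, Glu, His, Cys, Tyr, Lys, Arg side chains
plus the two termini. The working pH is 6.5 (the condition at which
reference electrophoretic mobilities are measured). The default pKa table
uses conventional free-residue constants (Asp 3.90, Glu 4.25, His 6.50,
Cys 8.50, Tyr 10.46, Lys 10.53, Arg 12.48, N-terminus 8.00, C-terminus
3.60); it is fully overridable from a TSV, including per-site overrides for
structure-aware constants. With this table a Lys/Arg gain or an Asp loss is
+1.00 at two decimals and a Glu loss is +0.99 — all within the
"integral +1" regime used when classifying substitutions with the default
0.5 e threshold. Totals are kept at full precision internally and rounded
half-even to 2 decimals for reporting.

```{r charge-example}
substitution_delta("Ser", "Lys")      # the canonical +1 gain
round_zmb(0.07 + substitution_delta("Ser", "Lys"))
```

Gaps and unknown residues (`X`) contribute zero charge; a deletion of an
ionizable residue therefore removes its contribution, which is exactly how
the recurrent one-residue deletion in the G–H loop region of several
eulipotyphlan myoglobins is handled.

## Ancestral sequence reconstruction

Reconstruction is maximum-likelihood and marginal: per internal node and
site, the posterior over the 20 residues given all tip data under a
reversible empirical model (Dayhoff by default; JTT/LG/WAG loadable) with
K = 4 discrete-gamma rate categories. Numerical choices:

* Category rates are conditional means of the gamma(α, α) quantile bands,
  computed in closed form, so the mean rate is exactly 1.
* The pruning pass rescales partial likelihoods per node and tracks log
  scale factors, so 50+-tip trees with small branch lengths are safe from
  underflow.
* The input tree is typically a chronogram; `fit_scaling()` maximises the
  likelihood over the gamma shape α (bounds 0.05–50) and a global
  branch-length multiplier ρ (bounds 1e-8–10) by bounded quasi-Newton on
  the log scale, tolerance 1e-6 in log-likelihood. The (lengths × c, ρ / c)
  symmetry means only the product is identified, which is what the
  reconstruction needs.
* Node posteriors come from an inside–outside pass and are mixed over rate
  categories by each site's category posterior.
* The root prior is the stationary distribution; the tree is used as
  given (rooted) — reversibility makes the likelihood root-invariant.

Indel states are reconstructed separately as a binary presence/absence
character by minimum-change parsimony with ties resolved toward
"present" (deletions treated as derived). This replaces a likelihood
mixture model for indels; on clean phylogenetic deletion patterns the two
agree, and the approximation is flagged here deliberately: it is exact
whenever each deletion is confined to a clade and reversals are absent.

Ancestral charges use the MAP sequence per node. Reconstruction
uncertainty is not folded into Z~Mb~ by default; instead
`charge_robustness()` audits every node × site: cells are classified as
confident (MAP p > 0.95 and no alternative residue above 0.05),
same-charge alternatives, or different-charge alternatives (reporting the
summed probability of alternative-charge residues and the worst-case
|ΔZ~Mb~|). That mirrors how the analysis is meant to be read: a point
estimate plus an explicit ledger of where it could move.

## Lifestyle models

**Parsimony.** `fitch_parsimony()`/`count_origins()` use exact
dynamic programming over per-node state costs (valid on polytomies), count
0→1 transitions minimised and maximised over all minimum-change
reconstructions, and so report ranges in equi-parsimonious cases such as
"one gain plus one loss versus two gains".

**Threshold model.** The binary lifestyle is the sign of a latent liability
evolving by Brownian motion (or its Pagel-λ transform) on the tree. The
liability rate is fixed at 1 — the sign is scale-invariant, so the rate is
unidentifiable and fixing it costs nothing. Node liabilities are updated by
Gibbs draws from their tree-structured Gaussian full conditionals,
truncated at tips to match observed states; λ is Metropolis-updated on
[0, 1]. Exact conditional draws mix faster than random-walk updates and
need no proposal tuning for the liabilities. Model choice between BM and λ
liabilities uses a DIC built from the truncated-Gaussian tip likelihood.
The λ transform is applied as a tree surgery (internal branches scaled by
λ, tip branches extended to preserve tip depths), which keeps the
branch-based Gibbs pass valid.

**Liability correlation.** `threshbayes_correlation()` fits a bivariate
Brownian model: the continuous trait (Z~Mb~) and the lifestyle liability
evolve as correlated Brownian motions with correlation r. Tip liabilities
are Gibbs-sampled from truncated Gaussians; the continuous-trait rate, r
(on the atanh scale) and the two root means are random-walk Metropolis
with proposal scales tuned during burn-in toward 20–40% acceptance.
Priors are weakly informative: flat root means, scale-invariant rate,
uniform-equivalent r. `generations` counts elementary updates (matching
the convention of the reference MCMC tools whose run lengths are quoted in
units of 10^6^–10^7^); one full sweep is about n + 4 updates. Reported:
posterior mean of r, 95% HPD (shortest interval), autocorrelation-based
ESS with a warning below 100.

**PGLS.** `pgls_fit()` is closed-form GLS with residual covariance
λC + (1 − λ)diag(C), λ fixed (default 1; it is not estimated because the
mobility panels this calibrates are small). With an ultrametric tree and
λ = 0 this is OLS. R² uses the GLS definition against the GLS
intercept-only model.

## The synthetic-data generator

`scenario()`/`simulate_study()` generate a complete study with known truth:

* **Tree** — default is the bundled `example_eulipotyphla()` phylogeny: a
  55-tip composite of the eulipotyphlan species tree with the five
  semi-aquatic lineages and the two fossorial mole clades in their
  published arrangement. Branch lengths are invented (Grafen, scaled to a
  75-unit, Ma-like depth): the analyses that consume this tree as a
  default — parsimony counting, topology-dependent simulation — depend on
  topology, not dates.
* **Sequences** — a 153-residue root (deterministic draw from Dayhoff
  stationary frequencies, adjusted to 19 ionizable residues and
  near-neutral charge, the composition regime of terrestrial myoglobins)
  evolves site-independently under Dayhoff + Γ (α = 0.8, K = 4) at
  ρ = 0.002 substitutions/site per unit length, i.e. ~15% expected change
  root-to-tip — mammalian-myoglobin-like divergence.
* **Purifying charge filter** — with probability `charge_purify = 0.8` a
  background substitution that would move the side-chain charge by ≥ 0.5 e
  is rejected. Neutral evolution lets Z~Mb~ drift over several charge
  units on a 75-unit-deep tree, which real myoglobins demonstrably do not
  do (terrestrial species cluster within ~1 unit); the filter is the
  simplest mechanism that reproduces that conservation. Set it to 0 for
  the pure empirical-model process (the stationarity tests do exactly
  that).
* **Charge shifts** — each of the five semi-aquatic stems receives
  targeted substitutions (neutral → Lys/Arg or Asp/Glu → Asn/Gln at
  eligible sites) until its ΔZ~Mb~ reaches +2, the published contrast
  between semi-aquatic and background lineages. Every substitution,
  background or planted, is logged, so ASR and branch classification can
  be scored with precision/recall.
* **Lifestyle** — the ground-truth labels are clade membership of the
  shifted branches (`shifted_clade_trait()`), as in the real study where
  lifestyle is observed; `simulate_binary_trait()` additionally draws
  noisy labels from a liability correlated with Z~Mb~ (default
  r = 0.8) for calibration experiments of the correlation machinery.
* **Mobility** — y = 0.1488 Z~Mb~ + 0.3075 plus Brownian-structured noise
  (SD 0.02), the reference calibration line.

What passing on these data does **not** show: the generator has no codon
structure, no site-specific structural constraints (every non-charged site
is "surface" for shift eligibility), and its purifying filter is a cartoon
of selection. Results on real data additionally depend on alignment
quality and on the chronogram's dates, neither of which is stressed here.

## Problem sizes and determinism

The test-suite and example runs use the 55-tip bundled tree with 153-site
alignments, 4-tip exhaustive-enumeration oracles for the likelihood
machinery, 8-tip brute-force checks (100 random instances) for parsimony,
and MCMC runs of 2–4 × 10^5^ elementary updates with 20 replicate seeds
for the correlation-calibration experiments — sizes chosen so the whole
suite completes in a few minutes while leaving the Monte-Carlo assertions
comfortable margins. All stochastic components take explicit seeds;
identical seed + configuration reproduces chains, simulations and report
files byte-for-byte.

## Known limitations

* Absolute Z~Mb~ of real species depends on the exact (structure-specific)
  ionization constants used; with the default free-residue table,
  branch *differences* are robust but absolute values can differ by a few
  hundredths from values computed with site-specific constants.
* Indel reconstruction is parsimony, not likelihood; ambiguous indel
  histories with reversals would need the mixture-model treatment.
* Multi-hit sites within one branch are reported as unordered differences;
  no within-branch temporal ordering is attempted.
* The threshold-model DIC is a heuristic model-comparison device; its
  absolute scale should not be over-read.

## End-to-end example

```{r pipeline, eval = FALSE}
sc <- scenario(seed = 101)
st <- simulate_study(sc)
cfg <- pipeline_config(
  fasta = st$alignment, tree = st$tree,
  traits = tibble::tibble(
    tip_id = st$traits$tip_id,
    lifestyle = ifelse(st$traits$state == 1, "semi_aquatic", "terrestrial")),
  out_dir = "run1", seed = 7,
  mcmc = list(generations = 2e5, sample_every = 200))
res <- run_pipeline(cfg)
glance(res$anc)        # fitted alpha, rho, lnL
res$origins            # parsimony origin count
tidy(res$correlation)  # posterior of r with HPD
```
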