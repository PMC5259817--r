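---
title: "Evaluating database inflation in proteogenomic search"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating database inflation in proteogenomic search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup, message = FALSE}
library(sepfdr)
```

## The problem

A proteogenomic search matches MS/MS spectra against a database that combines
a reference proteome with sequence derived from genomic or transcriptomic
evidence — for example a six-frame translation of the genome. Most of the
added ("novel") sequence is spurious: it is never produced in vivo, but it is
searchable, and that has two consequences for peptide identification at a
fixed false discovery rate (FDR):

1. **Reliability.** Random hits to spurious novel sequence count as *target*
   hits. A pooled target-decoy FDR estimate is dominated by the
   (well-identified) known class, so the error rate *within the novel class*
   can be far above the nominal level — the FDR of novel peptides is
   underestimated.
2. **Sensitivity.** The decoy database grows with the target. The best random
   match score is an extreme value: the maximum of $m$ independent
   per-candidate scores. If per-candidate scores are Gumbel$(\mu_0, \beta)$,
   the maximum is Gumbel$(\mu_0 + \beta \log m, \beta)$, so every
   $(n+1)$-fold inflation of the search space shifts the random-hit score up
   by $\beta \log (n+1)$ and pushes the acceptance threshold into the correct
   score distribution.

`sepfdr` builds the databases, simulates the searches with known ground
truth, and applies six validation methods plus a two-stage FDR, so both
effects can be measured and the remedy — *separate filtering* of known and
novel peptides — can be evaluated quantitatively.

## Database construction

A simulated proteogenomic target of inflation factor $n$ ("1TnD") is the
reference database plus $n$ reference-sized blocks of simulated novel
sequence: one pseudo-reversed copy and $n-1$ pseudo-shuffled copies. Its
decoy is $n+1$ pseudo-shuffled copies, so target and decoy always have equal
total length. Both transforms operate per tryptic segment (the protein is cut
at every K/R not followed by P) with the segment's C-terminal residue fixed,
so decoys stay tryptic and preserve per-protein length and amino-acid
composition.

```{r simdb}
base <- synthetic_reference_db(10000, n_proteins = 20, seed = 1)
target <- build_simulated_target(base, n = 2, seed = 1)
decoy  <- build_simulated_decoy(base, n = 2, seed = 1)
c(base = total_aa(base), target = total_aa(target), decoy = total_aa(decoy))
```

Digestion follows the trypsin rule with up to 2 missed cleavages and a
minimum peptide length of 8 by default (`digest_params()`); `db_stats()`
reports total/unique peptide counts and the redundancy proportion
$1 - \text{unique}/\text{total}$, the quantity used to check that repeated
pseudo-shuffling does not flood the decoy with duplicate peptides. Real
proteogenomic databases are supported through `six_frame_translate()`, which
emits every region from an ATG to the first in-frame stop (both strands,
three frames each, splicing ignored), flags stop-less trailing regions as
partial rather than dropping them, translates N-containing codons to X, and
reports 1-based inclusive forward-strand coordinates. Alternative start
codons are not supported; the minimum ORF length defaults to 8 residues to
match the digestion minimum.

## The search simulator

Real search-engine runs are out of scope; the simulator reproduces the
*structure* of their output — one best-match PSM per spectrum with known
provenance and correctness — under the same distributional assumptions the
mixture-model validator relies on:

* With probability `p_correct` a spectrum's true peptide is in the database
  and its correct candidate scores Normal$(\mu, \sigma)$; with probability
  `p_novel_true` that peptide belongs to the novel partition.
* Each partition (known / novel / decoy, sizes `m_known`, `m_novel`,
  `m_decoy`) contributes its best random score,
  Gumbel$(\mu_0 + \beta\log m, \beta)$.
* The reported PSM is the maximum of the available candidates; a winning
  decoy is attributed to the known group with probability
  `m_known / m_decoy` (one decoy copy per reference block — each group's
  decoy search space then matches its target search space).
* Three features are carried: the score, the margin over the runner-up, and
  a mass-error-like feature, tight (Normal, sd 0.05) for correct matches and
  diffuse (uniform on ±2.5) for incorrect ones — so a rescorer has real but
  limited signal to exploit.

Defaults emulate a yeast-scale experiment: `m_known = 688452` (the number of
unique fully-tryptic reference peptides at yeast scale), 20,000 spectra per
charge stratum, `p_correct = 0.4`, `p_novel_true = 0.01` (novel true
peptides are of the order of 1% of identifications in published
proteogenomic searches), `gumbel_mu0 = 0`, `gumbel_beta = 1`,
`gaussian_mu = 25`, `gaussian_sigma = 3`. The score scale is arbitrary; what
matters is the geometry it implies, chosen so that (i) essentially all
correct matches beat the random background even for a 12-fold search space
($\mu - (\mu_0 + \beta\log 12 m) \approx 3\sigma$, so inflation steals well
under 1% of correct spectra — real searches show almost no stealing), while
(ii) the 1% acceptance threshold still sits on the flank of the correct
distribution, so threshold shifts are visible in the accepted counts. Under
these conditions roughly 3,900 known peptides are accepted at 1% FDR, the
scale of the corresponding published yeast counts. Distinct true peptides
number 60% of expected correct spectra, so peptide-level collapse is
non-trivial.

```{r sim}
res <- simulate_search(sim_config(n_spectra = 5000, charge_strata = "2+",
                                  seed = 7))
dplyr::count(res$psms, group, is_decoy, is_correct)
```

## Validation methods

All methods operate at peptide level: `peptide_collapse()` keeps the
best-scoring PSM per peptide (ties broken by spectrum identifier).

**TD.** `filter_at_fdr()` estimates FDR as $N_D/N_T$ at every observed
threshold, monotonises by cumulative minimum from the most permissive
threshold upward (a q-value), and accepts all targets with $q \le \alpha$.
The plain estimator (no $+1$ correction) follows the published procedure;
combined with threshold selection it is mildly anticonservative, which the
calibration test quantifies against a binomial band rather than assuming
away.

**MB.** `fit_mixture_em()` fits
$\pi_0\,\mathrm{Gumbel}(\mu_g, \beta_g) + \pi_1\,\mathcal N(\mu_n,\sigma_n)$
by EM: closed-form weighted Gaussian moments and weighted Gumbel maximum
likelihood with one-dimensional root finding for $\beta_g$ (computed on
shifted scores for numerical stability). The fit uses target scores only by
default — the mixture method does not need decoys — and is configurable to
pooled. Initialisation is moment-based on a median split; degenerate fits
($\sigma_n$ or $\beta_g \to 0$, or a vanishing component) are flagged
non-converged. The log-likelihood is non-decreasing by construction and is
asserted in the tests. `compute_pep()` gives the posterior error probability
and `mb_filter()` thresholds on the mean PEP above the cutoff. A parametric
caveat: because the Gumbel right tail ($e^{-x/\beta}$) is heavier than the
Gaussian's, PEP is not monotone arbitrarily far into the right tail; the
cumulative-minimum monotonisation makes the accepted set well-defined
regardless.

**BP.** `boosted_rescore()` is a deliberately simplified Percolator-style
rescorer: per boosting round and cross-validation fold (defaults: 5 rounds,
3 folds), a Fisher linear discriminant is trained on positives — targets
accepted at `init_fdr` under the current ranking; rounds after the first
re-draw a random 80% of that positive set, the perturbed labeling that makes
the procedure robust to its initial ranking — versus decoy negatives, and
scores its held-out fold. The rescored value is the mean held-out
discriminant score. LDA was chosen over unregularised logistic regression
because the training classes are nearly separable by construction and
quasi-separation lets uninformative features keep inflated weights; the
pooled-covariance discriminant is well conditioned there (with pure-noise
side features the rescored ranking agrees with the raw score at Kendall
$\tau \approx 0.98$). Without decoys or positives the raw score is returned
with a warning.

**Separate filtering (SepTD/SepBP/SepMB).** `separate_filter()` runs any
learning step once on the pooled PSMs (a novel-only model cannot be
trained), then partitions records into known and novel groups and applies
$N_D/N_T$ filtering within each group, ranking by raw score, rescored value,
or $1-\mathrm{PEP}$ respectively. A decoy PSM belongs to the group of the
decoy block it was drawn from: one reference-sized decoy copy serves the
known group and $n$ copies the novel group, so each group's estimator
compares like with like. This choice makes the known-group threshold exactly
invariant in $n$ in expectation: the known-assigned decoy count scales as
$1/(n+1)$ while the decoy score location rises by $\beta\log(n+1)$, and the
two effects cancel in the tail — which is the mechanism behind separate
filtering preserving sensitivity.

**Two-stage FDR.** `two_stage_filter()` filters a reference-only search at
$\alpha$; only spectra *not* accepted there are re-searched against the full
proteogenomic database (supplied by a caller-provided function, in the
experiment a fresh simulated competition for the residual spectra with the
same per-spectrum ground truth) and stage 2 is filtered at $\alpha$. Stage-1
acceptances can never re-enter stage 2.

## The inflation experiment

`run_inflation_experiment()` sweeps $n$ (default $\{0, 1, 2, 5\}$): per
replicate it derives `m_novel = n * m_known` and
`m_decoy = (n + 1) * m_known`, simulates the search, runs the requested
methods, and records accepted known/novel counts, thresholds, and estimated
and empirical FDR per (replicate, n, charge, method, group) row. Every
stochastic step draws a named sub-stream from the master seed
(`substream_seed()`), so tables are exactly reproducible and target/decoy
shuffle streams never collide.

```{r experiment}
cfg <- experiment_config(
  n_values = c(0L, 5L), n_replicates = 2L, methods = c("TD", "SepTD"),
  sim = sim_config(n_spectra = 5000L, m_known = 100000L,
                   charge_strata = "2+"),
  master_seed = 7L
)
tab <- run_inflation_experiment(cfg)
summarise_experiment(tab)
```

At full scale (20 replicates of 20,000 spectra, as in the package's
acceptance suite) the pattern is: pooled TD and MB counts fall monotonically
with $n$; the SepTD known count at $n = 5$ stays within 2% of its $n = 0$
value; pooled filtering accepts several times more novel peptides than
separate filtering, and with a fully spurious novel partition the empirical
FDR among pooled-accepted novel peptides is an order of magnitude above the
nominal 1% — the underestimation effect. These statements are exactly what
`tests/testthat/test-acceptance.R` verifies; the vignette intentionally
reports no number the test suite does not itself compute.

## What the simulation does and does not show

The generator reproduces the score geometry (Gaussian correct / extreme-value
incorrect with $\beta\log m$ growth), class structure, decoy symmetry, and
peptide multiplicity of a proteogenomic search. It does not simulate spectra,
retention times, precursor masses, engine-specific score functions, shared
peptides between the known and novel partitions, or homology between target
and decoy sequence. Passing tests therefore demonstrate properties of the
validation procedures under the stated generative assumptions — calibration,
the direction and rough magnitude of inflation effects — not the absolute
peptide counts of any real data set, which depend on the spectra and engines.
Accordingly the experiment module reproduces published *arithmetic* exactly
(database sizes, percent changes) and published *trends* qualitatively, by
design.

## Numerical and design notes

* `filter_at_fdr()` defines $N_D/N_T = 0$ when $N_T = 0$ and resolves tied
  scores as a single threshold block.
* EM requires at least 50 scores; the Gumbel M-step root is bracketed
  adaptively and falls back to a degenerate-fit flag rather than erroring
  mid-EM.
* Pseudo-shuffling is uniform over permutations fixing the segment's last
  residue (verified by an exact multinomial test); segments of length one or
  two are invariant.
* Decoy construction segments proteins at mc = 0 cleavage points — the only
  segmentation that reassembles unambiguously into a same-length protein —
  while digestion statistics use the configured missed-cleavage limit.
* Peptides containing X are kept in sequences but excluded from peptide
  statistics, since an indeterminate residue cannot be matched.
* `percent_change()`, `decrease_rate()` and `size_difference()` round to two
  decimals; `size_difference()` uses the real proteogenomic database size as
  the denominator (the convention that reproduces both published values).
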