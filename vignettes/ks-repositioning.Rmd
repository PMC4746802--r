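---
title: "Signed KS enrichment for expression-based drug repositioning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signed KS enrichment for expression-based drug repositioning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ksenrich)
```

## The problem and the model

Expression-based repositioning asks: which known compounds interact
preferentially with the genes that a disease perturbs most? `ksenrich`
answers it in "inverse Connectivity-Map" form: the query is one
*complete* ranked case/control gene list (the **instance**), and the
database holds many short, unordered compound–gene sets (the
**signatures**). Two deliberate modelling choices drive everything
else:

* **Directionless interaction.** A signature is a set, not an
  up/down-regulation profile, so curated interaction databases without
  (or with conflicting) regulatory direction — such as CTD dumps
  reduced to compound → gene sets — are first-class inputs.
* **The whole instance, regardless of significance.** Every gene in
  the study enters the ranking, which guarantees overlap with short
  signatures; significance is handled downstream by the null model,
  not by pre-filtering.

For a signature whose genes occupy sorted instance positions
$V(1) \le \dots \le V(t)$ out of $n$:

$$a = \max_{j=1}^{t}\Big[\frac{j}{t} - \frac{V(j)}{n}\Big], \qquad
  b = \max_{j=1}^{t}\Big[\frac{V(j)}{n} - \frac{j-1}{t}\Big],$$

with $KS = a$ if $a > b$ and $KS = -b$ otherwise. $a$ measures how far
the observed rank distribution runs ahead of the uniform expectation
(enrichment toward rank 1), $b$ how far it lags (depletion). Strongly
enriched signatures score near $+1$; unenriched or inversely enriched
ones near zero or negative.

The statistic has no convenient closed-form null, and its distribution
depends on the signature length, so significance is empirical and
**length-stratified**: for each unique overlap size $\ell$ in the
restricted database, `B` random $\ell$-subsets of the instance are
scored and shared as the null by every signature of that length. The
p-value of a signature is the proportion of its null scores strictly
exceeding the observed score; Benjamini–Hochberg adjustment across all
scored compounds yields the reported FDR. Testing is one-sided — only
top-rank enrichment is of repositioning interest — so inversely
enriched signatures get p near 1.

## Numerical choices

* **Exact tie handling.** Every term of $a$ and $b$ is a rational with
  denominator $t\,n$. Evaluated in floating point, exact ties
  mis-resolve (for $n = 10$, ranks $\{3, 7\}$: $1 - 7/10 > 3/10$ in
  doubles, although both equal $0.3$). The implementation therefore
  maximises and compares *integer numerators* and divides once. A tie
  $a = b$ yields $-b$: the assignment rule "KS $= a$ if $a > b$" is
  read strictly, and this choice is observable exactly at top blocks
  of size $t = n - 1$, which score $-1/n$ rather than $1 - t/n$.
* **Strict exceedance, with an add-one option.** The default p-value
  counts null scores strictly greater than the observed one, which can
  return 0; `add_one = TRUE` gives the standard never-zero
  $(\text{count}+1)/(B+1)$ estimator, preferable when p-values feed a
  calibration analysis.
* **Resampling without replacement.** Signatures are sets of unique
  genes, so a null draw of length $\ell$ is a random $\ell$-subset of
  the instance.
* **Seeding.** Every random quantity flows from an explicit integer
  seed; each signature length draws its null from an independently
  derived substream, so results do not depend on the order in which
  lengths are processed, and identical inputs give byte-identical
  outputs.
* **Deterministic output order.** Results sort by ascending p, then
  descending KS, then compound identifier. The tie-breaks matter: with
  small `B`, many p-values coincide, and percentile-rank evaluation
  uses this order.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `B` | 10,000 | resamples per signature length; Monte-Carlo SE of a p-value is $\sqrt{p(1-p)/B}$, so 10,000 resolves $p \approx 0.05$ to about $\pm 0.002$ |
| `seed` | none (mandatory in the API) | reproducibility; recorded in the output metadata sidecar |
| `min_overlap` | 1 | smallest instance overlap scored; 1 keeps every signature with any overlap, and removals are always counted in the log |
| `add_one` | `FALSE` | p-value estimator (see above) |
| `descending` | `FALSE` | score direction when reading ranked lists: the default treats scores as p-value-like (smaller = stronger); set it for effect-size-like scores. Ties in score keep file order (stable sort), which fixes the rank positions the KS score depends on |

Ingest decisions: identifier mapping is file-driven (a two-column
alias → Entrez table; no species annotation database is bundled), and
duplicate identifiers — typically many probes per gene — collapse to
their best-ranked occurrence, i.e. the strongest evidence for that
gene. CTD conversion keeps literature-supported rows (nonempty PubMed
field) for the requested organism, uses the MeSH accession as the
compound identifier to avoid name collisions, and ignores
interaction-direction annotations by design.

## What the synthetic generator emulates — and what it does not

Only rank structure matters to the method, so the generator builds
instances as seeded permutations of synthetic identifiers with
p-value-like pseudo-scores, and signatures as draws over rank
positions:

* `make_null_db()` draws uniformly random signatures with lengths from
  a configurable pool (default 5–50, the short-signature regime that
  curated interaction databases occupy).
* `plant_signature()` draws ranks without replacement with weights
  proportional to the Beta(1, `concentration`) density at the rank
  midpoints. `concentration = 1` *is* the uniform null;
  `concentration` large pushes all signature genes toward rank 1. One
  interpretable knob containing the null as a special case — chosen
  because the method itself defines no generative model for an
  enriched compound.

Default study conditions for the simulated screen: $n = 2000$ genes,
$m = 100$ signatures, one planted signature of $t = 20$ genes at
`concentration = 50` (mean planted rank $\approx n/51$, i.e. the top
2% of the list), decoy lengths 5–50. Tests and the acceptance script
use $B = 2000$ at these sizes, and smaller instances ($n \le 12$)
where a check enumerates all $\binom{n}{t}$ signatures exactly.

What passing these tests shows: the statistic matches its closed forms
and the exact permutation null, p-values are calibrated under the
uniform null, and a strongly enriched compound is recovered with FDR
control. What they do not show: performance on real expression data —
correlated gene ranks, platform effects, noisy differential-expression
estimates, and curation bias in real interaction databases are all
absent from the generator. A planted Beta signature is a clean,
literal version of "interacting genes are highly ranked"; real
therapies are weaker and dirtier signals.

## Degenerate inputs and edge behaviour

Empty instances, empty databases, signatures with no instance overlap,
lengths exceeding $n$, and p-values outside $[0,1]$ are errors, never
silent. A signature equal to the whole instance ($t = n$) scores
$-1/n$ (with $a = 0$, $b = 1/n$); a single-gene instance is the fully
degenerate case $KS = -1$. Dropped signatures are counted and
reported, and result rows plus dropped signatures always account for
every database compound.

## Known limitations

* One-sided testing only; no up/down two-list enrichment.
* Bootstrap p-values have resolution $1/B$; compounds sharing $p = 0$
  are ordered by KS, which is a heuristic within the tied set.
* The hypergeometric evaluation treats "significant" as a fixed
  selection; it inherits whatever threshold produced it.
* CTD snapshot composition changes over time; converted databases are
  reproducible only from an archived dump.

## A worked call

```{r example, eval = FALSE}
sim <- simulate_screen(n = 2000, m = 100, planted = 1,
                       concentration = 50, seed = 42)
res <- repo(sim$instance, sim$db, B = 2000, seed = 42)
head(res, 3)
hypergeometric_enrichment(N = nrow(res), K = 1,
                          n_sig = sum(res$fdr < 0.05),
                          k_hit = as.integer(res$fdr[1] < 0.05))
```
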