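# ksenrich

Expression-based computational drug repositioning for any pairing of
disease study and compound database. `ksenrich` scores one complete
ranked case/control gene list (an **instance**) against a database of
short, unordered compound–gene interaction **signatures**, and reports
bootstrapped, FDR-corrected candidate compounds. Because signatures are
plain gene sets — no direction of regulation, no platform-specific
profile — the method works with expert-curated interaction resources
such as the Comparative Toxicogenomics Database (CTD) and with ranked
lists from any differential-expression pipeline (microarray, RNA-seq),
as long as both sides share one identifier system (typically Entrez
Gene IDs).

It is aimed at computational biologists running repositioning screens:
feed in a ranked disease gene list, get back a ranked table of
compounds whose interacting genes cluster unexpectedly near the top.

## The statistic

Let *n* be the instance size and *t* the number of signature genes
present in the instance, with sorted 1-based positions
*V(1) ≤ … ≤ V(t)*. The signed Kolmogorov–Smirnov enrichment score is

```
a  = max_j [ j/t − V(j)/n ]
b  = max_j [ V(j)/n − (j−1)/t ]
KS = a   if a > b,   else  −b        (an exact tie yields −b)
```

Signatures concentrated at top ranks get KS near +1; unenriched or
inversely enriched signatures get KS near 0 or negative. The statistic
depends only on rank positions, so all comparisons are carried out on
integer numerators over the common denominator *t·n* (exact ties stay
exact).

Significance is empirical: for each unique signature length ℓ, the
score distribution of `B` (default 10,000) random ℓ-gene subsets of
the instance forms the null, shared by every signature of that length.
The p-value is the proportion of null scores strictly exceeding the
observed score (an add-one estimator is available), and
Benjamini–Hochberg adjustment controls the FDR across all compounds.

## Worked example

A synthetic screen with one enriched compound planted among 99 decoys:

```r
library(ksenrich)

sim <- simulate_screen(n = 2000, m = 100, planted = 1,
                       concentration = 50, seed = 42)
res <- repo(sim$instance, sim$db, B = 2000, seed = 42)
head(res, 3)
#>   compound_id compound_name  t        ks p_value  fdr
#> 1 planted_001   planted_001 20 0.9445000  0.0000 0.00
#> 2   null_0031     null_0031 40 0.2520000  0.0040 0.15
#> 3   null_0086     null_0086 38 0.2554737  0.0045 0.15

sim$planted_ids
#> [1] "planted_001"
percentile_rank(res, sim$planted_ids)
#> planted_001
#>           1
```

The planted compound scores KS ≈ 0.94 (its 20 genes sit in the top
ranks), its bootstrap p-value is 0 (no random 20-gene subset scored
higher in 2000 resamples) and it survives FDR correction, ranking in
the 1st percentile; the decoys' adjusted p-values are far from
significance. With a real ranked list and a CTD-derived GMT the call is
the same, plus `prepare_instance()` for identifier mapping and
`convert_ctd()` (or the `convert-ctd` subcommand) for database
construction, and `hypergeometric_enrichment()` to ask whether known
therapies are over-represented among the significant calls.

A command-line wrapper with `run`, `convert-ctd`, `simulate` and
`evaluate` subcommands is installed at
`system.file("scripts", "ksenrich", package = "ksenrich")`.

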