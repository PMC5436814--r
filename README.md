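# molbarval

Mock-community validation of 16S metabarcoding assays for molluscs — an R
package for designing, simulating and scoring environmental-DNA (eDNA)
amplicon assays against communities of known template copy number.

## The problem

eDNA metabarcoding detects many taxa at once by amplifying a short marker
from a water sample with group-specific primers and sequencing the pool.
Before such an assay can be trusted for monitoring — say, early detection
of invasive bivalves and snails — two things must be demonstrated: that
the primers amplify the intended group (and only it, for a group-specific
assay), and that read abundances reflect input template abundances. The
standard instrument for both is the *mock community*: a mixture of DNA
extractions combined at known target-amplicon copy numbers, sequenced and
pushed through the same bioinformatic pipeline as field samples.

`molbarval` is written for assay developers and molecular ecologists who
want that validation loop to be reproducible end to end. It packages:

* degenerate (IUPAC) primer matching, in-silico PCR and specificity
  screens, including blocking-primer overlap analysis
  (`find_amplicons()`, `specificity_matrix()`, `blocking_overlap_report()`);
* competitive-PCR copy-number estimation against an internal standard,
  and recipe/volume math for building communities
  (`estimate_copy_number()`, `design_internal_standard()`, `recipe_volumes()`);
* the five built-in community recipes and assay-conditional expected
  fractions (`builtin_communities()`, `expected_fractions()`);
* a paired-end MiSeq-style read simulator with ground truth — two-step
  library construct with spacers, substitution errors, chimeras, PhiX
  decoys, amplification bias and blocking-primer suppression
  (`simulate_reads()`, `simulate_reference_db()`);
* read merging, construct trimming and retention filters with a conserved
  per-stage read ledger (`merge_pairs()`, `trim_construct()`,
  `retention_filters()`);
* both assignment paths: exhaustive exact matching against collapsed
  reference amplicons (`assign_exact()`) and greedy 97% OTU clustering
  with local-alignment identification under ≥80% coverage / >1 read /
  ≥97% identity retention rules (`cluster_otus()`, `identify_otus()`);
* observed-vs-expected statistics: log10–log10 OLS regressions and
  blocking-primer efficacy (`loglog_regression()`, `blocking_reduction()`).

## The core quantities

For a community with copies $c_s$ and an assay amplifying species set
$A$: expected fraction $E_s = 100\,c_s / \sum_{t\in A} c_t$ for
$s \in A$, else 0; observed fraction $O_s$ = reads over sample total.
Quantitative recovery is the OLS fit of $\log_{10} O$ on $\log_{10} E$
(slope 1, intercept 0 is perfect recovery; a significant positive slope
preserves rank abundance). Competitive PCR estimates copies from the
regression of $\log_{10}(\mathrm{NT/IS})$ product molarity on
$\log_{10}$ IS input copies: ideal slope −1, NT copies
$= 10^{\text{intercept}}$. Blocking-primer efficacy is
$100\,(1 - O_\text{with}/O_\text{without})$ for the blocked taxon.

## Worked example

Simulate mock community 1 (error-free, no decoys) with the broad mollusc
assay, run the exact-match validation path, and compare observed with
expected fractions:

```r
library(molbarval)
db  <- simulate_reference_db()
cfg <- pipeline_config(mode = "mock_validation", assay = mol16s_assay(),
                       refdb = db, community = builtin_communities()$MC1,
                       n_read_pairs = 20000,
                       sim_args = list(error_rate = 0, chimera_rate = 0,
                                       phix_fraction = 0, q_jitter = 0),
                       seed = 7)
res <- run_pipeline(cfg)
res$abundance[order(-res$abundance$pct_expected), ]
#>                    species read_count pct_observed pct_expected
#>          Sphaerium similie      11524       57.620     57.61552
#>    Mytilopsis leucophaeata       2862       14.310     14.40071
#>     Dreissena rostriformis       2375       11.875     11.52310
#>       Dreissena polymorpha       1386        6.930      7.20035
#>   Potamopyrgus antipodarum        704        3.520      3.60018
#>             Sander vitreus        463        2.315      2.30082
#>             Gillia altilis        361        1.805      1.80009
#>  Cipangopaludina chinensis        185        0.925      0.90004
#>          Sphaerium corneum        103        0.515      0.45636
#>     Melanoides tuberculata         23        0.115      0.11409
#>        Pisidium compressum         14        0.070      0.08874
res$regression
#> <loglog_regression> slope 1.012  intercept -0.008  R^2 0.998  p 6.86e-14  n 11 (0 zero-observed excluded)
```

Every species' observed percentage sits within sampling noise of its
expected value across a 650-fold copy-number range, and the log-log fit
has slope ≈ 1 with R² ≈ 1: under a clean error model the pipeline itself
introduces no abundance distortion, so distortions seen on real data can
be attributed to the chemistry, not the bookkeeping. The per-stage ledger
(`res$accounting`) shows 20000 pairs in and 20000 reads assigned, with
every rejection reason enumerated and summing to zero here.

Copy-number estimation from an ideal competitive-PCR dilution series:

```r
estimate_copy_number(data.frame(is_copies = c(500, 5000, 50000),
                                nt_molarity = c(10, 1, 0.1),
                                is_molarity = 1))
#> <copy_number_estimate> NT = 5000 copies/reaction (10^intercept)
#>   slope -1.000  intercept 3.699  R^2 1.0000  n 3 (0 zero-NT excluded)
```

The NT:IS ratio crosses 1:1 at 5000 IS copies, so the extraction carries
5000 target copies per reaction.

See the vignette (`vignettes/mock-community-validation.Rmd`) for the full
model description, parameter defaults and numerical choices.

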