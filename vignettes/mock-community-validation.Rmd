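---
title: "Validating 16S metabarcoding assays with mock communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating 16S metabarcoding assays with mock communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(molbarval)
```

## The problem

Environmental DNA (eDNA) metabarcoding amplifies a short marker from a
mixed water sample with group-specific primers and sequences the pool,
identifying many taxa at once. Two questions decide whether such an assay
is usable for monitoring: does it amplify the taxa it claims to (and not
swamp them with non-targets), and do read abundances carry information
about input template abundances? `molbarval` implements the standard
validation design for answering both: *mock communities* — mixtures of DNA
extractions combined at known target-amplicon copy numbers — are sequenced
(here: simulated), pushed through the bioinformatic pipeline, and the
observed read fractions are compared with the fractions expected from the
input copy numbers.

The package ships the two 16S mini-barcode assays of the validation design
it models: a degenerate broad mollusc assay (`mol16s_assay()`, forward
`RRWRGACRAGAAGACCCT`, reverse `ARTCCAACATCGAGGT`, amplicons roughly
183–310 bp depending on species, plus a 3'-blocked fish blocking primer)
and a non-degenerate assay specific to fingernail/pea clams
(`sph16s_assay()`, 299 bp amplicon). It also ships the five mock-community
recipes (`builtin_communities()`): eleven species — eight molluscs rotated
through two geometric copy-number series (14–9090 and 142–2272), walleye
as the blocking-primer target, and a constant 18-copy trace species.

## The quantitative model

For a community with copy numbers $c_s$ and an assay that amplifies the
species set $A$, the expected read fraction of species $s \in A$ is

$$E_s = 100 \cdot \frac{c_s}{\sum_{t \in A} c_t},$$

and $E_s = 0$ outside $A$ (`expected_fractions()`). Conditioning on $A$ is
what makes one community yield different expectations under the broad
assay (all eleven species count) and the family-specific assay (only the
three sphaeriids count). Observed fractions $O_s$ are read counts over the
sample total (`observed_percentages()`). Quantitative recovery is
summarised by ordinary least squares of $\log_{10} O$ on $\log_{10} E$
(`loglog_regression()`): slope 1 and intercept 0 mean perfect recovery; a
significantly positive slope (two-sided t-test on the slope, no
multiple-testing correction) means rank abundance is preserved. Both the
within-community view (across species) and the within-species view (across
communities) are available through `regress_observed_expected()`.

Copy numbers themselves come from competitive PCR
(`estimate_copy_number()`): a fixed native template (NT) is co-amplified
with a serial dilution of an internal standard (IS) that shares both
primer sites but is 10% shorter (`design_internal_standard()`). Because NT
and IS compete equally, $\log_{10}(\mathrm{NT}/\mathrm{IS})$ product
molarity is linear in $\log_{10}$ IS input copies with ideal slope $-1$,
and the intercept reads off the NT copy number as $10^{\text{intercept}}$.

## Pipeline stages and the two assignment paths

A run (`run_pipeline()`) chains: simulation (or FASTQ input) → pair
merging (`merge_pairs()`) → construct trimming (`trim_construct()`) →
either *exact-match assignment* against the collapsed reference amplicons
(`assign_exact()`, the mock-community path) or *de-novo OTU clustering
plus local-alignment identification* (`cluster_otus()`,
`identify_otus()`, the survey path, preceded by `retention_filters()`).
Every stage returns a `stage_accounting()` record obeying
`n_in = n_out + rejections`, so reads are never dropped silently.

Exactness is the mock path's chimera and error filter: a chimera spliced
from two parents, or a read with any substitution inside the insert, can
never equal a reference amplicon string, so both fall into the unassigned
pool rather than biasing species counts. Reference records whose amplicons
are identical strings are collapsed into amplicon-level OTUs
(`collapse_amplicon_otus()`); a read matching an amplicon shared by
several species is reported as ambiguous, not split.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `max_mismatch` (in-silico PCR) | 0 | mismatches/primer | reference predictions are exact-site based; screens may raise it |
| amplicon length window | 100–500 | bp | brackets the 183–310 bp assay range, excludes spurious distant primer pairings |
| `min_overlap` (merge) | 16 | bp | short enough for 2×300 reads of ≤600 bp fragments, long enough to make chance overlaps negligible |
| `max_mismatch_rate` (merge) | 0.1 | fraction | tolerates substitution errors in the overlap without admitting misalignments |
| `max_primer_mismatch` (trim) | 1 | mismatches | retains reads with one error in a primer site; exactness downstream still rejects insert errors |
| `fwd_window` / `rev_window` (trim) | 25 | nt | spacers are 7–17 nt, so a true forward primer starts within 17 nt; the window blocks interior false hits |
| `min_length` (filter) | 100 | bp | boundary inclusive; shorter inserts are unreliable for identification |
| `drop_singletons` | TRUE | — | exact-sequence multiplicity within one sample; removes stray error reads and trace contamination |
| `threshold` (clustering) | 0.97 | fraction | the conventional species-level OTU radius for 16S |
| `min_coverage` / `min_reads` / `species_identity` | 80 / 2 / 97 | % / reads / % | the retention and species-level rules of the identification step |
| `slope_tolerance` (competitive PCR) | 0.15 | — | warns when competition deviates from the ideal slope −1, where the intercept rule is unreliable |

## The read simulator

`simulate_reads()` is the package's synthetic-data stage: it generates
paired-end reads with a full ground-truth table so that every downstream
stage is testable without sequencer output. It emulates:

* **Template sampling** proportional to copy number × a per-species
  amplification efficiency factor, with blocked taxa down-weighted by
  `blocking_efficiency` — amplification bias and blocking act on observed,
  never expected, fractions.
* **The two-step library construct**: reads begin after the sequencing
  primer region, i.e. with one of the four 7–17 nt spacer sets, then the
  assay primer site and insert; reads are truncated at the fragment end
  (read-through of short fragments).
* **2 × 300 bp chemistry** with substitution errors at a uniform per-base
  rate (default 0.003) and Phred qualities decaying linearly along the
  cycle with Gaussian jitter (Q38 start, 0.02/cycle, SD 2). The platform
  specifies none of these; they are configuration, chosen as typical
  values, and the error model is substitution-only so that exact-match
  semantics stay interpretable.
* **Chimeras** (default rate 0.01) spliced from two templates at a uniform
  interior breakpoint, and **PhiX/unindexed decoys** (default fraction
  0.45, the midpoint of the 40–50% spike-in used on low-diversity runs)
  emitted as random-sequence pairs.

What it does *not* emulate: indels, PCR-cycle-by-cycle drift, index
hopping, flowcell cluster effects, quality-dependent error rates, or
pipetting/quantification error in the recipes. Passing tests therefore
show that the pipeline's arithmetic and bookkeeping are correct under a
clean error model — not that a real sequencing run would be free of the
biases those processes introduce. Per-species amplification efficiencies
in real runs are unknown; the simulator's `efficiency_bias` is a free
parameter for sensitivity exercises, not an estimate.

The companion generator `simulate_reference_db()` builds the synthetic
stand-in for the curated reference collection: labelled templates carrying
concrete expansions of the degenerate mollusc primer sites around random
species-specific inserts (lengths spread over the assay's range), with the
three sphaeriids additionally carrying the family assay's sites spanning a
299 bp amplicon, and one species holding two accessions with an identical
amplicon to exercise amplicon-level collapsing. Random inserts make
between-species identities far below any clustering threshold — real 16S
congeners can sit much closer, so species resolution on real references is
harder than in these tests.

## Numerical choices

* **Merging** slides the reverse-complemented mate over the forward read;
  candidate overlaps are scored by mismatch rate, ties going to the longer
  overlap. Disagreements resolve to the higher-quality base carrying the
  *lower* of the two qualities; agreements take the max, capped at Q41.
* **Clustering identity** is computed on a terminal-gap-free (overlap)
  alignment but normalised by the *shorter sequence's length* (matches /
  min length), not by aligned columns alone: with free end gaps, a short
  perfectly matching end-overlap between unrelated sequences would
  otherwise count as 100% identity and glue separate OTUs together.
  Centroid order is abundance desc, length desc, then lexicographic; a
  sequence joins the *first* centroid reaching the threshold. At threshold
  1.0 clustering reduces exactly to string deduplication.
* **Identification** replaces a remote BLAST search with deterministic
  local alignment against a supplied reference FASTA, scored
  megablast-like (match +2, mismatch −3, gap open −5, gap extend −2).
  The best hit is chosen by score, ties broken by identity, then coverage,
  then lexicographically smallest accession — a reproducible stand-in for
  "first BLAST hit", which is database-order dependent. Identity is
  matching columns over alignment columns; coverage is aligned query span
  over query length; e-values are not computed (the retention rules never
  used them).
* **Zero observed percentages** are excluded from log-log regressions by
  default (a taxon can reach zero reads; log of zero is undefined and no
  imputation rule is stated anywhere authoritative); exclusions are always
  counted and reported. A floor policy is available for sensitivity
  checks. Regressions use raw count-derived fractions, not
  presentation-rounded ones.
* **Blocking-primer overlap** is reported as the maximal degenerate-aware
  suffix/prefix overlap between the reverse primer and the blocking
  primer, scanned in both the direct and the reverse-complement
  orientation, because annealing strand conventions differ between
  designs; degenerate positions are compatible when their expansions
  intersect.
* **Internal-standard sizing**: the deletion is `round(fraction ×
  amplicon length)` bases (10% default makes the IS 10% shorter than the
  NT product), centred in the insert so both primer sites stay intact.
* **`N` handling**: an `N` in a target sequence matches nothing, so
  reference regions containing `N` can never claim reads under exact
  matching — the conservative reading of an exact-match retention rule.
* **Competitive-PCR estimator**: NT copies are `10^intercept`, valid when
  the slope is near −1; the root-solving alternative
  `10^(−intercept/slope)` is reported for diagnostics, and a slope warning
  (tolerance 0.15) guards misuse. Points where the NT band is absent
  (zero molarity) are excluded and counted, never imputed. The intercept
  rule is exactly scale-equivariant only at slope −1.

## Problem sizes used by the test-suite

The packaged tests run the full pipeline at 10^5 error-free read pairs for
the convergence check (observed within 1% absolute of expected;
multinomial noise at that depth is ~0.16% for the largest fraction),
2 × 10^4 pairs for the error-model assignment oracle, and a few hundred
to a few thousand pairs elsewhere; the competitive-PCR recovery property
uses 100 seeded replicates of a 6-point dilution series spanning
10^2–10^5 copies under σ = 0.05 lognormal noise. These sizes were chosen
so the whole suite exercises every stage at statistically meaningful depth
while remaining quick to run.

## Known limitations

* The clustering path inherits chimeras (no dedicated chimera detector);
  only the exact-match path removes them by construction. In practice
  most simulated chimeras are singletons and fall to the singleton filter.
* Greedy clustering is order-dependent by design (it mirrors the
  UCLUST-style tool it models); the documented ordering makes it
  deterministic but not order-free.
* Multi-species amplicon OTUs are reported as ambiguous rather than
  resolved; with real congeneric references (e.g. several
  *Cipangopaludina* species sharing an amplicon) downstream species
  tallies must treat the ambiguous pool explicitly.
* The exact-match path's assigned *fraction* depends on insert length
  (longer inserts accumulate more errors), so assigned-read proportions
  are not a length-unbiased estimator of template proportions at high
  error rates; at the default error rate the distortion is small relative
  to amplification bias in real data.

## A worked example

```{r example, eval = FALSE}
db  <- simulate_reference_db()
cfg <- pipeline_config(mode = "mock_validation", assay = mol16s_assay(),
                       refdb = db, community = builtin_communities()$MC1,
                       n_read_pairs = 20000,
                       sim_args = list(error_rate = 0, chimera_rate = 0,
                                       phix_fraction = 0, q_jitter = 0),
                       seed = 7)
res <- run_pipeline(cfg)
res$abundance      # observed vs expected percentages per species
res$regression     # log-log recovery fit
res$accounting     # per-stage read ledger
```
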