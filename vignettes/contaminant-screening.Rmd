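---
title: "Order-level contaminant screening for low-biomass amplicon surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Order-level contaminant screening for low-biomass amplicon surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(contamscreen)
```

## The screening model

Low-biomass subseafloor samples are sequenced against a background of foreign
DNA whose biomass often exceeds the sample's own: drilling fluid (seawater
plus sepiolite), lubricants and equipment surfaces, laboratory air, and
extraction/PCR reagents. `contamscreen` treats contaminant identification as
a *membership* problem at the taxonomic order level rather than a statistical
decontamination problem: an order either is or is not on a list compiled from
negative controls, and a query sample's reads are partitioned accordingly.

The procedure has three stages.

1. **ASV filtering.** Within the analysis unit, ASVs with fewer than
   `min_reads` total reads (default 5, inclusive, summed across samples — one
   sample with 5 reads and five samples with 1 read each both qualify) and
   ASVs present in fewer than `min_occurrence` samples (default 2; presence
   means at least one read) are removed. Singleton, ultra-rare ASVs in
   negative controls are dominated by index hopping and sequencing error;
   these filters remove them before any order-level statement is made.
2. **Rollup.** Surviving counts are aggregated to the working rank (default
   order) by integer summation, so per-sample read totals are conserved
   exactly. ASVs lacking a label at that rank pool into a reserved
   `unassigned` bucket whose internal name (`__unassigned__`) can never
   collide with a reference-taxonomy label. Labels are matched verbatim and
   case-sensitively: "Subgroup 2" and "subgroup 2" are different strings, and
   normalising them would be invisible data editing.
3. **Database building / screening.** For each control pool (laboratory =
   roles `control_I` + `control_II`; seawater = `control_III`) the orders are
   ranked by pooled read fraction — total reads of the order across the
   pool's samples divided by the pool's total reads, unassigned reads
   included in the denominator but excluded from the ranking — and the top
   `top_k` (default 30) orders with pooled fraction at or above
   `min_pooled_fraction` (default 1%) become the pool's list. Screening then
   labels each (sample, order) pair by the precedence: unassigned →
   below-threshold (sample relative abundance < `per_sample_threshold`,
   default 1%) → laboratory member → seawater member → endemic.

### Why these choices

* **Order level.** Mixed studies amplify different 16S regions (V4, V4–V5,
  V3–V4), so an exact-sequence cutoff cannot work across them; order is the
  lowest rank at which short, heterogeneous amplicons are still assigned
  with confidence while separating typical contaminant taxa from plausibly
  endemic ones.
* **Laboratory precedence for ubiquitous orders.** Many orders (e.g.
  *Burkholderiales*) appear in both control pools. In practice most
  contamination in drilling surveys traces to handling and reagents rather
  than seawater, so a ubiquitous order is labelled `potential_contaminant`;
  both membership flags are kept in the per-order detail table so users can
  re-bin.
* **Seawater as its own label.** Fluid flow in subsurface environments can
  carry genuinely present marine organisms, so seawater-list membership is
  reported separately, and `contamination_fraction(include_seawater = FALSE)`
  lets users exclude it from the contamination load.
* **`unassigned` is not endemic.** "Endemic" means *assigned and found in no
  control list*; reads with no assignment at the working rank carry no
  evidence either way and are reported as their own bucket.
* **Pooled fraction, not mean of per-sample fractions.** The ranking
  statistic is reads-over-pool-total, which weights deeply sequenced controls
  more. This matches a "fraction of all reads in all samples" membership rule
  and is robust to near-empty blanks; the per-sample alternative would let a
  single 50-read blank dominated by one order promote that order.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `rank` | `"order"` | aggregation rank (any of domain…genus) |
| `top_k` | 30 | orders retained per control pool |
| `min_pooled_fraction` | 0.01 | pooled-fraction floor for membership |
| `min_reads` | 5 | minimum ASV total reads (inclusive) |
| `min_occurrence` | 2 | minimum samples an ASV appears in |
| `per_sample_threshold` | 0.01 | per-sample order abundance floor |

Notes on the defaults. Published compilations of drilling-survey controls
describe both a top-25 and a top-30 rule in different places; `top_k = 30`
follows the tabulated lists, and the parameter is configurable for users who
prefer the stricter cut. Whether the ASV filters should feed the database
ranking at all is likewise not fixed by prior practice; they are applied by
default (contaminant lists should not be shaped by sequencing noise) and can
be disabled with `min_reads = 0, min_occurrence = 0`. When screening a
*single* query sample, `min_occurrence = 2` removes every ASV — occurrence is
counted within the screened set — so single-sample screening should pass
`min_occurrence = 1`, as the command-line examples do.

## The per-sample threshold and its denominator

The `below_threshold` bucket exists because sub-1% order abundances in a
low-biomass amplicon survey are rarely interpretable. The threshold is
applied *after* rollup, *within* each sample, and *independently of database
membership* — below-threshold reads are never counted as contamination, even
when the order is on a list. The denominator of every per-sample fraction is
the sample's total filtered reads across all five labels (i.e. unassigned
reads are not excluded first). Database *coverage*, by contrast, ignores the
threshold entirely: it is the plain fraction of a sample's reads whose order
is on either list, and therefore always bounds the labelled contamination
from above.

## The synthetic-data generator

`simulate_bundle()` generates control and query communities with known ground
truth:

* **Order proportions** for each sample are drawn from a Dirichlet
  distribution centred on the pool's base weights with total concentration
  `concentration` (default 50 — visible sample-to-sample variability without
  losing the pool's identity).
* **Mixing.** Control groups I/II are pure laboratory-pool draws, group III
  pure seawater-pool draws; each query mixes laboratory, seawater and endemic
  pools with planted weights `contaminant_load` (default 0.3) and
  `seawater_load` (default 0.1), the remainder endemic. Defaults reflect the
  moderate-to-heavy contamination typical of archived drilling cores.
* **ASV structure.** Each order expands into `n_asvs` ASVs with geometric
  weights of ratio `skew`; dominance-flagged orders (such as
  *Burkholderiales* in the default community, 12× base weight, 20 ASVs,
  `skew = 0.3`) therefore concentrate reads in their first few ASVs,
  reproducing the many-reads-few-ASVs signature of overamplified taxa. The
  geometric series is the simplest mechanism with that property; it is a
  stand-in, not an estimate of any amplification model.
* **Depths** are drawn log-uniformly over `depth_range` (default 10³–4×10⁵
  reads), echoing the several-orders-of-magnitude depth spread of real
  control sets, and counts are multinomial at the drawn depth, so column sums
  match depths exactly. `n_blanks` extra blanks are emitted as all-zero
  columns, mirroring extraction/PCR blanks that yield no ASVs.
* **Determinism.** Every sample has its own RNG stream keyed on
  (seed, sample id), so the seed fully determines the bundle and adding a
  sample never perturbs existing ones.

Two stock communities ship with the package. `default_community_spec()` uses
the packaged reference database's own order lists (plus ten invented endemic
orders), so simulated data exercise the reference database; its pools overlap
in the ubiquitous orders, as real pools do. `disjoint_community_spec()` uses
synthetic, non-overlapping labels so that the true laboratory fraction of a
sample is exactly its fraction of laboratory-pool reads — the configuration
used for recovery experiments.

What the generator does **not** emulate: sequence errors and chimeras (it
starts from ASVs), PCR bias beyond the static skew parameter, cross-sample
index hopping, compositional correlations between orders, or realistic
taxonomies below the order rank (other ranks are mostly missing). Passing
tests on simulated data therefore demonstrate the pipeline's correctness —
conservation, recovery of planted signal, determinism — not the biological
validity of any particular contaminant call on real data.

## Numerical choices and degenerate inputs

* Counts are integers end to end until the final division, so conservation
  checks are exact, not approximate; fraction sums are asserted to 1 ± 1e-9.
* Ranking ties are broken lexicographically (C locale, radix sort) for
  reproducibility across platforms; ties *at* the `top_k` boundary are all
  retained before the fraction floor is applied.
* Zero-read samples are kept through validation and filtering with warnings
  (they are part of the sample accounting) but excluded from relative
  abundance, database pooling and screening.
* Database JSON is written with fixed key order and full precision, and
  contains no timestamp (timestamps live in the CLI run manifest), so
  identical inputs give byte-identical files; on load, the ubiquitous set is
  recomputed from the two lists and verified against the stored value.
* The transposed feature-table dialect must be requested explicitly; a
  square-ish table silently read in the wrong orientation is the classic
  failure mode of count-table IO.
* The packaged reference lists each carry 29 orders (their source compilation
  describes "the 30 most common"); the two lists share 10 orders, two more
  than the source's own ubiquity flags — the stored ubiquitous set is the
  recomputed 10-order intersection, and the 8 flagged orders are retained in
  the file's provenance.

## Problem sizes in the test suite

The suite validates selection against brute-force oracles on hundreds of
random instances of up to 8 orders × 12 samples, recovery of planted
databases across ten seeds (12 controls per bundle, depths 5×10³–5×10⁴), and
contamination-load recovery on 20 query samples at 5×10⁴ reads with a planted
40% load, where the binomial sampling floor is σ ≈ √(0.4·0.6/5×10⁴) ≈ 0.0022
and the acceptance tolerance of 0.01 mean absolute error is roughly 3σ with
margin. Convergence of realized to planted fractions is checked at 10⁶ reads.
These sizes keep the full suite under a few seconds while leaving the
statistical assertions well-powered.

## Known limitations

* Membership screening is deliberately cruder than frequency-based
  decontamination methods; it cannot rescue a genuinely endemic member of a
  contaminant order, and ubiquitous orders may be misclassified in
  environments with real fluid-borne marine input.
* Each input table is one analysis unit; merging across sequencing runs, if
  desired, must happen upstream.
* The reference database reflects the biases of the surveys it was compiled
  from (primer sets, geographic coverage, reference-taxonomy gaps) and
  complements, never replaces, study-specific negative controls.
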