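---
title: "Detecting somatic gene conversion in Ig V-region repertoires"
author: "sgcfinder"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting somatic gene conversion in Ig V-region repertoires}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sgcfinder)
```

## The problem

Species such as the chicken express a single functional immunoglobulin V
allele per locus and diversify it mainly by **somatic gene conversion
(SGC)**: AID-initiated, templated replacement of V-gene segments by
homologous sequence copied from a library of upstream pseudogenes. A
repertoire read therefore looks like the functional allele interrupted by
tracts of pseudogene sequence, overlaid with some untemplated point
mutation (SHM). `sgcfinder` detects these conversion events, nominates the
donor pseudogene for each, and summarises conversion patterns across a
repertoire.

Only *gene-altering* conversion events are observable: a conversion that
copies sequence identical to the functional allele leaves no trace. This
single fact drives most of the design below — the min/max dual interval
definition, the detectable-core scoring of the simulator, and the caution
attached to every boundary estimate.

## Detection model

For each observed sequence the pipeline:

1. **Aligns** it globally to the functional allele
   (`Biostrings::pairwiseAlignment`, affine scores; defaults match +2,
   mismatch −3, gap open 5, gap extend 2). The sources this package
   follows name the alignment function but not the scores or mode, so
   both are exposed in `sgc_params()` and recorded with outputs.
2. **Finds maximal mismatch stretches** on functional-allele coordinates.
   A column where the read has `N` counts as a match (ambiguity must not
   fabricate conversions). A deletion marks the functional interval it
   spans; an insertion marks the two flanking functional positions, so
   length changes are never invisible.
3. **Merges** stretches whose intervening identical span is at most *x*
   nucleotides, under two windows: loose (*x* = 6, favouring longer
   proposed conversions at the risk of fusing unrelated ones) and strict
   (*x* = 3). Merged units spanning fewer than 3 nt are discarded as
   SHM-like. The minimum-span rule is applied **after** merging: two
   isolated point mutations 2 nt apart merge into a span-4 event, while a
   lone substitution never becomes an event. Every strict event nests
   inside exactly one loose event, an invariant the suite asserts on
   simulated repertoires.
4. **Nominates a donor** per loose event through three alignment sets, in
   order: (a) the event segment itself, (b) the full-length read (hits
   restricted to those overlapping the event), (c) the strict
   sub-segments. The donor search is seeded — a donor is considered only
   if it shares an exact 6-mer with the query (step 1, forward strand) —
   followed by local alignment under the same scoring; hits below a raw
   score of 20 are dropped and survivors are ranked by identity
   (matches/columns), then score, then name, with identity ties recorded
   in `co_best`. The reported Levenshtein distance always compares the
   event's observed segment with the donor segment projected onto the
   same functional interval, so distances are comparable across events
   and donors.
5. **Applies the adequacy rule**: an assignment with edit distance above
   `0.5·w` (event width *w*) is inadequate. Inadequate wide events
   (*w* > 10) are replaced by their separately annotated strict
   sub-events (parent interval kept in provenance columns); inadequate
   narrow events are reported `unmatched`.
6. **Prunes** consecutive same-donor events whose intervening functional
   segment is identical to the donor segment — in all likelihood one
   tract interrupted by a silent stretch — recomputing the edit distance
   on the merged segment. The operation is idempotent.
7. **Annotates** each event with its **maximum interval** (grown outward
   while functional and donor agree, i.e. the largest extent the tract
   could silently have), 10-nt functional-allele flanks, the 5′ distance
   to the nearest AID hotspot motif, and whether the conversion wrote a
   new hotspot into the read.

### AID hotspot conventions

The motif set is the seven trinucleotides `AGC AGT GGC GGT TGC AAC TAC`,
searched on the forward strand only (the sources list a fixed set with no
strand statement). Distance is measured from the motif's 3′-most base to
the position, so 0 means "immediately follows a motif"; positions with no
5′ motif are `NA` and excluded from histograms. The new-hotspot test pads
the event's minimum interval by 2 nt (= motif length − 1) on each side so
motifs straddling the boundary are seen; a conversion that only destroys
motifs returns `FALSE`.

### Donor projection

All donor-coordinate reasoning goes through one global alignment of each
donor to the functional allele (`project_donors()`), giving the donor base
aligned at every functional position. Pseudogene libraries are
near-identical to their functional allele, so this pairwise projection is
stable and avoids a second alignment engine; donor insertions relative to
the functional allele are dropped from the projection. The same frame
serves donor-segment extraction, maximum-interval extension, pruning, the
diversity profile and tract implanting in the simulator.

## Repertoire summaries

* `positional_coverage()` — per-position event-overlap counts (min or max
  definition), the positional conversion map; total count mass always
  equals the sum of event spans.
* `diversity_profile()` — per functional position, the Hill number of the
  donor-library base composition: the effective number of equally
  frequent bases, between 1 (monomorphic) and 4 (equifrequent). The
  underlying metric in the source literature is only constrained to that
  1–4 range; the order-1 Hill number (exp Shannon) has exactly that range
  over four symbols and is standard repertoire-diversity practice, so it
  is the default, with q ∈ {0, 1, 2} configurable. Gap and `N` characters
  are excluded from column frequencies.
* `pseudogene_usage()` — per-group (typically per-bird) percent of
  donor-assigned events per donor; `unmatched` events are excluded from
  the denominator and reported separately; donors above 2% in every
  group are `preferred_all`, in at least one group `preferred_any`.
* `usage_vs_distance()` — mean usage against germline distance (kb), with
  Spearman's ρ (midranks; ρ defined as 0 when a margin is constant) and
  an exact permutation p-value up to n = 7 pairs.
* `aid_distance_distribution()` — percent histograms of event AID
  distances against the all-positions baseline of the allele.
* `control_mode_rate()` — the false-discovery control: the identical
  pipeline run with a surrogate donor library (in the original design,
  same-family germline alleles of a species that does not gene convert),
  reporting the fraction of sequences with any called event.

## The simulator: a stated world

`simulate_repertoire()` generates reads as: functional allele, minus
sampled non-overlapping tracts replaced via the donor projection, plus
uniform per-site substitution noise. Defaults: 100 sequences, Poisson(2)
tracts per sequence, tract lengths uniform on 10–300 nt (conversion
tracts are reported to reach ~300 nt), uniform donor choice, SHM rate
0.005/nt, all randomness fixed by one seed (the caller's RNG state is
untouched). Optional switches: AID-seeded tract placement (tract starts
at most 3 nt 3′ of a motif), template jumping (a chimera of two simulated
molecules, emulating the PCR artifact), minimum visible differences per
tract.

`synthetic_reference_set()` builds the germline world: a random
functional allele plus donors whose divergence is concentrated in shared
hypervariable blocks (default five blocks of 12–30 nt at 45% per-site
divergence, 2% background). The block structure matters: real pseudogene
divergence is clustered (CDR-focused), and clustered divergence is what
makes a conversion tract appear as dense mismatch stretches that the
6-nt merge window can reassemble. Under *uniform* divergence at realistic
overall identity, the mean spacing between differences (~7 nt at 15%)
exceeds the merge window and implanted tracts shatter into
sub-threshold fragments — a world that contradicts the premise of the
method. These generator settings were fixed once; green recovery tests
establish that the detector recovers tracts in this stated world, not
that it would do so for arbitrarily diffuse divergence, for
reverse-strand donors, or for real sequencing error profiles (none of
which are modelled).

### Scoring recovery

`score_recovery()` compares detected events with the implanted truth.
Under the max definition the target is the full implanted tract. Under
the min definition it is the tract's **detectable core**: the true
difference positions clustered by the same published merge arithmetic
(within 6 nt, clusters spanning ≥ 3 nt), computed by integer arithmetic
on the truth table — the detector is, by contract, blind to silent tract
edges and to isolated 1–2 nt differences, so scoring the raw implanted
interval would penalise exactly the blindness the method's rules
prescribe. Detection requires the union of overlapping predicted events
to cover ≥ 50% of the target positions (configurable); donor accuracy
uses the largest-overlap event; the boundary error compares the bounds of
the union of overlapping events with the target bounds.

## Numerical and degenerate-input choices

* Coordinates are 1-based inclusive on the ungapped functional allele in
  every input and output; IMGT-gapped references are degapped on load
  with the gapped→ungapped map retained.
* "Within *x* nucleotides apart" is read as "number of intervening
  functional positions ≤ *x*"; the endpoint-distance alternative is
  available via `merge_gap_semantics = "endpoints"`.
* Alignment tie-breaking is delegated to the deterministic Biostrings
  traceback; identical inputs and parameters give byte-identical output.
  Note that under the default scores a 1-nt gap costs 7 against 3 per
  mismatch, so a dense mismatch block can legitimately have a gapped
  optimal alignment when chance shift-homology exists.
* Donor ranking ties are broken by raw score then donor name (never by
  library order); co-ranked donors are reported in `co_best`.
* The local-score threshold 20 is interpreted on this package's raw
  affine score scale; the external tool it models scores differently, so
  the knob is configurable and recorded.
* Queries shorter than the 6-nt seed skip the seed gate and are aligned
  exhaustively; an event whose observed segment is entirely deleted
  yields an empty query and falls through to the full-length set.
* `levenshtein()` is `utils::adist` (unit costs); the suite checks it
  against an independent DP oracle.
* Empty groups in usage tables are dropped with a warning; all-gap
  diversity columns are `NA`; a motif-free allele yields an empty AID
  baseline.

## Known limitations

* Single-donor nomination: mosaic events templated by two pseudogenes are
  nominated to one donor, as in the original method.
* Forward strand only, single functional allele per run, no
  reverse-complement donors.
* No probabilistic SHM/SGC discrimination: a dense SHM cluster spanning
  ≥ 3 nt is indistinguishable from a short conversion.
* The simulator's SHM is uniform per-site; AID-biased mutation spectra
  are not modelled.
* Boundary estimates inherit the min/max ambiguity: the true tract edge
  is unidentifiable wherever donor and functional allele agree.

## A worked example

```{r example, eval = FALSE}
rs <- synthetic_reference_set(seed = 11, distances = TRUE)
cfg <- sim_config(n_sequences = 50, events_min = 1, events_max = 3,
                  tract_min = 30, tract_max = 90, shm_rate = 0.005,
                  min_tract_diff = 5, seed = 7)
sim <- simulate_repertoire(rs, cfg)
res <- annotate_repertoire(sim$sequences, rs)
head(res$events)
score_recovery(sim$truth, res$events, sequence_ids = names(sim$sequences))
```

Every figure reported by this vignette's claims (detection rates,
diversity anchors, conservation identities) is computed by the test suite
in `tests/testthat/`; nothing here states an empirical result the tests
do not themselves produce.
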