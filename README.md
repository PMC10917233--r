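# sgcfinder

Detection, donor annotation and repertoire-level summary of **somatic gene
conversion (SGC)** events in immunoglobulin V-region sequences.

## Who this is for

In chickens (and other species relying on gene conversion), a single
functional immunoglobulin V allele is diversified by AID-initiated,
templated replacement of V-gene segments with homologous sequence copied
from a germline library of pseudogene donors, overlaid with untemplated
point mutation (SHM). `sgcfinder` is for immunogenetics groups analysing
B-cell receptor repertoires from such loci: given the functional allele, a
pseudogene library and repertoire reads (FASTA), it reports every visible
conversion event with its donor, boundaries, and AID-hotspot context, and
computes the repertoire summaries used to study conversion patterns.

## The method in brief

For each read, a global pairwise alignment to the functional allele
(affine scoring, defaults match +2 / mismatch −3 / gap open 5 / extend 2)
yields maximal mismatch stretches on functional coordinates. Stretches
within *x* nt of each other are merged into candidate events under a loose
(*x* = 6) and a strict (*x* = 3) window; merged units spanning < 3 nt are
discarded as SHM-like. Donors are nominated by seeded local alignment
(exact 6-mer seeds, step 1, min score 20) over three query sets — event
segment, full read, strict sub-segments — ranked by identity with the
Levenshtein distance of the event segment to the projected donor segment
reported. Assignments with edit distance > 0.5·*w* (event width *w*) are
inadequate; wide ones (*w* > 10) are replaced by their strict sub-events.
Same-donor neighbours separated by functional==donor sequence are merged.
Each event gets:

* a **minimum interval** (mismatch-bounded) and a **maximum interval**
  (extended while functional and donor agree — the largest extent the
  tract could silently have),
* 10-nt functional flanks, the 5′ distance to the nearest AID hotspot
  motif (`AGC AGT GGC GGT TGC AAC TAC`, forward strand, 0 = adjacent),
  and whether the conversion introduced a new hotspot.

Summaries: positional event coverage, per-position pseudogene diversity
(Hill number, 1–4), pseudogene usage with >2% "preferred" calls, usage vs
germline distance (Spearman, exact small-n permutation p), AID-distance
histograms vs the positional baseline, a false-discovery control mode
(same pipeline, surrogate same-family donor set), and a seeded simulator
with implanted tracts plus a recovery scorer.

See `vignettes/sgc-detection-methods.Rmd` for the full model, parameter
semantics and limitations.

## Worked example

Entirely self-contained (synthetic germline world, simulated repertoire):

```r
library(sgcfinder)

rs  <- synthetic_reference_set(seed = 11, distances = TRUE)
cfg <- sim_config(n_sequences = 50, events_min = 1, events_max = 3,
                  tract_min = 30, tract_max = 90, shm_rate = 0.005,
                  min_tract_diff = 5, seed = 7)
sim <- simulate_repertoire(rs, cfg)
res <- annotate_repertoire(sim$sequences, rs)
head(res$events[, c("sequence_id", "min_start", "min_end", "max_start",
                    "max_end", "donor", "levenshtein", "match_status")])
#>   sequence_id min_start min_end max_start max_end donor levenshtein match_status
#> 1     seq0001        81     150        55     202  PG08           0      optimal
#> 2     seq0001       202     208       166     269  PG04           0      optimal
#> 3     seq0001       270     285       215     300  PG07           1      optimal
#> 4     seq0002        78     148        55     149  PG08           1      optimal
#> 5     seq0002       203     212       155     221  PG06           0      optimal
#> 6     seq0002       270     285       215     300  PG07           0      optimal
```

Each row is one conversion event: `min_start..min_end` is the visibly
changed interval, `max_start..max_end` the largest interval the tract
could occupy given silent flanking identity with the nominated donor
(`PG08` etc.), and `levenshtein` the residual edit distance of the event
segment to that donor (0 = perfect template match; nonzero usually means
hypermutation on top of the tract).

Scoring against the simulator's ground truth:

```r
sc <- score_recovery(sim$truth, res$events,
                     sequence_ids = names(sim$sequences))
c(detection = sc$detection_rate, donor = sc$donor_accuracy,
  boundary_nt = sc$mean_boundary_error)
#>   detection       donor boundary_nt
#>   1.0000000   0.9693878   0.4489796
```

i.e. every implanted tract's detectable core was recovered, 97% of
detected tracts were assigned the true donor, and event boundaries were
off by under half a nucleotide on average.

Writing the event table and a usage summary:

```r
write_event_table(res$events, "events.tsv")
u <- pseudogene_usage(transform(res$events, bird = "b1"))
head(u$donors)   # mean usage percent and preferred flags per donor
```

A command-line front end with `detect` / `summarize` / `simulate` /
`score` subcommands is installed at `inst/cli/sgcfinder.R`.

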