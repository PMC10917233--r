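p0 <- sgc_params()

make_pruning_world <- function() {
  # functional and one donor agreeing on 16..19 but not 26..29
  set.seed(301)
  fun <- random_dna(60)
  d <- mutate_at(fun, c(10:15, 20:25, 30:35))
  list(fun = fun, proj = fake_projection(fun, c(P1 = d, P2 = mutate_at(fun, 40:50))),
       donor = d)
}

test_that("prune_merge merges same-donor events across identical stretches", {
  w <- make_pruning_world()
  obs <- paste0(substring(w$fun, 1, 9), substring(w$donor, 10, 25),
                substring(w$fun, 26, 60))
  aln <- align_global(obs, w$fun, p0)
  ev <- data.frame(min_start = c(10L, 20L), min_end = c(15L, 25L),
                   donor = c("P1", "P1"), levenshtein = c(0L, 0L),
                   match_status = c("optimal", "optimal"),
                   stringsAsFactors = FALSE)
  out <- prune_merge(ev, aln, obs, w$proj)
  expect_equal(nrow(out), 1L)
  expect_equal(out$min_start, 10L)
  expect_equal(out$min_end, 25L)
  expect_equal(out$levenshtein, 0L)
  # idempotent
  expect_equal(prune_merge(out, aln, obs, w$proj), out)
})

test_that("prune_merge leaves different donors and non-identical gaps alone", {
  w <- make_pruning_world()
  obs <- w$fun
  aln <- align_global(obs, w$fun, p0)
  ev_diff_donor <- data.frame(min_start = c(10L, 20L), min_end = c(15L, 25L),
                              donor = c("P1", "P2"),
                              levenshtein = c(0L, 0L),
                              match_status = c("optimal", "optimal"),
                              stringsAsFactors = FALSE)
  expect_equal(nrow(prune_merge(ev_diff_donor, aln, obs, w$proj)), 2L)
  # gap 26..29 differs between functional and P1 (donor mutated 30:35 only,
  # but 26:29 equals functional, so use 20..25 vs 30..35 whose gap is fine);
  # construct instead events around a non-identical stretch 26..29 vs donor:
  ev_bad_gap <- data.frame(min_start = c(20L, 31L), min_end = c(25L, 35L),
                           donor = c("P1", "P1"), levenshtein = c(0L, 0L),
                           match_status = c("optimal", "optimal"),
                           stringsAsFactors = FALSE)
  # intervening 26..30 contains position 30 where donor differs
  expect_equal(nrow(prune_merge(ev_bad_gap, aln, obs, w$proj)), 2L)
})

test_that("extend_max grows through identity and stops at disagreement", {
  set.seed(302)
  fun <- random_dna(40)
  # donor identical to functional on 6..9 and 16..19, different at 5 and 20
  d <- mutate_at(fun, c(1:5, 10:15, 20:24))
  proj <- fake_projection(fun, c(P1 = d))
  ev <- data.frame(min_start = 10L, min_end = 15L, donor = "P1")
  ext <- extend_max(ev, proj)
  expect_equal(ext$max_start, 6L)
  expect_equal(ext$max_end, 19L)
  expect_equal(ext$identical_flank_5len, 4L)
  expect_equal(ext$identical_flank_3len, 4L)
  # boundary: event at position 1 cannot extend 5'
  ev1 <- data.frame(min_start = 1L, min_end = 5L, donor = "P1")
  expect_equal(extend_max(ev1, proj)$max_start, 1L)
  # donor differing immediately adjacent on both sides: max == min
  d2 <- mutate_at(fun, 9:16)
  proj2 <- fake_projection(fun, c(P1 = d2))
  ext2 <- extend_max(data.frame(min_start = 10L, min_end = 15L, donor = "P1"),
                     proj2)
  expect_equal(c(ext2$max_start, ext2$max_end), c(10L, 15L))
  expect_equal(c(ext2$identical_flank_5len, ext2$identical_flank_3len),
               c(0L, 0L))
  # unmatched events stay put
  extu <- extend_max(data.frame(min_start = 10L, min_end = 15L,
                                donor = NA_character_), proj)
  expect_equal(c(extu$max_start, extu$max_end), c(10L, 15L))
})

test_that("flank_context extracts and truncates 10-nt flanks", {
  fun <- paste(rep("ACGT", 10), collapse = "")  # 40 nt
  fl <- flank_context(data.frame(min_start = 11L, min_end = 20L), fun, 10L)
  expect_equal(fl$flank5, substring(fun, 1, 10))
  expect_equal(fl$flank3, substring(fun, 21, 30))
  fl2 <- flank_context(data.frame(min_start = 4L, min_end = 20L), fun, 10L)
  expect_equal(fl2$flank5, substring(fun, 1, 3))
  fl3 <- flank_context(data.frame(min_start = 11L, min_end = 40L), fun, 10L)
  expect_equal(fl3$flank3, "")
})

test_that("aid_distance follows the 3'-end origin convention", {
  expect_equal(aid_distance(6L, "AAAGCTTTT"), 0L)  # AGC at 3..5
  expect_equal(aid_distance(8L, "AAAGCTTTT"), 2L)
  expect_equal(aid_distance(3L, "AAAGCTTTT"), NA_integer_)
  expect_equal(aid_distance(4L, "TTTTTT"), NA_integer_)
})

test_that("aid_distance equals the brute-force scan on random sequences", {
  set.seed(303)
  motifs <- p0$aid_motifs
  for (i in 1:20) {
    fun <- random_dna(300)
    pos <- seq_len(300)
    expect_equal(aid_distance(pos, fun, motifs),
                 aid_distance_bruteforce(pos, fun, motifs))
  }
})

test_that("introduces_new_hotspot compares padded windows", {
  # functional window without AGC; conversion writes one in
  fun <- "TTTTTTTTTTTTTTTTTTTT"
  obs <- "TTTTTTTTAGCTTTTTTTTT"
  aln <- identity_alignment(fun, obs)
  ev <- data.frame(min_start = 9L, min_end = 11L)
  expect_true(introduces_new_hotspot(ev, aln, obs, fun))
  # identical windows
  expect_false(introduces_new_hotspot(ev, aln, fun, fun))
  # conversion that only destroys a motif
  fun2 <- "TTTTTTTTAGCTTTTTTTTT"
  obs2 <- "TTTTTTTTTTTTTTTTTTTT"
  aln2 <- identity_alignment(fun2, obs2)
  expect_false(introduces_new_hotspot(ev, aln2, obs2, fun2))
  # motif straddling the event edge is caught by the 2-nt pad
  fun3 <- "TTTTTTTTTTTTTTTTTTTT"
  obs3 <- "TTTTTTTAGCTTTTTTTTTT"  # AGC at 8..10, event starts at 10
  aln3 <- identity_alignment(fun3, obs3)
  ev3 <- data.frame(min_start = 10L, min_end = 12L)
  expect_true(introduces_new_hotspot(ev3, aln3, obs3, fun3))
})

test_that("max interval contains min and its margin is functional==donor", {
  rs <- synthetic_reference_set(seed = 33)
  cfg <- sim_config(n_sequences = 25, events_per_sequence = 2,
                    tract_min = 20, tract_max = 80, shm_rate = 0.005,
                    min_tract_diff = 4, seed = 5)
  sim <- simulate_repertoire(rs, cfg)
  res <- annotate_repertoire(sim$sequences, rs)
  ev <- res$events
  expect_gt(nrow(ev), 0L)
  expect_true(all(ev$max_start <= ev$min_start))
  expect_true(all(ev$min_end <= ev$max_end))
  proj <- project_donors(rs)
  fun <- strsplit(unname(rs$functional), "")[[1]]
  for (i in seq_len(nrow(ev))) {
    margin <- setdiff(ev$max_start[i]:ev$max_end[i],
                      ev$min_start[i]:ev$min_end[i])
    if (length(margin) == 0L || is.na(ev$donor[i])) next
    expect_true(all(proj$donor_at[ev$donor[i], margin] == fun[margin]))
  }
})
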