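test_that("simulation is deterministic and seed-isolated", {
  rs <- synthetic_reference_set(seed = 10)
  cfg <- sim_config(n_sequences = 15, seed = 99, tract_min = 20,
                    tract_max = 60)
  a <- simulate_repertoire(rs, cfg)
  set.seed(123)  # caller RNG state must not leak in
  b <- simulate_repertoire(rs, cfg)
  expect_identical(a$sequences, b$sequences)
  expect_identical(a$truth, b$truth)
  expect_identical(a$shm, b$shm)
  # ... and the caller's RNG stream must not be disturbed by a simulation
  set.seed(123); y1 <- stats::runif(1)
  set.seed(123); invisible(simulate_repertoire(rs, cfg)); y2 <- stats::runif(1)
  expect_identical(y1, y2)
})

test_that("no events and no noise reproduces the functional allele", {
  rs <- synthetic_reference_set(seed = 10)
  cfg <- sim_config(n_sequences = 5, events_per_sequence = 0,
                    events_max = 0, shm_rate = 0, seed = 1)
  sim <- simulate_repertoire(rs, cfg)
  expect_true(all(sim$sequences == unname(rs$functional)))
  expect_equal(nrow(sim$truth), 0L)
})

test_that("implanted tracts change exactly the implanted interval", {
  rs <- synthetic_reference_set(seed = 10)
  cfg <- sim_config(n_sequences = 10, events_per_sequence = 1,
                    events_min = 1, events_max = 1, shm_rate = 0,
                    tract_min = 30, tract_max = 60, min_tract_diff = 3,
                    seed = 2)
  sim <- simulate_repertoire(rs, cfg)
  fun <- strsplit(unname(rs$functional), "")[[1]]
  proj <- project_donors(rs)
  for (i in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[i, ]
    ch <- strsplit(sim$sequences[[tr$sequence_id]], "")[[1]]
    iv <- tr$fun_start:tr$fun_end
    expect_identical(ch[iv], unname(proj$donor_at[tr$donor, iv]))
    expect_identical(ch[-iv], fun[-iv])
    diffs <- iv[ch[iv] != fun[iv]]
    expect_equal(diffs, as.integer(strsplit(tr$diff_pos, ",")[[1]]))
    expect_gte(tr$n_diff, 3L)
  }
})

test_that("SHM count matches the binomial expectation", {
  rs <- synthetic_reference_set(seed = 10)
  L <- nchar(rs$functional)
  cfg <- sim_config(n_sequences = 400, events_max = 0,
                    events_per_sequence = 0, shm_rate = 0.01, seed = 3)
  sim <- simulate_repertoire(rs, cfg)
  mean_muts <- nrow(sim$shm) / 400
  expect_lt(abs(mean_muts - 0.01 * L), 3 * sqrt(0.01 * L / 400) * 3)
})

test_that("AID-seeded placement starts tracts close 3' of motifs", {
  rs <- synthetic_reference_set(seed = 10)
  cfg <- sim_config(n_sequences = 30, events_per_sequence = 1,
                    events_min = 1, events_max = 1, shm_rate = 0,
                    tract_min = 20, tract_max = 40, aid_seeded = TRUE,
                    seed = 4)
  sim <- simulate_repertoire(rs, cfg)
  d <- aid_distance(sim$truth$fun_start, unname(rs$functional))
  expect_true(all(d <= cfg$aid_offset_max))
})

test_that("template jumping produces recorded chimeras", {
  rs <- synthetic_reference_set(seed = 10)
  cfg <- sim_config(n_sequences = 40, events_per_sequence = 1,
                    template_jump_rate = 0.5, seed = 5)
  sim <- simulate_repertoire(rs, cfg)
  expect_gt(nrow(sim$jumps), 0L)
  expect_true(all(sim$jumps$sequence_id %in% names(sim$sequences)))
})

test_that("score_recovery on perfect and empty predictions", {
  truth <- data.frame(sequence_id = c("s1", "s1", "s2"),
                      tract_index = c(1L, 2L, 1L),
                      donor = c("P1", "P2", "P1"),
                      fun_start = c(10L, 50L, 20L), fun_end = c(30L, 70L, 45L),
                      donor_start = NA_integer_, donor_end = NA_integer_,
                      core_start = c(12L, 52L, 22L), core_end = c(28L, 68L, 43L),
                      n_diff = c(8L, 8L, 8L),
                      diff_pos = c("12,13,14,20,26,27,28",
                                   "52,53,54,60,66,67,68",
                                   "22,23,24,30,41,42,43"),
                      stringsAsFactors = FALSE)
  perfect <- data.frame(sequence_id = c("s1", "s1", "s2"),
                        min_start = c(12L, 52L, 22L),
                        min_end = c(28L, 68L, 43L),
                        max_start = c(10L, 50L, 20L),
                        max_end = c(30L, 70L, 45L),
                        donor = c("P1", "P2", "P1"),
                        stringsAsFactors = FALSE)
  sc <- score_recovery(truth, perfect, sequence_ids = c("s1", "s2", "s3"))
  expect_equal(sc$detection_rate, 1)
  expect_equal(sc$donor_accuracy, 1)
  expect_equal(sc$mean_boundary_error, 0)
  expect_equal(sc$fp_events_per_clean_sequence, 0)
  scx <- score_recovery(truth, perfect, sequence_ids = c("s1", "s2"),
                        definition = "max")
  expect_equal(scx$detection_rate, 1)
  expect_equal(scx$mean_boundary_error, 0)
  empty <- perfect[0, ]
  sc0 <- score_recovery(truth, empty, sequence_ids = c("s1", "s2"))
  expect_equal(sc0$detection_rate, 0)
  # shuffled donor labels: detection stays, donor accuracy drops
  shuffled <- perfect
  shuffled$donor <- c("P2", "P1", "P2")
  scs <- score_recovery(truth, shuffled, sequence_ids = c("s1", "s2"))
  expect_equal(scs$detection_rate, 1)
  expect_equal(scs$donor_accuracy, 0)
  expect_error(score_recovery(truth, perfect, sequence_ids = "s1"),
               "unknown sequence id")
})

test_that("perfect-world recovery: no noise, distinct donors", {
  rs <- synthetic_reference_set(seed = 12, n_donors = 4)
  cfg <- sim_config(n_sequences = 30, events_per_sequence = 1,
                    events_min = 1, events_max = 2, shm_rate = 0,
                    tract_min = 25, tract_max = 70, min_tract_diff = 5,
                    seed = 6)
  sim <- simulate_repertoire(rs, cfg)
  res <- annotate_repertoire(sim$sequences, rs)
  sc <- score_recovery(sim$truth, res$events,
                       sequence_ids = names(sim$sequences))
  expect_equal(sc$detection_rate, 1)
  expect_gt(sc$donor_accuracy, 0.9)
})

test_that("detection degrades as hypermutation noise rises", {
  rs <- synthetic_reference_set(seed = 13)
  rates <- c(0, 0.005, 0.01, 0.02)
  det <- vapply(rates, function(r) {
    cfg <- sim_config(n_sequences = 40, events_per_sequence = 1,
                      events_min = 1, events_max = 2, shm_rate = r,
                      tract_min = 30, tract_max = 80, min_tract_diff = 5,
                      seed = 7)
    sim <- simulate_repertoire(rs, cfg)
    res <- annotate_repertoire(sim$sequences, rs)
    score_recovery(sim$truth, res$events,
                   sequence_ids = names(sim$sequences))$detection_rate
  }, 0)
  expect_true(all(diff(det) <= 1e-9))
})
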