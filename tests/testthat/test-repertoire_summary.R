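mk_events <- function(starts, ends, donors = NULL, birds = "b1",
                      ids = NULL) {
  n <- length(starts)
  if (is.null(ids)) ids <- sprintf("s%d", seq_len(n))
  data.frame(sequence_id = ids,
             bird = rep_len(birds, n),
             min_start = as.integer(starts), min_end = as.integer(ends),
             max_start = as.integer(starts), max_end = as.integer(ends),
             donor = if (is.null(donors)) rep("P1", n) else donors,
             stringsAsFactors = FALSE)
}

test_that("positional_coverage counts event overlap per position", {
  pc <- positional_coverage(mk_events(5, 7), 10)
  expect_equal(pc$profile$count, c(0, 0, 0, 0, 1, 1, 1, 0, 0, 0))
  pc2 <- positional_coverage(mk_events(c(5, 7), c(7, 9)), 10)
  expect_equal(pc2$profile$count[7], 2)
  pc0 <- positional_coverage(mk_events(integer(), integer()), 10)
  expect_equal(pc0$profile$count, rep(0L, 10))
  # conservation: total mass equals the sum of event spans
  ev <- mk_events(c(2, 5, 8), c(4, 9, 8))
  pc3 <- positional_coverage(ev, 12)
  expect_equal(sum(pc3$profile$count),
               sum(ev$min_end - ev$min_start + 1L))
})

test_that("positional_coverage grouping splits counts and keeps mass", {
  ev <- mk_events(c(2, 5, 8), c(4, 9, 8), birds = c("b1", "b2", "b1"))
  pc <- positional_coverage(ev, 12, group_by = "bird")
  expect_equal(sum(pc$profile$count),
               sum(ev$min_end - ev$min_start + 1L))
  b1 <- pc$profile[pc$profile$bird == "b1", ]
  expect_equal(sum(b1$count), 3 + 1)
})

test_that("diversity_profile hits its exact anchor values", {
  m <- rbind(c("A", "A", "A", "A"),
             c("A", "C", "G", "C"),
             c("A", "A", "T", "G"),
             c("A", "C", "C", "T"))
  dp <- diversity_profile(m)
  expect_equal(dp$score[1], 1, tolerance = 1e-12)          # monomorphic
  expect_equal(dp$score[2], 2, tolerance = 1e-12)          # 50/50 two-base
  expect_equal(dp$score[4], 4, tolerance = 1e-12)          # uniform
  expect_true(all(dp$score >= 1 - 1e-12 & dp$score <= 4 + 1e-12))
  # gap/N columns are excluded from frequencies; all-gap column is NA
  m2 <- rbind(c("A", "-"), c("A", "-"), c("N", "-"))
  dp2 <- diversity_profile(m2)
  expect_equal(dp2$score[1], 1)
  expect_true(is.na(dp2$score[2]))
  # alternative orders keep the anchors
  expect_equal(diversity_profile(m, q = 0)$score[2], 2)
  expect_equal(diversity_profile(m, q = 2)$score[4], 4)
})

test_that("diversity_profile bounds hold on random libraries (property)", {
  set.seed(401)
  for (i in 1:25) {
    m <- matrix(sample(c("A", "C", "G", "T"), 40 * 8, TRUE), nrow = 8)
    sc <- diversity_profile(m)$score
    expect_true(all(sc >= 1 - 1e-9 & sc <= 4 + 1e-9))
    mono <- apply(m, 2, function(col) length(unique(col)) == 1L)
    expect_true(all(abs(sc[mono] - 1) < 1e-12))
  }
})

test_that("pseudogene_usage computes percents and preferred flags", {
  donors <- c(rep("P1", 5), rep("P2", 95))
  ev <- mk_events(rep(5, 100), rep(9, 100), donors = donors)
  u <- pseudogene_usage(ev, threshold = 2)
  expect_equal(u$usage$percent[u$usage$donor == "P1"], 5)
  expect_true(u$donors$preferred_all[u$donors$donor == "P1"])
  # 3% in bird A, 1% in bird B: preferred_any but not preferred_all
  evA <- mk_events(rep(5, 100), rep(9, 100),
                   donors = c(rep("PX", 3), rep("PZ", 97)), birds = "A")
  evB <- mk_events(rep(5, 100), rep(9, 100),
                   donors = c(rep("PX", 1), rep("PZ", 99)), birds = "B")
  u2 <- pseudogene_usage(rbind(evA, evB), threshold = 2)
  px <- u2$donors[u2$donors$donor == "PX", ]
  expect_true(px$preferred_any)
  expect_false(px$preferred_all)
  # unmatched events are excluded from the denominator
  ev3 <- mk_events(rep(5, 10), rep(9, 10),
                   donors = c(rep("P1", 5), rep(NA, 5)))
  u3 <- pseudogene_usage(ev3)
  expect_equal(u3$usage$percent, 100)
  expect_equal(u3$unmatched$n_unmatched, 5L)
  # percents sum to 100 per group
  for (g in unique(u2$usage$group)) {
    expect_equal(sum(u2$usage$percent[u2$usage$group == g]), 100,
                 tolerance = 1e-9)
  }
  # missing group metadata pools into one "(ungrouped)" group
  ev_na <- mk_events(rep(5, 4), rep(9, 4))
  ev_na$bird <- NA_character_
  una <- pseudogene_usage(ev_na)
  expect_equal(unique(una$usage$group), "(ungrouped)")
  expect_equal(sum(una$usage$percent), 100)
})

test_that("usage_vs_distance reports Spearman rho with exact p for small n", {
  ev <- mk_events(rep(5, 100), rep(9, 100),
                  donors = rep(paste0("P", 1:5), times = c(40, 30, 15, 10, 5)))
  u <- pseudogene_usage(ev)
  d <- c(P1 = 1, P2 = 2, P3 = 5, P4 = 9, P5 = 14)
  uv <- usage_vs_distance(u, d)
  expect_equal(uv$rho, -1)
  expect_equal(uv$p_value, 2 / factorial(5), tolerance = 1e-12)
  # constant usage: rho defined as 0
  ev_const <- mk_events(rep(5, 100), rep(9, 100),
                        donors = rep(paste0("P", 1:5), each = 20))
  uvc <- usage_vs_distance(pseudogene_usage(ev_const), d)
  expect_equal(uvc$rho, 0)
  # 6-donor table equals the direct rank formula (no ties)
  set.seed(402)
  usage6 <- c(12, 30, 8, 25, 20, 5)
  ev6 <- mk_events(rep(5, 100), rep(9, 100),
                   donors = rep(paste0("P", 1:6), times = usage6))
  d6 <- c(P1 = 3, P2 = 1, P3 = 11, P4 = 6, P5 = 8, P6 = 20)
  uv6 <- usage_vs_distance(pseudogene_usage(ev6), d6)
  rd <- rank(d6[uv6$table$donor]); ru <- rank(uv6$table$mean_percent)
  rho_formula <- 1 - 6 * sum((rd - ru)^2) / (6 * (36 - 1))
  expect_equal(uv6$rho, rho_formula, tolerance = 1e-12)
  # < 3 paired donors: table only
  uv2 <- usage_vs_distance(u, d[1:2])
  expect_true(is.na(uv2$rho))
  expect_equal(nrow(uv2$table), 2L)
})

test_that("aid_distance_distribution compares events with the baseline", {
  fun <- paste0("AAAGC", paste(rep("T", 25), collapse = ""))  # motif at 3..5
  ev <- mk_events(rep(6, 4), rep(9, 4))  # all starts right after the motif
  h <- aid_distance_distribution(ev, fun)
  expect_equal(h$event$distance, 0L)
  expect_equal(h$event$percent, 100)
  expect_equal(sum(h$baseline$percent), 100, tolerance = 1e-9)
  # motif-free allele: empty baseline and no scoreable events
  h0 <- aid_distance_distribution(ev, paste(rep("T", 30), collapse = ""))
  expect_equal(nrow(h0$baseline), 0L)
  expect_equal(h0$n_events, 0L)
  # baseline equals the brute-force scan
  set.seed(403)
  fun2 <- random_dna(80)
  h2 <- aid_distance_distribution(mk_events(10, 14), fun2)
  brute <- aid_distance_bruteforce(seq_len(80), fun2, sgc_params()$aid_motifs)
  brute <- brute[!is.na(brute)]
  expect_equal(h2$baseline$distance, sort(unique(brute)))
  expect_equal(h2$baseline$percent,
               100 * as.vector(table(brute)) / length(brute))
})

test_that("control mode is silent on clean or point-mutated sequences", {
  rs <- synthetic_reference_set(seed = 44, n_donors = 4)
  fun <- unname(rs$functional)
  clean <- stats::setNames(rep(fun, 3), paste0("c", 1:3))
  out <- control_mode_rate(clean, rs$functional, rs$pseudogenes)
  expect_equal(out$rate, 0)
  # isolated 1-2 nt substitutions never produce events
  set.seed(404)
  iso <- vapply(1:5, function(i) mutate_at(fun, c(30, 120, 210)), "")
  names(iso) <- paste0("i", 1:5)
  out2 <- control_mode_rate(iso, rs$functional, rs$pseudogenes)
  expect_equal(out2$rate, 0)
  expect_error(control_mode_rate(clean, rs$functional, character()), "empty")
})

test_that("sequence_event_stats counts per group", {
  rec <- data.frame(id = paste0("s", 1:10), bird = rep(c("b1", "b2"), 5),
                    n_events = c(0, 1, 2, 0, 3, 1, 0, 0, 2, 5))
  st <- sequence_event_stats(rec)
  expect_equal(st$pct_with_event, 60)
  expect_equal(st$pct_with_2plus, 40)
  expect_equal(st$mean_events, 1.4)
  stg <- sequence_event_stats(rec, group_by = "bird")
  expect_equal(nrow(stg), 2L)
  expect_equal(sort(stg$group), c("b1", "b2"))
  b1 <- stg[stg$group == "b1", ]
  expect_equal(b1$pct_with_event, 100 * mean(c(0, 2, 3, 0, 2) >= 1))
})
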