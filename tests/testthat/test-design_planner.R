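test_that("split_grid tiles and truncates", {
  img <- matrix(seq_len(300 * 300), 300, 300)
  g <- split_grid(img)
  expect_length(g, 9L)
  expect_true(all(vapply(g, function(p) all(dim(p) == c(100, 100)), logical(1))))
  # reassembly reproduces the image
  rebuilt <- rbind(cbind(g$p1, g$p2, g$p3),
                   cbind(g$p4, g$p5, g$p6),
                   cbind(g$p7, g$p8, g$p9))
  expect_identical(rebuilt, img)

  g2 <- split_grid(matrix(0, 301, 302))
  expect_true(all(vapply(g2, function(p) all(dim(p) == c(100, 100)), logical(1))))
  expect_error(split_grid(matrix(0, 2, 2)), "too small")
})

test_that("eccentricity geometry reproduces the printed display values", {
  expect_equal(eccentricity_dva(5, 19.4), 0)
  expect_equal(round(eccentricity_dva(2, 19.4), 1), 6.5)
  expect_equal(round(eccentricity_dva(1, 19.4), 1), 9.2)
  # small-angle limit: ratios approach {0, 1, sqrt(2)} of a patch width
  w <- 0.3
  expect_equal(eccentricity_dva(2, 3 * w) / w, 1, tolerance = 1e-4)
  expect_equal(eccentricity_dva(1, 3 * w) / w, sqrt(2), tolerance = 1e-4)
  expect_error(eccentricity_dva(10, 19.4), "location")
})

test_that("eccentricity classes map the 3x3 grid", {
  expect_identical(eccentricity_class(5L), "fovea")
  expect_identical(eccentricity_class(c(2L, 4L, 6L, 8L)),
                   rep("parafovea", 4))
  expect_identical(eccentricity_class(c(1L, 3L, 7L, 9L)),
                   rep("periphery", 4))
  expect_error(eccentricity_class(0), "location")
})

test_that("visual_angle", {
  expect_equal(visual_angle(0, 60), 0)
  expect_equal(round(visual_angle(20.5, 60), 1), 19.4)
  expect_gt(visual_angle(20.5, 30), visual_angle(20.5, 60))
  expect_error(visual_angle(10, 0), "distance")
})

test_that("trial plans satisfy the probe-composition invariants", {
  # exp1, odd critical location: 21 probes, presents at remaining odd locations
  p <- plan_trial("exp1", "pairA", "congruent", 5L, rng_seed = 11)
  expect_equal(nrow(p), 21L)
  expect_equal(sum(p$patch_type == "original"), 1L)
  expect_equal(sum(p$patch_type == "modified"), 1L)
  expect_equal(sum(p$patch_type == "present"), 4L)
  expect_equal(sum(p$patch_type == "null"), 15L)
  expect_setequal(p$location[p$patch_type == "present"], c(1, 3, 7, 9))
  expect_equal(unique(p$location[p$patch_type %in% c("original", "modified")]), 5)
  expect_identical(attr(p, "location_set"), "odd")

  # exp1, even critical location: 20 probes
  p2 <- plan_trial("exp1", "pairA", "congruent", 4L, rng_seed = 11)
  expect_equal(nrow(p2), 20L)
  expect_equal(sum(p2$patch_type == "present"), 3L)
  expect_identical(attr(p2, "location_set"), "even")

  # exp2: 6 probes, exactly one critical of the requested kind
  p3 <- plan_trial("exp2", "pairA", "incongruent", 7L, rng_seed = 11,
                   critical_kind = "modified")
  expect_equal(nrow(p3), 6L)
  expect_equal(sum(p3$patch_type == "modified"), 1L)
  expect_equal(sum(p3$patch_type == "original"), 0L)
  expect_equal(sum(p3$patch_type == "present"), 2L)
  expect_equal(sum(p3$patch_type == "null"), 3L)

  # reproducibility: same seed, identical plan; plans leave global RNG alone
  expect_identical(plan_trial("exp1", "x", "congruent", 3L, 99),
                   plan_trial("exp1", "x", "congruent", 3L, 99))

  # property over random seeds
  set.seed(33)
  for (i in 1:25) {
    loc <- sample(1:9, 1)
    pp <- plan_trial("exp1", "p", "incongruent", loc, rng_seed = sample(1e6, 1))
    expect_equal(nrow(pp), if (loc %% 2 == 1) 21L else 20L)
    expect_true(all(pp$location[pp$patch_type == "present"] %% 2 == loc %% 2))
  }
})

test_that("null-patch allocation is disjoint and capacity-checked", {
  pool <- sprintf("np%04d", 1:7044)
  a <- allocate_nulls(15, 15, pool, "img1", rng_seed = 7)
  expect_equal(nrow(a), 225L)
  expect_equal(length(unique(a$patch_id)), 225L)
  split_ids <- split(a$patch_id, a$participant)
  for (i in 1:14) {
    expect_length(intersect(split_ids[[i]], split_ids[[i + 1]]), 0L)
  }
  small <- allocate_nulls(1, 3, c("a", "b", "c"), "img", 1)
  expect_setequal(small$patch_id, c("a", "b", "c"))
  expect_error(allocate_nulls(2, 3, letters[1:5], "img", 1), "short by 1")
})

test_that("experiment 2 cohort arithmetic", {
  p <- plan_experiment2(136, 34, 60)
  expect_equal(p$n_participants, 240L)
  expect_equal(p$n_batches, 4L)
  expect_equal(p$n_trials, 8160L)
  expect_equal(p$batches[[2]], 35:68)
  expect_equal(plan_experiment2(34, 34, 1)$n_participants, 1L)
  expect_error(plan_experiment2(100, 34, 60), "divisible")
})

test_that("catch cutoff: exact binomial and Monte-Carlo agree", {
  expect_equal(catch_cutoff(13, 8, 0.99)$cutoff, 0.38)
  expect_equal(catch_cutoff(13, 8, 0.99)$k, 5L)
  expect_equal(catch_cutoff(12, 8, 0.99)$cutoff, 0.42)
  expect_equal(catch_cutoff(5, 1, 0.99)$cutoff, 1.00)
  expect_error(catch_cutoff(13, 8, 1.2), "quantile")
  mc <- catch_cutoff(13, 8, 0.99, method = "montecarlo", n_sim = 1e5, seed = 4)
  expect_lte(abs(mc$cutoff_raw - catch_cutoff(13, 8, 0.99)$cutoff_raw), 1 / 13)
  # non-increasing in the number of options
  cuts <- vapply(c(2, 4, 8, 16), function(k) catch_cutoff(13, k, 0.99)$cutoff_raw,
                 numeric(1))
  expect_true(all(diff(cuts) <= 0))
})

test_that("full design plans respect per-participant structure", {
  d1 <- plan_experiment("exp1", tiny_pairs(82), n_participants = 3, seed = 5)
  tr <- d1$trials
  expect_equal(nrow(tr), 3 * 80)
  by_part <- split(tr, tr$participant)
  for (b in by_part) {
    expect_equal(nrow(b), 80L)
    expect_equal(sum(b$congruence == "congruent"), 40L)
    expect_equal(anyDuplicated(b$pair_id), 0L) # no initial image repeats
  }

  d2 <- plan_experiment("exp2", tiny_pairs(136), n_participants = 4, seed = 5)
  tr2 <- d2$trials
  by_part2 <- split(tr2, tr2$participant)
  for (b in by_part2) {
    expect_equal(nrow(b), 34L)
    expect_equal(sum(b$congruence == "congruent"), 17L)
    expect_equal(anyDuplicated(b$pair_id), 0L)
  }
  cs <- split(d2$catch_schedule, d2$catch_schedule$participant)
  for (b in cs) {
    expect_equal(nrow(b), 13L)
    expect_equal(sum(b$phase == "practice"), 1L)
    expect_equal(sum(b$phase == "experimental"), 12L)
  }
  # determinism
  d2b <- plan_experiment("exp2", tiny_pairs(136), n_participants = 4, seed = 5)
  expect_identical(d2$trials, d2b$trials)
})
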