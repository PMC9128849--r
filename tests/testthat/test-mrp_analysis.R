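test_that("delta tD x C: frozen arithmetic, antisymmetry, bounds", {
  expect_equal(delta_tdxc(c(1, 2, 3), c(1, 2, 3)), 0)
  orig <- transform_tdxc(c(4, 4, 3))
  modf <- transform_tdxc(c(1, -2))
  expect_equal(delta_tdxc(orig, modf), 3.1666667 - (-0.5), tolerance = 1e-6)
  expect_equal(delta_tdxc(rep(3.5, 5), rep(-3.5, 5)), 7)
  expect_equal(delta_tdxc(orig, modf), -delta_tdxc(modf, orig))
  expect_error(delta_tdxc(numeric(0), 1), "insufficient")

  set.seed(12)
  for (i in 1:50) {
    a <- transform_tdxc(rand_dxc(10)); b <- transform_tdxc(rand_dxc(10))
    expect_lte(abs(delta_tdxc(a, b)), 7)
  }
})

test_that("classify_image_pair colours constructed effect patterns", {
  set.seed(5)
  base <- function(cong, type, dxc) make_responses(type, dxc, congruence = cong)
  # large effect only under congruent -> blue
  d_blue <- rbind(
    base("congruent", "original", rep(c(4, 3), 8)),
    base("congruent", "modified", rep(c(-4, -3), 8)),
    base("incongruent", "original", rand_dxc(16)),
    base("incongruent", "modified", rand_dxc(16))
  )
  r <- classify_image_pair(d_blue)
  expect_identical(r$category, "blue")
  expect_gt(r$delta_tdxc_congruent, 5)

  # opposite-sign large effects -> black with the interaction flagged
  d_black <- rbind(
    base("congruent", "original", rep(c(4, 3), 10)),
    base("congruent", "modified", rep(c(-4, -3), 10)),
    base("incongruent", "original", rep(c(-4, -3), 10)),
    base("incongruent", "modified", rep(c(4, 3), 10))
  )
  rb <- classify_image_pair(d_black)
  expect_identical(rb$category, "black")
  expect_true(rb$interaction_flag)
  expect_lt(rb$delta_tdxc_incongruent, 0)

  # untestable cell (single observation) -> missing category, not guessed
  d_small <- rbind(
    base("congruent", "original", 4), base("congruent", "modified", -4),
    base("incongruent", "original", rand_dxc(5)),
    base("incongruent", "modified", rand_dxc(5))
  )
  expect_true(is.na(classify_image_pair(d_small)$category))
})

test_that("classifier type-I error is calibrated under a null effect", {
  # modest Monte-Carlo here (the full 1e4-rep version runs in acceptance)
  set.seed(61)
  reps <- 800
  fp <- logical(reps)
  for (i in seq_len(reps)) {
    d <- rbind(
      make_responses("original", rand_dxc(15), congruence = "congruent"),
      make_responses("modified", rand_dxc(15), congruence = "congruent"),
      make_responses("original", rand_dxc(15), congruence = "incongruent"),
      make_responses("modified", rand_dxc(15), congruence = "incongruent")
    )
    fp[i] <- classify_image_pair(d)$p_congruent < 0.05
  }
  se <- sqrt(0.05 * 0.95 / reps)
  expect_lt(abs(mean(fp) - 0.05), 4 * se)
})

test_that("proportion curves normalize per participant and flag separations", {
  plan <- plan_experiment("exp1", tiny_pairs(82), n_participants = 6, seed = 51)
  resp <- simulate_responses(plan, sdt_preset("default"), seed = 51)
  pc <- proportion_curves(resp)
  sums <- tapply(pc$per_participant$proportion,
                 list(pc$per_participant$participant_id, pc$per_participant$group),
                 sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  expect_equal(nrow(pc$curves), 16L) # 2 groups x 8 bins
  # present curve dominated by high-confidence yes, null curve by high-conf no
  m <- function(g, b) pc$curves$mean[pc$curves$group == g & pc$curves$dxc == b]
  expect_gt(m("signal", 4), m("signal", -4))
  expect_gt(m("noise", -4), m("noise", 4))
  # strong separation at the extremes should be flagged at the * threshold
  expect_true(pc$tests$star[pc$tests$dxc == 4])

  # identical populations: flags are rare (null calibration is in acceptance)
  pc0 <- proportion_curves(resp, groups = list(a = "null", b = "null"))
  expect_true(all(is.na(pc0$tests$p_value) | pc0$tests$p_value > 0.003 |
                    !pc0$tests$star))
})

test_that("auc_summary: chance and ceiling presets, missing Type 2", {
  plan <- plan_experiment("exp1", tiny_pairs(82), n_participants = 5, seed = 71)
  null_resp <- simulate_responses(plan, sdt_preset("null"), seed = 71)
  a0 <- auc_summary(null_resp, "present_vs_null", by_stratum = FALSE)
  expect_lt(abs(a0$summary$type1_mean - 0.5), 0.02)

  perfect <- simulate_responses(plan, sdt_preset("perfect"), seed = 72)
  a1 <- auc_summary(perfect, "present_vs_null", by_stratum = FALSE)
  expect_equal(a1$auc$type1_auc, rep(1.0, 5))
  # no errors at all -> Type 2 undefined, reported missing
  expect_true(all(is.na(a1$auc$type2_auc)))
  expect_equal(a1$summary$type2_n, 0)
})

test_that("likelihood-ratio chi-squared plumbing", {
  r0 <- lrt_chi2(-100, -100, 1)
  expect_equal(r0$chi2, 0)
  expect_equal(r0$p, 1)
  r1 <- lrt_chi2(-100, -102, 1)
  expect_equal(r1$chi2, 4)
  expect_equal(r1$p, pchisq(4, 1, lower.tail = FALSE))
  expect_equal(round(r1$p, 4), 0.0455)
  r2 <- lrt_chi2(-100, -102, 2)
  expect_equal(round(r2$p, 4), 0.1353)
  expect_error(lrt_chi2(-102, -100, 1), "misordered")
  expect_error(lrt_chi2(-100, -102, 0), "df_diff")
})

test_that("modelling export is tidy and joinable with image stats", {
  plan <- plan_experiment("exp2", tiny_pairs(34), n_participants = 3, seed = 81)
  resp <- simulate_responses(plan, sdt_preset("default"), seed = 81)
  ex <- modelling_export(resp)
  expect_true(all(c("image_pair_id", "congruence", "delta_tdxc", "n") %in% names(ex)))
  expect_true(all(abs(ex$delta_tdxc[!is.na(ex$delta_tdxc)]) <= 7))

  fx <- make_fixture_pair(90L, c(10L, 10L, 30L, 30L), texture_seed = 1)
  st <- image_pair_stats(ex$image_pair_id[1], fx$img_a, fx$img_b)
  ex2 <- modelling_export(resp, image_stats = st)
  expect_true("object_size" %in% names(ex2))
  expect_equal(sum(!is.na(ex2$object_size)),
               sum(ex2$image_pair_id == ex$image_pair_id[1]))
})
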