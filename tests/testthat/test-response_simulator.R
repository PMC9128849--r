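test_that("sdt_params validates its inputs", {
  expect_error(sdt_params(matrix(0, 4, 3), matrix(0, 4, 3),
                          seq(-3, 3, 1)), "sigmas")
  expect_error(sdt_params(matrix(0, 4, 3), matrix(1, 4, 3), c(1, 2, 3)),
               "criteria")
  expect_error(sdt_params(matrix(0, 4, 3), matrix(1, 4, 3),
                          seq(3, -3, -1)), "criteria")
  expect_error(sdt_params(matrix(0, 4, 3), matrix(1, 4, 3),
                          seq(-3, 3, 1), lapse_rate = 1.5), "lapse")
  p <- sdt_preset("default")
  expect_s3_class(p, "sdt_params")
  expect_true(all(diff(p$criteria) > 0))
})

test_that("true_rating_auc: closed form against edge cases and Monte Carlo", {
  nullp <- sdt_preset("null")
  expect_equal(true_rating_auc(nullp, "present", "null"), 0.5)

  # d' = 1 equal variance: below the continuous ceiling pnorm(1/sqrt(2))
  p1 <- sdt_params(rbind(c(0, 0, 0), c(1, 1, 1), c(1, 1, 1), c(0, 0, 0)),
                   matrix(1, 4, 3), seq(-2.25, 2.25, 0.75))
  auc1 <- true_rating_auc(p1, "present", "null")
  expect_lt(auc1, pnorm(1 / sqrt(2)))
  expect_gt(auc1, 0.5)

  # collapsing criteria toward one point drives the AUC toward 0.5
  eps <- 1e-6
  collapsed <- sdt_params(p1$mu, p1$sigma, 0.5 + eps * (-3:3))
  # one effective cut at 0.5: AUC of a two-point rating scale
  expect_lt(true_rating_auc(collapsed, "present", "null"), auc1)

  # Monte-Carlo cross-check of the closed form (independent route)
  set.seed(42)
  n <- 2e5
  s <- findInterval(rnorm(n, 1, 1), p1$criteria)
  no <- findInterval(rnorm(n, 0, 1), p1$criteria)
  # rank AUC from binned counts
  ts <- tabulate(s + 1L, 8); tn <- tabulate(no + 1L, 8)
  ps <- ts / sum(ts); pn <- tn / sum(tn)
  mc_auc <- sum(ps * (cumsum(pn) - pn)) + 0.5 * sum(ps * pn)
  expect_equal(true_rating_auc(p1, "present", "null"), mc_auc, tolerance = 5e-3)
})

test_that("simulate_dxc recovers chance and ceiling AUCs", {
  s <- simulate_dxc(10000, mu = 0, sigma = 1, rng = 7)
  n <- simulate_dxc(10000, mu = 0, sigma = 1, rng = 8)
  expect_lt(abs(type1_roc(s, n)$auc - 0.5), 0.02)

  s2 <- simulate_dxc(2000, mu = 100, sigma = 1, rng = 9)
  n2 <- simulate_dxc(2000, mu = -100, sigma = 1, rng = 10)
  expect_equal(type1_roc(s2, n2)$auc, 1.0)
})

test_that("parameter recovery across a d-prime grid", {
  crit <- seq(-2.25, 2.25, 0.75)
  for (dp in c(0, 0.5, 1, 2)) {
    p <- sdt_params(rbind(c(0, 0, 0), rep(dp, 3), rep(dp, 3), c(0, 0, 0)),
                    matrix(1, 4, 3), crit)
    truth <- true_rating_auc(p, "present", "null")
    s <- simulate_dxc(5000, dp, 1, crit, rng = 100 + dp * 10)
    n <- simulate_dxc(5000, 0, 1, crit, rng = 200 + dp * 10)
    expect_lt(abs(type1_roc(s, n)$auc - truth), 0.02)
  }
})

test_that("simulated responses carry Type 2 signal that shuffling destroys", {
  plan <- plan_experiment("exp1", tiny_pairs(82), n_participants = 4, seed = 21)
  resp <- simulate_responses(plan, sdt_preset("default"), seed = 21)
  correct <- classify_correct(resp$decision, resp$patch_type, "present_vs_null")
  conf_c <- resp$confidence[which(correct)]
  conf_i <- resp$confidence[which(!correct)]
  t2 <- type2_roc(conf_c, conf_i)$auc
  expect_gt(t2, 0.5)

  set.seed(77)
  shuf <- sample(resp$confidence)
  t2s <- type2_roc(shuf[which(correct)], shuf[which(!correct)])$auc
  expect_lt(abs(t2s - 0.5), 0.02)
})

test_that("default preset reproduces the qualitative effect directions", {
  plan <- plan_experiment("exp1", tiny_pairs(82), n_participants = 10, seed = 32)
  resp <- simulate_responses(plan, sdt_preset("default"), seed = 32)

  pn <- auc_summary(resp, "present_vs_null", by_stratum = TRUE)
  om_c <- auc_summary(resp, "original_vs_modified", by_stratum = FALSE,
                      congruence = "congruent")
  om_i <- auc_summary(resp, "original_vs_modified", by_stratum = FALSE,
                      congruence = "incongruent")
  m <- function(x, s = "all") x$summary$type1_mean[x$summary$stratum == s]
  expect_gt(m(pn), m(om_c))          # present/null easier than original/modified
  expect_gt(m(om_c), m(om_i))        # congruent gist helps
  # eccentricity attenuation: fovea > parafovea > periphery
  expect_gt(m(pn, "fovea"), m(pn, "parafovea"))
  expect_gt(m(pn, "parafovea"), m(pn, "periphery"))
})

test_that("catch-trial agents behave as designed", {
  att <- agent_profile("attentive", sdt_preset("perfect")) # lapse 0
  expect_equal(simulate_catch(att, 13, seed = 1), 1.0)

  accs <- vapply(1:4000, function(s)
    simulate_catch(agent_profile("random"), 13, seed = s), numeric(1))
  expect_lt(abs(mean(accs) - 1 / 8), 0.01)
  # false-pass rate at the 0.38 cutoff is at most 1% by construction
  expect_lte(mean(accs > 0.38), 0.015)
})

test_that("simulate_responses is deterministic and schema-valid", {
  plan <- plan_experiment("exp2", tiny_pairs(34), n_participants = 2, seed = 3)
  r1 <- simulate_responses(plan, sdt_preset("default"), seed = 3)
  r2 <- simulate_responses(plan, sdt_preset("default"), seed = 3)
  expect_identical(r1, r2)
  expect_silent(validate_responses(r1))
  # 34 trials x 6 probes + 13 catch rows per participant
  expect_equal(nrow(r1), 2 * (34 * 6 + 13))
  expect_equal(sum(r1$is_catch), 26L)
})
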