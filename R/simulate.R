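# Generative rating model for synthetic response tables. Each probe draws a
# scalar evidence value X ~ Normal(mu[role, eccentricity], sigma[role,
# eccentricity]); seven fixed, strictly increasing criteria partition the
# evidence axis into the 8 D x C bins (-4 .. -1, +1 .. +4). The middle
# criterion is the yes/no decision criterion; distance from it in criterion
# steps is the confidence. With probability `lapse_rate` the response is
# instead uniform over the 8 options (attention failure). This is standard
# unequal-variance rating SDT, so the exact population AUC of the
# discretized ratings is available in closed form (true_rating_auc).

PATCH_ROLES <- c("null", "present", "original", "modified")
ECC_CLASSES <- c("fovea", "parafovea", "periphery")

#' Rating-model parameters
#'
#' @param mu,sigma 4 x 3 numeric matrices (rows = patch roles `null`,
#'   `present`, `original`, `modified`; columns = `fovea`, `parafovea`,
#'   `periphery`): evidence means and SDs in criterion units.
#' @param criteria 7 strictly increasing thresholds partitioning the
#'   evidence axis into the 8 D x C bins; the 4th is the yes/no criterion.
#' @param congruence_effect additive widening of the original-modified
#'   separation when the initial image is congruent with the scene gist
#'   (+half to original, -half to modified).
#' @param lapse_rate probability of a uniformly random response.
#' @return object of class `sdt_params`.
#' @seealso [sdt_preset()] for named, versioned presets.
#' @export
sdt_params <- function(mu, sigma, criteria, congruence_effect = 0,
                       lapse_rate = 0) {
  mu <- .as_role_matrix(mu, "mu")
  sigma <- .as_role_matrix(sigma, "sigma")
  if (any(sigma <= 0)) stop("all sigmas must be > 0", call. = FALSE)
  if (length(criteria) != 7L || any(diff(criteria) <= 0)) {
    stop("`criteria` must be 7 strictly increasing thresholds", call. = FALSE)
  }
  if (lapse_rate < 0 || lapse_rate > 1) {
    stop("`lapse_rate` must be in [0, 1]", call. = FALSE)
  }
  structure(list(mu = mu, sigma = sigma, criteria = as.numeric(criteria),
                 congruence_effect = congruence_effect,
                 lapse_rate = lapse_rate),
            class = "sdt_params")
}

.as_role_matrix <- function(m, what) {
  if (is.null(dim(m))) m <- matrix(m, nrow = 4L, ncol = 3L)
  stopifnot(nrow(m) == 4L, ncol(m) == 3L)
  dimnames(m) <- list(PATCH_ROLES, ECC_CLASSES)
  m
}

#' @export
print.sdt_params <- function(x, ...) {
  cat("<sdt_params>\nmu:\n"); print(round(x$mu, 3))
  cat(sprintf("criteria: %s\ncongruence_effect: %g, lapse_rate: %g\n",
              paste(round(x$criteria, 3), collapse = " "),
              x$congruence_effect, x$lapse_rate))
  invisible(x)
}

#' Named parameter presets
#'
#' * `"default"` — the directional stand-in for the empirical pattern:
#'   present >> null separation that attenuates with eccentricity, a much
#'   smaller original-vs-modified separation that widens under congruent
#'   gist, mild unequal variance, 2% lapses. Criteria sit symmetric about
#'   the midpoint between the null and pooled present means, making
#'   observers conservative on null probes (confident rejections dominate,
#'   as in real data); criteria centred on the null mean would make the
#'   null response distribution symmetric, which no attentive observer
#'   shows.
#' * `"null"` — all roles share the null distribution (chance AUC 0.5).
#' * `"perfect"` — near-infinite separations, no lapses: Type 1 AUC 1 and
#'   no incorrect trials (Type 2 undefined).
#'
#' @param name preset name.
#' @return an `sdt_params` object.
#' @export
sdt_preset <- function(name = c("default", "null", "perfect")) {
  name <- match.arg(name)
  crit <- seq(-2.25, 2.25, by = 0.75)
  switch(name,
    default = {
      mu <- rbind(null     = c(0, 0, 0),
                  present  = c(2.0, 1.3, 0.9),
                  original = c(2.0, 1.3, 0.9),
                  modified = c(1.6, 0.9, 0.5))
      sigma <- rbind(null = c(1, 1, 1), present = c(1.1, 1.1, 1.1),
                     original = c(1.1, 1.1, 1.1), modified = c(1.1, 1.1, 1.1))
      sdt_params(mu, sigma, crit + 0.9, congruence_effect = 0.5,
                 lapse_rate = 0.02)
    },
    null = sdt_params(matrix(0, 4, 3), matrix(1, 4, 3), crit),
    perfect = {
      mu <- rbind(null = c(-50, -50, -50), present = c(50, 50, 50),
                  original = c(50, 50, 50), modified = c(-50, -50, -50))
      sdt_params(mu, sigma = matrix(1, 4, 3), crit)
    }
  )
}

# Effective evidence mean for a probe, including the congruence shift on the
# original/modified separation.
.effective_mu <- function(params, role, ecc, congruence) {
  mu <- params$mu[cbind(role, ecc)]
  shift <- ifelse(congruence == "congruent", params$congruence_effect / 2, 0)
  mu + ifelse(role == "original", shift, ifelse(role == "modified", -shift, 0))
}

#' Draw D x C responses from the rating model
#'
#' Low-level sampler used by [simulate_responses()]; exposed so analyses can
#' draw arbitrary numbers of probes per condition directly.
#'
#' @param n number of probes.
#' @param mu,sigma evidence mean and SD.
#' @param criteria 7 increasing thresholds (default: preset criteria).
#' @param lapse_rate uniform-lapse probability.
#' @param rng a stream from `.substream()`, or an integer seed.
#' @return integer vector of D x C codes.
#' @export
simulate_dxc <- function(n, mu, sigma = 1, criteria = sdt_preset("null")$criteria,
                         lapse_rate = 0, rng = 1L) {
  if (!is.environment(rng)) rng <- .substream(rng)
  x <- .rng_rnorm(rng, n, mu, sigma)
  dxc <- .bin_evidence(x, criteria)
  if (lapse_rate > 0) {
    lapse <- .rng_runif(rng, n) < lapse_rate
    if (any(lapse)) {
      dxc[lapse] <- .rng_sample(rng, c(-4:-1, 1:4), sum(lapse), replace = TRUE)
    }
  }
  dxc
}

.bin_evidence <- function(x, criteria) {
  # bins: (-Inf,c1] -> -4 ... (c7,Inf) -> +4; bin index 1..8
  idx <- findInterval(x, criteria) + 1L
  c(-4L, -3L, -2L, -1L, 1L, 2L, 3L, 4L)[idx]
}

# 8-bin probability vector of the discretized rating distribution.
.bin_probs <- function(mu, sigma, criteria, lapse_rate = 0) {
  edges <- c(-Inf, criteria, Inf)
  p <- diff(stats::pnorm(edges, mean = mu, sd = sigma))
  (1 - lapse_rate) * p + lapse_rate / 8
}

#' Exact population AUC of the discretized rating model
#'
#' Closed-form ground truth for parameter-recovery tests: the Mann-Whitney
#' AUC of the 8-level rating distributions of a signal and a noise role,
#' computed from the Gaussian bin probabilities at the criteria (ties count
#' half). Discretization can only lose area relative to the continuous
#' ceiling `pnorm(d' / sqrt(2))`.
#'
#' @param params an `sdt_params`.
#' @param signal_role,noise_role patch roles.
#' @param ecc eccentricity class.
#' @param congruence `"congruent"` or `"incongruent"` (affects
#'   original/modified means only).
#' @return AUC in `[0, 1]`.
#' @export
true_rating_auc <- function(params, signal_role, noise_role,
                            ecc = "fovea", congruence = "incongruent") {
  stopifnot(inherits(params, "sdt_params"))
  p <- .bin_probs(.effective_mu(params, signal_role, ecc, congruence),
                  params$sigma[signal_role, ecc], params$criteria,
                  params$lapse_rate)
  q <- .bin_probs(.effective_mu(params, noise_role, ecc, congruence),
                  params$sigma[noise_role, ecc], params$criteria,
                  params$lapse_rate)
  # P(signal bin > noise bin) + 0.5 P(equal), bins ordered low -> high
  gt <- sum(p * (cumsum(q) - q))
  tie <- sum(p * q)
  gt + 0.5 * tie
}

#' Simulate a full response table from a design plan
#'
#' Expands every trial of an [plan_experiment()] design into its probe
#' sequence, draws one D x C response per probe from the rating model, and
#' answers any scheduled catch trials (correct unless a lapse occurs).
#' Deterministic given `seed`.
#'
#' @param plan an `mrp_design`.
#' @param params an `sdt_params`.
#' @param seed integer seed.
#' @return data.frame in the canonical response-table schema (see
#'   [read_responses()]), one row per probe plus one per catch trial.
#' @export
simulate_responses <- function(plan, params, seed = 1L) {
  stopifnot(inherits(plan, "mrp_design"), inherits(params, "sdt_params"))
  tr <- plan$trials
  n_tr <- nrow(tr)
  probe_rows <- vector("list", n_tr)
  for (i in seq_len(n_tr)) {
    trial_seed <- (seed * 1000003 + i) %% .Machine$integer.max
    kind <- tr$critical_kind[i]
    probes <- plan_trial(plan$experiment, tr$pair_id[i], tr$congruence[i],
                         tr$critical_location[i], rng_seed = trial_seed,
                         critical_kind = if (is.na(kind)) "original" else kind)
    ecc <- eccentricity_class(probes$location)
    mu <- .effective_mu(params, probes$patch_type, ecc, tr$congruence[i])
    sg <- params$sigma[cbind(probes$patch_type, ecc)]
    rng <- .substream((seed * 2000003 + i) %% .Machine$integer.max)
    x <- .rng_rnorm(rng, nrow(probes), mu, sg)
    dxc <- .bin_evidence(x, params$criteria)
    if (params$lapse_rate > 0) {
      lapse <- .rng_runif(rng, nrow(probes)) < params$lapse_rate
      if (any(lapse)) {
        dxc[lapse] <- .rng_sample(rng, c(-4:-1, 1:4), sum(lapse), replace = TRUE)
      }
    }
    probe_rows[[i]] <- data.frame(
      participant_id = tr$participant[i],
      experiment = plan$experiment,
      trial_index = tr$trial_index[i],
      image_pair_id = tr$pair_id[i],
      initial_congruence = tr$congruence[i],
      probe_index = probes$probe_index,
      patch_type = probes$patch_type,
      location = probes$location,
      eccentricity_class = ecc,
      decision = ifelse(dxc > 0, "yes", "no"),
      confidence = abs(dxc),
      dxc = dxc,
      is_catch = FALSE,
      catch_correct = NA,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, probe_rows)

  if (!is.null(plan$catch_schedule)) {
    cs <- plan$catch_schedule
    rng <- .substream((seed * 3000017) %% .Machine$integer.max)
    lapse <- .rng_runif(rng, nrow(cs)) < params$lapse_rate
    resp_dec <- cs$required_decision
    resp_conf <- cs$required_confidence
    if (any(lapse)) {
      rand_dxc <- .rng_sample(rng, c(-4:-1, 1:4), sum(lapse), replace = TRUE)
      resp_dec[lapse] <- ifelse(rand_dxc > 0, "yes", "no")
      resp_conf[lapse] <- abs(rand_dxc)
    }
    catch_rows <- data.frame(
      participant_id = cs$participant,
      experiment = plan$experiment,
      trial_index = cs$position,
      image_pair_id = NA_character_,
      initial_congruence = NA_character_,
      probe_index = 1L,
      patch_type = NA_character_,
      location = NA_integer_,
      eccentricity_class = NA_character_,
      decision = resp_dec,
      confidence = resp_conf,
      dxc = encode_dxc(resp_dec, resp_conf),
      is_catch = TRUE,
      catch_correct = resp_dec == cs$required_decision &
        resp_conf == cs$required_confidence,
      stringsAsFactors = FALSE
    )
    out <- rbind(out, catch_rows)
  }
  rownames(out) <- NULL
  out
}

#' Agent profile for catch-trial simulation
#'
#' @param kind `"attentive"` (responds from the rating model, failing a
#'   catch only through lapses) or `"random"` (uniform over the 8 options,
#'   expected catch accuracy 1/8).
#' @param params `sdt_params` for attentive agents.
#' @return object of class `agent_profile`.
#' @export
agent_profile <- function(kind = c("attentive", "random"),
                          params = sdt_preset("default")) {
  kind <- match.arg(kind)
  structure(list(kind = kind, params = params), class = "agent_profile")
}

#' Simulate catch-trial accuracy for one agent
#'
#' @param profile an [agent_profile()].
#' @param n_catch number of catch trials.
#' @param seed integer seed.
#' @return fraction of catch trials answered as required.
#' @export
simulate_catch <- function(profile, n_catch, seed = 1L) {
  stopifnot(inherits(profile, "agent_profile"), n_catch >= 1)
  rng <- if (is.environment(seed)) seed else .substream(seed)
  if (profile$kind == "random") {
    mean(.rng_sample(rng, 1:8, n_catch, replace = TRUE) == 1L)
  } else {
    lam <- profile$params$lapse_rate
    lapse <- .rng_runif(rng, n_catch) < lam
    # a lapse picks uniformly among the 8 options; 1/8 chance it is still right
    correct <- !lapse | (.rng_runif(rng, n_catch) < 1 / 8)
    mean(correct)
  }
}
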