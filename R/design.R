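# Experiment layout: a briefly flashed natural scene is probed with a
# sequence of image patches cut from a 3x3 grid. Locations are numbered
# row-major, 1 (top-left) .. 9 (bottom-right), 5 = centre/fixation.

ODD_LOCATIONS  <- c(1L, 3L, 5L, 7L, 9L)
EVEN_LOCATIONS <- c(2L, 4L, 6L, 8L)

#' Split a square image into the 3x3 probe grid
#'
#' @param image numeric array, H x W (grayscale) or H x W x C. Non-divisible
#'   dimensions are truncated (trailing rows/columns dropped) so the nine
#'   patches are exactly equal-sized.
#' @return named list `p1` .. `p9` of sub-arrays, row-major, 5 = centre.
#' @export
split_grid <- function(image) {
  d <- dim(image)
  if (is.null(d) || length(d) < 2L) stop("`image` must be a matrix or array", call. = FALSE)
  h <- (d[1] %/% 3L) * 3L
  w <- (d[2] %/% 3L) * 3L
  if (h < 3L || w < 3L) stop("image too small to split into a 3x3 grid", call. = FALSE)
  ph <- h %/% 3L; pw <- w %/% 3L
  out <- vector("list", 9L)
  for (loc in 1:9) {
    row <- (loc - 1L) %/% 3L
    col <- (loc - 1L) %% 3L
    ri <- (row * ph + 1L):((row + 1L) * ph)
    ci <- (col * pw + 1L):((col + 1L) * pw)
    out[[loc]] <- if (length(d) == 2L) image[ri, ci, drop = FALSE]
                  else image[ri, ci, , drop = FALSE]
  }
  names(out) <- paste0("p", 1:9)
  out
}

#' Visual angle subtended by an on-screen extent
#'
#' @param extent_cm physical extent on the display, cm.
#' @param distance_cm viewing distance, cm (> 0).
#' @return angle in degrees: `2 * atan(extent / (2 * distance))`.
#' @examples
#' visual_angle(20.5, 60)  # ~19.4 dva
#' @export
visual_angle <- function(extent_cm, distance_cm) {
  if (any(distance_cm <= 0)) stop("`distance_cm` must be > 0", call. = FALSE)
  if (any(extent_cm < 0)) stop("`extent_cm` must be >= 0", call. = FALSE)
  2 * atan(extent_cm / (2 * distance_cm)) * 180 / pi
}

#' Patch eccentricity in degrees of visual angle
#'
#' Centre-to-centre angular distance of a grid location from fixation
#' (location 5). Offsets are computed on the display plane — the image's
#' half-width in distance units is `tan(width/2)`, a patch width is a third
#' of that doubled — and converted back to an angle with `atan`. For a
#' 19.4-dva image this yields 0, 6.5 and 9.2 dva for the centre, edge and
#' corner patches (the small-angle linear approximation would give 9.1 for
#' the corners).
#'
#' @param location integer 1..9.
#' @param image_width_dva full image width in degrees of visual angle.
#' @return eccentricity in degrees (not rounded).
#' @export
eccentricity_dva <- function(location, image_width_dva) {
  .check_location(location)
  if (any(image_width_dva <= 0)) stop("`image_width_dva` must be > 0", call. = FALSE)
  half_width <- tan(image_width_dva / 2 * pi / 180) # screen units, distance = 1
  patch_w <- 2 * half_width / 3
  mult <- c(sqrt(2), 1, sqrt(2), 1, 0, 1, sqrt(2), 1, sqrt(2))[location]
  atan(mult * patch_w) * 180 / pi
}

#' Eccentricity class of a grid location
#'
#' Fovea = location 5, parafovea = edge locations (2, 4, 6, 8), periphery =
#' corner locations (1, 3, 7, 9).
#'
#' @param location integer vector, 1..9.
#' @return character vector in \{`fovea`, `parafovea`, `periphery`\}.
#' @export
eccentricity_class <- function(location) {
  .check_location(location)
  c("periphery", "parafovea", "periphery",
    "parafovea", "fovea", "parafovea",
    "periphery", "parafovea", "periphery")[location]
}

.check_location <- function(location) {
  if (anyNA(location) || any(location < 1 | location > 9) ||
      any(location != round(location))) {
    stop("`location` must be an integer in 1..9", call. = FALSE)
  }
  invisible(location)
}

#' Plan one experimental trial
#'
#' Experiment 1: the probe sequence holds 1 original + 1 modified patch at
#' the critical location, present patches at the remaining locations of the
#' critical location's parity set (odd \{1,3,5,7,9\} or even \{2,4,6,8\}, so
#' probes are never spatially contiguous), and 15 null patches at uniformly
#' random locations; 21 probes for the odd set, 20 for the even. Experiment
#' 2: 2 present + 3 null + exactly one of original/modified (6 probes).
#' Probe order is fully randomized per trial.
#'
#' @param experiment `"exp1"` or `"exp2"`.
#' @param image_pair_id identifier of the image pair.
#' @param congruence `"congruent"` or `"incongruent"` (the initial image).
#' @param critical_location grid location (1..9) of the critical object.
#' @param rng_seed integer seed; the same seed reproduces the same plan.
#' @param critical_kind for `exp2`, `"original"` or `"modified"` — which of
#'   the two critical probes this trial shows. Ignored for `exp1`.
#' @return data.frame, one row per probe: `probe_index`, `patch_type`,
#'   `location`, `patch_id`, plus attributes `location_set` and metadata.
#' @export
plan_trial <- function(experiment = c("exp1", "exp2"), image_pair_id,
                       congruence = c("congruent", "incongruent"),
                       critical_location, rng_seed,
                       critical_kind = c("original", "modified")) {
  experiment <- match.arg(experiment)
  congruence <- match.arg(congruence)
  critical_kind <- match.arg(critical_kind)
  .check_location(critical_location)
  rng <- .substream(rng_seed)

  if (experiment == "exp1") {
    loc_set <- if (critical_location %% 2L == 1L) ODD_LOCATIONS else EVEN_LOCATIONS
    present_locs <- setdiff(loc_set, critical_location)
    patch_type <- c("original", "modified", rep("present", length(present_locs)),
                    rep("null", 15L))
    location <- c(critical_location, critical_location, present_locs,
                  .rng_sample(rng, 1:9, 15L, replace = TRUE))
    set_name <- if (critical_location %% 2L == 1L) "odd" else "even"
  } else {
    loc_set <- if (critical_location %% 2L == 1L) ODD_LOCATIONS else EVEN_LOCATIONS
    present_locs <- .rng_sample(rng, setdiff(loc_set, critical_location), 2L)
    patch_type <- c(critical_kind, rep("present", 2L), rep("null", 3L))
    location <- c(critical_location, present_locs,
                  .rng_sample(rng, 1:9, 3L, replace = TRUE))
    set_name <- if (critical_location %% 2L == 1L) "odd" else "even"
  }
  ord <- .rng_sample(rng, seq_along(patch_type), length(patch_type))
  plan <- data.frame(
    probe_index = seq_along(patch_type),
    patch_type = patch_type[ord],
    location = location[ord],
    patch_id = paste0(image_pair_id, ":", patch_type[ord], "@", location[ord]),
    stringsAsFactors = FALSE
  )
  attr(plan, "location_set") <- set_name
  attr(plan, "image_pair_id") <- image_pair_id
  attr(plan, "congruence") <- congruence
  attr(plan, "critical_location") <- critical_location
  plan
}

# Seeded sub-generator: an environment holding a private .Random.seed so
# plan/simulation code never disturbs (or depends on) the caller's RNG.
.substream <- function(seed) {
  env <- new.env(parent = emptyenv())
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed %% .Machine$integer.max))
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv())
  else assign(".Random.seed", old, envir = globalenv())
  env
}

.with_stream <- function(rng, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  assign(".Random.seed", rng$state, envir = globalenv())
  on.exit({
    rng$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  expr
}

.rng_sample <- function(rng, x, size, replace = FALSE) {
  .with_stream(rng, sample(x, size, replace = replace))
}

.rng_runif <- function(rng, n) .with_stream(rng, stats::runif(n))

.rng_rnorm <- function(rng, n, mean = 0, sd = 1) {
  .with_stream(rng, stats::rnorm(n, mean, sd))
}

#' Allocate null patches disjointly across participants
#'
#' Each initial image needs `nulls_per_trial` unrelated ("null") patches per
#' participant, and no null patch may repeat across participants for the
#' same image (e.g. 15 participants x 15 nulls = 225 distinct patches).
#'
#' @param n_participants number of participants.
#' @param nulls_per_trial null patches each participant sees for this image.
#' @param pool character/integer vector of available null patch ids.
#' @param image_id identifier (recorded in the output).
#' @param rng_seed integer seed.
#' @return data.frame `participant`, `image_id`, `patch_id`; assignments are
#'   pairwise disjoint across participants.
#' @export
allocate_nulls <- function(n_participants, nulls_per_trial, pool, image_id,
                           rng_seed) {
  need <- n_participants * nulls_per_trial
  if (length(pool) < need) {
    stop(sprintf("null-patch pool too small: need %d, have %d (short by %d)",
                 need, length(pool), need - length(pool)), call. = FALSE)
  }
  rng <- .substream(rng_seed)
  chosen <- .rng_sample(rng, pool, need)
  data.frame(
    participant = rep(seq_len(n_participants), each = nulls_per_trial),
    image_id = image_id,
    patch_id = chosen,
    stringsAsFactors = FALSE
  )
}

#' Experiment 2 cohort arithmetic and batching
#'
#' The image-pair set is divided into consecutive batches of
#' `pairs_per_participant` pairs; each participant sees one full batch (one
#' trial per pair), and each pair is seen by `participants_per_pair`
#' participants. Defaults reproduce the registered design: 136 pairs / 34
#' per participant x 60 participants per pair = 240 participants and
#' 240 x 34 = 8160 experimental trials.
#'
#' @param n_pairs,pairs_per_participant,participants_per_pair integers.
#' @return list with `n_participants`, `n_batches`, `n_trials`, and
#'   `batches` (list of pair-index vectors).
#' @export
plan_experiment2 <- function(n_pairs = 136L, pairs_per_participant = 34L,
                             participants_per_pair = 60L) {
  if (n_pairs %% pairs_per_participant != 0L) {
    stop("`n_pairs` must be divisible by `pairs_per_participant` for equal batches",
         call. = FALSE)
  }
  n_batches <- n_pairs %/% pairs_per_participant
  n_participants <- participants_per_pair * n_pairs / pairs_per_participant
  batches <- lapply(seq_len(n_batches), function(b) {
    ((b - 1L) * pairs_per_participant + 1L):(b * pairs_per_participant)
  })
  list(n_participants = as.integer(n_participants),
       n_batches = n_batches,
       n_trials = as.integer(n_participants * pairs_per_participant),
       batches = batches)
}

#' Catch-trial accuracy cutoff
#'
#' Attention-check exclusion threshold: the accuracy a purely random
#' responder (uniform over `n_options` response options) exceeds with
#' probability at most `1 - quantile`. Computed as the exact binomial
#' inverse CDF — the smallest k with `pbinom(k, n_catch, 1/n_options) >=
#' quantile` — divided by `n_catch`. A seeded Monte-Carlo estimate is
#' available as a cross-check. With 13 catch trials, 8 options and the 99%
#' quantile the cutoff is 5/13 = 0.38 (two decimals).
#'
#' @param n_catch number of catch trials.
#' @param n_options number of response options (8 = yes/no x confidence 1-4).
#' @param quantile quantile of the random-responder accuracy distribution.
#' @param method `"exact"` (default) or `"montecarlo"`.
#' @param n_sim,seed Monte-Carlo replicates and seed (montecarlo only).
#' @return list: `cutoff` (rounded to two decimals), `cutoff_raw`, `k`.
#' @export
catch_cutoff <- function(n_catch, n_options, quantile = 0.99,
                         method = c("exact", "montecarlo"),
                         n_sim = 1e5, seed = 1L) {
  method <- match.arg(method)
  stopifnot(n_catch >= 1, n_options >= 1)
  if (quantile <= 0 || quantile >= 1) {
    stop("`quantile` must be strictly between 0 and 1", call. = FALSE)
  }
  p <- 1 / n_options
  k <- if (method == "exact") {
    stats::qbinom(quantile, n_catch, p)
  } else {
    rng <- .substream(seed)
    draws <- .with_stream(rng, stats::rbinom(n_sim, n_catch, p))
    stats::quantile(draws, probs = quantile, names = FALSE, type = 1)
  }
  list(cutoff = round(k / n_catch, 2), cutoff_raw = k / n_catch, k = as.integer(k))
}

#' Build a full design plan
#'
#' Assembles per-participant trial schedules for either experiment.
#' Experiment 1: 80 trials per participant (40 congruent + 40 incongruent),
#' drawn without replacement from the image-pair table so no initial image
#' repeats within a participant. Experiment 2: 34 trials (17 + 17) from the
#' participant's batch, original-vs-modified assigned randomly per trial,
#' plus 12 experimental catch trials and 1 practice catch trial.
#'
#' @param experiment `"exp1"` or `"exp2"`.
#' @param image_pairs data.frame with columns `pair_id` and
#'   `critical_location`; needs >= 80 rows for exp1, and a multiple of
#'   `pairs_per_participant` rows for exp2.
#' @param n_participants cohort size.
#' @param seed master seed; each participant gets a derived substream.
#' @return object of class `mrp_design`: list with `experiment`,
#'   `participants`, `trials` (data.frame, one row per trial: participant,
#'   trial_index, pair_id, congruence, critical_location, critical_kind),
#'   and `catch_schedule`.
#' @export
plan_experiment <- function(experiment = c("exp1", "exp2"), image_pairs,
                            n_participants, seed = 1L) {
  experiment <- match.arg(experiment)
  stopifnot(is.data.frame(image_pairs),
            all(c("pair_id", "critical_location") %in% names(image_pairs)))
  .check_location(image_pairs$critical_location)

  per_part <- if (experiment == "exp1") 80L else 34L
  half <- per_part %/% 2L
  trials <- vector("list", n_participants)

  if (experiment == "exp2") {
    layout <- plan_experiment2(n_pairs = nrow(image_pairs))
    batch_of <- function(i) layout$batches[[((i - 1L) %% layout$n_batches) + 1L]]
  } else if (nrow(image_pairs) < per_part) {
    stop(sprintf("experiment 1 needs >= %d image pairs, have %d",
                 per_part, nrow(image_pairs)), call. = FALSE)
  }

  for (i in seq_len(n_participants)) {
    rng <- .substream(seed * 10000L + i)
    idx <- if (experiment == "exp1") {
      .rng_sample(rng, seq_len(nrow(image_pairs)), per_part)
    } else {
      .rng_sample(rng, batch_of(i), per_part)
    }
    congruence <- .rng_sample(rng, rep(c("congruent", "incongruent"), half), per_part)
    kind <- if (experiment == "exp2") {
      .rng_sample(rng, c("original", "modified"), per_part, replace = TRUE)
    } else rep(NA_character_, per_part)
    trials[[i]] <- data.frame(
      participant = sprintf("P%03d", i),
      trial_index = seq_len(per_part),
      pair_id = image_pairs$pair_id[idx],
      congruence = congruence,
      critical_location = image_pairs$critical_location[idx],
      critical_kind = kind,
      stringsAsFactors = FALSE
    )
  }
  trials <- do.call(rbind, trials)

  catch <- NULL
  if (experiment == "exp2") {
    catch <- do.call(rbind, lapply(seq_len(n_participants), function(i) {
      rng <- .substream(seed * 10000L + i + 500000L)
      pos <- sort(.rng_sample(rng, seq_len(per_part + 12L), 12L))
      req_dec <- .rng_sample(rng, c("yes", "no"), 13L, replace = TRUE)
      req_conf <- .rng_sample(rng, 1:4, 13L, replace = TRUE)
      data.frame(
        participant = sprintf("P%03d", i),
        catch_index = seq_len(13L),
        phase = c("practice", rep("experimental", 12L)),
        position = c(0L, pos),
        required_decision = req_dec,
        required_confidence = req_conf,
        stringsAsFactors = FALSE
      )
    }))
  }

  structure(
    list(experiment = experiment,
         participants = sprintf("P%03d", seq_len(n_participants)),
         trials = trials,
         catch_schedule = catch,
         seed = seed),
    class = "mrp_design"
  )
}

#' @export
print.mrp_design <- function(x, ...) {
  cat(sprintf("<mrp_design: %s, %d participants, %d trials%s>\n",
              x$experiment, length(x$participants), nrow(x$trials),
              if (is.null(x$catch_schedule)) ""
              else sprintf(", %d catch trials", nrow(x$catch_schedule))))
  invisible(x)
}
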