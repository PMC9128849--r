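# Pipeline statistics computed from a canonical response table: AUC
# summaries per participant and eccentricity stratum, per-D x C proportion
# curves with bin-wise comparisons, per-image-pair delta tD x C with the
# four-way significance classification, and likelihood-ratio plumbing for
# externally fitted mixed models.

#' Per-image-pair difference of mean transformed D x C
#'
#' `mean(tDxC(original)) - mean(tDxC(modified))`; positive values mean the
#' original patch was endorsed more strongly than the modified one.
#' Bounded by +/-7 and antisymmetric under swapping the two lists.
#'
#' @param original_tdxc,modified_tdxc numeric vectors of tD x C values.
#' @return difference of means.
#' @export
delta_tdxc <- function(original_tdxc, modified_tdxc) {
  if (length(original_tdxc) == 0L || length(modified_tdxc) == 0L) {
    stop("insufficient data: both tD x C sets must be non-empty", call. = FALSE)
  }
  mean(original_tdxc) - mean(modified_tdxc)
}

#' Classify one image pair by its congruence-specific effects
#'
#' Runs two two-sample t-tests on tD x C (original vs modified), one within
#' each congruence of the initial image, and colours the pair as in the
#' standard four-way scheme: `grey` = neither significant, `blue` = only
#' congruent, `red` = only incongruent, `black` = both. The interaction
#' between patch type and congruence is assessed by comparing ordinary
#' least-squares fits of `tdxc ~ patch_type * congruence` against the
#' additive model (an F-test on the interaction term; equivalent to the
#' Type II/III sum of squares for this term).
#'
#' @param responses data.frame with columns `patch_type` (must include
#'   `original`/`modified`), `initial_congruence`, and `dxc`.
#' @param alpha significance level for both t-tests and the interaction.
#' @param var_equal classical Student t-test (default) or Welch.
#' @return one-row data.frame: `delta_tdxc_congruent`,
#'   `delta_tdxc_incongruent`, `p_congruent`, `p_incongruent`, `category`
#'   (`grey`/`blue`/`red`/`black`, or `NA` if any cell is untestable),
#'   `interaction_p`, `interaction_flag`.
#' @export
classify_image_pair <- function(responses, alpha = 0.05, var_equal = TRUE) {
  d <- responses[responses$patch_type %in% c("original", "modified"), ]
  d$tdxc <- transform_tdxc(d$dxc)

  cell <- function(cong, type) d$tdxc[d$initial_congruence == cong & d$patch_type == type]
  test_one <- function(cong) {
    a <- cell(cong, "original"); b <- cell(cong, "modified")
    if (length(a) < 2L || length(b) < 2L) {
      return(list(delta = if (length(a) && length(b)) delta_tdxc(a, b) else NA_real_,
                  p = NA_real_))
    }
    p <- tryCatch(stats::t.test(a, b, var.equal = var_equal)$p.value,
                  error = function(e) NA_real_) # zero-variance cells: untestable
    list(delta = delta_tdxc(a, b), p = p)
  }
  con <- test_one("congruent")
  inc <- test_one("incongruent")

  category <- if (is.na(con$p) || is.na(inc$p)) NA_character_ else {
    sc <- con$p < alpha; si <- inc$p < alpha
    if (sc && si) "black" else if (sc) "blue" else if (si) "red" else "grey"
  }

  int_p <- NA_real_
  counts <- table(d$initial_congruence, d$patch_type)
  if (all(dim(counts) == c(2L, 2L)) && all(counts >= 2L)) {
    full <- stats::lm(tdxc ~ patch_type * initial_congruence, data = d)
    red <- stats::lm(tdxc ~ patch_type + initial_congruence, data = d)
    int_p <- stats::anova(red, full)[2, "Pr(>F)"]
  }

  data.frame(
    delta_tdxc_congruent = con$delta,
    delta_tdxc_incongruent = inc$delta,
    p_congruent = con$p,
    p_incongruent = inc$p,
    category = category,
    interaction_p = int_p,
    interaction_flag = !is.na(int_p) && int_p < alpha,
    stringsAsFactors = FALSE
  )
}

#' Classify every image pair in a response table
#'
#' @param responses canonical response table.
#' @inheritParams classify_image_pair
#' @return data.frame, one row per `image_pair_id`.
#' @export
classify_image_pairs <- function(responses, alpha = 0.05, var_equal = TRUE) {
  resp <- responses[!responses$is_catch, ]
  ids <- unique(resp$image_pair_id)
  out <- do.call(rbind, lapply(ids, function(id) {
    classify_image_pair(resp[resp$image_pair_id == id, ], alpha, var_equal)
  }))
  cbind(data.frame(image_pair_id = ids, stringsAsFactors = FALSE), out)
}

#' Per-D x C response proportion curves with bin-wise comparisons
#'
#' For each participant, the proportion of responses in each of the 8
#' D x C bins within each of two probe groups (e.g. present+original vs
#' null, or original vs modified), then the across-participant mean and
#' SEM per bin, and a per-bin two-sample t-test between the groups,
#' flagged at the `p < 0.003` (*) and `p < 0.0001` (**) display
#' thresholds. Participants contributing no responses to a group are
#' excluded from that group's curve with a warning.
#'
#' @param responses canonical response table (non-catch rows used).
#' @param groups named list of two character vectors of patch types, e.g.
#'   `list(signal = c("present", "original"), noise = "null")`.
#' @param stratum optional eccentricity class to restrict to.
#' @param var_equal Student (default) or Welch t-tests.
#' @param thresholds display significance thresholds.
#' @return list with `curves` (group x dxc mean/SEM/n) and `tests`
#'   (per-bin p-values and flags).
#' @export
proportion_curves <- function(responses,
                              groups = list(signal = c("present", "original"),
                                            noise = "null"),
                              stratum = NULL, var_equal = TRUE,
                              thresholds = c(star = 0.003, double_star = 1e-4)) {
  stopifnot(length(groups) == 2L, !is.null(names(groups)))
  resp <- responses[!responses$is_catch, ]
  if (!is.null(stratum)) resp <- resp[resp$eccentricity_class == stratum, ]
  levels_dxc <- c(-4, -3, -2, -1, 1, 2, 3, 4)

  per_part <- function(types, label) {
    r <- resp[resp$patch_type %in% types, ]
    parts <- unique(resp$participant_id)
    rows <- lapply(parts, function(p) {
      v <- r$dxc[r$participant_id == p]
      if (length(v) == 0L) {
        warning(sprintf("participant %s has no '%s' responses in this stratum; excluded",
                        p, label), call. = FALSE)
        return(NULL)
      }
      prop <- vapply(levels_dxc, function(b) mean(v == b), numeric(1))
      data.frame(participant_id = p, group = label, dxc = levels_dxc,
                 proportion = prop, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }
  pp <- rbind(per_part(groups[[1]], names(groups)[1]),
              per_part(groups[[2]], names(groups)[2]))

  agg <- do.call(rbind, lapply(split(pp, list(pp$group, pp$dxc)), function(g) {
    data.frame(group = g$group[1], dxc = g$dxc[1],
               mean = mean(g$proportion),
               sem = stats::sd(g$proportion) / sqrt(nrow(g)),
               n = nrow(g), stringsAsFactors = FALSE)
  }))
  agg <- agg[order(agg$group, agg$dxc), ]
  rownames(agg) <- NULL

  tests <- do.call(rbind, lapply(levels_dxc, function(b) {
    a <- pp$proportion[pp$group == names(groups)[1] & pp$dxc == b]
    c2 <- pp$proportion[pp$group == names(groups)[2] & pp$dxc == b]
    p <- if (length(a) >= 2L && length(c2) >= 2L &&
             (stats::sd(a) > 0 || stats::sd(c2) > 0)) {
      stats::t.test(a, c2, var.equal = var_equal)$p.value
    } else NA_real_
    data.frame(dxc = b, p_value = p,
               star = !is.na(p) && p < thresholds[["star"]],
               double_star = !is.na(p) && p < thresholds[["double_star"]],
               stringsAsFactors = FALSE)
  }))
  list(curves = agg, per_participant = pp, tests = tests)
}

#' Per-participant Type 1 and Type 2 AUC summary
#'
#' Computes, for each participant (optionally within each eccentricity
#' stratum), the criterion-sweep Type 1 AUC for the requested task and the
#' Type 2 AUC over correctness-conditioned confidence, then group mean,
#' SEM, and a one-sample t-test of the AUCs against chance (0.5).
#' Participants with an empty signal or noise set in a stratum get `NA`
#' for Type 1; participants with no correct or no incorrect trials get
#' `NA` for Type 2 (never 1.0).
#'
#' @param responses canonical response table.
#' @param task `"present_vs_null"` (signal = present+original, noise =
#'   null) or `"original_vs_modified"` (signal = original, noise =
#'   modified).
#' @param by_stratum also split by eccentricity class.
#' @param congruence optional: restrict to one congruence of the initial
#'   image (by default congruent and incongruent trials are pooled).
#' @return list with `auc` (participant-level table) and `summary`
#'   (per-stratum group mean, SEM, t and p vs 0.5 for both AUC types).
#' @export
auc_summary <- function(responses,
                        task = c("present_vs_null", "original_vs_modified"),
                        by_stratum = TRUE, congruence = NULL) {
  task <- match.arg(task)
  resp <- responses[!responses$is_catch, ]
  if (!is.null(congruence)) resp <- resp[resp$initial_congruence == congruence, ]
  signal_types <- if (task == "present_vs_null") c("present", "original") else "original"
  noise_types <- if (task == "present_vs_null") "null" else "modified"
  resp <- resp[resp$patch_type %in% c(signal_types, noise_types), ]

  strata <- if (by_stratum) c("all", ECC_CLASSES) else "all"
  rows <- list()
  for (p in unique(resp$participant_id)) {
    for (s in strata) {
      r <- resp[resp$participant_id == p, ]
      if (s != "all") r <- r[r$eccentricity_class == s, ]
      sig <- r$dxc[r$patch_type %in% signal_types]
      noi <- r$dxc[r$patch_type %in% noise_types]
      t1 <- if (length(sig) && length(noi)) type1_roc(sig, noi)$auc else NA_real_
      correct <- classify_correct(r$decision, r$patch_type, task)
      conf_c <- r$confidence[which(correct)]
      conf_i <- r$confidence[which(!correct)]
      t2 <- if (length(conf_c) && length(conf_i)) {
        type2_roc(conf_c, conf_i)$auc
      } else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        participant_id = p, stratum = s, task = task,
        n_signal = length(sig), n_noise = length(noi),
        type1_auc = t1, type2_auc = t2, stringsAsFactors = FALSE)
    }
  }
  auc <- do.call(rbind, rows)

  summ <- do.call(rbind, lapply(split(auc, auc$stratum), function(g) {
    one <- function(v) {
      v <- v[!is.na(v)]
      if (length(v) < 2L || stats::sd(v) == 0) {
        c(mean = mean(v), sem = NA, t = NA, p = NA, n = length(v))
      } else {
        tt <- stats::t.test(v, mu = 0.5)
        c(mean = mean(v), sem = stats::sd(v) / sqrt(length(v)),
          t = unname(tt$statistic), p = tt$p.value, n = length(v))
      }
    }
    s1 <- one(g$type1_auc); s2 <- one(g$type2_auc)
    data.frame(stratum = g$stratum[1],
               type1_mean = s1["mean"], type1_sem = s1["sem"],
               type1_t = s1["t"], type1_p = s1["p"], type1_n = s1["n"],
               type2_mean = s2["mean"], type2_sem = s2["sem"],
               type2_t = s2["t"], type2_p = s2["p"], type2_n = s2["n"],
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  list(auc = auc, summary = summ)
}

#' Likelihood-ratio chi-squared test
#'
#' Plumbing for externally fitted nested models: `chi2 = 2 * (logLik_full -
#' logLik_reduced)`, p-value from the chi-squared distribution with
#' `df_diff` degrees of freedom.
#'
#' @param loglik_full,loglik_reduced log-likelihoods of the nested fits.
#' @param df_diff difference in number of parameters (>= 1).
#' @return list with `chi2` and `p`.
#' @export
lrt_chi2 <- function(loglik_full, loglik_reduced, df_diff) {
  if (df_diff < 1) stop("`df_diff` must be >= 1", call. = FALSE)
  chi2 <- 2 * (loglik_full - loglik_reduced)
  if (chi2 < 0) {
    stop("negative chi-squared: full model has lower likelihood (models misordered?)",
         call. = FALSE)
  }
  list(chi2 = chi2, p = stats::pchisq(chi2, df = df_diff, lower.tail = FALSE))
}

#' Tidy export for external mixed-model fitting
#'
#' Emits the modelling table consumed by external LME software: one row per
#' image pair x congruence with the mean tD x C difference, plus optional
#' image covariates (log object size, Weibull scale) joined by pair id.
#'
#' @param responses canonical response table.
#' @param image_stats optional data.frame from [image_pair_stats()].
#' @return data.frame: `image_pair_id`, `congruence`, `delta_tdxc`, `n`,
#'   plus any joined covariates.
#' @export
modelling_export <- function(responses, image_stats = NULL) {
  resp <- responses[!responses$is_catch &
                      responses$patch_type %in% c("original", "modified"), ]
  resp$tdxc <- transform_tdxc(resp$dxc)
  keys <- unique(resp[, c("image_pair_id", "initial_congruence")])
  out <- do.call(rbind, lapply(seq_len(nrow(keys)), function(i) {
    d <- resp[resp$image_pair_id == keys$image_pair_id[i] &
                resp$initial_congruence == keys$initial_congruence[i], ]
    a <- d$tdxc[d$patch_type == "original"]
    b <- d$tdxc[d$patch_type == "modified"]
    data.frame(image_pair_id = keys$image_pair_id[i],
               congruence = keys$initial_congruence[i],
               delta_tdxc = if (length(a) && length(b)) delta_tdxc(a, b) else NA_real_,
               n = nrow(d), stringsAsFactors = FALSE)
  }))
  if (!is.null(image_stats)) {
    out <- merge(out, image_stats, by.x = "image_pair_id", by.y = "pair_id",
                 all.x = TRUE, sort = FALSE)
  }
  out
}
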