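# Canonical response-table schema and I/O. The table is plain CSV with a
# versioned header comment; one row per probe judgement (or catch trial).

RESPONSE_COLUMNS <- c(
  "participant_id", "experiment", "trial_index", "image_pair_id",
  "initial_congruence", "probe_index", "patch_type", "location",
  "eccentricity_class", "decision", "confidence", "dxc",
  "is_catch", "catch_correct"
)

SCHEMA_HEADER <- "# mrpscore response table v1"

#' Write a canonical response table
#'
#' Plain CSV prefixed with a one-line versioned schema comment.
#'
#' @param responses data.frame in the canonical schema.
#' @param path output file.
#' @export
write_responses <- function(responses, path) {
  validate_responses(responses)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(SCHEMA_HEADER, con)
  utils::write.csv(responses[, RESPONSE_COLUMNS], con, row.names = FALSE)
  invisible(path)
}

#' Read and validate a canonical response table
#'
#' Reads the CSV, coerces column types, and validates every invariant of
#' the schema: D x C consistent with decision and confidence, location
#' consistent with eccentricity class, catch rows carrying `catch_correct`
#' and no patch fields. Violations are reported with row numbers.
#'
#' @param path input CSV (canonical dialect).
#' @return validated data.frame.
#' @export
read_responses <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  missing_cols <- setdiff(RESPONSE_COLUMNS, names(d))
  if (length(missing_cols)) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  d$is_catch <- as.logical(d$is_catch)
  d$catch_correct <- as.logical(d$catch_correct)
  validate_responses(d)
  d
}

#' Validate a response table against the canonical schema
#'
#' @param d data.frame to check.
#' @return invisibly `d`; raises an error listing offending row numbers.
#' @export
validate_responses <- function(d) {
  bad <- function(cond) which(!is.na(cond) & cond)
  probs <- list()
  note <- function(rows, msg) {
    if (length(rows)) probs[[length(probs) + 1L]] <<-
      sprintf("%s (rows %s)", msg,
              paste(utils::head(rows, 5), collapse = ", "))
  }
  pr <- !d$is_catch
  note(bad(pr & !(d$decision %in% c("yes", "no"))), "invalid decision")
  note(bad(pr & !(d$confidence %in% 1:4)), "confidence outside 1..4")
  note(bad(pr & d$dxc != ifelse(d$decision == "yes", d$confidence, -d$confidence)),
       "dxc inconsistent with decision x confidence")
  note(bad(pr & !(d$patch_type %in% PATCH_ROLES)), "invalid patch_type")
  note(bad(pr & !(d$location %in% 1:9)), "location outside 1..9")
  ok_loc <- pr & d$location %in% 1:9
  note(bad(ok_loc & d$eccentricity_class !=
             eccentricity_class(ifelse(ok_loc, d$location, 1L))),
       "eccentricity_class inconsistent with location")
  note(bad(d$is_catch & is.na(d$catch_correct)), "catch row missing catch_correct")
  note(bad(d$is_catch & !is.na(d$patch_type)), "catch row carries patch fields")
  if (length(probs)) {
    stop("response table validation failed:\n  ",
         paste(unlist(probs), collapse = "\n  "), call. = FALSE)
  }
  invisible(d)
}

#' Exclude participants by catch-trial accuracy
#'
#' Removes every participant whose catch accuracy is not strictly greater
#' than `cutoff` (accuracy exactly at the cutoff is excluded). Participants
#' with no catch rows are retained with a warning.
#'
#' @param responses canonical response table.
#' @param cutoff accuracy threshold (default 0.38, the 99% quantile of
#'   random responding over 13 catch trials with 8 options).
#' @return list: `responses` (filtered), `report` (per-participant catch
#'   accuracy and exclusion decision).
#' @export
apply_exclusions <- function(responses, cutoff = 0.38) {
  parts <- unique(responses$participant_id)
  report <- do.call(rbind, lapply(parts, function(p) {
    cc <- responses$catch_correct[responses$participant_id == p & responses$is_catch]
    if (length(cc) == 0L) {
      warning(sprintf("participant %s has no catch trials; retained", p),
              call. = FALSE)
      return(data.frame(participant_id = p, n_catch = 0L,
                        catch_accuracy = NA_real_, excluded = FALSE,
                        stringsAsFactors = FALSE))
    }
    acc <- mean(cc)
    data.frame(participant_id = p, n_catch = length(cc),
               catch_accuracy = acc, excluded = !(acc > cutoff),
               stringsAsFactors = FALSE)
  }))
  keep <- report$participant_id[!report$excluded]
  list(responses = responses[responses$participant_id %in% keep, ],
       report = report)
}

#' Run configuration
#'
#' Gathers every constant that can appear in an output, so all results are
#' traceable to a config key.
#'
#' @param experiment `"exp1"` or `"exp2"`.
#' @param preset `sdt_preset` name for simulation.
#' @param n_participants cohort size (default: 15 for exp1, 240 for exp2).
#' @param n_pairs image pairs available (default: 82 for exp1, 136 exp2).
#' @param seed master seed.
#' @param alpha,star_alpha,double_star_alpha significance constants.
#' @param catch_n,catch_options,catch_quantile exclusion-threshold inputs.
#' @param image_threshold,filter_scale image-statistics constants.
#' @param exclusions apply the catch filter.
#' @return object of class `mrp_config`.
#' @export
mrp_config <- function(experiment = "exp2", preset = "default",
                       n_participants = NULL, n_pairs = NULL, seed = 1L,
                       alpha = 0.05, star_alpha = 0.003,
                       double_star_alpha = 1e-4,
                       catch_n = 13L, catch_options = 8L,
                       catch_quantile = 0.99,
                       image_threshold = 10, filter_scale = 1,
                       exclusions = TRUE) {
  if (is.null(n_participants)) n_participants <- if (experiment == "exp1") 15L else 240L
  if (is.null(n_pairs)) n_pairs <- if (experiment == "exp1") 82L else 136L
  structure(list(
    experiment = experiment, preset = preset,
    n_participants = as.integer(n_participants),
    n_pairs = as.integer(n_pairs), seed = as.integer(seed),
    alpha = alpha, star_alpha = star_alpha,
    double_star_alpha = double_star_alpha,
    catch_n = catch_n, catch_options = catch_options,
    catch_quantile = catch_quantile,
    image_threshold = image_threshold, filter_scale = filter_scale,
    exclusions = exclusions
  ), class = "mrp_config")
}

#' Run the full pipeline: simulate, exclude, score, report
#'
#' Generates a design and synthetic responses from the config's preset,
#' applies the catch-trial exclusion, scores Type 1/Type 2 AUCs and image
#' -pair classifications, and writes the report CSVs to `out_dir`:
#' `responses.csv`, `exclusions.csv`, `auc_present_vs_null.csv`,
#' `auc_original_vs_modified.csv`, `pair_classification.csv`,
#' `modelling_export.csv`, and `run_log.txt` (row counts, seed, and config
#' echo at every stage). Byte-identical outputs for identical configs.
#'
#' @param config an [mrp_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list of the in-memory artefacts.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "mrp_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(sprintf("mrpscore pipeline | experiment=%s preset=%s seed=%d",
                         config$experiment, config$preset, config$seed),
                 sprintf("config: %s", paste(names(unclass(config)),
                                             vapply(unclass(config), function(v)
                                               paste(format(v), collapse = ","),
                                               character(1)),
                                             sep = "=", collapse = " ")))
  stage <- function(msg) log_lines <<- c(log_lines, msg)

  pairs <- data.frame(
    pair_id = sprintf("pair%03d", seq_len(config$n_pairs)),
    critical_location = rep(1:9, length.out = config$n_pairs),
    stringsAsFactors = FALSE
  )
  plan <- plan_experiment(config$experiment, pairs, config$n_participants,
                          seed = config$seed)
  stage(sprintf("design: %d trials", nrow(plan$trials)))

  responses <- simulate_responses(plan, sdt_preset(config$preset),
                                  seed = config$seed)
  stage(sprintf("simulate: %d rows", nrow(responses)))

  if (config$exclusions && any(responses$is_catch)) {
    cut <- catch_cutoff(config$catch_n, config$catch_options,
                        config$catch_quantile)$cutoff
    excl <- apply_exclusions(responses, cut)
    stage(sprintf("exclude: cutoff=%.2f, %d excluded, %d rows remain",
                  cut, sum(excl$report$excluded), nrow(excl$responses)))
  } else {
    excl <- list(responses = responses,
                 report = data.frame(participant_id = character(0)))
    stage("exclude: skipped")
  }
  resp <- excl$responses

  auc_pn <- auc_summary(resp, "present_vs_null")
  auc_om <- auc_summary(resp, "original_vs_modified")
  pairs_cls <- classify_image_pairs(resp, alpha = config$alpha)
  export <- modelling_export(resp)
  stage(sprintf("score: %d participants, %d pairs classified",
                length(unique(resp$participant_id)), nrow(pairs_cls)))

  wr <- function(d, f) utils::write.csv(d, file.path(out_dir, f), row.names = FALSE)
  write_responses(responses, file.path(out_dir, "responses.csv"))
  wr(excl$report, "exclusions.csv")
  wr(auc_pn$auc, "auc_present_vs_null.csv")
  wr(auc_om$auc, "auc_original_vs_modified.csv")
  wr(pairs_cls, "pair_classification.csv")
  wr(export, "modelling_export.csv")
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))

  invisible(list(plan = plan, responses = responses, exclusions = excl$report,
                 auc_present_vs_null = auc_pn, auc_original_vs_modified = auc_om,
                 pair_classification = pairs_cls, modelling_export = export,
                 log = log_lines))
}
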