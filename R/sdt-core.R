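#' @title Decision-by-confidence (D x C) encoding
#'
#' @description In the massive report paradigm each probe elicits a yes/no
#' decision plus a confidence rating on a 1-4 scale. The two are folded into
#' a single signed 8-level code: the sign carries the decision (`yes` = +,
#' `no` = -) and the magnitude carries the confidence, giving values in
#' \{-4, -3, -2, -1, 1, 2, 3, 4\} with 0 unreachable.
#'
#' @param decision character vector, each element `"yes"` or `"no"`.
#' @param confidence integer vector in 1..4, recycled against `decision`.
#' @return integer vector of D x C codes.
#' @examples
#' encode_dxc("yes", 4)  # +4
#' encode_dxc("no", 3)   # -3
#' @export
encode_dxc <- function(decision, confidence) {
  if (!all(decision %in% c("yes", "no"))) {
    stop("`decision` must be 'yes' or 'no'", call. = FALSE)
  }
  confidence <- as.integer(confidence)
  if (anyNA(confidence) || any(confidence < 1L | confidence > 4L)) {
    stop("`confidence` must be an integer in 1..4", call. = FALSE)
  }
  ifelse(decision == "yes", confidence, -confidence)
}

#' Transformed D x C (tD x C)
#'
#' Shifts each D x C level half a unit toward zero, so the 8 levels become
#' equally spaced half-integers from -3.5 to +3.5 (unit spacing, no gap at
#' zero). This is the scale on which per-image-pair means and differences
#' (delta tD x C) are computed.
#'
#' @param dxc integer vector of D x C codes (non-zero, |dxc| <= 4).
#' @return numeric vector of tD x C values in \{-3.5, ..., -0.5, 0.5, ..., 3.5\}.
#' @examples
#' transform_tdxc(c(-4, -1, 1, 4))  # -3.5 -0.5 0.5 3.5
#' @export
transform_tdxc <- function(dxc) {
  .check_dxc(dxc)
  dxc - sign(dxc) * 0.5
}

.check_dxc <- function(dxc) {
  if (length(dxc) == 0L) stop("empty D x C vector", call. = FALSE)
  if (anyNA(dxc) || any(dxc == 0) || any(abs(dxc) > 4) || any(dxc != round(dxc))) {
    stop("D x C values must be integers in {-4..-1, 1..4}", call. = FALSE)
  }
  invisible(dxc)
}

# Interior criteria of the Type 1 sweep: response >= t counted as a
# "yes"-at-criterion, from strictest (>= +4) to most lenient (>= -3).
# ">= -4" would classify everything as yes and is the implicit (1,1) endpoint.
DXC_CRITERIA <- c(4L, 3L, 2L, 1L, -1L, -2L, -3L)

# Type 2 sweep over confidence 1..4: three non-trivial cut points.
CONF_CRITERIA <- c(4L, 3L, 2L)

#' Construct an ROC curve object
#'
#' @param fa,hit numeric vectors of false-alarm and hit rates at each
#'   criterion (interior points; the (0,0) and (1,1) endpoints are implicit).
#' @param criteria the thresholds that generated the points.
#' @param curve_kind `"type1"` or `"type2"`.
#' @return an object of class `mrp_roc` with elements `points` (data.frame
#'   `criterion`, `fa`, `hit`), `auc`, and `curve_kind`.
#' @keywords internal
new_roc <- function(fa, hit, criteria, curve_kind = c("type1", "type2")) {
  curve_kind <- match.arg(curve_kind)
  stopifnot(length(fa) == length(hit), length(fa) == length(criteria))
  pts <- data.frame(criterion = criteria, fa = fa, hit = hit)
  roc <- structure(
    list(points = pts, criteria = criteria, auc = NA_real_,
         curve_kind = curve_kind),
    class = "mrp_roc"
  )
  roc$auc <- auc_trapezoid(roc)
  roc
}

#' @export
print.mrp_roc <- function(x, ...) {
  cat(sprintf("<mrp_roc: %s, %d interior points, AUC = %.4f>\n",
              x$curve_kind, nrow(x$points), x$auc))
  print(x$points, row.names = FALSE)
  invisible(x)
}

#' Criterion-sweep Type 1 ROC curve
#'
#' Sweeps the seven cut points of the 8-level D x C scale from strictest
#' (only +4 counts as a yes) to most lenient (everything above -4): at each
#' criterion t, hit = P(signal D x C >= t), FA = P(noise D x C >= t). The
#' seven criteria exhaust every cut point of the discrete scale, so the
#' trapezoidal area under the resulting curve equals the Mann-Whitney
#' (rank) statistic exactly.
#'
#' @param signal_dxc,noise_dxc integer vectors of D x C codes for
#'   signal-class (e.g. present/original) and noise-class (e.g. null) probes.
#' @return an `mrp_roc` of kind `"type1"` with 7 interior points.
#' @seealso [type2_roc()], [auc_rank_oracle()]
#' @examples
#' type1_roc(c(4, 3, -1), c(-4, -2, 1))$auc  # 8/9
#' @export
type1_roc <- function(signal_dxc, noise_dxc) {
  if (length(signal_dxc) == 0L || length(noise_dxc) == 0L) {
    stop("insufficient data: both signal and noise D x C sets must be non-empty",
         call. = FALSE)
  }
  .check_dxc(signal_dxc)
  .check_dxc(noise_dxc)
  hit <- vapply(DXC_CRITERIA, function(t) mean(signal_dxc >= t), numeric(1))
  fa  <- vapply(DXC_CRITERIA, function(t) mean(noise_dxc >= t), numeric(1))
  new_roc(fa, hit, DXC_CRITERIA, "type1")
}

#' Criterion-sweep Type 2 (metacognitive) ROC curve
#'
#' Relates confidence to correctness: a correct trial rated at or above the
#' confidence criterion is a metacognitive hit, an incorrect trial rated at
#' or above it a metacognitive false alarm. The three cut points of the
#' 4-level confidence scale give 3 interior points.
#'
#' Undefined when a participant has no correct or no incorrect trials; that
#' case raises an error and callers report the AUC as missing (reporting it
#' as 1.0 would create a ceiling artefact).
#'
#' @param correct_confidences,incorrect_confidences integer vectors (1..4)
#'   of confidence ratings on correct and incorrect trials.
#' @return an `mrp_roc` of kind `"type2"` with 3 interior points.
#' @examples
#' type2_roc(c(4, 2), c(1, 3))$auc  # 0.75
#' @export
type2_roc <- function(correct_confidences, incorrect_confidences) {
  if (length(correct_confidences) == 0L || length(incorrect_confidences) == 0L) {
    stop("insufficient data: Type 2 AUC undefined without both correct and incorrect trials",
         call. = FALSE)
  }
  .check_conf(correct_confidences)
  .check_conf(incorrect_confidences)
  hit <- vapply(CONF_CRITERIA, function(c) mean(correct_confidences >= c), numeric(1))
  fa  <- vapply(CONF_CRITERIA, function(c) mean(incorrect_confidences >= c), numeric(1))
  new_roc(fa, hit, CONF_CRITERIA, "type2")
}

.check_conf <- function(conf) {
  if (anyNA(conf) || any(conf < 1 | conf > 4) || any(conf != round(conf))) {
    stop("confidence values must be integers in 1..4", call. = FALSE)
  }
  invisible(conf)
}

#' Trial correctness for Type 2 analysis
#'
#' For the present-vs-null task, hits (a yes to a present or original patch)
#' and correct rejections (a no to a null patch) are correct; everything
#' else is incorrect. The original-vs-modified task applies the same rule
#' with the original patch in the signal role and the modified patch in the
#' noise role.
#'
#' @param decision character vector, `"yes"` or `"no"`.
#' @param patch_type character vector in
#'   \{`present`, `original`, `modified`, `null`\}.
#' @param task `"present_vs_null"` or `"original_vs_modified"`.
#' @return logical vector: `TRUE` = correct, `NA` for patch types outside
#'   the task's domain (the caller filters those probes out).
#' @export
classify_correct <- function(decision, patch_type,
                             task = c("present_vs_null", "original_vs_modified")) {
  task <- match.arg(task)
  stopifnot(all(decision %in% c("yes", "no")),
            all(patch_type %in% c("present", "original", "modified", "null")))
  if (task == "present_vs_null") {
    signal <- patch_type %in% c("present", "original")
    in_domain <- signal | patch_type == "null"
  } else {
    signal <- patch_type == "original"
    in_domain <- signal | patch_type == "modified"
  }
  out <- ifelse(decision == "yes", signal, !signal)
  out[!in_domain] <- NA
  out
}

#' Trapezoidal area under an ROC curve
#'
#' Area under the piecewise-linear curve through (0,0), the interior
#' criterion points sorted lexicographically by (fa, hit) with duplicates
#' removed, and (1,1). For criterion sweeps that exhaust every cut point of
#' a discrete rating scale this equals the rank-based (Mann-Whitney) AUC
#' exactly.
#'
#' @param roc an `mrp_roc`, or anything with a `points` data.frame carrying
#'   `fa` and `hit` columns in the unit square.
#' @return AUC in `[0, 1]`.
#' @export
auc_trapezoid <- function(roc) {
  pts <- roc$points
  fa <- pts$fa
  hit <- pts$hit
  if (any(fa < 0 | fa > 1 | hit < 0 | hit > 1)) {
    stop("ROC coordinates must lie in the unit square", call. = FALSE)
  }
  o <- order(fa, hit)
  fa <- c(0, fa[o], 1)
  hit <- c(0, hit[o], 1)
  keep <- !duplicated(cbind(fa, hit))
  fa <- fa[keep]; hit <- hit[keep]
  sum(diff(fa) * (utils::head(hit, -1) + utils::tail(hit, -1)) / 2)
}

#' Rank-based AUC oracle
#'
#' Independent of the ROC construction: the proportion of signal-noise
#' pairs ranked correctly, ties counted half. Equals the trapezoidal area
#' under the full criterion-sweep ROC for discrete ratings; used to
#' cross-check [type1_roc()] and [type2_roc()].
#'
#' @param signal,noise numeric vectors of ratings.
#' @return AUC in `[0, 1]`.
#' @export
auc_rank_oracle <- function(signal, noise) {
  if (length(signal) == 0L || length(noise) == 0L) {
    stop("insufficient data: both rating sets must be non-empty", call. = FALSE)
  }
  cmp <- outer(signal, noise, ">")
  tie <- outer(signal, noise, "==")
  (sum(cmp) + 0.5 * sum(tie)) / (length(signal) * length(noise))
}
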