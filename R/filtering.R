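#' Two-stage PSM filter configuration
#'
#' Defaults reproduce the study's identification filter: 1% peptide FDR by
#' the target-decoy approach plus removal of search scores below 18.
#'
#' @param fdr_threshold q-value cutoff in (0, 1].
#' @param score_floor Minimum retained search score.
#' @return Object of class `"filter_config"`.
#' @export
filter_config <- function(fdr_threshold = 0.01, score_floor = 18) {
  if (!(is.numeric(fdr_threshold) && length(fdr_threshold) == 1L &&
        is.finite(fdr_threshold) && fdr_threshold > 0 && fdr_threshold <= 1))
    stop("invalid filter config field 'fdr_threshold'", call. = FALSE)
  if (!(is.numeric(score_floor) && length(score_floor) == 1L &&
        is.finite(score_floor)))
    stop("invalid filter config field 'score_floor'", call. = FALSE)
  structure(list(fdr_threshold = fdr_threshold, score_floor = score_floor),
            class = "filter_config")
}

# q-values for one score vector: for threshold t,
#   FDR(t) = #decoys with score >= t / max(1, #targets with score >= t)
# and q(s) = min_{t <= s} FDR(t) over observed thresholds, which is
# monotone non-increasing in s.
.qvalues_one <- function(score, is_decoy) {
  o <- order(score, decreasing = TRUE)
  s <- score[o]
  d <- is_decoy[o]
  cum_d <- cumsum(d)
  cum_t <- cumsum(!d)
  # index of the last PSM in each tie block = counts at threshold s[i]
  last <- which(!duplicated(s, fromLast = TRUE))
  fdr <- cum_d[last] / pmax(1, cum_t[last])
  q_at <- rev(cummin(rev(fdr)))          # min FDR over thresholds <= each value
  block <- rep(seq_along(last), diff(c(0L, last)))
  q <- numeric(length(s))
  q[o] <- q_at[block]
  q
}

#' Target-decoy q-value estimation
#'
#' Annotates PSMs with q-values from the plain target-decoy competition:
#' the FDR at score threshold t is the number of decoys scoring at or above
#' t divided by the number of targets scoring at or above t (floored at 1),
#' and a PSM's q-value is the minimum FDR over all thresholds at or below
#' its score.  No semi-supervised rescoring is performed, and no
#' peptide-level collapsing: q-values are per PSM.
#'
#' @param psms PSM data frame with `score` and `is_decoy` columns.
#' @param per_experiment If `TRUE` (default) q-values are estimated within
#'   each `experiment_id` separately, i.e. per labeling experiment; set to
#'   `FALSE` to pool all PSMs.
#' @return `psms` with a `qvalue` column appended.
#' @export
estimate_qvalues <- function(psms, per_experiment = TRUE) {
  if (is.null(psms) || nrow(psms) == 0L)
    stop("cannot estimate q-values from an empty PSM set", call. = FALSE)
  if (all(psms$is_decoy))
    stop("cannot estimate q-values: no target PSMs", call. = FALSE)
  psms$qvalue <- NA_real_
  groups <- if (per_experiment) split(seq_len(nrow(psms)), psms$experiment_id)
            else list(seq_len(nrow(psms)))
  for (idx in groups) {
    if (all(psms$is_decoy[idx]))
      stop("cannot estimate q-values: experiment '",
           psms$experiment_id[idx[1]], "' has no target PSMs", call. = FALSE)
    psms$qvalue[idx] <- .qvalues_one(psms$score[idx], psms$is_decoy[idx])
  }
  psms
}

#' Apply the two-stage identification filter
#'
#' Retains target PSMs with `qvalue <= fdr_threshold` and
#' `score >= score_floor`; decoys are always removed.  Input order is
#' preserved.
#'
#' @param psms PSM data frame annotated by [estimate_qvalues()].
#' @param config A [filter_config()].
#' @return The retained subset of `psms`.
#' @export
apply_psm_filter <- function(psms, config = filter_config()) {
  if (!inherits(config, "filter_config"))
    stop("'config' must be created by filter_config()", call. = FALSE)
  if (is.null(psms$qvalue))
    stop("PSMs carry no q-values; run estimate_qvalues() first", call. = FALSE)
  keep <- !psms$is_decoy &
    psms$qvalue <= config$fdr_threshold &
    psms$score >= config$score_floor
  out <- psms[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
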