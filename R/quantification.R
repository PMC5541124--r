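#' Four-plex experiment design
#'
#' Maps reporter channels to biological conditions for one labeling
#' experiment.  The default is the study's assignment: 114 = U0126-treated,
#' 115 = vehicle-treated, 116 = sham (the reference), 117 unused.  The
#' reference channel must map to `"sham"` and no condition other than
#' `"unused"` may be assigned to more than one channel.
#'
#' @param experiment_id Experiment identifier the design applies to.
#' @param channel_map Named character vector mapping channels
#'   (`"114"`,...,`"117"`) to conditions in
#'   `c("u0126", "vehicle", "sham", "unused")`.
#' @param reference_channel Channel used as denominator of all ratios.
#' @return Object of class `"experiment_design"`.
#' @export
experiment_design <- function(experiment_id,
                              channel_map = c("114" = "u0126",
                                              "115" = "vehicle",
                                              "116" = "sham",
                                              "117" = "unused"),
                              reference_channel = "116") {
  channels <- c("114", "115", "116", "117")
  if (!setequal(names(channel_map), channels))
    stop("channel_map must name channels 114, 115, 116, 117", call. = FALSE)
  channel_map <- channel_map[channels]
  bad <- setdiff(channel_map, c("u0126", "vehicle", "sham", "unused"))
  if (length(bad))
    stop("unknown condition '", bad[1], "' in channel_map", call. = FALSE)
  assigned <- channel_map[channel_map != "unused"]
  if (anyDuplicated(assigned))
    stop("each condition may be assigned to at most one channel",
         call. = FALSE)
  if (!reference_channel %in% channels ||
      channel_map[[reference_channel]] != "sham")
    stop("reference_channel must map to the sham condition", call. = FALSE)
  structure(list(experiment_id = experiment_id,
                 channel_map = channel_map,
                 reference_channel = reference_channel),
            class = "experiment_design")
}

#' Per-PSM log2 reporter ratio
#'
#' Vectorized over the rows of `psms`: log2 of the channel intensity over
#' the reference-channel intensity.  Missing if either intensity is missing
#' or zero; never an error.
#'
#' @param psms PSM data frame.
#' @param channel,reference_channel Channel identifiers
#'   (`"114"`,...,`"117"`).
#' @return Numeric vector, `NA` where undefined.
#' @export
psm_log2_ratio <- function(psms, channel, reference_channel = "116") {
  num <- psms[[paste0("i", channel)]]
  den <- psms[[paste0("i", reference_channel)]]
  ratio <- ifelse(is.na(num) | is.na(den) | num == 0 | den == 0,
                  NA_real_, num / den)
  log2(ratio)
}

#' Aggregate filtered PSMs to protein-level ratios
#'
#' For every (accession, experiment, assigned non-reference channel), the
#' protein log2 ratio is the median of the per-PSM log2 ratios — robust to
#' single aberrant spectra — with `n_psms` the number of contributing PSMs.
#' Proteins with no usable PSM for a channel are absent for that channel.
#'
#' @param psms Filtered PSM data frame.
#' @param designs A single [experiment_design()] applied to every
#'   experiment present, or a list of designs covering each
#'   `experiment_id`.
#' @return Data frame with columns `accession`, `experiment_id`, `channel`,
#'   `condition`, `log2_ratio`, `n_psms`.
#' @export
aggregate_protein <- function(psms, designs = experiment_design("")) {
  empty <- data.frame(accession = character(), experiment_id = character(),
                      channel = character(), condition = character(),
                      log2_ratio = numeric(), n_psms = integer(),
                      stringsAsFactors = FALSE)
  if (is.null(psms) || nrow(psms) == 0L) return(empty)
  design_for <- function(exp_id) {
    if (inherits(designs, "experiment_design")) return(designs)
    for (d in designs) if (d$experiment_id == exp_id) return(d)
    stop("no design for experiment '", exp_id, "'", call. = FALSE)
  }
  out <- list()
  for (exp_id in unique(psms$experiment_id)) {
    d <- design_for(exp_id)
    sub <- psms[psms$experiment_id == exp_id, , drop = FALSE]
    quant <- names(d$channel_map)[!d$channel_map %in% c("unused", "sham")]
    for (ch in quant) {
      r <- psm_log2_ratio(sub, ch, d$reference_channel)
      ok <- !is.na(r)
      if (!any(ok)) next
      med <- tapply(r[ok], sub$accession[ok], stats::median)
      n <- tapply(r[ok], sub$accession[ok], length)
      acc <- names(med)
      out[[length(out) + 1L]] <- data.frame(
        accession = acc, experiment_id = exp_id, channel = ch,
        condition = unname(d$channel_map[[ch]]),
        log2_ratio = unname(med[acc]), n_psms = as.integer(n[acc]),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Median normalization of protein log2 ratios
#'
#' Centers each channel of each labeling experiment so that the median
#' protein log2 ratio is exactly zero, correcting loading and labeling
#' bias.  The subtracted offsets are reported.  Normalization is
#' idempotent, and adding a constant to a channel changes only that
#' channel's offset, not the normalized values.
#'
#' @param ratios Protein ratio data frame from [aggregate_protein()].
#' @return List with elements `ratios` (normalized data frame) and
#'   `offsets` (data frame `experiment_id`, `channel`, `condition`,
#'   `offset`).
#' @export
median_normalize <- function(ratios) {
  key <- paste(ratios$experiment_id, ratios$channel)
  offsets <- list()
  for (k in unique(key)) {
    idx <- which(key == k)
    if (length(idx) < 2L)
      stop("cannot median-normalize channel ", ratios$channel[idx[1]],
           " of experiment '", ratios$experiment_id[idx[1]],
           "': fewer than 2 proteins", call. = FALSE)
    m <- stats::median(ratios$log2_ratio[idx])
    ratios$log2_ratio[idx] <- ratios$log2_ratio[idx] - m
    offsets[[length(offsets) + 1L]] <- data.frame(
      experiment_id = ratios$experiment_id[idx[1]],
      channel = ratios$channel[idx[1]],
      condition = ratios$condition[idx[1]],
      offset = m, stringsAsFactors = FALSE)
  }
  list(ratios = ratios,
       offsets = if (length(offsets)) do.call(rbind, offsets) else
         data.frame(experiment_id = character(), channel = character(),
                    condition = character(), offset = numeric()))
}

#' Merge duplicate labeling experiments
#'
#' Combines normalized protein ratios across experiments into one value per
#' (accession, condition) by averaging the per-experiment log2 ratios where
#' the protein was quantified; `n_psms` are summed and `n_experiments`
#' counts contributing experiments.  With `strict = TRUE`, only proteins
#' quantified in every experiment of the input whose per-experiment ratios
#' agree in sign are kept (a concordance requirement for duplicate runs).
#'
#' @param ratios Normalized protein ratio data frame.
#' @param strict Require full presence and sign concordance across
#'   experiments.
#' @return Data frame with columns `accession`, `condition`, `log2_ratio`,
#'   `n_psms`, `n_experiments`.
#' @export
merge_experiments <- function(ratios, strict = FALSE) {
  n_exp_total <- length(unique(ratios$experiment_id))
  key <- paste(ratios$accession, ratios$condition, sep = "\r")
  mean_r <- tapply(ratios$log2_ratio, key, mean)
  n_psms <- tapply(ratios$n_psms, key, sum)
  n_exp <- tapply(ratios$experiment_id, key, function(x) length(unique(x)))
  concord <- tapply(ratios$log2_ratio, key, function(x)
    all(x >= 0) || all(x <= 0))
  keys <- unique(key)
  parts <- strsplit(keys, "\r", fixed = TRUE)
  out <- data.frame(
    accession = vapply(parts, `[`, "", 1L),
    condition = vapply(parts, `[`, "", 2L),
    log2_ratio = unname(mean_r[keys]),
    n_psms = as.integer(n_psms[keys]),
    n_experiments = as.integer(n_exp[keys]),
    stringsAsFactors = FALSE)
  if (strict)
    out <- out[out$n_experiments == n_exp_total & unname(concord[keys]), ,
               drop = FALSE]
  rownames(out) <- NULL
  out
}
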