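# shared fixtures and independent oracles used across test files

# brute-force target-decoy q-values: enumerate every observed threshold
# at or below each PSM's score and take the minimum FDR
oracle_qvalues <- function(score, is_decoy) {
  vapply(seq_along(score), function(i) {
    ts <- unique(score[score <= score[i]])
    min(vapply(ts, function(t) {
      sum(is_decoy & score >= t) / max(1, sum(!is_decoy & score >= t))
    }, numeric(1)))
  }, numeric(1))
}

# minimal PSM data frame with sensible defaults
make_psms <- function(score, is_decoy = rep(FALSE, length(score)),
                      experiment_id = "EXP1",
                      accession = sprintf("ACC%03d", seq_along(score)),
                      i114 = 100, i115 = 100, i116 = 100, i117 = NA_real_) {
  n <- length(score)
  data.frame(psm_id = sprintf("PSM%03d", seq_len(n)),
             experiment_id = rep_len(experiment_id, n),
             peptide = sprintf("PEPTIDEK%03d", seq_len(n)),
             accession = rep_len(accession, n),
             score = score,
             is_decoy = is_decoy,
             i114 = rep_len(i114, n), i115 = rep_len(i115, n),
             i116 = rep_len(i116, n), i117 = rep_len(i117, n),
             stringsAsFactors = FALSE)
}

# protein ratio frame for one experiment/channel
make_ratios <- function(log2_ratio, condition = "vehicle",
                        channel = c(vehicle = "115", u0126 = "114")[[condition]],
                        experiment_id = "EXP1",
                        accession = sprintf("ACC%03d", seq_along(log2_ratio))) {
  data.frame(accession = accession,
             experiment_id = experiment_id,
             channel = channel,
             condition = condition,
             log2_ratio = log2_ratio,
             n_psms = 1L,
             stringsAsFactors = FALSE)
}

# independent contrast-classification oracle: literal case analysis
oracle_group <- function(sv, su) {
  if (sv == "up" && su != "up") return("group1")
  if (sv == "down" && su != "down") return("group2")
  if (sv == "up" && su == "up") return("persistent_up")
  if (sv == "down" && su == "down") return("persistent_down")
  "none"
}
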