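#' Configuration for the synthetic iTRAQ PSM generator
#'
#' Builds a validated configuration for [generate_experiment()].  The
#' defaults emulate the study design the pipeline was written for: a
#' four-plex iTRAQ labeling with U0126-treated animals on reporter channel
#' 114, vehicle-treated on 115 and sham-operated on 116 (117 quantified but
#' unassigned), run as two independent labeling experiments on pooled
#' cerebral-artery samples.
#'
#' Reporter intensities are multiplicative:
#' `intensity(channel) = base_abundance * 2^(true_log2 + eps)` with
#' `eps ~ Normal(0, noise_sd)` drawn independently per PSM and channel, so
#' that per-PSM log2 ratios against the reference channel are centered on
#' the protein's true effect.
#'
#' @param n_proteins Number of target proteins to simulate.
#' @param peptides_mean,peptides_dispersion Mean and negative-binomial
#'   dispersion (size) of the peptides-per-protein distribution; every
#'   protein gets at least one peptide.
#' @param base_abundance_meanlog,base_abundance_sdlog Log-normal parameters
#'   of the per-protein reference intensity.
#' @param noise_sd Standard deviation of the per-PSM, per-channel log2
#'   reporter noise.  Must be >= 0.
#' @param frac_up_vehicle,frac_down_vehicle Fractions of proteins truly up-
#'   or downregulated in the vehicle channel relative to sham; their sum
#'   must not exceed 1.
#' @param frac_reversed Fraction of truly regulated proteins whose effect is
#'   absent in the U0126 channel (the treatment "reverses" the change, i.e.
#'   the U0126-vs-sham true log2 is 0).  Non-reversed regulated proteins
#'   carry the same effect in both channels (persistent regulation).
#' @param effect_size True absolute log2 change of regulated proteins.
#' @param decoy_fraction Fraction of all PSMs that are decoys.
#' @param target_score_mean,target_score_sd,decoy_score_mean,decoy_score_sd
#'   Normal parameters of the search-engine score for target and decoy
#'   PSMs.  Decoy scores should sit below target scores for the
#'   target-decoy FDR filter to be exercisable.
#' @param n_experiments Number of independent labeling experiments.
#' @param channel117 Either `"unused"` (default; channel 117 intensities are
#'   missing, mirroring a 3-of-4-channel design) or one of `"u0126"`,
#'   `"vehicle"`, `"sham"` to populate 117 as a replicate of that condition.
#' @param seed Integer seed; identical config and seed give byte-identical
#'   output.
#'
#' @return An object of class `"generator_config"` (a named list).
#' @seealso [generate_experiment()], [write_psm_table()]
#' @export
generator_config <- function(n_proteins = 2000,
                             peptides_mean = 4,
                             peptides_dispersion = 2,
                             base_abundance_meanlog = log(1e5),
                             base_abundance_sdlog = 1,
                             noise_sd = 0.3,
                             frac_up_vehicle = 0.05,
                             frac_down_vehicle = 0.05,
                             frac_reversed = 1,
                             effect_size = 1.5,
                             decoy_fraction = 0.1,
                             target_score_mean = 40,
                             target_score_sd = 5,
                             decoy_score_mean = 10,
                             decoy_score_sd = 5,
                             n_experiments = 2,
                             channel117 = "unused",
                             seed = 1L) {
  cfg <- list(
    n_proteins = n_proteins,
    peptides_mean = peptides_mean,
    peptides_dispersion = peptides_dispersion,
    base_abundance_meanlog = base_abundance_meanlog,
    base_abundance_sdlog = base_abundance_sdlog,
    noise_sd = noise_sd,
    frac_up_vehicle = frac_up_vehicle,
    frac_down_vehicle = frac_down_vehicle,
    frac_reversed = frac_reversed,
    effect_size = effect_size,
    decoy_fraction = decoy_fraction,
    target_score_mean = target_score_mean,
    target_score_sd = target_score_sd,
    decoy_score_mean = decoy_score_mean,
    decoy_score_sd = decoy_score_sd,
    n_experiments = n_experiments,
    channel117 = channel117,
    seed = seed
  )
  .check_scalar <- function(field, ok) {
    x <- cfg[[field]]
    if (length(x) != 1L || !is.numeric(x) && !is.character(x) || is.na(ok) || !ok)
      stop("invalid generator config field '", field, "'", call. = FALSE)
  }
  num1 <- function(field) {
    x <- cfg[[field]]
    length(x) == 1L && is.numeric(x) && is.finite(x)
  }
  .check_scalar("n_proteins", num1("n_proteins") && n_proteins >= 1 &&
                  n_proteins == round(n_proteins))
  .check_scalar("peptides_mean", num1("peptides_mean") && peptides_mean >= 1)
  .check_scalar("peptides_dispersion",
                num1("peptides_dispersion") && peptides_dispersion > 0)
  .check_scalar("base_abundance_meanlog", num1("base_abundance_meanlog"))
  .check_scalar("base_abundance_sdlog",
                num1("base_abundance_sdlog") && base_abundance_sdlog >= 0)
  .check_scalar("noise_sd", num1("noise_sd") && noise_sd >= 0)
  .check_scalar("frac_up_vehicle",
                num1("frac_up_vehicle") && frac_up_vehicle >= 0 && frac_up_vehicle <= 1)
  .check_scalar("frac_down_vehicle",
                num1("frac_down_vehicle") && frac_down_vehicle >= 0 &&
                  frac_down_vehicle <= 1)
  if (frac_up_vehicle + frac_down_vehicle > 1)
    stop("invalid generator config field 'frac_up_vehicle': ",
         "frac_up_vehicle + frac_down_vehicle must be <= 1", call. = FALSE)
  .check_scalar("frac_reversed",
                num1("frac_reversed") && frac_reversed >= 0 && frac_reversed <= 1)
  .check_scalar("effect_size", num1("effect_size") && effect_size > 0)
  .check_scalar("decoy_fraction",
                num1("decoy_fraction") && decoy_fraction >= 0 && decoy_fraction < 1)
  .check_scalar("target_score_mean", num1("target_score_mean"))
  .check_scalar("target_score_sd", num1("target_score_sd") && target_score_sd >= 0)
  .check_scalar("decoy_score_mean", num1("decoy_score_mean"))
  .check_scalar("decoy_score_sd", num1("decoy_score_sd") && decoy_score_sd >= 0)
  .check_scalar("n_experiments", num1("n_experiments") && n_experiments >= 1 &&
                  n_experiments == round(n_experiments))
  if (!(is.character(channel117) && length(channel117) == 1L &&
        channel117 %in% c("unused", "u0126", "vehicle", "sham")))
    stop("invalid generator config field 'channel117'", call. = FALSE)
  .check_scalar("seed", num1("seed") && seed == round(seed))
  cfg$n_proteins <- as.integer(n_proteins)
  cfg$n_experiments <- as.integer(n_experiments)
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "generator_config")
}

# random tryptic-looking peptide strings, unique across the whole run
.random_peptides <- function(n) {
  aa <- strsplit("ACDEFGHILMNPQSTVWY", "")[[1]]
  gen <- function(k) {
    len <- sample(8:14, k, replace = TRUE)
    vapply(len, function(l) {
      paste0(paste(sample(aa, l - 1L, replace = TRUE), collapse = ""),
             sample(c("K", "R"), 1L))
    }, character(1))
  }
  pep <- gen(n)
  while (anyDuplicated(pep)) {
    dup <- duplicated(pep)
    pep[dup] <- gen(sum(dup))
  }
  pep
}

#' Simulate a four-plex iTRAQ experiment with known ground truth
#'
#' Draws a PSM-level table for the three assigned reporter channels
#' (114 = U0126, 115 = vehicle, 116 = sham reference) together with the
#' protein-level ground truth used to score downstream recovery.  Decoy
#' PSMs carry synthetic `DECOY_` accessions, scores from the decoy score
#' distribution, and no truth entry.  Peptides are unique to one protein;
#' shared-peptide protein inference is deliberately out of the generator's
#' vocabulary.
#'
#' The function seeds R's RNG from `config$seed`, so the same configuration
#' always reproduces the same tables.
#'
#' @param config A [generator_config()].
#' @return A list with elements
#'   \describe{
#'     \item{psms}{data frame with columns `psm_id`, `experiment_id`,
#'       `peptide`, `accession`, `score`, `is_decoy` (logical), `i114`,
#'       `i115`, `i116`, `i117` (`NA` = missing).}
#'     \item{truth}{data frame with columns `accession`,
#'       `true_log2_vehicle`, `true_log2_u0126`, `status_vehicle`
#'       (`"up"`/`"down"`/`"none"`), `reversed` (logical).}
#'   }
#' @export
generate_experiment <- function(config) {
  if (!inherits(config, "generator_config"))
    stop("'config' must be created by generator_config()", call. = FALSE)
  set.seed(config$seed)
  n <- config$n_proteins

  accession <- sprintf("SYN%05d", seq_len(n))
  n_up <- round(config$frac_up_vehicle * n)
  n_down <- round(config$frac_down_vehicle * n)
  status <- sample(rep(c("up", "down", "none"),
                       c(n_up, n_down, n - n_up - n_down)))
  true_veh <- ifelse(status == "up", config$effect_size,
                     ifelse(status == "down", -config$effect_size, 0))
  regulated <- status != "none"
  reversed <- regulated & (stats::runif(n) < config$frac_reversed)
  true_u0126 <- ifelse(reversed, 0, true_veh)

  truth <- data.frame(
    accession = accession,
    true_log2_vehicle = true_veh,
    true_log2_u0126 = true_u0126,
    status_vehicle = status,
    reversed = reversed,
    stringsAsFactors = FALSE
  )

  n_pep <- stats::rnbinom(n, size = config$peptides_dispersion,
                          mu = config$peptides_mean - 1) + 1L
  peptide <- .random_peptides(sum(n_pep))
  prot_of_pep <- rep(seq_len(n), n_pep)
  base_ab <- stats::rlnorm(n, config$base_abundance_meanlog,
                           config$base_abundance_sdlog)

  per_exp <- function(exp_id) {
    m <- length(prot_of_pep)
    A <- base_ab[prot_of_pep]
    eps <- function() stats::rnorm(m, 0, config$noise_sd)
    df <- data.frame(
      experiment_id = exp_id,
      peptide = peptide,
      accession = accession[prot_of_pep],
      score = stats::rnorm(m, config$target_score_mean, config$target_score_sd),
      is_decoy = FALSE,
      i114 = A * 2^(true_u0126[prot_of_pep] + eps()),
      i115 = A * 2^(true_veh[prot_of_pep] + eps()),
      i116 = A * 2^(eps()),
      i117 = NA_real_,
      stringsAsFactors = FALSE
    )
    if (config$channel117 != "unused") {
      tl <- switch(config$channel117,
                   u0126 = true_u0126[prot_of_pep],
                   vehicle = true_veh[prot_of_pep],
                   sham = rep(0, m))
      df$i117 <- A * 2^(tl + eps())
    }
    df
  }
  psms <- do.call(rbind, lapply(seq_len(config$n_experiments),
                                function(e) per_exp(sprintf("EXP%d", e))))

  n_target <- nrow(psms)
  n_decoy <- round(n_target * config$decoy_fraction / (1 - config$decoy_fraction))
  if (n_decoy > 0) {
    A <- stats::rlnorm(n_decoy, config$base_abundance_meanlog,
                       config$base_abundance_sdlog)
    eps <- function() stats::rnorm(n_decoy, 0, config$noise_sd)
    dec <- data.frame(
      experiment_id = sprintf("EXP%d",
                              sample(config$n_experiments, n_decoy, replace = TRUE)),
      peptide = .random_peptides(n_decoy),
      accession = sprintf("DECOY_%05d", seq_len(n_decoy)),
      score = stats::rnorm(n_decoy, config$decoy_score_mean, config$decoy_score_sd),
      is_decoy = TRUE,
      i114 = A * 2^(eps()),
      i115 = A * 2^(eps()),
      i116 = A * 2^(eps()),
      i117 = NA_real_,
      stringsAsFactors = FALSE
    )
    psms <- rbind(psms, dec)
  }
  psms <- cbind(psm_id = sprintf("PSM%07d", seq_len(nrow(psms))), psms,
                stringsAsFactors = FALSE)
  rownames(psms) <- NULL
  list(psms = psms, truth = truth)
}

#' Write / read the generator's ground-truth table
#'
#' Tab-separated with columns `accession`, `true_log2_vehicle`,
#' `true_log2_u0126`, `status_vehicle`, `reversed` (0/1).
#'
#' @param truth Truth data frame from [generate_experiment()].
#' @param path File path.
#' @return `write_truth_table()` returns `path` invisibly;
#'   `read_truth_table()` returns the truth data frame.
#' @export
write_truth_table <- function(truth, path) {
  out <- truth
  out$reversed <- as.integer(out$reversed)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_truth_table
#' @export
read_truth_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$reversed <- as.logical(df$reversed)
  df
}
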