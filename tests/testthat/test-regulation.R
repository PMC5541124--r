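test_that("the tag distribution matches closed forms and rejects degeneracy", {
  d <- fit_tag_distribution(c(-1, 0, 1))
  expect_equal(d$median, 0)
  expect_equal(d$sd, 1)

  # direct-formula oracle on a small sample with one outlier
  x <- c(0.1, -0.1, 0.0, 0.2, -0.2, 3.0)
  d <- fit_tag_distribution(x)
  expect_equal(d$median, (0.0 + 0.1) / 2)
  expect_equal(d$sd, sqrt(sum((x - mean(x))^2) / (length(x) - 1)))
  call <- call_regulation(x, d)
  expect_identical(call$status[6], "up")
  expect_identical(call$status[1:5], rep("unchanged", 5))

  expect_error(fit_tag_distribution(c(1, 1, 1, 1)), "zero spread")
  expect_error(fit_tag_distribution(c(1, 2)), "fewer than 3")
})

test_that("a deviation exactly at the threshold is unchanged", {
  d <- structure(list(condition = "vehicle", median = 0, sd = 1, n = 10,
                      robust = FALSE), class = "tag_distribution")
  calls <- call_regulation(c(2, 2 + 1e-9, -2, -2 - 1e-9, 0), d)
  expect_identical(calls$status,
                   c("unchanged", "up", "unchanged", "down", "unchanged"))
  expect_identical(unique(calls$contrast), "vehicle_vs_sham")
})

test_that("regulation calls are equivariant under affine channel rescaling", {
  set.seed(31)
  x <- rnorm(200)
  base <- call_regulation(x, fit_tag_distribution(x))$status
  for (ab in list(c(3, 0), c(1, -5), c(0.2, 2.7))) {
    y <- ab[1] * x + ab[2]
    expect_identical(call_regulation(y, fit_tag_distribution(y))$status, base)
  }
})

test_that("the robust scale option uses the consistent MAD", {
  set.seed(32)
  x <- c(rnorm(100), 50)   # one wild outlier
  d_sd <- fit_tag_distribution(x)
  d_mad <- fit_tag_distribution(x, robust = TRUE)
  expect_equal(d_mad$sd, mad(x))
  expect_lt(d_mad$sd, d_sd$sd)
})

test_that("null ratios are flagged at close to the two-sided 2-SD rate", {
  set.seed(33)
  x <- rnorm(20000)
  calls <- call_regulation(x, fit_tag_distribution(x))
  p <- mean(calls$status != "unchanged")
  p0 <- 2 * pnorm(-2)
  expect_lt(abs(p - p0), 3 * sqrt(p0 * (1 - p0) / length(x)))
})

test_that("well-separated true effects are flagged with the correct sign", {
  cfg <- generator_config(n_proteins = 500, noise_sd = 0.2, effect_size = 2,
                          frac_up_vehicle = 0.05, frac_down_vehicle = 0.05,
                          decoy_fraction = 0, seed = 37)
  sim <- generate_experiment(cfg)
  merged <- merge_experiments(median_normalize(
    aggregate_protein(sim$psms))$ratios)
  calls <- call_regulation(merged, fit_tag_distribution(merged, "vehicle"))
  truth <- sim$truth[match(calls$accession, sim$truth$accession), ]
  reg <- truth$status_vehicle != "none"
  expect_gte(mean(calls$status[reg] == truth$status_vehicle[reg]), 0.95)
})

test_that("contrast classification reproduces the published examples", {
  veh <- data.frame(accession = c("Q9JJ54", "Q64478", "P50116", "X1", "X2"),
                    contrast = "vehicle_vs_sham",
                    log2_ratio = c(3.84, -4.82, 3.96, 0.1, -0.2),
                    deviation = c(4, -5, 4.2, 0.3, -0.4),
                    status = c("up", "down", "up", "unchanged", "down"),
                    stringsAsFactors = FALSE)
  u <- data.frame(accession = c("Q9JJ54", "Q64478", "P50116", "X1", "X2"),
                  contrast = "u0126_vs_sham",
                  log2_ratio = c(0.1, 0.0, 3.5, 0.0, -3),
                  deviation = c(0.2, 0.1, 3.9, 0.1, -4),
                  status = c("unchanged", "unchanged", "up", "unchanged",
                             "down"),
                  stringsAsFactors = FALSE)
  cls <- classify_contrast(veh, u)
  got <- setNames(cls$group, cls$accession)
  # the strongest group-1 protein: up in vehicle, unchanged under U0126
  expect_identical(unname(got["Q9JJ54"]), "group1")
  # the strongest group-2 protein: down in vehicle, unchanged under U0126
  expect_identical(unname(got["Q64478"]), "group2")
  # up in both contrasts persists (as for the top vehicle protein, which is
  # absent from the group-1 table)
  expect_identical(unname(got["P50116"]), "persistent_up")
  expect_identical(unname(got["X1"]), "none")
  expect_identical(unname(got["X2"]), "persistent_down")
})

test_that("classification matches the case-analysis oracle and is disjoint", {
  set.seed(41)
  statuses <- c("up", "down", "unchanged")
  for (rep in 1:20) {
    n <- 50
    sv <- sample(statuses, n, replace = TRUE)
    su <- sample(statuses, n, replace = TRUE)
    acc <- sprintf("P%03d", seq_len(n))
    mk <- function(st, ctr) data.frame(accession = acc, contrast = ctr,
                                       log2_ratio = 0, deviation = 0,
                                       status = st, stringsAsFactors = FALSE)
    cls <- classify_contrast(mk(sv, "vehicle_vs_sham"), mk(su, "u0126_vs_sham"))
    expect_identical(cls$group, mapply(oracle_group, sv, su, USE.NAMES = FALSE))
    # one label per protein: group1 and group2 can never intersect
    expect_length(intersect(cls$accession[cls$group == "group1"],
                            cls$accession[cls$group == "group2"]), 0)
  }
})

test_that("proteins without a U0126 call are excluded but reported", {
  veh <- data.frame(accession = c("A", "B"), contrast = "vehicle_vs_sham",
                    log2_ratio = c(2, 3), deviation = c(3, 4),
                    status = c("up", "up"), stringsAsFactors = FALSE)
  u <- data.frame(accession = "A", contrast = "u0126_vs_sham",
                  log2_ratio = 0, deviation = 0, status = "unchanged",
                  stringsAsFactors = FALSE)
  cls <- classify_contrast(veh, u)
  expect_identical(cls$accession, "A")
  expect_identical(attr(cls, "unpaired")$accession, "B")
  expect_error(classify_contrast(rbind(veh, veh), u), "duplicate")
})

test_that("the published group replay reports counts and discordance", {
  res <- reproduce_paper_groups()
  expect_identical(res, reproduce_paper_groups())  # pure
  expect_equal(res$rows_total, res$rows_group1 + res$rows_group2)
  expect_equal(res$stated_group1, 133L)
  expect_equal(res$stated_group2, 51L)
  expect_equal(res$stated_total, 184L)
  expect_type(res$concordant, "logical")
})
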