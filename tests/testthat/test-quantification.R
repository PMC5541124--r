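test_that("per-PSM log2 ratios follow the closed form and missing rules", {
  psms <- make_psms(c(30, 30, 30, 30),
                    i114 = c(200, 100, 50, NA),
                    i116 = c(100, 100, 0, 100))
  r <- psm_log2_ratio(psms, "114")
  expect_equal(r[1], 1)
  expect_equal(r[2], 0)
  expect_true(is.na(r[3]))  # zero reference
  expect_true(is.na(r[4]))  # missing numerator
})

test_that("protein aggregation takes the median of per-PSM ratios", {
  one <- make_psms(30, accession = "A", i114 = 300, i116 = 100)
  agg <- aggregate_protein(one)
  expect_equal(agg$log2_ratio[agg$channel == "114"], log2(3))
  expect_equal(agg$n_psms[agg$channel == "114"], 1L)

  # ratios 1, 1, 5 on the u0126 channel: the outlier does not move the median
  tri <- make_psms(c(30, 30, 30), accession = "A",
                   i114 = c(200, 200, 3200), i116 = 100)
  agg <- aggregate_protein(tri)
  expect_equal(agg$log2_ratio[agg$channel == "114"], 1)
  expect_equal(agg$n_psms[agg$channel == "114"], 3L)

  expect_equal(nrow(aggregate_protein(make_psms(numeric(0)))), 0)
})

test_that("noiseless synthetic ratios recover the true effects exactly", {
  cfg <- generator_config(n_proteins = 100, noise_sd = 0, effect_size = 1.5,
                          frac_up_vehicle = 0.1, frac_down_vehicle = 0.1,
                          decoy_fraction = 0, n_experiments = 1, seed = 13)
  sim <- generate_experiment(cfg)
  agg <- aggregate_protein(sim$psms)
  veh <- agg[agg$condition == "vehicle", ]
  truth <- sim$truth$true_log2_vehicle[match(veh$accession,
                                             sim$truth$accession)]
  expect_equal(veh$log2_ratio, truth, tolerance = 1e-12)
  u <- agg[agg$condition == "u0126", ]
  truth_u <- sim$truth$true_log2_u0126[match(u$accession,
                                             sim$truth$accession)]
  expect_equal(u$log2_ratio, truth_u, tolerance = 1e-12)
})

test_that("median normalization centers each channel at exactly zero", {
  ratios <- make_ratios(c(0.5, 1.5, 2.5))
  norm <- median_normalize(ratios)
  expect_equal(norm$ratios$log2_ratio, c(-1, 0, 1))
  expect_equal(norm$offsets$offset, 1.5)

  # idempotence: a second pass changes nothing and reports zero offsets
  again <- median_normalize(norm$ratios)
  expect_equal(again$ratios$log2_ratio, norm$ratios$log2_ratio)
  expect_equal(again$offsets$offset, 0)

  set.seed(1)
  r2 <- make_ratios(rnorm(51))
  expect_lt(abs(median(median_normalize(r2)$ratios$log2_ratio)), 1e-12)
})

test_that("normalization is equivariant under per-channel shifts", {
  set.seed(2)
  ratios <- rbind(make_ratios(rnorm(20), "vehicle"),
                  make_ratios(rnorm(20), "u0126"))
  shifted <- ratios
  sel <- shifted$condition == "vehicle"
  shifted$log2_ratio[sel] <- shifted$log2_ratio[sel] + 0.8
  a <- median_normalize(ratios)
  b <- median_normalize(shifted)
  expect_equal(a$ratios$log2_ratio, b$ratios$log2_ratio, tolerance = 1e-12)
  dv <- b$offsets$offset[b$offsets$condition == "vehicle"] -
    a$offsets$offset[a$offsets$condition == "vehicle"]
  expect_equal(dv, 0.8, tolerance = 1e-12)
})

test_that("a channel with fewer than two proteins cannot be normalized", {
  ratios <- rbind(make_ratios(c(0.1, 0.2), "vehicle"),
                  make_ratios(0.3, "u0126"))
  expect_error(median_normalize(ratios), "114")
})

test_that("an injected labeling bias is recovered as the channel offset", {
  cfg <- generator_config(n_proteins = 400, noise_sd = 0.3,
                          frac_up_vehicle = 0, frac_down_vehicle = 0,
                          decoy_fraction = 0, n_experiments = 1, seed = 23)
  sim <- generate_experiment(cfg)
  sim$psms$i115 <- sim$psms$i115 * 2^0.7
  norm <- median_normalize(aggregate_protein(sim$psms))
  off <- norm$offsets$offset[norm$offsets$condition == "vehicle"]
  expect_lt(abs(off - 0.7), 4 * cfg$noise_sd / sqrt(cfg$n_proteins))
})

test_that("duplicate experiments merge by averaging where present", {
  r <- rbind(make_ratios(c(1, 2), "vehicle", experiment_id = "EXP1",
                         accession = c("A", "B")),
             make_ratios(c(3, -2), "vehicle", experiment_id = "EXP2",
                         accession = c("A", "C")))
  m <- merge_experiments(r)
  expect_equal(m$log2_ratio[m$accession == "A"], 2)      # mean of 1, 3
  expect_equal(m$log2_ratio[m$accession == "B"], 2)      # single experiment
  expect_equal(m$n_experiments[m$accession == "A"], 2L)
  expect_equal(m$n_psms[m$accession == "A"], 2L)

  # strict mode: require presence in all experiments and sign concordance
  r2 <- rbind(make_ratios(c(1, 2), "vehicle", experiment_id = "EXP1",
                          accession = c("A", "B")),
              make_ratios(c(3, -2), "vehicle", experiment_id = "EXP2",
                          accession = c("A", "B")))
  strict <- merge_experiments(r2, strict = TRUE)
  expect_identical(strict$accession, "A")
})

test_that("the experiment design rejects inconsistent channel maps", {
  expect_error(experiment_design("E", reference_channel = "115"), "sham")
  expect_error(experiment_design("E", channel_map = c("114" = "vehicle",
                                                      "115" = "vehicle",
                                                      "116" = "sham",
                                                      "117" = "unused")),
               "at most one channel")
  d <- experiment_design("E")
  expect_identical(unname(d$channel_map[["114"]]), "u0126")
})
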