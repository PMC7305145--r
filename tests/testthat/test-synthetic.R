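test_that("the default lumping scheme partitions 19 amino acids as 3/4/9/3", {
  sch <- lumping_scheme()
  expect_identical(length(sch$group_of), 19L)
  expect_identical(sch$group_sizes, c(3L, 4L, 9L, 3L))
  for (g in 1:4)
    expect_equal(sum(sch$shares[sch$group_of == g]), 1, tolerance = 1e-12)
  expect_error(lumping_scheme(c(a = 1L, b = 3L)), "1..k")
  expect_error(lumping_scheme(shares = c(bad = 1)), "named")
})

test_that("zero jitter splits pools exactly proportionally", {
  sch <- lumping_scheme()
  tr <- simulate_growth(default_cybernetic_params(), 0.1,
                        0.2 * sch$group_sizes, times = seq(0, 6, 0.5))
  aa <- disaggregate(tr, sch, jitter_sd = 0)
  for (m in c("Gln", "Glu", "Arg"))
    expect_equal(unname(aa[m, ]), unname(tr$substrates[, 1] / 3),
                 tolerance = 1e-12)
})

test_that("jittered disaggregation preserves pool totals exactly", {
  sch <- lumping_scheme()
  tr <- simulate_growth(default_cybernetic_params(), 0.1,
                        0.2 * sch$group_sizes, times = seq(0, 6, 0.5))
  set.seed(55)
  aa <- disaggregate(tr, sch, jitter_sd = 0.3)
  for (g in 1:4) {
    members <- names(sch$group_of)[sch$group_of == g]
    expect_equal(colSums(aa[members, , drop = FALSE]),
                 unname(tr$substrates[, g]), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("jitter separates members within a pool but keeps groups distinct", {
  exper <- generate_experiment(seed = 42)
  dep <- depletion_times(exper$truth$times, exper$truth$aa_profiles)
  c1 <- dep[c("Gln", "Glu", "Arg")]
  expect_gt(max(c1) - min(c1), 0)            # members differ
  c2 <- dep[c("Asn", "Asp", "Leu", "Pro")]
  expect_lt(max(c1), min(c2))                # groups stay separated
  d <- stats::dist(normalize_profiles(exper$truth$aa_profiles))
  sil <- cluster::silhouette(aa_groups()[rownames(exper$truth$aa_profiles)], d)
  expect_gt(mean(sil[, "sil_width"]), 0.5)
})

test_that("generated experiments have the documented shape", {
  exper <- generate_experiment(seed = 42)
  expect_setequal(unique(exper$data$species_id),
                  c(names(aa_groups()), "biomass"))
  expect_identical(sort(unique(exper$data$replicate_id)), 1:2)
  expect_true(all(exper$data$value >= 0))
  expect_identical(nrow(exper$data), 2L * 20L * 21L)
})

test_that("noiseless amino-acid curves sum to the lumped trajectory", {
  exper <- generate_experiment(noise = noise_model(measurement_sd = 0,
                                                   replicates = 1),
                               seed = 9)
  tot_aa <- colSums(exper$truth$aa_profiles)
  tot_pool <- rowSums(exper$truth$trajectory$substrates)
  expect_equal(tot_aa, unname(tot_pool), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("generation is deterministic given the seed", {
  e1 <- generate_experiment(seed = 4)
  e2 <- generate_experiment(seed = 4)
  expect_identical(e1$data, e2$data)
  e3 <- generate_experiment(seed = 5)
  expect_false(identical(e1$data, e3$data))
})

test_that("default parameters produce a triauxic curve with ordered pools", {
  exper <- generate_experiment(seed = 42)
  dep <- exper$truth$pool_depletion
  expect_lt(dep[["C1"]], dep[["C2"]])
  expect_lt(dep[["C2"]], dep[["C3"]])
  expect_identical(dep[["C4"]], Inf)  # last pool barely touched in horizon
  expect_identical(length(exper$truth$switch_times), 2L)
  tr <- exper$truth$trajectory
  io <- interpolate_series(tr$times, tr$biomass, n_out = 201)
  expect_gte(nrow(detect_lags(io$time_h, io$value)), 2L)
})

test_that("pooled observed data reconstruct the lumped series", {
  exper <- generate_experiment(noise = noise_model(measurement_sd = 0,
                                                   replicates = 1),
                               seed = 2)
  obs <- lump_observed(exper$data)
  obsw <- cybgrowth:::observed_wide(obs)
  tr <- exper$truth$trajectory
  expect_equal(unname(obsw$Y[, "C3"]), unname(tr$substrates[, 3]),
               tolerance = 1e-9)
  expect_equal(unname(obsw$Y[, "biomass"]), unname(tr$biomass),
               tolerance = 1e-9)
})

test_that("expression generation is seeded and respects the design", {
  d <- data.frame(size = c(3, 4), rho = c(0.9, 0))
  s1 <- generate_expression(d, n_timepoints = 5, seed = 3)
  s2 <- generate_expression(d, n_timepoints = 5, seed = 3)
  expect_identical(s1$tpm, s2$tpm)
  expect_identical(dim(s1$tpm), c(7L, 5L))
  expect_identical(lengths(s1$regulons), c(set1 = 3L, set2 = 4L))
  expect_true(all(s1$tpm >= 0))
  expect_error(generate_expression(data.frame(size = 2, rho = 1)), "rho")

  # independent genes: mean pairwise correlation near zero over many pairs
  set.seed(19)
  rs <- replicate(100, {
    sim <- generate_expression(data.frame(size = 2, rho = 0),
                               n_timepoints = 6, seed = sample.int(1e6, 1))
    lg <- log2(sim$tpm + 1)
    stats::cor(lg[1, ], lg[2, ])
  })
  expect_lt(abs(mean(rs)), 0.1)
})
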