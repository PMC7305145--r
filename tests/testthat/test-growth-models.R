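test_that("MMM derivatives match hand-evaluated kinetics", {
  p <- mmm_params(beta = c(2, 1, 1, 1), k = rep(1, 4), death_rate = 0)
  d <- mmm_derivatives(1, c(1, 0, 0, 0), p)
  expect_equal(unname(d[["biomass"]]), 2 * 1^2 / (1 + 1) * 1)
  expect_equal(unname(d[["S1"]]), -1)
  expect_equal(unname(d[c("S2", "S3", "S4")]), c(S2 = 0, S3 = 0, S4 = 0),
               ignore_attr = TRUE)
})

test_that("MMM with no substrate reduces to first-order death", {
  p <- mmm_params(beta = c(2, 1, 1, 1), k = rep(1, 4), death_rate = 0.1)
  d <- mmm_derivatives(1, rep(0, 4), p)
  expect_equal(unname(d[["biomass"]]), -0.1)
  expect_true(all(d[paste0("S", 1:4)] == 0))
})

test_that("MMM biomass gain balances substrate loss when death is zero", {
  set.seed(101)
  for (i in 1:20) {
    p <- random_mmm_params()
    p$death_rate <- 0
    d <- mmm_derivatives(stats::runif(1, 0.05, 3), stats::runif(4, 0, 2), p)
    expect_lt(abs(sum(d)), 1e-12)
    expect_true(all(d[paste0("S", 1:4)] <= 0))
  }
})

test_that("derivative functions reject invalid states", {
  p <- mmm_params(beta = rep(1, 4), k = rep(1, 4), death_rate = 0.1)
  expect_error(mmm_derivatives(NaN, rep(1, 4), p), "finite")
  expect_error(mmm_derivatives(1, c(-1, 1, 1, 1), p), "non-negative")
  expect_error(mmm_derivatives(1, rep(1, 3), p), "per pool")
})

test_that("control variables follow the matched-allocation laws", {
  ctrl <- cybernetic_controls(c(2, 1, 1, 0))
  expect_equal(ctrl$u, c(0.5, 0.25, 0.25, 0))
  expect_equal(ctrl$v, c(1, 0.5, 0.5, 0))

  expect_equal(cybernetic_controls(rep(0, 4)),
               list(u = rep(0, 4), v = rep(0, 4)))

  ctrl <- cybernetic_controls(rep(0.37, 4))
  expect_equal(ctrl$u, rep(0.25, 4))
  expect_equal(ctrl$v, rep(1, 4))

  expect_error(cybernetic_controls(c(1, -0.1, 0, 0)), "non-negative")
  expect_error(cybernetic_controls(c(1, NA, 0, 0)), "finite")
})

test_that("controls are normalized at every positive rate vector", {
  set.seed(7)
  for (i in 1:200) {
    r <- stats::runif(4, 0, 10)
    ctrl <- cybernetic_controls(r)
    expect_lt(abs(sum(ctrl$u) - 1), 1e-12)
    expect_identical(max(ctrl$v), 1)
    expect_true(all(ctrl$u >= 0 & ctrl$u <= 1))
    expect_true(all(ctrl$v >= 0 & ctrl$v <= 1))
  }
})

test_that("cybernetic derivatives match hand evaluation", {
  p <- cybernetic_params(v_max = c(2, 1, 1, 1), k_s = rep(1, 4),
                         v_e = rep(1, 4), k_e = rep(1, 4),
                         alpha = 0.05, beta_const = 0.05, death_rate = 0)
  d <- cybernetic_derivatives(1, c(1, 0, 0, 0), c(0.5, 0.01, 0.01, 0.01), p)
  # r1 = 2 * 0.5 * 1 / (1 + 1) = 0.5, v1 = 1
  expect_equal(unname(d[["S1"]]), -0.5)
  expect_equal(unname(d[["biomass"]]), 0.5)
  ctrl <- attr(d, "controls")
  expect_equal(ctrl$r[1], 0.5)
  expect_equal(ctrl$v[1], 1)
})

test_that("zero enzymes leave only constitutive synthesis", {
  p <- cybernetic_params(v_max = rep(1, 4), k_s = rep(1, 4),
                         v_e = rep(1, 4), k_e = rep(1, 4),
                         alpha = 0.1, beta_const = 0.05, death_rate = 0)
  d <- cybernetic_derivatives(1, c(1, 1, 1, 1), rep(0, 4), p)
  expect_equal(unname(d[paste0("E", 1:4)]), rep(0.05, 4), ignore_attr = TRUE)
  expect_equal(unname(d[["biomass"]]), 0)
})

test_that("cybernetic growth/consumption symmetry holds with zero death", {
  set.seed(11)
  for (i in 1:20) {
    p <- random_cybernetic_params()
    p$death_rate <- 0
    d <- cybernetic_derivatives(stats::runif(1, 0.05, 3),
                                stats::runif(4, 0, 2),
                                stats::runif(4, 0, 0.5), p)
    expect_lt(abs(d[["biomass"]] + sum(d[paste0("S", 1:4)])), 1e-12)
  }
})

test_that("as-printed dilution scales with biomass instead of enzyme", {
  base <- list(v_max = rep(1, 4), k_s = rep(1, 4), v_e = rep(1, 4),
               k_e = rep(1, 4), alpha = 0.1, beta_const = 0.01,
               death_rate = 0)
  p_std <- do.call(cybernetic_params, c(base, dilution_mode = "standard"))
  p_ap <- do.call(cybernetic_params, c(base, dilution_mode = "as_printed"))
  P <- 2; S <- c(1, 1, 1, 1); E <- c(0.4, 0.3, 0.2, 0.1)
  d_std <- cybernetic_derivatives(P, S, E, p_std)
  d_ap <- cybernetic_derivatives(P, S, E, p_ap)
  growth <- sum(attr(d_std, "controls")$v * attr(d_std, "controls")$r)
  delta <- d_ap[paste0("E", 1:4)] - d_std[paste0("E", 1:4)]
  expect_equal(unname(delta), unname(growth * E - growth * P),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("free-parameter counts match the default model configurations", {
  expect_identical(count_free_parameters("mmm"), 9L)
  expect_identical(count_free_parameters("cybernetic"), 19L)
  expect_identical(count_free_parameters("cybernetic",
                                         beta_sharing = "per_pool"), 22L)
  expect_identical(count_free_parameters("mmm", n_pools = 2), 5L)
})

test_that("with all substrate exhausted biomass decays exponentially", {
  for (params in list(
    mmm_params(beta = rep(1, 4), k = rep(1, 4), death_rate = 0.05),
    cybernetic_params(v_max = rep(1, 4), k_s = rep(1, 4), v_e = rep(1, 4),
                      k_e = rep(1, 4), alpha = 0.1, beta_const = 0.01,
                      death_rate = 0.05))) {
    tr <- simulate_growth(params, 0.1, rep(0, 4), times = seq(0, 10, 0.5))
    expect_equal(tr$biomass, 0.1 * exp(-0.05 * tr$times), tolerance = 1e-6)
  }
})

test_that("total mass is conserved along trajectories when death is zero", {
  set.seed(21)
  for (i in 1:5) {
    p <- random_mmm_params(); p$death_rate <- 0
    tr <- simulate_growth(p, 0.2, default_s0, times = seq(0, 8, 0.5))
    total <- tr$biomass + rowSums(tr$substrates)
    expect_lt(max(abs(total - total[1])) / total[1], 1e-6)

    q <- random_cybernetic_params(); q$death_rate <- 0
    tr <- simulate_growth(q, 0.2, default_s0, times = seq(0, 8, 0.5))
    total <- tr$biomass + rowSums(tr$substrates)
    expect_lt(max(abs(total - total[1])) / total[1], 1e-6)
  }
})

test_that("substrates never increase and enzymes stay non-negative", {
  set.seed(31)
  for (i in 1:5) {
    q <- random_cybernetic_params()
    tr <- simulate_growth(q, 0.1, default_s0, times = seq(0, 8, 0.25))
    expect_true(all(diff(tr$substrates) <= 1e-9))
    expect_true(all(tr$enzymes >= 0))  # post-clipping contract

    p <- random_mmm_params()
    tr <- simulate_growth(p, 0.1, default_s0, times = seq(0, 8, 0.25))
    expect_true(all(diff(tr$substrates) <= 1e-9))
  }
})

test_that("adaptive trajectories agree with the fixed-step Euler oracle", {
  set.seed(41)
  times <- seq(0, 4, 0.5)
  p <- random_mmm_params()
  tr <- simulate_growth(p, 0.1, default_s0, times = times)
  or <- euler_simulate(p, 0.1, default_s0, times = times)
  got <- cbind(tr$biomass, tr$substrates)
  expect_lt(max(abs(got - or) / pmax(apply(or, 2, max), 1e-3)[col(or)]), 1e-3)

  q <- random_cybernetic_params()
  tr <- simulate_growth(q, 0.1, default_s0, times = times)
  or <- euler_simulate(q, 0.1, default_s0, times = times)
  got <- cbind(tr$biomass, tr$substrates, tr$enzymes)
  expect_lt(max(abs(got - or) / pmax(apply(or, 2, max), 1e-3)[col(or)]), 1e-3)
})

test_that("trajectories tidy into long format with one row per state", {
  p <- default_cybernetic_params()
  tr <- simulate_growth(p, 0.1, default_s0, times = seq(0, 2, 0.5))
  df <- as.data.frame(tr)
  expect_setequal(unique(df$species_id),
                  c("biomass", paste0("C", 1:4), paste0("E", 1:4)))
  expect_identical(nrow(df), 5L * 9L)
  expect_true(all(df$model == "cybernetic"))
})
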