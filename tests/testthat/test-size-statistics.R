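test_that("size atoms sit at s0 e^{mu t}/2^i with master-equation
           weights", {
  p <- params_unit()
  tg <- grid_tau(7, per_tau = 20L)
  d <- fsp_propagate(p, 30, tg)
  a0 <- size_atoms(d, 0)
  expect_equal(nrow(a0$atoms), 1L)            # single atom at s0
  expect_equal(a0$atoms$size, p$s0)
  expect_equal(a0$atoms$weight, 1)
  a7 <- size_atoms(d, 7)
  expect_true(all(diff(a7$atoms$size) < 0 | diff(a7$atoms$i) < 0) ||
                all(diff(a7$atoms$size[order(a7$atoms$i)]) < 0))
  # consecutive counts halve the size exactly
  s_by_i <- a7$atoms$size[order(a7$atoms$i)]
  expect_equal(s_by_i[-1] / s_by_i[-length(s_by_i)],
               rep(0.5, length(s_by_i) - 1))
  # mass concentrates near i = t/tau = 7: heaviest atoms within 2x of s0
  top <- a7$atoms[order(-a7$atoms$weight), ][1:3, ]
  expect_true(all(top$i %in% 6:8))
  expect_true(all(top$size >= p$s0 / 2 * (1 - 1e-9) &
                    top$size <= 2 * p$s0 * (1 + 1e-9)))
  # mass conservation: kept weight + leak + dropped tail = 1
  expect_equal(sum(a7$atoms$weight) + a7$leak, 1, tolerance = 1e-9)
  expect_error(size_atoms(d, 1.2345), "grid")
})

test_that("size moments match direct evaluation over the atoms and are
           asymptotically tau-periodic", {
  p <- params_unit()
  tg <- grid_tau(7, per_tau = 20L)
  d <- fsp_propagate(p, 30, tg)
  ms <- size_moments(d)
  expect_equal(ms$mean[1], p$s0)
  expect_equal(ms$var[1], 0)
  for (t in c(2, 4.5, 7)) {
    a <- size_atoms(d, t, drop_below = 0)
    m <- sum(a$atoms$weight * a$atoms$size)
    v <- sum(a$atoms$weight * (a$atoms$size - m)^2)
    row <- which(ms$t == t)
    expect_equal(ms$mean[row], m, tolerance = 1e-12)
    expect_equal(ms$var[row], v, tolerance = 1e-12)
  }
  # periodic limit: <s(t + tau)> = <s(t)> for large t
  i6 <- which(ms$t == 6); i7 <- which(ms$t == 7)
  expect_lt(abs(ms$mean[i7] - ms$mean[i6]), 1e-3 * p$s0)
})

test_that("envelope over initial sizes: reduction to a single source and
           the three-source configuration", {
  p <- params_unit()
  env1 <- envelope_atoms(p$s0, 7, p, grid_points = 141L)
  d <- fsp_propagate(p, fsp_auto_truncate(p, 7, 1e-8),
                     seq(0, 7, length.out = 141L))
  a <- size_atoms(d, 7)
  expect_equal(env1$atoms[order(env1$atoms$i), ]$weight,
               a$atoms[order(a$atoms$i), ]$weight, tolerance = 1e-9)
  env3 <- envelope_atoms(c(1, 4 / 3, 5 / 3), 7, p, grid_points = 141L)
  expect_setequal(unique(env3$atoms$source_s0), c(1, 4 / 3, 5 / 3))
  for (s0 in c(1, 4 / 3, 5 / 3)) {
    w <- env3$atoms$weight[env3$atoms$source_s0 == s0]
    expect_equal(sum(w), 1, tolerance = 1e-7)
  }
  expect_error(envelope_atoms(c(1, -1), 7, p), "positive")
})

test_that("envelope atom weights match per-source stochastic ensembles", {
  p <- params_unit()
  s0v <- c(1, 4 / 3, 5 / 3)
  env <- envelope_atoms(s0v, 7, p, grid_points = 141L)
  for (j in seq_along(s0v)) {
    pj <- model_params(p$mu, p$k, s0v[j])
    cfg <- simulation_config(4000, 7, seed = 300 + j,
                             record_grid = seq(0, 7, length.out = 15L))
    h <- empirical_division_count_dist(simulate_ensemble(cfg, pj), 7)
    aj <- env$atoms[env$atoms$source_s0 == s0v[j], ]
    w <- aj$weight[match(seq_along(h) - 1L, aj$i)]
    w[is.na(w)] <- 0
    expect_lt(sum(abs(h - w)) / 2, 0.03)
  }
})

test_that("initial-size mixtures: point-mass reduction, atom merging for
           commensurate sizes, quantile-node convergence", {
  p <- params_unit()
  a_fix <- initial_size_mixture(initial_size_spec("fixed", s0 = 1),
                                n_nodes = 8, t = 7, p,
                                grid_points = 141L)
  env1 <- envelope_atoms(1, 7, p, grid_points = 141L)
  expect_equal(a_fix$atoms$weight[order(a_fix$atoms$i)],
               env1$atoms$weight[order(env1$atoms$i)], tolerance = 1e-9)
  # a 2 s0 component is the s0 component shifted one division: merged atoms
  spec2 <- initial_size_spec("atoms", values = c(1, 2),
                             weights = c(0.5, 0.5))
  mix2 <- initial_size_mixture(spec2, n_nodes = 2, t = 7, p,
                               grid_points = 141L)
  sizes1 <- envelope_atoms(1, 7, p, grid_points = 141L)$atoms$size
  sizes2 <- envelope_atoms(2, 7, p, grid_points = 141L)$atoms$size
  n_union <- nrow(mix2$atoms)
  expect_lt(n_union, length(sizes1) + length(sizes2))  # merging happened
  expect_true(any(is.na(mix2$atoms$source_s0)))
  expect_equal(sum(mix2$atoms$weight) + mix2$leak, 1, tolerance = 1e-9)
  # lognormal initial sizes: deterministic quantile mixture reproduces the
  # sampled-initial-size ensemble mean within its confidence band
  specln <- initial_size_spec("lognormal", meanlog = 0, sdlog = 0.1)
  mixln <- initial_size_mixture(specln, n_nodes = 32, t = 7, p,
                                grid_points = 141L)
  m_mix <- sum(mixln$atoms$weight * mixln$atoms$size)
  cfg <- simulation_config(4000, 7, seed = 77,
                           record_grid = seq(0, 7, length.out = 8L),
                           initial_size = specln)
  sm <- simulate_ensemble(cfg, p)$summary
  last <- nrow(sm)
  expect_lt(abs(m_mix - sm$mean_s[last]), sm$ci_s[last])
  expect_error(initial_size_mixture(list(type = "nope"), 4, 7, p),
               "initial_size_spec")
})
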