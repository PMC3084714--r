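test_that("migration settings are validated", {
  expect_error(migration_config(speed = 0, total_time = 10), "speed")
  expect_error(migration_config(tau_min = 3, total_time = 10), "tau_min")
  expect_error(migration_config(substep_dt = 0.3, total_time = 10),
               "substep_dt")
  expect_error(migration_config(v_sat = 5, total_time = 10), "v_sat")
  expect_error(migration_config(total_time = 10.003), "sub-steps")
})

test_that("tracks are reproducible bit-for-bit under a fixed seed", {
  env <- single_env()
  pl <- list(L = des_params())
  cfg <- short_config(total_time = 10, seed = 7L)
  a <- simulate_track(c(800, 0), env, pl, config = cfg)
  b <- simulate_track(c(800, 0), env, pl, config = cfg)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c2 <- short_config(total_time = 10, seed = 8L)
  expect_false(identical(as.data.frame(a),
                         as.data.frame(simulate_track(c(800, 0), env, pl,
                                                      config = c2))))
})

test_that("compiled and pure-R engines produce the same trajectory", {
  env <- opposing_env()
  pl <- list(L1 = des_params(), L2 = nondes_params())
  cfg <- short_config(total_time = 5, seed = 3L)
  a <- simulate_track(c(-250, 40), env, pl, config = cfg, engine = "cpp")
  b <- simulate_track(c(-250, 40), env, pl, config = cfg, engine = "r")
  expect_equal(nrow(a), nrow(b))
  for (cl in c("t_min", "x_um", "y_um", "heading_rad", "net_mag"))
    expect_equal(a[[cl]], b[[cl]], tolerance = 1e-8)
  expect_identical(a$mode, b$mode)
  fs_a <- attr(a, "final_states"); fs_b <- attr(b, "final_states")
  for (lig in names(fs_a))
    expect_equal(unname(fs_a[[lig]]), unname(fs_b[[lig]]),
                 tolerance = 1e-8)
})

test_that("motion never pauses: path length equals speed times time", {
  env <- single_env()
  pl <- list(L = des_params())
  cfg <- short_config(total_time = 20, seed = 5L)
  tr <- simulate_track(c(850, 0), env, pl, config = cfg)
  seg <- sqrt(diff(tr$x_um)^2 + diff(tr$y_um)^2)
  # each consecutive displacement is one straight sub-step
  expect_equal(seg, rep(cfg$speed * cfg$substep_dt, length(seg)),
               tolerance = 1e-6)
  expect_equal(sum(seg), cfg$speed * cfg$total_time, tolerance = 1e-6)
  # sampling grid spans [0, total_time] strictly increasing
  expect_equal(tr$t_min[1], 0)
  expect_equal(tr$t_min[nrow(tr)], cfg$total_time)
  expect_true(all(diff(tr$t_min) > 0))
  expect_true(all(tr$heading_rad >= 0 & tr$heading_rad < 2 * pi))
  expect_true(all(tr$mode %in% c("directed", "random")))
})

test_that("receptor conservation holds along migration trajectories", {
  env <- single_env()
  pl <- list(L = des_params())
  cfg <- short_config(total_time = 30, seed = 2L)
  tr <- simulate_track(c(800, 0), env, pl, config = cfg)
  expect_lt(attr(tr, "max_conservation_error"), 1e-6 * pl$L$R_u)
  fs <- attr(tr, "final_states")$L
  expect_equal(unname(rowSums(fs)), rep(pl$L$R_u, 4), tolerance = 1e-6)
  expect_true(all(fs >= 0))
})

test_that("with no ligand anywhere the cell performs an unbiased random walk", {
  # start far outside the field support: every step is sub-threshold
  env <- single_env()
  pl <- list(L = des_params())
  disp <- numeric(200)
  for (s in seq_len(200)) {
    cfg <- migration_config(total_time = 15, seed = 1000L + s)
    tr <- simulate_track(c(8000, 0), env, pl, config = cfg)
    expect_true(all(tr$mode == "random"))
    disp[s] <- dist_to(final_pos(tr), c(8000, 0))
  }
  path <- 10 * 15
  # diffusive, not ballistic: mean displacement is a small fraction of the
  # path length (expected ratio ~ 0.13 for 60 independent 2.5 um steps)
  expect_lt(mean(disp), 0.3 * path)
  expect_gt(mean(disp), 0.03 * path)
})

test_that("sub-threshold steps last tau_min and move in a straight line", {
  env <- single_env()
  pl <- list(L = des_params())
  cfg <- short_config(total_time = 5, seed = 9L)
  tr <- simulate_track(c(8000, 0), env, pl, config = cfg)
  # |v| = 0 < threshold: step time floors at tau_min = 5 sub-steps
  first <- tr[2:6, ]
  expect_equal(length(unique(round(first$heading_rad, 12))), 1L)
  d <- dist_to(c(first$x_um[5], first$y_um[5]), c(8000, 0))
  expect_equal(d, cfg$speed * cfg$tau_min, tolerance = 1e-9)
})

test_that("cohorts reproduce track-by-track from the base seed", {
  env <- single_env()
  pl <- list(L = des_params())
  cfg <- short_config(total_time = 5, seed = 21L)
  pop <- simulate_population(rbind(c(800, 0), c(700, 100)), env, pl,
                             config = cfg, base_seed = 21L)
  expect_equal(sort(unique(pop$track_id)), c(1L, 2L))

  t1 <- simulate_track(c(800, 0), env, pl, config = cfg)
  expect_equal(track_of(pop, 1)$x_um, t1$x_um)

  cfg2 <- short_config(total_time = 5, seed = 22L)
  t2 <- simulate_track(c(700, 100), env, pl, config = cfg2)
  expect_equal(track_of(pop, 2)$y_um, t2$y_um)

  expect_error(simulate_population(matrix(numeric(0), ncol = 2), env, pl,
                                   config = cfg), "non-empty")
})

test_that("a directed cell heads up-gradient and arrests near saturation", {
  # deterministic behaviour summary: from inside the sensing annulus the
  # desensitizable cell approaches the source but stops at the inner edge
  # where saturation and desensitization quench the orientation vector
  env <- single_env()
  pl <- list(L = des_params())
  cfg <- migration_config(total_time = 75, seed = 4L)
  tr <- simulate_track(c(900, 0), env, pl, config = cfg)
  d_final <- dist_to(final_pos(tr), c(0, 0))
  expect_lt(d_final, 800)
  expect_gt(d_final, 500)
  expect_true(any(tr$mode == "directed"))
})
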