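test_that("unit positions are exact on the axes and equivariant", {
  g <- cell_geometry()
  p <- unit_positions(c(0, 0), g)
  expect_identical(dim(p), c(4L, 2L))
  # the four default units lie exactly on the +-x, +-y axes at r = 5
  expect_equal(unname(p),
               rbind(c(5, 0), c(0, 5), c(-5, 0), c(0, -5)))
  expect_true(all(p[1, 1] == 5, p[1, 2] == 0, p[2, 1] == 0, p[3, 2] == 0))

  # translation equivariance
  p2 <- unit_positions(c(100, 0), g)
  expect_equal(unname(p2), unname(p) + rep(c(100, 0), each = 4))

  # eight units at 45-degree spacing
  g8 <- cell_geometry(n_units = 8)
  p8 <- unit_positions(c(0, 0), g8)
  ang <- atan2(p8[, 2], p8[, 1]) %% (2 * pi)
  expect_equal(ang, 2 * pi * (0:7) / 8)
  expect_equal(sqrt(rowSums(p8^2)), rep(5, 8))

  expect_error(cell_geometry(n_units = 6), "multiple of 4")
})

test_that("uniform ligand exposure gives a zero orientation vector", {
  # far from any source every unit sees the basal level
  env <- single_env()
  v <- ligand_orientation_steady(c(5000, 0), env, "L", des_params())
  expect_equal(v$magnitude, 0)

  # two identical opposing fields: exact cancellation at the midpoint
  v2 <- net_orientation_steady(c(0, 0), opposing_env(),
                               list(L1 = des_params(), L2 = des_params()))
  expect_equal(v2$magnitude, 0, tolerance = 1e-12)
})

test_that("on-axis orientation matches the closed-form per-unit oracle", {
  env <- single_env()
  p <- des_params()
  v <- ligand_orientation_steady(c(800, 0), env, "L", p)
  # by symmetry no transverse component; the up-gradient direction is -x
  expect_equal(v$vy, 0, tolerance = 1e-12)
  expect_lt(v$vx, 0)

  # oracle: steady-state active complexes at each unit position by hand
  L_units <- ligand_concentration(env, "L",
                                  c(805, 800, 795, 800),
                                  c(0, 5, 0, -5))
  lr <- steady_lr_act(L_units, p)
  expect_equal(v$vx, lr[1] - lr[3])
  expect_equal(v$vy, lr[2] - lr[4])
})

test_that("missing kinetic parameters are reported per ligand", {
  expect_error(
    net_orientation_steady(c(0, 0), opposing_env(),
                           list(L1 = des_params())),
    "L2")
})

test_that("fine unit rings agree with the 4-unit cell within 0.03%", {
  env <- single_env()
  p <- des_params()
  for (rho in c(600, 800, 900)) {
    m4 <- ligand_orientation_steady(c(rho, 0), env, "L", p)$magnitude
    for (n in c(36L, 72L)) {
      mn <- ligand_orientation_steady(c(rho, 0), env, "L", p,
                                      cell_geometry(n_units = n))$magnitude
      expect_lt(abs(mn - m4) / m4 * 100, 0.03)
    }
  }
})

test_that("orientation from supplied states applies the combination rule", {
  g <- cell_geometry()
  p <- des_params()

  # identical states at all units cancel
  same <- matrix(rep(c(1000, 120, 40, 20), each = 4), nrow = 4)
  v0 <- orientation_from_states(list(L = same), g)
  expect_equal(v0$magnitude, 0)

  # hand-built LR_act (30, 0, 10, 0) on units (+x, +y, -x, -y) -> (20, 0)
  m <- matrix(0, nrow = 4, ncol = 4)
  m[, 2] <- c(30, 0, 10, 0)
  v <- orientation_from_states(list(L = m), g)
  expect_equal(c(v$vx, v$vy), c(20, 0))

  # consistency: states taken from the closed-form steady state reproduce
  # the steady-state orientation
  env <- single_env()
  pos <- unit_positions(c(750, 0), g)
  L <- ligand_concentration(env, "L", pos[, 1], pos[, 2])
  sm <- t(vapply(L, function(l) unclass(steady_state(l, p)), numeric(4)))
  vs <- orientation_from_states(list(L = sm), g)
  vref <- ligand_orientation_steady(c(750, 0), env, "L", p, g)
  expect_equal(c(vs$vx, vs$vy), c(vref$vx, vref$vy))

  expect_error(orientation_from_states(list(L = m[1:3, ]), g), "per unit")
})

test_that("orientation map flags the threshold-gated directed band", {
  env <- single_env()
  geom <- cell_geometry()

  # a grid wholly outside every support: all zero, none directed
  m0 <- orientation_map(env, list(L = des_params()), geom,
                        bbox = c(2000, 2000, 2400, 2400), step = 200)
  expect_true(all(m0$vx == 0 & m0$vy == 0))
  expect_false(any(m0$directed))

  # along a radius of the 17.6 nM field: desensitizable receptors have a
  # directed annulus and an undirected inner region near the source
  md <- orientation_map(env, list(L = des_params()), geom,
                        bbox = c(50, 0, 1000, 0), step = 50)
  expect_true(any(md$directed))
  inner <- md$x_um <= 500
  expect_false(any(md$directed[inner]))

  # nondesensitizable receptors orient over a strictly larger region that
  # contains the desensitizable directed set
  mn <- orientation_map(env, list(L = nondes_params()), geom,
                        bbox = c(50, 0, 1000, 0), step = 50)
  expect_true(all(mn$directed[md$directed]))
  expect_gt(sum(mn$directed), sum(md$directed))
})

test_that("orientation is mirror-symmetric and rotation-equivariant", {
  p <- des_params()
  env <- ligand_environment(power_field("L", c(200, 150)))
  env_mirror <- ligand_environment(power_field("L", c(200, -150)))
  set.seed(3)
  for (i in 1:10) {
    pos <- c(runif(1, -800, 800), runif(1, -800, 800))
    v <- ligand_orientation_steady(pos, env, "L", p)
    vm <- ligand_orientation_steady(c(pos[1], -pos[2]), env_mirror, "L", p)
    expect_equal(vm$vx, v$vx, tolerance = 1e-12)
    expect_equal(vm$vy, -v$vy, tolerance = 1e-12)
  }

  # 90-degree rotation of the whole scene rotates the vector
  rot <- function(q) c(-q[2], q[1])
  env_rot <- ligand_environment(power_field("L", rot(c(200, 150))))
  for (i in 1:5) {
    pos <- c(runif(1, -800, 800), runif(1, -800, 800))
    v <- ligand_orientation_steady(pos, env, "L", p)
    vr <- ligand_orientation_steady(rot(pos), env_rot, "L", p)
    expect_equal(c(vr$vx, vr$vy), rot(c(v$vx, v$vy)), tolerance = 1e-9)
  }
})

test_that("single-value sweeps reduce to the plain steady evaluation", {
  env <- single_env()
  pl <- list(L = des_params())
  sw <- sweep_orientation("k_des", 0.065, c(800, 0), env, pl)
  v <- net_orientation_steady(c(800, 0), env, pl)
  # positive component toward the source center at (0, 0) from (800, 0)
  expect_equal(sw$component[1], -v$vx)
  expect_error(sweep_orientation("k_x", 0.1, 800, env, pl), "arg")
})

test_that("sweeping ligand 1's desensitization leaves ligand 2 untouched", {
  env <- opposing_env()
  pl <- list(L1 = des_params(), L2 = des_params())
  sw <- sweep_orientation("k_des1", c(0, 0.2), cbind(-300, 0), env, pl,
                          toward = c(-500, 0))
  # at k_des1 = 0 ligand 1 signals much more strongly than at 0.2
  expect_gt(sw$component[1], sw$component[2])
})
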