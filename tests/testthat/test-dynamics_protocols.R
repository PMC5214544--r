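test_that("coupler constraints transmit no power on prescribed motions and
           a mis-signed reconstruction is detected", {
  am <- assemble(load_model_description(double_pendulum_desc(
    coupler_slope = 0.6)))
  t <- seq(0, 2, by = 0.01)
  motion <- data.frame(time = t, q1 = deg2rad(40) * sin(2 * pi * t / 2))
  audit <- constraint_power_audit(am, motion)
  expect_lt(attr(audit, "max_abs_total"), 1e-6)
  expect_equal(audit$total, audit$power_external_term +
                 audit$power_generalized_term, tolerance = 1e-12)

  ## negative control: reconstruct the constraint forces with a
  ## mis-signed coupling derivative while keeping the true kinematics
  am_bad <- am
  am_bad$couplers[[1]]$df <- function(x) -0.6
  q0 <- default_q(am)
  r <- 50
  q <- q0; q[1] <- motion$q1[r]
  q <- enforce_couplers(am, q)
  qd1 <- (motion$q1[r + 1] - motion$q1[r - 1]) / (t[r + 1] - t[r - 1])
  G <- cervidyn:::coupler_G(am, q)
  qd_full <- as.numeric(G %*% c(qd1))
  res <- cervidyn:::rnea(am, q, qd_full, numeric(2))
  rec_bad <- cervidyn:::reconstruct_constraint_forces(am_bad, q, res$tau)
  expect_gt(abs(sum(rec_bad$Q_constraint * qd_full)), 1e-3)
})

test_that("a stationary locked coordinate produces identically zero
           constraint power", {
  d <- double_pendulum_desc()
  d$joints[[2]]$coordinates[[1]]$locked <- TRUE
  am <- assemble(load_model_description(d))
  t <- seq(0, 1, by = 0.01)
  motion <- data.frame(time = t, q1 = deg2rad(30) * sin(2 * pi * t))
  audit <- constraint_power_audit(am, motion)
  expect_identical(max(abs(audit$total)), 0)
})

test_that("shoulder couplers are workless during a servo-driven humeral
           elevation sweep", {
  am <- default_assembled()
  sim <- simulate_humeral_elevation(am, duration = 4, dt = 0.04)
  audit <- constraint_power_audit(attr(sim, "model"), sim)
  expect_lt(attr(audit, "max_abs_total"), 1e-6)
})

test_that("passive loading of a known rotational spring deflects by M/k", {
  ## single pin about the vertical axis: gravity torque identically zero
  d <- list(name = "rotor", gravity = c(0, -9.81, 0),
            segments = list(list(name = "rotor", mass = 2,
                                 com = c(0, 0, 0),
                                 inertia = c(0.02, 0.01, 0.02))),
            joints = list(list(name = "piv", parent = "ground",
                               child = "rotor",
                               coordinates = list(list(
                                 name = "psi", axis = c(0, 1, 0),
                                 range = c(-180, 180), default = 0)))))
  am <- assemble(load_model_description(d))
  k <- 3.5                              # N m / rad
  for (M in c(0.05, 0.1)) {             # small-angle regime
    res <- passive_rom_protocol(am, "axial_rotation", M,
                                segment = "rotor",
                                bushing = c(psi = k), damping = 0.8,
                                t_max = 20)
    expect_equal(unname(res$angles[["psi"]]), rad2deg(M / k),
                 tolerance = 0.01)
  }
  ## zero moment -> zero deflection (<= 0.01 deg)
  res0 <- passive_rom_protocol(am, "axial_rotation", 0, segment = "rotor",
                               bushing = c(psi = k), damping = 0.8)
  expect_lt(abs(res0$angles[["psi"]]), 0.01)
})

test_that("passive deflection is monotone in the applied moment and odd
           under moment reversal on a symmetric toy neck", {
  ## fibers ~7% stretched at neutral so the passive chain carries
  ## pre-tension (neutral path 0.10 m, slack 0.02 m)
  am <- assemble(toy_neck_model(n_joints = 2, f_max = 300,
                                l_opt = 0.08 / 1.07))
  defl <- vapply(c(0.5, 1, 2), function(M) {
    r <- passive_rom_protocol(am, "flexion_extension", M,
                              segment = "vert2", damping = 1,
                              t_max = 40)
    unname(r$angles[["flex1"]] + r$angles[["flex2"]])
  }, numeric(1))
  expect_true(all(diff(abs(defl)) > 0))
  ## odd symmetry (the toy is bilaterally symmetric in the sagittal plane
  ## once gravity is compensated)
  rp <- passive_rom_protocol(am, "flexion_extension", 1.5,
                             segment = "vert2", damping = 1, t_max = 40)
  rm <- passive_rom_protocol(am, "flexion_extension", -1.5,
                             segment = "vert2", damping = 1, t_max = 40)
  expect_lt(max(abs(rp$angles + rm$angles)), 0.05)
})

test_that("protocol reports non-convergence with the final state attached", {
  ## undamped, unsprung rotor under constant moment never settles
  d <- list(name = "rotor", gravity = c(0, 0, 0),
            segments = list(list(name = "rotor", mass = 1,
                                 com = c(0, 0, 0),
                                 inertia = c(0.01, 0.01, 0.01))),
            joints = list(list(name = "piv", parent = "ground",
                               child = "rotor",
                               coordinates = list(list(
                                 name = "psi", axis = c(0, 1, 0),
                                 range = c(-36000, 36000), default = 0)))))
  am <- assemble(load_model_description(d))
  expect_error(passive_rom_protocol(am, "axial_rotation", 0.5,
                                    segment = "rotor", damping = 0,
                                    t_max = 2),
               "no quasi-static equilibrium")
})

test_that("maximal isometric moment closed forms: r x F and linearity", {
  ## single muscle at perpendicular distance 0.03 m, full activation, at
  ## optimal fiber length, no antagonist
  d <- 0.03
  desc <- list(name = "pin", gravity = c(0, -9.81, 0),
               segments = list(list(name = "link", mass = 1,
                                    com = c(0, -0.5, 0),
                                    inertia = c(0, 0, 0))),
               joints = list(list(name = "j", parent = "ground",
                                  child = "link",
                                  coordinates = list(list(
                                    name = "q", axis = c(0, 0, 1),
                                    range = c(-720, 720), default = 0)))),
               muscles = list(list(name = "mu", group = "g",
                                   action = "flexor", f_max = 1000,
                                   l_opt = 2, l_slack = 0,
                                   path = list(
                                     list(segment = "ground",
                                          point = c(d, 1, 0)),
                                     list(segment = "link",
                                          point = c(d, -1, 0))))))
  am <- assemble(load_model_description(desc))
  dir <- sign(moment_arm(am, 0, "mu", "q"))
  res <- max_isometric_moments(am, "q", dir)
  expect_equal(abs(res$net_moment), d * 1000, tolerance = 1e-7)
  expect_identical(res$agonists, "mu")
  expect_identical(res$antagonists, character(0))
  ## doubling every f_max doubles the net moment (no passive overlap)
  desc2 <- desc
  desc2$muscles[[1]]$f_max <- 2000
  am2 <- assemble(load_model_description(desc2))
  expect_equal(max_isometric_moments(am2, "q", dir)$net_moment,
               2 * res$net_moment, tolerance = 1e-10)
  ## a coordinate with no crossing muscles yields an empty result
  none <- max_isometric_moments(default_assembled(), "knee_angle_r", 1)
  expect_identical(none$net_moment, 0)
  expect_length(none$agonists, 0)
})

test_that("toy multi-muscle isometric moment equals a brute-force sum of
           per-muscle torque contributions", {
  am <- assemble(toy_neck_model(n_joints = 2, f_max = 400, l_opt = 0.07))
  q <- default_q(am)
  dir <- 1
  res <- max_isometric_moments(am, "flex1", dir)
  ## brute force: per muscle, arm x tension at the assigned activation
  ref <- 0
  fk <- forward_kinematics(am, q)
  for (mu in am$muscles) {
    r <- moment_arm(am, q, mu, "flex1")
    if (abs(r) < 1e-6) next
    a <- if (sign(r) == dir) 1 else 0
    l <- musculotendon_length(am, q, mu, fk)
    ref <- ref + r * cervidyn:::muscle_tension(am, mu, a, l, 0)
  }
  expect_equal(res$net_moment, ref, tolerance = 1e-10)
})

test_that("agonist classification matches per-muscle sign inspection", {
  set.seed(33)
  am <- assemble(toy_neck_model(n_joints = 2))
  for (k in 1:4) {
    q <- deg2rad(runif(2, -25, 25))
    q <- enforce_couplers(am, q)
    cls <- classify_agonists(am, q, "flex2", 1)
    for (mu in am$muscles) {
      r <- moment_arm(am, q, mu, "flex2")
      if (abs(r) < 1e-6) {
        expect_false(mu$name %in% c(cls$agonists, cls$antagonists))
      } else if (r > 0) {
        expect_true(mu$name %in% cls$agonists)
      } else {
        expect_true(mu$name %in% cls$antagonists)
      }
    }
  }
})

test_that("rugby strength scaling stiffens the neck: larger extension
           capacity, smaller passive range of motion", {
  am <- default_assembled()
  masi <- apply_strength_scaling(am, strength_scaling("MASI"))
  rugby <- apply_strength_scaling(am, strength_scaling("Rugby"))
  expect_gt(abs(neck_capacity(rugby, "extension")$net_moment),
            abs(neck_capacity(masi, "extension")$net_moment))
  pair <- c("neck_flexion", "head_flexion")
  lockfn <- function(m) lock_coordinates(
    m, setdiff(m$coords$name[!m$coords$dependent], pair))
  rom <- function(m) {
    r <- passive_rom_protocol(lockfn(m), "flexion_extension", -2,
                              damping = 2, t_max = 30)
    abs(unname(r$angles[["neck_flexion"]]))
  }
  expect_gt(rom(masi), rom(rugby))
})
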