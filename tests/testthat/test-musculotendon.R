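test_that("musculotendon length: fixed path, pin-joint law of cosines, and
           brute-force multi-point sums", {
  ## 2-point path on ground: constant 1 m regardless of q
  d <- double_pendulum_desc()
  d$muscles <- list(list(
    name = "gg", group = "g", action = "extensor", f_max = 10, l_opt = 0.5,
    path = list(list(segment = "ground", point = c(0, 0, 0)),
                list(segment = "ground", point = c(0, 1, 0)))))
  am <- assemble(load_model_description(d))
  for (qv in list(c(0, 0), c(0.4, -1), c(-1.2, 0.3))) {
    expect_equal(musculotendon_length(am, qv, "gg"), 1, tolerance = 1e-14)
  }

  ## path spanning a pin joint: law of cosines
  a <- 0.3; b <- 0.4
  d2 <- list(name = "pin", gravity = c(0, -9.81, 0),
             segments = list(list(name = "link", mass = 1,
                                  com = c(0, -0.5, 0),
                                  inertia = c(0, 0, 0))),
             joints = list(list(name = "j", parent = "ground",
                                child = "link",
                                coordinates = list(list(name = "q",
                                                        axis = c(0, 0, 1),
                                                        range = c(-720, 720),
                                                        default = 0)))),
             muscles = list(list(name = "mu", group = "g",
                                 action = "flexor", f_max = 10,
                                 l_opt = 0.5,
                                 path = list(
                                   list(segment = "ground",
                                        point = c(0, a, 0)),
                                   list(segment = "link",
                                        point = c(0, -b, 0))))))
  am2 <- assemble(load_model_description(d2))
  for (qd in c(10, 45, 120)) {
    q <- deg2rad(qd)
    ## angle between the two attachment rays is pi - q
    L_ref <- sqrt(a^2 + b^2 - 2 * a * b * cos(pi - q))
    expect_equal(musculotendon_length(am2, q, "mu"), L_ref,
                 tolerance = 1e-12)
  }

  ## arbitrary 4-point path equals the sum of pairwise distances
  am3 <- default_assembled()
  mu <- am3$muscles[[1]]
  mu$path <- c(mu$path,
               list(list(segment = "cerv3", point = c(0.02, 0, 0.01)),
                    list(segment = "scapula_r", point = c(0, 0.01, 0))))
  q <- default_q(am3)
  fk <- forward_kinematics(am3, q)
  pts <- sapply(mu$path, function(p) point_world(am3, fk, p$segment,
                                                 p$point))
  L_ref <- sum(sapply(1:(ncol(pts) - 1), function(k)
    sqrt(sum((pts[, k + 1] - pts[, k])^2))))
  expect_equal(musculotendon_length(am3, q, mu), L_ref, tolerance = 1e-12)
})

test_that("moment arm: perpendicular-distance closed form, distal muscles,
           and tendon-excursion vs effective-torque agreement", {
  ## vertical line at perpendicular distance d from a z-axis pin
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
  expect_lt(abs(abs(moment_arm(am, 0, "mu", "q")) - d), 1e-8)
  expect_lt(abs(moment_arm(am, 0, "mu", "q", method = "effective_torque") -
                  moment_arm(am, 0, "mu", "q")), 1e-8)

  ## muscle entirely distal to the queried joint -> 0
  am2 <- default_assembled()
  expect_identical(moment_arm(am2, default_q(am2), "rectus_cap_post_r_1",
                              "hip_flexion_r"), 0)

  ## dual-method agreement across a posture grid on a 2-joint toy neck
  amn <- assemble(toy_neck_model(n_joints = 2))
  grid <- expand.grid(f1 = seq(-30, 30, length.out = 10),
                      f2 = seq(-30, 30, length.out = 10))
  worst <- 0
  for (r in seq_len(nrow(grid))) {
    q <- deg2rad(c(grid$f1[r], grid$f2[r]))
    for (mu in c("ant", "post")) {
      for (coord in c("flex1", "flex2")) {
        te <- moment_arm(amn, q, mu, coord)
        et <- moment_arm(amn, q, mu, coord, method = "effective_torque")
        worst <- max(worst, abs(te - et))
      }
    }
  }
  expect_lt(worst, 1e-8)
})

test_that("dual-method moment arms agree on the packaged muscles", {
  am <- default_assembled()
  set.seed(21)
  worst <- 0
  coords <- c("neck_flexion", "neck_bending", "neck_rotation",
              "head_flexion", "humeral_elev_r")
  for (k in 1:5) {
    q <- default_q(am)
    q[am$coord_index[coords]] <- q[am$coord_index[coords]] +
      deg2rad(runif(5, -8, 8))
    q <- enforce_couplers(am, q)
    for (mi in sample(seq_along(am$muscles), 12)) {
      for (coord in coords) {
        te <- moment_arm(am, q, am$muscles[[mi]], coord)
        et <- moment_arm(am, q, am$muscles[[mi]], coord,
                         method = "effective_torque")
        worst <- max(worst, abs(te - et))
      }
    }
  }
  expect_lt(worst, 1e-8)
})

test_that("Hill muscle force: definitions, passive-only limit and the
           packaged-constants formula oracle", {
  mtu <- list(f_max = 500, l_opt = 0.1, pennation = 0)
  ## a = 1 at optimal length, zero velocity -> exactly f_max
  expect_equal(muscle_force(mtu, 1, 0.1, 0), 500, tolerance = 1e-12)
  ## a = 0 at optimal length -> passive term zero
  expect_identical(muscle_force(mtu, 0, 0.1, 0), 0)
  ## formula oracle: recompute from the shipped constants file directly
  k <- read.table(system.file("extdata", "hill_constants.tsv",
                              package = "cervidyn"),
                  header = TRUE, sep = "\t")
  kv <- setNames(k$value, k$constant)
  a <- 0.5; ln <- 1.1
  fl <- exp(-((ln - 1) / kv[["fl_width"]])^2)
  fp <- (exp(kv[["fp_kpe"]] * (ln - 1) / kv[["fp_e0"]]) - 1) /
    (exp(kv[["fp_kpe"]]) - 1)
  expect_equal(muscle_force(mtu, a, 0.11, 0), 500 * (a * fl + fp),
               tolerance = 1e-12)
  ## velocity dependence at shortening half max speed
  v <- -0.5 * kv[["vmax_norm"]] * 0.1
  fv <- (1 - 0.5) / (1 + 0.5 / kv[["fv_af"]])
  expect_equal(muscle_force(mtu, 1, 0.1, v), 500 * fv, tolerance = 1e-12)
  ## monotone non-decreasing in activation at fixed kinematics
  fcurve <- vapply(seq(0, 1, by = 0.1), function(aa)
    muscle_force(mtu, aa, 0.12, -0.05), numeric(1))
  expect_true(all(diff(fcurve) >= 0))
  ## domain errors
  expect_error(muscle_force(mtu, 1, -0.1), "positive")
  expect_error(muscle_force(mtu, 2, 0.1), "\\[0, 1\\]")
})

test_that("activation dynamics: fixed point, closed-form step, ODE oracle", {
  expect_equal(activation_step(0.4, 0.4, 0.01), 0.4, tolerance = 1e-14)
  ## rising from 0 toward 1 over one activation time constant
  expect_equal(activation_step(0, 1, 0.015, tau_act = 0.015),
               1 - exp(-1), tolerance = 1e-12)
  expect_error(activation_step(0.5, 0.5, 0), "positive")
  ## arbitrary excitation trace vs a fine-grained deSolve solution
  set.seed(9)
  tt <- seq(0, 0.5, by = 0.002)
  exc_knots <- runif(6)
  exc_cont <- function(t) approx(seq(0, 0.5, length.out = 6), exc_knots,
                                 t, rule = 2)$y
  dt <- 0.002
  ## zero-order-hold excitation: the discrete update integrates exactly
  exc <- function(t) exc_cont(floor(t / dt + 1e-9) * dt)
  tau_a <- 0.012; tau_d <- 0.045
  a <- 0
  for (i in 2:length(tt)) {
    a <- activation_step(a, exc(tt[i - 1]), dt,
                         tau_act = tau_a, tau_deact = tau_d)
  }
  ode_fn <- function(t, y, p) {
    e <- exc(t)
    tau <- ifelse(e > y, tau_a, tau_d)
    list((e - y) / tau)
  }
  ref <- deSolve::ode(y = 0, times = tt, func = ode_fn, parms = NULL,
                      method = "ode45", rtol = 1e-10, atol = 1e-12,
                      hmax = dt / 4)
  expect_equal(a, unname(ref[nrow(ref), 2]), tolerance = 1e-6)
})

test_that("strength-scaling factors reproduce the published ratios", {
  expect_identical(compute_scaling_factor(51, 34.1), 1.5)
  expect_identical(compute_scaling_factor(66, 34.1), 1.9)
  expect_identical(compute_scaling_factor(61, 22.6), 2.7)
  expect_identical(compute_scaling_factor(32, 22.6), 1.4)
  expect_identical(compute_scaling_factor(7, 7), 1)
  expect_error(compute_scaling_factor(-1, 2), "positive")
  ss_m <- strength_scaling("MASI")
  expect_identical(ss_m$extensor_factor, 1.5)
  expect_identical(ss_m$flexor_factor, 1.4)
  ss_r <- strength_scaling("Rugby")
  expect_identical(ss_r$extensor_factor, 1.9)
  expect_identical(ss_r$flexor_factor, 2.7)
})

test_that("applying strength scaling multiplies forces by class, preserves
           geometry, and refuses double application", {
  am <- assemble(toy_neck_model(n_joints = 1, f_max = 100))
  sc <- list(extensor_factor = 1.5, flexor_factor = 1.4,
             population = "toy")
  am2 <- apply_strength_scaling(am, sc)
  f <- setNames(vapply(am2$muscles, `[[`, numeric(1), "f_max"),
                vapply(am2$muscles, `[[`, "", "name"))
  expect_equal(unname(f["post"]), 150)
  expect_equal(unname(f["ant"]), 140)
  ## unit factors leave the model unchanged
  am1 <- apply_strength_scaling(am, list(extensor_factor = 1,
                                         flexor_factor = 1))
  expect_identical(vapply(am1$muscles, `[[`, numeric(1), "f_max"),
                   vapply(am$muscles, `[[`, numeric(1), "f_max"))
  ## geometry untouched: moment arms identical after scaling
  q <- deg2rad(10)
  expect_identical(moment_arm(am2, q, "post", "flex1"),
                   moment_arm(am, q, "post", "flex1"))
  ## double application is refused
  expect_error(apply_strength_scaling(am2, sc), "already")
  ## untagged muscles are named in the error
  am_bad <- am
  am_bad$muscles[[1]]$action <- NULL
  expect_error(apply_strength_scaling(am_bad, sc), "ant")
})

test_that("isometric capacity scales exactly with the group factors when
           no antagonist passive force overlaps", {
  am <- assemble(toy_neck_model(n_joints = 1, f_max = 200, l_opt = 0.12))
  ## at neutral both muscles sit at l_opt (built that way: l_slack +
  ## fiber exactly spans the neutral path) -> no passive overlap
  dir_ext <- sign(moment_arm(am, default_q(am), "post", "flex1"))
  base <- max_isometric_moments(am, "flex1", dir_ext)
  am2 <- apply_strength_scaling(am, list(extensor_factor = 1.9,
                                         flexor_factor = 2.7))
  up <- max_isometric_moments(am2, "flex1", dir_ext)
  expect_equal(up$net_moment / base$net_moment, 1.9, tolerance = 1e-9)
})
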