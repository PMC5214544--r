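test_that("IK recovers a static pose exactly from noise-free markers", {
  am <- default_assembled()
  q_true <- default_q(am)
  q_true[am$coord_index["neck_flexion"]] <- deg2rad(6)
  q_true[am$coord_index["hip_flexion_r"]] <- deg2rad(15)
  q_true[am$coord_index["elbow_flex_l"]] <- deg2rad(40)
  q_true <- enforce_couplers(am, q_true)
  fk <- forward_kinematics(am, q_true)
  n <- 3
  mk <- lapply(am$markers, function(d)
    matrix(rep(point_world(am, fk, d$segment, d$offset), each = n), n, 3))
  names(mk) <- vapply(am$markers, `[[`, "", "name")
  ms <- marker_set(seq(0, by = 0.01, length.out = n), mk, rate = 100)
  ik <- inverse_kinematics(am, ms)
  free <- cervidyn:::free_coord_idx(am)
  err <- max(abs(as.matrix(ik[, 1 + free]) -
                   matrix(rep(q_true[free], each = n), n)))
  expect_lt(rad2deg(err), 1e-6)
  expect_lt(max(attr(ik, "rms")), 1e-9)
})

test_that("IK tracks a moving synthetic trial within 0.5 deg RMS", {
  am <- default_assembled()
  spec <- motion_spec("flexion_extension", amplitude = 15, duration = 1.5,
                      rate = 20, noise_sd = 0, seed = 4)
  syn <- synth_markers(am, spec)
  ik <- inverse_kinematics(am, syn$markers)
  ci <- am$coord_index[["neck_flexion"]]
  rmse <- sqrt(mean((ik$neck_flexion - syn$q_true$neck_flexion)^2))
  expect_lt(rad2deg(rmse), 0.5)
  ## coupled SC/AC coordinates in the solution satisfy their couplers
  r <- nrow(ik)
  qrow <- as.numeric(as.matrix(ik[r, -1]))
  expect_lt(max(abs(qrow - enforce_couplers(am, qrow))), 1e-9)
})

test_that("IK marker residual reflects the injected marker noise", {
  am <- default_assembled()
  rms_all <- c()
  for (seed in 1:3) {
    spec <- motion_spec("flexion_extension", amplitude = 10, duration = 0.2,
                        rate = 20, noise_sd = 1e-3, seed = seed)
    syn <- synth_markers(am, spec)
    ik <- inverse_kinematics(am, syn$markers)
    rms_all <- c(rms_all, attr(ik, "rms"))
  }
  m <- mean(rms_all)
  expect_gt(m, 0.5e-3)
  expect_lt(m, 1.5e-3)
})

test_that("IK flags unsolvable frames and interpolates short gaps", {
  am <- default_assembled()
  spec <- motion_spec("flexion_extension", amplitude = 10, duration = 0.5,
                      rate = 20, noise_sd = 0, seed = 2)
  syn <- synth_markers(am, spec)
  for (nm in names(syn$markers$markers)) {
    syn$markers$markers[[nm]][5:6, ] <- NA   # 0.1 s gap, all markers out
  }
  ik <- inverse_kinematics(am, syn$markers)
  expect_true(all(attr(ik, "flagged")[5:6]))
  ok <- !attr(ik, "flagged")
  expect_lt(rad2deg(max(abs(ik$neck_flexion[ok] -
                              syn$q_true$neck_flexion[ok]))), 0.01)
  ## interpolated gap frames stay close to the true smooth motion
  expect_lt(rad2deg(max(abs(ik$neck_flexion - syn$q_true$neck_flexion))),
            2)
})

test_that("inverse dynamics closed forms: static gravity compensation", {
  m <- 1; l <- 1
  am <- assemble(toy_pendulum_model(length = l, mass = m))
  ## held horizontal: support moment = m g l at the COM lever
  t <- seq(0, 0.2, by = 0.01)
  traj <- data.frame(time = t, theta = rep(deg2rad(90), length(t)))
  id <- inverse_dynamics(am, traj)
  expect_equal(unname(id$theta), rep(m * 9.81 * l, length(t)),
               tolerance = 1e-9)
  ## zero motion, zero loads -> gravity compensation exactly
  traj0 <- data.frame(time = t, theta = rep(deg2rad(30), length(t)))
  id0 <- inverse_dynamics(am, traj0)
  expect_equal(unname(id0$theta), rep(m * 9.81 * l * sin(deg2rad(30)),
                                      length(t)), tolerance = 1e-9)
})

test_that("FD/ID round trip recovers the applied generalized forces", {
  am <- assemble(load_model_description(double_pendulum_desc(
    m1 = 1.2, m2 = 0.8, l1 = 0.9, l2 = 0.6, q1 = 20, q2 = 10)))
  trq <- function(t, q, u) c(q1 = 0.8 * sin(2 * pi * t),
                             q2 = 0.3 * cos(3 * t))
  tt <- seq(0, 3, by = 0.002)
  sim <- simulate_model(am, tt, torque_fn = trq, rtol = 1e-10,
                        atol = 1e-12)
  traj <- data.frame(time = sim$time, q1 = sim$q1, q2 = sim$q2)
  id <- inverse_dynamics(am, traj)
  keep <- 5:(nrow(id) - 4)            # drop end-effect samples
  tau_ref <- vapply(tt[keep], function(t) trq(t)[["q1"]], numeric(1))
  tau_ref2 <- vapply(tt[keep], function(t) trq(t)[["q2"]], numeric(1))
  rms1 <- sqrt(mean((id$q1[keep] - tau_ref)^2))
  rms2 <- sqrt(mean((id$q2[keep] - tau_ref2)^2))
  expect_lt(rms1, 1e-3)
  expect_lt(rms2, 1e-3)
})

test_that("joint reactions: static single segment and stacked segments", {
  ## 5 kg head-like segment pinned and held still: support force 49.05 N
  d <- list(name = "head1", gravity = c(0, -9.81, 0),
            segments = list(list(name = "head", mass = 5,
                                 com = c(0, 0.05, 0),
                                 inertia = c(0.03, 0.02, 0.03))),
            joints = list(list(name = "neck", parent = "ground",
                               child = "head",
                               coordinates = list(list(
                                 name = "q", axis = c(0, 0, 1),
                                 range = c(-90, 90), default = 0)))))
  am <- assemble(load_model_description(d))
  t <- seq(0, 0.1, by = 0.01)
  traj <- data.frame(time = t, q = rep(0, length(t)))
  jr <- compute_joint_reactions(am, traj)
  expect_equal(sqrt(sum(jr$forces$neck[1, ]^2)), 49.05, tolerance = 1e-9)
  expect_equal(jr$forces$neck[1, ], c(0, 49.05, 0), tolerance = 1e-9)

  ## two stacked static segments: lower joint carries the combined weight
  d$segments[[2]] <- list(name = "upper", mass = 2, com = c(0, 0.05, 0),
                          inertia = c(0.01, 0.008, 0.01))
  d$joints[[2]] <- list(name = "upper_j", parent = "head", child = "upper",
                        location_in_parent = c(0, 0.1, 0),
                        coordinates = list(list(name = "q2",
                                                axis = c(0, 0, 1),
                                                range = c(-90, 90),
                                                default = 0)))
  am2 <- assemble(load_model_description(d))
  traj2 <- data.frame(time = t, q = 0, q2 = 0)
  jr2 <- compute_joint_reactions(am2, traj2)
  expect_equal(jr2$forces$neck[1, ], c(0, 7 * 9.81, 0), tolerance = 1e-9)
  expect_equal(jr2$forces$upper_j[1, ], c(0, 2 * 9.81, 0),
               tolerance = 1e-9)
})

test_that("joint-reaction recursion matches the independent free-body
           Newton-Euler oracle on random dynamic chains", {
  for (seed in c(3, 14, 27)) {
    n <- 4 + seed %% 3
    m <- random_chain_model(n_links = n, seed = seed)
    am <- assemble(m)
    q0 <- default_q(am)
    v0 <- seq(0.4, 1.1, length.out = n)
    acc <- seq(-2, 2.5, length.out = n)
    ## quadratic coordinate histories: central differences are exact, so
    ## the comparison isolates the force recursion itself
    tt <- seq(0, 0.08, by = 0.02)
    qs <- t(vapply(tt, function(t2) q0 + v0 * t2 + 0.5 * acc * t2^2,
                   numeric(n)))
    colnames(qs) <- coordinate_names(am)
    traj <- data.frame(time = tt, qs, check.names = FALSE)
    ext <- list(list(segment = paste0("link", n - 1),
                     point = c(0.03, -0.1, 0), force = c(15, 25, -10)))
    jr <- compute_joint_reactions(am, traj, external_loads = ext)
    r_mid <- 3L
    t_mid <- tt[r_mid]
    q_mid <- q0 + v0 * t_mid + 0.5 * acc * t_mid^2
    qd_mid <- v0 + acc * t_mid
    for (k in c(1L, min(3L, n))) {
      oracle <- oracle_newton_euler_reaction(m$config, q_mid, qd_mid,
                                             acc, k, ext = ext)
      expect_lt(max(abs(jr$forces[[paste0("j", k)]][r_mid, ] - oracle)),
                1e-9)
    }
  }
})

test_that("joint-reaction recursion matches the oracle analytically at
           machine precision on a static loaded chain", {
  am <- assemble(random_chain_model(n_links = 5, seed = 8))
  q0 <- default_q(am)
  tt <- seq(0, 0.04, by = 0.01)
  traj <- data.frame(time = tt,
                     matrix(rep(q0, each = length(tt)), length(tt),
                            dimnames = list(NULL, coordinate_names(am))),
                     check.names = FALSE)
  ext <- list(list(segment = "link4", point = c(0.02, -0.1, 0),
                   force = c(12, -30, 7)))
  jr <- compute_joint_reactions(am, traj, external_loads = ext)
  ## static oracle: subtree weights + external loads, no accelerations
  for (jn in c("j1", "j3", "j5")) {
    k <- as.integer(sub("j", "", jn))
    segs <- paste0("link", k:5)
    w <- -sum(am$model$segments$mass[match(segs, am$seg_names)]) *
      am$gravity
    f_ref <- w - if (any(c("link4", "link5") %in% segs) && k <= 4)
      c(12, -30, 7) else c(0, 0, 0)
    expect_lt(max(abs(jr$forces[[jn]][2, ] - f_ref)), 1e-9)
  }
})

test_that("reaction frame rotates into the child body frame on request", {
  am <- assemble(toy_pendulum_model(length = 1, mass = 2))
  t <- seq(0, 0.05, by = 0.01)
  traj <- data.frame(time = t, theta = rep(deg2rad(90), length(t)))
  jr_g <- compute_joint_reactions(am, traj, frame = "ground")
  jr_c <- compute_joint_reactions(am, traj, frame = "child")
  R <- cervidyn:::rot_axis_angle(c(0, 0, 1), deg2rad(90))
  expect_equal(jr_c$forces$pin[1, ],
               as.numeric(t(R) %*% jr_g$forces$pin[1, ]),
               tolerance = 1e-10)
})

test_that("static optimization: single-muscle balance and symmetric split", {
  ## one muscle, torque within capacity -> a = tau / (r Fmax-at-length)
  d <- 0.03
  desc <- list(name = "pin", gravity = c(0, 0, 0),
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
  r_arm <- moment_arm(am, 0, "mu", "q")
  tau_target <- 0.5 * abs(r_arm) * 1000
  t <- c(0, 0.1, 0.2)
  traj <- data.frame(time = t, q = c(0, 0, 0))
  tau <- data.frame(time = t, q = rep(sign(r_arm) * tau_target, 3))
  sol <- static_activation_solve(am, traj, tau, rate_limit = FALSE)
  expect_equal(unname(sol$activations[2, "mu"]), 0.5, tolerance = 1e-4)
  expect_false(any(sol$flagged))

  ## two identical parallel muscles share the load equally
  desc$muscles[[2]] <- desc$muscles[[1]]
  desc$muscles[[2]]$name <- "mu2"
  am2 <- assemble(load_model_description(desc))
  sol2 <- static_activation_solve(am2, traj, tau, rate_limit = FALSE)
  expect_equal(unname(sol2$activations[2, "mu"]),
               unname(sol2$activations[2, "mu2"]), tolerance = 1e-6)
  expect_equal(unname(sol2$activations[2, "mu"]), 0.25, tolerance = 1e-3)

  ## infeasible demand is flagged and absorbed by reserves
  tau_big <- data.frame(time = t, q = rep(sign(r_arm) * 5 * abs(r_arm) *
                                            1000, 3))
  sol3 <- static_activation_solve(am2, traj, tau_big, rate_limit = FALSE)
  expect_true(all(sol3$flagged))
  expect_true(all(sol3$activations[2, ] > 0.99))
})

test_that("static optimization recovers constructed minimum-norm
           activations on a 4-muscle fixture", {
  am <- assemble(toy_neck_model(n_joints = 2, f_max = 600, l_opt = 0.07))
  ## add a second muscle pair with different leverage
  m <- am$model
  m$muscles[[3]] <- m$muscles[[1]]; m$muscles[[3]]$name <- "ant2"
  m$muscles[[3]]$path[[1]]$point <- c(0.06, 0, 0)
  m$muscles[[3]]$path[[2]]$point <- c(0.06, 0.05, 0)
  m$muscles[[4]] <- m$muscles[[2]]; m$muscles[[4]]$name <- "post2"
  m$muscles[[4]]$path[[1]]$point <- c(-0.06, 0, 0)
  m$muscles[[4]]$path[[2]]$point <- c(-0.06, 0.05, 0)
  am <- assemble(m)
  q0 <- default_q(am)
  t <- seq(0, 0.2, by = 0.05)
  traj <- data.frame(time = t, flex1 = 0 * t, flex2 = 0 * t)
  ## ground truth = the minimum-norm solution of the moment balance for
  ## the flexor pair (extensors passive): build tau from it
  nm <- vapply(am$muscles, `[[`, "", "name")
  arms <- vapply(am$muscles, function(mu)
    c(moment_arm(am, q0, mu, "flex1"), moment_arm(am, q0, mu, "flex2")),
    numeric(2))
  fk <- forward_kinematics(am, q0)
  Fcap <- vapply(am$muscles, function(mu) {
    l <- musculotendon_length(am, q0, mu, fk)
    cervidyn:::muscle_tension(am, mu, 1, l, 0) -
      cervidyn:::muscle_tension(am, mu, 0, l, 0)
  }, numeric(1))
  Fpas <- vapply(am$muscles, function(mu) {
    l <- musculotendon_length(am, q0, mu, fk)
    cervidyn:::muscle_tension(am, mu, 0, l, 0)
  }, numeric(1))
  A <- arms * rep(Fcap, each = 2)
  ## pick the flexor-only minimum-norm activation for a target in the
  ## span of the flexor columns
  Af <- A[, c(1, 3)]
  a_truth_f <- c(0.35, 0.21)
  ## project onto the minimum-norm solution of its own induced torque
  tau_vec <- Af %*% a_truth_f
  a_min <- as.numeric(MASS::ginv(Af) %*% tau_vec)
  tau <- data.frame(time = t,
                    flex1 = rep(tau_vec[1] + sum(arms[1, ] * Fpas),
                                length(t)),
                    flex2 = rep(tau_vec[2] + sum(arms[2, ] * Fpas),
                                length(t)))
  sol <- static_activation_solve(am, traj, tau, rate_limit = FALSE)
  got <- sol$activations[3, c("ant", "ant2")]
  expect_lt(sqrt(mean((got - a_min)^2)), 0.05)
  ## extensors stay silent (they would fight the flexion torque)
  expect_lt(max(sol$activations[3, c("post", "post2")]), 0.05)
})

test_that("the sum-of-forces objective is exposed and favours
           strong-leverage muscles", {
  am <- assemble(toy_neck_model(n_joints = 1, f_max = 500, l_opt = 0.04))
  t <- c(0, 0.1)
  traj <- data.frame(time = t, flex1 = c(0, 0))
  r <- moment_arm(am, default_q(am), "ant", "flex1")
  tau <- data.frame(time = t, flex1 = rep(r * 100, 2))
  s1 <- static_activation_solve(am, traj, tau, rate_limit = FALSE)
  s2 <- static_activation_solve(am, traj, tau,
                                objective = "sum_forces",
                                rate_limit = FALSE)
  expect_identical(s1$objective_kind, "sum_squared_activations")
  expect_identical(s2$objective_kind, "sum_forces")
  expect_false(any(s2$flagged))
})

test_that("low-pass filter: DC gain, attenuation and zero-phase symmetry", {
  rate <- 500
  x <- rep(2.5, 1000)
  expect_equal(lowpass_filter(x, rate), x, tolerance = 1e-6)
  ## 2 Hz passes, 50 Hz attenuated by >= 40 dB at the 12 Hz default
  t <- seq(0, 4, by = 1 / rate)
  sig <- sin(2 * pi * 2 * t) + sin(2 * pi * 50 * t)
  y <- lowpass_filter(sig, rate)
  mid <- 300:1700
  amp50 <- function(v) {
    sp <- Mod(fft(v[mid]))
    f <- (seq_along(mid) - 1) * rate / length(mid)
    max(sp[abs(f - 50) < 1])
  }
  expect_lt(amp50(y) / amp50(sig), 10^(-40 / 20))
  ## impulse response is symmetric when bidirectional
  imp <- c(rep(0, 200), 1, rep(0, 200))
  h <- lowpass_filter(imp, rate)
  expect_lt(max(abs(h - rev(h))), 1e-8)
  expect_error(lowpass_filter(x, rate, cutoff = 300), "Nyquist")
})

test_that("EMG envelope: zeros, MVC self-normalization, and correlation
           with the generating activation", {
  rate <- 2000
  expect_equal(emg_envelope(rep(0, 4000), rate, 1), rep(0, 4000))
  expect_error(emg_envelope(rnorm(1000), 1000, 1), "Nyquist")
  expect_error(emg_envelope(rnorm(1000), 2000, 0), "positive")
  ## samples above the MVC reference are reported, not clipped
  mvc1 <- synth_emg(rep(1, 10), duration = 1, rate = rate, seed = 999)
  expect_warning(emg_envelope(mvc1$raw, rate,
                              0.5 * mvc_reference(mvc1$raw, rate)),
                 "exceed the MVC")
  cors <- numeric(0); selfn <- numeric(0)
  for (seed in 1:20) {
    act <- 0.15 + 0.8 * (0.5 - 0.5 * cos(2 * pi * seq(0, 1,
                                                      length.out = 50)))
    syn <- synth_emg(act, duration = 2, rate = rate, seed = seed)
    mvc <- synth_emg(rep(1, 10), duration = 1, rate = rate,
                     seed = 1000 + seed)
    ref <- mvc_reference(mvc$raw, rate)
    env <- suppressWarnings(emg_envelope(syn$raw, rate, ref))
    cors <- c(cors, cor(env, syn$activation_true))
    selfn <- c(selfn,
               mean(suppressWarnings(emg_envelope(mvc$raw, rate, ref))))
  }
  expect_gt(mean(cors), 0.9)
  expect_gt(mean(selfn), 0.9)
  expect_lt(mean(selfn), 1.1)
})
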