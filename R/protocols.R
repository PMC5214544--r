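## Forward-dynamics verification protocols: workless-constraint audit,
## passive range-of-motion loading, and maximal isometric neck moments.

#' Lock or unlock coordinates
#'
#' Returns a copy of the assembled model with the named coordinates locked
#' (held at their defaults during simulation and excluded from the free set)
#' or unlocked. Coupler-driven coordinates cannot be locked.
#'
#' @param am a `cd_assembled`.
#' @param names coordinate names.
#' @return modified `cd_assembled`.
#' @export
lock_coordinates <- function(am, names) {
  ii <- am$coord_index[names]
  if (anyNA(ii)) {
    stop("unknown coordinate(s): ",
         paste(names[is.na(ii)], collapse = ", "), call. = FALSE)
  }
  if (any(am$coords$dependent[ii])) {
    stop("cannot lock coupler-dependent coordinate(s): ",
         paste(names[am$coords$dependent[ii]], collapse = ", "),
         call. = FALSE)
  }
  am$coords$locked[ii] <- TRUE
  am
}

#' @rdname lock_coordinates
#' @export
unlock_coordinates <- function(am, names) {
  ii <- am$coord_index[names]
  if (anyNA(ii)) {
    stop("unknown coordinate(s): ",
         paste(names[is.na(ii)], collapse = ", "), call. = FALSE)
  }
  am$coords$locked[ii] <- FALSE
  am
}

## all-but helper: lock everything independent except `keep`
lock_all_except <- function(am, keep) {
  free_names <- am$coords$name[!am$coords$dependent]
  lock_coordinates(am, setdiff(free_names, keep))
}

#' Workless-constraint power audit
#'
#' For a simulated or prescribed motion, reconstructs the coupler-constraint
#' generalized forces from the full-space inverse-dynamics residual at every
#' sample and reports the power they transmit. For an ideal (workless)
#' coordinate-coupler constraint this power is zero up to numerical
#' round-off: constraint forces are orthogonal to every velocity compatible
#' with the couplings. The trace also reports the scalar product of any
#' external forces with their segment's centre-of-mass velocity (the
#' external-power term of the verification protocol).
#'
#' @param am a `cd_assembled` (with the motion's locked set applied).
#' @param motion a `cd_simulation` from [simulate_model()], or a data.frame
#'   with a `time` column and one column per free coordinate (radians).
#' @param external_loads optional list of constant wrenches
#'   (`list(segment, point, force, torque)`) active during the motion.
#' @return data.frame of class `cd_constraint_power`: `t`,
#'   `power_external_term`, `power_generalized_term`, `total` (W), with
#'   `attr(,"max_abs_total")` and `attr(,"t_at_max")`.
#' @export
constraint_power_audit <- function(am, motion, external_loads = list()) {
  free <- free_coord_idx(am)
  ind <- independent_coord_idx(am)
  if (inherits(motion, "cd_simulation")) {
    t <- motion$time
    qfree <- as.matrix(motion[, 1L + seq_along(free), drop = FALSE])
  } else {
    t <- motion$time
    nms <- am$coords$name[free]
    missing <- setdiff(nms, names(motion))
    if (length(missing)) {
      stop("motion lacks column(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    qfree <- as.matrix(motion[, nms, drop = FALSE])
  }
  n <- length(t)
  if (n < 3L) stop("motion needs at least 3 samples", call. = FALSE)
  ## central differences on the (possibly non-uniform) grid
  dq <- apply(qfree, 2L, function(col) num_deriv(t, col))
  d2q <- apply(dq, 2L, function(col) num_deriv(t, col))

  q0 <- default_q(am)
  out <- data.frame(t = t, power_external_term = 0,
                    power_generalized_term = 0, total = 0)
  max_abs <- 0; t_at <- t[1L]
  for (r in seq_len(n)) {
    q <- q0; q[free] <- qfree[r, ]
    q <- enforce_couplers(am, q)
    G <- coupler_G(am, q)
    Gf <- G[, match(free, ind), drop = FALSE]
    qd_full <- as.numeric(Gf %*% dq[r, ])
    qdd_full <- as.numeric(Gf %*% d2q[r, ]) +
      coupler_cterm(am, q, qd_full)
    res <- rnea(am, q, qd_full, qdd_full, external = external_loads)
    rec <- reconstruct_constraint_forces(am, q, res$tau)
    p_gen <- sum(rec$Q_constraint * qd_full)
    p_ext <- 0
    if (length(external_loads)) {
      for (w in external_loads) {
        if (w$segment == "ground") next
        fkr <- structure(list(q = q, node_R = res$node_R,
                              node_p = res$node_p, node_z = res$node_z),
                         class = "cd_fk")
        Jp <- point_jacobian(am, fkr, w$segment, w$point %||% c(0, 0, 0))
        v <- as.numeric(Jp %*% qd_full)
        p_ext <- p_ext + sum((w$force %||% c(0, 0, 0)) * v)
      }
    }
    tot <- p_gen + p_ext
    out$power_external_term[r] <- p_ext
    out$power_generalized_term[r] <- p_gen
    out$total[r] <- tot
    if (abs(p_gen) > max_abs) { max_abs <- abs(p_gen); t_at <- t[r] }
  }
  attr(out, "max_abs_total") <- max_abs
  attr(out, "t_at_max") <- t_at
  class(out) <- c("cd_constraint_power", class(out))
  out
}

## central differences on a possibly non-uniform grid
num_deriv <- function(t, y) {
  n <- length(t)
  d <- numeric(n)
  d[1L] <- (y[2L] - y[1L]) / (t[2L] - t[1L])
  d[n] <- (y[n] - y[n - 1L]) / (t[n] - t[n - 1L])
  if (n > 2L) {
    d[2:(n - 1L)] <- (y[3:n] - y[1:(n - 2L)]) / (t[3:n] - t[1:(n - 2L)])
  }
  d
}

#' Forward-simulate a humeral elevation sweep
#'
#' Locks every independent coordinate except the elevation coordinate and
#' runs a servo-driven forward simulation tracking a smooth (minimum-jerk)
#' elevation profile; the coupled SC/AC coordinates follow their constraint
#' functions throughout. Used as the motion source for the
#' workless-constraint audit.
#'
#' @param am a `cd_assembled`.
#' @param coordinate elevation coordinate name.
#' @param from,to elevation endpoints (deg).
#' @param duration sweep duration (s).
#' @param dt reporting interval (s).
#' @param kp,kd servo gains (N m/rad, N m s/rad).
#' @return a `cd_simulation` (on the locked model, returned as
#'   `attr(,"model")`).
#' @export
simulate_humeral_elevation <- function(am, coordinate = "humeral_elev_r",
                                       from = 25, to = 135, duration = 10,
                                       dt = 0.05, kp = 300, kd = 60) {
  am2 <- lock_all_except(am, coordinate)
  ci <- am2$coord_index[[coordinate]]
  th0 <- deg2rad(from); th1 <- deg2rad(to)
  ref <- function(t) {
    s <- pmin(pmax(t / duration, 0), 1)
    blend <- 10 * s^3 - 15 * s^4 + 6 * s^5      # minimum-jerk
    dblend <- (30 * s^2 - 60 * s^3 + 30 * s^4) / duration
    list(q = th0 + (th1 - th0) * blend, qd = (th1 - th0) * dblend)
  }
  q0 <- default_q(am2)
  q0[ci] <- th0
  trq <- function(t, q, u) {
    r <- ref(t)
    stats::setNames(kp * (r$q - q[ci]) + kd * (r$qd - u[1L]), coordinate)
  }
  sim <- simulate_model(am2, seq(0, duration, by = dt), q0 = q0,
                        torque_fn = trq)
  attr(sim, "model") <- am2
  sim
}

#' Passive range-of-motion loading protocol
#'
#' Applies a pure moment to the C2 vertebra (or any chosen segment) about a
#' body-frame anatomical axis with all muscle activations at zero, and
#' forward-integrates with viscous damping until quasi-static equilibrium
#' (`max |u| < u_tol` sustained over one settling window). The damping does
#' not shift the equilibrium of the conservative passive system; it only
#' accelerates settling. Per-joint equilibrium angles are reported for the
#' cervical chain.
#'
#' @param am a `cd_assembled`, already locked so only the chain under test
#'   (plus whatever the protocol leaves free) moves; see
#'   [lock_all_except()] usage in the examples.
#' @param movement `"flexion_extension"`, `"lateral_bending"` or
#'   `"axial_rotation"` (selects the body-frame axis: z, x, y).
#' @param moment applied moment magnitude (N m); sign selects direction.
#' @param segment segment receiving the couple (default `"cerv2"`).
#' @param q0 starting configuration (default: model defaults).
#' @param damping viscous damping per coordinate (N m s/rad).
#' @param bushing optional named vector of linear rotational stiffnesses
#'   (N m/rad) pulling coordinates toward their defaults.
#' @param u_tol,settle_window,t_max equilibrium detection: velocity
#'   tolerance (rad/s), sustained window (s), simulation budget (s).
#' @param gravity_compensation apply a constant generalized torque that
#'   balances gravity at the starting posture (default TRUE), emulating the
#'   in vitro situation of a mounted specimen loaded by pure moments: the
#'   reported deflection then isolates the applied moment against the
#'   passive structures. With FALSE the chain additionally sags under
#'   gravity.
#' @param report_joints coordinate names to report (default: all free).
#' @return list of class `cd_passive_rom`: `movement`, `moment`, `angles`
#'   (named, deg), full equilibrium `q` (rad), `t_settle`, `converged`.
#' @export
passive_rom_protocol <- function(am, movement = c("flexion_extension",
                                                  "lateral_bending",
                                                  "axial_rotation"),
                                 moment, segment = "cerv2", q0 = NULL,
                                 damping = 0.5, bushing = NULL,
                                 u_tol = 1e-4, settle_window = 0.5,
                                 t_max = 30, gravity_compensation = TRUE,
                                 report_joints = NULL) {
  movement <- match.arg(movement)
  axis_local <- switch(movement,
                       flexion_extension = c(0, 0, 1),
                       lateral_bending = c(1, 0, 0),
                       axial_rotation = c(0, 1, 0))
  free <- free_coord_idx(am)
  qdef <- default_q(am)
  if (is.null(q0)) q0 <- qdef
  bush_vec <- numeric(am$n_coords)
  if (!is.null(bushing)) {
    bush_vec[am$coord_index[names(bushing)]] <- as.numeric(bushing)
  }
  wrench <- function(t, q) {
    if (moment == 0) return(list())
    fk <- forward_kinematics(am, q, enforce = FALSE)
    ax <- segment_pose(am, fk, segment)$R %*% axis_local
    list(list(segment = segment, point = c(0, 0, 0),
              force = c(0, 0, 0), torque = as.numeric(ax) * moment))
  }
  comp <- numeric(am$n_coords)
  if (gravity_compensation) {
    eom0 <- equations_of_motion(am, q0)
    muscQ0 <- if (length(am$muscles)) {
      as.numeric(crossprod(eom0$G_free,
                           muscle_generalized_forces(am, eom0$q,
                                                     rep(0, length(am$muscles)))$Q))
    } else 0
    ## hold the start posture: cancel gravity net of passive muscle forces
    comp[free] <- eom0$bias - muscQ0
  }
  trq <- function(t, q, u) {
    comp - bush_vec * (q - qdef)
  }
  act0 <- if (length(am$muscles)) rep(0, length(am$muscles)) else NULL

  t_now <- 0; converged <- FALSE
  q_curr <- q0; u_curr <- numeric(length(free))
  n_chunk <- 6L
  while (t_now < t_max) {
    tt <- seq(0, settle_window, length.out = n_chunk)
    sim <- simulate_model(am, tt, q0 = q_curr, u0 = u_curr,
                          torque_fn = trq, wrench_fn = wrench,
                          activation = act0, damping = damping)
    qf <- attr(sim, "q_full")
    last <- nrow(sim)
    u_mat <- as.matrix(sim[, 1L + length(free) + seq_along(free),
                           drop = FALSE])
    q_curr <- qf[last, ]
    u_curr <- as.numeric(u_mat[last, ])
    t_now <- t_now + settle_window
    if (max(abs(u_mat)) < u_tol) { converged <- TRUE; break }
  }
  if (!converged) {
    stop(sprintf(paste0("no quasi-static equilibrium within %g s ",
                        "(max |u| = %.2e rad/s); final state attached"),
                 t_max, max(abs(u_curr))), call. = FALSE)
  }
  if (is.null(report_joints)) report_joints <- am$coords$name[free]
  angles <- rad2deg(q_curr[am$coord_index[report_joints]])
  names(angles) <- report_joints
  structure(list(movement = movement, moment = moment, angles = angles,
                 q = q_curr, t_settle = t_now, converged = converged),
            class = "cd_passive_rom")
}

#' @export
print.cd_passive_rom <- function(x, ...) {
  cat(sprintf("<passive ROM: %s, %.3g N m> settled in %.1f s\n",
              x$movement, x$moment, x$t_settle))
  print(round(x$angles, 3))
  invisible(x)
}

#' Classify agonist and antagonist muscles for a coordinate direction
#'
#' Muscles whose constrained moment arm about the coordinate exceeds 1e-6 m
#' in magnitude are split by moment-arm sign: arms matching the requested
#' direction are agonists, opposing arms antagonists. Muscles below the
#' threshold are excluded from both sets.
#'
#' @param am a `cd_assembled`.
#' @param q full coordinate vector.
#' @param coordinate coordinate name.
#' @param direction +1 or -1 (sign of the moment to be generated).
#' @return list with `agonists`, `antagonists` (names) and `arms` (named
#'   moment arms, m).
#' @export
classify_agonists <- function(am, q, coordinate, direction = 1,
                              constrained = TRUE) {
  stopifnot(direction %in% c(-1, 1))
  arms <- vapply(am$muscles, function(mu)
    moment_arm(am, q, mu, coordinate, constrained = constrained),
    numeric(1L))
  names(arms) <- vapply(am$muscles, `[[`, character(1L), "name")
  crossing <- abs(arms) >= 1e-6
  ag <- names(arms)[crossing & sign(arms) == direction]
  an <- names(arms)[crossing & sign(arms) == -direction]
  list(agonists = ag, antagonists = an, arms = arms)
}

#' Maximal isometric joint moment
#'
#' With the posture fixed, sets agonist activations to 1 and antagonists to
#' 0 and sums moment-arm-weighted muscle tensions about the coordinate
#' (antagonists still contribute their passive force). The net moment equals
#' `sum_i r_i F_i` along the constrained manifold.
#'
#' @inheritParams classify_agonists
#' @param constrained use moment arms along the coupler-constrained manifold
#'   (TRUE, the generalized moment about the coordinate) or the plain
#'   partial-derivative arm at the coordinate's own joint (FALSE, the
#'   physical moment transmitted across that joint, which is what a
#'   dynamometer fixed at the neck base measures).
#' @return list of class `cd_isometric_moment`: `coordinate`, `direction`,
#'   `net_moment` (N m), `agonists`, `antagonists`, per-muscle
#'   `contributions` (N m).
#' @export
max_isometric_moments <- function(am, coordinate, direction = 1, q = NULL,
                                  constrained = TRUE) {
  if (is.null(q)) q <- default_q(am)
  q <- enforce_couplers(am, q)
  cls <- classify_agonists(am, q, coordinate, direction, constrained)
  nm <- vapply(am$muscles, `[[`, character(1L), "name")
  act <- ifelse(nm %in% cls$agonists, 1, 0)
  fk <- forward_kinematics(am, q, enforce = FALSE)
  contrib <- numeric(length(nm)); names(contrib) <- nm
  for (i in seq_along(am$muscles)) {
    mu <- am$muscles[[i]]
    if (!(nm[i] %in% c(cls$agonists, cls$antagonists))) next
    l <- musculotendon_length(am, q, mu, fk)
    f <- muscle_tension(am, mu, act[i], l, 0)
    contrib[i] <- cls$arms[i] * f
  }
  structure(list(coordinate = coordinate, direction = direction,
                 net_moment = sum(contrib),
                 agonists = cls$agonists, antagonists = cls$antagonists,
                 contributions = contrib), class = "cd_isometric_moment")
}

#' @export
print.cd_isometric_moment <- function(x, ...) {
  cat(sprintf("<isometric moment about %s (dir %+d)>: %.2f N m (%d agonists, %d antagonists)\n",
              x$coordinate, x$direction, x$net_moment, length(x$agonists),
              length(x$antagonists)))
  invisible(x)
}

#' Maximal neck capacity of the default full-body model
#'
#' Convenience wrapper mapping anatomical movement names onto the neck
#' master coordinates of the packaged model. Capacity is reported as the
#' physical moment transmitted across the neck-base (T1-C7) joint
#' (`constrained = FALSE`): the quantity a fixed dynamometer measures.
#'
#' @param am assembled default model (optionally strength-scaled).
#' @param movement `"extension"`, `"flexion"`, `"lateral_bending"` or
#'   `"axial_rotation"`.
#' @return `cd_isometric_moment` (net moment magnitude is
#'   `abs(net_moment)`).
#' @export
neck_capacity <- function(am, movement = c("extension", "flexion",
                                           "lateral_bending",
                                           "axial_rotation")) {
  movement <- match.arg(movement)
  spec <- switch(movement,
                 extension = list(coord = "neck_flexion", dir = -1),
                 flexion = list(coord = "neck_flexion", dir = 1),
                 lateral_bending = list(coord = "neck_bending", dir = 1),
                 axial_rotation = list(coord = "neck_rotation", dir = 1))
  max_isometric_moments(am, spec$coord, spec$dir, constrained = FALSE)
}
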