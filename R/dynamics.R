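## Rigid-body dynamics on the expanded node tree.
##
## Inverse dynamics uses a recursive Newton-Euler pass in the ground frame;
## the mass matrix is built column-wise from inverse-dynamics calls (unit
## accelerations, gravity off). Coupler-driven coordinates are eliminated by
## reduction to the independent set; constraint generalized forces are
## reconstructed on demand from the full-space residual.

## Full inverse dynamics: generalized forces required to produce qdd given
## (q, qd). Gravity enters via a fictitious base acceleration so the returned
## vector is M qdd + bias(q, qd) with bias including gravity.
## `external` is a list of wrenches: list(segment, point (local), force
## (ground frame N), torque (ground frame N m)).
## Thin wrapper over the compiled Newton-Euler core; rnea_r() below is the
## plain-R reference implementation used as a cross-check in the test suite.
rnea <- function(am, q, qd, qdd, external = list(), gravity = TRUE,
                 want_kinematics = TRUE) {
  nq <- am$n_coords
  a0 <- if (gravity) -am$gravity else c(0, 0, 0)
  ne <- length(external)
  ext_node <- integer(ne)
  ext_lp <- matrix(0, 3L, ne)
  ext_f <- matrix(0, 3L, ne)
  ext_t <- matrix(0, 3L, ne)
  for (e in seq_len(ne)) {
    w <- external[[e]]
    if (w$segment == "ground") next
    nd <- am$seg_node[[w$segment]]
    if (is.null(nd)) stop("unknown segment '", w$segment, "'", call. = FALSE)
    if (nd == 0L) next
    Rp <- am$seg_Rpost[[w$segment]]; tp <- am$seg_tpost[[w$segment]]
    ext_node[e] <- nd
    ext_lp[, e] <- as.numeric(tp + Rp %*% (w$point %||% c(0, 0, 0)))
    ext_f[, e] <- w$force %||% c(0, 0, 0)
    ext_t[, e] <- w$torque %||% c(0, 0, 0)
  }
  out <- rnea_cpp(am$flat$parent, am$flat$is_rot, am$flat$Rpre, am$flat$tpre,
                  am$flat$axis, am$flat$mass, am$flat$com, am$flat$inertia,
                  as.numeric(q), as.numeric(qd), as.numeric(qdd),
                  as.numeric(a0), ext_node, ext_lp, ext_f, ext_t,
                  want_kinematics)
  out$tau <- as.numeric(out$tau)
  out
}

## Pure-R reference Newton-Euler (identical contract to rnea(); kept as an
## independent oracle and for readability).
rnea_r <- function(am, q, qd, qdd, external = list(), gravity = TRUE) {
  nq <- am$n_coords
  Rn <- vector("list", nq)
  pn <- matrix(0, 3L, max(nq, 1L))
  zn <- matrix(0, 3L, max(nq, 1L))
  wn <- matrix(0, 3L, max(nq, 1L))   # angular velocity
  an <- matrix(0, 3L, max(nq, 1L))   # angular acceleration
  vn <- matrix(0, 3L, max(nq, 1L))   # linear velocity of node origin
  ln <- matrix(0, 3L, max(nq, 1L))   # linear acceleration of node origin
  a0 <- if (gravity) -am$gravity else c(0, 0, 0)

  for (i in seq_len(nq)) {
    pa <- am$node_parent[i]
    if (pa == 0L) {
      Rpar <- diag(3); ppar <- c(0, 0, 0)
      wpar <- c(0, 0, 0); apar <- c(0, 0, 0)
      vpar <- c(0, 0, 0); lpar <- a0
    } else {
      Rpar <- Rn[[pa]]; ppar <- pn[, pa]
      wpar <- wn[, pa]; apar <- an[, pa]
      vpar <- vn[, pa]; lpar <- ln[, pa]
    }
    Ra <- Rpar %*% am$node_Rpre[[i]]
    p_a <- ppar + Rpar %*% am$node_tpre[[i]]
    z <- as.numeric(Ra %*% am$node_axis[[i]])
    if (am$node_type[i] == "rot") {
      Rn[[i]] <- Ra %*% rot_axis_angle(am$node_axis[[i]], q[i])
      pi_ <- as.numeric(p_a)
      d <- pi_ - ppar
      wn[, i] <- wpar + z * qd[i]
      an[, i] <- apar + z * qdd[i] + cross3(wpar, z) * qd[i]
      vn[, i] <- vpar + cross3(wpar, d)
      ln[, i] <- lpar + cross3(apar, d) + cross3(wpar, cross3(wpar, d))
      pn[, i] <- pi_
    } else {
      Rn[[i]] <- Ra
      pi_ <- as.numeric(p_a) + z * q[i]
      d <- pi_ - ppar
      wn[, i] <- wpar
      an[, i] <- apar
      vn[, i] <- vpar + cross3(wpar, d) + z * qd[i]
      ln[, i] <- lpar + cross3(apar, d) + cross3(wpar, cross3(wpar, d)) +
        2 * cross3(wpar, z) * qd[i] + z * qdd[i]
      pn[, i] <- pi_
    }
    zn[, i] <- z
  }

  ## external wrenches grouped by node
  ext_force <- vector("list", nq)
  for (w in external) {
    pw <- list(node = 0L)
    if (w$segment != "ground") {
      nd <- am$seg_node[[w$segment]]
      if (is.null(nd)) stop("unknown segment '", w$segment, "'", call. = FALSE)
      if (nd > 0L) {
        Rp <- am$seg_Rpost[[w$segment]]; tp <- am$seg_tpost[[w$segment]]
        loc_n <- as.numeric(tp + Rp %*% (w$point %||% c(0, 0, 0)))
        p_app <- as.numeric(pn[, nd] + Rn[[nd]] %*% loc_n)
        ext_force[[nd]] <- c(ext_force[[nd]],
                             list(list(p = p_app,
                                       f = w$force %||% c(0, 0, 0),
                                       t = w$torque %||% c(0, 0, 0))))
      }
    }
  }

  ## backward pass
  tau <- numeric(nq)
  fjoint <- matrix(0, 3L, max(nq, 1L))
  njoint <- matrix(0, 3L, max(nq, 1L))
  acom <- matrix(0, 3L, max(nq, 1L))
  children <- vector("list", nq)
  for (i in seq_len(nq)) {
    pa <- am$node_parent[i]
    if (pa > 0L) children[[pa]] <- c(children[[pa]], i)
  }
  for (i in rev(seq_len(nq))) {
    m <- am$node_mass[i]
    r <- as.numeric(Rn[[i]] %*% am$node_com[[i]])
    a_c <- ln[, i] + cross3(an[, i], r) +
      cross3(wn[, i], cross3(wn[, i], r))
    acom[, i] <- a_c
    Iw <- Rn[[i]] %*% am$node_inertia[[i]] %*% t(Rn[[i]])
    Fi <- m * a_c
    Ni <- as.numeric(Iw %*% an[, i]) + cross3(wn[, i],
                                              as.numeric(Iw %*% wn[, i]))
    f <- Fi
    n <- Ni + cross3(r, Fi)
    for (ch in children[[i]]) {
      f <- f + fjoint[, ch]
      n <- n + njoint[, ch] + cross3(pn[, ch] - pn[, i], fjoint[, ch])
    }
    for (w in ext_force[[i]]) {
      f <- f - w$f
      n <- n - cross3(w$p - pn[, i], w$f) - w$t
    }
    fjoint[, i] <- f
    njoint[, i] <- n
    tau[i] <- if (am$node_type[i] == "rot") sum(zn[, i] * n) else
      sum(zn[, i] * f)
  }
  list(tau = tau, fjoint = fjoint, njoint = njoint, acom = acom,
       node_p = pn, node_R = Rn, node_z = zn, node_w = wn, node_v = vn)
}

#' Equations of motion
#'
#' Builds the mass matrix, bias vector (gravity + Coriolis/centrifugal,
#' including coupler-curvature terms) and the generalized applied-force
#' vector, both in the full coordinate space and reduced to the free
#' (independent, unlocked) coordinate set. The reduced mass matrix is
#' symmetric positive definite away from singular configurations.
#'
#' @param am a `cd_assembled`.
#' @param q full coordinate vector (couplers enforced internally).
#' @param qd_free velocities of the free coordinates (default zero).
#' @param applied optional list of external wrenches, each
#'   `list(segment, point, force, torque)` with `point` in the segment frame
#'   and `force`/`torque` in the ground frame.
#' @param coord_torques optional named vector of generalized torques applied
#'   directly to coordinates.
#' @return list with `M` (reduced), `bias` (reduced, so that
#'   `M %*% qdd_free + bias = applied_reduced`), `applied` (reduced),
#'   their full-space counterparts `M_full`, `bias_full`, `applied_full`,
#'   the coupler map `G_free` and the free coordinate indices `free`.
#' @export
equations_of_motion <- function(am, q, qd_free = NULL, applied = list(),
                                coord_torques = NULL) {
  q <- enforce_couplers(am, unname(q))
  free <- free_coord_idx(am)
  nf <- length(free)
  if (is.null(qd_free)) qd_free <- numeric(nf)
  ind <- independent_coord_idx(am)
  G <- coupler_G(am, q)
  Gf <- G[, match(free, ind), drop = FALSE]
  qd_full <- as.numeric(Gf %*% qd_free)
  cterm <- coupler_cterm(am, q, qd_full)

  bias_full <- rnea(am, q, qd_full, cterm, gravity = TRUE,
                    want_kinematics = FALSE)$tau
  zero <- numeric(am$n_coords)
  M_full <- matrix(0, am$n_coords, am$n_coords)
  for (j in seq_len(am$n_coords)) {
    e <- zero; e[j] <- 1
    M_full[, j] <- rnea(am, q, zero, e, gravity = FALSE,
                        want_kinematics = FALSE)$tau
  }
  applied_full <- generalized_applied(am, q, applied, coord_torques)
  M_red <- crossprod(Gf, M_full %*% Gf)
  M_red <- (M_red + t(M_red)) / 2
  if (nf > 0) {
    rc <- tryCatch(rcond(M_red), error = function(e) 0)
    if (!is.finite(rc) || rc < 1e-14) {
      stop("singular reduced mass matrix at q = [",
           paste(signif(q[free], 4), collapse = ", "), "]", call. = FALSE)
    }
  }
  list(M = M_red,
       bias = as.numeric(crossprod(Gf, bias_full)),
       applied = as.numeric(crossprod(Gf, applied_full)),
       M_full = M_full, bias_full = bias_full, applied_full = applied_full,
       G_free = Gf, free = free, q = q)
}

## Generalized forces from wrenches + direct coordinate torques (full space).
generalized_applied <- function(am, q, applied = list(),
                                coord_torques = NULL, fk = NULL) {
  Q <- numeric(am$n_coords)
  if (length(applied)) {
    if (is.null(fk)) fk <- forward_kinematics(am, q, enforce = FALSE)
    for (w in applied) {
      pw <- point_node_world(am, fk, w$segment, w$point %||% c(0, 0, 0))
      Q <- Q + wrench_generalized(am, fk, w$segment, pw$p,
                                  w$force %||% c(0, 0, 0),
                                  w$torque %||% c(0, 0, 0))
    }
  }
  if (!is.null(coord_torques)) {
    if (is.null(names(coord_torques))) {
      Q <- Q + as.numeric(coord_torques)
    } else {
      ii <- am$coord_index[names(coord_torques)]
      Q[ii] <- Q[ii] + as.numeric(coord_torques)
    }
  }
  Q
}

## Reconstruct coupler-constraint generalized forces from the full-space
## residual: lambda per coupler, Q_constraint = A^T lambda where the
## constraint rows are q_dep - f(q_ind) = 0. Processing couplers in reverse
## topological order handles chained couplers (a dependent driving another).
reconstruct_constraint_forces <- function(am, q, residual_full) {
  lam <- numeric(length(am$couplers))
  if (length(am$couplers)) {
    for (k in rev(seq_along(am$couplers))) {
      cp <- am$couplers[[k]]
      extra <- 0
      for (k2 in seq_along(am$couplers)) {
        cp2 <- am$couplers[[k2]]
        if (cp2$ind == cp$dep) extra <- extra + cp2$df(q[cp2$ind]) * lam[k2]
      }
      lam[k] <- residual_full[cp$dep] + extra
    }
  }
  Qc <- numeric(am$n_coords)
  for (k in seq_along(am$couplers)) {
    cp <- am$couplers[[k]]
    Qc[cp$dep] <- Qc[cp$dep] + lam[k]
    Qc[cp$ind] <- Qc[cp$ind] - cp$df(q[cp$ind]) * lam[k]
  }
  list(lambda = lam, Q_constraint = Qc)
}

#' Forward-dynamics simulation
#'
#' Integrates the reduced equations of motion over time with the adaptive
#' integrators of \pkg{deSolve}. Controls are supplied as functions of time
#' and state; coupler-driven coordinates follow their drivers exactly
#' (dependent-coordinate elimination), locked coordinates stay at their
#' defaults.
#'
#' @param am a `cd_assembled`.
#' @param t_span simulation times at which to report the state (s).
#' @param q0 optional full coordinate start (defaults to [default_q()]).
#' @param u0 optional free-coordinate start velocities (default zero).
#' @param torque_fn optional `function(t, q_full, u_free)` returning a named
#'   (or full-length) vector of coordinate torques.
#' @param wrench_fn optional `function(t, q_full)` returning a list of
#'   external wrenches (see [equations_of_motion()]).
#' @param activation optional muscle activation vector (length = number of
#'   muscles) or `function(t)`; enables musculotendon forces.
#' @param damping per-coordinate viscous damping (scalar or full-length
#'   vector, N m s/rad); opposes full-space coordinate velocity.
#' @param method,rtol,atol integrator settings (defaults: `"lsoda"`,
#'   1e-6, 1e-8).
#' @return a data.frame of class `cd_simulation`: time, free coordinates,
#'   free speeds, plus the full enforced coordinate matrix in
#'   `attr(, "q_full")`.
#' @export
simulate_model <- function(am, t_span, q0 = NULL, u0 = NULL,
                           torque_fn = NULL, wrench_fn = NULL,
                           activation = NULL, damping = 0,
                           method = "lsoda", rtol = 1e-6, atol = 1e-8) {
  free <- free_coord_idx(am)
  nf <- length(free)
  if (is.null(q0)) q0 <- default_q(am)
  q0 <- enforce_couplers(am, unname(q0))
  if (is.null(u0)) u0 <- numeric(nf)
  damping <- rep(damping, length.out = am$n_coords)
  ind <- independent_coord_idx(am)
  act_fn <- if (is.null(activation)) NULL else
    if (is.function(activation)) activation else function(t) activation

  deriv <- function(t, y, parms) {
    q <- q0
    q[free] <- y[seq_len(nf)]
    u <- y[nf + seq_len(nf)]
    q <- enforce_couplers(am, q)
    G <- coupler_G(am, q)
    Gf <- G[, match(free, ind), drop = FALSE]
    qd_full <- as.numeric(Gf %*% u)
    cterm <- coupler_cterm(am, q, qd_full)
    b_full <- rnea(am, q, qd_full, cterm, gravity = TRUE,
                   want_kinematics = FALSE)$tau
    Mr <- matrix(0, nf, nf)
    zero <- numeric(am$n_coords)
    for (k in seq_len(nf)) {
      Mr[, k] <- crossprod(Gf, rnea(am, q, zero, Gf[, k], gravity = FALSE,
                                    want_kinematics = FALSE)$tau)
    }
    Mr <- (Mr + t(Mr)) / 2
    fk <- forward_kinematics(am, q, enforce = FALSE)
    Q_full <- numeric(am$n_coords)
    if (!is.null(torque_fn)) {
      Q_full <- Q_full + expand_named_torques(am, torque_fn(t, q, u))
    }
    if (!is.null(wrench_fn)) {
      Q_full <- Q_full + generalized_applied(am, q, wrench_fn(t, q),
                                             NULL, fk = fk)
    }
    if (!is.null(act_fn)) {
      Q_full <- Q_full + muscle_generalized_forces(am, q, act_fn(t),
                                                   fk = fk)$Q
    }
    Q_full <- Q_full - damping * qd_full
    udot <- solve(Mr, as.numeric(crossprod(Gf, Q_full - b_full)))
    list(c(u, udot))
  }

  y0 <- c(q0[free], u0)
  sol <- deSolve::ode(y = y0, times = t_span, func = deriv, parms = NULL,
                      method = method, rtol = rtol, atol = atol)
  out <- as.data.frame(sol)
  names(out) <- c("time", am$coords$name[free],
                  paste0(am$coords$name[free], "_u"))
  qfull <- matrix(rep(q0, each = nrow(out)), nrow = nrow(out))
  colnames(qfull) <- am$coords$name
  for (k in seq_len(nf)) qfull[, free[k]] <- out[[1L + k]]
  for (r in seq_len(nrow(qfull))) {
    qfull[r, ] <- enforce_couplers(am, qfull[r, ])
  }
  attr(out, "q_full") <- qfull
  attr(out, "free") <- free
  class(out) <- c("cd_simulation", class(out))
  out
}

expand_named_torques <- function(am, tq) {
  Q <- numeric(am$n_coords)
  if (is.null(tq)) return(Q)
  if (is.null(names(tq))) {
    if (length(tq) != am$n_coords) {
      stop("unnamed torque vector must have one entry per coordinate",
           call. = FALSE)
    }
    return(as.numeric(tq))
  }
  ii <- am$coord_index[names(tq)]
  Q[ii] <- as.numeric(tq)
  Q
}

#' Total mechanical energy of a configuration
#'
#' Kinetic plus gravitational potential energy; useful as a conservation
#' oracle for unforced simulations.
#'
#' @param am a `cd_assembled`.
#' @param q full coordinate vector.
#' @param qd_full full coordinate velocity vector.
#' @return energy in joules.
#' @export
mechanical_energy <- function(am, q, qd_full) {
  dyn <- rnea(am, q, qd_full, numeric(am$n_coords), gravity = FALSE)
  ke <- 0; pe <- 0
  g <- am$gravity
  for (i in seq_len(am$n_coords)) {
    m <- am$node_mass[i]
    Ri <- matrix(dyn$node_R[, i], 3L, 3L)
    r <- as.numeric(Ri %*% am$node_com[[i]])
    ## COM velocity: v_origin + w x r
    vc <- dyn$node_v[, i] + cross3(dyn$node_w[, i], r)
    Iw <- Ri %*% am$node_inertia[[i]] %*% t(Ri)
    ke <- ke + 0.5 * m * sum(vc^2) +
      0.5 * sum(dyn$node_w[, i] * (Iw %*% dyn$node_w[, i]))
    pe <- pe - m * sum(g * (dyn$node_p[, i] + r))
  }
  ke + pe
}
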