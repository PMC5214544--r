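## Marker-based inverse kinematics, inverse dynamics, joint-reaction
## recursion, and static-optimization activation estimation.

#' Marker trajectory set constructor
#'
#' @param time time vector (s), strictly increasing.
#' @param markers named list of n x 3 matrices (ground frame, m); NA rows are
#'   treated as occluded samples.
#' @param rate sampling rate (Hz); inferred from `time` when omitted.
#' @param weights optional named weights (default 1).
#' @return list of class `cd_markers`.
#' @export
marker_set <- function(time, markers, rate = NULL, weights = NULL) {
  if (is.null(rate)) rate <- 1 / stats::median(diff(time))
  if (rate <= 0) stop("rate must be positive", call. = FALSE)
  structure(list(time = time, markers = markers, rate = rate,
                 weights = weights %||%
                   stats::setNames(rep(1, length(markers)), names(markers))),
            class = "cd_markers")
}

#' Inverse kinematics
#'
#' Per frame, solves the weighted least-squares marker-fit problem
#' `min sum_i w_i || x_i^exp - x_i^model(q) ||^2` over the free coordinates
#' by damped Gauss-Newton with analytic marker Jacobians; coupler-dependent
#' coordinates follow their constraint functions. Frames are warm-started
#' from the previous solution. Frames with fewer than 3 visible markers are
#' flagged and their coordinates cubic-interpolated afterwards up to the gap
#' limit.
#'
#' @param am a `cd_assembled` (scaled to the subject).
#' @param markers a `cd_markers`; names must match the model's virtual
#'   markers.
#' @param q0 starting configuration for the first frame.
#' @param max_iter,tol Gauss-Newton iteration cap and step tolerance.
#' @param gap_limit maximum occlusion gap to interpolate (s).
#' @return data.frame of class `cd_ik_result`: `time`, all model coordinate
#'   columns (radians, couplers enforced), with per-frame RMS marker error
#'   (m) in `attr(,"rms")` and flagged frames in `attr(,"flagged")`.
#' @export
inverse_kinematics <- function(am, markers, q0 = NULL, max_iter = 60L,
                               tol = 1e-12, gap_limit = 0.2) {
  stopifnot(inherits(markers, "cd_markers"))
  model_mk <- am$markers
  mk_names <- vapply(model_mk, `[[`, character(1L), "name")
  use <- intersect(names(markers$markers), mk_names)
  if (length(use) < 3L) {
    stop("need at least 3 markers matching the model's virtual marker set",
         call. = FALSE)
  }
  mk_def <- model_mk[match(use, mk_names)]
  w <- markers$weights[use]
  free <- free_coord_idx(am)
  ind <- independent_coord_idx(am)
  nf <- length(free)
  nT <- length(markers$time)
  qs <- matrix(NA_real_, nT, am$n_coords,
               dimnames = list(NULL, am$coords$name))
  rms <- rep(NA_real_, nT)
  flagged <- logical(nT)
  qdef <- default_q(am)
  q_curr <- if (is.null(q0)) qdef else enforce_couplers(am, q0)
  lo <- am$coords$min[free]; hi <- am$coords$max[free]

  for (r in seq_len(nT)) {
    vis <- vapply(use, function(nm)
      all(is.finite(markers$markers[[nm]][r, ])), logical(1L))
    if (sum(vis) < 3L) { flagged[r] <- TRUE; next }
    tgt <- t(vapply(use[vis], function(nm)
      markers$markers[[nm]][r, ], numeric(3L)))
    defs <- mk_def[vis]
    wv <- sqrt(rep(w[vis], each = 3L))
    x <- q_curr[free]
    lam <- 1e-6
    for (it in seq_len(max_iter)) {
      q <- qdef; q[free] <- x
      q <- enforce_couplers(am, q)
      fk <- forward_kinematics(am, q, enforce = FALSE)
      G <- coupler_G(am, q)
      Gf <- G[, match(free, ind), drop = FALSE]
      res <- numeric(0); J <- NULL
      Jrows <- vector("list", length(defs))
      pred <- vapply(defs, function(d)
        point_world(am, fk, d$segment, d$offset), numeric(3L))
      res <- as.numeric(pred - t(tgt)) * wv
      Jl <- lapply(defs, function(d)
        point_jacobian(am, fk, d$segment, d$offset) %*% Gf)
      J <- do.call(rbind, Jl) * wv
      g <- crossprod(J, res)
      if (max(abs(g)) < 1e-14) break
      H <- crossprod(J)
      step <- tryCatch(-solve(H + lam * diag(nf), g),
                       error = function(e) NULL)
      if (is.null(step)) { lam <- lam * 10; next }
      x_new <- pmin(pmax(x + as.numeric(step), lo), hi)
      if (max(abs(x_new - x)) < tol) { x <- x_new; break }
      x <- x_new
    }
    q <- qdef; q[free] <- x
    q <- enforce_couplers(am, q)
    q_curr <- q
    qs[r, ] <- q
    fk <- forward_kinematics(am, q, enforce = FALSE)
    pred <- vapply(defs, function(d)
      point_world(am, fk, d$segment, d$offset), numeric(3L))
    rms[r] <- sqrt(mean((pred - t(tgt))^2))
  }
  ## interpolate flagged frames up to the gap limit
  if (any(flagged) && any(!flagged)) {
    max_gap <- round(gap_limit * markers$rate)
    runs <- rle(flagged)
    pos <- cumsum(c(1L, runs$lengths))
    for (k in seq_along(runs$values)) {
      if (!runs$values[k] || runs$lengths[k] > max_gap) next
      idx <- pos[k]:(pos[k + 1L] - 1L)
      for (cc in seq_len(ncol(qs))) {
        qs[idx, cc] <- stats::spline(markers$time[!flagged],
                                     qs[!flagged, cc],
                                     xout = markers$time[idx])$y
      }
    }
  }
  out <- data.frame(time = markers$time, qs, check.names = FALSE)
  attr(out, "rms") <- rms
  attr(out, "flagged") <- flagged
  attr(out, "free") <- free
  class(out) <- c("cd_ik_result", class(out))
  out
}

## coerce a coordinate trajectory (cd_ik_result / cd_simulation / df with
## named coordinate columns) into a full q matrix (n x n_coords)
coord_matrix <- function(am, traj) {
  qdef <- default_q(am)
  n <- nrow(traj)
  qs <- matrix(rep(qdef, each = n), n, am$n_coords,
               dimnames = list(NULL, am$coords$name))
  hit <- intersect(colnames(traj), am$coords$name)
  for (nm in hit) qs[, nm] <- traj[[nm]]
  for (r in seq_len(n)) qs[r, ] <- enforce_couplers(am, qs[r, ])
  qs
}

#' Inverse dynamics
#'
#' Computes per-coordinate net generalized moments from a coordinate
#' trajectory and external loads: velocities and accelerations by central
#' differences (apply [lowpass_filter()] to the coordinates beforehand for
#' noisy data), then the reduced Newton-Euler generalized forces
#' `tau = G^T (M qdd + bias - Q_ext)`.
#'
#' @param am a `cd_assembled`.
#' @param traj coordinate trajectory: `cd_ik_result`, `cd_simulation`, or a
#'   data.frame with `time` plus named coordinate columns (radians).
#' @param external_loads optional function `(t, q) -> list of wrenches` or a
#'   constant list of wrenches.
#' @return data.frame of class `cd_id_result`: `time` plus one net-moment
#'   column per free coordinate (N m or N).
#' @export
inverse_dynamics <- function(am, traj, external_loads = NULL) {
  t <- traj$time
  qs <- coord_matrix(am, traj)
  free <- free_coord_idx(am)
  ind <- independent_coord_idx(am)
  qd_i <- apply(qs[, ind, drop = FALSE], 2L, function(y) num_deriv(t, y))
  qdd_i <- apply(qd_i, 2L, function(y) num_deriv(t, y))
  n <- length(t)
  tau <- matrix(0, n, length(free),
                dimnames = list(NULL, am$coords$name[free]))
  for (r in seq_len(n)) {
    q <- qs[r, ]
    G <- coupler_G(am, q)
    Gf <- G[, match(free, ind), drop = FALSE]
    qd_full <- as.numeric(G %*% qd_i[r, ])
    qdd_full <- as.numeric(G %*% qdd_i[r, ]) + coupler_cterm(am, q, qd_full)
    ext <- if (is.null(external_loads)) list() else
      if (is.function(external_loads)) external_loads(t[r], q) else
        external_loads
    full <- rnea(am, q, qd_full, qdd_full, external = ext)$tau
    tau[r, ] <- as.numeric(crossprod(Gf, full))
  }
  out <- data.frame(time = t, tau, check.names = FALSE)
  class(out) <- c("cd_id_result", class(out))
  out
}

#' Joint reaction analysis
#'
#' Leaf-to-root recursion of the segment force balance
#' `R_j = m_j a_j - (sum F_ext + sum F_const + R_(j+1))`, where gravity is
#' among the external forces and `R_(j+1)` collects the reactions from
#' distal segments. Reported reactions are the force exerted by the parent
#' on the child, in the ground frame by default or rotated into the child
#' body frame. When `activations` are omitted muscles contribute nothing
#' (the analysis mode of the published scrummaging study); otherwise muscle
#' path forces enter as external point forces on their segments.
#'
#' @inheritParams inverse_dynamics
#' @param frame `"ground"` or `"child"`.
#' @param activations optional activation vector or n x n_muscles matrix.
#' @param joints joint names to report (default: all).
#' @return list of class `cd_joint_reactions`: `time`, `frame`, `forces`
#'   (named list of n x 3 matrices, N).
#' @export
compute_joint_reactions <- function(am, traj, external_loads = NULL,
                                    frame = c("ground", "child"),
                                    activations = NULL, joints = NULL) {
  frame <- match.arg(frame)
  t <- traj$time
  qs <- coord_matrix(am, traj)
  ind <- independent_coord_idx(am)
  qd_i <- apply(qs[, ind, drop = FALSE], 2L, function(y) num_deriv(t, y))
  qdd_i <- apply(qd_i, 2L, function(y) num_deriv(t, y))
  jdefs <- am$model$joints
  jnames <- vapply(jdefs, `[[`, character(1L), "name")
  if (is.null(joints)) joints <- jnames
  n <- length(t)
  forces <- lapply(joints, function(j) matrix(0, n, 3L))
  names(forces) <- joints
  nm_mu <- length(am$muscles)
  if (!is.null(activations) && is.null(dim(activations))) {
    activations <- matrix(rep(activations, each = n), n, nm_mu)
  }
  for (r in seq_len(n)) {
    q <- qs[r, ]
    G <- coupler_G(am, q)
    qd_full <- as.numeric(G %*% qd_i[r, ])
    qdd_full <- as.numeric(G %*% qdd_i[r, ]) + coupler_cterm(am, q, qd_full)
    ext <- if (is.null(external_loads)) list() else
      if (is.function(external_loads)) external_loads(t[r], q) else
        external_loads
    if (!is.null(activations) && nm_mu) {
      fk <- forward_kinematics(am, q, enforce = FALSE)
      mf <- muscle_point_wrenches(am, fk, activations[r, ])
      ext <- c(ext, mf)
    }
    dyn <- rnea(am, q, qd_full, qdd_full, external = ext)
    fkr <- structure(list(q = q, node_R = dyn$node_R, node_p = dyn$node_p,
                          node_z = dyn$node_z), class = "cd_fk")
    for (jn in joints) {
      jd <- jdefs[[match(jn, jnames)]]
      child <- jd$child
      nd <- am$seg_node[[child]]
      has_nodes <- length(jd$coordinates) > 0L
      if (has_nodes) {
        ## force across the joint = force into its first expanded node
        own <- joint_first_node(am, jd)
        f <- dyn$fjoint[, own]
      } else {
        f <- subtree_inertial_force(am, dyn, child, ext)
      }
      if (frame == "child") {
        ps <- segment_pose(am, fkr, child)
        f <- as.numeric(t(ps$R) %*% f)
      }
      forces[[jn]][r, ] <- f
    }
  }
  structure(list(time = t, frame = frame, forces = forces),
            class = "cd_joint_reactions")
}

## index of the first expanded node belonging to a (non-weld) joint
joint_first_node <- function(am, jdef) {
  child_anchor <- am$seg_node[[jdef$child]]
  parent_anchor <- if (jdef$parent == "ground") 0L else
    am$seg_node[[jdef$parent]]
  chain <- am$ancestors[[child_anchor]]
  own <- setdiff(chain, if (parent_anchor == 0L) integer(0) else
    am$ancestors[[parent_anchor]])
  own[1L]
}

## free-body fallback for weld joints: sum m*a - externals over the subtree
subtree_inertial_force <- function(am, dyn, child, ext) {
  ## collect all segments in the subtree rooted at `child`
  segs <- child
  repeat {
    add <- vapply(am$model$joints, function(j)
      j$parent %in% segs && !(j$child %in% segs), logical(1L))
    if (!any(add)) break
    segs <- c(segs, vapply(am$model$joints[add], `[[`, character(1L),
                           "child"))
  }
  f <- c(0, 0, 0)
  for (s in segs) {
    i <- match(s, am$seg_names)
    m <- am$model$segments$mass[i]
    nd <- am$seg_node[[s]]
    if (nd == 0L || m == 0) next
    ## COM acceleration of this segment (node composite includes gravity
    ## through the base-acceleration trick)
    Rp <- am$seg_Rpost[[s]]; tp <- am$seg_tpost[[s]]
    com_n <- as.numeric(tp + Rp %*% am$model$segments$com[[i]])
    Rn <- matrix(dyn$node_R[, nd], 3L, 3L)
    rr <- as.numeric(Rn %*% com_n)
    a_c <- dyn$node_a[, nd] + cross3(dyn$node_alpha[, nd], rr) +
      cross3(dyn$node_w[, nd], cross3(dyn$node_w[, nd], rr))
    f <- f + m * a_c
  }
  for (w in ext) {
    if (w$segment %in% segs) f <- f - (w$force %||% c(0, 0, 0))
  }
  f
}

## muscle tensions at activations -> list of external point wrenches
muscle_point_wrenches <- function(am, fk, act) {
  out <- list()
  for (i in seq_along(am$muscles)) {
    mu <- am$muscles[[i]]
    l <- musculotendon_length(am, fk$q, mu, fk)
    f <- muscle_tension(am, mu, act[i], l, 0)
    if (f == 0) next
    pts <- vapply(mu$path, function(p)
      point_world(am, fk, p$segment, p$point), numeric(3L))
    np <- ncol(pts)
    for (k in seq_len(np - 1L)) {
      d <- pts[, k + 1L] - pts[, k]
      len <- sqrt(sum(d^2)); if (len < 1e-12) next
      u <- d / len
      out <- c(out,
               list(list(segment = mu$path[[k]]$segment,
                         point = mu$path[[k]]$point, force = f * u),
                    list(segment = mu$path[[k + 1L]]$segment,
                         point = mu$path[[k + 1L]]$point, force = -f * u)))
    }
  }
  out
}

#' Static-optimization activation estimation
#'
#' Per frame, distributes the net joint moments over the muscles by solving
#' a box-constrained convex program: muscle forces are affine in activation
#' at fixed kinematics (rigid tendon, zero fiber velocity), the moment
#' balance per tracked coordinate is enforced through heavily penalized
#' reserve torques, and the objective is either the sum of squared
#' activations or the sum of muscle forces. Activation-rate limits between
#' frames follow first-order activation dynamics with the muscles' time
#' constants.
#'
#' @param am a `cd_assembled`.
#' @param traj coordinate trajectory (as in [inverse_dynamics()]).
#' @param tau a `cd_id_result` (or data.frame `time` + moment columns) for
#'   the tracked coordinates.
#' @param objective `"sum_squared_activations"` (default) or `"sum_forces"`.
#' @param coordinates tracked coordinate names (default: the moment columns
#'   of `tau`).
#' @param reserve_weight quadratic penalty weight on reserve torques.
#' @param rate_limit apply activation-dynamics rate limiting across frames.
#' @return list of class `cd_activation_solution`: `time`, `activations`
#'   (n x n_muscles), `reserves` (n x n_coords), `objective`, `flagged`
#'   (frames where reserves exceed 1e-3 of the moment scale).
#' @export
static_activation_solve <- function(am, traj, tau,
                                    objective = c("sum_squared_activations",
                                                  "sum_forces"),
                                    coordinates = NULL,
                                    reserve_weight = 1e4,
                                    rate_limit = TRUE) {
  objective <- match.arg(objective)
  qs <- coord_matrix(am, traj)
  t <- traj$time
  n <- length(t)
  if (is.null(coordinates)) {
    coordinates <- setdiff(colnames(tau), "time")
  }
  nmu <- length(am$muscles)
  if (!nmu) stop("model has no muscles", call. = FALSE)
  nco <- length(coordinates)
  acts <- matrix(0, n, nmu,
                 dimnames = list(NULL, vapply(am$muscles, `[[`,
                                              character(1L), "name")))
  reserves <- matrix(0, n, nco, dimnames = list(NULL, coordinates))
  objv <- numeric(n)
  flagged <- logical(n)
  a_prev <- rep(0, nmu)
  tau_m <- as.matrix(tau[, coordinates, drop = FALSE])

  for (r in seq_len(n)) {
    q <- qs[r, ]
    fk <- forward_kinematics(am, q, enforce = FALSE)
    Fpas <- numeric(nmu); Fcap <- numeric(nmu)
    for (i in seq_len(nmu)) {
      mu <- am$muscles[[i]]
      l <- musculotendon_length(am, q, mu, fk)
      Fpas[i] <- muscle_tension(am, mu, 0, l, 0)
      Fcap[i] <- muscle_tension(am, mu, 1, l, 0) - Fpas[i]
    }
    Rarm <- matrix(0, nco, nmu)
    for (j in seq_len(nco)) {
      for (i in seq_len(nmu)) {
        Rarm[j, i] <- moment_arm(am, q, am$muscles[[i]], coordinates[j])
      }
    }
    A <- Rarm * rep(Fcap, each = nco)
    b <- tau_m[r, ] - as.numeric(Rarm %*% Fpas)
    lo <- rep(0, nmu); hi <- rep(1, nmu)
    if (rate_limit && r > 1L) {
      dt <- t[r] - t[r - 1L]
      taus_a <- vapply(am$muscles, `[[`, numeric(1L), "tau_act")
      taus_d <- vapply(am$muscles, `[[`, numeric(1L), "tau_deact")
      hi <- pmin(1, 1 + (a_prev - 1) * exp(-dt / taus_a))
      lo <- pmax(0, a_prev * exp(-dt / taus_d))
    }
    w <- reserve_weight
    if (objective == "sum_squared_activations") {
      fn <- function(a) sum(a^2) + w * sum((b - A %*% a)^2)
      gr <- function(a) 2 * a - 2 * w * as.numeric(crossprod(A, b - A %*% a))
    } else {
      fn <- function(a) sum(Fcap * a + Fpas) +
        w * sum((b - A %*% a)^2)
      gr <- function(a) Fcap - 2 * w * as.numeric(crossprod(A, b - A %*% a))
    }
    a0 <- pmin(pmax(a_prev, lo), hi)
    sol <- stats::optim(a0, fn, gr, method = "L-BFGS-B",
                        lower = lo, upper = hi,
                        control = list(maxit = 500L, factr = 1e4))
    a <- sol$par
    resid <- b - as.numeric(A %*% a)
    acts[r, ] <- a
    reserves[r, ] <- resid
    objv[r] <- if (objective == "sum_squared_activations") sum(a^2) else
      sum(Fcap * a + Fpas)
    flagged[r] <- any(abs(resid) > 1e-3 * max(1, max(abs(tau_m[r, ]))))
    a_prev <- a
  }
  structure(list(time = t, activations = acts, reserves = reserves,
                 objective = objv, flagged = flagged,
                 objective_kind = objective),
            class = "cd_activation_solution")
}
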