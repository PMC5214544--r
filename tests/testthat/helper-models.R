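## Shared fixtures and independent oracles for the test suite.

## point-mass double pendulum description (planar, z-axis pins)
double_pendulum_desc <- function(m1 = 1, m2 = 0.7, l1 = 1, l2 = 0.8,
                                 q1 = 60, q2 = -30, coupler_slope = NULL) {
  d <- list(
    name = "dp", gravity = c(0, -9.81, 0),
    segments = list(
      list(name = "l1", mass = m1, com = c(0, -l1, 0),
           inertia = c(0, 0, 0)),
      list(name = "l2", mass = m2, com = c(0, -l2, 0),
           inertia = c(0, 0, 0))),
    joints = list(
      list(name = "j1", parent = "ground", child = "l1",
           coordinates = list(list(name = "q1", axis = c(0, 0, 1),
                                   range = c(-720, 720), default = q1))),
      list(name = "j2", parent = "l1", child = "l2",
           location_in_parent = c(0, -l1, 0),
           coordinates = list(list(name = "q2", axis = c(0, 0, 1),
                                   range = c(-720, 720), default = q2)))))
  if (!is.null(coupler_slope)) {
    d$couplers <- list(list(name = "cp", independent = "q1",
                            dependent = "q2", kind = "linear",
                            slope = coupler_slope, intercept = 0))
  }
  d
}

## independent forward kinematics: homogeneous 4x4 transform composition
## built directly from the description (no package kinematics code)
oracle_fk_chain <- function(desc, q_deg_or_rad) {
  ## q in radians, one entry per coordinate in declaration order
  T <- diag(4)
  rot4 <- function(axis, ang) {
    axis <- axis / sqrt(sum(axis^2))
    K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                  -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
    R <- diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
    out <- diag(4); out[1:3, 1:3] <- R
    out
  }
  tr4 <- function(v) { out <- diag(4); out[1:3, 4] <- v; out }
  poses <- list()
  k <- 0
  for (j in desc$joints) {
    T <- T %*% tr4(j$location_in_parent %||% c(0, 0, 0))
    if (!is.null(j$orientation_in_parent)) {
      o <- j$orientation_in_parent * pi / 180
      T <- T %*% rot4(c(1, 0, 0), o[1]) %*% rot4(c(0, 1, 0), o[2]) %*%
        rot4(c(0, 0, 1), o[3])
    }
    for (co in (j$coordinates %||% list())) {
      k <- k + 1
      if ((co$kind %||% "rotational") == "rotational") {
        T <- T %*% rot4(co$axis, q_deg_or_rad[k])
      } else {
        ax <- co$axis / sqrt(sum(co$axis^2))
        T <- T %*% tr4(ax * q_deg_or_rad[k])
      }
    }
    poses[[j$child]] <- T
  }
  poses
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## default full-body model, cached per test run
the_cache <- new.env()
default_assembled <- function() {
  if (is.null(the_cache$am)) {
    the_cache$am <- assemble(load_model_description(default_model_path()))
  }
  the_cache$am
}

neck_free <- c("neck_flexion", "neck_bending", "neck_rotation",
               "head_flexion", "head_bending", "head_rotation")

## independent subtree free-body oracle for joint reactions: sums
## m_i * (a_i - g) - F_ext over all segments distal to the joint, with
## per-segment COM accelerations from 4th-order central differences of
## package forward kinematics along an analytic trajectory.
oracle_subtree_reaction <- function(am, q_of_t, t, joint, h = 1e-3,
                                    ext = list()) {
  jdefs <- am$model$joints
  jd <- jdefs[[match(joint, vapply(jdefs, `[[`, "", "name"))]]
  segs <- jd$child
  repeat {
    add <- vapply(jdefs, function(j)
      j$parent %in% segs && !(j$child %in% segs), logical(1))
    if (!any(add)) break
    segs <- c(segs, vapply(jdefs[add], `[[`, "", "child"))
  }
  com_pos <- function(tt) {
    fk <- forward_kinematics(am, q_of_t(tt))
    vapply(segs, function(s) {
      i <- match(s, am$seg_names)
      point_world(am, fk, s, am$model$segments$com[[i]])
    }, numeric(3))
  }
  ## 4th-order second derivative: (-p2 + 16 p1 - 30 p0 + 16 m1 - m2)/(12 h^2)
  a <- (-com_pos(t + 2 * h) + 16 * com_pos(t + h) - 30 * com_pos(t) +
          16 * com_pos(t - h) - com_pos(t - 2 * h)) / (12 * h^2)
  f <- c(0, 0, 0)
  for (k in seq_along(segs)) {
    m <- am$model$segments$mass[match(segs[k], am$seg_names)]
    f <- f + m * (a[, k] - am$gravity)
  }
  for (w in ext) {
    if (w$segment %in% segs) f <- f - (w$force %||% c(0, 0, 0))
  }
  f
}

## independent analytic Newton-Euler free-body oracle for single-coordinate
## revolute chains: per-segment kinematics from textbook recursion written
## against the description (not the package's node arrays), reactions from
## subtree sums of m * (a_com - g) minus external forces.
oracle_newton_euler_reaction <- function(desc, q, qd, qdd, joint_k,
                                         gravity = c(0, -9.81, 0),
                                         ext = list()) {
  rotm <- function(u, th) {
    u <- u / sqrt(sum(u^2))
    K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
                byrow = TRUE)
    diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  }
  n <- length(desc$joints)
  R <- diag(3); p <- c(0, 0, 0); w <- c(0, 0, 0); al <- c(0, 0, 0)
  a <- c(0, 0, 0)
  acom <- vector("list", n); mass <- numeric(n)
  cr <- function(x, y) c(x[2] * y[3] - x[3] * y[2],
                         x[3] * y[1] - x[1] * y[3],
                         x[1] * y[2] - x[2] * y[1])
  for (i in seq_len(n)) {
    j <- desc$joints[[i]]
    d <- j$location_in_parent %||% c(0, 0, 0)
    o <- (j$orientation_in_parent %||% c(0, 0, 0)) * pi / 180
    p_new <- p + R %*% d
    Ra <- R %*% rotm(c(1, 0, 0), o[1]) %*% rotm(c(0, 1, 0), o[2]) %*%
      rotm(c(0, 0, 1), o[3])
    u <- j$coordinates[[1]]$axis
    z <- as.numeric(Ra %*% (u / sqrt(sum(u^2))))
    dvec <- as.numeric(p_new) - p
    a_new <- a + cr(al, dvec) + cr(w, cr(w, dvec))
    w_new <- w + z * qd[i]
    al_new <- al + z * qdd[i] + cr(w, z) * qd[i]
    R <- Ra %*% rotm(u, q[i])
    p <- as.numeric(p_new); w <- w_new; al <- al_new; a <- a_new
    seg <- desc$segments[[i]]
    rc <- as.numeric(R %*% seg$com)
    acom[[i]] <- a + cr(al, rc) + cr(w, cr(w, rc))
    mass[i] <- seg$mass
  }
  f <- c(0, 0, 0)
  seg_names <- vapply(desc$segments, `[[`, "", "name")
  for (i in joint_k:n) f <- f + mass[i] * (acom[[i]] - gravity)
  for (wr in ext) {
    k <- match(wr$segment, seg_names)
    if (!is.na(k) && k >= joint_k) f <- f - (wr$force %||% c(0, 0, 0))
  }
  f
}
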