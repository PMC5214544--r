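## Forward kinematics and geometric Jacobians on the assembled node tree.

#' Forward kinematics
#'
#' Computes every segment's pose (position and orientation in the ground
#' frame) by composing joint transforms root to leaf. Coupler-driven
#' coordinates are evaluated from their drivers before composing, so any `q`
#' whose independent entries are valid yields a constraint-consistent pose.
#'
#' @param am a `cd_assembled`.
#' @param q full coordinate vector (length `am$n_coords`, radians / metres).
#' @param enforce evaluate coupler functions before composing (default TRUE).
#' @return an object of class `cd_fk`: per-node rotation/position/world joint
#'   axis arrays plus the enforced `q`. Use [segment_pose()] and
#'   [point_world()] to query it.
#' @export
forward_kinematics <- function(am, q, enforce = TRUE) {
  if (length(q) != am$n_coords) {
    stop("q has length ", length(q), ", model has ", am$n_coords,
         " coordinates", call. = FALSE)
  }
  if (enforce) q <- enforce_couplers(am, unname(q))
  out <- fk_cpp(am$flat$parent, am$flat$is_rot, am$flat$Rpre, am$flat$tpre,
                am$flat$axis, as.numeric(q))
  structure(list(q = q, node_R = out$node_R, node_p = out$node_p,
                 node_z = out$node_z, am_name = am$name),
            class = "cd_fk")
}

## node rotation matrix as 3x3 from the flattened fk store
fk_R <- function(fk, i) matrix(fk$node_R[, i], 3L, 3L)

#' Pose of a segment in the ground frame
#'
#' @param am a `cd_assembled`.
#' @param fk result of [forward_kinematics()].
#' @param segment segment name (or "ground").
#' @return list with rotation matrix `R` (local -> ground) and origin `p`.
#' @export
segment_pose <- function(am, fk, segment) {
  if (segment == "ground") return(list(R = diag(3), p = c(0, 0, 0)))
  nd <- am$seg_node[[segment]]
  if (is.null(nd)) stop("unknown segment '", segment, "'", call. = FALSE)
  Rp <- am$seg_Rpost[[segment]]; tp <- am$seg_tpost[[segment]]
  if (nd == 0L) return(list(R = Rp, p = tp))
  Rn <- fk_R(fk, nd)
  list(R = Rn %*% Rp,
       p = as.numeric(fk$node_p[, nd] + Rn %*% tp))
}

#' Ground-frame position of a point fixed on a segment
#'
#' @inheritParams segment_pose
#' @param local point in the segment's local frame (3-vector, m).
#' @return 3-vector in the ground frame.
#' @export
point_world <- function(am, fk, segment, local) {
  ps <- segment_pose(am, fk, segment)
  as.numeric(ps$p + ps$R %*% local)
}

## node id + world position for a segment-fixed point (internal fast path)
point_node_world <- function(am, fk, segment, local) {
  if (segment == "ground") {
    return(list(node = 0L, p = as.numeric(local)))
  }
  nd <- am$seg_node[[segment]]
  Rp <- am$seg_Rpost[[segment]]; tp <- am$seg_tpost[[segment]]
  loc_n <- as.numeric(tp + Rp %*% local)  # point in node frame
  if (nd == 0L) return(list(node = 0L, p = loc_n))
  list(node = nd,
       p = as.numeric(fk$node_p[, nd] + fk_R(fk, nd) %*% loc_n))
}

#' Jacobian of a segment-fixed point with respect to all coordinates
#'
#' Rows are the ground-frame x/y/z velocity components, columns the full
#' coordinate set (independent and dependent alike); chain through the
#' coupler map `G` to obtain derivatives along the constrained manifold.
#'
#' @inheritParams point_world
#' @return 3 x n_coords matrix `J` with `dp/dt = J %*% qdot_full`.
#' @export
point_jacobian <- function(am, fk, segment, local) {
  J <- matrix(0, 3L, am$n_coords)
  pw <- point_node_world(am, fk, segment, local)
  if (pw$node == 0L) return(J)
  for (j in am$ancestors[[pw$node]]) {
    z <- fk$node_z[, j]
    if (am$node_type[j] == "rot") {
      J[, j] <- cross3(z, pw$p - fk$node_p[, j])
    } else {
      J[, j] <- z
    }
  }
  J
}

## angular-velocity Jacobian of a segment (3 x n_coords)
segment_angular_jacobian <- function(am, fk, segment) {
  J <- matrix(0, 3L, am$n_coords)
  if (segment == "ground") return(J)
  nd <- am$seg_node[[segment]]
  if (nd == 0L) return(J)
  for (j in am$ancestors[[nd]]) {
    if (am$node_type[j] == "rot") J[, j] <- fk$node_z[, j]
  }
  J
}

## Map a wrench applied to a segment (force at world point p_app + couple)
## to generalized forces on the full coordinate set.
wrench_generalized <- function(am, fk, segment, p_app, force,
                               torque = c(0, 0, 0)) {
  Q <- numeric(am$n_coords)
  if (segment == "ground") return(Q)
  nd <- am$seg_node[[segment]]
  if (nd == 0L) return(Q)
  for (j in am$ancestors[[nd]]) {
    z <- fk$node_z[, j]
    if (am$node_type[j] == "rot") {
      Q[j] <- sum(z * (cross3(p_app - fk$node_p[, j], force) + torque))
    } else {
      Q[j] <- sum(z * force)
    }
  }
  Q
}
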