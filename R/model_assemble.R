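## Assembly: turn a loaded description into an indexed kinematic tree.
##
## Internally every coordinate becomes one single-axis "node" (revolute or
## prismatic); multi-coordinate joints expand into a chain of nodes with
## massless intermediates, the last node carrying the child segment's inertia.
## Zero-coordinate (weld) joints fold into fixed transforms and their child
## segment's inertia is composited onto the nearest moving ancestor node.

#' Assemble a loaded model
#'
#' Validates the joint graph (a tree rooted at ground), builds coordinate
#' index maps, flags coupler-driven coordinates, composes fixed transforms and
#' attaches mass properties. Most other functions in the package operate on
#' the assembled form.
#'
#' @param model a `cd_model` from [load_model_description()].
#' @return an object of class `cd_assembled`.
#' @export
assemble <- function(model) {
  stopifnot(inherits(model, "cd_model"))

  ## ---- tree validation -------------------------------------------------
  seg_names <- model$segments$name
  child_of <- vapply(model$joints, `[[`, character(1L), "child")
  parent_of <- vapply(model$joints, `[[`, character(1L), "parent")
  if (length(child_of) && anyDuplicated(child_of)) {
    stop("segment with more than one parent joint: ",
         paste(unique(child_of[duplicated(child_of)]), collapse = ", "),
         call. = FALSE)
  }
  missing_parent <- setdiff(seg_names, child_of)
  if (length(missing_parent)) {
    stop("segment(s) without a parent joint (tree must be rooted at ",
         "ground): ", paste(missing_parent, collapse = ", "), call. = FALSE)
  }
  if ("ground" %in% child_of) {
    stop("ground cannot be the child of a joint", call. = FALSE)
  }
  ## topological order of joints walking out from ground; leftover => cycle
  ordered <- integer(0)
  reached <- "ground"
  remaining <- seq_along(model$joints)
  repeat {
    idx <- remaining[parent_of[remaining] %in% reached]
    if (!length(idx)) break
    ordered <- c(ordered, idx)
    reached <- c(reached, child_of[idx])
    remaining <- setdiff(remaining, idx)
  }
  if (length(remaining)) {
    stop("cyclic or disconnected joint graph involving joint(s): ",
         paste(vapply(model$joints[remaining], `[[`, character(1L), "name"),
               collapse = ", "), call. = FALSE)
  }

  ## ---- coordinate table ------------------------------------------------
  coords <- list()
  for (ji in ordered) {
    j <- model$joints[[ji]]
    for (co in j$coordinates) {
      coords[[length(coords) + 1L]] <- data.frame(
        name = co$name, joint = j$name, kind = co$kind,
        min = co$range[1L], max = co$range[2L], default = co$default,
        locked = co$locked, stringsAsFactors = FALSE)
      if (!(co$range[1L] <= co$default && co$default <= co$range[2L])) {
        stop("coordinate '", co$name, "' default outside its range",
             call. = FALSE)
      }
    }
  }
  coords <- if (length(coords)) do.call(rbind, coords) else
    data.frame(name = character(), joint = character(), kind = character(),
               min = numeric(), max = numeric(), default = numeric(),
               locked = logical())
  nq <- nrow(coords)
  cidx <- seq_len(nq); names(cidx) <- coords$name
  ## locks may also be declared as a top-level name list
  if (length(model$locks)) {
    coords$locked[coords$name %in% model$locks] <- TRUE
  }

  ## ---- couplers: dependency order and callable functions ---------------
  dep_names <- vapply(model$couplers, `[[`, character(1L), "dependent")
  coords$dependent <- coords$name %in% dep_names
  bad <- coords$dependent & coords$locked
  if (any(bad)) {
    stop("coordinate both locked and coupler-dependent: ",
         paste(coords$name[bad], collapse = ", "), call. = FALSE)
  }
  couplers <- lapply(model$couplers, function(cp) {
    out <- list(name = cp$name, kind = cp$kind,
                dep = unname(cidx[[cp$dependent]]),
                ind = unname(cidx[[cp$independent]]),
                valid_range = cp$valid_range, clamp = cp$clamp)
    if (cp$kind == "spline") {
      sf <- stats::splinefun(cp$x, cp$y, method = "natural")
      out$f <- function(x) sf(x)
      out$df <- function(x) sf(x, deriv = 1L)
      out$d2f <- function(x) sf(x, deriv = 2L)
      out$x <- cp$x; out$y <- cp$y
    } else {
      s <- cp$slope; b <- cp$intercept
      out$f <- function(x) s * x + b
      out$df <- function(x) rep(s, length(x))
      out$d2f <- function(x) rep(0, length(x))
      out$slope <- s; out$intercept <- b
    }
    out
  })
  ## order couplers so drivers are evaluated before driven couplers
  if (length(couplers)) {
    dep_idx <- vapply(couplers, `[[`, integer(1L), "dep")
    ind_idx <- vapply(couplers, `[[`, integer(1L), "ind")
    placed <- logical(length(couplers))
    order_cp <- integer(0)
    while (any(!placed)) {
      ready <- which(!placed & !(ind_idx %in% dep_idx[!placed]))
      if (!length(ready)) {
        stop("circular coupler dependency involving: ",
             paste(vapply(couplers[!placed], `[[`, character(1L), "name"),
                   collapse = ", "), call. = FALSE)
      }
      order_cp <- c(order_cp, ready)
      placed[ready] <- TRUE
    }
    couplers <- couplers[order_cp]
  }

  ## ---- node expansion --------------------------------------------------
  ## node arrays (one node per coordinate)
  node_parent <- integer(nq)         # 0 = ground
  node_Rpre <- vector("list", nq)
  node_tpre <- vector("list", nq)
  node_axis <- vector("list", nq)
  node_type <- character(nq)         # "rot" | "trans"
  ## per-segment anchor: node index (0 = ground) + fixed post transform
  seg_node <- integer(length(seg_names)); names(seg_node) <- seg_names
  seg_Rpost <- vector("list", length(seg_names)); names(seg_Rpost) <- seg_names
  seg_tpost <- vector("list", length(seg_names)); names(seg_tpost) <- seg_names

  anchor <- function(seg) {
    if (seg == "ground") {
      list(node = 0L, R = diag(3), t = c(0, 0, 0))
    } else {
      list(node = seg_node[[seg]], R = seg_Rpost[[seg]], t = seg_tpost[[seg]])
    }
  }
  k <- 0L
  for (ji in ordered) {
    j <- model$joints[[ji]]
    pa <- anchor(j$parent)
    ## fixed transform: parent segment frame -> joint frame in parent
    Rp <- pa$R %*% rot_xyz(j$orientation_in_parent)
    tp <- pa$t + pa$R %*% j$location_in_parent
    ncj <- length(j$coordinates)
    if (ncj == 0L) {
      ## weld: child frame = joint frame composed with inverse child offset
      Rc <- rot_xyz(j$orientation_in_child)
      R_post <- Rp %*% t(Rc)
      t_post <- tp - R_post %*% j$location_in_child
      seg_node[[j$child]] <- pa$node
      seg_Rpost[[j$child]] <- R_post
      seg_tpost[[j$child]] <- as.numeric(t_post)
    } else {
      pnode <- pa$node
      Rfix <- Rp; tfix <- tp
      for (ci in seq_len(ncj)) {
        k <- k + 1L
        co <- j$coordinates[[ci]]
        node_parent[k] <- pnode
        node_Rpre[[k]] <- Rfix
        node_tpre[[k]] <- as.numeric(tfix)
        node_axis[[k]] <- co$axis
        node_type[k] <- if (co$kind == "rotational") "rot" else "trans"
        pnode <- k
        Rfix <- diag(3); tfix <- c(0, 0, 0)
      }
      Rc <- rot_xyz(j$orientation_in_child)
      R_post <- t(Rc)
      t_post <- -R_post %*% j$location_in_child
      seg_node[[j$child]] <- k
      seg_Rpost[[j$child]] <- R_post
      seg_tpost[[j$child]] <- as.numeric(t_post)
    }
  }
  stopifnot(k == nq)

  ## ---- attach mass properties to nodes ---------------------------------
  node_mass <- numeric(nq)
  node_com <- vector("list", nq)      # composite COM in node frame
  node_inertia <- vector("list", nq)  # composite inertia about COM, node frame
  for (i in seq_len(nq)) { node_com[[i]] <- c(0, 0, 0)
                           node_inertia[[i]] <- matrix(0, 3, 3) }
  ground_mass_warned <- FALSE
  for (si in seq_along(seg_names)) {
    sn <- seg_names[si]
    m <- model$segments$mass[si]
    if (m == 0 && all(model$segments$inertia[[si]] == 0)) next
    nd <- seg_node[[sn]]
    if (nd == 0L) next  # mass welded to ground never moves
    R <- seg_Rpost[[sn]]; t <- seg_tpost[[sn]]
    com_n <- as.numeric(t + R %*% model$segments$com[[si]])
    I_n <- R %*% diag(model$segments$inertia[[si]], 3) %*% t(R)
    m0 <- node_mass[nd]; c0 <- node_com[[nd]]
    mtot <- m0 + m
    cnew <- if (mtot > 0) (m0 * c0 + m * com_n) / mtot else c0
    shift <- function(I, m, d) I + m * (sum(d^2) * diag(3) - outer(d, d))
    node_inertia[[nd]] <- shift(node_inertia[[nd]], m0, c0 - cnew) +
      shift(I_n, m, com_n - cnew)
    node_com[[nd]] <- cnew
    node_mass[nd] <- mtot
  }

  ## ancestor chains (root -> node), used by Jacobians
  ancestors <- vector("list", nq)
  for (i in seq_len(nq)) {
    chain <- integer(0); a <- i
    while (a != 0L) { chain <- c(a, chain); a <- node_parent[a] }
    ancestors[[i]] <- chain
  }

  ## muscles / markers resolved to indices
  muscles <- lapply(model$muscles, function(mu) {
    mu$path <- lapply(mu$path, function(p) {
      p$seg_id <- match(p$segment, seg_names)  # NA for ground
      p
    })
    mu
  })

  ## flattened muscle-path arrays for the compiled kernel: per path point,
  ## the anchoring node and the point's position in that node's frame
  npts_total <- sum(vapply(muscles, function(mu) length(mu$path), 1L))
  mp_node <- integer(npts_total)
  mp_local <- matrix(0, 3L, max(npts_total, 1L))
  mu_ptr <- integer(length(muscles) + 1L)
  mu_ptr[1L] <- 1L
  pk <- 0L
  for (mi in seq_along(muscles)) {
    for (p in muscles[[mi]]$path) {
      pk <- pk + 1L
      if (p$segment == "ground") {
        mp_node[pk] <- 0L
        mp_local[, pk] <- p$point
      } else {
        mp_node[pk] <- seg_node[[p$segment]]
        mp_local[, pk] <- as.numeric(seg_tpost[[p$segment]] +
                                       seg_Rpost[[p$segment]] %*% p$point)
      }
    }
    mu_ptr[mi + 1L] <- pk + 1L
  }
  mflat <- list(pt_node = mp_node, pt_local = mp_local, mu_ptr = mu_ptr,
                f_max = vapply(muscles, `[[`, numeric(1L), "f_max"),
                l_opt = vapply(muscles, `[[`, numeric(1L), "l_opt"),
                l_slack = vapply(muscles, `[[`, numeric(1L), "l_slack"),
                penn = vapply(muscles, `[[`, numeric(1L), "pennation"))

  ## flattened arrays for the compiled kinematics/dynamics core
  flat <- list(
    parent = as.integer(node_parent),
    is_rot = as.integer(node_type == "rot"),
    Rpre = if (nq) vapply(node_Rpre, as.numeric, numeric(9L)) else
      matrix(0, 9L, 0L),
    tpre = if (nq) vapply(node_tpre, as.numeric, numeric(3L)) else
      matrix(0, 3L, 0L),
    axis = if (nq) vapply(node_axis, as.numeric, numeric(3L)) else
      matrix(0, 3L, 0L),
    mass = node_mass,
    com = if (nq) vapply(node_com, as.numeric, numeric(3L)) else
      matrix(0, 3L, 0L),
    inertia = if (nq) vapply(node_inertia, as.numeric, numeric(9L)) else
      matrix(0, 9L, 0L))
  if (nq) {
    flat$Rpre <- matrix(flat$Rpre, 9L, nq)
    flat$tpre <- matrix(flat$tpre, 3L, nq)
    flat$axis <- matrix(flat$axis, 3L, nq)
    flat$com <- matrix(flat$com, 3L, nq)
    flat$inertia <- matrix(flat$inertia, 9L, nq)
  }

  am <- structure(list(
    name = model$name,
    flat = flat,
    mflat = mflat,
    gravity = model$gravity,
    model = model,
    coords = coords,
    coord_index = cidx,
    couplers = couplers,
    n_coords = nq,
    node_parent = node_parent,
    node_Rpre = node_Rpre,
    node_tpre = node_tpre,
    node_axis = node_axis,
    node_type = node_type,
    node_mass = node_mass,
    node_com = node_com,
    node_inertia = node_inertia,
    ancestors = ancestors,
    seg_names = seg_names,
    seg_node = seg_node,
    seg_Rpost = seg_Rpost,
    seg_tpost = seg_tpost,
    muscles = muscles,
    markers = model$markers,
    actuators = model$actuators,
    locks = model$locks
  ), class = "cd_assembled")
  am
}

#' @export
print.cd_assembled <- function(x, ...) {
  a <- audit_degrees_of_freedom(x)
  cat("<cd_assembled> ", x$name, "\n", sep = "")
  cat(sprintf("  %d segments, %d joints, %d coordinates (%d independent, %d constraints)\n",
              a$n_segments, a$n_joints, a$n_coordinates, a$n_independent,
              a$n_constraints))
  cat(sprintf("  %d independent after locks; %d muscles in %d groups; %d torque actuators\n",
              a$n_independent_after_locks, a$n_muscles, a$n_muscle_groups,
              a$n_torque_actuators))
  invisible(x)
}

#' Structural audit of an assembled model
#'
#' Counts segments (including ground, the tree root), joints, coordinates,
#' coupler constraints, independent coordinates before and after locks,
#' muscles, muscle groups and torque actuators. The identities
#' `n_independent = n_coordinates - n_constraints` and
#' `n_independent_after_locks = n_independent - (# locked independent
#' coordinates)` hold by construction.
#'
#' @param am a `cd_assembled`.
#' @return a list of class `cd_dof_audit` with the counts.
#' @export
#' @examples
#' am <- assemble(load_model_description(default_model_path()))
#' audit_degrees_of_freedom(am)
audit_degrees_of_freedom <- function(am) {
  stopifnot(inherits(am, "cd_assembled"))
  co <- am$coords
  n_constraints <- length(am$couplers)
  n_independent <- nrow(co) - n_constraints
  locked_indep <- sum(co$locked & !co$dependent)
  structure(list(
    n_segments = length(am$seg_names) + 1L,  # + ground root
    n_joints = length(am$model$joints),
    n_coordinates = nrow(co),
    n_constraints = n_constraints,
    n_independent = n_independent,
    n_independent_after_locks = n_independent - locked_indep,
    n_muscles = length(am$muscles),
    n_muscle_groups = length(unique(vapply(am$muscles, `[[`, character(1L),
                                           "group"))),
    n_torque_actuators = length(am$actuators)
  ), class = "cd_dof_audit")
}

#' @export
print.cd_dof_audit <- function(x, ...) {
  cat("Model structural audit\n")
  for (nm in names(x)) cat(sprintf("  %-26s %d\n", nm, x[[nm]]))
  invisible(x)
}

#' Coordinate names and default configuration
#'
#' @param am a `cd_assembled`.
#' @return `coordinate_names()`: character vector; `default_q()`: named
#'   numeric vector of coordinate defaults with coupler-driven entries
#'   evaluated from their drivers.
#' @export
coordinate_names <- function(am) am$coords$name

#' @rdname coordinate_names
#' @export
default_q <- function(am) {
  q <- am$coords$default
  names(q) <- am$coords$name
  enforce_couplers(am, q)
}

#' Indices of free (independent, unlocked) coordinates
#' @keywords internal
free_coord_idx <- function(am) {
  which(!am$coords$dependent & !am$coords$locked)
}

independent_coord_idx <- function(am) which(!am$coords$dependent)

#' Evaluate coupler constraints, overwriting dependent coordinates
#'
#' @param am a `cd_assembled`.
#' @param q full coordinate vector.
#' @return `q` with every coupler-driven entry replaced by its coupling
#'   function evaluated at the driver's current value.
#' @export
enforce_couplers <- function(am, q) {
  for (cp in am$couplers) {
    x <- q[cp$ind]
    if (x < cp$valid_range[1L] || x > cp$valid_range[2L]) {
      if (cp$clamp) {
        x <- min(max(x, cp$valid_range[1L]), cp$valid_range[2L])
      }
      ## outside range without clamp: natural-spline linear extension is used
      ## by simulation internals; evaluate_sc_coupling() errors at the API
    }
    q[cp$dep] <- cp$f(x)
  }
  q
}

## Velocity map G (n_coords x n_independent): qdot_full = G %*% qdot_ind,
## columns ordered as independent_coord_idx(am).
coupler_G <- function(am, q) {
  ind <- independent_coord_idx(am)
  nq <- am$n_coords
  G <- matrix(0, nq, length(ind))
  G[cbind(ind, seq_along(ind))] <- 1
  for (cp in am$couplers) {
    G[cp$dep, ] <- cp$df(q[cp$ind]) * G[cp$ind, ]
  }
  G
}

## Acceleration offset c (length n_coords): qddot_full = G qddot_ind + c,
## where c collects coupling-function curvature terms f'' * qdot_ind^2.
coupler_cterm <- function(am, q, qd_full) {
  cvec <- numeric(am$n_coords)
  for (cp in am$couplers) {
    x <- q[cp$ind]
    cvec[cp$dep] <- cp$df(x) * cvec[cp$ind] + cp$d2f(x) * qd_full[cp$ind]^2
  }
  cvec
}

## Expand independent-velocity vector to the full coordinate space.
expand_qd <- function(am, q, qd_ind) {
  as.numeric(coupler_G(am, q) %*% qd_ind)
}
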