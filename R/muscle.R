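## Hill-type muscle-tendon units: path geometry, moment arms, force
## generation, activation dynamics, and population strength scaling.
##
## The tendon is rigid by default: fiber length follows from path length
## minus tendon slack under a constant-thickness pennation assumption.

the_hill_cache <- new.env(parent = emptyenv())

#' Hill curve shape constants
#'
#' Reads the packaged curve-constant table (one value per row) so the
#' force-length / force-velocity formulas are reproducible from a single data
#' file: `fl_width` (active force-length bell width), `fp_kpe` / `fp_e0`
#' (passive exponential shape and strain at one normalized force),
#' `fv_af` (concentric curvature), `fv_flen` (eccentric plateau),
#' `fv_gamma_ecc` (eccentric curvature) and `vmax_norm` (maximum shortening
#' velocity in optimal fiber lengths per second).
#'
#' @return named list of constants.
#' @export
hill_constants <- function() {
  if (is.null(the_hill_cache$k)) {
    path <- system.file("extdata", "hill_constants.tsv", package = "cervidyn",
                        mustWork = TRUE)
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    the_hill_cache$k <- stats::setNames(as.list(tab$value), tab$constant)
  }
  the_hill_cache$k
}

#' Normalized Hill curves
#'
#' `fl_active`: Gaussian bell centred at normalized fiber length 1.
#' `fl_passive`: zero at and below optimal length, exponential above.
#' `fv_curve`: Hill hyperbola for shortening (negative velocities), smooth
#' saturating branch for lengthening, bounded in `[0, fv_flen]`.
#'
#' @param lnorm fiber length / optimal fiber length.
#' @param vnorm fiber velocity / (vmax_norm * optimal fiber length), negative
#'   when shortening.
#' @return numeric vector of normalized force multipliers.
#' @export
fl_active <- function(lnorm) {
  k <- hill_constants()
  exp(-((lnorm - 1) / k$fl_width)^2)
}

#' @rdname fl_active
#' @export
fl_passive <- function(lnorm) {
  k <- hill_constants()
  ifelse(lnorm <= 1, 0,
         (exp(k$fp_kpe * (lnorm - 1) / k$fp_e0) - 1) / (exp(k$fp_kpe) - 1))
}

#' @rdname fl_active
#' @export
fv_curve <- function(vnorm) {
  k <- hill_constants()
  out <- numeric(length(vnorm))
  sh <- vnorm < 0
  vs <- pmax(vnorm[sh], -1)
  out[sh] <- (1 + vs) / (1 - vs / k$fv_af)
  vl <- vnorm[!sh] / k$fv_gamma_ecc
  out[!sh] <- (k$fv_flen * vl + 1) / (vl + 1)
  pmax(out, 0)
}

#' Musculotendon path length
#'
#' Sum of straight-line distances between consecutive path points in the
#' ground frame (no wrapping surfaces).
#'
#' @param am a `cd_assembled`.
#' @param q full coordinate vector.
#' @param mtu a muscle (index, name, or muscle list entry).
#' @param fk optional precomputed [forward_kinematics()] result.
#' @return length in metres.
#' @export
musculotendon_length <- function(am, q, mtu, fk = NULL) {
  mu <- resolve_muscle(am, mtu)
  if (is.null(fk)) fk <- forward_kinematics(am, q)
  pts <- vapply(mu$path, function(p)
    point_world(am, fk, p$segment, p$point), numeric(3L))
  sum(sqrt(rowSums(matrix(diff(t(pts)), ncol = 3L)^2)))
}

resolve_muscle <- function(am, mtu) {
  if (is.list(mtu)) return(mtu)
  if (is.character(mtu)) {
    i <- match(mtu, vapply(am$muscles, `[[`, character(1L), "name"))
    if (is.na(i)) stop("unknown muscle '", mtu, "'", call. = FALSE)
    return(am$muscles[[i]])
  }
  am$muscles[[mtu]]
}

#' Muscle moment arm about a coordinate
#'
#' Tendon-excursion definition: minus the derivative of musculotendon length
#' with respect to the coordinate, evaluated by central finite difference
#' (default step 1e-6 rad). With `method = "effective_torque"` the moment arm
#' is instead computed as the generalized force produced by a unit tendon
#' tension along the path (the Effective Torque Method); the two methods
#' agree to numerical precision and the test-suite asserts agreement to
#' 1e-8 m on posture grids.
#'
#' When the coordinate drives coupler-dependent coordinates (or is itself a
#' driver), `constrained = TRUE` (default) differentiates along the
#' constrained manifold, i.e. dependent coordinates follow their couplers.
#'
#' @inheritParams musculotendon_length
#' @param coordinate coordinate name.
#' @param method `"tendon_excursion"` (default) or `"effective_torque"`.
#' @param constrained follow coupler constraints while differentiating.
#' @param h finite-difference step (rad).
#' @return moment arm in metres; 0 if the path does not cross the coordinate.
#' @export
moment_arm <- function(am, q, mtu, coordinate,
                       method = c("tendon_excursion", "effective_torque"),
                       constrained = TRUE, h = 1e-6) {
  method <- match.arg(method)
  ci <- am$coord_index[[coordinate]]
  if (is.null(ci) || is.na(ci)) {
    stop("unknown coordinate '", coordinate, "'", call. = FALSE)
  }
  if (am$coords$kind[ci] != "rotational") {
    stop("moment arms are defined for rotational coordinates", call. = FALSE)
  }
  mu <- resolve_muscle(am, mtu)
  if (method == "tendon_excursion") {
    qp <- q; qm <- q
    qp[ci] <- q[ci] + h
    qm[ci] <- q[ci] - h
    if (constrained) {
      qp <- enforce_couplers(am, qp)
      qm <- enforce_couplers(am, qm)
      fkp <- forward_kinematics(am, qp, enforce = FALSE)
      fkm <- forward_kinematics(am, qm, enforce = FALSE)
    } else {
      fkp <- forward_kinematics(am, qp, enforce = FALSE)
      fkm <- forward_kinematics(am, qm, enforce = FALSE)
    }
    -(musculotendon_length(am, qp, mu, fkp) -
        musculotendon_length(am, qm, mu, fkm)) / (2 * h)
  } else {
    q <- enforce_couplers(am, q)
    fk <- forward_kinematics(am, q, enforce = FALSE)
    Q <- path_generalized_force(am, fk, mu, tension = 1)
    if (constrained && am$coords$dependent[ci]) {
      stop("effective-torque moment arm about a dependent coordinate is ",
           "ambiguous under constraints; use constrained = FALSE",
           call. = FALSE)
    }
    if (constrained) {
      G <- coupler_G(am, q)
      ind <- independent_coord_idx(am)
      as.numeric(crossprod(G[, match(ci, ind), drop = FALSE], Q))
    } else {
      Q[ci]
    }
  }
}

## Generalized force (full space) of a unit/given tension along a muscle path.
path_generalized_force <- function(am, fk, mu, tension = 1) {
  Q <- numeric(am$n_coords)
  np <- length(mu$path)
  pts <- vapply(mu$path, function(p)
    point_world(am, fk, p$segment, p$point), numeric(3L))
  for (k in seq_len(np - 1L)) {
    a <- pts[, k]; b <- pts[, k + 1L]
    d <- b - a; len <- sqrt(sum(d^2))
    if (len < 1e-12) next
    u <- d / len
    Q <- Q + wrench_generalized(am, fk, mu$path[[k]]$segment, a, tension * u)
    Q <- Q + wrench_generalized(am, fk, mu$path[[k + 1L]]$segment, b,
                                -tension * u)
  }
  Q
}

#' Hill-type muscle force
#'
#' `force = f_max * (a * fl_active(lnorm) * fv(vnorm) + fl_passive(lnorm)) *
#' cos(pennation)`, with pennation at the current fiber length under the
#' constant-thickness assumption.
#'
#' @param mtu muscle list entry (needs `f_max`, `l_opt`, `pennation`).
#' @param activation activation in `[0, 1]`.
#' @param fiber_length fiber length (m), must be positive.
#' @param fiber_velocity fiber velocity (m/s), negative when shortening.
#' @return tendon-direction force in newtons.
#' @export
muscle_force <- function(mtu, activation, fiber_length, fiber_velocity = 0) {
  if (any(activation < 0 | activation > 1)) {
    stop("activation must lie in [0, 1]", call. = FALSE)
  }
  if (any(fiber_length <= 0)) {
    stop("fiber length must be positive", call. = FALSE)
  }
  k <- hill_constants()
  lnorm <- fiber_length / mtu$l_opt
  vnorm <- fiber_velocity / (k$vmax_norm * mtu$l_opt)
  sin_a <- sin(mtu$pennation) * mtu$l_opt / fiber_length
  sin_a <- pmin(pmax(sin_a, 0), 1)
  cos_a <- sqrt(1 - sin_a^2)
  mtu$f_max * (activation * fl_active(lnorm) * fv_curve(vnorm) +
                 fl_passive(lnorm)) * cos_a
}

## Fiber length from musculotendon length under the rigid-tendon,
## constant-thickness pennation assumption.
fiber_length_rigid <- function(mtu, l_mt) {
  l_along <- pmax(l_mt - mtu$l_slack, 1e-6)
  h <- mtu$l_opt * sin(mtu$pennation)
  sqrt(l_along^2 + h^2)
}

## Tendon-direction tension of one muscle at (q, qd) for a given activation.
muscle_tension <- function(am, mu, a, l_mt, v_mt = 0) {
  lf <- fiber_length_rigid(mu, l_mt)
  cos_a <- pmax((l_mt - mu$l_slack) / lf, 1e-9)
  vf <- v_mt * cos_a
  muscle_force(mu, a, lf, vf)
}

## Generalized forces of all muscles at activations `act` (full space).
## Returns Q plus per-muscle tensions and musculotendon lengths. The zero
## fiber-velocity case runs through the compiled kernel; the plain-R path
## (also used when fiber velocities are requested) doubles as its oracle.
muscle_generalized_forces <- function(am, q, act, fk = NULL,
                                      qd_full = NULL) {
  nm <- length(am$muscles)
  if (!nm) {
    return(list(Q = numeric(am$n_coords), tension = numeric(0),
                l_mt = numeric(0)))
  }
  if (is.null(qd_full)) {
    k <- hill_constants()
    out <- muscle_q_cpp(am$flat$parent, am$flat$is_rot, am$flat$Rpre,
                        am$flat$tpre, am$flat$axis, as.numeric(q),
                        am$mflat$pt_node, am$mflat$pt_local,
                        am$mflat$mu_ptr, am$mflat$f_max, am$mflat$l_opt,
                        am$mflat$l_slack, am$mflat$penn,
                        rep(as.numeric(act), length.out = nm),
                        c(k$fl_width, k$fp_kpe, k$fp_e0))
    return(list(Q = as.numeric(out$Q), tension = as.numeric(out$tension),
                l_mt = as.numeric(out$l_mt)))
  }
  muscle_generalized_forces_r(am, q, act, fk = fk, qd_full = qd_full)
}

muscle_generalized_forces_r <- function(am, q, act, fk = NULL,
                                        qd_full = NULL) {
  nm <- length(am$muscles)
  Q <- numeric(am$n_coords)
  tension <- numeric(nm)
  lmt <- numeric(nm)
  if (!nm) return(list(Q = Q, tension = tension, l_mt = lmt))
  act <- rep(act, length.out = nm)
  if (is.null(fk)) fk <- forward_kinematics(am, q)
  for (i in seq_len(nm)) {
    mu <- am$muscles[[i]]
    pts <- vapply(mu$path, function(p)
      point_world(am, fk, p$segment, p$point), numeric(3L))
    segl <- sqrt(rowSums(matrix(diff(t(pts)), ncol = 3L)^2))
    l <- sum(segl)
    v <- 0
    if (!is.null(qd_full)) {
      ## ldot = sum over path segments of u . (v_b - v_a)
      for (k in seq_along(segl)) {
        if (segl[k] < 1e-12) next
        u <- (pts[, k + 1L] - pts[, k]) / segl[k]
        Ja <- point_jacobian(am, fk, mu$path[[k]]$segment, mu$path[[k]]$point)
        Jb <- point_jacobian(am, fk, mu$path[[k + 1L]]$segment,
                             mu$path[[k + 1L]]$point)
        v <- v + sum(u * as.numeric((Jb - Ja) %*% qd_full))
      }
    }
    f <- muscle_tension(am, mu, act[i], l, v)
    tension[i] <- f
    lmt[i] <- l
    if (f != 0) Q <- Q + path_generalized_force(am, fk, mu, f)
  }
  list(Q = Q, tension = tension, l_mt = lmt)
}

#' One step of first-order activation dynamics
#'
#' Exact exponential update toward the excitation with time constant
#' `tau_act` when excitation exceeds the current activation and `tau_deact`
#' otherwise; the result is clipped to `[0, 1]`.
#'
#' @param a current activation in `[0, 1]`.
#' @param excitation neural excitation in `[0, 1]`.
#' @param dt time step (s), positive.
#' @param tau_act,tau_deact activation / deactivation time constants (s).
#' @return updated activation.
#' @export
activation_step <- function(a, excitation, dt, tau_act = 0.010,
                            tau_deact = 0.040) {
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  if (any(a < 0 | a > 1) || any(excitation < 0 | excitation > 1)) {
    stop("activation and excitation must lie in [0, 1]", call. = FALSE)
  }
  tau <- ifelse(excitation > a, tau_act, tau_deact)
  out <- excitation + (a - excitation) * exp(-dt / tau)
  pmin(pmax(out, 0), 1)
}

#' Population strength-scaling factor
#'
#' Ratio of in vivo maximal neck strength to the baseline model's maximal
#' moment-generating capacity, rounded to one decimal (the printed precision
#' of the published factors).
#'
#' @param in_vivo_strength measured maximal moment (N m), positive.
#' @param baseline_capacity baseline model capacity (N m), positive.
#' @return dimensionless factor.
#' @export
#' @examples
#' compute_scaling_factor(51, 34.1)  # healthy-male extensors -> 1.5
#' compute_scaling_factor(61, 22.6)  # rugby flexors (lateral bending) -> 2.7
compute_scaling_factor <- function(in_vivo_strength, baseline_capacity) {
  if (in_vivo_strength <= 0 || baseline_capacity <= 0) {
    stop("strength and capacity must be positive", call. = FALSE)
  }
  round(in_vivo_strength / baseline_capacity, 1L)
}

#' Strength-scaling parameter sets
#'
#' Constructs the extensor/flexor scaling factors for a population from the
#' published in vivo strength and baseline-capacity pairs: healthy males
#' (extensors 51/34.1 N m, flexors matched through lateral bending 32/22.6)
#' and front-row rugby players (66/34.1 and 61/22.6). Factors are recomputed
#' from the provenance pairs with [compute_scaling_factor()].
#'
#' @param population `"MASI"` (healthy male) or `"Rugby"`.
#' @return list of class `cd_strength_scaling` with `extensor_factor`,
#'   `flexor_factor`, `population` and the provenance pairs.
#' @export
strength_scaling <- function(population = c("MASI", "Rugby")) {
  population <- match.arg(population)
  prov <- if (population == "MASI") {
    list(extensor = c(in_vivo = 51, baseline = 34.1),
         flexor = c(in_vivo = 32, baseline = 22.6))
  } else {
    list(extensor = c(in_vivo = 66, baseline = 34.1),
         flexor = c(in_vivo = 61, baseline = 22.6))
  }
  structure(list(
    population = population,
    extensor_factor = compute_scaling_factor(prov$extensor[["in_vivo"]],
                                             prov$extensor[["baseline"]]),
    flexor_factor = compute_scaling_factor(prov$flexor[["in_vivo"]],
                                           prov$flexor[["baseline"]]),
    provenance = prov), class = "cd_strength_scaling")
}

#' @export
print.cd_strength_scaling <- function(x, ...) {
  cat(sprintf("<strength scaling: %s>  extensors x%.1f, flexors x%.1f\n",
              x$population, x$extensor_factor, x$flexor_factor))
  invisible(x)
}

#' Apply strength scaling to a model's muscles
#'
#' Multiplies every muscle's maximum isometric force by the factor of its
#' flexor/extensor classification (muscles whose primary action is lateral
#' bending or axial rotation carry the factor of their tagged class). All
#' other parameters are untouched, so moment arms are preserved exactly.
#' Re-applying a scaling to an already scaled model is refused.
#'
#' @param am a `cd_assembled`.
#' @param scaling a `cd_strength_scaling` (or list with `extensor_factor`,
#'   `flexor_factor`).
#' @return the scaled model.
#' @export
apply_strength_scaling <- function(am, scaling) {
  if (!is.null(am$strength_scaled)) {
    stop("model already strength-scaled (", am$strength_scaled,
         "); scaling twice would compound the factors", call. = FALSE)
  }
  acts <- vapply(am$muscles, function(mu)
    as.character(mu$action %||% NA_character_), character(1L))
  bad <- !(acts %in% c("flexor", "extensor"))
  if (any(bad)) {
    stop("muscles without a flexor/extensor tag: ",
         paste(vapply(am$muscles[bad], `[[`, character(1L), "name"),
               collapse = ", "), call. = FALSE)
  }
  for (i in seq_along(am$muscles)) {
    f <- if (acts[i] == "extensor") scaling$extensor_factor else
      scaling$flexor_factor
    am$muscles[[i]]$f_max <- am$muscles[[i]]$f_max * f
  }
  ## keep the compiled kernel's flattened parameters in step
  am$mflat$f_max <- vapply(am$muscles, `[[`, numeric(1L), "f_max")
  am$strength_scaled <- scaling$population %||% "custom"
  am
}
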