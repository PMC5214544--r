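## Population inertial parameter sets and marker-based linear scaling.

#' Build a population inertial parameter set
#'
#' Reads the packaged per-segment mass-fraction table for a population and
#' converts it to absolute segment masses for a given total body mass
#' (`mass = fraction * total_mass / 100`). The front-row rugby set
#' additionally carries principal moments of inertia, consumed verbatim from
#' the published table. Fractions for bilateral segments are per-side (the
#' printed fractions sum to ~100% of body mass only when paired segments are
#' counted twice).
#'
#' @param population `"MASI"` (baseline healthy male) or `"Rugby"`.
#' @param total_mass total body mass in kg, positive.
#' @return data.frame of class `cd_inertial_set`: `segment`, `mass_pct`,
#'   `bilateral`, `mass` (kg) and, for the rugby set, `Ixx`, `Iyy`, `Izz`
#'   (kg m^2); `attr(, "total_mass")` records the requested mass.
#' @export
#' @examples
#' set <- build_inertial_set("Rugby", 120.4)
#' set$mass[set$segment == "HEAD"]  # 4.1% of 120.4 kg
build_inertial_set <- function(population = c("MASI", "Rugby"), total_mass) {
  population <- tryCatch(match.arg(population),
                         error = function(e)
                           stop("unknown population tag '", population[1L],
                                "'", call. = FALSE))
  if (!is.numeric(total_mass) || total_mass <= 0) {
    stop("total_mass must be positive", call. = FALSE)
  }
  fname <- if (population == "MASI") "inertial_masi.tsv" else
    "inertial_rugby.tsv"
  tab <- utils::read.table(system.file("extdata", fname,
                                       package = "cervidyn", mustWork = TRUE),
                           header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  tab$mass <- tab$mass_pct * total_mass / 100
  attr(tab, "total_mass") <- total_mass
  attr(tab, "population") <- population
  class(tab) <- c("cd_inertial_set", class(tab))
  tab
}

## Map the table's segment labels onto default-model segment names.
inertial_segment_map <- function() {
  list(HEAD = "head", JAW = "jaw", TORSO = "torso",
       CERV1 = "cerv1", CERV2 = "cerv2", CERV3 = "cerv3", CERV4 = "cerv4",
       CERV5 = "cerv5", CERV6 = "cerv6", CERV7 = "cerv7",
       PELVIS = "pelvis",
       SCAPULA = c("scapula_r", "scapula_l"),
       CLAV = c("clavicle_r", "clavicle_l"),
       FEMUR = c("femur_r", "femur_l"), TIBIA = c("tibia_r", "tibia_l"),
       TALLUS = c("talus_r", "talus_l"),
       CALCANEUS = c("calcaneus_r", "calcaneus_l"),
       TOES = c("toes_r", "toes_l"),
       HUMERUS = c("humerus_r", "humerus_l"),
       ULNA = c("ulna_r", "ulna_l"), RADIUS = c("radius_r", "radius_l"),
       HAND = c("hand_r", "hand_l"))
}

#' Apply an inertial parameter set to a model
#'
#' Replaces segment masses (and, when the set carries them, principal
#' inertias) with the population values. Bilateral rows apply per side. With
#' `normalize = TRUE` (default) masses are rescaled by the set's effective
#' fraction sum so the model total equals the requested total body mass
#' exactly.
#'
#' @param model a `cd_model` or `cd_assembled`.
#' @param set a `cd_inertial_set` from [build_inertial_set()].
#' @param normalize rescale masses to land the requested total exactly.
#' @return model of the same class with updated mass properties.
#' @export
apply_inertial_set <- function(model, set, normalize = TRUE) {
  was_assembled <- inherits(model, "cd_assembled")
  m <- if (was_assembled) model$model else model
  map <- inertial_segment_map()
  eff_sum <- sum(set$mass_pct * ifelse(set$bilateral == 1, 2, 1))
  corr <- if (normalize) 100 / eff_sum else 1
  for (k in seq_len(nrow(set))) {
    targets <- map[[set$segment[k]]]
    if (is.null(targets)) next
    for (tg in targets) {
      i <- match(tg, m$segments$name)
      if (is.na(i)) next
      m$segments$mass[i] <- set$mass[k] * corr
      if (!is.null(set$Ixx)) {
        m$segments$inertia[[i]] <- c(set$Ixx[k], set$Iyy[k], set$Izz[k])
      }
    }
  }
  if (was_assembled) {
    out <- assemble(m)
    out$strength_scaled <- model$strength_scaled
    out$muscles <- model$muscles  # preserve any strength scaling
    out$mflat$f_max <- vapply(out$muscles, `[[`, numeric(1L), "f_max")
    out$mflat$l_opt <- vapply(out$muscles, `[[`, numeric(1L), "l_opt")
    out$mflat$l_slack <- vapply(out$muscles, `[[`, numeric(1L), "l_slack")
    out$mflat$penn <- vapply(out$muscles, `[[`, numeric(1L), "pennation")
    out
  } else {
    m
  }
}

#' Per-segment scale factors from marker-pair distances
#'
#' Computes isotropic per-segment scale factors as the ratio of experimental
#' to model virtual-marker distances.
#'
#' @param pairs data.frame with columns `segment`, `model_distance`,
#'   `experimental_distance` (m); several rows per segment are averaged.
#' @return data.frame of class `cd_scale_set` with `segment`, `sx`, `sy`,
#'   `sz`.
#' @export
scale_set_from_markers <- function(pairs) {
  if (any(pairs$model_distance <= 0)) {
    stop("zero or negative model-marker distance for segment(s): ",
         paste(unique(pairs$segment[pairs$model_distance <= 0]),
               collapse = ", "), call. = FALSE)
  }
  ratio <- pairs$experimental_distance / pairs$model_distance
  agg <- tapply(ratio, pairs$segment, mean)
  out <- data.frame(segment = names(agg), sx = as.numeric(agg),
                    sy = as.numeric(agg), sz = as.numeric(agg),
                    stringsAsFactors = FALSE)
  class(out) <- c("cd_scale_set", class(out))
  out
}

#' Linearly scale a model to a subject
#'
#' Scales segment geometry per axis: joint frame locations (by the parent
#' and child segment's factors respectively), centres of mass, muscle path
#' points and marker offsets (by their segment's factors). Muscle optimal
#' fiber and tendon slack lengths scale by the ratio of scaled to unscaled
#' default-posture path length. Inertia components scale as
#' `mass_ratio * (s_a^2 + s_b^2) / 2` over the two axes they gyrate about;
#' masses scale by `mass_ratio` (default 1). Segments without a row in
#' `scales` keep factor 1. An all-ones scale set is an exact no-op.
#'
#' @param model a `cd_model` or `cd_assembled`.
#' @param scales a `cd_scale_set` (columns `segment`, `sx`, `sy`, `sz`) or a
#'   data.frame of marker pairs accepted by [scale_set_from_markers()].
#' @param mass_ratio overall subject-to-model mass ratio applied to all
#'   segment masses.
#' @return model of the same class, rescaled.
#' @export
linear_scale <- function(model, scales, mass_ratio = 1) {
  was_assembled <- inherits(model, "cd_assembled")
  m <- if (was_assembled) model$model else model
  if (!inherits(scales, "cd_scale_set")) {
    if (all(c("segment", "model_distance", "experimental_distance")
            %in% names(scales))) {
      scales <- scale_set_from_markers(scales)
    } else {
      stopifnot(all(c("segment", "sx", "sy", "sz") %in% names(scales)))
    }
  }
  if (any(scales$sx <= 0 | scales$sy <= 0 | scales$sz <= 0)) {
    stop("scale factors must be positive", call. = FALSE)
  }
  sfac <- function(seg) {
    i <- match(seg, scales$segment)
    if (is.na(i)) c(1, 1, 1) else
      as.numeric(c(scales$sx[i], scales$sy[i], scales$sz[i]))
  }
  ref_len <- if (length(m$muscles)) {
    am0 <- if (was_assembled) model else assemble(m)
    q0 <- default_q(am0)
    fk0 <- forward_kinematics(am0, q0)
    vapply(am0$muscles, function(mu)
      musculotendon_length(am0, q0, mu, fk0), numeric(1L))
  } else numeric(0)

  for (i in seq_len(nrow(m$segments))) {
    s <- sfac(m$segments$name[i])
    m$segments$com[[i]] <- m$segments$com[[i]] * s
    I <- m$segments$inertia[[i]]
    m$segments$inertia[[i]] <- mass_ratio * c(
      I[1L] * (s[2L]^2 + s[3L]^2) / 2,
      I[2L] * (s[1L]^2 + s[3L]^2) / 2,
      I[3L] * (s[1L]^2 + s[2L]^2) / 2)
    m$segments$mass[i] <- m$segments$mass[i] * mass_ratio
  }
  m$joints <- lapply(m$joints, function(j) {
    j$location_in_parent <- j$location_in_parent * sfac(j$parent)
    j$location_in_child <- j$location_in_child * sfac(j$child)
    j
  })
  m$muscles <- lapply(m$muscles, function(mu) {
    mu$path <- lapply(mu$path, function(p) {
      p$point <- p$point * sfac(p$segment)
      p
    })
    mu
  })
  m$markers <- lapply(m$markers, function(mk) {
    mk$offset <- mk$offset * sfac(mk$segment)
    mk
  })
  if (length(ref_len)) {
    am1 <- assemble(m)
    q1 <- default_q(am1)
    fk1 <- forward_kinematics(am1, q1)
    for (k in seq_along(m$muscles)) {
      new_len <- musculotendon_length(am1, q1, am1$muscles[[k]], fk1)
      r <- new_len / ref_len[k]
      m$muscles[[k]]$l_opt <- m$muscles[[k]]$l_opt * r
      m$muscles[[k]]$l_slack <- m$muscles[[k]]$l_slack * r
    }
  }
  if (was_assembled) assemble(m) else m
}
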