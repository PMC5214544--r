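## Model description loading and validation.
##
## A model description is a hierarchical config (YAML on disk, equivalently a
## nested R list) with sections: segments, joints, couplers, muscles,
## actuators, locks, markers, inertial_sets. Angles in the description are in
## degrees (I/O boundary); everything is converted to SI radians on read.

#' Load a hierarchical model description
#'
#' Reads a model description from a YAML file, a YAML string, or an already
#' parsed nested list, validates every cross-reference (segment names used by
#' joints, coordinate names used by couplers, locks and actuators; segment
#' names used by muscle path points and markers) and returns an unassembled
#' model object.
#'
#' @param document path to a YAML file, a single YAML string containing a
#'   newline, or a nested list with the same structure.
#' @return an object of class `cd_model`.
#' @seealso [assemble()], [default_model_path()]
#' @export
#' @examples
#' m <- load_model_description(default_model_path())
#' m
load_model_description <- function(document) {
  if (is.character(document) && length(document) == 1L) {
    if (grepl("\n", document)) {
      cfg <- yaml::yaml.load(document)
      base_dir <- "."
    } else {
      if (!file.exists(document)) {
        stop("model description file not found: ", document, call. = FALSE)
      }
      cfg <- yaml::read_yaml(document)
      base_dir <- dirname(document)
    }
  } else if (is.list(document)) {
    cfg <- document
    base_dir <- "."
  } else {
    stop("`document` must be a file path, a YAML string or a list",
         call. = FALSE)
  }
  model <- normalize_model_config(cfg, base_dir)
  validate_model_refs(model)
  model
}

## Turn the raw config into typed internal tables. Degrees -> radians here.
normalize_model_config <- function(cfg, base_dir) {
  need <- function(x, field, where) {
    if (is.null(x[[field]])) {
      stop("missing field '", field, "' in ", where, call. = FALSE)
    }
    x[[field]]
  }
  num3 <- function(x, where) {
    x <- as.numeric(x)
    if (length(x) != 3L || anyNA(x)) {
      stop("expected a numeric 3-vector in ", where, call. = FALSE)
    }
    x
  }

  segs <- cfg$segments
  if (is.null(segs) || length(segs) == 0L) {
    stop("model description declares no segments", call. = FALSE)
  }
  seg_names <- vapply(segs, function(s) as.character(need(s, "name", "segment")),
                      character(1L))
  if (anyDuplicated(seg_names)) {
    stop("duplicate segment name: ",
         paste(unique(seg_names[duplicated(seg_names)]), collapse = ", "),
         call. = FALSE)
  }
  segments <- data.frame(
    name = seg_names,
    mass = vapply(segs, function(s) as.numeric(s$mass %||% 0), numeric(1L)),
    stringsAsFactors = FALSE)
  segments$com <- lapply(segs, function(s) num3(s$com %||% c(0, 0, 0), s$name))
  segments$inertia <- lapply(segs, function(s)
    num3(s$inertia %||% c(0, 0, 0), s$name))
  for (i in seq_len(nrow(segments))) {
    check_segment_inertia(segments$name[i], segments$mass[i],
                          segments$inertia[[i]])
  }

  joints <- lapply(cfg$joints %||% list(), function(j) {
    jn <- as.character(need(j, "name", "joint"))
    coords <- lapply(j$coordinates %||% list(), function(co) {
      kind <- match.arg(co$kind %||% "rotational",
                        c("rotational", "translational"))
      rot <- kind == "rotational"
      conv <- if (rot) deg2rad else identity
      rng <- conv(as.numeric(co$range %||% if (rot) c(-180, 180) else c(-2, 2)))
      axis <- num3(co$axis %||% c(0, 0, 1), paste0("coordinate ", co$name))
      axis <- axis / sqrt(sum(axis^2))
      list(name = as.character(need(co, "name", paste0("joint ", jn))),
           kind = kind,
           axis = axis,
           range = rng,
           default = conv(as.numeric(co$default %||% 0)),
           locked = isTRUE(co$locked))
    })
    list(name = jn,
         parent = as.character(need(j, "parent", paste0("joint ", jn))),
         child = as.character(need(j, "child", paste0("joint ", jn))),
         location_in_parent = num3(j$location_in_parent %||% c(0, 0, 0), jn),
         orientation_in_parent = deg2rad(num3(j$orientation_in_parent %||%
                                                c(0, 0, 0), jn)),
         location_in_child = num3(j$location_in_child %||% c(0, 0, 0), jn),
         orientation_in_child = deg2rad(num3(j$orientation_in_child %||%
                                               c(0, 0, 0), jn)),
         coordinates = coords)
  })
  jnames <- vapply(joints, `[[`, character(1L), "name")
  if (anyDuplicated(jnames)) {
    stop("duplicate joint name: ",
         paste(unique(jnames[duplicated(jnames)]), collapse = ", "),
         call. = FALSE)
  }

  couplers <- lapply(cfg$couplers %||% list(), function(cp) {
    kind <- match.arg(need(cp, "kind", "coupler"), c("spline", "linear"))
    out <- list(name = as.character(cp$name %||%
                                      paste0(cp$dependent, "_coupler")),
                independent = as.character(need(cp, "independent", "coupler")),
                dependent = as.character(need(cp, "dependent", "coupler")),
                kind = kind)
    if (kind == "spline") {
      if (!is.null(cp$file)) {
        tab <- utils::read.table(file.path(base_dir, cp$file), header = TRUE)
        x <- tab[[1L]]; y <- tab[[2L]]
      } else {
        ## knots_x/knots_y aliases avoid the YAML 1.1 boolean "y" key
        x <- as.numeric(cp$x %||% need(cp, "knots_x", "spline coupler"))
        y <- as.numeric(cp$y %||% need(cp, "knots_y", "spline coupler"))
      }
      if (length(x) != length(y) || length(x) < 2L) {
        stop("spline coupler '", out$name,
             "' needs matching x/y knot vectors (>= 2 knots)", call. = FALSE)
      }
      if (any(diff(x) <= 0)) {
        stop("spline coupler '", out$name,
             "' knots must be strictly increasing", call. = FALSE)
      }
      ## knots declared in degrees for rotational couplings
      out$x <- deg2rad(x); out$y <- deg2rad(y)
      out$valid_range <- range(out$x)
    } else {
      out$slope <- as.numeric(need(cp, "slope", "linear coupler"))
      out$intercept <- deg2rad(as.numeric(need(cp, "intercept",
                                               "linear coupler")))
      out$valid_range <- c(-Inf, Inf)
    }
    out$clamp <- isTRUE(cp$clamp)
    out
  })

  muscles <- lapply(cfg$muscles %||% list(), function(mu) {
    nm <- as.character(need(mu, "name", "muscle"))
    pts <- lapply(need(mu, "path", paste0("muscle ", nm)), function(p) {
      list(segment = as.character(need(p, "segment", paste0("muscle ", nm))),
           point = num3(need(p, "point", paste0("muscle ", nm)), nm))
    })
    if (length(pts) < 2L) {
      stop("muscle '", nm, "' needs at least 2 path points", call. = FALSE)
    }
    f_max <- as.numeric(need(mu, "f_max", paste0("muscle ", nm)))
    l_opt <- as.numeric(need(mu, "l_opt", paste0("muscle ", nm)))
    if (f_max <= 0 || l_opt <= 0) {
      stop("muscle '", nm, "' needs positive f_max and l_opt", call. = FALSE)
    }
    list(name = nm,
         group = as.character(mu$group %||% nm),
         action = match.arg(mu$action %||% "extensor",
                            c("flexor", "extensor")),
         primary = as.character(mu$primary %||% "sagittal"),
         path = pts,
         f_max = f_max,
         l_opt = l_opt,
         l_slack = as.numeric(mu$l_slack %||% 0),
         pennation = deg2rad(as.numeric(mu$pennation %||% 0)),
         tau_act = as.numeric(mu$tau_act %||% 0.010),
         tau_deact = as.numeric(mu$tau_deact %||% 0.040))
  })
  mnames <- vapply(muscles, `[[`, character(1L), "name")
  if (anyDuplicated(mnames)) {
    stop("duplicate muscle name: ",
         paste(unique(mnames[duplicated(mnames)]), collapse = ", "),
         call. = FALSE)
  }

  markers <- lapply(cfg$markers %||% list(), function(mk) {
    list(name = as.character(need(mk, "name", "marker")),
         segment = as.character(need(mk, "segment", "marker")),
         offset = num3(mk$offset %||% c(0, 0, 0), mk$name),
         weight = as.numeric(mk$weight %||% 1))
  })

  structure(list(
    name = as.character(cfg$name %||% "model"),
    gravity = as.numeric(cfg$gravity %||% c(0, -9.81, 0)),
    segments = segments,
    joints = joints,
    couplers = couplers,
    muscles = muscles,
    markers = markers,
    actuators = as.character(unlist(cfg$actuators %||% character())),
    locks = as.character(unlist(cfg$locks %||% character())),
    config = cfg
  ), class = "cd_model")
}

check_segment_inertia <- function(name, mass, inertia, rtol = 1e-9) {
  if (mass < 0) stop("segment '", name, "' has negative mass", call. = FALSE)
  if (any(inertia < 0)) {
    stop("segment '", name, "' has a negative principal inertia",
         call. = FALSE)
  }
  s <- sum(inertia)
  tol <- rtol * max(s, 1e-30)
  for (k in 1:3) {
    if (s - inertia[k] < inertia[k] - tol) {
      stop("segment '", name, "' violates the principal-inertia triangle ",
           "inequality", call. = FALSE)
    }
  }
  invisible(TRUE)
}

validate_model_refs <- function(model) {
  seg_names <- c("ground", model$segments$name)
  for (j in model$joints) {
    for (side in c("parent", "child")) {
      if (!(j[[side]] %in% seg_names)) {
        stop("joint '", j$name, "' references unknown segment '", j[[side]],
             "'", call. = FALSE)
      }
    }
  }
  coord_names <- unlist(lapply(model$joints, function(j)
    vapply(j$coordinates, `[[`, character(1L), "name")))
  if (anyDuplicated(coord_names)) {
    stop("duplicate coordinate name: ",
         paste(unique(coord_names[duplicated(coord_names)]), collapse = ", "),
         call. = FALSE)
  }
  for (cp in model$couplers) {
    for (side in c("independent", "dependent")) {
      if (!(cp[[side]] %in% coord_names)) {
        stop("coupler '", cp$name, "' references unknown coordinate '",
             cp[[side]], "'", call. = FALSE)
      }
    }
    if (cp$independent == cp$dependent) {
      stop("coupler '", cp$name, "' couples coordinate '", cp$dependent,
           "' to itself", call. = FALSE)
    }
  }
  dep_names <- vapply(model$couplers, `[[`, character(1L), "dependent")
  if (anyDuplicated(dep_names)) {
    stop("coordinate driven by more than one coupler: ",
         paste(unique(dep_names[duplicated(dep_names)]), collapse = ", "),
         call. = FALSE)
  }
  for (nm in model$locks) {
    if (!(nm %in% coord_names)) {
      stop("lock references unknown coordinate '", nm, "'", call. = FALSE)
    }
  }
  for (nm in model$actuators) {
    if (!(nm %in% coord_names)) {
      stop("actuator references unknown coordinate '", nm, "'", call. = FALSE)
    }
  }
  for (mu in model$muscles) {
    for (p in mu$path) {
      if (!(p$segment %in% seg_names)) {
        stop("muscle '", mu$name, "' references unknown segment '",
             p$segment, "'", call. = FALSE)
      }
    }
  }
  for (mk in model$markers) {
    if (!(mk$segment %in% seg_names)) {
      stop("marker '", mk$name, "' references unknown segment '",
           mk$segment, "'", call. = FALSE)
    }
  }
  invisible(model)
}

#' @export
print.cd_model <- function(x, ...) {
  cat("<cd_model> ", x$name, "\n", sep = "")
  cat("  segments: ", nrow(x$segments), " (+ ground)\n", sep = "")
  cat("  joints:   ", length(x$joints), "\n", sep = "")
  cat("  couplers: ", length(x$couplers), "\n", sep = "")
  cat("  muscles:  ", length(x$muscles), "\n", sep = "")
  cat("  markers:  ", length(x$markers), "\n", sep = "")
  invisible(x)
}

#' Serialize a model description to JSON and back
#'
#' The JSON rendering round-trips losslessly with the YAML form: loading the
#' JSON yields a model with identical structure and numeric content.
#'
#' @param model a `cd_model`.
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @return `model_to_json`: JSON string (invisibly when written to a file);
#'   `model_from_json`: a `cd_model`.
#' @export
model_to_json <- function(model, path = NULL) {
  stopifnot(inherits(model, "cd_model"))
  js <- jsonlite::toJSON(model$config, auto_unbox = TRUE, digits = NA,
                         null = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' @rdname model_to_json
#' @param json JSON string or path to a JSON file.
#' @export
model_from_json <- function(json) {
  if (length(json) == 1L && file.exists(json)) {
    cfg <- jsonlite::read_json(json, simplifyVector = TRUE,
                               simplifyDataFrame = FALSE,
                               simplifyMatrix = FALSE)
  } else {
    cfg <- jsonlite::fromJSON(paste(json, collapse = "\n"),
                              simplifyVector = TRUE,
                              simplifyDataFrame = FALSE,
                              simplifyMatrix = FALSE)
  }
  load_model_description(cfg)
}

#' Path to the packaged default full-body model description
#'
#' The packaged description encodes the full-body structure: 35 segments
#' (counting ground), 34 joints, 73 coordinates of which 30 are
#' coupler-driven, 78 neck muscle-tendon units in 19 groups, 23 coordinate
#' torque actuators, and lockable wrist/metatarsophalangeal coordinates.
#'
#' @return file path of the YAML description.
#' @export
default_model_path <- function() {
  system.file("extdata", "masi_model.yaml", package = "cervidyn",
              mustWork = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
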