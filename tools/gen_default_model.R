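## Generates inst/extdata/masi_model.yaml: the packaged default full-body
## model description. Run from the package root:
##   Rscript tools/gen_default_model.R
## Two-pass: build geometry, assemble, set muscle l_opt / l_slack from
## neutral path lengths, calibrate group maximal forces so the baseline
## (unscaled) neck capacities match the source head-neck model's printed
## maxima (extension 34.1 N m, lateral bending 22.6 N m), then emit YAML.

suppressMessages(pkgload::load_all(".", quiet = TRUE))

num <- function(x) {
  s <- formatC(x, format = "g", digits = 6)
  gsub("\\s", "", s)
}
vec <- function(v) paste0("[", paste(num(v), collapse = ", "), "]")

## ---------------------------------------------------------------- segments
seg <- function(name, mass, com, inertia)
  list(name = name, mass = mass, com = com, inertia = inertia)

total_mass <- 75.2  # generic healthy male
pct <- c(HEAD = 5.0, JAW = 0.6, TORSO = 26.2, CERV1 = 0.7, CERV2 = 0.9,
         CERV3 = 0.6, CERV4 = 0.6, CERV5 = 0.6, CERV6 = 0.7, CERV7 = 0.9,
         PELVIS = 14.7, SCAPULA = 3.0, CLAV = 0.6, FEMUR = 9.3, TIBIA = 4.6,
         TALLUS = 0.1, CALCANEUS = 1.6, TOES = 0.3, HUMERUS = 2.5,
         ULNA = 0.8, RADIUS = 0.8, HAND = 0.6)
m_of <- function(lbl) unname(pct[lbl]) * total_mass / 100

## crude box/rod inertias (kg m^2), triangle-inequality safe
rodI <- function(m, L, r = L / 8) {
  I_long <- 0.5 * m * r^2
  I_tran <- m * (L^2 / 12 + r^2 / 4)
  c(I_tran, I_long, I_tran)
}
boxI <- function(m, a, b, c_) {
  c(m * (b^2 + c_^2), m * (a^2 + c_^2), m * (a^2 + b^2)) / 12
}

segs <- list(
  seg("pelvis", m_of("PELVIS"), c(0, 0, 0), boxI(m_of("PELVIS"), .25, .15, .30)),
  seg("torso", m_of("TORSO"), c(0, 0.25, 0), boxI(m_of("TORSO"), .22, .45, .32)),
  seg("head", m_of("HEAD"), c(0.01, 0.06, 0), boxI(m_of("HEAD"), .16, .20, .15)),
  seg("jaw", m_of("JAW"), c(0.02, -0.01, 0), boxI(m_of("JAW"), .08, .04, .08)),
  seg("hyoid", 0, c(0, 0, 0), c(0, 0, 0)))
for (k in 1:7) {
  lbl <- paste0("CERV", k)
  segs[[length(segs) + 1L]] <-
    seg(paste0("cerv", k), m_of(lbl), c(0, 0.011, 0),
        boxI(m_of(lbl), .09, .03, .09))
}
bilat <- function(name, lbl, com, dims, flipz = TRUE) {
  m <- m_of(lbl)
  I <- if (length(dims) == 2L) rodI(m, dims[1L], dims[2L]) else
    boxI(m, dims[1L], dims[2L], dims[3L])
  list(seg(paste0(name, "_r"), m, com, I),
       seg(paste0(name, "_l"), m, com * c(1, 1, if (flipz) -1 else 1), I))
}
segs <- c(segs,
  bilat("clavicle", "CLAV", c(0, 0, 0.08), c(.16, .015)),
  bilat("scapula", "SCAPULA", c(-0.05, -0.04, 0), c(.12, .15, .03)),
  bilat("humerus", "HUMERUS", c(0, -0.16, 0), c(.33, .035)),
  bilat("ulna", "ULNA", c(0, -0.12, 0), c(.26, .02)),
  bilat("radius", "RADIUS", c(0, -0.12, 0), c(.25, .02)),
  bilat("hand", "HAND", c(0, -0.07, 0), c(.18, .04, .09)),
  bilat("femur", "FEMUR", c(0, -0.20, 0), c(.45, .06)),
  bilat("tibia", "TIBIA", c(0, -0.19, 0), c(.43, .04)),
  bilat("talus", "TALLUS", c(0, 0, 0), c(.05, .05, .05)),
  bilat("calcaneus", "CALCANEUS", c(0.08, -0.02, 0), c(.18, .06, .07)),
  bilat("toes", "TOES", c(0.03, 0, 0), c(.08, .02, .07)))

## ----------------------------------------------------------------- joints
rot <- function(name, axis, range = c(-120, 120), default = 0, locked = FALSE)
  list(name = name, kind = "rotational", axis = axis, range = range,
       default = default, locked = locked)
trn <- function(name, axis, range = c(-5, 5), default = 0)
  list(name = name, kind = "translational", axis = axis, range = range,
       default = default)
joint <- function(name, parent, child, lp = c(0, 0, 0), coords = list())
  list(name = name, parent = parent, child = child,
       location_in_parent = lp, coordinates = coords)

ZF <- c(0, 0, -1)  # positive rotation = flexion (forward-down), x anterior/y up/z right
joints <- list(
  joint("ground_pelvis", "ground", "pelvis", c(0, 0.95, 0), list(
    rot("pelvis_tilt", ZF, c(-90, 90)),
    rot("pelvis_list", c(1, 0, 0), c(-90, 90)),
    rot("pelvis_rotation", c(0, 1, 0), c(-180, 180)),
    trn("pelvis_tx", c(1, 0, 0)), trn("pelvis_ty", c(0, 1, 0)),
    trn("pelvis_tz", c(0, 0, 1)))),
  joint("back", "pelvis", "torso", c(-0.02, 0.08, 0), list(
    rot("lumbar_extension", ZF, c(-90, 90)),
    rot("lumbar_bending", c(1, 0, 0), c(-60, 60)),
    rot("lumbar_rotation", c(0, 1, 0), c(-60, 60)))),
  joint("t1_c7", "torso", "cerv7", c(-0.03, 0.47, 0), list(
    rot("neck_flexion", ZF, c(-20, 20)),
    rot("neck_bending", c(1, 0, 0), c(-15, 15)),
    rot("neck_rotation", c(0, 1, 0), c(-25, 25)))))
prev <- "cerv7"
for (k in 6:1) {
  nm <- paste0("cerv", k)
  joints[[length(joints) + 1L]] <- joint(
    paste0("c", k + 1L, "_c", k), prev, nm, c(0, 0.022, 0), list(
      rot(paste0("c", k, "_flexion"), ZF, c(-45, 45)),
      rot(paste0("c", k, "_bending"), c(1, 0, 0), c(-35, 35)),
      rot(paste0("c", k, "_rotation"), c(0, 1, 0), c(-45, 45))))
  prev <- nm
}
joints <- c(joints, list(
  joint("c1_head", "cerv1", "head", c(0, 0.025, 0), list(
    rot("head_flexion", ZF, c(-40, 40)),
    rot("head_bending", c(1, 0, 0), c(-30, 30)),
    rot("head_rotation", c(0, 1, 0), c(-45, 45)))),
  joint("jaw_weld", "head", "jaw", c(0.02, -0.02, 0)),
  joint("hyoid_weld", "head", "hyoid", c(0.03, -0.08, 0))))

side <- function(sfx, sgn) {
  sc <- paste0("sc_", c("elevation", "protraction", "axial"), "_", sfx)
  ac <- paste0("ac_", c("lateral", "protraction", "tilt"), "_", sfx)
  list(
    joint(paste0("sternoclavicular_", sfx), "torso",
          paste0("clavicle_", sfx), c(0.03, 0.43, sgn * 0.02), list(
      rot(sc[1], c(1, 0, 0), c(-60, 60)),
      rot(sc[2], c(0, 1, 0), c(-60, 60)),
      rot(sc[3], c(0, 0, 1), c(-60, 60)))),
    joint(paste0("acromioclavicular_", sfx), paste0("clavicle_", sfx),
          paste0("scapula_", sfx), c(0, 0, sgn * 0.16), list(
      rot(ac[1], c(1, 0, 0), c(-60, 60)),
      rot(ac[2], c(0, 1, 0), c(-60, 60)),
      rot(ac[3], c(0, 0, 1), c(-60, 60)))),
    joint(paste0("shoulder_", sfx), paste0("scapula_", sfx),
          paste0("humerus_", sfx), c(-0.01, -0.04, sgn * 0.02), list(
      rot(paste0("humeral_elev_", sfx), c(-sgn, 0, 0), c(0, 180),
          default = 25),
      rot(paste0("shoulder_rot_", sfx), c(0, 1, 0), c(-90, 90)),
      rot(paste0("shoulder_plane_", sfx), ZF, c(-90, 130)))),
    joint(paste0("elbow_", sfx), paste0("humerus_", sfx),
          paste0("ulna_", sfx), c(0.01, -0.32, 0), list(
      rot(paste0("elbow_flex_", sfx), ZF, c(0, 150), default = 10))),
    joint(paste0("radioulnar_", sfx), paste0("ulna_", sfx),
          paste0("radius_", sfx), c(0.01, -0.02, sgn * 0.02), list(
      rot(paste0("pro_sup_", sfx), c(0, 1, 0), c(-90, 90)))),
    joint(paste0("wrist_", sfx), paste0("radius_", sfx),
          paste0("hand_", sfx), c(0, -0.24, 0), list(
      rot(paste0("wrist_flex_", sfx), ZF, c(-70, 70), locked = TRUE),
      rot(paste0("wrist_dev_", sfx), c(1, 0, 0), c(-25, 35),
          locked = TRUE))),
    joint(paste0("hip_", sfx), "pelvis", paste0("femur_", sfx),
          c(-0.07, -0.07, sgn * 0.08), list(
      rot(paste0("hip_flexion_", sfx), ZF, c(-30, 120)),
      rot(paste0("hip_adduction_", sfx), c(1, 0, 0), c(-50, 30)),
      rot(paste0("hip_rotation_", sfx), c(0, 1, 0), c(-40, 40)))),
    joint(paste0("knee_", sfx), paste0("femur_", sfx),
          paste0("tibia_", sfx), c(0, -0.40, 0), list(
      rot(paste0("knee_angle_", sfx), c(0, 0, 1), c(0, 140)))),
    joint(paste0("ankle_", sfx), paste0("tibia_", sfx),
          paste0("talus_", sfx), c(0, -0.40, 0), list(
      rot(paste0("ankle_angle_", sfx), ZF, c(-40, 30)))),
    joint(paste0("subtalar_", sfx), paste0("talus_", sfx),
          paste0("calcaneus_", sfx), c(-0.04, -0.04, 0), list(
      rot(paste0("subtalar_angle_", sfx), c(1, 0, 0), c(-30, 30)))),
    joint(paste0("mtp_", sfx), paste0("calcaneus_", sfx),
          paste0("toes_", sfx), c(0.16, -0.01, 0), list(
      rot(paste0("mtp_angle_", sfx), ZF, c(-40, 60), locked = TRUE))))
}
joints <- c(joints, side("r", +1), side("l", -1))

## --------------------------------------------------------------- couplers
cerv_tab <- utils::read.table("inst/extdata/cervical_coupling.tsv",
                              header = TRUE, sep = "\t")
couplers <- list()
for (k in seq_len(nrow(cerv_tab))) {
  lev <- cerv_tab$level[k]
  for (ch in c("flexion", "bending", "rotation")) {
    couplers[[length(couplers) + 1L]] <- list(
      name = paste0(lev, "_", ch, "_coupler"),
      independent = paste0("neck_", ch),
      dependent = paste0(lev, "_", ch),
      kind = "linear",
      slope = cerv_tab[[paste0(ch, "_fraction")]][k], intercept = 0)
  }
}
sc_tab <- utils::read.table("inst/extdata/sc_coupling.tsv", header = TRUE,
                            sep = "\t")
ac_tab <- utils::read.table("inst/extdata/ac_coupling.tsv", header = TRUE,
                            sep = "\t")
for (sfx in c("r", "l")) {
  mir <- function(ch, v) if (sfx == "l" && ch %in%
                               c("sc_protraction", "sc_axial")) -v else v
  for (ch in c("sc_elevation", "sc_protraction", "sc_axial")) {
    couplers[[length(couplers) + 1L]] <- list(
      name = paste0(ch, "_", sfx, "_coupler"),
      independent = paste0("humeral_elev_", sfx),
      dependent = paste0(ch, "_", sfx),
      kind = "spline", x = sc_tab$elevation, y = mir(ch, sc_tab[[ch]]))
  }
  for (k in seq_len(nrow(ac_tab))) {
    ch <- ac_tab$channel[k]
    slope <- ac_tab$slope[k]; icept <- ac_tab$intercept[k]
    if (sfx == "l") {
      if (ch == "protraction") icept <- -icept
      if (ch == "tilt") slope <- -slope
    }
    couplers[[length(couplers) + 1L]] <- list(
      name = paste0("ac_", ch, "_", sfx, "_coupler"),
      independent = paste0(ac_tab$sc_channel[k], "_", sfx),
      dependent = paste0("ac_", ch, "_", sfx),
      kind = "linear", slope = slope, intercept = icept)
  }
}
stopifnot(length(couplers) == 30L)

## ---------------------------------------------------------------- muscles
## 19 groups, 39 units per side. Attachments are plausible but synthetic
## (flagged in the YAML header); see the calibration note above.
mk_path <- function(...) {
  pts <- list(...)
  lapply(pts, function(p) list(segment = p[[1L]], point = p[[2L]]))
}
muscle_defs <- function(sfx, sgn) {
  M <- list()
  add <- function(group, action, primary, origin, insertion, via = NULL,
                  n = 1L, spread = 0.008) {
    for (i in seq_len(n)) {
      off <- c(0, 0, sgn * spread * (i - (n + 1) / 2))
      pth <- c(list(list(origin[[1L]], origin[[2L]] + off)),
               if (!is.null(via)) list(list(via[[1L]], via[[2L]] + off)),
               list(list(insertion[[1L]], insertion[[2L]] + off)))
      M[[length(M) + 1L]] <<- list(
        name = paste0(group, "_", sfx, if (n > 1L) paste0("_", i) else ""),
        group = group, action = action, primary = primary,
        path = do.call(mk_path, pth))
    }
  }
  z <- function(v) sgn * v
  ## flexors (anterior, x > 0); lateral offsets larger for benders
  add("scm", "flexor", "sagittal",
      list("torso", c(0.055, 0.44, z(0.045))),
      list("head", c(0.005, 0.02, z(0.055))), n = 3L)
  add("scalenus_ant", "flexor", "lateral",
      list("torso", c(0.035, 0.40, z(0.04))),
      list("cerv4", c(0.025, 0.005, z(0.035))))
  add("scalenus_med", "flexor", "lateral",
      list("torso", c(0.02, 0.40, z(0.05))),
      list("cerv5", c(0.01, 0.005, z(0.045))))
  add("scalenus_post", "flexor", "lateral",
      list("torso", c(0.005, 0.40, z(0.055))),
      list("cerv6", c(-0.005, 0.005, z(0.05))))
  add("longus_cap", "flexor", "sagittal",
      list("torso", c(0.045, 0.45, z(0.012))),
      list("head", c(0.025, -0.005, z(0.012))), n = 2L)
  add("longus_colli", "flexor", "sagittal",
      list("torso", c(0.04, 0.44, z(0.01))),
      list("cerv2", c(0.03, 0.005, z(0.012))), n = 4L)
  add("hyoid_mm", "flexor", "sagittal",
      list("torso", c(0.06, 0.43, z(0.008))),
      list("hyoid", c(0.005, 0.0, z(0.008))))
  ## extensors (posterior, x < 0); lateral offsets kept nearly equal at
  ## origin and insertion so extensor lines stay near-vertical and the
  ## lateral-bending capacity remains in the flexor/lateral groups
  add("trap_clav", "extensor", "sagittal",
      list("clavicle_" %+% sfx, c(-0.01, 0.005, z(0.03))),
      list("head", c(-0.045, 0.0, z(0.03))), n = 2L, spread = 0.004)
  add("trap_acr", "extensor", "sagittal",
      list("scapula_" %+% sfx, c(-0.05, 0.0, z(-0.13))),
      list("cerv3", c(-0.045, 0.005, z(0.02))), n = 2L, spread = 0.004)
  add("levator_scap", "extensor", "lateral",
      list("scapula_" %+% sfx, c(-0.06, 0.01, z(-0.12))),
      list("cerv1", c(-0.03, 0.005, z(0.035))))
  add("splenius_cap", "extensor", "sagittal",
      list("torso", c(-0.055, 0.42, z(0.028))),
      list("head", c(-0.05, 0.01, z(0.03))), n = 2L, spread = 0.004)
  add("splenius_cerv", "extensor", "rotator",
      list("torso", c(-0.055, 0.41, z(0.02))),
      list("cerv2", c(-0.04, 0.005, z(0.022))))
  add("semispinalis_cap", "extensor", "sagittal",
      list("torso", c(-0.05, 0.43, z(0.015))),
      list("head", c(-0.055, 0.02, z(0.015))), n = 3L, spread = 0.004)
  add("semispinalis_cerv", "extensor", "sagittal",
      list("torso", c(-0.05, 0.42, z(0.012))),
      list("cerv3", c(-0.045, 0.005, z(0.014))), n = 3L, spread = 0.004)
  add("longissimus_cap", "extensor", "lateral",
      list("torso", c(-0.04, 0.41, z(0.036))),
      list("head", c(-0.04, 0.0, z(0.04))))
  add("longissimus_cerv", "extensor", "lateral",
      list("torso", c(-0.04, 0.40, z(0.028))),
      list("cerv5", c(-0.035, 0.005, z(0.03))), n = 2L, spread = 0.004)
  add("multifidus", "extensor", "sagittal",
      list("torso", c(-0.05, 0.45, z(0.01))),
      list("cerv6", c(-0.045, 0.01, z(0.012))), n = 5L, spread = 0.004)
  add("rectus_cap_post", "extensor", "sagittal",
      list("cerv2", c(-0.04, 0.005, z(0.012))),
      list("head", c(-0.05, 0.005, z(0.014))), n = 2L, spread = 0.004)
  add("obliquus_cap", "extensor", "rotator",
      list("cerv1", c(-0.03, 0.0, z(0.02))),
      list("head", c(-0.035, 0.0, z(0.016))), n = 2L, spread = 0.004)
  M
}
`%+%` <- function(a, b) paste0(a, b)
muscles <- c(muscle_defs("r", +1), muscle_defs("l", -1))
stopifnot(length(muscles) == 78L,
          length(unique(vapply(muscles, `[[`, "", "group"))) == 19L)
for (i in seq_along(muscles)) {
  muscles[[i]]$f_max <- 50
  muscles[[i]]$l_opt <- 0.1
  muscles[[i]]$l_slack <- 0.05
  muscles[[i]]$pennation <- 0
  muscles[[i]]$tau_act <- 0.01
  muscles[[i]]$tau_deact <- 0.04
}

## ---------------------------------------------------------------- markers
mark <- function(name, segment, offset)
  list(name = name, segment = segment, offset = offset)
markers <- list(
  mark("LFHD", "head", c(0.09, 0.09, -0.06)),
  mark("RFHD", "head", c(0.09, 0.09, 0.06)),
  mark("LBHD", "head", c(-0.08, 0.09, -0.06)),
  mark("RBHD", "head", c(-0.08, 0.09, 0.06)),
  mark("CHIN", "jaw", c(0.06, -0.03, 0)),
  mark("C7", "cerv7", c(-0.06, 0.01, 0)),
  mark("C3", "cerv3", c(-0.055, 0.01, 0)),
  mark("CLAV", "torso", c(0.07, 0.46, 0)),
  mark("STRN", "torso", c(0.09, 0.30, 0)),
  mark("T10", "torso", c(-0.09, 0.18, 0)),
  mark("BACK", "torso", c(-0.10, 0.38, 0)),
  mark("RASI", "pelvis", c(0.08, 0.02, 0.12)),
  mark("LASI", "pelvis", c(0.08, 0.02, -0.12)),
  mark("RPSI", "pelvis", c(-0.09, 0.03, 0.05)),
  mark("LPSI", "pelvis", c(-0.09, 0.03, -0.05)),
  mark("SACR", "pelvis", c(-0.10, -0.02, 0)))
side_marks <- function(S, sgn) {
  s <- tolower(S)
  list(
    mark(S %+% "CLV", "clavicle_" %+% s, c(0.01, 0.01, sgn * 0.08)),
    mark(S %+% "SHO", "scapula_" %+% s, c(0.0, 0.02, sgn * 0.03)),
    mark(S %+% "SCAP", "scapula_" %+% s, c(-0.08, -0.02, sgn * -0.02)),
    mark(S %+% "SCAI", "scapula_" %+% s, c(-0.09, -0.10, sgn * -0.01)),
    mark(S %+% "UPA", "humerus_" %+% s, c(0.02, -0.12, sgn * 0.03)),
    mark(S %+% "UPB", "humerus_" %+% s, c(-0.02, -0.20, sgn * 0.03)),
    mark(S %+% "ELB", "humerus_" %+% s, c(0.0, -0.31, sgn * 0.04)),
    mark(S %+% "FRA", "radius_" %+% s, c(0.02, -0.12, sgn * 0.02)),
    mark(S %+% "WRA", "radius_" %+% s, c(0.02, -0.23, sgn * 0.03)),
    mark(S %+% "WRB", "radius_" %+% s, c(-0.02, -0.23, sgn * 0.03)),
    mark(S %+% "FIN", "hand_" %+% s, c(0.01, -0.09, 0)),
    mark(S %+% "THI", "femur_" %+% s, c(0.04, -0.18, sgn * 0.05)),
    mark(S %+% "THB", "femur_" %+% s, c(-0.02, -0.28, sgn * 0.05)),
    mark(S %+% "KNE", "femur_" %+% s, c(0.0, -0.40, sgn * 0.06)),
    mark(S %+% "TIB", "tibia_" %+% s, c(0.02, -0.18, sgn * 0.04)),
    mark(S %+% "TIB2", "tibia_" %+% s, c(-0.01, -0.30, sgn * 0.04)),
    mark(S %+% "ANK", "tibia_" %+% s, c(0.0, -0.40, sgn * 0.045)),
    mark(S %+% "HEE", "calcaneus_" %+% s, c(-0.03, -0.02, 0)),
    mark(S %+% "MT5", "calcaneus_" %+% s, c(0.12, -0.03, sgn * 0.05)),
    mark(S %+% "TOE", "toes_" %+% s, c(0.06, -0.01, 0)),
    mark(S %+% "HUM", "humerus_" %+% s, c(0.03, -0.05, sgn * 0.02)),
    mark(S %+% "RAD", "radius_" %+% s, c(0.03, -0.05, sgn * 0.01)),
    mark(S %+% "PAT", "femur_" %+% s, c(0.05, -0.38, 0)),
    mark(S %+% "CAL", "calcaneus_" %+% s, c(-0.04, 0.02, sgn * 0.02)),
    mark(S %+% "NECK", "cerv5", c(0.0, 0.005, sgn * 0.05)),
    mark(S %+% "MAS", "head", c(0.01, -0.01, sgn * 0.07)))
}
markers <- c(markers, side_marks("R", +1), side_marks("L", -1))
stopifnot(length(markers) == 68L)

actuators <- c(
  paste0(rep(c("hip_flexion_", "hip_adduction_", "hip_rotation_",
               "knee_angle_", "ankle_angle_", "subtalar_angle_"),
             each = 2L), c("r", "l")),
  "lumbar_extension", "lumbar_bending", "lumbar_rotation",
  paste0(rep(c("humeral_elev_", "shoulder_rot_", "shoulder_plane_",
               "elbow_flex_"), each = 2L), c("r", "l")))
stopifnot(length(actuators) == 23L)

## ------------------------------------------------- pass 1: assemble, tune
build_cfg <- function(muscles) {
  list(name = "masi", gravity = c(0, -9.81, 0), segments = segs,
       joints = joints, couplers = couplers, muscles = muscles,
       markers = markers, actuators = as.list(actuators), locks = list())
}
am <- assemble(load_model_description(build_cfg(muscles)))
q0 <- default_q(am)
fk0 <- forward_kinematics(am, q0)
## fibers carry ~8% stretch at the neutral posture: bilateral passive
## pre-tension gives the unloaded neck positive stiffness (without it the
## passive chain has zero stiffness at neutral and buckles under gravity)
pretension <- 1.10
for (i in seq_along(muscles)) {
  L <- musculotendon_length(am, q0, am$muscles[[i]], fk0)
  muscles[[i]]$l_opt <- round(0.65 * L / pretension, 5)
  muscles[[i]]$l_slack <- round(0.35 * L, 5)
}
am <- assemble(load_model_description(build_cfg(muscles)))

## calibrate baseline capacities: extension 34.1 N m, lateral bending 22.6
cap <- function(am, coord, dir) {
  abs(max_isometric_moments(am, coord, dir, constrained = FALSE)$net_moment)
}
## with passive pre-tension the two capacity targets couple weakly;
## a few fixed-point sweeps land both
cls_m <- vapply(muscles, `[[`, "", "action")
for (sweep in 1:4) {
  ext0 <- cap(am, "neck_flexion", -1)
  alpha_e <- 34.1 / ext0
  for (i in seq_along(muscles)) {
    if (cls_m[i] == "extensor") muscles[[i]]$f_max <- muscles[[i]]$f_max * alpha_e
  }
  am <- assemble(load_model_description(build_cfg(muscles)))
  res <- max_isometric_moments(am, "neck_bending", 1, constrained = FALSE)
  cls <- vapply(am$muscles, `[[`, "", "action")
  contrib <- res$contributions
  lat_ext <- sum(contrib[cls == "extensor"])
  lat_flex <- sum(contrib[cls == "flexor"])
  alpha_f <- (22.6 - lat_ext) / lat_flex
  cat(sprintf("sweep %d: ext0=%.3f alpha_e=%.4f lat_ext=%.2f lat_flex=%.2f alpha_f=%.4f\n",
              sweep, ext0, alpha_e, lat_ext, lat_flex, alpha_f))
  stopifnot(alpha_f > 0)
  for (i in seq_along(muscles)) {
    if (cls_m[i] == "flexor") muscles[[i]]$f_max <- muscles[[i]]$f_max * alpha_f
  }
  am <- assemble(load_model_description(build_cfg(muscles)))
}
for (i in seq_along(muscles)) {
  muscles[[i]]$f_max <- round(muscles[[i]]$f_max, 2)
}
am <- assemble(load_model_description(build_cfg(muscles)))
cat(sprintf("baseline capacities: ext %.2f, flex %.2f, latbend %.2f, axrot %.2f N m\n",
            cap(am, "neck_flexion", -1), cap(am, "neck_flexion", 1),
            cap(am, "neck_bending", 1), cap(am, "neck_rotation", 1)))
aud <- audit_degrees_of_freedom(am)
print(aud)
stopifnot(aud$n_segments == 35L, aud$n_joints == 34L,
          aud$n_constraints == 30L, aud$n_independent == 43L,
          aud$n_independent_after_locks == 37L, aud$n_muscles == 78L,
          aud$n_muscle_groups == 19L, aud$n_torque_actuators == 23L)

## ------------------------------------------------------------ emit YAML
emit <- function(path) {
  con <- file(path, "w")
  w <- function(...) writeLines(sprintf(...), con)
  w("# Default full-body model description.")
  w("# Structure: 35 segments (counting the ground root), 34 joints,")
  w("# 73 coordinates = 43 independent + 30 coupler-driven; wrist and")
  w("# metatarsophalangeal coordinates locked (-> 37 free); 78 neck")
  w("# muscle-tendon units in 19 groups; 23 coordinate torque actuators.")
  w("# Coordinate allocation (couplers): 6 cervical joints x 3 rotations")
  w("# driven linearly by the 3 neck master coordinates (18), plus 2 x 6")
  w("# scapula-clavicular couplers (SC splines driven by humeral")
  w("# elevation, AC linear in SC). Cervical distribution fractions are a")
  w("# default linear table (see cervical_coupling.tsv), overridable.")
  w("# MUSCLE GEOMETRY IS SYNTHETIC: plausible straight-line attachments,")
  w("# NOT anatomically validated; baseline group strengths calibrated so")
  w("# maximal extension / lateral-bending capacity matches the published")
  w("# baseline head-neck model (34.1 / 22.6 N m).")
  w("# Angles in degrees, lengths in metres, masses in kg.")
  w("name: masi")
  w("gravity: [0, -9.81, 0]")
  w("segments:")
  for (s in segs) {
    w("  - {name: %s, mass: %s, com: %s, inertia: %s}",
      s$name, num(s$mass), vec(s$com), vec(s$inertia))
  }
  w("joints:")
  for (j in joints) {
    w("  - name: %s", j$name)
    w("    parent: %s", j$parent)
    w("    child: %s", j$child)
    if (any(j$location_in_parent != 0)) {
      w("    location_in_parent: %s", vec(j$location_in_parent))
    }
    if (length(j$coordinates)) {
      w("    coordinates:")
      for (co in j$coordinates) {
        w("      - {name: %s, kind: %s, axis: %s, range: %s, default: %s%s}",
          co$name, co$kind, vec(co$axis), vec(co$range), num(co$default),
          if (isTRUE(co$locked)) ", locked: true" else "")
      }
    }
  }
  w("couplers:")
  for (cp in couplers) {
    if (cp$kind == "linear") {
      w("  - {name: %s, independent: %s, dependent: %s, kind: linear, slope: %s, intercept: %s}",
        cp$name, cp$independent, cp$dependent, num(cp$slope),
        num(cp$intercept))
    } else {
      w("  - name: %s", cp$name)
      w("    independent: %s", cp$independent)
      w("    dependent: %s", cp$dependent)
      w("    kind: spline")
      w("    knots_x: %s", vec(cp$x))
      w("    knots_y: %s", vec(cp$y))
    }
  }
  w("muscles:")
  for (mu in muscles) {
    w("  - name: %s", mu$name)
    w("    group: %s", mu$group)
    w("    action: %s", mu$action)
    w("    primary: %s", mu$primary)
    w("    f_max: %s", num(mu$f_max))
    w("    l_opt: %s", num(mu$l_opt))
    w("    l_slack: %s", num(mu$l_slack))
    pth <- paste(vapply(mu$path, function(p)
      sprintf("{segment: %s, point: %s}", p$segment, vec(p$point)), ""),
      collapse = ", ")
    w("    path: [%s]", pth)
  }
  w("markers:")
  for (mk in markers) {
    w("  - {name: %s, segment: %s, offset: %s}", mk$name, mk$segment,
      vec(mk$offset))
  }
  w("actuators: [%s]", paste(actuators, collapse = ", "))
  close(con)
}
emit("inst/extdata/masi_model.yaml")
am2 <- assemble(load_model_description("inst/extdata/masi_model.yaml"))
aud2 <- audit_degrees_of_freedom(am2)
stopifnot(identical(unclass(aud), unclass(aud2)))
cat("wrote inst/extdata/masi_model.yaml (",
    file.size("inst/extdata/masi_model.yaml"), " bytes )\n")
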