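test_that("glenoid frame: axis-aligned case and orthonormality", {
  ## axis-aligned plane with the tubercle superior and slightly out of
  ## plane: z perpendicular, y superior (frame origin = landmark centroid)
  lm <- rbind(c(-1, 1 / 3, 0), c(1, 1 / 3, 0), c(0, 4 / 3, 0))
  fr <- build_glenoid_frame(lm, c(0, 2, 0.5))
  expect_equal(abs(fr$z_axis), c(0, 0, 1), tolerance = 1e-12)
  expect_equal(fr$y_axis, c(0, 1, 0), tolerance = 1e-12)
  ## orthonormal and right-handed for random valid inputs
  set.seed(3)
  for (k in 1:10) {
    lm <- matrix(rnorm(9), 3, 3)
    tb <- rnorm(3)
    fr <- tryCatch(build_glenoid_frame(lm, tb), error = function(e) NULL)
    if (is.null(fr)) next
    A <- cbind(fr$x_axis, fr$y_axis, fr$z_axis)
    expect_lt(max(abs(crossprod(A) - diag(3))), 1e-10)
    expect_gt(det(A), 0)
  }
  expect_error(build_glenoid_frame(rbind(c(0, 0, 0), c(1, 0, 0),
                                         c(2, 0, 0)), c(0, 1, 0)),
               "collinear")
})

test_that("glenoid frame is equivariant under rigid rotations", {
  set.seed(11)
  lm <- rbind(c(0.01, 0.02, 0), c(0.03, 0.01, 0.005),
              c(0.015, 0.04, -0.003))
  tb <- c(0.02, 0.06, 0.01)
  fr <- build_glenoid_frame(lm, tb)
  for (k in 1:5) {
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
    R <- cervidyn:::rot_axis_angle(ax, runif(1, -pi, pi))
    fr2 <- build_glenoid_frame(t(R %*% t(lm)), as.numeric(R %*% tb))
    for (f in c("x_axis", "y_axis", "z_axis")) {
      expect_equal(fr2[[f]], as.numeric(R %*% fr[[f]]), tolerance = 1e-10)
    }
    expect_equal(fr2$origin, as.numeric(R %*% fr$origin), tolerance = 1e-12)
  }
})

test_that("SC spline coupling passes through its knots and matches an
           independent interpolation oracle", {
  tabs <- default_coupling_tables()
  knots <- read.table(system.file("extdata", "sc_coupling.tsv",
                                  package = "cervidyn"),
                      header = TRUE, sep = "\t")
  at_knots <- evaluate_sc_coupling(knots$elevation, tabs$sc)
  expect_equal(unname(at_knots[, "sc_elevation"]), knots$sc_elevation,
               tolerance = 1e-12)
  expect_equal(unname(at_knots[, "sc_axial"]), knots$sc_axial,
               tolerance = 1e-12)
  ## mid-span values against pracma's independent natural cubic spline
  skip_if_not_installed("pracma")
  grid <- seq(25, 135, by = 7.5)
  ours <- evaluate_sc_coupling(grid, tabs$sc)
  for (ch in c("sc_elevation", "sc_protraction", "sc_axial")) {
    ref <- pracma::cubicspline(knots$elevation, knots[[ch]], grid,
                               endp2nd = FALSE)
    expect_equal(unname(ours[, ch]), ref, tolerance = 1e-10)
  }
})

test_that("out-of-range elevation errors unless clamped", {
  expect_error(evaluate_sc_coupling(150), "valid range")
  expect_error(evaluate_sc_coupling(10), "valid range")
  clamped <- evaluate_sc_coupling(c(10, 150), clamp = TRUE)
  ends <- evaluate_sc_coupling(c(20, 140))
  expect_equal(clamped, ends, tolerance = 1e-12)
})

test_that("AC coupling is the declared affine map", {
  ## identity and intercept-only cases
  id <- list(coupler_constraint("sc_elevation", "ac_lateral", "linear",
                                slope = 1, intercept = 0),
             coupler_constraint("sc_protraction", "ac_protraction",
                                "linear", slope = 1, intercept = 0),
             coupler_constraint("sc_axial", "ac_tilt", "linear",
                                slope = 1, intercept = 0))
  sc <- c(5, -20, 12)
  expect_equal(unname(evaluate_ac_coupling(sc, id)[1, ]), sc,
               tolerance = 1e-12)
  ## sc = 0 returns the intercepts exactly
  tabs <- default_coupling_tables()
  ac0 <- evaluate_ac_coupling(c(0, 0, 0), tabs$ac)
  icpt <- read.table(system.file("extdata", "ac_coupling.tsv",
                                 package = "cervidyn"),
                     header = TRUE, sep = "\t")$intercept
  expect_equal(unname(ac0[1, ]), icpt, tolerance = 1e-12)
  ## random affine maps against direct arithmetic
  set.seed(5)
  for (k in 1:5) {
    sl <- rnorm(3); ic <- rnorm(3)
    cps <- list(
      coupler_constraint("sc_elevation", "ac_lateral", "linear",
                         slope = sl[1], intercept = ic[1]),
      coupler_constraint("sc_protraction", "ac_protraction", "linear",
                         slope = sl[2], intercept = ic[2]),
      coupler_constraint("sc_axial", "ac_tilt", "linear",
                         slope = sl[3], intercept = ic[3]))
    sc <- rnorm(3, 0, 20)
    expect_equal(unname(evaluate_ac_coupling(sc, cps)[1, ]),
                 sl * sc + ic, tolerance = 1e-12)
  }
  expect_error(evaluate_ac_coupling(c(NA, 0, 0)), "finite")
})

test_that("rhythm trace stays inside the packaged reference envelopes and
           is continuous over the validated span", {
  env <- read.table(system.file("extdata", "rhythm_envelope.tsv",
                                package = "cervidyn"),
                    header = TRUE, sep = "\t")
  tr <- rhythm_trace(seq(20, 140, by = 0.1))
  for (ch in unique(env$channel)) {
    e <- env[env$channel == ch, ]
    lo <- approx(e$elevation, e$mean - 2 * e$sd, tr$humeral_elevation)$y
    hi <- approx(e$elevation, e$mean + 2 * e$sd, tr$humeral_elevation)$y
    expect_true(all(tr[[ch]] >= lo & tr[[ch]] <= hi))
  }
  ## no jump larger than 0.01 deg per 0.1 deg elevation step
  for (ch in c("sc_elevation", "sc_protraction", "sc_axial",
               "ac_lateral", "ac_protraction", "ac_tilt")) {
    expect_lt(max(abs(diff(tr[[ch]]))), 0.05)
  }
})

test_that("left-side tables mirror protraction and axial rotation", {
  r <- rhythm_trace(seq(20, 140, by = 10), side = "r")
  l <- rhythm_trace(seq(20, 140, by = 10), side = "l")
  expect_equal(l$sc_elevation, r$sc_elevation, tolerance = 1e-12)
  expect_equal(l$sc_protraction, -r$sc_protraction, tolerance = 1e-12)
  expect_equal(l$sc_axial, -r$sc_axial, tolerance = 1e-12)
  expect_equal(l$ac_protraction, -r$ac_protraction, tolerance = 1e-12)
  expect_equal(l$ac_tilt, r$ac_tilt, tolerance = 1e-12)
})

test_that("rhythm RMS deviation: identity, offset and sinusoid closed forms", {
  tr <- rhythm_trace(seq(20, 140, by = 1))
  expect_identical(rhythm_rms_deviation(tr, tr, "sc_elevation"), 0)
  tr2 <- tr
  tr2$sc_elevation <- tr2$sc_elevation + 2
  expect_equal(rhythm_rms_deviation(tr, tr2, "sc_elevation"), 2,
               tolerance = 1e-12)
  ## sinusoid vs zero over one period -> amplitude / sqrt(2)
  x <- seq(0, 1, length.out = 2001)
  a <- data.frame(humeral_elevation = x, ch = 3 * sin(2 * pi * x))
  b <- data.frame(humeral_elevation = x, ch = 0 * x)
  expect_equal(rhythm_rms_deviation(a, b, "ch"), 3 / sqrt(2),
               tolerance = 1e-3)
  ## disjoint elevation ranges error
  c1 <- data.frame(humeral_elevation = 1:10, ch = 1:10)
  c2 <- data.frame(humeral_elevation = 21:30, ch = 1:10)
  expect_error(rhythm_rms_deviation(c1, c2, "ch"), "disjoint")
})

test_that("the full model's SC/AC coordinates obey the couplers during an
           elevation sweep", {
  am <- default_assembled()
  for (elev in c(30, 75, 120)) {
    q <- default_q(am)
    q[am$coord_index[["humeral_elev_r"]]] <- deg2rad(elev)
    q <- enforce_couplers(am, q)
    sc <- evaluate_sc_coupling(elev)
    expect_equal(unname(rad2deg(q[am$coord_index[["sc_elevation_r"]]])),
                 unname(sc[1, "sc_elevation"]), tolerance = 1e-9)
    ac <- evaluate_ac_coupling(sc)
    expect_equal(unname(rad2deg(q[am$coord_index[["ac_tilt_r"]]])),
                 unname(ac[1, "ac_tilt"]), tolerance = 1e-9)
  }
})
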