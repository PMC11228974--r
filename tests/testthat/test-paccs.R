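test_that("single-sphere PA CCS matches the analytic disk", {
  s <- structure_model("C", 0, 0, 0, radius = 1.7)
  res <- pa_ccs(s, probe_radius = 1.4, n_orientations = 30,
                n_mc_points = 8000, seed = 2)
  analytic <- pi * (1.7 + 1.4)^2 / 100
  expect_equal(res$ccs_pa, analytic, tolerance = 0.02)
  expect_equal(res$ccs_calc, 1.14 * res$ccs_pa)
  # coincident atoms: union is idempotent
  s2 <- structure_model(c("C", "C"), c(0, 0), c(0, 0), c(0, 0),
                        radius = c(1.7, 1.7))
  res2 <- pa_ccs(s2, n_orientations = 30, n_mc_points = 8000, seed = 2)
  expect_equal(res2$ccs_pa, analytic, tolerance = 0.02)
})

test_that("two distant spheres match the orientation-averaged union oracle", {
  s <- structure_model(c("C", "C"), c(0, 100), c(0, 0), c(0, 0),
                       radius = c(1.7, 1.7))
  res <- pa_ccs(s, probe_radius = 1.4, n_orientations = 400,
                n_mc_points = 6000, seed = 7)
  oracle <- two_sphere_union_area(3.1, 100) / 100
  expect_equal(res$ccs_pa, oracle, tolerance = 0.01)
})

test_that("PA CCS is rotation invariant and probe-monotone", {
  set.seed(13)
  s <- simulate_structure(15, seed = 6)
  xyz <- as.matrix(s[, c("x", "y", "z")])
  r1 <- pa_ccs(s, n_orientations = 80, n_mc_points = 2000, seed = 3)
  moved <- random_rigid_transform(xyz)
  s2 <- structure_model(s$element, moved[, 1], moved[, 2], moved[, 3])
  r2 <- pa_ccs(s2, n_orientations = 80, n_mc_points = 2000, seed = 4)
  expect_equal(r1$ccs_pa, r2$ccs_pa,
               tolerance = 5 * (r1$stderr + r2$stderr) / r1$ccs_pa)
  r_small <- pa_ccs(s, probe_radius = 1.0, n_orientations = 40,
                    n_mc_points = 2000, seed = 5)
  r_big <- pa_ccs(s, probe_radius = 2.0, n_orientations = 40,
                  n_mc_points = 2000, seed = 5)
  expect_gt(r_big$ccs_pa, r_small$ccs_pa)
})

test_that("stderr shrinks with the number of orientations", {
  s <- simulate_structure(20, seed = 9)
  r_few <- pa_ccs(s, n_orientations = 16, n_mc_points = 1500, seed = 1)
  r_many <- pa_ccs(s, n_orientations = 256, n_mc_points = 1500, seed = 1)
  expect_lt(r_many$stderr, r_few$stderr)
  expect_equal(r_few$ccs_pa, r_many$ccs_pa,
               tolerance = 6 * (r_few$stderr + r_many$stderr) / r_many$ccs_pa)
})

test_that("the 1.14 empirical correction is exact and linear", {
  expect_equal(corrected_ccs_calc(0.3019), 0.3019 * 1.14)
  expect_equal(corrected_ccs_calc(2 * 0.77), 2 * corrected_ccs_calc(0.77))
  expect_error(corrected_ccs_calc(0), "> 0")
  r <- pa_ccs(structure_model("C", 0, 0, 0), n_orientations = 2,
              n_mc_points = 500)
  expect_identical(r$ccs_calc / r$ccs_pa, 1.14)
})

test_that("Kabsch RMSD removes rigid motion and matches the quaternion oracle", {
  set.seed(17)
  P <- matrix(rnorm(30, sd = 4), 10)
  ref <- structure_model(rep("C", 10), P[, 1], P[, 2], P[, 3])
  expect_equal(kabsch_rmsd(ref, ref), 0, tolerance = 1e-12)
  for (i in 1:5) {
    M <- random_rigid_transform(P)
    frame <- structure_model(rep("C", 10), M[, 1], M[, 2], M[, 3])
    expect_equal(kabsch_rmsd(frame, ref), 0, tolerance = 1e-9)
  }
  # toy 4-point sets against the independent quaternion computation
  A <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 2, 0), c(0, 0, 3))
  B <- rbind(c(0.1, 0, 0), c(1, 0.2, 0), c(0, 1.8, 0.1), c(0.2, 0, 2.9))
  sa <- structure_model(rep("C", 4), A[, 1], A[, 2], A[, 3])
  sb <- structure_model(rep("C", 4), B[, 1], B[, 2], B[, 3])
  expect_equal(kabsch_rmsd(sa, sb), horn_rmsd(A, B), tolerance = 1e-9)
  C <- rbind(c(2, 1, 0), c(0, 1, 1), c(1, 0, 2), c(3, 2, 1))
  sc <- structure_model(rep("C", 4), C[, 1], C[, 2], C[, 3])
  expect_equal(kabsch_rmsd(sa, sc), horn_rmsd(A, C), tolerance = 1e-9)
  # degenerate geometry rejected
  line <- structure_model(rep("C", 4), 1:4, rep(0, 4), rep(0, 4))
  expect_error(kabsch_rmsd(line, line), "collinear")
  expect_error(kabsch_rmsd(sa, structure_model(rep("C", 3), 1:3, c(0, 1, 0),
                                               c(0, 0, 1)), NULL), "differ")
})

test_that("center-of-mass distances are mass-weighted and invariant", {
  s <- structure_model(c("C", "C"), c(0, 10), c(0, 0), c(0, 0),
                       mass = c(1, 1), label = c("a", "b"))
  expect_equal(com_distance(s, "a", "b"), 10)
  expect_equal(com_distance(s, "a", "a"), 0)
  shifted <- structure_model(c("C", "C"), c(5, 15), c(3, 3), c(-2, -2),
                             mass = c(1, 1), label = c("a", "b"))
  expect_equal(com_distance(shifted, "a", "b"), 10)
  # mass weighting: COM of (m=3 at 0, m=1 at 4) sits at x = 1
  s2 <- structure_model(rep("C", 3), c(0, 4, 10), c(0, 0, 0), c(0, 0, 0),
                        mass = c(3, 1, 1), label = c("g", "g", "h"))
  expect_equal(com_distance(s2, "g", "h"), 9)
  expect_error(com_distance(s, "a", "zzz"), "empty")
})

test_that("trajectory profiles honour stride and reject mismatched frames", {
  base <- simulate_structure(8, seed = 3)
  frames <- lapply(0:4, function(k) {
    structure_model(base$element, base$x + 0.2 * k, base$y, base$z)
  })
  prof <- trajectory_profile(frames, frames[[1]], n_orientations = 8,
                             n_mc_points = 400, seed = 2)
  expect_equal(nrow(prof), 5)
  expect_equal(prof$rmsd, rep(0, 5), tolerance = 1e-9)  # pure translation
  single <- trajectory_profile(frames[1], frames[[1]], n_orientations = 8,
                               n_mc_points = 400, seed = 2)
  expect_equal(single$rmsd, 0, tolerance = 1e-12)
  expect_equal(single$ccs_calc,
               pa_ccs(frames[[1]], 1.4, 8, 400, seed = sub_seed(2, 1))$ccs_calc)
  prof2 <- trajectory_profile(frames, frames[[1]], stride = 2,
                              n_orientations = 8, n_mc_points = 400, seed = 2)
  expect_equal(nrow(prof2), 3)   # ceil(5 / 2)
  expect_equal(prof2$frame, c(1, 3, 5))
  short <- structure_model("C", 0, 0, 0)
  expect_error(trajectory_profile(list(short), frames[[1]]), "differ")
})
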