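test_that("superposing a model onto itself gives the identity and RMSD 0", {
  m <- toy_model(toy_cloud())
  tf <- superpose(m, m)
  expect_equal(tf$R, diag(3), tolerance = 1e-12)
  expect_equal(tf$t, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(tf$rmsd, 0, tolerance = 1e-12)
})

test_that("a known rotation + shift is recovered exactly", {
  m <- toy_model(toy_cloud())
  R <- rotation_about_axis(c(0, 0, 1), 30)
  moved <- apply_transform(m, rigid_transform(R, c(1, 2, 3)))
  tf <- superpose(moved, m)
  expect_lt(tf$rmsd, 1e-9)
  expect_equal(tf$R, t(R), tolerance = 1e-9)
  back <- apply_transform(moved, tf)
  expect_equal(coords(back), coords(m), tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("degenerate selections are rejected", {
  line <- toy_model(cbind(1:5, 0, 0))
  expect_error(superpose(line, line), "collinear|degenerate")
  two <- toy_model(toy_cloud()[1:2, ])
  expect_error(superpose(two, two), "3 matched")
})

test_that("mismatched residue sets are reported", {
  a <- toy_model(toy_cloud(8), resno = 1:8)
  b <- toy_model(toy_cloud(8), resno = 3:10)
  expect_warning(superpose(a, b), "unmatched")
  c2 <- toy_model(toy_cloud(8), resno = 101:108)
  expect_error(suppressWarnings(superpose(a, c2)), "3 matched")
})

test_that("kabsch fit matches a refined random-search oracle on a noisy pair", {
  withr::local_seed(7)
  P <- toy_cloud(10, seed = 13)
  R <- random_rotation()
  Q <- sweep(P %*% t(R), 2, c(4, -2, 1), "+") + matrix(rnorm(30, 0, 0.2), ncol = 3)
  tf <- superpose(toy_model(P), toy_model(Q))

  # independent oracle: random search over rotations with shrinking local
  # refinement; translation is optimal (centroid-matching) for any rotation
  Pc <- sweep(P, 2, colMeans(P)); Qc <- sweep(Q, 2, colMeans(Q))
  rmsd_of <- function(Rm) sqrt(mean(rowSums((Pc %*% t(Rm) - Qc)^2)))
  best_R <- diag(3); best <- rmsd_of(best_R)
  for (i in 1:2000) {
    cand <- random_rotation()
    v <- rmsd_of(cand)
    if (v < best) { best <- v; best_R <- cand }
  }
  for (scale in c(0.3, 0.1, 0.03, 0.01, 0.003, 0.001)) {
    for (i in 1:1500) {
      ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
      cand <- rotation_about_axis(ax, scale * 57.29578 * rnorm(1)) %*% best_R
      v <- rmsd_of(cand)
      if (v < best) { best <- v; best_R <- cand }
    }
  }
  expect_gte(best, tf$rmsd - 1e-12)         # never better than the fit
  expect_equal(tf$rmsd, best, tolerance = 1e-3)
})

test_that("kabsch fit agrees with the bio3d reference implementation", {
  withr::local_seed(21)
  P <- toy_cloud(20, seed = 5)
  Q <- apply_transform(P, random_transform()) + matrix(rnorm(60, 0, 0.3), ncol = 3)
  tf <- superpose(toy_model(P), toy_model(Q))
  inds <- seq_len(3 * nrow(P))
  xyz_fit <- bio3d::fit.xyz(fixed = as.vector(t(Q)), mobile = as.vector(t(P)),
                            fixed.inds = inds, mobile.inds = inds)
  ref_rmsd <- bio3d::rmsd(as.vector(t(Q)), xyz_fit)   # bio3d rounds to 3 decimals
  expect_lt(abs(tf$rmsd - ref_rmsd), 6e-4)
})

test_that("axis-angle decomposition handles canonical and degenerate cases", {
  sa <- rotation_to_axis_angle(rigid_transform(rotation_about_axis(c(0, 0, 1), 90)))
  expect_equal(abs(sa$direction[3]), 1, tolerance = 1e-12)
  expect_equal(sa$angle_deg, 90, tolerance = 1e-9)

  id <- rotation_to_axis_angle(rigid_transform())
  expect_true(id$no_rotation)
  expect_error(axis_direction(id), "undefined")

  # near-180 degrees uses the symmetric-part fallback
  sa180 <- rotation_to_axis_angle(rigid_transform(rotation_about_axis(c(1, 1, 0) / sqrt(2), 179.9999)))
  expect_equal(sa180$angle_deg, 179.9999, tolerance = 1e-6)
  expect_equal(abs(sum(sa180$direction * c(1, 1, 0) / sqrt(2))), 1, tolerance = 1e-6)
})

test_that("screw decomposition round-trips random rigid transforms", {
  withr::local_seed(31)
  for (i in 1:200) {
    tf <- random_transform()
    sa <- rotation_to_axis_angle(tf)
    back <- screw_to_transform(sa)
    expect_equal(back$R, tf$R, tolerance = 1e-9)
    expect_equal(back$t, tf$t, tolerance = 1e-9)
    # the axis point is a fixed point of the in-plane motion
    img <- apply_transform(matrix(sa$point, 1), tf)[1, ]
    expect_equal(img, sa$point + sa$translation_along_axis * sa$direction,
                 tolerance = 1e-8)
  }
})

test_that("planted hinge rotations are recovered exactly without noise", {
  ens <- make_two_domain_ensemble(n_res_a = 30, n_res_b = 20,
                                  angles_deg = c(0, 6, 15),
                                  hinge_axis = c(0, 0, 1), noise_sd = 0, seed = 1)
  fixed <- residue_selection(1:30); moving <- residue_selection(31:50)
  sa6 <- screw_axis_between(ens$members$m1, ens$members$m2, fixed, moving)
  sa15 <- screw_axis_between(ens$members$m1, ens$members$m3, fixed, moving)
  expect_equal(sa6$angle_deg, 6, tolerance = 1e-6)
  expect_equal(sa15$angle_deg, 15, tolerance = 1e-6)
  ang <- acos(min(1, abs(sum(axis_direction(sa6) * c(0, 0, 1)))))
  expect_lt(ang, 1e-6)
})

test_that("identical conformers give the no-rotation flag", {
  ens <- make_two_domain_ensemble(n_res_a = 20, n_res_b = 10, angles_deg = c(3, 3),
                                  noise_sd = 0, seed = 4)
  sa <- screw_axis_between(ens$members$m1, ens$members$m2,
                           residue_selection(1:20), residue_selection(21:30))
  expect_true(sa$no_rotation)
})

test_that("screw_axis_between is symmetric in its arguments", {
  ens <- make_two_domain_ensemble(n_res_a = 30, n_res_b = 20, angles_deg = c(0, 11),
                                  hinge_axis = c(0, 1, 1) / sqrt(2),
                                  noise_sd = 0, seed = 9)
  fixed <- residue_selection(1:30); moving <- residue_selection(31:50)
  ab <- screw_axis_between(ens$members$m1, ens$members$m2, fixed, moving)
  ba <- screw_axis_between(ens$members$m2, ens$members$m1, fixed, moving)
  expect_equal(ab$angle_deg, ba$angle_deg, tolerance = 1e-6)
  expect_equal(abs(sum(axis_direction(ab) * axis_direction(ba))), 1,
               tolerance = 1e-6)
})

test_that("recovered hinge angle degrades gracefully under coordinate noise", {
  for (s in 1:4) {
    ens <- make_two_domain_ensemble(n_res_a = 25, n_res_b = 25,
                                    angles_deg = c(0, 6), noise_sd = 0.3,
                                    seed = 100 + s)
    sa <- screw_axis_between(ens$members$m1, ens$members$m2,
                             residue_selection(1:25), residue_selection(26:50),
                             atom_set = "all_heavy")
    expect_equal(sa$angle_deg, 6, tolerance = 1 / 6)   # within 1 degree
  }
})

test_that("superposition beats randomly sampled rigid transforms", {
  withr::local_seed(55)
  P <- toy_cloud(15, seed = 3)
  Q <- apply_transform(P, random_transform()) + matrix(rnorm(45, 0, 0.5), ncol = 3)
  tf <- superpose(toy_model(P), toy_model(Q))
  for (i in 1:1000) {
    rnd <- random_transform()
    expect_gte(sqrt(mean(rowSums((apply_transform(P, rnd) - Q)^2))),
               tf$rmsd - 1e-12)
  }
})
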