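# Shrake-Rupley SASA against closed-form oracles; NLS detector behaviour.

lone_atom <- function(el = "C") {
  angtraj:::new_structure(make_atoms(1L, "UNK", el, el, matrix(c(0, 0, 0), 1)))
}

test_that("an isolated atom recovers the analytic sphere area", {
  cfg <- marker_config()
  for (el in c("C", "N", "O", "S")) {
    s <- lone_atom(el)
    r <- unname(angtraj:::.vdw_radii[el]) + cfg$sasa_probe_radius
    got <- shrake_rupley_sasa(matrix(c(0, 0, 0), 1), s, cfg)
    expect_equal(unname(got), 4 * pi * r^2, tolerance = 0.01)
  }
  expect_error(shrake_rupley_sasa(matrix(c(0, 0, 0), 1),
                                  lone_atom("FE"), cfg), "unknown element")
})

test_that("non-overlapping atoms each score the isolated-atom value", {
  cfg <- marker_config()
  at <- rbind(make_atoms(1L, "UNK", "C", "C", matrix(c(0, 0, 0), 1)),
              make_atoms(2L, "UNK", "C", "C", matrix(c(10, 0, 0), 1)))
  at$resnum <- 1:2
  s <- angtraj:::new_structure(at)
  got <- shrake_rupley_sasa(rbind(c(0, 0, 0), c(10, 0, 0)), s, cfg)
  expect_equal(unname(got), rep(4 * pi * 3.1^2, 2), tolerance = 0.01)
})

test_that("overlapping pairs match the spherical-cap closed form", {
  cfg <- marker_config(sasa_sphere_points = 2000)
  for (case in list(c("C", "C", 2.5), c("C", "O", 3.0), c("N", "S", 2.2),
                    c("O", "O", 1.8))) {
    els <- case[1:2]
    d <- as.numeric(case[3])
    at <- rbind(make_atoms(1L, "UNK", els[1], els[1], matrix(c(0, 0, 0), 1)),
                make_atoms(2L, "UNK", els[2], els[2], matrix(c(d, 0, 0), 1)))
    at$resnum <- 1:2
    s <- angtraj:::new_structure(at)
    got <- shrake_rupley_sasa(rbind(c(0, 0, 0), c(d, 0, 0)), s, cfg)
    oracle <- two_sphere_sasa(angtraj:::.vdw_radii[els[1]],
                              angtraj:::.vdw_radii[els[2]], d,
                              cfg$sasa_probe_radius)
    expect_equal(unname(got), unname(oracle), tolerance = 0.02)
  }
})

test_that("SASA and gyration are invariant under rigid transforms", {
  s <- ang_model_fixture()
  tr <- generate_trajectory(synthetic_spec(s, n_frames = 2, noise_sigma = 0.1,
                                           compaction_factor = 0.2, seed = 2))
  cfg <- marker_config()
  base <- nls_features(tr, cfg)
  set.seed(4)
  rot <- random_rotation()
  shift <- rnorm(3, sd = 20)
  moved <- traj_from_frames(s, lapply(1:2, function(i)
    sweep(frame_coords(tr, i) %*% rot, 2, shift, "+")))
  got <- nls_features(moved, cfg)
  expect_equal(got$series$rrr_gyration, base$series$rrr_gyration,
               tolerance = 1e-6)
  # point lattices do not co-rotate, so SASA matches to quadrature accuracy
  expect_equal(got$mean_total, base$mean_total, tolerance = 0.01)
  expect_equal(got$mean_gyration, base$mean_gyration, tolerance = 1e-6)
})

test_that("NLS detector requires arginines at 31-33 and sees compaction", {
  s <- ang_model_fixture()
  quiet <- generate_trajectory(synthetic_spec(s, n_frames = 3, seed = 6,
                                              noise_sigma = 0))
  f0 <- nls_features(quiet, marker_config())
  expect_equal(diff(range(f0$series$sasa_r31)), 0, tolerance = 1e-9)
  compacted <- generate_trajectory(synthetic_spec(s, n_frames = 3, seed = 6,
                                                  noise_sigma = 0,
                                                  compaction_factor = 0.3))
  f1 <- nls_features(compacted, marker_config())
  expect_lt(f1$mean_total, f0$mean_total)
  expect_lt(f1$mean_gyration, f0$mean_gyration)

  renum <- s
  renum$atoms$resnum <- renum$atoms$resnum + 5L
  tr2 <- traj_from_frames(renum, list(angtraj:::coords_of(renum),
                                      angtraj:::coords_of(renum)))
  expect_error(nls_features(tr2, marker_config()), "not ARG")
})
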