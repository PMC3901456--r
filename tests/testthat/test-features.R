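# Backbone RMSD series, rotamer-state tracking, and the feature aggregator.

test_that("identical or rigidly transformed frames give zero backbone RMSD", {
  s <- ang_model_fixture()
  b <- angtraj:::coords_of(s)
  tr <- traj_from_frames(s, list(b, b, b))
  r <- backbone_rmsd_series(tr)
  expect_equal(r$rmsd, rep(0, 3), tolerance = 1e-9)
  expect_equal(r$time_ps, c(0, 1, 2))

  set.seed(9)
  frames <- c(list(b), lapply(1:3, function(i)
    sweep(b %*% random_rotation(), 2, rnorm(3, sd = 8), "+")))
  r2 <- backbone_rmsd_series(traj_from_frames(s, frames))
  expect_lt(max(r2$rmsd), 1e-6)
})

test_that("backbone RMSD of isotropic noise matches the fitted-DOF theory", {
  s <- ang_model_fixture()
  b <- angtraj:::coords_of(s)
  sigma <- 0.5
  set.seed(23)
  frames <- c(list(b), lapply(1:40, function(i)
    b + matrix(rnorm(length(b), sd = sigma), ncol = 3)))
  r <- backbone_rmsd_series(traj_from_frames(s, frames))
  nbb <- sum(s$atoms$name %in% c("N", "CA", "C", "O"))
  theory <- sigma * sqrt(3) * sqrt(1 - 6 / nbb)
  expect_equal(mean(r$rmsd[-1]), theory, tolerance = 0.05)
})

test_that("missing backbone atoms are reported by residue", {
  s <- ang_model_fixture()
  drop <- which(s$atoms$resnum == 50 & s$atoms$name == "O")
  s$atoms <- s$atoms[-drop, ]
  tr <- traj_from_frames(s, list(angtraj:::coords_of(s), angtraj:::coords_of(s)))
  expect_error(backbone_rmsd_series(tr), "residue 50")
})

test_that("rotamer states derive from chi1 and switching counts are exact", {
  s <- ang_model_fixture()
  quiet <- generate_trajectory(synthetic_spec(s, n_frames = 10, seed = 2))
  ch <- chi_series(quiet, 114)
  expect_equal(ch$native_state, "g+")
  expect_equal(ch$switch_fraction, 0)
  expect_equal(ch$series$chi1[1] %% 360, 300, tolerance = 1e-6)

  inj <- generate_trajectory(synthetic_spec(s, n_frames = 10, seed = 2,
                                            switch_fraction_target = 0.3))
  ch2 <- chi_series(inj, 114)
  expect_equal(ch2$switch_fraction, 0.3)
  # the rotated frames land exactly 120 degrees away, in a single other bin
  other <- unique(ch2$series$state[ch2$series$state != ch2$native_state])
  expect_equal(length(other), 1L)

  expect_error(chi_series(quiet, 999), "no residue")
})

test_that("dihedrals and states are invariant under rigid transforms", {
  s <- ang_model_fixture()
  tr <- generate_trajectory(synthetic_spec(s, n_frames = 3, seed = 8,
                                           switch_fraction_target = 0.3,
                                           noise_sigma = 0.05))
  ref <- chi_series(tr, 114)
  set.seed(31)
  rot <- random_rotation()
  moved <- traj_from_frames(s, lapply(1:3, function(i)
    sweep(frame_coords(tr, i) %*% rot, 2, c(3, -7, 11), "+")))
  got <- chi_series(moved, 114)
  expect_equal(got$series$chi1, ref$series$chi1, tolerance = 1e-6)
  expect_equal(got$series$state, ref$series$state)
})

test_that("extract_features populates all markers and respects the WT contract", {
  s <- ang_model_fixture()
  wt <- generate_trajectory(make_preset("wt_like", base = s, seed = 12,
                                        n_frames = 10))
  fw <- extract_features(wt)
  expect_s3_class(fw, "feature_set")
  expect_equal(fw$his114$switch_fraction, 0)
  expect_true(is.na(fw$path_persistence))
  expect_null(fw$best_path)
  expect_lt(fw$rmsd$window_mean, 0.3)  # flat apart from 0.1 A jitter
  expect_equal(fw$rmsd$series$rmsd[1], 0)

  k17i <- generate_trajectory(make_preset("k17i_like", base = s, seed = 12,
                                          n_frames = 10))
  fm <- extract_features(k17i, "K17I")
  expect_gte(fm$his114$switch_fraction, fm$config$switch_threshold)
  expect_gte(fm$path_persistence, fm$config$path_threshold)
  expect_true(fm$best_path$mediated)
  expect_true(115 %in% fm$best_path$residues)

  empty <- angtraj:::new_trajectory(s, matrix(numeric(0), nrow = 0,
                                              ncol = 3 * nrow(s$atoms)))
  expect_error(extract_features(empty), "empty trajectory")
})
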