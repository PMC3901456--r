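# Verdict logic: mechanism rules, monotonicity, purity.

features_pair <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      s <- ang_model_fixture()
      wt <- generate_trajectory(make_preset("wt_like", base = s, seed = 20,
                                            n_frames = 10))
      mu <- generate_trajectory(make_preset("k17i_like", base = s, seed = 21,
                                            n_frames = 10))
      cache <<- list(wt = extract_features(wt),
                     mut = extract_features(mu, "K17I"))
    }
    cache
  }
})

test_that("self-comparison of wild-type features is benign and the relative
           rules never fire on self-comparison", {
  fp <- features_pair()
  v <- classify(fp$wt, fp$wt)
  expect_false(v$deleterious)
  expect_false(v$loss_ribonucleolytic)
  expect_false(v$loss_nuclear_translocation)
  expect_false(v$destabilized)
  # the ribonucleolytic rule reads absolute mutant attributes, so a switching
  # mutant stays flagged even against itself; the relative rules do not fire
  vm <- classify(fp$mut, fp$mut)
  expect_false(vm$loss_nuclear_translocation)
  expect_false(vm$destabilized)
  expect_equal(vm$deleterious, vm$loss_ribonucleolytic)
})

test_that("the ribonucleolytic rule needs switching and the mediated path", {
  fp <- features_pair()
  v <- classify(fp$mut, fp$wt)
  expect_true(v$loss_ribonucleolytic)
  expect_true(v$deleterious)
  expect_false(v$loss_nuclear_translocation)
  expect_false(v$destabilized)
  # remove the path: AND rule drops the call, OR rule keeps it
  nopath <- fp$mut
  nopath$path_persistence <- 0
  expect_false(classify(nopath, fp$wt)$loss_ribonucleolytic)
  cfg_or <- marker_config(ribo_rule = "or")
  nopath_or <- nopath; nopath_or$config <- cfg_or
  wt_or <- fp$wt; wt_or$config <- cfg_or
  expect_true(classify(nopath_or, wt_or)$loss_ribonucleolytic)
})

test_that("verdicts are monotone in the ribonucleolytic statistics", {
  fp <- features_pair()
  base <- classify(fp$mut, fp$wt)
  expect_true(base$deleterious)
  for (bump in list(c("switch", 0.2), c("path", 0.3))) {
    worse <- fp$mut
    if (bump[1] == "switch")
      worse$his114$switch_fraction <- min(1, worse$his114$switch_fraction +
                                            as.numeric(bump[2]))
    else
      worse$path_persistence <- min(1, worse$path_persistence +
                                      as.numeric(bump[2]))
    expect_true(classify(worse, fp$wt)$deleterious)
  }
})

test_that("the stability rule fires on excess window-mean RMSD", {
  fp <- features_pair()
  drifted <- fp$mut
  drifted$rmsd$window_mean <- fp$wt$rmsd$window_mean +
    fp$mut$config$rmsd_margin + 0.5
  v <- classify(drifted, fp$wt)
  expect_true(v$destabilized)
  expect_true(v$deleterious)
  near <- fp$mut
  near$rmsd$window_mean <- fp$wt$rmsd$window_mean + fp$mut$config$rmsd_margin - 0.1
  expect_false(classify(near, fp$wt)$destabilized)
})

test_that("the nuclear-translocation rule needs both SASA and folding", {
  fp <- features_pair()
  folded <- fp$mut
  folded$nls$mean_total <- fp$wt$nls$mean_total * 0.7      # 30% SASA drop
  folded$nls$mean_gyration <- fp$wt$nls$mean_gyration * 0.8 # 20% gyration drop
  expect_true(classify(folded, fp$wt)$loss_nuclear_translocation)
  sasa_only <- fp$mut
  sasa_only$nls$mean_total <- fp$wt$nls$mean_total * 0.7
  expect_false(classify(sasa_only, fp$wt)$loss_nuclear_translocation)
})

test_that("classification is pure and rejects mismatched configurations", {
  fp <- features_pair()
  v1 <- classify(fp$mut, fp$wt)
  v2 <- classify(fp$mut, fp$wt)
  expect_identical(v1, v2)
  expect_true(all(c("switch_fraction", "path_persistence") %in%
                    names(v1$evidence$loss_ribonucleolytic)))
  other <- fp$wt
  other$config <- marker_config(switch_threshold = 0.4)
  expect_error(classify(fp$mut, other), "different configurations")
})
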