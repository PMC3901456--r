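# Rule-based deleterious/benign classification from mutant and wild-type
# feature sets.

#' Classify a mutant trajectory against its wild-type control
#'
#' Applies the three mechanism rules:
#' \itemize{
#'   \item loss of ribonucleolytic activity: His114 spent at least
#'     `switch_threshold` of frames outside its native rotamer bin AND a
#'     Leu115-mediated hydrogen-bond path from the mutation site to His114 was
#'     present in at least `path_threshold` of frames (rule combinator
#'     configurable via `ribo_rule`);
#'   \item loss of nuclear translocation: window-mean total SASA of R31-R33
#'     reduced relative to wild type by at least `sasa_reduction_threshold` AND
#'     their side-chain gyration radius reduced by at least `fold_threshold`
#'     (local folding / close packing);
#'   \item destabilized: mutant window-mean backbone RMSD exceeds the wild-type
#'     value by more than `rmsd_margin`.
#' }
#' The overall call is deleterious when any flag is raised, benign otherwise.
#'
#' @param mut,wt `feature_set`s computed under the same configuration
#'   ([extract_features()]); a configuration mismatch is an error.
#' @param cfg Optional config override for the thresholds; defaults to the
#'   configuration stored in the feature sets.
#' @return An `ang_verdict`: logical flags `loss_ribonucleolytic`,
#'   `loss_nuclear_translocation`, `destabilized`, `deleterious`, and an
#'   `evidence` record (statistic, threshold, wild-type baseline per flag).
#' @export
classify <- function(mut, wt, cfg = NULL) {
  stopifnot(inherits(mut, "feature_set"), inherits(wt, "feature_set"))
  if (!identical(mut$config, wt$config))
    stop("feature sets were computed under different configurations")
  if (is.null(cfg)) cfg <- mut$config
  stopifnot(inherits(cfg, "marker_config"))

  switch_frac <- mut$his114$switch_fraction
  path_frac <- if (is.na(mut$path_persistence)) 0 else mut$path_persistence
  switching <- switch_frac >= cfg$switch_threshold
  pathy <- path_frac >= cfg$path_threshold
  loss_ribo <- if (cfg$ribo_rule == "and") switching && pathy
               else switching || pathy

  sasa_red <- (wt$nls$mean_total - mut$nls$mean_total) / wt$nls$mean_total
  fold_red <- (wt$nls$mean_gyration - mut$nls$mean_gyration) / wt$nls$mean_gyration
  loss_nt <- sasa_red >= cfg$sasa_reduction_threshold &&
    fold_red >= cfg$fold_threshold

  rmsd_excess <- mut$rmsd$window_mean - wt$rmsd$window_mean
  destab <- rmsd_excess > cfg$rmsd_margin

  evidence <- list(
    loss_ribonucleolytic = list(
      switch_fraction = switch_frac, switch_threshold = cfg$switch_threshold,
      native_state = mut$his114$native_state,
      path_persistence = path_frac, path_threshold = cfg$path_threshold,
      best_path = if (!is.null(mut$best_path)) mut$best_path$residues,
      rule = cfg$ribo_rule,
      baseline_switch_fraction = wt$his114$switch_fraction
    ),
    loss_nuclear_translocation = list(
      mut_sasa = mut$nls$mean_total, wt_sasa = wt$nls$mean_total,
      sasa_reduction = sasa_red,
      sasa_reduction_threshold = cfg$sasa_reduction_threshold,
      mut_gyration = mut$nls$mean_gyration, wt_gyration = wt$nls$mean_gyration,
      fold_reduction = fold_red, fold_threshold = cfg$fold_threshold
    ),
    destabilized = list(
      mut_rmsd = mut$rmsd$window_mean, wt_rmsd = wt$rmsd$window_mean,
      rmsd_excess = rmsd_excess, rmsd_margin = cfg$rmsd_margin
    )
  )
  structure(list(
    mutation = if (!is.null(mut$mutation)) format(mut$mutation),
    loss_ribonucleolytic = loss_ribo,
    loss_nuclear_translocation = loss_nt,
    destabilized = destab,
    deleterious = loss_ribo || loss_nt || destab,
    evidence = evidence
  ), class = "ang_verdict")
}

#' Human-readable verdict report
#'
#' @param v An `ang_verdict`.
#' @return Character vector of report lines.
#' @export
verdict_report <- function(v) {
  stopifnot(inherits(v, "ang_verdict"))
  ev <- v$evidence
  lines <- c(
    sprintf("Mutation: %s", v$mutation %||% "(none given)"),
    sprintf("Overall call: %s", if (v$deleterious) "DELETERIOUS" else "BENIGN"),
    "",
    sprintf("Ribonucleolytic activity: %s",
            if (v$loss_ribonucleolytic) "predicted LOSS" else "retained"),
    sprintf("  His114 conformational switching: %.1f%% of frames outside native bin '%s' (threshold %.0f%%)",
            100 * ev$loss_ribonucleolytic$switch_fraction,
            ev$loss_ribonucleolytic$native_state,
            100 * ev$loss_ribonucleolytic$switch_threshold),
    sprintf("  Leu115-mediated H-bond path to His114: present in %.1f%% of frames (threshold %.0f%%)",
            100 * ev$loss_ribonucleolytic$path_persistence,
            100 * ev$loss_ribonucleolytic$path_threshold)
  )
  if (!is.null(ev$loss_ribonucleolytic$best_path))
    lines <- c(lines, sprintf("  modal path: %s",
                              paste(ev$loss_ribonucleolytic$best_path, collapse = "-")))
  lines <- c(lines,
    "",
    sprintf("Nuclear translocation activity: %s",
            if (v$loss_nuclear_translocation) "predicted LOSS" else "retained"),
    sprintf("  SASA of NLS residues 31RRR33: %.1f A^2 vs wild-type %.1f A^2 (reduction %.1f%%, threshold %.0f%%)",
            ev$loss_nuclear_translocation$mut_sasa,
            ev$loss_nuclear_translocation$wt_sasa,
            100 * ev$loss_nuclear_translocation$sasa_reduction,
            100 * ev$loss_nuclear_translocation$sasa_reduction_threshold),
    sprintf("  RRR side-chain gyration: %.2f A vs wild-type %.2f A (reduction %.1f%%, threshold %.0f%%)",
            ev$loss_nuclear_translocation$mut_gyration,
            ev$loss_nuclear_translocation$wt_gyration,
            100 * ev$loss_nuclear_translocation$fold_reduction,
            100 * ev$loss_nuclear_translocation$fold_threshold),
    "",
    sprintf("Stability: %s",
            if (v$destabilized) "destabilized" else "comparable to wild type"),
    sprintf("  window-mean backbone RMSD: %.2f A vs wild-type %.2f A (margin %.1f A)",
            ev$destabilized$mut_rmsd, ev$destabilized$wt_rmsd,
            ev$destabilized$rmsd_margin)
  )
  lines
}

#' @export
print.ang_verdict <- function(x, ...) {
  cat(verdict_report(x), sep = "\n")
  invisible(x)
}
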