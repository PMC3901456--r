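# Backbone RMSD, His114 rotamer-state tracking, and the FeatureSet aggregator.

#' Backbone RMSD versus the first frame
#'
#' RMSD of the backbone N, CA, C, O atoms of all polymer residues against
#' frame 0 after optimal rigid superposition ([kabsch_superpose()]). One value
#' per frame; the first value is zero by construction.
#'
#' @param t A `pdb_trajectory`.
#' @return Data frame with `time_ps` and `rmsd` (Angstrom).
#' @export
backbone_rmsd_series <- function(t) {
  stopifnot(inherits(t, "pdb_trajectory"))
  a <- t$topology$atoms
  bb <- which(!a$het & a$name %in% .backbone_names & a$element != "H")
  res_keys <- unique(paste(a$chain[!a$het], a$resnum[!a$het]))
  for (key in res_keys) {
    parts <- strsplit(key, " ")[[1]]
    have <- a$name[bb][a$chain[bb] == parts[1] & a$resnum[bb] == as.integer(parts[2])]
    miss <- setdiff(.backbone_names, have)
    if (length(miss) > 0)
      stop("missing backbone atom(s) ", paste(miss, collapse = ", "),
           " in residue ", parts[2], " chain ", parts[1])
  }
  n <- n_frames(t)
  ref <- frame_coords(t, 1)[bb, , drop = FALSE]
  vals <- vapply(seq_len(n), function(i) {
    if (i == 1) return(0)
    kabsch_superpose(frame_coords(t, i)[bb, , drop = FALSE], ref)$rmsd
  }, numeric(1))
  data.frame(time_ps = (seq_len(n) - 1) * t$dt_ps, rmsd = vals)
}

chi1_state <- function(chi_deg, cfg) {
  x <- chi_deg %% 360
  cfg$chi1_labels[findInterval(x, cfg$chi1_breaks, rightmost.closed = FALSE)]
}

#' Side-chain dihedral (chi1/chi2) and rotamer-state series
#'
#' Computes chi1 (N-CA-CB-X) and, where defined, chi2 per frame for one
#' residue; discretises chi1 into the three 120-degree rotamer bins and reports
#' the fraction of frames spent outside the frame-0 (native) bin. For His114
#' that fraction is the conformational-switching statistic.
#'
#' @param t A `pdb_trajectory`.
#' @param residue Residue number (default: the catalytic histidine in `cfg`).
#' @param cfg A [marker_config()].
#' @return A `chi_state_series`: `residue`, `resname`, `series` data frame
#'   (`time_ps`, `chi1`, `chi2`, `state`), `native_state`, `switch_fraction`.
#' @export
chi_series <- function(t, residue = NULL, cfg = marker_config()) {
  stopifnot(inherits(t, "pdb_trajectory"))
  if (is.null(residue)) residue <- cfg$catalytic_his
  a <- t$topology$atoms
  idx <- which(!a$het & a$resnum == residue)
  if (length(idx) == 0) stop("no residue at position ", residue)
  resname <- unique(a$resname[idx])
  chi1_atom <- .chi1_fourth[resname]
  if (is.na(chi1_atom)) stop("chi1 undefined for residue type ", resname)
  need1 <- c("N", "CA", "CB", unname(chi1_atom))
  i1 <- idx[match(need1, a$name[idx])]
  if (anyNA(i1))
    stop("residue ", residue, " lacks side-chain atom(s) ",
         paste(need1[is.na(i1)], collapse = ", "))
  chi2_atom <- .chi2_fourth[resname]
  i2 <- NULL
  if (!is.na(chi2_atom)) {
    need2 <- c("CA", "CB", unname(chi1_atom), unname(chi2_atom))
    i2 <- idx[match(need2, a$name[idx])]
    if (anyNA(i2)) i2 <- NULL
  }
  n <- n_frames(t)
  chi1 <- numeric(n)
  chi2 <- rep(NA_real_, n)
  for (k in seq_len(n)) {
    fc <- frame_coords(t, k)
    chi1[k] <- dihedral_angle(fc[i1[1], ], fc[i1[2], ], fc[i1[3], ], fc[i1[4], ])
    if (!is.null(i2))
      chi2[k] <- dihedral_angle(fc[i2[1], ], fc[i2[2], ], fc[i2[3], ], fc[i2[4], ])
  }
  state <- chi1_state(chi1, cfg)
  structure(list(
    residue = residue, resname = resname,
    series = data.frame(time_ps = (seq_len(n) - 1) * t$dt_ps,
                        chi1 = chi1, chi2 = chi2, state = state),
    native_state = state[1],
    switch_fraction = mean(state != state[1])
  ), class = "chi_state_series")
}

#' @export
print.chi_state_series <- function(x, ...) {
  cat("chi_state_series:", x$resname, x$residue, "- native", x$native_state,
      "- switch fraction", round(x$switch_fraction, 3), "\n")
  invisible(x)
}

#' Extract the four trajectory markers
#'
#' Runs all marker detectors on one trajectory: backbone RMSD series, His114
#' rotamer switching, persistence of the Leu115-mediated hydrogen-bond path
#' from the mutation site to His114 (mutant trajectories only), and SASA plus
#' compaction of the NLS arginines.
#'
#' @param t A `pdb_trajectory`.
#' @param m Mutation token / `mutation_spec`, or `NULL` for a wild-type
#'   trajectory (path fields are then absent).
#' @param cfg A [marker_config()].
#' @return A `feature_set` with components `rmsd` (list: `series`,
#'   `window_mean`), `his114` (`chi_state_series`), `path_persistence`
#'   (fraction or `NA` for wild type), `best_path`, `nls` (`sasa_series`),
#'   `mutation`, `config`.
#' @export
extract_features <- function(t, m = NULL, cfg = marker_config()) {
  stopifnot(inherits(t, "pdb_trajectory"))
  n <- n_frames(t)
  if (n < 1) stop("empty trajectory")
  rmsd <- backbone_rmsd_series(t)
  win <- window_indices(n, cfg$analysis_window)
  his <- chi_series(t, cfg$catalytic_his, cfg)
  nls <- nls_features(t, cfg)
  pp <- NULL
  if (!is.null(m)) {
    m <- parse_mutation(m)
    pp <- path_persistence(t, m, cfg)
  }
  structure(list(
    rmsd = list(series = rmsd, window_mean = mean(rmsd$rmsd[win])),
    his114 = his,
    path_persistence = if (is.null(pp)) NA_real_ else pp$fraction,
    best_path = if (is.null(pp)) NULL else pp$best_path,
    nls = nls,
    mutation = if (is.null(m)) NULL else m,
    config = cfg
  ), class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat("feature_set", if (!is.null(x$mutation)) format(x$mutation) else "(wild type)", "\n")
  cat("  backbone RMSD window mean:", round(x$rmsd$window_mean, 3), "A\n")
  cat("  His114 switch fraction:   ", round(x$his114$switch_fraction, 3), "\n")
  if (!is.na(x$path_persistence)) {
    cat("  mediated-path persistence:", round(x$path_persistence, 3), "\n")
    if (!is.null(x$best_path))
      cat("  modal path:", paste(x$best_path$residues, collapse = "-"), "\n")
  }
  cat("  NLS RRR SASA window mean: ", round(x$nls$mean_total, 1), "A^2;",
      "gyration", round(x$nls$mean_gyration, 2), "A\n")
  invisible(x)
}
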