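# Detector configuration: thresholds, geometry parameters, and the residue
# conventions of mature angiogenin numbering (catalytic His114, mediator
# Leu115, NLS arginines 31-33).

#' Marker-detector configuration
#'
#' Houses every tunable the four marker detectors and the classifier read.
#' The hydrogen-bond cutoff (3.2 Angstrom, donor-acceptor heavy-atom distance)
#' is the published criterion; the decision thresholds are configurable
#' defaults, declared here because the published protocol does not print them.
#'
#' @param hbond_cutoff Donor-acceptor heavy-atom distance cutoff, Angstrom.
#' @param hbond_angle_min Optional minimal D-H...A angle in degrees (applied
#'   only when hydrogens are present in the input); `NULL` (default) disables
#'   the angle term, matching the published distance-only criterion.
#' @param sasa_probe_radius Solvent probe radius, Angstrom (water, 1.4).
#' @param sasa_sphere_points Number of quasi-uniform test points per atom.
#' @param switch_threshold Minimum fraction of frames His114 must spend outside
#'   its frame-0 rotamer bin to call conformational switching.
#' @param path_threshold Minimum fraction of frames with a Leu115-mediated
#'   hydrogen-bond path from the mutation site to His114.
#' @param sasa_reduction_threshold Minimum relative reduction of window-mean
#'   total R31-R33 SASA versus wild type.
#' @param fold_threshold Minimum relative reduction of window-mean R31-R33
#'   side-chain radius of gyration versus wild type (local folding).
#' @param rmsd_margin Excess of mutant over wild-type window-mean backbone RMSD
#'   (Angstrom) beyond which the mutant is called destabilized.
#' @param analysis_window Final fraction of frames used for window means.
#' @param ribo_rule `"and"` (default) requires both switching and the mediated
#'   path for the ribonucleolytic-loss call; `"or"` accepts either (sensitivity
#'   analysis).
#' @param catalytic_his,mediator,nls_residues Residue numbers of the monitored
#'   sites in mature-angiogenin numbering; change only for renumbered inputs.
#' @return A `marker_config` list.
#' @export
marker_config <- function(hbond_cutoff = 3.2,
                          hbond_angle_min = NULL,
                          sasa_probe_radius = 1.4,
                          sasa_sphere_points = 960,
                          switch_threshold = 0.20,
                          path_threshold = 0.10,
                          sasa_reduction_threshold = 0.20,
                          fold_threshold = 0.10,
                          rmsd_margin = 1.0,
                          analysis_window = 0.5,
                          ribo_rule = c("and", "or"),
                          catalytic_his = 114L,
                          mediator = 115L,
                          nls_residues = 31:33) {
  ribo_rule <- match.arg(ribo_rule)
  cfg <- list(
    hbond_cutoff = hbond_cutoff, hbond_angle_min = hbond_angle_min,
    sasa_probe_radius = sasa_probe_radius,
    sasa_sphere_points = as.integer(sasa_sphere_points),
    chi1_breaks = c(0, 120, 240, 360),
    chi1_labels = c("g-", "t", "g+"),
    switch_threshold = switch_threshold, path_threshold = path_threshold,
    sasa_reduction_threshold = sasa_reduction_threshold,
    fold_threshold = fold_threshold, rmsd_margin = rmsd_margin,
    analysis_window = analysis_window, ribo_rule = ribo_rule,
    catalytic_his = as.integer(catalytic_his),
    mediator = as.integer(mediator),
    nls_residues = as.integer(nls_residues)
  )
  validate_config(cfg)
  structure(cfg, class = "marker_config")
}

validate_config <- function(cfg) {
  pos <- c("hbond_cutoff", "sasa_probe_radius", "rmsd_margin")
  for (f in pos)
    if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0) stop(f, " must be > 0")
  frac <- c("switch_threshold", "path_threshold", "sasa_reduction_threshold",
            "fold_threshold", "analysis_window")
  for (f in frac)
    if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0 || cfg[[f]] >= 1)
      stop(f, " must lie in (0, 1)")
  if (cfg$sasa_sphere_points < 16) stop("sasa_sphere_points too small")
  if (!identical(cfg$chi1_breaks, c(0, 120, 240, 360)))
    stop("chi1 bins must partition [0, 360)")
  invisible(cfg)
}

#' Read a detector configuration from a flat key = value file
#'
#' Unknown keys are rejected; missing keys take their defaults.
#' @param path Path to a text file of `key = value` lines (`#` comments allowed).
#' @return A `marker_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  kv <- parse_kv(path)
  allowed <- setdiff(names(formals(marker_config)), "ribo_rule")
  bad <- setdiff(names(kv), c(allowed, "ribo_rule"))
  if (length(bad) > 0) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  args <- lapply(seq_along(kv), function(i) {
    if (names(kv)[i] == "ribo_rule") kv[[i]]
    else as.numeric(strsplit(kv[[i]], "[ ,]+")[[1]])
  })
  names(args) <- names(kv)
  do.call(marker_config, args)
}

#' Write a detector configuration as a flat key = value file
#' @param cfg A `marker_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "marker_config"))
  skip <- c("chi1_breaks", "chi1_labels")
  keys <- setdiff(names(cfg), skip)
  lines <- vapply(keys, function(k) {
    v <- cfg[[k]]
    if (is.null(v)) return(sprintf("# %s =", k))
    sprintf("%s = %s", k, paste(v, collapse = " "))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

parse_kv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  parts <- regmatches(lines, regexec("^([A-Za-z0-9_]+)\\s*=\\s*(.*)$", lines))
  bad <- vapply(parts, length, 1L) != 3L
  if (any(bad)) stop("cannot parse config line: ", lines[bad][1])
  vals <- vapply(parts, `[`, character(1), 3)
  names(vals) <- vapply(parts, `[`, character(1), 2)
  as.list(vals)
}

#' @export
print.marker_config <- function(x, ...) {
  cat("marker_config: hbond cutoff", x$hbond_cutoff, "A; thresholds: switch",
      x$switch_threshold, "path", x$path_threshold, "sasa",
      x$sasa_reduction_threshold, "fold", x$fold_threshold, "rmsd margin",
      x$rmsd_margin, "A\n")
  invisible(x)
}
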