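# Synthetic trajectory generator: injects each trajectory marker independently
# at known strength into a base structure, so every detector and the classifier
# can be validated without running molecular dynamics. The constructions are
# geometric, not physical; they emulate only the statistical structure the
# detectors read (rotamer-bin occupancy, contact persistence, side-chain
# compaction, progressive backbone drift, isotropic positional noise).

#' Specification of a synthetic trajectory
#'
#' @param base A `pdb_structure` the frames are derived from (typically
#'   [build_ang_model()], possibly after [mutate_residue()]).
#' @param n_frames Number of frames (>= 2; frame 1 stays native).
#' @param dt_ps Frame interval in ps.
#' @param noise_sigma Isotropic Gaussian jitter per atom per axis, Angstrom.
#' @param switch_fraction_target Fraction of frames whose His114 chi1 is
#'   rotated by exactly 120 degrees into the adjacent rotamer bin
#'   (`round(target * n_frames)` frames, never frame 1).
#' @param path_persistence_target Fraction of frames in which the hydrogen-bond
#'   contacts along `path_residues` are created (donor pulled to 3.0 Angstrom
#'   of an acceptor for every consecutive residue pair).
#' @param path_residues List of integer vectors: residue paths whose
#'   consecutive pairs receive injected contacts (branches allowed as extra
#'   vectors). Required when `path_persistence_target > 0`.
#' @param compaction_factor Fractional displacement of the R31-R33 side-chain
#'   atoms toward their common centroid (applied in every frame).
#' @param drift_amplitude Progressive coherent displacement, Angstrom; frame k
#'   moves each residue by `drift_amplitude * (k-1)/(n_frames-1)` along a fixed
#'   random per-residue direction, so the final frame's backbone RMSD is close
#'   to the amplitude.
#' @param seed Integer seed; generation is fully reproducible.
#' @param preset,mutation Optional bookkeeping fields set by [make_preset()].
#' @return A `synthetic_spec`.
#' @export
synthetic_spec <- function(base, n_frames = 100L, dt_ps = 1,
                           noise_sigma = 0,
                           switch_fraction_target = 0,
                           path_persistence_target = 0,
                           path_residues = NULL,
                           compaction_factor = 0,
                           drift_amplitude = 0,
                           seed = 1L,
                           preset = NULL, mutation = NULL) {
  stopifnot(inherits(base, "pdb_structure"))
  n_frames <- as.integer(n_frames)
  if (n_frames < 2L) stop("n_frames must be >= 2")
  for (f in c(switch_fraction_target, path_persistence_target, compaction_factor))
    if (f < 0 || f > 1) stop("fractions must lie in [0, 1]")
  if (noise_sigma < 0 || drift_amplitude < 0) stop("amplitudes must be >= 0")
  if (round(switch_fraction_target * n_frames) > n_frames - 1L)
    stop("switch fraction too high: frame 1 must remain in the native rotamer")
  a <- base$atoms
  if (switch_fraction_target > 0 &&
      !any(!a$het & a$resnum == 114L & a$resname == "HIS"))
    stop("base lacks His114; cannot inject rotamer switching")
  if (path_persistence_target > 0) {
    if (is.null(path_residues)) stop("path_residues required for path injection")
    if (is.numeric(path_residues)) path_residues <- list(as.integer(path_residues))
    missing <- setdiff(unique(unlist(path_residues)), a$resnum[!a$het])
    if (length(missing) > 0)
      stop("path residues absent from base: ", paste(missing, collapse = ", "))
  }
  structure(list(
    base = base, n_frames = n_frames, dt_ps = dt_ps,
    noise_sigma = noise_sigma,
    switch_fraction_target = switch_fraction_target,
    path_persistence_target = path_persistence_target,
    path_residues = path_residues,
    compaction_factor = compaction_factor,
    drift_amplitude = drift_amplitude,
    seed = as.integer(seed), preset = preset, mutation = mutation
  ), class = "synthetic_spec")
}

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic trajectory from a specification
#'
#' Frame 1 is the (noise-free aside, unmodified) base conformation; exactly
#' `round(switch_fraction_target * n_frames)` later frames carry the His114
#' rotamer switch, exactly `round(path_persistence_target * n_frames)` frames
#' carry the injected hydrogen-bond path contacts at 3.0 Angstrom, compaction
#' applies to all frames, and drift grows linearly with frame index.
#'
#' @param spec A [synthetic_spec()].
#' @return A `pdb_trajectory`.
#' @export
generate_trajectory <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  base <- spec$base
  a <- base$atoms
  b_xyz <- coords_of(base)
  n <- spec$n_frames
  natoms <- nrow(a)

  his_idx <- which(!a$het & a$resnum == 114L & a$resname == "HIS")
  his_rot <- his_idx[!a$name[his_idx] %in% c("N", "CA", "C", "O", "OXT", "CB")]
  his_ca <- his_idx[match("CA", a$name[his_idx])]
  his_cb <- his_idx[match("CB", a$name[his_idx])]

  nls_idx <- which(!a$het & a$resnum %in% 31:33 & a$element != "H" &
                     !a$name %in% c("N", "CA", "C", "O", "OXT"))

  pairs <- NULL
  if (spec$path_persistence_target > 0) {
    paths <- spec$path_residues
    if (is.numeric(paths)) paths <- list(paths)
    pairs <- do.call(rbind, lapply(paths, function(p)
      cbind(p[-length(p)], p[-1])))
  }
  roles <- hbond_roles(base)

  xyz <- matrix(NA_real_, n, 3L * natoms)
  with_seed(spec$seed, {
    drift_field <- NULL
    if (spec$drift_amplitude > 0) {
      ures <- unique(a$resnum)
      g <- matrix(stats::rnorm(3 * length(ures)), ncol = 3)
      g <- sweep(g, 2, colMeans(g))
      g <- g / sqrt(rowSums(g^2))
      drift_field <- g[match(a$resnum, ures), , drop = FALSE]
    }
    k_sw <- round(spec$switch_fraction_target * n)
    switch_frames <- if (k_sw > 0) sample(2:n, k_sw) else integer()
    k_p <- round(spec$path_persistence_target * n)
    path_frames <- if (k_p > 0) sample(seq_len(n), k_p) else integer()

    for (k in seq_len(n)) {
      x <- b_xyz
      if (!is.null(drift_field))
        x <- x + spec$drift_amplitude * (k - 1) / (n - 1) * drift_field
      if (spec$noise_sigma > 0)
        x <- x + matrix(stats::rnorm(length(x), sd = spec$noise_sigma),
                        ncol = 3)
      if (k %in% switch_frames)
        x[his_rot, ] <- rotate_about_axis(x[his_rot, , drop = FALSE],
                                          x[his_ca, ],
                                          x[his_cb, ] - x[his_ca, ], 120)
      if (spec$compaction_factor > 0 && length(nls_idx) > 0) {
        cen <- colMeans(x[nls_idx, , drop = FALSE])
        x[nls_idx, ] <- sweep(sweep(x[nls_idx, , drop = FALSE], 2, cen) *
                                (1 - spec$compaction_factor), 2, cen, "+")
      }
      if (k %in% path_frames)
        x <- inject_contacts(x, a, pairs, roles)
      xyz[k, ] <- as.vector(t(x))
    }
  })
  new_trajectory(base, xyz, dt_ps = spec$dt_ps)
}

# Create the hydrogen-bond edge for each residue pair by pulling one
# donor/acceptor atom to 3.0 Angstrom of a partner atom. Only side-chain atoms
# are relocated (backbone positions feed the RMSD detector and must stay put),
# each atom is moved at most once per frame, and atoms already serving as the
# stationary end of an earlier edge are protected from later moves. Pairs
# already in contact (e.g. chain neighbours) are left alone.
inject_contacts <- function(x, atoms, pairs, roles) {
  protected <- integer()  # moved this frame, or anchoring an injected edge
  bb_names <- c("N", "O", "OXT")
  for (r in seq_len(nrow(pairs))) {
    ra <- pairs[r, 1]; rb <- pairs[r, 2]
    # candidate (mobile, anchor) assignments in both donor/acceptor orientations
    cand_for <- function(mob_res, anc_res) {
      rbind(
        expand.grid(mob = roles$donor[atoms$resnum[roles$donor] == mob_res],
                    anc = roles$acceptor[atoms$resnum[roles$acceptor] == anc_res]),
        expand.grid(mob = roles$acceptor[atoms$resnum[roles$acceptor] == mob_res],
                    anc = roles$donor[atoms$resnum[roles$donor] == anc_res])
      )
    }
    cand <- rbind(cbind(cand_for(ra, rb), first = TRUE),
                  cbind(cand_for(rb, ra), first = FALSE))
    if (nrow(cand) == 0)
      stop("no donor/acceptor pairing between residues ", ra, " and ", rb)
    d_all <- sqrt(rowSums((x[cand$mob, , drop = FALSE] -
                             x[cand$anc, , drop = FALSE])^2))
    if (min(d_all) <= 3.2) next
    mob_side <- !atoms$name[cand$mob] %in% bb_names
    mob_free <- !cand$mob %in% protected
    anc_bb <- atoms$name[cand$anc] %in% bb_names
    ok <- mob_free
    if (any(ok & mob_side)) ok <- ok & mob_side  # never move backbone if avoidable
    if (!any(ok))
      stop("cannot inject contact between residues ", ra, " and ", rb,
           ": all candidate atoms already committed")
    j <- which(ok)[order(!anc_bb[ok], !cand$first[ok], d_all[ok])[1]]
    mob <- cand$mob[j]; anc <- cand$anc[j]
    u <- x[mob, ] - x[anc, ]
    x[mob, ] <- x[anc, ] + 3.0 * u / sqrt(sum(u^2))
    protected <- c(protected, mob, anc)
  }
  x
}

#' Preset synthetic study conditions
#'
#' Encodes the qualitative case-study outcomes as generator settings applied to
#' the angiogenin model: `wt_like` (all injections zero, small noise),
#' `k17i_like` (His114 switching 0.4 and the Ile17-Asp15-Ile46-His13-Leu115-
#' Gln117-Asp116-His114 path in 40% of frames, no compaction), `l35p_like`
#' (switching 0.4, the Pro35-Lys40-Gln12-His13-(Thr44 and Leu115)-Gln117-
#' Asp116-His114 branched path in 40% of frames, NLS compaction 0.3), and
#' `destabilized` (3 Angstrom progressive backbone drift). The mutant presets
#' first apply the corresponding point mutation to the base structure.
#'
#' @param name One of `"wt_like"`, `"k17i_like"`, `"l35p_like"`,
#'   `"destabilized"`.
#' @param base The wild-type `pdb_structure` (default [build_ang_model()]).
#' @param seed Integer seed.
#' @param n_frames,dt_ps Trajectory size; 100 frames at 1 ps by default.
#' @return A [synthetic_spec()].
#' @export
make_preset <- function(name, base = build_ang_model(), seed = 1L,
                        n_frames = 100L, dt_ps = 1) {
  noise <- 0.1
  switch (name,
    wt_like = synthetic_spec(base, n_frames, dt_ps, noise_sigma = noise,
                             seed = seed, preset = name),
    k17i_like = synthetic_spec(
      mutate_residue(base, "K17I"), n_frames, dt_ps, noise_sigma = noise,
      switch_fraction_target = 0.4, path_persistence_target = 0.4,
      path_residues = list(c(17L, 15L, 46L, 13L, 115L, 117L, 116L, 114L)),
      seed = seed, preset = name, mutation = "K17I"),
    l35p_like = synthetic_spec(
      mutate_residue(base, "L35P"), n_frames, dt_ps, noise_sigma = noise,
      switch_fraction_target = 0.4, path_persistence_target = 0.4,
      path_residues = list(c(35L, 40L, 12L, 13L, 115L, 117L, 116L, 114L),
                           c(13L, 44L, 117L)),
      compaction_factor = 0.3,
      seed = seed, preset = name, mutation = "L35P"),
    destabilized = synthetic_spec(base, n_frames, dt_ps, noise_sigma = noise,
                                  drift_amplitude = 3, seed = seed,
                                  preset = name),
    stop("unknown preset: ", name)
  )
}

#' Write a synthetic-trajectory specification as key = value text
#'
#' The base structure itself is not serialised; [read_synthetic_spec()] takes
#' it as an argument.
#'
#' @param spec A [synthetic_spec()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_synthetic_spec <- function(spec, path) {
  stopifnot(inherits(spec, "synthetic_spec"))
  lines <- c(
    sprintf("n_frames = %d", spec$n_frames),
    sprintf("dt_ps = %g", spec$dt_ps),
    sprintf("noise_sigma = %g", spec$noise_sigma),
    sprintf("switch_fraction_target = %g", spec$switch_fraction_target),
    sprintf("path_persistence_target = %g", spec$path_persistence_target),
    sprintf("compaction_factor = %g", spec$compaction_factor),
    sprintf("drift_amplitude = %g", spec$drift_amplitude),
    sprintf("seed = %d", spec$seed)
  )
  if (!is.null(spec$path_residues))
    lines <- c(lines, sprintf("path_residues = %s",
                              paste(vapply(spec$path_residues, paste,
                                           character(1), collapse = " "),
                                    collapse = "; ")))
  if (!is.null(spec$preset)) lines <- c(lines, sprintf("preset = %s", spec$preset))
  if (!is.null(spec$mutation)) lines <- c(lines, sprintf("mutation = %s", spec$mutation))
  writeLines(lines, path)
  invisible(path)
}

#' Read a synthetic-trajectory specification from key = value text
#'
#' @param path Path written by [write_synthetic_spec()].
#' @param base The `pdb_structure` the spec applies to.
#' @return A [synthetic_spec()].
#' @export
read_synthetic_spec <- function(path, base) {
  kv <- parse_kv(path)
  num <- function(k, default = 0) if (is.null(kv[[k]])) default else as.numeric(kv[[k]])
  pr <- NULL
  if (!is.null(kv$path_residues))
    pr <- lapply(strsplit(kv$path_residues, ";")[[1]], function(s)
      as.integer(strsplit(trimws(s), "[ ,]+")[[1]]))
  synthetic_spec(
    base, n_frames = num("n_frames", 100), dt_ps = num("dt_ps", 1),
    noise_sigma = num("noise_sigma"),
    switch_fraction_target = num("switch_fraction_target"),
    path_persistence_target = num("path_persistence_target"),
    path_residues = pr,
    compaction_factor = num("compaction_factor"),
    drift_amplitude = num("drift_amplitude"),
    seed = as.integer(num("seed", 1)),
    preset = kv$preset, mutation = kv$mutation
  )
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat("synthetic_spec:", x$n_frames, "frames;",
      "switch", x$switch_fraction_target, "path", x$path_persistence_target,
      "compaction", x$compaction_factor, "drift", x$drift_amplitude,
      "noise", x$noise_sigma, "seed", x$seed,
      if (!is.null(x$preset)) paste0("(", x$preset, ")") else "", "\n")
  invisible(x)
}
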