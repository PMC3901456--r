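# Shrake-Rupley solvent-accessible surface area and the NLS-arginine
# accessibility/compaction detector.

#' Shrake-Rupley solvent-accessible surface area, per residue
#'
#' Classic test-point algorithm: each heavy atom is expanded by the probe
#' radius and covered with a deterministic quasi-uniform (Fibonacci lattice)
#' point set; a point is accessible when it lies outside every expanded
#' neighbour sphere. Atom areas are summed per residue. All heavy atoms of the
#' structure occlude, including heteroatoms when present; hydrogens are
#' ignored. van der Waals radii: C 1.70, N 1.55, O 1.52, S 1.80 Angstrom.
#'
#' @param frame n_atoms x 3 coordinate matrix congruent with `topology`.
#' @param topology A `pdb_structure`.
#' @param cfg A [marker_config()] (probe radius and point count).
#' @param residues Residue numbers to report (default: all polymer residues).
#' @return Named numeric vector of SASA (Angstrom^2) per requested residue.
#' @export
shrake_rupley_sasa <- function(frame, topology, cfg = marker_config(),
                               residues = NULL) {
  stopifnot(inherits(topology, "pdb_structure"))
  frame <- as.matrix(frame)
  a <- topology$atoms
  if (nrow(frame) != nrow(a)) stop("frame does not match topology atom count")
  heavy <- which(a$element != "H")
  el <- a$element[heavy]
  unknown <- setdiff(unique(el), names(.vdw_radii))
  if (length(unknown) > 0)
    stop("unknown element(s) for SASA radii: ", paste(unknown, collapse = ", "))
  xyz <- frame[heavy, , drop = FALSE]
  rad <- unname(.vdw_radii[el])
  probe <- cfg$sasa_probe_radius
  if (is.null(residues)) residues <- sort(unique(a$resnum[heavy][!a$het[heavy]]))
  target <- which(a$resnum[heavy] %in% residues)
  pts <- fibonacci_sphere(cfg$sasa_sphere_points)
  sq <- rowSums(xyz^2)
  out <- stats::setNames(numeric(length(residues)), residues)
  for (i in target) {
    ri <- rad[i] + probe
    # neighbours whose expanded spheres can intersect this atom's test sphere
    lim <- (ri + rad + probe)^2
    d2 <- sq + sq[i] - 2 * as.numeric(xyz %*% xyz[i, ])
    nb <- which(d2 < lim & seq_along(d2) != i)
    n_acc <- if (length(nb) == 0) {
      cfg$sasa_sphere_points
    } else {
      tp <- sweep(pts * ri, 2, xyz[i, ], "+")
      nxyz <- xyz[nb, , drop = FALSE]
      pd2 <- outer(rowSums(tp^2), rowSums(nxyz^2), "+") - 2 * tp %*% t(nxyz)
      blocked <- pd2 < matrix((rad[nb] + probe)^2, nrow(tp), length(nb),
                              byrow = TRUE)
      sum(rowSums(blocked) == 0L)
    }
    key <- as.character(a$resnum[heavy][i])
    out[key] <- out[key] + 4 * pi * ri^2 * n_acc / cfg$sasa_sphere_points
  }
  out
}

#' SASA and compaction of the nuclear-localization-signal arginines
#'
#' Tracks, per frame, the solvent-accessible surface area of each of R31, R32
#' and R33 and the radius of gyration of their pooled side-chain heavy atoms.
#' Local folding/close packing of the 31-RRR-33 segment shows up as a joint
#' drop in SASA and gyration radius; the window means feed the
#' nuclear-translocation rule of [classify()].
#'
#' @param t A `pdb_trajectory` in mature-angiogenin numbering (residues 31-33
#'   must be arginines; a mismatch raises an error to protect against
#'   renumbered inputs).
#' @param cfg A [marker_config()].
#' @return A `sasa_series`: `series` data frame (`time_ps`, `sasa_r31`,
#'   `sasa_r32`, `sasa_r33`, `rrr_gyration`), plus `mean_total` (window mean of
#'   summed SASA, Angstrom^2) and `mean_gyration` (Angstrom) over the final
#'   `analysis_window` fraction of frames.
#' @export
nls_features <- function(t, cfg = marker_config()) {
  stopifnot(inherits(t, "pdb_trajectory"))
  a <- t$topology$atoms
  rr <- cfg$nls_residues
  for (r in rr) {
    nm <- unique(a$resname[!a$het & a$resnum == r])
    if (length(nm) != 1L || nm != "ARG")
      stop("residue ", r, " is not ARG: input numbering does not match the ",
           "mature-angiogenin convention")
  }
  side <- which(!a$het & a$resnum %in% rr & a$element != "H" &
                  !a$name %in% c("N", "CA", "C", "O", "OXT"))
  n <- n_frames(t)
  sasa <- matrix(0, n, length(rr))
  gyr <- numeric(n)
  for (i in seq_len(n)) {
    fc <- frame_coords(t, i)
    sasa[i, ] <- shrake_rupley_sasa(fc, t$topology, cfg, residues = rr)
    p <- fc[side, , drop = FALSE]
    cen <- colMeans(p)
    gyr[i] <- sqrt(mean(rowSums(sweep(p, 2, cen)^2)))
  }
  series <- data.frame(time_ps = (seq_len(n) - 1) * t$dt_ps,
                       sasa_r31 = sasa[, 1], sasa_r32 = sasa[, 2],
                       sasa_r33 = sasa[, 3], rrr_gyration = gyr)
  names(series)[2:4] <- paste0("sasa_r", rr)
  win <- window_indices(n, cfg$analysis_window)
  structure(list(series = series,
                 mean_total = mean(rowSums(sasa)[win]),
                 mean_gyration = mean(gyr[win])),
            class = "sasa_series")
}

window_indices <- function(n, fraction) {
  k <- max(1L, round(fraction * n))
  seq.int(n - k + 1L, n)
}

#' @export
print.sasa_series <- function(x, ...) {
  cat("sasa_series:", nrow(x$series), "frames; window mean total SASA",
      round(x$mean_total, 1), "A^2; gyration", round(x$mean_gyration, 2), "A\n")
  invisible(x)
}
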