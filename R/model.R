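# Synthetic angiogenin reference model.
#
# The package's reference structure is built in code: the 123-residue mature
# human angiogenin sequence placed on an ideal fully-extended backbone with
# Chemical Component Dictionary ideal side-chain geometry. It is a synthetic
# stand-in for the 1B1I crystal structure -- correct sequence, identities and
# topology in mature-ANG numbering (catalytic triad His13/Lys40/His114, NLS
# arginines 31-33), but not the crystallographic fold. The extended backbone is
# deliberate: apart from chain neighbours, no two residues form hydrogen-bond
# contacts, so the synthetic-trajectory generator fully controls which marker
# signals are present.

#' Mature human angiogenin sequence (123 residues)
#'
#' One-letter sequence in mature-protein numbering: His13/Lys40/His114
#' catalytic triad, Lys17, NLS 29-IMRRRGL-35 with arginines 31-33.
#'
#' @return Character string of length 123.
#' @export
ang_sequence <- function() {
  paste0(
    "QDNSRYTHFLTQHYDAKPQGRDDRYCESIMRRRGLTSPCKDINTFIHGNKRSIKAICENKNGNPHREN",
    "LRISKSSFQVTTCKLHGGSPWPPCQYRATAGFRNVVVACENGLPVHLDQSIFRRP"
  )
}

#' Build the synthetic angiogenin reference model
#'
#' Ideal-geometry extended chain (phi = psi = omega = 180 degrees) carrying the
#' [ang_sequence()] side chains in their ideal template conformations; His114
#' chi1 is set to 300 degrees (mid g+ bin) so its rotamer state is
#' unambiguous. Heavy atoms only.
#'
#' @param sequence Optional alternative one-letter sequence (standard residues).
#' @return A `pdb_structure` in mature-angiogenin numbering (1-123).
#' @export
build_ang_model <- function(sequence = ang_sequence()) {
  letters1 <- strsplit(sequence, "")[[1]]
  bad <- setdiff(unique(letters1), names(.aa1to3))
  if (length(bad) > 0) stop("unknown amino-acid code(s): ", paste(bad, collapse = ", "))
  res3 <- unname(.aa1to3[letters1])
  nres <- length(res3)
  # ideal extended backbone via sequential atom placement
  b_nca <- 1.458; b_cac <- 1.525; b_cn <- 1.329
  a_ncac <- 111.2; a_cacn <- 116.2; a_cnca <- 121.7
  bb <- array(NA_real_, dim = c(nres, 3, 3))  # residue x {N, CA, C} x xyz
  bb[1, 1, ] <- c(0, 0, 0)
  bb[1, 2, ] <- c(b_nca, 0, 0)
  th <- a_ncac * pi / 180
  bb[1, 3, ] <- bb[1, 2, ] + b_cac * c(-cos(th), sin(th), 0)
  for (i in seq_len(nres - 1)) {
    n_i <- bb[i, 1, ]; ca_i <- bb[i, 2, ]; c_i <- bb[i, 3, ]
    n_j <- place_atom(n_i, ca_i, c_i, b_cn, a_cacn, 180)   # psi
    ca_j <- place_atom(ca_i, c_i, n_j, b_nca, a_cnca, 180) # omega
    c_j <- place_atom(c_i, n_j, ca_j, b_cac, a_ncac, 180)  # phi
    bb[i + 1, 1, ] <- n_j; bb[i + 1, 2, ] <- ca_j; bb[i + 1, 3, ] <- c_j
  }
  rows <- vector("list", nres)
  for (i in seq_len(nres)) {
    tmpl <- residue_template(res3[i])
    fit <- kabsch_superpose(
      as.matrix(tmpl[match(c("N", "CA", "C"), tmpl$name), c("x", "y", "z")]),
      rbind(bb[i, 1, ], bb[i, 2, ], bb[i, 3, ])
    )
    xyz <- sweep(as.matrix(tmpl[, c("x", "y", "z")]) %*% fit$rotation,
                 2, fit$translation, "+")
    k <- match(c("N", "CA", "C"), tmpl$name)
    xyz[k, ] <- rbind(bb[i, 1, ], bb[i, 2, ], bb[i, 3, ])
    rows[[i]] <- data.frame(
      serial = NA_integer_, name = tmpl$name, altloc = NA_character_,
      resname = res3[i], chain = "A", resnum = i,
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      occupancy = 1, b_factor = 0, element = toupper(tmpl$element),
      het = FALSE, stringsAsFactors = FALSE
    )
  }
  atoms <- do.call(rbind, rows)
  atoms$serial <- seq_len(nrow(atoms))
  s <- new_structure(atoms, title = "synthetic angiogenin model (ideal extended geometry)")
  his <- which(atoms$resname == "HIS" & atoms$resnum == 114)
  if (length(his) > 0) s <- set_chi1(s, 114L, 300)
  s
}

# Rotate a residue's side chain about the CA-CB axis so that chi1 equals
# `target_deg` (degrees, reported modulo 360).
set_chi1 <- function(s, resnum, target_deg) {
  a <- s$atoms
  idx <- which(!a$het & a$resnum == resnum)
  nm <- a$name[idx]
  need <- c("N", "CA", "CB", unname(.chi1_fourth[a$resname[idx][1]]))
  pts <- function(x) as.numeric(a[idx[match(x, nm)], c("x", "y", "z")])
  cur <- dihedral_angle(pts("N"), pts("CA"), pts("CB"), pts(need[4]))
  rot_idx <- idx[!nm %in% c("N", "CA", "C", "O", "OXT", "CB")]
  orig <- as.matrix(a[rot_idx, c("x", "y", "z")])
  for (sgn in c(1, -1)) {
    moved <- rotate_about_axis(orig, pts("CA"), pts("CB") - pts("CA"),
                               sgn * ((target_deg - cur) %% 360))
    s$atoms[rot_idx, c("x", "y", "z")] <- moved
    b <- s$atoms
    chk <- dihedral_angle(pts2(b, idx, nm, "N"), pts2(b, idx, nm, "CA"),
                          pts2(b, idx, nm, "CB"), pts2(b, idx, nm, need[4]))
    if (abs(((chk - target_deg) + 180) %% 360 - 180) < 1e-6) return(s)
  }
  stop("internal error: chi1 rotation did not reach target")
}

pts2 <- function(atoms, idx, nm, name) {
  as.numeric(atoms[idx[match(name, nm)], c("x", "y", "z")])
}
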