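# Structure and trajectory I/O (PDB dialect), heteroatom stripping, in-silico
# point mutation, and sequence utilities.
#
# PDB parsing and serialisation are delegated to bio3d; this layer adds the
# containers used throughout the package, input validation with informative
# errors, and the altloc/hydrogen conventions documented below:
#   - alternate locations: "A" or blank kept, others dropped (bio3d rm.alt);
#   - hydrogens: retained on read, ignored by every detector (heavy-atom
#     criteria throughout).

new_structure <- function(atoms, title = "") {
  stopifnot(is.data.frame(atoms))
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, title = title), class = "pdb_structure")
}

new_trajectory <- function(topology, xyz, dt_ps = 1) {
  if (!inherits(topology, "pdb_structure")) stop("topology must be a pdb_structure")
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L * nrow(topology$atoms))
    stop("topology error: frame width does not match topology atom count")
  if (!is.numeric(dt_ps) || length(dt_ps) != 1L || dt_ps <= 0)
    stop("dt_ps must be a positive scalar")
  structure(list(topology = topology, xyz = xyz, dt_ps = dt_ps),
            class = "pdb_trajectory")
}

#' Number of frames in a trajectory
#' @param t A `pdb_trajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(t) {
  stopifnot(inherits(t, "pdb_trajectory"))
  nrow(t$xyz)
}

#' Coordinates of one trajectory frame
#' @param t A `pdb_trajectory`.
#' @param i Frame index (1-based).
#' @return An n_atoms x 3 coordinate matrix (Angstrom).
#' @export
frame_coords <- function(t, i) {
  stopifnot(inherits(t, "pdb_trajectory"), i >= 1, i <= nrow(t$xyz))
  matrix(t$xyz[i, ], ncol = 3, byrow = TRUE,
         dimnames = list(NULL, c("x", "y", "z")))
}

coords_of <- function(s) {
  as.matrix(s$atoms[, c("x", "y", "z")])
}

#' Read a PDB structure or multi-model trajectory
#'
#' Fixed-column ATOM/HETATM/MODEL/ENDMDL records are honoured; other record
#' types are ignored. MODEL/ENDMDL blocks become trajectory frames when
#' `model_policy = "all"`; the frame interval is not stored in PDB files and is
#' supplied via `dt_ps` (default 1 ps).
#'
#' @param path Path to a PDB-dialect text file.
#' @param model_policy `"first"` returns a `pdb_structure` (first model);
#'   `"all"` returns a `pdb_trajectory` when the file holds several models.
#' @param dt_ps Frame interval in picoseconds for multi-model input.
#' @return A `pdb_structure`, or a `pdb_trajectory` for multi-model input read
#'   with `model_policy = "all"`.
#' @export
read_pdb <- function(path, model_policy = c("first", "all"), dt_ps = 1) {
  model_policy <- match.arg(model_policy)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  is_atom <- startsWith(lines, "ATOM  ") | startsWith(lines, "HETATM")
  if (!any(is_atom)) stop("no ATOM/HETATM records in ", path)
  for (i in which(is_atom)) {
    ln <- lines[i]
    coords <- suppressWarnings(as.numeric(c(
      substr(ln, 31, 38), substr(ln, 39, 46), substr(ln, 47, 54))))
    if (nchar(ln) < 54 || anyNA(coords))
      stop("malformed ATOM record at line ", i, " of ", path)
  }
  model_starts <- which(startsWith(lines, "MODEL"))
  multi <- length(model_starts) > 1L
  if (multi) {
    # atom counts must agree across models before bio3d flattens them
    model_ends <- which(startsWith(lines, "ENDMDL"))
    if (length(model_ends) != length(model_starts))
      stop("topology error: unbalanced MODEL/ENDMDL records in ", path)
    counts <- mapply(function(a, b) sum(is_atom[a:b]), model_starts, model_ends)
    if (length(unique(counts)) != 1L)
      stop("topology error: inconsistent atom counts across models in ", path)
  }
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = multi, verbose = FALSE))
  atoms <- bio3d_atoms(pdb)
  title <- paste(trimws(sub("^TITLE\\s{0,4}\\d?", "",
                            lines[startsWith(lines, "TITLE")])), collapse = " ")
  s <- new_structure(atoms, title = title)
  if (multi && model_policy == "all")
    return(new_trajectory(s, pdb$xyz, dt_ps = dt_ps))
  if (multi) {
    s$atoms[, c("x", "y", "z")] <- matrix(pdb$xyz[1, ], ncol = 3, byrow = TRUE)
  }
  s
}

bio3d_atoms <- function(pdb) {
  a <- pdb$atom
  element <- a$elesy
  missing_el <- is.na(element) | element == ""
  if (any(missing_el))
    element[missing_el] <- suppressWarnings(bio3d::atom2ele(a$elety[missing_el]))
  if (any(is.na(element) | element == ""))
    stop("element could not be determined for some atoms")
  data.frame(
    serial = a$eleno, name = a$elety, altloc = a$alt, resname = a$resid,
    chain = ifelse(is.na(a$chain), "A", a$chain), resnum = a$resno,
    x = a$x, y = a$y, z = a$z,
    occupancy = ifelse(is.na(a$o), 1, a$o),
    b_factor = ifelse(is.na(a$b), 0, a$b),
    element = toupper(element), het = a$type == "HETATM",
    stringsAsFactors = FALSE
  )
}

#' Write a structure or trajectory as (multi-model) PDB
#'
#' @param x A `pdb_structure` or `pdb_trajectory`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(x, path) {
  if (inherits(x, "pdb_structure")) {
    atoms <- x$atoms
    xyz <- as.vector(t(coords_of(x)))
  } else if (inherits(x, "pdb_trajectory")) {
    atoms <- x$topology$atoms
    xyz <- x$xyz
  } else stop("x must be a pdb_structure or pdb_trajectory")
  bio3d::write.pdb(
    pdb = NULL, file = path, xyz = xyz,
    type = ifelse(atoms$het, "HETATM", "ATOM"),
    resno = atoms$resnum, resid = atoms$resname,
    eleno = atoms$serial, elety = atoms$name, chain = atoms$chain,
    o = atoms$occupancy, b = atoms$b_factor, elesy = atoms$element
  )
  invisible(path)
}

#' Remove heteroatom residues (waters, cofactors, ions)
#'
#' Drops every HETATM-derived residue (for angiogenin 1B1I: the crystallographic
#' waters and the citric-acid cofactor); polymer residues are untouched.
#'
#' @param s A `pdb_structure`.
#' @return A `pdb_structure` containing only polymer residues.
#' @export
strip_heteroatoms <- function(s) {
  stopifnot(inherits(s, "pdb_structure"))
  atoms <- s$atoms[!s$atoms$het, , drop = FALSE]
  new_structure(atoms, title = s$title)
}

#' Parse a point-mutation token
#'
#' @param token A token such as `"K17I"` (wild-type residue, position in mature
#'   angiogenin numbering, mutant residue). Wild type and mutant must differ.
#' @return A `mutation_spec` with fields `wt`, `position`, `mut`.
#' @export
parse_mutation <- function(token) {
  if (inherits(token, "mutation_spec")) return(token)
  m <- regmatches(token, regexec("^([A-Za-z])([0-9]+)([A-Za-z])$", token))[[1]]
  if (length(m) != 4L) stop("cannot parse mutation token: ", token)
  wt <- toupper(m[2]); mut <- toupper(m[4])
  if (!wt %in% names(.aa1to3) || !mut %in% names(.aa1to3))
    stop("unknown amino-acid code in mutation token: ", token)
  if (wt == mut)
    stop("degenerate mutation (wild type equals mutant): ", token)
  structure(list(wt = wt, position = as.integer(m[3]), mut = mut),
            class = "mutation_spec")
}

#' @export
format.mutation_spec <- function(x, ...) paste0(x$wt, x$position, x$mut)

#' @export
print.mutation_spec <- function(x, ...) {
  cat("mutation", format(x), "\n")
  invisible(x)
}

# Ideal heavy-atom geometry per residue type (Chemical Component Dictionary
# ideal coordinates), loaded once per session.
residue_template <- function(resname) {
  env <- template_cache()
  tmpl <- env$templates[[resname]]
  if (is.null(tmpl)) stop("no geometry template for residue ", resname)
  tmpl
}

template_cache <- local({
  env <- NULL
  function() {
    if (is.null(env)) {
      path <- system.file("extdata", "residue_templates.csv", package = "angtraj")
      df <- utils::read.csv(path, stringsAsFactors = FALSE)
      env <<- new.env()
      env$templates <- split(df, df$resname)
    }
    env
  }
})

#' In-silico point mutation
#'
#' Replaces the side chain of one residue. Backbone atoms (N, CA, C, O, and CB
#' when present in both residues) keep their original coordinates; the new side
#' chain is transplanted from an idealised-geometry template superposed on
#' N-CA-CB (N-CA-C when the source residue lacks CB). No energy refinement is
#' performed: relaxation is the job of whatever simulation engine consumes the
#' structure.
#'
#' @param s A `pdb_structure`.
#' @param m A mutation token (e.g. `"K17I"`) or `mutation_spec`. The wild-type
#'   letter must match the residue found at the position, guarding against
#'   numbering-convention mistakes.
#' @return A `pdb_structure` with the mutated residue; all other residues are
#'   untouched.
#' @export
mutate_residue <- function(s, m) {
  stopifnot(inherits(s, "pdb_structure"))
  m <- parse_mutation(m)
  atoms <- s$atoms
  idx <- which(!atoms$het & atoms$resnum == m$position)
  if (length(idx) == 0L) stop("no residue at position ", m$position)
  if (length(unique(atoms$chain[idx])) != 1L)
    stop("position ", m$position, " is ambiguous across chains")
  res <- atoms[idx, , drop = FALSE]
  resname <- unique(res$resname)
  found <- unname(.aa3to1[resname])
  if (is.na(found) || found != m$wt)
    stop("wild-type mismatch at position ", m$position, ": found ", resname,
         " (", found, "), token says ", m$wt,
         " - check the residue-numbering convention of the input")
  mut3 <- unname(.aa1to3[m$mut])
  tmpl <- residue_template(mut3)
  heavy <- res[res$element != "H", , drop = FALSE]
  get_xyz <- function(df, nm) {
    i <- match(nm, df$name)
    if (anyNA(i)) stop("residue ", m$position, " lacks atom(s) ",
                       paste(nm[is.na(i)], collapse = ", "))
    as.matrix(df[i, c("x", "y", "z")])
  }
  has_cb_src <- "CB" %in% heavy$name
  has_cb_tmpl <- "CB" %in% tmpl$name
  if (has_cb_src && has_cb_tmpl) {
    fit_names <- c("N", "CA", "CB")
    keep_names <- intersect(c("N", "CA", "C", "O", "OXT", "CB"), heavy$name)
  } else {
    fit_names <- c("N", "CA", "C")
    keep_names <- intersect(c("N", "CA", "C", "O", "OXT"), heavy$name)
  }
  side_tmpl <- tmpl[!tmpl$name %in% c("N", "CA", "C", "O", keep_names), , drop = FALSE]
  kept <- res[match(keep_names, res$name), , drop = FALSE]
  kept$resname <- mut3
  if (nrow(side_tmpl) > 0) {
    fit <- kabsch_superpose(get_xyz(tmpl, fit_names), get_xyz(heavy, fit_names))
    new_xyz <- sweep(as.matrix(side_tmpl[, c("x", "y", "z")]) %*% fit$rotation,
                     2, fit$translation, "+")
    side <- data.frame(
      serial = NA_integer_, name = side_tmpl$name, altloc = NA_character_,
      resname = mut3, chain = kept$chain[1], resnum = m$position,
      x = new_xyz[, 1], y = new_xyz[, 2], z = new_xyz[, 3],
      occupancy = 1, b_factor = 0, element = toupper(side_tmpl$element),
      het = FALSE, stringsAsFactors = FALSE
    )
    newres <- rbind(kept, side)
  } else {
    newres <- kept
  }
  before <- atoms[seq_len(nrow(atoms)) < min(idx), , drop = FALSE]
  after <- atoms[seq_len(nrow(atoms)) > max(idx), , drop = FALSE]
  out <- rbind(before, newres, after)
  out$serial <- seq_len(nrow(out))
  new_structure(out, title = s$title)
}

#' One-letter amino-acid sequence of a structure
#'
#' Heteroatom residues are ignored; residues outside the 20 standard types map
#' to `"X"`.
#'
#' @param s A `pdb_structure`.
#' @return A single character string, one letter per polymer residue in file
#'   order.
#' @export
sequence_of <- function(s) {
  stopifnot(inherits(s, "pdb_structure"))
  a <- s$atoms[!s$atoms$het, , drop = FALSE]
  key <- paste(a$chain, a$resnum)
  resnames <- a$resname[!duplicated(key)]
  letters1 <- unname(.aa3to1[resnames])
  letters1[is.na(letters1)] <- "X"
  paste(letters1, collapse = "")
}

#' Average molecular weight of a peptide sequence
#'
#' Sum of average residue masses plus one water (18.02 Da).
#'
#' @param seq One-letter amino-acid string (standard residues only).
#' @return Mass in Daltons.
#' @examples
#' molecular_weight("G")  # 75.07
#' @export
molecular_weight <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  if (length(chars) == 0L) stop("empty sequence")
  bad <- setdiff(unique(chars), names(.residue_mass))
  if (length(bad) > 0)
    stop("unknown amino-acid code(s): ", paste(bad, collapse = ", "))
  sum(.residue_mass[chars]) + .water_mass
}

#' @export
print.pdb_structure <- function(x, ...) {
  a <- x$atoms
  nres <- sum(!duplicated(paste(a$chain, a$resnum, a$het)))
  cat("pdb_structure:", nrow(a), "atoms,", nres, "residues",
      if (any(a$het)) sprintf("(%d heteroatom records)", sum(a$het)) else "",
      "\n")
  invisible(x)
}

#' @export
print.pdb_trajectory <- function(x, ...) {
  cat("pdb_trajectory:", nrow(x$xyz), "frames x",
      nrow(x$topology$atoms), "atoms, dt =", x$dt_ps, "ps\n")
  invisible(x)
}
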