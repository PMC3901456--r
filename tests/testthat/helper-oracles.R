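# Independent oracles used by the test suite. Each implements the quantity a
# detector computes by a different route (closed form, quaternion eigenvalue,
# exhaustive enumeration), so agreement is evidence, not tautology.

# Minimum RMSD between paired point sets via Horn's quaternion method: the
# largest eigenvalue of the 4x4 key matrix gives the optimal rotation overlap.
quaternion_rmsd <- function(mobile, reference) {
  p <- sweep(mobile, 2, colMeans(mobile))
  q <- sweep(reference, 2, colMeans(reference))
  s <- crossprod(p, q)
  k <- matrix(0, 4, 4)
  k[1, 1] <- s[1, 1] + s[2, 2] + s[3, 3]
  k[1, 2] <- k[2, 1] <- s[2, 3] - s[3, 2]
  k[1, 3] <- k[3, 1] <- s[3, 1] - s[1, 3]
  k[1, 4] <- k[4, 1] <- s[1, 2] - s[2, 1]
  k[2, 2] <- s[1, 1] - s[2, 2] - s[3, 3]
  k[2, 3] <- k[3, 2] <- s[1, 2] + s[2, 1]
  k[2, 4] <- k[4, 2] <- s[3, 1] + s[1, 3]
  k[3, 3] <- -s[1, 1] + s[2, 2] - s[3, 3]
  k[3, 4] <- k[4, 3] <- s[2, 3] + s[3, 2]
  k[4, 4] <- -s[1, 1] - s[2, 2] + s[3, 3]
  lambda <- max(eigen(k, symmetric = TRUE, only.values = TRUE)$values)
  sqrt(max(0, (sum(p^2) + sum(q^2) - 2 * lambda)) / nrow(p))
}

# Accessible area of each of two overlapping probe-expanded spheres
# (radii R1, R2 = vdW + probe, centre distance d): closed-form spherical caps.
two_sphere_sasa <- function(r1, r2, d, probe) {
  R1 <- r1 + probe
  R2 <- r2 + probe
  if (d >= R1 + R2) return(c(4 * pi * R1^2, 4 * pi * R2^2))
  h1 <- R1 - (d^2 + R1^2 - R2^2) / (2 * d)
  h2 <- R2 - (d^2 + R2^2 - R1^2) / (2 * d)
  c(4 * pi * R1^2 - 2 * pi * R1 * h1,
    4 * pi * R2^2 - 2 * pi * R2 * h2)
}

# Exhaustive simple-path enumeration on an hbond_graph-like edge set.
# Returns the minimal-length simple path source -> target (optionally with
# `via` as an interior node), lexicographically smallest among ties, or NULL.
brute_force_path <- function(nodes, edges, source, target, via = NULL) {
  adj <- lapply(nodes, function(n)
    sort(unique(c(edges$res_b[edges$res_a == n], edges$res_a[edges$res_b == n]))))
  names(adj) <- as.character(nodes)
  best <- NULL
  dfs <- function(path) {
    u <- path[length(path)]
    if (u == target) {
      if (length(path) >= 2 || source == target) {
        interior <- path[-c(1, length(path))]
        if (is.null(via) || via %in% interior) {
          if (is.null(best) || length(path) < length(best) ||
              (length(path) == length(best) && lex_less(path, best)))
            best <<- path
        }
      }
      return(invisible())
    }
    if (!is.null(best) && length(path) >= length(best)) return(invisible())
    for (v in adj[[as.character(u)]]) {
      if (v %in% path) next
      dfs(c(path, v))
    }
  }
  if (source == target) return(source)
  dfs(source)
  best
}

lex_less <- function(a, b) {
  for (i in seq_len(min(length(a), length(b)))) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  length(a) < length(b)
}

# Random undirected graph on `n` integer-labelled nodes with edge prob `p`.
random_graph <- function(n, p) {
  nodes <- seq_len(n)
  pairs <- utils::combn(nodes, 2)
  keep <- stats::runif(ncol(pairs)) < p
  edges <- data.frame(res_a = pairs[1, keep], res_b = pairs[2, keep],
                      distance = rep(3.0, sum(keep)))
  structure(list(nodes = nodes, edges = edges, cutoff = 3.2),
            class = "hbond_graph")
}

# Tiny peptide-like structures built in code for structio tests.
make_atoms <- function(resnum, resname, names, elements, coords, het = FALSE,
                       chain = "A") {
  data.frame(
    serial = seq_along(names), name = names, altloc = NA_character_,
    resname = resname, chain = chain, resnum = resnum,
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    occupancy = 1, b_factor = 0, element = elements, het = het,
    stringsAsFactors = FALSE
  )
}

# Two-glycine fixture with backbone N...O separation `no_dist` between the
# residues (the only inter-residue donor-acceptor pairing in range).
two_gly_fixture <- function(no_dist) {
  g1 <- make_atoms(1L, "GLY", c("N", "CA", "C", "O"), c("N", "C", "C", "O"),
                   rbind(c(0, 0, 0), c(1.46, 0, 0), c(2.0, 1.42, 0), c(1.25, 2.39, 0)))
  # second residue far along x; its N sits `no_dist` from O of residue 1
  off <- c(1.25, 2.39 + no_dist, 0)
  g2 <- make_atoms(2L, "GLY", c("N", "CA", "C", "O"), c("N", "C", "C", "O"),
                   rbind(off, off + c(1.46, 0, 0), off + c(2.0, 1.42, 0),
                         off + c(1.25, 30, 0)))
  g2$serial <- g2$serial + 4L
  angtraj:::new_structure(rbind(g1, g2))
}

# Multi-frame trajectory from a structure plus a list of coordinate matrices.
traj_from_frames <- function(topology, frames, dt_ps = 1) {
  xyz <- do.call(rbind, lapply(frames, function(f) as.vector(t(f))))
  angtraj:::new_trajectory(topology, xyz, dt_ps = dt_ps)
}

# Shared fixture: the synthetic angiogenin model, built once per test run.
ang_model_fixture <- local({
  model <- NULL
  function() {
    if (is.null(model)) model <<- angtraj::build_ang_model()
    model
  }
})

random_rotation <- function() {
  m <- matrix(stats::rnorm(9), 3)
  qr_d <- qr(m)
  q <- qr.Q(qr_d)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
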