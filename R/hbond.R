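# Per-frame residue-level hydrogen-bond graphs and interaction-path search.
#
# An edge joins two residues when some donor heavy atom (N/O/S carrying a
# hydrogen in standard protonation chemistry) of one lies within the distance
# cutoff of an acceptor heavy atom (N/O/S) of the other. The published
# criterion is distance-only (<= 3.2 Angstrom); an optional D-H...A angle
# filter can be enabled when the input carries hydrogens.

# Per-atom hydrogen-bond roles for a topology (polymer heavy atoms only).
hbond_roles <- function(topology) {
  a <- topology$atoms
  poly <- !a$het & a$element != "H"
  donor <- poly & (
    (a$name == "N" & a$resname != "PRO") |
      mapply(function(rn, nm) nm %in% (.sidechain_donors[[rn]] %||% character()),
             a$resname, a$name)
  )
  acceptor <- poly & (
    a$name %in% c("O", "OXT") |
      mapply(function(rn, nm) nm %in% (.sidechain_acceptors[[rn]] %||% character()),
             a$resname, a$name)
  )
  list(donor = which(donor), acceptor = which(acceptor))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Residue-level hydrogen-bond graph of one frame
#'
#' @param frame An n_atoms x 3 coordinate matrix congruent with `topology`
#'   (see [frame_coords()]).
#' @param topology A `pdb_structure` supplying atom identities.
#' @param cfg A [marker_config()].
#' @return An `hbond_graph`: list with `nodes` (all polymer residue numbers)
#'   and `edges`, a data frame of residue pairs (`res_a` < `res_b`) with the
#'   minimum qualifying donor-acceptor distance in Angstrom.
#' @export
hbond_graph <- function(frame, topology, cfg = marker_config()) {
  stopifnot(inherits(topology, "pdb_structure"))
  frame <- as.matrix(frame)
  a <- topology$atoms
  if (nrow(frame) != nrow(a))
    stop("frame does not match topology atom count")
  poly <- !a$het
  if (anyDuplicated(unique(a[poly, c("chain", "resnum")])$resnum))
    stop("duplicate residue numbers across chains are not supported")
  nodes <- sort(unique(a$resnum[poly]))
  roles <- hbond_roles(topology)
  di <- roles$donor; ai <- roles$acceptor
  edges <- data.frame(res_a = integer(), res_b = integer(), distance = numeric())
  if (length(di) > 0 && length(ai) > 0) {
    dxyz <- frame[di, , drop = FALSE]
    axyz <- frame[ai, , drop = FALSE]
    d2 <- outer(rowSums(dxyz^2), rowSums(axyz^2), "+") - 2 * dxyz %*% t(axyz)
    hit <- which(d2 <= cfg$hbond_cutoff^2 + 1e-12, arr.ind = TRUE)
    if (nrow(hit) > 0) {
      rd <- a$resnum[di[hit[, 1]]]
      ra <- a$resnum[ai[hit[, 2]]]
      keep <- rd != ra
      if (!is.null(cfg$hbond_angle_min) && any(keep))
        keep <- keep & hbond_angle_ok(frame, a, di[hit[, 1]], ai[hit[, 2]],
                                      cfg$hbond_angle_min)
      if (any(keep)) {
        r1 <- pmin(rd[keep], ra[keep])
        r2 <- pmax(rd[keep], ra[keep])
        d <- sqrt(pmax(0, d2[hit[keep, , drop = FALSE]]))
        o <- order(r1, r2, d)
        dup <- duplicated(cbind(r1[o], r2[o]))
        edges <- data.frame(res_a = r1[o][!dup], res_b = r2[o][!dup],
                            distance = d[o][!dup])
      }
    }
  }
  structure(list(nodes = nodes, edges = edges, cutoff = cfg$hbond_cutoff),
            class = "hbond_graph")
}

# D-H...A angle test; only meaningful when hydrogens are present. Donors with
# no hydrogen within 1.25 A pass unfiltered (criterion stays distance-only).
hbond_angle_ok <- function(frame, atoms, don_idx, acc_idx, min_angle) {
  h_idx <- which(atoms$element == "H")
  ok <- rep(TRUE, length(don_idx))
  if (length(h_idx) == 0) return(ok)
  hxyz <- frame[h_idx, , drop = FALSE]
  for (k in seq_along(don_idx)) {
    d <- frame[don_idx[k], ]
    dh <- sqrt(rowSums(sweep(hxyz, 2, d)^2))
    hs <- which(dh <= 1.25)
    if (length(hs) == 0) next
    acc <- frame[acc_idx[k], ]
    angs <- vapply(hs, function(i) {
      h <- hxyz[i, ]
      v1 <- d - h; v2 <- acc - h
      acos(pmin(1, pmax(-1, sum(v1 * v2) /
                          sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
    }, numeric(1))
    ok[k] <- any(angs >= min_angle)
  }
  ok
}

#' @export
print.hbond_graph <- function(x, ...) {
  cat("hbond_graph:", length(x$nodes), "residues,", nrow(x$edges),
      "edges (cutoff", x$cutoff, "A)\n")
  invisible(x)
}

adjacency_list <- function(g) {
  adj <- lapply(g$nodes, function(n) integer())
  names(adj) <- as.character(g$nodes)
  if (nrow(g$edges) > 0) {
    for (i in seq_len(nrow(g$edges))) {
      a <- as.character(g$edges$res_a[i]); b <- as.character(g$edges$res_b[i])
      adj[[a]] <- c(adj[[a]], g$edges$res_b[i])
      adj[[b]] <- c(adj[[b]], g$edges$res_a[i])
    }
    adj <- lapply(adj, function(v) sort(unique(v)))
  }
  adj
}

graph_distances <- function(g, from) {
  ig <- igraph::graph_from_data_frame(
    data.frame(from = as.character(g$edges$res_a),
               to = as.character(g$edges$res_b)),
    directed = FALSE, vertices = as.character(g$nodes))
  d <- igraph::distances(ig, v = as.character(from))
  stats::setNames(as.numeric(d[1, ]), colnames(d))
}

#' Shortest hydrogen-bond interaction path, optionally through a mediator
#'
#' Without `via`, returns the shortest path from `source` to `target`
#' (lexicographic tie-break on residue numbers). With `via`, returns the
#' minimal-length simple path that contains `via` as an interior node -- the
#' form in which a "mediated through Leu115" path is reported -- again with a
#' lexicographic tie-break. The constrained search is an iterative-deepening
#' DFS with breadth-first-search lower-bound pruning, exact on any graph.
#'
#' @param g An [hbond_graph()].
#' @param source,target Residue numbers (must be nodes of `g`).
#' @param via Residue number that must appear as an interior node, or `NULL`.
#' @param max_len Maximum path length (edges) explored for the constrained
#'   search; defaults to nodes - 1 (no restriction).
#' @return An `interaction_path` (fields `residues`, `mediated`, `trivial`) or
#'   `NULL` when no qualifying path exists.
#' @export
find_interaction_path <- function(g, source, target, via = NULL, max_len = NULL) {
  stopifnot(inherits(g, "hbond_graph"))
  if (!source %in% g$nodes) stop("source residue ", source, " not in graph")
  if (!target %in% g$nodes) stop("target residue ", target, " not in graph")
  mk <- function(res) {
    interior <- res[-c(1, length(res))]
    structure(list(residues = res,
                   mediated = if (is.null(via)) NA else via %in% interior,
                   trivial = length(res) == 1L),
              class = "interaction_path")
  }
  if (source == target) return(mk(source))
  if (is.null(via)) {
    dt <- graph_distances(g, target)
    if (!is.finite(dt[as.character(source)])) return(NULL)
    adj <- adjacency_list(g)
    path <- source
    u <- source
    while (u != target) {
      nb <- adj[[as.character(u)]]
      cand <- nb[dt[as.character(nb)] == dt[as.character(u)] - 1]
      u <- min(cand)
      path <- c(path, u)
    }
    return(mk(path))
  }
  if (!via %in% g$nodes || via == source || via == target) return(NULL)
  adj <- adjacency_list(g)
  d_via <- graph_distances(g, via)
  d_tgt <- graph_distances(g, target)
  lb <- d_via[as.character(source)] + d_tgt[as.character(via)]
  if (!is.finite(lb)) return(NULL)
  if (is.null(max_len)) max_len <- length(g$nodes) - 1L
  if (max(2, lb) > max_len) return(NULL)
  for (L in seq(from = max(2, lb), to = max_len)) {
    res <- via_dfs(source, target, via, L, adj, d_via, d_tgt)
    if (!is.null(res)) return(mk(res))
  }
  NULL
}

# Depth-bounded DFS for a simple source->target path of exactly L edges
# containing `via` as an interior node. Neighbors are explored in ascending
# order, so the first complete path is the lexicographically smallest of
# length L. BFS distances give admissible pruning bounds.
via_dfs <- function(source, target, via, L, adj, d_via, d_tgt) {
  path <- integer(L + 1)
  path[1] <- source
  on_path <- stats::setNames(logical(length(adj)), names(adj))
  on_path[as.character(source)] <- TRUE
  recurse <- function(u, depth, via_seen) {
    if (u == target)
      return(if (depth == L && via_seen) path[seq_len(depth + 1)] else NULL)
    if (depth == L) return(NULL)
    rem <- L - depth
    bound <- if (via_seen) d_tgt[as.character(u)]
             else d_via[as.character(u)] + d_tgt[as.character(via)]
    if (!is.finite(bound) || bound > rem) return(NULL)
    for (v in adj[[as.character(u)]]) {
      key <- as.character(v)
      if (on_path[key]) next
      if (v == target && depth + 1 < L) next
      on_path[key] <<- TRUE
      path[depth + 2] <<- v
      hit <- recurse(v, depth + 1, via_seen || v == via)
      on_path[key] <<- FALSE
      if (!is.null(hit)) return(hit)
    }
    NULL
  }
  recurse(source, 0L, FALSE)
}

#' @export
print.interaction_path <- function(x, ...) {
  cat("interaction_path:", paste(x$residues, collapse = " - "),
      if (isTRUE(x$mediated)) "(mediated)" else "", "\n")
  invisible(x)
}

#' Persistence of the mediator-routed path across a trajectory
#'
#' For every frame, builds the hydrogen-bond graph and asks whether a path from
#' the mutation site to the catalytic histidine exists with the mediator
#' residue (Leu115) as an interior node.
#'
#' @param t A `pdb_trajectory`.
#' @param m Mutation token or `mutation_spec`; its position is the path source.
#' @param cfg A [marker_config()].
#' @return List with `fraction` (of frames bearing a mediated path),
#'   `best_path` (the modal mediated path, an `interaction_path`, or `NULL`),
#'   and `found` (per-frame logical).
#' @export
path_persistence <- function(t, m, cfg = marker_config()) {
  stopifnot(inherits(t, "pdb_trajectory"))
  m <- parse_mutation(m)
  n <- n_frames(t)
  found <- logical(n)
  keys <- character(n)
  paths <- vector("list", n)
  for (i in seq_len(n)) {
    g <- hbond_graph(frame_coords(t, i), t$topology, cfg)
    p <- find_interaction_path(g, m$position, cfg$catalytic_his,
                               via = cfg$mediator)
    if (!is.null(p) && isTRUE(p$mediated)) {
      found[i] <- TRUE
      keys[i] <- paste(p$residues, collapse = "-")
      paths[[i]] <- p
    }
  }
  best <- NULL
  if (any(found)) {
    tab <- table(keys[found])
    modal <- names(tab)[which.max(tab)]
    best <- paths[[which(found & keys == modal)[1]]]
  }
  list(fraction = mean(found), best_path = best, found = found)
}

#' Export a hydrogen-bond graph as a plain-text edge list
#'
#' Writes `res_a, res_b, distance` rows (residue labels such as `LYS17`),
#' loadable by network viewers.
#'
#' @param g An [hbond_graph()].
#' @param topology The `pdb_structure` the graph was computed from.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(g, topology, path) {
  a <- topology$atoms[!topology$atoms$het, ]
  lab <- function(r) {
    nm <- a$resname[match(r, a$resnum)]
    paste0(nm, r)
  }
  df <- data.frame(res_a = lab(g$edges$res_a), res_b = lab(g$edges$res_b),
                   distance = round(g$edges$distance, 3))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
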