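# Per-atom interaction graph: static edges (covalent bonds and user-supplied
# canonical pairing constraints) plus dynamic distance-gated edges, with
# distances, one-/two-hop angles and radial/spherical basis expansions as
# edge features. Node indices are 1-based (R convention); residue indices in
# secondary structures remain 0-based global.

LOCAL_CUTOFF <- 5     # Angstrom, close contacts
GLOBAL_CUTOFF <- 16   # Angstrom, long-range interactions
KNN_CAP <- 20         # per-class cap on dynamic neighbours per atom

# Close-contact classes share angular features; global edges carry only d.
CLOSE_CLASSES <- c("covalent", "pairing", "local")

#' Static edges of a coarse-grained structure
#'
#' Per residue: the P-C4' and C4'-anchor backbone/glycosidic bonds plus the
#' three base-triangle bonds (5 intraresidue edges, 4 when the 5' P is
#' absent); the backbone link C4'(i)-P(i+1) between consecutive residues of
#' a chain; and, per canonical pair of the user-supplied secondary
#' structure, two pairing edges — anchor(i)-anchor(j) and C2(i)-C2(j) —
#' which pin both the distance and the relative twist of the pair.
#'
#' @param s A coarse-grained `rna_structure`.
#' @param ss An `rna_ss` over the structure's residues (0-based global), or
#'   NULL for no pairing constraints.
#' @return Data frame (i, j, class) of undirected edges, 1-based atom rows.
#' @export
build_static_edges <- function(s, ss = NULL) {
  stopifnot(inherits(s, "rna_structure"))
  if (!s$coarse_grained) stop("static edges require a coarse-grained structure")
  a <- s$atoms
  rt <- residue_table(s)
  # atom row lookup per (residue global index, atom name)
  gres <- rt$global_index[match(paste(a$chain, a$res_index),
                                paste(rt$chain, rt$res_index))]
  rowof <- function(g, name) {
    hit <- which(gres == g & a$atom == name)
    if (length(hit) == 1L) hit else NA_integer_
  }
  edges <- NULL
  for (g in rt$global_index) {
    base <- rt$base[g + 1L]
    anc <- anchor_atom_name(base); thr <- third_base_atom_name(base)
    p <- rowof(g, "P"); c4 <- rowof(g, "C4'"); an <- rowof(g, anc)
    c2 <- rowof(g, "C2"); th <- rowof(g, thr)
    if (!is.na(p)) edges <- rbind(edges, c(p, c4))
    edges <- rbind(edges, c(c4, an), c(an, c2), c(c2, th), c(th, an))
  }
  n_cov_intra <- nrow(edges)
  # backbone links between consecutive residues of the same chain
  for (g in rt$global_index) {
    if (g + 1L > max(rt$global_index)) next
    if (rt$chain[g + 2L] != rt$chain[g + 1L]) next
    if (rt$res_index[g + 2L] != rt$res_index[g + 1L] + 1L) next
    pnext <- rowof(g + 1L, "P")
    if (!is.na(pnext)) edges <- rbind(edges, c(rowof(g, "C4'"), pnext))
  }
  cls <- rep("covalent", nrow(edges))
  if (!is.null(ss) && nrow(ss$pairs) > 0) {
    if (max(ss$pairs) >= nrow(rt)) stop("pair index out of range")
    for (k in seq_len(nrow(ss$pairs))) {
      gi <- ss$pairs[k, 1]; gj <- ss$pairs[k, 2]
      ai <- rowof(gi, anchor_atom_name(rt$base[gi + 1L]))
      aj <- rowof(gj, anchor_atom_name(rt$base[gj + 1L]))
      edges <- rbind(edges, c(ai, aj), c(rowof(gi, "C2"), rowof(gj, "C2")))
      cls <- c(cls, "pairing", "pairing")
    }
  }
  data.frame(i = pmin(edges[, 1], edges[, 2]),
             j = pmax(edges[, 1], edges[, 2]), class = cls,
             stringsAsFactors = FALSE)
}

#' Dynamic distance-gated edges
#'
#' Atom pairs with no static edge are connected by a local edge when their
#' distance is at most 5 Angstrom and by a global edge when it lies in
#' (5, 16\] Angstrom; the two classes are disjoint. Candidate edges are
#' accepted in order of increasing distance (ties broken by lower node
#' index) while both endpoints remain below the per-class cap of `k_max`
#' neighbours, so no atom exceeds `k_max` dynamic neighbours per class.
#'
#' @param coords n x 3 coordinate matrix in Angstrom.
#' @param static_edges Data frame from [build_static_edges()] (or NULL).
#' @param k_max Per-atom, per-class neighbour cap.
#' @param local_cutoff,global_cutoff Class distance thresholds in Angstrom.
#' @return Data frame (i, j, class, d) of undirected dynamic edges.
#' @export
build_dynamic_edges <- function(coords, static_edges = NULL, k_max = KNN_CAP,
                                local_cutoff = LOCAL_CUTOFF,
                                global_cutoff = GLOBAL_CUTOFF) {
  n <- nrow(coords)
  if (n < 2L) stop("need at least 2 atoms")
  D <- as.matrix(stats::dist(coords))
  blocked <- matrix(FALSE, n, n)
  if (!is.null(static_edges) && nrow(static_edges) > 0) {
    idx <- cbind(static_edges$i, static_edges$j)
    blocked[idx] <- TRUE
    blocked[idx[, c(2, 1), drop = FALSE]] <- TRUE
  }
  ut <- which(upper.tri(D) & !blocked & D > 0 & D <= global_cutoff,
              arr.ind = TRUE)
  if (nrow(ut) == 0L)
    return(data.frame(i = integer(0), j = integer(0), class = character(0),
                      d = numeric(0)))
  d <- D[ut]
  cls <- ifelse(d <= local_cutoff, "local", "global")
  ord <- order(d, ut[, 1], ut[, 2])
  deg_local <- integer(n); deg_global <- integer(n)
  keep <- logical(length(ord))
  for (k in ord) {
    i <- ut[k, 1]; j <- ut[k, 2]
    if (cls[k] == "local") {
      if (deg_local[i] < k_max && deg_local[j] < k_max) {
        keep[k] <- TRUE
        deg_local[i] <- deg_local[i] + 1L; deg_local[j] <- deg_local[j] + 1L
      }
    } else {
      if (deg_global[i] < k_max && deg_global[j] < k_max) {
        keep[k] <- TRUE
        deg_global[i] <- deg_global[i] + 1L; deg_global[j] <- deg_global[j] + 1L
      }
    }
  }
  out <- data.frame(i = ut[keep, 1], j = ut[keep, 2], class = cls[keep],
                    d = d[keep], stringsAsFactors = FALSE)
  out[order(out$i, out$j), , drop = FALSE]
}

#' Geometric edge features: distances and one-/two-hop angles
#'
#' Expands the undirected edge table into directed edges and, for every
#' directed close-contact edge j -> i (classes covalent, pairing, local),
#' computes the one-hop angles theta between (i - j) and (k - j) over the
#' other close neighbours k of j, and the two-hop angles phi between
#' (i - j) and (m - k) over chains i <- j <- k -> m. Global edges carry
#' only their distance.
#'
#' @param edges Data frame (i, j, class) of undirected edges.
#' @param coords n x 3 coordinates in Angstrom.
#' @return List with `dir_edges` (src, dst, class, d) and parallel lists
#'   `theta` and `phi` of angle vectors (radians, empty for global edges).
#' @export
edge_geometry <- function(edges, coords) {
  de <- data.frame(src = c(edges$i, edges$j), dst = c(edges$j, edges$i),
                   class = c(edges$class, edges$class),
                   stringsAsFactors = FALSE)
  vec <- coords[de$dst, , drop = FALSE] - coords[de$src, , drop = FALSE]
  de$d <- sqrt(rowSums(vec^2))
  if (any(de$d == 0)) stop("coincident atoms on an edge")
  n <- nrow(coords)
  close <- de$class %in% CLOSE_CLASSES
  # close-neighbour adjacency: for node v, the atoms it shares a close edge with
  nbr <- split(de$dst[close], factor(de$src[close], levels = seq_len(n)))
  theta <- vector("list", nrow(de))
  phi <- vector("list", nrow(de))
  ang <- function(u, v) {
    cs <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
    acos(max(-1, min(1, cs)))
  }
  for (e in which(close)) {
    j <- de$src[e]; i <- de$dst[e]
    vij <- coords[i, ] - coords[j, ]
    ks <- setdiff(nbr[[j]], i)
    theta[[e]] <- vapply(ks, function(k) ang(vij, coords[k, ] - coords[j, ]),
                         numeric(1))
    ph <- numeric(0)
    for (k in ks) {
      ms <- setdiff(nbr[[k]], j)
      if (length(ms) > 0)
        ph <- c(ph, vapply(ms, function(m)
          ang(vij, coords[m, ] - coords[k, ]), numeric(1)))
    }
    phi[[e]] <- ph
  }
  theta[!close] <- list(numeric(0))
  phi[!close] <- list(numeric(0))
  list(dir_edges = de, theta = theta, phi = phi)
}

#' Radial and spherical basis expansion of an edge
#'
#' The radial basis is the zeroth-order spherical Bessel family
#' `sqrt(2/c) * sin(n pi d / c) / d` under a smooth cosine envelope that
#' vanishes at the class cutoff `c`; without the envelope the family is
#' orthonormal on \[0, c\] with weight d^2. The spherical basis combines the
#' radial components with 7 angular harmonics (Legendre polynomials
#' P_l(cos theta), l = 0..6) and is only defined for close-contact edges.
#'
#' @param d Distance in Angstrom (> 0).
#' @param theta Angle(s) in radians, or NULL for a distance-only edge.
#' @param cutoff Class cutoff in Angstrom (5 local, 16 global).
#' @param n_radial Number of radial basis functions.
#' @param n_spherical Number of angular harmonics.
#' @return List with `rbf` (length `n_radial`) and `sbf`
#'   (`n_spherical` x `n_radial` matrix, or NULL when `theta` is NULL;
#'   averaged over the supplied angles).
#' @export
basis_expand <- function(d, theta = NULL, cutoff = LOCAL_CUTOFF,
                         n_radial = 16L, n_spherical = 7L) {
  stopifnot(d > 0, cutoff > 0)
  rbf <- radial_basis(d, cutoff, n_radial)
  sbf <- NULL
  if (!is.null(theta)) {
    pl <- if (length(theta) == 0) rep(0, n_spherical)
    else rowMeans(legendre_matrix(cos(theta), n_spherical))
    sbf <- outer(pl, rbf)
  }
  list(rbf = rbf, sbf = sbf)
}

# Enveloped sine-Bessel radial basis; zero at and beyond the cutoff,
# finite as d -> 0.
radial_basis <- function(d, cutoff, n_radial = 16L) {
  if (d >= cutoff) return(rep(0, n_radial))
  env <- 0.5 * (cos(pi * d / cutoff) + 1)
  n <- seq_len(n_radial)
  env * sqrt(2 / cutoff) * sin(n * pi * d / cutoff) / d
}

# Vectorised form: one row of radial basis per distance.
radial_basis_rows <- function(d, cutoff, n_radial = 16L) {
  env <- ifelse(d >= cutoff, 0, 0.5 * (cos(pi * d / cutoff) + 1))
  sin(outer(d, seq_len(n_radial) * pi / cutoff)) *
    (env * sqrt(2 / cutoff) / d)
}

# Legendre polynomials P_0..P_{L-1} at x (vectorised over x): L x |x| matrix.
legendre_matrix <- function(x, L) {
  out <- matrix(0, L, length(x))
  out[1, ] <- 1
  if (L > 1) out[2, ] <- x
  if (L > 2) for (l in 2:(L - 1))
    out[l + 1, ] <- ((2 * l - 1) * x * out[l, ] - (l - 1) * out[l - 1, ]) / l
  out
}

#' Assemble the full interaction graph for the denoiser
#'
#' Nodes follow structure atom order and carry the one-hot atom type
#' (C/P/N), the C4' flag, the one-hot residue type, the residue's sequence
#' embedding (shared by all of its atoms) and the diffusion time embedding.
#' Static edges come first, then dynamic edges built from the supplied
#' coordinates; all geometry is computed in unscaled Angstrom.
#'
#' @param s A coarse-grained `rna_structure` (coordinates in Angstrom).
#' @param ss An `rna_ss` or NULL.
#' @param seq_embeddings Residue x 256 embedding matrix
#'   (see [embed_sequences()]).
#' @param t_embedding Length-16 time-embedding vector
#'   (see [time_embedding()]).
#' @param coords Optional override of the coordinates used for dynamic
#'   edges and geometry (defaults to the structure's own).
#' @return An `rna_graph`: node table + feature matrix, undirected edge
#'   table, directed-edge geometry and pooled basis features.
#' @export
assemble_graph <- function(s, ss = NULL, seq_embeddings = NULL,
                           t_embedding = rep(0, 16), coords = NULL) {
  rt <- residue_table(s)
  a <- s$atoms
  if (is.null(coords)) coords <- coords_matrix(s)
  n <- nrow(a)
  gres <- rt$global_index[match(paste(a$chain, a$res_index),
                                paste(rt$chain, rt$res_index))]
  if (is.null(seq_embeddings))
    seq_embeddings <- matrix(0, nrow(rt), 256)
  if (nrow(seq_embeddings) != nrow(rt))
    stop("embedding count does not match residue count")
  atom_onehot <- cbind(C = as.numeric(a$element == "C"),
                       P = as.numeric(a$element == "P"),
                       N = as.numeric(a$element == "N"))
  res_onehot <- cbind(A = as.numeric(a$base == "A"),
                      G = as.numeric(a$base == "G"),
                      C = as.numeric(a$base == "C"),
                      U = as.numeric(a$base == "U"))
  feat <- cbind(atom_onehot, c4 = as.numeric(a$atom == "C4'"), res_onehot,
                seq_embeddings[gres + 1L, , drop = FALSE],
                matrix(t_embedding, n, length(t_embedding), byrow = TRUE))
  static <- build_static_edges(s, ss)
  static$d <- sqrt(rowSums((coords[static$i, , drop = FALSE] -
                              coords[static$j, , drop = FALSE])^2))
  dynamic <- build_dynamic_edges(coords, static)
  edges <- rbind(static, dynamic)
  geom <- edge_geometry(edges[, c("i", "j", "class")], coords)
  de <- geom$dir_edges
  close <- de$class %in% CLOSE_CLASSES
  rbf_dim <- 16L; sbf_dim <- 7L * 16L
  rbf <- matrix(0, nrow(de), rbf_dim)
  sbf <- matrix(0, nrow(de), sbf_dim)
  for (e in seq_len(nrow(de))) {
    if (close[e]) {
      b <- basis_expand(de$d[e], geom$theta[[e]], cutoff = LOCAL_CUTOFF)
      rbf[e, ] <- b$rbf
      sbf[e, ] <- as.numeric(b$sbf)
    } else {
      rbf[e, ] <- radial_basis(de$d[e], GLOBAL_CUTOFF)
    }
  }
  structure(list(nodes = data.frame(atom = a$atom, base = a$base,
                                    residue = gres, stringsAsFactors = FALSE),
                 node_features = feat,
                 coords = coords,
                 edges = edges,
                 dir_edges = de,
                 theta = geom$theta, phi = geom$phi,
                 rbf = rbf, sbf = sbf,
                 node_count = n, edge_count = nrow(edges)),
            class = "rna_graph")
}

#' @export
print.rna_graph <- function(x, ...) {
  cat(sprintf("rna_graph: %d nodes, %d undirected edges (%s)\n",
              x$node_count, x$edge_count,
              paste(names(table(x$edges$class)), table(x$edges$class),
                    sep = ":", collapse = ", ")))
  invisible(x)
}

#' Dump a graph as delimited node/edge tables
#' @param g An `rna_graph`.
#' @param prefix Output path prefix (writes `<prefix>_nodes.tsv` and
#'   `<prefix>_edges.tsv` with deterministic ordering).
#' @export
graph_dump <- function(g, prefix) {
  ed <- g$edges[order(g$edges$i, g$edges$j, g$edges$class), ]
  utils::write.table(ed, paste0(prefix, "_edges.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(g$nodes, paste0(prefix, "_nodes.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(prefix)
}
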