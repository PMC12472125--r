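# Structure comparison: superposed RMSD, eRMSD, INF, plus the geometric
# canonical-pair annotator that feeds INF(WCF).

#' Optimal rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimising the RMSD of `moving`
#' onto `fixed` (rows correspond).
#'
#' @param moving,fixed n x 3 coordinate matrices, n >= 3.
#' @return List with `R` (3 x 3 rotation applied on the right of row
#'   vectors), `t` (translation), `rmsd`, and `transform(xyz)` applying the
#'   fit to arbitrary coordinates.
#' @export
kabsch_superpose <- function(moving, fixed) {
  stopifnot(nrow(moving) == nrow(fixed), nrow(moving) >= 3)
  cm <- colMeans(moving); cf <- colMeans(fixed)
  P <- sweep(moving, 2, cm); Q <- sweep(fixed, 2, cf)
  H <- t(P) %*% Q
  sv <- svd(H)
  d <- sign(det(sv$u %*% t(sv$v)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  fit <- sweep(P %*% R, 2, cf, "+")
  rmsd <- sqrt(mean(rowSums((fit - fixed)^2)))
  tvec <- cf - as.numeric(cm %*% R)
  list(R = R, t = tvec, rmsd = rmsd,
       transform = function(xyz) sweep(xyz %*% R, 2, tvec, "+"))
}

# Atom correspondence between two structures by (residue global index,
# atom name); returns matching coordinate matrices.
corresponding_coords <- function(pred, ref, atoms = NULL) {
  ap <- pred$atoms; ar <- ref$atoms
  rtp <- residue_table(pred); rtr <- residue_table(ref)
  if (!identical(rtp$base, rtr$base))
    stop("structures have different residue sequences")
  gp <- rtp$global_index[match(paste(ap$chain, ap$res_index),
                               paste(rtp$chain, rtp$res_index))]
  gr <- rtr$global_index[match(paste(ar$chain, ar$res_index),
                               paste(rtr$chain, rtr$res_index))]
  kp <- paste(gp, ap$atom); kr <- paste(gr, ar$atom)
  if (!is.null(atoms)) {
    selp <- ap$atom %in% atoms; selr <- ar$atom %in% atoms
    ap <- ap[selp, ]; ar <- ar[selr, ]; kp <- kp[selp]; kr <- kr[selr]
  }
  common <- intersect(kp, kr)
  if (length(common) == 0L) stop("no common atoms between structures")
  list(pred = as.matrix(ap[match(common, kp), c("x", "y", "z")]),
       ref = as.matrix(ar[match(common, kr), c("x", "y", "z")]))
}

#' Root-mean-square deviation between two structures
#'
#' Atoms are corresponded by residue position and atom name. With
#' `superpose = TRUE` (default) an optimal least-squares rigid fit is applied
#' first; with `FALSE` the raw deviation in the given frames is returned.
#'
#' @param pred,ref `rna_structure` objects with identical residue sequences.
#' @param superpose Apply the Kabsch fit before measuring?
#' @param atoms Optional atom-name filter (e.g. `"C4'"` for a backbone-trace
#'   RMSD).
#' @return RMSD in Angstrom.
#' @export
kabsch_rmsd <- function(pred, ref, superpose = TRUE, atoms = NULL) {
  cc <- corresponding_coords(pred, ref, atoms = atoms)
  if (!superpose) return(sqrt(mean(rowSums((cc$pred - cc$ref)^2))))
  if (nrow(cc$pred) < 3) stop("need >= 3 common atoms to superpose")
  kabsch_superpose(cc$pred, cc$ref)$rmsd
}

#' eRMSD parameters
#'
#' The rescaling constants and cutoff of the published eRMSD definition:
#' base-relative positions are shrunk by 5 Angstrom in the base plane and
#' 3 Angstrom along the base normal, and the smooth indicator G vanishes at
#' rescaled distance `cutoff`.
#'
#' @param scale_xy,scale_z Anisotropic rescaling divisors (Angstrom).
#' @param cutoff Dimensionless rescaled-distance cutoff.
#' @return List of class `ermsd_params`; `gamma` is `pi / cutoff`.
#' @export
ermsd_params <- function(scale_xy = 5, scale_z = 3, cutoff = 2.4) {
  stopifnot(scale_xy > 0, scale_z > 0, cutoff > 0)
  structure(list(scale_xy = scale_xy, scale_z = scale_z, cutoff = cutoff,
                 gamma = pi / cutoff), class = "ermsd_params")
}

# Base-fixed orthonormal frames: one row block per residue.
# Origin: centroid of (anchor, C2, third). x toward C2, z normal to the
# base triangle. Requires the three base-triangle atoms.
base_frames <- function(s) {
  rt <- residue_table(s)
  anchors <- atom_per_residue(s, c("N9", "N1"))
  c2 <- atom_per_residue(s, "C2")
  third <- atom_per_residue(s, c("C6", "C4"))
  if (anyNA(anchors) || anyNA(c2) || anyNA(third))
    stop("missing base atoms required for eRMSD frames")
  origin <- (anchors + c2 + third) / 3
  n <- nrow(rt)
  R <- array(NA_real_, c(n, 3, 3))
  for (i in seq_len(n)) {
    x <- c2[i, ] - origin[i, ]
    x <- x / sqrt(sum(x^2))
    zv <- pracma_cross(c2[i, ] - origin[i, ], third[i, ] - origin[i, ])
    zv <- zv / sqrt(sum(zv^2))
    y <- pracma_cross(zv, x)
    R[i, , ] <- cbind(x, y, zv)   # columns are the frame axes
  }
  list(origin = origin, R = R, n = n)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Smooth indicator G of the eRMSD definition, mapping a rescaled relative
# position to a 4-vector; zero at/beyond the cutoff, continuous everywhere.
ermsd_g <- function(rtilde, params) {
  rho <- sqrt(sum(rtilde^2))
  if (rho >= params$cutoff || rho == 0) return(c(0, 0, 0, 0))
  g <- params$gamma
  c(sin(g * rho) * rtilde / rho, 1 + cos(g * rho)) / g
}

# All-pairs G vectors for one structure: (n*n) x 4 matrix, row-major over
# ordered pairs (i, j), zero rows on the diagonal.
ermsd_gmat <- function(s, params) {
  fr <- base_frames(s)
  n <- fr$n
  out <- matrix(0, n * n, 4)
  for (i in seq_len(n)) {
    Ri <- fr$R[i, , ]
    for (j in seq_len(n)) {
      if (i == j) next
      v <- as.numeric(t(Ri) %*% (fr$origin[j, ] - fr$origin[i, ]))
      rtilde <- v / c(params$scale_xy, params$scale_xy, params$scale_z)
      out[(i - 1L) * n + j, ] <- ermsd_g(rtilde, params)
    }
  }
  out
}

#' eRMSD between two structures
#'
#' Base-centric structural distance: every ordered base pair (i, j) is
#' described by the position of base j in the base-fixed frame of base i,
#' anisotropically rescaled and passed through the smooth indicator G; the
#' eRMSD is the root mean square of the G differences over all ordered
#' pairs, normalised by the residue count.
#'
#' @param pred,ref `rna_structure` objects with identical residue sequences
#'   carrying the base-triangle atoms.
#' @param params An [ermsd_params()] object.
#' @return Dimensionless eRMSD (>= 0, 0 for identical base networks).
#' @export
ermsd <- function(pred, ref, params = ermsd_params()) {
  rtp <- residue_table(pred); rtr <- residue_table(ref)
  if (!identical(rtp$base, rtr$base))
    stop("structures have different residue sequences")
  gp <- ermsd_gmat(pred, params)
  gr <- ermsd_gmat(ref, params)
  sqrt(sum((gp - gr)^2) / nrow(rtp))
}

#' Geometric annotation of canonical base pairs
#'
#' Distance/orientation detector for Watson-Crick-Franklin pairs on
#' coordinates alone: two residues are candidate partners when their bases
#' are complementary (A-U, G-C and, by default, the G-U wobble), the
#' glycosidic anchor atoms (N9/N1) fall within `anchor_range`, the C2-C2
#' distance falls within `c2_range`, and the base planes are tilted by less
#' than `max_plane_angle`. Candidates are accepted greedily by closeness to
#' ideal pair geometry, each residue joining at most one reported pair.
#'
#' @param s An `rna_structure` with base-triangle atoms.
#' @param wobble Count G-U as canonical (default TRUE).
#' @param anchor_range,c2_range Distance windows in Angstrom.
#' @param max_plane_angle Maximum angle between base-plane normals, degrees.
#' @return Two-column integer matrix of 0-based global residue indices,
#'   one row per pair (possibly zero rows).
#' @export
annotate_wcf_pairs <- function(s, wobble = TRUE,
                               anchor_range = c(7.5, 10.5),
                               c2_range = c(4.5, 7.5),
                               max_plane_angle = 35) {
  rt <- residue_table(s)
  n <- nrow(rt)
  anchors <- atom_per_residue(s, c("N9", "N1"))
  c2 <- atom_per_residue(s, "C2")
  third <- atom_per_residue(s, c("C6", "C4"))
  ok <- !(is.na(anchors[, 1]) | is.na(c2[, 1]) | is.na(third[, 1]))
  comp <- c(A = "U", U = "A", G = "C", C = "G")
  normals <- matrix(NA_real_, n, 3)
  for (i in which(ok)) {
    v <- pracma_cross(c2[i, ] - anchors[i, ], third[i, ] - anchors[i, ])
    normals[i, ] <- v / sqrt(sum(v^2))
  }
  cand <- NULL
  for (i in seq_len(n - 1L)) {
    if (!ok[i]) next
    for (j in (i + 1L):n) {
      if (!ok[j]) next
      bi <- rt$base[i]; bj <- rt$base[j]
      compat <- (comp[[bi]] == bj) ||
        (wobble && ((bi == "G" && bj == "U") || (bi == "U" && bj == "G")))
      if (!compat) next
      da <- sqrt(sum((anchors[i, ] - anchors[j, ])^2))
      if (da < anchor_range[1] || da > anchor_range[2]) next
      dc <- sqrt(sum((c2[i, ] - c2[j, ])^2))
      if (dc < c2_range[1] || dc > c2_range[2]) next
      ang <- acos(min(1, abs(sum(normals[i, ] * normals[j, ])))) * 180 / pi
      if (ang > max_plane_angle) next
      # deviation from ideal pair geometry (anchor 9.0, C2 6.0, coplanar)
      score <- abs(da - 9) + abs(dc - 6) + ang / 90
      cand <- rbind(cand, c(i, j, score))
    }
  }
  if (is.null(cand)) return(matrix(integer(0), ncol = 2))
  cand <- cand[order(cand[, 3], cand[, 1], cand[, 2]), , drop = FALSE]
  used <- rep(FALSE, n)
  out <- NULL
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1]; j <- cand[k, 2]
    if (used[i] || used[j]) next
    used[i] <- used[j] <- TRUE
    out <- rbind(out, c(i - 1L, j - 1L))   # back to 0-based global indices
  }
  out <- matrix(as.integer(out), ncol = 2)
  out[order(out[, 1]), , drop = FALSE]
}

canonical_pair_key <- function(pairs) {
  if (is.null(pairs) || nrow(pairs) == 0L) return(character(0))
  apply(cbind(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2])),
        1, paste, collapse = "-")
}

#' Interaction Network Fidelity
#'
#' Geometric mean of precision and recall over base-pair sets:
#' `INF = sqrt(TP/(TP+FP) * TP/(TP+FN))`. Two empty sets agree perfectly
#' (INF = 1); exactly one empty set scores 0.
#'
#' @param pred_pairs,ref_pairs Two-column matrices of residue-index pairs
#'   over the same index space (order within a pair ignored).
#' @return List with `inf` in \[0, 1\] and `confusion` (TP/FP/FN counts).
#' @export
inf_score <- function(pred_pairs, ref_pairs) {
  kp <- canonical_pair_key(pred_pairs)
  kr <- canonical_pair_key(ref_pairs)
  tp <- length(intersect(kp, kr))
  fp <- length(setdiff(kp, kr))
  fn <- length(setdiff(kr, kp))
  inf <- if (tp + fp + fn == 0L) 1
  else if (tp == 0L) 0
  else sqrt(tp / (tp + fp) * tp / (tp + fn))
  list(inf = inf, confusion = c(TP = tp, FP = fp, FN = fn))
}

#' Full metric report for one prediction/reference pair
#'
#' @param pred,ref Comparable `rna_structure` objects.
#' @param pred_nwc_pairs,ref_nwc_pairs Optional externally annotated
#'   non-canonical pair sets; INF(NWC) is reported only when both are given
#'   (the package does not annotate non-canonical geometries itself).
#' @param wobble Passed to [annotate_wcf_pairs()].
#' @return List of class `metric_report` with `rmsd`, `ermsd`, `inf_wcf`,
#'   `inf_nwc` (NA when undefined) and `confusion_wcf`.
#' @export
evaluate_structures <- function(pred, ref, pred_nwc_pairs = NULL,
                                ref_nwc_pairs = NULL, wobble = TRUE) {
  pw <- annotate_wcf_pairs(pred, wobble = wobble)
  rw <- annotate_wcf_pairs(ref, wobble = wobble)
  wcf <- inf_score(pw, rw)
  nwc <- if (!is.null(pred_nwc_pairs) && !is.null(ref_nwc_pairs))
    inf_score(pred_nwc_pairs, ref_nwc_pairs)$inf else NA_real_
  structure(list(rmsd = kabsch_rmsd(pred, ref),
                 ermsd = ermsd(pred, ref),
                 inf_wcf = wcf$inf,
                 inf_nwc = nwc,
                 confusion_wcf = wcf$confusion),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("RMSD %.3f A | eRMSD %.3f | INF(WCF) %.3f | INF(NWC) %s\n",
              x$rmsd, x$ermsd, x$inf_wcf,
              if (is.na(x$inf_nwc)) "n/a" else sprintf("%.3f", x$inf_nwc)))
  cat(sprintf("pair confusion: TP %d FP %d FN %d\n",
              x$confusion_wcf["TP"], x$confusion_wcf["FP"],
              x$confusion_wcf["FN"]))
  invisible(x)
}

#' Serialize / restore a metric report as a one-line text record
#' @param x A `metric_report`.
#' @param path File path.
#' @export
write_metric_report <- function(x, path) {
  df <- data.frame(rmsd = x$rmsd, ermsd = x$ermsd, inf_wcf = x$inf_wcf,
                   inf_nwc = x$inf_nwc, tp = x$confusion_wcf["TP"],
                   fp = x$confusion_wcf["FP"], fn = x$confusion_wcf["FN"])
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_metric_report
#' @export
read_metric_report <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  structure(list(rmsd = df$rmsd, ermsd = df$ermsd, inf_wcf = df$inf_wcf,
                 inf_nwc = df$inf_nwc,
                 confusion_wcf = c(TP = df$tp, FP = df$fp, FN = df$fn)),
            class = "metric_report")
}
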