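# Local 3D RNA descriptors: extraction around each central residue, and
# curation of a descriptor set by identity, segment-count and geometric
# redundancy filters.

#' Curation thresholds
#'
#' Defaults: duplicates are descriptors sharing more than 80% sequence
#' identity; descriptors with more than three segments are discarded; two
#' descriptors are geometrically redundant when their central elements
#' superpose within 2.5 Angstrom, at least one duplex (central element plus
#' one more segment) fits within 4 Angstrom, the alignment covers more than
#' half the structural elements and more than two thirds of the residues,
#' and the overall alignment RMSD is at most 3.5 Angstrom.
#'
#' @param max_identity Maximum tolerated sequence identity fraction.
#' @param max_segments Maximum number of segments kept.
#' @param rmsd_central_max,rmsd_duplex_max,rmsd_overall_max RMSD thresholds
#'   (Angstrom).
#' @param min_element_coverage,min_residue_coverage Coverage fractions that
#'   must be exceeded.
#' @return List of class `curation_config`.
#' @export
curation_config <- function(max_identity = 0.80, max_segments = 3L,
                            rmsd_central_max = 2.5, rmsd_duplex_max = 4.0,
                            rmsd_overall_max = 3.5,
                            min_element_coverage = 1 / 2,
                            min_residue_coverage = 2 / 3) {
  stopifnot(max_identity > 0, max_identity <= 1, max_segments >= 1,
            rmsd_central_max > 0, rmsd_duplex_max > 0, rmsd_overall_max > 0,
            min_element_coverage > 0, min_element_coverage <= 1,
            min_residue_coverage > 0, min_residue_coverage <= 1)
  structure(as.list(environment()), class = "curation_config")
}

#' Extract local 3D descriptors from a full-atom structure
#'
#' For every central residue (the 3rd through the (N-2)th of each chain,
#' giving N-4 descriptors per chain), all residues whose C5' atom lies
#' within `threshold` of the central C5' are collected, each central and
#' in-contact residue is extended by two flanking residues on each side
#' (truncated at chain termini), and overlapping extensions are merged into
#' maximal contiguous segments. The default threshold of 16 Angstrom covers
#' the C5'-C5' span of canonical and non-canonical contacts.
#'
#' @param s A full-atom `rna_structure` (must carry C5' atoms; run before
#'   [coarse_grain()], which removes them).
#' @param threshold Contact distance T in Angstrom.
#' @param parent_id Identifier stored on each descriptor.
#' @return List of `rna_descriptor` objects, each holding its central
#'   residue, segment table (parent residue indices) and sub-structure.
#' @export
extract_descriptors <- function(s, threshold = 16, parent_id = "structure") {
  stopifnot(inherits(s, "rna_structure"), threshold > 0)
  rt <- residue_table(s)
  c5 <- atom_per_residue(s, "C5'")
  if (all(is.na(c5[, 1]))) stop("structure has no C5' atoms")
  if (anyNA(c5[, 1]))
    warning("residues lacking C5' are excluded from the contact search: ",
            paste(rt$global_index[is.na(c5[, 1])], collapse = ", "))
  chains <- unique(rt$chain)
  chain_len <- table(factor(rt$chain, levels = chains))
  out <- list()
  for (ch in chains) {
    nc <- chain_len[[ch]]
    if (nc < 5L) next
    for (ci in 2:(nc - 3L)) {        # 0-based central index within chain
      crow <- which(rt$chain == ch & rt$res_index == ci)
      if (is.na(c5[crow, 1])) next
      d2 <- rowSums(sweep(c5, 2, c5[crow, ])^2)
      contacts <- which(!is.na(d2) & d2 <= threshold^2)
      core <- union(crow, contacts)
      # extend by 2 on each side within each core residue's own chain
      ext <- unique(unlist(lapply(core, function(r) {
        i <- rt$res_index[r]; chr <- rt$chain[r]
        lim <- chain_len[[chr]] - 1L
        idx <- max(0L, i - 2L):min(lim, i + 2L)
        which(rt$chain == chr & rt$res_index %in% idx)
      })))
      ext <- sort(ext)
      segs <- merge_runs(rt[ext, , drop = FALSE])
      central_seg <- which(segs$chain == ch & segs$start <= ci & segs$end >= ci)
      d <- structure(list(parent_id = parent_id,
                          central = list(chain = ch, res_index = ci),
                          central_segment = central_seg,
                          segments = segs,
                          threshold = threshold,
                          structure = subset_residues(s, ext)),
                     class = "rna_descriptor")
      out[[length(out) + 1L]] <- d
    }
  }
  out
}

# Merge sorted residue-table rows into maximal contiguous per-chain runs.
merge_runs <- function(rt_rows) {
  segs <- NULL
  for (ch in unique(rt_rows$chain)) {
    idx <- sort(rt_rows$res_index[rt_rows$chain == ch])
    brk <- c(0L, which(diff(idx) > 1L), length(idx))
    for (k in seq_len(length(brk) - 1L)) {
      run <- idx[(brk[k] + 1L):brk[k + 1L]]
      segs <- rbind(segs, data.frame(chain = ch, start = run[1],
                                     end = run[length(run)],
                                     stringsAsFactors = FALSE))
    }
  }
  segs$length <- segs$end - segs$start + 1L
  segs
}

#' @export
print.rna_descriptor <- function(x, ...) {
  cat(sprintf("rna_descriptor (%s): central %s:%d, %d segment(s), %d residues\n",
              x$parent_id, x$central$chain, x$central$res_index,
              nrow(x$segments), sum(x$segments$length)))
  invisible(x)
}

#' Per-segment base strings of a descriptor
#' @param d An `rna_descriptor`.
#' @export
segment_sequences <- function(d) {
  rt <- residue_table(d$structure)
  vapply(seq_len(nrow(d$segments)), function(k) {
    sel <- rt$chain == d$segments$chain[k] &
      rt$res_index >= d$segments$start[k] & rt$res_index <= d$segments$end[k]
    paste(rt$base[sel], collapse = "")
  }, character(1))
}

#' @rdname segment_sequences
#' @export
descriptor_sequence <- function(d) paste(segment_sequences(d), collapse = "")

# C5' trace (n x 3) of one segment of a descriptor.
segment_trace <- function(d, k) {
  rt <- residue_table(d$structure)
  c5 <- atom_per_residue(d$structure, "C5'")
  sel <- rt$chain == d$segments$chain[k] &
    rt$res_index >= d$segments$start[k] & rt$res_index <= d$segments$end[k]
  c5[sel, , drop = FALSE]
}

#' Pairwise sequence identity
#'
#' Global alignment with match 1, mismatch 0 and gap -1 (via
#' `Biostrings::pairwiseAlignment`); identity is the fraction of identical
#' aligned positions over the alignment length, a symmetric quantity.
#'
#' @param a,b Non-empty base strings over A/C/G/U.
#' @return Identity fraction in \[0, 1\].
#' @export
sequence_identity <- function(a, b) {
  a <- toupper(a); b <- toupper(b)
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  if (grepl("[^ACGU]", a) || grepl("[^ACGU]", b))
    stop("sequences must be over A/C/G/U")
  m <- matrix(0, 4, 4, dimnames = list(c("A", "C", "G", "U"),
                                       c("A", "C", "G", "U")))
  diag(m) <- 1
  aln <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                       substitutionMatrix = m,
                                       gapOpening = 0, gapExtension = 1)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  ps <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  sum(pa == ps) / length(pa)
}

#' Minimum-cost assignment (Hungarian algorithm)
#'
#' Solves the square linear assignment problem in O(n^3) by successive
#' shortest augmenting paths with potentials.
#'
#' @param cost Square numeric cost matrix.
#' @return Integer vector `a` with `a[i]` the column assigned to row i.
#' @export
hungarian_solve <- function(cost) {
  stopifnot(is.matrix(cost), nrow(cost) == ncol(cost), all(is.finite(cost)))
  n <- nrow(cost)
  u <- numeric(n)            # row potentials
  vv <- numeric(n + 1)       # column potentials, col 0 (virtual) at index 1
  pp <- integer(n + 1)       # pp[j+1]: row matched to column j, 0 = none
  way <- integer(n)          # predecessor column of column j on the path
  for (i in seq_len(n)) {
    pp[1] <- i
    j0 <- 0L
    minv <- rep(Inf, n)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- pp[j0 + 1L]
      delta <- Inf; j1 <- 0L
      for (j in seq_len(n)) {
        if (used[j + 1L]) next
        cur <- cost[i0, j] - u[i0] - vv[j + 1L]
        if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
        if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
      }
      for (j in 0:n) {
        if (used[j + 1L]) {
          if (pp[j + 1L] > 0L) u[pp[j + 1L]] <- u[pp[j + 1L]] + delta
          vv[j + 1L] <- vv[j + 1L] - delta
        } else if (j > 0L) minv[j] <- minv[j] - delta
      }
      j0 <- j1
      if (pp[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      pp[j0 + 1L] <- pp[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  out <- integer(n)
  for (j in seq_len(n)) out[pp[j + 1L]] <- j
  out
}

# Best sliding-window RMSD between two traces, optionally after applying a
# rigid transform to the second. refit = TRUE performs a fresh Kabsch fit
# per window; refit = FALSE measures the raw deviation.
best_window_fit <- function(ta, tb, refit = TRUE) {
  la <- nrow(ta); lb <- nrow(tb)
  w <- min(la, lb)
  best <- list(rmsd = Inf)
  for (oa in 0:(la - w)) for (ob in 0:(lb - w)) {
    wa <- ta[(oa + 1):(oa + w), , drop = FALSE]
    wb <- tb[(ob + 1):(ob + w), , drop = FALSE]
    r <- if (refit && w >= 3) kabsch_superpose(wb, wa)
    else list(rmsd = sqrt(mean(rowSums((wa - wb)^2))), transform = identity)
    if (r$rmsd < best$rmsd)
      best <- list(rmsd = r$rmsd, oa = oa, ob = ob, w = w, fit = r)
  }
  best
}

#' Partial structural alignment of two descriptors
#'
#' The central elements (the segments containing the central residues) are
#' superposed first by an optimal rigid fit of their C5' traces (sliding the
#' shorter trace along the longer). The remaining segments are then matched
#' by a minimum-cost assignment in which every segment also has a dummy
#' (unmatched) option priced at `dummy_penalty`, so the alignment may be
#' partial. Segment costs are raw per-segment C5' RMSDs in the frame fixed
#' by the central superposition.
#'
#' @param a,b `rna_descriptor` objects carrying C5' coordinates.
#' @param dummy_penalty Cost of leaving a segment unmatched (Angstrom).
#' @return List of class `alignment_result`: `matched_segments` (two-column
#'   matrix of segment indices of a and b), `central_rmsd`,
#'   `best_duplex_rmsd` (NA when either descriptor has a single segment),
#'   `overall_rmsd`, `element_coverage`, `residue_coverage`.
#' @export
align_descriptors <- function(a, b, dummy_penalty = 4.0) {
  ca <- a$central_segment; cb <- b$central_segment
  fitc <- best_window_fit(segment_trace(a, ca), segment_trace(b, cb),
                          refit = TRUE)
  transform <- fitc$fit$transform
  # residue correspondences from the central windows
  corr_a <- list(segment_trace(a, ca)[(fitc$oa + 1):(fitc$oa + fitc$w), ,
                                      drop = FALSE])
  corr_b <- list(segment_trace(b, cb)[(fitc$ob + 1):(fitc$ob + fitc$w), ,
                                      drop = FALSE])
  resta <- setdiff(seq_len(nrow(a$segments)), ca)
  restb <- setdiff(seq_len(nrow(b$segments)), cb)
  na <- length(resta); nb <- length(restb)
  matched <- matrix(integer(0), ncol = 2)
  seg_windows <- list()
  if (na > 0 && nb > 0) {
    fits <- vector("list", na * nb)
    cost <- matrix(dummy_penalty, na + nb, na + nb)
    cost[(na + 1):(na + nb), (nb + 1):(nb + na)] <- 0   # dummy-dummy
    for (i in seq_len(na)) for (j in seq_len(nb)) {
      f <- best_window_fit(segment_trace(a, resta[i]),
                           transform(segment_trace(b, restb[j])),
                           refit = FALSE)
      fits[[(i - 1L) * nb + j]] <- f
      cost[i, j] <- f$rmsd
    }
    asg <- hungarian_solve(cost)
    for (i in seq_len(na)) {
      j <- asg[i]
      if (j <= nb && cost[i, j] <= dummy_penalty) {
        matched <- rbind(matched, c(resta[i], restb[j]))
        f <- fits[[(i - 1L) * nb + j]]
        ta <- segment_trace(a, resta[i]); tb <- segment_trace(b, restb[j])
        seg_windows[[length(seg_windows) + 1L]] <- list(
          a = ta[(f$oa + 1):(f$oa + f$w), , drop = FALSE],
          b = tb[(f$ob + 1):(f$ob + f$w), , drop = FALSE])
      }
    }
  }
  # duplex RMSDs: central element + one matched segment, freshly superposed
  duplex <- NA_real_
  if (nrow(matched) > 0) {
    duplex <- min(vapply(seq_len(nrow(matched)), function(k) {
      pa <- rbind(corr_a[[1]], seg_windows[[k]]$a)
      pb <- rbind(corr_b[[1]], seg_windows[[k]]$b)
      kabsch_superpose(pb, pa)$rmsd
    }, numeric(1)))
  }
  all_a <- do.call(rbind, c(corr_a, lapply(seg_windows, `[[`, "a")))
  all_b <- do.call(rbind, c(corr_b, lapply(seg_windows, `[[`, "b")))
  overall <- kabsch_superpose(all_b, all_a)$rmsd
  n_el_matched <- 1L + nrow(matched)
  n_res_matched <- nrow(all_a)
  structure(list(matched_segments = matched,
                 central_rmsd = fitc$rmsd,
                 best_duplex_rmsd = duplex,
                 overall_rmsd = overall,
                 element_coverage =
                   2 * n_el_matched / (nrow(a$segments) + nrow(b$segments)),
                 residue_coverage =
                   2 * n_res_matched /
                   (sum(a$segments$length) + sum(b$segments$length))),
            class = "alignment_result")
}

#' Four-criterion geometric redundancy test
#'
#' Two descriptors are redundant when all of the following hold for their
#' partial alignment: (i) central-element RMSD at most `rmsd_central_max`;
#' (ii) some duplex (central element plus one matched segment) within
#' `rmsd_duplex_max` — vacuously satisfied when either descriptor has a
#' single segment; (iii) element coverage above `min_element_coverage` and
#' residue coverage above `min_residue_coverage`; (iv) overall alignment
#' RMSD at most `rmsd_overall_max`.
#'
#' @param a,b `rna_descriptor` objects.
#' @param cfg A [curation_config()].
#' @return Logical.
#' @export
is_redundant <- function(a, b, cfg = curation_config()) {
  al <- align_descriptors(a, b, dummy_penalty = cfg$rmsd_duplex_max)
  crit_i <- al$central_rmsd <= cfg$rmsd_central_max
  crit_ii <- if (nrow(a$segments) == 1L || nrow(b$segments) == 1L) TRUE
  else !is.na(al$best_duplex_rmsd) &&
    al$best_duplex_rmsd <= cfg$rmsd_duplex_max
  crit_iii <- al$element_coverage > cfg$min_element_coverage &&
    al$residue_coverage > cfg$min_residue_coverage
  crit_iv <- al$overall_rmsd <= cfg$rmsd_overall_max
  crit_i && crit_ii && crit_iii && crit_iv
}

#' Curate a descriptor set
#'
#' Pipeline, in order: (1) drop unfolded fragments — single-segment
#' descriptors in which [annotate_wcf_pairs()] finds no canonical pair;
#' (2) drop descriptors with more than `max_segments` segments; (3) greedy
#' sequence-identity deduplication in input order (a descriptor with more
#' than `max_identity` to an already-kept one is dropped); (4) greedy
#' structural deduplication with [is_redundant()], keeping the first
#' representative.
#'
#' @param descriptors List of `rna_descriptor` objects.
#' @param cfg A [curation_config()].
#' @return The curated sub-list, in input order.
#' @export
curate_dataset <- function(descriptors, cfg = curation_config()) {
  if (length(descriptors) == 0L) return(descriptors)
  folded <- vapply(descriptors, function(d) {
    nrow(d$segments) > 1L || nrow(annotate_wcf_pairs(d$structure)) > 0L
  }, logical(1))
  descriptors <- descriptors[folded]
  descriptors <- Filter(function(d) nrow(d$segments) <= cfg$max_segments,
                        descriptors)
  kept <- list()
  for (d in descriptors) {
    dup <- any(vapply(kept, function(k)
      sequence_identity(descriptor_sequence(d), descriptor_sequence(k)) >
        cfg$max_identity, logical(1)))
    if (!dup) kept[[length(kept) + 1L]] <- d
  }
  final <- list()
  for (d in kept) {
    red <- any(vapply(final, function(k) is_redundant(d, k, cfg), logical(1)))
    if (!red) final[[length(final) + 1L]] <- d
  }
  final
}

#' Family-based train/test partition
#'
#' @param descriptors List of `rna_descriptor` objects.
#' @param labels Named character vector mapping `parent_id` to a family
#'   label (e.g. "rRNA", "tRNA", "riboswitch").
#' @param train_families Families assigned to the training split (default
#'   the ribosomal and transfer RNA families).
#' @return List with `train` and `test` descriptor lists; every descriptor
#'   lands in exactly one split.
#' @export
partition_by_family <- function(descriptors, labels,
                                train_families = c("rRNA", "tRNA")) {
  ids <- vapply(descriptors, `[[`, character(1), "parent_id")
  missing <- setdiff(unique(ids), names(labels))
  if (length(missing) > 0L)
    stop("unlabelled parent_id(s): ", paste(missing, collapse = ", "))
  fam <- unname(labels[ids])
  list(train = descriptors[fam %in% train_families],
       test = descriptors[!(fam %in% train_families)])
}

#' Write a descriptor manifest and per-descriptor PDB files
#'
#' @param descriptors List of `rna_descriptor` objects.
#' @param dir Output directory (created if needed).
#' @return Path of the manifest file, invisibly.
#' @export
write_descriptor_set <- function(descriptors, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_along(descriptors), function(i) {
    d <- descriptors[[i]]
    fn <- sprintf("descriptor_%04d.pdb", i)
    write_pdb(d$structure, file.path(dir, fn))
    data.frame(id = i, parent_id = d$parent_id,
               central = paste0(d$central$chain, ":", d$central$res_index),
               n_segments = nrow(d$segments),
               segments = paste(sprintf("%s:%d-%d", d$segments$chain,
                                        d$segments$start, d$segments$end),
                                collapse = ";"),
               sequence = descriptor_sequence(d),
               file = fn, stringsAsFactors = FALSE)
  })
  manifest <- file.path(dir, "manifest.tsv")
  utils::write.table(do.call(rbind, rows), manifest, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(manifest)
}
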