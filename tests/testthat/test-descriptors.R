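# Line-geometry builder: chains of residues with C5' (and the five coarse
# atoms) laid out along straight lines, giving full control over contacts.
line_structure <- function(chain_specs, spacing = 6) {
  rows <- list()
  for (spec in chain_specs) {
    n <- spec$n
    for (i in seq_len(n)) {
      org <- spec$origin + (i - 1) * spacing * spec$dir
      rows[[length(rows) + 1L]] <- data.frame(
        chain = spec$chain, res_index = i - 1L, auth_number = i, base = "G",
        atom = c("P", "C4'", "C5'", "N9", "C2", "C6"),
        x = org[1] + c(0, 1, 0.5, 2, 2.5, 3),
        y = org[2] + c(0, 0.5, 1, 0, 1, -1),
        z = org[3], stringsAsFactors = FALSE)
    }
  }
  new_rna_structure(do.call(rbind, rows))
}

test_that("descriptor count per chain is N - 4", {
  short <- line_structure(list(list(chain = "A", n = 4, origin = c(0, 0, 0),
                                    dir = c(1, 0, 0))))
  expect_length(extract_descriptors(short), 0L)
  n30 <- make_hairpin(13, 4)   # one chain of 30 residues
  expect_length(extract_descriptors(n30$structure), 26L)
  straight <- line_structure(list(list(chain = "A", n = 9,
                                       origin = c(0, 0, 0),
                                       dir = c(1, 0, 0))))
  expect_length(extract_descriptors(straight), 5L)
})

test_that("descriptor segments match a brute-force contact-scan oracle on a hairpin", {
  hp <- make_hairpin(4, 4)
  ds <- extract_descriptors(hp$structure, 16)
  rt <- residue_table(hp$structure)
  c5 <- coords_matrix(hp$structure, "C5'")
  n <- nrow(rt)
  for (d in ds) {
    ci <- d$central$res_index
    dist <- sqrt(rowSums(sweep(c5, 2, c5[ci + 1, ])^2))
    core <- union(ci, which(dist <= 16) - 1L)
    ext <- sort(unique(unlist(lapply(core, function(i)
      max(0, i - 2):min(n - 1, i + 2)))))
    # reconstruct expected runs
    brk <- c(0, which(diff(ext) > 1), length(ext))
    runs <- lapply(seq_len(length(brk) - 1),
                   function(k) ext[(brk[k] + 1):brk[k + 1]])
    expect_equal(nrow(d$segments), length(runs), info = paste("central", ci))
    for (k in seq_along(runs)) {
      expect_equal(d$segments$start[k], runs[[k]][1])
      expect_equal(d$segments$end[k], runs[[k]][length(runs[[k]])])
    }
    # every in-contact residue lies inside some segment
    for (r in core) {
      expect_true(any(d$segments$start <= r & d$segments$end >= r))
    }
  }
  # the stem forces at least one descriptor spanning both strands of it
  expect_true(any(vapply(ds, function(d)
    min(d$segments$start) <= 1 && max(d$segments$end) >= 10, logical(1))))
})

test_that("an isolated in-contact residue interior to its chain yields a 5-residue segment", {
  s <- line_structure(list(
    list(chain = "A", n = 9, origin = c(0, 0, 0), dir = c(1, 0, 0)),
    # chain B parallel to A, only its middle residue within 16 A of A's centre
    list(chain = "B", n = 5, origin = c(24 - 12, 15, 0), dir = c(1, 0, 0))))
  ds <- extract_descriptors(s, 16)
  d_mid <- ds[[3]]          # central residue index 4 of chain A (x = 24)
  expect_equal(d_mid$central$res_index, 4L)
  bseg <- d_mid$segments[d_mid$segments$chain == "B", ]
  expect_equal(nrow(bseg), 1L)
  expect_equal(bseg$length, 5L)
  # segments not truncated by a chain terminus can never be shorter than 5
  chain_n <- c(A = 9L, B = 5L)
  for (d in ds) {
    interior <- d$segments$start > 0 &
      d$segments$end < chain_n[d$segments$chain] - 1L
    expect_true(all(d$segments$length[interior] >= 5))
  }
})

test_that("sequence identity follows the stated alignment scheme", {
  expect_equal(sequence_identity("GAUC", "GAUC"), 1.0)
  expect_equal(sequence_identity("AAAA", "UUUU"), 0.0)
  expect_equal(sequence_identity("GAUC", "GAUU"), 0.75)
  expect_equal(sequence_identity("GAUC", "GAUU"),
               sequence_identity("GAUU", "GAUC"))
  expect_error(sequence_identity("", "AAC"), "empty")
  # exhaustive alignment oracle on random 4-mers: enumerate every global
  # alignment (match 1 / mismatch 0 / gap -1), keep the best-scoring ones
  enum_align <- function(a, b) {
    rec <- function(i, j, pa, pb) {
      if (i > nchar(a) && j > nchar(b)) return(list(list(pa = pa, pb = pb)))
      out <- list()
      if (i <= nchar(a) && j <= nchar(b))
        out <- c(out, rec(i + 1, j + 1, c(pa, substr(a, i, i)),
                          c(pb, substr(b, j, j))))
      if (i <= nchar(a))
        out <- c(out, rec(i + 1, j, c(pa, substr(a, i, i)), c(pb, "-")))
      if (j <= nchar(b))
        out <- c(out, rec(i, j + 1, c(pa, "-"), c(pb, substr(b, j, j))))
      out
    }
    rec(1, 1, character(0), character(0))
  }
  set.seed(4)
  for (rep in 1:5) {
    a <- paste(sample(c("A", "C", "G", "U"), 4, TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G", "U"), 4, TRUE), collapse = "")
    alns <- enum_align(a, b)
    scores <- vapply(alns, function(al)
      sum(ifelse(al$pa == "-" | al$pb == "-", -1, al$pa == al$pb)),
      numeric(1))
    best <- alns[scores == max(scores)]
    ids <- vapply(best, function(al) mean(al$pa == al$pb), numeric(1))
    expect_true(any(abs(sequence_identity(a, b) - ids) < 1e-12),
                info = paste(a, b))
  }
})

test_that("hungarian assignment matches brute-force enumeration", {
  set.seed(42)
  for (n in 2:5) for (rep in 1:10) {
    C <- matrix(runif(n * n), n, n)
    a <- hungarian_solve(C)
    expect_equal(sort(a), 1:n)
    perms <- as.matrix(expand.grid(rep(list(1:n), n)))
    perms <- perms[apply(perms, 1, function(p) length(unique(p)) == n), ,
                   drop = FALSE]
    best <- min(apply(perms, 1, function(p) sum(C[cbind(1:n, p)])))
    expect_equal(sum(C[cbind(1:n, a)]), best, tolerance = 1e-12)
  }
})

test_that("descriptor alignment is exact on self and rigid-motion copies", {
  hp <- make_hairpin(4, 4)
  d <- extract_descriptors(hp$structure)[[1]]
  al <- align_descriptors(d, d)
  expect_lt(al$central_rmsd, 1e-9)
  expect_lt(al$overall_rmsd, 1e-9)
  expect_equal(al$element_coverage, 1)
  expect_equal(al$residue_coverage, 1)
  d2 <- d
  d2$structure <- transform_structure(d2$structure, angle = 1.2,
                                      shift = c(-3, 8, 1))
  al2 <- align_descriptors(d, d2)
  expect_lt(al2$central_rmsd, 1e-6)
  expect_lt(al2$overall_rmsd, 1e-6)
})

test_that("segment matching recovers the known-best correspondence", {
  # rigid-motion copy: the identity matching has zero cost by construction,
  # every alternative is strictly worse, so the optimum is known a priori
  ms <- make_multisegment_fixture(4, seed = 3)
  ds <- extract_descriptors(ms$structure)
  d <- ds[[which.max(vapply(ds, function(x) nrow(x$segments), integer(1)))]]
  expect_gte(nrow(d$segments), 3)
  d2 <- d
  d2$structure <- transform_structure(d2$structure, angle = 0.6)
  al <- align_descriptors(d, d2, dummy_penalty = 4)
  resta <- setdiff(seq_len(nrow(d$segments)), d$central_segment)
  expect_equal(nrow(al$matched_segments), length(resta))
  expect_true(all(al$matched_segments[, 1] == al$matched_segments[, 2]))
  expect_lt(al$overall_rmsd, 1e-6)
})

test_that("the four-criterion redundancy test matches hand evaluation", {
  hp <- make_hairpin(4, 4)
  d <- extract_descriptors(hp$structure)[[1]]
  cfg <- curation_config()
  expect_true(is_redundant(d, d, cfg))
  # engineered central-element deviation of exactly 3.0 A fails criterion (i):
  # isotropic stretch about the centroid leaves the optimal rotation at the
  # identity, so the fitted C5'-trace RMSD is (k - 1) x the centered trace rms
  d3 <- d
  c5 <- coords_matrix(d3$structure, "C5'")
  rmsc <- sqrt(mean(rowSums(sweep(c5, 2, colMeans(c5))^2)))
  ctr <- colMeans(coords_matrix(d3$structure))
  cs <- sweep(coords_matrix(d3$structure), 2, ctr)
  k <- 1 + 3.0 / rmsc
  d3$structure <- set_coords(d3$structure, sweep(cs * k, 2, ctr, "+"))
  al <- align_descriptors(d, d3, dummy_penalty = cfg$rmsd_duplex_max)
  expect_equal(al$central_rmsd, 3.0, tolerance = 0.2)
  expect_false(is_redundant(d, d3, cfg))
  # multi-segment case: deleting a segment from a rotated copy must agree
  # with applying the four criteria to the alignment result by hand
  ms <- make_multisegment_fixture(3, seed = 6)
  ds <- extract_descriptors(ms$structure)
  dm <- ds[[which.max(vapply(ds, function(x) nrow(x$segments), integer(1)))]]
  dm2 <- dm
  dm2$structure <- transform_structure(dm2$structure, angle = 0.4)
  drop_seg <- nrow(dm2$segments)
  if (drop_seg > dm2$central_segment) {
    keep <- dm2$segments[-drop_seg, , drop = FALSE]
    rt <- residue_table(dm2$structure)
    keep_rows <- which(apply(vapply(seq_len(nrow(keep)), function(k)
      rt$chain == keep$chain[k] & rt$res_index >= keep$start[k] &
        rt$res_index <= keep$end[k], logical(nrow(rt))), 1, any))
    dm2$structure <- subset_residues(dm2$structure, keep_rows)
    dm2$segments <- keep
    alm <- align_descriptors(dm, dm2, dummy_penalty = cfg$rmsd_duplex_max)
    hand <- (alm$central_rmsd <= cfg$rmsd_central_max) &&
      (nrow(dm$segments) == 1 || nrow(dm2$segments) == 1 ||
         (!is.na(alm$best_duplex_rmsd) &&
            alm$best_duplex_rmsd <= cfg$rmsd_duplex_max)) &&
      (alm$element_coverage > cfg$min_element_coverage) &&
      (alm$residue_coverage > cfg$min_residue_coverage) &&
      (alm$overall_rmsd <= cfg$rmsd_overall_max)
    expect_identical(is_redundant(dm, dm2, cfg), hand)
  }
})

test_that("redundancy is reflexive and symmetric on generated descriptors", {
  hp <- make_hairpin(5, 4)
  ds <- extract_descriptors(hp$structure)[c(1, 4, 7)]
  for (d in ds) expect_true(is_redundant(d, d))
  for (i in 1:2) for (j in (i + 1):3) {
    expect_identical(is_redundant(ds[[i]], ds[[j]]),
                     is_redundant(ds[[j]], ds[[i]]))
  }
})

test_that("curation removes unfolded, oversized, duplicate and redundant descriptors", {
  expect_length(curate_dataset(list()), 0L)
  hp <- make_hairpin(4, 4)
  d1 <- extract_descriptors(hp$structure, parent_id = "hp1")[[1]]
  # 85%-identity duplicate: same fold, one loop base changed
  hp2 <- make_hairpin(4, 4, loop_seq = "AAAU")
  d2 <- extract_descriptors(hp2$structure, parent_id = "hp2")[[1]]
  expect_gt(sequence_identity(descriptor_sequence(d1),
                              descriptor_sequence(d2)), 0.8)
  # rigid-motion copy
  d3 <- d1
  d3$parent_id <- "hp3"
  d3$structure <- transform_structure(d3$structure, angle = 0.8)
  # 4-segment descriptor: central strand with three satellites, each
  # within the contact threshold only at the central residue
  ls4 <- line_structure(list(
    list(chain = "A", n = 9, origin = c(0, 0, 0), dir = c(1, 0, 0)),
    list(chain = "B", n = 5, origin = c(12, 15, 0), dir = c(1, 0, 0)),
    list(chain = "C", n = 5, origin = c(12, -15, 0), dir = c(1, 0, 0)),
    list(chain = "D", n = 5, origin = c(12, 0, 15), dir = c(1, 0, 0))))
  ds4 <- extract_descriptors(ls4, parent_id = "ms")
  d4 <- ds4[[which(vapply(ds4, function(x) nrow(x$segments), integer(1)) > 3)[1]]]
  expect_equal(nrow(d4$segments), 4L)
  out <- curate_dataset(list(d1, d4, d2, d3))
  expect_length(out, 1L)
  expect_identical(out[[1]]$parent_id, "hp1")
  # idempotence
  expect_length(curate_dataset(out), 1L)
  # unfolded single strands are dropped
  straight <- make_helix("GGCAUGGCA")$structure
  solo <- subset_residues(straight,
                          which(residue_table(straight)$chain == "A"))
  un <- extract_descriptors(solo, parent_id = "line")
  expect_length(curate_dataset(un), 0L)
})

test_that("family partition is exhaustive, disjoint, and validates labels", {
  hp <- make_hairpin(4, 4)
  ds <- extract_descriptors(hp$structure, parent_id = "x")
  labels <- c(x = "tRNA")
  pt <- partition_by_family(ds, labels)
  expect_length(pt$train, length(ds))
  expect_length(pt$test, 0L)
  ds2 <- extract_descriptors(hp$structure, parent_id = "y")
  both <- c(ds[1:3], ds2[1:2])
  pt2 <- partition_by_family(both, c(x = "tRNA", y = "riboswitch"))
  expect_length(pt2$train, 3L)
  expect_length(pt2$test, 2L)
  expect_error(partition_by_family(both, c(x = "tRNA")), "unlabelled")
})

test_that("descriptor sets are written as a manifest plus PDB files", {
  hp <- make_hairpin(4, 4)
  ds <- extract_descriptors(hp$structure, parent_id = "hp")[1:2]
  dir <- withr::local_tempdir()
  man <- write_descriptor_set(ds, dir)
  tab <- read.table(man, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  expect_equal(nrow(tab), 2L)
  expect_true(all(file.exists(file.path(dir, tab$file))))
  back <- read_pdb(file.path(dir, tab$file[1]))
  expect_equal(n_residues(back), sum(ds[[1]]$segments$length))
})
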