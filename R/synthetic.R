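# Synthetic fixtures: idealized A-form duplexes, hairpins and multi-strand
# assemblies with known coordinates and known canonical pairs. The geometry
# is parametric (helical twist/rise + a per-residue atom template), not
# crystallographic: distances between paired bases, along the backbone and
# across the grooves are placed in the ranges the rest of the package
# expects (pair annotation gates, descriptor contact threshold), which is
# what property-based testing of the pipeline needs.

#' Helical parameters for fixture generation
#'
#' @param twist Helical twist in degrees per base pair (A-form default 32.7).
#' @param rise Rise in Angstrom per base pair (A-form default 2.81).
#' @return List of class `helix_params` with the twist, rise and the
#'   per-residue atom template (local coordinates in the base-pair frame for
#'   P, C4', C5', the glycosidic anchor, C2, the third base-triangle atom
#'   and N3). C5' and N3 are carried beyond the coarse five so descriptor
#'   extraction and pair annotation run directly on fixtures.
#' @export
helix_params <- function(twist = 32.7, rise = 2.81) {
  stopifnot(twist > 0, twist < 90, rise > 0)
  template <- rbind(
    P      = c(9.5 * cos(40 * pi / 180), 9.5 * sin(40 * pi / 180), 1.2),
    `C4'`  = c(9.0 * cos(20 * pi / 180), 9.0 * sin(20 * pi / 180), 0.2),
    `C5'`  = c(9.3 * cos(30 * pi / 180), 9.3 * sin(30 * pi / 180), 0.8),
    anchor = c(4.5, 0.0, 0.0),
    C2     = c(3.0, 1.0, 0.0),
    third  = c(3.0, -1.0, 0.0),
    N3     = c(3.6, 0.0, 0.0))
  structure(list(twist = twist, rise = rise, template = template),
            class = "helix_params")
}

#' Complement of a base string
#' @param seq Base string over A/C/G/U.
#' @param reverse Reverse the result (reverse complement)?
#' @export
complement_seq <- function(seq, reverse = FALSE) {
  comp <- chartr("ACGU", "UGCA", toupper(seq))
  if (reverse) comp <- paste(rev(strsplit(comp, "")[[1]]), collapse = "")
  comp
}

rot_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
}

# Atom rows for one residue: local template transformed by Rz(psi) + (0,0,z).
# strand = "A" uses the template as-is; strand = "B" applies the dyad map
# (x,y,z) -> (-x,y,-z), a proper rotation producing the antiparallel strand.
residue_atoms <- function(base, chain, res_index, auth, psi_deg, z,
                          params, strand = "A", with_p = TRUE) {
  tpl <- params$template
  if (strand == "B") tpl <- tpl %*% diag(c(-1, 1, -1))
  xyz <- tpl %*% t(rot_z(psi_deg))
  xyz[, 3] <- xyz[, 3] + z
  names <- c("P", "C4'", "C5'", anchor_atom_name(base), "C2",
             third_base_atom_name(base), "N3")
  keep <- if (with_p) seq_len(7) else 2:7
  data.frame(chain = chain, res_index = res_index, auth_number = auth,
             base = base, atom = names[keep],
             x = xyz[keep, 1], y = xyz[keep, 2], z = xyz[keep, 3],
             stringsAsFactors = FALSE)
}

#' Ideal duplex fixture
#'
#' Builds a two-chain duplex of `seq` (chain A, 5'->3') and its reverse
#' complement (chain B) with the given twist and rise. Base pair i of the
#' helix joins chain-A residue i and chain-B residue n-1-i, so the returned
#' secondary structure contains exactly `nchar(seq)` canonical pairs
#' (global indices `(i, 2n-1-i)`).
#'
#' @param seq Base string for strand A.
#' @param params A [helix_params()] object.
#' @return List with `structure` (an `rna_structure`) and `ss` (`rna_ss`).
#' @export
make_helix <- function(seq, params = helix_params()) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n == 0L) stop("empty sequence")
  if (grepl("[^ACGU]", seq)) stop("sequence must be over A/C/G/U")
  bases_a <- strsplit(seq, "")[[1]]
  bases_b <- strsplit(complement_seq(seq), "")[[1]]  # pair order (not 5'->3')
  rows <- vector("list", 2L * n)
  for (i in seq_len(n)) {          # chain A: pair i-1, ascending
    rows[[i]] <- residue_atoms(bases_a[i], "A", i - 1L, i,
                               (i - 1) * params$twist, (i - 1) * params$rise,
                               params, strand = "A")
  }
  for (j in seq_len(n)) {          # chain B 5'->3': pairs n-1 .. 0
    pr <- n - j                    # pair index of this residue
    rows[[n + j]] <- residue_atoms(bases_b[pr + 1L], "B", j - 1L, j,
                                   pr * params$twist, pr * params$rise,
                                   params, strand = "B")
  }
  s <- new_rna_structure(do.call(rbind, rows))
  pairs <- cbind(0:(n - 1L), (2L * n - 1L):n)
  list(structure = s, ss = new_rna_ss(pairs, 2L * n, strand_breaks = n))
}

#' Hairpin fixture
#'
#' Single chain of `2 * stem_len + loop_len` residues: an A-form stem closed
#' by a smooth arc of loop residues over the helix top. Consecutive C4'-C4'
#' distances stay below 8 Angstrom throughout, so the chain reads as one
#' continuous strand.
#'
#' @param stem_len Number of stem base pairs (>= 1).
#' @param loop_len Number of loop residues (>= 3).
#' @param params A [helix_params()] object.
#' @param stem_seq,loop_seq Optional base strings (defaults: alternating GC
#'   stem, all-A loop).
#' @return List with `structure` and `ss` (stem pairs `(i, n-1-i)`).
#' @export
make_hairpin <- function(stem_len, loop_len, params = helix_params(),
                         stem_seq = NULL, loop_seq = NULL) {
  stopifnot(stem_len >= 1)
  if (loop_len < 3) stop("loop_len must be >= 3")
  if (is.null(stem_seq))
    stem_seq <- paste(rep(c("G", "C"), length.out = stem_len), collapse = "")
  if (is.null(loop_seq))
    loop_seq <- paste(rep("A", loop_len), collapse = "")
  stopifnot(nchar(stem_seq) == stem_len, nchar(loop_seq) == loop_len)
  sa <- strsplit(toupper(stem_seq), "")[[1]]
  la <- strsplit(toupper(loop_seq), "")[[1]]
  n <- 2L * stem_len + loop_len
  rows <- vector("list", n)
  for (i in seq_len(stem_len)) {   # 5' stem strand, pairs 0..stem_len-1
    rows[[i]] <- residue_atoms(sa[i], "A", i - 1L, i,
                               (i - 1) * params$twist, (i - 1) * params$rise,
                               params, strand = "A")
  }
  top_psi <- (stem_len - 1) * params$twist
  top_z <- (stem_len - 1) * params$rise
  arc_span <- 140                  # angular gap between the two strands' C4'
  for (j in seq_len(loop_len)) {   # loop on an arch over the helix top
    frac <- j / (loop_len + 1)
    rows[[stem_len + j]] <- residue_atoms(
      la[j], "A", stem_len + j - 1L, stem_len + j,
      top_psi + frac * arc_span, top_z + 1.5 * sin(pi * frac),
      params, strand = "A")
  }
  for (k in seq_len(stem_len)) {   # 3' stem strand, pairs descending
    pr <- stem_len - k
    rows[[stem_len + loop_len + k]] <- residue_atoms(
      complement_seq(sa[pr + 1L]), "A", stem_len + loop_len + k - 1L,
      stem_len + loop_len + k, pr * params$twist, pr * params$rise,
      params, strand = "B")
  }
  s <- new_rna_structure(do.call(rbind, rows))
  pairs <- cbind(0:(stem_len - 1L), (n - 1L):(n - stem_len))
  list(structure = s, ss = new_rna_ss(pairs, n))
}

#' Multi-segment fixture
#'
#' For `n_segments == 1` a hairpin; otherwise one long central strand duplexed
#' against `n_segments - 1` short satellite strands (4 nt each), so every
#' added strand contributes canonical inter-strand pairs with the central
#' strand. A small seeded jitter (0.02 Angstrom) makes distinct seeds produce
#' distinct but reproducible coordinates.
#'
#' @param n_segments Integer in 1..5.
#' @param seed Integer seed.
#' @param params A [helix_params()] object.
#' @return List with `structure` and `ss`.
#' @export
make_multisegment_fixture <- function(n_segments, seed = 1,
                                      params = helix_params()) {
  stopifnot(n_segments >= 1, n_segments <= 5)
  if (n_segments == 1L) return(make_hairpin(4, 4, params))
  m <- 4L * (n_segments - 1L)
  seq <- with_seed(seed, paste(sample(c("A", "C", "G", "U"), m, replace = TRUE),
                               collapse = ""))
  hx <- make_helix(seq, params)
  atoms <- hx$structure$atoms
  # split chain B into consecutive 4-nt satellite chains
  bsel <- atoms$chain == "B"
  piece <- atoms$res_index[bsel] %/% 4L
  atoms$chain[bsel] <- LETTERS[2L + piece]
  atoms$res_index[bsel] <- atoms$res_index[bsel] %% 4L
  jit <- with_seed(seed + 1L, matrix(stats::rnorm(3L * nrow(atoms), 0, 0.02),
                                     ncol = 3))
  atoms$x <- atoms$x + jit[, 1]; atoms$y <- atoms$y + jit[, 2]
  atoms$z <- atoms$z + jit[, 3]
  s <- new_rna_structure(atoms)
  breaks <- m + 4L * (0:(n_segments - 2L))
  list(structure = s,
       ss = new_rna_ss(hx$ss$pairs, 2L * m, strand_breaks = breaks))
}

#' Seeded Gaussian perturbation of atom coordinates
#'
#' @param s An `rna_structure`.
#' @param sigma Per-coordinate displacement standard deviation in the
#'   structure's current units (Angstrom for unscaled structures);
#'   `sigma = 0` returns the input unchanged.
#' @param seed Integer seed.
#' @export
perturb <- function(s, sigma, seed = 1) {
  stopifnot(inherits(s, "rna_structure"), sigma >= 0)
  if (sigma == 0) return(s)
  n <- nrow(s$atoms)
  d <- with_seed(seed, matrix(stats::rnorm(3L * n, 0, sigma), ncol = 3))
  s$atoms$x <- s$atoms$x + d[, 1]
  s$atoms$y <- s$atoms$y + d[, 2]
  s$atoms$z <- s$atoms$z + d[, 3]
  s
}

# Evaluate expr under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
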