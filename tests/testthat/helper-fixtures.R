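# Shared fixtures, built in code at test time.

fixture_helix <- function(seq = "GGCAUGGC") make_helix(seq)

fixture_hairpin <- function(stem = 4, loop = 4) make_hairpin(stem, loop)

# Rigid motion: rotation about an arbitrary axis plus translation.
rigid_motion <- function(xyz, angle = 0.9, axis = c(1, 2, 3),
                         shift = c(4, -2, 7)) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
  sweep(xyz %*% R, 2, shift, "+")
}

transform_structure <- function(s, ...) {
  set_coords(s, rigid_motion(coords_matrix(s), ...))
}

# Independent brute-force dot-bracket matcher (one stack per bracket layer).
oracle_dotbracket_pairs <- function(db) {
  open <- c("(", "[", "{", "<"); close <- c(")", "]", "}", ">")
  chars <- strsplit(db, "")[[1]]
  pairs <- NULL
  for (l in 1:4) {
    st <- integer(0)
    for (p in seq_along(chars)) {
      if (chars[p] == open[l]) st <- c(st, p)
      else if (chars[p] == close[l]) {
        pairs <- rbind(pairs, c(st[length(st)] - 1L, p - 1L))
        st <- st[-length(st)]
      }
    }
  }
  if (is.null(pairs)) return(matrix(integer(0), ncol = 2))
  pairs[order(pairs[, 1]), , drop = FALSE]
}

# Random balanced dot-bracket string over one or two layers.
random_dotbracket <- function(n, seed) {
  set.seed(seed)
  chars <- rep(".", n)
  for (l in sample(1:2, 2)) {
    open <- c("(", "[")[l]; close <- c(")", "]")[l]
    free <- which(chars == ".")
    k <- min(length(free) %/% 2, sample(0:3, 1))
    if (k > 0) for (i in seq_len(k)) {
      free <- which(chars == ".")
      if (length(free) < 2) break
      ij <- sort(sample(free, 2))
      chars[ij[1]] <- open; chars[ij[2]] <- close
    }
  }
  paste(chars, collapse = "")
}
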