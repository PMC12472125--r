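# Minimal reverse-mode automatic differentiation over dense matrices.
# Values are plain numeric matrices; a tape records every operation in
# creation order and backward() replays it in reverse, accumulating
# gradients into parameter nodes. This is all the machinery the denoiser
# needs: matrix products, broadcast add/multiply, a few pointwise
# nonlinearities, row softmax / layer norm, and gather/scatter for message
# passing.

ad_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 256L)
  t$n <- 0L
  t
}

ad_node <- function(tape, value, parents = list(), backfn = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$parents <- parents
  nd$backfn <- backfn
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes))
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  tape$nodes[[tape$n]] <- nd
  nd
}

ad_const <- function(tape, value) ad_node(tape, as_mat(value))

as_mat <- function(x) if (is.matrix(x)) x else matrix(x, nrow = 1)

ad_accum <- function(node, g) {
  node$grad <- if (is.null(node$grad)) g else node$grad + g
}

# Run reverse-mode accumulation from a scalar output node.
ad_backward <- function(tape, out) {
  out$grad <- matrix(1, 1, 1)
  for (k in seq(tape$n, 1L)) {
    nd <- tape$nodes[[k]]
    if (!is.null(nd$grad) && !is.null(nd$backfn)) nd$backfn(nd$grad)
  }
  invisible(NULL)
}

ad_matmul <- function(tape, a, b) {
  ad_node(tape, a$value %*% b$value, list(a, b), function(g) {
    ad_accum(a, g %*% t(b$value))
    ad_accum(b, t(a$value) %*% g)
  })
}

# Elementwise add with broadcasting of b over rows (1 x d), columns (n x 1)
# or as a scalar (1 x 1).
ad_add <- function(tape, a, b) {
  av <- a$value; bv <- b$value
  val <- if (identical(dim(av), dim(bv))) av + bv
  else if (nrow(bv) == 1L && ncol(bv) == ncol(av))
    sweep(av, 2, as.numeric(bv), "+")
  else if (ncol(bv) == 1L && nrow(bv) == nrow(av)) av + as.numeric(bv)
  else if (length(bv) == 1L) av + as.numeric(bv)
  else stop("ad_add: incompatible shapes")
  ad_node(tape, val, list(a, b), function(g) {
    ad_accum(a, g)
    gb <- if (identical(dim(av), dim(bv))) g
    else if (nrow(bv) == 1L && ncol(bv) == ncol(av))
      matrix(colSums(g), 1)
    else if (ncol(bv) == 1L && nrow(bv) == nrow(av))
      matrix(rowSums(g), ncol = 1)
    else matrix(sum(g), 1, 1)
    ad_accum(b, gb)
  })
}

# Elementwise multiply with the same broadcasting rules as ad_add.
ad_mul <- function(tape, a, b) {
  av <- a$value; bv <- b$value
  expand_b <- if (identical(dim(av), dim(bv))) bv
  else if (nrow(bv) == 1L && ncol(bv) == ncol(av))
    matrix(bv, nrow(av), ncol(av), byrow = TRUE)
  else if (ncol(bv) == 1L && nrow(bv) == nrow(av))
    matrix(bv, nrow(av), ncol(av))
  else if (length(bv) == 1L) matrix(as.numeric(bv), nrow(av), ncol(av))
  else stop("ad_mul: incompatible shapes")
  ad_node(tape, av * expand_b, list(a, b), function(g) {
    ad_accum(a, g * expand_b)
    gb_full <- g * av
    gb <- if (identical(dim(av), dim(bv))) gb_full
    else if (nrow(bv) == 1L && ncol(bv) == ncol(av))
      matrix(colSums(gb_full), 1)
    else if (ncol(bv) == 1L && nrow(bv) == nrow(av))
      matrix(rowSums(gb_full), ncol = 1)
    else matrix(sum(gb_full), 1, 1)
    ad_accum(b, gb)
  })
}

ad_scale <- function(tape, a, k) {
  ad_node(tape, a$value * k, list(a), function(g) ad_accum(a, g * k))
}

ad_sub <- function(tape, a, b) ad_add(tape, a, ad_scale(tape, b, -1))

ad_relu <- function(tape, a) {
  mask <- a$value > 0
  ad_node(tape, a$value * mask, list(a), function(g) ad_accum(a, g * mask))
}

ad_sigmoid <- function(tape, a) {
  y <- 1 / (1 + exp(-a$value))
  ad_node(tape, y, list(a), function(g) ad_accum(a, g * y * (1 - y)))
}

ad_softmax_rows <- function(tape, a) {
  rmax <- a$value[cbind(seq_len(nrow(a$value)),
                        max.col(a$value, ties.method = "first"))]
  e <- exp(a$value - rmax)
  y <- e / rowSums(e)
  ad_node(tape, y, list(a), function(g) {
    ad_accum(a, y * (g - rowSums(g * y)))
  })
}

# Row-wise layer normalisation (no affine part; compose with ad_mul/ad_add
# against gamma/beta parameters for the affine transform).
ad_layernorm_rows <- function(tape, a, eps = 1e-5) {
  mu <- rowMeans(a$value)
  xc <- a$value - mu
  v <- rowMeans(xc^2)
  s <- sqrt(v + eps)
  xhat <- xc / s
  d <- ncol(a$value)
  ad_node(tape, xhat, list(a), function(g) {
    gm <- rowMeans(g)
    gx <- rowMeans(g * xhat)
    ad_accum(a, (g - gm - xhat * gx) / s)
  })
}

ad_gather_rows <- function(tape, a, idx) {
  ad_node(tape, a$value[idx, , drop = FALSE], list(a), function(g) {
    ga <- matrix(0, nrow(a$value), ncol(a$value))
    rs <- rowsum(g, group = idx)
    ga[as.integer(rownames(rs)), ] <- rs
    ad_accum(a, ga)
  })
}

# Scatter-add rows of a into an n-row output by destination index.
ad_scatter_rows <- function(tape, a, idx, n) {
  val <- matrix(0, n, ncol(a$value))
  rs <- rowsum(a$value, group = idx)
  val[as.integer(rownames(rs)), ] <- rs
  ad_node(tape, val, list(a), function(g) {
    ad_accum(a, g[idx, , drop = FALSE])
  })
}

ad_cbind <- function(tape, a, b) {
  na <- ncol(a$value)
  ad_node(tape, cbind(a$value, b$value), list(a, b), function(g) {
    ad_accum(a, g[, seq_len(na), drop = FALSE])
    ad_accum(b, g[, -seq_len(na), drop = FALSE])
  })
}

ad_slice_cols <- function(tape, a, cols) {
  ad_node(tape, a$value[, cols, drop = FALSE], list(a), function(g) {
    ga <- matrix(0, nrow(a$value), ncol(a$value))
    ga[, cols] <- g
    ad_accum(a, ga)
  })
}

ad_transpose <- function(tape, a) {
  ad_node(tape, t(a$value), list(a), function(g) ad_accum(a, t(g)))
}

# Mean of squared differences against a constant target matrix.
ad_mse <- function(tape, a, target) {
  diff <- a$value - target
  n <- length(diff)
  ad_node(tape, matrix(mean(diff^2), 1, 1), list(a), function(g) {
    ad_accum(a, (2 / n) * diff * as.numeric(g))
  })
}
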