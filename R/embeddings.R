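# Per-residue sequence embeddings. An external RNA language model can be
# plugged in through a provider registry; the built-in fallback provider is
# a deterministic per-nucleotide table pushed through the projection head,
# so the whole pipeline runs without downloads. Swapping providers changes
# feature values only, never shapes or graph topology.

.provider_registry <- new.env(parent = emptyenv())

#' Register / look up an embedding provider
#'
#' A provider is a function `f(merged_sequence, seed)` returning an
#' `nchar(merged_sequence)` x 256 numeric matrix, deterministic for a fixed
#' provider state and seed.
#'
#' @param name Provider name.
#' @param fn Provider function.
#' @export
register_embedding_provider <- function(name, fn) {
  stopifnot(is.character(name), is.function(fn))
  assign(name, fn, envir = .provider_registry)
  invisible(name)
}

#' @rdname register_embedding_provider
#' @export
get_embedding_provider <- function(name) {
  if (!exists(name, envir = .provider_registry)) {
    if (name != "fallback")
      message("embedding provider '", name,
              "' not registered; using the built-in fallback")
    return(fallback_embed)
  }
  get(name, envir = .provider_registry)
}

#' Merge segment sequences into one string
#'
#' Segments are concatenated in order with no separator token, mirroring how
#' multi-segment inputs are fed to a sequence model as a single string to
#' keep sequential context (a documented approximation: positions at
#' segment junctions see spurious neighbours).
#'
#' @param sequences Character vector of per-segment base strings.
#' @return List with `merged` and `offsets`, a data frame mapping each
#'   merged position (0-based) to its (segment, position) origin.
#' @export
merge_segments <- function(sequences) {
  if (length(sequences) == 0L || any(!nzchar(sequences)))
    stop("empty segment")
  merged <- paste(sequences, collapse = "")
  offsets <- do.call(rbind, lapply(seq_along(sequences), function(k)
    data.frame(segment = k, position = seq_len(nchar(sequences[k])) - 1L)))
  offsets$merged_position <- seq_len(nrow(offsets)) - 1L
  list(merged = merged, offsets = offsets)
}

#' Projection head dimensions
#'
#' The head maps a provider's raw per-residue representation through a
#' bias-free linear layer of 1280 units with ReLU activation into the
#' 256-dimensional embedding consumed by the graph.
#'
#' @param hidden_width,output_width Layer widths.
#' @export
projection_head_config <- function(hidden_width = 1280L,
                                   output_width = 256L) {
  stopifnot(hidden_width > 0, output_width > 0)
  list(hidden_width = as.integer(hidden_width),
       output_width = as.integer(output_width), bias_free = TRUE)
}

#' Deterministic fallback embedding
#'
#' Each of the four nucleotides gets a fixed seeded input vector; the four
#' vectors are pushed through the projection head (bias-free linear to 1280,
#' ReLU, linear to 256) and looked up per position. The embedding of a
#' position therefore depends only on its base identity — a documented
#' limitation relative to a contextual language model.
#'
#' @param merged Base string over A/C/G/U.
#' @param seed Integer seed fixing the table and head weights.
#' @param head A [projection_head_config()].
#' @return `nchar(merged)` x 256 matrix.
#' @export
fallback_embed <- function(merged, seed = 1L,
                           head = projection_head_config()) {
  merged <- toupper(merged)
  chars <- strsplit(merged, "")[[1]]
  if (any(!chars %in% c("A", "C", "G", "U")))
    stop("unknown symbol in sequence")
  d_in <- 16L
  tabs <- with_seed(seed, {
    base_vecs <- matrix(stats::rnorm(4 * d_in), 4, d_in,
                        dimnames = list(c("A", "C", "G", "U"), NULL))
    W1 <- matrix(stats::rnorm(d_in * head$hidden_width, 0,
                              1 / sqrt(d_in)), d_in, head$hidden_width)
    W2 <- matrix(stats::rnorm(head$hidden_width * head$output_width, 0,
                              1 / sqrt(head$hidden_width)),
                 head$hidden_width, head$output_width)
    emb4 <- pmax(base_vecs %*% W1, 0) %*% W2
    emb4 / sqrt(rowSums(emb4^2))     # unit-norm rows
  })
  tabs[chars, , drop = FALSE]
}

#' Per-residue embeddings for a set of segments
#'
#' Merges the segment sequences, runs the named provider on the merged
#' string, and returns one 256-vector per residue in merged order.
#'
#' @param sequences Per-segment base strings.
#' @param provider Provider name (default the built-in `"fallback"`).
#' @param seed Seed forwarded to the provider.
#' @return n x 256 matrix, n the total residue count.
#' @export
embed_sequences <- function(sequences, provider = "fallback", seed = 1L) {
  ms <- merge_segments(sequences)
  fn <- get_embedding_provider(provider)
  E <- fn(ms$merged, seed)
  if (nrow(E) != nchar(ms$merged) || ncol(E) != 256L)
    stop("provider returned wrong embedding shape")
  E
}

#' Broadcast per-residue embeddings to atoms
#'
#' Every atom of residue r receives exactly residue r's embedding vector.
#'
#' @param per_residue n_residues x k matrix in residue (global) order.
#' @param s A `rna_structure`.
#' @return n_atoms x k matrix in structure atom order.
#' @export
broadcast_to_atoms <- function(per_residue, s) {
  rt <- residue_table(s)
  if (nrow(per_residue) != nrow(rt))
    stop("embedding count does not match residue count")
  gres <- rt$global_index[match(paste(s$atoms$chain, s$atoms$res_index),
                                paste(rt$chain, rt$res_index))]
  per_residue[gres + 1L, , drop = FALSE]
}
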