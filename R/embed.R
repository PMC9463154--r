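#' Configuration for random-walk embedding
#'
#' Defaults follow common practice for walk-based node embeddings: 100 walks
#' of length 100 per node, return/in-out parameters `p = q = 1` (a
#' first-order walker), 128 dimensions, and word2vec-convention skip-gram
#' settings (window 5, 5 negative samples, 5 epochs, initial learning rate
#' 0.025).
#'
#' @param dimension embedding dimension (>= 2).
#' @param walks_per_node,walk_length walks started per node and their length.
#' @param p,q node2vec return and in-out parameters (both must be > 0;
#'   `p = q = 1` enables the fast first-order walker).
#' @param window skip-gram context window.
#' @param negative negative samples per positive pair.
#' @param epochs training passes over the corpus.
#' @param alpha,min_alpha initial / floor learning rate (linear decay).
#' @param seed integer seed driving walk generation and training.
#' @return A list of class `embed_config`.
#' @export
embed_config <- function(dimension = 128L, walks_per_node = 100L,
                         walk_length = 100L, p = 1, q = 1,
                         window = 5L, negative = 5L, epochs = 5L,
                         alpha = 0.025, min_alpha = 0.0001, seed = 1L) {
  if (dimension < 2L) stop("`dimension` must be >= 2", call. = FALSE)
  if (p <= 0 || q <= 0) stop("`p` and `q` must be positive", call. = FALSE)
  structure(list(dimension = as.integer(dimension),
                 walks_per_node = as.integer(walks_per_node),
                 walk_length = as.integer(walk_length),
                 p = p, q = q, window = as.integer(window),
                 negative = as.integer(negative), epochs = as.integer(epochs),
                 alpha = alpha, min_alpha = min_alpha,
                 seed = as.integer(seed)),
            class = "embed_config")
}

# Build the (possibly bipartite) walk graph of a network: a symmetric
# weighted adjacency over all embeddable nodes, plus ids and entity types.
#' @keywords internal
#' @noRd
walk_graph <- function(network) {
  if (inherits(network, "dataset_network")) {
    M <- dataset_adjacency(network)
    network <- new_dwpc_matrix(M, network$metaedge$source, network$metaedge$target,
                               n_steps = 1L)
  }
  if (inherits(network, "dwpc_matrix")) {
    M <- network$matrix
    st <- network$source_type; tt <- network$target_type
    homo <- network$homogeneous && nrow(M) == ncol(M) &&
      identical(rownames(M), colnames(M))
  } else {
    M <- network
    homo <- nrow(M) == ncol(M) && identical(rownames(M), colnames(M))
    st <- tt <- "NOD"
  }
  if (homo) {
    # coerce to a general matrix: symmetric sparse classes store one
    # triangle only, which would hide half the neighbourhoods
    W <- methods::as((M + Matrix::t(M)) / 2, "generalMatrix")
    ids <- rownames(M)
    types <- rep(st, length(ids))
  } else {
    Z1 <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                               dims = c(nrow(M), nrow(M)))
    Z2 <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                               dims = c(ncol(M), ncol(M)))
    W <- rbind(cbind(Z1, M), cbind(Matrix::t(M), Z2))
    ids <- c(rownames(M), colnames(M))
    types <- c(rep(st, nrow(M)), rep(tt, ncol(M)))
  }
  W <- methods::as(W, "CsparseMatrix")
  list(W = W, ids = ids, types = types)
}

#' Generate a weighted random-walk corpus
#'
#' Runs `walks_per_node` walks of `walk_length` steps from every
#' non-isolated node. Edge weights (DWPC values for multi-step metapaths)
#' are scaled per node to sum to one and used as transition probabilities;
#' unweighted networks give uniform steps. Bipartite networks are walked on
#' their two-layer graph, so walks alternate sides. With `p = q = 1` the
#' walk is first-order Markov; other values enable the second-order
#' node2vec walker. Fully seeded and reproducible.
#'
#' @param network a `dwpc_matrix`, [dataset_network()], or sparse matrix
#'   with dimnames (square with identical dimnames = homogeneous).
#' @param cfg an [embed_config()].
#' @return An object of class `walk_corpus`: integer matrix of node indices
#'   (one walk per row), node `ids` and `types`.
#' @export
generate_walks <- function(network, cfg = embed_config()) {
  wg <- walk_graph(network)
  W <- wg$W
  if (any(W@x < 0)) stop("negative edge weights", call. = FALSE)
  deg <- Matrix::rowSums(W)
  isolated <- deg == 0
  if (any(isolated))
    warning(sprintf("%d isolated node(s) skipped", sum(isolated)), call. = FALSE)
  # CSR of W: row v's neighbours = column indices of t(W)'s CSC slot, sorted
  Wt <- methods::as(Matrix::t(W), "CsparseMatrix")
  walks <- .walk_corpus_cpp(Wt@p, Wt@i, Wt@x, nrow(W),
                            cfg$walks_per_node, cfg$walk_length,
                            cfg$p, cfg$q, as.double(cfg$seed))
  structure(list(walks = walks, ids = wg$ids, types = wg$types, cfg = cfg),
            class = "walk_corpus")
}

#' @export
print.walk_corpus <- function(x, ...) {
  cat(sprintf("<walk_corpus> %d walks x %d steps over %d nodes\n",
              nrow(x$walks), ncol(x$walks), length(x$ids)))
  invisible(x)
}

#' @keywords internal
#' @noRd
new_node_embedding <- function(vectors, ids, types, meta = list()) {
  rn <- ids
  if (anyDuplicated(rn)) rn <- paste(types, ids, sep = ":")
  rownames(vectors) <- rn
  structure(list(vectors = vectors, ids = ids, types = types, meta = meta),
            class = "node_embedding")
}

#' Train skip-gram node vectors on a walk corpus
#'
#' Learns one fixed-length vector per node with a skip-gram
#' negative-sampling model over the walks (nodes play the role of tokens,
#' walks of sentences). Single-threaded training is bit-reproducible for a
#' given seed.
#'
#' @param corpus a [generate_walks()] result.
#' @param cfg an [embed_config()] (defaults to the corpus' own config).
#' @return An object of class `node_embedding`: `vectors`
#'   (nodes x dimension), node `ids`, `types` and `meta`.
#' @export
train_skipgram <- function(corpus, cfg = corpus$cfg) {
  stopifnot(inherits(corpus, "walk_corpus"))
  walks <- corpus$walks
  if (!nrow(walks)) stop("empty walk corpus", call. = FALSE)
  present <- sort(unique(as.vector(walks)))
  if (length(present) < 2L) stop("vocabulary must contain at least 2 nodes", call. = FALSE)
  remap <- match(walks, present)
  dim(remap) <- dim(walks)
  counts <- tabulate(remap, nbins = length(present))
  V <- .sgns_train_cpp(remap, counts, cfg$dimension, cfg$window,
                       cfg$negative, cfg$epochs, cfg$alpha, cfg$min_alpha,
                       as.double(cfg$seed))
  new_node_embedding(V, corpus$ids[present], corpus$types[present],
                     meta = list(config = cfg, seed = cfg$seed))
}

#' @export
print.node_embedding <- function(x, ...) {
  tt <- table(x$types)
  cat(sprintf("<node_embedding> %d nodes x %d dims (%s)\n",
              nrow(x$vectors), ncol(x$vectors),
              paste(sprintf("%s: %d", names(tt), tt), collapse = ", ")))
  if (!is.null(x$meta$metapath)) cat("  metapath:", x$meta$metapath, "\n")
  invisible(x)
}

#' @export
summary.node_embedding <- function(object, ...) {
  cat(sprintf("node embedding: %d nodes, %d dimensions\n",
              nrow(object$vectors), ncol(object$vectors)))
  if (!is.null(object$meta$metapath)) cat("metapath:", object$meta$metapath, "\n")
  if (!is.null(object$meta$evaluation))
    cat(sprintf("reconstruction AUROC: %.3f\n", object$meta$evaluation$auroc))
  nrm <- sqrt(rowSums(object$vectors^2))
  cat(sprintf("vector norms: median %.3f [%.3f, %.3f]\n",
              stats::median(nrm), min(nrm), max(nrm)))
  invisible(object)
}

#' @export
as.matrix.node_embedding <- function(x, ...) x$vectors

#' Plot a 2-D principal-component projection of an embedding
#'
#' @param x a `node_embedding`.
#' @param labels optional per-node grouping used for colours (defaults to
#'   the entity types).
#' @param ... passed to [graphics::plot()].
#' @export
plot.node_embedding <- function(x, labels = NULL, ...) {
  pc <- stats::prcomp(x$vectors, rank. = 2L)
  grp <- factor(labels %||% x$types)
  graphics::plot(pc$x[, 1], pc$x[, 2], col = as.integer(grp), pch = 16,
                 xlab = "PC1", ylab = "PC2", ...)
  if (nlevels(grp) > 1L)
    graphics::legend("topright", legend = levels(grp), col = seq_len(nlevels(grp)),
                     pch = 16, cex = 0.8)
  invisible(pc)
}

# Look up embedding row indices for (id, type) pairs; NA when missing.
#' @keywords internal
#' @noRd
embedding_index <- function(emb, ids, type = NULL) {
  if (is.null(type)) return(match(ids, emb$ids))
  key <- paste(emb$types, emb$ids, sep = ":")
  match(paste(type, ids, sep = ":"), key)
}

#' Embed a metapath end to end
#'
#' Composition of the full pipeline: [dwpc_matrix()] (for multi-step
#' metapaths; length-1 metapaths use the unweighted union of their
#' datasets), [cap_edges()], [filter_components()], [generate_walks()] and
#' [train_skipgram()]. Aborts when component filtering flags the network
#' as REJECTED (less than half the node universe retained).
#'
#' @param spec a [parse_metapath()] result.
#' @param kg the knowledge graph ([assemble_graph()]).
#' @param dwpc_cfg a [dwpc_config()].
#' @param embed_cfg an [embed_config()].
#' @param force embed even a REJECTED network.
#' @return A `node_embedding` whose `meta` records the metapath, dataset
#'   combinations, configs, retention report and the filtered network (used
#'   by [reconstruction_auroc()] as the default evaluation network).
#' @export
embed_metapath <- function(spec, kg, dwpc_cfg = dwpc_config(),
                           embed_cfg = embed_config(), force = FALSE) {
  stopifnot(inherits(spec, "metapath"))
  if (spec$length == 1L) {
    mats <- step_alternatives(spec$steps[[1L]], kg, w = 0)
    dw <- merge_networks(mats, mode = "union")
    dw <- new_dwpc_matrix(dw, spec$source_type, spec$target_type,
                          metapath = spec$expr, n_steps = 1L,
                          datasets = names(mats))
  } else {
    dw <- dwpc_matrix(spec, kg, dwpc_cfg)
  }
  dw <- cap_edges(dw, dwpc_cfg)
  fc <- filter_components(dw, dwpc_cfg)
  if (fc$report$rejected && !force)
    stop(sprintf("metapath %s REJECTED: only %.1f%% of nodes retained",
                 spec$expr, 100 * fc$report$retained_frac), call. = FALSE)
  corpus <- generate_walks(fc$dwpc, embed_cfg)
  emb <- train_skipgram(corpus, embed_cfg)
  emb$meta$metapath <- spec$expr
  emb$meta$datasets <- dw$datasets
  emb$meta$dwpc_config <- dwpc_cfg
  emb$meta$retention <- fc$report
  emb$meta$network <- fc$dwpc
  emb
}

#' Write / read an embedding as TSV + JSON metadata
#'
#' The TSV holds `node_id`, `type` and the vector components `v1..vd`; the
#' JSON sidecar stores the metapath, dataset combinations, configuration and
#' retention report. An optional nearest-neighbour sidecar lists the top-k
#' cosine neighbours per node.
#'
#' @param emb a `node_embedding`.
#' @param prefix output path prefix (`<prefix>.tsv`, `<prefix>.json`,
#'   optionally `<prefix>_neighbors.tsv`).
#' @param neighbors integer; write the top-k neighbour sidecar (0 = skip).
#' @return `prefix`, invisibly.
#' @export
write_embedding <- function(emb, prefix, neighbors = 0L) {
  stopifnot(inherits(emb, "node_embedding"))
  df <- data.frame(node_id = emb$ids, type = emb$types,
                   emb$vectors, check.names = FALSE)
  colnames(df) <- c("node_id", "type", paste0("v", seq_len(ncol(emb$vectors))))
  utils::write.table(df, paste0(prefix, ".tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  meta <- emb$meta
  meta$network <- NULL  # the network is not serializable to JSON
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       force = TRUE, digits = NA)
  if (neighbors > 0L) {
    nn <- cosine_knn(emb, k = neighbors)
    utils::write.table(nn, paste0(prefix, "_neighbors.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(prefix)
}

#' @rdname write_embedding
#' @export
read_embedding <- function(prefix) {
  df <- utils::read.table(paste0(prefix, ".tsv"), sep = "\t", header = TRUE,
                          check.names = FALSE, colClasses = c(
                            node_id = "character", type = "character"))
  V <- as.matrix(df[, -(1:2), drop = FALSE])
  meta_path <- paste0(prefix, ".json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path, simplifyVector = TRUE)
          else list()
  new_node_embedding(V, df$node_id, df$type, meta = meta)
}
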