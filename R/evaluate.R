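#' Configuration for embedding evaluation
#'
#' @param negatives_per_edge random node-pair permutations sampled per
#'   network edge (default 100).
#' @param auroc_retention_threshold embeddings below this reconstruction
#'   AUROC are not retained (default 0.8).
#' @param dwpc_subset_fractions for weighted (multi-step) networks, extra
#'   AUROCs are computed on subsets keeping each node's top 1%, 25% and 50%
#'   neighbours by DWPC weight.
#' @param seed seed for negative sampling.
#' @return A list of class `eval_config`.
#' @export
eval_config <- function(negatives_per_edge = 100L,
                        auroc_retention_threshold = 0.8,
                        dwpc_subset_fractions = c(0.01, 0.25, 0.50),
                        seed = 1L) {
  structure(list(negatives_per_edge = as.integer(negatives_per_edge),
                 auroc_retention_threshold = auroc_retention_threshold,
                 dwpc_subset_fractions = dwpc_subset_fractions,
                 seed = as.integer(seed)),
            class = "eval_config")
}

# Extract typed edges of a network as a data.frame
# (source, target, source_type, target_type, weight). Homogeneous matrices
# are symmetrized and reported as unordered pairs.
#' @keywords internal
#' @noRd
network_edges <- function(network) {
  if (inherits(network, "dataset_network")) {
    ed <- network$edges
    return(list(edges = data.frame(source = ed$source, target = ed$target,
                                   weight = 1, stringsAsFactors = FALSE),
                source_type = network$metaedge$source,
                target_type = network$metaedge$target,
                row_universe = network$source_universe,
                col_universe = network$target_universe,
                homogeneous = network$homogeneous))
  }
  if (inherits(network, "dwpc_matrix")) {
    M <- network$matrix; st <- network$source_type; tt <- network$target_type
    homo <- network$homogeneous && identical(rownames(M), colnames(M))
  } else {
    M <- network
    homo <- nrow(M) == ncol(M) && identical(rownames(M), colnames(M))
    st <- tt <- "NOD"
  }
  if (homo) M <- methods::as((M + Matrix::t(M)) / 2, "generalMatrix")
  d <- as.data.frame(Matrix::summary(methods::as(Matrix::drop0(M), "TsparseMatrix")))
  if (homo) d <- d[d$i < d$j, , drop = FALSE]
  list(edges = data.frame(source = rownames(M)[d$i], target = colnames(M)[d$j],
                          weight = d$x, stringsAsFactors = FALSE),
       source_type = st, target_type = tt,
       row_universe = rownames(M), col_universe = colnames(M),
       homogeneous = homo)
}

# Sample `n_neg` random node pairs per positive edge by resampling both
# endpoints within their entity side, rejecting self-pairs and true edges.
#' @keywords internal
#' @noRd
sample_negative_pairs <- function(pos_a, pos_b, cand_a, cand_b, n_neg,
                                  homogeneous) {
  n <- length(pos_a) * n_neg
  truth <- unique(c(paste(pos_a, pos_b, sep = "\r"),
                    if (homogeneous) paste(pos_b, pos_a, sep = "\r")))
  na <- sample(cand_a, n, replace = TRUE)
  nb <- sample(cand_b, n, replace = TRUE)
  for (iter in 1:100) {
    bad <- na == nb | paste(na, nb, sep = "\r") %in% truth
    if (!any(bad)) break
    na[bad] <- sample(cand_a, sum(bad), replace = TRUE)
    nb[bad] <- sample(cand_b, sum(bad), replace = TRUE)
  }
  bad <- na == nb | paste(na, nb, sep = "\r") %in% truth
  if (any(bad)) { na <- na[!bad]; nb <- nb[!bad] }  # dense degenerate case
  list(a = na, b = nb)
}

# Cosine distances between embedding rows ia and ib (same length).
#' @keywords internal
#' @noRd
pair_cosine_distance <- function(Vn, ia, ib) {
  1 - rowSums(Vn[ia, , drop = FALSE] * Vn[ib, , drop = FALSE])
}

#' @keywords internal
#' @noRd
auroc_for_edges <- function(Vn, ia, ib, cand_a, cand_b, n_neg, homogeneous,
                            ids_a, ids_b) {
  d_pos <- pair_cosine_distance(Vn, ia, ib)
  neg <- sample_negative_pairs(ids_a, ids_b, cand_a$ids, cand_b$ids, n_neg,
                               homogeneous)
  d_neg <- pair_cosine_distance(Vn,
                                cand_a$index[match(neg$a, cand_a$ids)],
                                cand_b$index[match(neg$b, cand_b$ids)])
  list(auroc = rank_auroc(-d_pos, -d_neg), n_pos = length(d_pos),
       n_neg = length(d_neg))
}

#' Network reconstruction AUROC of an embedding
#'
#' Measures how well embedding distances recover the network the embedding
#' was trained on: the cosine distance of every network edge is compared
#' with the distances of `negatives_per_edge` random node-pair permutations
#' (endpoints resampled within the correct entity side, true edges and
#' self-pairs rejected), and the AUROC over the pooled distances is
#' computed by rank statistic (smaller distance ranks as edge-like).
#' Weighted multi-step networks additionally report AUROCs on the subsets
#' keeping each node's closest neighbours by DWPC weight.
#'
#' @param emb a `node_embedding`.
#' @param network the network to reconstruct; defaults to the network the
#'   embedding was trained on (`emb$meta$network`).
#' @param cfg an [eval_config()].
#' @param subsets compute the DWPC-subset AUROCs (only meaningful for
#'   weighted multi-step networks).
#' @return An `embedding_evaluation`: `auroc`, `n_pos`, `n_neg`, `retained`
#'   flag and optional `subset_aurocs`.
#' @export
reconstruction_auroc <- function(emb, network = NULL, cfg = eval_config(),
                                 subsets = NULL) {
  stopifnot(inherits(emb, "node_embedding"))
  network <- network %||% emb$meta$network
  if (is.null(network)) stop("no network to evaluate against", call. = FALSE)
  ne <- network_edges(network)
  Vn <- l2_normalize_rows(emb$vectors)

  side <- function(universe, type) {
    idx <- embedding_index(emb, universe, type)
    ok <- !is.na(idx)
    list(ids = universe[ok], index = idx[ok])
  }
  type_a <- if (ne$source_type == "NOD") NULL else ne$source_type
  type_b <- if (ne$target_type == "NOD") NULL else ne$target_type
  cand_a <- side(ne$row_universe, type_a)
  cand_b <- side(ne$col_universe, type_b)

  ia <- embedding_index(emb, ne$edges$source, type_a)
  ib <- embedding_index(emb, ne$edges$target, type_b)
  ok <- !is.na(ia) & !is.na(ib)
  if (!any(ok)) stop("no network edge has both endpoints embedded", call. = FALSE)

  res <- with_seed(cfg$seed, {
    main <- auroc_for_edges(Vn, ia[ok], ib[ok], cand_a, cand_b,
                            cfg$negatives_per_edge, ne$homogeneous,
                            ne$edges$source[ok], ne$edges$target[ok])
    subset_aurocs <- NULL
    do_subsets <- subsets %||%
      (inherits(network, "dwpc_matrix") && isTRUE(network$n_steps > 1L))
    if (isTRUE(do_subsets) && length(cfg$dwpc_subset_fractions)) {
      M <- if (inherits(network, "dwpc_matrix")) network$matrix else network
      homo <- ne$homogeneous
      subset_aurocs <- vapply(cfg$dwpc_subset_fractions, function(f) {
        kr <- max(1L, round_half_up(f * (ncol(M) - homo)))
        kc <- max(1L, round_half_up(f * (nrow(M) - homo)))
        Ms <- top_k_union(M, kr, kc)$matrix
        nes <- network_edges(if (homo) Ms else Ms)
        sa <- embedding_index(emb, nes$edges$source, type_a)
        sb <- embedding_index(emb, nes$edges$target, type_b)
        sok <- !is.na(sa) & !is.na(sb)
        if (!any(sok)) return(NA_real_)
        auroc_for_edges(Vn, sa[sok], sb[sok], cand_a, cand_b,
                        cfg$negatives_per_edge, homo,
                        nes$edges$source[sok], nes$edges$target[sok])$auroc
      }, numeric(1))
      names(subset_aurocs) <- paste0("top_", 100 * cfg$dwpc_subset_fractions, "%")
    }
    list(main = main, subset_aurocs = subset_aurocs)
  })
  structure(list(auroc = res$main$auroc, n_pos = res$main$n_pos,
                 n_neg = res$main$n_neg,
                 retained = res$main$auroc >= cfg$auroc_retention_threshold,
                 subset_aurocs = res$subset_aurocs),
            class = "embedding_evaluation")
}

#' @export
print.embedding_evaluation <- function(x, ...) {
  cat(sprintf("<embedding_evaluation> AUROC %.4f (%d positives, %d negatives) -> %s\n",
              x$auroc, x$n_pos, x$n_neg,
              if (isTRUE(x$retained)) "retained" else "not retained"))
  if (!is.null(x$subset_aurocs))
    cat("  DWPC subsets:", paste(sprintf("%s %.4f", names(x$subset_aurocs),
                                         x$subset_aurocs), collapse = ", "), "\n")
  invisible(x)
}

#' Recapitulation of an orthogonal reference network
#'
#' Characterizes an embedding by its capacity to recover the edges of an
#' independent reference network: the reference is restricted to the nodes
#' both datasets share and the reconstruction AUROC is computed on that
#' overlap. Coverage is the number of overlapping nodes; with fewer than
#' two overlapping nodes on a side (or no covered edge) the AUROC is
#' reported as missing, never 0.5.
#'
#' @param emb a `node_embedding`.
#' @param reference a [dataset_network()] (or sparse matrix) typed over the
#'   embedded entity types.
#' @param cfg an [eval_config()].
#' @return List with `coverage`, `auroc` and `n_edges`.
#' @export
recapitulation <- function(emb, reference, cfg = eval_config()) {
  ne <- network_edges(reference)
  type_a <- if (ne$source_type == "NOD") NULL else ne$source_type
  type_b <- if (ne$target_type == "NOD") NULL else ne$target_type
  ra <- ne$row_universe[!is.na(embedding_index(emb, ne$row_universe, type_a))]
  rb <- ne$col_universe[!is.na(embedding_index(emb, ne$col_universe, type_b))]
  coverage <- if (ne$homogeneous) length(unique(c(ra, rb)))
              else length(ra) + length(rb)
  covered <- ne$edges$source %in% ra & ne$edges$target %in% rb
  if (coverage < 2L || !any(covered))
    return(list(coverage = coverage, auroc = NA_real_, n_edges = sum(covered)))
  ev <- reconstruction_auroc(emb, reference, cfg, subsets = FALSE)
  list(coverage = coverage, auroc = ev$auroc, n_edges = ev$n_pos)
}

# Incidence matrix (rows x cols, binary) of a bipartite network.
#' @keywords internal
#' @noRd
incidence_of <- function(network) {
  ne <- network_edges(network)
  i <- match(ne$edges$source, ne$row_universe)
  j <- match(ne$edges$target, ne$col_universe)
  M <- Matrix::sparseMatrix(i = i, j = j, x = 1,
                            dims = c(length(ne$row_universe), length(ne$col_universe)),
                            dimnames = list(ne$row_universe, ne$col_universe))
  list(M = M, source_type = ne$source_type, target_type = ne$target_type)
}

# Top-k neighbour edges per row of a similarity matrix (self excluded,
# ties by id ascending).
#' @keywords internal
#' @noRd
top_k_similar <- function(S, k, require_positive = FALSE) {
  ids <- rownames(S)
  out <- vector("list", nrow(S))
  for (i in seq_len(nrow(S))) {
    s <- S[i, ]
    s[i] <- -Inf
    if (require_positive) s[s <= 0] <- -Inf
    o <- order(-s, xtfrm(ids))
    o <- o[is.finite(s[o])]
    o <- utils::head(o, k)
    if (length(o))
      out[[i]] <- data.frame(source = ids[i], target = ids[o],
                             similarity = s[o], stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(source = character(0), target = character(0),
                      similarity = numeric(0))
  rownames(res) <- NULL
  res
}

#' Entity similarity networks from a bipartite reference
#'
#' For each side of a bipartite network, encodes every entity by its
#' neighbour incidence, reweights with TF-IDF, computes pairwise cosine
#' similarities within the side, and links each entity to its `top_k`
#' closest neighbours. Entities with no annotations are excluded.
#'
#' @param network a bipartite [dataset_network()] (or sparse
#'   incidence matrix).
#' @param top_k neighbours kept per entity (default 5).
#' @return List of two data.frames (`source`, `target`, `similarity`), named
#'   by the two entity types.
#' @export
entity_similarity_network <- function(network, top_k = 5L) {
  inc <- incidence_of(network)
  one_side <- function(M) {
    M <- M[Matrix::rowSums(M) > 0, , drop = FALSE]
    if (nrow(M) < 2L)
      return(data.frame(source = character(0), target = character(0),
                        similarity = numeric(0)))
    W <- tfidf_transform(as.matrix(M))
    S <- tcrossprod(W)
    dimnames(S) <- list(rownames(M), rownames(M))
    top_k_similar(S, top_k)
  }
  out <- list(one_side(inc$M), one_side(Matrix::t(inc$M)))
  names(out) <- c(inc$source_type, inc$target_type)
  out
}

#' Shared-neighbour similarity network
#'
#' Links each entity of a bipartite network with the `top_k` partners on
#' its own side that share the most neighbours (ties broken by id; partners
#' sharing no neighbour are never linked).
#'
#' @param network a bipartite [dataset_network()] (or sparse incidence
#'   matrix).
#' @param top_k partners kept per entity (default 3).
#' @param side which side to link (`"source"` or `"target"`).
#' @return data.frame `source`, `target`, `shared` (shared-neighbour count).
#' @export
shared_neighbor_network <- function(network, top_k = 3L,
                                    side = c("source", "target")) {
  side <- match.arg(side)
  inc <- incidence_of(network)
  M <- if (side == "source") inc$M else Matrix::t(inc$M)
  M <- M[Matrix::rowSums(M) > 0, , drop = FALSE]
  S <- as.matrix(Matrix::tcrossprod(M))
  dimnames(S) <- list(rownames(M), rownames(M))
  res <- top_k_similar(S, top_k, require_positive = TRUE)
  names(res)[names(res) == "similarity"] <- "shared"
  res
}
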