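#' Exact cosine nearest neighbours in an embedding space
#'
#' Exact (not approximate) cosine-distance ranking of all embedded nodes for
#' each query, self excluded, deterministic tie order by node id.
#'
#' @param emb a `node_embedding`.
#' @param queries character vector of query node ids (default: all nodes).
#' @param k neighbours returned per query.
#' @param type restrict queries/candidates to one entity type.
#' @param include_self keep the query itself (rank 1 at distance 0, as
#'   exact index scans do); set `FALSE` to drop it.
#' @return data.frame `query`, `neighbor`, `rank`, `distance`.
#' @export
cosine_knn <- function(emb, queries = NULL, k = 10L, type = NULL,
                       include_self = TRUE) {
  stopifnot(inherits(emb, "node_embedding"))
  keep <- if (is.null(type)) seq_along(emb$ids) else which(emb$types == type)
  ids <- emb$ids[keep]
  Vn <- l2_normalize_rows(emb$vectors[keep, , drop = FALSE])
  queries <- queries %||% ids
  qi <- match(queries, ids)
  if (anyNA(qi)) stop("query node(s) not embedded: ",
                      paste(utils::head(queries[is.na(qi)], 5), collapse = ", "),
                      call. = FALSE)
  res <- vector("list", length(queries))
  for (t in seq_along(queries)) {
    d <- 1 - as.vector(Vn %*% Vn[qi[t], ])
    if (!include_self) d[qi[t]] <- Inf
    else d[qi[t]] <- -Inf  # self always first, reported at distance 0
    o <- utils::head(order(d, xtfrm(ids)), k)
    d[qi[t]] <- if (include_self) 0 else Inf
    res[[t]] <- data.frame(query = queries[t], neighbor = ids[o],
                           rank = seq_along(o), distance = d[o],
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Co-rank empirical P values for node pairs
#'
#' For a pair (a, b), the rank of b in a's ascending cosine-distance list
#' (1-based, self excluded, ties broken by id) is normalized by the number
#' of other covered nodes, and symmetrically for a in b's list; the
#' empirical P value is the geometric mean of the two normalized co-ranks.
#' Mutual nearest neighbours get P close to 1/n; a pair mutually farthest
#' apart gets exactly 1. These are empirical quantiles of the embedding's
#' distance structure, not significance tests: they require both nodes to
#' be close to each other, which normalizes away the tendency of broadly
#' connected entities to be close to everything.
#'
#' @param emb a `node_embedding`.
#' @param pairs two-column data.frame of node ids.
#' @param type restrict the covered universe to one entity type.
#' @return A data.frame of class `corank_table`: `a`, `b`, `rank_ab`,
#'   `rank_ba`, `pvalue`, `covered`; attribute `n_covered` is the size of
#'   the covered universe.
#' @export
corank_pvalue <- function(emb, pairs, type = NULL) {
  stopifnot(inherits(emb, "node_embedding"))
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  a <- as.character(pairs[[1]]); b <- as.character(pairs[[2]])
  keep <- if (is.null(type)) seq_along(emb$ids) else which(emb$types == type)
  ids <- emb$ids[keep]
  n <- length(ids)
  if (n < 2L) stop("fewer than 2 covered nodes", call. = FALSE)
  Vn <- l2_normalize_rows(emb$vectors[keep, , drop = FALSE])
  ia <- match(a, ids); ib <- match(b, ids)
  covered <- !is.na(ia) & !is.na(ib) & ia != ib

  # rank of `to` in `from`'s ascending-distance list (ties by id);
  # the full rank vector of each queried node is computed once and cached
  id_order <- xtfrm(ids)
  rank_cache <- new.env(parent = emptyenv())
  ranks_from <- function(from) {
    key <- as.character(from)
    rk <- rank_cache[[key]]
    if (is.null(rk)) {
      d <- 1 - as.vector(Vn %*% Vn[from, ])
      d[from] <- Inf
      rk <- integer(n)
      rk[order(d, id_order)] <- seq_len(n)
      rank_cache[[key]] <- rk
    }
    rk
  }
  rank_ab <- rank_ba <- rep(NA_real_, length(a))
  for (t in which(covered)) {
    rank_ab[t] <- ranks_from(ia[t])[ib[t]]
    rank_ba[t] <- ranks_from(ib[t])[ia[t]]
  }
  p <- sqrt((rank_ab / (n - 1)) * (rank_ba / (n - 1)))
  out <- data.frame(a = a, b = b, rank_ab = rank_ab, rank_ba = rank_ba,
                    pvalue = p, covered = covered, stringsAsFactors = FALSE)
  attr(out, "n_covered") <- n
  class(out) <- c("corank_table", "data.frame")
  out
}

#' Degree-preserving network permutation
#'
#' Randomizes a network by repeated double-edge swaps (each swap exchanges
#' the endpoints of two edges), preserving every node's degree exactly and
#' creating no self-loops or multi-edges. The number of attempted swaps is
#' `swaps_per_edge` times the edge count. Bipartite networks remain
#' bipartite because swaps only exchange same-side endpoints.
#'
#' @param network a [dataset_network()] or two-column edge data.frame.
#' @param swaps_per_edge attempted swaps per edge (default 10).
#' @param seed RNG seed.
#' @return An object of the same kind as the input with permuted edges.
#' @export
permute_network <- function(network, swaps_per_edge = 10L, seed = NULL) {
  is_ds <- inherits(network, "dataset_network")
  if (is_ds) {
    ed <- network$edges
    bip <- !network$homogeneous
  } else {
    ed <- as.data.frame(network, stringsAsFactors = FALSE)
    names(ed)[1:2] <- c("source", "target")
    bip <- length(intersect(ed$source, ed$target)) == 0L
  }
  if (nrow(ed) < 2L) stop("need at least 2 edges to permute", call. = FALSE)
  if (bip) {
    # bipartite double-edge swaps: (s1-t1, s2-t2) -> (s1-t2, s2-t1), which
    # preserves both sides' degrees and the bipartite structure (generic
    # degree-preserving rewiring would mix the sides)
    el <- with_seed(seed, bipartite_swaps(ed$source, ed$target,
                                          swaps_per_edge * nrow(ed)))
    out <- data.frame(source = el$source, target = el$target,
                      stringsAsFactors = FALSE)
  } else {
    verts <- unique(c(ed$source, ed$target))
    g <- igraph::graph_from_data_frame(ed[, 1:2], directed = FALSE,
                                       vertices = verts)
    g2 <- with_seed(seed,
                    igraph::rewire(g, igraph::keeping_degseq(
                      loops = FALSE, niter = swaps_per_edge * nrow(ed))))
    el <- igraph::as_edgelist(g2)
    out <- data.frame(source = el[, 1], target = el[, 2], stringsAsFactors = FALSE)
  }
  if (is_ds)
    dataset_network(paste0(network$name, "_permuted"), network$metaedge, out,
                    source_universe = network$source_universe,
                    target_universe = network$target_universe)
  else out
}

# Attempted double-edge swaps on a bipartite edge list; multi-edges are
# rejected (self-loops cannot arise across sides).
#' @keywords internal
#' @noRd
bipartite_swaps <- function(src, tgt, n_attempts) {
  m <- length(src)
  keys <- new.env(parent = emptyenv(), size = m)
  for (e in seq_len(m)) keys[[paste(src[e], tgt[e], sep = "\r")]] <- TRUE
  pick <- sample.int(m, 2L * n_attempts, replace = TRUE)
  for (a in seq_len(n_attempts)) {
    e1 <- pick[2L * a - 1L]; e2 <- pick[2L * a]
    if (e1 == e2) next
    s1 <- src[e1]; t1 <- tgt[e1]; s2 <- src[e2]; t2 <- tgt[e2]
    if (t1 == t2 || s1 == s2) next
    k1 <- paste(s1, t2, sep = "\r"); k2 <- paste(s2, t1, sep = "\r")
    if (!is.null(keys[[k1]]) || !is.null(keys[[k2]])) next
    rm(list = c(paste(s1, t1, sep = "\r"), paste(s2, t2, sep = "\r")),
       envir = keys)
    keys[[k1]] <- TRUE; keys[[k2]] <- TRUE
    tgt[e1] <- t2; tgt[e2] <- t1
  }
  list(source = src, target = tgt)
}

#' @keywords internal
#' @noRd
pvals_of <- function(x) {
  if (inherits(x, "corank_table")) x$pvalue[x$covered] else x[!is.na(x)]
}

#' Default P value cutoff sweep
#'
#' @param n number of points.
#' @param lo,hi range of the sweep.
#' @return Log-spaced cutoffs from `hi` down to `lo`.
#' @export
pvalue_cutoffs <- function(n = 50L, lo = 0.001, hi = 1) {
  exp(seq(log(hi), log(lo), length.out = n))
}

#' Fold change of edge recovery over permutation nulls
#'
#' For each P value cutoff, the number of real query edges with P at or
#' below the cutoff is divided by the average count in the permuted
#' networks (the null mean is floored at one edge to keep the ratio
#' finite). A fold change well above 1 at small cutoffs indicates that the
#' embedding places truly interacting pairs closer than degree-matched
#' chance expects.
#'
#' @param p_real co-rank P values of the real network edges
#'   ([corank_pvalue()] table or numeric vector).
#' @param p_null list of P value sets, one per permuted network.
#' @param cutoffs P value cutoffs, swept from 1 towards 0.001 by default.
#' @return data.frame `cutoff`, `n_real`, `n_null_mean`, `fold_change`.
#' @export
fold_change_curve <- function(p_real, p_null, cutoffs = pvalue_cutoffs()) {
  pr <- pvals_of(p_real)
  pn <- lapply(p_null, pvals_of)
  n_real <- vapply(cutoffs, function(cc) sum(pr <= cc), numeric(1))
  n_null <- vapply(cutoffs, function(cc)
    mean(vapply(pn, function(p) sum(p <= cc), numeric(1))), numeric(1))
  data.frame(cutoff = cutoffs, n_real = n_real, n_null_mean = n_null,
             fold_change = n_real / pmax(n_null, 1))
}

#' Empirical FDR-controlling P value cutoff from permutation nulls
#'
#' Finds the P value cutoff at which no more than `fdr` of the permuted
#' network edges are covered on average. `which = "largest"` returns the
#' largest qualifying cutoff (the more permissive reading, maximizing
#' recall at the nominal FDR); `which = "smallest"` returns the smallest
#' cutoff at which null coverage first reaches `fdr`. Candidate cutoffs
#' form a step function over the pooled null P values (no interpolation).
#'
#' @param p_null list of P value sets, one per permuted network.
#' @param fdr nominal false discovery rate (default 0.05).
#' @param which `"largest"` or `"smallest"` (see above).
#' @return The P value cutoff (0 when even the smallest null P value
#'   exceeds the budget at `which = "largest"`).
#' @export
fdr_pvalue_cutoff <- function(p_null, fdr = 0.05, which = c("largest", "smallest")) {
  which <- match.arg(which)
  pn <- lapply(p_null, pvals_of)
  # mean-over-permutations coverage as a weighted pooled ECDF: each null
  # value contributes 1 / (n_permutations * its permutation's edge count)
  v <- unlist(pn, use.names = FALSE)
  w <- rep(1 / (length(pn) * lengths(pn)), lengths(pn))
  o <- order(v)
  v <- v[o]
  cum <- cumsum(w[o])
  last <- !duplicated(v, fromLast = TRUE)   # coverage at each distinct value
  cand <- c(v[last], 1)
  frac <- c(cum[last], 1)
  if (which == "largest") {
    ok <- frac <= fdr
    if (!any(ok)) return(0)
    max(cand[ok])
  } else {
    ok <- frac >= fdr
    if (!any(ok)) return(1)
    min(cand[ok])
  }
}

#' Categorize query edges by their metapath support
#'
#' Labels each query edge by which metapath embedding spaces place it below
#' the P value cutoff: `"known and supported"` (the PPI metapath and at
#' least one other), `"known"` (only the PPI metapath), `"supported"`
#' (at least one non-PPI metapath), or `"potentially novel"` (none).
#'
#' @param p_tables named list (one per metapath) of [corank_pvalue()] tables
#'   or P value vectors, all aligned to the same query edges.
#' @param ppi_metapath name of the entry representing direct
#'   protein-protein interaction evidence.
#' @param cutoff P value cutoff (e.g. from [fdr_pvalue_cutoff()]); a single
#'   value or one named value per metapath.
#' @return Factor of categories, one per query edge.
#' @export
support_categories <- function(p_tables, ppi_metapath, cutoff) {
  stopifnot(ppi_metapath %in% names(p_tables))
  get_p <- function(x) if (inherits(x, "corank_table"))
    ifelse(x$covered, x$pvalue, NA_real_) else as.numeric(x)
  P <- vapply(p_tables, get_p, numeric(length(get_p(p_tables[[1]]))))
  if (is.null(dim(P))) P <- matrix(P, nrow = 1, dimnames = list(NULL, names(p_tables)))
  cut_vec <- if (length(cutoff) == 1L) rep(cutoff, ncol(P))
             else cutoff[colnames(P)]
  pass <- sweep(P, 2L, cut_vec, `<=`)
  pass[is.na(pass)] <- FALSE
  ppi <- pass[, ppi_metapath]
  other <- rowSums(pass[, setdiff(colnames(P), ppi_metapath), drop = FALSE]) > 0
  lab <- ifelse(ppi & other, "known and supported",
         ifelse(ppi, "known",
         ifelse(other, "supported", "potentially novel")))
  factor(lab, levels = c("known and supported", "known", "supported",
                         "potentially novel"))
}
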