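#' Configuration for DWPC construction and network filtering
#'
#' @param degree_exponent exponent used to damp node degrees when weighting
#'   paths (default `-0.5`; `0` gives raw path counts).
#' @param cap_fraction,cap_min,cap_max per-node edge cap: each node keeps its
#'   top `clamp(round(cap_fraction * n_possible), cap_min, cap_max)`
#'   neighbours by weight (defaults 5%, 3, 250).
#' @param component_min_frac connected components covering less than this
#'   fraction of the entities are removed (default 0.05).
#' @param node_retention_min a metapath network retaining fewer than this
#'   fraction of its node universe is flagged REJECTED (default 0.5).
#' @return A list of class `dwpc_config`.
#' @export
dwpc_config <- function(degree_exponent = -0.5, cap_fraction = 0.05,
                        cap_min = 3L, cap_max = 250L,
                        component_min_frac = 0.05, node_retention_min = 0.5) {
  assert_scalar_number(cap_fraction, "cap_fraction", 0, 1)
  assert_scalar_number(component_min_frac, "component_min_frac", 0, 1)
  assert_scalar_number(node_retention_min, "node_retention_min", 0, 1)
  if (cap_min > cap_max) stop("cap_min must not exceed cap_max", call. = FALSE)
  structure(list(degree_exponent = degree_exponent, cap_fraction = cap_fraction,
                 cap_min = as.integer(cap_min), cap_max = as.integer(cap_max),
                 component_min_frac = component_min_frac,
                 node_retention_min = node_retention_min),
            class = "dwpc_config")
}

#' @keywords internal
#' @noRd
new_dwpc_matrix <- function(matrix, source_type, target_type,
                            metapath = NULL, n_steps = NA_integer_,
                            datasets = NULL) {
  structure(list(matrix = matrix, source_type = source_type,
                 target_type = target_type, metapath = metapath,
                 n_steps = n_steps, datasets = datasets,
                 homogeneous = identical(source_type, target_type)),
            class = "dwpc_matrix")
}

#' @export
print.dwpc_matrix <- function(x, ...) {
  cat(sprintf("<dwpc_matrix> %s: %d x %d (%s x %s), %d nonzero entries\n",
              x$metapath %||% "<adhoc>", nrow(x$matrix), ncol(x$matrix),
              x$source_type, x$target_type, Matrix::nnzero(x$matrix)))
  invisible(x)
}

# Degree-damped normalization of one dataset adjacency:
# diag(rowdeg^w) %*% A %*% diag(coldeg^w), degrees within this dataset.
#' @keywords internal
#' @noRd
dwpc_normalize <- function(A, w) {
  if (w == 0) return(A)
  r <- Matrix::rowSums(A != 0)
  cdeg <- Matrix::colSums(A != 0)
  rf <- ifelse(r > 0, r^w, 0)
  cf <- ifelse(cdeg > 0, cdeg^w, 0)
  Matrix::Diagonal(x = rf) %*% A %*% Matrix::Diagonal(x = cf)
}

# Oriented, degree-damped adjacency alternatives for one metapath step:
# one matrix per (metaedge, dataset) pair bound to the step.
#' @keywords internal
#' @noRd
step_alternatives <- function(step, kg, w) {
  alts <- list()
  for (i in seq_along(step$metaedges)) {
    me <- step$metaedges[[i]]
    lab <- metaedge_label(me)
    dss <- kg$datasets[[lab]] %||% list()
    nm <- vapply(dss, `[[`, character(1), "name")
    if (length(step$datasets)) dss <- dss[nm %in% step$datasets]
    for (ds in dss) {
      reverse <- if (me$directed) !step$along else step$flipped[i]
      A <- dataset_adjacency(ds, if (reverse) "reverse" else "forward")
      N <- dwpc_normalize(A, w)
      dimnames(N) <- dimnames(A)
      alts[[paste(lab, ds$name, sep = "/")]] <- N
    }
  }
  if (!length(alts))
    stop(sprintf("step '%s': no datasets bound", step$token), call. = FALSE)
  alts
}

#' Degree-weighted path counts along a metapath
#'
#' Collapses a metapath into a sparse source x target matrix of
#' degree-weighted path counts (DWPC): each dataset adjacency is damped as
#' `diag(rowdeg^w) A diag(coldeg^w)` with `w = degree_exponent` (degrees
#' counted within that dataset), the damped matrices are chained by
#' multiplication with node universes aligned between consecutive steps, and
#' hub-dominated paths are thereby down-weighted. When a step binds several
#' datasets or `'+'`-combined relations, one matrix is computed per
#' single-dataset chain (cartesian product over steps) and the results are
#' summed.
#'
#' @param spec a [parse_metapath()] result with dataset bindings.
#' @param kg the knowledge graph ([assemble_graph()]).
#' @param cfg a [dwpc_config()].
#' @return A `dwpc_matrix` object.
#' @examples
#' fx <- synthetic_kg(fixture_spec(seed = 1, sizes = c(GEN = 40, DIS = 20)))
#' mp <- parse_metapath("DIS-ass-GEN-ass-DIS", fx$kg)
#' dwpc_matrix(mp, fx$kg)
#' @export
dwpc_matrix <- function(spec, kg, cfg = dwpc_config()) {
  stopifnot(inherits(spec, "metapath"), inherits(kg, "knowledge_graph"))
  w <- cfg$degree_exponent
  step_mats <- lapply(spec$steps, step_alternatives, kg = kg, w = w)
  counts <- lengths(step_mats)
  if (prod(counts) > 10000)
    stop("too many dataset combinations (>10000); bind fewer datasets", call. = FALSE)
  combos <- expand.grid(lapply(counts, seq_len))
  total <- NULL
  combo_names <- character(0)
  for (r in seq_len(nrow(combos))) {
    M <- step_mats[[1L]][[combos[r, 1L]]]
    ok <- TRUE
    if (length(step_mats) > 1L) for (s in 2L:length(step_mats)) {
      N <- step_mats[[s]][[combos[r, s]]]
      shared <- intersect(colnames(M), rownames(N))
      if (!length(shared)) { ok <- FALSE; break }
      M <- M[, shared, drop = FALSE] %*% N[shared, , drop = FALSE]
    }
    if (!ok) next
    combo_names <- c(combo_names,
                     paste(vapply(seq_along(counts), function(s)
                       names(step_mats[[s]])[combos[r, s]], character(1)),
                       collapse = " | "))
    total <- if (is.null(total)) M else sparse_add(total, M)
  }
  if (is.null(total))
    stop("disconnected metapath: no dataset chain shares intermediate nodes",
         call. = FALSE)
  # self paths (x -> ... -> x) are not edges: drop the diagonal of
  # homogeneous round-trip matrices
  if (spec$source_type == spec$target_type &&
      nrow(total) == ncol(total) &&
      identical(rownames(total), colnames(total)))
    Matrix::diag(total) <- 0
  total <- Matrix::drop0(total)
  new_dwpc_matrix(total, spec$source_type, spec$target_type,
                  metapath = spec$expr, n_steps = spec$length,
                  datasets = combo_names)
}

# Keep the union of each row's top-k_row and each column's top-k_col
# entries by (weight desc, neighbour id asc). Weights are unchanged.
#' @keywords internal
#' @noRd
top_k_union <- function(M, k_row, k_col) {
  d <- as.data.frame(Matrix::summary(methods::as(M, "TsparseMatrix")))
  cn <- colnames(M); rn <- rownames(M)
  rank_within <- function(grp, other_id) {
    o <- order(grp, -d$x, xtfrm(other_id))
    rk <- integer(nrow(d))
    rk[o] <- stats::ave(seq_along(o), grp[o], FUN = seq_along)
    rk
  }
  r_rank <- rank_within(d$i, cn[d$j])
  c_rank <- rank_within(d$j, rn[d$i])
  keep <- r_rank <= k_row | c_rank <= k_col
  list(matrix = Matrix::sparseMatrix(i = d$i[keep], j = d$j[keep], x = d$x[keep],
                                     dims = dim(M), dimnames = dimnames(M)),
       kept_per_row = tabulate(d$i[r_rank <= k_row], nbins = nrow(M)),
       kept_per_col = tabulate(d$j[c_rank <= k_col], nbins = ncol(M)))
}

# Sum two sparse matrices over the union of their dimnames.
#' @keywords internal
#' @noRd
sparse_add <- function(A, B, binary = FALSE) {
  rn <- sort(unique(c(rownames(A), rownames(B))))
  cn <- sort(unique(c(colnames(A), colnames(B))))
  expand <- function(M) {
    d <- as.data.frame(Matrix::summary(methods::as(M, "TsparseMatrix")))
    Matrix::sparseMatrix(i = match(rownames(M), rn)[d$i],
                         j = match(colnames(M), cn)[d$j], x = d$x,
                         dims = c(length(rn), length(cn)),
                         dimnames = list(rn, cn))
  }
  S <- expand(A) + expand(B)
  if (binary && length(S@x)) S@x[] <- 1
  S
}

#' Cap the number of edges per node
#'
#' Each node keeps its top-`k` incident edges by weight, where
#' `k = clamp(round(cap_fraction * n_possible), cap_min, cap_max)` and
#' `n_possible` is the size of the opposite-side universe (minus one for
#' homogeneous networks). The cap is applied from the row and the column
#' perspective; an edge survives if either endpoint keeps it. Ties are
#' broken by descending weight then ascending neighbour id, and surviving
#' edge weights are unchanged, so the operation is idempotent.
#'
#' @param x a `dwpc_matrix` (or a sparse matrix with dimnames).
#' @param cfg a [dwpc_config()].
#' @return The capped object, with attribute `cap_report` holding `k_row`,
#'   `k_col` and the per-node kept-edge counts (`kept_per_row`,
#'   `kept_per_col`: the size of each node's own top-`k` selection).
#' @export
cap_edges <- function(x, cfg = dwpc_config()) {
  M <- if (inherits(x, "dwpc_matrix")) x$matrix else x
  homo <- if (inherits(x, "dwpc_matrix")) x$homogeneous else FALSE
  clamp <- function(k) max(cfg$cap_min, min(cfg$cap_max, k))
  k_row <- clamp(round_half_up(cfg$cap_fraction * (ncol(M) - homo)))
  k_col <- clamp(round_half_up(cfg$cap_fraction * (nrow(M) - homo)))
  res <- top_k_union(M, k_row, k_col)
  out <- res$matrix
  report <- c(list(k_row = k_row, k_col = k_col), res[c("kept_per_row", "kept_per_col")])
  if (inherits(x, "dwpc_matrix")) {
    x$matrix <- out
    attr(x, "cap_report") <- report
    x
  } else {
    attr(out, "cap_report") <- report
    out
  }
}

#' Merge metapath networks
#'
#' Combines networks over the same pair of entity types, taking the union of
#' the edges (`mode = "union"`, the rule for stacks of length-1 metapaths,
#' which are unweighted) or adding the DWPC values elementwise
#' (`mode = "sum"`, the rule for longer metapaths). Node universes are
#' aligned by id over the union.
#'
#' @param parts list of `dwpc_matrix` objects (or sparse matrices with
#'   dimnames).
#' @param mode `"sum"` or `"union"`.
#' @return A merged `dwpc_matrix` (or sparse matrix if no part was one).
#' @export
merge_networks <- function(parts, mode = c("sum", "union")) {
  mode <- match.arg(mode)
  if (!length(parts)) stop("`parts` is empty", call. = FALSE)
  is_dw <- vapply(parts, inherits, logical(1), "dwpc_matrix")
  if (any(is_dw)) {
    st <- unique(vapply(parts[is_dw], `[[`, character(1), "source_type"))
    tt <- unique(vapply(parts[is_dw], `[[`, character(1), "target_type"))
    if (length(st) > 1L || length(tt) > 1L)
      stop("cannot merge networks over different entity types", call. = FALSE)
  }
  mats <- lapply(parts, function(p) if (inherits(p, "dwpc_matrix")) p$matrix else p)
  out <- mats[[1L]]
  if (mode == "union" && length(out@x)) out@x[] <- 1
  if (length(mats) > 1L) for (i in 2L:length(mats)) {
    out <- sparse_add(out, mats[[i]], binary = mode == "union")
  }
  out <- Matrix::drop0(out)
  if (any(is_dw)) {
    tmpl <- parts[is_dw][[1L]]
    new_dwpc_matrix(out, tmpl$source_type, tmpl$target_type,
                    metapath = paste(unique(vapply(
                      parts[is_dw], function(p) p$metapath %||% "<adhoc>",
                      character(1))), collapse = " + "),
                    n_steps = tmpl$n_steps)
  } else out
}

#' Remove small network components and report node retention
#'
#' Builds the (bipartite or homogeneous) graph of the matrix, drops
#' connected components covering less than `component_min_frac` of the
#' entities, and flags the network as REJECTED when the surviving components
#' retain less than `node_retention_min` of the node universe. Rejected
#' metapaths are excluded from embedding.
#'
#' @param x a `dwpc_matrix` (or sparse matrix).
#' @param cfg a [dwpc_config()].
#' @return List with the filtered `dwpc` and a `report`
#'   (`n_components`, `n_dropped_components`, `retained_nodes`,
#'   `total_nodes`, `retained_frac`, `rejected`).
#' @export
filter_components <- function(x, cfg = dwpc_config()) {
  M <- if (inherits(x, "dwpc_matrix")) x$matrix else x
  homo <- if (inherits(x, "dwpc_matrix")) x$homogeneous
          else (nrow(M) == ncol(M) && identical(rownames(M), colnames(M)))
  d <- as.data.frame(Matrix::summary(methods::as(M, "TsparseMatrix")))
  if (homo) {
    n_total <- nrow(M)
    verts <- seq_len(n_total)
    el <- cbind(d$i, d$j)
  } else {
    n_total <- nrow(M) + ncol(M)
    verts <- seq_len(n_total)
    el <- cbind(d$i, nrow(M) + d$j)
  }
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  g <- igraph::add_vertices(g, n_total - igraph::vcount(g))
  comp <- igraph::components(g)
  keep_comp <- which(comp$csize >= cfg$component_min_frac * n_total &
                       comp$csize > 1L)
  keep_vert <- comp$membership %in% keep_comp
  if (homo) {
    rows_keep <- cols_keep <- keep_vert
  } else {
    rows_keep <- keep_vert[seq_len(nrow(M))]
    cols_keep <- keep_vert[nrow(M) + seq_len(ncol(M))]
  }
  Mf <- M[rows_keep, cols_keep, drop = FALSE]
  retained <- sum(keep_vert)
  report <- list(n_components = comp$no,
                 n_dropped_components = comp$no - length(keep_comp),
                 retained_nodes = retained, total_nodes = n_total,
                 retained_frac = retained / n_total,
                 rejected = retained / n_total < cfg$node_retention_min)
  if (inherits(x, "dwpc_matrix")) {
    x$matrix <- Mf
    list(dwpc = x, report = report)
  } else {
    list(dwpc = Mf, report = report)
  }
}
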