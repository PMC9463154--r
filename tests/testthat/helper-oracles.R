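# Independent oracles used to freeze expected values.

# Brute-force DWPC by explicit path enumeration: for every path from a
# source of the first matrix to a target of the last, multiply
# rowdeg(u)^w * coldeg(v)^w for each edge (u, v) crossed, degrees counted
# within that step's matrix, and sum per (source, target) pair.
dwpc_oracle <- function(mats, w) {
  mats <- lapply(mats, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    (m != 0) * 1
  })
  rdeg <- lapply(mats, rowSums)
  cdeg <- lapply(mats, colSums)
  pw <- function(d) if (w == 0) 1 else if (d > 0) d^w else 0
  src <- rownames(mats[[1]])
  tgt <- colnames(mats[[length(mats)]])
  out <- matrix(0, length(src), length(tgt), dimnames = list(src, tgt))
  cur_src <- NULL
  recurse <- function(step, node, weight) {
    m <- mats[[step]]
    if (!node %in% rownames(m)) return(invisible(NULL))
    for (v in colnames(m)[m[node, ] != 0]) {
      wt <- weight * pw(rdeg[[step]][[node]]) * pw(cdeg[[step]][[v]])
      if (step == length(mats)) {
        out[cur_src, v] <<- out[cur_src, v] + wt
      } else {
        recurse(step + 1L, v, wt)
      }
    }
  }
  for (s in src) {
    cur_src <- s
    recurse(1L, s, 1)
  }
  out
}

# Build a knowledge graph holding one dataset per step of a chain of binary
# matrices, typed over distinct placeholder metanodes, plus the matching
# metapath expression. Universes are the full dimnames so degree-zero nodes
# are preserved.
chain_kg <- function(mats) {
  n_types <- length(mats) + 1L
  types <- vapply(seq_len(n_types), function(i)
    paste0(LETTERS[c(i, i, i) %% 26 + 1], collapse = ""), character(1))
  rels <- vapply(seq_along(mats), function(i)
    paste0(letters[c(i, i, i) %% 26 + 1], collapse = ""), character(1))
  mes <- lapply(seq_along(mats), function(i)
    metaedge(types[i], rels[i], types[i + 1L]))
  datasets <- lapply(seq_along(mats), function(i) {
    m <- as.matrix(mats[[i]])
    idx <- which(m != 0, arr.ind = TRUE)
    dataset_network(paste0("ds", i), mes[[i]],
                    data.frame(source = rownames(m)[idx[, 1]],
                               target = colnames(m)[idx[, 2]],
                               stringsAsFactors = FALSE),
                    source_universe = rownames(m),
                    target_universe = colnames(m))
  })
  kg <- assemble_graph(datasets, metagraph(types, mes))
  expr <- paste(types[1], paste(rels, types[-1], sep = "-", collapse = "-"),
                sep = "-")
  list(kg = kg, expr = expr)
}

# Random binary matrix with guaranteed non-empty dimnames; prefixes keep
# node ids distinct across layers.
random_binary_matrix <- function(nr, nc, density, rp, cp) {
  m <- matrix(as.numeric(stats::runif(nr * nc) < density), nr, nc,
              dimnames = list(sprintf("%s%02d", rp, seq_len(nr)),
                              sprintf("%s%02d", cp, seq_len(nc))))
  if (all(m == 0)) m[1, 1] <- 1
  m
}

# Mean silhouette of points under a labelling (Euclidean distances).
mean_silhouette <- function(X, labels) {
  D <- as.matrix(stats::dist(X))
  sil <- vapply(seq_len(nrow(X)), function(i) {
    own <- labels == labels[i]
    a <- mean(D[i, own & seq_len(nrow(X)) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(l) mean(D[i, labels == l]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(sil)
}

# Dense reference TF-IDF (same variant the package states: smoothed idf
# ln((1+N)/(1+df)) + 1, L2 rows), written independently with explicit loops.
tfidf_reference <- function(m) {
  n <- nrow(m)
  out <- matrix(0, nrow(m), ncol(m), dimnames = dimnames(m))
  df <- integer(ncol(m))
  for (j in seq_len(ncol(m))) df[j] <- sum(m[, j] > 0)
  for (i in seq_len(n)) {
    row <- numeric(ncol(m))
    for (j in seq_len(ncol(m))) row[j] <- m[i, j] * (log((1 + n) / (1 + df[j])) + 1)
    nrm <- sqrt(sum(row^2))
    out[i, ] <- if (nrm > 0) row / nrm else row
  }
  out
}
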