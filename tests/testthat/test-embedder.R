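# Small helper: sparse homogeneous adjacency from an edge list.
adj_from_edges <- function(edges, ids, weights = 1) {
  M <- Matrix::sparseMatrix(i = match(edges[, 1], ids),
                            j = match(edges[, 2], ids), x = weights,
                            dims = c(length(ids), length(ids)),
                            dimnames = list(ids, ids))
  methods::as(M + Matrix::t(M), "generalMatrix")
}

test_that("a single-edge graph forces alternating walks", {
  M <- adj_from_edges(cbind("a", "b"), c("a", "b"))
  corpus <- generate_walks(M, embed_config(walks_per_node = 3, walk_length = 8,
                                           seed = 1))
  expect_equal(nrow(corpus$walks), 6L)
  for (r in seq_len(nrow(corpus$walks))) {
    w <- corpus$ids[corpus$walks[r, ]]
    expect_true(all(w == rep(c(w[1], setdiff(c("a", "b"), w[1])), 4)))
  }
})

test_that("transition frequencies follow the edge weights", {
  # star: uniform over 4 leaves
  ids <- c("hub", paste0("leaf", 1:4))
  M <- adj_from_edges(cbind("hub", paste0("leaf", 1:4)), ids)
  corpus <- generate_walks(M, embed_config(walks_per_node = 40, walk_length = 50,
                                           seed = 2))
  w <- matrix(corpus$ids[corpus$walks], nrow(corpus$walks))
  from_hub <- w[, -ncol(w)] == "hub"
  nxt <- w[, -1][from_hub]
  freq <- table(nxt) / length(nxt)
  n <- length(nxt)
  # binomial 4-sigma band around 1/4
  expect_true(all(abs(freq - 0.25) < 4 * sqrt(0.25 * 0.75 / n)))

  # weighted pair {0.9, 0.1} from a common node: ~9:1 transitions
  ids2 <- c("x", "h", "l")
  W <- Matrix::sparseMatrix(i = c(1, 1), j = c(2, 3), x = c(0.9, 0.1),
                            dims = c(3, 3), dimnames = list(ids2, ids2))
  W <- methods::as(W + Matrix::t(W), "generalMatrix")
  corpus2 <- generate_walks(W, embed_config(walks_per_node = 60, walk_length = 50,
                                            seed = 3))
  w2 <- matrix(corpus2$ids[corpus2$walks], nrow(corpus2$walks))
  from_x <- w2[, -ncol(w2)] == "x"
  nxt2 <- w2[, -1][from_x]
  p_h <- mean(nxt2 == "h")
  expect_lt(abs(p_h - 0.9), 4 * sqrt(0.9 * 0.1 / length(nxt2)))
})

test_that("walk corpus covers every non-isolated node and skips isolated ones", {
  ids <- c("a", "b", "c", "iso")
  M <- adj_from_edges(rbind(c("a", "b"), c("b", "c")), ids)
  cfg <- embed_config(walks_per_node = 7, walk_length = 5, seed = 4)
  expect_warning(corpus <- generate_walks(M, cfg), "isolated")
  expect_equal(nrow(corpus$walks), 3L * 7L)
  anchors <- corpus$ids[corpus$walks[, 1]]
  expect_equal(unname(table(anchors)[c("a", "b", "c")]),
               rep(7L, 3), ignore_attr = TRUE)
  expect_false("iso" %in% corpus$ids[corpus$walks])
})

test_that("walks and embeddings are reproducible for a seed and vary across seeds", {
  fx <- planted_partition_network(60, 3, 0.4, 0.05, seed = 5)
  cfg <- embed_config(dimension = 16, walks_per_node = 5, walk_length = 20,
                      epochs = 2, seed = 11)
  c1 <- generate_walks(fx$network, cfg)
  c2 <- generate_walks(fx$network, cfg)
  expect_identical(c1$walks, c2$walks)
  e1 <- train_skipgram(c1, cfg)
  e2 <- train_skipgram(c2, cfg)
  expect_identical(e1$vectors, e2$vectors)

  cfg2 <- embed_config(dimension = 16, walks_per_node = 5, walk_length = 20,
                       epochs = 2, seed = 12)
  c3 <- generate_walks(fx$network, cfg2)
  expect_false(identical(c1$walks, c3$walks))
})

test_that("skip-gram separates disconnected cliques and planted blocks", {
  # two 8-cliques
  ids <- c(sprintf("u%02d", 1:8), sprintf("v%02d", 1:8))
  edges <- rbind(t(utils::combn(ids[1:8], 2)), t(utils::combn(ids[9:16], 2)))
  M <- adj_from_edges(edges, ids)
  cfg <- embed_config(dimension = 16, walks_per_node = 20, walk_length = 20,
                      epochs = 3, seed = 6)
  emb <- train_skipgram(generate_walks(M, cfg), cfg)
  S <- tcrossprod(emb$vectors / sqrt(rowSums(emb$vectors^2)))
  grp <- substr(emb$ids, 1, 1)
  same <- outer(grp, grp, "==") & !diag(length(grp))
  expect_gt(mean(S[same]), mean(S[!same & !diag(length(grp))]))

  # planted-partition fixture: positive silhouette over the true blocks
  fx <- planted_partition_network(90, 3, 0.35, 0.02, seed = 7)
  cfg2 <- embed_config(dimension = 32, walks_per_node = 20, walk_length = 40,
                       epochs = 3, seed = 8)
  emb2 <- train_skipgram(generate_walks(fx$network, cfg2), cfg2)
  sil <- mean_silhouette(emb2$vectors, fx$labels[emb2$ids])
  expect_gt(sil, 0)
})

test_that("skip-gram contracts: dimension, vocabulary guard", {
  M <- adj_from_edges(rbind(c("a", "b"), c("b", "c")), c("a", "b", "c"))
  cfg <- embed_config(dimension = 24, walks_per_node = 2, walk_length = 10,
                      epochs = 1, seed = 1)
  emb <- train_skipgram(generate_walks(M, cfg), cfg)
  expect_equal(ncol(emb$vectors), 24L)
  expect_setequal(emb$ids, c("a", "b", "c"))

  lone <- structure(list(walks = matrix(1L, 2, 5), ids = "a", types = "NOD",
                         cfg = cfg), class = "walk_corpus")
  expect_error(train_skipgram(lone, cfg), "at least 2")
})

test_that("embed_metapath aborts on REJECTED networks and records provenance", {
  fx <- synthetic_kg(fixture_spec(seed = 10, sizes = c(GEN = 60L, DIS = 30L)))
  mp <- parse_metapath("DIS-ass-GEN-ass-DIS", fx$kg)
  cfg <- embed_config(dimension = 16, walks_per_node = 5, walk_length = 20,
                      epochs = 2, seed = 3)
  emb <- embed_metapath(mp, fx$kg, embed_cfg = cfg)
  expect_identical(emb$meta$metapath, "DIS-ass-GEN-ass-DIS")
  expect_false(emb$meta$retention$rejected)
  expect_s3_class(emb$meta$network, "dwpc_matrix")

  # a pairing network fragments into dimers and must be rejected
  n <- 60
  ids <- sprintf("g%03d", 1:n)
  pair_edges <- data.frame(source = ids[seq(1, n, 2)], target = ids[seq(2, n, 2)])
  ds <- dataset_network("dimers", metaedge("GEN", "ppi", "GEN"), pair_edges,
                        source_universe = ids)
  kg2 <- assemble_graph(list(ds), default_metagraph())
  mp2 <- parse_metapath("GEN-ppi-GEN", kg2)
  expect_error(embed_metapath(mp2, kg2, embed_cfg = cfg), "REJECTED")
})

test_that("embeddings round-trip through TSV", {
  fx <- planted_partition_network(30, 2, 0.5, 0.05, seed = 13)
  cfg <- embed_config(dimension = 8, walks_per_node = 3, walk_length = 10,
                      epochs = 1, seed = 2)
  emb <- train_skipgram(generate_walks(fx$network, cfg), cfg)
  prefix <- file.path(withr::local_tempdir(), "emb")
  write_embedding(emb, prefix, neighbors = 3)
  back <- read_embedding(prefix)
  expect_equal(unname(back$vectors), unname(emb$vectors), tolerance = 1e-12)
  expect_identical(back$ids, emb$ids)
  nn <- utils::read.table(paste0(prefix, "_neighbors.tsv"), header = TRUE,
                          sep = "\t")
  expect_equal(nrow(nn), nrow(emb$vectors) * 3L)
})
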