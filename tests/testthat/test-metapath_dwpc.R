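mg <- default_metagraph()

test_that("metapath parsing resolves steps, orientations and errors", {
  mp <- parse_metapath("CPD-int-GEN-ass-DIS", mg)
  expect_equal(mp$length, 2L)
  expect_equal(mp$source_type, "CPD")
  expect_equal(mp$target_type, "DIS")
  # DIS-ass-GEN is stored canonically; the second step traverses it flipped
  expect_true(mp$steps[[2]]$flipped[1])

  kin <- parse_metapath("GEN-_pho-GEN-ass-PWY", mg)
  expect_true(kin$steps[[1]]$along)
  sub <- parse_metapath("GEN-pho_-GEN-ass-PWY", mg)
  expect_false(sub$steps[[1]]$along)

  both <- parse_metapath("CLL-dwr+upr-GEN-dwr+upr-CLL", mg)
  expect_equal(both$steps[[1]]$relations, c("dwr", "upr"))

  expect_error(parse_metapath("CPD-int-GEN-has-CLL", mg), "not declared")
  expect_error(parse_metapath("CPD-int-GEN-ass", mg), "malformed")
  expect_error(parse_metapath("CPD-_int-GEN", mg), "homogeneous")
  expect_error(parse_metapath("GEN-_ppi-GEN", mg), "undirected")
  expect_error(parse_metapath("GEN-ppi+pho-GEN", mg), "combine")
})

test_that("metapath grammar rules flag the composition violations", {
  expect_match(validate_metapath_rules(parse_metapath("CPD-sim-CPD", mg)),
               "similarity", all = FALSE)
  expect_match(validate_metapath_rules(parse_metapath("DIS-xrf-DIS", mg)),
               "cross-reference", all = FALSE)
  expect_match(validate_metapath_rules(parse_metapath("PGN-pup-GEN", mg)),
               "perturbagen", all = FALSE)
  # PGN-perturbed genes may not continue through undirected homogeneous edges
  v <- validate_metapath_rules(parse_metapath("PGN-pup-GEN-ppi-GEN", mg))
  expect_match(v, "undirected homogeneous", all = FALSE)
  expect_length(validate_metapath_rules(parse_metapath("PGN-pup-GEN-_reg-GEN", mg)), 0L)
  expect_length(validate_metapath_rules(parse_metapath("PGN-pup-GEN-ass-DIS", mg)), 0L)
  # CLL rules
  expect_length(validate_metapath_rules(
    parse_metapath("CLL-dwr+upr-GEN-dwr+upr-CLL", mg)), 0L)
  mg2 <- metagraph(c("CLL", "GEN"), list(metaedge("CLL", "exp", "GEN")))
  expect_match(validate_metapath_rules(parse_metapath("CLL-exp-GEN", mg2)),
               "upr/dwr/mut", all = FALSE)
})

test_that("DWPC matches hand-derived values on the canonical examples", {
  # chain A1-B1-C1, all degrees 1: DWPC = 1
  m1 <- matrix(1, 1, 1, dimnames = list("A1", "B1"))
  m2 <- matrix(1, 1, 1, dimnames = list("B1", "C1"))
  ck <- chain_kg(list(m1, m2))
  dw <- dwpc_matrix(parse_metapath(ck$expr, ck$kg), ck$kg)
  expect_equal(as.numeric(dw$matrix["A1", "C1"]), 1)

  # A1 -> {B1, B2}; B1 -> C1; B2 -> {C1, C2}
  mA <- matrix(c(1, 1), 1, 2, dimnames = list("A1", c("B1", "B2")))
  mB <- matrix(c(1, 0, 1, 1), 2, 2, byrow = TRUE,
               dimnames = list(c("B1", "B2"), c("C1", "C2")))
  ck2 <- chain_kg(list(mA, mB))
  dw2 <- dwpc_matrix(parse_metapath(ck2$expr, ck2$kg), ck2$kg)
  expect_equal(as.numeric(dw2$matrix["A1", "C1"]),
               2^-0.5 * (1 * 2^-0.5 + 1 * (2^-0.5 * 2^-0.5)), tolerance = 1e-12)

  # exponent 0: raw path counts
  dw0 <- dwpc_matrix(parse_metapath(ck2$expr, ck2$kg), ck2$kg,
                     dwpc_config(degree_exponent = 0))
  expect_equal(unname(as.matrix(dw0$matrix)), unname((mA != 0) %*% (mB != 0)))
})

test_that("DWPC equals brute-force path enumeration on random chains", {
  set.seed(101)
  for (rep in 1:30) {
    n_steps <- sample(2:3, 1)
    dims <- sample(3:9, n_steps + 1, replace = TRUE)
    mats <- lapply(seq_len(n_steps), function(s)
      random_binary_matrix(dims[s], dims[s + 1], runif(1, 0.2, 0.7),
                           paste0("n", s, "_"), paste0("n", s + 1, "_")))
    ck <- chain_kg(mats)
    dw <- dwpc_matrix(parse_metapath(ck$expr, ck$kg), ck$kg)
    expected <- dwpc_oracle(mats, -0.5)
    got <- as.matrix(dw$matrix)[rownames(expected), colnames(expected)]
    expect_lt(max(abs(got - expected)), 1e-9)
  }
})

test_that("DWPC handles directed and undirected homogeneous steps", {
  # directed homogeneous traversed with and against its direction
  pho <- dataset_network("kin", metaedge("GEN", "pho", "GEN", directed = TRUE),
                         data.frame(source = c("k1", "k1", "k2"),
                                    target = c("s1", "s2", "s1")),
                         source_universe = c("k1", "k2", "s1", "s2"))
  pwy <- dataset_network("pw", metaedge("PWY", "ass", "GEN"),
                         data.frame(source = c("p1", "p2", "p2"),
                                    target = c("k1", "s1", "s2")),
                         source_universe = c("p1", "p2"),
                         target_universe = c("k1", "k2", "s1", "s2"))
  kg <- assemble_graph(list(pho, pwy), mg)
  # kinases reach their substrates' pathways (p2), not their own (p1)
  fwd <- dwpc_matrix(parse_metapath("GEN-_pho-GEN-ass-PWY", kg), kg)
  expect_gt(fwd$matrix["k1", "p2"], 0)
  expect_gt(fwd$matrix["k2", "p2"], 0)
  expect_equal(as.numeric(fwd$matrix["k1", "p1"]), 0)
  # substrates reach their kinases' pathways (p1), not their own (p2)
  rev <- dwpc_matrix(parse_metapath("GEN-pho_-GEN-ass-PWY", kg), kg)
  expect_gt(rev$matrix["s1", "p1"], 0)
  expect_gt(rev$matrix["s2", "p1"], 0)
  expect_equal(as.numeric(rev$matrix["s1", "p2"]), 0)

  # symmetric dataset stack gives a symmetric DWPC matrix
  fx <- synthetic_kg(fixture_spec(seed = 9, sizes = c(GEN = 40L, DIS = 20L),
                                  n_blocks = 2L))
  dw <- dwpc_matrix(parse_metapath("DIS-ass-GEN-ass-DIS", fx$kg), fx$kg)
  expect_lt(max(abs(dw$matrix - Matrix::t(dw$matrix))), 1e-12)
  expect_equal(sum(Matrix::diag(dw$matrix)), 0)  # self paths are not edges

  # oracle agreement for an undirected homogeneous middle step, off-diagonal
  ppi <- matrix(0, 4, 4, dimnames = list(paste0("g", 1:4), paste0("g", 1:4)))
  ppi["g1", "g2"] <- ppi["g2", "g3"] <- ppi["g3", "g4"] <- 1
  ppi_sym <- pmax(ppi, t(ppi))
  dis <- matrix(1, 2, 4, dimnames = list(c("d1", "d2"), paste0("g", 1:4)))
  dis["d1", 3:4] <- 0; dis["d2", 1:2] <- 0
  dsl <- list(
    dataset_network("ass", metaedge("DIS", "ass", "GEN"),
                    data.frame(source = rownames(dis)[which(dis != 0, arr.ind = TRUE)[, 1]],
                               target = colnames(dis)[which(dis != 0, arr.ind = TRUE)[, 2]]),
                    source_universe = rownames(dis), target_universe = colnames(dis)),
    dataset_network("net", metaedge("GEN", "ppi", "GEN"),
                    data.frame(source = c("g1", "g2", "g3"),
                               target = c("g2", "g3", "g4")),
                    source_universe = paste0("g", 1:4)))
  kg2 <- assemble_graph(dsl, mg)
  dw2 <- dwpc_matrix(parse_metapath("DIS-ass-GEN-ppi-GEN-ass-DIS", kg2), kg2)
  expected <- dwpc_oracle(list(dis, ppi_sym, t(dis)), -0.5)
  got <- as.matrix(dw2$matrix)[rownames(expected), colnames(expected)]
  diag(expected) <- 0  # implementation drops self paths
  expect_lt(max(abs(got - expected)), 1e-9)
})

test_that("dwpc_matrix rejects disconnected chains", {
  m1 <- matrix(1, 2, 2, dimnames = list(c("A1", "A2"), c("B1", "B2")))
  m2 <- matrix(1, 2, 2, dimnames = list(c("BX", "BY"), c("C1", "C2")))
  ck <- chain_kg(list(m1, m2))
  expect_error(dwpc_matrix(parse_metapath(ck$expr, ck$kg), ck$kg),
               "disconnected metapath")
})

test_that("edge capping clamps per-node neighbour counts and is idempotent", {
  cfg <- dwpc_config()
  # node with 20 possible neighbours: k clamps up to the minimum of 3
  set.seed(7)
  M <- Matrix::Matrix(matrix(runif(5 * 20), 5, 20,
                             dimnames = list(paste0("r", 1:5), paste0("c", 1:20))),
                      sparse = TRUE)
  capped <- cap_edges(M, cfg)
  rep1 <- attr(capped, "cap_report")
  expect_equal(rep1$k_row, 3L)
  expect_true(all(rep1$kept_per_row == 3L))

  # already sparse rows are unchanged
  S <- Matrix::sparseMatrix(i = c(1, 1, 2), j = c(1, 2, 3), x = c(5, 4, 1),
                            dims = c(3, 60),
                            dimnames = list(paste0("r", 1:3), paste0("c", 1:60)))
  expect_equal(Matrix::nnzero(cap_edges(S, cfg)), 3L)

  # idempotence, weights unchanged
  fx <- synthetic_kg(fixture_spec(seed = 2, sizes = c(GEN = 60L, DIS = 40L)))
  dw <- dwpc_matrix(parse_metapath("DIS-ass-GEN-ass-DIS", fx$kg), fx$kg)
  c1 <- cap_edges(dw, cfg)
  c2 <- cap_edges(c1, cfg)
  expect_equal(c1$matrix, c2$matrix)
  d1 <- Matrix::summary(c1$matrix)
  expect_true(all(abs(dw$matrix[cbind(d1$i, d1$j)] - d1$x) < 1e-15))

  # deterministic tie-break: uniform weights keep lowest ids; the union
  # rule additionally keeps every edge the low-id rows were chosen for by
  # the column perspective
  U <- Matrix::Matrix(1, 30, 100, sparse = TRUE,
                      dimnames = list(sprintf("r%02d", 1:30),
                                      sprintf("c%03d", 1:100)))
  cu <- cap_edges(U, dwpc_config(cap_fraction = 0.05, cap_min = 3, cap_max = 250))
  su <- Matrix::summary(cu)
  kept10 <- colnames(U)[su$j[su$i == 10]]
  expect_setequal(kept10, sprintf("c%03d", 1:5))   # its own top-5 only
  kept01 <- colnames(U)[su$j[su$i == 1]]
  expect_length(kept01, 100L)                      # kept by every column too
})

test_that("network merging unions L1 edges and sums DWPC weights", {
  A <- Matrix::sparseMatrix(i = 1:2, j = 1:2, x = c(2, 3), dims = c(2, 2),
                            dimnames = list(c("a", "b"), c("x", "y")))
  B <- Matrix::sparseMatrix(i = c(1, 2), j = c(1, 2), x = c(5, 7), dims = c(2, 2),
                            dimnames = list(c("a", "c"), c("x", "z")))
  expect_equal(merge_networks(list(A), "sum"), Matrix::drop0(A))

  s <- merge_networks(list(A, B), "sum")
  expect_equal(as.numeric(s["a", "x"]), 7)   # 2 + 5
  expect_equal(as.numeric(s["c", "z"]), 7)
  expect_equal(as.numeric(s["b", "y"]), 3)

  u <- merge_networks(list(A, B), "union")
  expect_true(all(u@x == 1))
  expect_equal(Matrix::nnzero(u), 3L)  # a-x shared, b-y and c-z disjoint

  # commutative and associative under sum
  C <- Matrix::sparseMatrix(i = 1, j = 2, x = 11, dims = c(1, 2),
                            dimnames = list("a", c("x", "y")))
  lhs <- merge_networks(list(merge_networks(list(A, B), "sum"), C), "sum")
  rhs <- merge_networks(list(A, merge_networks(list(B, C), "sum")), "sum")
  expect_equal(lhs, rhs)
  expect_equal(merge_networks(list(B, A), "sum")[rownames(s), colnames(s)], s)
})

test_that("component filtering drops minor components and flags rejection", {
  # one giant component (a ring): unchanged, retained
  ring <- Matrix::sparseMatrix(i = 1:50, j = c(2:50, 1), x = 1,
                               dims = c(50, 50),
                               dimnames = list(sprintf("r%02d", 1:50),
                                               sprintf("r%02d", 1:50)))
  fc <- filter_components(ring)
  expect_false(fc$report$rejected)
  expect_equal(fc$report$retained_frac, 1)
  expect_equal(fc$dwpc, ring)

  # 96%/4% split: the small component disappears
  big <- igraph::sample_gnp(96, 0.2)
  small <- igraph::make_full_graph(4)
  el <- rbind(igraph::as_edgelist(big), igraph::as_edgelist(small) + 96)
  M <- Matrix::sparseMatrix(i = el[, 1], j = el[, 2], x = 1, dims = c(100, 100),
                            dimnames = list(sprintf("n%03d", 1:100),
                                            sprintf("n%03d", 1:100)))
  fc2 <- filter_components(M)
  expect_equal(nrow(fc2$dwpc), 96L)
  expect_false(fc2$report$rejected)

  # fragmentation into tiny components: REJECTED
  tiny <- Matrix::sparseMatrix(i = seq(1, 99, by = 2), j = seq(2, 100, by = 2),
                               x = 1, dims = c(100, 100),
                               dimnames = list(sprintf("m%03d", 1:100),
                                               sprintf("m%03d", 1:100)))
  fc3 <- filter_components(tiny)
  expect_true(fc3$report$rejected)
})
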