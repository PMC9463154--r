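test_that("expression binarization yields disjoint top-k signatures per sample", {
  # groups cover at most 20% of samples so per-gene robust scaling is not
  # inflated by the shifted group itself
  fx <- synthetic_expression(n_genes = 2000L, n_samples = 15L, n_groups = 5L,
                             effect = 2, seed = 5)
  cfg <- standardize_config(top_k_genes = 200L)
  res <- binarize_expression(fx$values, cfg)
  up <- split(res$upregulated$edges$target, res$upregulated$edges$source)
  dn <- split(res$downregulated$edges$target, res$downregulated$edges$source)
  expect_true(all(lengths(up) == 200L))
  expect_true(all(lengths(dn) == 200L))
  for (s in names(up)) expect_length(intersect(up[[s]], dn[[s]]), 0L)

  # quantile normalization leaves every sample with one value distribution
  qn <- res$normalized
  sorted <- apply(qn, 2L, sort)
  expect_lt(max(abs(sorted - sorted[, 1])), 1e-8)

  # group markers are recovered in the group's up-signatures far beyond chance
  for (g in seq_along(fx$markers)) {
    samples <- names(fx$groups)[fx$groups == g]
    hits <- vapply(samples, function(s)
      length(intersect(up[[s]], fx$markers[[g]]$up)), numeric(1))
    n_mark <- length(fx$markers[[g]]$up)
    p <- phyper(min(hits) - 1, n_mark, 2000 - n_mark, 200, lower.tail = FALSE)
    expect_lt(p, 1e-6)
  }
})

test_that("expression binarization guards and options behave", {
  fx <- synthetic_expression(n_genes = 300L, n_samples = 4L, seed = 1)
  expect_error(binarize_expression(fx$values), "at least 500 genes")

  # already log-scale data: log2 must be skipped
  lg <- log2(fx$values)
  cfg <- standardize_config(top_k_genes = 20L)
  a <- binarize_expression(lg, cfg, log_transform = FALSE)
  b <- binarize_expression(fx$values, cfg, log_transform = TRUE)
  expect_identical(a$upregulated$edges, b$upregulated$edges)

  # duplicate genes collapse by mean before anything else
  v <- fx$values
  dup <- rbind(v, v[1:5, ])
  d <- binarize_expression(dup, cfg, log_transform = FALSE)
  expect_equal(nrow(d$scaled), 300L)

  # nonpositive values are shifted before log2, and the shift is recorded
  v2 <- v - min(v) - 1
  s <- binarize_expression(v2, cfg)
  expect_gt(s$meta$shift, 0)

  # a gene at the floor of every sample stays constant after quantile
  # normalization: scaled by 1 with a warning
  v3 <- v
  v3[7, ] <- min(v) - 10
  expect_warning(binarize_expression(v3, cfg, log_transform = FALSE),
                 "zero IQR")
})

test_that("waterfall binarization finds the elbow and respects its bounds", {
  cfg <- standardize_config()
  # all resistant above the AUC cutoff: empty call set
  flat <- stats::setNames(rep(0.95, 50), sprintf("c%02d", 1:50))
  expect_length(waterfall_binarize(flat, cfg), 0L)

  # 5 clearly sensitive cells out of 100
  set.seed(42)
  auc <- c(stats::rnorm(5, 0.2, 0.01), stats::rnorm(95, 0.85, 0.01))
  names(auc) <- sprintf("c%03d", seq_along(auc))
  sens <- waterfall_binarize(auc, cfg)
  expect_setequal(sens, names(auc)[1:5])

  # output fraction is 0 or within [min_frac, max_frac] before the AUC filter
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(20:300, 1)
    prof <- stats::setNames(runif(n), sprintf("c%03d", seq_len(n)))
    got <- waterfall_binarize(prof, cfg)
    expect_lte(length(got) / n, cfg$waterfall_max_frac)
  }

  # monotone: making a sensitive cell more sensitive never drops it
  auc2 <- auc
  auc2["c001"] <- 0.05
  expect_true("c001" %in% waterfall_binarize(auc2, cfg))
  expect_error(waterfall_binarize(auc[1:5], cfg), "at least 10")
})

test_that("perturbation records are reified into typed PGN networks", {
  rec <- data.frame(
    perturbation_id = c("pgn1", "pgn2", "pgn3"),
    perturbation_kind = c("shRNA-silence", "overexpression", "CRISPR-ko"),
    perturbed_gene = c("G_A", "G_B", "G_A"),
    outcome_relation = c("upr", "dwr", "upr"),
    outcome_node = c("G_B", "G_C", "G_D"))
  out <- reify_perturbagens(rec)
  dwn <- out$gene_down$edges
  expect_setequal(paste(dwn$source, dwn$target),
                  c("pgn1 G_A", "pgn3 G_A"))  # two perturbations, two PGN nodes
  expect_equal(out$gene_up$edges$source, "pgn2")
  expect_identical(metaedge_label(out$gene_up$metaedge), "PGN-pup-GEN")
  upr <- out$outcome_upr_GEN$edges
  expect_setequal(paste(upr$source, upr$target), c("pgn1 G_B", "pgn3 G_D"))

  rec$perturbation_kind[1] <- "mystery"
  expect_error(reify_perturbagens(rec), "unknown perturbation kind")
})

test_that("information content follows the -log2 frequency formula", {
  ont <- ontology(data.frame(child = c("mid", "leaf"), parent = c("root", "mid")))
  ann <- list(leaf = "e1", mid = sprintf("e%d", 1:4), root = sprintf("e%d", 1:8))
  ic <- information_content(ont, ann)
  expect_equal(unname(ic[c("root", "mid", "leaf")]), c(0, 1, 3))

  # propagation + IC is monotone non-decreasing from root to leaves
  raw <- list(leaf = sprintf("e%d", 1:2), mid = sprintf("e%d", 3:5),
              root = sprintf("e%d", 6:8))
  icp <- information_content(ont, propagate_annotations(ont, raw))
  expect_lte(icp[["root"]], icp[["mid"]])
  expect_lte(icp[["mid"]], icp[["leaf"]])
  expect_equal(unname(icp[["root"]]), 0)
})

test_that("IC pruning removes the least informative terms monotonically", {
  ic <- c(a = 0, b = 1, c = 2, d = 3, e = 4)
  pr <- prune_uninformative_terms(NULL, ic, cutoff = 1.5)
  expect_setequal(pr$removed, c("a", "b"))
  expect_setequal(prune_uninformative_terms(NULL, ic, cutoff = 0)$removed,
                  character(0))
  # raising the cutoff removes supersets
  r1 <- prune_uninformative_terms(NULL, ic, cutoff = 1.5)$removed
  r2 <- prune_uninformative_terms(NULL, ic, cutoff = 3.5)$removed
  expect_true(all(r1 %in% r2))
  expect_error(prune_uninformative_terms(NULL, ic, cutoff = 99), "every term")
  # default quantile rule removes the bottom tail
  pq <- prune_uninformative_terms(NULL, ic, standardize_config(ic_prune_quantile = 0.25))
  expect_true("a" %in% pq$removed)
})

test_that("TF-IDF cross-reference mapping respects the cosine cutoff", {
  src <- list(s_same = c("x1", "x2", "x3"),
              s_far = c("x4", "x5"),
              s_mid = c("x1", "x6", "x7", "x8"))
  tgt <- list(t_same = c("x1", "x2", "x3"),
              t_other = c("x9", "x10"))
  res <- tfidf_crossref_map(src, tgt)
  best <- attr(res, "best")
  expect_equal(best$target[best$source == "s_same"], "t_same")
  expect_gt(best$cosine[best$source == "s_same"], 0.999)
  expect_false("s_far" %in% res$source)  # disjoint: cosine 0

  # cutoff behaviour checked against an independent dense TF-IDF computation
  all_sets <- c(src, tgt)
  uni <- sort(unique(unlist(all_sets)))
  m <- t(vapply(all_sets, function(s) as.numeric(uni %in% s),
                numeric(length(uni))))
  ref <- tfidf_reference(m)
  ref_cos <- ref[1:3, ] %*% t(ref[4:5, ])
  for (i in 1:3) for (j in 1:2) {
    pair_in <- any(res$source == names(src)[i] & res$target == names(tgt)[j])
    expect_identical(pair_in, ref_cos[i, j] >= 0.5)
    if (pair_in)
      expect_equal(res$cosine[res$source == names(src)[i] &
                                res$target == names(tgt)[j]],
                   unname(ref_cos[i, j]), tolerance = 1e-12)
  }

  expect_error(tfidf_crossref_map(list(a = "u1"), list(b = "u2")),
               "share no cross-references")
})

test_that("pathway clustering merges by overlap and links by Jaccard", {
  genes <- sprintf("g%03d", 1:60)
  sets <- list(p1 = genes[1:25], p2 = genes[1:25],      # identical
               p3 = genes[26:50],                        # separate
               p4 = genes[1:10],                         # too small
               p5 = genes[c(1:12, 30:41)])               # overlap coeff 0.5 with p1
  res <- cluster_pathways(sets)
  expect_setequal(res$excluded, "p4")
  expect_identical(res$membership$superpath[res$membership$pathway == "p1"],
                   res$membership$superpath[res$membership$pathway == "p2"])
  # overlap coefficient 12/24 = 0.5 < 0.9: p5 not merged with p1+p2
  expect_false(identical(
    res$membership$superpath[res$membership$pathway == "p5"],
    res$membership$superpath[res$membership$pathway == "p1"]))
  # identical pathways share a SuperPath and get a Jaccard-1 edge
  e <- res$similarity_edges
  expect_true(any(e$a == "p1" & e$b == "p2" & e$jaccard == 1))
  expect_false(any(e$a == "p1" & e$b == "p3" | e$a == "p3" & e$b == "p1"))
})
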