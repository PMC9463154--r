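#' Specification of the synthetic test universe
#'
#' Seeded parameters for the synthetic generators that emulate the
#' structures every pipeline stage assumes: block-structured homogeneous
#' and bipartite networks, expression matrices with correlated sample
#' groups, and per-drug response profiles with a sensitive tail. Sizes are
#' chosen so the full pipeline (graph, DWPC, embedding, evaluation) runs in
#' minutes on one CPU.
#'
#' @param seed master seed.
#' @param sizes named node counts per metanode (subset of GEN/DIS/CPD/PWY).
#' @param n_blocks planted blocks shared by all layers.
#' @param p_in,p_out within-/between-block edge probabilities.
#' @param expression parameters for [synthetic_expression()].
#' @param response parameters for [synthetic_drug_response()].
#' @return A list of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 0L,
                         sizes = c(GEN = 200L, DIS = 120L, CPD = 80L, PWY = 40L),
                         n_blocks = 4L, p_in = 0.25, p_out = 0.02,
                         expression = list(n_genes = 2000L, n_samples = 40L,
                                           n_groups = 4L, effect = 2),
                         response = list(n_drugs = 50L, n_cells = 500L,
                                         sens_frac = 0.05)) {
  assert_scalar_number(p_in, "p_in", 0, 1)
  assert_scalar_number(p_out, "p_out", 0, 1)
  if (any(sizes < 2L)) stop("all sizes must be >= 2", call. = FALSE)
  structure(list(seed = as.integer(seed), sizes = sizes,
                 n_blocks = as.integer(n_blocks), p_in = p_in, p_out = p_out,
                 expression = expression, response = response),
            class = "fixture_spec")
}

#' Planted-partition (stochastic block model) network
#'
#' Homogeneous random graph with `k_blocks` equal planted blocks: node
#' pairs within a block are connected with probability `p_in`, across
#' blocks with `p_out`. The true block labels are returned for downstream
#' silhouette/AUROC checks.
#'
#' @param n nodes.
#' @param k_blocks number of blocks.
#' @param p_in,p_out edge probabilities.
#' @param seed RNG seed.
#' @param type metanode abbreviation (default `"GEN"`).
#' @param relation relation tag (default `"ppi"`).
#' @param name dataset name.
#' @return List with `network` (a [dataset_network()]) and `labels` (named
#'   integer block labels).
#' @export
planted_partition_network <- function(n, k_blocks, p_in, p_out, seed = 0L,
                                      type = "GEN", relation = "ppi",
                                      name = "planted_partition") {
  stopifnot(n >= 2L, k_blocks >= 1L)
  ids <- sprintf("%s%04d", tolower(type), seq_len(n))
  labels <- stats::setNames(sort(rep(seq_len(k_blocks), length.out = n)), ids)
  pairs <- utils::combn(n, 2L)
  same <- labels[pairs[1, ]] == labels[pairs[2, ]]
  keep <- with_seed(seed,
                    stats::runif(ncol(pairs)) < ifelse(same, p_in, p_out))
  net <- dataset_network(name, metaedge(type, relation, type),
                         data.frame(source = ids[pairs[1, keep]],
                                    target = ids[pairs[2, keep]],
                                    stringsAsFactors = FALSE),
                         source_universe = ids)
  list(network = net, labels = labels)
}

# Block-correlated bipartite layer: each left node links right nodes of its
# own block with p_in and others with p_out.
#' @keywords internal
#' @noRd
block_bipartite <- function(left_ids, left_blocks, right_ids, right_blocks,
                            p_in, p_out, metaedge, name, seed) {
  grid <- expand.grid(i = seq_along(left_ids), j = seq_along(right_ids))
  same <- left_blocks[grid$i] == right_blocks[grid$j]
  keep <- with_seed(seed, stats::runif(nrow(grid)) < ifelse(same, p_in, p_out))
  dataset_network(name, metaedge,
                  data.frame(source = left_ids[grid$i[keep]],
                             target = right_ids[grid$j[keep]],
                             stringsAsFactors = FALSE),
                  source_universe = left_ids, target_universe = right_ids)
}

#' Synthetic knowledge graph with shared block structure
#'
#' Builds a small knowledge graph (genes, diseases, compounds, pathways)
#' whose layers all share one planted block structure: a homogeneous
#' `GEN-ppi-GEN` stochastic block model plus block-correlated bipartite
#' layers `DIS-ass-GEN`, `CPD-int-GEN` and `PWY-ass-GEN`. Because the
#' blocks are shared, multi-step metapaths (e.g. `DIS-ass-GEN-ass-DIS`)
#' carry signal: same-block endpoints accumulate more degree-weighted paths
#' than cross-block ones.
#'
#' @param fixture a [fixture_spec()].
#' @return List with `kg` (a knowledge graph ([assemble_graph()])) and `labels` (named list
#'   of block labels per metanode).
#' @export
synthetic_kg <- function(fixture = fixture_spec()) {
  stopifnot(inherits(fixture, "fixture_spec"))
  sz <- fixture$sizes
  blocks_of <- function(n) sort(rep(seq_len(fixture$n_blocks), length.out = n))
  mk_ids <- function(type, n) sprintf("%s%04d", tolower(type), seq_len(n))

  gen_ids <- mk_ids("GEN", sz[["GEN"]]); gen_b <- blocks_of(sz[["GEN"]])
  pp <- planted_partition_network(sz[["GEN"]], fixture$n_blocks,
                                  fixture$p_in, fixture$p_out,
                                  seed = fixture$seed + 1L,
                                  type = "GEN", relation = "ppi",
                                  name = "sbm_ppi")
  datasets <- list(pp$network)
  labels <- list(GEN = pp$labels)

  layer <- function(type, relation, n, seed_off) {
    ids <- mk_ids(type, n); b <- blocks_of(n)
    ds <- block_bipartite(ids, b, gen_ids, gen_b, fixture$p_in, fixture$p_out,
                          metaedge(type, relation, "GEN"),
                          paste0("block_", tolower(type), "_", relation),
                          fixture$seed + seed_off)
    labels[[type]] <<- stats::setNames(b, ids)
    ds
  }
  if ("DIS" %in% names(sz)) datasets <- c(datasets, list(layer("DIS", "ass", sz[["DIS"]], 2L)))
  if ("CPD" %in% names(sz)) datasets <- c(datasets, list(layer("CPD", "int", sz[["CPD"]], 3L)))
  if ("PWY" %in% names(sz)) datasets <- c(datasets, list(layer("PWY", "ass", sz[["PWY"]], 4L)))

  list(kg = assemble_graph(datasets, default_metagraph()), labels = labels)
}

#' Synthetic expression matrix with correlated sample groups
#'
#' Log-normal baseline expression (per-gene log2 mean ~ N(8, 1.5), sample
#' noise ~ N(0, 0.5)) with group-specific shifts: each sample group has a
#' disjoint set of up- and down-marker genes (2% of genes each) shifted by
#' `effect` log2 units in that group's samples. Returned on the raw
#' (anti-logged, strictly positive) scale so the standard binarization
#' pipeline applies.
#'
#' @param n_genes,n_samples matrix dimensions.
#' @param n_groups sample groups.
#' @param effect log2 shift of marker genes (0 = no signal).
#' @param seed RNG seed.
#' @param marker_frac fraction of genes per group per direction.
#' @return List: `values` (genes x samples), `groups` (named sample groups),
#'   `markers` (per group, `up` and `down` gene ids).
#' @export
synthetic_expression <- function(n_genes = 2000L, n_samples = 40L,
                                 n_groups = 4L, effect = 2, seed = 0L,
                                 marker_frac = 0.02) {
  genes <- sprintf("g%05d", seq_len(n_genes))
  samples <- sprintf("s%03d", seq_len(n_samples))
  groups <- stats::setNames(rep(seq_len(n_groups), length.out = n_samples), samples)
  n_mark <- max(1L, round_half_up(marker_frac * n_genes))
  with_seed(seed, {
    mu <- stats::rnorm(n_genes, mean = 8, sd = 1.5)
    lg <- matrix(stats::rnorm(n_genes * n_samples, sd = 0.5), n_genes, n_samples) + mu
    dimnames(lg) <- list(genes, samples)
    pool <- sample(genes, 2L * n_mark * n_groups)
    markers <- vector("list", n_groups)
    for (g in seq_len(n_groups)) {
      up <- pool[((g - 1L) * 2L * n_mark) + seq_len(n_mark)]
      dn <- pool[((g - 1L) * 2L * n_mark) + n_mark + seq_len(n_mark)]
      cols <- names(groups)[groups == g]
      lg[up, cols] <- lg[up, cols] + effect
      lg[dn, cols] <- lg[dn, cols] - effect
      markers[[g]] <- list(up = sort(up), down = sort(dn))
    }
    list(values = 2^lg, groups = groups, markers = markers)
  })
}

#' Synthetic per-drug response profiles with a sensitive tail
#'
#' For each drug, each cell line is sensitive with probability `sens_frac`
#' (AUC ~ N(0.3, 0.05)) and resistant otherwise (AUC ~ N(0.92, 0.03));
#' values are clipped to `[0, 1]`. The planted sensitive sets are returned so
#' recovery by the waterfall binarization can be scored.
#'
#' @param n_drugs,n_cells profile counts.
#' @param sens_frac sensitive probability per (drug, cell).
#' @param seed RNG seed.
#' @param sens_mean,sens_sd,res_mean,res_sd AUC distribution parameters.
#' @return List of per-drug profiles, each `auc` (named vector) and
#'   `sensitive` (planted sensitive cell ids).
#' @export
synthetic_drug_response <- function(n_drugs = 50L, n_cells = 500L,
                                    sens_frac = 0.05, seed = 0L,
                                    sens_mean = 0.3, sens_sd = 0.05,
                                    res_mean = 0.92, res_sd = 0.03) {
  cells <- sprintf("cl%04d", seq_len(n_cells))
  with_seed(seed, {
    lapply(seq_len(n_drugs), function(d) {
      sens <- stats::runif(n_cells) < sens_frac
      auc <- ifelse(sens, stats::rnorm(n_cells, sens_mean, sens_sd),
                    stats::rnorm(n_cells, res_mean, res_sd))
      auc <- pmin(pmax(auc, 0), 1)
      names(auc) <- cells
      list(drug = sprintf("d%03d", d), auc = auc,
           sensitive = cells[sens])
    })
  })
}
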