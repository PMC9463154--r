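#' Configuration for dataset standardization
#'
#' Holds the cutoffs used when converting continuous source data into binary
#' networks and when harmonizing vocabularies.
#'
#' @param top_k_genes genes kept per sample and direction when binarizing
#'   expression-like matrices (default 250).
#' @param waterfall_min_frac,waterfall_max_frac bounds on the fraction of
#'   cell lines a drug may call sensitive (defaults 0.01 and 0.20).
#' @param waterfall_auc_cut sensitive cells must additionally have
#'   AUC below this value (default 0.9).
#' @param waterfall_elbow_tol relative tolerance used to resolve near-tied
#'   chord distances when locating the waterfall elbow (default 0.02).
#' @param tfidf_cosine_cut minimum TF-IDF cosine similarity for a
#'   cross-reference mapping (default 0.5).
#' @param pathway_overlap_cut overlap coefficient at which pathways merge
#'   into a SuperPath (default 0.9).
#' @param pathway_min_genes pathways below this size are excluded from
#'   clustering (default 20).
#' @param pathway_jaccard_cut Jaccard similarity between SuperPath gene sets
#'   that yields a similarity edge (default 0.7).
#' @param ic_prune_quantile quantile of the information-content distribution
#'   below which ontology terms are pruned as uninformative (default 0.05).
#' @return A list of class `standardize_config`.
#' @export
standardize_config <- function(top_k_genes = 250L,
                               waterfall_min_frac = 0.01,
                               waterfall_max_frac = 0.20,
                               waterfall_auc_cut = 0.9,
                               waterfall_elbow_tol = 0.02,
                               tfidf_cosine_cut = 0.5,
                               pathway_overlap_cut = 0.9,
                               pathway_min_genes = 20L,
                               pathway_jaccard_cut = 0.7,
                               ic_prune_quantile = 0.05) {
  assert_scalar_number(waterfall_min_frac, "waterfall_min_frac", 0, 1)
  assert_scalar_number(waterfall_max_frac, "waterfall_max_frac", 0, 1)
  if (waterfall_min_frac > waterfall_max_frac)
    stop("waterfall_min_frac must not exceed waterfall_max_frac", call. = FALSE)
  structure(list(top_k_genes = as.integer(top_k_genes),
                 waterfall_min_frac = waterfall_min_frac,
                 waterfall_max_frac = waterfall_max_frac,
                 waterfall_auc_cut = waterfall_auc_cut,
                 waterfall_elbow_tol = waterfall_elbow_tol,
                 tfidf_cosine_cut = tfidf_cosine_cut,
                 pathway_overlap_cut = pathway_overlap_cut,
                 pathway_min_genes = as.integer(pathway_min_genes),
                 pathway_jaccard_cut = pathway_jaccard_cut,
                 ic_prune_quantile = ic_prune_quantile),
            class = "standardize_config")
}

# Collapse duplicated row/column names by their mean value.
#' @keywords internal
#' @noRd
collapse_duplicates <- function(m) {
  if (anyDuplicated(rownames(m))) {
    grp <- rownames(m)
    m <- rowsum(m, grp) / as.vector(table(grp)[sort(unique(grp))])
    # rowsum sorts groups; counts aligned via sorted unique names
  }
  if (anyDuplicated(colnames(m))) {
    m <- t(collapse_duplicates(t(m)))
  }
  m
}

#' Binarize an expression-like matrix into up/down gene signatures
#'
#' Implements the signature-extraction pipeline for transcriptomics or
#' proteomics matrices: duplicates are collapsed by their mean, values are
#' log2-transformed (unless already on log scale), samples are
#' quantile-normalized so that every sample shares one value distribution,
#' each gene is robust-scaled (median subtracted, divided by its
#' inter-quartile range), and finally the `top_k_genes` most positive and
#' most negative genes of each sample become its up- and downregulated
#' signature edges.
#'
#' @param values genes x samples numeric matrix with row and column names.
#'   Values must be strictly positive before log2; otherwise they are
#'   shifted by `1 - min` (recorded in the output metadata).
#' @param cfg a [standardize_config()].
#' @param log_transform set `FALSE` when the data are already log-scaled.
#' @param sample_type,gene_type metanode abbreviations for the two sides
#'   (defaults `"CLL"` and `"GEN"`).
#' @param dataset name stem for the two output networks.
#' @return List with `upregulated` and `downregulated` [dataset_network()]s
#'   (relations `upr`/`dwr`), the robust-`scaled` matrix, the
#'   quantile-`normalized` matrix, and `meta` (applied shift, zero-IQR
#'   genes).
#' @export
binarize_expression <- function(values, cfg = standardize_config(),
                                log_transform = TRUE,
                                sample_type = "CLL", gene_type = "GEN",
                                dataset = "expression") {
  m <- as.matrix(values)
  if (!is.numeric(m)) stop("`values` must be numeric", call. = FALSE)
  if (anyNA(m)) stop("`values` contains missing values; impute first", call. = FALSE)
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("`values` needs gene rownames and sample colnames", call. = FALSE)
  m <- collapse_duplicates(m)
  k <- cfg$top_k_genes
  if (nrow(m) < 2L * k)
    stop(sprintf("need at least %d genes for non-overlapping top-%d signatures, got %d",
                 2L * k, k, nrow(m)), call. = FALSE)

  shift <- 0
  if (log_transform) {
    mn <- min(m)
    if (mn <= 0) {
      shift <- 1 - mn
      m <- m + shift
    }
    m <- log2(m)
  }
  m <- limma::normalizeQuantiles(m, ties = TRUE)
  qn <- m

  med <- apply(m, 1L, stats::median)
  iqr <- apply(m, 1L, stats::IQR)
  zero_iqr <- iqr == 0
  if (any(zero_iqr)) {
    warning(sprintf("%d gene(s) with zero IQR scaled by 1", sum(zero_iqr)),
            call. = FALSE)
    iqr[zero_iqr] <- 1
  }
  z <- (m - med) / iqr

  genes <- rownames(z)
  pick <- function(col, decreasing) {
    o <- if (decreasing) order(-col, xtfrm(genes)) else order(col, xtfrm(genes))
    genes[o[seq_len(k)]]
  }
  upr <- lapply(seq_len(ncol(z)), function(j) pick(z[, j], TRUE))
  dwr <- lapply(seq_len(ncol(z)), function(j) pick(z[, j], FALSE))
  samples <- colnames(z)
  mk <- function(rel, sets) {
    dataset_network(paste(dataset, rel, sep = "_"),
                    metaedge(sample_type, rel, gene_type),
                    data.frame(source = rep(samples, each = k),
                               target = unlist(sets), stringsAsFactors = FALSE),
                    source_universe = samples, target_universe = genes)
  }
  list(upregulated = mk("upr", upr), downregulated = mk("dwr", dwr),
       scaled = z, normalized = qn,
       meta = list(shift = shift, log_transform = log_transform,
                   zero_iqr_genes = genes[zero_iqr]))
}

#' Waterfall binarization of a drug-response profile
#'
#' Ranks cell lines by ascending response AUC (area under the growth
#' inhibition curve; low AUC = sensitive) and places the sensitivity
#' threshold at the elbow of the ranked curve, located by exhaustive scan
#' of the perpendicular distances to the chord joining the curve's
#' endpoints: on the usual concave profile the elbow is the corner where
#' the resistant plateau leaves the chord and the cells ranked before it
#' are called sensitive. The
#' sensitive call count is then clipped to `[waterfall_min_frac,
#' waterfall_max_frac]` of the lines and calls with AUC at or above
#' `waterfall_auc_cut` are discarded, so the result may be empty.
#'
#' @param auc named numeric vector of per-cell-line AUC values in `[0, 1]`.
#' @param cfg a [standardize_config()].
#' @return Character vector of sensitive cell ids (possibly empty), with
#'   attribute `elbow` (the pre-clipping cut index).
#' @export
waterfall_binarize <- function(auc, cfg = standardize_config()) {
  if (is.null(names(auc))) names(auc) <- as.character(seq_along(auc))
  auc <- auc[is.finite(auc)]
  n <- length(auc)
  if (n < 10L) stop("need at least 10 cell lines with finite AUC", call. = FALSE)
  if (any(auc < 0 | auc > 1)) stop("AUC values must lie in [0, 1]", call. = FALSE)
  o <- order(auc, xtfrm(names(auc)))
  y <- auc[o]
  x <- seq_len(n)
  # signed distance of (x_i, y_i) above the chord (1, y_1) -- (n, y_n).
  # On the usual concave curve (resistant plateau above the chord) the
  # elbow is the plateau corner: the earliest rank within `elbow_tol` of
  # the maximal distance (order statistics make the distances past the
  # corner near-ties); the sensitive set is the prefix before it. On a
  # convex curve the knee lies below the chord and is itself included.
  dx <- n - 1; dy <- y[n] - y[1]
  d_above <- (dx * (y - y[1]) - dy * (x - 1)) / sqrt(dx^2 + dy^2)
  tol <- cfg$waterfall_elbow_tol
  if (max(d_above) >= max(-d_above)) {
    e <- which(d_above >= max(d_above) * (1 - tol))[1]
    elbow <- e
    k <- e - 1L
  } else {
    e <- which(-d_above >= max(-d_above) * (1 - tol))[1]
    elbow <- e
    k <- e
  }
  k_min <- ceiling(cfg$waterfall_min_frac * n)
  k_max <- floor(cfg$waterfall_max_frac * n)
  k <- min(max(k, k_min), k_max)
  sens <- names(y)[seq_len(k)]
  sens <- sens[y[seq_len(k)] < cfg$waterfall_auc_cut]
  structure(sens, elbow = elbow)
}

#' Reify perturbation experiments as perturbagen (PGN) nodes
#'
#' Splits two-step perturbation records ("perturbing gene A yields outcome
#' X") into a perturbagen node per experiment, an edge to the perturbed gene
#' typed by the perturbation kind (knockdown-like kinds give `PGN-pdw-GEN`,
#' overexpression-like kinds give `PGN-pup-GEN`), and an edge to the
#' observed outcome.
#'
#' @param records data.frame with columns `perturbation_id`,
#'   `perturbation_kind`, `perturbed_gene`, `outcome_relation`,
#'   `outcome_node` and optionally `outcome_type` (default `"GEN"`).
#'   Recognized kinds: `shRNA`, `siRNA`, `CRISPR`, `knockdown`, `knockout`,
#'   `silencing` (down); `overexpression`, `activation`, `cDNA` (up); a kind
#'   such as `"shRNA-silence"` matches by its prefix.
#' @param dataset name stem for the emitted networks.
#' @return List of [dataset_network()]s: `gene_down` (`PGN-pdw-GEN`),
#'   `gene_up` (`PGN-pup-GEN`, either may be absent), and one
#'   `outcome_<rel>_<type>` network per outcome metaedge.
#' @export
reify_perturbagens <- function(records, dataset = "perturbation") {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  need <- c("perturbation_id", "perturbation_kind", "perturbed_gene",
            "outcome_relation", "outcome_node")
  if (!all(need %in% names(records)))
    stop("`records` must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  if (!"outcome_type" %in% names(records)) records$outcome_type <- "GEN"
  per <- unique(records[c("perturbation_id", "perturbation_kind", "perturbed_gene")])
  if (anyDuplicated(per$perturbation_id))
    stop("a perturbation_id maps to more than one kind/gene", call. = FALSE)

  down_kinds <- c("shrna", "sirna", "crispr", "knockdown", "knockout", "silencing")
  up_kinds <- c("overexpression", "activation", "cdna")
  kind_dir <- function(kind) {
    k <- tolower(kind)
    if (any(startsWith(k, down_kinds) | vapply(down_kinds, startsWith, TRUE, x = k)))
      return("pdw")
    if (any(startsWith(k, up_kinds) | vapply(up_kinds, startsWith, TRUE, x = k)))
      return("pup")
    stop(sprintf("unknown perturbation kind '%s'", kind), call. = FALSE)
  }
  dir <- vapply(per$perturbation_kind, kind_dir, character(1))

  out <- list()
  pgn_uni <- sort(unique(per$perturbation_id))
  for (d in c("pdw", "pup")) {
    sel <- dir == d
    if (!any(sel)) next
    nm <- if (d == "pdw") "gene_down" else "gene_up"
    out[[nm]] <- dataset_network(
      paste(dataset, d, sep = "_"), metaedge("PGN", d, "GEN"),
      data.frame(source = per$perturbation_id[sel],
                 target = per$perturbed_gene[sel], stringsAsFactors = FALSE),
      source_universe = pgn_uni)
  }
  grp <- paste(records$outcome_relation, records$outcome_type, sep = "_")
  for (g in sort(unique(grp))) {
    sel <- grp == g
    rel <- records$outcome_relation[sel][1]
    typ <- records$outcome_type[sel][1]
    out[[paste0("outcome_", g)]] <- dataset_network(
      paste(dataset, g, sep = "_"), metaedge("PGN", rel, typ),
      data.frame(source = records$perturbation_id[sel],
                 target = records$outcome_node[sel], stringsAsFactors = FALSE),
      source_universe = pgn_uni)
  }
  out
}

#' Propagate term annotations to ancestor terms
#'
#' @param ont an [ontology()].
#' @param annotations named list term -> character vector of annotated
#'   entities.
#' @return Named list over all terms reachable from the annotated ones, each
#'   the union of the entities of the term and all its descendants.
#' @export
propagate_annotations <- function(ont, annotations) {
  stopifnot(inherits(ont, "ontology"))
  anc <- ontology_ancestors(ont, names(annotations))
  out <- new.env(parent = emptyenv())
  for (t in names(annotations)) {
    for (a in c(t, anc[[t]])) {
      out[[a]] <- c(out[[a]], annotations[[t]])
    }
  }
  res <- lapply(as.list(out), function(x) sort(unique(x)))
  res[order(names(res))]
}

#' Information content of ontology terms
#'
#' `IC(t) = -log2(|entities(t)| / n_corpus)` where `entities(t)` is the
#' propagated annotation set of `t` and `n_corpus` the number of distinct
#' annotated entities. A term annotated to the whole corpus (the root after
#' propagation) has IC 0; rarer terms have higher IC. Terms with no
#' propagated annotations are excluded (IC undefined).
#'
#' @param ont an [ontology()] (used to validate term membership; pass
#'   `NULL` to skip).
#' @param annotations named list term -> entities, already propagated to
#'   ancestors (see [propagate_annotations()]).
#' @return Named numeric vector of IC values in bits.
#' @export
information_content <- function(ont, annotations) {
  counts <- lengths(lapply(annotations, unique))
  counts <- counts[counts > 0]
  if (!length(counts)) stop("no annotated terms", call. = FALSE)
  n_corpus <- length(unique(unlist(annotations, use.names = FALSE)))
  ic <- -log2(counts / n_corpus)
  if (!is.null(ont)) ic <- ic[names(ic) %in% ont$terms]
  ic
}

#' Prune uninformative ontology terms
#'
#' Removes the least informative terms — those high up in the ontology whose
#' annotation sets are so broad that they attract connections while carrying
#' little meaning. Terms with IC below the cutoff are removed.
#'
#' @param ont an [ontology()] (or `NULL`).
#' @param ic_table named IC vector from [information_content()].
#' @param cfg a [standardize_config()]; the default cutoff is the
#'   `ic_prune_quantile` quantile of the IC distribution.
#' @param cutoff explicit IC cutoff overriding the quantile rule.
#' @return List with `kept` and `removed` term vectors and the `cutoff`
#'   used.
#' @export
prune_uninformative_terms <- function(ont, ic_table, cfg = standardize_config(),
                                      cutoff = NULL) {
  if (is.null(cutoff))
    cutoff <- unname(stats::quantile(ic_table, cfg$ic_prune_quantile, type = 7))
  removed <- names(ic_table)[ic_table < cutoff]
  kept <- setdiff(names(ic_table), removed)
  if (!length(kept)) stop("IC cutoff would remove every term", call. = FALSE)
  list(kept = kept, removed = removed, cutoff = cutoff)
}

# TF-IDF transform of a binary incidence matrix (rows = documents/terms,
# cols = features). Smoothed idf ln((1+N)/(1+df)) + 1, L2-normalized rows.
#' @keywords internal
#' @noRd
tfidf_transform <- function(m) {
  m <- as.matrix(m)
  n_doc <- nrow(m)
  df <- colSums(m > 0)
  idf <- log((1 + n_doc) / (1 + df)) + 1
  w <- sweep(m, 2L, idf, `*`)
  l2_normalize_rows(w)
}

#' Map terms across vocabularies by TF-IDF cosine similarity
#'
#' Encodes each term of two vocabularies as a binary vector over their
#' shared cross-reference universe, reweights with TF-IDF (smoothed idf
#' `ln((1+N)/(1+df)) + 1`, L2-normalized rows) and keeps term pairs whose
#' cosine similarity reaches `tfidf_cosine_cut`.
#'
#' @param source_terms,target_terms named lists: term -> character vector of
#'   cross-references.
#' @param cfg a [standardize_config()].
#' @return data.frame `source, target, cosine` sorted by decreasing
#'   similarity (ties by ids); attribute `best` holds the single best match
#'   per source term.
#' @export
tfidf_crossref_map <- function(source_terms, target_terms,
                               cfg = standardize_config()) {
  su <- unique(unlist(source_terms, use.names = FALSE))
  tu <- unique(unlist(target_terms, use.names = FALSE))
  if (!length(intersect(su, tu)))
    stop("source and target vocabularies share no cross-references", call. = FALSE)
  universe <- sort(unique(c(su, tu)))
  inc <- function(sets) {
    m <- matrix(0, nrow = length(sets), ncol = length(universe),
                dimnames = list(names(sets), universe))
    for (i in seq_along(sets)) m[i, match(unique(sets[[i]]), universe)] <- 1
    m
  }
  m <- rbind(inc(source_terms), inc(target_terms))
  w <- tfidf_transform(m)
  ns <- length(source_terms)
  sim <- tcrossprod(w[seq_len(ns), , drop = FALSE],
                    w[-seq_len(ns), , drop = FALSE])
  idx <- which(sim >= cfg$tfidf_cosine_cut, arr.ind = TRUE)
  out <- data.frame(source = rownames(sim)[idx[, 1]],
                    target = colnames(sim)[idx[, 2]],
                    cosine = sim[idx], stringsAsFactors = FALSE)
  out <- out[order(-out$cosine, xtfrm(out$source), xtfrm(out$target)), ]
  rownames(out) <- NULL
  best <- out[!duplicated(out$source), ]
  rownames(best) <- NULL
  attr(out, "best") <- best
  out
}

#' @keywords internal
#' @noRd
overlap_coefficient <- function(a, b) length(intersect(a, b)) / min(length(a), length(b))

#' @keywords internal
#' @noRd
jaccard_index <- function(a, b) length(intersect(a, b)) / length(union(a, b))

#' Cluster pathways into SuperPaths and derive pathway similarity
#'
#' Pathways smaller than `pathway_min_genes` are excluded. Remaining
#' pathways are greedily agglomerated: while any two clusters have a gene-set
#' overlap coefficient of at least `pathway_overlap_cut`, the most
#' overlapping pair (ties by id) is merged into one SuperPath whose gene set
#' is the union. Pathway pairs whose SuperPath gene sets reach a Jaccard
#' similarity of `pathway_jaccard_cut` become similarity edges.
#'
#' @param pathway_gene_sets named list pathway id -> character gene vector.
#' @param cfg a [standardize_config()].
#' @return List: `superpaths` (named list of gene sets, named by their
#'   member pathway ids joined with `"+"`), `membership` (data.frame
#'   pathway/superpath), `similarity_edges` (data.frame a/b/jaccard) and
#'   `excluded` (too-small pathways).
#' @export
cluster_pathways <- function(pathway_gene_sets, cfg = standardize_config()) {
  sets <- lapply(pathway_gene_sets, unique)
  small <- names(sets)[lengths(sets) < cfg$pathway_min_genes]
  sets <- sets[!names(sets) %in% small]
  clusters <- lapply(names(sets), function(p) list(members = p, genes = sets[[p]]))
  repeat {
    n <- length(clusters)
    if (n < 2L) break
    best <- NULL; best_ov <- -Inf
    for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
      ov <- overlap_coefficient(clusters[[i]]$genes, clusters[[j]]$genes)
      if (ov > best_ov + 1e-12) { best_ov <- ov; best <- c(i, j) }
    }
    if (is.null(best) || best_ov < cfg$pathway_overlap_cut) break
    i <- best[1]; j <- best[2]
    clusters[[i]] <- list(members = sort(c(clusters[[i]]$members, clusters[[j]]$members)),
                          genes = union(clusters[[i]]$genes, clusters[[j]]$genes))
    clusters[[j]] <- NULL
  }
  sp_names <- vapply(clusters, function(cl) paste(cl$members, collapse = "+"), character(1))
  superpaths <- lapply(clusters, function(cl) sort(cl$genes))
  names(superpaths) <- sp_names
  membership <- do.call(rbind, lapply(seq_along(clusters), function(i)
    data.frame(pathway = clusters[[i]]$members, superpath = sp_names[i],
               stringsAsFactors = FALSE)))
  if (is.null(membership))
    membership <- data.frame(pathway = character(0), superpath = character(0))
  # pathway-pair similarity: Jaccard between the gene sets of the
  # SuperPaths the two pathways belong to
  edges <- list()
  pw <- membership$pathway
  sp_of <- stats::setNames(membership$superpath, pw)
  if (length(pw) >= 2L) for (i in seq_len(length(pw) - 1L)) for (j in seq(i + 1L, length(pw))) {
    jc <- jaccard_index(superpaths[[sp_of[pw[i]]]], superpaths[[sp_of[pw[j]]]])
    if (jc >= cfg$pathway_jaccard_cut)
      edges[[length(edges) + 1L]] <- data.frame(a = min(pw[i], pw[j]),
                                                b = max(pw[i], pw[j]),
                                                jaccard = jc, stringsAsFactors = FALSE)
  }
  edges <- if (length(edges)) do.call(rbind, edges)
           else data.frame(a = character(0), b = character(0), jaccard = numeric(0))
  list(superpaths = superpaths, membership = membership,
       similarity_edges = edges, excluded = small)
}
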