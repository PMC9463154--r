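#' Create a binary dataset network bound to one metaedge
#'
#' A dataset network is one named source of binary associations mapped to
#' exactly one metaedge. Edges are unweighted: confidence scores from the
#' original sources are deliberately not carried into the graph. Edges whose
#' endpoints fall outside the declared node universes are dropped (with a
#' warning and a recorded drop rate). Self-loops are dropped unless the
#' metaedge is homogeneous and `allow_self_loops = TRUE`. Duplicate edges
#' (including reversed duplicates on undirected homogeneous metaedges) are
#' deduplicated.
#'
#' @param name dataset identifier.
#' @param metaedge a [metaedge()].
#' @param edges two-column data.frame (source id, target id) or matrix;
#'   ids are opaque strings.
#' @param source_universe,target_universe optional character vectors of
#'   admissible ids per side; default is the set of ids observed in `edges`.
#'   For homogeneous metaedges the two universes are merged.
#' @param allow_self_loops allow `x -> x` edges on homogeneous metaedges.
#' @return An object of class `dataset_network`.
#' @examples
#' dn <- dataset_network("toy_ppi", metaedge("GEN", "ppi", "GEN"),
#'                       data.frame(a = c("g1", "g2"), b = c("g2", "g3")))
#' dn
#' @export
dataset_network <- function(name, metaedge, edges,
                            source_universe = NULL, target_universe = NULL,
                            allow_self_loops = FALSE) {
  stopifnot(is.character(name), length(name) == 1L, inherits(metaedge, "metaedge"))
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (ncol(edges) < 2L) stop("`edges` needs two columns (source, target)", call. = FALSE)
  src <- as.character(edges[[1]]); tgt <- as.character(edges[[2]])
  keep <- !is.na(src) & !is.na(tgt) & nzchar(src) & nzchar(tgt)
  src <- src[keep]; tgt <- tgt[keep]
  homogeneous <- metaedge$source == metaedge$target

  if (homogeneous) {
    uni <- sort(unique(c(source_universe, target_universe,
                         if (is.null(source_universe) && is.null(target_universe)) c(src, tgt))))
    source_universe <- target_universe <- uni
  } else {
    source_universe <- sort(unique(source_universe %||% src))
    target_universe <- sort(unique(target_universe %||% tgt))
  }

  n_in <- length(src)
  ok <- src %in% source_universe & tgt %in% target_universe
  if (any(!ok)) {
    warning(sprintf("dataset '%s': dropped %d/%d edges outside the node universes",
                    name, sum(!ok), n_in), call. = FALSE)
  }
  src <- src[ok]; tgt <- tgt[ok]
  n_outside <- n_in - length(src)

  loops <- src == tgt
  n_loops <- 0L
  if (any(loops) && !(homogeneous && allow_self_loops)) {
    n_loops <- sum(loops)
    src <- src[!loops]; tgt <- tgt[!loops]
  }

  if (homogeneous && !metaedge$directed && length(src)) {
    a <- pmin(src, tgt); b <- pmax(src, tgt)
    src <- a; tgt <- b
  }
  key <- paste(src, tgt, sep = "\r")
  dup <- duplicated(key)
  src <- src[!dup]; tgt <- tgt[!dup]

  structure(
    list(name = name, metaedge = metaedge,
         edges = data.frame(source = src, target = tgt, stringsAsFactors = FALSE),
         source_universe = source_universe, target_universe = target_universe,
         homogeneous = homogeneous,
         dropped = c(outside_universe = n_outside, self_loops = n_loops,
                     duplicates = sum(dup))),
    class = "dataset_network"
  )
}

#' @export
print.dataset_network <- function(x, ...) {
  cat(sprintf("<dataset_network> '%s' [%s]: %d edges, %d x %d universe\n",
              x$name, metaedge_label(x$metaedge), nrow(x$edges),
              length(x$source_universe), length(x$target_universe)))
  if (sum(x$dropped) > 0)
    cat("  dropped:", paste(names(x$dropped), x$dropped, collapse = ", "), "\n")
  invisible(x)
}

# Sparse binary adjacency of a dataset over its universes.
# orientation = "forward" keeps the stored direction (rows = source universe),
# "reverse" transposes. Undirected homogeneous adjacencies are symmetrized.
#' @keywords internal
#' @noRd
dataset_adjacency <- function(ds, orientation = c("forward", "reverse")) {
  orientation <- match.arg(orientation)
  ru <- ds$source_universe; cu <- ds$target_universe
  i <- match(ds$edges$source, ru); j <- match(ds$edges$target, cu)
  A <- Matrix::sparseMatrix(i = i, j = j, x = 1,
                            dims = c(length(ru), length(cu)),
                            dimnames = list(ru, cu))
  if (ds$homogeneous && !ds$metaedge$directed) {
    A <- methods::as(A + Matrix::t(A), "generalMatrix")  # avoid one-triangle storage
    A@x[] <- 1
  }
  A <- methods::as(A, "CsparseMatrix")
  if (orientation == "reverse") Matrix::t(A) else A
}

#' Assemble a validated knowledge graph
#'
#' Groups dataset networks under their metaedges after validating each
#' against the metagraph. Datasets are kept as individual sources (never
#' merged) so that any subset can later back a metapath.
#'
#' @param datasets list of [dataset_network()] objects.
#' @param metagraph a [metagraph()].
#' @return An object of class `knowledge_graph`.
#' @examples
#' mg <- metagraph("GEN", list(metaedge("GEN", "ppi", "GEN")))
#' dn <- dataset_network("toy", metaedge("GEN", "ppi", "GEN"),
#'                       data.frame(c("g1"), c("g2")))
#' assemble_graph(list(dn), mg)
#' @export
assemble_graph <- function(datasets, metagraph) {
  stopifnot(inherits(metagraph, "metagraph"))
  if (inherits(datasets, "dataset_network")) datasets <- list(datasets)
  out <- list()
  for (ds in datasets) {
    if (!inherits(ds, "dataset_network"))
      stop("`datasets` must contain dataset_network objects", call. = FALSE)
    lab <- metaedge_label(ds$metaedge)
    declared <- metagraph$metaedges[[lab]]
    if (is.null(declared))
      stop(sprintf("dataset '%s' is tagged with undeclared metaedge %s", ds$name, lab),
           call. = FALSE)
    if (!identical(declared$directed, ds$metaedge$directed))
      stop(sprintf("dataset '%s': directedness of %s disagrees with the metagraph",
                   ds$name, lab), call. = FALSE)
    if (ds$name %in% vapply(out[[lab]], `[[`, character(1), "name"))
      stop(sprintf("duplicate dataset name '%s' under %s", ds$name, lab), call. = FALSE)
    out[[lab]] <- c(out[[lab]], list(ds))
  }
  structure(list(metagraph = metagraph, datasets = out),
            class = "knowledge_graph")
}

#' @export
print.knowledge_graph <- function(x, ...) {
  nds <- sum(lengths(x$datasets))
  ne <- sum(vapply(unlist(x$datasets, recursive = FALSE),
                   function(d) nrow(d$edges), integer(1)))
  cat(sprintf("<knowledge_graph> %d datasets over %d metaedges (%d edges total)\n",
              nds, length(x$datasets), ne))
  for (lab in names(x$datasets)) {
    nm <- vapply(x$datasets[[lab]], `[[`, character(1), "name")
    cat(sprintf("  %s: %s\n", lab, paste(nm, collapse = ", ")))
  }
  invisible(x)
}

# Retrieve datasets of a metaedge label, optionally a named subset.
#' @keywords internal
#' @noRd
kg_datasets <- function(kg, label, names = NULL) {
  dss <- kg$datasets[[label]]
  if (is.null(dss)) stop(sprintf("no datasets for metaedge %s", label), call. = FALSE)
  if (is.null(names)) return(dss)
  have <- vapply(dss, `[[`, character(1), "name")
  miss <- setdiff(names, have)
  if (length(miss))
    stop(sprintf("unknown dataset(s) for %s: %s", label, paste(miss, collapse = ", ")),
         call. = FALSE)
  dss[match(names, have)]
}

#' Create an ontology (term DAG)
#'
#' @param parents two-column data.frame (child, parent) of is-a /
#'   part-of style relations. Must be acyclic.
#' @return An object of class `ontology` with a `parents` mapping and the
#'   term universe.
#' @examples
#' ont <- ontology(data.frame(child = c("t2", "t3"), parent = c("t1", "t2")))
#' @export
ontology <- function(parents) {
  parents <- as.data.frame(parents, stringsAsFactors = FALSE)
  if (ncol(parents) < 2L) stop("`parents` needs two columns (child, parent)", call. = FALSE)
  child <- as.character(parents[[1]]); par <- as.character(parents[[2]])
  terms <- sort(unique(c(child, par)))
  g <- igraph::graph_from_data_frame(data.frame(child, par), directed = TRUE,
                                     vertices = terms)
  if (!igraph::is_dag(g)) stop("ontology contains a cycle", call. = FALSE)
  pmap <- split(par, child)
  structure(list(parents = pmap, terms = terms, graph = g), class = "ontology")
}

#' @export
print.ontology <- function(x, ...) {
  roots <- setdiff(x$terms, names(x$parents))
  cat(sprintf("<ontology> %d terms, %d parent links, %d root(s)\n",
              length(x$terms), length(unlist(x$parents)), length(roots)))
  invisible(x)
}

#' Ancestors of ontology terms
#'
#' Transitive closure over the parent relation (the term itself excluded).
#'
#' @param ont an [ontology()].
#' @param terms character vector; defaults to all terms.
#' @return Named list term -> character vector of ancestors.
#' @export
ontology_ancestors <- function(ont, terms = ont$terms) {
  stopifnot(inherits(ont, "ontology"))
  memo <- new.env(parent = emptyenv())
  anc <- function(t) {
    if (!is.null(memo[[t]])) return(memo[[t]])
    ps <- ont$parents[[t]]
    res <- if (is.null(ps)) character(0)
           else sort(unique(c(ps, unlist(lapply(ps, anc), use.names = FALSE))))
    memo[[t]] <- res
    res
  }
  out <- lapply(terms, function(t) if (t %in% ont$terms) anc(t) else character(0))
  names(out) <- terms
  out
}

#' Propagate annotations through an ontology
#'
#' Every edge `(x, term)` on the ontological side of a dataset also implies
#' `(x, ancestor)` for all ancestors of the term; this adds those edges.
#' The operation is idempotent and monotone (the output contains the input).
#'
#' @param ds a [dataset_network()] whose `side` endpoints are ontology terms.
#' @param ont an [ontology()] covering that side. Terms absent from the
#'   ontology are kept but not propagated.
#' @param side which side of the metaedge holds the terms.
#' @return A new `dataset_network` including the propagated edges. The side
#'   universe is extended with any newly reachable ancestor terms.
#' @export
propagate_ontology <- function(ds, ont, side = c("target", "source")) {
  stopifnot(inherits(ds, "dataset_network"), inherits(ont, "ontology"))
  side <- match.arg(side)
  ed <- ds$edges
  terms <- if (side == "target") ed$target else ed$source
  anc <- ontology_ancestors(ont, unique(terms))
  n_anc <- lengths(anc)[terms]
  other <- if (side == "target") ed$source else ed$target
  new_other <- rep(other, n_anc)
  new_terms <- unlist(anc[terms], use.names = FALSE)
  if (side == "target") {
    all_src <- c(ed$source, new_other); all_tgt <- c(ed$target, new_terms)
    tgt_uni <- sort(unique(c(ds$target_universe, new_terms)))
    src_uni <- ds$source_universe
  } else {
    all_src <- c(ed$source, new_terms); all_tgt <- c(ed$target, new_other)
    src_uni <- sort(unique(c(ds$source_universe, new_terms)))
    tgt_uni <- ds$target_universe
  }
  dataset_network(ds$name, ds$metaedge,
                  data.frame(source = all_src, target = all_tgt,
                             stringsAsFactors = FALSE),
                  source_universe = src_uni, target_universe = tgt_uni)
}
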