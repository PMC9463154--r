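#' Parse a metapath expression
#'
#' A metapath is an ordered chain of metaedges defining a semantic route
#' between a source and a target entity type, written e.g.
#' `"CPD-int-GEN-ass-DIS"`. Relation tokens may combine sibling relations
#' with `'+'` (e.g. `dwr+upr`, only between relations sharing both
#' endpoints) and directed homogeneous relations carry a `'_'` mark next to
#' the entity acting as the relation's source (`GEN-_pho-GEN-ass-PWY` routes
#' kinases to their substrates' pathways; `GEN-pho_-GEN-ass-PWY` routes
#' substrates to their kinases' pathways). Heterogeneous metaedges are
#' stored in one canonical direction but may be traversed either way.
#'
#' @param expr the metapath string.
#' @param kg a knowledge graph ([assemble_graph()]) or a bare [metagraph()]. With a knowledge
#'   graph, every step must be backed by at least one dataset unless
#'   `require_datasets = FALSE`.
#' @param datasets optional dataset bindings: a list with one character
#'   vector of dataset names per step (`NULL` elements bind all datasets of
#'   the step's metaedges).
#' @param require_datasets check that every step has at least one dataset.
#' @return An object of class `metapath`: steps with resolved metaedges,
#'   traversal orientations and dataset bindings, plus `source_type` /
#'   `target_type`.
#' @examples
#' mg <- default_metagraph()
#' parse_metapath("CPD-int-GEN-ass-DIS", mg)
#' parse_metapath("CLL-dwr+upr-GEN-dwr+upr-CLL", mg)
#' @export
parse_metapath <- function(expr, kg, datasets = NULL, require_datasets = TRUE) {
  mg <- if (inherits(kg, "knowledge_graph")) kg$metagraph else kg
  if (!inherits(mg, "metagraph"))
    stop("`kg` must be a knowledge_graph or metagraph", call. = FALSE)
  has_kg <- inherits(kg, "knowledge_graph")

  tokens <- strsplit(expr, "-", fixed = TRUE)[[1]]
  if (length(tokens) < 3L || length(tokens) %% 2L == 0L)
    stop(sprintf("malformed metapath expression: '%s'", expr), call. = FALSE)
  nodes <- tokens[seq(1L, length(tokens), by = 2L)]
  rels <- tokens[seq(2L, length(tokens), by = 2L)]
  if (!all(grepl("^[A-Z]{3}$", nodes)))
    stop("metanode tokens must be 3 uppercase letters", call. = FALSE)
  bad <- nodes[!nodes %in% mg$metanodes]
  if (length(bad))
    stop(sprintf("unknown metanode abbreviation(s): %s", paste(unique(bad), collapse = ", ")),
         call. = FALSE)
  if (!is.null(datasets) && length(datasets) != length(rels))
    stop("`datasets` must have one element per metapath step", call. = FALSE)

  steps <- vector("list", length(rels))
  for (s in seq_along(rels)) {
    left <- nodes[s]; right <- nodes[s + 1L]
    tok <- rels[s]
    if (!grepl("^_?[a-z]{3}(\\+[a-z]{3})*_?$", tok))
      stop(sprintf("malformed relation token '%s'", tok), call. = FALSE)
    pre <- startsWith(tok, "_"); post <- endsWith(tok, "_")
    if (pre && post) stop("at most one '_' direction mark per step", call. = FALSE)
    base <- gsub("_", "", tok, fixed = TRUE)
    parts <- strsplit(base, "+", fixed = TRUE)[[1]]
    if ((pre || post) && left != right)
      stop("'_' direction marks are only valid on homogeneous steps", call. = FALSE)

    mes <- vector("list", length(parts))
    flipped <- logical(length(parts))
    for (i in seq_along(parts)) {
      hit <- find_metaedge(mg, left, parts[i], right)
      if (is.null(hit))
        stop(sprintf("step %d: metaedge %s-%s-%s not declared in the metagraph",
                     s, left, parts[i], right), call. = FALSE)
      mes[[i]] <- hit$metaedge
      flipped[i] <- hit$flipped
    }
    dir <- vapply(mes, `[[`, logical(1), "directed")
    if (any(dir) && !all(dir))
      stop(sprintf("step %d: cannot '+'-combine directed and undirected relations", s),
           call. = FALSE)
    if ((pre || post) && !any(dir))
      stop(sprintf("step %d: '_' mark on an undirected relation", s), call. = FALSE)
    # along = TRUE: traverse the stored direction (left node is the source
    # of the relation). Unmarked directed steps default to along.
    along <- !post

    ds <- NULL
    if (!is.null(datasets)) ds <- datasets[[s]]
    if (has_kg) {
      avail <- unlist(lapply(mes, function(me) {
        vapply(kg$datasets[[metaedge_label(me)]] %||% list(),
               `[[`, character(1), "name")
      }))
      if (is.null(ds)) ds <- avail
      else {
        miss <- setdiff(ds, avail)
        if (length(miss))
          stop(sprintf("step %d: unknown dataset(s) %s", s, paste(miss, collapse = ", ")),
               call. = FALSE)
      }
      if (require_datasets && !length(ds))
        stop(sprintf("step %d (%s): no datasets available", s, tok), call. = FALSE)
    }
    steps[[s]] <- list(left = left, right = right, token = tok,
                       relations = parts, metaedges = mes, flipped = flipped,
                       directed = any(dir), along = along, datasets = ds)
  }
  structure(list(expr = expr, steps = steps,
                 source_type = nodes[1L], target_type = nodes[length(nodes)],
                 length = length(steps)),
            class = "metapath")
}

#' @export
print.metapath <- function(x, ...) {
  cat(sprintf("<metapath> %s (L%d, %s -> %s)\n", x$expr, x$length,
              x$source_type, x$target_type))
  for (s in seq_along(x$steps)) {
    st <- x$steps[[s]]
    ds <- if (length(st$datasets)) paste(st$datasets, collapse = ",") else "<unbound>"
    cat(sprintf("  %d. %s-%s-%s  datasets: %s\n", s, st$left, st$token, st$right, ds))
  }
  invisible(x)
}

#' Check a metapath against the composition grammar
#'
#' Advisory (non-fatal) checks of the metapath composition rules: similarity,
#' cross-reference, ontology and perturbagen relations are not embedded as
#' standalone length-1 metapaths; cell lines link to genes only through
#' `upr`/`dwr`/`mut`; cells and tissues connect through `has`; and genes
#' reached from a perturbagen (`PGN-pup/pdw-GEN`) continue only through
#' heterogeneous or directed homogeneous associations, never undirected
#' homogeneous ones.
#'
#' @param spec a [parse_metapath()] result.
#' @return Character vector of rule violations (empty when compliant).
#' @export
validate_metapath_rules <- function(spec) {
  stopifnot(inherits(spec, "metapath"))
  v <- character(0)
  steps <- spec$steps
  if (spec$length == 1L) {
    st <- steps[[1L]]
    if (any(st$relations == "sim"))
      v <- c(v, "L1: similarity relations are computed after the graph is populated, not embedded standalone")
    if (any(st$relations == "xrf"))
      v <- c(v, "L1: cross-reference relations are not embedded standalone")
    if (any(st$relations == "hsp"))
      v <- c(v, "L1: ontology (parent-child) relations are not embedded standalone")
    if (st$left == "PGN" || st$right == "PGN")
      v <- c(v, "L1: perturbagen associations are only used inside longer metapaths")
  }
  for (s in seq_along(steps)) {
    st <- steps[[s]]
    ends <- c(st$left, st$right)
    if (setequal(ends, c("CLL", "GEN")) &&
        !all(st$relations %in% c("upr", "dwr", "mut")))
      v <- c(v, sprintf("step %d: cells and genes may only be linked through upr/dwr/mut", s))
    if (setequal(ends, c("CLL", "TIS")) && !all(st$relations == "has"))
      v <- c(v, sprintf("step %d: cells and tissues must be connected through CLL-has-TIS", s))
  }
  # genes reached from PGN-pup/pdw-GEN must continue through heterogeneous
  # or directed homogeneous steps
  for (s in seq_along(steps)) {
    st <- steps[[s]]
    if (!any(st$relations %in% c("pup", "pdw"))) next
    nxt <- NULL
    if (st$left == "PGN" && st$right == "GEN" && s < length(steps)) nxt <- steps[[s + 1L]]
    if (st$right == "PGN" && st$left == "GEN" && s > 1L) nxt <- steps[[s - 1L]]
    if (!is.null(nxt) && nxt$left == "GEN" && nxt$right == "GEN" && !nxt$directed)
      v <- c(v, "genes perturbed by a PGN may not continue through undirected homogeneous gene associations")
  }
  v
}
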