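#' Define a typed relation (metaedge) between two entity types
#'
#' A metaedge is a typed relation in the knowledge-graph schema, written
#' `SRC-rel-TGT` with 3-letter uppercase entity-type abbreviations (metanodes)
#' and a 3-letter lowercase relation tag, e.g. `GEN-ppi-GEN` for
#' protein-protein interactions or `CLL-has-TIS` linking cell lines to their
#' tissue of origin. Heterogeneous metaedges are stored in one canonical
#' direction but may be traversed either way inside a metapath. A metaedge is
#' directed only when it is homogeneous and has a single valid directionality
#' (e.g. `GEN-pho-GEN`, kinase phosphorylates substrate).
#'
#' @param source,target 3-letter uppercase metanode abbreviations.
#' @param relation 3-letter lowercase relation tag.
#' @param directed logical; only allowed for homogeneous metaedges.
#' @return An object of class `metaedge`.
#' @examples
#' metaedge("GEN", "ppi", "GEN")
#' metaedge("GEN", "pho", "GEN", directed = TRUE)
#' @export
metaedge <- function(source, relation, target, directed = FALSE) {
  for (x in list(source = source, target = target)) {
    if (!is.character(x) || length(x) != 1L || !grepl("^[A-Z]{3}$", x))
      stop("metanode abbreviations must be 3 uppercase letters", call. = FALSE)
  }
  if (!is.character(relation) || length(relation) != 1L || !grepl("^[a-z]{3}$", relation))
    stop("relation tags must be 3 lowercase letters", call. = FALSE)
  if (isTRUE(directed) && source != target)
    stop("directed metaedges must be homogeneous (source_type == target_type)",
         call. = FALSE)
  structure(
    list(source = source, relation = relation, target = target,
         directed = isTRUE(directed)),
    class = "metaedge"
  )
}

#' @export
print.metaedge <- function(x, ...) {
  cat(sprintf("<metaedge> %s%s\n", metaedge_label(x),
              if (x$directed) " (directed)" else ""))
  invisible(x)
}

#' Canonical label of a metaedge
#'
#' @param x a `metaedge`.
#' @return `"SRC-rel-TGT"`.
#' @export
metaedge_label <- function(x) {
  stopifnot(inherits(x, "metaedge"))
  paste(x$source, x$relation, x$target, sep = "-")
}

#' Define a knowledge-graph schema (metagraph)
#'
#' The metagraph declares the entity types (metanodes) and typed relations
#' (metaedges) a knowledge graph may contain. Every dataset added to the
#' graph must be tagged with one declared metaedge.
#'
#' @param metanodes character vector of 3-letter uppercase abbreviations,
#'   optionally named by a human-readable entity-type name.
#' @param metaedges list of [metaedge()] objects.
#' @return An object of class `metagraph`.
#' @examples
#' mg <- metagraph(c(gene = "GEN", disease = "DIS"),
#'                 list(metaedge("GEN", "ppi", "GEN"),
#'                      metaedge("DIS", "ass", "GEN")))
#' mg
#' @export
metagraph <- function(metanodes, metaedges = list()) {
  if (!is.character(metanodes) || length(metanodes) == 0L)
    stop("`metanodes` must be a non-empty character vector", call. = FALSE)
  if (!all(grepl("^[A-Z]{3}$", metanodes)))
    stop("metanode abbreviations must be 3 uppercase letters", call. = FALSE)
  if (anyDuplicated(metanodes))
    stop("metanode abbreviations must be unique", call. = FALSE)
  if (inherits(metaedges, "metaedge")) metaedges <- list(metaedges)
  labels <- character(length(metaedges))
  for (i in seq_along(metaedges)) {
    me <- metaedges[[i]]
    if (!inherits(me, "metaedge")) stop("`metaedges` must be metaedge objects", call. = FALSE)
    if (!(me$source %in% metanodes) || !(me$target %in% metanodes))
      stop(sprintf("metaedge %s references undeclared metanodes", metaedge_label(me)),
           call. = FALSE)
    labels[i] <- metaedge_label(me)
  }
  if (anyDuplicated(labels)) stop("duplicate metaedge labels", call. = FALSE)
  names(metaedges) <- labels
  structure(list(metanodes = metanodes, metaedges = metaedges),
            class = "metagraph")
}

#' @export
print.metagraph <- function(x, ...) {
  cat(sprintf("<metagraph> %d metanodes, %d metaedges\n",
              length(x$metanodes), length(x$metaedges)))
  cat("  metanodes:", paste(unname(x$metanodes), collapse = " "), "\n")
  if (length(x$metaedges)) {
    dir <- vapply(x$metaedges, `[[`, logical(1), "directed")
    cat("  metaedges:", paste0(names(x$metaedges),
                               ifelse(dir, ">", ""), collapse = " "), "\n")
  }
  invisible(x)
}

# Find a metaedge in `mg` matching (left, rel, right) in either stored
# orientation. Returns list(metaedge, flipped) or NULL.
#' @keywords internal
#' @noRd
find_metaedge <- function(mg, left, rel, right) {
  lab <- paste(left, rel, right, sep = "-")
  if (!is.null(mg$metaedges[[lab]]))
    return(list(metaedge = mg$metaedges[[lab]], flipped = FALSE))
  rev_lab <- paste(right, rel, left, sep = "-")
  if (!is.null(mg$metaedges[[rev_lab]]))
    return(list(metaedge = mg$metaedges[[rev_lab]], flipped = TRUE))
  NULL
}

#' Parse a metaedge label
#'
#' Parses `"SRC-rel-TGT"` labels. For directed homogeneous relations an
#' underscore marks the entity acting as the source of the relation:
#' `GEN-_pho-GEN` reads "left genes are the kinases", `GEN-pho_-GEN` reads
#' "right genes are the kinases". The mark is a grammar error on
#' heterogeneous or undirected relations.
#'
#' @param label the label string.
#' @param metagraph optional [metagraph()]; when supplied the abbreviations
#'   and the relation must be declared in it, and directedness is taken from
#'   the schema.
#' @return A `metaedge` with attribute `source_side` (`"left"`, `"right"` or
#'   `NA` for undirected relations).
#' @examples
#' parse_metaedge_label("GEN-ppi-GEN")
#' parse_metaedge_label("GEN-_pho-GEN")
#' @export
parse_metaedge_label <- function(label, metagraph = NULL) {
  m <- regmatches(label,
                  regexec("^([A-Z]{3})-(_?)([a-z]{3})(_?)-([A-Z]{3})$", label))[[1]]
  if (length(m) == 0L)
    stop(sprintf("malformed metaedge label: '%s'", label), call. = FALSE)
  left <- m[2]; pre <- m[3]; rel <- m[4]; post <- m[5]; right <- m[6]
  if (nzchar(pre) && nzchar(post))
    stop("at most one '_' direction mark is allowed", call. = FALSE)
  marked <- nzchar(pre) || nzchar(post)
  if (marked && left != right)
    stop("'_' direction marks are only valid on homogeneous relations", call. = FALSE)
  if (!is.null(metagraph)) {
    if (!(left %in% metagraph$metanodes) || !(right %in% metagraph$metanodes))
      stop(sprintf("unknown metanode abbreviation in '%s'", label), call. = FALSE)
    hit <- find_metaedge(metagraph, left, rel, right)
    if (is.null(hit))
      stop(sprintf("metaedge '%s-%s-%s' not declared in metagraph", left, rel, right),
           call. = FALSE)
    me <- hit$metaedge
    if (marked && !me$directed)
      stop("'_' direction marks are only valid on directed relations", call. = FALSE)
  } else {
    me <- metaedge(left, rel, right, directed = marked)
  }
  attr(me, "source_side") <-
    if (!me$directed) NA_character_
    else if (nzchar(post)) "right"
    else "left"
  me
}

#' Render a metaedge back to its label
#'
#' Inverse of [parse_metaedge_label()]: includes the `'_'` direction mark for
#' directed relations according to the `source_side` attribute.
#'
#' @param spec a `metaedge` (optionally carrying a `source_side` attribute).
#' @return The label string.
#' @export
render_metaedge_label <- function(spec) {
  stopifnot(inherits(spec, "metaedge"))
  side <- attr(spec, "source_side") %||% NA_character_
  rel <- spec$relation
  if (spec$directed && !is.na(side))
    rel <- if (side == "right") paste0(rel, "_") else paste0("_", rel)
  paste(spec$source, rel, spec$target, sep = "-")
}

#' A ready-made biomedical metagraph
#'
#' A schema with the common biomedical entity types (genes/proteins GEN,
#' diseases DIS, compounds CPD, pathways PWY, cell lines CLL, tissues TIS,
#' perturbagens PGN, pharmacologic classes PHC, domains DOM, molecular
#' functions MFN, cellular components CMP, chemical entities CHE) and a set
#' of typical relations between them. Used by the synthetic fixtures and as
#' a starting point for user graphs.
#'
#' @return A [metagraph()].
#' @export
default_metagraph <- function() {
  mn <- c(gene = "GEN", disease = "DIS", compound = "CPD", pathway = "PWY",
          cell = "CLL", tissue = "TIS", perturbagen = "PGN",
          pharmacologic_class = "PHC", domain = "DOM",
          molecular_function = "MFN", cellular_component = "CMP",
          chemical_entity = "CHE")
  me <- list(
    metaedge("GEN", "ppi", "GEN"),
    metaedge("GEN", "cex", "GEN"),
    metaedge("GEN", "pho", "GEN", directed = TRUE),
    metaedge("GEN", "reg", "GEN", directed = TRUE),
    metaedge("CLL", "upr", "GEN"),
    metaedge("CLL", "dwr", "GEN"),
    metaedge("CLL", "mut", "GEN"),
    metaedge("CLL", "has", "TIS"),
    metaedge("CLL", "sns", "CPD"),
    metaedge("TIS", "upr", "GEN"),
    metaedge("TIS", "dwr", "GEN"),
    metaedge("CPD", "int", "GEN"),
    metaedge("CPD", "trt", "DIS"),
    metaedge("CPD", "cau", "DIS"),
    metaedge("CPD", "sim", "CPD"),
    metaedge("CPD", "has", "PHC"),
    metaedge("DIS", "ass", "GEN"),
    metaedge("DIS", "xrf", "DIS"),
    metaedge("PWY", "ass", "GEN"),
    metaedge("PWY", "hsp", "PWY"),
    metaedge("PGN", "pup", "GEN"),
    metaedge("PGN", "pdw", "GEN"),
    metaedge("PGN", "upr", "GEN"),
    metaedge("PGN", "dwr", "GEN"),
    metaedge("PGN", "bfn", "CLL"),
    metaedge("DOM", "has", "GEN"),
    metaedge("MFN", "has", "GEN"),
    metaedge("CMP", "has", "GEN"),
    metaedge("CHE", "has", "CPD")
  )
  metagraph(mn, me)
}
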