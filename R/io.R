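#' Read / write edge lists as TSV
#'
#' Edge lists are tab-separated `source<TAB>target` files with no header;
#' lines starting with `#` are ignored; files are UTF-8.
#'
#' @param path file path.
#' @return `read_edges`: data.frame `source`, `target`.
#' @export
read_edges <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                          colClasses = "character", quote = "",
                          col.names = c("source", "target"),
                          fileEncoding = "UTF-8")
  df
}

#' @rdname read_edges
#' @param edges a two-column data.frame or a [dataset_network()].
#' @export
write_edges <- function(edges, path) {
  if (inherits(edges, "dataset_network")) edges <- edges$edges
  utils::write.table(edges[, 1:2], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a knowledge graph to a directory
#'
#' Lays out one TSV edge list per dataset plus per-side node-universe
#' lists, the metagraph, and a YAML manifest tying files to metaedges and
#' dataset names. [read_kg()] restores the graph exactly (edge sets are
#' preserved through the round trip).
#'
#' @param kg a knowledge graph ([assemble_graph()]).
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_kg <- function(kg, dir) {
  stopifnot(inherits(kg, "knowledge_graph"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mg <- kg$metagraph
  me_df <- do.call(rbind, lapply(mg$metaedges, function(me)
    data.frame(source = me$source, relation = me$relation, target = me$target,
               directed = me$directed)))
  manifest <- list(metanodes = as.list(mg$metanodes),
                   metaedges = lapply(mg$metaedges, function(me)
                     list(source = me$source, relation = me$relation,
                          target = me$target, directed = me$directed)),
                   datasets = list())
  for (lab in names(kg$datasets)) for (ds in kg$datasets[[lab]]) {
    stem <- paste0(gsub("-", "_", lab), ".", ds$name)
    write_edges(ds, file.path(dir, paste0(stem, ".tsv")))
    writeLines(ds$source_universe, file.path(dir, paste0(stem, ".source_universe.txt")))
    writeLines(ds$target_universe, file.path(dir, paste0(stem, ".target_universe.txt")))
    manifest$datasets[[length(manifest$datasets) + 1L]] <-
      list(name = ds$name, metaedge = lab, file = paste0(stem, ".tsv"))
  }
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' @rdname write_kg
#' @export
read_kg <- function(dir) {
  manifest <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  mn <- unlist(manifest$metanodes)
  mes <- lapply(manifest$metaedges, function(m)
    metaedge(m$source, m$relation, m$target, directed = isTRUE(m$directed)))
  mg <- metagraph(mn, mes)
  datasets <- lapply(manifest$datasets, function(d) {
    ed <- read_edges(file.path(dir, d$file))
    stem <- sub("\\.tsv$", "", d$file)
    su <- readLines(file.path(dir, paste0(stem, ".source_universe.txt")))
    tu <- readLines(file.path(dir, paste0(stem, ".target_universe.txt")))
    me <- parse_metaedge_label(d$metaedge, mg)
    dataset_network(d$name, me, ed, source_universe = su, target_universe = tu)
  })
  assemble_graph(datasets, mg)
}

#' Build a knowledge graph from a YAML manifest
#'
#' The manifest lists the schema and the edge-list files:
#' ```yaml
#' metanodes: [GEN, DIS]
#' metaedges:
#'   - {source: GEN, relation: ppi, target: GEN}
#'   - {source: DIS, relation: ass, target: GEN}
#' datasets:
#'   - {name: my_ppi, metaedge: GEN-ppi-GEN, file: ppi.tsv}
#' ```
#' File paths are resolved relative to the manifest.
#'
#' @param path manifest path.
#' @return A knowledge graph ([assemble_graph()]).
#' @export
read_manifest <- function(path) {
  manifest <- yaml::read_yaml(path)
  base <- dirname(path)
  mn <- unlist(manifest$metanodes)
  mes <- lapply(manifest$metaedges, function(m)
    metaedge(m$source, m$relation, m$target, directed = isTRUE(m$directed)))
  mg <- metagraph(mn, mes)
  datasets <- lapply(manifest$datasets, function(d) {
    me <- parse_metaedge_label(d$metaedge, mg)
    ed <- read_edges(file.path(base, d$file))
    su <- if (!is.null(d$source_universe))
      readLines(file.path(base, d$source_universe)) else NULL
    tu <- if (!is.null(d$target_universe))
      readLines(file.path(base, d$target_universe)) else NULL
    dataset_network(d$name, me, ed, source_universe = su, target_universe = tu)
  })
  assemble_graph(datasets, mg)
}

#' Write a DWPC network as weighted TSV
#'
#' @param dw a `dwpc_matrix`.
#' @param path output TSV (`source<TAB>target<TAB>dwpc`).
#' @export
write_dwpc <- function(dw, path) {
  ne <- network_edges(dw)
  utils::write.table(ne$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = c("source", "target", "dwpc"))
  invisible(path)
}
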