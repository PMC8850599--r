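# miRNA-centric regulatory network: an undirected bipartite igraph with typed
# nodes (miRNA / gene), "targets" edges, common-target identification and
# Cytoscape-compatible SIF / GraphML export.

#' Build a miRNA-target regulatory network
#'
#' One node per requested miRNA, one per distinct target passing the score
#' gate, one undirected edge per retained interaction. Node ordering is
#' deterministic: miRNAs (sorted) then genes (sorted).
#'
#' @param mirna_gene_table data.frame `mirna_id`, `gene_id` and optionally
#'   `prediction_score`.
#' @param mirna_ids miRNAs to seed the network with; an id absent from the
#'   table is an error.
#' @param min_score Optional minimum prediction score (interactions with
#'   `prediction_score >= min_score` are kept; `NULL` keeps all).
#' @return An `igraph` object with vertex attributes `name` and `type`
#'   (`"miRNA"`/`"gene"`) and, when scores are present, edge attribute
#'   `score`.
#' @export
build_network <- function(mirna_gene_table, mirna_ids, min_score = NULL) {
  assert_that(all(c("mirna_id", "gene_id") %in% names(mirna_gene_table)),
              "table needs columns mirna_id, gene_id")
  mirna_ids <- unique(as.character(mirna_ids))
  unknown <- setdiff(mirna_ids, unique(mirna_gene_table$mirna_id))
  if (length(unknown)) {
    stop(sprintf("unknown miRNA id(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  edges <- mirna_gene_table[mirna_gene_table$mirna_id %in% mirna_ids, , drop = FALSE]
  has_score <- "prediction_score" %in% names(edges)
  if (!is.null(min_score) && has_score) {
    edges <- edges[edges$prediction_score >= min_score, , drop = FALSE]
  }
  edges <- edges[!duplicated(edges[c("mirna_id", "gene_id")]), , drop = FALSE]
  edges <- edges[edges$mirna_id != edges$gene_id, , drop = FALSE]

  mirnas <- sort(mirna_ids)
  genes <- sort(unique(edges$gene_id))
  vertices <- data.frame(name = c(mirnas, genes),
                         type = c(rep("miRNA", length(mirnas)),
                                  rep("gene", length(genes))),
                         stringsAsFactors = FALSE)
  edge_df <- data.frame(from = edges$mirna_id, to = edges$gene_id,
                        stringsAsFactors = FALSE)
  if (has_score) edge_df$score <- edges$prediction_score
  igraph::graph_from_data_frame(edge_df, directed = FALSE, vertices = vertices)
}

#' Common targets of the network's miRNAs
#'
#' Genes adjacent to at least `min_degree` distinct miRNA nodes, sorted
#' lexicographically.
#'
#' @param network Network from [build_network()].
#' @param min_degree Minimum number of distinct adjacent miRNAs (default 2).
#' @return Character vector of gene ids.
#' @export
common_targets <- function(network, min_degree = 2) {
  genes <- igraph::V(network)[igraph::V(network)$type == "gene"]
  if (!length(genes)) return(character())
  n_mirna_neighbors <- vapply(genes, function(v) {
    nb <- igraph::neighbors(network, v)
    length(unique(nb$name[nb$type == "miRNA"]))
  }, numeric(1))
  sort(genes$name[n_mirna_neighbors >= min_degree])
}

#' Summarize a regulatory network
#'
#' @param network Network from [build_network()].
#' @return List with `n_nodes`, `n_edges`, `n_mirna`, `n_gene`,
#'   `n_common_targets` (genes adjacent to >= 2 miRNAs), and
#'   `degree_table` (data.frame `node`, `type`, `degree`).
#' @export
network_summary <- function(network) {
  types <- igraph::V(network)$type
  deg <- igraph::degree(network)
  list(n_nodes = as.integer(igraph::vcount(network)),
       n_edges = as.integer(igraph::ecount(network)),
       n_mirna = as.integer(sum(types == "miRNA")),
       n_gene = as.integer(sum(types == "gene")),
       n_common_targets = length(common_targets(network, 2)),
       degree_table = data.frame(node = igraph::V(network)$name, type = types,
                                 degree = unname(deg), stringsAsFactors = FALSE))
}

#' Export a regulatory network
#'
#' `"sif"` writes Cytoscape simple-interaction lines
#' `miRNA<TAB>targets<TAB>gene` (one per edge; isolated nodes as bare
#' single-column lines). `"graphml"` writes GraphML with the node-type and
#' score attributes; [import_network()] on that file reproduces an
#' isomorphic network with identical attributes.
#'
#' @param network Network from [build_network()].
#' @param path Output file path.
#' @param format `"graphml"` or `"sif"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(network, path, format = c("graphml", "sif")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(network, path, format = "graphml")
  } else {
    el <- igraph::as_edgelist(network)
    # orient each SIF line miRNA -> gene
    lines <- character(0)
    if (nrow(el)) {
      type_of <- stats::setNames(igraph::V(network)$type, igraph::V(network)$name)
      src <- ifelse(type_of[el[, 1]] == "miRNA", el[, 1], el[, 2])
      dst <- ifelse(type_of[el[, 1]] == "miRNA", el[, 2], el[, 1])
      lines <- sprintf("%s\ttargets\t%s", src, dst)
    }
    isolated <- igraph::V(network)$name[igraph::degree(network) == 0]
    writeLines(c(lines, isolated), path)
  }
  invisible(path)
}

#' Import a GraphML regulatory network
#'
#' @param path A GraphML file written by [export_network()].
#' @return An `igraph` network.
#' @export
import_network <- function(path) {
  assert_that(file.exists(path), sprintf("file not found: %s", path))
  igraph::read_graph(path, format = "graphml")
}
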