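# Hub ranking by intramodular connectivity and trait-level hub subnetworks.

#' Select hub genes per module
#'
#' The hubs of a module are its `n_hubs` top-ranked genes by intramodular
#' connectivity (kWithin); exact ties are broken lexicographically by gene id.
#' Modules smaller than `n_hubs` contribute all their genes. The grey
#' pseudo-module is skipped.
#'
#' @param connectivity data.frame from [intramodular_connectivity()].
#' @param n_hubs hubs per module (default 10).
#' @return named list module -> data.frame (`gene`, `k_within`), ordered by
#'   decreasing kWithin.
#' @export
select_hubs <- function(connectivity, n_hubs = 10L) {
  stop_if(n_hubs <= 0, "'n_hubs' must be positive")
  mods <- setdiff(sort(unique(connectivity$module)), "grey")
  out <- lapply(mods, function(m) {
    d <- connectivity[connectivity$module == m, c("gene", "k_within")]
    d <- d[order(-d$k_within, d$gene), , drop = FALSE]
    utils::head(d, n_hubs)
  })
  stats::setNames(out, mods)
}

#' Build a trait-level hub subnetwork
#'
#' Pools the hubs of the modules associated with a trait, weights every hub
#' pair by `|cor|^beta`, keeps edges above `weight_threshold` (default 0.2)
#' and returns the largest connected component as an igraph graph with node
#' module colours and degrees.
#'
#' @param expr numeric genes x samples matrix containing the hub genes.
#' @param hubs list from [select_hubs()].
#' @param modules_for_trait character vector of module colours to pool.
#' @param beta soft-threshold exponent used for edge weights (default 10).
#' @param weight_threshold minimum retained edge weight (default 0.2).
#' @return igraph graph (possibly empty, with a warning, when no edge
#'   survives) with vertex attributes `module` and `degree` and edge
#'   attribute `weight`.
#' @export
build_hub_subnetwork <- function(expr, hubs, modules_for_trait,
                                 beta = 10, weight_threshold = 0.2) {
  missing_mod <- setdiff(modules_for_trait, names(hubs))
  stop_if(length(missing_mod) > 0,
          "no hubs for module(s): ", paste(missing_mod, collapse = ", "))
  pool <- do.call(rbind, lapply(modules_for_trait, function(m)
    cbind(hubs[[m]], module = m)))
  pool <- pool[!duplicated(pool$gene), ]
  genes <- pool$gene
  stop_if(!all(genes %in% rownames(expr)),
          "hub genes absent from 'expr': ",
          paste(utils::head(setdiff(genes, rownames(expr))), collapse = ", "))
  w <- abs(stats::cor(t(expr[genes, , drop = FALSE])))^beta
  diag(w) <- 0
  w[w <= weight_threshold] <- 0
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE)
  igraph::V(g)$module <- pool$module[match(igraph::V(g)$name, pool$gene)]
  g <- igraph::delete_vertices(g, which(igraph::degree(g) == 0))
  if (igraph::ecount(g) == 0) {
    warning("no edge exceeds the weight threshold; returning an empty network",
            call. = FALSE)
    return(g)
  }
  comp <- igraph::components(g)
  keep <- which(comp$membership == which.max(comp$csize))
  g <- igraph::induced_subgraph(g, keep)
  igraph::V(g)$degree <- igraph::degree(g)
  g
}

#' Export a hub subnetwork
#'
#' Writes the weighted edge list as TSV and, optionally, the graph as GraphML.
#'
#' @param graph igraph graph from [build_hub_subnetwork()].
#' @param edge_file path of the edge-list TSV (`from`, `to`, `weight`).
#' @param graphml_file optional path of a GraphML export.
#' @return invisibly, the edge-list data.frame.
#' @export
write_subnetwork <- function(graph, edge_file, graphml_file = NULL) {
  el <- igraph::as_data_frame(graph, what = "edges")
  out <- el
  out$weight <- fmt_num(out$weight)
  utils::write.table(out, edge_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(graphml_file))
    igraph::write_graph(graph, graphml_file, format = "graphml")
  invisible(el)
}
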