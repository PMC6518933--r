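#' Build the spatial habitat network for one epoch
#'
#' The network is the complete graph on all ponds extant in the epoch, with
#' edge weights the Euclidean distances between pond coordinates, in
#' kilometres. No distance threshold is applied: for passively dispersing
#' pond organisms every pair of habitats is a potential dispersal route,
#' weighted only by how far apart they are.
#'
#' @param ponds a `pond_table`.
#' @param epoch `"1957"` or `"2010"`.
#' @return a `habitat_network`: list with `epoch`, `ids`, the full distance
#'   matrix `dist_km`, and the per-node `closeness` index (km).
#' @export
build_network <- function(ponds, epoch) {
  extant <- ponds[[paste0("extant_", epoch)]]
  if (sum(extant) < 2) stop("need at least 2 extant ponds in epoch ", epoch)
  xy <- cbind(ponds$x[extant], ponds$y[extant])
  if (anyNA(xy)) stop("missing coordinates for extant ponds")
  ids <- ponds$pond_id[extant]
  d <- as.matrix(stats::dist(xy)) / 1000
  dimnames(d) <- list(ids, ids)
  net <- structure(list(epoch = as.character(epoch), ids = ids, dist_km = d),
                   class = "habitat_network")
  net$closeness <- closeness_index(net)
  net
}

#' Closeness centrality index of every pond
#'
#' Defined as the mean shortest-path distance (km) from a pond to all other
#' extant ponds. On a complete graph with Euclidean weights the direct edge
#' is always a shortest path (triangle inequality), so the index is the row
#' mean of the off-diagonal distance matrix. Lower values mean a more
#' central, better-connected pond; a temporal increase means the pond
#' became more peripheral. Normalising by `n - 1` keeps the index
#' comparable between networks of different size (e.g. 116 vs 30 nodes).
#'
#' @param net a `habitat_network`.
#' @return named numeric vector of mean distances (km), one per pond.
#' @export
closeness_index <- function(net) {
  stopifnot(inherits(net, "habitat_network"))
  n <- length(net$ids)
  stats::setNames(rowSums(net$dist_km) / (n - 1), net$ids)
}

#' Temporal change in closeness for ponds present in both networks
#'
#' `delta(v) = index_2010(v) - index_1957(v)`; positive values mean the
#' pond became more isolated as the network contracted.
#'
#' @param net_a epoch-1 `habitat_network`.
#' @param net_b epoch-2 `habitat_network`.
#' @param ids pond ids present in both networks.
#' @return named numeric vector of closeness changes (km).
#' @export
delta_closeness <- function(net_a, net_b, ids) {
  missing_a <- setdiff(ids, net_a$ids)
  missing_b <- setdiff(ids, net_b$ids)
  if (length(missing_a) > 0 || length(missing_b) > 0) {
    stop("id(s) missing from network: ",
         paste(unique(c(missing_a, missing_b)), collapse = ", "))
  }
  net_b$closeness[ids] - net_a$closeness[ids]
}

#' Export a habitat network to GraphML
#'
#' Thin wrapper over igraph for interoperability with network tools.
#'
#' @param net a `habitat_network`.
#' @param path output `.graphml` path.
#' @export
export_graphml <- function(net, path) {
  if (!requireNamespace("igraph", quietly = TRUE)) {
    stop("igraph is required for GraphML export")
  }
  g <- igraph::graph_from_adjacency_matrix(net$dist_km, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  igraph::V(g)$closeness_km <- unname(net$closeness[igraph::V(g)$name])
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
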