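#' The a priori cortical grasping network
#'
#' Builds the five-source network used throughout the package: inferior
#' parietal lobule (IPL), primary motor cortex (M1), ventral premotor cortex
#' (PMv), supplementary motor area (SMA) and dorsolateral prefrontal cortex
#' (DLPFC). Backward (top-down) connections run DLPFC->PMv, DLPFC->SMA,
#' PMv->M1, SMA->M1, PMv->IPL and SMA->IPL; forward (bottom-up) connections
#' run in the reverse direction; PMv and SMA are linked by reciprocal lateral
#' connections. This yields 14 extrinsic couplings.
#'
#' @param coordinates optional named list of 3-vectors (mm) per node; stored
#'   as configuration only, never used in computation.
#' @return an object of class `dcm_network` with elements `nodes`,
#'   `forward`, `backward`, `lateral` (two-column from/to character
#'   matrices) and `coordinates`.
#' @examples
#' net <- grasping_network()
#' n_extrinsic(net)  # 14
#' @export
grasping_network <- function(coordinates = NULL) {
  nodes <- c("IPL", "M1", "PMv", "SMA", "DLPFC")
  backward <- rbind(
    c("DLPFC", "PMv"),
    c("DLPFC", "SMA"),
    c("PMv", "M1"),
    c("SMA", "M1"),
    c("PMv", "IPL"),
    c("SMA", "IPL")
  )
  forward <- backward[, 2:1, drop = FALSE]
  lateral <- rbind(c("PMv", "SMA"), c("SMA", "PMv"))
  colnames(forward) <- colnames(backward) <- colnames(lateral) <- c("from", "to")
  if (is.null(coordinates)) {
    # placeholder positions (mm); configuration only
    coordinates <- list(
      IPL = c(-40, -46, 46), M1 = c(-38, -22, 54), PMv = c(-52, 8, 28),
      SMA = c(-4, -6, 58), DLPFC = c(-38, 36, 28)
    )
  }
  net <- structure(
    list(nodes = nodes, forward = forward, backward = backward,
         lateral = lateral, coordinates = coordinates),
    class = "dcm_network"
  )
  validate_network(net)
  net
}

validate_network <- function(net) {
  edges <- rbind(net$forward, net$backward, net$lateral)
  if (any(edges[, 1] == edges[, 2]))
    stop("network contains a self-edge")
  if (!all(edges %in% net$nodes))
    stop("edge endpoint not among network nodes")
  ids <- c(edge_ids(net$forward, "forward"), edge_ids(net$backward, "backward"),
           edge_ids(net$lateral, "lateral"))
  key <- sub("^[a-z]+:", "", ids)
  if (anyDuplicated(key))
    stop("forward/backward/lateral edge sets are not disjoint")
  invisible(net)
}

edge_ids <- function(edges, type) {
  if (nrow(edges) == 0) return(character(0))
  paste0(type, ":", edges[, 1], "->", edges[, 2])
}

#' Extrinsic edge labels of a network
#'
#' Canonical ordering: forward edges, then backward, then lateral, each in
#' the order returned by [grasping_network()]. This ordering is used for the
#' coupling parameter vector everywhere in the package.
#'
#' @param net a `dcm_network`
#' @return character vector of edge ids, e.g. `"forward:IPL->PMv"`
#' @export
network_edges <- function(net) {
  c(edge_ids(net$forward, "forward"),
    edge_ids(net$backward, "backward"),
    edge_ids(net$lateral, "lateral"))
}

#' Number of extrinsic couplings in a network
#' @param net a `dcm_network`
#' @return integer count of extrinsic edges
#' @export
n_extrinsic <- function(net) {
  nrow(net$forward) + nrow(net$backward) + nrow(net$lateral)
}

#' Remove all extrinsic connections of one source (hidden-source model)
#'
#' Returns the same network with every extrinsic edge that originates from
#' or targets `source` removed. The node itself is retained, so the
#' dimensionality of the model (and of the data it predicts) is unchanged;
#' the source merely becomes hidden to the rest of the network.
#'
#' @param net a `dcm_network`
#' @param source node name, e.g. `"IPL"`
#' @return a `dcm_network`
#' @export
hide_source <- function(net, source) {
  if (!source %in% net$nodes)
    stop("unknown source: ", source)
  drop_touching <- function(edges) {
    keep <- edges[, 1] != source & edges[, 2] != source
    edges[keep, , drop = FALSE]
  }
  net$forward <- drop_touching(net$forward)
  net$backward <- drop_touching(net$backward)
  net$lateral <- drop_touching(net$lateral)
  validate_network(net)
  net
}

#' @export
print.dcm_network <- function(x, ...) {
  cat("Cortical network:", paste(x$nodes, collapse = ", "), "\n")
  cat(sprintf("  %d forward, %d backward, %d lateral extrinsic connections\n",
              nrow(x$forward), nrow(x$backward), nrow(x$lateral)))
  invisible(x)
}
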