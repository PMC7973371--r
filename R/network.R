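#' Undirected gene-interaction network
#'
#' A simple undirected graph over gene symbols: no self-loops, no duplicate
#' edges, edges stored canonically with `from` lexicographically before `to`.
#' Per-edge provenance (the pathway ids an edge was seen in) is kept as a
#' semicolon-separated string.
#'
#' @param edges data.frame with character columns `from` and `to`, and
#'   optionally `pathway` (provenance).
#' @param nodes optional character vector of node names; defaults to the
#'   symbols present in `edges`. Isolated nodes may be added this way.
#' @return An object of class `myonet_network` with elements `nodes`
#'   (sorted character vector) and `edges` (data.frame `from`, `to`,
#'   `pathways`).
#' @export
network <- function(edges, nodes = NULL) {
  if (!is.data.frame(edges) || !all(c("from", "to") %in% names(edges))) {
    stop_input("'edges' must be a data.frame with columns 'from' and 'to'")
  }
  from <- as.character(edges$from)
  to <- as.character(edges$to)
  bad <- which(is.na(from) | is.na(to) | from == "" | to == "")
  if (length(bad)) {
    stop_input("malformed edge row(s): empty or missing gene symbol at line ",
               paste(bad, collapse = ", "))
  }
  pathway <- if ("pathway" %in% names(edges)) as.character(edges$pathway) else rep(NA_character_, length(from))

  loops <- from == to
  if (any(loops)) {
    warning(sum(loops), " self-loop(s) dropped", call. = FALSE)
    from <- from[!loops]; to <- to[!loops]; pathway <- pathway[!loops]
  }
  # canonical orientation, then collapse duplicates accumulating provenance
  a <- pmin(from, to); b <- pmax(from, to)
  key <- paste(a, b, sep = "\r")
  prov <- vapply(split(pathway, key), function(p) {
    p <- sort(unique(p[!is.na(p)]))
    if (length(p)) paste(p, collapse = ";") else NA_character_
  }, character(1))
  u <- !duplicated(key)
  ed <- data.frame(from = a[u], to = b[u], stringsAsFactors = FALSE)
  ed$pathways <- unname(prov[key[u]])
  ed <- ed[order(ed$from, ed$to), , drop = FALSE]
  rownames(ed) <- NULL

  nodes <- sort(unique(c(ed$from, ed$to, as.character(nodes))))
  nodes <- nodes[nodes != ""]
  structure(list(nodes = nodes, edges = ed), class = "myonet_network")
}

#' @export
print.myonet_network <- function(x, ...) {
  cat("myonet network:", length(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  invisible(x)
}

#' Number of nodes and edges
#' @param net a `myonet_network`.
#' @return named integer vector with elements `nodes` and `edges`.
#' @export
network_size <- function(net) {
  stopifnot(inherits(net, "myonet_network"))
  c(nodes = length(net$nodes), edges = nrow(net$edges))
}

#' Merge per-pathway edge lists into a parent network
#'
#' Takes edge lists (one per pathway or a single table with a `pathway`
#' column), unions nodes and edges, collapses duplicate edges while
#' accumulating pathway provenance, and drops self-loops.
#'
#' @param edge_lists either a single data.frame with columns
#'   `from`/`to` (or `gene_a`/`gene_b`) and optionally `pathway`, or a
#'   (possibly named) list of such data.frames; list names are used as
#'   pathway ids when a `pathway` column is absent.
#' @return a [network()] object.
#' @export
merge_pathway_networks <- function(edge_lists) {
  if (is.data.frame(edge_lists)) edge_lists <- list(edge_lists)
  ids <- names(edge_lists) %||% rep(NA_character_, length(edge_lists))
  parts <- vector("list", length(edge_lists))
  for (i in seq_along(edge_lists)) {
    el <- edge_lists[[i]]
    if (!is.data.frame(el)) stop_input("edge list ", i, " is not a data.frame")
    nm <- names(el)
    if (all(c("gene_a", "gene_b") %in% nm)) {
      el <- data.frame(from = el$gene_a, to = el$gene_b,
                       pathway = if ("pathway" %in% nm) el$pathway else NA,
                       stringsAsFactors = FALSE)
    }
    if (!all(c("from", "to") %in% names(el))) {
      stop_input("edge list ", i, " lacks 'from'/'to' (or 'gene_a'/'gene_b') columns")
    }
    if (!"pathway" %in% names(el) || all(is.na(el$pathway))) {
      el$pathway <- if (!is.na(ids[i]) && nzchar(ids[i])) ids[i] else NA_character_
    }
    parts[[i]] <- el[, c("from", "to", "pathway")]
  }
  network(do.call(rbind, parts))
}

# integer adjacency list over node indices 1..n
adjacency_list <- function(net) {
  n <- length(net$nodes)
  adj <- rep(list(integer(0)), n)
  if (nrow(net$edges)) {
    idx <- seq_len(n)
    names(idx) <- net$nodes
    from <- unname(idx[net$edges$from])
    to <- unname(idx[net$edges$to])
    ii <- c(from, to); jj <- c(to, from)
    o <- order(ii, jj)
    grp <- split(jj[o], ii[o])
    adj[as.integer(names(grp))] <- grp
  }
  adj
}

as_igraph <- function(net, node_attrs = NULL) {
  v <- data.frame(name = net$nodes, stringsAsFactors = FALSE)
  if (!is.null(node_attrs)) {
    stopifnot(is.data.frame(node_attrs), "name" %in% names(node_attrs))
    v <- merge(v, node_attrs, by = "name", all.x = TRUE, sort = TRUE)
  }
  igraph::graph_from_data_frame(net$edges, directed = FALSE, vertices = v)
}

from_igraph <- function(g) {
  ed <- igraph::as_data_frame(g, what = "edges")
  names(ed)[1:2] <- c("from", "to")
  if (!"pathways" %in% names(ed)) ed$pathways <- NA_character_
  ed$pathway <- ed$pathways
  network(ed[, c("from", "to", "pathway")], nodes = igraph::V(g)$name)
}

#' Extract the induced subgraph on a node set
#' @param net a `myonet_network`.
#' @param nodes character vector of node names (must exist in `net`).
#' @return a `myonet_network` restricted to `nodes` and the edges among them.
#' @export
induced_network <- function(net, nodes) {
  stopifnot(inherits(net, "myonet_network"))
  missing <- setdiff(nodes, net$nodes)
  if (length(missing)) stop_input("nodes not in network: ", paste(missing, collapse = ", "))
  keep <- net$edges$from %in% nodes & net$edges$to %in% nodes
  ed <- net$edges[keep, , drop = FALSE]
  ed$pathway <- ed$pathways
  network(ed[, c("from", "to", "pathway")], nodes = nodes)
}
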