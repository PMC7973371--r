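# Fisher-combined gene scoring over timepoints and extraction of the
# disease subnetwork from the merged pathway network: a maximum-weight
# connected subgraph found by a prize-collecting Steiner tree heuristic
# (metric closure + minimum spanning tree, Kou-Markowsky-Berman style,
# followed by strong pruning and a deterministic hill climb).

#' Fisher-combined significance scores across timepoints
#'
#' Aggregates each gene's per-timepoint FDRs (default) or raw p-values with
#' Fisher's combined probability method: `X2 = -2 * sum(log(q_t))` compared
#' to a chi-square with `2 * n_timepoints` degrees of freedom. The gene
#' score is `-log10` of the combined upper-tail probability, so a gene
#' scores higher the more significantly it changes over time. Genes missing
#' from a table contribute 1 at that timepoint; values are clamped to
#' `[1e-300, 1]` before logging, bounding scores at 300.
#'
#' @param de_tables list of per-timepoint DE tables.
#' @param use `"fdr"` (default, matching scoring on aggregated FDRs) or
#'   `"p"` for raw p-values.
#' @return named numeric vector of scores, one per gene seen in any table.
#' @export
combine_scores <- function(de_tables, use = c("fdr", "p")) {
  use <- match.arg(use)
  if (!is.list(de_tables) || !length(de_tables)) stop_input("'de_tables' must be a nonempty list")
  genes <- sort(unique(unlist(lapply(de_tables, function(d) d$gene))))
  q <- matrix(1, nrow = length(genes), ncol = length(de_tables),
              dimnames = list(genes, NULL))
  for (j in seq_along(de_tables)) {
    d <- de_tables[[j]]
    v <- d[[use]]
    if (any(is.na(v)) || any(v < 0 | v > 1)) {
      stop_input("'", use, "' values outside [0, 1] in DE table ", j)
    }
    q[d$gene, j] <- v
  }
  q <- pmin(pmax(q, 1e-300), 1)
  x2 <- -2 * rowSums(log(q))
  comb <- pchisq(x2, df = 2 * length(de_tables), lower.tail = FALSE)
  comb <- pmin(pmax(comb, 1e-300), 1)
  setNames(-log10(comb), genes)
}

# node costs for the Steiner search: nonnegative penalty for crossing a
# below-threshold node
node_costs <- function(w) pmax(-w, 0)

# KMB-style Steiner module for a fixed threshold theta.
# g: igraph of the parent network (vertex name set = score names);
# w: named node weights (score - theta). Returns character node set or NULL.
steiner_module <- function(g, w) {
  terminals <- names(w)[w >= 0]
  if (!length(terminals)) return(NULL)
  cost <- node_costs(w)
  ends <- igraph::as_edgelist(g, names = TRUE)
  ew <- (cost[ends[, 1]] + cost[ends[, 2]]) / 2
  d <- igraph::distances(g, v = terminals, to = terminals, weights = ew)

  # group terminals by finite-distance blocks (connected components of the
  # parent restricted to terminal reachability)
  blocks <- list()
  left <- terminals
  while (length(left)) {
    t0 <- left[1]
    blk <- left[is.finite(d[t0, left])]
    blocks[[length(blocks) + 1L]] <- blk
    left <- setdiff(left, blk)
  }

  expand_block <- function(blk) {
    if (length(blk) == 1) return(blk)
    db <- d[blk, blk, drop = FALSE]
    pairs <- which(upper.tri(db), arr.ind = TRUE)
    closure_edges <- data.frame(from = blk[pairs[, 1]], to = blk[pairs[, 2]],
                                weight = db[pairs], stringsAsFactors = FALSE)
    closure <- igraph::graph_from_data_frame(closure_edges, directed = FALSE,
                                             vertices = data.frame(name = blk))
    mst <- igraph::mst(closure, weights = igraph::E(closure)$weight)
    nodes <- character(0)
    me <- igraph::as_edgelist(mst, names = TRUE)
    for (r in seq_len(nrow(me))) {
      sp <- igraph::shortest_paths(g, from = me[r, 1], to = me[r, 2],
                                   weights = ew, output = "vpath")
      nodes <- union(nodes, names(sp$vpath[[1]]))
    }
    union(nodes, blk)
  }

  best_of <- function(cands) {
    cands <- cands[!vapply(cands, is.null, logical(1))]
    netw <- vapply(cands, function(m) sum(w[m]), numeric(1))
    sizes <- lengths(cands)
    keyset <- vapply(cands, function(m) paste(sort(m), collapse = ","), character(1))
    cands[[order(-netw, -sizes, keyset)[1]]]
  }
  modules <- lapply(blocks, function(blk) {
    raw <- expand_block(blk)
    # candidate modules: leaf-pruned union of paths, strong-pruned optimal
    # subtree of its spanning tree, strong-pruned BFS and cost-weighted MST
    # spanning trees of the whole component, and the best single terminal;
    # the winner is polished by a deterministic hill climb
    top <- blk[order(-w[blk], blk)][1]
    comp <- sort(igraph::as_ids(igraph::subcomponent(g, blk[1])))
    cand <- best_of(list(prune_negative_leaves(g, raw, w),
                         strong_prune(g, raw, w),
                         strong_prune(g, comp, w),
                         strong_prune(g, comp, w, use_mst = TRUE),
                         top))
    local_improve(g, cand, w)
  })
  # best block-module: max net weight, then size, then lexicographically
  # smallest node set
  sort(best_of(modules))
}

# optimal subtree of a deterministic BFS spanning tree of the induced
# subgraph on `nodes`, by the classic strong-pruning dynamic program for
# node-weighted prize-collecting trees: f(v) = w(v) + sum over children of
# max(0, f(child)); the module is the best-rooted subtree, keeping children
# with nonnegative contribution.
strong_prune <- function(g, nodes, w, use_mst = FALSE) {
  if (length(nodes) <= 1) return(nodes)
  sub <- igraph::induced_subgraph(g, nodes)
  if (use_mst) {
    # replace the induced subgraph by its minimum spanning tree under the
    # averaged node-cost edge weights, so the DP sees the cheapest links
    cost <- node_costs(w)
    ends <- igraph::as_edgelist(sub, names = TRUE)
    if (nrow(ends)) {
      sub <- igraph::mst(sub, weights = (cost[ends[, 1]] + cost[ends[, 2]]) / 2)
    }
  }
  nm <- igraph::V(sub)$name
  root <- which(nm == min(nm))
  b <- igraph::bfs(sub, root = root, father = TRUE, unreachable = FALSE)
  parent <- as.integer(b$father)
  ord <- as.integer(b$order)
  ord <- ord[!is.na(ord)]
  f <- unname(w[nm])
  for (v in rev(ord)) {
    p <- parent[v]
    if (!is.na(p) && f[v] > 0) f[p] <- f[p] + f[v]
  }
  # recover the subtree under the best vertex (ties: lexicographic name)
  best <- order(-f, nm)[1]
  children <- split(seq_along(parent)[!is.na(parent)], parent[!is.na(parent)])
  keep <- best
  stack <- best
  while (length(stack)) {
    v <- stack[[1]]; stack <- stack[-1]
    ch <- children[[as.character(v)]]
    ch <- ch[f[ch] >= 0]
    keep <- c(keep, ch)
    stack <- c(stack, ch)
  }
  nm[keep]
}

# deterministic hill climb on net weight: add every positive-weight
# neighbor of the module, then drop the most negative non-articulation
# node, until a fixed point. Every step strictly increases the total
# weight, so the loop terminates; the result has no negative-weight leaf.
local_improve <- function(g, nodes, w) {
  repeat {
    changed <- FALSE
    nb <- unique(unlist(lapply(igraph::adjacent_vertices(g, nodes),
                               igraph::as_ids)))
    add <- setdiff(nb[w[nb] > 0], nodes)
    if (length(add)) {
      nodes <- union(nodes, add)
      changed <- TRUE
    }
    if (length(nodes) > 1) {
      sub <- igraph::induced_subgraph(g, nodes)
      arts <- igraph::as_ids(igraph::articulation_points(sub))
      cand <- setdiff(nodes[w[nodes] < 0], arts)
      if (length(cand)) {
        nodes <- setdiff(nodes, cand[order(w[cand], cand)][1])
        changed <- TRUE
      }
    }
    if (!changed) return(nodes)
  }
}

# iteratively drop degree-<=1 nodes with negative weight from the induced
# subgraph on `nodes`
prune_negative_leaves <- function(g, nodes, w) {
  repeat {
    sub <- igraph::induced_subgraph(g, nodes)
    deg <- igraph::degree(sub)
    drop <- names(deg)[deg <= 1 & w[names(deg)] < 0]
    if (!length(drop) || length(nodes) <= 1) return(nodes)
    nodes <- setdiff(nodes, drop)
  }
}

#' Extract the high-score subnetwork (prize-collecting Steiner heuristic)
#'
#' Selects a connected subgraph of the parent network containing the highly
#' scored genes, linked where necessary through a few low-scoring linker
#' nodes. Node weights are `w(v) = s(v) - theta`; nodes with `w >= 0` are
#' terminals; terminals are joined by a minimum spanning tree of their
#' metric closure under path cost `sum(max(-w, 0))` over interior nodes; the
#' union of tree paths is taken as a candidate module and pruned by the
#' strong-pruning dynamic program (optimal subtree of the Steiner tree),
#' which subsumes iterative negative-leaf pruning. A second candidate comes
#' from strong-pruning the cost-weighted minimum spanning tree of the whole
#' component, and the winning candidate is polished by a deterministic hill
#' climb (add positive-weight neighbors, drop negative non-articulation
#' nodes) before the induced subgraph on the module nodes is returned. On
#' tree-shaped parent networks this recovers the exact maximum-weight
#' connected subgraph. The
#' threshold `theta` is chosen by scanning the observed score values from
#' high to low and accepting the first module whose size falls within
#' `size_range`; if no threshold achieves the range, the nearest achievable
#' size is returned and flagged. Ties are broken lexicographically on gene
#' symbols throughout (nodes are ordered lexicographically before any graph
#' search).
#'
#' @param net parent [network()].
#' @param scores named numeric vector from [combine_scores()]; network nodes
#'   without a score get 0 (eligible as linkers only).
#' @param size_range target module size interval (default `c(30, 60)`).
#' @param de_tables optional list of DE tables used to annotate module nodes
#'   with per-timepoint log2 fold changes and FDRs.
#' @param theta optional fixed threshold; when supplied the scan is skipped
#'   and the module for this threshold is returned regardless of
#'   `size_range`.
#' @return object of class `subnetwork_result`: `network` (the induced
#'   module), `nodes`, `scores`, `theta`, `net_weight`
#'   (`sum(scores - theta)` over module nodes), `size_in_range`, and
#'   `node_data` (per-node score plus per-timepoint annotation when
#'   `de_tables` is given).
#' @export
find_subnetwork <- function(net, scores, size_range = c(30, 60),
                            de_tables = NULL, theta = NULL) {
  stopifnot(inherits(net, "myonet_network"))
  if (!length(net$nodes)) stop_input("empty network")
  if (is.null(names(scores))) stop_input("'scores' must be a named vector")
  if (any(!is.finite(scores)) || any(scores < 0)) stop_input("scores must be finite and >= 0")
  if (length(size_range) != 2 || size_range[1] > size_range[2]) {
    stop_input("'size_range' must be c(n_min, n_max) with n_min <= n_max")
  }
  s <- setNames(rep(0, length(net$nodes)), net$nodes)
  known <- intersect(names(scores), net$nodes)
  s[known] <- scores[known]
  if (all(s <= 0)) stop_input("no positive-score nodes; nothing to extract")

  g <- as_igraph(net)
  if (!is.null(theta)) {
    mod <- steiner_module(g, s - theta)
    if (is.null(mod)) stop_input("no terminal nodes at theta = ", theta)
    size <- length(mod)
    chosen <- list(nodes = mod, theta = theta,
                   in_range = size >= size_range[1] && size <= size_range[2])
    return(finish_subnetwork(net, s, chosen, de_tables))
  }
  thetas <- sort(unique(s[s > 0]), decreasing = TRUE)
  best <- NULL
  best_dist <- Inf
  chosen <- NULL
  for (theta in thetas) {
    w <- s - theta
    mod <- steiner_module(g, w)
    if (is.null(mod)) next
    size <- length(mod)
    dist <- max(0, size_range[1] - size, size - size_range[2])
    if (dist == 0) {
      chosen <- list(nodes = mod, theta = theta, in_range = TRUE)
      break
    }
    if (dist < best_dist) {
      best_dist <- dist
      best <- list(nodes = mod, theta = theta, in_range = FALSE)
    }
    if (size > size_range[2]) break  # modules only grow as theta decreases
  }
  if (is.null(chosen)) chosen <- best
  if (is.null(chosen)) stop_input("no candidate module at any threshold")
  finish_subnetwork(net, s, chosen, de_tables)
}

finish_subnetwork <- function(net, s, chosen, de_tables) {
  nodes <- sort(chosen$nodes)
  subnet <- induced_network(net, nodes)
  w <- s[nodes] - chosen$theta
  node_data <- data.frame(name = nodes, score = unname(s[nodes]),
                          weight = unname(w), stringsAsFactors = FALSE)
  if (!is.null(de_tables)) {
    for (d in de_tables) {
      tp <- as.character(d$timepoint[1])
      m <- match(nodes, d$gene)
      node_data[[paste0("log2fc_", tp)]] <- d$log2fc[m]
      node_data[[paste0("fdr_", tp)]] <- d$fdr[m]
    }
  }
  structure(list(network = subnet, nodes = nodes,
                 scores = s[nodes], theta = chosen$theta,
                 net_weight = sum(w), size_in_range = chosen$in_range,
                 node_data = node_data),
            class = "subnetwork_result")
}

#' @export
print.subnetwork_result <- function(x, ...) {
  cat("subnetwork:", length(x$nodes), "nodes,", nrow(x$network$edges), "edges;",
      sprintf("theta = %.4g, net weight = %.4g%s\n", x$theta, x$net_weight,
              if (x$size_in_range) "" else " (size outside requested range)"))
  invisible(x)
}

#' Check subnetwork structural invariants
#'
#' Verifies that a module is connected, is a subgraph of its parent, and has
#' no negative-weight leaf (every below-threshold node lies on a path
#' between two at-or-above-threshold nodes).
#'
#' @param subnet a `subnetwork_result`.
#' @param parent the parent [network()].
#' @return `TRUE` invisibly; errors otherwise.
#' @export
validate_subnetwork <- function(subnet, parent) {
  stopifnot(inherits(subnet, "subnetwork_result"), inherits(parent, "myonet_network"))
  if (!all(subnet$nodes %in% parent$nodes)) stop_input("module nodes not in parent network")
  ed <- subnet$network$edges
  pe <- paste(parent$edges$from, parent$edges$to)
  if (nrow(ed) && !all(paste(ed$from, ed$to) %in% pe)) stop_input("module edges not in parent network")
  if (length(subnet$nodes) > 1) {
    if (giant_component_size(subnet$network) != length(subnet$nodes)) {
      stop_input("module is not connected")
    }
  }
  w <- subnet$scores - subnet$theta
  adj <- adjacency_list(subnet$network)
  deg <- lengths(adj)
  if (length(subnet$nodes) > 1 && any(deg <= 1 & w[subnet$network$nodes] < 0)) {
    stop_input("module has a negative-weight leaf")
  }
  invisible(TRUE)
}
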