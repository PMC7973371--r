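# Percolation-based node criticality ("attackness") and combinatorial attack.
#
# Attackness of a removed node set S is the fraction of network nodes
# disconnected from the giant component after deleting S. Two conventions:
#   count-removed  : (N - G_after) / N   (removed nodes count as disconnected)
#   remaining-only : (N - |S| - G_after) / N
# The count-removed convention is monotone under set inclusion, which makes
# it a sound objective for combinatorial maximization.

# size of the largest connected component among nodes where keep == TRUE,
# by iterative BFS on an integer adjacency list
lcc_size <- function(adj, keep) {
  n <- length(adj)
  if (!n) return(0L)
  unvis <- keep
  remaining <- sum(keep)
  best <- 0L
  queue <- integer(n)
  for (s in seq_len(n)) {
    if (!unvis[s]) next
    head <- 1L; tail <- 1L
    queue[1L] <- s
    unvis[s] <- FALSE
    while (head <= tail) {
      v <- queue[head]; head <- head + 1L
      for (w in adj[[v]]) {
        if (unvis[w]) {
          unvis[w] <- FALSE
          tail <- tail + 1L
          queue[tail] <- w
        }
      }
    }
    if (tail > best) best <- tail
    remaining <- remaining - tail
    if (remaining <= best) break
  }
  best
}

#' Size of the giant (largest connected) component
#' @param net a [network()] object.
#' @return integer; 0 for an empty network.
#' @export
giant_component_size <- function(net) {
  stopifnot(inherits(net, "myonet_network"))
  lcc_size(adjacency_list(net), rep(TRUE, length(net$nodes)))
}

attack_conventions <- c("count-removed", "remaining-only")

new_attack_record <- function(removed, att, n, g_before, g_after, convention) {
  data.frame(
    nodes = paste(sort(removed), collapse = ","),
    k = length(removed),
    attackness = att,
    n_nodes = n,
    giant_before = g_before,
    giant_after = g_after,
    convention = convention,
    stringsAsFactors = FALSE
  )
}

attackness_value <- function(n, k, g_after, convention) {
  switch(convention,
         "count-removed" = (n - g_after) / n,
         "remaining-only" = (n - k - g_after) / n)
}

#' Attackness of a removed node set
#'
#' Fraction of network nodes disconnected from the giant component after
#' deleting the nodes in `removed`.
#'
#' @param net a [network()] object (nonempty).
#' @param removed character vector of node names to delete (must all be in
#'   the network; may be empty).
#' @param convention `"count-removed"` (default; removed nodes count as
#'   disconnected, monotone under set inclusion) or `"remaining-only"`.
#' @return one-row data.frame (an attack record): `nodes`, `k`,
#'   `attackness`, `n_nodes`, `giant_before`, `giant_after`, `convention`.
#'   Both conventions are recomputable from the recorded sizes.
#' @export
attackness <- function(net, removed, convention = c("count-removed", "remaining-only")) {
  stopifnot(inherits(net, "myonet_network"))
  convention <- match.arg(convention)
  n <- length(net$nodes)
  if (!n) stop_input("attackness is undefined on an empty network")
  removed <- unique(as.character(removed))
  missing <- setdiff(removed, net$nodes)
  if (length(missing)) stop_input("removed node(s) not in network: ", paste(missing, collapse = ", "))
  adj <- adjacency_list(net)
  g_before <- lcc_size(adj, rep(TRUE, n))
  keep <- !(net$nodes %in% removed)
  g_after <- lcc_size(adj, keep)
  att <- attackness_value(n, length(removed), g_after, convention)
  new_attack_record(removed, att, n, g_before, g_after, convention)
}

#' Single-node attackness profile
#'
#' Attackness of every node removed individually, sorted descending
#' (ties broken lexicographically by node name).
#'
#' @inheritParams attackness
#' @return data.frame of attack records, one row per node.
#' @export
attackness_profile <- function(net, convention = c("count-removed", "remaining-only")) {
  stopifnot(inherits(net, "myonet_network"))
  convention <- match.arg(convention)
  n <- length(net$nodes)
  if (!n) stop_input("attackness profile is undefined on an empty network")
  adj <- adjacency_list(net)
  g_before <- lcc_size(adj, rep(TRUE, n))
  g_after <- integer(n)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    keep[i] <- FALSE
    g_after[i] <- lcc_size(adj, keep)
    keep[i] <- TRUE
  }
  att <- attackness_value(n, 1L, g_after, convention)
  out <- data.frame(
    nodes = net$nodes, k = 1L, attackness = att, n_nodes = n,
    giant_before = g_before, giant_after = g_after,
    convention = convention, stringsAsFactors = FALSE
  )
  out <- out[order(-out$attackness, out$nodes), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Combinatorial attack: best k-node removal combinations
#'
#' Evaluates the attackness of `base_set` plus every size-`k` combination of
#' `candidates` by exhaustive enumeration, and returns the top combinations.
#' Exhaustive semantics define correctness; the enumeration short-circuits
#' component search but never prunes candidate combinations.
#'
#' @inheritParams attackness
#' @param k combination size (1 to `k_max`).
#' @param candidates nodes eligible for removal (default: all nodes).
#' @param base_set nodes removed unconditionally in every evaluation
#'   (disjoint from `candidates`).
#' @param top_m number of top-ranked combinations to return (`Inf` for all).
#' @param k_max ceiling on `k` (default 5).
#' @param max_combinations guard on the enumeration size (default 1e7).
#' @return data.frame of attack records ranked by decreasing attackness
#'   (ties broken lexicographically on the sorted removed node set), with an
#'   `added` column naming the combination on top of `base_set`.
#' @export
combinatorial_attack <- function(net, k, candidates = net$nodes,
                                 base_set = character(),
                                 top_m = 10,
                                 convention = c("count-removed", "remaining-only"),
                                 k_max = 5, max_combinations = 1e7) {
  stopifnot(inherits(net, "myonet_network"))
  convention <- match.arg(convention)
  if (!is_count(k) || k < 1 || k > k_max) {
    stop_input("'k' must be an integer in 1..", k_max)
  }
  candidates <- sort(unique(as.character(candidates)))
  base_set <- unique(as.character(base_set))
  missing <- setdiff(c(candidates, base_set), net$nodes)
  if (length(missing)) stop_input("node(s) not in network: ", paste(missing, collapse = ", "))
  if (length(intersect(base_set, candidates))) {
    stop_input("'base_set' and 'candidates' must be disjoint")
  }
  n <- length(net$nodes)
  if (length(base_set) + k > n) stop_input("cannot remove more nodes than the network has")
  n_comb <- choose(length(candidates), k)
  if (n_comb < 1) stop_input("fewer than 'k' candidate nodes")
  if (n_comb > max_combinations) {
    stop_input("combination space too large (", format(n_comb, big.mark = ","),
               " > max_combinations); restrict 'candidates' or lower 'k'")
  }

  adj <- adjacency_list(net)
  g_before <- lcc_size(adj, rep(TRUE, n))
  keep_base <- !(net$nodes %in% base_set)
  cand_idx <- match(candidates, net$nodes)
  combos <- combn(cand_idx, k)
  m <- ncol(combos)
  g_after <- integer(m)
  for (j in seq_len(m)) {
    keep <- keep_base
    keep[combos[, j]] <- FALSE
    g_after[j] <- lcc_size(adj, keep)
  }
  k_total <- length(base_set) + k
  att <- attackness_value(n, k_total, g_after, convention)
  added <- apply(combos, 2, function(ix) paste(net$nodes[ix], collapse = ","))
  full <- vapply(seq_len(m), function(j) {
    paste(sort(c(base_set, net$nodes[combos[, j]])), collapse = ",")
  }, character(1))
  out <- data.frame(
    nodes = full, added = added, k = k_total, attackness = att,
    n_nodes = n, giant_before = g_before, giant_after = g_after,
    convention = convention, stringsAsFactors = FALSE
  )
  out <- out[order(-out$attackness, out$nodes), , drop = FALSE]
  rownames(out) <- NULL
  if (is.finite(top_m)) out <- out[seq_len(min(top_m, nrow(out))), , drop = FALSE]
  out
}
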