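# Shared fixtures and independent oracles. The oracles deliberately use a
# different code path from the package (igraph components vs the package's
# own BFS; exhaustive enumeration vs heuristics; closed forms vs library
# calls) so each check compares two independent routes.

# Erdos-Renyi style random network with named nodes
random_network <- function(n, p, seed) {
  set.seed(seed)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- runif(nrow(pairs)) < p
  nodes <- sprintf("n%02d", seq_len(n))
  ed <- data.frame(from = nodes[pairs[keep, 1]], to = nodes[pairs[keep, 2]],
                   stringsAsFactors = FALSE)
  network(ed, nodes = nodes)
}

net_to_igraph <- function(net) {
  igraph::graph_from_data_frame(net$edges[, c("from", "to")], directed = FALSE,
                                vertices = data.frame(name = net$nodes))
}

# attackness via igraph: delete vertices, take largest component
oracle_attackness <- function(net, removed, convention = "count-removed") {
  g <- net_to_igraph(net)
  n <- igraph::vcount(g)
  h <- igraph::delete_vertices(g, removed)
  g_after <- if (igraph::vcount(h) == 0) 0L else max(igraph::components(h)$csize)
  if (convention == "count-removed") (n - g_after) / n
  else (n - length(removed) - g_after) / n
}

# exhaustive best k-combination by attackness (value and tie set)
oracle_best_combination <- function(net, k, candidates = net$nodes,
                                    base_set = character()) {
  combos <- combn(sort(candidates), k)
  vals <- apply(combos, 2, function(cmb) {
    oracle_attackness(net, c(base_set, cmb))
  })
  best <- max(vals)
  ties <- apply(combos[, vals == best, drop = FALSE], 2, function(cmb) {
    paste(sort(c(base_set, cmb)), collapse = ",")
  })
  list(value = best, ties = sort(ties))
}

# exhaustive maximum-weight connected subgraph over all nonempty node
# subsets (feasible for n <= about 14)
oracle_mwcs <- function(net, w) {
  g <- net_to_igraph(net)
  n <- length(net$nodes)
  best <- -Inf
  best_set <- NULL
  for (mask in seq_len(2^n - 1)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) != 0)
    sub <- igraph::induced_subgraph(g, net$nodes[sel])
    if (igraph::components(sub)$no != 1) next
    tot <- sum(w[net$nodes[sel]])
    if (tot > best) { best <- tot; best_set <- net$nodes[sel] }
  }
  list(weight = best, nodes = sort(best_set))
}

# five-line BH reference: min over j >= i of p_(j) * n / j, mapped back
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- rev(cummin(rev(sort(p) * n / seq_len(n))))
  pmin(adj, 1)[order(o)]
}

# exhaustive hypergeometric upper tail by direct summation of the pmf
oracle_hyper_upper <- function(k, m, N, g) {
  kk <- k:min(m, g)
  sum(choose(m, kk) * choose(N - m, g - kk)) / choose(N, g)
}

# chi-square survival closed form for df = 6
oracle_chisq6_sf <- function(x) exp(-x / 2) * (1 + x / 2 + x^2 / 8)

# small DE fixture: counts table with given per-group means
toy_counts <- function(mu_d, mu_c, n = 4, phi = 0.1, timepoint = 15, seed = 1,
                       extra_null = 0, mu_null = 200) {
  set.seed(seed)
  ng <- length(mu_d) + extra_null
  mu_d <- c(mu_d, rep(mu_null, extra_null))
  mu_c <- c(mu_c, rep(mu_null, extra_null))
  cts <- t(vapply(seq_len(ng), function(i) {
    c(rnbinom(n, mu = mu_d[i], size = 1 / phi),
      rnbinom(n, mu = mu_c[i], size = 1 / phi))
  }, numeric(2 * n)))
  rownames(cts) <- sprintf("g%04d", seq_len(ng))
  colnames(cts) <- c(sprintf("d_r%d", seq_len(n)), sprintf("c_r%d", seq_len(n)))
  smp <- data.frame(sample_id = colnames(cts),
                    condition = rep(c("disease", "control"), each = n),
                    timepoint = timepoint,
                    replicate = rep(seq_len(n), 2))
  counts_table(cts, smp)
}

# DE table stub for grouping/scoring tests
de_stub <- function(genes, calls, timepoint, fdr = NULL) {
  if (!length(genes)) {
    return(data.frame(gene = character(0), timepoint = numeric(0),
                      log2fc = numeric(0), p = numeric(0), fdr = numeric(0),
                      call = character(0), stringsAsFactors = FALSE))
  }
  fdr <- fdr %||% ifelse(calls == "ns", 0.5, 0.001)
  lfc <- ifelse(calls == "induced", 2, ifelse(calls == "repressed", -2, 0))
  data.frame(gene = genes, timepoint = timepoint, log2fc = lfc,
             p = fdr / 2, fdr = fdr, call = calls, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
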