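test_that("Fisher-combined scores match the df-6 chi-square closed form", {
  mk <- function(fdr) lapply(c(10, 15, 21), function(tp) {
    data.frame(gene = "g", timepoint = tp, log2fc = 0, p = fdr, fdr = fdr)
  })
  expect_equal(unname(combine_scores(mk(1))), 0)

  s_half <- combine_scores(mk(0.5))
  x2 <- -2 * 3 * log(0.5)
  expect_equal(unname(s_half), -log10(oracle_chisq6_sf(x2)), tolerance = 1e-10)
  expect_equal(unname(s_half), 0.1836, tolerance = 1e-3)

  s_01 <- combine_scores(mk(0.01))
  x2b <- -2 * 3 * log(0.01)
  expect_equal(unname(s_01), -log10(oracle_chisq6_sf(x2b)), tolerance = 1e-10)
  expect_equal(unname(s_01), 3.96, tolerance = 1e-2)

  expect_error(combine_scores(mk(1.5)), "\\[0, 1\\]")
})

test_that("scores are monotone in the per-timepoint significance and handle missing genes", {
  t1 <- data.frame(gene = c("a", "b"), timepoint = 10, log2fc = 0,
                   p = c(0.01, 0.01), fdr = c(0.01, 0.05))
  t2 <- data.frame(gene = "a", timepoint = 15, log2fc = 0, p = 0.5, fdr = 0.5)
  s <- combine_scores(list(t1, t2))
  # lower fdr at t1 never lowers the score
  expect_gt(s[["a"]], combine_scores(list(transform(t1, fdr = c(0.05, 0.05)), t2))[["a"]])
  # gene b missing from t2 is treated as fdr 1 there
  t2b <- rbind(t2, data.frame(gene = "b", timepoint = 15, log2fc = 0, p = 1, fdr = 1))
  expect_equal(s[["b"]], combine_scores(list(t1, t2b))[["b"]])
  # extreme significance clamps to a finite score
  tx <- lapply(c(10, 15, 21), function(tp) {
    data.frame(gene = "g", timepoint = tp, log2fc = 0, p = 0, fdr = 0)
  })
  expect_true(is.finite(combine_scores(tx)))
})

test_that("a linker is included when it joins two prizes profitably", {
  net <- network(data.frame(from = c("A", "B"), to = c("B", "C")))
  sn <- find_subnetwork(net, c(A = 5, B = 0, C = 5), size_range = c(1, 3), theta = 1)
  expect_equal(sn$nodes, c("A", "B", "C"))
  expect_equal(sn$net_weight, (5 - 1) + (0 - 1) + (5 - 1))
  validate_subnetwork(sn, net)
})

test_that("uniform high scores return the whole connected network", {
  set.seed(4)
  net <- random_network(40, 0.15, seed = 4)
  # connect stragglers so the graph is one component
  comp <- igraph::components(net_to_igraph(net))
  if (comp$no > 1) {
    reps <- vapply(seq_len(comp$no), function(i) net$nodes[comp$membership == i][1], "")
    ed <- rbind(net$edges[, c("from", "to")],
                data.frame(from = reps[-1], to = reps[1]))
    net <- network(ed)
  }
  sn <- find_subnetwork(net, setNames(rep(10, 40), net$nodes), size_range = c(30, 60))
  expect_setequal(sn$nodes, net$nodes)
  expect_true(sn$size_in_range)
})

test_that("heuristic net weight is near the exhaustive MWCS optimum on random graphs", {
  n_tree_exact <- 0L
  n_tree <- 0L
  for (seed in 1:50) {
    net <- random_network(10, 0.3, seed = 3000 + seed)
    set.seed(seed)
    s <- setNames(runif(10, 0, 10), net$nodes)
    theta <- 5
    w <- s - theta
    if (!any(w >= 0)) next
    sn <- try(find_subnetwork(net, s, size_range = c(1, 10), theta = theta), silent = TRUE)
    if (inherits(sn, "try-error")) next
    opt <- oracle_mwcs(net, w)
    expect_gte(sn$net_weight, 0.9 * opt$weight - 1e-9)
    validate_subnetwork(sn, net)
    # on trees the strong-pruned Steiner tree is exact
    if (nrow(net$edges) == length(net$nodes) - 1 &&
        giant_component_size(net) == length(net$nodes)) {
      n_tree <- n_tree + 1L
      if (abs(sn$net_weight - opt$weight) < 1e-9) n_tree_exact <- n_tree_exact + 1L
    }
  }
  if (n_tree > 0) expect_gte(n_tree_exact / n_tree, 0.9)
})

test_that("exact optimum is found on explicit tree networks", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- 10
    # random labelled tree: attach each node to a random earlier node
    ed <- data.frame(from = sprintf("n%02d", 2:n),
                     to = sprintf("n%02d", vapply(2:n, function(i) sample.int(i - 1, 1), 1L)))
    net <- network(ed)
    s <- setNames(runif(n, 0, 10), net$nodes)
    sn <- find_subnetwork(net, s, size_range = c(1, n), theta = 5)
    opt <- oracle_mwcs(net, s - 5)
    expect_equal(sn$net_weight, opt$weight, tolerance = 1e-9)
  }
})

test_that("planted high-score modules are recovered from simulated networks", {
  jac <- numeric(0)
  for (seed in 1:20) {
    sim <- simulate_network_and_pathways(n_pathways = 10, genes_per_pathway = 30,
                                         overlap_fraction = 0.2,
                                         planted_module_size = 20, seed = seed)
    set.seed(seed)
    s <- setNames(runif(length(sim$network$nodes), 0, 0.5), sim$network$nodes)
    s[sim$module] <- runif(20, 3, 5)
    sn <- find_subnetwork(sim$network, s, size_range = c(20, 40))
    jac <- c(jac, length(intersect(sn$nodes, sim$module)) /
               length(union(sn$nodes, sim$module)))
  }
  expect_gte(mean(jac), 0.8)
})

test_that("subnetwork extraction is deterministic and validates inputs", {
  net <- random_network(30, 0.15, seed = 12)
  set.seed(12)
  s <- setNames(runif(30, 0, 4), net$nodes)
  a <- find_subnetwork(net, s, size_range = c(5, 15))
  b <- find_subnetwork(net, s, size_range = c(5, 15))
  expect_identical(a$nodes, b$nodes)
  expect_identical(a$theta, b$theta)

  expect_error(find_subnetwork(net, setNames(rep(0, 30), net$nodes),
                               size_range = c(5, 15)), "no positive-score")
  expect_error(find_subnetwork(net, unname(s)), "named")
})
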