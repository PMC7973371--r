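test_that("simulation config enforces its invariants", {
  expect_error(sim_config(n_genes = 100,
                          group_sizes = setNames(rep(20L, 7), unname(group_rules()))),
               "exceed")
  expect_error(sim_config(nb_dispersion = 0), "dispersion")
  expect_error(sim_config(n_replicates = 1), "replicates")
  expect_error(sim_config(effect_log2fc = -1), "effect_log2fc")
})

test_that("count simulation is deterministic and respects planted structure", {
  cfg <- sim_config(n_genes = 150, group_sizes = setNames(rep(10L, 7), unname(group_rules())),
                    seed = 9)
  a <- simulate_counts(cfg)
  b <- simulate_counts(cfg)
  expect_identical(a$counts$counts, b$counts$counts)
  expect_identical(a$truth, b$truth)
  expect_true(all(a$counts$counts >= 0))
  expect_true(all(a$counts$counts == floor(a$counts$counts)))
  expect_equal(sum(a$truth$group != "null"), 70L)

  # all group sizes zero: everything is null
  cfg0 <- sim_config(n_genes = 50, group_sizes = setNames(rep(0L, 7), unname(group_rules())),
                     seed = 9)
  s0 <- simulate_counts(cfg0)
  expect_true(all(s0$truth$group == "null"))
})

test_that("null genes carry no condition effect", {
  cfg <- sim_config(n_genes = 1500, group_sizes = setNames(rep(0L, 7), unname(group_rules())),
                    seed = 31)
  sim <- simulate_counts(cfg)
  de <- test_differential(filter_low_counts(sim$counts), 15)
  expect_lte(mean(de$call != "ns"), 0.025)
})

test_that("planted-effect recovery is monotone in the effect size", {
  recov <- function(e) {
    hits <- 0L; tot <- 0L
    for (seed in 1:3) {
      cfg <- sim_config(n_genes = 400, group_sizes = c(EPi = 50), effect_log2fc = e,
                        seed = 600 + seed)
      sim <- simulate_counts(cfg)
      tabs <- lapply(cfg$timepoints, function(tp)
        test_differential(filter_low_counts(sim$counts), tp))
      grp <- assign_groups(call_patterns(tabs))
      hits <- hits + sum(grp$group[match(sim$truth$gene[1:50], grp$gene)] == "EPi",
                         na.rm = TRUE)
      tot <- tot + 50L
    }
    hits / tot
  }
  expect_gte(recov(3), recov(1))
})

test_that("simulated pathway networks have the promised structure", {
  one <- simulate_network_and_pathways(n_pathways = 1, genes_per_pathway = 5,
                                       planted_module_size = 0, seed = 2)
  expect_setequal(one$network$nodes, one$pathways$genes[[1]])

  two <- simulate_network_and_pathways(n_pathways = 2, genes_per_pathway = 10,
                                       overlap_fraction = 0, planted_module_size = 0,
                                       seed = 3)
  comp <- igraph::components(net_to_igraph(two$network))
  expect_gte(comp$no, 2)

  sim <- simulate_network_and_pathways(seed = 5)
  expect_length(sim$module, 20)
  sub <- induced_network(sim$network, sim$module)
  expect_equal(giant_component_size(sub), 20L)
  # per-pathway edge sets connect their members
  for (p in seq_along(sim$pathways$id)) {
    mem <- sim$pathways$genes[[p]]
    ed <- sim$edge_lists[sim$edge_lists$pathway == sim$pathways$id[p], ]
    pw <- network(ed[, c("from", "to")], nodes = mem)
    expect_equal(giant_component_size(pw), length(mem))
  }

  expect_error(simulate_network_and_pathways(n_pathways = 1, genes_per_pathway = 5,
                                             planted_module_size = 10, seed = 1),
               "planted_module_size")
})

test_that("drug table simulation plants the filter-exercising records", {
  genes <- sprintf("T%02d", 1:15)
  tab <- simulate_drug_table(genes, fraction_approved = 0.4, seed = 8)
  expect_identical(tab, simulate_drug_table(genes, fraction_approved = 0.4, seed = 8))
  expect_true(any(tab$withdrawn))
  # planted duplicate (gene, indication) pair at phases 2 and 4
  dup <- tab[tab$drug_id %in% c("DRUGD01", "DRUGD02"), ]
  expect_equal(sort(dup$max_phase), c(2L, 4L))
  expect_equal(unique(paste(dup$gene, dup$indication)),
               paste(dup$gene[1], dup$indication[1]))

  all_appr <- simulate_drug_table(genes, fraction_approved = 1, seed = 8)
  expect_true(all(all_appr$max_phase[!all_appr$withdrawn] == 4L))
})

test_that("fixture graphs have the constructed node and edge counts", {
  fx <- make_fixture_graphs()
  expect_equal(unname(network_size(fx$star5)), c(5L, 4L))
  expect_equal(unname(network_size(fx$path3)), c(3L, 2L))
  # two 4-cliques plus a cut vertex bridged to each: 2*C(4,2) + 2 edges
  expect_equal(unname(network_size(fx$barbell9)), c(9L, 14L))
})
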