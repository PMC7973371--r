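fx <- make_fixture_graphs()

test_that("giant component size handles fixtures, unions and the empty graph", {
  expect_equal(giant_component_size(fx$path3), 3L)
  two_tri <- network(data.frame(from = c("a", "b", "c", "x", "y", "z"),
                                to = c("b", "c", "a", "y", "z", "x")))
  expect_equal(giant_component_size(two_tri), 3L)
  empty <- structure(list(nodes = character(0),
                          edges = data.frame(from = character(0), to = character(0),
                                             pathways = character(0))),
                     class = "myonet_network")
  expect_equal(giant_component_size(empty), 0L)
})

test_that("single-node attackness on fixtures matches the definition", {
  hub <- attackness(fx$star5, "hub")
  expect_equal(hub$attackness, 0.8)
  expect_equal(hub$giant_after, 1L)

  leaf <- attackness(fx$star5, "leaf1")
  expect_equal(leaf$attackness, 0.2)
  leaf_r <- attackness(fx$star5, "leaf1", convention = "remaining-only")
  expect_equal(leaf_r$attackness, 0)

  expect_error(attackness(fx$star5, "nothere"), "nothere")
})

test_that("attackness of the empty removal set reflects baseline connectivity", {
  rec <- attackness(fx$path3, character(0))
  expect_equal(rec$attackness, 0)
  two <- network(data.frame(from = c("a", "x"), to = c("b", "y")))
  rec2 <- attackness(two, character(0))
  expect_equal(rec2$attackness, (4 - 2) / 4)
})

test_that("attackness profile ranks hub first, cut vertices first, K5 flat", {
  prof <- attackness_profile(fx$star5)
  expect_equal(prof$nodes[1], "hub")
  expect_equal(prof$attackness, c(0.8, 0.2, 0.2, 0.2, 0.2))
  expect_equal(prof$nodes[-1], paste0("leaf", 1:4))  # lexicographic ties

  barb <- attackness_profile(fx$barbell9)
  expect_equal(barb$nodes[1], "cut")
  expect_gt(barb$attackness[1], barb$attackness[2])

  k5 <- network(data.frame(from = combn(letters[1:5], 2)[1, ],
                           to = combn(letters[1:5], 2)[2, ]))
  pk5 <- attackness_profile(k5)
  expect_true(all(pk5$attackness == 0.2))
})

test_that("attackness agrees with an igraph component oracle on random graphs", {
  for (seed in 1:25) {
    net <- random_network(10, 0.3, seed = seed)
    for (v in net$nodes[c(1, 5, 9)]) {
      expect_equal(attackness(net, v)$attackness, oracle_attackness(net, v))
    }
    pair <- net$nodes[c(2, 7)]
    expect_equal(attackness(net, pair)$attackness, oracle_attackness(net, pair))
    expect_equal(attackness(net, pair, convention = "remaining-only")$attackness,
                 oracle_attackness(net, pair, "remaining-only"))
  }
})

test_that("count-removed attackness is monotone under set inclusion", {
  set.seed(42)
  for (i in 1:200) {
    net <- random_network(sample(5:12, 1), runif(1, 0.2, 0.6), seed = 1000 + i)
    s_size <- sample(0:3, 1)
    S <- sample(net$nodes, s_size)
    v <- sample(setdiff(net$nodes, S), 1)
    expect_gte(attackness(net, c(S, v))$attackness,
               attackness(net, S)$attackness)
  }
})

test_that("combinatorial attack matches the profile for k = 1 and brute force for k <= 3", {
  net <- random_network(10, 0.35, seed = 7)
  top1 <- combinatorial_attack(net, k = 1, top_m = 1)
  prof <- attackness_profile(net)
  expect_equal(top1$nodes[1], prof$nodes[1])
  expect_equal(top1$attackness[1], prof$attackness[1])

  for (seed in 1:10) {
    net <- random_network(10, 0.3, seed = 200 + seed)
    for (k in 2:3) {
      res <- combinatorial_attack(net, k = k, top_m = Inf)
      oracle <- oracle_best_combination(net, k)
      expect_equal(res$attackness[1], oracle$value)
      ties <- sort(res$nodes[res$attackness == res$attackness[1]])
      expect_equal(ties, oracle$ties)
    }
  }
})

test_that("combinatorial attack honors base sets and validates inputs", {
  net <- fx$barbell9
  res <- combinatorial_attack(net, k = 1, base_set = "cut", candidates = c("a1", "b1"))
  base_only <- attackness(net, "cut")$attackness
  expect_true(all(res$attackness >= base_only))

  expect_error(combinatorial_attack(net, k = 0), "1..5")
  expect_error(combinatorial_attack(net, k = 6), "1..5")
  expect_error(combinatorial_attack(net, k = 1, base_set = "a1",
                                    candidates = c("a1", "b1")), "disjoint")
})

test_that("attack output is deterministic including tie order", {
  net <- random_network(12, 0.3, seed = 99)
  a <- combinatorial_attack(net, k = 2, top_m = 20)
  b <- combinatorial_attack(net, k = 2, top_m = 20)
  expect_identical(a, b)
})
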