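test_that("game configuration enforces the constraint ordering", {
  cfg <- pdc_config()
  expect_equal(cfg$lambda, 0.6)
  expect_equal(cfg$gamma, 0.65)
  expect_equal(cfg$p, 2L)
  expect_equal(cfg$min_size, 3L)
  expect_error(pdc_config(lambda = 0.7, gamma = 0.65), "lambda <= gamma")
  expect_error(pdc_config(lambda = 0), "lambda")
  expect_error(pdc_config(gamma = 1.2), "gamma")
  expect_error(pdc_config(p = 0), "positive integer")
  expect_error(pdc_config(min_size = 1), ">= 2")
})

test_that("proposals are closed p-balls among active players", {
  k6 <- g_complete(sprintf("k%d", 1:6))
  expect_setequal(propose_coalition(k6, "k1"), sprintf("k%d", 1:6))

  iso <- ppi_network(nodes = "alone")
  expect_equal(propose_coalition(iso, "alone"), "alone")

  fx <- bridged_blocks()
  # p02 is a non-bridge vertex: its 2-ball is its block plus the far bridge end
  expect_setequal(propose_coalition(fx$graph, "p02"), c(fx$block1, "p07"))
  # restricted to active players
  expect_setequal(
    propose_coalition(fx$graph, "p02", active = c(fx$block1, "p08")),
    fx$block1
  )
  expect_error(propose_coalition(fx$graph, "p02", active = "p07"),
               "already assigned")
})

test_that("refinement keeps cliques, prunes bridges, rejects sparse stars", {
  cfg <- pdc_config()

  # a clique needs no pruning and no growth
  k6 <- g_complete(sprintf("k%d", 1:6))
  co <- refine_coalition(k6, sprintf("k%d", 1:6), "k1", cfg)
  expect_equal(co$members, sprintf("k%d", 1:6))
  expect_equal(co$stats$degree_density, 1)
  expect_equal(co$stats$diameter, 1)

  # bridged blocks: the far bridge endpoint has within-degree 1 and is pruned
  fx <- bridged_blocks()
  co <- refine_coalition(fx$graph, c(fx$block1, "p07"), "p02", cfg)
  expect_equal(co$members, fx$block1)
  expect_equal(co$stats$edge_density, 0.8)

  # sparse star: pruning bottoms out below feasibility -> failure, confirmed
  # by brute force (no feasible subset of any size exists in the star)
  star <- g_edges("h", "a", "h", "b", "h", "c", "h", "d")
  expect_null(refine_coalition(star, igraph::V(star)$name, "h", cfg))
  expect_length(oracle_feasible_subsets(star, igraph::V(star)$name, cfg), 0)

  # candidate below min_size fails outright
  expect_null(refine_coalition(star, c("h", "a"), "h", cfg))
})

test_that("refinement errors on inconsistent preconditions", {
  k4 <- g_complete(c("a", "b", "c", "d"))
  expect_error(refine_coalition(k4, c("a", "b"), "z"), "member of")
  expect_error(refine_coalition(k4, c("a", "b", "z"), "a"), "not in the graph")
  expect_error(refine_coalition(k4, c("a", "b", "c"), "a", active = c("a", "b")),
               "active")
})

test_that("the bridged two-block fixture resolves to its Nash partition", {
  fx <- bridged_blocks()
  cover <- nash_pdc(fx$graph)
  expect_length(cover$coalitions, 2)
  sets <- cover_sets(cover)
  expect_setequal(sets[[1]], fx$block1)
  expect_setequal(sets[[2]], fx$block2)
  expect_length(cover$residual, 0)
  # each block meets the constraints on its own
  for (s in sets) {
    st <- subgraph_stats(fx$graph, s)
    expect_gte(st$degree_density, 0.6)
    expect_gte(st$edge_density, 0.65)
    expect_lte(st$diameter, 2)
  }
  v <- verify_cover_set(fx$graph, cover, exhaustive_residual_check = TRUE)
  expect_true(v$pass)
})

test_that("a lone clique forms a single coalition with empty residual", {
  k5 <- g_complete(sprintf("q%d", 1:5))
  cover <- nash_pdc(k5)
  expect_length(cover$coalitions, 1)
  expect_setequal(cover$coalitions[[1]]$members, sprintf("q%d", 1:5))
  expect_length(cover$residual, 0)
})

test_that("detection is deterministic, partitions the vertex set, and is sound", {
  cfg <- pdc_config()
  set.seed(11)
  for (rep in 1:12) {
    g <- generate_er(sample(8:16, 1), runif(1, 0.2, 0.6),
                     seed = sample.int(1e6, 1))
    c1 <- nash_pdc(g, cfg)
    c2 <- nash_pdc(g, cfg)
    # determinism, including coalition order
    expect_identical(cover_sets(c1), cover_sets(c2))
    expect_identical(c1$residual, c2$residual)

    # partition property
    members <- unlist(cover_sets(c1))
    expect_equal(anyDuplicated(members), 0)
    expect_setequal(c(members, c1$residual), igraph::V(g)$name)

    # soundness of every emitted coalition
    for (co in c1$coalitions) {
      expect_gte(length(co$members), cfg$min_size)
      expect_gte(co$stats$degree_density, cfg$lambda)
      expect_gte(co$stats$edge_density, cfg$gamma)
      expect_lte(co$stats$diameter, cfg$p)
      # the diameter bound confines a coalition to its proposer's p-ball
      expect_true(all(co$members %in%
                        p_neighborhood(g, co$proposer, cfg$p, closed = TRUE)))
    }
  }
})

test_that("tightening the edge-density floor keeps emitted coalitions feasible at the looser one", {
  set.seed(23)
  loose <- pdc_config(gamma = 0.65)
  tight <- pdc_config(gamma = 0.8)
  for (rep in 1:5) {
    g <- generate_er(14, 0.45, seed = sample.int(1e6, 1))
    ct <- nash_pdc(g, tight)
    for (co in ct$coalitions) {
      expect_gte(co$stats$edge_density, tight$gamma)
      expect_true(oracle_feasible(g, co$members, loose))
    }
  }
})

test_that("the verifier names the violated property", {
  fx <- bridged_blocks()
  cfg <- pdc_config()

  # overlapping coalitions -> (b)
  v <- verify_cover_set(fx$graph, list(fx$block1, c("p01", fx$block2)),
                        config = cfg)
  expect_false(v$pass)
  expect_true("b" %in% v$violations$property)

  # a feasible block left in the residual -> (g) under the exhaustive check
  v <- verify_cover_set(fx$graph, list(fx$block1), config = cfg,
                        exhaustive_residual_check = TRUE)
  expect_false(v$pass)
  expect_true("g" %in% v$violations$property)

  # a sparse set breaks the density floors -> (e): p01-p02 is a removed
  # matching edge, so {p01, p02, p03} is a path with alpha = 1/2 < lambda
  v <- verify_cover_set(fx$graph, list(c("p01", "p02", "p03")), config = cfg)
  expect_false(v$pass)
  expect_true("e" %in% v$violations$property)

  # members outside the vertex set -> (c)
  v <- verify_cover_set(fx$graph, list(c(fx$block1, "ghost")), config = cfg)
  expect_true("c" %in% v$violations$property)

  # the engine's own output always verifies
  v <- verify_cover_set(fx$graph, nash_pdc(fx$graph))
  expect_true(v$pass)
})

test_that("tidy and glance summarise a cover", {
  fx <- bridged_blocks()
  cover <- nash_pdc(fx$graph)
  td <- tidy(cover)
  expect_equal(nrow(td), 2)
  expect_equal(td$size, c(6L, 6L))
  expect_equal(td$edge_density, c(0.8, 0.8))
  gl <- glance(cover)
  expect_equal(gl$n_coalitions, 2)
  expect_equal(gl$coverage, 1)
  expect_equal(gl$n_residual, 0)
})
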