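test_that("NMI closed forms: identity, independence, trivial partitions", {
  a <- data.frame(node = 1:4, cls = c("x", "x", "y", "y"))
  expect_equal(nmi(a, a), 1)

  # crossing pairs: every joint count is 1 and the numerator vanishes
  b <- data.frame(node = 1:4, cls = c("u", "v", "u", "v"))
  expect_equal(nmi(a, b), 0)

  # both single-class: 0/0 convention -> identical partitions -> 1
  one <- data.frame(node = 1:4, cls = "all")
  expect_equal(nmi(one, one), 1)

  expect_error(nmi(a, data.frame(node = 2:5, cls = "q")), "same set of nodes")
  expect_error(nmi(data.frame(node = c(1, 1, 2), cls = c("a", "b", "c")), a),
               "not a partition")
})

test_that("NMI matches an independent entropy oracle and is symmetric", {
  set.seed(31)
  nodes <- sprintf("v%02d", 1:20)
  for (rep in 1:20) {
    a <- random_partition(nodes, sample(2:6, 1))
    b <- random_partition(nodes, sample(2:6, 1))
    ma <- stats::setNames(as.character(a$cls), a$node)
    mb <- stats::setNames(as.character(b$cls), b$node)
    expect_equal(nmi(a, b), oracle_nmi(ma, mb), tolerance = 1e-12)
    expect_equal(nmi(a, b), nmi(b, a), tolerance = 1e-15)
    expect_equal(nmi(a, a), 1, tolerance = 1e-12)
  }
})

test_that("contingency tables count shared members", {
  expect_equal(contingency(list(c("a", "b")), list(c("a", "b")))$t,
               matrix(2L, 1, 1))
  expect_equal(contingency(list(c("a", "b", "c")), list(c("b", "c", "d")))$t,
               matrix(2L, 1, 1))
  expect_equal(contingency(list(c("a", "b")), list(c("x", "y")))$t,
               matrix(0L, 1, 1))
  tab <- contingency(list(c("a", "b"), c("c")), list(c("a", "c"), c("b")))
  expect_equal(tab$ref_sizes, c(2L, 1L))
  expect_equal(tab$col_sums, c(2L, 1L))
})

test_that("the matching score is the geometric mean of directional overlaps", {
  same <- list(c("a", "b", "c"), c("d", "e"))
  ms <- matching_score(same, same)
  expect_equal(ms$S, 1)
  expect_equal(ms$T, 1)
  expect_equal(ms$D, 1)

  ms <- matching_score(list(c("a", "b", "c")), list(c("b", "c", "d")))
  expect_equal(ms$D, 0.5, tolerance = 1e-12)

  ms <- matching_score(list(c("a", "b"), c("c", "d")), list(c("a", "b")))
  expect_equal(ms$S, 0.5)
  expect_equal(ms$T, 1)
  expect_equal(ms$D, sqrt(0.5), tolerance = 1e-12)
  expect_equal(ms$D^2, ms$S * ms$T, tolerance = 1e-12)
})

test_that("Sn, PPV and Acc reproduce their closed-form extremes", {
  perfect <- sn_ppv_acc(contingency(list(c("a", "b")), list(c("a", "b"))))
  expect_equal(perfect$Sn, 1)
  expect_equal(perfect$PPV, 1)
  expect_equal(perfect$Acc, 1)

  # every protein its own cluster: PPV maximal, Sn = 1/4
  singletons <- as.list(c("a", "b", "c", "d"))
  ref <- list(c("a", "b", "c", "d"))
  sp <- sn_ppv_acc(contingency(singletons, ref))
  expect_equal(sp$Sn, 0.25, tolerance = 1e-12)
  expect_equal(sp$PPV, 1, tolerance = 1e-12)
  expect_equal(sp$Acc, 0.5, tolerance = 1e-12)

  # one grand cluster over reference complexes of sizes 3 and 1
  grand <- list(c("a", "b", "c", "d"))
  ref2 <- list(c("a", "b", "c"), "d")
  sp <- sn_ppv_acc(contingency(grand, ref2))
  expect_equal(sp$Sn, 1, tolerance = 1e-12)
  expect_equal(sp$PPV, 0.75, tolerance = 1e-12)
  expect_equal(sp$Acc, sqrt(3) / 2, tolerance = 1e-12)

  expect_error(sn_ppv_acc(contingency(list("x"), list("y"))), "undefined")
})

test_that("Sn ignores splits of clusters that are no reference's best match", {
  ref <- list(c("a", "b", "c", "d"), c("e", "f"))
  pred <- list(c("a", "b", "c", "d"), c("e", "f", "g"), c("a", "e"))
  split_pred <- list(c("a", "b", "c", "d"), c("e", "f", "g"), "a", "e")
  sn1 <- sn_ppv_acc(contingency(pred, ref))$Sn
  sn2 <- sn_ppv_acc(contingency(split_pred, ref))$Sn
  expect_equal(sn1, sn2, tolerance = 1e-15)
})

test_that("connectivity density is within-degree mass over total edges", {
  # triangle abc inside a 10-edge graph
  g <- g_edges(
    "a", "b", "b", "c", "c", "a",          # the module
    "a", "x", "b", "y", "c", "z",
    "x", "y", "y", "z", "z", "w", "w", "x"
  )
  expect_equal(igraph::ecount(g), 10)
  expect_equal(connectivity_density(g, c("a", "b", "c")), 0.6)

  # module with no internal edges
  expect_equal(connectivity_density(g, c("x", "z")), 0)

  # whole graph: handshake lemma
  expect_equal(connectivity_density(g, igraph::V(g)$name), 2)

  expect_error(connectivity_density(ppi_network(nodes = c("a", "b")), "a"),
               "no edges")
})

test_that("module shifts preserve size and draw forced replacements", {
  # triangle module plus one outside vertex adjacent to all members:
  # whichever member is removed, the only eligible replacement is d
  g <- g_edges("a", "b", "b", "c", "c", "a", "d", "a", "d", "b", "d", "c")
  for (s in 1:5) {
    shifted <- shift_module(g, c("a", "b", "c"), 0.3, seed = s)
    expect_length(shifted, 3)
    expect_true("d" %in% shifted)
    expect_length(setdiff(shifted, c("a", "b", "c", "d")), 0)
  }
  expect_identical(shift_module(g, c("a", "b", "c"), 0.3, seed = 4),
                   shift_module(g, c("a", "b", "c"), 0.3, seed = 4))

  # shortfall: no outside vertex adjacent to the kept members
  lone <- g_edges("a", "b")
  expect_error(shift_module(lone, c("a", "b"), 0.4, seed = 1),
               "need 1, found 0")
  expect_error(shift_module(g, c("a", "b"), 1.5), "fraction")
})

test_that("shifting a dense planted module lowers its connectivity density", {
  net <- generate_gn(0.2, seed = 91)
  mod <- net$truth$node[net$truth$module == "m01"]
  d0 <- connectivity_density(net$graph, mod)
  shifted <- vapply(1:40, function(i) {
    connectivity_density(net$graph, shift_module(net$graph, mod, 0.2, seed = i))
  }, numeric(1))
  expect_lt(mean(shifted), d0)
})

test_that("evaluate_complexes aggregates the structural metrics", {
  pred <- list(c("a", "b", "c"), c("x", "y"))
  ref <- list(c("a", "b", "c"), c("x", "y", "z"))
  g <- g_edges("a", "b", "b", "c", "c", "a", "x", "y", "y", "z")
  ev <- evaluate_complexes(pred, ref, graph = g)
  expect_equal(ev$n_pred, 2)
  expect_equal(ev$n_ref, 2)
  expect_equal(ev$D, matching_score(pred, ref)$D)
  expect_equal(ev$Acc, sn_ppv_acc(contingency(pred, ref))$Acc)
  expect_true(ev$mean_connectivity_density > 0)
})
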