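# a diamond with one cheap arm and one dearer arm: effect gene a is regulated
# by b and c, both regulated by d; c regulates one extra gene so its edge
# costs slightly more
diamond_net <- function() {
  net <- network()
  for (g in c("a", "b", "c", "d", "e")) net <- add_gene_product(net, g)
  net |>
    add_regulation("r1", "b_p", "a", "transcriptional", "+") |>
    add_regulation("r2", "c_p", "a", "transcriptional", "+") |>
    add_regulation("r3", "d_p", "b", "transcriptional", "+") |>
    add_regulation("r4", "d_p", "c", "transcriptional", "-") |>
    add_regulation("r5", "c_p", "e", "transcriptional", "+")
}

test_that("a unique shortest path is the sole result at offset zero", {
  net <- network() |> add_gene_product("a") |> add_gene_product("tf") |>
    add_regulation("r1", "tf_p", "a", "transcriptional", "+")
  g1 <- build_metreg_graph("a", net)
  p <- enumerate_paths(g1, "a", "tf", offset = 0)
  expect_equal(nrow(p), 1)
  expect_equal(p$n_edges, 1)
  expect_false(attr(p, "truncated"))
})

test_that("the offset admits slightly longer alternatives", {
  g1 <- build_metreg_graph("a", diamond_net())
  # arm costs: via b = 1.15 + 1.15 = 2.30; via c = 1.20 + 1.15 = 2.35
  both <- enumerate_paths(g1, "a", "d", offset = 0.5)
  expect_equal(nrow(both), 2)
  expect_equal(both$total_cost, c(2.3, 2.35))
  only <- enumerate_paths(g1, "a", "d", offset = 0.02)
  expect_equal(nrow(only), 1)
  expect_equal(only$total_cost, min(both$total_cost))
  # parity: ++ vs -+ arms
  expect_setequal(both$parity, c("+", "-"))
})

test_that("an absent terminus yields an empty result", {
  g1 <- build_metreg_graph("a", diamond_net())
  expect_equal(nrow(enumerate_paths(g1, "a", "zz", offset = 2)), 0)
})

test_that("enumeration equals exhaustive search on a random graph", {
  net <- generate_network(synth_params(seed = 6))
  lmap <- logical_node_map(net)
  eff <- unique(unname(lmap))[1]
  g1 <- build_metreg_graph(eff, net, C_max = 6)
  targets <- setdiff(g1$nodes$id, eff)
  for (tm in targets[seq_len(min(4, length(targets)))]) {
    mine <- enumerate_paths(g1, eff, tm, offset = 1.5,
                            max_paths = 10000)
    ref <- oracle_paths(g1, eff, tm, offset = 1.5)
    expect_sets_equal(
      vapply(mine$steps, path_edge_key, character(1)),
      vapply(ref, function(r) path_edge_key(g1$edges[r$idx, ]), character(1)))
  }
})

test_that("parity consistency follows the sign algebra", {
  expect_true(parity_consistent("+", "up", "up"))
  expect_false(parity_consistent("+", "up", "down"))
  expect_true(parity_consistent("-", "up", "down"))
  expect_false(parity_consistent("-", "down", "down"))
  expect_true(parity_consistent("ambiguous", "up", "down"))
  expect_true(parity_consistent("ambiguous", "down", "down"))
  expect_error(parity_consistent("+", "unspecified", "up"), "directions")
})

test_that("path parity is the sign product with absorbing ambiguity", {
  for (k in 1:6) {
    combos <- expand.grid(rep(list(c("+", "-", "ambiguous")), k),
                          stringsAsFactors = FALSE)
    for (i in seq_len(nrow(combos))) {
      signs <- unlist(combos[i, ])
      expected <- if (any(signs == "ambiguous")) "ambiguous" else
        if (sum(signs == "-") %% 2) "-" else "+"
      expect_identical(metregr:::path_parity(signs), expected)
    }
  }
})

test_that("directed filtering unions kept paths and reports the unreached", {
  net <- diamond_net()
  g1 <- build_metreg_graph("a", net, input_entities = c("a", "d"))
  g2 <- filter_directed(g1, c("d", "e"))
  # e regulates no path to a; it is unconnected
  expect_identical(g2$unconnected, "e")
  expect_equal(nrow(g2$pairs), 1)
  # union of both arm paths
  expect_setequal(g2$nodes$id, c("a", "b", "c", "d"))
  got_edges <- paste(g2$edges$from, g2$edges$to)
  path_nodes <- unique(unlist(purrr::map(g2$paths$steps,
                                         ~ c(.x$from, .x$to))))
  expect_setequal(g2$nodes$id, path_nodes)
})

test_that("parity filtering prunes inconsistent paths when over budget", {
  net <- diamond_net()
  g1 <- build_metreg_graph("a", net, input_entities = c("a", "d"))
  conds <- target_spec("d", "condition", "up")
  effs <- target_spec("a", "effect", "up")
  # both arms kept when within budget
  g2 <- filter_directed(g1, conds, effs, offset = 2, max_paths = 5)
  expect_equal(nrow(g2$paths), 2)
  expect_equal(sum(g2$paths$consistent), 1)
  expect_equal(nrow(g2$consistent_pairs), 1)
  # over budget: the consistent path survives
  g2b <- filter_directed(g1, conds, effs, offset = 2, max_paths = 1)
  expect_equal(nrow(g2b$paths), 1)
  expect_true(g2b$paths$consistent)
  expect_equal(g2b$paths$parity, "+")
})

test_that("the minimum-cost path is always kept when any path is kept", {
  net <- generate_network(synth_params(seed = 8))
  lmap <- logical_node_map(net)
  eff <- unique(unname(lmap))[1]
  g1 <- build_metreg_graph(eff, net, C_max = 8)
  for (tm in setdiff(g1$nodes$id, eff)[1:3]) {
    for (mp in c(1, 3)) {
      g2 <- filter_directed(g1, tm, offset = 2, max_paths = mp)
      if (!nrow(g2$paths)) next
      expect_lte(min(g2$paths$total_cost[g2$paths$terminus == tm]),
                 path_cost(g1, eff, tm) + 1e-9)
      expect_true(all(g2$paths$total_cost <=
                        path_cost(g1, eff, tm) + 2 + 1e-9))
    }
  }
})

# hub regulating three target genes; a fourth target sits apart
hub_net <- function() {
  net <- network()
  for (g in c("t1", "t2", "t3", "t4", "hub", "solo")) {
    net <- add_gene_product(net, g)
  }
  net |>
    add_regulation("h1", "hub_p", "t1", "transcriptional", "+") |>
    add_regulation("h2", "hub_p", "t2", "transcriptional", "+") |>
    add_regulation("h3", "hub_p", "t3", "transcriptional", "-") |>
    add_regulation("s1", "solo_p", "t4", "transcriptional", "+")
}

test_that("influence scores apply the printed sum-plus-penalty formula", {
  net <- hub_net()
  targets <- c("t1", "t2", "t3", "t4")
  g1 <- build_metreg_graph(targets, net, mode = "undirected")
  sc <- score_influencers(g1)
  hub <- sc[sc$entity == "hub", ]
  # each edge t_i -> hub costs 1 + (|Regs_ti| + |G_hub|)/20 = 1 + 4/20;
  # hub reaches 3 of 4 targets: 3 * 1.2 + 1.5 * 20 * 1
  expect_equal(hub$n_reached, 3)
  expect_equal(hub$score, 3 * 1.2 + 1.5 * 20 * 1)
  # solo reaches only t4: not scored
  expect_false("solo" %in% sc$entity)
  expect_error(score_influencers(g1, targets = "t1"), "at least two")
})

test_that("ranking is ascending with ties broken by breadth then id", {
  ranked <- score_influencers(
    build_metreg_graph(c("t1", "t2", "t3", "t4"), hub_net(),
                       mode = "undirected"))
  expect_equal(ranked$score, sort(ranked$score))
  expect_lte(nrow(attr(ranked, "top_ten")), 10)
})

test_that("greedy covering follows the printed accumulation rule", {
  fake <- tibble::tibble(
    entity = c("A", "B", "C"),
    score = c(10, 12, 15),
    n_reached = c(2L, 1L, 1L),
    reached = list(c("t1", "t2"), "t2", "t3"),
    per_target_cost = list(c(t1 = 5, t2 = 5), c(t2 = 12), c(t3 = 15)))
  attr(fake, "targets") <- c("t1", "t2", "t3")
  cov <- covering_set(fake)
  expect_identical(cov$cover$entity, c("A", "C"))
  expect_identical(cov$covered, c("t1", "t2", "t3"))
  expect_identical(cov$uncovered, character())
  # first influencer covering everything ends the walk immediately
  fake2 <- fake
  fake2$reached[[1]] <- c("t1", "t2", "t3")
  expect_identical(covering_set(fake2)$cover$entity, "A")
  # exhausted empty ranking
  cov0 <- covering_set(fake[0, ], targets = c("t1", "t2"))
  expect_equal(nrow(cov0$cover), 0)
  expect_identical(cov0$uncovered, c("t1", "t2"))
})

test_that("undirected filtering posits the covering set as conditions", {
  net <- hub_net()
  targets <- c("t1", "t2", "t3", "t4")
  g1 <- build_metreg_graph(targets, net, mode = "undirected")
  res <- filter_undirected(g1)
  expect_true("hub" %in% res$cover$entity)
  # solo reaches a single target so it is never scored: t4 stays uncovered
  expect_setequal(res$covered, c("t1", "t2", "t3"))
  expect_identical(res$uncovered, "t4")
  expect_true("t4" %in% res$g2$unconnected)
  g2 <- res$g2
  expect_true(all(c("t1", "t2", "t3") %in% g2$paths$root))
})

test_that("a target can be its own best influencer", {
  net <- network()
  for (g in c("t1", "t2", "t3")) net <- add_gene_product(net, g)
  net <- net |>
    add_regulation("r1", "t1_p", "t2", "transcriptional", "+") |>
    add_regulation("r2", "t1_p", "t3", "transcriptional", "+")
  g1 <- build_metreg_graph(c("t1", "t2", "t3"), net, mode = "undirected")
  res <- filter_undirected(g1)
  expect_true("t1" %in% res$scores$entity)
  expect_true("t1" %in% res$cover$entity)
})

test_that("mutually unreachable targets yield an empty cover", {
  net <- network()
  for (g in c("t1", "t2")) net <- add_gene_product(net, g)
  g1 <- build_metreg_graph(c("t1", "t2"), net, mode = "undirected")
  res <- filter_undirected(g1)
  expect_equal(nrow(res$cover), 0)
  expect_setequal(res$g2$unconnected, c("t1", "t2"))
})

test_that("the path report names every pair and flags consistency", {
  net <- diamond_net()
  g1 <- build_metreg_graph("a", net, input_entities = c("a", "d"))
  g2 <- filter_directed(g1, target_spec("d", "condition", "up"),
                        target_spec("a", "effect", "up"))
  rep <- path_report(g2)
  expect_true(any(grepl("a -> d", rep, fixed = TRUE)))
  expect_true(any(grepl("[consistent]", rep, fixed = TRUE)))
  expect_true(any(grepl("[inconsistent]", rep, fixed = TRUE)))
})
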