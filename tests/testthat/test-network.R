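# brute-force edge oracle: all node pairs sharing >= 1 non-abundant
# metabolite across their reactions, plus within-reaction cliques
oracle_een_edges <- function(reactions, abundant) {
  node_of <- function(i) {
    if (length(reactions$enzymes[[i]]) == 0L)
      paste0("RXN:", reactions$reaction_id[[i]])
    else reactions$enzymes[[i]]
  }
  n <- nrow(reactions)
  edges <- character(0)
  add <- function(a, b) {
    if (a != b)
      edges <<- c(edges, paste(min(a, b), max(a, b), sep = "|"))
  }
  for (i in seq_len(n)) {
    m_i <- setdiff(reactions$metabolites[[i]], abundant)
    for (a in node_of(i)) for (b in node_of(i)) add(a, b)
    for (j in seq_len(n)) {
      if (i == j) next
      if (length(intersect(m_i,
                           setdiff(reactions$metabolites[[j]],
                                   abundant))) > 0L)
        for (a in node_of(i)) for (b in node_of(j)) add(a, b)
    }
  }
  sort(unique(edges))
}

net_edges <- function(net) {
  el <- igraph::as_edgelist(net$graph)
  sort(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]), sep = "|"))
}

test_that("abundant metabolites never create edges", {
  rt <- reaction_table(c("r1", "r2"),
                       list("E1", "E2"),
                       list(c("atp", "m1"), c("atp", "m2")))
  net <- build_een(rt, abundant = "atp")
  expect_equal(igraph::ecount(net$graph), 0)
  # dropping atp from the exclusion list can only add edges
  net2 <- build_een(rt, abundant = character(0))
  expect_true(all(net_edges(net) %in% net_edges(net2)))
  expect_gt(igraph::ecount(net2$graph), 0)
})

test_that("co-catalyzing enzymes are connected even without shared metabolites", {
  rt <- reaction_table("r1", list(c("E1", "E2")), list("m1"))
  net <- build_een(rt, abundant = character(0))
  expect_true(igraph::are_adjacent(net$graph, "E1", "E2"))
})

test_that("orphan reactions become pseudo-enzyme nodes with metabolite edges", {
  rt <- reaction_table(c("r1", "r2"),
                       list(character(0), "E1"),
                       list(c("m1"), c("m1", "m2")))
  net <- build_een(rt)
  expect_true("RXN:r1" %in% net$nodes)
  expect_true(net$is_pseudo[["RXN:r1"]])
  expect_false(net$is_pseudo[["E1"]])
  expect_true(igraph::are_adjacent(net$graph, "RXN:r1", "E1"))
})

test_that("network construction matches the brute-force shared-metabolite oracle", {
  set.seed(21)
  for (rep in 1:6) {
    n_rxn <- 6
    mets <- sprintf("m%d", 1:5)
    rt <- reaction_table(
      sprintf("r%d", 1:n_rxn),
      lapply(1:n_rxn, function(i)
        if (stats::runif(1) < 0.25) character(0)
        else sample(sprintf("E%d", 1:5), sample(1:2, 1))),
      lapply(1:n_rxn, function(i) sample(mets, sample(1:3, 1))))
    abundant <- if (rep %% 2 == 0) "m1" else character(0)
    expect_equal(net_edges(build_een(rt, abundant)),
                 oracle_een_edges(rt, abundant))
  }
})

test_that("neighbor levels partition reachable nodes by exact distance", {
  path3 <- graph_as_network(c("A", "B", "C"),
                            rbind(c("A", "B"), c("B", "C")))
  expect_identical(neighbors_at_level(path3, "A", 2), "C")
  tri <- graph_as_network(c("A", "B", "C"),
                          rbind(c("A", "B"), c("B", "C"), c("A", "C")))
  for (v in c("A", "B", "C"))
    expect_length(neighbors_at_level(tri, v, 2), 0)
  # random graphs against the hand-rolled BFS
  for (seed in 1:6) {
    g <- random_graph(20, 0.15, seed = 30 + seed)
    net <- graph_as_network(g$nodes, g$edges)
    for (v in sample(g$nodes, 5)) {
      d <- oracle_bfs_levels(g$edges, g$nodes, v)
      for (k in 1:3)
        expect_setequal(neighbors_at_level(net, v, k),
                        names(d)[!is.na(d) & d == k])
    }
  }
  # levels are disjoint and cover the connected component
  g <- random_graph(15, 0.2, seed = 99)
  net <- graph_as_network(g$nodes, g$edges)
  v <- g$nodes[1]
  lv <- lapply(1:14, function(k) neighbors_at_level(net, v, k))
  expect_equal(anyDuplicated(unlist(lv)), 0)
  comp <- igraph::subcomponent(net$graph, v)
  expect_setequal(c(v, unlist(lv)), names(comp))
})

test_that("a lone connected pair has full topological overlap", {
  net <- graph_as_network(c("X", "Y"), rbind(c("X", "Y")))
  W <- gtom(net, 1)
  expect_equal(W["X", "Y"], 1)   # (0 + 1) / (1 + 1 - 1)
})

test_that("gtom matches the set-based oracle on random graphs", {
  for (seed in 1:12) {
    g <- random_graph(sample(6:15, 1), stats::runif(1, 0.1, 0.4),
                      seed = 50 + seed)
    net <- graph_as_network(g$nodes, g$edges)
    for (m in 1:2) {
      W <- gtom(net, m)
      expect_equal(W, oracle_gtom(g$edges, g$nodes, m))
      expect_true(all(W >= 0 & W <= 1))
      expect_equal(W, t(W))
      expect_true(all(diag(W) == 1))
    }
  }
})

test_that("isolated node pairs have zero overlap weight", {
  net <- graph_as_network(c("A", "B", "C"), rbind(c("A", "B")))
  W <- gtom(net, 1)
  expect_equal(W["A", "C"], 0)
  expect_equal(W["C", "C"], 1)
})

test_that("connecting two nodes never lowers their first-order overlap", {
  for (seed in 1:6) {
    g <- random_graph(10, 0.2, seed = 70 + seed)
    net <- graph_as_network(g$nodes, g$edges)
    W <- gtom(net, 1)
    # pick a currently unconnected pair and wire it
    D <- igraph::distances(net$graph)
    free <- which(D > 1 & upper.tri(D), arr.ind = TRUE)
    if (nrow(free) == 0L) next
    pick <- free[sample(nrow(free), 1), ]
    x <- g$nodes[pick[1]]; y <- g$nodes[pick[2]]
    net2 <- graph_as_network(g$nodes, rbind(g$edges, c(x, y)))
    expect_gte(gtom(net2, 1)[x, y], W[x, y])
  }
})

test_that("reaction tables and networks survive disk round trips", {
  rt <- reaction_table(c("r1", "r2"),
                       list(c("E1", "E2"), character(0)),
                       list(c("m1", "m2"), "m2"))
  path <- tempfile(fileext = ".tsv")
  write_reactions(rt, path)
  back <- read_reactions(path)
  expect_equal(back$reaction_id, rt$reaction_id)
  expect_equal(back$enzymes, rt$enzymes)
  expect_equal(back$metabolites, rt$metabolites)

  net <- build_een(rt, abundant = character(0))
  ep <- tempfile(); np <- tempfile()
  write_network(net, ep, np)
  nodes <- utils::read.delim(np)
  expect_setequal(nodes$node, net$nodes)
  expect_equal(sum(nodes$is_pseudo), 1)

  expect_error(reaction_table(c("r1", "r1"), list("E", "F"),
                              list("m", "m")), "duplicate")
  expect_error(reaction_table(c("r1", "r2"),
                              list("E", "F"), list("m", character(0))),
               "empty metabolite")
})
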