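test_that("expression similarity is absolute rank correlation", {
  expr <- rbind(a = c(1, 3, 2, 5, 4),
                b = c(1, 3, 2, 5, 4),
                rev = c(5, 3, 4, 1, 2),
                flat = c(2, 2, 2, 2, 2),
                x = c(2.5, 1, 4, 3, 6),
                y = c(1, 2, 2.5, 5, 4))
  expect_equal(expr_similarity("a", "b", expr), 1)
  expect_equal(expr_similarity("a", "rev", expr), 1)   # rho = -1, |rho| = 1
  expect_equal(expr_similarity("x", "y", expr),
               abs(oracle_spearman(expr["x", ], expr["y", ])))
  expect_equal(expr_similarity("a", "flat", expr), 0)  # undefined -> 0
  expect_error(expr_similarity("a", "nope", expr), "absent")
})

test_that("phylogenetic similarity is Pearson on presence vectors", {
  phy <- rbind(a = c(1, 0, 1, 1, 0, 0),
               b = c(1, 0, 1, 1, 0, 0),
               comp = c(0, 1, 0, 0, 1, 1),
               ones = c(1, 1, 1, 1, 1, 1))
  expect_equal(phyl_similarity("a", "b", phy), 1)
  expect_equal(phyl_similarity("a", "comp", phy), -1)
  expect_equal(phyl_similarity("a", "ones", phy), 0)  # constant -> 0
  set.seed(31)
  for (i in 1:5) {
    m <- rbind(x = stats::rbinom(10, 1, 0.5), y = stats::rbinom(10, 1, 0.5))
    if (stats::sd(m["x", ]) == 0 || stats::sd(m["y", ]) == 0) next
    expect_equal(phyl_similarity("x", "y", m),
                 oracle_pearson(m["x", ], m["y", ]))
  }
})

# a deterministic scorer keyed on gene pairs, for aggregation tests
table_scorer <- function(tbl, default = NA_real_) {
  function(x, y) {
    v <- tbl[pair_key(x, y)]
    if (is.na(v)) default else unname(v)
  }
}

test_that("relatedness is the mean over exact-level neighbors", {
  star <- graph_as_network(c("P", "N1", "N2", "N3", "N4"),
                           cbind("P", c("N1", "N2", "N3", "N4")))
  tbl <- stats::setNames(c(0.9, 0.1, 0.5, 0.3),
                         pair_key("cand", c("N1", "N2", "N3", "N4")))
  sc <- table_scorer(tbl)
  expect_equal(rel_score(star, "P", "cand", sc, 1),
               mean(c(0.9, 0.1, 0.5, 0.3)))
  # single neighbor reduces to the pairwise score
  pair_net <- graph_as_network(c("P", "N1"), rbind(c("P", "N1")))
  expect_equal(rel_score(pair_net, "P", "cand",
                         table_scorer(stats::setNames(0.42,
                                                      pair_key("cand", "N1"))),
                         1), 0.42)
  # all-equal scores return that constant
  expect_equal(rel_score(star, "P", "cand",
                         function(x, y) 0.7, 1), 0.7)
  # neighbors without data are skipped, empty level scores 0
  expect_equal(rel_score(star, "P", "cand",
                         table_scorer(stats::setNames(0.8, pair_key("cand", "N1"))),
                         1), 0.8)
  expect_equal(rel_score(star, "P", "cand", function(x, y) NA_real_, 1), 0)
  expect_equal(rel_score(star, "P", "cand", function(x, y) 1, 3), 0)
})

test_that("uniform weights collapse the weighted form onto the plain mean", {
  for (seed in 1:8) {
    g <- random_graph(12, 0.25, seed = 80 + seed)
    net <- graph_as_network(g$nodes, g$edges)
    set.seed(seed)
    vals <- stats::setNames(stats::runif(length(g$nodes)),
                            pair_key("cand", g$nodes))
    sc <- table_scorer(vals)
    ones <- matrix(1, length(g$nodes), length(g$nodes),
                   dimnames = list(g$nodes, g$nodes))
    for (v in sample(g$nodes, 4)) for (k in 1:2) {
      expect_equal(gtom_rel_score(net, v, "cand", sc, k, ones),
                   rel_score(net, v, "cand", sc, k), tolerance = 1e-12)
    }
  }
})

test_that("weighted relatedness follows the explicit weighted sum", {
  star <- graph_as_network(c("P", "N1", "N2", "N3"),
                           cbind("P", c("N1", "N2", "N3")))
  w <- matrix(0, 4, 4, dimnames = list(c("P", "N1", "N2", "N3"),
                                       c("P", "N1", "N2", "N3")))
  w["P", c("N1", "N2", "N3")] <- c(0.5, 0.25, 0.25)
  tbl <- stats::setNames(c(0.8, 0.4, 0.2), pair_key("cand", c("N1", "N2", "N3")))
  sc <- table_scorer(tbl)
  manual <- (0.5 * 0.8 + 0.25 * 0.4 + 0.25 * 0.2) / 1
  expect_equal(gtom_rel_score(star, "P", "cand", sc, 1, w), manual)
  # a single positive weight selects that neighbor's score
  w2 <- w; w2["P", c("N2", "N3")] <- 0
  expect_equal(gtom_rel_score(star, "P", "cand", sc, 1, w2), 0.8)
  # all-zero weights flag out as 0
  w3 <- w; w3["P", ] <- 0
  expect_equal(gtom_rel_score(star, "P", "cand", sc, 1, w3), 0)
})

test_that("feature matrix has the contracted shape and neutral degenerate rows", {
  ts <- local({   # a small annotated world
    dag <- ontology_dag(
      list(bp = character(0), p1 = "bp", l1 = "p1", l2 = "p1"),
      c(bp = "BP", p1 = "BP", l1 = "BP", l2 = "BP"))
    ann <- make_ann(P = "l1", N = "l1", c1 = "l1", c2 = "l2")
    list(dag = dag, ann = ann,
         freq = build_term_frequencies(dag, ann),
         cooc = build_cooccurrence(ann))
  })
  net <- graph_as_network(c("P", "N", "Iso"), rbind(c("P", "N")))
  sc <- make_scorers(ts$dag, ts$ann, ts$freq, ts$cooc)
  pools <- list(P = c("c1", "c2"), Iso = c("c1", "c2"))
  fm <- build_feature_matrix(net, "P", pools, sc, forms = "N1",
                             truth = c(P = "c1"))
  expect_equal(nrow(fm), 2)
  expect_setequal(attr(fm, "feature_cols"), c("CAS_N1", "funsim_N1"))
  expect_equal(sum(fm$label), 1)
  expect_true(all(is.finite(as.matrix(fm[, attr(fm, "feature_cols")]))))

  # an isolated position yields a valid all-neutral row (CAS at log(eps))
  fm_iso <- build_feature_matrix(net, "Iso", pools, sc, forms = "N1",
                                 truth = c(Iso = "c1"))
  expect_equal(unname(unlist(fm_iso[1, c("CAS_N1", "funsim_N1")])),
               c(log(1e-6), 0))
  expect_error(build_feature_matrix(net, "P", list(), sc, forms = "N1"),
               "pool")
})

test_that("feature matrix agrees with direct per-pair aggregation", {
  fx <- shared_fixture(effect = 0.9)
  sc <- fixture_scorers(fx)
  pos <- fx$positions[1:3]
  pools <- stats::setNames(
    lapply(pos, function(p) c(fx$truth[[p]], sprintf("dec%03d", 1:10))), pos)
  fm <- build_feature_matrix(fx$net, pos, pools, sc,
                             forms = c("N1", "GTOM1_N1"), truth = fx$truth)
  W <- gtom(fx$net, 1)
  for (p in pos) {
    rows <- fm[fm$position == p, ]
    for (cd in sample(rows$candidate, 3)) {
      expect_equal(rows$funsim_N1[rows$candidate == cd],
                   rel_score(fx$net, p, cd, sc$funsim, 1))
      expect_equal(rows$CAS_GTOM1_N1[rows$candidate == cd],
                   log_transform(gtom_rel_score(fx$net, p, cd, sc$CAS, 1, W)))
    }
  }
})

test_that("the planted correct gene outscores decoys on coherence features", {
  fx <- shared_fixture(effect = 0.9)
  sc <- fixture_scorers(fx)
  pools <- fixture_pools(fx, n_decoy_pool = 60, seed = 2)
  fm <- build_feature_matrix(fx$net, fx$positions, pools, sc["CAS"],
                             forms = "N1", truth = fx$truth)
  # across positions, the correct gene beats the decoy median CAS almost
  # always (a distributional check, not per-row determinism)
  frac_above <- mean(vapply(unique(fm$position), function(p) {
    rows <- fm[fm$position == p, ]
    rows$CAS_N1[rows$label == 1] >
      stats::median(rows$CAS_N1[rows$label == 0])
  }, TRUE))
  expect_gt(frac_above, 0.9)
})

test_that("gene matrices survive a disk round trip", {
  m <- matrix(stats::rnorm(12), 3, 4,
              dimnames = list(c("g1", "g2", "g3"), paste0("c", 1:4)))
  path <- tempfile(fileext = ".tsv")
  write_gene_matrix(m, path)
  expect_equal(read_gene_matrix(path), m)
})
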