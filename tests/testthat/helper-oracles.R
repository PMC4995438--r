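# Independent brute-force oracles and tiny constructors used across tests.
# Oracles deliberately avoid the package's internal algorithms: paths are
# enumerated, closures iterated to a fixed point, neighborhoods built from
# edge lists by hand.

## ---- ontology oracles -------------------------------------------------

# longest root-to-term path by exhaustive DFS over child edges
oracle_level <- function(dag, term) {
  if (term == dag$root) return(0L)
  paths <- 0L
  walk <- function(t, len) {
    if (t == dag$root) {
      paths <<- max(paths, len)
      return(invisible())
    }
    for (p in dag$parents[[t]]) walk(p, len + 1L)
  }
  walk(term, 0L)
  paths
}

# transitive closure by repeated parent expansion to a fixed point
oracle_ancestors <- function(dag, term) {
  acc <- character(0)
  frontier <- dag$parents[[term]]
  repeat {
    new <- setdiff(frontier, acc)
    if (length(new) == 0L) break
    acc <- c(acc, new)
    frontier <- unique(unlist(dag$parents[new], use.names = FALSE))
  }
  sort(acc)
}

# per-term gene tally after up-propagating each gene's annotations
oracle_term_counts <- function(dag, ann) {
  counts <- stats::setNames(numeric(length(dag$terms)), dag$terms)
  for (g in names(ann$annotations)) {
    hit <- unique(unlist(lapply(ann$annotations[[g]], function(t)
      c(t, oracle_ancestors(dag, t))), use.names = FALSE))
    counts[hit] <- counts[hit] + 1
  }
  counts
}

# a random DAG: n terms in one namespace, each with 1-2 parents drawn from
# earlier terms (index order guarantees acyclicity)
random_dag <- function(n, seed) {
  set.seed(seed)
  ids <- sprintf("T%02d", seq_len(n))
  parents <- list()
  parents[[ids[1L]]] <- character(0)
  for (i in seq(2L, n)) {
    k <- sample(1:2, 1L)
    parents[[ids[i]]] <- sample(ids[seq_len(i - 1L)], min(k, i - 1L))
  }
  ontology_dag(parents, stats::setNames(rep("BP", n), ids))
}

## ---- network oracles --------------------------------------------------

# exact-distance neighbor sets from an explicit breadth-first search over an
# adjacency list (no igraph)
oracle_bfs_levels <- function(edges, nodes, start) {
  adj <- stats::setNames(lapply(nodes, function(v) {
    unique(c(edges[edges[, 1L] == v, 2L], edges[edges[, 2L] == v, 1L]))
  }), nodes)
  dist <- stats::setNames(rep(NA_integer_, length(nodes)), nodes)
  dist[[start]] <- 0L
  frontier <- start
  d <- 0L
  while (length(frontier) > 0L) {
    d <- d + 1L
    nxt <- setdiff(unique(unlist(adj[frontier], use.names = FALSE)),
                   names(dist)[!is.na(dist)])
    dist[nxt] <- d
    frontier <- nxt
  }
  dist
}

# set-based GTOM: explicit within-distance-m neighborhoods and the stated
# ratio, computed pair by pair
oracle_gtom <- function(edges, nodes, m) {
  nbhd <- lapply(stats::setNames(nodes, nodes), function(v) {
    d <- oracle_bfs_levels(edges, nodes, v)
    names(d)[!is.na(d) & d >= 1L & d <= m]
  })
  W <- matrix(0, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  for (x in nodes) for (y in nodes) {
    if (x == y) { W[x, y] <- 1; next }
    a <- as.numeric(y %in% nbhd[[x]])
    shared <- length(intersect(nbhd[[x]], nbhd[[y]]))
    den <- min(length(nbhd[[x]]), length(nbhd[[y]])) + 1 - a
    W[x, y] <- if (den == 0) 0 else (shared + a) / den
  }
  W
}

# a random simple graph as an edge matrix over sprintf-named nodes
random_graph <- function(n, p, seed) {
  set.seed(seed)
  nodes <- sprintf("n%02d", seq_len(n))
  all_pairs <- t(utils::combn(nodes, 2L))
  keep <- stats::runif(nrow(all_pairs)) < p
  list(nodes = nodes, edges = all_pairs[keep, , drop = FALSE])
}

# wrap an explicit edge list as an enzyme_network (all real enzymes)
graph_as_network <- function(nodes, edges) {
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(nodes), name = nodes)
  if (nrow(edges) > 0L) g <- igraph::add_edges(g, as.vector(t(edges)))
  g <- igraph::simplify(g)
  structure(list(graph = g, nodes = nodes,
                 is_pseudo = stats::setNames(rep(FALSE, length(nodes)),
                                             nodes)),
            class = "enzyme_network")
}

## ---- statistics oracles ------------------------------------------------

# Spearman by explicit rank-then-product-moment computation
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# Pearson from the covariance formula
oracle_pearson <- function(x, y) {
  n <- length(x)
  cov_xy <- sum((x - mean(x)) * (y - mean(y))) / (n - 1)
  cov_xy / (stats::sd(x) * stats::sd(y))
}

## ---- shared tiny fixtures ----------------------------------------------

# chain all -> a -> b -> c within one namespace
chain_dag <- function() {
  ontology_dag(list(a = character(0), b = "a", c = "b"),
               c(a = "BP", b = "BP", c = "BP"))
}

# diamond: a and b sit directly under the root; c reachable at depths 2
# (via a) and 3 (via b -> d), so its level is 3
diamond_dag <- function() {
  ontology_dag(list(a = character(0), b = character(0), d = "b",
                    c = c("a", "d")),
               c(a = "BP", b = "BP", c = "BP", d = "BP"))
}

make_ann <- function(...) {
  pairs <- list(...)
  rows <- do.call(rbind, lapply(names(pairs), function(g)
    data.frame(gene = g, term = pairs[[g]], evidence = "EXP",
               stringsAsFactors = FALSE)))
  annotation_set(rows)
}

# a small fixture bundle shared by the slower integration tests; built once
# per test run
shared_fixture <- local({
  cache <- new.env(parent = emptyenv())
  function(effect = 0.9, seed = 42) {
    key <- paste0("fx_", effect, "_", seed)
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    dir <- file.path(tempdir(), paste0("enzgap_", key))
    generate_fixture(fixture_spec(seed = seed, effect_size = effect), dir)
    fx <- load_fixture(dir)
    cache[[key]] <- fx
    fx
  }
})
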