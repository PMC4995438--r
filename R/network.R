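#' Default abundant-metabolite exclusion list
#'
#' Currency metabolites participate in a large share of reactions and would
#' produce non-function-specific edges, so they are excluded before edge
#' formation. The default list covers ATP, water, AMP, ADP, CO2, ammonium,
#' NAD(H), NADP(H) (each expanded to the oxidized and reduced id), coenzyme A,
#' L-glutamate, phosphate, diphosphate and hydrogen, as lowercase canonical
#' ids. Editable: pass any character vector of metabolite ids to
#' \code{\link{build_een}}.
#'
#' @return character vector of metabolite ids
#' @export
default_abundant_metabolites <- function() {
  c("atp", "h2o", "amp", "adp", "co2", "nh4",
    "nad", "nadh", "nadp", "nadph",
    "coa", "glu-L", "pi", "ppi", "h")
}

#' Read a reaction table
#'
#' TSV with columns \code{reaction_id}, \code{enzyme_ids} (semicolon-
#' separated, may be empty for orphan reactions) and \code{metabolite_ids}
#' (semicolon-separated, non-empty).
#'
#' @param path file path
#' @return a \code{reaction_table}: data.frame with list columns
#'   \code{enzymes} and \code{metabolites}
#' @export
read_reactions <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  stopifnot(all(c("reaction_id", "enzyme_ids", "metabolite_ids") %in% names(df)))
  reaction_table(df$reaction_id,
                 strsplit(df$enzyme_ids, ";", fixed = TRUE),
                 strsplit(df$metabolite_ids, ";", fixed = TRUE))
}

#' Construct a reaction table
#'
#' @param reaction_id character vector of unique reaction ids
#' @param enzymes list of character vectors (possibly empty) of enzyme ids
#' @param metabolites list of non-empty character vectors of metabolite ids
#' @return a \code{reaction_table}
#' @export
reaction_table <- function(reaction_id, enzymes, metabolites) {
  stopifnot(length(reaction_id) == length(enzymes),
            length(reaction_id) == length(metabolites))
  if (anyDuplicated(reaction_id)) stop("duplicate reaction ids")
  enzymes <- lapply(enzymes, function(e) unique(e[nzchar(e)]))
  metabolites <- lapply(metabolites, function(m) unique(m[nzchar(m)]))
  if (any(lengths(metabolites) == 0L))
    stop("reaction(s) with empty metabolite list")
  df <- data.frame(reaction_id = reaction_id, stringsAsFactors = FALSE)
  df$enzymes <- enzymes
  df$metabolites <- metabolites
  structure(df, class = c("reaction_table", "data.frame"))
}

#' Write a reaction table
#' @param reactions a \code{reaction_table}
#' @param path file path
#' @return invisibly, \code{path}
#' @export
write_reactions <- function(reactions, path) {
  df <- data.frame(
    reaction_id = reactions$reaction_id,
    enzyme_ids = vapply(reactions$enzymes, paste, "", collapse = ";"),
    metabolite_ids = vapply(reactions$metabolites, paste, "", collapse = ";"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Build the enzyme-enzyme network
#'
#' Nodes are enzymes; a reaction with no associated enzyme contributes a
#' pseudo-enzyme node named \code{RXN:<reaction id>}. After removing abundant
#' metabolites from every reaction, two nodes are connected when their
#' reactions share at least one remaining metabolite; all enzymes catalyzing
#' the same reaction are additionally connected as a clique. A reaction left
#' with no metabolites contributes no shared-metabolite edges (its co-enzyme
#' clique edges still apply).
#'
#' @param reactions a \code{reaction_table}
#' @param abundant metabolite ids excluded before edge formation
#' @return an \code{enzyme_network}: list with \code{graph} (igraph),
#'   \code{nodes} and \code{is_pseudo} (named logical)
#' @export
build_een <- function(reactions, abundant = default_abundant_metabolites()) {
  rxn_nodes <- mapply(function(id, enz) {
    if (length(enz) == 0L) paste0("RXN:", id) else enz
  }, reactions$reaction_id, reactions$enzymes, SIMPLIFY = FALSE)
  nodes <- unique(unlist(rxn_nodes, use.names = FALSE))
  is_pseudo <- stats::setNames(startsWith(nodes, "RXN:"), nodes)

  clique_edges <- function(members) {
    members <- unique(members)
    if (length(members) < 2L) return(NULL)
    t(utils::combn(members, 2L))
  }
  edges <- list()
  # co-enzyme edges within each reaction
  for (m in rxn_nodes) edges[[length(edges) + 1L]] <- clique_edges(m)
  # shared-metabolite edges
  metab <- lapply(reactions$metabolites, setdiff, y = abundant)
  if (any(lengths(metab) == 0L))
    message(sum(lengths(metab) == 0L),
            " reaction(s) with only abundant metabolites contribute no metabolite edges")
  all_met <- unique(unlist(metab, use.names = FALSE))
  for (m in all_met) {
    touching <- unlist(rxn_nodes[vapply(metab, function(x) m %in% x, TRUE)],
                       use.names = FALSE)
    edges[[length(edges) + 1L]] <- clique_edges(touching)
  }
  edges <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(nodes), name = nodes)
  if (!is.null(edges))
    g <- igraph::add_edges(g, as.vector(t(edges)))
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  structure(list(graph = g, nodes = nodes, is_pseudo = is_pseudo),
            class = "enzyme_network")
}

#' @export
print.enzyme_network <- function(x, ...) {
  cat("enzyme_network:", length(x$nodes), "nodes (",
      sum(x$is_pseudo), "pseudo ),", igraph::ecount(x$graph), "edges\n")
  invisible(x)
}

check_node <- function(net, node) {
  bad <- setdiff(node, net$nodes)
  if (length(bad) > 0L)
    stop("unknown network node(s): ", paste(bad, collapse = ", "))
  invisible(TRUE)
}

#' Neighbors at an exact network distance
#'
#' Nodes at exact unweighted shortest-path distance \code{k} from
#' \code{node} (breadth-first), excluding the node itself. An isolated node
#' has an empty neighbor set at every level.
#'
#' @param net an \code{enzyme_network}
#' @param node node id
#' @param k distance (1, 2 or 3)
#' @return character vector of node ids
#' @export
neighbors_at_level <- function(net, node, k) {
  check_node(net, node)
  stopifnot(length(k) == 1L, k >= 1)
  d <- igraph::distances(net$graph, v = node, to = igraph::V(net$graph))[1L, ]
  names(d)[is.finite(d) & d == k]
}

#' Generalized topological overlap (GTOM) weights
#'
#' For nodes \eqn{x \ne y} with \eqn{N_m(\cdot)} the within-distance-\eqn{m}
#' neighborhood (excluding the node itself) and \eqn{a_{xy} = 1} when the two
#' nodes are within path length \eqn{m} of each other,
#' \deqn{GTOM_m(x,y) = \frac{|N_m(x) \cap N_m(y)| + a_{xy}}{\min(|N_m(x)|, |N_m(y)|) + 1 - a_{xy}}}
#' and \eqn{GTOM_m(x,x) = 1}. The score is symmetric, lies in [0, 1], and
#' measures shared \eqn{m}-step neighborhoods against the smaller
#' neighborhood. A pair of isolated nodes scores 0.
#'
#' @param net an \code{enzyme_network}
#' @param m neighborhood order (1 or 2)
#' @return symmetric numeric matrix with node dimnames
#' @export
gtom <- function(net, m = 1) {
  stopifnot(m %in% c(1, 2))
  g <- net$graph
  if (igraph::vcount(g) == 0L) stop("empty network")
  D <- igraph::distances(g)
  A <- (is.finite(D) & D > 0 & D <= m) * 1     # m-step adjacency, no diagonal
  shared <- A %*% t(A)                          # |N_m(x) /\ N_m(y)|
  sizes <- rowSums(A)
  den <- outer(sizes, sizes, pmin) + 1 - A
  W <- (shared + A) / den
  diag(W) <- 1
  dimnames(W) <- list(net$nodes, net$nodes)
  W
}

#' Export a network as edge-list and node-attribute files
#'
#' @param net an \code{enzyme_network}
#' @param edge_path,node_path output TSV paths
#' @return invisibly, the paths written
#' @export
write_network <- function(net, edge_path, node_path) {
  el <- igraph::as_edgelist(net$graph)
  utils::write.table(data.frame(from = el[, 1L], to = el[, 2L]),
                     edge_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(node = net$nodes,
                                is_pseudo = unname(net$is_pseudo[net$nodes])),
                     node_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(edge_path, node_path))
}
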