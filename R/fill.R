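#' Iteratively fill multiple missing nodes
#'
#' Emulates the regime where a substantial fraction of network nodes have no
#' known gene. Iteration 0 assigns a seeded-random candidate to every missing
#' node. In each subsequent iteration every missing node's candidate pool is
#' re-scored with a trained combiner: the coherence scores (CAS, PAS, funsim)
#' see the genes provisionally assigned to neighboring missing nodes in the
#' previous iteration (synchronous update), while expression/phylogenetic
#' scores use known-gene neighbors only; the top-probability candidate is
#' committed when its probability exceeds \code{cutoff}, otherwise the node
#' keeps its previous assignment. Pseudo-enzyme nodes never contribute gene
#' data.
#'
#' @param net an \code{enzyme_network}
#' @param missing_nodes node ids whose genes are treated as unknown
#' @param model a \code{combiner_model} trained on the non-missing nodes
#' @param pools named list: missing node -> candidate gene pool (must contain
#'   the node's true gene for evaluation)
#' @param scorers list from \code{\link{make_scorers}}
#' @param forms score forms matching the model's feature columns
#' @param truth named character vector node -> correct gene (defaults to the
#'   node ids themselves); also resolves the genes standing at known
#'   (non-missing) nodes, which fall back to their own node id when absent
#' @param cutoff commitment probability threshold (default 0.99)
#' @param iterations number of re-scoring iterations (default 50)
#' @param seed seed for the iteration-0 random assignment
#' @param epsilon log-transform offset for CAS/PAS feature columns
#' @return a \code{fill_trajectory}: list with \code{iterations} (one
#'   data.frame per iteration: node, assigned, prob_assigned, committed,
#'   rank_correct, prob_correct), \code{assignment} (final named vector) and
#'   \code{ranking} (a \code{ranking_result} for the last iteration)
#' @export
iterative_fill <- function(net, missing_nodes, model, pools, scorers,
                           forms = c("GTOM1_N1", "GTOM1_N2"), truth = NULL,
                           cutoff = 0.99, iterations = 50, seed = 1,
                           epsilon = 1e-6) {
  check_node(net, missing_nodes)
  if (is.null(truth))
    truth <- stats::setNames(missing_nodes, missing_nodes)
  if (length(missing_nodes) == 0L) {
    return(structure(list(iterations = list(),
                          assignment = character(0), ranking = NULL),
                     class = "fill_trajectory"))
  }
  stopifnot(all(missing_nodes %in% names(pools)))

  known_nodes <- setdiff(net$nodes[!net$is_pseudo], missing_nodes)
  known_map <- stats::setNames(
    ifelse(known_nodes %in% names(truth), truth[known_nodes], known_nodes),
    known_nodes)
  coherence <- vapply(scorers, function(s)
    isTRUE(attr(s, "coherence")), TRUE)

  set.seed(seed)
  assignment <- vapply(missing_nodes, function(nd)
    sample(pools[[nd]], 1L), character(1))

  trajectory <- vector("list", iterations)
  for (it in seq_len(iterations)) {
    # node -> gene maps as of the previous iteration (synchronous update)
    map_coh <- c(known_map, assignment)
    map_plain <- known_map
    new_assignment <- assignment
    rows <- lapply(missing_nodes, function(nd) {
      cands <- pools[[nd]]
      fm <- build_feature_matrix(
        net, nd, pools[nd], scorers, forms = forms,
        truth = truth[nd],
        node_gene = map_coh, epsilon = epsilon)
      # non-coherence scorers must not see provisional assignments: recompute
      # their columns against known neighbors only
      if (any(!coherence)) {
        fm_plain <- build_feature_matrix(
          net, nd, pools[nd], scorers[!coherence], forms = forms,
          truth = truth[nd], node_gene = map_plain, epsilon = epsilon)
        plain_cols <- attr(fm_plain, "feature_cols")
        fm[plain_cols] <- fm_plain[plain_cols]
      }
      probs <- stats::setNames(predict_combiner(model, fm), cands)
      top <- names(probs)[which.max(probs)]
      committed <- probs[[top]] > cutoff
      data.frame(node = nd,
                 assigned = if (committed) top else assignment[[nd]],
                 prob_assigned = if (committed) probs[[top]]
                                 else unname(probs[assignment[[nd]]]),
                 committed = committed,
                 rank_correct = rank_candidates(probs, truth[[nd]]),
                 prob_correct = unname(probs[truth[[nd]]]),
                 stringsAsFactors = FALSE)
    })
    step <- do.call(rbind, rows)
    new_assignment <- stats::setNames(step$assigned, step$node)
    trajectory[[it]] <- step
    assignment <- new_assignment
  }
  last <- trajectory[[iterations]]
  structure(list(
    iterations = trajectory,
    assignment = assignment,
    ranking = ranking_result(last$node, last$rank_correct,
                             lengths(pools[last$node]),
                             last$prob_correct)),
    class = "fill_trajectory")
}

#' @export
print.fill_trajectory <- function(x, ...) {
  n_it <- length(x$iterations)
  cat("fill_trajectory:", length(x$assignment), "missing nodes,",
      n_it, "iterations\n")
  if (n_it > 0L) {
    last <- x$iterations[[n_it]]
    cat("  final: ", sum(last$committed), " committed, MRR ",
        round(mrr(x$ranking), 4), "\n", sep = "")
  }
  invisible(x)
}

#' Concordance between committed probability and correct-gene rank
#'
#' Spearman correlation between the probability assigned to the correct gene
#' and the reciprocal of its rank at each missing node in the final
#' iteration: positive concordance means high-probability assignments are the
#' trustworthy ones.
#'
#' @param trajectory a \code{fill_trajectory}
#' @param iteration iteration to evaluate (default: the last)
#' @return Spearman correlation in [-1, 1]
#' @export
fill_concordance <- function(trajectory,
                             iteration = length(trajectory$iterations)) {
  stopifnot(inherits(trajectory, "fill_trajectory"), iteration >= 1)
  step <- trajectory$iterations[[iteration]]
  suppressWarnings(stats::cor(step$prob_correct, 1 / step$rank_correct,
                              method = "spearman"))
}
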