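#' Read a gene-by-column numeric matrix
#'
#' TSV with a header row of condition/genome ids and gene ids in the first
#' column. Used for both the expression matrix (genes x conditions, real) and
#' the phylogenetic-profile matrix (genes x genomes, 0/1).
#'
#' @param path file path
#' @return numeric matrix with gene rownames
#' @export
read_gene_matrix <- function(path) {
  df <- utils::read.delim(path, row.names = 1L, check.names = FALSE)
  m <- as.matrix(df)
  if (anyDuplicated(rownames(m))) stop("duplicate gene ids in ", path)
  storage.mode(m) <- "double"
  m
}

#' Write a gene-by-column matrix
#' @param m numeric matrix with gene rownames
#' @param path file path
#' @param id_col name of the first (gene id) column in the header
#' @return invisibly, \code{path}
#' @export
write_gene_matrix <- function(m, path, id_col = "gene") {
  df <- data.frame(rownames(m), m, check.names = FALSE)
  names(df)[1L] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Expression-profile similarity
#'
#' Absolute Spearman rank correlation of two genes' expression profiles; both
#' co-expression and anti-correlation count as similarity. A constant profile
#' (undefined correlation) scores 0.
#'
#' @param x,y gene ids (rows of \code{expr})
#' @param expr expression matrix from \code{\link{read_gene_matrix}}
#' @return similarity in [0, 1]
#' @export
expr_similarity <- function(x, y, expr) {
  if (!(x %in% rownames(expr))) stop("gene absent from expression matrix: ", x)
  if (!(y %in% rownames(expr))) stop("gene absent from expression matrix: ", y)
  ok <- is.finite(expr[x, ]) & is.finite(expr[y, ])
  if (sum(ok) < 3L) stop("fewer than 3 shared conditions for ", x, ", ", y)
  r <- suppressWarnings(stats::cor(expr[x, ok], expr[y, ok],
                                   method = "spearman"))
  if (is.na(r)) 0 else abs(r)
}

#' Phylogenetic-profile similarity
#'
#' Pearson correlation of two genes' binary presence/absence profiles across
#' genomes: 1 for identical patterns of presence, -1 for complementary ones.
#' An all-zero or all-one profile (undefined correlation) scores 0.
#'
#' @param x,y gene ids (rows of \code{phylo})
#' @param phylo binary matrix from \code{\link{read_gene_matrix}}
#' @return correlation in [-1, 1]
#' @export
phyl_similarity <- function(x, y, phylo) {
  if (!(x %in% rownames(phylo))) stop("gene absent from phylo matrix: ", x)
  if (!(y %in% rownames(phylo))) stop("gene absent from phylo matrix: ", y)
  r <- suppressWarnings(stats::cor(phylo[x, ], phylo[y, ]))
  if (is.na(r)) 0 else r
}

#' Build the pairwise gene scorers
#'
#' Packages the five pairwise score types into memoised functions
#' \code{f(x, y)} returning a number, or \code{NA} when either gene lacks the
#' relevant data (annotations or matrix rows) so that neighbor aggregation can
#' skip it. The coherence scorers (\code{CAS}, \code{PAS}, \code{funsim})
#' carry \code{attr(, "coherence") = TRUE}: during iterative filling only
#' these receive contributions from provisionally assigned neighbor genes.
#' \code{CAS} and \code{PAS} carry \code{attr(, "log_scale") = TRUE} and are
#' log-converted when assembled into a feature matrix.
#'
#' @param dag an \code{\link{ontology_dag}}
#' @param ann an \code{annotation_set}
#' @param freq a \code{term_frequency}
#' @param cooc gene co-occurrence \code{assoc_counts}
#' @param abstracts abstract \code{assoc_counts} (or NULL to omit PAS)
#' @param expr expression matrix (or NULL to omit EXPR)
#' @param phylo phylogenetic-profile matrix (or NULL to omit PHYL)
#' @return named list of scorer functions (subset of \code{CAS}, \code{PAS},
#'   \code{funsim}, \code{EXPR}, \code{PHYL})
#' @export
make_scorers <- function(dag, ann, freq, cooc, abstracts = NULL,
                         expr = NULL, phylo = NULL) {
  memo_pair <- function(f) {
    cache <- new.env(parent = emptyenv())
    function(x, y) {
      key <- pair_key(x, y)
      hit <- cache[[key]]
      if (!is.null(hit)) return(hit)
      v <- f(x, y)
      cache[[key]] <- v
      v
    }
  }
  terms_of <- function(g) gene_terms(ann, g)
  annotated <- function(g) length(terms_of(g)) > 0L

  # term-pair similarity over the annotated vocabulary, computed once
  ann_terms <- sort(unique(unlist(ann$annotations, use.names = FALSE)))
  SIM <- term_sim_matrix(ann_terms, dag, freq)
  by_cat <- lapply(stats::setNames(c("MF", "BP", "CC"), c("MF", "BP", "CC")),
                   function(cat) ann_terms[!is.na(dag$namespace[ann_terms]) &
                                             dag$namespace[ann_terms] == cat])
  funsim_fast <- function(tx, ty) {
    per_cat <- vapply(c("MF", "BP", "CC"), function(cat) {
      a <- intersect(tx, by_cat[[cat]]); b <- intersect(ty, by_cat[[cat]])
      if (length(a) == 0L || length(b) == 0L) return(NA_real_)
      mean(SIM[a, b])
    }, numeric(1))
    avail <- per_cat[!is.na(per_cat)]
    if (length(avail) == 0L) 0 else mean(avail)
  }

  scorers <- list()
  scorers$CAS <- memo_pair(function(x, y) {
    if (!annotated(x) || !annotated(y)) return(NA_real_)
    assoc_cross_mean(terms_of(x), terms_of(y), cooc)
  })
  attr(scorers$CAS, "coherence") <- TRUE
  attr(scorers$CAS, "log_scale") <- TRUE
  if (!is.null(abstracts)) {
    scorers$PAS <- memo_pair(function(x, y) {
      if (!annotated(x) || !annotated(y)) return(NA_real_)
      assoc_cross_mean(terms_of(x), terms_of(y), abstracts)
    })
    attr(scorers$PAS, "coherence") <- TRUE
    attr(scorers$PAS, "log_scale") <- TRUE
  }
  scorers$funsim <- memo_pair(function(x, y) {
    if (!annotated(x) || !annotated(y)) return(NA_real_)
    funsim_fast(terms_of(x), terms_of(y))
  })
  attr(scorers$funsim, "coherence") <- TRUE
  if (!is.null(expr)) {
    # Spearman is Pearson on within-gene ranks: one correlation matrix
    ECOR <- abs(stats::cor(apply(expr, 1L, rank)))
    ECOR[is.na(ECOR)] <- 0   # constant profiles
    scorers$EXPR <- function(x, y) {
      if (!(x %in% rownames(expr)) || !(y %in% rownames(expr)))
        return(NA_real_)
      ECOR[x, y]
    }
  }
  if (!is.null(phylo)) {
    PCOR <- suppressWarnings(stats::cor(t(phylo)))
    PCOR[is.na(PCOR)] <- 0   # all-present / all-absent profiles
    scorers$PHYL <- function(x, y) {
      if (!(x %in% rownames(phylo)) || !(y %in% rownames(phylo)))
        return(NA_real_)
      PCOR[x, y]
    }
  }
  scorers
}

#' Build a profile scorer
#'
#' Memoised \code{f(position, candidate)} evaluating the candidate's
#' annotations against the position's functional profile, or \code{NA} when
#' the position has no profile or the candidate no annotations.
#'
#' @param profiles named list of \code{\link{functional_profile}} objects
#' @inheritParams make_scorers
#' @return function \code{(position, candidate) -> numeric}
#' @export
make_profile_scorer <- function(profiles, dag, ann, freq) {
  vocab <- sort(unique(c(
    unlist(lapply(profiles, `[[`, "terms"), use.names = FALSE),
    unlist(ann$annotations, use.names = FALSE))))
  SIM <- term_sim_matrix(vocab, dag, freq)
  split_cat <- function(ts) lapply(
    stats::setNames(c("MF", "BP", "CC"), c("MF", "BP", "CC")),
    function(cat) ts[!is.na(dag$namespace[ts]) & dag$namespace[ts] == cat])
  prof_split <- lapply(profiles, function(pr) split_cat(pr$terms))
  cache <- new.env(parent = emptyenv())
  function(position, candidate) {
    ps <- prof_split[[position]]
    if (is.null(ps)) return(NA_real_)
    tc <- gene_terms(ann, candidate)
    if (length(tc) == 0L) return(NA_real_)
    key <- paste(position, candidate, sep = "\r")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    cs <- split_cat(tc)
    per_cat <- vapply(c("MF", "BP", "CC"), function(cat) {
      a <- ps[[cat]]; b <- cs[[cat]]
      if (length(a) == 0L || length(b) == 0L) return(NA_real_)
      mean(SIM[a, b])
    }, numeric(1))
    avail <- per_cat[!is.na(per_cat)]
    v <- if (length(avail) == 0L) 0 else mean(avail)
    cache[[key]] <- v
    v
  }
}

# genes standing at the given neighbor nodes: known nodes map to themselves;
# pseudo nodes and nodes without an entry yield NA (skipped by aggregation)
neighbor_genes <- function(net, nbrs, node_gene = NULL) {
  if (is.null(node_gene)) {
    g <- ifelse(net$is_pseudo[nbrs], NA_character_, nbrs)
  } else {
    g <- node_gene[nbrs]
    g[!(nbrs %in% names(node_gene))] <- NA_character_
  }
  stats::setNames(as.character(g), nbrs)
}

#' Relatedness of a candidate to an enzyme position
#'
#' Mean pairwise score between the candidate and the genes at the position's
#' exact level-\code{k} network neighbors:
#' \deqn{Rel\_Score_{t,k}(i, j) = \frac{1}{n_k} \sum_{P_l \in N_k(i)} score_t(j, P_l)}
#' Neighbors lacking data for the score type (including pseudo-enzyme nodes,
#' which carry no gene data) are skipped and \eqn{n_k} reduced accordingly;
#' if no neighbor remains the score is 0.
#'
#' @param net an \code{enzyme_network}
#' @param position node id of the target enzyme position
#' @param candidate candidate gene id
#' @param scorer a pairwise scorer from \code{\link{make_scorers}}
#' @param k neighbor level (1, 2 or 3)
#' @param node_gene optional named character vector mapping nodes to the genes
#'   currently standing at them (used during iterative filling); by default
#'   every non-pseudo node stands for its own gene
#' @return the aggregated score
#' @export
rel_score <- function(net, position, candidate, scorer, k, node_gene = NULL) {
  nbrs <- neighbors_at_level(net, position, k)
  if (length(nbrs) == 0L) return(0)
  genes <- neighbor_genes(net, nbrs, node_gene)
  genes <- genes[!is.na(genes)]
  if (length(genes) == 0L) return(0)
  s <- vapply(genes, function(g) scorer(candidate, g), numeric(1))
  s <- s[!is.na(s)]
  if (length(s) == 0L) return(0)
  mean(s)
}

#' GTOM-weighted relatedness
#'
#' As \code{\link{rel_score}} but weighting each level-\code{k} neighbor by
#' its GTOM weight to the position, normalized by the sum of weights (a
#' weighted mean), so that uniform weights reduce exactly to the unweighted
#' relatedness:
#' \deqn{GTOMm\_Rel\_Score_{t,k}(i, j) = \frac{\sum_l GTOM_m(i, P_l)\, score_t(j, P_l)}{\sum_l GTOM_m(i, P_l)}}
#'
#' @inheritParams rel_score
#' @param weights symmetric weight matrix from \code{\link{gtom}} (any
#'   symmetric node-by-node weighting is accepted)
#' @return the aggregated score; 0 when all usable weights are 0
#' @export
gtom_rel_score <- function(net, position, candidate, scorer, k, weights,
                           node_gene = NULL) {
  nbrs <- neighbors_at_level(net, position, k)
  if (length(nbrs) == 0L) return(0)
  genes <- neighbor_genes(net, nbrs, node_gene)
  keep <- !is.na(genes)
  if (!any(keep)) return(0)
  nbrs <- nbrs[keep]; genes <- genes[keep]
  s <- vapply(genes, function(g) scorer(candidate, g), numeric(1))
  w <- weights[position, nbrs]
  ok <- !is.na(s)
  if (!any(ok) || sum(w[ok]) == 0) return(0)
  sum(w[ok] * s[ok]) / sum(w[ok])
}

parse_form <- function(form) {
  if (grepl("^N[123]$", form))
    return(list(m = NA_integer_, k = as.integer(substring(form, 2L))))
  mm <- regmatches(form, regexec("^GTOM([12])_N([123])$", form))[[1L]]
  if (length(mm) == 0L) stop("unknown score form: ", form)
  list(m = as.integer(mm[[2L]]), k = as.integer(mm[[3L]]))
}

#' Assemble the per-candidate feature matrix
#'
#' One row per (position, candidate); for every pairwise score type and every
#' requested form (\code{N1}, \code{N2}, \code{GTOM1_N1}, \code{GTOM1_N2},
#' \code{GTOM2_N1}, \code{GTOM2_N2}) a column named
#' \code{<type>_<form>}, plus a single \code{PROFILE} column when a profile
#' scorer is supplied. CAS/PAS columns are stored after
#' \code{\link{log_transform}}. The \code{label} column is 1 for the
#' position's true gene.
#'
#' @param net an \code{enzyme_network}
#' @param positions character vector of position node ids
#' @param pools named list: position -> character vector of candidate genes
#' @param scorers list from \code{\link{make_scorers}}
#' @param forms score forms to compute (default the two forms used by the
#'   combiner, \code{GTOM1_N1} and \code{GTOM1_N2})
#' @param profile_scorer optional function from
#'   \code{\link{make_profile_scorer}}
#' @param truth named character vector position -> correct gene (defaults to
#'   the position ids themselves, the usual case where the position is a known
#'   enzyme node held out for evaluation)
#' @param node_gene see \code{\link{rel_score}}
#' @param epsilon log-transform offset for CAS/PAS columns
#' @return a \code{feature_matrix}: data.frame with columns \code{position},
#'   \code{candidate}, \code{label} and one column per feature;
#'   \code{attr(, "feature_cols")} lists the feature columns in order
#' @export
build_feature_matrix <- function(net, positions, pools, scorers,
                                 forms = c("GTOM1_N1", "GTOM1_N2"),
                                 profile_scorer = NULL, truth = NULL,
                                 node_gene = NULL, epsilon = 1e-6) {
  check_node(net, positions)
  parsed <- lapply(forms, parse_form)
  ms <- unique(stats::na.omit(vapply(parsed, function(p) p$m, integer(1))))
  weights <- stats::setNames(lapply(ms, function(m) gtom(net, m)),
                             as.character(ms))
  if (is.null(truth)) truth <- stats::setNames(positions, positions)

  feature_cols <- as.vector(outer(names(scorers), forms, paste, sep = "_"))
  if (!is.null(profile_scorer)) feature_cols <- c(feature_cols, "PROFILE")

  # one BFS per position, shared across candidates, score types and forms
  D <- igraph::distances(net$graph, v = positions, to = igraph::V(net$graph))
  nbr_info <- lapply(stats::setNames(positions, positions), function(pos) {
    lapply(parsed, function(p) {
      nbrs <- colnames(D)[is.finite(D[pos, ]) & D[pos, ] == p$k]
      genes <- neighbor_genes(net, nbrs, node_gene)
      keep <- !is.na(genes)
      nbrs <- nbrs[keep]; genes <- unname(genes[keep])
      w <- if (is.na(p$m)) rep(1, length(nbrs))
           else unname(weights[[as.character(p$m)]][pos, nbrs])
      list(genes = genes, w = w)
    })
  })

  # pairwise scores as candidate-by-neighbor-gene matrices, one per score
  # type, so that aggregation is a weighted matrix product
  all_cands <- unique(unlist(pools[positions], use.names = FALSE))
  all_nbr_genes <- unique(unlist(lapply(nbr_info, function(pf)
    lapply(pf, `[[`, "genes")), use.names = FALSE))
  score_mat <- lapply(scorers, function(scorer) {
    M <- matrix(NA_real_, length(all_cands), length(all_nbr_genes),
                dimnames = list(all_cands, all_nbr_genes))
    for (g in all_nbr_genes)
      M[, g] <- vapply(all_cands, function(cd) scorer(cd, g), numeric(1))
    M
  })

  weighted_agg <- function(M, genes, w, cands) {
    if (length(genes) == 0L) return(rep(0, length(cands)))
    S <- M[cands, genes, drop = FALSE]
    ok <- !is.na(S)
    S[!ok] <- 0
    den <- drop(ok %*% w)
    num <- drop(S %*% w)
    out <- rep(0, length(cands))
    out[den > 0] <- num[den > 0] / den[den > 0]
    out
  }

  rows <- lapply(positions, function(pos) {
    cands <- pools[[pos]]
    if (is.null(cands) || length(cands) == 0L)
      stop("no candidate pool for position ", pos)
    vals <- matrix(0, nrow = length(cands), ncol = length(feature_cols),
                   dimnames = list(NULL, feature_cols))
    for (t in names(scorers)) {
      for (fi in seq_along(forms)) {
        nb <- nbr_info[[pos]][[fi]]
        v <- weighted_agg(score_mat[[t]], nb$genes, nb$w, cands)
        if (isTRUE(attr(scorers[[t]], "log_scale")))
          v <- log_transform(v, epsilon)
        vals[, paste(t, forms[[fi]], sep = "_")] <- v
      }
    }
    if (!is.null(profile_scorer)) {
      v <- vapply(cands, function(cd) profile_scorer(pos, cd), numeric(1))
      v[is.na(v)] <- 0
      vals[, "PROFILE"] <- v
    }
    data.frame(position = pos, candidate = cands,
               label = as.integer(cands == truth[[pos]]),
               vals, row.names = NULL, check.names = FALSE)
  })
  fm <- do.call(rbind, rows)
  attr(fm, "feature_cols") <- feature_cols
  class(fm) <- c("feature_matrix", "data.frame")
  fm
}

#' Write a feature matrix as TSV
#' @param fm a \code{feature_matrix}
#' @param path file path
#' @return invisibly, \code{path}
#' @export
write_feature_matrix <- function(fm, path) {
  utils::write.table(fm, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
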