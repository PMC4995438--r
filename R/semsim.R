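#' Term-level semantic similarity
#'
#' Lin-form similarity over the most informative common ancestor: with
#' \eqn{p(c)} the fraction of the annotation corpus annotated with term
#' \eqn{c} (see \code{\link{build_term_frequencies}}),
#' \deqn{sim(c_1, c_2) = \max_{c \in CA(c_1, c_2)} \frac{2 \ln p(c)}{\ln p(c_1) + \ln p(c_2)}}
#' where the common-ancestor set includes \eqn{c_1} and \eqn{c_2} themselves
#' when one is an ancestor of the other (and always when identical). Because
#' \eqn{p} is non-decreasing toward the root the score lies in [0, 1]; it is
#' 1 for identical informative terms and 0 when the only common ancestor is
#' uninformative (\eqn{p = 1}).
#'
#' @param c1,c2 term ids from the same namespace
#' @param dag an \code{\link{ontology_dag}}
#' @param freq a \code{term_frequency} from \code{\link{build_term_frequencies}}
#' @return similarity in [0, 1]
#' @export
term_similarity <- function(c1, c2, dag, freq) {
  check_term(dag, c(c1, c2))
  ns1 <- dag$namespace[[c1]]; ns2 <- dag$namespace[[c2]]
  if (is.na(ns1) || is.na(ns2) || ns1 != ns2)
    stop("terms from different namespaces: ", c1, " (", ns1, ") vs ",
         c2, " (", ns2, ")")
  p1 <- freq$p[[c1]]; p2 <- freq$p[[c2]]
  if (c1 == c2) {
    if (is.na(p1) || p1 >= 1) return(0)   # uninformative term
    return(1)                             # includes the never-annotated case
  }
  common <- intersect(c(c1, term_ancestors(dag, c1)),
                      c(c2, term_ancestors(dag, c2)))
  pc <- freq$p[common]
  pc <- pc[pc > 0]
  if (length(pc) == 0L) return(0)
  num <- 2 * min(log(pc))                 # most informative common ancestor
  den <- log(p1) + log(p2)                # -Inf if either term unannotated
  if (num == 0) return(0)                 # only p = 1 ancestors in common
  if (!is.finite(den)) return(0)
  if (den == 0) return(0)
  min(max(num / den, 0), 1)
}

# dense pairwise similarity over a term set (NA across namespaces), computed
# once so gene-pair scoring reduces to submatrix means
term_sim_matrix <- function(terms, dag, freq) {
  terms <- unique(terms)
  S <- matrix(NA_real_, length(terms), length(terms),
              dimnames = list(terms, terms))
  ns <- dag$namespace[terms]
  for (cat in c("MF", "BP", "CC")) {
    idx <- which(!is.na(ns) & ns == cat)
    for (a in seq_along(idx)) {
      for (b in a:length(idx)) {
        s <- term_similarity(terms[idx[a]], terms[idx[b]], dag, freq)
        S[idx[a], idx[b]] <- s
        S[idx[b], idx[a]] <- s
      }
    }
  }
  S
}

# all-pairs mean of term_similarity between two term sets restricted to one
# namespace; 0 when either set is empty in that namespace
go_score_terms <- function(tx, ty, category, dag, freq, sim_cache = NULL) {
  tx <- tx[!is.na(dag$namespace[tx]) & dag$namespace[tx] == category]
  ty <- ty[!is.na(dag$namespace[ty]) & dag$namespace[ty] == category]
  if (length(tx) == 0L || length(ty) == 0L) return(NA_real_)
  total <- 0
  for (a in tx) for (b in ty) {
    if (is.null(sim_cache)) {
      total <- total + term_similarity(a, b, dag, freq)
    } else {
      key <- pair_key(a, b)
      hit <- sim_cache[[key]]
      if (is.null(hit)) {
        hit <- term_similarity(a, b, dag, freq)
        sim_cache[[key]] <- hit
      }
      total <- total + hit
    }
  }
  total / (length(tx) * length(ty))
}

#' Per-category GO score between two genes
#'
#' Mean of \code{\link{term_similarity}} over all pairs of the two genes'
#' annotations restricted to one namespace. A gene with no annotation in the
#' category yields a category score of 0.
#'
#' @param X,Y gene ids
#' @param category \code{"MF"}, \code{"BP"} or \code{"CC"}
#' @param ann an \code{annotation_set}
#' @inheritParams term_similarity
#' @return score in [0, 1]
#' @export
go_score_category <- function(X, Y, category, ann, dag, freq) {
  stopifnot(category %in% c("MF", "BP", "CC"))
  s <- go_score_terms(gene_terms(ann, X), gene_terms(ann, Y),
                      category, dag, freq)
  if (is.na(s)) 0 else s
}

funsim_terms <- function(tx, ty, dag, freq, sim_cache = NULL) {
  per_cat <- vapply(c("MF", "BP", "CC"), function(cat)
    go_score_terms(tx, ty, cat, dag, freq, sim_cache), numeric(1))
  avail <- per_cat[!is.na(per_cat)]   # categories where both sides annotate
  if (length(avail) == 0L) return(0)
  mean(avail)
}

#' Functional similarity between two genes
#'
#' Combines the per-category GO scores (\code{\link{go_score_category}}) into
#' a single value in [0, 1] by averaging over the categories in which both
#' genes carry annotations; categories missing on either side are excluded
#' from the mean rather than counted as zero, so a partially annotated gene
#' still satisfies \code{funsim(X, X) = 1} when its terms are informative.
#'
#' @inheritParams go_score_category
#' @return score in [0, 1], symmetric in \code{X}, \code{Y}
#' @export
funsim <- function(X, Y, ann, dag, freq) {
  tx <- gene_terms(ann, X); ty <- gene_terms(ann, Y)
  if (length(tx) == 0L && length(ty) == 0L)
    stop("both genes are unannotated: ", X, ", ", Y)
  funsim_terms(tx, ty, dag, freq)
}

#' Functional profile of an enzyme position
#'
#' A set of GO terms (across namespaces) describing the function expected at
#' an enzyme position — in practice derived from the enzyme's EC number and
#' localization. Consumed by \code{\link{profile_score}}.
#'
#' @param position position id
#' @param terms character vector of term ids
#' @param dag optional \code{\link{ontology_dag}} for validation
#' @return a \code{functional_profile}
#' @export
functional_profile <- function(position, terms, dag = NULL) {
  terms <- unique(terms)
  if (length(terms) == 0L) stop("empty functional profile for ", position)
  if (!is.null(dag)) check_term(dag, terms)
  structure(list(position = position, terms = terms),
            class = "functional_profile")
}

#' Profile score of a candidate against an enzyme position
#'
#' \code{\link{funsim}} computed between the position's functional profile
#' (treated as the annotations of a pseudo-gene) and the candidate's
#' annotations.
#'
#' @param profile a \code{\link{functional_profile}}
#' @param candidate gene id
#' @inheritParams go_score_category
#' @return score in [0, 1]
#' @export
profile_score <- function(profile, candidate, ann, dag, freq) {
  stopifnot(inherits(profile, "functional_profile"))
  tc <- gene_terms(ann, candidate)
  if (length(tc) == 0L) stop("candidate without annotations: ", candidate)
  funsim_terms(profile$terms, tc, dag, freq)
}

#' Read functional profiles
#'
#' Two-column TSV (\code{position}, \code{term}), multiple rows per position.
#'
#' @param path file path
#' @param dag optional \code{\link{ontology_dag}} for validation
#' @return named list of \code{\link{functional_profile}} objects
#' @export
read_profiles <- function(path, dag = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("position", "term") %in% names(df)))
  by_pos <- split(df$term, df$position)
  out <- lapply(names(by_pos), function(p)
    functional_profile(p, by_pos[[p]], dag))
  stats::setNames(out, names(by_pos))
}

#' Write functional profiles
#' @param profiles named list of \code{\link{functional_profile}} objects
#' @param path file path
#' @return invisibly, \code{path}
#' @export
write_profiles <- function(profiles, path) {
  df <- do.call(rbind, lapply(profiles, function(pr)
    data.frame(position = pr$position, term = pr$terms,
               stringsAsFactors = FALSE)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
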