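#' Association-score count tables
#'
#' Container for the co-occurrence statistics behind the two functional
#' coherence scores: per-term counts (\code{single}), unordered term-pair
#' counts (\code{pair}) and the corpus size (\code{total}). For the
#' annotation-based score the corpus is genes and a pair is counted when both
#' terms annotate the same gene; for the literature-based score the corpus is
#' abstracts and a pair is counted when both term names occur in the same
#' abstract.
#'
#' @param single named numeric vector: term -> count
#' @param pair named numeric vector keyed by \code{pair_key(a, b)}
#' @param total corpus size (number of genes or abstracts)
#' @param type \code{"gene"} or \code{"abstract"} (informational)
#' @return an \code{assoc_counts} object
#' @export
assoc_counts <- function(single, pair, total, type = "gene") {
  stopifnot(is.numeric(single), !is.null(names(single)),
            is.numeric(total), total >= 0)
  if (length(pair) > 0L && is.null(names(pair)))
    stop("pair counts must be named by pair_key()")
  # pair(a,b) <= min(single(a), single(b))
  if (length(pair) > 0L) {
    ab <- strsplit(names(pair), "\r", fixed = TRUE)
    a <- vapply(ab, `[[`, "", 1L); b <- vapply(ab, `[[`, "", 2L)
    known <- a %in% names(single) & b %in% names(single)
    if (!all(known)) stop("pair counts reference unknown terms")
    if (any(pair > pmin(single[a], single[b]) + 1e-9))
      stop("pair count exceeds a single-term count")
  }
  structure(list(single = single, pair = pair, total = total, type = type),
            class = "assoc_counts")
}

#' @export
print.assoc_counts <- function(x, ...) {
  cat("assoc_counts (", x$type, "): ", length(x$single), " terms, ",
      length(x$pair), " pairs, total ", x$total, "\n", sep = "")
  invisible(x)
}

#' Canonical key for an unordered term pair
#' @param a,b term ids
#' @return character key, symmetric in its arguments
#' @export
pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")

pair_count <- function(counts, a, b) {
  if (a == b) return(unname(counts$single[[a]]))  # self-pair: every gene with t has both
  hit <- counts$pair[pair_key(a, b)]
  if (is.na(hit)) 0 else unname(hit)
}

#' Build gene co-occurrence counts from an annotation set
#'
#' Counts, over the (direct, unpropagated) annotation sets, how many genes
#' carry each term and each unordered term pair.
#'
#' @param ann an \code{annotation_set}
#' @return an \code{assoc_counts} of type \code{"gene"}
#' @export
build_cooccurrence <- function(ann) {
  genes <- names(ann$annotations)
  if (length(genes) == 0L) stop("empty annotation corpus")
  single_l <- lapply(ann$annotations, unique)
  single <- table(unlist(single_l, use.names = FALSE))
  single <- stats::setNames(as.numeric(single), names(single))
  keys <- unlist(lapply(single_l, function(ts) {
    ts <- sort(ts)
    if (length(ts) < 2L) return(character(0))
    cmb <- utils::combn(ts, 2L)
    pair_key(cmb[1L, ], cmb[2L, ])
  }), use.names = FALSE)
  pair <- if (length(keys) > 0L) {
    tb <- table(keys)
    stats::setNames(as.numeric(tb), names(tb))
  } else stats::setNames(numeric(0), character(0))
  assoc_counts(single, pair, total = length(genes), type = "gene")
}

assoc_ratio <- function(a, b, counts) {
  if (!(a %in% names(counts$single)) || !(b %in% names(counts$single)))
    stop("term(s) absent from the count table: ",
         paste(setdiff(c(a, b), names(counts$single)), collapse = ", "))
  sa <- counts$single[[a]]; sb <- counts$single[[b]]
  if (sa == 0 || sb == 0) return(0)
  pc <- pair_count(counts, a, b)
  if (pc == 0) return(0)
  counts$total * pc / (sa * sb)
}

#' Co-occurrence association score between two terms
#'
#' The ratio of the frequency with which both terms annotate the same gene to
#' the product of their individual annotation frequencies: with counts
#' \eqn{n_{ab}}, \eqn{n_a}, \eqn{n_b} over a corpus of \eqn{N} genes,
#' \eqn{CAS(a,b) = N \cdot n_{ab} / (n_a n_b)} (a lift / pointwise-mutual-
#' information-style ratio; 1 means independence). Terms with a zero single
#' count score 0. Unlike tree-based similarity scores, the score is defined
#' across namespaces.
#'
#' @param a,b term ids
#' @param counts an \code{assoc_counts} of type \code{"gene"}
#' @return non-negative number, symmetric in \code{a}, \code{b}
#' @export
cas_term <- function(a, b, counts) assoc_ratio(a, b, counts)

#' Literature association score between two terms
#'
#' Same functional form as \code{\link{cas_term}} but over an abstract corpus:
#' the count of abstracts mentioning both term names against those mentioning
#' each name independently.
#'
#' @inheritParams cas_term
#' @param counts an \code{assoc_counts} of type \code{"abstract"}
#' @export
pas_term <- function(a, b, counts) assoc_ratio(a, b, counts)

# vectorized mean of assoc_ratio over the tx x ty cross product; terms with
# no single count (or absent from the table) contribute 0
assoc_cross_mean <- function(tx, ty, counts) {
  ga <- rep(tx, times = length(ty))
  gb <- rep(ty, each = length(tx))
  sa <- counts$single[ga]; sb <- counts$single[gb]
  sa[is.na(sa)] <- 0; sb[is.na(sb)] <- 0
  pc <- counts$pair[pair_key(ga, gb)]
  pc[is.na(pc)] <- 0
  self <- ga == gb
  pc[self] <- sa[self]
  ok <- sa > 0 & sb > 0
  v <- numeric(length(ga))
  v[ok] <- counts$total * pc[ok] / (sa[ok] * sb[ok])
  mean(v)
}

assoc_protein <- function(X, Y, ann, counts) {
  tx <- gene_terms(ann, X); ty <- gene_terms(ann, Y)
  if (length(tx) == 0L) stop("gene without annotations: ", X)
  if (length(ty) == 0L) stop("gene without annotations: ", Y)
  assoc_cross_mean(tx, ty, counts)
}

#' Protein-pair co-occurrence association score
#'
#' Mean of \code{\link{cas_term}} over all ordered pairs of the two genes'
#' annotations (the full annotation cross product, identical terms included).
#'
#' @param X,Y gene ids
#' @param ann an \code{annotation_set}
#' @param counts an \code{assoc_counts} of type \code{"gene"}
#' @return non-negative number, symmetric in \code{X}, \code{Y}
#' @export
cas_protein <- function(X, Y, ann, counts) assoc_protein(X, Y, ann, counts)

#' Protein-pair literature association score
#'
#' Mean of \code{\link{pas_term}} over the annotation cross product.
#'
#' @inheritParams cas_protein
#' @param counts an \code{assoc_counts} of type \code{"abstract"}
#' @export
pas_protein <- function(X, Y, ann, counts) assoc_protein(X, Y, ann, counts)

#' Logarithmic conversion of association scores
#'
#' The raw association scores span several orders of magnitude; before
#' entering the combiner they are log-converted as \code{log(score + epsilon)}
#' with a small fixed offset keeping zero scores finite.
#'
#' @param score non-negative numeric vector
#' @param epsilon additive offset (default \code{1e-6})
#' @return numeric vector, monotone in \code{score}
#' @export
log_transform <- function(score, epsilon = 1e-6) {
  if (any(score < 0)) stop("log_transform requires non-negative scores")
  log(score + epsilon)
}

#' Read association count tables
#'
#' Reads the three-file TSV representation of an \code{\link{assoc_counts}}
#' object: a single-term table (columns \code{term}, \code{count}), a pair
#' table (columns \code{term_a}, \code{term_b}, \code{count}) and a one-line
#' total file.
#'
#' @param single_path,pair_path,total_path file paths
#' @param type \code{"gene"} or \code{"abstract"}
#' @return an \code{assoc_counts}
#' @export
read_assoc_counts <- function(single_path, pair_path, total_path,
                              type = "abstract") {
  s <- utils::read.delim(single_path, stringsAsFactors = FALSE)
  p <- utils::read.delim(pair_path, stringsAsFactors = FALSE)
  total <- as.numeric(readLines(total_path, warn = FALSE)[1L])
  single <- stats::setNames(as.numeric(s$count), s$term)
  pair <- if (nrow(p) > 0L)
    stats::setNames(as.numeric(p$count), pair_key(p$term_a, p$term_b))
  else stats::setNames(numeric(0), character(0))
  if (anyDuplicated(names(pair)))
    stop("duplicate (or asymmetric duplicate) pair rows in ", pair_path)
  assoc_counts(single, pair, total, type = type)
}

#' Write association count tables
#'
#' Inverse of \code{\link{read_assoc_counts}}.
#'
#' @param counts an \code{assoc_counts}
#' @inheritParams read_assoc_counts
#' @return invisibly, the paths written
#' @export
write_assoc_counts <- function(counts, single_path, pair_path, total_path) {
  utils::write.table(
    data.frame(term = names(counts$single), count = counts$single),
    single_path, sep = "\t", quote = FALSE, row.names = FALSE)
  ab <- strsplit(names(counts$pair), "\r", fixed = TRUE)
  utils::write.table(
    data.frame(term_a = vapply(ab, `[[`, "", 1L),
               term_b = vapply(ab, `[[`, "", 2L),
               count = unname(counts$pair)),
    pair_path, sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(as.character(counts$total), total_path)
  invisible(c(single_path, pair_path, total_path))
}
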