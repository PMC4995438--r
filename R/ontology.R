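#' Ontology DAG
#'
#' Builds the directed acyclic graph of ontology terms used throughout the
#' package. Terms point to their parents via \code{is_a}/\code{part_of} edges
#' (traversed identically); a synthetic root term \code{"all"} is inserted
#' above the three namespace roots so that term levels are counted from
#' \code{"all"} (the root has level 0, the namespace roots level 1).
#'
#' @param parents named list mapping each term id to a character vector of its
#'   parent term ids. Namespace roots have no parents (empty vector or absent).
#' @param namespace named character vector mapping each term id to one of
#'   \code{"MF"}, \code{"BP"}, \code{"CC"}.
#' @param term_names optional named character vector of human-readable term
#'   names (used by the literature-score tokenizer in the fixture generator).
#' @return an object of class \code{ontology_dag} with elements \code{terms},
#'   \code{parents}, \code{children}, \code{namespace}, \code{level},
#'   \code{name}, \code{root}.
#' @export
ontology_dag <- function(parents, namespace, term_names = NULL) {
  terms <- unique(c(names(parents), unlist(parents, use.names = FALSE),
                    names(namespace)))
  terms <- setdiff(terms, "all")
  if (length(terms) == 0L) stop("ontology has no terms")
  missing_ns <- setdiff(terms, names(namespace))
  if (length(missing_ns) > 0L)
    stop("terms without a namespace: ", paste(missing_ns, collapse = ", "))
  bad_ns <- setdiff(unique(namespace), c("MF", "BP", "CC"))
  if (length(bad_ns) > 0L)
    stop("unknown namespace value(s): ", paste(bad_ns, collapse = ", "))

  par <- stats::setNames(vector("list", length(terms)), terms)
  for (t in terms) {
    p <- unique(parents[[t]])
    p <- setdiff(p, t)
    par[[t]] <- p
  }
  # synthetic root above the namespace roots
  roots <- terms[vapply(par, length, 1L) == 0L]
  if (length(roots) == 0L) stop("ontology has no namespace root (cycle?)")
  for (t in roots) par[[t]] <- "all"
  par[["all"]] <- character(0)
  all_terms <- c("all", terms)
  namespace <- c(stats::setNames(NA_character_, "all"), namespace[terms])

  # namespace constant along parent chains below the namespace roots
  for (t in terms) {
    for (p in par[[t]]) {
      if (p != "all" && !is.na(namespace[[p]]) &&
          namespace[[p]] != namespace[[t]])
        stop("edge crosses namespaces: ", t, " -> ", p)
    }
  }

  # topological order (children before parents); also detects cycles
  order <- topo_sort_terms(par, all_terms)

  # level = longest path from the root "all"; root is 0
  level <- stats::setNames(integer(length(all_terms)), all_terms)
  for (t in rev(order)) {        # parents before children
    if (t == "all") { level[[t]] <- 0L; next }
    level[[t]] <- 1L + max(level[par[[t]]])
  }

  children <- stats::setNames(vector("list", length(all_terms)), all_terms)
  for (t in all_terms) for (p in par[[t]]) children[[p]] <- c(children[[p]], t)

  nm <- stats::setNames(rep(NA_character_, length(all_terms)), all_terms)
  if (!is.null(term_names)) nm[names(term_names)] <- term_names

  structure(list(terms = all_terms, parents = par, children = children,
                 namespace = namespace, level = level, name = nm,
                 root = "all", cache = new.env(parent = emptyenv())),
            class = "ontology_dag")
}

# Kahn topological sort over the parent relation; order has children first.
topo_sort_terms <- function(par, terms) {
  n_unresolved <- vapply(par, length, 1L)[terms]
  children <- stats::setNames(vector("list", length(terms)), terms)
  for (t in terms) for (p in par[[t]]) children[[p]] <- c(children[[p]], t)
  out <- character(0)
  queue <- terms[n_unresolved == 0L]   # the root(s)
  done <- stats::setNames(rep(FALSE, length(terms)), terms)
  while (length(queue) > 0L) {
    t <- queue[[1L]]; queue <- queue[-1L]
    out <- c(out, t); done[[t]] <- TRUE
    for (ch in children[[t]]) {
      n_unresolved[[ch]] <- n_unresolved[[ch]] - 1L
      if (n_unresolved[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(out) != length(terms)) stop("ontology graph contains a cycle")
  rev(out)
}

#' @export
print.ontology_dag <- function(x, ...) {
  cat("ontology_dag:", length(x$terms) - 1L, "terms +1 synthetic root;",
      "max level", max(x$level), "\n")
  invisible(x)
}

check_term <- function(dag, term) {
  bad <- setdiff(term, dag$terms)
  if (length(bad) > 0L)
    stop("unknown ontology term(s): ", paste(bad, collapse = ", "))
  invisible(TRUE)
}

#' Level of a term
#'
#' The level of a term is its maximum distance (longest directed path) from
#' the root term \code{"all"}; the root itself has level 0 and the three
#' namespace roots level 1.
#'
#' @param dag an \code{\link{ontology_dag}}
#' @param term term id(s)
#' @return integer vector of levels
#' @export
term_level <- function(dag, term) {
  check_term(dag, term)
  dag$level[term]
}

#' Ancestors of a term
#'
#' Transitive closure over parent edges, excluding the term itself and
#' including the root \code{"all"}.
#'
#' @inheritParams term_level
#' @return character vector of ancestor term ids
#' @export
term_ancestors <- function(dag, term) {
  stopifnot(length(term) == 1L)
  check_term(dag, term)
  key <- paste0("anc:", term)
  hit <- get0(key, envir = dag$cache, inherits = FALSE)
  if (!is.null(hit)) return(hit)
  seen <- character(0)
  frontier <- dag$parents[[term]]
  while (length(frontier) > 0L) {
    new <- setdiff(frontier, seen)
    seen <- c(seen, new)
    frontier <- unique(unlist(dag$parents[new], use.names = FALSE))
  }
  assign(key, seen, envir = dag$cache)
  seen
}

#' Map terms to a parental level
#'
#' Terms whose level is at most \code{L} pass through unchanged; a deeper term
#' is replaced by its ancestors whose level equals \code{L}. Because the level
#' is a maximum distance, a deep term can lack ancestors at exactly level
#' \code{L}; such a term falls back to its ancestors of maximal level strictly
#' below \code{L}, so no annotation is discarded.
#'
#' @inheritParams term_level
#' @param terms character vector of term ids
#' @param L target level, >= 1
#' @return deduplicated character vector of mapped term ids
#' @export
map_to_level <- function(dag, terms, L) {
  stopifnot(length(L) == 1L, L >= 1)
  check_term(dag, terms)
  out <- lapply(unique(terms), function(t) {
    if (dag$level[[t]] <= L) return(t)
    anc <- term_ancestors(dag, t)
    lev <- dag$level[anc]
    at <- anc[lev == L]
    if (length(at) > 0L) return(at)
    below <- lev[lev < L]
    anc[lev == max(below)]
  })
  unique(unlist(out, use.names = FALSE))
}

#' Read an OBO-format ontology
#'
#' Minimal OBO 1.2 reader covering the stanza fields \code{id}, \code{name},
#' \code{namespace}, \code{is_a} and \code{relationship: part_of}. Both
#' \code{is_a} and \code{part_of} are traversed identically as parent edges;
#' other relationship types are ignored, and obsolete terms are skipped.
#'
#' @param path path to an OBO file
#' @return an \code{\link{ontology_dag}}
#' @export
read_obo <- function(path) {
  lines <- readLines(path, warn = FALSE)
  ns_map <- c(molecular_function = "MF", biological_process = "BP",
              cellular_component = "CC")
  parents <- list(); namespace <- character(0); nms <- character(0)
  id <- NULL; in_term <- FALSE; obsolete <- FALSE; par <- character(0)
  ns <- NA_character_; nm <- NA_character_
  flush <- function() {
    if (!is.null(id) && !obsolete && !is.na(ns)) {
      parents[[id]] <<- par
      namespace[[id]] <<- ns
      nms[[id]] <<- nm
    }
  }
  for (ln in lines) {
    ln <- sub("\\s*!.*$", "", trimws(ln))
    if (ln == "") next
    if (grepl("^\\[", ln)) {
      flush()
      in_term <- identical(ln, "[Term]")
      id <- NULL; obsolete <- FALSE; par <- character(0)
      ns <- NA_character_; nm <- NA_character_
      next
    }
    if (!in_term) next
    if (grepl("^id:", ln)) id <- trimws(sub("^id:", "", ln))
    else if (grepl("^name:", ln)) nm <- trimws(sub("^name:", "", ln))
    else if (grepl("^namespace:", ln)) {
      raw <- trimws(sub("^namespace:", "", ln))
      ns <- if (raw %in% names(ns_map)) ns_map[[raw]] else NA_character_
    }
    else if (grepl("^is_a:", ln)) par <- c(par, trimws(sub("^is_a:", "", ln)))
    else if (grepl("^relationship:\\s*part_of", ln))
      par <- c(par, trimws(sub("^relationship:\\s*part_of", "", ln)))
    else if (grepl("^is_obsolete:\\s*true", ln)) obsolete <- TRUE
  }
  flush()
  if (length(parents) == 0L) stop("no terms found in ", path)
  # drop parent references to terms we skipped (e.g. obsolete)
  keep <- names(parents)
  parents <- lapply(parents, function(p) intersect(p, keep))
  ontology_dag(parents, namespace, nms)
}

#' Read a GAF 2.x annotation file
#'
#' Reads gene to GO-term annotations from a tab-separated GAF file (columns 2,
#' 5 and 7: object id, GO id, evidence code). Comment lines starting with
#' \code{!} are skipped. Annotations with an excluded evidence code (by
#' default \code{IEA}, electronically inferred) are removed; annotations to
#' terms absent from the ontology are dropped with a warning.
#'
#' @param path path to a GAF file
#' @param dag an \code{\link{ontology_dag}} used to validate term ids
#' @param exclude_evidence evidence codes to drop (default \code{"IEA"})
#' @return an \code{annotation_set}: list with \code{annotations} (named list
#'   gene -> character vector of term ids) and \code{evidence} (data.frame)
#' @export
read_gaf <- function(path, dag, exclude_evidence = "IEA") {
  df <- utils::read.delim(path, header = FALSE, comment.char = "!",
                          stringsAsFactors = FALSE, quote = "")
  if (ncol(df) < 7L) stop("GAF file has fewer than 7 columns: ", path)
  ann <- data.frame(gene = as.character(df[[2L]]),
                    term = as.character(df[[5L]]),
                    evidence = as.character(df[[7L]]),
                    stringsAsFactors = FALSE)
  annotation_set(ann, dag, exclude_evidence = exclude_evidence)
}

#' Construct an annotation set
#'
#' @param ann data.frame with columns \code{gene}, \code{term},
#'   \code{evidence}
#' @inheritParams read_gaf
#' @return an \code{annotation_set}
#' @export
annotation_set <- function(ann, dag = NULL, exclude_evidence = "IEA") {
  stopifnot(all(c("gene", "term", "evidence") %in% names(ann)))
  ann <- ann[!(ann$evidence %in% exclude_evidence), , drop = FALSE]
  if (!is.null(dag)) {
    bad <- !(ann$term %in% dag$terms)
    if (any(bad)) {
      warning(sum(bad), " annotation(s) to terms absent from the ontology dropped")
      ann <- ann[!bad, , drop = FALSE]
    }
  }
  ann <- unique(ann[, c("gene", "term", "evidence")])
  annotations <- lapply(split(ann$term, ann$gene), unique)
  structure(list(annotations = annotations, evidence = ann),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat("annotation_set:", length(x$annotations), "genes,",
      nrow(x$evidence), "annotations\n")
  invisible(x)
}

gene_terms <- function(ann, gene) {
  ts <- ann$annotations[[gene]]
  if (is.null(ts)) character(0) else ts
}

#' Map every annotation in a set to a parental level
#'
#' Applies \code{\link{map_to_level}} to each gene's term set, emulating
#' analyses at a reduced annotation resolution.
#'
#' @param ann an \code{annotation_set}
#' @param dag an \code{\link{ontology_dag}}
#' @param L target level
#' @return a new \code{annotation_set}
#' @export
map_annotations <- function(ann, dag, L) {
  mapped <- lapply(ann$annotations, function(ts) map_to_level(dag, ts, L))
  rows <- data.frame(
    gene = rep(names(mapped), lengths(mapped)),
    term = unlist(mapped, use.names = FALSE),
    evidence = "mapped", stringsAsFactors = FALSE)
  annotation_set(rows, dag, exclude_evidence = character(0))
}

#' Annotation-frequency table
#'
#' Up-propagates each gene's annotations through all ancestors (the true-path
#' rule) and counts, per term, the number of distinct genes whose propagated
#' set contains the term. \code{p(term)} is the fraction of the annotation
#' corpus annotated (directly or via descendants) with the term; it is
#' non-decreasing from child to parent and equals 1 at the root.
#'
#' @param dag an \code{\link{ontology_dag}}
#' @param ann an \code{annotation_set}
#' @return a \code{term_frequency} object: list with \code{count} and \code{p}
#'   (named numeric over all terms) and \code{total_genes}
#' @export
build_term_frequencies <- function(dag, ann) {
  genes <- names(ann$annotations)
  if (length(genes) == 0L) stop("empty annotation corpus")
  count <- stats::setNames(numeric(length(dag$terms)), dag$terms)
  for (g in genes) {
    ts <- ann$annotations[[g]]
    anc <- unique(unlist(lapply(ts, term_ancestors, dag = dag),
                         use.names = FALSE))
    hit <- unique(c(ts, anc))
    count[hit] <- count[hit] + 1
  }
  structure(list(count = count, p = count / length(genes),
                 total_genes = length(genes)),
            class = "term_frequency")
}

#' @export
print.term_frequency <- function(x, ...) {
  cat("term_frequency:", sum(x$count > 0), "terms with nonzero count over",
      x$total_genes, "genes\n")
  invisible(x)
}
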