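#' Specification of a synthetic fixture
#'
#' Parameters of the synthetic data bundle used to exercise every stage of
#' the pipeline offline. The planted signal follows the same logic the method
#' assumes of real data: the gene at an enzyme position resembles its network
#' neighbors. With effect size \eqn{s}, the correct gene copies a fraction
#' \eqn{s} of each first-level neighbor's annotations, mixes its expression
#' profile with the neighbors' mean (weight \eqn{\sqrt{s}}) and copies the
#' neighbors' majority presence/absence bit with probability \eqn{s};
#' the position's functional profile draws a fraction \eqn{s} of its terms
#' from the correct gene's annotations. At \eqn{s = 0} the correct gene is
#' statistically exchangeable with the decoys.
#'
#' @param seed RNG seed; the same spec and seed give byte-identical files
#' @param depth,branching ontology shape per namespace (levels below the
#'   namespace root; level width grows by \code{branching} per level, capped
#'   at 48, so deep terms stay rare and informative)
#' @param n_enzymes,n_decoys gene counts (enzymes occupy network positions;
#'   decoys form the negative candidate pool)
#' @param terms_per_gene base annotation density (split across MF/BP/CC)
#' @param effect_size planted effect in [0, 1]
#' @param n_reactions,n_metabolites,n_abundant,orphan_fraction network shape;
#'   abundant metabolites are drawn from
#'   \code{\link{default_abundant_metabolites}}
#' @param n_conditions expression matrix width
#' @param n_genomes phylogenetic-profile width
#' @param n_abstracts synthetic literature corpus size
#' @param profile_terms terms per position profile
#' @return a \code{fixture_spec}
#' @export
fixture_spec <- function(seed = 1, depth = 6, branching = 3,
                         n_enzymes = 60, n_decoys = 200,
                         terms_per_gene = 5, effect_size = 0.8,
                         n_reactions = 90, n_metabolites = 100,
                         n_abundant = 5, orphan_fraction = 0.1,
                         n_conditions = 20, n_genomes = 25,
                         n_abstracts = 300, profile_terms = 4) {
  stopifnot(depth >= 3, branching >= 2, n_enzymes >= 2, n_decoys >= 1,
            terms_per_gene >= 1, effect_size >= 0, effect_size <= 1,
            n_reactions >= n_enzymes / 2, n_metabolites >= 3,
            orphan_fraction >= 0, orphan_fraction < 1,
            n_conditions >= 3, n_genomes >= 3, profile_terms >= 1)
  if (n_abundant > length(default_abundant_metabolites()))
    stop("n_abundant exceeds the built-in abundant-metabolite list")
  structure(as.list(environment()), class = "fixture_spec")
}

fixture_vocab <- function() {
  paste0(rep(c("kinase", "transferase", "hydrolase", "ligase", "oxidase",
               "reductase", "synthase", "phosphatase", "transport", "binding",
               "membrane", "nuclear", "ribosome", "glycolysis", "lipid",
               "amino", "acid", "sterol", "heme", "cation", "anion", "proton",
               "sugar", "folate", "purine", "pyrimidine", "vesicle", "wall",
               "redox", "signal"), each = 4),
         rep(c("alpha", "beta", "gamma", "delta"), times = 30))
}

# random ontology: per namespace, `depth` levels below the namespace root,
# each term with 1 parent one level up (20% get a second, forming diamonds)
generate_dag <- function(spec) {
  parents <- list(); namespace <- character(0); nms <- character(0)
  vocab <- fixture_vocab()
  counter <- 0L
  new_id <- function() {
    counter <<- counter + 1L
    sprintf("GO:%07d", counter)
  }
  levels_of <- list()
  for (ns in c("MF", "BP", "CC")) {
    root <- new_id()
    parents[[root]] <- character(0)
    namespace[[root]] <- ns
    nms[[root]] <- paste(tolower(ns), "root")
    lv <- list(root)
    for (l in 2:spec$depth) {
      width <- min(spec$branching^(l - 1L), 48L)
      ids <- vapply(seq_len(width), function(i) new_id(), "")
      for (id in ids) {
        par <- sample(lv[[l - 1L]], 1L)
        if (length(lv[[l - 1L]]) > 1L && stats::runif(1) < 0.2)
          par <- unique(c(par, sample(setdiff(lv[[l - 1L]], par), 1L)))
        parents[[id]] <- par
        namespace[[id]] <- ns
        tokens <- sample(vocab, 2L)
        if (stats::runif(1) < 0.1)
          tokens <- c(tokens[1L], sample(c("and", "or", "not"), 1L),
                      tokens[2L])
        nms[[id]] <- paste(tokens, collapse = " ")
      }
      lv[[l]] <- ids
    }
    levels_of[[ns]] <- lv
  }
  list(dag = ontology_dag(parents, namespace, nms), levels_of = levels_of)
}

write_obo <- function(dag, path) {
  ns_long <- c(MF = "molecular_function", BP = "biological_process",
               CC = "cellular_component")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (t in setdiff(dag$terms, "all")) {
    writeLines("[Term]", con)
    writeLines(paste0("id: ", t), con)
    writeLines(paste0("name: ", dag$name[[t]]), con)
    writeLines(paste0("namespace: ", ns_long[[dag$namespace[[t]]]]), con)
    for (p in setdiff(dag$parents[[t]], "all"))
      writeLines(paste0("is_a: ", p), con)
    writeLines("", con)
  }
  invisible(path)
}

write_gaf <- function(rows, dag, path) {
  aspect <- c(MF = "F", BP = "P", CC = "C")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("!gaf-version: 2.1", con)
  fields <- cbind("SYNTH", rows$gene, rows$gene, "", rows$term, "REF:0000001",
                  rows$evidence, "", aspect[dag$namespace[rows$term]],
                  "", "", "protein", "taxon:0", "20160101", "SYNTH", "", "")
  writeLines(apply(fields, 1L, paste, collapse = "\t"), con)
  invisible(path)
}

#' Tally abstract association counts from a synthetic corpus
#'
#' A term matches an abstract when every non-stopword token of the term's
#' name occurs among the abstract's tokens (the words "and", "or", "not" are
#' removed from term names before matching). Single counts tally matching
#' abstracts per term; pair counts tally abstracts matched by both terms of a
#' pair.
#'
#' @param term_names named character vector: term id -> name
#' @param abstracts list of character vectors (an abstract's tokens)
#' @param stopwords words removed from term names before matching
#' @return an \code{assoc_counts} of type \code{"abstract"}
#' @export
generate_abstract_counts <- function(term_names, abstracts,
                                     stopwords = c("and", "or", "not")) {
  tokens_of <- lapply(strsplit(term_names, "\\s+"), setdiff, y = stopwords)
  single <- stats::setNames(numeric(length(term_names)), names(term_names))
  pair_env <- new.env(parent = emptyenv())
  for (ab in abstracts) {
    matched <- names(term_names)[vapply(tokens_of, function(tk)
      length(tk) > 0L && all(tk %in% ab), TRUE)]
    single[matched] <- single[matched] + 1
    if (length(matched) >= 2L) {
      cmb <- utils::combn(sort(matched), 2L)
      for (j in seq_len(ncol(cmb))) {
        key <- pair_key(cmb[1L, j], cmb[2L, j])
        pair_env[[key]] <- (if (is.null(pair_env[[key]])) 0
                            else pair_env[[key]]) + 1
      }
    }
  }
  keys <- ls(pair_env)
  pair <- stats::setNames(vapply(keys, function(k) pair_env[[k]], 0),
                          keys)
  assoc_counts(single, pair, total = length(abstracts), type = "abstract")
}

#' Generate a synthetic fixture bundle
#'
#' Emits every input the pipeline consumes — ontology (OBO), annotations
#' (GAF), reaction table, abundant-metabolite list, expression and
#' phylogenetic-profile matrices, abstract count tables, per-position
#' functional profiles and a ground-truth table — into \code{dir}, plus a
#' \code{manifest.json} with the spec and per-file MD5 checksums. See
#' \code{\link{fixture_spec}} for how the planted signal scales with the
#' effect size.
#'
#' @param spec a \code{\link{fixture_spec}}
#' @param dir output directory (created if needed)
#' @return invisibly, a list with \code{dir}, named \code{files}, and the
#'   \code{positions} (enzyme nodes with at least one informative neighbor)
#' @export
generate_fixture <- function(spec, dir) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  set.seed(spec$seed)

  gd <- generate_dag(spec)
  dag <- gd$dag
  deep_terms <- lapply(gd$levels_of, function(lv)
    unlist(lv[(spec$depth - 1L):spec$depth], use.names = FALSE))

  enzymes <- sprintf("enz%03d", seq_len(spec$n_enzymes))
  decoys <- sprintf("dec%03d", seq_len(spec$n_decoys))
  genes <- c(enzymes, decoys)

  ## --- reactions and network -------------------------------------------
  abundant <- default_abundant_metabolites()[seq_len(spec$n_abundant)]
  specific <- sprintf("m%03d", seq_len(spec$n_metabolites))
  rxn_ids <- sprintf("R%03d", seq_len(spec$n_reactions))
  orphan <- stats::runif(spec$n_reactions) < spec$orphan_fraction
  if (sum(!orphan) < spec$n_enzymes)
    stop("infeasible spec: fewer non-orphan reactions than enzymes")
  rxn_enz <- vector("list", spec$n_reactions)
  carrier <- rep(sample(enzymes), length.out = sum(!orphan))
  slot <- 1L
  for (i in seq_len(spec$n_reactions)) {
    if (orphan[[i]]) { rxn_enz[[i]] <- character(0); next }
    e <- carrier[[slot]]; slot <- slot + 1L
    if (stats::runif(1) < 0.2) e <- unique(c(e, sample(enzymes, 1L)))
    rxn_enz[[i]] <- e
  }
  rxn_met <- lapply(seq_len(spec$n_reactions), function(i) {
    m <- sample(specific, sample(2:3, 1L))
    if (stats::runif(1) < 0.5) m <- c(m, sample(abundant, 1L))
    m
  })
  reactions <- reaction_table(rxn_ids, rxn_enz, rxn_met)
  net <- build_een(reactions, abundant)

  # positions: enzyme nodes with >= 1 first-level gene (non-pseudo) neighbor
  n1_genes <- lapply(stats::setNames(enzymes, enzymes), function(e) {
    if (!(e %in% net$nodes)) return(character(0))
    nb <- neighbors_at_level(net, e, 1L)
    nb[!net$is_pseudo[nb]]
  })
  positions <- enzymes[lengths(n1_genes) > 0L]
  # every first-level gene neighbor donates planted signal
  plant_nb <- n1_genes[positions]

  ## --- annotations ------------------------------------------------------
  ns_seq <- rep(c("MF", "BP", "CC"), length.out = spec$terms_per_gene)
  base_terms <- stats::setNames(lapply(genes, function(g) {
    unlist(lapply(c("MF", "BP", "CC"), function(ns) {
      k <- sum(ns_seq == ns)
      if (k == 0L) character(0) else sample(deep_terms[[ns]], k)
    }), use.names = FALSE)
  }), genes)
  final_terms <- base_terms
  for (e in positions) {
    copied <- unlist(lapply(plant_nb[[e]], function(g) {
      src <- base_terms[[g]]
      k <- round(spec$effect_size * length(src))
      if (k == 0L) character(0) else sample(src, k)
    }), use.names = FALSE)
    final_terms[[e]] <- unique(c(base_terms[[e]], copied))
  }
  codes <- c("EXP", "IDA", "IMP", "ISS")
  ann_rows <- do.call(rbind, lapply(genes, function(g) {
    data.frame(gene = g, term = final_terms[[g]],
               evidence = sample(codes, length(final_terms[[g]]),
                                 replace = TRUE),
               stringsAsFactors = FALSE)
  }))
  # electronically-inferred noise that readers must filter out
  iea_genes <- sample(genes, max(1L, round(0.2 * length(genes))))
  iea_rows <- do.call(rbind, lapply(iea_genes, function(g) {
    data.frame(gene = g,
               term = sample(unlist(deep_terms, use.names = FALSE), 2L),
               evidence = "IEA", stringsAsFactors = FALSE)
  }))
  ann_rows <- rbind(ann_rows, iea_rows)
  ann_rows <- ann_rows[order(ann_rows$gene, ann_rows$term), , drop = FALSE]

  ## --- expression -------------------------------------------------------
  base_expr <- matrix(stats::rnorm(length(genes) * spec$n_conditions),
                      nrow = length(genes),
                      dimnames = list(genes,
                                      sprintf("cond%02d",
                                              seq_len(spec$n_conditions))))
  expr <- base_expr
  for (e in positions) {
    nb <- plant_nb[[e]]
    sig <- colMeans(base_expr[nb, , drop = FALSE])
    if (stats::sd(sig) > 0) {
      sig <- sig / stats::sd(sig)
      expr[e, ] <- sqrt(spec$effect_size) * sig +
        sqrt(1 - spec$effect_size) * base_expr[e, ]
    }
  }
  expr <- round(expr, 6)

  ## --- phylogenetic profiles -------------------------------------------
  base_phy <- matrix(stats::rbinom(length(genes) * spec$n_genomes, 1L, 0.4),
                     nrow = length(genes),
                     dimnames = list(genes,
                                     sprintf("gen%02d",
                                             seq_len(spec$n_genomes))))
  phy <- base_phy
  for (e in positions) {
    nb <- plant_nb[[e]]
    maj <- as.integer(colMeans(base_phy[nb, , drop = FALSE]) >= 0.5)
    take <- stats::runif(spec$n_genomes) < spec$effect_size
    phy[e, take] <- maj[take]
  }

  ## --- functional profiles ---------------------------------------------
  all_terms <- unlist(deep_terms, use.names = FALSE)
  profiles <- stats::setNames(lapply(positions, function(e) {
    k_true <- round(spec$effect_size * spec$profile_terms)
    own <- final_terms[[e]]
    from_gene <- if (k_true > 0L) sample(own, min(k_true, length(own)))
                 else character(0)
    rand <- sample(all_terms, spec$profile_terms - length(from_gene))
    functional_profile(e, unique(c(from_gene, rand)), dag)
  }), positions)

  ## --- literature corpus ------------------------------------------------
  vocab <- fixture_vocab()
  abstracts <- lapply(seq_len(spec$n_abstracts), function(i) {
    g <- sample(genes, 1L)
    ts <- final_terms[[g]]
    ts <- sample(ts, min(2L, length(ts)))
    if (stats::runif(1) < 0.3) ts <- c(ts, sample(all_terms, 1L))
    tokens <- unlist(strsplit(dag$name[ts], "\\s+"), use.names = FALSE)
    unique(c(tokens, sample(vocab, 3L)))
  })
  abstract_counts <- generate_abstract_counts(
    dag$name[setdiff(dag$terms, "all")], abstracts)

  ## --- write the bundle -------------------------------------------------
  files <- c(ontology = "ontology.obo", annotations = "annotations.gaf",
             reactions = "reactions.tsv", abundant = "abundant.txt",
             expression = "expression.tsv", phylo = "phylo.tsv",
             profiles = "profiles.tsv",
             abstract_single = "abstract_single.tsv",
             abstract_pair = "abstract_pair.tsv",
             abstract_total = "abstract_total.txt",
             truth = "truth.tsv")
  paths <- stats::setNames(file.path(dir, files), names(files))
  write_obo(dag, paths[["ontology"]])
  write_gaf(ann_rows, dag, paths[["annotations"]])
  write_reactions(reactions, paths[["reactions"]])
  writeLines(abundant, paths[["abundant"]])
  write_gene_matrix(expr, paths[["expression"]])
  write_gene_matrix(phy, paths[["phylo"]])
  write_profiles(profiles, paths[["profiles"]])
  write_assoc_counts(abstract_counts, paths[["abstract_single"]],
                     paths[["abstract_pair"]], paths[["abstract_total"]])
  utils::write.table(data.frame(position = positions, gene = positions),
                     paths[["truth"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  manifest <- list(
    spec = unclass(spec),
    files = as.list(stats::setNames(unname(tools::md5sum(paths)), files)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(dir = dir, files = paths, positions = positions))
}

#' Read a truth table
#' @param path two-column TSV (\code{position}, \code{gene})
#' @return named character vector: position -> correct gene
#' @export
read_truth <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(df$gene, df$position)
}

#' Load a fixture bundle back into analysis-ready objects
#'
#' Reads every file written by \code{\link{generate_fixture}} through the
#' package's own readers and derives the downstream objects (co-occurrence
#' counts, term frequencies, network).
#'
#' @param dir fixture directory
#' @return list with \code{dag}, \code{ann}, \code{freq}, \code{cooc},
#'   \code{abstracts}, \code{reactions}, \code{abundant}, \code{net},
#'   \code{expr}, \code{phylo}, \code{profiles}, \code{truth},
#'   \code{positions}
#' @export
load_fixture <- function(dir) {
  p <- function(f) file.path(dir, f)
  dag <- read_obo(p("ontology.obo"))
  ann <- read_gaf(p("annotations.gaf"), dag)
  reactions <- read_reactions(p("reactions.tsv"))
  abundant <- readLines(p("abundant.txt"), warn = FALSE)
  net <- build_een(reactions, abundant)
  truth <- read_truth(p("truth.tsv"))
  list(dag = dag, ann = ann,
       freq = build_term_frequencies(dag, ann),
       cooc = build_cooccurrence(ann),
       abstracts = read_assoc_counts(p("abstract_single.tsv"),
                                     p("abstract_pair.tsv"),
                                     p("abstract_total.txt")),
       reactions = reactions, abundant = abundant, net = net,
       expr = read_gene_matrix(p("expression.tsv")),
       phylo = read_gene_matrix(p("phylo.tsv")),
       profiles = read_profiles(p("profiles.tsv"), dag),
       truth = truth, positions = names(truth))
}
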