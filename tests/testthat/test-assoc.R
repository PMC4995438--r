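# brute-force count tables from an explicit list of per-gene term sets
counts_from_corpus <- function(corpus) {
  terms <- sort(unique(unlist(corpus)))
  single <- vapply(terms, function(t)
    sum(vapply(corpus, function(ts) t %in% ts, TRUE)), 0)
  keys <- character(0); vals <- numeric(0)
  for (i in seq_along(terms)) {
    for (j in seq_along(terms)) {
      if (i >= j) next
      k <- pair_key(terms[i], terms[j])
      n <- sum(vapply(corpus, function(ts)
        terms[i] %in% ts && terms[j] %in% ts, TRUE))
      if (n > 0) { keys <- c(keys, k); vals <- c(vals, n) }
    }
  }
  assoc_counts(single, stats::setNames(vals, keys), length(corpus))
}

test_that("term association is the lift of co-annotation over independence", {
  # a and b always co-annotated in 5 of 10 genes: lift = 10 * 5 / (5 * 5) = 2
  corpus <- c(rep(list(c("a", "b")), 5), rep(list("z"), 5))
  counts <- counts_from_corpus(corpus)
  expect_equal(cas_term("a", "b", counts), 2)
  # zero co-occurrence scores zero
  corpus2 <- list(c("a"), c("b"), c("a", "z"))
  expect_equal(cas_term("a", "b", counts_from_corpus(corpus2)), 0)
  # symmetric on random counts
  set.seed(1)
  for (i in 1:10) {
    corpus3 <- lapply(1:8, function(.) sample(letters[1:5], sample(1:3, 1)))
    c3 <- counts_from_corpus(corpus3)
    pairs <- t(utils::combn(names(c3$single), 2))
    for (r in seq_len(nrow(pairs)))
      expect_equal(cas_term(pairs[r, 1], pairs[r, 2], c3),
                   cas_term(pairs[r, 2], pairs[r, 1], c3))
  }
  expect_error(cas_term("a", "missing", counts), "absent")
})

test_that("association scores are invariant to a uniform count rescaling", {
  set.seed(2)
  corpus <- lapply(1:10, function(.) sample(letters[1:6], sample(2:4, 1)))
  counts <- counts_from_corpus(corpus)
  doubled <- assoc_counts(counts$single * 2, counts$pair * 2,
                          counts$total * 2)
  for (i in 1:10) {
    ab <- sample(names(counts$single), 2)
    expect_equal(cas_term(ab[1], ab[2], counts),
                 cas_term(ab[1], ab[2], doubled))
  }
})

test_that("protein association averages the full annotation cross product", {
  set.seed(3)
  corpus <- lapply(1:12, function(.) sample(letters[1:8], sample(2:4, 1)))
  counts <- counts_from_corpus(corpus)
  ann <- make_ann(X = c("a", "b"), Y = c("c", "d", "e"))
  # identical singleton annotations collapse to the single term pair
  ann1 <- make_ann(P = "a", Q = "a")
  expect_equal(cas_protein("P", "Q", ann1, counts),
               cas_term("a", "a", counts))
  # exhaustive double loop over the 2 x 3 cross product
  manual <- mean(outer(c("a", "b"), c("c", "d", "e"),
                       Vectorize(function(u, v) cas_term(u, v, counts))))
  expect_equal(cas_protein("X", "Y", ann, counts), manual)
  expect_equal(cas_protein("X", "Y", ann, counts),
               cas_protein("Y", "X", ann, counts))
  # bounded by the best term pair
  best <- max(outer(c("a", "b"), c("c", "d", "e"),
                    Vectorize(function(u, v) cas_term(u, v, counts))))
  expect_lte(cas_protein("X", "Y", ann, counts), best)
  expect_error(cas_protein("X", "nogene", ann, counts), "annotations")
})

test_that("self term pairs count every annotated gene", {
  corpus <- list(c("a", "b"), c("a"), c("c"))
  counts <- counts_from_corpus(corpus)
  # pair(a, a) = single(a) = 2; score = 3 * 2 / (2 * 2)
  expect_equal(cas_term("a", "a", counts), 3 * 2 / 4)
})

test_that("abstract association mirrors the gene form on a toy corpus", {
  # six abstracts with known co-mentions, tallied by hand:
  #   names: t1 "alpha kinase", t2 "beta kinase", t3 "gamma pump"
  nm <- c(t1 = "alpha kinase", t2 = "beta kinase", t3 = "gamma pump")
  abstracts <- list(
    c("alpha", "kinase", "beta"),            # t1, t2
    c("alpha", "kinase"),                    # t1
    c("beta", "kinase", "gamma", "pump"),    # t2, t3
    c("gamma", "pump"),                      # t3
    c("alpha", "beta", "kinase"),            # t1, t2
    c("unrelated"))
  counts <- generate_abstract_counts(nm, abstracts)
  expect_equal(unname(counts$single[c("t1", "t2", "t3")]), c(3, 3, 2))
  expect_equal(unname(counts$pair[pair_key("t1", "t2")]), 2)
  expect_equal(pas_term("t1", "t2", counts), 6 * 2 / (3 * 3))
  expect_equal(pas_term("t1", "t3", counts), 0)
  ann <- make_ann(X = c("t1"), Y = c("t2", "t3"))
  expect_equal(pas_protein("X", "Y", ann, counts),
               mean(c(pas_term("t1", "t2", counts),
                      pas_term("t1", "t3", counts))))
})

test_that("stopwords are stripped from term names before matching", {
  nm <- c(t1 = "alpha and kinase")
  counts <- generate_abstract_counts(nm, list(c("alpha", "kinase")))
  expect_equal(unname(counts$single["t1"]), 1)   # matched despite no "and"
})

test_that("log conversion is offset, monotone and exact at closed forms", {
  expect_equal(log_transform(0, epsilon = 1e-6), log(1e-6))
  expect_equal(log_transform(exp(1) - 1, epsilon = 1), 1)
  s <- sort(stats::runif(20) * 100)
  expect_true(all(diff(log_transform(s)) > 0))
  expect_error(log_transform(-0.5), "non-negative")
})

test_that("count tables survive a disk round trip and reject bad input", {
  set.seed(4)
  corpus <- lapply(1:9, function(.) sample(letters[1:6], sample(2:3, 1)))
  counts <- counts_from_corpus(corpus)
  d <- tempfile(); dir.create(d)
  write_assoc_counts(counts, file.path(d, "s.tsv"), file.path(d, "p.tsv"),
                     file.path(d, "t.txt"))
  back <- read_assoc_counts(file.path(d, "s.tsv"), file.path(d, "p.tsv"),
                            file.path(d, "t.txt"), type = "gene")
  expect_equal(back$single[order(names(back$single))],
               counts$single[order(names(counts$single))])
  expect_equal(back$pair[order(names(back$pair))],
               counts$pair[order(names(counts$pair))])
  expect_equal(back$total, counts$total)
  # pair exceeding a single count violates the containment bound
  expect_error(assoc_counts(c(a = 1, b = 5),
                            stats::setNames(3, pair_key("a", "b")), 10),
               "exceeds")
})

test_that("co-occurrence built from an annotation set matches the hand tally", {
  ann <- make_ann(g1 = c("a", "b"), g2 = c("a", "b", "c"), g3 = "c")
  cooc <- build_cooccurrence(ann)
  expect_equal(cooc$total, 3)
  expect_equal(unname(cooc$single[c("a", "b", "c")]), c(2, 2, 2))
  expect_equal(unname(cooc$pair[pair_key("a", "b")]), 2)
  expect_equal(unname(cooc$pair[pair_key("b", "c")]), 1)
  expect_true(is.na(cooc$pair[pair_key("a", "z")]))
})
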