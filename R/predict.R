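#' Rank of the correct gene among scored candidates
#'
#' Descending-score rank; tied scores receive the mean rank of the tied block
#' (deterministic, seed-free), so an uninformative constant score over a pool
#' of n candidates ranks the correct gene (n + 1) / 2.
#'
#' @param scores named numeric vector: candidate -> score
#' @param correct id of the correct gene (must be in \code{scores})
#' @return the rank (possibly fractional under ties)
#' @export
rank_candidates <- function(scores, correct) {
  if (length(scores) == 0L) stop("empty candidate pool")
  if (!(correct %in% names(scores)))
    stop("correct gene ", correct, " not in the candidate pool")
  unname(rank(-scores, ties.method = "average")[correct])
}

#' Ranking result over a set of enzyme positions
#'
#' @param position character vector of position ids
#' @param rank numeric vector: rank of the correct gene at each position
#' @param pool_size integer vector: candidate pool size at each position
#' @param prob_correct optional: combiner probability of the correct gene
#' @return a \code{ranking_result} data.frame
#' @export
ranking_result <- function(position, rank, pool_size,
                           prob_correct = NULL) {
  stopifnot(length(position) == length(rank),
            length(position) == length(pool_size),
            all(rank >= 1), all(rank <= pool_size))
  df <- data.frame(position = position, rank = rank, pool_size = pool_size,
                   stringsAsFactors = FALSE)
  if (!is.null(prob_correct)) df$prob_correct <- prob_correct
  structure(df, class = c("ranking_result", "data.frame"))
}

#' Mean reciprocal rank
#'
#' \eqn{MRR = \frac{1}{N_E} \sum_{i=1}^{N_E} 1 / R_i} over the queried enzyme
#' positions; 1.0 (the highest value possible) when the correct gene is
#' always ranked at the top.
#'
#' @param result a \code{ranking_result} or a numeric vector of ranks
#' @return value in (0, 1]
#' @export
mrr <- function(result) {
  ranks <- if (inherits(result, "ranking_result")) result$rank else result
  if (length(ranks) == 0L) stop("no positions in the ranking result")
  mean(1 / ranks)
}

#' Cumulative correct-within-rank curve
#'
#' For each threshold r = 1..\code{max_rank}, the number of positions where
#' the correct gene was ranked within the top r; non-decreasing in r.
#'
#' @inheritParams mrr
#' @param max_rank largest threshold
#' @return named integer vector (threshold -> count)
#' @export
cumulative_rank_curve <- function(result, max_rank) {
  stopifnot(max_rank >= 1)
  ranks <- if (inherits(result, "ranking_result")) result$rank else result
  stats::setNames(vapply(seq_len(max_rank), function(r) sum(ranks <= r), 0L),
                  seq_len(max_rank))
}

#' Train the L2-regularized logistic combiner
#'
#' Fits a ridge-penalized (L2) logistic regression of the position labels on
#' the feature columns, with negative examples down-weighted to counter their
#' large number (default class weight 0.001). The penalty is parameterized by
#' \code{C} (larger C, weaker penalty), mapped to the glmnet lambda as
#' \code{1 / (C * n)}. Features are standardized internally before fitting
#' (coefficients are reported on the original scale), so the log-converted
#' association scores and the [0, 1] similarity scores are penalized
#' comparably.
#'
#' @param x numeric feature matrix (rows = candidate examples)
#' @param y 0/1 labels
#' @param C inverse regularization strength (default 1)
#' @param negative_weight observation weight of the negative class
#' @return a \code{combiner_model}: list with \code{beta} (named coefficient
#'   vector), \code{intercept}, \code{C}, \code{negative_weight},
#'   \code{feature_cols}
#' @export
train_combiner <- function(x, y, C = 1, negative_weight = 0.001) {
  x <- as.matrix(x)
  y <- as.integer(y)
  if (length(unique(y)) < 2L)
    stop("degenerate training set: a single class only")
  w <- ifelse(y == 1L, 1, negative_weight)
  fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                        lambda = 1 / (C * nrow(x)), weights = w,
                        standardize = TRUE)
  cf <- as.matrix(stats::coef(fit))[, 1L]
  structure(list(beta = cf[-1L], intercept = unname(cf[1L]), C = C,
                 negative_weight = negative_weight,
                 feature_cols = colnames(x)),
            class = "combiner_model")
}

#' @export
print.combiner_model <- function(x, ...) {
  cat("combiner_model:", length(x$beta), "features, C =", x$C,
      ", negative weight =", x$negative_weight, "\n")
  invisible(x)
}

#' Candidate probabilities from a trained combiner
#'
#' @param model a \code{combiner_model}
#' @param newx numeric matrix (or feature-column data.frame) with the same
#'   feature columns the model was trained on
#' @return numeric vector of probabilities in [0, 1]
#' @export
predict_combiner <- function(model, newx) {
  newx <- as.matrix(newx[, model$feature_cols, drop = FALSE])
  stats::plogis(drop(newx %*% model$beta) + model$intercept)
}

# sample training rows: all positives plus n_neg_train negatives per position
sample_training_rows <- function(fm, positions, n_neg_train) {
  idx <- lapply(positions, function(p) {
    rows <- which(fm$position == p)
    pos <- rows[fm$label[rows] == 1L]
    neg <- rows[fm$label[rows] == 0L]
    if (length(neg) > n_neg_train)
      neg <- sample(neg, n_neg_train)
    c(pos, neg)
  })
  unlist(idx, use.names = FALSE)
}

#' Leave-one-out combiner training
#'
#' Fits the combiner on every position except the held-out one, using each
#' training position's single positive example plus a random sample of its
#' negative candidates.
#'
#' @param fm a \code{feature_matrix} from \code{\link{build_feature_matrix}}
#' @param held_out_position position id to exclude
#' @param feature_cols feature columns (default all of them)
#' @param n_neg_train negatives sampled per training position (default 1000)
#' @param C,negative_weight see \code{\link{train_combiner}}
#' @param seed optional seed for the negative sampling
#' @return a \code{combiner_model}
#' @export
train_combiner_loo <- function(fm, held_out_position,
                               feature_cols = attr(fm, "feature_cols"),
                               n_neg_train = 1000, C = 1,
                               negative_weight = 0.001, seed = NULL) {
  positions <- setdiff(unique(fm$position), held_out_position)
  if (length(positions) < 1L)
    stop("leave-one-out requires at least 2 positions")
  if (!is.null(seed)) set.seed(seed)
  rows <- sample_training_rows(fm, positions, n_neg_train)
  train_combiner(fm[rows, feature_cols, drop = FALSE], fm$label[rows],
                 C = C, negative_weight = negative_weight)
}

#' Leave-one-out evaluation of the combiner
#'
#' For each position, trains the combiner on all other positions
#' (\code{\link{train_combiner_loo}}), scores the held-out position's
#' candidate pool and records the rank of the correct gene.
#'
#' @inheritParams train_combiner_loo
#' @param seed seed controlling all negative sampling (one sub-seed per
#'   position, derived deterministically)
#' @return a \code{ranking_result} with \code{prob_correct}
#' @export
evaluate_loo <- function(fm, feature_cols = attr(fm, "feature_cols"),
                         n_neg_train = 1000, C = 1, negative_weight = 0.001,
                         seed = 1) {
  positions <- unique(fm$position)
  if (length(positions) < 2L) stop("leave-one-out requires >= 2 positions")
  res <- lapply(seq_along(positions), function(i) {
    p <- positions[[i]]
    model <- train_combiner_loo(fm, p, feature_cols, n_neg_train, C,
                                negative_weight,
                                seed = (seed * 1009L + i) %% .Machine$integer.max)
    rows <- fm[fm$position == p, , drop = FALSE]
    probs <- stats::setNames(predict_combiner(model, rows), rows$candidate)
    correct <- rows$candidate[rows$label == 1L]
    if (length(correct) != 1L)
      stop("position ", p, " must have exactly one positive candidate")
    data.frame(position = p,
               rank = rank_candidates(probs, correct),
               pool_size = nrow(rows),
               prob_correct = unname(probs[correct]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  ranking_result(out$position, out$rank, out$pool_size, out$prob_correct)
}
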