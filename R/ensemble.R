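# Seeded bagged-tree ensemble grader.
#
# The deterministic decision-table grader is the reference path; this
# ensemble reproduces the probabilistic grading stage as a bagged CART
# forest trained on lesion feature vectors. No tree package is assumed:
# the CART grower below is self-contained, uses Gini impurity, samples
# `mtry` candidate features per node, and is fully deterministic given
# the training seed.

build_cart <- function(X, y, K, mtry, max_depth = 14L, min_node = 2L) {
  grow <- function(idx, depth) {
    counts <- tabulate(y[idx], K)
    n <- length(idx)
    if (depth >= max_depth || n < min_node || sum(counts > 0) == 1L) {
      return(list(leaf = TRUE, prob = counts / n))
    }
    feats <- sample.int(ncol(X), min(mtry, ncol(X)))
    gini_parent <- 1 - sum((counts / n)^2)
    best <- NULL
    best_gain <- 1e-12
    for (j in feats) {
      x <- X[idx, j]
      o <- order(x)
      xs <- x[o]
      ys <- y[idx][o]
      if (xs[1L] == xs[n]) next
      cum <- vapply(seq_len(K), function(k) cumsum(ys == k), numeric(n))
      cut_at <- which(xs[-n] < xs[-1L])
      if (!length(cut_at)) next
      nl <- cut_at
      nr <- n - nl
      left <- cum[cut_at, , drop = FALSE]
      right <- matrix(counts, length(cut_at), K, byrow = TRUE) - left
      gl <- 1 - rowSums((left / nl)^2)
      gr <- 1 - rowSums((right / nr)^2)
      gain <- gini_parent - (nl * gl + nr * gr) / n
      m <- which.max(gain)
      if (gain[m] > best_gain) {
        best_gain <- gain[m]
        best <- list(j = j, thr = (xs[cut_at[m]] + xs[cut_at[m] + 1L]) / 2)
      }
    }
    if (is.null(best)) return(list(leaf = TRUE, prob = counts / n))
    go_left <- X[idx, best$j] <= best$thr
    list(leaf = FALSE, feature = best$j, threshold = best$thr,
         left = grow(idx[go_left], depth + 1L),
         right = grow(idx[!go_left], depth + 1L))
  }
  grow(seq_len(nrow(X)), 0L)
}

predict_cart <- function(tree, x) {
  node <- tree
  while (!node$leaf) {
    node <- if (x[node$feature] <= node$threshold) node$left else node$right
  }
  node$prob
}

#' Train the bagged-tree ensemble grader
#'
#' Fits a seeded bagged CART ensemble on lesion feature vectors (see
#' [featurise()]) labelled with severity levels. Training is fully
#' deterministic given `seed`; prediction returns per-class
#' probabilities that sum to 1.
#'
#' @param features numeric matrix, one row per image (columns as
#'   produced by [featurise()]).
#' @param labels level labels, one per row of `features`; must take at
#'   least two distinct values from the scheme's ladder.
#' @param table the [grading_table()] defining the level ladder.
#' @param ntree number of bagged trees (default 60).
#' @param mtry candidate features per node; default
#'   `ceiling(sqrt(ncol(features)))`.
#' @param max_depth maximum tree depth.
#' @param seed integer seed fixing bootstrap resampling and feature
#'   subsampling.
#' @return an object of class `ensemble_grader`.
#' @export
#' @seealso [predict_ensemble()]
train_ensemble_grader <- function(features, labels, table, ntree = 60L,
                                  mtry = NULL, max_depth = 14L, seed = 1L) {
  stopifnot(inherits(table, "grading_scheme"))
  X <- as.matrix(features)
  storage.mode(X) <- "double"
  y <- match(as.character(labels), table$levels)
  if (anyNA(y)) {
    stop("labels contain values not on the ", table$scheme, " ladder",
         call. = FALSE)
  }
  if (nrow(X) != length(y)) stop("features/labels length mismatch",
                                 call. = FALSE)
  if (length(unique(y)) < 2L) {
    stop("training requires at least two distinct classes", call. = FALSE)
  }
  K <- length(table$levels)
  mtry <- as.integer(mtry %||% ceiling(sqrt(ncol(X))))
  trees <- with_seed(seed, {
    lapply(seq_len(ntree), function(b) {
      boot <- sample.int(nrow(X), nrow(X), replace = TRUE)
      build_cart(X[boot, , drop = FALSE], y[boot], K, mtry, max_depth)
    })
  })
  structure(list(trees = trees, levels = table$levels,
                 scheme = table$scheme, table = table,
                 n_features = ncol(X), feature_names = colnames(X),
                 ntree = ntree, mtry = mtry, seed = as.integer(seed)),
            class = "ensemble_grader")
}

#' @export
print.ensemble_grader <- function(x, ...) {
  cat(sprintf("<ensemble_grader> %s, %d trees (mtry %d), %d features, seed %d\n",
              x$scheme, x$ntree, x$mtry, x$n_features, x$seed))
  invisible(x)
}

#' Predict a grade from a feature vector with the ensemble
#'
#' Averages the per-tree class probabilities; the predicted level is the
#' probability argmax with ties broken toward the lower severity
#' (conservative against severity over-calling, the dominant error mode
#' in lesion-based screening).
#'
#' @param model an [train_ensemble_grader()] result.
#' @param features a feature vector of length `model$n_features`, or a
#'   matrix of such rows.
#' @param summary optional [summarise_lesions()] result used to assess
#'   maculopathy for the returned grade; otherwise `dmo` is `FALSE`.
#' @return a `grade_result` with `probabilities` set (or a list of them
#'   when `features` is a multi-row matrix).
#' @export
predict_ensemble <- function(model, features, summary = NULL) {
  stopifnot(inherits(model, "ensemble_grader"))
  X <- if (is.null(dim(features))) matrix(features, nrow = 1L) else
    as.matrix(features)
  if (ncol(X) != model$n_features) {
    stop(sprintf("expected %d features, got %d", model$n_features, ncol(X)),
         call. = FALSE)
  }
  out <- lapply(seq_len(nrow(X)), function(i) {
    probs <- rowMeans(vapply(model$trees, predict_cart, x = X[i, ],
                             numeric(length(model$levels))))
    probs <- probs / sum(probs)
    names(probs) <- model$levels
    level <- model$levels[which.max(probs)]  # first max = lower severity
    dmo <- if (!is.null(summary)) assess_maculopathy(summary, model$table)
           else FALSE
    new_grade_result(model$table, level, dmo = dmo,
                     evidence = list(rule = "ensemble",
                                     lesion_ids = integer(0)),
                     probabilities = probs)
  })
  if (nrow(X) == 1L) out[[1L]] else out
}
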