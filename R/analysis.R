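.angle_matrix <- function(vectors) {
  if (is.data.frame(vectors)) {
    ts <- if ("timestamp" %in% names(vectors)) vectors$timestamp else NULL
    X <- as.matrix(vectors[, intersect(angle_ids(), names(vectors)), drop = FALSE])
  } else {
    ts <- attr(vectors, "timestamps")
    X <- as.matrix(vectors)
  }
  if (ncol(X) == 0 || !is.numeric(X)) {
    s2s_error("no angle columns found", "s2s_domain_error")
  }
  list(X = X, timestamps = ts)
}

# k-means++ seeding (D^2-weighted) on rows of X.
.kmpp_centers <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(NA_real_, k, ncol(X))
  centers[1, ] <- X[sample.int(n, 1), ]
  if (k > 1) {
    d2 <- rowSums((X - matrix(centers[1, ], n, ncol(X), byrow = TRUE))^2)
    for (j in 2:k) {
      if (sum(d2) <= 0) {
        # all remaining points coincide with a center: duplicate the farthest
        idx <- which.max(d2)
      } else {
        idx <- sample.int(n, 1, prob = d2)
      }
      centers[j, ] <- X[idx, ]
      d2 <- pmin(d2, rowSums((X - matrix(centers[j, ], n, ncol(X), byrow = TRUE))^2))
    }
  }
  centers
}

# Lloyd iterations with the documented empty-cluster rule: an emptied cluster
# is re-seeded at the point farthest from its assigned centroid.
.lloyd <- function(X, centers, iter_max = 100, tol = 1e-6) {
  n <- nrow(X); k <- nrow(centers)
  assign_rows <- function(centers) {
    d <- outer(rowSums(X^2), rep(1, k)) - 2 * X %*% t(centers) +
      outer(rep(1, n), rowSums(centers^2))
    max.col(-d, ties.method = "first")
  }
  cl <- assign_rows(centers)
  for (it in seq_len(iter_max)) {
    newc <- centers
    for (j in seq_len(k)) {
      members <- which(cl == j)
      if (length(members) == 0) {
        dmin <- rowSums((X - centers[cl, , drop = FALSE])^2)
        newc[j, ] <- X[which.max(dmin), ]
      } else {
        newc[j, ] <- colMeans(X[members, , drop = FALSE])
      }
    }
    shift <- max(sqrt(rowSums((newc - centers)^2)))
    centers <- newc
    cl <- assign_rows(centers)
    if (shift < tol) break
  }
  wss <- sum((X - centers[cl, , drop = FALSE])^2)
  list(cluster = cl, centers = centers, tot_withinss = wss, iterations = it)
}

#' Cluster per-frame postures into center postures
#'
#' k-means over the 12-dimensional angle vectors, with k-means++
#' initialization, 10 restarts and a 1e-6 convergence tolerance on the
#' centroid shift, keeping the restart with the lowest total within-cluster
#' sum of squares. Initialization samples rows in a canonical (lexicographic)
#' order, so the result does not depend on frame order given the seed.
#'
#' @param vectors Data frame with the 12 angle columns (and optionally a
#'   `timestamp` column, used to order stages), or a numeric matrix.
#' @param k Number of clusters (1 <= k <= number of frames).
#' @param seed Integer seed.
#' @param nstart Number of k-means++ restarts (default 10).
#' @return Object of class `posture_clusters`: list with `k`, `centroids`
#'   (k x 12), `cluster` (assignments), `timestamps`, `stage_order` (cluster
#'   ids ordered by mean timestamp), `tot_withinss`.
#' @export
cluster_postures <- function(vectors, k, seed = 1, nstart = 10) {
  am <- .angle_matrix(vectors)
  X <- am$X
  if (!is.finite(k) || k < 1 || k > nrow(X)) {
    s2s_error(sprintf("k must lie in [1, %d]", nrow(X)), "s2s_domain_error")
  }
  k <- as.integer(k)
  ord <- do.call(order, as.data.frame(X))
  Xs <- X[ord, , drop = FALSE]
  set.seed(as.integer(seed))
  best <- NULL
  for (r in seq_len(nstart)) {
    centers <- .kmpp_centers(Xs, k)
    fit <- tryCatch(
      {
        km <- stats::kmeans(X, centers = centers, iter.max = 100,
                            algorithm = "Lloyd")
        list(cluster = km$cluster, centers = km$centers,
             tot_withinss = km$tot.withinss, iterations = km$iter)
      },
      error = function(e) .lloyd(X, centers),
      warning = function(w) .lloyd(X, centers)
    )
    if (is.null(best) || fit$tot_withinss < best$tot_withinss) best <- fit
  }
  ts <- am$timestamps
  stage_order <- if (!is.null(ts)) {
    mt <- vapply(seq_len(k), function(j) mean(ts[best$cluster == j]), numeric(1))
    order(mt)
  } else seq_len(k)
  colnames(best$centers) <- colnames(X)
  structure(list(k = k, centroids = best$centers, cluster = best$cluster,
                 timestamps = ts, stage_order = stage_order,
                 tot_withinss = best$tot_withinss,
                 iterations = best$iterations),
            class = "posture_clusters")
}

#' @export
print.posture_clusters <- function(x, ...) {
  cat(sprintf("<posture_clusters> k = %d, %d frames, tot.withinss = %.3f\n",
              x$k, length(x$cluster), x$tot_withinss))
  invisible(x)
}

#' Per-angle activity thresholds per cohort
#'
#' The activity threshold of an angle is the [min, max] range it traverses
#' over all frames of all subjects in a cohort. Degenerate frames are skipped
#' (with a warning reporting the count); a subject whose frames are all
#' degenerate raises an error.
#'
#' @param sequences List of `motion_sequence` objects (one or both cohorts).
#' @param defs Angle definitions.
#' @return Object of class `threshold_table`: data frame with columns
#'   `cohort`, `angle`, `lower`, `upper`.
#' @export
extract_thresholds <- function(sequences, defs = default_angle_definitions()) {
  if (inherits(sequences, "motion_sequence")) sequences <- list(sequences)
  if (length(sequences) == 0) {
    s2s_error("at least one sequence is required", "s2s_domain_error")
  }
  tab <- extract_angle_table(sequences, defs = defs, on_degenerate = "skip")
  ids <- names(defs)
  out <- do.call(rbind, lapply(unique(tab$cohort), function(co) {
    sub <- tab[tab$cohort == co, , drop = FALSE]
    data.frame(cohort = co, angle = ids,
               lower = vapply(ids, function(a) min(sub[[a]]), numeric(1)),
               upper = vapply(ids, function(a) max(sub[[a]]), numeric(1)),
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  structure(out, class = c("threshold_table", "data.frame"))
}

#' @export
print.threshold_table <- function(x, ...) {
  cat("<threshold_table>\n")
  print(as.data.frame(x))
  invisible(x)
}

#' Normalize an importance vector by its maximum
#'
#' @param importance Non-negative importance values.
#' @return Percentages: `importance / max(importance) * 100` (the most
#'   influential entry is 100%).
#' @export
normalized_importance <- function(importance) {
  if (any(importance < 0)) {
    s2s_error("importance values must be non-negative", "s2s_domain_error")
  }
  m <- max(importance)
  if (m <= 0) s2s_error("all importance values are zero", "s2s_domain_error")
  importance / m * 100
}

#' Rank angle importance with a small neural network
#'
#' Fits a single-hidden-layer perceptron (4 hidden units by default, softmax
#' class output, covariates z-scored on the training split) to predict the
#' stage label from the 12 angles, then scores each angle by permutation
#' importance on the held-out split: the mean decrease in test accuracy over
#' `n_perm` independent permutations of that angle's column, clipped at zero
#' and normalized to sum to one. The normalized importance rescales by the
#' maximum, so the most influential angle reads 100%.
#'
#' @param vectors Data frame or matrix with the 12 angle columns.
#' @param labels Stage labels (>= 2 classes), one per row.
#' @param split Training fraction in (0, 1); default 0.75.
#' @param hidden_units Hidden layer size; default 4.
#' @param seed Integer seed (split, network init, permutations).
#' @param n_perm Permutations per angle (default 20).
#' @param maxit,decay Optimizer settings passed to [nnet::nnet()].
#' @return Object of class `importance_result`: data frame with columns
#'   `angle`, `importance`, `normalized`, `raw_drop` (unnormalized mean
#'   accuracy decrease) and `perm_se` (its permutation standard error), plus
#'   attributes `train_n`, `test_n`, `test_accuracy`, `flags`.
#' @export
rank_importance <- function(vectors, labels, split = 0.75, hidden_units = 4,
                            seed = 1, n_perm = 20, maxit = 500, decay = 1e-4) {
  am <- .angle_matrix(vectors)
  X <- am$X
  y <- factor(labels)
  if (length(y) != nrow(X)) {
    s2s_error("labels must have one entry per frame", "s2s_domain_error")
  }
  if (nlevels(droplevels(y)) < 2) {
    s2s_error("labels must contain at least 2 classes", "s2s_domain_error")
  }
  if (!is.finite(split) || split <= 0 || split >= 1) {
    s2s_error("split must lie in (0, 1)", "s2s_domain_error")
  }
  y <- droplevels(y)
  set.seed(as.integer(seed))
  n <- nrow(X)
  idx_train <- sort(sample.int(n, max(2, round(split * n))))
  idx_test <- setdiff(seq_len(n), idx_train)
  if (length(idx_test) < 1 || nlevels(droplevels(y[idx_train])) < 2) {
    s2s_error("split leaves too few rows or classes for training/testing",
              "s2s_domain_error")
  }
  mu <- colMeans(X[idx_train, , drop = FALSE])
  sdv <- apply(X[idx_train, , drop = FALSE], 2, stats::sd)
  sdv[sdv < 1e-12] <- 1
  scale_x <- function(M) sweep(sweep(M, 2, mu), 2, sdv, "/")
  Xtr <- scale_x(X[idx_train, , drop = FALSE])
  Xte <- scale_x(X[idx_test, , drop = FALSE])
  ytr <- y[idx_train]; yte <- y[idx_test]
  fit <- nnet::nnet(Xtr, nnet::class.ind(ytr), size = hidden_units,
                    softmax = TRUE, maxit = maxit, decay = decay,
                    trace = FALSE)
  pred_class <- function(M) {
    p <- stats::predict(fit, M)
    levels(y)[max.col(p, ties.method = "first")]
  }
  acc0 <- mean(pred_class(Xte) == as.character(yte))
  flags <- character(0)
  if (acc0 <= 1 / nlevels(y) + 1e-9) {
    flags <- c(flags, "test accuracy no better than chance; importances unreliable")
    warning("network test accuracy is no better than chance")
  }
  nte <- nrow(Xte)
  drops <- matrix(NA_real_, n_perm, ncol(X))
  for (j in seq_len(ncol(X))) {
    for (r in seq_len(n_perm)) {
      Xp <- Xte
      Xp[, j] <- Xp[sample.int(nte), j]
      drops[r, j] <- acc0 - mean(pred_class(Xp) == as.character(yte))
    }
  }
  raw <- pmax(0, colMeans(drops))
  perm_se <- apply(drops, 2, stats::sd) / sqrt(n_perm)
  if (sum(raw) <= 0) {
    flags <- c(flags, "no permutation reduced accuracy; importances set uniform")
    imp <- rep(1 / ncol(X), ncol(X))
  } else {
    imp <- raw / sum(raw)
  }
  res <- data.frame(angle = colnames(X), importance = imp,
                    normalized = normalized_importance(imp),
                    raw_drop = raw, perm_se = perm_se, row.names = NULL,
                    stringsAsFactors = FALSE)
  structure(res, class = c("importance_result", "data.frame"),
            train_n = length(idx_train), test_n = nte,
            test_accuracy = acc0, flags = flags)
}

#' @export
print.importance_result <- function(x, ...) {
  cat(sprintf("<importance_result> train n = %d, test n = %d, test accuracy = %.3f\n",
              attr(x, "train_n"), attr(x, "test_n"), attr(x, "test_accuracy")))
  df <- as.data.frame(x)
  print(df[order(-df$importance), ], row.names = FALSE)
  for (f in attr(x, "flags")) cat("note:", f, "\n")
  invisible(x)
}

#' Temporally ordered stage summary of a posture clustering
#'
#' Orders clusters by mean timestamp and reports member counts and centroid
#' angles. With `coarse = m`, fine clusters are agglomerated into `m` coarse
#' stages by average-linkage clustering of the centroids (each fine cluster
#' maps to exactly one coarse stage); coarse stages are again ordered by mean
#' timestamp.
#'
#' @param clusters A `posture_clusters` object with timestamps.
#' @param coarse Optional number of coarse stages (< k).
#' @return Object of class `stage_report`: data frame with one row per fine
#'   cluster in temporal order (`stage`, `cluster_id`, `n`, `mean_time`,
#'   centroid angle columns, and `coarse_stage` if requested), with the
#'   fine-to-coarse mapping as attribute `"coarse_map"`.
#' @export
stage_report <- function(clusters, coarse = NULL) {
  if (!inherits(clusters, "posture_clusters")) {
    s2s_error("clusters must be a posture_clusters object", "s2s_domain_error")
  }
  ts <- clusters$timestamps
  if (is.null(ts)) ts <- rep(NA_real_, length(clusters$cluster))
  k <- clusters$k
  mean_time <- vapply(seq_len(k), function(j) mean(ts[clusters$cluster == j]),
                      numeric(1))
  counts <- tabulate(clusters$cluster, nbins = k)
  ord <- clusters$stage_order
  df <- data.frame(stage = seq_len(k), cluster_id = ord, n = counts[ord],
                   mean_time = mean_time[ord], row.names = NULL)
  df <- cbind(df, as.data.frame(clusters$centroids[ord, , drop = FALSE],
                                row.names = NULL))
  coarse_map <- NULL
  if (!is.null(coarse)) {
    if (!is.finite(coarse) || coarse < 1 || coarse > k) {
      s2s_error("coarse must lie in [1, k]", "s2s_domain_error")
    }
    hc <- stats::hclust(stats::dist(clusters$centroids), method = "average")
    fine_to_coarse <- stats::cutree(hc, k = as.integer(coarse))
    ct <- vapply(seq_len(max(fine_to_coarse)),
                 function(g) mean(ts[fine_to_coarse[clusters$cluster] == g]),
                 numeric(1))
    relabel <- match(seq_along(ct), order(ct))
    coarse_map <- relabel[fine_to_coarse]
    df$coarse_stage <- coarse_map[df$cluster_id]
  }
  structure(df, class = c("stage_report", "data.frame"), coarse_map = coarse_map)
}

#' @export
print.stage_report <- function(x, ...) {
  cat(sprintf("<stage_report> %d fine stage(s)\n", nrow(x)))
  print(as.data.frame(x)[, c("stage", "cluster_id", "n", "mean_time",
                             intersect("coarse_stage", names(x)))],
        row.names = FALSE)
  invisible(x)
}
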