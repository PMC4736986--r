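#' Partitioning Around Medoids over samples
#'
#' k-medoids clustering of the *samples* (columns) of an expression table,
#' with Euclidean distance in gene space.  The classic two-phase algorithm
#' is used: BUILD greedily seeds `k` medoids (first the sample minimizing
#' total distance to all others, then repeatedly the sample giving the
#' largest reduction in total cost), then SWAP repeatedly applies the
#' single best-improving medoid/non-medoid exchange until none improves.
#' The fit is deterministic given the input column order; ties are broken
#' towards lower sample indices.  The final total cost (sum of distances of
#' every sample to its nearest medoid) is a local optimum under single
#' swaps.  Because the medoids are actual training samples, the model can
#' assign *new* samples to clusters ([pam_assign()]).
#'
#' @param x An expression table; samples are the points to cluster.
#' @param k Number of clusters (2 <= k <= number of samples).
#' @return An object of class `pam_model`: medoid ids and expression
#'   vectors, the training clustering, and the total cost.
#' @export
pam_fit <- function(x, k) {
  x <- ensure_expr(x, arg = "x")
  m <- expr_mat(x)
  n <- ncol(m)
  if (!is.numeric(k) || length(k) != 1L || k != round(k) || k < 1L) {
    rlang::abort("`k` must be a positive integer", class = "tdmnorm_invalid")
  }
  if (k > n) {
    rlang::abort(sprintf("k (%d) exceeds the number of samples (%d)", k, n),
                 class = "tdmnorm_invalid")
  }
  d <- as.matrix(stats::dist(t(m), method = "euclidean"))

  if (k == n) {
    med <- seq_len(n)
  } else {
    # BUILD
    med <- which.min(colSums(d))
    while (length(med) < k) {
      best_gain <- -Inf
      best_j <- NA_integer_
      dn <- apply(d[, med, drop = FALSE], 1L, min)
      for (j in setdiff(seq_len(n), med)) {
        gain <- sum(pmax(dn - d[, j], 0))
        if (gain > best_gain + 1e-12) {
          best_gain <- gain
          best_j <- j
        }
      }
      med <- c(med, best_j)
    }
    # SWAP
    repeat {
      dmed <- d[, med, drop = FALSE]
      if (k > 1L) {
        ord <- t(apply(dmed, 1L, function(v) sort(v, partial = 1:2)[1:2]))
        d1 <- ord[, 1L]
        d2 <- ord[, 2L]
      } else {
        d1 <- dmed[, 1L]
        d2 <- rep(Inf, n)
      }
      nearest <- med[apply(dmed, 1L, which.min)]
      cur <- sum(d1)
      best_delta <- 0
      best_swap <- NULL
      for (mi in seq_along(med)) {
        is_m <- nearest == med[mi]
        for (h in setdiff(seq_len(n), med)) {
          newd <- ifelse(is_m, pmin(d2, d[, h]), pmin(d1, d[, h]))
          delta <- sum(newd) - cur
          if (delta < best_delta - 1e-12) {
            best_delta <- delta
            best_swap <- c(mi, h)
          }
        }
      }
      if (is.null(best_swap)) break
      med[best_swap[1L]] <- best_swap[2L]
    }
    med <- sort(med)
  }

  assign_idx <- apply(d[, med, drop = FALSE], 1L, which.min)
  structure(
    list(k = k,
         medoid_index = med,
         medoid_ids = expr_samples(x)[med],
         medoids = m[, med, drop = FALSE],
         gene_ids = rownames(m),
         clustering = as.integer(assign_idx),
         cost = sum(d[cbind(seq_len(n), med[assign_idx])]),
         distance = "euclidean"),
    class = "pam_model")
}

#' @export
print.pam_model <- function(x, ...) {
  cat(sprintf("PAM model: k = %d medoids (%s), total cost %.4f\n",
              x$k, paste(x$medoid_ids, collapse = ", "), x$cost))
  invisible(x)
}

#' Assign new samples to the nearest medoid
#'
#' Each sample of `x` is assigned to the cluster of its nearest medoid
#' (Euclidean distance over genes); exact ties go to the lowest medoid
#' index.  The genes of `x` must match the model's genes in order (use
#' [align_genes()] first).
#'
#' @param model A [pam_fit()] model.
#' @param x An expression table with genes aligned to the model.
#' @return A tibble with columns `sample` and `cluster` (integer).
#' @export
pam_assign <- function(model, x) {
  stopifnot(inherits(model, "pam_model"))
  x <- ensure_expr(x, arg = "x")
  if (!identical(expr_genes(x), model$gene_ids)) {
    rlang::abort("gene identifiers/order do not match the PAM model; align first",
                 class = "tdmnorm_invalid")
  }
  m <- expr_mat(x)
  d2 <- vapply(seq_len(model$k),
               function(j) colSums((m - model$medoids[, j])^2),
               numeric(ncol(m)))
  if (is.null(dim(d2))) d2 <- matrix(d2, nrow = ncol(m))
  cl <- apply(d2, 1L, which.min)
  tibble::tibble(sample = expr_samples(x), cluster = as.integer(cl))
}

#' Cluster-majority accuracy
#'
#' The proportion of samples placed in a cluster whose most common true
#' class matches their own: for each cluster the modal true class is found
#' (ties broken towards the alphabetically first class) and a sample counts
#' as correct iff its class equals its cluster's modal class.
#'
#' @param clusters Cluster labels (any atomic vector).
#' @param truth True class labels, same length.
#' @return A proportion in `[0, 1]`.
#' @export
cluster_majority_accuracy <- function(clusters, truth) {
  if (length(clusters) == 0L || length(clusters) != length(truth)) {
    rlang::abort("`clusters` and `truth` must be non-empty and equal length",
                 class = "tdmnorm_invalid")
  }
  truth <- as.character(truth)
  modal <- tapply(truth, as.character(clusters), function(v) {
    tab <- table(v)
    names(tab)[tab == max(tab)][1L]  # table() names are sorted
  })
  mean(truth == modal[as.character(clusters)])
}
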