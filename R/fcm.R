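# Fuzzy c-means clustering of PTM profiles with automatic fuzzifier and
# cluster-number estimation, and correlation-distance hierarchical clustering.

#' Estimate the fuzzifier from dataset dimensions
#'
#' Heuristic fuzzifier for clustering standardised omics profiles: grows with
#' dimensionality D and shrinks with the number of items N, so memberships
#' stay informative in high noise:
#' `m = 1 + (1418/N + 22.05) D^-2 + (12.33/N + 0.243) D^(-0.0406 ln N - 0.1134)`.
#'
#' @param n items (rows), `d` dimensions (columns).
#' @return fuzzifier m > 1.
#' @export
estimate_fuzzifier <- function(n, d) {
  1 + (1418 / n + 22.05) * d^-2 +
    (12.33 / n + 0.243) * d^(-0.0406 * log(n) - 0.1134)
}

#' Fuzzy c-means clustering
#'
#' Standard fuzzy c-means on row profiles: memberships
#' `u_ik = d_ik^(-2/(m-1)) / sum_j d_ij^(-2/(m-1))` and centroids as
#' membership^m-weighted means, iterated until the objective changes by less
#' than `tol`. Initialisation is k-means++-style seeding from `seed`, with
#' `n_init` restarts keeping the best objective.
#'
#' When `c = "auto"`, candidate cluster numbers `c_range` are scanned and the
#' largest c is kept whose minimum pairwise centroid distance exceeds
#' `min_sep` (duplicated centroids indicate an over-split solution). When
#' `m = "auto"`, the fuzzifier comes from [estimate_fuzzifier()].
#'
#' @param profiles items x dimensions numeric matrix; rows are z-scored
#'   when `standardize = TRUE` (default), the convention for abundance
#'   profiles.
#' @param c number of clusters (>= 2) or `"auto"`.
#' @param m fuzzifier (> 1) or `"auto"`.
#' @param seed integer seed controlling initialisation.
#' @param tol convergence tolerance on the relative objective change.
#' @param max_iter iteration cap; non-convergence returns the best iterate
#'   with `converged = FALSE`.
#' @param n_init random restarts.
#' @param c_range candidate cluster numbers for `c = "auto"`.
#' @param min_sep minimum centroid separation (Euclidean, on the standardised
#'   profile scale) for a candidate c to be admissible.
#' @param min_members minimum number of confident profiles (membership above
#'   0.5) every cluster must hold for a candidate c to be admissible.
#' @param standardize z-score rows before clustering.
#' @return object of class `fcm_fit`: `membership` (items x c, rows sum to
#'   1), `centers`, `m`, `c`, `objective`, `iterations`, `converged`, `seed`,
#'   `cluster` (hard assignment by maximal membership).
#' @export
fuzzy_cmeans <- function(profiles, c = "auto", m = "auto", seed = 1L,
                         tol = 1e-8, max_iter = 200L, n_init = 10L,
                         c_range = 2:12, min_sep = 0.8, min_members = 3L,
                         standardize = TRUE) {
  x <- as.matrix(profiles)
  stop_if(nrow(x) < 3, "at least 3 profiles are required")
  if (standardize) {
    sds <- apply(x, 1, stats::sd)
    stop_if(any(sds == 0), "constant profile row(s): ",
            paste(utils::head(rownames(x)[sds == 0]), collapse = ", "))
    x <- t(scale(t(x)))
  }
  if (identical(m, "auto")) m <- estimate_fuzzifier(nrow(x), ncol(x))
  stop_if(!is.numeric(m) || m <= 1, "fuzzifier 'm' must exceed 1")
  if (identical(c, "auto")) {
    fits <- lapply(c_range, function(cc)
      fcm_best(x, cc, m, seed, tol, max_iter, n_init))
    sep <- vapply(fits, function(f) min_center_sep(f$centers), 0)
    # admissible: centroids mutually separated AND every cluster supported by
    # at least min_members confident profiles (an extra centroid that only
    # captures outliers indicates an over-split solution)
    supported <- vapply(fits, function(f)
      min(colSums(f$membership > 0.5)) >= min_members, TRUE)
    ok <- which(sep > min_sep & supported)
    stop_if(length(ok) == 0, "no admissible cluster number in 'c_range'")
    fit <- fits[[max(ok)]]
  } else {
    stop_if(c < 2, "'c' must be at least 2")
    stop_if(c > nrow(x), "'c' exceeds the number of profiles")
    fit <- fcm_best(x, c, m, seed, tol, max_iter, n_init)
  }
  fit$cluster <- apply(fit$membership, 1, which.max)
  names(fit$cluster) <- rownames(x)
  fit$seed <- seed
  fit$data <- x
  class(fit) <- "fcm_fit"
  fit
}

min_center_sep <- function(centers) {
  if (nrow(centers) < 2) return(Inf)
  min(stats::dist(centers))
}

fcm_best <- function(x, c, m, seed, tol, max_iter, n_init) {
  best <- NULL
  for (r in seq_len(n_init)) {
    set.seed(derive_seed(seed, 1000L * c + r))
    fit <- fcm_once(x, c, m, tol, max_iter)
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  best
}

fcm_once <- function(x, c, m, tol, max_iter) {
  centers <- kmeanspp_init(x, c)
  obj_old <- Inf
  for (it in seq_len(max_iter)) {
    d2 <- pmax(dist2(x, centers), 0)
    u <- (d2 + 1e-12)^(-1 / (m - 1))
    # a point sitting on a centroid gets full membership there
    hit <- d2 < 1e-12
    u[rowSums(hit) > 0, ] <- hit[rowSums(hit) > 0, ] /
      pmax(rowSums(hit)[rowSums(hit) > 0], 1)
    u <- u / rowSums(u)
    um <- u^m
    centers <- (t(um) %*% x) / colSums(um)
    obj <- sum(um * d2)
    if (is.finite(obj_old) && abs(obj_old - obj) <= tol * max(obj, 1e-300))
      return(list(membership = u, centers = centers, m = m, c = c,
                  objective = obj, iterations = it, converged = TRUE))
    obj_old <- obj
  }
  list(membership = u, centers = centers, m = m, c = c, objective = obj,
       iterations = max_iter, converged = FALSE)
}

dist2 <- function(x, centers) {
  # squared Euclidean distances items x centers
  xx <- rowSums(x^2)
  cc <- rowSums(centers^2)
  outer(xx, cc, "+") - 2 * x %*% t(centers)
}

kmeanspp_init <- function(x, c) {
  n <- nrow(x)
  idx <- sample.int(n, 1L)
  for (j in seq_len(c - 1L)) {
    d2 <- apply(dist2(x, x[idx, , drop = FALSE]), 1, min)
    d2[idx] <- 0
    if (sum(d2) <= 0) {
      idx <- c(idx, sample(setdiff(seq_len(n), idx), 1L))
    } else {
      idx <- c(idx, sample.int(n, 1L, prob = d2 / sum(d2)))
    }
  }
  x[idx, , drop = FALSE]
}

#' @export
print.fcm_fit <- function(x, ...) {
  cat("Fuzzy c-means fit: c =", x$c, " m =", round(x$m, 3),
      " objective =", signif(x$objective, 6), "\n")
  cat("  converged:", x$converged, "after", x$iterations, "iterations\n")
  cat("  hard cluster sizes:\n")
  print(table(x$cluster))
  invisible(x)
}

#' @export
summary.fcm_fit <- function(object, ...) {
  list(c = object$c, m = object$m, objective = object$objective,
       sizes = table(object$cluster),
       mean_max_membership = mean(apply(object$membership, 1, max)))
}

#' @export
plot.fcm_fit <- function(x, ...) {
  graphics::matplot(t(x$centers), type = "l", lty = 1,
                    xlab = "sample", ylab = "centroid (z profile)",
                    main = paste0("FCM centroids (c = ", x$c, ")"), ...)
  invisible(x)
}

#' Hierarchical clustering with correlation distance
#'
#' Agglomerative clustering of matrix rows or columns with distance
#' `1 - Pearson r` and complete (default) or average linkage; the convention
#' for clustering expression or abundance profiles.
#'
#' @param mat numeric matrix.
#' @param axis cluster `"rows"` or `"cols"`.
#' @param linkage `"complete"` or `"average"`.
#' @return the [stats::hclust] dendrogram (heights, merge order, labels);
#'   cophenetic distances available via [stats::cophenetic()].
#' @export
hierarchical_cluster <- function(mat, axis = c("rows", "cols"),
                                 linkage = c("complete", "average")) {
  axis <- match.arg(axis)
  linkage <- match.arg(linkage)
  x <- if (axis == "rows") mat else t(mat)
  stop_if(nrow(x) < 2, "at least 2 items are required")
  sds <- apply(x, 1, stats::sd)
  stop_if(any(sds == 0), "constant row(s): ",
          paste(utils::head(rownames(x)[sds == 0]), collapse = ", "))
  d <- stats::as.dist(1 - stats::cor(t(x)))
  stats::hclust(d, method = linkage)
}
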