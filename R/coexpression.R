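# Unsigned weighted co-expression network: adjacency, soft-threshold scan,
# topological overlap, module detection/merging, eigengenes and kWithin.

check_expr <- function(expr) {
  stop_if(!is.matrix(expr) || !is.numeric(expr),
          "'expr' must be a numeric genes x samples matrix")
  stop_if(anyNA(expr), "'expr' contains missing values")
  stop_if(is.null(rownames(expr)), "'expr' must have gene ids as rownames")
  stop_if(anyDuplicated(rownames(expr)) > 0, "duplicate gene ids in 'expr'")
  v <- apply(expr, 1, stats::var)
  if (any(v == 0))
    stop("zero-variance gene(s): ",
         paste(utils::head(rownames(expr)[v == 0], 5), collapse = ", "),
         call. = FALSE)
  invisible(expr)
}

#' Keep the most variable genes
#'
#' Retains the `n_top` genes with the largest variance across samples,
#' the usual pre-filter before network construction. Ties in variance are
#' broken by gene id (lexicographically smaller kept first).
#'
#' @param expr numeric genes x samples matrix with gene rownames.
#' @param n_top number of genes to keep.
#' @return the filtered matrix, rows ordered by decreasing variance.
#' @export
variance_filter <- function(expr, n_top = 5000L) {
  stop_if(n_top <= 0, "'n_top' must be positive")
  stop_if(n_top > nrow(expr), "'n_top' exceeds the number of genes")
  v <- apply(expr, 1, stats::var)
  ord <- order(-v, rownames(expr))
  expr[ord[seq_len(n_top)], , drop = FALSE]
}

#' Unsigned weighted adjacency
#'
#' `a_ij = |cor(x_i, x_j)|^beta` with Pearson correlation over samples; the
#' diagonal is set to 0 so connectivities are sums over neighbours only.
#'
#' @param expr numeric genes x samples matrix.
#' @param beta positive soft-threshold exponent.
#' @return symmetric genes x genes matrix in `[0, 1]` with zero diagonal.
#' @export
adjacency_matrix <- function(expr, beta = 10) {
  stop_if(beta <= 0, "'beta' must be positive")
  stop_if(ncol(expr) < 3, "at least 3 samples are required")
  check_expr(expr)
  a <- abs(stats::cor(t(expr)))^beta
  diag(a) <- 0
  a
}

#' Scan soft-threshold candidates for scale-free fit
#'
#' For each candidate exponent, computes whole-network connectivities
#' `k_i = sum_j a_ij`, bins them, and regresses `log10 p(k)` on `log10 k`
#' (bin means). The fit R^2 is signed: negated when the slope is positive, so
#' maximising it prefers decaying degree distributions. Also reports the mean
#' connectivity, which decreases in beta.
#'
#' @param expr numeric genes x samples matrix.
#' @param candidate_betas candidate exponents.
#' @param n_bins connectivity histogram bins (about 10 is customary).
#' @param r2_cut fit threshold for the recommendation: the smallest beta whose
#'   signed R^2 reaches `r2_cut` is recommended.
#' @return `soft_threshold_scan` data.frame with columns `beta`, `r_squared`
#'   (signed; `NA` when fewer than 3 non-empty bins), `slope`,
#'   `mean_connectivity`; attribute `recommended` holds the recommended beta
#'   (`NA` if none qualifies).
#' @export
pick_soft_threshold <- function(expr, candidate_betas = c(1:10, 12, 14, 16, 18, 20),
                                n_bins = 10L, r2_cut = 0.8) {
  stop_if(length(candidate_betas) == 0, "no candidate beta values")
  check_expr(expr)
  ac <- abs(stats::cor(t(expr)))
  diag(ac) <- 0
  fit_one <- function(beta) {
    k <- colSums(ac^beta)
    sf <- scale_free_fit(k, n_bins)
    c(r_squared = sf$r2, slope = sf$slope, mean_connectivity = mean(k))
  }
  res <- t(vapply(candidate_betas, fit_one, c(0, 0, 0)))
  out <- data.frame(beta = candidate_betas, res)
  qual <- which(!is.na(out$r_squared) & out$r_squared >= r2_cut)
  attr(out, "recommended") <- if (length(qual)) out$beta[min(qual)] else NA_real_
  class(out) <- c("soft_threshold_scan", "data.frame")
  out
}

scale_free_fit <- function(k, n_bins = 10L) {
  br <- seq(min(k), max(k), length.out = n_bins + 1L)
  bin <- cut(k, br, include.lowest = TRUE)
  p <- tapply(k, bin, length) / length(k)
  km <- tapply(k, bin, mean)
  keep <- !is.na(p) & p > 0 & !is.na(km) & km > 0
  if (sum(keep) < 3) return(list(r2 = NA_real_, slope = NA_real_))
  f <- stats::lm(log10(p[keep]) ~ log10(km[keep]))
  r2 <- summary(f)$r.squared
  sl <- unname(stats::coef(f)[2])
  list(r2 = -sign(sl) * r2, slope = sl)
}

#' @export
print.soft_threshold_scan <- function(x, ...) {
  cat("Soft-threshold scan (recommended beta:",
      attr(x, "recommended"), ")\n")
  print.data.frame(x, row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
plot.soft_threshold_scan <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(op))
  graphics::plot(x$beta, x$r_squared, type = "b", xlab = "soft threshold",
                 ylab = "scale-free fit R2 (signed)", ...)
  graphics::abline(h = 0.8, lty = 2)
  graphics::plot(x$beta, x$mean_connectivity, type = "b",
                 xlab = "soft threshold", ylab = "mean connectivity", ...)
  invisible(x)
}

#' Topological overlap dissimilarity
#'
#' `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `l_ij = sum_u a_iu a_uj` over shared neighbours and `k_i` the connectivity;
#' `TOM_ii = 1`. Returns `1 - TOM`, the dissimilarity used for clustering.
#'
#' @param adjacency symmetric adjacency with zero diagonal, entries in `[0, 1]`.
#' @return symmetric dissimilarity matrix in `[0, 1]` with zero diagonal.
#' @export
tom_dissimilarity <- function(adjacency) {
  stop_if(!isSymmetric(unname(adjacency), tol = 1e-10),
          "adjacency must be symmetric")
  stop_if(any(diag(adjacency) != 0), "adjacency diagonal must be zero")
  a <- adjacency
  l <- a %*% a                 # since diag(a) = 0, this sums over u != i, j
  k <- colSums(a)
  kmin <- outer(k, k, pmin)
  tom <- (l + a) / (kmin + 1 - a)
  diag(tom) <- 1
  d <- 1 - tom
  dimnames(d) <- dimnames(adjacency)
  d
}

#' Detect co-expression modules from a TOM dissimilarity
#'
#' Average-linkage hierarchical clustering of the dissimilarity followed by a
#' tree cut. `method = "adaptive"` (default) is a dynamic-hybrid-style
#' procedure: it scans candidate cut heights over the dendrogram and keeps
#' the cut producing the most clusters of at least `min_module_size` genes;
#' clusters are only accepted when cohesive (mean within-cluster similarity
#' well above the network-wide background); genes left unassigned are
#' re-clustered recursively (so modules hidden below a coarse first cut are
#' still extracted), and finally a PAM-like reattachment assigns every
#' remaining unlabelled gene to its most similar module when close enough
#' (`pam_frac`). `deep_split` (0-4) biases
#' ties towards coarser (low values) or finer (high values) cuts.
#' `method = "fixed"` is a plain single cut at `cut_height`. Clusters smaller
#' than `min_module_size` are pooled into the "grey" pseudo-module; the rest
#' are labelled by descending size with the canonical colour sequence.
#'
#' @param diss square dissimilarity matrix (e.g. from [tom_dissimilarity()]).
#' @param min_module_size smallest admissible module.
#' @param method `"adaptive"` or `"fixed"`.
#' @param cut_height fixed cut height (required for `method = "fixed"`).
#' @param deep_split integer 0-4 (adaptive cut only).
#' @param pam_frac reattachment stringency of the adaptive cut; a grey gene
#'   joins its most similar module only when its mean similarity to it is at
#'   least this fraction of the module's internal cohesion (mean
#'   within-module similarity). Set 0 or `Inf` to disable.
#' @return named character vector gene -> module colour, with the dendrogram
#'   in attribute `"dendro"` and the first-round height in `"cut_height"`.
#' @export
detect_modules <- function(diss, min_module_size = 50L,
                           method = c("adaptive", "fixed"),
                           cut_height = NULL, deep_split = 2L,
                           pam_frac = 0.5) {
  method <- match.arg(method)
  stop_if(nrow(diss) != ncol(diss), "'diss' must be square")
  stop_if(min_module_size > nrow(diss), "min_module_size exceeds gene count")
  stop_if(!deep_split %in% 0:4, "'deep_split' must be an integer in 0..4")
  hc <- stats::hclust(stats::as.dist(diss), method = "average")
  if (method == "fixed") {
    stop_if(is.null(cut_height), "'cut_height' is required for the fixed cut")
    first <- cut_tree_best(hc, cut_height, NULL, min_module_size)
    lab <- first$labels
    h <- cut_height
  } else {
    sim <- 1 - diss
    med_sim <- stats::median(sim[upper.tri(sim)])
    # a cluster counts as a module only if it is cohesive: mean within-cluster
    # similarity well above both its similarity to the rest of the network and
    # the network-wide typical (median) similarity
    cohesive <- function(genes) {
      s <- sim[genes, genes, drop = FALSE]
      w <- (sum(s) - length(genes)) / (length(genes) * (length(genes) - 1))
      rest <- setdiff(rownames(sim), genes)
      b <- if (length(rest) == 0) 0 else mean(sim[genes, rest])
      w > 3 * max(b, med_sim)
    }
    drop_loose <- function(labels) {
      for (m in setdiff(unique(labels), "0"))
        if (!cohesive(names(labels)[labels == m])) labels[labels == m] <- "0"
      labels
    }
    first <- cut_tree_best(hc, NULL, deep_split, min_module_size)
    lab <- drop_loose(first$labels)
    h <- first$height
    # recursively re-extract modules hidden among the unassigned genes
    for (round in 1:3) {
      grey_genes <- names(lab)[lab == "0"]
      if (length(grey_genes) < max(2 * min_module_size, 4)) break
      sub <- diss[grey_genes, grey_genes, drop = FALSE]
      hc_sub <- stats::hclust(stats::as.dist(sub), method = "average")
      res <- cut_tree_best(hc_sub, NULL, deep_split, min_module_size)
      res$labels <- drop_loose(res$labels)
      if (all(res$labels == "0")) break
      new <- res$labels != "0"
      lab[grey_genes[new]] <- paste0("r", round, ".", res$labels[new])
    }
    # PAM-like stage: reattach an unassigned gene to its most similar module
    # when its mean similarity there reaches pam_frac of the module's own
    # internal cohesion
    if (pam_frac > 0 && is.finite(pam_frac)) {
      grey_genes <- which(lab == "0")
      mods <- setdiff(unique(lab), "0")
      if (length(mods) > 0 && length(grey_genes) > 0) {
        within <- vapply(mods, function(m) {
          s <- sim[lab == m, lab == m, drop = FALSE]
          (sum(s) - nrow(s)) / (nrow(s) * (nrow(s) - 1))
        }, 0)
        msim <- vapply(mods, function(m)
          rowMeans(sim[grey_genes, lab == m, drop = FALSE]),
          numeric(length(grey_genes)))
        msim <- matrix(msim, nrow = length(grey_genes))
        score <- sweep(msim, 2, within, "/")
        best_m <- max.col(score, ties.method = "first")
        best_s <- score[cbind(seq_along(grey_genes), best_m)]
        take <- best_s > pam_frac
        lab[grey_genes[take]] <- mods[best_m[take]]
      }
    }
  }
  lab[lab == "0"] <- "grey"
  lab <- relabel_by_size(lab)
  attr(lab, "dendro") <- hc
  attr(lab, "cut_height") <- h
  lab
}

# Cut a dendrogram at the height maximising the number of clusters of at
# least min_size genes (or at a fixed height); clusters below min_size get
# label "0". Returns labels named by the tree's leaf names.
cut_tree_best <- function(hc, cut_height, deep_split, min_size) {
  if (is.null(cut_height)) {
    hts <- sort(unique(hc$height))
    cand <- unique(stats::quantile(hts, probs = seq(0.05, 0.999,
                                                    length.out = 80),
                                   names = FALSE, type = 7))
    n_ok <- vapply(cand, function(hh)
      sum(table(stats::cutree(hc, h = hh)) >= min_size), 0L)
    best <- which(n_ok == max(n_ok))
    # deep_split 0..4: 0 prefers the coarsest qualifying cut, 4 the finest
    pick <- best[round(1 + (length(best) - 1) * (1 - deep_split / 4))]
    cut_height <- cand[pick]
  }
  cl <- stats::cutree(hc, h = cut_height)
  sizes <- table(cl)
  lab <- ifelse(sizes[as.character(cl)] >= min_size, as.character(cl), "0")
  names(lab) <- hc$labels
  list(labels = lab, height = cut_height)
}

#' Module eigengenes
#'
#' The eigengene of a module is the first principal component of its genes'
#' standardised expression (each gene scaled to mean 0, SD 1 across samples):
#' the first right singular vector of the standardised submatrix, sign-oriented
#' so its correlation with the module's mean expression profile is
#' non-negative. A singleton module's eigengene is its standardised profile.
#'
#' @param expr numeric genes x samples matrix.
#' @param modules named character vector gene -> module label.
#' @param exclude_grey drop the "grey" pseudo-module (default `FALSE`).
#' @return modules x samples matrix of eigengene values; each row has unit
#'   Euclidean norm.
#' @export
module_eigengenes <- function(expr, modules, exclude_grey = FALSE) {
  stop_if(!all(names(modules) %in% rownames(expr)),
          "partition refers to genes absent from 'expr'")
  labs <- sort(unique(modules))
  if (exclude_grey) labs <- setdiff(labs, "grey")
  me <- matrix(NA_real_, length(labs), ncol(expr),
               dimnames = list(labs, colnames(expr)))
  for (m in labs) {
    x <- expr[names(modules)[modules == m], , drop = FALSE]
    xs <- t(scale(t(x)))
    sv <- svd(xs, nu = 0, nv = 1)
    e <- sv$v[, 1]
    if (stats::cor(e, colMeans(xs)) < 0) e <- -e
    me[m, ] <- e
  }
  me
}

#' Merge modules with highly correlated eigengenes
#'
#' Eigengene dissimilarity is `1 - cor`; while any module pair (grey excluded)
#' is closer than `merge_cut_height`, the closest pair is merged and
#' eigengenes are recomputed. Labels are re-assigned by size afterwards.
#'
#' @param expr numeric genes x samples matrix.
#' @param modules named character vector gene -> module label.
#' @param merge_cut_height merge threshold on `1 - cor` (default 0.25,
#'   i.e. eigengene correlation above 0.75 merges).
#' @return new named character vector gene -> module colour.
#' @export
merge_close_modules <- function(expr, modules, merge_cut_height = 0.25) {
  stop_if(merge_cut_height <= 0 || merge_cut_height >= 1,
          "'merge_cut_height' must be in (0, 1)")
  mods <- modules
  repeat {
    labs <- setdiff(sort(unique(mods)), "grey")
    if (length(labs) < 2) break
    me <- module_eigengenes(expr, mods[mods != "grey"])
    d <- 1 - stats::cor(t(me[labs, , drop = FALSE]))
    diag(d) <- Inf
    ij <- which(d == min(d), arr.ind = TRUE)[1, ]
    if (d[ij[1], ij[2]] >= merge_cut_height) break
    a <- labs[ij[1]]; b <- labs[ij[2]]
    keep <- if (sum(mods == a) >= sum(mods == b)) a else b
    mods[mods %in% c(a, b)] <- keep
  }
  relabel_by_size(mods)
}

#' Intramodular and whole-network connectivity
#'
#' `kWithin` of a gene is the sum of its adjacency weights to the other genes
#' of its own module; `kTotal` sums over all genes. A singleton module has
#' `kWithin = 0`.
#'
#' @param adjacency symmetric adjacency with zero diagonal.
#' @param modules named character vector gene -> module label covering the
#'   adjacency rownames.
#' @return data.frame with columns `gene`, `module`, `k_within`, `k_total`.
#' @export
intramodular_connectivity <- function(adjacency, modules) {
  genes <- rownames(adjacency)
  stop_if(!setequal(genes, names(modules)),
          "partition inconsistent with adjacency index")
  modules <- modules[genes]
  k_total <- colSums(adjacency)
  k_within <- numeric(length(genes))
  for (m in unique(modules)) {
    idx <- which(modules == m)
    k_within[idx] <- colSums(adjacency[idx, idx, drop = FALSE])
  }
  data.frame(gene = genes, module = unname(modules),
             k_within = unname(k_within), k_total = unname(k_total),
             stringsAsFactors = FALSE)
}

#' Fit an unsigned weighted co-expression network
#'
#' One-call wrapper over the network stages: variance filtering, adjacency at
#' the chosen soft threshold, topological overlap, module detection, merging
#' of correlated modules, eigengenes and intramodular connectivity.
#'
#' @param expr numeric genes x samples matrix (log-scale normalised values).
#' @param beta soft-threshold exponent (default 10).
#' @param n_top_genes genes kept by the variance filter (default 5000; capped
#'   at the number of genes supplied).
#' @param min_module_size smallest admissible module (default 50).
#' @param merge_cut_height eigengene-dissimilarity merge threshold (0.25).
#' @param deep_split tree-cut granularity, 0-4 (default 2).
#' @param cut_method `"adaptive"` or `"fixed"`; see [detect_modules()].
#' @param cut_height fixed cut height when `cut_method = "fixed"`.
#' @param kme_min module-membership quality cut: after merging, genes whose
#'   absolute correlation with their own module eigengene (kME) falls below
#'   this value are returned to grey (0 disables; default 0.7). Standard practice to strip
#'   genes attached to a module by chance correlation.
#' @param keep_adjacency store the adjacency matrix in the fit (memory-heavy
#'   for large gene sets; default `FALSE`).
#' @return object of class `coexp_fit`: list with `modules` (gene -> colour),
#'   `eigengenes`, `connectivity`, `dendro`, `params`, `expr` (the filtered
#'   matrix) and optionally `adjacency`.
#' @seealso [module_trait_correlation()], [select_hubs()]
#' @export
coexpress <- function(expr, beta = 10, n_top_genes = 5000L,
                      min_module_size = 50L, merge_cut_height = 0.25,
                      deep_split = 2L, cut_method = "adaptive",
                      cut_height = NULL, kme_min = 0.6,
                      keep_adjacency = FALSE) {
  check_expr(expr)
  expr <- variance_filter(expr, min(n_top_genes, nrow(expr)))
  a <- adjacency_matrix(expr, beta)
  d <- tom_dissimilarity(a)
  mods <- detect_modules(d, min_module_size = min_module_size,
                         method = cut_method, cut_height = cut_height,
                         deep_split = deep_split)
  dendro <- attr(mods, "dendro")
  mods2 <- merge_close_modules(expr,
                               stats::setNames(as.character(mods), names(mods)),
                               merge_cut_height)
  if (kme_min > 0) {
    me0 <- module_eigengenes(expr, mods2)
    for (m in setdiff(unique(mods2), "grey")) {
      genes <- names(mods2)[mods2 == m]
      kme <- abs(stats::cor(t(expr[genes, , drop = FALSE]), me0[m, ]))
      mods2[genes[kme < kme_min]] <- "grey"
    }
    # a module can fall below the size floor after the QC step
    sz <- table(mods2[mods2 != "grey"])
    mods2[mods2 %in% names(sz)[sz < min_module_size]] <- "grey"
    mods2 <- relabel_by_size(mods2)
  }
  me <- module_eigengenes(expr, mods2)
  conn <- intramodular_connectivity(a, mods2)
  fit <- list(modules = mods2, eigengenes = me, connectivity = conn,
              dendro = dendro, expr = expr,
              params = list(beta = beta, n_top_genes = n_top_genes,
                            min_module_size = min_module_size,
                            merge_cut_height = merge_cut_height,
                            deep_split = deep_split, cut_method = cut_method),
              adjacency = if (keep_adjacency) a else NULL)
  class(fit) <- "coexp_fit"
  fit
}

#' @export
print.coexp_fit <- function(x, ...) {
  sz <- module_sizes(x$modules)
  cat("Weighted co-expression network fit\n")
  cat("  genes:", length(x$modules), " samples:", ncol(x$expr),
      " beta:", x$params$beta, "\n")
  cat("  modules (grey excluded):", length(sz), "\n")
  print(sz)
  cat("  unassigned (grey):", sum(x$modules == "grey"), "\n")
  invisible(x)
}

#' @export
summary.coexp_fit <- function(object, ...) {
  list(n_modules = length(module_sizes(object$modules)),
       sizes = module_sizes(object$modules),
       n_grey = sum(object$modules == "grey"),
       params = object$params)
}

#' @export
plot.coexp_fit <- function(x, ...) {
  graphics::plot(x$dendro, labels = FALSE, hang = -1,
                 main = "Gene dendrogram (TOM dissimilarity)",
                 xlab = "", sub = "", ...)
  cols <- x$modules[x$dendro$labels[x$dendro$order]]
  n <- length(cols)
  graphics::points(seq_len(n), rep(graphics::par("usr")[3], n),
                   col = cols, pch = 15, cex = 0.5, xpd = NA)
  invisible(x)
}

#' Module sizes of a partition
#'
#' Sizes of non-grey modules, in decreasing order.
#'
#' @param modules named character vector gene -> module label.
#' @return named integer vector.
#' @export
module_sizes <- function(modules) {
  tab <- table(modules[modules != "grey"])
  sort(tab, decreasing = TRUE)
}
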