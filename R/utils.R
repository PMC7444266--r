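# Internal helpers shared across modules.

#' Canonical module colour sequence
#'
#' Ordered colour vocabulary used to label co-expression modules by descending
#' size; "grey" is reserved for unassigned genes and never appears here.
#'
#' @return Character vector of colour names.
#' @export
module_colors <- function() {
  c("turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
    "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
    "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
    "royalblue", "darkred", "darkgreen", "darkturquoise", "darkgrey",
    "orange", "darkorange", "white", "skyblue", "saddlebrown", "steelblue",
    "paleturquoise", "violet", "darkolivegreen", "darkmagenta", "sienna3",
    "yellowgreen", "skyblue3", "plum1", "orangered4", "mediumpurple3",
    "lightsteelblue1", "lightcyan1", "ivory", "floralwhite", "darkorange2",
    "brown4", "bisque4", "darkslateblue", "plum2", "thistle2")
}

#' Cell lines of the progression panel
#'
#' The four states of the stepwise melanoma-progression panel, in progression
#' order: non-malignant melanocytes (melan-a), pre-malignant mesenchymal-like
#' melanocytes (4C), non-metastatic melanoma (4C11-) and metastasis-prone
#' melanoma (4C11+).
#'
#' @return Character vector of length 4.
#' @export
cell_lines <- function() c("melan-a", "4C", "4C11-", "4C11+")

stop_if <- function(cond, ...) if (isTRUE(cond)) stop(..., call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Relabel an integer/character partition by descending cluster size using the
# canonical colour order; `grey_label` entries are preserved.
relabel_by_size <- function(labels, grey_label = "grey") {
  stopifnot(!is.null(names(labels)))
  non_grey <- labels != grey_label
  out <- labels
  if (any(non_grey)) {
    tab <- table(labels[non_grey])
    # ties in size broken by first gene index so labelling is deterministic
    first_idx <- vapply(names(tab), function(l) min(which(labels == l)), 1L)
    ord <- order(-as.integer(tab), first_idx)
    cols <- module_colors()
    new <- setNames(cols[seq_along(ord)], names(tab)[ord])
    out[non_grey] <- new[labels[non_grey]]
  }
  out
}

#' Match predicted clusters to reference clusters
#'
#' Exact one-to-one assignment of predicted cluster labels to reference labels
#' maximising the number of agreeing items (solved by exhaustive search over
#' permutations for up to 8 clusters, greedy otherwise). Used to evaluate
#' recovery of planted structure where cluster identities are arbitrary.
#'
#' @param pred,truth vectors of equal length; `NA`s in `truth` are ignored.
#' @return list with `mapping` (named character: predicted -> reference),
#'   `accuracy` (agreement fraction over non-`NA` items) and `n`.
#' @export
match_clusters <- function(pred, truth) {
  keep <- !is.na(truth) & !is.na(pred)
  pred <- as.character(pred[keep]); truth <- as.character(truth[keep])
  pl <- sort(unique(pred)); tl <- sort(unique(truth))
  ct <- table(factor(pred, pl), factor(truth, tl))
  k <- max(length(pl), length(tl))
  # pad to square with zero rows/cols
  m <- matrix(0L, k, k, dimnames = list(c(pl, rep("", k - length(pl))),
                                        c(tl, rep("", k - length(tl)))))
  m[seq_along(pl), seq_along(tl)] <- ct
  if (k <= 8L) {
    perms <- permutations_of(k)
    scores <- vapply(perms, function(p) sum(m[cbind(seq_len(k), p)]), 0)
    best <- perms[[which.max(scores)]]
  } else {
    best <- integer(k); used <- logical(k)
    for (i in order(-apply(m, 1, max))) {
      j <- order(-m[i, ])[!used[order(-m[i, ])]][1]
      best[i] <- j; used[j] <- TRUE
    }
  }
  map <- setNames(colnames(m)[best], rownames(m))
  map <- map[names(map) != "" & map != ""]
  acc <- sum(m[cbind(seq_len(k), best)]) / length(truth)
  list(mapping = map, accuracy = acc, n = length(truth))
}

permutations_of <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- permutations_of(n - 1L)
  out <- vector("list", n * length(sub)); k <- 0L
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    for (p in sub) { k <- k + 1L; out[[k]] <- c(i, rest[p]) }
  }
  out
}

# Deterministic seed derivation: keeps derived seeds strictly below 2^31.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483647)
}

fmt_num <- function(x) formatC(x, digits = 15, format = "g")
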