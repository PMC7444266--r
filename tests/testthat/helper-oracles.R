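# Independent oracles used to check the implementation by a second route:
# brute-force loops and exhaustive enumeration, kept deliberately naive.

# Topological overlap by explicit triple loop.
brute_tom_dissimilarity <- function(a) {
  n <- nrow(a)
  k <- colSums(a)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l <- 0
    for (u in seq_len(n)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
    d[i, j] <- 1 - (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  dimnames(d) <- dimnames(a)
  d
}

# Upper-tail hypergeometric probability by exhaustive enumeration of all
# C(N, n) draws (N <= 12).
enum_hyper_p <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  hits <- apply(draws, 2, function(d) sum(d <= K))   # items 1..K are the set
  mean(hits >= k)
}

# Two-group log-rank chi-square from first principles (observed minus
# expected events at each distinct event time, hypergeometric variance).
oracle_logrank_stat <- function(time, event, group) {
  group <- as.integer(factor(group))
  o_minus_e <- 0; v <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n_t <- sum(at_risk)
    n1 <- sum(at_risk & group == 1)
    d_t <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == 1)
    o_minus_e <- o_minus_e + d1 - d_t * n1 / n_t
    if (n_t > 1)
      v <- v + d_t * (n1 / n_t) * (1 - n1 / n_t) * (n_t - d_t) / (n_t - 1)
  }
  unname(o_minus_e^2 / v)
}

# Exact permutation p for the log-rank statistic over all relabellings that
# preserve group sizes, using the oracle statistic.
oracle_logrank_perm_p <- function(time, event, group) {
  group <- factor(group)
  n <- length(group)
  n1 <- sum(group == levels(group)[1])
  obs <- oracle_logrank_stat(time, event, group)
  idx <- utils::combn(n, n1)
  stats <- apply(idx, 2, function(ii) {
    g <- ifelse(seq_len(n) %in% ii, "a", "b")
    oracle_logrank_stat(time, event, g)
  })
  mean(stats >= obs - 1e-12)
}

# Naive agglomerative clustering: returns the merge heights in order, for
# complete or average linkage on a distance matrix.
brute_linkage_heights <- function(d, method = "complete") {
  d <- as.matrix(d)
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  link <- function(c1, c2) {
    vals <- d[c1, c2, drop = FALSE]
    if (method == "complete") max(vals) else mean(vals)
  }
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) for (j in seq_len(i - 1)) {
      h <- link(clusters[[i]], clusters[[j]])
      if (h < best[1]) best <- c(h, i, j)
    }
    heights <- c(heights, best[1])
    clusters[[best[3]]] <- c(clusters[[best[3]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

# Small expression fixture: two planted blocks with orthogonal profiles.
two_block_expr <- function(n1 = 100, n2 = 100, noise = 0, seed = 1) {
  set.seed(seed)
  p1 <- rep(c(1, 1, -1, -1), 3)
  p2 <- rep(c(1, -1, 1, -1), 3)
  expr <- rbind(outer(stats::runif(n1, 0.5, 1.5), p1),
                outer(stats::runif(n2, 0.5, 1.5), p2))
  if (noise > 0) expr <- expr + matrix(stats::rnorm(length(expr), 0, noise),
                                       nrow(expr))
  rownames(expr) <- sprintf("g%04d", seq_len(n1 + n2))
  colnames(expr) <- paste0("s", 1:12)
  expr
}

# Canonical tiny PTM table: one H3 9-17 backbone with three forms whose
# areas imply relative abundances 0.6 / 0.3 / 0.1 in every sample.
tiny_ptm_df <- function(samples = paste0("s", 1:4)) {
  df <- data.frame(histone = "H3.1", start = 9L, end = 17L,
                   modifications = c("unmod", "K9me2", "K9ac"),
                   stringsAsFactors = FALSE)
  for (s in samples) df[[s]] <- c(60, 30, 10) * 1e4
  df
}

# Simulated cohort under proportional hazards for a single binary group.
null_cohort <- function(n, seed) {
  set.seed(seed)
  data.frame(patient = seq_len(n),
             time = stats::rexp(n, 0.05),
             event = stats::rbinom(n, 1, 0.8),
             g = stats::rnorm(n))
}

small_sim_config <- function(seed = 1, ...) {
  sim_config(seed = seed,
             module_specs = data.frame(
               size = c(60L, 50L),
               trait_pattern = c("metastasis", "emt"),
               sign = 1,
               loading_mean = 1, noise_sd = 0.4),
             n_background = 80L,
             cohort_size = 120L, n_cohort_genes = 12L, n_prognostic = 3L,
             n_peptides = 12L, n_forms = 48L, ...)
}
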