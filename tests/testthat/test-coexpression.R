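test_that("variance filter keeps the most variable genes with stable ties", {
  expr <- rbind(a = c(1, 2, 3, 4) * 2,         # var 20/3 * ...
                b = c(1, 1, 1, 2),
                c = c(1, 2, 3, 4) * 3)
  colnames(expr) <- paste0("s", 1:4)
  expect_identical(rownames(variance_filter(expr, 2)), c("c", "a"))
  expect_identical(variance_filter(expr, 3), expr[c("c", "a", "b"), ])
  # tie in variance: lexicographically smaller id first
  tie <- rbind(zz = c(0, 1, 0, 1), aa = c(1, 0, 1, 0), mm = c(5, 5, 5, 6))
  colnames(tie) <- paste0("s", 1:4)
  expect_identical(rownames(variance_filter(tie, 2)), c("aa", "zz"))
  expect_error(variance_filter(expr, 0), "positive")
  expect_error(variance_filter(expr, 9), "exceeds")
})

test_that("adjacency equals elementwise |cor|^beta with zero diagonal", {
  # perfectly correlated pair has weight 1 for any beta
  x <- rbind(g1 = 1:6, g2 = 2 * (1:6) + 3, g3 = c(2, 1, 4, 3, 6, 5))
  colnames(x) <- paste0("s", 1:6)
  a <- adjacency_matrix(x, beta = 7)
  expect_equal(a["g1", "g2"], 1)
  expect_equal(diag(a), setNames(rep(0, 3), rownames(x)))
  # direct power: cor 0.9 at beta 10
  expect_equal(0.9^10, 0.3486784401)
  # brute-force oracle on a random 5-gene matrix
  set.seed(11)
  y <- matrix(rnorm(5 * 8), 5, dimnames = list(paste0("g", 1:5), paste0("s", 1:8)))
  a2 <- adjacency_matrix(y, beta = 10)
  for (i in 1:5) for (j in 1:5)
    expect_equal(a2[i, j],
                 if (i == j) 0 else abs(cor(y[i, ], y[j, ]))^10,
                 tolerance = 1e-12)
  # zero-variance gene rejected by name
  z <- rbind(ok = rnorm(6), flat = rep(1, 6)); colnames(z) <- paste0("s", 1:6)
  expect_error(adjacency_matrix(z, 10), "flat")
})

test_that("soft-threshold scan: connectivity decreases in beta, fit is signed", {
  expr <- simulate_expression(sim_config(seed = 1))$expr
  scan <- pick_soft_threshold(expr, candidate_betas = c(1:10, 12, 14))
  expect_true(all(diff(scan$mean_connectivity) < 0))
  # a strongly positive slope at beta 1 is reported with a negative sign
  expect_lt(scan$r_squared[scan$beta == 1], 0)
  # the planted-module network attains a strong scale-free fit somewhere
  expect_true(any(scan$r_squared >= 0.8, na.rm = TRUE))
  # the recommendation is the smallest qualifying beta
  rec <- attr(scan, "recommended")
  qual <- scan$beta[!is.na(scan$r_squared) & scan$r_squared >= 0.8]
  expect_equal(rec, min(qual))
  expect_output(print(scan), "recommended")
})

test_that("TOM dissimilarity matches hand values and the brute-force oracle", {
  # 3-node clique: dissimilarity 0
  a1 <- matrix(1, 3, 3) - diag(3)
  dimnames(a1) <- list(paste0("g", 1:3), paste0("g", 1:3))
  expect_equal(max(abs(tom_dissimilarity(a1))), 0)
  # all weights 0.5: TOM_12 = (0.25 + 0.5) / (1 + 1 - 0.5) = 0.5
  a2 <- matrix(0.5, 3, 3) - diag(0.5, 3)
  d2 <- tom_dissimilarity(a2)
  expect_equal(d2[1, 2], 1 - 0.5, tolerance = 1e-12)
  # 20-node random adjacency vs triple loop
  set.seed(4)
  m <- matrix(runif(400), 20); m <- (m + t(m)) / 2; diag(m) <- 0
  expect_lt(max(abs(tom_dissimilarity(m) - brute_tom_dissimilarity(m))), 1e-10)
  expect_error(tom_dissimilarity(matrix(runif(9), 3)), "symmetric")
})

test_that("module detection separates planted blocks and labels by size", {
  expr <- two_block_expr(100, 100)
  d <- tom_dissimilarity(adjacency_matrix(expr, 10))
  mods <- detect_modules(d, min_module_size = 50)
  expect_equal(sum(mods == "grey"), 0)
  expect_setequal(unique(mods), c("turquoise", "blue"))
  # both blocks intact
  expect_equal(length(unique(mods[1:100])), 1)
  expect_equal(length(unique(mods[101:200])), 1)
  expect_error(detect_modules(d, min_module_size = 500), "exceeds")
})

test_that("colour labels follow the canonical order by descending size", {
  sizes <- c(944, 721, 519, 509, 40)
  labels <- rep(paste0("c", seq_along(sizes)), times = sizes)
  names(labels) <- sprintf("g%05d", seq_along(labels))
  labels[labels == "c5"] <- "grey"
  out <- melprog:::relabel_by_size(labels)
  got <- table(out)
  expect_equal(as.integer(got[c("turquoise", "blue", "brown", "yellow")]),
               c(944L, 721L, 519L, 509L))
  expect_equal(as.integer(got["grey"]), 40L)
})

test_that("eigengenes are first principal components with fixed orientation", {
  # identical standardised profiles: eigengene equals the profile (unit norm)
  prof <- as.numeric(scale(c(1, 3, 2, 5, 4, 6)))
  expr <- outer(c(1, 2, 0.5, 3), prof)
  dimnames(expr) <- list(paste0("g", 1:4), paste0("s", 1:6))
  me <- module_eigengenes(expr, setNames(rep("m1", 4), rownames(expr)))
  expect_equal(unname(me["m1", ]), prof / sqrt(sum(prof^2)), tolerance = 1e-10)
  # positive orientation towards the module mean profile
  expect_gt(cor(me["m1", ], colMeans(expr)), 0)
  # optimality: variance explained beats 100 random unit combinations
  set.seed(21)
  x <- matrix(rnorm(10 * 8), 10, dimnames = list(paste0("g", 1:10),
                                                 paste0("s", 1:8)))
  xs <- t(scale(t(x)))
  me2 <- module_eigengenes(x, setNames(rep("m", 10), rownames(x)))
  v_eig <- sum((xs %*% me2["m", ])^2)
  for (r in 1:100) {
    w <- rnorm(8); w <- w / sqrt(sum(w^2))
    expect_lte(sum((xs %*% w)^2), v_eig + 1e-8)
  }
  # singleton module: eigengene is its standardised profile
  one <- matrix(c(3, 1, 4, 1, 5, 9), 1, dimnames = list("solo", paste0("s", 1:6)))
  me3 <- module_eigengenes(one, c(solo = "m"))
  zs <- as.numeric(scale(one[1, ]))
  expect_equal(unname(me3["m", ]), zs / sqrt(sum(zs^2)), tolerance = 1e-10)
})

test_that("module merging is iterative and respects the cut height", {
  set.seed(31)
  prof1 <- rnorm(12)
  expr <- rbind(outer(runif(30, 0.8, 1.2), prof1),
                outer(runif(30, 0.8, 1.2), prof1),      # identical eigengene
                outer(runif(30, 0.8, 1.2), rnorm(12)))  # independent
  rownames(expr) <- sprintf("g%03d", 1:90)
  colnames(expr) <- paste0("s", 1:12)
  mods <- setNames(rep(c("a", "b", "c"), each = 30), rownames(expr))
  merged <- merge_close_modules(expr, mods, 0.25)
  expect_equal(length(unique(merged[1:60])), 1)     # a and b fused
  expect_equal(length(unique(merged)), 2)
  # all eigengene correlations below 1 - cut: partition unchanged in structure
  expr2 <- rbind(outer(runif(30, 0.8, 1.2), c(rep(1, 6), rep(-1, 6))),
                 outer(runif(30, 0.8, 1.2), rep(c(1, -1), 6)))
  rownames(expr2) <- sprintf("h%03d", 1:60); colnames(expr2) <- paste0("s", 1:12)
  mods2 <- setNames(rep(c("a", "b"), each = 30), rownames(expr2))
  merged2 <- merge_close_modules(expr2, mods2, 0.25)
  expect_equal(length(unique(merged2)), 2)
  # chained correlations ~0.85: only after the first merge does the combined
  # eigengene come close enough to the third module -- the iteration must reach
  # the single-module fixed point
  u <- as.numeric(scale(rep(c(1, -1), 6)))
  v <- as.numeric(scale(rep(c(1, 1, -1, -1), 3)))
  w <- as.numeric(scale(rep(c(1, -1, -1, 1), 3)))
  r <- 0.85; q <- sqrt(1 - r^2)
  p1 <- u; p2 <- r * u + q * v; p3 <- r * p2 + q * w
  mk <- function(p, pre) {
    m <- outer(runif(25, 0.9, 1.1), p)
    rownames(m) <- paste0(pre, 1:25); m
  }
  expr3 <- rbind(mk(p1, "a"), mk(p2, "b"), mk(p3, "c"))
  colnames(expr3) <- paste0("s", 1:12)
  mods3 <- setNames(rep(c("a", "b", "c"), each = 25), rownames(expr3))
  me <- module_eigengenes(expr3, mods3)
  cc <- cor(t(me))
  expect_lt(cc["a", "c"], 0.75)          # not directly mergeable
  merged3 <- merge_close_modules(expr3, mods3, 0.25)
  expect_equal(length(unique(merged3)), 1)
})

test_that("intramodular connectivity matches hand and brute-force values", {
  a <- matrix(0, 3, 3, dimnames = list(c("g1", "g2", "g3"), c("g1", "g2", "g3")))
  a["g1", "g2"] <- a["g2", "g1"] <- 0.3
  a["g1", "g3"] <- a["g3", "g1"] <- 0.2
  a["g2", "g3"] <- a["g3", "g2"] <- 0.4
  conn <- intramodular_connectivity(a, c(g1 = "m", g2 = "m", g3 = "m"))
  expect_equal(conn$k_within, c(0.5, 0.7, 0.6))
  expect_equal(conn$k_within, conn$k_total)
  # singleton module has kWithin 0
  conn2 <- intramodular_connectivity(a, c(g1 = "m", g2 = "m", g3 = "solo"))
  expect_equal(conn2$k_within[conn2$gene == "g3"], 0)
  expect_equal(conn2$k_total[conn2$gene == "g3"], 0.6)
  # brute-force double loop on a random instance
  set.seed(5)
  m <- matrix(runif(144), 12); m <- (m + t(m)) / 2; diag(m) <- 0
  dimnames(m) <- list(paste0("g", 1:12), paste0("g", 1:12))
  part <- setNames(rep(c("x", "y", "grey"), each = 4), rownames(m))
  conn3 <- intramodular_connectivity(m, part)
  for (i in 1:12) {
    kw <- 0
    for (j in 1:12) if (j != i && part[j] == part[i]) kw <- kw + m[i, j]
    expect_equal(conn3$k_within[i], kw, tolerance = 1e-12)
  }
})

test_that("coexpress returns a printable fit with consistent components", {
  expr <- two_block_expr(60, 60, noise = 0.5, seed = 13)
  fit <- coexpress(expr, n_top_genes = nrow(expr), min_module_size = 40)
  expect_s3_class(fit, "coexp_fit")
  expect_setequal(names(fit$modules), rownames(expr))
  expect_equal(sort(rownames(fit$eigengenes)), sort(unique(fit$modules)))
  expect_equal(nrow(fit$connectivity), nrow(expr))
  expect_output(print(fit), "modules")
  s <- summary(fit)
  expect_equal(s$n_modules, length(module_sizes(fit$modules)))
})
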