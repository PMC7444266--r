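test_that("fuzzy c-means separates blobs and honours symmetry", {
  set.seed(18)
  x <- rbind(matrix(rnorm(40 * 4, 0, 0.2), 40),
             matrix(rnorm(40 * 4, 5, 0.2), 40))
  rownames(x) <- paste0("p", 1:80)
  fit <- fuzzy_cmeans(x, c = 2, m = 2, seed = 1, standardize = FALSE)
  lab1 <- fit$cluster[1:40]; lab2 <- fit$cluster[41:80]
  expect_equal(length(unique(lab1)), 1)
  expect_equal(length(unique(lab2)), 1)
  expect_false(unique(lab1) == unique(lab2))
  expect_true(all(apply(fit$membership, 1, max) > 0.95))
  # memberships are row-stochastic
  expect_equal(unname(rowSums(fit$membership)), rep(1, 80), tolerance = 1e-12)
  # a point equidistant from two symmetric clusters splits 0.5 / 0.5
  y <- rbind(matrix(c(-1, 0), 20, 2, byrow = TRUE) + rnorm(40, 0, 1e-3),
             matrix(c(1, 0), 20, 2, byrow = TRUE) + rnorm(40, 0, 1e-3),
             c(0, 0))
  fit2 <- fuzzy_cmeans(y, c = 2, m = 2, seed = 2, standardize = FALSE)
  expect_equal(unname(fit2$membership[41, ]), c(0.5, 0.5), tolerance = 0.01)
})

test_that("the objective is non-increasing over iterations", {
  set.seed(19)
  x <- matrix(rnorm(60 * 5), 60)
  objs <- sapply(1:8, function(it) {
    set.seed(melprog:::derive_seed(1L, 2000L + 1L))  # same init every time
    melprog:::fcm_once(x, c = 3, m = 1.5, tol = 0, max_iter = it)$objective
  })
  expect_true(all(diff(objs) <= 1e-8))
})

test_that("small fuzzifier approaches hard k-means on separable data", {
  set.seed(20)
  x <- rbind(matrix(rnorm(30 * 3, 0, 0.3), 30), matrix(rnorm(30 * 3, 6, 0.3), 30))
  fit <- fuzzy_cmeans(x, c = 2, m = 1.05, seed = 3, standardize = FALSE)
  expect_true(all(apply(fit$membership, 1, max) > 0.999))
})

test_that("fcm agrees with an independent fuzzy clustering implementation", {
  skip_if_not_installed("e1071")
  set.seed(22)
  x <- rbind(matrix(rnorm(35 * 6, 0, 0.4), 35),
             matrix(rnorm(35 * 6, 3, 0.4), 35),
             matrix(rnorm(35 * 6, -3, 0.4), 35))
  rownames(x) <- paste0("p", 1:105)
  fit <- fuzzy_cmeans(x, c = 3, m = 1.8, seed = 4, standardize = FALSE)
  ref <- e1071::cmeans(x, centers = 3, m = 1.8, iter.max = 300)
  mm <- match_clusters(fit$cluster, ref$cluster)
  expect_gte(mm$accuracy, 0.99)
  # centroids coincide after label alignment
  for (k in seq_len(3)) {
    tgt <- as.integer(mm$mapping[as.character(k)])
    expect_lt(sqrt(sum((fit$centers[k, ] - ref$centers[tgt, ])^2)), 0.15)
  }
})

test_that("fcm is seed-reproducible and stable across seeds", {
  sim <- simulate_ptm_table(sim_config(seed = 5))
  ab <- relative_abundance(parse_ptm_table(sim$ptm))
  keep <- !is.na(sim$truth$forms$archetype)
  x <- ab$ratios[keep, ]
  f1 <- fuzzy_cmeans(x, c = 8, seed = 10)
  f2 <- fuzzy_cmeans(x, c = 8, seed = 10)
  expect_identical(f1$membership, f2$membership)
  f3 <- fuzzy_cmeans(x, c = 8, seed = 99)
  skip_if_not_installed("mclust")
  expect_gte(mclust::adjustedRandIndex(f1$cluster, f3$cluster), 0.95)
})

test_that("auto estimation picks the fuzzifier heuristic and a supported c", {
  expect_gt(estimate_fuzzifier(245, 12), 1)
  expect_lt(estimate_fuzzifier(245, 12), 2)
  # more items or dimensions push the fuzzifier towards 1
  expect_gt(estimate_fuzzifier(50, 12), estimate_fuzzifier(5000, 12))
  expect_gt(estimate_fuzzifier(245, 6), estimate_fuzzifier(245, 24))
})

test_that("hierarchical clustering: linkage heights match brute force; samples
           split by epithelial/mesenchymal structure", {
  set.seed(23)
  m <- matrix(rnorm(5 * 10), 5, dimnames = list(paste0("i", 1:5), NULL))
  hc <- hierarchical_cluster(m, "rows", linkage = "complete")
  d <- 1 - cor(t(m))
  expect_equal(sort(hc$height),
               sort(brute_linkage_heights(d, "complete")), tolerance = 1e-10)
  hc_a <- hierarchical_cluster(m, "rows", linkage = "average")
  expect_equal(sort(hc_a$height),
               sort(brute_linkage_heights(d, "average")), tolerance = 1e-10)
  # duplicated item merges at height 0
  m2 <- rbind(m, i6 = m["i1", ])
  hc2 <- hierarchical_cluster(m2, "rows")
  expect_equal(min(hc2$height), 0, tolerance = 1e-12)
  # constant row rejected by name
  m3 <- rbind(m, flat = rep(2, 10))
  expect_error(hierarchical_cluster(m3, "rows"), "flat")
  # EMT-structured abundances place melan-a with 4C11+ and 4C with 4C11-
  sim <- simulate_ptm_table(sim_config(seed = 6,
                                       archetype_mix = c(0, 0, 0, 1, 1, 0, 0, 0)))
  ab <- relative_abundance(parse_ptm_table(sim$ptm))
  keep <- !is.na(sim$truth$forms$archetype)
  hc3 <- hierarchical_cluster(ab$ratios[keep, ], "cols")
  top2 <- cutree(hc3, k = 2)
  lines <- sim$meta$cell_line[match(names(top2), sim$meta$sample)]
  expect_equal(length(unique(top2[lines %in% c("melan-a", "4C11+")])), 1)
  expect_equal(length(unique(top2[lines %in% c("4C", "4C11-")])), 1)
  expect_false(top2[lines == "melan-a"][1] == top2[lines == "4C"][1])
})

test_that("cluster matching solves the assignment exactly for small k", {
  pred <- c(1, 1, 2, 2, 3, 3)
  truth <- c("b", "b", "c", "c", "a", "a")
  mm <- match_clusters(pred, truth)
  expect_equal(mm$accuracy, 1)
  expect_equal(unname(mm$mapping[c("1", "2", "3")]), c("b", "c", "a"))
  # NAs in the reference are ignored
  mm2 <- match_clusters(c(pred, 1), c(truth, NA))
  expect_equal(mm2$accuracy, 1)
})
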