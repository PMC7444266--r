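test_that("modification grammar parses and round-trips; invalid marks fail", {
  df <- tiny_ptm_df()
  df$modifications[2] <- "K9me2K14ac"
  tab <- parse_ptm_table(df)
  mods <- attr(tab, "mods")[["H3.1:9-17:K9me2K14ac"]]
  expect_equal(mods$position, c(9L, 14L))
  expect_equal(mods$mark, c("me2", "ac"))
  expect_equal(serialize_mods(mods), "K9me2K14ac")
  # unmod parses to the empty modification set and serialises back
  expect_equal(nrow(attr(tab, "mods")[["H3.1:9-17:unmod"]]), 0)
  expect_equal(serialize_mods(attr(tab, "mods")[["H3.1:9-17:unmod"]]), "unmod")
  # invalid mark, out-of-range position, duplicates: errors with row numbers
  bad <- tiny_ptm_df(); bad$modifications[2] <- "K9me4"
  expect_error(parse_ptm_table(bad), "row 2")
  bad2 <- tiny_ptm_df(); bad2$modifications[2] <- "K25ac"
  expect_error(parse_ptm_table(bad2), "outside backbone")
  bad3 <- tiny_ptm_df(); bad3$modifications[3] <- "K9me2"
  expect_error(parse_ptm_table(bad3), "duplicate")
})

test_that("parse -> serialise -> parse is the identity on a simulated table", {
  sim <- simulate_ptm_table(small_sim_config(seed = 3))
  tab <- parse_ptm_table(sim$ptm)
  mods <- attr(tab, "mods")
  for (f in names(mods)) {
    s <- serialize_mods(mods[[f]])
    expect_equal(s, tab$modifications[tab$form == f])
  }
})

test_that("relative abundances normalise per backbone and are scale invariant", {
  tab <- parse_ptm_table(tiny_ptm_df())
  ab <- relative_abundance(tab)
  expect_equal(unname(ab$ratios[, "s1"]), c(0.6, 0.3, 0.1))
  expect_equal(colSums(ab$ratios), setNames(rep(1, 4), paste0("s", 1:4)))
  # single-form backbone: ratio 1 everywhere
  solo <- data.frame(histone = "H4", start = 4L, end = 17L,
                     modifications = "K5ac", s1 = 3, s2 = 99)
  expect_true(all(relative_abundance(parse_ptm_table(solo))$ratios == 1))
  # rescaling one sample's areas leaves the ratios unchanged
  df7 <- tiny_ptm_df(); df7$s2 <- df7$s2 * 7
  ab7 <- relative_abundance(parse_ptm_table(df7))
  expect_equal(ab7$ratios, ab$ratios)
})

test_that("global mark levels sum union-wise over forms carrying the class", {
  df <- tiny_ptm_df()
  df$modifications <- c("unmod", "K9me2K14ac", "K9me2")
  df[paste0("s", 1:4)] <- NULL
  df$s1 <- c(50, 30, 20)   # ratios 0.5, 0.3, 0.2
  gl <- global_mark_levels(relative_abundance(parse_ptm_table(df)))
  expect_equal(gl["acetylation", "s1"], 0.3)
  expect_equal(gl["me2", "s1"], 0.5)
  expect_equal(gl["methylation", "s1"], 0.5)
  expect_equal(gl["me1", "s1"], 0)
  # all-unmodified table: every level 0
  df0 <- data.frame(histone = "H3.1", start = 9L, end = 17L,
                    modifications = "unmod", s1 = 10)
  expect_true(all(global_mark_levels(
    relative_abundance(parse_ptm_table(df0))) == 0))
})

test_that("replicate correlations behave and separate lines on simulated data", {
  df <- tiny_ptm_df()
  df$s2 <- df$s1                      # duplicated sample column
  df$s3 <- c(10, 30, 60) * 1e4       # reversed profile
  ab <- relative_abundance(parse_ptm_table(df))
  rc <- replicate_correlation(ab)
  expect_equal(rc["s1", "s2"], 1)
  expect_lt(rc["s1", "s3"], 0)
  expect_equal(diag(rc), setNames(rep(1, 4), paste0("s", 1:4)))
  # within-line correlations exceed between-line correlations on the fixture
  sim <- simulate_ptm_table(sim_config(seed = 4))
  ab2 <- relative_abundance(parse_ptm_table(sim$ptm))
  rc2 <- replicate_correlation(ab2)
  same <- outer(sim$meta$cell_line, sim$meta$cell_line, "==")
  diag(same) <- NA
  expect_gt(mean(rc2[which(same)]), mean(rc2[which(!same)]))
})

test_that("single-mark levels sum over carrying forms; z-scores standardise", {
  df <- tiny_ptm_df()
  df$modifications <- c("unmod", "K9me2K14ac", "K9me2")
  df[paste0("s", 1:4)] <- NULL
  df$s1 <- c(50, 30, 20); df$s2 <- c(20, 30, 50); df$s3 <- c(40, 40, 20)
  ab <- relative_abundance(parse_ptm_table(df))
  sm <- single_mark_levels(ab)
  expect_equal(sm["H3.1K9me2", ], c(s1 = 0.5, s2 = 0.8, s3 = 0.6))
  expect_equal(sm["H3.1K14ac", ], c(s1 = 0.3, s2 = 0.3, s3 = 0.4))
  smz <- single_mark_levels(ab, zscore = TRUE)
  expect_equal(unname(rowMeans(smz)), rep(0, nrow(smz)), tolerance = 1e-12)
  expect_equal(unname(apply(smz, 1, sd)), rep(1, nrow(smz)), tolerance = 1e-12)
})

test_that("ANOVA/Tukey finds planted shifts; k = 2 reduces to the t-test", {
  set.seed(17)
  groups <- factor(rep(cell_lines(), each = 3), levels = cell_lines())
  # 3-sd shift in 4C11+ only: last pairwise comparison significant
  y <- rnorm(12, 10, 0.5); y[groups == "4C11+"] <- y[groups == "4C11+"] + 3 * 0.5
  st <- anova_tukey(matrix(y, 1, dimnames = list("f1", NULL)), groups)
  expect_lt(st$p, 0.05)
  expect_true(st$`sig_4C11+_vs_4C11-`)
  expect_gt(st$`d_4C11+_vs_4C11-`, 0)
  # degenerate: zero variance everywhere is flagged, not an error
  st0 <- anova_tukey(matrix(rep(1, 12), 1, dimnames = list("z", NULL)), groups)
  expect_true(is.na(st0$p))
  # two groups only: Tukey-adjusted p equals the pooled-variance t-test
  g2 <- factor(rep(c("x", "y"), each = 4))
  v <- rnorm(8)
  st2 <- anova_tukey(matrix(v, 1, dimnames = list("w", NULL)), g2)
  tt <- t.test(v[g2 == "y"], v[g2 == "x"], var.equal = TRUE)
  expect_equal(st2$p_y_vs_x, tt$p.value, tolerance = 1e-6)
})

test_that("pairwise line ratios use consecutive and anchor comparisons", {
  df <- tiny_ptm_df(samples = paste0("s", 1:12))
  groups <- factor(rep(cell_lines(), each = 3), levels = cell_lines())
  ab <- relative_abundance(parse_ptm_table(df))
  pr <- pairwise_line_ratios(ab, groups)
  # equal line means: every ratio 1, log2 0
  rc <- grep("^ratio_", names(pr), value = TRUE)
  expect_true(all(abs(as.matrix(pr[, rc]) - 1) < 1e-12))
  expect_true(all(abs(as.matrix(pr[, sub("ratio", "log2", rc)])) < 1e-12))
  # doubled mean in 4C11+ doubles the 4C11+/4C11- ratio
  df2 <- df
  plus_cols <- paste0("s", 10:12)
  df2[df2$modifications == "K9ac", plus_cols] <-
    df2[df2$modifications == "K9ac", plus_cols] * 2.25
  ab2 <- relative_abundance(parse_ptm_table(df2))
  pr2 <- pairwise_line_ratios(ab2, groups)
  k9 <- which(ab2$info$modifications == "K9ac")
  m <- tapply(ab2$ratios[k9, ], groups, mean)
  expect_equal(pr2$ratio_4C11pos_over_4C11neg[k9],
               unname(m["4C11+"] / m["4C11-"]), tolerance = 1e-12)
})
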