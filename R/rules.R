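# Rule-based assignment of PTMs and PTM clusters to progression, EMT and
# metastasis phenotypes from significance patterns across the panel.

#' Significance patterns across the panel
#'
#' Derives, per form, the inputs of the phenotype rules: significance and
#' direction of the three consecutive pairwise Tukey comparisons
#' (melan-a vs 4C, 4C vs 4C11-, 4C11- vs 4C11+), the anchor comparison
#' (melan-a vs 4C11+), and an epithelial-group (melan-a + 4C11+) versus
#' mesenchymal-group (4C + 4C11-) Welch t-test.
#'
#' @param values forms x samples numeric matrix of relative abundances.
#' @param groups factor of cell lines per sample (levels among
#'   [cell_lines()]).
#' @param alpha significance level (default 0.05, on Tukey-adjusted p for the
#'   pairwise comparisons).
#' @param stats optional precomputed [anova_tukey()] result for `values`;
#'   computed when omitted.
#' @return `significance_pattern` data.frame, one row per form, with logical
#'   `sig_*` and numeric `dir_*` columns for the five comparisons.
#' @export
significance_pattern <- function(values, groups, alpha = 0.05, stats = NULL) {
  groups <- factor(groups, levels = cell_lines())
  if (is.null(stats)) stats <- anova_tukey(values, groups, alpha = alpha)
  cmp <- list(MA_vs_4C = c("melan-a", "4C"),
              `4C_vs_4C11neg` = c("4C", "4C11-"),
              `4C11neg_vs_4C11pos` = c("4C11-", "4C11+"),
              MA_vs_4C11pos = c("melan-a", "4C11+"))
  out <- data.frame(form = stats$form, stringsAsFactors = FALSE)
  for (nm in names(cmp)) {
    a <- cmp[[nm]][1]; b <- cmp[[nm]][2]
    # anova_tukey names comparisons "<later>_vs_<earlier>" in level order
    key_p <- paste0("p_", b, "_vs_", a)
    key_d <- paste0("d_", b, "_vs_", a)
    out[[paste0("sig_", nm)]] <- !is.na(stats[[key_p]]) & stats[[key_p]] < alpha
    out[[paste0("dir_", nm)]] <- stats[[key_d]]        # mean(b) - mean(a)
  }
  epi <- groups %in% c("melan-a", "4C11+")
  grp_t <- apply(values, 1, function(y) {
    if (stats::sd(y[epi]) == 0 && stats::sd(y[!epi]) == 0)
      return(c(p = NA_real_, d = 0))
    tt <- tryCatch(stats::t.test(y[!epi], y[epi]),
                   error = function(e) NULL)
    if (is.null(tt)) return(c(p = NA_real_, d = mean(y[!epi]) - mean(y[epi])))
    c(p = tt$p.value, d = unname(diff(rev(tt$estimate))))
  })
  out$sig_epi_vs_mes <- !is.na(grp_t["p", ]) & grp_t["p", ] < alpha
  out$dir_epi_vs_mes <- grp_t["d", ]                   # mesenchymal - epithelial
  attr(out, "alpha") <- alpha
  class(out) <- c("significance_pattern", "data.frame")
  out
}

#' Classify PTMs into progression / EMT / metastasis
#'
#' Pure function of a significance pattern. Rules, per form:
#' * EMT: the epithelial-vs-mesenchymal group contrast is significant while
#'   neither within-group contrast (melan-a vs 4C11+, 4C vs 4C11-) is.
#'   An EMT call is exclusive: the V-shaped group profile necessarily also
#'   trips the step-wise comparisons, so no further rule is evaluated.
#' * progression: the melan-a vs 4C comparison is significant, or at least
#'   two of the three consecutive comparisons are.
#' * metastasis: the 4C11- vs 4C11+ comparison is significant.
#'
#' Progression and metastasis may co-occur; forms firing no rule are
#' unclassified (empty label set).
#'
#' @param pattern a [significance_pattern()] data.frame.
#' @return `phenotype_assignment` data.frame: `form`, logical `progression`,
#'   `emt`, `metastasis`, `labels` (comma-joined) and `evidence` (which rule
#'   fired).
#' @export
classify_ptm <- function(pattern) {
  req <- c("sig_MA_vs_4C", "sig_4C_vs_4C11neg", "sig_4C11neg_vs_4C11pos",
           "sig_MA_vs_4C11pos", "sig_epi_vs_mes")
  miss <- setdiff(req, names(pattern))
  if (length(miss) > 0)
    warning("missing comparison(s) skipped: ", paste(miss, collapse = ", "),
            call. = FALSE)
  has <- function(nm) if (nm %in% names(pattern)) pattern[[nm]] else
    rep(FALSE, nrow(pattern))
  emt <- has("sig_epi_vs_mes") & !has("sig_MA_vs_4C11pos") &
    !has("sig_4C_vs_4C11neg")
  consec <- has("sig_MA_vs_4C") + has("sig_4C_vs_4C11neg") +
    has("sig_4C11neg_vs_4C11pos")
  prog <- !emt & (has("sig_MA_vs_4C") | consec >= 2)
  met <- !emt & has("sig_4C11neg_vs_4C11pos")
  evidence <- character(nrow(pattern))
  evidence[emt] <- "group contrast epi vs mes, within-group n.s."
  evidence[prog & has("sig_MA_vs_4C")] <- "melan-a vs 4C significant"
  evidence[prog & !has("sig_MA_vs_4C")] <- ">= 2 consecutive changes"
  evidence[met] <- trimws(paste(evidence[met],
                                "4C11- vs 4C11+ significant", sep = "; "))
  evidence[!emt & !prog & !met] <- "no rule fired"
  labels <- mapply(function(p, e, m)
    paste(c(if (p) "progression", if (e) "EMT", if (m) "metastasis"),
          collapse = ","), prog, emt, met)
  out <- data.frame(form = pattern$form, progression = prog, emt = emt,
                    metastasis = met, labels = labels, evidence = evidence,
                    stringsAsFactors = FALSE)
  class(out) <- c("phenotype_assignment", "data.frame")
  out
}

#' Classify fuzzy clusters by their members
#'
#' Each cluster inherits the majority label set of its confident members
#' (membership above `threshold`). Ties, and clusters without confident
#' members, fall back to a centroid-level rule: the centroid profile's line
#' means are compared with an effect-size threshold (`centroid_delta`, in
#' z-units) in place of significance, and the same rules as [classify_ptm()]
#' are applied; the fallback is reported in `evidence` and via a message.
#'
#' @param fit a [fuzzy_cmeans()] fit.
#' @param assignments per-form [classify_ptm()] result (rows matching the
#'   clustered profiles).
#' @param groups factor of cell lines per clustered sample column.
#' @param threshold membership cut for a confident member (default 0.5).
#' @param centroid_delta z-difference treated as a change in the centroid
#'   fallback rule (default 0.5).
#' @return data.frame with one row per cluster: `cluster`, `n_members`,
#'   `labels`, `evidence`.
#' @export
classify_cluster <- function(fit, assignments, groups, threshold = 0.5,
                             centroid_delta = 0.5) {
  stopifnot(inherits(fit, "fcm_fit"))
  groups <- factor(groups, levels = cell_lines())
  out <- list()
  for (k in seq_len(fit$c)) {
    member <- which(fit$membership[, k] > threshold)
    lab_tab <- table(assignments$labels[member])
    if (length(lab_tab) > 0 &&
        sum(lab_tab == max(lab_tab)) == 1L) {
      lab <- names(lab_tab)[which.max(lab_tab)]
      ev <- sprintf("majority of %d confident members", length(member))
    } else {
      # tie or empty cluster: centroid-level effect-size rule
      if (length(member) == 0 && length(lab_tab) == 0) {
        ev_prefix <- "empty cluster; centroid rule"
      } else {
        ev_prefix <- "member tie; centroid rule"
      }
      cen <- fit$centers[k, ]
      lm_ <- tapply(cen, groups, mean)
      big <- function(a, b) abs(lm_[b] - lm_[a]) > centroid_delta
      pat <- data.frame(form = paste0("cluster", k),
                        sig_MA_vs_4C = big("melan-a", "4C"),
                        sig_4C_vs_4C11neg = big("4C", "4C11-"),
                        sig_4C11neg_vs_4C11pos = big("4C11-", "4C11+"),
                        sig_MA_vs_4C11pos = big("melan-a", "4C11+"),
                        sig_epi_vs_mes =
                          abs(mean(lm_[c("4C", "4C11-")]) -
                                mean(lm_[c("melan-a", "4C11+")])) >
                          centroid_delta)
      cl_assign <- classify_ptm(pat)
      lab <- cl_assign$labels
      ev <- ev_prefix
      message("cluster ", k, ": ", ev_prefix, " -> ",
              if (nzchar(lab)) lab else "unclassified")
    }
    out[[k]] <- data.frame(cluster = k, n_members = length(member),
                           labels = lab, evidence = ev,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
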