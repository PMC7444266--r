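# Phenotype encodings of the four-line panel and module-trait correlation.

#' Encode sample phenotypes as numeric traits
#'
#' Fixed encoding of the panel's phenotypes per sample: `tumor` is 1 for the
#' tumourigenic lines (4C11-, 4C11+), `emt` is 1 for the mesenchymal-like
#' lines (4C, 4C11-), `metastasis` is 1 only for 4C11+, and `progression`
#' numbers the lines 1-4 in order melan-a, 4C, 4C11-, 4C11+. Replicates share
#' their line's values.
#'
#' @param sample_metadata data.frame with columns `sample` and `cell_line`
#'   (values among [cell_lines()]).
#' @return data.frame with columns `sample`, `tumor`, `emt`, `metastasis`,
#'   `progression`.
#' @export
encode_traits <- function(sample_metadata) {
  stop_if(!all(c("sample", "cell_line") %in% names(sample_metadata)),
          "'sample_metadata' needs columns 'sample' and 'cell_line'")
  cl <- as.character(sample_metadata$cell_line)
  bad <- setdiff(unique(cl), cell_lines())
  stop_if(length(bad) > 0,
          "unknown cell-line label(s): ", paste(bad, collapse = ", "))
  i <- match(cl, cell_lines())
  data.frame(sample = sample_metadata$sample,
             tumor = c(0, 0, 1, 1)[i],
             emt = c(0, 1, 1, 0)[i],
             metastasis = c(0, 0, 0, 1)[i],
             progression = i,
             stringsAsFactors = FALSE)
}

#' Correlate module eigengenes with sample traits
#'
#' Pearson correlation of each eigengene with each numeric trait over samples;
#' two-sided p-values from the Student-t transform
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom. A module
#' is flagged for a trait when `|r| > r_threshold` and `p < p_threshold`
#' (defaults 0.3 and 0.1; `preset = "strict"` uses 0.5 and 0.1).
#'
#' @param eigengenes modules x samples matrix (rows are eigengenes).
#' @param traits data.frame from [encode_traits()] (column `sample` optional;
#'   sample order must match the eigengene columns).
#' @param r_threshold,p_threshold significance cutoffs.
#' @param preset `"default"` or `"strict"`; overrides `r_threshold` when set
#'   to `"strict"`.
#' @return `module_trait_table` data.frame with one row per module x trait:
#'   `module`, `trait`, `r`, `p`, `significant`, `sign`. Constant traits or
#'   eigengenes give `NA` with a warning.
#' @export
module_trait_correlation <- function(eigengenes, traits,
                                     r_threshold = 0.3, p_threshold = 0.1,
                                     preset = c("default", "strict")) {
  preset <- match.arg(preset)
  if (preset == "strict") r_threshold <- 0.5
  tr <- traits[, setdiff(names(traits), "sample"), drop = FALSE]
  stop_if(ncol(eigengenes) != nrow(tr),
          "eigengene columns and trait rows must align")
  stop_if(ncol(eigengenes) < 4, "at least 4 samples are required")
  n <- ncol(eigengenes)
  out <- expand.grid(module = rownames(eigengenes), trait = names(tr),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$r <- NA_real_; out$p <- NA_real_
  for (i in seq_len(nrow(out))) {
    e <- eigengenes[out$module[i], ]
    t_ <- tr[[out$trait[i]]]
    if (stats::sd(e) == 0 || stats::sd(t_) == 0) {
      warning("constant eigengene or trait for ", out$module[i], " x ",
              out$trait[i], "; correlation undefined", call. = FALSE)
      next
    }
    r <- stats::cor(e, t_)
    out$r[i] <- r
    if (abs(r) >= 1) {
      out$p[i] <- 0
    } else {
      tt <- r * sqrt((n - 2) / (1 - r^2))
      out$p[i] <- 2 * stats::pt(-abs(tt), df = n - 2)
    }
  }
  out$significant <- !is.na(out$r) & abs(out$r) > r_threshold &
    out$p < p_threshold
  out$sign <- ifelse(is.na(out$r), NA, ifelse(out$r >= 0, "+", "-"))
  attr(out, "thresholds") <- c(r = r_threshold, p = p_threshold)
  class(out) <- c("module_trait_table", "data.frame")
  out
}

#' @export
print.module_trait_table <- function(x, ...) {
  th <- attr(x, "thresholds")
  cat("Module-trait correlations (|r| > ", th["r"], ", p < ", th["p"],
      ")\n", sep = "")
  df <- as.data.frame(x)
  df$r <- round(df$r, 3); df$p <- signif(df$p, 3)
  print(df, row.names = FALSE)
  invisible(x)
}
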