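# Histone PTM quantification from peptide-area tables: parsing and grammar
# validation, relative abundances, global and single-mark levels, replicate
# correlations, pairwise line ratios, and ANOVA/Tukey statistics.

PTM_MARKS <- c("ac", "me1", "me2", "me3", "ph")

#' Parse a histone PTM peptide-area table
#'
#' Expects columns `histone`, `start`, `end`, `modifications` and one numeric
#' area column per sample. The modification string is either the sentinel
#' `"unmod"` or a concatenation of `<residue letter><position><mark>` tokens
#' (e.g. `"K9me2K14ac"`), with marks among `ac`, `me1`, `me2`, `me3`, `ph`.
#' Every token position must lie inside `[start, end]`. Other table dialects
#' can be adapted with `column_map`.
#'
#' @param x path of a CSV/TSV file, or a data.frame.
#' @param column_map named character vector renaming input columns to the
#'   canonical names, e.g. `c(histone = "Histone", modifications = "PTM")`.
#' @param sep field separator when `x` is a path (default `","`;
#'   autodetected as tab when the file has no comma in its header).
#' @return `ptm_table` data.frame with the canonical columns, a `form` id
#'   column, and a `mods` attribute (list of per-form data.frames with
#'   `residue`, `position`, `mark`).
#' @export
parse_ptm_table <- function(x, column_map = NULL, sep = ",") {
  if (is.character(x)) {
    header <- readLines(x, n = 1L)
    if (!grepl(sep, header, fixed = TRUE) && grepl("\t", header)) sep <- "\t"
    x <- utils::read.table(x, header = TRUE, sep = sep, check.names = FALSE,
                           stringsAsFactors = FALSE)
  }
  if (!is.null(column_map))
    names(x)[match(column_map, names(x))] <- names(column_map)
  req <- c("histone", "start", "end", "modifications")
  missing_c <- setdiff(req, names(x))
  stop_if(length(missing_c) > 0,
          "missing column(s): ", paste(missing_c, collapse = ", "))
  sample_cols <- setdiff(names(x), req)
  stop_if(length(sample_cols) == 0, "no sample area columns found")
  for (sc in sample_cols) {
    stop_if(!is.numeric(x[[sc]]), "non-numeric area column: ", sc)
    stop_if(any(x[[sc]] <= 0 | is.na(x[[sc]])),
            "areas must be positive in column: ", sc)
  }
  mods <- vector("list", nrow(x))
  for (i in seq_len(nrow(x))) {
    mods[[i]] <- parse_mod_string(x$modifications[i], x$start[i], x$end[i],
                                  row = i)
  }
  form <- paste0(x$histone, ":", x$start, "-", x$end, ":", x$modifications)
  dup <- duplicated(form)
  stop_if(any(dup), "duplicate (backbone, modification) row(s): ",
          paste(utils::head(which(dup)), collapse = ", "))
  out <- cbind(data.frame(form = form, stringsAsFactors = FALSE), x)
  attr(out, "mods") <- stats::setNames(mods, form)
  attr(out, "sample_cols") <- sample_cols
  class(out) <- c("ptm_table", "data.frame")
  out
}

parse_mod_string <- function(s, start, end, row = NA) {
  if (identical(s, "unmod"))
    return(data.frame(residue = character(0), position = integer(0),
                      mark = character(0), stringsAsFactors = FALSE))
  m <- gregexpr("[A-Z][0-9]+(me[123]|ac|ph)", s)[[1]]
  tokens <- regmatches(s, gregexpr("[A-Z][0-9]+(me[123]|ac|ph)", s))[[1]]
  covered <- if (m[1] == -1) 0 else sum(attr(m, "match.length"))
  stop_if(covered != nchar(s),
          "malformed modification token in row ", row, ": '", s, "'")
  residue <- substr(tokens, 1, 1)
  position <- as.integer(gsub("^[A-Z]([0-9]+).*$", "\\1", tokens))
  mark <- gsub("^[A-Z][0-9]+", "", tokens)
  stop_if(any(position < start | position > end),
          "modification position outside backbone range in row ", row,
          ": '", s, "'")
  stop_if(anyDuplicated(position) > 0,
          "duplicate residue position in row ", row, ": '", s, "'")
  data.frame(residue = residue, position = position, mark = mark,
             stringsAsFactors = FALSE)
}

#' Serialise parsed modifications back to the canonical string
#'
#' Inverse of the parser's grammar: tokens ordered by position, or `"unmod"`
#' for the empty set. `parse -> serialise -> parse` is the identity.
#'
#' @param mods data.frame with `residue`, `position`, `mark`.
#' @return canonical modification string.
#' @export
serialize_mods <- function(mods) {
  if (nrow(mods) == 0) return("unmod")
  mods <- mods[order(mods$position), ]
  paste0(mods$residue, mods$position, mods$mark, collapse = "")
}

#' Relative abundances of PTM forms
#'
#' The relative abundance of a form is its area divided by the total area of
#' all forms of the same (histone, backbone) in the same sample; abundances
#' therefore sum to 1 per backbone per sample.
#'
#' @param ptm a [parse_ptm_table()] result.
#' @return object of class `ptm_abundance`: list with `ratios` (forms x
#'   samples matrix in `[0, 1]`), `info` (form metadata), `mods` (parsed
#'   modification lists) and `samples`.
#' @export
relative_abundance <- function(ptm) {
  stopifnot(inherits(ptm, "ptm_table"))
  sample_cols <- attr(ptm, "sample_cols")
  key <- paste0(ptm$histone, ":", ptm$start, "-", ptm$end)
  areas <- as.matrix(ptm[, sample_cols, drop = FALSE])
  rownames(areas) <- ptm$form
  ratios <- areas
  for (k in unique(key)) {
    idx <- which(key == k)
    tot <- colSums(areas[idx, , drop = FALSE])
    bad <- which(tot <= 0)
    stop_if(length(bad) > 0, "zero total area for backbone ", k,
            " in sample ", sample_cols[bad[1]])
    ratios[idx, ] <- sweep(areas[idx, , drop = FALSE], 2, tot, "/")
  }
  out <- list(ratios = ratios,
              info = data.frame(form = ptm$form, histone = ptm$histone,
                                start = ptm$start, end = ptm$end,
                                modifications = ptm$modifications,
                                backbone = key, stringsAsFactors = FALSE),
              mods = attr(ptm, "mods"), samples = sample_cols)
  class(out) <- "ptm_abundance"
  out
}

#' @export
print.ptm_abundance <- function(x, ...) {
  cat("PTM relative abundances:", nrow(x$ratios), "forms on",
      length(unique(x$info$backbone)), "backbones x", length(x$samples),
      "samples\n")
  invisible(x)
}

form_has_mark <- function(ab, marks) {
  vapply(ab$mods[rownames(ab$ratios)],
         function(m) any(m$mark %in% marks), TRUE)
}

#' Global acetylation and methylation levels
#'
#' Per sample, the sum of the relative abundances of all forms carrying at
#' least one token of the mark class: acetylation (`ac`), mono-, di-,
#' tri-methylation (`me1`/`me2`/`me3`) and total methylation (any of the
#' three). Each form counts once per class however many matching tokens it
#' carries.
#'
#' @param abundance a [relative_abundance()] result.
#' @return matrix with rows `acetylation`, `me1`, `me2`, `me3`, `methylation`
#'   and one column per sample.
#' @export
global_mark_levels <- function(abundance) {
  stopifnot(inherits(abundance, "ptm_abundance"))
  classes <- list(acetylation = "ac", me1 = "me1", me2 = "me2", me3 = "me3",
                  methylation = c("me1", "me2", "me3"))
  out <- matrix(0, length(classes), ncol(abundance$ratios),
                dimnames = list(names(classes), colnames(abundance$ratios)))
  for (i in seq_along(classes)) {
    sel <- form_has_mark(abundance, classes[[i]])
    if (any(sel)) out[i, ] <- colSums(abundance$ratios[sel, , drop = FALSE])
  }
  out
}

#' Replicate correlation matrix
#'
#' Pearson correlation of the relative-abundance profiles between all sample
#' pairs; the usual replicate-quality diagnostic.
#'
#' @param abundance a [relative_abundance()] result (needs >= 3 forms).
#' @return symmetric samples x samples correlation matrix with unit diagonal;
#'   constant sample vectors give `NA` entries with a warning.
#' @export
replicate_correlation <- function(abundance) {
  stopifnot(inherits(abundance, "ptm_abundance"))
  stop_if(nrow(abundance$ratios) < 3, "at least 3 forms are required")
  r <- abundance$ratios
  const <- apply(r, 2, stats::sd) == 0
  if (any(const))
    warning("constant sample vector(s): ",
            paste(colnames(r)[const], collapse = ", "), call. = FALSE)
  suppressWarnings(stats::cor(r))
}

#' Single-mark levels
#'
#' For each (histone, residue position, mark) token, sums the relative
#' abundances of all forms carrying that token, giving the marginal level of
#' the single mark per sample. Optionally z-scores each row (mean 0, SD 1
#' across samples).
#'
#' @param abundance a [relative_abundance()] result.
#' @param zscore return row-wise z-scores instead of raw sums.
#' @return `single_mark_table`: matrix with rownames like `"H3.1K9me2"` and
#'   one column per sample; attribute `"info"` maps rows to (histone,
#'   position, mark).
#' @export
single_mark_levels <- function(abundance, zscore = FALSE) {
  stopifnot(inherits(abundance, "ptm_abundance"))
  rows <- list()
  for (f in rownames(abundance$ratios)) {
    m <- abundance$mods[[f]]
    if (nrow(m) == 0) next
    hist <- abundance$info$histone[abundance$info$form == f]
    for (j in seq_len(nrow(m))) {
      key <- paste0(hist, m$residue[j], m$position[j], m$mark[j])
      rows[[key]] <- c(rows[[key]] %||% list(),
                       list(abundance$ratios[f, ]))
    }
  }
  out <- t(vapply(rows, function(v) Reduce(`+`, v),
                  numeric(ncol(abundance$ratios))))
  colnames(out) <- colnames(abundance$ratios)
  if (zscore) out <- t(scale(t(out)))
  info <- data.frame(key = rownames(out), stringsAsFactors = FALSE)
  attr(out, "info") <- info
  out
}

#' One-way ANOVA with Tukey HSD contrasts per form
#'
#' For every PTM form (or any row of a values matrix), a one-way ANOVA of the
#' relative abundance across the four cell lines, followed by all pairwise
#' Tukey honestly-significant-difference comparisons (studentised range;
#' Tukey-Kramer for unbalanced groups, as [stats::TukeyHSD()] provides).
#' Significance is called at multiplicity-adjusted p below `alpha`. Rows with
#' zero variance within every group are flagged degenerate and given `NA`
#' statistics.
#'
#' @param values forms x samples numeric matrix (e.g. `$ratios` of a
#'   [relative_abundance()] result).
#' @param groups factor of cell lines per sample (>= 2 replicates each).
#' @param alpha significance level on adjusted p (default 0.05).
#' @return `ptm_stats` data.frame: one row per form with `f`, `p`, then per
#'   pairwise comparison `p_<a>_vs_<b>` (Tukey-adjusted), `d_<a>_vs_<b>`
#'   (mean difference b - a) and `sig_<a>_vs_<b>`.
#' @export
anova_tukey <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  stop_if(any(table(groups) < 2), "at least 2 replicates per group")
  stop_if(ncol(values) != length(groups),
          "'groups' must match the value columns")
  lev <- levels(groups)
  pairs <- utils::combn(lev, 2)
  pair_names <- apply(pairs, 2, function(p) paste0(p[2], "_vs_", p[1]))
  one <- function(y) {
    if (all(tapply(y, groups, stats::sd) == 0)) {
      return(c(f = NA_real_, p = NA_real_,
               stats::setNames(rep(NA_real_, 2 * ncol(pairs)),
                               c(paste0("p_", pair_names),
                                 paste0("d_", pair_names)))))
    }
    fit <- stats::aov(y ~ groups)
    an <- summary(fit)[[1]]
    tk <- stats::TukeyHSD(fit)$groups
    # TukeyHSD labels rows "b-a"; map onto our pair order
    lab <- paste0(pairs[2, ], "-", pairs[1, ])
    p_adj <- tk[lab, "p adj"]
    dif <- tk[lab, "diff"]
    c(f = an[1, "F value"], p = an[1, "Pr(>F)"],
      stats::setNames(p_adj, paste0("p_", pair_names)),
      stats::setNames(dif, paste0("d_", pair_names)))
  }
  res <- t(apply(values, 1, one))
  out <- data.frame(form = rownames(values), res, check.names = FALSE,
                    stringsAsFactors = FALSE)
  for (pn in pair_names)
    out[[paste0("sig_", pn)]] <- !is.na(out[[paste0("p_", pn)]]) &
      out[[paste0("p_", pn)]] < alpha
  attr(out, "pairs") <- pair_names
  attr(out, "alpha") <- alpha
  class(out) <- c("ptm_stats", "data.frame")
  out
}

#' Pairwise cell-line abundance ratios
#'
#' Ratios of mean relative abundance between consecutive lines of the panel
#' (4C / melan-a, 4C11- / 4C, 4C11+ / 4C11-) and the end-to-end anchor
#' (4C11+ / melan-a), with a log2 variant. Zero denominators give `NA` with a
#' flag column.
#'
#' @param abundance a [relative_abundance()] result.
#' @param groups factor of cell lines per sample (levels among
#'   [cell_lines()]).
#' @return data.frame with one row per form: `ratio_<cmp>`, `log2_<cmp>` and
#'   `undefined_<cmp>` per comparison.
#' @export
pairwise_line_ratios <- function(abundance, groups) {
  stopifnot(inherits(abundance, "ptm_abundance"))
  groups <- factor(groups, levels = cell_lines())
  means <- t(apply(abundance$ratios, 1, tapply, groups, mean))
  cmps <- list(c("4C", "melan-a"), c("4C11-", "4C"), c("4C11+", "4C11-"),
               c("4C11+", "melan-a"))
  out <- data.frame(form = rownames(abundance$ratios),
                    stringsAsFactors = FALSE)
  code <- c("melan-a" = "MA", "4C" = "4C", "4C11-" = "4C11neg",
            "4C11+" = "4C11pos")
  for (cmp in cmps) {
    nm <- paste0(code[cmp[1]], "_over_", code[cmp[2]])
    num <- means[, cmp[1]]; den <- means[, cmp[2]]
    undef <- den == 0
    r <- ifelse(undef, NA_real_, num / den)
    out[[paste0("ratio_", nm)]] <- r
    out[[paste0("log2_", nm)]] <- ifelse(is.na(r) | r <= 0, NA_real_, log2(r))
    out[[paste0("undefined_", nm)]] <- undef
  }
  out
}
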