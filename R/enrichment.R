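# Hypergeometric over-representation of gene sets in modules, GMT I/O and
# ortholog mapping.

#' Read / write GMT gene-set files
#'
#' Standard GMT semantics: one set per line, tab-separated
#' `name<TAB>description<TAB>member...`. Duplicate members within a set are
#' dropped with a warning on read.
#'
#' @param file path.
#' @return named list of character vectors; set descriptions in attribute
#'   `"description"`.
#' @export
read_gmt <- function(file) {
  lines <- readLines(file, warn = FALSE)
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3)
  stop_if(length(bad) > 0, "malformed GMT line(s): ",
          paste(utils::head(bad), collapse = ", "))
  nm <- vapply(parts, `[[`, "", 1L)
  stop_if(anyDuplicated(nm) > 0, "duplicate set names in GMT")
  sets <- lapply(parts, function(p) {
    members <- p[-(1:2)]
    members <- members[nzchar(members)]
    if (anyDuplicated(members) > 0) {
      warning("duplicate members deduplicated in set '", p[1L], "'",
              call. = FALSE)
      members <- unique(members)
    }
    members
  })
  names(sets) <- nm
  attr(sets, "description") <- stats::setNames(vapply(parts, `[[`, "", 2L), nm)
  sets
}

#' @rdname read_gmt
#' @param sets named list of character vectors.
#' @param descriptions optional named character vector of set descriptions.
#' @export
write_gmt <- function(sets, file, descriptions = NULL) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, descriptions[nm] %||% "na", sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, file)
  invisible(file)
}

#' Read a two-column ortholog map
#'
#' @param file TSV with source ids in column 1 and target ids in column 2
#'   (header optional, autodetected by the column count staying 2).
#' @return data.frame with columns `source`, `target`.
#' @export
read_ortholog_map <- function(file) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE)
  stop_if(ncol(df) < 2, "ortholog map needs two columns")
  stats::setNames(df[, 1:2], c("source", "target"))
}

#' Map gene ids through an ortholog table
#'
#' Applies a (possibly many-to-one) source -> target map; unmapped genes are
#' dropped and their count reported in a message.
#'
#' @param genes character vector of source ids.
#' @param map data.frame with columns `source`, `target`.
#' @return character vector of unique target ids.
#' @export
map_orthologs <- function(genes, map) {
  hit <- map$target[match(genes, map$source)]
  n_drop <- sum(is.na(hit))
  if (n_drop > 0)
    message(n_drop, " gene(s) had no ortholog and were dropped")
  unique(hit[!is.na(hit)])
}

#' Hypergeometric over-representation of gene sets in modules
#'
#' For each module and set, counts the overlap `k` between the module's `n`
#' genes and the `K` set members present in the `N`-gene universe, and reports
#' the upper-tail hypergeometric probability `P(X >= k)`. The universe
#' defaults to every gene in the partition (grey included); the grey
#' pseudo-module itself is not tested. Benjamini-Hochberg adjusted p-values
#' across all module x set tests are reported alongside the raw values;
#' significance calls at `alpha` use raw p-values.
#'
#' @param modules named character vector gene -> module label.
#' @param sets named list of character vectors (e.g. from [read_gmt()]).
#' @param universe optional character vector overriding the default universe.
#' @param map optional ortholog map (data.frame `source`, `target`) applied to
#'   the module genes and the universe before intersection with the sets.
#' @param alpha significance level on the raw p-value (default 0.05).
#' @return data.frame with one row per module x set: `module`, `set`, `N`,
#'   `K`, `n`, `k`, `p`, `p_adj`, `significant`.
#' @export
hypergeometric_enrichment <- function(modules, sets, universe = NULL,
                                      map = NULL, alpha = 0.05) {
  stop_if(length(modules) == 0, "empty partition")
  genes_by_module <- split(names(modules), modules)
  genes_by_module <- genes_by_module[setdiff(names(genes_by_module), "grey")]
  if (is.null(universe)) universe <- names(modules)
  stop_if(length(universe) == 0, "empty universe")
  if (!is.null(map)) {
    universe <- map_orthologs(universe, map)
    genes_by_module <- lapply(genes_by_module, map_orthologs, map = map)
  }
  not_in <- unlist(lapply(genes_by_module, setdiff, y = universe))
  stop_if(length(not_in) > 0, "module gene(s) outside the universe: ",
          paste(utils::head(not_in), collapse = ", "))
  N <- length(universe)
  rows <- list()
  for (m in names(genes_by_module)) {
    mg <- genes_by_module[[m]]
    for (s in names(sets)) {
      set_u <- intersect(sets[[s]], universe)
      K <- length(set_u)
      n <- length(mg)
      k <- length(intersect(mg, set_u))
      p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        module = m, set = s, N = N, K = K, n = n, k = k, p = p,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$p < alpha
  out
}

#' Rank genes by survival p-value
#'
#' Orders a gene-wise survival screen by ascending p-value (ties broken by
#' gene id) and returns the `top_n` gene ids, e.g. to define a top-ranked
#' prognostic gene list for enrichment testing.
#'
#' @param survival_results data.frame with columns `gene` and `p` (as from
#'   [gene_wise_survival_screen()], where `p` is the screen's primary
#'   p-value).
#' @param top_n list length (default 500). When larger than the number of
#'   genes with non-missing p, all are returned with a warning.
#' @return character vector of gene ids.
#' @export
rank_prognostic_genes <- function(survival_results, top_n = 500L) {
  stop_if(!all(c("gene", "p") %in% names(survival_results)),
          "'survival_results' needs columns 'gene' and 'p'")
  if (top_n <= 0) return(character(0))
  d <- survival_results[!is.na(survival_results$p), ]
  d <- d[order(d$p, d$gene), ]
  if (top_n > nrow(d)) {
    warning("top_n exceeds available genes; returning all ", nrow(d),
            call. = FALSE)
    top_n <- nrow(d)
  }
  d$gene[seq_len(top_n)]
}
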