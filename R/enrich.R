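#' Read a gene-set collection in GMT format
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then gene symbols. Symbols are upper-cased and duplicates within a set
#' collapsed.
#'
#' @param path GMT file path.
#' @return list of class `gene_set_collection`: `sets` (named list of
#'   character vectors), `descriptions` (named character).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop_ps("GMT file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list(); desc <- character(0)
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop_ps("malformed GMT line %d in %s: expected >= 3 tab-separated fields",
              i, path)
    genes <- unique(toupper(f[-(1:2)]))
    genes <- genes[nzchar(genes)]
    if (length(genes) < 1)
      stop_ps("empty gene set '%s' at line %d in %s", f[1], i, path)
    if (f[1] %in% names(sets))
      stop_ps("duplicated set name '%s' at line %d in %s", f[1], i, path)
    sets[[f[1]]] <- genes
    desc[f[1]] <- f[2]
  }
  structure(list(sets = sets, descriptions = desc),
            class = "gene_set_collection")
}

#' @rdname read_gmt
#' @param collection a `gene_set_collection`.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection$sets), function(nm)
    paste(c(nm, collection$descriptions[nm] %||% "", collection$sets[[nm]]),
          collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric gene-set over-representation analysis
#'
#' Tests each gene set for over-representation of the panel genes against a
#' background universe of annotated genes: with `N` universe genes, `K` of
#' them in the set, and an `n`-gene panel overlapping the set in `k` genes,
#' `p = P(X >= k)` for `X ~ Hypergeometric(N, K, n)`. P-values are adjusted
#' across all tested terms by Benjamini-Hochberg FDR. Panel genes outside
#' the universe are dropped with a warning (only annotated genes count);
#' set membership is likewise restricted to the universe.
#'
#' @param panel character vector of gene symbols (case-insensitive).
#' @param collection a [read_gmt()] collection (or named list of sets).
#' @param universe background gene universe; default: union of all genes in
#'   the collection.
#' @param fdr_cutoff significance cut-off recorded in the result attribute
#'   (default 0.01); rows are not filtered.
#' @return data.frame of class `enrichment_result`, sorted by `q` then `p`:
#'   `term`, `k`, `K`, `n`, `N`, `p`, `q`, `genes` (overlap, comma-joined).
#' @export
#' @examples
#' coll <- list(sets = list(TERM1 = c("A", "B", "C"), TERM2 = c("D", "E")))
#' hypergeometric_enrichment(c("A", "B", "C"), coll,
#'                           universe = c(LETTERS[1:5], paste0("G", 1:24)))
hypergeometric_enrichment <- function(panel, collection, universe = NULL,
                                      fdr_cutoff = 0.01) {
  sets <- if (is.list(collection) && !is.null(collection$sets))
    collection$sets else collection
  sets <- lapply(sets, toupper)
  panel <- unique(toupper(panel))
  universe <- unique(toupper(universe %||% unlist(sets, use.names = FALSE)))
  N <- length(universe)

  dropped <- setdiff(panel, universe)
  if (length(dropped) > 0)
    warning(sprintf("dropping %d panel gene(s) outside the universe: %s",
                    length(dropped), paste(dropped, collapse = ", ")),
            call. = FALSE)
  panel <- intersect(panel, universe)
  if (length(panel) == 0)
    stop_ps("no panel gene is in the annotated universe")
  n <- length(panel)

  rows <- lapply(names(sets), function(nm) {
    K <- length(intersect(sets[[nm]], universe))
    ov <- intersect(panel, sets[[nm]])
    k <- length(ov)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = nm, k = k, K = K, n = n, N = N, p = p,
               genes = paste(sort(ov), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$q, out$p, out$term),
             c("term", "k", "K", "n", "N", "p", "q", "genes")]
  rownames(out) <- NULL
  attr(out, "fdr_cutoff") <- fdr_cutoff
  class(out) <- c("enrichment_result", "data.frame")
  out
}
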