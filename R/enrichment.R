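# Two-list (target vs background) hypergeometric term enrichment with fold
# enrichment and Benjamini-Hochberg FDR.

validate_counts <- function(N, B, n, b) {
  if (N < 1 || B < 0 || n < 0 || b < 0) stop("counts must be non-negative (N >= 1)")
  if (B > N || n > N) stop("need B <= N and n <= N")
  if (b > min(n, B)) stop("invalid counts: b > min(n, B)")
}

#' Fold enrichment (b/n) / (B/N)
#'
#' The enrichment ratio convention of two-list term enrichment: the rate of
#' term genes in the target list over their rate in the background,
#' `(b/n) / (B/N) = b*N / (n*B)`.
#'
#' @param N Background size. @param B Term genes within background.
#' @param n Target size. @param b Term genes within target.
#' @return Fold enrichment (double precision; round only at display).
#' @examples
#' enrichment_ratio(15154, 10, 28, 2) # 108.24
#' @export
enrichment_ratio <- function(N, B, n, b) {
  validate_counts(N, B, n, b)
  if (n == 0 || B == 0) stop("fold enrichment undefined for n = 0 or B = 0")
  (b * N) / (n * B)
}

#' Hypergeometric upper-tail probability P(X >= b)
#'
#' For X ~ Hypergeometric(N, B, n): the probability of drawing at least `b`
#' term genes in a size-`n` sample from a background of `N` genes of which
#' `B` carry the term. Computed through the log-space-stable distribution
#' function; `P(X >= 0)` is exactly 1.
#'
#' @inheritParams enrichment_ratio
#' @return Tail probability in \[0, 1\].
#' @examples
#' hypergeom_tail(15154, 10, 28, 2) # 1.47e-4
#' @export
hypergeom_tail <- function(N, B, n, b) {
  validate_counts(N, B, n, b)
  if (b == 0) return(1)
  stats::phyper(b - 1, B, N - B, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up q-values
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return q-values in the input order.
#' @export
bh_fdr <- function(pvalues) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Read gene sets from a GMT file
#'
#' One term per line: term id, description, then tab-separated gene ids.
#'
#' @param path GMT path.
#' @return List with `sets` (named list of gene vectors) and `descriptions`
#'   (named character vector).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(parts, length, integer(1)) < 3
  if (any(short)) stop("malformed GMT line ", which(short)[1])
  ids <- vapply(parts, `[[`, character(1), 1)
  if (anyDuplicated(ids)) stop("duplicate term id in GMT")
  list(sets = stats::setNames(lapply(parts, function(p) unique(p[-(1:2)])), ids),
       descriptions = stats::setNames(vapply(parts, `[[`, character(1), 2), ids))
}

#' Two-list hypergeometric term enrichment
#'
#' For each term with at least one target overlap: counts
#' `N = |background|`, `n = |target|`, `B = |term ∩ background|`,
#' `b = |term ∩ target|`, fold enrichment, hypergeometric tail p and BH q.
#' Target genes outside the background are dropped with a warning. Terms
#' disjoint from the background are skipped. By default the BH adjustment
#' runs over the terms with `b >= 1` only; `fdr_universe = "all"` includes
#' every tested term with `B >= 1` in the multiplicity burden.
#'
#' @param target Character vector of target genes.
#' @param background Character vector of background genes.
#' @param terms Named list: term id -> gene ids (e.g. `read_gmt(...)$sets`).
#' @param descriptions Optional named character vector of term descriptions.
#' @param fdr_universe `"nonzero"` (default) or `"all"`.
#' @return data.frame sorted by (p, term): term, description, p, q, fold,
#'   N, B, n, b, genes (";"-joined overlap).
#' @export
enrich_terms <- function(target, background, terms, descriptions = NULL,
                         fdr_universe = c("nonzero", "all")) {
  fdr_universe <- match.arg(fdr_universe)
  background <- unique(background)
  target <- unique(target)
  if (length(background) == 0) stop("background is empty")
  drop <- setdiff(target, background)
  if (length(drop)) {
    warning(length(drop), " target gene(s) outside the background dropped")
    target <- intersect(target, background)
  }
  if (length(target) == 0) stop("target is empty after background subsetting")
  N <- length(background); n <- length(target)
  rows <- lapply(names(terms), function(tm) {
    tg <- intersect(unique(terms[[tm]]), background)
    B <- length(tg)
    if (B == 0) return(NULL)  # term not represented in background
    ov <- intersect(tg, target)
    b <- length(ov)
    data.frame(term = tm,
               description = if (!is.null(descriptions)) descriptions[[tm]] %||% "" else "",
               p = hypergeom_tail(N, B, n, b),
               fold = enrichment_ratio(N, B, n, b),
               N = N, B = B, n = n, b = b,
               genes = paste(sort(ov), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) stop("no term overlaps the background")
  if (fdr_universe == "all") {
    res$q <- bh_fdr(res$p)
    res <- res[res$b >= 1, , drop = FALSE]
  } else {
    res <- res[res$b >= 1, , drop = FALSE]
    if (nrow(res)) res$q <- bh_fdr(res$p)
  }
  res <- res[order(res$p, res$term),
             c("term", "description", "p", "q", "fold", "N", "B", "n", "b", "genes")]
  rownames(res) <- NULL
  res
}
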