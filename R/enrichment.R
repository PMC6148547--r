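#' Hypergeometric over-representation analysis
#'
#' Tests each gene set for over-representation of the candidate genes in the
#' declared universe. `mode = "exact"` uses the upper hypergeometric tail
#' `P(X >= k)`; `mode = "ease"` uses the more conservative jackknifed tail
#' `P(X >= k - 1)` (the DAVID EASE convention, the default here). Sets are
#' intersected with the universe before testing; terms with zero overlap are
#' excluded. BH FDR is computed within each category. Significance flags use
#' `go_alpha` (default 0.01) for the GO-style categories CC/BP/MF and
#' `pathway_alpha` (default 0.05) for pathways.
#'
#' @param candidates character vector, must be a subset of `universe`.
#' @param sets named list of gene sets; an optional `categories` attribute
#'   (named by set) assigns each term to CC/BP/MF/pathway, default
#'   `"pathway"`.
#' @param universe character vector of background genes.
#' @param mode `"ease"` or `"exact"`.
#' @param go_alpha,pathway_alpha significance thresholds on raw p.
#' @return data.frame: `term_id`, `category`, `k`, `n`, `K`, `N`, `p`,
#'   `fdr`, `neg_log10_p`, `significant`, sorted by p.
#' @export
hypergeom_enrich <- function(candidates, sets, universe,
                             mode = c("ease", "exact"),
                             go_alpha = 0.01, pathway_alpha = 0.05) {
  mode <- match.arg(mode)
  if (!all(candidates %in% universe)) {
    stop("candidate outside universe: enrichment background must contain all candidates")
  }
  categories <- attr(sets, "categories")
  N <- length(universe)
  n <- length(unique(candidates))
  rows <- lapply(names(sets), function(id) {
    term <- intersect(sets[[id]], universe)
    K <- length(term)
    k <- length(intersect(candidates, term))
    if (k == 0) return(NULL)
    kk <- if (mode == "ease") k - 1L else k
    # P(X >= kk); for ease with k = 1 this is P(X >= 0) = 1
    p <- if (kk <= 0) 1 else stats::phyper(kk - 1L, K, N - K, n, lower.tail = FALSE)
    cat_i <- if (!is.null(categories) && !is.na(categories[id])) categories[[id]] else "pathway"
    data.frame(term_id = id, category = cat_i, k = k, n = n, K = K, N = N,
               p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(term_id = character(0), category = character(0),
                      k = integer(0), n = integer(0), K = integer(0),
                      N = integer(0), p = numeric(0), fdr = numeric(0),
                      neg_log10_p = numeric(0), significant = logical(0)))
  }
  out$fdr <- stats::ave(out$p, out$category,
                        FUN = function(p) stats::p.adjust(p, "BH"))
  out$neg_log10_p <- -log10(out$p)
  out$significant <- ifelse(out$category == "pathway",
                            out$p < pathway_alpha, out$p < go_alpha)
  out <- out[order(out$p, -out$k, out$term_id), ]
  rownames(out) <- NULL
  out
}

#' Top enriched terms per category
#'
#' Ranks by ascending p within each category, breaking ties by larger
#' overlap `k` then lexical term id, and keeps the top `per_category`.
#'
#' @param results a [hypergeom_enrich()] table.
#' @param per_category terms kept per category (default 20).
#' @return subset of `results`, ordered category-wise by rank.
#' @export
top_terms <- function(results, per_category = 20L) {
  if (nrow(results) == 0) stop("top_terms needs a non-empty result table")
  parts <- lapply(split(results, results$category), function(d) {
    d <- d[order(d$p, -d$k, d$term_id), ]
    utils::head(d, per_category)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}
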