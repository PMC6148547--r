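#' Per-gene, per-study differential-expression p-values
#'
#' Two-sided Welch t-test per gene within each study (log2 scale applied to
#' raw studies). Genes missing from a study get NA there.
#'
#' @param studies list of `expression_study` objects.
#' @param genes genes to report; default the union over studies.
#' @return numeric matrix, genes x studies.
#' @export
gene_study_pvals <- function(studies, genes = NULL) {
  if (is.null(genes)) {
    genes <- sort(unique(unlist(lapply(studies, function(s) rownames(s$values)))))
  }
  cols <- lapply(studies, function(st) {
    tab <- de_test(st)
    stats::setNames(tab$p, tab$gene)[genes]
  })
  out <- do.call(cbind, cols)
  dimnames(out) <- list(genes, vapply(studies, `[[`, "", "study_id"))
  out
}

# Median rank across studies; ranks are within-study (1 = smallest p),
# missing studies excluded per gene.
.median_ranks <- function(p_mat) {
  ranks <- apply(p_mat, 2, function(p) rank(p, ties.method = "average",
                                            na.last = "keep"))
  apply(ranks, 1, stats::median, na.rm = TRUE)
}

#' Median-rank multi-study meta-analysis
#'
#' Emulates a median-rank expression meta-analysis: genes are ranked by
#' p-value within each study (1 = smallest), the per-gene statistic is the
#' median rank across studies, and the combined p is the permutation tail
#' probability of a median rank at least this small under independent
#' uniform ranks, with the add-one correction `p = (b + 1)/(n_perm + 1)`.
#' The permutation null is seeded and shared across genes.
#'
#' @param p_mat numeric matrix of p-values, genes x studies.
#' @param n_perm permutation-null size (default 10000).
#' @param seed RNG seed for the null draws.
#' @return named numeric vector of combined p-values, one per gene, with the
#'   median-rank statistics as attribute `stat`.
#' @export
median_rank_meta <- function(p_mat, n_perm = 10000L, seed = 1L) {
  if (ncol(p_mat) < 2) stop("median-rank meta-analysis needs at least two studies")
  m <- nrow(p_mat)
  k <- ncol(p_mat)
  stat <- .median_ranks(p_mat)
  null <- .with_stream(seed, 23L, {
    draws <- matrix(sample.int(m, n_perm * k, replace = TRUE), ncol = k)
    apply(draws, 1, stats::median)
  })
  null <- sort(null)
  b <- findInterval(stat, null)  # count of null values <= stat
  p <- (b + 1) / (n_perm + 1)
  names(p) <- rownames(p_mat)
  attr(p, "stat") <- stat
  p
}

#' Key-gene records with leave-one-out stability
#'
#' Recomputes the median-rank combined p omitting each study in turn. A gene
#' is `stable` when the full combined p and every leave-one-out p are below
#' `alpha`; key genes are the stable members of `genes_of_interest`.
#'
#' @param p_mat p-value matrix, genes x studies (at least 3 studies); ranks
#'   are taken over all rows, so pass the full tested universe and restrict
#'   reporting with `genes_of_interest`.
#' @param genes_of_interest genes to report (default all rows).
#' @param alpha significance/stability level (default 0.05).
#' @param n_perm,seed permutation-null controls, as in [median_rank_meta()].
#' @return data.frame (`gene`, `combined_p`, `max_loo_p`, `stable`, `key`)
#'   with the per-omission p matrix in attribute `loo_p`.
#' @export
keygene_influence <- function(p_mat, genes_of_interest = rownames(p_mat),
                              alpha = 0.05, n_perm = 10000L, seed = 1L) {
  if (ncol(p_mat) < 3) stop("leave-one-out stability needs at least 3 studies")
  combined <- median_rank_meta(p_mat, n_perm = n_perm, seed = seed)
  loo <- vapply(seq_len(ncol(p_mat)), function(j) {
    median_rank_meta(p_mat[, -j, drop = FALSE], n_perm = n_perm,
                     seed = seed + j)
  }, numeric(nrow(p_mat)))
  colnames(loo) <- paste0("omit_", colnames(p_mat))
  idx <- match(genes_of_interest, rownames(p_mat))
  if (anyNA(idx)) stop("genes_of_interest must be rows of p_mat")
  stable <- combined[idx] < alpha & apply(loo[idx, , drop = FALSE], 1, max) < alpha
  out <- data.frame(gene = genes_of_interest,
                    combined_p = unname(combined[idx]),
                    max_loo_p = unname(apply(loo[idx, , drop = FALSE], 1, max)),
                    stable = unname(stable), key = unname(stable),
                    stringsAsFactors = FALSE)
  attr(out, "loo_p") <- loo[idx, , drop = FALSE]
  out
}

#' Crucial pathways of the key genes
#'
#' The pathways that every key gene participates in: the intersection of the
#' per-gene pathway memberships.
#'
#' @param key_genes character vector, non-empty.
#' @param gene_pathway_map a [map_gene_pathway()] result (or its `edges`
#'   data.frame).
#' @return sorted character vector of pathway ids; warns when empty.
#' @export
crucial_pathways <- function(key_genes, gene_pathway_map) {
  if (length(key_genes) == 0) stop("crucial_pathways needs a non-empty key-gene set")
  edges <- if (is.data.frame(gene_pathway_map)) gene_pathway_map else gene_pathway_map$edges
  per_gene <- lapply(key_genes, function(g) edges$pathway[edges$gene == g])
  out <- sort(Reduce(intersect, per_gene))
  if (length(out) == 0) warning("no pathway contains every key gene")
  out
}
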