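#' Differential-expression screen (Welch t + BH)
#'
#' Per-gene Welch two-sample t-test between tumor and normal columns of a
#' log2-scale matrix, BH FDR across genes, and the selection rule
#' `|log2FC| > 1 & FDR < 0.05`. `log2fc` is mean(tumor) - mean(normal).
#' Constant rows get p = 1 with a warning rather than NaN.
#'
#' @param study an `expression_study`; raw-scale studies are log2-transformed
#'   first.
#' @param lfc_cut,fdr_cut selection thresholds.
#' @return data.frame: `gene`, `log2fc`, `p`, `fdr`, `direction`
#'   (up/down/none), `selected`.
#' @export
de_test <- function(study, lfc_cut = 1, fdr_cut = 0.05) {
  vals <- study$values
  if (!study$log2) vals <- log2_transform(vals)
  tum <- vals[, study$group == "tumor", drop = FALSE]
  nor <- vals[, study$group == "normal", drop = FALSE]
  if (ncol(tum) < 2 || ncol(nor) < 2) stop("need at least 2 samples per group")
  n1 <- ncol(tum); n2 <- ncol(nor)
  v1 <- .row_vars(tum); v2 <- .row_vars(nor)
  lfc <- rowMeans(tum) - rowMeans(nor)
  se2 <- v1 / n1 + v2 / n2
  const <- se2 == 0
  if (any(const)) warning(sum(const), " constant gene row(s): p set to 1")
  tstat <- ifelse(const, 0, lfc / sqrt(pmax(se2, .Machine$double.xmin)))
  df <- ifelse(const, 1,
               se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1)))
  p <- ifelse(const, 1, 2 * stats::pt(-abs(tstat), df))
  fdr <- stats::p.adjust(p, "BH")
  selected <- abs(lfc) > lfc_cut & fdr < fdr_cut
  direction <- ifelse(!selected, "none", ifelse(lfc > 0, "up", "down"))
  data.frame(gene = rownames(vals), log2fc = lfc, p = p, fdr = fdr,
             direction = direction, selected = selected,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Multi-database vote filter for predicted targets
#'
#' Keeps genes predicted by at least `min_db` databases ("overlapping in at
#' least five databases" by default).
#'
#' @param votes 0/1 matrix, genes x databases.
#' @param min_db minimum vote count (default 5).
#' @return character vector of gene names passing the filter.
#' @export
vote_filter <- function(votes, min_db = 5L) {
  stopifnot(min_db >= 1)
  counts <- rowSums(votes)
  rownames(votes)[counts >= min_db]
}

#' Intersect selected DEGs with predicted targets
#'
#' @param degs a [de_test()] table.
#' @param predicted character vector of predicted target genes.
#' @return list `candidates`, plus Venn counts `n_deg_only`, `n_pred_only`,
#'   `n_both`. Warns on an empty intersection.
#' @export
intersect_candidates <- function(degs, predicted) {
  sel <- degs$gene[degs$selected]
  both <- intersect(sel, predicted)
  if (length(both) == 0) warning("empty candidate set: DEGs and predictions do not overlap")
  list(candidates = sort(both),
       n_deg_only = length(setdiff(sel, predicted)),
       n_pred_only = length(setdiff(predicted, sel)),
       n_both = length(both))
}

#' Clinical association battery for the marker
#'
#' One test per clinical item: Kruskal-Wallis for multi-class factors,
#' Wilcoxon rank-sum for binary factors (normal approximation with tie
#' correction), Spearman correlation for continuous covariates, and a Cox
#' proportional-hazards model (Efron ties, Wald test) for overall survival.
#' BH FDR is applied across the battery and rows are sorted by p. The
#' reported statistic is the Kruskal-Wallis chi-square, the Spearman rho,
#' the Wilcoxon rank-biserial correlation, or the Cox coefficient.
#'
#' @param marker_expression per-sample marker values.
#' @param clinical data.frame of covariates, same sample order, with
#'   attribute `assoc_types` naming each item's test (as produced by
#'   [gen_clinical()]); survival items use columns `os_time`/`os_status`.
#' @return data.frame: `item`, `method`, `statistic`, `p`, `fdr`.
#' @export
clinical_assoc <- function(marker_expression, clinical) {
  types <- attr(clinical, "assoc_types")
  if (is.null(types)) stop("clinical table must carry an 'assoc_types' attribute")
  rows <- list()
  for (item in names(types)) {
    method <- types[[item]]
    res <- tryCatch(switch(
      method,
      kruskal_wallis = {
        f <- droplevels(factor(clinical[[item]]))
        if (nlevels(f) < 2) stop("single level")
        kt <- stats::kruskal.test(marker_expression, f)
        c(unname(kt$statistic), kt$p.value)
      },
      spearman = {
        ct <- suppressWarnings(
          stats::cor.test(marker_expression, clinical[[item]], method = "spearman"))
        c(unname(ct$estimate), ct$p.value)
      },
      wilcoxon = {
        f <- droplevels(factor(clinical[[item]]))
        if (nlevels(f) != 2) stop("needs exactly 2 levels")
        x <- marker_expression[f == levels(f)[1]]
        y <- marker_expression[f == levels(f)[2]]
        wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE))
        rb <- 2 * unname(wt$statistic) / (length(x) * length(y)) - 1
        c(rb, wt$p.value)
      },
      cox = {
        fit <- survival::coxph(
          survival::Surv(clinical$os_time, clinical$os_status) ~ marker_expression,
          ties = "efron")
        sm <- summary(fit)$coefficients
        c(sm[1, "coef"], sm[1, "Pr(>|z|)"])
      },
      stop("unknown method: ", method)
    ), error = function(e) e)
    if (inherits(res, "error")) {
      warning("skipping clinical item '", item, "': ", conditionMessage(res))
      next
    }
    rows[[item]] <- data.frame(item = item, method = method,
                               statistic = res[1], p = res[2],
                               stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) {
    return(data.frame(item = character(0), method = character(0),
                      statistic = numeric(0), p = numeric(0), fdr = numeric(0)))
  }
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p, "BH")
  out <- out[order(out$p), ]
  rownames(out) <- NULL
  out
}
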