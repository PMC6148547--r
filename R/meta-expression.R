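#' Log2-transform a non-negative expression matrix
#'
#' @param x numeric matrix or vector, all values non-negative.
#' @param offset pseudo-count added before taking log2 (default 1).
#' @return `log2(x + offset)` with dimensions preserved.
#' @export
log2_transform <- function(x, offset = 1) {
  if (any(x < 0, na.rm = TRUE)) {
    stop("domain error: log2_transform requires non-negative input")
  }
  log2(x + offset)
}

#' Hedges g standardized mean difference for one study
#'
#' Cohen d on the pooled SD, corrected for small-sample bias:
#' `J = 1 - 3 / (4 (n_t + n_n - 2) - 1)`, `g = J d`, with sampling variance
#' `var_g = (n_t + n_n) / (n_t n_n) + g^2 / (2 (n_t + n_n))`.
#'
#' @param tumor_values,normal_values numeric vectors (log2 scale), length
#'   at least 2 each.
#' @param study_id,subgroup optional labels carried through to pooling.
#' @return one-row data.frame (`study_id`, `g`, `var_g`, `n_tumor`,
#'   `n_normal`, `subgroup`).
#' @export
compute_smd <- function(tumor_values, normal_values, study_id = "study",
                        subgroup = NA_character_) {
  n_t <- length(tumor_values)
  n_n <- length(normal_values)
  if (n_t < 2 || n_n < 2) stop("need at least 2 values per group")
  s2 <- ((n_t - 1) * stats::var(tumor_values) +
           (n_n - 1) * stats::var(normal_values)) / (n_t + n_n - 2)
  if (s2 <= 0) stop("degenerate-variance error: pooled SD is zero")
  d <- (mean(tumor_values) - mean(normal_values)) / sqrt(s2)
  J <- 1 - 3 / (4 * (n_t + n_n - 2) - 1)
  g <- J * d
  var_g <- (n_t + n_n) / (n_t * n_n) + g^2 / (2 * (n_t + n_n))
  data.frame(study_id = study_id, g = g, var_g = var_g,
             n_tumor = n_t, n_normal = n_n, subgroup = subgroup,
             stringsAsFactors = FALSE)
}

#' Per-study marker effects from a list of expression studies
#'
#' Applies the log2 transform to raw-scale studies and computes Hedges g of
#' the marker row for each study.
#'
#' @param studies list of `expression_study` objects.
#' @param marker marker row name.
#' @return data.frame of study effects, one row per study.
#' @export
study_effects <- function(studies, marker = "miR-106b-5p") {
  do.call(rbind, lapply(studies, function(st) {
    vals <- st$values[marker, ]
    if (!st$log2) vals <- log2_transform(vals)
    compute_smd(vals[st$group == "tumor"], vals[st$group == "normal"],
                study_id = st$study_id, subgroup = st$subgroup)
  }))
}

.meta_result <- function(pooled, se, Q, df, tau2, model) {
  I2 <- if (df >= 1 && Q > 0) max(0, (Q - df) / Q) * 100 else 0
  structure(list(pooled = pooled,
                 ci_low = pooled - 1.96 * se, ci_high = pooled + 1.96 * se,
                 se = se, p = 2 * stats::pnorm(-abs(pooled / se)),
                 Q = Q, df = df,
                 p_Q = if (df >= 1) stats::pchisq(Q, df, lower.tail = FALSE) else NA_real_,
                 I2 = I2, tau2 = tau2, model = model),
            class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("<meta_result %s> SMD %.3f [%.3f, %.3f], p = %.4g; Q = %.2f (df %d), I2 = %.1f%%, tau2 = %.3f\n",
              x$model, x$pooled, x$ci_low, x$ci_high, x$p, x$Q, x$df, x$I2, x$tau2))
  invisible(x)
}

#' Fixed-effect (inverse-variance) pooling
#'
#' Weights `w_i = 1/var_i`; pooled effect is the weighted mean, 95% CI uses
#' the normal multiplier 1.96, two-sided normal p.
#'
#' @param effects data.frame with columns `g`, `var_g`.
#' @return a `meta_result` with `model = "fixed"` and `tau2 = 0`.
#' @export
pool_fixed <- function(effects) {
  if (nrow(effects) < 1) stop("pool_fixed needs at least one study")
  w <- 1 / effects$var_g
  pooled <- sum(w * effects$g) / sum(w)
  Q <- sum(w * (effects$g - pooled)^2)
  .meta_result(pooled, 1 / sqrt(sum(w)), Q, nrow(effects) - 1L, 0, "fixed")
}

#' Random-effects (DerSimonian-Laird) pooling
#'
#' Between-study variance `tau2 = max(0, (Q - df) / (sum(w) - sum(w^2)/sum(w)))`
#' with fixed-model weights, then inverse-variance pooling with weights
#' `1 / (var_i + tau2)`.
#'
#' @param effects data.frame with columns `g`, `var_g`.
#' @return a `meta_result` with `model = "random"`.
#' @export
pool_random <- function(effects) {
  if (nrow(effects) < 2) stop("pool_random needs at least two studies")
  w <- 1 / effects$var_g
  fixed <- pool_fixed(effects)
  C <- sum(w) - sum(w^2) / sum(w)
  tau2 <- max(0, (fixed$Q - fixed$df) / C)
  ws <- 1 / (effects$var_g + tau2)
  pooled <- sum(ws * effects$g) / sum(ws)
  .meta_result(pooled, 1 / sqrt(sum(ws)), fixed$Q, fixed$df, tau2, "random")
}

#' Heterogeneity statistics
#'
#' Cochran Q against the fixed-effect pooled value, chi-square p with
#' `k - 1` df, and `I2 = max(0, (Q - df)/Q) * 100` (percent scale).
#'
#' @param effects data.frame with columns `g`, `var_g`.
#' @return list `Q`, `df`, `p_Q`, `I2`.
#' @export
heterogeneity <- function(effects) {
  if (nrow(effects) < 2) stop("heterogeneity needs at least two studies")
  fixed <- pool_fixed(effects)
  list(Q = fixed$Q, df = fixed$df, p_Q = fixed$p_Q, I2 = fixed$I2)
}

#' Heterogeneity-driven model selection
#'
#' Random effects when the heterogeneity is significant (`p_Q < 0.05`) or
#' `I2 > 50` (strict inequalities); fixed otherwise.
#'
#' @param p_Q heterogeneity p-value.
#' @param I2 I-squared on the percent scale.
#' @return `"random"` or `"fixed"`.
#' @export
select_model <- function(p_Q, I2) {
  if (p_Q < 0.05 || I2 > 50) "random" else "fixed"
}

#' Egger regression test for funnel-plot asymmetry
#'
#' Regresses the standardized effect `g/SE` on precision `1/SE`; the
#' intercept is tested against zero with a t reference on `k - 2` df.
#' Significant asymmetry is declared strictly below 0.1.
#'
#' @param effects data.frame with columns `g`, `var_g`.
#' @return list `intercept`, `se_intercept`, `t`, `df`, `p`, `significant`.
#' @export
egger_test <- function(effects) {
  if (nrow(effects) < 3) stop("insufficient-studies error: Egger test needs at least 3 studies")
  se <- sqrt(effects$var_g)
  fit <- stats::lm(I(effects$g / se) ~ I(1 / se))
  sm <- summary(fit)$coefficients
  list(intercept = sm[1, 1], se_intercept = sm[1, 2], t = sm[1, 3],
       df = nrow(effects) - 2L, p = sm[1, 4], significant = sm[1, 4] < 0.1)
}

#' Leave-one-out influence analysis
#'
#' Re-pools after omitting each study in turn. An omission is flagged when
#' the full-analysis point estimate falls outside the omitted-analysis CI,
#' or when significance at 0.05 flips.
#'
#' @param effects data.frame with columns `study_id`, `g`, `var_g`.
#' @param model `"auto"` (re-select by heterogeneity per subset), `"fixed"`
#'   or `"random"`.
#' @return data.frame: `omitted_study`, pooled/CI/p of each re-analysis, and
#'   `flagged`; attribute `any_flagged`.
#' @export
influence_loo <- function(effects, model = c("auto", "fixed", "random")) {
  model <- match.arg(model)
  k <- nrow(effects)
  if (k < 3) stop("influence analysis needs at least 3 studies")
  full <- .pool_by_rule(effects, model)
  rows <- lapply(seq_len(k), function(i) {
    res <- .pool_by_rule(effects[-i, , drop = FALSE], model)
    flagged <- (full$pooled < res$ci_low || full$pooled > res$ci_high) ||
      ((full$p < 0.05) != (res$p < 0.05))
    data.frame(omitted_study = effects$study_id[i], pooled = res$pooled,
               ci_low = res$ci_low, ci_high = res$ci_high, p = res$p,
               model = res$model, flagged = flagged, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "any_flagged") <- any(out$flagged)
  attr(out, "full") <- full
  out
}

.pool_by_rule <- function(effects, model) {
  if (nrow(effects) == 1) {
    return(.meta_result(effects$g[1], sqrt(effects$var_g[1]), 0, 0L, 0, "fixed"))
  }
  if (model == "fixed") return(pool_fixed(effects))
  if (model == "random") return(pool_random(effects))
  het <- heterogeneity(effects)
  if (select_model(het$p_Q, het$I2) == "random") pool_random(effects) else pool_fixed(effects)
}

#' Fixed/random sensitivity comparison
#'
#' Computes both models and reports whether they agree in significance and
#' direction at the 0.05 level.
#'
#' @param effects data.frame with columns `g`, `var_g`.
#' @return list `fixed`, `random`, `consistent`.
#' @export
sensitivity_switch <- function(effects) {
  if (nrow(effects) < 2) stop("sensitivity analysis needs at least two studies")
  fx <- pool_fixed(effects)
  rd <- pool_random(effects)
  consistent <- ((fx$p < 0.05) == (rd$p < 0.05)) &&
    (sign(fx$pooled) == sign(rd$pooled))
  list(fixed = fx, random = rd, consistent = consistent)
}

#' Subgroup meta-analysis
#'
#' Pools within each subgroup with the heterogeneity-selected model
#' (single-study subgroups pass through as fixed with a warning), and
#' reports per-subgroup and overall heterogeneity.
#'
#' @param effects data.frame of study effects.
#' @param labels subgroup labels; defaults to `effects$subgroup`.
#' @return named list of per-subgroup `meta_result`s with attribute
#'   `overall_I2`.
#' @export
subgroup_pool <- function(effects, labels = effects$subgroup) {
  if (any(is.na(labels))) stop("every effect must carry a subgroup label")
  out <- lapply(split(effects, labels), function(sub) {
    if (nrow(sub) == 1) {
      warning("subgroup with a single study: fixed passthrough")
      return(.pool_by_rule(sub, "auto"))
    }
    .pool_by_rule(sub, "auto")
  })
  attr(out, "overall_I2") <- heterogeneity(effects)$I2
  out
}
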