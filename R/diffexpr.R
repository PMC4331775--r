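# Per-gene two-group linear models, empirical-Bayes variance moderation,
# moderated t-statistics and Benjamini-Hochberg adjustment.

# The three pairwise comparisons of the design; the first label is the
# treatment group, the second the reference, so log2FC = mean(trt) - mean(ref).
COMPARISONS <- list(
  cx_vs_sham = c(trt = "cx",   ref = "sham"),
  T_vs_cx    = c(trt = "cx_T", ref = "cx"),
  F_vs_cx    = c(trt = "cx_F", ref = "cx"))

#' Per-gene two-group linear fit
#'
#' For each gene, estimates the log2 fold change as the difference of group
#' means, the pooled within-group residual variance, the unscaled standard
#' deviation sqrt(1/n1 + 1/n2) and the residual degrees of freedom
#' n1 + n2 - 2, within one tissue.
#'
#' @param expr genes x samples log2 matrix.
#' @param samples sample metadata (`sample_id`, `tissue`, `condition`).
#' @param tissue tissue to analyse; comparisons are never pooled across
#'   tissues.
#' @param comparison one of `"cx_vs_sham"`, `"T_vs_cx"`, `"F_vs_cx"`, or a
#'   named `c(trt=, ref=)` pair of condition labels.
#' @return data.frame: gene_id, log2fc, s2 (pooled variance), u (unscaled
#'   sd), df.
#' @export
fit_per_gene <- function(expr, samples, tissue, comparison) {
  if (is.character(comparison) && length(comparison) == 1L) {
    if (!comparison %in% names(COMPARISONS))
      stop_input("unknown comparison '", comparison, "'")
    comparison <- COMPARISONS[[comparison]]
  }
  sel <- function(cond) {
    ids <- samples$sample_id[samples$tissue == tissue &
                               samples$condition == cond]
    if (length(ids) < 2L)
      stop_input("condition '", cond, "' needs >= 2 replicates in tissue '",
                 tissue, "'")
    expr[, ids, drop = FALSE]
  }
  x1 <- sel(comparison[["trt"]])
  x0 <- sel(comparison[["ref"]])
  n1 <- ncol(x1); n0 <- ncol(x0)
  m1 <- rowMeans(x1); m0 <- rowMeans(x0)
  ss <- rowSums((x1 - m1)^2) + rowSums((x0 - m0)^2)
  df <- n1 + n0 - 2L
  data.frame(gene_id = rownames(expr),
             log2fc = m1 - m0,
             s2 = ss / df,
             u = sqrt(1 / n1 + 1 / n0),
             df = df,
             row.names = NULL, stringsAsFactors = FALSE)
}

# Newton solve of trigamma(y) = x, x > 0 (monotone decreasing, convex).
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2L)
    y <- y + dif
    if (abs(dif) < 1e-10 * y) break
  }
  y
}

#' Estimate the variance-moderation prior
#'
#' Fits a scaled inverse-chi-square prior (df d0, scale s0^2) to the sample
#' variances by matching the mean and variance of log s^2 through digamma /
#' trigamma identities. Genes with zero residual df or zero variance carry no
#' information and are excluded. When the spread of log s^2 is no larger than
#' sampling alone implies, the prior df is +Inf (a point prior).
#'
#' @param fits output of [fit_per_gene()] (needs `s2`, `df`), or any
#'   data.frame with those columns.
#' @return list with `d0` (prior df, possibly `Inf`) and `s02` (prior
#'   scale).
#' @export
estimate_moderation <- function(fits) {
  keep <- fits$df >= 1L & fits$s2 > 0 & is.finite(fits$s2)
  s2 <- fits$s2[keep]
  d <- fits$df[keep]
  if (length(s2) < 2L) {
    if (all(fits$s2 == 0))  # noise-free data: a point prior at zero variance
      return(list(d0 = Inf, s02 = 0))
    stop_input("need >= 2 genes with positive variance and df >= 1")
  }
  if (max(s2) - min(s2) == 0)
    return(list(d0 = Inf, s02 = s2[1L]))
  e <- log(s2) - digamma(d / 2) + log(d / 2)
  evar <- stats::var(e) - mean(trigamma(d / 2))
  if (evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s02 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s02 <- exp(mean(e))
  }
  list(d0 = d0, s02 = s02)
}

#' Moderated t-statistics and p-values
#'
#' Shrinks each gene's variance toward the prior,
#' s2_post = (d0 s0^2 + df s^2) / (d0 + df), forms t = log2fc / (u *
#' sqrt(s2_post)) and a two-sided p-value from the t-distribution with
#' d0 + df degrees of freedom (standard normal when d0 is infinite).
#'
#' @param fits output of [fit_per_gene()].
#' @param params list with `d0`, `s02` from [estimate_moderation()], or
#'   `d0 = 0` for no moderation.
#' @return `fits` with added columns `t_mod`, `p`.
#' @export
moderated_t <- function(fits, params) {
  if (any(fits$u <= 0)) stop_input("unscaled sd u must be positive")
  d0 <- params$d0; s02 <- params$s02
  if (is.infinite(d0)) {
    s2_post <- rep(s02, nrow(fits))
    p <- 2 * stats::pnorm(-abs(fits$log2fc / (fits$u * sqrt(s2_post))))
  } else {
    s2_post <- (d0 * s02 + fits$df * fits$s2) / (d0 + fits$df)
    tt <- fits$log2fc / (fits$u * sqrt(s2_post))
    p <- 2 * stats::pt(-abs(tt), df = d0 + fits$df)
  }
  fits$t_mod <- fits$log2fc / (fits$u * sqrt(s2_post))
  fits$p <- p
  if (any(s2_post == 0)) {
    # degenerate noise-free limit: any nonzero effect is certain
    z <- s2_post == 0
    fits$t_mod[z] <- ifelse(fits$log2fc[z] == 0, 0,
                            sign(fits$log2fc[z]) * Inf)
    fits$p[z] <- ifelse(fits$log2fc[z] == 0, 1, 0)
  }
  fits
}

#' Benjamini-Hochberg adjusted p-values (q-values)
#'
#' Step-up adjustment q_(i) = min_{j >= i} min(1, p_(j) * n / j), returned in
#' input order. These adjusted p-values are what the classification rule
#' thresholds as q-values.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return Adjusted values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop_input("p-values must be finite and in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Run the three contrasts for one tissue
#'
#' Fits each comparison, estimates its own moderation prior, computes
#' moderated t p-values and BH q-values.
#'
#' @inheritParams fit_per_gene
#' @param comparisons character vector of comparison labels (default all
#'   three).
#' @return Named list of per-comparison data.frames: gene_id, log2fc, t_mod,
#'   p, q.
#' @export
run_differential_expression <- function(expr, samples, tissue,
                                        comparisons = names(COMPARISONS)) {
  out <- lapply(comparisons, function(cmp) {
    fits <- fit_per_gene(expr, samples, tissue, cmp)
    res <- moderated_t(fits, estimate_moderation(fits))
    res$q <- bh_adjust(res$p)
    res$comparison <- cmp
    res$tissue <- tissue
    res[, c("gene_id", "tissue", "comparison", "log2fc", "t_mod", "p", "q")]
  })
  stats::setNames(out, comparisons)
}
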