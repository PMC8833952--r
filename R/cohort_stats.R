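#' Kruskal-Wallis rank test
#'
#' H statistic on mid-ranks with the standard tie correction and a
#' chi-squared upper-tail p-value on k-1 degrees of freedom. Implemented
#' directly (not delegated) so the package's multigroup testing is
#' self-contained and auditable.
#'
#' @param x numeric vector of observations.
#' @param g group labels (factor or vector), same length as \code{x}.
#' @return list with \code{H}, \code{p} and \code{df}.
#' @export
kruskal_wallis <- function(x, g) {
  g <- as.factor(as.vector(g))
  g <- droplevels(g)
  if (length(x) != length(g)) .stopf("kruskal_wallis: length mismatch")
  k <- nlevels(g)
  n <- length(x)
  if (k < 2L) .stopf("kruskal_wallis: need >= 2 groups")
  r <- rank(x)
  N1 <- n + 1
  H <- 12 / (n * N1) * sum(tapply(r, g, function(ri) {
    length(ri) * (mean(ri) - N1 / 2)^2
  }))
  ties <- table(x)
  tie_corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (tie_corr == 0) {
    # all observations identical: no evidence against the null
    return(list(H = 0, p = 1, df = k - 1L))
  }
  H <- H / tie_corr
  list(H = H, p = stats::pchisq(H, df = k - 1L, lower.tail = FALSE),
       df = k - 1L)
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' \code{q_i = min_{j >= i} p_(j) * m / j} on the ascending order
#' statistics, returned in input order and capped at 1.
#'
#' @param pvals numeric vector of p-values in [0, 1].
#' @return numeric vector of adjusted values (FDRs), same order as input.
#' @export
bh_adjust <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) {
    .stopf("bh_adjust: p-values outside [0, 1]")
  }
  m <- length(pvals)
  if (m == 0L) return(numeric())
  ord <- order(pvals)
  q <- pvals[ord] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[ord] <- q
  out
}

#' Six-trend classification of four-group expression profiles
#'
#' Classifies the 4-tuple of group geometric means (W normal, W tumor,
#' B/AA normal, B/AA tumor) into one of six trends, evaluated in
#' precedence order: strictly monotonic increasing or decreasing along the
#' four groups first; otherwise per-race tumor-vs-normal direction
#' (up/down in both races, or opposite directions). Any within-race
#' equality leaves the profile UNCLASSIFIED, since the trend taxonomy
#' leaves ties undefined.
#'
#' @param g numeric vector of length 4: \code{(g_WN, g_WT, g_BN, g_BT)},
#'   all >= 0.
#' @return one of \code{MONOTONIC_INC, MONOTONIC_DEC, UP_BOTH, DOWN_BOTH,
#'   UP_W_DOWN_BAA, DOWN_W_UP_BAA, UNCLASSIFIED}.
#' @export
classify_trend <- function(g) {
  stopifnot(length(g) == 4L)
  if (any(g < 0)) .stopf("classify_trend: negative geometric mean")
  wn <- g[1L]; wt <- g[2L]; bn <- g[3L]; bt <- g[4L]
  if (wn < wt && wt < bn && bn < bt) return("MONOTONIC_INC")
  if (wn > wt && wt > bn && bn > bt) return("MONOTONIC_DEC")
  if (wt == wn || bt == bn) return("UNCLASSIFIED")
  w_up <- wt > wn
  b_up <- bt > bn
  if (w_up && b_up) return("UP_BOTH")
  if (!w_up && !b_up) return("DOWN_BOTH")
  if (w_up) "UP_W_DOWN_BAA" else "DOWN_W_UP_BAA"
}

#' Four-group differential isomiR analysis
#'
#' For each feature of a jointly TMM-normalized count matrix: group
#' geometric means of normalized CPM, Kruskal-Wallis test across the four
#' groups, Benjamini-Hochberg FDR across features, and a six-trend label
#' for features significant at \code{fdr < alpha} (others are labeled
#' UNCLASSIFIED). The table is sorted by FDR.
#'
#' @param m a \code{\link{count_matrix}} (expression-filtered; TMM factors
#'   are computed across all samples jointly if unset).
#' @param design group factor with levels \code{W_N, W_T, BAA_N, BAA_T}
#'   (one entry per sample column).
#' @param alpha FDR significance threshold (default 0.05).
#' @return data.frame: \code{isomir, g_WN, g_WT, g_BAAN, g_BAAT, H, p,
#'   fdr, trend}.
#' @export
differential_isomirs <- function(m, design, alpha = 0.05) {
  m <- .as_count_matrix(m)
  design <- factor(as.vector(design), levels = c("W_N", "W_T", "BAA_N", "BAA_T"))
  if (anyNA(design)) .stopf("differential_isomirs: design must use groups W_N, W_T, BAA_N, BAA_T")
  if (length(design) != ncol(m$counts)) .stopf("differential_isomirs: design length mismatch")
  small <- names(which(table(design) < 2L))
  if (length(small)) {
    .warnf("differential_isomirs: group(s) with < 2 samples: %s",
           paste(small, collapse = ", "))
  }
  if (all(m$norm_factors == 1)) m <- tmm_normalize(m)
  expr <- normalized_cpm(m)
  gm <- vapply(levels(design), function(g) {
    .row_geom_means(expr[, design == g, drop = FALSE])
  }, numeric(nrow(expr)))
  if (is.null(dim(gm))) gm <- matrix(gm, nrow = 1L, dimnames = list(rownames(expr), levels(design)))
  kw <- apply(expr, 1L, function(x) {
    r <- kruskal_wallis(x, design)
    c(r$H, r$p)
  })
  H <- kw[1L, ]; p <- kw[2L, ]
  fdr <- bh_adjust(p)
  trend <- rep("UNCLASSIFIED", nrow(expr))
  sig <- fdr < alpha
  trend[sig] <- apply(gm[sig, , drop = FALSE], 1L, classify_trend)
  out <- data.frame(isomir = rownames(expr),
                    g_WN = gm[, "W_N"], g_WT = gm[, "W_T"],
                    g_BAAN = gm[, "BAA_N"], g_BAAT = gm[, "BAA_T"],
                    H = H, p = p, fdr = fdr, trend = trend,
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(out$fdr, out$p, out$isomir), , drop = FALSE]
}
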