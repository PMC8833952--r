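#' Quartile stratification of samples by one feature's expression
#'
#' Splits samples into a low group (expression at or below the first
#' quartile) and a high group (at or above the third quartile), with cuts
#' from the linear-interpolation quantile definition (R type 7). Boundary
#' samples are included (<= Q1 / >= Q3).
#'
#' @param expr named numeric vector of per-sample expression (>= 8
#'   samples).
#' @return list of class \code{quartile_split}: \code{q1_samples,
#'   q3_samples, q1_cut, q3_cut}.
#' @export
quartile_groups <- function(expr) {
  if (is.null(names(expr))) .stopf("quartile_groups: expr must be named by sample")
  if (length(expr) < 8L) .stopf("quartile_groups: need >= 8 samples")
  if (max(expr) == min(expr)) .stopf("quartile_groups: all values identical; split undefined")
  q1 <- unname(stats::quantile(expr, 0.25, type = 7))
  q3 <- unname(stats::quantile(expr, 0.75, type = 7))
  q1s <- names(expr)[expr <= q1]
  q3s <- names(expr)[expr >= q3]
  if (length(intersect(q1s, q3s))) {
    .stopf("quartile_groups: quartile groups overlap (near-constant expression)")
  }
  structure(list(q1_samples = q1s, q3_samples = q3s,
                 q1_cut = q1, q3_cut = q3),
            class = "quartile_split")
}

#' FPKM geometric-mean gene filter
#'
#' Keeps genes with \code{floor(geometric mean FPKM) > 1} across the
#' scoped samples; same contract as \code{\link{expression_filter}} with
#' FPKM in place of RPM (zeros annihilate the geometric mean).
#'
#' @param fpkm numeric matrix, genes x samples.
#' @param scope optional sample subset.
#' @return character vector of kept gene ids.
#' @export
filter_genes_fpkm <- function(fpkm, scope = NULL) {
  if (is.null(rownames(fpkm))) .stopf("filter_genes_fpkm: fpkm needs rownames")
  if (!is.null(scope)) fpkm <- fpkm[, scope, drop = FALSE]
  gm <- .row_geom_means(fpkm)
  rownames(fpkm)[floor(gm) > 1]
}

#' Negative-binomial exact test for two groups of counts
#'
#' Two-sided exact test of equal means, conditional on the pooled sum:
#' under a common NB dispersion the group sums are NB distributed and the
#' conditional distribution of one group's sum given the total is
#' evaluated exactly; the p-value sums the probabilities of all outcomes
#' no more likely than the observed one. With dispersion 0 the NB
#' degenerates to Poisson and the test reduces to the exact binomial test.
#' When \code{dispersion} is NULL, a pooled method-of-moments estimate is
#' used: \code{max(0, (pooled within-group variance - mean) / mean^2)}.
#'
#' @param counts_g1,counts_g2 non-negative integer count vectors.
#' @param dispersion common NB dispersion (>= 0), or NULL to estimate.
#' @return two-sided p-value.
#' @export
nb_exact_test <- function(counts_g1, counts_g2, dispersion = NULL) {
  if (any(c(counts_g1, counts_g2) < 0)) .stopf("nb_exact_test: negative counts")
  n1 <- length(counts_g1); n2 <- length(counts_g2)
  if (n1 == 0L || n2 == 0L) .stopf("nb_exact_test: empty group")
  s1 <- sum(counts_g1); s2 <- sum(counts_g2)
  s <- s1 + s2
  if (s == 0) return(1)
  if (is.null(dispersion)) {
    mu <- s / (n1 + n2)
    df <- n1 + n2 - 2L
    v <- if (df > 0) {
      ((n1 - 1) * stats::var(counts_g1) + (n2 - 1) * stats::var(counts_g2)) / df
    } else 0
    dispersion <- max(0, (v - mu) / mu^2)
  }
  if (dispersion < 0) .stopf("nb_exact_test: dispersion must be >= 0")
  x <- 0:s
  logp <- if (dispersion == 0) {
    stats::dbinom(x, s, n1 / (n1 + n2), log = TRUE)
  } else {
    mu <- s / (n1 + n2)
    stats::dnbinom(x, size = n1 / dispersion, mu = n1 * mu, log = TRUE) +
      stats::dnbinom(s - x, size = n2 / dispersion, mu = n2 * mu, log = TRUE)
  }
  logp <- logp - max(logp)
  pr <- exp(logp)
  pr <- pr / sum(pr)
  obs <- pr[s1 + 1L]
  min(1, sum(pr[pr <= obs * (1 + 1e-8)]))
}

#' Gene-level differential expression between quartile groups
#'
#' Compares the Q1 (low) and Q3 (high) sample groups of a
#' \code{\link{quartile_groups}} split. Counts are TMM-normalized within
#' the Q1 union Q3 subset and scaled to a common (geometric-mean
#' effective) library size; each gene is tested with
#' \code{\link{nb_exact_test}} (per-gene method-of-moments dispersion
#' unless supplied). Fold changes are ratios of normalized group means
#' with pseudocount 1, reported as signed linear fold change (magnitude
#' >= 1, sign = direction of Q3 relative to Q1). A gene is significant
#' iff \code{p < 0.01} and \code{|linearFC| > 1.5}.
#'
#' @param gene_counts a \code{\link{count_matrix}} of raw gene counts
#'   (FPKM-filtered upstream).
#' @param split a \code{quartile_split}.
#' @param dispersion optional common dispersion for all genes.
#' @return data.frame: \code{gene, log2FC, linearFC, p, significant}.
#' @export
differential_genes <- function(gene_counts, split, dispersion = NULL) {
  stopifnot(inherits(split, "quartile_split"))
  m <- .as_count_matrix(gene_counts)
  q1 <- intersect(split$q1_samples, colnames(m$counts))
  q3 <- intersect(split$q3_samples, colnames(m$counts))
  if (!length(q1) || !length(q3)) .stopf("differential_genes: empty Q1 or Q3 group")
  sub <- count_matrix(m$counts[, c(q1, q3), drop = FALSE])
  sub <- tmm_normalize(sub)
  eff <- sub$lib_sizes * sub$norm_factors
  common <- exp(mean(log(eff)))
  pseudo <- round(sweep(sub$counts, 2L, eff, "/") * common)
  g1 <- pseudo[, q1, drop = FALSE]
  g2 <- pseudo[, q3, drop = FALSE]
  p <- vapply(seq_len(nrow(pseudo)), function(i) {
    nb_exact_test(g1[i, ], g2[i, ], dispersion)
  }, 0)
  m1 <- rowMeans(g1); m2 <- rowMeans(g2)
  ratio <- (m2 + 1) / (m1 + 1)
  linearFC <- ifelse(ratio >= 1, ratio, -1 / ratio)
  data.frame(gene = rownames(pseudo), log2FC = log2(ratio),
             linearFC = linearFC, p = p,
             significant = p < 0.01 & abs(linearFC) > 1.5,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Correlation between two expression vectors
#'
#' Pearson or Spearman correlation with a two-sided p-value from the t
#' approximation \code{t = r * sqrt((n - 2) / (1 - r^2))} on \code{n - 2}
#' degrees of freedom (applied to the rank correlation for Spearman).
#'
#' @param x,y paired numeric vectors (>= 3 samples).
#' @param method "pearson" (default) or "spearman".
#' @return list with \code{r} and \code{p}.
#' @export
correlate_expression <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y)) .stopf("correlate_expression: length mismatch")
  n <- length(x)
  if (n < 3L) .stopf("correlate_expression: need >= 3 paired samples")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    .stopf("correlate_expression: zero variance")
  }
  if (method == "spearman") { x <- rank(x); y <- rank(y) }
  r <- stats::cor(x, y)
  p <- if (abs(r) >= 1) 0 else {
    tt <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tt), df = n - 2)
  }
  list(r = r, p = p)
}

#' Hypergeometric over-representation analysis
#'
#' Open substitute for commercial pathway tools: for each gene set, the
#' upper-tail hypergeometric probability of observing at least the
#' attained overlap between the differentially expressed genes and the
#' set, given the universe; Benjamini-Hochberg adjustment across sets.
#'
#' @param de_genes character vector of DE genes (must be contained in
#'   \code{universe}).
#' @param universe character vector of all tested genes.
#' @param gene_sets named list of character vectors.
#' @return data.frame: \code{set, overlap, size, p, fdr}, sorted by p.
#' @export
ora_enrichment <- function(de_genes, universe, gene_sets) {
  universe <- unique(universe)
  if (!length(universe)) .stopf("ora_enrichment: empty universe")
  if (!all(de_genes %in% universe)) {
    .stopf("ora_enrichment: de_genes must be a subset of the universe")
  }
  de_genes <- unique(de_genes)
  N <- length(universe); n <- length(de_genes)
  res <- lapply(names(gene_sets), function(nm) {
    set <- intersect(unique(gene_sets[[nm]]), universe)
    K <- length(set)
    k <- length(intersect(de_genes, set))
    p <- if (K == 0L) 1 else stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, overlap = k, size = K, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$fdr <- bh_adjust(out$p)
  out[order(out$p, out$set), , drop = FALSE]
}

#' Read a gene-set file (set name TAB comma-separated genes)
#' @param path TSV-like file, no header: \code{set\tgene1,gene2,...}.
#' @return named list of character vectors.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 2L)) .stopf("malformed gene-set file: %s", path)
  sets <- lapply(parts, function(p) strsplit(p[2L], ",", fixed = TRUE)[[1L]])
  names(sets) <- vapply(parts, `[`, "", 1L)
  sets
}
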