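#' Count matrix container
#'
#' Thin S3 wrapper around a non-negative integer matrix (features x
#' samples) carrying per-sample library sizes (column sums) and TMM
#' normalization factors (default 1).
#'
#' @param counts numeric matrix, rows = isomiRs or genes, columns =
#'   samples; must be non-negative and have dimnames.
#' @param norm_factors optional positive per-column factors.
#' @return A \code{count_matrix} object.
#' @export
count_matrix <- function(counts, norm_factors = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    .stopf("count_matrix: counts must have row and column names")
  }
  if (any(counts < 0) || any(is.na(counts))) {
    .stopf("count_matrix: counts must be non-negative and complete")
  }
  if (is.null(norm_factors)) norm_factors <- rep(1, ncol(counts))
  if (any(norm_factors <= 0)) .stopf("count_matrix: norm_factors must be > 0")
  structure(list(counts = counts,
                 lib_sizes = colSums(counts),
                 norm_factors = stats::setNames(norm_factors, colnames(counts))),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d features x %d samples (TMM %s)\n",
              nrow(x$counts), ncol(x$counts),
              if (all(x$norm_factors == 1)) "unset" else "set"))
  invisible(x)
}

.as_count_matrix <- function(m) {
  if (inherits(m, "count_matrix")) m else count_matrix(m)
}

#' Reads-per-million scaling
#'
#' \code{rpm[i,j] = counts[i,j] / lib_size[j] * 1e6}; raw library sizes,
#' no normalization factors. Columns therefore sum to 1e6.
#'
#' @param m a \code{\link{count_matrix}} or plain matrix.
#' @return numeric matrix of RPM values.
#' @export
compute_rpm <- function(m) {
  m <- .as_count_matrix(m)
  if (any(m$lib_sizes == 0)) {
    .stopf("compute_rpm: zero library size for sample(s): %s",
           paste(names(which(m$lib_sizes == 0)), collapse = ", "))
  }
  sweep(m$counts, 2L, m$lib_sizes, "/") * 1e6
}

#' Geometric-mean expression filter
#'
#' A feature is expressed iff \code{floor(geometric mean of its RPM values
#' over the scoped samples) > 1}. The geometric mean uses no pseudocount:
#' a single zero annihilates it, so a feature absent from any scoped
#' sample is dropped.
#'
#' @param m a \code{\link{count_matrix}}.
#' @param scope optional character/integer vector of sample columns
#'   (default: all).
#' @return character vector of kept row ids.
#' @export
expression_filter <- function(m, scope = NULL) {
  m <- .as_count_matrix(m)
  rpm <- compute_rpm(m)
  if (!is.null(scope)) {
    if (length(scope) == 0L) .stopf("expression_filter: empty scope")
    rpm <- rpm[, scope, drop = FALSE]
  }
  gm <- .row_geom_means(rpm)
  rownames(rpm)[floor(gm) > 1]
}

# edgeR-style 75th-percentile-of-CPM reference column choice
.tmm_ref_column <- function(counts, lib_sizes) {
  f75 <- apply(counts, 2L, stats::quantile, probs = 0.75) / lib_sizes
  which.min(abs(f75 - mean(f75)))
}

# pairwise TMM factor of column obs against column ref (published
# estimator: doubly trimmed, inverse-variance weighted mean of M values)
.tmm_pair <- function(obs, ref, lib_obs, lib_ref, trim_M, trim_A,
                      do_weighting = TRUE) {
  M <- log2((obs / lib_obs) / (ref / lib_ref))
  A <- (log2(obs / lib_obs) + log2(ref / lib_ref)) / 2
  v <- (lib_obs - obs) / lib_obs / obs + (lib_ref - ref) / lib_ref / ref
  fin <- is.finite(M) & is.finite(A) & (A > -1e10)
  M <- M[fin]; A <- A[fin]; v <- v[fin]
  if (length(M) == 0L) return(NA_real_)
  if (max(abs(M)) < 1e-6) return(1)
  n <- length(M)
  loM <- floor(n * trim_M) + 1; hiM <- n + 1 - loM
  loA <- floor(n * trim_A) + 1; hiA <- n + 1 - loA
  keep <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
  f <- if (do_weighting) {
    sum(M[keep] / v[keep], na.rm = TRUE) / sum(1 / v[keep], na.rm = TRUE)
  } else {
    mean(M[keep], na.rm = TRUE)
  }
  if (!is.finite(f)) f <- 0
  2^f
}

#' Trimmed mean of M-values normalization factors
#'
#' From-scratch implementation of the published TMM estimator. The
#' reference column is the one whose 75th percentile of scaled counts is
#' closest to the mean across columns; per column, M (log2 expression
#' ratio) and A (average log2 abundance) are computed over features
#' positive in both columns, the top/bottom \code{trim_M} of M and
#' \code{trim_A} of A are removed, and the factor is 2 to the
#' inverse-variance-weighted mean of the remaining M values. Factors are
#' rescaled so their geometric mean is 1.
#'
#' @param m a \code{\link{count_matrix}} (>= 2 columns, each with at least
#'   one positive count).
#' @param trim_M,trim_A two-sided trim fractions (defaults 0.30 / 0.05).
#' @param do_weighting use inverse-variance weights (default TRUE).
#' @return named numeric vector of normalization factors.
#' @export
tmm_factors <- function(m, trim_M = 0.30, trim_A = 0.05, do_weighting = TRUE) {
  m <- .as_count_matrix(m)
  counts <- m$counts
  if (ncol(counts) < 2L) .stopf("tmm_factors: need >= 2 samples")
  if (any(colSums(counts > 0) == 0L)) {
    .stopf("tmm_factors: sample(s) with no positive counts: %s",
           paste(colnames(counts)[colSums(counts > 0) == 0L], collapse = ", "))
  }
  lib <- m$lib_sizes
  ref <- .tmm_ref_column(counts, lib)
  f <- vapply(seq_len(ncol(counts)), function(j) {
    if (sum(counts[, j] > 0) <= 1L) {
      .warnf("tmm_factors: degenerate column '%s' (single positive feature); factor set to 1",
             colnames(counts)[j])
      return(1)
    }
    fj <- .tmm_pair(counts[, j], counts[, ref], lib[j], lib[ref],
                    trim_M, trim_A, do_weighting)
    if (is.na(fj)) 1 else fj
  }, 0)
  f <- f / exp(mean(log(f)))
  stats::setNames(f, colnames(counts))
}

#' Apply TMM factors to a count matrix
#'
#' @param m a \code{\link{count_matrix}}.
#' @param ... passed to \code{\link{tmm_factors}}.
#' @return The matrix with \code{norm_factors} set.
#' @export
tmm_normalize <- function(m, ...) {
  m <- .as_count_matrix(m)
  m$norm_factors <- tmm_factors(m, ...)
  m
}

#' Normalized expression (CPM on effective library sizes)
#'
#' Counts per million computed against effective library sizes
#' (\code{lib_size * norm_factor}); this is the expression unit used by
#' the downstream differential and survival modules. With \code{log =
#' TRUE}, \code{log2(cpm + prior)} is returned.
#'
#' @param m a \code{\link{count_matrix}} (usually TMM-normalized).
#' @param log return log2 values (default FALSE).
#' @param prior pseudocount added before the log (default 1).
#' @return numeric matrix.
#' @export
normalized_cpm <- function(m, log = FALSE, prior = 1) {
  m <- .as_count_matrix(m)
  eff <- m$lib_sizes * m$norm_factors
  if (any(eff == 0)) .stopf("normalized_cpm: zero effective library size")
  cpm <- sweep(m$counts, 2L, eff, "/") * 1e6
  if (log) log2(cpm + prior) else cpm
}

#' Per-group expressed sets and their intersections
#'
#' Runs the geometric-mean expression filter independently within each of
#' the four sample groups (each group is TMM-normalized separately, though
#' the filter itself acts on raw RPM), and reports the per-group expressed
#' sets, the common core, and each group's exclusive set.
#'
#' @param m a \code{\link{count_matrix}} covering all samples.
#' @param design factor or character vector (one entry per column of
#'   \code{m}, named or in column order) giving the group of each sample.
#' @return list with \code{per_group} (named list of kept id vectors),
#'   \code{core} (intersection over groups), \code{exclusive} (named list:
#'   ids expressed in exactly that group) and \code{union}.
#' @export
group_expressed_sets <- function(m, design) {
  m <- .as_count_matrix(m)
  design <- as.factor(design)
  if (length(design) != ncol(m$counts)) {
    .stopf("group_expressed_sets: design length != number of samples")
  }
  if (any(table(design) == 0L)) .stopf("group_expressed_sets: empty group")
  groups <- levels(design)
  per_group <- lapply(groups, function(g) {
    cols <- which(design == g)
    sub <- count_matrix(m$counts[, cols, drop = FALSE])
    if (length(cols) >= 2L) sub <- tmm_normalize(sub)
    expression_filter(sub)
  })
  names(per_group) <- groups
  core <- Reduce(intersect, per_group)
  uni <- Reduce(union, per_group)
  exclusive <- lapply(groups, function(g) {
    others <- unlist(per_group[setdiff(groups, g)], use.names = FALSE)
    setdiff(per_group[[g]], others)
  })
  names(exclusive) <- groups
  list(per_group = per_group, core = core, exclusive = exclusive, union = uni)
}

#' Build an isomiR count matrix from per-sample call tables
#'
#' @param call_tables named list (one annotated call table per sample,
#'   each with a \code{count} column).
#' @return A \code{\link{count_matrix}} with isomiR names as rows.
#' @export
isomir_count_matrix <- function(call_tables) {
  if (!length(call_tables) || is.null(names(call_tables))) {
    .stopf("isomir_count_matrix: need a named list of call tables")
  }
  tallies <- lapply(call_tables, tally_isomirs)
  ids <- sort(unique(unlist(lapply(tallies, names), use.names = FALSE)))
  counts <- vapply(tallies, function(tt) {
    v <- stats::setNames(integer(length(ids)), ids)
    v[names(tt)] <- tt
    v
  }, integer(length(ids)))
  count_matrix(matrix(counts, nrow = length(ids),
                      dimnames = list(ids, names(call_tables))))
}

#' Read / write a count matrix as TSV
#'
#' First column \code{feature_id}, remaining columns samples.
#' @param path TSV file.
#' @return \code{read_count_matrix}: a \code{\link{count_matrix}};
#'   \code{write_count_matrix}: invisibly, \code{path}.
#' @export
read_count_matrix <- function(path) {
  df <- .read_tsv(path)
  if (ncol(df) < 2L) .stopf("count matrix TSV needs feature_id + samples")
  mat <- as.matrix(df[, -1L, drop = FALSE])
  rownames(mat) <- df[[1L]]
  count_matrix(mat)
}

#' @rdname read_count_matrix
#' @param m a \code{\link{count_matrix}} or matrix.
#' @export
write_count_matrix <- function(m, path) {
  m <- .as_count_matrix(m)
  df <- data.frame(feature_id = rownames(m$counts), m$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  .write_tsv(df, path)
  invisible(path)
}
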