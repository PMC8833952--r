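#' Geometric mean with annihilating zeros
#'
#' Plain geometric mean of a non-negative vector. Any zero (or negative
#' clamped input) yields 0: no pseudocount is added, matching the
#' floor(geometric-mean) expression filters used throughout the package.
#'
#' @param x numeric vector, all values >= 0.
#' @return A single number, \code{prod(x)^(1/length(x))} computed on the log
#'   scale; 0 if any element is 0.
#' @export
geom_mean <- function(x) {
  if (length(x) == 0L) stop("geom_mean: empty vector")
  if (any(is.na(x))) stop("geom_mean: NA values")
  if (any(x < 0)) stop("geom_mean: negative values")
  if (any(x == 0)) return(0)
  exp(mean(log(x)))
}

# vectorised row geometric means (zeros annihilate) for a numeric matrix
.row_geom_means <- function(m) {
  if (is.null(dim(m))) m <- matrix(m, nrow = 1L)
  gm <- exp(rowMeans(log(pmax(m, .Machine$double.xmin))))
  gm[apply(m == 0, 1L, any)] <- 0
  gm
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# DNA alphabet helpers: U is normalized to T on ingest
.normalize_dna <- function(x) {
  x <- toupper(x)
  gsub("U", "T", x, fixed = TRUE)
}

.check_dna <- function(x, what = "sequence") {
  bad <- grepl("[^ACGT]", x)
  if (any(bad)) {
    .stopf("invalid %s alphabet (non-ACGT after U->T) in: %s",
           what, paste(utils::head(x[bad], 3L), collapse = ", "))
  }
  invisible(x)
}

.read_tsv <- function(path, ...) {
  utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE, ...)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
}

.require_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    .stopf("%s: missing required column(s): %s", what,
           paste(miss, collapse = ", "))
  }
  invisible(df)
}
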