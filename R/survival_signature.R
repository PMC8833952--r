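#' Cohort eligibility for a survival analysis
#'
#' A cohort is eligible iff it has at least ten patients with the event
#' observed and at least ten without (e.g. dead/alive for overall
#' survival, relapse/no relapse for relapse-free survival). Records with
#' missing time or event are ignored.
#'
#' @param records data.frame with \code{time} and \code{event} columns.
#' @param min_per_type minimum patients per event type (default 10).
#' @return TRUE/FALSE.
#' @export
check_eligibility <- function(records, min_per_type = 10L) {
  ok <- !is.na(records$time) & !is.na(records$event)
  sum(records$event[ok] == 1) >= min_per_type &&
    sum(records$event[ok] == 0) >= min_per_type
}

# greedy pruning on a precomputed |correlation| matrix
.prune_from_cor <- function(C, threshold) {
  keep <- rownames(C)
  diag(C) <- 0
  while (length(keep) > 1L) {
    sub <- C[keep, keep, drop = FALSE]
    over <- sub > threshold
    if (!any(over)) break
    involved <- keep[rowSums(over) > 0]
    mean_abs <- rowMeans(sub[involved, , drop = FALSE])
    worst <- max(mean_abs)
    # deterministic tie-break: among equals, remove the later name
    drop_f <- max(involved[mean_abs >= worst - 1e-15])
    keep <- setdiff(keep, drop_f)
  }
  keep
}

#' Greedy correlation pruning of features
#'
#' Computes pairwise absolute Pearson correlations between features and
#' repeatedly removes the feature with the largest mean absolute
#' correlation among those participating in any pair above the threshold,
#' until no pair exceeds it. Ties are broken by feature name
#' (lexicographically later name removed), so the result is
#' deterministic.
#'
#' @param expr numeric matrix, features x patients (normalized
#'   expression).
#' @param threshold correlation threshold in (0, 1].
#' @return character vector of retained feature ids (original row order).
#' @export
correlation_prune <- function(expr, threshold) {
  if (threshold <= 0 || threshold > 1) .stopf("correlation_prune: threshold must be in (0, 1]")
  if (is.null(rownames(expr))) .stopf("correlation_prune: expr needs rownames")
  C <- abs(stats::cor(t(expr)))
  C[is.na(C)] <- 0
  kept <- .prune_from_cor(C, threshold)
  rownames(expr)[rownames(expr) %in% kept]
}

# ridge-penalized logistic regression (IRLS/Newton); intercept unpenalized
.ridge_logistic <- function(X, y, lambda = 1, tol = 1e-8, max_iter = 100L) {
  n <- nrow(X); p <- ncol(X)
  Z <- cbind(1, X)
  beta <- numeric(p + 1L)
  pen <- diag(c(0, rep(lambda, p)), p + 1L)
  for (it in seq_len(max_iter)) {
    eta <- drop(Z %*% beta)
    mu <- 1 / (1 + exp(-eta))
    g <- crossprod(Z, y - mu) - pen %*% beta
    W <- mu * (1 - mu)
    H <- crossprod(Z, Z * W) + pen
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) break
    beta <- beta + drop(step)
    if (max(abs(g)) < tol) break
  }
  list(intercept = beta[1L], coef = stats::setNames(beta[-1L], colnames(X)))
}

#' Recursive feature elimination with an L2 logistic estimator
#'
#' Standard RFE: fit an L2-regularized logistic regression of the binary
#' event flag on standardized features, drop the feature with the
#' smallest absolute coefficient, and repeat down to each requested size.
#' Fully deterministic (no resampling; ties broken by feature name).
#'
#' @param expr numeric matrix, features x patients.
#' @param labels 0/1 event flags, one per patient.
#' @param target_sizes integer vector of subset sizes to report; sizes
#'   exceeding the number of available features are capped with a
#'   warning.
#' @param lambda ridge penalty (default 1).
#' @return named list: one character vector of retained features per
#'   target size; attribute \code{elimination_order} gives the drop
#'   sequence.
#' @export
rfe_select <- function(expr, labels, target_sizes, lambda = 1) {
  if (!all(labels %in% c(0, 1))) .stopf("rfe_select: labels must be 0/1")
  feats <- rownames(expr)
  if (any(target_sizes > length(feats))) {
    .warnf("rfe_select: target size(s) > available features; capped at %d",
           length(feats))
  }
  target_sizes <- sort(unique(pmin(as.integer(target_sizes), length(feats))))
  target_sizes <- target_sizes[target_sizes >= 1L]
  Xz <- t(apply(expr, 1L, function(x) {
    s <- stats::sd(x)
    if (s == 0) rep(0, length(x)) else (x - mean(x)) / s
  }))
  Xz <- matrix(Xz, nrow = nrow(expr), dimnames = dimnames(expr))
  current <- feats
  subsets <- list()
  dropped <- character()
  for (size in seq(length(feats), 1L)) {
    if (size %in% target_sizes) subsets[[as.character(size)]] <- sort(current)
    if (size == 1L) break
    fit <- .ridge_logistic(t(Xz[current, , drop = FALSE]), labels, lambda)
    a <- abs(fit$coef)
    weakest <- min(names(a)[a <= min(a) + 1e-15])
    dropped <- c(dropped, weakest)
    current <- setdiff(current, weakest)
  }
  structure(subsets[as.character(target_sizes)],
            elimination_order = dropped)
}

#' Per-patient prognostic risk scores
#'
#' \code{score_j = sum_i expr[i, j] * beta_i} over the signature features,
#' using the univariate Cox coefficients.
#'
#' @param expr numeric matrix, features x patients.
#' @param betas named numeric vector of coefficients; every name must be
#'   a row of \code{expr}.
#' @return named numeric vector of scores (one per patient).
#' @export
risk_scores <- function(expr, betas) {
  miss <- setdiff(names(betas), rownames(expr))
  if (length(miss)) {
    .stopf("risk_scores: feature(s) missing from expression matrix: %s",
           paste(miss, collapse = ", "))
  }
  E <- expr[names(betas), , drop = FALSE]
  if (anyNA(E)) .stopf("risk_scores: missing expression values")
  drop(crossprod(E, betas))
}

# evaluate one candidate feature set: risk scores, median split, log-rank,
# AUC against the event flag
.evaluate_candidate <- function(feats, expr, rec, uni_betas) {
  betas <- uni_betas[feats]
  scores <- risk_scores(expr[, rec$sample_id, drop = FALSE], betas)
  cutoff <- stats::median(scores)
  grp <- ifelse(scores <= cutoff, "low", "high")
  if (length(unique(grp)) < 2L) return(NULL)
  lr <- km_logrank(rec, grp)
  auc <- roc_auc(scores, rec$event)
  list(features = sort(feats), betas = betas[sort(feats)],
       risk_scores = scores, cutoff = cutoff,
       logrank_p = lr$p, auc = auc)
}

#' Two-stage prognostic signature search
#'
#' For each correlation threshold in the sweep: prune highly correlated
#' features; keep features with univariate Cox FDR < 0.05 (BH across the
#' pruned set); fit a multivariate Cox model and keep features with
#' p < 0.05; reduce by recursive feature elimination over the requested
#' sizes; score patients with the univariate coefficients, split at the
#' median risk score (score <= median = low risk), and evaluate the
#' log-rank p-value and the ROC AUC of the score against the event flag.
#' The signature with the highest AUC wins; ties prefer fewer features,
#' then the smaller threshold.
#'
#' @param expr numeric matrix, features x patients (normalized
#'   expression; constant features are dropped with a warning).
#' @param records data.frame with \code{sample_id, time, event}; rows
#'   with missing values are dropped; the cohort must satisfy
#'   \code{\link{check_eligibility}}.
#' @param event_type label stored on the result ("OS" or "RFS").
#' @param thresholds correlation sweep (default 0.60 to 0.80 by 0.01).
#' @param sizes RFE target sizes (default 3:15).
#' @return An \code{isomir_signature} object (list with
#'   \code{event_type, features, betas, corr_threshold, risk_scores,
#'   cutoff, logrank_p, auc, n_patients}), or a \code{no_signature}
#'   object when no threshold yields a surviving feature.
#' @export
signature_search <- function(expr, records, event_type = c("OS", "RFS"),
                             thresholds = seq(0.60, 0.80, by = 0.01),
                             sizes = 3:15) {
  event_type <- match.arg(event_type)
  rec <- records[!is.na(records$time) & !is.na(records$event), , drop = FALSE]
  if (!check_eligibility(rec)) {
    .stopf("signature_search: cohort not eligible (need >= 10 patients per event type)")
  }
  if (!all(rec$sample_id %in% colnames(expr))) {
    .stopf("signature_search: records reference samples absent from expr")
  }
  E <- expr[, rec$sample_id, drop = FALSE]
  sds <- apply(E, 1L, stats::sd)
  if (any(sds == 0)) {
    .warnf("signature_search: dropping %d constant feature(s)", sum(sds == 0))
    E <- E[sds > 0, , drop = FALSE]
  }
  if (!nrow(E)) return(structure(list(reason = "no usable features"),
                                 class = "no_signature"))

  uni <- cox_fit(E, rec, mode = "univariate-each")
  uni <- uni[uni$converged, , drop = FALSE]
  uni_betas <- stats::setNames(uni$beta, uni$feature)
  uni_p <- stats::setNames(uni$p, uni$feature)
  C <- abs(stats::cor(t(E)))
  C[is.na(C)] <- 0

  best <- NULL
  for (th in thresholds) {
    retained <- intersect(.prune_from_cor(C, th), uni$feature)
    if (!length(retained)) next
    fdr <- bh_adjust(uni_p[retained])
    sig_uni <- retained[fdr < 0.05]
    if (!length(sig_uni)) next
    multi <- if (length(sig_uni) == 1L) {
      data.frame(feature = sig_uni, p = uni_p[sig_uni])
    } else {
      cox_fit(E[sig_uni, , drop = FALSE], rec, mode = "multivariate")
    }
    surv_feats <- multi$feature[multi$p < 0.05]
    if (!length(surv_feats)) next
    cand_sets <- if (length(surv_feats) == 1L) {
      list(surv_feats)
    } else {
      subs <- rfe_select(E[surv_feats, , drop = FALSE], rec$event, sizes)
      unique(unname(subs))
    }
    for (feats in cand_sets) {
      cand <- .evaluate_candidate(feats, E, rec, uni_betas)
      if (is.null(cand)) next
      better <- is.null(best) ||
        cand$auc > best$auc + 1e-12 ||
        (abs(cand$auc - best$auc) <= 1e-12 &&
           (length(cand$features) < length(best$features) ||
              (length(cand$features) == length(best$features) &&
                 th < best$corr_threshold)))
      if (better) {
        cand$corr_threshold <- th
        best <- cand
      }
    }
  }
  if (is.null(best)) {
    return(structure(list(reason = "no threshold yielded a surviving feature"),
                     class = "no_signature"))
  }
  structure(c(list(event_type = event_type), best,
              list(n_patients = nrow(rec))),
            class = "isomir_signature")
}

#' @export
print.isomir_signature <- function(x, ...) {
  cat(sprintf("isomiR %s signature: %d features, threshold %.2f, AUC %.3f, log-rank p %.3g\n",
              x$event_type, length(x$features), x$corr_threshold, x$auc,
              x$logrank_p))
  cat("  features:", paste(x$features, collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.no_signature <- function(x, ...) {
  cat("no signature:", x$reason, "\n")
  invisible(x)
}

#' Apply a signature to another cohort
#'
#' Scores the new cohort with the original univariate coefficients,
#' splits at the new cohort's own median risk score, and reports the
#' log-rank p-value and AUC. If any signature feature is absent from the
#' new expression matrix the signature is not testable there.
#'
#' @param sig an \code{isomir_signature}.
#' @param expr numeric matrix, features x patients, for the new cohort.
#' @param records data.frame with \code{sample_id, time, event} for the
#'   new cohort.
#' @return list with \code{auc, logrank_p, risk_scores, cutoff}, or a
#'   \code{not_testable} object when a feature is missing.
#' @export
cross_apply <- function(sig, expr, records) {
  stopifnot(inherits(sig, "isomir_signature"))
  missing_feats <- setdiff(sig$features, rownames(expr))
  if (length(missing_feats)) {
    return(structure(list(reason = sprintf(
      "feature(s) not expressed in target cohort: %s",
      paste(missing_feats, collapse = ", "))), class = "not_testable"))
  }
  rec <- records[!is.na(records$time) & !is.na(records$event), , drop = FALSE]
  if (!all(rec$sample_id %in% colnames(expr))) {
    .stopf("cross_apply: records reference samples absent from expr")
  }
  scores <- risk_scores(expr[, rec$sample_id, drop = FALSE], sig$betas)
  cutoff <- stats::median(scores)
  grp <- ifelse(scores <= cutoff, "low", "high")
  if (length(unique(grp)) < 2L) {
    return(structure(list(reason = "degenerate risk split in target cohort"),
                     class = "not_testable"))
  }
  lr <- km_logrank(rec, grp)
  list(auc = roc_auc(scores, rec$event), logrank_p = lr$p,
       risk_scores = scores, cutoff = cutoff)
}

#' Write a signature as a JSON artifact
#'
#' @param sig an \code{isomir_signature}.
#' @param path output file.
#' @return Invisibly, \code{path}.
#' @export
write_signature_json <- function(sig, path) {
  stopifnot(inherits(sig, "isomir_signature"))
  esc <- function(s) gsub("\"", "\\\"", s, fixed = TRUE)
  num <- function(x) formatC(x, format = "g", digits = 15)
  json <- paste0(
    "{\n",
    sprintf('  "event_type": "%s",\n', sig$event_type),
    sprintf('  "features": [%s],\n',
            paste(sprintf('"%s"', esc(sig$features)), collapse = ", ")),
    sprintf('  "betas": [%s],\n', paste(num(sig$betas), collapse = ", ")),
    sprintf('  "corr_threshold": %s,\n', num(sig$corr_threshold)),
    sprintf('  "cutoff": %s,\n', num(sig$cutoff)),
    sprintf('  "logrank_p": %s,\n', num(sig$logrank_p)),
    sprintf('  "auc": %s\n', num(sig$auc)),
    "}\n")
  writeLines(json, path)
  invisible(path)
}
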