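#' Cox proportional-hazards regression (Efron ties, Newton-Raphson)
#'
#' Maximizes the Cox partial likelihood with Efron's approximation for
#' tied event times by Newton-Raphson with step-halving (tolerance 1e-8 on
#' the gradient max-norm, at most 50 iterations). Implemented from first
#' principles so the prognostic cascade is fully auditable; standard
#' survival software serves as an external cross-check in the test suite.
#'
#' @param X numeric matrix, patients x covariates (no constant columns).
#' @param time non-negative follow-up times.
#' @param event 0/1 event indicators (1 = event observed).
#' @param tol gradient max-norm convergence tolerance.
#' @param max_iter maximum Newton iterations.
#' @return list with \code{beta, se, p} (Wald, per coefficient),
#'   \code{loglik, gradient, converged, iter}.
#' @export
cox_ph <- function(X, time, event, tol = 1e-8, max_iter = 50L) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(time) == n, length(event) == n)
  if (any(time < 0)) .stopf("cox_ph: negative times")
  if (!all(event %in% c(0, 1))) .stopf("cox_ph: event must be 0/1")
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0)) {
    .stopf("cox_ph: constant covariate(s): %s",
           paste(colnames(X)[sds == 0], collapse = ", "))
  }
  if (sum(event) == 0) .stopf("cox_ph: no events")

  ord <- order(time)
  t_s <- time[ord]; d_s <- event[ord]; X_s <- X[ord, , drop = FALSE]
  ev_times <- unique(t_s[d_s == 1])
  # index sets precomputed once: risk set = suffix of the sorted order
  risk_start <- vapply(ev_times, function(tt) match(TRUE, t_s >= tt), 0L)
  death_idx <- lapply(ev_times, function(tt) which(t_s == tt & d_s == 1))
  n_tied <- lengths(death_idx)
  untied <- which(n_tied == 1L)           # Efron == Breslow terms here
  u_D <- unlist(death_idx[untied])
  u_f <- risk_start[untied]
  tied <- which(n_tied > 1L)

  # upper-triangle pair index for the second-moment suffix sums
  pairs <- which(upper.tri(matrix(0, p, p), diag = TRUE), arr.ind = TRUE)
  unpack <- function(v) {
    m <- matrix(0, p, p)
    m[pairs] <- v
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    m
  }

  obj <- function(beta) {
    eta <- drop(X_s %*% beta)
    eta <- eta - max(eta)  # guard overflow; cancels in all ratios
    w <- exp(eta)
    WX <- w * X_s
    WXX <- WX[, pairs[, 1L], drop = FALSE] * X_s[, pairs[, 2L], drop = FALSE]
    # suffix (reverse cumulative) sums
    S0 <- rev(cumsum(rev(w)))
    S1 <- apply(WX, 2L, function(col) rev(cumsum(rev(col))))
    if (p == 1L) S1 <- matrix(S1, ncol = 1L)
    S2 <- apply(WXX, 2L, function(col) rev(cumsum(rev(col))))
    if (nrow(pairs) == 1L) S2 <- matrix(S2, ncol = 1L)
    ll <- 0; gr <- numeric(p); info <- matrix(0, p, p)
    if (length(untied)) {
      den <- S0[u_f]
      num1 <- S1[u_f, , drop = FALSE]
      ll <- ll + sum(eta[u_D]) - sum(log(den))
      gr <- gr + colSums(X_s[u_D, , drop = FALSE]) - colSums(num1 / den)
      info <- info + unpack(colSums(S2[u_f, , drop = FALSE] / den)) -
        crossprod(num1 / den)
    }
    for (k in tied) {
      D <- death_idx[[k]]; dk <- length(D); f <- risk_start[k]
      S0R <- S0[f]
      S1R <- S1[f, ]
      XD <- X_s[D, , drop = FALSE]
      wD <- w[D]
      S0D <- sum(wD)
      S1D <- colSums(wD * XD)
      S2R <- unpack(S2[f, ])
      S2D <- crossprod(XD, wD * XD)
      ll <- ll + sum(eta[D])
      gr <- gr + colSums(XD)
      for (j in seq_len(dk) - 1L) {
        fr <- j / dk
        den <- S0R - fr * S0D
        num1 <- S1R - fr * S1D
        num2 <- S2R - fr * S2D
        ll <- ll - log(den)
        gr <- gr - num1 / den
        info <- info + num2 / den - tcrossprod(num1) / den^2
      }
    }
    list(ll = ll, gr = gr, info = info)
  }

  beta <- numeric(p)
  st <- obj(beta)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    step <- tryCatch(solve(st$info, st$gr), error = function(e) NULL)
    if (is.null(step)) break
    halve <- 0L
    repeat {
      cand <- beta + step
      st2 <- obj(cand)
      if (is.finite(st2$ll) && st2$ll >= st$ll - 1e-12) break
      step <- step / 2
      halve <- halve + 1L
      if (halve > 25L) break
    }
    if (halve > 25L) break
    beta <- cand; st <- st2
    if (max(abs(st$gr)) < tol) { converged <- TRUE; break }
  }
  if (max(abs(beta)) > 20) converged <- FALSE  # monotone likelihood

  covb <- tryCatch(solve(st$info), error = function(e) matrix(NA_real_, p, p))
  se <- sqrt(diag(covb))
  z <- beta / se
  list(beta = stats::setNames(beta, colnames(X)),
       se = stats::setNames(se, colnames(X)),
       p = stats::setNames(2 * stats::pnorm(-abs(z)), colnames(X)),
       loglik = st$ll, gradient = st$gr,
       converged = converged, iter = iter)
}

#' Univariate or multivariate Cox fits over an expression matrix
#'
#' In \code{univariate-each} mode, each feature (row of \code{expr}) is
#' fitted alone against survival and the Wald p-values are
#' Benjamini-Hochberg adjusted across features; non-converging features
#' (monotone likelihood) are flagged \code{converged = FALSE} and excluded
#' from the adjustment, with a warning. In \code{multivariate} mode all
#' features enter one model; features causing non-convergence are dropped
#' (largest coefficient first) and the model refitted, with a warning.
#'
#' @param expr numeric matrix, features x patients.
#' @param records data.frame with \code{sample_id, time, event}; rows with
#'   missing time or event are dropped. Column names of \code{expr} must
#'   cover the record sample ids.
#' @param mode \code{"univariate-each"} (default) or
#'   \code{"multivariate"}.
#' @return data.frame: \code{feature, beta, se, p, converged}, plus
#'   \code{fdr} in univariate mode.
#' @export
cox_fit <- function(expr, records, mode = c("univariate-each", "multivariate")) {
  mode <- match.arg(mode)
  rec <- records[!is.na(records$time) & !is.na(records$event), , drop = FALSE]
  if (!all(rec$sample_id %in% colnames(expr))) {
    .stopf("cox_fit: records reference samples absent from expr")
  }
  if (!check_eligibility(rec)) {
    .stopf("cox_fit: cohort not eligible (need >= 10 patients per event type)")
  }
  E <- expr[, rec$sample_id, drop = FALSE]
  feats <- rownames(E)
  if (mode == "univariate-each") {
    rows <- lapply(feats, function(f) {
      fit <- cox_ph(matrix(E[f, ], ncol = 1L, dimnames = list(NULL, f)),
                    rec$time, rec$event)
      data.frame(feature = f, beta = unname(fit$beta), se = unname(fit$se),
                 p = unname(fit$p), converged = fit$converged,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (any(!out$converged)) {
      .warnf("cox_fit: %d feature(s) failed to converge; excluded from FDR",
             sum(!out$converged))
    }
    out$fdr <- NA_real_
    out$fdr[out$converged] <- bh_adjust(out$p[out$converged])
    out
  } else {
    keep <- feats
    repeat {
      fit <- cox_ph(t(E[keep, , drop = FALSE]), rec$time, rec$event)
      if (fit$converged || length(keep) == 1L) break
      worst <- keep[which.max(abs(fit$beta))]
      .warnf("cox_fit: dropping non-converging feature '%s' from multivariate model", worst)
      keep <- setdiff(keep, worst)
    }
    data.frame(feature = keep, beta = unname(fit$beta[keep]),
               se = unname(fit$se[keep]), p = unname(fit$p[keep]),
               converged = fit$converged, stringsAsFactors = FALSE)
  }
}

#' Kaplan-Meier product-limit estimate
#'
#' @param time follow-up times.
#' @param event 0/1 event indicators.
#' @return data.frame: \code{time, n_risk, n_event, surv} (one row per
#'   distinct event time).
#' @export
km_curve <- function(time, event) {
  stopifnot(length(time) == length(event))
  ev_times <- sort(unique(time[event == 1]))
  n_risk <- vapply(ev_times, function(tt) sum(time >= tt), 0)
  n_event <- vapply(ev_times, function(tt) sum(time == tt & event == 1), 0)
  surv <- cumprod(1 - n_event / n_risk)
  data.frame(time = ev_times, n_risk = n_risk, n_event = n_event,
             surv = surv)
}

#' Two-group log-rank test with Kaplan-Meier curves
#'
#' Standard log-rank statistic (hypergeometric variance at each distinct
#' event time) referred to chi-squared on 1 degree of freedom.
#'
#' @param records data.frame with \code{time, event}.
#' @param group factor/character with two levels (e.g. high/low risk), one
#'   entry per record.
#' @return list with \code{chi2, p} and \code{curves} (named list of
#'   Kaplan-Meier tables).
#' @export
km_logrank <- function(records, group) {
  group <- as.factor(as.vector(group))
  group <- droplevels(group)
  if (nlevels(group) != 2L) .stopf("km_logrank: need exactly two non-empty groups")
  time <- records$time; event <- records$event
  g1 <- levels(group)[1L]
  if (any(tapply(event, group, sum) == 0)) {
    .warnf("km_logrank: a group has zero events")
  }
  ev_times <- sort(unique(time[event == 1]))
  O <- 0; E <- 0; V <- 0
  for (tt in ev_times) {
    at_risk <- time >= tt
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == g1)
    d <- sum(time == tt & event == 1)
    d1 <- sum(time == tt & event == 1 & group == g1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chi2 <- if (V > 0) (O - E)^2 / V else 0
  p <- if (V > 0) stats::pchisq(chi2, df = 1L, lower.tail = FALSE) else 1
  curves <- lapply(levels(group), function(g) {
    km_curve(time[group == g], event[group == g])
  })
  names(curves) <- levels(group)
  list(chi2 = chi2, p = p, curves = curves)
}

#' Rank-based ROC AUC of a score against a binary label
#'
#' Probability that a randomly chosen positive (event) scores above a
#' randomly chosen negative, ties counted one half (Wilcoxon rank
#' formula).
#'
#' @param scores numeric scores.
#' @param labels 0/1 labels (1 = event); both classes must be present.
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  if (!all(labels %in% c(0, 1))) .stopf("roc_auc: labels must be 0/1")
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L) .stopf("roc_auc: both label classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
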