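test_that("eligibility needs ten patients per event type", {
  rec <- function(n1, n0) data.frame(time = rep(100, n1 + n0),
                                     event = rep(c(1L, 0L), c(n1, n0)))
  expect_false(check_eligibility(rec(9, 50)))
  expect_true(check_eligibility(rec(10, 10)))
  expect_false(check_eligibility(data.frame(time = numeric(),
                                            event = integer())))
})

test_that("correlation pruning is greedy, deterministic and threshold-faithful", {
  set.seed(10)
  base <- rnorm(40)
  expr <- rbind(a = base + rnorm(40, sd = 0.1),
                b = base + rnorm(40, sd = 0.1),
                c = rnorm(40))
  colnames(expr) <- paste0("p", 1:40)
  kept <- correlation_prune(expr, 0.8)
  expect_equal(length(intersect(kept, c("a", "b"))), 1L)
  expect_true("c" %in% kept)
  # identical features: exactly one retained
  dup <- rbind(x = base, y = base, z = rnorm(40))
  colnames(dup) <- paste0("p", 1:40)
  expect_equal(sort(correlation_prune(dup, 0.9)), c("x", "z"))
  # everything under threshold: all retained
  expect_setequal(correlation_prune(expr, 0.999), c("a", "b", "c"))
  # hand-trace of the greedy mean-|r| rule on a 3-feature system:
  # r(a,b) ~ 0.9, c independent; the member of {a,b} with the larger mean
  # absolute correlation is removed
  C <- abs(cor(t(expr)))
  means <- rowMeans(C - diag(diag(C)))[c("a", "b")]
  expect_equal(setdiff(c("a", "b"), kept),
               names(means)[which.max(means)])
})

test_that("cox_ph agrees with the survival package and satisfies its score equation", {
  skip_if_not_installed("survival")
  set.seed(20)
  n <- 150
  X <- cbind(f1 = rnorm(n), f2 = rbinom(n, 1, 0.4))
  tt <- rexp(n, 0.05 * exp(0.6 * X[, "f1"] - 0.4 * X[, "f2"]))
  ev <- rbinom(n, 1, 0.75)
  tt <- round(tt, 1)  # force ties to exercise the Efron terms
  fit <- cox_ph(X, tt, ev)
  oracle <- survival::coxph(survival::Surv(tt, ev) ~ X, ties = "efron")
  expect_equal(unname(fit$beta), unname(coef(oracle)), tolerance = 1e-7)
  expect_equal(unname(fit$se),
               unname(sqrt(diag(vcov(oracle)))), tolerance = 1e-6)
  expect_lt(max(abs(fit$gradient)), 1e-6)
  expect_true(fit$converged)
  # duplicating every patient introduces ties, so the Efron estimate moves
  # slightly (exact invariance holds only under Breslow weights); it must
  # still track the oracle exactly and the original closely
  fit2 <- cox_ph(rbind(X, X), rep(tt, 2), rep(ev, 2))
  oracle2 <- survival::coxph(survival::Surv(rep(tt, 2), rep(ev, 2)) ~ rbind(X, X),
                             ties = "efron")
  expect_equal(unname(fit2$beta), unname(coef(oracle2)), tolerance = 1e-7)
  expect_lt(max(abs(fit2$beta - fit$beta)), 0.05)
  expect_error(cox_ph(cbind(const = rep(1, n)), tt, ev), "constant")
})

test_that("cox_ph null coverage: a non-prognostic feature stays near zero", {
  set.seed(30)
  inside <- replicate(30, {
    n <- 300
    x <- matrix(rnorm(n), dimnames = list(NULL, "x"))
    tt <- rexp(n, 0.02)
    fit <- cox_ph(x, tt, rbinom(n, 1, 0.8))
    abs(fit$beta) < 3 * fit$se
  })
  expect_gte(mean(inside), 0.9)
})

test_that("cox_fit univariate mode BH-adjusts across features", {
  set.seed(40)
  n <- 120
  expr <- matrix(rnorm(3 * n), 3, n,
                 dimnames = list(c("s1", "s2", "noise"), paste0("p", 1:n)))
  lp <- 0.9 * expr["s1", ] - 0.9 * expr["s2", ]
  tt <- rexp(n, 0.05 * exp(lp))
  horizon <- unname(quantile(tt, 0.7))  # administrative censoring
  rec <- data.frame(sample_id = colnames(expr),
                    time = pmin(tt, horizon),
                    event = as.integer(tt <= horizon))
  uni <- cox_fit(expr, rec, mode = "univariate-each")
  expect_equal(uni$fdr[uni$converged], bh_adjust(uni$p[uni$converged]))
  expect_true(all(uni$fdr[uni$feature %in% c("s1", "s2")] < 0.05))
  multi <- cox_fit(expr, rec, mode = "multivariate")
  expect_equal(nrow(multi), 3L)
  expect_true(all(multi$p[multi$feature %in% c("s1", "s2")] < 0.05))
})

test_that("rfe keeps strong features and has a stable elimination trace", {
  set.seed(50)
  n <- 80
  expr <- matrix(rnorm(10 * n), 10, n,
                 dimnames = list(paste0("f", 1:10), paste0("p", 1:n)))
  labels <- as.integer(expr["f1", ] + rnorm(n, sd = 0.3) > 0)
  subs <- rfe_select(expr, labels, target_sizes = c(1, 3, 5, 10))
  expect_true(all(vapply(subs, function(s) "f1" %in% s, NA)))
  expect_setequal(subs[["10"]], paste0("f", 1:10))  # identity at full size
  # removing the first-eliminated feature leaves the rest of the trace
  # unchanged (algorithm structure)
  ord <- attr(subs, "elimination_order")
  subs2 <- rfe_select(expr[setdiff(rownames(expr), ord[1]), , drop = FALSE],
                      labels, target_sizes = c(1, 3))
  expect_equal(attr(subs2, "elimination_order"), ord[-1])
  expect_warning(rfe_select(expr, labels, target_sizes = 99), "capped")
})

test_that("risk scores are the plain linear combination", {
  expr <- matrix(c(2, 3, 1, 4), 2, 2,
                 dimnames = list(c("fA", "fB"), c("p1", "p2")))
  sc <- risk_scores(expr, c(fA = 0.5, fB = -1))
  expect_equal(unname(sc), c(2 * 0.5 - 3, 1 * 0.5 - 4))
  expect_equal(risk_scores(expr, c(fB = 0, fA = 0)), c(p1 = 0, p2 = 0))
  expect_equal(risk_scores(expr * 2, c(fA = 0.5, fB = -1)), sc * 2)
  # feature order must not matter
  expect_equal(risk_scores(expr, c(fB = -1, fA = 0.5)), sc)
  expect_error(risk_scores(expr, c(missing = 1)), "missing")
})

test_that("Kaplan-Meier and log-rank match hand values and the survival oracle", {
  skip_if_not_installed("survival")
  km <- km_curve(c(1, 2, 3, 4), c(1, 1, 1, 1))
  expect_equal(km$surv, c(0.75, 0.5, 0.25, 0))
  # identical groups: chi2 = 0, p = 1
  rec <- data.frame(time = rep(c(1, 2, 3, 5, 8), 2),
                    event = rep(c(1, 0, 1, 1, 0), 2))
  lr <- suppressWarnings(km_logrank(rec, rep(c("a", "b"), each = 5)))
  expect_equal(lr$chi2, 0)
  expect_equal(lr$p, 1)
  set.seed(60)
  n <- 50
  tt <- rexp(n, 0.1); ev <- rbinom(n, 1, 0.8); gg <- rep(c("hi", "lo"), n / 2)
  mine <- km_logrank(data.frame(time = tt, event = ev), gg)
  oracle <- survival::survdiff(survival::Surv(tt, ev) ~ gg)
  expect_equal(mine$chi2, oracle$chisq, tolerance = 1e-10)
})

test_that("roc_auc equals exhaustive pair counting", {
  set.seed(70)
  scores <- sample(c(rnorm(6), rnorm(4) + 1))
  scores[2] <- scores[7]  # inject a tie
  labels <- c(rep(0, 6), rep(1, 4))
  expect_equal(roc_auc(scores, labels), oracle_auc_pairs(scores, labels))
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_equal(roc_auc(rep(1, 6), c(0, 1, 0, 1, 0, 1)), 0.5)
  expect_error(roc_auc(1:3, c(1, 1, 1)), "both label classes")
})

test_that("signature search finds planted features, is deterministic, and cross-applies", {
  cfg <- sim_config(seed = 123)
  sv <- simulate_survival(cfg, n_features = 60, n_patients = 150,
                          true_betas = c(f005 = 0.9, f010 = -0.9))
  sig <- suppressWarnings(signature_search(sv$expr, sv$records, "OS",
                                           sizes = 2:6))
  expect_s3_class(sig, "isomir_signature")
  expect_gte(length(intersect(sig$features, c("f005", "f010"))), 1L)
  expect_gt(sig$auc, 0.6)
  expect_equal(sig$cutoff, median(sig$risk_scores))
  # deterministic: a second run returns the identical signature
  sig2 <- suppressWarnings(signature_search(sv$expr, sv$records, "OS",
                                            sizes = 2:6))
  expect_equal(sig, sig2)
  # row-permutation invariance of the expression matrix
  perm <- sample(nrow(sv$expr))
  sig3 <- suppressWarnings(signature_search(sv$expr[perm, ], sv$records, "OS",
                                            sizes = 2:6))
  expect_equal(sig3$features, sig$features)
  expect_equal(sig3$auc, sig$auc)
  # applying to the training cohort reproduces the training numbers
  self <- cross_apply(sig, sv$expr, sv$records)
  expect_equal(self$auc, sig$auc)
  expect_equal(self$logrank_p, sig$logrank_p)
  # a missing feature makes the signature untestable
  reduced <- sv$expr[setdiff(rownames(sv$expr), sig$features[1]), ]
  expect_s3_class(cross_apply(sig, reduced, sv$records), "not_testable")
})

test_that("ineligible cohorts are rejected", {
  expr <- matrix(rnorm(40), 2, 20,
                 dimnames = list(c("a", "b"), paste0("p", 1:20)))
  rec <- data.frame(sample_id = paste0("p", 1:20), time = rexp(20),
                    event = rep(c(1L, 0L), c(5, 15)))
  expect_error(signature_search(expr, rec, "OS"), "eligible")
})
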