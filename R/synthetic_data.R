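#' Simulation configuration
#'
#' Bundles and validates the knobs of the synthetic-data generators. The
#' defaults describe the stated world the test-suite exercises: 10
#' hairpins, 5000 reads over a mixture of isoform categories, four
#' negative-binomial groups of 15 samples with 4-fold planted effects,
#' and 30\% censoring in survival cohorts.
#'
#' @param seed integer RNG seed; every generator is deterministic given
#'   the config.
#' @param n_hairpins number of synthetic hairpins.
#' @param read_depth number of simulated reads.
#' @param fractions named fractions over the planted read categories
#'   \code{canonical, shift5, shift3, shift53, nta, edit}; must sum to at
#'   most 1 (any remainder is assigned to canonical).
#' @param editing_rate probability that a read of category \code{edit}
#'   actually carries the A-to-G change.
#' @param nb_mean range (length-2) of per-feature base means, drawn
#'   log-uniformly.
#' @param nb_dispersion common negative-binomial dispersion.
#' @param group_sizes samples per group (W_N, W_T, BAA_N, BAA_T).
#' @param effect_size multiplicative planted effect (tumor/normal ratio;
#'   monotonic trends span this ratio end to end).
#' @param censoring_rate target fraction of censored patients.
#' @param snp_site_prob probability a mature gets one catalogued SNP site
#'   outside the seed.
#' @return list of class \code{sim_config}.
#' @export
sim_config <- function(seed = 1L, n_hairpins = 10L, read_depth = 5000L,
                       fractions = c(canonical = 0.35, shift5 = 0.10,
                                     shift3 = 0.20, shift53 = 0.10,
                                     nta = 0.15, edit = 0.10),
                       editing_rate = 1.0,
                       nb_mean = c(20, 500), nb_dispersion = 0.1,
                       group_sizes = c(15L, 15L, 15L, 15L),
                       effect_size = 4, censoring_rate = 0.3,
                       snp_site_prob = 0.2) {
  cats <- c("canonical", "shift5", "shift3", "shift53", "nta", "edit")
  fr <- stats::setNames(rep(0, 6L), cats)
  fr[names(fractions)] <- fractions
  if (any(fr < 0) || sum(fr) > 1 + 1e-12) {
    .stopf("sim_config: fractions must be non-negative and sum to <= 1")
  }
  fr["canonical"] <- fr["canonical"] + max(0, 1 - sum(fr))
  for (r in c(editing_rate, censoring_rate, snp_site_prob)) {
    if (r < 0 || r > 1) .stopf("sim_config: rates must be in [0, 1]")
  }
  if (length(group_sizes) != 4L || any(group_sizes < 1L)) {
    .stopf("sim_config: group_sizes must be four positive integers")
  }
  structure(list(seed = as.integer(seed), n_hairpins = as.integer(n_hairpins),
                 read_depth = as.integer(read_depth), fractions = fr,
                 editing_rate = editing_rate, nb_mean = nb_mean,
                 nb_dispersion = nb_dispersion,
                 group_sizes = as.integer(group_sizes),
                 effect_size = effect_size, censoring_rate = censoring_rate,
                 snp_site_prob = snp_site_prob),
            class = "sim_config")
}

.rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                               collapse = "")

#' Generate a synthetic miRNA reference with registered variant sites
#'
#' Random hairpins (60-90 nt) each carrying one 20-23 nt mature with at
#' least 5 nt of hairpin flank on both sides (so templated end shifts are
#' observable) and at least one A in seed positions 2-7. Every seed A is
#' registered as an A-to-I EDITING site; some matures additionally get a
#' catalogued non-seed SNP. Mature sequences are rejection-sampled to
#' occur exactly once across all hairpins, making read placement
#' unambiguous by construction.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @return A \code{\link{mirna_reference}}.
#' @export
make_reference <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_hairpins
  hp <- vector("list", n)
  seqs <- character(n)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in 1:500) {
      len <- sample(60:90, 1L)
      s <- .rand_dna(len)
      mlen <- sample(20:23, 1L)
      mstart <- sample(5:(len - mlen - 5L), 1L)  # 0-based
      mat <- substr(s, mstart + 1L, mstart + mlen)
      seed_region <- substr(mat, 2L, 7L)
      if (!grepl("A", seed_region, fixed = TRUE)) next
      # uniqueness: the mature occurs once in its own hairpin, nowhere in
      # the previous ones, and no previous mature occurs in this hairpin
      n_occ <- function(h, pat) {
        hits <- gregexpr(pat, h, fixed = TRUE)[[1L]]
        sum(hits > 0L)
      }
      prev <- seqs[seq_len(i - 1L)]
      unique_here <- n_occ(s, mat) == 1L &&
        all(vapply(prev, n_occ, 0L, pat = mat) == 0L) &&
        all(vapply(seq_len(i - 1L),
                   function(j) n_occ(s, hp[[j]]$mat), 0L) == 0L)
      if (unique_here) {
        hp[[i]] <- list(seq = s, mstart = mstart, mlen = mlen, mat = mat)
        seqs[i] <- s
        ok <- TRUE
        break
      }
    }
    if (!ok) .stopf("make_reference: could not build a unique mature after 500 tries")
  }
  hairpins <- data.frame(
    id = sprintf("hp-sim-%02d", seq_len(n)),
    sequence = seqs, chrom = "chrS",
    genome_start = 1000L * seq_len(n),
    genome_end = 1000L * seq_len(n) + nchar(seqs) - 1L,
    strand = "+", stringsAsFactors = FALSE)
  arm <- vapply(hp, function(h) {
    if (h$mstart + h$mlen / 2 < nchar(h$seq) / 2) "5p" else "3p"
  }, "")
  matures <- data.frame(
    name = sprintf("miR-sim-%02d-%s", seq_len(n), arm),
    hairpin_id = hairpins$id,
    start = vapply(hp, `[[`, 0L, "mstart"),
    end = vapply(hp, function(h) h$mstart + h$mlen, 0L),
    arm = arm, stringsAsFactors = FALSE)
  vrows <- list()
  for (i in seq_len(n)) {
    mat <- hp[[i]]$mat
    seed_pos <- 1L + which(strsplit(substr(mat, 2L, 7L), "")[[1L]] == "A")
    for (p in seed_pos) {
      vrows[[length(vrows) + 1L]] <- data.frame(
        mature_name = matures$name[i], pos_on_mature = p, ref = "A",
        alt = "G", class = "EDITING", stringsAsFactors = FALSE)
    }
    if (stats::runif(1) < cfg$snp_site_prob) {
      pos <- sample(8:hp[[i]]$mlen, 1L)
      ref <- substr(mat, pos, pos)
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
      vrows[[length(vrows) + 1L]] <- data.frame(
        mature_name = matures$name[i], pos_on_mature = pos, ref = ref,
        alt = alt, class = "SNP", stringsAsFactors = FALSE)
    }
  }
  variants <- do.call(rbind, vrows)
  mirna_reference(hairpins, matures, variants)
}

#' Simulate small-RNA reads with planted isomiR truth
#'
#' Draws reads from the reference according to the category fractions:
#' canonical, templated 5'/3'/both-end shifts (offsets of 1-2 nt),
#' non-templated 3' additions of 1-3 bases from \{A, T\} (adenylation /
#' uridylation; each NTA base is chosen to differ from the hairpin
#' continuation so the planted annotation is unambiguous), and seed
#' A-to-G edits at registered EDITING sites (applied with probability
#' \code{editing_rate}). Every read carries its exact planted event
#' parameters in the truth table.
#'
#' @param ref a \code{\link{mirna_reference}} from
#'   \code{\link{make_reference}}.
#' @param cfg a \code{\link{sim_config}}.
#' @return list with \code{reads} (data.frame \code{read_id, read}) and
#'   \code{truth} (data.frame \code{read_id, read, mature_name, offset5,
#'   offset3, nta_seq, snv, category}; \code{snv} is
#'   \code{"<pos><ref>><alt>"} or "").
#' @export
simulate_reads <- function(ref, cfg) {
  stopifnot(inherits(ref, "mirna_reference"), inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1L)
  n <- cfg$read_depth
  mi <- sample(nrow(ref$matures), n, replace = TRUE)
  cat_names <- names(cfg$fractions)
  category <- sample(cat_names, n, replace = TRUE, prob = cfg$fractions)
  hseq <- ref$hairpins$sequence[match(ref$matures$hairpin_id, ref$hairpins$id)]
  out <- vector("list", n)
  for (r in seq_len(n)) {
    i <- mi[r]
    H <- hseq[i]
    L <- nchar(H)
    ms <- ref$matures$start[i]; me <- ref$matures$end[i]
    o5 <- 0L; o3 <- 0L; nta <- ""; snv <- ""
    cat_r <- category[r]
    pick_off <- function(lo, hi) {
      ch <- setdiff(max(lo, -2L):min(hi, 2L), 0L)
      ch[sample.int(length(ch), 1L)]
    }
    if (cat_r %in% c("shift5", "shift53")) {
      # keep >= 50% mature overlap and read length >= 15
      o5 <- pick_off(-ms, 2L)
    }
    if (cat_r %in% c("shift3", "shift53")) {
      o3 <- pick_off(-2L, L - me)
    }
    s <- ms + o5
    e <- me + o3
    read <- substr(H, s + 1L, e)
    if (cat_r == "nta") {
      nl <- sample(1:3, 1L)
      bases <- character(nl)
      for (j in seq_len(nl)) {
        cont <- if (me + j <= L) substr(H, me + j, me + j) else ""
        bases[j] <- sample(setdiff(c("A", "T"), cont), 1L)
      }
      nta <- paste(bases, collapse = "")
      read <- paste0(read, nta)
      o3 <- nl
    }
    if (cat_r == "edit" && stats::runif(1) < cfg$editing_rate) {
      sites <- ref$variants[ref$variants$mature_name == ref$matures$name[i] &
                              ref$variants$class == "EDITING", ]
      pos <- sites$pos_on_mature[sample(nrow(sites), 1L)]
      substr(read, pos, pos) <- "G"
      snv <- sprintf("%dA>G", pos)
    }
    out[[r]] <- data.frame(
      read_id = sprintf("read%05d", r), read = read,
      mature_name = ref$matures$name[i], offset5 = o5, offset3 = o3,
      nta_seq = nta, snv = snv, category = cat_r,
      stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, out)
  list(reads = truth[, c("read_id", "read")], truth = truth)
}

#' Write simulated reads as FASTQ (constant quality)
#' @param reads data.frame with \code{read_id, read}.
#' @param path output FASTQ file.
#' @return Invisibly, \code{path}.
#' @export
write_fastq <- function(reads, path) {
  qual <- vapply(nchar(reads$read), function(k) strrep("I", k), "")
  writeLines(paste0("@", reads$read_id, "\n", reads$read, "\n+\n", qual),
             path)
  invisible(path)
}

# group-mean multipliers implementing each planted trend at effect f
.trend_multipliers <- function(trend, f) {
  s <- f^(1 / 3)  # per-step factor so monotonic trends span f end-to-end
  switch(trend,
         MONOTONIC_INC = c(1, s, s^2, s^3),
         MONOTONIC_DEC = c(s^3, s^2, s, 1),
         UP_BOTH = c(1, f, 1, f),
         DOWN_BOTH = c(f, 1, f, 1),
         UP_W_DOWN_BAA = c(1, f, f, 1),
         DOWN_W_UP_BAA = c(f, 1, 1, f),
         NULL_TREND = c(1, 1, 1, 1),
         .stopf("unknown trend: %s", trend))
}

#' Simulate a four-group count matrix with planted trends
#'
#' Negative-binomial counts for four groups (W_N, W_T, BAA_N, BAA_T) with
#' per-row base means drawn log-uniformly over \code{cfg$nb_mean} and
#' per-group mean multipliers implementing each planted trend at
#' \code{cfg$effect_size}; null rows share one mean across groups.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @param n_null number of null rows.
#' @param n_per_trend rows planted per non-null trend (named vector or a
#'   single count applied to all six trends).
#' @return list with \code{matrix} (a \code{\link{count_matrix}}),
#'   \code{design} (group factor) and \code{truth} (data.frame
#'   \code{feature, trend, effect}).
#' @export
simulate_count_matrix <- function(cfg, n_null = 200L,
                                  n_per_trend = 10L) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 2L)
  trends <- c("MONOTONIC_INC", "MONOTONIC_DEC", "UP_BOTH", "DOWN_BOTH",
              "UP_W_DOWN_BAA", "DOWN_W_UP_BAA")
  if (length(n_per_trend) == 1L) {
    n_per_trend <- stats::setNames(rep(n_per_trend, 6L), trends)
  }
  plan <- c(rep("NULL_TREND", n_null),
            rep(trends, times = n_per_trend[trends]))
  nrows <- length(plan)
  groups <- factor(rep(c("W_N", "W_T", "BAA_N", "BAA_T"), cfg$group_sizes),
                   levels = c("W_N", "W_T", "BAA_N", "BAA_T"))
  base <- exp(stats::runif(nrows, log(cfg$nb_mean[1L]), log(cfg$nb_mean[2L])))
  counts <- matrix(0L, nrows, length(groups))
  for (i in seq_len(nrows)) {
    mult <- .trend_multipliers(plan[i], cfg$effect_size)
    mu <- base[i] * mult[as.integer(groups)]
    counts[i, ] <- stats::rnbinom(length(groups), mu = mu,
                                  size = 1 / cfg$nb_dispersion)
  }
  rownames(counts) <- sprintf("iso%04d", seq_len(nrows))
  colnames(counts) <- sprintf("s%03d", seq_along(groups))
  truth <- data.frame(feature = rownames(counts), trend = plan,
                      effect = ifelse(plan == "NULL_TREND", 1,
                                      cfg$effect_size),
                      stringsAsFactors = FALSE)
  list(matrix = count_matrix(counts), design = groups, truth = truth)
}

# calibrate the uniform censoring horizon so the expected censored
# fraction matches the target, given subject-specific exponential rates
.calibrate_censor_horizon <- function(rates, target) {
  censored_frac <- function(cmax) {
    mean((1 - exp(-rates * cmax)) / (rates * cmax)) # P(C < T), C~U(0,cmax)
  }
  lo <- 1e-8; hi <- 1
  while (censored_frac(hi) > target && hi < 1e12) hi <- hi * 10
  stats::uniroot(function(cm) censored_frac(cm) - target, c(lo, hi),
                 tol = 1e-10)$root
}

#' Simulate a survival cohort tied to a known feature subset
#'
#' Feature expression is log-normal (meanlog 0, sdlog 1); survival times
#' are exponential with hazard \code{h0 * exp(sum(beta_i * x_i))} over
#' the prognostic subset, under independent uniform censoring on a
#' horizon calibrated so the expected censored fraction equals
#' \code{cfg$censoring_rate}.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @param n_features total number of features.
#' @param n_patients cohort size.
#' @param true_betas named numeric vector (names become prognostic
#'   features, e.g. \code{c(f001 = 0.8)}); may be empty for an all-null
#'   cohort.
#' @param h0 baseline hazard (default 0.01 per day).
#' @return list with \code{expr} (features x patients), \code{records}
#'   (data.frame \code{sample_id, time, event}) and \code{truth}
#'   (data.frame \code{feature, beta}).
#' @export
simulate_survival <- function(cfg, n_features = 200L, n_patients = 200L,
                              true_betas = numeric(), h0 = 0.01) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 3L)
  feats <- sprintf("f%03d", seq_len(n_features))
  if (length(true_betas) && !all(names(true_betas) %in% feats)) {
    .stopf("simulate_survival: true_betas names must be among f001..f%03d",
           n_features)
  }
  expr <- matrix(exp(stats::rnorm(n_features * n_patients)), n_features,
                 dimnames = list(feats, sprintf("p%03d", seq_len(n_patients))))
  beta <- stats::setNames(rep(0, n_features), feats)
  beta[names(true_betas)] <- true_betas
  lp <- drop(crossprod(expr, beta))
  rates <- h0 * exp(lp)
  t_ev <- stats::rexp(n_patients, rate = rates)
  if (cfg$censoring_rate > 0) {
    cmax <- .calibrate_censor_horizon(rates, cfg$censoring_rate)
    cens <- stats::runif(n_patients, 0, cmax)
    event <- as.integer(t_ev <= cens)
    time <- pmin(t_ev, cens)
  } else {
    event <- rep(1L, n_patients)
    time <- t_ev
  }
  list(expr = expr,
       records = data.frame(sample_id = colnames(expr), time = time,
                            event = event, stringsAsFactors = FALSE),
       truth = data.frame(feature = feats, beta = unname(beta),
                          stringsAsFactors = FALSE))
}
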