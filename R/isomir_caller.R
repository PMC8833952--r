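#' @title isomiR calling from small-RNA reads
#' @description
#' Reads are placed on hairpin precursors by ungapped search (the package's
#' stand-in for an external small-RNA aligner), assigned to a mature miRNA,
#' and annotated as isomiRs: 5'/3' end shifts relative to the canonical
#' mature, templated-ness of 3' extensions, non-templated additions (NTA),
#' and single-nucleotide variants (SNVs) positioned on the canonical mature
#' coordinate system so that "position 3" always means seed position 3.
#'
#' Sign conventions: \code{offset5 > 0} means the 5' end is trimmed
#' (starts inside the mature), \code{offset5 < 0} extended;
#' \code{offset3 > 0} means the 3' end is extended (templated bases and/or
#' NTA), \code{offset3 < 0} trimmed. \code{templated3} is TRUE iff the read
#' carries no non-templated bases.
#' @name isomir_calling
NULL

.call_table_cols <- function() {
  c("mature_name", "offset5", "offset3", "templated3", "nta_seq",
    "snvs", "snv_read_pos", "shift_class", "variant_class",
    "is_canonical", "name")
}

.empty_call_table <- function() {
  df <- data.frame(mature_name = character(), offset5 = integer(),
                   offset3 = integer(), templated3 = logical(),
                   nta_seq = character(), snvs = character(),
                   snv_read_pos = character(), shift_class = character(),
                   variant_class = character(), is_canonical = logical(),
                   name = character(), stringsAsFactors = FALSE)
  df
}

# precomputed per-hairpin character vectors, sorted by id for deterministic
# tie-breaking
.hairpin_index <- function(ref) {
  h <- ref$hairpins[order(ref$hairpins$id), ]
  list(ids = h$id, seqs = h$sequence, chars = strsplit(h$sequence, ""))
}

#' Place one read on the hairpin reference
#'
#' Best ungapped placement maximizing the matched prefix length (the
#' aligned region always ends on a matching base), with at most
#' \code{max_mismatches} internal mismatches and at most \code{max_nta}
#' unmatched 3'-terminal bases peeled off as overhang (candidate
#' non-templated additions). Ties are broken by fewest mismatches, then
#' leftmost start, then lexicographically smallest hairpin id.
#'
#' @param read read sequence (DNA or RNA; U normalized to T); length >= 15.
#' @param ref a \code{\link{mirna_reference}}.
#' @param max_mismatches maximum internal mismatches (default 2).
#' @param max_nta maximum 3' overhang length (default 3).
#' @return A list with \code{read_seq, hairpin_id, start_on_hairpin}
#'   (0-based), \code{aligned_len}, \code{mismatches} (data.frame
#'   \code{pos_on_read, ref_base, read_base}) and \code{overhang3}; or
#'   \code{NULL} if no placement qualifies.
#' @export
place_read <- function(read, ref, max_mismatches = 2L, max_nta = 3L) {
  if (!nzchar(read)) .stopf("place_read: empty read")
  read <- .normalize_dna(read)
  .check_dna(read, "read")
  if (nchar(read) < 15L) .stopf("place_read: read shorter than 15 nt")
  idx <- .hairpin_index(ref)
  .place_one(read, idx, as.integer(max_mismatches), as.integer(max_nta))
}

.place_one <- function(read, idx, max_mm, max_nta) {
  m <- nchar(read)
  min_aligned <- m - max_nta

  # fast path: an exact full-length match is globally optimal
  starts <- vapply(idx$seqs, function(s) {
    r <- regexpr(read, s, fixed = TRUE)
    as.integer(r)
  }, 0L)
  hit <- which(starts > 0L)
  if (length(hit)) {
    best <- hit[order(starts[hit], idx$ids[hit])][1L]
    return(list(read_seq = read, hairpin_id = idx$ids[best],
                start_on_hairpin = unname(starts[best]) - 1L, aligned_len = m,
                mismatches = data.frame(pos_on_read = integer(),
                                        ref_base = character(),
                                        read_base = character(),
                                        stringsAsFactors = FALSE),
                overhang3 = ""))
  }

  R <- strsplit(read, "")[[1L]]
  best <- NULL
  # tie-break order: longest aligned, fewest mismatches, leftmost start,
  # smallest hairpin id (ids are pre-sorted in the index)
  improves <- function(k, mm, s0, hi) {
    if (is.null(best)) return(TRUE)
    if (k != best$k) return(k > best$k)
    if (mm != best$mm) return(mm < best$mm)
    if (s0 != best$s0) return(s0 < best$s0)
    hi < best$hi
  }
  for (hi in seq_along(idx$ids)) {
    H <- idx$chars[[hi]]
    L <- length(H)
    if (L < min_aligned) next
    for (s0 in 0L:(L - min_aligned)) {
      avail <- min(m, L - s0)
      cmp <- R[seq_len(avail)] == H[s0 + seq_len(avail)]
      mmcum <- cumsum(!cmp)
      ks <- which(cmp)
      ks <- ks[ks >= min_aligned & mmcum[ks] <= max_mm]
      if (!length(ks)) next
      k <- max(ks)
      mm <- mmcum[k]
      if (improves(k, mm, s0, hi)) {
        best <- list(k = k, mm = mm, s0 = s0, hi = hi,
                     mmpos = which(!cmp[seq_len(k)]))
      }
    }
  }
  if (is.null(best)) return(NULL)
  H <- idx$chars[[best$hi]]
  list(read_seq = read, hairpin_id = idx$ids[best$hi],
       start_on_hairpin = best$s0, aligned_len = best$k,
       mismatches = data.frame(pos_on_read = best$mmpos,
                               ref_base = H[best$s0 + best$mmpos],
                               read_base = R[best$mmpos],
                               stringsAsFactors = FALSE),
       overhang3 = if (best$k < m) substr(read, best$k + 1L, m) else "")
}

#' Derive an isomiR call from a read placement
#'
#' The placement is assigned to the unique mature annotation it overlaps by
#' at least 50\% of the mature length; placements overlapping zero or two
#' matures are unassigned (\code{NULL}).
#' Offsets are computed relative to the canonical mature ends, a 3'
#' extension is templated where the extending bases equal the hairpin
#' continuation, and internal mismatches become SNVs positioned on the
#' canonical mature coordinate system. SNV annotations are initialized to
#' UNKNOWN; see \code{\link{annotate_variants}}.
#'
#' @param placement result of \code{\link{place_read}}.
#' @param ref a \code{\link{mirna_reference}}.
#' @return One-row isomiR call data.frame, or \code{NULL} if unassigned.
#' @export
call_isomir <- function(placement, ref) {
  if (is.null(placement)) return(NULL)
  mt <- ref$matures[ref$matures$hairpin_id == placement$hairpin_id, ]
  if (!nrow(mt)) return(NULL)
  rs <- placement$start_on_hairpin
  re <- rs + placement$aligned_len  # 0-based half-open aligned interval
  ov <- pmin(re, mt$end) - pmax(rs, mt$start)
  cand <- which(ov >= 0.5 * (mt$end - mt$start))
  if (length(cand) != 1L) return(NULL)  # zero or ambiguous mature overlap
  mat <- mt[cand, ]

  offset5 <- rs - mat$start
  nta <- placement$overhang3
  offset3 <- (re + nchar(nta)) - mat$end
  templated3 <- !nzchar(nta)

  mm <- placement$mismatches
  if (nrow(mm)) {
    pos_mature <- rs + mm$pos_on_read - mat$start  # 1-based on mature
    ord <- order(pos_mature)
    snvs <- paste0(pos_mature[ord], mm$ref_base[ord], ">", mm$read_base[ord],
                   ":UNKNOWN", collapse = ",")
    snv_read_pos <- paste(mm$pos_on_read[ord], collapse = ",")
  } else {
    snvs <- ""
    snv_read_pos <- ""
  }

  shift5 <- offset5 != 0L
  shift3 <- offset3 != 0L || nzchar(nta)
  shift_class <- if (shift5 && shift3) "SHIFT53" else if (shift5) "SHIFT5" else if (shift3) "SHIFT3" else "NO_SHIFT"
  is_canonical <- offset5 == 0L && offset3 == 0L && !nzchar(nta) && !nzchar(snvs)
  variant_class <- if (nzchar(snvs)) "UNKNOWN" else "NONE"

  out <- data.frame(mature_name = mat$name, offset5 = as.integer(offset5),
                    offset3 = as.integer(offset3), templated3 = templated3,
                    nta_seq = nta, snvs = snvs, snv_read_pos = snv_read_pos,
                    shift_class = shift_class, variant_class = variant_class,
                    is_canonical = is_canonical, name = "",
                    stringsAsFactors = FALSE)
  out$name <- isomir_name(out)
  out$aligned_len <- placement$aligned_len
  out
}

# split an encoded SNV string "3A>G:UNKNOWN,10C>T:SNP" into a data.frame
.parse_snvs <- function(snvs) {
  if (!nzchar(snvs)) {
    return(data.frame(pos_on_mature = integer(), ref = character(),
                      alt = character(), annotation = character(),
                      in_seed = logical(), stringsAsFactors = FALSE))
  }
  parts <- strsplit(snvs, ",", fixed = TRUE)[[1L]]
  m <- regmatches(parts, regexec("^(-?[0-9]+)([ACGT])>([ACGT]):([A-Z_]+)$", parts))
  if (any(lengths(m) != 5L)) .stopf("malformed SNV field: %s", snvs)
  pos <- as.integer(vapply(m, `[`, "", 2L))
  data.frame(pos_on_mature = pos,
             ref = vapply(m, `[`, "", 3L),
             alt = vapply(m, `[`, "", 4L),
             annotation = vapply(m, `[`, "", 5L),
             in_seed = pos >= 2L & pos <= 7L,
             stringsAsFactors = FALSE)
}

.encode_snvs <- function(df) {
  if (!nrow(df)) return("")
  ord <- order(df$pos_on_mature, df$alt)
  paste0(df$pos_on_mature[ord], df$ref[ord], ">", df$alt[ord], ":",
         df$annotation[ord], collapse = ",")
}

#' Annotate call SNVs against the variant catalog
#'
#' Each SNV is labeled EDITING if it matches a catalogued A-to-I editing
#' record at that mature position (A to G; sequence alone never proves
#' editing), DNA_VARIANT if it matches a SNP or somatic record (position,
#' ref and alt), and UNKNOWN otherwise. The per-call variant-class set and
#' nomenclature string are recomputed; a call may carry several classes at
#' once.
#'
#' @param calls an isomiR call table.
#' @param ref a \code{\link{mirna_reference}} (its \code{variants} table is
#'   used) or a variant data.frame.
#' @return The call table with updated \code{snvs}, \code{variant_class}
#'   and \code{name}.
#' @export
annotate_variants <- function(calls, ref) {
  variants <- if (inherits(ref, "mirna_reference")) ref$variants else ref
  if (!nrow(calls)) return(calls)
  vkey_edit <- with(variants[variants$class == "EDITING", , drop = FALSE],
                    paste(mature_name, pos_on_mature, ref, alt))
  vkey_dna <- with(variants[variants$class %in% c("SNP", "SOMATIC"), , drop = FALSE],
                   paste(mature_name, pos_on_mature, ref, alt))
  for (i in which(nzchar(calls$snvs))) {
    sv <- .parse_snvs(calls$snvs[i])
    key <- paste(calls$mature_name[i], sv$pos_on_mature, sv$ref, sv$alt)
    sv$annotation <- ifelse(sv$ref == "A" & sv$alt == "G" & key %in% vkey_edit,
                            "EDITING",
                            ifelse(key %in% vkey_dna, "DNA_VARIANT", "UNKNOWN"))
    calls$snvs[i] <- .encode_snvs(sv)
    calls$variant_class[i] <- paste(sort(unique(sv$annotation)), collapse = ",")
  }
  calls$variant_class[!nzchar(calls$snvs)] <- "NONE"
  calls$name <- isomir_name(calls)
  calls
}

#' Discard isomiRs with unannotated terminal SNVs
#'
#' A call is discarded iff it has at least one SNV with annotation UNKNOWN
#' whose position lies in the first two or last two nucleotides of the
#' read-aligned region — the signature of linker-ligation imperfections and
#' sequencing errors rather than biology. Annotated (EDITING/DNA_VARIANT)
#' terminal SNVs are kept.
#'
#' @param calls an annotated isomiR call table with an \code{aligned_len}
#'   column (present on caller output; if absent, the span implied by the
#'   call's offsets is used).
#' @return list with elements \code{kept} and \code{discarded}; the two
#'   tables partition the input.
#' @export
filter_terminal_unannotated <- function(calls) {
  if (!nrow(calls)) return(list(kept = calls, discarded = calls))
  alen <- calls$aligned_len
  if (is.null(alen)) {
    .stopf("filter_terminal_unannotated: calls lack the aligned_len column (apply the filter to caller output)")
  }
  drop <- vapply(seq_len(nrow(calls)), function(i) {
    if (!nzchar(calls$snvs[i])) return(FALSE)
    sv <- .parse_snvs(calls$snvs[i])
    rp <- as.integer(strsplit(calls$snv_read_pos[i], ",", fixed = TRUE)[[1L]])
    any(sv$annotation == "UNKNOWN" & (rp <= 2L | rp >= alen[i] - 1L))
  }, NA)
  list(kept = calls[!drop, , drop = FALSE],
       discarded = calls[drop, , drop = FALSE])
}

#' Classify a call into the 16-category taxonomy
#'
#' Categories are the cross of the shift class (NO_SHIFT, SHIFT5, SHIFT3,
#' SHIFT53) with the variant label (NONE, DNA_VARIANT, EDITING, UNKNOWN).
#' A call with SNVs of several distinct labels contributes one cell per
#' label (multi-counting), mirroring how variant-bearing molecules are
#' summarized per category.
#'
#' @param call one row of an annotated call table.
#' @return list with \code{shift_class} (scalar) and \code{variant_classes}
#'   (character vector of the distinct labels).
#' @export
classify_isomir <- function(call) {
  stopifnot(nrow(call) == 1L)
  list(shift_class = call$shift_class,
       variant_classes = strsplit(call$variant_class, ",", fixed = TRUE)[[1L]])
}

#' Tabulate calls over the 16 shift-by-variant categories
#'
#' @param calls annotated call table.
#' @param weights optional per-call weights (e.g. read counts); default 1.
#' @return 4x4 integer matrix (rows: shift classes, columns: variant
#'   labels) with multi-class multiplicity, so its sum is >= the number
#'   (or total weight) of calls.
#' @export
isomir_category_table <- function(calls, weights = NULL) {
  shifts <- c("NO_SHIFT", "SHIFT5", "SHIFT3", "SHIFT53")
  vars <- c("NONE", "DNA_VARIANT", "EDITING", "UNKNOWN")
  tab <- matrix(0, 4L, 4L, dimnames = list(shifts, vars))
  if (!nrow(calls)) return(tab)
  if (is.null(weights)) weights <- rep(1, nrow(calls))
  for (i in seq_len(nrow(calls))) {
    vc <- strsplit(calls$variant_class[i], ",", fixed = TRUE)[[1L]]
    tab[calls$shift_class[i], vc] <- tab[calls$shift_class[i], vc] + weights[i]
  }
  tab
}

#' Deterministic isomiR nomenclature
#'
#' Builds the canonical name string
#' \code{<mature>|5p<offset5>|3p<offset3>|nta:<seq|->|snv:<pos><ref>><alt>:<class>[,...]|-}
#' (the final field is \code{-} when the call has no SNVs). The mapping is
#' injective over distinct (mature, offset5, offset3, nta_seq, SNV set)
#' tuples and is inverted by \code{\link{parse_isomir_name}}.
#'
#' @param calls an isomiR call table (any number of rows).
#' @return character vector of names, one per row.
#' @export
isomir_name <- function(calls) {
  snvf <- ifelse(nzchar(calls$snvs), paste0("snv:", calls$snvs), "-")
  ntaf <- ifelse(nzchar(calls$nta_seq), calls$nta_seq, "-")
  sprintf("%s|5p%d|3p%d|nta:%s|%s", calls$mature_name, calls$offset5,
          calls$offset3, ntaf, snvf)
}

#' Parse isomiR nomenclature strings
#'
#' @param names character vector of names produced by
#'   \code{\link{isomir_name}}.
#' @return data.frame with columns \code{mature_name, offset5, offset3,
#'   nta_seq, snvs, is_canonical, shift_class, variant_class, templated3,
#'   snv_read_pos, name} (the last three reconstructed as far as the name
#'   determines them).
#' @export
parse_isomir_name <- function(names) {
  parts <- strsplit(names, "|", fixed = TRUE)
  if (any(lengths(parts) != 5L)) .stopf("malformed isomiR name")
  f <- function(k) vapply(parts, `[`, "", k)
  offset5 <- as.integer(sub("^5p", "", f(2L)))
  offset3 <- as.integer(sub("^3p", "", f(3L)))
  nta <- sub("^nta:", "", f(4L))
  nta[nta == "-"] <- ""
  snvs <- f(5L)
  snvs <- ifelse(snvs == "-", "", sub("^snv:", "", snvs))
  variant_class <- vapply(snvs, function(s) {
    if (!nzchar(s)) return("NONE")
    paste(sort(unique(.parse_snvs(s)$annotation)), collapse = ",")
  }, "", USE.NAMES = FALSE)
  shift5 <- offset5 != 0L
  shift3 <- offset3 != 0L | nzchar(nta)
  df <- data.frame(
    mature_name = f(1L), offset5 = offset5, offset3 = offset3,
    templated3 = !nzchar(nta), nta_seq = nta, snvs = snvs,
    snv_read_pos = "",
    shift_class = ifelse(shift5 & shift3, "SHIFT53",
                         ifelse(shift5, "SHIFT5",
                                ifelse(shift3, "SHIFT3", "NO_SHIFT"))),
    variant_class = variant_class,
    is_canonical = !shift5 & !shift3 & !nzchar(snvs),
    name = names, stringsAsFactors = FALSE)
  df
}

#' Call isomiRs for a set of reads
#'
#' End-to-end driver: places each distinct read sequence, derives and
#' annotates its isomiR call, and returns one row per distinct read with
#' its aggregate count. Reads that cannot be placed, or whose placement
#' overlaps zero or two mature annotations, are dropped and tallied in the
#' attributes \code{n_unplaced} and \code{n_unassigned}.
#'
#' @param reads data.frame with columns \code{read, count} (e.g. from
#'   \code{\link{read_small_rna}}), or a character vector of read
#'   sequences (each counted once).
#' @param ref a \code{\link{mirna_reference}}.
#' @param max_mismatches,max_nta placement parameters (see
#'   \code{\link{place_read}}).
#' @return Annotated isomiR call table with a \code{count} column;
#'   attributes \code{n_unplaced} and \code{n_unassigned} give dropped
#'   read totals.
#' @export
call_isomirs <- function(reads, ref, max_mismatches = 2L, max_nta = 3L) {
  if (is.character(reads)) {
    reads <- data.frame(read = reads, count = 1L, stringsAsFactors = FALSE)
  }
  .require_cols(reads, c("read", "count"), "reads")
  reads$read <- .normalize_dna(reads$read)
  agg <- tapply(reads$count, reads$read, sum)
  seqs <- names(agg)
  idx <- .hairpin_index(ref)
  n_unplaced <- 0L
  n_unassigned <- 0L
  rows <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    pl <- .place_one(seqs[i], idx, as.integer(max_mismatches),
                     as.integer(max_nta))
    if (is.null(pl)) { n_unplaced <- n_unplaced + agg[[i]]; next }
    cl <- call_isomir(pl, ref)
    if (is.null(cl)) { n_unassigned <- n_unassigned + agg[[i]]; next }
    cl$count <- as.integer(agg[[i]])
    cl$read <- seqs[i]
    rows[[i]] <- cl
  }
  rows <- rows[!vapply(rows, is.null, NA)]
  calls <- if (length(rows)) do.call(rbind, rows) else {
    e <- .empty_call_table(); e$count <- integer(); e$read <- character();
    e$aligned_len <- integer(); e
  }
  calls <- annotate_variants(calls, ref)
  structure(calls, n_unplaced = n_unplaced, n_unassigned = n_unassigned)
}

#' Aggregate isomiR calls into a per-sample count vector
#'
#' @param calls annotated call table with a \code{count} column.
#' @return named integer vector: total count per isomiR name.
#' @export
tally_isomirs <- function(calls) {
  if (!nrow(calls)) return(stats::setNames(integer(), character()))
  out <- tapply(calls$count, calls$name, sum)
  stats::setNames(as.integer(out), names(out))
}
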