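#' Reference bundles: hairpins, mature annotations, variant catalogs
#'
#' A \code{mirna_reference} bundles the three tables the isomiR caller
#' needs: hairpin (precursor) sequences with genomic coordinates, mature
#' miRNA intervals on those hairpins, and a catalog of known single-base
#' variants (A-to-I editing sites, SNPs, somatic mutations) positioned on
#' the mature sequence.
#'
#' Coordinate conventions: hairpin-relative mature intervals are 0-based
#' half-open (unambiguous arithmetic); genomic coordinates are 1-based
#' inclusive. Sequences are normalized to the DNA alphabet (U -> T) on
#' ingest.
#'
#' @param hairpins data.frame with columns \code{id, sequence, chrom,
#'   genome_start, genome_end, strand}.
#' @param matures data.frame with columns \code{name, hairpin_id, start,
#'   end, arm} (start/end 0-based half-open on the hairpin).
#' @param variants data.frame with columns \code{mature_name,
#'   pos_on_mature, ref, alt, class}; \code{pos_on_mature} is 1-based on
#'   the mature sequence; \code{class} is one of EDITING, SNP, SOMATIC.
#'   EDITING records must be A->G (inosine is read as G by sequencers).
#' @return An object of class \code{mirna_reference}: a list with the three
#'   validated data.frames; \code{matures} gains a derived \code{sequence}
#'   column.
#' @export
mirna_reference <- function(hairpins, matures, variants = NULL) {
  .require_cols(hairpins, c("id", "sequence", "chrom", "genome_start",
                            "genome_end", "strand"), "hairpins")
  .require_cols(matures, c("name", "hairpin_id", "start", "end", "arm"),
                "matures")
  if (is.null(variants)) {
    variants <- data.frame(mature_name = character(), pos_on_mature = integer(),
                           ref = character(), alt = character(),
                           class = character(), stringsAsFactors = FALSE)
  }
  .require_cols(variants, c("mature_name", "pos_on_mature", "ref", "alt",
                            "class"), "variants")

  hairpins$sequence <- .normalize_dna(hairpins$sequence)
  if (any(nchar(hairpins$sequence) == 0L)) .stopf("empty hairpin sequence")
  .check_dna(hairpins$sequence, "hairpin")
  if (anyDuplicated(hairpins$id)) .stopf("duplicated hairpin ids")
  if (!all(hairpins$strand %in% c("+", "-"))) .stopf("hairpin strand must be + or -")
  span <- hairpins$genome_end - hairpins$genome_start + 1L
  bad <- span != nchar(hairpins$sequence)
  if (any(bad)) {
    .stopf("hairpin %s: genomic span %d != sequence length %d",
           hairpins$id[bad][1L], span[bad][1L],
           nchar(hairpins$sequence[bad][1L]))
  }

  if (anyDuplicated(matures$name)) .stopf("duplicated mature names")
  idx <- match(matures$hairpin_id, hairpins$id)
  if (anyNA(idx)) {
    row <- which(is.na(idx))[1L]
    .stopf("mature table row %d ('%s'): unknown hairpin_id '%s'",
           row, matures$name[row], matures$hairpin_id[row])
  }
  hlen <- nchar(hairpins$sequence)[idx]
  bad <- !(matures$start >= 0L & matures$start < matures$end &
             matures$end <= hlen)
  if (any(bad)) {
    row <- which(bad)[1L]
    .stopf("mature table row %d ('%s'): interval [%d,%d) out of range on hairpin of length %d",
           row, matures$name[row], matures$start[row], matures$end[row], hlen[row])
  }
  if (!all(matures$arm %in% c("5p", "3p"))) .stopf("mature arm must be 5p or 3p")
  matures$sequence <- substr(hairpins$sequence[idx], matures$start + 1L,
                             matures$end)

  if (nrow(variants)) {
    variants$ref <- .normalize_dna(variants$ref)
    variants$alt <- .normalize_dna(variants$alt)
    .check_dna(variants$ref, "variant ref")
    .check_dna(variants$alt, "variant alt")
    if (!all(variants$class %in% c("EDITING", "SNP", "SOMATIC"))) {
      .stopf("variant class must be EDITING, SNP or SOMATIC")
    }
    midx <- match(variants$mature_name, matures$name)
    if (anyNA(midx)) {
      row <- which(is.na(midx))[1L]
      .stopf("variant table row %d: unknown mature_name '%s'",
             row, variants$mature_name[row])
    }
    mlen <- nchar(matures$sequence)[midx]
    bad <- !(variants$pos_on_mature >= 1L & variants$pos_on_mature <= mlen)
    if (any(bad)) {
      row <- which(bad)[1L]
      .stopf("variant table row %d: position %d outside mature '%s' (length %d)",
             row, variants$pos_on_mature[row], variants$mature_name[row],
             mlen[row])
    }
    ed <- variants$class == "EDITING"
    if (any(ed & !(variants$ref == "A" & variants$alt == "G"))) {
      row <- which(ed & !(variants$ref == "A" & variants$alt == "G"))[1L]
      .stopf("variant table row %d: EDITING records must be A->G (got %s->%s)",
             row, variants$ref[row], variants$alt[row])
    }
    refbase <- substr(matures$sequence[midx], variants$pos_on_mature,
                      variants$pos_on_mature)
    if (any(refbase != variants$ref)) {
      row <- which(refbase != variants$ref)[1L]
      .stopf("variant table row %d: declared ref '%s' != mature base '%s' at position %d of '%s'",
             row, variants$ref[row], refbase[row], variants$pos_on_mature[row],
             variants$mature_name[row])
    }
  }

  structure(list(hairpins = hairpins, matures = matures, variants = variants),
            class = "mirna_reference")
}

#' @export
print.mirna_reference <- function(x, ...) {
  cat(sprintf("mirna_reference: %d hairpins, %d matures, %d variant records\n",
              nrow(x$hairpins), nrow(x$matures), nrow(x$variants)))
  invisible(x)
}

#' Read a miRNA reference bundle from disk
#'
#' Loads hairpin sequences (FASTA, headers
#' \code{id chrom:start-end:strand}), the mature annotation table and the
#' variant catalog, cross-validates them and returns a
#' \code{\link{mirna_reference}}. Dangling identifiers and out-of-range
#' coordinates are hard errors naming the offending row.
#'
#' @param hairpin_fasta path to the hairpin FASTA file.
#' @param mature_table path to the mature TSV (columns \code{name,
#'   hairpin_id, start, end, arm}; 0-based half-open).
#' @param variant_table optional path to the variant TSV (columns
#'   \code{mature_name, pos_on_mature, ref, alt, class}).
#' @return A validated \code{mirna_reference}.
#' @export
read_reference_bundle <- function(hairpin_fasta, mature_table,
                                  variant_table = NULL) {
  for (p in c(hairpin_fasta, mature_table, variant_table)) {
    if (!file.exists(p)) .stopf("file not found: %s", p)
  }
  seqs <- read_fasta(hairpin_fasta)
  hdr <- do.call(rbind, lapply(strsplit(names(seqs), "[ \t]+"), function(f) {
    if (length(f) != 5L) {
      .stopf("FASTA header must be 'id chrom start end strand': %s",
             paste(f, collapse = " "))
    }
    f
  }))
  hairpins <- data.frame(id = hdr[, 1L], sequence = unname(seqs),
                         chrom = hdr[, 2L],
                         genome_start = as.integer(hdr[, 3L]),
                         genome_end = as.integer(hdr[, 4L]),
                         strand = hdr[, 5L], stringsAsFactors = FALSE)
  matures <- .read_tsv(mature_table)
  .require_cols(matures, c("name", "hairpin_id", "start", "end", "arm"),
                basename(mature_table))
  matures$start <- as.integer(matures$start)
  matures$end <- as.integer(matures$end)
  variants <- if (!is.null(variant_table)) {
    v <- .read_tsv(variant_table)
    v$pos_on_mature <- as.integer(v$pos_on_mature)
    v
  }
  mirna_reference(hairpins, matures[, c("name", "hairpin_id", "start",
                                        "end", "arm")], variants)
}

#' Write a reference bundle to disk
#'
#' Inverse of \code{\link{read_reference_bundle}}: writes
#' \code{hairpins.fa}, \code{matures.tsv} and \code{variants.tsv} under
#' \code{dir}. Reading the written files back reproduces the bundle.
#'
#' @param ref a \code{mirna_reference}.
#' @param dir output directory (created if absent).
#' @return Invisibly, the three file paths (named list).
#' @export
write_reference_bundle <- function(ref, dir) {
  stopifnot(inherits(ref, "mirna_reference"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "hairpins.fa")
  h <- ref$hairpins
  headers <- sprintf("%s %s %d %d %s", h$id, h$chrom, h$genome_start,
                     h$genome_end, h$strand)
  write_fasta(stats::setNames(h$sequence, headers), fa)
  mt <- file.path(dir, "matures.tsv")
  .write_tsv(ref$matures[, c("name", "hairpin_id", "start", "end", "arm")], mt)
  vt <- file.path(dir, "variants.tsv")
  .write_tsv(ref$variants, vt)
  invisible(list(hairpin_fasta = fa, mature_table = mt, variant_table = vt))
}

#' Read a sample sheet
#'
#' Loads the per-sample metadata TSV: race (\code{W} or \code{BAA};
#' \code{B/AA} is accepted and normalized), tissue (\code{TUMOR} /
#' \code{NORMAL}) and optional right-censored overall-survival (OS) and
#' relapse-free-survival (RFS) fields. Each sample is assigned to one of
#' the four analysis groups W_N, W_T, BAA_N, BAA_T. A sample with a missing
#' time or event flag for an endpoint is excluded from that survival
#' analysis but retained for expression work (both fields are set NA).
#'
#' @param path TSV with columns \code{sample_id, race, tissue} and
#'   optionally \code{os_time, os_event, rfs_time, rfs_event}.
#' @return data.frame with validated columns plus a derived \code{group}
#'   factor with levels \code{W_N, W_T, BAA_N, BAA_T}.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  ss <- .read_tsv(path)
  .require_cols(ss, c("sample_id", "race", "tissue"), basename(path))
  if (anyDuplicated(ss$sample_id)) .stopf("duplicated sample_id in sample sheet")
  ss$race[ss$race == "B/AA"] <- "BAA"
  if (!all(ss$race %in% c("W", "BAA"))) {
    .stopf("unknown race token(s): %s",
           paste(unique(setdiff(ss$race, c("W", "BAA"))), collapse = ", "))
  }
  if (!all(ss$tissue %in% c("TUMOR", "NORMAL"))) {
    .stopf("unknown tissue token(s): %s",
           paste(unique(setdiff(ss$tissue, c("TUMOR", "NORMAL"))), collapse = ", "))
  }
  for (ep in c("os", "rfs")) {
    tcol <- paste0(ep, "_time"); ecol <- paste0(ep, "_event")
    if (!tcol %in% names(ss)) ss[[tcol]] <- NA_real_
    if (!ecol %in% names(ss)) ss[[ecol]] <- NA_integer_
    ss[[tcol]] <- as.numeric(ss[[tcol]])
    ss[[ecol]] <- as.integer(ss[[ecol]])
    if (any(ss[[tcol]] < 0, na.rm = TRUE)) .stopf("negative %s in sample sheet", tcol)
    if (!all(ss[[ecol]] %in% c(0L, 1L, NA_integer_))) {
      .stopf("%s must be 0/1 or missing", ecol)
    }
    # an endpoint is usable only when both fields are present
    partial <- is.na(ss[[tcol]]) != is.na(ss[[ecol]])
    if (any(partial)) {
      .warnf("%d sample(s) with partial %s fields; treated as missing",
             sum(partial), toupper(ep))
      ss[[tcol]][partial] <- NA_real_
      ss[[ecol]][partial] <- NA_integer_
    }
  }
  ss$group <- factor(paste(ss$race, substr(ss$tissue, 1L, 1L), sep = "_"),
                     levels = c("W_N", "W_T", "BAA_N", "BAA_T"))
  ss
}

#' Write isomiR calls in a mirGFF3-style dialect
#'
#' One 9-column GFF3 record per call; the attributes column carries the
#' deterministic nomenclature string (\code{Name=}) from
#' \code{\link{isomir_name}} plus enough auxiliary keys for a lossless
#' round trip through \code{\link{read_isomir_gff}}.
#'
#' @param calls an isomiR call table (see \code{\link{call_isomirs}}).
#' @param path output file.
#' @return Invisibly, \code{path}.
#' @export
write_isomir_gff <- function(calls, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##gff-version 3", "#isomirdisp isomiR calls"), con)
  if (nrow(calls)) {
    attrs <- sprintf(
      "ID=call%d;Name=%s;shift_class=%s;variant_class=%s;canonical=%s;templated3=%s;read_pos=%s",
      seq_len(nrow(calls)), calls$name, calls$shift_class,
      gsub(",", "|", calls$variant_class), as.integer(calls$is_canonical),
      as.integer(calls$templated3),
      ifelse(calls$snv_read_pos == "", "-", calls$snv_read_pos))
    lines <- paste(calls$mature_name, "isomirdisp", "isomiR",
                   "1", "1", ".", "+", ".", attrs, sep = "\t")
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read isomiR calls written by \code{\link{write_isomir_gff}}
#'
#' @param path GFF file produced by \code{\link{write_isomir_gff}}.
#' @return An isomiR call table equal (up to row order preserved by the
#'   writer) to the one written.
#' @export
read_isomir_gff <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (!length(lines)) return(.empty_call_table())
  fields <- do.call(rbind, strsplit(lines, "\t", fixed = TRUE))
  if (ncol(fields) != 9L) .stopf("malformed GFF: expected 9 columns")
  attr_get <- function(attrs, key) {
    m <- regmatches(attrs, regexec(paste0("(?:^|;)", key, "=([^;]*)"), attrs))
    vapply(m, function(x) if (length(x) == 2L) x[2L] else NA_character_, "")
  }
  name <- attr_get(fields[, 9L], "Name")
  parsed <- parse_isomir_name(name)
  parsed$templated3 <- attr_get(fields[, 9L], "templated3") == "1"
  rp <- attr_get(fields[, 9L], "read_pos")
  parsed$snv_read_pos <- ifelse(rp == "-", "", rp)
  parsed$shift_class <- attr_get(fields[, 9L], "shift_class")
  parsed$variant_class <- gsub("|", ",", attr_get(fields[, 9L], "variant_class"),
                               fixed = TRUE)
  parsed$is_canonical <- attr_get(fields[, 9L], "canonical") == "1"
  parsed[, .call_table_cols()]
}

#' Read a FASTA file into a named character vector
#'
#' Minimal single-purpose FASTA reader for hairpin references; sequences
#' may wrap over multiple lines.
#' @param path FASTA file.
#' @return Named character vector of sequences (full header as name).
#' @export
read_fasta <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  hdr <- grepl("^>", lines)
  if (!any(hdr)) .stopf("not a FASTA file: %s", path)
  if (!hdr[1L]) .stopf("FASTA must start with a '>' header: %s", path)
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]), paste0, "", collapse = "")
  stats::setNames(unname(seqs), sub("^>", "", lines[hdr]))
}

#' Write a named character vector as FASTA
#' @param seqs named character vector (names become headers).
#' @param path output file.
#' @return Invisibly, \code{path}.
#' @export
write_fasta <- function(seqs, path) {
  writeLines(paste0(">", names(seqs), "\n", unname(seqs)), path)
  invisible(path)
}

#' Read small-RNA reads from FASTQ or a read/count TSV
#'
#' FASTQ qualities are ignored (the caller never uses them). The TSV form
#' has columns \code{read} and \code{count} and represents pre-collapsed
#' reads.
#'
#' @param path FASTQ (\code{.fq}/\code{.fastq}) or TSV file.
#' @return data.frame with columns \code{read} (sequence) and \code{count}.
#' @export
read_small_rna <- function(path) {
  if (grepl("\\.(fq|fastq)$", path, ignore.case = TRUE)) {
    lines <- readLines(path)
    if (length(lines) %% 4L != 0L) .stopf("truncated FASTQ: %s", path)
    seqs <- .normalize_dna(lines[seq(2L, length(lines), by = 4L)])
    tab <- table(seqs)
    data.frame(read = names(tab), count = as.integer(tab),
               stringsAsFactors = FALSE)
  } else {
    df <- .read_tsv(path)
    .require_cols(df, c("read", "count"), basename(path))
    df$read <- .normalize_dna(df$read)
    df$count <- as.integer(df$count)
    df[, c("read", "count")]
  }
}
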