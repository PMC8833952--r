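# Hand-built toy reference used across the caller tests.
#
# Hairpin hp1 (60 nt), mature mat-5p = positions [10, 32) (22 nt):
#   mature sequence: ACAGTCCAGGAGTTCAGATTAC
#     seed (positions 2-7): C A G T C C  -> A at mature position 3
#   hairpin continuation after the mature 3' end: G T G C ...
# Variant catalog: EDITING at mat-5p position 3 (A>G),
#                  SNP at position 10 (G>A).
toy_reference <- function() {
  up <- "GGCTGACTT"                           # hairpin positions 1-9
  mature <- "ACAGTCCAGGAGTTCAGATTAC"          # positions 10-31 (1-based)
  down <- "GTGCAAGCTGGTCAGTAAGGCTCAACTGG"     # positions 32-60
  hairpins <- data.frame(
    id = "hp1", sequence = paste0(up, mature, down), chrom = "chr19",
    genome_start = 13836509L, genome_end = 13836509L + 59L, strand = "-",
    stringsAsFactors = FALSE)
  matures <- data.frame(name = "mat-5p", hairpin_id = "hp1",
                        start = 9L, end = 31L, arm = "5p",
                        stringsAsFactors = FALSE)
  variants <- data.frame(
    mature_name = "mat-5p", pos_on_mature = c(3L, 10L),
    ref = c("A", "G"), alt = c("G", "A"),
    class = c("EDITING", "SNP"), stringsAsFactors = FALSE)
  mirna_reference(hairpins, matures, variants)
}

toy_mature_seq <- function() "ACAGTCCAGGAGTTCAGATTAC"

# substitute a base at a 1-based position of a sequence
subst_base <- function(seq, pos, base) {
  substr(seq, pos, pos) <- base
  seq
}

# a count matrix whose library sizes are exactly 1e6, so RPM == counts:
# a filler row absorbs the remainder of each column.
rpm_exact_matrix <- function(counts) {
  counts <- as.matrix(counts)
  filler <- 1e6 - colSums(counts)
  stopifnot(all(filler >= 0))
  m <- rbind(counts, filler = filler)
  rownames(m) <- c(rownames(counts), "filler")
  count_matrix(m)
}
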