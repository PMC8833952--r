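ref <- toy_reference()
mat <- toy_mature_seq()
hp <- ref$hairpins$sequence

test_that("place_read finds exact substrings and peels non-templated overhang", {
  pl <- place_read(mat, ref)
  expect_equal(pl$hairpin_id, "hp1")
  expect_equal(pl$start_on_hairpin, 9L)
  expect_equal(pl$aligned_len, 22L)
  expect_equal(nrow(pl$mismatches), 0L)
  expect_equal(pl$overhang3, "")

  # hairpin continues with G after the mature; a trailing A is overhang
  pl2 <- place_read(paste0(mat, "A"), ref)
  expect_equal(pl2$overhang3, "A")
  expect_equal(pl2$aligned_len, 22L)

  # a read unlike any hairpin window yields no placement
  expect_null(place_read(strrep("ACGT", 5), ref))
  expect_error(place_read("", ref), "empty")
  expect_error(place_read("ACGTACGTACGT", ref), "15")
})

test_that("call_isomir computes offsets, templated extensions and SNVs", {
  canon <- call_isomir(place_read(mat, ref), ref)
  expect_equal(canon$shift_class, "NO_SHIFT")
  expect_true(canon$is_canonical)
  expect_equal(canon$offset5, 0L)
  expect_equal(canon$offset3, 0L)

  # +2 templated downstream bases (hairpin continues GT)
  ext <- call_isomir(place_read(paste0(mat, "GT"), ref), ref)
  expect_equal(ext$shift_class, "SHIFT3")
  expect_true(ext$templated3)
  expect_equal(ext$nta_seq, "")
  expect_equal(ext$offset3, 2L)

  # seed position 3 read as G
  edited <- call_isomir(place_read(subst_base(mat, 3, "G"), ref), ref)
  expect_equal(edited$shift_class, "NO_SHIFT")
  expect_equal(edited$snvs, "3A>G:UNKNOWN")
  expect_false(edited$is_canonical)

  # start 1 nt inside with non-templated AA: SHIFT53 (hand-checked: the
  # hairpin continues with G, so AA cannot be templated)
  s53 <- call_isomir(place_read(paste0(substr(mat, 2, 22), "AA"), ref), ref)
  expect_equal(s53$shift_class, "SHIFT53")
  expect_equal(s53$offset5, 1L)
  expect_equal(s53$nta_seq, "AA")
  expect_equal(s53$offset3, 2L)
  expect_false(s53$templated3)
})

test_that("annotate_variants labels EDITING only at catalogued sites", {
  calls <- rbind(
    call_isomir(place_read(subst_base(mat, 3, "G"), ref), ref),    # catalogued edit
    call_isomir(place_read(subst_base(mat, 10, "A"), ref), ref),   # catalogued SNP
    call_isomir(place_read(subst_base(mat, 12, "C"), ref), ref))   # nothing known
  ann <- annotate_variants(calls, ref)
  expect_equal(ann$variant_class, c("EDITING", "DNA_VARIANT", "UNKNOWN"))
  sv <- isomirdisp:::.parse_snvs(ann$snvs[1])
  expect_true(sv$in_seed)
  expect_equal(sv$annotation, "EDITING")
  # A>G at an uncatalogued position stays UNKNOWN: sequence alone never
  # proves editing
  ref_noed <- ref
  ref_noed$variants <- ref$variants[ref$variants$class != "EDITING", ]
  ann2 <- annotate_variants(calls[1, ], ref_noed)
  expect_equal(ann2$variant_class, "UNKNOWN")
})

test_that("terminal-unannotated filter drops exactly the artifact calls", {
  reads <- c(subst_base(mat, 1, "G"),    # unannotated SNV at read pos 1
             subst_base(mat, 5, "A"),    # internal unannotated SNV
             subst_base(mat, 21, "G"),   # unannotated SNV at read pos n-1
             subst_base(mat, 2, "G"))    # pos 2 but NOT catalogued (ref C)
  calls <- annotate_variants(
    do.call(rbind, lapply(reads, function(r) call_isomir(place_read(r, ref), ref))),
    ref)
  # an annotated terminal SNV is kept: plant the catalogued edit at pos 3
  # of a 5'-trimmed read where it sits at read position 1
  trimmed <- substr(subst_base(mat, 3, "G"), 3, 22)
  calls <- rbind(calls, annotate_variants(
    call_isomir(place_read(trimmed, ref), ref), ref))
  expect_equal(calls$snvs[5], "3A>G:EDITING")
  res <- filter_terminal_unannotated(calls)
  expect_equal(nrow(res$kept) + nrow(res$discarded), nrow(calls))
  expect_setequal(res$discarded$name, calls$name[c(1, 3, 4)])
  # partition: re-filtering the kept set is the identity
  again <- filter_terminal_unannotated(res$kept)
  expect_equal(again$kept, res$kept)
  expect_equal(nrow(again$discarded), 0L)
})

test_that("classification covers the 16 shift-by-variant categories", {
  canon <- annotate_variants(call_isomir(place_read(mat, ref), ref), ref)
  cl <- classify_isomir(canon)
  expect_equal(cl$shift_class, "NO_SHIFT")
  expect_equal(cl$variant_classes, "NONE")

  shifted_edit <- annotate_variants(
    call_isomir(place_read(paste0(subst_base(mat, 3, "G"), "G"), ref), ref), ref)
  cl2 <- classify_isomir(shifted_edit)
  expect_equal(cl2$shift_class, "SHIFT3")
  expect_equal(cl2$variant_classes, "EDITING")

  # one EDITING plus one UNKNOWN SNV -> both categories, so the category
  # table over-counts relative to the number of calls
  multi <- annotate_variants(
    call_isomir(place_read(subst_base(subst_base(mat, 3, "G"), 12, "C"), ref), ref),
    ref)
  cl3 <- classify_isomir(multi)
  expect_setequal(cl3$variant_classes, c("EDITING", "UNKNOWN"))
  tab <- isomir_category_table(rbind(canon, shifted_edit, multi))
  expect_equal(tab["NO_SHIFT", "EDITING"], 1)
  expect_equal(tab["NO_SHIFT", "UNKNOWN"], 1)
  expect_equal(sum(tab), 4)  # 3 calls, one counted twice
})

test_that("nomenclature is injective and round-trips", {
  canon <- call_isomir(place_read(mat, ref), ref)
  expect_equal(canon$name, "mat-5p|5p0|3p0|nta:-|-")

  cfg <- sim_config(seed = 23, read_depth = 1500)
  sref <- make_reference(cfg)
  calls <- call_isomirs(simulate_reads(sref, cfg)$reads$read, sref)
  parsed <- parse_isomir_name(calls$name)
  expect_equal(isomir_name(parsed), calls$name)
  expect_equal(parsed$mature_name, calls$mature_name)
  expect_equal(parsed$offset5, calls$offset5)
  expect_equal(parsed$offset3, calls$offset3)
  expect_equal(parsed$nta_seq, calls$nta_seq)
  expect_equal(parsed$shift_class, calls$shift_class)
  # distinct identity tuples get distinct names
  key <- with(calls, paste(mature_name, offset5, offset3, nta_seq, snvs))
  expect_equal(anyDuplicated(calls$name[!duplicated(key)]), 0L)
  # same tuple differing only in SNV class yields a different name
  a <- calls[match("EDITING", calls$variant_class), ]
  b <- a
  b$snvs <- sub("EDITING", "UNKNOWN", b$snvs)
  expect_false(isomir_name(b) == isomir_name(a))
})

test_that("reads overlapping no mature are unassigned and logged", {
  # a window in the downstream arm, away from the mature
  distal <- substr(hp, 38, 57)
  pl <- place_read(distal, ref)
  expect_equal(pl$aligned_len, 20L)
  expect_null(call_isomir(pl, ref))
  calls <- call_isomirs(c(mat, distal), ref)
  expect_equal(nrow(calls), 1L)
  expect_equal(attr(calls, "n_unassigned"), 1L)
})
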