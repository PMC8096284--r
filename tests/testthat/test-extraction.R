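ref16 <- "AAAACCCCGGGGTTTT"

test_that("reference-derived candidates enumerate junction and inner windows", {
  ref <- c(c = ref16)
  del <- sv_records("d", "c", 4, 8, "DEL")
  cand <- candidates_from_reference(ref, del, k = 4, flank = 4)
  ja <- cand$kmer[cand$role == "junction_alt"]
  # windows of the spliced haplotype "AAAAGGGG" straddling position 4
  expect_setequal(ja, canonical_kmer(c("AAAG", "AAGG", "AGGG")))
  expect_setequal(cand$kmer[cand$role == "inner_ref"], canonical_kmer("CCCC"))

  ins <- sv_records("i", "c", 8, 8, "INS", "TT")
  ci <- candidates_from_reference(ref, ins, k = 4, flank = 4)
  expect_equal(sum(ci$role == "inner_alt"), 0)  # |seq| < k
  # junction_alt: windows of "CCCCTTGGGG" overlapping either junction
  expect_setequal(ci$kmer[ci$role == "junction_alt"],
                  unique(canonical_kmer(c("CCCT", "CCTT", "CTTG", "TTGG",
                                          "TGGG"))))
  # an SV of length zero produces an identity haplotype: nothing alt-specific
  del0 <- sv_records("z", "c", 8, 8, "DEL")
  cz <- candidates_from_reference(ref, del0, k = 4, flank = 4)
  expect_equal(nrow(cz[endsWith(cz$role, "_alt"), ]), 0)
})

test_that("candidate neighbors are the windows at +-1 base in the source", {
  withr::with_seed(21, {
    ref <- c(c = random_dna(3000))
    sv <- sv_records("d", "c", 1000, 1200, "DEL")
    k <- 32
    cand <- candidates_from_reference(ref, sv, k = k)
    ir <- cand[cand$role == "inner_ref", ][1, ]
    # locate the k-mer in the reference and check its flanking windows
    alln <- naive_windows(ref[["c"]], k)
    pos <- which(vapply(alln, naive_canonical, character(1)) == ir$kmer)
    expect_length(pos, 1)
    expect_equal(ir$left_neighbor, naive_canonical(alln[pos - 1]))
    expect_equal(ir$right_neighbor, naive_canonical(alln[pos + 1]))
  })
})

test_that("reference-occurrence filter removes non-unique k-mers and is idempotent", {
  withr::with_seed(22, {
    base <- random_dna(3000)
    dup <- substr(base, 1021, 1080)  # 60 bp inside the deletion, repeated far away
    ref <- c(c = paste0(base, dup, random_dna(500)))
    sv <- sv_records("d", "c", 1000, 1150, "DEL")
    cand <- candidates_from_reference(ref, sv, k = 32)
    filt <- filter_reference_occurrences(cand, ref, sv, k = 32)
    # inner_ref k-mers fully inside the duplicated block occur twice -> removed
    dup_kmers <- canonical_kmer(naive_windows(dup, 32))
    expect_true(all(!filt$kmer %in% dup_kmers))
    expect_true(any(cand$kmer %in% dup_kmers))
    dropped <- attr(filt, "dropped")
    expect_true(all(dup_kmers %in% dropped$kmer))
    expect_match(dropped$reason[dropped$kmer %in% dup_kmers][1], "not unique")
    # idempotent
    again <- filter_reference_occurrences(filt, ref, sv, k = 32)
    expect_equal(again$kmer, filt$kmer)
    # on a clean random reference every candidate survives
    ref2 <- c(c = random_dna(10000))
    sv2 <- sv_records("d2", "c", 4000, 4200, "DEL")
    cand2 <- candidates_from_reference(ref2, sv2, k = 32)
    filt2 <- filter_reference_occurrences(cand2, ref2, sv2, k = 32)
    expect_equal(nrow(filt2), nrow(cand2))
  })
})

test_that("k-mers claimed by multiple SVs are dropped from all of them", {
  prof <- function(kmer, sv) data.frame(
    kmer = kmer, sv_id = sv, role = "junction_alt",
    left_neighbor = NA_character_, right_neighbor = NA_character_,
    copies_00 = 0, copies_01 = 1, copies_11 = 2, stringsAsFactors = FALSE)
  shared <- canonical_kmer("ACGTACGTAC")
  a <- canonical_kmer("AAAACCCCGG"); b <- canonical_kmer("TTTTGGGGCC")
  cands <- rbind(prof(shared, "sv1"), prof(a, "sv1"),
                 prof(shared, "sv2"), prof(b, "sv3"))
  out <- deduplicate_across_svs(cands)
  expect_setequal(out$kmer, unique(c(a, b)))
  # disjoint sets pass unchanged
  disj <- rbind(prof(a, "sv1"), prof(b, "sv2"))
  expect_equal(deduplicate_across_svs(disj), disj)
})

test_that("training filter keeps k-mers that genotype their SV correctly", {
  stats <- estimate_sample_stats(rep(c(28, 30, 32), 40))
  prof <- function(kmer, count_role = "inner_alt") data.frame(
    kmer = kmer, sv_id = "sv1", role = count_role,
    left_neighbor = NA_character_, right_neighbor = NA_character_,
    copies_00 = 0, copies_01 = 1, copies_11 = 2, stringsAsFactors = FALSE)
  cands <- rbind(prof("AAAATTTT"), prof("CCCCGGGG"))
  truth <- c(sv1 = "0/1")
  # count 14 predicts 0/1 (kept); 31 predicts 1/1 (a hidden paralog; removed)
  counts <- c(AAAATTTT = 14, CCCCGGGG = 31)
  out <- filter_by_training_genotype(cands, counts, stats, truth)
  expect_equal(out$kmer, "AAAATTTT")
  # unknown truth: vacuously kept
  out2 <- filter_by_training_genotype(cands, counts, stats, c(sv1 = NA))
  expect_equal(nrow(out2), 2)
})

test_that("soft-clipped reads yield junction candidates near breakpoints", {
  withr::with_seed(23, {
    dir <- withr::local_tempdir()
    read <- "ACGTTGCA"  # bases 0-3 aligned, 4-7 soft-clipped
    rec <- paste("r1", 0, "c", 101, 60, "4M4S", "*", 0, 0, read,
                 "IIIIIIII", sep = "\t")
    bam <- make_clipped_bam(dir, "c", 1000, rec)
    sv <- sv_records("d", "c", 104, 180, "DEL")  # breakpoint at clip point 104
    cand <- candidates_from_clipped_reads(bam, sv, k = 4, search_radius = 10)
    # read k-mers overlapping at least one clipped base: windows 2..5 (1-based)
    expect_setequal(cand$kmer,
                    unique(canonical_kmer(substring(read, 2:5, 5:8))))
    expect_true(all(cand$role == "junction_alt"))
    # no soft clips near the SV -> empty set with a warning
    far <- sv_records("f", "c", 500, 600, "DEL")
    expect_warning(none <- candidates_from_clipped_reads(bam, far, k = 4,
                                                         search_radius = 10),
                   "no soft-clipped")
    expect_equal(nrow(none), 0)
  })
})

test_that("extraction pipeline only removes candidates, never alters codes", {
  fx <- sim_fixture()
  cand <- candidates_from_reference(fx$ref, fx$svs, k = 32)
  filt <- filter_reference_occurrences(cand, fx$ref, fx$svs, k = 32)
  expect_true(all(filt$kmer %in% cand$kmer))
  dedup <- deduplicate_across_svs(filt)
  expect_true(all(dedup$kmer %in% filt$kmer))
})

test_that("panel k-mers re-counted on the training sample reproduce its genotypes", {
  fx <- sim_fixture()
  calls <- genotype_sample(fx$panel,
                           list(reads = c(fx$reads$read1, fx$reads$read2)))
  covered <- calls$sv_id[calls$n_kmers >= 1]
  expect_equal(calls$genotype[match(covered, calls$sv_id)],
               unname(fx$dip$truth[covered]))
})

test_that("control k-mers are unique, outside footprints, and depth-calibrated", {
  fx <- sim_fixture()
  ctrl <- fx$panel[fx$panel$role == "control", ]
  expect_gte(nrow(ctrl), 900)
  occ <- count_occurrences(unname(fx$ref), ctrl$kmer, 32)
  expect_true(all(occ == 1))
  expect_true(all(ctrl$copies_00 == 2 & ctrl$copies_11 == 2))
})
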