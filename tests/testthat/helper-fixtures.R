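# Shared simulated fixture, built once per test run: a 200 kb reference with
# 20 SVs, a 30x training sample and an independently genotyped test sample.

.fixture_env <- new.env(parent = emptyenv())

sim_fixture <- function() {
  if (!is.null(.fixture_env$fx)) return(.fixture_env$fx)
  ref <- c(chrSim = generate_reference(2e5, seed = 101))
  svs <- random_sv_set(ref, 20, k = 32, seed = 102)
  dip <- build_diploid(ref, svs, seed = 103)
  reads <- simulate_reads(dip, coverage = 30, seed = 104)
  panel <- extract_panel(ref, svs,
                         list(list(reads = c(reads$read1, reads$read2),
                                   truth = dip$truth)),
                         k = 32, n_control = 1000, seed = 105)
  svs_test <- svs
  svs_test$genotype <- withr::with_seed(106,
    sample(c("0/0", "0/1", "1/1"), nrow(svs), replace = TRUE))
  dip_test <- build_diploid(ref, svs_test, seed = 107)
  reads_test <- simulate_reads(dip_test, coverage = 30, seed = 108)
  .fixture_env$fx <- list(ref = ref, svs = svs, dip = dip, reads = reads,
                          panel = panel, svs_test = svs_test,
                          dip_test = dip_test, reads_test = reads_test)
  .fixture_env$fx
}

# a tiny SAM->BAM fixture: reads soft-clipped at a deletion breakpoint
make_clipped_bam <- function(dir, chrom, chrom_len, records) {
  sam <- file.path(dir, "clipped.sam")
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", chrom, chrom_len))
  writeLines(c(hdr, records), sam)
  Rsamtools::asBam(sam, file.path(dir, "clipped"),
                   overwrite = TRUE, indexDestination = TRUE)
}
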