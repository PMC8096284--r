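# Desk-scale replication of the evaluation protocol: a random reference, SV
# injection into a diploid genome, and a seeded wgsim-like paired-end read
# simulator (substitution errors only).

#' Generate a random reference sequence
#'
#' Uniform i.i.d. A/C/G/T, reproducible by seed. A random reference keeps the
#' whole evaluation download-free; it understates the repeat content of real
#' genomes, so tests on it bound the method's behavior on non-repetitive
#' loci only.
#'
#' @param length sequence length (>= 1).
#' @param seed optional RNG seed.
#' @return a single DNA string.
#' @export
generate_reference <- function(length, seed = NULL) {
  if (length < 1) stop("length must be >= 1")
  gen <- function() paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
                          collapse = "")
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Draw a random non-overlapping SV set with genotypes
#'
#' Places `n_svs` deletions/insertions (optionally inversions) with footprints
#' separated by at least `2*k` bases, lengths uniform in `sv_length_range`,
#' and genotypes drawn uniformly from `genotypes`. A training-style set uses
#' `genotypes = c("0/1", "1/1")` (every event present on the genome); a
#' test-style set also allows `"0/0"` (event in the panel, absent from the
#' genome).
#'
#' @param ref reference sequence (single contig string) or named vector; the
#'   first contig is used.
#' @param n_svs number of SVs.
#' @param sv_length_range min/max event length (bp).
#' @param svtype_mix named probabilities over `DEL`/`INS`/`INV`.
#' @param genotypes genotype states to draw from.
#' @param k k-mer length (sets the minimum separation `2*k`).
#' @param chrom contig name recorded in the records.
#' @param seed optional RNG seed.
#' @param max_tries placement retries before giving up.
#' @return [sv_records()] table with an extra `genotype` column.
#' @export
random_sv_set <- function(ref, n_svs, sv_length_range = c(50L, 500L),
                          svtype_mix = c(DEL = 0.5, INS = 0.5),
                          genotypes = c("0/1", "1/1"), k = 32L,
                          chrom = "chrSim", seed = NULL, max_tries = 1000L) {
  refseq <- if (!is.null(names(ref))) ref[[1]] else ref
  n <- nchar(refseq)
  min_gap <- 2L * k
  margin <- max(2L * k, 200L)
  draw <- function() {
    acc <- data.frame(start = integer(0), len = integer(0))
    for (try in seq_len(max_tries)) {
      need <- n_svs - nrow(acc)
      if (need <= 0) break
      len <- sample(seq.int(sv_length_range[1], sv_length_range[2]), need, TRUE)
      start <- floor(runif(need) * (n - 2 * margin - max(len))) + margin
      all <- rbind(acc, data.frame(start = start, len = len))
      all <- all[order(all$start), , drop = FALSE]
      keep <- logical(nrow(all))
      last_end <- -Inf
      for (i in seq_len(nrow(all))) {
        if (all$start[i] >= last_end + min_gap) {
          keep[i] <- TRUE
          last_end <- all$start[i] + all$len[i]
        }
      }
      acc <- all[keep, , drop = FALSE]
    }
    if (nrow(acc) < n_svs)
      stop(sprintf("could not place %d non-overlapping SVs (placed %d)",
                   n_svs, nrow(acc)))
    acc <- acc[seq_len(n_svs), , drop = FALSE]
    svtype <- sample(names(svtype_mix), n_svs, TRUE, prob = svtype_mix)
    gts <- sample(genotypes, n_svs, TRUE)
    ins_seq <- ifelse(svtype == "INS",
                      vapply(acc$len, function(l)
                        paste(sample(c("A", "C", "G", "T"), l, TRUE), collapse = ""),
                        character(1)), "")
    end <- ifelse(svtype == "INS", acc$start, acc$start + acc$len)
    svs <- sv_records(id = sprintf("sv%04d", seq_len(n_svs)), chrom = chrom,
                      start = acc$start, end = end, svtype = svtype,
                      inserted_seq = ins_seq)
    svs$genotype <- gts
    svs
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# splice a set of SVs (sorted by start, non-overlapping) into one haplotype
.apply_svs <- function(refseq, svs) {
  if (nrow(svs) == 0L) return(refseq)
  svs <- svs[order(svs$start), , drop = FALSE]
  n <- nchar(refseq)
  pieces <- character(0)
  pos <- 0L  # 0-based position consumed so far
  for (i in seq_len(nrow(svs))) {
    s <- svs$start[i]; e <- svs$end[i]
    pieces <- c(pieces, substr(refseq, pos + 1L, s))
    pieces <- c(pieces, switch(svs$svtype[i],
      DEL = "",
      INS = svs$inserted_seq[i],
      INV = revcomp(substr(refseq, s + 1L, e))))
    pos <- e
  }
  pieces <- c(pieces, substr(refseq, pos + 1L, n))
  paste(pieces, collapse = "")
}

#' Build a diploid genome carrying a genotyped SV set
#'
#' Applies 1/1 SVs to both haplotypes, 0/1 SVs to one haplotype chosen at
#' random, and 0/0 SVs to neither. SVs must be non-overlapping.
#'
#' @param ref reference contig string.
#' @param svs [random_sv_set()] output (with `genotype` column).
#' @param seed optional RNG seed for the heterozygous haplotype choice.
#' @return list of class `diploid_genome`: `hap1`, `hap2`, `svs`, `truth`
#'   (named genotype vector).
#' @export
build_diploid <- function(ref, svs, seed = NULL) {
  refseq <- if (!is.null(names(ref))) ref[[1]] else ref
  svs <- svs[order(svs$start), , drop = FALSE]
  if (nrow(svs) > 1 && any(svs$start[-1] < svs$end[-nrow(svs)]))
    stop("overlapping SVs")
  pick <- function() sample(1:2, sum(svs$genotype == "0/1"), replace = TRUE)
  het_hap <- if (is.null(seed)) pick() else withr::with_seed(seed, pick())
  hap_of <- matrix(FALSE, nrow(svs), 2)
  hap_of[svs$genotype == "1/1", ] <- TRUE
  het_rows <- which(svs$genotype == "0/1")
  for (j in seq_along(het_rows)) hap_of[het_rows[j], het_hap[j]] <- TRUE
  structure(list(
    hap1 = .apply_svs(refseq, svs[hap_of[, 1], , drop = FALSE]),
    hap2 = .apply_svs(refseq, svs[hap_of[, 2], , drop = FALSE]),
    svs = svs,
    truth = stats::setNames(svs$genotype, svs$id)), class = "diploid_genome")
}

#' Simulate paired-end reads from a diploid genome
#'
#' wgsim-like: fragments of normally distributed length are drawn uniformly
#' from both haplotypes (equal expected coverage per haplotype); mate 1 is
#' the fragment's leading bases, mate 2 the reverse complement of its
#' trailing bases; substitution errors are applied per base at
#' `base_error_rate` (no indel errors: k-mer counting is length-sensitive and
#' indel errors only depress counts slightly). The number of pairs is
#' `round(coverage * total_diploid_length / (2 * 2 * read_length))`.
#'
#' @param diploid a [build_diploid()] genome.
#' @param coverage mean per-base depth over the diploid genome.
#' @param read_length read length (bp).
#' @param fragment_mean,fragment_sd fragment length distribution (bp).
#' @param base_error_rate per-base substitution error probability.
#' @param seed optional RNG seed.
#' @return list `read1`, `read2`: character vectors of equal length.
#' @export
simulate_reads <- function(diploid, coverage, read_length = 100L,
                           fragment_mean = 400, fragment_sd = 50,
                           base_error_rate = 0.001, seed = NULL) {
  gen <- function() {
    haps <- c(diploid$hap1, diploid$hap2)
    hlen <- nchar(haps)
    total <- sum(hlen)
    if (any(hlen < fragment_mean)) stop("haplotype shorter than fragment length")
    n_pairs <- round(coverage * total / (2 * 2 * read_length))
    hap <- sample(1:2, n_pairs, replace = TRUE)
    flen <- pmax(round(rnorm(n_pairs, fragment_mean, fragment_sd)),
                 read_length)
    flen <- pmin(flen, hlen[hap])
    start <- floor(runif(n_pairs) * (hlen[hap] - flen + 1)) + 1L
    r1 <- character(n_pairs); r2 <- character(n_pairs)
    for (h in 1:2) {
      sel <- hap == h
      r1[sel] <- substring(haps[h], start[sel], start[sel] + read_length - 1L)
      r2[sel] <- substring(haps[h], start[sel] + flen[sel] - read_length,
                           start[sel] + flen[sel] - 1L)
    }
    r2 <- revcomp(r2)
    if (base_error_rate > 0) {
      reads <- c(r1, r2)
      n_err <- rbinom(1, length(reads) * read_length, base_error_rate)
      if (n_err > 0) {
        idx <- sample.int(length(reads), n_err, replace = TRUE)
        pos <- sample.int(read_length, n_err, replace = TRUE)
        shift <- sample.int(3L, n_err, replace = TRUE)
        reads <- .inject_errors(reads, idx, pos, shift)
      }
      r1 <- reads[seq_len(n_pairs)]
      r2 <- reads[n_pairs + seq_len(n_pairs)]
    }
    list(read1 = r1, read2 = r2)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Simulate a complete dataset on disk
#'
#' Runs [generate_reference()], [random_sv_set()], [build_diploid()] and
#' [simulate_reads()] under one top-level seed and writes `ref.fa`,
#' `svs.bed`, `truth.vcf`, `reads_1.fastq.gz`, `reads_2.fastq.gz` and a
#' `manifest.yaml` of all parameters to `dir`. All randomness descends from
#' `seed`: identical seeds give identical files.
#'
#' @param dir output directory (created if needed).
#' @param genome_length reference length (bp).
#' @param n_svs number of SVs.
#' @param sv_length_range min/max SV length.
#' @param svtype_mix named probabilities over DEL/INS/INV.
#' @param genotypes genotype states to draw from (training:
#'   `c("0/1","1/1")`; test: all three).
#' @param coverage,read_length,fragment_mean,fragment_sd,base_error_rate
#'   read-simulation parameters (see [simulate_reads()]).
#' @param k minimum-separation parameter for SV placement.
#' @param seed top-level seed.
#' @param ref optional pre-built reference (to share one reference between a
#'   training and a test dataset).
#' @param svs optional pre-built SV table (genotypes re-drawn if
#'   `regenotype = TRUE`).
#' @param regenotype redraw genotypes of a supplied `svs` from `genotypes`.
#' @return invisibly, a list with the in-memory `ref`, `svs`, `diploid`,
#'   `reads` and the file paths.
#' @export
simulate_dataset <- function(dir, genome_length = 5e6, n_svs = 300L,
                             sv_length_range = c(50L, 500L),
                             svtype_mix = c(DEL = 0.5, INS = 0.5),
                             genotypes = c("0/1", "1/1"), coverage = 30,
                             read_length = 100L, fragment_mean = 400,
                             fragment_sd = 50, base_error_rate = 0.001,
                             k = 32L, seed = 1L, ref = NULL, svs = NULL,
                             regenotype = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- derive_seeds(seed, 4)
  if (is.null(ref))
    ref <- c(chrSim = generate_reference(genome_length, seed = seeds[1]))
  if (is.null(svs)) {
    svs <- random_sv_set(ref, n_svs, sv_length_range, svtype_mix, genotypes,
                         k = k, chrom = names(ref)[1], seed = seeds[2])
  } else if (regenotype) {
    svs$genotype <- withr::with_seed(seeds[2],
                                     sample(genotypes, nrow(svs), TRUE))
  }
  diploid <- build_diploid(ref, svs, seed = seeds[3])
  reads <- simulate_reads(diploid, coverage, read_length, fragment_mean,
                          fragment_sd, base_error_rate, seed = seeds[4])
  paths <- list(ref = file.path(dir, "ref.fa"),
                bed = file.path(dir, "svs.bed"),
                truth = file.path(dir, "truth.vcf"),
                fastq = file.path(dir, c("reads_1.fastq.gz", "reads_2.fastq.gz")),
                manifest = file.path(dir, "manifest.yaml"))
  write_fasta(ref, paths$ref)
  write_sv_bed(svs, paths$bed)
  truth_calls <- data.frame(sv_id = svs$id, genotype = svs$genotype,
                            stringsAsFactors = FALSE)
  write_genotype_vcf(truth_calls, svs, ref, paths$truth)
  write_fastq(reads$read1, paths$fastq[1], suffix = "/1")
  write_fastq(reads$read2, paths$fastq[2], suffix = "/2")
  yaml::write_yaml(list(genome_length = genome_length, n_svs = nrow(svs),
                        sv_length_range = as.integer(sv_length_range),
                        svtype_mix = as.list(svtype_mix),
                        genotypes = genotypes, coverage = coverage,
                        read_length = as.integer(read_length),
                        fragment_mean = fragment_mean, fragment_sd = fragment_sd,
                        base_error_rate = base_error_rate, k = as.integer(k),
                        seed = as.integer(seed)), paths$manifest)
  invisible(list(ref = ref, svs = svs, diploid = diploid, reads = reads,
                 paths = paths))
}

#' Derive independent sub-seeds from one top-level seed
#'
#' @param seed top-level integer seed.
#' @param n number of sub-seeds.
#' @return integer vector of `n` seeds, all below 2^31.
#' @export
derive_seeds <- function(seed, n) {
  withr::with_seed(as.integer(seed), sample.int(.Machine$integer.max, n))
}
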