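# k-mer extraction: enumerate candidate k-mers whose copy number an SV
# changes, then filter them against the reference genome and against training
# samples with known genotypes. The surviving profiles form the genotyping
# panel.

.profile_df <- function(kmer, sv_id, role, left, right, svtype) {
  if (length(kmer) == 0L) return(.empty_profiles())
  ct <- expected_copy_table(role, svtype)
  data.frame(kmer = kmer, sv_id = sv_id, role = role,
             left_neighbor = left, right_neighbor = right,
             copies_00 = unname(ct["0/0"]), copies_01 = unname(ct["0/1"]),
             copies_11 = unname(ct["1/1"]), stringsAsFactors = FALSE)
}

.empty_profiles <- function() {
  data.frame(kmer = character(0), sv_id = character(0), role = character(0),
             left_neighbor = character(0), right_neighbor = character(0),
             copies_00 = numeric(0), copies_01 = numeric(0),
             copies_11 = numeric(0), stringsAsFactors = FALSE)
}

# windows of `seq` starting at 0-based positions `starts0`, with the adjacent
# windows at +-1 base as neighbors (NA at sequence edges); canonical forms
.windows_at <- function(seq, starts0, k) {
  n <- nchar(seq)
  starts0 <- starts0[starts0 >= 0 & starts0 + k <= n]
  if (length(starts0) == 0L)
    return(list(kmer = character(0), left = character(0), right = character(0)))
  s1 <- starts0 + 1L  # 1-based
  kmer <- canonical_kmer(substring(seq, s1, s1 + k - 1L))
  left <- ifelse(starts0 >= 1L,
                 canonical_kmer(substring(seq, s1 - 1L, s1 + k - 2L)), NA_character_)
  right <- ifelse(starts0 + k < n,
                  canonical_kmer(substring(seq, s1 + 1L, s1 + k)), NA_character_)
  keep <- !is.na(kmer)
  list(kmer = kmer[keep], left = left[keep], right = right[keep])
}

# 0-based window starts straddling a boundary b (between positions b-1 and b)
.straddling <- function(b, k) seq.int(b - k + 1L, b - 1L)

#' Candidate k-mers for an SV from the reference sequence
#'
#' Emits, per SV: junction k-mers of the alternate haplotype (windows of the
#' spliced sequence straddling a novel junction), junction k-mers of the
#' reference destroyed by the event (windows straddling a breakpoint), inner
#' reference k-mers for deletions (windows fully inside the deleted region)
#' and inner alternate k-mers for insertions (windows fully inside the
#' inserted sequence). Each profile stores its immediate left/right neighbor
#' windows in the source haplotype and its expected copy table. SVs shorter
#' than k simply yield no inner k-mers. Within one SV, a canonical code
#' appearing with both alt- and ref-derived roles is contradictory and is
#' dropped.
#'
#' @param ref named character vector of contig sequences.
#' @param svs an [sv_records()] table.
#' @param k k-mer length.
#' @param flank flank width used to build the alternate window; at least k
#'   so every junction k-mer has neighbors on both sides.
#' @return profile data.frame (columns `kmer`, `sv_id`, `role`,
#'   `left_neighbor`, `right_neighbor`, `copies_00`, `copies_01`,
#'   `copies_11`).
#' @export
candidates_from_reference <- function(ref, svs, k = 32L, flank = k + 1L) {
  if (flank < k - 1) stop("flank must be >= k-1")
  out <- lapply(seq_len(nrow(svs)), function(i) {
    sv <- svs[i, , drop = FALSE]
    refseq <- ref[[sv$chrom]]
    if (is.null(refseq)) stop("contig not in reference: ", sv$chrom)
    s <- sv$start; e <- sv$end
    alt <- alt_haplotype_window(refseq, sv, flank)
    lflank <- min(flank, s)  # truncation at contig start
    mid_len <- switch(sv$svtype, DEL = 0L, INS = nchar(sv$inserted_seq),
                      INV = e - s)
    alt_bounds <- switch(sv$svtype,
      DEL = lflank,
      INS = c(lflank, lflank + mid_len),
      INV = c(lflank, lflank + mid_len))
    ref_bounds <- switch(sv$svtype, DEL = c(s, e), INS = s, INV = c(s, e))

    ja <- .windows_at(alt, unique(unlist(lapply(alt_bounds, .straddling, k = k))), k)
    jr <- .windows_at(refseq, unique(unlist(lapply(ref_bounds, .straddling, k = k))), k)
    parts <- list(
      .profile_df(ja$kmer, sv$id, "junction_alt", ja$left, ja$right, sv$svtype),
      .profile_df(jr$kmer, sv$id, "junction_ref", jr$left, jr$right, sv$svtype))
    if (sv$svtype == "DEL" && e - s >= k) {
      ir <- .windows_at(refseq, seq.int(s, e - k), k)
      parts <- c(parts, list(.profile_df(ir$kmer, sv$id, "inner_ref",
                                         ir$left, ir$right, sv$svtype)))
    }
    if (sv$svtype == "INS" && mid_len >= k) {
      # positions of the inserted block within the alt window
      ia <- .windows_at(alt, seq.int(lflank, lflank + mid_len - k), k)
      parts <- c(parts, list(.profile_df(ia$kmer, sv$id, "inner_alt",
                                         ia$left, ia$right, sv$svtype)))
    }
    df <- do.call(rbind, parts)
    # drop within-SV contradictions (same code as both alt- and ref-derived)
    alt_codes <- df$kmer[endsWith(df$role, "_alt")]
    ref_codes <- df$kmer[endsWith(df$role, "_ref")]
    both <- intersect(alt_codes, ref_codes)
    df <- df[!df$kmer %in% both, , drop = FALSE]
    df[!duplicated(df$kmer), , drop = FALSE]
  })
  do.call(rbind, out)
}

#' Candidate k-mers from soft-clipped reads near SV breakpoints
#'
#' Reads crossing an SV breakpoint are soft-clipped when mapped to the
#' reference; their clipped tails spell the alternate-haplotype junction even
#' when the input coordinates are only approximate. This collects alignments
#' whose clip point lies within `search_radius` of either breakpoint and
#' emits every read k-mer overlapping at least one clipped base, with
#' neighbors taken from the read and an alt-derived copy table.
#'
#' @param bam path to an indexed, sorted BAM.
#' @param sv one row of an [sv_records()] table.
#' @param k k-mer length.
#' @param search_radius max distance (bp) between clip point and breakpoint.
#' @return profile data.frame (role `junction_alt`); empty, with a warning,
#'   when no clipped reads are found.
#' @export
candidates_from_clipped_reads <- function(bam, sv, k = 32L, search_radius = 100L) {
  stopifnot(nrow(sv) == 1L)
  bps <- if (sv$svtype == "INS") sv$start else c(sv$start, sv$end)
  which <- GenomicRanges::GRanges(sv$chrom, IRanges::IRanges(
    pmax(1L, min(bps) - search_radius), max(bps) + search_radius + 1L))
  param <- Rsamtools::ScanBamParam(what = c("pos", "cigar", "seq"), which = which)
  res <- tryCatch(Rsamtools::scanBam(bam, param = param)[[1]],
                  error = function(e) stop("region fetch failed for contig ",
                                           sv$chrom, ": ", conditionMessage(e)))
  parts <- list()
  for (i in seq_along(res$pos)) {
    cigar <- res$cigar[i]
    if (is.na(cigar) || !grepl("S", cigar, fixed = TRUE)) next
    seq <- as.character(res$seq[i])
    len <- nchar(seq)
    lead <- if (grepl("^\\d+S", cigar))
      as.integer(sub("^(\\d+)S.*", "\\1", cigar)) else 0L
    trail <- if (grepl("[A-Z=]\\d+S$", cigar))
      as.integer(sub(".*[A-Z=](\\d+)S$", "\\1", cigar)) else 0L
    ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
    oplen <- as.integer(sub("[A-Z=]", "", ops))
    opchr <- sub("\\d+", "", ops)
    ref_consumed <- sum(oplen[opchr %in% c("M", "D", "N", "=", "X")])
    pos0 <- res$pos[i] - 1L  # 0-based position of first aligned base
    starts <- integer(0)
    if (lead > 0 && any(abs(pos0 - bps) <= search_radius))
      starts <- c(starts, seq.int(0L, min(lead - 1L, len - k)))
    if (trail > 0 && any(abs(pos0 + ref_consumed - bps) <= search_radius))
      starts <- c(starts, seq.int(max(0L, len - trail - k + 1L), len - k))
    starts <- unique(starts[starts >= 0 & starts + k <= len])
    if (length(starts) == 0L) next
    w <- .windows_at(seq, starts, k)
    parts[[length(parts) + 1L]] <-
      .profile_df(w$kmer, sv$id, "junction_alt", w$left, w$right, sv$svtype)
  }
  if (length(parts) == 0L) {
    warning("no soft-clipped reads near breakpoints of ", sv$id)
    return(.empty_profiles())
  }
  df <- do.call(rbind, parts)
  df[!duplicated(df$kmer), , drop = FALSE]
}

# footprint windows: SV interval +- (k-1) bases, as substrings per SV
.footprint_seqs <- function(ref, svs, k) {
  vapply(seq_len(nrow(svs)), function(i) {
    sv <- svs[i, , drop = FALSE]
    refseq <- ref[[sv$chrom]]
    substr(refseq, max(1L, sv$start - k + 2L), min(nchar(refseq), sv$end + k - 1L))
  }, character(1))
}

#' Reference-occurrence filter
#'
#' Counts each candidate's occurrences across the whole reference
#' (canonically, both strands) and keeps only candidates whose occurrences
#' all lie inside the footprint windows (SV interval plus k-1 bases on each
#' side) of the input SVs: alt-derived k-mers must not occur anywhere outside
#' those windows, and reference-derived k-mers must occur exactly once, at
#' their own locus. Idempotent; removed candidates can be inspected via the
#' `dropped` attribute.
#'
#' @param candidates profile data.frame.
#' @param ref named character vector of contig sequences.
#' @param all_svs the full [sv_records()] table defining impacted loci.
#' @param k k-mer length.
#' @return filtered profile data.frame.
#' @export
filter_reference_occurrences <- function(candidates, ref, all_svs,
                                         k = nchar(candidates$kmer[1])) {
  if (nrow(candidates) == 0L) return(candidates)
  occ_total <- count_occurrences(unname(unlist(ref)), candidates$kmer, k)
  occ_inside <- count_occurrences(.footprint_seqs(ref, all_svs, k),
                                  candidates$kmer, k)
  is_alt <- endsWith(candidates$role, "_alt")
  keep <- ifelse(is_alt, occ_total == occ_inside, occ_total == 1)
  out <- candidates[keep, , drop = FALSE]
  attr(out, "dropped") <- data.frame(
    kmer = candidates$kmer[!keep], sv_id = candidates$sv_id[!keep],
    reason = ifelse(is_alt[!keep], "occurs outside SV footprints",
                    "not unique in reference"), stringsAsFactors = FALSE)
  out
}

#' Drop k-mers shared between SVs
#'
#' A canonical code claimed by more than one SV cannot be attributed to
#' either; it is removed from all of them.
#'
#' @param candidates profile data.frame.
#' @return filtered profile data.frame.
#' @export
deduplicate_across_svs <- function(candidates) {
  if (nrow(candidates) == 0L) return(candidates)
  tab <- table(unique(candidates[, c("kmer", "sv_id")])$kmer)
  shared <- names(tab)[tab > 1]
  candidates[!candidates$kmer %in% shared, , drop = FALSE]
}

# keep at most `cap` k-mers per SV, junction roles first
.cap_per_sv <- function(candidates, cap = 64L) {
  if (nrow(candidates) == 0L || is.infinite(cap)) return(candidates)
  prio <- match(candidates$role,
                c("junction_alt", "junction_ref", "inner_alt", "inner_ref"))
  ord <- order(candidates$sv_id, prio)
  ranked <- candidates[ord, , drop = FALSE]
  sel <- stats::ave(seq_len(nrow(ranked)), ranked$sv_id, FUN = seq_along) <= cap
  out <- ranked[sel, , drop = FALSE]
  out[order(match(out$kmer, candidates$kmer)), , drop = FALSE]
}

#' Sample unique control k-mers for depth estimation
#'
#' Draws k-mers from reference loci outside every SV footprint, verified to
#' occur exactly once in the reference (canonically), to serve as
#' diploid-unique depth controls (the role conserved exonic k-mers play on
#' real genomes). Controls carry their reference neighbors so they are
#' counted under the same verification regime as SV k-mers.
#'
#' @param ref named character vector of contig sequences.
#' @param svs [sv_records()] table whose footprints are excluded.
#' @param k k-mer length.
#' @param n number of control k-mers to return.
#' @param exclude canonical codes that may not be used (e.g. SV candidates).
#' @param seed optional RNG seed.
#' @return profile data.frame with role `"control"`, sv_id `"."` and a
#'   constant copy table of 2 (present on both haplotypes in any genotype).
#' @export
sample_control_kmers <- function(ref, svs, k = 32L, n = 10000L,
                                 exclude = character(0), seed = NULL) {
  draw <- function() {
    picked <- .empty_profiles()
    for (attempt in 1:20) {
      need <- n - nrow(picked)
      if (need <= 0) break
      # oversample, then keep the verified-unique ones
      m <- max(200L, 3L * need)
      contig <- sample(names(ref), m, replace = TRUE,
                       prob = nchar(ref) / sum(nchar(ref)))
      pos0 <- floor(runif(m) * (nchar(ref)[contig] - k - 1)) + 1L
      keepfree <- rep(TRUE, m)
      for (i in seq_len(nrow(svs))) {
        sv <- svs[i, , drop = FALSE]
        hit <- contig == sv$chrom & pos0 + k > sv$start - k + 1 & pos0 < sv$end + k - 1
        keepfree[hit] <- FALSE
      }
      contig <- contig[keepfree]; pos0 <- pos0[keepfree]
      parts <- lapply(unique(contig), function(cn) {
        w <- .windows_at(ref[[cn]], pos0[contig == cn], k)
        .profile_df(w$kmer, ".", "junction_alt", w$left, w$right, "DEL")
      })
      cand <- do.call(rbind, parts)
      if (is.null(cand) || nrow(cand) == 0L) next
      cand <- cand[!duplicated(cand$kmer), , drop = FALSE]
      cand <- cand[!cand$kmer %in% c(exclude, picked$kmer), , drop = FALSE]
      if (nrow(cand) == 0L) next
      occ <- count_occurrences(unname(unlist(ref)), cand$kmer, k)
      cand <- cand[occ == 1, , drop = FALSE]
      picked <- rbind(picked, utils::head(cand, need))
    }
    if (nrow(picked) < n)
      warning(sprintf("only %d of %d requested control k-mers found", nrow(picked), n))
    picked$role <- "control"
    picked$copies_00 <- picked$copies_01 <- picked$copies_11 <- 2
    picked
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Training-genotype concordance filter
#'
#' Uses each candidate k-mer on its own to genotype its SV on a training
#' sample with known genotypes, and keeps only candidates whose single-k-mer
#' maximum-likelihood genotype matches the known genotype in every training
#' sample where the SV's genotype is known. Candidates of SVs with no known
#' genotype anywhere pass unchanged.
#'
#' @param candidates profile data.frame.
#' @param counts named count vector of the candidates on the training sample.
#' @param stats [estimate_sample_stats()] of the training sample.
#' @param truth named character vector sv_id -> genotype (`NA` = unknown).
#' @return filtered profile data.frame.
#' @export
filter_by_training_genotype <- function(candidates, counts, stats, truth) {
  if (nrow(candidates) == 0L) return(candidates)
  tr <- truth[candidates$sv_id]
  cnt <- counts[candidates$kmer]
  cnt[is.na(cnt)] <- 0
  cnt <- pmin(cnt, 2 * stats$mu)
  copies <- as.matrix(candidates[, c("copies_00", "copies_01", "copies_11")])
  ll <- .loglik_matrix(unname(cnt), copies, stats)
  pred <- GENOTYPES[max.col(ll, ties.method = "first")]
  keep <- is.na(tr) | pred == tr
  candidates[keep, , drop = FALSE]
}

#' Run the full k-mer extraction phase
#'
#' Generates candidates from the reference (optionally augmented with
#' soft-clipped-read candidates from training BAMs), applies the
#' reference-occurrence filter, removes k-mers shared between SVs, caps the
#' per-SV k-mer count (junction k-mers preferred), counts the survivors on
#' each training sample and applies the genotype-concordance filter, and
#' appends unique control k-mers for depth estimation. The result is the
#' genotyping panel.
#'
#' @param ref named character vector of contig sequences.
#' @param svs an [sv_records()] table.
#' @param training list of training samples; each a list with `truth` (named
#'   genotype vector) and one of `reads` (character vector), `fastq`
#'   (file paths) or `bam` (file path).
#' @param k k-mer length (default 32: one 64-bit word).
#' @param flank flank width for alternate windows.
#' @param cap maximum k-mers kept per SV.
#' @param n_control number of control k-mers.
#' @param use_clipped also harvest candidates from soft-clipped reads of
#'   training BAMs (requires `bam` entries).
#' @param search_radius clip-point search radius (bp) for the clipped path.
#' @param verify_neighbors apply neighbor verification while counting.
#' @param seed RNG seed for control-k-mer sampling.
#' @return panel data.frame (SV profiles plus `control` rows), with
#'   attributes `k` and `extraction` (a summary list with the per-SV
#'   extraction rate and per-filter drop counts).
#' @export
extract_panel <- function(ref, svs, training, k = 32L, flank = k + 1L,
                          cap = 64L, n_control = 10000L, use_clipped = FALSE,
                          search_radius = 100L, verify_neighbors = TRUE,
                          seed = NULL) {
  k <- as.integer(k)
  cand <- candidates_from_reference(ref, svs, k, flank)
  n0 <- nrow(cand)
  if (use_clipped) {
    for (ts in training) {
      if (is.null(ts$bam)) next
      clipped <- do.call(rbind, lapply(seq_len(nrow(svs)), function(i)
        candidates_from_clipped_reads(ts$bam, svs[i, , drop = FALSE], k,
                                      search_radius)))
      if (!is.null(clipped) && nrow(clipped)) {
        cand <- rbind(cand, clipped)
        # union of reference- and read-derived candidates, first wins per code
        cand <- cand[!duplicated(cand[, c("kmer", "sv_id")]), , drop = FALSE]
      }
    }
  }
  cand <- filter_reference_occurrences(cand, ref, svs, k)
  n_ref <- nrow(cand)
  cand <- deduplicate_across_svs(cand)
  n_dedup <- nrow(cand)
  cand <- .cap_per_sv(cand, cap)
  controls <- sample_control_kmers(ref, svs, k, n_control,
                                   exclude = cand$kmer, seed = seed)
  index <- kmer_index(c(cand$kmer, controls$kmer),
                      c(.neighbor_list(cand), .neighbor_list(controls)), k)
  for (ts in training) {
    counts <- .count_sample(ts, index, verify_neighbors)
    stats <- estimate_sample_stats(unname(counts[controls$kmer]))
    cand <- filter_by_training_genotype(cand, counts, stats, ts$truth)
  }
  n_train <- nrow(cand)
  panel <- rbind(cand, controls)
  rownames(panel) <- NULL
  genotypeable <- unique(cand$sv_id)
  attr(panel, "k") <- k
  attr(panel, "extraction") <- list(
    n_svs = nrow(svs), n_genotypeable = length(genotypeable),
    rate = length(genotypeable) / nrow(svs),
    missing_svs = setdiff(svs$id, genotypeable),
    n_candidates = n0, n_after_reference_filter = n_ref,
    n_after_dedup = n_dedup, n_after_training_filter = n_train)
  panel
}

.neighbor_list <- function(profiles) {
  lapply(seq_len(nrow(profiles)), function(i)
    c(profiles$left_neighbor[i], profiles$right_neighbor[i]))
}

# count a training/target sample given as in-memory reads, FASTQ or BAM
.count_sample <- function(sample, index, verify_neighbors = TRUE) {
  if (!is.null(sample$reads))
    count_reads(sample$reads, index, verify_neighbors)
  else if (!is.null(sample$fastq))
    count_fastq(sample$fastq, index, verify_neighbors)
  else if (!is.null(sample$bam))
    count_bam(sample$bam, index, verify_neighbors)
  else stop("sample must have one of: reads, fastq, bam")
}

#' Genotype a sample against an extracted panel
#'
#' Counts the panel's k-mers in the sample's reads (neighbor-verified),
#' estimates depth statistics from the panel's control k-mers and calls every
#' SV by maximum likelihood.
#'
#' @param panel panel data.frame from [extract_panel()] / [read_panel()].
#' @param sample list with one of `reads`, `fastq`, `bam` (as in
#'   [extract_panel()]).
#' @param verify_neighbors apply neighbor verification while counting.
#' @return calls data.frame from [call_genotypes()], with the sample's
#'   [estimate_sample_stats()] in attribute `stats`.
#' @export
genotype_sample <- function(panel, sample, verify_neighbors = TRUE) {
  k <- attr(panel, "k")
  if (is.null(k)) k <- nchar(panel$kmer[1])
  index <- kmer_index(panel$kmer, .neighbor_list(panel), k)
  counts <- .count_sample(sample, index, verify_neighbors)
  call_genotypes(panel, counts)
}
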