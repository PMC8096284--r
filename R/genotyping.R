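# Genotype likelihoods from k-mer counts.
#
# The count of a k-mer present at a single diploid locus is modeled as the sum
# of two per-haplotype normals; the sample-wide mean mu and variance sigma2 of
# that sum are estimated from control k-mers (unique k-mers outside all SV
# footprints). A k-mer present on one haplotype then has count ~ N(mu/2,
# sigma2/2); a k-mer absent from the genome has mean 0 with a small fixed
# variance. Genotypes are called by maximizing the product of per-k-mer
# normal densities over a SV's k-mers (independence approximation).

#' Estimate sample-wide depth statistics from control k-mer counts
#'
#' Trims the top and bottom 2.5\% of the counts (guarding against collapsed
#' repeats and dropped loci) and returns the mean and variance of the rest.
#'
#' @param control_counts integer counts of diploid-unique control k-mers in
#'   the sample's reads; at least 2 values.
#' @param trim fraction trimmed from each tail.
#' @param min_var variance floor (degenerate all-equal counts).
#' @param min_mu mean floor; a zero mean indicates a sample/panel mismatch.
#' @return object of class `sample_stats`: list with `mu`, `sigma2`,
#'   `n_control`.
#' @examples
#' estimate_sample_stats(c(28, 30, 32)) # mu 30, sigma2 4
#' @export
estimate_sample_stats <- function(control_counts, trim = 0.025,
                                  min_var = 1.0, min_mu = 0.1) {
  counts <- as.numeric(control_counts)
  if (length(counts) < 2L) stop("need at least 2 control counts")
  if (all(counts == 0)) stop("all control k-mer counts are zero: sample/panel mismatch?")
  if (length(counts) < 100L)
    warning("fewer than 100 control k-mers; depth estimate may be unstable")
  ndrop <- floor(length(counts) * trim)
  if (ndrop > 0) {
    counts <- sort(counts)
    counts <- counts[(ndrop + 1L):(length(counts) - ndrop)]
  }
  structure(list(mu = max(mean(counts), min_mu),
                 sigma2 = max(var(counts), min_var),
                 n_control = length(counts)),
            class = "sample_stats")
}

#' @export
print.sample_stats <- function(x, ...) {
  cat(sprintf("sample_stats: mu = %.2f, sigma2 = %.2f (n = %d control k-mers)\n",
              x$mu, x$sigma2, x$n_control))
  invisible(x)
}

#' Normal model for a k-mer count at a given diploid copy number
#'
#' Copy 2 (both haplotypes): `N(mu, sigma2)`. Copy 1 (one haplotype):
#' `N(mu/2, sigma2/2)` (half of the two-haplotype sum). Copy 0 (absent from
#' the genome): mean 0 with small fixed variance `max(1, (mu/10)^2)`, which
#' keeps the absent model tight but scales mildly with depth so that stray
#' error k-mers at high coverage are not over-penalized.
#'
#' @param copy expected diploid copy number, 0, 1 or 2.
#' @param stats a [estimate_sample_stats()] object.
#' @return numeric vector `c(mean =, variance =)`.
#' @export
genotype_distribution <- function(copy, stats) {
  stopifnot(inherits(stats, "sample_stats"))
  if (!copy %in% c(0, 1, 2)) stop("copy must be 0, 1 or 2")
  mu <- stats$mu; s2 <- stats$sigma2
  switch(as.character(copy),
    "2" = c(mean = mu, variance = s2),
    "1" = c(mean = mu / 2, variance = s2 / 2),
    "0" = c(mean = 0, variance = max(1, (mu / 10)^2)))
}

# vectorized genotype log-likelihood matrix: counts (already capped) x copies
# per genotype; copies is an n x 3 matrix with columns 0/0, 0/1, 1/1
.loglik_matrix <- function(counts, copies, stats) {
  mu <- stats$mu; s2 <- stats$sigma2
  eps <- max(1, (mu / 10)^2)
  mean_of <- c(0, mu / 2, mu)          # indexed by copy + 1
  var_of <- c(eps, s2 / 2, s2)
  ll <- matrix(NA_real_, nrow = length(counts), ncol = 3,
               dimnames = list(NULL, GENOTYPES))
  for (g in 1:3) {
    cp <- copies[, g] + 1L
    ll[, g] <- dnorm(counts, mean = mean_of[cp], sd = sqrt(var_of[cp]), log = TRUE)
  }
  ll
}

#' Per-genotype log-likelihood of a single k-mer count
#'
#' Evaluates, for each genotype, the normal log-density of the observed count
#' under the distribution implied by the k-mer's expected copy number for that
#' genotype ([genotype_distribution()]).
#'
#' @param count observed count (non-negative).
#' @param copy_table named vector `c("0/0"=, "0/1"=, "1/1"=)` of expected
#'   diploid copies, as returned by [expected_copy_table()].
#' @param stats a [estimate_sample_stats()] object.
#' @return named numeric vector of log-likelihoods for `0/0`, `0/1`, `1/1`.
#' @export
single_kmer_loglik <- function(count, copy_table, stats) {
  stopifnot(length(count) == 1L, count >= 0)
  copies <- matrix(copy_table[GENOTYPES], nrow = 1)
  drop(.loglik_matrix(count, copies, stats))
}

#' Call the genotype of one SV from its k-mer counts
#'
#' Sums per-k-mer log-likelihoods (independence approximation of the product
#' likelihood) and returns the maximizing genotype. Counts are capped at
#' `2 * mu` before evaluation to damp repetitive k-mers that escaped
#' filtering. Ties break toward fewer alternate alleles (0/0 < 0/1 < 1/1).
#' An SV with no k-mers is reported as `MISSING` (`NA` genotype).
#'
#' @param sv_profiles data.frame of the SV's panel rows: columns `kmer`,
#'   `copies_00`, `copies_01`, `copies_11` (see [extract_panel()]).
#' @param counts named count vector from [count_reads()] / [count_fastq()].
#' @param stats a [estimate_sample_stats()] object.
#' @return one-row data.frame: `genotype` (`NA` = missing), `ll_00`, `ll_01`,
#'   `ll_11`, `n_kmers`.
#' @export
call_genotype <- function(sv_profiles, counts, stats) {
  if (is.null(sv_profiles) || nrow(sv_profiles) == 0L) {
    return(data.frame(genotype = NA_character_, ll_00 = NA_real_,
                      ll_01 = NA_real_, ll_11 = NA_real_, n_kmers = 0L,
                      stringsAsFactors = FALSE))
  }
  cnt <- counts[sv_profiles$kmer]
  cnt[is.na(cnt)] <- 0
  cnt <- pmin(cnt, 2 * stats$mu)
  copies <- as.matrix(sv_profiles[, c("copies_00", "copies_01", "copies_11")])
  ll <- colSums(.loglik_matrix(cnt, copies, stats))
  g <- GENOTYPES[which.max(ll)]  # which.max takes the first: ties go to 0/0
  data.frame(genotype = g, ll_00 = ll[1], ll_01 = ll[2], ll_11 = ll[3],
             n_kmers = nrow(sv_profiles), stringsAsFactors = FALSE)
}

#' Genotype every SV in a panel from a counted sample
#'
#' @param panel a panel data.frame from [extract_panel()] or [read_panel()]
#'   (control rows are used for depth estimation unless `stats` is given).
#' @param counts named counts over the panel's k-mers.
#' @param stats optional precomputed [estimate_sample_stats()]; by default
#'   estimated from the panel's control rows.
#' @return data.frame with one row per SV in the panel: `sv_id`, `genotype`,
#'   `ll_00`, `ll_01`, `ll_11`, `n_kmers`.
#' @export
call_genotypes <- function(panel, counts, stats = NULL) {
  if (is.null(stats)) {
    ctrl <- panel$kmer[panel$role == "control"]
    if (length(ctrl) == 0L) stop("panel has no control k-mers; supply `stats`")
    stats <- estimate_sample_stats(unname(counts[ctrl]))
  }
  svp <- panel[panel$role != "control", , drop = FALSE]
  sv_ids <- unique(svp$sv_id)
  rows <- lapply(sv_ids, function(s) {
    call_genotype(svp[svp$sv_id == s, , drop = FALSE], counts, stats)
  })
  out <- do.call(rbind, rows)
  out <- cbind(data.frame(sv_id = sv_ids, stringsAsFactors = FALSE), out)
  attr(out, "stats") <- stats
  out
}

#' Genotype-call accuracy metrics
#'
#' Four measures over a call set and a truth table: the true genotyping rate
#' (exactly correct genotype calls over all input events), the false
#' genotyping rate (wrong genotype calls over calls made; missing calls are
#' not calls), and presence-level precision and recall, where a positive is a
#' 0/1 or 1/1 genotype and a true positive is a positive call on an event
#' whose true genotype is positive.
#'
#' @param calls data.frame with `sv_id` and `genotype` (`NA` = missing call).
#' @param truth named character vector: true genotype per sv_id; must cover
#'   every event in `calls`.
#' @return list of class `genotype_metrics`: `tgr`, `fgr`, `precision`,
#'   `recall` and the integer counts backing them.
#' @export
evaluate_calls <- function(calls, truth) {
  if (length(truth) == 0L) stop("empty truth set")
  if (!all(calls$sv_id %in% names(truth)))
    stop("truth does not cover all events in calls")
  tr <- truth[calls$sv_id]
  called <- !is.na(calls$genotype)
  correct <- called & calls$genotype == tr
  pos_call <- called & calls$genotype %in% c("0/1", "1/1")
  pos_truth <- tr %in% c("0/1", "1/1")
  n_events <- nrow(calls)
  n_calls <- sum(called)
  tp <- sum(pos_call & pos_truth)
  structure(list(
    tgr = sum(correct) / n_events,
    fgr = if (n_calls > 0) sum(called & !correct) / n_calls else 0,
    precision = if (sum(pos_call) > 0) tp / sum(pos_call) else NA_real_,
    recall = if (sum(pos_truth) > 0) tp / sum(pos_truth) else NA_real_,
    n_events = n_events, n_calls = n_calls, n_correct = sum(correct),
    n_positive_calls = sum(pos_call), n_positive_truth = sum(pos_truth),
    n_true_positive = tp), class = "genotype_metrics")
}

#' @export
print.genotype_metrics <- function(x, ...) {
  cat(sprintf("TGR %.4f  FGR %.4f  precision %.4f  recall %.4f (%d events, %d calls)\n",
              x$tgr, x$fgr, x$precision, x$recall, x$n_events, x$n_calls))
  invisible(x)
}
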