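stats30 <- estimate_sample_stats(rep(c(28, 30, 32), 40))  # mu 30, sigma2 ~4

test_that("sample statistics are the trimmed mean and variance of control counts", {
  st <- suppressWarnings(estimate_sample_stats(c(28, 30, 32)))  # n=3: nothing to trim
  expect_equal(st$mu, 30)
  expect_equal(st$sigma2, 4)
  # degenerate all-equal counts hit the variance floor
  st2 <- estimate_sample_stats(rep(25, 200))
  expect_equal(st2$mu, 25)
  expect_equal(st2$sigma2, 1.0)
  # trimming removes the 2.5% tails: a gross outlier does not move mu
  counts <- c(rep(30, 198), 0, 10000)
  st3 <- estimate_sample_stats(counts)
  expect_equal(st3$mu, 30)
  expect_equal(st3$n_control, 190)
  expect_error(estimate_sample_stats(rep(0, 200)), "zero")
  expect_error(estimate_sample_stats(5), "at least 2")
  expect_warning(estimate_sample_stats(c(10, 12, 14)), "100 control")
})

test_that("genotype distributions follow the two-haplotype normal model", {
  st <- structure(list(mu = 30, sigma2 = 16, n_control = 1000),
                  class = "sample_stats")
  expect_equal(genotype_distribution(2, st), c(mean = 30, variance = 16))
  expect_equal(genotype_distribution(1, st), c(mean = 15, variance = 8))
  # absent k-mer: mean 0, variance max(1, (mu/10)^2)
  expect_equal(genotype_distribution(0, st), c(mean = 0, variance = 9))
  st_low <- structure(list(mu = 5, sigma2 = 4, n_control = 1000),
                      class = "sample_stats")
  expect_equal(genotype_distribution(0, st_low)[["variance"]], 1)
})

test_that("single-k-mer likelihoods match the direct normal-density oracle", {
  st <- structure(list(mu = 30, sigma2 = 30, n_control = 1000),
                  class = "sample_stats")
  ct <- expected_copy_table("inner_alt", "INS")
  oracle <- function(count) {
    eps <- max(1, (st$mu / 10)^2)
    c("0/0" = dnorm(count, 0, sqrt(eps), log = TRUE),
      "0/1" = dnorm(count, st$mu / 2, sqrt(st$sigma2 / 2), log = TRUE),
      "1/1" = dnorm(count, st$mu, sqrt(st$sigma2), log = TRUE))
  }
  for (count in c(0, 15, 30)) {
    expect_equal(single_kmer_loglik(count, ct, st), oracle(count))
  }
  expect_equal(names(which.max(single_kmer_loglik(0, ct, st))), "0/0")
  expect_equal(names(which.max(single_kmer_loglik(15, ct, st))), "0/1")
  expect_equal(names(which.max(single_kmer_loglik(30, ct, st))), "1/1")
})

test_that("the single-k-mer call is monotone in the count", {
  for (mu in seq(10, 60, by = 10)) {
    for (s2 in c(mu / 2, mu, (mu / 2)^2)) {
      st <- structure(list(mu = mu, sigma2 = s2, n_control = 1000),
                      class = "sample_stats")
      ct <- expected_copy_table("junction_alt", "DEL")
      calls <- vapply(0:ceiling(mu), function(cnt)
        names(which.max(single_kmer_loglik(cnt, ct, st))), character(1))
      ranks <- match(calls, c("0/0", "0/1", "1/1"))
      expect_true(all(diff(ranks) >= 0),
                  info = sprintf("mu=%g sigma2=%g", mu, s2))
      expect_equal(calls[1], "0/0")
      expect_equal(calls[length(calls)], "1/1")
    }
  }
})

test_that("SV calls sum per-k-mer log-likelihoods and break ties toward 0/0", {
  profiles <- data.frame(kmer = c("K1", "K2"), sv_id = "sv1",
                         role = "inner_alt",
                         copies_00 = 0, copies_01 = 1, copies_11 = 2)
  st <- structure(list(mu = 30, sigma2 = 30, n_control = 1000),
                  class = "sample_stats")
  call <- call_genotype(profiles, c(K1 = 14, K2 = 16), st)
  expect_equal(call$genotype, "0/1")
  # against a brute-force sum of densities
  oracle <- sapply(list(c(0, 0), c(1, 1), c(2, 2)), function(cp) {
    means <- c(0, st$mu / 2, st$mu)[cp + 1]
    vars <- c(max(1, (st$mu / 10)^2), st$sigma2 / 2, st$sigma2)[cp + 1]
    sum(dnorm(c(14, 16), means, sqrt(vars), log = TRUE))
  })
  expect_equal(unlist(call[c("ll_00", "ll_01", "ll_11")]), oracle,
               ignore_attr = TRUE)
  # no k-mers: MISSING
  miss <- call_genotype(profiles[0, ], numeric(0), st)
  expect_true(is.na(miss$genotype))
  expect_equal(miss$n_kmers, 0)
  # constructed degenerate tie: equal loglik for 0/0 and 0/1 -> 0/0
  ct_sym <- data.frame(kmer = "K1", sv_id = "s", role = "x",
                       copies_00 = 1, copies_01 = 1, copies_11 = 2)
  tie <- call_genotype(ct_sym, c(K1 = 15), st)
  expect_equal(tie$ll_00, tie$ll_01)
  expect_equal(tie$genotype, "0/0")
})

test_that("counts are capped at twice the sample mean before evaluation", {
  st <- structure(list(mu = 30, sigma2 = 30, n_control = 1000),
                  class = "sample_stats")
  profiles <- data.frame(kmer = "K1", sv_id = "s", role = "inner_alt",
                         copies_00 = 0, copies_01 = 1, copies_11 = 2)
  c1 <- call_genotype(profiles, c(K1 = 60), st)
  c2 <- call_genotype(profiles, c(K1 = 6000), st)  # repeat that escaped filters
  expect_equal(c1[, -1], c2[, -1])
})

test_that("a count at a genotype's mean never flips the call away from it", {
  st <- structure(list(mu = 30, sigma2 = 20, n_control = 1000),
                  class = "sample_stats")
  withr::with_seed(31, {
    for (trial in 1:20) {
      n <- sample(1:6, 1)
      profiles <- data.frame(kmer = paste0("K", 1:(n + 1)), sv_id = "s",
                             role = "inner_alt", copies_00 = 0, copies_01 = 1,
                             copies_11 = 2)
      g <- sample(1:3, 1)
      mean_g <- c(0, st$mu / 2, st$mu)[g]
      counts <- setNames(c(pmax(0, round(rnorm(n, mean_g, 3))), mean_g),
                         profiles$kmer)
      base_ll <- call_genotype(profiles[1:n, ], counts, st)
      full_ll <- call_genotype(profiles, counts, st)
      lls <- c("ll_00", "ll_01", "ll_11")
      margin_before <- base_ll[[lls[g]]] - max(unlist(base_ll[lls[-g]]))
      margin_after <- full_ll[[lls[g]]] - max(unlist(full_ll[lls[-g]]))
      expect_gte(margin_after, margin_before - 1e-9)
    }
  })
})

test_that("relabeling a DEL inner_ref as an INS inner_alt mirrors the calls", {
  st <- structure(list(mu = 30, sigma2 = 25, n_control = 1000),
                  class = "sample_stats")
  ct_ref <- expected_copy_table("inner_ref", "DEL")
  ct_alt <- expected_copy_table("inner_alt", "INS")
  for (count in c(0, 7, 15, 23, 30)) {
    g_ref <- names(which.max(single_kmer_loglik(count, ct_ref, st)))
    g_alt <- names(which.max(single_kmer_loglik(count, ct_alt, st)))
    mirror <- c("0/0" = "1/1", "0/1" = "0/1", "1/1" = "0/0")
    expect_equal(g_ref, unname(mirror[g_alt]))
  }
})

test_that("accuracy metrics follow their definitions on a toy truth table", {
  truth <- setNames(c("0/0", "0/0", "0/1", "0/1", "0/1", "1/1", "1/1", "1/1",
                      "0/0", "0/1"), paste0("sv", 1:10))
  calls <- data.frame(
    sv_id = paste0("sv", 1:10),
    genotype = c("0/0", "0/1", "0/1", "0/1", "1/1", "1/1", "1/1", "0/0",
                 "0/0", "0/1"),
    stringsAsFactors = FALSE)
  m <- evaluate_calls(calls, truth)
  expect_equal(m$tgr, 7 / 10)          # 7 exactly correct of 10 events
  expect_equal(m$fgr, 3 / 10)          # 3 wrong of 10 calls made
  # positive calls: 2,3,4,5,6,7,10 (7); true positives: 3,4,5,6,7,10 (6);
  # truth-positive events: 3,4,5,6,7,8,10 (7)
  expect_equal(m$precision, 6 / 7)
  expect_equal(m$recall, 6 / 7)
  # missing calls count against TGR but are not "calls made"
  calls$genotype[2] <- NA
  m2 <- evaluate_calls(calls, truth)
  expect_equal(m2$tgr, 7 / 10)
  expect_equal(m2$fgr, 2 / 9)
  expect_error(evaluate_calls(calls, character(0)), "empty")
  expect_error(evaluate_calls(calls, truth[1:3]), "cover")
})
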