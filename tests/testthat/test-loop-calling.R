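test_that("hypergeometric upper tail matches exhaustive enumeration", {
  expect_equal(hypergeometric_pvalue(2, 2, 2, 10), 1 / 45)
  expect_equal(hypergeometric_pvalue(0, 3, 4, 10), 1)
  expect_equal(hypergeometric_pvalue(2, 4, 2, 4), 1)
  expect_error(hypergeometric_pvalue(3, 2, 5, 10), "exceeds")
  # enumeration oracle: P(X >= k) by summing the pmf over all draws
  for (N in c(5, 8, 12)) for (ni in 1:4) for (nj in 1:4) {
    for (k in 0:min(ni, nj)) {
      exact <- sum(vapply(k:min(ni, nj), function(x)
        choose(ni, x) * choose(N - ni, nj - x) / choose(N, nj), 0))
      expect_equal(hypergeometric_pvalue(k, ni, nj, N), exact,
                   tolerance = 1e-12)
    }
  }
})

test_that("Benjamini-Hochberg step-up rejects per the step-up rule", {
  r <- benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04), 0.05)
  expect_true(all(r$reject))
  expect_false(benjamini_hochberg(1.0, 0.5)$reject)
  set.seed(2)
  p <- runif(50)
  q <- benjamini_hochberg(p)$q_value
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  expect_equal(benjamini_hochberg(numeric(0))$q_value, numeric(0))
})

test_that("local filter expected values equal the local background mean", {
  n <- 60L
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  const <- contact_matrix(data.frame(bin_i = idx[, 1] - 1L,
                                     bin_j = idx[, 2] - 1L, count = 7L),
                          "chr1", 1000L, n)
  e <- local_filter_expected(const, 25L, 40L, P = 3L, W = 6L)
  expect_equal(unname(e), rep(7, 4))

  solo <- contact_matrix(data.frame(bin_i = 25L, bin_j = 40L, count = 50L),
                         "chr1", 1000L, n)
  e0 <- local_filter_expected(solo, 25L, 40L, P = 3L, W = 6L)
  expect_equal(unname(e0), rep(0, 4))
})

test_that("local filters recover a homogeneous Poisson intensity", {
  lambda <- 9
  n <- 80L
  set.seed(5)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  m <- contact_matrix(data.frame(bin_i = idx[, 1] - 1L, bin_j = idx[, 2] - 1L,
                                 count = rpois(nrow(idx), lambda)),
                      "chr1", 1000L, n)
  e <- local_filter_expected(m, 30L, 50L, P = 2L, W = 4L)
  # donut footprint has (2W+1)^2 - (2P+1)^2 = 56 cells; allow 3 SE
  for (f in seq_along(e)) {
    expect_lt(abs(e[f] - lambda), 3 * sqrt(lambda / 12))
  }
})

test_that("planted focal peaks are called and a null matrix is quiet", {
  cfg <- generator_config(seed = 31)
  pl <- data.frame(bin_i = c(40, 120, 200), bin_j = c(100, 180, 280))
  gm <- generate_contact_matrix(cfg, planted = pl)
  calls <- call_hic(gm$matrix)
  expect_equal(nrow(calls), 3)
  expect_equal(calls$start1 / 1000, sort(pl$bin_i))
  null <- generate_contact_matrix(generator_config(seed = 32))
  expect_equal(nrow(call_hic(null$matrix)), 0)
})

test_that("HiChIP calling drops off-peak pairs and enforces the PET floor", {
  set.seed(8)
  peaks <- data.frame(chrom = "chr1", start = seq(0, 49e4, 1e4),
                      end = seq(0, 49e4, 1e4) + 1000)
  np <- nrow(peaks)
  i <- sample(np, 1500, replace = TRUE); j <- sample(np, 1500, replace = TRUE)
  keep <- i != j
  mk <- function(a, b) data.frame(
    chrom1 = "chr1", start1 = peaks$start[a] + 100, end1 = peaks$start[a] + 200,
    chrom2 = "chr1", start2 = peaks$start[b] + 100, end2 = peaks$start[b] + 200)
  pairs <- mk(i[keep], j[keep])
  hot <- mk(rep(3, 50), rep(17, 50))
  calls <- call_hichip(rbind(pairs, hot), peaks, extension = 0)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$start1, peaks$start[3])
  expect_gte(calls$pet, 50)

  # order invariance
  shuffled <- rbind(pairs, hot)[sample(nrow(pairs) + 50), ]
  expect_equal(call_hichip(shuffled, peaks, extension = 0), calls)

  # a highly significant pair below the PET floor is excluded
  tiny <- rbind(mk(rep(2, 3), rep(9, 3)))
  calls2 <- call_hichip(rbind(tiny, mk(1, 5)), peaks, extension = 0,
                        min_pet = 4)
  expect_false(any(calls2$start1 == peaks$start[2] &
                     calls2$start2 == peaks$start[9]))

  # everything off-peak -> empty with a warning
  off <- data.frame(chrom1 = "chr1", start1 = 5000, end1 = 5100,
                    chrom2 = "chr1", start2 = 25000, end2 = 25100)
  expect_warning(res <- call_hichip(off, peaks, extension = 0), "no valid")
  expect_equal(nrow(res), 0)
  expect_error(call_hichip(off, peaks[0, ]), "empty peak")
})

test_that("contact matrices reject invalid counts and round-trip", {
  expect_error(contact_matrix(data.frame(bin_i = 0, bin_j = 1, count = 1.5),
                              "chr1", 1000, 10), "integer")
  cfg <- generator_config(seed = 33, matrix_bins = 40L)
  m <- generate_contact_matrix(cfg)$matrix
  f <- withr::local_tempfile()
  write_contact_matrix(m, f)
  m2 <- read_contact_matrix(f)
  expect_equal(m2$counts, m$counts, ignore_attr = TRUE)
  expect_equal(m2$n_bins, m$n_bins)
  expect_error(read_contact_matrix(f, max_bins = 10), "exceeds")
})
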