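# Significance-based loop calling.
#
# Two callers: (1) a HiChIP-style hypergeometric test on peak-pair
# counts of valid pairs, and (2) a Hi-C-style local-background Poisson
# test on a binned contact matrix with donut / vertical / horizontal /
# lower-left footprints (HiCCUPS geometry), a call requiring all four
# filters to pass Benjamini-Hochberg control.

#' Upper-tail hypergeometric p-value for a peak pair
#'
#' P(X >= k) with X ~ Hypergeometric(population N, successes n_i, draws
#' n_j): the chance that peaks i and j share at least k of the N
#' peak-anchored valid pairs given their totals.
#'
#' @param k observed pairs linking the two peaks.
#' @param n_i,n_j total pairs touching each peak.
#' @param N total peak-overlapping pairs.
#' @return p-value.
#' @export
hypergeometric_pvalue <- function(k, n_i, n_j, N) {
  if (any(k > pmin(n_i, n_j))) {
    stop("hypergeometric_pvalue: k exceeds min(n_i, n_j)")
  }
  phyper(k - 1, n_i, N - n_i, n_j, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up procedure
#'
#' @param p vector of p-values in [0, 1].
#' @param q target FDR.
#' @return list with `q_value` (monotone BH-adjusted p-values) and
#'   `reject` (logical).
#' @export
benjamini_hochberg <- function(p, q = 0.05) {
  if (!length(p)) return(list(q_value = numeric(0), reject = logical(0)))
  stopifnot(all(p >= 0 & p <= 1))
  qv <- p.adjust(p, method = "BH")
  list(q_value = qv, reject = qv <= q)
}

#' Call significant HiChIP interactions
#'
#' Valid pairs are filtered to those with both ends overlapping a peak
#' (after symmetric `extension`), counted per unordered peak pair, tested
#' with the upper-tail hypergeometric distribution against the totals per
#' peak, and Benjamini-Hochberg corrected. A call is returned iff
#' `q <= fdr` and its supporting pair count is at least `min_pet`.
#'
#' @param pairs valid-pair data frame ([read_bedpe()]).
#' @param peaks peak intervals ([read_bed()]).
#' @param extension anchor extension in bp before the peak overlap test
#'   (default 250).
#' @param fdr Benjamini-Hochberg threshold (default 0.05).
#' @param min_pet minimum supporting valid pairs per call (default 4).
#' @return BEDPE-like data frame of calls (anchors = the two peaks) with
#'   `pet`, `p`, `q` columns.
#' @export
call_hichip <- function(pairs, peaks, extension = 250L, fdr = 0.05,
                        min_pet = 4L) {
  if (is.null(peaks) || nrow(peaks) == 0) stop("call_hichip: empty peak list")
  stopifnot(fdr > 0, fdr < 1)
  empty <- data.frame(chrom1 = character(0), start1 = integer(0),
                      end1 = integer(0), chrom2 = character(0),
                      start2 = integer(0), end2 = integer(0),
                      pet = integer(0), p = numeric(0), q = numeric(0))
  if (nrow(pairs) == 0) return(empty)
  a1 <- data.frame(chrom = pairs$chrom1, start = pairs$start1,
                   end = pairs$end1, stringsAsFactors = FALSE)
  a2 <- data.frame(chrom = pairs$chrom2, start = pairs$start2,
                   end = pairs$end2, stringsAsFactors = FALSE)
  p1 <- best_peak(a1, peaks, extension)
  p2 <- best_peak(a2, peaks, extension)
  keep <- !is.na(p1) & !is.na(p2)
  if (!any(keep)) {
    warning("call_hichip: no valid pair has both ends on a peak")
    return(empty)
  }
  u <- pmin(p1[keep], p2[keep])
  v <- pmax(p1[keep], p2[keep])
  N <- sum(keep)
  key <- paste(u, v)
  k <- as.vector(table(key)[unique(key)])
  uk <- unique(key)
  uv <- do.call(rbind, strsplit(uk, " "))
  pi <- as.integer(uv[, 1]); pj <- as.integer(uv[, 2])
  per_peak <- table(c(u, v))
  n_i <- as.integer(per_peak[as.character(pi)])
  n_j <- as.integer(per_peak[as.character(pj)])
  # self-pairs (both ends on one peak) count once per end above; test the
  # distinct peak pairs only
  distinct <- pi != pj
  pi <- pi[distinct]; pj <- pj[distinct]
  k <- k[distinct]; n_i <- n_i[distinct]; n_j <- n_j[distinct]
  if (!length(k)) return(empty)
  pv <- hypergeometric_pvalue(k, pmin(n_i, N), pmin(n_j, N), N)
  bh <- benjamini_hochberg(pv, fdr)
  sel <- bh$reject & k >= min_pet
  out <- data.frame(chrom1 = peaks$chrom[pi], start1 = peaks$start[pi],
                    end1 = peaks$end[pi], chrom2 = peaks$chrom[pj],
                    start2 = peaks$start[pj], end2 = peaks$end[pj],
                    pet = k, p = pv, q = bh$q_value)[sel, , drop = FALSE]
  out <- out[order(out$chrom1, out$start1, out$start2), , drop = FALSE]
  rownames(out) <- NULL
  canonicalize_bedpe(out)
}

#' Contact matrices
#'
#' A binned intra-chromosomal contact matrix held sparsely: data frame
#' (`bin_i`, `bin_j`, `count`) with 0-based upper-triangle bins, plus
#' `chrom`, `resolution` (bp) and `n_bins`.
#'
#' @param df sparse counts (bin_i, bin_j, count), 0-based bins.
#' @param chrom chromosome name.
#' @param resolution bin size in bp.
#' @param n_bins number of bins.
#' @return object of class `contact_matrix`.
#' @export
contact_matrix <- function(df, chrom, resolution, n_bins) {
  stopifnot(all(df$count >= 0), all(df$bin_i >= 0), all(df$bin_j >= 0),
            all(df$bin_i < n_bins), all(df$bin_j < n_bins))
  if (any(df$count != round(df$count))) {
    stop("contact_matrix: counts must be integers")
  }
  i <- pmin(df$bin_i, df$bin_j); j <- pmax(df$bin_i, df$bin_j)
  structure(list(counts = data.frame(bin_i = i, bin_j = j,
                                     count = as.integer(df$count)),
                 chrom = chrom, resolution = resolution,
                 n_bins = as.integer(n_bins)),
            class = "contact_matrix")
}

#' Read a sparse contact matrix
#'
#' 3-column tab-separated text (bin_i, bin_j, count) with a header line
#' `#chrom=<chrom> resolution=<bp> n_bins=<n>`.
#'
#' @param path file path.
#' @param max_bins guard against accidentally huge dense matrices
#'   (default 20000 bins).
#' @return a `contact_matrix`.
#' @export
read_contact_matrix <- function(path, max_bins = 20000L) {
  hdr <- readLines(path, n = 1)
  m <- regmatches(hdr, regexec(
    "^#chrom=(\\S+)\\s+resolution=(\\d+)\\s+n_bins=(\\d+)", hdr))[[1]]
  if (length(m) != 4) stop("read_contact_matrix: missing sidecar header")
  n_bins <- as.integer(m[4])
  if (n_bins > max_bins) {
    stop(sprintf("read_contact_matrix: %d bins exceeds max_bins=%d",
                 n_bins, max_bins))
  }
  df <- read.table(path, header = FALSE, sep = "\t", skip = 1,
                   col.names = c("bin_i", "bin_j", "count"))
  contact_matrix(df, m[2], as.integer(m[3]), n_bins)
}

#' Write a sparse contact matrix
#' @param m a `contact_matrix`.
#' @param path output path.
#' @export
write_contact_matrix <- function(m, path) {
  con <- file(path, "w")
  writeLines(sprintf("#chrom=%s resolution=%d n_bins=%d",
                     m$chrom, m$resolution, m$n_bins), con)
  write.table(m$counts, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  close(con)
  invisible(path)
}

dense_counts <- function(m) {
  M <- matrix(0, m$n_bins, m$n_bins)
  M[cbind(m$counts$bin_i + 1, m$counts$bin_j + 1)] <- m$counts$count
  M[cbind(m$counts$bin_j + 1, m$counts$bin_i + 1)] <- m$counts$count
  M
}

# 2D prefix sums: S[i+1, j+1] = sum of M[1..i, 1..j]
prefix2d <- function(M) {
  n <- nrow(M)
  S <- matrix(0, n + 1, n + 1)
  S[-1, -1] <- t(apply(apply(M, 2, cumsum), 1, cumsum))
  S
}

# vectorised clipped rectangle sum from a prefix matrix (1-based bounds)
rect_sum <- function(S, r1, r2, c1, c2, n) {
  r1 <- pmax(r1, 1); c1 <- pmax(c1, 1); r2 <- pmin(r2, n); c2 <- pmin(c2, n)
  empty <- r1 > r2 | c1 > c2
  r1 <- pmin(r1, n); c1 <- pmin(c1, n); r2 <- pmax(r2, 1); c2 <- pmax(c2, 1)
  out <- S[cbind(r2 + 1, c2 + 1)] - S[cbind(r1, c2 + 1)] -
    S[cbind(r2 + 1, c1)] + S[cbind(r1, c1)]
  out[empty] <- 0
  out
}

#' Local-background expected values for a bin pair
#'
#' Mean background count around (i, j) under the four footprints used in
#' focal contact-peak detection: donut (square annulus of half-widths
#' P..W), vertical (3-wide column band of half-height W), horizontal
#' (3-wide row band), and lower-left (the quadrant between P and W
#' below-left of the pixel). All footprints exclude the (2P+1)^2 peak
#' box, are clipped to matrix bounds and to the upper triangle. A
#' footprint with no surviving cell yields NA (pair skipped by the
#' caller).
#'
#' @param m a `contact_matrix` (or dense matrix via internal use).
#' @param i,j 0-based bin indices, i < j.
#' @param P peak-box half-width in bins (default 20).
#' @param W outer half-width in bins (default 40); P < W.
#' @return named numeric vector (donut, vertical, horizontal, lowerleft).
#' @export
local_filter_expected <- function(m, i, j, P = 20L, W = 40L) {
  stopifnot(P < W, all(i < j), all(i >= 0))
  M <- dense_counts(m)
  pre <- precompute_filters(M)
  e <- local_expected(pre, i + 1, j + 1, P, W, m$n_bins)
  if (length(i) == 1) {
    setNames(as.numeric(e), c("donut", "vertical", "horizontal",
                              "lowerleft"))
  } else {
    colnames(e) <- c("donut", "vertical", "horizontal", "lowerleft")
    e
  }
}

precompute_filters <- function(M) {
  n <- nrow(M)
  Mut <- M
  Mut[lower.tri(Mut, diag = TRUE)] <- 0   # strict upper triangle only
  U <- matrix(0, n, n)
  U[upper.tri(U)] <- 1
  list(S = prefix2d(Mut), SU = prefix2d(U), n = n)
}

# matrix (length(r) x 4) of donut/vertical/horizontal/lowerleft means at
# 1-based positions (r, c); NA where a footprint has no surviving cell
local_expected <- function(pre, r, c, P, W, n) {
  sums <- function(r1, r2, c1, c2) rect_sum(pre$S, r1, r2, c1, c2, n)
  cnts <- function(r1, r2, c1, c2) rect_sum(pre$SU, r1, r2, c1, c2, n)
  peak_s <- sums(r - P, r + P, c - P, c + P)
  peak_c <- cnts(r - P, r + P, c - P, c + P)
  d_s <- sums(r - W, r + W, c - W, c + W) - peak_s
  d_c <- cnts(r - W, r + W, c - W, c + W) - peak_c
  v_s <- sums(r - W, r + W, c - 1, c + 1) - sums(r - P, r + P, c - 1, c + 1)
  v_c <- cnts(r - W, r + W, c - 1, c + 1) - cnts(r - P, r + P, c - 1, c + 1)
  h_s <- sums(r - 1, r + 1, c - W, c + W) - sums(r - 1, r + 1, c - P, c + P)
  h_c <- cnts(r - 1, r + 1, c - W, c + W) - cnts(r - 1, r + 1, c - P, c + P)
  l_s <- sums(r + P, r + W, c - W, c - P) - sums(r + P, r + P, c - P, c - P)
  l_c <- cnts(r + P, r + W, c - W, c - P) - cnts(r + P, r + P, c - P, c - P)
  cbind(ifelse(d_c > 0, d_s / d_c, NA_real_),
        ifelse(v_c > 0, v_s / v_c, NA_real_),
        ifelse(h_c > 0, h_s / h_c, NA_real_),
        ifelse(l_c > 0, l_s / l_c, NA_real_))
}

#' Call significant Hi-C contacts with four local filters
#'
#' Candidate bin pairs (distance strictly more than 2 bins and at most
#' `max_distance`) are tested against each of the four local-background
#' expected values with an upper-tail Poisson p-value
#' `P(Pois(lambda_f) >= observed)`; Benjamini-Hochberg is applied
#' separately within each filter and a contact is called iff it passes
#' all four at `q <= fdr`. Pairs with an undefined footprint are skipped.
#'
#' @param m a `contact_matrix`.
#' @param P,W footprint half-widths in bins (defaults 20 and 40).
#' @param fdr per-filter BH threshold (default 0.025).
#' @param max_distance maximum pair distance in bp (default 1 Mb).
#' @return BEDPE-like data frame of calls (anchor intervals = bins) with
#'   `pet` (observed count), `p` and `q` (max over the four filters).
#' @export
call_hic <- function(m, P = 20L, W = 40L, fdr = 0.025, max_distance = 1e6) {
  stopifnot(inherits(m, "contact_matrix"))
  M <- dense_counts(m)
  pre <- precompute_filters(M)
  n <- m$n_bins
  maxd <- floor(max_distance / m$resolution)
  cand <- which(upper.tri(M), arr.ind = TRUE)
  d <- cand[, 2] - cand[, 1]
  cand <- cand[d > 2 & d <= maxd, , drop = FALSE]
  if (!nrow(cand)) {
    return(hic_empty())
  }
  exp4 <- local_expected(pre, cand[, 1], cand[, 2], P, W, n)
  ok <- rowSums(is.na(exp4)) == 0
  cand <- cand[ok, , drop = FALSE]
  exp4 <- exp4[ok, , drop = FALSE]
  if (!nrow(cand)) return(hic_empty())
  obs <- M[cand]
  pmat <- matrix(NA_real_, nrow(cand), 4)
  for (f in 1:4) {
    lam <- exp4[, f]
    pv <- ppois(obs - 1, lam, lower.tail = FALSE)
    pv[lam == 0 & obs > 0] <- 0
    pv[lam == 0 & obs == 0] <- 1
    pmat[, f] <- pv
  }
  qmat <- apply(pmat, 2, function(p) p.adjust(p, method = "BH"))
  if (is.null(dim(qmat))) qmat <- matrix(qmat, nrow = 1)
  pass <- rowSums(qmat <= fdr) == 4
  if (!any(pass)) return(hic_empty())
  bi <- cand[pass, 1] - 1L; bj <- cand[pass, 2] - 1L
  res <- m$resolution
  out <- data.frame(chrom1 = m$chrom, start1 = bi * res,
                    end1 = (bi + 1L) * res, chrom2 = m$chrom,
                    start2 = bj * res, end2 = (bj + 1L) * res,
                    pet = as.integer(obs[pass]),
                    p = apply(pmat[pass, , drop = FALSE], 1, max),
                    q = apply(qmat[pass, , drop = FALSE], 1, max),
                    stringsAsFactors = FALSE)
  out[order(out$start1, out$start2), , drop = FALSE]
}

hic_empty <- function() {
  data.frame(chrom1 = character(0), start1 = integer(0), end1 = integer(0),
              chrom2 = character(0), start2 = integer(0), end2 = integer(0),
              pet = integer(0), p = numeric(0), q = numeric(0))
}
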