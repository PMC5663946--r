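# Observed / expected interaction enrichment between annotation classes.
#
# The expected number of edges between annotation classes A and B is, per
# chromosome, the chromosome's observed edge total multiplied by the
# fraction of admissible node pairs (same chromosome, midpoint distance
# <= max_distance) that are A-B pairs, summed over chromosomes. For A = B
# the numerator counts unordered within-class pairs, so that expected
# values over all unordered label pairs sum exactly to the edge count.

# per-chromosome admissible unordered pair counts for every label pair
admissible_pair_counts <- function(net, max_distance = 1e6) {
  labels <- sort(unique(net$nodes$annotation))
  L <- length(labels)
  per_chrom <- list()
  denom_by_chrom <- list()
  edges_by_chrom <- list()
  node_chrom <- net$nodes$chrom[match(net$edges$u, net$nodes$node_id)]
  for (ch in unique(net$nodes$chrom)) {
    ix <- which(net$nodes$chrom == ch)
    mid <- (net$nodes$start[ix] + net$nodes$end[ix]) / 2
    lab <- net$nodes$annotation[ix]
    ord <- order(mid)
    mid <- mid[ord]; lab <- lab[ord]
    n <- length(mid)
    lab_f <- factor(lab, levels = labels)
    ind <- matrix(0L, n, L)
    ind[cbind(seq_len(n), as.integer(lab_f))] <- 1L
    pref <- rbind(0L, apply(ind, 2, cumsum))   # (n+1) x L
    hi <- findInterval(mid + max_distance, mid)
    cnt <- matrix(0, L, L, dimnames = list(labels, labels))
    for (a in seq_len(L)) {
      ja <- which(as.integer(lab_f) == a)
      if (!length(ja)) next
      # labels of partners strictly after j within range
      win <- pref[hi[ja] + 1L, , drop = FALSE] - pref[ja + 1L, , drop = FALSE]
      cnt[a, ] <- cnt[a, ] + colSums(win)
    }
    # cnt[a, b]: ordered (earlier a, later b); fold to unordered
    un <- cnt
    for (a in seq_len(L)) for (b in seq_len(L)) {
      if (a < b) { un[a, b] <- cnt[a, b] + cnt[b, a]; un[b, a] <- un[a, b] }
    }
    denom_by_chrom[[ch]] <- sum(un[upper.tri(un, diag = FALSE)]) +
      sum(diag(un))
    edges_by_chrom[[ch]] <- sum(node_chrom == ch)
    if (edges_by_chrom[[ch]] > 0 && denom_by_chrom[[ch]] == 0) {
      stop("enrichment: chromosome with edges but no admissible node pairs")
    }
    per_chrom[[ch]] <- un
  }
  list(labels = labels, denom = denom_by_chrom, edges = edges_by_chrom,
       per_chrom = per_chrom)
}

#' Expected number of edges between two annotation classes
#'
#' @param net an annotated `chromnet` network.
#' @param a,b annotation labels (may be equal).
#' @param max_distance admissible-pair distance cap in bp (default 1 Mb,
#'   matching the network's edge distance cap).
#' @return expected edge count (float).
#' @export
expected_edges <- function(net, a, b, max_distance = 1e6) {
  ac <- admissible_pair_counts(net, max_distance)
  if (!(a %in% ac$labels) || !(b %in% ac$labels)) return(0)
  tot <- 0
  for (ch in names(ac$per_chrom)) {
    if (ac$denom[[ch]] == 0) next
    tot <- tot + ac$edges[[ch]] * ac$per_chrom[[ch]][a, b] / ac$denom[[ch]]
  }
  tot
}

#' Observed/expected interaction enrichment matrix
#'
#' Tallies each edge once under its unordered annotation pair and
#' compares with the admissible-pair expectation. Pairs with zero
#' observed edges get `log2_ratio = -Inf` (depleted, flagged rather than
#' dropped).
#'
#' @param net an annotated `chromnet` network.
#' @param max_distance admissible-pair distance cap in bp.
#' @return object of class `enrichment_matrix`: list of square matrices
#'   `observed`, `expected`, `log2_ratio` over the annotation labels.
#' @export
enrichment_matrix <- function(net, max_distance = 1e6) {
  ac <- admissible_pair_counts(net, max_distance)
  labels <- ac$labels
  L <- length(labels)
  expected <- matrix(0, L, L, dimnames = list(labels, labels))
  for (ch in names(ac$per_chrom)) {
    if (ac$denom[[ch]] == 0) next
    expected <- expected +
      ac$edges[[ch]] * ac$per_chrom[[ch]] / ac$denom[[ch]]
  }
  lab_u <- net$nodes$annotation[match(net$edges$u, net$nodes$node_id)]
  lab_v <- net$nodes$annotation[match(net$edges$v, net$nodes$node_id)]
  observed <- matrix(0, L, L, dimnames = list(labels, labels))
  for (i in seq_along(lab_u)) {
    a <- lab_u[i]; b <- lab_v[i]
    observed[a, b] <- observed[a, b] + 1
    if (a != b) observed[b, a] <- observed[b, a] + 1
  }
  ratio <- suppressWarnings(log2(observed / expected))
  ratio[observed == 0] <- -Inf
  ratio[expected == 0] <- NA_real_
  structure(list(labels = labels, observed = observed, expected = expected,
                 log2_ratio = ratio),
            class = "enrichment_matrix")
}

#' @export
print.enrichment_matrix <- function(x, digits = 2, ...) {
  cat("interaction enrichment, log2(observed/expected):\n")
  print(round(x$log2_ratio, digits))
  invisible(x)
}

#' Write an enrichment matrix as TSV
#'
#' Writes the log2 ratio matrix (zero-observed pairs as `-inf`) and a
#' companion long-format table of observed and expected counts.
#'
#' @param x an `enrichment_matrix`.
#' @param path output path for the log2 matrix; the companion table goes
#'   to `<path>.counts`.
#' @export
write_enrichment <- function(x, path) {
  m <- x$log2_ratio
  mm <- format(m, trim = TRUE)
  mm[is.infinite(m) & m < 0] <- "-inf"
  df <- data.frame(annotation = rownames(m), mm, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  idx <- which(upper.tri(x$observed, diag = TRUE), arr.ind = TRUE)
  counts <- data.frame(a = x$labels[idx[, 1]], b = x$labels[idx[, 2]],
                       observed = x$observed[idx], expected = x$expected[idx])
  write.table(counts, paste0(path, ".counts"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Split super-enhancer edges by domain
#'
#' Partitions edges whose two endpoints are both super-enhancer nodes
#' into those connecting members of the same super-enhancer domain and
#' those crossing distinct domains.
#'
#' @param net a network with `se_domains` assigned.
#' @return list with `within`, `across` counts and `within_fraction`
#'   (NaN when there are no SE-SE edges).
#' @export
se_edge_split <- function(net) {
  dom <- net$se_domains
  if (is.null(dom)) stop("se_edge_split: super-enhancer domains not assigned")
  d <- setNames(dom$domain_id, dom$node_id)
  du <- d[as.character(net$edges$u)]
  dv <- d[as.character(net$edges$v)]
  sese <- !is.na(du) & !is.na(dv)
  within <- sum(sese & du == dv)
  across <- sum(sese & du != dv)
  list(within = within, across = across,
       within_fraction = within / (within + across))
}
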