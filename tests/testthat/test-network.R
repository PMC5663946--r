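peaks3 <- data.frame(chrom = "chr1",
                     start = c(1000L, 50000L, 2000000L),
                     end = c(2000L, 51000L, 2001000L))

call_row <- function(s1, e1, s2, e2, pet = 1L, chrom2 = "chr1") {
  data.frame(chrom1 = "chr1", start1 = s1, end1 = e1,
             chrom2 = chrom2, start2 = s2, end2 = e2, pet = pet)
}

test_that("calls survive only when both anchors overlap a peak", {
  hit <- call_row(1100L, 1200L, 50100L, 50200L)
  miss <- call_row(30000L, 30100L, 50100L, 50200L)   # left anchor off-peak
  net <- build_network(rbind(hit, miss), peaks3, extension = 250)
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$log$unanchored, 1)
  # extension can rescue a near-miss anchor
  near <- call_row(2100L, 2200L, 50100L, 50200L)
  expect_equal(nrow(build_network(near, peaks3, extension = 0)$edges), 0)
  expect_equal(nrow(build_network(near, peaks3, extension = 250)$edges), 1)
})

test_that("duplicate peak-pair calls merge with summed PET", {
  calls <- rbind(call_row(1100L, 1200L, 50100L, 50200L, pet = 3L),
                 call_row(1300L, 1400L, 50300L, 50400L, pet = 4L))
  net <- build_network(calls, peaks3, extension = 250)
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$pet, 7L)
})

test_that("distance cap, self-loops and inter-chromosomal calls drop", {
  far <- call_row(1100L, 1200L, 2000100L, 2000200L)   # ~2 Mb apart
  net <- build_network(far, peaks3, extension = 250)
  expect_equal(nrow(net$edges), 0)
  expect_equal(net$log$too_far, 1)
  selfy <- call_row(1050L, 1150L, 1800L, 1900L)       # both anchors -> peak 1
  expect_equal(build_network(selfy, peaks3, 250)$log$self_loop, 1)
  inter <- call_row(1100L, 1200L, 50100L, 50200L, chrom2 = "chr2")
  expect_equal(build_network(inter, peaks3, 250)$log$interchrom, 1)
  expect_error(build_network(far, peaks3[0, ]), "empty peak")
})

test_that("anchors map to the largest-overlap peak, leftmost on ties", {
  peaks <- data.frame(chrom = "chr1",
                      start = c(1000L, 1600L, 99000L),
                      end = c(1700L, 2600L, 100000L))
  # anchor overlaps peak1 by 100 bp, peak2 by 400 bp
  a <- call_row(1600L, 2000L, 99100L, 99200L)
  net <- build_network(a, peaks, extension = 0)
  expect_equal(net$nodes$peak, c(2L, 3L))
  # tie: anchor covering both peaks equally maps to the leftmost
  peaks_t <- data.frame(chrom = "chr1", start = c(1000L, 2000L, 99000L),
                        end = c(1500L, 2500L, 100000L))
  b <- call_row(1000L, 2500L, 99100L, 99200L)
  net_t <- build_network(b, peaks_t, extension = 0)
  expect_equal(net_t$nodes$peak, c(1L, 3L))
})

test_that("edge count is monotone in the distance cap", {
  pl <- shared_pipeline()
  calls <- read_bedpe(pl$gen$files$calls)
  peaks <- read_bed(pl$gen$files$peaks)
  e <- vapply(c(2e5, 5e5, 1e6, 2e6), function(d)
    nrow(build_network(calls, peaks, max_distance = d)$edges), 0)
  expect_true(all(diff(e) >= 0))
})

test_that("components match a union-find oracle and are maximal", {
  uf_components <- function(n, edges) {
    parent <- seq_len(n)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    for (r in seq_len(nrow(edges))) {
      a <- find(edges$u[r]); b <- find(edges$v[r])
      if (a != b) parent[a] <- b
    }
    vapply(seq_len(n), find, 0L)
  }
  set.seed(9)
  for (rep in 1:10) {
    n <- sample(5:14, 1)
    edges <- data.frame(u = sample(n, 12, TRUE), v = sample(n, 12, TRUE))
    edges <- edges[edges$u != edges$v, ]
    edges <- data.frame(u = pmin(edges$u, edges$v),
                        v = pmax(edges$u, edges$v),
                        pet = 1L)
    edges <- edges[!duplicated(edges[, 1:2]), ]
    nodes <- data.frame(chrom = "chr1", start = (1:n) * 1000L,
                        end = (1:n) * 1000L + 100L,
                        annotation = "other")
    net <- mk_net(nodes, edges)
    used <- sort(unique(c(edges$u, edges$v)))
    oracle <- uf_components(n, edges)[used]
    got <- net$nodes$component[match(used, net$nodes$node_id)]
    expect_equal(length(unique(got)), length(unique(oracle)))
    expect_true(all(tapply(got, oracle, function(x) length(unique(x))) == 1))
  }
})

test_that("network summaries count a triangle and the generator truth", {
  tri <- mk_net(data.frame(chrom = "chr1", start = c(0L, 1000L, 2000L),
                           end = c(100L, 1100L, 2100L), annotation = "other"),
                data.frame(u = c(1L, 2L, 1L), v = c(2L, 3L, 3L), pet = 1L))
  s <- network_summary(tri)
  expect_equal(unlist(s[c("n_nodes", "n_edges", "n_components")]),
               c(n_nodes = 3, n_edges = 3, n_components = 1))
  pl <- shared_pipeline()
  s2 <- network_summary(pl$net)
  expect_equal(s2$n_edges, nrow(pl$net$edges))
  # every generated super-enhancer member that survived is annotated SE
  truth_se <- pl$gen$truth$nodes$node[!is.na(pl$gen$truth$nodes$domain)]
  in_net <- pl$net$nodes$peak %in% truth_se
  expect_true(all(pl$net$nodes$annotation[in_net] == "super_enhancer"))
  expect_equal(sum(in_net),
               unname(s2$annotation_counts["super_enhancer"]))
})

test_that("every node participates in at least one edge", {
  pl <- shared_pipeline()
  touched <- unique(c(pl$net$edges$u, pl$net$edges$v))
  expect_setequal(pl$net$nodes$node_id, touched)
  expect_lte(nrow(pl$net$nodes), nrow(read_bed(pl$gen$files$peaks)))
})
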