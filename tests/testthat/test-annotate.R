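seg <- function(chrom, start, end, state) {
  data.frame(chrom = chrom, start = start, end = end, state = state,
             stringsAsFactors = FALSE)
}

two_node_net <- function(states = c("other", "other")) {
  mk_net(data.frame(chrom = "chr1", start = c(1000L, 50000L),
                    end = c(2000L, 51000L), annotation = states),
         data.frame(u = 1L, v = 2L, pet = 1L))
}

no_tss <- data.frame(chrom = character(0), start = integer(0),
                     end = integer(0), gene_id = character(0),
                     strand = character(0))

test_that("state priority resolves multi-state overlaps", {
  net <- two_node_net()
  segs <- rbind(seg("chr1", 900, 2100, "enhancer"),
                seg("chr1", 900, 2100, "insulator"),
                seg("chr1", 49000, 52000, "repressed"),
                seg("chr1", 49000, 52000, "transcribed"))
  out <- assign_state(net, segs, no_tss)
  expect_equal(out$nodes$annotation, c("enhancer", "repressed"))
  # poised promoter yields to the active promoter state
  segs2 <- rbind(seg("chr1", 900, 2100, "poised_promoter"),
                 seg("chr1", 900, 2100, "promoter"),
                 seg("chr1", 49000, 52000, "low_signal"))
  out2 <- assign_state(net, segs2, no_tss)
  expect_equal(out2$nodes$annotation, c("promoter", "low_signal"))
  # no overlapping segment at all -> other
  out3 <- assign_state(net, seg("chr2", 0, 10, "promoter"), no_tss)
  expect_equal(out3$nodes$annotation, c("other", "other"))
})

test_that("promoter/enhancer ambiguity is settled by TSS proximity", {
  net <- two_node_net()
  segs <- rbind(seg("chr1", 900, 2100, "promoter"),
                seg("chr1", 900, 2100, "enhancer"),
                seg("chr1", 49000, 52000, "promoter"),
                seg("chr1", 49000, 52000, "enhancer"))
  tss <- data.frame(chrom = "chr1", start = c(3500L), end = c(3501L),
                    gene_id = "g1", strand = "+")
  # node 1 boundary at 2000, TSS at 3500 -> 1.5 kb away -> promoter;
  # node 2 is ~46 kb from the TSS -> enhancer
  out <- assign_state(net, segs, tss)
  expect_equal(out$nodes$annotation, c("promoter", "enhancer"))
  # TSS inside the node counts as distance 0
  tss_in <- data.frame(chrom = "chr1", start = 50500L, end = 50501L,
                       gene_id = "g2", strand = "-")
  out2 <- assign_state(net, segs, tss_in)
  expect_equal(out2$nodes$annotation[2], "promoter")
})

test_that("broad domains crown the largest-overlap promoter, ties crown all", {
  nodes <- data.frame(chrom = "chr1",
                      start = c(1000L, 5000L, 20000L),
                      end = c(1500L, 5400L, 21000L),
                      annotation = c("promoter", "promoter", "enhancer"))
  net <- mk_net(nodes, data.frame(u = c(1L, 2L), v = c(3L, 3L), pet = 1L))
  net$nodes$state <- net$nodes$annotation
  # domain overlaps node1 by 300 bp, node2 by 120 bp
  dom <- data.frame(chrom = "chr1", start = 1200L, end = 5120L)
  out <- assign_broad_domains(net, dom)
  expect_equal(out$nodes$annotation,
               c("broad_domain", "promoter", "enhancer"))
  # exact tie (200 bp each) relabels both
  dom_t <- data.frame(chrom = "chr1", start = 1300L, end = 5200L)
  out_t <- assign_broad_domains(net, dom_t)
  expect_equal(out_t$nodes$annotation[1:2], rep("broad_domain", 2))
  # a domain over an enhancer node changes nothing
  dom_e <- data.frame(chrom = "chr1", start = 20000L, end = 21000L)
  out_e <- assign_broad_domains(net, dom_e)
  expect_equal(out_e$nodes$annotation, nodes$annotation)
  expect_equal(out_e$log$bd_unmatched, 1)
})

test_that("super-enhancer overlay relabels enhancer nodes and records domains", {
  nodes <- data.frame(chrom = "chr1",
                      start = c(1000L, 3000L, 5000L, 9000L, 30000L),
                      end = c(1500L, 3500L, 5500L, 9500L, 30500L),
                      annotation = c("enhancer", "enhancer", "enhancer",
                                     "promoter", "enhancer"))
  net <- mk_net(nodes, data.frame(u = c(1L, 2L, 3L, 4L),
                                  v = c(2L, 3L, 4L, 5L), pet = 1L))
  net$nodes$state <- net$nodes$annotation
  se <- data.frame(chrom = "chr1", start = 900L, end = 9600L)
  out <- assign_super_enhancers(net, se)
  expect_equal(out$nodes$annotation,
               c(rep("super_enhancer", 3), "promoter", "enhancer"))
  expect_equal(nrow(out$se_domains), 3)
  expect_equal(unique(out$se_domains$domain_id), 1L)
})

test_that("annotation labels partition nodes exactly", {
  pl <- shared_pipeline()
  net <- pl$net
  expect_false(any(is.na(net$nodes$annotation)))
  ann <- table(net$nodes$annotation)
  st <- table(net$nodes$state)
  expect_equal(unname(ann["broad_domain"] + ann["promoter"]),
               unname(st["promoter"]))
  expect_equal(unname(ann["super_enhancer"] + ann["enhancer"]),
               unname(st["enhancer"]))
})

test_that("merging super-enhancer domains collapses members and edges", {
  nodes <- data.frame(chrom = "chr1",
                      start = c(1000L, 3000L, 20000L, 40000L),
                      end = c(1500L, 3500L, 20500L, 40500L),
                      annotation = c("super_enhancer", "super_enhancer",
                                     "enhancer", "promoter"))
  edges <- data.frame(u = c(1L, 1L, 2L, 3L), v = c(2L, 3L, 3L, 4L),
                      pet = c(5L, 2L, 3L, 1L))
  net <- mk_net(nodes, edges)
  net$nodes$state <- c("enhancer", "enhancer", "enhancer", "promoter")
  net$se_domains <- data.frame(node_id = c(1L, 2L), domain_id = c(1L, 1L))
  merged <- merge_super_enhancer_nodes(net)
  expect_equal(nrow(merged$nodes), 3)
  expect_equal(nrow(merged$edges), 2)
  m_id <- merged$nodes$node_id[merged$nodes$annotation == "super_enhancer"]
  e <- merged$edges[merged$edges$u == m_id | merged$edges$v == m_id, ]
  expect_equal(sum(e$pet), 5L)   # (1,3) pet 2 + (2,3) pet 3 merged
  expect_equal(merged$nodes$start[merged$nodes$node_id == m_id], 1000L)
  expect_equal(merged$nodes$end[merged$nodes$node_id == m_id], 3500L)
  # idempotent: merging again changes nothing
  expect_equal(merge_super_enhancer_nodes(merged), merged)
})

test_that("merging never increases node or edge counts", {
  pl <- shared_pipeline()
  merged <- merge_super_enhancer_nodes(pl$net)
  expect_lte(nrow(merged$nodes), nrow(pl$net$nodes))
  expect_lte(nrow(merged$edges), nrow(pl$net$edges))
})
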