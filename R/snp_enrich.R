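# GWAS SNP enrichment in target-partitioned enhancer sets.
#
# Enhancer and super-enhancer nodes are split by what they target in the
# network: E_BD (at least one broad-domain target) versus E_P (only
# regular-promoter targets). Per phenotype, a one-sided label-permutation
# test asks whether the fraction of E_BD nodes harboring at least one
# phenotype SNP exceeds the E_P fraction; Benjamini-Hochberg corrects
# across phenotypes.

#' Partition targeted enhancers by target class
#'
#' Enhancer/super-enhancer nodes with at least one broad-domain target go
#' to `e_bd`; those with only regular-promoter targets to `e_p`;
#' untargeted enhancers are excluded.
#'
#' @param assignment target assignment ([assign_targets()]).
#' @param net the annotated network.
#' @return list with integer node-id vectors `e_bd` and `e_p`.
#' @export
partition_enhancers <- function(assignment, net) {
  ann <- setNames(net$nodes$annotation, net$nodes$node_id)
  t_ann <- ann[as.character(assignment$target_id)]
  has_bd <- tapply(t_ann == "broad_domain", assignment$enhancer_id, any)
  ids <- as.integer(names(has_bd))
  list(e_bd = sort(ids[has_bd]), e_p = sort(ids[!has_bd]))
}

#' Which nodes harbor a phenotype SNP
#'
#' A node harbors a SNP iff any SNP of the phenotype falls inside the
#' node interval (0-based).
#'
#' @param net the network.
#' @param node_ids nodes to test.
#' @param snps SNP records ([read_snps()]).
#' @param phenotype phenotype name.
#' @return named logical vector over `node_ids`.
#' @export
snp_overlap <- function(net, node_ids, snps, phenotype) {
  sn <- snps[snps$phenotype == phenotype, , drop = FALSE]
  nodes <- net$nodes[match(node_ids, net$nodes$node_id), , drop = FALSE]
  out <- rep(FALSE, length(node_ids))
  if (nrow(sn)) {
    hits <- overlap_join(nodes, sn, extension = 0L)
    out[unique(hits$query)] <- TRUE
  }
  setNames(out, node_ids)
}

#' Permutation test for SNP enrichment in E_BD versus E_P
#'
#' Per phenotype: statistic = harboring fraction in `e_bd` minus in
#' `e_p`; the null is built by repartitioning the pooled nodes into sets
#' of the original sizes `n_perm` times. The one-sided p-value uses the
#' add-one estimator (b + 1)/(n_perm + 1), so it is never exactly 0.
#' Benjamini-Hochberg q-values are computed across phenotypes.
#'
#' @param net the network.
#' @param e_bd,e_p node-id vectors ([partition_enhancers()]).
#' @param snps SNP records.
#' @param phenotypes phenotypes to test (default: all in `snps`).
#' @param n_perm number of permutations (default 10000; fewer than 100
#'   triggers a warning).
#' @param seed RNG seed.
#' @return data frame (phenotype, n_ebd, n_ep, k_ebd, k_ep, statistic,
#'   p_value, bh_q).
#' @export
enrichment_test <- function(net, e_bd, e_p, snps, phenotypes = NULL,
                            n_perm = 10000L, seed = 1L) {
  if (!length(e_bd) || !length(e_p)) {
    stop("enrichment_test: both node sets must be non-empty")
  }
  if (n_perm < 100) warning("enrichment_test: n_perm < 100 is unreliable")
  if (is.null(phenotypes)) phenotypes <- sort(unique(snps$phenotype))
  n1 <- length(e_bd); n2 <- length(e_p)
  set.seed(seed)
  perm_idx <- replicate(n_perm, sample.int(n1 + n2, n1))
  res <- lapply(phenotypes, function(ph) {
    harb <- snp_overlap(net, c(e_bd, e_p), snps, ph)
    k1 <- sum(harb[seq_len(n1)]); k2 <- sum(harb[n1 + seq_len(n2)])
    stat <- k1 / n1 - k2 / n2
    if (sum(harb) == 0) {
      p <- 1
    } else {
      tot <- sum(harb)
      null_k1 <- colSums(matrix(harb[perm_idx], nrow = n1))
      null_stat <- null_k1 / n1 - (tot - null_k1) / n2
      p <- (sum(null_stat >= stat) + 1) / (n_perm + 1)
    }
    data.frame(phenotype = ph, n_ebd = n1, n_ep = n2,
               k_ebd = k1, k_ep = k2, statistic = stat, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$bh_q <- p.adjust(out$p_value, method = "BH")
  out
}
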