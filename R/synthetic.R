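# Synthetic data generator with recorded ground truth.
#
# Emulates the statistical structure the pipeline assumes: distance-
# decaying intra-chromosomal contacts capped at 1 Mb, annotation classes
# with planted enrichment multipliers (broad-domain/super-enhancer,
# within-domain super-enhancer, promoter-promoter), geometric PET counts,
# TSS and gene structure with cell-type-specific expression for
# broad-domain genes, phenotype SNPs planted preferentially in enhancers
# that target broad domains, and Poisson contact matrices with planted
# focal peaks. Every emitted file round-trips through the package
# readers.

#' Generator configuration
#'
#' @param seed RNG seed; all generator randomness derives from it.
#' @param n_chromosomes,chrom_length,n_nodes genome shape: chromosomes,
#'   length (bp) and nodes per chromosome. Nodes sit on a 5 kb grid so
#'   peaks never overlap and TSS assignments stay unambiguous.
#' @param proportions annotation proportions over
#'   promoter/broad_domain/enhancer/insulator/other for nodes outside
#'   super-enhancer domains; must sum to 1.
#' @param n_se_domains,members_per_domain super-enhancer domains per
#'   chromosome and constituent nodes per domain.
#' @param alpha distance-decay exponent of the edge probability
#'   `base_rate * (gd/1e6)^(-alpha)`.
#' @param base_rate baseline edge probability at 1 Mb separation
#'   (calibrated so the default genome yields roughly 4000 edges).
#' @param multipliers planted enrichment multipliers: `bd_se`
#'   (broad-domain to super-enhancer), `se_se_same` (within-domain
#'   super-enhancer pairs), `se_se_across`, `p_p` (pairs of
#'   promoter-state nodes, broad domains included, so broad domains
#'   accumulate hub-like connectivity); unlisted pairs are 1.
#' @param pet_mean mean of the geometric PET count (support >= 1).
#' @param panel_size expression panel width (cell/tissue types).
#' @param cell_type query cell type name (first panel column).
#' @param expr_high,expr_base expression level of a specific gene in its
#'   cell type, and the near-uniform baseline.
#' @param snp_rate background SNP rate per bp; `snp_fold` multiplies it
#'   in enhancers targeting broad domains; `n_control_phenotypes`
#'   background-only phenotypes.
#' @param matrix_bins,matrix_lambda,matrix_decay,loop_fold contact-matrix
#'   block: bins, background Poisson mean, distance-decay exponent of the
#'   background (0 = homogeneous), and planted peak fold.
#' @return list of class `chromnet_config`.
#' @export
generator_config <- function(seed = 1L, n_chromosomes = 3L,
                             chrom_length = 3e7, n_nodes = 600L,
                             proportions = c(promoter = 0.25,
                                             broad_domain = 0.06,
                                             enhancer = 0.39,
                                             insulator = 0.12,
                                             other = 0.18),
                             n_se_domains = 12L, members_per_domain = 5L,
                             alpha = 0.3, base_rate = 0.077,
                             multipliers = list(bd_se = 4, se_se_same = 5,
                                                se_se_across = 1, p_p = 2),
                             pet_mean = 4, panel_size = 23L,
                             cell_type = "query_cell",
                             expr_high = 50, expr_base = 10,
                             snp_rate = 5e-5, snp_fold = 5,
                             n_control_phenotypes = 3L,
                             matrix_bins = 300L, matrix_lambda = 10,
                             matrix_decay = 0, loop_fold = 10) {
  if (abs(sum(proportions) - 1) > 1e-8) {
    stop("generator_config: proportions must sum to 1")
  }
  if (n_se_domains * members_per_domain > 0.45 * n_nodes) {
    stop("generator_config: super-enhancer members exceed feasible count")
  }
  defaults <- list(bd_se = 1, se_se_same = 1, se_se_across = 1, p_p = 1)
  defaults[names(multipliers)] <- multipliers
  if (any(unlist(defaults) < 0)) stop("generator_config: multipliers < 0")
  structure(list(seed = seed, n_chromosomes = n_chromosomes,
                 chrom_length = chrom_length, n_nodes = n_nodes,
                 proportions = proportions, n_se_domains = n_se_domains,
                 members_per_domain = members_per_domain, alpha = alpha,
                 base_rate = base_rate, multipliers = defaults,
                 pet_mean = pet_mean, panel_size = panel_size,
                 cell_type = cell_type, expr_high = expr_high,
                 expr_base = expr_base, snp_rate = snp_rate,
                 snp_fold = snp_fold,
                 n_control_phenotypes = n_control_phenotypes,
                 matrix_bins = matrix_bins, matrix_lambda = matrix_lambda,
                 matrix_decay = matrix_decay, loop_fold = loop_fold),
            class = "chromnet_config")
}

#' Generate network-stage input files
#'
#' Writes peaks (BED), interaction calls (BEDPE), state segments (BED4),
#' broad-domain and super-enhancer regions (BED), and TSS definitions
#' (BED6) under `dir`, and returns the ground truth: per-node labels and
#' domain membership, the planted multipliers, and per-label-pair edge
#' bookkeeping.
#'
#' Nodes are placed on a 5 kb grid; candidate node pairs within 1 Mb are
#' turned into edges by independent Bernoulli draws with probability
#' `base_rate * (gd/1e6)^(-alpha) * M(label_u, label_v)` (clipped at
#' 0.9); PET counts are geometric with the configured mean.
#'
#' @param cfg a [generator_config()].
#' @param dir output directory (created if needed).
#' @return invisibly, a list with `files` (paths) and `truth`.
#' @export
generate_network_inputs <- function(cfg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  nodes <- list(); se_regions <- list(); truth_dom <- list()
  for (ci in seq_len(cfg$n_chromosomes)) {
    ch <- paste0("chr", ci)
    slots <- floor(cfg$chrom_length / 5000) - 2
    mid <- (sort(sample.int(slots, cfg$n_nodes)) + 1) * 5000
    w <- round(runif(cfg$n_nodes, 400, 1200))
    start <- as.integer(mid - w %/% 2)
    end <- as.integer(start + w)
    lab <- rep(NA_character_, cfg$n_nodes)
    dom <- rep(NA_integer_, cfg$n_nodes)
    # contiguous runs of nodes become super-enhancer domains
    m <- cfg$members_per_domain
    starts_pool <- seq(1, cfg$n_nodes - m + 1)
    run_starts <- integer(0)
    while (length(run_starts) < cfg$n_se_domains) {
      s <- sample(starts_pool, 1)
      if (!any(abs(s - run_starts) < m + 2)) run_starts <- c(run_starts, s)
    }
    run_starts <- sort(run_starts)
    for (di in seq_along(run_starts)) {
      ix <- run_starts[di] + 0:(m - 1)
      lab[ix] <- "super_enhancer"
      dom[ix] <- (ci - 1) * cfg$n_se_domains + di
      se_regions[[length(se_regions) + 1]] <- data.frame(
        chrom = ch, start = min(start[ix]) - 200L, end = max(end[ix]) + 200L)
    }
    rest <- which(is.na(lab))
    lab[rest] <- sample(names(cfg$proportions), length(rest),
                        replace = TRUE, prob = cfg$proportions)
    nodes[[ci]] <- data.frame(chrom = ch, start = start, end = end,
                              label = lab, domain = dom,
                              stringsAsFactors = FALSE)
  }
  nodes <- do.call(rbind, nodes)
  nodes$node <- seq_len(nrow(nodes))
  se_regions <- do.call(rbind, se_regions)

  # edges
  edges <- list(); pair_counts <- list()
  for (ch in unique(nodes$chrom)) {
    nd <- nodes[nodes$chrom == ch, , drop = FALSE]
    midp <- (nd$start + nd$end) / 2
    n <- nrow(nd)
    hi <- findInterval(midp + 1e6, midp)
    ii <- rep(seq_len(n), pmax(0, hi - seq_len(n)))
    jj <- unlist(lapply(seq_len(n), function(i)
      if (hi[i] > i) (i + 1):hi[i] else integer(0)))
    gd <- midp[jj] - midp[ii]
    M <- planted_multiplier(nd$label[ii], nd$label[jj],
                            nd$domain[ii], nd$domain[jj], cfg$multipliers)
    p <- pmin(0.9, cfg$base_rate * (gd / 1e6)^(-cfg$alpha) * M)
    hit <- runif(length(p)) < p
    if (any(hit)) {
      edges[[ch]] <- data.frame(
        chrom1 = ch, start1 = nd$start[ii[hit]], end1 = nd$end[ii[hit]],
        chrom2 = ch, start2 = nd$start[jj[hit]], end2 = nd$end[jj[hit]],
        pet = rgeom(sum(hit), 1 / cfg$pet_mean) + 1L,
        u = nd$node[ii[hit]], v = nd$node[jj[hit]])
    }
    pair_counts[[ch]] <- data.frame(expected_edges = sum(p),
                                    admissible_pairs = length(p))
  }
  edges <- do.call(rbind, edges)
  rownames(edges) <- NULL

  files <- list(
    peaks = file.path(dir, "peaks.bed"),
    calls = file.path(dir, "calls.bedpe"),
    states = file.path(dir, "states.bed"),
    broad_domains = file.path(dir, "broad_domains.bed"),
    super_enhancers = file.path(dir, "super_enhancers.bed"),
    tss = file.path(dir, "tss.bed"))
  write_bed(nodes[, c("chrom", "start", "end")], files$peaks)
  write_bedpe(edges[, 1:7], files$calls)

  base_state <- c(promoter = "promoter", broad_domain = "promoter",
                  enhancer = "enhancer", super_enhancer = "enhancer",
                  insulator = "insulator", other = NA)
  st <- nodes[!is.na(base_state[nodes$label]), , drop = FALSE]
  states <- data.frame(chrom = st$chrom, start = st$start, end = st$end,
                       name = unname(base_state[st$label]))
  write_bed(states, files$states)

  bd <- nodes[nodes$label == "broad_domain", , drop = FALSE]
  write_bed(data.frame(chrom = bd$chrom, start = bd$start - 500L,
                       end = bd$end + 500L), files$broad_domains)
  write_bed(se_regions, files$super_enhancers)

  prom <- nodes[nodes$label %in% c("promoter", "broad_domain"), ,
                drop = FALSE]
  tss_pos <- as.integer((prom$start + prom$end) %/% 2)
  tss <- data.frame(chrom = prom$chrom, start = tss_pos,
                    end = tss_pos + 1L,
                    name = sprintf("gene_%05d", prom$node),
                    strand = sample(c("+", "-"), nrow(prom), replace = TRUE))
  write_bed(tss, files$tss)

  truth <- list(nodes = nodes, se_regions = se_regions,
                genes = data.frame(gene_id = tss$name, node = prom$node,
                                   label = prom$label,
                                   stringsAsFactors = FALSE),
                edges = edges, pair_counts = pair_counts,
                multipliers = cfg$multipliers, config = cfg)
  invisible(list(files = files, truth = truth))
}

planted_multiplier <- function(la, lb, da, db, mult) {
  M <- rep(1, length(la))
  bd_se <- (la == "broad_domain" & lb == "super_enhancer") |
    (la == "super_enhancer" & lb == "broad_domain")
  M[bd_se] <- mult$bd_se
  sese <- la == "super_enhancer" & lb == "super_enhancer"
  same <- sese & !is.na(da) & !is.na(db) & da == db
  M[sese & !same] <- mult$se_se_across
  M[same] <- mult$se_se_same
  # promoter-promoter boost covers broad domains (promoter-state nodes)
  promlike <- c("promoter", "broad_domain")
  pp <- la %in% promlike & lb %in% promlike
  M[pp & !bd_se] <- mult$p_p
  M
}

#' Generate an expression panel
#'
#' One gene per promoter-side node. Genes of broad-domain nodes are
#' cell-type specific (high expression only in `cfg$cell_type`); all
#' other genes near-uniform across the panel, giving SPM near
#' `1/sqrt(panel_size)`.
#'
#' @param cfg a [generator_config()].
#' @param truth ground truth from [generate_network_inputs()].
#' @param path output TSV path.
#' @return invisibly the expression matrix.
#' @export
generate_expression <- function(cfg, truth, path) {
  set.seed(cfg$seed + 1L)
  genes <- truth$genes
  types <- c(cfg$cell_type,
             sprintf("tissue_%02d", seq_len(cfg$panel_size - 1)))
  m <- matrix(abs(rnorm(nrow(genes) * cfg$panel_size, cfg$expr_base,
                        cfg$expr_base / 10)),
              nrow = nrow(genes), dimnames = list(genes$gene_id, types))
  specific <- genes$label == "broad_domain"
  m[specific, ] <- abs(rnorm(sum(specific) * cfg$panel_size, cfg$expr_base / 10,
                         cfg$expr_base / 30))
  m[specific, cfg$cell_type] <- cfg$expr_high
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(m)
}

#' Generate phenotype SNPs
#'
#' One disease phenotype whose per-bp SNP rate is `snp_fold` times the
#' background inside the given E_BD nodes, plus background-rate control
#' phenotypes; SNP counts per node are Poisson in the node length.
#'
#' @param cfg a [generator_config()].
#' @param truth ground truth.
#' @param e_bd node ids (generator numbering, `truth$nodes$node`) of
#'   enhancers targeting broad domains.
#' @param path output TSV path.
#' @return invisibly the SNP data frame.
#' @export
generate_snps <- function(cfg, truth, e_bd, path) {
  set.seed(cfg$seed + 2L)
  nd <- truth$nodes
  len <- nd$end - nd$start
  phenos <- c("disease", sprintf("control_%d", seq_len(cfg$n_control_phenotypes)))
  out <- list()
  for (ph in phenos) {
    rate <- cfg$snp_rate * len
    if (ph == "disease") rate[nd$node %in% e_bd] <- rate[nd$node %in% e_bd] *
        cfg$snp_fold
    k <- rpois(nrow(nd), rate)
    ix <- rep(seq_len(nrow(nd)), k)
    if (!length(ix)) next
    pos0 <- nd$start[ix] + floor(runif(length(ix)) * len[ix])
    out[[ph]] <- data.frame(phenotype = ph, chrom = nd$chrom[ix],
                            start = as.integer(pos0),
                            end = as.integer(pos0) + 1L,
                            stringsAsFactors = FALSE)
  }
  snps <- do.call(rbind, out)
  rownames(snps) <- NULL
  write_snps(snps, path)
  invisible(snps)
}

#' Generate a contact matrix with planted focal peaks
#'
#' Poisson background `matrix_lambda * (1 + d)^(-matrix_decay)` at bin
#' distance d (homogeneous when the decay is 0); planted peaks draw
#' their count at `loop_fold` times the local background mean.
#'
#' @param cfg a [generator_config()].
#' @param planted data frame (bin_i, bin_j) of peak positions (0-based),
#'   or NULL for a null matrix.
#' @param chrom chromosome name for the matrix.
#' @return list with `matrix` (a `contact_matrix`) and `planted`.
#' @export
generate_contact_matrix <- function(cfg, planted = NULL, chrom = "chr1") {
  set.seed(cfg$seed + 3L)
  n <- cfg$matrix_bins
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  d <- idx[, 2] - idx[, 1]
  lam <- cfg$matrix_lambda * (1 + d)^(-cfg$matrix_decay)
  cnt <- rpois(nrow(idx), lam)
  df <- data.frame(bin_i = idx[, 1] - 1L, bin_j = idx[, 2] - 1L,
                   count = cnt)
  if (!is.null(planted) && nrow(planted)) {
    for (r in seq_len(nrow(planted))) {
      i <- planted$bin_i[r]; j <- planted$bin_j[r]
      lam_ij <- cfg$matrix_lambda * (1 + (j - i))^(-cfg$matrix_decay)
      df$count[df$bin_i == i & df$bin_j == j] <-
        rpois(1, cfg$loop_fold * lam_ij)
    }
  }
  df <- df[df$count > 0, , drop = FALSE]
  list(matrix = contact_matrix(df, chrom, 1000L, n), planted = planted)
}
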