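# Graphlet / orbit machinery.
#
# Graphlets are the connected non-isomorphic graphs on 2-5 vertices
# (30 of them); orbits are the automorphism-equivalence classes of their
# vertices (73 in total). The catalog is generated from scratch by
# exhaustive enumeration; nothing is hard-coded.

# pair index for the adjacency bit code, combn(k, 2) order
pair_index <- function(k) {
  p <- combn(k, 2)
  m <- matrix(NA_integer_, k, k)
  for (b in seq_len(ncol(p))) {
    m[p[1, b], p[2, b]] <- b
    m[p[2, b], p[1, b]] <- b
  }
  m
}

all_perms <- function(k) {
  if (k == 1) return(list(1L))
  out <- list()
  for (i in seq_len(k)) {
    rest <- all_perms(k - 1)
    for (r in rest) {
      v <- integer(k); v[1] <- i
      v[-1] <- setdiff(seq_len(k), i)[r]
      out[[length(out) + 1]] <- v
    }
  }
  out
}

code_to_adj <- function(code, k, pidx) {
  a <- matrix(FALSE, k, k)
  p <- combn(k, 2)
  bits <- as.integer(intToBits(code))[seq_len(ncol(p))]
  for (b in which(bits == 1L)) {
    a[p[1, b], p[2, b]] <- TRUE
    a[p[2, b], p[1, b]] <- TRUE
  }
  a
}

adj_to_code <- function(a, pidx) {
  k <- nrow(a)
  p <- combn(k, 2)
  sum(2^(which(a[cbind(p[1, ], p[2, ])]) - 1))
}

# relabel graph: vertex v of the input becomes perm[v] in the output
recode <- function(code, perm, k, pidx) {
  a <- code_to_adj(code, k, pidx)
  b <- matrix(FALSE, k, k)
  b[perm, perm] <- a
  adj_to_code(b, pidx)
}

# bit-level permutation table: column p gives, for each bit of the code,
# the bit it maps to under permutation p (edge (i,j) -> (p[i], p[j]))
perm_bit_table <- function(k, perms, pidx) {
  pr <- combn(k, 2)
  vapply(perms, function(p) {
    pidx[cbind(p[pr[1, ]], p[pr[2, ]])]
  }, integer(ncol(pr)))
}

adj_connected <- function(a) {
  k <- nrow(a)
  seen <- logical(k); seen[1] <- TRUE
  frontier <- 1L
  while (length(frontier)) {
    nxt <- which(apply(a[frontier, , drop = FALSE], 2, any) & !seen)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  all(seen)
}

#' Build the graphlet orbit catalog
#'
#' Enumerates every graph on 2-5 labeled vertices, keeps the connected
#' ones, deduplicates up to isomorphism (30 graphlets) and computes the
#' vertex automorphism orbits of each (73 orbits). Graphlets are ordered
#' by (vertex count, edge count, descending degree sequence, canonical
#' adjacency code); orbits within a graphlet by increasing vertex degree,
#' so that orbit 0 is the edge endpoint, orbits 1/2 the 3-path end/middle,
#' orbit 3 the triangle, and the last orbit the 5-clique.
#'
#' @return an object of class `orbit_catalog`: list with `graphlets`
#'   (data frame: graphlet_id, n, m), `orbits` (data frame: orbit_id,
#'   graphlet_id, degree), `adj` (list of adjacency matrices),
#'   `vertex_orbit` (per graphlet, canonical-vertex -> orbit_id) and `lut`
#'   (per size, labeled-code x position -> orbit_id lookup used by the
#'   counter).
#' @export
build_orbit_catalog <- function() {
  graphlets <- list()   # each: list(k, m, code, adj, degseq)
  for (k in 2:5) {
    pidx <- pair_index(k)
    perms <- all_perms(k)
    nbits <- k * (k - 1) / 2
    canon_of_code <- rep(NA_real_, 2^nbits)
    canon_perm <- vector("list", 2^nbits)
    seen_canon <- numeric(0)
    bt <- perm_bit_table(k, perms, pidx)
    if (is.null(dim(bt))) bt <- matrix(bt, nrow = 1)
    pow2 <- 2^(bt - 1)           # nbits x nperms: weight of each old bit
    for (code in 0:(2^nbits - 1)) {
      a <- code_to_adj(code, k, pidx)
      if (!adj_connected(a)) next
      bits <- as.integer(intToBits(code))[seq_len(nbits)] == 1L
      rcs <- colSums(pow2[bits, , drop = FALSE])
      best <- min(rcs); bestp <- perms[[which.min(rcs)]]
      canon_of_code[code + 1] <- best
      canon_perm[[code + 1]] <- bestp
      if (!(best %in% seen_canon)) {
        seen_canon <- c(seen_canon, best)
        ac <- code_to_adj(best, k, pidx)
        graphlets[[length(graphlets) + 1]] <- list(
          k = k, m = sum(ac) / 2, code = best, adj = ac,
          degseq = sort(colSums(ac), decreasing = TRUE))
      }
    }
    attr(graphlets, paste0("canon_of_code_", k)) <- canon_of_code
    attr(graphlets, paste0("canon_perm_", k)) <- canon_perm
  }
  # deterministic graphlet order
  ord <- order(vapply(graphlets, `[[`, 0, "k"),
               vapply(graphlets, `[[`, 0, "m"),
               vapply(graphlets, function(g)
                 sum(g$degseq * (10^((length(g$degseq) - 1):0))), 0),
               vapply(graphlets, `[[`, 0, "code"))
  graphlets_sorted <- graphlets[ord]

  # automorphism orbits per graphlet, on the canonical representative
  orbit_id <- 0L
  orbits <- list(); vertex_orbit <- list()
  for (gi in seq_along(graphlets_sorted)) {
    g <- graphlets_sorted[[gi]]
    k <- g$k; pidx <- pair_index(k)
    autos <- Filter(function(p) recode(g$code, p, k, pidx) == g$code,
                    all_perms(k))
    # orbit partition: v ~ u iff some automorphism maps v to u
    part <- rep(NA_integer_, k)
    for (v in seq_len(k)) {
      if (!is.na(part[v])) next
      members <- unique(vapply(autos, `[`, 0L, v))
      part[members] <- v
    }
    reps <- unique(part)
    deg <- colSums(g$adj)
    reps <- reps[order(deg[reps], reps)]
    vmap <- integer(k)
    for (r in reps) {
      vmap[part == r] <- orbit_id
      orbits[[orbit_id + 1]] <- data.frame(
        orbit_id = orbit_id, graphlet_id = gi - 1L, degree = deg[r])
      orbit_id <- orbit_id + 1L
    }
    vertex_orbit[[gi]] <- vmap
  }

  # labeled-code lookup tables for the counter
  lut <- list()
  canon_codes <- vapply(graphlets_sorted, `[[`, 0, "code")
  canon_k <- vapply(graphlets_sorted, `[[`, 0, "k")
  for (k in 2:5) {
    coc <- attr(graphlets, paste0("canon_of_code_", k))
    cpm <- attr(graphlets, paste0("canon_perm_", k))
    nb <- 2^(k * (k - 1) / 2)
    tab <- matrix(-1L, nrow = nb, ncol = k)
    for (code in 0:(nb - 1)) {
      if (is.na(coc[code + 1])) next
      gi <- which(canon_codes == coc[code + 1] & canon_k == k)
      p <- cpm[[code + 1]]
      # vertex v of the labeled graph sits at canonical position p[v]
      tab[code + 1, ] <- vertex_orbit[[gi]][p]
    }
    lut[[k]] <- tab
  }

  structure(list(
    graphlets = data.frame(
      graphlet_id = seq_along(graphlets_sorted) - 1L,
      n = vapply(graphlets_sorted, `[[`, 0, "k"),
      m = vapply(graphlets_sorted, `[[`, 0, "m")),
    orbits = do.call(rbind, orbits),
    adj = lapply(graphlets_sorted, `[[`, "adj"),
    vertex_orbit = vertex_orbit,
    lut = lut
  ), class = "orbit_catalog")
}

#' @export
print.orbit_catalog <- function(x, ...) {
  cat(sprintf("orbit catalog: %d graphlets (2-5 vertices), %d orbits\n",
              nrow(x$graphlets), nrow(x$orbits)))
  invisible(x)
}

the_catalog <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_orbit_catalog()
    cache
  }
})

#' Per-node graphlet orbit signatures
#'
#' For every node, counts the connected induced subgraphs of size 2-5 it
#' participates in, classified by the orbit the node occupies (ESU
#' enumeration, each induced subgraph visited exactly once). Column `o0`
#' equals the node degree. Proportions normalise each node's 73 counts to
#' sum to 1 (all-zero rows stay zero).
#'
#' @param net a `chromnet` network (or an igraph graph).
#' @param catalog an [build_orbit_catalog()] result; the packaged catalog
#'   by default.
#' @return list with `counts` and `proportions`: numeric matrices, one row
#'   per node (rownames = node ids), 73 columns `o0..o72`.
#' @export
count_orbits <- function(net, catalog = the_catalog()) {
  g <- as_igraph_any(net)
  n <- igraph::vcount(g)
  counts <- matrix(0, nrow = n, ncol = 73,
                   dimnames = list(igraph::V(g)$name, paste0("o", 0:72)))
  if (n > 0 && igraph::ecount(g) > 0) {
    adj <- lapply(igraph::as_adj_list(g, mode = "all"),
                  function(v) sort(as.integer(v)) - 1L)
    luts <- lapply(2:5, function(k) as.integer(t(catalog$lut[[k]])))
    cnt <- orbit_counts_esu(adj, luts)
    counts[, ] <- cnt
  }
  tot <- rowSums(counts)
  prop <- counts / ifelse(tot > 0, tot, 1)
  list(counts = counts, proportions = prop)
}

as_igraph_any <- function(net) {
  if (inherits(net, "igraph")) {
    g <- net
    if (is.null(igraph::V(g)$name)) {
      igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
    }
    g
  } else if (inherits(net, "chromnet")) {
    as_igraph(net)
  } else {
    stop("expected a chromnet network or an igraph graph")
  }
}

#' Cluster orbits by cross-node Spearman correlation
#'
#' Orbits 0 and 1 (edge endpoint and 3-path end), which behave alike for
#' all nodes, are excluded. The remaining 71 orbits are clustered
#' agglomeratively (average linkage) on distance 1 - Spearman rho between
#' their per-node proportion profiles, and the tree is cut at correlation
#' `cutoff`. Orbits with zero variance across nodes cannot be correlated
#' and are reported in a `degenerate` vector, not assigned to a cluster.
#' Clusters are numbered by their smallest member orbit index.
#'
#' @param signatures result of [count_orbits()] (or a node x 73 proportion
#'   matrix).
#' @param cutoff Spearman correlation cutoff at which the dendrogram is
#'   cut (default 0.3, i.e. height 0.7).
#' @param k optionally force a fixed number of clusters instead of the
#'   correlation cutoff.
#' @param exclude orbit indices excluded from clustering (default 0:1).
#' @return object of class `orbit_clustering`: list with `cluster` (named
#'   integer vector orbit -> cluster), `degenerate` (orbit names), `k`,
#'   `cutoff`, `hclust`.
#' @export
cluster_orbits <- function(signatures, cutoff = 0.3, k = NULL,
                           exclude = 0:1) {
  prop <- if (is.list(signatures) && !is.null(signatures$proportions)) {
    signatures$proportions
  } else signatures
  stopifnot(ncol(prop) == 73, nrow(prop) >= 2)
  keep <- setdiff(0:72, exclude)
  m <- prop[, paste0("o", keep), drop = FALSE]
  degen <- colnames(m)[apply(m, 2, function(x) length(unique(x)) == 1)]
  m <- m[, setdiff(colnames(m), degen), drop = FALSE]
  rho <- suppressWarnings(cor(m, method = "spearman"))
  d <- as.dist(1 - rho)
  hc <- hclust(d, method = "average")
  cl <- if (is.null(k)) cutree(hc, h = 1 - cutoff) else cutree(hc, k = k)
  # renumber clusters by smallest member orbit index
  first <- vapply(split(as.integer(sub("^o", "", names(cl))), cl), min, 0)
  remap <- setNames(rank(first), names(first))
  cl <- setNames(as.integer(remap[as.character(cl)]), names(cl))
  structure(list(cluster = cl, degenerate = degen,
                 k = length(unique(cl)), cutoff = cutoff, hclust = hc),
            class = "orbit_clustering")
}

#' @export
print.orbit_clustering <- function(x, ...) {
  cat(sprintf("orbit clustering: %d clusters (cutoff %.2f), %d degenerate orbit(s)\n",
              x$k, x$cutoff, length(x$degenerate)))
  invisible(x)
}

#' Central orbit cluster
#'
#' Returns the id of the cluster containing orbit `o2` (the middle of
#' the 3-path), the canonical "node between others" orbit; its score is
#' a hubness/centrality summary comparable across annotations.
#'
#' @param clustering an [cluster_orbits()] result.
#' @return integer cluster id.
#' @export
central_cluster <- function(clustering) {
  unname(clustering$cluster["o2"])
}

#' Per-node orbit cluster scores
#'
#' For node i and cluster k the score is `max_j (O_ij - mu_j) / sigma_j`
#' over the cluster's member orbits j, where O_ij is the node's normalised
#' orbit proportion and mu_j, sigma_j are that orbit's mean and
#' (population) standard deviation over all nodes. Orbits with zero
#' standard deviation contribute a z-score of 0.
#'
#' @param signatures result of [count_orbits()].
#' @param clustering result of [cluster_orbits()] on the same node set.
#' @return numeric matrix, node x cluster, columns `CS1..CSk`.
#' @export
cluster_scores <- function(signatures, clustering) {
  prop <- if (is.list(signatures) && !is.null(signatures$proportions)) {
    signatures$proportions
  } else signatures
  ks <- sort(unique(clustering$cluster))
  out <- matrix(0, nrow(prop), length(ks),
                dimnames = list(rownames(prop), paste0("CS", ks)))
  n <- nrow(prop)
  for (k in ks) {
    orbs <- names(clustering$cluster)[clustering$cluster == k]
    z <- vapply(orbs, function(o) {
      x <- prop[, o]
      mu <- mean(x)
      sg <- sqrt(mean((x - mu)^2))   # population SD
      if (sg == 0) rep(0, n) else (x - mu) / sg
    }, numeric(n))
    if (is.null(dim(z))) z <- matrix(z, nrow = n)
    out[, paste0("CS", k)] <- apply(z, 1, max)
  }
  out
}
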