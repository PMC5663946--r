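# Test fixtures and independent oracles, all built in code.

# construct a chromnet object directly from node/edge tables
mk_net <- function(nodes, edges) {
  nodes$node_id <- seq_len(nrow(nodes))
  if (is.null(nodes$state)) nodes$state <- nodes$annotation
  net <- structure(list(nodes = nodes, edges = edges, se_domains = NULL,
                        log = list()), class = "chromnet")
  net$nodes$component <- connected_components(net)
  net
}

# hand-checkable enrichment network: one chromosome, four nodes mutually
# within 1 Mb, labels A = {n1, n2}, B = {n3, n4},
# edges (n1,n3), (n2,n4), (n1,n2)
toy_ab_net <- function() {
  nodes <- data.frame(chrom = "chr1",
                      start = c(10000, 200000, 400000, 600000),
                      end = c(11000, 201000, 401000, 601000),
                      annotation = c("A", "A", "B", "B"))
  edges <- data.frame(u = c(1L, 2L, 1L), v = c(3L, 4L, 2L),
                      pet = c(1L, 1L, 1L))
  mk_net(nodes, edges)
}

shared_catalog <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_orbit_catalog()
    cache
  }
})

# a generated dataset shared across tests (single build per run)
shared_pipeline <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- generator_config(seed = 11L)
      dir <- file.path(tempdir(), "chromnet-shared")
      gen <- generate_network_inputs(cfg, dir)
      net <- build_network(read_bedpe(gen$files$calls),
                           read_bed(gen$files$peaks))
      tss <- read_tss(gen$files$tss)
      net <- annotate_network(net, read_states(gen$files$states), tss,
                              read_bed(gen$files$broad_domains),
                              read_bed(gen$files$super_enhancers))
      cache <<- list(cfg = cfg, gen = gen, net = net, tss = tss, dir = dir)
    }
    cache
  }
})

random_gnp <- function(n, p, seed) {
  set.seed(seed)
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- as.character(seq_len(n))
  g
}

## ---- independent orbit-counting oracle -------------------------------
## Enumerates every vertex subset of size 2-5 (combn), keeps connected
## induced subgraphs, and classifies the position of each vertex by
## explicit permutation search against the catalog's canonical graphlets.

oracle_pidx <- function(k) {
  p <- combn(k, 2)
  m <- matrix(NA_integer_, k, k)
  for (b in seq_len(ncol(p))) {
    m[p[1, b], p[2, b]] <- b; m[p[2, b], p[1, b]] <- b
  }
  m
}

oracle_perms <- function(k) {
  if (k == 1) return(list(1L))
  out <- list()
  for (i in seq_len(k)) for (r in oracle_perms(k - 1)) {
    v <- integer(k); v[1] <- i; v[-1] <- setdiff(seq_len(k), i)[r]
    out[[length(out) + 1]] <- v
  }
  out
}

oracle_code <- function(a) {
  k <- nrow(a); p <- combn(k, 2)
  sum(2^(which(a[cbind(p[1, ], p[2, ])]) - 1))
}

oracle_connected <- function(a) {
  k <- nrow(a); seen <- logical(k); seen[1] <- TRUE; stack <- 1L
  while (length(stack)) {
    v <- stack[1]; stack <- stack[-1]
    nb <- which(a[v, ] & !seen)
    seen[nb] <- TRUE; stack <- c(stack, nb)
  }
  all(seen)
}

oracle_orbit_counts <- function(g, catalog) {
  n <- igraph::vcount(g)
  A <- as.matrix(igraph::as_adjacency_matrix(g)) > 0
  counts <- matrix(0, n, 73, dimnames = list(igraph::V(g)$name,
                                             paste0("o", 0:72)))
  canon <- vapply(seq_len(nrow(catalog$graphlets)), function(gi)
    oracle_code(catalog$adj[[gi]]), 0)
  kk <- catalog$graphlets$n
  for (k in 2:5) {
    if (n < k) next
    perms <- oracle_perms(k)
    subsets <- combn(n, k)
    for (s in seq_len(ncol(subsets))) {
      vs <- subsets[, s]
      a <- A[vs, vs, drop = FALSE]
      if (!oracle_connected(a)) next
      best <- Inf; bestp <- NULL
      for (p in perms) {
        b <- matrix(FALSE, k, k); b[p, p] <- a
        cd <- oracle_code(b)
        if (cd < best) { best <- cd; bestp <- p }
      }
      gi <- which(canon == best & kk == k)
      orb <- catalog$vertex_orbit[[gi]]
      for (i in seq_len(k)) {
        counts[vs[i], orb[bestp[i]] + 1] <- counts[vs[i], orb[bestp[i]] + 1] + 1
      }
    }
  }
  counts
}

## ---- independent centrality oracle -----------------------------------
## All-pairs BFS for distances; betweenness by enumerating every simple
## path and keeping the shortest ones (feasible for n <= 8).

oracle_centralities <- function(g) {
  n <- igraph::vcount(g)
  A <- as.matrix(igraph::as_adjacency_matrix(g)) > 0
  dist <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    d <- rep(Inf, n); d[s] <- 0; frontier <- s
    while (length(frontier)) {
      nxt <- unique(unlist(lapply(frontier, function(v) which(A[v, ]))))
      nxt <- nxt[d[nxt] == Inf]
      d[nxt] <- d[frontier[1]] + 1
      frontier <- nxt
    }
    dist[s, ] <- d
  }
  all_paths <- function(u, x) {
    paths <- list()
    walk <- function(v, seen) {
      if (v == x) { paths[[length(paths) + 1]] <<- seen; return() }
      for (w in which(A[v, ])) if (!(w %in% seen)) walk(w, c(seen, w))
    }
    walk(u, u)
    paths
  }
  btw <- numeric(n)
  for (u in seq_len(n)) for (x in seq_len(n)) {
    if (u >= x || !is.finite(dist[u, x])) next
    ps <- all_paths(u, x)
    lens <- lengths(ps) - 1
    sp <- ps[lens == min(lens)]
    for (v in seq_len(n)) {
      if (v == u || v == x) next
      btw[v] <- btw[v] + mean(vapply(sp, function(p) v %in% p, TRUE))
    }
  }
  comp <- igraph::components(g)$membership
  clo <- har <- numeric(n)
  for (v in seq_len(n)) {
    others <- setdiff(which(comp == comp[v]), v)
    clo[v] <- if (length(others)) 1 / sum(dist[v, others]) else 0
    har[v] <- sum(1 / dist[v, others])
  }
  list(closeness = clo, harmonic = har, betweenness = btw,
       degree = rowSums(A))
}
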