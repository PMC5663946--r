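test_that("the orbit catalog has the known graphlet and orbit structure", {
  cat_ <- shared_catalog()
  expect_equal(nrow(cat_$graphlets), 30)
  expect_equal(nrow(cat_$orbits), 73)
  # connected graph counts per size: 1, 2, 6, 21
  expect_equal(as.integer(table(cat_$graphlets$n)), c(1L, 2L, 6L, 21L))
  # the single 2-vertex graphlet has one orbit; complete graphs one orbit
  per_graphlet <- table(cat_$orbits$graphlet_id)
  expect_equal(unname(per_graphlet["0"]), 1L)
  cliques <- which(cat_$graphlets$m == choose(cat_$graphlets$n, 2))
  for (gi in cliques) {
    expect_equal(unname(per_graphlet[as.character(gi - 1)]), 1L)
  }
  # orbits within each graphlet partition its vertices
  for (gi in seq_along(cat_$vertex_orbit)) {
    vo <- cat_$vertex_orbit[[gi]]
    expect_equal(length(vo), cat_$graphlets$n[gi])
    expect_true(all(vo %in% cat_$orbits$orbit_id[
      cat_$orbits$graphlet_id == gi - 1]))
  }
})

test_that("orbit counts reproduce closed forms on canonical graphs", {
  cat_ <- shared_catalog()
  tri <- count_orbits(igraph::make_ring(3), cat_)$counts
  expect_equal(unname(tri[1, "o0"]), 2)
  expect_equal(unname(tri[1, "o3"]), 1)
  expect_equal(unname(tri[1, "o1"]), 0)  # only induced 3-set is the triangle
  k5 <- count_orbits(igraph::make_full_graph(5), cat_)$counts
  expect_equal(unname(k5[1, "o72"]), 1)
  expect_equal(unname(k5[1, "o14"]), choose(4, 3))
  star <- count_orbits(igraph::make_star(4, "undirected", center = 1),
                       cat_)$counts
  expect_equal(unname(star[1, "o2"]), choose(3, 2))
  expect_equal(unname(star[1, "o7"]), 1)
})

test_that("orbit counts match exhaustive enumeration on random graphs", {
  cat_ <- shared_catalog()
  for (seed in 1:8) {
    n <- sample(6:12, 1)
    g <- random_gnp(n, runif(1, 0.2, 0.5), seed)
    got <- count_orbits(g, cat_)$counts
    want <- oracle_orbit_counts(g, cat_)
    expect_equal(got, want, ignore_attr = TRUE)
  }
})

test_that("orbit counts are isomorphism invariant and degree-consistent", {
  cat_ <- shared_catalog()
  g <- random_gnp(10, 0.35, 99)
  c1 <- count_orbits(g, cat_)$counts
  set.seed(1); perm <- sample(10)
  g2 <- igraph::permute(g, perm)
  c2 <- count_orbits(g2, cat_)$counts
  expect_equal(unname(c2[perm, ]), unname(c1))
  expect_equal(unname(c1[, "o0"]), unname(igraph::degree(g)))
})

test_that("orbit counts across one graphlet agree on the subgraph total", {
  # sum over nodes of counts[j] / |orbit j| must be equal for all orbits
  # of one graphlet (each induced subgraph is counted once per position)
  cat_ <- shared_catalog()
  g <- random_gnp(11, 0.4, 5)
  cnt <- count_orbits(g, cat_)$counts
  orbit_size <- vapply(seq_len(nrow(cat_$orbits)), function(i) {
    gi <- cat_$orbits$graphlet_id[i] + 1
    sum(cat_$vertex_orbit[[gi]] == cat_$orbits$orbit_id[i])
  }, 0)
  tot <- colSums(cnt) / orbit_size
  for (gi in unique(cat_$orbits$graphlet_id)) {
    vals <- tot[cat_$orbits$graphlet_id == gi]
    expect_true(max(vals) - min(vals) < 1e-9)
  }
})

test_that("proportions normalise to one and zero rows stay zero", {
  cat_ <- shared_catalog()
  sig <- count_orbits(random_gnp(9, 0.3, 12), cat_)
  tot <- rowSums(sig$counts)
  expect_equal(unname(rowSums(sig$proportions)[tot > 0]),
               rep(1, sum(tot > 0)))
  expect_true(all(sig$proportions[tot == 0, ] == 0))
})

test_that("centralities reproduce closed forms on paths and triangles", {
  p3 <- centralities(igraph::make_graph(~ a - b, b - c))
  b <- p3[p3$node_id == "b", ]
  expect_equal(b$closeness, 1 / 2)
  expect_equal(b$harmonic, 2)
  expect_equal(b$betweenness, 1)
  a <- p3[p3$node_id == "a", ]
  expect_equal(a$closeness, 1 / 3)
  expect_equal(a$harmonic, 1.5)
  expect_equal(a$betweenness, 0)
  tri <- centralities(igraph::make_ring(3))
  expect_equal(tri$betweenness, rep(0, 3))
  expect_equal(tri$harmonic, rep(2, 3))
})

test_that("centralities match the brute-force path-enumeration oracle", {
  for (seed in 1:6) {
    n <- sample(5:8, 1)
    g <- random_gnp(n, runif(1, 0.3, 0.6), seed + 40)
    got <- centralities(g)
    want <- oracle_centralities(g)
    ord <- as.integer(got$node_id)
    expect_equal(got$degree, want$degree[ord], ignore_attr = TRUE)
    expect_equal(got$closeness, want$closeness[ord], tolerance = 1e-12)
    expect_equal(got$harmonic, want$harmonic[ord], tolerance = 1e-12)
    expect_equal(got$betweenness, want$betweenness[ord], tolerance = 1e-9)
  }
})

test_that("normalized centralities use the component size", {
  # two components: an edge pair and a 4-star
  g <- igraph::graph_from_edgelist(
    rbind(c("a", "b"), c("c", "d"), c("c", "e"), c("c", "f")),
    directed = FALSE)
  ce <- centralities(g)
  ab <- ce[ce$node_id == "a", ]
  expect_equal(ab$component_size, 2L)
  expect_equal(ab$degree_norm, 1)
  expect_equal(ab$betweenness_norm, 0)
  cc <- ce[ce$node_id == "c", ]
  expect_equal(cc$component_size, 4L)
  expect_equal(cc$degree_norm, 1)
  expect_equal(cc$closeness_norm, 1)
  expect_equal(cc$betweenness_norm, 1)
})

test_that("orbit clustering groups identical profiles and is deterministic", {
  # two orbits with identical profiles must always co-cluster
  set.seed(6)
  prop <- matrix(runif(40 * 73), 40, 73,
                 dimnames = list(NULL, paste0("o", 0:72)))
  prop[, "o10"] <- prop[, "o20"]
  cl <- cluster_orbits(prop, cutoff = 0.3)
  expect_equal(unname(cl$cluster["o10"]), unname(cl$cluster["o20"]))
  cl2 <- cluster_orbits(prop, cutoff = 0.3)
  expect_identical(cl$cluster, cl2$cluster)
  # mutually non-positively correlated profiles become singletons
  prop2 <- matrix(0, 21, 73, dimnames = list(NULL, paste0("o", 0:72)))
  prop2[, "o2"] <- rep(c(2, 0, 0), 7)
  prop2[, "o3"] <- rep(c(0, 2, 0), 7)
  prop2[, "o4"] <- rep(c(0, 0, 2), 7)
  cl3 <- cluster_orbits(prop2, cutoff = 0.3,
                        exclude = setdiff(0:72, c(2, 3, 4)))
  expect_equal(cl3$k, 3)
  expect_length(cl3$degenerate, 0)
  # an orbit with no variation across nodes is reported as degenerate
  cl4 <- cluster_orbits(prop2, cutoff = 0.3,
                        exclude = setdiff(0:72, c(2, 3, 4, 5)))
  expect_equal(cl4$degenerate, "o5")
})

test_that("cluster scores equal an explicit two-pass z-score oracle", {
  set.seed(7)
  prop <- matrix(runif(30 * 73), 30, 73,
                 dimnames = list(as.character(1:30), paste0("o", 0:72)))
  sig <- list(proportions = prop)
  cl <- cluster_orbits(prop, cutoff = 0.3)
  cs <- cluster_scores(sig, cl)
  for (k in sort(unique(cl$cluster))[1:3]) {
    orbs <- names(cl$cluster)[cl$cluster == k]
    z <- sapply(orbs, function(o) {
      x <- prop[, o]
      (x - mean(x)) / sqrt(mean((x - mean(x))^2))
    })
    if (is.null(dim(z))) z <- matrix(z, ncol = 1)
    expect_equal(unname(cs[, paste0("CS", k)]), unname(apply(z, 1, max)),
                 tolerance = 1e-12)
  }
  zerovar <- matrix(0.5, 10, 73, dimnames = list(NULL, paste0("o", 0:72)))
  zerovar[, "o2"] <- runif(10)
  clz <- cluster_orbits(rbind(zerovar, zerovar + 0.001), cutoff = 0.3)
  # zero-sigma orbits contribute zero z-scores (no NaN anywhere)
  csz <- cluster_scores(list(proportions = zerovar), clz)
  expect_true(all(is.finite(csz)))
})

test_that("broad domains score higher on the central cluster than promoters", {
  pl <- shared_pipeline()
  sig <- count_orbits(pl$net)
  cl <- cluster_orbits(sig, k = 7)
  cs <- cluster_scores(sig, cl)
  cc <- paste0("CS", central_cluster(cl))
  ann <- pl$net$nodes$annotation
  expect_gt(mean(cs[ann == "broad_domain", cc]),
            mean(cs[ann == "promoter", cc]))
  expect_gt(mean(cs[ann == "super_enhancer", cc]),
            mean(cs[ann == "enhancer", cc]))
})
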