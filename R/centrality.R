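# Node centrality within connected components.
#
# All distances are unweighted shortest-path edge counts restricted to
# the node's connected component. Closeness is the reciprocal of the sum
# of distances to the component's other nodes; harmonic centrality the
# sum of reciprocal distances; betweenness the usual shortest-path-count
# ratio summed over unordered pairs excluding the node. Normalised
# variants are taken with respect to the component size |Nc|: degree and
# harmonic divided by |Nc|-1, closeness multiplied by |Nc|-1, betweenness
# divided by (|Nc|-1)(|Nc|-2)/2 (0 whenever a denominator vanishes).

#' Centrality measures for every network node
#'
#' @param net a `chromnet` network (or igraph graph).
#' @return data frame with node_id, component size, degree, closeness,
#'   harmonic, betweenness and their normalised variants.
#' @export
centralities <- function(net) {
  g <- as_igraph_any(net)
  n <- igraph::vcount(g)
  comp <- igraph::components(g)
  csize <- comp$csize[comp$membership]
  deg <- igraph::degree(g)
  clo <- suppressWarnings(igraph::closeness(g))   # 1 / sum of distances
  clo[csize == 1] <- 0
  har <- igraph::harmonic_centrality(g, normalized = FALSE)
  btw <- igraph::betweenness(g, directed = FALSE)
  s1 <- csize - 1
  s2 <- pmax(0, (csize - 1) * (csize - 2) / 2)
  data.frame(
    node_id = igraph::V(g)$name,
    component_size = as.integer(csize),
    degree = as.integer(deg),
    closeness = as.numeric(clo),
    harmonic = as.numeric(har),
    betweenness = as.numeric(btw),
    degree_norm = ifelse(s1 > 0, deg / s1, 0),
    closeness_norm = as.numeric(clo) * s1,
    harmonic_norm = ifelse(s1 > 0, har / s1, 0),
    betweenness_norm = ifelse(s2 > 0, btw / s2, 0),
    stringsAsFactors = FALSE)
}

#' One-sided Wilcoxon rank-sum comparison of two groups
#'
#' Rank-sum test with normal approximation and tie correction, as used
#' for comparing connectivity of annotation classes (e.g. broad domains
#' vs regular promoters).
#'
#' The exact null distribution is used for small untied samples;
#' otherwise the normal approximation with tie correction.
#'
#' @param a,b numeric vectors (non-empty).
#' @param alternative "greater" tests a shifted above b.
#' @return list with `p_value`, `statistic`, `n_a`, `n_b`.
#' @export
compare_groups <- function(a, b, alternative = c("greater", "less",
                                                 "two.sided")) {
  alternative <- match.arg(alternative)
  if (!length(a) || !length(b)) stop("compare_groups: empty group")
  wt <- suppressWarnings(wilcox.test(a, b, alternative = alternative,
                                     correct = TRUE))
  list(p_value = wt$p.value, statistic = unname(wt$statistic),
       n_a = length(a), n_b = length(b))
}
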