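# Chromatin interaction network construction.
#
# Nodes are open-chromatin peaks; edges are interaction calls whose two
# anchors (optionally extended) each overlap a peak. Inter-chromosomal
# calls and calls spanning more than `max_distance` between node midpoints
# are removed; duplicate peak-pair calls are merged with PET counts
# summed. The result is a simple undirected graph.

#' Build a chromatin interaction network
#'
#' @param calls interaction call data frame ([read_bedpe()]).
#' @param peaks open-chromatin peak intervals ([read_bed()]); define the
#'   candidate nodes.
#' @param extension bp added to both sides of each anchor before the peak
#'   overlap test (250 for ChIA-PET, 0 for HiChIP, 1250 for Hi-C calls).
#' @param max_distance maximum node-midpoint distance for an edge
#'   (default 1 Mb).
#' @return object of class `chromnet`: list with `nodes` (node_id, chrom,
#'   start, end, state, annotation, component), `edges` (u, v, pet),
#'   `se_domains` (filled by [assign_super_enhancers()]) and `log`
#'   (dropped-call bookkeeping).
#' @export
build_network <- function(calls, peaks, extension = 250L,
                          max_distance = 1e6) {
  if (is.null(peaks) || nrow(peaks) == 0) stop("build_network: empty peak list")
  validate_intervals(peaks, "peaks")
  log <- list(n_calls = nrow(calls), unanchored = 0L, interchrom = 0L,
              self_loop = 0L, too_far = 0L)
  if (nrow(calls) == 0) {
    return(new_chromnet(data.frame(u = integer(0), v = integer(0),
                                   pet = integer(0)), peaks, log))
  }
  a1 <- data.frame(chrom = calls$chrom1, start = calls$start1,
                   end = calls$end1, stringsAsFactors = FALSE)
  a2 <- data.frame(chrom = calls$chrom2, start = calls$start2,
                   end = calls$end2, stringsAsFactors = FALSE)
  p1 <- best_peak(a1, peaks, extension)
  p2 <- best_peak(a2, peaks, extension)
  interchrom <- calls$chrom1 != calls$chrom2
  log$interchrom <- sum(interchrom)
  keep <- !interchrom & !is.na(p1) & !is.na(p2)
  log$unanchored <- sum(!interchrom & (is.na(p1) | is.na(p2)))
  self <- keep & p1 == p2
  log$self_loop <- sum(self)
  keep <- keep & !self
  pk1 <- peaks[p1[keep], , drop = FALSE]
  pk2 <- peaks[p2[keep], , drop = FALSE]
  gd <- genomic_distance(pk1, pk2)
  far <- gd > max_distance
  log$too_far <- sum(far)
  u <- pmin(p1[keep], p2[keep])[!far]
  v <- pmax(p1[keep], p2[keep])[!far]
  pet <- calls$pet[keep][!far]
  if (length(u)) {
    key <- paste(u, v)
    agg <- rowsum(as.numeric(pet), key)
    uv <- do.call(rbind, strsplit(rownames(agg), " "))
    edges <- data.frame(u = as.integer(uv[, 1]), v = as.integer(uv[, 2]),
                        pet = as.integer(agg[, 1]))
    edges <- edges[order(edges$u, edges$v), ]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(u = integer(0), v = integer(0), pet = integer(0))
  }
  new_chromnet(edges, peaks, log)
}

# map each anchor to the index (into peaks) of the overlapping peak with
# the largest extended-anchor overlap; ties -> leftmost peak. NA if none.
best_peak <- function(anchors, peaks, extension) {
  hits <- overlap_join(anchors, peaks, extension)
  out <- rep(NA_integer_, nrow(anchors))
  if (!nrow(hits)) return(out)
  bp_ext <- pmin(anchors$end[hits$query] + extension,
                 peaks$end[hits$subject]) -
    pmax(anchors$start[hits$query] - extension, peaks$start[hits$subject])
  ord <- order(hits$query, -bp_ext, peaks$start[hits$subject], hits$subject)
  hits <- hits[ord, ]
  first <- !duplicated(hits$query)
  out[hits$query[first]] <- hits$subject[first]
  out
}

new_chromnet <- function(edges, peaks, log) {
  used <- sort(unique(c(edges$u, edges$v)))
  nodes <- peaks[used, c("chrom", "start", "end"), drop = FALSE]
  rownames(nodes) <- NULL
  nodes <- cbind(node_id = seq_along(used), nodes)
  nodes$peak <- used   # row index into the input peak list
  remap <- setNames(seq_along(used), used)
  edges$u <- as.integer(remap[as.character(edges$u)])
  edges$v <- as.integer(remap[as.character(edges$v)])
  nodes$state <- rep(NA_character_, nrow(nodes))
  nodes$annotation <- rep(NA_character_, nrow(nodes))
  net <- structure(list(nodes = nodes, edges = edges,
                        se_domains = NULL, log = log),
                   class = "chromnet")
  net$nodes$component <- connected_components(net)
  net
}

#' Convert a network to an igraph graph
#'
#' Vertex names are node ids; edge attribute `pet` carries the PET count.
#'
#' @param net a `chromnet` network.
#' @return an igraph undirected graph.
#' @export
as_igraph <- function(net) {
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(net$edges$u),
               to = as.character(net$edges$v)),
    directed = FALSE,
    vertices = data.frame(name = as.character(net$nodes$node_id)))
  igraph::E(g)$pet <- net$edges$pet
  g
}

#' Connected components of a network
#'
#' @param net a `chromnet` network.
#' @return integer vector, one component id per node (in node order);
#'   components are maximal connected sets.
#' @export
connected_components <- function(net) {
  if (nrow(net$nodes) == 0) return(integer(0))
  g <- as_igraph(net)
  comp <- igraph::components(g)$membership
  as.integer(comp[as.character(net$nodes$node_id)])
}

#' Network summary counts
#'
#' @param net a `chromnet` network.
#' @return list with `n_nodes`, `n_edges`, `n_components` and
#'   `annotation_counts` (named table over node annotations).
#' @export
network_summary <- function(net) {
  list(n_nodes = nrow(net$nodes),
       n_edges = nrow(net$edges),
       n_components = length(unique(net$nodes$component)),
       annotation_counts = table(net$nodes$annotation, useNA = "ifany"))
}

#' Serialize a network
#'
#' Writes `<prefix>.nodes.tsv` and `<prefix>.edges.tsv` (tab-separated
#' with header), and `<prefix>.json` (the whole object) when jsonlite is
#' available.
#'
#' @param net a `chromnet` network.
#' @param prefix output path prefix.
#' @export
write_network <- function(net, prefix) {
  write.table(net$nodes, paste0(prefix, ".nodes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(net$edges, paste0(prefix, ".edges.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(list(nodes = net$nodes, edges = net$edges,
                              se_domains = net$se_domains),
                         paste0(prefix, ".json"), dataframe = "rows")
  }
  invisible(prefix)
}

#' @export
print.chromnet <- function(x, ...) {
  s <- network_summary(x)
  cat(sprintf("chromatin interaction network: %d nodes, %d edges, %d components\n",
              s$n_nodes, s$n_edges, s$n_components))
  if (!all(is.na(x$nodes$annotation))) {
    tab <- table(x$nodes$annotation)
    cat("annotations:", paste(names(tab), tab, sep = "=", collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' @export
summary.chromnet <- function(object, ...) {
  s <- network_summary(object)
  comp_sizes <- table(object$nodes$component)
  s$component_size_summary <- summary(as.integer(comp_sizes))
  s$pet_summary <- if (nrow(object$edges)) summary(object$edges$pet) else NULL
  class(s) <- "summary.chromnet"
  s
}

#' @export
print.summary.chromnet <- function(x, ...) {
  cat(sprintf("nodes: %d  edges: %d  components: %d\n",
              x$n_nodes, x$n_edges, x$n_components))
  cat("component sizes:\n"); print(x$component_size_summary)
  if (!is.null(x$pet_summary)) { cat("edge PET counts:\n"); print(x$pet_summary) }
  invisible(x)
}

#' @export
plot.chromnet <- function(x, component = NULL, ...) {
  g <- as_igraph(x)
  if (!is.null(component)) {
    keep <- x$nodes$node_id[x$nodes$component %in% component]
    g <- igraph::induced_subgraph(g, as.character(keep))
  }
  ann <- x$nodes$annotation[match(igraph::V(g)$name, x$nodes$node_id)]
  pal <- c(broad_domain = "firebrick", promoter = "salmon",
           super_enhancer = "darkgreen", enhancer = "gold",
           insulator = "steelblue", other = "grey70")
  col <- pal[ann]; col[is.na(col)] <- "grey50"
  igraph::plot.igraph(g, vertex.color = col, vertex.label = NA,
                      vertex.size = 4, ...)
  invisible(x)
}
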