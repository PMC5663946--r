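# Expression specificity (SPM) and enhancer target assignment.

#' Cell-type specificity (SPM) of gene expression
#'
#' SPM of gene g for cell type c is the cosine similarity between the
#' gene's cross-tissue expression vector and the indicator profile of
#' that cell type: `x_c / ||x||_2`, in [0, 1]. A gene expressed in a
#' single type scores 1; uniform expression over N types scores
#' `1/sqrt(N)`. All-zero genes are undefined and dropped.
#'
#' @param expr expression matrix ([read_expression()]): genes x cell
#'   types, non-negative.
#' @param cell_type column name of the query type.
#' @return named numeric vector of SPM scores (all-zero genes omitted).
#' @export
spm <- function(expr, cell_type) {
  if (!cell_type %in% colnames(expr)) {
    stop(sprintf("spm: unknown cell type '%s'", cell_type))
  }
  nrm <- sqrt(rowSums(expr^2))
  keep <- nrm > 0
  setNames(expr[keep, cell_type] / nrm[keep], rownames(expr)[keep])
}

#' Assign promoter targets to enhancer nodes by bounded BFS
#'
#' From every enhancer and super-enhancer node, a breadth-first search of
#' at most `max_depth` edges; at the first depth where at least one
#' promoter or broad-domain node is reached, all such nodes at that depth
#' become targets and the search stops (so ties at the minimal depth are
#' all kept and the result is independent of neighbor order). The search
#' never expands beyond a promoter node.
#'
#' @param net an annotated `chromnet` network.
#' @param max_depth maximum search depth in edges (default 4).
#' @return data frame (enhancer_id, target_id, depth); enhancers with no
#'   reachable promoter within `max_depth` are absent.
#' @export
assign_targets <- function(net, max_depth = 4L) {
  g <- as_igraph(net)
  adj <- igraph::as_adj_list(g, mode = "all")
  ids <- as.integer(igraph::V(g)$name)
  ann <- net$nodes$annotation[match(ids, net$nodes$node_id)]
  is_target <- ann %in% c("promoter", "broad_domain")
  sources <- which(ann %in% c("enhancer", "super_enhancer"))
  out <- list()
  for (s in sources) {
    seen <- logical(length(ids)); seen[s] <- TRUE
    frontier <- s
    for (d in seq_len(max_depth)) {
      nxt <- unique(unlist(lapply(frontier, function(v) as.integer(adj[[v]]))))
      nxt <- nxt[!seen[nxt]]
      if (!length(nxt)) break
      seen[nxt] <- TRUE
      hit <- nxt[is_target[nxt]]
      if (length(hit)) {
        out[[length(out) + 1]] <- data.frame(
          enhancer_id = ids[s], target_id = sort(ids[hit]), depth = d)
        break
      }
      frontier <- nxt
    }
  }
  if (!length(out)) {
    return(data.frame(enhancer_id = integer(0), target_id = integer(0),
                      depth = integer(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Map nodes to genes by TSS overlap
#'
#' A promoter-side node is associated with every gene whose TSS falls
#' within `window` bp of the node boundary (0 = inside only).
#'
#' @param net a `chromnet` network.
#' @param tss TSS records ([read_tss()]).
#' @param window bp around the node within which a TSS associates its
#'   gene (default 2000).
#' @return data frame (node_id, gene_id).
#' @export
node_genes <- function(net, tss, window = 2000) {
  hits <- overlap_join(net$nodes, tss, extension = window)
  if (!nrow(hits)) {
    return(data.frame(node_id = integer(0), gene_id = character(0)))
  }
  data.frame(node_id = net$nodes$node_id[hits$query],
             gene_id = tss$gene_id[hits$subject],
             stringsAsFactors = FALSE)
}

#' Per-node SPM scores
#'
#' Averages the SPM of all genes associated with a node. For promoter
#' nodes the association is direct (TSS overlap, [node_genes()]); for
#' enhancer nodes genes are inherited from their assigned promoter
#' targets. Nodes with no associated gene are excluded.
#'
#' @param gene_map data frame (node_id, gene_id).
#' @param expr expression matrix.
#' @param cell_type query cell type.
#' @param assignment optional target assignment ([assign_targets()]):
#'   when given, enhancer nodes inherit the genes of their targets.
#' @return named numeric vector node_id -> mean SPM.
#' @export
node_spm <- function(gene_map, expr, cell_type, assignment = NULL) {
  s <- spm(expr, cell_type)
  gm <- gene_map
  if (!is.null(assignment) && nrow(assignment)) {
    inherited <- merge(assignment[, c("enhancer_id", "target_id")],
                       gene_map, by.x = "target_id", by.y = "node_id")
    if (nrow(inherited)) {
      gm <- rbind(gm, data.frame(node_id = inherited$enhancer_id,
                                 gene_id = inherited$gene_id))
    }
  }
  gm <- unique(gm)
  gm$spm <- s[gm$gene_id]
  gm <- gm[!is.na(gm$spm), , drop = FALSE]
  if (!nrow(gm)) return(setNames(numeric(0), character(0)))
  agg <- tapply(gm$spm, gm$node_id, mean)
  setNames(as.numeric(agg), names(agg))
}
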