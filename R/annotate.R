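# Node annotation.
#
# Each node first receives one base regulatory state from a ChromHMM-style
# segmentation via a priority schema; broad-domain and super-enhancer
# region calls then overlay the promoter and enhancer states respectively.

state_priority <- c(promoter = 1, enhancer = 1, insulator = 2,
                    poised_promoter = 3, repressed = 4, transcribed = 5,
                    low_signal = 6)

#' Assign base regulatory states to network nodes
#'
#' Among the segmentation states overlapping a node, the highest-priority
#' state wins: (1) enhancer/promoter, (2) insulator, (3) poised promoter,
#' (4) repressed, (5) transcribed, (6) low signal. When both promoter and
#' enhancer overlap, the node is a promoter iff it lies within
#' `tss_window` bp of a TSS (distance from the node boundary, 0 inside),
#' otherwise an enhancer. Nodes overlapping no segment are labeled
#' `other`.
#'
#' @param net a `chromnet` network.
#' @param segments state segments ([read_states()]).
#' @param tss TSS records ([read_tss()]); used only for the
#'   promoter/enhancer disambiguation.
#' @param tss_window promoter TSS distance window in bp (default 2000).
#' @return the network with `state` and `annotation` node columns filled.
#' @export
assign_state <- function(net, segments, tss, tss_window = 2000) {
  hits <- overlap_join(net$nodes, segments, extension = 0L)
  n <- nrow(net$nodes)
  state <- rep("other", n)
  if (nrow(hits)) {
    st <- split(segments$state[hits$subject], hits$query)
    near_tss <- tss_within(net$nodes, tss, tss_window)
    for (nm in names(st)) {
      i <- as.integer(nm)
      s <- unique(st[[nm]])
      has_p <- "promoter" %in% s
      has_e <- "enhancer" %in% s
      state[i] <- if (has_p && has_e) {
        if (near_tss[i]) "promoter" else "enhancer"
      } else if (has_p || has_e) {
        if (has_p) "promoter" else "enhancer"
      } else {
        s[which.min(state_priority[s])]
      }
    }
  }
  net$nodes$state <- state
  net$nodes$annotation <- state
  net
}

# TRUE per node when the nearest TSS is within `window` bp of the node
# boundary (0 if the TSS falls inside the node).
tss_within <- function(nodes, tss, window) {
  out <- rep(FALSE, nrow(nodes))
  if (is.null(tss) || nrow(tss) == 0) return(out)
  for (ch in unique(nodes$chrom)) {
    ni <- which(nodes$chrom == ch)
    tp <- sort(tss$start[tss$chrom == ch])
    if (!length(tp) || !length(ni)) next
    for (i in ni) {
      d <- tss_node_distance(tp, nodes$start[i], nodes$end[i])
      out[i] <- d <= window
    }
  }
  out
}

tss_node_distance <- function(pos, start, end) {
  inside <- any(pos >= start & pos < end)
  if (inside) return(0)
  min(c(start - pos[pos < start], pos[pos >= end] - end + 1, Inf))
}

#' Overlay broad-domain labels on promoter nodes
#'
#' For each broad domain region, the promoter-state node with the largest
#' base-pair overlap is relabeled `broad_domain`; ties relabel every tied
#' node. Non-promoter nodes are ignored; domains overlapping no promoter
#' node leave the network unchanged (counted in the log).
#'
#' @param net an annotated `chromnet` network.
#' @param domains broad-domain region intervals ([read_bed()]).
#' @return the network with updated annotations.
#' @export
assign_broad_domains <- function(net, domains) {
  elig <- which(net$nodes$state == "promoter")
  net$log$bd_unmatched <- 0L
  if (!length(elig) || is.null(domains) || nrow(domains) == 0) {
    net$log$bd_unmatched <- if (is.null(domains)) 0L else nrow(domains)
    return(net)
  }
  hits <- overlap_join(domains, net$nodes[elig, , drop = FALSE],
                       extension = 0L)
  hits <- hits[hits$bp > 0, , drop = FALSE]
  matched <- unique(hits$query)
  net$log$bd_unmatched <- nrow(domains) - length(matched)
  for (d in matched) {
    h <- hits[hits$query == d, , drop = FALSE]
    best <- h$subject[h$bp == max(h$bp)]       # ties: all
    net$nodes$annotation[elig[best]] <- "broad_domain"
  }
  net
}

#' Overlay super-enhancer labels on enhancer nodes
#'
#' Every enhancer-state node overlapping a super-enhancer region is
#' relabeled `super_enhancer`; a node overlapping several regions joins
#' the region of largest overlap. Domain membership is recorded in
#' `net$se_domains` (node_id, domain_id), with one domain per input
#' region that acquired members.
#'
#' @param net an annotated `chromnet` network.
#' @param se_regions super-enhancer region intervals ([read_bed()]).
#' @return the network with updated annotations and `se_domains` filled.
#' @export
assign_super_enhancers <- function(net, se_regions) {
  net$se_domains <- data.frame(node_id = integer(0), domain_id = integer(0))
  elig <- which(net$nodes$state == "enhancer")
  if (!length(elig) || is.null(se_regions) || nrow(se_regions) == 0) {
    return(net)
  }
  hits <- overlap_join(net$nodes[elig, , drop = FALSE], se_regions,
                       extension = 0L)
  hits <- hits[hits$bp > 0, , drop = FALSE]
  if (!nrow(hits)) return(net)
  ord <- order(hits$query, -hits$bp, hits$subject)
  hits <- hits[ord, ]
  hits <- hits[!duplicated(hits$query), , drop = FALSE]
  node_ids <- net$nodes$node_id[elig[hits$query]]
  net$nodes$annotation[elig[hits$query]] <- "super_enhancer"
  net$se_domains <- data.frame(node_id = node_ids,
                               domain_id = hits$subject)
  net$se_regions <- se_regions
  net
}

#' Annotate a network in one step
#'
#' Convenience wrapper: [assign_state()], then [assign_broad_domains()],
#' then [assign_super_enhancers()].
#'
#' @param net a `chromnet` network.
#' @param states,tss,broad_domains,super_enhancers inputs for the three
#'   stages; `broad_domains`/`super_enhancers` may be NULL.
#' @param tss_window promoter TSS window in bp.
#' @return the annotated network.
#' @export
annotate_network <- function(net, states, tss, broad_domains = NULL,
                             super_enhancers = NULL, tss_window = 2000) {
  net <- assign_state(net, states, tss, tss_window)
  if (!is.null(broad_domains)) net <- assign_broad_domains(net, broad_domains)
  if (!is.null(super_enhancers)) {
    net <- assign_super_enhancers(net, super_enhancers)
  }
  net
}

#' Merge super-enhancer nodes by domain
#'
#' Collapses the member nodes of each super-enhancer domain into a single
#' node spanning their union; edges are re-attached to the merged node,
#' within-domain edges are removed, parallel edges merged with PET counts
#' summed, and components recomputed. Idempotent.
#'
#' @param net a network with `se_domains` assigned.
#' @return a new `chromnet` with merged super-enhancer nodes.
#' @export
merge_super_enhancer_nodes <- function(net) {
  dom <- net$se_domains
  if (is.null(dom) || nrow(dom) == 0) return(net)
  nodes <- net$nodes
  group <- setNames(-dom$domain_id, dom$node_id)   # negative = domain key
  key_of <- function(ids) {
    g <- group[as.character(ids)]
    ifelse(is.na(g), ids, g)
  }
  ku <- key_of(nodes$node_id)
  # merged node intervals: union span per domain, original otherwise
  merged_nodes <- do.call(rbind, lapply(split(seq_len(nrow(nodes)), ku),
    function(ix) {
      data.frame(chrom = nodes$chrom[ix[1]],
                 start = min(nodes$start[ix]), end = max(nodes$end[ix]),
                 state = nodes$state[ix[1]],
                 annotation = if (length(ix) > 1 ||
                                  nodes$annotation[ix] == "super_enhancer")
                   "super_enhancer" else nodes$annotation[ix],
                 stringsAsFactors = FALSE)
    }))
  keys <- as.numeric(rownames(merged_nodes))
  merged_nodes$node_id <- seq_len(nrow(merged_nodes))
  remap <- setNames(merged_nodes$node_id, keys)
  eu <- as.integer(remap[as.character(key_of(net$edges$u))])
  ev <- as.integer(remap[as.character(key_of(net$edges$v))])
  keep <- eu != ev
  u <- pmin(eu, ev)[keep]; v <- pmax(eu, ev)[keep]
  pet <- net$edges$pet[keep]
  if (length(u)) {
    agg <- rowsum(as.numeric(pet), paste(u, v))
    uv <- do.call(rbind, strsplit(rownames(agg), " "))
    edges <- data.frame(u = as.integer(uv[, 1]), v = as.integer(uv[, 2]),
                        pet = as.integer(agg[, 1]))
    edges <- edges[order(edges$u, edges$v), ]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(u = integer(0), v = integer(0), pet = integer(0))
  }
  used <- sort(unique(c(edges$u, edges$v)))
  nodes_out <- merged_nodes[match(used, merged_nodes$node_id),
                            c("node_id", "chrom", "start", "end", "state",
                              "annotation")]
  rownames(nodes_out) <- NULL
  new_ids <- setNames(seq_along(used), used)
  nodes_out$node_id <- seq_along(used)
  edges$u <- as.integer(new_ids[as.character(edges$u)])
  edges$v <- as.integer(new_ids[as.character(edges$v)])
  out <- structure(list(nodes = nodes_out, edges = edges,
                        se_domains = NULL, log = net$log),
                   class = "chromnet")
  out$nodes$component <- connected_components(out)
  out
}
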