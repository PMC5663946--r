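# SVM classification of cell-specific regulatory elements.
#
# Two tasks share the machinery: broad domains vs regular promoters and
# super enhancers vs regular enhancers. Sixteen network features (four
# centrality measures raw + normalised, component size, seven orbit
# cluster scores) and seven genomic features (node length, length ratio
# to neighbors, mean edge PET, distance and strand of the closest
# upstream and downstream TSS) feed an RBF-kernel SVM tuned by grid
# search on the Matthews correlation coefficient with stratified
# cross-validation.

#' Matthews correlation coefficient
#'
#' @param truth,pred logical (or 0/1) vectors.
#' @return MCC in [-1, 1]; 0 when a marginal is degenerate.
#' @export
mcc <- function(truth, pred) {
  truth <- as.logical(truth); pred <- as.logical(pred)
  tp <- sum(truth & pred); tn <- sum(!truth & !pred)
  fp <- sum(!truth & pred); fn <- sum(truth & !pred)
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / den
}

#' Area under the ROC curve (concordance statistic)
#'
#' Rank-based AUC: the probability that a random positive scores above a
#' random negative, with ties counted 1/2.
#'
#' @param truth logical vector.
#' @param score numeric predictions.
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(truth, score) {
  truth <- as.logical(truth)
  n1 <- sum(truth); n0 <- sum(!truth)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score)
  (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

roc_curve <- function(truth, score) {
  ord <- order(score, decreasing = TRUE)
  truth <- as.logical(truth)[ord]
  tpr <- c(0, cumsum(truth) / max(1, sum(truth)))
  fpr <- c(0, cumsum(!truth) / max(1, sum(!truth)))
  data.frame(fpr = fpr, tpr = tpr)
}

pr_curve <- function(truth, score) {
  ord <- order(score, decreasing = TRUE)
  truth <- as.logical(truth)[ord]
  tp <- cumsum(truth)
  data.frame(recall = tp / max(1, sum(truth)),
             precision = tp / seq_along(truth))
}

#' Extract the classification feature table
#'
#' Builds the 16 network + 7 genomic features for the nodes of the two
#' classes of a task. TSS distances are measured from the node midpoint
#' to the nearest TSS on each side, capped at `tss_cap` when a side has
#' no gene (strand then encoded 0; otherwise +1/-1).
#'
#' @param net an annotated `chromnet` network.
#' @param cent centralities ([centralities()]).
#' @param scores orbit cluster score matrix ([cluster_scores()]); its
#'   columns become the cluster-score features.
#' @param tss TSS records.
#' @param positive,negative annotation labels of the two classes (e.g.
#'   `"broad_domain"` vs `"promoter"`).
#' @param tss_cap distance cap in bp for missing TSS (default 1 Mb).
#' @return data frame with `node_id`, `label` (logical, positive class)
#'   and the feature columns.
#' @export
extract_features <- function(net, cent, scores, tss,
                             positive = "super_enhancer",
                             negative = "enhancer", tss_cap = 1e6) {
  sel <- net$nodes$annotation %in% c(positive, negative)
  nodes <- net$nodes[sel, , drop = FALSE]
  if (!nrow(nodes)) stop("extract_features: no nodes in the two classes")
  ids <- as.character(nodes$node_id)
  ci <- match(ids, as.character(cent$node_id))
  if (anyNA(ci)) stop("extract_features: centralities missing for some nodes")
  si <- match(ids, rownames(scores))
  if (anyNA(si)) stop("extract_features: cluster scores missing for some nodes")
  len <- nodes$end - nodes$start
  # mean neighbor length and mean PET per node
  all_len <- setNames(net$nodes$end - net$nodes$start, net$nodes$node_id)
  nb_len <- numeric(nrow(nodes)); mean_pet <- numeric(nrow(nodes))
  inc_u <- split(seq_len(nrow(net$edges)), net$edges$u)
  inc_v <- split(seq_len(nrow(net$edges)), net$edges$v)
  for (i in seq_len(nrow(nodes))) {
    id <- nodes$node_id[i]
    ei <- c(inc_u[[as.character(id)]], inc_v[[as.character(id)]])
    partners <- c(net$edges$v[ei], net$edges$u[ei])
    partners <- partners[partners != id]
    nb_len[i] <- mean(all_len[as.character(partners)])
    mean_pet[i] <- mean(net$edges$pet[ei])
  }
  ts <- tss_flanks(nodes, tss, tss_cap)
  feat <- data.frame(
    node_id = nodes$node_id,
    label = nodes$annotation == positive,
    degree = cent$degree[ci],
    closeness = cent$closeness[ci],
    harmonic = cent$harmonic[ci],
    betweenness = cent$betweenness[ci],
    degree_norm = cent$degree_norm[ci],
    closeness_norm = cent$closeness_norm[ci],
    harmonic_norm = cent$harmonic_norm[ci],
    betweenness_norm = cent$betweenness_norm[ci],
    component_size = cent$component_size[ci],
    node_length = len,
    length_ratio = len / nb_len,
    mean_pet = mean_pet,
    tss_dist_up = ts$dist_up, tss_dist_down = ts$dist_down,
    tss_strand_up = ts$strand_up, tss_strand_down = ts$strand_down)
  feat <- cbind(feat, as.data.frame(scores[si, , drop = FALSE],
                                    row.names = NULL))
  feat
}

# nearest TSS upstream (position < midpoint) and downstream per node
tss_flanks <- function(nodes, tss, cap) {
  n <- nrow(nodes)
  out <- list(dist_up = rep(cap, n), dist_down = rep(cap, n),
              strand_up = rep(0, n), strand_down = rep(0, n))
  for (ch in unique(nodes$chrom)) {
    ni <- which(nodes$chrom == ch)
    ti <- which(tss$chrom == ch)
    if (!length(ti)) next
    tp <- tss$start[ti]; str <- ifelse(tss$strand[ti] == "+", 1, -1)
    ord <- order(tp); tp <- tp[ord]; str <- str[ord]
    mid <- (nodes$start[ni] + nodes$end[ni]) / 2
    pos <- findInterval(mid, tp)
    up <- pos >= 1
    out$dist_up[ni[up]] <- pmin(cap, mid[up] - tp[pos[up]])
    out$strand_up[ni[up]] <- str[pos[up]]
    dn <- pos < length(tp)
    out$dist_down[ni[dn]] <- pmin(cap, tp[pos[dn] + 1] - mid[dn])
    out$strand_down[ni[dn]] <- str[pos[dn] + 1]
  }
  out
}

feature_columns <- function(table) {
  setdiff(names(table), c("node_id", "label"))
}

stratified_folds <- function(label, folds, seed) {
  set.seed(seed)
  f <- integer(length(label))
  for (cls in unique(label)) {
    ix <- which(label == cls)
    f[ix] <- sample(rep_len(seq_len(folds), length(ix)))
  }
  f
}

# cross-validated out-of-fold positive-class probabilities for one
# (C, gamma); features standardised within training folds
cv_probs <- function(x, y, fold, C, gamma) {
  p <- numeric(length(y))
  for (k in sort(unique(fold))) {
    tr <- fold != k
    mu <- colMeans(x[tr, , drop = FALSE])
    sg <- apply(x[tr, , drop = FALSE], 2, sd)
    sg[sg == 0 | is.na(sg)] <- 1
    xs <- scale(x, center = mu, scale = sg)
    fit <- e1071::svm(xs[tr, , drop = FALSE], factor(y[tr]),
                      kernel = "radial", cost = C, gamma = gamma,
                      probability = TRUE, scale = FALSE)
    pr <- attr(stats::predict(fit, xs[!tr, , drop = FALSE],
                              probability = TRUE), "probabilities")
    p[!tr] <- pr[, "TRUE"]
  }
  p
}

#' Train and evaluate an RBF SVM with grid search
#'
#' Stratified `folds`-fold cross-validation; for every (C, gamma) on the
#' grid, out-of-fold class probabilities (Platt scaling fitted within
#' the training folds) are pooled and the hyper-parameters maximising
#' MCC at probability 0.5 are kept. The report carries the pooled
#' out-of-fold ROC/PR curves, AUC, MCC and accuracy at
#' `prob_threshold`.
#'
#' @param table feature table ([extract_features()], or any data frame
#'   with `label` plus numeric features).
#' @param folds number of cross-validation folds (default 5).
#' @param cost_grid,gamma_grid hyper-parameter candidates; `gamma_grid`
#'   accepts the string `"scale"` for 1/(p * var).
#' @param seed RNG seed controlling fold assignment.
#' @param prob_threshold probability cutoff for the reported accuracy
#'   (default 0.2).
#' @param features optional character vector restricting the feature
#'   columns used.
#' @return object of class `svm_report`: probabilities, curves, AUC,
#'   MCC, accuracy, selected hyper-parameters.
#' @export
train_svm <- function(table, folds = 5L,
                      cost_grid = c(0.1, 1, 10, 100),
                      gamma_grid = c(1e-3, 1e-2, 1e-1, 1, "scale"),
                      seed = 1L, prob_threshold = 0.2, features = NULL) {
  y <- as.logical(table$label)
  if (length(unique(y)) < 2) stop("train_svm: single-class input")
  if (min(table(y)) < folds) {
    stop("train_svm: fewer examples in a class than folds")
  }
  cols <- if (is.null(features)) feature_columns(table) else features
  x <- as.matrix(table[, cols, drop = FALSE])
  storage.mode(x) <- "double"
  fold <- stratified_folds(y, folds, seed)
  gam_val <- function(g) {
    if (identical(g, "scale")) 1 / (ncol(x) * max(1e-12, mean(apply(x, 2, var))))
    else as.numeric(g)
  }
  best <- NULL
  for (C in cost_grid) for (g in gamma_grid) {
    set.seed(seed + 1)   # e1071 probability calibration uses RNG
    p <- cv_probs(x, y, fold, C, gam_val(g))
    m <- mcc(y, p >= 0.5)
    if (is.null(best) || m > best$mcc) {
      best <- list(C = C, gamma = gam_val(g), gamma_label = g,
                   mcc = m, probs = p)
    }
  }
  p <- best$probs
  structure(list(
    probabilities = data.frame(node_id = if (!is.null(table$node_id))
      table$node_id else seq_along(y), label = y, prob = p),
    roc = roc_curve(y, p), pr = pr_curve(y, p),
    auc = roc_auc(y, p), mcc = best$mcc,
    accuracy = mean((p >= prob_threshold) == y),
    prob_threshold = prob_threshold,
    C = best$C, gamma = best$gamma,
    folds = folds, seed = seed, features = cols),
    class = "svm_report")
}

#' @export
print.svm_report <- function(x, ...) {
  cat(sprintf(
    "SVM report: AUC %.3f, MCC %.3f, accuracy %.3f at p>=%.2f (C=%g, gamma=%.4g)\n",
    x$auc, x$mcc, x$accuracy, x$prob_threshold, x$C, x$gamma))
  invisible(x)
}

#' @export
plot.svm_report <- function(x, ...) {
  plot(x$roc$fpr, x$roc$tpr, type = "l", xlab = "false positive rate",
       ylab = "true positive rate",
       main = sprintf("ROC (AUC = %.3f)", x$auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Greedy forward feature selection by cross-validated MCC
#'
#' At each round every remaining feature is tentatively added and the
#' one maximising out-of-fold MCC is kept, until all features are
#' ranked.
#'
#' @param table feature table.
#' @param folds cross-validation folds.
#' @param seed RNG seed.
#' @param cost,gamma fixed SVM hyper-parameters used during selection.
#' @return data frame (rank, feature, mcc): the selection order with the
#'   MCC trajectory.
#' @export
forward_select <- function(table, folds = 5L, seed = 1L, cost = 1,
                           gamma = 0.1) {
  y <- as.logical(table$label)
  if (length(unique(y)) < 2) stop("forward_select: single-class input")
  cols <- feature_columns(table)
  x <- as.matrix(table[, cols, drop = FALSE])
  storage.mode(x) <- "double"
  fold <- stratified_folds(y, folds, seed)
  chosen <- character(0); traj <- numeric(0)
  while (length(chosen) < length(cols)) {
    rest <- setdiff(cols, chosen)
    sc <- vapply(rest, function(f) {
      set.seed(seed + 1)
      p <- cv_probs(x[, c(chosen, f), drop = FALSE], y, fold, cost, gamma)
      mcc(y, p >= 0.5)
    }, 0)
    pick <- rest[which.max(sc)]
    chosen <- c(chosen, pick)
    traj <- c(traj, max(sc))
  }
  data.frame(rank = seq_along(chosen), feature = chosen, mcc = traj,
             stringsAsFactors = FALSE)
}

#' Compare network-only, genomic-only and combined feature sets
#'
#' Trains three models on identical folds and reports their AUCs.
#'
#' @param table feature table from [extract_features()].
#' @param folds,seed,... passed to [train_svm()].
#' @return list of three `svm_report`s: `network`, `genomic`,
#'   `combined`.
#' @export
ablate_feature_groups <- function(table, folds = 5L, seed = 1L, ...) {
  cols <- feature_columns(table)
  genomic <- intersect(cols, c("node_length", "length_ratio", "mean_pet",
                               "tss_dist_up", "tss_dist_down",
                               "tss_strand_up", "tss_strand_down"))
  network <- setdiff(cols, genomic)
  list(network = train_svm(table, folds, seed = seed, features = network, ...),
       genomic = train_svm(table, folds, seed = seed, features = genomic, ...),
       combined = train_svm(table, folds, seed = seed, features = cols, ...))
}
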