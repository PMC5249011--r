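#' Normalized edge ranks of a learner network
#'
#' Edges are ranked by decreasing strength; rank position r among the
#' learner's E predicted edges maps to the normalized rank r/E in (0, 1]
#' (1 = worst). Tied strengths share the mean of their positions, so the
#' ranking is independent of input order.
#'
#' @param net a `learner_network` (or an [edge_table()] with strengths).
#' @return Named numeric vector of normalized ranks, names = canonical pair
#'   keys.
#' @export
rank_edges <- function(net) {
  edges <- if (inherits(net, "learner_network")) net$final_edges else net
  E <- nrow(edges)
  if (!E) return(stats::setNames(numeric(0), character(0)))
  rk <- rank(-edges$strength, ties.method = "average") / E
  stats::setNames(rk, pair_key(edges))
}

#' Consensus network by rank averaging across learners
#'
#' Every pair predicted by at least one learner receives, per learner, its
#' normalized rank (from [rank_edges()]); a learner that did not predict the
#' pair contributes the worst possible rank, 1. The consensus score is the
#' unweighted mean over all learners (lower = more significant). Pairs are
#' sorted ascending by score — ties broken by more supporting learners, then
#' lexicographically by pair — and only the `e_max` best are retained.
#' Orientation is a weighted vote over the orienting learners that predicted
#' the pair, each casting weight \eqn{1 - rank + 1/(2 E_l)} for its
#' direction, so top-ranked edges weigh most and even a rank-1 edge retains
#' positive weight; equal weights or no directed votes give an undirected
#' edge.
#'
#' @param networks list of `learner_network` objects (>= 1), distinct ids.
#' @param e_max number of consensus edges to retain (>= 1).
#' @return Object of class `"consensus_network"`: `edges` (retained, with
#'   per-learner ranks, score, orientation, support), `all_pairs` (the
#'   pre-truncation table), `e_max`, `learner_ids`.
#' @export
scs_consensus <- function(networks, e_max) {
  stopifnot(length(networks) >= 1L)
  e_max <- as.integer(e_max)
  if (e_max < 1L) stop("e_max must be at least 1")
  ids <- vapply(networks, `[[`, "", "learner_id")
  if (anyDuplicated(ids)) stop("duplicate learner ids in consensus input")
  ranks <- lapply(networks, rank_edges)
  all_keys <- sort(unique(unlist(lapply(ranks, names))))
  L <- length(networks)
  if (!length(all_keys)) {
    empty <- data.frame(source = character(0), target = character(0),
                        orientation = character(0),
                        consensus_score = numeric(0), support = character(0),
                        stringsAsFactors = FALSE)
    for (id in ids) empty[[paste0("rank_", id)]] <- numeric(0)
    return(structure(list(edges = empty, all_pairs = empty, e_max = e_max,
                          learner_ids = ids), class = "consensus_network"))
  }
  rk <- matrix(1, nrow = length(all_keys), ncol = L,
               dimnames = list(all_keys, ids))
  predicted <- matrix(FALSE, nrow = length(all_keys), ncol = L,
                      dimnames = list(all_keys, ids))
  for (l in seq_len(L)) {
    r <- ranks[[l]]
    if (length(r)) {
      rk[names(r), l] <- r
      predicted[names(r), l] <- TRUE
    }
  }
  score <- rowMeans(rk)
  support <- apply(predicted, 1L, function(z) paste(ids[z], collapse = "+"))
  n_support <- rowSums(predicted)
  ends <- do.call(rbind, strsplit(all_keys, "|", fixed = TRUE))
  ori <- vapply(seq_along(all_keys), function(i) {
    consensus_orientation(all_keys[i], networks, ranks)
  }, "")
  df <- data.frame(source = ends[, 1L], target = ends[, 2L],
                   orientation = ori, consensus_score = score,
                   support = support, stringsAsFactors = FALSE)
  for (l in seq_len(L)) df[[paste0("rank_", ids[l])]] <- rk[, l]
  ord <- order(score, -n_support, df$source, df$target)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  retained <- df[seq_len(min(e_max, nrow(df))), , drop = FALSE]
  structure(list(edges = retained, all_pairs = df, e_max = e_max,
                 learner_ids = ids), class = "consensus_network")
}

#' Rank-weighted consensus orientation of one pair
#'
#' @param key canonical pair key `"a|b"`.
#' @param networks list of `learner_network` objects.
#' @param ranks optional precomputed list of [rank_edges()] results.
#' @return Orientation string (canonical pair order: `"source_to_target"`
#'   means a -> b).
#' @export
consensus_orientation <- function(key, networks, ranks = NULL) {
  if (is.null(ranks)) ranks <- lapply(networks, rank_edges)
  w_fwd <- 0; w_rev <- 0
  for (l in seq_along(networks)) {
    net <- networks[[l]]
    if (!isTRUE(net$provides_orientation)) next
    r <- ranks[[l]]
    if (!key %in% names(r)) next
    edges <- net$final_edges
    i <- which(pair_key(edges) == key)[1L]
    ori <- canonical_orientation(edges$source[i], edges$target[i],
                                 edges$orientation[i])
    if (ori == "undirected") next
    E <- length(r)
    w <- 1 - r[[key]] + 1 / (2 * E)
    if (ori == "source_to_target") w_fwd <- w_fwd + w else w_rev <- w_rev + w
  }
  if (w_fwd > w_rev + 1e-12) "source_to_target"
  else if (w_rev > w_fwd + 1e-12) "target_to_source"
  else "undirected"
}

#' Edge counts by learner-support category
#'
#' Partitions the *pre-truncation* consensus pairs by the exact set of
#' learners that predicted them (the 2^L - 1 non-empty support classes);
#' the class counts always sum to the total number of consensus pairs.
#'
#' @param net a `consensus_network`.
#' @return Named integer vector, names like `"aracne"`, `"aracne+hc"`.
#' @export
support_categories <- function(net) {
  stopifnot(inherits(net, "consensus_network"))
  if (!nrow(net$all_pairs)) return(stats::setNames(integer(0), character(0)))
  tab <- table(net$all_pairs$support)
  stats::setNames(as.integer(tab), names(tab))
}

#' @export
print.consensus_network <- function(x, ...) {
  cat("Consensus network over learners {",
      paste(x$learner_ids, collapse = ", "), "}\n", sep = "")
  cat("  ", nrow(x$all_pairs), " candidate pairs; ", nrow(x$edges),
      " retained (e_max = ", x$e_max, ")\n", sep = "")
  if (nrow(x$edges)) {
    cat("  best score: ", signif(min(x$edges$consensus_score), 4),
        "; worst retained: ", signif(max(x$edges$consensus_score), 4), "\n",
        sep = "")
  }
  invisible(x)
}
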