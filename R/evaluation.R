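#' Score a predicted network against a ground truth
#'
#' Matching is on unordered pairs (the skeleton). With the misorientation
#' penalty on, a predicted edge whose pair is in the truth but whose
#' direction contradicts the truth's direction counts as a false positive,
#' and the contradicted true edge as a false negative — so a wrongly
#' directed detection scores as badly as a miss, while recall's denominator
#' stays |truth|. An undirected prediction of a directed true edge is not
#' penalized (only *falsely oriented* edges are), and a directed prediction
#' of an undirected true edge cannot contradict it.
#'
#' @param predicted an [edge_table()] (or network object accepted by
#'   `as_edge_frame`).
#' @param truth a [network_truth()].
#' @param orientation_penalty apply the misorientation convention (default
#'   `TRUE`).
#' @return Object of class `"evaluation_report"`: `tp`, `fp`, `fn`,
#'   `misoriented`, `precision`, `recall`, `f_score`.
#' @export
score_network <- function(predicted, truth, orientation_penalty = TRUE) {
  stopifnot(inherits(truth, "network_truth"))
  pred <- as_edge_frame(predicted)
  if (nrow(pred)) pred <- pred[!duplicated(pair_key(pred)), , drop = FALSE]
  pk <- if (nrow(pred)) pair_key(pred) else character(0)
  tk <- if (nrow(truth$edges)) pair_key(truth$edges) else character(0)
  in_truth <- pk %in% tk
  misoriented <- logical(length(pk))
  if (orientation_penalty && any(in_truth)) {
    pori <- canonical_orientation(pred$source, pred$target, pred$orientation)
    tori <- canonical_orientation(truth$edges$source, truth$edges$target,
                                  truth$edges$orientation)[match(pk, tk)]
    misoriented <- in_truth & pori != "undirected" & tori != "undirected" &
      pori != tori
  }
  tp <- sum(in_truth & !misoriented)
  fp <- sum(!in_truth) + sum(misoriented)
  fn <- length(tk) - tp
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f_score <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  structure(list(tp = tp, fp = fp, fn = fn, misoriented = sum(misoriented),
                 precision = precision, recall = recall, f_score = f_score),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("TP %d  FP %d  FN %d  (misoriented %d)\n",
              x$tp, x$fp, x$fn, x$misoriented))
  cat(sprintf("Precision %.3f  Recall %.3f  F-score %.3f\n",
              x$precision, x$recall, x$f_score))
  invisible(x)
}

#' Average degree of a graph
#'
#' `2 * edges / nodes`; e.g. 223 nodes and 338 edges give 3.03.
#'
#' @param nodes node count (> 0).
#' @param edges edge count.
#' @return Numeric.
#' @export
average_degree <- function(nodes, edges) {
  if (nodes <= 0) stop("nodes must be positive")
  2 * edges / nodes
}

# round half up to integer (matching reported percentages)
round_half_up <- function(x) floor(x + 0.5)

#' Overlap statistics between two edge sets
#'
#' @param edges_a,edges_b edge tables or character vectors of canonical pair
#'   keys.
#' @return List with `common`, `only_a`, `only_b` counts and
#'   `pct_common_of_a` (= 100 * common / |A|, rounded half-up to an
#'   integer, as overlaps are conventionally reported).
#' @export
overlap_stats <- function(edges_a, edges_b) {
  ka <- unique(if (is.data.frame(edges_a)) pair_key(edges_a) else as.character(edges_a))
  kb <- unique(if (is.data.frame(edges_b)) pair_key(edges_b) else as.character(edges_b))
  common <- length(intersect(ka, kb))
  list(common = common,
       only_a = length(ka) - common,
       only_b = length(kb) - common,
       pct_common_of_a = if (length(ka)) round_half_up(100 * common / length(ka)) else 0)
}

#' Pairwise Fisher's-exact co-presence baseline
#'
#' The pairwise competitor for presence/absence data: for every variable
#' pair, a 2x2 contingency table of presence/absence is tested with a
#' two-sided Fisher exact test; pairs significant after multiple-testing
#' correction become edges. Strength is -log10(p). The association side is
#' flagged from the sample odds ratio: `"co_presence"` for positive
#' association (the gray edges of co-occurrence graphs), `"absence_presence"`
#' for negative (red edges).
#'
#' @param data a [discrete_dataset()] with all variables binary; the second
#'   (lexicographically larger) category is "present". Missing values drop
#'   pairwise.
#' @param alpha significance level (default 0.05).
#' @param correction `"bh"` (Benjamini-Hochberg, default) or `"none"`.
#' @return An [edge_table()] with extra columns `p_value`, `association`.
#' @export
fisher_baseline <- function(data, alpha = 0.05, correction = c("bh", "none")) {
  stopifnot(inherits(data, "discrete_dataset"))
  correction <- match.arg(correction)
  if (any(lengths(data$alphabets) != 2L)) {
    stop("fisher_baseline requires binary variables")
  }
  p <- data$p
  vals <- data$values
  nms <- data$variable_names
  src <- character(0); tgt <- character(0)
  pv <- numeric(0); assoc <- character(0)
  for (i in seq_len(p - 1L)) for (j in (i + 1L):p) {
    xi <- vals[, i]; yj <- vals[, j]
    ok <- !(is.na(xi) | is.na(yj))
    tab <- table(factor(xi[ok], levels = 1:2), factor(yj[ok], levels = 1:2))
    pval <- stats::fisher.test(tab, alternative = "two.sided")$p.value
    or_num <- tab[1, 1] * tab[2, 2]
    or_den <- tab[1, 2] * tab[2, 1]
    src <- c(src, nms[i]); tgt <- c(tgt, nms[j])
    pv <- c(pv, pval)
    assoc <- c(assoc, if (or_num >= or_den) "co_presence" else "absence_presence")
  }
  padj <- if (correction == "bh") stats::p.adjust(pv, "BH") else pv
  keep <- padj < alpha
  out <- edge_table(src[keep], tgt[keep], orientation = "undirected",
                    strength = -log10(pmax(pv[keep], .Machine$double.xmin)))
  out$p_value <- pv[keep]
  out$p_adjusted <- padj[keep]
  out$association <- assoc[keep]
  out
}
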