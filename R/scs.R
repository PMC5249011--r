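#' Fit a spectral consensus network
#'
#' Runs the full three-phase Spectral Consensus Strategy on a categorical
#' dataset:
#'
#' 1. *spectral* — the pairwise mutual-information similarity matrix is
#'    built, the random-walk normalized Laplacian \eqn{L_{rw} = I - D^{-1}W}
#'    decomposed, and `k` leading eigenvectors chosen (by the eigengap
#'    heuristic unless fixed);
#' 2. *learn* — for each eigenvector, the `m` most positive and `m` most
#'    negative elements define two overlapping variable subsets; every
#'    registered learner reconstructs each subset locally, and each
#'    learner's locals are merged by the every-time intersection rule with
#'    majority-rule orientation;
#' 3. *consensus* — per-learner edge ranks are normalized to (0, 1],
#'    averaged across learners with worst-rank (= 1) imputation for missing
#'    pairs, and the `e_max` best-scoring edges form the consensus network.
#'
#' @param data a [discrete_dataset()] (or a matrix/data frame of categorical
#'   values, converted via [as_discrete_dataset()]).
#' @param m subset size: number of variables per local reconstruction.
#' @param e_max number of consensus edges to retain.
#' @param learners character vector of registered learner ids (default
#'   ARACNE and BDeu hill climbing).
#' @param k number of leading eigenvectors; `NULL` (default) applies the
#'   eigengap heuristic capped at `k_max`.
#' @param k_max cap for the eigengap search (default `ceiling(0.4 * p)`,
#'   the largest eigenvector proportion explored in benchmark evaluations).
#' @param selector subset selector: `"spectral"` (the method), or the
#'   comparison selectors `"kmeans"`, `"bipartition"`, `"random"`.
#' @param seed root seed; all randomness in the run flows from it.
#' @param mi_log_base MI log base (default 2).
#' @param learner_options named list (by learner id) of option lists.
#' @param truth optional [network_truth()]; when supplied, the consensus and
#'   each learner network are scored with the misorientation penalty.
#' @return Object of class `"scs"`: the consensus network, per-learner
#'   networks, subsets, spectral decomposition, configuration, and (when
#'   truth is given) evaluation reports.
#' @examples
#' bench <- generate_copresence(p = 12, n = 300, n_blocks = 3, seed = 7)
#' fit <- scs(bench$data, m = 4, e_max = nrow(bench$truth$edges),
#'            learners = c("aracne", "hc"), seed = 7, truth = bench$truth)
#' fit
#' summary(fit)
#' @export
scs <- function(data, m, e_max, learners = c("aracne", "hc"), k = NULL,
                k_max = NULL, selector = c("spectral", "kmeans",
                                           "bipartition", "random"),
                seed = 1L, mi_log_base = 2, learner_options = list(),
                truth = NULL) {
  if (!inherits(data, "discrete_dataset")) data <- as_discrete_dataset(data)
  selector <- match.arg(selector)
  m <- as.integer(m)
  if (m < 2L || m > data$p) stop("m must be in [2, p]")
  for (id in learners) get_learner(id)   # fail early on unknown ids

  set.seed(seed)
  W <- mi_matrix(data, log_base = mi_log_base)
  lap <- build_laplacian(W)
  sd <- eigendecompose(lap)
  p_eff <- length(sd$names)
  if (is.null(k_max)) k_max <- max(2L, ceiling(0.4 * p_eff))
  k_max <- min(as.integer(k_max), p_eff)
  if (is.null(k)) k <- eigengap_k(sd$eigenvalues, k_max)
  k <- min(as.integer(k), p_eff)
  # constant null eigenvectors consume slots but carry no sign structure;
  # guarantee at least one informative eigenvector (all selectors share the
  # same k so comparison runs keep matched subset cardinality)
  k <- min(max(k, n_components(sd) + 1L), p_eff)

  subsets <- switch(selector,
    spectral = scs_subsets(sd, k, m),
    kmeans = kmeans_subsets(sd, k, n_clusters = min(2L * k, p_eff %/% 2L),
                            seed = NULL),
    bipartition = bipartition_subsets(W, min_size = m),
    random = random_subsets(p_eff, count = 2L * k, m, seed = NULL,
                            names = sd$names))
  if (!length(subsets)) stop("subset selection produced no subsets")

  networks <- vector("list", length(learners))
  names(networks) <- learners
  for (id in learners) {
    opts <- learner_options[[id]] %||% list()
    locals <- lapply(subsets, function(sub) {
      if (length(sub$indices) < 2L) {       # singleton: nothing to learn
        return(local_graph(sub, edge_table(), id))
      }
      sub_data <- restrict_dataset(data, sub$names %||% sub$indices,
                                   drop_incomplete = TRUE)
      learn_local(list(id = id, options = opts), sub_data, subset = sub,
                  seed = NULL)
    })
    networks[[id]] <- assemble(locals, subsets, learner_id = id)
  }
  consensus <- scs_consensus(networks, e_max = e_max)

  scores <- NULL
  if (!is.null(truth)) {
    scores <- c(list(consensus = score_network(consensus$edges, truth)),
                lapply(networks, function(nw) score_network(nw$final_edges, truth)))
  }
  structure(list(consensus = consensus, networks = networks,
                 subsets = subsets, spectral = sd, k = k, m = m,
                 e_max = as.integer(e_max), selector = selector,
                 learners = learners, seed = seed, scores = scores,
                 call = match.call()),
            class = "scs")
}

#' Coerce a matrix or data frame of categorical values to a dataset
#'
#' Columns are coded against lexicographically sorted per-column alphabets.
#'
#' @param x matrix or data frame; column names become variable names.
#' @return A [discrete_dataset()].
#' @export
as_discrete_dataset <- function(x) {
  x <- as.data.frame(x)
  nms <- colnames(x)
  if (is.null(nms)) nms <- paste0("V", seq_along(x))
  alphabets <- lapply(x, function(col) sort(unique(as.character(col[!is.na(col)]))))
  vals <- mapply(function(col, a) match(as.character(col), a), x, alphabets)
  discrete_dataset(matrix(as.integer(vals), nrow = nrow(x)), nms, alphabets)
}

#' @export
print.scs <- function(x, ...) {
  cat("Spectral consensus network fit\n")
  cat("  selector:", x$selector, " k =", x$k, " m =", x$m,
      " e_max =", x$e_max, "\n")
  cat("  learners:", paste(x$learners, collapse = ", "), "\n")
  cat("  subsets:", length(x$subsets), " consensus edges:",
      nrow(x$consensus$edges), "\n")
  if (!is.null(x$scores)) {
    cat(sprintf("  consensus F-score: %.3f\n", x$scores$consensus$f_score))
  }
  invisible(x)
}

#' @export
summary.scs <- function(object, ...) {
  cat("Spectral consensus strategy fit\n\n")
  cat("Spectral phase: k =", object$k, "eigenvectors,",
      length(object$subsets), "subsets of size", object$m,
      "(selector:", object$selector, ")\n")
  if (length(object$spectral$dropped)) {
    cat("  isolated variables dropped:",
        length(object$spectral$dropped), "\n")
  }
  cat("\nPer-learner networks:\n")
  for (id in names(object$networks)) {
    nw <- object$networks[[id]]
    cat(sprintf("  %-8s %5d edges retained of %5d co-included pairs\n",
                id, nrow(nw$final_edges), nrow(nw$pairs)))
  }
  cat("\nConsensus:", nrow(object$consensus$all_pairs), "candidate pairs,",
      nrow(object$consensus$edges), "retained (e_max =",
      object$consensus$e_max, ")\n")
  sc <- support_categories(object$consensus)
  if (length(sc)) {
    cat("Support categories (pre-truncation):\n")
    for (nm in names(sc)) cat(sprintf("  %-20s %d\n", nm, sc[[nm]]))
  }
  if (!is.null(object$scores)) {
    cat("\nEvaluation vs truth (misorientation penalty on):\n")
    for (nm in names(object$scores)) {
      s <- object$scores[[nm]]
      cat(sprintf("  %-10s P %.3f  R %.3f  F %.3f\n",
                  nm, s$precision, s$recall, s$f_score))
    }
  }
  invisible(object)
}

#' Plot a fitted consensus network
#'
#' Draws the retained consensus edges as an igraph plot; edge width scales
#' with significance (1 - consensus score) and arrows follow the consensus
#' orientation.
#'
#' @param x an `"scs"` fit.
#' @param ... passed to [igraph::plot.igraph()].
#' @export
plot.scs <- function(x, ...) {
  df <- x$consensus$edges
  if (!nrow(df)) {
    warning("empty consensus network; nothing to plot")
    return(invisible(NULL))
  }
  src <- ifelse(df$orientation == "target_to_source", df$target, df$source)
  tgt <- ifelse(df$orientation == "target_to_source", df$source, df$target)
  g <- igraph::graph_from_data_frame(
    data.frame(from = src, to = tgt), directed = TRUE)
  w <- 1 - df$consensus_score
  igraph::E(g)$width <- 1 + 3 * (w - min(w)) / max(1e-12, diff(range(w)))
  igraph::E(g)$arrow.size <- ifelse(df$orientation == "undirected", 0, 0.4)
  igraph::plot.igraph(g, ...)
  invisible(g)
}
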