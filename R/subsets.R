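#' Variable subset for local reconstruction
#'
#' @param indices ordered variable indices (most extreme eigenvector element
#'   first for spectral subsets).
#' @param selector `"spectral"`, `"kmeans"`, `"bipartition"` or `"random"`.
#' @param eigenvector_index eigenvector of origin (spectral subsets).
#' @param sign `"positive"` or `"negative"` (spectral subsets).
#' @param names optional variable names.
#' @return Object of class `"variable_subset"`.
#' @export
variable_subset <- function(indices, selector = "spectral",
                            eigenvector_index = NA_integer_,
                            sign = NA_character_, names = NULL) {
  indices <- as.integer(indices)
  if (anyDuplicated(indices)) stop("subset indices must be unique")
  if (length(indices) < 1L) stop("empty subset")
  structure(list(indices = indices, selector = selector,
                 eigenvector_index = as.integer(eigenvector_index),
                 sign = sign, names = names),
            class = "variable_subset")
}

#' @export
print.variable_subset <- function(x, ...) {
  tag <- if (!is.na(x$eigenvector_index)) {
    paste0(" [v", x$eigenvector_index, ", ", x$sign, "]")
  } else ""
  cat("Subset (", x$selector, tag, "): ", length(x$indices), " variables\n",
      sep = "")
  invisible(x)
}

# constant up to numeric noise relative to the vector's scale
is_constant_vector <- function(v, tol = 1e-9) {
  (max(v) - min(v)) <= tol * max(abs(v), 1e-300)
}

#' Spectral variable subsets from eigenvector element magnitude and sign
#'
#' For each of the first `k` eigenvectors, two subsets are formed: the `m`
#' variables with the largest (most positive) elements and the `m` with the
#' smallest (most negative) elements. Only the order of the elements matters
#' — the "negative" subset need not contain negative values. Ties are broken
#' by ascending variable index. A constant eigenvector (the trivial
#' \eqn{\lambda = 0} vector of a connected graph) carries no sign structure:
#' it is skipped with a message but still consumes one of the `k` slots, so
#' `k` keeps its meaning of "first k eigenvectors of the spectrum".
#'
#' @param sd a `spectral_decomposition`.
#' @param k number of leading eigenvectors to use (1..p).
#' @param m subset size (2..p).
#' @return List of [variable_subset()] objects (at most `2 * k`).
#' @export
scs_subsets <- function(sd, k, m) {
  p <- length(sd$names)
  m <- as.integer(m); k <- as.integer(k)
  if (m > p) stop("m (", m, ") exceeds the number of variables (", p, ")")
  if (m < 2L) stop("m must be at least 2")
  if (k < 1L || k > p) stop("k must be in [1, ", p, "]")
  out <- list()
  skipped <- 0L
  for (ki in seq_len(k)) {
    v <- sd$vectors[, ki]
    if (is_constant_vector(v)) {
      skipped <- skipped + 1L
      next
    }
    pos <- order(-v, seq_along(v))[seq_len(m)]
    neg <- order(v, seq_along(v))[seq_len(m)]
    out[[length(out) + 1L]] <- variable_subset(pos, "spectral", ki, "positive",
                                               sd$names[pos])
    out[[length(out) + 1L]] <- variable_subset(neg, "spectral", ki, "negative",
                                               sd$names[neg])
  }
  if (skipped) {
    message("skipped ", skipped,
            " constant eigenvector(s) (no usable sign structure)")
  }
  dup <- duplicated(vapply(out, function(s) paste(sort(s$indices), collapse = ","), ""))
  if (any(dup)) {
    message(sum(dup), " of ", length(out),
            " subsets duplicate an earlier subset (kept; harmless under the ",
            "intersection rule)")
  }
  out
}

#' Spectral K-means comparison selector
#'
#' K-means on the k-dimensional spectral embedding (rows of the first `k`
#' eigenvectors); each cluster becomes one subset. This is the partitioning
#' baseline the subset selector is compared against: clusters are disjoint,
#' so edges across cluster boundaries can never be tested.
#'
#' @param sd a `spectral_decomposition`.
#' @param k embedding dimension.
#' @param n_clusters number of clusters/subsets.
#' @param seed integer seed, or `NULL` to use the current RNG stream.
#' @return List of [variable_subset()]; clusters may differ in size.
#' @export
kmeans_subsets <- function(sd, k, n_clusters, seed = NULL) {
  emb <- sd$vectors[, seq_len(k), drop = FALSE]
  if (n_clusters == nrow(emb)) {     # exact solution: every point its own cluster
    return(lapply(seq_len(n_clusters), function(cl)
      variable_subset(cl, "kmeans", names = sd$names[cl])))
  }
  with_local_seed(seed, {
    fit <- NULL
    for (try in seq_len(10L)) {
      # Hartigan-Wong errors out on transiently empty clusters; fall back to
      # Lloyd for the later attempts
      alg <- if (try <= 5L) "Hartigan-Wong" else "Lloyd"
      fit <- tryCatch(
        suppressWarnings(stats::kmeans(emb, centers = n_clusters,
                                       nstart = 5L, algorithm = alg)),
        error = function(e) NULL)
      if (!is.null(fit) && all(tabulate(fit$cluster, n_clusters) > 0L)) break
      fit <- NULL
    }
    if (is.null(fit)) stop("k-means failed to produce ", n_clusters,
                           " non-empty clusters after 10 restarts")
    lapply(seq_len(n_clusters), function(cl) {
      idx <- which(fit$cluster == cl)
      variable_subset(idx, "kmeans", names = sd$names[idx])
    })
  })
}

#' Recursive bi-partitioning comparison selector
#'
#' Recursively splits each part at the sign of its Fiedler vector (second
#' eigenvector of the part's own random-walk Laplacian) until a part has at
#' most `min_size` vertices or a further split would create a part smaller
#' than `min_size`. Disconnected parts split into their components first.
#'
#' @param W similarity matrix.
#' @param min_size smallest allowed part.
#' @return List of [variable_subset()] covering all vertices.
#' @export
bipartition_subsets <- function(W, min_size) {
  W <- check_similarity(W)
  nms <- rownames(W)
  leaves <- list()
  split_part <- function(idx) {
    if (length(idx) <= max(min_size, 1L)) {
      leaves[[length(leaves) + 1L]] <<- idx
      return(invisible())
    }
    sub <- W[idx, idx, drop = FALSE]
    comp <- graph_components(sub)
    if (max(comp) > 1L) {
      for (c in seq_len(max(comp))) split_part(idx[comp == c])
      return(invisible())
    }
    if (length(idx) < 2L * min_size) {
      leaves[[length(leaves) + 1L]] <<- idx
      return(invisible())
    }
    sd <- eigendecompose(suppressWarnings(build_laplacian(sub)))
    f <- sd$vectors[, 2L]
    side <- f >= 0
    if (sum(side) < min_size || sum(!side) < min_size) {
      leaves[[length(leaves) + 1L]] <<- idx
      return(invisible())
    }
    split_part(idx[side])
    split_part(idx[!side])
  }
  split_part(seq_len(nrow(W)))
  lapply(leaves, function(idx) {
    idx <- sort(idx)
    variable_subset(idx, "bipartition", names = nms[idx])
  })
}

# connected components of the positive-weight graph (label vector)
graph_components <- function(W) {
  p <- nrow(W)
  comp <- integer(p)
  cur <- 0L
  for (s in seq_len(p)) {
    if (comp[s]) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      nb <- which(W[v, ] > 0 & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Random subsets comparison selector
#'
#' Uniform m-subsets drawn without replacement (within each subset), the
#' null selector for judging what the spectral selection contributes.
#'
#' @param p number of variables.
#' @param count number of subsets (use `2 * k` to match the spectral
#'   selector's cardinality).
#' @param m subset size.
#' @param seed integer seed, or `NULL` to use the current RNG stream.
#' @param names optional variable names.
#' @return List of [variable_subset()].
#' @export
random_subsets <- function(p, count, m, seed = NULL, names = NULL) {
  if (m > p) stop("m exceeds p")
  with_local_seed(seed, {
    lapply(seq_len(count), function(i) {
      idx <- sort(sample.int(p, m))
      variable_subset(idx, "random", names = if (!is.null(names)) names[idx])
    })
  })
}
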