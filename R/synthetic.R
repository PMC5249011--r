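# Synthetic benchmarks: every pipeline stage is testable without external
# downloads. Two generators cover the two application regimes — forward-
# sampled discrete Bayesian networks (benchmark-style oriented truths) and
# planted co-presence block matrices (sparse microbiome-style binary data).

#' Random discrete Bayesian network benchmark
#'
#' Draws a DAG over a random topological order with edges placed uniformly
#' to hit the target average degree, equips each node with conditional
#' probability tables drawn from a flat Dirichlet(1) per parent
#' configuration (so dependence strengths vary from near-deterministic to
#' weak), and forward-samples `n` observations in topological order.
#'
#' @param p number of variables (>= 2).
#' @param n sample size (>= 1).
#' @param avg_degree target average degree (undirected sense,
#'   `2 * edges / p`); the generated count is exact, `round(avg_degree * p
#'   / 2)`.
#' @param categories categories per variable (default 2).
#' @param seed integer seed, or `NULL` for the current stream.
#' @return Object of class `"generated_benchmark"`: `truth` (oriented
#'   [network_truth()]), `data` ([discrete_dataset()]), `params`.
#' @export
generate_dag_benchmark <- function(p, n, avg_degree, categories = 2L,
                                   seed = NULL) {
  p <- as.integer(p); n <- as.integer(n)
  stopifnot(p >= 2L, n >= 1L, avg_degree >= 0)
  n_edges <- round(avg_degree * p / 2)
  if (n_edges > p * (p - 1) / 2) stop("infeasible average degree ", avg_degree,
                                      " for p = ", p)
  r <- as.integer(categories)
  stopifnot(r >= 2L)
  nms <- sprintf("V%03d", seq_len(p))
  with_local_seed(seed, {
    ord <- sample.int(p)                       # ord[k] = variable at position k
    pairs <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
    sel <- if (n_edges > 0) sample.int(nrow(pairs), n_edges) else integer(0)
    parent <- ord[pairs[sel, 1L]]              # earlier position -> parent
    child <- ord[pairs[sel, 2L]]
    parents_of <- split(parent, factor(child, levels = seq_len(p)))
    # CPTs: rows = parent configurations, columns = categories
    cpt <- vector("list", p)
    for (v in seq_len(p)) {
      q <- prod(c(1L, r^length(parents_of[[v]])))
      g <- matrix(stats::rgamma(q * r, shape = 1), nrow = q)
      cpt[[v]] <- g / rowSums(g)
    }
    vals <- matrix(NA_integer_, n, p)
    for (k in seq_len(p)) {
      v <- ord[k]
      pa <- parents_of[[v]]
      if (!length(pa)) {
        probs <- cpt[[v]][1L, ]
        vals[, v] <- sample.int(r, n, replace = TRUE, prob = probs)
      } else {
        cfg <- rep(1L, n)
        stride <- 1L
        for (u in pa) {
          cfg <- cfg + (vals[, u] - 1L) * stride
          stride <- stride * r
        }
        u01 <- stats::runif(n)
        cum <- t(apply(cpt[[v]], 1L, cumsum))
        vals[, v] <- 1L + rowSums(u01 > cum[cfg, , drop = FALSE])
      }
    }
    truth <- network_truth(
      edge_table(nms[parent], nms[child], orientation = "source_to_target"),
      nodes = nms)
    data <- discrete_dataset(vals, nms,
                             rep(list(as.character(seq_len(r) - 1L)), p))
    structure(list(truth = truth, data = data,
                   params = list(p = p, n = n, avg_degree = avg_degree,
                                 categories = r, seed = seed)),
              class = "generated_benchmark")
  })
}

#' Planted co-presence block data
#'
#' Emulates sparse presence/absence data with block-structured co-presence:
#' variables are split into `n_blocks` near-equal blocks; in each sample a
#' block is jointly "on" with probability `block_on_prob` (a latent switch),
#' and a member variable is then present with probability `within_prob` when
#' its block is on and `background_prob` otherwise. The ground truth is the
#' union of within-block cliques (undirected), the transitive co-presence
#' structure the intersection rule is meant to recover.
#'
#' @param p number of variables.
#' @param n samples.
#' @param n_blocks number of planted blocks (<= p).
#' @param within_prob presence probability when the block is on (default
#'   0.9).
#' @param background_prob presence probability otherwise (default 0.05).
#' @param block_on_prob latent switch probability (default 0.5).
#' @param seed integer seed or `NULL`.
#' @return A `"generated_benchmark"` (binary alphabets `"0"`/`"1"`).
#' @export
generate_copresence <- function(p, n, n_blocks, within_prob = 0.9,
                                background_prob = 0.05, block_on_prob = 0.5,
                                seed = NULL) {
  p <- as.integer(p); n <- as.integer(n); n_blocks <- as.integer(n_blocks)
  stopifnot(p >= 2L, n >= 1L, n_blocks >= 1L, n_blocks <= p)
  for (prob in c(within_prob, background_prob, block_on_prob)) {
    if (prob < 0 || prob > 1) stop("probabilities must lie in [0, 1]")
  }
  nms <- sprintf("V%03d", seq_len(p))
  block <- sort(rep_len(seq_len(n_blocks), p))
  with_local_seed(seed, {
    vals <- matrix(NA_integer_, n, p)
    on <- matrix(stats::runif(n * n_blocks) < block_on_prob, n, n_blocks)
    for (j in seq_len(p)) {
      pr <- ifelse(on[, block[j]], within_prob, background_prob)
      vals[, j] <- 1L + (stats::runif(n) < pr)   # 1 = absent, 2 = present
    }
    src <- character(0); tgt <- character(0)
    for (b in seq_len(n_blocks)) {
      members <- nms[block == b]
      if (length(members) >= 2L) {
        cmb <- utils::combn(members, 2L)
        src <- c(src, cmb[1L, ]); tgt <- c(tgt, cmb[2L, ])
      }
    }
    truth <- network_truth(edge_table(src, tgt, orientation = "undirected"),
                           nodes = nms)
    data <- discrete_dataset(vals, nms, rep(list(c("0", "1")), p))
    structure(list(truth = truth, data = data,
                   params = list(p = p, n = n, n_blocks = n_blocks,
                                 within_prob = within_prob,
                                 background_prob = background_prob,
                                 block_on_prob = block_on_prob, seed = seed)),
              class = "generated_benchmark")
  })
}

#' Block-constant similarity matrix
#'
#' Fixture builder for the spectral invariants: a p x p similarity with
#' `within_weight` inside each block, `between_weight` across blocks and a
#' zero diagonal. With `between_weight = 0` the graph has exactly one zero
#' eigenvalue per block and indicator-structured eigenvectors.
#'
#' @param block_sizes integer vector of block sizes.
#' @param within_weight within-block weight (default 1).
#' @param between_weight between-block weight (default 0).
#' @return Similarity matrix with names `B<block>_<member>`.
#' @export
make_block_similarity <- function(block_sizes, within_weight = 1,
                                  between_weight = 0) {
  stopifnot(all(block_sizes >= 1L), within_weight >= 0, between_weight >= 0)
  p <- sum(block_sizes)
  block <- rep(seq_along(block_sizes), block_sizes)
  W <- matrix(between_weight, p, p)
  for (b in seq_along(block_sizes)) {
    idx <- which(block == b)
    W[idx, idx] <- within_weight
  }
  diag(W) <- 0
  nms <- unlist(lapply(seq_along(block_sizes), function(b)
    paste0("B", b, "_", seq_len(block_sizes[b]))))
  dimnames(W) <- list(nms, nms)
  W
}

#' @export
print.generated_benchmark <- function(x, ...) {
  cat("Generated benchmark: p =", x$data$p, ", n =", x$data$n,
      ",", nrow(x$truth$edges), "true edges\n")
  invisible(x)
}
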