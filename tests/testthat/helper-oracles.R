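# Independent oracles: deliberately naive implementations used to verify the
# package's optimized code paths. Each is written directly from the defining
# formula or by exhaustive enumeration, never by calling the function under
# test.

# plug-in MI by explicit sum over the joint table cells
oracle_mi <- function(x, y, base = 2) {
  n <- length(x)
  tab <- table(x, y)
  px <- rowSums(tab) / n
  py <- colSums(tab) / n
  total <- 0
  for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab))) {
    pxy <- tab[i, j] / n
    if (pxy > 0) total <- total + pxy * log(pxy / (px[i] * py[j]), base = base)
  }
  unname(total)
}

# Ncut by direct evaluation of the defining sum
oracle_ncut <- function(blocks, W) {
  deg <- rowSums(W)
  total <- 0
  for (A in blocks) {
    Abar <- setdiff(seq_len(nrow(W)), A)
    cut <- 0
    for (i in A) for (j in Abar) cut <- cut + W[i, j]
    vol <- sum(deg[A])
    if (vol > 0) total <- total + cut / vol
  }
  total / 2
}

# dense eigensolver oracle: eigenvalues/eigenvectors of the (nonsymmetric)
# L_rw itself, via base eigen() without the symmetric shortcut
oracle_eigen_lrw <- function(W) {
  deg <- rowSums(W)
  stopifnot(all(deg > 0))
  L <- diag(nrow(W)) - W / deg
  e <- eigen(L)
  ord <- order(Re(e$values))
  list(values = Re(e$values)[ord],
       vectors = Re(e$vectors)[, ord, drop = FALSE])
}

# brute-force DPI pruning on an MI matrix: threshold, then mark the weakest
# edge of every triangle (lexicographically smallest pair on ties) and remove
# all marked edges simultaneously
oracle_dpi <- function(W, threshold, tol = 0) {
  p <- nrow(W)
  adj <- W > threshold
  diag(adj) <- FALSE
  marked <- matrix(FALSE, p, p)
  if (p >= 3) {
    trip <- t(utils::combn(p, 3))
    for (t in seq_len(nrow(trip))) {
      i <- trip[t, 1]; j <- trip[t, 2]; k <- trip[t, 3]
      if (!(adj[i, j] && adj[i, k] && adj[j, k])) next
      edges <- list(c(i, j), c(i, k), c(j, k))
      mis <- c(W[i, j], W[i, k], W[j, k])
      weak <- sapply(1:3, function(e) mis[e] <= min(mis[-e]) - tol)
      if (any(weak)) {
        e <- edges[[min(which(weak))]]   # lexicographic tie-break
        marked[e[1], e[2]] <- marked[e[2], e[1]] <- TRUE
      }
    }
  }
  keep <- adj & !marked
  which(keep & upper.tri(keep), arr.ind = TRUE)
}

# all DAG adjacency matrices on p nodes (adj[u, v] = u -> v), by filtering
# every orientation of every subset of ordered pairs
oracle_all_dags <- function(p) {
  pairs <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
  np <- nrow(pairs)
  out <- list()
  # each unordered pair is absent (0), forward (1) or backward (2)
  states <- rep(0L, np)
  repeat {
    adj <- matrix(FALSE, p, p)
    for (e in seq_len(np)) {
      if (states[e] == 1L) adj[pairs[e, 1], pairs[e, 2]] <- TRUE
      if (states[e] == 2L) adj[pairs[e, 2], pairs[e, 1]] <- TRUE
    }
    if (oracle_acyclic(adj)) out[[length(out) + 1L]] <- adj
    e <- 1L
    while (e <= np) {
      states[e] <- states[e] + 1L
      if (states[e] <= 2L) break
      states[e] <- 0L
      e <- e + 1L
    }
    if (e > np) break
  }
  out
}

oracle_acyclic <- function(adj) {
  p <- ncol(adj)
  indeg <- colSums(adj)
  active <- rep(TRUE, p)
  repeat {
    src <- which(active & indeg == 0)
    if (!length(src)) break
    active[src] <- FALSE
    for (v in src) indeg <- indeg - adj[v, ]
  }
  !any(active)
}

# direct enumeration of the every-time intersection rule over all pairs
oracle_assemble <- function(locals, subsets) {
  members <- lapply(subsets, function(s) s$names)
  all_names <- sort(unique(unlist(members)))
  kept <- character(0)
  if (length(all_names) >= 2) {
    cmb <- utils::combn(all_names, 2)
    for (c in seq_len(ncol(cmb))) {
      a <- cmb[1, c]; b <- cmb[2, c]
      co <- 0L; learned <- 0L
      for (t in seq_along(subsets)) {
        if (a %in% members[[t]] && b %in% members[[t]]) {
          co <- co + 1L
          ek <- paste(pmin(locals[[t]]$edges$source, locals[[t]]$edges$target),
                      pmax(locals[[t]]$edges$source, locals[[t]]$edges$target),
                      sep = "|")
          if (paste(a, b, sep = "|") %in% ek) learned <- learned + 1L
        }
      }
      if (co >= 1L && learned == co) kept <- c(kept, paste(a, b, sep = "|"))
    }
  }
  sort(kept)
}

# two-sided Fisher exact p-value by hypergeometric enumeration:
# sum the probabilities of all tables (with the observed margins) whose
# probability does not exceed the observed table's
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b          # row 1 total
  n2 <- c + d         # row 2 total
  k <- a + c          # column 1 total
  lo <- max(0, k - n2)
  hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n2, k)
  obs <- stats::dhyper(a, m, n2, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# random symmetric nonnegative similarity matrix with zero diagonal
random_similarity <- function(p, density = 0.6, names = TRUE) {
  W <- matrix(0, p, p)
  up <- upper.tri(W)
  w <- ifelse(stats::runif(sum(up)) < density, stats::runif(sum(up)), 0)
  W[up] <- w
  W <- W + t(W)
  if (names) dimnames(W) <- list(paste0("V", 1:p), paste0("V", 1:p))
  W
}

# quick learner-network builder for consensus tests: strengths named by pair
fake_learner_network <- function(id, strengths, orientations = NULL,
                                 provides_orientation = !is.null(orientations)) {
  keys <- names(strengths)
  ends <- do.call(rbind, strsplit(keys, "|", fixed = TRUE))
  ori <- if (is.null(orientations)) rep("undirected", length(keys)) else orientations
  structure(list(learner_id = id,
                 final_edges = edge_table(ends[, 1], ends[, 2], ori,
                                          unname(strengths)),
                 provides_orientation = provides_orientation),
            class = "learner_network")
}
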