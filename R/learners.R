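# Learner registry: structure learners plug in by id so external methods can
# be embedded without touching the pipeline (the integration point for, e.g.,
# hybrid information-theoretic learners not shipped here).

.learner_registry <- new.env(parent = emptyenv())

#' Register a structure learner
#'
#' A learner is a function `function(data, options, seed)` taking a
#' [discrete_dataset()] restricted to a subset and returning an
#' [edge_table()] over that subset's variable names.
#'
#' @param id unique learner identifier.
#' @param fn the learner function.
#' @param provides_orientation does the learner orient edges?
#' @param options default option list.
#' @param overwrite allow replacing an existing id (default `FALSE`:
#'   duplicate ids are an error).
#' @return `id`, invisibly.
#' @export
register_learner <- function(id, fn, provides_orientation = FALSE,
                             options = list(), overwrite = FALSE) {
  stopifnot(is.character(id), length(id) == 1L, is.function(fn))
  if (!overwrite && exists(id, envir = .learner_registry, inherits = FALSE)) {
    stop("learner id '", id, "' is already registered")
  }
  assign(id, list(id = id, fn = fn,
                  provides_orientation = isTRUE(provides_orientation),
                  options = options),
         envir = .learner_registry)
  invisible(id)
}

#' List registered learner ids
#' @return Character vector.
#' @export
list_learners <- function() sort(ls(.learner_registry))

get_learner <- function(id) {
  if (!exists(id, envir = .learner_registry, inherits = FALSE)) {
    stop("unknown learner '", id, "'; registered learners: ",
         paste(list_learners(), collapse = ", "))
  }
  get(id, envir = .learner_registry)
}

#' Local graph: one learner's reconstruction on one subset
#'
#' @param subset the [variable_subset()] the reconstruction ran on.
#' @param edges [edge_table()] whose endpoints are all subset members.
#' @param learner_id learner identifier.
#' @return Object of class `"local_graph"`.
#' @export
local_graph <- function(subset, edges, learner_id) {
  stopifnot(inherits(subset, "variable_subset"), is.data.frame(edges))
  members <- subset$names
  if (is.null(members)) members <- as.character(subset$indices)
  bad <- setdiff(c(edges$source, edges$target), members)
  if (length(bad)) stop("local graph has edges leaving its subset: ",
                        paste(bad, collapse = ", "))
  structure(list(subset = subset, edges = edges, learner_id = learner_id),
            class = "local_graph")
}

#' Run one learner on one variable subset
#'
#' @param learner a registered learner id, or a list
#'   `list(id = , options = )` overriding default options.
#' @param data a [discrete_dataset()] already restricted to the subset's
#'   variables (rows with missing values in these columns are dropped).
#' @param subset the originating [variable_subset()] (defaults to all of
#'   `data`'s variables).
#' @param seed integer seed, or `NULL` to draw from the current stream.
#' @return A [local_graph()].
#' @export
learn_local <- function(learner, data, subset = NULL, seed = NULL) {
  opts <- list()
  if (is.list(learner)) {
    opts <- learner$options %||% list()
    learner <- learner$id
  }
  spec <- get_learner(learner)
  options <- utils::modifyList(spec$options, opts)
  if (is.null(subset)) {
    subset <- variable_subset(seq_len(data$p), names = data$variable_names)
  }
  if (anyNA(data$values)) {
    data <- restrict_dataset(data, seq_len(data$p), drop_incomplete = TRUE)
  }
  edges <- with_local_seed(seed, spec$fn(data, options, seed = NULL))
  local_graph(subset, edges, spec$id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- ARACNE -----------------------------------------------------------------

#' ARACNE: mutual-information network with DPI pruning
#'
#' (1) computes the pairwise plug-in MI matrix; (2) keeps pairs whose MI
#' exceeds a significance threshold; (3) applies data-processing-inequality
#' pruning: in every triangle (i, j, k) of surviving edges, edge (i, j) is
#' removed when \eqn{MI_{ij} \le \min(MI_{ik}, MI_{jk}) - tol}. All triangle
#' checks use the pre-pruning graph and removals are applied simultaneously.
#' When several edges of a triangle tie as weakest (possible at tolerance 0),
#' only the lexicographically smallest pair is removed, keeping the output
#' deterministic. Edge strength is the MI; edges are undirected.
#'
#' @param data a [discrete_dataset()].
#' @param mi_threshold numeric MI cutoff, or `NULL` (default) for a
#'   permutation null: columns are permuted independently `n_perm` times and
#'   the threshold is the 95th percentile of the pooled permuted pairwise MI.
#' @param dpi_tolerance DPI slack (default 0).
#' @param n_perm permutations for the null (default 100).
#' @param log_base MI log base.
#' @param seed seed for the permutation null, or `NULL` for the current
#'   stream.
#' @return An [edge_table()] of undirected edges with MI strengths.
#' @export
aracne <- function(data, mi_threshold = NULL, dpi_tolerance = 0,
                   n_perm = 100L, log_base = 2, seed = NULL) {
  W <- mi_matrix(data, log_base = log_base)
  if (is.null(mi_threshold)) {
    mi_threshold <- with_local_seed(seed, {
      vals <- data$values
      ok <- stats::complete.cases(vals)
      vals <- vals[ok, , drop = FALSE]
      r <- lengths(data$alphabets)
      p <- ncol(vals)
      null_mi <- numeric(n_perm * p * (p - 1L) / 2L)
      pos <- 0L
      for (b in seq_len(n_perm)) {
        perm <- apply(vals, 2L, sample)
        for (i in seq_len(p - 1L)) for (j in (i + 1L):p) {
          pos <- pos + 1L
          null_mi[pos] <- mi_codes(perm[, i], r[i], perm[, j], r[j])
        }
      }
      stats::quantile(null_mi / log(log_base), 0.95, names = FALSE)
    })
  }
  aracne_from_mi(W, mi_threshold, dpi_tolerance)
}

# threshold + simultaneous DPI pruning on a precomputed MI matrix
aracne_from_mi <- function(W, mi_threshold, dpi_tolerance = 0) {
  W <- check_similarity(W)
  p <- nrow(W)
  adj <- W > mi_threshold
  diag(adj) <- FALSE
  remove <- matrix(FALSE, p, p)
  if (p >= 3L) {
    for (i in seq_len(p - 2L)) for (j in (i + 1L):(p - 1L)) for (k in (j + 1L):p) {
      if (!(adj[i, j] && adj[i, k] && adj[j, k])) next
      e <- rbind(c(i, j), c(i, k), c(j, k))
      mi <- c(W[i, j], W[i, k], W[j, k])
      weak <- vapply(1:3, function(t) mi[t] <= min(mi[-t]) - dpi_tolerance, TRUE)
      if (sum(weak) > 1L) {
        # tie: edges already in lexicographic (i,j) < (i,k) < (j,k) order
        weak[which(weak)[-1L]] <- FALSE
      }
      if (any(weak)) {
        t <- which(weak)
        remove[e[t, 1L], e[t, 2L]] <- TRUE
      }
    }
  }
  keep <- which(adj & upper.tri(adj) & !remove, arr.ind = TRUE)
  nms <- rownames(W)
  edge_table(nms[keep[, 1L]], nms[keep[, 2L]],
             orientation = "undirected",
             strength = W[keep])
}

# ---- hill climbing with the BDeu score --------------------------------------

# log BDeu family score of node v given parent set (column indices)
bde_family_score <- function(vals, r, v, parents, ess) {
  rv <- r[v]
  xv <- vals[, v]
  if (!length(parents)) {
    q <- 1L
    cfg <- rep(1L, length(xv))
  } else {
    q <- prod(r[parents])
    cfg <- rep(1L, length(xv))
    stride <- 1L
    for (pa in parents) {
      cfg <- cfg + (vals[, pa] - 1L) * stride
      stride <- stride * r[pa]
    }
  }
  njk <- tabulate((cfg - 1L) * rv + xv, nbins = q * rv)
  njk <- matrix(njk, nrow = rv, ncol = q)
  nj <- colSums(njk)
  aj <- ess / q
  ajk <- ess / (q * rv)
  obs <- nj > 0
  sum(lgamma(aj) - lgamma(aj + nj[obs])) +
    sum(lgamma(ajk + njk[, obs, drop = FALSE]) - lgamma(ajk))
}

# total decomposable BDeu score of a DAG given as a parent adjacency matrix
# (adj[u, v] = TRUE means u -> v)
bde_score <- function(vals, r, adj, ess, cache = NULL) {
  total <- 0
  for (v in seq_len(ncol(adj))) {
    total <- total + bde_family_cached(vals, r, v, which(adj[, v]), ess, cache)
  }
  total
}

bde_family_cached <- function(vals, r, v, parents, ess, cache) {
  if (is.null(cache)) return(bde_family_score(vals, r, v, parents, ess))
  key <- paste0(v, "|", paste(parents, collapse = ","))
  hit <- cache[[key]]
  if (!is.null(hit)) return(hit)
  s <- bde_family_score(vals, r, v, parents, ess)
  cache[[key]] <- s
  s
}

# is there a directed path from a to b in adj?
has_path <- function(adj, a, b) {
  if (a == b) return(TRUE)
  seen <- logical(ncol(adj))
  queue <- a
  seen[a] <- TRUE
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]
    nb <- which(adj[v, ] & !seen)
    if (b %in% nb) return(TRUE)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  FALSE
}

dag_is_acyclic <- function(adj) {
  p <- ncol(adj)
  indeg <- colSums(adj)
  active <- rep(TRUE, p)
  repeat {
    leaf <- which(active & indeg == 0L)
    if (!length(leaf)) break
    active[leaf] <- FALSE
    for (v in leaf) indeg <- indeg - adj[v, ]
  }
  !any(active)
}

#' Greedy hill climbing over DAGs with the BDeu score
#'
#' Maximizes the decomposable Bayesian Dirichlet equivalent (uniform) log
#' marginal likelihood by greedy single-edge moves (add, delete, reverse)
#' under an acyclicity constraint, stopping at a local optimum. The first
#' restart starts from the empty graph; subsequent restarts start from random
#' DAGs of expected degree 1, and the best-scoring local optimum wins. Edge
#' strength is the score drop from deleting the edge from the final DAG
#' (always > 0 at a local optimum); orientations come from the DAG. Family
#' scores are cached across moves and restarts.
#'
#' @param data a [discrete_dataset()] (complete rows; missing values must be
#'   dropped beforehand).
#' @param equivalent_sample_size BDeu prior strength (default 1).
#' @param restarts total number of starts (default 2).
#' @param max_iter cap on greedy moves per restart.
#' @param seed seed for random restarts, or `NULL` for the current stream.
#' @return An [edge_table()] of directed edges.
#' @export
hill_climb_bde <- function(data, equivalent_sample_size = 1, restarts = 2L,
                           max_iter = 200L, seed = NULL) {
  p <- data$p
  vals <- data$values
  if (anyNA(vals)) {
    vals <- vals[stats::complete.cases(vals), , drop = FALSE]
    if (!nrow(vals)) stop("no complete rows for hill climbing")
  }
  r <- lengths(data$alphabets)
  ess <- equivalent_sample_size
  cache <- new.env(parent = emptyenv())
  nms <- data$variable_names
  if (p < 2L) return(edge_table())

  climb <- function(adj) {
    fam <- vapply(seq_len(p), function(v)
      bde_family_cached(vals, r, v, which(adj[, v]), ess, cache), 0)
    for (iter in seq_len(max_iter)) {
      best <- list(delta = 1e-10, apply = NULL)
      for (u in seq_len(p)) for (v in seq_len(p)) {
        if (u == v) next
        if (!adj[u, v] && !adj[v, u]) {            # add u -> v
          if (has_path(adj, v, u)) next
          new_v <- bde_family_cached(vals, r, v, sort(c(which(adj[, v]), u)), ess, cache)
          delta <- new_v - fam[v]
          if (delta > best$delta) best <- list(delta = delta, apply = list("add", u, v, new_v))
        } else if (adj[u, v]) {
          pa_v <- which(adj[, v])
          new_v <- bde_family_cached(vals, r, v, setdiff(pa_v, u), ess, cache)
          delta <- new_v - fam[v]                  # delete u -> v
          if (delta > best$delta) best <- list(delta = delta, apply = list("del", u, v, new_v))
          adj[u, v] <- FALSE                       # reverse u -> v
          rev_ok <- !has_path(adj, u, v)
          adj[u, v] <- TRUE
          if (rev_ok) {
            new_u <- bde_family_cached(vals, r, u, sort(c(which(adj[, u]), v)), ess, cache)
            delta2 <- (new_v - fam[v]) + (new_u - fam[u])
            if (delta2 > best$delta) {
              best <- list(delta = delta2, apply = list("rev", u, v, new_v, new_u))
            }
          }
        }
      }
      if (is.null(best$apply)) break
      mv <- best$apply
      u <- mv[[2L]]; v <- mv[[3L]]
      if (mv[[1L]] == "add") {
        adj[u, v] <- TRUE; fam[v] <- mv[[4L]]
      } else if (mv[[1L]] == "del") {
        adj[u, v] <- FALSE; fam[v] <- mv[[4L]]
      } else {
        adj[u, v] <- FALSE; adj[v, u] <- TRUE
        fam[v] <- mv[[4L]]; fam[u] <- mv[[5L]]
      }
    }
    list(adj = adj, score = sum(fam))
  }

  random_start <- function() {
    ord <- sample.int(p)
    adj <- matrix(FALSE, p, p)
    prob <- min(1, 1 / (p - 1))   # expected degree ~ 1
    for (a in seq_len(p - 1L)) for (b in (a + 1L):p) {
      if (stats::runif(1) < prob) adj[ord[a], ord[b]] <- TRUE
    }
    adj
  }

  with_local_seed(seed, {
    best <- climb(matrix(FALSE, p, p))
    if (restarts > 1L) for (s in seq_len(restarts - 1L)) {
      cand <- climb(random_start())
      if (cand$score > best$score + 1e-9) best <- cand
    }
    adj <- best$adj
    idx <- which(adj, arr.ind = TRUE)
    if (!nrow(idx)) return(edge_table())
    strength <- vapply(seq_len(nrow(idx)), function(e) {
      u <- idx[e, 1L]; v <- idx[e, 2L]
      pa <- which(adj[, v])
      bde_family_cached(vals, r, v, pa, ess, cache) -
        bde_family_cached(vals, r, v, setdiff(pa, u), ess, cache)
    }, 0)
    edge_table(nms[idx[, 1L]], nms[idx[, 2L]],
               orientation = "source_to_target", strength = pmax(strength, 0))
  })
}

# ---- random classifier ------------------------------------------------------

#' Random-classifier learner
#'
#' Keeps each unordered pair independently with probability `q`, with a
#' uniform(0, 1) strength; undirected. A floor for what any structure
#' learner must beat.
#'
#' @param data a [discrete_dataset()] (only its variable names are used).
#' @param q edge inclusion probability (default 0.5).
#' @param seed seed or `NULL`.
#' @return An [edge_table()].
#' @export
random_classifier <- function(data, q = 0.5, seed = NULL) {
  nms <- data$variable_names
  p <- length(nms)
  with_local_seed(seed, {
    pairs <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
    keep <- stats::runif(nrow(pairs)) < q
    pairs <- pairs[keep, , drop = FALSE]
    edge_table(nms[pairs[, 1L]], nms[pairs[, 2L]],
               orientation = "undirected",
               strength = stats::runif(nrow(pairs)))
  })
}

# built-in learners registered at load
register_builtin_learners <- function() {
  for (id in list_learners()) rm(list = id, envir = .learner_registry)
  register_learner("aracne",
    function(data, options, seed) {
      do.call(aracne, c(list(data = data, seed = seed), options))
    },
    provides_orientation = FALSE,
    options = list(mi_threshold = NULL, dpi_tolerance = 0, n_perm = 100L))
  register_learner("hc",
    function(data, options, seed) {
      do.call(hill_climb_bde, c(list(data = data, seed = seed), options))
    },
    provides_orientation = TRUE,
    options = list(equivalent_sample_size = 1, restarts = 2L))
  register_learner("random",
    function(data, options, seed) {
      do.call(random_classifier, c(list(data = data, seed = seed), options))
    },
    provides_orientation = FALSE,
    options = list(q = 0.5))
}

.onLoad <- function(libname, pkgname) {
  register_builtin_learners()
}
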