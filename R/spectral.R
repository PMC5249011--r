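#' Plug-in mutual information between two categorical vectors
#'
#' Empirical (maximum-likelihood) mutual information
#' \eqn{\sum_{x,y} \hat p(x,y) \log [\hat p(x,y) / (\hat p(x)\hat p(y))]}.
#' Symmetric, nonnegative, and equal to the empirical entropy when the two
#' vectors are identical. Pairs with a missing value in either vector are
#' dropped before counting.
#'
#' @param x,y vectors of equal length (integer codes or factors).
#' @param log_base logarithm base; 2 (bits, default) or `exp(1)` (nats).
#' @return Nonnegative scalar.
#' @export
mutual_information <- function(x, y, log_base = 2) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- !(is.na(x) | is.na(y))
  x <- x[ok]; y <- y[ok]
  if (!length(x)) stop("no complete observation pairs")
  xi <- as.integer(factor(x))
  yi <- as.integer(factor(y))
  mi_codes(xi, max(xi), yi, max(yi)) / log(log_base)
}

# MI in nats from 1-based integer codes with known alphabet sizes (fast path)
mi_codes <- function(xi, rx, yi, ry) {
  n <- length(xi)
  joint <- tabulate((xi - 1L) * ry + yi, nbins = rx * ry)
  jm <- matrix(joint, nrow = ry, ncol = rx)
  cx <- colSums(jm)
  cy <- rowSums(jm)
  nz <- jm > 0
  px <- rep(cx, each = ry)[nz]
  py <- rep(cy, times = rx)[nz]
  pj <- jm[nz]
  sum(pj / n * log(pj * n / (px * py)))
}

#' Mutual-information similarity matrix
#'
#' Pairwise plug-in MI over all variable pairs, used as the weight matrix
#' \eqn{W} of the variable-similarity graph. The diagonal is set to zero:
#' self-similarity would only inflate vertex degrees without conveying any
#' pairwise information. Missing values are dropped pairwise.
#'
#' @param data a [discrete_dataset()].
#' @param log_base logarithm base for MI (default 2).
#' @return Symmetric nonnegative p x p matrix with zero diagonal and variable
#'   names as dimnames.
#' @export
mi_matrix <- function(data, log_base = 2) {
  stopifnot(inherits(data, "discrete_dataset"))
  p <- data$p
  vals <- data$values
  r <- lengths(data$alphabets)
  W <- matrix(0, p, p, dimnames = list(data$variable_names, data$variable_names))
  complete <- !anyNA(vals)
  for (i in seq_len(p - 1L)) {
    xi <- vals[, i]
    for (j in (i + 1L):p) {
      yj <- vals[, j]
      if (complete) {
        w <- mi_codes(xi, r[i], yj, r[j])
      } else {
        ok <- !(is.na(xi) | is.na(yj))
        if (!any(ok)) stop("variables '", data$variable_names[i], "' and '",
                           data$variable_names[j], "' share no complete pairs")
        w <- mi_codes(xi[ok], r[i], yj[ok], r[j])
      }
      W[i, j] <- W[j, i] <- w
    }
  }
  W / log(log_base)
}

check_similarity <- function(W) {
  if (!is.matrix(W) || nrow(W) != ncol(W)) stop("W must be a square matrix")
  if (any(W < -1e-12)) stop("W must be nonnegative")
  if (max(abs(W - t(W))) > 1e-8 * max(1, max(abs(W)))) stop("W must be symmetric")
  W[W < 0] <- 0
  diag(W) <- 0
  if (is.null(rownames(W))) {
    dimnames(W) <- list(paste0("V", seq_len(nrow(W))), paste0("V", seq_len(nrow(W))))
  }
  W
}

#' Random-walk normalized Laplacian of a similarity matrix
#'
#' Builds \eqn{L_{rw} = I - D^{-1} W} with \eqn{d_{ii} = \sum_j w_{ij}}.
#' Isolated vertices (zero degree) carry no random-walk dynamics and make
#' \eqn{D^{-1}} undefined; they are removed before decomposition, reported
#' via a warning, and recorded in the returned object.
#'
#' @param W symmetric nonnegative similarity matrix with zero diagonal.
#' @return Object of class `"scs_laplacian"`: `L` (rows sum to 0), `W`,
#'   `degrees`, `names`, `dropped` (names of removed isolated vertices).
#' @export
build_laplacian <- function(W) {
  W <- check_similarity(W)
  deg <- rowSums(W)
  if (all(deg == 0)) stop("graph has no edges")
  dropped <- character(0)
  if (any(deg == 0)) {
    dropped <- rownames(W)[deg == 0]
    warning("removing ", length(dropped), " isolated vertex/vertices: ",
            paste(utils::head(dropped, 5L), collapse = ", "),
            if (length(dropped) > 5L) ", ..." else "")
    keep <- deg > 0
    W <- W[keep, keep, drop = FALSE]
    deg <- deg[keep]
  }
  L <- diag(nrow(W)) - W / deg
  dimnames(L) <- dimnames(W)
  structure(list(L = L, W = W, degrees = deg, names = rownames(W),
                 dropped = dropped),
            class = "scs_laplacian")
}

#' Eigendecomposition of the random-walk Laplacian
#'
#' Solved through the symmetric form \eqn{L_{sym} = D^{-1/2} L_{rw} D^{1/2}
#' = I - D^{-1/2} W D^{-1/2}}, whose eigenvalues are real and shared with
#' \eqn{L_{rw}}; eigenvectors are mapped back as \eqn{v_{rw} = D^{-1/2}
#' v_{sym}}. Eigenvalues are returned in ascending order and lie in
#' \eqn{[0, 2]}. The sign of each eigenvector is fixed so that its entry of
#' largest absolute value is positive (signs are otherwise arbitrary and
#' solver-dependent; subset selection uses both signs anyway).
#'
#' @param lap an `"scs_laplacian"` from [build_laplacian()], or a similarity
#'   matrix (then [build_laplacian()] is applied first).
#' @return Object of class `"spectral_decomposition"`: `eigenvalues`
#'   (ascending), `vectors` (columns are eigenvectors of `L_rw`),
#'   `degrees`, `names`, `dropped`.
#' @export
eigendecompose <- function(lap) {
  if (!inherits(lap, "scs_laplacian")) lap <- build_laplacian(lap)
  d <- lap$degrees
  s <- 1 / sqrt(d)
  Lsym <- diag(length(d)) - t(lap$W * s) * s   # D^{-1/2} W D^{-1/2}
  Lsym <- (Lsym + t(Lsym)) / 2
  e <- eigen(Lsym, symmetric = TRUE)
  ord <- rev(seq_along(e$values))              # ascending
  vals <- e$values[ord]
  vals[abs(vals) < 1e-12] <- pmax(vals[abs(vals) < 1e-12], 0)
  V <- e$vectors[, ord, drop = FALSE] * s      # v_rw = D^{-1/2} v_sym
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  rownames(V) <- lap$names
  structure(list(eigenvalues = vals, vectors = V, degrees = d,
                 names = lap$names, dropped = lap$dropped),
            class = "spectral_decomposition")
}

#' @export
print.spectral_decomposition <- function(x, ...) {
  cat("Spectral decomposition of L_rw:", length(x$eigenvalues), "eigenvalues\n")
  cat("  lambda_1..5:",
      paste(signif(utils::head(x$eigenvalues, 5L), 4), collapse = ", "), "\n")
  ncomp <- sum(x$eigenvalues < 1e-9 * max(x$eigenvalues, 1))
  cat("  zero eigenvalues (connected components):", ncomp, "\n")
  invisible(x)
}

#' Number of connected components from the spectrum
#'
#' Multiplicity of the zero eigenvalue at relative tolerance `tol`.
#'
#' @param sd a `spectral_decomposition`.
#' @param tol relative tolerance (to the largest eigenvalue).
#' @return Integer count.
#' @export
n_components <- function(sd, tol = 1e-9) {
  scale <- max(sd$eigenvalues, 1)
  sum(sd$eigenvalues < tol * scale)
}

#' Normalized cut of a partition
#'
#' \eqn{Ncut(A_1,\dots,A_k) = \tfrac12 \sum_i W(A_i, \bar A_i)/vol(A_i)}
#' with \eqn{W(A,B) = \sum_{i \in A, j \in B} w_{ij}} and
#' \eqn{vol(A) = \sum_{j \in A} d_j}.
#'
#' @param blocks list of disjoint index vectors covering `1:nrow(W)`, none
#'   empty.
#' @param W similarity matrix.
#' @return Nonnegative scalar; 0 when every block is a union of connected
#'   components (or there is a single block).
#' @export
ncut <- function(blocks, W) {
  W <- check_similarity(W)
  p <- nrow(W)
  if (any(lengths(blocks) == 0L)) stop("empty block in partition")
  idx <- sort(unlist(blocks))
  if (length(idx) != p || any(idx != seq_len(p))) {
    stop("blocks must be disjoint and cover all ", p, " vertices")
  }
  deg <- rowSums(W)
  total <- 0
  for (A in blocks) {
    vol <- sum(deg[A])
    if (vol == 0) next  # a block of isolated vertices cuts nothing
    cut <- sum(W[A, setdiff(seq_len(p), A), drop = FALSE])
    total <- total + cut / vol
  }
  total / 2
}

#' Eigengap heuristic for the number of eigenvectors
#'
#' Picks k where the ascending eigenvalue sequence stops being "dissimilar
#' enough": with gaps \eqn{g_i = \lambda_{i+1} - \lambda_i} for
#' \eqn{i < k_{max}}, k is the largest index i with
#' \eqn{g_i \ge} `threshold` \eqn{\times \max_i g_i}. When all gaps are
#' within 10\% of each other no gap stands out and k falls back to `k_max`.
#'
#' @param eigenvalues ascending eigenvalues.
#' @param k_max upper bound on k.
#' @param threshold fraction of the largest gap a gap must reach (default
#'   0.5).
#' @return Integer k in `[1, k_max]`; with fewer than 3 eigenvalues, their
#'   count.
#' @export
eigengap_k <- function(eigenvalues, k_max, threshold = 0.5) {
  stopifnot(k_max >= 1)
  p <- length(eigenvalues)
  if (is.unsorted(eigenvalues, strictly = FALSE)) {
    stop("eigenvalues must be ascending")
  }
  if (p < 3L) return(min(p, k_max))
  k_max <- min(as.integer(k_max), p)
  gaps <- diff(eigenvalues)[seq_len(k_max - 1L)]
  if (!length(gaps)) return(1L)
  gmax <- max(gaps)
  if (gmax <= 0) return(k_max)
  if (min(gaps) >= 0.9 * gmax) return(k_max)  # no conspicuous gap
  max(which(gaps >= threshold * gmax))
}
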