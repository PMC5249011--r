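path3 <- function() {
  W <- matrix(0, 3, 3, dimnames = list(paste0("V", 1:3), paste0("V", 1:3)))
  W[1, 2] <- W[2, 1] <- 1
  W[2, 3] <- W[3, 2] <- 1
  W
}

test_that("mutual information matches its defining plug-in sum", {
  expect_equal(mutual_information(c(0, 1, 0, 1), c(0, 1, 0, 1)), 1.0)
  expect_equal(mutual_information(c(0, 0, 1, 1), c(7, 7, 7, 7)), 0)
  # joint counts {(0,0):3, (0,1):1, (1,0):1, (1,1):3} over n = 8
  x <- c(0, 0, 0, 0, 1, 1, 1, 1)
  y <- c(0, 0, 0, 1, 0, 1, 1, 1)
  expect_equal(mutual_information(x, y), oracle_mi(x, y))
  expect_equal(mutual_information(x, y), 0.1887219, tolerance = 1e-6)
  expect_error(mutual_information(1:3, 1:4), "equal length")
})

test_that("MI is symmetric, nonnegative, and MI(x,x) = H(x)", {
  set.seed(101)
  for (rep in 1:25) {
    n <- sample(5:60, 1)
    x <- sample(0:2, n, replace = TRUE)
    y <- sample(0:3, n, replace = TRUE)
    expect_equal(mutual_information(x, y), mutual_information(y, x))
    expect_gte(mutual_information(x, y), 0)
    px <- table(x) / n
    expect_equal(mutual_information(x, x), -sum(px * log2(px)))
  }
})

test_that("mi_matrix equals element-wise pairwise MI calls", {
  set.seed(7)
  vals <- cbind(sample(1:2, 40, TRUE), sample(1:3, 40, TRUE),
                sample(1:2, 40, TRUE))
  d <- discrete_dataset(vals, c("a", "b", "c"),
                        list(c("0", "1"), c("0", "1", "2"), c("0", "1")))
  W <- mi_matrix(d)
  expect_equal(diag(W), c(a = 0, b = 0, c = 0))
  for (i in 1:2) for (j in (i + 1):3) {
    expect_equal(W[i, j], oracle_mi(vals[, i], vals[, j]))
    expect_equal(W[i, j], W[j, i])
  }
  # duplicated columns meet at the column entropy
  d2 <- discrete_dataset(cbind(vals[, 1], vals[, 1]), c("a", "b"),
                         list(c("0", "1"), c("0", "1")))
  expect_equal(mi_matrix(d2)[1, 2],
               mutual_information(vals[, 1], vals[, 1]))
})

test_that("independent uniform columns have near-zero MI at large n", {
  set.seed(11)
  n <- 20000
  x <- sample(1:2, n, TRUE)
  y <- sample(1:2, n, TRUE)
  # small-sample bias of plug-in MI is ~ (|X|-1)(|Y|-1) / (2 n ln 2)
  expect_lt(mutual_information(x, y), 10 * 1 / (2 * n * log(2)))
})

test_that("L_rw rows sum to zero and degrees are stored", {
  lap <- build_laplacian(path3())
  expect_equal(unname(rowSums(lap$L)), rep(0, 3), tolerance = 1e-12)
  expect_equal(unname(lap$degrees), c(1, 2, 1))
  expect_error(build_laplacian(matrix(0, 3, 3)), "no edges")
})

test_that("isolated vertices are dropped with a warning, names preserved", {
  W <- make_block_similarity(c(3, 1))   # one singleton block = isolated
  expect_warning(lap <- build_laplacian(W), "isolated")
  expect_equal(lap$dropped, "B2_1")
  expect_equal(lap$names, paste0("B1_", 1:3))
})

test_that("eigendecomposition of the 3-path gives eigenvalues (0, 1, 2)", {
  sd <- eigendecompose(build_laplacian(path3()))
  expect_equal(sd$eigenvalues, c(0, 1, 2), tolerance = 1e-9)
  # residual check: L_rw v = lambda v
  lap <- build_laplacian(path3())
  for (k in 1:3) {
    expect_equal(unname(lap$L %*% sd$vectors[, k]),
                 unname(sd$eigenvalues[k] * cbind(sd$vectors[, k])),
                 tolerance = 1e-9)
  }
})

test_that("zero-eigenvalue multiplicity counts connected components", {
  W <- make_block_similarity(c(3, 3))   # two disjoint triangles
  sd <- eigendecompose(build_laplacian(W))
  expect_equal(n_components(sd), 2L)
  # the two null eigenvectors are constant on each component
  for (k in 1:2) {
    v <- sd$vectors[, k]
    expect_lt(diff(range(v[1:3])), 1e-8)
    expect_lt(diff(range(v[4:6])), 1e-8)
  }
  expect_lte(max(sd$eigenvalues), 2 + 1e-9)
})

test_that("component count and indicator structure hold on random block fixtures", {
  set.seed(202)
  for (rep in 1:30) {
    nb <- sample(2:4, 1)
    sizes <- sample(2:6, nb, replace = TRUE)
    W <- make_block_similarity(sizes, within_weight = stats::runif(1, 0.5, 2))
    # randomly shuffle vertices so blocks are not contiguous
    perm <- sample(sum(sizes))
    W <- W[perm, perm]
    sd <- eigendecompose(build_laplacian(W))
    expect_equal(n_components(sd), nb)
    block <- rep(seq_len(nb), sizes)[perm]
    for (k in seq_len(nb)) {
      v <- sd$vectors[, k]
      within_spread <- max(vapply(seq_len(nb), function(b)
        diff(range(v[block == b])), 0))
      expect_lt(within_spread, 1e-7)
    }
  }
})

test_that("eigendecompose agrees with a dense nonsymmetric eigensolver", {
  set.seed(303)
  for (rep in 1:40) {
    p <- sample(2:8, 1)
    W <- random_similarity(p, density = 0.8)
    deg <- rowSums(W)
    if (any(deg == 0)) next
    sd <- eigendecompose(build_laplacian(W))
    ora <- oracle_eigen_lrw(W)
    expect_equal(sd$eigenvalues, ora$values, tolerance = 1e-8)
    for (k in seq_len(p)) {
      a <- sd$vectors[, k]
      b <- ora$vectors[, k]
      # eigenvectors agree up to sign and scale (skip near-degenerate pairs)
      gap_ok <- all(abs(ora$values[k] - ora$values[-k]) > 1e-6)
      if (gap_ok) {
        cosang <- abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))
        expect_gt(cosang, 1 - 1e-7)
      }
    }
  }
})

test_that("ncut evaluates the normalized-cut sum", {
  W <- matrix(0, 4, 4)
  W[1, 2] <- W[2, 1] <- 1
  W[3, 4] <- W[4, 3] <- 1
  W[2, 3] <- W[3, 2] <- 1
  expect_equal(ncut(list(1:2, 3:4), W), 0.5 * (1 / 3 + 1 / 3))
  expect_equal(ncut(list(1:4), W), 0)
  # partition into connected components cuts nothing
  W2 <- make_block_similarity(c(3, 3))
  expect_equal(ncut(list(1:3, 4:6), W2), 0)
  expect_error(ncut(list(integer(0), 1:4), W), "empty block")
  expect_error(ncut(list(1:2), W), "cover")
  # random fixtures against the brute-force sum
  set.seed(404)
  for (rep in 1:20) {
    p <- sample(4:9, 1)
    Wr <- random_similarity(p)
    cut <- sample(2:(p - 1), 1)
    blocks <- list(1:cut, (cut + 1):p)
    expect_equal(ncut(blocks, Wr), oracle_ncut(blocks, Wr))
  }
})

test_that("eigengap heuristic picks the last conspicuous gap", {
  expect_equal(eigengap_k(c(0, 0, 0, 0.8, 0.85, 0.9), k_max = 5), 3)
  expect_equal(eigengap_k(seq(0, 1, length.out = 8), k_max = 5), 5)
  expect_equal(eigengap_k(c(0, 0.01, 0.5, 0.51, 0.52), k_max = 4), 2)
  expect_equal(eigengap_k(c(0, 1), k_max = 5), 2)
  expect_error(eigengap_k(c(0, 1, 0.5), k_max = 3), "ascending")
})

test_that("separator vertices sit between the two sides of the Fiedler vector", {
  # A - S - B fixture: two 4-cliques joined through a 2-vertex separator at
  # step rho = 2; scaled to [-1, 1], separator elements must lie within
  # [-1 + 2/rho, 1 - 2/rho] stretched by tolerance, and adjacent vertices
  # must differ by at most 2/rho (plus tolerance)
  p <- 10
  A <- 1:4; S <- 5:6; B <- 7:10
  W <- matrix(0, p, p)
  W[A, A] <- 1; W[B, B] <- 1
  W[A, S] <- 1; W[S, A] <- 1
  W[B, S] <- 1; W[S, B] <- 1
  diag(W) <- 0
  sd <- eigendecompose(build_laplacian(W))
  v <- sd$vectors[, 2]
  v <- 2 * (v - min(v)) / diff(range(v)) - 1   # scale to [-1, 1]
  if (mean(v[A]) < 0) v <- -v
  rho <- 2
  tol <- 0.15
  expect_true(all(v[S] >= -1 + 2 / rho - tol & v[S] <= 1 - 2 / rho + tol))
  for (i in seq_len(p)) for (j in seq_len(p)) {
    if (W[i, j] > 0) expect_lte(abs(v[i] - v[j]), 2 / rho + tol)
  }
})
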