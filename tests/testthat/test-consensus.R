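test_that("normalized ranks map decreasing strength to (0, 1]", {
  nw <- fake_learner_network("A", c("a|b" = 0.9, "c|d" = 0.5, "e|f" = 0.1))
  rk <- rank_edges(nw)
  expect_equal(unname(rk[c("a|b", "c|d", "e|f")]), c(1 / 3, 2 / 3, 1))
  # all strengths tied share the mean rank (E+1)/(2E)
  nw2 <- fake_learner_network("A", c("a|b" = 0.5, "c|d" = 0.5, "e|f" = 0.5))
  expect_equal(unname(rank_edges(nw2)), rep(4 / 6, 3))
  # a single edge ranks 1
  expect_equal(unname(rank_edges(fake_learner_network("A", c("a|b" = 2)))), 1)
})

test_that("consensus averages ranks with worst-rank imputation", {
  A <- fake_learner_network("A", c("a|b" = 0.9, "c|d" = 0.5))
  B <- fake_learner_network("B", c("a|b" = 0.7))
  cn <- scs_consensus(list(A, B), e_max = 10)
  ab <- cn$all_pairs[pair_key(cn$all_pairs) == "a|b", ]
  expect_equal(ab$consensus_score, mean(c(0.5, 1)))
  cd <- cn$all_pairs[pair_key(cn$all_pairs) == "c|d", ]
  expect_equal(cd$consensus_score, mean(c(1, 1)))   # imputed rank 1 for B
  # 3 learners, predicted only by the first at rank 0.1 -> (0.1 + 1 + 1)/3
  A3 <- fake_learner_network("A", c("a|b" = 9, "c|d" = 5, "e|f" = 4,
                                    "g|h" = 3, "i|j" = 2, "k|l" = 1,
                                    "m|n" = 0.5, "o|p" = 0.4, "q|r" = 0.3,
                                    "s|t" = 0.2))
  B3 <- fake_learner_network("B", c("c|d" = 1))
  C3 <- fake_learner_network("C", c("e|f" = 1))
  cn3 <- scs_consensus(list(A3, B3, C3), e_max = 20)
  top <- cn3$all_pairs[pair_key(cn3$all_pairs) == "a|b", ]
  expect_equal(top$consensus_score, (0.1 + 1 + 1) / 3)
})

test_that("e_max truncation keeps exactly the best-scoring pairs", {
  set.seed(61)
  strengths <- stats::setNames(stats::runif(10),
                               sprintf("e%02d|f%02d", 1:10, 1:10))
  A <- fake_learner_network("A", strengths)
  cn <- scs_consensus(list(A), e_max = 3)
  expect_equal(nrow(cn$edges), 3)
  expect_equal(cn$edges$consensus_score,
               sort(cn$all_pairs$consensus_score)[1:3])
  expect_error(scs_consensus(list(A), e_max = 0), "e_max")
})

test_that("with a single learner the consensus ordering is the strength ordering", {
  set.seed(62)
  strengths <- stats::setNames(stats::runif(8),
                               paste0("m", 1:8, "|n", 1:8))
  A <- fake_learner_network("solo", strengths)
  cn <- scs_consensus(list(A), e_max = 8)
  expect_equal(pair_key(cn$edges),
               names(sort(strengths, decreasing = TRUE)))
})

test_that("worst-rank imputation never beats an actual prediction", {
  # pair predicted by A only vs same configuration with B predicting it too
  for (rb in c(0.1, 0.5, 0.99)) {
    A <- fake_learner_network("A", c("a|b" = 0.9))
    B_with <- fake_learner_network("B", c("a|b" = 1, "x|y" = 2))
    missing_score <- scs_consensus(list(A, fake_learner_network("B", c("x|y" = 2))),
                                   e_max = 5)
    with_score <- scs_consensus(list(A, B_with), e_max = 5)
    ms <- missing_score$all_pairs
    ws <- with_score$all_pairs
    expect_gte(ms$consensus_score[pair_key(ms) == "a|b"],
               ws$consensus_score[pair_key(ws) == "a|b"])
  }
})

test_that("improving one learner's rank never worsens the consensus score", {
  set.seed(63)
  for (rep in 1:20) {
    n_edges <- sample(3:8, 1)
    keys <- paste0("p", seq_len(n_edges), "|q", seq_len(n_edges))
    sA <- stats::setNames(stats::runif(n_edges), keys)
    sB <- stats::setNames(stats::runif(n_edges), keys)
    cn1 <- scs_consensus(list(fake_learner_network("A", sA),
                              fake_learner_network("B", sB)), e_max = 99)
    target <- sample(keys, 1)
    sA2 <- sA
    sA2[target] <- max(sA) + 1   # strictly better rank for one pair
    cn2 <- scs_consensus(list(fake_learner_network("A", sA2),
                              fake_learner_network("B", sB)), e_max = 99)
    s1 <- cn1$all_pairs$consensus_score[pair_key(cn1$all_pairs) == target]
    s2 <- cn2$all_pairs$consensus_score[pair_key(cn2$all_pairs) == target]
    expect_lte(s2, s1 + 1e-12)
  }
})

test_that("consensus orientation weights upper ranks more", {
  # single orienting learner: its direction wins
  A <- fake_learner_network("A", c("a|b" = 0.9, "c|d" = 0.1),
                            orientations = c("source_to_target",
                                             "source_to_target"))
  cn <- scs_consensus(list(A), e_max = 5)
  expect_equal(cn$all_pairs$orientation[pair_key(cn$all_pairs) == "a|b"],
               "source_to_target")
  # two learners, opposite directions, identical ranks -> undirected
  B <- fake_learner_network("B", c("a|b" = 0.9, "c|d" = 0.1),
                            orientations = c("target_to_source",
                                             "target_to_source"))
  cn2 <- scs_consensus(list(A, B), e_max = 5)
  expect_true(all(cn2$all_pairs$orientation == "undirected"))
  # opposite directions at very different ranks: the better rank wins
  A2 <- fake_learner_network("A", c("a|b" = 10, "x|y" = 9, "z|w" = 1,
                                    "c|d" = 0.5),
                             orientations = c("source_to_target",
                                              "undirected", "undirected",
                                              "undirected"))
  B2 <- fake_learner_network("B", c("x|y" = 9, "z|w" = 5, "c|d" = 3,
                                    "a|b" = 0.5),
                             orientations = c("undirected", "undirected",
                                              "undirected",
                                              "target_to_source"))
  cn3 <- scs_consensus(list(A2, B2), e_max = 9)
  expect_equal(cn3$all_pairs$orientation[pair_key(cn3$all_pairs) == "a|b"],
               "source_to_target")
})

test_that("support categories partition the pre-truncation pairs", {
  A <- fake_learner_network("A", c("a|b" = 1, "c|d" = 2, "e|f" = 3))
  B <- fake_learner_network("B", c("a|b" = 1, "g|h" = 2))
  cn <- scs_consensus(list(A, B), e_max = 2)
  sc <- support_categories(cn)
  expect_equal(sum(sc), nrow(cn$all_pairs))
  expect_equal(unname(sc[c("A", "A+B", "B")]), c(2L, 1L, 1L))
  # randomized 3-learner fixtures: category counts always recount the total
  set.seed(64)
  for (rep in 1:20) {
    nets <- lapply(c("A", "B", "C"), function(id) {
      n_edges <- sample(1:12, 1)
      pool <- utils::combn(paste0("v", 1:8), 2,
                           function(z) paste(z, collapse = "|"))
      keys <- sample(pool, n_edges)
      fake_learner_network(id, stats::setNames(stats::runif(n_edges), keys))
    })
    cn <- scs_consensus(nets, e_max = 5)
    sc <- support_categories(cn)
    expect_equal(sum(sc), nrow(cn$all_pairs))
    expect_true(all(nchar(names(sc)) > 0))
    # brute-force recount per category
    all_keys <- lapply(nets, function(nw) pair_key(nw$final_edges))
    for (cat in names(sc)) {
      ids <- strsplit(cat, "+", fixed = TRUE)[[1]]
      inset <- Reduce(intersect, all_keys[match(ids, c("A", "B", "C"))])
      outset <- unlist(all_keys[-match(ids, c("A", "B", "C"))])
      expect_equal(unname(sc[cat]), length(setdiff(inset, outset)))
    }
  }
})

test_that("every retained edge has non-empty support and scores in (0, 1]", {
  set.seed(65)
  nets <- lapply(c("A", "B"), function(id) {
    keys <- paste0("e", 1:6, "|f", 1:6)
    fake_learner_network(id, stats::setNames(stats::runif(6), sample(keys)))
  })
  cn <- scs_consensus(nets, e_max = 4)
  expect_true(all(nzchar(cn$edges$support)))
  expect_true(all(cn$edges$consensus_score > 0 &
                    cn$edges$consensus_score <= 1))
  expect_equal(cn$edges$consensus_score, sort(cn$edges$consensus_score))
})
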