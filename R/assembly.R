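#' Assemble one learner's local reconstructions into a network
#'
#' Implements the every-time intersection rule: an unordered pair is retained
#' in the learner's network if and only if it was learned in *every* local
#' reconstruction whose subset contained both endpoints (and was co-included
#' at least once). The retained strength is the arithmetic mean of the local
#' strengths. For orienting learners, a strict majority among the directed
#' local predictions fixes the orientation; undirected local predictions
#' abstain, and without a strict majority the edge is set undirected.
#' Duplicate subsets contribute duplicate trials: a pair co-included by two
#' identical subsets must be learned twice.
#'
#' @param locals list of [local_graph()] objects.
#' @param subsets list of [variable_subset()] aligned one-to-one with
#'   `locals` (defaults to the subsets carried by the local graphs).
#' @param learner_id identifier (defaults to the locals' common id).
#' @param provides_orientation whether orientation votes are meaningful
#'   (defaults to the registered learner's declaration when the id is
#'   registered, else to whether any local edge is directed).
#' @return Object of class `"learner_network"`: `learner_id`, `pairs` (a
#'   data frame over every co-included pair with counts `co_included`,
#'   `learned`, vote counts and mean strength) and `final_edges` (an
#'   [edge_table()] of the retained edges).
#' @export
assemble <- function(locals, subsets = NULL, learner_id = NULL,
                     provides_orientation = NULL) {
  stopifnot(length(locals) >= 1L)
  if (is.null(subsets)) subsets <- lapply(locals, `[[`, "subset")
  if (length(subsets) != length(locals)) {
    stop("locals and subsets must align one-to-one")
  }
  if (is.null(learner_id)) {
    ids <- unique(vapply(locals, `[[`, "", "learner_id"))
    if (length(ids) != 1L) stop("locals come from different learners: ",
                                paste(ids, collapse = ", "))
    learner_id <- ids
  }
  if (is.null(provides_orientation)) {
    provides_orientation <- if (exists(learner_id, envir = .learner_registry,
                                       inherits = FALSE)) {
      get_learner(learner_id)$provides_orientation
    } else {
      any(vapply(locals, function(lg) any(lg$edges$orientation != "undirected"), TRUE))
    }
  }

  co <- new.env(parent = emptyenv())   # pair key -> record
  get_rec <- function(key) {
    rec <- co[[key]]
    if (is.null(rec)) rec <- list(co_included = 0L, learned = 0L,
                                  strengths = numeric(0),
                                  fwd = 0L, rev = 0L, undir = 0L)
    rec
  }
  for (t in seq_along(locals)) {
    lg <- locals[[t]]
    sub <- subsets[[t]]
    members <- sub$names
    if (is.null(members)) members <- as.character(sub$indices)
    bad <- setdiff(c(lg$edges$source, lg$edges$target), members)
    if (length(bad)) stop("local graph ", t, " has edges leaving its subset: ",
                          paste(bad, collapse = ", "))
    if (length(members) >= 2L) {
      cmb <- utils::combn(sort(members), 2L)
      for (c in seq_len(ncol(cmb))) {
        key <- paste(cmb[1L, c], cmb[2L, c], sep = "|")
        rec <- get_rec(key)
        rec$co_included <- rec$co_included + 1L
        co[[key]] <- rec
      }
    }
    ed <- lg$edges
    if (nrow(ed)) {
      key <- pair_key(ed)
      ori <- canonical_orientation(ed$source, ed$target, ed$orientation)
      dup <- duplicated(key)
      if (any(dup)) { ed <- ed[!dup, , drop = FALSE]; key <- key[!dup]; ori <- ori[!dup] }
      for (e in seq_along(key)) {
        rec <- get_rec(key[e])
        rec$learned <- rec$learned + 1L
        rec$strengths <- c(rec$strengths, ed$strength[e])
        rec[[switch(ori[e], source_to_target = "fwd",
                    target_to_source = "rev", "undir")]] <-
          rec[[switch(ori[e], source_to_target = "fwd",
                      target_to_source = "rev", "undir")]] + 1L
        co[[key[e]]] <- rec
      }
    }
  }

  keys <- sort(ls(co))
  if (length(keys)) {
    recs <- lapply(keys, function(k) co[[k]])
    ends <- do.call(rbind, strsplit(keys, "|", fixed = TRUE))
    pairs <- data.frame(
      source = ends[, 1L], target = ends[, 2L],
      co_included = vapply(recs, `[[`, 0L, "co_included"),
      learned = vapply(recs, `[[`, 0L, "learned"),
      votes_forward = vapply(recs, `[[`, 0L, "fwd"),
      votes_backward = vapply(recs, `[[`, 0L, "rev"),
      votes_undirected = vapply(recs, `[[`, 0L, "undir"),
      mean_strength = vapply(recs, function(r)
        if (length(r$strengths)) mean(r$strengths) else NA_real_, 0),
      stringsAsFactors = FALSE)
  } else {
    pairs <- data.frame(source = character(0), target = character(0),
                        co_included = integer(0), learned = integer(0),
                        votes_forward = integer(0), votes_backward = integer(0),
                        votes_undirected = integer(0), mean_strength = numeric(0),
                        stringsAsFactors = FALSE)
  }
  stopifnot(all(pairs$learned <= pairs$co_included))
  keep <- pairs$co_included >= 1L & pairs$learned == pairs$co_included
  kept <- pairs[keep, , drop = FALSE]
  ori <- if (provides_orientation && nrow(kept)) {
    mapply(resolve_orientation, kept$votes_forward, kept$votes_backward)
  } else rep("undirected", nrow(kept))
  final <- edge_table(kept$source, kept$target, orientation = ori,
                      strength = kept$mean_strength)
  structure(list(learner_id = learner_id, pairs = pairs, final_edges = final,
                 provides_orientation = provides_orientation),
            class = "learner_network")
}

#' Majority-rule orientation from direction votes
#'
#' Strict majority between the two directions wins; a tie, or no directed
#' votes at all, yields an undirected edge. Undirected local predictions are
#' abstentions — they never form a third candidate.
#'
#' @param votes_forward count of source-to-target votes (canonical pair
#'   order).
#' @param votes_backward count of target-to-source votes.
#' @return `"source_to_target"`, `"target_to_source"` or `"undirected"`.
#' @export
resolve_orientation <- function(votes_forward, votes_backward) {
  if (votes_forward > votes_backward) "source_to_target"
  else if (votes_backward > votes_forward) "target_to_source"
  else "undirected"
}

#' @export
print.learner_network <- function(x, ...) {
  cat("Learner network [", x$learner_id, "]: ", nrow(x$final_edges),
      " edges retained of ", nrow(x$pairs), " co-included pairs\n", sep = "")
  invisible(x)
}
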