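#' Discrete dataset of categorical observations
#'
#' Container for an n x p matrix of categorical observations, stored as
#' 1-based integer codes into per-variable category alphabets. This is the
#' input object for every stage of the spectral consensus pipeline; the
#' motivating case is binary presence/absence data (e.g. co-abundance gene
#' groups across metagenomic samples), but any discrete alphabet of size
#' >= 2 per variable is supported.
#'
#' @param values integer matrix (n samples x p variables); `values[i, j]`
#'   indexes into `alphabets[[j]]`. `NA` marks a missing observation.
#' @param variable_names character vector of p unique, non-empty names.
#' @param alphabets list of p character vectors of category labels, each of
#'   length >= 2.
#' @return An object of class `"discrete_dataset"` with fields `values`,
#'   `variable_names`, `alphabets`, `n`, `p`.
#' @export
discrete_dataset <- function(values, variable_names, alphabets) {
  values <- as.matrix(values)
  storage.mode(values) <- "integer"
  p <- ncol(values)
  n <- nrow(values)
  if (n < 1L) stop("dataset needs at least one sample")
  if (p < 2L) stop("dataset needs at least two variables")
  variable_names <- as.character(variable_names)
  if (length(variable_names) != p) stop("need one name per variable")
  if (anyDuplicated(variable_names)) {
    stop("duplicate variable names: ",
         paste(unique(variable_names[duplicated(variable_names)]), collapse = ", "))
  }
  if (any(!nzchar(variable_names))) stop("variable names must be non-empty")
  if (length(alphabets) != p) stop("need one alphabet per variable")
  for (j in seq_len(p)) {
    a <- alphabets[[j]]
    if (length(a) < 2L) stop("alphabet of variable '", variable_names[j],
                             "' has fewer than 2 categories")
    v <- values[, j]
    ok <- is.na(v) | (v >= 1L & v <= length(a))
    if (!all(ok)) stop("value out of alphabet range in variable '",
                       variable_names[j], "'")
  }
  colnames(values) <- variable_names
  structure(list(values = values, variable_names = variable_names,
                 alphabets = alphabets, n = n, p = p),
            class = "discrete_dataset")
}

#' @export
print.discrete_dataset <- function(x, ...) {
  cat("Discrete dataset:", x$n, "samples x", x$p, "variables\n")
  sizes <- lengths(x$alphabets)
  cat("  alphabet sizes:", paste(sort(unique(sizes)), collapse = ", "), "\n")
  if (anyNA(x$values)) cat("  contains missing values\n")
  invisible(x)
}

#' Restrict a dataset to a subset of variables
#'
#' @param data a [discrete_dataset()].
#' @param indices variable indices (integer) or names (character).
#' @param drop_incomplete drop rows with a missing value in any retained
#'   column. Learners require complete local data, so restriction ahead of a
#'   local reconstruction uses `TRUE`; the default keeps all rows.
#' @return A `discrete_dataset` over the selected variables.
#' @export
restrict_dataset <- function(data, indices, drop_incomplete = FALSE) {
  stopifnot(inherits(data, "discrete_dataset"))
  if (is.character(indices)) indices <- match(indices, data$variable_names)
  if (anyNA(indices)) stop("unknown variable in subset")
  vals <- data$values[, indices, drop = FALSE]
  if (drop_incomplete && anyNA(vals)) {
    vals <- vals[stats::complete.cases(vals), , drop = FALSE]
    if (nrow(vals) == 0L) stop("no complete rows left after dropping missing values")
  }
  discrete_dataset(vals, data$variable_names[indices], data$alphabets[indices])
}

#' Read a categorical data matrix from TSV/CSV
#'
#' Expects samples as rows and a header row of variable names. Tokens in each
#' column are mapped to a lexicographically sorted alphabet, so the integer
#' coding is a deterministic function of the file content.
#'
#' @param path file path.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @param missing optional token marking a missing observation; without it any
#'   token is treated as a category label.
#' @return A [discrete_dataset()]. Columns observed with a single category
#'   are kept but flagged with a warning (they are uninformative for
#'   inference); their alphabet is padded with a placeholder level so the
#'   alphabet invariant (>= 2 categories) holds.
#' @export
read_dataset <- function(path, dialect = c("tsv", "csv"), missing = NULL) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop("file has no data rows: ", path)
  fields <- strsplit(lines, sep, fixed = TRUE)
  header <- trimws(fields[[1L]])
  if (anyDuplicated(header)) {
    stop("duplicate variable name in header: ",
         paste(unique(header[duplicated(header)]), collapse = ", "))
  }
  p <- length(header)
  widths <- lengths(fields[-1L])
  if (any(widths != p)) {
    bad <- which(widths != p)[1L] + 1L
    stop("ragged row at line ", bad, ": expected ", p, " fields, got ",
         widths[bad - 1L])
  }
  tok <- matrix(trimws(unlist(fields[-1L], use.names = FALSE)),
                ncol = p, byrow = TRUE)
  if (!is.null(missing)) tok[tok == missing] <- NA_character_
  vals <- matrix(NA_integer_, nrow(tok), p)
  alphabets <- vector("list", p)
  single <- character(0)
  for (j in seq_len(p)) {
    a <- sort(unique(tok[!is.na(tok[, j]), j]))
    if (length(a) == 0L) stop("variable '", header[j], "' has no observed values")
    if (length(a) == 1L) {
      single <- c(single, header[j])
      a <- c(a, paste0(".unobserved_", a[1L]))
    }
    alphabets[[j]] <- a
    vals[, j] <- match(tok[, j], a)
  }
  if (length(single)) {
    warning("uninformative variable(s) with a single observed category: ",
            paste(single, collapse = ", "))
  }
  discrete_dataset(vals, header, alphabets)
}

# ---- edges and ground truth -------------------------------------------------

ORIENTATIONS <- c("undirected", "source_to_target", "target_to_source")

#' Build an edge table
#'
#' Edges are rows of a data frame with columns `source`, `target`,
#' `orientation` (one of `"undirected"`, `"source_to_target"`,
#' `"target_to_source"`) and `strength`. The unordered `{source, target}`
#' pair identifies an edge; orientation is an attribute of it.
#'
#' @param source,target character endpoint names (no self-loops).
#' @param orientation orientation per edge, recycled.
#' @param strength nonnegative confidence per edge, recycled.
#' @return A data frame of class `"edge_table"`.
#' @export
edge_table <- function(source = character(0), target = character(0),
                       orientation = "undirected", strength = NA_real_) {
  source <- as.character(source)
  target <- as.character(target)
  stopifnot(length(source) == length(target))
  if (length(source) && any(source == target)) stop("self-loop edge not allowed")
  orientation <- rep_len(as.character(orientation), length(source))
  if (length(source) && !all(orientation %in% ORIENTATIONS)) {
    stop("orientation must be one of: ", paste(ORIENTATIONS, collapse = ", "))
  }
  df <- data.frame(source = source, target = target,
                   orientation = orientation,
                   strength = rep_len(as.numeric(strength), length(source)),
                   stringsAsFactors = FALSE)
  class(df) <- c("edge_table", "data.frame")
  df
}

#' Canonical unordered-pair keys for an edge table
#'
#' @param edges an edge table or any data frame with `source`/`target`.
#' @return Character vector `"a|b"` with `a < b` lexicographically.
#' @export
pair_key <- function(edges) {
  if (is.data.frame(edges)) {
    paste(pmin(edges$source, edges$target), pmax(edges$source, edges$target),
          sep = "|")
  } else {
    stop("pair_key expects a data frame of edges")
  }
}

# orientation of an edge re-expressed with the canonical (sorted) pair order
canonical_orientation <- function(source, target, orientation) {
  flip <- source > target
  out <- orientation
  out[flip & orientation == "source_to_target"] <- "target_to_source"
  out[flip & orientation == "target_to_source"] <- "source_to_target"
  out
}

#' Ground-truth network
#'
#' @param nodes character vector of node names (defaults to the union of edge
#'   endpoints).
#' @param edges an [edge_table()]; duplicate unordered pairs are not allowed
#'   here (use [read_truth()] for collapsing readers).
#' @return Object of class `"network_truth"` with `nodes` and `edges`.
#' @export
network_truth <- function(edges, nodes = NULL) {
  stopifnot(is.data.frame(edges))
  if (is.null(nodes)) nodes <- sort(unique(c(edges$source, edges$target)))
  nodes <- as.character(nodes)
  unknown <- setdiff(c(edges$source, edges$target), nodes)
  if (length(unknown)) stop("edge names unknown node(s): ",
                            paste(unknown, collapse = ", "))
  if (anyDuplicated(pair_key(edges))) stop("duplicate unordered edge pair in truth")
  structure(list(nodes = nodes, edges = edges), class = "network_truth")
}

#' @export
print.network_truth <- function(x, ...) {
  cat("Network truth:", length(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  invisible(x)
}

#' Read a ground-truth edge list (TSV or SIF)
#'
#' TSV columns: source, target, optional orientation, optional score, with or
#' without a header. SIF rows are `source <relation> target...`. Duplicate
#' unordered pairs are collapsed to a single edge with a warning; when the
#' duplicates disagree on direction the collapsed edge is undirected.
#'
#' @param path file path; `.sif` extension selects the SIF reader.
#' @param nodes optional full node list; an edge naming an unknown node then
#'   raises an error.
#' @return A [network_truth()]; empty files give an empty truth.
#' @export
read_truth <- function(path, nodes = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    return(network_truth(edge_table(), nodes = if (is.null(nodes)) character(0) else nodes))
  }
  sif <- grepl("\\.sif$", path, ignore.case = TRUE)
  if (sif) {
    parts <- strsplit(lines, "[\t ]+")
    src <- vapply(parts, `[`, "", 1L)
    tgt <- vapply(parts, `[`, "", 3L)
    ori <- rep("undirected", length(src))
  } else {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    first <- parts[[1L]]
    has_header <- identical(tolower(first[1:2]), c("source", "target"))
    if (has_header) parts <- parts[-1L]
    if (!length(parts)) return(network_truth(edge_table(), nodes = if (is.null(nodes)) character(0) else nodes))
    src <- vapply(parts, `[`, "", 1L)
    tgt <- vapply(parts, `[`, "", 2L)
    ori <- vapply(parts, function(f) if (length(f) >= 3L && nzchar(f[3L])) f[3L] else "undirected", "")
    arrows <- c("->" = "source_to_target", "<-" = "target_to_source",
                "--" = "undirected")
    ori <- ifelse(ori %in% names(arrows), arrows[ori], ori)
    if (!all(ori %in% ORIENTATIONS)) stop("unknown orientation token in ", path)
  }
  keep <- src != tgt
  if (!all(keep)) warning("dropping ", sum(!keep), " self-loop edge(s)")
  edges <- edge_table(src[keep], tgt[keep], ori[keep])
  key <- pair_key(edges)
  if (anyDuplicated(key)) {
    warning("collapsing ", sum(duplicated(key)), " duplicate unordered edge pair(s)")
    can <- canonical_orientation(edges$source, edges$target, edges$orientation)
    uk <- unique(key)
    ori <- vapply(uk, function(k) {
      o <- unique(can[key == k])
      if (length(o) == 1L) o else "undirected"
    }, "", USE.NAMES = FALSE)
    ends <- do.call(rbind, strsplit(uk, "|", fixed = TRUE))
    edges <- edge_table(ends[, 1L], ends[, 2L], ori)
  }
  network_truth(edges, nodes = nodes)
}

# ---- network writers --------------------------------------------------------

#' Write a network to disk
#'
#' `edge_tsv` writes one row per edge, best score first (consensus score
#' ascending, or strength descending for learner networks), ties broken
#' lexicographically by (source, target). `graphml` encodes the orientation
#' as a per-edge `directed` attribute via igraph.
#'
#' @param net a `consensus_network`, `learner_network`, or plain edge table.
#' @param path output file path.
#' @param format `"edge_tsv"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("edge_tsv", "graphml")) {
  format <- match.arg(format)
  df <- as_edge_frame(net)
  if (format == "edge_tsv") {
    ok <- tryCatch({
      utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
      TRUE
    }, error = function(e) stop("cannot write network to ", path, ": ",
                                conditionMessage(e)))
  } else {
    g <- igraph::graph_from_data_frame(df, directed = FALSE)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

# flatten any network object into a sorted exportable data frame
as_edge_frame <- function(net) {
  if (inherits(net, "consensus_network")) {
    df <- net$edges
    ord <- order(df$consensus_score, df$source, df$target)
  } else if (inherits(net, "learner_network")) {
    df <- net$final_edges
    ord <- order(-df$strength, df$source, df$target)
  } else if (is.data.frame(net)) {
    df <- net
    ord <- if ("strength" %in% names(df) && !all(is.na(df$strength))) {
      order(-df$strength, df$source, df$target)
    } else order(df$source, df$target)
  } else stop("unsupported network object of class ", paste(class(net), collapse = "/"))
  df[ord, , drop = FALSE]
}

#' Read an edge TSV written by [write_network()]
#'
#' @param path file path.
#' @return An [edge_table()] (extra columns preserved).
#' @export
read_network <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = c(source = "character", target = "character"))
  if (nrow(df) == 0L) return(edge_table())
  if (is.null(df$orientation)) df$orientation <- "undirected"
  if (is.null(df$strength)) {
    df$strength <- if (!is.null(df$consensus_score)) df$consensus_score else NA_real_
  }
  out <- edge_table(df$source, df$target, df$orientation, df$strength)
  extra <- setdiff(names(df), names(out))
  for (nm in extra) out[[nm]] <- df[[nm]]
  out
}

#' Pipeline configuration
#'
#' Bundles the tunable parameters of a full spectral-consensus run.
#'
#' @param m subset size (number of variables per local reconstruction).
#' @param k_mode how to choose the number of eigenvectors: `"fixed"`,
#'   `"proportion"` (of p), or `"eigengap"`.
#' @param k_value integer (fixed) or fraction in (0, 1] (proportion); for
#'   `"eigengap"` it caps the search (`k_max`).
#' @param e_max number of top consensus edges retained.
#' @param learners character vector of registered learner ids.
#' @param learner_options named list (by learner id) of option lists.
#' @param seed integer root seed; all randomness in a run flows from it.
#' @param mi_log_base 2 (bits, default) or `exp(1)` (nats).
#' @return Object of class `"scs_config"`.
#' @export
scs_config <- function(m, k_mode = c("eigengap", "fixed", "proportion"),
                       k_value = NULL, e_max, learners = c("aracne", "hc"),
                       learner_options = list(), seed = 1L, mi_log_base = 2) {
  k_mode <- match.arg(k_mode)
  m <- as.integer(m)
  e_max <- as.integer(e_max)
  if (m < 2L) stop("m must be at least 2")
  if (e_max < 1L) stop("e_max must be at least 1")
  if (k_mode == "fixed" && (is.null(k_value) || k_value < 1)) {
    stop("fixed k_mode needs an integer k_value >= 1")
  }
  if (k_mode == "proportion" &&
      (is.null(k_value) || k_value <= 0 || k_value > 1)) {
    stop("proportion k_mode needs k_value in (0, 1]")
  }
  if (!mi_log_base %in% c(2, exp(1))) stop("mi_log_base must be 2 or exp(1)")
  structure(list(m = m, k_mode = k_mode, k_value = k_value, e_max = e_max,
                 learners = learners, learner_options = learner_options,
                 seed = as.integer(seed), mi_log_base = mi_log_base),
            class = "scs_config")
}

# run expr with a locally-seeded RNG, restoring the caller's RNG state;
# seed = NULL draws from the current stream (used when a root seed governs)
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}
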