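#' Cosine similarity between sample feature profiles
#'
#' `S[i, j] = <x_i, x_j> / (||x_i|| ||x_j||)`. A zero-norm row (a sample with
#' no signal anywhere in its window) gets similarity 0 to every other sample
#' and 1 to itself by convention. The result is symmetric with unit diagonal
#' and entries in `[-1, 1]`, and is invariant to positive rescaling of any
#' row.
#'
#' @param x Numeric matrix (samples x features) or a `feature_matrix`.
#' @return Symmetric n x n similarity matrix.
#' @export
cosine_similarity_matrix <- function(x) {
  if (inherits(x, "feature_matrix")) x <- x$values
  if (anyNA(x)) stop("feature matrix contains NA values")
  norms <- sqrt(rowSums(x^2))
  zero <- norms == 0
  norms[zero] <- 1
  xn <- x / norms
  s <- tcrossprod(xn)
  s[zero, ] <- 0
  s[, zero] <- 0
  diag(s) <- 1
  # guard rounding drift outside [-1, 1]
  s[s > 1] <- 1
  s[s < -1] <- -1
  (s + t(s)) / 2
}

#' Sparsify a similarity matrix to a target average degree
#'
#' Negative similarities are clipped to 0 and the diagonal zeroed (self-loops
#' are added later, inside [normalize_adjacency()]). Off-diagonal entries are
#' then thresholded at `t`, the smallest edge weight retained when keeping
#' the strongest edges down to an average degree of at least `avg_degree`;
#' ties at the threshold are all kept. With `avg_degree >= n - 1` every
#' non-negative edge survives, recovering the fully weighted network.
#'
#' @param s Symmetric similarity matrix (e.g. from
#'   [cosine_similarity_matrix()]).
#' @param avg_degree Target average degree k >= 1.
#' @return Symmetric non-negative adjacency matrix with zero diagonal.
#' @export
sparsify_adjacency <- function(s, avg_degree = 1) {
  if (avg_degree < 1) stop("avg_degree must be >= 1")
  n <- nrow(s)
  a <- s
  a[a < 0] <- 0
  diag(a) <- 0
  a <- (a + t(a)) / 2
  up <- a[upper.tri(a)]
  pos <- up[up > 0]
  # edges needed so that 2 * n_edges / n >= k
  needed <- ceiling(n * avg_degree / 2)
  if (length(pos) > needed) {
    t_thresh <- sort(pos, decreasing = TRUE)[needed]
    a[a < t_thresh] <- 0
  }
  a
}

#' Symmetric self-loop normalization of an adjacency matrix
#'
#' The spectral graph-convolution normalization: with `A~ = A + I` and
#' `D~ = diag(rowSums(A~))`, returns `A^ = D~^(-1/2) A~ D~^(-1/2)`. The
#' result is symmetric with spectrum in `(-1, 1]`; an isolated node gets
#' `A^[i, i] = 1`.
#'
#' @param a Symmetric non-negative adjacency matrix with zero diagonal.
#' @return Normalized adjacency of the same dimension.
#' @export
normalize_adjacency <- function(a) {
  if (nrow(a) != ncol(a)) stop("adjacency must be square")
  if (any(a < 0)) stop("adjacency must be non-negative")
  at <- a + diag(nrow(a))
  dinv <- 1 / sqrt(rowSums(at))
  ah <- at * tcrossprod(dinv)
  (ah + t(ah)) / 2
}

#' Build the per-view sample similarity graph
#'
#' Convenience wrapper chaining [cosine_similarity_matrix()],
#' [sparsify_adjacency()], an edge-weight rescaling, and
#' [normalize_adjacency()]. Deterministic: the same feature matrix always
#' yields a bit-identical normalized adjacency.
#'
#' The two graph parameters encode one principle: neighborhood quality over
#' neighborhood size. `avg_degree` keeps only the strongest cosine edges —
#' in a small cell-line panel a sample has very few genuinely informative
#' partners (same gene, shared regulatory state), so the default keeps about
#' one edge per node. `edge_scale` multiplies the surviving edge weights
#' before the self-loop normalization, setting the balance between a node's
#' own signal and its neighbors' in the convolution: at the default 0.1 the
#' aggregation is a mild relational smoothing rather than an averaging that
#' washes out the per-sample magnitudes the expression target depends on.
#'
#' @param fm A `feature_matrix` (or plain numeric matrix).
#' @param avg_degree Target average degree for sparsification (default 1).
#'   Use `avg_degree >= n - 1` for the dense, fully weighted network.
#' @param edge_scale Multiplier applied to the sparsified edge weights
#'   before normalization (default 0.1; 1 leaves the cosine weights as-is).
#' @return An object of class `"similarity_graph"`: list with `weights`
#'   (cosine matrix), `adjacency` (sparsified, unscaled), `norm_adjacency`
#'   (from the scaled adjacency), `sample_ids`, `avg_degree`, `edge_scale`.
#' @export
build_similarity_graph <- function(fm, avg_degree = 1, edge_scale = 0.1) {
  if (edge_scale <= 0) stop("edge_scale must be positive")
  sample_ids <- if (inherits(fm, "feature_matrix")) fm$sample_ids else rownames(fm)
  s <- cosine_similarity_matrix(fm)
  a <- sparsify_adjacency(s, avg_degree)
  structure(list(weights = s, adjacency = a,
                 norm_adjacency = normalize_adjacency(a * edge_scale),
                 sample_ids = sample_ids, avg_degree = avg_degree,
                 edge_scale = edge_scale),
            class = "similarity_graph")
}

#' @export
print.similarity_graph <- function(x, ...) {
  n <- nrow(x$adjacency)
  ne <- sum(x$adjacency[upper.tri(x$adjacency)] > 0)
  cat("Sample similarity graph:", n, "nodes,", ne, "edges",
      sprintf("(mean degree %.1f)\n", 2 * ne / n))
  invisible(x)
}

#' Write / read a similarity graph as an edge-list TSV
#'
#' Edges `(i, j, weight)` of the sparsified adjacency, upper triangle only,
#' with sample ids as a leading commented index block.
#'
#' @param graph A `similarity_graph`.
#' @param path Output path.
#' @return `path` invisibly (writer); a `similarity_graph` (reader).
#' @export
write_similarity_graph <- function(graph, path) {
  con <- file(path, "w")
  on.exit(close(con))
  ids <- graph$sample_ids
  if (is.null(ids)) ids <- as.character(seq_len(nrow(graph$adjacency)))
  writeLines(c(sprintf("# n=%d avg_degree=%s", nrow(graph$adjacency),
                       format_bp(graph$avg_degree)),
               paste0("# sample ", seq_along(ids), " ", ids)), con)
  idx <- which(upper.tri(graph$adjacency) & graph$adjacency > 0, arr.ind = TRUE)
  writeLines("i\tj\tweight", con)
  if (nrow(idx) > 0L) {
    writeLines(sprintf("%d\t%d\t%s", idx[, 1L], idx[, 2L],
                       format_signal(graph$adjacency[idx])), con)
  }
  invisible(path)
}

#' @rdname write_similarity_graph
#' @export
read_similarity_graph <- function(path) {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#")]
  n <- as.integer(sub("^# n=(\\d+).*", "\\1", meta[1L]))
  k <- as.numeric(sub(".*avg_degree=([0-9.]+).*", "\\1", meta[1L]))
  ids <- sub("^# sample \\d+ ", "", meta[-1L])
  body <- lines[!startsWith(lines, "#")]
  a <- matrix(0, n, n)
  if (length(body) > 1L) {
    tab <- utils::read.delim(text = body, stringsAsFactors = FALSE)
    a[cbind(tab$i, tab$j)] <- tab$weight
    a[cbind(tab$j, tab$i)] <- tab$weight
  }
  structure(list(weights = NULL, adjacency = a,
                 norm_adjacency = normalize_adjacency(a),
                 sample_ids = if (length(ids)) ids else NULL, avg_degree = k,
                 edge_scale = 1),
            class = "similarity_graph")
}
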