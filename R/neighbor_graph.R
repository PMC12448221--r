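## CDR3-constrained Hamming neighbor graphs driving the contrastive loss.

#' Hamming distance between two equal-length sequences
#'
#' Gap characters from pre-aligned input count as ordinary symbols unless
#' `ignore_gap_gap` is set, in which case columns that are gaps in both
#' sequences are skipped.
#'
#' @param a,b character scalars of equal length.
#' @param ignore_gap_gap skip columns where both sequences have `-`.
#' @return Integer count of mismatching positions.
#' @export
hamming <- function(a, b, ignore_gap_gap = FALSE) {
  ra <- charToRaw(a)
  rb <- charToRaw(b)
  if (length(ra) != length(rb)) {
    stop("hamming: sequences have different lengths (", length(ra), " vs ",
         length(rb), "); group/align sequences first")
  }
  if (ignore_gap_gap) {
    gap <- charToRaw("-")
    keep <- !(ra == gap & rb == gap)
    ra <- ra[keep]
    rb <- rb[keep]
  }
  sum(ra != rb)
}

## Integer code matrix (N x L) for equal-length sequences.
seq_code_matrix <- function(seqs) {
  if (!length(seqs)) return(matrix(integer(0), 0, 0))
  L <- unique(nchar(seqs))
  if (length(L) != 1L) {
    stop("sequences must all have the same length (found lengths ",
         paste(sort(L), collapse = ", "), ")")
  }
  if (L == 0L) return(matrix(integer(0), length(seqs), 0))
  m <- matrix(utf8ToInt(paste(seqs, collapse = "")), ncol = L, byrow = TRUE)
  m
}

## All-pairs Hamming distance matrix via sparse one-hot cross-products.
## Exact; O(N^2 L / word) through BLAS rather than an R-level double loop.
hamming_matrix <- function(seqs, seqs2 = NULL) {
  codes <- seq_code_matrix(seqs)
  n <- length(seqs)
  if (is.null(seqs2)) {
    if (!n) return(matrix(0, 0, 0))
    L <- ncol(codes)
    if (L == 0L) return(matrix(0, n, n))
    sym <- sort(unique(as.vector(codes)))
    X <- Matrix::sparseMatrix(
      i = rep(seq_len(n), L),
      j = (as.vector(col(codes)) - 1L) * length(sym) +
        match(as.vector(codes), sym),
      x = 1, dims = c(n, L * length(sym)))
    L - as.matrix(Matrix::tcrossprod(X))
  } else {
    codes2 <- seq_code_matrix(seqs2)
    if (ncol(codes) != ncol(codes2)) {
      stop("sequence sets have different lengths")
    }
    L <- ncol(codes)
    if (L == 0L) return(matrix(0, n, length(seqs2)))
    sym <- sort(unique(c(as.vector(codes), as.vector(codes2))))
    onehot <- function(cm) {
      Matrix::sparseMatrix(
        i = rep(seq_len(nrow(cm)), ncol(cm)),
        j = (as.vector(col(cm)) - 1L) * length(sym) +
          match(as.vector(cm), sym),
        x = 1, dims = c(nrow(cm), L * length(sym)))
    }
    L - as.matrix(Matrix::tcrossprod(onehot(codes), onehot(codes2)))
  }
}

graph_sequences <- function(table) {
  full <- full_sequences(table)
  cdr3s <- list()
  if (any(nzchar(table$hcdr3))) cdr3s$hcdr3 <- table$hcdr3
  if (any(nzchar(table$lcdr3))) cdr3s$lcdr3 <- table$lcdr3
  for (nm in names(cdr3s)) {
    if (any(!nzchar(cdr3s[[nm]]))) {
      stop("column ", nm, " is non-empty for some records but empty for ",
           "others within the group")
    }
    if (length(unique(nchar(cdr3s[[nm]]))) != 1L) {
      stop("unequal ", nm, " lengths within a group; regroup first")
    }
  }
  list(full = full, cdr3s = cdr3s)
}

#' Build the neighbor graph of a length-homogeneous sequence group
#'
#' Two sequences are neighbors iff their full-sequence Hamming distance is
#' at most `full_cutoff` AND the Hamming distance within each non-empty
#' CDR3 is at most `cdr3_cutoff` (both bounds inclusive; defaults 5 and 2).
#' The relation is symmetric with no self-loops.
#'
#' @param table a [seq_table()] group from [group_by_length()] (all primary
#'   chains and CDR3s equal length).
#' @param full_cutoff inclusive Hamming cutoff on the full sequence.
#' @param cdr3_cutoff inclusive Hamming cutoff within the CDR3 region.
#' @return A `neighbor_graph`: list with `neighbors` (per-sequence sorted
#'   integer index lists), `counts`, `kept` (all `TRUE` before filtering),
#'   `ids`, and the cutoffs.
#' @export
build_graph <- function(table, full_cutoff = 5L, cdr3_cutoff = 2L) {
  stopifnot(inherits(table, "seq_table"))
  gs <- graph_sequences(table)
  n <- nrow(table)
  ok <- hamming_matrix(gs$full) <= full_cutoff
  for (cd in gs$cdr3s) {
    ok <- ok & (hamming_matrix(cd) <= cdr3_cutoff)
  }
  diag(ok) <- FALSE
  neighbors <- lapply(seq_len(n), function(i) which(ok[i, ]))
  structure(list(neighbors = neighbors,
                 counts = lengths(neighbors),
                 kept = rep(TRUE, n),
                 ids = table$id,
                 full_cutoff = as.integer(full_cutoff),
                 cdr3_cutoff = as.integer(cdr3_cutoff),
                 min_neighbors = NA_integer_),
            class = "neighbor_graph")
}

#' @export
print.neighbor_graph <- function(x, ...) {
  cat(sprintf(paste0("neighbor_graph: %d sequence(s), cutoffs full<=%d ",
                     "cdr3<=%d, mean neighbors %.2f, kept %d\n"),
              length(x$neighbors), x$full_cutoff, x$cdr3_cutoff,
              mean(x$counts), sum(x$kept)))
  invisible(x)
}

#' Choose the Hamming cutoff achieving a target mean neighbor count
#'
#' Scans `full_cutoff = 1, 2, ...,` up to `c_max` and returns the smallest
#' cutoff whose graph (with `cdr3_cutoff = min(ceiling(0.4 * c), c)`,
#' preserving the default 2/5 ratio) reaches a mean neighbor count of at
#' least `target_mean_neighbors`. For large groups the mean is estimated on
#' a uniform subsample of anchor sequences (neighbors still counted against
#' the whole group).
#'
#' @param table a length-homogeneous [seq_table()] group.
#' @param target_mean_neighbors required average neighbor count (>= 1);
#'   values of 5-10 give stable maps.
#' @param c_max largest cutoff scanned; if even `c_max` misses the target
#'   it is returned with a warning.
#' @param subsample_above estimate the mean on a subsample when the group
#'   exceeds this size.
#' @param subsample_size number of anchor sequences in the subsample.
#' @return `c(full_cutoff, cdr3_cutoff)` (integer).
#' @export
adaptive_cutoff <- function(table, target_mean_neighbors, c_max = 15L,
                            subsample_above = 3000L, subsample_size = 1000L) {
  stopifnot(target_mean_neighbors >= 1)
  gs <- graph_sequences(table)
  n <- nrow(table)
  anchors <- seq_len(n)
  if (n > subsample_above) {
    anchors <- sort(sample.int(n, subsample_size))
  }
  dfull <- hamming_matrix(gs$full[anchors], gs$full)
  dcdr3 <- lapply(gs$cdr3s, function(cd) {
    hamming_matrix(cd[anchors], cd)
  })
  self <- cbind(seq_along(anchors), anchors)
  for (cutoff in seq_len(c_max)) {
    c3 <- min(ceiling(0.4 * cutoff), cutoff)
    ok <- dfull <= cutoff
    for (dc in dcdr3) ok <- ok & (dc <= c3)
    ok[self] <- FALSE
    if (mean(rowSums(ok)) >= target_mean_neighbors) {
      return(c(full_cutoff = cutoff, cdr3_cutoff = c3))
    }
  }
  warning("no cutoff <= ", c_max, " reaches a mean of ",
          target_mean_neighbors, " neighbors; returning c_max")
  c(full_cutoff = as.integer(c_max),
    cdr3_cutoff = min(ceiling(0.4 * c_max), c_max))
}

#' Exclude sequences with too few neighbors
#'
#' Sequences with fewer than `min_neighbors` neighbors are excluded from
#' training (they have hard-to-place positions and act as background
#' noise). A single pass by default; with `iterate = TRUE` the filter is
#' repeated until no further sequence drops below the threshold.
#'
#' @param graph a [build_graph()] result.
#' @param min_neighbors minimum neighbor count to keep a sequence.
#' @param iterate repeat the filter to a fixed point.
#' @return The graph with `kept` updated and neighbor lists/counts
#'   restricted to kept sequences.
#' @export
filter_min_neighbors <- function(graph, min_neighbors = 5L, iterate = FALSE) {
  stopifnot(inherits(graph, "neighbor_graph"))
  kept <- graph$kept
  counts <- graph$counts
  repeat {
    drop <- kept & (counts < min_neighbors)
    if (!any(drop)) break
    kept[drop] <- FALSE
    keep_idx <- which(kept)
    counts <- integer(length(kept))
    counts[keep_idx] <- vapply(graph$neighbors[keep_idx], function(nb) {
      sum(kept[nb])
    }, integer(1L))
    if (!iterate) {
      ## one recount pass: lists restricted to kept, but no re-dropping
      break
    }
  }
  if (!any(kept)) {
    stop("all sequences excluded by the min-neighbor filter; relax the ",
         "Hamming cutoffs or lower min_neighbors")
  }
  graph$neighbors <- lapply(seq_along(graph$neighbors), function(i) {
    if (!kept[i]) return(integer(0))
    nb <- graph$neighbors[[i]]
    nb[kept[nb]]
  })
  graph$counts <- lengths(graph$neighbors)
  graph$kept <- kept
  graph$min_neighbors <- as.integer(min_neighbors)
  graph
}

#' Log-neighbor sampling weights
#'
#' The training sampler draws sequences with probability proportional to
#' the natural logarithm of their neighbor count, prioritizing sequences in
#' dense regions.
#'
#' @param graph a filtered [neighbor_graph] (all kept counts >= 2 so
#'   weights are positive).
#' @return Numeric vector of positive weights for kept sequences (named by
#'   id); normalized to probabilities by the sampler.
#' @export
sampling_weights <- function(graph) {
  stopifnot(inherits(graph, "neighbor_graph"))
  counts <- graph$counts[graph$kept]
  if (any(counts < 2L)) {
    stop("sampling_weights: some kept sequences have < 2 neighbors ",
         "(weight would be <= 0); filter with min_neighbors >= 2 first")
  }
  setNames(log(counts), graph$ids[graph$kept])
}

#' Export a neighbor graph as an edge list
#'
#' Writes a two-column TSV of undirected edges (`id_i`, `id_j`, i < j) plus
#' a JSON sidecar (`<path>.json`) with the cutoffs and per-sequence counts.
#'
#' @param graph a [neighbor_graph].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(graph, path) {
  stopifnot(inherits(graph, "neighbor_graph"))
  edges <- do.call(rbind, lapply(seq_along(graph$neighbors), function(i) {
    nb <- graph$neighbors[[i]]
    nb <- nb[nb > i]
    if (!length(nb)) return(NULL)
    cbind(i, nb)
  }))
  df <- if (is.null(edges)) {
    data.frame(id_i = character(0), id_j = character(0))
  } else {
    data.frame(id_i = graph$ids[edges[, 1L]], id_j = graph$ids[edges[, 2L]])
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(full_cutoff = graph$full_cutoff, cdr3_cutoff = graph$cdr3_cutoff,
         min_neighbors = graph$min_neighbors,
         counts = setNames(as.list(graph$counts), graph$ids),
         kept = setNames(as.list(graph$kept), graph$ids)),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
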