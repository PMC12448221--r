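## Leiden clustering on the 2D map and CDR3-feature refinement.

#' Leiden clustering of 2D map coordinates
#'
#' Builds the undirected union of the directed k-nearest-neighbor graph on
#' Euclidean distances (unit edge weights) and runs Leiden modularity
#' optimization.
#'
#' @param coords `N x 2` coordinate matrix.
#' @param k_neighbors neighbors per point for the kNN graph (20 is a good
#'   map-scale default; 10 for sparser maps).
#' @param resolution Leiden resolution parameter.
#' @param seed RNG seed (Leiden refinement is stochastic).
#' @param n_iterations Leiden iterations.
#' @return Integer vector of cluster labels, contiguous from 0, with
#'   attribute `"method"` recording the hyperparameters.
#' @export
leiden_on_map <- function(coords, k_neighbors = 20L, resolution = 1.0,
                          seed = 1L, n_iterations = 5L) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  stopifnot(k_neighbors >= 1L)
  if (n <= k_neighbors) {
    stop("need more points (", n, ") than k_neighbors (", k_neighbors, ")")
  }
  d <- as.matrix(stats::dist(coords))
  diag(d) <- Inf
  ## directed kNN -> undirected union
  nn <- t(apply(d, 1L, function(r) order(r)[seq_len(k_neighbors)]))
  edges <- cbind(rep(seq_len(n), k_neighbors), as.vector(nn))
  edges <- t(apply(edges, 1L, sort))
  edges <- unique(edges)
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  set.seed(seed)
  comm <- igraph::cluster_leiden(g, objective_function = "modularity",
                                 resolution = resolution,
                                 n_iterations = n_iterations)
  labels <- as.integer(igraph::membership(comm)) - 1L
  structure(labels, method = list(algorithm = "leiden",
                                  k_neighbors = k_neighbors,
                                  resolution = resolution, seed = seed))
}

## 6-class physicochemical reduction of the amino-acid alphabet
GENERALIZE_MAP <- local({
  m <- c(setNames(rep("+", 3L), c("K", "R", "H")),
         setNames(rep("-", 2L), c("D", "E")),
         setNames(rep("a", 3L), c("F", "W", "Y")),
         setNames(rep("h", 6L), c("A", "V", "L", "I", "M", "C")),
         setNames(rep("p", 4L), c("S", "T", "N", "Q")),
         setNames(rep("s", 2L), c("G", "P")))
  m
})

#' Rewrite a CDR3 in a reduced physicochemical alphabet
#'
#' Six residue classes: positive `K,R,H` to `+`; negative `D,E` to `-`;
#' aromatic `F,W,Y` to `a`; aliphatic/hydrophobic `A,V,L,I,M,C` to `h`;
#' polar `S,T,N,Q` to `p`; special `G,P` to `s`. Anything else maps to
#' `x`. Length-preserving and idempotent on its own output alphabet.
#'
#' @param cdr3 amino-acid CDR3 string(s).
#' @return Generalized string(s) of the same length.
#' @export
generalize_cdr3 <- function(cdr3) {
  classes <- c("+", "-", "a", "h", "p", "s", "x")
  vapply(cdr3, function(s) {
    if (!nzchar(s)) return("")
    ## case is significant: upper-case = residues, lower-case = class
    ## symbols (so the map is idempotent on its own output)
    chars <- strsplit(s, "")[[1]]
    out <- GENERALIZE_MAP[chars]
    keep <- chars %in% classes
    out[keep] <- chars[keep]
    out[is.na(out)] <- "x"
    paste(out, collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

## overlapping k-mer counts over a set of strings (shared k-mer vocabulary)
kmer_counts <- function(strings, k = 3L) {
  kmers_of <- function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    substring(s, seq_len(n - k + 1L), seq.int(k, n))
  }
  lst <- lapply(strings, kmers_of)
  vocab <- sort(unique(unlist(lst)))
  mat <- matrix(0L, length(strings), length(vocab),
                dimnames = list(NULL, vocab))
  for (i in seq_along(lst)) {
    if (!length(lst[[i]])) next
    tab <- table(lst[[i]])
    mat[i, names(tab)] <- as.integer(tab)
  }
  mat
}

#' 2D feature embedding of CDR3 sequences
#'
#' Generalizes the CDR3s to the 6-class physicochemical alphabet, counts
#' overlapping k-mers, and reduces the count matrix with PCA to a 2D
#' representation (component signs fixed for determinism). CDR3s shorter
#' than `k` get zero-vector features with a warning.
#'
#' @param cdr3s amino-acid CDR3 strings (non-empty).
#' @param k k-mer length.
#' @param pca_dims number of PCA components retained before taking the
#'   leading two as coordinates (capped at the matrix rank).
#' @param seed kept for interface stability; the reduction is
#'   deterministic.
#' @return List of class `cdr3_features`: `generalized`, `kmer_matrix`,
#'   `embedding2d` (`N x 2`).
#' @export
cdr3_embedding <- function(cdr3s, k = 3L, pca_dims = 10L, seed = 1L) {
  if (any(!nzchar(cdr3s))) stop("all CDR3s must be non-empty")
  gen <- generalize_cdr3(cdr3s)
  if (any(nchar(gen) < k)) {
    warning(sum(nchar(gen) < k), " CDR3(s) shorter than k=", k,
            " get zero-vector features")
  }
  km <- kmer_counts(gen, k)
  if (!ncol(km)) {
    emb <- matrix(0, length(cdr3s), 2L)
  } else {
    ctr <- scale(km, center = TRUE, scale = FALSE)
    ncomp <- min(pca_dims, nrow(km) - 1L, ncol(km))
    pc <- prcomp(ctr, center = FALSE, rank. = max(2L, ncomp))
    ## fix component signs: largest-|loading| entry positive
    for (j in seq_len(ncol(pc$rotation))) {
      piv <- which.max(abs(pc$rotation[, j]))
      if (pc$rotation[piv, j] < 0) {
        pc$rotation[, j] <- -pc$rotation[, j]
        pc$x[, j] <- -pc$x[, j]
      }
    }
    emb <- pc$x[, seq_len(min(2L, ncol(pc$x))), drop = FALSE]
    if (ncol(emb) < 2L) emb <- cbind(emb, 0)
  }
  structure(list(generalized = gen, kmer_matrix = km,
                 embedding2d = unname(emb)),
            class = "cdr3_features")
}

#' Attach post-hoc projected points to existing map clusters
#'
#' Each query point takes the cluster label of its nearest clustered map
#' point, provided it lies within `radius_factor` times the median
#' k-th-neighbor distance of the clustered points; farther points stay
#' `-1` (unclustered).
#'
#' @param query `M x 2` coordinates of projected points.
#' @param coords `N x 2` coordinates of clustered points.
#' @param labels integer cluster labels of `coords`.
#' @param k neighbor rank used for the radius scale.
#' @param radius_factor multiplier on the median k-th-neighbor distance.
#' @return Integer labels for the query points (`-1` = unattached).
#' @export
attach_to_clusters <- function(query, coords, labels, k = 20L,
                               radius_factor = 2) {
  query <- as.matrix(query)
  coords <- as.matrix(coords)
  stopifnot(nrow(coords) == length(labels))
  d <- as.matrix(dist(coords))
  diag(d) <- Inf
  kk <- min(k, nrow(coords) - 1L)
  dk <- apply(d, 1L, function(r) sort(r, partial = kk)[kk])
  radius <- radius_factor * stats::median(dk)
  cross <- outer(rowSums(query^2), rowSums(coords^2), "+") -
    2 * tcrossprod(query, coords)
  cross[cross < 0] <- 0
  nearest <- max.col(-cross, ties.method = "first")
  dmin <- sqrt(cross[cbind(seq_len(nrow(query)), nearest)])
  out <- ifelse(dmin <= radius, as.integer(labels[nearest]), -1L)
  as.integer(out)
}

## standardize an embedding to zero centroid and unit RMS radius
standardize_embedding <- function(x) {
  x <- as.matrix(x)
  x <- sweep(x, 2L, colMeans(x))
  r <- sqrt(mean(rowSums(x^2)))
  if (r > 0) x / r else x
}

#' Refine map cluster labels with CDR3 features
#'
#' Standardizes the primary 2D map and the CDR3 feature embedding to unit
#' root-mean-square radius and sums them (`primary + cdr3_weight * cdr3`),
#' then re-runs Leiden on the combined coordinates. With `edge_only =
#' TRUE`, only ambiguous sequences — those whose map neighborhood does not
#' reach `ambiguity_threshold` agreement with their own label — change
#' labels; they are reassigned to the dominant original label among their
#' unambiguous neighbors in the combined embedding.
#'
#' @param map2d `N x 2` primary map coordinates (or an [ab_map]).
#' @param cdr3_features a [cdr3_embedding()] result (or an `N x 2` matrix).
#' @param cdr3_weight relative weight of the CDR3 embedding (>= 0; 0
#'   reproduces the unrefined clustering).
#' @param k_neighbors,resolution,seed passed to [leiden_on_map()].
#' @param edge_only re-label only ambiguous sequences.
#' @param ambiguity_threshold minimum fraction of same-label map neighbors
#'   for a sequence to count as unambiguous.
#' @return Integer cluster labels (see [leiden_on_map()]).
#' @export
refine_labels <- function(map2d, cdr3_features, cdr3_weight = 0.3,
                          k_neighbors = 20L, resolution = 1.0, seed = 1L,
                          edge_only = FALSE, ambiguity_threshold = 0.6) {
  if (cdr3_weight < 0) stop("cdr3_weight must be >= 0")
  coords <- if (inherits(map2d, "ab_map")) map2d$coords else as.matrix(map2d)
  cemb <- if (inherits(cdr3_features, "cdr3_features")) {
    cdr3_features$embedding2d
  } else {
    as.matrix(cdr3_features)
  }
  stopifnot(nrow(coords) == nrow(cemb))
  base_labels <- leiden_on_map(coords, k_neighbors, resolution, seed)
  if (cdr3_weight == 0) return(base_labels)
  combined <- standardize_embedding(coords) +
    cdr3_weight * standardize_embedding(cemb)
  refined <- leiden_on_map(combined, k_neighbors, resolution, seed)
  if (!edge_only) return(refined)

  d <- as.matrix(stats::dist(coords))
  diag(d) <- Inf
  n <- nrow(coords)
  ambiguous <- vapply(seq_len(n), function(i) {
    nb <- order(d[i, ])[seq_len(k_neighbors)]
    mean(base_labels[nb] == base_labels[i]) < ambiguity_threshold
  }, logical(1L))
  out <- base_labels
  if (any(ambiguous)) {
    dc <- as.matrix(stats::dist(combined))
    diag(dc) <- Inf
    anchors <- which(!ambiguous)
    for (i in which(ambiguous)) {
      if (!length(anchors)) break
      nb <- anchors[order(dc[i, anchors])][seq_len(min(k_neighbors,
                                                       length(anchors)))]
      tab <- sort(table(base_labels[nb]), decreasing = TRUE)
      out[i] <- as.integer(names(tab)[1L])
    }
  }
  attributes(out) <- attributes(base_labels)
  out
}
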