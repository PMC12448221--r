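## Benchmark metrics: pairwise P/R/F1, cluster-type fractions, per-cluster
## edit distance and label entropy, enrichment homogeneity, and the
## seed-distance correlation used to judge global structure preservation.

norm_labels <- function(x) {
  x <- as.character(x)
  if (anyNA(x)) stop("labels contain NA")
  x
}

## unclustered marker: inferred label -1 (or "-1") is treated as a
## per-sequence singleton and never as a cluster of its own
expand_unclustered <- function(labels) {
  un <- labels == "-1"
  labels[un] <- paste0("__single", seq_len(sum(un)))
  labels
}

#' Pairwise precision / recall / F1 of a clustering against ground truth
#'
#' Every unordered pair of non-noise sequences is classified: TP if
#' clustered together in both the inferred and true labelings, FP if
#' together only in the inferred one, FN if together only in the true one,
#' TN otherwise. Inferred label `-1` means "unclustered" and is treated as
#' a singleton. Zero denominators yield 0 with a warning.
#'
#' @param true_labels,inferred_labels aligned label vectors.
#' @param noise_mask logical; `TRUE` marks noise sequences excluded from
#'   the evaluation.
#' @return List with `tp`, `fp`, `fn`, `tn`, `precision`, `recall`, `f1`.
#' @export
pairwise_prf <- function(true_labels, inferred_labels,
                         noise_mask = rep(FALSE, length(true_labels))) {
  if (length(true_labels) != length(inferred_labels) ||
      length(true_labels) != length(noise_mask)) {
    stop("label vectors and noise mask must have equal length")
  }
  keep <- !noise_mask
  tl <- norm_labels(true_labels[keep])
  il <- expand_unclustered(norm_labels(inferred_labels[keep]))
  n <- length(tl)
  ct <- table(tl, il)
  pairs2 <- function(x) sum(choose(x, 2))
  tp <- pairs2(as.vector(ct))
  fp <- pairs2(colSums(ct)) - tp
  fn <- pairs2(rowSums(ct)) - tp
  tn <- choose(n, 2) - tp - fp - fn
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning("zero denominator for ", what, "; reporting 0")
      return(0)
    }
    num / den
  }
  precision <- safe_div(tp, tp + fp, "precision")
  recall <- safe_div(tp, tp + fn, "recall")
  f1 <- if (precision + recall == 0) 0 else {
    2 * precision * recall / (precision + recall)
  }
  list(tp = tp, fp = fp, fn = fn, tn = tn,
       precision = precision, recall = recall, f1 = f1)
}

#' Classify inferred clusters into true-inferred / mix / noise fractions
#'
#' A cluster is *true-inferred* (TIC) when it reconstructs at least
#' `tic_threshold` (default 80%) of some true family's members; *noise*
#' when it contains only noise sequences; *mix* otherwise. Each cluster is
#' counted once (its best-covered family decides). Sequences with inferred
#' label `-1` are unclustered and do not form clusters.
#'
#' @inheritParams pairwise_prf
#' @param tic_threshold fraction of a family that a cluster must hold.
#' @param require_purity additionally require that the cluster's non-noise
#'   members all come from that family (off by default).
#' @return List with `tic_fraction`, `mix_fraction`, `noise_fraction`
#'   (summing to 1 over clusters), the per-cluster `types`, and
#'   `n_clusters`.
#' @export
cluster_type_fractions <- function(true_labels, inferred_labels,
                                   noise_mask = rep(FALSE,
                                                    length(true_labels)),
                                   tic_threshold = 0.8,
                                   require_purity = FALSE) {
  tl <- norm_labels(true_labels)
  il <- norm_labels(inferred_labels)
  if (length(tl) != length(il) || length(tl) != length(noise_mask)) {
    stop("label vectors and noise mask must have equal length")
  }
  clusters <- setdiff(unique(il), "-1")
  if (!length(clusters)) stop("empty clustering: no clusters to classify")
  fam_sizes <- table(tl[!noise_mask])
  types <- vapply(clusters, function(cl) {
    in_cl <- il == cl
    if (all(noise_mask[in_cl])) return("noise")
    cov <- table(tl[in_cl & !noise_mask])
    frac <- as.numeric(cov) / as.numeric(fam_sizes[names(cov)])
    best <- which.max(frac)
    is_tic <- frac[best] >= tic_threshold
    if (require_purity && is_tic) {
      is_tic <- sum(cov) == cov[best]
    }
    if (is_tic) "tic" else "mix"
  }, character(1L))
  list(tic_fraction = mean(types == "tic"),
       mix_fraction = mean(types == "mix"),
       noise_fraction = mean(types == "noise"),
       types = setNames(types, clusters),
       n_clusters = length(clusters))
}

#' Mean pairwise Hamming distance within each cluster
#'
#' @param table a [seq_table()] (members of one cluster must share a
#'   sequence length).
#' @param labels cluster labels aligned with `table`; label `-1` is
#'   skipped.
#' @return Named numeric vector of per-cluster means (singletons give 0).
#' @export
intra_cluster_edit_distance <- function(table, labels) {
  stopifnot(inherits(table, "seq_table"), nrow(table) == length(labels))
  labels <- norm_labels(labels)
  seqs <- full_sequences(table)
  clusters <- setdiff(unique(labels), "-1")
  out <- vapply(clusters, function(cl) {
    s <- seqs[labels == cl]
    if (length(s) < 2L) return(0)
    if (length(unique(nchar(s))) != 1L) {
      stop("cluster ", cl, " mixes sequence lengths")
    }
    d <- hamming_matrix(s)
    mean(d[upper.tri(d)])
  }, numeric(1L))
  setNames(out, clusters)
}

#' Shannon entropy (bits) of a categorical label within each cluster
#'
#' @param cluster_labels cluster assignment per sequence.
#' @param categorical_label the label whose mixing is measured (e.g. FACS
#'   bin).
#' @return Named numeric vector: `H = -sum p log2 p` per cluster.
#' @export
label_entropy <- function(cluster_labels, categorical_label) {
  stopifnot(length(cluster_labels) == length(categorical_label))
  cl <- norm_labels(cluster_labels)
  vapply(split(as.character(categorical_label), cl), function(v) {
    p <- table(v) / length(v)
    -sum(p * log2(p))
  }, numeric(1L))
}

#' Per-cluster homogeneity of enrichment classes
#'
#' The fraction of the cluster taken by its dominant class; ties return
#' the tied maximum fraction (noted via the `"ties"` attribute).
#'
#' @param cluster_labels cluster assignment per sequence.
#' @param enrichment_classes class per sequence (e.g. enriched / depleted /
#'   unclear).
#' @return Named numeric vector in (0, 1].
#' @export
homogeneity <- function(cluster_labels, enrichment_classes) {
  stopifnot(length(cluster_labels) == length(enrichment_classes))
  cl <- norm_labels(cluster_labels)
  tied <- character(0)
  out <- vapply(split(as.character(enrichment_classes), cl), function(v) {
    tab <- table(v)
    if (sum(tab == max(tab)) > 1L) tied <<- c(tied, v[1L])
    max(tab) / length(v)
  }, numeric(1L))
  groups <- names(out)
  ties <- vapply(split(as.character(enrichment_classes), cl), function(v) {
    tab <- table(v)
    sum(tab == max(tab)) > 1L
  }, logical(1L))
  attr(out, "ties") <- groups[ties]
  out
}

#' Correlation between edit distance from a seed and map distance
#'
#' Pearson (default) correlation between each sequence's Hamming distance
#' to a seed sequence and the Euclidean distance of its map position to the
#' seed's position — the global-structure preservation score of a map.
#'
#' @param coords `N x 2` matrix of map coordinates.
#' @param sequences character vector of N equal-length sequences.
#' @param seed_sequence the seed; must be one of `sequences` (its
#'   coordinates are taken from the matching row) unless `seed_coords` is
#'   given.
#' @param seed_coords optional length-2 coordinates of the seed.
#' @param method `"pearson"` or `"spearman"`.
#' @return The correlation; `NA` with a warning if either variable has
#'   zero variance.
#' @export
seed_distance_correlation <- function(coords, sequences, seed_sequence,
                                      seed_coords = NULL,
                                      method = c("pearson", "spearman")) {
  method <- match.arg(method)
  coords <- as.matrix(coords)
  stopifnot(nrow(coords) == length(sequences), ncol(coords) == 2L)
  if (is.null(seed_coords)) {
    i <- match(seed_sequence, sequences)
    if (is.na(i)) stop("seed sequence not found; supply seed_coords")
    seed_coords <- coords[i, ]
  }
  edit <- vapply(sequences, hamming, integer(1L), b = seed_sequence,
                 USE.NAMES = FALSE)
  eucl <- sqrt((coords[, 1L] - seed_coords[1L])^2 +
               (coords[, 2L] - seed_coords[2L])^2)
  if (stats::sd(edit) == 0 || stats::sd(eucl) == 0) {
    warning("zero variance; correlation undefined")
    return(NA_real_)
  }
  cor(edit, eucl, method = method)
}
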