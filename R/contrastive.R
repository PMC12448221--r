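## Contrastive 2D projection: Cauchy similarities on squared Euclidean
## distances between anchors and sampled neighbors, masked repulsion of
## non-neighbors, optional fitted kernel transform, three-stage training.

#' Loss configuration for the contrastive projection
#'
#' @param epsilon small positive constant added to squared distances for
#'   numerical stability.
#' @param min_dist kernel target scale: distances below it should keep
#'   similarity ~1 (used by [fit_kernel()]).
#' @param use_kernel transform squared distances as `a * dsq^b` before the
#'   Cauchy similarity; `kernel_a`/`kernel_b` are fitted on demand when
#'   `NULL`.
#' @param kernel_a,kernel_b fitted kernel coefficients (both > 0).
#' @param normalize_by_counts divide each row's positive term by its
#'   in-batch neighbor count and its negative term by its in-batch
#'   non-neighbor count.
#' @param pos_sum_in_log use the aggregate positive term
#'   `-log(sum_i phi_(i,i+N))` instead of the per-row default
#'   `-log phi_(i,i+N)`.
#' @return List of class `loss_config`.
#' @export
loss_config <- function(epsilon = 1e-6, min_dist = 1.0, use_kernel = FALSE,
                        kernel_a = NULL, kernel_b = NULL,
                        normalize_by_counts = FALSE,
                        pos_sum_in_log = FALSE) {
  stopifnot(epsilon > 0, min_dist > 0)
  if (use_kernel) {
    if (is.null(kernel_a) || is.null(kernel_b)) {
      ab <- fit_kernel(min_dist)
      kernel_a <- ab[["a"]]
      kernel_b <- ab[["b"]]
    }
    stopifnot(kernel_a > 0, kernel_b > 0)
  }
  structure(list(epsilon = epsilon, min_dist = min_dist,
                 use_kernel = use_kernel, kernel_a = kernel_a,
                 kernel_b = kernel_b,
                 normalize_by_counts = normalize_by_counts,
                 pos_sum_in_log = pos_sum_in_log),
            class = "loss_config")
}

#' Three-stage training schedule
#'
#' Stage 1 trains the encoder and the linear transform on the contrastive
#' loss in the transform's d-dimensional output; stage 2 freezes them and
#' trains only the 2-unit projection head; stage 3 unfreezes everything.
#'
#' @param stage1_epochs,stage2_epochs,stage3_epochs epochs per stage
#'   (defaults 400/100/400; scale down for desk-size runs).
#' @param batch_size anchors per batch (clamped to the number of kept
#'   sequences).
#' @param lr1,lr2,lr3 Adam learning rates per stage.
#' @param seed RNG seed controlling sampling and head initialization.
#' @return List of class `training_schedule`.
#' @export
training_schedule <- function(stage1_epochs = 400L, stage2_epochs = 100L,
                              stage3_epochs = 400L, batch_size = 256L,
                              lr1 = 1e-3, lr2 = 1e-3, lr3 = 1e-4,
                              seed = 1L) {
  stopifnot(stage1_epochs >= 0L, stage2_epochs >= 0L, stage3_epochs >= 0L)
  structure(list(stage1_epochs = as.integer(stage1_epochs),
                 stage2_epochs = as.integer(stage2_epochs),
                 stage3_epochs = as.integer(stage3_epochs),
                 batch_size = as.integer(batch_size),
                 lr = c(lr1, lr2, lr3), seed = as.integer(seed)),
            class = "training_schedule")
}

#' Pairwise squared Euclidean distances with a stability constant
#'
#' @param E,F `N x d` embedding matrices (anchors and sampled neighbors).
#' @param epsilon constant added to every squared distance.
#' @return List with `d11` (`E` vs `E`) and `d12` (`E` vs `F`), both
#'   `N x N`.
#' @export
pairwise_sq_dists <- function(E, F, epsilon = 1e-6) {
  E <- as.matrix(E)
  F <- as.matrix(F)
  stopifnot(ncol(E) == ncol(F), epsilon > 0 || epsilon == 0)
  if (!all(is.finite(E)) || !all(is.finite(F))) {
    stop("non-finite embeddings")
  }
  sq <- function(A, B) {
    d <- outer(rowSums(A * A), rowSums(B * B), "+") - 2 * tcrossprod(A, B)
    pmax(d, 0)
  }
  list(d11 = sq(E, E) + epsilon, d12 = sq(E, F) + epsilon)
}

#' Cauchy similarity of squared distances
#'
#' @param dsq non-negative squared-distance matrix.
#' @return `1 / (1 + dsq)`, entrywise in (0, 1].
#' @export
cauchy_similarity <- function(dsq) {
  stopifnot(all(dsq >= 0))
  1 / (1 + dsq)
}

#' Fit the distance-kernel coefficients for a given min_dist
#'
#' The target assigns similarity 1 to distances below `min_dist` and decays
#' as `exp(-(x - min_dist))` beyond it; the model `1 / (1 + a * x^(2b))` is
#' least-squares fitted to the target on a grid, subject to the plateau
#' constraint that the fitted similarity stays at or above `plateau_floor`
#' for all distances below `min_dist` (the model is monotone decreasing, so
#' the constraint binds at `min_dist` itself: `a * min_dist^(2b) <=
#' 1/plateau_floor - 1`, enforced by reparametrization). An unconstrained
#' fit sacrifices the plateau — the kernel's purpose — to chase the
#' exponential tail.
#'
#' @param min_dist threshold below which similarities should stay ~1.
#' @param x_max upper end of the fitting grid (default `3 * min_dist`).
#' @param n_grid grid points.
#' @param plateau_floor lowest similarity tolerated below `min_dist`.
#' @return Named vector `c(a, b)`, both positive.
#' @export
fit_kernel <- function(min_dist = 1.0, x_max = 3 * min_dist,
                       n_grid = 300L, plateau_floor = 0.9) {
  stopifnot(min_dist > 0, plateau_floor > 0, plateau_floor < 1)
  x <- seq(1e-3, x_max, length.out = n_grid)
  target <- ifelse(x < min_dist, 1, exp(-(x - min_dist)))
  a_max <- function(b) (1 / plateau_floor - 1) / min_dist^(2 * b)
  obj <- function(par) {
    b <- exp(par[2L])
    a <- stats::plogis(par[1L]) * a_max(b)
    sum((1 / (1 + a * x^(2 * b)) - target)^2)
  }
  fit <- optim(c(2, 0), obj, method = "Nelder-Mead",
               control = list(maxit = 4000L, reltol = 1e-12))
  baseline <- sum((1 / (1 + x^2) - target)^2)
  if (!is.finite(fit$value) || fit$value > baseline + 1e-9) {
    stop("kernel fit failed: residual ", fit$value, " vs baseline ",
         baseline)
  }
  b <- exp(fit$par[2L])
  c(a = stats::plogis(fit$par[1L]) * a_max(b), b = b)
}

#' Apply the fitted kernel transform to squared distances
#'
#' @param dsq squared-distance matrix.
#' @param a,b positive kernel coefficients from [fit_kernel()].
#' @return `a * dsq^b`, elementwise.
#' @export
apply_kernel <- function(dsq, a, b) {
  stopifnot(a > 0, b > 0)
  a * dsq^b
}

#' Batch pairing of anchors with sampled neighbors
#'
#' For each sampled anchor, draws one neighbor uniformly from its list.
#'
#' @param graph a filtered [neighbor_graph].
#' @param indices anchor sequence indices (into the graph).
#' @return List of class `batch_pairing` with `indices` and
#'   `partner_indices`.
#' @export
sample_batch_pairing <- function(graph, indices) {
  partners <- vapply(indices, function(i) {
    nb <- graph$neighbors[[i]]
    if (!length(nb)) stop("sequence ", i, " has no neighbors; filter first")
    resample(nb, 1L)
  }, integer(1L))
  structure(list(indices = indices, partner_indices = partners),
            class = "batch_pairing")
}

#' Build the repulsion mask for a batch
#'
#' `M[i, j] = 0` when column `j` (anchor block for `j <= N`, partner block
#' for `j > N`) refers to sequence `i` itself or to one of its neighbors —
#' including `i`'s own sampled partner, a neighbor by construction; `1`
#' otherwise, so repulsion only acts between non-neighbors.
#'
#' @param batch a [sample_batch_pairing()] result.
#' @param graph the [neighbor_graph] the pairing was drawn from.
#' @return Binary `N x 2N` matrix.
#' @export
build_mask <- function(batch, graph) {
  idx <- batch$indices
  n <- length(idx)
  colseq <- c(idx, batch$partner_indices)
  M <- matrix(1, n, 2L * n)
  for (i in seq_len(n)) {
    excluded <- c(idx[i], graph$neighbors[[idx[i]]])
    M[i, colseq %in% excluded] <- 0
  }
  M
}

## in-batch neighbor counts (for normalize_by_counts)
batch_neighbor_counts <- function(batch, graph) {
  idx <- batch$indices
  colseq <- c(idx, batch$partner_indices)
  vapply(seq_along(idx), function(i) {
    sum(colseq %in% graph$neighbors[[idx[i]]])
  }, numeric(1L))
}

#' Contrastive loss of a batch (with optional analytic gradient)
#'
#' Positive term `-log phi_(i, i+N)` pulls each anchor toward its sampled
#' neighbor; negative term `log sum_j M_ij phi_ij` repels it from masked-in
#' non-neighbors; the loss is the mean of their per-row sums. Rows whose
#' repulsion set is empty contribute a zero negative term (warned).
#'
#' @param E,F `N x d` anchor and partner embeddings.
#' @param M binary `N x 2N` mask from [build_mask()].
#' @param config a [loss_config()].
#' @param n_neighbors optional per-row in-batch neighbor counts (needed
#'   when `normalize_by_counts`).
#' @param with_grad also return `dE`, `dF`.
#' @return List with `loss`, per-row `l_pos`, `l_neg`, and (optionally)
#'   gradients `dE`, `dF`.
#' @export
contrastive_loss <- function(E, F, M, config = loss_config(),
                             n_neighbors = NULL, with_grad = FALSE) {
  E <- as.matrix(E)
  F <- as.matrix(F)
  n <- nrow(E)
  stopifnot(nrow(F) == n, nrow(M) == n, ncol(M) == 2L * n)
  dd <- pairwise_sq_dists(E, F, config$epsilon)
  dsq <- cbind(dd$d11, dd$d12)
  tm <- if (config$use_kernel) {
    apply_kernel(dsq, config$kernel_a, config$kernel_b)
  } else {
    dsq
  }
  phi <- cauchy_similarity(tm)

  pos_idx <- cbind(seq_len(n), n + seq_len(n))
  ppos <- phi[pos_idx]
  S <- rowSums(M * phi)
  empty <- S == 0
  if (any(empty)) {
    warning(sum(empty), " row(s) with an empty repulsion set; their ",
            "negative term is 0")
  }
  l_neg <- ifelse(empty, 0, log(pmax(S, .Machine$double.xmin)))

  w_pos <- rep(1, n)
  w_neg <- rep(1, n)
  if (config$normalize_by_counts) {
    if (is.null(n_neighbors)) {
      stop("normalize_by_counts requires n_neighbors")
    }
    w_pos <- 1 / pmax(n_neighbors, 1)
    w_neg <- 1 / pmax(rowSums(M), 1)
  }

  if (config$pos_sum_in_log) {
    l_pos <- rep(-log(sum(ppos)), n)
    loss <- -log(sum(ppos)) + mean(w_neg * l_neg)
  } else {
    l_pos <- -log(ppos)
    loss <- mean(w_pos * l_pos + w_neg * l_neg)
  }
  out <- list(loss = loss, l_pos = l_pos, l_neg = l_neg)
  if (!with_grad) return(out)

  ## dloss/dphi
  dphi <- (w_neg / pmax(S, .Machine$double.xmin)) * M / n
  dphi[empty, ] <- 0
  if (config$pos_sum_in_log) {
    dphi[pos_idx] <- dphi[pos_idx] - 1 / sum(ppos)
  } else {
    dphi[pos_idx] <- dphi[pos_idx] - w_pos / (n * ppos)
  }
  dtm <- -dphi * phi * phi
  ddsq <- if (config$use_kernel) {
    dtm * config$kernel_a * config$kernel_b *
      dsq^(config$kernel_b - 1)
  } else {
    dtm
  }
  G11 <- ddsq[, seq_len(n), drop = FALSE]
  G12 <- ddsq[, n + seq_len(n), drop = FALSE]
  out$dE <- 2 * ((rowSums(G11) + colSums(G11) + rowSums(G12)) * E -
                   (G11 + t(G11)) %*% E - G12 %*% F)
  out$dF <- 2 * (colSums(G12) * F - crossprod(G12, E))
  out
}
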