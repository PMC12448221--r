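test_that("pairwise squared distances match the naive loop with the epsilon offset", {
  ## single zero vector: both matrices equal epsilon
  z <- matrix(0, 1L, 3L)
  dd <- pairwise_sq_dists(z, z, epsilon = 1e-6)
  expect_equal(dd$d11, matrix(1e-6, 1L, 1L))
  expect_equal(dd$d12, matrix(1e-6, 1L, 1L))

  ## 3-4-5 triangle
  E <- rbind(c(0, 0), c(3, 4))
  dd2 <- pairwise_sq_dists(E, E, epsilon = 0)
  expect_equal(dd2$d11[1L, 2L], 25)

  ## random matrices vs a double loop
  set.seed(13)
  E <- matrix(rnorm(18), 6L, 3L)
  Fm <- matrix(rnorm(18), 6L, 3L)
  dd3 <- pairwise_sq_dists(E, Fm, epsilon = 1e-6)
  for (i in 1:6) {
    for (j in 1:6) {
      expect_equal(dd3$d11[i, j], sum((E[i, ] - E[j, ])^2) + 1e-6,
                   tolerance = 1e-12)
      expect_equal(dd3$d12[i, j], sum((E[i, ] - Fm[j, ])^2) + 1e-6,
                   tolerance = 1e-12)
    }
  }
  expect_error(pairwise_sq_dists(matrix(NaN, 1, 2), matrix(0, 1, 2)),
               "non-finite")
})

test_that("cauchy similarity and the kernel transform follow their closed forms", {
  expect_equal(cauchy_similarity(matrix(0)), matrix(1))
  expect_equal(cauchy_similarity(matrix(1)), matrix(0.5))
  set.seed(14)
  m <- matrix(rexp(20), 4L, 5L)
  expect_equal(cauchy_similarity(m), 1 / (1 + m), tolerance = 1e-15)

  expect_equal(apply_kernel(m, 1, 1), m)
  expect_equal(apply_kernel(matrix(4), 2, 0.5), matrix(4))
  a <- 1.7
  b <- 0.8
  expect_equal(apply_kernel(m, a, b), a * m^b, tolerance = 1e-12)
})

test_that("fitted kernel keeps similarity ~1 below min_dist and decays monotonically", {
  for (md in c(0.5, 1.0, 2.0)) {
    ab <- fit_kernel(md)
    expect_true(all(ab > 0))
    x <- seq(1e-3, 10 * md, length.out = 400L)
    sim <- 1 / (1 + ab[["a"]] * x^(2 * ab[["b"]]))
    expect_gte(min(sim[x < md]), 0.9)
    expect_true(all(diff(sim) <= 1e-12))
    ## the fit beats the (a, b) = (1, 1) baseline
    target <- ifelse(x < md, 1, exp(-(x - md)))
    expect_lte(sum((sim - target)^2), sum((1 / (1 + x^2) - target)^2))
  }
})

test_that("the repulsion mask zeroes self, partner, and neighbor columns", {
  graph <- structure(list(
    neighbors = list(2L, 1L, 4L, 3L, integer(0)),
    counts = c(1L, 1L, 1L, 1L, 0L), kept = rep(TRUE, 5L),
    ids = letters[1:5], full_cutoff = 5L, cdr3_cutoff = 2L,
    min_neighbors = NA_integer_), class = "neighbor_graph")

  ## mutually non-neighboring anchors: zeros only at self and own partner
  batch <- structure(list(indices = c(1L, 3L),
                          partner_indices = c(2L, 4L)),
                     class = "batch_pairing")
  M <- build_mask(batch, graph)
  expect_equal(M, rbind(c(0, 1, 0, 1), c(1, 0, 1, 0)))

  ## fully connected clique: all-zero mask
  clique <- structure(list(
    neighbors = list(2:3, c(1L, 3L), 1:2), counts = rep(2L, 3L),
    kept = rep(TRUE, 3L), ids = c("x", "y", "z"), full_cutoff = 5L,
    cdr3_cutoff = 2L, min_neighbors = NA_integer_),
    class = "neighbor_graph")
  b2 <- structure(list(indices = 1:3, partner_indices = c(2L, 3L, 1L)),
                  class = "batch_pairing")
  expect_true(all(build_mask(b2, clique) == 0))

  ## random graphs: per-entry rule oracle
  set.seed(15)
  for (rep in 1:5) {
    n <- 6L
    adj <- matrix(runif(n * n) < 0.4, n, n)
    adj <- adj | t(adj)
    diag(adj) <- FALSE
    g <- structure(list(neighbors = lapply(seq_len(n), function(i) {
      which(adj[i, ])
    }), counts = rowSums(adj), kept = rep(TRUE, n), ids = as.character(1:n),
    full_cutoff = 5L, cdr3_cutoff = 2L, min_neighbors = NA_integer_),
    class = "neighbor_graph")
    anchors <- sample.int(n, 4L)
    partners <- vapply(anchors, function(i) {
      nb <- which(adj[i, ])
      if (length(nb)) nb[sample.int(length(nb), 1L)] else i
    }, integer(1L))
    bt <- structure(list(indices = anchors, partner_indices = partners),
                    class = "batch_pairing")
    M3 <- build_mask(bt, g)
    colseq <- c(anchors, partners)
    for (i in seq_along(anchors)) {
      for (j in seq_along(colseq)) {
        expected <- !(colseq[j] == anchors[i] ||
                        adj[anchors[i], colseq[j]])
        expect_equal(M3[i, j] == 1, expected)
      }
    }
  }
})

test_that("contrastive loss matches a hand evaluation on a 2-sequence batch", {
  ## embeddings chosen so every phi is hand-computable
  E <- rbind(c(0, 0), c(2, 0))
  Fm <- rbind(c(1, 0), c(2, 1))
  M <- rbind(c(0, 1, 0, 1), c(1, 0, 1, 0))
  cfg <- loss_config(epsilon = 0.5)
  got <- contrastive_loss(E, Fm, M, cfg)
  phi <- function(dsq) 1 / (1 + dsq + 0.5)
  l_pos <- c(-log(phi(1)), -log(phi(1)))
  l_neg <- c(log(phi(4) + phi(5)), log(phi(4) + phi(1)))
  expect_equal(got$l_pos, l_pos, tolerance = 1e-12)
  expect_equal(got$l_neg, l_neg, tolerance = 1e-12)
  expect_equal(got$loss, mean(l_pos + l_neg), tolerance = 1e-12)

  ## partner at the anchor, epsilon -> 0: positive loss -> 0
  cfg0 <- loss_config(epsilon = 1e-12)
  same <- suppressWarnings(contrastive_loss(rbind(c(1, 1)), rbind(c(1, 1)),
                                            matrix(c(0, 0), 1L), cfg0))
  expect_equal(same$l_pos[1L], 0, tolerance = 1e-10)

  ## doubling coordinates increases distances: negative term shrinks
  set.seed(16)
  E2 <- matrix(rnorm(8L), 4L)
  F2 <- E2 + matrix(rnorm(8L, sd = 0.1), 4L)
  M2 <- matrix(1, 4L, 8L)
  M2[cbind(1:4, 1:4)] <- 0
  M2[cbind(1:4, 5:8)] <- 0
  l1 <- contrastive_loss(E2, F2, M2, loss_config())
  l2 <- contrastive_loss(2 * E2, 2 * F2, M2, loss_config())
  expect_true(all(l2$l_neg < l1$l_neg))
})

test_that("loss is invariant to translation and rotation of all embeddings", {
  set.seed(17)
  n <- 5L
  E <- matrix(rnorm(n * 2L), n)
  Fm <- matrix(rnorm(n * 2L), n)
  M <- matrix(rbinom(n * 2L * n, 1L, 0.5), n)
  M[cbind(1:n, 1:n)] <- 0
  M[cbind(1:n, n + 1:n)] <- 0
  base <- contrastive_loss(E, Fm, M, loss_config())$loss
  shift <- matrix(c(3, -7), n, 2L, byrow = TRUE)
  expect_equal(contrastive_loss(E + shift, Fm + shift, M,
                                loss_config())$loss, base,
               tolerance = 1e-10)
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  expect_equal(contrastive_loss(E %*% R, Fm %*% R, M, loss_config())$loss,
               base, tolerance = 1e-10)
})

test_that("empty repulsion rows contribute zero negative loss with a warning", {
  E <- rbind(c(0, 0), c(1, 0))
  Fm <- rbind(c(0, 1), c(1, 1))
  M <- matrix(0, 2L, 4L)
  expect_warning(out <- contrastive_loss(E, Fm, M, loss_config()),
                 "empty repulsion")
  expect_equal(out$l_neg, c(0, 0))
})

test_that("analytic loss gradients match finite differences in every config", {
  set.seed(18)
  n <- 4L
  d <- 3L
  E <- matrix(rnorm(n * d), n)
  Fm <- matrix(rnorm(n * d), n)
  M <- matrix(rbinom(n * 2L * n, 1L, 0.6), n)
  M[cbind(1:n, 1:n)] <- 0
  M[cbind(1:n, n + 1:n)] <- 0
  nnb <- sample(1:3, n, replace = TRUE)
  h <- 1e-6
  for (cfg in list(loss_config(), loss_config(use_kernel = TRUE),
                   loss_config(normalize_by_counts = TRUE),
                   loss_config(pos_sum_in_log = TRUE))) {
    cl <- contrastive_loss(E, Fm, M, cfg, nnb, with_grad = TRUE)
    for (i in sample(seq_along(E), 5L)) {
      E1 <- E
      E1[i] <- E1[i] + h
      E2 <- E
      E2[i] <- E2[i] - h
      fd <- (contrastive_loss(E1, Fm, M, cfg, nnb)$loss -
               contrastive_loss(E2, Fm, M, cfg, nnb)$loss) / (2 * h)
      expect_equal(cl$dE[i], fd, tolerance = 1e-4)
    }
    for (i in sample(seq_along(Fm), 5L)) {
      F1 <- Fm
      F1[i] <- F1[i] + h
      F2 <- Fm
      F2[i] <- F2[i] - h
      fd <- (contrastive_loss(E, F1, M, cfg, nnb)$loss -
               contrastive_loss(E, F2, M, cfg, nnb)$loss) / (2 * h)
      expect_equal(cl$dF[i], fd, tolerance = 1e-4)
    }
  }
})

test_that("train_map honours zero-epoch schedules deterministically and separates lineages", {
  tab <- simulate_lineages(n_lineages = 2L, lineage_size_range = c(30L, 40L),
                           seq_lengths = 20L, cdr3_lengths = 5L,
                           n_noise = 0L, alphabet = "amino_acid", seed = 41L)
  tab <- deduplicate(tab)
  gr <- filter_min_neighbors(build_graph(tab, 5L, 2L), 3L)
  cfg <- encoder_config(embed_dim = 16L, n_layers = 1L, n_heads = 2L,
                        hidden_dim = 24L, max_len = 32L, seed = 9L)
  enc <- pretrain_mlm(tab, cfg, epochs = 1L, batch_size = 32L)

  ## zero epochs: coordinates equal the untrained head output, reproducibly
  sch0 <- training_schedule(0L, 0L, 0L, batch_size = 16L, seed = 2L)
  m1 <- train_map(tab, gr, enc, sch0)
  m2 <- train_map(tab, gr, enc, sch0)
  expect_identical(m1$coords, m2$coords)
  expect_equal(dim(m1$coords), c(sum(gr$kept), 2L))

  ## short training separates two well-separated lineages
  sch <- suppressWarnings(training_schedule(8L, 8L, 8L, batch_size = 64L,
                                            seed = 2L))
  m3 <- suppressWarnings(train_map(tab, gr, enc, sch))
  lin <- tab$lineage_id[m3$kept_idx]
  co <- m3$coords
  dmat <- as.matrix(dist(co))
  same <- outer(lin, lin, "==")
  diag(same) <- NA
  expect_gt(mean(dmat[!same & !is.na(same)]),
            mean(dmat[same & !is.na(same)]))

  ## same seed twice: identical coordinates
  m4 <- suppressWarnings(train_map(tab, gr, enc, sch))
  expect_identical(m3$coords, m4$coords)

  ## predict() reproduces training coordinates
  pred <- predict(m3, abmapr:::full_sequences(tab)[m3$kept_idx])
  expect_equal(pred, m3$coords, tolerance = 1e-12)
})
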