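## Shared fixtures, built in code.

tiny_table <- function() {
  seq_table(data.frame(
    id = c("a", "b", "c", "d"),
    fv_heavy = c("ACDEFGHIKL", "ACDEFGHIKL", "ACDEYGHIKL", "WMNPQRSTVW"),
    hcdr3 = c("EFG", "EFG", "YGH", "QRS"),
    read_count = c(3L, 2L, 1L, 5L),
    stringsAsFactors = FALSE))
}

random_aa <- function(L, n = 1L) {
  vapply(seq_len(n), function(i) {
    paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], L,
                 replace = TRUE), collapse = "")
  }, character(1L))
}

## naive position-by-position Hamming oracle
hamming_oracle <- function(a, b) {
  va <- strsplit(a, "")[[1]]
  vb <- strsplit(b, "")[[1]]
  stopifnot(length(va) == length(vb))
  sum(va != vb)
}

## a tiny trained encoder reused across tests (cached per session)
tiny_encoder <- local({
  enc <- NULL
  function() {
    if (is.null(enc)) {
      set.seed(99)
      tab <- simulate_labeled_library(n_groups = 2L, per_group = 20L,
                                      seq_length = 20L, seed = 99L)
      enc <<- pretrain_mlm(tab, encoder_config(embed_dim = 16L,
                                               n_layers = 1L,
                                               n_heads = 2L,
                                               hidden_dim = 32L,
                                               max_len = 64L, seed = 99L),
                           epochs = 1L, batch_size = 16L)
    }
    enc
  }
})

## scalar transcription of the contrastive objective (independent oracle):
## explicit loops, no matrix algebra shared with the implementation
oracle_contrastive <- function(E, Fm, M, eps, kernel = NULL,
                               normalize = FALSE, n_neighbors = NULL) {
  n <- nrow(E)
  phi1 <- function(x, y) {
    dsq <- sum((x - y)^2) + eps
    tt <- if (!is.null(kernel)) kernel[1] * dsq^kernel[2] else dsq
    1 / (1 + tt)
  }
  total <- 0
  for (i in seq_len(n)) {
    lpos <- -log(phi1(E[i, ], Fm[i, ]))
    s <- 0
    for (j in seq_len(2 * n)) {
      other <- if (j <= n) E[j, ] else Fm[j - n, ]
      s <- s + M[i, j] * phi1(E[i, ], other)
    }
    lneg <- if (s == 0) 0 else log(s)
    if (normalize) {
      lpos <- lpos / max(n_neighbors[i], 1)
      lneg <- lneg / max(sum(M[i, ]), 1)
    }
    total <- total + lpos + lneg
  }
  total / n
}

## definitional pair-loop oracle for the pairwise scores
prf_oracle <- function(true, inferred, noise) {
  keep <- which(!noise)
  tp <- fp <- fn <- tn <- 0L
  together_inf <- function(a, b) {
    inferred[a] == inferred[b] && inferred[a] != -1L && inferred[b] != -1L
  }
  for (x in seq_along(keep)) {
    for (y in seq_len(x - 1L)) {
      i <- keep[x]
      j <- keep[y]
      st <- true[i] == true[j]
      si <- together_inf(i, j)
      if (st && si) tp <- tp + 1L
      else if (!st && si) fp <- fp + 1L
      else if (st && !si) fn <- fn + 1L
      else tn <- tn + 1L
    }
  }
  list(tp = tp, fp = fp, fn = fn, tn = tn,
       precision = if (tp + fp > 0) tp / (tp + fp) else 0,
       recall = if (tp + fn > 0) tp / (tp + fn) else 0)
}

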