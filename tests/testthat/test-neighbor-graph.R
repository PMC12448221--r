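test_that("hamming counts mismatches and enforces equal length", {
  expect_equal(hamming("ACDE", "ACDE"), 0L)
  expect_equal(hamming("ACDE", "ACDF"), 1L)
  expect_error(hamming("ACDE", "ACD"), "length")
  set.seed(7)
  for (i in 1:50) {
    L <- sample(3:40, 1L)
    a <- random_aa(L)
    b <- random_aa(L)
    expect_equal(hamming(a, b), hamming_oracle(a, b))
  }
  ## gap handling
  expect_equal(hamming("A-C", "A-G"), 1L)
  expect_equal(hamming("A-C", "AAC", ignore_gap_gap = TRUE), 1L)
  expect_equal(hamming("A--", "A-C", ignore_gap_gap = TRUE), 1L)
})

test_that("hamming_matrix equals the pairwise loop oracle", {
  set.seed(8)
  seqs <- random_aa(12L, 30L)
  D <- abmapr:::hamming_matrix(seqs)
  for (i in 1:30) {
    for (j in 1:30) {
      expect_equal(D[i, j], hamming_oracle(seqs[i], seqs[j]))
    }
  }
})

test_that("build_graph applies both cutoffs inclusively and symmetrically", {
  base <- strrep("A", 20L)
  ## pair at full distance 5 with CDR3 distance 2 -> neighbors (inclusive)
  s2 <- paste0("CC", "CCC", strrep("A", 15L))  # 5 diffs, 2 in cdr3 (pos 1-2)
  tab <- seq_table(data.frame(
    fv_heavy = c(base, s2),
    hcdr3 = substr(c(base, s2), 1L, 2L)), alphabet = "amino_acid")
  gr <- build_graph(tab, 5L, 2L)
  expect_equal(gr$neighbors[[1L]], 2L)
  expect_equal(gr$neighbors[[2L]], 1L)

  ## pair at full distance 4 but CDR3 distance 3 -> not neighbors
  s3 <- paste0("CCCC", strrep("A", 16L))
  tab2 <- seq_table(data.frame(
    fv_heavy = c(base, s3),
    hcdr3 = substr(c(base, s3), 1L, 4L)), alphabet = "amino_acid")
  gr2 <- build_graph(tab2, 5L, 2L)
  expect_length(gr2$neighbors[[1L]], 0L)

  ## simulated group vs brute-force all-pairs oracle
  sim <- simulate_lineages(n_lineages = 3L, lineage_size_range = c(20L, 30L),
                           seq_lengths = 24L, cdr3_lengths = 6L,
                           n_noise = 20L, seed = 3L)
  sim <- deduplicate(sim)
  gr3 <- build_graph(sim, 5L, 2L)
  n <- nrow(sim)
  for (i in seq_len(n)) {
    nb <- integer(0)
    for (j in seq_len(n)) {
      if (i == j) next
      if (hamming_oracle(sim$fv_heavy[i], sim$fv_heavy[j]) <= 5L &&
            hamming_oracle(sim$hcdr3[i], sim$hcdr3[j]) <= 2L) {
        nb <- c(nb, j)
      }
    }
    expect_identical(gr3$neighbors[[i]], nb)
  }
  ## symmetry + irreflexivity
  for (i in seq_len(n)) {
    expect_false(i %in% gr3$neighbors[[i]])
    for (j in gr3$neighbors[[i]]) {
      expect_true(i %in% gr3$neighbors[[j]])
    }
  }
})

test_that("enlarging cutoffs never removes an edge (monotonicity)", {
  sim <- deduplicate(simulate_lineages(n_lineages = 2L,
                                       lineage_size_range = c(15L, 20L),
                                       seq_lengths = 20L, cdr3_lengths = 5L,
                                       n_noise = 10L, seed = 4L))
  g1 <- build_graph(sim, 3L, 1L)
  g2 <- build_graph(sim, 5L, 2L)
  for (i in seq_len(nrow(sim))) {
    expect_true(all(g1$neighbors[[i]] %in% g2$neighbors[[i]]))
  }
})

test_that("adaptive_cutoff returns the smallest cutoff reaching the target", {
  ## identical sequences: any cutoff works, smallest returned
  tab <- seq_table(data.frame(fv_heavy = rep(strrep("A", 10L), 100L),
                              hcdr3 = rep("AAA", 100L)),
                   alphabet = "amino_acid")
  expect_equal(unname(adaptive_cutoff(tab, 5)["full_cutoff"]), 1L)

  ## matches an exhaustive scan on simulated lineages
  sim <- deduplicate(simulate_lineages(n_lineages = 2L,
                                       lineage_size_range = c(80L, 100L),
                                       seq_lengths = 30L, cdr3_lengths = 6L,
                                       n_noise = 0L, seed = 6L))
  got <- adaptive_cutoff(sim, 8)
  scan <- NA_integer_
  for (cutoff in 1:15) {
    gr <- build_graph(sim, cutoff, min(ceiling(0.4 * cutoff), cutoff))
    if (mean(gr$counts) >= 8) {
      scan <- cutoff
      break
    }
  }
  expect_equal(unname(got["full_cutoff"]), scan)

  ## unreachable target on mutually distant sequences -> c_max + warning
  set.seed(10)
  far <- seq_table(data.frame(fv_heavy = random_aa(40L, 12L),
                              hcdr3 = strrep("A", 0L)))
  expect_warning(res <- adaptive_cutoff(far, 5, c_max = 3L), "c_max|returning")
  expect_equal(unname(res["full_cutoff"]), 3L)
})

test_that("min-neighbor filtering excludes sparse sequences; iterate reaches a fixed point", {
  ## clique of 10 identical sequences: all kept
  tab <- seq_table(data.frame(fv_heavy = rep(strrep("A", 10L), 10L),
                              hcdr3 = rep("AA", 10L)),
                   alphabet = "amino_acid")
  gr <- filter_min_neighbors(build_graph(tab), 5L)
  expect_true(all(gr$kept))

  ## a sequence with 4 neighbors is excluded while a dense clique stays
  base <- strrep("A", 12L)
  mutants <- vapply(1:4, function(k) {
    s <- strsplit(base, "")[[1]]
    s[k] <- "C"
    paste(s, collapse = "")
  }, character(1L))
  clique <- rep(strrep("G", 12L), 8L)
  tab2 <- seq_table(data.frame(fv_heavy = c(base, mutants, clique),
                               hcdr3 = ""), alphabet = "amino_acid")
  gr2 <- build_graph(tab2, 1L, 0L)
  expect_equal(gr2$counts[1L], 4L)
  f2 <- filter_min_neighbors(gr2, 5L)
  expect_false(f2$kept[1L])
  expect_true(all(f2$kept[6:13]))

  ## chain into a clique: single pass vs iterate-until-stable oracle
  chain <- vapply(0:3, function(k) {
    paste0(strrep("C", k), strrep("A", 9L - k))
  }, character(1L))
  tail_clique <- rep(chain[4L], 4L)
  tab3 <- seq_table(data.frame(fv_heavy = c(chain, tail_clique),
                               hcdr3 = ""), alphabet = "amino_acid")
  gr3 <- build_graph(tab3, 1L, 0L)
  one_pass <- filter_min_neighbors(gr3, 2L)
  expect_equal(one_pass$kept, c(FALSE, rep(TRUE, 7L)))
  iter <- filter_min_neighbors(gr3, 2L, iterate = TRUE)
  ## oracle: repeatedly drop nodes below threshold until stable
  kept <- rep(TRUE, 8L)
  repeat {
    counts <- vapply(seq_len(8L), function(i) {
      if (!kept[i]) return(0L)
      sum(kept[gr3$neighbors[[i]]])
    }, integer(1L))
    drop <- kept & counts < 2L
    if (!any(drop)) break
    kept[drop] <- FALSE
  }
  expect_equal(iter$kept, kept)

  ## everything excluded -> advisory error
  set.seed(11)
  lonely <- seq_table(data.frame(fv_heavy = random_aa(30L, 6L), hcdr3 = ""))
  gl <- build_graph(lonely, 2L, 2L)
  expect_error(filter_min_neighbors(gl, 5L), "relax")
})

test_that("sampling weights are log neighbor counts and drive sampling frequency", {
  gr <- structure(list(neighbors = list(2:6, c(1L, 3:6), c(1:2, 4:6),
                                        c(1:3, 5:6), c(1:4, 6L), 1:5),
                       counts = rep(5L, 6L), kept = rep(TRUE, 6L),
                       ids = letters[1:6], full_cutoff = 5L,
                       cdr3_cutoff = 2L, min_neighbors = 5L),
                  class = "neighbor_graph")
  w <- sampling_weights(gr)
  expect_true(all(w == w[1L]))  # equal counts -> equal weights

  ## counts e^2 and e^4 -> weight ratio 1:2
  gr2 <- gr
  gr2$counts <- c(round(exp(2)), round(exp(4)), 5L, 5L, 5L, 5L)
  w2 <- sampling_weights(gr2)
  expect_equal(unname(w2[2L] / w2[1L]), 2, tolerance = 0.05)

  ## counts < 2 are rejected
  gr3 <- gr
  gr3$counts[1L] <- 1L
  expect_error(sampling_weights(gr3), "< 2")

  ## empirical sampling frequency matches weights within 3 sigma
  set.seed(12)
  probs <- w2 / sum(w2)
  draws <- sample.int(6L, 1e5L, replace = TRUE, prob = w2)
  freq <- tabulate(draws, 6L) / 1e5
  sigma <- sqrt(probs * (1 - probs) / 1e5)
  expect_true(all(abs(freq - probs) < 3 * sigma + 1e-12))
})

test_that("edge-list export writes symmetric unique edges with a JSON sidecar", {
  tab <- seq_table(data.frame(fv_heavy = c("AAAA", "AAAC", "GGGG"),
                              hcdr3 = ""), alphabet = "amino_acid")
  gr <- build_graph(tab, 1L, 0L)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(gr, path)
  edges <- read.delim(path)
  expect_equal(nrow(edges), 1L)
  side <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(side$full_cutoff, 1L)
})
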