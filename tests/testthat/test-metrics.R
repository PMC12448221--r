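test_that("pairwise precision/recall/F1 match their definitions", {
  ## perfect recovery
  tl <- rep(c("a", "b", "c"), each = 5L)
  p <- pairwise_prf(tl, as.integer(factor(tl)))
  expect_equal(c(p$precision, p$recall, p$f1), c(1, 1, 1))

  ## one giant cluster over 2 equal families of size m:
  ## recall 1, precision = 2 C(m,2) / C(2m,2)
  m <- 7L
  tl2 <- rep(c("a", "b"), each = m)
  p2 <- pairwise_prf(tl2, rep(0L, 2L * m))
  expect_equal(p2$recall, 1)
  expect_equal(p2$precision, 2 * choose(m, 2) / choose(2 * m, 2))

  ## all singletons: recall 0, precision reported as 0 with a warning
  expect_warning(p3 <- pairwise_prf(tl, seq_along(tl)), "zero denominator")
  expect_equal(p3$recall, 0)
  expect_equal(p3$precision, 0)

  ## random labelings vs the O(n^2) loop oracle, noise and -1 included
  set.seed(33)
  for (rep in 1:5) {
    n <- 30L
    true <- sample(letters[1:4], n, TRUE)
    inf <- sample(c(-1L, 0L, 1L, 2L), n, TRUE)
    noise <- runif(n) < 0.2
    got <- pairwise_prf(true, inf, noise)
    want <- prf_oracle(true, inf, noise)
    expect_equal(got[c("tp", "fp", "fn", "tn")],
                 want[c("tp", "fp", "fn", "tn")])
    expect_equal(got$precision, want$precision)
    expect_equal(got$recall, want$recall)
    expect_equal(got$tp + got$fp + got$fn + got$tn, choose(sum(!noise), 2))
  }
})

test_that("cluster typing follows the 80%-of-family rule", {
  ## perfect clustering + one all-noise cluster
  true <- c(rep("f1", 10L), rep("f2", 10L), rep("noise", 5L))
  noise <- true == "noise"
  inf <- c(rep(0L, 10L), rep(1L, 10L), rep(2L, 5L))
  ctf <- cluster_type_fractions(true, inf, noise)
  expect_equal(ctf$tic_fraction, 2 / 3)
  expect_equal(ctf$noise_fraction, 1 / 3)
  expect_equal(ctf$mix_fraction, 0)

  ## cluster holding 79% of a family and nothing else is a mix
  true2 <- rep("f", 100L)
  inf2 <- c(rep(0L, 79L), rep(1L, 21L))
  ctf2 <- cluster_type_fractions(true2, inf2)
  expect_equal(unname(ctf2$types["0"]), "mix")
  ## 80% exactly qualifies
  inf3 <- c(rep(0L, 80L), rep(1L, 20L))
  expect_equal(unname(cluster_type_fractions(true2, inf3)$types["0"]),
               "tic")

  ## fractions sum to 1; lowering the threshold never lowers tic_fraction
  set.seed(34)
  for (rep in 1:5) {
    n <- 60L
    true <- sample(c("a", "b", "c"), n, TRUE)
    noise <- runif(n) < 0.2
    true[noise] <- "zz_noise"
    inf <- sample(0:4, n, TRUE)
    hi <- cluster_type_fractions(true, inf, noise, tic_threshold = 0.8)
    lo <- cluster_type_fractions(true, inf, noise, tic_threshold = 0.5)
    expect_equal(hi$tic_fraction + hi$mix_fraction + hi$noise_fraction, 1)
    expect_gte(lo$tic_fraction, hi$tic_fraction)
    ## definition-loop oracle
    for (cl in names(hi$types)) {
      members <- which(inf == as.integer(cl))
      if (all(noise[members])) {
        expect_equal(unname(hi$types[cl]), "noise")
      } else {
        fams <- unique(true[!noise])
        is_tic <- any(vapply(fams, function(f) {
          sum(true[members] == f & !noise[members]) >=
            0.8 * sum(true == f & !noise)
        }, logical(1L)))
        expect_equal(unname(hi$types[cl]), if (is_tic) "tic" else "mix")
      }
    }
  }
  expect_error(cluster_type_fractions("a", -1L), "empty clustering")
})

test_that("intra-cluster edit distance averages all unordered pairs", {
  tab <- seq_table(data.frame(
    fv_heavy = c("AAAA", "AAAA", "AACC", "ACCC", "GGGG"),
    hcdr3 = ""), alphabet = "amino_acid")
  labels <- c(0L, 0L, 1L, 1L, -1L)
  d <- intra_cluster_edit_distance(tab, labels)
  expect_equal(unname(d["0"]), 0)
  expect_equal(unname(d["1"]), 1)
  expect_false("-1" %in% names(d))

  ## identical / singleton / random-loop checks
  set.seed(35)
  seqs <- random_aa(10L, 12L)
  lab <- sample(0:2, 12L, TRUE)
  t2 <- seq_table(data.frame(fv_heavy = seqs, hcdr3 = ""))
  d2 <- intra_cluster_edit_distance(t2, lab)
  for (cl in unique(lab)) {
    members <- which(lab == cl)
    if (length(members) < 2L) {
      expect_equal(unname(d2[as.character(cl)]), 0)
    } else {
      pairs <- combn(members, 2L)
      want <- mean(apply(pairs, 2L, function(p) {
        hamming_oracle(seqs[p[1L]], seqs[p[2L]])
      }))
      expect_equal(unname(d2[as.character(cl)]), want)
    }
  }
})

test_that("label entropy matches closed forms", {
  expect_equal(unname(label_entropy(rep(0L, 6L), rep("x", 6L))), 0)
  expect_equal(unname(label_entropy(rep(0L, 6L),
                                    rep(c("x", "y"), 3L))), 1)
  h <- label_entropy(rep(0L, 4L), c("a", "a", "b", "c"))
  expect_equal(unname(h), 1.5)
})

test_that("homogeneity is the dominant-class fraction with ties flagged", {
  expect_equal(as.numeric(homogeneity(rep(0L, 5L), rep("e", 5L))), 1)
  expect_equal(as.numeric(homogeneity(rep(0L, 10L),
                                      rep(c("e", "d"), c(6L, 4L)))), 0.6)
  hh <- homogeneity(rep(0L, 4L), c("e", "e", "d", "d"))
  expect_equal(as.numeric(hh), 0.5)
  expect_true("0" %in% attr(hh, "ties"))
})

test_that("seed-distance correlation behaves at its extremes and on a worked fixture", {
  seed <- strrep("A", 10L)
  muts <- vapply(1:4, function(k) {
    paste0(strrep("C", k), strrep("A", 10L - k))
  }, character(1L))
  seqs <- c(seed, muts)
  ## coordinates on a line at exactly the edit distances
  coords <- cbind(0:4, 0)
  expect_equal(seed_distance_correlation(coords, seqs, seed), 1)

  ## worked 5-point fixture vs closed-form Pearson
  co2 <- cbind(c(0, 1.5, 1.0, 3.2, 4.1), c(0, 0.5, -1, 0.3, 1))
  eucl <- sqrt(rowSums(co2^2))
  want <- cor(0:4, eucl)
  expect_equal(seed_distance_correlation(co2, seqs, seed), want)

  ## shuffled coordinates: |r| small over a permutation null
  set.seed(36)
  seqs200 <- c(seed, vapply(1:199, function(i) {
    k <- sample(1:6, 1L)
    s <- strsplit(seed, "")[[1]]
    s[sample(10L, k)] <- "G"
    paste(s, collapse = "")
  }, character(1L)))
  coords200 <- matrix(rnorm(400L), 200L, 2L)
  r <- seed_distance_correlation(coords200, seqs200, seed)
  expect_lt(abs(r), 0.25)

  ## degenerate variance is reported
  expect_warning(
    r0 <- seed_distance_correlation(matrix(0, 5L, 2L), seqs, seed),
    "zero variance")
  expect_true(is.na(r0))
})
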