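test_that("kd-tree splits alternate axes at the lower median", {
  ## 4 corner points, depth 2: four singleton leaves
  coords <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  tree <- build_kdtree(coords, max_depth = 2L, leaf_size = 1L)
  leaves <- abmapr:::nodes_at_level(tree, 2L)
  expect_length(leaves, 4L)
  expect_true(all(lengths(lapply(leaves, `[[`, "members")) == 1L))

  ## identical points stop at leaf_size
  t2 <- build_kdtree(matrix(1, 7L, 2L), max_depth = 10L, leaf_size = 2L)
  expect_gte(abmapr:::tree_depth(t2$root), 1L)

  ## every leaf member satisfies all ancestor split predicates
  set.seed(41)
  co <- matrix(rnorm(120L), 60L, 2L)
  t3 <- build_kdtree(co, max_depth = 5L, leaf_size = 2L)
  replay <- function(node, lo = c(-Inf, -Inf), hi = c(Inf, Inf)) {
    for (m in node$members) {
      expect_true(all(co[m, ] >= lo - 1e-12) && all(co[m, ] <= hi + 1e-12))
    }
    if (!node$leaf) {
      hil <- hi
      hil[node$axis] <- node$split
      lor <- lo
      lor[node$axis] <- node$split
      replay(node$left, lo, hil)
      replay(node$right, lor, hi)
    }
  }
  replay(t3$root)

  expect_error(build_kdtree(matrix(numeric(0), 0L, 2L)), "empty")
})

test_that("kd-tree membership is invariant to input permutation", {
  set.seed(42)
  co <- matrix(rnorm(80L), 40L, 2L)
  ids <- sprintf("s%02d", 1:40)
  t1 <- build_kdtree(co, max_depth = 4L, leaf_size = 1L, ids = ids)
  perm <- sample(40L)
  t2 <- build_kdtree(co[perm, ], max_depth = 4L, leaf_size = 1L,
                     ids = ids[perm])
  sets1 <- lapply(abmapr:::nodes_at_level(t1, 3L), function(nd) {
    sort(t1$ids[nd$members])
  })
  sets2 <- lapply(abmapr:::nodes_at_level(t2, 3L), function(nd) {
    sort(t2$ids[nd$members])
  })
  expect_setequal(vapply(sets1, paste, "", collapse = ","),
                  vapply(sets2, paste, "", collapse = ","))
})

test_that("node consensus takes the column plurality with tie codes", {
  coords <- matrix(c(0, 0, 0, 1, 1, 1), 3L, 2L)
  tree <- build_kdtree(coords, max_depth = 0L)
  seqs <- c("ACGT", "ACGA", "ACTA")
  cons <- consensus_at_level(tree, seqs, level = 0L,
                             alphabet = "nucleotide")
  expect_identical(as.character(cons), "ACGA")

  ## identical sequences give themselves; consensus is idempotent
  cons2 <- consensus_at_level(tree, rep("TTTT", 3L), 0L, "nucleotide")
  expect_identical(as.character(cons2), "TTTT")

  ## two-way ties: IUPAC for nucleotides, X for amino acids
  t2 <- build_kdtree(coords[1:2, , drop = FALSE], max_depth = 0L)
  expect_identical(as.character(consensus_at_level(t2, c("AC", "GC"), 0L,
                                                   "nucleotide")), "RC")
  expect_identical(as.character(consensus_at_level(t2, c("AC", "GC"), 0L,
                                                   "amino_acid")), "XC")

  expect_error(consensus_at_level(tree, seqs, level = 9L), "deeper")

  ## planted subclade mutations localize in the level consensus
  set.seed(43)
  base <- strrep("A", 30L)
  left <- vapply(1:10, function(i) {
    s <- strsplit(base, "")[[1]]
    s[5L] <- "C"  # planted clade marker
    s[sample(20:30, 1L)] <- sample(c("G", "T"), 1L)
    paste(s, collapse = "")
  }, character(1L))
  right <- vapply(1:10, function(i) {
    s <- strsplit(base, "")[[1]]
    s[9L] <- "G"
    s[sample(20:30, 1L)] <- sample(c("C", "T"), 1L)
    paste(s, collapse = "")
  }, character(1L))
  co <- rbind(cbind(rnorm(10L, -5, 0.1), rnorm(10L, 0, 0.1)),
              cbind(rnorm(10L, 5, 0.1), rnorm(10L, 0, 0.1)))
  t3 <- build_kdtree(co, max_depth = 1L, leaf_size = 1L)
  cons3 <- consensus_at_level(t3, c(left, right), 1L, "nucleotide")
  expect_length(cons3, 2L)
  ## one node consensus carries C at 5, the other G at 9
  chars5 <- vapply(cons3, substr, "", 5L, 5L)
  chars9 <- vapply(cons3, substr, "", 9L, 9L)
  expect_setequal(unname(chars5), c("C", "A"))
  expect_setequal(unname(chars9), c("A", "G"))
})

test_that("trajectory MSA orders by projection and flags deviations", {
  seed <- strrep("A", 12L)
  n <- 20L
  set.seed(45)
  seqs <- vapply(seq_len(n), function(i) {
    k <- ceiling(i / 7)  # mutation load grows along y, positions scattered
    s <- strsplit(seed, "")[[1]]
    s[sample.int(12L, k)] <- "C"
    paste(s, collapse = "")
  }, character(1L))
  coords <- cbind(0, seq_len(n))  # on the segment itself
  tr <- trajectory_msa(coords, seqs, list(p0 = c(0, 0), p1 = c(0, n + 1)),
                       n_samples = n, alphabet = "nucleotide")
  expect_identical(tr$order, seq_len(n))
  ## consensus row deviates nowhere from itself
  expect_equal(length(which(charToRaw(tr$consensus) !=
                              charToRaw(tr$consensus))), 0L)
  ## deviation counts increase along the trajectory
  devs <- lengths(tr$deviations)
  expect_gt(cor(seq_len(n), devs, method = "spearman"), 0)

  expect_error(trajectory_msa(coords + 100, seqs,
                              list(p0 = c(0, 0), p1 = c(0, 1))),
               "capture radius")

  ## FASTA + deviation-table export round-trips
  prefix <- tempfile()
  write_trajectory_msa(tr, prefix)
  fa <- readLines(paste0(prefix, ".fasta"))
  expect_identical(fa[1:2], c(">consensus", tr$consensus))
  expect_equal(sum(grepl("^>", fa)), n + 1L)
  dev <- read.delim(paste0(prefix, ".tsv"))
  expect_equal(nrow(dev), sum(lengths(tr$deviations)))
  if (nrow(dev)) {
    expect_true(all(substr(tr$sequences[dev$rank], dev$position,
                           dev$position) == dev$observed))
  }
  unlink(paste0(prefix, c(".fasta", ".tsv")))
})

test_that("newick export parses and covers all leaves", {
  skip_if_not_installed("ape")
  set.seed(44)
  co <- matrix(rnorm(30L), 15L, 2L)
  ids <- sprintf("sq%02d", 1:15)
  tree <- build_kdtree(co, max_depth = 3L, leaf_size = 1L, ids = ids)
  nwk <- kdtree_newick(tree)
  phy <- ape::read.tree(text = nwk)
  expect_setequal(phy$tip.label, ids)

  obj <- kdtree_json(tree)
  expect_equal(obj$depth, 0L)
  expect_length(obj$ids, 15L)
})
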