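## Ground-truth-bearing simulators for benchmarking every pipeline stage:
## (a) clonal lineages + singleton noise, (b) a seed-rooted hierarchical
## mutant set with exact edits-from-seed, (c) labelled display libraries.

alphabet_chars <- function(alphabet) {
  switch(alphabet, nucleotide = NT_CHARS, amino_acid = AA_CHARS,
         stop("unknown alphabet: ", alphabet))
}

random_sequence <- function(L, chars) {
  paste(sample(chars, L, replace = TRUE), collapse = "")
}

## substitute k distinct positions with uniformly drawn *different* symbols
substitute_positions <- function(seq, positions, chars) {
  s <- strsplit(seq, "")[[1]]
  for (p in positions) {
    s[p] <- resample(setdiff(chars, s[p]), 1L)
  }
  paste(s, collapse = "")
}

#' Simulate clonal lineages with singleton noise
#'
#' Emulates a somatic-hypermutation benchmark: each lineage starts from a
#' random ancestor with a designated CDR3 window and grows by repeatedly
#' copying a uniformly chosen existing member with `Binomial(L,
#' mutation_rate)` random substitutions (star/branching mixtures). Noise
#' sequences are independent random sequences drawn to match the lineage
#' length design, so they fall into the same length groups but have no
#' Hamming neighbors with overwhelming probability.
#'
#' @param n_lineages number of clonal families.
#' @param lineage_size_range inclusive range of members per lineage.
#' @param mutation_rate per-position substitution probability per copy
#'   (benchmark default 0.01).
#' @param seq_lengths pool of full-sequence lengths; each lineage draws one
#'   (several distinct values force multiple length groups).
#' @param cdr3_lengths pool of CDR3 window lengths, drawn per lineage.
#' @param n_noise number of noise singletons.
#' @param alphabet `"nucleotide"` (default, as in the benchmark) or
#'   `"amino_acid"`.
#' @param seed RNG seed; identical config + seed reproduces the table.
#' @return A [seq_table()] with truth columns `lineage_id` (`"noise"` for
#'   singletons) and `is_noise`.
#' @export
simulate_lineages <- function(n_lineages = 10L,
                              lineage_size_range = c(150L, 250L),
                              mutation_rate = 0.01,
                              seq_lengths = c(90L, 96L, 102L),
                              cdr3_lengths = c(15L, 18L, 21L),
                              n_noise = 2000L,
                              alphabet = "nucleotide",
                              seed = 1L) {
  stopifnot(mutation_rate > 0 || mutation_rate == 0, mutation_rate < 1,
            n_lineages >= 1L)
  set.seed(seed)
  chars <- alphabet_chars(alphabet)
  designs <- data.frame(
    L = resample(seq_lengths, n_lineages, replace = TRUE),
    c3 = resample(cdr3_lengths, n_lineages, replace = TRUE),
    size = resample(seq.int(lineage_size_range[1L],
                             lineage_size_range[2L]),
                     n_lineages, replace = TRUE))
  designs$c3start <- vapply(seq_len(n_lineages), function(i) {
    sample.int(designs$L[i] - designs$c3[i] + 1L, 1L)
  }, integer(1L))

  rows <- vector("list", n_lineages)
  for (i in seq_len(n_lineages)) {
    L <- designs$L[i]
    members <- character(designs$size[i])
    members[1L] <- random_sequence(L, chars)
    for (j in seq_len(designs$size[i])[-1L]) {
      parent <- members[sample.int(j - 1L, 1L)]
      k <- rbinom(1L, L, mutation_rate)
      members[j] <- if (k > 0L) {
        substitute_positions(parent, sample.int(L, k), chars)
      } else {
        parent
      }
    }
    rows[[i]] <- data.frame(
      fv_heavy = members,
      hcdr3 = substr(members, designs$c3start[i],
                     designs$c3start[i] + designs$c3[i] - 1L),
      lineage_id = sprintf("L%03d", i),
      is_noise = FALSE, stringsAsFactors = FALSE)
  }

  if (n_noise > 0L) {
    di <- sample.int(n_lineages, n_noise, replace = TRUE)
    noise <- vapply(di, function(i) {
      random_sequence(designs$L[i], chars)
    }, character(1L))
    rows[[n_lineages + 1L]] <- data.frame(
      fv_heavy = noise,
      hcdr3 = substr(noise, designs$c3start[di],
                     designs$c3start[di] + designs$c3[di] - 1L),
      lineage_id = "noise", is_noise = TRUE, stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  df$id <- sprintf("s%06d", seq_len(nrow(df)))
  seq_table(df, alphabet = alphabet)
}

#' Simulate a seed-rooted hierarchical mutant set
#'
#' Emulates a designed antibody library expanding from a single seed the
#' way optimization campaigns do: substitutions are confined to a fixed
#' pool of designed positions (CDR-window positions enter the pool with
#' `cdr_bias`-fold weight), each carrying one designated alternative
#' residue, and variants grow along persistent design lineages — every new
#' variant inherits the mutation set of its lineage's current member and
#' adds or removes pool mutations to hit its drawn edit target exactly.
#' Consecutive tiers are therefore Hamming-connected, same-edit shells
#' share pool mutations, and `edit_from_seed` equals the Hamming distance
#' to the seed by construction (re-verified internally).
#'
#' @param seed_sequence the root sequence; `NULL` draws a random one.
#' @param seq_length length of the random seed when `seed_sequence` is
#'   `NULL`.
#' @param tiers data.frame with columns `origin` (label), `count`,
#'   `min_edit`, `max_edit` — one row per tier, ordered outward from the
#'   seed. Default spans edits 1-11 over ~3,000 sequences.
#' @param cdr_positions integer positions treated as the CDR window;
#'   `NULL` places a central window of length `cdr3_length`.
#' @param cdr3_length length of the default CDR3 window.
#' @param cdr_bias relative weight of CDR positions when drawing the
#'   designed-position pool.
#' @param pool_size number of mutable positions in the design pool (must
#'   be at least the largest `max_edit`).
#' @param n_lineages number of persistent design lineages the tiers grow
#'   along.
#' @param alphabet residue alphabet.
#' @param seed RNG seed.
#' @return A [seq_table()] with truth columns `origin` (`"seed"`, then tier
#'   labels) and `edit_from_seed`; the root is kept as attribute
#'   `"seed_sequence"`.
#' @export
simulate_hierarchical <- function(seed_sequence = NULL, seq_length = 115L,
                                  tiers = default_hier_tiers(),
                                  cdr_positions = NULL, cdr3_length = 15L,
                                  cdr_bias = 2, pool_size = 24L,
                                  n_lineages = 20L,
                                  alphabet = "amino_acid", seed = 1L) {
  set.seed(seed)
  chars <- alphabet_chars(alphabet)
  if (is.null(seed_sequence)) {
    seed_sequence <- random_sequence(seq_length, chars)
  }
  L <- nchar(seed_sequence)
  pool_size <- min(pool_size, L)
  if (nrow(tiers) && any(tiers$max_edit > min(L, pool_size))) {
    stop("requested mutation count exceeds the sequence length or the ",
         "design pool")
  }
  if (is.null(cdr_positions)) {
    start <- max(1L, floor((L - cdr3_length) / 2L))
    cdr_positions <- seq.int(start, length.out = cdr3_length)
  }
  seed_chars <- strsplit(seed_sequence, "")[[1]]
  w <- rep(1, L)
  w[cdr_positions] <- cdr_bias
  pool <- sort(resample(seq_len(L), pool_size, prob = w))
  alt <- vapply(pool, function(p) {
    resample(setdiff(chars, seed_chars[p]), 1L)
  }, character(1L))

  realize <- function(mut) {
    s <- seed_chars
    if (length(mut)) s[pool[mut]] <- alt[mut]
    paste(s, collapse = "")
  }

  lineage <- replicate(n_lineages, integer(0), simplify = FALSE)
  out <- data.frame(fv_heavy = seed_sequence, origin = "seed",
                    edit_from_seed = 0L, stringsAsFactors = FALSE)
  for (t in seq_len(nrow(tiers))) {
    seqs <- character(tiers$count[t])
    edits <- integer(tiers$count[t])
    for (j in seq_len(tiers$count[t])) {
      li <- sample.int(n_lineages, 1L)
      mut <- lineage[[li]]
      target <- resample(seq.int(tiers$min_edit[t], tiers$max_edit[t]), 1L)
      if (length(mut) > target) {
        mut <- sort(resample(mut, target))
      } else if (length(mut) < target) {
        free <- setdiff(seq_len(pool_size), mut)
        mut <- sort(c(mut, resample(free, target - length(mut))))
      }
      lineage[[li]] <- mut
      seqs[j] <- realize(mut)
      edits[j] <- length(mut)
    }
    out <- rbind(out, data.frame(
      fv_heavy = seqs, origin = tiers$origin[t], edit_from_seed = edits,
      stringsAsFactors = FALSE))
  }
  c3a <- min(cdr_positions)
  c3b <- max(cdr_positions)
  out$hcdr3 <- substr(out$fv_heavy, c3a, c3b)
  out$id <- sprintf("h%06d", seq_len(nrow(out)))
  tab <- seq_table(out, alphabet = alphabet)
  stopifnot(all(vapply(seq_len(nrow(tab)), function(i) {
    hamming(tab$fv_heavy[i], seed_sequence)
  }, integer(1L)) == tab$edit_from_seed))
  attr(tab, "seed_sequence") <- seed_sequence
  tab
}

#' Default tier design for [simulate_hierarchical()]
#'
#' Seven tiers emulating a train set of low-mutation variants plus six
#' generative-design waves, spanning edit distances 1-11 over about 3,000
#' sequences.
#'
#' @return data.frame with columns `origin`, `count`, `min_edit`,
#'   `max_edit`.
#' @export
default_hier_tiers <- function() {
  data.frame(
    origin   = c("Train", "GP-HC", "GP-GA", "GP-Gibbs",
                 "En-HC", "En-GA", "En-Gibbs"),
    count    = c(400L, 450L, 450L, 450L, 450L, 400L, 400L),
    min_edit = c(1L, 2L, 3L, 4L, 6L, 7L, 8L),
    max_edit = c(2L, 4L, 5L, 6L, 9L, 10L, 11L),
    stringsAsFactors = FALSE)
}

#' Simulate a labelled display library
#'
#' Groups of mutational variants around distinct random prototypes, with a
#' categorical binding label per group and configurable label noise; used
#' to exercise the cluster-quality metrics (label entropy, intra-cluster
#' edit distance).
#'
#' @param n_groups number of prototype groups.
#' @param per_group members per group.
#' @param label_scheme label categories cycled over groups.
#' @param label_noise probability that a member's label is replaced by a
#'   uniform draw from the other categories.
#' @param seq_length prototype length.
#' @param mutation_rate per-position substitution rate around the
#'   prototype.
#' @param alphabet residue alphabet.
#' @param seed RNG seed.
#' @return A [seq_table()] with truth columns `group_id` and `label`.
#' @export
simulate_labeled_library <- function(n_groups = 5L, per_group = 50L,
                                     label_scheme = c("binder", "weak",
                                                      "non-binder"),
                                     label_noise = 0, seq_length = 60L,
                                     mutation_rate = 0.02,
                                     alphabet = "amino_acid", seed = 1L) {
  set.seed(seed)
  chars <- alphabet_chars(alphabet)
  rows <- lapply(seq_len(n_groups), function(g) {
    proto <- random_sequence(seq_length, chars)
    members <- vapply(seq_len(per_group), function(j) {
      k <- rbinom(1L, seq_length, mutation_rate)
      if (k > 0L) substitute_positions(proto, sample.int(seq_length, k),
                                       chars) else proto
    }, character(1L))
    lab <- rep(label_scheme[(g - 1L) %% length(label_scheme) + 1L],
               per_group)
    flip <- runif(per_group) < label_noise
    lab[flip] <- vapply(lab[flip], function(l) {
      resample(setdiff(label_scheme, l), 1L)
    }, character(1L))
    data.frame(fv_heavy = members,
               hcdr3 = substr(members, max(1L, seq_length - 14L),
                              seq_length),
               group_id = sprintf("G%02d", g), label = lab,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  df$id <- sprintf("b%05d", seq_len(nrow(df)))
  seq_table(df, alphabet = alphabet)
}
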