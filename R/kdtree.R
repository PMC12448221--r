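## Phylogeny-like kd-tree over map coordinates: node consensus sequences
## and trajectory alignments.

## IUPAC codes for nucleotide plurality ties
IUPAC <- c(AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K",
           ACG = "V", ACT = "H", AGT = "D", CGT = "B", ACGT = "N")

#' Build a kd-tree over 2D map coordinates
#'
#' Axis-aligned binary partition: split axes alternate starting with x, at
#' the lower median of the coordinate (ties broken by sequence id, so the
#' tree is independent of input order). The lower-median point goes left.
#'
#' @param coords `N x 2` coordinate matrix.
#' @param max_depth maximum tree depth (root is depth 0).
#' @param leaf_size stop splitting nodes at or below this size.
#' @param ids sequence identifiers (default row numbers as strings).
#' @return Nested list of nodes, class `kd_tree`; each node has `depth`,
#'   `axis` (1 = x, 2 = y), `split`, `members` (row indices), `path`, and
#'   `left`/`right` children or `leaf = TRUE`.
#' @export
build_kdtree <- function(coords, max_depth = 6L, leaf_size = 1L,
                         ids = NULL) {
  coords <- as.matrix(coords)
  if (!nrow(coords)) stop("empty input: no coordinates")
  stopifnot(ncol(coords) == 2L, all(is.finite(coords)))
  if (is.null(ids)) ids <- as.character(seq_len(nrow(coords)))
  stopifnot(length(ids) == nrow(coords))

  grow <- function(members, depth, path) {
    node <- list(depth = depth, members = members, path = path)
    if (length(members) <= leaf_size || depth >= max_depth) {
      node$leaf <- TRUE
      class(node) <- "kd_node"
      return(node)
    }
    axis <- depth %% 2L + 1L
    ord <- members[order(coords[members, axis], ids[members])]
    m <- ceiling(length(ord) / 2)  # lower median goes left
    node$axis <- axis
    node$split <- coords[ord[m], axis]
    node$leaf <- FALSE
    node$left <- grow(ord[seq_len(m)], depth + 1L, paste0(path, "L"))
    node$right <- grow(ord[seq.int(m + 1L, length(ord))], depth + 1L,
                       paste0(path, "R"))
    class(node) <- "kd_node"
    node
  }
  root <- grow(seq_len(nrow(coords)), 0L, "n")
  structure(list(root = root, ids = ids, n = nrow(coords),
                 max_depth = max_depth, leaf_size = leaf_size),
            class = "kd_tree")
}

#' @export
print.kd_tree <- function(x, ...) {
  cat(sprintf("kd_tree: %d point(s), max_depth=%d, leaf_size=%d\n",
              x$n, x$max_depth, x$leaf_size))
  invisible(x)
}

## Collect the nodes that partition the points at a depth: nodes exactly at
## `level`, plus leaves that bottomed out above it (so every sequence is
## covered).
nodes_at_level <- function(tree, level) {
  out <- list()
  walk <- function(node) {
    if (node$depth == level || (node$leaf && node$depth < level)) {
      out[[length(out) + 1L]] <<- node
      return(invisible())
    }
    if (!node$leaf) {
      walk(node$left)
      walk(node$right)
    }
  }
  walk(tree$root)
  out
}

tree_depth <- function(node) {
  if (node$leaf) node$depth else max(tree_depth(node$left),
                                     tree_depth(node$right))
}

## Per-column plurality consensus; ties -> IUPAC code (nucleotide) or 'X'.
consensus_string <- function(seqs, alphabet = "amino_acid") {
  stopifnot(length(seqs) >= 1L)
  cm <- seq_code_matrix(seqs)
  cons <- vapply(seq_len(ncol(cm)), function(j) {
    tab <- sort(table(cm[, j]), decreasing = TRUE)
    top <- as.integer(names(tab[tab == max(tab)]))
    if (length(top) == 1L) return(intToUtf8(top))
    if (alphabet == "nucleotide") {
      key <- paste(sort(vapply(top, intToUtf8, "")), collapse = "")
      code <- unname(IUPAC[key])
      if (is.na(code)) "N" else code
    } else {
      "X"
    }
  }, character(1L))
  paste(cons, collapse = "")
}

#' Consensus sequences of kd-tree nodes at a given level
#'
#' For each node at depth `level` (plus leaves that bottom out earlier),
#' the per-column plurality character over its member sequences; ties give
#' an IUPAC ambiguity code for nucleotides or `X` for amino acids. The
#' level-3 consensus highlights key residues preserved along map
#' trajectories.
#'
#' @param tree a [build_kdtree()] result.
#' @param sequences equal-length sequences aligned with the tree's points.
#' @param level node depth (root = 0).
#' @param alphabet `"amino_acid"` or `"nucleotide"`.
#' @return Named character vector (names = node paths); attribute
#'   `"members"` holds per-node member indices.
#' @export
consensus_at_level <- function(tree, sequences, level = 3L,
                               alphabet = c("amino_acid", "nucleotide")) {
  stopifnot(inherits(tree, "kd_tree"), length(sequences) == tree$n)
  alphabet <- match.arg(alphabet)
  if (level > tree_depth(tree$root)) {
    stop("level ", level, " is deeper than the tree (depth ",
         tree_depth(tree$root), ")")
  }
  nodes <- nodes_at_level(tree, level)
  out <- vapply(nodes, function(nd) {
    consensus_string(sequences[nd$members], alphabet)
  }, character(1L))
  names(out) <- vapply(nodes, `[[`, "", "path")
  attr(out, "members") <- setNames(lapply(nodes, `[[`, "members"),
                                   names(out))
  out
}

#' Order sequences along a map trajectory and align them to the consensus
#'
#' Selects the sequences closest (perpendicular distance within
#' `capture_radius`) to a line segment drawn on the map, orders them by
#' their projection onto it, and reports each sequence's deviations from
#' the selection's consensus.
#'
#' @param coords `N x 2` coordinates.
#' @param sequences equal-length sequences aligned with `coords`.
#' @param line_segment list or matrix giving the segment endpoints `p0`,
#'   `p1` (each length 2).
#' @param n_samples keep at most this many sequences (the nearest ones).
#' @param capture_radius maximal perpendicular distance; default 5% of the
#'   map diagonal.
#' @param alphabet consensus alphabet.
#' @return List with `order` (row indices along the trajectory),
#'   `sequences`, `consensus`, and `deviations` (per-sequence integer
#'   positions differing from the consensus).
#' @export
trajectory_msa <- function(coords, sequences, line_segment,
                           n_samples = 100L, capture_radius = NULL,
                           alphabet = c("amino_acid", "nucleotide")) {
  alphabet <- match.arg(alphabet)
  coords <- as.matrix(coords)
  stopifnot(nrow(coords) == length(sequences))
  if (is.matrix(line_segment)) {
    p0 <- line_segment[1L, ]
    p1 <- line_segment[2L, ]
  } else {
    p0 <- line_segment$p0 %||% line_segment[[1L]]
    p1 <- line_segment$p1 %||% line_segment[[2L]]
  }
  if (is.null(capture_radius)) {
    rng <- apply(coords, 2L, range)
    capture_radius <- 0.05 * sqrt(sum((rng[2L, ] - rng[1L, ])^2))
  }
  v <- p1 - p0
  len2 <- sum(v^2)
  if (len2 == 0) stop("degenerate segment: p0 == p1")
  rel <- sweep(coords, 2L, p0)
  t <- pmin(pmax((rel %*% v) / len2, 0), 1)
  foot <- cbind(p0[1L] + t * v[1L], p0[2L] + t * v[2L])
  perp <- sqrt(rowSums((coords - foot)^2))
  cand <- which(perp <= capture_radius)
  if (!length(cand)) stop("no sequences within the capture radius")
  if (length(cand) > n_samples) {
    cand <- cand[order(perp[cand])][seq_len(n_samples)]
  }
  ord <- cand[order(t[cand], perp[cand])]
  seqs <- sequences[ord]
  cons <- consensus_string(seqs, alphabet)
  devs <- lapply(seqs, function(s) {
    which(charToRaw(s) != charToRaw(cons))
  })
  list(order = ord, sequences = seqs, consensus = cons, deviations = devs)
}

#' Write a trajectory alignment as FASTA plus a TSV deviation table
#'
#' The FASTA holds the consensus (first record) followed by the selected
#' sequences in trajectory order; the TSV lists one row per deviation from
#' the consensus (`rank`, `id`, `position`, `consensus`, `observed`).
#'
#' @param msa a [trajectory_msa()] result.
#' @param prefix output path prefix (writes `<prefix>.fasta` and
#'   `<prefix>.tsv`).
#' @param ids optional sequence identifiers (indexed by `msa$order`);
#'   defaults to the row indices.
#' @return The two file paths, invisibly.
#' @export
write_trajectory_msa <- function(msa, prefix, ids = NULL) {
  if (is.null(ids)) ids <- as.character(msa$order)
  else ids <- as.character(ids[msa$order])
  fasta <- c(">consensus", msa$consensus,
             as.vector(rbind(paste0(">", ids), msa$sequences)))
  writeLines(fasta, paste0(prefix, ".fasta"))
  cons_chars <- strsplit(msa$consensus, "")[[1L]]
  rows <- do.call(rbind, lapply(seq_along(msa$deviations), function(k) {
    pos <- msa$deviations[[k]]
    if (!length(pos)) return(NULL)
    data.frame(rank = k, id = ids[k], position = pos,
               consensus = cons_chars[pos],
               observed = strsplit(msa$sequences[k], "")[[1L]][pos],
               stringsAsFactors = FALSE)
  }))
  if (is.null(rows)) {
    rows <- data.frame(rank = integer(0), id = character(0),
                       position = integer(0), consensus = character(0),
                       observed = character(0))
  }
  write.table(rows, paste0(prefix, ".tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(paste0(prefix, ".fasta"), paste0(prefix, ".tsv")))
}

#' Export a kd-tree as a Newick string or file
#'
#' Leaves are named by sequence id (multi-member leaves expand into a
#' multifurcation of their ids); internal nodes carry their path labels.
#'
#' @param tree a [build_kdtree()] result.
#' @param path optional file to write; `NULL` returns the string.
#' @return The Newick string, invisibly when written to a file.
#' @export
kdtree_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "kd_tree"))
  esc <- function(x) gsub("[ ,:;()\\[\\]]", "_", x)
  render <- function(node) {
    if (node$leaf) {
      ids <- esc(tree$ids[node$members])
      if (length(ids) == 1L) return(ids)
      return(paste0("(", paste(ids, collapse = ","), ")", node$path))
    }
    paste0("(", render(node$left), ",", render(node$right), ")", node$path)
  }
  nwk <- paste0(render(tree$root), ";")
  if (is.null(path)) return(nwk)
  writeLines(nwk, path)
  invisible(nwk)
}

#' Export a kd-tree as nested JSON
#'
#' @param tree a [build_kdtree()] result.
#' @param path optional JSON file.
#' @return The nested list (invisibly when written).
#' @export
kdtree_json <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "kd_tree"))
  strip <- function(node) {
    out <- list(depth = node$depth, path = node$path,
                ids = tree$ids[node$members])
    if (!node$leaf) {
      out$axis <- c("x", "y")[node$axis]
      out$split <- node$split
      out$children <- list(strip(node$left), strip(node$right))
    }
    out
  }
  obj <- strip(tree$root)
  if (is.null(path)) return(obj)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(obj)
}
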