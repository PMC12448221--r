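## Per-sequence physicochemical and selection-derived annotations.

## EMBOSS-style side-chain pKa values
PKA_POS <- c(K = 10.8, R = 12.5, H = 6.5)
PKA_NEG <- c(D = 3.9, E = 4.1, C = 8.5, Y = 10.1)
PKA_NTERM <- 8.6
PKA_CTERM <- 3.6

## Kyte-Doolittle hydropathy
KD_SCALE <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
              E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
              M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
              Y = -1.3, V = 4.2)

check_aa <- function(seq, what) {
  if (!nzchar(seq)) stop(what, ": empty sequence")
  chars <- strsplit(toupper(seq), "")[[1]]
  if (detect_alphabet(seq) == "nucleotide" && nchar(seq) >= 10L) {
    stop(what, " expects an amino-acid sequence, got nucleotides")
  }
  bad <- setdiff(chars, AA_CHARS)
  if (length(bad)) {
    warning(what, ": unknown residue(s) ", paste(unique(bad), collapse = ""),
            " ignored")
    chars <- chars[chars %in% AA_CHARS]
  }
  chars
}

#' Net charge of a peptide at a given pH
#'
#' Henderson–Hasselbalch sum over ionizable side chains (K, R, H positive;
#' D, E, C, Y negative) with a fixed standard pKa table; the free termini
#' are excluded by default since variable-fragment inputs are interior
#' slices of the antibody.
#'
#' @param seq amino-acid sequence.
#' @param pH solvent pH (default 7.4, physiological).
#' @param termini include the free N/C termini.
#' @return Net charge in elementary-charge units.
#' @export
net_charge <- function(seq, pH = 7.4, termini = FALSE) {
  chars <- check_aa(seq, "net_charge")
  pos <- sum(vapply(chars[chars %in% names(PKA_POS)], function(a) {
    1 / (1 + 10^(pH - PKA_POS[[a]]))
  }, numeric(1L)))
  neg <- sum(vapply(chars[chars %in% names(PKA_NEG)], function(a) {
    1 / (1 + 10^(PKA_NEG[[a]] - pH))
  }, numeric(1L)))
  if (termini) {
    pos <- pos + 1 / (1 + 10^(pH - PKA_NTERM))
    neg <- neg + 1 / (1 + 10^(PKA_CTERM - pH))
  }
  pos - neg
}

#' Mean Kyte–Doolittle hydropathy of a peptide
#'
#' @param seq amino-acid sequence.
#' @return Mean hydropathy over residues (positive = hydrophobic).
#' @export
hydrophobicity <- function(seq) {
  chars <- check_aa(seq, "hydrophobicity")
  mean(KD_SCALE[chars])
}

#' Selection enrichment as a regularized log frequency ratio
#'
#' `ln( ((post+pc)/(post_total+pc)) / ((pre+pc)/(pre_total+pc)) )`, the
#' natural-log ratio of post- to pre-selection frequency with a
#' pseudocount added to counts and totals.
#'
#' @param pre_count,post_count per-sequence read counts before/after
#'   selection.
#' @param pre_total,post_total library totals.
#' @param pseudocount regularizer added to every count and total.
#' @return Enrichment in natural-log units (vectorized).
#' @export
enrichment <- function(pre_count, post_count, pre_total, post_total,
                       pseudocount = 1) {
  if (any(c(pre_count, post_count, pre_total, post_total) < 0)) {
    stop("counts must be non-negative")
  }
  if (any(pre_total < pre_count) || any(post_total < post_count)) {
    stop("totals must be >= counts")
  }
  log(((post_count + pseudocount) / (post_total + pseudocount)) /
      ((pre_count + pseudocount) / (pre_total + pseudocount)))
}

#' Classify an enrichment value
#'
#' Enriched above +0.05, depleted below -0.05, unclear otherwise
#' (boundary values inclusive of unclear).
#'
#' @param value enrichment value(s) in natural-log units.
#' @return Character vector in `{"enriched", "depleted", "unclear"}`.
#' @export
classify_enrichment <- function(value) {
  ifelse(value > 0.05, "enriched",
         ifelse(value < -0.05, "depleted", "unclear"))
}

#' Annotate a sequence table for map overlays
#'
#' Computes per-sequence net charge and hydrophobicity (amino-acid input
#' only), copies neighbor counts from a graph, and, when pre/post count
#' columns are named, enrichment and its class.
#'
#' @param table a [seq_table()].
#' @param graph optional [neighbor_graph] aligned with `table`.
#' @param pre_col,post_col optional names of pre-/post-selection count
#'   columns in `table`.
#' @param pseudocount see [enrichment()].
#' @return data.frame of annotation columns aligned with `table`.
#' @export
annotate_table <- function(table, graph = NULL, pre_col = NULL,
                           post_col = NULL, pseudocount = 1) {
  stopifnot(inherits(table, "seq_table"))
  out <- data.frame(row.names = seq_len(nrow(table)))
  if (attr(table, "alphabet") == "amino_acid" && nrow(table)) {
    seqs <- full_sequences(table)
    seqs_plain <- gsub("|", "", seqs, fixed = TRUE)
    out$net_charge <- vapply(seqs_plain, net_charge, numeric(1L),
                             USE.NAMES = FALSE)
    out$hydrophobicity <- vapply(seqs_plain, hydrophobicity, numeric(1L),
                                 USE.NAMES = FALSE)
  }
  if (!is.null(graph)) {
    stopifnot(length(graph$counts) == nrow(table))
    out$neighbor_count <- graph$counts
  }
  if (!is.null(pre_col) && !is.null(post_col)) {
    pre <- as.numeric(table[[pre_col]])
    post <- as.numeric(table[[post_col]])
    out$enrichment <- enrichment(pre, post, sum(pre), sum(post),
                                 pseudocount)
    out$enrichment_class <- classify_enrichment(out$enrichment)
  }
  out
}
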