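## Sequence tables: read, validate, deduplicate, group, write.

AA_CHARS <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
NT_CHARS <- c("A", "C", "G", "T")

#' Construct a validated sequence table
#'
#' A `seq_table` is a plain `data.frame` with one row per sequence and the
#' columns `id`, `fv_heavy`, `fv_light`, `hcdr3`, `lcdr3`, `read_count`
#' (additional columns are carried along as annotations, e.g. FACS bins or
#' pre/post selection counts). Either chain column may be empty, but not
#' both; each non-empty CDR3 must be a contiguous substring of its chain.
#'
#' @param df data.frame with at least an `fv_heavy` or `fv_light` column.
#' @param alphabet `"amino_acid"`, `"nucleotide"` or `NULL` to auto-detect
#'   (>= 95% of residue characters in `A,C,G,T,N` means nucleotide).
#' @param validate_cdr3 flag rows whose CDR3 is not a substring of the chain
#'   (warning + logical column `cdr3_ok`) instead of failing.
#' @return A `seq_table` (data.frame subclass) with attribute `alphabet`.
#' @export
seq_table <- function(df, alphabet = NULL, validate_cdr3 = TRUE) {
  stopifnot(is.data.frame(df))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  for (col in c("fv_heavy", "fv_light", "hcdr3", "lcdr3")) {
    if (is.null(df[[col]])) df[[col]] <- character(nrow(df))
    df[[col]] <- toupper(gsub("[[:space:]]", "", as.character(df[[col]])))
    df[[col]][is.na(df[[col]])] <- ""
  }
  if (is.null(df$id)) df$id <- sprintf("seq%06d", seq_len(nrow(df)))
  df$id <- as.character(df$id)
  dup <- df$id[duplicated(df$id)]
  if (length(dup)) {
    stop("duplicate sequence id(s): ", paste(unique(dup), collapse = ", "))
  }
  if (is.null(df$read_count)) df$read_count <- rep(1L, nrow(df))
  df$read_count <- as.integer(df$read_count)
  if (any(is.na(df$read_count)) || any(df$read_count < 1L)) {
    stop("read_count must be a positive integer for every record")
  }

  both_empty <- !nzchar(df$fv_heavy) & !nzchar(df$fv_light)
  rejected <- df[both_empty, , drop = FALSE]
  if (nrow(rejected)) {
    warning(nrow(rejected), " row(s) with both chains empty were rejected: ",
            paste(head(rejected$id, 5L), collapse = ", "),
            if (nrow(rejected) > 5L) ", ...")
    df <- df[!both_empty, , drop = FALSE]
  }

  cdr3_ok <- rep(TRUE, nrow(df))
  check <- function(cdr3, chain) {
    !nzchar(cdr3) | !nzchar(chain) |
      mapply(grepl, pattern = cdr3, x = chain,
             MoreArgs = list(fixed = TRUE))
  }
  if (nrow(df)) {
    cdr3_ok <- check(df$hcdr3, df$fv_heavy) & check(df$lcdr3, df$fv_light)
  }
  if (validate_cdr3 && any(!cdr3_ok)) {
    warning(sum(!cdr3_ok), " row(s) whose CDR3 is not a substring of its ",
            "chain were flagged (column cdr3_ok)")
    df$cdr3_ok <- cdr3_ok
  }

  first <- c("id", "fv_heavy", "fv_light", "hcdr3", "lcdr3", "read_count")
  df <- df[, c(first, setdiff(names(df), first)), drop = FALSE]
  rownames(df) <- NULL

  if (is.null(alphabet)) {
    alphabet <- detect_alphabet(c(df$fv_heavy, df$fv_light))
  }
  alphabet <- match.arg(alphabet, c("amino_acid", "nucleotide"))
  structure(df, class = c("seq_table", "data.frame"),
            alphabet = alphabet, rejected = rejected)
}

#' Auto-detect the residue alphabet of a set of sequences
#'
#' @param seqs character vector of sequences (empty strings ignored).
#' @return `"nucleotide"` if at least 95% of residue characters fall in
#'   `A,C,G,T,N`, else `"amino_acid"`. Empty input defaults to amino acid.
#' @export
detect_alphabet <- function(seqs) {
  chars <- unlist(strsplit(toupper(seqs[nzchar(seqs)]), ""), use.names = FALSE)
  if (!length(chars)) return("amino_acid")
  if (mean(chars %in% c(NT_CHARS, "N")) >= 0.95) "nucleotide" else "amino_acid"
}

#' Read a sequence table from CSV/TSV
#'
#' Expects a header row with (remappable) columns `fv_heavy`, `fv_light`,
#' `HCDR3`, `LCDR3`; either chain column may be empty or absent. Any other
#' columns are retained as annotations. The delimiter is sniffed from the
#' first line unless given.
#'
#' @param path file path.
#' @param column_map optional named character vector mapping canonical names
#'   (`fv_heavy`, `fv_light`, `hcdr3`, `lcdr3`, `id`, `read_count`) to the
#'   file's column names, e.g. `c(fv_heavy = "VH", hcdr3 = "CDRH3")`.
#' @param sep field delimiter; `NULL` sniffs `,` vs tab.
#' @param alphabet see [seq_table()].
#' @return A [seq_table()].
#' @export
read_seq_table <- function(path, column_map = NULL, sep = NULL,
                           alphabet = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  if (!length(first) || !nzchar(first)) {
    return(seq_table(data.frame(fv_heavy = character(0),
                                hcdr3 = character(0)),
                     alphabet = alphabet %||% "amino_acid"))
  }
  if (is.null(sep)) {
    sep <- if (lengths(regmatches(first, gregexpr("\t", first))) >=
               lengths(regmatches(first, gregexpr(",", first)))) "\t" else ","
  }
  df <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                 check.names = FALSE, colClasses = "character")
  canon <- c(id = "id", fv_heavy = "fv_heavy", fv_light = "fv_light",
             hcdr3 = "HCDR3", lcdr3 = "LCDR3", read_count = "read_count")
  if (!is.null(column_map)) canon[names(column_map)] <- column_map
  ## also accept already-canonical lower-case names
  for (key in names(canon)) {
    src <- if (canon[[key]] %in% names(df)) canon[[key]]
           else if (key %in% names(df)) key else NA_character_
    if (!is.na(src) && src != key) {
      names(df)[match(src, names(df))] <- key
    }
  }
  if (!("fv_heavy" %in% names(df)) && !("fv_light" %in% names(df))) {
    stop("schema error: neither fv_heavy nor fv_light column found in ", path,
         " (have: ", paste(names(df), collapse = ", "), ")")
  }
  if (!is.null(df$read_count)) df$read_count <- as.integer(df$read_count)
  for (col in c("x", "y")) if (!is.null(df[[col]])) {
    df[[col]] <- as.numeric(df[[col]])
  }
  if (!is.null(df$cluster)) df$cluster <- as.integer(df$cluster)
  seq_table(df, alphabet = alphabet)
}

#' @export
print.seq_table <- function(x, ...) {
  cat(sprintf("seq_table: %d record(s), alphabet=%s\n", nrow(x),
              attr(x, "alphabet")))
  if (!is.null(attr(x, "group_key"))) {
    cat("  group:", paste(attr(x, "group_key"), collapse = "/"), "\n")
  }
  print(head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("  ...", nrow(x) - 6L, "more row(s)\n")
  invisible(x)
}

#' Deduplicate a sequence table
#'
#' Records are merged when their `(fv_heavy, fv_light)` pair is identical
#' (after uppercasing/whitespace-stripping, done at construction).
#' `read_count` of merged records is summed; other columns keep the
#' first-seen value, with conflicts reported via the `"conflicts"`
#' attribute. Merged duplicates whose CDR3s disagree are also reported.
#'
#' @param table a [seq_table()].
#' @return A deduplicated `seq_table`; total read count is conserved.
#' @export
deduplicate <- function(table) {
  stopifnot(inherits(table, "seq_table"))
  if (!nrow(table)) return(table)
  key <- paste(table$fv_heavy, table$fv_light, sep = "\r")
  idx <- split(seq_len(nrow(table)), factor(key, levels = unique(key)))
  conflicts <- character(0)
  rows <- lapply(idx, function(i) {
    out <- table[i[1L], , drop = FALSE]
    out$read_count <- sum(table$read_count[i])
    if (length(i) > 1L) {
      for (col in setdiff(names(table), c("id", "read_count"))) {
        vals <- unique(table[[col]][i])
        if (length(vals) > 1L) {
          conflicts <<- c(conflicts, sprintf("%s[%s]", col, out$id))
        }
      }
    }
    out
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (length(conflicts)) {
    warning("merged duplicates disagreed on: ",
            paste(head(conflicts, 10L), collapse = ", "),
            if (length(conflicts) > 10L) ", ...")
  }
  structure(out, class = class(table), alphabet = attr(table, "alphabet"),
            conflicts = conflicts)
}

primary_chain_of <- function(table, primary_chain = c("auto", "heavy",
                                                      "light")) {
  primary_chain <- match.arg(primary_chain)
  if (primary_chain == "auto") {
    primary_chain <- if (any(nzchar(table$fv_heavy))) "heavy" else "light"
  }
  primary_chain
}

#' Group a sequence table by chain and CDR3 lengths
#'
#' Partitions records by the lengths of both chains and both CDR3s (so all
#' members of a group have equal-length sequences end to end — the
#' precondition for Hamming distances). Records missing the primary chain
#' are routed to a reject group named `"__reject__"`.
#'
#' @param table a [seq_table()].
#' @param primary_chain `"auto"` (heavy if any present, else light),
#'   `"heavy"` or `"light"`.
#' @param group_col optional name of a pre-computed grouping column (e.g. a
#'   V-gene call) combined into the group key.
#' @return Named list of `seq_table` groups; each carries its
#'   `group_key` attribute `(chain_length, cdr3_length)`.
#' @export
group_by_length <- function(table, primary_chain = "auto", group_col = NULL) {
  stopifnot(inherits(table, "seq_table"))
  primary_chain <- primary_chain_of(table, primary_chain)
  pc <- if (primary_chain == "heavy") table$fv_heavy else table$fv_light
  missing_pc <- !nzchar(pc)
  key <- paste(nchar(table$fv_heavy), nchar(table$fv_light),
               nchar(table$hcdr3), nchar(table$lcdr3), sep = "_")
  if (!is.null(group_col)) {
    stopifnot(group_col %in% names(table))
    key <- paste(key, table[[group_col]], sep = "_")
  }
  key[missing_pc] <- "__reject__"
  if (any(missing_pc)) {
    warning(sum(missing_pc), " record(s) missing the primary (",
            primary_chain, ") chain routed to the reject group")
  }
  out <- lapply(split(seq_len(nrow(table)), key), function(i) {
    g <- table[i, , drop = FALSE]
    rownames(g) <- NULL
    cl <- if (primary_chain == "heavy") nchar(g$fv_heavy[1L])
          else nchar(g$fv_light[1L])
    c3 <- if (primary_chain == "heavy") nchar(g$hcdr3[1L])
          else nchar(g$lcdr3[1L])
    structure(g, class = class(table), alphabet = attr(table, "alphabet"),
              group_key = c(chain_length = cl, cdr3_length = c3),
              primary_chain = primary_chain)
  })
  out
}

## Full sequence fed to Hamming / the encoder: heavy chain, then (for paired
## records) a separator and the light chain.
full_sequences <- function(table) {
  paired <- nzchar(table$fv_heavy) & nzchar(table$fv_light)
  ifelse(paired, paste(table$fv_heavy, table$fv_light, sep = "|"),
         paste0(table$fv_heavy, table$fv_light))
}

#' Write a map table (sequences + 2D coordinates + annotations) to CSV
#'
#' @param table a [seq_table()].
#' @param map2d `NULL`, an `N x 2` matrix of coordinates, a data.frame with
#'   `x`,`y` (and optionally `cluster`) columns, or an [ab_map] object whose
#'   ids are matched to the table (sequences absent from the map get `NA`
#'   coordinates and cluster `-1`).
#' @param annotations `NULL` or a data.frame of extra per-sequence columns
#'   aligned with `table`.
#' @param path output CSV path.
#' @return The path, invisibly. The file round-trips through
#'   [read_seq_table()].
#' @export
write_map_table <- function(table, map2d = NULL, annotations = NULL, path) {
  stopifnot(inherits(table, "seq_table"))
  out <- as.data.frame(table)
  if (!is.null(map2d)) {
    if (inherits(map2d, "ab_map")) {
      i <- match(out$id, map2d$ids)
      out$x <- map2d$coords[i, 1L]
      out$y <- map2d$coords[i, 2L]
    } else if (is.matrix(map2d)) {
      if (nrow(map2d) != nrow(out)) {
        stop("map2d has ", nrow(map2d), " rows but table has ", nrow(out))
      }
      out$x <- map2d[, 1L]
      out$y <- map2d[, 2L]
    } else {
      if (nrow(map2d) != nrow(out)) {
        stop("map2d has ", nrow(map2d), " rows but table has ", nrow(out))
      }
      for (col in intersect(c("x", "y", "cluster"), names(map2d))) {
        out[[col]] <- map2d[[col]]
      }
    }
  }
  if (!is.null(annotations)) {
    if (nrow(annotations) != nrow(out)) {
      stop("annotations have ", nrow(annotations), " rows but table has ",
           nrow(out))
    }
    for (col in names(annotations)) out[[col]] <- annotations[[col]]
  }
  write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read single-chain sequences from FASTA with CDR3s in a side CSV
#'
#' @param fasta_path FASTA file of chain sequences (ids from headers).
#' @param cdr3_csv optional CSV with columns `id` and `cdr3`.
#' @param chain which chain the FASTA holds, `"heavy"` or `"light"`.
#' @inheritParams seq_table
#' @return A [seq_table()].
#' @export
read_fasta_table <- function(fasta_path, cdr3_csv = NULL,
                             chain = c("heavy", "light"), alphabet = NULL) {
  chain <- match.arg(chain)
  lines <- readLines(fasta_path)
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("no FASTA headers in ", fasta_path)
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- vapply(strsplit(ids, "[ \t]"), `[[`, "", 1L)
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]), paste0, "", collapse = "")
  df <- data.frame(id = ids, stringsAsFactors = FALSE)
  df[[if (chain == "heavy") "fv_heavy" else "fv_light"]] <- unname(seqs)
  if (!is.null(cdr3_csv)) {
    cc <- read.csv(cdr3_csv, stringsAsFactors = FALSE)
    df[[if (chain == "heavy") "hcdr3" else "lcdr3"]] <-
      cc$cdr3[match(df$id, cc$id)]
  }
  seq_table(df, alphabet = alphabet)
}
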