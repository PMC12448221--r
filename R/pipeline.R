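## End-to-end orchestration: read -> dedup -> group -> graph -> encoder ->
## map -> cluster -> refine -> annotate -> score/export, per length group.

#' Assemble a full run configuration
#'
#' One serializable record of every stage's tunables, with the method's
#' standard defaults (cutoffs 5/2, at least 5 neighbors, 256-wide encoder,
#' 400/100/400 epochs, min_dist 1.0, 20 Leiden neighbors).
#'
#' @param full_cutoff,cdr3_cutoff Hamming cutoffs ([build_graph()]); set
#'   `target_mean_neighbors` to choose them adaptively instead.
#' @param target_mean_neighbors if non-`NULL`, [adaptive_cutoff()] picks
#'   the cutoffs per group.
#' @param min_neighbors minimum neighbors to keep a sequence.
#' @param encoder an [encoder_config()].
#' @param mlm_epochs,mlm_batch_size encoder pretraining budget.
#' @param schedule a [training_schedule()].
#' @param loss a [loss_config()].
#' @param leiden_k,leiden_resolution map clustering hyperparameters
#'   (low resolution keeps elongated map clusters whole; modularity at
#'   resolution 1 tends to chop the worm-shaped blobs contrastive maps
#'   produce).
#' @param refine_weight CDR3-feature refinement weight (0 disables
#'   refinement).
#' @param min_group_size groups smaller than this are skipped (reported,
#'   labels -1).
#' @param primary_chain see [group_by_length()].
#' @param seed master seed for all stages.
#' @return List of class `run_config`.
#' @export
run_config <- function(full_cutoff = 5L, cdr3_cutoff = 2L,
                       target_mean_neighbors = NULL, min_neighbors = 5L,
                       encoder = encoder_config(embed_dim = 256L),
                       mlm_epochs = 10L, mlm_batch_size = 64L,
                       schedule = training_schedule(),
                       loss = loss_config(), leiden_k = 20L,
                       leiden_resolution = 0.05, refine_weight = 0,
                       min_group_size = 20L, primary_chain = "auto",
                       seed = 1L) {
  structure(list(full_cutoff = as.integer(full_cutoff),
                 cdr3_cutoff = as.integer(cdr3_cutoff),
                 target_mean_neighbors = target_mean_neighbors,
                 min_neighbors = as.integer(min_neighbors),
                 encoder = encoder, mlm_epochs = as.integer(mlm_epochs),
                 mlm_batch_size = as.integer(mlm_batch_size),
                 schedule = schedule, loss = loss,
                 leiden_k = as.integer(leiden_k),
                 leiden_resolution = leiden_resolution,
                 refine_weight = refine_weight,
                 min_group_size = as.integer(min_group_size),
                 primary_chain = primary_chain, seed = as.integer(seed)),
            class = "run_config")
}

#' Save / load a run configuration as JSON
#'
#' The JSON round-trip is lossless: `load_config(save_config(cfg)) == cfg`.
#'
#' @param config a [run_config()].
#' @param path JSON file path.
#' @return `path` (save) / the restored `run_config` (load).
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  jsonlite::write_json(strip_classes(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  to_int <- function(x) if (is.null(x)) NULL else as.integer(x)
  run_config(
    full_cutoff = to_int(raw$full_cutoff),
    cdr3_cutoff = to_int(raw$cdr3_cutoff),
    target_mean_neighbors = raw$target_mean_neighbors,
    min_neighbors = to_int(raw$min_neighbors),
    encoder = do.call(encoder_config, raw$encoder),
    mlm_epochs = to_int(raw$mlm_epochs),
    mlm_batch_size = to_int(raw$mlm_batch_size),
    schedule = do.call(training_schedule, c(
      raw$schedule[c("stage1_epochs", "stage2_epochs", "stage3_epochs",
                     "batch_size")],
      list(lr1 = raw$schedule$lr[1L], lr2 = raw$schedule$lr[2L],
           lr3 = raw$schedule$lr[3L], seed = raw$schedule$seed))),
    loss = do.call(loss_config, raw$loss),
    leiden_k = to_int(raw$leiden_k),
    leiden_resolution = raw$leiden_resolution,
    refine_weight = raw$refine_weight,
    min_group_size = to_int(raw$min_group_size),
    primary_chain = raw$primary_chain,
    seed = to_int(raw$seed))
}

#' Run the full mapping pipeline
#'
#' Reads (or takes) a sequence table, deduplicates, groups by length,
#' pretrains one masked-LM encoder on all sequences, then per group builds
#' the neighbor graph, trains the contrastive map, clusters it with
#' Leiden, optionally refines labels with CDR3 features, annotates, and
#' writes per-group and combined map CSVs plus a metrics JSON and the
#' resolved config.
#'
#' @param input a [seq_table()] or a CSV/TSV path for [read_seq_table()].
#' @param config a [run_config()].
#' @param out_dir output directory (`NULL` skips writing files).
#' @param encoder optional pre-trained `seq_encoder` (skips pretraining).
#' @param truth_col optional name of a true-family column; if present,
#'   pairwise precision/recall/F1 and cluster-type fractions are computed
#'   (pooled across groups) against it, treating rows of the
#'   `noise_col` column (if named) marked `TRUE` as noise.
#' @param noise_col optional logical truth column marking noise sequences.
#' @param verbose log stage timings and counts.
#' @return List of class `ab_run`: the combined `table` (with `x`, `y`,
#'   `cluster`, annotation columns), per-group `maps` and `graphs`,
#'   pooled `metrics`, the `encoder`, and the resolved `config`.
#' @export
run_pipeline <- function(input, config = run_config(), out_dir = NULL,
                         encoder = NULL, truth_col = NULL, noise_col = NULL,
                         verbose = TRUE) {
  t0 <- Sys.time()
  stage <- function(name, expr) {
    t1 <- Sys.time()
    out <- tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    abmapr_msg(sprintf("%-12s %6.1fs", name,
                       as.numeric(Sys.time() - t1, units = "secs")),
               verbose = verbose)
    out
  }

  orig <- stage("read", {
    if (inherits(input, "seq_table")) input else read_seq_table(input)
  })
  table <- stage("dedup", deduplicate(orig))
  ## map unique variants back to every original row for output/scoring
  key <- paste(orig$fv_heavy, orig$fv_light, sep = "\r")
  ukey <- paste(table$fv_heavy, table$fv_light, sep = "\r")
  rep_of <- match(key, ukey)
  groups <- stage("group", group_by_length(table, config$primary_chain))
  groups <- groups[names(groups) != "__reject__"]
  sizes <- vapply(groups, nrow, integer(1L))
  skipped <- names(groups)[sizes < config$min_group_size]
  if (length(skipped)) {
    abmapr_msg("skipping ", length(skipped), " group(s) smaller than ",
               config$min_group_size, " (", sum(sizes[skipped]),
               " sequence(s))", verbose = verbose)
  }
  groups <- groups[sizes >= config$min_group_size]
  if (!length(groups)) stop("no group reaches min_group_size")

  if (is.null(encoder)) {
    encoder <- stage("pretrain", {
      cfg <- config$encoder
      cfg$seed <- config$seed
      pretrain_mlm(table, cfg, epochs = config$mlm_epochs,
                   batch_size = config$mlm_batch_size)
    })
  }

  maps <- list()
  graphs <- list()
  cluster_of <- setNames(rep(-1L, nrow(table)), table$id)
  coords_of <- matrix(NA_real_, nrow(table), 2L,
                      dimnames = list(table$id, c("x", "y")))
  label_base <- 0L

  for (gname in names(groups)) {
    g <- groups[[gname]]
    graph <- stage(paste0("graph ", gname), {
      cut <- c(config$full_cutoff, config$cdr3_cutoff)
      if (!is.null(config$target_mean_neighbors)) {
        cut <- adaptive_cutoff(g, config$target_mean_neighbors)
      }
      gr <- build_graph(g, cut[1L], cut[2L])
      filter_min_neighbors(gr, config$min_neighbors)
    })
    abmapr_msg(sprintf("  %s: %d seq, mean neighbors %.1f, kept %d",
                       gname, nrow(g), mean(graph$counts),
                       sum(graph$kept)), verbose = verbose)
    graphs[[gname]] <- graph
    if (sum(graph$kept) < max(3L, config$leiden_k + 1L)) {
      abmapr_msg("  ", gname, ": too few kept sequences; left unclustered",
                 verbose = verbose)
      next
    }
    sched <- config$schedule
    sched$seed <- config$seed
    map <- stage(paste0("map ", gname),
                 train_map(g, graph, encoder, sched, config$loss))
    labels <- stage(paste0("cluster ", gname), {
      base <- leiden_on_map(map$coords, config$leiden_k,
                            config$leiden_resolution, seed = config$seed)
      if (config$refine_weight > 0 &&
            any(nzchar(g$hcdr3[map$kept_idx])) &&
            attr(table, "alphabet") == "amino_acid") {
        feats <- cdr3_embedding(g$hcdr3[map$kept_idx])
        refine_labels(map$coords, feats, config$refine_weight,
                      config$leiden_k, config$leiden_resolution,
                      seed = config$seed)
      } else {
        base
      }
    })
    maps[[gname]] <- map
    cluster_of[g$id[map$kept_idx]] <- labels + label_base
    coords_of[g$id[map$kept_idx], ] <- map$coords
    ## sequences excluded from training are still projected with the
    ## trained model and attached to the nearest cluster within an
    ## adaptive radius (stay -1 beyond it)
    excl <- setdiff(seq_len(nrow(g)), map$kept_idx)
    if (length(excl)) {
      co_x <- predict(map, full_sequences(g)[excl])
      coords_of[g$id[excl], ] <- co_x
      att <- attach_to_clusters(co_x, map$coords, labels,
                                k = config$leiden_k)
      assigned <- att >= 0L
      cluster_of[g$id[excl[assigned]]] <- att[assigned] + label_base
    }
    label_base <- label_base + max(labels) + 1L
  }

  annotations <- stage("annotate", annotate_table(orig))
  out_table <- orig
  out_table$x <- coords_of[rep_of, 1L]
  out_table$y <- coords_of[rep_of, 2L]
  out_table$cluster <- unname(cluster_of)[rep_of]
  for (col in names(annotations)) out_table[[col]] <- annotations[[col]]

  metrics <- NULL
  if (!is.null(truth_col) && truth_col %in% names(orig)) {
    noise <- if (!is.null(noise_col) && noise_col %in% names(orig)) {
      as.logical(orig[[noise_col]])
    } else {
      rep(FALSE, nrow(orig))
    }
    prf <- pairwise_prf(orig[[truth_col]], out_table$cluster, noise)
    ctf <- cluster_type_fractions(orig[[truth_col]], out_table$cluster,
                                  noise)
    metrics <- list(precision = prf$precision, recall = prf$recall,
                    f1 = prf$f1, tp = prf$tp, fp = prf$fp, fn = prf$fn,
                    tic_fraction = ctf$tic_fraction,
                    mix_fraction = ctf$mix_fraction,
                    noise_fraction = ctf$noise_fraction,
                    n_clusters = ctf$n_clusters)
  }

  cfg_json <- jsonlite::toJSON(strip_classes(config), auto_unbox = TRUE,
                               null = "null")
  run <- structure(list(table = out_table, maps = maps, graphs = graphs,
                        metrics = metrics, encoder = encoder,
                        config = config,
                        config_hash = config_hash(as.character(cfg_json)),
                        skipped_groups = skipped),
                   class = "ab_run")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(cbind(config_hash = run$config_hash,
                    as.data.frame(out_table)),
              file.path(out_dir, "map_combined.csv"), row.names = FALSE)
    for (gname in names(maps)) {
      g <- groups[[gname]]
      sub <- out_table[match(g$id, out_table$id), , drop = FALSE]
      write.csv(cbind(config_hash = run$config_hash, as.data.frame(sub)),
                file.path(out_dir, paste0("map_group_", gname, ".csv")),
                row.names = FALSE)
    }
    if (!is.null(metrics)) {
      jsonlite::write_json(c(list(config_hash = run$config_hash), metrics),
                           file.path(out_dir, "metrics.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    save_config(config, file.path(out_dir, "config.json"))
  }
  abmapr_msg(sprintf("pipeline done in %.1fs",
                     as.numeric(Sys.time() - t0, units = "secs")),
             verbose = verbose)
  run
}

#' @export
print.ab_run <- function(x, ...) {
  cat(sprintf("ab_run: %d sequence(s), %d mapped group(s), config %s\n",
              nrow(x$table), length(x$maps), x$config_hash))
  if (!is.null(x$metrics)) {
    cat(sprintf("  precision %.3f recall %.3f F1 %.3f | TIC %.2f mix %.2f noise %.2f\n",
                x$metrics$precision, x$metrics$recall, x$metrics$f1,
                x$metrics$tic_fraction, x$metrics$mix_fraction,
                x$metrics$noise_fraction))
  }
  invisible(x)
}
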