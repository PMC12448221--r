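## Three-stage contrastive training of the 2D map, and the ab_map object.

init_projection <- function(d, seed) {
  set.seed(seed)
  list(Wl = diag(d) + matrix(rnorm(d * d, sd = 0.01), d, d),
       bl = numeric(d),
       Wh = matrix(rnorm(d * 2L, sd = 0.1), d, 2L),
       bh = numeric(2L))
}

#' Train the contrastive 2D map of a sequence group
#'
#' Runs the three-stage schedule: stage 1 trains the encoder and the
#' linear transform on the contrastive loss in the transform's
#' d-dimensional output; stage 2 freezes them and trains the 2-unit
#' projection head; stage 3 fine-tunes everything. Batches are drawn with
#' log-neighbor weighted sampling (with replacement; one epoch visits as
#' many anchors as there are kept sequences), each anchor paired with a
#' uniformly sampled neighbor. Only sequences kept by the min-neighbor
#' filter are used. Fully reproducible given the schedule seed; maps are
#' identified up to rotation/flip, so reproducibility of coordinates is
#' judged via pairwise distances.
#'
#' @param table the [seq_table()] group the graph was built from.
#' @param graph a filtered [neighbor_graph] (kept counts >= 2).
#' @param encoder a `seq_encoder` ([pretrain_mlm()] or
#'   [external_encoder()]; external encoders are not fine-tuned — stages 1
#'   and 3 then train the transform/head only).
#' @param schedule a [training_schedule()].
#' @param config a [loss_config()].
#' @param verbose log per-epoch losses.
#' @return An object of class `ab_map`: `coords` (kept x 2), `ids`,
#'   `kept_idx`, the trained `model`, `history`, and a provenance hash of
#'   schedule + loss config.
#' @export
train_map <- function(table, graph, encoder, schedule = training_schedule(),
                      config = loss_config(), verbose = FALSE) {
  stopifnot(inherits(table, "seq_table"), inherits(graph, "neighbor_graph"),
            inherits(encoder, "seq_encoder"))
  kept <- which(graph$kept)
  ## single-pass filtering can leave a few kept sequences with < 2
  ## neighbors among the kept set; they cannot anchor a positive pair or
  ## carry a positive log-weight, so they sit out of training (the
  ## pipeline still projects them afterwards)
  low <- kept[graph$counts[kept] < 2L]
  if (length(low)) {
    message("[abmapr] ", length(low), " kept sequence(s) with < 2 ",
            "post-filter neighbors sit out of training")
    kept <- setdiff(kept, low)
  }
  n_kept <- length(kept)
  if (n_kept < 3L) stop("fewer than 3 kept sequences; relax the filter")
  seqs <- full_sequences(table)
  d <- encoder$config$embed_dim
  external <- isTRUE(encoder$external)
  set.seed(schedule$seed)
  proj <- init_projection(d, schedule$seed)
  weights <- log(graph$counts[kept])

  batch_size <- schedule$batch_size
  if (batch_size > n_kept) {
    warning("batch_size clamped from ", batch_size, " to ", n_kept)
    batch_size <- n_kept
  }

  enc_params <- if (external) NULL else encoder$params
  enc_cfg <- encoder$config
  vocab <- encoder$vocab

  embed_all <- function() {
    enc <- encoder
    if (!external) enc$params <- enc_params
    embed_sequences(enc, seqs[kept])
  }
  Eall <- if (external) embed_all() else NULL

  history <- data.frame(stage = integer(0), epoch = integer(0),
                        loss = numeric(0))

  run_stage <- function(stage, epochs, lr) {
    if (epochs == 0L) return(invisible())
    train_enc <- !external && stage %in% c(1L, 3L)
    train_head <- stage %in% c(2L, 3L)
    train_linear <- stage %in% c(1L, 3L)
    params <- list()
    if (train_enc) params$enc <- enc_params
    if (train_linear) {
      params$Wl <- proj$Wl
      params$bl <- proj$bl
    }
    if (train_head) {
      params$Wh <- proj$Wh
      params$bh <- proj$bh
    }
    opt <- adam_init(params)
    zfrozen <- NULL
    if (stage == 2L) {
      E0 <- if (external) Eall else {
        enc <- encoder
        enc$params <- enc_params
        embed_sequences(enc, seqs[kept])
      }
      zfrozen <- sweep(E0 %*% proj$Wl, 2L, proj$bl, "+")
    }
    for (ep in seq_len(epochs)) {
      anchors_all <- resample(kept, n_kept, replace = TRUE, prob = weights)
      ep_loss <- 0
      nb_batches <- 0L
      for (batch in split(anchors_all,
                          ceiling(seq_along(anchors_all) / batch_size))) {
        pair <- sample_batch_pairing(graph, batch)
        M <- build_mask(pair, graph)
        nnb <- if (config$normalize_by_counts) {
          batch_neighbor_counts(pair, graph)
        } else {
          NULL
        }
        nB <- length(batch)
        allidx <- c(pair$indices, pair$partner_indices)

        if (stage == 2L) {
          z <- zfrozen[match(allidx, kept), , drop = FALSE]
          y <- sweep(z %*% params$Wh, 2L, params$bh, "+")
          cl <- contrastive_loss(y[seq_len(nB), , drop = FALSE],
                                 y[nB + seq_len(nB), , drop = FALSE],
                                 M, config, nnb, with_grad = TRUE)
          dy <- rbind(cl$dE, cl$dF)
          grads <- list(Wh = crossprod(z, dy), bh = colSums(dy))
        } else {
          if (external) {
            e <- Eall[match(allidx, kept), , drop = FALSE]
          } else {
            ## weighted sampling repeats sequences; encode each once
            uniq <- unique(allidx)
            umap <- match(allidx, uniq)
            toks <- tokenize_batch(seqs[uniq], vocab, enc_cfg$max_len,
                                   enc_cfg$pooling)
            fw <- enc_forward(params$enc, toks, enc_cfg, want_cache = TRUE)
            e <- pool_forward(fw, enc_cfg$pooling)[umap, , drop = FALSE]
          }
          z <- sweep(e %*% params$Wl, 2L, params$bl, "+")
          emb <- if (stage == 3L) {
            sweep(z %*% params$Wh, 2L, params$bh, "+")
          } else {
            z
          }
          cl <- contrastive_loss(emb[seq_len(nB), , drop = FALSE],
                                 emb[nB + seq_len(nB), , drop = FALSE],
                                 M, config, nnb, with_grad = TRUE)
          demb <- rbind(cl$dE, cl$dF)
          if (stage == 3L) {
            dz <- demb %*% t(params$Wh)
            gWh <- crossprod(z, demb)
            gbh <- colSums(demb)
          } else {
            dz <- demb
          }
          grads <- list()
          de <- dz %*% t(params$Wl)
          if (!external) {
            de_uniq <- rowsum(de, group = umap, reorder = TRUE)
            dH <- pool_backward(fw, de_uniq, enc_cfg$pooling)
            grads$enc <- enc_backward(params$enc, fw, dH, enc_cfg)
          }
          grads$Wl <- crossprod(e, dz)
          grads$bl <- colSums(dz)
          if (stage == 3L) {
            grads$Wh <- gWh
            grads$bh <- gbh
          }
        }
        grads <- grads[names(params)]
        step <- adam_step(params, grads, opt, lr = lr)
        params <- step$params
        opt <- step$state
        ep_loss <- ep_loss + cl$loss
        nb_batches <- nb_batches + 1L
      }
      history[nrow(history) + 1L, ] <<- list(stage, ep,
                                             ep_loss / nb_batches)
      abmapr_msg(sprintf("stage %d epoch %d/%d loss %.4f", stage, ep,
                         epochs, ep_loss / nb_batches), verbose = verbose)
    }
    if (train_enc) enc_params <<- params$enc
    if (train_linear) {
      proj$Wl <<- params$Wl
      proj$bl <<- params$bl
    }
    if (train_head) {
      proj$Wh <<- params$Wh
      proj$bh <<- params$bh
    }
    invisible()
  }

  run_stage(1L, schedule$stage1_epochs, schedule$lr[1L])
  run_stage(2L, schedule$stage2_epochs, schedule$lr[2L])
  run_stage(3L, schedule$stage3_epochs, schedule$lr[3L])

  enc_final <- encoder
  if (!external) enc_final$params <- enc_params
  Efin <- embed_sequences(enc_final, seqs[kept])
  z <- sweep(Efin %*% proj$Wl, 2L, proj$bl, "+")
  coords <- sweep(z %*% proj$Wh, 2L, proj$bh, "+")
  prov <- config_hash(jsonlite::toJSON(list(schedule = unclass(schedule),
                                            loss = unclass(config)),
                                       auto_unbox = TRUE))
  structure(list(coords = unname(coords), ids = graph$ids[kept],
                 kept_idx = kept,
                 model = list(encoder = enc_final, Wl = proj$Wl,
                              bl = proj$bl, Wh = proj$Wh, bh = proj$bh),
                 schedule = schedule, loss_config = config,
                 history = history, provenance = prov),
            class = "ab_map")
}

#' @export
print.ab_map <- function(x, ...) {
  cat(sprintf("ab_map: %d sequence(s) embedded in 2D (provenance %s)\n",
              nrow(x$coords), x$provenance))
  if (nrow(x$history)) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("  final training loss %.4f (stage %d, epoch %d)\n",
                last$loss, last$stage, last$epoch))
  }
  invisible(x)
}

#' @export
summary.ab_map <- function(object, ...) {
  cat(sprintf("ab_map over %d sequence(s)\n", nrow(object$coords)))
  cat("coordinate ranges:\n")
  print(apply(object$coords, 2L, range))
  if (nrow(object$history)) {
    cat("loss by stage (first/last epoch):\n")
    for (s in unique(object$history$stage)) {
      h <- object$history[object$history$stage == s, ]
      cat(sprintf("  stage %d: %.4f -> %.4f (%d epochs)\n", s,
                  h$loss[1L], h$loss[nrow(h)], nrow(h)))
    }
  }
  invisible(object)
}

#' Project new sequences onto a trained map
#'
#' @param object an [ab_map].
#' @param newdata a [seq_table()] or character vector of sequences (same
#'   alphabet/length family as the training group).
#' @param ... unused.
#' @return `N x 2` coordinate matrix.
#' @export
predict.ab_map <- function(object, newdata, ...) {
  E <- embed_sequences(object$model$encoder, newdata)
  z <- sweep(E %*% object$model$Wl, 2L, object$model$bl, "+")
  unname(sweep(z %*% object$model$Wh, 2L, object$model$bh, "+"))
}

#' Plot a contrastive 2D map
#'
#' @param x an [ab_map].
#' @param labels optional per-sequence categorical labels used for colors
#'   (e.g. Leiden clusters).
#' @param ... passed to [graphics::plot()].
#' @export
plot.ab_map <- function(x, labels = NULL, ...) {
  col <- "grey30"
  if (!is.null(labels)) {
    f <- as.factor(labels)
    pal <- hcl.colors(max(3L, nlevels(f)), "Dark 3")
    col <- pal[as.integer(f)]
  }
  plot(x$coords, col = col, pch = 16L, cex = 0.6, xlab = "map x",
       ylab = "map y", ...)
  invisible(x)
}
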