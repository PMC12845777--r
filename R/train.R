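# Desk-scale training harness: SGD with momentum over the compiled graph,
# horizontal-flip and scale-jitter augmentation, per-epoch validation
# mAP@0.5, best-epoch checkpointing and early stopping.

#' Training configuration
#'
#' Defaults follow the published schedule: 300 epochs, batch size 40,
#' learning rate 0.01, momentum 0.937, SGD, early stopping with a waiting
#' time of 100 epochs, 640 px images.  Loss gains and the anchor-matching
#' ratio threshold are the baseline family's public convention.
#'
#' @param epochs,batch_size,lr,momentum,optimizer,early_stop_patience,image_size,seed
#'   schedule parameters.
#' @param box_gain,obj_gain,cls_gain loss component weights.
#' @param balance per-scale objectness weights (strides 8/16/32).
#' @param anchor_t anchor width/height ratio threshold for assignment.
#' @param augment horizontal flip + scale jitter on training samples.
#' @param eval_conf,eval_iou decoding thresholds used for validation mAP.
#' @param eval_batch_stats validate with per-image batch statistics.
#' @param eval_every validate every this many epochs (always at the last).
#' @param lr_final final learning-rate fraction; the rate decays linearly
#'   from `lr` to `lr * lr_final` over the scheduled epochs (1 = constant).
#' @export
train_config <- function(epochs = 300L, batch_size = 40L, lr = 0.01,
                         momentum = 0.937, optimizer = "SGD",
                         early_stop_patience = 100L, image_size = 640L,
                         seed = 0L, box_gain = 0.05, obj_gain = 1.0,
                         cls_gain = 0.5, balance = c(4.0, 1.0, 0.4),
                         anchor_t = 4, augment = TRUE, eval_conf = 0.05,
                         eval_iou = 0.45, eval_every = 1L, lr_final = 1.0,
                         eval_batch_stats = FALSE) {
  stopifnot(epochs >= 1, batch_size >= 1, lr > 0, momentum >= 0,
            momentum < 1, identical(optimizer, "SGD"),
            early_stop_patience >= 1, early_stop_patience <= epochs,
            image_size %% 32 == 0)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 momentum = momentum, optimizer = optimizer,
                 early_stop_patience = as.integer(early_stop_patience),
                 image_size = as.integer(image_size), seed = as.integer(seed),
                 box_gain = box_gain, obj_gain = obj_gain,
                 cls_gain = cls_gain, balance = balance, anchor_t = anchor_t,
                 augment = isTRUE(augment), eval_conf = eval_conf,
                 eval_iou = eval_iou, eval_every = as.integer(eval_every),
                 lr_final = lr_final,
                 eval_batch_stats = isTRUE(eval_batch_stats)),
            class = "train_config")
}

## ---- augmentation -------------------------------------------------------

augment_sample <- function(img, labels) {
  d <- dim(img)
  if (stats::runif(1) < 0.5) {                    # horizontal flip
    img <- img[, , d[3]:1, drop = FALSE]
    if (nrow(labels)) labels[, 2] <- 1 - labels[, 2]
  }
  sc <- stats::runif(1, 0.9, 1.1)                 # scale jitter about centre
  if (abs(sc - 1) > 1e-3) {
    H <- d[2]; W <- d[3]
    src_r <- round((seq_len(H) - (H + 1) / 2) / sc + (H + 1) / 2)
    src_c <- round((seq_len(W) - (W + 1) / 2) / sc + (W + 1) / 2)
    ok_r <- src_r >= 1 & src_r <= H; ok_c <- src_c >= 1 & src_c <= W
    new <- array(mean(img), d)
    new[, ok_r, ok_c] <- img[, src_r[ok_r], src_c[ok_c], drop = FALSE]
    img <- new
    if (nrow(labels)) {
      labels[, 2] <- (labels[, 2] - 0.5) * sc + 0.5
      labels[, 3] <- (labels[, 3] - 0.5) * sc + 0.5
      labels[, 4] <- labels[, 4] * sc
      labels[, 5] <- labels[, 5] * sc
      x1 <- pmax(labels[, 2] - labels[, 4] / 2, 0)
      x2 <- pmin(labels[, 2] + labels[, 4] / 2, 1)
      y1 <- pmax(labels[, 3] - labels[, 5] / 2, 0)
      y2 <- pmin(labels[, 3] + labels[, 5] / 2, 1)
      labels[, 2] <- (x1 + x2) / 2; labels[, 4] <- x2 - x1
      labels[, 3] <- (y1 + y2) / 2; labels[, 5] <- y2 - y1
      labels <- labels[labels[, 4] > 0.01 & labels[, 5] > 0.01, ,
                       drop = FALSE]
    }
  }
  list(img = img, labels = labels)
}

## ---- optimiser ----------------------------------------------------------

zero_like_params <- function(params)
  lapply(params, function(p) if (is.null(p)) NULL else lapply(p, function(a) a * 0))

sgd_step <- function(params, grads, vel, lr, momentum) {
  for (i in seq_along(params)) {
    if (is.null(grads[[i]])) next
    for (nm in names(grads[[i]])) {
      g <- grads[[i]][[nm]]
      v <- momentum * vel[[i]][[nm]] - lr * g
      vel[[i]][[nm]] <- v
      params[[i]][[nm]] <- params[[i]][[nm]] + v
    }
  }
  list(params = params, vel = vel)
}

acc_grads <- function(total, g) {
  if (is.null(total)) return(g)
  for (i in seq_along(g)) {
    if (is.null(g[[i]])) next
    if (is.null(total[[i]])) total[[i]] <- g[[i]]
    else total[[i]] <- Map(`+`, total[[i]], g[[i]])
  }
  total
}

scale_grads <- function(g, f)
  lapply(g, function(p) if (is.null(p)) NULL else lapply(p, function(a) a * f))

## ---- evaluation ---------------------------------------------------------

#' Evaluate a model on a dataset split
#'
#' Runs detection on every image and scores the result with [evaluate_map()].
#'
#' @param model a `gefay_model`.
#' @param data a dataset from [load_dataset()] (list of samples with `img`
#'   and `labels`).
#' @param conf,iou decoding and NMS thresholds.
#' @param batch_stats normalise with per-image batch statistics (see
#'   [detect()]).
#' @export
evaluate_model <- function(model, data, conf = 0.05, iou = 0.45,
                           batch_stats = FALSE) {
  preds <- list(); truths <- list()
  for (i in seq_along(data)) {
    smp <- data[[i]]
    d <- dim(smp$img)
    dets <- detect(model, smp$img, conf = conf, iou = iou,
                   batch_stats = batch_stats)
    if (nrow(dets)) { dets$image <- i; preds[[length(preds) + 1L]] <- dets }
    lb <- smp$labels
    if (nrow(lb)) {
      truths[[length(truths) + 1L]] <- data.frame(
        image = i,
        x1 = (lb[, 2] - lb[, 4] / 2) * d[3], y1 = (lb[, 3] - lb[, 5] / 2) * d[2],
        x2 = (lb[, 2] + lb[, 4] / 2) * d[3], y2 = (lb[, 3] + lb[, 5] / 2) * d[2],
        class = lb[, 1])
    }
  }
  empty <- data.frame(image = integer(0), x1 = numeric(0), y1 = numeric(0),
                      x2 = numeric(0), y2 = numeric(0), score = numeric(0),
                      class = integer(0))
  p <- if (length(preds)) do.call(rbind, preds) else empty
  t <- if (length(truths)) do.call(rbind, truths) else empty[, -6]
  evaluate_map(p, t)
}

## ---- training loop ------------------------------------------------------

#' Train a detector
#'
#' SGD with momentum on the composite detection loss; keeps the best-epoch
#' weights by validation mAP@0.5 and stops early after
#' `cfg$early_stop_patience` epochs without improvement.  Fixed-seed runs
#' are reproducible on a single thread.
#'
#' @param model a `gefay_model`.
#' @param train_data,val_data datasets from [load_dataset()]; `val_data`
#'   defaults to the training set.
#' @param cfg a [train_config()].
#' @param verbose print one line per epoch.
#' @return list with `model` (best weights), `history` data.frame and
#'   `best_epoch`.
#' @export
train <- function(model, train_data, val_data = train_data,
                  cfg = train_config(), verbose = FALSE) {
  if (length(train_data) == 0) stop("empty training set", call. = FALSE)
  params <- model$params
  vel <- zero_like_params(params)
  best <- list(map = -Inf, params = params, state = model$state, epoch = 0L)
  hist <- list()
  with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$epochs)) {
      lr_e <- cfg$lr * (1 - (epoch - 1) / cfg$epochs * (1 - cfg$lr_final))
      ord <- sample(seq_along(train_data))
      ep_loss <- c(box = 0, obj = 0, cls = 0)
      nb_seen <- 0L
      for (start in seq(1, length(ord), by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1L, length(ord))]
        gtot <- NULL
        for (ii in idx) {
          smp <- train_data[[ii]]
          img <- smp$img; labels <- smp$labels
          if (cfg$augment) {
            au <- augment_sample(img, labels)
            img <- au$img; labels <- au$labels
          }
          model$params <- params
          fw <- forward_graph(model, params, img, train = TRUE, keep = TRUE)
          model$state <- fw$state
          ls <- detection_loss(model, fw$heads, labels, cfg)
          ep_loss <- ep_loss + ls$components
          gtot <- acc_grads(gtot, backward_graph(model, params, fw, ls$dheads))
        }
        gtot <- scale_grads(gtot, 1 / length(idx))
        st <- sgd_step(params, gtot, vel, lr_e, cfg$momentum)
        params <- st$params; vel <- st$vel
        nb_seen <- nb_seen + length(idx)
      }
      model$params <- params
      do_eval <- epoch %% cfg$eval_every == 0 || epoch == cfg$epochs
      vm50 <- NA_real_
      if (do_eval) {
        vm <- evaluate_model(model, val_data, conf = cfg$eval_conf,
                             iou = cfg$eval_iou,
                             batch_stats = cfg$eval_batch_stats)
        vm50 <- vm$map50
      }
      hist[[epoch]] <- data.frame(epoch = epoch,
                                  loss = sum(ep_loss) / max(nb_seen, 1),
                                  box = ep_loss["box"] / max(nb_seen, 1),
                                  obj = ep_loss["obj"] / max(nb_seen, 1),
                                  cls = ep_loss["cls"] / max(nb_seen, 1),
                                  val_map50 = vm50)
      if (verbose)
        cat(sprintf("epoch %3d  loss %.4f  val mAP@0.5 %s\n", epoch,
                    hist[[epoch]]$loss,
                    if (do_eval) sprintf("%.3f", vm50) else "-"))
      if (do_eval) {
        if (vm50 > best$map) {
          best <- list(map = vm50, params = params, state = model$state,
                       epoch = epoch)
        } else if (epoch - best$epoch >= cfg$early_stop_patience) break
      }
    }
  })
  model$params <- best$params
  model$state <- best$state
  history <- do.call(rbind, hist)
  rownames(history) <- NULL
  list(model = model, history = history, best_epoch = best$epoch,
       best_map50 = best$map)
}
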