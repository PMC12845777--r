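# Deterministic synthetic "field" scenes: a textured soil/vegetation
# background with procedural leaf-like weeds.  Each class has a distinct
# lobe count, edge exponent and hue, so classes are separable but not
# trivially so; labels are derived from the rendered per-object masks, so
# the annotation is exact by construction.

#' Scene specification for the synthetic field generator
#'
#' @param image_size square image size in pixels.
#' @param n_images number of images in the dataset.
#' @param n_classes number of weed classes (default 12).
#' @param objects_per_image inclusive integer range of instances per image.
#' @param scale_range object diameter as a fraction of the image side.
#' @param clutter background clutter level in `[0, 1]`.
#' @param seed master seed; identical specs yield byte-identical datasets.
#' @export
scene_spec <- function(image_size = 640L, n_images = 100L, n_classes = 12L,
                       objects_per_image = c(1L, 5L),
                       scale_range = c(0.12, 0.35), clutter = 0.5,
                       seed = 0L) {
  stopifnot(image_size >= 32, n_images >= 1, n_classes >= 1,
            length(objects_per_image) == 2,
            objects_per_image[1] >= 1,
            objects_per_image[2] >= objects_per_image[1],
            all(scale_range > 0), all(scale_range < 1),
            clutter >= 0, clutter <= 1)
  structure(list(image_size = as.integer(image_size),
                 n_images = as.integer(n_images),
                 n_classes = as.integer(n_classes),
                 objects_per_image = as.integer(objects_per_image),
                 scale_range = scale_range, clutter = clutter,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

class_style <- function(cl, n_classes) {
  list(lobes = 3L + cl %% 5L,
       edge = 0.55 + 0.12 * ((cl %/% 5L) %% 3L),
       rgb = grDevices::col2rgb(grDevices::hsv((cl + 0.5) / n_classes,
                                               0.55, 0.55))[, 1] / 255)
}

# Render one scene.  Object classes are drawn round-robin from a global
# counter (seeded shuffle within each cycle) so the class distribution stays
# close to uniform across the dataset.
render_scene <- function(spec, index) {
  with_seed((spec$seed * 7919L + index * 104729L) %% 2147483647L, {
    S <- spec$image_size
    img <- array(0, c(3, S, S))
    base <- c(0.32, 0.30, 0.18)
    low <- array(stats::runif(3 * 64, -1, 1), c(3, 8, 8))
    field <- local_unpool(low, S, S)
    for (ch in 1:3)
      img[ch, , ] <- base[ch] + 0.10 * spec$clutter * field[ch, , ]
    img <- img + 0.05 * spec$clutter *
      array(stats::runif(3 * S * S, -1, 1), c(3, S, S))
    # grass clutter streaks
    for (b in seq_len(round(14 * spec$clutter))) {
      cx <- stats::runif(1, 1, S); cy <- stats::runif(1, 1, S)
      rx <- stats::runif(1, S / 60, S / 14); ry <- stats::runif(1, S / 60, S / 14)
      xr <- max(1, floor(cx - rx)):min(S, ceiling(cx + rx))
      yr <- max(1, floor(cy - ry)):min(S, ceiling(cy + ry))
      d2 <- outer(((yr - cy) / ry)^2, ((xr - cx) / rx)^2, `+`)
      mk <- d2 <= 1
      g <- stats::runif(1, 0.25, 0.5)
      for (ch in 1:3) {
        patch <- img[ch, yr, xr]
        patch[mk] <- 0.6 * patch[mk] + 0.4 * c(0.2, g, 0.12)[ch]
        img[ch, yr, xr] <- patch
      }
    }
    n_obj <- sample(spec$objects_per_image[1]:spec$objects_per_image[2], 1)
    counter0 <- (index - 1L) * max(spec$objects_per_image)
    objects <- list(); boxes <- NULL
    for (oi in seq_len(n_obj)) {
      cl <- (counter0 + oi - 1L) %% spec$n_classes
      sty <- class_style(cl, spec$n_classes)
      R <- stats::runif(1, spec$scale_range[1], spec$scale_range[2]) * S / 2
      placed <- FALSE
      for (try in 1:30) {
        cx <- stats::runif(1, R + 2, S - R - 2)
        cy <- stats::runif(1, R + 2, S - R - 2)
        cand <- c(cx - R, cy - R, cx + R, cy + R)
        if (is.null(boxes) ||
            all(box_iou(matrix(cand, 1), boxes) < 0.05)) {
          placed <- TRUE; break
        }
      }
      if (!placed) next
      phi <- stats::runif(1, 0, 2 * pi)
      xr <- max(1, floor(cx - R)):min(S, ceiling(cx + R))
      yr <- max(1, floor(cy - R)):min(S, ceiling(cy + R))
      dx <- outer(rep(1, length(yr)), xr - cx)
      dy <- outer(yr - cy, rep(1, length(xr)))
      rr <- sqrt(dx^2 + dy^2)
      th <- atan2(dy, dx)
      rad <- R * (0.45 + 0.55 * abs(cos(sty$lobes * th / 2 + phi))^sty$edge)
      mk <- rr <= rad
      mk[ceiling(length(yr) / 2), ceiling(length(xr) / 2)] <- TRUE
      shade <- pmin(pmax(0.75 + 0.5 * (dx + dy) / (2 * R), 0.5), 1.25)
      for (ch in 1:3) {
        patch <- img[ch, yr, xr]
        patch[mk] <- sty$rgb[ch] * shade[mk]
        img[ch, yr, xr] <- patch
      }
      cols <- which(apply(mk, 2, any)); rows <- which(apply(mk, 1, any))
      bb <- c(x1 = xr[min(cols)] - 1, y1 = yr[min(rows)] - 1,
              x2 = xr[max(cols)], y2 = yr[max(rows)])
      boxes <- rbind(boxes, unname(bb))
      objects[[length(objects) + 1L]] <-
        list(class = cl, bbox = bb, rows = yr, cols = xr, mask = mk)
    }
    img[img < 0] <- 0; img[img > 1] <- 1
    labels <- if (length(objects)) {
      do.call(rbind, lapply(objects, function(o) {
        b <- o$bbox
        c(o$class, (b["x1"] + b["x2"]) / 2 / S, (b["y1"] + b["y2"]) / 2 / S,
          (b["x2"] - b["x1"]) / S, (b["y2"] - b["y1"]) / S)
      }))
    } else matrix(numeric(0), ncol = 5)
    list(img = img, labels = unname(labels), objects = objects)
  })
}

#' Generate a synthetic field dataset on disk
#'
#' Writes `images/{train,val,test}/*.png`, matching YOLO-format
#' `labels/{split}/*.txt` (one `class cx cy w h` line per object, normalised,
#' 0-based class ids) and a `data.yaml`, split 7:2:1 by image index.
#'
#' @param spec a [scene_spec()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a manifest data.frame (file, split, n_objects).
#' @export
generate_fields <- function(spec, out_dir) {
  stopifnot(inherits(spec, "scene_spec"))
  n <- spec$n_images
  n_tr <- round(0.7 * n); n_va <- round(0.2 * n)
  splits <- c(rep("train", n_tr), rep("val", n_va),
              rep("test", n - n_tr - n_va))
  for (s in unique(splits)) {
    dir.create(file.path(out_dir, "images", s), recursive = TRUE,
               showWarnings = FALSE)
    dir.create(file.path(out_dir, "labels", s), recursive = TRUE,
               showWarnings = FALSE)
  }
  if (!dir.exists(out_dir)) stop("cannot create ", out_dir, call. = FALSE)
  manifest <- list()
  for (i in seq_len(n)) {
    sc <- render_scene(spec, i)
    stem <- sprintf("field_%04d", i)
    ipath <- file.path(out_dir, "images", splits[i], paste0(stem, ".png"))
    lpath <- file.path(out_dir, "labels", splits[i], paste0(stem, ".txt"))
    png::writePNG(aperm(sc$img, c(2, 3, 1)), ipath)
    writeLines(apply(sc$labels, 1, function(r)
      sprintf("%d %.6f %.6f %.6f %.6f", as.integer(r[1]), r[2], r[3], r[4],
              r[5])), lpath)
    manifest[[i]] <- data.frame(file = ipath, split = splits[i],
                                n_objects = nrow(sc$labels))
  }
  yaml::write_yaml(list(path = normalizePath(out_dir), train = "images/train",
                        val = "images/val", test = "images/test",
                        nc = spec$n_classes,
                        names = sprintf("weed%02d",
                                        seq_len(spec$n_classes) - 1L)),
                   file.path(out_dir, "data.yaml"))
  invisible(do.call(rbind, manifest))
}

## ---- dataset IO ---------------------------------------------------------

#' Read a PNG image as a channel-first array
#'
#' @param path PNG file path.
#' @return array `c(3, H, W)` in `[0, 1]`.
#' @export
read_image_chw <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 2) a <- array(rep(a, 3), c(dim(a), 3))
  if (dim(a)[3] > 3) a <- a[, , 1:3, drop = FALSE]
  aperm(a, c(3, 1, 2))
}

resize_nearest_chw <- function(img, size) {
  d <- dim(img)
  if (d[2] == size && d[3] == size) return(img)
  ri <- pmin(pmax(round(seq_len(size) * d[2] / size), 1), d[2])
  ci <- pmin(pmax(round(seq_len(size) * d[3] / size), 1), d[3])
  img[, ri, ci, drop = FALSE]
}

#' Load a dataset split from disk
#'
#' Expects the layout written by [generate_fields()]: paired
#' `images/{split}` PNGs and `labels/{split}` YOLO text files, with class
#' count taken from `data.yaml`.
#'
#' @param dir dataset root containing `data.yaml`.
#' @param split one of `"train"`, `"val"`, `"test"`.
#' @param image_size optionally resize (nearest neighbour) to this square
#'   size.
#' @return list of samples, each `list(img, labels, path)`.
#' @export
load_dataset <- function(dir, split = "train", image_size = NULL) {
  meta <- yaml::read_yaml(file.path(dir, "data.yaml"))
  ipaths <- sort(list.files(file.path(dir, "images", split),
                            pattern = "\\.png$", full.names = TRUE))
  lapply(ipaths, function(ip) {
    lp <- file.path(dir, "labels", split,
                    sub("\\.png$", ".txt", basename(ip)))
    img <- read_image_chw(ip)
    labels <- if (file.exists(lp) && length(readLines(lp))) {
      m <- do.call(rbind, lapply(strsplit(readLines(lp), " +"), as.numeric))
      validate_labels(m, meta$nc, lp)
    } else matrix(numeric(0), ncol = 5)
    if (!is.null(image_size)) img <- resize_nearest_chw(img, image_size)
    list(img = img, labels = labels, path = ip)
  })
}
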