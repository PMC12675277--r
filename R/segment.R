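#' Configuration of the shoot segmentation pipeline
#'
#' Thresholds and morphological settings for extracting rosette shoots from
#' top-view RGB scans. Pixels are kept when their CIELAB coordinates satisfy
#' `a* <= a_max` (green side of the green-red axis), `b* >= b_min` (excludes
#' strongly blue pixels) and `L* >= L_min` (excludes dark background).
#' Objects smaller than `min_size_pre` pixels are discarded before a
#' morphological closing with a disk of `closing_radius` pixels, after which
#' objects smaller than `min_size_post` pixels are discarded.
#'
#' The default thresholds (-9.5 / -9.5 / 18.5) and sizes (2048 / 8 / 8192)
#' are the fixed values the pipeline was calibrated with; candidate
#' thresholds for new imaging setups can be obtained from
#' [estimate_thresholds()].
#'
#' @param a_max keep pixels with a* <= this; default -9.5.
#' @param b_min keep pixels with b* >= this; default -9.5.
#' @param L_min keep pixels with L* >= this; default 18.5.
#' @param min_size_pre pre-closing minimum object size, pixels; default 2048.
#' @param closing_radius disk radius for morphological closing, pixels;
#'   default 8.
#' @param min_size_post post-closing minimum object size, pixels; default
#'   8192.
#' @param connectivity 4 (faces only, the default) or 8 (faces + corners)
#'   for connected components.
#' @return A list of class `segmentation_config`.
#' @export
segmentation_config <- function(a_max = -9.5, b_min = -9.5, L_min = 18.5,
                                min_size_pre = 2048L, closing_radius = 8L,
                                min_size_post = 8192L, connectivity = 4L) {
  for (nm in c("min_size_pre", "closing_radius", "min_size_post")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v <= 0 || v != round(v))
      validation_error(sprintf("`%s` must be a positive integer", nm))
  }
  if (!connectivity %in% c(4L, 8L))
    validation_error("`connectivity` must be 4 or 8")
  if (any(!is.finite(c(a_max, b_min, L_min))))
    validation_error("thresholds must be finite")
  structure(list(a_max = a_max, b_min = b_min, L_min = L_min,
                 min_size_pre = as.integer(min_size_pre),
                 closing_radius = as.integer(closing_radius),
                 min_size_post = as.integer(min_size_post),
                 connectivity = as.integer(connectivity)),
            class = "segmentation_config")
}

#' Convert an sRGB image array to CIELAB
#'
#' Assumes sRGB input under the D65 illuminant; returns L* in [0, 100] and
#' signed a*, b*.
#'
#' @param img numeric array, height x width x 3, values in [0, 1].
#' @return Array height x width x 3 with CIELAB channels (L*, a*, b*).
#' @export
rgb_to_lab <- function(img) {
  check_rgb(img)
  d <- dim(img)
  lab <- grDevices::convertColor(matrix(img, ncol = 3L),
                                 from = "sRGB", to = "Lab",
                                 to.ref.white = "D65")
  array(lab, dim = d)
}

check_rgb <- function(img) {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3L] != 3L)
    validation_error("expected an RGB array of dimension height x width x 3")
  invisible(img)
}

#' Candidate CIELAB thresholds by multi-Otsu
#'
#' Converts the image to CIELAB and, per channel, returns the class
#' boundaries of a multi-Otsu split (maximising between-class variance over
#' a 256-bin histogram; 3 classes, i.e. 2 boundaries, by default). These are
#' advisory starting points for choosing fixed thresholds on a new imaging
#' setup; the segmentation defaults are not derived from them at run time.
#'
#' @param img RGB array (see [rgb_to_lab()]).
#' @param n_classes number of classes per channel; default 3.
#' @return List with per-channel numeric threshold vectors (`L`, `a`, `b`)
#'   and a logical `degenerate` flag per channel for near-constant channels.
#' @export
estimate_thresholds <- function(img, n_classes = 3L) {
  check_rgb(img)
  lab <- rgb_to_lab(img)
  out <- list()
  degenerate <- logical(3)
  names(degenerate) <- c("L", "a", "b")
  for (ch in 1:3) {
    x <- as.vector(lab[, , ch])
    if (diff(range(x)) < 1e-9) {
      degenerate[ch] <- TRUE
      out[[c("L", "a", "b")[ch]]] <- numeric(0)
    } else {
      out[[c("L", "a", "b")[ch]]] <- multi_otsu(x, n_classes = n_classes)
    }
  }
  out$degenerate <- degenerate
  out
}

# exhaustive multi-Otsu over a fixed-bin histogram: choose n_classes - 1
# cut points maximising the between-class variance sum(w_k * mu_k^2)
multi_otsu <- function(x, n_classes = 3L, n_bins = 256L) {
  if (n_classes < 2L) validation_error("`n_classes` must be >= 2")
  rng <- range(x)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  counts <- tabulate(findInterval(x, breaks, all.inside = TRUE), n_bins)
  mids <- (breaks[-1L] + breaks[-(n_bins + 1L)]) / 2
  w <- counts / sum(counts)
  cw <- cumsum(w)                 # cumulative weight
  cm <- cumsum(w * mids)          # cumulative first moment
  class_crit <- function(lo, hi) { # bins lo..hi as one class
    wk <- cw[hi] - if (lo > 1L) cw[lo - 1L] else 0
    if (wk <= 0) return(0)
    mk <- cm[hi] - if (lo > 1L) cm[lo - 1L] else 0
    mk^2 / wk
  }
  cuts <- utils::combn(seq_len(n_bins - 1L), n_classes - 1L)
  # for 3 classes this is an exhaustive scan of all boundary pairs
  best <- -Inf; best_cut <- NULL
  for (j in seq_len(ncol(cuts))) {
    ks <- cuts[, j]
    edges <- c(0L, ks, n_bins)
    crit <- 0
    for (k in seq_len(n_classes))
      crit <- crit + class_crit(edges[k] + 1L, edges[k + 1L])
    if (crit > best) { best <- crit; best_cut <- ks }
  }
  breaks[best_cut + 1L]
}

#' Segment rosette shoots from a top-view RGB scan
#'
#' Runs the fixed segmentation recipe, in order: convert to CIELAB; keep
#' pixels passing the three thresholds; drop connected components smaller
#' than `min_size_pre`; morphologically close with a disk footprint of
#' `closing_radius`; drop components smaller than `min_size_post`; label the
#' survivors and measure their pixel areas. An image with no passing objects
#' yields a valid result with `object_count = 0`.
#'
#' @param img RGB array, height x width x 3, values in [0, 1].
#' @param cfg a [segmentation_config()].
#' @return Object of class `segmentation_result`: `label_mask` (integer
#'   matrix, 0 = background, objects labelled 1..n in raster order), `areas`
#'   (pixel counts per object), `object_count`.
#' @export
segment_shoots <- function(img, cfg = segmentation_config()) {
  check_rgb(img)
  stopifnot(inherits(cfg, "segmentation_config"))
  lab <- rgb_to_lab(img)
  mask <- lab[, , 2L] <= cfg$a_max &
          lab[, , 3L] >= cfg$b_min &
          lab[, , 1L] >= cfg$L_min
  mask <- filter_small(mask, cfg$min_size_pre, cfg$connectivity)
  if (any(mask)) {
    brush <- EBImage::makeBrush(2L * cfg$closing_radius + 1L, shape = "disc")
    mask <- EBImage::closing(mask * 1, brush) > 0
  }
  mask <- filter_small(mask, cfg$min_size_post, cfg$connectivity)
  labels <- label_components(mask, cfg$connectivity)
  n <- max(labels)
  areas <- if (n > 0L) as.integer(tabulate(labels[labels > 0L], n)) else integer(0)
  structure(list(label_mask = labels, areas = areas, object_count = n),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("<segmentation_result> %d object(s)", x$object_count))
  if (x$object_count > 0)
    cat(": areas [px] =", paste(x$areas, collapse = ", "))
  cat("\n")
  invisible(x)
}

filter_small <- function(mask, min_size, connectivity) {
  labels <- label_components(mask, connectivity)
  if (max(labels) == 0L) return(mask)
  sizes <- tabulate(labels[labels > 0L], max(labels))
  keep <- which(sizes >= min_size)
  matrix(labels %in% keep, nrow(mask), ncol(mask))
}

#' Label connected components of a binary mask
#'
#' 4-connectivity uses `EBImage::bwlabel`; 8-connectivity uses a run-based
#' union-find pass (EBImage labels faces-only components). Labels are
#' renumbered 1..n in raster order.
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8.
#' @return Integer matrix of labels, 0 for background.
#' @export
label_components <- function(mask, connectivity = 4L) {
  stopifnot(is.matrix(mask))
  if (!any(mask)) return(matrix(0L, nrow(mask), ncol(mask)))
  if (connectivity == 4L) {
    lab <- EBImage::imageData(EBImage::bwlabel(mask * 1))
    storage.mode(lab) <- "integer"
  } else {
    lab <- label_components_8(mask)
  }
  renumber_labels(lab)
}

# contiguous labels 1..n ordered by first appearance in column-major raster
renumber_labels <- function(lab) {
  ids <- unique(lab[lab > 0L])
  map <- integer(max(ids))
  map[ids] <- seq_along(ids)
  out <- lab
  out[lab > 0L] <- map[lab[lab > 0L]]
  out
}

# run-length union-find labelling with corner adjacency
label_components_8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  parent <- integer(0)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  lab <- matrix(0L, nr, nc)
  prev_runs <- NULL   # data.frame: start, end, id (runs of previous column)
  for (j in seq_len(nc)) {
    col <- mask[, j]
    if (!any(col)) { prev_runs <- NULL; next }
    r <- rle(col)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    idx <- which(r$values)
    runs <- data.frame(start = starts[idx], end = ends[idx], id = NA_integer_)
    for (k in seq_len(nrow(runs))) {
      touch <- integer(0)
      if (!is.null(prev_runs)) {
        # 8-connectivity: overlap allowing diagonal contact
        hit <- prev_runs$end >= runs$start[k] - 1L &
               prev_runs$start <= runs$end[k] + 1L
        touch <- prev_runs$id[hit]
      }
      if (length(touch) == 0L) {
        parent[length(parent) + 1L] <- length(parent) + 1L
        runs$id[k] <- length(parent)
      } else {
        roots <- unique(vapply(touch, find, integer(1)))
        runs$id[k] <- roots[1L]
        for (r2 in roots[-1L]) parent[r2] <- roots[1L]
      }
      lab[runs$start[k]:runs$end[k], j] <- runs$id[k]
    }
    prev_runs <- runs
  }
  lab[lab > 0L] <- vapply(lab[lab > 0L], find, integer(1))
  lab
}

#' Tabulate measured object areas
#'
#' Per-object areas in pixels and, when the scan resolution is supplied, in
#' square millimetres (`mm2 = px * (25.4 / dpi)^2`). Rows are sorted by
#' descending area.
#'
#' @param result a `segmentation_result`.
#' @param dpi optional scan resolution, dots per inch; > 0.
#' @return data.frame with columns `object`, `area_px` and, with `dpi`,
#'   `area_mm2`.
#' @export
areas_report <- function(result, dpi = NULL) {
  stopifnot(inherits(result, "segmentation_result"))
  if (!is.null(dpi)) check_number(dpi, "dpi", min = 0, strict = TRUE)
  if (result$object_count == 0L) {
    out <- data.frame(object = integer(0), area_px = integer(0))
    if (!is.null(dpi)) out$area_mm2 <- numeric(0)
    return(out)
  }
  ord <- order(result$areas, decreasing = TRUE)
  out <- data.frame(object = ord, area_px = result$areas[ord])
  if (!is.null(dpi)) out$area_mm2 <- out$area_px * (25.4 / dpi)^2
  out
}
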