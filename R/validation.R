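# Technical validation of DCIS segmentation against pathologist
# annotations: per-slide intersection-over-union of the DCIS class
# area, and Pearson correlation of duct counts.

#' Intersection-over-union of two region sets
#'
#' `|P intersect A| / |P union A|` over DCIS-class area. Inputs are
#' either two `label_mask`s on the same pixel grid (pixel counting of
#' the duct class) or two sets of polygons in microns (lists of vertex
#' matrices, a single matrix, an `annotation_set`, or a
#' [slide_objects] table, whose DCIS/duct polygons are used). The
#' polygon path is exact for convex polygons -- within each set the
#' polygons must be disjoint, as segmented ducts are -- and falls back
#' to rasterization at `raster_mpp` with a warning when a non-convex
#' polygon is present. Both sets empty is degenerate and returns 1 with
#' a warning.
#'
#' @param predicted,annotated region sets (same representation).
#' @param raster_mpp pixel size of the rasterized fallback (um).
#' @return IOU in `[0, 1]`.
#' @export
iou_score <- function(predicted, annotated, raster_mpp = 1) {
  if (inherits(predicted, "label_mask") &&
      inherits(annotated, "label_mask")) {
    if (!isTRUE(all.equal(predicted$microns_per_pixel,
                          annotated$microns_per_pixel)))
      stop("masks have different microns_per_pixel; reproject first")
    if (!all(dim(predicted$pixels) == dim(annotated$pixels)))
      stop("masks have different pixel dimensions")
    p <- predicted$pixels == 2L
    a <- annotated$pixels == 2L
    return(iou_binary(p, a))
  }
  p <- as_polygon_set(predicted)
  a <- as_polygon_set(annotated)
  if (!length(p) && !length(a)) {
    warning("both region sets empty; IOU defined as 1")
    return(1)
  }
  if (!length(p) || !length(a)) return(0)
  if (all(vapply(c(p, a), poly_is_convex, logical(1)))) {
    # bounding-box prefilter: disjoint pairs contribute nothing, and
    # identical polygons (a detection reproducing an annotation
    # exactly) intersect in themselves without clipping
    bb <- function(poly) c(range(poly[, 1]), range(poly[, 2]))
    bp <- vapply(p, bb, numeric(4))
    ba <- vapply(a, bb, numeric(4))
    area_p <- vapply(p, poly_area, numeric(1))
    inter <- 0
    for (i in seq_along(p)) for (j in seq_along(a)) {
      if (bp[2, i] < ba[1, j] || ba[2, j] < bp[1, i] ||
          bp[4, i] < ba[3, j] || ba[4, j] < bp[3, i]) next
      pp <- p[[i]]; aa <- a[[j]]
      if (nrow(pp) == nrow(aa) && max(abs(pp - aa)) < 1e-12) {
        inter <- inter + area_p[i]
        next
      }
      cl <- convex_clip(pp, aa)
      if (!is.null(cl)) inter <- inter + poly_area(cl)
    }
    ap <- sum(area_p)
    aa_ <- sum(vapply(a, poly_area, numeric(1)))
    # clamp out floating-point residue from the clipping step
    return(min(1, max(0, inter / (ap + aa_ - inter))))
  }
  warning("non-convex polygon present; using rasterized IOU at ",
          raster_mpp, " um/px")
  allxy <- do.call(rbind, c(p, a))
  nc <- ceiling(max(allxy[, 1]) / raster_mpp) + 2L
  nr <- ceiling(max(allxy[, 2]) / raster_mpp) + 2L
  rast <- function(polys) {
    m <- matrix(FALSE, nr, nc)
    for (poly in polys) {
      g <- expand.grid(r = seq_len(nr), c = seq_len(nc))
      inside <- points_in_polygon((g$c - 0.5) * raster_mpp,
                                  (g$r - 0.5) * raster_mpp, poly)
      m[cbind(g$r[inside], g$c[inside])] <- TRUE
    }
    m
  }
  iou_binary(rast(p), rast(a))
}

iou_binary <- function(p, a) {
  u <- sum(p | a)
  if (u == 0) {
    warning("both region sets empty; IOU defined as 1")
    return(1)
  }
  sum(p & a) / u
}

as_polygon_set <- function(x) {
  if (inherits(x, "slide_objects")) {
    sel <- x$objects$class == "duct"
    polys <- x$objects$polygon[sel]
    if (any(vapply(polys, is.null, logical(1))))
      stop("slide ducts lack polygons; use the mask IOU path")
    return(polys)
  }
  if (inherits(x, "annotation_set")) {
    sel <- toupper(x$polygons$class) %in% c("DCIS", "DUCT")
    return(x$polygons$polygon[sel])
  }
  if (is.matrix(x)) return(list(x))
  if (is.list(x)) return(x)
  stop("unsupported region set representation: ", class(x)[1])
}

#' Summarize per-slide IOU scores
#'
#' Median and interquartile range with type-7 (linear interpolation)
#' quantiles, the R default, so results are bit-reproducible.
#'
#' @param scores numeric vector of per-slide IOU values in `[0, 1]`.
#' @return object of class `iou_summary`: median, IQR, quartiles,
#'   n_slides, scores.
#' @export
iou_summary <- function(scores) {
  if (!length(scores)) stop("no IOU scores supplied")
  stopifnot(all(scores >= 0 & scores <= 1))
  q <- stats::quantile(scores, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  structure(list(median = q[2], iqr = q[3] - q[1],
                 q25 = q[1], q75 = q[3],
                 n_slides = length(scores), scores = scores),
            class = "iou_summary")
}

#' @export
print.iou_summary <- function(x, ...) {
  cat(sprintf("<iou_summary> median %.3f (IQR %.3f-%.3f), n=%d\n",
              x$median, x$q25, x$q75, x$n_slides))
  invisible(x)
}

#' Pearson correlation of predicted vs annotated duct counts
#'
#' Pearson r with a 95% Fisher-z confidence interval and a two-sided
#' test, as implemented by `stats::cor.test`.
#'
#' @param pred_counts,annot_counts paired duct counts (n >= 3).
#' @return object of class `count_correlation`: r, CI, p, n.
#' @export
duct_count_correlation <- function(pred_counts, annot_counts) {
  stopifnot(length(pred_counts) == length(annot_counts))
  if (length(pred_counts) < 3L) stop("need at least 3 paired counts")
  if (stats::sd(pred_counts) == 0 || stats::sd(annot_counts) == 0)
    stop("zero variance in counts; correlation undefined")
  ct <- stats::cor.test(pred_counts, annot_counts, method = "pearson",
                        conf.level = 0.95)
  structure(list(r = unname(ct$estimate), ci95 = as.numeric(ct$conf.int),
                 p = ct$p.value, n = length(pred_counts)),
            class = "count_correlation")
}

#' @export
print.count_correlation <- function(x, ...) {
  cat(sprintf("<count_correlation> r = %.3f (95%% CI %.3f-%.3f), p = %.3g, n = %d\n",
              x$r, x$ci95[1], x$ci95[2], x$p, x$n))
  invisible(x)
}
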