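# Deterministic static SVG rendering of a heatmap document: column
# dendrogram on top, row dendrogram on the left, heatmap in the centre,
# metadata columns (their own colour scale) on the right. Identical
# (document, options) input yields byte-identical SVG output.

#' Named sequential colour scales
#'
#' Each scale is a vector of hex colour stops interpolated linearly.
#' @return Named list of character vectors.
#' @export
colour_scales <- function() {
  list(
    Greys  = c("#FFFFFF", "#878787", "#000000"),
    Reds   = c("#FFF5F0", "#FB6A4A", "#67000D"),
    Blues  = c("#F7FBFF", "#6BAED6", "#08306B"),
    Greens = c("#F7FCF5", "#74C476", "#00441B"),
    BuWhRd = c("#2166AC", "#F7F7F7", "#B2182B"),
    YlGnBu = c("#FFFFD9", "#41B6C4", "#081D58"),
    YlOrRd = c("#FFFFCC", "#FD8D3C", "#800026"))
}

# fixed qualitative palette for categorical metadata
CATEGORICAL_PALETTE <- c("#8DD3C7", "#FFFFB3", "#BEBADA", "#FB8072",
                         "#80B1D3", "#FDB462", "#B3DE69", "#FCCDE5",
                         "#D9D9D9", "#BC80BD", "#CCEBC5", "#FFED6F")

#' Map a numeric value to a colour on a named scale
#'
#' Linear interpolation across the scale's stops; values outside `[lo, hi]`
#' are clamped, and a degenerate range (`lo == hi`) maps every value to the
#' scale midpoint.
#'
#' @param value numeric value.
#' @param lo,hi range endpoints, `lo <= hi`.
#' @param scale name of a scale from [colour_scales()].
#' @return Hex colour string `#RRGGBB`.
#' @examples
#' value_to_colour(0.5, 0, 1, "BuWhRd")
#' @export
value_to_colour <- function(value, lo, hi, scale = "BuWhRd") {
  stops <- colour_scales()[[scale]]
  if (is.null(stops)) stop(sprintf("unknown colour scale '%s'", scale))
  if (is.na(value)) return("#FFFFFF")
  t <- if (lo == hi) 0.5 else min(1, max(0, (value - lo) / (hi - lo)))
  pos <- t * (length(stops) - 1L)
  i <- min(floor(pos), length(stops) - 2L)
  frac <- pos - i
  rgb_lo <- grDevices::col2rgb(stops[i + 1L])[, 1L]
  rgb_hi <- grDevices::col2rgb(stops[i + 2L])[, 1L]
  mix <- round(rgb_lo + frac * (rgb_hi - rgb_lo))
  sprintf("#%02X%02X%02X", mix[1L], mix[2L], mix[3L])
}

#' Rendering options
#'
#' @param data_scale colour scale name for the data heatmap.
#' @param metadata_scale colour scale name for numeric metadata columns
#'   (metadata always use a scale independent of the data's).
#' @param heatmap_visible logical; when `FALSE` the data cells are omitted
#'   and only the dendrogram(s) and metadata are drawn.
#' @param highlight character vector of leaf IDs to highlight.
#' @param highlight_scale scale used for the highlight overlay (default
#'   `"Reds"`).
#' @param cell_w,cell_h cell size in pixels (positive).
#' @param font_size label font size in pixels.
#' @param per_column_range logical; colour each data column by its own
#'   min/max instead of the document-wide range.
#' @return An object of class `render_options`.
#' @export
render_options <- function(data_scale = "BuWhRd", metadata_scale = "YlGnBu",
                           heatmap_visible = TRUE, highlight = character(0L),
                           highlight_scale = "Reds", cell_w = 14, cell_h = 12,
                           font_size = 10, per_column_range = FALSE) {
  reg <- names(colour_scales())
  for (s in c(data_scale, metadata_scale, highlight_scale)) {
    if (!s %in% reg) stop(sprintf("unknown colour scale '%s'", s))
  }
  if (cell_w <= 0 || cell_h <= 0) stop("cell size must be positive")
  structure(list(data_scale = data_scale, metadata_scale = metadata_scale,
                 heatmap_visible = isTRUE(heatmap_visible),
                 highlight = as.character(highlight),
                 highlight_scale = highlight_scale,
                 cell_w = cell_w, cell_h = cell_h, font_size = font_size,
                 per_column_range = isTRUE(per_column_range)),
            class = "render_options")
}

fmt_px <- function(x) sprintf("%.2f", x)

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  x
}

svg_rect <- function(x, y, w, h, fill, class, opacity = NULL) {
  sprintf('<rect class="%s" x="%s" y="%s" width="%s" height="%s" fill="%s"%s/>',
          class, fmt_px(x), fmt_px(y), fmt_px(w), fmt_px(h), fill,
          if (is.null(opacity)) "" else sprintf(' fill-opacity="%s"', opacity))
}

svg_polyline <- function(pts, class) {
  sprintf('<polyline class="%s" points="%s" fill="none" stroke="#333333" stroke-width="1"/>',
          class, paste(vapply(pts, function(p) {
            paste0(fmt_px(p[1L]), ",", fmt_px(p[2L]))
          }, character(1L)), collapse = " "))
}

# node -> coordinate along the item axis (centre of its leaf span) and
# coordinate along the distance axis
dendro_segments <- function(tree, item_pos, dist_to_px) {
  pos <- new.env(parent = emptyenv())
  for (id in names(item_pos)) assign(id, item_pos[[id]], envir = pos)
  segs <- list()
  walk <- function(id) {
    nd <- tree$nodes[[id]]
    if (is.null(nd$left_child)) return(get(id, envir = pos))
    yl <- walk(nd$left_child)
    yr <- walk(nd$right_child)
    xl <- dist_to_px(tree$nodes[[nd$left_child]]$distance)
    xr <- dist_to_px(tree$nodes[[nd$right_child]]$distance)
    xn <- dist_to_px(nd$distance)
    segs[[length(segs) + 1L]] <<- list(xl = xl, yl = yl, xr = xr, yr = yr,
                                       xn = xn)
    y <- (yl + yr) / 2
    assign(id, y, envir = pos)
    y
  }
  walk(tree$root_id)
  segs
}

#' Render a heatmap document as SVG
#'
#' Draws the row dendrogram (left), the data heatmap (centre, omitted when
#' `heatmap_visible` is `FALSE`), metadata columns (right, numeric columns on
#' the metadata scale, categorical columns on a fixed qualitative palette)
#' and, when present, the column dendrogram (top). Highlighted leaves get a
#' translucent overlay in the highlight scale's strongest colour. Dendrogram
#' branches are placed linearly in merge distance, so deeper merges are drawn
#' farther from the leaves. Output is deterministic: the same document and
#' options always produce identical bytes.
#'
#' @param doc a valid `heatmap_document`.
#' @param opts a [render_options] object.
#' @return SVG 1.1 document as a character scalar.
#' @export
render_svg <- function(doc, opts = render_options()) {
  problems <- validate_document(doc)
  if (length(problems) > 0L) {
    stop(paste(c("refusing to render an invalid document:",
                 paste0("  - ", problems)), collapse = "\n"))
  }
  tree <- doc$data$nodes
  leaves <- leaf_order(tree)
  n <- length(leaves)
  m <- length(doc$data$feature_names)
  meta <- doc$metadata
  mm <- if (is.null(meta)) 0L else length(meta$feature_names)

  margin <- 10
  dendro_w <- 80
  col_dendro_h <- if (is.null(doc$column_dendrogram)) 0 else 60
  gap <- 6
  heat_w <- if (opts$heatmap_visible) m * opts$cell_w else 0
  meta_w <- if (mm > 0L) mm * opts$cell_w + gap else 0
  label_w <- 90
  width <- margin * 2 + dendro_w + gap + heat_w + meta_w + label_w
  top <- margin + col_dendro_h + gap
  height <- top + n * opts$cell_h + margin

  out <- character(0L)
  emit <- function(s) out <<- c(out, s)
  emit(sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" version="1.1" ',
                      'width="%s" height="%s">'), fmt_px(width), fmt_px(height)))
  emit(sprintf('<rect x="0" y="0" width="%s" height="%s" fill="#FFFFFF"/>',
               fmt_px(width), fmt_px(height)))

  row_y <- stats::setNames((seq_len(n) - 0.5) * opts$cell_h + top, leaves)

  # row dendrogram (left)
  maxd <- max(tree$nodes[[tree$root_id]]$distance,
              vapply(names(tree$nodes),
                     function(id) tree$nodes[[id]]$distance, numeric(1L)))
  if (maxd <= 0) maxd <- 1
  dist_to_px <- function(d) margin + (1 - d / maxd) * dendro_w
  for (seg in dendro_segments(tree, as.list(row_y), dist_to_px)) {
    emit(svg_polyline(list(c(seg$xl, seg$yl), c(seg$xn, seg$yl),
                           c(seg$xn, seg$yr), c(seg$xr, seg$yr)),
                      "row-dendro"))
  }

  heat_x <- margin + dendro_w + gap
  # data heatmap
  if (opts$heatmap_visible) {
    featmat <- t(vapply(leaves, function(id) tree$nodes[[id]]$features,
                        numeric(m)))
    if (m == 1L) featmat <- matrix(featmat, ncol = 1L)
    lo_all <- min(featmat); hi_all <- max(featmat)
    for (j in seq_len(m)) {
      lo <- if (opts$per_column_range) min(featmat[, j]) else lo_all
      hi <- if (opts$per_column_range) max(featmat[, j]) else hi_all
      for (i in seq_len(n)) {
        emit(svg_rect(heat_x + (j - 1L) * opts$cell_w,
                      top + (i - 1L) * opts$cell_h,
                      opts$cell_w, opts$cell_h,
                      value_to_colour(featmat[i, j], lo, hi, opts$data_scale),
                      "data-cell"))
      }
    }
  }

  # column dendrogram (top), over the heatmap columns
  if (!is.null(doc$column_dendrogram) && opts$heatmap_visible) {
    ctree <- doc$column_dendrogram
    cleaves <- leaf_order(ctree)
    col_x <- stats::setNames((seq_along(cleaves) - 0.5) * opts$cell_w + heat_x,
                             cleaves)
    cmax <- max(vapply(names(ctree$nodes),
                       function(id) ctree$nodes[[id]]$distance, numeric(1L)))
    if (cmax <= 0) cmax <- 1
    cdist_to_px <- function(d) margin + (1 - d / cmax) * col_dendro_h
    for (seg in dendro_segments(ctree, as.list(col_x), cdist_to_px)) {
      # item axis is horizontal here: swap coordinate roles
      emit(svg_polyline(list(c(seg$yl, seg$xl), c(seg$yl, seg$xn),
                             c(seg$yr, seg$xn), c(seg$yr, seg$xr)),
                        "col-dendro"))
    }
  }

  # metadata columns (right of the heatmap), independent colour scale
  meta_x <- heat_x + heat_w + (if (mm > 0L) gap else 0)
  if (mm > 0L) {
    for (j in seq_len(mm)) {
      cells <- lapply(leaves, function(id) meta$nodes[[id]][[j]])
      nums <- suppressWarnings(vapply(cells, function(c0) {
        if (is.null(c0) || is.na(c0)) NA_real_ else as.numeric(c0)
      }, numeric(1L)))
      numeric_col <- all(is.na(nums) == vapply(cells, function(c0) {
        is.null(c0) || (length(c0) == 1L && is.na(c0))
      }, logical(1L))) && any(!is.na(nums))
      if (numeric_col) {
        lo <- min(nums, na.rm = TRUE); hi <- max(nums, na.rm = TRUE)
        fills <- vapply(nums, value_to_colour, character(1L),
                        lo = lo, hi = hi, scale = opts$metadata_scale)
      } else {
        labels <- vapply(cells, function(c0) {
          if (is.null(c0) || is.na(c0)) NA_character_ else as.character(c0)
        }, character(1L))
        lv <- sort(unique(labels[!is.na(labels)]))
        fills <- ifelse(is.na(labels), "#FFFFFF",
                        CATEGORICAL_PALETTE[(match(labels, lv) - 1L) %%
                                              length(CATEGORICAL_PALETTE) + 1L])
      }
      for (i in seq_len(n)) {
        emit(svg_rect(meta_x + (j - 1L) * opts$cell_w,
                      top + (i - 1L) * opts$cell_h,
                      opts$cell_w, opts$cell_h, fills[i], "meta-cell"))
      }
    }
  }

  # highlight overlays across heatmap + metadata
  hi_col <- utils::tail(colour_scales()[[opts$highlight_scale]], 1L)
  for (id in opts$highlight) {
    i <- match(id, leaves)
    if (is.na(i)) next
    emit(svg_rect(heat_x, top + (i - 1L) * opts$cell_h,
                  heat_w + meta_w, opts$cell_h, hi_col, "highlight",
                  opacity = "0.35"))
  }

  # row labels: the leaf's objects, comma-joined
  label_x <- meta_x + (if (mm > 0L) mm * opts$cell_w else 0) + gap
  for (i in seq_len(n)) {
    objs <- paste(tree$nodes[[leaves[i]]]$objects, collapse = ",")
    emit(sprintf('<text class="row-label" x="%s" y="%s" font-size="%s" font-family="sans-serif">%s</text>',
                 fmt_px(label_x), fmt_px(row_y[[i]] + opts$font_size / 3),
                 fmt_px(opts$font_size), xml_escape(objs)))
  }

  emit("</svg>")
  paste(out, collapse = "\n")
}
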