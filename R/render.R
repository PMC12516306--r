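# Device handling and grid drawing: the combined triangular figure plus one
# dot plot per pair, each as PNG (raster) and PDF (vector).

cell_viewport <- function(box, xscale, yscale, clip = "on") {
  grid::viewport(x = grid::unit(box[1], "npc"), y = grid::unit(box[2], "npc"),
                 width = grid::unit(box[3] - box[1], "npc"),
                 height = grid::unit(box[4] - box[2], "npc"),
                 just = c("left", "bottom"),
                 xscale = xscale, yscale = yscale, clip = clip)
}

draw_cell <- function(box, cell, layout, style) {
  ax <- cell_axes(layout, cell$i, cell$j)
  xlen <- layout$lengths[[ax$x_seq]]
  ylen <- layout$lengths[[ax$y_seq]]
  vp <- cell_viewport(box, c(0, xlen), c(0, ylen))
  grid::pushViewport(vp)

  bl <- cell$bp_lines
  if (nrow(bl) > 0) {
    # target-axis coordinates are vertical lines when the target is on x
    for (r in seq_len(nrow(bl))) {
      on_x <- (bl$axis[r] == "t") == (ax$t_axis == "x")
      gp <- grid::gpar(col = style$bp_color, lwd = style$bp_lwidth)
      if (on_x) {
        grid::grid.lines(x = grid::unit(rep(bl$coord[r], 2), "native"),
                         y = grid::unit(c(0, ylen), "native"), gp = gp)
      } else {
        grid::grid.lines(x = grid::unit(c(0, xlen), "native"),
                         y = grid::unit(rep(bl$coord[r], 2), "native"), gp = gp)
      }
    }
  }

  seg <- cell$segments
  if (nrow(seg) > 0) {
    if (ax$t_axis == "x") {
      x0 <- seg$t0; y0 <- seg$q0; x1 <- seg$t1; y1 <- seg$q1
    } else {
      x0 <- seg$q0; y0 <- seg$t0; x1 <- seg$q1; y1 <- seg$t1
    }
    grid::grid.segments(x0 = grid::unit(x0, "native"),
                        y0 = grid::unit(y0, "native"),
                        x1 = grid::unit(x1, "native"),
                        y1 = grid::unit(y1, "native"),
                        gp = grid::gpar(col = seg$color, lwd = seg$width,
                                        lineend = "round"))
  }
  grid::popViewport()
  # border drawn unclipped so it stays crisp
  grid::grid.rect(x = grid::unit(box[1], "npc"), y = grid::unit(box[2], "npc"),
                  width = grid::unit(box[3] - box[1], "npc"),
                  height = grid::unit(box[4] - box[2], "npc"),
                  just = c("left", "bottom"),
                  gp = grid::gpar(fill = NA, col = "grey40", lwd = 0.6))
}

draw_track <- function(box, track, len) {
  grid::grid.rect(x = grid::unit(box[1], "npc"), y = grid::unit(box[2], "npc"),
                  width = grid::unit(box[3] - box[1], "npc"),
                  height = grid::unit(box[4] - box[2], "npc"),
                  just = c("left", "bottom"),
                  gp = grid::gpar(fill = NA, col = "grey70", lwd = 0.4))
  if (nrow(track) == 0) return(invisible())
  vp <- cell_viewport(box, c(0, len), c(0, 1))
  grid::pushViewport(vp)
  grid::grid.rect(x = grid::unit(track$start, "native"),
                  y = grid::unit(0.1, "native"),
                  width = grid::unit(track$end - track$start, "native"),
                  height = grid::unit(0.8, "native"),
                  just = c("left", "bottom"),
                  gp = grid::gpar(fill = track$fill, col = NA))
  grid::popViewport()
}

draw_legend <- function(box, legend) {
  if (legend$type == "swatch") {
    grid::grid.rect(x = grid::unit(box[1], "npc"),
                    y = grid::unit(box[2], "npc"),
                    width = grid::unit(0.03, "npc"),
                    height = grid::unit(box[4] - box[2], "npc") * 0.6,
                    just = c("left", "bottom"),
                    gp = grid::gpar(fill = legend$colors[1], col = "grey40"))
    grid::grid.text("alignments",
                    x = grid::unit(box[1] + 0.04, "npc"),
                    y = grid::unit((box[2] + box[4]) / 2, "npc"),
                    just = "left", gp = grid::gpar(cex = 0.7))
    return(invisible())
  }
  bar_y0 <- box[2] + (box[4] - box[2]) * 0.45
  grid::grid.raster(matrix(legend$colors, nrow = 1),
                    x = grid::unit(box[1], "npc"),
                    y = grid::unit(bar_y0, "npc"),
                    width = grid::unit(box[3] - box[1], "npc"),
                    height = grid::unit(box[4] - bar_y0, "npc"),
                    just = c("left", "bottom"), interpolate = FALSE)
  grid::grid.rect(x = grid::unit(box[1], "npc"), y = grid::unit(bar_y0, "npc"),
                  width = grid::unit(box[3] - box[1], "npc"),
                  height = grid::unit(box[4] - bar_y0, "npc"),
                  just = c("left", "bottom"),
                  gp = grid::gpar(fill = NA, col = "grey40", lwd = 0.5))
  grid::grid.text(sprintf("%g", legend$pi_min),
                  x = grid::unit(box[1], "npc"),
                  y = grid::unit(box[2], "npc"),
                  just = c("left", "bottom"), gp = grid::gpar(cex = 0.65))
  grid::grid.text(sprintf("%g", legend$pi_max),
                  x = grid::unit(box[3], "npc"),
                  y = grid::unit(box[2], "npc"),
                  just = c("right", "bottom"), gp = grid::gpar(cex = 0.65))
  grid::grid.text("Percent identity",
                  x = grid::unit((box[1] + box[3]) / 2, "npc"),
                  y = grid::unit(box[2], "npc"),
                  just = c("centre", "bottom"), gp = grid::gpar(cex = 0.65))
}

draw_matrix_figure <- function(render_data, style) {
  layout <- render_data$layout
  grid::grid.newpage()
  for (key in names(render_data$cells)) {
    draw_cell(layout$cell_boxes[[key]], render_data$cells[[key]],
              layout, style)
  }
  if (layout$show_annot) {
    for (sid in names(layout$annot_boxes)) {
      draw_track(layout$annot_boxes[[sid]], render_data$tracks[[sid]],
                 layout$lengths[[sid]])
    }
  }
  lb <- layout$labels
  for (r in seq_len(nrow(lb))) {
    grid::grid.text(lb$label[r],
                    x = grid::unit(lb$x[r], "npc"),
                    y = grid::unit(lb$y[r], "npc"),
                    rot = lb$rot[r], hjust = lb$hjust[r],
                    gp = grid::gpar(cex = 0.8))
  }
  draw_legend(layout$legend_box, render_data$legend)
}

# Single pairwise panel: target on x, query on y, legend below.
draw_pair_figure <- function(cell, tid, qid, tlab, qlab, tlen, qlen,
                             legend, style) {
  grid::grid.newpage()
  box <- c(0.12, 0.22, 0.95, 0.88)
  local_axes <- list(x_seq = cell$i, y_seq = cell$j, t_axis = "x")
  draw_cell_local(box, cell, local_axes, tlen, qlen, style)
  grid::grid.text(tlab, x = grid::unit(mean(box[c(1, 3)]), "npc"),
                  y = grid::unit(0.93, "npc"), gp = grid::gpar(cex = 0.9))
  grid::grid.text(qlab, x = grid::unit(0.05, "npc"),
                  y = grid::unit(mean(box[c(2, 4)]), "npc"),
                  rot = 90, gp = grid::gpar(cex = 0.9))
  draw_legend(c(0.3, 0.04, 0.7, 0.12), legend)
  invisible(TRUE)
}

draw_cell_local <- function(box, cell, ax, xlen, ylen, style) {
  vp <- cell_viewport(box, c(0, xlen), c(0, ylen))
  grid::pushViewport(vp)
  bl <- cell$bp_lines
  if (nrow(bl) > 0) {
    for (r in seq_len(nrow(bl))) {
      on_x <- (bl$axis[r] == "t") == (ax$t_axis == "x")
      gp <- grid::gpar(col = style$bp_color, lwd = style$bp_lwidth)
      if (on_x) {
        grid::grid.lines(x = grid::unit(rep(bl$coord[r], 2), "native"),
                         y = grid::unit(c(0, ylen), "native"), gp = gp)
      } else {
        grid::grid.lines(x = grid::unit(c(0, xlen), "native"),
                         y = grid::unit(rep(bl$coord[r], 2), "native"), gp = gp)
      }
    }
  }
  seg <- cell$segments
  if (nrow(seg) > 0) {
    grid::grid.segments(x0 = grid::unit(seg$t0, "native"),
                        y0 = grid::unit(seg$q0, "native"),
                        x1 = grid::unit(seg$t1, "native"),
                        y1 = grid::unit(seg$q1, "native"),
                        gp = grid::gpar(col = seg$color, lwd = seg$width,
                                        lineend = "round"))
  }
  grid::popViewport()
  grid::grid.rect(x = grid::unit(box[1], "npc"), y = grid::unit(box[2], "npc"),
                  width = grid::unit(box[3] - box[1], "npc"),
                  height = grid::unit(box[4] - box[2], "npc"),
                  just = c("left", "bottom"),
                  gp = grid::gpar(fill = NA, col = "grey40", lwd = 0.6))
}

# Replace the PDF creation/modification timestamps in place with a fixed
# epoch so identical renders are byte-identical. The replacement preserves
# byte length, keeping the xref table valid.
strip_pdf_timestamps <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  fixed <- charToRaw("19700101000000")
  for (tag in c("/CreationDate (D:", "/ModDate (D:")) {
    pat <- charToRaw(tag)
    hits <- which(raw == pat[1])
    for (h in hits) {
      if (h + length(pat) + 13 > length(raw)) next
      if (identical(raw[h:(h + length(pat) - 1)], pat)) {
        raw[(h + length(pat)):(h + length(pat) + 13)] <- fixed
      }
    }
  }
  writeBin(raw, path)
  invisible(path)
}

open_device <- function(path, format, width, height, transparent, dpi) {
  if (format == "png") {
    grDevices::png(path, width = width * dpi, height = height * dpi,
                   res = dpi, bg = if (transparent) "transparent" else "white",
                   type = "cairo")
  } else {
    grDevices::pdf(path, width = width, height = height, bg = "white",
                   onefile = TRUE, paper = "special")
  }
}

figure_size <- function(layout, fig_width = NULL, bp_per_inch = 5e4) {
  aspect <- layout$mat_avail[["w"]] / layout$mat_avail[["h"]]
  if (is.null(fig_width)) {
    total <- sum(layout$lengths)
    fig_width <- total / bp_per_inch / layout$mat_avail[["w"]]
    fig_width <- min(max(fig_width, 5), 16)
  }
  c(width = fig_width, height = fig_width * aspect)
}

#' Render the triangular matrix and all pairwise panels to files
#'
#' Writes `<out_dir>/<prefix>.png` and `<out_dir>/<prefix>.pdf` for the
#' combined matrix, plus `<out_dir>/pairwise/<idA>__<idB>.{png,pdf}` for
#' every pair. PNG output is rasterized at `dpi` with a transparent
#' background iff `style$transparent`; PDF output is vector and has its
#' embedded timestamps fixed so reruns are byte-identical.
#'
#' @param render_data output of [build_render_data()].
#' @param entries oriented entries tibble (for labels).
#' @param style a [render_style()].
#' @param out_dir output directory, created if needed.
#' @param prefix combined-figure file stem (default `"dotquilt"`).
#' @param formats subset of `c("png", "pdf")`.
#' @param fig_width figure width in inches; by default scaled from total
#'   sequence length at `bp_per_inch`, clamped to 5--16 in.
#' @param bp_per_inch bp per inch used to derive the default figure size.
#' @param dpi raster resolution (default 300).
#' @return character vector of the files written.
#' @export
render_matrix <- function(render_data, entries, style, out_dir,
                          prefix = "dotquilt", formats = c("png", "pdf"),
                          fig_width = NULL, bp_per_inch = 5e4, dpi = 300) {
  dir.create(file.path(out_dir, "pairwise"),
             recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    dq_io_error(sprintf("cannot create output directory '%s'", out_dir))
  }
  entries <- entries[order(entries$order_index), , drop = FALSE]
  layout <- render_data$layout
  size <- figure_size(layout, fig_width, bp_per_inch)
  written <- character(0)

  for (fmt in formats) {
    path <- file.path(out_dir, paste0(prefix, ".", fmt))
    open_device(path, fmt, size[["width"]], size[["height"]],
                style$transparent, dpi)
    ok <- tryCatch({
      draw_matrix_figure(render_data, style); TRUE
    }, finally = grDevices::dev.off())
    if (fmt == "pdf") strip_pdf_timestamps(path)
    written <- c(written, path)
  }

  pair_w <- 6
  for (key in names(render_data$cells)) {
    cell <- render_data$cells[[key]]
    i <- cell$i; j <- cell$j
    tid <- entries$sample_id[i]; qid <- entries$sample_id[j]
    tlen <- entries$length[i]; qlen <- entries$length[j]
    pair_h <- pair_w * 0.66 * (qlen / tlen) + pair_w * 0.34
    pair_h <- min(max(pair_h, 3), 14)
    for (fmt in formats) {
      path <- file.path(out_dir, "pairwise",
                        paste0(pair_name(tid, qid), ".", fmt))
      open_device(path, fmt, pair_w, pair_h, style$transparent, dpi)
      tryCatch({
        draw_pair_figure(cell, tid, qid, entries$label[i], entries$label[j],
                         tlen, qlen, render_data$legend, style)
      }, finally = grDevices::dev.off())
      if (fmt == "pdf") strip_pdf_timestamps(path)
      written <- c(written, path)
    }
  }
  dq_log("INFO", "render", sprintf("wrote %d file(s) to '%s'",
                                   length(written), out_dir))
  written
}
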