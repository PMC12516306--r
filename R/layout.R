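# Triangular-matrix geometry and drawing primitives.
#
# Cell (i, j), i <= j (1-based indices in input order), shows alignments of
# sequences i (target) and j (query). In upper mode the cell sits at row i,
# column j; lower mode is the transpose (row j, column i). In both modes
# column k carries sequence k on the x axis; in upper mode row i carries
# sequence i on the y axis (so a dot-plot point (t, q) is drawn at
# x = q, y = t), in lower mode the roles are mirrored (x = t, y = q).

#' Lay out the triangular matrix
#'
#' Computes normalized-figure rectangles for every cell, the per-sequence
#' annotation strips, label anchors, and the legend box. Cell widths and
#' heights are proportional to sequence lengths, so one bp maps to the same
#' figure distance everywhere (diagonal self-cells come out square).
#'
#' @param entries entries tibble with lengths loaded.
#' @param side `"upper"` or `"lower"` triangle.
#' @param show_annot reserve annotation strips on the margin.
#' @return a `matrix_layout` list: `n`, `side`, `sample_ids`, `lengths`,
#'   `cell_boxes` (named `"i_j"`, each `c(x0, y0, x1, y1)` in `[0,1]`),
#'   `annot_boxes` (per sequence), `labels` (anchor tibble), `legend_box`,
#'   `col_x`/`row_y` bands and the matrix aspect needed for a uniform
#'   bp scale.
#' @export
build_layout <- function(entries, side = c("upper", "lower"),
                         show_annot = FALSE) {
  side <- match.arg(side)
  n <- nrow(entries)
  if (is.null(n) || n == 0) dq_validation_error("no sequences to lay out")
  if (anyNA(entries$length)) {
    dq_contract_error("sequence lengths must be loaded before layout")
  }
  L <- as.numeric(entries$length)
  ids <- entries$sample_id

  gap <- if (n > 1) 0.012 else 0
  label_h <- 0.045
  annot_h <- if (show_annot) 0.035 else 0
  legend_h <- 0.05
  pad <- 0.02

  if (side == "upper") {
    # labels + annotation strips above the matrix, legend below
    mat_x0 <- pad + 0.02; mat_x1 <- 1 - pad
    mat_y1 <- 1 - pad - label_h - annot_h - 0.005
    mat_y0 <- pad + legend_h + 0.03
  } else {
    # labels on the left, annotation strips + legend below
    mat_x0 <- pad + 0.10; mat_x1 <- 1 - pad
    mat_y1 <- 1 - pad
    mat_y0 <- pad + legend_h + 0.03 + annot_h + (if (show_annot) 0.005 else 0)
  }

  avail_w <- (mat_x1 - mat_x0) - gap * (n - 1)
  avail_h <- (mat_y1 - mat_y0) - gap * (n - 1)
  if (avail_w <= 0 || avail_h <= 0) {
    dq_validation_error("too many sequences for the figure margins")
  }
  wfrac <- avail_w * L / sum(L)
  hfrac <- avail_h * L / sum(L)

  col_x <- matrix(NA_real_, n, 2, dimnames = list(ids, c("x0", "x1")))
  x <- mat_x0
  for (k in seq_len(n)) {
    col_x[k, ] <- c(x, x + wfrac[k])
    x <- x + wfrac[k] + gap
  }
  row_y <- matrix(NA_real_, n, 2, dimnames = list(ids, c("y0", "y1")))
  y <- mat_y1
  for (k in seq_len(n)) {
    row_y[k, ] <- c(y - hfrac[k], y)
    y <- y - hfrac[k] - gap
  }

  cell_boxes <- list()
  for (i in seq_len(n)) {
    for (j in i:n) {
      rc <- if (side == "upper") c(i, j) else c(j, i)  # (row, column)
      cell_boxes[[paste(i, j, sep = "_")]] <-
        c(col_x[rc[2], 1], row_y[rc[1], 1], col_x[rc[2], 2], row_y[rc[1], 2])
    }
  }

  annot_boxes <- list()
  if (show_annot) {
    for (k in seq_len(n)) {
      ys <- if (side == "upper") {
        c(mat_y1 + 0.005, mat_y1 + 0.005 + annot_h)
      } else {
        c(mat_y0 - 0.005 - annot_h, mat_y0 - 0.005)
      }
      annot_boxes[[ids[k]]] <- c(col_x[k, 1], ys[1], col_x[k, 2], ys[2])
    }
  }

  labels <- if (side == "upper") {
    tibble::tibble(sample_id = ids, label = entries$label,
                   x = rowMeans(col_x), y = 1 - pad - label_h / 2,
                   rot = 0, hjust = 0.5)
  } else {
    tibble::tibble(sample_id = ids, label = entries$label,
                   x = pad, y = rowMeans(row_y), rot = 0, hjust = 0)
  }

  structure(
    list(n = n, side = side, sample_ids = ids,
         lengths = setNames(L, ids),
         col_x = col_x, row_y = row_y,
         cell_boxes = cell_boxes, annot_boxes = annot_boxes,
         labels = labels,
         legend_box = c(0.32, pad, 0.68, pad + legend_h),
         mat_avail = c(w = avail_w, h = avail_h),
         show_annot = show_annot),
    class = "matrix_layout")
}

# Which sequence sits on which axis of cell (i, j).
cell_axes <- function(layout, i, j) {
  if (layout$side == "upper") {
    list(x_seq = j, y_seq = i, t_axis = "y")  # x = query, y = target
  } else {
    list(x_seq = i, y_seq = j, t_axis = "x")  # x = target, y = query
  }
}

#' Build drawable segments for one cell
#'
#' One segment per styled record. Endpoints follow the dot-plot rule in
#' (target, query) data space: a `+` record runs `(t_start, q_start)` to
#' `(t_end, q_end)`; a `-` record runs `(t_start, q_end)` to
#' `(t_end, q_start)`, so the slope sign equals the strand sign.
#'
#' @param styled styled records (see [style_records()]) for the cell's pair.
#' @param cell integer pair `c(i, j)`, `i <= j`, 1-based input indices.
#' @param layout the [build_layout()] result (for id and bounds checks).
#' @param lwidth line width to stamp on each segment.
#' @return a tibble with `i`, `j`, `t0`, `q0`, `t1`, `q1`, `color`, `width`.
#' @export
segments_for_cell <- function(styled, cell, layout, lwidth = 1) {
  i <- cell[[1]]; j <- cell[[2]]
  tid <- layout$sample_ids[i]; qid <- layout$sample_ids[j]
  if (nrow(styled) == 0) {
    return(tibble::tibble(i = integer(), j = integer(),
                          t0 = numeric(), q0 = numeric(),
                          t1 = numeric(), q1 = numeric(),
                          color = character(), width = numeric()))
  }
  if (!all(styled$target_id == tid) || !all(styled$query_id == qid)) {
    dq_contract_error(sprintf(
      "styled records do not belong to cell (%d, %d) = (%s, %s)",
      i, j, tid, qid))
  }
  if (any(styled$t_end > layout$lengths[[tid]]) ||
      any(styled$q_end > layout$lengths[[qid]])) {
    dq_contract_error(sprintf(
      "record coordinates exceed axis extents of cell (%d, %d)", i, j))
  }
  minus <- styled$strand == "-"
  tibble::tibble(
    i = i, j = j,
    t0 = styled$t_start,
    q0 = ifelse(minus, styled$q_end, styled$q_start),
    t1 = styled$t_end,
    q1 = ifelse(minus, styled$q_start, styled$q_end),
    color = styled$color,
    width = lwidth)
}

#' Breakpoint guide lines for one cell
#'
#' Every record contributes its target start/end as lines across the
#' target axis and its query start/end across the query axis; duplicate
#' (axis, coordinate) pairs are merged. Records should be pre-filtered by
#' [select_breakpoint_records()].
#'
#' @param records alignment-record tibble.
#' @param cell integer pair `c(i, j)`.
#' @return a tibble with `i`, `j`, `axis` (`"t"`/`"q"`) and `coord` (bp).
#' @export
breakpoint_lines <- function(records, cell) {
  if (nrow(records) == 0) {
    return(tibble::tibble(i = integer(), j = integer(),
                          axis = character(), coord = numeric()))
  }
  df <- rbind(
    data.frame(axis = "t", coord = c(records$t_start, records$t_end)),
    data.frame(axis = "q", coord = c(records$q_start, records$q_end)))
  df <- unique(df)
  tibble::tibble(i = cell[[1]], j = cell[[2]],
                 axis = df$axis, coord = df$coord)
}

#' Annotation-track rectangles for one sequence
#'
#' One filled rectangle per interval on the sequence's bp axis; intervals
#' without a color are filled black. Intervals must already be reoriented
#' if the sequence is displayed reversed.
#'
#' @param intervals annotation tibble.
#' @param entry one-row entries tibble for the owning sequence.
#' @return a tibble with `sample_id`, `start`, `end`, `fill`, `name`.
#' @export
annotation_track <- function(intervals, entry) {
  if (is.null(intervals) || nrow(intervals) == 0) {
    return(tibble::tibble(sample_id = character(), start = numeric(),
                          end = numeric(), fill = character(),
                          name = character()))
  }
  fill <- intervals$color
  fill[is.na(fill)] <- "#000000"
  tibble::tibble(sample_id = entry$sample_id,
                 start = intervals$start, end = intervals$end,
                 fill = fill, name = intervals$name)
}

#' Legend primitives
#'
#' A horizontal color bar mapping percent identity `min_pi..max_pi` to the
#' same colors [style_records()] assigns (including colormap reversal), or
#' a single swatch when `single_color` is set.
#'
#' @param style a [render_style()].
#' @param n_steps resolution of the color bar.
#' @return a list: `type` (`"colorbar"`/`"swatch"`), `colors`, `pi_min`,
#'   `pi_max`.
#' @export
render_legend <- function(style, n_steps = 256) {
  if (!is.null(style$single_color)) {
    return(list(type = "swatch", colors = style$single_color,
                pi_min = style$min_pi, pi_max = style$max_pi))
  }
  u <- seq(0, 1, length.out = n_steps)
  cols <- colormap_fun(style$cmap)(if (style$reverse_cmap) 1 - u else u)
  list(type = "colorbar", colors = cols,
       pi_min = style$min_pi, pi_max = style$max_pi)
}

#' Assemble all drawing primitives for a run
#'
#' Applies the length filter, styling and breakpoint selection per pair and
#' collects segments, breakpoint lines and annotation tracks keyed by cell.
#'
#' @param entries oriented entries tibble.
#' @param sets named list of (reoriented) alignment sets.
#' @param style a [render_style()].
#' @param side triangle side; defaults to `style$matrix_side`.
#' @return a list with `layout`, `cells` (per pair: `segments`,
#'   `bp_lines`), `tracks` (per sequence) and `legend`.
#' @export
build_render_data <- function(entries, sets, style,
                              side = style$matrix_side) {
  entries <- entries[order(entries$order_index), , drop = FALSE]
  layout <- build_layout(entries, side, show_annot = style$show_annot)
  cells <- list()
  for (i in seq_len(layout$n)) {
    for (j in i:layout$n) {
      key <- pair_name(entries$sample_id[i], entries$sample_id[j])
      set <- sets[[key]]
      rec <- if (is.null(set)) empty_records() else set$records
      kept <- filter_by_length(rec, style$min_len)
      styled <- style_records(kept, style)
      segs <- segments_for_cell(styled, c(i, j), layout,
                                lwidth = style$lwidth)
      bl <- if (style$show_bp) {
        breakpoint_lines(select_breakpoint_records(rec, style$bp_min_len),
                         c(i, j))
      } else {
        breakpoint_lines(empty_records(), c(i, j))
      }
      cells[[paste(i, j, sep = "_")]] <-
        list(i = i, j = j, segments = segs, bp_lines = bl,
             n_records = nrow(rec), n_kept = nrow(kept))
    }
  }
  tracks <- lapply(seq_len(nrow(entries)), function(k) {
    annotation_track(entries$annotations[[k]], entries[k, , drop = FALSE])
  })
  names(tracks) <- entries$sample_id
  list(layout = layout, cells = cells, tracks = tracks,
       legend = render_legend(style))
}
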