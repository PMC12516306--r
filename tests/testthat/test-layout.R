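# Matrix geometry and drawing primitives (no graphics device involved).

boxes_overlap <- function(a, b) {
  a[1] < b[3] && b[1] < a[3] && a[2] < b[4] && b[2] < a[4]
}

test_that("the layout has n(n+1)/2 cells with squares on the diagonal", {
  for (n in c(1, 2, 5, 8)) {
    entries <- make_entries(sprintf("s%d", 1:n), rep(50000, n))
    layout <- build_layout(entries, "upper")
    expect_equal(length(layout$cell_boxes), n * (n + 1) / 2)
    diag_keys <- paste(1:n, 1:n, sep = "_")
    expect_true(all(diag_keys %in% names(layout$cell_boxes)))
  }
  expect_error(build_layout(make_entries(character(0), numeric(0)), "upper"),
               class = "dq_validation_error")
})

test_that("cell sizes are proportional to sequence lengths, pairwise disjoint", {
  entries <- make_entries(c("a", "b", "c"), c(100000, 50000, 25000))
  layout <- build_layout(entries, "upper")
  w <- layout$col_x[, 2] - layout$col_x[, 1]
  h <- layout$row_y[, 2] - layout$row_y[, 1]
  expect_equal(unname(w[1] / w[2]), 2, tolerance = 1e-9)
  expect_equal(unname(w[2] / w[3]), 2, tolerance = 1e-9)
  expect_equal(unname(w / h), rep(w[[1]] / h[[1]], 3), tolerance = 1e-9)

  keys <- names(layout$cell_boxes)
  for (a in seq_along(keys)) {
    for (b in seq_along(keys)) {
      if (a < b) {
        expect_false(boxes_overlap(layout$cell_boxes[[keys[a]]],
                                   layout$cell_boxes[[keys[b]]]))
      }
    }
  }
  # equal-length sequences get equal-size cells
  eq <- build_layout(make_entries(c("x", "y"), c(30000, 30000)), "upper")
  wx <- eq$col_x[, 2] - eq$col_x[, 1]
  expect_equal(wx[[1]], wx[[2]])
})

test_that("upper and lower layouts are transposes of each other", {
  entries <- make_entries(c("a", "b", "c"), c(10000, 20000, 30000))
  up <- build_layout(entries, "upper")
  lo <- build_layout(entries, "lower")
  for (i in 1:3) {
    for (j in i:3) {
      key <- paste(i, j, sep = "_")
      ub <- up$cell_boxes[[key]]
      lb <- lo$cell_boxes[[key]]
      # upper places (i, j) at (row i, col j); lower at (row j, col i)
      expect_equal(ub[c(1, 3)], up$col_x[j, ], ignore_attr = TRUE)
      expect_equal(lb[c(1, 3)], lo$col_x[i, ], ignore_attr = TRUE)
      expect_equal(ub[c(2, 4)], up$row_y[i, ], ignore_attr = TRUE)
      expect_equal(lb[c(2, 4)], lo$row_y[j, ], ignore_attr = TRUE)
    }
  }
})

test_that("segment endpoints follow the strand-signed dot-plot rule", {
  entries <- make_entries(c("a", "b"), c(1000, 1000))
  layout <- build_layout(entries, "upper")
  styled <- style_records(
    make_records("a", "b", t_start = 100, t_end = 200,
                 q_start = 400, q_end = 450, strand = "+"),
    render_style())
  seg <- segments_for_cell(styled, c(1, 2), layout)
  expect_equal(c(seg$t0, seg$q0, seg$t1, seg$q1), c(100, 400, 200, 450))
  # slope l2/l1 = 50/100
  expect_equal((seg$q1 - seg$q0) / (seg$t1 - seg$t0), 0.5)

  styled_m <- styled
  styled_m$strand <- "-"
  seg_m <- segments_for_cell(styled_m, c(1, 2), layout)
  expect_equal(c(seg_m$q0, seg_m$q1), c(450, 400))
  expect_lt((seg_m$q1 - seg_m$q0) / (seg_m$t1 - seg_m$t0), 0)

  # self-cell identity record sits on the main diagonal
  self_rec <- style_records(
    make_records("a", "a", t_start = 0, t_end = 1000,
                 q_start = 0, q_end = 1000), render_style())
  ds <- segments_for_cell(self_rec, c(1, 1), layout)
  expect_equal(c(ds$t0, ds$q0, ds$t1, ds$q1), c(0, 0, 1000, 1000))

  # out-of-bounds coordinates violate the cell contract
  bad <- style_records(make_records("a", "b", t_start = 0, t_end = 2000,
                                    q_start = 0, q_end = 10), render_style())
  expect_error(segments_for_cell(bad, c(1, 2), layout),
               class = "dq_contract_error")
  # records from another pair are rejected
  expect_error(segments_for_cell(styled, c(1, 1), layout),
               class = "dq_contract_error")
})

test_that("segment slope sign equals strand sign over generated records", {
  locus <- generate_locus_set(tiny_locus_spec())
  entries <- locus$entries
  layout <- build_layout(entries, "upper")
  style <- render_style(min_len = 0)
  for (i in 1:3) {
    for (j in i:3) {
      key <- dotquilt:::pair_name(entries$sample_id[i], entries$sample_id[j])
      styled <- style_records(locus$records[[key]], style)
      seg <- segments_for_cell(styled, c(i, j), layout)
      slope_sign <- sign((seg$q1 - seg$q0) * (seg$t1 - seg$t0))
      expect_equal(slope_sign, ifelse(styled$strand == "+", 1, -1))
    }
  }
})

test_that("breakpoint lines are four per record, deduplicated across records", {
  one <- make_records(t_start = 0, t_end = 100, q_start = 10, q_end = 90)
  expect_equal(nrow(breakpoint_lines(one, c(1, 2))), 4L)
  expect_equal(nrow(breakpoint_lines(one[0, ], c(1, 2))), 0L)

  # two records sharing one target start: 8 - 1 = 7 unique lines
  two <- make_records(t_start = c(0, 0), t_end = c(100, 200),
                      q_start = c(10, 300), q_end = c(90, 400))
  bl <- breakpoint_lines(two, c(1, 2))
  expect_equal(nrow(bl), 7L)
  expect_equal(sum(bl$axis == "t"), 3L)
  expect_equal(sum(bl$axis == "q"), 4L)
})

test_that("annotation tracks fill colorless intervals black", {
  entry <- make_entries("s", 1000)
  iv <- tibble::tibble(sample_id = "s", start = c(0L, 0L), end = c(1000L, 10L),
                       name = c("whole", "tip"), color = c(NA, "#112233"),
                       line = 1:2)
  tr <- annotation_track(iv, entry)
  expect_equal(tr$fill, c("#000000", "#112233"))
  expect_equal(tr$start[1], 0)
  expect_equal(tr$end[1], 1000)
  expect_equal(nrow(annotation_track(iv[0, ], entry)), 0L)
})

test_that("the legend reproduces the styling colors end to end", {
  style <- render_style()
  leg <- render_legend(style)
  expect_equal(leg$type, "colorbar")
  styled <- style_records(make_records(pi = c(85, 100)), style)
  expect_equal(leg$colors[1], styled$color[1])
  expect_equal(leg$colors[length(leg$colors)], styled$color[2])

  fwd <- render_legend(render_style(reverse_cmap = FALSE))
  expect_equal(fwd$colors[1], leg$colors[length(leg$colors)])
  expect_equal(fwd$colors[length(fwd$colors)], leg$colors[1])

  sw <- render_legend(render_style(single_color = "black"))
  expect_equal(sw$type, "swatch")
  expect_equal(sw$colors, "#000000")
})

test_that("layout and primitives are deterministic", {
  locus <- generate_locus_set(tiny_locus_spec())
  style <- render_style(show_bp = TRUE, show_annot = TRUE)
  a <- build_render_data(locus$entries, lapply(locus$records, function(r)
    alignment_set(r$target_id[1], r$query_id[1], r)), style)
  b <- build_render_data(locus$entries, lapply(locus$records, function(r)
    alignment_set(r$target_id[1], r$query_id[1], r)), style)
  expect_equal(a$cells, b$cells)
  expect_equal(a$layout$cell_boxes, b$layout$cell_boxes)
  expect_equal(a$legend, b$legend)
})
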