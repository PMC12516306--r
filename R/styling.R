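# Length filtering and percent-identity color mapping.
#
# An alignment's "length" for both display thresholds is max(l1, l2), the
# longer of its two aligned spans: symmetric in the pair and conservative
# toward showing structure. Both thresholds are inclusive (>=).

#' Visualization parameters
#'
#' Bundles every tunable display parameter with its default.
#'
#' @param min_len minimum alignment length shown, bp (default 5000).
#' @param min_pi,max_pi percent-identity range mapped onto the colormap
#'   (defaults 85 and 100); PI values outside the range are clamped to the
#'   nearest bound.
#' @param cmap colormap name (default `"rainbow"`); see [colormap_fun()].
#' @param single_color optional single color overriding the colormap.
#' @param reverse_cmap reverse the colormap direction (default `TRUE`).
#' @param lwidth alignment line width (default 1).
#' @param transparent transparent PNG background (default `FALSE`).
#' @param show_annot draw annotation tracks (default `FALSE`).
#' @param show_bp draw breakpoint guide lines (default `FALSE`).
#' @param bp_color breakpoint line color (default `"#7F7F7F"`).
#' @param bp_lwidth breakpoint line width (default 0.2).
#' @param bp_min_len minimum alignment length contributing breakpoint
#'   lines, bp (default 10000); independent of `min_len`.
#' @param matrix_side `"upper"` or `"lower"` triangle (default `"upper"`).
#' @return a `render_style` list.
#' @export
render_style <- function(min_len = 5000,
                         min_pi = 85,
                         max_pi = 100,
                         cmap = "rainbow",
                         single_color = NULL,
                         reverse_cmap = TRUE,
                         lwidth = 1,
                         transparent = FALSE,
                         show_annot = FALSE,
                         show_bp = FALSE,
                         bp_color = "#7F7F7F",
                         bp_lwidth = 0.2,
                         bp_min_len = 10000,
                         matrix_side = c("upper", "lower")) {
  matrix_side <- match.arg(matrix_side)
  if (!is.numeric(min_pi) || !is.numeric(max_pi) || min_pi >= max_pi) {
    dq_config_error(sprintf(
      "min_pi (%s) must be smaller than max_pi (%s)", min_pi, max_pi))
  }
  if (min_len < 0 || bp_min_len < 0) {
    dq_config_error("length thresholds must be non-negative")
  }
  if (lwidth <= 0 || bp_lwidth <= 0) {
    dq_config_error("line widths must be positive")
  }
  colormap_fun(cmap)  # fail early on unknown colormap names
  if (!is.null(single_color)) single_color <- normalize_color(single_color)
  structure(
    list(min_len = min_len, min_pi = min_pi, max_pi = max_pi,
         cmap = cmap, single_color = single_color,
         reverse_cmap = isTRUE(reverse_cmap), lwidth = lwidth,
         transparent = isTRUE(transparent), show_annot = isTRUE(show_annot),
         show_bp = isTRUE(show_bp),
         bp_color = normalize_color(bp_color, "bp_color"),
         bp_lwidth = bp_lwidth, bp_min_len = bp_min_len,
         matrix_side = matrix_side),
    class = "render_style")
}

#' Keep alignments at least `min_len` long
#'
#' A record passes when `max(l1, l2) >= min_len`, where `l1` and `l2` are
#' the target and query spans. Input order is preserved.
#'
#' @param records alignment-record tibble.
#' @param min_len threshold in bp.
#' @return the surviving records.
#' @export
filter_by_length <- function(records, min_len) {
  if (min_len < 0) dq_config_error("min_len must be non-negative")
  if (nrow(records) == 0) return(records)
  span <- pmax(records$t_end - records$t_start,
               records$q_end - records$q_start)
  records[span >= min_len, , drop = FALSE]
}

#' Select alignments contributing breakpoint lines
#'
#' Same rule as [filter_by_length()] but with the independent
#' `bp_min_len` threshold.
#'
#' @param records alignment-record tibble.
#' @param bp_min_len threshold in bp.
#' @return the surviving records.
#' @export
select_breakpoint_records <- function(records, bp_min_len) {
  filter_by_length(records, bp_min_len)
}

#' Map percent identity onto the unit interval
#'
#' Clamps `pi` into `[min_pi, max_pi]` and rescales affinely:
#' `(clamp(pi) - min_pi) / (max_pi - min_pi)`. Values at or below `min_pi`
#' map to 0, at or above `max_pi` to 1. Vectorized over `pi`.
#'
#' @param pi percent identity values.
#' @param min_pi,max_pi the display range, `min_pi < max_pi`.
#' @return values in `[0, 1]`.
#' @export
pi_to_unit <- function(pi, min_pi, max_pi) {
  if (min_pi >= max_pi) {
    dq_config_error(sprintf(
      "min_pi (%s) must be smaller than max_pi (%s)", min_pi, max_pi))
  }
  (pmin(pmax(pi, min_pi), max_pi) - min_pi) / (max_pi - min_pi)
}

#' Continuous colormap lookup
#'
#' Resolves a colormap name to a function mapping `[0, 1]` to hex colors.
#' `"rainbow"` is the classic violet-to-red hue sweep; any palette known to
#' [grDevices::hcl.colors()] (`"viridis"`, `"plasma"`, `"inferno"`,
#' `"Spectral"`, ...) is accepted, case-insensitively.
#'
#' @param name colormap name.
#' @return `function(u)` returning hex colors for `u` in `[0, 1]`.
#' @export
colormap_fun <- function(name) {
  pal <- if (tolower(name) == "rainbow") {
    rev(grDevices::rainbow(256, start = 0, end = 5 / 6))
  } else {
    pals <- grDevices::hcl.pals()
    hit <- pals[tolower(pals) == tolower(name)]
    if (length(hit) == 0) {
      dq_config_error(sprintf("unknown colormap name: '%s'", name))
    }
    grDevices::hcl.colors(256, palette = hit[1])
  }
  ramp <- grDevices::colorRamp(pal, space = "Lab")
  function(u) {
    if (any(u < 0 | u > 1)) dq_contract_error("colormap input outside [0, 1]")
    m <- ramp(u)
    grDevices::rgb(m[, 1], m[, 2], m[, 3], maxColorValue = 255)
  }
}

#' Assign display colors to alignment records
#'
#' Each record's percent identity is mapped to `unit_value` by
#' [pi_to_unit()]; its color is the colormap evaluated at `unit_value`
#' (or at `1 - unit_value` when `reverse_cmap` is set, so higher identity
#' takes the colormap's low end). When `single_color` is set all records
#' get that color while `unit_value` is still computed for the legend.
#'
#' @param records alignment-record tibble.
#' @param style a [render_style()].
#' @return the records with `unit_value` and `color` columns appended.
#' @export
style_records <- function(records, style) {
  u <- pi_to_unit(records$percent_identity, style$min_pi, style$max_pi)
  records$unit_value <- u
  records$color <- if (!is.null(style$single_color)) {
    rep(style$single_color, nrow(records))
  } else if (nrow(records) == 0) {
    character(0)
  } else {
    colormap_fun(style$cmap)(if (style$reverse_cmap) 1 - u else u)
  }
  records
}
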