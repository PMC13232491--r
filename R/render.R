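#' Plot configuration
#'
#' Validated configuration for snail plot rendering. `badge = TRUE`
#' produces a text-free assembly badge and forces the linear scale
#' function so that badges remain visually comparable.
#'
#' @param segments Number of polygon sides / summary bins (>= 1).
#' @param scale_function Radial axis scale: `"linear"`, `"sqrt"`, `"log"`.
#' @param max_span,max_scaffold Optional fixed circumferential/radial axis
#'   maxima in bases.
#' @param badge Render as a text-free badge?
#' @param show_score Print the selected snail score on the plot?
#' @param score_type Score variant to display: `"base"`, `"g"`, `"gs"`,
#'   `"ag"`, `"ags"`.
#' @param significant_digits Significant digits for absolute values (>= 1).
#' @param decimal_precision Decimal places for percentages (>= 0).
#' @param rounding Display rounding strategy: `"round"` (half away from
#'   zero), `"down"` (toward zero), `"up"` (away from zero).
#' @param show_numbers Label the circumferential axis with absolute values
#'   instead of percentages.
#' @param busco_numbers Show absolute BUSCO counts instead of percentages.
#' @param assembly_name,reference_name Display names.
#' @return A `snail_plot_config` list.
#' @export
plot_config <- function(segments = 1000,
                        scale_function = c("linear", "sqrt", "log"),
                        max_span = NULL, max_scaffold = NULL,
                        badge = FALSE, show_score = FALSE,
                        score_type = c("base", "g", "gs", "ag", "ags"),
                        significant_digits = 3, decimal_precision = 2,
                        rounding = c("round", "down", "up"),
                        show_numbers = FALSE, busco_numbers = FALSE,
                        assembly_name = NULL, reference_name = NULL) {
  scale_function <- match.arg(scale_function)
  score_type <- match.arg(score_type)
  rounding <- match.arg(rounding)
  if (!is.numeric(segments) || segments < 1) {
    stop("segments must be an integer >= 1")
  }
  if (significant_digits < 1) stop("significant_digits must be >= 1")
  if (decimal_precision < 0) stop("decimal_precision must be >= 0")
  if (isTRUE(badge)) scale_function <- "linear"
  structure(list(
    segments = as.integer(segments), scale_function = scale_function,
    max_span = max_span, max_scaffold = max_scaffold,
    badge = isTRUE(badge), show_score = isTRUE(show_score),
    score_type = score_type,
    significant_digits = as.integer(significant_digits),
    decimal_precision = as.integer(decimal_precision),
    rounding = rounding, show_numbers = isTRUE(show_numbers),
    busco_numbers = isTRUE(busco_numbers),
    assembly_name = assembly_name, reference_name = reference_name
  ), class = "snail_plot_config")
}

#' Radial axis scale functions
#'
#' Maps a scaffold length to a fraction of the radial axis. `linear` is
#' `L / Lmax`; `sqrt` is `sqrt(L) / sqrt(Lmax)` (over-emphasising short
#' scaffolds); `log` is `log10(max(L, 1)) / log10(max(Lmax, 2))` with
#' lengths below 1 clamped to 0. All functions map 0 to 0 and `Lmax` to 1
#' and are monotone non-decreasing.
#'
#' @param length Scaffold length(s) in bases.
#' @param max_scaffold Radial axis maximum in bases (> 0).
#' @param fun Scale function name.
#' @return Fraction(s) in \[0, 1\].
#' @export
radial_scale <- function(length, max_scaffold,
                         fun = c("linear", "sqrt", "log")) {
  fun <- match.arg(fun)
  stopifnot(max_scaffold > 0, all(length >= 0, na.rm = TRUE))
  out <- switch(fun,
    linear = length / max_scaffold,
    sqrt = sqrt(length) / sqrt(max_scaffold),
    log = log10(pmax(length, 1)) / log10(max(max_scaffold, 2))
  )
  pmin(pmax(out, 0), 1)
}

#' Resolve plot geometry
#'
#' The circumferential axis is scaled to the largest of the assembly span,
#' the reference span (when present), and a configured `max_span`; the
#' radial axis analogously for the longest scaffold. The assembly sweeps
#' `360 * span / max_span` degrees clockwise from 12 o'clock. A configured
#' maximum smaller than the assembly's own value triggers a warning and
#' the assembly value wins.
#'
#' @param summary An `assembly_summary`.
#' @param reference Optional reference `assembly_summary`.
#' @param config A `snail_plot_config`.
#' @return A `snail_geometry` list with the resolved maxima, swept angle,
#'   radius budget, and canvas parameters.
#' @export
resolve_geometry <- function(summary, reference = NULL,
                             config = plot_config()) {
  max_span <- summary$span
  max_scaffold <- summary$longest
  if (!is.null(reference)) {
    max_span <- max(max_span, reference$span)
    max_scaffold <- max(max_scaffold, reference$longest)
  }
  if (!is.null(config$max_span)) {
    if (config$max_span < summary$span) {
      warning("max_span is smaller than the assembly span; using the span")
    }
    max_span <- max(max_span, config$max_span)
  }
  if (!is.null(config$max_scaffold)) {
    if (config$max_scaffold < summary$longest) {
      warning("max_scaffold is smaller than the longest scaffold; ",
              "using the longest scaffold")
    }
    max_scaffold <- max(max_scaffold, config$max_scaffold)
  }
  structure(list(
    center = c(500, 500), radius = 400,
    count_band = c(0, 0.25), scaffold_band = c(0.25, 0.85),
    composition_band = c(0.85, 1),
    max_span = max_span, max_scaffold = max_scaffold,
    sweep_deg = 360 * summary$span / max_span,
    segments = config$segments, scale_function = config$scale_function
  ), class = "snail_geometry")
}

#' Format a number for display
#'
#' Absolute values are rounded to `significant_digits` significant digits
#' and printed with kb/Mb/Gb unit suffixes at powers of 1000; percentages
#' (given as proportions) are rounded to `decimal_precision` decimal
#' places. Rounding follows the configured strategy.
#'
#' @param value Finite numeric value; for `mode = "percentage"` a
#'   proportion in natural units (0.5 prints as `"50.00%"`).
#' @param mode `"absolute"` or `"percentage"`.
#' @param config A `snail_plot_config`.
#' @return Display string.
#' @examples
#' format_number(200127270)            # "200 Mb"
#' format_number(0.11888, "percentage") # "11.89%"
#' @export
format_number <- function(value, mode = c("absolute", "percentage"),
                          config = plot_config()) {
  mode <- match.arg(mode)
  stopifnot(is.finite(value))
  if (mode == "percentage") {
    r <- round_value(100 * value, config$decimal_precision, config$rounding)
    return(sprintf("%.*f%%", config$decimal_precision, r))
  }
  units <- c(Gb = 1e9, Mb = 1e6, kb = 1e3)
  suffix <- ""
  unit <- 1
  for (u in seq_along(units)) {
    if (abs(value) >= units[u]) {
      unit <- units[u]
      suffix <- paste0(" ", names(units)[u])
      break
    }
  }
  if (value == 0) return("0")
  r <- round_value(value / unit, config$significant_digits, config$rounding,
                   significant = TRUE)
  paste0(format(r, scientific = FALSE, trim = TRUE, big.mark = ""), suffix)
}

# --- internal drawing helpers ---------------------------------------------

snail_palette <- list(
  longest = "#e31a1c", n50 = "#ff7f00", n90 = "#fdbf6f",
  scaffold = "#595959", count = "#d9d9d9",
  gc = "#1f77b4", gc_range_dark = "#3182bd", gc_range_light = "#9ecae1",
  at = "#c6dbef", reference = "#6a3d9a",
  busco_complete = "#33a02c", busco_duplicated = "#1a6b14",
  busco_fragmented = "#b2df8a"
)

# point on the plot circle: f is the fraction of a full turn clockwise
# from 12 o'clock, r the radius in canvas units
polar_xy <- function(cx, cy, f, r) {
  a <- 2 * pi * f
  c(cx + r * sin(a), cy - r * cos(a))
}

fmt_pt <- function(p) sprintf("%.2f,%.2f", p[1], p[2])

polygon_el <- function(points, fill, opacity = NULL, class = NULL) {
  sprintf("<polygon points=\"%s\" fill=\"%s\"%s%s/>",
          paste(points, collapse = " "), fill,
          if (is.null(opacity)) "" else sprintf(" fill-opacity=\"%s\"", opacity),
          if (is.null(class)) "" else sprintf(" class=\"%s\"", class))
}

circle_el <- function(cx, cy, r, stroke, class, dashed = FALSE, width = 1) {
  sprintf(paste0("<circle cx=\"%.2f\" cy=\"%.2f\" r=\"%.2f\" fill=\"none\" ",
                 "stroke=\"%s\" stroke-width=\"%s\"%s class=\"%s\"/>"),
          cx, cy, r, stroke, width,
          if (dashed) " stroke-dasharray=\"4 3\"" else "", class)
}

# annular wedge from angle fraction 0 to f_end between radii r_outer and
# r_inner, stepped along bin boundaries so it follows the plot polygon
wedge_points <- function(cx, cy, f_end, r_outer, r_inner, segments) {
  fs <- seq(0, 1, length.out = segments + 1)
  fs <- c(fs[fs < f_end], f_end)
  outer <- vapply(fs, function(f) fmt_pt(polar_xy(cx, cy, f, r_outer)), "")
  inner <- vapply(rev(fs), function(f) fmt_pt(polar_xy(cx, cy, f, r_inner)), "")
  c(outer, inner)
}

# stepped region between a constant outer radius and a per-bin inner
# radius; bins is a subset of consecutive bin indices (0-based), radii_in
# the matching inner radius per bin, f_end the exact final angle fraction
stepped_region_points <- function(cx, cy, bin_idx, radii_in, r_outer,
                                  segments, f_end) {
  f0 <- bin_idx / segments
  f1 <- pmin((bin_idx + 1) / segments, f_end)
  outer <- character(0)
  outer <- c(outer, fmt_pt(polar_xy(cx, cy, f0[1], r_outer)))
  for (i in seq_along(bin_idx)) {
    outer <- c(outer, fmt_pt(polar_xy(cx, cy, f1[i], r_outer)))
  }
  inner <- character(0)
  for (i in rev(seq_along(bin_idx))) {
    inner <- c(inner,
               fmt_pt(polar_xy(cx, cy, f1[i], radii_in[i])),
               fmt_pt(polar_xy(cx, cy, f0[i], radii_in[i])))
  }
  c(outer, inner)
}

stepped_line_points <- function(cx, cy, bin_idx, radii, segments, f_end) {
  f0 <- bin_idx / segments
  f1 <- pmin((bin_idx + 1) / segments, f_end)
  pts <- character(0)
  for (i in seq_along(bin_idx)) {
    pts <- c(pts, fmt_pt(polar_xy(cx, cy, f0[i], radii[i])),
             fmt_pt(polar_xy(cx, cy, f1[i], radii[i])))
  }
  pts
}

text_el <- function(x, y, content, size = 16, anchor = "start",
                    class = NULL) {
  sprintf(paste0("<text x=\"%.2f\" y=\"%.2f\" font-size=\"%d\" ",
                 "font-family=\"sans-serif\" text-anchor=\"%s\"%s>%s</text>"),
          x, y, size, anchor,
          if (is.null(class)) "" else sprintf(" class=\"%s\"", class),
          content)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

# donut arc for the BUSCO inset, from fraction f0 to f1 of the circle
donut_arc_points <- function(cx, cy, f0, f1, r_in, r_out) {
  n <- max(2L, ceiling((f1 - f0) * 90))
  fs <- seq(f0, f1, length.out = n + 1)
  outer <- vapply(fs, function(f) fmt_pt(polar_xy(cx, cy, f, r_out)), "")
  inner <- vapply(rev(fs), function(f) fmt_pt(polar_xy(cx, cy, f, r_in)), "")
  c(outer, inner)
}

# --- main renderer ---------------------------------------------------------

#' Render a snail plot as an SVG document
#'
#' Composes the layered circular plot: a circumferential axis with
#' cumulative labels, an outer GC/AT/N composition track with min-max GC
#' range shading, a central log-scaled cumulative scaffold count region
#' with power-of-ten gridlines, the size-sorted scaffold length region
#' (drawn from each bin's shortest overlapping scaffold) with dashed
#' radial gridlines, red/dark-orange/light-orange overlays for the longest
#' scaffold, N50 and N90, an optional purple reference overlay, a BUSCO
#' completeness inset, and a statistics legend. Every layer is emitted as
#' a `<g>` group with a stable `id`. Rendering is deterministic: identical
#' inputs yield byte-identical SVG.
#'
#' @param summary An `assembly_summary`.
#' @param bins Bin series from [bin_assembly()] with `config$segments`
#'   bins over the resolved `max_span`.
#' @param busco Optional `busco_summary`.
#' @param scores Optional `snail_scores` (required for `show_score`).
#' @param reference Optional reference `assembly_summary`.
#' @param reference_bins Optional reference bin series (same segments and
#'   `max_span` as `bins`).
#' @param config A `snail_plot_config`.
#' @return An `xml2::xml_document` holding the SVG.
#' @export
render_snail <- function(summary, bins, busco = NULL, scores = NULL,
                         reference = NULL, reference_bins = NULL,
                         config = plot_config()) {
  geom <- resolve_geometry(summary, reference, config)
  segments <- config$segments
  if (nrow(bins) != segments) {
    stop("bin series has ", nrow(bins), " bins but config requests ",
         segments, " segments")
  }
  cx <- geom$center[1]
  cy <- geom$center[2]
  R <- geom$radius
  sf <- geom$scale_function
  r_len <- function(L) {
    R * (geom$scaffold_band[2] -
           diff(geom$scaffold_band) *
             radial_scale(L, geom$max_scaffold, sf))
  }
  f_end <- summary$span / geom$max_span
  occupied <- which(!bins$empty)
  bidx <- bins$index[occupied]

  parts <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    paste0("<svg xmlns=\"http://www.w3.org/2000/svg\" width=\"1000\" ",
           "height=\"1000\" viewBox=\"0 0 1000 1000\">"),
    "<rect width=\"1000\" height=\"1000\" fill=\"#ffffff\"/>"
  )

  ## composition track (Fig 1b): per-bin annular quads; N as white space
  ## split equally at both track edges, remainder split GC (dark, outer) /
  ## AT (light, inner) with the per-bin GC min-max range shaded about the
  ## mean
  comp <- c(sprintf("<g id=\"composition\">"))
  r_in_t <- R * geom$composition_band[1]
  r_out_t <- R * geom$composition_band[2]
  track_w <- r_out_t - r_in_t
  for (k in seq_along(occupied)) {
    b <- occupied[k]
    i <- bidx[k]
    f0 <- i / segments
    f1 <- min((i + 1) / segments, f_end)
    n_half <- bins$n_fraction_mean[b] * track_w / 2
    lo <- r_in_t + n_half
    hi <- r_out_t - n_half
    w <- hi - lo
    quad <- function(ra, rb, fill, class) {
      if (rb - ra < 1e-9) return(NULL)
      polygon_el(c(fmt_pt(polar_xy(cx, cy, f0, rb)),
                   fmt_pt(polar_xy(cx, cy, f1, rb)),
                   fmt_pt(polar_xy(cx, cy, f1, ra)),
                   fmt_pt(polar_xy(cx, cy, f0, ra))), fill, class = class)
    }
    b_min <- hi - bins$gc_min[b] * w
    b_mean <- hi - bins$gc_mean[b] * w
    b_max <- hi - bins$gc_max[b] * w
    comp <- c(comp,
      quad(lo, b_max, snail_palette$at, "comp-at"),
      quad(b_max, b_mean, snail_palette$gc_range_light, "comp-gc-range"),
      quad(b_mean, b_min, snail_palette$gc_range_dark, "comp-gc-range"),
      quad(b_min, hi, snail_palette$gc, "comp-gc"))
  }
  comp <- c(comp, "</g>")
  parts <- c(parts, comp)

  ## cumulative count region (Fig 1c): log axis with count 1 at the outer
  ## edge of the band, 10^ceil(log10(total)) at the center
  total_count <- summary$scaffold_count
  E <- max(1, ceiling(log10(total_count)))
  r_cnt <- function(cnt) {
    R * geom$count_band[2] * (1 - log10(pmax(cnt, 1)) / E)
  }
  cnt_pts <- stepped_region_points(
    cx, cy, bidx, r_cnt(bins$cumulative_count[occupied]),
    R * geom$count_band[2], segments, f_end)
  parts <- c(parts, "<g id=\"count\">",
             polygon_el(cnt_pts, snail_palette$count),
             vapply(seq_len(floor(log10(total_count))), function(k) {
               circle_el(cx, cy, r_cnt(10^k), "#ffffff", "count-gridline")
             }, ""),
             "</g>")

  ## reference shading below the target distribution (Fig 1h)
  has_ref <- !is.null(reference) && !is.null(reference_bins)
  if (has_ref) {
    rocc <- which(!reference_bins$empty)
    rf_end <- reference$span / geom$max_span
    ref_pts <- stepped_region_points(
      cx, cy, reference_bins$index[rocc],
      r_len(reference_bins$min_length[rocc]),
      R * geom$scaffold_band[2], segments, rf_end)
    parts <- c(parts, "<g id=\"reference-shading\">",
               polygon_el(ref_pts, snail_palette$reference, opacity = "0.35",
                          class = "reference-fill"),
               "</g>")
  }

  ## scaffold length region (Fig 1d), shaded from each bin's shortest
  ## overlapping scaffold
  sc_pts <- stepped_region_points(
    cx, cy, bidx, r_len(bins$min_length[occupied]),
    R * geom$scaffold_band[2], segments, f_end)
  parts <- c(parts, "<g id=\"scaffolds\">",
             polygon_el(sc_pts, snail_palette$scaffold), "</g>")

  ## N90 / N50 overlays (Fig 1f,g): constant depth, 0 to 90% / 50% of span
  overlay <- function(id, x_frac, L, fill) {
    f_x <- x_frac * f_end
    ext <- x_frac * geom$sweep_deg
    c(sprintf("<g id=\"%s\" data-extent-deg=\"%.4f\">", id, ext),
      polygon_el(wedge_points(cx, cy, f_x, R * geom$scaffold_band[2],
                              r_len(L), segments), fill),
      "</g>")
  }
  parts <- c(parts, overlay("n90", 0.9, summary$n90, snail_palette$n90))
  parts <- c(parts, overlay("n50", 0.5, summary$n50, snail_palette$n50))

  ## longest-scaffold overlay (Fig 1e): only when the first bin holds
  ## exactly one scaffold
  first_bin_single <- !bins$empty[1] && bins$cumulative_count[1] == 1
  if (first_bin_single) {
    f_l <- summary$longest / geom$max_span
    parts <- c(parts,
      sprintf("<g id=\"longest\" data-extent-deg=\"%.4f\">",
              360 * f_l),
      polygon_el(wedge_points(cx, cy, f_l, R * geom$scaffold_band[2],
                              r_len(summary$longest), segments),
                 snail_palette$longest),
      "</g>")
  }

  ## dashed white radial gridlines at major scaffold-length ticks
  ticks <- pretty(c(0, geom$max_scaffold), n = 5)
  ticks <- ticks[ticks > 0 & ticks <= geom$max_scaffold]
  parts <- c(parts, "<g id=\"scaffold-gridlines\">",
             vapply(ticks, function(t) {
               circle_el(cx, cy, r_len(t), "#ffffff", "scaffold-gridline",
                         dashed = TRUE)
             }, ""),
             "</g>")

  ## reference line above the distribution, continued across the
  ## composition track when the reference is shorter than the target
  if (has_ref) {
    rocc <- which(!reference_bins$empty)
    rf_end <- reference$span / geom$max_span
    line_pts <- stepped_line_points(
      cx, cy, reference_bins$index[rocc],
      r_len(reference_bins$min_length[rocc]), segments, rf_end)
    parts <- c(parts, "<g id=\"reference\">",
      sprintf(paste0("<polyline points=\"%s\" fill=\"none\" stroke=\"%s\" ",
                     "stroke-width=\"2\" class=\"reference-line\"/>"),
              paste(line_pts, collapse = " "), snail_palette$reference))
    if (reference$span < summary$span) {
      p1 <- polar_xy(cx, cy, rf_end, R * geom$scaffold_band[2])
      p2 <- polar_xy(cx, cy, rf_end, R * geom$composition_band[2])
      parts <- c(parts,
        sprintf(paste0("<line x1=\"%.2f\" y1=\"%.2f\" x2=\"%.2f\" ",
                       "y2=\"%.2f\" stroke=\"%s\" stroke-width=\"2\" ",
                       "class=\"reference-end\"/>"),
                p1[1], p1[2], p2[1], p2[2], snail_palette$reference))
    }
    parts <- c(parts, "</g>")
  }

  ## BUSCO completeness inset (Fig 1i)
  if (!is.null(busco)) {
    icx <- 870
    icy <- 130
    parts <- c(parts, "<g id=\"busco-inset\">",
               circle_el(icx, icy, 85, "#cccccc", "busco-outline"))
    cf <- busco$complete_fraction
    df <- busco$duplicated_fraction
    ff <- busco$fragmented_fraction
    if (cf > 0) {
      parts <- c(parts, polygon_el(
        donut_arc_points(icx, icy, 0, cf, 55, 85),
        snail_palette$busco_complete, class = "busco-complete"))
    }
    if (df > 0) {
      parts <- c(parts, polygon_el(
        donut_arc_points(icx, icy, 0, df, 55, 85),
        snail_palette$busco_duplicated, class = "busco-duplicated"))
    }
    if (ff > 0) {
      parts <- c(parts, polygon_el(
        donut_arc_points(icx, icy, cf, cf + ff, 55, 85),
        snail_palette$busco_fragmented, class = "busco-fragmented"))
    }
    if (!config$badge) {
      fmt_busco <- function(frac, count) {
        if (config$busco_numbers || config$show_numbers) {
          sprintf("%d", count)
        } else {
          format_number(frac, "percentage", config)
        }
      }
      label <- sprintf("BUSCO C:%s [S:%s, D:%s], F:%s, M:%s, n:%d",
                       fmt_busco(cf, busco$single + busco$duplicated),
                       fmt_busco(busco$single_fraction, busco$single),
                       fmt_busco(df, busco$duplicated),
                       fmt_busco(ff, busco$fragmented),
                       fmt_busco(busco$missing_fraction, busco$missing),
                       busco$total)
      parts <- c(parts,
                 text_el(icx, icy + 110, xml_escape(label), size = 14,
                         anchor = "middle", class = "busco-label"),
                 text_el(icx, icy + 128, xml_escape(busco$lineage),
                         size = 12, anchor = "middle",
                         class = "busco-lineage"))
    }
    parts <- c(parts, "</g>")
  }

  ## circumferential axis and legend text (suppressed on badges)
  if (!config$badge) {
    axis <- c("<g id=\"axis\">",
              circle_el(cx, cy, R * geom$composition_band[2], "#999999",
                        "axis-outline"))
    for (k in 0:9) {
      p <- k / 10
      f_t <- p * f_end
      p1 <- polar_xy(cx, cy, f_t, R)
      p2 <- polar_xy(cx, cy, f_t, R * 1.03)
      p3 <- polar_xy(cx, cy, f_t, R * 1.08)
      label <- if (config$show_numbers) {
        format_number(p * summary$span, "absolute", config)
      } else {
        sprintf("%d%%", as.integer(p * 100))
      }
      axis <- c(axis,
        sprintf(paste0("<line x1=\"%.2f\" y1=\"%.2f\" x2=\"%.2f\" ",
                       "y2=\"%.2f\" stroke=\"#999999\" class=\"axis-tick\"/>"),
                p1[1], p1[2], p2[1], p2[2]),
        text_el(p3[1], p3[2], xml_escape(label), size = 13,
                anchor = "middle", class = "axis-label"))
    }
    axis <- c(axis, "</g>")
    parts <- c(parts, axis)

    fmt <- function(v) format_number(v, "absolute", config)
    lines <- c(
      xml_escape(config$assembly_name %||% "assembly"),
      sprintf("Span: %s", fmt(summary$span)),
      sprintf("Scaffolds: %s", format(summary$scaffold_count)),
      sprintf("Longest: %s", fmt(summary$longest)),
      sprintf("N50: %s", fmt(summary$n50)),
      sprintf("N90: %s", fmt(summary$n90)),
      sprintf("GC: %s", format_number(summary$gc_fraction, "percentage",
                                      config)),
      sprintf("N: %s", format_number(summary$n_fraction, "percentage",
                                     config)))
    if (has_ref) {
      lines <- c(lines, sprintf("Reference: %s",
                                xml_escape(config$reference_name %||%
                                             "reference")))
    }
    legend <- c("<g id=\"legend\">",
                mapply(function(txt, i) {
                  text_el(20, 820 + 20 * i, txt, size = 15,
                          class = "legend-line")
                }, lines, seq_along(lines)),
                "</g>")
    parts <- c(parts, legend)

    if (config$show_score && !is.null(scores)) {
      val <- scores[[config$score_type]]
      if (!is.na(val)) {
        parts <- c(parts, "<g id=\"score\">",
                   text_el(980, 980,
                           xml_escape(sprintf("snail score (%s): %.3f",
                                              config$score_type, val)),
                           size = 16, anchor = "end", class = "score-label"),
                   "</g>")
      }
    }
  }

  parts <- c(parts, "</svg>")
  xml2::read_xml(paste(unlist(parts), collapse = "\n"))
}

#' Assemble the processed plot statistics for JSON/YAML export
#'
#' @param summary An `assembly_summary`.
#' @param bins Optional bin series.
#' @param busco Optional `busco_summary`.
#' @param scores Optional `snail_scores`.
#' @param name Dataset display name.
#' @return A plain nested list suitable for [export()].
#' @export
assemble_stats <- function(summary, bins = NULL, busco = NULL,
                           scores = NULL, name = "assembly") {
  out <- list(name = name, summary = unclass(summary))
  out$summary$sorted_lengths <- NULL
  if (!is.null(scores)) out$scores <- unclass(scores)
  if (!is.null(busco)) out$busco <- unclass(busco)
  if (!is.null(bins)) out$bins <- as.list(bins[!bins$empty, , drop = FALSE])
  out
}

#' Export a snail plot or its statistics
#'
#' The destination suffix selects the format: `.svg` writes the SVG
#' document verbatim, `.png` rasterizes it (via the rsvg package or an
#' `rsvg-convert` executable), `.json`/`.yaml` write the full processed
#' statistics from [assemble_stats()].
#'
#' @param x An `xml2::xml_document` (svg/png) or statistics list
#'   (json/yaml).
#' @param dest Output path with suffix `svg`, `png`, `json`, or `yaml`.
#' @return `dest`, invisibly.
#' @export
export <- function(x, dest) {
  ext <- tolower(tools::file_ext(dest))
  if (ext == "svg") {
    stopifnot(inherits(x, "xml_document"))
    writeLines(as.character(x), dest, sep = "")
  } else if (ext == "png") {
    stopifnot(inherits(x, "xml_document"))
    svg_tmp <- tempfile(fileext = ".svg")
    on.exit(unlink(svg_tmp))
    writeLines(as.character(x), svg_tmp, sep = "")
    if (requireNamespace("rsvg", quietly = TRUE)) {
      rsvg::rsvg_png(svg_tmp, dest)
    } else if (nzchar(Sys.which("rsvg-convert"))) {
      system2("rsvg-convert", c("-o", shQuote(dest), shQuote(svg_tmp)))
    } else {
      stop("PNG export requires the rsvg package or an rsvg-convert ",
           "executable")
    }
  } else if (ext == "json") {
    stopifnot(is.list(x), !inherits(x, "xml_document"))
    jsonlite::write_json(x, dest, auto_unbox = TRUE, digits = NA,
                         na = "null")
  } else if (ext == "yaml") {
    stopifnot(is.list(x), !inherits(x, "xml_document"))
    yaml::write_yaml(x, dest, precision = 15)
  } else {
    stop("unsupported output suffix '", ext,
         "' (valid suffixes: svg, png, json, yaml)")
  }
  invisible(dest)
}
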