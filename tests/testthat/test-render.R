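test_that("radial scale functions share endpoints and ordering", {
  for (fun in c("linear", "sqrt", "log")) {
    expect_equal(radial_scale(1e6, 1e6, fun), 1)
    expect_equal(radial_scale(0, 1e6, fun), 0)
  }
  expect_equal(radial_scale(25, 100, "sqrt"), 0.5)
  grid <- seq(0, 1e6, length.out = 101)
  expect_true(all(radial_scale(grid, 1e6, "sqrt") >=
                    radial_scale(grid, 1e6, "linear")))
  # monotone non-decreasing under every scale
  for (fun in c("linear", "sqrt", "log")) {
    expect_true(all(diff(radial_scale(grid, 1e6, fun)) >= 0))
  }
})

test_that("geometry resolves maxima and swept angle", {
  s <- summarize_assembly(rec(c(600, 400)))
  g <- resolve_geometry(s, config = plot_config())
  expect_equal(g$sweep_deg, 360)
  expect_equal(g$max_span, 1000)

  g2 <- resolve_geometry(s, config = plot_config(max_span = 2000))
  expect_equal(g2$sweep_deg, 180)

  # published-scale example: 2,560 Mb target on a 2,770,968,735 b axis
  big <- summarize_assembly(rec(2.56e9))
  g3 <- resolve_geometry(big, config = plot_config(max_span = 2770968735))
  expect_equal(g3$sweep_deg, 360 * 2.56e9 / 2770968735, tolerance = 1e-12)
  expect_lt(abs(g3$sweep_deg - 332.6), 0.1)

  expect_warning(resolve_geometry(s, config = plot_config(max_span = 500)),
                 "smaller")
  ref <- summarize_assembly(rec(c(1500, 500)))
  g4 <- resolve_geometry(s, reference = ref, config = plot_config())
  expect_equal(g4$max_span, 2000)
  expect_equal(g4$max_scaffold, 1500)
})

test_that("numbers format with unit suffixes and rounding strategies", {
  expect_equal(format_number(200127270), "200 Mb")
  expect_equal(format_number(0.11888, "percentage"), "11.89%")
  expect_equal(format_number(0.99999, "percentage",
                             plot_config(rounding = "down")), "99.99%")
  expect_equal(format_number(2540000), "2.54 Mb")
  expect_equal(format_number(2.54e9), "2.54 Gb")
  expect_equal(format_number(1234), "1.23 kb")
  expect_equal(format_number(999), "999")
  expect_equal(format_number(1235, config = plot_config(rounding = "up")),
               "1.24 kb")
  expect_equal(format_number(0.5, "percentage",
                             plot_config(decimal_precision = 0)), "50%")
})

test_that("rendering is deterministic and badge mode is text-free", {
  gen <- generate_assembly(
    assembly_profile("chromosomal", genome_size = 1e5,
                     chromosome_count = 5, seed = 8, name = "draw"))
  s <- summarize_assembly(gen$records)
  cfg <- plot_config(segments = 200)
  b <- bin_assembly(gen$records, 200)
  d1 <- render_snail(s, b, scores = score_assembly(s), config = cfg)
  d2 <- render_snail(s, b, scores = score_assembly(s), config = cfg)
  expect_identical(as.character(d1), as.character(d2))
  expect_gt(length(svg_texts(d1)), 0)

  badge <- render_snail(s, b, config = plot_config(segments = 200,
                                                   badge = TRUE))
  expect_length(svg_texts(badge), 0)
})

test_that("badge mode forces the linear scale function", {
  cfg <- plot_config(badge = TRUE, scale_function = "sqrt")
  expect_equal(cfg$scale_function, "linear")
})

test_that("N50/N90 overlays sweep their share of the assembly angle", {
  gen <- generate_assembly(
    assembly_profile("chromosomal", genome_size = 1e5,
                     chromosome_count = 4, seed = 14, name = "arcs"))
  s <- summarize_assembly(gen$records)
  segments <- 180
  b <- bin_assembly(gen$records, segments, max_span = 2 * s$span)
  cfg <- plot_config(segments = segments, max_span = 2 * s$span)
  doc <- render_snail(s, b, config = cfg)
  g <- resolve_geometry(s, config = cfg)
  tol <- 360 / segments
  n50 <- as.numeric(xml2::xml_attr(svg_group(doc, "n50"), "data-extent-deg"))
  n90 <- as.numeric(xml2::xml_attr(svg_group(doc, "n90"), "data-extent-deg"))
  expect_lt(abs(n50 - 0.5 * g$sweep_deg), tol)
  expect_lt(abs(n90 - 0.9 * g$sweep_deg), tol)
})

test_that("longest-scaffold overlay obeys the single-scaffold rule", {
  single <- rec(5000)
  s <- summarize_assembly(single)
  doc <- render_snail(s, bin_assembly(single, 100),
                      config = plot_config(segments = 100))
  red <- svg_group(doc, "longest")
  expect_false(is.na(xml2::xml_name(red)))
  expect_equal(as.numeric(xml2::xml_attr(red, "data-extent-deg")), 360)

  # many scaffolds in the first bin: no red overlay, count region crosses
  # at least three power-of-ten gridlines
  gen <- generate_assembly(
    assembly_profile("fragmented", genome_size = 2e6, scaffold_n50 = 1.5e3,
                     seed = 31, name = "frag"))
  sf <- summarize_assembly(gen$records)
  expect_gt(sf$scaffold_count, 1000)
  docf <- render_snail(sf, bin_assembly(gen$records, 100),
                       config = plot_config(segments = 100))
  expect_true(is.na(xml2::xml_name(svg_group(docf, "longest"))))
  gridlines <- xml2::xml_find_all(
    docf, "//*[local-name()='circle'][@class='count-gridline']")
  expect_gte(length(gridlines), 3)
})

test_that("scaffold region area approximates relative auN", {
  set.seed(77)
  lens <- sort(pmax(round(rlnorm(400, 9, 0.6)), 50), decreasing = TRUE)
  r <- rec(lens)
  s <- summarize_assembly(r)
  segments <- 200
  b <- bin_assembly(r, segments)
  # span-weighted mean of the drawn (linear) radial value per bin
  filled <- mean(b$min_length[!b$empty] / s$longest)
  expect_lt(abs(filled - s$aun / s$longest), 2 / segments + 0.01)
})

test_that("reference overlay draws shading, line, and end marker", {
  target <- rec(c(600, 250, 100))
  ref <- rec(c(900, 600, 300))
  st <- summarize_assembly(target)
  sr <- summarize_assembly(ref)
  cfg <- plot_config(segments = 120)
  g <- resolve_geometry(st, sr, cfg)
  doc <- render_snail(st, bin_assembly(target, 120, max_span = g$max_span),
                      reference = sr,
                      reference_bins = bin_assembly(ref, 120,
                                                    max_span = g$max_span),
                      config = cfg)
  expect_false(is.na(xml2::xml_name(svg_group(doc, "reference"))))
  expect_false(is.na(xml2::xml_name(svg_group(doc, "reference-shading"))))
  # reference longer than target: no end-of-reference marker
  expect_length(xml2::xml_find_all(
    doc, "//*[local-name()='line'][@class='reference-end']"), 0)

  # shorter reference: purple line continues across the composition track
  short_ref <- rec(c(300, 100))
  ssr <- summarize_assembly(short_ref)
  g2 <- resolve_geometry(st, ssr, cfg)
  doc2 <- render_snail(st, bin_assembly(target, 120, max_span = g2$max_span),
                       reference = ssr,
                       reference_bins = bin_assembly(short_ref, 120,
                                                     max_span = g2$max_span),
                       config = cfg)
  expect_length(xml2::xml_find_all(
    doc2, "//*[local-name()='line'][@class='reference-end']"), 1)
})

test_that("export writes valid SVG and round-trips statistics", {
  gen <- generate_assembly(
    assembly_profile("chromosomal", genome_size = 5e4,
                     chromosome_count = 4, n_run_rate = 5, seed = 44,
                     name = "exp"))
  s <- summarize_assembly(gen$records)
  b <- bin_assembly(gen$records, 50)
  doc <- render_snail(s, b, config = plot_config(segments = 50))

  svg_path <- tempfile(fileext = ".svg")
  export(doc, svg_path)
  reparsed <- xml2::read_xml(svg_path)
  expect_equal(xml2::xml_name(reparsed), "svg")

  stats <- assemble_stats(s, b, scores = score_assembly(s), name = "exp")
  yml <- tempfile(fileext = ".yaml")
  export(stats, yml)
  back <- yaml::read_yaml(yml)
  expect_equal(back$summary$span, s$span)
  expect_equal(back$summary$aun, s$aun, tolerance = 1e-12)
  expect_equal(back$scores$base, stats$scores$base, tolerance = 1e-12)

  jsn <- tempfile(fileext = ".json")
  export(stats, jsn)
  jback <- jsonlite::fromJSON(jsn)
  expect_equal(jback$summary$n50, s$n50)

  expect_error(export(doc, tempfile(fileext = ".bmp")),
               "svg, png, json, yaml")
})
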