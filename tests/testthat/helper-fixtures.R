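# Shared helpers: lightweight record construction, file fixtures, and the
# independent brute-force auN oracle used to validate the closed form.

# build sequence records directly from counts (no sequence needed)
rec <- function(lengths, gc = NULL, n = NULL, ids = NULL) {
  k <- length(lengths)
  if (is.null(n)) n <- rep(0, k)
  if (is.null(gc)) gc <- floor((lengths - n) / 2)
  if (is.null(ids)) ids <- sprintf("s%d", seq_len(k))
  structure(
    data.frame(id = ids, length = as.numeric(lengths),
               gc_count = as.numeric(gc),
               at_count = as.numeric(lengths - n - gc),
               n_count = as.numeric(n), stringsAsFactors = FALSE),
    class = c("snail_records", "data.frame"))
}

write_fasta_lines <- function(lines) {
  path <- tempfile(fileext = ".fa")
  writeLines(lines, path)
  path
}

gzip_copy <- function(path) {
  out <- paste0(path, ".gz")
  con <- gzfile(out, "wb")
  writeBin(readBin(path, "raw", file.size(path)), con)
  close(con)
  out
}

# Independent oracle: auN as the mean of the N(x) step curve over a fine
# x grid (midpoints of 1000 equal slices of (0, 1)).
brute_force_aun <- function(lengths, grid = 1000) {
  sorted <- sort(lengths, decreasing = TRUE)
  span <- sum(sorted)
  cum <- cumsum(sorted)
  xs <- (seq_len(grid) - 0.5) / grid
  mean(vapply(xs, function(x) sorted[which(cum >= x * span)[1]], 0))
}

# random assembly for property sweeps
random_records <- function(n, seed, with_n = FALSE) {
  set.seed(seed)
  len <- pmax(round(rlnorm(n, 8, 1.2)), 10)
  nn <- if (with_n) floor(len * runif(n, 0, 0.3)) else rep(0, n)
  rec(len, n = nn)
}

svg_texts <- function(doc) {
  xml2::xml_find_all(doc, "//*[local-name()='text']")
}

svg_group <- function(doc, id) {
  xml2::xml_find_first(doc, sprintf("//*[local-name()='g'][@id='%s']", id))
}
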