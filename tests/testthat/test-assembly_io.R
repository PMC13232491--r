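test_that("read_fasta classifies every base case-insensitively", {
  fa <- write_fasta_lines(c(">s1 some description", "ACGT"))
  r <- read_fasta(fa)
  expect_equal(r$id, "s1")
  expect_equal(r$length, 4)
  expect_equal(r$gc_count, 2)
  expect_equal(r$at_count, 2)
  expect_equal(r$n_count, 0)

  fa2 <- write_fasta_lines(c(">s1", "ACGTNNacgtn"))
  r2 <- read_fasta(fa2)
  expect_equal(unlist(r2[, c("length", "gc_count", "at_count", "n_count")]),
               c(length = 11, gc_count = 4, at_count = 4, n_count = 3))
})

test_that("non-ACGTN ambiguity codes and gaps count as N", {
  fa <- write_fasta_lines(c(">amb", "ACGTRYKMSWBDHV-N"))
  r <- read_fasta(fa)
  expect_equal(r$gc_count + r$at_count, 4)
  expect_equal(r$n_count, 12)
  expect_equal(r$gc_count + r$at_count + r$n_count, r$length)
})

test_that("read_fasta errors are informative", {
  expect_error(read_fasta(tempfile()), "cannot read FASTA")
  bad <- write_fasta_lines(c("", "ACGT no header"))
  expect_error(read_fasta(bad), "line 2")
  empty <- tempfile(fileext = ".fa")
  file.create(empty)
  expect_error(read_fasta(empty), "no sequences")
  zero <- write_fasta_lines(c(">a", ">b", "ACGT"))
  expect_error(read_fasta(zero), "zero-length")
})

test_that("gzip-compressed FASTA reads identically to plain", {
  gen <- generate_assembly(
    assembly_profile("fragmented", genome_size = 5e4, scaffold_n50 = 5e3,
                     n_run_rate = 20, seed = 11, name = "gztest"),
    dir = tempfile())
  plain <- read_fasta(gen$fasta)
  gz <- read_fasta(gzip_copy(gen$fasta))
  expect_identical(plain, gz)
})

test_that("total record length equals non-header character count", {
  gen <- generate_assembly(
    assembly_profile("chromosomal", genome_size = 3e4,
                     chromosome_count = 3, seed = 5, name = "chars"),
    dir = tempfile())
  lines <- readLines(gen$fasta)
  chars <- sum(nchar(trimws(lines[!startsWith(lines, ">")])))
  expect_equal(sum(read_fasta(gen$fasta)$length), chars)
})

test_that("BUSCO tables parse one row per hit with lineage detection", {
  tbl <- tempfile(fileext = ".tsv")
  writeLines(c(
    "# BUSCO version is: 6.0.0",
    "# The lineage dataset is: rodentia_odb12 (Creation date: 2025-01-01, number of BUSCOs: 4)",
    "# Busco id\tStatus\tSequence\tGene Start\tGene End\tStrand\tScore\tLength\tOrthoDB url\tDescription",
    "1at100\tComplete\tscafA\t1\t100\t+\t50\t99\turl\tdesc",
    "2at100\tDuplicated\tscafA\t1\t100\t+\t50\t99\turl\tdesc",
    "2at100\tDuplicated\tscafB\t1\t100\t+\t50\t99\turl\tdesc",
    "3at100\tMissing"), tbl)
  parsed <- parse_busco_table(tbl)
  expect_equal(parsed$lineage, "rodentia_odb12")
  expect_equal(nrow(parsed$genes), 4)
  expect_equal(sum(parsed$genes$busco_id == "2at100"), 2)
  expect_true(is.na(parsed$genes$scaffold_id[parsed$genes$status == "Missing"]))
})

test_that("BUSCO parse errors quote the offending token", {
  tbl <- tempfile()
  writeLines(c("# header", "1at1\tPartial\tscaf"), tbl)
  expect_error(parse_busco_table(tbl), "Partial")
  empty <- tempfile()
  writeLines("# only comments", empty)
  expect_error(parse_busco_table(empty), "no data rows")
})

test_that("v4, v5, and v6 dialects parse to the same gene multiset", {
  ids <- sprintf("scaffold_%d", 1:6)
  tables <- lapply(c(4, 5, 6), function(v) {
    path <- tempfile(fileext = ".tsv")
    generate_busco_table(40, 0.9, 0.1, 0.05, scaffold_ids = ids,
                         version = v, seed = 42, path = path)
    parse_busco_table(path)$genes
  })
  key <- function(g) {
    g <- g[order(g$busco_id, g$status, g$scaffold_id), ]
    rownames(g) <- NULL
    g
  }
  expect_identical(key(tables[[1]]), key(tables[[2]]))
  expect_identical(key(tables[[2]]), key(tables[[3]]))
})

test_that("BlobDir write/read round-trips records and BUSCO hits", {
  gen <- generate_assembly(
    assembly_profile("chromosomal", genome_size = 2e4,
                     chromosome_count = 3, n_run_rate = 10, seed = 2,
                     name = "bd"))
  busco <- generate_busco_table(30, 0.9, 0.1, 0.03,
                                scaffold_ids = gen$records$id, seed = 9)
  dir <- tempfile()
  bundle <- write_blobdir(gen$records, dir, busco = busco, name = "bd")
  expect_equal(bundle$meta$records, nrow(gen$records))
  expect_length(bundle$length, nrow(gen$records))
  expect_true(file.exists(file.path(dir, "eukaryota_odb10_busco.json")))

  back <- read_blobdir(dir)
  expect_equal(back$records$length, gen$records$length)
  expect_equal(back$records$gc_count, gen$records$gc_count)
  expect_equal(back$records$at_count, gen$records$at_count)
  expect_equal(back$records$n_count, gen$records$n_count)
  key <- function(g) {
    g <- g[order(g$busco_id, g$status, g$scaffold_id), ]
    rownames(g) <- NULL
    g
  }
  expect_identical(key(back$busco$genes), key(busco$genes))
})

test_that("BlobDir accepts gzip members and enforces mandatory fields", {
  dir <- tempfile()
  write_blobdir(rec(c(300, 200, 100), n = c(30, 0, 10)), dir)
  expect_null(read_blobdir(dir)$busco)

  # gzip one member in place
  gz <- gzip_copy(file.path(dir, "gc.json"))
  file.remove(file.path(dir, "gc.json"))
  back <- read_blobdir(dir)
  expect_equal(back$records$length, c(300, 200, 100))
  expect_equal(back$records$n_count, c(30, 0, 10))

  file.remove(file.path(dir, "ncount.json"))
  expect_error(read_blobdir(dir), "missing field: ncount")
})
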