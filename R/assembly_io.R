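#' Read an assembly FASTA into per-scaffold sequence records
#'
#' Reads a plain or gzip-compressed FASTA file (local path or http(s) URL)
#' and classifies every base of every scaffold into one of three bins: GC
#' (G or C), AT (A or T), or N (N, any other IUPAC ambiguity code, or a gap
#' character). Classification is case-insensitive. These per-scaffold counts
#' are all that downstream statistics, scores, and plots require.
#'
#' @param source Path or http(s) URL of a FASTA file, optionally
#'   gzip-compressed.
#' @return A `snail_records` data frame with one row per sequence in file
#'   order and columns `id`, `length`, `gc_count`, `at_count`, `n_count`.
#'   Counts always satisfy `gc_count + at_count + n_count == length`.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">s1", "ACGTNNacgtn"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(source) {
  path <- local_source(source)
  if (!file.exists(path)) {
    stop("cannot read FASTA source: ", source)
  }
  check_fasta_header(path)
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0) {
    stop("no sequences in FASTA source: ", source)
  }
  len <- Biostrings::width(seqs)
  if (any(len == 0)) {
    stop("zero-length sequence in FASTA source: ",
         names(seqs)[which(len == 0)[1]])
  }
  gc <- as.numeric(Biostrings::letterFrequency(seqs, "GC"))
  at <- as.numeric(Biostrings::letterFrequency(seqs, "AT"))
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) {
    stop("duplicate sequence identifier: ", ids[anyDuplicated(ids)])
  }
  new_records(id = ids, length = as.numeric(len), gc_count = gc,
              at_count = at, n_count = as.numeric(len) - gc - at)
}

# First non-blank line must be a FASTA header; report the line number if not.
check_fasta_header <- function(path) {
  con <- gzfile(path, "rt")
  on.exit(close(con))
  lineno <- 0L
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0) stop("no sequences in FASTA source: ", path)
    lineno <- lineno + 1L
    if (nzchar(trimws(line))) break
  }
  if (!startsWith(trimws(line), ">")) {
    stop("malformed FASTA (expected '>' header) at line ", lineno,
         " of ", path)
  }
  invisible(TRUE)
}

new_records <- function(id, length, gc_count, at_count, n_count) {
  stopifnot(all(nzchar(id)), all(length >= 1),
            all(gc_count >= 0), all(at_count >= 0), all(n_count >= 0))
  structure(
    data.frame(id = id, length = length, gc_count = gc_count,
               at_count = at_count, n_count = n_count,
               stringsAsFactors = FALSE),
    class = c("snail_records", "data.frame")
  )
}

#' Parse a BUSCO full table
#'
#' Accepts full-table TSVs written by BUSCO versions 4, 5, and 6 (odb10 or
#' odb12 lineages). Comment lines beginning `#` form the header; the lineage
#' name is extracted from the header when present. Data rows start with
#' `busco_id` and `status` columns; located hits carry the scaffold in the
#' third column, `Missing` rows carry none. Duplicated markers appear as one
#' row per hit.
#'
#' @param source Path or http(s) URL of a BUSCO full table TSV.
#' @return A list with elements `lineage` (string, `"unknown"` when the
#'   header does not name one) and `genes`, a data frame with columns
#'   `busco_id`, `status` (one of Complete, Duplicated, Fragmented,
#'   Missing), and `scaffold_id` (`NA` for Missing markers).
#' @export
parse_busco_table <- function(source) {
  path <- local_source(source)
  if (!file.exists(path)) stop("cannot read BUSCO table: ", source)
  lines <- readLines(gzfile(path), warn = FALSE)
  comments <- lines[startsWith(lines, "#")]
  rows <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  if (length(rows) == 0) stop("no data rows in BUSCO table: ", source)

  lineage <- "unknown"
  for (cm in comments) {
    m <- regmatches(cm, regexpr("[A-Za-z0-9]+_odb[0-9]+", cm))
    if (length(m) == 1) {
      lineage <- m
      break
    }
    m <- regmatches(cm, regexec("lineage[ _]dataset[^:]*:\\s*(\\S+)", cm))[[1]]
    if (length(m) == 2) {
      lineage <- m[2]
      break
    }
  }

  fields <- strsplit(rows, "\t", fixed = TRUE)
  busco_id <- vapply(fields, `[`, "", 1L)
  status <- vapply(fields, function(f) if (length(f) >= 2) f[2] else "", "")
  scaffold <- vapply(fields, function(f) {
    if (length(f) >= 3 && nzchar(f[3])) f[3] else NA_character_
  }, "")
  valid <- c("Complete", "Duplicated", "Fragmented", "Missing")
  bad <- setdiff(unique(status), valid)
  if (length(bad) > 0) {
    stop("unknown BUSCO status '", bad[1], "' (expected one of: ",
         paste(valid, collapse = ", "), ")")
  }
  scaffold[status == "Missing"] <- NA_character_
  list(
    lineage = lineage,
    genes = data.frame(busco_id = busco_id, status = status,
                       scaffold_id = scaffold, stringsAsFactors = FALSE)
  )
}

# ---------------------------------------------------------------------------
# Minimal BlobDir-style dataset: one JSON file per field (meta.json,
# length.json, gc.json, n.json, ncount.json, {lineage}_busco.json), each an
# object with a "values" array in the shared scaffold order recorded in
# meta.json. ".json.gz" members are accepted on read. The gc file stores the
# GC proportion of ATGC bases, n the N proportion of total length, and ncount
# integer N counts, so integer base counts round-trip exactly via length and
# ncount.

#' Write sequence records as a minimal BlobDir-style dataset
#'
#' @param records A `snail_records` data frame (see [read_fasta()]).
#' @param dest Directory to create/populate.
#' @param busco Optional list as returned by [parse_busco_table()]; when
#'   present a `{lineage}_busco.json` field is written holding the located
#'   hits per scaffold plus the identifiers of missing markers.
#' @param name Dataset display name recorded in `meta.json`.
#' @return The written bundle, invisibly: a list with `meta` plus the
#'   per-field value arrays.
#' @export
write_blobdir <- function(records, dest, busco = NULL, name = "assembly") {
  stopifnot(inherits(records, "data.frame"), nrow(records) > 0)
  if (!dir.exists(dest)) {
    ok <- dir.create(dest, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create BlobDir directory: ", dest)
  }
  if (file.access(dest, 2) != 0) stop("BlobDir directory not writable: ", dest)

  n <- nrow(records)
  atgc <- records$gc_count + records$at_count
  gc_prop <- ifelse(atgc > 0, records$gc_count / atgc, 0)
  n_prop <- records$n_count / records$length

  fields <- list(
    length = list(id = "length", type = "variable", datatype = "integer"),
    gc = list(id = "gc", type = "variable", datatype = "float"),
    n = list(id = "n", type = "variable", datatype = "float"),
    ncount = list(id = "ncount", type = "variable", datatype = "integer")
  )
  meta <- list(name = name, records = n, identifiers = records$id,
               fields = unname(fields))

  values <- list(length = records$length, gc = gc_prop, n = n_prop,
                 ncount = records$n_count)
  busco_field <- NULL
  if (!is.null(busco)) {
    lineage <- busco$lineage %||% "unknown"
    hits <- busco$genes[!is.na(busco$genes$scaffold_id), , drop = FALSE]
    unknown <- setdiff(hits$scaffold_id, records$id)
    if (length(unknown) > 0) {
      stop("BUSCO hit on unknown scaffold: ", unknown[1])
    }
    per_scaffold <- lapply(records$id, function(sid) {
      sel <- hits$scaffold_id == sid
      unname(Map(function(b, s) list(b, s), hits$busco_id[sel],
                 hits$status[sel]))
    })
    missing_ids <- unique(
      busco$genes$busco_id[busco$genes$status == "Missing"])
    busco_field <- sprintf("%s_busco", lineage)
    meta$busco <- list(lineage = lineage,
                       total = length(unique(busco$genes$busco_id)))
    meta$fields <- c(meta$fields,
                     list(list(id = busco_field, type = "multi_array",
                               datatype = "mixed")))
    values[[busco_field]] <- list(values = per_scaffold,
                                  missing = as.list(missing_ids))
  }

  jsonlite::write_json(meta, file.path(dest, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  for (f in c("length", "gc", "n", "ncount")) {
    jsonlite::write_json(list(values = values[[f]]),
                         file.path(dest, paste0(f, ".json")),
                         auto_unbox = FALSE, digits = NA)
  }
  if (!is.null(busco_field)) {
    jsonlite::write_json(values[[busco_field]],
                         file.path(dest, paste0(busco_field, ".json")),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(c(list(meta = meta), values))
}

read_blobdir_member <- function(dir, field, required = TRUE) {
  for (suffix in c(".json", ".json.gz")) {
    path <- file.path(dir, paste0(field, suffix))
    if (file.exists(path)) {
      con <- gzfile(path, "rt")
      on.exit(close(con))
      return(jsonlite::fromJSON(paste(readLines(con, warn = FALSE),
                                      collapse = "\n"),
                                simplifyVector = TRUE,
                                simplifyDataFrame = FALSE,
                                simplifyMatrix = FALSE))
    }
  }
  if (required) stop("missing field: ", field)
  NULL
}

#' Read a minimal BlobDir-style dataset
#'
#' Reconstructs sequence records from the `meta`, `length`, `gc`, `n`, and
#' `ncount` fields (plain or gzip-compressed JSON members); integer GC/AT
#' counts are recovered from the stored proportions and lengths, rounded to
#' integers. An optional `{lineage}_busco` field is returned alongside.
#'
#' @param source BlobDir directory path.
#' @return A list with `records` (a `snail_records` data frame), `busco`
#'   (as from [parse_busco_table()], or `NULL`), and `name`.
#' @export
read_blobdir <- function(source) {
  if (!dir.exists(source)) stop("cannot read BlobDir directory: ", source)
  meta <- read_blobdir_member(source, "meta")
  n <- meta$records
  len <- as.numeric(unlist(read_blobdir_member(source, "length")$values))
  gc_prop <- as.numeric(unlist(read_blobdir_member(source, "gc")$values))
  n_prop <- as.numeric(unlist(read_blobdir_member(source, "n")$values))
  ncount <- as.numeric(unlist(read_blobdir_member(source, "ncount")$values))
  for (v in list(len, gc_prop, n_prop, ncount)) {
    if (length(v) != n) {
      stop("field array length ", length(v),
           " does not match meta record count ", n)
    }
  }
  ids <- as.character(unlist(meta$identifiers))
  if (length(ids) != n) stop("meta identifiers do not match record count")
  gc <- round(gc_prop * (len - ncount))
  records <- new_records(id = ids, length = len, gc_count = gc,
                         at_count = len - ncount - gc, n_count = ncount)

  busco <- NULL
  if (!is.null(meta$busco)) {
    field <- sprintf("%s_busco", meta$busco$lineage)
    raw <- read_blobdir_member(source, field, required = FALSE)
    if (!is.null(raw)) {
      rows <- list()
      for (i in seq_along(raw$values)) {
        for (hit in raw$values[[i]]) {
          rows[[length(rows) + 1L]] <- data.frame(
            busco_id = as.character(hit[[1]]),
            status = as.character(hit[[2]]),
            scaffold_id = ids[i], stringsAsFactors = FALSE)
        }
      }
      for (mid in raw$missing) {
        rows[[length(rows) + 1L]] <- data.frame(
          busco_id = as.character(mid), status = "Missing",
          scaffold_id = NA_character_, stringsAsFactors = FALSE)
      }
      genes <- if (length(rows) > 0) do.call(rbind, rows) else
        data.frame(busco_id = character(), status = character(),
                   scaffold_id = character(), stringsAsFactors = FALSE)
      busco <- list(lineage = meta$busco$lineage, genes = genes)
    }
  }
  list(records = records, busco = busco, name = meta$name %||% "assembly")
}
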