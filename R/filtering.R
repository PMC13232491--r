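#' Parse a scaffold filter expression
#'
#' Grammar: `{field}:{kind}=value` with kinds `min` and `max` (inclusive
#' numeric bounds; values may contain comma thousands separators) or `keys`
#' and `inv` (comma-separated keyword lists to exclude or keep). The
#' BlobToolKit-compatible `--` dialect `{field}--{Kind}=value` is accepted
#' with a case-insensitive kind.
#'
#' @param text Filter expression, e.g. `"length:min=1,000"`.
#' @return A `filter_expression` list: `field`, `kind`, `value`.
#' @export
parse_filter <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  m <- regmatches(text, regexec("^([^:=-]+)--([A-Za-z]+)=(.*)$", text))[[1]]
  if (length(m) == 0 || length(m) < 4) {
    m <- regmatches(text, regexec("^([^:=]+):([A-Za-z]+)=(.*)$", text))[[1]]
  }
  if (length(m) < 4) {
    stop("cannot parse filter '", text,
         "'; expected {field}:{kind}=value or {field}--{Kind}=value")
  }
  field <- m[2]
  kind <- tolower(m[3])
  raw <- m[4]
  valid <- c("min", "max", "keys", "inv")
  if (!kind %in% valid) {
    stop("unknown filter kind '", m[3], "' (valid kinds: ",
         paste(valid, collapse = ", "), ")")
  }
  if (kind %in% c("min", "max")) {
    value <- suppressWarnings(as.numeric(gsub(",", "", raw, fixed = TRUE)))
    if (is.na(value)) {
      stop("non-numeric value '", raw, "' for filter kind '", kind, "'")
    }
  } else {
    value <- strsplit(raw, ",", fixed = TRUE)[[1]]
    value <- value[nzchar(value)]
    if (length(value) == 0) {
      stop("empty keyword list for filter kind '", kind, "'")
    }
  }
  structure(list(field = field, kind = kind, value = value),
            class = "filter_expression")
}

# Resolve a filterable field to a per-record vector. The minimal dataset
# exposes exactly the per-scaffold values it stores.
filter_field_values <- function(records, field) {
  switch(field,
    id = ,
    identifiers = records$id,
    length = records$length,
    gc = {
      atgc <- records$gc_count + records$at_count
      ifelse(atgc > 0, records$gc_count / atgc, 0)
    },
    n = records$n_count / records$length,
    ncount = records$n_count,
    stop("cannot resolve filter field '", field, "' on these records")
  )
}

#' Apply filter expressions to sequence records
#'
#' All expressions are combined as a conjunction (AND). `min`/`max` keep
#' records whose field value is `>=`/`<=` the threshold (inclusive);
#' `keys` excludes records whose value is in the keyword list; `inv` keeps
#' only listed values. Filtering is idempotent.
#'
#' @param records A `snail_records` data frame.
#' @param expressions List of `filter_expression` objects (or strings,
#'   parsed on the fly).
#' @return The retained records, same class as the input.
#' @export
apply_filters <- function(records, expressions) {
  if (length(expressions) == 0) return(records)
  if (inherits(expressions, "filter_expression")) {
    expressions <- list(expressions)
  }
  keep <- rep(TRUE, nrow(records))
  for (expr in expressions) {
    if (is.character(expr)) expr <- parse_filter(expr)
    values <- filter_field_values(records, expr$field)
    keep <- keep & switch(expr$kind,
      min = values >= expr$value,
      max = values <= expr$value,
      keys = !(as.character(values) %in% expr$value),
      inv = as.character(values) %in% expr$value
    )
  }
  if (!any(keep)) stop("empty assembly after filtering")
  records[keep, , drop = FALSE]
}
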