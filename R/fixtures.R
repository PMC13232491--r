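#' Synthetic assembly profile
#'
#' Describes a deterministic synthetic assembly for testing. Two stock
#' kinds are provided. `"chromosomal"` emits `chromosome_count` near-equal
#' chromosome-scale scaffolds (5% length spread) plus a short-scaffold
#' tail holding `tail_fraction` of the span, mimicking the stepped length
#' profile of chromosome-level assemblies where a few percent of the span
#' sits in unplaced scaffolds. `"fragmented"` emits a heavy-tailed
#' log-normal scaffold length distribution (the smooth spiral profile of
#' scaffold-level assemblies) with interspersed N runs. `"custom"` takes
#' the log-normal parameters directly.
#'
#' @param kind One of `"chromosomal"`, `"fragmented"`, `"custom"`.
#' @param genome_size Target span in bases; generated span equals it
#'   exactly.
#' @param chromosome_count Chromosome count for the chromosomal kind.
#' @param tail_fraction Fraction of span in the short-scaffold tail.
#' @param scaffold_n50 Target scaffold N50 for the fragmented kind; sets
#'   `length_meanlog = log(scaffold_n50) - length_sdlog^2` via the
#'   length-biased median of the log-normal.
#' @param length_meanlog,length_sdlog Log-normal scaffold length
#'   parameters (sdlog 1.5 reflects the heavy tail typical of fragmented
#'   assemblies).
#' @param gc_mean,gc_sd Per-scaffold GC proportion distribution.
#' @param n_run_rate Expected N bases per kb, realised as runs of
#'   geometric length (mean 100 b).
#' @param min_length Minimum scaffold length in bases.
#' @param seed RNG seed; identical seeds give byte-identical output.
#' @param name Dataset name used for generated file names.
#' @return An `assembly_profile` list.
#' @export
assembly_profile <- function(kind = c("chromosomal", "fragmented", "custom"),
                             genome_size = 1e7, chromosome_count = 10,
                             tail_fraction = 0.04, scaffold_n50 = NULL,
                             length_meanlog = NULL, length_sdlog = 1.5,
                             gc_mean = 0.41, gc_sd = 0.02, n_run_rate = 0,
                             min_length = 100, seed = 1, name = "synthetic") {
  kind <- match.arg(kind)
  if (genome_size < 1000) stop("genome_size must be at least 1 kb")
  if (kind == "chromosomal") {
    if (chromosome_count < 1) stop("chromosome_count must be >= 1")
    if (chromosome_count > genome_size / 1000) {
      stop("infeasible profile: chromosome_count too large for genome_size")
    }
  } else {
    if (is.null(length_meanlog)) {
      if (is.null(scaffold_n50)) {
        stop("fragmented/custom profiles need scaffold_n50 or length_meanlog")
      }
      length_meanlog <- log(scaffold_n50) - length_sdlog^2
    }
  }
  structure(list(
    kind = kind, genome_size = genome_size,
    chromosome_count = chromosome_count, tail_fraction = tail_fraction,
    length_meanlog = length_meanlog, length_sdlog = length_sdlog,
    gc_mean = gc_mean, gc_sd = gc_sd, n_run_rate = n_run_rate,
    min_length = min_length, seed = seed, name = name
  ), class = "assembly_profile")
}

# draw scaffold lengths for a profile; sums exactly to genome_size
profile_lengths <- function(p) {
  g <- p$genome_size
  if (p$kind == "chromosomal") {
    k <- p$chromosome_count
    main <- round(g * (1 - p$tail_fraction))
    base <- main / k
    ch <- pmax(round(stats::rnorm(k, base, 0.05 * base)), p$min_length)
    ch[k] <- ch[k] + (main - sum(ch))
    if (ch[k] < 1) stop("infeasible chromosomal profile")
    tail_span <- g - main
    tl <- numeric(0)
    while (sum(tl) < tail_span) {
      tl <- c(tl, pmax(round(stats::rlnorm(256, log(base / 100), 1)), 50))
    }
    cut <- which(cumsum(tl) >= tail_span)[1]
    tl <- tl[seq_len(cut)]
    tl[cut] <- tl[cut] - (sum(tl) - tail_span)
    c(ch, tl[tl >= 1])
  } else {
    lens <- numeric(0)
    while (sum(lens) < g) {
      lens <- c(lens, pmax(round(stats::rlnorm(1024, p$length_meanlog,
                                               p$length_sdlog)),
                           p$min_length))
    }
    cut <- which(cumsum(lens) >= g)[1]
    lens <- lens[seq_len(cut)]
    lens[cut] <- lens[cut] - (sum(lens) - g)
    lens[lens >= 1]
  }
}

#' Generate a synthetic assembly
#'
#' Draws scaffold lengths and per-base composition for the profile,
#' producing sequence records whose GC/AT/N counts are tallied from the
#' actual generated bases (the truth record), and optionally writing the
#' assembly as FASTA with a YAML truth sidecar. The generator is fully
#' seeded: the same profile yields byte-identical files.
#'
#' @param profile An [assembly_profile()].
#' @param dir Optional output directory; when given, writes
#'   `<name>.fa` and `<name>.fa.truth.yaml`.
#' @return List with `records` (a `snail_records` data frame), `truth`
#'   (per-scaffold counts plus profile facts), `profile`, and `fasta`
#'   (path or `NULL`).
#' @export
generate_assembly <- function(profile, dir = NULL) {
  stopifnot(inherits(profile, "assembly_profile"))
  with_seed(profile$seed, {
    len <- profile_lengths(profile)
    n <- length(len)
    ids <- sprintf("scaffold_%d", seq_len(n))
    gc_target <- pmin(pmax(stats::rnorm(n, profile$gc_mean, profile$gc_sd),
                           0.2), 0.8)
    total <- sum(len)
    ends <- cumsum(len)
    starts <- ends - len

    gcv <- rep(gc_target, len)
    u1 <- stats::runif(total)
    u2 <- stats::runif(total)
    # utf8 codes: A=65 T=84 C=67 G=71 N=78
    codes <- c(65L, 84L, 67L, 71L)[1L + (u2 < 0.5) + 2L * (u1 < gcv)]
    rm(gcv, u1, u2)

    if (profile$n_run_rate > 0) {
      lambda <- len * profile$n_run_rate / 1000 / 100
      k <- stats::rpois(n, lambda)
      if (sum(k) > 0) {
        sidx <- rep(seq_len(n), k)
        pos <- floor(stats::runif(sum(k)) * len[sidx])
        rl <- stats::rgeom(sum(k), 1 / 100) + 1
        from <- starts[sidx] + pos + 1
        to <- pmin(starts[sidx] + pos + rl, ends[sidx])
        idx <- unlist(mapply(function(a, b) a:b, from, to,
                             SIMPLIFY = FALSE), use.names = FALSE)
        codes[idx] <- 78L
      }
    }

    grp <- rep(seq_len(n), len)
    gc_count <- as.numeric(rowsum(as.integer(codes == 67L | codes == 71L),
                                  grp))
    n_count <- as.numeric(rowsum(as.integer(codes == 78L), grp))
    at_count <- len - gc_count - n_count
    records <- new_records(ids, len, gc_count, at_count, n_count)

    truth <- list(
      name = profile$name, kind = profile$kind, seed = profile$seed,
      genome_size = profile$genome_size, span = total,
      scaffold_count = n,
      scaffolds = lapply(seq_len(n), function(i) {
        list(id = ids[i], length = len[i], gc_count = gc_count[i],
             at_count = at_count[i], n_count = n_count[i])
      }))

    fasta <- NULL
    if (!is.null(dir)) {
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      seqs <- vapply(seq_len(n), function(i) {
        intToUtf8(codes[(starts[i] + 1):ends[i]])
      }, "")
      dss <- Biostrings::DNAStringSet(seqs)
      names(dss) <- ids
      fasta <- file.path(dir, paste0(profile$name, ".fa"))
      Biostrings::writeXStringSet(dss, fasta, width = 80)
      yaml::write_yaml(truth, paste0(fasta, ".truth.yaml"), precision = 15)
    }
    list(records = records, truth = truth, profile = profile, fasta = fasta)
  })
}

#' Generate a BUSCO full table in a chosen version dialect
#'
#' Marker counts are derived exactly from the requested fractions
#' (rounded to whole markers), so [summarize_busco()] on the parsed table
#' reproduces the fractions to within `1/markers`. Duplicated markers
#' emit two rows. The v4 dialect uses the 7-column table; v5 and v6 use
#' the 10-column table; all carry a `# BUSCO version is:` and lineage
#' header. The same seed yields the same gene multiset in every dialect.
#'
#' @param markers Total marker count.
#' @param complete_fraction,duplicated_fraction,fragmented_fraction
#'   Requested proportions; complete includes duplicated, and
#'   `complete + fragmented <= 1`.
#' @param scaffold_ids Scaffold identifiers hits are placed on.
#' @param version BUSCO dialect: 4, 5, or 6.
#' @param lineage Lineage name; defaults to an odb10 name for v4/v5 and
#'   odb12 for v6.
#' @param seed RNG seed.
#' @param path Optional output TSV path.
#' @return List with `genes`, `lineage`, `lines`, and `path`.
#' @export
generate_busco_table <- function(markers, complete_fraction,
                                 duplicated_fraction = 0,
                                 fragmented_fraction = 0,
                                 scaffold_ids, version = 5,
                                 lineage = NULL, seed = 1, path = NULL) {
  stopifnot(markers >= 1, length(scaffold_ids) >= 1)
  if (any(c(complete_fraction, duplicated_fraction,
            fragmented_fraction) < 0) ||
      any(c(complete_fraction, duplicated_fraction,
            fragmented_fraction) > 1)) {
    stop("fractions must be in [0, 1]")
  }
  if (duplicated_fraction > complete_fraction) {
    stop("inconsistent fractions: duplicated exceeds complete")
  }
  if (complete_fraction + fragmented_fraction > 1 + 1e-9) {
    stop("inconsistent fractions: complete + fragmented exceed 1")
  }
  if (!version %in% c(4, 5, 6)) stop("version must be 4, 5, or 6")
  n_complete <- round(complete_fraction * markers)
  n_dup <- round(duplicated_fraction * markers)
  n_frag <- round(fragmented_fraction * markers)
  if (n_dup > n_complete || n_complete + n_frag > markers) {
    stop("inconsistent fractions after rounding to whole markers")
  }
  n_single <- n_complete - n_dup
  n_miss <- markers - n_complete - n_frag
  if (is.null(lineage)) {
    lineage <- if (version == 6) "eukaryota_odb12" else "eukaryota_odb10"
  }

  with_seed(seed, {
    ids <- sprintf("%dat2759", 10000 + seq_len(markers))
    status <- rep(c("Complete", "Duplicated", "Fragmented", "Missing"),
                  c(n_single, n_dup, n_frag, n_miss))
    # one row per hit: duplicated markers contribute two rows
    row_id <- c(ids[status == "Complete"],
                rep(ids[status == "Duplicated"], each = 2),
                ids[status == "Fragmented"],
                ids[status == "Missing"])
    row_status <- c(rep("Complete", n_single),
                    rep("Duplicated", 2 * n_dup),
                    rep("Fragmented", n_frag),
                    rep("Missing", n_miss))
    n_hits <- n_single + 2 * n_dup + n_frag
    row_scaffold <- c(sample(scaffold_ids, n_hits, replace = TRUE),
                      rep(NA_character_, n_miss))
    gene_start <- floor(stats::runif(n_hits) * 1e6) + 1
    gene_end <- gene_start + floor(stats::runif(n_hits) * 5e3) + 100
    score <- round(stats::runif(n_hits) * 1000, 1)
    glen <- gene_end - gene_start

    version_line <- sprintf("# BUSCO version is: %s",
                            c(`4` = "4.1.4", `5` = "5.4.7",
                              `6` = "6.0.0")[as.character(version)])
    lineage_line <- sprintf(
      "# The lineage dataset is: %s (Creation date: 2024-01-08, number of BUSCOs: %d)",
      lineage, markers)
    if (version == 4) {
      header <- "# Busco id\tStatus\tSequence\tGene Start\tGene End\tScore\tLength"
      mk_row <- function(i) {
        if (row_status[i] == "Missing") {
          paste(row_id[i], "Missing", sep = "\t")
        } else {
          paste(row_id[i], row_status[i], row_scaffold[i], gene_start[i],
                gene_end[i], score[i], glen[i], sep = "\t")
        }
      }
    } else {
      header <- paste("# Busco id\tStatus\tSequence\tGene Start\tGene End",
                      "Strand\tScore\tLength\tOrthoDB url\tDescription",
                      sep = "\t")
      mk_row <- function(i) {
        if (row_status[i] == "Missing") {
          paste(row_id[i], "Missing", sep = "\t")
        } else {
          paste(row_id[i], row_status[i], row_scaffold[i], gene_start[i],
                gene_end[i], "+", score[i], glen[i],
                paste0("https://www.orthodb.org/v10?query=", row_id[i]),
                "synthetic marker", sep = "\t")
        }
      }
    }
    lines <- c(version_line, lineage_line, header,
               vapply(seq_along(row_id), mk_row, ""))
    if (!is.null(path)) writeLines(lines, path)
    list(
      genes = data.frame(busco_id = row_id, status = row_status,
                         scaffold_id = row_scaffold,
                         stringsAsFactors = FALSE),
      lineage = lineage, lines = lines, path = path)
  })
}

#' Canonical contiguity profile family
#'
#' Five profiles at a shared genome size spanning scaffold N50 targets of
#' 10^3 to 10^7 bases: three fragmented profiles with heavy-tailed length
#' distributions and decreasing N-run rates (80, 50, 30 N per kb — the
#' scaffolded-assembly range), then two chromosomal profiles (around
#' 1.25 Mb chromosomes, then a single chromosome) with few or no Ns.
#' Snail scores are expected to increase along the family.
#'
#' @param genome_size Shared genome size in bases.
#' @param seed Base seed; each profile derives its own offset seed.
#' @return Named list of five [assembly_profile()]s in increasing
#'   contiguity rank order.
#' @export
contiguity_profiles <- function(genome_size = 1e7, seed = 101) {
  list(
    frag_n50_1e3 = assembly_profile("fragmented", genome_size,
                                    scaffold_n50 = 1e3, n_run_rate = 80,
                                    seed = seed + 1, name = "frag_n50_1e3"),
    frag_n50_1e4 = assembly_profile("fragmented", genome_size,
                                    scaffold_n50 = 1e4, n_run_rate = 50,
                                    seed = seed + 2, name = "frag_n50_1e4"),
    frag_n50_1e5 = assembly_profile("fragmented", genome_size,
                                    scaffold_n50 = 1e5, n_run_rate = 30,
                                    seed = seed + 3, name = "frag_n50_1e5"),
    chrom_n50_1e6 = assembly_profile(
      "chromosomal", genome_size,
      chromosome_count = max(2L, as.integer(round(genome_size / 1.25e6))),
      n_run_rate = 2, seed = seed + 4, name = "chrom_n50_1e6"),
    chrom_n50_1e7 = assembly_profile("chromosomal", genome_size,
                                     chromosome_count = 1, n_run_rate = 0,
                                     seed = seed + 5, name = "chrom_n50_1e7")
  )
}
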