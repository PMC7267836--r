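# Run configuration: defaults, file parsing, validation.

config_spec <- function() {
  # field, file key, type, default, check
  tibble::tribble(
    ~field, ~key, ~type, ~default,
    "sampling_num",                "SAMPLING_NUM",                "count",    1e5,
    "max_iterations",              "MAX_ITERATIONS",              "count",    11,
    "novel_fraction_threshold",    "NOVEL_FRACTION_THRESHOLD",    "rate",     0.01,
    "derep_min_identity",          "DEREP_MIN_IDENTITY",          "fraction", 0.99,
    "derep_max_edits",             "DEREP_MAX_EDITS",             "count0",   5,
    "map_minid",                   "MAP_MINID",                   "fraction", 0.96,
    "map_idfilter",                "MAP_IDFILTER",                "fraction", 0.98,
    "map_minhits",                 "MAP_MINHITS",                 "count",    2,
    "map_maxindel",                "MAP_MAXINDEL",                "count0",   1,
    "filter_min_coverage",         "FILTER_MIN_COVERAGE",         "nonneg",   2.0,
    "filter_min_covered_fraction", "FILTER_MIN_COVERED_FRACTION", "fraction", 0.80,
    "base_seed",                   "BASE_SEED",                   "int",      1,
    "em_max_iterations",           "EM_MAX_ITERATIONS",           "count",    15,
    "em_epsilon",                  "EM_EPSILON",                  "epsilon",  0.005,
    "em_merge_identity",           "EM_MERGE_IDENTITY",           "fraction", 0.97,
    "em_tol",                      "EM_TOL",                      "pos",      1e-3,
    "em_prune_prior",              "EM_PRUNE_PRIOR",              "pos",      1e-4,
    "em_report_prior",             "EM_REPORT_PRIOR",             "pos",      1e-3,
    "em_min_identity",             "EM_MIN_IDENTITY",             "fraction", 0.90,
    "merge_min_overlap",           "MERGE_MIN_OVERLAP",           "count",    20,
    "merge_max_mismatch_rate",     "MERGE_MAX_MISMATCH_RATE",     "rate",     0.05,
    "seed_k",                      "SEED_K",                      "kmer",     13,
    "simulate_indels",             "SIMULATE_INDELS",             "flag",     0
  )
}

#' Default run configuration
#'
#' Builds the configuration object driving the whole pipeline. Defaults are
#' the tool's documented operating point: subsample size n = 100000, at most
#' 11 iterations plus one final 2n iteration triggered when an iteration
#' contributes fewer novel contigs than 1% of the contig set; dereplication
#' at >= 99% identity with <= 5 indel columns; mapping with search identity
#' 0.96, mapped/unmapped decision at 0.98, seed prefilter of 2 shared
#' 13-mers, at most 1 indel; contig filters of mean coverage 2 and covered
#' fraction 80%.
#'
#' @param ... Named overrides for any configuration field (e.g.
#'   `sampling_num = 10000`).
#' @return A `riboloop_config` object (named list).
#' @export
#' @examples
#' cfg <- default_config(sampling_num = 1000, base_seed = 7)
#' cfg$sampling_num
default_config <- function(...) {
  spec <- config_spec()
  cfg <- as.list(spec$default)
  names(cfg) <- spec$field
  cfg$align_match <- 1
  cfg$align_mismatch <- -1
  cfg$align_gap <- -2
  cfg$samples <- list()        # label -> c(fq1, fq2)
  cfg$reference_fasta <- NA_character_
  cfg$output_dir <- NA_character_
  overrides <- list(...)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(cfg))
    if (length(bad)) stop("unknown configuration field(s): ",
                          paste(bad, collapse = ", "))
    cfg <- modifyList(cfg, overrides)
  }
  class(cfg) <- "riboloop_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  spec <- config_spec()
  for (i in seq_len(nrow(spec))) {
    f <- spec$field[i]; v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v))
      stop("invalid value for ", f, ": must be a single number")
    ok <- switch(spec$type[i],
      fraction = v > 0 && v <= 1,
      rate     = v >= 0 && v < 1,
      epsilon  = v > 0 && v < 0.75,
      count    = v >= 1 && v == floor(v),
      count0   = v >= 0 && v == floor(v),
      nonneg   = v >= 0,
      pos      = v > 0,
      int      = v == floor(v),
      kmer     = v >= 8 && v <= 31 && v == floor(v),
      flag     = v %in% c(0, 1),
      TRUE)
    if (!ok) stop("invalid value for ", f, " (", spec$key[i], "): ", v)
  }
  invisible(cfg)
}

#' Load a run configuration from a key=value file
#'
#' Parses a flat `KEY=value` text file (`#` starts a comment). Unspecified
#' keys take the defaults of [default_config()]; unknown keys produce a
#' warning; invalid values produce an error naming the key. Sample inputs
#' are given as repeated `SAMPLE=label:reads_1.fastq:reads_2.fastq` lines;
#' `REFERENCE_FASTA` and `OUTPUT_DIR` are paths.
#'
#' @param path Path to the configuration file.
#' @return A `riboloop_config` object.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  cfg <- default_config()
  spec <- config_spec()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE)) {
      warning("ignoring malformed configuration line: ", ln)
      next
    }
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    if (key == "SAMPLE") {
      parts <- strsplit(val, ":", fixed = TRUE)[[1]]
      if (length(parts) != 3)
        stop("invalid SAMPLE entry (want label:fq1:fq2): ", val)
      cfg$samples[[parts[1]]] <- parts[2:3]
    } else if (key == "REFERENCE_FASTA") {
      cfg$reference_fasta <- val
    } else if (key == "OUTPUT_DIR") {
      cfg$output_dir <- val
    } else if (key %in% spec$key) {
      f <- spec$field[match(key, spec$key)]
      num <- suppressWarnings(as.numeric(val))
      if (is.na(num)) stop("invalid value for ", key, ": ", val)
      cfg[[f]] <- num
    } else {
      warning("unknown configuration key: ", key)
    }
  }
  validate_config(cfg)
  cfg
}

#' @export
print.riboloop_config <- function(x, ...) {
  cat("<riboloop_config>\n")
  spec <- config_spec()
  for (f in spec$field)
    cat(sprintf("  %-28s %s\n", f, format(x[[f]])))
  if (length(x$samples))
    cat("  samples:", paste(names(x$samples), collapse = ", "), "\n")
  if (!is.na(x$reference_fasta))
    cat("  reference_fasta:", x$reference_fasta, "\n")
  invisible(x)
}
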