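# Readers, writers and the pipeline entry point.
# TSV (tab-separated, header, UTF-8, LF) is the primary tabular dialect;
# CSV is accepted on input for the registry table.

#' Packaged yearly DM2 testing registry (2007--2020)
#'
#' The yearly registry of DM2 genetic-test requests: cohort size, sex
#' split and confirmed positives per year, 2007--2020 (570 requests, 187
#' positives in total).
#'
#' @return Data frame with columns `year`, `cohort`, `males`, `females`,
#'   `positives`.
#' @export
#' @examples
#' registry_totals(dm2_registry())
dm2_registry <- function() {
  read_registry(system.file("extdata", "dm2_registry_2007_2020.csv",
                            package = "cnbprepeat", mustWork = TRUE))
}

#' Read a testing registry table
#'
#' @param path CSV or TSV file with columns `year`, `cohort`, `males`,
#'   `females`, `positives` (delimiter inferred from the extension;
#'   comma by default).
#' @return Validated data frame (see [registry_totals()] for the row
#'   consistency rules, enforced here too).
#' @export
read_registry <- function(path) {
  if (!file.exists(path)) stop(sprintf("registry file not found: %s", path), call. = FALSE)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  r <- read.csv(path, sep = sep, stringsAsFactors = FALSE)
  need <- c("year", "cohort", "males", "females", "positives")
  missing_cols <- setdiff(need, names(r))
  if (length(missing_cols)) {
    stop(sprintf("registry is missing column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  registry_totals(r)  # validates; result discarded
  r
}

#' Write decompositions as FASTA
#'
#' Renders each decomposition with [render_tract()] and writes a
#' multi-record FASTA via Biostrings.
#'
#' @param decompositions Named list of [motif_decomposition()] objects
#'   (names become record ids; unnamed lists get `allele1`, `allele2`, ...).
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_tract_fasta <- function(decompositions, path) {
  if (!length(decompositions)) stop("nothing to write", call. = FALSE)
  seqs <- vapply(decompositions, render_tract, "")
  ids <- names(decompositions)
  if (is.null(ids) || any(!nzchar(ids))) ids <- sprintf("allele%d", seq_along(seqs))
  set <- Biostrings::DNAStringSet(seqs)
  names(set) <- ids
  Biostrings::writeXStringSet(set, filepath = path)
  invisible(path)
}

#' Decompose every record of a FASTA file
#'
#' Runs [decompose_tract()] on each record and returns one row per
#' record. By default any unparseable record aborts with its error;
#' with `skip_bad = TRUE` such records are kept in the output flagged
#' `parsed = FALSE` (decomposition columns `NA`).
#'
#' @param path FASTA file (uncompressed or gzip, as Biostrings accepts).
#' @param skip_bad Keep unparseable records as flagged rows instead of
#'   erroring? Default `FALSE`.
#' @param full Passed to [decompose_tract()]; default `TRUE` (records are
#'   expected to be pure tracts).
#' @return Data frame with columns `id`, `parsed`, `strand`, `start`,
#'   `end`, `v`, `w`, `x`, `y`, `z`, `block`, `tract_bp`, `notation`.
#'   Empty FASTA yields an empty data frame with a warning.
#' @export
decompose_fasta <- function(path, skip_bad = FALSE, full = TRUE) {
  if (!file.exists(path)) stop(sprintf("FASTA file not found: %s", path), call. = FALSE)
  set <- tryCatch(Biostrings::readDNAStringSet(path),
                  error = function(e) stop(sprintf("malformed FASTA '%s': %s",
                                                   path, conditionMessage(e)),
                                           call. = FALSE))
  empty <- data.frame(id = character(), parsed = logical(), strand = character(),
                      start = integer(), end = integer(), v = integer(),
                      w = integer(), x = integer(), y = integer(), z = integer(),
                      block = character(), tract_bp = integer(),
                      notation = character(), stringsAsFactors = FALSE)
  if (!length(set)) {
    warning(sprintf("empty FASTA: %s", path), call. = FALSE)
    return(empty)
  }
  rows <- lapply(seq_along(set), function(i) {
    id <- names(set)[i] %||% sprintf("record%d", i)
    res <- tryCatch(decompose_tract(as.character(set[[i]]), full = full),
                    error = function(e) e)
    if (inherits(res, "error")) {
      if (!skip_bad) {
        stop(sprintf("record '%s': %s", id, conditionMessage(res)), call. = FALSE)
      }
      return(data.frame(id = id, parsed = FALSE, strand = NA_character_,
                        start = NA_integer_, end = NA_integer_, v = NA_integer_,
                        w = NA_integer_, x = NA_integer_, y = NA_integer_,
                        z = NA_integer_, block = NA_character_,
                        tract_bp = NA_integer_, notation = "unparsed",
                        stringsAsFactors = FALSE))
    }
    d <- res$decomposition
    data.frame(id = id, parsed = TRUE, strand = res$strand,
               start = res$start, end = res$end, v = d$v, w = d$w, x = d$x,
               y = length(d$block), z = d$z,
               block = paste(d$block, collapse = "-"),
               tract_bp = tract_length(d), notation = repeat_notation(d),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write / read an allele length spectrum as TSV
#'
#' Two-column TSV (`length_bp`, `count`); write then read round-trips to
#' an identical [frequency_spectrum()].
#'
#' @param s A [frequency_spectrum()].
#' @param path File path.
#' @return `write_spectrum`: invisibly `path`; `read_spectrum`: a
#'   [frequency_spectrum()].
#' @export
write_spectrum <- function(s, path) {
  if (!inherits(s, "frequency_spectrum")) stop("expected a 'frequency_spectrum'", call. = FALSE)
  write.table(as.data.frame(s), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path) {
  if (!file.exists(path)) stop(sprintf("spectrum file not found: %s", path), call. = FALSE)
  df <- read.csv(path, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("length_bp", "count") %in% names(df))) {
    stop("spectrum TSV needs columns length_bp, count", call. = FALSE)
  }
  frequency_spectrum(df$length_bp, df$count)
}

#' Flatten genotypes to a data frame
#'
#' One row per individual with allele summaries (notation or count range,
#' tract bp, diagnostic category), registry metadata and true status.
#'
#' @param genotypes List of [genotype_record()] objects.
#' @return Data frame.
#' @export
genotypes_to_table <- function(genotypes) {
  allele_str <- function(a) {
    if (!is.null(a$decomposition)) repeat_notation(a$decomposition)
    else sprintf("(CCTG)%d-%d", a$count_range[1], a$count_range[2])
  }
  rows <- lapply(genotypes, function(g) {
    data.frame(id = g$id, sex = g$sex, year = g$year,
               allele1 = allele_str(g$allele1),
               allele1_bp = allele_length_bp(g$allele1),
               allele1_category = g$allele1$diagnostic_category,
               allele2 = allele_str(g$allele2),
               allele2_bp = allele_length_bp(g$allele2),
               allele2_category = g$allele2$diagnostic_category,
               indications = paste(g$indications, collapse = ","),
               onset_age = g$onset_age,
               true_status = g$true_status, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Build and validate a pipeline run configuration
#'
#' @param n Cohort size.
#' @param positivity,premutation_rate,mosaic_width,indication_rates,expansion_range
#'   Passed to [simulate_cohort()].
#' @param detection_rate Passed to [run_assay()].
#' @param thresholds A [class_thresholds()].
#' @param seed Integer seed for the whole run.
#' @param out_dir Optional output directory for report files.
#' @return A validated list of class `run_config`. Missing or invalid
#'   fields raise an error naming the field.
#' @export
run_config <- function(n = 570L, positivity = 0.328,
                       premutation_rate = 5 / 570,
                       expansion_range = c(75L, 11000L),
                       mosaic_width = 0.05,
                       indication_rates = default_indication_rates(),
                       detection_rate = 0.99,
                       thresholds = class_thresholds(),
                       seed = 1L, out_dir = NULL) {
  cfg <- list(n = as_count(n, "n", 1),
              positivity = as_prob(positivity, "positivity"),
              premutation_rate = as_prob(premutation_rate, "premutation_rate"),
              expansion_range = expansion_range,
              mosaic_width = as_prob(mosaic_width, "mosaic_width"),
              indication_rates = indication_rates,
              detection_rate = as_prob(detection_rate, "detection_rate"),
              thresholds = thresholds,
              seed = as_count(seed, "seed", 0),
              out_dir = out_dir)
  if (!inherits(thresholds, "class_thresholds")) {
    stop("'thresholds' must be a class_thresholds object", call. = FALSE)
  }
  structure(cfg, class = "run_config")
}

#' Run the full simulate -> assay -> classify -> stats pipeline
#'
#' Simulates a cohort from the configuration, runs the diagnostic
#' workflow on every genotype, classifies all alleles and computes the
#' cohort summaries. When `out_dir` is set, writes `genotypes.tsv`,
#' `assay.tsv`, `stats.json` and a human-readable `summary.txt` echoing
#' the headline metrics (positivity, heterozygosity, spectrum mode);
#' outputs are byte-identical across runs with the same configuration
#' (the seed and thresholds are recorded in the JSON report).
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `genotypes`, `assay`, `classes`,
#'   `stats` (positivity observed/true, heterozygosity, spectrum stats,
#'   indication profile) and `config`.
#' @export
run_pipeline <- function(config = run_config()) {
  if (!inherits(config, "run_config")) stop("expected a 'run_config'", call. = FALSE)
  sim <- simulate_cohort(config$n, config$positivity, config$premutation_rate,
                         config$expansion_range, config$mosaic_width,
                         config$indication_rates, seed = config$seed)
  genotypes <- sim$genotypes
  assay <- run_assay(genotypes, config$detection_rate,
                     seed = config$seed + 1L, thresholds = config$thresholds)
  alleles <- unlist(lapply(genotypes, function(g) list(g$allele1, g$allele2)),
                    recursive = FALSE)
  classes <- classify_cohort(alleles)
  spectrum <- build_length_spectrum()
  sstats <- spectrum_stats(spectrum)
  stats <- list(
    n = config$n,
    positivity_called = round_half_up(
      100 * mean(assay$interpreted_call == "positive"), 1),
    positivity_true = round_half_up(
      100 * mean(assay$true_status == "DM2_positive"), 1),
    observed_heterozygosity = observed_heterozygosity(genotypes),
    expected_heterozygosity = expected_heterozygosity(spectrum),
    spectrum_mode_bp = sstats$mode_bp,
    spectrum_mode_pct = sstats$mode_pct,
    indications = indication_profile(genotypes),
    seed = config$seed,
    thresholds = unclass(config$thresholds)
  )
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    wtsv <- function(df, f) write.table(df, file.path(config$out_dir, f),
                                        sep = "\t", quote = FALSE, row.names = FALSE)
    wtsv(genotypes_to_table(genotypes), "genotypes.tsv")
    wtsv(assay, "assay.tsv")
    js <- stats
    js$indications <- as.list(stats$indications)
    jsonlite::write_json(js, file.path(config$out_dir, "stats.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    summary_lines <- c(
      sprintf("cohort n = %d (seed %d)", config$n, config$seed),
      sprintf("positivity: %.1f%% called / %.1f%% true",
              stats$positivity_called, stats$positivity_true),
      sprintf("observed heterozygosity: %.3f (expected from spectrum: %.3f)",
              stats$observed_heterozygosity, stats$expected_heterozygosity),
      sprintf("spectrum mode: %d bp (%.1f%%)",
              stats$spectrum_mode_bp, stats$spectrum_mode_pct))
    writeLines(summary_lines, file.path(config$out_dir, "summary.txt"))
  }
  invisible(list(genotypes = genotypes, assay = assay, classes = classes,
                 stats = stats, config = config))
}
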