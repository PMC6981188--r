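# Readers and writers for the plain-text formats the pipeline exchanges.
# Internal coordinates are 0-based half-open; conversion to/from 1-based
# (VCF-style) coordinates happens only here.

#' Read a FASTA file into a tibble
#'
#' @param path File path.
#' @return A tibble with columns `name`, `seq`.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  tibble::tibble(name = names(ss), seq = unname(as.character(ss)))
}

#' Write sequences to FASTA
#'
#' @param x Data frame with columns `name` (or `clone_id`) and `seq`.
#' @param path Output path.
#' @export
write_fasta <- function(x, path) {
  x <- tibble::as_tibble(x)
  if (!"name" %in% names(x) && "clone_id" %in% names(x)) {
    x <- dplyr::rename(x, name = "clone_id")
  }
  ss <- Biostrings::DNAStringSet(stats::setNames(x$seq, x$name))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read a BED file (0-based half-open intervals)
#'
#' @param path File path.
#' @return A tibble `chrom`, `start`, `end` and, when present, `name`.
#' @export
read_bed <- function(path) {
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  raw <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                         progress = FALSE, comment = "#")
  if (ncol(raw) < 3) abort(sprintf("%s: BED needs at least 3 columns", path))
  names(raw) <- cols[seq_len(min(ncol(raw), length(cols)))]
  raw$start <- as.integer(raw$start)
  raw$end <- as.integer(raw$end)
  if (any(raw$end <= raw$start)) abort(sprintf("%s: empty BED interval", path))
  raw
}

#' Write a BED file
#'
#' @param x Data frame with `chrom`, `start`, `end` (+ optional `name`).
#' @param path Output path.
#' @export
write_bed <- function(x, path) {
  cols <- intersect(c("chrom", "start", "end", "name"), names(x))
  readr::write_tsv(tibble::as_tibble(x)[cols], path, col_names = FALSE)
  invisible(path)
}

#' Convert a BED interval to 1-based closed coordinates
#'
#' BED `[10, 20)` covers 1-based positions 11..20.
#'
#' @param start,end 0-based half-open interval.
#' @return A list with `first` and `last` 1-based positions.
#' @export
bed_to_1based <- function(start, end) {
  list(first = start + 1L, last = end)
}

#' Read variant records from a minimal VCF or the TSV dialect
#'
#' A minimal VCF needs the fixed columns `#CHROM POS ID REF ALT`; `##`
#' meta lines are skipped and `INFO`/`FORMAT` columns ignored. The TSV
#' dialect has a header `chrom pos ref alt [vaf] [sample]`. The format is
#' sniffed from the first non-empty line. Mixed line endings are
#' tolerated; malformed lines are reported with their line number.
#'
#' @param path File path.
#' @param sample Sample label to attach when the file has none.
#' @return A tibble `chrom`, `pos` (1-based), `ref`, `alt`, `vaf`,
#'   `sample`.
#' @export
read_variants <- function(path, sample = NULL) {
  lines <- readr::read_lines(path)
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble::tibble(chrom = character(), pos = integer(),
                          ref = character(), alt = character(),
                          vaf = numeric(), sample = character()))
  }
  if (startsWith(lines[1], "##") || startsWith(lines[1], "#CHROM")) {
    parse_vcf_min(lines, path, sample %||% "sample1")
  } else {
    parse_variant_tsv(lines, path, sample)
  }
}

parse_vcf_min <- function(lines, path, sample) {
  body_idx <- which(!startsWith(lines, "#"))
  hdr_idx <- which(startsWith(lines, "#CHROM"))
  if (length(hdr_idx) != 1) abort(sprintf("%s: missing #CHROM header line", path))
  rows <- purrr::map(body_idx, function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 5) abort(sprintf("%s:%d: fewer than 5 VCF columns", path, i))
    pos <- suppressWarnings(as.integer(f[2]))
    if (is.na(pos) || pos < 1) abort(sprintf("%s:%d: bad POS '%s'", path, i, f[2]))
    assert_dna(f[4], sprintf("%s:%d REF", path, i))
    assert_dna(f[5], sprintf("%s:%d ALT", path, i))
    tibble::tibble(chrom = f[1], pos = pos, ref = f[4], alt = f[5])
  })
  out <- dplyr::bind_rows(rows)
  out$vaf <- NA_real_
  out$sample <- sample
  out
}

parse_variant_tsv <- function(lines, path, sample) {
  out <- readr::read_tsv(I(paste(lines, collapse = "\n")),
                         show_col_types = FALSE, progress = FALSE)
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% names(out))) {
    abort(sprintf("%s: TSV needs columns %s", path, paste(need, collapse = ", ")))
  }
  out$pos <- as.integer(out$pos)
  if (!"vaf" %in% names(out)) out$vaf <- NA_real_
  if (!"sample" %in% names(out)) out$sample <- sample %||% "sample1"
  bad <- which(is.na(out$pos) | out$pos < 1 | out$ref == out$alt)
  if (length(bad) > 0) {
    abort(sprintf("%s:%d: malformed variant record", path, bad[1] + 1L))
  }
  tibble::as_tibble(out)[c("chrom", "pos", "ref", "alt", "vaf", "sample")]
}

#' Write variant records as minimal VCF
#'
#' @param x Tibble with `chrom`, `pos`, `ref`, `alt`.
#' @param path Output path.
#' @export
write_vcf_min <- function(x, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t.", x$chrom, x$pos, x$ref, x$alt)
  readr::write_lines(c(hdr, body), path)
  invisible(path)
}

# ---- pipeline configuration -------------------------------------------------

config_defaults <- function() {
  list(
    locus = list(mutation_len = 59L, intercut_mutant = 87L,
                 amplicon_len = 670L, mha_len = 20L),
    tolerances = list(max_sub_frac = 0.01, cut_window = 10L,
                      min_aav_match = 20L, min_clone_len = 100L),
    bias = list(form = "exponential", strength = -log(0.60) * 100 / 59,
                reference_length = 611L),
    detection = list(slope = NULL, intercept = NULL),
    rod_fraction = 0.75,
    seed = 1L,
    inputs = list(clones_fasta = NULL, fixture = NULL, error_rate = 0),
    sample = "sample1"
  )
}

#' Read and validate a pipeline configuration file
#'
#' YAML with the sections `locus`, `tolerances`, `bias`, `detection`,
#' `inputs` plus scalars `rod_fraction`, `seed`, `sample`; unknown keys are
#' rejected. Values omitted from the file take the package defaults.
#'
#' @param path YAML file path.
#' @return A validated config list.
#' @export
read_pipeline_config <- function(path) {
  validate_config(yaml::read_yaml(path))
}

validate_config <- function(cfg) {
  defaults <- config_defaults()
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown) > 0) {
    abort(sprintf("unknown config keys: %s", paste(unknown, collapse = ", ")))
  }
  for (sect in c("locus", "tolerances", "bias", "detection", "inputs")) {
    if (!is.null(cfg[[sect]])) {
      unknown <- setdiff(names(cfg[[sect]]), names(defaults[[sect]]))
      if (length(unknown) > 0) {
        abort(sprintf("unknown config keys in %s: %s", sect,
                      paste(unknown, collapse = ", ")))
      }
      defaults[[sect]][names(cfg[[sect]])] <- cfg[[sect]]
    }
  }
  for (k in c("rod_fraction", "seed", "sample")) {
    if (!is.null(cfg[[k]])) defaults[[k]] <- cfg[[k]]
  }
  if (defaults$rod_fraction <= 0 || defaults$rod_fraction > 1) {
    abort("rod_fraction must be in (0, 1]")
  }
  defaults
}

#' Run the classification-to-efficiency pipeline
#'
#' Orchestrates the full chain: build the locus and allele models, obtain
#' clones (from a FASTA file or a named simulation fixture), classify them,
#' and assemble the efficiency report, applying the detection-bias
#' correction when the config supplies a fitted slope/intercept. When
#' `output_dir` is given, the count table, per-clone classifications,
#' report (JSON), resolved config (YAML) and a log with input checksums
#' are written there.
#'
#' @param config A config list (see [read_pipeline_config()]) or a YAML
#'   path.
#' @param output_dir Optional output directory.
#' @return A list with `report` ([efficiency_report()]), `counts`
#'   (`clone_count_table`), `locus` and `config` (resolved), invisibly.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  cfg <- if (is.character(config)) read_pipeline_config(config)
         else validate_config(config)
  locus <- default_locus(mutation_len = cfg$locus$mutation_len,
                         intercut_mutant = cfg$locus$intercut_mutant,
                         amplicon_len = cfg$locus$amplicon_len,
                         mha_len = cfg$locus$mha_len)
  aset <- build_allele_set(locus)
  clones <- if (!is.null(cfg$inputs$clones_fasta)) {
    if (!file.exists(cfg$inputs$clones_fasta)) {
      abort(sprintf("clone FASTA not found: %s", cfg$inputs$clones_fasta))
    }
    read_fasta(cfg$inputs$clones_fasta)
  } else if (!is.null(cfg$inputs$fixture)) {
    spec <- fixture_clone_spec(cfg$inputs$fixture,
                               error_rate = cfg$inputs$error_rate,
                               seed = cfg$seed)
    simulate_clone_set(locus, spec, aset)
  } else {
    abort("config must provide inputs$clones_fasta or inputs$fixture")
  }
  if (nrow(clones) == 0) abort("no clones to classify")
  tol <- do.call(clone_tolerances, cfg$tolerances)
  counts <- classify_set(clones, aset, tol, sample = cfg$sample)
  model <- if (!is.null(cfg$detection$slope)) {
    detection_model(cfg$detection$slope, cfg$detection$intercept %||% 0)
  }
  report <- efficiency_report(counts, model, rod_fraction = cfg$rod_fraction)

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(tibble::as_tibble(counts),
                     file.path(output_dir, "clone_counts.tsv"))
    readr::write_tsv(clone_details(counts),
                     file.path(output_dir, "clone_classifications.tsv"))
    write_efficiency_report(report, file.path(output_dir, "report.json"))
    yaml::write_yaml(cfg, file.path(output_dir, "config_resolved.yaml"))
    log_lines <- c(
      sprintf("mmejquant %s", as.character(utils::packageVersion("mmejquant"))),
      sprintf("config_hash: %s",
              rlang::hash(cfg)),
      sprintf("n_clones: %d", nrow(clones)),
      sprintf("clones_checksum: %s", rlang::hash(clones$seq)))
    readr::write_lines(log_lines, file.path(output_dir, "run.log"))
  }
  invisible(list(report = report, counts = counts, locus = locus, config = cfg))
}

#' Write an efficiency report as JSON
#'
#' @param report An [efficiency_report()].
#' @param path Output path.
#' @export
write_efficiency_report <- function(report, path) {
  x <- report[c("observed_success_fraction", "corrected_success_fraction",
                "absolute_rod_rate_uncorrected", "absolute_rod_rate_corrected",
                "relative_success_among_edited", "rod_fraction",
                "total_clones")]
  x$shares <- report$shares |>
    dplyr::mutate(category = as.character(.data$category))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
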