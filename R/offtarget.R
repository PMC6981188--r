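#' Select candidate off-target sites shared across post-treatment samples
#'
#' Unbiased candidate filter over somatic variant tables: a variant (keyed
#' by `chrom`, `pos`, `ref`, `alt`) is *selected* when present in every
#' post-treatment sample and absent from every pre-treatment sample;
#' intersection variants also found pre-treatment are returned as
#' *excluded*. The canonical design uses 3 post samples and 1 pre sample.
#'
#' @param variants Long variant table: columns `chrom`, `pos` (1-based),
#'   `ref`, `alt`, `sample`, optionally `vaf`.
#' @param post_samples Character vector of post-treatment sample labels.
#' @param pre_samples Character vector of pre-treatment sample labels.
#' @param min_vaf Optional minimum variant allele frequency for a record to
#'   count as present (default 0, any record).
#' @return A tibble `chrom`, `pos`, `ref`, `alt`, `status`
#'   (`"selected"` or `"excluded_in_pre"`), sorted by `(chrom, pos)`.
#' @export
select_candidate_sites <- function(variants, post_samples, pre_samples,
                                   min_vaf = 0) {
  variants <- tibble::as_tibble(variants)
  need <- c("chrom", "pos", "ref", "alt", "sample")
  if (!all(need %in% names(variants))) {
    abort(sprintf("variant table needs columns %s", paste(need, collapse = ", ")))
  }
  if (length(post_samples) < 1) abort("at least one post-treatment sample required")
  if (length(pre_samples) < 1) abort("at least one pre-treatment sample required")
  # a sample with zero variant rows is legitimate: it simply contributes an
  # empty set to the intersection
  if (min_vaf > 0 && "vaf" %in% names(variants)) {
    variants <- dplyr::filter(variants, .data$vaf >= min_vaf)
  }
  key_cols <- c("chrom", "pos", "ref", "alt")
  per_sample <- function(sm) {
    dplyr::distinct(variants[variants$sample == sm, key_cols])
  }
  shared <- Reduce(function(a, b) dplyr::inner_join(a, b, by = key_cols),
                   lapply(post_samples, per_sample))
  pre <- dplyr::distinct(
    variants[variants$sample %in% pre_samples, key_cols])
  selected <- dplyr::anti_join(shared, pre, by = key_cols)
  excluded <- dplyr::semi_join(shared, pre, by = key_cols)
  out <- dplyr::bind_rows(
    dplyr::mutate(selected, status = "selected"),
    dplyr::mutate(excluded, status = "excluded_in_pre"))
  dplyr::arrange(out, .data$chrom, .data$pos, .data$ref, .data$alt)
}

#' Screen candidate off-target sites for overlapping variant events
#'
#' Counts variant records overlapping each site interval; a site with zero
#' overlapping records is "clean".
#'
#' @param variants Variant table (`chrom`, `pos` 1-based, `ref`, `alt`,
#'   ...).
#' @param sites Site table in BED convention: `chrom`, `start`, `end`
#'   (0-based half-open), optionally `name`.
#' @return The `sites` tibble with `n_events` and `clean` columns appended,
#'   in the input site order.
#' @export
screen_sites <- function(variants, sites) {
  variants <- tibble::as_tibble(variants)
  sites <- tibble::as_tibble(sites)
  if (any(sites$end <= sites$start)) abort("site intervals must be non-empty")
  n_events <- purrr::map_int(seq_len(nrow(sites)), function(i) {
    # BED [start, end) vs 1-based variant pos: overlap iff pos-1 in [start, end)
    sum(variants$chrom == sites$chrom[i] &
        variants$pos - 1L >= sites$start[i] &
        variants$pos - 1L < sites$end[i])
  })
  dplyr::mutate(sites, n_events = n_events, clean = n_events == 0L)
}

#' Detect vector integration junctions from split-read alignment segments
#'
#' Groups reads carrying at least one host-genome segment and at least one
#' vector (`"AAV"`) segment — the tabular form of dual soft-clipped
#' mappings — infers each read's host/vector breakpoint from the adjacent
#' boundary between its host and vector read intervals, clusters junctions
#' within `cluster_window` bp on the same chromosome and orientation, and
#' reports clusters with at least `min_support` supporting reads.
#'
#' @param segments Alignment-segment table as from
#'   [simulate_integration_reads()]: `read_id`, `ref`, `ref_start`,
#'   `ref_end`, `read_start`, `read_end`, `strand`.
#' @param min_support Minimum supporting reads per junction (default 1).
#' @param cluster_window Clustering window in bp (default 10).
#' @param aav_name Reference name of the vector genome (default `"AAV"`).
#' @return A tibble `host_chrom`, `host_pos`, `aav_pos`, `orientation`,
#'   `n_reads`, `read_ids` (list column), sorted by support (descending)
#'   then coordinate.
#' @export
detect_integrations <- function(segments, min_support = 1L,
                                cluster_window = 10L, aav_name = "AAV") {
  segments <- tibble::as_tibble(segments)
  if (cluster_window < 0) abort("cluster_window must be >= 0")
  empty <- tibble::tibble(host_chrom = character(), host_pos = numeric(),
                          aav_pos = numeric(), orientation = character(),
                          n_reads = integer(), read_ids = list())
  if (nrow(segments) == 0) return(empty)

  per_read <- split(segments, segments$read_id)
  junc <- purrr::map(per_read, function(sg) {
    refs <- unique(sg$ref)
    if (!aav_name %in% refs || length(setdiff(refs, aav_name)) == 0) return(NULL)
    sg <- dplyr::arrange(sg, .data$read_start)
    if (nrow(sg) > 1 &&
        any(sg$read_start[-1] < sg$read_end[-nrow(sg)])) {
      warn(sprintf("read %s has overlapping read intervals; skipped",
                   sg$read_id[1]))
      return(NULL)
    }
    out <- list()
    for (i in seq_len(nrow(sg) - 1L)) {
      a <- sg[i, ]; b <- sg[i + 1L, ]
      if ((a$ref == aav_name) == (b$ref == aav_name)) next
      if (a$ref != aav_name) {          # host then vector in the read
        out[[length(out) + 1L]] <- tibble::tibble(
          host_chrom = a$ref, host_pos = a$ref_end, aav_pos = b$ref_start,
          orientation = "host_left", read_id = a$read_id)
      } else {                          # vector then host
        out[[length(out) + 1L]] <- tibble::tibble(
          host_chrom = b$ref, host_pos = b$ref_start, aav_pos = a$ref_end,
          orientation = "host_right", read_id = a$read_id)
      }
    }
    dplyr::bind_rows(out)
  })
  junc <- dplyr::bind_rows(junc)
  if (nrow(junc) == 0) return(empty)

  clusters <- junc |>
    dplyr::group_by(.data$host_chrom, .data$orientation) |>
    dplyr::arrange(.data$host_pos, .by_group = TRUE) |>
    dplyr::mutate(cluster = cumsum(c(1, diff(.data$host_pos) > cluster_window))) |>
    dplyr::group_by(.data$host_chrom, .data$orientation, .data$cluster) |>
    dplyr::summarise(
      host_pos = stats::median(.data$host_pos),
      aav_pos = stats::median(.data$aav_pos),
      n_reads = dplyr::n_distinct(.data$read_id),
      read_ids = list(sort(unique(.data$read_id))),
      .groups = "drop") |>
    dplyr::filter(.data$n_reads >= min_support) |>
    dplyr::arrange(dplyr::desc(.data$n_reads), .data$host_chrom,
                   .data$host_pos) |>
    dplyr::select("host_chrom", "host_pos", "aav_pos", "orientation",
                  "n_reads", "read_ids")
  clusters
}
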