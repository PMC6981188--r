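#' Editing-outcome categories
#'
#' The six mutually exclusive outcome categories a clone amplicon can be
#' assigned to, in classification precedence order: `Success` (mutation
#' replaced as planned, recut-proof edits included), `Deletion` (simple
#' excision of the mutation between the two cuts, blunt re-join),
#' `AAVIntegration` (unplanned insertion of vector genome sequence),
#' `CleavageSiteIndel` (indel at either cut site without replacement of the
#' mutation), `OtherIndel` (any other above-tolerance variant), and
#' `Unedited` (mutant allele as it was).
#'
#' @export
OUTCOME_LEVELS <- c("Success", "Deletion", "CleavageSiteIndel",
                    "AAVIntegration", "OtherIndel", "Unedited")

#' Classifier tolerances
#'
#' @param max_sub_frac Maximum substitution fraction (relative to the
#'   matched amplicon length) attributed to sequencing error (default 0.01).
#' @param cut_window Half-width in bp of the window around each cut site
#'   within which an indel counts as a cleavage-site indel (default 10).
#' @param min_aav_match Minimum length in bp of an inserted segment that
#'   must match the vector fragment to call an AAV integration (default 20).
#' @param min_clone_len Clones shorter than this are flagged
#'   `Unclassifiable` and excluded from counts (default 100).
#' @return A named list of tolerances.
#' @export
clone_tolerances <- function(max_sub_frac = 0.01, cut_window = 10L,
                             min_aav_match = 20L, min_clone_len = 100L) {
  stopifnot(max_sub_frac >= 0, cut_window >= 0, min_aav_match >= 1,
            min_clone_len >= 1)
  list(max_sub_frac = max_sub_frac, cut_window = as.integer(cut_window),
       min_aav_match = as.integer(min_aav_match),
       min_clone_len = as.integer(min_clone_len))
}

align_submat <- function() {
  Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                           baseOnly = TRUE)
}

# global affine-gap alignment of clone vs allele; returns score plus event
# lists in 0-based subject (allele) coordinates
align_events <- function(clone, allele) {
  aln <- Biostrings::pairwiseAlignment(
    clone, allele, type = "global",
    substitutionMatrix = align_submat(),
    gapOpening = 10, gapExtension = 0.5)
  # for a global alignment, pattern()/subject() are the full gapped strings
  p <- strsplit(as.character(Biostrings::pattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::subject(aln)), "")[[1]]
  pgap <- p == "-"
  sgap <- s == "-"
  # 0-based subject coordinate of each alignment column (for a column that
  # consumes a subject base: its coordinate; for an insertion column: the
  # coordinate of the next subject base)
  scoord <- cumsum(!sgap)
  subs <- scoord[!pgap & !sgap & p != s] - 1L

  ins <- list()
  if (any(sgap)) {
    r <- rle(sgap)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      i0 <- starts[k]; i1 <- ends[k]
      ins[[length(ins) + 1L]] <- list(
        pos = if (i0 == 1L) 0L else scoord[i0 - 1L],
        seq = paste(p[i0:i1], collapse = ""))
    }
  }
  del <- list()
  if (any(pgap)) {
    r <- rle(pgap)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      st <- scoord[starts[k]] - 1L
      del[[length(del) + 1L]] <- list(start = st, end = st + r$lengths[k])
    }
  }
  list(score = Biostrings::score(aln), subs = subs, ins = ins, del = del)
}

# does any indel touch the window [cut - w, cut + w]?
indel_near <- function(events, cut, w) {
  any(vapply(events$ins, function(e) e$pos >= cut - w && e$pos <= cut + w,
             logical(1))) ||
  any(vapply(events$del, function(e) e$start <= cut + w && e$end >= cut - w,
             logical(1)))
}

#' Classify one clone amplicon sequence
#'
#' Assigns a clone to exactly one editing-outcome category by a fixed,
#' deterministic decision procedure: (1) the clone is compared (global
#' alignment, affine gaps; a fast Hamming path when lengths match) to each
#' model amplicon; (2) an indel-free match to the success amplicon within
#' the substitution tolerance is `Success`; (3) likewise for the deletion
#' amplicon, `Deletion`; (4) otherwise, an inserted segment of at least
#' `min_aav_match` bp matching the vector fragment is `AAVIntegration`;
#' (5) otherwise, if the mutation region is still absent (mutant-like) and
#' an indel lies within `cut_window` of either cut site, `CleavageSiteIndel`;
#' (6) any other above-tolerance variant is `OtherIndel`; (7) else
#' `Unedited`. A clone combining replacement with junction indels therefore
#' falls into `OtherIndel` — such co-existing outcomes are not given a
#' category of their own.
#'
#' @param clone_seq Clone amplicon sequence (character).
#' @param allele_set [build_allele_set()] result for the locus.
#' @param tolerances [clone_tolerances()].
#' @return A one-row tibble: `category`, `evidence`, `mismatch_count`,
#'   `unclassifiable`. Clones shorter than `min_clone_len` are flagged
#'   unclassifiable with `category = NA`.
#' @export
classify_clone <- function(clone_seq, allele_set,
                           tolerances = clone_tolerances()) {
  if (!is.character(clone_seq) || length(clone_seq) != 1L ||
      is.na(clone_seq) || nchar(clone_seq) == 0L) {
    abort("clone_seq must be a non-empty DNA string")
  }
  tol <- tolerances
  if (nchar(clone_seq) < tol$min_clone_len) {
    return(tibble::tibble(category = NA_character_,
                          evidence = "short sequence",
                          mismatch_count = NA_integer_,
                          unclassifiable = TRUE))
  }
  amps <- allele_set$amplicons
  result <- function(category, evidence, mism) {
    tibble::tibble(category = category, evidence = evidence,
                   mismatch_count = as.integer(mism), unclassifiable = FALSE)
  }
  # fast path: substitution-only matches preserve length
  for (nm in c("success", "deletion", "mutant", "wildtype")) {
    a <- amps[[nm]]
    if (nchar(clone_seq) == nchar(a)) {
      h <- hamming_distance(clone_seq, a)
      if (h <= tol$max_sub_frac * nchar(a)) {
        cat_nm <- switch(nm, success = "Success", deletion = "Deletion",
                         mutant = "Unedited",
                         # replacement without the planned recut edits
                         wildtype = "OtherIndel")
        return(result(cat_nm, paste0("matches ", nm, " amplicon"), h))
      }
    }
  }
  # alignment path. An indel-free within-tolerance match to the success or
  # deletion amplicon implies equal length, so the fast path above has
  # already decided those categories; here the clone is analysed against
  # the mutant amplicon, relative to which the remaining categories are
  # defined.
  me <- align_events(clone_seq, amps$mutant)
  n_indel <- length(me$ins) + length(me$del)
  # unplanned vector integration: inserted segment matching the AAV
  # fragment. Local alignment (not exact substring search) because the
  # global aligner may shift the insert boundaries by a few bases into
  # matching flank sequence.
  for (insertion in me$ins) {
    if (nchar(insertion$seq) >= tol$min_aav_match) {
      laln <- Biostrings::pairwiseAlignment(
        insertion$seq, allele_set$aav_fragment, type = "local",
        substitutionMatrix = align_submat(),
        gapOpening = 10, gapExtension = 0.5)
      # 2-base slack: sequencing errors or residual boundary ambiguity can
      # shave a couple of matched bases off a genuine vector insert
      if (Biostrings::nmatch(laln) >= tol$min_aav_match - 2L) {
        return(result("AAVIntegration",
                      sprintf("%d-bp insert at mutant pos %d maps to AAV fragment",
                              nchar(insertion$seq), insertion$pos),
                      length(me$subs)))
      }
    }
  }
  # mutation still absent (mutant-like) with an indel at a cut site
  mseq <- allele_set$mutation_seq
  mutation_present <- nchar(mseq) > 0 &&
    Biostrings::vcountPattern(mseq, Biostrings::DNAStringSet(clone_seq),
                              max.mismatch = max(1L, floor(tol$max_sub_frac * nchar(mseq))))[1] > 0
  if (!mutation_present &&
      (indel_near(me, allele_set$cut5_mut, tol$cut_window) ||
       indel_near(me, allele_set$cut3_mut, tol$cut_window))) {
    return(result("CleavageSiteIndel",
                  "indel within cut-site window, mutation not replaced",
                  length(me$subs)))
  }
  if (n_indel > 0 || length(me$subs) > tol$max_sub_frac * nchar(amps$mutant)) {
    return(result("OtherIndel",
                  sprintf("variant relative to mutant amplicon (%d indel(s), %d substitution(s))",
                          n_indel, length(me$subs)),
                  length(me$subs)))
  }
  result("Unedited", "matches mutant amplicon", length(me$subs))
}

#' Classify a set of clones and tabulate outcome counts
#'
#' Classifies every clone independently (so the result is invariant to
#' input order) and returns a per-category count table. Per-clone failures
#' (e.g. empty sequences) never abort the batch: such clones are flagged
#' unclassifiable, reported alongside, and excluded from the counts.
#'
#' @param clones A data frame with columns `clone_id` and `seq` (as returned
#'   by [simulate_clone_set()] or [read_fasta()], whose `name` column is
#'   accepted as `clone_id`), or a bare character vector of sequences.
#' @param allele_set [build_allele_set()] result.
#' @param tolerances [clone_tolerances()].
#' @param sample Optional sample label attached to the table.
#' @return A tibble of class `clone_count_table` with columns `sample`,
#'   `category`, `n` (all six categories always present), and attributes
#'   `total_clones`, `n_unclassifiable`, and `details` (the per-clone
#'   classification tibble).
#' @export
classify_set <- function(clones, allele_set, tolerances = clone_tolerances(),
                         sample = "sample1") {
  clones <- normalize_clones(clones)
  if (nrow(clones) == 0) {
    out <- tibble::tibble(sample = sample,
                          category = factor(OUTCOME_LEVELS,
                                            levels = OUTCOME_LEVELS),
                          n = 0L)
    return(structure(out, class = c("clone_count_table", class(out)),
                     total_clones = 0L, n_unclassifiable = 0L,
                     details = tibble::tibble(clone_id = character(),
                                              category = character(),
                                              evidence = character(),
                                              mismatch_count = integer(),
                                              unclassifiable = logical())))
  }
  details <- purrr::map(clones$seq, function(s) {
    tryCatch(classify_clone(s, allele_set, tolerances),
             error = function(e) tibble::tibble(
               category = NA_character_, evidence = conditionMessage(e),
               mismatch_count = NA_integer_, unclassifiable = TRUE))
  })
  details <- dplyr::bind_cols(clones["clone_id"], dplyr::bind_rows(details))
  counted <- details |>
    dplyr::filter(!.data$unclassifiable) |>
    dplyr::count(category = factor(.data$category, levels = OUTCOME_LEVELS),
                 .drop = FALSE)
  out <- tibble::tibble(sample = sample, category = counted$category,
                        n = counted$n)
  structure(out,
            class = c("clone_count_table", class(out)),
            total_clones = sum(counted$n),
            n_unclassifiable = sum(details$unclassifiable),
            details = details)
}

normalize_clones <- function(clones) {
  if (is.character(clones)) {
    return(tibble::tibble(clone_id = paste0("clone", seq_along(clones)),
                          seq = clones))
  }
  clones <- tibble::as_tibble(clones)
  if (!"clone_id" %in% names(clones) && "name" %in% names(clones)) {
    clones <- dplyr::rename(clones, clone_id = "name")
  }
  if (!all(c("clone_id", "seq") %in% names(clones))) {
    abort("clones needs columns clone_id (or name) and seq")
  }
  clones
}

#' Per-clone classification details
#'
#' @param x A `clone_count_table`.
#' @return The per-clone tibble (`clone_id`, `category`, `evidence`,
#'   `mismatch_count`, `unclassifiable`).
#' @export
clone_details <- function(x) attr(x, "details")

#' @export
print.clone_count_table <- function(x, ...) {
  NextMethod()
  cat(sprintf("# total clones: %d; unclassifiable: %d\n",
              attr(x, "total_clones"), attr(x, "n_unclassifiable")))
  invisible(x)
}

count_of <- function(table, category) {
  sum(table$n[table$category == category])
}

#' Total editing rate
#'
#' Fraction of classified clones showing any sign of genome editing,
#' i.e. `(total - Unedited) / total`.
#'
#' @param table A `clone_count_table` (or any tibble with `category`, `n`).
#' @return A fraction in `[0, 1]`.
#' @export
total_editing_rate <- function(table) {
  total <- sum(table$n)
  if (total == 0) abort("total_editing_rate undefined for zero clones")
  (total - count_of(table, "Unedited")) / total
}
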