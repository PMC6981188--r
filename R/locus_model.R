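#' Guide (gRNA) target site
#'
#' A light record describing one SaCas9 target site on the locus reference:
#' the protospacer, the PAM, the strand, and the blunt cut position. SaCas9
#' uses a 21-nt protospacer followed by an `NNGRRT` PAM and cuts bluntly
#' 3 bp 5' of the PAM; both the protospacer length and the cut offset are
#' configurable because neither is fixed by the assay itself.
#'
#' Coordinates are 0-based. `start` is the leftmost plus-strand position of
#' the full site (protospacer plus PAM); `cut_pos` is the splice index of the
#' blunt cut (the cut falls between reference positions `cut_pos - 1` and
#' `cut_pos`), which always lies inside the protospacer interval.
#'
#' @param protospacer Protospacer sequence, 5'->3' in guide orientation.
#' @param pam PAM sequence in guide orientation (e.g. `"TTGAGT"`).
#' @param strand `"+"` or `"-"`.
#' @param start 0-based plus-strand start of the protospacer+PAM interval.
#' @param cut_offset Cut distance in bp 5' of the PAM (default 3, blunt).
#' @return An object of class `guide_site`.
#' @export
guide_site <- function(protospacer, pam, strand = "+", start, cut_offset = 3L) {
  assert_dna(protospacer, "protospacer")
  assert_dna(pam, "pam")
  if (!strand %in% c("+", "-")) abort("strand must be '+' or '-'")
  p <- nchar(protospacer)
  k <- nchar(pam)
  cut_pos <- if (strand == "+") start + p - cut_offset else start + k + cut_offset
  site_width <- p + k
  # cut must fall inside the protospacer interval on the plus strand
  proto_iv <- if (strand == "+") c(start, start + p) else c(start + k, start + site_width)
  if (cut_pos <= proto_iv[1] || cut_pos >= proto_iv[2]) {
    abort("cut position falls outside the protospacer interval")
  }
  structure(
    list(protospacer = protospacer, pam = pam, strand = strand,
         start = start, cut_pos = cut_pos, cut_offset = cut_offset,
         width = site_width),
    class = "guide_site"
  )
}

#' @export
print.guide_site <- function(x, ...) {
  cat(sprintf("<guide_site> %s|%s (%s) site [%d,%d) cut %d\n",
              x$protospacer, x$pam, x$strand, x$start, x$start + x$width,
              x$cut_pos))
  invisible(x)
}

# plus-strand [start, end) of the full protospacer+PAM site
site_interval <- function(guide) c(guide$start, guide$start + guide$width)

# extract the protospacer+PAM sequence (guide orientation) of a guide site
# from any sequence in which the site keeps its reference coordinates,
# shifted by `offset` (e.g. -primer_fwd_pos for amplicon coordinates)
extract_site_seq <- function(seq, guide, offset = 0L) {
  iv <- site_interval(guide) + offset
  if (iv[1] < 0 || iv[2] > nchar(seq)) abort("guide site outside sequence bounds")
  s <- subseq0(seq, iv[1], iv[2])
  if (guide$strand == "-") revcomp(s) else s
}

#' Scan a sequence for PAM-adjacent guide sites
#'
#' Finds every position on both strands where the PAM pattern matches and a
#' full-length protospacer fits 5' of it, returning one row per candidate
#' guide site. Candidate enumeration of this kind is the first step of guide
#' selection; downstream activity scoring is out of scope.
#'
#' @param sequence Reference DNA string (plus strand).
#' @param pam_pattern IUPAC pattern for the PAM (default `"NNGRRT"`, SaCas9).
#' @param region Optional 0-based half-open `c(start, end)` restricting the
#'   full protospacer+PAM span; default is the whole sequence.
#' @param protospacer_len Protospacer length in nt (default 21, SaCas9).
#' @param cut_offset Blunt-cut distance 5' of the PAM in bp (default 3).
#' @return A tibble with columns `start` (plus-strand 0-based start of the
#'   protospacer+PAM span), `strand`, `protospacer`, `pam`, `cut_pos`,
#'   ordered by `(start, strand)`.
#' @export
scan_pams <- function(sequence, pam_pattern = "NNGRRT", region = NULL,
                      protospacer_len = 21L, cut_offset = 3L) {
  assert_dna(sequence, "sequence")
  assert_iupac(pam_pattern, "pam_pattern")
  n <- nchar(sequence)
  region <- region %||% c(0L, n)
  if (region[1] < 0 || region[2] > n || region[1] >= region[2]) {
    abort("region out of sequence bounds")
  }
  P <- as.integer(protospacer_len)
  K <- nchar(pam_pattern)
  subj <- Biostrings::DNAString(sequence)

  hits <- list()
  # plus strand: PAM matches directly; protospacer immediately 5'
  m <- Biostrings::matchPattern(pam_pattern, subj, fixed = "subject")
  for (s in BiocGenerics::start(m) - 1L) {
    site_start <- s - P
    if (site_start >= region[1] && s + K <= region[2]) {
      hits[[length(hits) + 1L]] <- tibble::tibble(
        start = site_start, strand = "+",
        protospacer = subseq0(sequence, site_start, s),
        pam = subseq0(sequence, s, s + K),
        cut_pos = s - cut_offset
      )
    }
  }
  # minus strand: the reverse-complement of the PAM matches the plus strand,
  # with the protospacer 3' of it in plus coordinates
  rc_pat <- revcomp_iupac(pam_pattern)
  m <- Biostrings::matchPattern(rc_pat, subj, fixed = "subject")
  for (s in BiocGenerics::start(m) - 1L) {
    if (s >= region[1] && s + K + P <= region[2]) {
      hits[[length(hits) + 1L]] <- tibble::tibble(
        start = s, strand = "-",
        protospacer = revcomp(subseq0(sequence, s + K, s + K + P)),
        pam = revcomp(subseq0(sequence, s, s + K)),
        cut_pos = s + K + cut_offset
      )
    }
  }
  out <- dplyr::bind_rows(hits)
  if (nrow(out) == 0) {
    return(tibble::tibble(start = integer(), strand = character(),
                          protospacer = character(), pam = character(),
                          cut_pos = integer()))
  }
  dplyr::arrange(out, .data$start, .data$strand)
}

# reverse-complement an IUPAC pattern (ambiguity-aware)
revcomp_iupac <- function(pattern) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", V = "B", D = "H", H = "D",
            N = "N")
  paste(rev(comp[strsplit(pattern, "")[[1]]]), collapse = "")
}

# turn one row of a scan_pams() tibble into a guide_site record
as_guide_site <- function(row, cut_offset = 3L) {
  if (row$strand == "+") {
    guide_site(row$protospacer, row$pam, "+", row$start, cut_offset)
  } else {
    guide_site(row$protospacer, row$pam, "-", row$start, cut_offset)
  }
}

#' Locus model for dual-cut mutation replacement
#'
#' Bundles the wildtype reference sequence, the pathogenic deletion interval,
#' the two flanking guide sites, the genotyping primer positions and
#' (optionally) the donor design. The mutant allele carries the deletion;
#' the two guides cut on either side of it so the mutant inter-cut segment
#' can be excised and replaced by the donor core.
#'
#' @param reference_seq Wildtype locus sequence, plus strand.
#' @param mutation_start,mutation_end 0-based half-open interval of the
#'   pathogenic deletion on `reference_seq`.
#' @param grna_5p,grna_3p [guide_site()] records; `grna_5p` must cut 5' of
#'   the mutation and `grna_3p` 3' of it.
#' @param primer_fwd_pos,primer_rev_pos 0-based positions delimiting the
#'   genotyping amplicon `[primer_fwd_pos, primer_rev_pos)`.
#' @param donor Optional [design_donor()] result; built on demand otherwise.
#' @return An object of class `locus_model`.
#' @export
locus_model <- function(reference_seq, mutation_start, mutation_end,
                        grna_5p, grna_3p, primer_fwd_pos, primer_rev_pos,
                        donor = NULL) {
  assert_dna(reference_seq, "reference_seq")
  n <- nchar(reference_seq)
  iv_ok <- function(a, b) a >= 0 && b <= n && a < b
  # an empty mutation interval (size-0 deletion) is allowed: the locus then
  # degenerates to wildtype == mutant, useful as an edge case
  if (!(mutation_start >= 0 && mutation_end <= n && mutation_start <= mutation_end)) {
    abort("mutation interval out of bounds")
  }
  if (!iv_ok(primer_fwd_pos, primer_rev_pos)) abort("primer interval out of bounds")
  if (!inherits(grna_5p, "guide_site") || !inherits(grna_3p, "guide_site")) {
    abort("grna_5p and grna_3p must be guide_site objects")
  }
  cut5 <- grna_5p$cut_pos
  cut3 <- grna_3p$cut_pos
  if (!(cut5 < mutation_start && mutation_end < cut3)) {
    abort("mutation interval must lie strictly between the two cut sites")
  }
  if (!(primer_fwd_pos < cut5 && cut3 < primer_rev_pos)) {
    abort("cut sites must lie strictly between the primer positions")
  }
  for (g in list(grna_5p, grna_3p)) {
    iv <- site_interval(g)
    if (iv[1] < 0 || iv[2] > n) abort("guide site out of sequence bounds")
    if (extract_site_seq(reference_seq, g) != paste0(g$protospacer, g$pam)) {
      abort("guide site sequence does not match the reference at its coordinates")
    }
  }
  structure(
    list(reference_seq = reference_seq,
         mutation_start = as.integer(mutation_start),
         mutation_end = as.integer(mutation_end),
         grna_5p = grna_5p, grna_3p = grna_3p,
         primer_fwd_pos = as.integer(primer_fwd_pos),
         primer_rev_pos = as.integer(primer_rev_pos),
         donor = donor),
    class = "locus_model"
  )
}

#' @export
print.locus_model <- function(x, ...) {
  cat(sprintf(paste0(
    "<locus_model> %d bp reference\n",
    "  mutation [%d,%d) (%d bp), cuts at %d / %d, amplicon [%d,%d) (%d bp)\n"),
    nchar(x$reference_seq), x$mutation_start, x$mutation_end,
    x$mutation_end - x$mutation_start, x$grna_5p$cut_pos, x$grna_3p$cut_pos,
    x$primer_fwd_pos, x$primer_rev_pos, x$primer_rev_pos - x$primer_fwd_pos))
  invisible(x)
}

mutation_len <- function(locus) locus$mutation_end - locus$mutation_start

#' Design a donor template with microhomology arms and recut-proof edits
#'
#' The donor core is the wildtype copy of the inter-cut region (so insertion
#' restores the deleted sequence) with recut-proofing substitutions applied
#' inside the guide target sites, so that the nuclease cannot cleave the
#' repaired allele again. Microhomology arms are exact copies of the genomic
#' flanks immediately outside the two cut positions.
#'
#' @param locus A [locus_model()].
#' @param mha_len Microhomology arm length in bp (default 20).
#' @param recut_edits Tibble/data frame with columns `pos` (0-based reference
#'   coordinate), `ref`, `alt` (single bases); every edit must fall inside
#'   one of the two guide target sites and inside the inter-cut region.
#'   `NULL` disables recut-proofing.
#' @return An object of class `donor_design` with fields `donor_core`,
#'   `mha_5p`, `mha_3p`, `recut_edits`, `target_site_5p`, `target_site_3p`.
#' @export
design_donor <- function(locus, mha_len = 20L, recut_edits = NULL) {
  if (mha_len < 1) abort("mha_len must be >= 1")
  ref <- locus$reference_seq
  cut5 <- locus$grna_5p$cut_pos
  cut3 <- locus$grna_3p$cut_pos
  if (cut5 - mha_len < 0 || cut3 + mha_len > nchar(ref)) {
    abort("microhomology arms extend beyond the reference")
  }
  edits <- normalize_edits(recut_edits)
  iv5 <- site_interval(locus$grna_5p)
  iv3 <- site_interval(locus$grna_3p)
  edited_ref <- ref
  if (nrow(edits) > 0) {
    for (i in seq_len(nrow(edits))) {
      p <- edits$pos[i]
      in5 <- p >= iv5[1] && p < iv5[2]
      in3 <- p >= iv3[1] && p < iv3[2]
      if (!in5 && !in3) abort(sprintf(
        "recut edit at %d falls outside both guide target sites", p))
      if (p >= locus$mutation_start && p < locus$mutation_end) abort(sprintf(
        "recut edit at %d falls inside the mutation interval", p))
      if (subseq0(ref, p, p + 1L) != edits$ref[i]) abort(sprintf(
        "recut edit at %d: reference base is %s, not %s",
        p, subseq0(ref, p, p + 1L), edits$ref[i]))
      edited_ref <- replace0(edited_ref, p, p + 1L, edits$alt[i])
    }
  }
  structure(
    list(donor_core = subseq0(edited_ref, cut5, cut3),
         mha_5p = subseq0(ref, cut5 - mha_len, cut5),
         mha_3p = subseq0(ref, cut3, cut3 + mha_len),
         mha_5p_len = as.integer(mha_len),
         mha_3p_len = as.integer(mha_len),
         recut_edits = edits,
         target_site_5p = extract_site_seq(edited_ref, locus$grna_5p),
         target_site_3p = extract_site_seq(edited_ref, locus$grna_3p)),
    class = "donor_design"
  )
}

normalize_edits <- function(recut_edits) {
  if (is.null(recut_edits)) {
    return(tibble::tibble(pos = integer(), ref = character(), alt = character()))
  }
  edits <- tibble::as_tibble(recut_edits)
  if (!all(c("pos", "ref", "alt") %in% names(edits))) {
    abort("recut_edits needs columns pos, ref, alt")
  }
  if (any(edits$ref == edits$alt)) abort("recut edit with ref == alt")
  dplyr::arrange(edits, .data$pos)
}

#' Score residual cleavability of an edited guide target site
#'
#' Compares an edited protospacer+PAM sequence against the original guide
#' site and returns a multiplicative mismatch score in `[0, 1]`: 1 for an
#' identical site, and the product of per-position mismatch penalties
#' otherwise. The shipped default penalty table is conservative all-or-none
#' (any protospacer or PAM mismatch abolishes cleavage, score 0); a full
#' per-position weight table in the CFD style can be supplied instead via
#' [read_penalty_table()] or as a data frame with columns
#' `position` (1-based along protospacer+PAM), `ref_base`, `alt_base`,
#' `weight`. A mismatch absent from a user table scores 0.
#'
#' @param guide A [guide_site()].
#' @param edited_site_seq Protospacer+PAM sequence of the edited site, guide
#'   orientation, same length as the guide's own site.
#' @param penalty_table `NULL` (all-or-none default), a data frame, or a
#'   path to a penalty TSV.
#' @return A numeric score in `[0, 1]`.
#' @export
verify_recut_proof <- function(guide, edited_site_seq, penalty_table = NULL) {
  assert_dna(edited_site_seq, "edited_site_seq")
  ref_site <- paste0(guide$protospacer, guide$pam)
  if (nchar(edited_site_seq) != nchar(ref_site)) {
    abort("edited_site_seq length differs from protospacer+PAM length")
  }
  mism <- hamming_positions(ref_site, edited_site_seq)
  if (length(mism) == 0) return(1.0)
  if (is.null(penalty_table)) return(0.0)
  tab <- if (is.character(penalty_table)) read_penalty_table(penalty_table)
         else validate_penalty_table(penalty_table)
  score <- 1.0
  refc <- strsplit(ref_site, "")[[1]]
  altc <- strsplit(edited_site_seq, "")[[1]]
  for (p0 in mism) {
    w <- tab$weight[tab$position == p0 + 1L &
                    tab$ref_base == refc[p0 + 1L] &
                    tab$alt_base == altc[p0 + 1L]]
    score <- score * (if (length(w) == 1L) w else 0.0)
  }
  score
}

validate_penalty_table <- function(tab) {
  tab <- tibble::as_tibble(tab)
  need <- c("position", "ref_base", "alt_base", "weight")
  if (!all(need %in% names(tab))) {
    abort("penalty table needs columns position, ref_base, alt_base, weight")
  }
  if (!is.numeric(tab$weight) || any(tab$weight < 0 | tab$weight > 1)) {
    abort("penalty weights must be numeric in [0, 1]")
  }
  if (anyDuplicated(tab[c("position", "ref_base", "alt_base")]) > 0) {
    abort("duplicate (position, ref_base, alt_base) rows in penalty table")
  }
  tab
}

#' Read a mismatch penalty table from TSV
#'
#' Format: tab-separated with header `position  ref_base  alt_base  weight`,
#' positions 1-based along the protospacer+PAM in guide orientation.
#'
#' @param path File path.
#' @return A validated tibble.
#' @export
read_penalty_table <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_penalty_table(tab)
}

#' Construct the default synthetic locus
#'
#' A deterministic synthetic locus whose geometry reproduces the genotyping
#' arithmetic of the modelled mutant line: a 59-bp pathogenic deletion whose
#' flanking cut sites sit 87 bp apart on the mutant allele, giving amplicons
#' of 670, 611 and 524 bp for the repaired (Success), mutant and simple
#' deletion alleles. The base composition outside the constrained elements
#' is pseudorandom but fixed, so repeated calls are byte-identical. The
#' donor carries the default recut-proofing scheme: 4 substitutions in the
#' 5' guide target site and 1 in the 3' site.
#'
#' @param mutation_len Pathogenic deletion length in bp (default 59).
#' @param intercut_mutant Distance between the two cuts on the mutant allele
#'   in bp (default 87).
#' @param amplicon_len Wildtype amplicon length in bp (default 670).
#' @param mha_len Microhomology arm length for the donor (default 20).
#' @return A `locus_model` with its `donor` field populated.
#' @export
default_locus <- function(mutation_len = 59L, intercut_mutant = 87L,
                          amplicon_len = 670L, mha_len = 20L) {
  synth_locus(seed = 20260925L, mutation_len = mutation_len,
              intercut_mutant = intercut_mutant, amplicon_len = amplicon_len,
              mha_len = mha_len, grna_3p_strand = "+")
}

#' Generate a random locus with valid geometry
#'
#' Draws a locus with randomized flank composition and (optionally)
#' randomized geometry, for property-style checks of the splicing
#' identities. All randomness flows from `seed`.
#'
#' @param seed Integer seed.
#' @param mutation_len,intercut_mutant,amplicon_len,mha_len Geometry knobs,
#'   as in [default_locus()].
#' @param grna_3p_strand Strand of the 3' guide (`"+"`, `"-"`, or
#'   `"random"`).
#' @return A `locus_model`.
#' @export
random_locus <- function(seed, mutation_len = NULL, intercut_mutant = NULL,
                         amplicon_len = NULL, mha_len = 20L,
                         grna_3p_strand = "random") {
  with_seed_if(seed, {
    mutation_len <- mutation_len %||% sample(20:120, 1)
    intercut_mutant <- intercut_mutant %||% sample(60:140, 1)
    amplicon_len <- amplicon_len %||%
      (mutation_len + intercut_mutant + 60L + sample(300:500, 1))
    if (grna_3p_strand == "random") {
      grna_3p_strand <- sample(c("+", "-"), 1)
    }
    synth_locus(seed = NULL, mutation_len = mutation_len,
                intercut_mutant = intercut_mutant, amplicon_len = amplicon_len,
                mha_len = mha_len, grna_3p_strand = grna_3p_strand)
  })
}

# shared locus builder; seed = NULL draws from the current RNG stream
synth_locus <- function(seed, mutation_len, intercut_mutant, amplicon_len,
                        mha_len, grna_3p_strand) {
  with_seed_if(seed, {
    P <- 21L; K <- 6L
    intercut_wt <- mutation_len + intercut_mutant
    flank <- 100L
    # place the 5' cut so the two amplicon halves are roughly balanced
    left <- max(P + 5L, (amplicon_len - intercut_wt) %/% 2L)
    right <- amplicon_len - intercut_wt - left
    if (right < P + K + 5L) abort("amplicon too short for the requested geometry")
    pf <- flank
    cut5 <- pf + left
    cut3 <- cut5 + intercut_wt
    pr <- pf + amplicon_len
    total <- pr + flank
    ref <- random_dna(total)

    # stamp a plus-strand SaCas9 site cutting at cut5:
    # protospacer [cut5-18, cut5+3), PAM [cut5+3, cut5+9)
    ref <- stamp_pam_plus(ref, cut5 + 3L)
    in_core_5p_end <- cut5 + 9L  # rightmost in-core base of the 5' site

    if (grna_3p_strand == "+") {
      # protospacer [cut3-18, cut3+3), PAM [cut3+3, cut3+9)
      ref <- stamp_pam_plus(ref, cut3 + 3L)
      site3_core_start <- cut3 - 18L
    } else {
      # minus-strand site: PAM plus-interval [cut3-9, cut3-3),
      # protospacer plus-interval [cut3-3, cut3+18)
      ref <- stamp_pam_minus(ref, cut3 - 9L)
      site3_core_start <- cut3 - 9L
    }

    # mutation interval strictly between the cuts, clear of both sites
    lo <- in_core_5p_end + 1L
    hi <- site3_core_start - 1L
    if (hi - lo < mutation_len) abort("inter-cut region too short for the mutation")
    mstart <- lo + sample.int(hi - lo - mutation_len + 1L, 1) - 1L
    mend <- mstart + mutation_len

    g5 <- guide_site(subseq0(ref, cut5 - 18L, cut5 + 3L),
                     subseq0(ref, cut5 + 3L, cut5 + 9L), "+", cut5 - 18L)
    g3 <- if (grna_3p_strand == "+") {
      guide_site(subseq0(ref, cut3 - 18L, cut3 + 3L),
                 subseq0(ref, cut3 + 3L, cut3 + 9L), "+", cut3 - 18L)
    } else {
      guide_site(revcomp(subseq0(ref, cut3 - 3L, cut3 + 18L)),
                 revcomp(subseq0(ref, cut3 - 9L, cut3 - 3L)), "-", cut3 - 9L)
    }
    locus <- locus_model(ref, mstart, mend, g5, g3, pf, pr)
    locus$donor <- design_donor(locus, mha_len = mha_len,
                                recut_edits = default_recut_edits(locus))
    locus
  })
}

# overwrite [pam_start, pam_start+6) with a concrete NNGRRT instance,
# keeping the two leading N bases as drawn
stamp_pam_plus <- function(ref, pam_start) {
  rr <- paste(sample(c("A", "G"), 2, replace = TRUE), collapse = "")
  replace0(ref, pam_start + 2L, pam_start + 6L, paste0("G", rr, "T"))
}

# minus-strand PAM at plus-interval [pam_start, pam_start+6):
# plus-strand sequence is revcomp(NNGRRT) = AYYCNN
stamp_pam_minus <- function(ref, pam_start) {
  yy <- paste(sample(c("C", "T"), 2, replace = TRUE), collapse = "")
  replace0(ref, pam_start, pam_start + 4L, paste0("A", yy, "C"))
}

# default recut-proofing: 4 substitutions in the in-core part of the 5'
# site (protospacer 3' end + PAM) and 1 in the in-core part of the 3' site
default_recut_edits <- function(locus) {
  ref <- locus$reference_seq
  cut5 <- locus$grna_5p$cut_pos
  cut3 <- locus$grna_3p$cut_pos
  iv5 <- site_interval(locus$grna_5p)
  iv3 <- site_interval(locus$grna_3p)
  core5 <- seq.int(max(iv5[1], cut5), min(iv5[2], cut3) - 1L)
  core3 <- seq.int(max(iv3[1], cut5), min(iv3[2], cut3) - 1L)
  pick <- function(pos, k) pos[seq(1L, length(pos), length.out = k)]
  transversion <- c(A = "C", C = "A", G = "T", T = "G")
  mk <- function(p) {
    r <- subseq0(ref, p, p + 1L)
    tibble::tibble(pos = p, ref = r, alt = unname(transversion[r]))
  }
  dplyr::bind_rows(
    purrr::map(pick(core5, 4L), mk),
    purrr::map(pick(core3, 1L), mk)
  )
}
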