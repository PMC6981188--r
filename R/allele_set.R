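#' Build the expected allele and amplicon sequences for a locus
#'
#' Constructs the four model alleles against which clone amplicons are
#' classified, together with their genotyping amplicons:
#'
#' * `wildtype` — the reference as given;
#' * `mutant` — reference with the pathogenic deletion spliced out;
#' * `success` — mutant with the inter-cut segment replaced by the donor
#'   core, i.e. the deletion restored and the recut-proof substitutions in
#'   place (equivalently, wildtype with the recut edits applied);
#' * `deletion` — mutant with the inter-cut segment excised and the two cut
#'   ends joined bluntly, the major unwanted editing outcome.
#'
#' With the default locus geometry the (success, mutant, deletion) amplicons
#' are 670, 611 and 524 bp: success exceeds mutant by the 59-bp mutation
#' size, and mutant exceeds deletion by the 87-bp inter-cut distance.
#'
#' @param locus A [locus_model()]; its `donor` field is used if present,
#'   otherwise a default donor is designed on the fly.
#' @param aav_fragment Optional DNA string used to model unplanned vector
#'   integrations; a fixed pseudorandom 1-kb fragment by default.
#' @return An object of class `allele_set`: named full-length sequences,
#'   named amplicon sequences, the AAV fragment, and cached geometry
#'   (cut positions in mutant-amplicon coordinates, the wildtype mutation
#'   sequence) used by the classifier.
#' @export
build_allele_set <- function(locus, aav_fragment = NULL) {
  ref <- locus$reference_seq
  pf <- locus$primer_fwd_pos
  pr <- locus$primer_rev_pos
  cut5 <- locus$grna_5p$cut_pos
  cut3 <- locus$grna_3p$cut_pos
  mstart <- locus$mutation_start
  mend <- locus$mutation_end
  donor <- locus$donor %||% design_donor(locus, recut_edits = default_recut_edits(locus))
  edits <- donor$recut_edits

  success_full <- ref
  if (nrow(edits) > 0) {
    for (i in seq_len(nrow(edits))) {
      success_full <- replace0(success_full, edits$pos[i], edits$pos[i] + 1L,
                               edits$alt[i])
    }
  }
  alleles <- list(
    wildtype = ref,
    mutant = splice0(ref, mstart, mend),
    success = success_full,
    deletion = splice0(ref, cut5, cut3)
  )
  amp_wt <- subseq0(ref, pf, pr)
  amplicons <- list(
    wildtype = amp_wt,
    mutant = splice0(amp_wt, mstart - pf, mend - pf),
    success = subseq0(success_full, pf, pr),
    deletion = splice0(amp_wt, cut5 - pf, cut3 - pf)
  )
  aav_fragment <- aav_fragment %||% withr::with_seed(58123L, random_dna(1000L))
  assert_dna(aav_fragment, "aav_fragment")

  mlen <- mend - mstart
  structure(
    list(alleles = alleles,
         amplicons = amplicons,
         aav_fragment = aav_fragment,
         # geometry in mutant-amplicon coordinates, used by the classifier
         cut5_mut = cut5 - pf,
         cut3_mut = cut3 - mlen - pf,
         mutation_pos_mut = mstart - pf,
         mutation_seq = subseq0(ref, mstart, mend),
         donor = donor),
    class = "allele_set"
  )
}

#' @export
print.allele_set <- function(x, ...) {
  cat("<allele_set>\n")
  print(allele_table(x))
  invisible(x)
}

#' Tabulate allele and amplicon lengths
#'
#' @param allele_set An [build_allele_set()] result.
#' @return A tibble with one row per model allele.
#' @export
allele_table <- function(allele_set) {
  nm <- names(allele_set$alleles)
  tibble::tibble(
    allele = nm,
    allele_length = vapply(allele_set$alleles[nm], nchar, integer(1)),
    amplicon_length = vapply(allele_set$amplicons[nm], nchar, integer(1))
  )
}
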