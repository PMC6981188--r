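test_that("scan_pams finds no site where the pattern cannot match", {
  expect_identical(nrow(scan_pams("AAAAAA", "NNGRRT")), 0L)
})

test_that("scan_pams recovers a single forced plus-strand site", {
  # flanks of pure T / pure C cannot match NNGRRT on either strand
  left <- strrep("T", 30)
  right <- strrep("C", 10)
  seq <- paste0(left, "TTGAGT", right)
  hits <- scan_pams(seq, "NNGRRT")
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$pam, "TTGAGT")
  expect_identical(hits$strand, "+")
  expect_identical(hits$start, 30L - 21L)
  expect_identical(hits$cut_pos, 30L - 3L)
})

test_that("scan_pams agrees with a brute-force both-strand scan", {
  for (s in 1:8) {
    seq <- withr::with_seed(s, paste(sample(c("A", "C", "G", "T"), 2000,
                                            replace = TRUE), collapse = ""))
    got <- as.data.frame(scan_pams(seq, "NNGRRT"))
    want <- oracle_scan(seq, "NNGRRT")
    expect_equal(got, want, ignore_attr = TRUE)
  }
})

test_that("scan_pams validates its inputs", {
  expect_error(scan_pams("ACGT", "NQX"), "IUPAC")
  expect_error(scan_pams("ACGTACGT", "NNGRRT", region = c(0, 99)), "bounds")
})

test_that("default locus produces the canonical amplicon lengths", {
  aset <- test_alleles()
  lens <- vapply(aset$amplicons, nchar, integer(1))
  expect_identical(unname(lens[c("success", "mutant", "deletion")]),
                   c(670L, 611L, 524L))
  expect_identical(lens[["success"]] - lens[["mutant"]], 59L)
  expect_identical(lens[["mutant"]] - lens[["deletion"]], 87L)
})

test_that("a size-0 mutation makes success and wildtype amplicons identical", {
  loc <- default_locus()
  loc$mutation_end <- loc$mutation_start
  loc$donor <- design_donor(loc, mha_len = 20, recut_edits = NULL)
  aset <- build_allele_set(loc)
  expect_identical(aset$amplicons$success, aset$amplicons$wildtype)
  expect_identical(aset$amplicons$mutant, aset$amplicons$wildtype)
})

test_that("splicing length identities hold on randomized locus geometry", {
  for (s in 1:20) {
    loc <- random_locus(s)
    aset <- build_allele_set(loc)
    mlen <- loc$mutation_end - loc$mutation_start
    intercut_mut <- loc$grna_3p$cut_pos - loc$grna_5p$cut_pos - mlen
    expect_identical(nchar(aset$amplicons$success) - nchar(aset$amplicons$mutant),
                     mlen)
    expect_identical(nchar(aset$amplicons$mutant) - nchar(aset$amplicons$deletion),
                     intercut_mut)
  }
})

test_that("build_allele_set is deterministic", {
  loc <- default_locus()
  a <- build_allele_set(loc)
  b <- build_allele_set(loc)
  expect_identical(a$alleles, b$alleles)
  expect_identical(a$amplicons, b$amplicons)
})

test_that("donor arms are exact copies of the genomic flanks", {
  loc <- test_locus()
  d <- design_donor(loc, mha_len = 20)
  ref <- loc$reference_seq
  cut5 <- loc$grna_5p$cut_pos
  cut3 <- loc$grna_3p$cut_pos
  expect_identical(nchar(d$mha_5p), 20L)
  expect_identical(d$mha_5p, substr(ref, cut5 - 19, cut5))
  expect_identical(d$mha_3p, substr(ref, cut3 + 1, cut3 + 20))
})

test_that("donor core restores the deleted sequence", {
  loc <- test_locus()
  d <- design_donor(loc, mha_len = 20, recut_edits = loc$donor$recut_edits)
  mut_seq <- substr(loc$reference_seq, loc$mutation_start + 1, loc$mutation_end)
  expect_true(grepl(mut_seq, d$donor_core, fixed = TRUE))
})

test_that("empty recut edits leave donor target sites genomic", {
  loc <- test_locus()
  d <- design_donor(loc, recut_edits = NULL)
  expect_identical(d$target_site_5p,
                   paste0(loc$grna_5p$protospacer, loc$grna_5p$pam))
  expect_identical(d$target_site_3p,
                   paste0(loc$grna_3p$protospacer, loc$grna_3p$pam))
})

test_that("edits outside the guide target sites are rejected", {
  loc <- test_locus()
  bad <- data.frame(pos = loc$mutation_start + 2,
                    ref = substr(loc$reference_seq, loc$mutation_start + 3,
                                 loc$mutation_start + 3),
                    alt = "A")
  if (bad$ref == "A") bad$alt <- "C"
  expect_error(design_donor(loc, recut_edits = bad), "outside")
})

test_that("the 4+1 recut-edit scheme abolishes both sites under the default table", {
  loc <- test_locus()
  aset <- test_alleles()
  edits <- loc$donor$recut_edits
  iv5 <- c(loc$grna_5p$start, loc$grna_5p$start + loc$grna_5p$width)
  n5 <- sum(edits$pos >= iv5[1] & edits$pos < iv5[2])
  expect_identical(n5, 4L)
  expect_identical(nrow(edits) - n5, 1L)
  expect_identical(
    verify_recut_proof(loc$grna_5p, loc$donor$target_site_5p), 0)
  expect_identical(
    verify_recut_proof(loc$grna_3p, loc$donor$target_site_3p), 0)
  # and the edited sites as they appear on the success allele
  s5 <- mmejquant:::extract_site_seq(aset$alleles$success, loc$grna_5p)
  expect_identical(verify_recut_proof(loc$grna_5p, s5), 0)
})

test_that("verify_recut_proof is 1 for an identical site, any site", {
  for (s in 1:10) {
    loc <- random_locus(s)
    for (g in list(loc$grna_5p, loc$grna_3p)) {
      expect_identical(
        verify_recut_proof(g, paste0(g$protospacer, g$pam)), 1)
    }
  }
})

test_that("a single mismatch scores 0 under the all-or-none default", {
  g <- test_locus()$grna_5p
  site <- paste0(g$protospacer, g$pam)
  mutated <- paste0("A", substr(site, 2, nchar(site)))
  if (substr(site, 1, 1) == "A") {
    mutated <- paste0("C", substr(site, 2, nchar(site)))
  }
  expect_identical(verify_recut_proof(g, mutated), 0)
})

test_that("user penalty tables multiply per-mismatch weights", {
  g <- test_locus()$grna_5p
  site <- paste0(g$protospacer, g$pam)
  chars <- strsplit(site, "")[[1]]
  flip <- c(A = "G", C = "T", G = "A", T = "C")
  # mismatches at positions 3 and 10
  chars2 <- chars
  chars2[3] <- flip[[chars[3]]]
  chars2[10] <- flip[[chars[10]]]
  tab <- data.frame(position = c(3L, 10L),
                    ref_base = chars[c(3, 10)],
                    alt_base = chars2[c(3, 10)],
                    weight = c(0.25, 0.5))
  got <- verify_recut_proof(g, paste(chars2, collapse = ""), tab)
  expect_equal(got, 0.25 * 0.5)
  # a mismatch missing from the table is conservative: weight 0
  chars2[12] <- flip[[chars[12]]]
  expect_identical(
    verify_recut_proof(g, paste(chars2, collapse = ""), tab), 0)
})

test_that("verify_recut_proof rejects length mismatches", {
  g <- test_locus()$grna_5p
  expect_error(verify_recut_proof(g, "ACGT"), "length")
})

test_that("locus invariants are enforced", {
  loc <- test_locus()
  expect_error(
    locus_model(loc$reference_seq, loc$grna_5p$cut_pos - 5,
                loc$mutation_end, loc$grna_5p, loc$grna_3p,
                loc$primer_fwd_pos, loc$primer_rev_pos),
    "strictly between")
  expect_error(
    locus_model(loc$reference_seq, loc$mutation_start, loc$mutation_end,
                loc$grna_5p, loc$grna_3p,
                loc$grna_5p$cut_pos + 1, loc$primer_rev_pos),
    "primer")
})

test_that("penalty tables read from TSV validate and apply", {
  path <- system.file("extdata", "penalty_table_synthetic.tsv",
                      package = "mmejquant")
  tab <- read_penalty_table(path)
  expect_true(all(c("position", "ref_base", "alt_base", "weight") %in%
                    names(tab)))
  expect_true(all(tab$weight >= 0 & tab$weight <= 1))
  bad <- tab
  bad$weight[1] <- 2
  expect_error(verify_recut_proof(test_locus()$grna_5p, "ACGT", bad))
})
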