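# Shared fixtures and independent oracles used across test files.

# default locus and allele set, built once per test run
test_locus <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- default_locus()
    cache
  }
})

test_alleles <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_allele_set(test_locus())
    cache
  }
})

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

# brute-force PAM scan oracle: per-position letter-set comparison on both
# strands, written independently of scan_pams()
oracle_scan <- function(sequence, pattern, protospacer_len = 21,
                        cut_offset = 3) {
  chars <- strsplit(sequence, "")[[1]]
  pat <- strsplit(pattern, "")[[1]]
  K <- length(pat)
  P <- protospacer_len
  n <- length(chars)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rc <- function(x) paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
  rows <- list()
  for (i in seq_len(n - K + 1)) {          # 1-based PAM start
    if (all(mapply(function(c, p) c %in% IUPAC_SETS[[p]],
                   chars[i:(i + K - 1)], pat))) {
      # plus strand: protospacer immediately 5'
      if (i - P >= 1) {
        rows[[length(rows) + 1]] <- data.frame(
          start = i - P - 1L, strand = "+",
          protospacer = substr(sequence, i - P, i - 1),
          pam = substr(sequence, i, i + K - 1),
          cut_pos = i - 1L - cut_offset)
      }
    }
    # minus strand: pattern matches revcomp of plus [i, i+K)
    if (all(mapply(function(c, p) comp[[c]] %in% IUPAC_SETS[[p]],
                   rev(chars[i:(i + K - 1)]), pat))) {
      if (i + K + P - 1 <= n) {
        rows[[length(rows) + 1]] <- data.frame(
          start = i - 1L, strand = "-",
          protospacer = rc(substr(sequence, i + K, i + K + P - 1)),
          pam = rc(substr(sequence, i, i + K - 1)),
          cut_pos = i - 1L + K + cut_offset)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(out)
  out <- out[order(out$start, out$strand), ]
  rownames(out) <- NULL
  out
}

# closed-form OLS via normal equations, independent of lm()
oracle_ols <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  ss_res <- sum((y - intercept - slope * x)^2)
  ss_tot <- sum((y - mean(y))^2)
  list(slope = slope, intercept = intercept, r2 = 1 - ss_res / ss_tot)
}

# brute-force set algebra for the off-target candidate filter
oracle_select <- function(variants, post, pre) {
  key <- function(d) unique(paste(d$chrom, d$pos, d$ref, d$alt, sep = ":"))
  keys_by_sample <- lapply(post, function(s) key(variants[variants$sample == s, ]))
  shared <- Reduce(intersect, keys_by_sample)
  pre_keys <- key(variants[variants$sample %in% pre, ])
  list(selected = sort(setdiff(shared, pre_keys)),
       excluded = sort(intersect(shared, pre_keys)))
}

variant_keys <- function(d) sort(paste(d$chrom, d$pos, d$ref, d$alt, sep = ":"))
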