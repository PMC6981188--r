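#' Specification for a simulated clone set
#'
#' @param proportions Named numeric vector or list mapping outcome
#'   categories (see [OUTCOME_LEVELS]) to fractions summing to 1. Omitted
#'   categories default to 0.
#' @param n_clones Number of clones to draw.
#' @param error_rate Per-base substitution (sequencing error) probability,
#'   in `[0, 0.05]`.
#' @param seed Integer seed; `NULL` draws from the caller's RNG stream.
#' @return A `clone_sim_spec` list.
#' @export
clone_sim_spec <- function(proportions, n_clones, error_rate = 0, seed = NULL) {
  props <- stats::setNames(rep(0, length(OUTCOME_LEVELS)), OUTCOME_LEVELS)
  proportions <- unlist(proportions)
  bad <- setdiff(names(proportions), OUTCOME_LEVELS)
  if (length(bad) > 0) {
    abort(sprintf("unknown outcome categories: %s", paste(bad, collapse = ", ")))
  }
  props[names(proportions)] <- proportions
  if (abs(sum(props) - 1) > 1e-9) abort("outcome proportions must sum to 1")
  if (n_clones <= 0) abort("n_clones must be positive")
  if (error_rate < 0 || error_rate > 0.05) abort("error_rate must be in [0, 0.05]")
  structure(list(proportions = props, n_clones = as.integer(n_clones),
                 error_rate = error_rate, seed = seed),
            class = "clone_sim_spec")
}

#' Canonical clone-set fixtures
#'
#' Per-category clone counts for the canonical study conditions. Only the
#' summary rates of each condition are published (success among edited,
#' absolute rod-level success, total edited); the per-category breakdowns
#' here were chosen once so that those rates are reproduced exactly:
#'
#' * `mmej_1m` — 57 clones: 2 Success, 9 Deletion, 2 CleavageSiteIndel,
#'   4 AAVIntegration, 1 OtherIndel, 39 Unedited (18 edited; 2/18 = 11.1%
#'   success among edited; 100*(2/57)/0.75 = 4.7% absolute in rods).
#' * `hiti_1m` — 86 clones: 1 Success, 12 Deletion, 3 CleavageSiteIndel,
#'   5 AAVIntegration, 1 OtherIndel, 64 Unedited (22 edited; 1/22 = 4.5%).
#' * `invitro_mmej` — 58 clones: 3 Success, 16 Deletion,
#'   3 CleavageSiteIndel, 5 AAVIntegration, 2 OtherIndel, 29 Unedited
#'   (29 edited; 3/29 = 10.3%).
#'
#' @param name Fixture name.
#' @param error_rate,seed Passed through to [clone_sim_spec()].
#' @return A `clone_sim_spec` whose proportions times `n_clones` are the
#'   integer counts above.
#' @export
fixture_clone_spec <- function(name = c("mmej_1m", "hiti_1m", "invitro_mmej"),
                               error_rate = 0, seed = NULL) {
  name <- match.arg(name)
  counts <- switch(name,
    mmej_1m = c(Success = 2, Deletion = 9, CleavageSiteIndel = 2,
                AAVIntegration = 4, OtherIndel = 1, Unedited = 39),
    hiti_1m = c(Success = 1, Deletion = 12, CleavageSiteIndel = 3,
                AAVIntegration = 5, OtherIndel = 1, Unedited = 64),
    invitro_mmej = c(Success = 3, Deletion = 16, CleavageSiteIndel = 3,
                     AAVIntegration = 5, OtherIndel = 2, Unedited = 29))
  n <- sum(counts)
  clone_sim_spec(counts / n, n, error_rate = error_rate, seed = seed)
}

# integer allocation by largest remainder; residuals assigned in the fixed
# category order of OUTCOME_LEVELS on ties
largest_remainder <- function(props, n) {
  exact <- props * n
  base <- floor(exact)
  rem <- n - sum(base)
  if (rem > 0) {
    ord <- order(-(exact - base), seq_along(props))
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  stats::setNames(as.integer(base), names(props))
}

apply_substitutions <- function(seq, rate) {
  if (rate <= 0) return(seq)
  n <- nchar(seq)
  idx <- which(stats::runif(n) < rate)
  if (length(idx) == 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  for (i in idx) {
    chars[i] <- sample(setdiff(DNA_BASES, chars[i]), 1)
  }
  paste(chars, collapse = "")
}

#' Simulate a clone set with known outcome labels
#'
#' Draws clone amplicon sequences from the category templates of the locus:
#' Success, Deletion and Unedited clones are the exact model amplicons;
#' CleavageSiteIndel clones carry a 1-10 bp insertion or deletion (uniform)
#' at one of the two cut sites of the mutant amplicon; AAVIntegration clones
#' carry a 20-100 bp substring of the vector fragment inserted at a cut
#' site; OtherIndel clones carry a 1-10 bp indel placed well away from both
#' cut-site windows. Per-base substitution errors are applied last. Category
#' counts follow largest-remainder allocation of `proportions * n_clones`,
#' so exact when those products are integers.
#'
#' @param locus A [locus_model()].
#' @param spec A [clone_sim_spec()] (or [fixture_clone_spec()]).
#' @param allele_set Optional prebuilt [build_allele_set()] for the locus.
#' @return A tibble `clone_id`, `seq`, `true_category`.
#' @export
simulate_clone_set <- function(locus, spec, allele_set = NULL) {
  stopifnot(inherits(spec, "clone_sim_spec"))
  aset <- allele_set %||% build_allele_set(locus)
  with_seed_if(spec$seed, {
    counts <- largest_remainder(spec$proportions, spec$n_clones)
    labels <- rep(names(counts), counts)
    seqs <- vapply(labels, function(cat) {
      draw_clone(cat, aset)
    }, character(1))
    if (spec$error_rate > 0) {
      seqs <- vapply(seqs, apply_substitutions, character(1),
                     rate = spec$error_rate)
    }
    tibble::tibble(clone_id = sprintf("clone%04d", seq_along(labels)),
                   seq = unname(seqs), true_category = labels)
  })
}

draw_clone <- function(category, aset) {
  amps <- aset$amplicons
  mut <- amps$mutant
  cuts <- c(aset$cut5_mut, aset$cut3_mut)
  switch(category,
    Success = amps$success,
    Deletion = amps$deletion,
    Unedited = mut,
    CleavageSiteIndel = {
      cut <- sample(cuts, 1)
      k <- sample(1:10, 1)
      if (stats::runif(1) < 0.5) {
        insert0(mut, cut, random_dna(k))
      } else {
        start <- max(0L, cut - k %/% 2L)
        splice0(mut, start, min(nchar(mut), start + k))
      }
    },
    AAVIntegration = {
      cut <- sample(cuts, 1)
      k <- sample(20:100, 1)
      left <- subseq0(mut, cut - 1L, cut)
      right <- subseq0(mut, cut, cut + 1L)
      # resample until the insert ends differ from the flanking bases, so
      # the insertion has a single unambiguous alignment placement
      repeat {
        s <- sample.int(nchar(aset$aav_fragment) - k + 1L, 1) - 1L
        frag <- subseq0(aset$aav_fragment, s, s + k)
        ends <- c(subseq0(frag, 0L, 1L), subseq0(frag, k - 1L, k))
        if (!any(ends %in% c(left, right))) break
      }
      insert0(mut, cut, frag)
    },
    OtherIndel = {
      margin <- 30L  # clear of the default 10-bp cut windows with slack
      ok <- setdiff(20:(nchar(mut) - 30L),
                    unlist(lapply(cuts, function(cc) (cc - margin):(cc + margin))))
      pos <- sample(ok, 1)
      k <- sample(1:10, 1)
      if (stats::runif(1) < 0.5) insert0(mut, pos, random_dna(k))
      else splice0(mut, pos, pos + k)
    },
    abort(sprintf("unknown category %s", category)))
}

#' Amplicon-length detection-bias model
#'
#' Models the preferential cloning/amplification of shorter PCR amplicons.
#' The functional form is a modelling choice (only the direction of the
#' bias is established empirically): the default is exponential decay per
#' 100 bp, `weight(L) = exp(-strength * (L - reference_length) / 100)`,
#' with `strength` calibrated so that a 670-bp amplicon is detected at 0.60
#' times the weight of a 611-bp one, echoing the empirically measured
#' under-representation factor. `power` uses
#' `(L / reference_length)^(-strength)`; `none` is the unbiased control.
#'
#' @param form `"exponential"`, `"power"` or `"none"`.
#' @param strength Relative weight decay per 100 bp (exponential) or power
#'   exponent.
#' @param reference_length Length (bp) at which the weight is 1.
#' @return A `bias_model` list with a `weight(L)` accessible through
#'   [bias_weight()].
#' @export
bias_model <- function(form = c("exponential", "power", "none"),
                       strength = -log(0.60) * 100 / 59,
                       reference_length = 611L) {
  form <- match.arg(form)
  if (form != "none" && strength < 0) abort("strength must be >= 0")
  structure(list(form = form, strength = strength,
                 reference_length = reference_length),
            class = "bias_model")
}

#' Detection weight of an amplicon length under a bias model
#'
#' @param model A [bias_model()].
#' @param length Amplicon length(s) in bp.
#' @return Positive weights, non-increasing in `length`.
#' @export
bias_weight <- function(model, length) {
  switch(model$form,
    none = rep(1, length(length)),
    exponential = exp(-model$strength * (length - model$reference_length) / 100),
    power = (length / model$reference_length)^(-model$strength))
}

#' Simulate a Success/mutant template mixture series
#'
#' Emulates the calibration experiment in which Success and unedited mutant
#' DNA are mixed at known molecular ratios, PCR-amplified, subcloned, and
#' the clones typed. Each clone is drawn Success with probability
#' `p * w_s / (p * w_s + (1 - p) * w_m)` where `p` is the true Success
#' fraction and `w_s`, `w_m` the bias weights of the success and mutant
#' amplicon lengths.
#'
#' @param locus A [locus_model()].
#' @param true_fractions True Success DNA fractions, each in (0, 1).
#' @param clones_per_mixture Clones sequenced per mixture (recycled).
#' @param bias A [bias_model()].
#' @param seed Integer seed.
#' @return A tibble of class `mixture_experiment`: `true_fraction`,
#'   `n_clones`, `observed_success`, `observed_fraction`.
#' @export
simulate_mixture_series <- function(locus, true_fractions, clones_per_mixture,
                                    bias = bias_model("none"), seed = NULL) {
  if (any(true_fractions <= 0 | true_fractions >= 1)) {
    abort("true_fractions must be in (0, 1)")
  }
  aset <- build_allele_set(locus)
  w_s <- bias_weight(bias, nchar(aset$amplicons$success))
  w_m <- bias_weight(bias, nchar(aset$amplicons$mutant))
  n <- as.integer(rep_len(clones_per_mixture, length(true_fractions)))
  with_seed_if(seed, {
    p_obs <- true_fractions * w_s / (true_fractions * w_s + (1 - true_fractions) * w_m)
    obs <- stats::rbinom(length(true_fractions), n, p_obs)
    out <- tibble::tibble(true_fraction = true_fractions, n_clones = n,
                          observed_success = obs, observed_fraction = obs / n)
    structure(out, class = c("mixture_experiment", class(out)))
  })
}

#' Simulate per-sample variant tables
#'
#' Generates the long variant table consumed by the off-target candidate
#' filter: `shared_sites` appear in every post-treatment sample and in no
#' pre-treatment sample; `private_sites` each appear in a single random
#' post sample; `n_noise` additional random sites are scattered over all
#' samples.
#'
#' @param n_post,n_pre Numbers of post- and pre-treatment samples.
#' @param shared_sites,private_sites Data frames with columns `chrom`,
#'   `pos`, `ref`, `alt` (1-based positions); `NULL` for none.
#' @param n_noise Number of random noise variants.
#' @param seed Integer seed.
#' @return A tibble `chrom`, `pos`, `ref`, `alt`, `vaf`, `sample`, with
#'   samples named `post1..postN` and `pre1..preM`.
#' @export
simulate_variant_tables <- function(n_post = 3L, n_pre = 1L,
                                    shared_sites = NULL, private_sites = NULL,
                                    n_noise = 0L, seed = NULL) {
  as_sites <- function(x) {
    if (is.null(x)) return(tibble::tibble(chrom = character(), pos = integer(),
                                          ref = character(), alt = character()))
    tibble::as_tibble(x)[c("chrom", "pos", "ref", "alt")]
  }
  shared <- as_sites(shared_sites)
  private <- as_sites(private_sites)
  post <- paste0("post", seq_len(n_post))
  pre <- paste0("pre", seq_len(n_pre))
  with_seed_if(seed, {
    rows <- list()
    if (nrow(shared) > 0) {
      rows$shared <- purrr::map_dfr(post,
                                    function(sm) dplyr::mutate(shared, sample = sm))
    }
    if (nrow(private) > 0) {
      rows$private <- dplyr::mutate(private,
                                    sample = sample(post, dplyr::n(), replace = TRUE))
    }
    if (n_noise > 0) {
      pool_pos <- sample.int(1e6, n_noise)  # without replacement: no duplicates
      refs <- sample(DNA_BASES, n_noise, replace = TRUE)
      alts <- vapply(refs, function(r) sample(setdiff(DNA_BASES, r), 1),
                     character(1))
      rows$noise <- tibble::tibble(
        chrom = sample(paste0("chr", 1:19), n_noise, replace = TRUE),
        pos = pool_pos, ref = refs, alt = unname(alts),
        sample = sample(c(post, pre), n_noise, replace = TRUE))
    }
    out <- dplyr::bind_rows(rows)
    if (nrow(out) == 0) {
      out <- tibble::tibble(chrom = character(), pos = integer(),
                            ref = character(), alt = character(),
                            sample = character())
    }
    if (anyDuplicated(out[c("chrom", "pos", "ref", "alt", "sample")]) > 0) {
      abort("duplicate (chrom, pos, ref, alt) within one sample")
    }
    out$vaf <- round(stats::runif(nrow(out), 0.02, 0.5), 3)
    dplyr::arrange(out[c("chrom", "pos", "ref", "alt", "vaf", "sample")],
                   .data$chrom, .data$pos, .data$sample)
  })
}

#' Simulate split-read alignment segments spanning vector-host junctions
#'
#' Each junction-spanning read is emitted as two alignment segments with
#' complementary read intervals: one on the host chromosome, one on the
#' vector (`"AAV"`) reference — the tabular equivalent of a soft-clipped
#' read pair of mappings. Background reads emit a single host segment.
#'
#' @param host_len,aav_len Host chromosome and vector reference lengths (bp).
#' @param junctions Data frame with columns `host_chrom`, `host_pos`,
#'   `aav_pos` and optionally `orientation` (`"host_left"` default:
#'   host sequence occupies the read 5' of the vector sequence), and
#'   optionally `n_reads` (spanning reads per junction).
#' @param n_reads Default spanning reads per junction (used when the
#'   `junctions` table has no `n_reads` column).
#' @param n_background Host-only background reads.
#' @param read_len Read length in bp (default 151).
#' @param seed Integer seed.
#' @return A tibble `read_id`, `ref`, `ref_start`, `ref_end`, `read_start`,
#'   `read_end`, `strand` (0-based half-open intervals).
#' @export
simulate_integration_reads <- function(host_len = 1e6, aav_len = 4700,
                                       junctions = NULL, n_reads = 10L,
                                       n_background = 0L, read_len = 151L,
                                       seed = NULL) {
  min_seg <- 20L
  read_len <- as.integer(read_len)
  junc <- if (is.null(junctions) || nrow(junctions) == 0) {
    tibble::tibble(host_chrom = character(), host_pos = integer(),
                   aav_pos = integer())
  } else tibble::as_tibble(junctions)
  if (nrow(junc) > 0) {
    junc$host_pos <- as.integer(junc$host_pos)
    junc$aav_pos <- as.integer(junc$aav_pos)
    if (!"orientation" %in% names(junc)) junc$orientation <- "host_left"
    if (!"n_reads" %in% names(junc)) junc$n_reads <- n_reads
    if (any(junc$host_pos < read_len | junc$host_pos > host_len - read_len) ||
        any(junc$aav_pos < read_len | junc$aav_pos > aav_len - read_len)) {
      abort("junction coordinates leave no room for spanning reads")
    }
  }
  with_seed_if(seed, {
    rows <- list()
    rid <- 0L
    for (i in seq_len(nrow(junc))) {
      for (r in seq_len(junc$n_reads[i])) {
        rid <- rid + 1L
        id <- sprintf("read%05d", rid)
        k <- sample(min_seg:(read_len - min_seg), 1)  # host bases in the read
        if (junc$orientation[i] == "host_left") {
          rows[[length(rows) + 1L]] <- tibble::tibble(
            read_id = id,
            ref = c(junc$host_chrom[i], "AAV"),
            ref_start = c(junc$host_pos[i] - k, junc$aav_pos[i]),
            ref_end = c(junc$host_pos[i], junc$aav_pos[i] + read_len - k),
            read_start = c(0L, k), read_end = c(k, read_len),
            strand = "+")
        } else {
          rows[[length(rows) + 1L]] <- tibble::tibble(
            read_id = id,
            ref = c("AAV", junc$host_chrom[i]),
            ref_start = c(junc$aav_pos[i] - (read_len - k), junc$host_pos[i]),
            ref_end = c(junc$aav_pos[i], junc$host_pos[i] + k),
            read_start = c(0L, read_len - k), read_end = c(read_len - k, read_len),
            strand = "+")
        }
      }
    }
    for (r in seq_len(n_background)) {
      rid <- rid + 1L
      p <- sample.int(host_len - read_len, 1)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        read_id = sprintf("read%05d", rid), ref = "chr1",
        ref_start = p, ref_end = p + read_len,
        read_start = 0L, read_end = read_len, strand = "+")
    }
    if (length(rows) == 0) {
      return(tibble::tibble(read_id = character(), ref = character(),
                            ref_start = integer(), ref_end = integer(),
                            read_start = integer(), read_end = integer(),
                            strand = character()))
    }
    dplyr::bind_rows(rows)
  })
}
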