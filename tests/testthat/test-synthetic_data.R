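test_that("a pure-Unedited error-free spec reproduces the mutant amplicon", {
  loc <- test_locus()
  aset <- test_alleles()
  cl <- simulate_clone_set(loc, clone_sim_spec(c(Unedited = 1), 10, seed = 1),
                           aset)
  expect_identical(unique(cl$seq), aset$amplicons$mutant)
  expect_identical(unique(cl$true_category), "Unedited")
})

test_that("clone simulation is a pure function of parameters and seed", {
  loc <- test_locus()
  spec <- fixture_clone_spec("mmej_1m", error_rate = 0.002, seed = 99)
  a <- simulate_clone_set(loc, spec)
  b <- simulate_clone_set(loc, spec)
  expect_identical(a, b)
})

test_that("category counts follow exact proportions and largest remainder", {
  loc <- test_locus()
  aset <- test_alleles()
  # exact integer products
  spec <- clone_sim_spec(c(Success = 0.25, Deletion = 0.25, Unedited = 0.5),
                         20, seed = 3)
  cl <- simulate_clone_set(loc, spec, aset)
  expect_identical(table(cl$true_category)[["Success"]], 5L)
  expect_identical(table(cl$true_category)[["Unedited"]], 10L)
  # non-integer products: largest-remainder allocation, n preserved
  spec2 <- clone_sim_spec(c(Success = 1 / 3, Deletion = 1 / 3,
                            Unedited = 1 / 3), 10, seed = 3)
  cl2 <- simulate_clone_set(loc, spec2, aset)
  expect_identical(nrow(cl2), 10L)
  counts <- table(cl2$true_category)
  expect_true(all(counts %in% 3:4))
})

test_that("fixture specs reproduce their per-category counts", {
  loc <- test_locus()
  counts <- function(name) {
    cl <- simulate_clone_set(loc, fixture_clone_spec(name, seed = 5))
    table(factor(cl$true_category, levels = OUTCOME_LEVELS))
  }
  m <- counts("mmej_1m")
  expect_identical(sum(m), 57L)
  expect_identical(m[["Success"]], 2L)
  expect_identical(m[["Unedited"]], 39L)
  h <- counts("hiti_1m")
  expect_identical(sum(h), 86L)
  expect_identical(h[["Success"]], 1L)
  expect_identical(h[["Unedited"]], 64L)
  v <- counts("invitro_mmej")
  expect_identical(sum(v) - v[["Unedited"]], 29L)
  expect_identical(v[["Success"]], 3L)
})

test_that("proportions must sum to one", {
  expect_error(clone_sim_spec(c(Success = 0.6, Unedited = 0.3), 10), "sum to 1")
  expect_error(clone_sim_spec(c(Succes = 1), 10), "unknown")
})

test_that("bias weights are positive, non-increasing, and hit the 0.60 calibration", {
  b <- bias_model("exponential")
  L <- seq(400, 900, by = 10)
  w <- bias_weight(b, L)
  expect_true(all(w > 0))
  expect_true(all(diff(w) <= 0))
  expect_equal(bias_weight(b, 670) / bias_weight(b, 611), 0.60,
               tolerance = 1e-12)
  expect_identical(bias_weight(bias_model("none"), L), rep(1, length(L)))
})

test_that("unbiased mixtures concentrate on the true fraction", {
  loc <- test_locus()
  mix <- simulate_mixture_series(loc, rep(0.5, 400), 100,
                                 bias = bias_model("none"), seed = 21)
  est <- mean(mix$observed_fraction)
  se <- sqrt(0.5 * 0.5 / 100 / 400)
  expect_lt(abs(est - 0.5), 3 * se)
})

test_that("biased mixtures match the closed-form observed fraction", {
  loc <- test_locus()
  b <- bias_model("exponential")
  p <- 0.2
  w_s <- bias_weight(b, 670)
  w_m <- bias_weight(b, 611)
  p_obs <- p * w_s / (p * w_s + (1 - p) * w_m)
  mix <- simulate_mixture_series(loc, rep(p, 400), 100, bias = b, seed = 22)
  se <- sqrt(p_obs * (1 - p_obs) / 100 / 400)
  expect_lt(abs(mean(mix$observed_fraction) - p_obs), 3 * se)
})

test_that("the canonical mixture design yields the expected shapes", {
  loc <- test_locus()
  mix <- simulate_mixture_series(loc, c(0.05, 0.1, 0.2, 0.5),
                                 c(61, 52, 64, 61), seed = 23)
  expect_identical(nrow(mix), 4L)
  expect_identical(mix$n_clones, c(61L, 52L, 64L, 61L))
  expect_true(all(mix$observed_success <= mix$n_clones))
})

test_that("mixture fractions outside (0,1) are rejected", {
  expect_error(simulate_mixture_series(test_locus(), c(0, 0.5), 10), "\\(0, 1\\)")
})

test_that("variant table generator places shared sites post-only", {
  shared <- data.frame(chrom = "chr3", pos = 1:5 * 100, ref = "A", alt = "T")
  v <- simulate_variant_tables(3, 1, shared_sites = shared, seed = 31)
  for (s in paste0("post", 1:3)) {
    expect_identical(variant_keys(v[v$sample == s, ]), variant_keys(shared))
  }
  expect_identical(nrow(v[v$sample == "pre1", ]), 0L)
})

test_that("variant table generator is seeded and rejects duplicates", {
  shared <- data.frame(chrom = "chr1", pos = 7, ref = "G", alt = "C")
  a <- simulate_variant_tables(3, 1, shared, n_noise = 50, seed = 5)
  b <- simulate_variant_tables(3, 1, shared, n_noise = 50, seed = 5)
  expect_identical(a, b)
  dup <- data.frame(chrom = c("chr1", "chr1"), pos = c(9, 9),
                    ref = c("A", "A"), alt = c("T", "T"))
  expect_error(simulate_variant_tables(1, 1, dup, seed = 5), "duplicate")
})

test_that("junction-spanning reads carry complementary host/AAV segments", {
  j <- data.frame(host_chrom = "chr5", host_pos = 5000, aav_pos = 1200)
  seg <- simulate_integration_reads(host_len = 1e4, aav_len = 4700,
                                    junctions = j, n_reads = 10,
                                    read_len = 151, seed = 41)
  expect_identical(length(unique(seg$read_id)), 10L)
  per_read <- split(seg, seg$read_id)
  for (sg in per_read) {
    expect_setequal(sg$ref, c("chr5", "AAV"))
    sg <- sg[order(sg$read_start), ]
    expect_identical(sg$read_end[1], sg$read_start[2])
    expect_identical(sg$read_start[1], 0L)
    expect_identical(sg$read_end[2], 151L)
    host <- sg[sg$ref == "chr5", ]
    expect_identical(host$ref_end, 5000L)
  }
})

test_that("background-only simulation emits single host segments", {
  seg <- simulate_integration_reads(junctions = NULL, n_background = 50,
                                    seed = 42)
  expect_identical(nrow(seg), 50L)
  expect_true(all(seg$ref != "AAV"))
  expect_true(all(seg$ref_end - seg$ref_start == 151L))
})

test_that("out-of-bounds junctions are rejected", {
  j <- data.frame(host_chrom = "chr1", host_pos = 10, aav_pos = 1200)
  expect_error(simulate_integration_reads(junctions = j, seed = 1), "room")
})
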