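test_that("metagene of a constant track is flat at that constant", {
  fr <- tile_fragments("c", seq(50, 9950, by = 50), 10000)
  tr <- make_track(rep(2.5, nrow(fr)), fr)
  genes <- data.frame(gene_id = paste0("g", 1:5), chrom = "c",
                      start = seq(2000, 6000, by = 1000),
                      end = seq(2400, 6400, by = 1000),
                      strand = c("+", "-", "+", "-", "+"))
  prof <- metagene(tr, genes, profile_params(n_body_bins = 20, flank_bp = 500,
                                             flank_bins = 10))
  expect_equal(prof$mean_score, rep(2.5, 40), tolerance = 1e-12)
  expect_length(prof$position, 2 * 10 + 20)
})

test_that("metagene shows the step at the TSS for a body-only signal", {
  fr <- tile_fragments("c", c(5000, 7000), 12000)
  tr <- make_track(c(0, 1, 0), fr)   # signal only inside [5000, 7000)
  genes <- data.frame(gene_id = "g", chrom = "c", start = 5000, end = 7000,
                      strand = "+")
  prof <- metagene(tr, genes, profile_params(n_body_bins = 10, flank_bp = 1000,
                                             flank_bins = 5))
  expect_equal(prof$mean_score, c(rep(0, 5), rep(1, 10), rep(0, 5)))
})

test_that("metagene recovers a linear ramp within discretization error", {
  # 1 bp fragments so per-base scores are exact; ramp 0..1 over each body
  glen <- 400
  gs <- c(1000, 3000)
  strand <- c("+", "-")
  bounds <- 1:5999
  fr <- tile_fragments("c", bounds, 6000)
  sc <- numeric(nrow(fr))
  for (k in 1:2) {
    ramp <- (seq_len(glen) - 0.5) / glen
    if (strand[k] == "-") ramp <- rev(ramp)     # ramp runs TSS -> TES
    sc[(gs[k] + 1):(gs[k] + glen)] <- ramp
  }
  tr <- make_track(sc, fr)
  genes <- data.frame(gene_id = c("g1", "g2"), chrom = "c",
                      start = gs, end = gs + glen, strand = strand)
  prof <- metagene(tr, genes, profile_params(n_body_bins = 40, flank_bp = 200,
                                             flank_bins = 10))
  body <- prof$mean_score[11:50]
  expected <- (seq_len(40) - 0.5) / 40
  expect_equal(body, expected, tolerance = 1 / 40)
  # strand-symmetric signal: flipping every strand leaves the profile intact
  genes_f <- genes; genes_f$strand <- c("-", "+")
  sc2 <- sc
  for (k in 1:2) {
    ramp <- (seq_len(glen) - 0.5) / glen
    if (genes_f$strand[k] == "-") ramp <- rev(ramp)
    sc2[(gs[k] + 1):(gs[k] + glen)] <- ramp
  }
  prof_f <- metagene(make_track(sc2, fr), genes_f,
                     profile_params(n_body_bins = 40, flank_bp = 200,
                                    flank_bins = 10))
  expect_equal(prof_f$mean_score, prof$mean_score, tolerance = 1e-12)
})

test_that("short genes are skipped and counted", {
  fr <- tile_fragments("c", c(500), 1000)
  tr <- make_track(c(1, 1), fr)
  genes <- data.frame(gene_id = c("long", "short"), chrom = "c",
                      start = c(100, 800), end = c(400, 805), strand = "+")
  prof <- metagene(tr, genes, profile_params(n_body_bins = 20, flank_bp = 50,
                                             flank_bins = 5))
  expect_equal(prof$n_genes, 1L)
  expect_equal(prof$n_skipped, 1L)
  expect_error(metagene(tr, genes[2, , drop = FALSE],
                        profile_params(n_body_bins = 20)), "long enough")
})

test_that("ranked bins aggregate expression by occupancy order", {
  scores <- data.frame(gene_id = paste0("g", 1:6), occupancy = 1:6)
  tpm <- data.frame(gene_id = paste0("g", 1:6), tpm = c(10, 10, 20, 20, 30, 30))
  out <- ranked_bin_comparison(scores, tpm, profile_params(bin_size_genes = 2))
  expect_equal(out$mean_expression, c(10, 20, 30))
  expect_equal(out$n_genes, c(2L, 2L, 2L))
  # row order of the inputs is irrelevant
  set.seed(51)
  out2 <- ranked_bin_comparison(scores[sample(1:6), ], tpm[sample(1:6), ],
                                profile_params(bin_size_genes = 2))
  expect_equal(out2, out, ignore_attr = TRUE)
  # monotone truth: expression an increasing function of occupancy
  expect_true(all(diff(out$mean_expression) > 0))
  expect_error(ranked_bin_comparison(scores,
                                     data.frame(gene_id = "zzz", tpm = 1)),
               "shared")
})

test_that("bin means rise monotonically when TPM tracks occupancy", {
  set.seed(52)
  n <- 6900
  occ <- rnorm(n)
  tpm <- exp(occ + rnorm(n, sd = 0.3))
  out <- ranked_bin_comparison(
    data.frame(gene_id = sprintf("g%05d", 1:n), occupancy = occ),
    data.frame(gene_id = sprintf("g%05d", 1:n), tpm = tpm),
    profile_params(bin_size_genes = 690))
  expect_equal(nrow(out), 10L)
  expect_equal(cor(out$bin, out$mean_expression, method = "spearman"), 1)
})

test_that("degenerate bootstrap inputs give degenerate intervals", {
  b1 <- bootstrap_tpr(11, 11, bootstrap_params(n_boot = 1000, seed = 1))
  expect_equal(c(b1$ci_lower, b1$ci_upper), c(1, 1))
  b0 <- bootstrap_tpr(0, 11, bootstrap_params(n_boot = 1000, seed = 1))
  expect_equal(c(b0$ci_lower, b0$ci_upper), c(0, 0))
  expect_error(bootstrap_tpr(1, 0), "n_total")
  b <- bootstrap_tpr(8, 11, bootstrap_params(n_boot = 5000, seed = 2))
  expect_true(b$ci_lower <= b$point_estimate & b$point_estimate <= b$ci_upper)
})

test_that("extrapolation scales CI bounds to gene counts", {
  tpr <- structure(list(point_estimate = 8 / 11, ci_lower = 0.45,
                        ci_upper = 0.88, ci_level = 0.95, n_boot = 1000,
                        n_positive = 8, n_total = 11), class = "tpr_boot")
  expect_equal(unname(extrapolate_expressed(tpr, 2362, "nearest100")),
               c(1100, 2100))
  tpr1 <- structure(list(ci_lower = 1, ci_upper = 1), class = "tpr_boot")
  expect_equal(unname(extrapolate_expressed(tpr1, 777)), c(777, 777))
  tpr5 <- structure(list(ci_lower = 0.5, ci_upper = 0.5), class = "tpr_boot")
  expect_equal(unname(extrapolate_expressed(tpr5, 200)), c(100, 100))
})
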