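test_that("gene occupancy is the overlap-weighted mean of fragment scores", {
  fr <- tile_fragments("c", c(5, 10), 15)
  tr <- make_track(c(2, 4, 0), fr)
  g <- data.frame(gene_id = "g1", chrom = "c", start = 0, end = 10, strand = "+")
  expect_equal(gene_occupancy(tr, g)$occupancy, 3)     # equal overlap of 2 and 4
  g2 <- data.frame(gene_id = "g2", chrom = "c", start = 6, end = 9, strand = "+")
  tr2 <- make_track(c(0, -1.5, 0), fr)
  expect_equal(gene_occupancy(tr2, g2)$occupancy, -1.5) # fully inside one fragment
  expect_error(gene_occupancy(tr, data.frame(gene_id = "bad", chrom = "c",
                                             start = 10, end = 99, strand = "+")),
               "bad")
})

test_that("gene occupancy equals a brute-force per-base average", {
  set.seed(41)
  bounds <- sort(sample(10:990, 60))
  fr <- tile_fragments("c", bounds, 1000)
  sc <- rnorm(nrow(fr))
  tr <- make_track(sc, fr)
  per_base <- rep(sc, fr$end - fr$start)   # base i+1 holds score at position i
  gs <- sample(0:900, 100, replace = TRUE)
  ge <- pmin(gs + sample(5:90, 100, replace = TRUE), 1000)
  genes <- data.frame(gene_id = paste0("g", 1:100), chrom = "c",
                      start = gs, end = ge, strand = "+")
  occ <- gene_occupancy(tr, genes)
  oracle <- vapply(1:100, function(i) mean(per_base[(gs[i] + 1):ge[i]]), 0)
  expect_equal(occ$occupancy, oracle, tolerance = 1e-9)
})

test_that("identical fragment scores give p = 1 for every gene", {
  fr <- tile_fragments("c", seq(10, 990, by = 10), 1000)
  tr <- make_track(rep(1.7, nrow(fr)), fr)
  genes <- data.frame(gene_id = paste0("g", 1:12), chrom = "c",
                      start = seq(0, 880, by = 80), end = seq(40, 920, by = 80),
                      strand = "+")
  calls <- call_expressed(gene_occupancy(tr, genes), tr,
                          call_params(n_permutations = 200, seed = 5))
  expect_true(all(calls$p_value == 1))
  expect_equal(sum(calls$fdr < 0.05), 0L)
})

test_that("spiked genes over a normal background are all detected", {
  set.seed(42)
  n_frag <- 5000
  fr <- tile_fragments("c", seq(100, by = 100, length.out = n_frag - 1), n_frag * 100)
  sc <- rnorm(n_frag)
  # 20 genes of 5 fragments each, spiked to score 5
  spike_start <- seq(1, by = 250, length.out = 20)
  genes <- data.frame(gene_id = paste0("g", 1:20), chrom = "c",
                      start = (spike_start - 1) * 100,
                      end = (spike_start + 4) * 100, strand = "+")
  for (s in spike_start) sc[s:(s + 4)] <- 5
  # background genes so BH has a realistic p distribution
  bg_start <- seq(10, by = 25, length.out = 180)
  genes_bg <- data.frame(gene_id = paste0("b", 1:180), chrom = "c",
                         start = (bg_start - 1) * 100, end = (bg_start + 4) * 100,
                         strand = "+")
  tr <- make_track(sc, fr)
  all_genes <- rbind(genes, genes_bg)
  calls <- call_expressed(gene_occupancy(tr, all_genes), tr,
                          call_params(n_permutations = 2000, seed = 6))
  spiked <- calls[1:20, ]
  expect_true(all(spiked$fdr < 0.05))
})

test_that("permutation p-values are reproducible under a fixed seed", {
  fr <- tile_fragments("c", seq(10, 990, by = 7), 1000)
  set.seed(43)
  tr <- make_track(rnorm(nrow(fr)), fr)
  genes <- data.frame(gene_id = paste0("g", 1:30), chrom = "c",
                      start = seq(0, 870, by = 30), end = seq(25, 895, by = 30),
                      strand = "+")
  occ <- gene_occupancy(tr, genes)
  c1 <- call_expressed(occ, tr, call_params(n_permutations = 500, seed = 9))
  c2 <- call_expressed(occ, tr, call_params(n_permutations = 500, seed = 9))
  expect_identical(c1$p_value, c2$p_value)
})

test_that("raising a gene's fragment scores never raises its p-value", {
  fr <- tile_fragments("c", seq(10, 990, by = 10), 1000)
  set.seed(44)
  sc <- rnorm(nrow(fr))
  genes <- data.frame(gene_id = paste0("g", 1:20), chrom = "c",
                      start = seq(0, 760, by = 40), end = seq(30, 790, by = 40),
                      strand = "+")
  tr <- make_track(sc, fr)
  occ1 <- gene_occupancy(tr, genes)
  calls1 <- call_expressed(occ1, tr, call_params(n_permutations = 1000, seed = 2))
  # push gene 1's occupancy up while keeping the same null (same track scores)
  occ2 <- occ1
  occ2$occupancy[1] <- occ2$occupancy[1] + 3
  calls2 <- call_expressed(occ2, tr, call_params(n_permutations = 1000, seed = 2))
  expect_lte(calls2$p_value[1], calls1$p_value[1])
})

test_that("BH adjustment matches the closed-form step-up on a hand vector", {
  p <- c(0.001, 0.01, 0.02, 0.04, 0.5)
  # step-up: p(i) * n / i, cumulative minimum from the largest rank down
  expect_equal(p.adjust(p, "BH"), c(0.005, 0.025, 0.1 / 3, 0.05, 0.5))
  fr <- tile_fragments("c", seq(10, 990, by = 10), 1000)
  calls <- structure(
    data.frame(gene_id = letters[1:5], occupancy = 1:5, p_value = p,
               fdr = p.adjust(p, "BH"), n_fragments = 1L),
    class = c("rapid_calls", "data.frame"))
  expect_true(all(calls$fdr >= calls$p_value))
})

test_that("detected-set algebra follows any/all replicate semantics", {
  mk <- function(sig, all_genes = c("a", "b", "c", "d")) {
    structure(data.frame(gene_id = all_genes, occupancy = 1,
                         p_value = ifelse(all_genes %in% sig, 0.001, 0.9),
                         fdr = ifelse(all_genes %in% sig, 0.01, 0.9),
                         n_fragments = 1L),
              class = c("rapid_calls", "data.frame"))
  }
  repA <- mk(c("a", "b")); repB <- mk(c("b", "c"))
  expect_setequal(detected_set(list(repA, repB), "any"), c("a", "b", "c"))
  expect_setequal(detected_set(list(repA, repB), "all"), "b")
  expect_setequal(detected_set(list(repA), "all"), c("a", "b"))
  expect_warning(
    detected_set(list(repA, mk("b", all_genes = c("a", "b"))), "all"),
    "universes")
})

test_that("tissue partition computes unique sets and Venn regions", {
  sets <- list(t1 = c("a", "b", "c"), t2 = c("b", "c", "d"), t3 = c("c", "e"))
  part <- tissue_partition(sets)
  expect_setequal(part$unique$t1, "a")
  expect_setequal(part$unique$t2, "d")
  expect_setequal(part$unique$t3, "e")
  expect_setequal(part$shared_all, "c")
  expect_equal(sum(part$regions$count), length(Reduce(union, sets)))
  # identical sets: no uniques, everything shared
  part2 <- tissue_partition(list(x = c("a", "b"), y = c("a", "b")))
  expect_length(part2$unique$x, 0)
  expect_setequal(part2$shared_all, c("a", "b"))
  # conservation on random sets
  set.seed(45)
  rs <- lapply(1:3, function(i) sample(paste0("g", 1:1000), 400))
  names(rs) <- paste0("t", 1:3)
  p3 <- tissue_partition(rs)
  expect_equal(sum(p3$regions$count), length(Reduce(union, rs)))
  expect_true(all(!duplicated(unlist(p3$unique))))
})

test_that("marker refinement removes worm-wide hits and close upstream neighbors", {
  genes <- data.frame(
    gene_id = c("a", "a_up", "b", "c"),
    chrom = "c",
    start = c(1000, 0, 5000, 9000),
    end = c(2000, 850, 6000, 9500),
    strand = "+")
  # a's neighbor ends 150 bp upstream -> excluded; b removed as worm-wide hit
  cand <- marker_candidates(c("a", "b", "c"), whole_detected = "b", genes,
                            upstream_gap = 200)
  expect_setequal(cand, "c")
  # boundary: exactly 200 bp away is retained (rule is strictly < 200)
  genes2 <- genes
  genes2$end[2] <- 800
  expect_setequal(marker_candidates(c("a", "c"), character(0), genes2), c("a", "c"))
  # minus-strand gene: upstream is to the right
  genes3 <- data.frame(gene_id = c("m", "m_up"), chrom = "c",
                       start = c(1000, 2100), end = c(2000, 2500),
                       strand = "-")
  expect_length(marker_candidates("m", character(0), genes3, upstream_gap = 200), 0)
  expect_setequal(marker_candidates("m", character(0), genes3, upstream_gap = 100), "m")
  # opposite-strand neighbor ignored in same-strand mode, honored in any mode
  genes4 <- genes
  genes4$strand[2] <- "-"
  expect_setequal(marker_candidates("a", character(0), genes4), "a")
  expect_length(marker_candidates("a", character(0), genes4,
                                  neighbor_strand = "any"), 0)
})

test_that("marker refinement agrees with a brute-force upstream scan", {
  set.seed(46)
  sim <- small_sim()
  genes <- sim$genes
  uniq <- sample(genes$gene_id, 60)
  cand <- marker_candidates(uniq, character(0), genes, upstream_gap = 600,
                            neighbor_strand = "any")
  brute <- vapply(uniq, function(id) {
    g <- genes[genes$gene_id == id, ]
    nb <- genes[genes$gene_id != id & genes$chrom == g$chrom, ]
    gap <- if (g$strand == "+") g$start - nb$end[nb$end <= g$start]
           else nb$start[nb$start >= g$end] - g$end
    !any(gap < 600)
  }, logical(1))
  expect_setequal(cand, uniq[brute])
})

test_that("set overlap reports count and coverage fraction", {
  ov <- set_overlap(c("a", "b", "c"), c("b", "c", "d"))
  expect_equal(ov$count, 2L)
  expect_equal(ov$fraction, 2 / 3, tolerance = 1e-12)
  expect_equal(set_overlap(c("a"), c("b"))$fraction, 0)
  expect_equal(set_overlap(c("a", "b"), c("a", "b", "z"))$fraction, 1)
  expect_true(is.na(set_overlap(character(0), "a")$fraction))
})

test_that("subset similarity uses a pooled-variance Student t-test", {
  x <- c(1, 2, 3, 4)
  r <- subset_similarity_test(x, x)
  expect_equal(r$t, 0)
  expect_equal(r$p_value, 1)
  set.seed(47)
  a <- rnorm(30); b <- rnorm(30, 5)
  r2 <- subset_similarity_test(a, b)
  expect_lt(r2$p_value, 1e-6)
  r3 <- subset_similarity_test(b, a)
  expect_equal(r2$p_value, r3$p_value)
  expect_equal(r2$t, -r3$t)
  # pooled t equals the classical formula
  sp2 <- ((29 * var(a) + 29 * var(b)) / 58)
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 30 + 1 / 30))
  expect_equal(r2$t, t_hand, tolerance = 1e-12)
  expect_error(subset_similarity_test(c(1, 1), c(1, 1)), "variance")
})
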