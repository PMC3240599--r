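test_that("EHH follows the pair-counting definition and truncation rule", {
  # 4 haplotypes, identity classes {3,1} then {2,1,1}
  h <- rbind(c(0, 0, 0), c(0, 0, 0), c(0, 1, 0), c(0, 0, 1))
  e <- compute_ehh(h, core = 1, "right")
  expect_equal(e$ehh, c(3 / 6, 1 / 6))
  # ancestry switch before x turns a would-be class member into a singleton:
  # without truncation classes at marker 2 are {2,2}; haplotype 4's switch
  # makes them {2,1,1}
  h2 <- rbind(c(0, 1), c(0, 1), c(0, 0), c(0, 0))
  lab <- rbind(c(1L, 1L), c(1L, 1L), c(1L, 1L), c(1L, 2L))
  e_plain <- compute_ehh(h2, 1, "right")
  e_trunc <- compute_ehh(h2, 1, "right", labels = lab, target = 1)
  expect_equal(e_plain$ehh, 2 / 6)
  expect_equal(e_trunc$ehh, 1 / 6)
  expect_error(compute_ehh(h[1, , drop = FALSE], 1, "right"), "fewer than 2")
})

test_that("EHH is non-increasing with distance from the core", {
  sim <- tiny_admixture(n_ind = 15, M = 500, n_source = 40, seed = 81)
  mk <- sim$markers
  on_ch <- which(mk$chrom == mk$chrom[250])
  for (core in on_ch[c(3, 10, 20)]) {
    e <- compute_ehh(sim$panel$alleles, core, "right", last = max(on_ch))
    expect_true(all(diff(e$ehh) <= 1e-12))
    el <- compute_ehh(sim$panel$alleles, core, "left", last = min(on_ch))
    expect_true(all(diff(el$ehh) <= 1e-12))
  }
})

test_that("iHH integrates trapezoidally with interpolation, gaps, and edges", {
  # (1 + 0.5)/2 * 10000 with the cutoff below 0.5, crossing at the next point
  r <- compute_ihh(c(1, 0.5, 0), c(0, 10000, 20000), cutoff = 0.05)
  expect_equal(r$ihh, 7500 + (0.5 + 0.05) / 2 * 10000 * (0.45 / 0.5))
  expect_false(r$edge)
  # constant EHH to the end of the chromosome: edge-flagged
  r2 <- compute_ihh(c(1, 1, 1), c(0, 1e4, 2e4), cutoff = 0.05)
  expect_true(r2$edge)
  # cutoff = 1: zero area
  expect_equal(compute_ihh(c(1, 0.5), c(0, 1e4), cutoff = 1)$ihh, 0)
  # large-gap guard scales the segment down
  g <- compute_ihh(c(1, 1, 0), c(0, 40000, 41000), cutoff = 0.5,
                   maxgap_bp = 20000)
  expect_equal(g$ihh, 40000 * 0.5 + (1 + 0.5) / 2 * 1000 * 0.5)
})

test_that("compiled scan agrees with the pure-R reference path", {
  set.seed(82)
  grid <- simulate_marker_grid(400, chrom_lengths_cm = c(cA = 90, cB = 50))
  fr <- draw_population_freqs(grid$p_anc, 0.1, K = 1)
  pan <- simulate_source_haplotypes(fr[1, ], 40, grid$markers, seed = 83)
  cfg2 <- sim_config(K = 2, M = 400, n_ind = 20, T_gen = 8, z_dist = 0.6,
                     seed = 84)
  tr <- simulate_admixed_cohort(cfg2, list(pan, pan), grid$markers)$track
  for (mode in c("truncate", "exclude400")) {
    cf <- ihs_config(ancestry_mode = mode, exclude_snps = 25)
    sc <- ihs_scan(pan, tr, target = 1, config = cf, standardize = FALSE)
    for (core in c(7, 60, 201, 350)) {
      r <- raw_ihs(core, pan, track = tr, target = 1, config = cf)
      if (is.na(r$raw)) {
        expect_true(is.na(sc$raw[core]))
      } else {
        expect_equal(sc$raw[core], r$raw, tolerance = 1e-10)
        expect_equal(sc$ihh_a[core], r$ihh_a, tolerance = 1e-10)
        expect_equal(sc$edge[core], r$edge)
      }
    }
  }
})

test_that("raw iHS is zero for symmetric classes and antisymmetric in labels", {
  # two allele classes with identical haplotype structure
  mk <- tiny_markers(seq(1e5, by = 1e5, length.out = 9))
  block <- rbind(c(0, 1, 0, 1), c(0, 1, 0, 1), c(1, 0, 1, 0), c(1, 0, 1, 0))
  alle <- cbind(block, c(0, 0, 1, 1), block[, 4:1])
  pan <- haplotype_panel(alle, mk, c("s1", "s2"))
  r <- raw_ihs(5, pan, config = ihs_config(min_class = 2))
  expect_equal(r$raw, 0)
  # swapping the ancestral/derived annotation negates every score exactly
  sim <- tiny_admixture(n_ind = 20, M = 600, n_source = 60, seed = 85)
  pa <- sim$panel
  sc1 <- ihs_scan(pa, standardize = FALSE)
  pa2 <- pa
  pa2$markers$ancestral_is_ref <- FALSE
  sc2 <- ihs_scan(pa2, standardize = FALSE)
  i <- which(is.finite(sc1$raw) & is.finite(sc2$raw))
  expect_gt(length(i), 50)
  expect_equal(sc2$raw[i], -sc1$raw[i], tolerance = 1e-12)
  expect_equal(sc2$daf[i], 1 - sc1$daf[i], tolerance = 1e-12)
})

test_that("ancestry modes coincide when no haplotype switches ancestry", {
  sim <- tiny_admixture(n_ind = 15, M = 500, n_source = 40, seed = 86)
  tr_const <- ancestry_track(matrix(1L, nrow(sim$panel$alleles), 500),
                             c("a", "b"))
  s1 <- ihs_scan(sim$panel, tr_const, target = 1,
                 config = ihs_config(ancestry_mode = "truncate"),
                 standardize = FALSE)
  s2 <- ihs_scan(sim$panel, tr_const, target = 1,
                 config = ihs_config(ancestry_mode = "exclude400"),
                 standardize = FALSE)
  expect_equal(s1$raw, s2$raw)
})

test_that("standardization recovers a standard normal from known laws", {
  set.seed(87)
  n <- 10000
  maf <- runif(n, 0.05, 0.5)
  # i.i.d. normal raw scores independent of frequency
  sc <- data.frame(chrom = "c1", pos_bp = seq_len(n) * 1000,
                   daf = maf, maf = maf,
                   raw = rnorm(n, 0.4, 1.7), edge = FALSE)
  out <- standardize_ihs(sc, ihs_config())
  u <- out$std[is.finite(out$std)]
  expect_lt(abs(mean(u)), 0.05)
  expect_lt(abs(sd(u) - 1), 0.05)
  # location and scale drifting linearly in MAF: standardized quartiles flat
  sc2 <- sc
  sc2$raw <- (1 - 3 * maf) + (0.5 + 2 * maf) * rnorm(n)
  out2 <- standardize_ihs(sc2, ihs_config())
  bins <- cut(out2$maf, quantile(out2$maf, 0:5 / 5), include.lowest = TRUE)
  q25 <- tapply(out2$std, bins, quantile, 0.25)
  q75 <- tapply(out2$std, bins, quantile, 0.75)
  expect_lt(diff(range(q25)), 0.2)
  expect_lt(diff(range(q75)), 0.2)
  expect_lt(max(abs((q75 + q25) / 2)), 0.1)
})

test_that("sweep-injected cores stand out from the neutral score distribution", {
  set.seed(88)
  grid <- simulate_marker_grid(6000)
  fr <- draw_population_freqs(grid$p_anc, 0.15, K = 1)
  pan <- simulate_source_haplotypes(fr[1, ], 200, grid$markers, seed = 89)
  mk <- grid$markers
  on_ch <- which(mk$chrom == "chr3")
  core <- on_ch[which.min(abs(mk$pos_cm[on_ch] - median(mk$pos_cm[on_ch])))]
  swept <- inject_sweep(pan, sweep_spec(core, 0.6, founder_span_cm = 6),
                        seed = 90)
  cf <- ihs_config(qr_basis = "quadratic")
  sc <- suppressWarnings(ihs_scan(swept, config = cf))
  neutral <- suppressWarnings(ihs_scan(pan, config = cf))
  thr95 <- quantile(abs(neutral$std), 0.95, na.rm = TRUE)
  # the extreme score sits at or next to the core (flanking markers often
  # carry the maximum, which is why candidate calling works on regions)
  win <- intersect((core - 3):(core + 3), on_ch)
  expect_gt(max(abs(sc$std[win]), na.rm = TRUE), thr95)
  # the sweep lengthens derived-allele haplotypes: raw iHS negative
  expect_lt(sc$raw[core], 0)
})

test_that("region calling follows the seed/extend/merge rules", {
  cf <- ihs_config()
  # all scores below threshold: no regions
  quiet <- data.frame(chrom = "c1", pos_bp = seq(0, 2e5, by = 2000))
  quiet$std <- 1.0
  expect_equal(nrow(call_candidate_regions(quiet, cf)), 0L)
  # SNPs every 2 kb on [0, 200kb]; scores 3.0 on the 60-120 kb run
  d <- data.frame(chrom = "c1", pos_bp = seq(0, 2e5, by = 2000))
  d$std <- ifelse(d$pos_bp >= 60000 & d$pos_bp <= 120000, 3.0, 0)
  reg <- call_candidate_regions(d, cf)
  expect_equal(nrow(reg), 1L)
  # merged seed windows: [60k - 25k, 120k + 25k]; no hot SNP beyond, so no
  # extension; 56 scored SNPs inside (35k..145k -> 36k..144k even grid)
  expect_equal(reg$start_bp, 35000)
  expect_equal(reg$end_bp, 145000)
  expect_equal(reg$n_snps, length(seq(36000, 144000, by = 2000)))
  expect_equal(reg$n_above, length(seq(60000, 120000, by = 2000)))
  expect_equal(reg$max_abs_ihs, 3.0)
  # two hot runs separated by > 50 kb: two regions ranked by max |iHS|
  d2 <- data.frame(chrom = "c1", pos_bp = seq(0, 6e5, by = 2000))
  d2$std <- 0
  d2$std[d2$pos_bp >= 50000 & d2$pos_bp <= 110000] <- 2.8
  d2$std[d2$pos_bp >= 400000 & d2$pos_bp <= 460000] <- 3.5
  reg2 <- call_candidate_regions(d2, cf)
  expect_equal(nrow(reg2), 2L)
  expect_equal(reg2$max_abs_ihs, c(3.5, 2.8))
  # sign flip and coordinate translation leave calls invariant
  d3 <- d2
  d3$std <- -d3$std
  d3$pos_bp <- d3$pos_bp + 123456
  reg3 <- call_candidate_regions(d3, cf)
  expect_equal(reg3$start_bp - 123456, reg2$start_bp)
  expect_equal(reg3$n_above, reg2$n_above)
  # retention filters: a hot singleton among few SNPs is dropped
  d4 <- data.frame(chrom = "c1", pos_bp = c(0, 60000, 120000), std = c(0, 3, 0))
  expect_equal(nrow(call_candidate_regions(d4, cf)), 0L)
})

test_that("overlap enrichment matches the hypergeometric law and a resampling oracle", {
  st <- overlap_enrichment(paste0("s", 1:100), paste0("s", c(1:10, 201:240)),
                           universe = 1000)
  expect_equal(st$expected, 100 * 50 / 1000)
  expect_equal(st$observed, 10)
  # Monte-Carlo oracle for the upper-tail probability
  set.seed(91)
  mc <- mean(replicate(4000, {
    b <- sample.int(1000, 50)
    sum(b <= 100) >= 10
  }))
  se <- sqrt(mc * (1 - mc) / 4000)
  expect_lt(abs(st$p_value - mc), 3 * se + 1e-6)
  # disjoint sets: observed 0, upper tail covers everything
  st0 <- overlap_enrichment(paste0("s", 1:5), paste0("s", 6:10),
                            universe = 1000)
  expect_equal(st0$observed, 0)
  expect_equal(st0$p_value, 1)
  # permutation method preserves order and returns a valid p
  uni <- paste0("m", 1:500)
  stp <- overlap_enrichment(uni[1:50], uni[c(1:10, 100:139)], universe = uni,
                            method = "permutation", n_shift = 500, seed = 92)
  expect_true(stp$p_value > 0 && stp$p_value <= 1)
  expect_error(overlap_enrichment(paste0("s", 1:100), "s1", universe = 50),
               "smaller")
})

test_that("sweeps planted in different components overlap only by chance", {
  set.seed(93)
  grid <- simulate_marker_grid(6000)
  fr <- draw_population_freqs(grid$p_anc, 0.15, K = 2)
  cf <- ihs_config(qr_basis = "quadratic")
  tops <- list()
  for (k in 1:2) {
    pan <- simulate_source_haplotypes(fr[k, ], 150, grid$markers,
                                      seed = 93 + k)
    on_ch <- which(grid$markers$chrom == c("chr2", "chr9")[k])
    core <- on_ch[round(length(on_ch) / 2)]
    swept <- inject_sweep(pan, sweep_spec(core, 0.5, 5), seed = 95 + k)
    sc <- suppressWarnings(ihs_scan(swept, config = cf))
    ok <- which(is.finite(sc$std))
    tops[[k]] <- ok[rank(-abs(sc$std[ok])) <= length(ok) * 0.01]
  }
  M <- 6000
  st <- overlap_enrichment(tops[[1]], tops[[2]], universe = M)
  # within 3 SD of the hypergeometric expectation
  vr <- st$expected * (1 - st$n_b / M) * (M - st$n_a) / (M - 1)
  expect_lt(abs(st$observed - st$expected), 3 * sqrt(vr) + 3)
})
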