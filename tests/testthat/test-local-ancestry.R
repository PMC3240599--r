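test_that("forward-backward log-likelihood equals brute-force enumeration", {
  set.seed(21)
  grid <- simulate_marker_grid(10, chrom_lengths_cm = c(a = 30, b = 20))
  fr <- draw_population_freqs(grid$p_anc, 0.2, K = 2, seed = 22)
  pans <- simulate_source_haplotypes(fr, 20, grid$markers, seed = 23)
  pan <- haplotype_panel(rbind(pans[[1]]$alleles[1:2, ],
                               pans[[2]]$alleles[1:2, ]),
                         grid$markers, c("s1", "s2"))
  big <- haplotype_panel(rbind(pans[[1]]$alleles, pans[[2]]$alleles),
                         grid$markers, paste0("x", 1:20))
  for (mo in 0:1) {
    params <- estimate_hmm_params(big, list(1:5, 6:10), q = c(0.6, 0.4),
                                  tau = 8, markov_order = mo)
    tr <- decode_ancestry(pan, params)
    ll <- attr(tr, "loglik")
    for (h in 1:4)
      expect_lt(abs(ll[h] - brute_loglik(pan$alleles[h, ], params,
                                         grid$markers)), 1e-8)
    s <- apply(tr$posteriors, c(1, 2), sum)
    expect_lt(max(abs(s - 1)), 1e-12)
  }
})

test_that("fully informative markers are decoded without error", {
  mk <- tiny_markers(seq(1e5, by = 1e5, length.out = 60),
                     pos_cm = seq(0.1, by = 0.5, length.out = 60))
  fr <- rbind(rep(1, 60), rep(0, 60))   # clipped internally
  set.seed(24)
  lab <- matrix(1L, 4, 60)
  lab[, 25:40] <- 2L                    # a planted foreign segment
  alle <- matrix(0L, 4, 60)
  alle[lab == 1L] <- 1L
  pan <- haplotype_panel(alle, mk, c("s1", "s2"))
  params <- hmm_params(fr, q = c(0.5, 0.5), tau = 12)
  tr <- decode_ancestry(pan, params)
  expect_identical(unname(tr$labels), lab)
})

test_that("K = 1 decoding yields certainty", {
  sim <- tiny_admixture(n_ind = 2, M = 50, n_source = 10, seed = 25)
  params <- hmm_params(matrix(0.4, 1, 50), q = 1, tau = 12)
  tr <- decode_ancestry(sim$panel, params)
  expect_true(all(tr$labels == 1L))
  expect_true(all(tr$posteriors == 1))
})

test_that("decoding is deterministic and reasonably accurate at scale", {
  sim <- tiny_admixture(n_ind = 12, M = 20000, n_source = 120, fst = 0.15,
                        founder_frac = 1, seed = 26)
  params <- estimate_hmm_params(sim$ref_panel, sim$ref_sets, tau = 12)
  tr1 <- decode_ancestry(sim$panel, params, store_posteriors = FALSE)
  tr2 <- decode_ancestry(sim$panel, params, store_posteriors = FALSE)
  expect_identical(tr1$labels, tr2$labels)
  # short foreign segments below the per-marker information content are
  # undetectable at this marker density, bounding accuracy near ~90%
  expect_lt(mean(tr1$labels != sim$track$labels), 0.12)
})

test_that("label error decreases with source differentiation", {
  errs <- matrix(NA_real_, 3, 10)
  fsts <- c(0.02, 0.05, 0.15)
  for (i in 1:3) for (s in 1:10) {
    sim <- tiny_admixture(n_ind = 6, M = 2000, n_source = 80, fst = fsts[i],
                          seed = 400 + 20 * i + s)
    params <- estimate_hmm_params(sim$ref_panel, sim$ref_sets, tau = 12)
    tr <- decode_ancestry(sim$panel, params, store_posteriors = FALSE)
    errs[i, s] <- mean(tr$labels != sim$track$labels)
  }
  m <- rowMeans(errs)
  expect_true(m[1] >= m[2] && m[2] >= m[3])
  # paired one-sided tests across seeds
  expect_lt(wilcox.test(errs[1, ], errs[3, ], paired = TRUE,
                        alternative = "greater")$p.value, 0.05)
})

test_that("reference refinement cleans contaminated panels", {
  set.seed(27)
  grid <- simulate_marker_grid(3000)
  fr <- draw_population_freqs(grid$p_anc, 0.5, K = 2, seed = 28)
  pans <- simulate_source_haplotypes(fr, 60, grid$markers, founder_frac = 1,
                                     seed = 29)
  clean <- haplotype_panel(rbind(pans[[1]]$alleles, pans[[2]]$alleles),
                           grid$markers, paste0("r", 1:60))
  # clean, strongly differentiated references: nothing is reassigned, so the
  # procedure stops after one pass with the plain empirical frequencies
  ref <- refine_reference_panel(clean, list(1:30, 31:60), tau = 12)
  expect_equal(attr(ref, "iterations"), 1L)
  direct <- estimate_hmm_params(clean, list(1:30, 31:60))
  expect_lt(max(abs(ref$ref_freqs - direct$ref_freqs)), 0.02)
  # contaminated pop-1 references: refinement moves frequencies toward truth
  tr_ref <- ancestry_track(matrix(1L, 60, 3000), c("a1", "a2"))
  cor_tr <- corrupt_ancestry_labels(tr_ref, 0.10, markers = grid$markers,
                                    seed = 30)
  planted <- ifelse(cor_tr$labels == 2L, pans[[2]]$alleles,
                    pans[[1]]$alleles)
  big <- haplotype_panel(rbind(planted, pans[[2]]$alleles), grid$markers,
                         paste0("q", 1:60))
  truth1 <- colMeans(pans[[1]]$alleles)
  unref <- estimate_hmm_params(big, list(1:30, 31:60))
  refp <- refine_reference_panel(big, list(1:30, 31:60), tau = 12)
  l2 <- function(a) sqrt(mean((a - truth1)^2))
  expect_lt(l2(refp$ref_freqs[1, ]), l2(unref$ref_freqs[1, ]))
  expect_error(refine_reference_panel(clean, list(integer(0), 31:60)),
               "empty")
})

test_that("global ancestry averages local posteriors correctly", {
  # uniform posteriors give 1/K
  post <- array(1 / 3, c(4, 20, 3))
  lab <- matrix(1L, 4, 20)
  tr <- ancestry_track(lab, c("a", "b", "c"), posteriors = post)
  ga <- global_ancestry_from_local(tr)
  expect_equal(unname(ga), matrix(1 / 3, 2, 3))
  # simulated cohort: correlation with the drawn proportions exceeds 0.99
  set.seed(31)
  grid <- simulate_marker_grid(4000)
  fr <- draw_population_freqs(grid$p_anc, 0.15, K = 2, seed = 32)
  pans <- simulate_source_haplotypes(fr, 100, grid$markers, seed = 33)
  cfg <- sim_config(K = 2, M = 4000, n_ind = 25, T_gen = 12,
                    z_dist = function(n) runif(n, 0.1, 0.9), seed = 34)
  sim <- simulate_admixed_cohort(cfg, pans, grid$markers)
  refp <- haplotype_panel(rbind(pans[[1]]$alleles, pans[[2]]$alleles),
                          grid$markers, paste0("r", 1:100))
  params <- estimate_hmm_params(refp, list(1:50, 51:100), tau = 12)
  dec <- decode_ancestry(sim$panel, params, store_posteriors = FALSE)
  ga2 <- global_ancestry_from_local(dec)
  expect_gt(cor(ga2[, 1], sim$z[, 1]), 0.99)
  expect_lt(max(abs(rowSums(ga2) - 1)), 1e-8)
  # single-ancestry individual: unit vector
  post1 <- array(0, c(2, 20, 2)); post1[, , 1] <- 1
  tr1 <- ancestry_track(matrix(1L, 2, 20), c("a", "b"), posteriors = post1)
  expect_equal(unname(global_ancestry_from_local(tr1)), cbind(1, 0))
})

test_that("ancestry deviation scan flags planted shifts and nothing else", {
  set.seed(35)
  grid <- simulate_marker_grid(4000)
  z <- runif(60, 0.3, 0.7)
  tr <- simulate_ancestry_tracks(grid$markers, cbind(z, 1 - z), 12, seed = 36)
  dev0 <- ancestry_deviation_scan(tr)
  expect_lt(length(dev0$flagged[[1]]) / 4000, 0.001)
  expect_equal(mean(dev0$locus_mean[, 1]), dev0$genome_mean[1])
  # plant a post-admixture shift: force ancestry 1 in a 1-cM window for
  # a subset of haplotypes
  mk <- grid$markers
  on_ch <- which(mk$chrom == "chr2")
  ctr <- mk$pos_cm[on_ch[round(length(on_ch) / 2)]]
  win <- on_ch[abs(mk$pos_cm[on_ch] - ctr) <= 0.5]
  lab <- tr$labels
  rows <- sample(nrow(lab), round(0.35 * nrow(lab)))
  lab[rows, win] <- 1L
  dev1 <- ancestry_deviation_scan(ancestry_track(lab, tr$ancestry_names))
  expect_true(any(win %in% dev1$flagged[[1]]))
  # degenerate input: identical tracks have zero betweem-locus SD
  same <- ancestry_track(matrix(1L, 6, 100), c("a", "b"))
  devs <- ancestry_deviation_scan(same)
  expect_equal(length(devs$flagged[[1]]), 0L)
  expect_true(all(is.na(devs$z[, 1])))
})
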