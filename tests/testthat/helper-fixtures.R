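# small deterministic fixtures shared across test files

tiny_markers <- function(pos_bp, chrom = "chr1", pos_cm = pos_bp / 1e6) {
  marker_info(chrom = chrom, pos_bp = pos_bp, pos_cm = pos_cm)
}

# a complete two-population reference panel plus an admixed cohort, small
# enough for fast tests; returns sources, cohort panel, truth track
tiny_admixture <- function(n_ind = 10, M = 1500, n_source = 80, fst = 0.15,
                           T_gen = 12, z = 0.5, founder_frac = 0.25,
                           seed = 1) {
  set.seed(seed)
  grid <- simulate_marker_grid(M)
  fr <- draw_population_freqs(grid$p_anc, fst, K = 2)
  pans <- simulate_source_haplotypes(fr, n_source, grid$markers,
                                     founder_frac = founder_frac)
  cfg <- sim_config(K = 2, fst = fst, M = M, n_ind = n_ind, T_gen = T_gen,
                    z_dist = z, seed = seed)
  sim <- simulate_admixed_cohort(cfg, pans, grid$markers, seed = seed + 1)
  ref_panel <- haplotype_panel(rbind(pans[[1]]$alleles, pans[[2]]$alleles),
                               grid$markers,
                               paste0("ref", seq_len(n_source)))
  list(markers = grid$markers, freqs = fr, sources = pans,
       ref_panel = ref_panel,
       ref_sets = list(seq_len(n_source / 2),
                       n_source / 2 + seq_len(n_source / 2)),
       panel = sim$panel, track = sim$track, z = sim$z)
}

# direct-counting r^2 between two marker columns of a haplotype matrix
r2_count <- function(x, y) {
  pAB <- mean(x == 1 & y == 1)
  pA <- mean(x == 1)
  pB <- mean(y == 1)
  D <- pAB - pA * pB
  denom <- pA * (1 - pA) * pB * (1 - pB)
  if (denom == 0) return(NA_real_)
  D^2 / denom
}

# brute-force HMM likelihood: sum over all K^M hidden paths
brute_loglik <- function(alle_row, params, markers) {
  K <- params$K
  M <- length(alle_row)
  q <- if (is.matrix(params$q)) params$q[1, ] else params$q
  chr_first <- c(TRUE, markers$chrom[-1] != markers$chrom[-M])
  d_mo <- c(0, diff(markers$pos_cm)) / 100
  stay <- exp(-params$tau * pmax(d_mo, 0))
  stay[chr_first] <- 0
  emis <- function(k, m, prev) {
    f <- if (params$markov_order == 1 && !chr_first[m])
      params$cond_freqs[k, m, 1 + prev] else params$ref_freqs[k, m]
    if (alle_row[m] == 1) f else 1 - f
  }
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), M)))
  tot <- 0
  for (i in seq_len(nrow(paths))) {
    p <- q[paths[i, 1]] * emis(paths[i, 1], 1, 0)
    for (m in 2:M) {
      s <- stay[m]
      tr <- s * (paths[i, m] == paths[i, m - 1]) + (1 - s) * q[paths[i, m]]
      p <- p * tr * emis(paths[i, m], m, alle_row[m - 1])
    }
    tot <- tot + p
  }
  log(tot)
}

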