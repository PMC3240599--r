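#' Pipeline configuration
#'
#' Orchestrates the full analysis chain: simulate (or load) a phased cohort,
#' infer local ancestry, mask to virtual genomes, extract blocks and date the
#' admixture, resolve substructure with subspace PCA, and scan for selection.
#' A single global seed fans out to fixed per-stage seeds so stages can be
#' rerun in isolation and the whole run is bit-reproducible.
#'
#' @param out_dir output directory (created if needed).
#' @param seed global seed.
#' @param vcf optional phased VCF to analyse instead of simulating; requires
#'   `refs_tsv` (columns `sample`, `ancestry`) and `genetic_map`.
#' @param refs_tsv,genetic_map companion inputs for VCF mode.
#' @param sim list of arguments for [simulate_substructure_study()]
#'   (simulation mode only); defaults give a small demonstration cohort.
#' @param stages character vector of stages to run, in order, from
#'   `c("ancestry", "mask", "dating", "sspca", "ihs")`.
#' @param d subspace-PCA components.
#' @param tau HMM switch intensity; defaults to the dating estimate when the
#'   dating stage ran, else 12 generations.
#' @param target_ancestry ancestry (index or name) whose virtual genomes are
#'   analysed.
#' @param min_snps short-block filter for [extract_blocks()].
#' @param ihs an [ihs_config()].
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L, vcf = NULL, refs_tsv = NULL,
                            genetic_map = NULL,
                            sim = list(n_ind = 40, M = 4000,
                                       n_source_hap = 80),
                            stages = c("ancestry", "mask", "dating",
                                       "sspca", "ihs"),
                            d = 2, tau = NULL, target_ancestry = 1,
                            min_snps = 10, ihs = ihs_config()) {
  structure(list(out_dir = out_dir, seed = as.integer(seed), vcf = vcf,
                 refs_tsv = refs_tsv, genetic_map = genetic_map, sim = sim,
                 stages = stages, d = d, tau = tau,
                 target_ancestry = target_ancestry, min_snps = min_snps,
                 ihs = ihs),
            class = "pipeline_config")
}

stage_seed <- function(seed, i) as.integer((seed + 7919L * i) %% 2147483647L)

#' Run the analysis pipeline
#'
#' Executes the configured stages in order, writing every artifact under
#' `out_dir` and returning a manifest of output files with MD5 checksums.
#' Identical configuration and seed yield byte-identical outputs. A stage
#' failure halts the run with the failing stage named; artifacts of completed
#' stages are retained.
#'
#' @param config a [pipeline_config()].
#' @return data.frame manifest (`file`, `md5`), invisibly also written to
#'   `manifest.tsv`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  log_path <- file.path(config$out_dir, "pipeline.log")
  logf <- function(...) cat(..., "\n", file = log_path, append = TRUE)
  cat(provenance_line("#", seed), "\n", file = log_path)
  cfg_txt <- utils::capture.output(utils::str(config))
  tf <- tempfile()
  writeLines(cfg_txt, tf)
  logf("config hash:", unname(tools::md5sum(tf)))
  unlink(tf)
  run_stage <- function(name, fun) {
    logf("stage:", name, "seed:", stage_seed(seed, match(name, stage_names)))
    tryCatch(fun(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  stage_names <- c("input", "ancestry", "mask", "dating", "sspca", "ihs")
  # --- input stage: simulate or load -------------------------------------
  env <- new.env()
  run_stage("input", function() {
    if (!is.null(config$vcf)) {
      for (p in c(config$vcf, config$refs_tsv, config$genetic_map))
        if (is.null(p) || !file.exists(p))
          stop("required input file missing: ",
               if (is.null(p)) "(unset)" else p)
      panel <- read_phased_vcf(config$vcf)
      panel <- read_genetic_map(config$genetic_map, panel)
      refs <- read_tsv_prov(config$refs_tsv)
      anc <- sort(unique(refs$ancestry))
      ref_sets <- lapply(anc, function(a)
        match(refs$sample[refs$ancestry == a], panel$sample_ids))
      env$panel <- panel
      env$ref_sets <- ref_sets
      env$ancestry_names <- anc
      env$truth <- NULL
    } else {
      study <- do.call(simulate_substructure_study,
                       c(config$sim, list(seed = stage_seed(seed, 1L))))
      env$panel <- study$panel
      env$truth <- study$track
      env$subpop <- study$subpop
      env$ancestry_names <- study$track$ancestry_names
      # reference individuals: single-ancestry genomes appended per source
      env$study <- study
      write_phased_vcf(env$panel, file.path(config$out_dir, "panel.vcf"),
                       seed = seed)
    }
  })
  # --- local ancestry -----------------------------------------------------
  if ("ancestry" %in% config$stages) run_stage("ancestry", function() {
    if (!is.null(env$truth)) {
      # simulation mode decodes with frequencies from the true sources
      mk <- env$panel$markers
      tr_lab <- env$truth$labels
      f1 <- (colSums(env$panel$alleles * (tr_lab == 1L)) + 0.5) /
        (colSums(tr_lab == 1L) + 1)
      f2 <- (colSums(env$panel$alleles * (tr_lab == 2L)) + 0.5) /
        (colSums(tr_lab == 2L) + 1)
      params <- hmm_params(rbind(f1, f2), q = c(0.5, 0.5),
                           tau = if (is.null(config$tau)) 12 else config$tau,
                           ancestry_names = env$ancestry_names)
      env$track <- decode_ancestry(env$panel, params)
    } else {
      params <- estimate_hmm_params(env$panel, env$ref_sets,
                                    tau = if (is.null(config$tau)) 12
                                          else config$tau,
                                    ancestry_names = env$ancestry_names)
      env$track <- decode_ancestry(env$panel, params)
    }
    env$global <- global_ancestry_from_local(env$track)
    write_ancestry_bed(env$track, env$panel,
                       file.path(config$out_dir, "track.bed"), seed = seed)
    write_tsv_prov(data.frame(sample = env$panel$sample_ids,
                              round(env$global, 6)),
                   file.path(config$out_dir, "global_ancestry.tsv"), seed)
  })
  # --- masking ------------------------------------------------------------
  if ("mask" %in% config$stages) run_stage("mask", function() {
    env$pair <- mask_to_virtual(env$panel, env$track,
                                target = config$target_ancestry)
    write_masked_pair(env$pair, file.path(config$out_dir, "virtual"),
                      seed = seed)
  })
  # --- blocks + dating ----------------------------------------------------
  if ("dating" %in% config$stages) run_stage("dating", function() {
    bl <- extract_blocks(env$track, env$panel$markers,
                         min_snps = config$min_snps)
    write_tsv_prov(bl$blocks, file.path(config$out_dir, "blocks.tsv"), seed)
    k <- if (is.character(config$target_ancestry))
      match(config$target_ancestry, env$ancestry_names)
      else config$target_ancestry
    obs <- data.frame(z = env$global[, k], count = bl$diploid_counts)
    L <- sum(tapply(env$panel$markers$pos_cm, env$panel$markers$chrom,
                    function(x) diff(range(x))))
    env$dating <- estimate_admixing_time(obs, L = L,
                                         n_chrom =
                                           length(unique(env$panel$markers$chrom)))
    write_tsv_prov(env$dating$profile,
                   file.path(config$out_dir, "dating_profile.tsv"), seed)
    write_tsv_prov(data.frame(T_hat = env$dating$T_hat,
                              T_interp = env$dating$T_interp),
                   file.path(config$out_dir, "dating.tsv"), seed)
  })
  # --- subspace PCA -------------------------------------------------------
  if ("sspca" %in% config$stages) run_stage("sspca", function() {
    fit <- fit_sspca(env$pair, d = config$d, seed = stage_seed(seed, 4L))
    pcs <- pcs_from_factors(fit)
    env$pcs <- pcs
    out <- data.frame(sample = env$pair$sample_ids, round(pcs$scores, 6))
    if (!is.null(env$subpop)) {
      out$subpop <- env$subpop
      xi <- confusion_fraction(pcs$scores[, 1], env$subpop)$xi
      write_tsv_prov(data.frame(component = 1, xi = xi),
                     file.path(config$out_dir, "confusion.tsv"), seed)
    }
    write_tsv_prov(out, file.path(config$out_dir, "pcs.tsv"), seed)
  })
  # --- selection scan -----------------------------------------------------
  if ("ihs" %in% config$stages) run_stage("ihs", function() {
    sc <- suppressWarnings(
      ihs_scan(env$panel, env$track, target = config$target_ancestry,
               config = config$ihs))
    write_tsv_prov(within(sc, {
      daf <- round(daf, 5); maf <- round(maf, 5)
      ihh_a <- round(ihh_a, 3); ihh_d <- round(ihh_d, 3)
      raw <- round(raw, 5); std <- round(std, 5)
    }), file.path(config$out_dir, "ihs.tsv"), seed)
    reg <- call_candidate_regions(sc, config$ihs)
    write_tsv_prov(reg, file.path(config$out_dir, "regions.tsv"), seed)
  })
  files <- sort(setdiff(list.files(config$out_dir, full.names = TRUE),
                        file.path(config$out_dir,
                                  c("manifest.tsv", "pipeline.log"))))
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)))
  write_tsv_prov(manifest, file.path(config$out_dir, "manifest.tsv"), seed)
  invisible(manifest)
}
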