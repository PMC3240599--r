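#' Construct a marker metadata table
#'
#' Builds and validates the per-SNP metadata used throughout the package:
#' chromosome, 1-based physical position, genetic position in centiMorgans,
#' alleles, and a flag stating whether the reference allele is the ancestral
#' allele (needed by the selection scan to orient derived-allele frequencies).
#'
#' @param chrom chromosome identifier (character or integer vector).
#' @param pos_bp integer base-pair position, 1-based, strictly increasing
#'   within each chromosome.
#' @param pos_cm genetic position in centiMorgans, non-decreasing within each
#'   chromosome. May be `NA` and filled later with [read_genetic_map()].
#' @param ref_allele,alt_allele nucleotide symbols; must differ at every site.
#' @param ancestral_is_ref logical; `TRUE` where the reference allele is
#'   ancestral (default `TRUE`).
#' @param id optional marker identifiers; autogenerated when missing.
#' @return a `data.frame` with one row per marker.
#' @export
marker_info <- function(chrom, pos_bp, pos_cm = NA_real_, ref_allele = "A",
                        alt_allele = "G", ancestral_is_ref = TRUE, id = NULL) {
  m <- length(pos_bp)
  mk <- data.frame(
    id = if (is.null(id)) paste0("snp", seq_len(m)) else as.character(id),
    chrom = as.character(rep_len(chrom, m)),
    pos_bp = as.integer(pos_bp),
    pos_cm = as.numeric(rep_len(pos_cm, m)),
    ref_allele = rep_len(ref_allele, m),
    alt_allele = rep_len(alt_allele, m),
    ancestral_is_ref = rep_len(as.logical(ancestral_is_ref), m),
    stringsAsFactors = FALSE
  )
  validate_markers(mk)
  mk
}

validate_markers <- function(mk) {
  stopifnot(is.data.frame(mk))
  need <- c("chrom", "pos_bp", "pos_cm", "ref_allele", "alt_allele",
            "ancestral_is_ref")
  miss <- setdiff(need, names(mk))
  if (length(miss)) stop("marker table lacks columns: ",
                         paste(miss, collapse = ", "))
  if (any(mk$ref_allele == mk$alt_allele))
    stop("ref_allele equals alt_allele at ",
         sum(mk$ref_allele == mk$alt_allele), " marker(s)")
  for (ch in unique(mk$chrom)) {
    i <- mk$chrom == ch
    if (is.unsorted(mk$pos_bp[i], strictly = TRUE))
      stop("pos_bp not strictly increasing on chromosome ", ch)
    cm <- mk$pos_cm[i]
    if (!anyNA(cm) && is.unsorted(cm))
      stop("pos_cm decreasing on chromosome ", ch)
  }
  invisible(mk)
}

#' Construct a phased haplotype panel
#'
#' The substrate for every stage of the pipeline: a complete (no missing
#' entries) 0/1 allele matrix over `2N` haplotypes by `M` markers, plus marker
#' metadata. Haplotype rows `2n - 1` and `2n` belong to individual `n`.
#'
#' @param alleles integer matrix in \{0, 1\}, `2N x M`, no `NA`: missingness is
#'   introduced only later, by ancestry masking.
#' @param markers marker metadata as produced by [marker_info()].
#' @param sample_ids `N` individual identifiers.
#' @param populations optional per-individual population label.
#' @return an object of class `haplotype_panel`.
#' @export
haplotype_panel <- function(alleles, markers, sample_ids, populations = NULL) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  validate_markers(markers)
  if (anyNA(alleles))
    stop("haplotype panel must be complete; found NA alleles")
  if (!all(alleles == 0L | alleles == 1L))
    stop("alleles must be 0/1 (biallelic, phased)")
  if (ncol(alleles) != nrow(markers))
    stop("allele matrix has ", ncol(alleles), " columns but ",
         nrow(markers), " markers")
  if (nrow(alleles) != 2L * length(sample_ids))
    stop("allele matrix has ", nrow(alleles),
         " rows; expected 2 x ", length(sample_ids), " haplotypes")
  if (!is.null(populations) && length(populations) != length(sample_ids))
    stop("populations must have one label per sample")
  structure(list(alleles = alleles, markers = markers,
                 sample_ids = as.character(sample_ids),
                 populations = populations),
            class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat("haplotype_panel:", length(x$sample_ids), "individuals (",
      nrow(x$alleles), "haplotypes ) x", ncol(x$alleles), "markers on",
      length(unique(x$markers$chrom)), "chromosome(s)\n")
  if (!is.null(x$populations))
    cat("  populations:",
        paste(names(table(x$populations)), table(x$populations),
              sep = "=", collapse = ", "), "\n")
  invisible(x)
}

n_ind <- function(panel) length(panel$sample_ids)
n_hap <- function(panel) nrow(panel$alleles)
n_mark <- function(panel) ncol(panel$alleles)

#' Haplotype row indices of an individual
#'
#' @param n individual index (1-based).
#' @return the two haplotype row indices `c(2n - 1, 2n)`.
#' @export
hap_rows <- function(n) {
  n <- as.integer(n)
  c(2L * n - 1L, 2L * n)
}

#' Construct an ancestry track
#'
#' Per-haplotype, per-marker ancestry assignment: hard labels (1..K, `NA` for
#' masked/missing) and, optionally, posterior probabilities. When both are
#' present the labels must be the posterior argmax.
#'
#' @param labels integer matrix `2N x M` with entries in `1..K` or `NA`.
#' @param ancestry_names `K` ancestry names.
#' @param posteriors optional `2N x M x K` array; rows sum to 1 at each cell.
#' @return an object of class `ancestry_track`.
#' @export
ancestry_track <- function(labels, ancestry_names, posteriors = NULL) {
  labels <- as.matrix(labels)
  storage.mode(labels) <- "integer"
  K <- length(ancestry_names)
  ok <- is.na(labels) | (labels >= 1L & labels <= K)
  if (!all(ok)) stop("labels must lie in 1..K or be NA")
  if (!is.null(posteriors)) {
    stopifnot(length(dim(posteriors)) == 3L,
              dim(posteriors)[1] == nrow(labels),
              dim(posteriors)[2] == ncol(labels),
              dim(posteriors)[3] == K)
    s <- matrix(0, nrow(labels), ncol(labels))
    for (k in seq_len(K)) s <- s + posteriors[, , k]
    if (max(abs(s - 1)) > 1e-8)
      stop("posteriors do not sum to 1 (max deviation ",
           format(max(abs(s - 1))), ")")
    best <- posteriors[, , 1]
    am <- matrix(1L, nrow(labels), ncol(labels))
    for (k in seq_len(K)[-1]) {
      hit <- posteriors[, , k] > best
      best[hit] <- posteriors[, , k][hit]
      am[hit] <- k
    }
    post_lab <- posteriors[cbind(as.vector(row(labels)),
                                 as.vector(col(labels)),
                                 as.vector(labels))]
    bad <- !is.na(labels) &
      matrix(post_lab, nrow(labels)) < best - 1e-12
    if (any(bad)) stop("labels disagree with posterior argmax at ",
                       sum(bad), " cell(s)")
  }
  structure(list(labels = labels, posteriors = posteriors,
                 K = K, ancestry_names = as.character(ancestry_names)),
            class = "ancestry_track")
}

#' @export
print.ancestry_track <- function(x, ...) {
  cat("ancestry_track:", nrow(x$labels), "haplotypes x", ncol(x$labels),
      "markers, K =", x$K,
      "(", paste(x$ancestry_names, collapse = ", "), ")\n")
  cat("  posteriors:", if (is.null(x$posteriors)) "absent" else "present",
      "; labelled cells:",
      sprintf("%.1f%%", 100 * mean(!is.na(x$labels))), "\n")
  invisible(x)
}
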