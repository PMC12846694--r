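# Marker/sample/breed quality control and the autosomal span L_AUTO.

#' Quality-control parameters
#'
#' Defaults match the conventional 50K-array filtering for multi-breed ROH
#' panels: MAF >= 0.05, SNP call rate >= 90%, sample missingness <= 10%,
#' breeds with fewer than five genotyped individuals dropped. Heterozygosity
#' outliers are flagged (never removed) beyond `het_outlier_sd` standard
#' deviations from the panel mean.
#'
#' @param maf_min Minimum minor allele frequency (markers below are removed).
#' @param snp_call_rate_min Minimum per-marker call rate.
#' @param sample_missing_max Maximum per-sample missing-call fraction.
#' @param breed_min_n Minimum post-filter individuals per breed.
#' @param het_outlier_sd Standard-deviation multiple for heterozygosity flags.
#' @return A list of class `qc_params`.
#' @export
qc_params <- function(maf_min = 0.05, snp_call_rate_min = 0.90,
                      sample_missing_max = 0.10, breed_min_n = 5L,
                      het_outlier_sd = 3) {
  stopifnot(maf_min >= 0, maf_min <= 1,
            snp_call_rate_min >= 0, snp_call_rate_min <= 1,
            sample_missing_max >= 0, sample_missing_max <= 1,
            breed_min_n >= 1, het_outlier_sd > 0)
  structure(list(maf_min = maf_min, snp_call_rate_min = snp_call_rate_min,
                 sample_missing_max = sample_missing_max,
                 breed_min_n = as.integer(breed_min_n),
                 het_outlier_sd = het_outlier_sd),
            class = "qc_params")
}

#' Apply marker, sample and breed quality-control filters
#'
#' Filters are applied in a fixed, documented order: (1) samples above the
#' missingness ceiling, (2) markers below the call-rate floor, (3) markers
#' below the MAF floor (computed on non-missing calls of the retained
#' samples), (4) breeds left with fewer than `breed_min_n` individuals.
#' PLINK applies its sample and marker filters jointly, so counts can differ
#' from PLINK on boundary cases. Heterozygosity outliers are flagged in the
#' report but never removed.
#'
#' @param geno Integer genotype matrix (0/1/2/NA), samples x markers.
#' @param map Marker map data.frame (snp, chr, pos).
#' @param samples Sample table data.frame with at least `sample` and `breed`.
#' @param params A [qc_params()] object.
#' @return A list: `geno`, `map`, `samples` (filtered), and `report` — a list
#'   with removal counts per filter, flagged samples, final dimensions and
#'   `l_auto_bp` computed on the retained markers.
#' @export
apply_qc <- function(geno, map, samples, params = qc_params()) {
  validate_marker_map(map); validate_genotypes(geno, map)
  stopifnot(inherits(params, "qc_params"))
  samples <- samples[match(rownames(geno), samples$sample), , drop = FALSE]
  if (anyNA(samples$sample)) stop("samples table does not cover all genotypes")

  n_snps0 <- ncol(geno)

  # 1) sample missingness
  miss_rate <- rowMeans(is.na(geno))
  keep_s <- miss_rate <= params$sample_missing_max
  samples_removed_missing <- sum(!keep_s)
  geno <- geno[keep_s, , drop = FALSE]
  samples <- samples[keep_s, , drop = FALSE]
  if (nrow(geno) == 0L) stop("empty after QC: all samples removed")

  # 2) SNP call rate
  call_rate <- colMeans(!is.na(geno))
  keep_cr <- call_rate >= params$snp_call_rate_min
  snps_removed_callrate <- sum(!keep_cr)
  geno <- geno[, keep_cr, drop = FALSE]
  map <- map[keep_cr, , drop = FALSE]

  # 3) MAF on non-missing calls
  if (ncol(geno)) {
    p_alt <- colMeans(geno, na.rm = TRUE) / 2
    maf <- pmin(p_alt, 1 - p_alt)
    maf[is.nan(maf)] <- 0
    keep_maf <- maf >= params$maf_min
  } else {
    keep_maf <- logical(0)
  }
  snps_removed_maf <- sum(!keep_maf)
  geno <- geno[, keep_maf, drop = FALSE]
  map <- map[keep_maf, , drop = FALSE]
  if (ncol(geno) == 0L) stop("empty after QC: all markers removed")

  # 4) breed size
  tab <- table(samples$breed)
  small <- names(tab)[tab < params$breed_min_n]
  keep_b <- !(samples$breed %in% small)
  geno <- geno[keep_b, , drop = FALSE]
  samples <- samples[keep_b, , drop = FALSE]
  if (nrow(geno) == 0L) stop("empty after QC: all samples removed")

  het <- individual_heterozygosity(geno, het_outlier_sd = params$het_outlier_sd)
  rownames(map) <- NULL

  report <- list(
    snps_removed_maf = snps_removed_maf,
    snps_removed_callrate = snps_removed_callrate,
    samples_removed_missing = samples_removed_missing,
    breeds_removed = small,
    het_flagged = het$sample[het$flagged],
    n_samples_final = nrow(geno),
    n_snps_final = ncol(geno),
    l_auto_bp = compute_l_auto(map))
  stopifnot(report$n_snps_final ==
              n_snps0 - snps_removed_callrate - snps_removed_maf)
  list(geno = geno, map = map, samples = samples, report = report)
}

#' Autosomal span covered by the marker panel
#'
#' L_AUTO is the sum over chromosomes of the physical range covered by the
#' retained markers, last minus first position plus one (1-based inclusive).
#' It is the denominator of the genomic inbreeding coefficient FROH.
#'
#' @param map Marker map data.frame (snp, chr, pos), non-empty.
#' @return Total span in base pairs (double, to avoid integer overflow).
#' @export
compute_l_auto <- function(map) {
  if (nrow(map) == 0L) stop("compute_l_auto: empty marker map")
  spans <- tapply(as.numeric(map$pos), map$chr,
                  function(p) max(p) - min(p) + 1)
  sum(spans)
}

#' Per-individual heterozygosity
#'
#' het_rate = heterozygous calls / non-missing calls. Samples whose rate lies
#' beyond `het_outlier_sd` standard deviations from the panel mean are
#' flagged; a sample with zero non-missing calls has an undefined (NA) rate
#' and is always flagged. Flagging is advisory: no sample is removed.
#'
#' @param geno Integer genotype matrix (0/1/2/NA).
#' @param het_outlier_sd Standard-deviation multiple for the flag.
#' @return data.frame(sample, het_rate, flagged).
#' @export
individual_heterozygosity <- function(geno, het_outlier_sd = 3) {
  if (nrow(geno) == 0L) stop("individual_heterozygosity: no samples")
  n_nonmiss <- rowSums(!is.na(geno))
  n_het <- rowSums(geno == 1L, na.rm = TRUE)
  het_rate <- ifelse(n_nonmiss > 0, n_het / n_nonmiss, NA_real_)
  ok <- !is.na(het_rate)
  mu <- mean(het_rate[ok])
  sdev <- stats::sd(het_rate[ok])
  flagged <- !ok
  if (sum(ok) > 1L && sdev > 0) {
    flagged[ok] <- abs(het_rate[ok] - mu) > het_outlier_sd * sdev
  }
  ids <- rownames(geno)
  if (is.null(ids)) ids <- paste0("S", seq_len(nrow(geno)))
  data.frame(sample = ids, het_rate = het_rate, flagged = flagged,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write a QC report as TSV plus a readable log
#'
#' @param report Report list from [apply_qc()].
#' @param out_prefix Writes `<out_prefix>.tsv` and `<out_prefix>.log`.
#' @return The prefix, invisibly.
#' @export
write_qc_report <- function(report, out_prefix) {
  flat <- data.frame(
    metric = c("snps_removed_maf", "snps_removed_callrate",
               "samples_removed_missing", "breeds_removed", "het_flagged",
               "n_samples_final", "n_snps_final", "l_auto_bp"),
    value = c(report$snps_removed_maf, report$snps_removed_callrate,
              report$samples_removed_missing,
              paste(report$breeds_removed, collapse = ","),
              paste(report$het_flagged, collapse = ","),
              report$n_samples_final, report$n_snps_final,
              format(report$l_auto_bp, scientific = FALSE)))
  utils::write.table(flat, paste0(out_prefix, ".tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  log <- c(
    sprintf("Markers removed for MAF: %d", report$snps_removed_maf),
    sprintf("Markers removed for call rate: %d", report$snps_removed_callrate),
    sprintf("Samples removed for missingness: %d",
            report$samples_removed_missing),
    sprintf("Breeds removed (<min individuals): %s",
            if (length(report$breeds_removed))
              paste(report$breeds_removed, collapse = ", ") else "none"),
    sprintf("Heterozygosity-flagged samples (advisory): %s",
            if (length(report$het_flagged))
              paste(report$het_flagged, collapse = ", ") else "none"),
    sprintf("Final panel: %d samples x %d markers",
            report$n_samples_final, report$n_snps_final),
    sprintf("L_AUTO (bp): %s", format(report$l_auto_bp, scientific = FALSE)))
  writeLines(log, paste0(out_prefix, ".log"))
  invisible(out_prefix)
}
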