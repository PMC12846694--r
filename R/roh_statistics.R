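# Descriptive ROH statistics: length classes, per-individual FROH, per-breed
# summaries, chromosome distributions.

#' ROH length-class labels, shortest to longest
#' @export
ROH_CLASSES <- c("1-5", "5-10", "10-20", "20-40", ">40")

#' Classify a ROH length into the five standard Mb classes
#'
#' Bins are half-open with boundaries assigned upward: \[1,5), \[5,10),
#' \[10,20), \[20,40), \[40, Inf) Mb, so a segment of exactly 5 Mb falls in
#' "5-10".
#'
#' @param length_bp Segment length(s) in bp, each >= 1 Mb.
#' @return Character vector of class labels (levels of [ROH_CLASSES]).
#' @export
classify_length <- function(length_bp) {
  if (any(length_bp < 1e6)) {
    stop("classify_length: ROH shorter than 1 Mb violates the calling contract")
  }
  mb <- length_bp / 1e6
  ROH_CLASSES[findInterval(mb, c(1, 5, 10, 20, 40))]
}

#' Per-individual ROH summary and genomic inbreeding coefficient
#'
#' FROH = L_ROH / L_AUTO: the summed length of the individual's ROH divided
#' by the autosomal span covered by the marker panel. An individual with no
#' segments has n_segments 0 and FROH 0.
#'
#' @param segments ROH data.frame (one sample's rows, or empty).
#' @param l_auto_bp Autosomal span from [compute_l_auto()], > 0.
#' @param sample Sample identifier (required when `segments` is empty).
#' @return One-row data.frame: sample, n_segments, total_length_bp,
#'   mean_length_mb, f_roh.
#' @export
summarize_individual <- function(segments, l_auto_bp, sample = NULL) {
  if (l_auto_bp <= 0) stop("summarize_individual: l_auto_bp must be > 0")
  if (nrow(segments) == 0L) {
    if (is.null(sample)) stop("sample id required for an empty segment set")
    return(data.frame(sample = sample, n_segments = 0L, total_length_bp = 0,
                      mean_length_mb = NA_real_, f_roh = 0,
                      stringsAsFactors = FALSE))
  }
  if (length(unique(segments$sample)) != 1L) {
    stop("summarize_individual: segments must belong to a single sample")
  }
  total <- sum(segments$length_bp)
  data.frame(sample = segments$sample[1], n_segments = nrow(segments),
             total_length_bp = total,
             mean_length_mb = mean(segments$length_bp) / 1e6,
             f_roh = total / l_auto_bp, stringsAsFactors = FALSE)
}

#' Per-individual summaries for a whole panel
#'
#' Convenience wrapper: one [summarize_individual()] row per sample,
#' including zero rows for samples without any called ROH.
#'
#' @param segments ROH data.frame for the panel.
#' @param samples Sample table (sample, breed, ...).
#' @param l_auto_bp Autosomal span.
#' @return data.frame with one row per sample plus the breed column.
#' @export
summarize_individuals <- function(segments, samples, l_auto_bp) {
  rows <- lapply(samples$sample, function(id) {
    summarize_individual(segments[segments$sample == id, , drop = FALSE],
                         l_auto_bp, sample = id)
  })
  out <- do.call(rbind, rows)
  out$breed <- samples$breed[match(out$sample, samples$sample)]
  out
}

#' Per-breed ROH summary
#'
#' Aggregates individual summaries of one breed: mean +/- sample standard
#' deviation (n-1) and min-max range of segment length, segment count and
#' FROH, plus counts of segments per length class. A breed of a single
#' individual has undefined dispersion; its sd fields are reported as 0 with
#' `sd_defined = FALSE`.
#'
#' @param per_individual data.frame from [summarize_individuals()], one breed.
#' @param segments The breed's ROH segments.
#' @return One-row data.frame with summary columns and `class_*` counts.
#' @export
summarize_breed <- function(per_individual, segments) {
  if (nrow(per_individual) == 0L) stop("summarize_breed: empty breed")
  breed <- unique(per_individual$breed)
  if (length(breed) > 1L) stop("summarize_breed: multiple breeds supplied")
  if (is.null(breed)) breed <- NA_character_

  sd0 <- function(x) if (length(x) > 1L) stats::sd(x) else 0
  lens_mb <- segments$length_bp / 1e6
  cls <- if (nrow(segments)) classify_length(segments$length_bp) else character()
  counts <- table(factor(cls, levels = ROH_CLASSES))
  stopifnot(sum(counts) == nrow(segments))

  out <- data.frame(
    breed = breed,
    sample_size = nrow(per_individual),
    mean_length_mb = if (length(lens_mb)) mean(lens_mb) else NA_real_,
    sd_length_mb = sd0(lens_mb),
    min_length_mb = if (length(lens_mb)) min(lens_mb) else NA_real_,
    max_length_mb = if (length(lens_mb)) max(lens_mb) else NA_real_,
    mean_n_segments = mean(per_individual$n_segments),
    sd_n_segments = sd0(per_individual$n_segments),
    min_n_segments = min(per_individual$n_segments),
    max_n_segments = max(per_individual$n_segments),
    mean_f_roh = mean(per_individual$f_roh),
    sd_f_roh = sd0(per_individual$f_roh),
    min_f_roh = min(per_individual$f_roh),
    max_f_roh = max(per_individual$f_roh),
    sd_defined = nrow(per_individual) > 1L,
    stringsAsFactors = FALSE)
  for (k in seq_along(ROH_CLASSES)) {
    out[[paste0("class_", gsub("[->]", "_", ROH_CLASSES[k]))]] <-
      as.integer(counts[k])
  }
  out
}

#' Per-breed summaries for a whole panel
#'
#' @param per_individual data.frame from [summarize_individuals()].
#' @param segments ROH data.frame for the panel.
#' @param samples Sample table mapping sample to breed.
#' @return data.frame, one row per breed (alphabetical).
#' @export
summarize_breeds <- function(per_individual, segments, samples) {
  segments$breed <- samples$breed[match(segments$sample, samples$sample)]
  breeds <- sort(unique(per_individual$breed))
  do.call(rbind, lapply(breeds, function(b) {
    summarize_breed(per_individual[per_individual$breed == b, , drop = FALSE],
                    segments[!is.na(segments$breed) & segments$breed == b, ,
                             drop = FALSE])
  }))
}

#' Segment counts per breed and chromosome
#'
#' @param segments ROH data.frame.
#' @param samples Sample table mapping sample to breed.
#' @param chromosomes Chromosomes to tabulate (zero-filled if absent).
#' @return data.frame breed x chromosome of counts (wide, one column per
#'   chromosome named `chr<k>`).
#' @export
chromosome_distribution <- function(segments, samples,
                                    chromosomes = AUTOSOMES) {
  breeds <- sort(unique(samples$breed))
  segments$breed <- samples$breed[match(segments$sample, samples$sample)]
  tab <- table(factor(segments$breed, levels = breeds),
               factor(segments$chr, levels = chromosomes))
  out <- as.data.frame.matrix(tab)
  names(out) <- paste0("chr", chromosomes)
  cbind(data.frame(breed = breeds, stringsAsFactors = FALSE), out,
        row.names = NULL)
}

#' Aggregate per-breed length-class counts into panel totals
#'
#' Takes a table of per-breed segment counts in the five length classes
#' (columns `1-5`, `5-10`, `10-20`, `20-40`, `>40` or the `class_*` columns
#' produced by [summarize_breed()]) and returns class totals, the grand
#' total, and each class's percentage of the grand total.
#'
#' @param class_counts data.frame of per-breed counts.
#' @return list(totals = named integer vector, grand_total, percent = named
#'   numeric vector).
#' @export
aggregate_class_counts <- function(class_counts) {
  plain <- ROH_CLASSES
  coded <- paste0("class_", gsub("[->]", "_", ROH_CLASSES))
  cols <- if (all(plain %in% names(class_counts))) plain else coded
  if (!all(cols %in% names(class_counts))) {
    stop("class-count columns not found")
  }
  totals <- vapply(cols, function(cl) sum(class_counts[[cl]]), numeric(1))
  names(totals) <- plain
  grand <- sum(totals)
  list(totals = totals, grand_total = grand,
       percent = 100 * totals / grand)
}
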