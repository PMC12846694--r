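# Multi-breed SNP-panel simulator with implanted autozygous tracts and
# recorded ground truth. Background genotypes are Hardy-Weinberg draws at
# per-breed, per-marker allele frequencies; markers are independent (no
# background LD), which exercises every pipeline stage but does not imitate
# the short-ROH behavior of real, LD-structured data.

#' Sample ROH-like tract lengths
#'
#' Draws tract lengths (in Mb) from a mixture over the five standard length
#' classes with weights matching the class proportions typical of worldwide
#' 50K-array pig panels (about 8% in 1-5 Mb, 53% in 5-10, 29% in 10-20,
#' 8% in 20-40, 1% above 40), uniform within class. The shortest class is
#' truncated at 3 Mb, near the smallest segment such panels resolve.
#'
#' @param n Number of lengths to draw.
#' @return Numeric vector of lengths in Mb.
#' @export
roh_length_sampler <- function(n) {
  lo <- c(3, 5, 10, 20, 40); hi <- c(5, 10, 20, 40, 60)
  w <- c(0.084, 0.529, 0.294, 0.083, 0.010)
  cls <- sample.int(5L, n, replace = TRUE, prob = w)
  stats::runif(n, lo[cls], hi[cls])
}

#' Simulation parameters
#'
#' Defaults describe the desk-scale panel used throughout the test suite:
#' 2 chromosomes of 100 Mb carrying 2,000 evenly spaced markers each (one
#' SNP per 50 kb), 4 breeds of 15 individuals, allele frequencies uniform on
#' \[0.05, 0.5\], no missingness and no genotype error unless requested.
#'
#' @param n_chromosomes Number of autosomes to simulate.
#' @param markers_per_chromosome Evenly spaced markers per chromosome.
#' @param chromosome_length_bp Length of every chromosome in bp.
#' @param breeds Character vector of breed codes.
#' @param breed_groups Origin label per breed (African/American/Asian/
#'   European/Cosmopolitan).
#' @param individuals_per_breed Integer, recycled over breeds.
#' @param freq_range Allele-frequency range for the uniform draw.
#' @param missing_rate Per-call missingness probability (applied after tract
#'   implantation).
#' @param genotype_error_rate Per-call probability of a hom<->het flip.
#' @param tract_spec List of tract prescriptions; each element is a list with
#'   fields `breed`, `fraction` (of the breed's individuals carrying tracts),
#'   `tracts_per_carrier`, and either `length_mb` (function(n) -> Mb, default
#'   [roh_length_sampler()]) for random placement, or fixed `chr` and
#'   `start_bp` plus scalar `length_mb` to implant the same region in every
#'   carrier (planting an island).
#' @param seed Integer RNG seed; fixed seed gives bit-reproducible output.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(n_chromosomes = 2L, markers_per_chromosome = 2000L,
                       chromosome_length_bp = 1e8,
                       breeds = c("REFB", "INDA", "INDB", "COSA"),
                       breed_groups = c("American", "Asian", "European",
                                        "Cosmopolitan"),
                       individuals_per_breed = 15L,
                       freq_range = c(0.05, 0.5),
                       missing_rate = 0, genotype_error_rate = 0,
                       tract_spec = list(), seed = 1L) {
  stopifnot(n_chromosomes >= 1, n_chromosomes <= 18,
            markers_per_chromosome >= 2, chromosome_length_bp > 0,
            length(breeds) == length(breed_groups),
            missing_rate >= 0, missing_rate <= 1,
            genotype_error_rate >= 0, genotype_error_rate <= 1)
  individuals_per_breed <- rep_len(as.integer(individuals_per_breed),
                                   length(breeds))
  structure(list(
    n_chromosomes = as.integer(n_chromosomes),
    markers_per_chromosome = as.integer(markers_per_chromosome),
    chromosome_length_bp = chromosome_length_bp,
    breeds = breeds, breed_groups = breed_groups,
    individuals_per_breed = individuals_per_breed,
    freq_range = freq_range, missing_rate = missing_rate,
    genotype_error_rate = genotype_error_rate,
    tract_spec = tract_spec, seed = as.integer(seed)),
    class = "sim_params")
}

#' Simulate a multi-breed genotype panel with implanted autozygous tracts
#'
#' Background genotypes are drawn per marker under Hardy-Weinberg at the
#' breed's allele frequency. Inside each implanted tract one founder
#' haplotype is drawn at the breed frequencies and doubled, forcing
#' homozygosity at every covered marker. Missingness and genotype errors are
#' applied after implantation; the truth table records tract coordinates
#' before any noise. Random tracts of one individual are placed at least
#' 3 Mb apart so implanted segments stay distinct under downstream calling.
#'
#' @param params A [sim_params()] object.
#' @return list(geno, map, samples, truth) where `truth` is a
#'   data.frame(sample, chr, start, end, length_bp, planted) — `planted`
#'   marks fixed-position (island) tracts.
#' @export
simulate_panel <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  M <- params$markers_per_chromosome
  spacing <- params$chromosome_length_bp / M
  chrs <- seq_len(params$n_chromosomes)
  map <- do.call(rbind, lapply(chrs, function(ch) {
    pos <- as.integer(round(spacing * seq_len(M)))
    data.frame(snp = sprintf("snp%d_%d", ch, seq_len(M)), chr = ch,
               pos = pos, stringsAsFactors = FALSE)
  }))
  validate_marker_map(map)
  n_mark <- nrow(map)

  n_per <- params$individuals_per_breed
  breed_of <- rep(params$breeds, times = n_per)
  ids <- unlist(lapply(seq_along(params$breeds), function(b) {
    sprintf("%s_%02d", params$breeds[b], seq_len(n_per[b]))
  }))
  samples <- data.frame(
    sample = ids, breed = breed_of,
    group = rep(params$breed_groups, times = n_per),
    category = ifelse(rep(params$breed_groups, times = n_per) ==
                        "Cosmopolitan", "cosmopolitan", "indigenous"),
    stringsAsFactors = FALSE)

  # per-breed, per-marker allele frequencies
  freqs <- matrix(stats::runif(length(params$breeds) * n_mark,
                               params$freq_range[1], params$freq_range[2]),
                  nrow = length(params$breeds))
  geno <- matrix(NA_integer_, nrow = length(ids), ncol = n_mark,
                 dimnames = list(ids, map$snp))
  for (b in seq_along(params$breeds)) {
    rows <- which(breed_of == params$breeds[b])
    for (i in rows) {
      geno[i, ] <- stats::rbinom(n_mark, 2L, freqs[b, ])
    }
  }

  # implant tracts
  truth <- list()
  occupied <- stats::setNames(vector("list", length(ids)), ids)
  for (spec in params$tract_spec) {
    b <- spec$breed
    rows <- which(breed_of == b)
    if (!length(rows)) stop("tract_spec names unknown breed: ", b)
    n_car <- max(1L, round(spec$fraction * length(rows)))
    carriers <- sample(rows, n_car)
    per <- if (is.null(spec$tracts_per_carrier)) 1L else spec$tracts_per_carrier
    fixed <- !is.null(spec$chr)
    sampler <- if (is.function(spec$length_mb)) spec$length_mb
               else if (fixed) function(n) rep(spec$length_mb, n)
               else roh_length_sampler
    for (i in carriers) {
      for (t in seq_len(per)) {
        for (try in 1:50) {
          len <- round(sampler(1L) * 1e6)
          if (len > params$chromosome_length_bp) {
            stop("tract longer than chromosome (", len, " bp)")
          }
          if (fixed) {
            ch <- spec$chr; start <- spec$start_bp
            if (start + len - 1 > params$chromosome_length_bp) {
              stop("fixed tract exceeds chromosome bounds")
            }
          } else {
            ch <- sample(chrs, 1L)
            start <- floor(stats::runif(1, 1,
                                        params$chromosome_length_bp - len + 2))
          }
          end <- start + len - 1
          prev <- occupied[[ids[i]]]
          clash <- FALSE
          if (!is.null(prev)) {
            same <- prev[prev$chr == ch, , drop = FALSE]
            clash <- any(start <= same$end + 3e6 & end >= same$start - 3e6)
          }
          if (!clash) break
          if (try == 50L) stop("could not place tract without clashing")
        }
        occupied[[ids[i]]] <- rbind(occupied[[ids[i]]],
                                    data.frame(chr = ch, start = start,
                                               end = end))
        idx <- which(map$chr == ch & map$pos >= start & map$pos <= end)
        bi <- match(b, params$breeds)
        hap <- stats::rbinom(length(idx), 1L, freqs[bi, idx])
        geno[i, idx] <- 2L * hap
        truth[[length(truth) + 1L]] <- data.frame(
          sample = ids[i], chr = ch, start = start, end = end,
          length_bp = len, planted = fixed, stringsAsFactors = FALSE)
      }
    }
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(sample = character(), chr = integer(), start = numeric(),
               end = numeric(), length_bp = numeric(), planted = logical(),
               stringsAsFactors = FALSE)

  # noise, applied after implantation
  if (params$genotype_error_rate > 0) {
    flip <- which(stats::runif(length(geno)) < params$genotype_error_rate)
    for (k in flip) {
      geno[k] <- if (geno[k] == 1L) sample(c(0L, 2L), 1L) else 1L
    }
  }
  if (params$missing_rate > 0) {
    geno[stats::runif(length(geno)) < params$missing_rate] <- NA_integer_
  }

  list(geno = geno, map = map, samples = samples, truth = truth)
}

#' Score called segments against simulated truth
#'
#' A truth tract counts as recovered when some called segment of the same
#' individual and chromosome overlaps it reciprocally by at least
#' `min_reciprocal_overlap` (overlap / truth length AND overlap / called
#' length). Precision applies the same rule from the called side. Boundary
#' error is the mean absolute endpoint offset over recovered tracts.
#'
#' @param called ROH data.frame from [call_roh()].
#' @param truth Truth data.frame from [simulate_panel()].
#' @param min_reciprocal_overlap Reciprocal-overlap fraction in (0, 1].
#' @return list(sensitivity, precision, boundary_error_bp, n_truth, n_called).
#' @export
score_recovery <- function(called, truth, min_reciprocal_overlap = 0.5) {
  match_one <- function(t_start, t_end, c_start, c_end) {
    ov <- pmin(t_end, c_end) - pmax(t_start, c_start) + 1
    len_t <- t_end - t_start + 1
    len_c <- c_end - c_start + 1
    ov > 0 & ov / len_t >= min_reciprocal_overlap &
      ov / len_c >= min_reciprocal_overlap
  }
  recovered <- logical(nrow(truth))
  bnd <- numeric(0)
  for (k in seq_len(nrow(truth))) {
    cand <- called[called$sample == truth$sample[k] &
                     called$chr == truth$chr[k], , drop = FALSE]
    if (!nrow(cand)) next
    hit <- match_one(truth$start[k], truth$end[k], cand$start, cand$end)
    if (any(hit)) {
      recovered[k] <- TRUE
      j <- which(hit)[1]
      bnd <- c(bnd, mean(c(abs(cand$start[j] - truth$start[k]),
                           abs(cand$end[j] - truth$end[k]))))
    }
  }
  matched_call <- logical(nrow(called))
  for (k in seq_len(nrow(called))) {
    cand <- truth[truth$sample == called$sample[k] &
                    truth$chr == called$chr[k], , drop = FALSE]
    if (!nrow(cand)) next
    matched_call[k] <- any(match_one(cand$start, cand$end,
                                     called$start[k], called$end[k]))
  }
  list(
    sensitivity = if (nrow(truth)) mean(recovered) else NA_real_,
    precision = if (nrow(called)) mean(matched_call) else NA_real_,
    boundary_error_bp = if (length(bnd)) mean(bnd) else NA_real_,
    n_truth = nrow(truth), n_called = nrow(called))
}
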