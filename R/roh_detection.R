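# Sliding-window detection of runs of homozygosity (ROH), PLINK-style.
#
# The scan, per individual and chromosome:
#   1. a fixed-size window of `window_snps` markers slides one marker at a
#      time; a window is "homozygous" if it holds at most `window_max_het`
#      heterozygous and `window_max_missing` missing calls;
#   2. every marker is scored by the fraction of windows covering it that are
#      homozygous; markers at or above `window_hit_threshold` are eligible;
#   3. maximal runs of consecutive eligible markers, split wherever adjacent
#      markers lie more than `max_gap_bp` apart, form candidate segments;
#   4. candidates survive if they span at least `min_length_bp`, contain at
#      least `min_segment_snps` markers, and keep the density
#      length/n_snps <= `min_density_bp_per_snp`.
# Chromosomes with fewer markers than a window are scanned with a single
# window covering the whole chromosome.

#' ROH calling parameters
#'
#' Defaults are the standard 50K-array configuration for pig panels: 50-SNP
#' windows allowing one heterozygote and two missing calls, minimum segment
#' length 1 Mb, density one SNP per 100 kb, maximum 500 kb between
#' consecutive SNPs. `window_hit_threshold` (the fraction of covering windows
#' that must be homozygous for a SNP to join a run) is PLINK's default 0.05;
#' `min_segment_snps` is set equal to the window size.
#'
#' @param window_snps Markers per sliding window.
#' @param window_max_het Maximum heterozygous calls per homozygous window.
#' @param window_max_missing Maximum missing calls per homozygous window.
#' @param min_length_bp Minimum segment span in bp.
#' @param min_density_bp_per_snp Maximum bp per SNP inside a segment.
#' @param max_gap_bp Maximum gap between consecutive SNPs inside a segment.
#' @param window_hit_threshold Minimum fraction of covering windows that are
#'   homozygous for a SNP to be eligible.
#' @param min_segment_snps Minimum markers per final segment.
#' @return A list of class `roh_call_params`.
#' @export
roh_call_params <- function(window_snps = 50L, window_max_het = 1L,
                            window_max_missing = 2L, min_length_bp = 1e6,
                            min_density_bp_per_snp = 1e5, max_gap_bp = 5e5,
                            window_hit_threshold = 0.05,
                            min_segment_snps = 50L) {
  stopifnot(window_snps >= 1, window_max_het >= 0,
            window_max_het < window_snps, window_max_missing >= 0,
            min_length_bp > 0, min_density_bp_per_snp > 0, max_gap_bp > 0,
            window_hit_threshold > 0, window_hit_threshold <= 1,
            min_segment_snps >= 1)
  structure(list(window_snps = as.integer(window_snps),
                 window_max_het = as.integer(window_max_het),
                 window_max_missing = as.integer(window_max_missing),
                 min_length_bp = min_length_bp,
                 min_density_bp_per_snp = min_density_bp_per_snp,
                 max_gap_bp = max_gap_bp,
                 window_hit_threshold = window_hit_threshold,
                 min_segment_snps = as.integer(min_segment_snps)),
            class = "roh_call_params")
}

empty_roh <- function() {
  data.frame(sample = character(), chr = integer(), start = numeric(),
             end = numeric(), n_snps = integer(), length_bp = numeric(),
             snp_first = character(), snp_last = character(),
             stringsAsFactors = FALSE)
}

# candidate runs of eligible markers -> surviving segments (shared contract,
# applied identically by the fast path; the oracle re-derives it naively)
runs_to_segments <- function(eligible, pos, params) {
  segs <- list()
  r <- rle(eligible)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in which(r$values)) {
    i0 <- starts[k]; i1 <- ends[k]
    # split at gaps > max_gap_bp
    cut <- i0
    idx <- i0:i1
    if (length(idx) > 1L) {
      gaps <- diff(pos[idx])
      brk <- which(gaps > params$max_gap_bp)
      bounds <- cbind(c(i0, idx[brk + 1L]), c(idx[brk], i1))
    } else {
      bounds <- cbind(i0, i1)
    }
    for (b in seq_len(nrow(bounds))) {
      a <- bounds[b, 1]; z <- bounds[b, 2]
      n <- z - a + 1L
      len <- pos[z] - pos[a] + 1
      if (len >= params$min_length_bp && n >= params$min_segment_snps &&
          len / n <= params$min_density_bp_per_snp) {
        segs[[length(segs) + 1L]] <- c(a, z)
      }
    }
  }
  segs
}

#' Call runs of homozygosity
#'
#' Runs the sliding-window scan described above for every individual on every
#' chromosome. Output is deterministic and sorted by (sample, chromosome,
#' start); segments of one individual never overlap.
#'
#' @param geno Integer genotype matrix (0/1/2/NA), samples x markers.
#' @param map Marker map data.frame (snp, chr, pos), sorted.
#' @param params A [roh_call_params()] object.
#' @return data.frame with columns sample, chr, start, end (1-based
#'   inclusive bp), n_snps, length_bp, snp_first, snp_last.
#' @export
call_roh <- function(geno, map, params = roh_call_params()) {
  validate_marker_map(map); validate_genotypes(geno, map)
  stopifnot(inherits(params, "roh_call_params"))
  ids <- rownames(geno)
  if (is.null(ids)) ids <- paste0("S", seq_len(nrow(geno)))

  out <- list()
  for (chr in unique(map$chr)) {
    sel <- which(map$chr == chr)
    pos <- as.numeric(map$pos[sel])
    snp <- map$snp[sel]
    M <- length(sel)
    w <- min(params$window_snps, M)  # short chromosome: one whole-chr window
    n_win <- M - w + 1L
    for (i in seq_len(nrow(geno))) {
      g <- geno[i, sel]
      het <- as.integer(!is.na(g) & g == 1L)
      mis <- as.integer(is.na(g))
      ch <- cumsum(het); cm <- cumsum(mis)
      ws <- seq_len(n_win)
      het_in <- ch[ws + w - 1L] - c(0, ch)[ws]
      mis_in <- cm[ws + w - 1L] - c(0, cm)[ws]
      pass <- het_in <= params$window_max_het &
        mis_in <= params$window_max_missing
      cp <- c(0, cumsum(pass))
      j <- seq_len(M)
      lo <- pmax(1L, j - w + 1L)
      hi <- pmin(j, n_win)
      n_hom <- cp[hi + 1L] - cp[lo]
      n_cov <- hi - lo + 1L
      eligible <- n_hom / n_cov >= params$window_hit_threshold
      for (seg in runs_to_segments(eligible, pos, params)) {
        a <- seg[1]; z <- seg[2]
        out[[length(out) + 1L]] <- data.frame(
          sample = ids[i], chr = chr, start = pos[a], end = pos[z],
          n_snps = z - a + 1L, length_bp = pos[z] - pos[a] + 1,
          snp_first = snp[a], snp_last = snp[z], stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) return(empty_roh())
  res <- do.call(rbind, out)
  res <- res[order(res$sample, res$chr, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Brute-force ROH caller (test oracle)
#'
#' Direct, unoptimized enumeration of every window and every candidate run,
#' implementing the same contract as [call_roh()] but sharing no code with
#' the fast path. Intended for validation on small instances only.
#'
#' @inheritParams call_roh
#' @param max_snps,max_samples Size guard; larger instances are refused.
#' @return Same shape as [call_roh()].
#' @export
call_roh_bruteforce <- function(geno, map, params = roh_call_params(),
                                max_snps = 2000L, max_samples = 50L) {
  validate_marker_map(map); validate_genotypes(geno, map)
  if (ncol(geno) > max_snps || nrow(geno) > max_samples) {
    stop("call_roh_bruteforce: instance too large (",
         nrow(geno), " x ", ncol(geno), ")")
  }
  ids <- rownames(geno)
  if (is.null(ids)) ids <- paste0("S", seq_len(nrow(geno)))

  rows <- list()
  for (i in seq_len(nrow(geno))) {
    for (chr in unique(map$chr)) {
      sel <- which(map$chr == chr)
      pos <- as.numeric(map$pos[sel])
      snp <- map$snp[sel]
      g <- geno[i, sel]
      M <- length(sel)
      w <- if (M < params$window_snps) M else params$window_snps
      win_start <- 1:(M - w + 1)
      hom <- logical(length(win_start))
      for (k in seq_along(win_start)) {
        slice <- g[win_start[k]:(win_start[k] + w - 1)]
        hom[k] <- sum(slice == 1, na.rm = TRUE) <= params$window_max_het &&
          sum(is.na(slice)) <= params$window_max_missing
      }
      eligible <- logical(M)
      for (j in 1:M) {
        covering <- which(win_start <= j & win_start + w - 1 >= j)
        eligible[j] <- mean(hom[covering]) >= params$window_hit_threshold
      }
      # naive run construction: walk markers, break on ineligible or big gap
      run <- integer(0)
      flush <- function(run) {
        if (!length(run)) return(NULL)
        n <- length(run)
        len <- pos[run[n]] - pos[run[1]] + 1
        if (len >= params$min_length_bp && n >= params$min_segment_snps &&
            len / n <= params$min_density_bp_per_snp) {
          data.frame(sample = ids[i], chr = chr, start = pos[run[1]],
                     end = pos[run[n]], n_snps = n, length_bp = len,
                     snp_first = snp[run[1]], snp_last = snp[run[n]],
                     stringsAsFactors = FALSE)
        } else NULL
      }
      for (j in 1:M) {
        if (!eligible[j]) {
          rows[[length(rows) + 1L]] <- flush(run); run <- integer(0)
        } else {
          if (length(run) && pos[j] - pos[run[length(run)]] > params$max_gap_bp) {
            rows[[length(rows) + 1L]] <- flush(run); run <- integer(0)
          }
          run <- c(run, j)
        }
      }
      rows[[length(rows) + 1L]] <- flush(run)
    }
  }
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows)) return(empty_roh())
  res <- do.call(rbind, rows)
  res <- res[order(res$sample, res$chr, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}
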