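# ROH islands: per-SNP ROH incidence, top-tail hotspot calling, island
# segment construction and cross-population sharing (Venn accounting).

#' Per-SNP ROH incidence within a population
#'
#' For each marker, the fraction of the population's individuals that have at
#' least one ROH covering its position. An individual contributes at most one
#' count per marker regardless of segment multiplicity (segments of one
#' individual are non-overlapping by construction, so simple coverage
#' counting satisfies this).
#'
#' @param segments ROH data.frame (any samples; only rows of
#'   `population_samples` are counted).
#' @param map Marker map data.frame.
#' @param population_samples Character vector of sample ids in the population.
#' @return data.frame(snp, chr, pos, incidence).
#' @export
snp_incidence <- function(segments, map, population_samples) {
  if (length(population_samples) == 0L) {
    stop("snp_incidence: empty population")
  }
  validate_marker_map(map)
  seg <- segments[segments$sample %in% population_samples, , drop = FALSE]
  count <- numeric(nrow(map))
  if (nrow(seg)) {
    marker_gr <- autosome_gr(map$chr, map$pos, map$pos)
    # count distinct individuals per marker: segments never overlap within an
    # individual, so hits per marker == individuals covered
    seg_gr <- autosome_gr(seg$chr, seg$start, seg$end)
    hits <- GenomicRanges::countOverlaps(marker_gr, seg_gr)
    count <- as.numeric(hits)
  }
  data.frame(snp = map$snp, chr = map$chr, pos = map$pos,
             incidence = count / length(population_samples),
             stringsAsFactors = FALSE)
}

#' Call hotspot SNPs from an incidence track
#'
#' The threshold is the `1 - top_fraction` quantile of the incidence values;
#' every marker at or above it is a hotspot, so ties at the threshold are all
#' included (the hotspot set is at least `ceiling(top_fraction * n)` markers
#' when incidences are positive). Markers with zero incidence never qualify,
#' even when the quantile itself is zero; an all-zero track yields an empty
#' set with a warning.
#'
#' @param track data.frame from [snp_incidence()].
#' @param top_fraction Upper tail fraction defining hotspots (default 1%).
#' @return `track` rows that are hotspots, with a `threshold` attribute.
#' @export
call_hotspots <- function(track, top_fraction = 0.01) {
  stopifnot(top_fraction > 0, top_fraction <= 1)
  if (all(track$incidence == 0)) {
    warning("call_hotspots: all incidences are zero; no hotspots")
    out <- track[0, , drop = FALSE]
    attr(out, "threshold") <- NA_real_
    return(out)
  }
  thr <- stats::quantile(track$incidence, probs = 1 - top_fraction,
                         names = FALSE)
  keep <- track$incidence >= thr & track$incidence > 0
  if (all(keep)) {
    warning("call_hotspots: every marker ties at the hotspot threshold")
  }
  out <- track[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "threshold") <- thr
  out
}

#' Build island segments from hotspot SNPs
#'
#' Maximal runs of hotspot markers on one chromosome, split where consecutive
#' hotspot markers lie more than `max_gap_bp` apart, become one island
#' spanning the first to the last hotspot position. A single isolated hotspot
#' yields a degenerate island with start == end, which is retained.
#'
#' @param hotspots data.frame from [call_hotspots()].
#' @param max_gap_bp Maximum distance between consecutive hotspot markers
#'   within one island.
#' @param population Optional population label stored in the output.
#' @return data.frame(population, chr, start, end, n_hotspot_snps,
#'   peak_incidence).
#' @export
build_islands <- function(hotspots, max_gap_bp = 5e5, population = NA) {
  empty <- data.frame(population = character(), chr = integer(),
                      start = numeric(), end = numeric(),
                      n_hotspot_snps = integer(), peak_incidence = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(hotspots) == 0L) return(empty)
  hs <- hotspots[order(hotspots$chr, hotspots$pos), , drop = FALSE]
  new_island <- c(TRUE, diff(hs$pos) > max_gap_bp | diff(hs$chr) != 0)
  grp <- cumsum(new_island)
  out <- do.call(rbind, lapply(split(hs, grp), function(d) {
    data.frame(population = population, chr = d$chr[1], start = min(d$pos),
               end = max(d$pos), n_hotspot_snps = nrow(d),
               peak_incidence = max(d$incidence), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

# all interval work shares one autosome seqlevel universe so overlaps across
# lists touching different chromosomes compare cleanly
autosome_gr <- function(chr, start, end) {
  GenomicRanges::GRanges(
    seqnames = factor(as.character(chr), levels = as.character(AUTOSOMES)),
    ranges = IRanges::IRanges(start, end))
}

islands_gr <- function(islands) {
  autosome_gr(islands$chr, islands$start, islands$end)
}

overlaps_any <- function(islands, other) {
  if (nrow(islands) == 0L) return(logical(0))
  if (is.null(other) || nrow(other) == 0L) return(rep(FALSE, nrow(islands)))
  GenomicRanges::countOverlaps(islands_gr(islands), islands_gr(other),
                               minoverlap = 1L) > 0
}

#' Three-set sharing (Venn) accounting over island lists
#'
#' An island of one group is "shared" with another group when it overlaps any
#' of that group's islands by at least `min_overlap_bp`. Each group's islands
#' are partitioned into four regions (exclusive, shared with one other, with
#' the other, with both) from that group's own perspective; the headline
#' seven-region counts are taken from the first-listed group for regions it
#' participates in (so `AB` counts A-islands overlapping B, which need not
#' equal the B-side count).
#'
#' @param islands_by_group Named list of exactly three island data.frames;
#'   names are the group labels, first name is the reporting perspective.
#' @param min_overlap_bp Minimum overlap to count as shared.
#' @return list(`regions` = per-group 4-region count table,
#'   `counts` = named vector only_A/only_B/only_C/AB/AC/BC/ABC,
#'   `totals` = islands per group).
#' @export
venn_segments <- function(islands_by_group, min_overlap_bp = 1L) {
  stopifnot(length(islands_by_group) == 3L,
            !is.null(names(islands_by_group)))
  gn <- names(islands_by_group)
  ov <- function(a, b) {
    ia <- islands_by_group[[a]]; ib <- islands_by_group[[b]]
    if (nrow(ia) == 0L) return(logical(0))
    if (nrow(ib) == 0L) return(rep(FALSE, nrow(ia)))
    GenomicRanges::countOverlaps(islands_gr(ia), islands_gr(ib),
                                 minoverlap = min_overlap_bp) > 0
  }
  regions <- do.call(rbind, lapply(seq_along(gn), function(k) {
    others <- gn[-k]
    h1 <- ov(gn[k], others[1]); h2 <- ov(gn[k], others[2])
    data.frame(group = gn[k],
               exclusive = sum(!h1 & !h2),
               with_first_other = sum(h1 & !h2),
               with_second_other = sum(!h1 & h2),
               with_both = sum(h1 & h2),
               total = nrow(islands_by_group[[gn[k]]]),
               stringsAsFactors = FALSE)
  }))
  counts <- c(
    only_A = regions$exclusive[1],
    only_B = regions$exclusive[2],
    only_C = regions$exclusive[3],
    AB = regions$with_first_other[1],   # from A's perspective
    AC = regions$with_second_other[1],  # from A's perspective
    BC = regions$with_second_other[2],  # from B's perspective
    ABC = regions$with_both[1])         # from A's perspective
  list(regions = regions, counts = counts,
       totals = stats::setNames(regions$total, gn))
}

#' Islands shared with a reference population
#'
#' For every non-reference population, retains the islands that overlap at
#' least one reference island, keeping coordinates and hotspot-SNP counts for
#' downstream annotation.
#'
#' @param islands_by_population Named list of island data.frames.
#' @param reference Name of the reference population in the list.
#' @param min_overlap_bp Minimum overlap to count as shared.
#' @return data.frame of retained islands (column `population` identifies
#'   the source population).
#' @export
shared_with_reference <- function(islands_by_population, reference,
                                  min_overlap_bp = 1L) {
  if (!reference %in% names(islands_by_population)) {
    stop("reference population '", reference, "' not present")
  }
  ref <- islands_by_population[[reference]]
  others <- setdiff(names(islands_by_population), reference)
  out <- lapply(others, function(p) {
    isl <- islands_by_population[[p]]
    if (nrow(isl) == 0L) return(isl)
    keep <- if (nrow(ref) == 0L) rep(FALSE, nrow(isl)) else
      GenomicRanges::countOverlaps(islands_gr(isl), islands_gr(ref),
                                   minoverlap = min_overlap_bp) > 0
    res <- isl[keep, , drop = FALSE]
    res$population <- rep(p, nrow(res))
    res
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
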