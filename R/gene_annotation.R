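# Gene annotation of island / hotspot regions from a local GFF3 or GTF file.

#' Read gene features from a GFF3/GTF annotation
#'
#' Imports the annotation with rtracklayer, keeps features of type "gene",
#' normalizes chromosome names by stripping a "chr" prefix, and drops
#' records on sequences outside autosomes 1-18 (a message reports the
#' count). Coordinates are 1-based inclusive as in GFF.
#'
#' @param path Path to a .gff3/.gff or .gtf file.
#' @return data.frame(gene_id, gene_name, chr, start, end, strand). Empty
#'   (with a warning) when the file holds no gene features.
#' @export
read_gff <- function(path) {
  stopifnot(file.exists(path))
  gr <- rtracklayer::import(path)
  empty <- data.frame(gene_id = character(), gene_name = character(),
                      chr = integer(), start = numeric(), end = numeric(),
                      strand = character(), stringsAsFactors = FALSE)
  type <- as.character(gr$type)
  genes <- gr[!is.na(type) & type == "gene"]
  if (length(genes) == 0L) {
    warning("read_gff: no gene features in ", path)
    return(empty)
  }
  md <- S4Vectors::mcols(genes)
  gene_id <- if ("gene_id" %in% names(md)) as.character(md$gene_id)
             else if ("ID" %in% names(md)) as.character(md$ID)
             else as.character(seq_along(genes))
  gene_name <- if ("gene_name" %in% names(md)) as.character(md$gene_name)
               else if ("Name" %in% names(md)) as.character(md$Name)
               else gene_id
  gene_name <- ifelse(is.na(gene_name) | gene_name == "", gene_id, gene_name)
  chr_raw <- sub("^chr", "", as.character(GenomicRanges::seqnames(genes)),
                 ignore.case = TRUE)
  chr <- suppressWarnings(as.integer(chr_raw))
  keep <- !is.na(chr) & chr %in% AUTOSOMES
  n_drop <- sum(!keep)
  if (n_drop > 0L) {
    message("read_gff: dropped ", n_drop,
            " gene(s) on scaffolds outside autosomes 1-18")
  }
  out <- data.frame(
    gene_id = gene_id[keep], gene_name = gene_name[keep], chr = chr[keep],
    start = GenomicRanges::start(genes)[keep],
    end = GenomicRanges::end(genes)[keep],
    strand = as.character(GenomicRanges::strand(genes))[keep],
    stringsAsFactors = FALSE)
  out <- out[order(out$chr, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Genes overlapping flanked island or hotspot-SNP windows
#'
#' Each region is expanded by `flank_bp` on both sides (for hotspot SNPs the
#' window is `[pos - flank, pos + flank]`; for islands
#' `[start - flank, end + flank]`), and a gene is reported when its span
#' overlaps the window by at least one bp. Strand is ignored: flanks are
#' symmetric and SNPs are strandless.
#'
#' @param regions data.frame with `chr` and either `start`/`end` (islands) or
#'   `pos` (hotspot SNPs); optional `population` column is carried through.
#' @param genes data.frame from [read_gff()].
#' @param flank_bp Flank added to each side of every region (default 50 kb,
#'   i.e. a 100 kb window around a single SNP).
#' @return data.frame with one row per (region, gene) hit: region_id,
#'   population, chr, window_start, window_end, gene_id, gene_name.
#' @export
genes_in_regions <- function(regions, genes, flank_bp = 5e4) {
  stopifnot(flank_bp >= 0)
  empty <- data.frame(region_id = integer(), population = character(),
                      chr = integer(), window_start = numeric(),
                      window_end = numeric(), gene_id = character(),
                      gene_name = character(), stringsAsFactors = FALSE)
  if (nrow(regions) == 0L || nrow(genes) == 0L) return(empty)
  if (!"start" %in% names(regions)) {
    regions$start <- regions$pos
    regions$end <- regions$pos
  }
  win_start <- pmax(1, regions$start - flank_bp)
  win_end <- regions$end + flank_bp
  win_gr <- autosome_gr(regions$chr, win_start, win_end)
  gene_gr <- autosome_gr(genes$chr, genes$start, genes$end)
  hits <- GenomicRanges::findOverlaps(win_gr, gene_gr, minoverlap = 1L)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  pop <- if ("population" %in% names(regions)) regions$population
         else rep(NA_character_, nrow(regions))
  out <- data.frame(
    region_id = qi, population = pop[qi], chr = regions$chr[qi],
    window_start = win_start[qi], window_end = win_end[qi],
    gene_id = genes$gene_id[si], gene_name = genes$gene_name[si],
    stringsAsFactors = FALSE)
  out <- unique(out)
  out <- out[order(out$region_id, out$chr, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-group annotation tally
#'
#' Summarizes an annotation table into one row per (population, chromosome):
#' number of islands, hotspot SNPs (when available in `regions`), and
#' deduplicated genes — the shape used to report shared-island gene content.
#'
#' @param annot data.frame from [genes_in_regions()].
#' @param regions The region table that produced `annot` (for island and
#'   SNP-count bookkeeping; needs `chr` and optionally `population`,
#'   `n_hotspot_snps`).
#' @return data.frame(population, chr, n_islands, n_snps, n_genes, genes).
#' @export
annotation_tally <- function(annot, regions) {
  pop <- if ("population" %in% names(regions)) regions$population
         else rep(NA_character_, nrow(regions))
  key <- split(seq_len(nrow(regions)), paste(pop, regions$chr, sep = "\r"))
  rows <- lapply(names(key), function(k) {
    idx <- key[[k]]
    parts <- strsplit(k, "\r")[[1]]
    hit <- annot[annot$region_id %in% idx, , drop = FALSE]
    genes <- sort(unique(hit$gene_name))
    data.frame(
      population = parts[1], chr = as.integer(parts[2]),
      n_islands = length(idx),
      n_snps = if ("n_hotspot_snps" %in% names(regions))
        sum(regions$n_hotspot_snps[idx]) else NA_integer_,
      n_genes = length(genes),
      genes = paste(genes, collapse = ","), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$population, out$chr), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export per-group gene lists and a combined annotation table
#'
#' Writes one plain-text gene list per group (one gene per line,
#' deduplicated, sorted — ready for pasting into an enrichment web service)
#' and a combined TSV carrying provenance (group, chromosome, window
#' coordinates, gene).
#'
#' @param annot data.frame from [genes_in_regions()].
#' @param out_dir Output directory (created if needed).
#' @return Character vector of files written, invisibly.
#' @export
export_gene_lists <- function(annot, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  groups <- unique(annot$population)
  if (nrow(annot) == 0L) {
    warning("export_gene_lists: empty annotation; writing empty combined table")
  }
  for (g in groups) {
    genes <- sort(unique(annot$gene_name[annot$population %in% g]))
    f <- file.path(out_dir, paste0("genes_", gsub("[^A-Za-z0-9_-]", "_", g),
                                   ".txt"))
    if (!length(genes)) warning("export_gene_lists: no genes for group ", g)
    writeLines(genes, f)
    files <- c(files, f)
  }
  comb <- file.path(out_dir, "annotation_combined.tsv")
  utils::write.table(
    annot[, c("population", "chr", "window_start", "window_end",
              "gene_id", "gene_name")],
    comb, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, comb)
  invisible(files)
}
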