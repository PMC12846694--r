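# Genotype and marker-map input/output in the two standard PLINK dialects.
#
# Internal model:
#   * marker map  -- data.frame(snp, chr, pos), strictly sorted by (chr, pos),
#                    autosomes 1-18 only, 1-based physical coordinates.
#   * genotypes   -- integer matrix, samples x markers, coded
#                    0 = homozygous A1/A1, 1 = heterozygous, 2 = homozygous
#                    A2/A2, NA = missing. Allele identity beyond hom/het is
#                    not carried: no downstream stage needs it.

AUTOSOMES <- 1:18
VALID_ALLELES <- c("A", "C", "G", "T", "1", "2")

#' Validate a marker map
#'
#' @param map data.frame with columns `snp`, `chr`, `pos`.
#' @return The map, invisibly, after checking sortedness, autosome range and
#'   duplicate positions.
#' @keywords internal
validate_marker_map <- function(map) {
  stopifnot(is.data.frame(map), all(c("snp", "chr", "pos") %in% names(map)))
  if (nrow(map) == 0L) return(invisible(map))
  if (!all(map$chr %in% AUTOSOMES)) {
    stop("marker map contains non-autosomal chromosomes (must be 1-18)")
  }
  if (any(map$pos < 1L)) stop("marker positions must be >= 1 (1-based)")
  key <- order(map$chr, map$pos)
  if (!identical(key, seq_len(nrow(map)))) {
    stop("marker map must be sorted by (chromosome, position)")
  }
  if (anyDuplicated(paste(map$chr, map$pos))) {
    stop("duplicate (chromosome, position) pairs in marker map")
  }
  invisible(map)
}

#' Validate a genotype matrix against its marker map
#' @keywords internal
validate_genotypes <- function(geno, map) {
  stopifnot(is.matrix(geno))
  if (ncol(geno) != nrow(map)) {
    stop("genotype matrix has ", ncol(geno), " markers but map has ", nrow(map))
  }
  vals <- geno[!is.na(geno)]
  if (length(vals) && !all(vals %in% 0:2)) {
    stop("genotype codes must be 0, 1, 2 or NA")
  }
  invisible(geno)
}

#' Read PLINK text genotypes (PED/MAP)
#'
#' Parses a PED/MAP pair into the 0/1/2/NA genotype coding. The first allele
#' encountered at each marker (scanning samples in file order) is taken as A1,
#' so homozygotes for it code as 0; "0 0" codes as missing. Markers mapped
#' outside autosomes 1-18 are dropped (a message reports the count), and the
#' retained markers are sorted by (chromosome, position).
#'
#' Note that the first-seen-allele convention means the 0/2 polarity of a
#' marker depends on sample order; hom/het/missing structure — all that the
#' ROH machinery consumes — is unaffected.
#'
#' @param ped_path Path to the .ped file (6 leading columns, then two allele
#'   columns per marker).
#' @param map_path Path to the .map file (chr, snp id, cM, bp).
#' @return A list with elements `geno` (integer matrix, samples x markers,
#'   rownames = within-family IDs), `map` (data.frame snp/chr/pos) and `fam`
#'   (data.frame of the six leading PED columns).
#' @export
read_ped_map <- function(ped_path, map_path) {
  stopifnot(file.exists(ped_path), file.exists(map_path))
  map_raw <- utils::read.table(map_path, header = FALSE,
                               colClasses = c("character", "character",
                                              "character", "integer"))
  names(map_raw) <- c("chr", "snp", "cm", "pos")
  chr_num <- suppressWarnings(as.integer(map_raw$chr))
  keep <- !is.na(chr_num) & chr_num %in% AUTOSOMES
  n_drop <- sum(!keep)
  if (n_drop > 0L) message("read_ped_map: dropped ", n_drop,
                           " non-autosomal marker(s)")
  n_map <- nrow(map_raw)

  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  n_samp <- length(lines)
  fam <- data.frame(fid = character(n_samp), iid = character(n_samp),
                    pat = character(n_samp), mat = character(n_samp),
                    sex = character(n_samp), pheno = character(n_samp),
                    stringsAsFactors = FALSE)
  a1 <- rep(NA_character_, n_map)  # first allele seen per marker
  geno <- matrix(NA_integer_, nrow = n_samp, ncol = n_map)
  for (i in seq_len(n_samp)) {
    tok <- strsplit(trimws(lines[[i]]), "[ \t]+")[[1]]
    if (length(tok) != 6L + 2L * n_map) {
      stop("malformed PED line ", i, ": expected ", 6L + 2L * n_map,
           " fields, found ", length(tok))
    }
    fam[i, ] <- tok[1:6]
    al1 <- tok[seq(7L, by = 2L, length.out = n_map)]
    al2 <- tok[seq(8L, by = 2L, length.out = n_map)]
    bad <- !(al1 %in% c(VALID_ALLELES, "0")) | !(al2 %in% c(VALID_ALLELES, "0"))
    if (any(bad)) {
      stop("parse error at PED line ", i, ", marker ", which(bad)[1],
           ": allele symbol outside {A,C,G,T,1,2,0}")
    }
    half <- xor(al1 == "0", al2 == "0")
    if (any(half)) {
      stop("parse error at PED line ", i, ", marker ", which(half)[1],
           ": half-missing genotype")
    }
    miss <- al1 == "0"
    new_ref <- is.na(a1) & !miss
    a1[new_ref] <- al1[new_ref]
    code <- (al1 != a1) + (al2 != a1)
    code[miss] <- NA_integer_
    geno[i, ] <- as.integer(code)
  }
  rownames(geno) <- fam$iid

  geno <- geno[, keep, drop = FALSE]
  map <- data.frame(snp = map_raw$snp[keep], chr = chr_num[keep],
                    pos = map_raw$pos[keep], stringsAsFactors = FALSE)
  ord <- order(map$chr, map$pos)
  map <- map[ord, , drop = FALSE]
  geno <- geno[, ord, drop = FALSE]
  rownames(map) <- NULL
  colnames(geno) <- map$snp
  validate_marker_map(map)
  validate_genotypes(geno, map)
  list(geno = geno, map = map, fam = fam)
}

#' Read PLINK binary genotypes (BED/BIM/FAM)
#'
#' Decodes SNP-major PLINK 1 binary files. Per-marker 2-bit codes follow the
#' PLINK spec: 00 = homozygous A1, 01 = missing, 10 = heterozygous,
#' 11 = homozygous A2, packed 4 genotypes per byte, least-significant bits
#' first. BIM allele columns fix the 0/2 polarity. Non-autosomal markers are
#' dropped; markers are sorted by (chromosome, position).
#'
#' @param prefix Path prefix; `<prefix>.bed`, `.bim` and `.fam` must exist.
#' @return A list with `geno`, `map`, and `samples` — a stub sample table
#'   (data.frame sample/breed from the FAM family ID, to be completed or
#'   replaced via [read_sample_table()]).
#' @export
read_bed_bim_fam <- function(prefix) {
  bed <- paste0(prefix, ".bed"); bim <- paste0(prefix, ".bim")
  fam <- paste0(prefix, ".fam")
  stopifnot(file.exists(bed), file.exists(bim), file.exists(fam))

  bim_df <- utils::read.table(bim, header = FALSE,
                              colClasses = c("character", "character",
                                             "character", "integer",
                                             "character", "character"))
  names(bim_df) <- c("chr", "snp", "cm", "pos", "a1", "a2")
  fam_df <- utils::read.table(fam, header = FALSE, colClasses = "character")
  names(fam_df) <- c("fid", "iid", "pat", "mat", "sex", "pheno")
  n_samp <- nrow(fam_df); n_snp <- nrow(bim_df)

  raw <- readBin(bed, what = "raw", n = file.size(bed))
  if (length(raw) < 3L || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b)) {
    stop("not a PLINK BED file: magic bytes 0x6c 0x1b missing")
  }
  if (raw[3] != as.raw(0x01)) {
    stop("only SNP-major BED files are supported (mode byte 0x01)")
  }
  bytes_per_snp <- ceiling(n_samp / 4)
  body <- raw[-(1:3)]
  if (length(body) < bytes_per_snp * n_snp) stop("BED file truncated")

  # 2-bit field -> genotype code (per PLINK bit spec: 00 hom A1, 01 missing,
  # 10 het, 11 hom A2); sample s lives in byte (s-1)%/%4, bits 2*((s-1)%%4)
  code_of <- c(0L, NA_integer_, 1L, 2L)
  geno <- matrix(NA_integer_, nrow = n_samp, ncol = n_snp)
  s <- seq_len(n_samp)
  byte_idx <- (s - 1L) %/% 4L + 1L
  shift <- 2L * ((s - 1L) %% 4L)
  for (j in seq_len(n_snp)) {
    blk <- as.integer(body[((j - 1L) * bytes_per_snp + 1L):(j * bytes_per_snp)])
    f <- bitwAnd(bitwShiftR(blk[byte_idx], shift), 3L)
    geno[, j] <- code_of[f + 1L]
  }
  rownames(geno) <- fam_df$iid

  chr_num <- suppressWarnings(as.integer(bim_df$chr))
  keep <- !is.na(chr_num) & chr_num %in% AUTOSOMES
  n_drop <- sum(!keep)
  if (n_drop > 0L) message("read_bed_bim_fam: dropped ", n_drop,
                           " non-autosomal marker(s)")
  geno <- geno[, keep, drop = FALSE]
  map <- data.frame(snp = bim_df$snp[keep], chr = chr_num[keep],
                    pos = bim_df$pos[keep], stringsAsFactors = FALSE)
  ord <- order(map$chr, map$pos)
  map <- map[ord, , drop = FALSE]
  geno <- geno[, ord, drop = FALSE]
  rownames(map) <- NULL
  colnames(geno) <- map$snp
  validate_marker_map(map)
  validate_genotypes(geno, map)
  samples <- data.frame(sample = fam_df$iid, breed = fam_df$fid,
                        stringsAsFactors = FALSE)
  list(geno = geno, map = map, samples = samples)
}

#' Write PLINK text genotypes (PED/MAP)
#'
#' Alleles are emitted as "1" (A1) and "2" (A2); missing as "0 0".
#'
#' @param geno Integer genotype matrix (0/1/2/NA), samples x markers.
#' @param map Marker map data.frame.
#' @param prefix Output path prefix (writes `<prefix>.ped`, `<prefix>.map`).
#' @param fam Optional data.frame of the six leading PED columns; defaults to
#'   family = sample id, unknown parents/sex, phenotype -9.
#' @return The prefix, invisibly.
#' @export
write_ped_map <- function(geno, map, prefix, fam = NULL) {
  validate_marker_map(map); validate_genotypes(geno, map)
  if (is.null(fam)) {
    ids <- rownames(geno)
    if (is.null(ids)) ids <- paste0("S", seq_len(nrow(geno)))
    fam <- data.frame(fid = ids, iid = ids, pat = "0", mat = "0",
                      sex = "0", pheno = "-9", stringsAsFactors = FALSE)
  }
  utils::write.table(
    data.frame(map$chr, map$snp, 0,
               format(map$pos, scientific = FALSE, trim = TRUE)),
    paste0(prefix, ".map"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  al1 <- c("1", "1", "2"); al2 <- c("1", "2", "2")
  con <- file(paste0(prefix, ".ped"), "w")
  on.exit(close(con))
  for (i in seq_len(nrow(geno))) {
    g <- geno[i, ]
    a <- ifelse(is.na(g), "0", al1[g + 1L])
    b <- ifelse(is.na(g), "0", al2[g + 1L])
    pair <- character(2L * length(g))
    pair[c(TRUE, FALSE)] <- a; pair[c(FALSE, TRUE)] <- b
    writeLines(paste(c(unlist(fam[i, ], use.names = FALSE), pair),
                     collapse = " "), con)
  }
  invisible(prefix)
}

#' Write PLINK binary genotypes (BED/BIM/FAM)
#'
#' SNP-major PLINK 1 encoding; BIM alleles are "1" (A1) and "2" (A2).
#'
#' @inheritParams write_ped_map
#' @return The prefix, invisibly.
#' @export
write_bed_bim_fam <- function(geno, map, prefix, fam = NULL) {
  validate_marker_map(map); validate_genotypes(geno, map)
  ids <- rownames(geno)
  if (is.null(ids)) ids <- paste0("S", seq_len(nrow(geno)))
  if (is.null(fam)) {
    fam <- data.frame(fid = ids, iid = ids, pat = "0", mat = "0",
                      sex = "0", pheno = "-9", stringsAsFactors = FALSE)
  }
  utils::write.table(
    data.frame(map$chr, map$snp, 0,
               format(map$pos, scientific = FALSE, trim = TRUE), "1", "2"),
    paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  utils::write.table(fam, paste0(prefix, ".fam"), sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)

  n_samp <- nrow(geno)
  bytes_per_snp <- ceiling(n_samp / 4)
  bits_of <- c(0L, 2L, 3L)  # code 0 -> 00, 1 -> 10, 2 -> 11; NA -> 01
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  pad <- bytes_per_snp * 4L - n_samp
  for (j in seq_len(ncol(geno))) {
    g <- geno[, j]
    f <- ifelse(is.na(g), 1L, bits_of[g + 1L])
    f <- c(f, rep(0L, pad))
    m <- matrix(f, nrow = 4L)
    byte <- m[1, ] + m[2, ] * 4L + m[3, ] * 16L + m[4, ] * 64L
    writeBin(as.raw(byte), con)
  }
  invisible(prefix)
}

#' Read a sample/breed metadata table
#'
#' Tab-separated with header columns `sample`, `breed`, `group`, `category`.
#' `group` is a broad origin label (African, American, Asian, European,
#' Cosmopolitan); `category` distinguishes indigenous from cosmopolitan
#' breeds and must equal "cosmopolitan" exactly when group is "Cosmopolitan".
#'
#' @param path Path to the TSV file.
#' @param geno Optional genotype matrix; if given, every sample in it must
#'   appear exactly once in the table.
#' @return data.frame with the four columns.
#' @export
read_sample_table <- function(path, geno = NULL) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character")
  need <- c("sample", "breed", "group", "category")
  if (!all(need %in% names(tab))) {
    stop("sample table must have columns: ", paste(need, collapse = ", "))
  }
  validate_sample_table(tab[need], geno)
}

#' @keywords internal
validate_sample_table <- function(tab, geno = NULL) {
  if (anyDuplicated(tab$sample)) stop("duplicate sample identifiers")
  mism <- xor(tab$group == "Cosmopolitan", tab$category == "cosmopolitan")
  if (any(mism)) {
    stop("category must be 'cosmopolitan' exactly for group 'Cosmopolitan' (",
         paste(tab$sample[mism], collapse = ", "), ")")
  }
  if (!is.null(geno)) {
    missing_ids <- setdiff(rownames(geno), tab$sample)
    if (length(missing_ids)) {
      stop("samples absent from sample table: ",
           paste(utils::head(missing_ids, 5), collapse = ", "))
    }
  }
  tab
}

#' Write called ROH segments as a PLINK .hom-style table
#'
#' Columns FID IID CHR SNP1 SNP2 POS1 POS2 KB NSNP, tab-separated, with
#' KB = (end - start + 1) / 1000 and rows ordered by (individual, chromosome,
#' start). Coordinates are 1-based inclusive.
#'
#' @param segments data.frame of ROH segments as returned by [call_roh()]
#'   (columns sample, chr, start, end, n_snps, plus optional snp_first,
#'   snp_last, fid).
#' @param out_path Output file path.
#' @return `out_path`, invisibly.
#' @export
write_roh_table <- function(segments, out_path) {
  cols <- c("FID", "IID", "CHR", "SNP1", "SNP2", "POS1", "POS2", "KB", "NSNP")
  if (nrow(segments) == 0L) {
    writeLines(paste(cols, collapse = "\t"), out_path)
    return(invisible(out_path))
  }
  ord <- order(segments$sample, segments$chr, segments$start)
  seg <- segments[ord, , drop = FALSE]
  out <- data.frame(
    FID = if ("fid" %in% names(seg)) seg$fid else seg$sample,
    IID = seg$sample,
    CHR = seg$chr,
    SNP1 = if ("snp_first" %in% names(seg)) seg$snp_first else ".",
    SNP2 = if ("snp_last" %in% names(seg)) seg$snp_last else ".",
    POS1 = seg$start,
    POS2 = seg$end,
    KB = (seg$end - seg$start + 1) / 1000,
    NSNP = seg$n_snps)
  utils::write.table(out, out_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(out_path)
}

#' Write genomic intervals as a BED track
#'
#' Converts from the package's 1-based inclusive coordinates to BED's 0-based
#' half-open convention on write.
#'
#' @param intervals data.frame with columns `chr`, `start`, `end` (1-based
#'   inclusive) and optionally `name`.
#' @param out_path Output file path.
#' @return `out_path`, invisibly.
#' @export
write_bed_track <- function(intervals, out_path) {
  if (nrow(intervals) == 0L) {
    file.create(out_path)
    return(invisible(out_path))
  }
  name <- if ("name" %in% names(intervals)) intervals$name else "."
  out <- data.frame(chr = intervals$chr, start = intervals$start - 1L,
                    end = intervals$end, name = name)
  out <- out[order(out$chr, out$start), , drop = FALSE]
  utils::write.table(out, out_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(out_path)
}
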