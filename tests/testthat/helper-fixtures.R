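# Shared fixture builders for the test suite. All fixtures are generated in
# code; nothing is read from disk except the packaged extdata tables.

# evenly spaced single-chromosome marker map
make_map <- function(n, spacing = 1e4, chr = 1L, start = spacing) {
  data.frame(snp = sprintf("s%d_%d", chr, seq_len(n)), chr = chr,
             pos = as.integer(start + spacing * (seq_len(n) - 1L)),
             stringsAsFactors = FALSE)
}

# genotype matrix from a list of per-sample code vectors
make_geno <- function(..., ids = NULL) {
  rows <- list(...)
  g <- do.call(rbind, rows)
  rownames(g) <- if (is.null(ids)) paste0("S", seq_len(nrow(g))) else ids
  storage.mode(g) <- "integer"
  g
}

# a randomized small ROH instance + parameter draw for oracle equivalence;
# genotypes alternate autozygous (homozygous) and outbred blocks so that
# candidate runs of every fate (kept, too short, split by gaps) arise
random_roh_instance <- function(seed) {
  set.seed(seed)
  n_chr <- sample(1:2, 1)
  maps <- lapply(seq_len(n_chr), function(ch) {
    n <- sample(60:250, 1)
    gaps <- ifelse(runif(n - 1) < 0.03,
                   runif(n - 1, 2e5, 1e6),   # occasional large gap
                   runif(n - 1, 5e3, 6e4))
    pos <- as.integer(cumsum(c(sample(1e4, 1), gaps)))
    data.frame(snp = sprintf("c%ds%d", ch, seq_len(n)), chr = ch, pos = pos,
               stringsAsFactors = FALSE)
  })
  map <- do.call(rbind, maps)
  map <- map[order(map$chr, map$pos), , drop = FALSE]
  map <- map[!duplicated(paste(map$chr, map$pos)), , drop = FALSE]
  rownames(map) <- NULL

  n_ind <- sample(2:8, 1)
  geno <- matrix(NA_integer_, nrow = n_ind, ncol = nrow(map))
  for (i in seq_len(n_ind)) {
    g <- integer(nrow(map))
    j <- 1L
    auto <- runif(1) < 0.5
    while (j <= nrow(map)) {
      len <- min(nrow(map) - j + 1L, 1L + stats::rgeom(1, 1 / 60))
      idx <- j:(j + len - 1L)
      if (auto) {
        g[idx] <- sample(c(0L, 2L), len, replace = TRUE)
        g[idx][runif(len) < 0.01] <- 1L   # rare embedded heterozygote
      } else {
        g[idx] <- sample(0:2, len, replace = TRUE, prob = c(0.35, 0.4, 0.25))
      }
      j <- j + len
      auto <- !auto
    }
    g[runif(nrow(map)) < 0.03] <- NA_integer_
    geno[i, ] <- g
  }
  rownames(geno) <- paste0("I", seq_len(n_ind))
  colnames(geno) <- map$snp

  params <- roh_call_params(
    window_snps = sample(c(10L, 20L, 30L), 1),
    window_max_het = sample(0:2, 1),
    window_max_missing = sample(0:3, 1),
    min_length_bp = runif(1, 5e5, 2e6),
    min_density_bp_per_snp = 1e5,
    max_gap_bp = runif(1, 1e5, 8e5),
    window_hit_threshold = 0.05,
    min_segment_snps = sample(c(10L, 20L, 30L), 1))
  list(geno = geno, map = map, params = params)
}

# four-breed sample table for a genotype matrix whose rownames encode breed
make_samples <- function(geno, breeds, groups) {
  breed <- sub("_.*$", "", rownames(geno))
  data.frame(sample = rownames(geno), breed = breed,
             group = groups[match(breed, breeds)],
             category = ifelse(groups[match(breed, breeds)] == "Cosmopolitan",
                               "cosmopolitan", "indigenous"),
             stringsAsFactors = FALSE)
}

extdata <- function(name) system.file("extdata", name, package = "rohscan")

# small three-breed panel with a shared island region, written in PLINK
# binary form with sample table and gene annotation, ready for run_pipeline
pipeline_fixture <- function(dir, seed = 29L) {
  p <- sim_params(
    n_chromosomes = 2L, markers_per_chromosome = 800L,
    chromosome_length_bp = 4e7,
    breeds = c("REFB", "INDA", "COSA"),
    breed_groups = c("American", "Asian", "Cosmopolitan"),
    individuals_per_breed = 8L,
    tract_spec = list(
      # an island region shared by reference and indigenous carriers
      list(breed = "REFB", fraction = 0.9, chr = 1L, start_bp = 1e7,
           length_mb = 6),
      list(breed = "INDA", fraction = 0.9, chr = 1L, start_bp = 1.1e7,
           length_mb = 6),
      list(breed = "COSA", fraction = 0.9, chr = 2L, start_bp = 2e7,
           length_mb = 6)),
    seed = seed)
  sim <- simulate_panel(p)
  pre <- file.path(dir, "panel")
  write_bed_bim_fam(sim$geno, sim$map, pre,
                    fam = data.frame(fid = sim$samples$breed,
                                     iid = sim$samples$sample,
                                     pat = "0", mat = "0", sex = "0",
                                     pheno = "-9"))
  st <- file.path(dir, "samples.tsv")
  utils::write.table(sim$samples, st, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  # gene annotation fixture matching the simulated coordinate system
  gff <- file.path(dir, "genes.gff3")
  writeLines(c("##gff-version 3",
               "1\tsyn\tgene\t12000000\t12100000\t.\t+\t.\tID=gA;Name=GENEA",
               "1\tsyn\tgene\t30000000\t30100000\t.\t+\t.\tID=gB;Name=GENEB",
               "2\tsyn\tgene\t21000000\t21050000\t.\t-\t.\tID=gC;Name=GENEC"),
             gff)
  pipeline_config(genotype_prefix = pre, sample_table_path = st,
                  gff_path = gff, out_dir = file.path(dir, "out"),
                  reference_population = "REFB", seed = seed)
}

# segments fabricated from a per-breed class-count table: one representative
# length per class, one synthetic carrier individual per breed
segments_from_class_counts <- function(counts) {
  rep_len_bp <- c(`1-5` = 3e6, `5-10` = 7e6, `10-20` = 15e6,
                  `20-40` = 30e6, `>40` = 45e6)
  rows <- list()
  for (r in seq_len(nrow(counts))) {
    for (cl in names(rep_len_bp)) {
      k <- counts[[cl]][r]
      if (k == 0) next
      rows[[length(rows) + 1L]] <- data.frame(
        sample = paste0(counts$breed[r], "_ix"), chr = 1L,
        start = 1, end = rep_len_bp[[cl]], n_snps = 100L,
        length_bp = rep(rep_len_bp[[cl]], k), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
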