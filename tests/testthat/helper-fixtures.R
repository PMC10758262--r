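# Fixtures are built in code; nothing is read from disk except files the
# tests themselves write to tempdir().

# Minimal HaplotypeMatrix from a binary matrix and variant positions.
mk_h <- function(values, pos, chrom = "chr1") {
  values <- as.matrix(values)
  storage.mode(values) <- "integer"
  n <- nrow(values)
  stopifnot(n %% 2 == 0, length(pos) == ncol(values))
  samples <- sprintf("S%03d", seq_len(n / 2))
  sample_ids <- data.frame(sample = rep(samples, each = 2),
                           haplotype = rep(1:2, n / 2),
                           stringsAsFactors = FALSE)
  rownames(values) <- paste0(sample_ids$sample, "_", sample_ids$haplotype)
  structure(list(
    values = values,
    variants = data.frame(chrom = rep_len(chrom, ncol(values)),
                          pos = as.integer(pos), ref_alt = "A>T",
                          maf = colMeans(values), missing = 0L,
                          stringsAsFactors = FALSE),
    sample_ids = sample_ids), class = "HaplotypeMatrix")
}

# The six-haplotype worked example: region A's rare alleles sit on haplotypes
# 1 and 4, region B's carriers are haplotypes 3, 4, 5 (two variants).
toy_fig1 <- function() {
  vals <- cbind(c(1, 0, 0, 1, 0, 0),   # region A variant, carriers {1, 4}
                c(0, 0, 1, 1, 0, 0),   # region B variant 1, carriers {3, 4}
                c(0, 0, 0, 0, 1, 0))   # region B variant 2, carrier {5}
  list(h = mk_h(vals, pos = c(150L, 310L, 350L)),
       regions = as_region_set(data.frame(
         name = c("A", "B"), chrom = "chr1",
         start = c(100L, 300L), end = c(200L, 400L),
         stringsAsFactors = FALSE)))
}

# CarrierProfile straight from an indicator vector (bypasses regions).
mk_profile <- function(ind, name = "R") {
  structure(list(region_name = name, indicator = as.integer(ind),
                 cmaf = mean(ind)), class = "CarrierProfile")
}

# Random polymorphic binary vector of length n.
rand_ind <- function(n, p = NULL) {
  if (is.null(p)) p <- stats::runif(1, 0.1, 0.9)
  repeat {
    x <- stats::rbinom(n, 1, p)
    if (any(x == 1) && any(x == 0)) return(x)
  }
}

# Write a small VCF from header lines + body rows (character vectors).
write_vcf_lines <- function(body, samples = c("S1", "S2", "S3")) {
  path <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", samples), collapse = "\t"),
               body), path)
  path
}

# r2 of two binary vectors via the squared Pearson correlation (the
# independent oracle for the moment-form statistic).
cor2 <- function(x, y) suppressWarnings(stats::cor(x, y))^2
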