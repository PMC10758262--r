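#' Load phased haplotypes from a VCF file
#'
#' Reads phased genotypes (GT fields with `|` separators) into a binary
#' haplotype-by-variant matrix with two rows per diploid sample. Alleles are
#' re-oriented so that the stored allele (coded 1) is the minor allele in the
#' loaded sample; multi-allelic sites are expanded into one binary column per
#' alternate allele; missing alleles are recorded as 0 (non-carrier) and
#' counted per variant.
#'
#' @param vcf_path Path to a VCF file (plain text or gzipped).
#' @param samples Optional character vector of sample IDs to keep. IDs absent
#'   from the VCF are an error.
#' @param chrom_filter Optional single chromosome name; only records on that
#'   chromosome are loaded.
#' @param verbose Print a per-variant missingness summary when missing alleles
#'   are encountered.
#' @return A `HaplotypeMatrix`: a list with elements
#'   \describe{
#'     \item{values}{binary matrix, haplotypes x variants}
#'     \item{variants}{data.frame with `chrom`, `pos` (0-based), `ref_alt`,
#'       `maf`, `missing`}
#'     \item{sample_ids}{data.frame mapping rows to (sample, haplotype index)}
#'   }
#'   Positions are converted to 0-based coordinates on load; BED-style
#'   half-open intervals can then be intersected directly.
#' @export
load_haplotypes <- function(vcf_path, samples = NULL, chrom_filter = NULL,
                            verbose = FALSE) {
  if (!file.exists(vcf_path)) stop("VCF file not found: ", vcf_path)
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- t(fix)   # single-record VCF
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT", convertNA = FALSE)
  if (is.null(gt)) stop("VCF contains no genotype columns")
  if (!is.matrix(gt))
    gt <- matrix(gt, nrow = nrow(fix), dimnames = list(NULL, names(gt)))
  if (ncol(gt) == 0) stop("VCF contains no genotype columns")
  if (!is.null(chrom_filter)) {
    keep <- fix$CHROM == chrom_filter
    fix <- fix[keep, , drop = FALSE]
    gt <- gt[keep, , drop = FALSE]
    if (nrow(fix) == 0) stop("no records on chromosome ", chrom_filter)
  }
  if (!is.null(samples)) {
    missing_ids <- setdiff(samples, colnames(gt))
    if (length(missing_ids))
      stop("sample ID(s) not in VCF: ", paste(missing_ids, collapse = ", "))
    gt <- gt[, samples, drop = FALSE]
  }
  bad <- which(grepl("/", gt, fixed = TRUE))
  if (length(bad)) {
    v <- ((bad[1] - 1) %% nrow(gt)) + 1
    s <- ((bad[1] - 1) %/% nrow(gt)) + 1
    stop(sprintf("unphased genotype '%s' at %s:%s sample %s (phased '|' data required)",
                 gt[bad[1]], fix$CHROM[v], fix$POS[v], colnames(gt)[s]))
  }
  n_samp <- ncol(gt)
  n_var <- nrow(gt)
  a1 <- suppressWarnings(matrix(as.integer(sub("\\|.*$", "", gt)), n_var, n_samp))
  a2 <- suppressWarnings(matrix(as.integer(sub("^.*\\|", "", gt)), n_var, n_samp))
  # haplotype rows interleaved: sample 1 hap 1, sample 1 hap 2, sample 2 hap 1, ...
  alleles <- matrix(NA_integer_, 2L * n_samp, n_var)
  alleles[seq(1L, 2L * n_samp, by = 2L), ] <- t(a1)
  alleles[seq(2L, 2L * n_samp, by = 2L), ] <- t(a2)

  cols <- list()
  meta <- list()
  for (v in seq_len(n_var)) {
    alts <- strsplit(fix$ALT[v], ",", fixed = TRUE)[[1]]
    av <- alleles[, v]
    n_miss <- sum(is.na(av))
    for (ai in seq_along(alts)) {
      col <- as.integer(!is.na(av) & av == ai)   # missing counts as major
      f <- mean(col)
      flipped <- f > 0.5                          # ties keep the ALT allele
      if (flipped) col <- 1L - col
      ra <- if (flipped) paste0(alts[ai], ">", fix$REF[v])
            else paste0(fix$REF[v], ">", alts[ai])
      cols[[length(cols) + 1L]] <- col
      meta[[length(meta) + 1L]] <- data.frame(
        chrom = fix$CHROM[v], pos = as.integer(fix$POS[v]) - 1L,
        ref_alt = ra, maf = mean(col), missing = n_miss,
        stringsAsFactors = FALSE)
    }
  }
  variants <- do.call(rbind, meta)
  values <- do.call(cbind, cols)
  if (verbose && any(variants$missing > 0)) {
    mm <- variants[variants$missing > 0, c("chrom", "pos", "missing")]
    message(sum(mm$missing), " missing allele(s) coded as major across ",
            nrow(mm), " variant column(s)")
  }
  sample_ids <- data.frame(
    sample = rep(colnames(gt), each = 2L),
    haplotype = rep(1:2, n_samp), stringsAsFactors = FALSE)
  rownames(values) <- paste0(sample_ids$sample, "_", sample_ids$haplotype)
  structure(list(values = values, variants = variants, sample_ids = sample_ids),
            class = "HaplotypeMatrix")
}

#' @export
print.HaplotypeMatrix <- function(x, ...) {
  cat("HaplotypeMatrix:", nrow(x$values), "haplotypes x",
      ncol(x$values), "variants\n")
  cat("  chromosomes:", paste(unique(x$variants$chrom), collapse = ", "), "\n")
  cat("  MAF range: [", signif(min(x$variants$maf), 3), ",",
      signif(max(x$variants$maf), 3), "]\n")
  invisible(x)
}

#' Load region definitions from a BED file
#'
#' Reads a BED4+ file (chrom, start, end, name) into a `RegionSet`. BED is
#' already 0-based half-open, which is the internal convention. Regions are
#' sorted by (chrom, start); duplicate names and empty intervals are rejected.
#' Overlapping regions are permitted.
#'
#' @param bed_path Path to a BED file with at least 4 columns.
#' @return A `RegionSet` data.frame with columns `name`, `chrom`, `start`, `end`.
#' @export
load_regions <- function(bed_path) {
  if (!file.exists(bed_path)) stop("BED file not found: ", bed_path)
  df <- utils::read.table(bed_path, header = FALSE, sep = "",
                          stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(df) < 4) stop("BED file must have >= 4 columns (chrom, start, end, name)")
  regions <- data.frame(name = as.character(df[[4]]), chrom = as.character(df[[1]]),
                        start = as.integer(df[[2]]), end = as.integer(df[[3]]),
                        stringsAsFactors = FALSE)
  as_region_set(regions)
}

#' Build a RegionSet from a data.frame
#'
#' @param regions data.frame with columns `name`, `chrom`, `start`, `end`
#'   (0-based half-open).
#' @return A sorted, validated `RegionSet`.
#' @export
as_region_set <- function(regions) {
  stopifnot(all(c("name", "chrom", "start", "end") %in% names(regions)))
  if (any(regions$start >= regions$end))
    stop("region(s) with start >= end: ",
         paste(regions$name[regions$start >= regions$end], collapse = ", "))
  if (anyDuplicated(regions$name))
    stop("duplicate region name(s): ",
         paste(unique(regions$name[duplicated(regions$name)]), collapse = ", "))
  regions <- regions[order(regions$chrom, regions$start), , drop = FALSE]
  rownames(regions) <- NULL
  structure(regions[, c("name", "chrom", "start", "end")],
            class = c("RegionSet", "data.frame"))
}

#' Filter a HaplotypeMatrix to rare polymorphic variants
#'
#' Retains exactly the variant columns with `0 < MAF < maf_cutoff` (strict
#' inequalities); monomorphic columns are always dropped. MAFs are recomputed
#' from the current matrix, so the operation is idempotent.
#'
#' @param h A `HaplotypeMatrix`.
#' @param maf_cutoff Maximum minor allele frequency, in (0, 0.5]. Default 0.005
#'   (0.5%), the conventional rare-variant threshold.
#' @return A `HaplotypeMatrix` with the retained columns (possibly none, with
#'   a warning).
#' @export
filter_rare <- function(h, maf_cutoff = 0.005) {
  stopifnot(inherits(h, "HaplotypeMatrix"), maf_cutoff > 0, maf_cutoff <= 0.5)
  maf <- colMeans(h$values)
  keep <- maf > 0 & maf < maf_cutoff
  if (!any(keep)) warning("no variants with 0 < MAF < ", maf_cutoff,
                          "; returning an empty matrix")
  h$values <- h$values[, keep, drop = FALSE]
  h$variants <- h$variants[keep, , drop = FALSE]
  h$variants$maf <- colMeans(h$values)
  rownames(h$variants) <- NULL
  h
}

#' Write a HaplotypeMatrix to a phased VCF file
#'
#' Inverse of [load_haplotypes()] for matrices whose stored allele is minor
#' (column frequency <= 0.5): each binary column becomes one biallelic record
#' with the stored allele written as ALT, so that write-then-read round-trips
#' the matrix exactly.
#'
#' @param h A `HaplotypeMatrix`.
#' @param vcf_path Output path.
#' @return `vcf_path`, invisibly.
#' @export
write_haplotypes <- function(h, vcf_path) {
  stopifnot(inherits(h, "HaplotypeMatrix"))
  v <- h$variants
  ra <- strsplit(v$ref_alt, ">", fixed = TRUE)
  ref <- vapply(ra, `[`, "", 1)
  alt <- vapply(ra, `[`, "", 2)
  n_samp <- nrow(h$sample_ids) / 2
  i1 <- seq(1L, 2L * n_samp, by = 2L)
  gt <- matrix("", ncol(h$values), n_samp)
  for (s in seq_len(n_samp))
    gt[, s] <- paste0(h$values[i1[s], ], "|", h$values[i1[s] + 1L, ])
  samp_names <- unique(h$sample_ids$sample)
  header <- c("##fileformat=VCFv4.2",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samp_names), collapse = "\t"))
  body <- apply(cbind(v$chrom, v$pos + 1L, ".", ref, alt, ".", "PASS", ".",
                      "GT", gt), 1, paste, collapse = "\t")
  # VCF records must be coordinate-sorted
  ord <- order(v$chrom, v$pos)
  writeLines(c(header, body[ord]), vcf_path)
  invisible(vcf_path)
}

#' Write a per-variant summary table
#'
#' Emits a TSV with columns chrom, pos (0-based), ref_alt, maf, missing_count.
#'
#' @param h A `HaplotypeMatrix`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_variant_summary <- function(h, path) {
  stopifnot(inherits(h, "HaplotypeMatrix"))
  df <- h$variants
  names(df)[names(df) == "missing"] <- "missing_count"
  .write_tsv(df, path)
}
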