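#' Phased haplotype panel
#'
#' Container for a phased, biallelic, ancestral/derived-polarized haplotype
#' panel: a haplotype-by-site 0/1 matrix (0 = ancestral, 1 = derived,
#' `NA` = missing), strictly increasing 1-based physical positions, sample
#' identifiers and a population label per sample. Rows `2i - 1` and `2i` are
#' the two phased haplotypes of diploid sample `i`.
#'
#' @param haps integer matrix, haplotypes x sites, values 0/1/NA.
#' @param positions numeric vector of 1-based bp positions, strictly
#'   increasing, one per site.
#' @param samples character vector of sample ids (one per diploid).
#' @param populations character vector of population labels, one per sample.
#' @param chrom chromosome identifier.
#' @return An object of class `haplotype_panel`.
#' @export
haplotype_panel <- function(haps, positions, samples, populations,
                            chrom = "1") {
  haps <- as.matrix(haps)
  storage.mode(haps) <- "integer"
  positions <- as.numeric(positions)
  if (ncol(haps) != length(positions))
    stop("number of sites does not match number of positions")
  if (nrow(haps) != 2L * length(samples))
    stop("haplotype rows must be 2 x sample count (diploid phased data)")
  if (length(populations) != length(samples))
    stop("one population label per sample required")
  if (length(positions) && (any(positions < 1) ||
                            any(diff(positions) <= 0)))
    stop("positions must be 1-based and strictly increasing")
  bad <- haps[!is.na(haps)]
  if (length(bad) && !all(bad %in% c(0L, 1L)))
    stop("alleles must be 0 (ancestral), 1 (derived) or NA")
  structure(list(haps = haps, positions = positions,
                 samples = as.character(samples),
                 populations = as.character(populations),
                 chrom = as.character(chrom)),
            class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat("Phased haplotype panel\n")
  cat(sprintf("  chrom %s: %d sites, %d haplotypes (%d diploid samples)\n",
              x$chrom, ncol(x$haps), nrow(x$haps), length(x$samples)))
  tb <- table(x$populations)
  cat("  populations:",
      paste(sprintf("%s (%d)", names(tb), as.integer(tb)), collapse = ", "),
      "\n")
  if (length(x$positions))
    cat(sprintf("  span: %s-%s bp\n", format(min(x$positions), big.mark = ","),
                format(max(x$positions), big.mark = ",")))
  invisible(x)
}

#' Number of sites / haplotypes of a panel
#' @param panel a [haplotype_panel()].
#' @return integer count.
#' @export
n_sites <- function(panel) ncol(panel$haps)

#' @rdname n_sites
#' @export
n_haplotypes <- function(panel) nrow(panel$haps)

#' Derived allele frequency per site
#'
#' @param panel a [haplotype_panel()].
#' @return numeric vector of derived-allele frequencies (missing calls are
#'   dropped from the denominator).
#' @export
derived_freq <- function(panel) {
  colMeans(panel$haps, na.rm = TRUE)
}

#' Subset a panel to one population
#'
#' @param panel a [haplotype_panel()].
#' @param population population label to keep.
#' @param drop_monomorphic drop sites monomorphic within the subset?
#' @return a [haplotype_panel()] restricted to the samples of `population`.
#' @export
subset_population <- function(panel, population, drop_monomorphic = FALSE) {
  keep <- panel$populations == population
  if (!any(keep)) stop("unknown population: ", population)
  rows <- rep(keep, each = 2L)
  haps <- panel$haps[rows, , drop = FALSE]
  pos <- panel$positions
  if (drop_monomorphic && ncol(haps)) {
    f <- colMeans(haps, na.rm = TRUE)
    poly <- !is.na(f) & f > 0 & f < 1
    haps <- haps[, poly, drop = FALSE]
    pos <- pos[poly]
  }
  haplotype_panel(haps, pos, panel$samples[keep], panel$populations[keep],
                  panel$chrom)
}

#' Write a panel as phased VCF plus a population map
#'
#' Emits a VCF 4.2 file with phased `GT` fields and an `INFO` `AA` tag
#' carrying the ancestral base (REF is written as the ancestral allele), and
#' a two-column tab-separated population map (`sample_id`, `population`).
#'
#' @param panel a [haplotype_panel()].
#' @param vcf_file output VCF path (plain text; use a `.gz` suffix to
#'   compress).
#' @param popmap_file output popmap TSV path, or `NULL` to skip.
#' @return invisibly, `vcf_file`.
#' @export
write_panel_vcf <- function(panel, vcf_file, popmap_file = NULL) {
  S <- n_sites(panel)
  ns <- length(panel$samples)
  meta <- c("##fileformat=VCFv4.2",
            "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
            "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
            paste0("##contig=<ID=", panel$chrom, ">"))
  fix <- matrix("", nrow = S, ncol = 8,
                dimnames = list(NULL, c("CHROM", "POS", "ID", "REF", "ALT",
                                        "QUAL", "FILTER", "INFO")))
  fix[, "CHROM"] <- panel$chrom
  fix[, "POS"] <- format(panel$positions, scientific = FALSE, trim = TRUE)
  fix[, "ID"] <- paste0("site", seq_len(max(S, 0)))
  fix[, "REF"] <- "A"
  fix[, "ALT"] <- "T"
  fix[, "QUAL"] <- "."
  fix[, "FILTER"] <- "PASS"
  fix[, "INFO"] <- "AA=A"
  a1 <- panel$haps[seq(1, 2 * ns, by = 2), , drop = FALSE]
  a2 <- panel$haps[seq(2, 2 * ns, by = 2), , drop = FALSE]
  fmt <- function(m) { m[is.na(m)] <- "."; m }
  gt <- matrix(paste0(fmt(t(a1)), "|", fmt(t(a2))), nrow = S, ncol = ns)
  colnames(gt) <- panel$samples
  gt <- cbind(FORMAT = rep("GT", S), gt)
  vcf <- methods::new(methods::getClassDef("vcfR", package = "vcfR"),
                      meta = meta, fix = fix, gt = gt)
  vcfR::write.vcf(vcf, file = vcf_file)
  if (!is.null(popmap_file))
    write_popmap(panel$samples, panel$populations, popmap_file)
  invisible(vcf_file)
}

#' @rdname write_panel_vcf
#' @param samples,populations sample ids and matching population labels.
#' @param file popmap output path.
#' @export
write_popmap <- function(samples, populations, file) {
  write.table(data.frame(sample_id = samples, population = populations),
              file, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(file)
}

#' Read a phased VCF and population map into a haplotype panel
#'
#' Genotypes must be phased (`|`). Alleles are polarized against the `AA`
#' INFO tag: the allele matching the ancestral base becomes 0. Sites whose
#' `AA` tag is absent or matches neither allele are dropped with a warning.
#'
#' @param vcf_file path to a VCF (optionally gzipped).
#' @param popmap_file path to a `sample_id<TAB>population` file (no header),
#'   or `NULL` to label every sample `"pop1"`.
#' @return a [haplotype_panel()].
#' @export
read_panel_vcf <- function(vcf_file, popmap_file = NULL) {
  vcf <- vcfR::read.vcfR(vcf_file, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1,
                                     dimnames = list(NULL, names(gt)))
  samples <- colnames(gt)
  aa <- vcfR::extract.info(vcf, element = "AA")
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  pos <- as.numeric(fix[, "POS"])
  chrom <- fix[1, "CHROM"]

  ok <- !is.na(aa) & (aa == ref | aa == alt)
  if (!all(ok)) warning(sum(!ok), " site(s) without usable AA tag dropped")
  gt <- gt[ok, , drop = FALSE]; pos <- pos[ok]
  flip <- aa[ok] == alt[ok]   # ALT is ancestral: swap polarity

  if (any(grepl("/", gt, fixed = TRUE)))
    stop("unphased genotypes found; phased (|) genotypes are required")
  a1 <- sub("\\|.*", "", gt); a2 <- sub(".*\\|", "", gt)
  parse_allele <- function(m) {
    v <- suppressWarnings(as.integer(m))
    matrix(v, nrow = nrow(gt))
  }
  m1 <- parse_allele(a1); m2 <- parse_allele(a2)
  if (any(flip)) {
    m1[flip, ] <- 1L - m1[flip, ]
    m2[flip, ] <- 1L - m2[flip, ]
  }
  haps <- matrix(NA_integer_, nrow = 2 * length(samples), ncol = length(pos))
  haps[seq(1, nrow(haps), by = 2), ] <- t(m1)
  haps[seq(2, nrow(haps), by = 2), ] <- t(m2)

  if (!is.null(popmap_file)) {
    pm <- read.table(popmap_file, sep = "\t", header = FALSE,
                     col.names = c("sample_id", "population"),
                     colClasses = "character")
    idx <- match(samples, pm$sample_id)
    if (anyNA(idx)) stop("samples missing from popmap: ",
                         paste(samples[is.na(idx)], collapse = ", "))
    pops <- pm$population[idx]
  } else pops <- rep("pop1", length(samples))

  ord <- order(pos)
  haplotype_panel(haps[, ord, drop = FALSE], pos[ord], samples, pops, chrom)
}
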