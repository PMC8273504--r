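#' Export the final polymorphism as VCF
#'
#' Writes a VCF 4.2 file with one record per segregating site (diploid
#' phased GT per individual; REF = ancestral `A`, ALT = derived `T`;
#' arbitrary nucleotides, since the model tracks derived-allele presence
#' only).  Each individual's sex is recorded in `##SAMPLE=` header lines,
#' and the SD position in a `##sd_position=` line.  Requires the `vcfR`
#' package.
#'
#' @param pop A `sim_population`.
#' @param path Output path; `vcfR::write.vcf` gzip-compresses, so a
#'   `.vcf.gz` suffix is conventional.
#' @return `path`, invisibly.
#' @export
write_population_vcf <- function(pop, path) {
  stopifnot(inherits(pop, "sim_population"))
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("VCF export requires the `vcfR` package", call. = FALSE)
  N <- length(pop$sexes)
  S <- length(pop$site_positions)
  samples <- sprintf("ind%03d_%s", seq_len(N), substr(pop$sexes, 1, 1))
  gt <- matrix("0|0", nrow = S, ncol = N + 1L,
               dimnames = list(NULL, c("FORMAT", samples)))
  gt[, 1L] <- "GT"
  for (j in seq_len(N)) {
    a <- pop$haplotypes[2L * j - 1L, ]
    b <- pop$haplotypes[2L * j, ]
    gt[, j + 1L] <- paste0(a, "|", b)
  }
  fix <- cbind(
    CHROM = "sim", POS = as.character(pop$site_positions + 1L),
    ID = ifelse(pop$site_positions == pop$sd_position & !is.na(pop$sd_position),
                "SD", "."),
    REF = "A", ALT = "T", QUAL = ".", FILTER = "PASS",
    INFO = paste0("AC=", colSums(pop$haplotypes), ";AN=", 2L * N)
  )
  meta <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=sim,length=%d>", pop$L),
    sprintf("##sd_position=%s",
            if (is.na(pop$sd_position)) "NA" else pop$sd_position + 1L),
    "##INFO=<ID=AC,Number=A,Type=Integer,Description=\"Derived allele count\">",
    "##INFO=<ID=AN,Number=1,Type=Integer,Description=\"Allele number\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    sprintf("##SAMPLE=<ID=%s,Sex=%s>", samples, pop$sexes)
  )
  v <- new("vcfR", meta = meta, fix = fix, gt = gt)
  vcfR::write.vcf(v, file = path)
  invisible(path)
}
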