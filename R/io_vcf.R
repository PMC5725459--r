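#' Read a multi-sample SNP VCF into a population call set
#'
#' Parses a VCF 4.x file with [vcfR::read.vcfR()], keeps biallelic SNP
#' records only (indels, multiallelic and symbolic records are skipped and
#' counted), and records per-sample alternative-allele presence: a sample is
#' alt-present at a site when its genotype carries at least one copy of the
#' alternative allele. INFO keys `QD`, `MQ`, `FS` and the simplified effect
#' annotation keys (`EFF`, `IMP`, `GENE`, `AAP`, `AAR`, `AAA`) are parsed
#' when present.
#'
#' @param path Path to a VCF file (plain or gzipped).
#' @param population_labels Named character vector mapping every sample name
#'   in the VCF to its population (e.g. subpopulation `"LT"`, `"ST"`, `"NT"`
#'   or a breed name). A sample without a label is an error naming it.
#' @return A list of class `population_callset` with elements:
#'   `variants` (data frame: chrom, pos, ref, alt, qual, qd, mq, fs,
#'   effect_class, impact, gene_id, protein_position, ref_aa, alt_aa),
#'   `geno` (logical matrix, sites x samples, alt-presence),
#'   `samples`, `population` (named vector sample -> population) and
#'   `skipped` (named counts of excluded records).
#' @export
read_vcf_cohort <- function(path, population_labels) {
  vcf <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  gt <- vcf@gt
  samples <- colnames(gt)[-1]
  missing <- setdiff(samples, names(population_labels))
  if (length(missing)) {
    stop("unlabelled sample(s) in VCF: ", paste(missing, collapse = ", "))
  }
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  is_snp <- !is.na(alt) & nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  multi <- grepl(",", alt, fixed = TRUE)
  skipped <- c(multiallelic = sum(multi),
               non_snp = sum(!is_snp & !multi))
  if (sum(skipped) > 0) {
    message(sum(skipped), " non-biallelic-SNP record(s) skipped (",
            skipped[["multiallelic"]], " multiallelic, ",
            skipped[["non_snp"]], " other)")
  }
  keep <- which(is_snp & !multi)
  info_num <- function(key) {
    v <- suppressWarnings(vcfR::extract.info(vcf, element = key, as.numeric = TRUE))
    if (is.null(v)) rep(NA_real_, nrow(fix)) else v
  }
  info_chr <- function(key) {
    v <- vcfR::extract.info(vcf, element = key)
    if (is.null(v)) rep(NA_character_, nrow(fix)) else v
  }
  variants <- data.frame(
    chrom = fix[keep, "CHROM"],
    pos = as.integer(fix[keep, "POS"]),
    ref = ref[keep],
    alt = alt[keep],
    qual = suppressWarnings(as.numeric(fix[keep, "QUAL"])),
    qd = info_num("QD")[keep],
    mq = info_num("MQ")[keep],
    fs = info_num("FS")[keep],
    effect_class = info_chr("EFF")[keep],
    impact = info_chr("IMP")[keep],
    gene_id = info_chr("GENE")[keep],
    protein_position = suppressWarnings(as.integer(info_chr("AAP")[keep])),
    ref_aa = info_chr("AAR")[keep],
    alt_aa = info_chr("AAA")[keep],
    stringsAsFactors = FALSE
  )
  gt_sub <- gt[keep, -1, drop = FALSE]
  # alt-presence: genotype string contains a "1" allele before the colon
  allele_part <- sub(":.*$", "", gt_sub)
  geno <- matrix(grepl("1", allele_part), nrow = length(keep),
                 dimnames = list(NULL, samples))
  geno[is.na(gt_sub)] <- FALSE
  structure(list(variants = variants,
                 geno = geno,
                 samples = samples,
                 population = population_labels[samples],
                 skipped = skipped),
            class = "population_callset")
}

#' Write a population call set as a plain-text VCF
#'
#' Emits a minimal VCF 4.2 with GT genotypes (`0/1` for alt carriers, `0/0`
#' otherwise) and the INFO keys used by this pipeline (`QD`, `MQ`, `FS` and
#' the simplified effect annotation). Round-trips through
#' [read_vcf_cohort()].
#'
#' @param callset A `population_callset`.
#' @param path Output path.
#' @export
write_callset <- function(callset, path) {
  v <- callset$variants
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Quality by depth\">",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"Mapping quality\">",
    "##INFO=<ID=FS,Number=1,Type=Float,Description=\"Fisher strand bias\">",
    "##INFO=<ID=EFF,Number=1,Type=String,Description=\"Effect class\">",
    "##INFO=<ID=IMP,Number=1,Type=String,Description=\"Impact\">",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene id\">",
    "##INFO=<ID=AAP,Number=1,Type=Integer,Description=\"Protein position\">",
    "##INFO=<ID=AAR,Number=1,Type=String,Description=\"Reference residue\">",
    "##INFO=<ID=AAA,Number=1,Type=String,Description=\"Alternative residue\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", callset$samples), collapse = "\t")
  )
  info_field <- function(key, val, fmt = "%s") {
    ifelse(is.na(val), NA_character_, sprintf(paste0(key, "=", fmt), val))
  }
  info_parts <- cbind(info_field("QD", v$qd, "%g"),
                      info_field("MQ", v$mq, "%g"),
                      info_field("FS", v$fs, "%g"),
                      info_field("EFF", v$effect_class),
                      info_field("IMP", v$impact),
                      info_field("GENE", v$gene_id),
                      info_field("AAP", v$protein_position, "%d"),
                      info_field("AAR", v$ref_aa),
                      info_field("AAA", v$alt_aa))
  info <- apply(info_parts, 1, function(row) {
    row <- row[!is.na(row)]
    if (length(row)) paste(row, collapse = ";") else "."
  })
  if (nrow(v) == 0) info <- character(0)
  gts <- matrix("0/0", nrow = nrow(v), ncol = length(callset$samples))
  gts[callset$geno] <- "0/1"
  gt_str <- if (nrow(v)) apply(gts, 1, paste, collapse = "\t") else character(0)
  body <- if (nrow(v)) {
    paste(v$chrom, v$pos, ".", v$ref, v$alt,
          ifelse(is.na(v$qual), ".", format(v$qual, trim = TRUE, digits = 10)),
          "PASS", info, "GT", gt_str, sep = "\t")
  } else character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @export
print.population_callset <- function(x, ...) {
  cat(sprintf("population_callset: %d SNP sites x %d samples (%s)\n",
              nrow(x$variants), length(x$samples),
              paste(sprintf("%s=%d", names(table(x$population)),
                            as.integer(table(x$population))), collapse = ", ")))
  invisible(x)
}
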