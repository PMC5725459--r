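COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

# Translate one codon with the standard genetic code.
codon_aa <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[[codon]]
  if (is.null(aa)) stop("invalid codon: ", codon)
  aa
}

#' Classify the coding effect of a SNP against one gene model
#'
#' Applies the standard genetic code to the codon containing the variant:
#' minus-strand variants are complemented before the codon substitution, and
#' the effect is `synonymous` exactly when the translated residue is
#' unchanged. Positions outside the coding exons are classified by region:
#' `splice_site` within 2 bp of an exon/intron boundary on the intron side,
#' otherwise `intron` between exons, `UTR` inside the transcript span but
#' outside the coding exons, and `intergenic` outside the transcript span.
#'
#' @param variant List or one-row data frame with `pos`, `ref`, `alt`
#'   (genomic sense, single bases).
#' @param gene_model A [gene_model()].
#' @param coding_sequence The gene's CDS as a character string (transcript
#'   sense, 5'->3', length divisible by 3).
#' @return List with `effect_class`, `ref_aa`, `alt_aa`, `protein_position`
#'   (the amino-acid fields are `NA` for non-coding classes).
#' @export
classify_coding_effect <- function(variant, gene_model, coding_sequence) {
  pos <- as.integer(variant$pos)
  ref <- as.character(variant$ref)
  alt <- as.character(variant$alt)
  gm <- gene_model
  non_coding <- function(cls) {
    list(effect_class = cls, ref_aa = NA_character_, alt_aa = NA_character_,
         protein_position = NA_integer_)
  }
  if (pos < gm$tx_start || pos > gm$tx_end) return(non_coding("intergenic"))
  in_exon <- any(pos >= gm$exon_start & pos <= gm$exon_end)
  if (!in_exon) {
    first <- min(gm$exon_start); last <- max(gm$exon_end)
    if (pos < first || pos > last) return(non_coding("UTR"))
    # intronic: splice region within 2 bp of the flanking exon boundaries
    d_left <- pos - gm$exon_end[gm$exon_end < pos]
    d_right <- gm$exon_start[gm$exon_start > pos] - pos
    if (min(c(d_left, d_right)) <= 2L) return(non_coding("splice_site"))
    return(non_coding("intron"))
  }
  c_pos <- genomic_to_cds(gm, pos)
  if (is.na(c_pos)) return(non_coding("UTR"))  # pre-frame exonic bases
  codon_idx <- (c_pos - 1L) %/% 3L + 1L
  in_codon <- c_pos - 3L * (codon_idx - 1L)
  codon <- substr(coding_sequence, 3L * codon_idx - 2L, 3L * codon_idx)
  if (nchar(codon) != 3L) stop("coding_sequence shorter than gene model implies")
  ref_t <- if (gm$strand == "+") ref else unname(COMPLEMENT[ref])
  alt_t <- if (gm$strand == "+") alt else unname(COMPLEMENT[alt])
  if (substr(codon, in_codon, in_codon) != ref_t) {
    stop("reference allele inconsistent with coding sequence at ",
         gm$gene_id, ":", pos)
  }
  alt_codon <- codon
  substr(alt_codon, in_codon, in_codon) <- alt_t
  ref_aa <- codon_aa(codon)
  alt_aa <- codon_aa(alt_codon)
  list(effect_class = if (ref_aa == alt_aa) "synonymous" else "non_synonymous",
       ref_aa = ref_aa, alt_aa = alt_aa, protein_position = codon_idx)
}

EFFECT_SEVERITY <- c(non_synonymous = 1L, synonymous = 1L, splice_site = 2L,
                     UTR = 3L, intron = 4L, intergenic = 5L)

# Pick the most severe class under the fixed precedence
# exonic > splice_site > UTR > intron > intergenic; a non_synonymous call
# outranks a synonymous one at equal severity.
resolve_effect_precedence <- function(classes) {
  if (!length(classes)) return("intergenic")
  sev <- EFFECT_SEVERITY[classes]
  best <- classes[sev == min(sev)]
  if ("non_synonymous" %in% best) "non_synonymous" else best[1]
}

#' Annotate variants against a set of gene models
#'
#' Classifies every variant against each overlapping gene model and resolves
#' multi-gene overlaps by severity precedence (exonic > splice_site > UTR >
#' intron > intergenic). Variants overlapping no transcript are intergenic.
#'
#' @param variants Data frame with `chrom`, `pos`, `ref`, `alt`.
#' @param gene_models Named list of [gene_model()] objects.
#' @param coding_sequences Named character vector/list of CDS strings,
#'   indexed by gene id.
#' @return The input data frame with `effect_class`, `gene_id`,
#'   `protein_position`, `ref_aa`, `alt_aa` columns (re)filled.
#' @export
annotate_variants <- function(variants, gene_models, coding_sequences) {
  n <- nrow(variants)
  eff <- character(n); gid <- rep(NA_character_, n)
  ppos <- rep(NA_integer_, n); raa <- rep(NA_character_, n)
  aaa <- rep(NA_character_, n)
  gm_chrom <- vapply(gene_models, `[[`, "", "chrom")
  for (i in seq_len(n)) {
    cand <- gene_models[gm_chrom == variants$chrom[i]]
    hits <- list()
    for (gm in cand) {
      if (variants$pos[i] < gm$tx_start || variants$pos[i] > gm$tx_end) next
      hits[[length(hits) + 1L]] <-
        c(classify_coding_effect(variants[i, ], gm,
                                 coding_sequences[[gm$gene_id]]),
          gene_id = gm$gene_id)
    }
    if (!length(hits)) { eff[i] <- "intergenic"; next }
    classes <- vapply(hits, `[[`, "", "effect_class")
    win_class <- resolve_effect_precedence(classes)
    win <- hits[[which(classes == win_class)[1]]]
    eff[i] <- win_class
    if (win_class %in% c("non_synonymous", "synonymous")) {
      gid[i] <- win$gene_id; ppos[i] <- win$protein_position
      raa[i] <- win$ref_aa; aaa[i] <- win$alt_aa
    } else if (win_class != "intergenic") {
      gid[i] <- win$gene_id
    }
  }
  variants$effect_class <- eff
  variants$gene_id <- gid
  variants$protein_position <- ppos
  variants$ref_aa <- raa
  variants$alt_aa <- aaa
  variants
}

# Translate a CDS string to its protein (no trailing stop expected).
translate_cds <- function(cds) {
  as.character(Biostrings::translate(Biostrings::DNAString(cds)))
}
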