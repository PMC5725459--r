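#' Read per-gene protein alignments from a directory of FASTA files
#'
#' One aligned FASTA per gene (`<gene_id>.fasta`), gap character `-`,
#' containing a row for the focal species (e.g. `dog`) and one row per
#' related species. All rows of a file must have equal width.
#'
#' @param dir Directory of `.fasta` files.
#' @return Named list of [Biostrings::AAStringSet] objects, keyed by gene id.
#' @export
read_gene_alignments <- function(dir) {
  files <- list.files(dir, pattern = "\\.fasta$", full.names = TRUE)
  alns <- lapply(files, Biostrings::readAAStringSet)
  names(alns) <- sub("\\.fasta$", "", basename(files))
  for (g in names(alns)) {
    if (length(unique(Biostrings::width(alns[[g]]))) > 1) {
      stop("ragged alignment for gene ", g)
    }
  }
  alns
}

#' Write per-gene protein alignments
#'
#' @param alignments Named list of [Biostrings::AAStringSet] objects.
#' @param dir Output directory (created if needed).
#' @export
write_gene_alignments <- function(alignments, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (g in names(alignments)) {
    Biostrings::writeXStringSet(alignments[[g]],
                                file.path(dir, paste0(g, ".fasta")))
  }
  invisible(dir)
}

#' Read a table of per-species alternative residues
#'
#' The related-species variant sets are represented at the protein level:
#' one row per (species, gene, alignment column) with the alternative
#' residue segregating in that species.
#'
#' @param path TSV with header `species`, `gene_id`, `column`, `residue`.
#' @return Data frame.
#' @export
read_species_residues <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  needed <- c("species", "gene_id", "column", "residue")
  if (!all(needed %in% names(df))) {
    stop("species residue table must have columns: ",
         paste(needed, collapse = ", "))
  }
  df
}

#' @rdname read_species_residues
#' @param residues Data frame as returned by [read_species_residues()].
#' @export
write_species_residues <- function(residues, path) {
  write.table(residues, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Map a protein position to its alignment column through the focal row
# (columns where the focal row is non-gap, in order).
protein_pos_to_column <- function(alignment, focal_row, protein_position) {
  chars <- strsplit(as.character(alignment[[focal_row]]), "")[[1]]
  non_gap <- which(chars != "-")
  if (protein_position > length(non_gap)) return(NA_integer_)
  non_gap[protein_position]
}

#' Identify focal-population-specific genes from unique missense SNPs
#'
#' A variant of the focal call set is *focal-unique* when all four
#' conditions hold: (a) it is non-synonymous with HIGH or MODERATE impact;
#' (b) at least one focal individual carries the alternative allele;
#' (c) no comparison breed's call list contains the same alternative allele
#' at the same chrom:pos; (d) no related species shows the focal
#' alternative residue at the aligned protein column, either as its aligned
#' residue or among its own segregating alternative residues (a gap column
#' makes that species non-informative). A gene is focal-specific when it
#' has at least one focal-unique variant; genes whose alignment is missing
#' are flagged unevaluable and excluded.
#'
#' @param focal Focal `population_callset` (samples labelled by
#'   subpopulation).
#' @param comparison_breeds List of `population_callset`s, one per breed.
#' @param alignments Named list of per-gene [Biostrings::AAStringSet]
#'   alignments (focal row named by `focal_row`).
#' @param species_residues Data frame of per-species alternative residues
#'   (see [read_species_residues()]); may be empty.
#' @param focal_row Name of the focal sequence in each alignment
#'   (default `"dog"`).
#' @param impact_levels Impacts accepted by condition (a).
#' @return List with `genes` (character vector of focal-specific gene ids),
#'   `variants` (data frame of supporting focal-unique variants with
#'   per-subpopulation carrier counts), and `unevaluable` (gene ids lacking
#'   an alignment).
#' @export
find_focal_specific_genes <- function(focal, comparison_breeds, alignments,
                                      species_residues = NULL,
                                      focal_row = "dog",
                                      impact_levels = c("HIGH", "MODERATE")) {
  v <- focal$variants
  carriers <- Matrix::rowSums(focal$geno) >= 1
  cand <- which(v$effect_class %in% "non_synonymous" &
                  v$impact %in% impact_levels & carriers)
  if (is.null(species_residues)) {
    species_residues <- data.frame(species = character(), gene_id = character(),
                                   column = integer(), residue = character())
  }
  breed_keys <- unique(unlist(lapply(comparison_breeds, function(cs) {
    paste(cs$variants$chrom, cs$variants$pos, cs$variants$alt)
  })))
  unevaluable <- character(0)
  keep <- logical(length(cand))
  for (k in seq_along(cand)) {
    i <- cand[k]
    gene <- v$gene_id[i]
    if (paste(v$chrom[i], v$pos[i], v$alt[i]) %in% breed_keys) next
    aln <- alignments[[gene]]
    if (is.null(aln)) {
      unevaluable <- union(unevaluable, gene)
      next
    }
    col <- protein_pos_to_column(aln, focal_row, v$protein_position[i])
    if (is.na(col)) {
      unevaluable <- union(unevaluable, gene)
      next
    }
    species <- setdiff(names(aln), focal_row)
    hit <- FALSE
    for (sp in species) {
      res <- substr(as.character(aln[[sp]]), col, col)
      if (res == "-") next  # gap: species non-informative here
      if (res == v$alt_aa[i]) { hit <- TRUE; break }
      alt_res <- species_residues$residue[
        species_residues$species == sp &
          species_residues$gene_id == gene &
          species_residues$column == col]
      if (v$alt_aa[i] %in% alt_res) { hit <- TRUE; break }
    }
    keep[k] <- !hit
  }
  if (length(unevaluable)) {
    message(length(unevaluable), " gene(s) without usable alignment excluded: ",
            paste(head(unevaluable, 5), collapse = ", "),
            if (length(unevaluable) > 5) ", ..." else "")
  }
  idx <- cand[keep]
  subpops <- focal$population
  carrier_count <- function(rows, pop) {
    as.integer(Matrix::rowSums(focal$geno[rows, subpops == pop, drop = FALSE]))
  }
  variants <- cbind(v[idx, c("chrom", "pos", "ref", "alt", "gene_id", "impact",
                             "protein_position", "ref_aa", "alt_aa")],
                    data.frame(carriers_lt = carrier_count(idx, "LT"),
                               carriers_st = carrier_count(idx, "ST"),
                               carriers_nt = carrier_count(idx, "NT")))
  rownames(variants) <- NULL
  list(genes = sort(unique(variants$gene_id)),
       variants = variants,
       unevaluable = unevaluable)
}

#' Partition focal-specific genes by subpopulation carriers
#'
#' A gene is tail-specific when all its focal-unique variants are carried
#' only by long-tail or short-tail individuals, non-tail-specific when
#' carried only by non-tail individuals, and common when its variants are
#' carried in both the tail and the non-tail subpopulations. The three
#' sets are pairwise disjoint and partition the carrier-bearing
#' focal-specific genes.
#'
#' @param specific Result of [find_focal_specific_genes()].
#' @return List of class `gene_classification` with `focal_specific`,
#'   `tail_specific`, `non_tail_specific`, `common` (character vectors) and
#'   `gene_table` (per-gene carrier summary).
#' @export
classify_by_subpopulation <- function(specific) {
  v <- specific$variants
  if (nrow(v) && any(v$carriers_lt + v$carriers_st + v$carriers_nt == 0)) {
    bad <- v[v$carriers_lt + v$carriers_st + v$carriers_nt == 0, ]
    stop("focal-unique variant with zero focal carriers at ",
         bad$chrom[1], ":", bad$pos[1], " contradicts focal-uniqueness")
  }
  tail_carr <- tapply(v$carriers_lt + v$carriers_st, v$gene_id, sum)
  nt_carr <- tapply(v$carriers_nt, v$gene_id, sum)
  genes <- names(tail_carr)
  class <- ifelse(tail_carr > 0 & nt_carr > 0, "common",
                  ifelse(tail_carr > 0, "tail_specific", "non_tail_specific"))
  gene_table <- data.frame(gene_id = genes,
                           carriers_tail = as.integer(tail_carr),
                           carriers_non_tail = as.integer(nt_carr),
                           class = unname(class),
                           row.names = NULL, stringsAsFactors = FALSE)
  out <- structure(list(
    focal_specific = sort(specific$genes),
    tail_specific = sort(genes[class == "tail_specific"]),
    non_tail_specific = sort(genes[class == "non_tail_specific"]),
    common = sort(genes[class == "common"]),
    gene_table = gene_table
  ), class = "gene_classification")
  # partition invariant, asserted on every run
  parts <- c(out$tail_specific, out$non_tail_specific, out$common)
  stopifnot(!anyDuplicated(parts), setequal(parts, genes),
            all(parts %in% out$focal_specific))
  out
}

#' @export
print.gene_classification <- function(x, ...) {
  cat(sprintf(paste0("gene_classification: %d focal-specific genes ",
                     "(%d tail, %d non-tail, %d common)\n"),
              length(x$focal_specific), length(x$tail_specific),
              length(x$non_tail_specific), length(x$common)))
  invisible(x)
}
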