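#' Construct a simplified gene model
#'
#' A minimal coding gene representation: 1-based closed coding-exon
#' intervals on a chromosome, a transcript span that may extend beyond the
#' coding exons (the extensions classify as UTR), a strand, and a coding
#' frame offset (number of leading bases of the exonic concatenation that
#' precede the first complete codon).
#'
#' @param gene_id,chrom,strand,protein_id Identifiers; `strand` is `"+"` or `"-"`.
#' @param exon_start,exon_end Integer vectors of coding-exon bounds (1-based,
#'   closed, sorted, non-overlapping).
#' @param tx_start,tx_end Transcript span containing all exons.
#' @param frame_offset Integer in `0:2`.
#' @return A list of class `gene_model`.
#' @export
gene_model <- function(gene_id, chrom, strand, exon_start, exon_end,
                       tx_start = min(exon_start), tx_end = max(exon_end),
                       frame_offset = 0L, protein_id = paste0(gene_id, "_p")) {
  stopifnot(strand %in% c("+", "-"),
            length(exon_start) == length(exon_end),
            all(exon_end >= exon_start),
            frame_offset %in% 0:2)
  ord <- order(exon_start)
  exon_start <- as.integer(exon_start[ord])
  exon_end <- as.integer(exon_end[ord])
  if (length(exon_start) > 1 &&
      any(exon_start[-1] <= exon_end[-length(exon_end)])) {
    stop("exons overlap or are unsorted in gene ", gene_id)
  }
  if (tx_start > min(exon_start) || tx_end < max(exon_end)) {
    stop("transcript span must contain all exons in gene ", gene_id)
  }
  len <- sum(exon_end - exon_start + 1L)
  if ((len - frame_offset) %% 3L != 0L) {
    stop("coding length after frame offset not divisible by 3 in gene ", gene_id)
  }
  structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                 exon_start = exon_start, exon_end = exon_end,
                 tx_start = as.integer(tx_start), tx_end = as.integer(tx_end),
                 frame_offset = as.integer(frame_offset),
                 protein_id = protein_id),
            class = "gene_model")
}

#' Read gene models from a TSV file
#'
#' Columns: `gene_id`, `chrom`, `strand`, `tx_start`, `tx_end`,
#' `exon_starts`, `exon_ends` (comma-separated), `frame_offset`,
#' `protein_id`. Each row is validated through [gene_model()].
#'
#' @param path TSV path with a header row.
#' @return Named list of `gene_model` objects.
#' @export
read_gene_models <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  needed <- c("gene_id", "chrom", "strand", "tx_start", "tx_end",
              "exon_starts", "exon_ends", "frame_offset", "protein_id")
  if (!all(needed %in% names(df))) {
    stop("gene model table must have columns: ", paste(needed, collapse = ", "))
  }
  gms <- lapply(seq_len(nrow(df)), function(i) {
    gene_model(df$gene_id[i], df$chrom[i], df$strand[i],
               as.integer(strsplit(df$exon_starts[i], ",")[[1]]),
               as.integer(strsplit(df$exon_ends[i], ",")[[1]]),
               df$tx_start[i], df$tx_end[i], df$frame_offset[i],
               df$protein_id[i])
  })
  names(gms) <- df$gene_id
  gms
}

#' Write gene models to a TSV file
#'
#' @param gene_models Named list of `gene_model` objects.
#' @param path Output path.
#' @export
write_gene_models <- function(gene_models, path) {
  df <- do.call(rbind, lapply(gene_models, function(gm) {
    data.frame(gene_id = gm$gene_id, chrom = gm$chrom, strand = gm$strand,
               tx_start = gm$tx_start, tx_end = gm$tx_end,
               exon_starts = paste(gm$exon_start, collapse = ","),
               exon_ends = paste(gm$exon_end, collapse = ","),
               frame_offset = gm$frame_offset, protein_id = gm$protein_id,
               stringsAsFactors = FALSE)
  }))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Total coding length (bases) after the frame offset.
cds_length <- function(gm) {
  sum(gm$exon_end - gm$exon_start + 1L) - gm$frame_offset
}

# Map a genomic position to a 1-based CDS coordinate (transcript sense,
# after the frame offset). NA when the position is not exonic or falls in
# the pre-frame bases.
genomic_to_cds <- function(gm, pos) {
  widths <- gm$exon_end - gm$exon_start + 1L
  before <- c(0L, cumsum(widths))[seq_along(widths)]
  hit <- which(pos >= gm$exon_start & pos <= gm$exon_end)
  if (!length(hit)) return(NA_integer_)
  left <- before[hit] + (pos - gm$exon_start[hit]) + 1L
  total <- sum(widths)
  t <- if (gm$strand == "+") left else total - left + 1L
  c_pos <- t - gm$frame_offset
  if (c_pos < 1L || c_pos > total - gm$frame_offset) return(NA_integer_)
  c_pos
}

# Inverse of genomic_to_cds.
cds_to_genomic <- function(gm, c_pos) {
  widths <- gm$exon_end - gm$exon_start + 1L
  total <- sum(widths)
  t <- c_pos + gm$frame_offset
  stopifnot(t >= 1L, t <= total)
  left <- if (gm$strand == "+") t else total - t + 1L
  cum <- cumsum(widths)
  hit <- which(left <= cum)[1]
  offset_in_exon <- left - c(0L, cum)[hit] - 1L
  gm$exon_start[hit] + offset_in_exon
}
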