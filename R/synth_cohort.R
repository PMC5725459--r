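SENSE_CODONS <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
AA_RESIDUES <- setdiff(unique(unname(Biostrings::GENETIC_CODE)), "*")
TRANSITION <- c(A = "G", G = "A", C = "T", T = "C")

# Sample alternative alleles at a target transition:transversion ratio:
# a site is a transition with probability titv/(1+titv).
sample_alt <- function(ref, ti_tv_target) {
  n <- length(ref)
  is_ti <- runif(n) < ti_tv_target / (1 + ti_tv_target)
  alt <- character(n)
  alt[is_ti] <- TRANSITION[ref[is_ti]]
  for (i in which(!is_ti)) {
    alt[i] <- sample(setdiff(c("A", "C", "G", "T"),
                             c(ref[i], TRANSITION[[ref[i]]])), 1)
  }
  alt
}

#' Specification of a synthetic sequencing cohort
#'
#' Defaults mirror the study design the pipeline targets: a focal
#' population of 22 dogs split into long-tail (7), short-tail (5) and
#' non-tail (10) subpopulations, a 12-breed comparison panel with the
#' published sample sizes, six related species compared at aligned protein
#' residues, and a transition:transversion target of 2.04. Gene counts and
#' sites per gene are desk-scale choices.
#'
#' @param n_long_tail,n_short_tail,n_non_tail Focal subpopulation sizes.
#' @param comparison_breeds Named integer vector of breed sample sizes.
#' @param related_species Species whose aligned protein residues enter the
#'   uniqueness screen.
#' @param n_genes Number of simulated genes.
#' @param n_sites_per_gene SNP sites per gene region (including any planted
#'   or decoy site).
#' @param fraction_focal_unique_missense Fraction of genes planted with a
#'   truly focal-unique missense SNP; `round(fraction * n_genes)` genes are
#'   planted.
#' @param n_decoy_genes Number of decoy genes, each violating exactly one
#'   uniqueness condition (cycling through: impact LOW; same alt in a
#'   comparison breed; focal alternative residue present in a related
#'   species).
#' @param ti_tv_target Target transition:transversion ratio.
#' @param fail_fraction Fraction of background sites given one failing
#'   hard-filter statistic.
#' @param rng_seed Integer seed.
#' @return A validated list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_long_tail = 7L, n_short_tail = 5L, n_non_tail = 10L,
                        comparison_breeds = c(
                          DiqingVillage = 10L, GermanShepherd = 10L,
                          Kunming = 10L, LijiangVillage = 10L,
                          TibetanMastiff = 10L, YingjiangVillage = 10L,
                          IndianVillage = 3L, LebanonVillage = 1L,
                          ModernEuropean = 1L, NamibiaVillage = 1L,
                          PortugalVillage = 2L, VietnamVillage = 2L),
                        related_species = c("cat", "cow", "horse", "human",
                                            "mouse", "pig"),
                        n_genes = 100L, n_sites_per_gene = 30L,
                        fraction_focal_unique_missense = 0.10,
                        n_decoy_genes = 50L,
                        ti_tv_target = 2.04,
                        fail_fraction = 0.05,
                        rng_seed = 1L) {
  stopifnot(n_long_tail >= 1, n_short_tail >= 1, n_non_tail >= 1,
            length(comparison_breeds) >= 1, all(comparison_breeds >= 1),
            !is.null(names(comparison_breeds)),
            n_genes >= 1, n_sites_per_gene >= 1,
            fraction_focal_unique_missense >= 0,
            fraction_focal_unique_missense <= 1,
            n_decoy_genes >= 0, ti_tv_target > 0,
            fail_fraction >= 0, fail_fraction <= 1)
  n_planted <- round(fraction_focal_unique_missense * n_genes)
  if (n_planted + n_decoy_genes > n_genes) {
    stop("n_genes (", n_genes, ") smaller than planted (", n_planted,
         ") + decoy (", n_decoy_genes, ") genes")
  }
  structure(list(n_long_tail = as.integer(n_long_tail),
                 n_short_tail = as.integer(n_short_tail),
                 n_non_tail = as.integer(n_non_tail),
                 comparison_breeds = comparison_breeds,
                 related_species = related_species,
                 n_genes = as.integer(n_genes),
                 n_sites_per_gene = as.integer(n_sites_per_gene),
                 fraction_focal_unique_missense = fraction_focal_unique_missense,
                 n_planted = as.integer(n_planted),
                 n_decoy_genes = as.integer(n_decoy_genes),
                 ti_tv_target = ti_tv_target,
                 fail_fraction = fail_fraction,
                 rng_seed = as.integer(rng_seed)),
            class = "cohort_spec")
}

make_callset <- function(variants, geno, population) {
  rownames(variants) <- NULL
  structure(list(variants = variants, geno = geno,
                 samples = colnames(geno), population = population,
                 skipped = c(multiallelic = 0L, non_snp = 0L)),
            class = "population_callset")
}

#' Simulate a full cohort with planted ground truth
#'
#' Generates everything the variant pipeline consumes: gene models with
#' coding frames on simulated chromosomes, per-population SNP call sets
#' (the focal population plus every comparison breed), per-gene protein
#' alignments across related species, a table of per-species alternative
#' residues, and a truth record. Planted genes carry a focal-unique
#' missense SNP of HIGH or MODERATE impact whose alternative allele occurs
#' in no comparison breed and whose alternative residue occurs in no
#' related species at the aligned column; each decoy gene violates exactly
#' one of those conditions (LOW impact, breed sharing, or species residue
#' sharing); background missense SNPs always recur in at least one breed.
#' Alternative alleles are drawn at the spec's transition:transversion
#' target; planted subpopulation carriers realize the designated
#' tail/non-tail/common classes.
#'
#' @param spec A [cohort_spec()].
#' @param out_dir Optional directory: when given, VCFs, the gene-model TSV,
#'   alignments, the species-residue table and truth tables are written
#'   there.
#' @return List with `focal` (a `population_callset` of the 22 focal dogs,
#'   samples labelled LT/ST/NT), `breeds` (named list of callsets),
#'   `gene_models`, `coding_sequences`, `proteins`, `alignments`,
#'   `species_residues`, `sites` (the full site table including
#'   zero-carrier and filtered sites), and `truth` (planted/decoy gene
#'   sets, planted classes, planted variant table).
#' @export
simulate_cohort <- function(spec, out_dir = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$rng_seed)
  bases <- c("A", "C", "G", "T")
  flank <- 300L
  focal_samples <- c(sprintf("DG_LT_%02d", seq_len(spec$n_long_tail)),
                     sprintf("DG_ST_%02d", seq_len(spec$n_short_tail)),
                     sprintf("DG_NT_%02d", seq_len(spec$n_non_tail)))
  focal_pop <- setNames(rep(c("LT", "ST", "NT"),
                            c(spec$n_long_tail, spec$n_short_tail,
                              spec$n_non_tail)), focal_samples)
  breed_samples <- lapply(names(spec$comparison_breeds), function(b) {
    sprintf("%s_%02d", b, seq_len(spec$comparison_breeds[[b]]))
  })
  names(breed_samples) <- names(spec$comparison_breeds)
  n_focal <- length(focal_samples)
  tail_idx <- which(focal_pop %in% c("LT", "ST"))
  nt_idx <- which(focal_pop == "NT")

  gene_ids <- sprintf("g%03d", seq_len(spec$n_genes))
  roles <- rep("background", spec$n_genes)
  special <- sample.int(spec$n_genes, spec$n_planted + spec$n_decoy_genes)
  planted_idx <- special[seq_len(spec$n_planted)]
  decoy_idx <- setdiff(special, planted_idx)
  roles[planted_idx] <- "planted"
  decoy_types <- rep(c("decoy_low", "decoy_breed", "decoy_species"),
                     length.out = length(decoy_idx))
  roles[decoy_idx] <- decoy_types
  planted_class <- rep(c("tail", "non_tail", "common"),
                       length.out = length(planted_idx))

  chroms <- sprintf("chr%d", 1:5)
  cursor <- setNames(rep(1L, length(chroms)), chroms)

  gene_models <- list(); cds_list <- list(); proteins <- list()
  alignments <- list()
  site_rows <- list(); focal_geno_rows <- list()
  breed_geno_rows <- setNames(vector("list", length(breed_samples)),
                              names(breed_samples))
  residue_rows <- list()
  planted_variant_rows <- list()

  for (gi in seq_len(spec$n_genes)) {
    g <- gene_ids[gi]
    role <- roles[gi]
    n_codons <- sample(50:120, 1)
    cds_chars <- strsplit(paste(sample(SENSE_CODONS, n_codons, replace = TRUE),
                                collapse = ""), "")[[1]]
    L <- 3L * n_codons
    strand <- sample(c("+", "-"), 1)
    chrom <- sample(chroms, 1)
    utr5 <- sample(80:150, 1); utr3 <- sample(80:150, 1)
    intron_len <- sample(120:300, 1)
    w1 <- sample(seq_len(L - 1L), 1)
    tx_start <- cursor[[chrom]] + flank
    e1s <- tx_start + utr5; e1e <- e1s + w1 - 1L
    e2s <- e1e + intron_len + 1L; e2e <- e2s + (L - w1) - 1L
    tx_end <- e2e + utr3
    region_lo <- tx_start - flank; region_hi <- tx_end + flank
    cursor[[chrom]] <- region_hi + 400L
    gm <- gene_model(g, chrom, strand, c(e1s, e2s), c(e1e, e2e),
                     tx_start, tx_end, 0L, paste0(g, "_p"))
    cds <- paste(cds_chars, collapse = "")
    protein_chars <- unname(Biostrings::GENETIC_CODE[
      substring(cds, seq(1, L, 3), seq(3, L, 3))])
    # region reference, exonic bases overwritten from the CDS (genome sense)
    region_seq <- sample(bases, region_hi - region_lo + 1L, replace = TRUE)
    genome_exonic <- if (strand == "+") cds_chars else rev(unname(COMPLEMENT[cds_chars]))
    region_seq[c(e1s:e1e, e2s:e2e) - region_lo + 1L] <- genome_exonic

    # planted / decoy missense sites, generated forward in CDS space
    n_special <- if (role == "planted") sample(1:2, 1)
                 else if (role != "background") 1L else 0L
    if (role == "planted" && planted_class[match(gi, planted_idx)] == "common") {
      n_special <- sample(1:2, 1)
    }
    special_sites <- NULL
    used_cds <- integer(0)
    if (n_special > 0) {
      rows <- list()
      for (s in seq_len(n_special)) {
        for (try in 1:100) {
          codon_i <- sample.int(n_codons, 1)
          p <- sample.int(3, 1)
          c_pos <- 3L * (codon_i - 1L) + p
          if (c_pos %in% used_cds) next
          tr_ref <- cds_chars[c_pos]
          gref <- if (strand == "+") tr_ref else unname(COMPLEMENT[tr_ref])
          galt <- sample_alt(gref, spec$ti_tv_target)
          tr_alt <- if (strand == "+") galt else unname(COMPLEMENT[galt])
          codon <- paste(cds_chars[(3L * codon_i - 2L):(3L * codon_i)],
                         collapse = "")
          alt_codon <- codon
          substr(alt_codon, p, p) <- tr_alt
          ref_aa <- Biostrings::GENETIC_CODE[[codon]]
          alt_aa <- Biostrings::GENETIC_CODE[[alt_codon]]
          if (alt_aa == "*" || alt_aa == ref_aa) next
          used_cds <- c(used_cds, c_pos)
          rows[[s]] <- data.frame(
            pos = cds_to_genomic(gm, c_pos), ref = gref, alt = galt,
            effect_class = "non_synonymous",
            impact = if (role == "decoy_low") "LOW"
                     else sample(c("HIGH", "MODERATE"), 1, prob = c(0.1, 0.9)),
            protein_position = codon_i, ref_aa = ref_aa, alt_aa = alt_aa,
            stringsAsFactors = FALSE)
          break
        }
      }
      special_sites <- do.call(rbind, rows)
      if (is.null(special_sites) || nrow(special_sites) < n_special) {
        stop("failed to place a non-synonymous site in gene ", g)
      }
    }

    # background sites over the whole region
    n_bg <- max(0L, spec$n_sites_per_gene - n_special)
    avail <- setdiff(seq(region_lo, region_hi),
                     if (n_special > 0) special_sites$pos else integer(0))
    bg_pos <- sort(sample(avail, min(n_bg, length(avail))))
    bg_ref <- region_seq[bg_pos - region_lo + 1L]
    bg_alt <- sample_alt(bg_ref, spec$ti_tv_target)
    bg_class <- character(length(bg_pos))
    bg_ppos <- rep(NA_integer_, length(bg_pos))
    bg_raa <- rep(NA_character_, length(bg_pos))
    bg_aaa <- rep(NA_character_, length(bg_pos))
    for (i in seq_along(bg_pos)) {
      pos <- bg_pos[i]
      if (pos < tx_start || pos > tx_end) { bg_class[i] <- "intergenic"; next }
      in_exon <- (pos >= e1s && pos <= e1e) || (pos >= e2s && pos <= e2e)
      if (!in_exon) {
        if (pos > e1e && pos < e2s) {
          bg_class[i] <- if (min(pos - e1e, e2s - pos) <= 2L) "splice_site"
                         else "intron"
        } else bg_class[i] <- "UTR"
        next
      }
      c_pos <- genomic_to_cds(gm, pos)
      codon_i <- (c_pos - 1L) %/% 3L + 1L
      p <- c_pos - 3L * (codon_i - 1L)
      tr_alt <- if (strand == "+") bg_alt[i] else unname(COMPLEMENT[bg_alt[i]])
      codon <- paste(cds_chars[(3L * codon_i - 2L):(3L * codon_i)],
                     collapse = "")
      alt_codon <- codon
      substr(alt_codon, p, p) <- tr_alt
      ref_aa <- Biostrings::GENETIC_CODE[[codon]]
      alt_aa <- Biostrings::GENETIC_CODE[[alt_codon]]
      bg_class[i] <- if (ref_aa == alt_aa) "synonymous" else "non_synonymous"
      bg_ppos[i] <- codon_i; bg_raa[i] <- ref_aa; bg_aaa[i] <- alt_aa
    }
    bg_impact <- ifelse(bg_class == "non_synonymous",
                        ifelse(runif(length(bg_pos)) < 0.1, "HIGH", "MODERATE"),
                        ifelse(bg_class == "synonymous", "LOW",
                               ifelse(bg_class == "splice_site", "LOW",
                                      "MODIFIER")))
    gene_sites <- data.frame(
      chrom = chrom,
      pos = c(bg_pos, if (n_special > 0) special_sites$pos),
      ref = c(bg_ref, if (n_special > 0) special_sites$ref),
      alt = c(bg_alt, if (n_special > 0) special_sites$alt),
      effect_class = c(bg_class, if (n_special > 0) special_sites$effect_class),
      impact = c(bg_impact, if (n_special > 0) special_sites$impact),
      gene_id = g,
      protein_position = c(bg_ppos,
                           if (n_special > 0) special_sites$protein_position),
      ref_aa = c(bg_raa, if (n_special > 0) special_sites$ref_aa),
      alt_aa = c(bg_aaa, if (n_special > 0) special_sites$alt_aa),
      role = c(rep("background", length(bg_pos)), rep(role, n_special)),
      stringsAsFactors = FALSE)
    gene_sites$gene_id[gene_sites$effect_class == "intergenic"] <- NA_character_
    ns <- nrow(gene_sites)
    is_special <- gene_sites$role != "background"

    # call statistics; a fraction of background sites fail one clause
    gene_sites$qual <- round(runif(ns, 60, 3000), 1)
    gene_sites$qd <- round(runif(ns, 8, 35), 2)
    gene_sites$mq <- round(runif(ns, 42, 60), 2)
    gene_sites$fs <- round(runif(ns, 0, 30), 2)
    failable <- which(!is_special)
    n_fail <- rbinom(1, length(failable), spec$fail_fraction)
    if (n_fail > 0) {
      fail_at <- sample(failable, n_fail)
      clause <- sample(c("QD", "MQ", "FS", "QUAL"), n_fail, replace = TRUE)
      gene_sites$qd[fail_at[clause == "QD"]] <-
        round(runif(sum(clause == "QD"), 0.5, 4.99), 2)
      gene_sites$mq[fail_at[clause == "MQ"]] <-
        round(runif(sum(clause == "MQ"), 10, 39.9), 2)
      gene_sites$fs[fail_at[clause == "FS"]] <-
        round(runif(sum(clause == "FS"), 200.1, 400), 2)
      gene_sites$qual[fail_at[clause == "QUAL"]] <-
        round(runif(sum(clause == "QUAL"), 1, 29.9), 1)
    }

    # carriers
    f <- pmax(rbeta(ns, 0.5, 3), 0.05)
    focal_geno <- matrix(runif(ns * n_focal), ns) < f
    colnames(focal_geno) <- focal_samples
    breed_geno <- lapply(names(breed_samples), function(b) {
      m <- matrix(runif(ns * length(breed_samples[[b]])), ns) < f
      colnames(m) <- breed_samples[[b]]
      m
    })
    names(breed_geno) <- names(breed_samples)
    # background missense carried in the focal population must recur in a
    # breed, so it cannot look focal-unique
    shared_needed <- which(!is_special &
                             gene_sites$effect_class == "non_synonymous" &
                             gene_sites$impact %in% c("HIGH", "MODERATE") &
                             rowSums(focal_geno) >= 1)
    for (i in shared_needed) {
      if (!any(vapply(breed_geno, function(m) any(m[i, ]), logical(1)))) {
        b <- sample(names(breed_geno), 1)
        breed_geno[[b]][i, sample.int(ncol(breed_geno[[b]]), 1)] <- TRUE
      }
    }
    # planted/decoy carriers: focal-only, realizing the designated class
    if (n_special > 0) {
      sp_rows <- which(is_special)
      for (i in sp_rows) focal_geno[i, ] <- FALSE
      for (b in names(breed_geno)) breed_geno[[b]][sp_rows, ] <- FALSE
      cls <- if (role == "planted") planted_class[match(gi, planted_idx)]
             else "tail"
      for (s in seq_along(sp_rows)) {
        i <- sp_rows[s]
        target <- if (cls == "tail") tail_idx
                  else if (cls == "non_tail") nt_idx
                  else if (length(sp_rows) >= 2) {
                    if (s == 1) tail_idx else nt_idx
                  } else c(sample(tail_idx, 1), sample(nt_idx, 1))
        k <- if (cls == "common" && length(sp_rows) == 1) length(target)
             else sample(seq_len(min(3, length(target))), 1)
        focal_geno[i, sample(target, k)] <- TRUE
      }
      if (role == "decoy_breed") {
        b <- sample(names(breed_geno), 1)
        breed_geno[[b]][sp_rows[1],
                        sample.int(ncol(breed_geno[[b]]), 1)] <- TRUE
      }
      if (role == "planted") {
        planted_variant_rows[[length(planted_variant_rows) + 1L]] <-
          cbind(gene_sites[sp_rows, c("chrom", "pos", "ref", "alt", "gene_id",
                                      "protein_position", "ref_aa", "alt_aa")],
                class = cls)
      }
    }

    # per-gene protein alignment across related species (focal row "dog",
    # no gaps in the focal row, so column == protein position)
    aln_chars <- list(dog = protein_chars)
    special_cols <- if (n_special > 0) special_sites$protein_position else integer(0)
    special_alts <- if (n_special > 0) special_sites$alt_aa else character(0)
    for (sp in spec$related_species) {
      ch <- protein_chars
      subst <- which(runif(n_codons) < 0.03)
      for (i in subst) ch[i] <- sample(setdiff(AA_RESIDUES, ch[i]), 1)
      if (runif(1) < 0.25) {
        start <- sample.int(n_codons, 1)
        len <- sample(2:6, 1)
        ch[start:min(n_codons, start + len - 1L)] <- "-"
      }
      # a species must never show the focal alternative residue at a
      # planted column (condition (d) holds by construction)
      for (s in seq_along(special_cols)) {
        if (ch[special_cols[s]] == special_alts[s]) {
          ch[special_cols[s]] <- protein_chars[special_cols[s]]
        }
      }
      aln_chars[[sp]] <- ch
      # occasional segregating alternative residues in the species
      if (runif(1) < 0.10) {
        col <- sample.int(n_codons, 1)
        forbidden <- c(ch[col], special_alts[special_cols == col])
        res <- sample(setdiff(AA_RESIDUES, forbidden), 1)
        residue_rows[[length(residue_rows) + 1L]] <- data.frame(
          species = sp, gene_id = g, column = col, residue = res,
          stringsAsFactors = FALSE)
      }
    }
    if (role == "decoy_species") {
      sp <- sample(spec$related_species, 1)
      col <- special_cols[1]
      if (aln_chars[[sp]][col] == "-") aln_chars[[sp]][col] <- protein_chars[col]
      residue_rows[[length(residue_rows) + 1L]] <- data.frame(
        species = sp, gene_id = g, column = col, residue = special_alts[1],
        stringsAsFactors = FALSE)
    }
    alignments[[g]] <- Biostrings::AAStringSet(
      vapply(aln_chars, paste, "", collapse = ""))

    gene_models[[g]] <- gm
    cds_list[[g]] <- cds
    proteins[[g]] <- paste(protein_chars, collapse = "")
    site_rows[[gi]] <- gene_sites
    focal_geno_rows[[gi]] <- focal_geno
    for (b in names(breed_geno)) {
      breed_geno_rows[[b]][[gi]] <- breed_geno[[b]]
    }
  }

  sites <- do.call(rbind, site_rows)
  rownames(sites) <- NULL
  focal_geno <- do.call(rbind, focal_geno_rows)
  ord <- order(sites$chrom, sites$pos)
  sites <- sites[ord, , drop = FALSE]
  focal_geno <- focal_geno[ord, , drop = FALSE]
  var_cols <- c("chrom", "pos", "ref", "alt", "qual", "qd", "mq", "fs",
                "effect_class", "impact", "gene_id", "protein_position",
                "ref_aa", "alt_aa")
  focal_keep <- rowSums(focal_geno) >= 1
  focal_cs <- make_callset(sites[focal_keep, var_cols],
                           focal_geno[focal_keep, , drop = FALSE], focal_pop)
  breeds <- list()
  for (b in names(breed_geno_rows)) {
    m <- do.call(rbind, breed_geno_rows[[b]])[ord, , drop = FALSE]
    keep <- rowSums(m) >= 1
    breeds[[b]] <- make_callset(sites[keep, var_cols], m[keep, , drop = FALSE],
                                setNames(rep(b, ncol(m)), colnames(m)))
  }
  species_residues <- if (length(residue_rows)) {
    do.call(rbind, residue_rows)
  } else {
    data.frame(species = character(), gene_id = character(),
               column = integer(), residue = character())
  }
  planted_variants <- if (length(planted_variant_rows)) {
    do.call(rbind, planted_variant_rows)
  } else NULL
  truth <- list(
    planted_genes = gene_ids[planted_idx],
    tail_specific = gene_ids[planted_idx][planted_class == "tail"],
    non_tail_specific = gene_ids[planted_idx][planted_class == "non_tail"],
    common = gene_ids[planted_idx][planted_class == "common"],
    decoys = data.frame(gene_id = gene_ids[decoy_idx], type = decoy_types,
                        stringsAsFactors = FALSE),
    planted_variants = planted_variants)
  out <- list(spec = spec, focal = focal_cs, breeds = breeds,
              gene_models = gene_models, coding_sequences = cds_list,
              proteins = proteins, alignments = alignments,
              species_residues = species_residues, sites = sites,
              truth = truth)
  if (!is.null(out_dir)) write_cohort(out, out_dir)
  out
}

#' Write a simulated cohort to disk
#'
#' Emits the formats the readers consume: one VCF per population
#' (`donggyeong.vcf` plus one per breed), `gene_models.tsv`, a directory of
#' per-gene aligned FASTAs, `species_residues.tsv`, `cds.fasta`, and truth
#' tables (`truth_genes.tsv`, `truth_variants.tsv`).
#'
#' @param cohort Result of [simulate_cohort()].
#' @param out_dir Output directory (created if needed).
#' @export
write_cohort <- function(cohort, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_callset(cohort$focal, file.path(out_dir, "donggyeong.vcf"))
  for (b in names(cohort$breeds)) {
    write_callset(cohort$breeds[[b]], file.path(out_dir, paste0(b, ".vcf")))
  }
  write_gene_models(cohort$gene_models, file.path(out_dir, "gene_models.tsv"))
  write_gene_alignments(cohort$alignments, file.path(out_dir, "alignments"))
  write_species_residues(cohort$species_residues,
                         file.path(out_dir, "species_residues.tsv"))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(unlist(cohort$coding_sequences)),
    file.path(out_dir, "cds.fasta"))
  truth_genes <- rbind(
    data.frame(gene_id = cohort$truth$tail_specific, class = "tail_specific"),
    data.frame(gene_id = cohort$truth$non_tail_specific,
               class = "non_tail_specific"),
    data.frame(gene_id = cohort$truth$common, class = "common"))
  write.table(truth_genes, file.path(out_dir, "truth_genes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(cohort$truth$planted_variants)) {
    write.table(cohort$truth$planted_variants,
                file.path(out_dir, "truth_variants.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(out_dir)
}
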