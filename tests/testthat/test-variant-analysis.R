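toy_variants <- function(qd = 10, mq = 50, fs = 10, qual = 100) {
  data.frame(chrom = "chr1", pos = seq_along(qd), ref = "A", alt = "G",
             qd = qd, mq = mq, fs = fs, qual = qual)
}

test_that("hard filter applies strict inequalities per clause", {
  # exactly at the thresholds: retained
  v <- toy_variants(qd = 5.0, mq = 40.0, fs = 200.0, qual = 30.0)
  res <- hard_filter(v)
  expect_equal(nrow(res$retained), 1L)
  expect_equal(unname(res$tally["removed"]), 0L)
  # just below/above: removed, tallied per clause
  v <- toy_variants(qd = c(4.0, 4.999, 10, 10, 10),
                    mq = c(50, 50, 39.9, 50, 50),
                    fs = c(1, 1, 1, 200.01, 1),
                    qual = c(100, 100, 100, 100, 29))
  res <- hard_filter(v)
  expect_equal(nrow(res$retained), 0L)
  expect_equal(unname(res$tally[c("QD", "MQ", "FS", "QUAL")]),
               c(2L, 1L, 1L, 1L))
  # missing INFO fields never fire their clause
  v <- toy_variants(qd = NA, mq = NA, fs = NA, qual = 100)
  expect_equal(nrow(hard_filter(v)$retained), 1L)
})

test_that("hard filter is order-independent and counts 3-of-10 style removals", {
  set.seed(5)
  v <- toy_variants(qd = c(4, rep(10, 9)), mq = c(50, 39, rep(50, 8)),
                    fs = c(1, 1, 201, rep(1, 7)), qual = rep(100, 10))
  res <- hard_filter(v)
  expect_equal(nrow(res$retained), 7L)
  perm <- sample(nrow(v))
  res_p <- hard_filter(v[perm, ])
  expect_setequal(res_p$retained$pos, res$retained$pos)
})

test_that("codon-level effect classification reproduces known substitutions", {
  # GCA with G>A at codon position 1: Ala -> Thr (missense)
  gm <- gene_model("bcanlike", "chr1", "+", exon_start = 101, exon_end = 103,
                   tx_start = 91, tx_end = 113)
  eff <- classify_coding_effect(list(pos = 101, ref = "G", alt = "A"),
                                gm, "GCA")
  expect_equal(eff[c("effect_class", "ref_aa", "alt_aa", "protein_position")],
               list(effect_class = "non_synonymous", ref_aa = "A",
                    alt_aa = "T", protein_position = 1L))
  # CCT with C>G at codon position 1: Pro -> Ala
  eff <- classify_coding_effect(list(pos = 101, ref = "C", alt = "G"),
                                gm, "CCT")
  expect_equal(eff$ref_aa, "P")
  expect_equal(eff$alt_aa, "A")
  expect_equal(eff$effect_class, "non_synonymous")
  # CTG with G>A at the degenerate third position: synonymous Leu
  eff <- classify_coding_effect(list(pos = 103, ref = "G", alt = "A"),
                                gm, "CTG")
  expect_equal(eff$effect_class, "synonymous")
  expect_equal(eff$ref_aa, "L")
})

test_that("minus-strand variants are complemented before codon substitution", {
  # CDS "GCA" on the minus strand occupies genome bases revcomp = TGC;
  # codon position 1 (the G) sits at the highest genomic coordinate.
  gm <- gene_model("neg", "chr1", "-", exon_start = 101, exon_end = 103,
                   tx_start = 95, tx_end = 110)
  eff <- classify_coding_effect(list(pos = 103, ref = "C", alt = "T"),
                                gm, "GCA")
  expect_equal(eff$ref_aa, "A")
  expect_equal(eff$alt_aa, "T")   # G>A in transcript sense: Ala -> Thr
  expect_equal(eff$protein_position, 1L)
})

test_that("non-coding regions classify by position: splice, intron, UTR, intergenic", {
  gm <- gene_model("spl", "chr1", "+", exon_start = c(101, 201),
                   exon_end = c(103, 203), tx_start = 80, tx_end = 220)
  cls <- function(pos) {
    classify_coding_effect(list(pos = pos, ref = "A", alt = "G"),
                           gm, "GCAGCA")$effect_class
  }
  expect_equal(cls(104), "splice_site")  # 1 bp into the intron
  expect_equal(cls(105), "splice_site")  # 2 bp
  expect_equal(cls(106), "intron")       # 3 bp
  expect_equal(cls(199), "splice_site")
  expect_equal(cls(150), "intron")
  expect_equal(cls(90), "UTR")
  expect_equal(cls(210), "UTR")
  expect_equal(cls(50), "intergenic")
})

test_that("category tabulation uses severity precedence and sane fractions", {
  v <- data.frame(effect_class = c("non_synonymous", "splice_site",
                                   "intron", "intergenic"))
  tab <- tabulate_categories(v)
  expect_equal(sum(tab$fraction), 1)
  expect_equal(tab$fraction[tab$category %in% v$effect_class], rep(0.25, 4))
  # empty input: all counts zero, fractions reported as 0
  tab0 <- tabulate_categories(v[0, , drop = FALSE])
  expect_equal(tab0$count, rep(0L, 6))
  expect_equal(tab0$fraction, rep(0, 6))
  # overlap resolution: intron of gene A + UTR of gene B -> UTR
  expect_equal(snpnetevo:::resolve_effect_precedence(c("intron", "UTR")), "UTR")
  expect_equal(snpnetevo:::resolve_effect_precedence(
    c("synonymous", "non_synonymous")), "non_synonymous")
  # annotate_variants applies the precedence across overlapping gene models
  gmA <- gene_model("gA", "chr1", "+", exon_start = c(101, 301),
                    exon_end = c(103, 303), tx_start = 90, tx_end = 310)
  gmB <- gene_model("gB", "chr1", "+", exon_start = 400, exon_end = 402,
                    tx_start = 150, tx_end = 420)
  ann <- annotate_variants(
    data.frame(chrom = "chr1", pos = 200, ref = "A", alt = "G"),
    list(gA = gmA, gB = gmB),
    list(gA = "GCAGCA", gB = "GCA"))
  expect_equal(ann$effect_class, "UTR")  # intron of gA, UTR of gB
})

test_that("Ti/Tv follows the transition definition and fails on zero transversions", {
  v <- data.frame(ref = c("A", "G", "C", "T", "A", "G"),
                  alt = c("G", "A", "T", "C", "C", "T"))
  expect_equal(ti_tv_ratio(v), 2.0)
  expect_equal(ti_tv_ratio(data.frame(ref = "A", alt = "C")), 0)
  expect_error(ti_tv_ratio(data.frame(ref = "A", alt = "G")), "undefined")
})

test_that("hypergeometric enrichment matches closed forms and Bonferroni arithmetic", {
  bg <- sprintf("g%02d", 1:20)
  tm <- data.frame(term_id = "T1", gene_id = bg[1:5])
  res <- term_enrichment(bg[1:5], bg, tm)
  expect_equal(res$raw_p, 1 / choose(20, 5), tolerance = 1e-12)
  # foreground == background: raw p is 1 for every term
  res <- term_enrichment(bg, bg, tm)
  expect_equal(res$raw_p, 1)
  # Bonferroni: raw 0.01 with 10 terms -> adjusted 0.10, not enriched
  tm10 <- data.frame(term_id = rep(sprintf("T%02d", 1:10), each = 2),
                     gene_id = bg[1:20])
  res <- term_enrichment(bg[1:6], bg, tm10, alpha = 0.05)
  expect_equal(res$adj_p, pmin(1, res$raw_p * 10))
  expect_error(term_enrichment("g01", character(0), tm), "empty background")
  expect_error(term_enrichment("zz", bg, tm), "missing from background")
})

test_that("hypergeometric p equals exhaustive enumeration for small backgrounds", {
  for (N in c(8, 10, 12)) {
    for (K in c(2, 4)) {
      for (n in c(3, 5)) {
        for (k_obs in 0:min(K, n)) {
          p_enum <- enumerate_hyper_p(N, K, n, k_obs)
          p_hyper <- stats::phyper(k_obs - 1, K, N - K, n, lower.tail = FALSE)
          expect_equal(p_hyper, p_enum, tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("subpopulation classification follows the carrier rules", {
  mk <- function(lt, st, nt, gene = "g1") {
    data.frame(chrom = "chr1", pos = seq_along(lt), ref = "A", alt = "G",
               gene_id = gene, impact = "MODERATE", protein_position = 1L,
               ref_aa = "A", alt_aa = "T",
               carriers_lt = lt, carriers_st = st, carriers_nt = nt)
  }
  # only LT carriers -> tail-specific
  cl <- classify_by_subpopulation(list(genes = "g1",
                                       variants = mk(2, 0, 0)))
  expect_equal(cl$tail_specific, "g1")
  # one variant in ST, one in NT -> common
  cl <- classify_by_subpopulation(list(genes = "g1",
                                       variants = mk(c(0, 0), c(1, 0), c(0, 2))))
  expect_equal(cl$common, "g1")
  # only NT -> non-tail-specific
  cl <- classify_by_subpopulation(list(genes = "g1",
                                       variants = mk(0, 0, 3)))
  expect_equal(cl$non_tail_specific, "g1")
  # zero focal carriers contradicts focal-uniqueness
  expect_error(classify_by_subpopulation(list(genes = "g1",
                                              variants = mk(0, 0, 0))),
               "zero focal carriers")
})

test_that("uniqueness screen excludes breed-shared, species-shared and LOW-impact variants", {
  # one focal gene with one candidate missense; three scenarios toggle the
  # disqualifying conditions
  base_variants <- data.frame(
    chrom = "chr1", pos = 10L, ref = "G", alt = "A", qual = 100, qd = 20,
    mq = 50, fs = 1, effect_class = "non_synonymous", impact = "MODERATE",
    gene_id = "g1", protein_position = 2L, ref_aa = "A", alt_aa = "T",
    stringsAsFactors = FALSE)
  geno <- matrix(c(TRUE, FALSE), nrow = 1,
                 dimnames = list(NULL, c("f1", "f2")))
  focal <- toy_callset(base_variants, geno, c(f1 = "LT", f2 = "NT"))
  aln <- list(g1 = Biostrings::AAStringSet(c(dog = "MAKL", cat = "MAKL",
                                             mouse = "M-KL")))
  empty_breed <- toy_callset(base_variants[0, ], geno[0, , drop = FALSE],
                             c(b1 = "B"))

  res <- find_focal_specific_genes(focal, list(B = empty_breed), aln)
  expect_equal(res$genes, "g1")

  # same alt at the same position in a breed: excluded
  breed_hit <- toy_callset(base_variants,
                           matrix(TRUE, 1, 1, dimnames = list(NULL, "b1")),
                           c(b1 = "B"))
  res <- find_focal_specific_genes(focal, list(B = breed_hit), aln)
  expect_equal(res$genes, character(0))

  # focal alternative residue seen in a species at the aligned column
  aln_hit <- list(g1 = Biostrings::AAStringSet(c(dog = "MAKL", cat = "MTKL")))
  res <- find_focal_specific_genes(focal, list(B = empty_breed), aln_hit)
  expect_equal(res$genes, character(0))
  # ... but a gap at that column makes the species non-informative
  aln_gap <- list(g1 = Biostrings::AAStringSet(c(dog = "MAKL", cat = "M-KL")))
  res <- find_focal_specific_genes(focal, list(B = empty_breed), aln_gap)
  expect_equal(res$genes, "g1")
  # species alternative-residue table also disqualifies
  res <- find_focal_specific_genes(
    focal, list(B = empty_breed), aln,
    species_residues = data.frame(species = "cat", gene_id = "g1",
                                  column = 2L, residue = "T"))
  expect_equal(res$genes, character(0))

  # LOW impact: excluded
  low <- focal
  low$variants$impact <- "LOW"
  res <- find_focal_specific_genes(low, list(B = empty_breed), aln)
  expect_equal(res$genes, character(0))

  # gene without an alignment is unevaluable, not called
  res <- suppressMessages(
    find_focal_specific_genes(focal, list(B = empty_breed), list()))
  expect_equal(res$genes, character(0))
  expect_equal(res$unevaluable, "g1")
})
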