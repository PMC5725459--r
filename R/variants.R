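#' Hard-filter variants on call quality statistics
#'
#' Removes a variant when any of the strict inequalities QD < 5.0,
#' MQ < 40.0, FS > 200.0 or QUAL < 30.0 holds (thresholds configurable).
#' A missing statistic never fires its clause. Values exactly at a
#' threshold are retained. Filtering is record-wise, hence
#' order-independent.
#'
#' @param variants Data frame with columns `qual`, `qd`, `mq`, `fs`
#'   (NA allowed).
#' @param thresholds Named list with `QD`, `MQ`, `FS`, `QUAL` (defaults from
#'   [run_config()]).
#' @return List with `retained` and `removed` data frames and `tally`, a
#'   named integer vector counting, per clause, how many variants violated
#'   it (a variant can violate several) plus `removed`/`retained` totals.
#' @export
hard_filter <- function(variants,
                        thresholds = run_config()$filter_thresholds) {
  na_false <- function(x) { x[is.na(x)] <- FALSE; x }
  v_qd <- na_false(variants$qd < thresholds$QD)
  v_mq <- na_false(variants$mq < thresholds$MQ)
  v_fs <- na_false(variants$fs > thresholds$FS)
  v_qual <- na_false(variants$qual < thresholds$QUAL)
  removed <- v_qd | v_mq | v_fs | v_qual
  list(retained = variants[!removed, , drop = FALSE],
       removed = variants[removed, , drop = FALSE],
       tally = c(QD = sum(v_qd), MQ = sum(v_mq), FS = sum(v_fs),
                 QUAL = sum(v_qual), removed = sum(removed),
                 retained = sum(!removed)))
}

# Filter a population_callset in place (variants and genotype rows).
hard_filter_callset <- function(callset,
                                thresholds = run_config()$filter_thresholds) {
  v <- callset$variants
  na_false <- function(x) { x[is.na(x)] <- FALSE; x }
  removed <- na_false(v$qd < thresholds$QD) | na_false(v$mq < thresholds$MQ) |
    na_false(v$fs > thresholds$FS) | na_false(v$qual < thresholds$QUAL)
  callset$variants <- v[!removed, , drop = FALSE]
  callset$geno <- callset$geno[!removed, , drop = FALSE]
  attr(callset, "filter_tally") <- hard_filter(v, thresholds)$tally
  callset
}

#' Transition/transversion ratio of a SNP set
#'
#' Transitions are A<->G and C<->T substitutions of the ref->alt pair (no
#' strand folding); everything else is a transversion.
#'
#' @param variants Data frame with `ref` and `alt` single-base columns.
#' @return The ratio (number of transitions / number of transversions).
#' @export
ti_tv_ratio <- function(variants) {
  key <- paste0(variants$ref, variants$alt)
  ti <- sum(key %in% c("AG", "GA", "CT", "TC"))
  tv <- length(key) - ti
  if (tv == 0L) stop("Ti/Tv undefined: no transversions in input")
  ti / tv
}

TABLE_CATEGORIES <- c("synonymous", "non_synonymous", "splice_site",
                      "intron", "UTR", "intergenic")

#' Tabulate variants by effect category
#'
#' Counts and fractions per category (synonymous, non-synonymous, splice
#' site, intron, UTR, intergenic). Every variant must carry exactly one
#' `effect_class`; multi-annotation overlaps are resolved upstream by
#' [annotate_variants()] using the severity precedence exonic > splice_site
#' > UTR > intron > intergenic. Fractions sum to 1 (all zero for empty
#' input).
#'
#' @param variants Data frame with an `effect_class` column.
#' @return Data frame with `category`, `count`, `fraction`.
#' @export
tabulate_categories <- function(variants) {
  cls <- variants$effect_class
  bad <- setdiff(unique(cls), TABLE_CATEGORIES)
  if (length(bad)) stop("unknown effect class: ", paste(bad, collapse = ", "))
  counts <- vapply(TABLE_CATEGORIES, function(k) sum(cls == k), integer(1))
  total <- sum(counts)
  data.frame(category = TABLE_CATEGORIES,
             count = as.integer(counts),
             fraction = if (total > 0) counts / total else rep(0, length(counts)),
             row.names = NULL, stringsAsFactors = FALSE)
}
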