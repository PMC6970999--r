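# The variant-level funnel: relatedness sanity check, site-quality hard
# filters, inheritance-mode partition, consequence-impact selection and
# panel allele-frequency exclusions. Every decision is appended to the
# per-variant provenance trail.

#' Trio SNP concordance check
#'
#' Relatedness sanity check: for each sample pair, the fraction of usable
#' autosomal SNV sites (all three genotypes non-missing) at which the pair
#' shares at least one allele index. Parent-proband values below
#' `flag_threshold` raise a warning, never a failure.
#'
#' @param variants a [trio_variants()] table.
#' @param pedigree a [trio_pedigree()].
#' @param min_sites minimum usable sites; fewer is an error.
#' @param flag_threshold warn when a parent-proband concordance falls below
#'   this value.
#' @return named numeric vector (`proband_mother`, `proband_father`,
#'   `mother_father`) with attribute `n_sites`.
#' @export
trio_concordance <- function(variants, pedigree, min_sites = 100L,
                             flag_threshold = 0.95) {
  cp <- gt_class(variants$gt_proband)
  cm <- gt_class(variants$gt_mother)
  cf <- gt_class(variants$gt_father)
  usable <- is_autosome(variants$chrom) &
    nchar(variants$ref) == 1L & nchar(variants$alt) == 1L &
    variants$ref %in% c("A", "C", "G", "T") &
    variants$alt %in% c("A", "C", "G", "T") &
    !gt_class_missing(cp) & !gt_class_missing(cm) & !gt_class_missing(cf)
  n <- sum(usable)
  if (n < min_sites) {
    stop("only ", n, " usable autosomal SNV sites for the concordance check; ",
         min_sites, " required")
  }
  share <- function(a, b) {
    # pairs share an allele index unless one call is ref-only and the other
    # alt-only
    !((gt_class_has_alt(a) & !gt_class_has_ref(a) &
         gt_class_has_ref(b) & !gt_class_has_alt(b)) |
        (gt_class_has_alt(b) & !gt_class_has_alt(a) &
           gt_class_has_ref(a) & !gt_class_has_ref(b)))
  }
  res <- c(
    proband_mother = mean(share(cp[usable], cm[usable])),
    proband_father = mean(share(cp[usable], cf[usable])),
    mother_father = mean(share(cm[usable], cf[usable]))
  )
  low <- res[c("proband_mother", "proband_father")] < flag_threshold
  if (any(low)) {
    warning("parent-proband SNP concordance below ", flag_threshold, ": ",
            paste(names(low)[low], collapse = ", "),
            " - check sample identity")
  }
  attr(res, "n_sites") <- n
  res
}

#' Apply site-quality hard filters
#'
#' Partitions variants into pass/fail using strict comparisons against the
#' five printed thresholds; absent metrics never fail a variant, and
#' equality at a threshold survives. Total function: every variant lands in
#' exactly one partition with a provenance tag.
#'
#' @param variants a [trio_variants()] table.
#' @param thresholds a [quality_thresholds()].
#' @return list with elements `pass` and `fail`, both [trio_variants()].
#' @export
apply_quality_filters <- function(variants, thresholds = quality_thresholds()) {
  stopifnot(inherits(thresholds, "quality_thresholds"))
  viol <- function(x, bad) !is.na(x) & bad
  fail <- viol(variants$QD, variants$QD < thresholds$qd_min) |
    viol(variants$FS, variants$FS > thresholds$fs_max) |
    viol(variants$MQ, variants$MQ < thresholds$mq_min) |
    viol(variants$MQRankSum, variants$MQRankSum < thresholds$mqranksum_min) |
    viol(variants$ReadPosRankSum,
         variants$ReadPosRankSum < thresholds$readposranksum_min)
  variants <- add_provenance(variants, "QC_PASS", !fail)
  variants <- add_provenance(variants, "QC_FAIL", fail)
  list(pass = variants[!fail], fail = variants[fail])
}

#' Assign Mendelian inheritance modes
#'
#' Presence rules evaluated per variant against the pedigree ("present"
#' means a non-missing genotype carrying at least one alt allele):
#' * `X_LINKED`: chrX, present in proband and mother but not father;
#' * `DE_NOVO`: present only in the proband, absent in both parents;
#' * `AUTOSOMAL_RECESSIVE`: autosomal, proband homozygous-alt with (strict
#'   model) both parents heterozygous, or (relaxed model) both parents
#'   carrying at least one alt and neither homozygous-alt.
#'
#' Any missing trio genotype yields no modes plus a `MISSING_GENOTYPE` tag.
#' A diploid heterozygous call on male chrX counts as present but is tagged
#' `XHET_MALE` (callers disagree on X ploidy encoding). With
#' `par_exclude = TRUE`, chrX variants inside the GRCh37 pseudoautosomal
#' regions are not eligible for `X_LINKED`.
#'
#' @param variants a [trio_variants()] table.
#' @param pedigree a [trio_pedigree()].
#' @param recessive_model `"strict"` or `"relaxed"` parental constraint.
#' @param par_exclude exclude pseudoautosomal chrX coordinates from the
#'   X-linked rule.
#' @return the variant table with a `modes` column (`;`-joined, `""` when
#'   none) and provenance tags.
#' @export
assign_inheritance_modes <- function(variants, pedigree,
                                     recessive_model = c("strict", "relaxed"),
                                     par_exclude = FALSE) {
  recessive_model <- match.arg(recessive_model)
  stopifnot(inherits(pedigree, "trio_pedigree"))
  cp <- gt_class(variants$gt_proband)
  cm <- gt_class(variants$gt_mother)
  cf <- gt_class(variants$gt_father)
  any_missing <- gt_class_missing(cp) | gt_class_missing(cm) | gt_class_missing(cf)
  present_p <- gt_class_has_alt(cp)
  present_m <- gt_class_has_alt(cm)
  present_f <- gt_class_has_alt(cf)

  on_x <- variants$chrom == "X"
  if (par_exclude) on_x <- on_x & !in_par_x(variants$chrom, variants$pos)
  auto <- is_autosome(variants$chrom)

  x_linked <- !any_missing & on_x & present_p & present_m & !present_f
  de_novo <- !any_missing & present_p & !present_m & !present_f
  if (recessive_model == "strict") {
    parents_ok <- cm == "HET" & cf == "HET"
  } else {
    parents_ok <- present_m & present_f & cm != "HOM_ALT" & cf != "HOM_ALT"
  }
  recessive <- !any_missing & auto & cp == "HOM_ALT" & parents_ok

  modes <- character(nrow(variants))
  add_mode <- function(modes, which, label) {
    ifelse(which, ifelse(modes == "", label, paste(modes, label, sep = ";")),
           modes)
  }
  modes <- add_mode(modes, x_linked, "X_LINKED")
  modes <- add_mode(modes, recessive, "AUTOSOMAL_RECESSIVE")
  modes <- add_mode(modes, de_novo, "DE_NOVO")
  variants$modes <- modes

  variants <- add_provenance(variants, "MISSING_GENOTYPE", any_missing)
  xhet_male <- pedigree$proband_sex == "MALE" & variants$chrom == "X" & cp == "HET"
  variants <- add_provenance(variants, "XHET_MALE", xhet_male)
  variants
}

#' Select variants by consequence impact class
#'
#' Retains variants whose Sequence Ontology consequence term maps to an
#' allowed impact class. Unknown terms are retained conservatively with an
#' `UNKNOWN_CONSEQUENCE` tag and a warning; variants without any
#' consequence annotation are dropped with a `NO_ANNOTATION` tag (they
#' cannot be classified as high or moderate impact).
#'
#' @param variants a [trio_variants()] table.
#' @param table an [impact_table()].
#' @param allowed impact classes to keep (default high + moderate).
#' @return the retained [trio_variants()].
#' @export
select_by_impact <- function(variants, table = impact_table(),
                             allowed = c("HIGH", "MODERATE")) {
  cls <- table$impact[match(variants$consequence, table$term)]
  no_ann <- is.na(variants$consequence)
  unknown <- !no_ann & is.na(cls)
  keep <- (!is.na(cls) & cls %in% allowed) | unknown
  if (any(unknown)) {
    warning(sum(unknown), " variant(s) with consequence terms absent from ",
            "the impact table were retained conservatively")
  }
  variants <- add_provenance(variants, "NO_ANNOTATION", no_ann)
  variants <- add_provenance(variants, "UNKNOWN_CONSEQUENCE", unknown)
  variants <- add_provenance(variants, "IMPACT_PASS", keep & !unknown)
  variants[keep]
}

#' Exclude common variants by panel allele frequency
#'
#' Drops a variant iff any present panel frequency strictly exceeds its
#' panel maximum; absent frequencies are treated as not exceeding, so novel
#' alleles survive.
#'
#' @param variants a [trio_variants()] table.
#' @param thresholds a [frequency_thresholds()].
#' @return the retained [trio_variants()].
#' @export
apply_frequency_exclusions <- function(variants,
                                       thresholds = frequency_thresholds()) {
  stopifnot(inherits(thresholds, "frequency_thresholds"))
  over <- function(x, mx) !is.na(x) & x > mx
  drop <- over(variants$dbSNP_GMAF, thresholds$dbsnp_gmaf_max) |
    over(variants$KGP_GMAF, thresholds$kgp_gmaf_max) |
    over(variants$ExAC_MAF, thresholds$exac_maf_max) |
    over(variants$gnomAD_AJ_MAF, thresholds$aj_maf_max)
  variants <- add_provenance(variants, "FREQ_PASS", !drop)
  variants[!drop]
}

#' Select rare alleles for the network workflow
#'
#' Workflow-1 admission: a variant is retained iff its Ashkenazi Jewish
#' panel frequency is absent or strictly below `aj_rare_max` (default
#' 0.1%). Runs after [apply_frequency_exclusions()].
#'
#' @param variants a [trio_variants()] table.
#' @param thresholds a [frequency_thresholds()].
#' @return the retained [trio_variants()].
#' @export
select_rare_aj <- function(variants, thresholds = frequency_thresholds()) {
  stopifnot(inherits(thresholds, "frequency_thresholds"))
  keep <- is.na(variants$gnomAD_AJ_MAF) |
    variants$gnomAD_AJ_MAF < thresholds$aj_rare_max
  variants <- add_provenance(variants, "AJ_RARE", keep)
  variants[keep]
}
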