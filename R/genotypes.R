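# Genotype-call handling. Calls are stored as normalized VCF GT strings
# ("0/1", "1|0", "1", ".", "./.") and classified into discrete zygosity
# classes; all pedigree logic runs on the classes, never on raw strings.

GT_CLASSES <- c("MISSING", "HOM_REF", "HET", "HOM_ALT", "HEMI_REF", "HEMI_ALT")

gt_class_one <- function(gt) {
  if (is.na(gt)) return("MISSING")
  g <- sub(":.*$", "", gt)
  if (g == "" || g == ".") return("MISSING")
  toks <- strsplit(g, "[/|]")[[1L]]
  if (length(toks) < 1L || length(toks) > 2L) return("INVALID")
  if (any(toks == ".")) return("MISSING")
  if (!all(toks %in% c("0", "1"))) return("INVALID")
  n_alt <- sum(toks == "1")
  if (length(toks) == 1L) {
    if (n_alt == 1L) "HEMI_ALT" else "HEMI_REF"
  } else {
    c("HOM_REF", "HET", "HOM_ALT")[n_alt + 1L]
  }
}

#' Classify genotype strings into zygosity classes
#'
#' Maps VCF `GT` strings (first colon-separated field, `/` or `|` separators,
#' allele indices restricted to 0/1 after multi-allelic splitting) onto
#' `MISSING`, `HOM_REF`, `HET`, `HOM_ALT`, `HEMI_REF` or `HEMI_ALT`.
#' Strings that cannot be parsed classify as `INVALID`; [read_trio_vcf()]
#' converts those to missing calls with a warning at ingest.
#'
#' @param gt character vector of genotype strings.
#' @return character vector of class labels, same length as `gt`.
#' @export
gt_class <- function(gt) {
  u <- unique(gt)
  cls <- vapply(u, gt_class_one, character(1L), USE.NAMES = FALSE)
  cls[match(gt, u)]
}

#' @rdname gt_class
#' @export
gt_has_alt <- function(gt) {
  gt_class(gt) %in% c("HET", "HOM_ALT", "HEMI_ALT")
}

gt_class_has_alt <- function(cls) cls %in% c("HET", "HOM_ALT", "HEMI_ALT")
gt_class_has_ref <- function(cls) cls %in% c("HOM_REF", "HET", "HEMI_REF")
gt_class_missing <- function(cls) cls %in% c("MISSING", "INVALID")

# allele-index sets for concordance: does the call carry a 0 / a 1?
gt_class_zygosity_label <- function(cls) {
  c(MISSING = NA_character_, INVALID = NA_character_,
    HOM_REF = "WILD_TYPE", HET = "HETEROZYGOUS",
    HOM_ALT = "HOMOZYGOUS_ALT", HEMI_REF = "WILD_TYPE",
    HEMI_ALT = "HEMIZYGOUS_ALT")[cls]
}
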