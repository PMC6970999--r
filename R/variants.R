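# The annotated-variant table: one row per (chrom, pos, ref, alt) after
# multi-allelic splitting, with trio genotypes, site QC metrics, gene /
# consequence / panel-frequency / predictor annotations and an append-only
# provenance trail of stage decisions.

QC_METRICS <- c("QD", "FS", "MQ", "MQRankSum", "ReadPosRankSum")
FREQ_PANELS <- c("dbSNP_GMAF", "KGP_GMAF", "ExAC_MAF", "gnomAD_AJ_MAF")
VARIANT_COLUMNS <- c(
  "chrom", "pos", "ref", "alt",
  "gt_proband", "gt_mother", "gt_father",
  QC_METRICS, "gene", "consequence", FREQ_PANELS,
  "sift", "polyphen", "provenance"
)

#' Normalize chromosome names
#'
#' Strips any `chr` prefix (case-insensitively) and upper-cases X/Y/MT so
#' that mixed-dialect inputs compare equal.
#'
#' @param x character vector of chromosome names.
#' @return normalized character vector.
#' @export
normalize_chrom <- function(x) {
  x <- sub("^[Cc][Hh][Rr]", "", as.character(x))
  up <- toupper(x)
  ifelse(up %in% c("X", "Y", "MT", "M"), up, x)
}

#' @rdname normalize_chrom
#' @param chrom normalized chromosome names.
#' @export
is_autosome <- function(chrom) chrom %in% as.character(1:22)

# GRCh37 chrX pseudoautosomal regions (1-based, inclusive)
PAR_X <- list(c(60001L, 2699520L), c(154931044L, 155260560L))

in_par_x <- function(chrom, pos) {
  chrom == "X" &
    ((pos >= PAR_X[[1L]][1L] & pos <= PAR_X[[1L]][2L]) |
       (pos >= PAR_X[[2L]][1L] & pos <= PAR_X[[2L]][2L]))
}

#' Construct an annotated trio-variant table
#'
#' Validates and normalizes a data frame of variant records into the table
#' every pipeline stage consumes. One row per alternate allele; absent
#' annotations are `NA` and are never silently treated as zero.
#'
#' @param df data frame with at least `chrom`, `pos`, `ref`, `alt`,
#'   `gt_proband`, `gt_mother`, `gt_father`. QC metric columns
#'   (`QD`, `FS`, `MQ`, `MQRankSum`, `ReadPosRankSum`), `gene`,
#'   `consequence`, panel frequencies (`dbSNP_GMAF`, `KGP_GMAF`, `ExAC_MAF`,
#'   `gnomAD_AJ_MAF`), `sift`, `polyphen` and `provenance` are optional and
#'   filled with `NA` (provenance: `""`) when missing.
#' @return a `data.table` with class `trio_variants`.
#' @export
trio_variants <- function(df) {
  dt <- as.data.table(df)
  need <- c("chrom", "pos", "ref", "alt", "gt_proband", "gt_mother", "gt_father")
  miss <- setdiff(need, names(dt))
  if (length(miss)) {
    stop("variant table is missing required columns: ", paste(miss, collapse = ", "))
  }
  for (col in c(QC_METRICS, FREQ_PANELS, "sift", "polyphen")) {
    if (!col %in% names(dt)) dt[, (col) := NA_real_]
    else dt[, (col) := as.numeric(get(col))]
  }
  for (col in c("gene", "consequence")) {
    if (!col %in% names(dt)) dt[, (col) := NA_character_]
    else dt[, (col) := as.character(get(col))]
  }
  if (!"provenance" %in% names(dt)) dt[, provenance := ""]
  dt[is.na(provenance), provenance := ""]
  dt[, chrom := normalize_chrom(chrom)]
  dt[, pos := as.integer(pos)]
  dt[, ref := toupper(as.character(ref))]
  dt[, alt := toupper(as.character(alt))]

  if (nrow(dt)) {
    if (any(dt$pos < 1L, na.rm = TRUE)) stop("variant positions must be >= 1")
    bad_allele <- !grepl("^[ACGTN]+$", dt$ref) | !grepl("^[ACGTN]+$", dt$alt)
    if (any(bad_allele)) {
      stop("ref/alt alleles must be nonempty strings over A/C/G/T/N (",
           sum(bad_allele), " offending records)")
    }
    if (any(dt$ref == dt$alt)) stop("ref and alt alleles must differ")
    for (col in c(FREQ_PANELS, "sift", "polyphen")) {
      v <- dt[[col]]
      if (any(!is.na(v) & (v < 0 | v > 1))) {
        stop("column ", col, " contains values outside [0, 1]")
      }
    }
  }
  setcolorder(dt, c(VARIANT_COLUMNS, setdiff(names(dt), VARIANT_COLUMNS)))
  setattr(dt, "class", c("trio_variants", class(dt)))
  dt[]
}

#' Append a provenance tag to selected rows
#'
#' Provenance only grows; stages append `|`-separated decision tags and no
#' stage ever removes one.
#'
#' @param variants a [trio_variants()] table (modified by reference and
#'   returned invisibly-compatible; callers use the return value).
#' @param tag single tag string (no `|`, `;` or whitespace).
#' @param idx logical or integer row index; defaults to all rows.
#' @return the variant table with tags appended.
#' @export
add_provenance <- function(variants, tag, idx = NULL) {
  stopifnot(is.character(tag), length(tag) == 1L)
  if (is.null(idx)) idx <- seq_len(nrow(variants))
  if (is.logical(idx)) idx <- which(idx)
  if (length(idx)) {
    prov <- variants$provenance[idx]
    variants$provenance[idx] <- ifelse(prov == "", tag, paste(prov, tag, sep = "|"))
  }
  variants
}

variant_key <- function(variants) {
  paste(variants$chrom, variants$pos, variants$ref, variants$alt, sep = ":")
}

empty_trio_variants <- function() {
  trio_variants(data.table(
    chrom = character(), pos = integer(), ref = character(), alt = character(),
    gt_proband = character(), gt_mother = character(), gt_father = character()
  ))
}
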