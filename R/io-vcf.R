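# VCF ingest and serialization. Reading is delegated to vcfR; writing is
# plain deterministic text so repeated writes of the same table are
# byte-identical and round trips are exact.

#' Annotation dialect for trio VCFs
#'
#' Maps the package's annotation slots onto the INFO keys a particular
#' annotator emitted. The defaults match what [write_trio_vcf()] writes, so
#' files produced by this package round-trip without options. Site QC
#' metrics always use the standard caller keys
#' (`QD`, `FS`, `MQ`, `MQRankSum`, `ReadPosRankSum`).
#'
#' @param gene,consequence,dbSNP_GMAF,KGP_GMAF,ExAC_MAF,gnomAD_AJ_MAF,sift,polyphen,provenance
#'   INFO key names.
#' @return named list of INFO keys.
#' @export
vcf_dialect <- function(gene = "GENE", consequence = "CONSEQUENCE",
                        dbSNP_GMAF = "DBSNP_GMAF", KGP_GMAF = "KGP_GMAF",
                        ExAC_MAF = "EXAC_MAF", gnomAD_AJ_MAF = "AJ_MAF",
                        sift = "SIFT", polyphen = "POLYPHEN",
                        provenance = "PROV") {
  list(gene = gene, consequence = consequence,
       dbSNP_GMAF = dbSNP_GMAF, KGP_GMAF = KGP_GMAF, ExAC_MAF = ExAC_MAF,
       gnomAD_AJ_MAF = gnomAD_AJ_MAF, sift = sift, polyphen = polyphen,
       provenance = provenance)
}

# pick the k-th comma-separated element (Number=A convention); values with a
# single element are site-level and copied to every split record
per_allele <- function(raw, idx, k, numeric = TRUE) {
  if (is.null(raw) || length(raw) == 0L) {
    out <- rep(NA_character_, length(idx))
    return(if (numeric) as.numeric(out) else out)
  }
  parts <- strsplit(as.character(raw), ",", fixed = TRUE)
  out <- vapply(seq_along(idx), function(i) {
    p <- parts[[idx[i]]]
    if (length(p) == 0L || all(is.na(p))) return(NA_character_)
    p[min(k[i], length(p))]
  }, character(1L))
  out[out %in% c(".", "")] <- NA_character_
  if (numeric) suppressWarnings(as.numeric(out)) else out
}

# remap a GT string after splitting allele k out of a multi-allelic record:
# allele index k becomes 1, every other allele becomes 0
remap_gt_alleles <- function(gt, k) {
  if (is.na(gt)) return(NA_character_)
  g <- sub(":.*$", "", gt)
  toks <- strsplit(g, "(?=[/|])", perl = TRUE)[[1L]]
  al <- toks[!toks %in% c("/", "|")]
  sep <- toks[toks %in% c("/", "|")]
  new <- ifelse(al == ".", ".", ifelse(al == as.character(k), "1", "0"))
  if (length(sep)) {
    paste0(new[1L], paste0(sep, new[-1L], collapse = ""))
  } else {
    new
  }
}

#' Read a trio VCF into an annotated variant table
#'
#' Multi-allelic records are split into one row per alternate allele
#' (site-level QC metrics copied to each row, per-allele annotations taken
#' positionally); `chr` prefixes are stripped; sample columns are bound to
#' pedigree roles by sample identifier; absent annotations stay `NA`.
#' Genotype strings that cannot be parsed become missing calls with a
#' warning.
#'
#' @param path VCF 4.x file path (uncompressed or gzipped).
#' @param pedigree a [trio_pedigree()]; its three sample IDs must be present
#'   in the VCF header.
#' @param dialect a [vcf_dialect()] mapping annotation slots to INFO keys.
#' @return a [trio_variants()] table in file order.
#' @export
read_trio_vcf <- function(path, pedigree, dialect = vcf_dialect()) {
  stopifnot(inherits(pedigree, "trio_pedigree"))
  body_lines <- sum(!startsWith(readLines(path, warn = FALSE), "#"))
  if (body_lines == 0L) return(empty_trio_variants())

  v <- vcfR::read.vcfR(path, verbose = FALSE)
  samples <- colnames(v@gt)[-1L]
  roles <- c(proband = pedigree$proband_id, mother = pedigree$mother_id,
             father = pedigree$father_id)
  missing_samp <- setdiff(roles, samples)
  if (length(missing_samp)) {
    stop("pedigree sample(s) absent from VCF header: ",
         paste(missing_samp, collapse = ", "))
  }

  fix <- v@fix
  n <- nrow(fix)
  alt_list <- strsplit(fix[, "ALT"], ",", fixed = TRUE)
  n_alt <- lengths(alt_list)
  if (any(n_alt == 0L)) stop("VCF records without an ALT allele are not supported")
  idx <- rep(seq_len(n), n_alt)
  k <- sequence(n_alt)

  gtm <- vcfR::extract.gt(v, element = "GT")
  get_gt <- function(role_id) {
    raw <- gtm[idx, role_id]
    multi <- n_alt[idx] > 1L
    if (any(multi)) {
      raw[multi] <- mapply(remap_gt_alleles, raw[multi], k[multi],
                           USE.NAMES = FALSE)
    }
    raw[is.na(raw)] <- "."
    raw
  }

  info_num <- function(key) {
    raw <- vcfR::extract.info(v, element = key)
    per_allele(raw, idx, k, numeric = TRUE)
  }
  info_chr <- function(key) {
    raw <- vcfR::extract.info(v, element = key)
    per_allele(raw, idx, k, numeric = FALSE)
  }

  dt <- data.table(
    chrom = fix[idx, "CHROM"],
    pos = as.integer(fix[idx, "POS"]),
    ref = fix[idx, "REF"],
    alt = unlist(alt_list),
    gt_proband = get_gt(roles[["proband"]]),
    gt_mother = get_gt(roles[["mother"]]),
    gt_father = get_gt(roles[["father"]])
  )
  for (m in QC_METRICS) dt[, (m) := info_num(m)]
  for (slot in c("dbSNP_GMAF", "KGP_GMAF", "ExAC_MAF", "gnomAD_AJ_MAF",
                 "sift", "polyphen")) {
    dt[, (slot) := info_num(dialect[[slot]])]
  }
  dt[, gene := info_chr(dialect$gene)]
  dt[, consequence := info_chr(dialect$consequence)]
  prov <- info_chr(dialect$provenance)
  dt[, provenance := ifelse(is.na(prov), "", prov)]

  # unparseable genotypes become MISSING with one warning per file
  n_invalid <- 0L
  for (col in c("gt_proband", "gt_mother", "gt_father")) {
    bad <- gt_class(dt[[col]]) == "INVALID"
    if (any(bad)) {
      n_invalid <- n_invalid + sum(bad)
      set(dt, which(bad), col, ".")
    }
  }
  if (n_invalid > 0L) {
    warning(n_invalid, " unparseable genotype call(s) set to missing")
  }
  trio_variants(dt)
}

fmt_vcf_num <- function(x) {
  ifelse(is.na(x), NA_character_,
         format(x, digits = 15, trim = TRUE, scientific = FALSE))
}

#' Write an annotated variant table as VCF 4.2
#'
#' The inverse of [read_trio_vcf()] under the default dialect: annotations
#' and provenance tags are serialized into documented INFO keys, genotypes
#' into a GT-only FORMAT, and output is deterministic (byte-stable across
#' repeated writes of the same table).
#'
#' @param variants a [trio_variants()] table.
#' @param pedigree a [trio_pedigree()]; sample columns are written in
#'   proband, mother, father order under the pedigree IDs.
#' @param path output file path.
#' @param dialect a [vcf_dialect()] naming the INFO keys to write.
#' @return `path`, invisibly.
#' @export
write_trio_vcf <- function(variants, pedigree, path, dialect = vcf_dialect()) {
  stopifnot(inherits(pedigree, "trio_pedigree"))
  info_defs <- c(
    sprintf('##INFO=<ID=%s,Number=1,Type=Float,Description="%s">',
            QC_METRICS,
            c("Variant confidence normalized by depth",
              "Phred-scaled strand-bias Fisher test p-value",
              "RMS mapping quality",
              "Alt-vs-ref mapping-quality rank-sum Z-score",
              "Alt-vs-ref read-position rank-sum Z-score")),
    sprintf('##INFO=<ID=%s,Number=1,Type=String,Description="Gene symbol">',
            dialect$gene),
    sprintf('##INFO=<ID=%s,Number=1,Type=String,Description="Sequence Ontology consequence term">',
            dialect$consequence),
    sprintf('##INFO=<ID=%s,Number=1,Type=Float,Description="%s">',
            unlist(dialect[c("dbSNP_GMAF", "KGP_GMAF", "ExAC_MAF", "gnomAD_AJ_MAF")]),
            c("dbSNP global minor allele frequency",
              "1000 Genomes global minor allele frequency",
              "ExAC minor allele frequency",
              "gnomAD Ashkenazi Jewish minor allele frequency")),
    sprintf('##INFO=<ID=%s,Number=1,Type=Float,Description="%s">',
            c(dialect$sift, dialect$polyphen),
            c("SIFT score (lower = more damaging)",
              "PolyPhen-2 score (higher = more damaging)")),
    sprintf('##INFO=<ID=%s,Number=1,Type=String,Description="Pipeline stage provenance tags, |-separated">',
            dialect$provenance)
  )
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=triofunnel",
    info_defs,
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", pedigree$proband_id, pedigree$mother_id,
            pedigree$father_id), collapse = "\t")
  )

  if (nrow(variants) == 0L) {
    writeLines(header, path)
    return(invisible(path))
  }

  info_parts <- vector("list", 0L)
  push <- function(key, vals) {
    info_parts[[length(info_parts) + 1L]] <<- ifelse(
      is.na(vals), NA_character_, paste0(key, "=", vals))
  }
  for (m in QC_METRICS) push(m, fmt_vcf_num(variants[[m]]))
  push(dialect$gene, variants$gene)
  push(dialect$consequence, variants$consequence)
  for (slot in c("dbSNP_GMAF", "KGP_GMAF", "ExAC_MAF", "gnomAD_AJ_MAF")) {
    push(dialect[[slot]], fmt_vcf_num(variants[[slot]]))
  }
  push(dialect$sift, fmt_vcf_num(variants$sift))
  push(dialect$polyphen, fmt_vcf_num(variants$polyphen))
  prov <- variants$provenance
  push(dialect$provenance, ifelse(is.na(prov) | prov == "", NA_character_, prov))

  info_mat <- do.call(cbind, info_parts)
  info <- apply(info_mat, 1L, function(r) {
    r <- r[!is.na(r)]
    if (length(r)) paste(r, collapse = ";") else "."
  })

  body <- paste(
    variants$chrom, variants$pos, ".", variants$ref, variants$alt, ".", ".",
    info, "GT",
    variants$gt_proband, variants$gt_mother, variants$gt_father,
    sep = "\t"
  )
  writeLines(c(header, body), path)
  invisible(path)
}
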