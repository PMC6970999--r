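# Threshold containers. Defaults are the exact printed values of the study
# design; every comparison downstream is strict, so equality at a threshold
# always survives.

#' Site-quality hard-filter thresholds
#'
#' A variant fails iff any *present* metric violates its threshold:
#' `QD < qd_min`, `FS > fs_max`, `MQ < mq_min`,
#' `MQRankSum < mqranksum_min`, `ReadPosRankSum < readposranksum_min`
#' (all strict). Absent metrics never fail a variant.
#'
#' @param mqranksum_min,readposranksum_min,qd_min,fs_max,mq_min numeric
#'   thresholds; defaults are the standard GATK-style hard-filter values.
#' @return list of class `quality_thresholds`.
#' @export
quality_thresholds <- function(mqranksum_min = -12.5, readposranksum_min = -8.0,
                               qd_min = 2.0, fs_max = 60.0, mq_min = 40.0) {
  th <- list(mqranksum_min = mqranksum_min,
             readposranksum_min = readposranksum_min,
             qd_min = qd_min, fs_max = fs_max, mq_min = mq_min)
  if (!all(vapply(th, function(x) is.numeric(x) && is.finite(x), logical(1L)))) {
    stop("all quality thresholds must be finite numbers")
  }
  structure(th, class = "quality_thresholds")
}

#' Panel allele-frequency thresholds
#'
#' Common-variant exclusions drop a variant iff any present panel frequency
#' strictly exceeds its maximum; `aj_rare_max` is the stricter cut used to
#' admit variants into the rare-allele (workflow 1) branch.
#'
#' @param dbsnp_gmaf_max,kgp_gmaf_max,exac_maf_max,aj_maf_max common-variant
#'   exclusion maxima per panel.
#' @param aj_rare_max strict upper bound on the Ashkenazi Jewish frequency
#'   for the rare-variant workflow (default 0.1%).
#' @return list of class `frequency_thresholds`.
#' @export
frequency_thresholds <- function(dbsnp_gmaf_max = 0.05, kgp_gmaf_max = 0.02,
                                 exac_maf_max = 0.05, aj_maf_max = 0.05,
                                 aj_rare_max = 0.001) {
  th <- list(dbsnp_gmaf_max = dbsnp_gmaf_max, kgp_gmaf_max = kgp_gmaf_max,
             exac_maf_max = exac_maf_max, aj_maf_max = aj_maf_max,
             aj_rare_max = aj_rare_max)
  vals <- unlist(th)
  if (any(vals < 0 | vals > 1)) stop("frequency thresholds must lie in [0, 1]")
  if (aj_rare_max >= aj_maf_max) {
    stop("aj_rare_max must be strictly below aj_maf_max")
  }
  structure(th, class = "frequency_thresholds")
}

#' Sequence Ontology consequence impact table
#'
#' Packaged mapping of SO consequence terms to impact classes
#' (`HIGH`/`MODERATE`/`LOW`/`MODIFIER`) with a total severity order
#' (rank 1 = most severe), following the common annotator convention.
#' User-overridable via `path`.
#'
#' @param path optional TSV with columns `rank`, `term`, `impact`; defaults
#'   to the packaged table.
#' @return `data.table` with columns `rank`, `term`, `impact`.
#' @export
impact_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "so_impact_table.tsv", package = "triofunnel")
  }
  tab <- fread(path, header = TRUE, sep = "\t")
  need <- c("rank", "term", "impact")
  if (!all(need %in% names(tab))) {
    stop("impact table must have columns rank, term, impact")
  }
  if (!all(tab$impact %in% c("HIGH", "MODERATE", "LOW", "MODIFIER"))) {
    stop("impact classes must be HIGH, MODERATE, LOW or MODIFIER")
  }
  if (anyDuplicated(tab$term) || anyDuplicated(tab$rank)) {
    stop("impact table terms and ranks must be unique")
  }
  hi <- tab[impact == "HIGH", rank]
  mo <- tab[impact == "MODERATE", rank]
  if (length(hi) && length(mo) && max(hi) > min(mo)) {
    stop("every HIGH term must rank above every MODERATE term")
  }
  setorder(tab, rank)
  tab[]
}
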