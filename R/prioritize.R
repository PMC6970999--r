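# Workflow 2 (pathogenicity-score prioritization), the merge of the two
# workflows, the manual exclusion list, and zygosity-based finalization
# into a ranked candidate report.

#' Call possibly damaging SNVs (PDS)
#'
#' A variant is a PDS iff both predictor scores are present and both cross
#' their damaging thresholds: `sift <= sift_max` (SIFT low = damaging) and
#' `polyphen >= polyphen_min` (PolyPhen-2 high = damaging). The combined
#' pathogenic score `polyphen + (1 - sift)` is computed whenever both
#' scores are present; it is a monotone merge of the two evidence
#' directions on a 0-2 scale.
#'
#' @param variants a [trio_variants()] table.
#' @param sift_max SIFT damaging threshold (canonical published value 0.05).
#' @param polyphen_min PolyPhen-2 possibly-damaging lower bound (canonical
#'   published value 0.447).
#' @return the variant table with `is_pds` and `combined` columns.
#' @export
call_pds <- function(variants, sift_max = 0.05, polyphen_min = 0.447) {
  both <- !is.na(variants$sift) & !is.na(variants$polyphen)
  variants$is_pds <- both & variants$sift <= sift_max &
    variants$polyphen >= polyphen_min
  variants$combined <- ifelse(both, variants$polyphen + (1 - variants$sift),
                              NA_real_)
  variants <- add_provenance(variants, "PDS", variants$is_pds)
  variants
}

#' Select the top pathogenic variants (workflow 2)
#'
#' Ranks PDS rows by combined score (descending), breaking ties by lower
#' SIFT then gene symbol, and keeps the top `k`. Fewer than `k` eligible
#' rows returns all of them with a warning.
#'
#' @param variants output of [call_pds()].
#' @param k number of variants to keep (default 2).
#' @return the selected [trio_variants()] rows.
#' @export
select_top_pathogenic <- function(variants, k = 2L) {
  if (!"is_pds" %in% names(variants)) {
    stop("run call_pds() before select_top_pathogenic()")
  }
  eligible <- variants[variants$is_pds]
  if (nrow(eligible) < k) {
    warning("only ", nrow(eligible), " possibly damaging variant(s) ",
            "available for top-", k, " selection")
  }
  ord <- order(-eligible$combined, eligible$sift, eligible$gene)
  out <- eligible[head(ord, k)]
  add_provenance(out, "TOP_PATHOGENIC")
}

#' Merge the network and pathogenicity workflows
#'
#' Set union on the variant key (chrom, pos, ref, alt) with workflow
#' provenance: `NETWORK`, `PATHOGENICITY` or `BOTH`.
#'
#' @param network_set,pathogenicity_set [trio_variants()] tables from the
#'   two branches.
#' @return the merged candidate table with a `workflow` column.
#' @export
merge_workflows <- function(network_set, pathogenicity_set) {
  nk <- variant_key(network_set)
  pk <- variant_key(pathogenicity_set)
  both_keys <- intersect(nk, pk)
  net_only <- network_set[!nk %in% both_keys]
  merged <- rbind(network_set, pathogenicity_set[!pk %in% nk], fill = TRUE)
  mk <- variant_key(merged)
  merged$workflow <- ifelse(mk %in% both_keys, "BOTH",
                            ifelse(mk %in% nk, "NETWORK", "PATHOGENICITY"))
  # rows present in both branches keep the union of branch annotations
  if (length(both_keys)) {
    pidx <- match(mk, pk)
    from_path <- !is.na(pidx) & mk %in% both_keys
    for (col in intersect(c("is_pds", "combined"), names(pathogenicity_set))) {
      if (!col %in% names(merged)) merged[[col]] <- NA
      merged[[col]][from_path] <- pathogenicity_set[[col]][pidx[from_path]]
    }
  }
  merged <- add_provenance(merged, "MERGED")
  merged
}

#' Apply the manual gene exclusion list
#'
#' Removes candidates whose gene appears on the user-supplied exclusion
#' list (the data-shaped stand-in for manual literature and domain review);
#' the stated reason is carried on the removed rows, which are returned as
#' the `excluded` component for the report.
#'
#' @param candidates merged candidate table.
#' @param exclusions `data.table` with columns `gene`, `reason` (e.g. from
#'   [read_exclusion_list()]), or `NULL` for no exclusions.
#' @return list with `retained` and `excluded` tables.
#' @export
apply_exclusion_list <- function(candidates, exclusions = NULL) {
  if (is.null(exclusions) || nrow(exclusions) == 0L) {
    return(list(retained = candidates, excluded = candidates[0L]))
  }
  unknown <- setdiff(exclusions$gene, candidates$gene)
  if (length(unknown)) {
    warning("excluded gene(s) not among candidates: ",
            paste(unknown, collapse = ", "))
  }
  hit <- candidates$gene %in% exclusions$gene
  excluded <- candidates[hit]
  if (nrow(excluded)) {
    excluded$exclusion_reason <-
      exclusions$reason[match(excluded$gene, exclusions$gene)]
  }
  retained <- add_provenance(candidates[!hit], "NOT_EXCLUDED")
  list(retained = retained, excluded = excluded)
}

# outcome of one candidate given an orthogonal zygosity observation
zygosity_outcome <- function(observed, modes, proband_male) {
  if (is.na(observed)) return("UNTESTED")
  has <- function(m) grepl(m, modes, fixed = TRUE)
  if (observed == "WILD_TYPE") return("FALSE_POSITIVE")
  if (observed == "HETEROZYGOUS" &&
      (has("AUTOSOMAL_RECESSIVE") || (has("X_LINKED") && proband_male))) {
    return("ZYGOSITY_INCONSISTENT")
  }
  # remaining alt-bearing observations corroborate the called variant
  "CONFIRMED"
}

#' Finalize candidates against orthogonal zygosity genotyping
#'
#' Resolves each candidate against an optional genotyping observation:
#' wild-type observations mark false positives (dropped from the ranking);
#' heterozygous observations on autosomal-recessive or male-proband
#' X-linked candidates are zygosity-inconsistent (dropped); alt-bearing
#' observations consistent with the candidate's mode confirm it; candidates
#' without an observation stay in the ranking flagged `UNTESTED` (absence
#' of genotyping is not evidence against). Confirmed candidates rank above
#' untested ones; within groups, dual-workflow (`BOTH`) candidates rank
#' above single-workflow ones, then by score (combined pathogenic score
#' when present, else diffusion, else direct), then gene symbol.
#'
#' @param candidates merged (and optionally exclusion-filtered) candidate
#'   table carrying `modes` and `workflow` columns.
#' @param observations a [read_zygosity_table()] table, or `NULL`.
#' @param pedigree a [trio_pedigree()].
#' @param excluded optional table of exclusion-list removals to carry into
#'   the report.
#' @return object of class `candidate_report`: list with `candidates`
#'   (all rows with `outcome` and `final_rank`; dropped rows rank `NA`),
#'   `excluded`, and `schema_version`.
#' @export
finalize_by_zygosity <- function(candidates, observations = NULL, pedigree,
                                 excluded = NULL) {
  stopifnot(inherits(pedigree, "trio_pedigree"))
  male <- pedigree$proband_sex == "MALE"
  cand <- as.data.table(copy(candidates))
  cand[, variant_key := variant_key(cand)]
  if (!"modes" %in% names(cand)) cand[, modes := ""]
  if (!"workflow" %in% names(cand)) cand[, workflow := NA_character_]

  obs_for <- rep(NA_character_, nrow(cand))
  if (!is.null(observations) && nrow(observations)) {
    unmatched <- setdiff(observations$variant_key, cand$variant_key)
    if (length(unmatched)) {
      warning(length(unmatched),
              " zygosity observation(s) match no candidate variant")
    }
    obs_for <- observations$observed[match(cand$variant_key,
                                           observations$variant_key)]
  }
  cand[, outcome := vapply(seq_len(.N), function(i) {
    zygosity_outcome(obs_for[i], modes[i], male)
  }, character(1L))]
  if (nrow(cand) == 0L) cand[, outcome := character(0L)]

  score_cols <- intersect(c("combined", "diffusion", "direct"), names(cand))
  cand[, rank_score := 0]
  for (col in rev(score_cols)) {
    v <- cand[[col]]
    cand[!is.na(v), rank_score := v[!is.na(v)]]
  }

  retained <- cand[outcome %in% c("CONFIRMED", "UNTESTED")]
  dropped <- cand[!outcome %in% c("CONFIRMED", "UNTESTED")]
  if (nrow(retained)) {
    ord <- order(retained$outcome != "CONFIRMED",
                 retained$workflow != "BOTH",
                 -retained$rank_score,
                 retained$gene)
    retained <- retained[ord]
    retained[, final_rank := seq_len(.N)]
  } else {
    retained[, final_rank := integer(0L)]
  }
  if (nrow(dropped)) dropped[, final_rank := NA_integer_]
  else dropped[, final_rank := integer(0L)]
  out <- rbind(retained, dropped, fill = TRUE)

  structure(list(candidates = out[],
                 excluded = if (is.null(excluded)) cand[0L] else excluded,
                 schema_version = "1.0"),
            class = "candidate_report")
}

#' @export
print.candidate_report <- function(x, ...) {
  cat("Candidate report (", nrow(x$candidates), " candidates, ",
      sum(x$candidates$outcome == "CONFIRMED"), " confirmed)\n", sep = "")
  if (nrow(x$candidates)) {
    show <- x$candidates[, .(final_rank, gene, variant_key, modes, workflow,
                             outcome)]
    print(head(show, 10L))
  }
  invisible(x)
}

REPORT_COLUMNS <- c("final_rank", "variant_key", "gene", "modes", "workflow",
                    "outcome", "direct", "diffusion", "combined", "sift",
                    "polyphen", "gnomAD_AJ_MAF", "provenance")

report_frame <- function(report) {
  cand <- copy(report$candidates)
  for (col in REPORT_COLUMNS) {
    if (!col %in% names(cand)) cand[, (col) := NA]
  }
  cand[, REPORT_COLUMNS, with = FALSE]
}

#' Write a candidate report to TSV or JSON
#'
#' Deterministic byte output for a fixed report; the TSV carries the column
#' contract and any exclusion-list removals as `#` header comments, the
#' JSON carries a schema version. Both formats serialize identical row
#' content.
#'
#' @param report a `candidate_report` from [finalize_by_zygosity()].
#' @param path output file path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  stopifnot(inherits(report, "candidate_report"))
  frame <- report_frame(report)
  excl <- report$excluded
  if (format == "tsv") {
    hdr <- c(
      paste0("#triofunnel candidate report, schema ", report$schema_version),
      paste0("#columns: ", paste(REPORT_COLUMNS, collapse = ",")),
      if (nrow(excl)) paste0("#excluded: ", excl$gene, "\t",
                             if ("exclusion_reason" %in% names(excl))
                               excl$exclusion_reason else "")
    )
    con <- file(path, open = "wt")
    on.exit(close(con))
    writeLines(hdr, con)
    write.table(frame, con, sep = "\t", quote = FALSE, row.names = FALSE,
                na = "")
  } else {
    payload <- list(
      schema_version = report$schema_version,
      candidates = frame,
      excluded = if (nrow(excl)) {
        data.table(gene = excl$gene,
                   reason = if ("exclusion_reason" %in% names(excl))
                     excl$exclusion_reason else "")
      } else {
        data.table(gene = character(), reason = character())
      }
    )
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         na = "null", dataframe = "rows")
  }
  invisible(path)
}
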