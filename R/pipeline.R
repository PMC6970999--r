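# Pipeline orchestration: configuration handling, the staged funnel with
# per-stage accounting, and the funnel summary artifacts.

#' Default pipeline configuration
#'
#' Nested configuration with every tunable of the funnel. Unknown keys in a
#' user configuration are rejected; every run writes its fully resolved
#' configuration beside its outputs so a run is reproducible from that
#' artifact alone.
#'
#' @return nested list of class `pipeline_config`.
#' @export
pipeline_config <- function() {
  structure(list(
    inputs = list(vcf = NULL, ped = NULL, network = NULL, seeds = NULL,
                  zygosity = NULL, exclusions = NULL),
    output = list(dir = NULL),
    quality = list(mqranksum_min = -12.5, readposranksum_min = -8.0,
                   qd_min = 2.0, fs_max = 60.0, mq_min = 40.0),
    frequency = list(dbsnp_gmaf_max = 0.05, kgp_gmaf_max = 0.02,
                     exac_maf_max = 0.05, aj_maf_max = 0.05,
                     aj_rare_max = 0.001),
    inheritance = list(recessive_model = "strict", par_exclude = FALSE),
    relatedness = list(min_sites = 100L, flag_threshold = 0.95),
    impact = list(allowed = c("HIGH", "MODERATE")),
    network = list(threshold = 0.7, case_insensitive_seeds = FALSE),
    propagation = list(alpha = 0.8, tol = 1e-10, max_iter = 10000L,
                       normalization = "SYMMETRIC_DEGREE"),
    selection = list(rule = "direct_or_topq", q = 0.10),
    pathogenicity = list(sift_max = 0.05, polyphen_min = 0.447, k = 2L)
  ), class = "pipeline_config")
}

merge_config <- function(defaults, user, path = character()) {
  for (key in names(user)) {
    if (!key %in% names(defaults)) {
      stop("unknown configuration key: ",
           paste(c(path, key), collapse = "."))
    }
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]])) &&
        is.list(user[[key]])) {
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]],
                                      c(path, key))
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Read and resolve a pipeline configuration file
#'
#' @param path YAML configuration file; keys must be a subset of
#'   [pipeline_config()].
#' @param overrides optional named list merged on top of the file.
#' @return resolved `pipeline_config`.
#' @export
read_pipeline_config <- function(path = NULL, overrides = NULL) {
  cfg <- pipeline_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg <- structure(merge_config(unclass(cfg), user),
                     class = "pipeline_config")
  }
  if (!is.null(overrides)) {
    cfg <- structure(merge_config(unclass(cfg), overrides),
                     class = "pipeline_config")
  }
  cfg
}

funnel_recorder <- function() {
  env <- new.env(parent = emptyenv())
  env$rows <- list()
  env$record <- function(stage, branch, n_in, n_out, params = "") {
    env$rows[[length(env$rows) + 1L]] <- data.table(
      stage = stage, branch = branch, n_in = as.integer(n_in),
      n_out = as.integer(n_out), params = params)
  }
  env
}

#' Assemble a funnel summary
#'
#' @param rows stage records (list of single-row `data.table`s or a
#'   `data.table` with columns `stage`, `branch`, `n_in`, `n_out`,
#'   `params`).
#' @param incomplete flag an aborted run.
#' @return `data.table` of class `funnel_summary`.
#' @export
summarize_funnel <- function(rows, incomplete = FALSE) {
  dt <- if (is.data.frame(rows)) as.data.table(rows) else rbindlist(rows)
  if (nrow(dt) && any(dt$n_out > dt$n_in)) {
    stop("funnel stage output exceeds its input")
  }
  setattr(dt, "incomplete", incomplete)
  setattr(dt, "class", c("funnel_summary", class(dt)))
  dt[]
}

#' @export
print.funnel_summary <- function(x, ...) {
  cat("Funnel summary",
      if (isTRUE(attr(x, "incomplete"))) "(INCOMPLETE)" else "", "\n")
  print(as.data.table(x))
  invisible(x)
}

#' Write a funnel summary as TSV and JSON
#'
#' @param funnel a [summarize_funnel()] result.
#' @param path_prefix files are written as `<path_prefix>.tsv` and
#'   `<path_prefix>.json`.
#' @return the two paths, invisibly.
#' @export
write_funnel <- function(funnel, path_prefix) {
  tsv <- paste0(path_prefix, ".tsv")
  jsn <- paste0(path_prefix, ".json")
  hdr <- paste0("#funnel summary",
                if (isTRUE(attr(funnel, "incomplete"))) " INCOMPLETE" else "")
  con <- file(tsv, open = "wt")
  writeLines(hdr, con)
  write.table(as.data.table(funnel), con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  close(con)
  jsonlite::write_json(
    list(incomplete = isTRUE(attr(funnel, "incomplete")),
         stages = as.data.table(funnel)),
    jsn, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(c(tsv = tsv, json = jsn))
}

#' Run the full prioritization pipeline
#'
#' Executes the staged funnel: relatedness check, site-quality hard
#' filters, inheritance-mode partition, impact selection, common-variant
#' frequency exclusions; then the two parallel workflows (rare-allele
#' selection plus network-propagation gene selection; PDS calling plus
#' top-k pathogenicity ranking); then the merge, the manual exclusion list
#' and zygosity finalization. Every stage's input/output counts are
#' recorded; on a stage failure the partial funnel is flagged incomplete
#' and written before the error propagates.
#'
#' @param config a resolved [pipeline_config()] whose `inputs` name
#'   existing files (`zygosity` and `exclusions` optional).
#' @return list with `report` (a `candidate_report`), `funnel`,
#'   `candidates` (merged pre-finalization set), `scores` (network-wide
#'   gene scores), and `concordance`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  rec <- funnel_recorder()
  out_dir <- config$output$dir
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE,
                                    recursive = TRUE)
  finish <- function(funnel, report = NULL) {
    if (!is.null(out_dir)) {
      write_funnel(funnel, file.path(out_dir, "funnel"))
      yaml::write_yaml(unclass(config), file.path(out_dir, "config.yaml"))
      if (!is.null(report)) {
        write_report(report, file.path(out_dir, "report.tsv"), "tsv")
        write_report(report, file.path(out_dir, "report.json"), "json")
      }
    }
  }

  result <- tryCatch({
    pedigree <- read_pedigree(config$inputs$ped)
    variants <- read_trio_vcf(config$inputs$vcf, pedigree)
    network <- read_network(config$inputs$network, config$network$threshold)
    network <- read_seed_genes(config$inputs$seeds, network,
                               config$network$case_insensitive_seeds)
    observations <- if (!is.null(config$inputs$zygosity)) {
      read_zygosity_table(config$inputs$zygosity)
    }
    exclusions <- if (!is.null(config$inputs$exclusions)) {
      read_exclusion_list(config$inputs$exclusions)
    }

    conc <- trio_concordance(variants, pedigree,
                             min_sites = config$relatedness$min_sites,
                             flag_threshold = config$relatedness$flag_threshold)
    rec$record("relatedness_check", "main", nrow(variants), nrow(variants),
               sprintf("min_concordance=%.4f", min(conc)))

    qth <- do.call(quality_thresholds, config$quality)
    qc <- apply_quality_filters(variants, qth)
    rec$record("quality_filters", "main", nrow(variants), nrow(qc$pass),
               paste(names(config$quality), unlist(config$quality),
                     sep = "=", collapse = ","))
    v <- qc$pass

    v <- assign_inheritance_modes(v, pedigree,
                                  recessive_model = config$inheritance$recessive_model,
                                  par_exclude = config$inheritance$par_exclude)
    withmode <- v[v$modes != ""]
    rec$record("inheritance_modes", "main", nrow(v), nrow(withmode),
               paste0("recessive_model=", config$inheritance$recessive_model))
    v <- withmode

    n_in <- nrow(v)
    v <- select_by_impact(v, allowed = config$impact$allowed)
    rec$record("impact_selection", "main", n_in, nrow(v),
               paste(config$impact$allowed, collapse = "|"))

    fth <- do.call(frequency_thresholds, config$frequency)
    n_in <- nrow(v)
    v <- apply_frequency_exclusions(v, fth)
    rec$record("frequency_exclusions", "main", n_in, nrow(v),
               paste(names(config$frequency), unlist(config$frequency),
                     sep = "=", collapse = ","))

    # branch 1: rare alleles -> network propagation
    rare <- select_rare_aj(v, fth)
    rec$record("rare_aj_selection", "network", nrow(v), nrow(rare),
               sprintf("aj_rare_max=%g", fth$aj_rare_max))
    params <- propagation_params(alpha = config$propagation$alpha,
                                 tol = config$propagation$tol,
                                 max_iter = config$propagation$max_iter,
                                 normalization = config$propagation$normalization)
    scores <- gene_scores(network, params)
    cand_genes <- unique(rare$gene[!is.na(rare$gene)])
    ranked <- rank_candidate_genes(scores, cand_genes, config$selection)
    sel_genes <- ranked$gene[ranked$selected]
    network_set <- rare[!is.na(rare$gene) & rare$gene %in% sel_genes]
    if (nrow(network_set)) {
      gidx <- match(network_set$gene, ranked$gene)
      network_set$direct <- ranked$direct[gidx]
      network_set$diffusion <- ranked$diffusion[gidx]
      network_set <- add_provenance(network_set, "NETWORK_SELECTED")
    }
    rec$record("network_selection", "network", nrow(rare), nrow(network_set),
               sprintf("rule=%s,q=%g", config$selection$rule,
                       config$selection$q))

    # branch 2: pathogenicity scores
    pds <- call_pds(v, sift_max = config$pathogenicity$sift_max,
                    polyphen_min = config$pathogenicity$polyphen_min)
    rec$record("pds_calling", "pathogenicity", nrow(v), sum(pds$is_pds),
               sprintf("sift_max=%g,polyphen_min=%g",
                       config$pathogenicity$sift_max,
                       config$pathogenicity$polyphen_min))
    top <- suppressWarnings(select_top_pathogenic(pds,
                                                  k = config$pathogenicity$k))
    rec$record("top_pathogenic", "pathogenicity", sum(pds$is_pds), nrow(top),
               sprintf("k=%d", config$pathogenicity$k))

    merged <- merge_workflows(network_set, top)
    rec$record("workflow_merge", "merge",
               nrow(network_set) + nrow(top), nrow(merged), "")

    excl <- apply_exclusion_list(merged, exclusions)
    rec$record("exclusion_list", "merge", nrow(merged),
               nrow(excl$retained),
               sprintf("n_listed=%d",
                       if (is.null(exclusions)) 0L else nrow(exclusions)))

    report <- finalize_by_zygosity(excl$retained, observations, pedigree,
                                   excluded = excl$excluded)
    n_final <- sum(report$candidates$outcome %in% c("CONFIRMED", "UNTESTED"))
    rec$record("zygosity_finalization", "finalize", nrow(excl$retained),
               n_final,
               sprintf("n_observations=%d",
                       if (is.null(observations)) 0L else nrow(observations)))

    funnel <- summarize_funnel(rec$rows)
    finish(funnel, report)
    list(report = report, funnel = funnel, candidates = excl$retained,
         scores = scores, concordance = conc)
  }, error = function(e) {
    funnel <- summarize_funnel(rec$rows, incomplete = TRUE)
    finish(funnel)
    stop("pipeline aborted: ", conditionMessage(e), call. = FALSE)
  })
  result
}
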