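# Seeded synthetic-data generator: Mendelian-consistent trio genotypes with
# controllable QC failures and de novo injection, panel-frequency and
# predictor annotations, a scale-free weighted gene network with a seed set,
# and a planted X-linked causal variant in a seed-adjacent gene so the whole
# funnel is testable with known ground truth.

sample_from <- function(x, n, replace = FALSE, prob = NULL) {
  x[sample.int(length(x), n, replace = replace, prob = prob)]
}

#' Simulation configuration
#'
#' Defines the synthetic study conditions. The planted defaults mirror the
#' headline case the pipeline is built around: an X-linked variant,
#' hemizygous in a male proband with a carrier mother, not rare in the
#' population-matched panel (Ashkenazi Jewish frequency 0.01991) but rare
#' elsewhere, with strongly damaging predictor scores - the route by which
#' such a variant fails the rare-allele workflow yet survives the
#' pathogenicity workflow.
#'
#' @param seed integer random seed; identical configurations produce
#'   byte-identical output files.
#' @param n_autosomal_sites,n_x_sites site counts.
#' @param af_shape Beta shape pair for true alt-allele frequencies.
#' @param qc_fail_fraction fraction of sites drawn with at least one
#'   quality-metric violation (exact count, rounded).
#' @param qc_missing_rate per-metric probability that a non-violating QC
#'   value is left absent.
#' @param panel_missing_rate per-panel probability that a background site's
#'   frequency annotation is absent.
#' @param denovo_count autosomal de novo variants to inject.
#' @param planted list describing the planted causal variant: `aj_freq`,
#'   `other_freq`, `sift`, `polyphen`, `consequence`.
#' @param network list of network parameters: `n_nodes`, `m` (edges added
#'   per preferential-attachment step), `power`, `seed_count`,
#'   `distractor_count`, `weight_range`.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_autosomal_sites = 2000L,
                              n_x_sites = 300L,
                              af_shape = c(0.7, 4),
                              qc_fail_fraction = 0.10,
                              qc_missing_rate = 0.05,
                              panel_missing_rate = 0.10,
                              denovo_count = 5L,
                              planted = list(),
                              network = list()) {
  planted_def <- list(aj_freq = 0.01991, other_freq = 3e-4,
                      sift = 0.001, polyphen = 0.999,
                      consequence = "missense_variant")
  network_def <- list(n_nodes = 300L, m = 1L, power = 1,
                      seed_count = 25L, distractor_count = 10L,
                      weight_range = c(0.705, 1.0))
  bad_p <- setdiff(names(planted), names(planted_def))
  bad_n <- setdiff(names(network), names(network_def))
  if (length(bad_p) || length(bad_n)) {
    stop("unknown simulation keys: ", paste(c(bad_p, bad_n), collapse = ", "))
  }
  cfg <- list(
    seed = as.integer(seed),
    n_autosomal_sites = as.integer(n_autosomal_sites),
    n_x_sites = as.integer(n_x_sites),
    af_shape = af_shape,
    qc_fail_fraction = qc_fail_fraction,
    qc_missing_rate = qc_missing_rate,
    panel_missing_rate = panel_missing_rate,
    denovo_count = as.integer(denovo_count),
    planted = modifyList(planted_def, planted),
    network = modifyList(network_def, network)
  )
  if (cfg$n_autosomal_sites < 0L || cfg$n_x_sites < 1L) {
    stop("site counts must be nonnegative (and at least one chrX site)")
  }
  if (cfg$qc_fail_fraction < 0 || cfg$qc_fail_fraction > 1) {
    stop("qc_fail_fraction must lie in [0, 1]")
  }
  if (cfg$denovo_count > cfg$n_autosomal_sites) {
    stop("denovo_count cannot exceed n_autosomal_sites")
  }
  if (cfg$network$n_nodes < cfg$network$seed_count + cfg$network$distractor_count + 1L) {
    stop("network must have room for seeds, distractors and the planted gene")
  }
  structure(cfg, class = "simulation_config")
}

# run expr under a local RNG stream, restoring global state afterwards
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Simulate the weighted gene network
#'
#' Preferential-attachment graph with edge confidences drawn above the
#' high-confidence threshold, a designated seed-gene set, a planted causal
#' gene adjacent to at least one seed (edge added if needed, weight
#' recorded), and distractor genes at hop distance >= 3 from every seed.
#'
#' @param config a [simulation_config()].
#' @param out_dir optional directory; when given, `network.tsv` and
#'   `seed_genes.txt` are written there.
#' @return list with `network` (a [gene_network()] with seeds set),
#'   `planted_gene`, `planted_edges` (data.table of its seed links),
#'   `distractors`, and `files`.
#' @export
simulate_network <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  nw <- config$network
  with_seed(config$seed + 1L, {
    g <- igraph::sample_pa(nw$n_nodes, power = nw$power, m = nw$m,
                           directed = FALSE)
    nodes <- sprintf("GENE%04d", seq_len(nw$n_nodes))
    el <- igraph::as_edgelist(g, names = FALSE)
    edges <- data.table(gene1 = nodes[pmin(el[, 1L], el[, 2L])],
                        gene2 = nodes[pmax(el[, 1L], el[, 2L])],
                        weight = round(runif(nrow(el), nw$weight_range[1L],
                                             nw$weight_range[2L]), 3L))
    edges <- edges[, .(weight = max(weight)), by = .(gene1, gene2)]

    seeds <- sort(sample_from(nodes, nw$seed_count))
    seed_idx <- match(seeds, nodes)

    hop <- igraph::distances(g, to = seed_idx, weights = NA)
    min_hop <- apply(hop, 1L, min)

    neighbors <- nodes[min_hop == 1 & !(nodes %in% seeds)]
    if (length(neighbors)) {
      planted <- sample_from(neighbors, 1L)
    } else {
      planted <- sample_from(setdiff(nodes, seeds), 1L)
      edges <- rbind(edges, data.table(
        gene1 = min(planted, seeds[1L]), gene2 = max(planted, seeds[1L]),
        weight = round(runif(1L, nw$weight_range[1L], nw$weight_range[2L]), 3L)))
    }

    far <- nodes[min_hop >= 3 & !(nodes %in% c(seeds, planted))]
    if (length(far) < nw$distractor_count) {
      stop("cannot place ", nw$distractor_count, " distractor genes at hop ",
           "distance >= 3 from all seeds; only ", length(far), " eligible")
    }
    distractors <- sort(sample_from(far, nw$distractor_count))

    setorder(edges, gene1, gene2)
    network <- gene_network(edges, nodes = nodes, seeds = seeds)
    planted_edges <- edges[(gene1 == planted & gene2 %in% seeds) |
                             (gene2 == planted & gene1 %in% seeds)]

    files <- list()
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      files$network <- file.path(out_dir, "network.tsv")
      fwrite(edges, files$network, sep = "\t", col.names = FALSE)
      files$seeds <- file.path(out_dir, "seed_genes.txt")
      writeLines(seeds, files$seeds)
    }
    list(network = network, planted_gene = planted,
         planted_edges = planted_edges, distractors = distractors,
         files = files)
  })
}

qc_passing_draw <- function(n) {
  data.table(
    QD = round(runif(n, 2.5, 35), 3L),
    FS = round(runif(n, 0, 55), 3L),
    MQ = round(runif(n, 45, 60), 3L),
    MQRankSum = round(runif(n, -5, 5), 3L),
    ReadPosRankSum = round(runif(n, -5, 5), 3L)
  )
}

qc_violating_value <- function(metric, n) {
  switch(metric,
         QD = round(runif(n, 0, 1.95), 3L),
         FS = round(runif(n, 60.5, 300), 3L),
         MQ = round(runif(n, 10, 39.5), 3L),
         MQRankSum = round(runif(n, -20, -12.6), 3L),
         ReadPosRankSum = round(runif(n, -15, -8.1), 3L))
}

#' Simulate a trio VCF, pedigree and ground-truth table
#'
#' Parental genotypes are drawn from per-site allele frequencies under
#' Hardy-Weinberg; the proband inherits one allele from each parent
#' (haploid X from the mother for the male proband); exactly
#' `denovo_count` autosomal sites overwrite transmission with a
#' proband-only alt; QC metrics are drawn so that exactly the configured
#' fraction of sites violates at least one hard-filter threshold; panel
#' frequencies are correlated noisy copies of the latent truth; the
#' planted variant and the distractor variants (X-linked, rare, benign
#' scores, in genes far from the network seeds) are injected per config.
#'
#' @param config a [simulation_config()].
#' @param out_dir optional directory for `trio.vcf`, `trio.ped`,
#'   `truth.tsv`.
#' @param network_map optional result of [simulate_network()]; supplies the
#'   gene vocabulary, the planted gene and the distractor genes so variant
#'   annotations and network nodes agree.
#' @return list with `variants` ([trio_variants()]), `pedigree`, `truth`
#'   (per-site ground-truth `data.table`), and `files`.
#' @export
simulate_trio <- function(config, out_dir = NULL, network_map = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (is.null(network_map)) {
    gene_universe <- sprintf("GENE%04d", seq_len(config$network$n_nodes))
    planted_gene <- "PLANTED1"
    distractor_genes <- character()
  } else {
    gene_universe <- network_map$network$nodes
    planted_gene <- network_map$planted_gene
    distractor_genes <- network_map$distractors
  }
  n_special_x <- 1L + length(distractor_genes)
  if (config$n_x_sites < n_special_x) {
    stop("n_x_sites must accommodate the planted and distractor variants")
  }

  with_seed(config$seed, {
    n_a <- config$n_autosomal_sites
    n_x <- config$n_x_sites
    n <- n_a + n_x
    chrom <- c(sample_from(as.character(1:22), n_a, replace = TRUE),
               rep("X", n_x))
    pos <- sample.int(2e8L, n)
    bases <- c("A", "C", "G", "T")
    ref <- sample_from(bases, n, replace = TRUE)
    alt <- vapply(ref, function(r) sample_from(setdiff(bases, r), 1L),
                  character(1L), USE.NAMES = FALSE)

    af <- pmin(pmax(rbeta(n, config$af_shape[1L], config$af_shape[2L]),
                    1e-4), 0.5)

    draw <- function(p) rbinom(length(p), 1L, p)
    m1 <- draw(af); m2 <- draw(af)
    f1 <- draw(af); f2 <- draw(af)
    is_x <- chrom == "X"
    # transmitted alleles: one from each parent; male proband takes a single
    # maternal allele on X
    from_m <- ifelse(runif(n) < 0.5, m1, m2)
    from_f <- ifelse(runif(n) < 0.5, f1, f2)

    gt_pair <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "/")
    gt_mother <- gt_pair(m1, m2)
    gt_father <- ifelse(is_x, as.character(f1), gt_pair(f1, f2))
    gt_proband <- ifelse(is_x, as.character(from_m), gt_pair(from_m, from_f))

    injected_denovo <- rep(FALSE, n)
    if (config$denovo_count > 0L) {
      dn <- sample_from(seq_len(n_a), config$denovo_count)
      gt_mother[dn] <- "0/0"
      gt_father[dn] <- "0/0"
      gt_proband[dn] <- "0/1"
      injected_denovo[dn] <- TRUE
    }

    # planted causal variant and X-linked distractor variants
    x_rows <- sample_from(which(is_x), n_special_x)
    planted_row <- x_rows[1L]
    distractor_rows <- x_rows[-1L]
    carrier <- c(planted_row, distractor_rows)
    gt_mother[carrier] <- "0/1"
    gt_father[carrier] <- "0"
    gt_proband[carrier] <- "1"

    # gene symbols: background sites never reuse the planted or distractor
    # genes, so zygosity truth is unambiguous per gene
    background_genes <- setdiff(gene_universe, c(planted_gene, distractor_genes))
    gene <- sample_from(background_genes, n, replace = TRUE)
    gene[runif(n) < 0.02] <- NA_character_
    gene[planted_row] <- planted_gene
    gene[distractor_rows] <- distractor_genes

    consequence_terms <- c("missense_variant", "synonymous_variant",
                           "stop_gained", "splice_donor_variant",
                           "splice_region_variant", "intron_variant",
                           "3_prime_UTR_variant")
    consequence <- sample_from(consequence_terms, n, replace = TRUE,
                               prob = c(0.25, 0.15, 0.02, 0.02, 0.06, 0.35, 0.15))
    consequence[carrier] <- config$planted$consequence

    # panel frequencies: shared latent truth plus panel noise
    panel_draw <- function() {
      v <- round(pmin(af * exp(rnorm(n, 0, 0.25)), 0.999), 6L)
      v[runif(n) < config$panel_missing_rate] <- NA_real_
      v
    }
    dbSNP_GMAF <- panel_draw()
    KGP_GMAF <- panel_draw()
    ExAC_MAF <- panel_draw()
    gnomAD_AJ_MAF <- panel_draw()
    gnomAD_AJ_MAF[planted_row] <- config$planted$aj_freq
    for (p in c("dbSNP_GMAF", "KGP_GMAF", "ExAC_MAF")) {
      v <- get(p)
      v[planted_row] <- config$planted$other_freq
      v[distractor_rows] <- round(runif(length(distractor_rows), 1e-5, 5e-4), 6L)
      assign(p, v)
    }
    gnomAD_AJ_MAF[distractor_rows] <-
      round(runif(length(distractor_rows), 1e-5, 9e-4), 6L)

    # predictor scores on missense variants only
    sift <- rep(NA_real_, n)
    polyphen <- rep(NA_real_, n)
    mis <- which(consequence == "missense_variant")
    sift[mis] <- round(rbeta(length(mis), 2, 1), 4L)
    polyphen[mis] <- round(rbeta(length(mis), 1, 4), 4L)
    sift[planted_row] <- config$planted$sift
    polyphen[planted_row] <- config$planted$polyphen
    sift[distractor_rows] <- round(runif(length(distractor_rows), 0.2, 0.8), 4L)
    polyphen[distractor_rows] <- round(runif(length(distractor_rows), 0, 0.3), 4L)

    # QC metrics: exactly the configured fraction of sites violates >= 1
    # threshold; the planted and distractor variants always pass
    qc <- qc_passing_draw(n)
    for (m in QC_METRICS) {
      v <- qc[[m]]
      v[runif(n) < config$qc_missing_rate] <- NA_real_
      qc[[m]] <- v
    }
    qc_fail <- rep(FALSE, n)
    n_fail <- round(config$qc_fail_fraction * n)
    eligible <- setdiff(seq_len(n), carrier)
    if (n_fail > length(eligible)) n_fail <- length(eligible)
    if (n_fail > 0L) {
      fail_rows <- sample_from(eligible, n_fail)
      metric <- sample_from(QC_METRICS, n_fail, replace = TRUE)
      for (m in QC_METRICS) {
        rows <- fail_rows[metric == m]
        if (length(rows)) set(qc, rows, m, qc_violating_value(m, length(rows)))
      }
      qc_fail[fail_rows] <- TRUE
    }
    for (m in QC_METRICS) set(qc, carrier, m, qc_passing_draw(length(carrier))[[m]])

    ord <- order(match(chrom, c(as.character(1:22), "X")), pos)
    dt <- data.table(chrom = chrom, pos = pos, ref = ref, alt = alt,
                     gt_proband = gt_proband, gt_mother = gt_mother,
                     gt_father = gt_father)
    dt <- cbind(dt, qc)
    dt[, `:=`(gene = gene, consequence = consequence,
              dbSNP_GMAF = dbSNP_GMAF, KGP_GMAF = KGP_GMAF,
              ExAC_MAF = ExAC_MAF, gnomAD_AJ_MAF = gnomAD_AJ_MAF,
              sift = sift, polyphen = polyphen,
              af_true = af, qc_fail = qc_fail,
              injected_denovo = injected_denovo,
              is_planted = seq_len(n) == planted_row,
              is_distractor = seq_len(n) %in% distractor_rows)]
    dt <- dt[ord]

    pedigree <- trio_pedigree("PROBAND", "MOTHER", "FATHER",
                              proband_sex = "MALE")

    truth <- dt[, .(chrom, pos, ref, alt, gene, gt_proband, gt_mother,
                    gt_father, af_true, qc_fail, injected_denovo,
                    is_planted, is_distractor, consequence)]
    variants <- trio_variants(dt[, !c("af_true", "qc_fail",
                                      "injected_denovo", "is_planted",
                                      "is_distractor")])

    files <- list()
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      files$vcf <- file.path(out_dir, "trio.vcf")
      write_trio_vcf(variants, pedigree, files$vcf)
      files$ped <- file.path(out_dir, "trio.ped")
      writeLines(c("FAM1\tPROBAND\tFATHER\tMOTHER\t1\t2",
                   "FAM1\tFATHER\t0\t0\t1\t1",
                   "FAM1\tMOTHER\t0\t0\t2\t1"), files$ped)
      files$truth <- file.path(out_dir, "truth.tsv")
      fwrite(truth, files$truth, sep = "\t")
    }
    list(variants = variants, pedigree = pedigree, truth = truth,
         files = files)
  })
}

#' Simulate an orthogonal zygosity genotyping table
#'
#' Emits one observation per requested gene's variant(s), consistent with
#' the simulated proband genotype, except for genes listed as false
#' positives, which are reported `WILD_TYPE` (emulating shortlisted calls
#' that orthogonal genotyping fails to confirm).
#'
#' @param truth truth table from [simulate_trio()].
#' @param genes genes to genotype; defaults to all genes in the truth
#'   table. Genes absent from the truth table are an error.
#' @param false_positive_genes genes forced to a `WILD_TYPE` observation.
#' @param path optional output TSV path.
#' @return observation `data.table` as from [read_zygosity_table()].
#' @export
simulate_zygosity_table <- function(truth, genes = NULL,
                                    false_positive_genes = character(),
                                    path = NULL) {
  if (is.null(genes)) genes <- unique(truth$gene[!is.na(truth$gene)])
  unknown <- setdiff(c(genes, false_positive_genes),
                     truth$gene[!is.na(truth$gene)])
  if (length(unknown)) {
    stop("gene(s) absent from the simulated truth table: ",
         paste(unknown, collapse = ", "))
  }
  obs <- truth[gene %in% genes,
               .(gene, chrom, pos, ref, alt,
                 observed = gt_class_zygosity_label(gt_class(gt_proband)))]
  obs[gene %in% false_positive_genes, observed := "WILD_TYPE"]
  obs <- obs[!is.na(observed)]
  obs[, variant_key := paste(chrom, pos, ref, alt, sep = ":")]
  if (!is.null(path)) {
    fwrite(obs[, !"variant_key"], path, sep = "\t")
  }
  obs[]
}
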