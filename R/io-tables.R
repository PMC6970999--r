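# Readers for the flat-file inputs around the VCF: STRING-style weighted
# networks, seed-gene lists, orthogonal zygosity genotyping tables and
# manual exclusion lists.

ZYGOSITY_CATEGORIES <- c("WILD_TYPE", "HETEROZYGOUS", "HOMOZYGOUS_ALT",
                         "HEMIZYGOUS_ALT")

#' Read a weighted gene-interaction network
#'
#' Accepts whitespace/tab-separated files with at least three columns
#' (gene1, gene2, confidence). STRING-style integer scores on the 0-1000
#' scale are auto-detected (any score > 1) and divided by 1000 so that the
#' strict `weight > weight_threshold` cut keeps its exact meaning across
#' dialects. Self-loops are dropped, duplicate unordered pairs collapse to
#' their maximum weight, and malformed lines are skipped with a warning.
#'
#' @param path network file; a header line is detected and skipped when its
#'   third field is not numeric.
#' @param weight_threshold edges are retained iff `weight > weight_threshold`
#'   (strict). Default 0.7, the conventional high-confidence STRING cut.
#' @return a [gene_network()] with an empty seed set.
#' @export
read_network <- function(path, weight_threshold = 0.7) {
  stopifnot(weight_threshold >= 0, weight_threshold <= 1)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[!grepl("^(#|$)", lines)]
  if (!length(lines)) stop("network file is empty: ", path)

  fields <- strsplit(lines, "[\t ]+")
  nf <- lengths(fields)
  malformed <- nf < 3L
  fields <- fields[!malformed]
  g1 <- vapply(fields, `[[`, character(1L), 1L)
  g2 <- vapply(fields, `[[`, character(1L), 2L)
  sc <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1L), 3L)))

  header_like <- is.na(sc[1L]) && length(sc) > 0L
  if (header_like) {
    g1 <- g1[-1L]; g2 <- g2[-1L]; sc <- sc[-1L]
  }
  bad <- is.na(sc)
  n_skipped <- sum(malformed) + sum(bad)
  if (n_skipped > 0L) {
    warning(n_skipped, " malformed network line(s) skipped")
  }
  g1 <- g1[!bad]; g2 <- g2[!bad]; sc <- sc[!bad]
  if (!length(sc)) stop("no parseable network edges in ", path)

  if (any(sc > 1)) sc <- sc / 1000  # STRING 0-1000 dialect

  edges <- data.table(gene1 = g1, gene2 = g2, weight = sc)
  n_self <- edges[gene1 == gene2, .N]
  if (n_self > 0L) {
    message(n_self, " self-loop(s) dropped")
    edges <- edges[gene1 != gene2]
  }
  edges[, `:=`(pair1 = pmin(gene1, gene2), pair2 = pmax(gene1, gene2))]
  edges <- edges[, .(weight = max(weight)), by = .(pair1, pair2)]
  setnames(edges, c("pair1", "pair2"), c("gene1", "gene2"))
  edges <- edges[weight > weight_threshold]
  if (nrow(edges) == 0L) {
    stop("all network edges fall at or below the weight threshold ",
         weight_threshold)
  }
  setorder(edges, gene1, gene2)
  gene_network(edges)
}

#' Attach a seed-gene list to a network
#'
#' Reads one symbol per line (`#` comments allowed, duplicates counted
#' once) and intersects with the network's node set; unmatched symbols are
#' reported. Propagation is undefined without seeds, so an empty
#' intersection is fatal.
#'
#' @param path seed list file.
#' @param network a [gene_network()].
#' @param case_insensitive match symbols to nodes case-insensitively,
#'   reporting the node's canonical casing.
#' @return the network with its `seeds` slot set.
#' @export
read_seed_genes <- function(path, network, case_insensitive = FALSE) {
  stopifnot(inherits(network, "gene_network"))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  symbols <- unique(lines[nzchar(lines)])
  if (!length(symbols)) stop("seed-gene list is empty: ", path)

  if (case_insensitive) {
    lookup <- setNames(network$nodes, toupper(network$nodes))
    hits <- unname(lookup[toupper(symbols)])
  } else {
    hits <- ifelse(symbols %in% network$nodes, symbols, NA_character_)
  }
  n_unmatched <- sum(is.na(hits))
  if (n_unmatched > 0L) {
    warning(n_unmatched, " seed symbol(s) not found in the network")
  }
  seeds <- unique(hits[!is.na(hits)])
  if (!length(seeds)) {
    stop("no seed gene matches a network node; propagation is undefined")
  }
  set_seeds(network, seeds)
}

#' Read an orthogonal zygosity genotyping table
#'
#' TSV with header columns `gene`, `chrom`, `pos`, `ref`, `alt`,
#' `observed`, where `observed` is one of `WILD_TYPE`, `HETEROZYGOUS`,
#' `HOMOZYGOUS_ALT`, `HEMIZYGOUS_ALT`.
#'
#' @param path table path.
#' @return a `data.table` of observations with a `variant_key` column.
#' @export
read_zygosity_table <- function(path) {
  obs <- fread(path, header = TRUE, colClasses = list(character = "chrom"))
  need <- c("gene", "chrom", "pos", "ref", "alt", "observed")
  miss <- setdiff(need, names(obs))
  if (length(miss)) {
    stop("zygosity table is missing column(s): ", paste(miss, collapse = ", "))
  }
  bad <- which(!obs$observed %in% ZYGOSITY_CATEGORIES)
  if (length(bad)) {
    stop("unknown zygosity category '", obs$observed[bad[1L]],
         "' on table row ", bad[1L], "; expected one of ",
         paste(ZYGOSITY_CATEGORIES, collapse = ", "))
  }
  obs[, chrom := normalize_chrom(chrom)]
  obs[, pos := as.integer(pos)]
  obs[, variant_key := paste(chrom, pos, ref, alt, sep = ":")]
  obs[]
}

#' Read a manual gene exclusion list
#'
#' Two-column TSV (`gene`, `reason`); models the curatorial literature /
#' domain review as data rather than computation. A header row named
#' `gene` is skipped if present.
#'
#' @param path table path.
#' @return `data.table` with columns `gene` and `reason`.
#' @export
read_exclusion_list <- function(path) {
  dt <- fread(path, header = FALSE, sep = "\t", colClasses = "character",
              fill = TRUE)
  if (ncol(dt) == 1L) dt[, V2 := ""]
  dt <- dt[, 1:2]
  setnames(dt, c("gene", "reason"))
  if (nrow(dt) && identical(tolower(dt$gene[1L]), "gene")) dt <- dt[-1L]
  dt[is.na(reason), reason := ""]
  dt[]
}
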