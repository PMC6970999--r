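# Weighted undirected gene network plus the two propagation scorers:
# one-hop direct-neighbor summation and Gaussian-smoothing diffusion
# (graph-regularized label propagation solved as a sparse linear system).

#' Construct a weighted gene network
#'
#' @param edges data frame with columns `gene1`, `gene2`, `weight`
#'   (weights in (0, 1], no self-loops, each unordered pair once).
#' @param nodes optional superset of node symbols; defaults to the genes
#'   appearing in `edges`.
#' @param seeds subset of nodes carrying the disease label.
#' @return object of class `gene_network` with elements `nodes`, `edges`,
#'   `seeds`.
#' @export
gene_network <- function(edges, nodes = NULL, seeds = character()) {
  edges <- as.data.table(edges)[, .(gene1 = as.character(gene1),
                                    gene2 = as.character(gene2),
                                    weight = as.numeric(weight))]
  if (nrow(edges)) {
    if (any(edges$gene1 == edges$gene2)) stop("self-loops are not allowed")
    if (any(edges$weight <= 0 | edges$weight > 1)) {
      stop("edge weights must lie in (0, 1]")
    }
    pairs <- paste(pmin(edges$gene1, edges$gene2),
                   pmax(edges$gene1, edges$gene2))
    if (anyDuplicated(pairs)) stop("each unordered gene pair may appear once")
  }
  all_nodes <- sort(unique(c(nodes, edges$gene1, edges$gene2)))
  seeds <- unique(as.character(seeds))
  if (length(setdiff(seeds, all_nodes))) {
    stop("seed genes must be a subset of network nodes")
  }
  structure(list(nodes = all_nodes, edges = edges[], seeds = sort(seeds)),
            class = "gene_network")
}

set_seeds <- function(network, seeds) {
  gene_network(network$edges, nodes = network$nodes, seeds = seeds)
}

#' @export
print.gene_network <- function(x, ...) {
  cat("Gene network:", length(x$nodes), "nodes,", nrow(x$edges), "edges,",
      length(x$seeds), "seed genes\n")
  invisible(x)
}

# symmetric sparse weighted adjacency over network$nodes (fixed node order)
adjacency_matrix <- function(network) {
  nodes <- network$nodes
  n <- length(nodes)
  e <- network$edges
  i <- match(e$gene1, nodes)
  j <- match(e$gene2, nodes)
  Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = c(e$weight, e$weight),
                       dims = c(n, n), dimnames = list(nodes, nodes))
}

#' Propagation hyperparameters
#'
#' @param alpha diffusion retention in (0, 1): the fraction of score mass
#'   re-propagated each step; `1 - alpha` anchors scores to the seed labels.
#' @param tol residual tolerance for the iterative solve (max-norm of
#'   `f - alpha*S f - (1-alpha)*y`).
#' @param max_iter iteration cap; exceeding it is an error.
#' @param normalization `"SYMMETRIC_DEGREE"` (default; `S = D^-1/2 W D^-1/2`)
#'   or `"NONE"` (raw weights; may diverge on dense graphs).
#' @return list of class `propagation_params`.
#' @export
propagation_params <- function(alpha = 0.8, tol = 1e-10, max_iter = 10000L,
                               normalization = c("SYMMETRIC_DEGREE", "NONE")) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must lie strictly between 0 and 1")
  }
  if (tol <= 0) stop("tol must be positive")
  structure(list(alpha = alpha, tol = tol, max_iter = as.integer(max_iter),
                 normalization = match.arg(normalization)),
            class = "propagation_params")
}

#' Direct-neighbor (one-hop) seed proximity scores
#'
#' The score of a gene is the sum of edge weights connecting it to seed
#' genes; genes without a seed neighbor score 0. Seeds themselves are
#' scored over the other seeds.
#'
#' @param network a [gene_network()] with nonempty seeds.
#' @return named numeric vector over all nodes.
#' @export
direct_neighbor_scores <- function(network) {
  if (!length(network$seeds)) stop("network has no seed genes")
  W <- adjacency_matrix(network)
  y <- as.numeric(network$nodes %in% network$seeds)
  setNames(as.numeric(W %*% y), network$nodes)
}

#' Gaussian-smoothing diffusion scores
#'
#' Network diffusion that minimizes
#' `sum_i (f_i - y_i)^2 (1-alpha)/alpha + sum_(i,j) w'_ij (f_i - f_j)^2`
#' with seed labels `y = 1` and normalized weights `w'`: the final score of
#' a labeled gene stays close to its initial label, and neighboring genes
#' stay close to each other. The unique minimizer solves
#' `f = (1-alpha) (I - alpha S)^-1 y` with `S` the (by default
#' symmetrically degree-normalized) weight matrix; it is computed by
#' fixed-point iteration `f <- alpha S f + (1-alpha) y` to the requested
#' residual. Isolated nodes receive `(1-alpha) y_i`.
#'
#' @param network a [gene_network()] with nonempty seeds.
#' @param params a [propagation_params()].
#' @return named numeric vector over all nodes.
#' @export
gaussian_smoothing_scores <- function(network, params = propagation_params()) {
  if (!length(network$seeds)) stop("network has no seed genes")
  stopifnot(inherits(params, "propagation_params"))
  nodes <- network$nodes
  W <- adjacency_matrix(network)
  if (params$normalization == "SYMMETRIC_DEGREE") {
    d <- Matrix::rowSums(W)
    inv_sqrt <- ifelse(d > 0, 1 / sqrt(d), 0)
    Dhalf <- Matrix::Diagonal(x = inv_sqrt)
    S <- Dhalf %*% W %*% Dhalf  # D^-1/2 W D^-1/2, stays sparse
  } else {
    S <- W
  }
  y <- as.numeric(nodes %in% network$seeds)
  alpha <- params$alpha
  anchor <- (1 - alpha) * y
  f <- anchor
  for (iter in seq_len(params$max_iter)) {
    f_new <- alpha * as.numeric(S %*% f) + anchor
    if (max(abs(f_new - f)) <= params$tol) {
      return(setNames(f_new, nodes))
    }
    f <- f_new
  }
  stop("diffusion failed to converge within ", params$max_iter,
       " iterations (last update ", format(max(abs(f_new - f))), ")")
}

#' Score and rank all genes against the seed set
#'
#' Computes both propagation scores and competition ranks (ties share the
#' smallest rank) among non-seed genes; seeds are excluded from the
#' rankings.
#'
#' @param network a [gene_network()] with nonempty seeds.
#' @param params a [propagation_params()].
#' @return `data.table` with columns `gene`, `is_seed`, `direct`,
#'   `diffusion`, `direct_rank`, `diffusion_rank` (ranks `NA` for seeds),
#'   ordered by diffusion rank then gene symbol.
#' @export
gene_scores <- function(network, params = propagation_params()) {
  direct <- direct_neighbor_scores(network)
  diffusion <- gaussian_smoothing_scores(network, params)
  dt <- data.table(gene = network$nodes,
                   is_seed = network$nodes %in% network$seeds,
                   direct = unname(direct),
                   diffusion = unname(diffusion))
  dt[, direct_rank := NA_integer_]
  dt[, diffusion_rank := NA_integer_]
  ns <- !dt$is_seed
  if (any(ns)) {
    dt$direct_rank[ns] <- as.integer(rank(-dt$direct[ns], ties.method = "min"))
    dt$diffusion_rank[ns] <- as.integer(rank(-dt$diffusion[ns], ties.method = "min"))
  }
  setorder(dt, is_seed, diffusion_rank, gene)
  dt[]
}

#' Select candidate genes by network proximity
#'
#' Applies the configurable selection rule that realizes "located in a
#' functional gene network": by default a candidate is selected iff it has
#' any direct seed neighbor (`direct > 0`) or its diffusion rank falls in
#' the top `q` fraction of non-seed genes. Candidates absent from the
#' network are flagged `NOT_IN_NETWORK` and never selected; both scores and
#' ranks are always reported so callers can apply their own cutoffs.
#'
#' @param scores output of [gene_scores()].
#' @param candidate_genes character vector of gene symbols (typically the
#'   genes of workflow-1 surviving variants).
#' @param selection list with elements `rule` (only `"direct_or_topq"` is
#'   defined) and `q` (top fraction of non-seed genes, default 0.10).
#' @return `data.table` with one row per candidate gene: scores, ranks,
#'   `in_network`, `selected` and a `flag` column.
#' @export
rank_candidate_genes <- function(scores, candidate_genes,
                                 selection = list(rule = "direct_or_topq", q = 0.10)) {
  q <- if (is.null(selection$q)) 0.10 else selection$q
  stopifnot(q >= 0, q <= 1)
  candidate_genes <- unique(as.character(candidate_genes))
  n_nonseed <- sum(!scores$is_seed)
  cutoff <- floor(q * n_nonseed)

  out <- data.table(gene = candidate_genes)
  out <- merge(out, scores, by = "gene", all.x = TRUE, sort = FALSE)
  out[, in_network := !is.na(direct)]
  out[, selected := in_network &
        ((direct > 0) | (!is.na(diffusion_rank) & diffusion_rank <= cutoff))]
  out[, flag := fifelse(!in_network, "NOT_IN_NETWORK",
                        fifelse(selected, "SELECTED", "NOT_SELECTED"))]
  setorder(out, -selected, diffusion_rank, gene, na.last = TRUE)
  out[]
}
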