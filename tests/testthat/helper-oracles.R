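# Shared fixtures and independent oracles used across the suite.

library(data.table)

default_pedigree <- function(sex = "MALE") {
  trio_pedigree("PROBAND", "MOTHER", "FATHER", proband_sex = sex)
}

# quick single/multi-row variant builder with benign defaults
make_variants <- function(chrom = "1", pos = NULL, ref = "A", alt = "G",
                          gt_proband = "0/1", gt_mother = "0/0",
                          gt_father = "0/0", ...) {
  n <- max(lengths(list(chrom, ref, alt, gt_proband, gt_mother, gt_father,
                        ...)), length(pos), 1L)
  if (is.null(pos)) pos <- seq_len(n) * 1000L
  trio_variants(data.table(chrom = chrom, pos = pos, ref = ref, alt = alt,
                           gt_proband = gt_proband, gt_mother = gt_mother,
                           gt_father = gt_father, ...))
}

# Erdos-Renyi-ish weighted random graph with named nodes and a seed set
random_network <- function(n_nodes, n_seeds = 3L, p_edge = 0.15,
                           wmin = 0.701, wmax = 1.0) {
  nodes <- sprintf("N%03d", seq_len(n_nodes))
  pairs <- t(combn(n_nodes, 2L))
  keep <- runif(nrow(pairs)) < p_edge
  if (!any(keep)) keep[sample.int(nrow(pairs), 1L)] <- TRUE
  edges <- data.table(gene1 = nodes[pairs[keep, 1L]],
                      gene2 = nodes[pairs[keep, 2L]],
                      weight = runif(sum(keep), wmin, wmax))
  seeds <- sample(nodes, n_seeds)
  gene_network(edges, nodes = nodes, seeds = seeds)
}

# independent brute-force direct-neighbor oracle: explicit double loop over
# (node, seed) pairs on the edge list
brute_direct_oracle <- function(network) {
  out <- setNames(numeric(length(network$nodes)), network$nodes)
  e <- network$edges
  for (g in network$nodes) {
    for (s in network$seeds) {
      for (i in seq_len(nrow(e))) {
        if ((e$gene1[i] == g && e$gene2[i] == s) ||
            (e$gene2[i] == g && e$gene1[i] == s)) {
          out[g] <- out[g] + e$weight[i]
        }
      }
    }
  }
  out
}

# independent dense direct solve of (I - alpha*S) f = (1-alpha) y
dense_diffusion_oracle <- function(network, alpha = 0.8) {
  nodes <- network$nodes
  n <- length(nodes)
  W <- matrix(0, n, n, dimnames = list(nodes, nodes))
  e <- network$edges
  for (i in seq_len(nrow(e))) {
    W[e$gene1[i], e$gene2[i]] <- e$weight[i]
    W[e$gene2[i], e$gene1[i]] <- e$weight[i]
  }
  d <- rowSums(W)
  inv_sqrt <- ifelse(d > 0, 1 / sqrt(d), 0)
  S <- diag(inv_sqrt) %*% W %*% diag(inv_sqrt)
  y <- as.numeric(nodes %in% network$seeds)
  setNames(as.numeric(solve(diag(n) - alpha * S, (1 - alpha) * y)), nodes)
}

# Mendelian-consistency checker, independent of the generator's internals:
# every proband allele must be attributable to a parent
mendelian_consistent <- function(truth) {
  alleles <- function(gt) lapply(strsplit(sub(":.*$", "", gt), "[/|]"),
                                 as.integer)
  p <- alleles(truth$gt_proband)
  m <- alleles(truth$gt_mother)
  f <- alleles(truth$gt_father)
  vapply(seq_len(nrow(truth)), function(i) {
    pa <- p[[i]]
    if (length(pa) == 1L) {
      pa %in% m[[i]]  # haploid X inherited from the mother (male proband)
    } else {
      (pa[1L] %in% m[[i]] && pa[2L] %in% f[[i]]) ||
        (pa[2L] %in% m[[i]] && pa[1L] %in% f[[i]])
    }
  }, logical(1L))
}

read_mode_fixture <- function(name) {
  fx <- fread(test_path(name), sep = "\t", header = TRUE, fill = TRUE,
              colClasses = "character")
  if (!"modes" %in% names(fx)) fx[, modes := ""]
  fx[is.na(modes), modes := ""]
  fx
}
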