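# Workflow 2, the merge, exclusion list, zygosity finalization and the
# report writers.

test_that("PDS calls require both predictors to cross their thresholds", {
  v <- make_variants(sift = c(0.01, 0.30, 0.01, NA),
                     polyphen = c(0.95, 0.95, 0.30, 0.95))
  out <- call_pds(v)
  expect_equal(out$is_pds, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(out$combined[1L], 0.95 + (1 - 0.01))
  expect_true(is.na(out$combined[4L]))  # needs both scores
})

test_that("PDS set equals a recount on generated damaging labels", {
  set.seed(77)
  n <- 400
  sift <- round(runif(n), 3); polyphen <- round(runif(n), 3)
  v <- make_variants(sift = sift, polyphen = polyphen)
  out <- call_pds(v, sift_max = 0.05, polyphen_min = 0.447)
  expect_equal(sum(out$is_pds), sum(sift <= 0.05 & polyphen >= 0.447))
})

test_that("top-pathogenic selection sorts by combined score with stable ties", {
  v <- make_variants(gene = sprintf("G%d", 1:5),
                     sift = c(0.01, 0.02, 0.01, 0.04, 0.5),
                     polyphen = c(0.9, 0.99, 0.99, 0.6, 0.99))
  out <- select_top_pathogenic(call_pds(v), k = 2L)
  expect_equal(nrow(out), 2L)
  expect_equal(out$gene, c("G3", "G2"))  # two largest combined scores

  one <- make_variants(sift = 0.01, polyphen = 0.9)
  expect_warning(got <- select_top_pathogenic(call_pds(one), k = 2L),
                 "only 1")
  expect_equal(nrow(got), 1L)
})

test_that("top-k agrees with a brute-force sort on random score sets", {
  set.seed(88)
  for (rep in 1:10) {
    n <- sample(5:30, 1)
    v <- make_variants(gene = sprintf("G%02d", 1:n),
                       sift = round(runif(n, 0, 0.05), 4),
                       polyphen = round(runif(n, 0.5, 1), 4))
    called <- call_pds(v)
    k <- sample(1:4, 1)
    got <- select_top_pathogenic(called, k = k)
    ord <- order(-(called$polyphen + 1 - called$sift), called$sift,
                 called$gene)
    expect_equal(got$gene, called$gene[ord][seq_len(k)])
  }
})

test_that("workflow merge is a provenance-tagged union", {
  a <- make_variants(chrom = "1", pos = 1:7 * 100L, gene = sprintf("N%d", 1:7))
  b <- make_variants(chrom = "2", pos = 1:2 * 100L, gene = sprintf("P%d", 1:2))
  m <- merge_workflows(a, b)
  expect_equal(nrow(m), 9L)  # disjoint 7 + 2
  expect_setequal(unique(m$workflow), c("NETWORK", "PATHOGENICITY"))

  same <- merge_workflows(a, a)
  expect_equal(nrow(same), 7L)
  expect_true(all(same$workflow == "BOTH"))
})

test_that("merge size obeys inclusion-exclusion on random sets", {
  set.seed(99)
  for (rep in 1:10) {
    pool <- make_variants(chrom = "3", pos = 1:40 * 10L,
                          gene = sprintf("G%02d", 1:40))
    a <- pool[sort(sample(40, sample(5:20, 1)))]
    b <- pool[sort(sample(40, sample(5:20, 1)))]
    m <- merge_workflows(a, b)
    inter <- length(intersect(a$pos, b$pos))
    expect_equal(nrow(m), nrow(a) + nrow(b) - inter)
    expect_equal(sum(m$workflow == "BOTH"), inter)
  }
})

test_that("the exclusion list removes listed genes and carries reasons", {
  cand <- make_variants(chrom = "4", pos = 1:9 * 10L,
                        gene = sprintf("G%d", 1:9))
  excl <- data.table(gene = c("G1", "G3", "G5", "G7"),
                     reason = rep("unrelated condition", 4))
  out <- apply_exclusion_list(cand, excl)
  expect_equal(nrow(out$retained), 5L)
  expect_equal(nrow(out$excluded), 4L)
  expect_true(all(out$excluded$exclusion_reason == "unrelated condition"))

  ident <- apply_exclusion_list(cand, NULL)
  expect_equal(nrow(ident$retained), 9L)

  all_listed <- data.table(gene = sprintf("G%d", 1:9), reason = "x")
  expect_equal(nrow(apply_exclusion_list(cand, all_listed)$retained), 0L)
  expect_warning(apply_exclusion_list(cand, data.table(gene = "NOPE",
                                                       reason = "y")),
                 "not among candidates")
})

five_gene_candidates <- function() {
  v <- make_variants(
    chrom = c("12", "1", "8", "21", "X"),
    pos = c(100L, 200L, 300L, 400L, 500L),
    gene = c("DTX1", "NOTCH2", "GFRA2", "GART", "ATP7A"),
    gt_proband = c("0/1", "0/1", "1/1", "1/1", "1"),
    gt_mother = c("0/0", "0/0", "0/1", "0/1", "0/1"),
    gt_father = c("0/0", "0/0", "0/1", "0/1", "0"),
    sift = c(0.02, 0.02, 0.02, 0.02, 0.001),
    polyphen = c(0.9, 0.9, 0.9, 0.9, 0.999)
  )
  v <- assign_inheritance_modes(v, default_pedigree())
  v <- call_pds(v)
  v$workflow <- c("NETWORK", "NETWORK", "NETWORK", "BOTH", "PATHOGENICITY")
  v
}

test_that("the five-finalist genotyping scenario confirms exactly one candidate", {
  cand <- five_gene_candidates()
  obs <- data.table(
    gene = cand$gene, chrom = cand$chrom, pos = cand$pos, ref = cand$ref,
    alt = cand$alt,
    observed = c("WILD_TYPE", "WILD_TYPE", "HETEROZYGOUS", "HETEROZYGOUS",
                 "HEMIZYGOUS_ALT"))
  obs[, variant_key := paste(chrom, pos, ref, alt, sep = ":")]
  report <- finalize_by_zygosity(cand, obs, default_pedigree())
  out <- report$candidates
  expect_equal(sum(out$outcome == "CONFIRMED"), 1L)
  expect_equal(out$gene[out$outcome == "CONFIRMED"], "ATP7A")
  expect_equal(sum(out$outcome == "FALSE_POSITIVE"), 2L)    # DTX1, NOTCH2
  expect_equal(sum(out$outcome == "ZYGOSITY_INCONSISTENT"), 2L)
  expect_equal(out$gene[!is.na(out$final_rank) & out$final_rank == 1L],
               "ATP7A")
})

test_that("candidates without observations stay ranked as UNTESTED", {
  cand <- five_gene_candidates()
  report <- finalize_by_zygosity(cand, NULL, default_pedigree())
  expect_true(all(report$candidates$outcome == "UNTESTED"))
  expect_equal(sort(report$candidates$final_rank), 1:5)
  # BOTH-provenance candidates outrank single-workflow ones
  expect_equal(report$candidates$gene[report$candidates$final_rank == 1L],
               "GART")
})

test_that("finalization outcomes match an independent rule-table evaluation", {
  rule_oracle <- function(observed, mode, male) {
    if (is.na(observed)) return("UNTESTED")
    tab <- list(
      WILD_TYPE = "FALSE_POSITIVE",
      HETEROZYGOUS = if (mode == "AUTOSOMAL_RECESSIVE" ||
                         (mode == "X_LINKED" && male))
        "ZYGOSITY_INCONSISTENT" else "CONFIRMED",
      HOMOZYGOUS_ALT = "CONFIRMED",
      HEMIZYGOUS_ALT = "CONFIRMED")
    tab[[observed]]
  }
  set.seed(123)
  modes <- c("X_LINKED", "AUTOSOMAL_RECESSIVE", "DE_NOVO")
  for (rep in 1:20) {
    n <- 12
    mode <- sample(modes, n, replace = TRUE)
    observed <- sample(c(ZYGOSITY_CATEGORIES <- c("WILD_TYPE", "HETEROZYGOUS",
                                                  "HOMOZYGOUS_ALT",
                                                  "HEMIZYGOUS_ALT"), NA),
                       n, replace = TRUE)
    cand <- make_variants(chrom = ifelse(mode == "X_LINKED", "X", "2"),
                          pos = 1:n * 50L, gene = sprintf("G%02d", 1:n))
    cand$modes <- mode
    obs <- data.table(gene = cand$gene, chrom = cand$chrom, pos = cand$pos,
                      ref = cand$ref, alt = cand$alt, observed = observed)
    obs[, variant_key := paste(chrom, pos, ref, alt, sep = ":")]
    obs <- obs[!is.na(observed)]
    report <- finalize_by_zygosity(cand, obs, default_pedigree())
    got <- report$candidates[order(report$candidates$pos)]
    want <- vapply(seq_len(n), function(i) rule_oracle(observed[i], mode[i],
                                                       TRUE), character(1))
    expect_equal(got$outcome, want)
  }
})

test_that("reports are deterministic and carry identical rows in TSV and JSON", {
  cand <- five_gene_candidates()
  report <- finalize_by_zygosity(cand, NULL, default_pedigree())
  t1 <- withr::local_tempfile(fileext = ".tsv")
  t2 <- withr::local_tempfile(fileext = ".tsv")
  j1 <- withr::local_tempfile(fileext = ".json")
  write_report(report, t1, "tsv")
  write_report(report, t2, "tsv")
  write_report(report, j1, "json")
  expect_identical(readLines(t1), readLines(t2))

  tsv <- fread(t1, skip = 2L, header = TRUE)
  jsn <- jsonlite::fromJSON(j1)
  expect_equal(tsv$gene, jsn$candidates$gene)
  expect_equal(tsv$final_rank, jsn$candidates$final_rank)
  expect_equal(tsv$outcome, jsn$candidates$outcome)

  empty <- finalize_by_zygosity(cand[0L], NULL, default_pedigree())
  e <- withr::local_tempfile(fileext = ".tsv")
  write_report(empty, e, "tsv")
  lines <- readLines(e)
  expect_true(startsWith(lines[1L], "#"))
  expect_equal(sum(!startsWith(lines, "#")), 1L)  # header row only
})
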