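# The variant funnel: concordance, quality hard filters, inheritance modes,
# impact selection and frequency exclusions.

test_that("trio concordance is 1 for identical calls and 0 for opposite homozygotes", {
  gts <- sample(c("0/0", "0/1", "1/1"), 200, replace = TRUE)
  v <- make_variants(chrom = "5", gt_proband = gts, gt_mother = gts,
                     gt_father = rep("0/0", 200))
  conc <- suppressWarnings(trio_concordance(v, default_pedigree()))
  expect_equal(unname(conc["proband_mother"]), 1.0)

  v2 <- make_variants(chrom = "5", gt_proband = rep("1/1", 150),
                      gt_mother = rep("0/0", 150),
                      gt_father = rep("0/0", 150))
  conc2 <- suppressWarnings(trio_concordance(v2, default_pedigree()))
  expect_equal(unname(conc2["proband_mother"]), 0.0)

  expect_error(trio_concordance(v[1:10], default_pedigree()),
               "usable autosomal SNV sites")
})

test_that("concordance matches an independent per-site recount on Mendelian data", {
  sim <- simulate_trio(simulation_config(seed = 11L,
                                         n_autosomal_sites = 1000L,
                                         n_x_sites = 10L, denovo_count = 0L))
  v <- sim$variants
  conc <- trio_concordance(v, sim$pedigree)
  # brute-force recount over allele-index sets
  sets <- function(gt) lapply(strsplit(gt, "/"), unique)
  auto <- v[is_autosome(v$chrom)]
  pm <- mapply(function(a, b) length(intersect(a, b)) > 0,
               sets(auto$gt_proband), sets(auto$gt_mother))
  expect_equal(unname(conc["proband_mother"]), mean(pm))
  expect_equal(attr(conc, "n_sites"), nrow(auto))
})

test_that("quality filters fail on any violated metric and pass at equality", {
  v <- make_variants(QD = c(1.5, 2.0, NA), FS = c(10, 60.0, NA),
                     MQ = c(50, 40.0, NA), MQRankSum = c(0, -12.5, NA),
                     ReadPosRankSum = c(0, -8.0, NA))
  res <- apply_quality_filters(v)
  expect_equal(res$fail$QD, 1.5)             # QD below threshold fails
  expect_equal(nrow(res$pass), 2L)           # equality survives strict "<"
  expect_true(all(grepl("QC_PASS", res$pass$provenance)))
  expect_true(all(grepl("QC_FAIL", res$fail$provenance)))
  # absent metrics never fail
  expect_true("QC_PASS" %in% res$pass$provenance[is.na(res$pass$QD)])
})

test_that("quality partition matches generator-recorded ground truth", {
  sim <- simulate_trio(simulation_config(seed = 3L,
                                         n_autosomal_sites = 4700L,
                                         n_x_sites = 300L,
                                         qc_fail_fraction = 0.12))
  res <- apply_quality_filters(sim$variants)
  key <- function(x) paste(x$chrom, x$pos)
  truth_fail <- key(sim$truth)[sim$truth$qc_fail]
  expect_setequal(key(res$fail), truth_fail)
  expect_equal(nrow(res$fail), round(0.12 * 5000))
})

test_that("inheritance modes follow the pedigree presence rules", {
  ped <- default_pedigree()
  x <- assign_inheritance_modes(
    make_variants(chrom = "X", gt_proband = "1", gt_mother = "0/1",
                  gt_father = "0"), ped)
  expect_equal(x$modes, "X_LINKED")

  dn <- assign_inheritance_modes(
    make_variants(chrom = "7", gt_proband = "0/1", gt_mother = "0/0",
                  gt_father = "0/0"), ped)
  expect_equal(dn$modes, "DE_NOVO")

  miss <- assign_inheritance_modes(
    make_variants(chrom = "7", gt_proband = "0/1", gt_mother = ".",
                  gt_father = "0/0"), ped)
  expect_equal(miss$modes, "")
  expect_match(miss$provenance, "MISSING_GENOTYPE")

  xhet <- assign_inheritance_modes(
    make_variants(chrom = "X", gt_proband = "0/1", gt_mother = "0/1",
                  gt_father = "0"), ped)
  expect_equal(xhet$modes, "X_LINKED")
  expect_match(xhet$provenance, "XHET_MALE")
})

test_that("exhaustive genotype enumeration matches the hand-verified tables", {
  ped <- default_pedigree()
  fx_a <- read_mode_fixture("fixture-modes-autosomal.tsv")
  got_a <- assign_inheritance_modes(
    make_variants(chrom = "12", gt_proband = fx_a$gt_proband,
                  gt_mother = fx_a$gt_mother, gt_father = fx_a$gt_father),
    ped)
  expect_equal(got_a$modes, fx_a$modes)

  fx_x <- read_mode_fixture("fixture-modes-chrx.tsv")
  got_x <- assign_inheritance_modes(
    make_variants(chrom = "X", gt_proband = fx_x$gt_proband,
                  gt_mother = fx_x$gt_mother, gt_father = fx_x$gt_father),
    ped)
  expect_equal(got_x$modes, fx_x$modes)
})

test_that("de novo and autosomal recessive are mutually exclusive", {
  combos <- expand.grid(p = c("0/0", "0/1", "1/1"),
                        m = c("0/0", "0/1", "1/1"),
                        f = c("0/0", "0/1", "1/1"),
                        stringsAsFactors = FALSE)
  got <- assign_inheritance_modes(
    make_variants(chrom = "2", gt_proband = combos$p, gt_mother = combos$m,
                  gt_father = combos$f), default_pedigree())
  expect_false(any(grepl("DE_NOVO", got$modes) &
                     grepl("AUTOSOMAL_RECESSIVE", got$modes)))
})

test_that("the relaxed recessive model admits carrier patterns the strict one rejects", {
  v <- make_variants(chrom = "3", gt_proband = "1/1", gt_mother = "0/1",
                     gt_father = "1/1")
  strict <- assign_inheritance_modes(v, default_pedigree(), "strict")
  relaxed <- assign_inheritance_modes(v, default_pedigree(), "relaxed")
  expect_equal(strict$modes, "")
  expect_equal(relaxed$modes, "")  # homozygous parent stays excluded

  v2 <- make_variants(chrom = "3", pos = 2000L, gt_proband = "1/1",
                      gt_mother = "0/1", gt_father = "0/1")
  expect_equal(assign_inheritance_modes(v2, default_pedigree(),
                                        "relaxed")$modes,
               "AUTOSOMAL_RECESSIVE")
})

test_that("pseudoautosomal exclusion removes PAR coordinates from the X-linked rule", {
  ped <- default_pedigree()
  v <- make_variants(chrom = "X", pos = c(61000L, 5000000L),
                     gt_proband = "1", gt_mother = "0/1", gt_father = "0")
  default <- assign_inheritance_modes(v, ped)
  expect_equal(default$modes, c("X_LINKED", "X_LINKED"))
  par_off <- assign_inheritance_modes(v, ped, par_exclude = TRUE)
  expect_equal(par_off$modes, c("", "X_LINKED"))
})

test_that("impact selection keeps allowed classes, warns on unknown terms", {
  v <- make_variants(consequence = c("missense_variant", "stop_gained",
                                     "synonymous_variant", "intron_variant",
                                     "made_up_term", NA))
  expect_warning(kept <- select_by_impact(v), "retained conservatively")
  expect_setequal(kept$consequence[!is.na(kept$consequence)],
                  c("missense_variant", "stop_gained", "made_up_term"))
  expect_match(kept$provenance[kept$consequence == "made_up_term"],
               "UNKNOWN_CONSEQUENCE")
  expect_false(any(is.na(kept$consequence)))  # NO_ANNOTATION dropped
})

test_that("impact selection matches a recount by class on generated labels", {
  tab <- impact_table()
  terms <- sample(tab$term, 500, replace = TRUE)
  v <- make_variants(consequence = terms)
  kept <- select_by_impact(v)
  expected <- sum(tab$impact[match(terms, tab$term)] %in%
                    c("HIGH", "MODERATE"))
  expect_equal(nrow(kept), expected)
})

test_that("frequency exclusions drop only on strict panel-maximum excess", {
  v <- make_variants(gnomAD_AJ_MAF = c(0.01991, NA, 0.06),
                     KGP_GMAF = c(0.001, 0.03, NA))
  kept <- apply_frequency_exclusions(v)
  # the not-rare-in-AJ frequency 0.01991 survives the 5% exclusion
  expect_equal(kept$gnomAD_AJ_MAF, 0.01991)
  # 0.03 > 2% 1KGP maximum drops; 0.06 > 5% AJ maximum drops
  expect_equal(nrow(kept), 1L)
  # all-absent frequencies survive
  expect_equal(nrow(apply_frequency_exclusions(make_variants())), 1L)
})

test_that("rare-AJ selection is strict at the 0.1% boundary", {
  v <- make_variants(gnomAD_AJ_MAF = c(0.01991, 0.0005, 0.001, NA))
  kept <- select_rare_aj(v)
  expect_setequal(kept$gnomAD_AJ_MAF, c(0.0005, NA))
})

test_that("tightening thresholds never enlarges any filter output", {
  sim <- simulate_trio(simulation_config(seed = 19L,
                                         n_autosomal_sites = 800L,
                                         n_x_sites = 100L))
  v <- sim$variants
  loose_q <- apply_quality_filters(v, quality_thresholds())
  tight_q <- apply_quality_filters(v, quality_thresholds(qd_min = 10,
                                                         mq_min = 55))
  expect_lte(nrow(tight_q$pass), nrow(loose_q$pass))
  key <- function(x) paste(x$chrom, x$pos)
  expect_true(all(key(tight_q$pass) %in% key(loose_q$pass)))

  loose_f <- apply_frequency_exclusions(v, frequency_thresholds())
  tight_f <- apply_frequency_exclusions(
    v, frequency_thresholds(dbsnp_gmaf_max = 0.01, kgp_gmaf_max = 0.005,
                            exac_maf_max = 0.01, aj_maf_max = 0.01,
                            aj_rare_max = 0.0005))
  expect_lte(nrow(tight_f), nrow(loose_f))
  expect_true(all(key(tight_f) %in% key(loose_f)))
})
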