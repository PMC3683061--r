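test_that("cohort generation is byte-identical under a fixed seed", {
  cfg <- simulation_config(n_subjects = 30, prevalence = 0.2, seed = 7,
                           image_size = 64, n_background_snps = 5)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_cohort(cfg, d1)
  simulate_cohort(cfg, d2)
  files <- list.files(d1, recursive = TRUE)
  expect_setequal(files, list.files(d2, recursive = TRUE))
  for (f in files) {
    a <- readBin(file.path(d1, f), "raw", file.size(file.path(d1, f)))
    b <- readBin(file.path(d2, f), "raw", file.size(file.path(d2, f)))
    expect_identical(a, b)
  }
  expect_equal(length(list.files(file.path(d1, "images"))), 30)
})

test_that("the truth file round-trips every configured parameter", {
  cfg <- simulation_config(n_subjects = 25, prevalence = 0.2, seed = 3,
                           image_size = 64, n_background_snps = 4,
                           maf_range = c(0.2, 0.4))
  d <- withr::local_tempdir()
  simulate_cohort(cfg, d)
  truth <- jsonlite::read_json(file.path(d, "truth.json"), simplifyVector = TRUE)
  expect_equal(truth$config$n_subjects, cfg$n_subjects)
  expect_equal(truth$config$prevalence, cfg$prevalence, tolerance = 1e-15)
  expect_equal(truth$config$image_contrast, cfg$image_contrast)
  expect_equal(truth$config$maf_range, cfg$maf_range)
  expect_equal(truth$config$seed, cfg$seed)
  expect_equal(sort(names(truth$odds_ratios)),
               sort(c(cfg$snp_panel$rs_id, names(truth$founder_freq)[
                 !names(truth$founder_freq) %in% cfg$snp_panel$rs_id])))
  expect_equal(length(truth$case_ids), round(25 * 0.2))
  expect_true(all(truth$founder_freq >= 0.2 & truth$founder_freq <= 0.4))
})

test_that("control genotypes are consistent with Hardy-Weinberg equilibrium", {
  cfg <- simulation_config(n_subjects = 400, prevalence = 0.05, seed = 13,
                           render_images = FALSE)
  d <- withr::local_tempdir()
  simulate_cohort(cfg, d)
  g <- read_genotypes_tsv(file.path(d, "genotypes.tsv"))
  labs <- utils::read.csv(file.path(d, "labels.csv"))
  ctrl <- labs$subject_id[labs$label < 0]
  pvals <- vapply(seq_along(g$snp_ids), function(j) {
    v <- g$calls[ctrl, j]; v <- v[!is.na(v)]
    hwe_exact_pvalue(sum(v == 0), sum(v == 1), sum(v == 2))
  }, numeric(1))
  expect_gt(mean(pvals > 0.001), 0.97)
})

test_that("a strong risk allele is enriched in cases", {
  panel <- read_panel()
  ors <- stats::setNames(rep(1, nrow(panel)), panel$rs_id)
  ors["rs634990"] <- 3.0
  cfg <- simulation_config(n_subjects = 2000, snp_or = ors, seed = 17,
                           maf_range = c(0.3, 0.3001), render_images = FALSE,
                           n_background_snps = 0)
  d <- withr::local_tempdir()
  simulate_cohort(cfg, d)
  g <- read_genotypes_tsv(file.path(d, "genotypes.tsv"))
  labs <- utils::read.csv(file.path(d, "labels.csv"))
  case <- labs$subject_id[labs$label > 0]
  ctrl <- labs$subject_id[labs$label < 0]
  j <- match("rs634990", g$snp_ids)
  cc <- g$calls[case, j]; vv <- g$calls[ctrl, j]
  tab <- matrix(c(sum(cc, na.rm = TRUE), 2 * sum(!is.na(cc)) - sum(cc, na.rm = TRUE),
                  sum(vv, na.rm = TRUE), 2 * sum(!is.na(vv)) - sum(vv, na.rm = TRUE)),
                2, 2)
  # one-sided two-proportion comparison of allele frequencies
  pt <- stats::prop.test(c(tab[1, 1], tab[2, 1]),
                         c(sum(tab[1, ]), sum(tab[2, ])),
                         alternative = "greater")
  expect_lt(pt$p.value, 0.01)
  expect_gt(tab[1, 1] / sum(tab[1, ]), tab[2, 1] / sum(tab[2, ]))
})

test_that("zero crescent contrast leaves positives and negatives indistinguishable", {
  set.seed(19)
  mg <- function(lab) {
    img <- render_fundus(lab, contrast = 0, size = 128)
    mean(img$pixels[, , 2])
  }
  pos <- replicate(60, mg(1))
  neg <- replicate(60, mg(-1))
  expect_gt(stats::t.test(pos, neg)$p.value, 0.01)
})

test_that("rendered images satisfy the raster contract and feed the pipeline", {
  set.seed(23)
  img <- render_fundus(1, contrast = 1, size = 256)
  expect_s3_class(img, "fundus_image")
  expect_equal(dim(img$pixels), c(256, 256, 3))
  expect_true(all(img$pixels >= 0 & img$pixels <= 1))
  pp <- preprocess_fundus(img)
  kp <- detect_keypoints(pp$gray, pp$mask)
  expect_gt(nrow(kp), 0)
})

test_that("positive-class crescents carry green-channel signal at high contrast", {
  set.seed(29)
  pos <- replicate(25, mean(render_fundus(1, contrast = 0.9, size = 128)$pixels[, , 2]))
  neg <- replicate(25, mean(render_fundus(-1, contrast = 0.9, size = 128)$pixels[, , 2]))
  expect_lt(stats::t.test(pos, neg)$p.value, 0.01)
  expect_gt(mean(pos), mean(neg))
})

test_that("switching one modality's effects off leaves it uninformative", {
  dv <- pmfuse:::default_demo_vars()
  dv$effect <- 0
  cfg <- simulation_config(n_subjects = 1200, prevalence = 0.05, seed = 31,
                           demo_vars = dv, render_images = FALSE)
  d <- withr::local_tempdir()
  simulate_cohort(cfg, d)
  cov <- clean_table(read_covariates(file.path(d, "covariates.csv"),
                                     file.path(d, "covariate_types.csv")))
  D <- encode_and_scale(cov)
  g <- qc_filter(read_genotypes_tsv(file.path(d, "genotypes.tsv")))$genotype
  G <- encode_additive(suppressMessages(select_panel(g, read_panel())))
  labs <- utils::read.csv(file.path(d, "labels.csv"))
  b <- suppressMessages(match_subjects(demographics = D, genotypes = G,
                                       labels = stats::setNames(labs$label, labs$subject_id)))
  tab <- compare_methods(run_protocol(b, methods = c("D", "G"), n_tests = 5,
                                      seed = 2))$table
  expect_lt(abs(tab$auc_mean[tab$method == "D"] - 0.5), 0.1)   # null band
  expect_gt(tab$auc_mean[tab$method == "G"], 0.65)             # unchanged signal
})

test_that("cohorts written with VCF output agree with the TSV genotypes", {
  skip_if_not_installed("vcfR")
  cfg <- simulation_config(n_subjects = 40, prevalence = 0.2, seed = 37,
                           render_images = FALSE, write_vcf = TRUE,
                           n_background_snps = 3)
  d <- withr::local_tempdir()
  simulate_cohort(cfg, d)
  g1 <- read_genotypes_tsv(file.path(d, "genotypes.tsv"))
  g2 <- suppressWarnings(read_genotypes_vcf(file.path(d, "genotypes.vcf")))
  expect_equal(g2$snp_ids, g1$snp_ids)
  common_ok <- vapply(seq_along(g1$snp_ids), function(j) {
    a <- g1$calls[, j]; b <- g2$calls[g1$subject_ids, j]
    if (!identical(is.na(a), is.na(b))) return(FALSE)
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    all(a == b) || all(a == 2 - b)   # identical up to allele polarity at MAF ties
  }, logical(1))
  expect_true(all(common_ok))
})
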