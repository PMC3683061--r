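#' Configuration of the synthetic cohort generator
#'
#' The defaults emulate the structure of a population-based eye study cohort:
#' 2,258 subjects at a pathological-myopia prevalence of 58/2258 (~2.6%),
#' genotypes for the shipped myopia SNP panel plus background markers
#' (87 SNPs in total), 44 demographic/clinical variables, and stylized fundus
#' photographs whose positive class carries a parapapillary-atrophy-like
#' crescent adjacent to the optic disc. Per-modality signal is partially
#' complementary: allelic odds ratios drive the genotype view, latent
#' standardized mean shifts the demographic view, and crescent contrast the
#' image view, each drawn independently given the label.
#'
#' @param n_subjects cohort size.
#' @param prevalence case fraction in (0, 1); the case count is
#'   `round(n_subjects * prevalence)`.
#' @param image_contrast crescent contrast in \[0, 1\] for the positive class;
#'   per-case severity is jittered by a multiplicative U(0.7, 1) factor,
#'   emulating variable atrophy severity.
#' @param image_noise_sd Gaussian pixel noise SD.
#' @param image_size rendered raster side (pixels).
#' @param snp_panel an `"snp_panel"` (default: the shipped panel).
#' @param snp_or named per-SNP allelic odds ratios; default: 2.8 for
#'   GWAS-sourced panel SNPs, 1.4 for the first 20 linkage-sourced SNPs,
#'   1.0 (null) otherwise. The defaults were calibrated so the
#'   genotype-only view reproduces the modality performance profile the
#'   framework is designed around (see the methods vignette).
#' @param n_background_snps extra null markers genotyped but absent from the
#'   panel.
#' @param maf_range founder minor-allele-frequency range (uniform draw).
#' @param genotype_missing_rate,demographic_missing_rate per-cell missingness.
#' @param demo_vars data.frame (`name`, `type`, `effect`, `n_levels`,
#'   `center`, `scale`) describing the demographic variables; default: the
#'   built-in 44-variable panel with 8 informative variables.
#' @param write_vcf also write a minimal VCF 4.2 alongside the genotype TSV.
#' @param render_images render per-subject fundus images (set `FALSE` for
#'   genotype/covariate-only studies; the image directory is then left empty).
#' @param seed master seed.
#' @return list of class `"simulation_config"`.
#' @export
simulation_config <- function(n_subjects = 2258, prevalence = 58 / 2258,
                              image_contrast = 0.9, image_noise_sd = 0.03,
                              image_size = 512,
                              snp_panel = NULL, snp_or = NULL,
                              n_background_snps = 30,
                              maf_range = c(0.1, 0.5),
                              genotype_missing_rate = 0.01,
                              demographic_missing_rate = 0.01,
                              demo_vars = NULL,
                              write_vcf = FALSE, render_images = TRUE,
                              seed = 1) {
  stopifnot(prevalence > 0, prevalence < 1, image_contrast >= 0,
            image_contrast <= 1, all(maf_range > 0), all(maf_range < 1))
  snp_panel <- snp_panel %||% read_panel()
  if (is.null(snp_or)) {
    snp_or <- rep(1.0, nrow(snp_panel))
    snp_or[snp_panel$source == "gwas"] <- 2.8
    linkage <- which(snp_panel$source == "linkage")
    snp_or[utils::head(linkage, 20)] <- 1.4
    names(snp_or) <- snp_panel$rs_id
  }
  if (any(snp_or <= 0)) pm_stop("odds ratios must be positive", "bad_config")
  demo_vars <- demo_vars %||% default_demo_vars()
  structure(list(n_subjects = n_subjects, prevalence = prevalence,
                 image_contrast = image_contrast,
                 image_noise_sd = image_noise_sd, image_size = image_size,
                 snp_panel = snp_panel, snp_or = snp_or,
                 n_background_snps = n_background_snps,
                 maf_range = maf_range,
                 genotype_missing_rate = genotype_missing_rate,
                 demographic_missing_rate = demographic_missing_rate,
                 demo_vars = demo_vars, write_vcf = write_vcf,
                 render_images = render_images, seed = seed),
            class = "simulation_config")
}

# The 44 demographic/clinical variables of the default cohort. `effect` is a
# standardized shift of the latent Gaussian in cases (categoricals are binned
# from the shifted latent). Informative variables mirror the risk factors a
# myopia study would flag: age, education, income, occupation, urbanicity and
# smoking.
default_demo_vars <- function() {
  inf <- data.frame(
    name = c("age", "education_level", "income_level", "job_category",
             "type_of_place", "ever_smoke", "current_smoker", "outdoor_hours"),
    type = c("numeric", "categorical", "categorical", "categorical",
             "categorical", "categorical", "categorical", "numeric"),
    effect = c(0.5, 0.45, 0.4, 0.35, 0.3, 0.3, 0.25, -0.3),
    n_levels = c(NA, 5, 4, 6, 4, 2, 2, NA),
    center = c(59, NA, NA, NA, NA, NA, NA, 2.5),
    scale = c(10, NA, NA, NA, NA, NA, NA, 1.2))
  noise_num <- c("height", "weight", "bmi", "systolic_bp", "diastolic_bp",
                 "pulse_pressure", "mean_arterial_pressure", "blood_creatinine",
                 "blood_glucose", "hba1c", "glycosylated_haemoglobin",
                 "total_cholesterol", "ldl_cholesterol", "hdl_cholesterol",
                 "triglycerides", "albumin_creatinine_ratio", "iop_right",
                 "iop_left", "axial_length_proxy", "corneal_curvature",
                 "visual_acuity_logmar", "pupil_diameter", "screen_hours",
                 "reading_hours", "sleep_hours", "ferritin", "vitamin_d",
                 "crp")
  centers <- c(163, 65, 24, 132, 76, 55, 95, 80, 5.6, 5.8, 5.7, 5.2, 3.1,
               1.3, 1.6, 10, 15, 15, 24, 7.7, 0.2, 4, 3, 2, 7, 90, 22, 2)
  scales <- c(9, 12, 4, 18, 10, 12, 11, 20, 1.2, 0.8, 0.8, 1.1, 0.9, 0.35,
              0.9, 8, 3, 3, 1.1, 0.3, 0.25, 0.8, 1.5, 1.2, 1.1, 40, 8, 1.5)
  noise_cat <- c("gender", "race", "marital_status", "place_of_birth",
                 "diabetes", "hypertension", "can_read", "can_write")
  cat_levels <- c(2, 3, 4, 3, 2, 2, 2, 2)
  rbind(inf,
        data.frame(name = noise_num, type = "numeric", effect = 0,
                   n_levels = NA, center = centers, scale = scales),
        data.frame(name = noise_cat, type = "categorical", effect = 0,
                   n_levels = cat_levels, center = NA, scale = NA))
}

#' Render a stylized fundus photograph
#'
#' Draws a 512x512 (configurable) RGB raster: dark surround, circular retinal
#' field with radial shading, a bright optic-disc ellipse at a jittered
#' temporal position, vessel-like dark polylines radiating from the disc, and
#' Gaussian pixel noise. Positive-class images additionally receive a bright
#' crescent rim adjacent to the disc -- a stylized parapapillary atrophy --
#' whose contrast is the `contrast` argument. The structure is carried by the
#' green channel (with a correlated red component), matching where retinal
#' detail lives in real fundus photographs. Uses the current RNG state;
#' callers seed it.
#'
#' @param label `+1` (case) or `-1` (control).
#' @param contrast crescent contrast in \[0, 1\]; ignored for controls.
#' @param noise_sd Gaussian pixel noise SD.
#' @param size raster side in pixels.
#' @param subject_id identifier for the resulting image.
#' @return a [fundus_image()].
#' @export
render_fundus <- function(label, contrast = 0.8, noise_sd = 0.03, size = 512,
                          subject_id = "subject") {
  stopifnot(label %in% c(-1, 1), contrast >= 0, contrast <= 1)
  H <- size; W <- size
  yy <- matrix(seq_len(H), H, W)
  xx <- matrix(seq_len(W), H, W, byrow = TRUE)
  cy <- H / 2; cx <- W / 2
  rr <- sqrt((yy - cy)^2 + (xx - cx)^2)
  field_r <- 0.47 * size
  field <- pmax(0, pmin(1, (field_r - rr) / (0.02 * size)))  # soft field edge
  shade <- 1 - 0.35 * (rr / field_r)^2

  R <- 0.08 + field * shade * 0.68
  G <- 0.04 + field * shade * 0.34
  B <- 0.02 + field * shade * 0.10

  # optic disc: bright ellipse, jittered around the temporal side
  dcx <- W * (0.63 + stats::runif(1, -0.03, 0.03))
  dcy <- H * (0.50 + stats::runif(1, -0.05, 0.05))
  da <- size * 0.065 * (1 + stats::runif(1, -0.1, 0.1))
  db <- da * 0.85
  de <- sqrt(((xx - dcx) / da)^2 + ((yy - dcy) / db)^2)
  disc <- pmax(0, pmin(1, (1.15 - de) / 0.3))
  R <- R + disc * field * 0.25
  G <- G + disc * field * 0.52
  B <- B + disc * field * 0.30

  # vessels: dark polylines radiating from the disc centre
  vmask <- matrix(0, H, W)
  n_vessels <- 6L
  for (v in seq_len(n_vessels)) {
    ang <- stats::runif(1, 0, 2 * pi)
    px <- dcx; py <- dcy
    wdt <- stats::runif(1, 1.5, 3)
    for (seg in 1:3) {
      len <- size * stats::runif(1, 0.1, 0.2)
      ang <- ang + stats::runif(1, -0.5, 0.5)
      steps <- max(2L, ceiling(len))
      tx <- px + cos(ang) * seq(0, len, length.out = steps)
      ty <- py + sin(ang) * seq(0, len, length.out = steps)
      keep <- tx >= 1 & tx <= W & ty >= 1 & ty <= H
      tx <- tx[keep]; ty <- ty[keep]
      if (!length(tx)) break
      rad <- max(1L, round(wdt * (1 - 0.2 * seg)))
      for (dy in -rad:rad) for (dx in -rad:rad) {
        if (dy * dy + dx * dx > rad * rad) next
        iy <- pmin(pmax(round(ty) + dy, 1), H)
        ix <- pmin(pmax(round(tx) + dx, 1), W)
        vmask[cbind(iy, ix)] <- 1
      }
      px <- tx[length(tx)]; py <- ty[length(ty)]
    }
  }
  vsoft <- gaussian_blur(vmask, 1) * field
  R <- R - vsoft * 0.25; G <- G - vsoft * 0.22; B <- B - vsoft * 0.05

  if (label > 0 && contrast > 0) {
    # parapapillary-atrophy-like crescent: bright rim hugging the disc on the
    # side facing away from the image centre
    phi <- atan2(dcy - cy, dcx - cx)  # outward direction
    theta <- atan2(yy - dcy, xx - dcx)
    dang <- abs(((theta - phi + pi) %% (2 * pi)) - pi)
    ring <- pmax(0, pmin(1, (de - 1.0) / 0.15)) * pmax(0, pmin(1, (1.9 - de) / 0.25))
    wedge <- pmax(0, pmin(1, (1.3 - dang) / 0.5))
    cres <- ring * wedge * field
    G <- G + cres * 0.55 * contrast
    R <- R + cres * 0.35 * contrast
    B <- B + cres * 0.15 * contrast
  }

  px <- array(0, c(H, W, 3))
  px[, , 1] <- R + stats::rnorm(H * W, 0, noise_sd)
  px[, , 2] <- G + stats::rnorm(H * W, 0, noise_sd)
  px[, , 3] <- B + stats::rnorm(H * W, 0, noise_sd)
  px[px < 0] <- 0; px[px > 1] <- 1
  fundus_image(px, subject_id)
}

#' Generate a complete synthetic cohort on disk
#'
#' Writes, under `dir`: `images/<id>.png`, `genotypes.tsv` (allele-pair
#' calls, `#chrom:` header line; optionally `genotypes.vcf`),
#' `covariates.csv` with `covariate_types.csv`, `labels.csv` and
#' `truth.json` (the full configuration plus realized founder allele
#' frequencies and per-case crescent contrasts). A fixed seed yields
#' byte-identical outputs.
#'
#' Disease labels are assigned to `round(n * prevalence)` randomly placed
#' subjects. Control genotypes are drawn in Hardy-Weinberg equilibrium at
#' founder frequencies ~ U(`maf_range`); case genotype probabilities are
#' reweighted per SNP by `OR^(minor-allele count)` and renormalized -- the
#' standard additive-risk construction, giving a closed-form case/control
#' frequency relationship. Demographic latents get additive standardized
#' shifts in cases; categorical variables are binned from the shifted latent.
#'
#' @param cfg a [simulation_config()].
#' @param dir output directory (created if needed).
#' @return invisibly, a manifest list with file paths, subject ids and the
#'   config.
#' @export
simulate_cohort <- function(cfg, dir) {
  stopifnot(inherits(cfg, "simulation_config"))
  n <- cfg$n_subjects
  n_cases <- round(n * cfg$prevalence)
  if (n_cases < 2) pm_stop("expected case count below 2; increase n or prevalence",
                           "too_few_positives")
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  ids <- sprintf("S%05d", seq_len(n))

  manifest <- with_seed(cfg$seed, {
    y <- rep(-1, n)
    y[sample.int(n, n_cases)] <- 1

    # ---- genotypes -------------------------------------------------------
    panel <- cfg$snp_panel
    rs_bg <- sprintf("rs9%07d", seq_len(cfg$n_background_snps))
    snp_ids <- c(panel$rs_id, rs_bg)
    chrom <- c(panel_chrom(panel), as.character(sample(1:22, cfg$n_background_snps,
                                                       replace = TRUE)))
    ors <- c(unname(cfg$snp_or[panel$rs_id]), rep(1, cfg$n_background_snps))
    p <- stats::runif(length(snp_ids), cfg$maf_range[1], cfg$maf_range[2])
    calls <- matrix(NA_real_, n, length(snp_ids), dimnames = list(ids, snp_ids))
    for (j in seq_along(snp_ids)) {
      q <- c((1 - p[j])^2, 2 * p[j] * (1 - p[j]), p[j]^2)
      qc <- q * ors[j]^(0:2)
      qc <- qc / sum(qc)
      u <- stats::runif(n)
      ctrl <- findInterval(u, cumsum(q)[1:2]) # 0,1,2
      case <- findInterval(u, cumsum(qc)[1:2])
      calls[, j] <- ifelse(y > 0, case, ctrl)
    }
    miss <- matrix(stats::runif(length(calls)) < cfg$genotype_missing_rate,
                   n, length(snp_ids))
    calls[miss] <- NA
    geno_alleles <- t(vapply(seq_along(snp_ids), function(j)
      sample(c("A", "C", "G", "T"), 2), character(2)))
    write_genotypes_tsv(calls, snp_ids, chrom, geno_alleles,
                        file.path(dir, "genotypes.tsv"))
    if (isTRUE(cfg$write_vcf))
      write_genotypes_vcf(calls, snp_ids, chrom, geno_alleles,
                          file.path(dir, "genotypes.vcf"))

    # ---- demographics ----------------------------------------------------
    dv <- cfg$demo_vars
    demo <- data.frame(row.names = ids)
    for (i in seq_len(nrow(dv))) {
      z <- stats::rnorm(n) + dv$effect[i] * (y > 0)
      if (dv$type[i] == "numeric") {
        demo[[dv$name[i]]] <- round(dv$center[i] + dv$scale[i] * z, 2)
      } else {
        nl <- dv$n_levels[i]
        br <- stats::qnorm(seq(0, 1, length.out = nl + 1))
        code <- cut(z, breaks = br, labels = FALSE, include.lowest = TRUE)
        demo[[dv$name[i]]] <- paste0("L", code)
      }
    }
    dmiss <- matrix(stats::runif(n * nrow(dv)) < cfg$demographic_missing_rate,
                    n, nrow(dv))
    for (i in seq_len(nrow(dv))) demo[[i]][dmiss[, i]] <- NA
    utils::write.csv(cbind(subject_id = ids, demo),
                     file.path(dir, "covariates.csv"), row.names = FALSE,
                     quote = FALSE, na = "NA")
    utils::write.csv(data.frame(name = dv$name, type = dv$type),
                     file.path(dir, "covariate_types.csv"), row.names = FALSE,
                     quote = FALSE)

    # ---- images ----------------------------------------------------------
    case_contrast <- stats::setNames(rep(0, n), ids)
    if (isTRUE(cfg$render_images)) {
      for (i in seq_len(n)) {
        contr <- if (y[i] > 0) cfg$image_contrast * stats::runif(1, 0.7, 1) else 0
        case_contrast[i] <- contr
        img <- render_fundus(y[i], contrast = contr,
                             noise_sd = cfg$image_noise_sd,
                             size = cfg$image_size, subject_id = ids[i])
        write_fundus(img, file.path(dir, "images", paste0(ids[i], ".png")))
      }
    }

    utils::write.csv(data.frame(subject_id = ids, label = y),
                     file.path(dir, "labels.csv"), row.names = FALSE,
                     quote = FALSE)

    # named vectors are wrapped as lists so JSON keeps the names
    truth <- list(
      config = cfg_to_list(cfg),
      founder_freq = as.list(stats::setNames(p, snp_ids)),
      odds_ratios = as.list(stats::setNames(ors, snp_ids)),
      demo_effects = as.list(stats::setNames(dv$effect, dv$name)),
      case_ids = ids[y > 0],
      case_contrast = as.list(case_contrast[y > 0]))
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
    list(dir = dir, subject_ids = ids, labels = stats::setNames(y, ids),
         paths = list(images = file.path(dir, "images"),
                      genotypes = file.path(dir, "genotypes.tsv"),
                      covariates = file.path(dir, "covariates.csv"),
                      covariate_types = file.path(dir, "covariate_types.csv"),
                      labels = file.path(dir, "labels.csv"),
                      truth = file.path(dir, "truth.json")),
         config = cfg)
  })
  invisible(manifest)
}

cfg_to_list <- function(cfg) {
  out <- unclass(cfg)
  out$snp_panel <- as.list(as.data.frame(out$snp_panel))
  out$demo_vars <- as.list(out$demo_vars)
  out$snp_or <- as.list(out$snp_or)
  out
}

# Chromosome labels from cytogenetic locations ("18p11.31" -> "18"); loci
# without a location are treated as autosomal ("1").
panel_chrom <- function(panel) {
  loc <- panel$location %||% rep(NA_character_, nrow(panel))
  chrom <- sub("^([0-9XY]+)[pq].*$", "\\1", loc)
  chrom[is.na(chrom) | chrom == "" | chrom == loc & !grepl("^[0-9XY]+$", chrom)] <- "1"
  chrom
}

write_genotypes_tsv <- function(calls, snp_ids, chrom, alleles, path) {
  n <- nrow(calls)
  strings <- matrix("./.", n, length(snp_ids))
  for (j in seq_along(snp_ids)) {
    maj <- alleles[j, 1]; mnr <- alleles[j, 2]
    gs <- c(paste0(maj, maj), paste0(maj, mnr), paste0(mnr, mnr))
    obs <- !is.na(calls[, j])
    strings[obs, j] <- gs[calls[obs, j] + 1]
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#chrom:\t", paste(chrom, collapse = "\t")), con)
  writeLines(paste(c("subject_id", snp_ids), collapse = "\t"), con)
  writeLines(paste(rownames(calls),
                   apply(strings, 1, paste, collapse = "\t"), sep = "\t"), con)
  invisible(path)
}

write_genotypes_vcf <- function(calls, snp_ids, chrom, alleles, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=pmfuse-synthetic-cohort",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(calls)), collapse = "\t")), con)
  gt_map <- c("0/0", "0/1", "1/1")
  for (j in seq_along(snp_ids)) {
    g <- ifelse(is.na(calls[, j]), "./.", gt_map[calls[, j] + 1])
    writeLines(paste(c(chrom[j], j * 1000L, snp_ids[j], alleles[j, 1],
                       alleles[j, 2], ".", "PASS", ".", "GT", g),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Load a simulated (or equivalently formatted) cohort from disk
#'
#' Reads the artifacts written by [simulate_cohort()] and runs the standard
#' feature pipeline: covariate cleaning and encoding, genotype QC, panel
#' restriction and additive encoding, BOW extraction with a codebook built
#' from a seeded half of the images, and subject matching.
#'
#' @param dir cohort directory.
#' @param codebook optional pre-built [build_codebook()]; by default one is
#'   built from the cohort's images.
#' @param config a [bow_config()].
#' @param seed seed for the codebook build.
#' @param panel SNP panel used for restriction (default: shipped panel).
#' @return a [match_subjects()] cohort bundle (attribute `"codebook"` holds
#'   the codebook used).
#' @export
load_cohort <- function(dir, codebook = NULL, config = bow_config(), seed = 1,
                        panel = NULL) {
  labs <- utils::read.csv(file.path(dir, "labels.csv"))
  labels <- stats::setNames(labs$label, labs$subject_id)

  cov <- read_covariates(file.path(dir, "covariates.csv"),
                         file.path(dir, "covariate_types.csv"))
  cov <- clean_table(cov)
  D <- encode_and_scale(cov)

  g <- read_genotypes_tsv(file.path(dir, "genotypes.tsv"))
  g <- qc_filter(g)$genotype
  g <- select_panel(g, panel %||% read_panel())
  G <- encode_additive(g)

  img_paths <- list.files(file.path(dir, "images"), pattern = "\\.png$",
                          full.names = TRUE)
  descs <- lapply(img_paths, fundus_descriptors, config = config)
  names(descs) <- sub("\\.png$", "", basename(img_paths))
  if (is.null(codebook))
    codebook <- build_codebook(descs, k = config$k, seed = seed, config = config)
  I <- matrix(0, length(descs), codebook$k,
              dimnames = list(names(descs), NULL))
  for (i in seq_along(descs))
    I[i, ] <- suppressWarnings(encode_bow(descs[[i]], codebook, config$norm))$histogram

  bundle <- match_subjects(demographics = D, genotypes = G, images = I,
                           labels = labels)
  attr(bundle, "codebook") <- codebook
  bundle
}
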