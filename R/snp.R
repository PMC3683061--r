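#' Construct a genotype matrix
#'
#' @param calls integer subject-by-SNP matrix of minor-allele counts in
#'   `{0, 1, 2}` with `NA` for missing calls; rownames are subject ids.
#' @param snp_ids unique rs identifiers, one per column.
#' @param chrom chromosome label per SNP (`"1"`..`"22"`, `"X"`, ...).
#' @return object of class `"genotype_matrix"`.
#' @export
genotype_matrix <- function(calls, snp_ids = colnames(calls), chrom = NULL) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "double"
  if (is.null(snp_ids)) pm_stop("snp_ids required", "bad_input")
  if (anyDuplicated(snp_ids)) pm_stop("snp_ids must be unique", "duplicate_snp")
  ok <- calls %in% c(0, 1, 2) | is.na(calls)
  if (!all(ok)) pm_stop("genotype calls must be 0/1/2 or missing", "bad_calls")
  colnames(calls) <- snp_ids
  if (is.null(chrom)) chrom <- rep(NA_character_, ncol(calls))
  structure(list(calls = calls, snp_ids = as.character(snp_ids),
                 chrom = as.character(chrom),
                 subject_ids = rownames(calls) %||% as.character(seq_len(nrow(calls)))),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("Genotype matrix:", nrow(x$calls), "subjects x", ncol(x$calls), "SNPs;",
      sprintf("%.2f%% missing\n", 100 * mean(is.na(x$calls))))
  invisible(x)
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact conditional test of genotype frequencies against Hardy-Weinberg
#' proportions: conditioning on the observed allele counts, the p-value is the
#' sum of probabilities of all heterozygote counts (same parity, same allele
#' totals) that are no more probable than the observed one. Used in genotype
#' QC to flag genotyping artifacts, which typically show up as heterozygote
#' deficits or excesses.
#'
#' Probabilities follow the hypergeometric-type recurrence
#' `P(h+2)/P(h) = 4 n_AA n_BB / ((h+2)(h+1))` over heterozygote counts `h`
#' of fixed parity, normalized over the attainable support.
#'
#' @param n_hom_major,n_het,n_hom_minor genotype counts (non-negative, total
#'   at least 1).
#' @return exact p-value in `(0, 1]`.
#' @export
hwe_exact_pvalue <- function(n_hom_major, n_het, n_hom_minor) {
  cts <- c(n_hom_major, n_het, n_hom_minor)
  if (any(!is.finite(cts)) || any(cts < 0) || any(cts != round(cts)))
    pm_stop("genotype counts must be non-negative integers", "bad_counts")
  n <- sum(cts)
  if (n < 1) pm_stop("at least one subject required", "bad_counts")
  n_minor <- 2 * n_hom_minor + n_het
  n_minor <- min(n_minor, 2 * n - n_minor)  # rarer allele count
  if (n_minor == 0) return(1.0)

  hets <- seq(n_minor %% 2, n_minor, by = 2)
  # unnormalized probabilities via the parity recurrence, anchored at the
  # largest attainable heterozygote count for numerical stability
  logp <- numeric(length(hets))
  for (k in seq_along(hets)[-1]) {
    h <- hets[k]
    naa <- (n_minor - (h - 2)) / 2        # hom-minor at the previous h
    nbb <- n - (h - 2) - naa              # hom-major at the previous h
    logp[k] <- logp[k - 1] + log(4 * naa * nbb) - log(h * (h - 1))
  }
  logp <- logp - max(logp)
  p <- exp(logp); p <- p / sum(p)
  p_obs <- p[match(n_het, hets)]
  min(1, sum(p[p <= p_obs * (1 + 1e-12)]))
}

#' Genotype quality control
#'
#' Applies the standard pre-analysis filters: subjects whose missing-call
#' fraction exceeds `subject_missing_max` are removed first; on the remaining
#' subjects, SNPs are removed when monomorphic, non-autosomal, below the
#' minor-allele-frequency floor, or failing the exact Hardy-Weinberg test at
#' `hwe_alpha`. Each dropped SNP is attributed to the first failing rule in
#' that order, so the removal reasons partition the dropped set.
#'
#' @param g a [genotype_matrix()].
#' @param subject_missing_max maximum tolerated per-subject missing fraction
#'   (default 0.05).
#' @param maf_min minimum minor allele frequency (default 0.01).
#' @param hwe_alpha HWE exact-test significance floor (default 1e-6).
#' @return list with the filtered `genotype` and a `report` (class
#'   `"qc_report"`) itemizing removals and thresholds.
#' @export
qc_filter <- function(g, subject_missing_max = 0.05, maf_min = 0.01,
                      hwe_alpha = 1e-6) {
  stopifnot(inherits(g, "genotype_matrix"))
  calls <- g$calls
  subj_miss <- rowMeans(is.na(calls))
  drop_subj <- subj_miss > subject_missing_max
  if (all(drop_subj)) pm_stop("all subjects removed by the missingness filter", "all_removed")
  calls <- calls[!drop_subj, , drop = FALSE]

  n_eff <- colSums(!is.na(calls))
  p_minor <- colSums(calls, na.rm = TRUE) / (2 * pmax(n_eff, 1))
  maf <- pmin(p_minor, 1 - p_minor)
  mono <- apply(calls, 2, function(v) length(unique(v[!is.na(v)])) <= 1L)
  nonauto <- !(g$chrom %in% as.character(1:22)) & !is.na(g$chrom)
  low_maf <- maf < maf_min
  hwe_p <- vapply(seq_len(ncol(calls)), function(j) {
    v <- calls[, j]; v <- v[!is.na(v)]
    if (!length(v)) return(1.0)
    hwe_exact_pvalue(sum(v == 0), sum(v == 1), sum(v == 2))
  }, numeric(1))
  hwe_fail <- hwe_p < hwe_alpha

  reason <- rep(NA_character_, ncol(calls))
  reason[hwe_fail] <- "hwe"
  reason[low_maf] <- "maf"
  reason[nonauto] <- "non_autosomal"
  reason[mono] <- "monomorphic"     # highest priority assigned last
  keep <- is.na(reason)
  if (!any(keep)) pm_stop("all SNPs removed by QC", "all_removed")

  out <- genotype_matrix(calls[, keep, drop = FALSE],
                         snp_ids = g$snp_ids[keep], chrom = g$chrom[keep])
  report <- structure(list(
    n_subjects_removed = sum(drop_subj),
    removed_subjects = g$subject_ids[drop_subj],
    n_snps_removed = c(monomorphic = sum(reason == "monomorphic", na.rm = TRUE),
                       non_autosomal = sum(reason == "non_autosomal", na.rm = TRUE),
                       maf = sum(reason == "maf", na.rm = TRUE),
                       hwe = sum(reason == "hwe", na.rm = TRUE)),
    removed_snps = split(g$snp_ids[!keep], reason[!keep]),
    thresholds = c(subject_missing_max = subject_missing_max,
                   maf_min = maf_min, hwe_alpha = hwe_alpha)),
    class = "qc_report")
  list(genotype = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Genotype QC report\n")
  cat("  subjects removed (missingness >", x$thresholds[["subject_missing_max"]],
      "):", x$n_subjects_removed, "\n")
  cat("  SNPs removed:\n")
  for (r in names(x$n_snps_removed))
    cat(sprintf("    %-14s %d\n", r, x$n_snps_removed[[r]]))
  invisible(x)
}

#' Read a SNP panel file
#'
#' The shipped panel (`system.file("extdata", "myopia_snp_panel.tsv",
#' package = "pmfuse")`) transcribes rs identifiers for myopia-associated loci
#' curated from genetic linkage studies and genome-wide association studies,
#' with gene/locus annotation and a source tag.
#'
#' @param path panel file: one rs ID per line, optional tab-separated `gene`,
#'   `location` and `source` columns, `#` comments allowed.
#' @return data.frame of class `"snp_panel"` with columns `rs_id`, `gene`,
#'   `location`, `source`.
#' @export
read_panel <- function(path = system.file("extdata", "myopia_snp_panel.tsv",
                                          package = "pmfuse")) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  parts <- strsplit(lines, "\t")
  col <- function(i) vapply(parts, function(p) if (length(p) >= i) p[i] else NA_character_, "")
  df <- data.frame(rs_id = col(1), gene = col(2), location = col(3),
                   source = col(4), stringsAsFactors = FALSE)
  if (!nrow(df)) pm_stop("panel file is empty", "empty_panel")
  if (!all(grepl("^rs[0-9]+$", df$rs_id)))
    pm_stop("panel contains syntactically invalid rs identifiers", "bad_panel")
  class(df) <- c("snp_panel", class(df))
  df
}

#' Restrict a genotype matrix to a SNP panel
#'
#' Keeps the intersection of panel and genotyped SNPs in panel order; subjects
#' are never reordered. Unmatched panel entries are reported via the
#' `"unmatched"` attribute (and a message), not an error.
#'
#' @param g a [genotype_matrix()].
#' @param panel an `"snp_panel"` data.frame or character vector of rs IDs.
#' @return panel-restricted `"genotype_matrix"`.
#' @export
select_panel <- function(g, panel) {
  stopifnot(inherits(g, "genotype_matrix"))
  rs <- if (is.data.frame(panel)) panel$rs_id else as.character(panel)
  if (!length(rs)) pm_stop("panel is empty", "empty_panel")
  hit <- rs[rs %in% g$snp_ids]
  if (!length(hit)) pm_stop("no panel SNP is present in the genotype data", "empty_intersection")
  miss <- setdiff(rs, hit)
  message(sprintf("select_panel: matched %d/%d panel SNPs", length(hit), length(rs)))
  idx <- match(hit, g$snp_ids)
  out <- genotype_matrix(g$calls[, idx, drop = FALSE], snp_ids = hit,
                         chrom = g$chrom[idx])
  attr(out, "unmatched") <- miss
  out
}

#' Additive encoding of genotypes to \[0, 1\]
#'
#' Maps minor-allele counts `{0, 1, 2}` to `{0, 0.5, 1}` so genotype features
#' share the scale of the other modalities; missing calls are imputed with the
#' per-SNP rounded mode computed on `fit_subjects` only (training subjects).
#'
#' @param g QC'd, panel-restricted [genotype_matrix()].
#' @param fit_subjects indices of training subjects used to compute imputation
#'   modes (default: all subjects).
#' @return a [feature_view()] with `source_id = "G"`.
#' @export
encode_additive <- function(g, fit_subjects = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  calls <- g$calls
  fit_subjects <- fit_subjects %||% seq_len(nrow(calls))
  for (j in seq_len(ncol(calls))) {
    v <- calls[fit_subjects, j]
    v <- v[!is.na(v)]
    if (!length(v)) pm_stop(sprintf("SNP %s has no observed training call", g$snp_ids[j]),
                            "all_missing")
    mode_call <- as.numeric(names(which.max(table(v))))
    calls[is.na(calls[, j]), j] <- round(mode_call)
  }
  x <- calls / 2
  rownames(x) <- g$subject_ids
  feature_view(x, source_id = "G")
}

#' Read genotypes from a simple TSV of allele-pair calls
#'
#' Format: header `subject_id` followed by one column per rs ID; calls are
#' two-letter allele strings such as `"AG"`, with `"./."` (or `"NN"`) for
#' missing. Each SNP is polarized to its minor allele as observed in the file
#' (ties at MAF 0.5 go to the alphabetically first allele, for determinism).
#'
#' @param path TSV path.
#' @param chrom optional chromosome labels per SNP (recycled from a
#'   `#chrom:` header line when present).
#' @return a [genotype_matrix()].
#' @export
read_genotypes_tsv <- function(path, chrom = NULL) {
  first <- readLines(path, n = 1L)
  tab <- utils::read.delim(path, check.names = FALSE, colClasses = "character",
                           comment.char = "")
  if (startsWith(first, "#chrom:")) {
    chrom <- strsplit(sub("^#chrom:\\s*", "", first), "\t")[[1]]
    tab <- utils::read.delim(path, check.names = FALSE, colClasses = "character",
                             skip = 1L)
  }
  ids <- tab[[1]]
  gt <- as.matrix(tab[, -1, drop = FALSE])
  snp_ids <- colnames(gt)
  calls <- matrix(NA_real_, nrow(gt), ncol(gt), dimnames = list(ids, snp_ids))
  for (j in seq_len(ncol(gt))) {
    s <- gt[, j]
    miss <- s %in% c("./.", "NN", "", NA)
    al <- strsplit(s[!miss], "")
    a1 <- vapply(al, `[`, "", 1); a2 <- vapply(al, `[`, "", 2)
    alleles <- sort(unique(c(a1, a2)))
    if (length(alleles) > 2) pm_stop(sprintf("SNP %s is not biallelic", snp_ids[j]), "bad_calls")
    if (length(alleles) == 0) next
    freq <- vapply(alleles, function(a) sum(a1 == a) + sum(a2 == a), numeric(1))
    minor <- if (length(alleles) == 1L) alleles else {
      if (freq[1] == freq[2]) alleles[1] else alleles[which.min(freq)]
    }
    cnt <- (a1 == minor) + (a2 == minor)
    v <- rep(NA_real_, length(s)); v[!miss] <- cnt
    calls[, j] <- v
  }
  genotype_matrix(calls, snp_ids = snp_ids, chrom = chrom)
}

#' Read genotypes from a VCF (GT field)
#'
#' Requires the suggested `vcfR` package. The ALT allele count is polarized to
#' the observed minor allele, as in [read_genotypes_tsv()].
#'
#' @param path VCF path (plain text).
#' @return a [genotype_matrix()].
#' @export
read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    pm_stop("the vcfR package is required to read VCF genotypes", "missing_dep")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  chrom <- vcfR::getCHROM(v)
  snp_ids <- vcfR::getID(v)
  alt_count <- function(s) {
    if (is.na(s) || s %in% c("./.", ".|.", ".")) return(NA_real_)
    sum(as.numeric(strsplit(s, "[/|]")[[1]]) > 0)
  }
  calls <- t(apply(gt, 1, function(r) vapply(r, alt_count, numeric(1))))
  # polarize each SNP to its observed minor allele
  for (i in seq_len(nrow(calls))) {
    p <- mean(calls[i, ], na.rm = TRUE) / 2
    if (is.finite(p) && p > 0.5) calls[i, ] <- 2 - calls[i, ]
  }
  calls <- t(calls)
  rownames(calls) <- colnames(gt)
  genotype_matrix(calls, snp_ids = snp_ids, chrom = sub("^chr", "", chrom))
}
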