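# Genotype I/O, allele frequencies, Hardy-Weinberg tests and model-based
# genotype coding.

#' Read a genotype matrix from VCF or CSV
#'
#' Reads biallelic genotypes into a subjects x markers minor-allele dosage
#' matrix. For VCF (GT field, v4.2) the ALT dosage is flipped whenever the
#' ALT allele is the major one, so entries always count the minor allele
#' determined from the observed frequencies (ties broken by lexicographic
#' allele order, with a message). Missing calls are preserved as `NA`.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"vcf"` or `"csv"`. CSV files must
#'   have subjects in rows (first column = subject id) and markers in
#'   columns, entries being minor-allele counts.
#' @return List with `genotypes` (integer matrix, subjects x markers) and
#'   `variants` (data.frame: marker, major, minor, maf).
#' @seealso [write_genotypes_vcf()], [write_genotypes_csv()]
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "csv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE))
      "vcf" else "csv"
  if (format == "vcf") .read_genotypes_vcf(path) else .read_genotypes_csv(path)
}

.read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix)))  # single-variant files come back as a vector
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt, fixed = TRUE)
  if (any(multi))
    stop("multi-allelic site(s) not supported: ",
         paste(fix[multi, "ID"], collapse = ", "))
  gt <- vcfR::extract.gt(v, element = "GT")
  # ALT allele dosage from GT strings like 0/0, 0|1, ./.
  dose <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt),
                 dimnames = dimnames(gt))
  clean <- gsub("\\|", "/", gt)
  dose[clean == "0/0"] <- 0L
  dose[clean %in% c("0/1", "1/0")] <- 1L
  dose[clean == "1/1"] <- 2L
  G <- t(dose)  # subjects x markers
  colnames(G) <- fix[, "ID"]
  .orient_to_minor(G, ref = fix[, "REF"], alt = alt)
}

.read_genotypes_csv <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  G <- as.matrix(d[, -1, drop = FALSE])
  storage.mode(G) <- "integer"
  rownames(G) <- d[[1]]
  if (any(G[!is.na(G)] < 0 | G[!is.na(G)] > 2))
    stop("CSV dosages must lie in {0, 1, 2} or be missing")
  # CSV dosages are minor-allele counts by contract: never reoriented, so
  # write -> read round trips are identities even when the sample frequency
  # drifts above 0.5 for near-0.5 markers
  freq <- colMeans(G, na.rm = TRUE) / 2
  if (any(freq > 0.5, na.rm = TRUE))
    message("observed dosage frequency > 0.5 for ",
            paste(colnames(G)[which(freq > 0.5)], collapse = ", "),
            "; kept as given (CSV dosages are minor-allele counts by contract)")
  list(genotypes = G,
       variants = data.frame(marker = colnames(G), major = "A1", minor = "A2",
                             maf = unname(pmin(freq, 1 - freq)),
                             stringsAsFactors = FALSE, row.names = NULL))
}

# ensure dosages count the observed minor allele; flip columns where the
# counted allele has frequency > 0.5
.orient_to_minor <- function(G, ref, alt) {
  freq <- colMeans(G, na.rm = TRUE) / 2
  flip <- !is.na(freq) & freq > 0.5
  tie <- !is.na(freq) & freq == 0.5
  if (any(tie)) {
    # tie: minor = lexicographically first allele label
    flip[tie] <- alt[tie] > ref[tie]
    message("MAF exactly 0.5 for ",
            paste(colnames(G)[tie], collapse = ", "),
            "; minor allele chosen by lexicographic order")
  }
  if (any(flip & !tie))
    message("flipped to minor-allele dosage: ",
            paste(colnames(G)[flip & !tie], collapse = ", "))
  G[, flip] <- 2L - G[, flip, drop = FALSE]
  major <- ifelse(flip, alt, ref)
  minor <- ifelse(flip, ref, alt)
  list(genotypes = G,
       variants = data.frame(marker = colnames(G), major = major,
                             minor = minor,
                             maf = unname(allele_frequencies(G)),
                             stringsAsFactors = FALSE, row.names = NULL))
}

#' Write genotypes as a minimal GT-only VCF (v4.2)
#'
#' @param G Subjects x markers minor-allele dosage matrix.
#' @param variants Optional data.frame with `marker`, `major`, `minor`
#'   (defaults to generic allele labels).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_genotypes_vcf <- function(G, path, variants = NULL) {
  if (is.null(variants))
    variants <- data.frame(marker = colnames(G),
                           major = "A", minor = "C",
                           stringsAsFactors = FALSE)
  stopifnot(all(colnames(G) %in% variants$marker))
  variants <- variants[match(colnames(G), variants$marker), ]
  gt_code <- c("0/0", "0/1", "1/1")
  lines <- c("##fileformat=VCFv4.2",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", rownames(G)), collapse = "\t"))
  body <- vapply(seq_len(ncol(G)), function(k) {
    g <- G[, k]
    calls <- ifelse(is.na(g), "./.", gt_code[g + 1L])
    paste(c("1", as.character(k), variants$marker[k],
            variants$major[k], variants$minor[k], ".", "PASS", ".", "GT",
            calls), collapse = "\t")
  }, character(1))
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Write genotypes as a CSV dosage matrix
#'
#' @param G Subjects x markers minor-allele dosage matrix.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_genotypes_csv <- function(G, path) {
  d <- data.frame(subject_id = rownames(G), G, check.names = FALSE,
                  stringsAsFactors = FALSE)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Per-marker minor-allele frequencies
#'
#' `MAF = (2 n_hom_minor + n_het) / (2 n_called)`; missing calls are excluded
#' from the denominator. Frequencies are conventionally computed on unrelated
#' subjects only (probands plus controls), via `subset`.
#'
#' @param G Subjects x markers dosage matrix (minor-allele counts).
#' @param subset Optional logical or integer subject subset.
#' @return Named numeric vector of frequencies.
#' @export
allele_frequencies <- function(G, subset = NULL) {
  G <- as.matrix(G)
  if (!is.null(subset)) G <- G[subset, , drop = FALSE]
  if (nrow(G) == 0L) stop("subject subset is empty")
  colMeans(G, na.rm = TRUE) / 2
}

#' Chi-square test of Hardy-Weinberg equilibrium
#'
#' Tests observed genotype counts `(n_AA, n_Aa, n_aa)` against the
#' Hardy-Weinberg proportions `p^2, 2pq, q^2` at the allele frequency
#' estimated from the same counts; the statistic is
#' `sum((obs - exp)^2 / exp)` on 1 degree of freedom. An exact
#' (conditional-on-allele-count) test is available for small samples.
#'
#' @param counts Genotype counts: a length-3 vector
#'   `(hom major, het, hom minor)` or an n x 3 matrix of such rows.
#' @param method `"chisq"` (default) or `"exact"` (conditional enumeration
#'   of heterozygote counts).
#' @return data.frame with `chi2`, `df`, `p`, `maf` and `monomorphic` (for
#'   monomorphic markers the test is undefined; `p = 1` with a warning).
#' @examples
#' hwe_test(c(25, 50, 25))   # exact HWE proportions: chi2 = 0, p = 1
#' hwe_test(c(30, 40, 30))   # chi2 = 4, p ~ 0.0455
#' @export
hwe_test <- function(counts, method = c("chisq", "exact")) {
  method <- match.arg(method)
  cm <- if (is.matrix(counts)) counts else matrix(counts, nrow = 1)
  stopifnot(ncol(cm) == 3, all(cm >= 0))
  if (any(rowSums(cm) == 0)) stop("total genotype count must be positive")
  out <- data.frame(chi2 = NA_real_, df = 1L, p = NA_real_,
                    maf = NA_real_, monomorphic = FALSE)
  out <- out[rep(1L, nrow(cm)), , drop = FALSE]
  rownames(out) <- rownames(cm)
  for (i in seq_len(nrow(cm))) {
    n <- sum(cm[i, ])
    q <- (2 * cm[i, 3] + cm[i, 2]) / (2 * n)
    out$maf[i] <- min(q, 1 - q)
    if (q == 0 || q == 1) {
      out$monomorphic[i] <- TRUE
      out$chi2[i] <- 0
      out$p[i] <- 1
      next
    }
    if (method == "chisq") {
      expd <- n * c((1 - q)^2, 2 * q * (1 - q), q^2)
      out$chi2[i] <- sum((cm[i, ] - expd)^2 / expd)
      out$p[i] <- stats::pchisq(out$chi2[i], df = 1, lower.tail = FALSE)
    } else {
      out$p[i] <- .hwe_exact_p(cm[i, ])
    }
  }
  if (any(out$monomorphic))
    warning("monomorphic marker(s): HWE test undefined, p set to 1")
  out
}

# exact HWE p-value: probability, conditional on the minor-allele count, of
# heterozygote counts at most as probable as the observed one
.hwe_exact_p <- function(cnt) {
  n <- sum(cnt)
  nm <- 2 * cnt[3] + cnt[2]           # minor allele copies
  hets <- seq(nm %% 2, min(nm, 2 * n - nm), by = 2)
  logp <- lfactorial(n) - lfactorial((nm - hets) / 2) - lfactorial(hets) -
    lfactorial(n - (nm + hets) / 2) + hets * log(2) +
    lfactorial(nm) + lfactorial(2 * n - nm) - lfactorial(2 * n)
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  sum(pr[pr <= pr[match(cnt[2], hets)] * (1 + 1e-12)])
}

#' Per-gene Bonferroni thresholds for HWE screening
#'
#' `0.05 / m` where `m` is the number of markers tested within the gene
#' (0.017 for 3-marker genes, 0.013 for 4, 0.008 for 6).
#'
#' @param genes Character vector of gene labels, one per marker.
#' @return Named numeric vector of per-marker thresholds.
#' @export
hwe_thresholds <- function(genes) {
  tab <- table(genes)
  stats::setNames(0.05 / as.numeric(tab[genes]), genes)
}

#' Code genotypes by the minor-allele-frequency rule
#'
#' Markers with MAF at or above `maf_threshold` (inclusive) keep the additive
#' three-level dosage coding (0/1/2 copies of the minor allele); all other
#' markers are coded by presence/absence of the minor allele (0/1). MAFs are
#' computed on the designated unrelated subjects.
#'
#' @param G Subjects x markers minor-allele dosage matrix.
#' @param maf_threshold Inclusive additive-coding threshold (default 0.35).
#' @param unrelated Optional logical/integer subset on which MAFs are
#'   computed (probands plus controls); defaults to all subjects.
#' @param maf Optional externally supplied MAF vector overriding the
#'   computation.
#' @return Numeric matrix of coded predictors with attributes `coding`
#'   (per-marker `"additive3"`/`"dominant2"`) and `maf`.
#' @export
code_genotypes <- function(G, maf_threshold = 0.35, unrelated = NULL,
                           maf = NULL) {
  G <- as.matrix(G)
  if (is.null(maf)) maf <- allele_frequencies(G, subset = unrelated)
  stopifnot(length(maf) == ncol(G))
  coding <- ifelse(maf >= maf_threshold, "additive3", "dominant2")
  out <- G
  storage.mode(out) <- "double"
  dom <- which(coding == "dominant2")
  for (k in dom) out[, k] <- pmin(out[, k], 1)
  attr(out, "coding") <- stats::setNames(coding, colnames(G))
  attr(out, "maf") <- maf
  out
}

#' Genotype QC report
#'
#' One row per marker: gene, alleles, minor-allele frequency in the
#' unrelated subset, HWE chi-square and p-value, the per-gene Bonferroni
#' threshold, a deviation flag and the coding model assigned by the MAF rule.
#'
#' @param G Subjects x markers dosage matrix.
#' @param variants data.frame with `marker`, `gene`, `major`, `minor`.
#' @param unrelated Logical/integer subset of unrelated subjects.
#' @param maf_threshold Additive-coding threshold.
#' @return data.frame QC table.
#' @export
qc_report <- function(G, variants, unrelated = NULL, maf_threshold = 0.35) {
  stopifnot(all(colnames(G) %in% variants$marker))
  variants <- variants[match(colnames(G), variants$marker), ]
  Gs <- if (is.null(unrelated)) G else G[unrelated, , drop = FALSE]
  counts <- t(apply(Gs, 2, function(g)
    c(sum(g == 0, na.rm = TRUE), sum(g == 1, na.rm = TRUE),
      sum(g == 2, na.rm = TRUE))))
  hwe <- hwe_test(counts)
  maf <- allele_frequencies(G, subset = unrelated)
  thr <- hwe_thresholds(variants$gene)
  data.frame(
    marker = variants$marker,
    gene = variants$gene,
    major = variants$major,
    minor = variants$minor,
    maf = round(unname(maf), 4),
    hwe_chi2 = round(hwe$chi2, 4),
    hwe_p = round(hwe$p, 4),
    hwe_threshold = round(unname(thr), 3),
    hwe_flag = hwe$p < thr,
    coding = ifelse(maf >= maf_threshold, "additive3", "dominant2"),
    stringsAsFactors = FALSE, row.names = NULL
  )
}
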