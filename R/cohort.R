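#' Configuration for the synthetic family cohort generator
#'
#' Builds and validates the full parameter set of the generator: family
#' structure, marker panel with per-marker minor-allele frequencies,
#' standardized structural paths, age effects, residual correlation among
#' mediators, and the within-family share of residual variance.
#'
#' All paths are standardized: genotypes (after additive or presence/absence
#' coding), age, mediators and the reading outcome are all unit-variance, so
#' an entry of `A` is the expected SD change in a mediator per SD of coded
#' genotype. The generator checks the implied variance budget of every
#' equation at construction time and refuses configurations whose residual
#' variance would be negative.
#'
#' @param n_families Number of nuclear families with at least one affected
#'   proband.
#' @param sibs_per_family Either a single count or a vector of candidate
#'   offspring counts per family; counts are drawn with `sib_weights`.
#' @param sib_weights Sampling weights over `sibs_per_family` (default tuned
#'   so the expected offspring per family is about 2.23, i.e. roughly 223
#'   offspring for 100 families).
#' @param n_controls Number of unrelated typical-reader controls (singleton
#'   families).
#' @param markers Marker metadata data.frame as from [dd_marker_panel()];
#'   must contain `marker`, `gene`, `maf`, `is_deletion`.
#' @param A 5 x n_marker standardized gene-to-mediator path matrix (rows in
#'   [ep_names()] order).
#' @param B Length-5 standardized mediator-to-reading path vector.
#' @param Cp Length-n_marker standardized direct gene-to-reading paths.
#' @param age_paths Length-5 standardized age-to-mediator paths.
#' @param mediator_residual_corr 5 x 5 residual correlation matrix (unit
#'   diagonal, positive semi-definite).
#' @param family_icc Proportion in `[0, 1)` of residual variance of mediators
#'   and outcome shared within a family.
#' @param age_range Age range in years; ages are drawn uniformly over it.
#' @param maf_threshold Minor-allele-frequency threshold at or above which a
#'   marker is coded additively (0/1/2); below it, presence/absence (0/1).
#' @param emit_trials If `TRUE`, [generate_cohort()] also emits raw
#'   trial-level task tables via [emit_trial_data()].
#' @param trial_scale Multiplier on the per-task trial counts when emitting
#'   trial data (1 = the task battery's real sizes).
#' @param missing_rate Per-genotype missingness probability.
#' @param seed Default random seed used by [generate_cohort()] when no seed
#'   is supplied there.
#'
#' @return An object of class `cohort_config`.
#' @examples
#' cfg <- cohort_config(n_families = 20, n_controls = 10)
#' cohort <- generate_cohort(cfg, seed = 1)
#' @export
cohort_config <- function(n_families = 100,
                          sibs_per_family = c(2, 3),
                          sib_weights = c(0.77, 0.23),
                          n_controls = 79,
                          markers = dd_marker_panel(),
                          A = default_gene_paths(markers),
                          B = default_mediator_paths(),
                          Cp = default_direct_paths(markers),
                          age_paths = default_age_paths(),
                          mediator_residual_corr = default_residual_corr(),
                          family_icc = 0.2,
                          age_range = c(7, 14),
                          maf_threshold = 0.35,
                          emit_trials = FALSE,
                          trial_scale = 1,
                          missing_rate = 0,
                          seed = 1L) {
  stopifnot(is.data.frame(markers),
            all(c("marker", "gene", "maf", "is_deletion") %in% names(markers)))
  p <- nrow(markers)
  if (any(markers$maf <= 0 | markers$maf > 0.5))
    stop("per-marker `maf` must lie in (0, 0.5]")
  if (anyDuplicated(markers$marker))
    stop("marker ids must be unique")

  A <- as.matrix(A)
  if (!all(dim(A) == c(5L, p)))
    stop("`A` must be a 5 x ", p, " matrix (mediators x markers)")
  if (is.null(rownames(A))) rownames(A) <- ep_names()
  if (is.null(colnames(A))) colnames(A) <- markers$marker
  if (length(B) != 5L) stop("`B` must have length 5")
  if (is.null(names(B))) names(B) <- ep_names()
  if (length(Cp) != p) stop("`Cp` must have length ", p)
  if (is.null(names(Cp))) names(Cp) <- markers$marker
  if (length(age_paths) != 5L) stop("`age_paths` must have length 5")
  if (is.null(names(age_paths))) names(age_paths) <- ep_names()

  Rm <- as.matrix(mediator_residual_corr)
  if (!all(dim(Rm) == c(5L, 5L)) || !isTRUE(all.equal(Rm, t(Rm))) ||
      !isTRUE(all.equal(unname(diag(Rm)), rep(1, 5))))
    stop("`mediator_residual_corr` must be a symmetric 5 x 5 correlation matrix with unit diagonal")
  if (min(eigen(Rm, symmetric = TRUE, only.values = TRUE)$values) < -1e-10)
    stop("`mediator_residual_corr` must be positive semi-definite")
  if (family_icc < 0 || family_icc >= 1)
    stop("`family_icc` must lie in [0, 1)")
  stopifnot(length(age_range) == 2L, age_range[2] > age_range[1])

  cfg <- structure(list(
    n_families = as.integer(n_families),
    sibs_per_family = as.integer(sibs_per_family),
    sib_weights = sib_weights / sum(sib_weights),
    n_controls = as.integer(n_controls),
    markers = markers,
    A = A, B = B, Cp = Cp,
    age_paths = age_paths,
    mediator_residual_corr = Rm,
    family_icc = family_icc,
    age_range = age_range,
    maf_threshold = maf_threshold,
    emit_trials = isTRUE(emit_trials),
    trial_scale = trial_scale,
    missing_rate = missing_rate,
    seed = as.integer(seed)
  ), class = "cohort_config")

  # variance budget: every structural equation must leave positive residual
  # variance once its standardized paths are accounted for.
  vb <- .variance_budget(cfg)
  bad <- names(vb$resid)[vb$resid <= 0]
  if (length(bad))
    stop("infeasible variance budget: standardized paths of equation(s) ",
         paste(bad, collapse = ", "),
         " imply residual variance <= 0; reduce |A|, |B|, |Cp| or |age_paths|")
  cfg
}

# Residual variances implied by the standardized paths. Coded genotypes are
# mutually independent and independent of age, so the explained variance of
# mediator j is sum_k A[j,k]^2 + age_paths[j]^2. The outcome adds the
# mediator covariance implied by the model.
.variance_budget <- function(cfg) {
  expl_m <- rowSums(cfg$A^2) + cfg$age_paths^2
  resid_m <- 1 - expl_m
  # implied mediator covariance (unit-variance mediators)
  Psi <- diag(sqrt(pmax(resid_m, 0))) %*% cfg$mediator_residual_corr %*%
    diag(sqrt(pmax(resid_m, 0)))
  Sigma_M <- cfg$A %*% t(cfg$A) + tcrossprod(cfg$age_paths) + Psi
  expl_y <- sum(cfg$Cp^2) +
    drop(cfg$B %*% Sigma_M %*% cfg$B) +
    2 * drop(cfg$B %*% cfg$A %*% cfg$Cp)
  resid <- c(resid_m, reading = 1 - expl_y)
  names(resid)[1:5] <- ep_names()
  list(resid = resid, Psi = Psi, Sigma_M = Sigma_M)
}

#' @export
#' @method print cohort_config
print.cohort_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat("  families:", x$n_families, " controls:", x$n_controls,
      " markers:", nrow(x$markers), "\n")
  cat("  nonzero gene->mediator paths:", sum(x$A != 0),
      "; nonzero mediator->reading paths:", sum(x$B != 0), "\n")
  cat("  family ICC:", x$family_icc, " ages:",
      paste(x$age_range, collapse = "-"), "years\n")
  invisible(x)
}

# HWE genotype draw: allele pairs Bernoulli(q); returns minor-allele counts.
.draw_hwe <- function(n, q) {
  stats::rbinom(n, 1L, q) + stats::rbinom(n, 1L, q)
}

#' Generate a synthetic family-structured cohort
#'
#' Draws a cohort of nuclear families (one proband plus siblings) and
#' unrelated controls with genotypes, ages, latent endophenotype (mediator)
#' values and a reading composite, from the structural model encoded in a
#' [cohort_config()]. Sibling genotypes arise from explicit parental
#' simulation: for each family two parental genotypes are drawn from
#' Hardy-Weinberg proportions and transmitted Mendelianly, so family
#' clustering is genetically real. Mediators and outcome follow the
#' linear-Gaussian structural model with a shared within-family residual
#' component (intraclass correlation `family_icc`) and the configured
#' residual correlation among mediators; every variable has unit marginal
#' variance.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed; defaults to `config$seed`. The same config and
#'   seed always reproduce the identical cohort.
#' @return An object of class `dd_cohort`: a list with `subjects` (subject
#'   id, family id, role, age), `genotypes` (subjects x markers minor-allele
#'   counts, possibly with `NA`), `markers`, `mediators` (latent standardized
#'   endophenotype values), `reading`, `truth` (the generating parameters)
#'   and, when `config$emit_trials`, `trials` (see [emit_trial_data()]).
#' @examples
#' cohort <- generate_cohort(cohort_config(n_families = 15, n_controls = 10), seed = 7)
#' head(cohort$subjects)
#' @export
generate_cohort <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(as.integer(seed))
  mk <- config$markers
  p <- nrow(mk)

  # family sizes
  sizes <- if (length(config$sibs_per_family) == 1L) {
    rep(config$sibs_per_family, config$n_families)
  } else {
    sample(config$sibs_per_family, config$n_families, replace = TRUE,
           prob = config$sib_weights)
  }
  n_off <- sum(sizes)
  n <- n_off + config$n_controls

  fam_of_child <- rep(seq_len(config$n_families), times = sizes)
  child_idx <- sequence(sizes)
  subjects <- data.frame(
    subject_id = c(sprintf("F%03d_%d", fam_of_child, child_idx),
                   sprintf("C%03d", seq_len(config$n_controls))),
    family_id = c(sprintf("F%03d", fam_of_child),
                  sprintf("C%03d", seq_len(config$n_controls))),
    role = c(ifelse(child_idx == 1L, "proband", "sibling"),
             rep("control", config$n_controls)),
    stringsAsFactors = FALSE
  )

  # genotypes: parental alleles per family, Mendelian transmission to
  # offspring; controls drawn directly from HWE proportions
  G <- matrix(0L, nrow = n, ncol = p,
              dimnames = list(subjects$subject_id, mk$marker))
  for (k in seq_len(p)) {
    q <- mk$maf[k]
    par_alleles <- matrix(stats::rbinom(config$n_families * 4L, 1L, q),
                          ncol = 4L)  # maternal a1,a2; paternal a1,a2
    mat <- par_alleles[cbind(fam_of_child,
                             sample(1:2, n_off, replace = TRUE))]
    pat <- par_alleles[cbind(fam_of_child,
                             sample(3:4, n_off, replace = TRUE))]
    G[seq_len(n_off), k] <- mat + pat
    G[n_off + seq_len(config$n_controls), k] <-
      .draw_hwe(config$n_controls, q)
  }
  if (config$missing_rate > 0) {
    miss <- matrix(stats::runif(n * p) < config$missing_rate, n, p)
    G[miss] <- NA_integer_
  }

  # ages, theoretical z-scale (uniform distribution over the range)
  age <- stats::runif(n, config$age_range[1], config$age_range[2])
  subjects$age <- round(age, 2)
  age_z <- (age - mean(config$age_range)) /
    (diff(config$age_range) / sqrt(12))

  # coded, theoretically standardized genotype predictors
  Gz <- matrix(0, n, p, dimnames = dimnames(G))
  for (k in seq_len(p)) {
    q <- mk$maf[k]
    g <- G[, k]
    if (q >= config$maf_threshold) {
      mu <- 2 * q; v <- 2 * q * (1 - q)
    } else {
      g <- pmin(g, 1L)
      mu <- 1 - (1 - q)^2; v <- mu * (1 - mu)
    }
    z <- (as.numeric(g) - mu) / sqrt(v)
    z[is.na(z)] <- 0  # missing genotypes contribute no genetic effect
    Gz[, k] <- z
  }

  vb <- .variance_budget(config)
  icc <- config$family_icc

  # residual draws: family-level component shared by siblings + individual
  # component, both with the configured cross-mediator correlation
  ev <- eigen(config$mediator_residual_corr, symmetric = TRUE)
  Crt <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0))) %*% t(ev$vectors)
  Dm <- diag(sqrt(vb$resid[1:5]))
  fam_ids <- unique(subjects$family_id)
  n_fam_all <- length(fam_ids)
  fam_index <- match(subjects$family_id, fam_ids)

  fam_m <- matrix(stats::rnorm(n_fam_all * 5), n_fam_all, 5) %*% Crt %*%
    (sqrt(icc) * Dm)
  ind_m <- matrix(stats::rnorm(n * 5), n, 5) %*% Crt %*%
    (sqrt(1 - icc) * Dm)
  M <- Gz %*% t(config$A) + tcrossprod(age_z, config$age_paths) +
    fam_m[fam_index, , drop = FALSE] + ind_m
  colnames(M) <- ep_names()

  resid_y <- vb$resid["reading"]
  fam_y <- stats::rnorm(n_fam_all, 0, sqrt(icc * resid_y))
  ind_y <- stats::rnorm(n, 0, sqrt((1 - icc) * resid_y))
  reading <- drop(Gz %*% config$Cp + M %*% config$B) +
    fam_y[fam_index] + ind_y

  cohort <- structure(list(
    subjects = subjects,
    genotypes = G,
    markers = mk,
    mediators = data.frame(subject_id = subjects$subject_id, M,
                           stringsAsFactors = FALSE),
    reading = stats::setNames(reading, subjects$subject_id),
    truth = list(A = config$A, B = config$B, Cp = config$Cp,
                 age_paths = config$age_paths,
                 residual_variances = vb$resid,
                 family_icc = icc),
    trials = NULL
  ), class = "dd_cohort")

  if (config$emit_trials)
    cohort$trials <- emit_trial_data(cohort, config)
  cohort
}

#' @export
#' @method print dd_cohort
print.dd_cohort <- function(x, ...) {
  tab <- table(x$subjects$role)
  cat("Synthetic dyslexia cohort:", nrow(x$subjects), "subjects (",
      paste(names(tab), tab, sep = " = ", collapse = ", "), ")\n")
  cat("  markers:", ncol(x$genotypes),
      "; families:", length(unique(x$subjects$family_id)), "\n")
  cat("  trial-level data:", if (is.null(x$trials)) "absent" else "present", "\n")
  invisible(x)
}

#' Assemble the subject-level analysis table of a cohort
#'
#' Combines coded genotype predictors (additive or presence/absence by the
#' minor-allele-frequency rule, computed on unrelated subjects), the latent
#' or scored endophenotype table, age, family id and the reading composite
#' into one data.frame ready for [path_mediation()].
#'
#' @param cohort A `dd_cohort`.
#' @param endophenotypes Optional replacement endophenotype table (e.g. the
#'   output of [score_cohort_trials()]); defaults to the latent mediators.
#' @param maf_threshold Coding threshold passed to [code_genotypes()].
#' @return data.frame with subject id, family id, age, one column per coded
#'   marker, the five endophenotype scores, and `reading`.
#' @export
mediation_data <- function(cohort, endophenotypes = NULL,
                           maf_threshold = 0.35) {
  stopifnot(inherits(cohort, "dd_cohort"))
  unrel <- cohort$subjects$role %in% c("proband", "control")
  coded <- code_genotypes(cohort$genotypes, maf_threshold = maf_threshold,
                          unrelated = unrel)
  eps <- if (is.null(endophenotypes)) cohort$mediators else endophenotypes
  stopifnot(all(c("subject_id", ep_names()) %in% names(eps)))
  m <- match(cohort$subjects$subject_id, eps$subject_id)
  out <- data.frame(
    subject_id = cohort$subjects$subject_id,
    family_id = cohort$subjects$family_id,
    age = cohort$subjects$age,
    coded[, , drop = FALSE],
    eps[m, ep_names(), drop = FALSE],
    reading = as.numeric(cohort$reading),
    check.names = FALSE,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}
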