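#' Candidate-gene marker panel for developmental dyslexia
#'
#' The default panel of 20 biallelic markers spanning the five historical
#' dyslexia candidate genes (DYX1C1, DCDC2, KIAA0319, ROBO1, GRIN2B),
#' including the READ1 intron-2 microdeletion of DCDC2 (a presence/absence
#' marker). Minor-allele frequencies are those observed in unrelated subjects
#' (probands plus typical readers) of the reference cohort and serve as the
#' synthetic generator's defaults.
#'
#' rs2143340 lies in the TTRAP/KIAA0319 region and is carried under the
#' KIAA0319 label.
#'
#' @return A data.frame with one row per marker and columns `marker`, `gene`,
#'   `major`, `minor` (allele labels), `maf` (minor-allele frequency in
#'   unrelated subjects) and `is_deletion` (presence/absence microdeletion
#'   flag).
#' @examples
#' panel <- dd_marker_panel()
#' table(panel$gene)
#' @export
dd_marker_panel <- function() {
  data.frame(
    marker = c("rs3743205", "rs57809907", "rs189983504",
               "rs793842", "READ1", "rs793862",
               "rs4504469", "rs2038137", "rs9461045", "rs2143340",
               "rs333491", "rs6803202", "rs9853895", "rs7644521",
               "rs5796555", "rs1012586", "rs2268119", "rs2216128",
               "rs11609779", "rs2192973"),
    gene = rep(c("DYX1C1", "DCDC2", "KIAA0319", "ROBO1", "GRIN2B"),
               times = c(3, 3, 4, 4, 6)),
    major = c("G", "G", "C",
              "C", "N", "G",
              "C", "G", "C", "A",
              "A", "T", "C", "T",
              "-", "G", "A", "A",
              "C", "G"),
    minor = c("A", "T", "G",
              "T", "DEL", "A",
              "T", "T", "T", "G",
              "G", "C", "T", "C",
              "A", "C", "T", "G",
              "T", "A"),
    maf = c(0.073, 0.109, 0.101,
            0.416, 0.078, 0.242,
            0.366, 0.358, 0.208, 0.161,
            0.455, 0.494, 0.413, 0.164,
            0.306, 0.305, 0.232, 0.216,
            0.183, 0.225),
    is_deletion = c(FALSE, FALSE, FALSE,
                    FALSE, TRUE, FALSE,
                    FALSE, FALSE, FALSE, FALSE,
                    FALSE, FALSE, FALSE, FALSE,
                    FALSE, FALSE, FALSE, FALSE,
                    FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

#' Mediator (endophenotype) names in canonical order
#'
#' The five endophenotype scores used as mediators, in the order used
#' throughout the package: multisensory warning effect (WE), motion-illusion
#' slope after log transform (RTLI_b), motion-illusion threshold after square
#' root transform (RTLI_t), rapid auditory processing score (RAP) and
#' normalized rapid-naming reaction time (RAN_rt).
#'
#' @return Character vector of length 5.
#' @export
ep_names <- function() c("WE", "RTLI_b", "RTLI_t", "RAP", "RAN_rt")

#' Residual-correlation pairs of the default path model
#'
#' Mediator pairs whose residuals are allowed to covary in the default
#' multiple-mediator model (collinearity control among the endophenotypes).
#'
#' @return List of length-2 character vectors.
#' @export
default_residual_pairs <- function() {
  list(c("WE", "RTLI_b"),
       c("RAP", "RTLI_b"),
       c("RAP", "RTLI_t"),
       c("RAP", "RAN_rt"),
       c("RTLI_b", "RTLI_t"))
}

# Default standardized gene -> mediator path matrix (5 x 20): the ROBO1
# rs9853895 dosage lowers RAP performance and the (log) illusion slope.
default_gene_paths <- function(markers = dd_marker_panel()) {
  A <- matrix(0, nrow = 5, ncol = nrow(markers),
              dimnames = list(ep_names(), markers$marker))
  A["RAP",    "rs9853895"] <- -0.188
  A["RTLI_b", "rs9853895"] <- -0.249
  A
}

# Default standardized mediator -> reading paths.
default_mediator_paths <- function() {
  c(WE = 0, RTLI_b = 0.249, RTLI_t = 0, RAP = 0.298, RAN_rt = 0)
}

# Default standardized direct gene -> reading paths.
default_direct_paths <- function(markers = dd_marker_panel()) {
  cp <- stats::setNames(numeric(nrow(markers)), markers$marker)
  cp["rs9853895"] <- -0.111
  cp
}

# Default standardized age -> mediator paths (school-age maturation:
# better auditory processing and a stronger illusion slope, faster naming).
default_age_paths <- function() {
  c(WE = 0, RTLI_b = 0.2, RTLI_t = 0, RAP = 0.3, RAN_rt = -0.3)
}

# Default residual correlation among mediators: 0.2 on the pairs the model
# frees, 0 elsewhere.
default_residual_corr <- function() {
  R <- diag(5)
  dimnames(R) <- list(ep_names(), ep_names())
  for (pr in default_residual_pairs()) {
    R[pr[1], pr[2]] <- 0.2
    R[pr[2], pr[1]] <- 0.2
  }
  R
}
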