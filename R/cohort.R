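#' Simulate a study-like territory cohort
#'
#' Draws per-territory MBF and TPR measurements directly at the territory
#' level, emulating the clinical study design: 43 patients contributing 94
#' coronary territories (each patient 2 or 3), about half haemodynamically
#' significant by FFR.  Ischaemic territories draw MBF from N(71.3, 24.3)
#' and TPR from N(0.85, 0.31); normal territories from N(92.2, 21.6) and
#' N(1.00, 0.25).  Because both indices derive from the same flow map, the
#' two draws share a latent severity component with correlation `rho`
#' (default 0.6).  FFR is drawn uniformly below / above the 0.80 threshold
#' according to status.
#'
#' This generator serves the statistical battery (ROC, DeLong, cluster
#' adjustment) with realistic score distributions; it bypasses the imaging
#' chain, which [run_experiment()] exercises instead.
#'
#' @param n_patients number of patients.
#' @param n_territories total territories (default scales the study's
#'   94/43 ratio, at least 2 per patient).
#' @param prevalence fraction of ischaemic territories (default 48/94).
#' @param mbf_ischaemic,mbf_normal,tpr_ischaemic,tpr_normal length-2
#'   `c(mean, sd)` of the measurement distributions.
#' @param rho latent correlation between the MBF and TPR draws.
#' @param seed integer seed.
#' @return a data.frame of territory records: `patient_id`, `territory`,
#'   `mbf`, `tpr`, `ffr`.
#' @export
simulate_cohort <- function(n_patients = 43, n_territories = NULL,
                            prevalence = 48 / 94,
                            mbf_ischaemic = c(71.3, 24.3),
                            mbf_normal = c(92.2, 21.6),
                            tpr_ischaemic = c(0.85, 0.31),
                            tpr_normal = c(1.00, 0.25),
                            rho = 0.6, seed = 1L) {
  stop_if_not(n_patients >= 2, "at least 2 patients are required")
  stop_if_not(rho >= 0 && rho < 1, "`rho` must lie in [0, 1)")
  if (is.null(n_territories)) {
    n_territories <- max(2 * n_patients, round(n_patients * 94 / 43))
  }
  stop_if_not(n_territories >= 2 * n_patients &&
                n_territories <= 3 * n_patients,
              "need between 2 and 3 territories per patient")
  set.seed(seed)
  counts <- rep(2L, n_patients)
  extra <- n_territories - 2L * n_patients
  if (extra > 0) counts[sample.int(n_patients, extra)] <- 3L
  patient_id <- rep(sprintf("P%03d", seq_len(n_patients)), counts)
  territory <- unlist(lapply(counts, function(k) {
    sample(c("LAD", "LCX", "RCA"), k)
  }))
  n <- n_territories
  n_isch <- round(prevalence * n)
  status <- rep(FALSE, n)
  status[sample.int(n, n_isch)] <- TRUE

  z <- stats::rnorm(n)
  e1 <- stats::rnorm(n)
  e2 <- stats::rnorm(n)
  mix <- function(e) sqrt(rho) * z + sqrt(1 - rho) * e
  mu_mbf <- ifelse(status, mbf_ischaemic[1], mbf_normal[1])
  sd_mbf <- ifelse(status, mbf_ischaemic[2], mbf_normal[2])
  mu_tpr <- ifelse(status, tpr_ischaemic[1], tpr_normal[1])
  sd_tpr <- ifelse(status, tpr_ischaemic[2], tpr_normal[2])
  mbf <- pmax(mu_mbf + sd_mbf * mix(e1), 5)
  tpr <- pmax(mu_tpr + sd_tpr * mix(e2), 0.05)
  ffr <- ifelse(status, stats::runif(n, 0.35, 0.80),
                stats::runif(n, 0.805, 1.0))
  data.frame(patient_id = patient_id, territory = territory,
             mbf = mbf, tpr = tpr, ffr = ffr, stringsAsFactors = FALSE)
}
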