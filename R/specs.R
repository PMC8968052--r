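# Builtin generator specs.
#
# clinical_generator_spec(): the default stated world.  Category marginals,
# per-variable missingness fractions and outcome prevalences are calibrated
# to the published multi-trial training cohort: categorical marginals are
# the published counts renormalised over non-missing patients; marginals of
# categorised continuous variables come from the published mean/sd under a
# normal assumption at the default cut points (derivations in the methods
# vignette).  The dependency structure is the expert DAG (so the expert
# structure is well-specified under the default generator) plus arcs tying
# in the four variables the experts excluded.
#
# recovery_generator_spec(): a 10-node tiered network with hand-fixed,
# strongly dependent CPTs and small parent sets, sized so that parameter
# and structure recovery at n = 50,000 / 10,000 are statistically feasible.
# Values were fixed at design time.

var_spec <- function(name, tier, levels, target = NULL, parents = NULL,
                     betas = NULL, cpt = NULL) {
  list(name = name, tier = tier, levels = levels,
       target = if (!is.null(target)) target / sum(target),
       parents = parents, betas = betas, cpt = cpt)
}

#' Default clinical generator spec (published-cohort calibration)
#'
#' Fourteen categorical predictors on tiers 0-4 plus binary local-recurrence
#' outcomes at 2, 3 and 5 years on the final tier; each outcome has the six
#' expert-structure parents.  Includes per-variable missingness fractions
#' and 14 synthetic trial-cohort sizes summing to 6754.
#'
#' @return Generator spec list (see source for the schema).
#' @export
clinical_generator_spec <- function() {
  out_par <- c("clinical_t", "clinical_n", "surgery_procedure",
               "crm", "pathological_t", "pathological_n")
  out_beta <- c(clinical_t = 0.6, clinical_n = 0.6, surgery_procedure = 0.8,
                crm = 1.0, pathological_t = 1.0, pathological_n = 1.0)
  outcome <- function(name, prev) {
    var_spec(name, 5L, c("False", "True"), c(1 - prev, prev),
             parents = out_par, betas = out_beta)
  }
  list(
    name = "clinical",
    variables = list(
      var_spec("age", 0L, c("<50", "50-65", ">65"), c(0.1175, 0.5287, 0.3538)),
      var_spec("gender", 0L, c("Male", "Female"), c(0.6976, 0.3024)),
      var_spec("clinical_t", 1L, c("cT1", "cT2", "cT3", "cT4"),
               c(0.0192, 0.0798, 0.8248, 0.0763)),
      var_spec("clinical_n", 1L, c("cN0", "cN1", "cN2"),
               c(0.4349, 0.4799, 0.0852),
               parents = "clinical_t", betas = c(clinical_t = 0.8)),
      var_spec("tumor_distance", 1L, c("<=5cm", ">5cm"), c(0.3735, 0.6265)),
      var_spec("neoadjuvant_chemo", 2L, c("5FU+OXI", "5FUbased", "NoChemo"),
               c(0.2178, 0.5418, 0.2404),
               parents = c("clinical_t", "clinical_n"),
               betas = c(clinical_t = 0.5, clinical_n = 0.5)),
      var_spec("rt_dose", 2L, c("<=45Gy", ">45Gy"), c(0.2266, 0.7734),
               parents = "clinical_t", betas = c(clinical_t = 0.5)),
      var_spec("overall_treatment_time", 2L, c("<=38d", ">38d"),
               c(0.5598, 0.4402), parents = "rt_dose",
               betas = c(rt_dose = 0.6)),
      var_spec("interval_rt_surgery", 2L, c("<=1wk", ">1wk"),
               c(0.5987, 0.4013)),
      var_spec("surgery_procedure", 3L, c("APR", "ARbased", "NoSurgery"),
               c(0.3118, 0.6678, 0.0205),
               parents = "tumor_distance", betas = c(tumor_distance = 0.8)),
      var_spec("crm", 4L, c("Negative", "Positive"), c(0.5552, 0.4448),
               parents = c("pathological_t", "tumor_distance"),
               betas = c(pathological_t = 0.8, tumor_distance = 0.5)),
      var_spec("pathological_t", 4L, c("ypT0", "ypT1", "ypT2", "ypT3", "ypT4"),
               c(0.1257, 0.0617, 0.2922, 0.4852, 0.0352),
               parents = c("clinical_t", "neoadjuvant_chemo", "rt_dose",
                           "interval_rt_surgery"),
               betas = c(clinical_t = 1.0, neoadjuvant_chemo = 0.6,
                         rt_dose = 0.5, interval_rt_surgery = 0.4)),
      var_spec("pathological_n", 4L, c("ypN0", "ypN1", "ypN2"),
               c(0.6909, 0.2463, 0.0627),
               parents = c("clinical_n", "pathological_t"),
               betas = c(clinical_n = 0.8, pathological_t = 0.8)),
      var_spec("adjuvant_chemo", 4L, c("5FU+OXI", "5FUbased", "NoChemo"),
               c(0.1259, 0.4828, 0.3913),
               parents = c("pathological_t", "pathological_n"),
               betas = c(pathological_t = 0.5, pathological_n = 0.5)),
      outcome("lr2y", 385 / (385 + 4168)),
      outcome("lr3y", 487 / (487 + 3445)),
      outcome("lr5y", 599 / (599 + 2036))
    ),
    outcomes = c("lr2y", "lr3y", "lr5y"),
    missingness = c(
      age = 0.017, gender = 0.002, clinical_t = 0.102, clinical_n = 0.342,
      rt_dose = 0.225, surgery_procedure = 0.033, crm = 0.819,
      overall_treatment_time = 0.261, neoadjuvant_chemo = 0.042,
      tumor_distance = 0.167, interval_rt_surgery = 0.367,
      adjuvant_chemo = 0.043, pathological_n = 0.080, pathological_t = 0.080,
      lr2y = 0.158, lr3y = 0.272, lr5y = 0.512
    ),
    cohorts = stats::setNames(
      c(850, 780, 720, 660, 600, 550, 500, 450, 400, 350, 300, 250, 200, 144),
      sprintf("trial%02d", 1:14))
  )
}

#' Ten-node tiered recovery spec (explicit CPTs)
#'
#' The ground truth used by the parameter- and structure-recovery suites:
#' nine predictors `x1..x9` on tiers 0-3 (x9 deliberately isolated) and a
#' binary outcome `y` with three parents.  All CPTs are explicit and far
#' from independence.
#'
#' @return Generator spec list.
#' @export
recovery_generator_spec <- function() {
  two <- function(p) cbind(1 - p, p)
  list(
    name = "recovery",
    variables = list(
      var_spec("x1", 0L, c("a", "b", "c"), cpt = matrix(c(0.5, 0.3, 0.2), 1L)),
      var_spec("x2", 0L, c("no", "yes"), cpt = matrix(c(0.6, 0.4), 1L)),
      var_spec("x3", 0L, c("no", "yes"), cpt = matrix(c(0.45, 0.55), 1L)),
      var_spec("x9", 0L, c("no", "yes"), cpt = matrix(c(0.6, 0.4), 1L)),
      # parent configs: first listed parent varies fastest
      var_spec("x4", 1L, c("no", "yes"), parents = c("x1", "x2"),
               cpt = two(c(0.15, 0.45, 0.75, 0.30, 0.60, 0.90))),
      var_spec("x5", 1L, c("lo", "mid", "hi"), parents = c("x1", "x3"),
               cpt = matrix(c(0.70, 0.20, 0.10,
                              0.30, 0.50, 0.20,
                              0.10, 0.30, 0.60,
                              0.45, 0.35, 0.20,
                              0.15, 0.45, 0.40,
                              0.05, 0.20, 0.75), ncol = 3L, byrow = TRUE)),
      var_spec("x6", 2L, c("no", "yes"), parents = c("x4", "x5"),
               cpt = two(c(0.10, 0.45, 0.35, 0.70, 0.60, 0.90))),
      var_spec("x7", 3L, c("lo", "mid", "hi"), parents = c("x5", "x6"),
               cpt = matrix(c(0.65, 0.25, 0.10,
                              0.30, 0.45, 0.25,
                              0.10, 0.40, 0.50,
                              0.40, 0.35, 0.25,
                              0.15, 0.40, 0.45,
                              0.05, 0.25, 0.70), ncol = 3L, byrow = TRUE)),
      var_spec("x8", 3L, c("no", "yes"), parents = "x6",
               cpt = two(c(0.25, 0.70))),
      var_spec("y", 4L, c("False", "True"), parents = c("x2", "x7", "x8"),
               target = c(0.7, 0.3),
               cpt = two(c(0.05, 0.15, 0.15, 0.30, 0.35, 0.55,
                           0.20, 0.35, 0.40, 0.60, 0.65, 0.85)))
    ),
    outcomes = "y",
    missingness = numeric(0),
    cohorts = NULL
  )
}
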