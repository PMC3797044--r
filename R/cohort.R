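# Two-group phantom cohorts with a latent severity coupling imaging effects
# and behavioral outcomes.

#' Specify a synthetic two-group cohort
#'
#' Cases receive the stated fractional reduction of the principal eigenvalue
#' inside the effect regions and the stated bundle thinning in the named
#' bundles. Each subject additionally carries a latent severity `s` (controls
#' centered at 0, cases at 1, SD `severity_sd`) driving the behavioral
#' outcomes through monotone links plus noise, so every reported
#' brain-behavior correlation sign has a plantable synthetic analogue.
#'
#' @param n_controls,n_cases Group sizes (default 11 and 10, the study
#'   design this cohort emulates).
#' @param effect_regions Atlas region names receiving the eigenvalue
#'   reduction in cases.
#' @param fa_effect Fractional reduction of lambda1 at severity 1 (0-1).
#' @param thinning Fraction of bundle voxels demoted to background at
#'   severity 1 (0-1).
#' @param thin_bundles Names of bundles subject to thinning.
#' @param severity_sd SD of the latent severity within groups.
#' @param subject_jitter SD of the per-subject log-normal jitter applied to
#'   bundle eigenvalues (biological between-subject variability).
#' @param seed Integer seed.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_controls = 11, n_cases = 10,
                        effect_regions = c("amygdala", "hippocampal formation",
                                           "hippocampus", "cingulate cortex"),
                        fa_effect = 0.3, thinning = 0.3,
                        thin_bundles = c("anxiety_left", "anxiety_right",
                                         "memory_left", "memory_right"),
                        severity_sd = 0.3, subject_jitter = 0.02,
                        seed = 1L) {
  if (n_controls < 2 || n_cases < 2) stop("need at least 2 subjects per group")
  if (fa_effect < 0 || fa_effect > 1) stop("fa_effect must be in [0,1]")
  if (thinning < 0 || thinning > 1) stop("thinning must be in [0,1]")
  structure(list(n_controls = n_controls, n_cases = n_cases,
                 effect_regions = effect_regions, fa_effect = fa_effect,
                 thinning = thinning, thin_bundles = thin_bundles,
                 severity_sd = severity_sd, subject_jitter = subject_jitter,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# behavioral outcomes as monotone functions of severity s and gender;
# coefficients chosen once to mirror the sign/significance structure of an
# open-field + object-recognition battery (anxious subjects: long latency,
# few central crossings, peripheral dwell, low discrimination index).
simulate_behavior <- function(s, gender, session = 600) {
  n <- length(s)
  male <- as.numeric(gender == "male")
  latency <- clip(exp(1.1 + 2.2 * s + 0.2 * male + rnorm(n, 0, 0.5)), 0, session)
  internal_sq <- rpois(n, exp(2.2 - 1.0 * s))
  external_sq <- pmax(0L, round(exp(4.6 - 0.45 * s + rnorm(n, 0, 0.25))))
  total_sq <- internal_sq + external_sq
  time_internal <- clip(exp(3.1 - 1.6 * s + rnorm(n, 0, 0.6)), 0, 0.2 * session)
  time_external <- session - time_internal
  total_time <- clip(424 - 94 * s + rnorm(n, 0, 80), 30, session)
  velocity <- ifelse(total_time > 0, total_sq / total_time, 0)
  grooming <- rpois(n, exp(0.1 - 0.8 * pmax(s, -0.1)))
  rearing <- rpois(n, exp(3.15 - 0.4 * s - 0.1 * male))
  familiar_t <- pmax(0.5, 3.6 + 3.1 * s + rnorm(n, 0, 1.5))
  novel_t <- pmax(0.2, 9.0 - 1.0 * s + rnorm(n, 0, 2.0))
  di <- clip((novel_t - familiar_t) / (novel_t + familiar_t), -1, 1)
  data.frame(
    latency = latency, total_squares = total_sq, total_time = total_time,
    velocity = velocity, external_squares = external_sq,
    time_external = time_external, internal_squares = internal_sq,
    time_internal = time_internal, grooming = grooming, rearing = rearing,
    familiar_time = familiar_t, novel_time = novel_t, di = di,
    learned = di > 0)
}

#' Simulate a two-group DWI + behavior cohort
#'
#' @param cspec A [cohort_spec()].
#' @param pspec A [phantom_spec()] serving as the template phantom.
#' @param scheme A [gradient_scheme()].
#' @param materialize If `TRUE` (default) each subject's phantom is generated
#'   and returned; if `FALSE` only per-subject phantom specifications are
#'   returned (realize them one at a time with [make_phantom()] to bound
#'   memory on larger grids).
#' @return List of class `cohort` with `subjects` (phantoms or phantom
#'   specs), `table` (the study table: id, group, gender, birth weight,
#'   behavioral scores, latent `severity`), and `specs` (always the
#'   per-subject phantom specs).
#' @export
simulate_cohort <- function(cspec, pspec, scheme, materialize = TRUE) {
  stopifnot(inherits(cspec, "cohort_spec"), inherits(pspec, "phantom_spec"))
  set.seed(cspec$seed)
  n <- cspec$n_controls + cspec$n_cases
  group <- factor(rep(c("control", "case"), c(cspec$n_controls, cspec$n_cases)),
                  levels = c("control", "case"))
  gender <- factor(sample(rep(c("female", "male"), length.out = n)),
                   levels = c("female", "male"))
  severity <- rnorm(n, mean = ifelse(group == "case", 1, 0),
                    sd = cspec$severity_sd)
  is_case <- group == "case"
  subject_seeds <- sample.int(.Machine$integer.max - 1L, n)
  beh <- simulate_behavior(severity, gender)
  birth_weight <- round(49.5 - 11 * severity + rnorm(n, 0, 4), 2)
  table <- cbind(
    data.frame(id = sprintf("S%02d", seq_len(n)), group = group,
               gender = gender, birth_weight = birth_weight),
    beh, severity = severity)

  specs <- vector("list", n)
  for (i in seq_len(n)) {
    sp <- pspec
    jit <- exp(rnorm(1, 0, cspec$subject_jitter))
    sp$bundles <- lapply(sp$bundles, function(b) {
      b$evals <- b$evals * jit
      b
    })
    if (cspec$fa_effect > 0 && is_case[i])
      sp$lambda1_scale <- list(regions = cspec$effect_regions,
                               factor = 1 - cspec$fa_effect)
    if (cspec$thinning > 0 && is_case[i])
      sp$dropout <- setNames(rep(cspec$thinning, length(cspec$thin_bundles)),
                             cspec$thin_bundles)
    sp$seed <- subject_seeds[i]
    specs[[i]] <- sp
  }
  subjects <- if (materialize) lapply(specs, make_phantom, scheme = scheme)
              else specs
  structure(list(subjects = subjects, table = table, specs = specs,
                 materialized = materialize),
            class = "cohort")
}
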