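#' Standard synthetic study designs
#'
#' Frozen cohort specifications used throughout the package's examples, tests
#' and acceptance runs, so every analysis refers to the same desk-scale study
#' conditions:
#' \describe{
#'   \item{standard_rct_spec()}{the balanced healthy-group RCT: 4 subjects,
#'     one 6-day session, one target meal per day with near-constant
#'     carbohydrate, postprandial-walk conditions low/moderate/high on days
#'     (1,4)/(2,5)/(3,6) -- 24 segments after segmentation.}
#'   \item{recovery_rct_spec()}{a larger balanced design for parameter
#'     recovery: 20 subjects, two 6-day sessions (12 segments per person).}
#'   \item{evaluation_patient_spec()}{the standard imbalanced free-living
#'     patient cohort for the model comparison: 30 patients, two monthly
#'     3-day sessions, 3 meals/day (360 training / 180 test segments), with
#'     postprandial exercise after only 5\% of meals and mostly low energy
#'     expenditure, so that segments above the 60 kcal threshold are rare
#'     (about 2\% of segments), mirroring the pronounced imbalance of
#'     free-living patient data while the cohort is large enough that the
#'     exercise test stratum is usually populated.}
#'   \item{transfer_recovery_patient_spec()}{a patient cohort with adequate
#'     postprandial exercise for identifiability of the mean-shift parameter:
#'     12 patients, two 3-day sessions, exercise after half the meals at a
#'     higher typical energy expenditure. Its exercise-strength mean is the
#'     healthy default attenuated by 0.5.}
#' }
#'
#' @name standard_specs
#' @return A [cohort_spec()].
NULL

#' @rdname standard_specs
#' @export
standard_rct_spec <- function() cohort_spec("healthy")

#' @rdname standard_specs
#' @export
recovery_rct_spec <- function() cohort_spec("healthy", n_persons = 20L,
                                            n_sessions = 2L)

#' @rdname standard_specs
#' @export
evaluation_patient_spec <- function() cohort_spec("patient", n_persons = 30L,
                                                  n_sessions = 2L,
                                                  exercise_fraction = 0.05)

#' @rdname standard_specs
#' @export
transfer_recovery_patient_spec <- function()
  cohort_spec("patient", n_persons = 12L, n_sessions = 2L,
              exercise_fraction = 0.5, ee_mean = 80)
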