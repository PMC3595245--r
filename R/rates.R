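#' Select one assessment per patient at random
#'
#' When a patient has several visits, downstream per-joint rate and
#' correlation analyses use a single representative assessment per patient,
#' drawn uniformly over that patient's visits. Deterministic given `seed`.
#'
#' @param table A valid assessment table.
#' @param seed Integer seed.
#' @return An assessment tibble with exactly one row per patient.
#' @export
resample_one_per_patient <- function(table, seed = 1L) {
  table <- validate_assessments(table)
  if (nrow(table) == 0) stop("empty assessment table", call. = FALSE)
  with_local_seed(seed, {
    table |>
      dplyr::group_by(.data$patient_id) |>
      dplyr::slice_sample(n = 1) |>
      dplyr::ungroup()
  })
}

#' Per-joint affected rates
#'
#' The affected rate of a joint is the fraction of patients with the symptom
#' at that joint, computed on one assessment per patient. The input must
#' already hold a single row per patient (use [resample_one_per_patient()]);
#' repeated patients are a precondition error, not silently pooled.
#'
#' @param table Assessment table, one row per patient.
#' @param symptom `"tender"` or `"swollen"`.
#' @param set_label Free-text label for the patient set the rates describe.
#' @return A `joint_profile` tibble: `joint`, `site`, `side`, `group`,
#'   `rate`, with attributes `symptom`, `n_patients`, `set_label`.
#' @export
#' @examples
#' sim <- generate_cohort(cohort_config(n_patients = 200, seed = 1))
#' one <- resample_one_per_patient(sim$assessments, seed = 2)
#' affected_rates(one, "tender")
affected_rates <- function(table, symptom = c("tender", "swollen"),
                           set_label = "cohort") {
  symptom <- match_symptom(symptom)
  table <- validate_assessments(table)
  if (anyDuplicated(table$patient_id)) {
    stop("affected_rates needs one assessment per patient; ",
         "call resample_one_per_patient() first", call. = FALSE)
  }
  cols <- flag_columns(symptom)
  out <- ra_joints() |>
    dplyr::mutate(rate = unname(colMeans(as.matrix(table[cols]))))
  attr(out, "symptom") <- symptom
  attr(out, "n_patients") <- nrow(table)
  attr(out, "set_label") <- set_label
  class(out) <- c("joint_profile", class(out))
  out
}

#' Spearman concordance between two joint profiles
#'
#' Compares the order of per-joint affected rates between two profiles
#' (e.g. two patient sets, or tenderness vs swelling) with Spearman's rank
#' correlation, average ranks for ties, two-sided p from the asymptotic
#' t approximation.
#'
#' @param a,b `joint_profile` tibbles over the same joints (or any data
#'   frames with `joint` and `rate` columns).
#' @return One-row tibble: `rho`, `p_value`, `n`, `degenerate` (TRUE when
#'   either profile is constant, in which case `rho` is `NA`).
#' @export
spearman_concordance <- function(a, b) {
  m <- dplyr::inner_join(
    dplyr::select(tibble::as_tibble(a), "joint", rate_a = "rate"),
    dplyr::select(tibble::as_tibble(b), "joint", rate_b = "rate"),
    by = "joint"
  )
  if (nrow(m) != nrow(a) || nrow(m) != nrow(b)) {
    stop("profiles cover different joint sets", call. = FALSE)
  }
  n <- nrow(m)
  if (stats::sd(m$rate_a) == 0 || stats::sd(m$rate_b) == 0) {
    return(tibble::tibble(rho = NA_real_, p_value = NA_real_, n = n,
                          degenerate = TRUE))
  }
  ct <- suppressWarnings(
    stats::cor.test(m$rate_a, m$rate_b, method = "spearman", exact = FALSE)
  )
  tibble::tibble(rho = unname(ct$estimate), p_value = ct$p.value, n = n,
                 degenerate = FALSE)
}

#' Exact binomial test of right-left laterality
#'
#' For each of the 14 bilateral sites, compares the right and the left
#' joint's affected rate. Sites where the right rate is strictly higher
#' count as right-dominant; exact ties are excluded. The count of
#' right-dominant sites is tested against a fair coin with the exact
#' two-sided binomial test (minimum-likelihood two-sided p: the sum of all
#' outcome probabilities no larger than that of the observed count, which
#' at p = 1/2 equals the doubled tail).
#'
#' @param profile A `joint_profile` from [affected_rates()] (any data frame
#'   with `site`, `side`, `rate`).
#' @return One-row tibble: `n_pairs_tested`, `n_right_dominant`,
#'   `n_ties_excluded`, `p_value`.
#' @export
#' @examples
#' sim <- generate_cohort(cohort_config(n_patients = 500, seed = 1))
#' one <- resample_one_per_patient(sim$assessments, seed = 2)
#' laterality_test(affected_rates(one, "tender"))
laterality_test <- function(profile) {
  wide <- tibble::as_tibble(profile) |>
    dplyr::select("site", "side", "rate") |>
    tidyr::pivot_wider(names_from = "side", values_from = "rate")
  if (nrow(wide) != 14 || anyNA(wide$l) || anyNA(wide$r)) {
    stop("profile must contain rates for all 14 bilateral sites",
         call. = FALSE)
  }
  ties <- wide$r == wide$l
  k <- sum(wide$r > wide$l)
  n <- sum(!ties)
  p <- if (n == 0) NA_real_ else stats::binom.test(k, n, p = 0.5)$p.value
  tibble::tibble(n_pairs_tested = n, n_right_dominant = k,
                 n_ties_excluded = sum(ties), p_value = p)
}

#' Split an assessment table by calendar-year availability
#'
#' Partitions patients into those with any assessment in `year` and those
#' without, mirroring patient-set splits defined by data availability in a
#' given year.
#'
#' @param table A valid assessment table.
#' @param year Calendar year defining the first set.
#' @return Named list of two assessment tibbles, `in_year` and `pre_year`.
#' @export
split_by_year <- function(table, year = 2011) {
  table <- validate_assessments(table)
  ids <- table |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(has = any(.data$visit_year == year), .groups = "drop")
  list(
    in_year = dplyr::semi_join(table, dplyr::filter(ids, .data$has),
                               by = "patient_id"),
    pre_year = dplyr::semi_join(table, dplyr::filter(ids, !.data$has),
                                by = "patient_id")
  )
}
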