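#' Group affected rates per evaluation
#'
#' For each assessment, the affected rate of a joint group is the number of
#' tender joints plus the number of swollen joints in the group, divided by
#' the group size (8 for large and wrist, 10 for MCP and for PIP). The rate
#' lives on a 0-2 scale: 2 means every joint in the group is both tender
#' and swollen; tenderness in four of the ten MCP joints alone gives an MCP
#' rate of 0.4.
#'
#' @param table A valid assessment table.
#' @return Tibble: `patient_id`, `visit_index`, `large_wrist`, `mcp`,
#'   `pip`, each rate in [0, 2].
#' @export
#' @examples
#' sim <- generate_cohort(cohort_config(n_patients = 20, seed = 1))
#' group_rates(sim$assessments)
group_rates <- function(table) {
  table <- validate_assessments(table)
  joints <- ra_joints()
  sizes <- joint_group_sizes()
  out <- tibble::tibble(patient_id = table$patient_id,
                        visit_index = table$visit_index)
  for (g in joint_group_levels()) {
    cols <- c(paste(joints$joint[joints$group == g], "tender", sep = "_"),
              paste(joints$joint[joints$group == g], "swollen", sep = "_"))
    out[[g]] <- rowSums(as.matrix(table[cols])) / sizes[[g]]
  }
  out
}

#' Sample evaluations with a per-patient cap
#'
#' Uniformly samples, without replacement, up to `max_per_patient` visits
#' from each patient so that frequently seen patients cannot dominate the
#' clustering; optionally subsamples the pooled set to exactly `target_n`
#' evaluations. Deterministic given `seed`.
#'
#' @param table A valid assessment table.
#' @param max_per_patient Cap on evaluations per patient (>= 1).
#' @param target_n Optional exact pooled size after capping.
#' @param seed Integer seed.
#' @return An assessment tibble (rows a subset of `table`).
#' @export
sample_evaluations <- function(table, max_per_patient = 6L,
                               target_n = NULL, seed = 1L) {
  stopifnot(max_per_patient >= 1)
  table <- validate_assessments(table)
  with_local_seed(seed, {
    kept <- table |>
      dplyr::group_by(.data$patient_id) |>
      dplyr::slice_sample(n = max_per_patient) |>
      dplyr::ungroup()
    if (!is.null(target_n)) {
      if (target_n > nrow(kept)) {
        stop(sprintf("target_n = %d exceeds the capped pool of %d evaluations",
                     target_n, nrow(kept)), call. = FALSE)
      }
      kept <- dplyr::slice_sample(kept, n = target_n)
    }
    dplyr::arrange(kept, .data$patient_id, .data$visit_index)
  })
}

#' Ward clustering of evaluations into subgroups
#'
#' Agglomerative clustering of evaluations in the three-dimensional group
#' affected-rate space (Ward minimum-variance criterion, Euclidean distance
#' on the raw rates -- the three axes share the 0-2 scale by construction,
#' so no rescaling). The tree is cut at `k` clusters and labels are
#' renumbered 1..k by ascending mean total rate, so subgroup 1 is always
#' the least active ("no synovitis") end and subgroup `k` the most active.
#'
#' @param features Tibble from [group_rates()] (columns `large_wrist`,
#'   `mcp`, `pip`; id columns are carried through).
#' @param k Number of clusters (default 6).
#' @return A `subgroup_model`: list with `tree` (the `hclust` object),
#'   `k`, `features` (input plus a `subgroup` column), `centers`
#'   (per-cluster share and mean rates).
#' @export
#' @examples
#' sim <- generate_cohort(cohort_config(n_patients = 300, seed = 1))
#' feats <- group_rates(sample_evaluations(sim$assessments, seed = 2))
#' model <- ward_cluster(feats, k = 6)
#' characterize(model)
ward_cluster <- function(features, k = 6L) {
  features <- tibble::as_tibble(features)
  need <- joint_group_levels()
  if (!all(need %in% names(features))) {
    stop("features must contain columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  X <- as.matrix(features[need])
  if (nrow(X) < k) {
    stop(sprintf("need at least k = %d evaluations, got %d", k, nrow(X)),
         call. = FALSE)
  }
  tree <- stats::hclust(stats::dist(X), method = "ward.D2")
  raw <- stats::cutree(tree, k = k)
  totals <- tapply(rowSums(X), raw, mean)
  relabel <- match(seq_len(k), order(totals))
  labels <- relabel[raw]
  features$subgroup <- labels
  centers <- features |>
    dplyr::group_by(subgroup = .data$subgroup) |>
    dplyr::summarise(
      n = dplyr::n(),
      dplyr::across(dplyr::all_of(need), mean),
      .groups = "drop"
    ) |>
    dplyr::mutate(share = .data$n / sum(.data$n), .after = "n") |>
    dplyr::arrange(.data$subgroup)
  structure(list(tree = tree, k = as.integer(k), features = features,
                 centers = centers),
            class = "subgroup_model")
}

#' @export
print.subgroup_model <- function(x, ...) {
  cat(sprintf("Ward subgroup model: %d evaluations, k = %d\n",
              nrow(x$features), x$k))
  print(x$centers)
  invisible(x)
}

#' Per-subgroup summary of a fitted model
#'
#' @param model A `subgroup_model`.
#' @return Tibble: `subgroup`, `n`, `share` (shares sum to 1), mean
#'   `large_wrist`, `mcp`, `pip` rates.
#' @export
characterize <- function(model) {
  stopifnot(inherits(model, "subgroup_model"))
  model$centers
}

#' Within-patient regularity of subgroup membership
#'
#' A patient with exactly `min_evals`-`max_evals` clustered evaluations
#' (default 4-5) is "regular" when strictly more than `threshold` (default
#' 60%) of their evaluations carry the same subgroup label -- the modal
#' fraction rule: 3 of 4 qualifies, 3 of 5 (exactly 0.6) does not.
#'
#' @param model A fitted `subgroup_model`.
#' @param min_evals,max_evals Eligibility window on the number of clustered
#'   evaluations per patient.
#' @param threshold Modal-fraction threshold; regular requires a strictly
#'   greater fraction.
#' @return List: `patients` (tibble `patient_id`, `n_evaluations`,
#'   `modal_subgroup`, `modal_fraction`, `regular`, eligible patients only)
#'   and `summary` (one row: `n_eligible`, `n_regular`,
#'   `regular_fraction`).
#' @export
regularity <- function(model, min_evals = 4L, max_evals = 5L,
                       threshold = 0.6) {
  stopifnot(inherits(model, "subgroup_model"))
  patients <- model$features |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(
      n_evaluations = dplyr::n(),
      modal_subgroup = as.integer(names(which.max(table(.data$subgroup)))),
      modal_fraction = max(table(.data$subgroup)) / dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_evaluations >= min_evals,
                  .data$n_evaluations <= max_evals) |>
    dplyr::mutate(regular = .data$modal_fraction > threshold)
  summary <- tibble::tibble(
    n_eligible = nrow(patients),
    n_regular = sum(patients$regular),
    regular_fraction = ifelse(nrow(patients) == 0, NA_real_,
                              mean(patients$regular))
  )
  list(patients = patients, summary = summary)
}
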