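#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment

#' Tidiers for subgroup models
#'
#' `tidy()` returns the per-cluster summary (one row per subgroup: size,
#' share, mean group rates), `augment()` the per-evaluation features with
#' their `subgroup` label, and `glance()` a one-row model summary.
#'
#' @param x A `subgroup_model`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.subgroup_model <- function(x, ...) {
  characterize(x)
}

#' @rdname tidy.subgroup_model
#' @export
augment.subgroup_model <- function(x, ...) {
  x$features
}

#' @rdname tidy.subgroup_model
#' @export
glance.subgroup_model <- function(x, ...) {
  tibble::tibble(
    k = x$k,
    n_evaluations = nrow(x$features),
    n_patients = dplyr::n_distinct(x$features$patient_id),
    max_merge_height = max(x$tree$height)
  )
}

#' Tidiers for joint embeddings
#'
#' `tidy()` returns the per-joint loadings of the leading components;
#' `glance()` the explained-variance summary.
#'
#' @param x A `joint_embedding`.
#' @param n_components Number of components to keep (default 2).
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.joint_embedding <- function(x, n_components = 2L, ...) {
  keep <- c("joint", "site", "side", "group",
            paste0("PC", seq_len(n_components)))
  dplyr::select(x$loadings, dplyr::all_of(keep))
}

#' @rdname tidy.joint_embedding
#' @export
glance.joint_embedding <- function(x, ...) {
  tibble::tibble(
    n_joints = nrow(x$loadings),
    n_patients = x$n_patients,
    joint_subset = x$joint_subset,
    symptom = x$symptom,
    prop_var_pc1 = x$explained[1] / sum(x$explained),
    prop_var_pc2 = x$explained[2] / sum(x$explained)
  )
}

#' Tidy a kappa matrix into unordered joint pairs
#'
#' @param x A `kappa_matrix`.
#' @param ... Unused.
#' @return Tibble: `joint_a`, `joint_b`, `kappa` (378 off-diagonal pairs).
#' @export
tidy.kappa_matrix <- function(x, ...) {
  tidy_kappa(x)
}
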