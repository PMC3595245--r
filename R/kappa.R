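#' Cohen's kappa for two binary indicators
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)`, where `p_o` is the
#' observed agreement fraction and `p_e` the expected agreement from the
#' marginals of the 2x2 contingency table. If either vector is constant the
#' coefficient is undefined and `NA` is returned (not an error): a joint
#' nobody (or everybody) has symptoms in carries no pairwise information.
#'
#' @param x,y Binary (0/1) vectors of equal length >= 2.
#' @return A single number in [-1, 1], or `NA`.
#' @export
#' @examples
#' cohen_kappa(c(1, 1, 0, 0), c(1, 0, 1, 0))  # 0
cohen_kappa <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  if (anyNA(x) || anyNA(y) || !all(x %in% c(0, 1)) || !all(y %in% c(0, 1))) {
    stop("x and y must be 0/1 vectors without missing values", call. = FALSE)
  }
  if (length(unique(x)) < 2 || length(unique(y)) < 2) return(NA_real_)
  n <- length(x)
  po <- mean(x == y)
  px <- mean(x); py <- mean(y)
  pe <- px * py + (1 - px) * (1 - py)
  (po - pe) / (1 - pe)
}

#' Pairwise kappa matrix over the 28 joints
#'
#' Resamples one assessment per patient (seeded), then computes Cohen's
#' kappa for every pair of joints for the given symptom. Degenerate joints
#' (constant across patients) yield `NA` rows/columns.
#'
#' @param table A valid assessment table.
#' @param symptom `"tender"` or `"swollen"`.
#' @param seed Seed for the per-patient resample.
#' @param resample If `FALSE`, the table is used as-is (it must then hold
#'   one row per patient).
#' @return A 28x28 symmetric matrix of class `kappa_matrix` with joint ids
#'   as dimnames and attributes `symptom` and `n_patients`.
#' @export
kappa_matrix <- function(table, symptom = c("tender", "swollen"),
                         seed = 1L, resample = TRUE) {
  symptom <- match_symptom(symptom)
  one <- if (resample) resample_one_per_patient(table, seed) else
    validate_assessments(table)
  if (anyDuplicated(one$patient_id)) {
    stop("one assessment per patient required", call. = FALSE)
  }
  X <- as.matrix(one[flag_columns(symptom)])
  colnames(X) <- ra_joints()$joint
  n <- nrow(X)
  p1 <- colMeans(X)
  n11 <- crossprod(X)
  # agreement = n11 + n00; n00 = n - n1i - n1j + n11
  po <- (2 * n11 + n - outer(p1, p1, function(a, b) n * (a + b))) / n
  pe <- outer(p1, p1) + outer(1 - p1, 1 - p1)
  K <- (po - pe) / (1 - pe)
  degenerate <- p1 %in% c(0, 1)
  K[degenerate, ] <- NA_real_
  K[, degenerate] <- NA_real_
  diag(K)[!degenerate] <- 1
  structure(K, class = c("kappa_matrix", "matrix", "array"),
            symptom = symptom, n_patients = n)
}

#' @export
print.kappa_matrix <- function(x, ...) {
  cat(sprintf("28x28 kappa matrix (%s), n = %d patients\n",
              attr(x, "symptom"), attr(x, "n_patients")))
  cat(sprintf("mean off-diagonal kappa: %.3f (%d degenerate joints)\n",
              mean(x[upper.tri(x)], na.rm = TRUE),
              sum(colSums(is.na(unclass(x))) == nrow(x))))
  invisible(x)
}

#' Summarise a kappa matrix by joint-group pair
#'
#' Means of the off-diagonal kappas within and between the three joint
#' groups; the within/between contrast is the tabular form of the
#' three-block structure visible in the kappa heatmap.
#'
#' @param x A `kappa_matrix`.
#' @return Tibble: `group_a`, `group_b`, `mean_kappa`, `n_pairs`, plus a
#'   `within` flag.
#' @export
kappa_group_summary <- function(x) {
  joints <- ra_joints()
  long <- tidy_kappa(x) |>
    dplyr::mutate(
      group_a = joints$group[match(.data$joint_a, joints$joint)],
      group_b = joints$group[match(.data$joint_b, joints$joint)]
    ) |>
    dplyr::mutate(
      pair = paste(pmin(.data$group_a, .data$group_b),
                   pmax(.data$group_a, .data$group_b), sep = ":")
    )
  long |>
    dplyr::group_by(.data$pair) |>
    dplyr::summarise(
      group_a = dplyr::first(pmin(.data$group_a, .data$group_b)),
      group_b = dplyr::first(pmax(.data$group_a, .data$group_b)),
      mean_kappa = mean(.data$kappa, na.rm = TRUE),
      n_pairs = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(within = .data$group_a == .data$group_b) |>
    dplyr::select("group_a", "group_b", "within", "mean_kappa", "n_pairs")
}

# long tibble of the unordered off-diagonal pairs
tidy_kappa <- function(x) {
  m <- unclass(x)
  idx <- which(upper.tri(m), arr.ind = TRUE)
  tibble::tibble(
    joint_a = rownames(m)[idx[, 1]],
    joint_b = colnames(m)[idx[, 2]],
    kappa = m[idx]
  )
}

#' Principal-component embedding of the joints
#'
#' One assessment per patient (seeded resample) gives a patients x joints
#' binary matrix; its principal components on the correlation scale embed
#' each joint by its loadings. Because per-joint prevalences differ more
#' than fourfold, the correlation scale (standardised columns) is used so
#' high-prevalence joints do not dominate. Constant joints are dropped with
#' a warning. Component signs are fixed so each component's
#' largest-magnitude loading is positive, making repeated resamples
#' comparable.
#'
#' @param table A valid assessment table.
#' @param symptom `"tender"` or `"swollen"`.
#' @param joint_subset `"all"` (28 joints) or `"no_large_wrist"` (the 20
#'   MCP and PIP joints, used to resolve the MCP/PIP split once the
#'   dominant large-and-wrist axis is removed).
#' @param seed Seed for the per-patient resample.
#' @param resample If `FALSE`, use the table as-is (one row per patient).
#' @return A `joint_embedding` object: list with `loadings` (tibble:
#'   `joint`, `site`, `side`, `group`, `PC1`, `PC2`, ...), `explained`
#'   (per-component variance, sums to the number of usable joints),
#'   `dropped` (degenerate joints), `symptom`, `joint_subset`,
#'   `n_patients`.
#' @export
eigen_embedding <- function(table, symptom = c("tender", "swollen"),
                            joint_subset = c("all", "no_large_wrist"),
                            seed = 1L, resample = TRUE) {
  symptom <- match_symptom(symptom)
  joint_subset <- match.arg(joint_subset)
  one <- if (resample) resample_one_per_patient(table, seed) else
    validate_assessments(table)
  if (anyDuplicated(one$patient_id)) {
    stop("one assessment per patient required", call. = FALSE)
  }
  joints <- ra_joints()
  if (joint_subset == "no_large_wrist") {
    joints <- dplyr::filter(joints, .data$group != "large_wrist")
  }
  X <- as.matrix(one[paste(joints$joint, symptom, sep = "_")])
  colnames(X) <- joints$joint
  constant <- apply(X, 2, function(v) length(unique(v)) < 2)
  if (any(constant)) {
    warning("dropping degenerate joint(s): ",
            paste(colnames(X)[constant], collapse = ", "), call. = FALSE)
    X <- X[, !constant, drop = FALSE]
    joints <- joints[!constant, ]
  }
  if (ncol(X) < 3) {
    stop("fewer than 3 non-degenerate joints in subset", call. = FALSE)
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  rot <- pc$rotation
  for (j in seq_len(ncol(rot))) {
    if (rot[which.max(abs(rot[, j])), j] < 0) rot[, j] <- -rot[, j]
  }
  loadings <- dplyr::bind_cols(joints, tibble::as_tibble(rot))
  structure(list(
    loadings = loadings,
    explained = unname(pc$sdev^2),
    dropped = names(constant)[constant],
    symptom = symptom,
    joint_subset = joint_subset,
    n_patients = nrow(X)
  ), class = "joint_embedding")
}

#' @export
print.joint_embedding <- function(x, ...) {
  cat(sprintf("joint embedding (%s, %s joints), n = %d patients\n",
              x$symptom,
              if (x$joint_subset == "all") "28" else "20 small",
              x$n_patients))
  pct <- 100 * x$explained[1:2] / sum(x$explained)
  cat(sprintf("PC1 %.1f%%, PC2 %.1f%% of variance\n", pct[1], pct[2]))
  invisible(x)
}

#' Silhouette separation of labelled joint groups in an embedding
#'
#' Quantifies how well a labelling of the joints (by default their joint
#' group) separates in the first two embedding components, using the mean
#' silhouette width with Euclidean distance.
#'
#' @param embedding A `joint_embedding`.
#' @param labels Named character vector or factor of labels per joint;
#'   default the joint groups of the embedded joints.
#' @return A list: `silhouette` (mean width; `NA` with `degenerate = TRUE`
#'   when all points coincide), `centroids` (tibble of per-label mean PC1/
#'   PC2), `degenerate`.
#' @export
group_separation <- function(embedding, labels = NULL) {
  stopifnot(inherits(embedding, "joint_embedding"))
  ld <- embedding$loadings
  if (is.null(labels)) {
    labels <- stats::setNames(ld$group, ld$joint)
  }
  labels <- labels[ld$joint]
  if (anyNA(labels)) stop("labels missing for some embedded joints",
                          call. = FALSE)
  if (length(unique(labels)) < 2) {
    stop("need at least 2 labelled groups", call. = FALSE)
  }
  xy <- as.matrix(ld[, c("PC1", "PC2")])
  centroids <- tibble::as_tibble(xy) |>
    dplyr::mutate(label = as.character(labels)) |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(PC1 = mean(.data$PC1), PC2 = mean(.data$PC2),
                     n = dplyr::n(), .groups = "drop")
  d <- stats::dist(xy)
  if (all(d == 0)) {
    return(list(silhouette = NA_real_, centroids = centroids,
                degenerate = TRUE))
  }
  sil <- cluster::silhouette(as.integer(factor(labels)), d)
  list(silhouette = mean(sil[, "sil_width"]), centroids = centroids,
       degenerate = FALSE)
}

#' Stability of the joint structure across resamples
#'
#' Repeats the seeded one-assessment-per-patient resample `k_repeats` times
#' and recomputes the embedding (and optionally the kappa matrix) for each,
#' summarising agreement between repeats as the absolute (sign-aligned)
#' correlation of component loadings over the shared joints.
#'
#' @param table A valid assessment table.
#' @param symptom `"tender"` or `"swollen"`.
#' @param k_repeats Number of resamples (>= 1).
#' @param seed Base seed; repeat `i` uses `seed + i - 1`.
#' @param joint_subset Passed to [eigen_embedding()].
#' @param n_components Components to compare (default 2).
#' @return List: `embeddings` (length `k_repeats`), `agreement` (tibble
#'   `repeat_a`, `repeat_b`, `component`, `abs_correlation`).
#' @export
resample_repeats <- function(table, symptom = c("tender", "swollen"),
                             k_repeats = 5L, seed = 1L,
                             joint_subset = "all", n_components = 2L) {
  stopifnot(k_repeats >= 1)
  symptom <- match_symptom(symptom)
  embeddings <- lapply(seq_len(k_repeats), function(i) {
    eigen_embedding(table, symptom, joint_subset, seed = seed + i - 1L)
  })
  pairs <- utils::combn(k_repeats, 2)
  agreement <- purrr::map_dfr(seq_len(ncol(pairs)), function(p) {
    a <- embeddings[[pairs[1, p]]]$loadings
    b <- embeddings[[pairs[2, p]]]$loadings
    shared <- intersect(a$joint, b$joint)
    purrr::map_dfr(seq_len(n_components), function(k) {
      col <- paste0("PC", k)
      tibble::tibble(
        repeat_a = pairs[1, p], repeat_b = pairs[2, p], component = k,
        abs_correlation = abs(stats::cor(
          a[[col]][match(shared, a$joint)],
          b[[col]][match(shared, b$joint)]
        ))
      )
    })
  })
  list(embeddings = embeddings, agreement = agreement)
}
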