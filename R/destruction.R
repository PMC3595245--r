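#' Joint destruction rates from modified-Sharp elements
#'
#' The destruction rate of a joint group is the sum of its element scores
#' (both sides, erosion plus narrowing) divided by the group's full score:
#' a sum of 50 in the large-and-wrist group against a full score of 108
#' gives 50/108 = 0.463. Regions map to groups as MCP -> mcp, PIP -> pip,
#' wrist (hand joints other than MCP and PIP) -> large_wrist.
#'
#' @param sharp A valid Sharp table ([read_sharp()] / [generate_sharp()]).
#' @param full_scores Named element full scores (default
#'   [sharp_full_scores()]); scores exceeding them are an error.
#' @return Tibble: `patient_id`, `large_wrist`, `mcp`, `pip`, each in
#'   [0, 1], with attribute `group_full_scores`.
#' @export
destruction_rates <- function(sharp, full_scores = sharp_full_scores()) {
  sharp <- validate_sharp(sharp, full_scores)
  region_group <- c(mcp = "mcp", pip = "pip", wrist = "large_wrist")
  out <- tibble::tibble(patient_id = sharp$patient_id)
  group_full <- numeric(0)
  for (region in names(region_group)) {
    cols <- grep(paste0("^[lr]_", region, "_"), sharp_elements(), value = TRUE)
    g <- region_group[[region]]
    group_full[g] <- sum(full_scores[cols])
    out[[g]] <- unname(rowSums(as.matrix(sharp[cols]))) / group_full[[g]]
  }
  out <- out[, c("patient_id", joint_group_levels())]
  attr(out, "group_full_scores") <- group_full[joint_group_levels()]
  out
}

#' Right-dominance of joint destruction, per Sharp element
#'
#' For each element (erosion/narrowing x MCP/PIP/wrist), compares each
#' patient's right and left score. Patients with equal scores are excluded;
#' the count with a higher right score is tested against a fair coin with
#' the exact two-sided binomial test (same minimum-likelihood two-sided p
#' as [laterality_test()]).
#'
#' @param sharp A valid Sharp table.
#' @param elements Which elements to analyse, as `<region>_<element>`
#'   (e.g. `"mcp_erosion"`); default all six.
#' @return Tibble, one row per element: `element`, `n_right_higher`,
#'   `n_left_higher`, `n_ties_excluded`, `p_value`, `degenerate` (TRUE
#'   when no patient differs between sides).
#' @export
right_dominance <- function(sharp,
                            elements = c("mcp_erosion", "mcp_narrowing",
                                         "pip_erosion", "pip_narrowing",
                                         "wrist_erosion", "wrist_narrowing")) {
  sharp <- validate_sharp(sharp)
  purrr::map_dfr(elements, function(el) {
    r <- sharp[[paste0("r_", el)]]
    l <- sharp[[paste0("l_", el)]]
    if (is.null(r) || is.null(l)) {
      stop("unknown element: ", el, call. = FALSE)
    }
    n_right <- sum(r > l)
    n_left <- sum(l > r)
    n <- n_right + n_left
    tibble::tibble(
      element = el,
      n_right_higher = n_right,
      n_left_higher = n_left,
      n_ties_excluded = sum(r == l),
      p_value = if (n == 0) NA_real_ else
        stats::binom.test(n_right, n, p = 0.5)$p.value,
      degenerate = n == 0
    )
  })
}

#' Dominant destruction of large and wrist joints per subgroup
#'
#' Within each patient subgroup, tests whether large-and-wrist destruction
#' exceeds MCP and PIP destruction using the paired differences
#' (large_wrist - mcp) and (large_wrist - pip) per patient and a two-sided
#' one-sample t test on each. Subgroups with fewer than two patients, or
#' with zero variance in the differences, are flagged degenerate rather
#' than tested.
#'
#' @param rates Output of [destruction_rates()].
#' @param labels Data frame mapping `patient_id` to `subgroup` (e.g. from a
#'   [ward_cluster()] model's per-patient modal subgroup).
#' @return Tibble, one row per subgroup x contrast: `subgroup`, `contrast`,
#'   `n`, `mean_difference`, `statistic`, `p_value`, `degenerate`.
#' @export
subgroup_destruction_difference <- function(rates, labels) {
  labels <- dplyr::select(tibble::as_tibble(labels), "patient_id", "subgroup")
  joined <- dplyr::inner_join(tibble::as_tibble(rates), labels,
                              by = "patient_id")
  contrasts <- c(large_wrist_minus_mcp = "mcp", large_wrist_minus_pip = "pip")
  purrr::map_dfr(sort(unique(joined$subgroup)), function(sg) {
    sub <- dplyr::filter(joined, .data$subgroup == sg)
    purrr::map_dfr(names(contrasts), function(con) {
      d <- sub$large_wrist - sub[[contrasts[[con]]]]
      degenerate <- length(d) < 2 || stats::sd(d) == 0
      if (degenerate) {
        tibble::tibble(subgroup = sg, contrast = con, n = length(d),
                       mean_difference = mean(d), statistic = NA_real_,
                       p_value = NA_real_, degenerate = TRUE)
      } else {
        tt <- stats::t.test(d)
        tibble::tibble(subgroup = sg, contrast = con, n = length(d),
                       mean_difference = mean(d),
                       statistic = unname(tt$statistic),
                       p_value = tt$p.value, degenerate = FALSE)
      }
    })
  })
}
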