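#' The 28 joints of the rheumatoid arthritis joint count
#'
#' The 28-joint count used by DAS28/SDAI/CDAI covers the bilateral shoulders,
#' elbows, wrists, knees, metacarpophalangeal joints 1-5 (MCP) and proximal
#' interphalangeal joints 1-5 (PIP). Each joint belongs to exactly one of
#' three joint groups: `large_wrist` (shoulder, elbow, wrist, knee; 8 joints),
#' `mcp` (10 joints) and `pip` (10 joints).
#'
#' @return A tibble with 28 rows and columns:
#' \describe{
#'   \item{joint}{canonical joint id, `<side>_<site>` (e.g. `"r_wrist"`)}
#'   \item{site}{one of the 14 anatomical sites (`"shoulder"` ... `"pip5"`)}
#'   \item{side}{`"l"` or `"r"`}
#'   \item{group}{joint group: `"large_wrist"`, `"mcp"` or `"pip"`}
#' }
#' Row order is the canonical joint order used for all file columns:
#' sites in the order shoulder, elbow, wrist, knee, mcp1-5, pip1-5,
#' left before right within each site.
#' @export
#' @examples
#' ra_joints()
#' table(ra_joints()$group)
ra_joints <- function() {
  sites <- joint_sites()
  tibble::tibble(
    site = rep(sites, each = 2L),
    side = rep(c("l", "r"), times = length(sites))
  ) |>
    dplyr::mutate(
      joint = paste(.data$side, .data$site, sep = "_"),
      group = joint_group(.data$site)
    ) |>
    dplyr::select("joint", "site", "side", "group")
}

#' The 14 bilateral sites, in canonical order
#' @return Character vector of length 14.
#' @export
joint_sites <- function() {
  c("shoulder", "elbow", "wrist", "knee",
    paste0("mcp", 1:5), paste0("pip", 1:5))
}

#' Map a joint site to its joint group
#'
#' Shoulders, elbows, wrists and knees form the "large and wrist" group;
#' MCP1-5 and PIP1-5 form the MCP and PIP groups. The mapping is total over
#' the 14 sites and does not depend on side.
#'
#' @param site Character vector of sites (as in [joint_sites()]) or full
#'   joint ids (`"r_wrist"` is accepted and reduced to its site).
#' @return Character vector: `"large_wrist"`, `"mcp"` or `"pip"`.
#' @export
#' @examples
#' joint_group("wrist")
#' joint_group(c("r_wrist", "l_mcp3"))
joint_group <- function(site) {
  site <- sub("^[lr]_", "", site)
  bad <- !site %in% joint_sites()
  if (any(bad)) {
    stop("unknown joint site(s): ", paste(unique(site[bad]), collapse = ", "),
         call. = FALSE)
  }
  dplyr::case_when(
    site %in% c("shoulder", "elbow", "wrist", "knee") ~ "large_wrist",
    grepl("^mcp", site) ~ "mcp",
    .default = "pip"
  )
}

#' Sizes of the three joint groups
#' @return Named integer vector `c(large_wrist = 8, mcp = 10, pip = 10)`.
#' @export
joint_group_sizes <- function() {
  c(large_wrist = 8L, mcp = 10L, pip = 10L)
}

joint_group_levels <- function() c("large_wrist", "mcp", "pip")

#' Canonical flag column names for an assessment table
#'
#' Columns are named `<side>_<site>_<symptom>` (e.g. `r_wrist_tender`) and
#' ordered: all 28 tenderness flags in canonical joint order, then all 28
#' swelling flags.
#'
#' @param symptom `"tender"`, `"swollen"`, or both (the default).
#' @return Character vector of column names.
#' @export
#' @examples
#' head(flag_columns("tender"))
flag_columns <- function(symptom = c("tender", "swollen")) {
  symptom <- match.arg(symptom, c("tender", "swollen"), several.ok = TRUE)
  unlist(lapply(symptom, function(s) paste(ra_joints()$joint, s, sep = "_")))
}

match_symptom <- function(symptom) {
  match.arg(symptom, c("tender", "swollen"))
}
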