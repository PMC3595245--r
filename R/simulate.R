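#' Configuration for the synthetic synovitis cohort generator
#'
#' The generator emulates the statistical structure of 28-joint synovitis in
#' a rheumatoid arthritis clinic cohort: heterogeneous per-joint prevalence
#' with the wrists most affected, left-right symmetric involvement with a
#' small right-side excess, three correlated blocks of joints (large and
#' wrist / MCP / PIP), tenderness-swelling coupling with shoulders swelling
#' far less often than they are tender, and six patient archetypes whose
#' synovitis pattern is stable across visits.
#'
#' Symptoms are generated by a latent-Gaussian (multivariate probit)
#' threshold model: each visit draws a 56-dimensional standard normal vector
#' with correlation `kron([[1, ts], [ts, 1]], C)` where `C` is the 28x28
#' joint correlation (block-compound-symmetric over the three groups plus a
#' left-right bump per site) and `ts = tender_swell_rho`; a flag is 1 when
#' its latent coordinate falls below the normal quantile of its configured
#' marginal probability. Marginals and correlation are therefore controlled
#' independently.
#'
#' @param n_patients Number of patients.
#' @param visits_per_patient Integer range `c(min, max)`; per-patient visit
#'   counts are uniform on this range.
#' @param archetype_weights Six nonnegative weights (normalised internally)
#'   for drawing each patient's archetype. Defaults follow the subgroup
#'   shares reported for clinic populations of this kind.
#' @param archetype_activity 6x3 matrix of per-archetype group symptom
#'   probabilities, columns `large_wrist`, `mcp`, `pip`. Default rows: no
#'   synovitis; mild large+wrist; MCP-dominant; PIP-dominant; active
#'   everywhere; moderate large+wrist.
#' @param site_multiplier Named multiplier per site on the group activity,
#'   encoding within-group prevalence heterogeneity (wrist highest).
#' @param right_bias Additive probability bonus for right-side joints,
#'   in [0, 0.2].
#' @param symmetry_rho Latent correlation between the left and right joint
#'   of a site, in [0, 1).
#' @param within_block_rho,between_block_rho Latent correlation among joints
#'   of the same / of different groups; must satisfy
#'   `0 <= between_block_rho < within_block_rho < 1`.
#' @param tender_swell_rho Latent tenderness-swelling coupling per joint.
#' @param shoulder_swell_attenuation Multiplicative factor < 1 on shoulder
#'   swelling probability.
#' @param visit_stability Probability that a visit expresses the patient's
#'   own archetype; otherwise the visit's profile is redrawn from the
#'   archetype weights (transient flares/remissions).
#' @param patient_rho Within-patient correlation of the latent Gaussian
#'   across visits, in [0, 1): each visit's latent vector is
#'   `sqrt(patient_rho)` times a per-patient draw plus
#'   `sqrt(1 - patient_rho)` visit noise, both with correlation `Sigma`,
#'   so the same patient tends to show the same affected joints from visit
#'   to visit while every cross-sectional marginal and correlation is
#'   unchanged.
#' @param destruction_scale Multiplier turning archetype group activity into
#'   the expected fraction of the Sharp full score accrued (used by
#'   [generate_sharp()]).
#' @param years Calendar years over which visits are spread.
#' @param seed Integer seed; all randomness derives from this one stream.
#' @return A `cohort_config` list.
#' @export
#' @examples
#' cfg <- cohort_config(n_patients = 50, seed = 1)
#' sim <- generate_cohort(cfg)
#' dplyr::count(sim$truth$patients, archetype)
cohort_config <- function(n_patients = 1314,
                          visits_per_patient = c(1, 26),
                          archetype_weights = c(0.346, 0.174, 0.183,
                                                0.093, 0.041, 0.164),
                          archetype_activity = default_archetype_activity(),
                          site_multiplier = default_site_multiplier(),
                          right_bias = 0.02,
                          symmetry_rho = 0.7,
                          within_block_rho = 0.35,
                          between_block_rho = 0.1,
                          tender_swell_rho = 0.7,
                          shoulder_swell_attenuation = 0.4,
                          visit_stability = 0.9,
                          patient_rho = 0.75,
                          destruction_scale = 0.5,
                          years = 2005:2011,
                          seed = 1L) {
  if (!(between_block_rho >= 0 && between_block_rho < within_block_rho &&
        within_block_rho < 1)) {
    stop("need 0 <= between_block_rho < within_block_rho < 1", call. = FALSE)
  }
  if (right_bias < 0 || right_bias > 0.2) {
    stop("right_bias must lie in [0, 0.2]", call. = FALSE)
  }
  if (symmetry_rho < 0 || symmetry_rho >= 1) {
    stop("symmetry_rho must lie in [0, 1)", call. = FALSE)
  }
  if (patient_rho < 0 || patient_rho >= 1) {
    stop("patient_rho must lie in [0, 1)", call. = FALSE)
  }
  archetype_activity <- as.matrix(archetype_activity)
  if (!all(dim(archetype_activity) == c(6, 3))) {
    stop("archetype_activity must be a 6 x 3 matrix", call. = FALSE)
  }
  colnames(archetype_activity) <- joint_group_levels()
  if (length(archetype_weights) != 6 || any(archetype_weights < 0)) {
    stop("archetype_weights must be 6 nonnegative numbers", call. = FALSE)
  }
  stopifnot(length(visits_per_patient) == 2,
            visits_per_patient[1] >= 1,
            visits_per_patient[1] <= visits_per_patient[2])
  structure(list(
    n_patients = as.integer(n_patients),
    visits_per_patient = as.integer(visits_per_patient),
    archetype_weights = archetype_weights / sum(archetype_weights),
    archetype_activity = archetype_activity,
    site_multiplier = site_multiplier,
    right_bias = right_bias,
    symmetry_rho = symmetry_rho,
    within_block_rho = within_block_rho,
    between_block_rho = between_block_rho,
    tender_swell_rho = tender_swell_rho,
    shoulder_swell_attenuation = shoulder_swell_attenuation,
    visit_stability = visit_stability,
    patient_rho = patient_rho,
    destruction_scale = destruction_scale,
    years = years,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

#' @rdname cohort_config
#' @export
default_archetype_activity <- function() {
  m <- rbind(
    none            = c(0.01, 0.01, 0.01),
    mild_lw         = c(0.30, 0.04, 0.04),
    mcp_dominant    = c(0.06, 0.55, 0.06),
    pip_dominant    = c(0.06, 0.06, 0.55),
    active          = c(0.65, 0.65, 0.65),
    moderate_lw     = c(0.60, 0.10, 0.10)
  )
  colnames(m) <- joint_group_levels()
  m
}

#' @rdname cohort_config
#' @export
default_site_multiplier <- function() {
  c(shoulder = 0.8, elbow = 0.6, wrist = 1.5, knee = 0.9,
    mcp1 = 0.5, mcp2 = 1.0, mcp3 = 0.9, mcp4 = 0.6, mcp5 = 0.5,
    pip1 = 0.6, pip2 = 1.1, pip3 = 1.0, pip4 = 0.7, pip5 = 0.5)
}

# run code under a seed without disturbing the caller's RNG state
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Latent joint-joint correlation matrix implied by a config
#'
#' Block compound symmetry over the three joint groups plus a left-right
#' bump per site; projected to the nearest positive semi-definite matrix
#' (eigenvalue clipping, tolerance 1e-8) if the assembled matrix is not PSD.
#'
#' @param config A [cohort_config()].
#' @return 28x28 correlation matrix, dimnames the canonical joint ids.
#' @export
latent_joint_correlation <- function(config) {
  joints <- ra_joints()
  n <- nrow(joints)
  C <- matrix(config$between_block_rho, n, n,
              dimnames = list(joints$joint, joints$joint))
  same_group <- outer(joints$group, joints$group, "==")
  C[same_group] <- config$within_block_rho
  same_site <- outer(joints$site, joints$site, "==") & !diag(n)
  C[same_site] <- pmax(C[same_site], config$symmetry_rho)
  diag(C) <- 1
  ev <- eigen(C, symmetric = TRUE)
  if (min(ev$values) < -1e-8) {
    v <- pmax(ev$values, 0)
    C <- ev$vectors %*% diag(v) %*% t(ev$vectors)
    d <- sqrt(diag(C))
    C <- C / outer(d, d)
    dimnames(C) <- list(joints$joint, joints$joint)
  }
  C
}

# 56-dim latent correlation: tender block, swollen block, coupled by ts
latent_full_correlation <- function(config) {
  C <- latent_joint_correlation(config)
  ts <- config$tender_swell_rho
  kronecker(matrix(c(1, ts, ts, 1), 2), C)
}

# marginal flag probabilities per archetype: 6 x 56 matrix, columns in
# flag_columns() order
archetype_marginals <- function(config) {
  joints <- ra_joints()
  mult <- config$site_multiplier[joints$site]
  out <- matrix(NA_real_, 6, 56,
                dimnames = list(rownames(config$archetype_activity),
                                flag_columns()))
  for (a in 1:6) {
    act <- config$archetype_activity[a, joints$group]
    p <- pmin(pmax(act * mult + config$right_bias * (joints$side == "r"), 0), 1)
    p_sw <- p * ifelse(joints$site == "shoulder",
                       config$shoulder_swell_attenuation, 1)
    out[a, ] <- c(p, p_sw)
  }
  out
}

#' Generate a synthetic assessment cohort with ground truth
#'
#' Draws each patient's archetype from the configured weights, then
#' generates every visit's 56 symptom flags from the latent-Gaussian
#' threshold model (see [cohort_config()]). With probability
#' `1 - visit_stability` a visit's marginal profile is redrawn from the
#' archetype weights instead of the patient's own archetype, giving
#' imperfect but high within-patient stability.
#'
#' @param config A [cohort_config()].
#' @return A list with elements
#' \describe{
#'   \item{assessments}{validated assessment tibble (one row per visit)}
#'   \item{truth}{list: `patients` (tibble `patient_id`, `archetype`),
#'     `marginals` (long tibble of configured per-flag probabilities per
#'     archetype), `correlation` (the 28x28 latent joint correlation)}
#' }
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  with_local_seed(config$seed, {
    n <- config$n_patients
    patient_id <- sprintf("P%05d", seq_len(n))
    archetype <- sample.int(6, n, replace = TRUE,
                            prob = config$archetype_weights)
    n_visits <- sample(seq(config$visits_per_patient[1],
                           config$visits_per_patient[2]),
                       n, replace = TRUE)
    pid <- rep(patient_id, n_visits)
    visit_index <- sequence(n_visits)
    visit_year <- unlist(lapply(n_visits, function(k) {
      sort(sample(config$years, k, replace = TRUE))
    }), use.names = FALSE)

    total <- length(pid)
    # effective archetype per visit: patient's own, or a redraw (instability)
    eff <- rep(archetype, n_visits)
    redraw <- stats::runif(total) > config$visit_stability
    if (any(redraw)) {
      eff[redraw] <- sample.int(6, sum(redraw), replace = TRUE,
                                prob = config$archetype_weights)
    }

    sigma <- latent_full_correlation(config)
    L <- chol(sigma)
    # visit latent = sqrt(r) * patient draw + sqrt(1-r) * visit noise;
    # both share Sigma, so cross-sectional structure is preserved exactly
    Zp <- matrix(stats::rnorm(n * 56), n, 56) %*% L
    E <- matrix(stats::rnorm(total * 56), total, 56) %*% L
    r <- config$patient_rho
    Z <- sqrt(r) * Zp[rep(seq_len(n), n_visits), , drop = FALSE] +
      sqrt(1 - r) * E
    thresholds <- stats::qnorm(archetype_marginals(config))  # 6 x 56
    flags <- (Z < thresholds[eff, , drop = FALSE]) * 1L

    colnames(flags) <- flag_columns()
    assessments <- dplyr::bind_cols(
      tibble::tibble(patient_id = pid, visit_index = visit_index,
                     visit_year = visit_year),
      tibble::as_tibble(flags)
    )
    marg <- archetype_marginals(config)
    truth <- list(
      patients = tibble::tibble(patient_id = patient_id,
                                archetype = archetype),
      marginals = tibble::as_tibble(marg) |>
        dplyr::mutate(archetype = dplyr::row_number(), .before = 1) |>
        tidyr::pivot_longer(-"archetype", names_to = "flag",
                            values_to = "probability"),
      correlation = latent_joint_correlation(config)
    )
    list(assessments = validate_assessments(assessments), truth = truth)
  })
}

#' Generate synthetic modified-Sharp scores for a cohort
#'
#' Each patient's expected destruction in a region tracks their archetype's
#' activity for the matching joint group (MCP region from MCP activity, PIP
#' from PIP, wrist region from large-and-wrist activity), so destruction is
#' correlated with the synovitis pattern. Element scores are binomial over
#' the element full score with success probability
#' `destruction_scale * activity` plus the right-side bias, so right scores
#' are stochastically at least the left scores whenever `right_bias > 0`.
#'
#' @param cohort Result of [generate_cohort()] (or its `truth` component).
#' @param config The [cohort_config()] used to generate the cohort.
#' @param patient_ids Optional subset of patients to score (default: all;
#'   ids not present in the cohort are an error).
#' @param seed Seed for the score draws (default derived from the config
#'   seed).
#' @return A validated Sharp tibble (one row per scored patient).
#' @export
generate_sharp <- function(cohort, config, patient_ids = NULL,
                           seed = config$seed + 1L) {
  truth <- if (!is.null(cohort$truth)) cohort$truth else cohort
  patients <- truth$patients
  if (is.null(patient_ids)) patient_ids <- patients$patient_id
  unknown <- setdiff(patient_ids, patients$patient_id)
  if (length(unknown) > 0) {
    stop("unknown patient id(s): ", paste(utils::head(unknown, 5),
                                          collapse = ", "), call. = FALSE)
  }
  fs <- sharp_full_scores()
  region_group <- c(mcp = "mcp", pip = "pip", wrist = "large_wrist")
  arch <- patients$archetype[match(patient_ids, patients$patient_id)]
  with_local_seed(seed, {
    scores <- sapply(sharp_elements(), function(col) {
      parts <- strsplit(col, "_")[[1]]
      side <- parts[1]; region <- parts[2]
      act <- config$archetype_activity[arch, region_group[[region]]]
      p <- pmin(pmax(config$destruction_scale * act +
                       config$right_bias * (side == "r"), 0), 1)
      stats::rbinom(length(arch), size = fs[[col]], prob = p)
    })
    scores <- matrix(scores, nrow = length(arch),
                     dimnames = list(NULL, sharp_elements()))
    validate_sharp(dplyr::bind_cols(
      tibble::tibble(patient_id = patient_ids),
      tibble::as_tibble(scores)
    ))
  })
}
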