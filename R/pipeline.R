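#' Configuration for an end-to-end pipeline run
#'
#' Bundles the inputs, per-stage toggles and the master seed for
#' [run_pipeline()]. Each stochastic stage draws its own seed from the
#' master seed by a fixed splitting rule, so a single integer reproduces
#' the whole run.
#'
#' @param out_dir Output directory (created if needed).
#' @param cohort A [cohort_config()] to simulate from, or `NULL` to read
#'   `assessments_path` / `sharp_path` instead.
#' @param assessments_path,sharp_path CSV inputs, used when `cohort` is
#'   `NULL` (the Sharp path may be `NULL` to skip destruction analysis).
#' @param stages Character subset of
#'   `c("simulate", "rates", "structure", "cluster", "destruction")`.
#' @param split_year Calendar year for the patient-set split in the rates
#'   stage.
#' @param k Number of patient subgroups.
#' @param max_per_patient,target_n Evaluation sampling for the clustering
#'   stage (see [sample_evaluations()]).
#' @param repeats Resampling repeats in the structure stage.
#' @param seed Master seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir,
                            cohort = cohort_config(),
                            assessments_path = NULL,
                            sharp_path = NULL,
                            stages = c("simulate", "rates", "structure",
                                       "cluster", "destruction"),
                            split_year = 2011,
                            k = 6L,
                            max_per_patient = 6L,
                            target_n = NULL,
                            repeats = 5L,
                            seed = 1L) {
  stages <- match.arg(stages, several.ok = TRUE)
  if (is.null(cohort) && is.null(assessments_path) &&
      any(stages != "destruction")) {
    stop("either a cohort config or an assessments path is required",
         call. = FALSE)
  }
  structure(list(
    out_dir = out_dir, cohort = cohort,
    assessments_path = assessments_path, sharp_path = sharp_path,
    stages = stages, split_year = split_year, k = as.integer(k),
    max_per_patient = as.integer(max_per_patient), target_n = target_n,
    repeats = as.integer(repeats), seed = as.integer(seed)
  ), class = "pipeline_config")
}

# fixed seed-splitting rule: one master seed -> one seed per stage use
stage_seed <- function(master, index) {
  as.integer((as.numeric(master) + 999983 * index) %% .Machine$integer.max)
}

#' Run the synovitis analysis pipeline end to end
#'
#' Executes the enabled stages in order -- simulate (or load), per-joint
#' rates with laterality and patient-set concordance, kappa/embedding joint
#' structure, Ward subgrouping with regularity, and destruction analysis --
#' writing every result as plain CSV/JSON under `config$out_dir` together
#' with a machine-readable `manifest.json` (inputs, stage seeds, package
#' version, output checksums) and a `summary.json` of headline numbers.
#' Every number in the summary is also present in a stage CSV. A failing
#' stage aborts with an error naming the stage and leaves a `FAILED` marker
#' listing it; earlier outputs are retained.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list of in-memory stage results.
#' @export
#' @examples
#' \donttest{
#' cfg <- pipeline_config(tempfile("run"),
#'                        cohort = cohort_config(n_patients = 150, seed = 3))
#' res <- run_pipeline(cfg)
#' names(res)
#' }
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  results <- list()
  summary <- list()
  written <- character(0)
  emit <- function(df, name) {
    path <- file.path(config$out_dir, name)
    readr::write_csv(df, path, progress = FALSE)
    written <<- c(written, path)
    path
  }
  run_stage <- function(name, fn) {
    tryCatch(fn(), error = function(e) {
      writeLines(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
                 file.path(config$out_dir, "FAILED"))
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  # -- inputs -----------------------------------------------------------
  sharp <- NULL
  if ("simulate" %in% config$stages) {
    sim <- run_stage("simulate", function() {
      cohort <- generate_cohort(config$cohort)
      emit(cohort$assessments, "assessments.csv")
      emit(cohort$truth$patients, "truth_patients.csv")
      cohort
    })
    assessments <- sim$assessments
    results$truth <- sim$truth
    if ("destruction" %in% config$stages) {
      sharp <- run_stage("simulate", function() {
        s <- generate_sharp(sim, config$cohort,
                            seed = stage_seed(config$seed, 1))
        emit(s, "sharp.csv")
        s
      })
    }
  } else {
    assessments <- if (!is.null(config$assessments_path)) {
      run_stage("load", function() read_assessments(config$assessments_path))
    }
    if (!is.null(config$sharp_path)) {
      sharp <- run_stage("load", function() read_sharp(config$sharp_path))
    }
  }
  results$assessments <- assessments

  # -- rates ------------------------------------------------------------
  if ("rates" %in% config$stages) {
    results$rates <- run_stage("rates", function() {
      sets <- split_by_year(assessments, config$split_year)
      sets <- Filter(function(s) nrow(s) > 0, sets)
      profiles <- list()
      for (sym in c("tender", "swollen")) {
        for (nm in names(sets)) {
          one <- resample_one_per_patient(sets[[nm]],
                                          stage_seed(config$seed, 2))
          profiles[[paste(sym, nm, sep = "_")]] <-
            affected_rates(one, sym, set_label = nm)
        }
      }
      all_rates <- purrr::imap_dfr(profiles, function(p, nm) {
        tibble::as_tibble(p) |>
          dplyr::mutate(symptom = attr(p, "symptom"),
                        set_label = attr(p, "set_label"),
                        n_patients = attr(p, "n_patients"))
      })
      emit(all_rates, "rates.csv")
      lat <- purrr::imap_dfr(profiles, function(p, nm) {
        dplyr::mutate(laterality_test(p), profile = nm, .before = 1)
      })
      emit(lat, "laterality.csv")
      conc <- purrr::map_dfr(c("tender", "swollen"), function(sym) {
        keys <- grep(paste0("^", sym), names(profiles), value = TRUE)
        if (length(keys) < 2) return(tibble::tibble())
        dplyr::mutate(
          spearman_concordance(profiles[[keys[1]]], profiles[[keys[2]]]),
          comparison = paste(keys, collapse = " vs "), .before = 1)
      })
      if (length(profiles) >= 2) {
        first_set <- sub("^tender_", "", grep("^tender", names(profiles),
                                              value = TRUE)[1])
        conc <- dplyr::bind_rows(conc, dplyr::mutate(
          spearman_concordance(profiles[[paste0("tender_", first_set)]],
                               profiles[[paste0("swollen_", first_set)]]),
          comparison = "tender vs swollen", .before = 1))
      }
      emit(conc, "concordance.csv")
      list(profiles = profiles, laterality = lat, concordance = conc)
    })
    summary$laterality <- results$rates$laterality
  }

  # -- structure --------------------------------------------------------
  if ("structure" %in% config$stages) {
    results$structure <- run_stage("structure", function() {
      km <- kappa_matrix(assessments, "tender",
                         seed = stage_seed(config$seed, 3))
      emit(tidy(km), "kappa_tender.csv")
      emit(kappa_group_summary(km), "kappa_group_summary.csv")
      emb28 <- eigen_embedding(assessments, "tender", "all",
                               seed = stage_seed(config$seed, 3))
      emb20 <- eigen_embedding(assessments, "tender", "no_large_wrist",
                               seed = stage_seed(config$seed, 3))
      emit(tidy(emb28), "loadings_28.csv")
      emit(tidy(emb20), "loadings_20.csv")
      sep28 <- group_separation(emb28)
      sep20 <- group_separation(emb20)
      rep <- resample_repeats(assessments, "tender",
                              k_repeats = config$repeats,
                              seed = stage_seed(config$seed, 4))
      sep <- list(silhouette_3group_28joint = sep28$silhouette,
                  silhouette_2group_20joint = sep20$silhouette,
                  min_repeat_loading_correlation =
                    min(rep$agreement$abs_correlation))
      jsonlite::write_json(sep, file.path(config$out_dir, "separation.json"),
                           auto_unbox = TRUE, digits = NA)
      written <<- c(written, file.path(config$out_dir, "separation.json"))
      list(kappa = km, embedding_28 = emb28, embedding_20 = emb20,
           separation = sep, repeats = rep)
    })
    summary$separation <- results$structure$separation
  }

  # -- cluster ----------------------------------------------------------
  if ("cluster" %in% config$stages) {
    results$cluster <- run_stage("cluster", function() {
      evals <- sample_evaluations(assessments, config$max_per_patient,
                                  config$target_n,
                                  seed = stage_seed(config$seed, 5))
      feats <- group_rates(evals)
      model <- ward_cluster(feats, k = config$k)
      emit(augment(model), "features.csv")
      emit(characterize(model), "subgroup_summary.csv")
      reg <- regularity(model)
      emit(reg$patients, "regularity.csv")
      list(model = model, regularity = reg)
    })
    summary$subgroups <- results$cluster$model$centers
    summary$regularity <- results$cluster$regularity$summary
  }

  # -- destruction ------------------------------------------------------
  if ("destruction" %in% config$stages && !is.null(sharp)) {
    results$destruction <- run_stage("destruction", function() {
      dr <- destruction_rates(sharp)
      emit(dr, "destruction_rates.csv")
      dom <- right_dominance(sharp)
      emit(dom, "dominance.csv")
      out <- list(rates = dr, dominance = dom)
      if (!is.null(results$cluster)) {
        labels <- augment(results$cluster$model) |>
          dplyr::group_by(.data$patient_id) |>
          dplyr::summarise(
            subgroup = as.integer(names(which.max(table(.data$subgroup)))),
            .groups = "drop")
        diff <- subgroup_destruction_difference(dr, labels)
        emit(diff, "subgroup_diff.csv")
        out$subgroup_diff <- diff
      }
      out
    })
    summary$dominance <- results$destruction$dominance
  }

  # -- manifest & summary ----------------------------------------------
  manifest <- list(
    package_version = as.character(utils::packageVersion("jointgroups")),
    master_seed = config$seed,
    stages = config$stages,
    split_year = config$split_year,
    k = config$k,
    max_per_patient = config$max_per_patient,
    outputs = as.list(tools::md5sum(sort(written)))
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       force = TRUE)
  invisible(results)
}
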