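# Programmatic fixtures: hand-built assessment rows and tiny tables.

# one assessment row with the named joints flagged
make_assessment <- function(patient_id = "P1", visit_index = 1L,
                            visit_year = 2011L,
                            tender = character(0),
                            swollen = character(0)) {
  row <- tibble::as_tibble(
    as.list(stats::setNames(rep(0L, 56), flag_columns()))
  )
  for (j in tender) row[[paste0(j, "_tender")]] <- 1L
  for (j in swollen) row[[paste0(j, "_swollen")]] <- 1L
  dplyr::bind_cols(
    tibble::tibble(patient_id = patient_id, visit_index = visit_index,
                   visit_year = visit_year),
    row
  )
}

# a random valid table: n patients, 1..max_visits visits each
random_table <- function(n_patients, max_visits = 3, seed = 1) {
  withr::with_seed(seed, {
    rows <- lapply(seq_len(n_patients), function(i) {
      k <- sample(max_visits, 1)
      dplyr::bind_rows(lapply(seq_len(k), function(v) {
        flags <- sample(ra_joints()$joint, sample(0:6, 1))
        make_assessment(sprintf("P%03d", i), v, 2005L + v,
                        tender = flags,
                        swollen = sample(flags, min(length(flags), 2)))
      }))
    })
    dplyr::bind_rows(rows)
  })
}

# a zero-symptom sharp row builder
make_sharp <- function(patient_id = "S1", ...) {
  row <- tibble::as_tibble(
    as.list(stats::setNames(rep(0, 12), sharp_elements()))
  )
  override <- list(...)
  for (nm in names(override)) row[[nm]] <- override[[nm]]
  dplyr::bind_cols(tibble::tibble(patient_id = patient_id), row)
}
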