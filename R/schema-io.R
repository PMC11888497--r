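# Case vignette I/O: a strict subset of the GA4GH Phenopacket Schema v2.
# Only the fields the prompting pipeline consumes are modeled: subject id,
# sex, age; observed/excluded phenotypic features with optional onset; and
# the ground-truth diagnosis (carried but never rendered into prompts).

sex_levels <- c("MALE", "FEMALE", "OTHER", "UNKNOWN")

#' Construct a case subject
#'
#' @param id opaque subject identifier.
#' @param sex one of `"MALE"`, `"FEMALE"`, `"OTHER"`, `"UNKNOWN"`.
#' @param age ISO-8601 duration string (e.g. `"P14Y2M"`) or `NULL`. Ages are
#'   kept as strings and only interpreted when a prompt is rendered, so no
#'   unit conversion can lose information.
#' @return a `pdx_subject` list.
#' @export
subject <- function(id, sex = "UNKNOWN", age = NULL) {
  sex <- match.arg(sex, sex_levels)
  if (!is.null(age)) {
    if (!is_iso8601_duration(age)) {
      abort_pdx("subject age must be an ISO-8601 duration, got {age}",
                class = "pdx_schema_error", age = age)
    }
  }
  structure(list(id = as.character(id), sex = sex, age = age),
            class = "pdx_subject")
}

#' Construct a phenotypic feature
#'
#' @param term_id HPO CURIE of the form `HP:NNNNNNN`.
#' @param excluded `TRUE` if the abnormality was explicitly ruled out.
#' @param onset optional ISO-8601 duration or an onset-class CURIE.
#' @return a one-row tibble; features of a case stack into an ordered tibble.
#' @export
phenotypic_feature <- function(term_id, excluded = FALSE, onset = NULL) {
  check_hp_curie(term_id)
  tibble(term_id = term_id, excluded = isTRUE(excluded),
         onset = if (is.null(onset)) NA_character_ else as.character(onset))
}

check_hp_curie <- function(term_id) {
  if (!is.character(term_id) || length(term_id) != 1L ||
      !grepl("^HP:[0-9]{7}$", term_id)) {
    abort_pdx("malformed HPO CURIE: {id}", class = "pdx_curie_error",
              id = paste(term_id, collapse = ","))
  }
  invisible(term_id)
}

#' Construct a case vignette
#'
#' One patient: subject demographics, an ordered feature table, and the
#' ground-truth diagnosis. The diagnosis is held out of prompts; it exists
#' only for scoring.
#'
#' @param id case identifier.
#' @param subject a [subject()].
#' @param features tibble with columns `term_id`, `excluded`, `onset`
#'   (rows in narrative order), e.g. stacked [phenotypic_feature()] rows.
#' @param diagnosis list with `disease_id` (Mondo- or OMIM-like CURIE) and
#'   `label`.
#' @param disease_onset optional ISO-8601 duration for disease-level onset.
#' @return a `case_vignette`.
#' @export
case_vignette <- function(id, subject, features, diagnosis,
                          disease_onset = NULL) {
  stopifnot(inherits(subject, "pdx_subject"), is.data.frame(features))
  features <- as_tibble(features)
  if (!all(c("term_id", "excluded") %in% names(features))) {
    abort_pdx("features need term_id and excluded columns",
              class = "pdx_schema_error")
  }
  if (!"onset" %in% names(features)) features$onset <- NA_character_
  purrr::walk(features$term_id, check_hp_curie)
  if (anyDuplicated(features$term_id)) {
    abort_pdx("duplicate feature term_ids in case {id}",
              class = "pdx_schema_error", id = id)
  }
  if (!any(!features$excluded)) {
    abort_pdx("case {id} has no observed (non-excluded) feature",
              class = "pdx_schema_error", id = id)
  }
  if (!is.list(diagnosis) || is.null(diagnosis$disease_id) ||
      is.null(diagnosis$label)) {
    abort_pdx("diagnosis needs disease_id and label",
              class = "pdx_schema_error")
  }
  if (!grepl("^[A-Za-z][A-Za-z0-9.]*:[A-Za-z0-9]+$", diagnosis$disease_id)) {
    abort_pdx("malformed diagnosis CURIE: {id}", class = "pdx_curie_error",
              id = diagnosis$disease_id)
  }
  structure(
    list(id = as.character(id), subject = subject,
         features = features[c("term_id", "excluded", "onset")],
         diagnosis = list(disease_id = diagnosis$disease_id,
                          label = diagnosis$label),
         disease_onset = disease_onset),
    class = "case_vignette")
}

#' @export
print.case_vignette <- function(x, ...) {
  cat(sprintf("<case_vignette %s: %s, %s, %d observed / %d excluded, dx %s>\n",
              x$id, x$subject$sex, x$subject$age %||% "age unknown",
              sum(!x$features$excluded), sum(x$features$excluded),
              x$diagnosis$disease_id))
  invisible(x)
}

#' Read one case vignette from Phenopacket-subset JSON
#'
#' Accepts only the schema fields the pipeline uses (`id`, `subject` with
#' `sex`/`timeAtLastEncounter.age.iso8601duration`, `phenotypicFeatures`
#' with `type.id`, `excluded`, `onset`, and `diseases[[1]]` as the
#' diagnosis). Unknown fields are ignored with a warning, so richer
#' phenopackets still load.
#'
#' @param json_text a JSON string, or a file path to one `.json` file.
#' @return a [case_vignette()].
#' @export
read_vignette <- function(json_text) {
  if (length(json_text) == 1L && !grepl("[{]", json_text) &&
      file.exists(json_text)) {
    json_text <- paste(readLines(json_text, warn = FALSE, encoding = "UTF-8"),
                       collapse = "\n")
  }
  x <- jsonlite::fromJSON(json_text, simplifyVector = FALSE)

  known <- c("id", "subject", "phenotypicFeatures", "diseases", "diseaseOnset")
  extra <- setdiff(names(x), known)
  if (length(extra)) {
    rlang::warn(paste0("ignoring unknown phenopacket fields: ",
                       paste(extra, collapse = ", ")),
                class = "pdx_unknown_field_warning")
  }
  if (is.null(x$subject)) {
    abort_pdx("phenopacket is missing subject", class = "pdx_schema_error")
  }
  if (is.null(x$phenotypicFeatures) || !length(x$phenotypicFeatures)) {
    abort_pdx("phenopacket is missing phenotypicFeatures",
              class = "pdx_schema_error")
  }
  if (is.null(x$diseases) || !length(x$diseases)) {
    abort_pdx("phenopacket is missing diseases (ground-truth diagnosis)",
              class = "pdx_schema_error")
  }

  subj <- subject(
    id = x$subject$id %||% "subject",
    sex = x$subject$sex %||% "UNKNOWN",
    age = x$subject$timeAtLastEncounter$age$iso8601duration)

  feats <- purrr::map(x$phenotypicFeatures, function(f) {
    onset <- f$onset$age$iso8601duration %||% f$onset$ontologyClass$id
    phenotypic_feature(term_id = f$type$id %||% f$type,
                       excluded = isTRUE(f$excluded),
                       onset = onset)
  }) %>% bind_rows()

  d <- x$diseases[[1]]
  case_vignette(
    id = x$id %||% subj$id,
    subject = subj,
    features = feats,
    diagnosis = list(disease_id = d$term$id %||% d$id,
                     label = d$term$label %||% d$label %||% ""),
    disease_onset = x$diseaseOnset)
}

#' Serialize a case vignette back to Phenopacket-subset JSON
#'
#' Inverse of [read_vignette()]: `read_vignette(write_vignette(v))` is the
#' identity on the canonical form, preserving feature order and age strings
#' byte-for-byte.
#'
#' @param v a [case_vignette()].
#' @return a JSON string.
#' @export
write_vignette <- function(v) {
  stopifnot(inherits(v, "case_vignette"))
  subj <- list(id = v$subject$id, sex = v$subject$sex)
  if (!is.null(v$subject$age)) {
    subj$timeAtLastEncounter <- list(age = list(iso8601duration = v$subject$age))
  }
  feats <- purrr::pmap(v$features, function(term_id, excluded, onset) {
    f <- list(type = list(id = term_id))
    if (excluded) f$excluded <- TRUE
    if (!is.na(onset)) {
      f$onset <- if (grepl("^P", onset)) {
        list(age = list(iso8601duration = onset))
      } else {
        list(ontologyClass = list(id = onset))
      }
    }
    f
  })
  out <- list(id = v$id, subject = subj, phenotypicFeatures = feats,
              diseases = list(list(term = list(id = v$diagnosis$disease_id,
                                               label = v$diagnosis$label))))
  if (!is.null(v$disease_onset)) out$diseaseOnset <- v$disease_onset
  jsonlite::toJSON(out, auto_unbox = TRUE, pretty = TRUE)
}

#' Read a cohort directory of vignette JSON files
#'
#' Files are read in lexicographic filename order so the cohort order never
#' depends on filesystem enumeration. Per-file failures are collected, not
#' fatal; they are attached as the `"failures"` attribute (a tibble with
#' `file` and `error`).
#'
#' @param path directory containing `*.json` vignette files.
#' @return list of [case_vignette()] objects with a `"failures"` attribute.
#' @export
read_cohort <- function(path) {
  files <- sort(list.files(path, pattern = "\\.json$", full.names = TRUE))
  results <- purrr::map(files, purrr::safely(read_vignette))
  ok <- purrr::map_lgl(results, ~ is.null(.x$error))
  vignettes <- purrr::map(results[ok], "result")
  failures <- tibble(
    file = basename(files[!ok]),
    error = purrr::map_chr(results[!ok], ~ conditionMessage(.x$error)))
  if (!length(vignettes)) {
    abort_pdx("no parseable vignette JSON files in {path}",
              class = "pdx_empty_cohort_error", path = path)
  }
  structure(vignettes, failures = failures)
}

#' Summarise a cohort as a tibble
#'
#' One row per case: id, sex, age, feature counts and the held-out diagnosis
#' id. Convenient for dplyr-style inspection of a loaded or generated cohort.
#'
#' @param vignettes list of [case_vignette()] objects.
#' @return a tibble.
#' @export
cohort_tibble <- function(vignettes) {
  purrr::map(vignettes, function(v) {
    tibble(case_id = v$id, sex = v$subject$sex,
           age = v$subject$age %||% NA_character_,
           n_features = nrow(v$features),
           n_observed = sum(!v$features$excluded),
           n_excluded = sum(v$features$excluded),
           disease_id = v$diagnosis$disease_id)
  }) %>% bind_rows()
}
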