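read_table_sniffed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1)
  if (!length(first)) stop("empty file: ", path)
  sep <- if (lengths(regmatches(first, gregexpr("\t", first))) >
             lengths(regmatches(first, gregexpr(",", first)))) "\t" else ","
  read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
}

check_columns <- function(df, required, what) {
  miss <- setdiff(required, names(df))
  if (length(miss)) stop(what, " is missing mandatory column(s): ",
                         paste(miss, collapse = ", "))
  invisible(df)
}

range_report <- function(bad, what) {
  if (any(bad, na.rm = TRUE))
    stop(what, " out of range in row(s): ",
         paste(head(which(bad), 10), collapse = ", "))
}

#' Read a regional volume table
#'
#' Reads a CSV or TSV (delimiter sniffed from the header row; UTF-8, period
#' decimal) of per-visit regional brain volumes and checks units and ranges:
#' volumes and ICV must be positive mm^3, sex labels are normalized to
#' `female`/`male`, and the configured region columns must be present.
#'
#' @param path File path.
#' @param regions Required region columns (default [sca3_regions()]).
#' @return Validated data.frame.
#' @export
read_volume_table <- function(path, regions = sca3_regions()) {
  df <- read_table_sniffed(path)
  check_columns(df, c("subject_id", "visit_index", "group", "age", "sex",
                      "icv", regions), "volume table")
  df$sex <- tolower(trimws(df$sex))
  df$sex[df$sex %in% c("f", "w")] <- "female"
  df$sex[df$sex == "m"] <- "male"
  bad_sex <- !df$sex %in% c("female", "male")
  if (any(bad_sex)) stop("unrecognized sex label(s): ",
                         paste(unique(df$sex[bad_sex]), collapse = ", "))
  range_report(df$icv <= 0, "icv")
  range_report(df$age <= 0 | df$age > 120, "age")
  for (r in regions) range_report(df[[r]] <= 0, r)
  df
}

#' Read a clinical table
#'
#' Reads a CSV/TSV of per-visit clinical assessments with range validation:
#' SARA in 0-40, INAS in 0-16, CAG repeats plausible, and normalized sex
#' labels when present.
#'
#' @param path File path.
#' @return Validated data.frame.
#' @export
read_clinical_table <- function(path) {
  df <- read_table_sniffed(path)
  check_columns(df, c("subject_id", "visit_index", "sara"), "clinical table")
  range_report(df$sara < 0 | df$sara > 40, "sara")
  if ("inas" %in% names(df)) range_report(df$inas < 0 | df$inas > 16, "inas")
  if ("cag_expanded" %in% names(df))
    range_report(df$cag_expanded < 40 | df$cag_expanded > 100, "cag_expanded")
  if ("sex" %in% names(df)) {
    df$sex <- tolower(trimws(df$sex))
    df$sex[df$sex %in% c("f", "w")] <- "female"
    df$sex[df$sex == "m"] <- "male"
  }
  df
}

MODEL_SCHEMA_VERSION <- "1.0"

#' Serialize a progression model to JSON
#'
#' Sequences are stored as ordered event-label lists; MCMC samples can be
#' elided (`include_samples = FALSE`), which is recorded in the file and does
#' not affect staging (staging uses the ML sequences only).
#'
#' @param model A [fit_subtypes()] model.
#' @param path Output path.
#' @param include_samples Store the MCMC samples (default TRUE).
#' @return `path`, invisibly.
#' @export
write_progression_model <- function(model, path, include_samples = TRUE) {
  stopifnot(inherits(model, "progression_model"))
  events <- model$events
  obj <- list(
    schema_version = MODEL_SCHEMA_VERSION,
    biomarkers = events$biomarkers,
    thresholds = events$thresholds,
    k = model$k,
    fractions = model$fractions,
    sequences = lapply(model$sequences, sequence_labels, events = events),
    sigma = model$control$sigma,
    z_max = model$control$z_max,
    stage_prior = model$control$stage_prior,
    loglik = model$loglik,
    samples_included = include_samples
  )
  if (include_samples) {
    obj$mcmc <- lapply(model$mcmc, function(mc) {
      if (is.null(mc$samples)) return(NULL)
      list(samples = unname(apply(mc$samples, 1, function(s)
        events$table$label[s], simplify = FALSE)),
        loglik = mc$loglik)
    })
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a progression model from JSON
#'
#' @param path A file written by [write_progression_model()].
#' @return A `progression_model` usable by [assign_stages()].
#' @export
read_progression_model <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e) stop("cannot parse model file: ",
                                           conditionMessage(e)))
  if (is.null(obj$schema_version) ||
      !identical(as.character(obj$schema_version), MODEL_SCHEMA_VERSION))
    stop("unsupported model schema version: ",
         obj$schema_version %||% "<missing>")
  events <- ebm_events(unlist(obj$biomarkers), unlist(obj$thresholds))
  k <- as.integer(obj$k)
  sequences <- lapply(obj$sequences, function(s)
    sequence_from_labels(unlist(s), events))
  mcmc <- vector("list", k)
  if (isTRUE(obj$samples_included) && !is.null(obj$mcmc)) {
    for (c in seq_len(k)) {
      mc <- obj$mcmc[[c]]
      if (is.null(mc) || is.null(mc$samples)) next
      smp <- do.call(rbind, lapply(mc$samples, function(s)
        sequence_from_labels(unlist(s), events)))
      mcmc[[c]] <- list(samples = smp, loglik = as.numeric(unlist(mc$loglik)))
    }
  }
  prior <- unlist(obj$stage_prior)
  if (!length(prior)) prior <- NULL
  control <- ebm_control(sigma = obj$sigma, z_max = obj$z_max,
                         stage_prior = prior, profile = "test")
  model <- list(events = events, k = k, sequences = sequences,
                fractions = as.numeric(unlist(obj$fractions)), mcmc = mcmc,
                control = control, loglik = obj$loglik, converged = TRUE)
  class(model) <- "progression_model"
  model
}

#' Write cohort tables to a directory
#'
#' Writes `volumes.csv`, `clinical.csv` and a `ground_truth.json` sidecar for
#' a synthetic cohort.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sca3_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write.csv(cohort$volumes, file.path(dir, "volumes.csv"), row.names = FALSE)
  write.csv(cohort$clinical, file.path(dir, "clinical.csv"),
            row.names = FALSE)
  truth <- list(sequence = cohort$truth$sequence_labels,
                stages = cohort$truth$stages,
                subjects = cohort$truth$subjects,
                seed = cohort$config$seed)
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}
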