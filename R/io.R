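# Canonical trial CSV, configuration files, and schema validation.
#
# Canonical schema (one row per trial): subject_id, drug, session_order,
# block, trial_index, trial_type {test, control, neutral}, choice {high,
# low, none}, outcome {win, lose, neutral}, rt_s (seconds), vas_rating
# (0-200), beh_delta_c (degrees C). A column-mapping argument adapts
# externally named deposits at load time.

TRIAL_COLUMNS <- c("subject_id", "drug", "session_order", "block",
                   "trial_index", "trial_type", "choice", "outcome",
                   "rt_s", "vas_rating", "beh_delta_c")

# typography guard: en-dash / unicode-minus to ASCII minus before coercion
normalize_minus <- function(x) {
  if (is.character(x)) gsub("−|–", "-", x) else x
}

#' Read and validate a canonical trial table
#'
#' Reads the trial CSV, optionally renames externally named columns,
#' normalizes en-dash minus signs, checks the schema (required columns,
#' valid trial types/choices/outcomes, VAS in \[0, 200\], positive RTs on
#' completed trials), and drops no-response test trials (no recorded
#' choice) with a logged count.
#'
#' @param path CSV file path.
#' @param mapping Optional named character vector `c(canonical = "file
#'   column")` adapting foreign column names.
#' @param drop_no_response Drop test trials without a button press
#'   (default `TRUE`, matching the analysis rule that such trials are
#'   excluded).
#' @return Validated trial data.frame.
#' @export
read_trials <- function(path, mapping = NULL, drop_no_response = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(mapping)) {
    for (canon in names(mapping)) {
      if (mapping[[canon]] %in% names(df))
        names(df)[names(df) == mapping[[canon]]] <- canon
    }
  }
  validate_trials(df, drop_no_response = drop_no_response)
}

#' Validate a trial table against the canonical schema
#'
#' @param df Trial data.frame.
#' @inheritParams read_trials
#' @return The validated (possibly row-reduced) data.frame.
#' @export
validate_trials <- function(df, drop_no_response = TRUE) {
  miss <- setdiff(TRIAL_COLUMNS, names(df))
  if (length(miss))
    stop("missing required columns: ", paste(miss, collapse = ", "))
  for (col in c("rt_s", "vas_rating", "beh_delta_c")) {
    df[[col]] <- as.numeric(normalize_minus(df[[col]]))
  }
  bad_type <- which(!df$trial_type %in% c("test", "control", "neutral"))
  if (length(bad_type))
    stop("invalid trial_type in rows: ",
         paste(head(bad_type, 10), collapse = ", "))
  bad_choice <- which(!df$choice %in% c("high", "low", "none"))
  if (length(bad_choice))
    stop("invalid choice in rows: ",
         paste(head(bad_choice, 10), collapse = ", "))
  bad_out <- which(!df$outcome %in% c("win", "lose", "neutral"))
  if (length(bad_out))
    stop("invalid outcome in rows: ",
         paste(head(bad_out, 10), collapse = ", "))
  bad_vas <- which(!is.na(df$vas_rating) &
                     (df$vas_rating < 0 | df$vas_rating > 200))
  if (length(bad_vas))
    stop("VAS rating outside [0, 200] in rows: ",
         paste(head(bad_vas, 10), collapse = ", "))
  bad_rt <- which(!is.na(df$rt_s) & df$rt_s <= 0)
  if (length(bad_rt))
    stop("non-positive reaction time in rows: ",
         paste(head(bad_rt, 10), collapse = ", "))
  if (drop_no_response) {
    no_resp <- df$trial_type == "test" &
      (df$choice == "none" | is.na(df$rt_s))
    if (any(no_resp)) {
      message("dropping ", sum(no_resp), " no-response test trial(s)")
      df <- df[!no_resp, ]
    }
  }
  rownames(df) <- NULL
  df
}

#' Write a trial table to CSV
#'
#' @param df Trial data.frame in the canonical schema.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(df, path) {
  write.csv(df[, TRIAL_COLUMNS], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Assemble a pipeline configuration
#'
#' Bundles the task and generative configurations, the model selection,
#' the fit profile and stage seeds into one serializable object. Round
#' trips losslessly through [write_config()] / [read_config()].
#'
#' @param task [task_config()] entries (list).
#' @param generative [generative_config()] entries (list).
#' @param spec Model id (1-4) used by fitting stages.
#' @param profile Fit profile, `"desk"` or `"paper"`.
#' @param seed Master integer seed recorded with every stage output.
#' @param out_dir Output directory for CLI stages.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(task = list(), generative = list(), spec = 4,
                            profile = "desk", seed = 1L, out_dir = ".") {
  cfg <- list(task = task, generative = generative, spec = spec,
              profile = profile, seed = as.integer(seed), out_dir = out_dir)
  class(cfg) <- "pipeline_config"
  cfg
}

#' @rdname pipeline_config
#' @param cfg A `pipeline_config`.
#' @param path YAML file path.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw[intersect(names(raw),
                                         names(formals(pipeline_config)))])
}

build_task <- function(cfg) do.call(task_config, cfg$task %||% list())

build_generative <- function(cfg) {
  args <- cfg$generative %||% list()
  for (nm in c("group_loc", "group_scale"))
    if (!is.null(args[[nm]])) args[[nm]] <- unlist(args[[nm]])
  if (is.null(args$seed)) args$seed <- cfg$seed
  do.call(generative_config, args)
}
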