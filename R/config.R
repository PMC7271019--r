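# Project configuration: defaults, YAML round trip, validation.

.config_defaults <- function(modality) {
  base <- list(
    modality = modality,
    data = list(
      participants = "participants.tsv",
      roi_mask = "roi.nii.gz",
      target_mask = NULL,
      reference_images = list()
    ),
    masks = list(
      median_filter = FALSE,
      remove_roi_from_target = TRUE,
      roi_border_mm = 0,
      subsample_target = FALSE,
      upsample_roi_factor = NULL,
      downsample_target_factor = NULL,
      validate_space = TRUE
    ),
    transforms = list(
      fisher_z = FALSE,
      cubic = FALSE,
      pca = NULL      # integer component count or variance fraction in (0,1)
    ),
    clustering = list(
      method = "kmeans",
      k_range = c(2L, 3L, 4L, 5L),
      n_init = 256L,
      max_iter = 10000L,
      init_method = "k-means++",
      linkage = "complete",
      group_mode = "mode",
      seed = 1L
    ),
    validity = list(
      internal = c("silhouette", "calinski_harabasz", "davies_bouldin"),
      similarity = "ari"
    ),
    output = list(figure_format = "png")
  )
  if (modality == "rsfmri") {
    base$data$time_series <- "{participant_id}_bold.nii.gz"
    base$data$confounds <- NULL
    base$data$confound_columns <- NULL
    base$parameters <- list(
      smoothing_fwhm_mm = 5,
      bandpass = list(low_hz = 0.01, high_hz = 0.08),
      tr_seconds = NULL
    )
    base$transforms$fisher_z <- TRUE
  } else if (modality == "dmri") {
    base$data$connectivity <- "{participant_id}_omat2.txt"
    base$data$connectivity_shape <- NULL   # c(n_rows, n_cols), required
    base$transforms$cubic <- TRUE
  } else if (modality == "connectivity") {
    base$data$connectivity <- "{participant_id}_connectivity.bin"
  } else {
    stop("unknown modality '", modality,
         "' (valid: connectivity, rsfmri, dmri)")
  }
  base
}

#' Build a complete example configuration
#'
#' One per input modality: `"rsfmri"` (4D BOLD time series per subject),
#' `"dmri"` (sparse tractography matrix per subject) or `"connectivity"`
#' (precomputed dense matrices). Each example validates with zero errors
#' and only omits options not applicable to its modality.
#'
#' @param data_type one of `"connectivity"`, `"rsfmri"`, `"dmri"`.
#' @return A `project_config` list.
#' @export
example_config <- function(data_type = c("connectivity", "rsfmri", "dmri")) {
  if (!is.character(data_type) ||
      !data_type[1] %in% c("connectivity", "rsfmri", "dmri"))
    stop("unknown data type '", data_type[1],
         "'; valid types: connectivity, rsfmri, dmri")
  structure(.config_defaults(data_type[1]), class = "project_config")
}

#' Read a project configuration from YAML
#'
#' Unspecified fields take the modality's defaults, so a minimal config can
#' name only the input paths.
#'
#' @param path path to a YAML config file.
#' @return A `project_config` list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw$modality))
    stop("config must name a 'modality' (connectivity, rsfmri, dmri)")
  merged <- .deep_merge(.config_defaults(raw$modality), raw)
  structure(merged, class = "project_config")
}

.deep_merge <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]) &&
        !is.null(names(base[[nm]])))
      base[[nm]] <- .deep_merge(base[[nm]], override[[nm]])
    else
      base[[nm]] <- override[[nm]]
  }
  base
}

#' Write a project configuration to YAML
#' @param config a `project_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Validate a project configuration
#'
#' Errors block project creation; warnings are informational and never
#' block execution. Checks the clustering parameter ranges, the presence of
#' the `{participant_id}` placeholder in every subject-wise path template,
#' and modality-specific requirements.
#'
#' @param config a `project_config`.
#' @param participants optional character vector of participant ids (used to
#'   decide whether a template without `{participant_id}` is fatal).
#' @return A list with character vectors `errors` and `warnings`.
#' @export
validate_config <- function(config, participants = NULL) {
  errors <- character(); warnings <- character()
  err <- function(msg) errors[[length(errors) + 1L]] <<- msg
  wrn <- function(msg) warnings[[length(warnings) + 1L]] <<- msg

  if (!config$modality %in% c("connectivity", "rsfmri", "dmri"))
    err(paste0("unknown modality '", config$modality, "'"))

  cl <- config$clustering
  ks <- cl$k_range
  if (length(ks) == 0L) err("k_range is empty")
  else {
    if (any(ks < 2)) err("k_range entries must be >= 2")
    if (length(ks) > 1 && any(diff(ks) <= 0))
      err("k_range must be strictly increasing")
  }
  if (is.null(cl$n_init) || cl$n_init < 1) err("n_init must be >= 1")
  if (is.null(cl$max_iter) || cl$max_iter < 1) err("max_iter must be >= 1")
  if (!cl$method %in% c("kmeans", "spectral", "agglomerative"))
    err(paste0("unknown clustering method '", cl$method, "'"))
  if (!cl$group_mode %in% c("mode", "hierarchical"))
    err(paste0("unknown group_mode '", cl$group_mode, "'"))

  n_subj <- if (is.null(participants)) 2L else length(participants)
  templates <- config$data[c("time_series", "confounds", "connectivity")]
  for (nm in names(templates)) {
    tpl <- templates[[nm]]
    if (is.null(tpl)) next
    if (!grepl("{participant_id}", tpl, fixed = TRUE)) {
      if (n_subj > 1L)
        err(paste0("path template '", nm,
                   "' lacks the {participant_id} placeholder"))
      else
        wrn(paste0("path template '", nm,
                   "' lacks {participant_id}; accepted for a single subject"))
    }
  }

  if (config$modality == "rsfmri") {
    if (is.null(config$data$time_series))
      err("rsfmri modality requires data$time_series")
    bp <- config$parameters$bandpass
    if (!is.null(bp) && (bp$low_hz <= 0 || bp$low_hz >= bp$high_hz))
      err("bandpass must satisfy 0 < low_hz < high_hz")
    sm <- config$parameters$smoothing_fwhm_mm
    if (!is.null(sm) && sm < 0) err("smoothing FWHM must be >= 0")
  }
  if (config$modality %in% c("dmri", "connectivity") &&
      is.null(config$data$connectivity))
    err(paste0(config$modality, " modality requires data$connectivity"))
  if (config$modality == "dmri" &&
      is.null(config$data$connectivity_shape))
    wrn("dmri: connectivity_shape not set; it must be inferable per subject")

  pca <- config$transforms$pca
  if (!is.null(pca) && (!is.numeric(pca) || pca <= 0))
    err("transforms$pca must be a positive component count or a variance fraction in (0,1)")
  if (isTRUE(config$transforms$cubic) && isTRUE(config$transforms$fisher_z))
    wrn("both cubic and fisher_z transforms enabled; this is unusual")

  bad_internal <- setdiff(config$validity$internal,
                          c("silhouette", "calinski_harabasz", "davies_bouldin"))
  if (length(bad_internal))
    err(paste0("unknown internal validity metric: ",
               paste(bad_internal, collapse = ", ")))
  if (!config$validity$similarity %in% c("ari", "v_measure", "ami"))
    err(paste0("unknown similarity metric '", config$validity$similarity, "'"))

  list(errors = errors, warnings = warnings)
}

#' Substitute a participant id into a path template
#' @param template path containing `{participant_id}`.
#' @param participant_id subject id.
#' @return The substituted path.
#' @export
subject_path <- function(template, participant_id) {
  gsub("{participant_id}", participant_id, template, fixed = TRUE)
}
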