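# Project lifecycle: create a validated project folder, run the stage
# graph (resumable, parallelizable over independent units), emit reports.
#
# A unit of work is (stage, subject_id, k). Outputs are a pure function of
# (inputs, config, master seed): every unit derives its own RNG seed, so
# the results do not depend on worker count or interruption history. A
# unit is skipped when its outputs exist and the config snapshot hash they
# were produced under is unchanged.

.state_path <- function(project_dir) file.path(project_dir, "state.json")

.read_state <- function(project_dir) {
  p <- .state_path(project_dir)
  if (!file.exists(p)) return(list(config_hash = "", completed = list()))
  jsonlite::read_json(p, simplifyVector = FALSE)
}

.write_state <- function(project_dir, state) {
  jsonlite::write_json(state, .state_path(project_dir), auto_unbox = TRUE)
}

.unit_key <- function(stage, subject_id = "-", k = "-") {
  paste(stage, subject_id, k, sep = ":")
}

.unit_done <- function(state, key, outputs) {
  isTRUE(state$completed[[key]] == state$config_hash) &&
    all(file.exists(outputs))
}

#' Write an example configuration file
#'
#' @param data_type `"connectivity"`, `"rsfmri"` or `"dmri"`.
#' @param path output YAML path (default `rcbp_<data_type>.yaml`).
#' @return The path, invisibly.
#' @export
cmd_example <- function(data_type, path = NULL) {
  cfg <- example_config(data_type)
  if (is.null(path)) path <- sprintf("rcbp_%s.yaml", data_type)
  write_config(cfg, path)
  .rcbp_log("wrote example ", data_type, " configuration to ", path)
  invisible(path)
}

#' Create a new project folder
#'
#' Validates the configuration against the participants file; errors must
#' be resolved before the project is created, warnings are logged but do
#' not block. The config and participants are snapshotted into the project
#' folder so later runs are insulated from edits to the originals.
#'
#' @param config a `project_config` or a path to a YAML config. Relative
#'   data paths are resolved against the config file's directory (or
#'   `base_dir`).
#' @param out_dir directory to create.
#' @param base_dir base for relative data paths when `config` is an object.
#' @return The project directory path, invisibly.
#' @export
project_create <- function(config, out_dir, base_dir = ".") {
  if (is.character(config)) {
    base_dir <- dirname(normalizePath(config))
    config <- read_config(config)
  }
  config <- .absolutize_paths(config, base_dir)
  participants <- read_participants(config$data$participants)
  v <- validate_config(config, participants)
  for (w in v$warnings) .rcbp_log(w, level = "WARN")
  if (length(v$errors) > 0L)
    stop("configuration errors must be resolved before project creation:\n  ",
         paste(v$errors, collapse = "\n  "))
  if (file.exists(file.path(out_dir, "config.yaml")))
    stop("project already exists at ", out_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_config(config, file.path(out_dir, "config.yaml"))
  write_participants(participants, file.path(out_dir, "participants.tsv"))
  state <- list(config_hash =
                  unname(tools::md5sum(file.path(out_dir, "config.yaml"))),
                completed = list())
  .write_state(out_dir, state)
  .rcbp_log("created project at ", out_dir, " with ",
            length(participants), " participants")
  invisible(out_dir)
}

.absolutize_paths <- function(config, base_dir) {
  fix <- function(p) {
    if (is.null(p) || grepl("^/", p)) p else file.path(base_dir, p)
  }
  for (nm in c("participants", "roi_mask", "target_mask", "time_series",
               "confounds", "connectivity"))
    config$data[[nm]] <- fix(config$data[[nm]])
  if (length(config$data$reference_images))
    config$data$reference_images <-
      lapply(config$data$reference_images, fix)
  config
}

.prepare_masks <- function(config) {
  roi <- read_mask(config$data$roi_mask)
  target <- if (!is.null(config$data$target_mask))
    read_mask(config$data$target_mask) else NULL
  mk <- config$masks
  if (isTRUE(mk$validate_space) && !is.null(target)) {
    rep <- validate_space(roi, template_space_of(target))
    if (!rep$ok)
      stop("ROI/target grid conformity check failed: ",
           paste(rep$messages, collapse = "; "))
  }
  if (isTRUE(mk$median_filter)) roi <- median_filter_mask(roi)
  if (!is.null(target)) {
    if (isTRUE(mk$remove_roi_from_target))
      target <- remove_roi_from_target(target, roi,
                                       border_mm = mk$roi_border_mm %||% 0)
    if (isTRUE(mk$subsample_target)) target <- subsample_target(target)
    if (!is.null(mk$downsample_target_factor))
      target <- downsample_target(target, mk$downsample_target_factor)
  }
  list(roi = roi, target = target)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.subject_connectivity <- function(config, sid, masks) {
  tpl <- config$data$connectivity
  if (config$modality == "rsfmri") {
    series <- read_bold(subject_path(config$data$time_series, sid),
                        tr_seconds = config$parameters$tr_seconds)
    conf <- NULL
    if (!is.null(config$data$confounds))
      conf <- read_confounds(subject_path(config$data$confounds, sid),
                             columns = config$data$confound_columns)
    return(rsfmri_connectivity(
      series, masks$roi, masks$target,
      smoothing_fwhm_mm = config$parameters$smoothing_fwhm_mm %||% 0,
      confounds = conf, bandpass = config$parameters$bandpass,
      fisher_z = isTRUE(config$transforms$fisher_z),
      pca = config$transforms$pca))
  }
  if (config$modality == "dmri") {
    shp <- config$data$connectivity_shape
    cm <- read_sparse_connectivity(subject_path(tpl, sid),
                                   n_rows = shp[1], n_cols = shp[2],
                                   voxel_index = mask_coordinates(masks$roi))
    if (isTRUE(config$transforms$cubic)) cm <- cubic_transform(cm)
    if (!is.null(config$transforms$pca))
      cm <- pca_reduce(cm, config$transforms$pca)
    return(cm)
  }
  cm <- read_dense_connectivity(subject_path(tpl, sid))
  if (isTRUE(config$transforms$fisher_z)) cm <- fisher_z(cm)
  if (isTRUE(config$transforms$cubic)) cm <- cubic_transform(cm)
  if (!is.null(config$transforms$pca))
    cm <- pca_reduce(cm, config$transforms$pca)
  cm
}

.apply_units <- function(units, fn, jobs) {
  if (jobs > 1L && .Platform$OS.type == "unix")
    parallel::mclapply(units, fn, mc.cores = jobs, mc.preschedule = FALSE)
  else
    lapply(units, fn)
}

#' Run (or resume) a project
#'
#' Executes the stage graph: mask preprocessing, per-subject connectivity,
#' per-(subject, k) clustering, per-k group consensus and validity
#' reports. Independent units run in parallel when `jobs > 1`; every unit
#' derives its own seed from the master seed, so results are identical for
#' any worker count. Completed units (outputs present under the current
#' config hash) are skipped, making interrupted runs resumable.
#'
#' @param project_dir a directory created by [project_create()].
#' @param jobs number of parallel workers.
#' @param subjects optional subset of participant ids to run.
#' @param ks optional subset of the configured k range.
#' @return The project directory, invisibly.
#' @export
project_run <- function(project_dir, jobs = 1L, subjects = NULL, ks = NULL) {
  config <- read_config(file.path(project_dir, "config.yaml"))
  participants <- read_participants(file.path(project_dir,
                                              "participants.tsv"))
  all_participants <- participants
  if (!is.null(subjects)) {
    bad <- setdiff(subjects, participants)
    if (length(bad)) stop("unknown subjects: ", paste(bad, collapse = ", "))
    participants <- intersect(participants, subjects)
  }
  k_range <- as.integer(config$clustering$k_range)
  if (!is.null(ks)) k_range <- intersect(k_range, as.integer(ks))
  state <- .read_state(project_dir)
  master <- config$clustering$seed

  masks <- .prepare_masks(config)
  conn_dir <- file.path(project_dir, "connectivity")
  clus_dir <- file.path(project_dir, "clustering")
  grp_dir <- file.path(project_dir, "group")
  val_dir <- file.path(project_dir, "validity")
  for (d in c(conn_dir, clus_dir, grp_dir, val_dir))
    dir.create(d, showWarnings = FALSE)

  # --- connectivity stage (per subject) --------------------------------
  conn_path <- function(sid) file.path(conn_dir, paste0(sid, ".bin"))
  todo <- Filter(function(sid)
    !.unit_done(state, .unit_key("connectivity", sid), conn_path(sid)),
    participants)
  .apply_units(todo, function(sid) {
    cm <- .subject_connectivity(config, sid, masks)
    write_dense_connectivity(cm, conn_path(sid))
    NULL
  }, jobs)
  for (sid in todo)
    state$completed[[.unit_key("connectivity", sid)]] <- state$config_hash
  .write_state(project_dir, state)

  # --- clustering stage (per subject x k) ------------------------------
  clus_path <- function(sid, k)
    file.path(clus_dir, sprintf("%s_k%d.tsv", sid, k))
  units <- expand.grid(sid = participants, k = k_range,
                       stringsAsFactors = FALSE)
  todo <- which(!vapply(seq_len(nrow(units)), function(i)
    .unit_done(state, .unit_key("clustering", units$sid[i], units$k[i]),
               clus_path(units$sid[i], units$k[i])), logical(1)))
  .apply_units(todo, function(i) {
    sid <- units$sid[i]; k <- units$k[i]
    cm <- read_dense_connectivity(conn_path(sid))
    params <- cluster_params(
      method = config$clustering$method, k = k,
      n_init = config$clustering$n_init,
      max_iter = config$clustering$max_iter,
      init_method = config$clustering$init_method,
      linkage = config$clustering$linkage,
      seed = derive_seed(master, sid, k))
    lab <- cluster_subject(cm, params, subject_id = sid)
    write.table(data.frame(voxel = seq_along(lab$labels) - 1L,
                           label = lab$labels),
                clus_path(sid, k), sep = "\t", quote = FALSE,
                row.names = FALSE)
    NULL
  }, jobs)
  for (i in todo)
    state$completed[[.unit_key("clustering", units$sid[i], units$k[i])]] <-
      state$config_hash
  .write_state(project_dir, state)

  read_labels <- function(sid, k)
    labeling(read.delim(clus_path(sid, k))$label, k = k, subject_id = sid)

  # --- group + validity stages (per k) ---------------------------------
  # a run restricted to a subject subset yields preview group outputs only:
  # they are not marked complete, so a later full run recomputes them
  full_cohort <- setequal(participants, all_participants)
  for (k in k_range) {
    grp_files <- c(file.path(grp_dir, sprintf("group_k%d.nii.gz", k)),
                   file.path(grp_dir, sprintf("relabel_accuracy_k%d.tsv", k)),
                   file.path(grp_dir, sprintf("linkage_k%d.tsv", k)),
                   file.path(val_dir, sprintf("internal_validity_k%d.tsv", k)),
                   file.path(val_dir, sprintf("similarity_k%d.tsv", k)))
    key <- .unit_key("group", k = k)
    if (.unit_done(state, key, grp_files)) next
    labs <- lapply(participants, read_labels, k = k)
    if (length(labs) >= 2L) {
      gr <- group_parcellation(labs, k = k,
                               linkage = config$clustering$linkage,
                               group_mode = config$clustering$group_mode)
      write_label_image(gr$mode_labels, masks$roi, grp_files[1])
      write.table(data.frame(participant_id = names(gr$relabel_accuracy),
                             relabel_accuracy = gr$relabel_accuracy,
                             cophenetic_r = gr$cophenetic_r),
                  grp_files[2], sep = "\t", quote = FALSE, row.names = FALSE)
      write.table(data.frame(merge1 = gr$tree$merge[, 1],
                             merge2 = gr$tree$merge[, 2],
                             height = gr$tree$height),
                  grp_files[3], sep = "\t", quote = FALSE, row.names = FALSE)
      sim <- similarity_report(labs, gr$mode_labels,
                               metric = config$validity$similarity)
      write.table(data.frame(participant_id = names(sim$to_group),
                             to_group = sim$to_group),
                  grp_files[5], sep = "\t", quote = FALSE, row.names = FALSE)
      fmt <- config$output$figure_format %||% "png"
      plot_similarity_dendrogram(
        sim, file.path(val_dir, sprintf("similarity_dendrogram_k%d.%s",
                                        k, fmt)))
      for (ref in config$data$reference_images) {
        cmp <- compare_reference(gr$mode_labels,
                                 read_label_image(ref, masks$roi),
                                 metric = config$validity$similarity)
        write.table(as.data.frame(cmp[c("similarity", "metric",
                                        "n_mismatch", "pct_mismatch",
                                        "n_voxels")]),
                    file.path(val_dir,
                              sprintf("reference_%s_k%d.tsv",
                                      tools::file_path_sans_ext(basename(ref)),
                                      k)),
                    sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
    mats <- lapply(participants, function(sid)
      read_dense_connectivity(conn_path(sid)))
    names(mats) <- participants
    vt <- validity_table(mats, setNames(list(labs), as.character(k)),
                         metrics = config$validity$internal)
    write.table(vt, grp_files[4], sep = "\t", quote = FALSE,
                row.names = FALSE)
    if (full_cohort) {
      state$completed[[key]] <- state$config_hash
      .write_state(project_dir, state)
    }
  }
  .rcbp_log("project run complete: ", project_dir)
  invisible(project_dir)
}
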