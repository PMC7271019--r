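# Tabular inputs: participants and confound tables (TSV).

#' Read the participants table
#'
#' A tab-separated file with a header row containing a `participant_id`
#' column. Extra columns are ignored; ids are returned in file order and
#' duplicates are rejected.
#'
#' @param path path to the TSV file.
#' @return Character vector of participant ids.
#' @export
read_participants <- function(path) {
  if (!file.exists(path)) stop("participants file not found: ", path)
  tab <- read.delim(path, sep = "\t", header = TRUE,
                    colClasses = "character", check.names = FALSE)
  if (!"participant_id" %in% names(tab))
    stop("participants file has no 'participant_id' column: ", path)
  ids <- tab[["participant_id"]]
  if (length(ids) == 0L) stop("participants file lists no subjects: ", path)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L)
    stop("duplicate participant_id: ", paste(unique(dup), collapse = ", "))
  ids
}

#' Write a participants table
#' @param ids character vector of participant ids.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_participants <- function(ids, path) {
  write.table(data.frame(participant_id = ids), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a confound table
#'
#' One column per confound regressor, one row per BOLD timepoint. Column
#' selection allows picking e.g. motion parameters out of a wider table.
#'
#' @param path path to the TSV file (header row required).
#' @param columns optional character vector of columns to keep.
#' @return Numeric matrix (timepoints x confounds) with column names.
#' @export
read_confounds <- function(path, columns = NULL) {
  if (!file.exists(path)) stop("confound file not found: ", path)
  tab <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE)
  if (!is.null(columns)) {
    missing <- setdiff(columns, names(tab))
    if (length(missing) > 0L)
      stop("confound columns not found: ", paste(missing, collapse = ", "))
    tab <- tab[, columns, drop = FALSE]
  }
  m <- as.matrix(tab)
  storage.mode(m) <- "double"
  m
}

#' Write a confound table
#' @param confounds numeric matrix with column names.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_confounds <- function(confounds, path) {
  write.table(as.data.frame(confounds), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
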