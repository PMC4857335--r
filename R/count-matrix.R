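#' Raw count container for an nCounter-style run
#'
#' Bundles a probes-by-lanes matrix of nonnegative integer counts with the
#' probe catalogue and per-lane metadata (binding density in spots/um^2,
#' fields of view counted and attempted, and the Gleason-pattern group
#' label when known).
#'
#' @param counts integer matrix, probes in rows (rownames = probe names),
#'   lanes in columns (colnames = lane ids).
#' @param codeset a [generate_codeset()] catalogue covering every row.
#' @param lane_meta data.frame with one row per lane: `lane_id`,
#'   `binding_density`, `fov_counted`, `fov_attempted`, `group`. Metadata
#'   fields other than `lane_id` may be `NA` (lanes are then unevaluable
#'   in QC, not silently passed).
#' @return An object of class `"count_matrix"`: a list with elements
#'   `counts`, `codeset`, `lane_meta`.
#' @export
count_matrix <- function(counts, codeset, lane_meta = NULL) {
  if (!is.matrix(counts)) stop_ctx("counts must be a matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop_ctx("counts must have probe rownames and lane colnames")
  }
  codeset <- validate_codeset(codeset)
  unknown <- setdiff(rownames(counts), codeset$probe_name)
  if (length(unknown)) {
    stop_ctx("probes absent from codeset: %s", paste(unknown, collapse = ", "))
  }
  neg <- which(counts < 0, arr.ind = TRUE)
  if (nrow(neg)) {
    stop_ctx("negative count at probe '%s', lane '%s'",
             rownames(counts)[neg[1, 1]], colnames(counts)[neg[1, 2]])
  }
  if (any(counts != round(counts))) stop_ctx("counts must be integers")
  storage.mode(counts) <- "double"
  if (anyDuplicated(colnames(counts))) {
    stop_ctx("duplicate lane IDs: %s",
             paste(unique(colnames(counts)[duplicated(colnames(counts))]),
                   collapse = ", "))
  }
  if (is.null(lane_meta)) {
    lane_meta <- data.frame(
      lane_id = colnames(counts), binding_density = NA_real_,
      fov_counted = NA_real_, fov_attempted = NA_real_,
      group = NA_character_, stringsAsFactors = FALSE
    )
  }
  req <- c("lane_id", "binding_density", "fov_counted", "fov_attempted", "group")
  miss <- setdiff(req, names(lane_meta))
  if (length(miss)) stop_ctx("lane_meta missing columns: %s", paste(miss, collapse = ", "))
  if (!setequal(lane_meta$lane_id, colnames(counts))) {
    stop_ctx("lane_meta lane_id set must match count columns")
  }
  lane_meta <- lane_meta[match(colnames(counts), lane_meta$lane_id), req]
  rownames(lane_meta) <- NULL
  bad_fov <- !is.na(lane_meta$fov_counted) & !is.na(lane_meta$fov_attempted) &
    lane_meta$fov_counted > lane_meta$fov_attempted
  if (any(bad_fov)) {
    stop_ctx("fov_counted exceeds fov_attempted in lane '%s'",
             lane_meta$lane_id[which(bad_fov)[1]])
  }
  structure(list(counts = counts, codeset = codeset, lane_meta = lane_meta),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cls <- table(x$codeset$probe_class[match(rownames(x$counts),
                                           x$codeset$probe_name)])
  cat(sprintf("count_matrix: %d probes x %d lanes\n",
              nrow(x$counts), ncol(x$counts)))
  cat("  probe classes:",
      paste(sprintf("%s=%d", names(cls), as.integer(cls)), collapse = ", "),
      "\n")
  grp <- table(x$lane_meta$group, useNA = "ifany")
  cat("  groups:",
      paste(sprintf("%s=%d", names(grp), as.integer(grp)), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

# Row indices of a probe class within a count_matrix.
probe_rows <- function(x, class) {
  cls <- x$codeset$probe_class[match(rownames(x$counts), x$codeset$probe_name)]
  which(cls == class)
}

#' Write a cohort as a CSV count table plus metadata and truth sidecars
#'
#' The tabular dialect is probes-as-rows, lanes-as-columns, with mandatory
#' `probe_name`, `probe_class`, `concentration` lead columns. Lane metadata
#' goes to a JSON sidecar; the ground-truth record (if supplied) to a
#' second JSON file.
#'
#' @param x a [count_matrix()].
#' @param path output CSV path; sidecar written to `<path>.meta.json`.
#' @param truth optional truth record from [simulate_cohort()], written to
#'   `<path>.truth.json`.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(x, path, truth = NULL) {
  stopifnot(inherits(x, "count_matrix"))
  idx <- match(rownames(x$counts), x$codeset$probe_name)
  df <- data.frame(
    probe_name = rownames(x$counts),
    probe_class = x$codeset$probe_class[idx],
    concentration = x$codeset$concentration[idx],
    x$counts, check.names = FALSE, stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(x$lane_meta, paste0(path, ".meta.json"),
                       dataframe = "rows", na = "null", digits = NA)
  if (!is.null(truth)) {
    jsonlite::write_json(truth, paste0(path, ".truth.json"),
                         auto_unbox = TRUE, na = "null", digits = NA)
  }
  invisible(path)
}

#' Write a cohort as per-lane RCC files
#'
#' Emits one Reporter Code Count (RCC) file per lane into `dir`, using the
#' platform's INI-like sectioned layout (`<Header>`, `<Lane_Attributes>`,
#' `<Code_Summary>` ...), for round-trip testing of the reader.
#'
#' @param x a [count_matrix()].
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_rcc_directory <- function(x, dir) {
  stopifnot(inherits(x, "count_matrix"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  idx <- match(rownames(x$counts), x$codeset$probe_name)
  code_class <- c(endogenous = "Endogenous", housekeeping = "Housekeeping",
                  positive = "Positive", negative = "Negative")
  cls <- code_class[x$codeset$probe_class[idx]]
  for (j in seq_len(ncol(x$counts))) {
    m <- x$lane_meta[j, ]
    lines <- c(
      "<Header>", "FileVersion,1.7", "SoftwareVersion,synthetic", "</Header>",
      "<Sample_Attributes>",
      sprintf("ID,%s", m$lane_id),
      sprintf("Owner,"),
      sprintf("Comments,group=%s", ifelse(is.na(m$group), "", m$group)),
      "</Sample_Attributes>",
      "<Lane_Attributes>",
      sprintf("ID,%d", j),
      sprintf("FovCount,%s", ifelse(is.na(m$fov_attempted), "",
                                    format(m$fov_attempted))),
      sprintf("FovCounted,%s", ifelse(is.na(m$fov_counted), "",
                                      format(m$fov_counted))),
      sprintf("BindingDensity,%s", ifelse(is.na(m$binding_density), "",
                                          format(m$binding_density))),
      "</Lane_Attributes>",
      "<Code_Summary>",
      "CodeClass,Name,Accession,Count",
      sprintf("%s,%s,NA,%d", cls, rownames(x$counts), as.integer(x$counts[, j])),
      "</Code_Summary>"
    )
    writeLines(lines, file.path(dir, sprintf("%s.RCC", m$lane_id)))
  }
  invisible(dir)
}
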