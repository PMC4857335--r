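#' Load nCounter count data from disk
#'
#' Two dialects are supported. `"rcc_directory"` reads every `*.RCC` file
#' (the platform's per-lane INI-like sectioned text) in a directory, one
#' lane each, parsing counts from `<Code_Summary>` and binding density /
#' fields of view from `<Lane_Attributes>`. `"count_table"` reads a CSV
#' written in the layout of [write_count_table()] — probes as rows, lanes
#' as columns, mandatory `probe_name`/`probe_class` lead columns — and
#' requires the `<path>.meta.json` lane-metadata sidecar.
#'
#' @param path directory of RCC files, or CSV path.
#' @param dialect `"rcc_directory"` or `"count_table"`.
#' @param codeset optional [generate_codeset()] catalogue to resolve probe
#'   classes against; when `NULL` the catalogue is reconstructed from the
#'   file's own class annotations.
#' @return A [count_matrix()].
#' @export
load_counts <- function(path, dialect = c("count_table", "rcc_directory"),
                        codeset = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_ctx("path does not exist: %s", path)
  switch(dialect,
         rcc_directory = read_rcc_directory(path, codeset),
         count_table = read_count_table(path, codeset))
}

read_count_table <- function(path, codeset = NULL) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  req <- c("probe_name", "probe_class")
  if (!all(req %in% names(df))) {
    stop_ctx("count table must carry columns %s", paste(req, collapse = ", "))
  }
  lead <- intersect(c("probe_name", "probe_class", "concentration"), names(df))
  lanes <- setdiff(names(df), lead)
  if (!length(lanes)) stop_ctx("count table has no lane columns")
  counts <- as.matrix(df[, lanes, drop = FALSE])
  rownames(counts) <- df$probe_name
  neg <- which(counts < 0, arr.ind = TRUE)
  if (nrow(neg)) {
    stop_ctx("negative count at probe '%s', lane '%s'",
             rownames(counts)[neg[1, 1]], colnames(counts)[neg[1, 2]])
  }
  if (is.null(codeset)) {
    codeset <- data.frame(
      probe_name = df$probe_name, probe_class = df$probe_class,
      concentration = if ("concentration" %in% names(df)) df$concentration
                      else NA_real_,
      stringsAsFactors = FALSE
    )
    class(codeset) <- c("codeset", "data.frame")
  }
  meta_path <- paste0(path, ".meta.json")
  if (!file.exists(meta_path)) {
    stop_ctx("count_table dialect requires the metadata sidecar %s", meta_path)
  }
  meta <- jsonlite::fromJSON(meta_path)
  for (col in c("binding_density", "fov_counted", "fov_attempted")) {
    if (!col %in% names(meta)) meta[[col]] <- NA_real_
    meta[[col]] <- as.numeric(meta[[col]])
  }
  if (!"group" %in% names(meta)) meta$group <- NA_character_
  count_matrix(counts, codeset, meta)
}

# Parse one RCC file into (lane metadata, named count vector, class vector).
parse_rcc <- function(file) {
  lines <- readLines(file, warn = FALSE)
  section <- function(name) {
    open <- grep(sprintf("^<%s>$", name), lines)
    close <- grep(sprintf("^</%s>$", name), lines)
    if (length(open) != 1L || length(close) != 1L || close <= open) {
      stop_ctx("unparseable RCC file (missing <%s> section): %s", name, file)
    }
    lines[(open + 1L):(close - 1L)]
  }
  kv <- function(block) {
    parts <- strsplit(block, ",", fixed = TRUE)
    stats::setNames(vapply(parts, function(p) if (length(p) > 1) p[2] else "",
                           character(1)),
                    vapply(parts, `[`, character(1), 1))
  }
  lane <- kv(section("Lane_Attributes"))
  samp <- kv(section("Sample_Attributes"))
  code <- section("Code_Summary")
  hdr <- strsplit(code[1], ",", fixed = TRUE)[[1]]
  need <- c("CodeClass", "Name", "Count")
  if (!all(need %in% hdr)) stop_ctx("unparseable RCC Code_Summary in %s", file)
  rows <- strsplit(code[-1], ",", fixed = TRUE)
  get <- function(col) vapply(rows, `[`, character(1), match(col, hdr))
  cnt <- suppressWarnings(as.numeric(get("Count")))
  if (anyNA(cnt)) stop_ctx("non-numeric count in RCC file %s", file)
  num_or_na <- function(x) {
    if (is.na(x) || !nzchar(x)) NA_real_ else as.numeric(x)
  }
  group <- NA_character_
  if (!is.na(samp["Comments"]) && grepl("^group=", samp["Comments"])) {
    g <- sub("^group=", "", samp["Comments"])
    if (nzchar(g)) group <- g
  }
  list(
    lane_id = unname(samp["ID"]),
    binding_density = num_or_na(lane["BindingDensity"]),
    fov_counted = num_or_na(lane["FovCounted"]),
    fov_attempted = num_or_na(lane["FovCount"]),
    group = group,
    counts = stats::setNames(cnt, get("Name")),
    probe_class = stats::setNames(tolower(get("CodeClass")), get("Name"))
  )
}

read_rcc_directory <- function(dir, codeset = NULL) {
  files <- list.files(dir, pattern = "\\.RCC$", full.names = TRUE,
                      ignore.case = TRUE)
  if (!length(files)) stop_ctx("no RCC files in %s", dir)
  lanes <- lapply(sort(files), parse_rcc)
  ids <- vapply(lanes, `[[`, character(1), "lane_id")
  if (anyDuplicated(ids)) {
    stop_ctx("duplicate lane IDs: %s",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  probes <- names(lanes[[1]]$counts)
  counts <- vapply(lanes, function(l) {
    if (!identical(names(l$counts), probes)) {
      stop_ctx("RCC lanes disagree on probe set (lane %s)", l$lane_id)
    }
    l$counts
  }, numeric(length(probes)))
  dimnames(counts) <- list(probes, ids)
  if (is.null(codeset)) {
    codeset <- data.frame(
      probe_name = probes,
      probe_class = unname(lanes[[1]]$probe_class[probes]),
      concentration = NA_real_, stringsAsFactors = FALSE
    )
    # recover the spiked ladder from probe names like POS_A(128)
    is_pos <- codeset$probe_class == "positive"
    conc <- suppressWarnings(as.numeric(sub("^.*\\(([^)]+)\\)$", "\\1",
                                            codeset$probe_name[is_pos])))
    codeset$concentration[is_pos] <- conc
    if (anyNA(conc)) {
      codeset$concentration[is_pos] <- c(128, 32, 8, 2, 0.5, 0.128)[
        seq_len(sum(is_pos))]
    }
    class(codeset) <- c("codeset", "data.frame")
  }
  meta <- data.frame(
    lane_id = ids,
    binding_density = vapply(lanes, `[[`, numeric(1), "binding_density"),
    fov_counted = vapply(lanes, `[[`, numeric(1), "fov_counted"),
    fov_attempted = vapply(lanes, `[[`, numeric(1), "fov_attempted"),
    group = vapply(lanes, `[[`, character(1), "group"),
    stringsAsFactors = FALSE
  )
  count_matrix(counts, codeset, meta)
}

#' Pre-normalization lane quality control
#'
#' A lane passes iff its binding density lies inside `bd_range`
#' (inclusive) and its ratio of fields of view counted to attempted is at
#' least `min_fov_ratio`. Lanes with missing metadata are flagged
#' `unevaluable`, never silently passed. The defaults are the platform's
#' recommended thresholds: binding density 0.05--2.25 spots/um^2, FOV
#' ratio 0.75. The stricter literal reading "counted/attempted >
#' 75/280" is available as `min_fov_ratio = 75/280`.
#'
#' @param x a [count_matrix()] with lane metadata.
#' @param bd_range length-2 numeric, inclusive binding-density interval.
#' @param min_fov_ratio minimum `fov_counted/fov_attempted`.
#' @return A `data.frame` of class `"qc_report"`: one row per lane with
#'   `pass`, `unevaluable`, per-criterion flags and a `reason` string.
#' @export
lane_qc <- function(x, bd_range = c(0.05, 2.25), min_fov_ratio = 0.75) {
  stopifnot(inherits(x, "count_matrix"))
  m <- x$lane_meta
  bd_ok <- !is.na(m$binding_density) &
    m$binding_density >= bd_range[1] & m$binding_density <= bd_range[2]
  fov_ratio <- m$fov_counted / m$fov_attempted
  fov_ok <- !is.na(fov_ratio) & fov_ratio >= min_fov_ratio
  unevaluable <- is.na(m$binding_density) | is.na(fov_ratio)
  reason <- character(nrow(m))
  reason[!bd_ok & !is.na(m$binding_density)] <- "binding density"
  fov_bad <- !fov_ok & !is.na(fov_ratio)
  reason[fov_bad] <- ifelse(nzchar(reason[fov_bad]),
                            paste(reason[fov_bad], "FOV", sep = "; "), "FOV")
  reason[unevaluable] <- "missing metadata"
  rep <- data.frame(
    lane_id = m$lane_id,
    binding_density = m$binding_density,
    fov_ratio = fov_ratio,
    bd_pass = bd_ok, fov_pass = fov_ok,
    unevaluable = unevaluable,
    pass = bd_ok & fov_ok,
    reason = reason, stringsAsFactors = FALSE
  )
  attr(rep, "thresholds") <- list(bd_range = bd_range,
                                  min_fov_ratio = min_fov_ratio)
  class(rep) <- c("qc_report", "data.frame")
  rep
}

#' @export
print.qc_report <- function(x, ...) {
  th <- attr(x, "thresholds")
  cat(sprintf("lane QC: %d/%d lanes pass (binding density in [%g, %g], FOV ratio >= %g)\n",
              sum(x$pass), nrow(x), th$bd_range[1], th$bd_range[2],
              th$min_fov_ratio))
  fail <- x[!x$pass, c("lane_id", "reason")]
  if (nrow(fail)) {
    for (i in seq_len(nrow(fail))) {
      cat(sprintf("  FAIL %s: %s\n", fail$lane_id[i], fail$reason[i]))
    }
  }
  invisible(x)
}
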