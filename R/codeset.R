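#' Build a NanoString-style probe catalogue
#'
#' Constructs a code set describing one probe per row: endogenous target
#' genes, housekeeping genes, six spiked-in positive controls on a
#' 128 to 0.128 fM concentration ladder, and eight synthetic negative
#' control sequences. The control complement is fixed; the endogenous and
#' housekeeping counts are the panel design choice.
#'
#' The positive ladder descends in 4-fold steps from 128 fM, ending at
#' 0.128 fM (the final step is therefore ~3.9-fold): 128, 32, 8, 2, 0.5,
#' 0.128 fM.
#'
#' @param n_endogenous number of endogenous target probes (default 102).
#' @param n_housekeeping number of housekeeping probes (default 5).
#' @return A `data.frame` of class `"codeset"` with columns `probe_name`,
#'   `probe_class` (one of `endogenous`, `housekeeping`, `positive`,
#'   `negative`) and `concentration` (fM, `NA` except for positives).
#' @examples
#' cs <- generate_codeset(102, 5)
#' table(cs$probe_class)
#' @export
generate_codeset <- function(n_endogenous = 102L, n_housekeeping = 5L) {
  n_endogenous <- as.integer(n_endogenous)
  n_housekeeping <- as.integer(n_housekeeping)
  if (is.na(n_endogenous) || n_endogenous < 0L) {
    stop_ctx("n_endogenous must be a nonnegative count")
  }
  if (is.na(n_housekeeping) || n_housekeeping < 0L) {
    stop_ctx("n_housekeeping must be a nonnegative count")
  }
  hk_pool <- c("ACTB", "CLTC", "GUSB", "HPRT1", "TUBB")
  hk <- if (n_housekeeping <= length(hk_pool)) {
    hk_pool[seq_len(n_housekeeping)]
  } else {
    c(hk_pool, sprintf("HK%02d", seq_len(n_housekeeping - length(hk_pool))))
  }
  pos_conc <- c(128, 32, 8, 2, 0.5, 0.128)
  cs <- data.frame(
    probe_name = c(
      if (n_endogenous > 0L) sprintf("GENE%03d", seq_len(n_endogenous)),
      hk,
      sprintf("POS_%s(%g)", LETTERS[1:6], pos_conc),
      sprintf("NEG_%s", LETTERS[1:8])
    ),
    probe_class = c(
      rep("endogenous", n_endogenous),
      rep("housekeeping", n_housekeeping),
      rep("positive", 6L),
      rep("negative", 8L)
    ),
    concentration = c(
      rep(NA_real_, n_endogenous + n_housekeeping),
      pos_conc,
      rep(NA_real_, 8L)
    ),
    stringsAsFactors = FALSE
  )
  class(cs) <- c("codeset", "data.frame")
  validate_codeset(cs)
}

#' @rdname generate_codeset
#' @param codeset object to validate.
#' @export
validate_codeset <- function(codeset) {
  req <- c("probe_name", "probe_class", "concentration")
  if (!all(req %in% names(codeset))) {
    stop_ctx("codeset must have columns: %s", paste(req, collapse = ", "))
  }
  if (anyDuplicated(codeset$probe_name)) {
    stop_ctx("duplicate probe names: %s",
             paste(unique(codeset$probe_name[duplicated(codeset$probe_name)]),
                   collapse = ", "))
  }
  ok <- c("endogenous", "housekeeping", "positive", "negative")
  bad <- setdiff(unique(codeset$probe_class), ok)
  if (length(bad)) stop_ctx("unknown probe classes: %s", paste(bad, collapse = ", "))
  pos <- codeset$concentration[codeset$probe_class == "positive"]
  if (anyNA(pos) || any(diff(pos) >= 0)) {
    stop_ctx("positive probes must carry strictly decreasing concentrations")
  }
  if (!inherits(codeset, "codeset")) class(codeset) <- c("codeset", class(codeset))
  codeset
}
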