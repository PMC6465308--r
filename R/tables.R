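# Delimited-text tables and the shooting ledger. All pipeline tables are
# TSV with a header line; parsing is locale-independent (C numeric format).

#' Write a pipeline table
#'
#' @param df data.frame.
#' @param path output file.
#' @param digits significant digits for numeric columns (default 17 keeps
#'   doubles lossless).
#' @return `path`, invisibly.
#' @export
write_table_tsv <- function(df, path, digits = 17) {
  out <- df
  for (j in seq_along(out))
    if (is.numeric(out[[j]]) && !is.integer(out[[j]]))
      out[[j]] <- formatC(out[[j]], digits = digits, format = "g")
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a pipeline table, checking its schema
#'
#' @param path TSV file with header.
#' @param required character vector of required column names.
#' @return data.frame with typed columns.
#' @export
read_table_tsv <- function(path, required = character(0)) {
  if (!file.exists(path)) stop("missing table file: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0)
    stop("schema error: missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  df
}

#' Append shooting events to a ledger
#'
#' The ledger is an append-only TSV of shooting events. Rows are never
#' rewritten; `point_id` + `seed` pairs must be unique.
#'
#' @param events data.frame with columns `point_id`, `seed`, `outcome`,
#'   `steps` (and optionally `path_id`).
#' @param path ledger file; created with a header if absent.
#' @return `path`, invisibly.
#' @export
ledger_append <- function(events, path) {
  req <- c("point_id", "seed", "outcome", "steps")
  if (!all(req %in% names(events)))
    stop("schema error: ledger events need columns ",
         paste(req, collapse = ", "))
  if (!"path_id" %in% names(events)) events$path_id <- NA_character_
  events <- events[, c(req, "path_id")]
  new <- !file.exists(path)
  if (!new) {
    old <- ledger_read(path)
    key <- paste(c(old$point_id, events$point_id),
                 c(old$seed, events$seed))
    if (anyDuplicated(key))
      stop("uniqueness error: duplicate point_id + seed in ledger")
  } else if (anyDuplicated(paste(events$point_id, events$seed))) {
    stop("uniqueness error: duplicate point_id + seed in ledger")
  }
  utils::write.table(events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = new, append = !new)
  invisible(path)
}

#' Read a shooting ledger
#'
#' @param path ledger TSV.
#' @return data.frame of events; errors if `point_id` + `seed` pairs are
#'   duplicated.
#' @export
ledger_read <- function(path) {
  df <- read_table_tsv(path, required = c("point_id", "seed", "outcome",
                                          "steps"))
  if (anyDuplicated(paste(df$point_id, df$seed)))
    stop("uniqueness error: duplicate point_id + seed in ledger")
  df
}

#' Serialize an RC model to a key-value text file
#'
#' Human-readable `key<TAB>value` lines; numeric values at full double
#' precision so the file round-trips losslessly.
#'
#' @param model an [rc_model()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_rc_model <- function(model, path) {
  num <- function(x) paste(formatC(x, digits = 17, format = "g"),
                           collapse = ",")
  lines <- c(
    paste0("descriptors\t", paste(model$descriptors, collapse = ",")),
    paste0("coefficients\t", num(model$coefficients)),
    paste0("center\t", num(model$center)),
    paste0("scale\t", num(model$scale))
  )
  if (!is.null(model$uncertainties))
    lines <- c(lines, paste0("uncertainties\t", num(model$uncertainties)))
  writeLines(lines, path)
  invisible(path)
}

#' Read an RC model written by [write_rc_model()]
#'
#' @param path model file.
#' @return an [rc_model()].
#' @export
read_rc_model <- function(path) {
  if (!file.exists(path)) stop("missing model file: ", path)
  lines <- readLines(path)
  kv <- strsplit(lines, "\t", fixed = TRUE)
  keys <- vapply(kv, `[[`, "", 1L)
  val <- function(key, numeric = TRUE) {
    i <- match(key, keys)
    if (is.na(i)) return(NULL)
    parts <- strsplit(kv[[i]][2], ",", fixed = TRUE)[[1]]
    if (numeric) as.numeric(parts) else parts
  }
  for (req in c("descriptors", "coefficients", "center", "scale"))
    if (is.na(match(req, keys)))
      stop("schema error: missing required key: ", req)
  rc_model(val("coefficients"), val("descriptors", numeric = FALSE),
           val("center"), val("scale"), uncertainties = val("uncertainties"))
}
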