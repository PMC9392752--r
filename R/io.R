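#' Write session and group outputs
#'
#' Writers for the package's plain-text interchange formats.  Every file
#' starts with `#`-prefixed provenance lines recording the parameters and
#' seed that produced it.  Existing files are only replaced when
#' `overwrite = TRUE`.
#'
#' `wcst_write_session()` writes the tab-separated trial log
#' (`<stem>_trials.tsv`), the tab-separated working-memory trace
#' (`<stem>_trace.tsv`) and the profile as JSON (`<stem>_profile.json`).
#' `wcst_write_group()` writes the per-session profiles
#' (`<stem>_profiles.csv`) and the group summary (`<stem>_summary.json`).
#'
#' @param x A [wcst_session()] or [wcst_simulate_group()] object.
#' @param stem Output path prefix (directories must exist).
#' @param overwrite Replace existing files?
#' @return The paths written, invisibly.
#' @name wcst-io
NULL

provenance <- function(x) {
  p <- x$params
  c(sprintf("# wcstsim %s", as.character(utils::packageVersion("wcstsim"))),
    sprintf("# params: mu=%g phi=%g tau=%g lam=%g",
            p[["mu"]], p[["phi"]], p[["tau"]], p[["lam"]]),
    sprintf("# seed: %s", if (is.null(x$seed)) "NA" else x$seed))
}

check_paths <- function(paths, overwrite) {
  exists <- file.exists(paths)
  if (any(exists) && !overwrite)
    stop("refusing to overwrite: ", paste(paths[exists], collapse = ", "),
         " (use overwrite = TRUE)")
}

write_tsv_with_header <- function(df, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname wcst-io
#' @export
wcst_write_session <- function(x, stem, overwrite = FALSE) {
  stopifnot(inherits(x, "wcst_session"))
  paths <- paste0(stem, c("_trials.tsv", "_trace.tsv", "_profile.json"))
  check_paths(paths, overwrite)
  hdr <- provenance(x)
  write_tsv_with_header(x$trials, paths[1], hdr)
  trace <- data.frame(trial = seq_len(nrow(x$trace)),
                      priority_colour = x$trace[, "colour"],
                      priority_shape = x$trace[, "shape"],
                      priority_size = x$trace[, "size"],
                      selected_rule = x$trials$selected_rule,
                      feedback = x$trials$feedback,
                      classification = x$trials$classification)
  write_tsv_with_header(trace, paths[2], hdr)
  jsonlite::write_json(as.list(x$profile), paths[3], auto_unbox = TRUE)
  invisible(paths)
}

#' @rdname wcst-io
#' @export
wcst_write_group <- function(x, stem, overwrite = FALSE) {
  stopifnot(inherits(x, "wcst_group"))
  paths <- paste0(stem, c("_profiles.csv", "_summary.json"))
  check_paths(paths, overwrite)
  con <- file(paths[1], "w")
  writeLines(provenance(x), con)
  write.csv(as.data.frame(x$profiles), con, row.names = FALSE, quote = FALSE)
  close(con)
  s <- summary(x)
  jsonlite::write_json(
    list(params = as.list(unclass(x$params)), seed = x$seed, n = s$n,
         mean = as.list(s$mean), sd = as.list(s$sd)),
    paths[2], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Read a fitting target
#'
#' Reads a group behavioural profile from CSV (columns `index`, `mean`, `sd`,
#' `n`; one row per index, `#` comment lines allowed) or from JSON (an object
#' with `mean`, `sd` and `n` fields as written by [wcst_write_group()]).
#'
#' @param path File path; format inferred from the `.json` / `.csv`
#'   extension.
#' @return A [wcst_group_profile()].
#' @export
wcst_read_target <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (!all(c("mean", "n") %in% names(x)))
      stop("JSON target must contain 'mean' and 'n' fields")
    return(wcst_group_profile(x$mean, x$sd, x$n))
  }
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  missing <- setdiff(c("index", "mean"), names(df))
  if (length(missing))
    stop("target file lacks column(s): ", paste(missing, collapse = ", "))
  mean <- stats::setNames(df$mean, df$index)
  sdv <- if ("sd" %in% names(df)) stats::setNames(df$sd, df$index) else NULL
  n <- if ("n" %in% names(df)) df$n[1] else 1L
  wcst_group_profile(mean, sdv, n)
}
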