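#' ADME screening criteria
#'
#' Bundles the three-property absorption/drug-likeness rule used to decide
#' which candidate herb compounds are orally absorbable and biologically
#' active: oral bioavailability (OB, percent, inclusive lower bound),
#' Caco-2 permeability (log-scale, strict lower bound) and drug-likeness
#' (DL, dimensionless in \[0,1\], inclusive lower bound). The defaults are
#' the standard TCMSP screening thresholds OB >= 30, Caco-2 > -0.4,
#' DL >= 0.18.
#'
#' @param ob_min Minimum oral bioavailability in percent (inclusive).
#' @param caco2_min Caco-2 permeability lower bound (exclusive: a compound
#'   at exactly this value fails).
#' @param dl_min Minimum drug-likeness index (inclusive).
#' @return An object of class `screen_criteria`.
#' @examples
#' screen_criteria()               # the standard 30 / -0.4 / 0.18 rule
#' screen_criteria(ob_min = 40)    # a stricter bioavailability cut
#' @export
screen_criteria <- function(ob_min = 30, caco2_min = -0.4, dl_min = 0.18) {
  for (v in list(ob_min, caco2_min, dl_min)) {
    if (!is_number(v)) stop("screen criteria bounds must be finite numbers")
  }
  structure(
    list(ob_min = ob_min, caco2_min = caco2_min, dl_min = dl_min),
    class = "screen_criteria"
  )
}

#' @export
print.screen_criteria <- function(x, ...) {
  cat(sprintf("ADME screen: OB >= %g%%, Caco-2 > %g, DL >= %g\n",
              x$ob_min, x$caco2_min, x$dl_min))
  invisible(x)
}

#' Screen candidate compounds by ADME properties
#'
#' Partitions a candidate-compound table into three disjoint groups:
#' `passed` (non-whitelist rows meeting all three criteria), `whitelisted`
#' (literature-supported rows kept regardless of their properties) and
#' `rejected` (everything else, with a reason code). The candidate set for
#' all downstream stages is `passed` plus `whitelisted`.
#'
#' A non-whitelist row with a missing OB, Caco-2 or DL value is rejected
#' with reason `"missing_property"`; it is never allowed to pass silently.
#'
#' @param compounds Data frame with columns `compound_id`, `name`, `herbs`
#'   (semicolon-separated herb labels), `ob`, `caco2`, `dl`, `whitelist`
#'   (logical). See [read_compound_table()].
#' @param criteria A [screen_criteria()] object.
#' @return An object of class `compound_screen`: a list with data-frame
#'   elements `passed`, `whitelisted`, `rejected` (each carrying `status`
#'   and `reason` columns) and the `criteria` used. `candidates()` extracts
#'   the combined downstream set.
#' @examples
#' tbl <- data.frame(
#'   compound_id = c("c1", "c2", "c3"), name = c("a", "b", "c"),
#'   herbs = "HQ", ob = c(35, 10, 50), caco2 = c(0.2, 0.5, -0.8),
#'   dl = c(0.3, 0.4, 0.2), whitelist = c(FALSE, FALSE, TRUE)
#' )
#' scr <- screen_compounds(tbl)
#' nrow(scr$passed); nrow(scr$whitelisted); nrow(scr$rejected)
#' @export
screen_compounds <- function(compounds, criteria = screen_criteria()) {
  if (!is.data.frame(compounds) || nrow(compounds) == 0) {
    stop("compound table must be a non-empty data frame")
  }
  if (!inherits(criteria, "screen_criteria")) {
    stop("`criteria` must be a screen_criteria object")
  }
  required <- c("compound_id", "ob", "caco2", "dl", "whitelist")
  missing_cols <- setdiff(required, names(compounds))
  if (length(missing_cols)) {
    stop("compound table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(compounds$compound_id)) {
    stop("duplicate compound_id values are an input error")
  }
  if (!"name" %in% names(compounds)) compounds$name <- compounds$compound_id
  if (!"herbs" %in% names(compounds)) compounds$herbs <- NA_character_

  wl <- compounds$whitelist %in% TRUE

  has_all <- !(is.na(compounds$ob) | is.na(compounds$caco2) | is.na(compounds$dl))
  meets <- has_all &
    compounds$ob >= criteria$ob_min &
    compounds$caco2 > criteria$caco2_min &
    compounds$dl >= criteria$dl_min

  status <- ifelse(wl, "whitelisted", ifelse(meets, "passed", "rejected"))
  reason <- rep("", nrow(compounds))
  reason[wl] <- "literature_whitelist"
  fail <- !wl & !meets
  reason[fail & !has_all] <- "missing_property"
  add <- function(rr, ok, tag) {
    i <- fail & has_all & !ok
    rr[i] <- ifelse(nzchar(rr[i]), paste(rr[i], tag, sep = "+"), tag)
    rr
  }
  rr <- character(nrow(compounds))
  rr <- add(rr, compounds$ob >= criteria$ob_min, "ob")
  rr <- add(rr, compounds$caco2 > criteria$caco2_min, "caco2")
  rr <- add(rr, compounds$dl >= criteria$dl_min, "dl")
  reason[fail & has_all] <- paste0("below_threshold:", rr[fail & has_all])

  compounds$status <- status
  compounds$reason <- reason
  out <- structure(
    list(
      passed = compounds[status == "passed", , drop = FALSE],
      whitelisted = compounds[status == "whitelisted", , drop = FALSE],
      rejected = compounds[status == "rejected", , drop = FALSE],
      criteria = criteria
    ),
    class = "compound_screen"
  )
  out
}

#' @export
print.compound_screen <- function(x, ...) {
  cat("Compound ADME screen\n")
  print(x$criteria)
  cat(sprintf("  passed: %d   whitelisted: %d   rejected: %d\n",
              nrow(x$passed), nrow(x$whitelisted), nrow(x$rejected)))
  invisible(x)
}

#' Downstream candidate set of a compound screen
#'
#' @param screen A `compound_screen` object.
#' @return Data frame of passed plus whitelisted compounds.
#' @export
candidates <- function(screen) {
  stopifnot(inherits(screen, "compound_screen"))
  rbind(screen$passed, screen$whitelisted)
}

#' Read a candidate-compound table
#'
#' Reads a tab- or comma-separated table with a one-line header. Column
#' names are configurable so exports from different compound databases can
#' be consumed without editing the file.
#'
#' @param path File path.
#' @param sep Field separator; `NULL` (default) auto-detects tab vs comma
#'   from the header line.
#' @param columns Named character vector mapping the canonical names
#'   (`compound_id`, `name`, `herbs`, `ob`, `caco2`, `dl`, `whitelist`) to
#'   the file's column names.
#' @return Data frame with the canonical columns; `herbs` stays a
#'   semicolon-separated string, `whitelist` is logical.
#' @export
read_compound_table <- function(path, sep = NULL,
                                columns = c(compound_id = "compound_id",
                                            name = "name", herbs = "herbs",
                                            ob = "ob", caco2 = "caco2",
                                            dl = "dl", whitelist = "whitelist")) {
  if (is.null(sep)) {
    hdr <- readLines(path, n = 1L)
    sep <- if (grepl("\t", hdr)) "\t" else ","
  }
  raw <- read.delim(path, sep = sep, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("compound_id", "ob", "caco2", "dl", "whitelist")
  miss <- setdiff(columns[need], names(raw))
  if (length(miss)) stop("compound table lacks columns: ", paste(miss, collapse = ", "))
  out <- data.frame(compound_id = as.character(raw[[columns[["compound_id"]]]]),
                    stringsAsFactors = FALSE)
  out$name <- if (columns[["name"]] %in% names(raw)) {
    as.character(raw[[columns[["name"]]]])
  } else out$compound_id
  out$herbs <- if (columns[["herbs"]] %in% names(raw)) {
    as.character(raw[[columns[["herbs"]]]])
  } else NA_character_
  for (f in c("ob", "caco2", "dl")) {
    out[[f]] <- suppressWarnings(as.numeric(raw[[columns[[f]]]]))
  }
  wl <- raw[[columns[["whitelist"]]]]
  out$whitelist <- if (is.logical(wl)) wl else {
    tolower(trimws(as.character(wl))) %in% c("true", "t", "1", "yes")
  }
  out
}

#' Write screen results as one table with status and reason columns
#'
#' @param screen A `compound_screen` object.
#' @param path Output file path (tab-separated).
#' @return The combined data frame, invisibly.
#' @export
write_screen_table <- function(screen, path) {
  stopifnot(inherits(screen, "compound_screen"))
  all_rows <- rbind(screen$passed, screen$whitelisted, screen$rejected)
  write.table(all_rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(all_rows)
}

#' Herb membership map of a compound table
#'
#' Splits the semicolon-separated `herbs` column into a named list keyed
#' by `compound_id`, the form [assemble_target_sets()] expects.
#'
#' @param compounds Data frame with `compound_id` and `herbs` columns.
#' @return Named list of herb-label character vectors.
#' @export
herb_map <- function(compounds) {
  labs <- strsplit(ifelse(is.na(compounds$herbs), "", compounds$herbs), ";")
  setNames(lapply(labs, function(x) unique(trimws(x[nzchar(trimws(x))]))),
           compounds$compound_id)
}
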