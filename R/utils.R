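#' @importFrom stats phyper p.adjust runif rbinom setNames
#' @importFrom utils read.delim write.table packageVersion
NULL

# Uppercase + trim a character vector of gene symbols; drops NA-producing blanks.
norm_symbols <- function(x) {
  x <- toupper(trimws(as.character(x)))
  x[nzchar(x)]
}

# Stop with a stage-prefixed message (pipeline contract: errors name their stage).
stage_stop <- function(stage, ...) {
  stop(sprintf("%s: %s", stage, paste0(...)), call. = FALSE)
}

is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

is_count <- function(x) is_number(x) && x == as.integer(x) && x >= 0
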