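#' @importFrom stats predict rnbinom runif sd setNames na.omit
#' @importFrom utils head
#' @importFrom methods as
NULL

# Reserved output label for cells rejected by the probability threshold.
# Never allowed as a training label.
UNCLASSIFIED <- "Unclassified"

#' Control progress messages emitted by cellcascade
#'
#' @param verbose logical; `TRUE` enables progress messages for the current
#'   session, `FALSE` silences them. Missing leaves the setting unchanged.
#' @return the current (possibly updated) setting, invisibly.
#' @export
cc_verbose <- function(verbose) {
  if (!missing(verbose)) {
    options(cellcascade.verbose = isTRUE(verbose))
  }
  invisible(getOption("cellcascade.verbose", FALSE))
}

cc_msg <- function(...) {
  if (isTRUE(getOption("cellcascade.verbose", FALSE))) {
    message("[cellcascade] ", ...)
  }
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Path-safe identifier used for per-layer filenames and standalone loading.
sanitize_id <- function(x) gsub("[^A-Za-z0-9._-]+", "-", x)

# Deterministic child seed derived from a base seed; stays well inside
# 32-bit integer range.
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 7919 + k * 104729) %% 2147483629L)
}
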