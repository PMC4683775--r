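# Internal helpers shared across modules.

ose_abort <- function(message, class, ...) {
  stop(errorCondition(message, ..., class = c(class, "studyframes_error", "error")))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Optional scalar read from parsed JSON: empty values ({} / [] / null) -> NULL.
json_opt <- function(x) if (length(x)) x else NULL

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

is_number <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x)

# Evaluate `code` under a fixed seed without disturbing the caller's RNG state.
with_preserved_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

ose_log <- function(...) {
  if (isTRUE(getOption("studyframes.verbose", FALSE))) {
    message(...)
  }
  invisible(NULL)
}

# Natural sort for ids of the form "<prefix>-<n>": by numeric suffix, then text.
sort_ids <- function(ids) {
  if (length(ids) == 0L) return(character())
  suffix <- suppressWarnings(as.integer(sub("^.*-", "", ids)))
  ids[order(is.na(suffix), suffix, ids)]
}
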