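#' Derive a stage-specific seed from a master seed
#'
#' Deterministically maps a master seed and a stream name to a derived seed
#' in [1, 2^31 - 2], so pipeline stages (simulation, fitting, projection,
#' benchmarking) consume independent, individually re-runnable random
#' streams from one user-supplied seed.
#'
#' @param seed integer master seed
#' @param stream character stream name, e.g. "fit" or "project"
#' @return a single integer seed
#' @examples
#' deriveSeed(1, "fit")
#' deriveSeed(1, "project")
#' @export
deriveSeed <- function(seed, stream) {
  stopifnot(length(seed) == 1L, is.finite(seed), is.character(stream),
            length(stream) == 1L, nzchar(stream))
  h <- 0
  for (ch in utf8ToInt(stream)) h <- (h * 131 + ch) %% 1000003
  as.integer(((abs(as.numeric(seed)) %% 97651) * 20011 + h * 7919 + 1) %%
               2147483646 + 1)
}

## Shared column schema of long-format incidence tables.
.REC_FIELDS <- c("location", "sex", "year", "age_group", "cases",
                 "person_years")
.SEX_LEVELS <- c("both", "male", "female")

## stop() with a compact multi-line detail block
.fail <- function(msg, details = NULL) {
  if (!is.null(details) && length(details))
    msg <- paste0(msg, "\n  ", paste(head(details, 20L), collapse = "\n  "),
                  if (length(details) > 20L)
                    sprintf("\n  ... and %d more", length(details) - 20L))
  stop(msg, call. = FALSE)
}
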