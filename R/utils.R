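# Internal constants and helpers shared across modules.

EARTH_RADIUS_KM <- 6371
KM_PER_DEG <- pi * EARTH_RADIUS_KM / 180  # meridional km per degree, ~111.195

#' Derive a reproducible child seed from a master seed and labels
#'
#' Hashes a master integer seed together with an arbitrary sequence of
#' string/numeric labels into a stable 31-bit integer. Used to fan a single
#' master seed out into independent named streams (background sampling,
#' occurrence synthesis, kernel draws, bootstrap) so that any stage can be
#' rerun in isolation with the same draws.
#'
#' @param seed Integer master seed.
#' @param ... Labels (character or numeric) identifying the stream.
#' @return A single integer in \code{[1, 2^31 - 2]}.
#' @export
#' @examples
#' deriveSeed(42, "background", "RCP4.5-like")
deriveSeed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  m <- 2147483647  # 2^31 - 1, prime
  h <- as.numeric(seed) %% m
  labels <- unlist(lapply(list(...), as.character), use.names = FALSE)
  for (lab in labels) {
    for (code in utf8ToInt(lab)) {
      h <- (h * 31 + code) %% m
    }
    h <- (h * 37 + 17) %% m
  }
  as.integer(h %% (m - 2) + 1)
}

# set.seed wrapper that tolerates NULL (no seeding)
.maybeSeed <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
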