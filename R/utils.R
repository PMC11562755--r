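#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible child seed
#'
#' Deterministically derives a secondary seed from a master seed, so that the
#' independent random stages of a simulation (placement, injury, labelling,
#' sectioning) each get their own stream while the whole run stays a function
#' of one integer. Result is always a valid 32-bit integer seed.
#'
#' @param seed master integer seed.
#' @param k stream index (any integer).
#' @return an integer seed.
#' @export
derive_seed <- function(seed, k) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.numeric(k), length(k) == 1)
  as.integer((abs(seed) * 69069 + 12345 * k + 1) %% .Machine$integer.max)
}

#' Test neurons for a label
#'
#' Labels are stored as a semicolon-joined string per neuron (e.g.
#' `"GFP;FB"`). Returns a logical vector.
#'
#' @param labels character vector of semicolon-joined label sets.
#' @param label single label name.
#' @return logical vector.
#' @export
has_label <- function(labels, label) {
  stopifnot(is.character(label), length(label) == 1)
  grepl(paste0("(^|;)", label, "(;|$)"), labels)
}

add_label <- function(labels, add) {
  ifelse(nzchar(labels), paste(labels, add, sep = ";"), add)
}

# sum-to-one check used for composition and territory fractions
check_fractions <- function(fr, what = "fractions", tol = 1e-9) {
  if (any(fr < 0)) stop(what, " must be non-negative", call. = FALSE)
  if (abs(sum(fr) - 1) > tol)
    stop(what, " must sum to 1 (got ", format(sum(fr), digits = 12), ")",
         call. = FALSE)
  invisible(TRUE)
}

check_prob <- function(p, what) {
  if (!is.numeric(p) || any(is.na(p)) || any(p < 0) || any(p > 1))
    stop(what, " must be a probability in [0, 1]", call. = FALSE)
  invisible(TRUE)
}
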