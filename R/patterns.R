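#' The six scoreable RIP patterns
#'
#' Respiratory inductive plethysmography (RIP) records are scored on a
#' sample-by-sample basis into six mutually exclusive patterns:
#' synchronous-breathing (`SYB`, ribcage and abdomen less than 90 degrees out
#' of phase), asynchronous-breathing (`ASB`, 90 degrees or more),
#' sigh (`SIH`), respiratory pause (`PAU`), movement artifact (`MVT`) and
#' unknown (`UNK`). The sentinel `"NONE"` marks unscored or no-consensus
#' samples and is never itself a scoreable category.
#'
#' @return Character vector of the six pattern codes, in canonical order.
#' @examples
#' rip_patterns()
#' @export
rip_patterns <- function() {
  c("SYB", "ASB", "SIH", "PAU", "MVT", "UNK")
}

#' @rdname rip_patterns
#' @export
rip_none <- function() "NONE"

# validate a vector of labels; NONE allowed only when allow_none = TRUE
assert_patterns <- function(x, allow_none = FALSE, what = "pattern") {
  ok <- rip_patterns()
  if (allow_none) ok <- c(ok, rip_none())
  bad <- setdiff(unique(as.character(x)), ok)
  if (length(bad) > 0L) {
    stop(sprintf("invalid %s code(s): %s", what,
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  invisible(as.character(x))
}

#' Interpretation band for a kappa value
#'
#' Maps a chance-corrected agreement coefficient to the conventional verbal
#' interpretation bands: kappa < 0 "poor", 0 <= kappa <= 0.2 "slight",
#' 0.2 < kappa <= 0.4 "fair", 0.4 < kappa <= 0.6 "moderate",
#' 0.6 < kappa <= 0.8 "substantial" and 0.8 < kappa <= 1 "almost perfect".
#' Upper bounds are closed, so `kappa_band(0.8)` is `"substantial"`.
#'
#' @param kappa Numeric scalar (or vector) in `[-1, 1]`.
#' @return Character vector of band labels.
#' @examples
#' kappa_band(c(-0.1, 0, 0.2, 0.41, 0.8, 0.81))
#' @export
kappa_band <- function(kappa) {
  if (any(!is.finite(kappa)) || any(kappa < -1) || any(kappa > 1)) {
    stop("kappa must lie in [-1, 1]", call. = FALSE)
  }
  vapply(kappa, function(k) {
    if (k < 0) "poor"
    else if (k <= 0.2) "slight"
    else if (k <= 0.4) "fair"
    else if (k <= 0.6) "moderate"
    else if (k <= 0.8) "substantial"
    else "almost perfect"
  }, character(1))
}
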