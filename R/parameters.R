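#' Rate constants for the HipBA toxin-antitoxin circuit
#'
#' Constructs the set of 17 mass-action rate constants governing the hipBA
#' operon: transcription from the three promoter states, promoter
#' binding/unbinding of the HipB dimer (B2) and the toxin-antitoxin complex
#' (AB2A), translation of HipB and HipA, HipB dimerization, complex
#' association/dissociation, and first-order degradation of all free species.
#' Each constant carries a nominal value and a tested (low, high) range used
#' by the log-normal parameter scans; the default ranges span a factor of 10
#' either side of the nominal.
#'
#' All amounts are molecule counts per cell; second- and third-order
#' constants are per molecule (per molecule squared for complex association).
#' Time is in hours.
#'
#' @param ... named overrides of nominal values, e.g. `delta_A = 2.4`.
#'   Unknown names and non-positive values are rejected.
#' @param ranges optional named list of length-2 numeric vectors overriding
#'   the tested range of individual constants.
#'
#' @return An object of class `hipba_params`: a list with elements
#'   `value` (named numeric vector of length 17) and `range` (17 x 2 matrix
#'   with columns `low`, `high`).
#'
#' @examples
#' p <- hipba_params()
#' p$value[["alpha"]]        # 60 transcripts/hour from the free promoter
#' hipba_params(delta_A = 2.4)$value[["delta_A"]]
#' @export
hipba_params <- function(..., ranges = NULL) {
  value <- c(
    alpha      = 60,   # transcription from free promoter P, hr^-1
    alpha_B2   = 6,    # transcription from B2-bound promoter P', hr^-1
    alpha_AB2A = 6,    # transcription from AB2A-bound promoter P'', hr^-1
    theta_B2   = 1500, # B2 binds promoter, hr^-1 molecule^-1
    gamma_B2   = 60,   # B2 unbinds, hr^-1
    theta_AB2A = 1500, # AB2A binds promoter, hr^-1 molecule^-1
    gamma_AB2A = 60,   # AB2A unbinds, hr^-1
    delta_M    = 6,    # mRNA degradation, hr^-1
    beta_B     = 60,   # HipB translation, molecules hr^-1 mRNA^-1
    beta_A     = 12,   # HipA translation, molecules hr^-1 mRNA^-1
    delta_B    = 18,   # HipB degradation, hr^-1 (labile antitoxin)
    delta_A    = 1.2,  # HipA degradation, hr^-1 (stable toxin)
    beta_B2    = 60,   # HipB dimerization, hr^-1 molecule^-1 (irreversible)
    delta_B2   = 5,    # HipB dimer degradation, hr^-1
    mu         = 60,   # complex association B2 + 2A -> AB2A, hr^-1 molecule^-2
    mu_R       = 60,   # complex dissociation AB2A -> B2 + 2A, hr^-1
    delta_AB2A = 1.2   # complex degradation, hr^-1
  )
  range <- cbind(low = value / 10, high = value * 10)
  rownames(range) <- names(value)

  overrides <- list(...)
  if (length(overrides)) {
    if (is.null(names(overrides)) || any(!nzchar(names(overrides))))
      stop("parameter overrides must be named", call. = FALSE)
    bad <- setdiff(names(overrides), names(value))
    if (length(bad))
      stop("unknown parameter name(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    vals <- vapply(overrides, function(v) as.numeric(v)[1], numeric(1))
    if (any(!is.finite(vals)) || any(vals <= 0))
      stop("parameter values must be finite and strictly positive; offending: ",
           paste(names(vals)[!is.finite(vals) | vals <= 0], collapse = ", "),
           call. = FALSE)
    value[names(vals)] <- vals
    # keep ranges bracketing overridden nominals
    range[names(vals), "low"] <- pmin(range[names(vals), "low"], vals)
    range[names(vals), "high"] <- pmax(range[names(vals), "high"], vals)
  }
  if (!is.null(ranges)) {
    bad <- setdiff(names(ranges), names(value))
    if (length(bad))
      stop("unknown parameter name(s) in ranges: ",
           paste(bad, collapse = ", "), call. = FALSE)
    for (nm in names(ranges)) {
      r <- as.numeric(ranges[[nm]])
      if (length(r) != 2L || any(!is.finite(r)) || r[1] <= 0 || r[1] > r[2])
        stop("range for ", nm, " must be two positive values low <= high",
             call. = FALSE)
      range[nm, ] <- r
    }
  }
  bad <- range[, "low"] > value | value > range[, "high"]
  if (any(bad))
    stop("range must bracket the nominal value for: ",
         paste(names(value)[bad], collapse = ", "), call. = FALSE)

  structure(list(value = value, range = range), class = "hipba_params")
}

#' @export
print.hipba_params <- function(x, ...) {
  cat("HipBA rate constants (", length(x$value), " parameters)\n", sep = "")
  df <- data.frame(value = x$value,
                   low = x$range[, "low"], high = x$range[, "high"])
  print(df, ...)
  invisible(x)
}

# internal: validate an object claiming to be hipba_params
assert_params <- function(params) {
  if (!inherits(params, "hipba_params"))
    stop("`params` must be created by hipba_params()", call. = FALSE)
  invisible(params)
}

#' Names of the HipBA rate constants, in canonical order
#'
#' @return Character vector of the 17 parameter names, in the order the
#'   single-parameter scan iterates them.
#' @export
hipba_param_names <- function() names(hipba_params()$value)
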