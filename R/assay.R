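#' @include AllGenerics.R
NULL

#' HTRF fold-ratio presets for specificity hit calling
#'
#' Two conventions are in use for calling a binder specific from HTRF plate
#' signals: a 25-fold target-to-negative ratio (the screening threshold) and
#' a more stringent 50-fold ratio. Neither is silently preferred; pick one
#' explicitly via \code{foldThreshold = htrfFoldPresets[["screening"]]} or
#' \code{[["stringent"]]}.
#'
#' @format Named numeric vector with entries \code{screening} (25) and
#'   \code{stringent} (50).
#' @export
htrfFoldPresets <- c(screening = 25, stringent = 50)

#' HTRF specificity ratio and hit call
#'
#' The specificity of a binder clone is the ratio of its HTRF signal against
#' the target complex to its signal against negative-control complexes. The
#' conservative reading is used: the ratio is taken against the WORST
#' (largest) negative signal, so a clone is a hit only if it clears the fold
#' threshold against every control. Zero or negative control signals are
#' floored at a small epsilon before division.
#'
#' @param target Signal against the target complex (arbitrary units, >= 0).
#' @param negatives Numeric vector of signals against the negative-control
#'   complexes (at least one).
#' @param foldThreshold Hit threshold; the call is \code{ratio >=
#'   foldThreshold} ("at least"), default 25. See \code{\link{htrfFoldPresets}}.
#' @param floorEps Floor applied to non-positive negative signals; default is
#'   the smallest positive observed signal times 1e-3.
#' @return List with \code{ratio} and logical \code{hit}.
#' @examples
#' htrfSpecificity(2500, c(100, 80))   # exactly 25-fold: a hit
#' @export
htrfSpecificity <- function(target, negatives, foldThreshold = 25,
                            floorEps = NULL) {
  stopifnot(length(target) == 1L, is.finite(target), target >= 0)
  if (length(negatives) < 1L)
    stop("at least one negative-control signal is required")
  if (any(!is.finite(negatives)))
    stop("negative-control signals must be finite")
  if (any(negatives <= 0)) {
    if (is.null(floorEps)) {
      pos <- c(target, negatives)
      pos <- pos[pos > 0]
      if (length(pos) == 0L)
        stop("all signals are non-positive; ratio undefined")
      floorEps <- min(pos) * 1e-3
    }
    negatives[negatives <= 0] <- floorEps
  }
  ratio <- target / max(negatives)
  list(ratio = ratio, hit = ratio >= foldThreshold)
}

#' Screen an HTRF plate table for specific binder hits
#'
#' @param df data.frame with a clone id column (first character column or
#'   \code{clone_id}), a \code{signal_target} column, and one or more
#'   \code{signal_neg*} columns of negative-control signals.
#' @param foldThreshold As in \code{\link{htrfSpecificity}}.
#' @return The input with \code{ratio} and \code{hit} columns appended.
#' @export
htrfScreen <- function(df, foldThreshold = 25) {
  stopifnot("signal_target" %in% names(df))
  negcols <- grep("^signal_neg", names(df), value = TRUE)
  if (length(negcols) == 0L)
    stop("no negative-control columns (signal_neg*) found")
  res <- lapply(seq_len(nrow(df)), function(i)
    htrfSpecificity(df$signal_target[i],
                    unlist(df[i, negcols], use.names = FALSE),
                    foldThreshold = foldThreshold))
  df$ratio <- vapply(res, `[[`, numeric(1), "ratio")
  df$hit <- vapply(res, `[[`, logical(1), "hit")
  df
}

#' Three-parameter log(agonist) vs response model
#'
#' \code{response = bottom + (top - bottom) / (1 + 10^(log10(EC50) -
#' log10(dose)))}: the three-parameter logistic with Hill slope fixed at 1
#' (fixing the slope is what distinguishes the three- from the
#' four-parameter model).
#'
#' @param dose Agonist concentrations (> 0, typically molar).
#' @param bottom,top Lower and upper response plateaus.
#' @param ec50 Half-maximal effective concentration.
#' @return Model responses at \code{dose}.
#' @export
doseResponseModel <- function(dose, bottom, top, ec50) {
  bottom + (top - bottom) / (1 + 10^(log10(ec50) - log10(dose)))
}

#' Fit the three-parameter dose-response model
#'
#' Least-squares fit via Levenberg-Marquardt (minpack.lm) with a fixed,
#' deterministic
#' initialization: bottom starts at the minimum observed response, top at the
#' maximum, and EC50 at the dose whose response is nearest the half-maximum.
#' EC50 is optimised on the log10 scale and bounded within three decades of
#' the tested dose range.
#'
#' @param dose Agonist concentrations (> 0); at least four distinct levels.
#' @param response Observed responses, same length.
#' @return A \linkS4class{DoseResponseFit}.
#' @examples
#' d <- 10^seq(-11, -7, by = 0.5)
#' fitDoseResponse(d, doseResponseModel(d, 0, 100, 1e-9))
#' @export
fitDoseResponse <- function(dose, response) {
  stopifnot(length(dose) == length(response))
  if (any(!is.finite(dose)) || any(dose <= 0))
    stop("all doses must be finite and positive")
  if (any(!is.finite(response)))
    stop("all responses must be finite")
  if (length(unique(dose)) < 4L)
    stop("at least four distinct dose levels are required")
  if (diff(range(response)) == 0)
    stop("responses are constant; the dose-response model is degenerate")
  b0 <- min(response)
  t0 <- max(response)
  half <- (b0 + t0) / 2
  e0 <- dose[which.min(abs(response - half))]
  lo <- log10(min(dose)) - 3
  hi <- log10(max(dose)) + 3
  df <- data.frame(dose = dose, response = response)
  resid_fn <- function(p)
    response - (p[1] + (p[2] - p[1]) / (1 + 10^(p[3] - log10(dose))))
  fit <- minpack.lm::nls.lm(
    par = c(bottom = b0, top = t0, logec50 = log10(e0)),
    fn = resid_fn,
    lower = c(-Inf, -Inf, lo), upper = c(Inf, Inf, hi),
    control = minpack.lm::nls.lm.control(maxiter = 500))
  cf <- fit$par
  bottom <- unname(cf["bottom"]); top <- unname(cf["top"])
  ec <- 10^unname(cf["logec50"])
  # the 3PL is symmetric under (bottom, top, ec50) -> (top, bottom, ec50) with
  # an inverted curve; report with top >= bottom
  if (top < bottom) { tmp <- top; top <- bottom; bottom <- tmp }
  fitted <- doseResponseModel(dose, bottom, top, ec)
  new("DoseResponseFit", bottom = bottom, top = top, ec50 = ec,
      data = df, fitted = fitted, residuals = response - fitted)
}

setGeneric("coef")

#' @param object A \linkS4class{DoseResponseFit}.
#' @param ... For \code{coef}: unused.
#' @return Named vector \code{c(bottom, top, ec50)}.
#' @rdname fitDoseResponse
#' @export
setMethod("coef", "DoseResponseFit", function(object, ...) {
  c(bottom = object@bottom, top = object@top, ec50 = object@ec50)
})

#' Effective concentration at a response fraction (EC_F)
#'
#' For the unit-slope three-parameter model, the dose producing F% of the
#' span between bottom and top has the closed form \code{EC_F = EC50 * F /
#' (100 - F)}; in particular EC90 = 9 x EC50 and EC50 is recovered at
#' F = 50.
#'
#' @param fit A \linkS4class{DoseResponseFit}, or a positive EC50 value.
#' @param F Target response percentage, strictly between 0 and 100
#'   (default 90).
#' @return The effective concentration, same units as the doses.
#' @examples
#' effectiveConcentration(2e-9, F = 90)   # 1.8e-8
#' @export
effectiveConcentration <- function(fit, F = 90) {
  if (is(fit, "DoseResponseFit")) fit <- fit@ec50
  stopifnot(is.numeric(fit), length(fit) == 1L, fit > 0)
  if (!is.finite(F) || F <= 0 || F >= 100)
    stop("F must be strictly between 0 and 100")
  fit * (F / (100 - F))
}

#' Percent specific lysis from chromium-release counts
#'
#' \code{((experimental - spontaneous) / (maximum - spontaneous)) * 100}.
#' Values below 0% or above 100% are legal (counting noise around the
#' plateaus) and reported as-is with a warning.
#'
#' @param experimental Experimental release counts.
#' @param spontaneous Spontaneous (target-only) release counts; recycled.
#' @param maximum Maximum (detergent) release counts; recycled; must exceed
#'   spontaneous.
#' @return Percent specific lysis, vectorized over \code{experimental}.
#' @examples
#' specificLysis(400, 100, 500)   # 75
#' @export
specificLysis <- function(experimental, spontaneous, maximum) {
  n <- length(experimental)
  spontaneous <- rep_len(spontaneous, n)
  maximum <- rep_len(maximum, n)
  if (any(!is.finite(c(experimental, spontaneous, maximum))))
    stop("all release counts must be finite")
  if (any(spontaneous < 0))
    stop("spontaneous release cannot be negative")
  if (any(maximum <= spontaneous))
    stop("maximum release must exceed spontaneous release")
  pct <- (experimental - spontaneous) / (maximum - spontaneous) * 100
  out_of_range <- pct < 0 | pct > 100
  if (any(out_of_range))
    warning(sprintf("%d value(s) outside [0, 100]%% reported as-is",
                    sum(out_of_range)))
  pct
}
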