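#' Recover the daughter scale factors from mean and difference
#'
#' Inverts the mean/half-difference construction:
#' \deqn{\beta_1 = \bar\beta + |\Delta\beta|, \qquad
#'       \beta_2 = \bar\beta - |\Delta\beta|.}
#' The absolute value makes the pair independent of the sign convention of
#' the stored difference.
#'
#' @param betaMean mean scale factor(s), > |betaDiff|.
#' @param betaDiff (signed) difference scale factor(s); recycled.
#' @return two-column matrix with columns beta1, beta2.
#' @examples
#' betaPair(0.7, 0.1) # 0.8, 0.6
#' @export
betaPair <- function(betaMean, betaDiff) {
  n <- max(length(betaMean), length(betaDiff))
  betaMean <- rep_len(betaMean, n)
  betaDiff <- rep_len(betaDiff, n)
  if (any(betaMean <= abs(betaDiff))) {
    stop("betaMean must exceed |betaDiff| (beta2 would be <= 0)",
      call. = FALSE
    )
  }
  cbind(
    beta1 = betaMean + abs(betaDiff),
    beta2 = betaMean - abs(betaDiff)
  )
}

#' Resistance of a cylindrical branch segment
#'
#' Under the cable/resistor approximation a branch of length l and radius r
#' has resistance rho * l / (pi * r^2); the physical constants rho/pi are
#' normalized to 1, so all resistances are relative.
#'
#' @param pathLength branch length(s), micrometres.
#' @param meanRadius branch radius(-i), micrometres, > 0.
#' @return resistance(s) in units of rho/pi.
#' @export
branchResistance <- function(pathLength, meanRadius) {
  if (any(meanRadius <= 0)) {
    stop("meanRadius must be > 0", call. = FALSE)
  }
  pathLength / meanRadius^2
}

#' Construct a scale schedule
#'
#' Vectorized constructor for [ScaleSchedule-class]; scalar arguments are
#' recycled to the longest length, which sets the level count N.
#'
#' @param betaMean,betaDiffAbs per-level mean and absolute difference radius
#'   scale factors.
#' @param gammaMean,gammaDiffAbs per-level length analogues.
#' @param terminalResistance total terminal-level resistance (> 0).
#' @return a [ScaleSchedule-class].
#' @export
scaleSchedule <- function(betaMean = numeric(), betaDiffAbs = 0,
                          gammaMean = 1, gammaDiffAbs = 0,
                          terminalResistance = 1) {
  n <- max(
    length(betaMean), length(betaDiffAbs),
    length(gammaMean), length(gammaDiffAbs)
  )
  if (length(betaMean) == 0L) n <- 0L
  lv <- data.frame(
    betaMean = rep_len(betaMean, n),
    betaDiffAbs = abs(rep_len(betaDiffAbs, n)),
    gammaMean = rep_len(gammaMean, n),
    gammaDiffAbs = abs(rep_len(gammaDiffAbs, n))
  )
  new("ScaleSchedule",
    levels = lv,
    terminalResistance = as.numeric(terminalResistance)
  )
}

#' Power loss of a hierarchically branching resistive network
#'
#' Evaluates the recursion for the dissipative power of signal current
#' through an asymmetrically branching network with N levels:
#' \deqn{P = R_{N,TOT} \sum_{k=0}^{N} \prod_{j=k}^{N-1}
#'   \left[\frac{(\bar\beta_j+|\Delta\beta_j|)^2}{\bar\gamma_j+|\Delta\gamma_j|}
#'       + \frac{(\bar\beta_j-|\Delta\beta_j|)^2}{\bar\gamma_j-|\Delta\gamma_j|}
#'   \right]}
#' with the empty product (k = N) equal to 1, so P is linear in the terminal
#' resistance. The denominator of the second bracket term pairs the
#' shorter daughter (gamma-bar minus |Delta-gamma|) with the thinner one, in
#' the same sibling structure by which beta1/beta2 are recovered from the
#' mean and difference; `denominator = "symmetric"` instead uses
#' gamma-bar + |Delta-gamma| in both terms. The two readings coincide
#' whenever Delta-gamma = 0. No claim is made that this recursion equals a
#' series-parallel reduction of an explicit branch tree.
#'
#' @param schedule a [ScaleSchedule-class].
#' @param denominator "asymmetric" (default) or "symmetric"; see Details.
#' @return the power loss (units of I0^2 x resistance), with attribute
#'   `"terms"` holding the N + 1 per-level summands (before the terminal
#'   resistance factor).
#' @examples
#' # area-preserving symmetric junctions: bracket = 1, P = N + 1
#' powerLoss(scaleSchedule(betaMean = rep(sqrt(0.5), 4)))
#' @export
powerLoss <- function(schedule, denominator = c("asymmetric", "symmetric")) {
  stopifnot(is(schedule, "ScaleSchedule"))
  denominator <- match.arg(denominator)
  validObject(schedule)
  lv <- schedule@levels
  b1 <- lv$betaMean + lv$betaDiffAbs
  b2 <- lv$betaMean - lv$betaDiffAbs
  g1 <- lv$gammaMean + lv$gammaDiffAbs
  g2 <- if (denominator == "asymmetric") {
    lv$gammaMean - lv$gammaDiffAbs
  } else {
    g1
  }
  f <- b1^2 / g1 + b2^2 / g2
  # terms_k = prod_{j=k}^{N-1} f_j ; suffix products, empty product = 1
  terms <- rev(cumprod(c(1, rev(f))))
  p <- schedule@terminalResistance * sum(terms)
  attr(p, "terms") <- terms
  p
}

#' @rdname ScaleSchedule-class
#' @export
setMethod("nLevels", "ScaleSchedule", function(x) nrow(x@levels))

#' @rdname ScaleSchedule-class
#' @export
setMethod(
  "terminalResistance", "ScaleSchedule",
  function(x) x@terminalResistance
)

setMethod("show", "ScaleSchedule", function(object) {
  cat(sprintf(
    "ScaleSchedule: %d level(s), terminal resistance %.4g\n",
    nrow(object@levels), object@terminalResistance
  ))
})
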