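# Peak/dip extraction from simulated transients. A step up in the absorption
# coefficient announces itself as a compression peak, a step down as a
# rarefaction dip; locating these extrema on the retarded-depth axis is how
# layer boundaries are read off a far-field signal.

# prominence of a local extremum in y (maxima; pass -y for minima):
# height above the higher of the two lowest points separating it from
# higher terrain (or the record ends).
peak_prominence <- function(y, i) {
  n <- length(y)
  left_min <- y[i]
  j <- i - 1
  while (j >= 1 && y[j] <= y[i]) {
    left_min <- min(left_min, y[j])
    j <- j - 1
  }
  right_min <- y[i]
  j <- i + 1
  while (j <= n && y[j] <= y[i]) {
    right_min <- min(right_min, y[j])
    j <- j + 1
  }
  y[i] - max(left_min, right_min)
}

local_maxima <- function(y) {
  n <- length(y)
  if (n < 3) return(integer(0))
  which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
}

#' Extract compression peaks and rarefaction dips
#'
#' Finds local extrema of a transient on its retarded-depth axis whose
#' prominence exceeds a threshold. Compression peaks must have positive
#' amplitude, rarefaction dips negative.
#'
#' @param signal an [oa_signal] with a `ctau` axis.
#' @param min_prominence absolute prominence threshold (a.u.); default 5% of
#'   `max(abs(p))`, above the binning noise and below the smallest resolved
#'   feature.
#' @return a `data.frame` with columns `kind` (`"compression_peak"` /
#'   `"rarefaction_dip"`), `ctau` (cm) and `amplitude` (a.u.), ordered by
#'   `ctau`. Zero rows if nothing qualifies.
#' @export
extract_features <- function(signal, min_prominence = NULL) {
  stopifnot(inherits(signal, "oa_signal"))
  if (is.null(signal$ctau))
    stop("signal must carry a retarded-depth axis; see to_retarded_depth()")
  p <- signal$p
  empty <- data.frame(kind = character(0), ctau = numeric(0),
                      amplitude = numeric(0))
  if (max(abs(p)) == 0) return(empty)
  if (is.null(min_prominence)) min_prominence <- 0.05 * max(abs(p))

  collect <- function(y, kind, sign) {
    idx <- local_maxima(y)
    idx <- idx[vapply(idx, function(i) peak_prominence(y, i),
                      numeric(1)) >= min_prominence]
    idx <- idx[sign * p[idx] > 0]
    if (!length(idx)) return(empty)
    data.frame(kind = kind, ctau = signal$ctau[idx], amplitude = p[idx])
  }
  out <- rbind(collect(p, "compression_peak", +1),
               collect(-p, "rarefaction_dip", -1))
  out[order(out$ctau), , drop = FALSE]
}
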