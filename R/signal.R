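# Pressure-transient container and shared signal utilities.
# All axes are propagation distance ct in cm; no speed of sound enters the
# core. The optional ctau axis is the retarded signal depth ctau = ct + z_D.

new_oa_signal <- function(ct, p, detection, bin_width, ctau = NULL) {
  structure(list(ct = ct, p = p, detection = detection,
                 bin_width = bin_width, ctau = ctau),
            class = "oa_signal")
}

#' Pressure transient
#'
#' A uniformly sampled optoacoustic pressure transient in arbitrary units
#' against propagation distance `ct` (cm), carrying its detection-point
#' metadata and bin width. Produced by the solvers ([oa_solve()],
#' [oa_solve_cart()]); the retarded-depth axis is added by
#' [to_retarded_depth()].
#'
#' @param x an `oa_signal`.
#' @param ... ignored.
#' @name oa_signal
NULL

#' @rdname oa_signal
#' @export
print.oa_signal <- function(x, ...) {
  cat(sprintf(
    "Optoacoustic pressure transient: %d samples, ct in [%.4g, %.4g] cm (bin %.3g cm)\n",
    length(x$ct), min(x$ct), max(x$ct), x$bin_width))
  cat(sprintf("  detector at x_D = %g cm, z_D = %g cm; max |p| = %.4g a.u.\n",
              x$detection$x_D, x$detection$z_D, max(abs(x$p))))
  if (!is.null(x$ctau))
    cat(sprintf("  retarded depth axis ctau = ct + z_D in [%.4g, %.4g] cm\n",
                min(x$ctau), max(x$ctau)))
  invisible(x)
}

#' @rdname oa_signal
#' @export
summary.oa_signal <- function(object, ...) {
  x <- object
  i_max <- which.max(x$p); i_min <- which.min(x$p)
  out <- data.frame(
    n = length(x$ct), bin_width = x$bin_width,
    ct_peak = x$ct[i_max], p_peak = x$p[i_max],
    ct_dip = x$ct[i_min], p_dip = x$p[i_min])
  if (!is.null(x$ctau)) {
    out$ctau_peak <- x$ctau[i_max]
    out$ctau_dip <- x$ctau[i_min]
  }
  out
}

#' @rdname oa_signal
#' @param xaxis which axis to plot against: `"ctau"` (if present) or `"ct"`.
#' @export
plot.oa_signal <- function(x, xaxis = c("ctau", "ct"), ...) {
  xaxis <- match.arg(xaxis)
  if (xaxis == "ctau" && is.null(x$ctau)) xaxis <- "ct"
  xx <- if (xaxis == "ctau") x$ctau else x$ct
  xlab <- if (xaxis == "ctau") expression(c * tau ~ "[cm]") else "ct [cm]"
  graphics::plot(xx, x$p, type = "l", xlab = xlab,
                 ylab = expression(p[D] ~ "[a.u.]"), ...)
  graphics::abline(h = 0, col = "grey70", lty = 3)
  invisible(x)
}

#' Write / read a pressure transient as CSV
#'
#' Two-column CSV `ct_cm,p_au`, with a third column `ctau_cm` when the
#' retarded-depth axis is present. Detection metadata travels in `# key: value`
#' header comments so a written signal can be read back losslessly.
#'
#' @param signal an `oa_signal`.
#' @param path file path.
#' @return `write_signal_csv` returns `path` invisibly; `read_signal_csv`
#'   returns an `oa_signal`.
#' @export
write_signal_csv <- function(signal, path) {
  stopifnot(inherits(signal, "oa_signal"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# x_D: %.10g", signal$detection$x_D), con)
  writeLines(sprintf("# z_D: %.10g", signal$detection$z_D), con)
  writeLines(sprintf("# bin_width: %.10g", signal$bin_width), con)
  df <- data.frame(ct_cm = signal$ct, p_au = signal$p)
  if (!is.null(signal$ctau)) df$ctau_cm <- signal$ctau
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_signal_csv
#' @export
read_signal_csv <- function(path) {
  hdr <- readLines(path, n = 10)
  hdr <- hdr[startsWith(hdr, "#")]
  meta <- function(key, default = NA_real_) {
    ln <- grep(paste0("^# ", key, ":"), hdr, value = TRUE)
    if (length(ln) == 0) return(default)
    as.numeric(sub(paste0("^# ", key, ": *"), "", ln[1]))
  }
  df <- utils::read.csv(path, comment.char = "#")
  z_D <- meta("z_D", -1)
  det <- oa_detection(z_D = z_D, x_D = meta("x_D", 0))
  bw <- meta("bin_width")
  if (is.na(bw)) bw <- stats::median(diff(df$ct_cm))
  new_oa_signal(ct = df$ct_cm, p = df$p_au, detection = det, bin_width = bw,
                ctau = if ("ctau_cm" %in% names(df)) df$ctau_cm else NULL)
}

# Centered moving average with the window shrunk symmetrically at the record
# edges (no zero padding), so short records get no spurious edge transients.
# n must be odd; n == 1 is the identity.
moving_average <- function(x, n) {
  stopifnot(n >= 1, n %% 2 == 1)
  if (n == 1) return(x)
  if (n > length(x)) stop("smoothing window exceeds record length")
  h <- (n - 1) / 2
  cs <- cumsum(c(0, x))
  N <- length(x)
  i <- seq_len(N)
  # symmetric shrink: half-width limited by distance to either edge
  hw <- pmin(h, i - 1, N - i)
  (cs[i + hw + 1] - cs[i - hw]) / (2 * hw + 1)
}
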