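#' Segmented-EPI acquisition protocol specification
#'
#' Defaults describe the 0.94 mm fixed-brain protocol: matrix 168 x 192 x 120
#' (readout x phase-encode x partitions), 32 lines per EPI segment,
#' TE/TR = 122/530 ms, flip 75 degrees, partial Fourier 5/8 along the blip
#' direction, b = 4500 s/mm^2, 54 directions + 6 b = 0, 3 repeats, fixed
#' white matter T1 about 340 ms.
#'
#' @param matrix_size length-3 (readout, PE lines, partitions/slices).
#' @param lines_per_segment EPI lines acquired per excitation.
#' @param tr_s,te_s repetition/echo time (s).
#' @param flip_deg excitation flip angle (degrees).
#' @param partial_fourier fraction of PE lines acquired, in (0.5, 1].
#' @param b b-value (s/mm^2).
#' @param n_directions,n_b0,repeats acquisition counts.
#' @param t1_s,t2_s tissue relaxation times (s).
#' @return list of class `protocol_spec`.
#' @export
protocol_spec <- function(matrix_size = c(168L, 192L, 120L),
                          lines_per_segment = 32L,
                          tr_s = 0.530, te_s = 0.122, flip_deg = 75,
                          partial_fourier = 5 / 8, b = 4500,
                          n_directions = 54L, n_b0 = 6L, repeats = 3L,
                          t1_s = 0.340, t2_s = 0.050) {
  if (any(c(matrix_size, lines_per_segment, tr_s, te_s, flip_deg, b,
            n_directions, n_b0, t1_s, t2_s) <= 0) || repeats < 0)
    stop("protocol parameters must be positive (repeats may be 0)")
  if (lines_per_segment > matrix_size[2])
    stop("lines per segment cannot exceed PE lines")
  if (partial_fourier <= 0.5 || partial_fourier > 1)
    stop("partial Fourier factor must lie in (0.5, 1]")
  structure(list(matrix_size = as.integer(matrix_size),
                 lines_per_segment = as.integer(lines_per_segment),
                 tr_s = tr_s, te_s = te_s, flip_deg = flip_deg,
                 partial_fourier = partial_fourier, b = b,
                 n_directions = as.integer(n_directions),
                 n_b0 = as.integer(n_b0), repeats = as.integer(repeats),
                 t1_s = t1_s, t2_s = t2_s),
            class = "protocol_spec")
}

#' The 0.73 mm high-resolution protocol
#'
#' Matrix 254 x 254 x 192, TE/TR = 114/670 ms, flip 77 degrees,
#' b = 3050 s/mm^2, 64 directions + 5 b = 0, 5 repeats.
#'
#' @return a [protocol_spec].
#' @export
protocol_spec_highres <- function() {
  protocol_spec(matrix_size = c(254L, 254L, 192L), lines_per_segment = 32L,
                tr_s = 0.670, te_s = 0.114, flip_deg = 77,
                partial_fourier = 5 / 8, b = 3050,
                n_directions = 64L, n_b0 = 5L, repeats = 5L)
}

#' Acquisition time per volume
#'
#' `ceiling(PE lines / lines per segment) * partitions * TR`. The printed
#' session timings of segmented 3D protocols are consistent with full PE-line
#' coverage, so partial Fourier is ignored by default; set
#' `use_partial_fourier = TRUE` to shorten the PE coverage by that factor.
#'
#' @param spec a [protocol_spec].
#' @param use_partial_fourier reduce acquired PE lines by the partial-Fourier
#'   factor.
#' @return seconds per volume.
#' @export
volume_time <- function(spec, use_partial_fourier = FALSE) {
  pe <- spec$matrix_size[2]
  if (use_partial_fourier) pe <- ceiling(pe * spec$partial_fourier)
  segments <- ceiling(pe / spec$lines_per_segment)
  segments * spec$matrix_size[3] * spec$tr_s
}

#' Total diffusion session time
#'
#' `(directions + b0s) * repeats * volume_time`.
#'
#' @inheritParams volume_time
#' @return list with `seconds`, `hours` and `per_volume_s`.
#' @export
session_time <- function(spec, use_partial_fourier = FALSE) {
  pv <- volume_time(spec, use_partial_fourier)
  s <- (spec$n_directions + spec$n_b0) * spec$repeats * pv
  list(seconds = s, hours = s / 3600, per_volume_s = pv)
}

#' Format seconds as mm:ss
#' @param seconds numeric.
#' @return character "m:ss".
#' @export
format_mmss <- function(seconds) {
  m <- floor(seconds / 60)
  s <- round(seconds - 60 * m)
  sprintf("%d:%02d", m, s)
}

#' SNR efficiency of a spoiled steady-state acquisition versus TR
#'
#' One plausible model of the TR tradeoff between T1 recovery (favouring
#' long TR) and sampling rate (favouring short TR):
#' `eff(TR) = sin(a) * (1 - E1) / (1 - E1 cos(a)) / sqrt(TR)` with
#' `E1 = exp(-TR/T1)` (fully-spoiled steady-state signal per unit sqrt of
#' scan time). Exploratory: protocol choices should not hinge on this model
#' alone.
#'
#' @param tr_s repetition time (s), vectorised.
#' @param t1_s tissue T1 (s).
#' @param flip_deg flip angle (degrees).
#' @return relative efficiency (arbitrary units).
#' @export
snr_efficiency <- function(tr_s, t1_s, flip_deg) {
  if (any(tr_s <= 0) || t1_s <= 0 || flip_deg <= 0)
    stop("TR, T1 and flip angle must be positive")
  a <- flip_deg * pi / 180
  e1 <- exp(-tr_s / t1_s)
  sin(a) * (1 - e1) / (1 - e1 * cos(a)) / sqrt(tr_s)
}

#' TR maximising the SNR efficiency model
#'
#' Bracketed 1-D maximisation of [snr_efficiency()]. For fixed white matter
#' (T1 about 340 ms) this model places the optimum below the 500-700 ms range
#' quoted for such tissue, which triggers a warning: the model is one reading
#' of the tradeoff, not a calibrated sequence simulation.
#'
#' @param t1_s tissue T1 (s).
#' @param flip_deg flip angle (degrees).
#' @return list: `tr_s` (optimal TR), `efficiency`.
#' @export
optimal_tr <- function(t1_s, flip_deg = 90) {
  o <- optimize(function(tr) snr_efficiency(tr, t1_s, flip_deg),
                interval = c(1e-4, 20 * t1_s), maximum = TRUE, tol = 1e-8)
  if (o$maximum < 0.5 && t1_s >= 0.3 && t1_s <= 0.4)
    warning(sprintf(
      "optimal TR %.0f ms falls below the 500-700 ms range quoted for fixed white matter; the efficiency model is exploratory",
      1000 * o$maximum))
  list(tr_s = o$maximum, efficiency = o$objective)
}

#' Tabulate the TR-efficiency curve
#'
#' @param t1_s tissue T1 (s).
#' @param flip_deg flip angle.
#' @param tr_grid_s TR values (s).
#' @return data.frame with `tr_s` and `efficiency`.
#' @export
tr_efficiency_curve <- function(t1_s, flip_deg = 90,
                                tr_grid_s = seq(0.05, 3, by = 0.01)) {
  data.frame(tr_s = tr_grid_s,
             efficiency = snr_efficiency(tr_grid_s, t1_s, flip_deg))
}
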