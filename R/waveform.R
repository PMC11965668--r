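# Periodic inlet velocity waveforms.
#
# Of the clinical Doppler traces only summary values are recorded: the
# cycle-averaged velocity of each vessel, the heart rate (~70 bpm) and the
# instants of maximum (~1.82 s), average (~2.02 s) and minimum (~2.58 s)
# velocity inside the third cardiac cycle. The default pulse honours those
# constraints exactly: a C1-periodic piecewise raised-cosine with its maximum
# anchored at 1.82 s (peak/mean = 1.4), its minimum at 2.58 s (trough/mean =
# 0.6), and a time average exactly equal to the prescribed mean (each
# raised-cosine arc averages to the arc midpoint analytically).

#' Clinical reference constants of the fistula forearm
#'
#' Printed cycle-averaged velocities and diameters (PRA 57.7 cm/s, 3.0 mm;
#' DRA 34.3 cm/s, 1.2 mm; CV 5.0 mm), heart period 60/70 s (~70 bpm), and
#' cephalic-vein pressure 8 mmHg (1064 Pa).
#'
#' @return named list of SI values, including the extremal/mean instants of
#'   the third cardiac cycle (`t_max`, `t_mean`, `t_min`).
#' @export
clinical_reference <- function() {
  list(
    v_pra = 0.577, v_dra = 0.343,                   # m/s, cycle averages
    d_pra = 3.0e-3, d_dra = 1.2e-3, d_cv = 5.0e-3,  # m
    period = 60 / 70,                               # s
    p_cv = mmhg_to_pa(8),                           # 1064 Pa
    t_max = 1.82, t_mean = 2.02, t_min = 2.58       # s, in 3rd cycle
  )
}

#' Synthesize a periodic inlet velocity waveform
#'
#' @param mean_velocity cycle-averaged velocity in m/s (non-negative; the
#'   sign convention of retrograde flow is applied at the boundary-condition
#'   stage, not here).
#' @param period cardiac period in s (default 60/70 s, ~70 bpm).
#' @param shape `"pulse"` (default) for the anchored raised-cosine pulse, or
#'   `"harmonics"` for a finite Fourier series.
#' @param peak_ratio,trough_ratio extremal values relative to the mean for
#'   `shape = "pulse"` (defaults 1.4 and 0.6). They are honoured exactly
#'   when `peak_ratio + trough_ratio == 2`; otherwise the pulse is rescaled
#'   by the midpoint so that the time average stays exactly at the mean.
#' @param t_max,t_min anchor instants (s) of the maximum and minimum,
#'   interpreted modulo the period (values quoted inside the third cycle may
#'   be passed as recorded).
#' @param harmonics for `shape = "harmonics"`: a matrix or data.frame with
#'   columns `amplitude` (m/s) and `phase` (rad) for k = 1..K, giving
#'   v(t) = mean + sum_k amplitude_k * cos(k w t + phase_k).
#' @return an object of class `avf_waveform`: a function of time `wf(t)`
#'   carrying its specification (see [waveform_spec()]).
#' @examples
#' wf <- synthesize_waveform(0.577)
#' wf(1.82) / 0.577 # 1.4
#' @export
synthesize_waveform <- function(mean_velocity, period = 60 / 70,
                                shape = c("pulse", "harmonics"),
                                peak_ratio = 1.4, trough_ratio = 0.6,
                                t_max = 1.82, t_min = 2.58,
                                harmonics = NULL) {
  shape <- match.arg(shape)
  if (!is.numeric(mean_velocity) || length(mean_velocity) != 1L ||
      mean_velocity < 0) {
    stop("mean_velocity must be a single non-negative number")
  }
  if (period <= 0) stop("period must be positive")
  spec <- list(mean_velocity = mean_velocity, period = period, shape = shape)
  if (shape == "pulse") {
    if (!(trough_ratio < 1 && 1 < peak_ratio)) {
      stop("need trough_ratio < 1 < peak_ratio")
    }
    if (trough_ratio < 0) stop("pulse trough would be negative")
    spec$phase_max <- (t_max %% period) / period
    spec$phase_min <- (t_min %% period) / period
    if (abs(spec$phase_max - spec$phase_min) < 1e-9) {
      stop("t_max and t_min coincide modulo the period")
    }
    spec$peak_ratio <- peak_ratio
    spec$trough_ratio <- trough_ratio
  } else {
    if (is.null(harmonics)) {
      stop("harmonics must have columns 'amplitude' and 'phase'")
    }
    h <- as.data.frame(harmonics)
    if (!all(c("amplitude", "phase") %in% names(h))) {
      stop("harmonics must have columns 'amplitude' and 'phase'")
    }
    spec$harmonics <- data.frame(amplitude = as.numeric(h$amplitude),
                                 phase = as.numeric(h$phase))
    tt <- seq(0, period, length.out = 4096L)
    if (min(eval_waveform_impl(spec, tt)) < -1e-12 * max(mean_velocity, 1)) {
      stop("harmonic amplitudes drive the anterograde inlet signal negative")
    }
  }
  wf <- function(t) eval_waveform_impl(spec, t)
  class(wf) <- "avf_waveform"
  attr(wf, "spec") <- spec
  wf
}

eval_waveform_impl <- function(spec, t) {
  ph <- (t / spec$period) %% 1
  if (spec$shape == "pulse") {
    s <- (ph - spec$phase_min) %% 1
    up <- (spec$phase_max - spec$phase_min) %% 1  # upstroke width, cycle frac
    mid <- (spec$peak_ratio + spec$trough_ratio) / 2
    half <- (spec$peak_ratio - spec$trough_ratio) / 2
    f <- ifelse(s < up,
                mid - half * cos(pi * s / up),
                mid + half * cos(pi * (s - up) / (1 - up)))
    # each raised-cosine arc averages to `mid`, so f/mid has unit time
    # average and the waveform mean equals mean_velocity analytically
    spec$mean_velocity * f / mid
  } else {
    om <- 2 * pi / spec$period
    v <- rep(spec$mean_velocity, length(t))
    for (i in seq_len(nrow(spec$harmonics))) {
      v <- v + spec$harmonics$amplitude[i] *
        cos(i * om * t + spec$harmonics$phase[i])
    }
    v
  }
}

#' Waveform specification and evaluation helpers
#'
#' `waveform_spec()` returns the stored parameters (mean velocity, period,
#' shape, anchors/harmonics); `waveform_eval()` evaluates the signal.
#'
#' @param wf an `avf_waveform`.
#' @param t numeric vector of times in s.
#' @return `waveform_spec()`: a named list; `waveform_eval()`: velocities in
#'   m/s.
#' @export
waveform_spec <- function(wf) {
  stopifnot(inherits(wf, "avf_waveform"))
  attr(wf, "spec")
}

#' @rdname waveform_spec
#' @export
waveform_eval <- function(wf, t) {
  stopifnot(inherits(wf, "avf_waveform"))
  eval_waveform_impl(attr(wf, "spec"), t)
}

#' @export
print.avf_waveform <- function(x, ...) {
  s <- attr(x, "spec")
  cat(sprintf("<avf_waveform> %s: mean %.4g m/s, period %.4g s\n",
              s$shape, s$mean_velocity, s$period))
  invisible(x)
}

#' Write a sampled waveform to CSV
#'
#' @param wf an `avf_waveform`.
#' @param path output file.
#' @param dt sampling step in s (default 0.01, the clinical reporting cadence).
#' @param n_periods number of periods to sample.
#' @return the path, invisibly.
#' @export
write_waveform_csv <- function(wf, path, dt = 0.01, n_periods = 1) {
  s <- attr(wf, "spec")
  t <- seq(0, n_periods * s$period, by = dt)
  write.csv(data.frame(t = t, v = waveform_eval(wf, t)), path,
            row.names = FALSE)
  invisible(path)
}
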