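#' ERP component specification
#'
#' A single ERP component: a Gaussian-envelope deflection with a peak
#' amplitude, a peak latency relative to event onset, a temporal width
#' (Gaussian SD) and a spatial profile given as per-channel gains in
#' \eqn{[0, 1]}.
#'
#' @param channels Named numeric vector of channel gains in `[0, 1]`; names
#'   are channel labels, the primary channel should have gain 1.
#' @param latency Peak latency in seconds from event onset.
#' @param width Gaussian SD in seconds (> 0).
#' @param amplitude Signed peak amplitude in microvolts at gain-1 channels.
#' @param name Optional component name.
#' @return An object of class `erp_component`.
#' @export
erp_component <- function(channels, latency, width, amplitude, name = NULL) {
  if (length(channels) < 1 || is.null(names(channels)))
    stopf("channels must be a named vector with at least one entry")
  if (any(channels < 0 | channels > 1)) stopf("channel gains must lie in [0, 1]")
  if (width <= 0) stopf("width must be positive")
  structure(list(channels = channels, latency = latency, width = width,
                 amplitude = amplitude, name = name %||% "component"),
            class = "erp_component")
}

#' Default emergency-response ERP components
#'
#' Three components model the emergency response: an early occipito-parietal
#' negativity (visual mismatch negativity, vMMN-like; POz-centred, -0.43 uV
#' peaking at 0.2 s), a centro-parietal positivity (P300-like, +0.84 uV,
#' delayed to 0.55 s by the preceding negativity), and a frontal negativity
#' (contingent negative variation, CNV-like; Fz-centred, -1.61 uV peaking at
#' 0.6 s).  Peak amplitudes and latencies are the grand-average values the
#' generator is asked to reproduce; the Gaussian envelopes, widths and
#' spatial gain profiles are modelling choices (see the vignette).
#'
#' @return List of [erp_component()] objects.
#' @export
emergency_components <- function() {
  list(
    erp_component(
      c(POz = 1, Oz = 0.9, O1 = 0.7, O2 = 0.7, Pz = 0.5, P3 = 0.45, P4 = 0.45,
        P7 = 0.35, P8 = 0.35),
      latency = 0.2, width = 0.18, amplitude = -0.43, name = "vmmn"),
    erp_component(
      c(POz = 1, Pz = 1, CP1 = 0.9, CP2 = 0.9, Cz = 0.5, P3 = 0.5, P4 = 0.5,
        Oz = 0.3),
      latency = 0.55, width = 0.10, amplitude = 0.84,
      name = "posterior_positivity"),
    erp_component(
      c(Fz = 1, F1 = 0.7, F2 = 0.7, FCz = 0.6, AF3 = 0.45, AF4 = 0.45,
        F3 = 0.4, F4 = 0.4, FC1 = 0.3, FC2 = 0.3, Fpz = 0.3, Fp1 = 0.2, Fp2 = 0.2),
      latency = 0.6, width = 0.18, amplitude = -1.61, name = "cnv"))
}

#' Default non-emergency-response ERP components
#'
#' The non-emergency (video switch) response shares the centro-parietal
#' positivity (+0.72 uV, earlier at 0.45 s since no preceding negativity
#' delays it) and a weaker frontal negativity (-0.70 uV at 0.6 s) but carries
#' no posterior negativity: the mismatch component is specific to
#' emergencies.
#'
#' @return List of [erp_component()] objects.
#' @export
nonemergency_components <- function() {
  em <- emergency_components()
  pos <- em[[2]]; pos$amplitude <- 0.72; pos$latency <- 0.45
  cnv <- em[[3]]; cnv$amplitude <- -0.70
  list(pos, cnv)
}

#' Default per-condition template set
#' @return Named list with `non_emergency` and `emergency` component lists.
#' @export
default_templates <- function() {
  list(non_emergency = nonemergency_components(),
       emergency = emergency_components())
}

#' Render an ERP template as a channels-by-samples waveform
#'
#' Sums Gaussian-enveloped components onto their target channels; all other
#' channels are zero.  The template is laid out on a time axis starting at
#' `window[1]` seconds relative to event onset.
#'
#' @param components List of [erp_component()] (may be empty: all-zero
#'   template).
#' @param fs Sampling rate in Hz.
#' @param window Length-2 numeric, template span in seconds relative to event
#'   onset (default `c(-0.4, 1.2)`, letting the Gaussian tails start before
#'   onset); must cover each component's latency +/- 3 widths.
#' @param channel_labels Channel label universe defining the row order.
#' @return Numeric matrix `length(channel_labels)` x samples with a `times`
#'   attribute (seconds relative to onset).
#' @export
render_erp_template <- function(components, fs, window = c(-0.4, 1.2),
                                channel_labels = default_scalp_labels()) {
  n <- round((window[2] - window[1]) * fs)
  times <- window[1] + (seq_len(n) - 1) / fs
  out <- matrix(0, nrow = length(channel_labels), ncol = n,
                dimnames = list(channel_labels, NULL))
  for (comp in components) {
    if (comp$amplitude == 0) next
    if (comp$latency - 3 * comp$width < window[1] - 1e-9 ||
        comp$latency + 3 * comp$width > window[2] + 1e-9)
      stopf("template window does not cover component '%s' +/- 3 widths",
            comp$name)
    env <- comp$amplitude * exp(-(times - comp$latency)^2 / (2 * comp$width^2))
    for (lab in names(comp$channels)) {
      if (!lab %in% channel_labels) next
      out[lab, ] <- out[lab, ] + comp$channels[[lab]] * env
    }
  }
  attr(out, "times") <- times
  attr(out, "fs") <- fs
  out
}
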