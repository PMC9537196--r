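# Stimulus protocols: time-dependent input channels driving a compiled
# model. The workhorse shape is the double-exponential transient used for
# both calcium spikes and dopamine transients; a spike train superposes
# several transients at a fixed frequency.

#' Build a stimulus time function
#'
#' Supported kinds:
#' \describe{
#'   \item{`double_exponential`}{`A * norm * (exp(-(t-t0)/tau_decay) -
#'     exp(-(t-t0)/tau_rise))` for `t >= t0`, zero before; `norm` is
#'     chosen so the peak equals `amplitude`.}
#'   \item{`spike_train`}{superposition of `count` such transients at
#'     interval `1/frequency`, starting at `onset`.}
#'   \item{`constant`}{the amplitude at all times.}
#'   \item{`tabulated`}{linear interpolation through `(times, values)`,
#'     held at the edge values outside the table.}
#' }
#'
#' @param kind one of `"double_exponential"`, `"spike_train"`,
#'   `"constant"`, `"tabulated"`.
#' @param amplitude peak concentration (nM), `>= 0`.
#' @param onset start time (s). Default 0.
#' @param count number of spikes (spike_train), `>= 1`.
#' @param frequency spike frequency (Hz), `> 0`.
#' @param tau_rise,tau_decay rise and decay time constants (s);
#'   `tau_rise < tau_decay` required.
#' @param times,values tabulated series (strictly increasing times).
#' @return a vectorized function of time returning concentration (nM).
#' @export
make_stimulus <- function(kind = c("double_exponential", "spike_train",
                                   "constant", "tabulated"),
                          amplitude = 0, onset = 0, count = 1, frequency = 1,
                          tau_rise = 0.005, tau_decay = 0.05,
                          times = NULL, values = NULL) {
  kind <- match.arg(kind)
  if (amplitude < 0) abort_sbtab("stimulus amplitude must be >= 0",
                                 "sbtab_parameter_error")
  if (kind == "constant") {
    force(amplitude)
    return(function(t) rep(amplitude, length(t)))
  }
  if (kind == "tabulated") {
    if (is.null(times) || is.null(values) || length(times) != length(values)) {
      abort_sbtab("tabulated stimulus needs matching times and values",
                  "sbtab_parameter_error")
    }
    if (any(diff(times) <= 0)) {
      abort_sbtab("tabulated stimulus times must be strictly increasing",
                  "sbtab_parameter_error")
    }
    f <- stats::approxfun(times, values, rule = 2)
    return(function(t) f(t))
  }
  if (tau_rise >= tau_decay) {
    abort_sbtab("stimulus requires tau_rise < tau_decay", "sbtab_parameter_error")
  }
  if (amplitude == 0) return(function(t) rep(0, length(t)))
  # peak of (e^{-s/td} - e^{-s/tr}) is at s* = tr*td/(td-tr) * log(td/tr)
  s_star <- tau_rise * tau_decay / (tau_decay - tau_rise) * log(tau_decay / tau_rise)
  norm <- 1 / (exp(-s_star / tau_decay) - exp(-s_star / tau_rise))
  pulse <- function(t, t0) {
    s <- t - t0
    out <- numeric(length(t))
    on <- s >= 0
    out[on] <- amplitude * norm * (exp(-s[on] / tau_decay) - exp(-s[on] / tau_rise))
    out
  }
  if (kind == "double_exponential") {
    return(function(t) pulse(t, onset))
  }
  # spike_train
  if (count < 1) abort_sbtab("spike_train requires count >= 1", "sbtab_parameter_error")
  if (frequency <= 0) abort_sbtab("spike_train requires frequency > 0",
                                  "sbtab_parameter_error")
  onsets <- onset + (seq_len(count) - 1) / frequency
  function(t) {
    out <- numeric(length(t))
    for (t0 in onsets) out <- out + pulse(t, t0)
    out
  }
}

#' Spike onset times of a spike-train stimulus
#'
#' @param onset burst start (s); @param count spikes; @param frequency Hz.
#' @return numeric vector of onset times.
#' @export
spike_onsets <- function(onset, count, frequency) {
  onset + (seq_len(count) - 1) / frequency
}

# Build the per-channel stimulus functions for one experiment from the
# Input table plus the experiment's override list.
build_protocol <- function(network, doc, overrides = list()) {
  intab <- doc$tables[["Input"]]
  channels <- list()
  if (is.null(intab) || !nrow(intab)) return(channels)
  getf <- function(df, col, i, default) {
    if (col %in% names(df)) {
      v <- df[[col]][i]
      if (is.character(v)) {
        if (!nzchar(v) || is.na(v)) default else v
      } else if (is.na(v)) default else v
    } else default
  }
  for (i in seq_len(nrow(intab))) {
    id <- as.character(intab[["!ID"]][i])
    spec <- list(
      kind = as.character(getf(intab, "!Kind", i, "constant")),
      amplitude = as.numeric(getf(intab, "!Amplitude", i,
                                  getf(intab, "!DefaultValue", i, 0))),
      onset = as.numeric(getf(intab, "!Onset", i, 0)),
      count = as.numeric(getf(intab, "!Count", i, 1)),
      frequency = as.numeric(getf(intab, "!Frequency", i, 1)),
      tau_rise = as.numeric(getf(intab, "!TauRise", i, 0.005)),
      tau_decay = as.numeric(getf(intab, "!TauDecay", i, 0.05)))
    for (key in names(overrides)) {
      if (startsWith(key, paste0(id, ":"))) {
        field <- tolower(sub("^[^:]*:", "", key))
        field <- c(kind = "kind", amplitude = "amplitude", onset = "onset",
                   count = "count", frequency = "frequency",
                   taurise = "tau_rise", taudecay = "tau_decay")[[field]]
        spec[[field]] <- overrides[[key]]
      } else if (key == id) {
        spec$kind <- "constant"; spec$amplitude <- overrides[[key]]
      }
    }
    channels[[id]] <- do.call(make_stimulus, spec)
  }
  channels
}
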