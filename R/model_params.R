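#' Gating-variable description
#'
#' Boltzmann steady state `1/(1 + exp(-(V - vhalf)/slope))` with a
#' bell-shaped voltage-dependent time constant
#' `tau_base + tau_amp / (exp(u) + exp(-u))`, `u = (V - tau_vhalf)/tau_sigma`.
#' A positive `slope` describes activation, a negative one inactivation.
#'
#' @param vhalf half-activation voltage (mV)
#' @param slope Boltzmann slope factor (mV)
#' @param tau_base minimum time constant (ms)
#' @param tau_amp amplitude of the voltage-dependent part of tau (ms);
#'   0 gives a voltage-independent time constant
#' @param tau_vhalf,tau_sigma centre and width (mV) of the tau bell
#' @return a `gate_spec` list
#' @export
gate_spec <- function(vhalf, slope, tau_base, tau_amp = 0,
                      tau_vhalf = vhalf, tau_sigma = 15) {
  stopifnot(is.finite(vhalf), slope != 0, tau_base > 0, tau_amp >= 0,
            tau_sigma > 0)
  structure(list(vhalf = vhalf, slope = slope, tau_base = tau_base,
                 tau_amp = tau_amp, tau_vhalf = tau_vhalf,
                 tau_sigma = tau_sigma),
            class = "gate_spec")
}

#' Single-compartment neuron model parameters
#'
#' Conductance densities and gating kinetics for the model neuron used to
#' emulate arcopallial upper motor neurons. Channels: transient Na+
#' (`nav`, m^3 h), a low-threshold delayed rectifier (`kv_low`, n^4), a
#' high-threshold fast Kv3-type conductance (`kv3`, p^2) and an inactivating
#' A-type K+ conductance (`kv_a`, a^3 b). `bias_current` sets the
#' depolarizing drive that produces spontaneous firing.
#'
#' @param capacitance membrane capacitance (pF)
#' @param leak list with `g` (nS) and `e` (mV)
#' @param nav,kv_low,kv3,kv_a channel descriptions: lists with maximal
#'   conductance `g` (nS), reversal `e` (mV), and [gate_spec()] entries
#'   `act` (and `inact` for nav/kv_a)
#' @param bias_current constant injected bias (pA)
#' @param q10_rates,q10_conductance temperature sensitivity of gating rates
#'   and of conductances (per 10 degrees C)
#' @param reference_temperature temperature at which the nominal parameters
#'   apply (degrees C)
#' @param label free-form preset label
#' @return a `neuron_model_params` object
#' @export
neuron_model_params <- function(capacitance, leak, nav, kv_low, kv3, kv_a,
                                bias_current = 0, q10_rates = 3,
                                q10_conductance = 1.5,
                                reference_temperature = 24,
                                label = "custom") {
  stopifnot(capacitance > 0, leak$g >= 0,
            nav$g >= 0, kv_low$g >= 0, kv3$g >= 0, kv_a$g >= 0,
            q10_rates > 0, q10_conductance > 0)
  if (kv3$act$vhalf <= kv_low$act$vhalf)
    stop("kv3 must be high-threshold relative to kv_low (vhalf ordering)")
  structure(list(capacitance = capacitance, leak = leak, nav = nav,
                 kv_low = kv_low, kv3 = kv3, kv_a = kv_a,
                 bias_current = bias_current, q10_rates = q10_rates,
                 q10_conductance = q10_conductance,
                 reference_temperature = reference_temperature,
                 label = label),
            class = "neuron_model_params")
}

#' Model presets for the two arcopallial neuron classes
#'
#' Deterministic parameter sets emulating the vocal-motor ("RAPN-like",
#' narrow-spike, Kv3-rich) and non-vocal ("AId-like", broad-spike, Kv3-poor)
#' phenotypes. Capacitance and leak follow the measured passive properties
#' of each class; the RAPN-like preset carries a several-fold larger Kv3
#' conductance, which is the lever behind every narrow-vs-broad contrast the
#' pipeline quantifies. Both presets fire spontaneously at rest.
#'
#' @param name `"RAPN-like"` or `"AId-like"`
#' @return a [neuron_model_params()] object
#' @export
make_preset <- function(name = c("RAPN-like", "AId-like")) {
  name <- match.arg(name)
  common <- list(
    nav_act = gate_spec(-35, 6, tau_base = 0.012, tau_amp = 0.03,
                        tau_vhalf = -40, tau_sigma = 15),
    nav_inact = gate_spec(-48, -5, tau_base = 1.0, tau_amp = 3.0,
                          tau_vhalf = -55, tau_sigma = 12),
    # RAPN delayed rectifier is moderately fast; the AId one below is a
    # slower Kv2-like rectifier that accumulates over spike trains and
    # limits sustained firing
    kvl_act = gate_spec(-35, 8, tau_base = 2.0, tau_amp = 6.0,
                        tau_vhalf = -45, tau_sigma = 20),
    kvl_act_slow = gate_spec(-35, 8, tau_base = 4.0, tau_amp = 12.0,
                             tau_vhalf = -45, tau_sigma = 20),
    kv3_act = gate_spec(-10, 9, tau_base = 0.35, tau_amp = 1.2,
                        tau_vhalf = -10, tau_sigma = 20),
    kva_act = gate_spec(-45, 10, tau_base = 0.3, tau_amp = 0.8,
                        tau_vhalf = -50, tau_sigma = 20),
    kva_inact = gate_spec(-70, -6, tau_base = 30)
  )
  e_na <- 55; e_k <- -90
  if (name == "RAPN-like") {
    neuron_model_params(
      capacitance = 115,
      leak = list(g = 5.7, e = -72),
      nav = list(g = 5200, e = e_na, act = common$nav_act,
                 inact = common$nav_inact),
      kv_low = list(g = 500, e = e_k, act = common$kvl_act),
      kv3 = list(g = 3400, e = e_k, act = common$kv3_act),
      kv_a = list(g = 300, e = e_k, act = common$kva_act,
                  inact = common$kva_inact),
      bias_current = 125, label = name)
  } else {
    neuron_model_params(
      capacitance = 76,
      leak = list(g = 4.8, e = -72),
      nav = list(g = 2400, e = e_na, act = common$nav_act,
                 inact = common$nav_inact),
      kv_low = list(g = 800, e = e_k, act = common$kvl_act_slow),
      kv3 = list(g = 400, e = e_k, act = common$kv3_act),
      kv_a = list(g = 350, e = e_k, act = common$kva_act,
                  inact = common$kva_inact),
      bias_current = 110, label = name)
  }
}

#' Pharmacological effect on the model channel repertoire
#'
#' @param block list of per-conductance block fractions in `[0, 1]` with any
#'   of the names `nav`, `kv_low`, `kv3`, `kv_a`, `leak`
#' @param activation_shift_kv3 shift of the Kv3 activation midpoint (mV);
#'   negative values are leftward
#' @param activation_speedup_kv3 factor (>= 1) dividing the Kv3 activation
#'   time constant
#' @param label drug label
#' @return a `drug_effect` object
#' @export
drug_effect <- function(block = list(), activation_shift_kv3 = 0,
                        activation_speedup_kv3 = 1, label = "custom") {
  block <- as.list(block)
  bad <- setdiff(names(block), c("nav", "kv_low", "kv3", "kv_a", "leak"))
  if (length(bad)) stop("unknown conductance class: ", paste(bad, collapse = ", "))
  fr <- unlist(block)
  if (length(fr) && (any(fr < 0) || any(fr > 1)))
    stop("block fractions must lie in [0, 1]")
  stopifnot(activation_speedup_kv3 >= 1)
  structure(list(block = block,
                 activation_shift_kv3 = activation_shift_kv3,
                 activation_speedup_kv3 = activation_speedup_kv3,
                 label = label),
            class = "drug_effect")
}

#' Built-in drug panel
#'
#' Default effects: sub-millimolar TEA (500 uM) blocks 80% of Kv3 and 50% of
#' the A-type conductance; 100 uM 4-AP blocks 70% of each; AUT5 (1 uM)
#' blocks nothing but left-shifts Kv3 activation by 5 mV and speeds its
#' activation 1.5-fold; "none" is the identity. The block fractions are
#' free parameters of the synthetic preparation, not measured values.
#'
#' @param name one of `"TEA"`, `"4AP"`, `"AUT5"`, `"none"`
#' @return a [drug_effect()] object
#' @export
drug_preset <- function(name = c("TEA", "4AP", "AUT5", "none")) {
  name <- match.arg(name)
  switch(name,
    TEA = drug_effect(block = list(kv3 = 0.8, kv_a = 0.5), label = "TEA"),
    `4AP` = drug_effect(block = list(kv3 = 0.7, kv_a = 0.7), label = "4AP"),
    AUT5 = drug_effect(activation_shift_kv3 = -5,
                       activation_speedup_kv3 = 1.5, label = "AUT5"),
    none = drug_effect(label = "none"))
}

#' Apply a drug effect to model parameters
#'
#' Scales each targeted maximal conductance by `1 - block_fraction`; for
#' AUT5-like modulators, shifts the Kv3 activation midpoint and divides the
#' Kv3 activation time constant by the speedup factor. The input object is
#' not modified.
#'
#' @param params a [neuron_model_params()] object
#' @param effect a [drug_effect()] object
#' @return a new `neuron_model_params` object
#' @export
apply_drug <- function(params, effect) {
  stopifnot(inherits(params, "neuron_model_params"),
            inherits(effect, "drug_effect"))
  out <- params
  for (nm in names(effect$block)) {
    f <- effect$block[[nm]]
    out[[nm]]$g <- out[[nm]]$g * (1 - f)
  }
  if (effect$activation_shift_kv3 != 0) {
    out$kv3$act$vhalf <- out$kv3$act$vhalf + effect$activation_shift_kv3
    out$kv3$act$tau_vhalf <- out$kv3$act$tau_vhalf + effect$activation_shift_kv3
  }
  s <- effect$activation_speedup_kv3
  if (s != 1) {
    out$kv3$act$tau_base <- out$kv3$act$tau_base / s
    out$kv3$act$tau_amp <- out$kv3$act$tau_amp / s
  }
  out$label <- paste0(params$label, "+", effect$label)
  out
}
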