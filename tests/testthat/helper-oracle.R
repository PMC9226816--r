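# Independent transcription of the 2004 epicardial model's current equations,
# written directly from the published formulas as a cross-check oracle for the
# compiled implementation. Deliberately structured differently (one closure
# per current, scalar arithmetic) from the C++ code path.

oracle_tnnp04_currents <- function(s, sKs = 1, sKr = 1, sK1 = 1) {
  R <- 8314.472; Temp <- 310; F <- 96485.3415
  rtf <- R * Temp / F
  Ko <- 5.4; Nao <- 140; Cao <- 2
  V <- s[["Vm"]]; Nai <- s[["Nai"]]; Ki <- s[["Ki"]]; Cai <- s[["Cai"]]

  ena <- rtf * log(Nao / Nai)
  ek  <- rtf * log(Ko / Ki)
  eks <- rtf * log((Ko + 0.03 * Nao) / (Ki + 0.03 * Nai))
  eca <- rtf / 2 * log(Cao / Cai)

  ina <- 14.838 * s[["m"]]^3 * s[["h"]] * s[["j"]] * (V - ena)
  z <- 2 * V / rtf
  ical <- 1.75e-4 * s[["d"]] * s[["f"]] * s[["fCa"]] * 4 * V * F / rtf *
    (Cai * exp(z) - 0.341 * Cao) / (exp(z) - 1)
  ito <- 0.294 * s[["r"]] * s[["s"]] * (V - ek)
  ikr <- sKr * 0.096 * sqrt(Ko / 5.4) * s[["xr1"]] * s[["xr2"]] * (V - ek)
  iks <- sKs * 0.245 * s[["xs"]]^2 * (V - eks)
  a1 <- 0.1 / (1 + exp(0.06 * ((V - ek) - 200)))
  b1 <- (3 * exp(2e-4 * ((V - ek) + 100)) + exp(0.1 * ((V - ek) - 10))) /
    (1 + exp(-0.5 * (V - ek)))
  ik1 <- sK1 * 5.405 * sqrt(Ko / 5.4) * (a1 / (a1 + b1)) * (V - ek)
  inaca <- 1000 *
    (exp(0.35 * V / rtf) * Nai^3 * Cao -
       exp(-0.65 * V / rtf) * Nao^3 * Cai * 2.5) /
    ((87.5^3 + Nao^3) * (1.38 + Cao) * (1 + 0.1 * exp(-0.65 * V / rtf)))
  inak <- 1.362 * Ko * Nai /
    ((Ko + 1) * (Nai + 40) *
       (1 + 0.1245 * exp(-0.1 * V / rtf) + 0.0353 * exp(-V / rtf)))
  ipca <- 0.825 * Cai / (Cai + 0.0005)
  ipk <- 0.0146 * (V - ek) / (1 + exp((25 - V) / 5.98))
  ibna <- 0.00029 * (V - ena)
  ibca <- 0.000592 * (V - eca)

  c(INa = ina, ICaL = ical, Ito = ito, IKr = ikr, IKs = iks, IK1 = ik1,
    INaCa = inaca, INaK = inak, IpCa = ipca, IpK = ipk, IbNa = ibna,
    IbCa = ibca)
}

# a depolarized mid-action-potential state for point checks, obtained by
# stepping the model briefly from rest with a stimulus
midap_state <- function(model = "tnnp2004epi", n = 2500, stim_steps = 50) {
  mod <- get_model(model)
  p <- scaled_params(model = model)
  s <- mod$initial_state()
  for (i in seq_len(n)) s <- mod$step(s, p, if (i <= stim_steps) -30 else 0, 0.02)
  s
}

# short control pacing shared across feature/protocol tests (cached once per
# test session)
.test_env <- new.env()
control_beat_1000 <- function() {
  if (is.null(.test_env$beat1000))
    .test_env$beat1000 <- pace(scaled_params(), bcl = 1000, n_beats = 25)
  .test_env$beat1000
}
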