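# Shared fixtures: small physiologies and closed-form oracles computed
# independently of the package implementation.

# One-compartment closed form written out explicitly (oracle for
# cbfOneCompartment and the generator roundtrip).
oracleCbf <- function(dmOverM0, lambda = 0.9, t1b = 2.1, alphaL = 0.821,
                      alphaBs = 0.95, ld = 1.280, pld = 1.160) {
  6000 * lambda * dmOverM0 * exp(pld / t1b) /
    (2 * alphaL * alphaBs * t1b * (1 - exp(-ld / t1b)))
}

# Davis model written out explicitly.
oracleDavis <- function(m, beta, rf, rv, rm = 1) {
  m * (1 - rm^beta * rv * rf^(-beta))
}

smallBhPhysiology <- function(n = 8) {
  layerPhysiology(n,
    baselineCbf = seq(45, 65, length.out = n),
    davisM = 0.055, davisBeta = 1.10,
    cbfResponse = seq(1.45, 1.32, length.out = n),
    cbvResponse = seq(1.14, 1.19, length.out = n),
    cmro2Response = 1, scenario = "custom")
}

noiseless <- c(asl = 0, vaso = 0, bold = 0)
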