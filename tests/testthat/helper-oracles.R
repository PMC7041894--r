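# Numerical-integration oracle for the per-step log moment of the
# subsampled Gaussian mechanism: log E_{z~nu}[(nu(z)/mu0(z))^lambda] with
# mu0 = N(0, sigma^2), mu1 = N(1, sigma^2), nu the q-mixture.
# Worked in log space (the raw moment overflows double precision for large
# lambda): the integrand's log is computed stably, its mode found, and the
# mode's value factored out before quadrature.
quadLogMoment <- function(q, sigma, lambda) {
    logIntegrand <- function(z) {
        l0 <- dnorm(z, 0, sigma, log = TRUE)
        l1 <- dnorm(z, 1, sigma, log = TRUE)
        m <- pmax(l0, l1)
        lnu <- m + log((1 - q) * exp(l0 - m) + q * exp(l1 - m))
        lnu + lambda * (lnu - l0)
    }
    M <- optimize(logIntegrand, c(-10 * sigma, (lambda + 2) * sigma^2 + 10 * sigma),
                  maximum = TRUE)$objective
    val <- integrate(function(z) exp(logIntegrand(z) - M), -Inf, Inf,
                     rel.tol = 1e-12, abs.tol = 0)$value
    M + log(val)
}
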