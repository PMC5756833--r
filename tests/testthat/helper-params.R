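# Shared fixtures: the Volvox carteri parameterization (M = 10,300 um^3,
# alpha = microgamete volume 80, beta = zygote volume 10,380) and small
# convenience constructors.

volvox_params <- function() survival_params(alpha = 80, beta = 10380)

volvox_config <- function(...) {
  sim_config(M = 10300, params = volvox_params(), ...)
}

# a normalized random frequency vector
random_freq <- function(n) {
  x <- stats::runif(n)
  x / sum(x)
}
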