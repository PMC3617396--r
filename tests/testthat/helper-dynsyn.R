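# shared fixtures built in code

# the 4-neuron, single-pattern hand example: xi = (1,1,0,0), a = 1/2
hand_pattern <- function() {
  structure(list(xi = matrix(c(1L, 1L, 0L, 0L), nrow = 1), a = 0.5,
                 balanced = TRUE),
            class = "pattern_set")
}

dep_synapse <- function(tau_rec = 26) {
  tm_params(U = 1, tau_rec = tau_rec, tau_fac = 0, mode = "depression")
}

static_synapse <- function(U = 1) tm_params(U = U, mode = "static")

# deterministic start for the condensed-pattern mean-field map
mf_pattern_start <- function(params) {
  U0 <- if (params$mode == "depression") 1 else params$U
  c(m_plus = 1, m_minus = 0, x_plus = 1, x_minus = 1,
    u_plus = U0, u_minus = U0)
}
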