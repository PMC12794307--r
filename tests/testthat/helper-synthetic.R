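# Shared fixtures: the two high-b shells of the acquisition protocol and
# forward-model feature generators used across test files.

high_b_shells <- function() {
  prot <- connectom_protocol()
  bs <- vapply(prot$shells, `[[`, numeric(1), "b")
  prot$shells[match(c(6, 30), bs)]
}

# rish_features carrying exact forward-model values (no SH fit)
forward_features <- function(params, shells = high_b_shells(),
                             model = "neumann") {
  lapply(shells, function(s) {
    structure(list(sm = as.numeric(sm_forward(s$grad, params, model)),
                   sv = as.numeric(sv_forward(s$grad, params, model)),
                   b = s$b),
              class = "rish_features")
  })
}

feature_pair <- function(sm, sv, b = c(6, 30)) {
  lapply(1:2, function(i)
    structure(list(sm = sm[i], sv = sv[i], b = b[i]),
              class = "rish_features"))
}

high_b_grads <- function() lapply(high_b_shells(), `[[`, "grad")
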