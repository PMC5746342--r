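# Shared fixtures, built in code.

# a soma-only morphology: the closest thing to a single isopotential
# compartment (perfect space clamp; analytic results are exact)
soma_only_morphology <- function(length = 20, diameter = 20) {
  fsi_morphology(data.frame(id = 1L, parent_id = NA_integer_,
                            type = "soma", length = length,
                            diameter = diameter, stringsAsFactors = FALSE))
}

soma_only_model <- function(leak = leak_spec(1e-4, 5e-5), kir = NULL,
                            config = engine_config()) {
  fsi_model(discretize(soma_only_morphology(), max_len = 25),
            leak = leak, kir = kir, config = config)
}

default_tree <- local({
  tree <- NULL
  function() {
    if (is.null(tree)) tree <<- discretize(build_reduced_fsi(), max_len = 10)
    tree
  }
})

# the calibrated model is the backbone of several acceptance checks and is
# expensive; compute it once per test run
calibrated_fixture <- local({
  cal <- NULL
  function() {
    if (is.null(cal)) cal <<- calibrate_modulated_state(fsi_model(default_tree()))
    cal
  }
})

# temporary file that is cleaned up by the caller's test block
tmpfile <- function(ext = "") tempfile(fileext = ext)
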