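# Shared fixture builders. Everything is generated in code; no data files.

# A tonic profile with known parameters, saturating well below the
# reference dose so the rate at dose -2 is essentially max_evoked_rate.
tonic_profile <- function(baseline = 5, evoked = 200, sens = "Da",
                          odorant = "test-odorant") {
  response_profile(sens, odorant, baseline_rate = baseline,
                   max_evoked_rate = evoked, kernel = "tonic",
                   ec50_dose = -6, hill_coefficient = 1)
}

phasic_profile <- function(baseline = 5, evoked = 200, tau = 0.15) {
  response_profile("Dg", "phasic-odorant", baseline_rate = baseline,
                   max_evoked_rate = evoked, kernel = "phasic",
                   phasic_decay_constant = tau, ec50_dose = -6,
                   hill_coefficient = 1)
}

# Replicate-rate records for a hand-built response matrix: `rates` is a
# named list class -> named numeric vectors are not needed; simplest is a
# matrix of means with one replicate each.
records_from_matrix <- function(m, classes) {
  df <- expand.grid(odorant = rownames(m), sensillum = colnames(m),
                    stringsAsFactors = FALSE)
  df$class <- classes[match(df$odorant, names(classes))]
  df$rate <- m[cbind(df$odorant, df$sensillum)]
  df
}

# A small deterministic response matrix: n odorants x 6 sensilla.
toy_matrix <- function(n = 10, seed = 42) {
  set.seed(seed)
  m <- matrix(round(stats::runif(n * 6, 0, 120), 1), nrow = n,
              dimnames = list(paste0("od", sprintf("%02d", seq_len(n))),
                              names(sensillum_types())))
  classes <- stats::setNames(rep(odorant_classes()[1:5], length.out = n),
                             rownames(m))
  build_response_matrix(records_from_matrix(m, classes))
}

# The default synthetic study matrix, generated once per test run.
study_matrix <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- gen_response_matrix(seed = 20150)
    cache
  }
})
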