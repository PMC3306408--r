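# shared fixtures: truth parameter sets and generated data sets

crs_truth <- c(b = 2, c = 0, d = 100, e = 10, f = 50, a = 1)
bc_truth <- c(b = 2, c = 0, d = 100, e = 10, f = 5)
default_doses <- c(0, 0.1, 0.3, 1, 3, 10, 30, 100)

# noiseless data on the default design (exact truth curve, 2 reps)
noiseless_data <- function(family = "cedergreen", params = crs_truth,
                           doses = default_doses, replicates = 2) {
  simulate_dose_response(family, params, doses, replicates, sd = 0)
}

default_data <- function(seed, family = "cedergreen", params = crs_truth,
                         replicates = 5, weighted = TRUE, ...) {
  d <- suppressWarnings(simulate_dose_response(
    family, params, default_doses, replicates, seed = seed, ...))
  if (weighted) d <- compute_weights(d) else d
}

# minimal hand-built fit object for inference unit tests that only need
# estimates/vcov/df
fake_fit <- function(estimates, ses, df = 20, family = "brain_cousens") {
  V <- diag(ses^2, nrow = length(ses))
  dimnames(V) <- list(names(estimates), names(estimates))
  structure(list(estimates = estimates, vcov = V, df_res = df,
                 fixed = setNames(numeric(0), character(0)),
                 implied = NULL, family = family,
                 model = list(kind = "natural", family = family)),
            class = "hormesis_fit")
}

# mixed BC/CRS truth bank for equivalence checks
truth_bank <- function() {
  crs_grid <- expand.grid(b = c(1.5, 3), f = c(30, 80), a = c(0.5, 1, 2))
  bank <- lapply(seq_len(nrow(crs_grid)), function(i) {
    list(family = "cedergreen",
         params = c(b = crs_grid$b[i], c = 0, d = 100, e = 10,
                    f = crs_grid$f[i], a = crs_grid$a[i]))
  })
  bc_grid <- expand.grid(b = c(1.5, 2, 3), f = c(2, 5, 10))
  bank <- c(bank, lapply(seq_len(nrow(bc_grid)), function(i) {
    list(family = "brain_cousens",
         params = c(b = bc_grid$b[i], c = 0, d = 100, e = 10,
                    f = bc_grid$f[i]))
  }))
  bank
}
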