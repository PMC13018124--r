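## Shared fixtures: the reference model, typical parameter shortcuts and a
## small cached dataset for the estimation tests.

ref_model <- function() population_model()

typ_params <- function(egfr = 84.85, oct2 = "GG", model = ref_model()) {
  typical_parameters(model, list(egfr = egfr, oct2 = oct2))
}

## Lognormally jittered but valid parameter sets for oracle comparisons.
random_params <- function(seed) {
  set.seed(seed)
  m <- ref_model()
  typ <- typ_params()
  eta <- stats::rnorm(6, 0, 0.4)
  p <- typ
  p$tlag <- typ$tlag * exp(eta[1]); p$ka <- typ$ka * exp(eta[2])
  p$cl <- typ$cl * exp(eta[3]); p$v1 <- typ$v1 * exp(eta[4])
  p$q <- typ$q * exp(eta[5]); p$v2 <- typ$v2 * exp(eta[6])
  p
}

## Small single-study dataset shared by the estimation tests (generated once
## per session).
small_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ds <- generate_study_dataset(study_design("study1"), seed = 42)
      cache <<- ds[ds$ID <= 12, ]
    }
    cache
  }
})
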