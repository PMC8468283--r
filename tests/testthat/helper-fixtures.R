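# Shared fixtures built in code: the bundled Australian analysis, fitted once.
aus_fit <- local({
  fit <- NULL
  function() {
    if (is.null(fit)) fit <<- run_pipeline(coi_example_config())
    fit
  }
})

crc_rr <- function() {
  dose_response_rr("colorectal cancer", 0.83, 0.78, 0.89, dose = 90,
                   n_studies = 6)
}

total_cancer_rr <- function() {
  dose_response_rr("total cancer mortality", 0.85, 0.80, 0.91, dose = 90,
                   n_studies = 6)
}

adult_gap <- function() intake_gap(21, 48)

cell_vec <- function(cell) c(cell$central, cell$lower, cell$upper)
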