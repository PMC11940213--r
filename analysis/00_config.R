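# Shared configuration for the numbered analysis scripts. Each script is a
# thin driver over the drgt2map package: run them in order from the
# repository root; every artefact lands under results/.

suppressPackageStartupMessages(library(drgt2map))

RESULTS_DIR <- "results"
STUDY_SEED <- 1L

dir.create(RESULTS_DIR, showWarnings = FALSE, recursive = TRUE)

study_config <- function() {
  pipeline_config(seed = STUDY_SEED, n_phantom_subjects = 4L)
}
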