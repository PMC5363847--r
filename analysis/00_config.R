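## Shared configuration for the analysis workflow.
## Data (FASTA/BED, large) go under scratch/; result tables under results/.

library(nucscan)

SEED <- 1L
DATA_DIR <- "scratch/analysis_data"
RESULTS_DIR <- "results"
DEPTH <- 3e5          # fragments per condition
CHROM_LENGTH <- 1e6
N_GENES <- 20
CONDITIONS <- c(BF = "A", SF = "B")   # display label -> generator condition id

dir.create(DATA_DIR, showWarnings = FALSE, recursive = TRUE)
dir.create(RESULTS_DIR, showWarnings = FALSE, recursive = TRUE)

res_path <- function(f) file.path(RESULTS_DIR, f)
data_path <- function(f) file.path(DATA_DIR, f)
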