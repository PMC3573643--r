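# Shared configuration for the analysis drivers. Every stage is seeded
# explicitly so reruns are byte-identical; outputs accumulate under results/.
suppressPackageStartupMessages({
  library(phyloconflict)
  library(ape)
})

SEED <- 1L
RESULTS <- "results"
DATA_DIR <- file.path(RESULTS, "data")
dir.create(DATA_DIR, recursive = TRUE, showWarnings = FALSE)

# study-like dimensions: an 40-taxon radiation scored for 220 morphological
# characters, a two-class molecular supermatrix (conservative + saturated
# fast class with compositional drift), and a 350-codon protein-coding gene
# with a convergent omega shift in a 3-tip foreground clade
N_TAXA <- 40
N_CHAR <- 220
LEN_SLOW <- 400
LEN_FAST <- 400
N_CODONS <- 350

model_slow <- substitution_model("HKY", rates = c(1, 4, 1, 1, 4, 1),
                                 pi = c(.3, .2, .2, .3))
model_fast <- substitution_model("HKY", rates = c(1, 6, 1, 1, 6, 1),
                                 pi = c(.35, .15, .15, .35))
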