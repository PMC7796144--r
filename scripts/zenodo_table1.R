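#!/usr/bin/env Rscript
# OPTIONAL reproduction of the published variance-partition table and
# whole-data PCA summary on the mice colorectal Raman data set. The data
# are NOT shipped with this package: download the deposit
# (https://zenodo.org/deposit/3975464) and export it to the package's CSV
# layout first:
#
#   response.csv : id, <one column per wavenumber>   (485 x 696 values)
#   design.csv   : id, Individual, Location, P53, Gender
#
#   Rscript scripts/zenodo_table1.R --response response.csv --design design.csv
#
# Prints, for classical ASCA, ASCA+ (deviation) and WE-ASCA: the
# percentage of variance of every effect of the model
#   Individual + Location + P53 + Gender
#     + Location:P53 + Location:Gender + P53:Gender
# and the sum over effects plus residual, plus the PC1/PC2 shares of the
# mean-centred whole-data PCA.

suppressPackageStartupMessages(library(weasca))

args <- commandArgs(trailingOnly = TRUE)
opt <- list()
i <- 1L
while (i <= length(args)) {
  key <- sub("^--", "", args[i])
  opt[[key]] <- args[i + 1L]
  i <- i + 2L
}
if (is.null(opt$response) || is.null(opt$design)) {
  stop("usage: Rscript scripts/zenodo_table1.R --response <csv> --design <csv>")
}

dat <- read_dataset(opt$response, opt$design)
terms <- paste("Individual + Location + P53 + Gender",
               "+ Location:P53 + Location:Gender + P53:Gender")

show <- function(vp, label) {
  cat("\n==", label, "==\n")
  print(vp$table, row.names = FALSE)
  cat("Sum (%):", round(vp$percent_sum, 2), "\n")
}

dec_cl <- classical_asca_decompose(dat$X, dat$design, model_spec(terms))
show(naive_percent_variance(dec_cl), "classical ASCA (naive partition)")

for (coding in c("deviation", "weighted")) {
  vp <- type3_percent_variance(dat$X, dat$design, model_spec(terms, coding))
  show(vp, paste0(coding, " coding (type III partition)"))
}

pca <- whole_data_pca(dat$X, k = 2)
cat("\nWhole-data PCA: PC1 =", round(pca$explained[1], 2),
    "% PC2 =", round(pca$explained[2], 2),
    "% (PC1+PC2 =", round(sum(pca$explained[1:2]), 2), "%)\n")
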