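#!/usr/bin/env Rscript

## Stage 2: classify the drug screen.
##
## Averages replicate viabilities, annotates regimens by mechanism of
## action (taxane-containing = anti-microtubule), bi-clusters the 19 x 5
## viability matrix, and names the three response groups from the MOA-class
## centroids. Writes the assignment, centroid table and MOA partition.

suppressPackageStartupMessages(library(pdoresponse))

data_dir <- "results/data"
out <- "results/02_screen"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

screen <- read.delim(file.path(data_dir, "viability.tsv"))
regimens <- read.delim(file.path(data_dir, "regimens.tsv"))

res <- classify_screen(screen, regimens)

message("response groups: ",
        paste(names(table(res$assignment$group)),
              table(res$assignment$group), sep = "=", collapse = ", "))
message("centroid separation statistic: ", signif(res$separation, 4))
message("resistant flag (viability > 0.75 under ", res$resistant_regimen,
        "): ", sum(res$assignment$resistant_flag), " sample(s)")

write.table(res$assignment, file.path(out, "assignment.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(data.frame(group = rownames(res$centroids), res$centroids,
                       check.names = FALSE),
            file.path(out, "centroids.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(data.frame(regimen = names(res$partition),
                       moa = unname(res$partition)),
            file.path(out, "moa_partition.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
message("data-driven treatment clustering ",
        if (isTRUE(res$treatment_clustering$moa_concordant))
          "matches" else "DIFFERS FROM",
        " the taxane annotation")
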