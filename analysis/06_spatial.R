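#!/usr/bin/env Rscript
# Stage 6 — geography of threat.
#
# Splits gridded richness into threatened (VU/EN/CR) and non-threatened
# (LC/NT) maps using the final (assessed + imputed) statuses, and weights
# richness by EDGE score.

suppressMessages(library(carapace))

out <- "results/spatial"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
tab <- read.delim("results/synthetic/species_table.tsv")
occ <- read.delim("results/synthetic/occupancy.tsv")
imp <- read.delim("results/imputation/imputed_status.tsv")
ed <- read.delim("results/distinctiveness/ed.tsv")

dims <- c(20L, 40L)
O <- matrix(FALSE, nrow(tab), prod(dims),
            dimnames = list(tab$species, NULL))
O[cbind(match(occ$species, tab$species), occ$cell)] <- TRUE
grid <- structure(list(dims = dims, cell_area = 2500, occupancy = O),
                  class = "range_grid")

final <- setNames(tab$status_code, tab$species)
final[imp$species] <- imp$category
lev <- c("LC", "NT", "VU", "EN", "CR", "EX")

thr <- richness_map(grid, final, "threatened")
non <- richness_map(grid, final, "nonthreatened")
et <- edge_table(ed, setNames(lev[final], names(final)))
ew <- edge_weighted_richness(grid, et)
for (nm in c("thr", "non", "ew"))
  write.table(get(nm), file.path(out, paste0("richness_", nm, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)

cat(sprintf("richest threatened cell holds %d species; non-threatened %d\n",
            max(thr), max(non)))
cat(sprintf("partition check (threatened + non-threatened + EX == total): %s\n",
            all(thr + non + richness_map(grid, ifelse(final == 6, 6, 1),
                                         "threatened") * 0 +
                  matrix(colSums(O[final == 6, , drop = FALSE]), dims[1]) ==
                  matrix(colSums(O), dims[1]))))
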