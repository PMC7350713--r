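#!/usr/bin/env Rscript
# Stage 7 — headline summaries.
#
# Final status breakdown (assessed + imputed), the ED-versus-threat
# two-sample test, EDGE ranking of the most distinct-and-endangered
# species, and a collected JSON of the run's key numbers.

suppressMessages(library(carapace))

out <- "results/report"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
tab <- read.delim("results/synthetic/species_table.tsv")
imp <- read.delim("results/imputation/imputed_status.tsv")
ed <- read.delim("results/distinctiveness/ed.tsv")

lev <- c("LC", "NT", "VU", "EN", "CR", "EX")
final <- setNames(tab$status_code, tab$species)
final[imp$species] <- imp$category
status <- setNames(lev[final], names(final))

ss <- status_summary(status, assessed = !tab$masked)
write.table(ss, file.path(out, "status_summary.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("%d%% of species threatened or extinct (%d of %d)\n",
            ss["overall", "pct_threatened_or_extinct"],
            ss["overall", "n_threatened"] + ss["overall", "EX"],
            ss["overall", "n"]))

edv <- setNames(ed$ed, ed$species)[names(status)]
tt <- ed_threat_ttest(edv, status)
cat(sprintf("ED, non-threatened vs threatened: t = %.2f, p = %.3g (medians %.1f vs %.1f Myr)\n",
            tt$t, tt$p_value, tt$median_nonthreatened, tt$median_threatened))

et <- edge_table(ed, status)
top <- rank_edge(et, 10)
write.table(top, file.path(out, "edge_top10.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("top-3 EDGE species:",
    paste(sprintf("%s (%.2f)", top$species[1:3], top$edge[1:3]),
          collapse = ", "), "\n")

jsonlite::write_json(list(
  pct_threatened_or_extinct = ss["overall", "pct_threatened_or_extinct"],
  ed_ttest_t = tt$t, ed_ttest_p = tt$p_value,
  median_ed_nonthreatened = tt$median_nonthreatened,
  median_ed_threatened = tt$median_threatened,
  top_edge_species = top$species[1]),
  file.path(out, "headline.json"), auto_unbox = TRUE, digits = NA)
cat("wrote", file.path(out, "headline.json"), "\n")
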