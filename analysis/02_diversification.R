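#!/usr/bin/env Rscript
# Stage 2 — diversification rates, rate shifts, and mass extinctions.
#
# Fits the constant-rate birth-death model (the empirical-hyperprior step),
# then runs the reversible-jump MCMC over rate-shift and mass-extinction
# events (caps 2 + 2, expected mass-extinction survival 0.05, prior
# concentration 100) and summarizes rates through time and Bayes factors.
# On a constant-rate synthetic tree the expected finding is a flat rate
# profile with no supported events — the same outcome the real turtle and
# crocodilian trees give.

suppressMessages(library(carapace))

seed <- 20260924L
out <- "results/diversification"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
tree <- read_trees("results/synthetic/tree.nwk")[[1]]

fit <- fit_constant_bd(tree)
cat(sprintf("constant-rate ML: lambda = %.4f, mu = %.4f (truth 0.07 / 0.03)\n",
            fit$lambda_hat, fit$mu_hat))

post <- comet_mcmc(tree, n_gen = 20000, thin = 10, seed = seed + 10)
cat("diagnostics: ESS =", paste(round(post$diagnostics$ess), collapse = "/"),
    "| converged:", post$diagnostics$converged, "\n")

rtt <- rates_through_time(post)
write.table(rtt, file.path(out, "rates_through_time.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
bf <- bayes_factors(post)
write.table(bf$me, file.path(out, "bayes_factors_me.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(bf$shift, file.path(out, "bayes_factors_shift.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("posterior P(0 mass extinctions) = %.2f; overall 2lnBF = %.2f\n",
            mean(post$samples$n_me == 0), bf$me_overall$two_ln_bf))
cat(sprintf("median turnover at present: %.2f (truth %.2f)\n",
            rtt$turnover[1], 0.03 / 0.07))
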