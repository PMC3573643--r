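#!/usr/bin/env Rscript
# Stage 6: localizing support. Computes per-site likelihoods for the true
# topology, its NNI alternative at a focal internal branch, and a random
# anchor topology; then partitioned likelihood support and the WSH/AU tests.
source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(),
  value = TRUE))), "00_config.R"))

tree <- sim_tree(8, depth = 0.6, seed = SEED + 2L)
aln <- sim_nucleotide(tree, list(
  list(name = "a", length = 350, model = model_slow, multiplier = 0.4),
  list(name = "b", length = 350, model = model_fast, multiplier = 3)),
  seed = SEED + 2L)

site_ll <- function(topo) {
  fit_tree(topo, aln, substitution_model("HKY", n_cat = 0),
           tol = 1e-4, max_passes = 4)$site_loglik
}
tru <- unroot(tree)
ie <- which(tru$edge[, 1] > Ntip(tru) & tru$edge[, 2] > Ntip(tru))
alts <- alternative_topologies(tru, ie[1])
rand_t <- random_topology(tru$tip.label, seed = SEED)
L <- cbind(true = site_ll(alts$original), nni = site_ll(alts$nni1),
           random = site_ll(rand_t))
slm <- site_likelihood_matrix(L,
  partition = aln$partition_names[aln$partition])
write_site_likelihoods(slm, file.path(RESULTS, "site_likelihoods.tsv"))

pls <- partitioned_support(slm)
tt <- topology_tests(slm, n_boot = 10000, seed = SEED)
pls_out <- data.frame(partition = rownames(pls$pls), pls$pls,
                      check.names = FALSE)
write.table(pls_out, file.path(RESULTS, "pls_table.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(tt, file.path(RESULTS, "topology_tests.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

print(pls)
cat("\n")
print(as.data.frame(tt)[, c("topology", "logLik", "delta", "p_WSH", "p_AU")])
cat(sprintf("\nconflict rule: alternatives count as conflicting at >= %.0f%% bootstrap or >= %.2f posterior\n",
            100 * CONFLICT_BOOTSTRAP, CONFLICT_POSTERIOR))
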