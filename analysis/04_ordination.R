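#!/usr/bin/env Rscript
# Distance-based structure: how regime shifts group by shared drivers and
# drivers by shared regime shifts (UPGMA dendrograms, classical MDS with
# permutation vector fitting of the categorical variable blocks).

suppressPackageStartupMessages(library(rsdnet))
seed <- 1

fx <- load_table1_fixture(canonical = TRUE)
d_shift <- pairwise_distance(fx$network, "shift", "sorensen_dice")
d_driver <- pairwise_distance(fx$network, "driver", "jaccard")
dend_shift <- upgma_cluster(d_shift)
dend_driver <- upgma_cluster(d_driver)
ord <- classical_mds(d_shift, k = 2)
message(sprintf("worked example MDS: first two axes carry %.0f%% of positive inertia",
                100 * sum(ord$proportion_explained)))

# vector fitting needs the categorical variable blocks: synthetic dataset
syn <- generate_rsdb_like(seed)
d_syn <- pairwise_distance(syn$network, "shift", "sorensen_dice")
ord_syn <- classical_mds(d_syn, k = 2)
sa <- syn$attributes[syn$attributes$side == "shift", ]
rownames(sa) <- sa$node_name
fit <- fit_variables(ord_syn, sa[, unlist(syn$blocks)], n_perm = 999,
                     seed = seed + 2)
message(sum(fit$significant), " of ", nrow(fit),
        " categorical variables significantly align with the ordination (p < 0.05)")
blocks <- categorical_block_distance(syn$attributes, syn$blocks)

write_results_bundle(
  c(list(shift_distances = d_shift, driver_distances = d_driver,
         shift_dendrogram = dend_shift, driver_dendrogram = dend_driver,
         mds_coordinates = ord$coordinates,
         fitted_variables = fit),
    stats::setNames(blocks, paste0("blockdist_", names(blocks)))),
  dir = "results/04_ordination", seed = seed,
  config = list(metric_shifts = "sorensen_dice",
                metric_drivers = "jaccard", n_perm = 999))
message("tables, newick trees written to results/04_ordination/")
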