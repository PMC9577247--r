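#!/usr/bin/env Rscript
# Stage 3: hierarchical clustering of samples and of characterisation
# metrics, with Newick dendrogram export and flat cluster assignments.

suppressMessages(library(nanoherit))

cfg <- read_run_config(system.file("extdata", "config.yml",
                                   package = "nanoherit"))
mm_path <- file.path(cfg$output_dir, "metric_matrix.csv")
if (!file.exists(mm_path)) stop("run analysis/01_simulate.R first")

cat("== Stage 3: hierarchical clustering ==\n")
pop <- read_metric_matrix(mm_path)

met_opts <- cfg$clustering$metrics
met_dend <- cluster_metrics(pop, measure = met_opts$measure,
                            linkage = met_opts$linkage)
met_groups <- cut(met_dend, k = met_opts$k)
cat("metric clustering (", met_opts$measure, "distance,",
    met_opts$linkage, "linkage), k =", met_opts$k, ":\n")
for (g in sort(unique(met_groups))) {
  cat("  cluster", g, ":",
      paste(names(met_groups)[met_groups == g], collapse = ", "), "\n")
}
writeLines(to_newick(met_dend),
           file.path(cfg$output_dir, "metric_dendrogram.nwk"))

smp_opts <- cfg$clustering$samples
smp_dend <- cluster_samples(pop, measure = smp_opts$measure,
                            linkage = smp_opts$linkage)
smp_groups <- cut(smp_dend, k = smp_opts$k)
cat("sample clustering (", smp_opts$measure, "/", smp_opts$linkage,
    "), k =", smp_opts$k, ": sizes",
    paste(table(smp_groups), collapse = "/"), "\n")
writeLines(to_newick(smp_dend),
           file.path(cfg$output_dir, "sample_dendrogram.nwk"))

write.csv(
  rbind(
    data.frame(axis = "metric", label = names(met_groups),
               cluster = unname(met_groups)),
    data.frame(axis = "sample", label = names(smp_groups),
               cluster = unname(smp_groups))
  ),
  file.path(cfg$output_dir, "cluster_assignments.csv"), row.names = FALSE
)
cat("wrote dendrograms (.nwk) and cluster_assignments.csv under",
    cfg$output_dir, "\n")
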