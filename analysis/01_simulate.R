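#!/usr/bin/env Rscript
# Stage 1 -- build the synthetic study genome.
#
# A 6-Mb genome (20 x 300 kb chromosomes) with nucleosome-excluding
# barriers placed by a Poisson process (border-to-border spacing mean
# 1541 bp, widths 36-450 bp around a 153-bp mean), AT-rich interiors
# with poly(dA:dT) edges, GC oscillating at the 153-bp repeat length
# in the flanks, statistically positioned dyad tags, patchy
# mappability, and neutral interspecies/intraspecies divergence with
# CpG hypermutability. Later stages regenerate this dataset
# deterministically from the same seed instead of re-reading large
# intermediates.

library(niebtools)

SEED <- 20260922L
dir.create("results", showWarnings = FALSE)

truth <- synth_truth()
ds <- simulate_dataset(truth, n_chrom = 20L, chrom_length = 3e5,
                       seed = SEED)

clen <- chrom_lengths(ds$genome)
cat(sprintf("genome: %d chromosomes, %.1f Mb\n",
            length(clen), sum(clen) / 1e6))
cat(sprintf("barriers: %d (mean width %.1f bp)\n", nrow(ds$catalog),
            mean(ds$catalog$end - ds$catalog$start)))
cat(sprintf("dyad tags: %d (%.2f /bp)\n", sum(ds$tags$count),
            sum(ds$tags$count) / sum(clen)))
cat(sprintf("SNPs: %d (%.1f %% above the 1 %% MAF filter)\n",
            nrow(ds$variants),
            100 * mean(ds$variants$af > truth$maf_min)))

write_bed(ds$catalog, "results/catalog.bed")
write_variants_vcf(ds$variants, "results/variants.vcf")
jsonlite::write_json(list(seed = SEED, truth = unclass(truth)),
                     "results/truth.json", auto_unbox = TRUE,
                     digits = NA)
cat("wrote results/catalog.bed, results/variants.vcf, results/truth.json\n")
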