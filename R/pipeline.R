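# Configuration-driven orchestration of the full analysis:
# simulate -> catalog -> profiles -> ztest -> divergence/selection,
# with per-stage logging, derived seeds and a run manifest.

#' Default pipeline configuration
#'
#' Every numeric parameter of every stage, with defaults equal to the
#' reference analysis values (width bounds 36/450 bp, 300-bp flanks,
#' n > 30, z threshold 1.645, large-region cutoff 800 bp, central
#' span +/-300 bp, 10-bp windows, 10000 bootstrap repetitions, 95 %
#' confidence, 1 % MAF, 70-bp dyad shift, 270-bp flank span, spacing
#' comb 117 + 153k, and the 100-kb window class cut points).
#'
#' @return nested named list.
#' @export
default_config <- function() {
    list(
        seed = 1L,
        simulate = list(enabled = TRUE, n_chrom = 20L,
                        chrom_length = 3e5, coverage = 0.3,
                        dyad_mode = "positioned",
                        truth = unclass(synth_truth())),
        tags = list(dyad_shift = 70L),
        catalog = list(enabled = TRUE, min_width = 36L, max_width = 450L,
                       n_run_min = 100L, fit_d_min = 1000,
                       period = 153, comb_offset = 117,
                       n_max = 5L, d_crystal = 800, flank_span = 270L,
                       gc_cuts = c(0.38, 0.42, 0.47, 0.52),
                       mrt_cuts = c(0.36, 0.69),
                       dnase_cuts = c(14.3, 29.3),
                       recomb_cuts = c(0.378, 1.681)),
        profiles = list(enabled = TRUE, max_in = 225L, max_out = 1000L,
                        smooth = 10L, heatmap_group = 200L,
                        heatmap_halfwidth = 800L),
        ztest = list(enabled = TRUE, flank = 300L, threshold = 1.645,
                     min_n = 30L),
        divergence = list(enabled = TRUE, max_out = 1000L,
                          maf_min = 0.01, cpg_strand_symmetric = TRUE,
                          l_min = 800L, center_halfwidth = 300L,
                          boot_window = 10L, reps = 10000L,
                          conf = 0.95),
        io = list(write_alignment = FALSE))
}

# recursive unknown-key validation against the default skeleton
.check_config <- function(cfg, ref = default_config(), path = "") {
    unknown <- setdiff(names(cfg), names(ref))
    if (length(unknown))
        stop("unknown configuration key(s): ",
             paste0(path, unknown, collapse = ", "))
    for (k in names(cfg)) {
        if (is.list(ref[[k]]) && !is.null(names(ref[[k]])) &&
            k != "truth") {
            if (!is.list(cfg[[k]]))
                stop("configuration key ", path, k, " must be a list")
            .check_config(cfg[[k]], ref[[k]], paste0(path, k, "$"))
        }
    }
    invisible(TRUE)
}

#' Merge user overrides into the default configuration
#'
#' Unknown keys are rejected rather than silently ignored.
#'
#' @param overrides nested list of overrides.
#' @return complete validated configuration.
#' @export
pipeline_config <- function(overrides = list()) {
    .check_config(overrides)
    merge2 <- function(base, over) {
        for (k in names(over)) {
            if (is.list(base[[k]]) && is.list(over[[k]]) && k != "truth")
                base[[k]] <- merge2(base[[k]], over[[k]])
            else base[[k]] <- over[[k]]
        }
        base
    }
    merge2(default_config(), overrides)
}

.stage_log <- function(quiet, ...) if (!quiet) message("[niebtools] ", ...)

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order on a synthetic
#' dataset, writes per-stage artifacts under `outdir` and returns (and
#' writes) a run manifest with the effective configuration, per-file
#' checksums, record counters and wall-clock per stage. Stage seeds
#' are derived from the configured seed (`seed` for the simulation,
#' `seed + 1` for the bootstrap), so toggling one stochastic stage
#' never changes another's output.
#'
#' @param config configuration from [pipeline_config()].
#' @param outdir output directory (created).
#' @param quiet suppress progress messages.
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir, quiet = FALSE) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    manifest <- list(package_version =
                         as.character(utils::packageVersion("niebtools")),
                     config = config, stages = list())
    files <- character(0)
    tic <- function() proc.time()[["elapsed"]]
    counters <- list()

    ## -- simulate ---------------------------------------------------
    stopifnot(isTRUE(config$simulate$enabled)) # source of all inputs
    t0 <- tic()
    .stage_log(quiet, "simulate: ", config$simulate$n_chrom, " x ",
               config$simulate$chrom_length, " bp")
    truth <- do.call(synth_truth, config$simulate$truth)
    ds <- simulate_dataset(truth, config$simulate$n_chrom,
                           config$simulate$chrom_length,
                           seed = config$seed,
                           coverage = config$simulate$coverage,
                           dyad_mode = config$simulate$dyad_mode)
    clen <- chrom_lengths(ds$genome)
    write_genome_fasta(ds$genome, file.path(outdir, "genome.fa"))
    write_bed(ds$catalog, file.path(outdir, "catalog.bed"))
    fwrite(ds$tags, file.path(outdir, "tags.tsv"), sep = "\t")
    write_variants_vcf(ds$variants, file.path(outdir, "variants.vcf"))
    if (isTRUE(config$io$write_alignment))
        write_alignment_tsv(ds$aln, file.path(outdir, "alignment.tsv"))
    files <- c(files, "genome.fa", "catalog.bed", "tags.tsv",
               "variants.vcf")
    counters$simulate <- list(barriers = nrow(ds$catalog),
                              tags = sum(ds$tags$count),
                              snps = nrow(ds$variants))
    manifest$stages$simulate <- list(seconds = tic() - t0)

    ## -- catalog ----------------------------------------------------
    if (isTRUE(config$catalog$enabled)) {
        t0 <- tic()
        cc <- config$catalog
        cat_f <- filter_widths(ds$catalog, cc$min_width, cc$max_width)
        regions <- internieb_regions(cat_f, ds$genome, cc$n_run_min)
        fit <- fit_exponential_tail(regions$d, cc$fit_d_min)
        comb <- detect_quantized_peaks(regions$d)
        cov <- coverage_accounting(cat_f, regions, ds$genome,
                                   flank_span = cc$flank_span,
                                   period = cc$period,
                                   offset = cc$comb_offset,
                                   n_max = cc$n_max,
                                   d_crystal = cc$d_crystal)
        hist_dt <- data.table(d = seq_len(2000),
                              count = tabulate(regions$d, nbins = 2000))
        fwrite(hist_dt, file.path(outdir, "spacing_histogram.tsv"),
               sep = "\t")
        jsonlite::write_json(list(fit = fit[c("mean", "se", "n", "d_min")],
                                  comb = comb, coverage = cov),
                             file.path(outdir, "spacing.json"),
                             auto_unbox = TRUE, digits = NA)
        files <- c(files, "spacing_histogram.tsv", "spacing.json")
        counters$catalog <- list(barriers = nrow(cat_f),
                                 regions = nrow(regions),
                                 discarded_width =
                                     attr(cat_f, "discarded"),
                                 dropped_unsequenced =
                                     attr(regions, "dropped_unsequenced"))
        manifest$stages$catalog <- list(seconds = tic() - t0)
    }

    ## -- profiles ---------------------------------------------------
    if (isTRUE(config$profiles$enabled)) {
        t0 <- tic()
        pc <- config$profiles
        offs <- catalog_offsets(ds$catalog, clen, pc$max_out)
        keep <- lapply(ds$genome, function(g) charToRaw(g$seq) != .RAW_N)
        gc_track <- lapply(ds$genome, function(g) {
            r <- charToRaw(g$seq)
            as.numeric(r == .RAW_G | r == .RAW_C)
        })
        names(gc_track) <- names(ds$genome)
        gc_prof <- aggregate_profile(gc_track, offs, pc$max_in,
                                     pc$max_out, keep = keep)
        tag_track <- lapply(names(clen), function(ch)
            as.numeric(dense_tags(ds$tags, ch, clen[[ch]])))
        names(tag_track) <- names(clen)
        dens_prof <- aggregate_profile(tag_track, offs, pc$max_in,
                                       pc$max_out,
                                       keep = lapply(ds$mappability,
                                                     identity),
                                       normalize = TRUE)
        fwrite(data.table(offset = gc_prof$offset, gc = gc_prof$mean,
                          gc_count = gc_prof$count,
                          density = dens_prof$mean,
                          density_count = dens_prof$count),
               file.path(outdir, "border_profiles.tsv"), sep = "\t")
        regions <- internieb_regions(ds$catalog)
        hm <- build_heatmap(regions, tags = ds$tags, chrom_len = clen,
                            group_size = pc$heatmap_group,
                            display_halfwidth = pc$heatmap_halfwidth)
        hm_dt <- as.data.table(hm$matrix)
        setnames(hm_dt, as.character(hm$offsets))
        fwrite(hm_dt, file.path(outdir, "heatmap.tsv"), sep = "\t")
        files <- c(files, "border_profiles.tsv", "heatmap.tsv")
        manifest$stages$profiles <- list(seconds = tic() - t0)
    }

    ## -- ztest ------------------------------------------------------
    if (isTRUE(config$ztest$enabled)) {
        t0 <- tic()
        zc <- config$ztest
        zin <- ztest_inputs(ds$catalog, ds$tags, ds$mappability, clen,
                            zc$flank)
        zres <- ztest_classify(zin, zc$threshold, zc$min_n)
        summ <- group_summary(zres)
        fwrite(zres, file.path(outdir, "ztest.tsv"), sep = "\t")
        jsonlite::write_json(summ, file.path(outdir, "ztest_summary.json"),
                             auto_unbox = TRUE, digits = NA)
        files <- c(files, "ztest.tsv", "ztest_summary.json")
        counters$ztest <- list(tested = summ$n_tested,
                               excluded = summ$n_excluded)
        manifest$stages$ztest <- list(seconds = tic() - t0)
    }

    ## -- divergence / selection ------------------------------------
    if (isTRUE(config$divergence$enabled)) {
        t0 <- tic()
        dc <- config$divergence
        tab <- divergence_tables(ds$aln, ds$catalog, clen, ds$variants,
                                 max_out = dc$max_out,
                                 maf_min = dc$maf_min,
                                 cpg_strand_symmetric =
                                     dc$cpg_strand_symmetric,
                                 l_min = dc$l_min,
                                 center_halfwidth = dc$center_halfwidth,
                                 boot_window = dc$boot_window)
        bg <- background_rates(tab)
        sel <- selection_profile(tab, bg, bin = dc$boot_window)
        set.seed(config$seed + 1L)
        bn <- bootstrap_null(tab, bg, reps = dc$reps, conf = dc$conf)
        gc_eq <- equilibrium_gc_profile(tab)
        fwrite(rate_profile(tab, "inter"),
               file.path(outdir, "rates_inter.tsv"), sep = "\t")
        fwrite(rate_profile(tab, "intra"),
               file.path(outdir, "rates_intra.tsv"), sep = "\t")
        sel2 <- merge(sel, bn$limits, by = "change")
        fwrite(sel2, file.path(outdir, "selection.tsv"), sep = "\t")
        fwrite(gc_eq, file.path(outdir, "equilibrium_gc.tsv"), sep = "\t")
        jsonlite::write_json(
            list(seed = config$seed + 1L, reps = dc$reps,
                 conf = dc$conf, maf_min = dc$maf_min,
                 l_min = dc$l_min, n_large = tab$n_large,
                 background = bg),
            file.path(outdir, "divergence_manifest.json"),
            auto_unbox = TRUE, digits = NA, dataframe = "columns")
        files <- c(files, "rates_inter.tsv", "rates_intra.tsv",
                   "selection.tsv", "equilibrium_gc.tsv",
                   "divergence_manifest.json")
        counters$divergence <- list(inter_events = sum(tab$interA),
                                    intra_events = sum(tab$intraX),
                                    n_large = tab$n_large)
        manifest$stages$divergence <- list(seconds = tic() - t0)
    }

    manifest$counters <- counters
    manifest$checksums <- as.list(tools::md5sum(file.path(outdir, files)))
    names(manifest$checksums) <- files
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    .stage_log(quiet, "done: ", length(files), " artifact(s) in ", outdir)
    invisible(manifest)
}
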