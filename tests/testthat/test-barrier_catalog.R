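test_that("width filtering keeps the configured range and logs discards", {
    cat_ <- data.frame(chrom = "c1", start = c(0L, 200L, 1000L),
                       end = c(100L, 660L, 1036L)) # widths 100, 460, 36
    f <- filter_widths(cat_)
    expect_equal(f$end - f$start, c(100L, 36L))
    expect_equal(attr(f, "discarded"), 1L)
    expect_equal(nrow(filter_widths(cat_[0, ])), 0L)
    allin <- filter_widths(cat_[c(1, 3), ])
    expect_equal(nrow(allin), 2L)
})

test_that("interdistances are border-to-border and drop unsequenced gaps", {
    cat_ <- data.frame(chrom = "c1", start = c(0L, 250L),
                       end = c(100L, 400L))
    expect_equal(interdistances(cat_), 150L)
    expect_length(interdistances(data.frame(chrom = "c1", start = 0L,
                                            end = 100L)), 0L)
    # a gap containing a long N run is discarded
    seqs <- paste0(strrep("A", 100), strrep("N", 150), strrep("C", 150))
    g <- genome_sequence(c(c1 = seqs))
    d <- interdistances(cat_, g, n_run_min = 100L)
    expect_length(d, 0L)
    d2 <- interdistances(cat_, g, n_run_min = 200L)
    expect_equal(d2, 150L)
})

test_that("exponential tail fit recovers a truncated exponential mean", {
    set.seed(202)
    draws <- rexp(4e5, 1 / 1500)
    fit <- fit_exponential_tail(draws, d_min = 1000)
    expect_lt(abs(fit$mean - 1500) / 1500, 0.02)
    expect_lt(abs(fit$mean - 1500), 3 * fit$se)
    # d_min = 0: MLE equals the sample mean
    x <- rexp(5000, 1 / 800)
    f0 <- fit_exponential_tail(x, 0)
    expect_equal(f0$mean, mean(x))
    expect_true(suppressWarnings(
        fit_exponential_tail(rep(5, 50), 0))$degenerate)
    expect_warning(fit_exponential_tail(rep(5, 50), 0), "100")
})

test_that("comb detection finds quantized spacings and stays silent on exponentials", {
    set.seed(7)
    ds <- c(rep(117 + 153 * (0:4), times = 400),
            sample.int(1000, 1500, replace = TRUE))
    pk <- detect_quantized_peaks(ds)
    expect_true(pk$significant)
    expect_equal(pk$offset, 117L)
    expect_equal(pk$period, 153L)
    ds_exp <- round(rexp(20000, 1 / 400))
    pk2 <- detect_quantized_peaks(ds_exp)
    expect_false(pk2$significant)
    expect_true(is.na(pk2$offset))
    # grid excluding the true period still returns an in-grid value or NA
    pk3 <- detect_quantized_peaks(ds, periods = 120:140)
    expect_true(is.na(pk3$period) || pk3$period %in% 120:140)
})

test_that("nucleosome-class assignment follows the comb and is monotone", {
    expect_equal(classify_internieb(117), 1L)
    expect_equal(classify_internieb(423), 3L)
    expect_true(is.na(classify_internieb(801)))
    expect_equal(classify_internieb(800), 5L)
    d <- 1:800
    n <- classify_internieb(d)
    expect_true(all(diff(n) >= 0L))
    expect_error(classify_internieb(0))
})

test_that("coverage accounting keeps components disjoint and bounded", {
    # one barrier of 153 bp in a 1000 bp sequenced genome: 15.3 %
    cat1 <- data.frame(chrom = "c1", start = 100L, end = 253L)
    reg1 <- internieb_regions(cat1)
    cov1 <- coverage_accounting(cat1, reg1, seq_len_total = 1000)
    expect_equal(cov1$barrier_pct, 15.3)
    expect_equal(cov1$crystal_bp + cov1$flank_bp, 0)
    # no barriers
    cat0 <- data.frame(chrom = character(), start = integer(),
                       end = integer())
    cov0 <- coverage_accounting(cat0, internieb_regions(cat0),
                                seq_len_total = 1000)
    expect_equal(cov0$total_bp, 0)
    # components never exceed the sequenced length on synthetic catalogs
    set.seed(12)
    ds <- simulate_dataset(synth_truth(), n_chrom = 2L,
                           chrom_length = 2e5, seed = 12,
                           with_divergence = FALSE, with_dyads = FALSE)
    reg <- internieb_regions(ds$catalog, ds$genome)
    cov <- coverage_accounting(ds$catalog, reg, ds$genome)
    expect_lte(cov$total_bp, cov$sequenced_bp)
    expect_gt(cov$barrier_pct, 5)
})

test_that("window stratification classifies covariates and conserves density", {
    set.seed(31)
    ds <- simulate_dataset(synth_truth(), n_chrom = 4L,
                           chrom_length = 3e5, seed = 31,
                           with_divergence = FALSE, with_dyads = FALSE)
    clen <- chrom_lengths(ds$genome)
    win <- data.table::rbindlist(lapply(names(clen), function(ch)
        data.table::data.table(chrom = ch,
                               start = seq(0L, clen[[ch]] - 1e5, by = 1e5))))
    win$end <- win$start + 1e5L
    n <- nrow(win)
    win$gc <- runif(n, 0.30, 0.60)
    win$mrt <- runif(n)
    win$dnase <- runif(n, 0, 60)
    win$recomb <- runif(n, 0, 4)
    ws <- window_stratification(ds$catalog, win)
    # Table-style class edges
    expect_equal(as.character(ws$windows$gc_class[
        which(abs(win$gc - 0.39) == min(abs(win$gc - 0.39)))[1]]),
        c("L1", "L2", "H1", "H2", "H3")[
            findInterval(win$gc[which.min(abs(win$gc - 0.39))],
                         c(0.38, 0.42, 0.47, 0.52)) + 1])
    w2 <- data.frame(chrom = "c9", start = 0L, end = 1e5L, gc = 0.39,
                     mrt = 0.36)
    ws2 <- window_stratification(ds$catalog[0, ], w2)
    expect_equal(as.character(ws2$windows$gc_class), "L2")
    expect_equal(as.character(ws2$windows$mrt_class), "medium")
    # conservation: pooled density over classes equals genome density
    gsum <- ws$summary[ws$summary$dimension == "gc_class", ]
    genome_density <- sum(ws$windows$n_nieb) /
        sum(ws$windows$width / 1e3)
    pooled <- sum(gsum$density * table(ws$windows$gc_class)[gsum$class]) /
        sum(table(ws$windows$gc_class))
    expect_equal(weighted.mean(gsum$density,
                               as.numeric(table(ws$windows$gc_class))),
                 genome_density, tolerance = 1e-10)
    # uniform placement: class densities agree within sampling error
    expect_lt(diff(range(gsum$density)), 0.35)
})

test_that("feature overlap profile sees constructed exclusion and uniform flatness", {
    set.seed(8)
    ds <- simulate_dataset(synth_truth(), n_chrom = 2L,
                           chrom_length = 2e5, seed = 8,
                           with_divergence = FALSE, with_dyads = FALSE)
    clen <- chrom_lengths(ds$genome)
    # anchors placed in barrier-free stretches: coverage 0 at offset 0
    reg <- internieb_regions(ds$catalog)
    big <- reg[reg$d > 1200, ]
    anchors <- data.frame(chrom = big$chrom,
                          pos = (big$start + big$end) %/% 2L)
    pr <- feature_overlap_profile(ds$catalog, anchors, clen,
                                  max_offset = 300L)
    expect_equal(pr$coverage[pr$offset == 0], 0)
    # uniform anchors: flat profile near the genome-average coverage
    anchors_u <- data.frame(
        chrom = sample(names(clen), 3000, replace = TRUE),
        pos = sample.int(2e5 - 1L, 3000, replace = TRUE))
    pru <- feature_overlap_profile(ds$catalog, anchors_u, clen,
                                   max_offset = 100L)
    gcov <- sum(ds$catalog$end - ds$catalog$start) / sum(clen)
    expect_lt(max(abs(pru$coverage - gcov)), 0.05)
    empty <- feature_overlap_profile(ds$catalog,
                                     anchors_u[0, ], clen)
    expect_equal(nrow(empty), 0L)
})
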