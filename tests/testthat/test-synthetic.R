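# The generator's contract: reproducibility, target composition,
# positioning phenomenology, mappability and frequency-law behavior.

test_that("generation is bit-reproducible from (truth, seed)", {
    a <- simulate_dataset(synth_truth(), n_chrom = 2L,
                          chrom_length = 1e5, seed = 99L)
    b <- simulate_dataset(synth_truth(), n_chrom = 2L,
                          chrom_length = 1e5, seed = 99L)
    expect_identical(a$catalog, b$catalog)
    expect_identical(vapply(a$genome, `[[`, "", "seq"),
                     vapply(b$genome, `[[`, "", "seq"))
    expect_identical(a$tags, b$tags)
    expect_identical(a$variants, b$variants)
    expect_identical(a$aln[[1]]$h, b$aln[[1]]$h)
})

test_that("no barriers are produced at zero placement rate", {
    tr <- synth_truth(gap_mean = 1e12)
    g <- generate_genome(tr, 1L, 1e5, seed = 1L)
    expect_equal(nrow(g$catalog), 0L)
    tags <- simulate_dyads(tr, g$catalog, chrom_lengths(g$genome),
                           coverage = 0.2, seed = 2L)
    # flat density away from chromosome-end anchoring
    x <- dense_tags(tags, "chr01", 1e5)
    mid <- x[20000:80000]
    expect_lt(abs(mean(mid) - 0.2), 0.02)
})

test_that("composition targets are met: spacing, widths, GC levels", {
    ds <- simulate_dataset(synth_truth(), n_chrom = 10L,
                           chrom_length = 3e5, seed = 41L,
                           with_divergence = FALSE, with_dyads = FALSE)
    w <- ds$catalog$end - ds$catalog$start
    expect_true(all(w >= 36 & w <= 450))
    expect_lt(abs(mean(w) - 153) / 153, 0.05)
    d <- interdistances(ds$catalog, ds$genome)
    fit <- fit_exponential_tail(d, 0)
    expect_lt(abs(fit$mean - 1541), 3 * fit$se)
    clen <- chrom_lengths(ds$genome)
    gcin <- nin <- gcfl <- nfl <- 0
    for (ch in names(clen)) {
        r <- charToRaw(ds$genome[[ch]]$seq)
        gc <- r == charToRaw("G") | r == charToRaw("C")
        sub <- ds$catalog[ds$catalog$chrom == ch, ]
        off <- border_offsets(sub$start, sub$end, clen[[ch]], 1500L)
        i <- !is.na(off$offset) & off$offset < 0
        f <- !is.na(off$offset) & off$offset >= 1 & off$offset <= 300
        gcin <- gcin + sum(gc[i]); nin <- nin + sum(i)
        gcfl <- gcfl + sum(gc[f]); nfl <- nfl + sum(f)
    }
    expect_lt(abs(gcin / nin - 0.265), 0.01)   # barrier GC target
    expect_lt(abs(gcfl / nfl - 0.425), 0.01)   # flanking 300 bp target
    # poly(dA:dT) edges: elevated A/T-run coverage at the borders
    offs <- catalog_offsets(ds$catalog, clen, 300L)
    pp <- polynucleotide_profile(ds$genome, offs, k = 5L,
                                 use_mask = FALSE, max_out = 300L)
    edge <- pp[pp$offset %in% -8:-2, ]
    bulk <- pp[pp$offset %in% 200:300, ]
    expect_gt(mean(edge$mean), 3 * mean(bulk$mean))
})

test_that("dyads vanish inside barriers and peak one footprint out", {
    set.seed(1)
    tr <- synth_truth()
    gg <- generate_genome(tr, 2L, 3e5)
    clen <- chrom_lengths(gg$genome)
    tags <- simulate_dyads(tr, gg$catalog, clen, coverage = 0.4)
    offs <- catalog_offsets(gg$catalog, clen, 600L)
    trk <- lapply(names(clen), function(ch)
        as.numeric(dense_tags(tags, ch, clen[[ch]])))
    names(trk) <- names(clen)
    pr <- aggregate_profile(trk, offs, normalize = TRUE)
    agg_in <- with(pr[pr$offset < 0, ],
                   sum(mean * count, na.rm = TRUE) /
                       sum(count[!is.na(mean)]))
    expect_lt(agg_in, 0.3)                   # depletion 0.15 plus jitter
    sm <- smooth_profile(pr, 10L)
    w1 <- sm$offset %in% 55:100
    expect_equal(sm$offset[w1][which.max(sm$mean[w1])], 76,
                 tolerance = 8)              # first dyad near border+74
    w2 <- sm$offset %in% 180:280
    p2 <- sm$offset[w2][which.max(sm$mean[w2])]
    expect_lt(abs(p2 - (76 + 153)), 25)      # second peak one NRL on
})

test_that("mappability gaps exclude exactly the covered barriers", {
    tr0 <- synth_truth(map_gap_rate = 0)
    mp0 <- simulate_mappability(tr0, c(c1 = 1e5), seed = 5L)
    expect_true(all(mp0$c1))
    tr <- synth_truth(map_gap_rate = 5e-4, map_gap_mean = 300)
    mp <- simulate_mappability(tr, c(c1 = 1e5), seed = 5L)
    frac <- mean(!mp$c1)
    expect_lt(abs(frac - 5e-4 * 300) / (5e-4 * 300), 0.5)
    # deterministic gap over one barrier excludes exactly that barrier
    cat_ <- data.frame(chrom = "c1", start = c(100L, 1000L),
                       end = c(300L, 1200L))
    mpd <- list(c1 = rep(TRUE, 2000L))
    mpd$c1[101:300] <- FALSE
    tags <- data.table::data.table(chrom = "c1",
                                   pos = seq(0L, 1999L, by = 2L),
                                   count = 1L)
    r <- ztest_classify(ztest_inputs(cat_, tags, mpd, c(c1 = 2000L)))
    expect_equal(as.character(r$group[1]), "excluded")
    expect_false(as.character(r$group[2]) == "excluded")
})

test_that("the allele-frequency law leaves most SNPs under the MAF filter", {
    tr <- synth_truth()
    q <- pbeta(tr$maf_min, tr$af_shape1, tr$af_shape2,
               lower.tail = FALSE)
    expect_lt(q, 0.25)                       # most mass below 1 %
    ds <- simulate_dataset(tr, n_chrom = 4L, chrom_length = 3e5,
                           seed = 13L, with_dyads = FALSE)
    frac_qual <- mean(ds$variants$af > tr$maf_min)
    expect_lt(abs(frac_qual - q), 0.02)
    # interspecies intensity off -> no events
    tr0 <- synth_truth(inter_ts = 0, inter_tv = 0, snp_qual_scale = 0)
    dv <- simulate_divergence(tr0,
                              generate_genome(tr0, 1L, 5e4, seed = 3)$genome,
                              data.frame(chrom = character(),
                                         start = integer(),
                                         end = integer()), seed = 4)
    expect_equal(dv$truth_events$n_inter, 0L)
    expect_equal(nrow(dv$variants), 0L)
})

test_that("injected interspecies selection shows up only where injected", {
    tr <- synth_truth(selection = list(changes = c("C>A", "C>T",
                                                   "G>A", "G>T"),
                                       mult = 3, where = "inside"))
    ds <- simulate_dataset(tr, n_chrom = 4L, chrom_length = 3e5,
                           seed = 17L, with_dyads = FALSE)
    clen <- chrom_lengths(ds$genome)
    tab <- divergence_tables(ds$aln, ds$catalog, clen, ds$variants)
    rp <- rate_profile(tab, "inter")
    sw <- rp[rp$change %in% c("C>A", "C>T", "G>A", "G>T"), ]
    rate_in <- sum(sw$events[sw$offset < 0]) /
        sum(sw$eligible[sw$offset < 0])
    rate_out <- sum(sw$events[sw$offset > 300]) /
        sum(sw$eligible[sw$offset > 300])
    expect_gt(rate_in / rate_out, 2)
    ww <- rp[rp$change %in% c("A>T", "T>A"), ]
    rin <- sum(ww$events[ww$offset < 0]) / sum(ww$eligible[ww$offset < 0])
    rout <- sum(ww$events[ww$offset > 300]) /
        sum(ww$eligible[ww$offset > 300])
    expect_lt(abs(rin / rout - 1), 0.5)      # untouched classes stay flat
})
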