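# Border-aligned aggregation, smoothing, symmetrization, heat maps,
# polynucleotide and TSS profiles.

make_world <- function(seed = 21, n_chrom = 2L, len = 2e5) {
    simulate_dataset(synth_truth(), n_chrom = n_chrom,
                     chrom_length = len, seed = seed,
                     with_divergence = FALSE, with_dyads = FALSE)
}

test_that("offset assignment matches a brute-force scan", {
    set.seed(77)
    starts <- c(50L, 300L, 1000L)
    ends <- c(120L, 420L, 1400L)
    off <- border_offsets(starts, ends, 2000L, max_out = 400L)
    for (p in c(0L, 49L, 50L, 85L, 119L, 120L, 200L, 210L, 299L,
                sample.int(2000L, 60L) - 1L)) {
        bo <- brute_offset(p, starts, ends)
        o <- bo$offset
        if (!is.na(o) && o > 400L) o <- NA
        expect_identical(off$offset[p + 1L], as.integer(o),
                         label = paste("offset at", p))
        if (!is.na(o))
            expect_identical(off$side[p + 1L], bo$side,
                             label = paste("side at", p))
    }
    none <- border_offsets(integer(0), integer(0), 100L)
    expect_true(all(is.na(none$offset)))
})

test_that("aggregate conserves mass, normalizes, and separates regions", {
    ds <- make_world()
    clen <- chrom_lengths(ds$genome)
    offs <- catalog_offsets(ds$catalog, clen, 1000L)
    # uniform track normalizes to 1 everywhere
    ones <- lapply(clen, function(L) rep(2.5, L))
    pr1 <- aggregate_profile(ones, offs, normalize = TRUE)
    expect_true(all(abs(pr1$mean[pr1$count > 0] - 1) < 1e-12))
    # mass conservation without normalization
    set.seed(5)
    trk <- lapply(clen, function(L) rpois(L, 0.2))
    pr <- aggregate_profile(trk, offs)
    in_axis <- sum(unlist(lapply(names(clen), function(ch) {
        o <- offs[[ch]]$offset
        sum(trk[[ch]][!is.na(o) & o >= -225 & o <= 1000])
    })))
    expect_equal(sum(pr$mean * pr$count, na.rm = TRUE), in_axis)
    # statistic confined to barrier interiors
    inside_trk <- lapply(names(clen), function(ch) {
        o <- offs[[ch]]$offset
        as.numeric(!is.na(o) & o < 0)
    })
    names(inside_trk) <- names(clen)
    pr_in <- aggregate_profile(inside_trk, offs)
    expect_true(all(pr_in$mean[pr_in$offset < 0 & pr_in$count > 0] == 1))
    expect_true(all(pr_in$mean[pr_in$offset > 0 & pr_in$count > 0] == 0))
    # zero average cannot normalize
    zero <- lapply(clen, function(L) numeric(L))
    expect_error(aggregate_profile(zero, offs, normalize = TRUE), "zero")
})

test_that("smoothing is a count-weighted moving average with end shrink", {
    prof <- niebtools:::.new_profile(
        offset = c(-5:-1, 1:45),
        sum = c(rep(0, 25), rep(1, 25)),
        count = rep(1, 50), max_in = 5L, max_out = 45L)
    expect_equal(smooth_profile(prof, 1L), prof)
    sm <- smooth_profile(prof, 10L)
    ramp <- sm$mean[sm$offset %in% 16:25]
    expect_true(all(diff(ramp) > 0))             # linear ramp of width 10
    expect_equal(max(diff(ramp)), 0.1, tolerance = 1e-12)
    const <- niebtools:::.new_profile(1:50, rep(2, 50), rep(1, 50),
                                      0L, 50L)
    expect_equal(smooth_profile(const, 10L)$mean, rep(2, 50))
    # mean preserved under full counts (up to axis-end shrinkage)
    expect_equal(mean(smooth_profile(prof, 4L)$mean), mean(prof$mean),
                 tolerance = 0.05)
    expect_error(smooth_profile(prof, 0L), "window")
})

test_that("symmetrization pools by counts and is idempotent on symmetric input", {
    a <- niebtools:::.new_profile(1:10, 1:10, rep(2, 10), 0L, 10L)
    expect_equal(symmetrize_profiles(a, a)$mean, a$mean)
    empty <- niebtools:::.new_profile(1:10, rep(0, 10), rep(0, 10),
                                      0L, 10L)
    left_only <- symmetrize_profiles(empty, a)
    expect_equal(left_only$mean, a$mean)
    b <- niebtools:::.new_profile(2:11, 1:10, rep(1, 10), 0L, 10L)
    expect_error(symmetrize_profiles(a, b), "axes")
})

test_that("heat map smears tags and is invariant to within-group shuffles", {
    reg <- data.frame(chrom = "c1", start = 100L, end = 300L, d = 200L)
    tags <- data.table::data.table(chrom = "c1", pos = 200L, count = 1L)
    hm <- build_heatmap(reg, tags = tags, chrom_len = c(c1 = 500L),
                        display_halfwidth = 150L)
    row <- hm$matrix[1, ]
    expect_equal(sum(row, na.rm = TRUE), 2)       # segment of length 2c=2
    expect_equal(which(row == 1), c(150, 151))    # centered at the locus
    hm0 <- build_heatmap(reg, tags = tags[0, ], chrom_len = c(c1 = 500L),
                         display_halfwidth = 150L)
    expect_true(all(hm0$matrix[!is.na(hm0$matrix)] == 0))
    # permutation invariance within a group
    set.seed(9)
    ds <- make_world(seed = 9, n_chrom = 1L, len = 1e5)
    regs <- internieb_regions(ds$catalog)
    tags2 <- simulate_dyads(synth_truth(), ds$catalog,
                            chrom_lengths(ds$genome), coverage = 0.2,
                            seed = 10)
    h1 <- build_heatmap(regs, tags = tags2,
                        chrom_len = chrom_lengths(ds$genome),
                        group_size = 1000L)
    h2 <- build_heatmap(regs[sample(nrow(regs)), ], tags = tags2,
                        chrom_len = chrom_lengths(ds$genome),
                        group_size = 1000L)
    expect_equal(h1$matrix, h2$matrix)
})

test_that("polynucleotide coverage marks homopolymer runs around barriers", {
    seqs <- c(c1 = paste0(strrep("C", 30), strrep("T", 10),
                          strrep("C", 20), strrep("A", 5),
                          strrep("G", 35)))
    cat_ <- data.frame(chrom = "c1", start = 30L, end = 40L)
    offs <- catalog_offsets(cat_, c(c1 = 100L), 100L)
    g <- genome_sequence(seqs)
    pp <- polynucleotide_profile(g, offs, k = c(3L, 5L), max_in = 10L,
                                 max_out = 60L)
    t3 <- pp[pp$motif == "TTT", ]
    expect_true(all(t3$mean[t3$offset %in% -5:-1] == 1))  # the T run
    a3 <- pp[pp$motif == "AAA", ]
    # the A run sits on the right flank only; both sides pool, so the
    # mean is 1/2 across its span
    expect_true(all(a3$mean[a3$offset %in% 21:25] == 0.5))
    expect_true(all(a3$mean[a3$offset %in% 1:19] == 0))
    a5 <- pp[pp$motif == "AAAAA", ]
    expect_equal(sum(a5$mean[a5$offset > 0] > 0, na.rm = TRUE), 5L)
    g7 <- pp[pp$motif == "TTT", ]
    expect_true(all(g7$mean[g7$offset %in% 30:60] == 0))  # motif absent
})

test_that("TSS profiles apply gene orientation and pool classes", {
    L <- 1000L
    v <- numeric(L); v[701:L] <- 1  # statistic downstream of pos 700
    track <- list(c1 = v)
    genes_p <- data.frame(chrom = "c1", pos = 700L, strand = "+")
    genes_m <- data.frame(chrom = "c1", pos = 700L, strand = "-")
    pp <- tss_profile(track, genes_p, c(c1 = L), max_offset = 100L)
    pm <- tss_profile(track, genes_m, c(c1 = L), max_offset = 100L)
    expect_equal(pp$mean[pp$offset > 0], rev(pm$mean[pm$offset < 0]))
    expect_equal(pp$mean[pp$offset == 50], 1)
    expect_equal(pm$mean[pm$offset == 50], 0)
    # unstranded genes are excluded; single class labels everything
    both <- rbind(genes_p, data.frame(chrom = "c1", pos = 500L,
                                      strand = "*"))
    pb <- tss_profile(track, both, c(c1 = L), max_offset = 50L)
    expect_equal(unique(pb$class), "all")
    expect_equal(max(pb$count), 1)
})
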