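# Isolated-substitution detection, CpG masking, rate tabulation,
# backgrounds, selection ratio, bootstrap null and equilibrium GC.

CH <- change_classes()

# a hand-built count-table object for exact arithmetic checks
hand_divtab <- function(K = 20L, max_in = 10L, max_out = 10L,
                        nwin = 60L, nreg = 5L) {
    z <- function() array(0, c(K, 12L, 2L))
    z4 <- function() array(0, c(K, 4L, 2L))
    structure(list(eligA = z4(), eligX = z4(), interA = z(),
                   interX = z(), intraX = z(),
                   W = array(0, c(28L, nwin, nreg)),
                   n_large = nreg, nwin = nwin, max_in = max_in,
                   max_out = max_out, boot_window = 10L, l_min = 800L,
                   center_halfwidth = 300L, has_variants = TRUE),
              class = "nieb_divtab")
}

test_that("isolated substitutions require outgroup agreement and flank identity", {
    fl <- detect_isolated_substitutions(
        toy_alignment("TAC", "TGC", "TGC", "TGC"))[[1]]
    expect_true(fl$evt[2])
    expect_equal(fl$anc[2], 3L)            # ancestral G
    expect_equal(fl$hum[2], 1L)            # human A: one G>A event
    expect_false(any(fl$elig[c(1, 3)]))    # chromosome ends lack flanks
    # identity across all four species: eligible, no event
    fl2 <- detect_isolated_substitutions(
        toy_alignment("TACG", "TACG", "TACG", "TACG"))[[1]]
    expect_true(all(fl2$elig[2:3]))
    expect_false(any(fl2$evt))
    # outgroup disagreement leaves the ancestral base undefined
    fl3 <- detect_isolated_substitutions(
        toy_alignment("TAC", "TAC", "TGC", "TAC"))[[1]]
    expect_equal(fl3$anc[2], 0L)
    expect_false(fl3$elig[2])
    # gap or N in a flank breaks isolation
    fl4 <- detect_isolated_substitutions(
        toy_alignment("TACGG", "TACGG", "TACGG", "TA-GG"))[[1]]
    expect_false(fl4$elig[2])
    expect_false(fl4$elig[4])
})

test_that("CpG flags follow the four-species dinucleotide pattern list", {
    cp <- detect_cpg_sites(
        toy_alignment("ATGA", "ACGA", "ACGA", "ACGA"))[[1]]
    expect_true(cp$cpg_c[2])               # NG/CG/CG/CG
    expect_true(cp$cpg_g[3])
    cp2 <- detect_cpg_sites(
        toy_alignment("ACAA", "ACAA", "ACAA", "ACAA"))[[1]]
    expect_false(any(cp2$cpg_c))
    cp3 <- detect_cpg_sites(
        toy_alignment("ACGA", "ACAA", "ACGA", "ACGA"))[[1]]
    expect_true(cp3$cpg_c[2])              # CG/CN/CG/CG
    # chromosome end has no dinucleotide
    expect_false(cp$cpg_c[4])
})

test_that("intraspecies changes respect the ancestral-allele and MAF rules", {
    flags <- list(anc = c(1L, 1L, 0L, 4L, 1L),
                  hum = c(1L, 1L, 1L, 4L, 1L),
                  elig = rep(TRUE, 5), evt = rep(FALSE, 5))
    v <- data.table::data.table(
        pos = c(0L, 1L, 2L, 3L, 4L),
        ref = c("A", "A", "A", "A", "G"),
        alt = c("G", "G", "G", "G", "A"),
        af = c(0.10, 0.005, 0.10, 0.10, 0.90))
    ev <- niebtools:::.intra_events(v, flags, maf_min = 0.01)
    # pos 0: ancestral A observed, derived G at 10 %: one A>G change
    # pos 1: derived below the MAF filter
    # pos 2: ancestral undefined
    # pos 3: ancestral T not among observed alleles
    # pos 4: ancestral A is the alternate allele: A>G with ref derived
    expect_equal(ev$pos, c(0L, 4L))
    expect_equal(CH$label[ev$change], c("A>G", "A>G"))
})

test_that("streamed rate tabulation equals the per-site brute recount", {
    ds <- toy_divergence_world()
    clen <- chrom_lengths(ds$genome)
    tab <- divergence_tables(ds$aln, ds$catalog, clen, ds$variants)
    got_i <- rate_profile(tab, "inter")
    exp_i <- brute_rate_profile(ds$aln, ds$catalog, clen, "inter")
    expect_equal(got_i$events, exp_i$events)
    expect_equal(got_i$eligible, exp_i$eligible)
    got_p <- rate_profile(tab, "intra")
    exp_p <- brute_rate_profile(ds$aln, ds$catalog, clen, "intra",
                                variants = ds$variants)
    expect_equal(got_p$events, exp_p$events)
    expect_equal(got_p$eligible, exp_p$eligible)
    # rates are events / eligible wherever defined
    expect_equal(got_i$rate[got_i$eligible > 0],
                 (got_i$events / got_i$eligible)[got_i$eligible > 0])
    # conservation: profile events sum to the events on the axis
    fl <- detect_isolated_substitutions(ds$aln)[[1]]
    cp <- detect_cpg_sites(ds$aln)[[1]]
    s <- ds$catalog
    on_axis <- vapply(which(fl$evt), function(i) {
        bo <- brute_offset(i - 1L, s$start, s$end)
        !is.na(bo$offset) && bo$offset >= -225 && bo$offset <= 1000
    }, logical(1))
    excl <- (fl$anc == 2L & cp$cpg_c) | (fl$anc == 3L & cp$cpg_g)
    expect_equal(sum(got_i$events),
                 sum(on_axis & !excl[fl$evt]))
})

test_that("context-dependent tabulation equals its brute recount", {
    ds <- toy_divergence_world(seed = 404)
    clen <- chrom_lengths(ds$genome)
    for (spec in list(context_spec("T", "T", "A", "T"),
                      context_spec(c("C", "G"), "T", "A", c("C", "G")))) {
        got <- context_rate_profile(ds$aln, ds$catalog, clen,
                                    contexts = list(spec),
                                    variants = ds$variants, bin = 1L)
        exp_ <- brute_context_counts(ds$aln, ds$catalog, clen, spec)
        expect_equal(got$eligible, exp_$eligible,
                     label = paste("eligible", spec$name))
        expect_equal(got$events_inter, exp_$events,
                     label = paste("events", spec$name))
    }
})

test_that("CpG exclusion moves only rates with C/G ancestral bases", {
    ds <- toy_divergence_world(seed = 505)
    clen <- chrom_lengths(ds$genome)
    tab <- divergence_tables(ds$aln, ds$catalog, clen, ds$variants)
    ex <- rate_profile(tab, "inter", cpg = "excluded")
    inc <- rate_profile(tab, "inter", cpg = "included")
    from_w <- CH$label[CH$from %in% c("A", "T")]
    expect_equal(ex[ex$change %in% from_w, ],
                 inc[inc$change %in% from_w, ])
    from_s <- CH$label[CH$from %in% c("C", "G")]
    expect_gt(sum(inc[inc$change %in% from_s, ]$eligible),
              sum(ex[ex$change %in% from_s, ]$eligible))
})

test_that("selection ratio follows the background-corrected formula", {
    tab <- hand_divtab()
    idx <- 11:20 # offsets 1..10 on a 10/10 axis
    gid <- 3L; ga <- 7L # ancestral G, change G>A
    tab$eligX[idx, gid, 2L] <- 100
    tab$interX[idx, ga, 2L] <- 2    # dInter = 20/1000 = 0.02
    tab$intraX[idx, ga, 2L] <- 0.4  # dIntra = 4/1000 = 0.004
    tab$W[gid, , ] <- 1000 / (60 * 5)
    tab$W[4L + ga, , ] <- 10 / (60 * 5)  # bgInter 0.01
    tab$W[16L + ga, , ] <- 4 / (60 * 5)  # bgIntra 0.004
    bg <- background_rates(tab)
    expect_equal(bg$bg_inter[ga], 0.01)
    expect_equal(bg$bg_intra[ga], 0.004)
    sp <- selection_profile(tab, bg, bin = 10L)
    s_ga <- sp[sp$change == "G>A" & sp$offset > 0, ]
    expect_equal(s_ga$S, 2)
    # neutral identity: dInter = background, dIntra = background -> S = 1
    tab$interX[idx, ga, 2L] <- 1
    tab$intraX[idx, ga, 2L] <- 0.4
    sp1 <- selection_profile(tab, bg, bin = 10L)
    expect_equal(sp1[sp1$change == "G>A" & sp1$offset > 0, ]$S, 1)
    # zero intraspecies events: S undefined, not infinite
    tab$intraX[idx, ga, 2L] <- 0
    sp0 <- selection_profile(tab, bg, bin = 10L)
    expect_true(is.na(sp0[sp0$change == "G>A" & sp0$offset > 0, ]$S))
})

test_that("background pools the central 600 bp of large regions only", {
    ds <- toy_divergence_world(seed = 606)
    clen <- chrom_lengths(ds$genome)
    tab <- divergence_tables(ds$aln, ds$catalog, clen, ds$variants)
    # eligible per region cannot exceed the 600 central positions
    per_reg <- apply(tab$W[1:4, , , drop = FALSE], 3, sum)
    expect_true(all(per_reg <= 600))
    # no large regions at all -> background is an error
    tab2 <- divergence_tables(ds$aln, ds$catalog, clen, ds$variants,
                              l_min = 10000L)
    expect_equal(tab2$n_large, 0L)
    expect_error(background_rates(tab2), "large")
})

test_that("a constant-rate world gives a degenerate bootstrap null", {
    tab <- hand_divtab()
    tab$W[1:4, , ] <- 10
    tab$W[5:16, , ] <- 2
    tab$W[17:28, , ] <- 1
    bg <- background_rates(tab)
    set.seed(50)
    bn <- bootstrap_null(tab, bg, reps = 200L)
    expect_true(all(abs(bn$draws - 1) < 1e-12))
    expect_equal(bn$limits$lower, rep(1, 12))
    expect_equal(bn$limits$upper, rep(1, 12))
    expect_warning(bootstrap_null(tab, bg, reps = 50L), "100")
    p <- selection_pvalue(2, bn$draws[, 1])
    expect_lt(p, 0.01)
    expect_equal(selection_pvalue(0.5, bn$draws[, 1], "below"),
                 selection_pvalue(2, bn$draws[, 1], "above"))
})

test_that("bootstrap draws are reproducible under a fixed seed", {
    ds <- toy_divergence_world(seed = 707, chrom_length = 20000L)
    clen <- chrom_lengths(ds$genome)
    tab <- divergence_tables(ds$aln, ds$catalog, clen, ds$variants,
                             l_min = 300L)
    bg <- background_rates(tab)
    set.seed(77); a <- bootstrap_null(tab, bg, reps = 300L)
    set.seed(77); b <- bootstrap_null(tab, bg, reps = 300L)
    expect_identical(a$draws, b$draws)
})

test_that("equilibrium GC solves the stationary composition exactly", {
    r <- rep(0.001, 12); names(r) <- CH$label
    expect_equal(stationary_gc(r), 0.5)
    # two-rate lumped chain: W->S twice S->W gives GC 2/3
    r2 <- c("A>G" = 0.002, "A>C" = 0.002, "T>C" = 0.002, "T>G" = 0.002,
            "C>T" = 0.001, "C>A" = 0.001, "G>A" = 0.001, "G>T" = 0.001,
            "A>T" = 0.0015, "T>A" = 0.0015, "C>G" = 0.0015,
            "G>C" = 0.0015)
    expect_equal(stationary_gc(r2), 2 / 3, tolerance = 1e-12)
    # absorbing strong class
    r3 <- r2
    r3[c("C>T", "C>A", "G>A", "G>T")] <- 0
    expect_equal(stationary_gc(r3), 1, tolerance = 1e-9)
    expect_true(is.na(stationary_gc(rep(0, 12))))
    # complement relabeling leaves the GC fraction unchanged
    set.seed(2)
    for (k in 1:5) {
        rr <- runif(12, 1e-4, 5e-3); names(rr) <- CH$label
        relab <- rr[complement_change(CH$label)]
        names(relab) <- CH$label
        expect_equal(stationary_gc(relab), stationary_gc(rr),
                     tolerance = 1e-10)
    }
})

test_that("equilibrium GC profile reacts to the substitution balance", {
    tab <- hand_divtab()
    idx <- 11:20
    # eligible everywhere, W->S flux only: equilibrium GC 1
    for (b in 1:4) tab$eligA[idx, b, ] <- 1000
    for (cc in which(CH$from %in% c("A", "T") & CH$to %in% c("C", "G")))
        tab$interA[idx, cc, ] <- 3
    for (cc in which(CH$from %in% c("C", "G") & CH$to %in% c("C", "G")))
        tab$interA[idx, cc, ] <- 2 # strong class stays irreducible
    eq <- equilibrium_gc_profile(tab, smooth = 10L)
    expect_equal(eq$gc_eq[eq$offset > 0], 1, tolerance = 1e-9)
})
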