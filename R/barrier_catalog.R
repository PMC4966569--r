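# Barrier catalog management: width filtering, spacing statistics,
# nucleosome-class assignment, coverage accounting and 100-kb window
# stratification.

#' Filter a barrier catalog by width
#'
#' Barriers outside `[min_width, max_width]` are discarded (the largest
#' predicted barriers carry non-negligible nucleosome occupancy and are
#' removed before any downstream analysis). The number discarded is
#' attached as attribute `discarded`.
#'
#' @param catalog barrier interval table (`chrom`, `start`, `end`).
#' @param min_width,max_width retained width bounds in bp (36, 450).
#' @return filtered catalog, sorted.
#' @export
filter_widths <- function(catalog, min_width = 36L, max_width = 450L) {
    dt <- as.data.table(catalog)
    w <- dt$end - dt$start
    keep <- w >= min_width & w <= max_width
    out <- dt[keep]
    setorder(out, chrom, start)
    setattr(out, "discarded", sum(!keep))
    out[]
}

# Runs of N of at least min_len bp, per chromosome, as intervals.
.n_runs <- function(genome, min_len = 100L) {
    out <- lapply(genome, function(g) {
        r <- charToRaw(g$seq) == .RAW_N
        if (!any(r)) return(NULL)
        e <- rle(r)
        ends <- cumsum(e$lengths)
        starts <- ends - e$lengths
        keep <- e$values & e$lengths >= min_len
        if (!any(keep)) return(NULL)
        data.table(chrom = g$chrom, start = starts[keep], end = ends[keep])
    })
    rbindlist(out[!vapply(out, is.null, logical(1))])
}

#' Inter-barrier regions and their border-to-border interdistances
#'
#' One region per adjacent barrier pair on a chromosome, spanning from
#' the end of the first to the start of the second. Regions containing
#' an unsequenced stretch (an N run of at least `n_run_min` bp) are
#' dropped and counted.
#'
#' @param catalog sorted barrier interval table.
#' @param genome optional `nieb_genome` used to detect unsequenced gaps.
#' @param n_run_min minimal N-run length flagging a gap as unsequenced.
#' @return data.table (`chrom`, `start`, `end`, `d`) with `d = end -
#'   start`; attribute `dropped_unsequenced` counts discarded regions.
#' @export
internieb_regions <- function(catalog, genome = NULL, n_run_min = 100L) {
    dt <- as.data.table(catalog)
    setorder(dt, chrom, start)
    gaps <- dt[, if (.N > 1L)
        list(start = head(end, -1L), end = tail(start, -1L)),
        by = "chrom"]
    if (!all(c("start", "end") %in% names(gaps)))
        gaps <- data.table(chrom = character(), start = integer(),
                           end = integer())
    gaps <- gaps[gaps$end > gaps$start]
    dropped <- 0L
    if (!is.null(genome)) {
        nr <- .n_runs(genome, n_run_min)
        if (nrow(nr)) {
            bad <- rep(FALSE, nrow(gaps))
            for (ch in unique(nr$chrom)) {
                gi <- which(gaps$chrom == ch)
                sub <- nr[nr$chrom == ch, ]
                if (length(gi) == 0L) next
                hit <- outer(gaps$start[gi], sub$end, `<`) &
                    outer(gaps$end[gi], sub$start, `>`)
                bad[gi] <- rowSums(hit) > 0L
            }
            dropped <- sum(bad)
            gaps <- gaps[!bad]
        }
    }
    gaps[, d := end - start]
    setattr(gaps, "dropped_unsequenced", dropped)
    gaps[]
}

#' @rdname internieb_regions
#' @return `interdistances()` returns the numeric vector of `d` values.
#' @export
interdistances <- function(catalog, genome = NULL, n_run_min = 100L) {
    internieb_regions(catalog, genome, n_run_min)$d
}

#' Maximum-likelihood exponential fit to the spacing tail
#'
#' Interdistances above `d_min` follow, for Poisson-like barrier
#' placement, an exponential law; by memorylessness the MLE of the
#' exponential mean from the truncated sample is `mean(d - d_min)`.
#'
#' @param ds interdistances (bp).
#' @param d_min truncation point of the fitted tail (bp).
#' @return list with `mean` (fitted exponential mean), `se` (its
#'   standard error `mean/sqrt(n)`), `n`, `d_min`, and `degenerate`
#'   (TRUE when the truncated sample is constant).
#' @export
fit_exponential_tail <- function(ds, d_min = 0) {
    x <- ds[ds > d_min] - d_min
    n <- length(x)
    if (n == 0L) stop("no interdistances above d_min")
    if (n < 100L)
        warning("fewer than 100 interdistances above d_min; ",
                "fit is unreliable")
    m <- mean(x)
    list(mean = m, se = m / sqrt(n), n = n, d_min = d_min,
         degenerate = isTRUE(stats::var(x) == 0))
}

#' Detect the quantized comb in the small-interdistance histogram
#'
#' Scores an offset/period comb against the 1-bp spacing histogram
#' below `d_max`: the score of `(o, p)` is the smoothed histogram mass
#' at `o + k*p`, `k = 0..n_teeth-1`, normalized by total mass. The comb
#' is reported only when its score stands out from the score
#' distribution over the whole grid (flat or pure-exponential
#' histograms yield a null result).
#'
#' @param ds interdistances (bp).
#' @param d_max histogram upper bound (default 1000).
#' @param offsets,periods search grids (bp).
#' @param n_teeth comb teeth summed (default 5).
#' @param bw half-width of the box smoother applied to the histogram.
#' @param z_min significance: best score must exceed the grid mean by
#'   `z_min` grid standard deviations.
#' @return list with `offset`, `period`, `score`, `significant`;
#'   `offset`/`period` are `NA` when no significant comb is found.
#' @export
detect_quantized_peaks <- function(ds, d_max = 1000L,
                                   offsets = 60:180, periods = 120:200,
                                   n_teeth = 5L, bw = 2L, z_min = 6) {
    x <- ds[ds > 0 & ds <= d_max]
    if (length(x) == 0L)
        return(list(offset = NA_integer_, period = NA_integer_,
                    score = NA_real_, significant = FALSE))
    h <- tabulate(x, nbins = d_max)
    k <- rep(1, 2L * bw + 1L)
    hs <- as.numeric(stats::filter(h, k, sides = 2))
    hs[is.na(hs)] <- 0
    total <- sum(h)
    score <- matrix(0, length(offsets), length(periods))
    for (j in seq_along(periods)) {
        teeth <- outer(offsets, periods[j] * (0:(n_teeth - 1L)), `+`)
        teeth[teeth > d_max] <- NA
        v <- matrix(hs[teeth], nrow(teeth), ncol(teeth))
        score[, j] <- rowSums(v, na.rm = TRUE) / total
    }
    best <- arrayInd(which.max(score), dim(score))
    mu <- mean(score); sdev <- sd(score)
    sig <- sdev > 0 && (max(score) - mu) / sdev > z_min
    o_best <- offsets[best[1]]
    p_best <- periods[best[2]]
    if (sig) {
        # refine on the raw histogram: smoothing blurs the tooth
        # position by up to bw
        o_grid <- intersect((o_best - bw):(o_best + bw), offsets)
        p_grid <- intersect((p_best - bw):(p_best + bw), periods)
        raw <- function(o, p) {
            teeth <- o + p * (0:(n_teeth - 1L))
            sum(h[teeth[teeth <= d_max]])
        }
        sc <- outer(o_grid, p_grid, Vectorize(raw))
        ref <- arrayInd(which.max(sc), dim(sc))
        o_best <- o_grid[ref[1]]
        p_best <- p_grid[ref[2]]
    }
    list(offset = if (sig) o_best else NA_integer_,
         period = if (sig) p_best else NA_integer_,
         score = max(score), significant = sig)
}

#' Nucleosome-class assignment of an inter-barrier region
#'
#' Small regions (`d <= d_crystal`) are assigned to the crystal-like
#' class holding `n` regularly spaced nucleosomes, by the nearest tooth
#' of the spacing comb `d = offset + period * (n - 1)`; larger regions
#' are `"fuzzy"` (central nucleosomes lose positional order).
#'
#' @param d interdistance(s) in bp, `> 0`.
#' @param period,offset comb parameters (153, 117 bp).
#' @param n_max largest crystal class (default 5).
#' @param d_crystal crystal/fuzzy boundary (default 800 bp).
#' @return integer vector of classes, `NA` meaning fuzzy.
#' @export
classify_internieb <- function(d, period = 153, offset = 117,
                               n_max = 5L, d_crystal = 800) {
    stopifnot(all(d > 0))
    n <- pmin(pmax(as.integer(round((d - offset) / period)) + 1L, 1L), n_max)
    n[d > d_crystal] <- NA_integer_
    n
}

#' Coverage accounting of barriers, crystal regions and flanking
#' nucleosomes
#'
#' Three disjoint components of the sequenced genome: (i) barrier bp;
#' (ii) bp of crystal-class (`n <= n_max`) inter-barrier regions;
#' (iii) `2 * flank_span` bp per large (`d > d_crystal`) inter-barrier
#' region, accounting for the well-positioned first two nucleosomes on
#' each side of widely spaced barriers.
#'
#' @param catalog barrier interval table.
#' @param regions inter-barrier regions from [internieb_regions()].
#' @param genome optional `nieb_genome`; when given, percentages are
#'   relative to the sequenced (non-N) length, otherwise to total
#'   chromosome length inferred from `seq_len_total`.
#' @param seq_len_total total sequence length used when `genome` is
#'   absent.
#' @param flank_span bp covered by the flanking nucleosomes on one side
#'   of a large region (default 270, i.e. 540 bp per region).
#' @inheritParams classify_internieb
#' @return list of per-component bp and percentages.
#' @export
coverage_accounting <- function(catalog, regions, genome = NULL,
                                seq_len_total = NULL, flank_span = 270L,
                                period = 153, offset = 117, n_max = 5L,
                                d_crystal = 800) {
    if (!is.null(genome)) {
        seq_len_total <- sum(vapply(genome, function(g)
            sum(charToRaw(g$seq) != .RAW_N), numeric(1)))
    }
    if (is.null(seq_len_total)) stop("need genome or seq_len_total")
    cls <- classify_internieb(regions$d, period, offset, n_max, d_crystal)
    barrier_bp <- sum(catalog$end - catalog$start)
    crystal_bp <- sum(regions$d[!is.na(cls)])
    n_large <- sum(is.na(cls))
    flank_bp <- 2 * flank_span * n_large
    if (2 * flank_span > d_crystal)
        stop("flanking components overlap: 2*flank_span > d_crystal")
    total_bp <- barrier_bp + crystal_bp + flank_bp
    stopifnot(total_bp <= seq_len_total)
    pct <- function(x) 100 * x / seq_len_total
    list(sequenced_bp = seq_len_total,
         barrier_bp = barrier_bp, barrier_pct = pct(barrier_bp),
         crystal_bp = crystal_bp, crystal_pct = pct(crystal_bp),
         n_large_regions = n_large,
         flank_bp = flank_bp, flank_pct = pct(flank_bp),
         total_bp = total_bp, total_pct = pct(total_bp))
}

#' Stratify 100-kb windows and summarize barrier density per class
#'
#' Windows are classified by GC content (isochore classes L1/L2/H1/H2/H3
#' at 38/42/47/52 %), mean replication timing (early/medium/late at
#' 0.36/0.69), DNase tag density and meiotic recombination rate
#' (low/medium/high, by fixed thresholds or by 30/40/30 quantiles).
#' Windows lacking a covariate are excluded from that stratification
#' only.
#'
#' @param catalog barrier interval table.
#' @param windows data.frame of non-overlapping windows with columns
#'   `chrom`, `start`, `end` and any of the covariates `gc` (fraction),
#'   `mrt` (0-1), `dnase` (reads/kb), `recomb` (cM/Mb).
#' @param dnase_cuts,recomb_cuts fixed class thresholds (defaults 14.3 /
#'   29.3 reads/kb and 0.378 / 1.681 cM/Mb).
#' @param quantile_classes use 30/40/30 quantiles for DNase and
#'   recombination instead of the fixed thresholds.
#' @return list with `windows` (per-window density, coverage and
#'   classes) and `summary` (per classification dimension and class:
#'   window share, mean barrier density per kb, mean barrier coverage
#'   percent).
#' @export
window_stratification <- function(catalog, windows,
                                  dnase_cuts = c(14.3, 29.3),
                                  recomb_cuts = c(0.378, 1.681),
                                  quantile_classes = FALSE) {
    win <- as.data.table(windows)
    stopifnot(all(c("chrom", "start", "end") %in% names(win)))
    cat_dt <- as.data.table(catalog)
    mid <- (cat_dt$start + cat_dt$end) / 2
    win[, width := end - start]
    # barrier count by midpoint membership; coverage by bp overlap
    nn <- integer(nrow(win))
    cv <- numeric(nrow(win))
    for (ch in unique(win$chrom)) {
        wi <- which(win$chrom == ch)
        wi <- wi[order(win$start[wi])]
        sub <- cat_dt[cat_dt$chrom == ch, ]
        if (nrow(sub) == 0L) next
        m <- mid[cat_dt$chrom == ch]
        idx <- findInterval(m, win$start[wi])
        ok <- idx >= 1L & m < win$end[wi][pmax(idx, 1L)]
        nn[wi] <- nn[wi] + tabulate(idx[ok], nbins = length(wi))
        ov_start <- pmax(rep(sub$start, length(wi)),
                         rep(win$start[wi], each = nrow(sub)))
        ov_end <- pmin(rep(sub$end, length(wi)),
                       rep(win$end[wi], each = nrow(sub)))
        ov <- pmax(ov_end - ov_start, 0)
        cv[wi] <- cv[wi] + colSums(matrix(ov, nrow(sub), length(wi)))
    }
    win[, n_nieb := nn]
    win[, cov_bp := cv]
    win[, density := n_nieb / (width / 1e3)]
    win[, coverage := 100 * cov_bp / width]
    cut3 <- function(x, cuts, labels) {
        if (quantile_classes)
            cuts <- quantile(x, c(0.3, 0.7), na.rm = TRUE)
        factor(labels[findInterval(x, cuts) + 1L], levels = labels)
    }
    if ("gc" %in% names(win))
        win[, gc_class := factor(c("L1", "L2", "H1", "H2", "H3")[
            findInterval(gc, c(0.38, 0.42, 0.47, 0.52)) + 1L],
            levels = c("L1", "L2", "H1", "H2", "H3"))]
    if ("mrt" %in% names(win))
        win[, mrt_class := factor(c("early", "medium", "late")[
            findInterval(mrt, c(0.36, 0.69)) + 1L],
            levels = c("early", "medium", "late"))]
    if ("dnase" %in% names(win))
        win[, dnase_class := cut3(dnase, dnase_cuts,
                                  c("low", "medium", "high"))]
    if ("recomb" %in% names(win))
        win[, recomb_class := cut3(recomb, recomb_cuts,
                                   c("low", "medium", "high"))]
    dims <- intersect(c("gc_class", "mrt_class", "dnase_class",
                        "recomb_class"), names(win))
    summ <- rbindlist(lapply(dims, function(d) {
        sub <- win[!is.na(win[[d]])]
        sub[, list(dimension = d,
                   pct_windows = 100 * .N / nrow(sub),
                   density = sum(n_nieb) / sum(width / 1e3),
                   coverage = 100 * sum(cov_bp) / sum(width)),
            by = list(class = sub[[d]])][order(class)]
    }))
    list(windows = win[], summary = summ[])
}

#' Barrier coverage as a function of distance to a feature anchor
#'
#' Mean barrier-coverage indicator at each offset from a set of anchor
#' positions (feature midpoints or annotated sites), e.g. to quantify
#' barrier depletion around DSB hotspots or TSS.
#'
#' @param catalog barrier interval table.
#' @param anchors data.frame with columns `chrom`, `pos` (0-based
#'   anchor positions).
#' @param chrom_len named vector of chromosome lengths.
#' @param max_offset profile half-width in bp.
#' @return data.table (`offset`, `coverage`, `n`) where `coverage` is
#'   the fraction of anchors whose position + offset lies in a barrier.
#' @export
feature_overlap_profile <- function(catalog, anchors, chrom_len,
                                    max_offset = 1000L) {
    if (nrow(anchors) == 0L)
        return(data.table(offset = integer(), coverage = numeric(),
                          n = integer()))
    offs <- seq.int(-max_offset, max_offset)
    hits <- numeric(length(offs))
    n <- integer(length(offs))
    for (ch in unique(anchors$chrom)) {
        L <- chrom_len[[ch]]
        ind <- logical(L)
        sub <- catalog[catalog$chrom == ch, ]
        for (k in seq_len(nrow(sub)))
            ind[(sub$start[k] + 1L):sub$end[k]] <- TRUE
        a <- anchors$pos[anchors$chrom == ch]
        for (j in seq_along(offs)) {
            p <- a + offs[j]
            ok <- p >= 0L & p < L
            hits[j] <- hits[j] + sum(ind[p[ok] + 1L])
            n[j] <- n[j] + sum(ok)
        }
    }
    data.table(offset = offs, coverage = ifelse(n > 0, hits / n, NA_real_),
               n = n)
}
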