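# Border-aligned averaging of per-base statistics, smoothing,
# symmetrization, heat maps over inter-barrier regions, polynucleotide
# and TSS-anchored profiles.

.new_profile <- function(offset, sum, count, max_in, max_out,
                         normalized = FALSE) {
    out <- data.table(offset = offset,
                      mean = ifelse(count > 0, sum / count, NA_real_),
                      count = count)
    setattr(out, "max_in", max_in)
    setattr(out, "max_out", max_out)
    setattr(out, "normalized", normalized)
    setattr(out, "class", c("nieb_profile", class(out)))
    out[]
}

#' Border-aligned mean profile of a per-base statistic
#'
#' Averages a per-base statistic (tag count, GC indicator, substitution
#' indicator, ...) as a function of signed distance to the nearest
#' barrier border: negative offsets inside the barrier, positive in the
#' flanks (sites interior to the *next* barrier are interior there and
#' never pollute flank averages). Offsets come from [catalog_offsets()].
#'
#' @param track named list (per chromosome) of numeric per-base vectors.
#' @param offsets result of [catalog_offsets()] on the same chromosomes.
#' @param max_in largest interior offset magnitude kept (default 225,
#'   half the maximal barrier width).
#' @param max_out largest flank offset kept; must not exceed the
#'   `max_out` used for `offsets`.
#' @param keep optional named list of per-base logicals (e.g. mappable
#'   and non-N sites); only `TRUE` sites contribute.
#' @param normalize divide the profile by the average of the statistic
#'   over all kept sites (profiles "normalized with respect to genome
#'   average"); an all-zero statistic cannot be normalized.
#' @return a `nieb_profile`: data.table (`offset`, `mean`, `count`)
#'   where `count` is the number of contributing sites at each offset.
#' @export
aggregate_profile <- function(track, offsets, max_in = 225L,
                              max_out = 1000L, keep = NULL,
                              normalize = FALSE) {
    K <- max_in + max_out
    sums <- numeric(K)
    counts <- numeric(K)
    tot_sum <- 0
    tot_n <- 0
    for (ch in names(track)) {
        v <- track[[ch]]
        off <- offsets[[ch]]$offset
        stopifnot(length(v) == length(off))
        ok <- if (is.null(keep[[ch]])) !is.na(v) else
            !is.na(v) & keep[[ch]]
        tot_sum <- tot_sum + sum(v[ok])
        tot_n <- tot_n + sum(ok)
        idx <- .axis_index(off, max_in, max_out)
        use <- ok & !is.na(idx)
        if (!any(use)) next
        s <- rowsum(v[use], idx[use])
        counts_ch <- tabulate(idx[use], nbins = K)
        sums[as.integer(rownames(s))] <- sums[as.integer(rownames(s))] + s[, 1]
        counts <- counts + counts_ch
    }
    if (normalize) {
        g <- tot_sum / tot_n
        if (!is.finite(g) || g == 0)
            stop("cannot normalize: zero or undefined genome average")
        sums <- sums / g
    }
    .new_profile(.axis_offsets(max_in, max_out), sums, counts,
                 max_in, max_out, normalize)
}

#' Smooth a profile by a centered, count-weighted moving average
#'
#' The window shrinks symmetrically at the axis ends. For even window
#' widths the extra position is taken on the right of the center (tie
#' convention, documented rather than configurable).
#'
#' @param profile a `nieb_profile`.
#' @param window window width in bp (1 = identity).
#' @return smoothed `nieb_profile` (counts are the per-window summed
#'   effective counts).
#' @export
smooth_profile <- function(profile, window = 10L) {
    if (window < 1L) stop("window must be >= 1")
    if (window == 1L) return(profile)
    n <- nrow(profile)
    left <- (window - 1L) %/% 2L
    right <- window - 1L - left
    cnt <- profile$count
    val <- ifelse(cnt > 0, profile$mean * cnt, 0)
    cs_v <- cumsum(val)
    cs_c <- cumsum(cnt)
    i <- seq_len(n)
    lo <- pmax(i - left, 1L)
    hi <- pmin(i + right, n)
    wv <- cs_v[hi] - c(0, cs_v)[lo]
    wc <- cs_c[hi] - c(0, cs_c)[lo]
    .new_profile(profile$offset, wv, wc,
                 attr(profile, "max_in"), attr(profile, "max_out"),
                 attr(profile, "normalized"))
}

#' Average two border-side profiles
#'
#' Pools a 3'-side profile with a 5'-side profile on an identical axis,
#' weighting by effective counts. For base-change statistics the caller
#' maps the 5'-side profile to the complementary change beforehand (the
#' divergence module does this automatically); `mode` records the
#' intent.
#'
#' @param right profile on the right of 3' borders.
#' @param left profile on the left of 5' borders (complement-mapped for
#'   base-change statistics).
#' @param mode `"average"` or `"revcomp_average"` (bookkeeping only;
#'   both pool by counts).
#' @return pooled `nieb_profile`.
#' @export
symmetrize_profiles <- function(right, left,
                                mode = c("average", "revcomp_average")) {
    mode <- match.arg(mode)
    if (!identical(right$offset, left$offset))
        stop("profiles are on different offset axes")
    cr <- right$count; cl <- left$count
    sums <- ifelse(cr > 0, right$mean * cr, 0) +
        ifelse(cl > 0, left$mean * cl, 0)
    .new_profile(right$offset, sums, cr + cl,
                 attr(right, "max_in"), attr(right, "max_out"),
                 attr(right, "normalized"))
}

#' Heat map of a statistic over inter-barrier regions
#'
#' Regions are centered at their midpoints and ordered from smallest to
#' largest; each heat-map row is the mean over a fixed-size group of
#' consecutive regions; values are clipped to `[0, 1]`. When `tags` is
#' given, each locus carrying `c` tags is smeared into a centered
#' segment of length `2c` (per-region binary coverage) before
#' averaging. Only the central `2 * display_halfwidth` bp of each
#' region are represented.
#'
#' @param regions inter-barrier regions ([internieb_regions()]).
#' @param tags tag track (`chrom`, `pos`, `count`), or `NULL` when
#'   `track` is given.
#' @param track named list of per-base numeric vectors in `[0, 1]`
#'   (e.g. a GC indicator), used when `tags` is `NULL`.
#' @param chrom_len named vector of chromosome lengths.
#' @param group_size regions per row (default 200; fewer regions give a
#'   single row).
#' @param display_halfwidth columns span `-display_halfwidth ..
#'   display_halfwidth - 1` around region centers (default 800).
#' @return list with `matrix` (rows x offsets, values in `[0, 1]`,
#'   `NA` outside regions), `offsets`, and `row_d` (mean interdistance
#'   per row).
#' @export
build_heatmap <- function(regions, tags = NULL, track = NULL, chrom_len,
                          group_size = 200L, display_halfwidth = 800L) {
    if (is.null(tags) && is.null(track))
        stop("need tags or track")
    reg <- as.data.table(regions)[order(d)]
    nreg <- nrow(reg)
    if (nreg == 0L) stop("no regions")
    ncol_ <- 2L * display_halfwidth
    offs <- seq.int(-display_halfwidth, display_halfwidth - 1L)
    # per-chromosome base-level values
    dense <- lapply(names(chrom_len), function(ch) {
        L <- chrom_len[[ch]]
        if (!is.null(tags)) {
            v <- numeric(L)
            sub <- tags[tags$chrom == ch & tags$count > 0, ]
            if (nrow(sub)) {
                from <- pmax(sub$pos - sub$count, 0L)
                to <- pmin(sub$pos + sub$count, L) # smear [p-c, p+c)
                for (k in seq_len(nrow(sub)))
                    v[(from[k] + 1L):to[k]] <- 1
            }
            v
        } else track[[ch]]
    })
    names(dense) <- names(chrom_len)
    vals <- matrix(NA_real_, nreg, ncol_)
    for (r in seq_len(nreg)) {
        ch <- reg$chrom[r]
        ctr <- (reg$start[r] + reg$end[r]) %/% 2L
        p <- ctr + offs
        ok <- p >= reg$start[r] & p < reg$end[r]
        vals[r, ok] <- dense[[ch]][p[ok] + 1L]
    }
    grp <- ceiling(seq_len(nreg) / group_size)
    nrow_ <- max(grp)
    m <- matrix(NA_real_, nrow_, ncol_)
    row_d <- numeric(nrow_)
    for (g in seq_len(nrow_)) {
        rows <- which(grp == g)
        m[g, ] <- colMeans(vals[rows, , drop = FALSE], na.rm = TRUE)
        row_d[g] <- mean(reg$d[rows])
    }
    m[is.nan(m)] <- NA_real_
    m <- pmin(pmax(m, 0), 1)
    dim(m) <- c(nrow_, ncol_)
    list(matrix = m, offsets = offs, row_d = row_d)
}

#' Border-aligned coverage profiles of poly(dA)/poly(dT) tracks
#'
#' For each motif `A^k` / `T^k` the per-base statistic is 1 when the
#' site lies in a homopolymer run of length at least `k` of that base.
#' Masked sites are excluded from both numerator and denominator when a
#' mask is present.
#'
#' @param genome a `nieb_genome`.
#' @param offsets result of [catalog_offsets()].
#' @param k run lengths (default 3, 5, 7).
#' @param bases homopolymer bases (default A and T).
#' @param use_mask exclude repeat-masked sites (default TRUE when the
#'   genome has a mask).
#' @inheritParams aggregate_profile
#' @return data.table with columns `motif`, `offset`, `mean`, `count`.
#' @export
polynucleotide_profile <- function(genome, offsets, k = c(3L, 5L, 7L),
                                   bases = c("A", "T"), use_mask = TRUE,
                                   max_in = 225L, max_out = 1000L) {
    keep <- lapply(genome, function(g) {
        r <- charToRaw(g$seq)
        ok <- r != .RAW_N
        if (use_mask && !is.null(g$mask)) ok <- ok & !g$mask
        ok
    })
    out <- list()
    for (b in bases) {
        rb <- charToRaw(b)
        for (kk in k) {
            track <- lapply(genome, function(g) {
                hit <- charToRaw(g$seq) == rb
                e <- rle(hit)
                as.numeric(rep(e$values & e$lengths >= kk, e$lengths))
            })
            names(track) <- names(genome)
            pr <- aggregate_profile(track, offsets, max_in, max_out,
                                    keep = keep)
            out[[paste0(b, kk)]] <- data.table(
                motif = strrep(b, kk), offset = pr$offset,
                mean = pr$mean, count = pr$count)
        }
    }
    rbindlist(out)[]
}

#' Profiles anchored at transcription start/termination sites
#'
#' Aggregates a per-base statistic around gene anchors with gene
#' orientation applied: for minus-strand genes the offset axis is
#' mirrored so positive offsets always point into the gene body.
#' Unstranded genes are excluded.
#'
#' @param track named list of per-base numeric vectors.
#' @param genes data.frame with columns `chrom`, `pos` (anchor, 0-based),
#'   `strand` (`"+"`/`"-"`), and optionally `class` (e.g. expressed /
#'   silent); one profile is returned per class.
#' @param chrom_len named vector of chromosome lengths.
#' @param max_offset profile half-width in bp.
#' @return data.table (`class`, `offset`, `mean`, `count`).
#' @export
tss_profile <- function(track, genes, chrom_len, max_offset = 2000L) {
    g <- as.data.table(genes)
    g <- g[g$strand %in% c("+", "-"), ]
    if (!"class" %in% names(g)) g[, class := "all"]
    offs <- seq.int(-max_offset, max_offset)
    out <- list()
    for (cl in unique(g$class)) {
        sums <- numeric(length(offs))
        counts <- numeric(length(offs))
        sub <- g[g$class == cl, ]
        for (i in seq_len(nrow(sub))) {
            v <- track[[sub$chrom[i]]]
            p <- if (sub$strand[i] == "+") sub$pos[i] + offs
                 else sub$pos[i] - offs
            ok <- p >= 0L & p < length(v)
            vv <- v[p[ok] + 1L]
            idx <- which(ok)[!is.na(vv)]
            sums[idx] <- sums[idx] + vv[!is.na(vv)]
            counts[idx] <- counts[idx] + 1
        }
        out[[cl]] <- data.table(class = cl, offset = offs,
                                mean = ifelse(counts > 0, sums / counts,
                                              NA_real_),
                                count = counts)
    }
    rbindlist(out)[]
}
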