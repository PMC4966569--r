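# Position-resolved interspecies and intraspecies divergence rates,
# CpG masking, background rates from the centers of large inter-barrier
# regions, the background-corrected selection ratio S, its bootstrap
# neutral null, context-dependent rates, and equilibrium GC content.

#' Construct a four-species alignment-column table
#'
#' Per-chromosome aligned bases for human, chimpanzee, orangutan and
#' macaque, stored as equal-length sequence strings over
#' `{A,C,G,T,N,-}`.
#'
#' @param columns named list (per chromosome) of lists with elements
#'   `h`, `c`, `o`, `m` (sequence strings).
#' @return object of class `nieb_alignment`.
#' @export
alignment_table <- function(columns) {
    for (ch in names(columns)) {
        x <- columns[[ch]]
        stopifnot(all(c("h", "c", "o", "m") %in% names(x)))
        len <- nchar(x$h)
        if (any(nchar(c(x$c, x$o, x$m)) != len))
            stop("chromosome ", ch, ": species lengths differ")
        joined <- paste0(x$h, x$c, x$o, x$m)
        if (grepl("[^ACGTN-]", joined))
            stop("chromosome ", ch, ": symbols outside {A,C,G,T,N,-}")
    }
    structure(columns, class = "nieb_alignment")
}

#' Read / write alignment columns as TSV
#'
#' Columns: `chrom`, `pos` (0-based), `h`, `c`, `o`, `m`. Positions
#' absent from the file become `N` in every species.
#'
#' @param path file path.
#' @param chrom_len named vector of chromosome lengths.
#' @return [read_alignment_tsv()] returns a `nieb_alignment`.
#' @export
read_alignment_tsv <- function(path, chrom_len) {
    dt <- fread(path, col.names = c("chrom", "pos", "h", "c", "o", "m"),
                colClasses = list(character = c(1, 3:6), integer = 2))
    cols <- lapply(names(chrom_len), function(ch) {
        L <- chrom_len[[ch]]
        sub <- dt[dt$chrom == ch]
        out <- lapply(c("h", "c", "o", "m"), function(sp) {
            v <- rep("N", L)
            v[sub$pos + 1L] <- sub[[sp]]
            paste(v, collapse = "")
        })
        names(out) <- c("h", "c", "o", "m")
        out
    })
    names(cols) <- names(chrom_len)
    alignment_table(cols)
}

#' @rdname read_alignment_tsv
#' @param aln a `nieb_alignment`.
#' @export
write_alignment_tsv <- function(aln, path) {
    out <- lapply(names(aln), function(ch) {
        x <- aln[[ch]]
        data.table(chrom = ch, pos = seq_len(nchar(x$h)) - 1L,
                   h = strsplit(x$h, "")[[1]], c = strsplit(x$c, "")[[1]],
                   o = strsplit(x$o, "")[[1]], m = strsplit(x$m, "")[[1]])
    })
    fwrite(rbindlist(out), path, sep = "\t", col.names = FALSE)
    invisible(path)
}

#' Isolated human-lineage substitutions and eligible sites
#'
#' A site carries a defined ancestral base when chimpanzee, orangutan
#' and macaque agree on a real base. It is *eligible* when additionally
#' (i) both immediately flanking sites are identical across all four
#' species (isolation criterion, guarding against alignment artifacts)
#' and (ii) the human base is a real base. An *event* is an eligible
#' site where human differs from the ancestral base. Gaps or N in any
#' species at the site or its flanks make it ineligible.
#'
#' @param aln a `nieb_alignment`.
#' @return named list (per chromosome) of lists with integer vectors
#'   `anc` and `hum` (base codes A=1, C=2, G=3, T=4; 0 = undefined) and
#'   logical vectors `elig`, `evt`.
#' @export
detect_isolated_substitutions <- function(aln) {
    lapply(unclass(aln), function(x) {
        h <- charToRaw(x$h); cc <- charToRaw(x$c)
        o <- charToRaw(x$o); m <- charToRaw(x$m)
        n <- length(h)
        anc_def <- cc == o & o == m & .is_acgt(cc)
        ident <- h == cc & anc_def
        flank_ok <- c(FALSE, ident[-n]) & c(ident[-1L], FALSE)
        elig <- anc_def & flank_ok & .is_acgt(h)
        evt <- elig & h != cc
        anc <- .base_ids(cc)
        anc[!anc_def] <- 0L
        list(anc = anc, hum = .base_ids(h), elig = elig, evt = evt)
    })
}

#' CpG-site flags from four-species dinucleotide patterns
#'
#' A position is flagged as the C of a CpG when its dinucleotide across
#' human/chimpanzee/orangutan/macaque matches one of the patterns
#' NG/CG/CG/CG, CG/NG/CG/CG, CN/CG/CG/CG or CG/CN/CG/CG (N = any
#' nucleotide): a CpG in three species with at most a single-position
#' deviation in human or chimpanzee, the hypermutable-deamination
#' signature. The following position is flagged as the corresponding G.
#'
#' @param aln a `nieb_alignment`.
#' @return named list (per chromosome) of lists with logical vectors
#'   `cpg_c` (flag at the C position) and `cpg_g` (at the G position).
#' @export
detect_cpg_sites <- function(aln) {
    lapply(unclass(aln), function(x) {
        h <- charToRaw(x$h); cc <- charToRaw(x$c)
        o <- charToRaw(x$o); m <- charToRaw(x$m)
        n <- length(h)
        at <- function(r, i) if (i == 1L) r[-n] else r[-1L]
        C1 <- function(r) at(r, 1L) == .RAW_C
        G2 <- function(r) at(r, 2L) == .RAW_G
        A1 <- function(r) .is_acgt(at(r, 1L))
        A2 <- function(r) .is_acgt(at(r, 2L))
        oCG <- C1(o) & G2(o); mCG <- C1(m) & G2(m)
        p1 <- A1(h) & G2(h) & C1(cc) & G2(cc) & oCG & mCG
        p2 <- C1(h) & G2(h) & A1(cc) & G2(cc) & oCG & mCG
        p3 <- C1(h) & A2(h) & C1(cc) & G2(cc) & oCG & mCG
        p4 <- C1(h) & G2(h) & C1(cc) & A2(cc) & oCG & mCG
        cpg <- p1 | p2 | p3 | p4
        list(cpg_c = c(cpg, FALSE), cpg_g = c(FALSE, cpg))
    })
}

# change-id lookup: M[from, to] -> 1..12, NA on diagonal
.change_lut <- local({
    M <- matrix(NA_integer_, 4L, 4L)
    for (i in seq_len(12L))
        M[match(.CHANGES$from[i], .BASES),
          match(.CHANGES$to[i], .BASES)] <- i
    M
})

# Qualifying intraspecies changes from a variant table for one
# chromosome. Returns data.table(pos, change) (0-based positions).
.intra_events <- function(variants_ch, flags_ch, maf_min) {
    if (is.null(variants_ch) || nrow(variants_ch) == 0L)
        return(data.table(pos = integer(), change = integer()))
    v <- variants_ch
    anc <- flags_ch$anc[v$pos + 1L]
    ref_id <- match(v$ref, .BASES)
    alt_id <- match(v$alt, .BASES)
    ref_q <- (1 - v$af) > maf_min
    alt_q <- v$af > maf_min
    # ancestral allele must be among the qualifying observed alleles
    anc_is_ref <- anc > 0L & anc == ref_id & ref_q
    anc_is_alt <- anc > 0L & anc == alt_id & alt_q
    evt_ref <- anc_is_ref & alt_q # change ref -> alt
    evt_alt <- anc_is_alt & ref_q # change alt -> ref
    out <- rbind(
        data.table(pos = v$pos[evt_ref],
                   change = .change_lut[cbind(ref_id[evt_ref],
                                              alt_id[evt_ref])]),
        data.table(pos = v$pos[evt_alt],
                   change = .change_lut[cbind(alt_id[evt_alt],
                                              ref_id[evt_alt])]))
    out[!is.na(out$change)]
}

#' Tabulate divergence counts around barriers
#'
#' Streams over chromosomes and accumulates, per offset from the
#' nearest barrier border and per border side (5'/3'), eligible-site
#' counts by ancestral base and interspecies/intraspecies event counts
#' for the 12 base changes, in CpG-excluded (for rates and selection)
#' and CpG-inclusive (for equilibrium GC) versions. Also collects the
#' per-window counts in the central spans of large inter-barrier
#' regions that back the background rates and the bootstrap null.
#'
#' @param aln a `nieb_alignment`.
#' @param catalog sorted barrier interval table.
#' @param chrom_len named vector of chromosome lengths.
#' @param variants optional variant table (`chrom`, `pos`, `ref`,
#'   `alt`, `af`); a change qualifies when every allele involved has
#'   frequency above `maf_min` and the ancestral allele is observed.
#'   When the interspecies ancestral base is undefined the chimpanzee
#'   base stands in.
#' @param max_in,max_out profile axis bounds (see
#'   [aggregate_profile()]).
#' @param maf_min minor-allele-frequency cutoff (default 0.01).
#' @param cpg_strand_symmetric also exclude the G of each CpG from
#'   G-ancestral rates (reverse-complement consistency; default TRUE).
#' @param l_min inter-barrier regions wider than this define the
#'   neutral background (default 800 bp).
#' @param center_halfwidth half-width of the central background span
#'   (default 300 bp).
#' @param boot_window bootstrap window width (default 10 bp; must
#'   divide `2 * center_halfwidth`).
#' @return object of class `nieb_divtab` bundling the count arrays.
#' @export
divergence_tables <- function(aln, catalog, chrom_len, variants = NULL,
                              max_in = 225L, max_out = 1000L,
                              maf_min = 0.01,
                              cpg_strand_symmetric = TRUE,
                              l_min = 800L, center_halfwidth = 300L,
                              boot_window = 10L) {
    if ((2L * center_halfwidth) %% boot_window != 0L)
        stop("boot_window must divide the central span")
    nwin <- (2L * center_halfwidth) %/% boot_window
    K <- max_in + max_out
    eligA <- array(0, c(K, 4L, 2L))  # CpG-inclusive eligible, by anc
    eligX <- array(0, c(K, 4L, 2L))  # CpG-excluded eligible
    interA <- array(0, c(K, 12L, 2L))
    interX <- array(0, c(K, 12L, 2L))
    intraX <- array(0, c(K, 12L, 2L))
    flags_all <- detect_isolated_substitutions(aln)
    cpg_all <- detect_cpg_sites(aln)
    regions <- internieb_regions(catalog)
    large <- regions[regions$d > l_min]
    nreg <- nrow(large)
    # window-count array for background + bootstrap: stats are
    # 4 eligible (by anc, CpG-excluded) + 12 inter + 12 intra
    W <- array(0, c(28L, nwin, max(nreg, 1L)))
    reg_offset <- 0L
    for (ch in names(chrom_len)) {
        fl <- flags_all[[ch]]
        cp <- cpg_all[[ch]]
        sub <- catalog[catalog$chrom == ch, ]
        off <- border_offsets(sub$start, sub$end, chrom_len[[ch]], max_out)
        idx <- .axis_index(off$offset, max_in, max_out)
        side <- off$side
        cpg_by_anc <- list(`2` = cp$cpg_c,
                           `3` = if (cpg_strand_symmetric) cp$cpg_g else
                               rep(FALSE, length(cp$cpg_g)))
        excl <- rep(FALSE, length(fl$anc))
        excl[fl$anc == 2L] <- cpg_by_anc[["2"]][fl$anc == 2L]
        excl[fl$anc == 3L] <- cpg_by_anc[["3"]][fl$anc == 3L]
        usable <- fl$elig & !is.na(idx)
        for (s in 1:2) {
            on_s <- usable & side == s
            for (b in 1:4) {
                sel <- on_s & fl$anc == b
                cnt <- tabulate(idx[sel], nbins = K)
                eligA[, b, s] <- eligA[, b, s] + cnt
                if (b %in% c(2L, 3L)) {
                    cntX <- tabulate(idx[sel & !excl], nbins = K)
                } else cntX <- cnt
                eligX[, b, s] <- eligX[, b, s] + cntX
            }
        }
        # interspecies events: sparse
        ev <- which(fl$evt)
        if (length(ev)) {
            cid <- .change_lut[cbind(fl$anc[ev], fl$hum[ev])]
            ei <- idx[ev]; es <- side[ev]; ex <- excl[ev]
            ok <- !is.na(ei)
            for (s in 1:2) for (cc in unique(cid[ok & es == s])) {
                sel <- ok & es == s & cid == cc
                interA[, cc, s] <- interA[, cc, s] +
                    tabulate(ei[sel], nbins = K)
                interX[, cc, s] <- interX[, cc, s] +
                    tabulate(ei[sel & !ex], nbins = K)
            }
        }
        # intraspecies events
        vch <- if (!is.null(variants)) {
            v <- as.data.table(variants)[variants$chrom == ch]
            # chimp fallback for undefined ancestral: substitute into
            # a copy of the flags for the ancestral lookup
            v
        } else NULL
        if (!is.null(vch) && nrow(vch)) {
            fl2 <- fl
            undef <- fl2$anc == 0L
            chimp <- .base_ids(charToRaw(aln[[ch]]$c))
            fl2$anc[undef] <- chimp[undef]
            ie <- .intra_events(vch, fl2, maf_min)
            # restrict to eligible, CpG-respecting sites
            if (nrow(ie)) {
                keep <- fl$elig[ie$pos + 1L] & !excl[ie$pos + 1L]
                ie <- ie[keep]
            }
            if (nrow(ie)) {
                ii <- idx[ie$pos + 1L]; is_ <- side[ie$pos + 1L]
                ok <- !is.na(ii)
                for (s in 1:2) for (cc in unique(ie$change[ok & is_ == s])) {
                    sel <- ok & is_ == s & ie$change == cc
                    intraX[, cc, s] <- intraX[, cc, s] +
                        tabulate(ii[sel], nbins = K)
                }
            }
        } else ie <- data.table(pos = integer(), change = integer())
        # central windows of large regions on this chromosome
        lg <- large[large$chrom == ch]
        if (nrow(lg)) {
            mid <- (lg$start + lg$end) %/% 2L
            span_start <- mid - center_halfwidth
            span_len <- 2L * center_halfwidth
            pos <- rep(span_start, each = span_len) +
                rep(seq_len(span_len) - 1L, times = nrow(lg))
            regid <- rep(seq_len(nrow(lg)), each = span_len) + reg_offset
            winid <- rep((seq_len(span_len) - 1L) %/% boot_window + 1L,
                         times = nrow(lg))
            flat <- (regid - 1L) * nwin + winid
            p1 <- pos + 1L
            el <- fl$elig[p1] & !excl[p1]
            for (b in 1:4) {
                sel <- el & fl$anc[p1] == b
                if (any(sel)) W[b, , ] <- W[b, , ] +
                    array(tabulate(flat[sel], nbins = nwin * nreg),
                          c(nwin, nreg))
            }
            evp <- fl$evt[p1] & el
            if (any(evp)) {
                cid <- .change_lut[cbind(fl$anc[p1][evp], fl$hum[p1][evp])]
                fe <- flat[evp]
                for (cc in unique(cid)) {
                    W[4L + cc, , ] <- W[4L + cc, , ] +
                        array(tabulate(fe[cid == cc], nbins = nwin * nreg),
                              c(nwin, nreg))
                }
            }
            if (nrow(ie)) {
                m_ <- match(ie$pos, pos)
                inwin <- !is.na(m_)
                if (any(inwin)) {
                    fi <- flat[m_[inwin]]
                    ci <- ie$change[inwin]
                    for (cc in unique(ci)) {
                        W[16L + cc, , ] <- W[16L + cc, , ] +
                            array(tabulate(fi[ci == cc],
                                           nbins = nwin * nreg),
                                  c(nwin, nreg))
                    }
                }
            }
            reg_offset <- reg_offset + nrow(lg)
        }
    }
    structure(list(eligA = eligA, eligX = eligX, interA = interA,
                   interX = interX, intraX = intraX, W = W,
                   n_large = nreg, nwin = nwin,
                   max_in = max_in, max_out = max_out,
                   boot_window = boot_window, l_min = l_min,
                   center_halfwidth = center_halfwidth,
                   has_variants = !is.null(variants)),
              class = "nieb_divtab")
}

#' @export
print.nieb_divtab <- function(x, ...) {
    cat("<nieb_divtab> axis", -x$max_in, "..", x$max_out,
        "| large regions:", x$n_large,
        "| inter events:", sum(x$interA),
        "| intra events:", sum(x$intraX), "\n")
    invisible(x)
}

# anc base id for each change id
.anc_of_change <- match(.CHANGES$from, .BASES)

#' Symmetrized per-offset divergence rates
#'
#' The rate profile of change X>Y pools sites on the right of 3'
#' barrier borders with the complementary change comp(X)>comp(Y) on the
#' left of 5' borders (reverse-complement averaging), so every profile
#' reads in a single strand-consistent orientation.
#'
#' @param tab a `nieb_divtab`.
#' @param type `"inter"` or `"intra"`.
#' @param cpg `"excluded"` (rates, selection) or `"included"`
#'   (equilibrium-GC input); intraspecies tables are always
#'   CpG-excluded.
#' @return data.table (`change`, `offset`, `events`, `eligible`,
#'   `rate`); `rate` is `NA` where no site was eligible.
#' @export
rate_profile <- function(tab, type = c("inter", "intra"),
                         cpg = c("excluded", "included")) {
    type <- match.arg(type)
    cpg <- match.arg(cpg)
    ev_arr <- if (type == "intra") tab$intraX else
        if (cpg == "excluded") tab$interX else tab$interA
    el_arr <- if (cpg == "excluded" || type == "intra") tab$eligX else
        tab$eligA
    comp <- .comp_change_id()
    offs <- .axis_offsets(tab$max_in, tab$max_out)
    out <- lapply(seq_len(12L), function(cc) {
        ev <- ev_arr[, cc, 2L] + ev_arr[, comp[cc], 1L]
        el <- el_arr[, .anc_of_change[cc], 2L] +
            el_arr[, .anc_of_change[comp[cc]], 1L]
        data.table(change = .CHANGES$label[cc], offset = offs,
                   events = ev, eligible = el,
                   rate = ifelse(el > 0, ev / el, NA_real_))
    })
    rbindlist(out)[]
}

#' Overall substitution-rate profile (all changes pooled)
#'
#' @inheritParams rate_profile
#' @return data.table (`offset`, `events`, `eligible`, `rate`).
#' @export
overall_rate_profile <- function(tab, type = c("inter", "intra"),
                                 cpg = c("excluded", "included")) {
    rp <- rate_profile(tab, type, cpg)
    out <- rp[, list(events = sum(events), eligible = sum(eligible) / 3),
              by = "offset"]
    # each eligible site is counted once per possible change (3x)
    out[, rate := ifelse(eligible > 0, events / eligible, NA_real_)]
    out[]
}

#' Background (neutral-proxy) divergence rates
#'
#' Rates pooled over the central positions (within `center_halfwidth`
#' of the midpoint) of the large (`d > l_min`) inter-barrier regions,
#' where nucleosome positioning is fuzzy and rates are flat; used to
#' correct the per-offset rates in the selection ratio.
#'
#' @param tab a `nieb_divtab`.
#' @return data.table (`change`, `bg_inter`, `bg_intra`,
#'   `events_inter`, `events_intra`, `eligible`).
#' @export
background_rates <- function(tab) {
    if (tab$n_large == 0L) stop("no large inter-barrier regions")
    tot <- apply(tab$W, 1L, sum)
    el <- tot[.anc_of_change]
    data.table(change = .CHANGES$label,
               bg_inter = ifelse(el > 0, tot[5:16] / el, NA_real_),
               bg_intra = ifelse(el > 0, tot[17:28] / el, NA_real_),
               events_inter = tot[5:16], events_intra = tot[17:28],
               eligible = el)
}

#' Background-corrected selection ratio per offset window
#'
#' `S = (dInter / backgroundInter) / (dIntra / backgroundIntra)` per
#' base change, computed over offset windows of `bin` bp (counts are
#' pooled within each window before any ratio is taken). `S > 1`
#' indicates an excess of fixed interspecies change (positive
#' selection), `S < 1` an excess of polymorphism (purifying selection).
#' Undefined components (zero eligible sites, zero intraspecies events,
#' zero background) propagate as `NA`, never as infinities.
#'
#' @param tab a `nieb_divtab`.
#' @param background output of [background_rates()].
#' @param bin offset window width in bp (default 10, the resolution at
#'   which null realizations are drawn).
#' @return data.table (`change`, `offset` = window center, `d_inter`,
#'   `d_intra`, `S`).
#' @export
selection_profile <- function(tab, background = background_rates(tab),
                              bin = 10L) {
    inter <- rate_profile(tab, "inter")
    intra <- rate_profile(tab, "intra")
    grp <- function(off) floor((off - ifelse(off > 0, 1, 0)) / bin)
    pool <- function(rp) {
        rp[, list(offset = mean(offset), events = sum(events),
                  eligible = sum(eligible)),
           by = list(change, win = grp(offset))]
    }
    a <- pool(inter); b <- pool(intra)
    setnames(b, c("events", "eligible"), c("events_i", "eligible_i"))
    m <- merge(a, b, by = c("change", "win", "offset"))
    m <- merge(m, background[, c("change", "bg_inter", "bg_intra")],
               by = "change")
    m[, d_inter := ifelse(eligible > 0, events / eligible, NA_real_)]
    m[, d_intra := ifelse(eligible_i > 0, events_i / eligible_i, NA_real_)]
    m[, S := ifelse(!is.na(d_inter) & !is.na(d_intra) & d_intra > 0 &
                        bg_inter > 0 & bg_intra > 0,
                    (d_inter / bg_inter) / (d_intra / bg_intra),
                    NA_real_)]
    setorder(m, change, offset)
    m[, c("change", "offset", "d_inter", "d_intra", "S")]
}

#' Bootstrap neutral null for the selection ratio
#'
#' Each repetition draws one random `boot_window`-bp window (from the
#' non-overlapping tiling of the central span) in every large
#' inter-barrier region, pools the counts, and computes one realization
#' of S per base change against the fixed backgrounds. The 2.5/97.5 %
#' percentiles of the realizations are the 95 % confidence limits under
#' neutral evolution; realizations with an undefined S (no intraspecies
#' event in the drawn windows) are dropped from the percentiles.
#'
#' @param tab a `nieb_divtab`.
#' @param background output of [background_rates()].
#' @param reps bootstrap repetitions (default 10000; fewer than 100
#'   draws a warning).
#' @param conf confidence level (default 0.95).
#' @return list with `draws` (reps x 12 matrix of S realizations),
#'   `limits` (per change: lower, upper, n_defined), `reps`, `conf`.
#' @export
bootstrap_null <- function(tab, background = background_rates(tab),
                           reps = 10000L, conf = 0.95) {
    if (reps < 100L) warning("fewer than 100 bootstrap repetitions")
    if (tab$n_large == 0L) stop("no large inter-barrier regions")
    sums <- boot_window_sums(tab$W, as.integer(reps))
    S <- matrix(NA_real_, reps, 12L)
    colnames(S) <- .CHANGES$label
    for (cc in seq_len(12L)) {
        el <- sums[, .anc_of_change[cc]]
        di <- ifelse(el > 0, sums[, 4L + cc] / el, NA_real_)
        dp <- ifelse(el > 0, sums[, 16L + cc] / el, NA_real_)
        bi <- background$bg_inter[cc]
        bp <- background$bg_intra[cc]
        ok <- !is.na(di) & !is.na(dp) & dp > 0 & bi > 0 & bp > 0
        S[ok, cc] <- (di[ok] / bi) / (dp[ok] / bp)
    }
    alpha <- (1 - conf) / 2
    lims <- t(apply(S, 2L, function(x) {
        x <- x[!is.na(x)]
        if (length(x) == 0L) return(c(NA_real_, NA_real_, 0))
        c(quantile(x, alpha, names = FALSE),
          quantile(x, 1 - alpha, names = FALSE), length(x))
    }))
    limits <- data.table(change = .CHANGES$label,
                         lower = lims[, 1], upper = lims[, 2],
                         n_defined = as.integer(lims[, 3]))
    list(draws = S, limits = limits, reps = reps, conf = conf)
}

#' Empirical p-value of an observed S against the neutral null
#'
#' Read off the bootstrap histogram without multiple-test correction
#' (non-overlapping 10-bp windows are independent observations).
#'
#' @param s_obs observed S value(s).
#' @param null_draws numeric vector of null S realizations for the same
#'   change (a column of `bootstrap_null()$draws`).
#' @param side `"above"` (excess, positive selection) or `"below"`.
#' @return empirical p-value(s), with the +1 continuity convention.
#' @export
selection_pvalue <- function(s_obs, null_draws,
                             side = c("above", "below")) {
    side <- match.arg(side)
    x <- null_draws[!is.na(null_draws)]
    vapply(s_obs, function(s) {
        if (is.na(s)) return(NA_real_)
        k <- if (side == "above") sum(x >= s) else sum(x <= s)
        (k + 1) / (length(x) + 1)
    }, numeric(1))
}

#' Stationary GC content of a substitution-rate matrix
#'
#' Builds the 4x4 continuous-time generator whose off-diagonal entries
#' are the 12 per-ancestral-base substitution rates, solves for its
#' stationary distribution, and returns pi(G) + pi(C): the GC content
#' toward which a sequence evolving under those rates converges.
#'
#' @param rates numeric vector of 12 rates named or ordered as
#'   [change_classes()].
#' @return equilibrium GC fraction in `[0, 1]`, or `NA` for a
#'   degenerate (reducible to nothing / all-zero) matrix.
#' @export
stationary_gc <- function(rates) {
    if (length(rates) != 12L) stop("need 12 rates")
    if (!is.null(names(rates))) rates <- rates[.CHANGES$label]
    Q <- matrix(0, 4L, 4L, dimnames = list(.BASES, .BASES))
    for (i in seq_len(12L))
        Q[.CHANGES$from[i], .CHANGES$to[i]] <- rates[i]
    if (any(is.na(Q)) || all(Q == 0)) return(NA_real_)
    diag(Q) <- -rowSums(Q)
    A <- rbind(t(Q), rep(1, 4))
    pi_ <- tryCatch(qr.solve(A, c(0, 0, 0, 0, 1)),
                    error = function(e) rep(NA_real_, 4))
    if (anyNA(pi_) || any(pi_ < -1e-9)) return(NA_real_)
    unname(pi_["G"] + pi_["C"])
}

#' Equilibrium-GC profile along the barrier axis
#'
#' Per offset, assembles the 4x4 substitution matrix from the
#' CpG-inclusive interspecies rates (neighbor-dependency is not
#' modeled, but CpG substitutions are counted) and returns the
#' stationary GC fraction. Counts are pooled over `smooth`-bp windows
#' first to stabilize the per-offset matrices.
#'
#' @param tab a `nieb_divtab`.
#' @param smooth pooling window in bp (default 10).
#' @return data.table (`offset`, `gc_eq`).
#' @export
equilibrium_gc_profile <- function(tab, smooth = 10L) {
    rp <- rate_profile(tab, "inter", cpg = "included")
    grp <- function(off) floor((off - ifelse(off > 0, 1, 0)) / smooth)
    pooled <- rp[, list(offset = mean(offset), events = sum(events),
                        eligible = sum(eligible)),
                 by = list(change, win = grp(offset))]
    pooled[, rate := ifelse(eligible > 0, events / eligible, NA_real_)]
    out <- pooled[, list(gc_eq = {
        r <- rate[match(.CHANGES$label, change)]
        if (anyNA(r)) NA_real_ else stationary_gc(r)
    }), by = "offset"]
    setorder(out, offset)
    out[]
}
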