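# Synthetic-data generator: Poisson-placed AT-rich barriers with
# poly(dA:dT) edges, statistically positioned nucleosome dyads, neutral
# or position-dependently selected substitution and SNP processes with
# CpG hypermutability, patchy mappability and repeat masking. The
# defaults are the study conditions every recovery test runs under.

#' Ground-truth parameters of the synthetic generator
#'
#' Returns the parameter list (amendable via `...`) controlling every
#' synthetic input. Defaults emulate the human-autosome statistics the
#' analysis was designed around: mean border-to-border spacing 1541 bp,
#' barrier widths in `[36, 450]` bp with mean 153 bp, barrier GC 26.5 %
#' against a 37.9 % bulk with flanks averaging 42.5 % and oscillating
#' at the 153-bp repeat length, 0.5 % interspecies divergence, CpG
#' hypermutability, and a qualifying (MAF > 1 %) SNP density of about
#' 0.22 %.
#'
#' @param ... named overrides of any default.
#' @return named list of class `synth_truth`.
#' @export
synth_truth <- function(...) {
    tr <- list(
        # barrier placement and shape
        gap_mean = 1541, width_min = 36L, width_max = 450L,
        width_shape = 2.2, width_scale = 53,
        # composition
        gc_barrier = 0.265, gc_bulk = 0.379,
        gc_flank_amp = 0.0646, gc_osc_amp = 0.05, gc_decay = 400,
        nrl = 153, dyad_phase = 74,
        poly_len_min = 5L, poly_len_max = 12L,
        # nucleosome positioning
        footprint = 147L, linker_mean = 6, jitter_sd = 10,
        depletion = 0.15,
        # divergence processes
        outgroup_noise = 0.002,
        inter_ts = 3e-3, inter_tv = 1e-3, cpg_mult = 8,
        snp_qual_scale = 0.44,        # qualifying intra / inter intensity
        af_shape1 = 0.05, af_shape2 = 2,
        maf_min = 0.01,
        selection = NULL,             # list(changes=, mult=, where="inside")
        # track imperfections
        map_gap_rate = 1e-4, map_gap_mean = 250,
        mask_rate = 1 / 3000, mask_mean = 900,
        n_gap_rate = 2e-7, n_gap_mean = 1000)
    dots <- list(...)
    unknown <- setdiff(names(dots), names(tr))
    if (length(unknown))
        stop("unknown truth parameter(s): ", paste(unknown, collapse = ", "))
    tr[names(dots)] <- dots
    stopifnot(tr$gap_mean > 0, tr$width_min >= 1,
              tr$width_max >= tr$width_min,
              tr$gc_barrier > 0, tr$gc_barrier < 1)
    class(tr) <- "synth_truth"
    tr
}

# raw SNP intensity so that alleles passing the MAF filter arrive at
# snp_qual_scale times the interspecies intensity
.snp_raw_scale <- function(tr) {
    q <- stats::pbeta(tr$maf_min, tr$af_shape1, tr$af_shape2,
                      lower.tail = FALSE)
    tr$snp_qual_scale / q
}

# renewal process of patches: returns logical per-base vector
.renewal_patches <- function(len, rate, mean_len) {
    out <- logical(len)
    n <- rpois(1L, len * rate)
    if (n == 0L) return(out)
    starts <- sort(sample.int(len, n, replace = TRUE)) - 1L
    lens <- pmax(1L, round(rexp(n, 1 / mean_len)))
    for (k in seq_len(n)) {
        a <- starts[k] + 1L
        b <- min(starts[k] + lens[k], len)
        out[a:b] <- TRUE
    }
    out
}

#' Generate a synthetic genome with its barrier catalog
#'
#' Barriers are placed by a Poisson process (exponential
#' border-to-border gaps of mean `gap_mean`) with bounded widths, so
#' spacing statistics downstream see a Poisson-like exponential tail.
#' Barrier interiors are drawn at low GC with poly(dA)/poly(dT) runs
#' planted at both inner edges; flanks oscillate around an elevated GC
#' with the nucleosome repeat period, decaying into the bulk
#' composition. Unsequenced N runs and a repeat mask are added as
#' renewal patches.
#'
#' @param truth a [synth_truth()] list.
#' @param n_chrom number of chromosomes.
#' @param chrom_length length of each chromosome (bp).
#' @param seed optional integer seed.
#' @return list with `genome` (`nieb_genome`), `catalog` (interval
#'   table) and `truth`.
#' @export
generate_genome <- function(truth, n_chrom = 20L, chrom_length = 3e5,
                            seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    tr <- truth
    mean_w <- tr$width_min + tr$width_shape * tr$width_scale
    if (mean_w / (tr$gap_mean + mean_w) >= 1)
        stop("inconsistent parameters: barriers would tile the genome")
    chroms <- sprintf("chr%02d", seq_len(n_chrom))
    seqs <- vector("list", n_chrom)
    masks <- vector("list", n_chrom)
    cats <- vector("list", n_chrom)
    for (ci in seq_len(n_chrom)) {
        L <- as.integer(chrom_length)
        n_est <- ceiling(L / (tr$gap_mean + mean_w) * 1.6) + 10L
        gaps <- rexp(n_est, 1 / tr$gap_mean)
        widths <- pmin(tr$width_min +
                           rgamma(n_est, tr$width_shape, scale = tr$width_scale),
                       tr$width_max)
        widths <- round(widths)
        starts <- round(cumsum(gaps + widths) - widths)
        ends <- starts + widths
        keep <- !is.na(ends) & ends <= L & starts >= 0
        starts <- as.integer(starts[keep])
        ends <- as.integer(ends[keep])
        off <- border_offsets(starts, ends, L, max_out = 1500L)
        gc <- rep(tr$gc_bulk, L)
        inside <- !is.na(off$offset) & off$offset < 0L
        out <- !is.na(off$offset) & off$offset > 0L
        # interior draw compensates the GC-free poly(dA:dT) edges so the
        # whole-barrier mean hits the gc_barrier target
        poly_bar <- tr$poly_len_min + tr$poly_len_max
        gc[inside] <- tr$gc_barrier * mean_w / (mean_w - poly_bar)
        o <- off$offset[out]
        gc[out] <- tr$gc_bulk + exp(-o / tr$gc_decay) *
            (tr$gc_flank_amp +
                 tr$gc_osc_amp * cospi(2 * (o - tr$dyad_phase) / tr$nrl))
        u1 <- runif(L) < gc
        u2 <- runif(L) < 0.5
        base <- ifelse(u1, ifelse(u2, "G", "C"), ifelse(u2, "A", "T"))
        r <- charToRaw(paste(base, collapse = ""))
        # poly(dA:dT) runs delineating barrier edges
        nb <- length(starts)
        if (nb > 0L) {
            lenL <- sample(tr$poly_len_min:tr$poly_len_max, nb, replace = TRUE)
            lenR <- sample(tr$poly_len_min:tr$poly_len_max, nb, replace = TRUE)
            bL <- sample(c(.RAW_A, .RAW_T), nb, replace = TRUE)
            bR <- sample(c(.RAW_A, .RAW_T), nb, replace = TRUE)
            for (k in seq_len(nb)) {
                r[(starts[k] + 1L):(starts[k] + lenL[k])] <- bL[k]
                r[(ends[k] - lenR[k] + 1L):ends[k]] <- bR[k]
            }
        }
        ngap <- .renewal_patches(L, tr$n_gap_rate, tr$n_gap_mean)
        r[ngap] <- .RAW_N
        seqs[[ci]] <- rawToChar(r)
        masks[[ci]] <- .renewal_patches(L, tr$mask_rate, tr$mask_mean)
        cats[[ci]] <- data.table(chrom = chroms[ci], start = starts,
                                 end = ends)
    }
    names(seqs) <- chroms
    names(masks) <- chroms
    list(genome = genome_sequence(seqs, masks),
         catalog = rbindlist(cats)[], truth = tr)
}

#' Simulate nucleosome dyad tags
#'
#' In `"positioned"` mode nucleosomes are placed by boundary-anchored
#' statistical positioning: from each barrier border an array of
#' 147-bp footprints grows into the inter-barrier region with random
#' (geometric, mean `linker_mean`) linkers, filled from both ends
#' toward the middle, where accumulated linker variance washes
#' positional order out. Each placed dyad emits Poisson tags with
#' small positional jitter; barrier interiors emit residual tags at
#' `depletion` times the genome rate. In `"uniform"` mode tags are iid
#' Poisson everywhere (the null of the occupancy Z-test).
#'
#' @param truth a [synth_truth()] list.
#' @param catalog barrier catalog from [generate_genome()].
#' @param chrom_len named vector of chromosome lengths.
#' @param coverage expected tags per bp (default 0.3).
#' @param mode `"positioned"` or `"uniform"`.
#' @param seed optional integer seed.
#' @return tag track (`chrom`, `pos`, `count`).
#' @export
simulate_dyads <- function(truth, catalog, chrom_len, coverage = 0.3,
                           mode = c("positioned", "uniform"),
                           seed = NULL) {
    mode <- match.arg(mode)
    if (coverage <= 0) stop("coverage must be positive")
    if (!is.null(seed)) set.seed(seed)
    tr <- truth
    out <- list()
    for (ch in names(chrom_len)) {
        L <- chrom_len[[ch]]
        if (mode == "uniform") {
            n <- rpois(1L, L * coverage)
            pos <- sample.int(L, n, replace = TRUE) - 1L
            out[[ch]] <- data.table(chrom = ch, pos = pos)
            next
        }
        sub <- catalog[catalog$chrom == ch, ]
        bounds <- c(0L, as.vector(rbind(sub$start, sub$end)), L)
        gs <- bounds[seq(1L, length(bounds), by = 2L)]
        ge <- bounds[seq(2L, length(bounds), by = 2L)]
        half <- tr$footprint %/% 2L
        dyads <- integer(0)
        p_link <- 1 / (1 + tr$linker_mean)
        for (g in seq_along(gs)) {
            a <- gs[g]; b <- ge[g]
            if (b - a < tr$footprint) next
            mid <- (a + b) / 2
            fill <- function(from, dir) {
                d <- integer(0)
                edge <- from
                repeat {
                    lnk <- rgeom(1L, p_link)
                    ctr <- edge + dir * (lnk + half)
                    if (dir * (ctr - mid) > 0) break
                    d <- c(d, ctr)
                    edge <- ctr + dir * (tr$footprint - half)
                }
                d
            }
            dl <- fill(a, +1L)
            dr <- fill(b, -1L)
            # drop a colliding middle pair
            if (length(dl) && length(dr) &&
                min(dr) - max(dl) < tr$footprint)
                dr <- dr[dr != min(dr)]
            dyads <- c(dyads, dl, dr)
        }
        tags_per_nuc <- coverage * tr$nrl
        cnt <- rpois(length(dyads), tags_per_nuc)
        pos <- rep(dyads, cnt) +
            as.integer(round(rnorm(sum(cnt), 0, tr$jitter_sd)))
        # residual tags inside barriers
        nin <- rpois(nrow(sub), (sub$end - sub$start) * coverage *
                         tr$depletion)
        ipos <- unlist(lapply(seq_len(nrow(sub)), function(k)
            if (nin[k] > 0)
                sample(sub$start[k]:(sub$end[k] - 1L), nin[k],
                       replace = TRUE) else integer(0)))
        pos <- c(pos, ipos)
        pos <- pos[pos >= 0L & pos < L]
        out[[ch]] <- data.table(chrom = ch, pos = pos)
    }
    tags <- rbindlist(out)[, list(count = .N), by = c("chrom", "pos")]
    setorder(tags, chrom, pos)
    tags[]
}

#' Simulate a patchy mappability track
#'
#' Unmappable patches are placed by a renewal process with the
#' configured start rate and mean length.
#'
#' @param truth a [synth_truth()] list.
#' @param chrom_len named vector of chromosome lengths.
#' @param seed optional integer seed.
#' @return named list of per-base logicals (TRUE = mappable).
#' @export
simulate_mappability <- function(truth, chrom_len, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    out <- lapply(chrom_len, function(L)
        !.renewal_patches(L, truth$map_gap_rate, truth$map_gap_mean))
    names(out) <- names(chrom_len)
    out
}

# per-site substitution of one lineage: returns raw vector
.mutate_uniform <- function(r, rate) {
    n <- length(r)
    hit <- which(runif(n) < rate & .is_acgt(r))
    if (length(hit)) {
        shift <- sample(1:3, length(hit), replace = TRUE)
        ids <- (.base_ids(r[hit]) - 1L + shift) %% 4L + 1L
        r[hit] <- charToRaw(paste(.BASES[ids], collapse = ""))
    }
    r
}

# intensity matrix per from-base: rows = target rank 1..3 (targets in
# .BASES order minus the from base)
.targets_of <- lapply(1:4, function(b) setdiff(1:4, b))

#' Simulate interspecies divergence and SNPs around barriers
#'
#' The generated genome is taken as the ancestral sequence. Three
#' outgroup copies receive small independent uniform noise (so the
#' flank-identity filter keeps most sites). The human copy mutates
#' per-site with the neutral change intensities, times the CpG
#' multiplier for the deamination channels (C>T and G>A at ancestral
#' CpG dinucleotides), times any configured selection multiplier
#' (interspecies only, e.g. S>W changes inside barriers). SNPs are
#' drawn the same way at the configured raw intensity with Beta
#' allele frequencies, most of which fall below the 1 % MAF filter.
#'
#' @param truth a [synth_truth()] list.
#' @param genome `nieb_genome` from [generate_genome()].
#' @param catalog matching barrier catalog.
#' @param seed optional integer seed.
#' @return list with `aln` (a `nieb_alignment`), `variants` (minimal
#'   variant table) and `truth_events` (realized event counts).
#' @export
simulate_divergence <- function(truth, genome, catalog, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    tr <- truth
    snp_raw <- .snp_raw_scale(tr)
    sel <- tr$selection
    sel_ids <- if (!is.null(sel)) match(sel$changes, .CHANGES$label) else
        integer(0)
    if (length(sel_ids) && anyNA(sel_ids)) stop("unknown selection change")
    cols <- list()
    vars <- list()
    n_inter <- 0L; n_snp <- 0L
    for (ch in names(genome)) {
        anc <- charToRaw(genome[[ch]]$seq)
        L <- length(anc)
        sub <- catalog[catalog$chrom == ch, ]
        off <- border_offsets(sub$start, sub$end, L, max_out = 1500L)
        inside <- !is.na(off$offset) & off$offset < 0L
        anc_id <- .base_ids(anc)
        is_ts <- matrix(FALSE, 4L, 3L) # transition indicator by from, rank
        for (b in 1:4) {
            tg <- .targets_of[[b]]
            is_ts[b, ] <- (.BASES[b] %in% c("A", "G") & .BASES[tg] %in%
                               c("G", "A")) |
                (.BASES[b] %in% c("C", "T") & .BASES[tg] %in% c("T", "C"))
        }
        cpg_c <- anc_id == 2L & c(anc_id[-1L], 0L) == 3L   # C of ancestral CpG
        cpg_g <- anc_id == 3L & c(0L, anc_id[-L]) == 2L    # its G
        human <- anc
        ev_pos <- integer(0); ev_to <- integer(0)
        snp_pos <- integer(0); snp_to <- integer(0)
        for (b in 1:4) {
            sites <- which(anc_id == b)
            if (!length(sites)) next
            tg <- .targets_of[[b]]
            p <- matrix(0, length(sites), 3L)
            ps <- matrix(0, length(sites), 3L)
            for (k in 1:3) {
                lam <- if (is_ts[b, k]) tr$inter_ts else tr$inter_tv
                lam_s <- lam * snp_raw
                lam <- rep(lam, length(sites))
                lam_s <- rep(lam_s, length(sites))
                # CpG deamination channels
                if (b == 2L && .BASES[tg[k]] == "T") {
                    w <- cpg_c[sites]
                    lam[w] <- lam[w] * tr$cpg_mult
                    lam_s[w] <- lam_s[w] * tr$cpg_mult
                } else if (b == 3L && .BASES[tg[k]] == "A") {
                    w <- cpg_g[sites]
                    lam[w] <- lam[w] * tr$cpg_mult
                    lam_s[w] <- lam_s[w] * tr$cpg_mult
                }
                cid <- .change_lut[b, tg[k]]
                if (cid %in% sel_ids && identical(sel$where, "inside")) {
                    w <- inside[sites]
                    lam[w] <- lam[w] * sel$mult
                }
                p[, k] <- lam
                ps[, k] <- lam_s
            }
            u <- runif(length(sites))
            cum <- cbind(p[, 1], p[, 1] + p[, 2], p[, 1] + p[, 2] + p[, 3])
            pick <- (u < cum[, 1]) + (u < cum[, 2]) + (u < cum[, 3])
            hit <- pick > 0L
            ev_pos <- c(ev_pos, sites[hit])
            ev_to <- c(ev_to, tg[4L - pick[hit]])
            u2 <- runif(length(sites))
            cum2 <- cbind(ps[, 1], ps[, 1] + ps[, 2],
                          ps[, 1] + ps[, 2] + ps[, 3])
            pick2 <- (u2 < cum2[, 1]) + (u2 < cum2[, 2]) + (u2 < cum2[, 3])
            hit2 <- pick2 > 0L & !hit # no SNP where the lineage substituted
            snp_pos <- c(snp_pos, sites[hit2])
            snp_to <- c(snp_to, tg[4L - pick2[hit2]])
        }
        if (length(ev_pos))
            human[ev_pos] <- charToRaw(paste(.BASES[ev_to], collapse = ""))
        chimp <- .mutate_uniform(anc, tr$outgroup_noise)
        orang <- .mutate_uniform(anc, tr$outgroup_noise)
        macaq <- .mutate_uniform(anc, tr$outgroup_noise)
        cols[[ch]] <- list(h = rawToChar(human), c = rawToChar(chimp),
                           o = rawToChar(orang), m = rawToChar(macaq))
        if (length(snp_pos)) {
            ord <- order(snp_pos)
            snp_pos <- snp_pos[ord]; snp_to <- snp_to[ord]
            vars[[ch]] <- data.table(
                chrom = ch, pos = snp_pos - 1L,
                ref = .BASES[.base_ids(anc[snp_pos])],
                alt = .BASES[snp_to],
                af = rbeta(length(snp_pos), tr$af_shape1, tr$af_shape2))
        }
        n_inter <- n_inter + length(ev_pos)
        n_snp <- n_snp + length(snp_pos)
    }
    variants <- if (length(vars)) rbindlist(vars) else
        data.table(chrom = character(), pos = integer(),
                   ref = character(), alt = character(), af = numeric())
    list(aln = alignment_table(cols), variants = variants,
         truth_events = list(n_inter = n_inter, n_snp = n_snp))
}

#' One-call synthetic dataset
#'
#' Generates genome, catalog, mappability, dyad tags and divergence
#' data in a fixed order from a single seed, so the whole dataset is
#' bit-reproducible from `(truth, dimensions, seed)`.
#'
#' @inheritParams generate_genome
#' @param coverage dyad-tag coverage (tags/bp).
#' @param dyad_mode `"positioned"` or `"uniform"`.
#' @param with_divergence simulate alignment and SNPs (default TRUE).
#' @param with_dyads simulate dyad tags (default TRUE).
#' @return list with `genome`, `catalog`, `mappability`, `tags`,
#'   `aln`, `variants`, `truth`.
#' @export
simulate_dataset <- function(truth = synth_truth(), n_chrom = 20L,
                             chrom_length = 3e5, seed = 1L,
                             coverage = 0.3,
                             dyad_mode = "positioned",
                             with_divergence = TRUE,
                             with_dyads = TRUE) {
    set.seed(seed)
    gg <- generate_genome(truth, n_chrom, chrom_length)
    clen <- chrom_lengths(gg$genome)
    mp <- simulate_mappability(truth, clen)
    tags <- if (with_dyads)
        simulate_dyads(truth, gg$catalog, clen, coverage, dyad_mode) else
        NULL
    div <- if (with_divergence)
        simulate_divergence(truth, gg$genome, gg$catalog) else NULL
    list(genome = gg$genome, catalog = gg$catalog, mappability = mp,
         tags = tags, aln = div$aln, variants = div$variants,
         truth = truth, seed = seed)
}
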