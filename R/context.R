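# Context-dependent substitution rates: rates of X>Y restricted to
# sites whose ancestral trinucleotide matches a flanking-base class
# (e.g. tTt>tAt, sTs>sAs with s in {c,g}), with the same background
# correction and reverse-complement symmetrization as the plain rates.

#' Define a context-dependent change class
#'
#' A context class is a set of allowed left flanking bases, a central
#' ancestral base, a target base, and a set of allowed right flanking
#' bases, all matched on the ancestral sequence. Overlapping classes
#' are allowed.
#'
#' @param left,right character vectors of allowed flanking bases.
#' @param x ancestral central base; `y` the human target base.
#' @param name optional label (defaults to e.g. `"tTt>tAt"`, with
#'   multi-base flanks shown as a set).
#' @return list of class `nieb_context`.
#' @export
context_spec <- function(left, x, y, right, name = NULL) {
    stopifnot(all(c(left, x, y, right) %in% .BASES), x != y)
    if (is.null(name)) {
        fmt <- function(s) if (length(s) == 1L) tolower(s) else
            paste0("[", paste(tolower(s), collapse = ""), "]")
        name <- paste0(fmt(left), x, fmt(right), ">",
                       fmt(left), y, fmt(right))
    }
    structure(list(left = left, x = x, y = y, right = right,
                   name = name), class = "nieb_context")
}

#' @rdname context_spec
#' @param spec a `nieb_context`.
#' @return `revcomp_context()` returns the reverse-complement class
#'   (e.g. tTt>tAt becomes aAa>aTa).
#' @export
revcomp_context <- function(spec) {
    context_spec(left = unname(.COMP[spec$right]),
                 x = unname(.COMP[spec$x]),
                 y = unname(.COMP[spec$y]),
                 right = unname(.COMP[spec$left]))
}

#' The context classes of the poly(dA:dT) analysis
#'
#' tTt>tAt, sTs>sAs (s in {c,g}), aGa>aAa and its complement-flank
#' contrast (left/right flanks in {c,t,g}), plus their reverse
#' complements added automatically during profiling.
#'
#' @return list of `nieb_context` objects.
#' @export
default_contexts <- function() {
    notA <- c("C", "T", "G")
    list(context_spec("T", "T", "A", "T"),
         context_spec(c("C", "G"), "T", "A", c("C", "G")),
         context_spec("A", "G", "A", "A"),
         context_spec(notA, "G", "A", notA))
}

# per-chromosome counts for one context on one side-resolved axis
.context_counts_chrom <- function(spec, fl, excl, idx, side, K,
                                  central_p1, hum, intra_pos, intra_to) {
    anc <- fl$anc
    n <- length(anc)
    Lok <- anc %in% match(spec$left, .BASES)
    Rok <- anc %in% match(spec$right, .BASES)
    xid <- match(spec$x, .BASES)
    yid <- match(spec$y, .BASES)
    memb <- fl$elig & anc == xid &
        c(FALSE, Lok[-n]) & c(Rok[-1L], FALSE) & !excl
    ev <- memb & hum == yid
    out <- list(elig = matrix(0, K, 2L), inter = matrix(0, K, 2L),
                intra = matrix(0, K, 2L),
                bg = c(elig = 0, inter = 0, intra = 0))
    for (s in 1:2) {
        sel <- memb & side == s & !is.na(idx)
        out$elig[, s] <- tabulate(idx[sel], nbins = K)
        out$inter[, s] <- tabulate(idx[sel & ev], nbins = K)
    }
    iv <- intra_pos[intra_to == yid & memb[intra_pos]]
    if (length(iv)) {
        for (s in 1:2) {
            sel <- side[iv] == s & !is.na(idx[iv])
            out$intra[, s] <- tabulate(idx[iv][sel], nbins = K)
        }
    }
    cm <- memb[central_p1]
    out$bg["elig"] <- sum(cm)
    out$bg["inter"] <- sum(ev[central_p1][cm])
    if (length(iv))
        out$bg["intra"] <- sum(iv %in% central_p1)
    out
}

#' Context-dependent rate and selection profiles
#'
#' For each context class (and, pooled by reverse-complement
#' symmetrization, its complementary class on the 5' side of
#' barriers), computes per-offset-window eligible counts, interspecies
#' and intraspecies events, rates, the per-context background from the
#' central spans of large inter-barrier regions, and the
#' background-corrected selection ratio S. Counts are pooled over
#' `bin`-bp offset windows.
#'
#' @param aln a `nieb_alignment`.
#' @param catalog sorted barrier interval table.
#' @param chrom_len named vector of chromosome lengths.
#' @param contexts list of [context_spec()] classes (default
#'   [default_contexts()]).
#' @param variants optional variant table for intraspecies events.
#' @inheritParams divergence_tables
#' @param bin offset pooling window (default 30 bp, the smoothing used
#'   for context profiles).
#' @return data.table (`context`, `offset`, `eligible`,
#'   `events_inter`, `events_intra`, `rate_inter`, `rate_intra`,
#'   `bg_inter`, `bg_intra`, `S`).
#' @export
context_rate_profile <- function(aln, catalog, chrom_len,
                                 contexts = default_contexts(),
                                 variants = NULL, max_in = 225L,
                                 max_out = 1000L, maf_min = 0.01,
                                 cpg_strand_symmetric = TRUE,
                                 l_min = 800L, center_halfwidth = 300L,
                                 bin = 30L) {
    K <- max_in + max_out
    specs <- lapply(contexts, function(sp)
        list(fwd = sp, rev = revcomp_context(sp)))
    acc <- lapply(specs, function(x)
        list(fwd = NULL, rev = NULL))
    zero <- list(elig = matrix(0, K, 2L), inter = matrix(0, K, 2L),
                 intra = matrix(0, K, 2L),
                 bg = c(elig = 0, inter = 0, intra = 0))
    add <- function(a, b) {
        if (is.null(a)) a <- zero
        list(elig = a$elig + b$elig, inter = a$inter + b$inter,
             intra = a$intra + b$intra, bg = a$bg + b$bg)
    }
    flags_all <- detect_isolated_substitutions(aln)
    cpg_all <- detect_cpg_sites(aln)
    regions <- internieb_regions(catalog)
    large <- regions[regions$d > l_min]
    for (ch in names(chrom_len)) {
        fl <- flags_all[[ch]]
        cp <- cpg_all[[ch]]
        sub <- catalog[catalog$chrom == ch, ]
        off <- border_offsets(sub$start, sub$end, chrom_len[[ch]], max_out)
        idx <- .axis_index(off$offset, max_in, max_out)
        excl <- rep(FALSE, length(fl$anc))
        excl[fl$anc == 2L] <- cp$cpg_c[fl$anc == 2L]
        if (cpg_strand_symmetric)
            excl[fl$anc == 3L] <- cp$cpg_g[fl$anc == 3L]
        hum <- fl$hum
        lg <- large[large$chrom == ch]
        central_p1 <- if (nrow(lg)) {
            mid <- (lg$start + lg$end) %/% 2L
            as.vector(outer(seq_len(2L * center_halfwidth) - 1L,
                            mid - center_halfwidth, `+`)) + 1L
        } else integer(0)
        # qualifying intraspecies events, any change
        vch <- if (!is.null(variants))
            as.data.table(variants)[variants$chrom == ch] else NULL
        if (!is.null(vch) && nrow(vch)) {
            fl2 <- fl
            undef <- fl2$anc == 0L
            chimp <- .base_ids(charToRaw(aln[[ch]]$c))
            fl2$anc[undef] <- chimp[undef]
            ie <- .intra_events(vch, fl2, maf_min)
            intra_pos <- ie$pos + 1L
            intra_to <- match(.CHANGES$to[ie$change], .BASES)
        } else {
            intra_pos <- integer(0); intra_to <- integer(0)
        }
        for (k in seq_along(specs)) {
            acc[[k]]$fwd <- add(acc[[k]]$fwd, .context_counts_chrom(
                specs[[k]]$fwd, fl, excl, idx, off$side, K, central_p1,
                hum, intra_pos, intra_to))
            acc[[k]]$rev <- add(acc[[k]]$rev, .context_counts_chrom(
                specs[[k]]$rev, fl, excl, idx, off$side, K, central_p1,
                hum, intra_pos, intra_to))
        }
    }
    offs <- .axis_offsets(max_in, max_out)
    grp <- floor((offs - ifelse(offs > 0, 1, 0)) / bin)
    out <- lapply(seq_along(specs), function(k) {
        a <- acc[[k]]
        # 3' side of the class pooled with 5' side of its revcomp
        el <- a$fwd$elig[, 2L] + a$rev$elig[, 1L]
        ei <- a$fwd$inter[, 2L] + a$rev$inter[, 1L]
        ep <- a$fwd$intra[, 2L] + a$rev$intra[, 1L]
        dt <- data.table(win = grp, offset = offs, el = el, ei = ei,
                         ep = ep)
        dd <- dt[, list(offset = mean(offset), eligible = sum(el),
                        events_inter = sum(ei), events_intra = sum(ep)),
                 by = "win"]
        bg <- a$fwd$bg + a$rev$bg
        bg_inter <- if (bg["elig"] > 0) bg[["inter"]] / bg[["elig"]] else
            NA_real_
        bg_intra <- if (bg["elig"] > 0) bg[["intra"]] / bg[["elig"]] else
            NA_real_
        dd[, rate_inter := ifelse(eligible > 0, events_inter / eligible,
                                  NA_real_)]
        dd[, rate_intra := ifelse(eligible > 0, events_intra / eligible,
                                  NA_real_)]
        dd[, S := ifelse(!is.na(rate_inter) & !is.na(rate_intra) &
                             rate_intra > 0 & !is.na(bg_inter) &
                             !is.na(bg_intra) & bg_inter > 0 &
                             bg_intra > 0,
                         (rate_inter / bg_inter) / (rate_intra / bg_intra),
                         NA_real_)]
        dd[, context := specs[[k]]$fwd$name]
        dd[, bg_inter := bg_inter]
        dd[, bg_intra := bg_intra]
        dd[, win := NULL]
        setorder(dd, offset)
        dd
    })
    rbindlist(out)[, c("context", "offset", "eligible", "events_inter",
                       "events_intra", "rate_inter", "rate_intra",
                       "bg_inter", "bg_intra", "S")]
}
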