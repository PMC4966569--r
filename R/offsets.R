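# Distance-to-border coordinates around barriers.
#
# Every border-aligned statistic in the package uses the same axis:
# negative offsets are inside a barrier (measured to the nearer border,
# -1 = first interior base), positive offsets are outside (+1 = first
# flank base). There is no offset 0. Each site also carries the border
# it was measured from: the barrier's 5' (start) or 3' (end) border,
# which strand-aware statistics need for reverse-complement pooling.

#' Per-base offsets from the nearest barrier border
#'
#' @param starts,ends sorted, non-overlapping barrier coordinates
#'   (0-based half-open) on one chromosome.
#' @param len chromosome length.
#' @param max_out largest flank offset retained; farther sites get `NA`.
#' @return list with integer vector `offset` (negative inside, positive
#'   outside, `NA` beyond `max_out` or when the chromosome has no
#'   barrier) and integer vector `side` (1 = measured from a 5' border,
#'   2 = from a 3' border). Interior ties go to the 5' border; exterior
#'   ties to the 3' border of the preceding barrier.
#' @export
border_offsets <- function(starts, ends, len, max_out = 1000L) {
    n <- length(starts)
    offset <- rep(NA_integer_, len)
    side <- rep(NA_integer_, len)
    if (n == 0L) return(list(offset = offset, side = side))
    stopifnot(length(ends) == n, !is.unsorted(starts),
              all(ends > starts), all(head(ends, -1L) <= tail(starts, -1L)))
    p <- 0:(len - 1L)
    i <- findInterval(p, starts)          # index of barrier with start <= p
    inside <- i >= 1L & p < ends[pmax(i, 1L)]

    # interior: distance to nearer border, ties to 5'
    pi_ <- p[inside]; ii <- i[inside]
    dL <- pi_ - starts[ii] + 1L
    dR <- ends[ii] - pi_
    offset[inside] <- -pmin(dL, dR)
    side[inside] <- ifelse(dL <= dR, 1L, 2L)

    # exterior: nearer of the preceding 3' border / following 5' border
    po <- p[!inside]; io <- i[!inside]
    dLeft <- ifelse(io >= 1L, po - ends[pmax(io, 1L)] + 1L, NA_integer_)
    dRight <- ifelse(io < n, starts[pmin(io + 1L, n)] - po, NA_integer_)
    useL <- !is.na(dLeft) & (is.na(dRight) | dLeft <= dRight)
    d <- ifelse(useL, dLeft, dRight)
    s <- ifelse(useL, 2L, 1L)
    keep <- !is.na(d) & d <= max_out
    offset[!inside][keep] <- as.integer(d[keep])
    side[!inside][keep] <- s[keep]
    list(offset = offset, side = side)
}

#' Offsets for every chromosome of a catalog
#'
#' @param catalog barrier interval table (`chrom`, `start`, `end`).
#' @param chrom_len named vector of chromosome lengths.
#' @inheritParams border_offsets
#' @return named list (per chromosome) of [border_offsets()] results.
#' @export
catalog_offsets <- function(catalog, chrom_len, max_out = 1000L) {
    lapply(names(chrom_len), function(ch) {
        sub <- catalog[catalog$chrom == ch, ]
        border_offsets(sub$start, sub$end, chrom_len[[ch]], max_out)
    }) |> stats::setNames(names(chrom_len))
}

# Axis bookkeeping: offsets -max_in..-1, 1..max_out map to indices
# 1..(max_in + max_out).
.axis_offsets <- function(max_in, max_out) {
    c(seq.int(-max_in, -1L), seq_len(max_out))
}

.axis_index <- function(offset, max_in, max_out) {
    idx <- ifelse(offset < 0L, offset + max_in + 1L, offset + max_in)
    idx[!is.na(offset) & (offset < -max_in | offset > max_out)] <- NA_integer_
    idx
}
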