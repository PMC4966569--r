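# Per-barrier depletion/enrichment classification by Z-score, and the
# one-sided normal-approximate Welch comparison used for group-level
# P-value statements.

#' Per-barrier tag summaries inside barriers and in their flanks
#'
#' For every barrier, computes the mean and standard deviation of the
#' per-site tag count over mappable sites inside the barrier (`m1`,
#' `s1`, `n1`) and over its two flanking windows pooled (`m2`, `s2`,
#' `n2`). Standard deviations use the population form (denominator
#' `n`); at the site counts the test requires (`> 30`) the distinction
#' from `n - 1` is negligible. Flank windows are truncated at
#' neighboring barrier borders and chromosome ends.
#'
#' @param catalog sorted barrier interval table.
#' @param tags tag track (`chrom`, `pos`, `count`).
#' @param mappability named list of per-base logicals (TRUE = uniquely
#'   mappable); `NULL` treats every site as mappable.
#' @param chrom_len named vector of chromosome lengths.
#' @param flank flanking-window span in bp on each side (default 300).
#' @return data.table with one row per barrier: `chrom`, `start`,
#'   `end`, `m1`, `s1`, `n1`, `m2`, `s2`, `n2`.
#' @export
ztest_inputs <- function(catalog, tags, mappability = NULL, chrom_len,
                         flank = 300L) {
    dt <- as.data.table(catalog)
    setorder(dt, chrom, start)
    out <- list()
    for (ch in unique(dt$chrom)) {
        sub <- dt[dt$chrom == ch, ]
        L <- chrom_len[[ch]]
        x <- as.numeric(dense_tags(tags, ch, L))
        mp <- if (is.null(mappability)) rep(TRUE, L) else mappability[[ch]]
        cs_n <- cumsum(mp)
        cs_s <- cumsum(x * mp)
        cs_q <- cumsum(x * x * mp)
        at <- function(cs, i) ifelse(i > 0L, cs[pmax(i, 1L)], 0)
        stat <- function(a, b) { # [a, b), 0-based
            a <- pmax(a, 0L); b <- pmin(b, L)
            n <- at(cs_n, b) - at(cs_n, a)
            s <- at(cs_s, b) - at(cs_s, a)
            q <- at(cs_q, b) - at(cs_q, a)
            m <- ifelse(n > 0, s / n, NA_real_)
            list(n = n, s = s, q = q, m = m)
        }
        nb <- nrow(sub)
        prev_end <- c(0L, head(sub$end, -1L))
        next_start <- c(tail(sub$start, -1L), L)
        inn <- stat(sub$start, sub$end)
        fl <- stat(pmax(sub$start - flank, prev_end), sub$start)
        fr <- stat(sub$end, pmin(sub$end + flank, next_start))
        n2 <- fl$n + fr$n
        s2 <- fl$s + fr$s
        q2 <- fl$q + fr$q
        m2 <- ifelse(n2 > 0, s2 / n2, NA_real_)
        sd_of <- function(q, n, m) sqrt(pmax(q / n - m * m, 0))
        out[[ch]] <- data.table(
            chrom = ch, start = sub$start, end = sub$end,
            m1 = inn$m, s1 = sd_of(inn$q, pmax(inn$n, 1), inn$m),
            n1 = inn$n,
            m2 = m2, s2 = sd_of(q2, pmax(n2, 1), m2), n2 = n2)
    }
    rbindlist(out)[]
}

#' Z-test classification of barriers by flank-versus-interior occupancy
#'
#' Computes `z = (m2 - m1) / sqrt(s1^2/n1 + s2^2/n2)` for each barrier
#' and classifies it at the 5 % confidence level: `G1` (depleted,
#' `z > threshold`), `G2` (enriched, `z < -threshold`), `G3`
#' (otherwise). Barriers with `min(n1, n2) <= 30` mappable sites are
#' `excluded` (the normal approximation needs more than 30 sites).
#' When both variances vanish and the means agree the score is
#' undefined and the barrier falls in `G3` by convention.
#'
#' @param inputs data.frame with columns `m1`, `s1`, `n1`, `m2`, `s2`,
#'   `n2` (see [ztest_inputs()]).
#' @param threshold one-sided 5 % normal quantile (1.645).
#' @param min_n site-count requirement; `n1`, `n2` must exceed it.
#' @return `inputs` with columns `z` and `group` appended; `group` is a
#'   factor with levels `G1`, `G2`, `G3`, `excluded`.
#' @export
ztest_classify <- function(inputs, threshold = 1.645, min_n = 30L) {
    dt <- as.data.table(inputs)
    se <- sqrt(dt$s1^2 / dt$n1 + dt$s2^2 / dt$n2)
    z <- (dt$m2 - dt$m1) / se
    z[se == 0 & dt$m2 == dt$m1] <- NA_real_ # undefined, G3 by convention
    grp <- rep("G3", nrow(dt))
    grp[!is.na(z) & z > threshold] <- "G1"
    grp[!is.na(z) & z < -threshold] <- "G2"
    grp[pmin(dt$n1, dt$n2) <= min_n] <- "excluded"
    dt[, z := z]
    dt[, group := factor(grp, levels = c("G1", "G2", "G3", "excluded"))]
    dt[]
}

#' Group fractions over classified barriers
#'
#' @param results output of [ztest_classify()].
#' @return list with `fractions` (G1/G2/G3 shares of testable barriers,
#'   summing to 1), `n_tested`, `n_excluded`, `excluded_fraction` (of
#'   all barriers).
#' @export
group_summary <- function(results) {
    grp <- results$group
    tested <- grp != "excluded"
    tab <- table(factor(grp[tested], levels = c("G1", "G2", "G3")))
    fr <- as.numeric(tab) / sum(tab)
    names(fr) <- c("G1", "G2", "G3")
    list(fractions = fr,
         n_tested = sum(tested),
         n_excluded = sum(!tested),
         excluded_fraction = sum(!tested) / length(grp))
}

#' One-sided Welch comparison with normal approximation
#'
#' Unequal-variance comparison of two sample means, with the t
#' distribution approximated by a standard normal; returns the
#' one-sided p-value for the alternative `mean_a > mean_b`.
#'
#' @param m_a,sd_a,n_a summary of sample a.
#' @param m_b,sd_b,n_b summary of sample b.
#' @return one-sided p-value.
#' @export
welch_one_sided <- function(m_a, sd_a, n_a, m_b, sd_b, n_b) {
    if (any(c(n_a, n_b) <= 0)) stop("sample sizes must be positive")
    t <- (m_a - m_b) / sqrt(sd_a^2 / n_a + sd_b^2 / n_b)
    pnorm(t, lower.tail = FALSE)
}
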