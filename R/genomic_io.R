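# Readers/writers and small derived quantities.
#
# Coordinate convention: every interval in this package is 0-based
# half-open, the native BED convention. Formats that are 1-based are
# converted at the reader boundary.

#' Construct a genome sequence object
#'
#' A genome is a named list of per-chromosome records, each holding an
#' uppercase sequence string over `{A,C,G,T,N}` and an optional per-base
#' logical repeat mask (`TRUE` = masked).
#'
#' @param seqs named character vector or list of sequence strings.
#' @param masks optional named list of logical vectors, one per
#'   chromosome, each the same length as the sequence.
#' @return an object of class `nieb_genome`.
#' @export
genome_sequence <- function(seqs, masks = NULL) {
    if (is.null(names(seqs)) || any(names(seqs) == ""))
        stop("sequences must be named by chromosome")
    out <- lapply(names(seqs), function(ch) {
        s <- toupper(as.character(seqs[[ch]]))
        if (grepl("[^ACGTN]", s))
            stop("chromosome ", ch, ": symbols outside {A,C,G,T,N}")
        m <- masks[[ch]]
        if (!is.null(m) && length(m) != nchar(s))
            stop("chromosome ", ch, ": mask length != sequence length")
        list(chrom = ch, seq = s, mask = m)
    })
    names(out) <- names(seqs)
    class(out) <- "nieb_genome"
    out
}

#' @export
print.nieb_genome <- function(x, ...) {
    len <- vapply(x, function(g) nchar(g$seq), numeric(1))
    cat("<nieb_genome> ", length(x), " chromosome(s), ",
        format(sum(len), big.mark = ","), " bp\n", sep = "")
    invisible(x)
}

#' Chromosome lengths of a genome
#' @param genome a `nieb_genome`.
#' @return named integer vector of sequence lengths.
#' @export
chrom_lengths <- function(genome) {
    vapply(genome, function(g) nchar(g$seq), integer(1))
}

#' Read / write genomes as FASTA
#'
#' FASTA input goes through [Biostrings::readDNAStringSet()]. Lowercase
#' letters are interpreted, by the common convention, as repeat-masked
#' bases and become the genome's mask; set `lowercase_mask = FALSE` to
#' ignore case.
#'
#' @param path file path.
#' @param lowercase_mask logical; treat lowercase as repeat-masked.
#' @return `read_genome_fasta()` returns a `nieb_genome`.
#' @export
read_genome_fasta <- function(path, lowercase_mask = TRUE) {
    ss <- Biostrings::readBStringSet(path)
    seqs <- as.character(ss)
    names(seqs) <- sub("\\s.*$", "", names(ss))
    masks <- NULL
    if (lowercase_mask) {
        masks <- lapply(seqs, function(s) {
            r <- charToRaw(s)
            r >= charToRaw("a") & r <= charToRaw("z")
        })
        names(masks) <- names(seqs)
        if (!any(vapply(masks, any, logical(1)))) masks <- NULL
    }
    genome_sequence(seqs, masks)
}

#' @rdname read_genome_fasta
#' @param genome a `nieb_genome`; masked bases are written lowercase.
#' @export
write_genome_fasta <- function(genome, path) {
    seqs <- vapply(genome, function(g) {
        s <- g$seq
        if (!is.null(g$mask) && any(g$mask)) {
            r <- charToRaw(s)
            idx <- g$mask & r != .RAW_N
            r[idx] <- as.raw(as.integer(r[idx]) + 32L)
            s <- rawToChar(r)
        }
        s
    }, character(1))
    ss <- Biostrings::BStringSet(seqs)
    names(ss) <- names(genome)
    Biostrings::writeXStringSet(ss, path)
    invisible(path)
}

#' Read a BED interval file
#'
#' Reads 3+ column BED text into a sorted interval table (0-based
#' half-open). Malformed lines and inverted intervals are rejected with
#' the offending line number.
#'
#' @param path BED file path.
#' @return data.table with columns `chrom`, `start`, `end` (and `name`
#'   when a 4th column is present), sorted by (chrom, start).
#' @export
read_bed <- function(path) {
    lines <- readLines(path)
    keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
    lineno <- which(keep)
    fields <- strsplit(lines[keep], "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 3L))
        stop("malformed BED line ", lineno[which(nf < 3L)[1]],
             ": fewer than 3 fields")
    chrom <- vapply(fields, `[[`, character(1), 1L)
    start <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 2L)))
    end <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 3L)))
    bad <- is.na(start) | is.na(end)
    if (any(bad))
        stop("malformed BED line ", lineno[which(bad)[1]],
             ": non-numeric coordinates")
    inv <- start >= end
    if (any(inv))
        stop("malformed BED line ", lineno[which(inv)[1]],
             ": start >= end")
    out <- data.table(chrom = chrom, start = as.integer(start),
                      end = as.integer(end))
    if (all(nf >= 4L)) out[, "name" := vapply(fields, `[[`, character(1), 4L)]
    setorder(out, chrom, start)
    out[]
}

#' @rdname read_bed
#' @param intervals interval table with `chrom`, `start`, `end` columns.
#' @export
write_bed <- function(intervals, path) {
    stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
    dt <- as.data.table(intervals)
    cols <- intersect(c("chrom", "start", "end", "name"), names(dt))
    fwrite(dt[, cols, with = FALSE], path, sep = "\t",
           col.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Merge overlapping or bookended intervals
#'
#' @param intervals interval table (`chrom`, `start`, `end`).
#' @return merged, sorted, non-overlapping interval table.
#' @export
merge_intervals <- function(intervals) {
    dt <- as.data.table(intervals)[, c("chrom", "start", "end")]
    setorder(dt, chrom, start)
    dt[, grp := cumsum(start > c(-Inf, head(cummax(end), -1L))),
       by = "chrom"]
    out <- dt[, list(start = min(start), end = max(end)),
              by = c("chrom", "grp")]
    out[, grp := NULL]
    out[]
}

#' Assign MNase read 5' positions to nucleosome dyads
#'
#' Each read's 5' position is shifted toward the nucleosome center:
#' `+shift` bp for plus-strand reads, `-shift` bp for minus-strand
#' reads. Shifted positions falling off the chromosome are dropped and
#' counted.
#'
#' @param reads data.frame with columns `chrom`, `pos` (0-based 5'
#'   position) and `strand` (`"+"` or `"-"`).
#' @param chrom_len named vector of chromosome lengths.
#' @param shift dyad shift in bp (default 70, appropriate for the short
#'   MNase-seq reads the analysis was designed around; configurable
#'   because read-length conventions vary).
#' @return a tag track: data.table (`chrom`, `pos`, `count`) of dyad
#'   counts, with attribute `dropped` giving the number of off-chromosome
#'   reads discarded.
#' @export
assign_dyads <- function(reads, chrom_len, shift = 70L) {
    stopifnot(all(c("chrom", "pos", "strand") %in% names(reads)))
    if (!all(reads$strand %in% c("+", "-")))
        stop("strand must be '+' or '-'")
    dt <- as.data.table(reads)
    dyad <- dt$pos + ifelse(dt$strand == "+", shift, -shift)
    len <- chrom_len[dt$chrom]
    ok <- dyad >= 0L & dyad < len
    dropped <- sum(!ok)
    if (dropped > 0L)
        message("assign_dyads: dropped ", dropped, " off-chromosome dyads")
    out <- data.table(chrom = dt$chrom[ok], pos = as.integer(dyad[ok]))
    out <- out[, list(count = .N), by = c("chrom", "pos")]
    setorder(out, chrom, pos)
    setattr(out, "dropped", dropped)
    out[]
}

#' Expand a sparse tag track to a dense per-base vector
#' @param tags tag track (`chrom`, `pos`, `count`).
#' @param chrom chromosome name.
#' @param len chromosome length.
#' @return integer vector of per-base tag counts.
#' @export
dense_tags <- function(tags, chrom, len) {
    out <- integer(len)
    keep <- tags$chrom == chrom # plain subset: avoids data.table scoping
    out[tags$pos[keep] + 1L] <- tags$count[keep]
    out
}

#' RPKM expression measure
#'
#' Reads per kilobase of exon model per million mapped reads:
#' `R = 1e9 * C / (N * L)` with `C` the exon-overlapping read count,
#' `N` the total mapped reads and `L` the total exon length in bp.
#'
#' @param C mappable exon-overlapping read count (C = 0 gives R = 0).
#' @param N total mapped reads (> 0).
#' @param L total exon length in bp (> 0).
#' @return RPKM value(s); `NA` where `N` or `L` is non-positive or `C`
#'   negative.
#' @export
rpkm <- function(C, N, L) {
    bad <- !(N > 0 & L > 0) | C < 0
    out <- 1e9 * C / (N * L)
    out[bad] <- NA_real_
    out
}

#' Crossover rate of a window from a genetic map
#'
#' The rate is the genetic distance (cM) between the two most distant
#' markers inside the window divided by their physical distance (Mb).
#' Windows with fewer than `min_markers` markers are undefined, as are
#' windows whose extreme markers coincide physically.
#'
#' @param start,end window in 0-based half-open bp coordinates (markers
#'   on the boundary belong to the window whose half-open span contains
#'   them).
#' @param markers data.frame with columns `pos` (bp) and `cM`, sorted by
#'   position, genetic positions non-decreasing.
#' @param min_markers minimum marker count (default 5).
#' @return crossover rate in cM/Mb, or `NA` when undefined.
#' @export
crossover_rate <- function(start, end, markers, min_markers = 5L) {
    stopifnot(all(c("pos", "cM") %in% names(markers)))
    inw <- markers$pos >= start & markers$pos < end
    if (sum(inw) < min_markers) return(NA_real_)
    sub <- markers[inw, , drop = FALSE]
    i <- which.min(sub$pos); j <- which.max(sub$pos)
    dbp <- sub$pos[j] - sub$pos[i]
    if (dbp == 0) return(NA_real_)
    (sub$cM[j] - sub$cM[i]) / (dbp / 1e6)
}

#' Intergenic regions from a merged gene set
#'
#' Gaps between consecutive (merged) genes, shrunk by `margin` bp on
#' each gene-adjacent side so that the retained intervals are safely
#' intergenic; gaps of `<= 2*margin` bp vanish. Chromosome-end gaps are
#' shrunk only on their gene side. Genes, intergenes and the margin
#' buffers partition each chromosome.
#'
#' @param genes merged, non-overlapping gene interval table.
#' @param chrom_len named vector of chromosome lengths.
#' @param margin bp removed from each side of every gap (default 2000).
#' @return interval table of intergenic regions.
#' @export
build_intergenes <- function(genes, chrom_len, margin = 2000L) {
    dt <- merge_intervals(genes)
    out <- lapply(names(chrom_len), function(ch) {
        g <- dt[dt$chrom == ch, ]
        L <- chrom_len[[ch]]
        if (nrow(g) == 0L)
            return(data.table(chrom = ch, start = 0L, end = as.integer(L)))
        gap_start <- c(0L, g$end + margin)
        gap_end <- c(g$start - margin, as.integer(L))
        # interior gaps got a margin on both sides; terminal gaps on one
        keep <- gap_start < gap_end
        data.table(chrom = ch, start = as.integer(gap_start[keep]),
                   end = as.integer(gap_end[keep]))
    })
    rbindlist(out)[]
}

#' Read / write a minimal variant table
#'
#' The minimal VCF interface used throughout: columns CHROM, POS
#' (1-based in the file, converted to 0-based in memory), REF, ALT and
#' an `AF=` INFO value giving the alternate-allele frequency.
#'
#' @param path file path.
#' @return data.table with columns `chrom`, `pos` (0-based), `ref`,
#'   `alt`, `af`.
#' @export
read_variants_vcf <- function(path) {
    lines <- readLines(path)
    body <- lines[!grepl("^#", lines) & nzchar(lines)]
    if (length(body) == 0L)
        return(data.table(chrom = character(), pos = integer(),
                          ref = character(), alt = character(),
                          af = numeric()))
    f <- strsplit(body, "\t", fixed = TRUE)
    if (any(lengths(f) < 8L)) stop("malformed VCF record")
    af <- vapply(f, function(x) {
        m <- regmatches(x[[8]], regexpr("AF=[0-9.eE+-]+", x[[8]]))
        if (length(m) == 0L) return(NA_real_)
        as.numeric(sub("AF=", "", m))
    }, numeric(1))
    out <- data.table(chrom = vapply(f, `[[`, character(1), 1L),
                      pos = as.integer(vapply(f, `[[`, character(1), 2L)) - 1L,
                      ref = vapply(f, `[[`, character(1), 4L),
                      alt = vapply(f, `[[`, character(1), 5L),
                      af = af)
    bad <- !(out$ref %in% .BASES) | !(out$alt %in% .BASES) |
        is.na(out$af) | out$af < 0 | out$af > 1
    if (any(bad)) stop("invalid variant record at line ", which(bad)[1])
    setorder(out, chrom, pos)
    out[]
}

#' @rdname read_variants_vcf
#' @param variants variant table as returned by [read_variants_vcf()].
#' @export
write_variants_vcf <- function(variants, path) {
    hdr <- c("##fileformat=VCFv4.2",
             "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Allele Frequency\">",
             "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
    rec <- sprintf("%s\t%d\t.\t%s\t%s\t.\t.\tAF=%s",
                   variants$chrom, variants$pos + 1L, variants$ref,
                   variants$alt, format(variants$af, digits = 6,
                                        scientific = FALSE, trim = TRUE))
    writeLines(c(hdr, rec), path)
    invisible(path)
}
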