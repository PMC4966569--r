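# Base-letter constants used throughout raw-vector sequence code.
.BASES <- c("A", "C", "G", "T")
.RAW_A <- charToRaw("A")
.RAW_C <- charToRaw("C")
.RAW_G <- charToRaw("G")
.RAW_T <- charToRaw("T")
.RAW_N <- charToRaw("N")

# The 12 single-base changes in fixed order: from-base major, to-base minor.
.CHANGES <- local({
    from <- rep(.BASES, each = 3L)
    to <- unlist(lapply(.BASES, function(b) setdiff(.BASES, b)))
    data.frame(id = seq_len(12L), from = from, to = to,
               label = paste0(from, ">", to), stringsAsFactors = FALSE)
})

.COMP <- c(A = "T", C = "G", G = "C", T = "A")

#' The 12 single-base substitution classes
#'
#' Fixed ordering of the 12 possible single-base changes (`"A>C"`,
#' `"A>G"`, ...) used by every rate table in the package, together with
#' complement lookup.
#'
#' @return `change_classes()` returns a data.frame with columns `id`,
#'   `from`, `to`, `label`; `complement_change()` maps change labels to
#'   the label of the complementary change (e.g. `"G>A"` to `"C>T"`).
#' @param label character vector of change labels such as `"G>A"`.
#' @export
#' @examples
#' change_classes()
#' complement_change("G>A")
change_classes <- function() .CHANGES

#' @rdname change_classes
#' @export
complement_change <- function(label) {
    i <- match(label, .CHANGES$label)
    if (anyNA(i)) stop("unknown change label: ",
                       paste(label[is.na(i)], collapse = ", "))
    paste0(.COMP[.CHANGES$from[i]], ">", .COMP[.CHANGES$to[i]])
}

# id of the complementary change, vectorised over 1:12
.comp_change_id <- local({
    function() match(complement_change(.CHANGES$label), .CHANGES$label)
})

.is_acgt <- function(x) x == .RAW_A | x == .RAW_C | x == .RAW_G | x == .RAW_T

.base_ids <- function(x) {
    # raw vector -> integer codes A=1 C=2 G=3 T=4, 0 otherwise
    out <- integer(length(x))
    out[x == .RAW_A] <- 1L
    out[x == .RAW_C] <- 2L
    out[x == .RAW_G] <- 3L
    out[x == .RAW_T] <- 4L
    out
}
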