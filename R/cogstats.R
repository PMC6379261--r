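#' @importFrom stats fisher.test p.adjust
NULL

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value by the minimum-likelihood rule: the sum of
#' hypergeometric probabilities (margins fixed) of all tables no more
#' probable than the observed one. A table with any zero margin carries no
#' information and returns p = 1 by convention (with a message).
#'
#' @param a,b,c,d non-negative integer cell counts, row-wise:
#'   `[[a, b], [c, d]]`.
#' @return the two-sided p-value.
#' @export
fisherExact2x2 <- function(a, b, c, d) {
    counts <- c(a, b, c, d)
    stopifnot(all(counts >= 0), all(counts == round(counts)))
    if (a + b == 0 || c + d == 0 || a + c == 0 || b + d == 0) {
        message("zero margin: p = 1 by convention")
        return(1)
    }
    stats::fisher.test(matrix(counts, nrow = 2, byrow = TRUE))$p.value
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `q_(i) = min_{j >= i} m * p_(j) / j`, capped at 1, returned in the
#' original order.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return q-values of the same length and order.
#' @export
bhAdjust <- function(p_values) {
    stopifnot(all(p_values >= 0 & p_values <= 1))
    stats::p.adjust(p_values, method = "BH")
}

#' Compare COG category usage between two replicons
#'
#' For every functional category present in either replicon, tests the 2x2
#' table (in-category vs not, replicon A vs B) with [fisherExact2x2()], then
#' adjusts over the categories of this pair with [bhAdjust()] (the FDR
#' family is the replicon pair). Counts are protein-category assignments:
#' a multi-category protein contributes once per assigned category.
#'
#' @param counts data.frame with columns `replicon`, `category`, `count`.
#' @param pair character vector of two replicon ids present in `counts`.
#' @param alpha,alpha_strict significance levels for the two flags.
#' @return data.frame with one row per category: counts, proportions,
#'   `p_value`, `q_value` and significance flags.
#' @export
compareReplicons <- function(counts, pair, alpha = 0.05, alpha_strict = 0.01) {
    stopifnot(length(pair) == 2)
    miss <- setdiff(pair, unique(counts$replicon))
    if (length(miss)) stop("replicon(s) absent from table: ",
                           paste(miss, collapse = ", "))
    sub <- counts[counts$replicon %in% pair, , drop = FALSE]
    tot <- tapply(sub$count, sub$replicon, sum)[pair]
    cats <- sort(unique(sub$category[sub$count > 0]))
    getc <- function(repl, cat) {
        v <- sub$count[sub$replicon == repl & sub$category == cat]
        if (length(v)) sum(v) else 0L
    }
    rows <- lapply(cats, function(cat) {
        a <- getc(pair[1], cat); c2 <- getc(pair[2], cat)
        data.frame(category = cat, replicon_a = pair[1], replicon_b = pair[2],
                   count_a = a, count_b = c2,
                   prop_a = a / tot[[1]], prop_b = c2 / tot[[2]],
                   p_value = suppressMessages(
                       fisherExact2x2(a, tot[[1]] - a, c2, tot[[2]] - c2)),
                   stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, rows)
    res$q_value <- bhAdjust(res$p_value)
    res$significant_05 <- res$q_value < alpha
    res$significant_01 <- res$q_value < alpha_strict
    rownames(res) <- NULL
    res
}
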