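#' @importFrom ape nj as.phylo prop.clades
NULL

# alignments are named character vectors (strain id -> aligned sequence);
# a list of them, named by gene, represents a multi-marker set.

.alnMatrix <- function(aln) {
    stopifnot(length(aln) >= 2, !is.null(names(aln)))
    L <- unique(nchar(aln))
    if (length(L) != 1) stop("alignment rows differ in length")
    m <- do.call(rbind, strsplit(toupper(aln), ""))
    rownames(m) <- names(aln)
    m
}

#' Remove gap and missing-data columns from an alignment
#'
#' Deletes every column that contains a gap (`-`, `.`) or a missing-data
#' symbol (`N` for nucleotides, `X` for proteins) in any row
#' (complete-deletion mode). Row order is preserved; the operation is
#' idempotent.
#'
#' @param aln named character vector of equal-length aligned sequences.
#' @return the filtered alignment (named character vector).
#' @export
removeGapColumns <- function(aln) {
    m <- .alnMatrix(aln)
    bad <- apply(m, 2, function(col) any(col %in% c("-", ".", "N", "X")))
    if (all(bad)) stop("no columns survive gap/missing-data removal")
    apply(m[, !bad, drop = FALSE], 1, paste0, collapse = "")
}

#' Concatenate marker alignments in a fixed gene order
#'
#' Rows are concatenated strain-wise in the order the genes are given; all
#' genes must cover the identical strain set. Per-gene lengths are recorded
#' and their sum always equals the total length.
#'
#' @param alns named list of alignments (named character vectors), in
#'   concatenation order.
#' @return `list(rows, gene_order, gene_lengths, total_length)`.
#' @export
concatenateAlignments <- function(alns) {
    stopifnot(length(alns) >= 1)
    strains <- sort(names(alns[[1]]))
    for (g in seq_along(alns)) {
        s <- sort(names(alns[[g]]))
        if (!identical(s, strains)) {
            off <- c(setdiff(strains, s), setdiff(s, strains))
            stop("strain sets differ between genes; offenders: ",
                 paste(off, collapse = ", "))
        }
    }
    ord <- names(alns[[1]])
    rows <- stats::setNames(rep("", length(ord)), ord)
    lens <- integer(length(alns))
    for (g in seq_along(alns)) {
        lens[[g]] <- unique(nchar(alns[[g]]))[[1]]
        rows <- paste0(rows, alns[[g]][ord])
    }
    rows <- stats::setNames(rows, ord)
    tot <- unique(nchar(rows))[[1]]
    stopifnot(tot == sum(lens))
    list(rows = rows,
         gene_order = names(alns) %||% as.character(seq_along(alns)),
         gene_lengths = stats::setNames(lens, names(alns)),
         total_length = tot)
}

#' Percent identity between two aligned sequences
#'
#' `100 * matches / comparable columns`, where a column is comparable when
#' both rows carry an unambiguous base (A, C, G or T); pairwise gap and
#' ambiguity columns are excluded.
#'
#' @param a,b aligned sequences of equal length.
#' @return percent identity; `NA` with a warning when no column is comparable.
#' @export
percentIdentity <- function(a, b) {
    stopifnot(nchar(a) == nchar(b))
    x <- strsplit(toupper(a), "")[[1]]
    y <- strsplit(toupper(b), "")[[1]]
    ok <- x %in% c("A", "C", "G", "T") & y %in% c("A", "C", "G", "T")
    if (!any(ok)) {
        warning("no comparable columns")
        return(NA_real_)
    }
    100 * sum(x[ok] == y[ok]) / sum(ok)
}

#' Pairwise distance matrix from an alignment
#'
#' The p-distance is the mismatch fraction over columns where both
#' sequences carry an unambiguous base; the JC69 distance is
#' `-(3/4) * log(1 - 4p/3)`, defined only for `p < 0.75`.
#'
#' @param aln named character vector of aligned sequences (>= 3), typically
#'   the `rows` of [concatenateAlignments()].
#' @param model `"p-distance"` or `"JC69"`.
#' @return `list(values, model)` with a symmetric zero-diagonal matrix.
#' @export
distanceMatrix <- function(aln, model = c("p-distance", "JC69")) {
    model <- match.arg(model)
    if (is.list(aln) && !is.null(aln$rows)) aln <- aln$rows
    if (length(aln) < 3) stop("need at least 3 strains")
    m <- .alnMatrix(aln)
    base <- m %in% c("A", "C", "G", "T")
    dim(base) <- dim(m)
    n <- nrow(m)
    d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
    for (i in seq_len(n - 1)) {
        for (j in seq(i + 1, n)) {
            ok <- base[i, ] & base[j, ]
            p <- if (any(ok)) mean(m[i, ok] != m[j, ok]) else NA_real_
            if (model == "JC69") {
                if (!is.na(p) && p >= 0.75)
                    stop("JC69 undefined (p >= 0.75) for pair ",
                         rownames(m)[[i]], " / ", rownames(m)[[j]])
                p <- -0.75 * log(1 - 4 * p / 3)
            }
            d[i, j] <- d[j, i] <- p
        }
    }
    if (any(!is.finite(d))) stop("non-finite distances")
    list(values = d, model = model)
}

.asDistMatrix <- function(d) {
    if (is.list(d) && !is.null(d$values)) d <- d$values
    if (methods::is(d, "ANIMatrix")) stop("convert ANI first with aniToDistance()")
    stopifnot(is.matrix(d))
    d
}

#' Neighbor-joining and UPGMA trees from a distance matrix
#'
#' `njTree()` runs canonical neighbor joining (via [ape::nj()]); negative
#' branch lengths are clamped to zero with a message. `upgmaTree()` runs
#' average-linkage agglomeration, producing an ultrametric tree; the
#' underlying `hclust` object travels in the `"hclust"` attribute for
#' threshold cutting.
#'
#' @param d a distance matrix (symmetric numeric matrix, or the list from
#'   [distanceMatrix()]).
#' @return an [ape::phylo] tree.
#' @export
njTree <- function(d) {
    d <- .asDistMatrix(d)
    if (any(!is.finite(d))) stop("non-finite distances")
    tr <- ape::nj(stats::as.dist(d))
    if (any(tr$edge.length < 0)) {
        message("clamping ", sum(tr$edge.length < 0),
                " negative NJ branch length(s) to 0")
        tr$edge.length[tr$edge.length < 0] <- 0
    }
    tr
}

#' @rdname njTree
#' @export
upgmaTree <- function(d) {
    d <- .asDistMatrix(d)
    if (any(!is.finite(d))) stop("non-finite distances")
    hc <- stats::hclust(stats::as.dist(d), method = "average")
    tr <- ape::as.phylo(hc)
    attr(tr, "hclust") <- hc
    tr
}

#' Bootstrap support for a distance tree
#'
#' Resamples alignment columns with replacement, rebuilds the tree for each
#' replicate, and annotates each internal node of the full-data tree with
#' the percentage of replicates containing its bipartition. Deterministic
#' for a given seed.
#'
#' @param aln named character vector of aligned sequences (>= 4 strains).
#' @param tree_builder `"nj"` or `"upgma"`.
#' @param model distance model, see [distanceMatrix()].
#' @param n_replicates number of bootstrap replicates (default 1000).
#' @param seed RNG seed.
#' @return the full-data [ape::phylo] with percent supports in `node.label`.
#' @export
bootstrapSupport <- function(aln, tree_builder = c("nj", "upgma"),
                             model = "p-distance", n_replicates = 1000L,
                             seed = 1L) {
    tree_builder <- match.arg(tree_builder)
    if (length(aln) < 4) stop("need at least 4 taxa")
    build <- function(a) {
        d <- distanceMatrix(a, model)
        if (tree_builder == "nj") njTree(d) else upgmaTree(d)
    }
    ref <- build(aln)
    m <- .alnMatrix(aln)
    L <- ncol(m)
    boots <- withSeed(seed, lapply(seq_len(n_replicates), function(i) {
        cols <- sample.int(L, L, replace = TRUE)
        build(apply(m[, cols, drop = FALSE], 1, paste0, collapse = ""))
    }))
    counts <- ape::prop.clades(ref, boots, rooted = FALSE)
    counts[is.na(counts)] <- 0L
    ref$node.label <- round(100 * counts / n_replicates, 1)
    ref
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global RNG seeded to `seed` and restores the
#' previous RNG state afterwards, so seeded helpers do not disturb the
#' caller's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
withSeed <- function(seed, expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
           else NULL
    on.exit({
        if (is.null(old)) rm(".Random.seed", envir = globalenv())
        else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
    expr
}
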